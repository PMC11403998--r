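# Pipeline orchestration: a single configuration drives the synthetic demo
# dataset, the assembled-genome scan, the short-read scan, orthology,
# dating and population/annotation stages, with deterministic seeding and a
# digest manifest. Stages exchange data through plain-text files in the
# output directory, so individual stages can be re-run.

.NUMT_STAGES <- c("simulate", "scan", "wgs", "orthology", "dating",
                  "popannot")

#' Default pipeline configuration
#'
#' All filter thresholds at their standard values: score threshold 30,
#' region merge gap 20 kb, contig-end exclusion 1 kb, breakpoint support 3,
#' clip length 7, clip identity 0.75, E-value 1e-4, breakpoint grouping
#' 100 bp, R1 0.75, R2 0.30/0.80, minimum NUMT length 30 bp, minimum 2
#' datasets, polymorphism threshold 0.97.
#'
#' @param seed Integer seed for the whole run.
#' @export
default_numt_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(
      genome_length = 1000000L, mt_length = 16600L,
      mito_rate = 2e-8, nuclear_rate = 2.2e-9, kappa = 4,
      n_wgs_samples = 3L, depth = 20, read_len = 100L,
      insert_size = 300L, error_rate = 0.01,
      n_reference_numts = 5L, n_novel_numts = 3L,
      min_numt_len = 100L, max_numt_len = 2000L),
    scoring = list(match = 1L, mismatch = -1L, gap_open = 7L,
                   gap_extend = 1L),
    thresholds = list(
      score = 30L, merge_gap = 20000L, end_exclusion = 1000L,
      clip_support = 3L, clip_len = 7L, identity = 0.75,
      e_value = 1e-4, group_window = 100L,
      r1 = 0.75, r2_low = 0.30, r2_high = 0.80,
      min_length = 30L, min_datasets = 2L, polymorphic = 0.97),
    rates = list(mammalian = 2.2e-9, ruminant = 2.48e-9,
                 pig_pedigree = 1.2e-9),
    divergence = list(sus = 3.5, suinae = 10, root = 55),
    dloop = c(15400L, 16600L))
}

#' Validate a pipeline configuration
#'
#' Type/range checks on every threshold; warns when a standard default is
#' overridden.
#'
#' @param config Configuration list (e.g. from [default_numt_config()] or
#'   `yaml::read_yaml`).
#' @return Invisibly TRUE; stops with an informative message otherwise.
#' @export
validate_numt_config <- function(config) {
  ref <- default_numt_config()
  th <- config$thresholds
  if (is.null(th)) stop("config$thresholds missing")
  missing <- setdiff(names(ref$thresholds), names(th))
  if (length(missing)) {
    stop("thresholds missing: ", paste(missing, collapse = ", "))
  }
  num <- vapply(th, is.numeric, logical(1))
  if (!all(num)) stop("non-numeric threshold: ",
                      paste(names(th)[!num], collapse = ", "))
  if (th$r2_high <= th$r2_low) stop("r2_high must exceed r2_low")
  if (th$identity < 0 || th$identity > 1) stop("identity outside [0, 1]")
  if (th$polymorphic <= 0 || th$polymorphic > 1) {
    stop("polymorphic threshold outside (0, 1]")
  }
  for (r in names(config$rates)) {
    if (config$rates[[r]] <= 0) stop("non-positive rate: ", r)
  }
  overridden <- names(ref$thresholds)[vapply(names(ref$thresholds),
    function(k) !isTRUE(all.equal(as.numeric(ref$thresholds[[k]]),
                                  as.numeric(th[[k]]))), logical(1))]
  if (length(overridden)) {
    warning("standard thresholds overridden: ",
            paste(overridden, collapse = ", "))
  }
  invisible(TRUE)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
.read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

.require_stage_file <- function(path, stage, needed_by) {
  if (!file.exists(path)) {
    stop("stage '", needed_by, "' requires '", basename(path),
         "' produced by stage '", stage, "'; run that stage first",
         call. = FALSE)
  }
  path
}

# Demo design: reference NUMTs (present in the scrofa reference and shared
# by age across species genomes) plus novel polymorphic NUMTs carried only
# by WGS samples. Ages are drawn from the class scaffold so every age class
# below the bovid split is represented.
.design_insertions <- function(cfg, spec, seed) {
  set.seed(seed)
  sim <- cfg$simulate
  n_ref <- sim$n_reference_numts
  n_nov <- sim$n_novel_numts
  n <- n_ref + n_nov
  glen <- sim$genome_length
  margin <- cfg$thresholds$end_exclusion + 5000L
  pos <- sort(sample(seq(margin, glen - margin), n))
  # keep planted loci well apart so regions never merge by accident
  while (any(diff(pos) < cfg$thresholds$merge_gap + 5000L)) {
    pos <- sort(sample(seq(margin, glen - margin), n))
  }
  lens <- sample(seq(sim$min_numt_len, sim$max_numt_len), n, replace = TRUE)
  ref_ages <- sample(c(1, 2.5, 5, 8, 20, 40), n_ref, replace = TRUE)
  nov_ages <- stats::runif(n_nov, 0.05, 0.5)   # young, segregating
  wgs <- paste0("s", seq_len(sim$n_wgs_samples))
  species_genomes <- c(ref_scrofa = "scrofa", g_cebifrons = "cebifrons",
                       g_warthog = "warthog")
  L <- sim$mt_length
  ins <- list()
  for (i in seq_len(n)) {
    is_ref <- i <= n_ref
    age <- if (is_ref) ref_ages[i] else nov_ages[i - n_ref]
    mt_start <- sample.int(L - 1L, 1L) - 1L
    mt_end <- mt_start + lens[i]
    wrap <- mt_end > L
    if (wrap) mt_end <- mt_end - L
    gt <- character(0)
    for (gname in names(species_genomes)) {
      carried <- is_ref &&
        age >= .divergence_mya(spec, "scrofa", species_genomes[[gname]])
      gt[gname] <- if (carried) "hom_ins" else "absent"
    }
    for (s in wgs) {
      gt[s] <- if (is_ref) "hom_ins"
        else sample(c("hom_ins", "het", "absent"), 1L)
    }
    if (!is_ref) {
      # a novel locus must be carried by at least two datasets to survive
      carriers <- wgs[gt[wgs] != "absent"]
      if (length(carriers) < 2L) {
        gt[sample(wgs, 2L)] <- c("het", "hom_ins")
      }
    }
    ins[[i]] <- insertion_spec(
      id = sprintf("%s%02d", if (is_ref) "ref" else "nov", i),
      host_contig = "chr1", host_position = pos[i],
      mt_start = mt_start, mt_end = mt_end, wraparound = wrap,
      age = age, species = "scrofa", genotypes = gt)
  }
  ins
}

.stage_simulate <- function(cfg, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  sim <- cfg$simulate
  spec <- suinae_tree_spec(mito_rate = sim$mito_rate,
                           nuclear_rate = sim$nuclear_rate,
                           kappa = sim$kappa, mt_length = sim$mt_length)
  seed <- cfg$seed
  cassettes <- data.frame(
    pos = as.integer(sim$genome_length * c(0.31, 0.56, 0.81)),
    seq = c(strrep("AT", 150), strrep("TAGGC", 60), strrep("AG", 150)),
    class = c("simple_AT", "SINE_like", "simple_AG"))
  bg <- background_genome(sim$genome_length, seed = seed + 1L,
                          cassettes = cassettes)
  ins <- .design_insertions(cfg, spec, seed + 2L)
  wgs <- paste0("s", seq_len(sim$n_wgs_samples))
  samples <- data.frame(
    sample = c("ref_scrofa", "g_cebifrons", "g_warthog", wgs),
    species = c("scrofa", "cebifrons", "warthog",
                rep("scrofa", length(wgs))), stringsAsFactors = FALSE)
  planted <- plant_numts(bg, ins, spec, seed = seed + 3L,
                         samples = samples)
  # genome FASTAs (hap1 = the assembled genome of each sample/species)
  for (g in c("ref_scrofa", "g_cebifrons", "g_warthog")) {
    write_fasta(stats::setNames(list(planted$genomes[[g]]$hap1), "chr1"),
                file.path(out, paste0(g, ".fa")))
  }
  write_fasta(as.list(planted$mt$tips), file.path(out, "mtdna_tips.fa"))
  write_fasta(as.list(planted$mt$ancestors),
              file.path(out, "mtdna_ancestors.fa"))
  .write_tsv(planted$truth, file.path(out, "truth.tsv"))
  .write_tsv(planted$truth_amr, file.path(out, "truth_amr.tsv"))
  bed <- planted$truth[planted$truth$haplotype == "hap1", ]
  .write_tsv(data.frame(contig = bed$contig, start = bed$start,
                        end = bed$end, name = bed$insertion,
                        score = 0L, strand = "+"),
             file.path(out, "truth.bed"))
  .write_tsv(bg$repeats, file.path(out, "repeats.tsv"))
  # simple gene annotation around the middle of the contig
  gl <- sim$genome_length
  genes <- data.frame(
    contig = "chr1",
    start = as.integer(gl * c(0.10, 0.10, 0.45, 0.45, 0.72)),
    end = as.integer(gl * c(0.14, 0.105, 0.50, 0.47, 0.74)),
    type = c("gene", "exon", "gene", "exon", "gene"),
    gene = c("GENE1", "GENE1", "GENE2", "GENE2", "GENE3"))
  con <- file(file.path(out, "genes.gff3"), "w")
  writeLines("##gff-version 3", con)
  writeLines(sprintf("chr1\tdemo\t%s\t%d\t%d\t.\t+\t.\tID=%s;Name=%s",
                     genes$type, genes$start + 1L, genes$end,
                     paste0(genes$gene, "_", genes$type), genes$gene), con)
  close(con)
  # WGS reads against the scrofa reference genome (which contains the
  # reference NUMTs): only novel insertions produce soft clips
  ref_seq <- planted$genomes$ref_scrofa$hap1
  ref_ins <- planted$truth$insertion[planted$truth$sample == "ref_scrofa"]
  for (k in seq_along(wgs)) {
    s <- wgs[k]
    tr <- planted$truth[planted$truth$sample == s, , drop = FALSE]
    novel <- tr[!(tr$insertion %in% ref_ins), , drop = FALSE]
    # reference breakpoint relative to the reference genome: shift the
    # background breakpoint by the reference insertions inserted before it
    shift_ref <- vapply(novel$ref_breakpoint, function(p) {
      rr <- planted$truth[planted$truth$sample == "ref_scrofa" &
                            planted$truth$ref_breakpoint <= p, , drop = FALSE]
      sum(rr$length)
    }, numeric(1))
    novel$ref_breakpoint <- novel$ref_breakpoint + as.integer(shift_ref)
    # haplotype coordinates of novel blocks are already correct per
    # haplotype; recompute start/end relative to each haplotype with the
    # shared (reference) insertions treated as reference sequence
    rd <- simulate_reads(planted$genomes[[s]], ref_seq, contig = "chr1",
                         truth = novel, depth = sim$depth,
                         read_len = sim$read_len,
                         insert_size = sim$insert_size,
                         error_rate = sim$error_rate,
                         seed = seed + 10L + k, sample_id = s)
    write_sam(rd$sam, rd$sq, file.path(out, paste0(s, ".sam")))
    .write_tsv(rd$breakpoints, file.path(out, paste0(s, ".breakpoints.tsv")))
  }
  .write_tsv(samples, file.path(out, "samples.tsv"))
  invisible(planted)
}

.stage_scan <- function(cfg, out) {
  sc <- scoring_scheme(cfg$scoring$match, cfg$scoring$mismatch,
                       cfg$scoring$gap_open, cfg$scoring$gap_extend,
                       min_score = cfg$thresholds$score)
  mt_path <- .require_stage_file(file.path(out, "mtdna_tips.fa"),
                                 "simulate", "scan")
  tips <- read_fasta(mt_path)
  all_hits <- NULL; all_regions <- NULL
  mt_of <- c(ref_scrofa = "scrofa", g_cebifrons = "cebifrons",
             g_warthog = "warthog")
  for (g in names(mt_of)) {
    genome <- read_fasta(.require_stage_file(
      file.path(out, paste0(g, ".fa")), "simulate", "scan"))
    thr <- calibrate_score_threshold(tips[[mt_of[[g]]]], genome, sc)
    eff <- min(as.integer(thr), cfg$thresholds$score)
    sc_g <- sc; sc_g$min_score <- eff
    hits <- scan_assembly(genome, tips[[mt_of[[g]]]], scoring = sc_g,
                          genome_id = g,
                          min_length = cfg$thresholds$min_length,
                          end_exclusion = cfg$thresholds$end_exclusion)
    br <- build_regions(hits, merge_gap = cfg$thresholds$merge_gap)
    all_hits <- rbind(all_hits, br$hits)
    all_regions <- rbind(all_regions, br$regions)
  }
  .write_tsv(all_hits, file.path(out, "numt_hits.tsv"))
  .write_tsv(all_regions, file.path(out, "numt_regions.tsv"))
  ref_regions <- all_regions[all_regions$genome_id == "ref_scrofa", ,
                             drop = FALSE]
  .write_tsv(data.frame(contig = ref_regions$contig,
                        start = ref_regions$start, end = ref_regions$end,
                        name = ref_regions$region_id, score = 0L,
                        strand = "+"),
             file.path(out, "numt_regions.bed"))
  export_gff(all_regions[all_regions$genome_id == "ref_scrofa", ],
             all_hits[all_hits$genome_id == "ref_scrofa", ],
             file.path(out, "numt_regions.gff3"))
  invisible(list(hits = all_hits, regions = all_regions))
}

.stage_wgs <- function(cfg, out) {
  th <- cfg$thresholds
  sc <- scoring_scheme(cfg$scoring$match, cfg$scoring$mismatch,
                       cfg$scoring$gap_open, cfg$scoring$gap_extend)
  samples <- .read_tsv(.require_stage_file(file.path(out, "samples.tsv"),
                                           "simulate", "wgs"))
  wgs <- samples$sample[grepl("^s[0-9]+$", samples$sample)]
  regions <- .read_tsv(.require_stage_file(
    file.path(out, "numt_regions.tsv"), "scan", "wgs"))
  regions <- regions[regions$genome_id == "ref_scrofa", , drop = FALSE]
  tips <- read_fasta(file.path(out, "mtdna_tips.fa"))
  mt <- tips[["scrofa"]]
  all_bp <- NULL
  recs_of <- list(); depth_of <- list(); cov_of <- list()
  for (s in wgs) {
    sam <- read_sam(.require_stage_file(file.path(out, paste0(s, ".sam")),
                                        "simulate", "wgs"))
    recs <- .prep_records(sam$records)
    recs_of[[s]] <- recs
    cov <- coverage_from_sam(recs, sam$sq$name[1], sam$sq$length[1])
    cov_of[[s]] <- cov
    depth_of[[s]] <- estimate_depth(cov)
    bp <- detect_breakpoints(sam, min_support = th$clip_support,
                             min_clip_len = th$clip_len, sample_id = s)
    keep <- vapply(seq_len(nrow(bp)), function(i) {
      depth_filter(bp[i, ], cov, depth_of[[s]])
    }, logical(1))
    all_bp <- rbind(all_bp, bp[keep, , drop = FALSE])
  }
  loci <- group_loci(all_bp, window = th$group_window)
  bps <- attr(loci, "breakpoints")
  genos <- NULL
  loci$novel <- vapply(seq_len(nrow(loci)), function(i) {
    classify_novel(loci[i, ], regions)
  }, logical(1))
  loci$length <- NA_integer_
  loci$mt_intervals <- NA_character_
  for (i in seq_len(nrow(loci))) {
    lid <- loci$locus_id[i]
    members <- bps[bps$locus_id == lid, , drop = FALSE]
    # putative sequence from the best-supported breakpoint across samples
    best <- members[which.max(members$n_clip_reads), , drop = FALSE]
    mc <- match_clips(best, recs_of[[best$sample_id]], mt, scoring = sc,
                      min_clip_len = th$clip_len,
                      min_identity = th$identity,
                      max_evalue = th$e_value)
    loci$length[i] <- nchar(mc$sequence)
    if (nrow(mc$mt_intervals)) {
      loci$mt_intervals[i] <- paste(
        sprintf("%d-%d", mc$mt_intervals$mt_start, mc$mt_intervals$mt_end),
        collapse = ",")
    }
    for (s in wgs) {
      g <- genotype_locus(loci[i, ],
                          members[members$sample_id == s, , drop = FALSE],
                          recs_of[[s]], mt, scoring = sc,
                          min_clip_len = th$clip_len,
                          min_identity = th$identity,
                          max_evalue = th$e_value, sample_id = s)
      g$sample_id <- s
      genos <- rbind(genos, g)
    }
  }
  accepted <- finalize_novel(loci, genos, regions,
                             min_length = th$min_length,
                             min_datasets = th$min_datasets)
  .write_tsv(loci, file.path(out, "wgs_loci.tsv"))
  .write_tsv(genos, file.path(out, "wgs_genotypes.tsv"))
  .write_tsv(as.data.frame(accepted), file.path(out, "wgs_novel.tsv"))
  .write_tsv(attr(accepted, "reject_reasons"),
             file.path(out, "wgs_reject_reasons.tsv"))
  gm <- unique(genos[, c("locus_id", "sample_id", "genotype", "carrier")])
  .write_tsv(gm, file.path(out, "wgs_genotype_matrix.tsv"))
  invisible(list(loci = loci, genotypes = genos, novel = accepted))
}

.stage_orthology <- function(cfg, out) {
  truth <- .read_tsv(.require_stage_file(file.path(out, "truth.tsv"),
                                         "simulate", "orthology"))
  regions <- .read_tsv(.require_stage_file(
    file.path(out, "numt_regions.tsv"), "scan", "orthology"))
  planted <- list(
    genomes = list(), truth = truth,
    background = list(seq = paste(character(0)))
  )
  # reconstruct the genome sequences from the stage files
  for (g in c("ref_scrofa", "g_cebifrons", "g_warthog")) {
    fa <- read_fasta(file.path(out, paste0(g, ".fa")))
    planted$genomes[[g]] <- list(hap1 = fa[["chr1"]])
  }
  ref_len <- nchar(planted$genomes$ref_scrofa$hap1) -
    sum(truth$length[truth$sample == "ref_scrofa" &
                       truth$haplotype == "hap1"])
  planted$background$seq <- strrep("N", ref_len)   # length carrier only
  statuses <- NULL
  ref_regions <- regions[regions$genome_id == "ref_scrofa", , drop = FALSE]
  for (other in c("g_cebifrons", "g_warthog")) {
    blocks <- emit_pairwise_maf(planted, "ref_scrofa", other)
    write_maf(blocks, file.path(out, paste0("ref_vs_", other, ".maf")))
    oregions <- regions[regions$genome_id == other, , drop = FALSE]
    for (i in seq_len(nrow(ref_regions))) {
      st <- map_region_status(ref_regions[i, ], blocks, oregions)
      statuses <- rbind(statuses, data.frame(
        region_id = ref_regions$region_id[i], genome_id = other,
        status = st$status,
        aligned_fraction = st$aligned_fraction, stringsAsFactors = FALSE))
    }
  }
  statuses <- rbind(statuses, data.frame(
    region_id = ref_regions$region_id, genome_id = "ref_scrofa",
    status = "CORRESPONDING", aligned_fraction = 1))
  .write_tsv(statuses, file.path(out, "orthology_status.tsv"))
  pm <- build_presence_matrix(statuses, regions = ref_regions)
  mdf <- cbind(region_id = rownames(pm$matrix), pm$matrix)
  .write_tsv(mdf, file.path(out, "presence_matrix.tsv"))
  .write_tsv(pm$groups, file.path(out, "presence_groups.tsv"))
  invisible(statuses)
}

.stage_dating <- function(cfg, out) {
  statuses <- .read_tsv(.require_stage_file(
    file.path(out, "orthology_status.tsv"), "orthology", "dating"))
  regions <- .read_tsv(.require_stage_file(
    file.path(out, "numt_regions.tsv"), "scan", "dating"))
  hits <- .read_tsv(file.path(out, "numt_hits.tsv"))
  tips <- read_fasta(file.path(out, "mtdna_tips.fa"))
  sim <- cfg$simulate
  spec <- suinae_tree_spec(mito_rate = sim$mito_rate,
                           nuclear_rate = sim$nuclear_rate,
                           kappa = sim$kappa, mt_length = sim$mt_length)
  fit <- fitch_ancestral(tips, spec$tree, node = "sus")
  genome <- read_fasta(file.path(out, "ref_scrofa.fa"))[["chr1"]]
  rates <- mutation_rate_config(cfg$rates$mammalian, cfg$rates$ruminant,
                                cfg$rates$pig_pedigree)
  ref_regions <- regions[regions$genome_id == "ref_scrofa", , drop = FALSE]
  ages <- NULL
  for (i in seq_len(nrow(ref_regions))) {
    r <- ref_regions[i, ]
    present <- function(g) {
      any(statuses$region_id == r$region_id & statuses$genome_id == g &
            statuses$status %in% c("CORRESPONDING", "COMPATIBLE_SEQUENCE"))
    }
    cls <- assign_age_class(TRUE, present("g_cebifrons"),
                            present("g_warthog"), FALSE)
    h <- hits[hits$genome_id == "ref_scrofa" &
                hits$region_id == r$region_id, , drop = FALSE]
    frags <- data.frame(
      mt_start = h$qstart, mt_end = h$qend,
      numt_seq = vapply(seq_len(nrow(h)), function(j) {
        substr(genome, h$tstart[j] + 1L, h$tend[j])
      }, character(1)))
    # indel-free fragments only: sequence length must equal the mt span
    frags <- frags[nchar(frags$numt_seq) ==
                     frags$mt_end - frags$mt_start, , drop = FALSE]
    est <- date_region(r, frags, cls,
                       mt_panel = list(ancestral = fit$sequence,
                                       modern = tips[["scrofa"]]),
                       dist_panel = list(species_seqs = as.list(tips),
                                         host = "scrofa", spec = spec),
                       rates = rates, dloop = cfg$dloop)
    ages <- rbind(ages, data.frame(
      region_id = r$region_id, age_class = est$age_class,
      method = est$method, age_mya = est$age_mya,
      amr = if (!is.null(est$amr)) est$amr else NA_real_,
      K = if (!is.null(est$K)) est$K else NA_real_,
      v_mt = if (!is.null(est$v_mt)) est$v_mt else NA_real_,
      age_ruminant = if (!is.null(est$ages_by_rate))
        est$ages_by_rate[["ruminant"]] else NA_real_,
      age_pig_pedigree = if (!is.null(est$ages_by_rate))
        est$ages_by_rate[["pig_pedigree"]] else NA_real_,
      stringsAsFactors = FALSE))
  }
  .write_tsv(ages, file.path(out, "region_ages.tsv"))
  invisible(ages)
}

.stage_popannot <- function(cfg, out) {
  genos <- .read_tsv(.require_stage_file(
    file.path(out, "wgs_genotype_matrix.tsv"), "wgs", "popannot"))
  loci <- .read_tsv(file.path(out, "wgs_loci.tsv"))
  regions <- .read_tsv(file.path(out, "numt_regions.tsv"))
  ages <- .read_tsv(.require_stage_file(file.path(out, "region_ages.tsv"),
                                        "dating", "popannot"))
  genos$region_id <- genos$locus_id
  ids <- sort(unique(genos$sample_id))
  groups <- stats::setNames(sub("^s", "breed", ids), ids)
  cf <- carrier_frequencies(genos, groups, min_datasets = 1L)
  freq_tab <- cbind(region_id = rownames(cf$table),
                    as.data.frame(cf$table))
  .write_tsv(freq_tab, file.path(out, "carrier_frequencies.tsv"))
  ancient <- ages$region_id[ages$age_class == "GT_55"]
  fn <- estimate_false_negative_rate(
    genos[genos$region_id %in% ancient, , drop = FALSE])
  species_freq <- rowMeans(cf$table, na.rm = TRUE)
  poly <- call_polymorphic(species_freq, fn,
                           fallback = cfg$thresholds$polymorphic)
  .write_tsv(data.frame(region_id = names(poly),
                        carrier_fraction = unname(species_freq),
                        polymorphic = unname(poly)),
             file.path(out, "polymorphic.tsv"))
  if (ncol(cf$table) >= 3L) {
    cl <- upgma_cluster(cf$table)
    writeLines(cl$newick, file.path(out, "breeds_upgma.nwk"))
  }
  ref_regions <- regions[regions$genome_id == "ref_scrofa", , drop = FALSE]
  genome <- read_fasta(file.path(out, "ref_scrofa.fa"))
  repeats <- tryCatch(.read_tsv(file.path(out, "repeats.tsv")),
                      error = function(e) NULL)
  ann <- annotate_regions(ref_regions, file.path(out, "genes.gff3"),
                          repeats = repeats, genome = genome)
  .write_tsv(ann, file.path(out, "annotation.tsv"))
  invisible(list(frequencies = cf, fn_rate = fn, polymorphic = poly,
                 annotation = ann))
}

#' Run the NUMT atlas pipeline
#'
#' Executes the requested stages in dependency order
#' (simulate, scan, wgs, orthology, dating, popannot), writing all outputs
#' as plain-text files under `out` plus a `manifest.json` with the seed and
#' an md5 digest of every output file. All randomness derives from
#' `config$seed`, so a rerun with the same configuration is byte-identical.
#'
#' @param config Configuration list ([default_numt_config()]); may also be
#'   a path to a YAML file.
#' @param out Output directory.
#' @param stages Character vector of stages to run (default: all).
#' @param seed Optional seed override.
#' @return Invisibly, the manifest.
#' @export
run_numt_pipeline <- function(config = default_numt_config(), out,
                              stages = .NUMT_STAGES, seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- utils::modifyList(default_numt_config(),
                                yaml::read_yaml(config))
  }
  if (!is.null(seed)) config$seed <- as.integer(seed)
  validate_numt_config(config)
  bad <- setdiff(stages, .NUMT_STAGES)
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         "; valid stages: ", paste(.NUMT_STAGES, collapse = ", "))
  }
  stages <- .NUMT_STAGES[.NUMT_STAGES %in% stages]
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  runner <- list(simulate = .stage_simulate, scan = .stage_scan,
                 wgs = .stage_wgs, orthology = .stage_orthology,
                 dating = .stage_dating, popannot = .stage_popannot)
  for (st in stages) {
    message("[numt-atlas] stage: ", st)
    runner[[st]](config, out)
  }
  files <- setdiff(list.files(out, recursive = TRUE), "manifest.json")
  manifest <- list(
    seed = config$seed,
    stages = stages,
    package = as.character(utils::packageVersion("numtatlas")),
    files = lapply(stats::setNames(files, files), function(f) {
      unname(tools::md5sum(file.path(out, f)))
    }))
  writeLines(.manifest_json(manifest), file.path(out, "manifest.json"))
  invisible(manifest)
}

# minimal canonical JSON for the manifest (stable key order, no
# dependency on serializer defaults)
.manifest_json <- function(x) {
  esc <- function(s) gsub('"', '\\\\"', s)
  files <- vapply(names(x$files), function(f) {
    sprintf('    "%s": "%s"', esc(f), x$files[[f]])
  }, character(1))
  paste0('{\n  "seed": ', x$seed, ',\n  "stages": [',
         paste(sprintf('"%s"', x$stages), collapse = ", "),
         '],\n  "package": "', x$package, '",\n  "files": {\n',
         paste(files, collapse = ",\n"), '\n  }\n}')
}
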
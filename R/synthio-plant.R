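#' Specify one NUMT insertion to plant
#'
#' @param id Insertion identifier.
#' @param host_contig Contig the insertion lands in.
#' @param host_position 0-based offset in the background (pre-insertion)
#'   coordinate system; the insertion is placed before this base.
#' @param mt_start,mt_end 0-based half-open interval on the circular mtDNA.
#'   `mt_end` may be smaller than `mt_start` only when `wraparound = TRUE`,
#'   in which case the segment crosses the circular origin.
#' @param age Insertion age in Mya (>= 0). The inserted copy is the true
#'   mtDNA of the host lineage at that time, subsequently evolved at the
#'   nuclear rate for `age` years.
#' @param species Species lineage in which the insertion occurred; defaults
#'   to the species of the first carrier sample.
#' @param fragmentation Optional list with elements `deletions` (data.frame
#'   `start`,`end`: 0-based half-open, non-overlapping, relative to the
#'   inserted segment) and `inversions` (same shape; segments are
#'   reverse-complemented in place). Deletions are applied after inversions.
#' @param genotypes Named character vector mapping sample ids to one of
#'   `"hom_ins"`, `"het"`, `"absent"`.
#' @return A list of class `numt_insertion_spec`.
#' @export
insertion_spec <- function(id, host_contig, host_position, mt_start, mt_end,
                           age, genotypes, species = NULL,
                           wraparound = FALSE, fragmentation = NULL) {
  stopifnot(host_position >= 0, mt_start >= 0, age >= 0)
  if (!wraparound && mt_end <= mt_start) {
    stop("mt_end <= mt_start without wraparound flag")
  }
  if (!is.null(fragmentation$deletions) && nrow(fragmentation$deletions) > 1) {
    d <- fragmentation$deletions[order(fragmentation$deletions$start), ]
    if (any(d$start[-1] < d$end[-nrow(d)])) {
      stop("fragmentation deletions overlap")
    }
  }
  stopifnot(all(genotypes %in% c("hom_ins", "het", "absent")))
  structure(list(id = id, host_contig = host_contig,
                 host_position = as.integer(host_position),
                 mt_start = as.integer(mt_start), mt_end = as.integer(mt_end),
                 wraparound = wraparound, age = age, species = species,
                 fragmentation = fragmentation, genotypes = genotypes),
            class = "numt_insertion_spec")
}

#' Generate a random nuclear background contig
#'
#' I.i.d. bases at the given GC content (default 41.6%, a mammalian
#' genome-wide value), with optional planted sequence cassettes (e.g. simple
#' repeats or SINE-like elements) for annotation and masking tests.
#'
#' @param length Contig length in bp (before cassette insertion).
#' @param seed Integer seed.
#' @param gc GC fraction.
#' @param contig Contig name.
#' @param cassettes Optional data.frame with columns `pos` (0-based offset in
#'   the plain background), `seq`, `class`; cassettes are inserted left to
#'   right.
#' @return List with `contig`, `seq` (character) and `repeats` (data.frame of
#'   realised 0-based half-open cassette coordinates and classes).
#' @export
background_genome <- function(length, seed, gc = 0.416, contig = "chr1",
                              cassettes = NULL) {
  set.seed(as.integer(seed))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq <- paste(sample(names(p), length, replace = TRUE, prob = p),
               collapse = "")
  repeats <- data.frame(contig = character(0), start = integer(0),
                        end = integer(0), class = character(0))
  if (!is.null(cassettes) && nrow(cassettes)) {
    cassettes <- cassettes[order(cassettes$pos), , drop = FALSE]
    shift <- 0L
    for (i in seq_len(nrow(cassettes))) {
      at <- cassettes$pos[i] + shift      # 0-based insertion point
      seq <- paste0(substr(seq, 1L, at), cassettes$seq[i],
                    substr(seq, at + 1L, nchar(seq)))
      w <- nchar(cassettes$seq[i])
      repeats <- rbind(repeats, data.frame(
        contig = contig, start = at, end = at + w,
        class = cassettes$class[i]))
      shift <- shift + w
    }
  }
  list(contig = contig, seq = seq, repeats = repeats)
}

# Extract a (possibly wraparound) 0-based half-open interval from a circular
# sequence given as a character string.
.circular_segment <- function(seq, start, end, wraparound) {
  L <- nchar(seq)
  if (!wraparound) {
    if (end > L) stop("mt interval exceeds circular length without ",
                      "wraparound flag")
    return(substr(seq, start + 1L, end))
  }
  paste0(substr(seq, start + 1L, L), substr(seq, 1L, end))
}

.revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Apply a fragmentation plan to an inserted segment. Inversions first (in
# place), then deletions (removing bases). Returns the rearranged sequence.
.apply_fragmentation <- function(seg, plan) {
  if (is.null(plan)) return(seg)
  if (!is.null(plan$inversions) && nrow(plan$inversions)) {
    for (i in seq_len(nrow(plan$inversions))) {
      s <- plan$inversions$start[i]; e <- plan$inversions$end[i]
      mid <- .revcomp_chr(substr(seg, s + 1L, e))
      seg <- paste0(substr(seg, 1L, s), mid, substr(seg, e + 1L, nchar(seg)))
    }
  }
  if (!is.null(plan$deletions) && nrow(plan$deletions)) {
    d <- plan$deletions[order(-plan$deletions$start), , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      seg <- paste0(substr(seg, 1L, d$start[i]),
                    substr(seg, d$end[i] + 1L, nchar(seg)))
    }
  }
  seg
}

#' Plant NUMT insertions of known age into nuclear genomes
#'
#' Builds per-sample nuclear genomes by inserting mtDNA segments into a
#' shared background, together with a ground-truth table. Each inserted copy
#' is taken from the true mtDNA sequence of the host lineage at the insertion
#' age (recorded by the mtDNA simulation), then evolved at the nuclear rate
#' for `age` years, then rearranged by its fragmentation plan — emulating a
#' single insertion event followed by nuclear-rate decay and local
#' rearrangement. Heterozygous samples receive two haplotypes, only the first
#' of which carries the insertion. When several species are present, each
#' species' background is independently evolved from the shared background at
#' the nuclear rate over twice its divergence time from the reference species
#' (the first sample's species), keeping the genomes colinear.
#'
#' @param background A [background_genome()] (the reference-without-insertion
#'   coordinate system).
#' @param insertions List of [insertion_spec()] objects.
#' @param spec A [species_tree_spec()].
#' @param seed Integer seed.
#' @param samples data.frame with columns `sample`, `species`; defaults to
#'   one `hom_ins`-style genome per genotyped sample name, all of the first
#'   tree species.
#' @return A list with `genomes` (per sample: named list of haplotype
#'   character sequences `hap1`/`hap2`), `reference` (per species background
#'   without insertions), `truth` (data.frame: one row per insertion x
#'   carrier haplotype with realised 0-based coordinates, breakpoint, true
#'   age), `truth_amr` (per insertion, allele matching ratio of the planted
#'   copy against each recorded ancestral node of the host lineage and the
#'   modern host mtDNA), `mt` (the simulated mtDNA set), and `insertions`.
#' @export
plant_numts <- function(background, insertions, spec, seed, samples = NULL) {
  stopifnot(inherits(spec, "numt_tree_spec"))
  for (ins in insertions) stopifnot(inherits(ins, "numt_insertion_spec"))
  if (is.null(samples)) {
    ids <- unique(unlist(lapply(insertions, function(i) names(i$genotypes))))
    samples <- data.frame(sample = ids,
                          species = spec$tree$tip.label[1],
                          stringsAsFactors = FALSE)
  }
  ages_ok <- vapply(insertions, function(i) i$age <= root_age(spec) + 1e-9,
                    logical(1))
  if (!all(ages_ok)) stop("insertion age exceeds root age")
  insertions <- lapply(insertions, function(ins) {
    if (is.null(ins$species)) {
      first <- names(ins$genotypes)[ins$genotypes != "absent"][1]
      if (is.na(first)) first <- names(ins$genotypes)[1]
      ins$species <- samples$species[match(first, samples$sample)]
    }
    ins
  })

  sp_points <- data.frame(
    species = vapply(insertions, function(i) i$species, character(1)),
    age = vapply(insertions, function(i) i$age, numeric(1)))
  mt <- simulate_mtdna_set(spec, seed = seed, sample_points = sp_points)

  set.seed(as.integer(seed) + 1L)
  # realised insert sequences
  inserted_seq <- list()
  for (ins in insertions) {
    src <- if (ins$age == 0) {
      mt$tips[[ins$species]]
    } else {
      mt$lineage[[paste0(ins$species, "@", ins$age)]]
    }
    seg <- .circular_segment(src, ins$mt_start, ins$mt_end, ins$wraparound)
    seg_int <- .dna2int(seg)
    seg_int <- .evolve_k80(seg_int, ins$age * 1e6, spec$nuclear_rate,
                           spec$kappa)
    inserted_seq[[ins$id]] <- .apply_fragmentation(.int2dna(seg_int),
                                                   ins$fragmentation)
  }

  # per-species backgrounds (reference species keeps the shared background)
  ref_species <- samples$species[1]
  species_bg <- list()
  for (sp in unique(samples$species)) {
    if (sp == ref_species) {
      species_bg[[sp]] <- background$seq
    } else {
      tdiv <- 2 * .divergence_mya(spec, sp, ref_species) * 1e6
      species_bg[[sp]] <- .int2dna(.evolve_k80(.dna2int(background$seq),
                                               tdiv, spec$nuclear_rate,
                                               spec$kappa))
    }
  }

  ord <- order(vapply(insertions, function(i) i$host_position, integer(1)))
  insertions <- insertions[ord]
  truth <- NULL
  genomes <- list()
  for (si in seq_len(nrow(samples))) {
    sid <- samples$sample[si]
    bg <- species_bg[[samples$species[si]]]
    for (hap in c("hap1", "hap2")) {
      seqh <- bg
      shift <- 0L
      for (ins in insertions) {
        g <- ins$genotypes[[sid]]
        if (is.null(g)) g <- "absent"
        carrier <- g == "hom_ins" || (g == "het" && hap == "hap1")
        if (!carrier) next
        iseq <- inserted_seq[[ins$id]]
        at <- ins$host_position + shift
        seqh <- paste0(substr(seqh, 1L, at), iseq,
                       substr(seqh, at + 1L, nchar(seqh)))
        truth <- rbind(truth, data.frame(
          insertion = ins$id, sample = sid, haplotype = hap,
          contig = ins$host_contig,
          start = at, end = at + nchar(iseq),
          ref_breakpoint = ins$host_position,
          length = nchar(iseq), age = ins$age,
          genotype = g, stringsAsFactors = FALSE))
        shift <- shift + nchar(iseq)
      }
      genomes[[sid]][[hap]] <- seqh
    }
  }

  truth_amr <- .truth_amr_table(insertions, inserted_seq, mt)
  list(genomes = genomes, reference = species_bg, truth = truth,
       truth_amr = truth_amr, mt = mt, insertions = insertions,
       samples = samples, background = background)
}

# Divergence time (Mya) between two tips = height of their MRCA.
.divergence_mya <- function(spec, a, b) {
  if (a == b) return(0)
  tree <- spec$tree
  ia <- match(a, tree$tip.label); ib <- match(b, tree$tip.label)
  mrca <- ape::getMRCA(tree, c(ia, ib))
  unname(spec$heights[tree$node.label[mrca - length(tree$tip.label)]])
}

# True allele matching ratio of each planted (un-fragmented) copy against
# every recorded ancestral node on the host lineage, by direct column
# counting: among columns where the ancestor differs from the modern host
# mtDNA, the fraction where the inserted copy carries the modern allele.
.truth_amr_table <- function(insertions, inserted_seq, mt) {
  out <- NULL
  for (ins in insertions) {
    # fragmentation rearranges coordinates; truth amr is defined on the
    # un-rearranged copy, so recompute it without the plan
    src <- if (ins$age == 0) mt$tips[[ins$species]] else
      mt$lineage[[paste0(ins$species, "@", ins$age)]]
    seg_modern <- .circular_segment(mt$tips[[ins$species]], ins$mt_start,
                                    ins$mt_end, ins$wraparound)
    numt <- inserted_seq[[ins$id]]
    if (!is.null(ins$fragmentation)) next  # rearranged: columns not comparable
    numt_v <- strsplit(numt, "")[[1]]
    modern_v <- strsplit(seg_modern, "")[[1]]
    for (node in .lineage_nodes(mt$spec, ins$species)) {
      anc_seg <- .circular_segment(mt$ancestors[[node]], ins$mt_start,
                                   ins$mt_end, ins$wraparound)
      anc_v <- strsplit(anc_seg, "")[[1]]
      diff_cols <- which(anc_v != modern_v)
      amr <- if (length(diff_cols)) {
        sum(numt_v[diff_cols] == modern_v[diff_cols]) / length(diff_cols)
      } else NA_real_
      out <- rbind(out, data.frame(
        insertion = ins$id, node = node,
        node_age = unname(mt$heights[node]),
        n_diff = length(diff_cols), amr = amr, stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) {
    out <- data.frame(insertion = character(0), node = character(0),
                      node_age = numeric(0), n_diff = integer(0),
                      amr = numeric(0))
  }
  out
}
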
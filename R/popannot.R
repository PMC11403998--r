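# Population-level summaries (carrier frequencies, polymorphism calling,
# UPGMA clustering of breeds) and genomic annotation of NUMT regions.

#' Carrier frequencies per group
#'
#' Fraction of datasets in each breed/group carrying each NUMT insertion.
#' Undetermined calls are excluded from the denominators; assembled-genome
#' statuses may be mixed in by coding CORRESPONDING/COMPATIBLE_SEQUENCE as
#' carrier and PRIVATE as non-carrier (UNALIGNED excluded) before calling.
#'
#' @param calls data.frame with `region_id`, `sample_id` and either
#'   `carrier` (logical) or `genotype` ("hom_ins"/"het"/"absent"/
#'   "undetermined").
#' @param groups Named vector mapping sample_id -> group.
#' @param min_datasets Groups with fewer datasets are flagged
#'   (`eligible = FALSE`) for downstream clustering.
#' @return List with `table` (regions x groups carrier fraction), `n`
#'   (datasets per group x region denominators) and `group_sizes`.
#' @export
carrier_frequencies <- function(calls, groups, min_datasets = 10L) {
  if (!("carrier" %in% names(calls))) {
    calls$carrier <- ifelse(calls$genotype == "undetermined", NA,
                            calls$genotype %in% c("hom_ins", "het"))
  }
  calls$group <- groups[calls$sample_id]
  if (anyNA(calls$group)) {
    warning("samples without group assignment skipped: ",
            paste(unique(calls$sample_id[is.na(calls$group)]),
                  collapse = ", "))
    calls <- calls[!is.na(calls$group), , drop = FALSE]
  }
  calls <- calls[!is.na(calls$carrier), , drop = FALSE]
  regions <- sort(unique(calls$region_id))
  grp <- sort(unique(calls$group))
  freq <- matrix(NA_real_, length(regions), length(grp),
                 dimnames = list(regions, grp))
  nmat <- matrix(0L, length(regions), length(grp),
                 dimnames = list(regions, grp))
  for (r in regions) {
    for (g in grp) {
      sel <- calls$region_id == r & calls$group == g
      n <- sum(sel)
      nmat[r, g] <- n
      if (n > 0L) freq[r, g] <- mean(calls$carrier[sel])
    }
  }
  sizes <- vapply(grp, function(g) {
    length(unique(calls$sample_id[calls$group == g]))
  }, integer(1))
  list(table = freq, n = nmat,
       group_sizes = data.frame(group = grp, n_datasets = sizes,
                                eligible = sizes >= min_datasets))
}

#' False-negative detection rate from ancient control regions
#'
#' NUMT regions older than the Suidae/Ruminantia split (class GT_55) are
#' fixed in the species, so any dataset in which such a region is not
#' detected is a false negative of the detection pipeline:
#' `rate = 1 - mean carrier fraction of GT_55 regions across all datasets`.
#'
#' @param calls Carrier calls (as in [carrier_frequencies()]) for the
#'   ancient regions only.
#' @return Rate in [0, 1]; NA when no ancient region is available.
#' @export
estimate_false_negative_rate <- function(calls) {
  if (!nrow(calls)) return(NA_real_)
  if (!("carrier" %in% names(calls))) {
    calls$carrier <- calls$genotype %in% c("hom_ins", "het")
  }
  calls <- calls[!is.na(calls$carrier), , drop = FALSE]
  per_region <- tapply(calls$carrier, calls$region_id, mean)
  1 - mean(per_region)
}

#' Call polymorphic NUMT regions
#'
#' A region is polymorphic (insertion/deletion segregating within the
#' species) when its species-wide carrier fraction is strictly below
#' `1 - fn_rate` — carrier fractions within the false-negative band of 1
#' are treated as fixed.
#'
#' @param carrier_fraction Named vector of species-wide carrier fractions.
#' @param fn_rate False-negative rate from
#'   [estimate_false_negative_rate()]; when NA, `fallback` is used.
#' @param fallback Polymorphism threshold when no ancient control exists.
#' @return Logical vector (TRUE = polymorphic), named by region.
#' @export
call_polymorphic <- function(carrier_fraction, fn_rate, fallback = 0.97) {
  thr <- if (is.na(fn_rate)) fallback else 1 - fn_rate
  !is.na(carrier_fraction) & carrier_fraction < thr
}

#' UPGMA clustering of groups by NUMT carrier-frequency profiles
#'
#' Euclidean distances between group frequency vectors, average-linkage
#' (UPGMA) agglomeration, deterministic tie-break by label order. Missing
#' cells are mean-imputed per region (with a message).
#'
#' @param freq Regions x groups matrix from [carrier_frequencies()].
#' @param eligible_only Optional character vector of groups to cluster
#'   (e.g. those with >= 10 datasets).
#' @return List with `hclust`, `phylo` (ape) and `newick`.
#' @export
upgma_cluster <- function(freq, eligible_only = NULL) {
  if (!is.null(eligible_only)) {
    freq <- freq[, intersect(colnames(freq), eligible_only), drop = FALSE]
  }
  if (ncol(freq) < 3L) stop("need at least 3 groups to cluster")
  if (anyNA(freq)) {
    message("mean-imputing ", sum(is.na(freq)), " missing cells")
    for (r in seq_len(nrow(freq))) {
      miss <- is.na(freq[r, ])
      if (any(miss)) freq[r, miss] <- mean(freq[r, !miss])
    }
  }
  freq <- freq[, order(colnames(freq)), drop = FALSE]   # deterministic ties
  d <- stats::dist(t(freq), method = "euclidean")
  hc <- stats::hclust(d, method = "average")
  ph <- ape::as.phylo(hc)
  list(hclust = hc, phylo = ph, newick = ape::write.tree(ph))
}

#' Annotate NUMT regions against gene and repeat annotation
#'
#' For each region: the gene-feature class at the insertion site (overlap
#' precedence exon > UTR > intron > intergenic), the closest gene and its
#' signed distance, the repeat classes within `flank` bp, and the GC
#' fraction of the +/- `flank` bp flanking sequence.
#'
#' @param regions Region table (`region_id`, `contig`, `start`, `end`;
#'   0-based half-open).
#' @param genes GFF3 path or data.frame with `contig`, `start`, `end`
#'   (0-based half-open), `type` ("gene"/"exon"/"five_prime_UTR"/
#'   "three_prime_UTR"), `gene` (gene name).
#' @param repeats Repeat table: `contig`, `start`, `end` (0-based
#'   half-open), `class`; NULL for none.
#' @param genome Named character vector of contig sequences (for flank GC);
#'   NULL skips GC.
#' @param flank Flank size in bp.
#' @return data.frame of annotation records, one per region.
#' @export
annotate_regions <- function(regions, genes, repeats = NULL, genome = NULL,
                             flank = 1000L) {
  if (is.character(genes)) genes <- read_gene_gff(genes)
  out <- NULL
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    g <- genes[genes$contig == r$contig, , drop = FALSE]
    ovl <- g[g$start < r$end & g$end > r$start, , drop = FALSE]
    feature <- if (any(ovl$type == "exon")) "exon"
      else if (any(ovl$type %in% c("five_prime_UTR", "three_prime_UTR")))
        "UTR"
      else if (any(ovl$type == "gene")) "intron"
      else "intergenic"
    gn <- g[g$type == "gene", , drop = FALSE]
    if (nrow(gn)) {
      dist <- ifelse(gn$start < r$end & gn$end > r$start, 0L,
                     ifelse(gn$end <= r$start, r$start - gn$end,
                            gn$start - r$end))
      ci <- which.min(abs(dist))
      closest <- gn$gene[ci]
      cdist <- dist[ci] * ifelse(gn$start[ci] >= r$end, 1L, -1L)
      if (dist[ci] == 0L) cdist <- 0L
    } else {
      closest <- NA_character_; cdist <- NA_integer_
    }
    flank_lo <- max(0L, r$start - flank)
    flank_hi <- r$end + flank
    clipped <- flank_lo == 0L
    rep_classes <- ""
    if (!is.null(repeats) && nrow(repeats)) {
      rr <- repeats[repeats$contig == r$contig &
                      repeats$start < flank_hi & repeats$end > flank_lo &
                      # repeats inside the region itself are not "flanking"
                      !(repeats$start >= r$start & repeats$end <= r$end), ,
                    drop = FALSE]
      rep_classes <- paste(sort(unique(rr$class)), collapse = ",")
    }
    gc <- NA_real_
    if (!is.null(genome) && r$contig %in% names(genome)) {
      cs <- genome[[r$contig]]
      flank_hi2 <- min(nchar(cs), flank_hi)
      clipped <- clipped || flank_hi > nchar(cs)
      fl <- paste0(substr(cs, flank_lo + 1L, r$start),
                   substr(cs, r$end + 1L, flank_hi2))
      if (nchar(fl)) {
        ch <- strsplit(fl, "")[[1]]
        gc <- mean(ch %in% c("G", "C"))
      }
    }
    out <- rbind(out, data.frame(
      region_id = r$region_id, contig = r$contig,
      start = r$start, end = r$end,
      feature = feature, closest_gene = closest,
      gene_distance = cdist, repeat_classes = rep_classes,
      flank_gc = gc, flank_clipped = clipped, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Read gene features from a GFF3 file
#'
#' Thin wrapper around `rtracklayer::import` returning the 0-based
#' half-open data.frame layout the annotator consumes.
#'
#' @param path GFF3 path.
#' @export
read_gene_gff <- function(path) {
  gr <- rtracklayer::import(path)
  gene <- as.character(GenomicRanges::mcols(gr)$Name)
  if (is.null(gene) || !length(gene)) gene <- rep(NA_character_, length(gr))
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             type = as.character(GenomicRanges::mcols(gr)$type),
             gene = gene, stringsAsFactors = FALSE)
}

#' Repeat-class enrichment in NUMT flanks
#'
#' Two-sided Fisher's exact test on nucleotide counts: bases overlapping a
#' repeat class vs not, in the pooled flanking sequence vs the whole
#' genome. No multiplicity correction is applied; per-class raw p-values
#' are reported.
#'
#' @param flank_cov Named vector: repeat-covered bp in flanks per class.
#' @param flank_total Total flank bp.
#' @param genome_cov Named vector: repeat-covered bp in the genome per
#'   class.
#' @param genome_total Total genome bp.
#' @return data.frame per class: counts, odds ratio, p-value.
#' @export
repeat_enrichment <- function(flank_cov, flank_total, genome_cov,
                              genome_total) {
  classes <- union(names(flank_cov), names(genome_cov))
  out <- NULL
  for (cl in classes) {
    a <- if (cl %in% names(flank_cov)) flank_cov[[cl]] else 0L
    b <- flank_total - a
    cc <- if (cl %in% names(genome_cov)) genome_cov[[cl]] else 0L
    d <- genome_total - cc
    tab <- matrix(c(a, b, cc, d), 2)
    if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
      p <- 1; or <- NA_real_
    } else {
      ft <- stats::fisher.test(tab)
      p <- ft$p.value; or <- unname(ft$estimate)
    }
    out <- rbind(out, data.frame(
      class = cl, flank_bp = a, flank_other = b,
      genome_bp = cc, genome_other = d,
      odds_ratio = or, p_value = p, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Export NUMT regions and fragments as GFF3
#'
#' One `NUMT_region` row per region and one `NUMT_fragment` child row per
#' member hit (`Parent` attribute), 1-based inclusive coordinates, source
#' column `numt-atlas`. The writer is canonical: write -> read -> write is
#' byte-identical.
#'
#' @param regions Region table.
#' @param hits Region-annotated hits (fragments); NULL for regions only.
#' @param path Output path.
#' @export
export_gff <- function(regions, hits = NULL, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  regions <- regions[order(regions$contig, regions$start), , drop = FALSE]
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    writeLines(sprintf(
      "%s\tnumt-atlas\tNUMT_region\t%d\t%d\t.\t.\t.\tID=%s",
      r$contig, r$start + 1L, r$end, r$region_id), con)
    if (!is.null(hits)) {
      h <- hits[hits$region_id == r$region_id, , drop = FALSE]
      h <- h[order(h$tstart), , drop = FALSE]
      for (j in seq_len(nrow(h))) {
        writeLines(sprintf(
          "%s\tnumt-atlas\tNUMT_fragment\t%d\t%d\t%d\t%s\t.\tID=%s.%d;Parent=%s;mt_start=%d;mt_end=%d",
          h$contig[j], h$tstart[j] + 1L, h$tend[j], h$score[j],
          h$strand[j], r$region_id, j, r$region_id,
          h$qstart[j], h$qend[j]), con)
      }
    }
  }
  invisible(path)
}

#' Read a NUMT GFF3 export
#'
#' @param path GFF3 path written by [export_gff()].
#' @return List with `regions` and `hits` data.frames (0-based half-open).
#' @export
read_numt_gff <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t")
  attr_of <- function(s, key) {
    m <- regmatches(s, regexpr(paste0(key, "=[^;]+"), s))
    if (!length(m)) return(NA_character_)
    sub(paste0(key, "="), "", m)
  }
  regions <- NULL; hits <- NULL
  for (p in parts) {
    if (p[3] == "NUMT_region") {
      regions <- rbind(regions, data.frame(
        region_id = attr_of(p[9], "ID"), contig = p[1],
        start = as.integer(p[4]) - 1L, end = as.integer(p[5]),
        stringsAsFactors = FALSE))
    } else if (p[3] == "NUMT_fragment") {
      hits <- rbind(hits, data.frame(
        region_id = attr_of(p[9], "Parent"), contig = p[1],
        tstart = as.integer(p[4]) - 1L, tend = as.integer(p[5]),
        score = as.integer(p[6]), strand = p[7],
        qstart = as.integer(attr_of(p[9], "mt_start")),
        qend = as.integer(attr_of(p[9], "mt_end")),
        stringsAsFactors = FALSE))
    }
  }
  list(regions = regions, hits = hits)
}
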
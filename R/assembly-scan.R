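# Assembled-genome NUMT scan: hits -> merged regions -> complexity flags ->
# summary statistics.

#' Scan an assembled genome for NUMT hits
#'
#' Full detection pipeline against one genome: circularise the mtDNA
#' consensus, align on both strands, mask low-complexity matches, apply the
#' score threshold and minimum length, exclude hits within `end_exclusion`
#' of contig ends (assembly quality there is unreliable and orthology cannot
#' be validated), and deduplicate hits arising from the doubled query.
#'
#' @param genome Named character vector of contig sequences.
#' @param mt_consensus Consensus mtDNA sequence (un-doubled).
#' @param scoring A [scoring_scheme()]; `min_score` is the reporting
#'   threshold (the calibrated/configured score threshold, default 30).
#' @param genome_id Genome label carried into the hit table.
#' @param min_length Minimum hit length on the target (bp).
#' @param end_exclusion Hits starting/ending within this many bp of a contig
#'   end are dropped.
#' @param ... Passed to [local_align()].
#' @return data.frame of NUMT hits (`genome_id`, `contig`, 0-based
#'   half-open `tstart`/`tend`, normalised `qstart`/`qend`, `strand`,
#'   `score`, `identity`, `aligned_length`).
#' @export
scan_assembly <- function(genome, mt_consensus, scoring = scoring_scheme(),
                          genome_id = "genome", min_length = 30L,
                          end_exclusion = 1000L, ...) {
  out <- NULL
  L <- nchar(mt_consensus)
  for (ci in seq_along(genome)) {
    contig <- names(genome)[ci]
    if (is.null(contig)) contig <- paste0("contig", ci)
    seq <- genome[[ci]]
    if (!nchar(seq)) next
    hits <- local_align(circularize(mt_consensus), seq, scoring = scoring,
                        ...)
    if (!nrow(hits)) next
    hits <- mask_low_complexity(hits, seq)
    if (!nrow(hits)) next
    hits <- hits[hits$tend - hits$tstart >= min_length, , drop = FALSE]
    hits <- hits[hits$tstart >= end_exclusion &
                 hits$tend <= nchar(seq) - end_exclusion, , drop = FALSE]
    if (!nrow(hits)) next
    hits <- normalize_circular_hits(hits, L)
    hits$genome_id <- genome_id
    hits$contig <- contig
    out <- rbind(out, hits)
  }
  if (is.null(out)) {
    out <- cbind(.empty_hits(),
                 data.frame(genome_id = character(0), contig = character(0)))
  }
  rownames(out) <- NULL
  out
}

#' Merge NUMT hits into NUMT regions
#'
#' Consecutive hits on the same contig less than `merge_gap` apart are
#' attributed to a single ancestral insertion event that was subsequently
#' fragmented, and merged (single linkage) into one NUMT region. Region ids
#' follow the `<CONTIG>_REGION_<k>` convention, ordinal in coordinate order
#' per contig.
#'
#' @param hits Hit data.frame from [scan_assembly()].
#' @param merge_gap Hits separated by fewer than this many bases are merged
#'   (strict: a gap of exactly `merge_gap` starts a new region).
#' @return List with `regions` (one row per region: span, fragment count,
#'   total NUMT bp, length-weighted mean identity, strand mix) and `hits`
#'   (input hits annotated with `region_id`).
#' @export
build_regions <- function(hits, merge_gap = 20000L) {
  if (!nrow(hits)) {
    regions <- data.frame(region_id = character(0), genome_id = character(0),
                          contig = character(0), start = integer(0),
                          end = integer(0), n_fragments = integer(0),
                          total_numt_bp = integer(0),
                          mean_identity = numeric(0), complex = logical(0),
                          inversion_present = logical(0))
    hits$region_id <- character(0)
    return(list(regions = regions, hits = hits))
  }
  hits <- hits[order(hits$genome_id, hits$contig, hits$tstart, hits$tend), ,
               drop = FALSE]
  hits$region_id <- NA_character_
  regions <- NULL
  for (g in unique(hits$genome_id)) {
    for (ct in unique(hits$contig[hits$genome_id == g])) {
      idx <- which(hits$genome_id == g & hits$contig == ct)
      running_end <- -Inf
      grp <- integer(length(idx))
      k <- 0L
      for (j in seq_along(idx)) {
        i <- idx[j]
        if (hits$tstart[i] - running_end >= merge_gap) k <- k + 1L
        grp[j] <- k
        running_end <- max(running_end, hits$tend[i])
      }
      for (r in seq_len(k)) {
        members <- idx[grp == r]
        rid <- paste0(ct, "_REGION_", r)
        hits$region_id[members] <- rid
        w <- hits$tend[members] - hits$tstart[members]
        strands <- unique(hits$strand[members])
        regions <- rbind(regions, data.frame(
          region_id = rid, genome_id = g, contig = ct,
          start = min(hits$tstart[members]),
          end = max(hits$tend[members]),
          n_fragments = length(members),
          total_numt_bp = sum(w),
          mean_identity = sum(w * hits$identity[members]) / sum(w),
          complex = FALSE, inversion_present = length(strands) > 1,
          stringsAsFactors = FALSE))
      }
    }
  }
  rownames(regions) <- NULL
  for (r in seq_len(nrow(regions))) {
    regions[r, c("complex", "inversion_present")] <-
      .complex_flags(hits[!is.na(hits$region_id) &
                          hits$region_id == regions$region_id[r] &
                          hits$genome_id == regions$genome_id[r], ,
                          drop = FALSE])
  }
  list(regions = regions, hits = hits)
}

# Complexity rule: a region is complex when two member hits overlap by more
# than `dup_overlap` bp on normalised mtDNA coordinates (a duplication), or
# when strands are mixed AND the mtDNA intervals of opposite-strand members
# overlap. Inversion flag: strands mixed at all.
.complex_flags <- function(members, dup_overlap = 50L) {
  n <- nrow(members)
  inversion <- length(unique(members$strand)) > 1
  complex <- FALSE
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        ov <- min(members$qend[i], members$qend[j]) -
          max(members$qstart[i], members$qstart[j])
        if (ov > dup_overlap) complex <- TRUE
        if (inversion && members$strand[i] != members$strand[j] && ov > 0) {
          complex <- TRUE
        }
      }
    }
  }
  data.frame(complex = complex, inversion_present = inversion)
}

#' Flag duplications and inversions in a region
#'
#' Recomputes the `complex` and `inversion_present` flags of a single region
#' row from its member hits (see [build_regions()], which applies the same
#' rule to every region).
#'
#' @param region One region row.
#' @param hits Member hits of that region.
#' @export
flag_complex <- function(region, hits) {
  region[, c("complex", "inversion_present")] <- .complex_flags(hits)
  region
}

#' Summary statistics over NUMT regions
#'
#' @param regions Region table from [build_regions()].
#' @param hits Annotated hits from [build_regions()].
#' @param genome_bp Total genome size (bp) for the genome fraction; NA
#'   allowed.
#' @return List of summary scalars plus `dotplot` (per-fragment nuclear-x /
#'   mtDNA-y coordinates for dot-plot style inspection).
#' @export
summarize_regions <- function(regions, hits = NULL, genome_bp = NA) {
  if (!nrow(regions)) {
    return(list(n_regions = 0L, n_sequences = 0L, n_singletons = 0L,
                total_numt_bp = 0L, min_length = NA, median_length = NA,
                mean_length = NA, sd_length = NA, genome_fraction = NA,
                dotplot = data.frame()))
  }
  lens <- if (!is.null(hits) && nrow(hits)) hits$tend - hits$tstart
          else regions$end - regions$start
  dot <- if (!is.null(hits) && nrow(hits)) {
    data.frame(region_id = hits$region_id, contig = hits$contig,
               nuclear_start = hits$tstart, nuclear_end = hits$tend,
               mt_start = hits$qstart, mt_end = hits$qend,
               strand = hits$strand)
  } else data.frame()
  list(n_regions = nrow(regions),
       n_sequences = sum(regions$n_fragments),
       n_singletons = sum(regions$n_fragments == 1L),
       total_numt_bp = sum(regions$total_numt_bp),
       min_length = min(lens), median_length = stats::median(lens),
       mean_length = mean(lens), sd_length = stats::sd(lens),
       genome_fraction = if (is.na(genome_bp)) NA else
         sum(regions$total_numt_bp) / genome_bp,
       dotplot = dot)
}
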
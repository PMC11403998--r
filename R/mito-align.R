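# Mitochondrial-side utilities: consensus building, circularisation,
# reversed-sequence score-threshold calibration and low-complexity masking.

#' Build a consensus sequence from aligned mtDNA sequences
#'
#' Plurality consensus over the columns of an equal-length gapped alignment.
#' A column is dropped when the gap character is the strict plurality;
#' ties between bases are broken alphabetically (A < C < G < T); a base
#' tying with the gap count keeps the column.
#'
#' @param aligned Character vector (>= 2) of equal-length gapped sequences.
#' @return Consensus sequence (character, no gaps).
#' @export
build_consensus <- function(aligned) {
  if (length(aligned) < 2) stop("need at least 2 sequences")
  if (length(unique(nchar(aligned))) != 1) {
    stop("aligned sequences must have equal gapped length")
  }
  m <- do.call(rbind, strsplit(toupper(aligned), ""))
  out <- character(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    base_counts <- c(A = sum(col == "A"), C = sum(col == "C"),
                     G = sum(col == "G"), T = sum(col == "T"))
    gap_count <- sum(col == "-")
    best <- max(base_counts)
    if (gap_count > best) {
      out[j] <- ""
    } else {
      out[j] <- names(base_counts)[which.max(base_counts)]  # alphabetical tie
    }
  }
  paste(out, collapse = "")
}

#' Circularise a mitochondrial sequence
#'
#' Concatenates two copies of the sequence so that local alignments can
#' extend across the origin of the circular molecule. Hits against the
#' doubled sequence are brought back to `[0, L)` with
#' [normalize_circular_hits()].
#'
#' @param seq Character sequence.
#' @return The doubled sequence.
#' @export
circularize <- function(seq) {
  seq <- as.character(seq)
  if (!nchar(seq)) stop("empty sequence")
  paste0(seq, seq)
}

#' Normalise hits on a doubled (circularised) query
#'
#' Query intervals with start >= L are shifted down by L; duplicate hits
#' (same target interval, same normalised query interval, same strand) that
#' arise from the two copies of the query are removed.
#'
#' @param hits Hit data.frame from [local_align()] against a doubled query.
#' @param L Length of the original (un-doubled) query.
#' @return Normalised, deduplicated hit data.frame. `qend` may exceed `L`
#'   for hits spanning the circular origin.
#' @export
normalize_circular_hits <- function(hits, L) {
  if (!nrow(hits)) return(hits)
  shift <- hits$qstart >= L
  hits$qstart[shift] <- hits$qstart[shift] - L
  hits$qend[shift] <- hits$qend[shift] - L
  key <- paste(hits$tstart, hits$tend, hits$qstart, hits$qend, hits$strand)
  hits <- hits[!duplicated(key), , drop = FALSE]
  # a hit whose target interval lies inside a higher-scoring same-strand hit
  # is a circular-copy shadow of it (the same nuclear bases seen through the
  # other copy of the doubled query): drop it
  hits <- hits[order(-hits$score, hits$tstart), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))[-1]) {
    j <- which(keep[seq_len(i - 1L)])
    contained <- hits$strand[j] == hits$strand[i] &
      hits$tstart[j] <= hits$tstart[i] + 5L &
      hits$tend[j] >= hits$tend[i] - 5L
    if (any(contained)) keep[i] <- FALSE
  }
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[order(hits$tstart, hits$tend), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Align a circular mtDNA query against a nuclear target
#'
#' Convenience wrapper: circularises the mtDNA, runs [local_align()] on both
#' strands, and normalises hit query coordinates back to the circle.
#'
#' @param mt mtDNA sequence (character).
#' @param target Nuclear sequence (character).
#' @param scoring A [scoring_scheme()].
#' @param ... Passed to [local_align()].
#' @export
align_mtdna <- function(mt, target, scoring = scoring_scheme(), ...) {
  L <- nchar(mt)
  hits <- local_align(circularize(mt), target, scoring = scoring, ...)
  normalize_circular_hits(hits, L)
}

#' Calibrate the score threshold with a reversed mtDNA control
#'
#' Aligns the reversed — not complemented — mtDNA against the nuclear
#' genome. DNA does not evolve by reversal, so every match is spurious and
#' the maximum spurious score bounds the noise floor of the search space:
#' the calibrated threshold is `max(spurious score) + 1`. The detection
#' pipeline then applies `min(calibrated, default)` so that deliberately
#' relaxed defaults (30, chosen to retain very old NUMT) are never raised.
#'
#' @param mt mtDNA sequence.
#' @param genome Named character vector of nuclear contigs (one allowed).
#' @param scoring A [scoring_scheme()]; its `min_score` is ignored here.
#' @param floor_score Smallest spurious score worth tracking (alignments
#'   below it are irrelevant to the maximum).
#' @param ... Passed to [local_align()].
#' @return Integer threshold with attribute `degenerate` set to TRUE when
#'   the control itself aligns near-perfectly (self-alignment pathologies).
#' @export
calibrate_score_threshold <- function(mt, genome, scoring = scoring_scheme(),
                                      floor_score = 15L, ...) {
  rev_mt <- paste(rev(strsplit(as.character(mt), "")[[1]]), collapse = "")
  sc <- scoring
  sc$min_score <- as.integer(floor_score)
  best <- 0L
  for (contig in genome) {
    hits <- local_align(rev_mt, contig, scoring = sc, ...)
    if (nrow(hits)) best <- max(best, max(hits$score))
  }
  thr <- as.integer(best + 1L)
  attr(thr, "degenerate") <- best >= nchar(mt) * scoring$match / 2
  thr
}

# Per-base low-complexity mask of a sequence: union of (i) tandem repeats of
# period <= max_period sustained for >= max(12, 3*period) bases and (ii)
# DUST-like triplet-biased windows (64 bp, step 32, score > 2).
.low_complexity_mask <- function(seq, max_period = 6L,
                                 window = 64L, dust_thresh = 2) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  mask <- logical(n)
  for (p in seq_len(max_period)) {
    if (n <= p) break
    eq <- c(rep(FALSE, p), chars[-seq_len(p)] == chars[seq_len(n - p)])
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    long <- which(r$values & r$lengths >= max(12L, 3L * p))
    for (i in long) mask[max(1L, starts[i] - p):ends[i]] <- TRUE
  }
  if (n >= window) {
    tri <- paste0(chars[1:(n - 2)], chars[2:(n - 1)], chars[3:n])
    for (s in seq(1L, n - window + 1L, by = max(1L, window %/% 2L))) {
      counts <- table(tri[s:(s + window - 3L)])
      score <- sum(counts * (counts - 1) / 2) / (window - 3L)
      if (score > dust_thresh) mask[s:(s + window - 1L)] <- TRUE
    }
  }
  mask
}

#' Remove hits dominated by low-complexity target sequence
#'
#' Drops hits whose target interval is more than half covered by DUST-like
#' low-complexity sequence or by tandem repeats of period <= 6.
#'
#' @param hits Hit data.frame with `tstart`/`tend` (0-based half-open).
#' @param target Target contig sequence the hits refer to.
#' @param max_fraction Maximum tolerated masked fraction.
#' @return Filtered hit data.frame.
#' @export
mask_low_complexity <- function(hits, target, max_fraction = 0.5) {
  if (!nrow(hits)) return(hits)
  keep <- vapply(seq_len(nrow(hits)), function(i) {
    sub <- substr(target, hits$tstart[i] + 1L, hits$tend[i])
    mean(.low_complexity_mask(sub)) <= max_fraction
  }, logical(1))
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
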
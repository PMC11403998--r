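#' Alignment scoring scheme
#'
#' Scoring parameters for local alignment of mitochondrial sequence against
#' nuclear sequence. The defaults (+1 match, -1 mismatch, gap-open 7,
#' gap-extend 1, reporting threshold 30) are tuned for detecting distant
#' homology between a modern mtDNA consensus and old, degraded NUMT copies:
#' a gap of length L costs `gap_open + L * gap_extend`.
#'
#' @param match Match reward (positive integer).
#' @param mismatch Mismatch penalty, given as a negative score.
#' @param gap_open Gap opening penalty (positive).
#' @param gap_extend Per-base gap extension penalty (positive).
#' @param min_score Minimum alignment score for a hit to be reported.
#' @return An object of class `numt_scoring`.
#' @export
scoring_scheme <- function(match = 1L, mismatch = -1L, gap_open = 7L,
                           gap_extend = 1L, min_score = 30L) {
  stopifnot(match > 0, mismatch <= 0, gap_open >= 0, gap_extend >= 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_score = as.integer(min_score)),
            class = "numt_scoring")
}

# Substitution matrix over A,C,G,T,N where N scores as mismatch against
# everything (including itself), so ambiguous bases never contribute
# positively to an extension.
.subst_matrix <- function(scoring) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- scoring$match
  m["N", "N"] <- scoring$mismatch
  m
}

.empty_hits <- function() {
  data.frame(tstart = integer(0), tend = integer(0),
             qstart = integer(0), qend = integer(0),
             strand = character(0), score = integer(0),
             identity = numeric(0), aligned_length = integer(0),
             stringsAsFactors = FALSE)
}

# Integer codes of all k-mers of a sequence (0-based base codes, radix 4);
# positions containing N (or any non-ACGT letter) code as NA and never seed.
.kmer_codes <- function(chars_int, k) {
  n <- length(chars_int)
  if (n < k) return(integer(0))
  m <- n - k + 1L
  code <- integer(m)
  for (i in 0:(k - 1L)) {
    code <- code + chars_int[(1L + i):(m + i)] * 4L^(k - 1L - i)
  }
  code
}

# Exact k-mer seeds of `query` in `target`; both DNAString. Returns a
# data.frame(qpos, tpos) of 1-based k-mer start positions, found by sorting
# target k-mer codes and range-matching query codes against them.
.find_seeds <- function(query, target, k) {
  none <- data.frame(qpos = integer(0), tpos = integer(0))
  if (length(query) < k || length(target) < k) return(none)
  enc <- function(s) {
    x <- match(strsplit(as.character(s), "")[[1]], .BASES) - 1L
    x
  }
  qc <- .kmer_codes(enc(query), k)
  tc <- .kmer_codes(enc(target), k)
  qpos <- which(!is.na(qc))
  if (!length(qpos)) return(none)
  tpos_valid <- which(!is.na(tc))
  if (!length(tpos_valid)) return(none)
  o <- order(tc[tpos_valid])
  tsorted <- tc[tpos_valid][o]
  tpos_sorted <- tpos_valid[o]
  hi <- findInterval(qc[qpos], tsorted)
  lo <- findInterval(qc[qpos] - 1L, tsorted) + 1L
  nmatch <- hi - lo + 1L
  has <- nmatch > 0L
  if (!any(has)) return(none)
  data.frame(qpos = rep(qpos[has], nmatch[has]),
             tpos = tpos_sorted[sequence(nmatch[has], from = lo[has])])
}

# Single-linkage clustering of seeds into candidate alignment loci: seeds are
# linked when their diagonals differ by <= band and their target starts are
# <= cluster_gap apart. Returns a list of data.frames.
.cluster_seeds <- function(seeds, band = 64L, cluster_gap = 500L) {
  if (!nrow(seeds)) return(list())
  seeds$diag <- seeds$tpos - seeds$qpos
  o <- order(seeds$diag, seeds$tpos)
  seeds <- seeds[o, , drop = FALSE]
  n <- nrow(seeds)
  new_grp <- c(TRUE, (diff(seeds$diag) > band) |
                     (abs(diff(seeds$tpos)) > cluster_gap))
  grp <- cumsum(new_grp)
  split(seeds, grp)
}

# Best ungapped X-drop extension score through the seed, used to triage
# singleton seed clusters before the (more expensive) gapped stage.
.ungapped_score <- function(qraw, traw, qpos, tpos, k, scoring, xdrop = 20L,
                            max_ext = 400L) {
  score0 <- k * scoring$match
  extend <- function(qidx, tidx, step) {
    best <- 0L; run <- 0L; gained <- 0L
    qlen <- length(qraw); tlen <- length(traw)
    n <- if (step > 0L) min(qlen - qidx, tlen - tidx, max_ext)
         else min(qidx - 1L, tidx - 1L, max_ext)
    if (n <= 0L) return(0L)
    qs <- qraw[qidx + step * seq_len(n)]
    ts <- traw[tidx + step * seq_len(n)]
    match <- qs == ts & qs != charToRaw("N")
    inc <- ifelse(match, scoring$match, scoring$mismatch)
    path <- cumsum(inc)
    runmax <- cummax(path)
    stop_at <- which(runmax - path > xdrop)
    lim <- if (length(stop_at)) stop_at[1] - 1L else n
    if (lim <= 0L) return(0L)
    max(0L, max(path[seq_len(lim)]))
  }
  score0 +
    extend(qpos + k - 1L, tpos + k - 1L, 1L) +
    extend(qpos, tpos, -1L)
}

# Gapped alignment on a window around a seed cluster; returns one hit row
# (coordinates 0-based half-open on the full query/target) or NULL. Seeds of
# low-identity (old) copies are sparse, so the optimal alignment can reach
# past the seed span: the window is re-expanded while the alignment touches
# its boundary.
.extend_cluster <- function(cl, query, target, scoring, k, margin = 150L,
                            max_margin = 4000L) {
  repeat {
    qlo <- max(1L, min(cl$qpos) - margin)
    qhi <- min(length(query), max(cl$qpos) + k - 1L + margin)
    tlo <- max(1L, min(cl$tpos) - margin)
    thi <- min(length(target), max(cl$tpos) + k - 1L + margin)
    al <- Biostrings::pairwiseAlignment(
      Biostrings::subseq(query, qlo, qhi),
      Biostrings::subseq(target, tlo, thi),
      type = "local", substitutionMatrix = .subst_matrix(scoring),
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
    score <- as.integer(round(BiocGenerics::score(al)))
    if (score <= 0L) return(NULL)
    pv <- Biostrings::pattern(al)
    sv <- Biostrings::subject(al)
    at_edge <-
      (BiocGenerics::start(pv) <= 3L && qlo > 1L) ||
      (BiocGenerics::end(pv) >= qhi - qlo - 1L && qhi < length(query)) ||
      (BiocGenerics::start(sv) <= 3L && tlo > 1L) ||
      (BiocGenerics::end(sv) >= thi - tlo - 1L && thi < length(target))
    if (!at_edge || margin >= max_margin) break
    margin <- min(max_margin, margin * 3L)
  }
  data.frame(
    tstart = tlo + BiocGenerics::start(sv) - 2L,    # 0-based
    tend   = tlo + BiocGenerics::end(sv) - 1L,      # half-open
    qstart = qlo + BiocGenerics::start(pv) - 2L,
    qend   = qlo + BiocGenerics::end(pv) - 1L,
    strand = "+", score = score,
    identity = Biostrings::pid(al, type = "PID1") / 100,
    aligned_length = Biostrings::nchar(al),
    stringsAsFactors = FALSE)
}

# Greedy removal of redundant hits: hits on the same strand whose target AND
# query intervals both overlap a higher-scoring hit by more than half of the
# shorter interval are dropped (max score kept).
.dedup_hits <- function(hits) {
  if (nrow(hits) <= 1L) return(hits)
  hits <- hits[order(-hits$score, hits$tstart), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  ovl_frac <- function(s1, e1, s2, e2) {
    ov <- pmax(0L, pmin(e1, e2) - pmax(s1, s2))
    ov / pmax(1L, pmin(e1 - s1, e2 - s2))
  }
  for (i in seq_len(nrow(hits))[-1]) {
    j <- which(keep[seq_len(i - 1L)])
    if (!length(j)) next
    same <- hits$strand[j] == hits$strand[i]
    to <- ovl_frac(hits$tstart[j], hits$tend[j], hits$tstart[i], hits$tend[i])
    qo <- ovl_frac(hits$qstart[j], hits$qend[j], hits$qstart[i], hits$qend[i])
    if (any(same & to > 0.5 & qo > 0.5)) keep[i] <- FALSE
  }
  hits[keep, , drop = FALSE]
}

.align_one_strand <- function(query, target, scoring, seed_k, xdrop,
                              ungapped_trigger, exact_always_cells,
                              exact_max_cells) {
  hits <- .empty_hits()
  seeds <- .find_seeds(query, target, seed_k)
  if (nrow(seeds)) {
    qraw <- charToRaw(as.character(query))
    traw <- charToRaw(as.character(target))
    clusters <- .cluster_seeds(seeds)
    for (cl in clusters) {
      if (nrow(cl) < 3L) {
        ug <- max(vapply(seq_len(nrow(cl)), function(i) {
          .ungapped_score(qraw, traw, cl$qpos[i], cl$tpos[i], seed_k,
                          scoring, xdrop)
        }, numeric(1)))
        if (ug < ungapped_trigger) next
      }
      h <- .extend_cluster(cl, query, target, scoring, seed_k)
      if (!is.null(h)) hits <- rbind(hits, h)
    }
  }
  # Exact full-matrix alignment guarantees the optimal local score is
  # present regardless of seed availability: always for small problems, and
  # as a fallback for mid-sized problems where seeding found nothing.
  cells <- as.numeric(length(query)) * length(target)
  if (cells <= exact_always_cells ||
      (nrow(hits) == 0L && cells <= exact_max_cells)) {
    al <- Biostrings::pairwiseAlignment(
      query, target, type = "local",
      substitutionMatrix = .subst_matrix(scoring),
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
    score <- as.integer(round(BiocGenerics::score(al)))
    if (score > 0L) {
      pv <- Biostrings::pattern(al); sv <- Biostrings::subject(al)
      hits <- rbind(hits, data.frame(
        tstart = BiocGenerics::start(sv) - 1L,
        tend = BiocGenerics::end(sv),
        qstart = BiocGenerics::start(pv) - 1L,
        qend = BiocGenerics::end(pv),
        strand = "+", score = score,
        identity = Biostrings::pid(al, type = "PID1") / 100,
        aligned_length = Biostrings::nchar(al), stringsAsFactors = FALSE))
    }
  }
  hits
}

#' Multi-hit seeded local alignment
#'
#' Aligns `query` against `target` on both strands and reports every local
#' alignment scoring at least `scoring$min_score`. Exact k-mer seeds are
#' clustered by diagonal, triaged by an ungapped X-drop extension, and
#' extended by affine-gap local dynamic programming on a window around each
#' cluster; for small problems an exact full-matrix alignment is always run
#' as well, so the optimal local score is reported even when no seed exists.
#' There is no cap on the number of reported hits.
#'
#' @param query,target Character strings or [Biostrings::DNAString] objects
#'   over the alphabet A,C,G,T,N.
#' @param scoring A [scoring_scheme()].
#' @param seed_k Seed k-mer length.
#' @param xdrop X-drop threshold for the ungapped extension stage.
#' @param both_strands Also align the reverse complement of the query.
#' @param ungapped_trigger Minimum ungapped extension score for a
#'   single-seed cluster to be promoted to gapped extension.
#' @param exact_always_cells Always run exact full-matrix DP (in addition to
#'   the seeded search) when `length(query) * length(target)` is at most
#'   this many cells, so small problems are solved optimally.
#' @param exact_max_cells Also fall back to exact DP up to this problem size
#'   when the seeded search finds no hit (e.g. short queries without seeds).
#' @return A data.frame of hits with 0-based half-open `tstart`/`tend` and
#'   `qstart`/`qend` (always on plus-strand query coordinates), `strand`,
#'   `score`, `identity` (fraction of identical columns over all aligned
#'   columns, gap columns counting as non-identical) and `aligned_length`.
#' @export
local_align <- function(query, target, scoring = scoring_scheme(),
                        seed_k = 11L, xdrop = 20L, both_strands = TRUE,
                        ungapped_trigger = 20L, exact_always_cells = 2.5e5,
                        exact_max_cells = 2e7) {
  query <- Biostrings::DNAString(toupper(as.character(query)))
  target <- Biostrings::DNAString(toupper(as.character(target)))
  if (length(query) == 0L || length(target) == 0L) return(.empty_hits())
  if (seed_k > min(length(query), length(target)) &&
      as.numeric(length(query)) * length(target) > exact_max_cells) {
    stop("seed_k exceeds the shorter sequence length and the problem is too",
         " large for exact alignment")
  }
  hits <- .align_one_strand(query, target, scoring, seed_k, xdrop,
                            ungapped_trigger, exact_always_cells,
                            exact_max_cells)
  if (both_strands) {
    rc <- Biostrings::reverseComplement(query)
    h2 <- .align_one_strand(rc, target, scoring, seed_k, xdrop,
                            ungapped_trigger, exact_always_cells,
                            exact_max_cells)
    if (nrow(h2)) {
      L <- length(query)
      qs <- L - h2$qend
      h2$qend <- L - h2$qstart
      h2$qstart <- qs
      h2$strand <- "-"
      hits <- rbind(hits, h2)
    }
  }
  hits <- .dedup_hits(hits)
  hits <- hits[hits$score >= scoring$min_score, , drop = FALSE]
  rownames(hits) <- NULL
  hits[order(hits$tstart, hits$tend), , drop = FALSE]
}

#' Karlin-Altschul expected alignment count
#'
#' Expected number of ungapped local alignments with score at least `score`
#' between random sequences of the given lengths, `E = K m n exp(-lambda S)`.
#' `lambda` solves `sum_ij p_i p_j exp(lambda s_ij) = 1` at uniform base
#' frequencies; for the +1/-1 scheme the root is `ln 3`. `K` is a scale
#' constant calibrated once from shuffled-sequence simulation and fixed in
#' configuration (default 0.1).
#'
#' @param score Alignment score.
#' @param query_len,db_len Sequence lengths.
#' @param scoring A [scoring_scheme()].
#' @param K Karlin-Altschul scale constant.
#' @return Expected alignment count (numeric).
#' @export
karlin_evalue <- function(score, query_len, db_len,
                          scoring = scoring_scheme(), K = 0.1) {
  lambda <- karlin_lambda(scoring)
  K * as.numeric(query_len) * as.numeric(db_len) * exp(-lambda * score)
}

#' @rdname karlin_evalue
#' @export
karlin_lambda <- function(scoring = scoring_scheme()) {
  f <- function(l) 0.25 * exp(l * scoring$match) +
    0.75 * exp(l * scoring$mismatch) - 1
  # positive root exists when expected score < 0
  exp_score <- 0.25 * scoring$match + 0.75 * scoring$mismatch
  if (exp_score >= 0) stop("scoring scheme has non-negative expected score; ",
                           "Karlin-Altschul statistics undefined")
  stats::uniroot(f, c(1e-6, 10), tol = 1e-12)$root
}
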
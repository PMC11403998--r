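# Analytic paired-end read simulation.
#
# Reads are drawn from sample haplotypes and their alignments to the
# insertion-free reference are constructed analytically from the known
# insertion coordinates: a read overlapping an insertion junction is aligned
# on the flank where it overlaps the reference most, and the remaining bases
# are soft-clipped (CIGAR S), exactly the signal the short-read NUMT caller
# consumes. Mapping quality is fixed at 60; no external mapper is involved.

# Haplotype -> reference coordinate segments. Insertion blocks are 0-based
# half-open intervals on the haplotype; `ref_at` is the reference position of
# each block (the insertion breakpoint).
.hap_segments <- function(hap_len, blocks) {
  if (is.null(blocks) || !nrow(blocks)) {
    return(data.frame(hs = 0L, he = hap_len, ref0 = 0L))
  }
  blocks <- blocks[order(blocks$start), , drop = FALSE]
  segs <- NULL
  cur <- 0L; ins_before <- 0L
  for (i in seq_len(nrow(blocks))) {
    if (blocks$start[i] > cur) {
      segs <- rbind(segs, data.frame(hs = cur, he = blocks$start[i],
                                     ref0 = cur - ins_before))
    }
    ins_before <- ins_before + (blocks$end[i] - blocks$start[i])
    cur <- blocks$end[i]
  }
  if (cur < hap_len) {
    segs <- rbind(segs, data.frame(hs = cur, he = hap_len,
                                   ref0 = cur - ins_before))
  }
  segs
}

# Analytic alignment of haplotype intervals [s, e) against the reference,
# vectorised over reads: each read is aligned on the reference segment it
# overlaps most; bases beyond that segment are soft-clipped.
.place_reads <- function(s, e, segs) {
  n <- length(s)
  k <- nrow(segs)
  ov <- matrix(0L, n, k)
  for (j in seq_len(k)) {
    ov[, j] <- pmin(e, segs$he[j]) - pmax(s, segs$hs[j])
  }
  best <- max.col(ov, ties.method = "first")
  bv <- ov[cbind(seq_len(n), best)]
  mapped <- bv > 0L
  ms <- pmax(s, segs$hs[best])
  me <- pmin(e, segs$he[best])
  left <- ms - s
  right <- e - me
  cigar <- paste0(ifelse(left > 0L, paste0(left, "S"), ""),
                  (me - ms), "M",
                  ifelse(right > 0L, paste0(right, "S"), ""))
  cigar[!mapped] <- "*"
  pos <- as.integer(segs$ref0[best] + (ms - segs$hs[best]) + 1L)  # 1-based
  pos[!mapped] <- 0L
  data.frame(mapped = mapped, pos = pos, cigar = cigar,
             stringsAsFactors = FALSE)
}

.add_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  n_err <- stats::rbinom(length(seqs), nchar(seqs), error_rate)
  for (i in which(n_err > 0L)) {
    chars <- strsplit(seqs[i], "")[[1]]
    at <- sample.int(length(chars), n_err[i])
    chars[at] <- vapply(chars[at], function(b) {
      sample(setdiff(.BASES, b), 1L)
    }, character(1))
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

#' Simulate paired-end reads with analytic SAM alignments
#'
#' @param haplotypes Named list of haplotype sequences (character). For a
#'   diploid sample pass its two haplotypes; for a pooled sample pass all
#'   pooled haplotypes with `proportions`.
#' @param reference Reference contig sequence *without* the insertions
#'   (character) — the coordinate system of the emitted SAM.
#' @param contig Reference contig name.
#' @param truth Truth table rows for these haplotypes (columns `haplotype`,
#'   `start`, `end`, `ref_breakpoint`), or NULL for an insertion-free sample.
#' @param depth Total requested mean coverage across all haplotypes.
#' @param read_len Read length (bp).
#' @param insert_size Fragment length (fixed).
#' @param error_rate Per-base substitution error rate.
#' @param seed Integer seed.
#' @param sample_id Sample name, used in read names.
#' @param proportions Haplotype mixing proportions (default: uniform).
#' @return List with `sam` (data.frame of SAM records), `sq`, and
#'   `breakpoints` (expected insertion breakpoints on the reference,
#'   0-based).
#' @export
simulate_reads <- function(haplotypes, reference, contig = "chr1",
                           truth = NULL, depth = 20, read_len = 100L,
                           insert_size = 300L, error_rate = 0.01,
                           seed = 1L, sample_id = "s1",
                           proportions = NULL) {
  stopifnot(depth >= 1)
  set.seed(as.integer(seed))
  read_len <- as.integer(read_len)
  insert_size <- as.integer(insert_size)
  hap_names <- names(haplotypes)
  if (is.null(proportions)) {
    proportions <- rep(1 / length(haplotypes), length(haplotypes))
  }
  stopifnot(length(proportions) == length(haplotypes))
  proportions <- proportions / sum(proportions)

  recs <- vector("list", length(haplotypes))
  for (h in seq_along(haplotypes)) {
    hseq <- haplotypes[[h]]
    hlen <- nchar(hseq)
    if (read_len > hlen) stop("read_len exceeds contig length")
    eff_insert <- min(insert_size, hlen)
    blocks <- NULL
    if (!is.null(truth) && nrow(truth)) {
      blocks <- truth[truth$haplotype == hap_names[h], , drop = FALSE]
    }
    segs <- .hap_segments(hlen, blocks)
    n_frag <- round(depth * proportions[h] * hlen / (2 * read_len))
    if (n_frag < 1L) next
    fs <- sample.int(hlen - eff_insert + 1L, n_frag, replace = TRUE) - 1L
    r1s <- fs; r1e <- fs + read_len
    r2s <- fs + eff_insert - read_len; r2e <- fs + eff_insert
    qname <- sprintf("%s_%s_f%06d", sample_id, hap_names[h], seq_len(n_frag))
    p1 <- .place_reads(r1s, r1e, segs)
    p2 <- .place_reads(r2s, r2e, segs)
    mk <- function(p, mate, s0, e0, first) {
      # reverse-strand bit belongs to the second mate; mate-reverse to first
      flag <- 1L +
        ifelse(p$mapped & mate$mapped, 2L, 0L) +
        ifelse(!p$mapped, 4L, 0L) +
        ifelse(!mate$mapped, 8L, 0L) +
        ifelse(first, 32L, 16L) +
        ifelse(first, 64L, 128L)
      data.frame(
        qname = qname, flag = flag,
        rname = ifelse(p$mapped, contig, "*"), pos = p$pos,
        mapq = ifelse(p$mapped, 60L, 0L),
        cigar = p$cigar,
        rnext = ifelse(mate$mapped, "=", "*"), pnext = mate$pos,
        tlen = 0L,
        seq = .add_errors(substr(rep(hseq, n_frag), s0 + 1L, e0),
                          error_rate),
        qual = strrep("I", read_len), stringsAsFactors = FALSE)
    }
    recs[[h]] <- rbind(mk(p1, p2, r1s, r1e, TRUE),
                       mk(p2, p1, r2s, r2e, FALSE))
  }
  sam <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(sam)) {
    sam <- data.frame(matrix(nrow = 0, ncol = 11,
                             dimnames = list(NULL, .sam_cols)))
  }
  sam <- sam[order(sam$rname, sam$pos, sam$qname), , drop = FALSE]
  rownames(sam) <- NULL
  bp <- if (!is.null(truth) && nrow(truth)) {
    unique(data.frame(contig = contig,
                      pos = truth$ref_breakpoint,
                      insertion = truth$insertion))
  } else {
    data.frame(contig = character(0), pos = integer(0),
               insertion = character(0))
  }
  list(sam = sam,
       sq = data.frame(name = contig, length = nchar(reference)),
       breakpoints = bp, sample_id = sample_id)
}
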
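# Non-reference NUMT detection from soft-clipped reads in SAM alignments:
# breakpoint detection, clip-to-mtDNA matching, the depth / R1 / R2 filter
# cascade, cross-sample locus grouping, genotyping and contig assembly.

# Annotate SAM records with 0-based alignment interval and clip lengths.
.prep_records <- function(records) {
  mapped <- bitwAnd(records$flag, 4L) == 0L
  records <- records[mapped, , drop = FALSE]
  # PCR/optical duplicates would inflate both R2 denominators and clip
  # support; records are deduplicated by (name, flag)
  records <- records[!duplicated(paste(records$qname, records$flag)), ,
                     drop = FALSE]
  if (!nrow(records)) {
    records$start0 <- integer(0); records$end0 <- integer(0)
    records$clip_left <- integer(0); records$clip_right <- integer(0)
    return(records)
  }
  records$start0 <- records$pos - 1L
  records$end0 <- records$start0 + cigar_ref_span(records$cigar)
  cl <- cigar_clips(records$cigar)
  records$clip_left <- cl$left
  records$clip_right <- cl$right
  records
}

# Clipped-off subsequences of a record (bases that did not align).
.clip_seq <- function(records, side) {
  if (side == "left") {
    substr(records$seq, 1L, records$clip_left)
  } else {
    substr(records$seq, nchar(records$seq) - records$clip_right + 1L,
           nchar(records$seq))
  }
}

#' Detect candidate insertion breakpoints from soft-clipped reads
#'
#' A breakpoint is a reference position where soft-clips pile up: for a
#' leading (left) clip the position is the alignment start, for a trailing
#' (right) clip the alignment end. Only clips of at least `min_clip_len`
#' bases count as support, and a breakpoint is emitted when supported by at
#' least `min_support` soft-clipped reads.
#'
#' @param sam A list as returned by [read_sam()] (`sq` + `records`), or a
#'   records data.frame (then `sq` must be supplied).
#' @param min_support Minimum number of supporting soft-clipped reads.
#' @param min_clip_len Minimum clip length to count as support.
#' @param sample_id Sample label attached to the breakpoints.
#' @param sq Reference dictionary when `sam` is a bare data.frame.
#' @return data.frame with `contig`, `pos` (0-based first inserted-adjacent
#'   reference base), `side` ("left"/"right"), `n_clip_reads`, `sample_id`.
#' @export
detect_breakpoints <- function(sam, min_support = 3L, min_clip_len = 7L,
                               sample_id = "s1", sq = NULL) {
  if (is.data.frame(sam)) {
    if (is.null(sq)) stop("missing @SQ reference dictionary")
    records <- sam
  } else {
    sq <- sam$sq
    records <- if (!is.null(sam$records)) sam$records else sam$sam
  }
  if (is.null(sq) || !nrow(sq)) stop("missing @SQ reference dictionary")
  records <- .prep_records(records)
  out <- NULL
  for (side in c("left", "right")) {
    len <- if (side == "left") records$clip_left else records$clip_right
    sel <- len >= min_clip_len
    if (!any(sel)) next
    pos <- if (side == "left") records$start0[sel] else records$end0[sel]
    tab <- stats::aggregate(list(n_clip_reads = pos),
                            by = list(contig = records$rname[sel], pos = pos),
                            FUN = length)
    tab$side <- side
    out <- rbind(out, tab)
  }
  if (is.null(out)) {
    return(data.frame(contig = character(0), pos = integer(0),
                      side = character(0), n_clip_reads = integer(0),
                      sample_id = character(0)))
  }
  out <- out[out$n_clip_reads >= min_support, , drop = FALSE]
  if (!nrow(out)) {
    return(data.frame(contig = character(0), pos = integer(0),
                      side = character(0), n_clip_reads = integer(0),
                      sample_id = character(0)))
  }
  out$sample_id <- sample_id
  out <- out[order(out$contig, out$pos, out$side), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("contig", "pos", "side", "n_clip_reads", "sample_id")]
}

#' Match clipped sequences against the mitochondrial genome
#'
#' Aligns every qualifying clipped sequence at a breakpoint to the
#' circularised mtDNA, keeps matches with identity strictly above
#' `min_identity` and E-value strictly below `max_evalue`, union-merges the
#' surviving mtDNA intervals and concatenates the corresponding mtDNA
#' segments into the putative inserted sequence.
#'
#' @param breakpoint One row of [detect_breakpoints()] output.
#' @param records Prepared or raw SAM records of the same sample.
#' @param mt mtDNA sequence (un-doubled).
#' @param scoring A [scoring_scheme()] (`min_score` is relaxed internally;
#'   the identity/E-value filters decide).
#' @param min_clip_len Minimum clip length considered.
#' @param min_identity,max_evalue Filter thresholds (strict inequalities).
#' @return List with `matches` (per-clip best hits and filter status),
#'   `mt_intervals` (merged, 0-based half-open on the circle) and
#'   `sequence` (putative NUMT sequence; "" when nothing survives).
#' @export
match_clips <- function(breakpoint, records, mt,
                        scoring = scoring_scheme(), min_clip_len = 7L,
                        min_identity = 0.75, max_evalue = 1e-4) {
  if (!("start0" %in% names(records))) records <- .prep_records(records)
  side <- breakpoint$side
  at <- if (side == "left") records$start0 else records$end0
  len <- if (side == "left") records$clip_left else records$clip_right
  sel <- records$rname == breakpoint$contig & at == breakpoint$pos &
    len >= min_clip_len
  clips <- .clip_seq(records[sel, , drop = FALSE], side)
  L <- nchar(mt)
  mt2 <- circularize(mt)
  matches <- .match_clip_set(clips, records$qname[sel], mt2, L, scoring,
                             min_identity, max_evalue)
  ok <- matches[matches$pass, , drop = FALSE]
  if (nrow(ok)) {
    ir <- IRanges::reduce(IRanges::IRanges(start = ok$mt_start + 1L,
                                           end = ok$mt_end))
    ints <- data.frame(mt_start = BiocGenerics::start(ir) - 1L,
                       mt_end = BiocGenerics::end(ir))
    seqs <- vapply(seq_len(nrow(ints)), function(i) {
      .circular_segment(mt, ints$mt_start[i] %% L,
                        if (ints$mt_end[i] > L) ints$mt_end[i] - L
                        else ints$mt_end[i],
                        wraparound = ints$mt_end[i] > L)
    }, character(1))
    sequence <- paste(seqs, collapse = "")
  } else {
    ints <- data.frame(mt_start = integer(0), mt_end = integer(0))
    sequence <- ""
  }
  list(matches = matches, mt_intervals = ints, sequence = sequence)
}

# Vectorised exact local alignment of a set of clipped sequences against
# the doubled mtDNA, on both strands; one row per clip with the best hit and
# its filter status.
.match_clip_set <- function(clips, read_names, mt2, L, scoring,
                            min_identity, max_evalue) {
  empty <- data.frame(read = character(0), clip_len = integer(0),
                      mt_start = integer(0), mt_end = integer(0),
                      strand = character(0), score = integer(0),
                      identity = numeric(0), e_value = numeric(0),
                      pass = logical(0))
  if (!length(clips)) return(empty)
  subject <- Biostrings::DNAString(mt2)
  mat <- .subst_matrix(scoring)
  one_strand <- function(set, subj, offset = 0L) {
    al <- Biostrings::pairwiseAlignment(
      set, subj, type = "local", substitutionMatrix = mat,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
    ident <- Biostrings::pid(al, type = "PID1") / 100
    sv <- Biostrings::subject(al)
    list(score = as.integer(round(BiocGenerics::score(al))),
         identity = ident,
         tstart = BiocGenerics::start(sv) - 1L + offset,
         tend = BiocGenerics::end(sv) + offset)
  }
  both_strands <- function(set, subj, offset = 0L) {
    fw <- one_strand(set, subj, offset)
    rv <- one_strand(Biostrings::reverseComplement(set), subj, offset)
    use_rv <- rv$score > fw$score
    list(score = ifelse(use_rv, rv$score, fw$score),
         identity = ifelse(use_rv, rv$identity, fw$identity),
         tstart = ifelse(use_rv, rv$tstart, fw$tstart),
         tend = ifelse(use_rv, rv$tend, fw$tend),
         strand = ifelse(use_rv, "-", "+"))
  }
  # clips at one breakpoint derive from one junction, so they share the mt
  # neighbourhood: locate it once with the longest clip, align the rest in
  # a window around it, and rescue failures with a full-length alignment
  anchor <- which.max(nchar(clips))
  full <- both_strands(Biostrings::DNAStringSet(clips[anchor]), subject)
  win_lo <- max(1L, full$tstart[1] - 400L)
  win_hi <- min(length(subject), full$tend[1] + 400L)
  window <- Biostrings::subseq(subject, win_lo, win_hi)
  res <- both_strands(Biostrings::DNAStringSet(clips), window,
                      offset = win_lo - 1L)
  ev0 <- karlin_evalue(res$score, nchar(clips), 2L * L, scoring)
  needs_rescue <- which(!(res$identity > min_identity & ev0 < max_evalue))
  if (length(needs_rescue)) {
    resc <- both_strands(Biostrings::DNAStringSet(clips[needs_rescue]),
                         subject)
    for (f in c("score", "identity", "tstart", "tend", "strand")) {
      res[[f]][needs_rescue] <- resc[[f]]
    }
  }
  score <- res$score
  identity <- res$identity
  mt_start <- res$tstart
  mt_end <- res$tend
  strand <- res$strand
  shift <- mt_start >= L
  mt_start[shift] <- mt_start[shift] - L
  mt_end[shift] <- mt_end[shift] - L
  ev <- karlin_evalue(score, nchar(clips), 2L * L, scoring)
  data.frame(read = read_names, clip_len = nchar(clips),
             mt_start = mt_start, mt_end = mt_end, strand = strand,
             score = score, identity = identity, e_value = ev,
             pass = identity > min_identity & ev < max_evalue,
             stringsAsFactors = FALSE)
}

#' Per-base aligned-read coverage of a contig
#'
#' @param records SAM records (raw or prepared).
#' @param contig Contig name.
#' @param contig_len Contig length.
#' @return Integer vector of length `contig_len` (coverage by aligned M
#'   spans; clips do not contribute).
#' @export
coverage_from_sam <- function(records, contig, contig_len) {
  if (!("start0" %in% names(records))) records <- .prep_records(records)
  records <- records[records$rname == contig, , drop = FALSE]
  if (!nrow(records)) return(integer(contig_len))
  cov <- IRanges::coverage(IRanges::IRanges(start = records$start0 + 1L,
                                            end = records$end0),
                           width = contig_len)
  as.integer(cov)
}

#' Estimate genome-wide sample depth
#'
#' Trimmed mean of per-window mean coverage over 1-kb tiling windows.
#'
#' @param cov Per-base coverage vector (or list of vectors, one per contig).
#' @param window Window size.
#' @param trim Fraction trimmed at each tail.
#' @export
estimate_depth <- function(cov, window = 1000L, trim = 0.1) {
  if (!is.list(cov)) cov <- list(cov)
  wm <- unlist(lapply(cov, function(v) {
    n <- length(v) %/% window
    if (n < 1L) return(mean(v))
    colMeans(matrix(v[seq_len(n * window)], nrow = window))
  }))
  mean(wm, trim = trim)
}

#' Breakpoint depth filter
#'
#' Rejects breakpoints in copy-number-variable or otherwise anomalous
#' regions: the mean aligned depth in a +/- `window` bp window around the
#' breakpoint must lie in `[6, d + 4*sqrt(d)]` (both bounds inclusive),
#' where `d` is the genome-wide mean depth of the sample.
#'
#' @param breakpoint One breakpoint row (`contig`, `pos`).
#' @param cov Per-base coverage of the breakpoint's contig.
#' @param d Sample mean depth.
#' @param window Half-window size in bp.
#' @param min_depth Lower bound.
#' @return TRUE when the breakpoint passes.
#' @export
depth_filter <- function(breakpoint, cov, d, window = 200L, min_depth = 6) {
  stopifnot(d > 0)
  lo <- max(1L, breakpoint$pos - window + 1L)
  hi <- min(length(cov), breakpoint$pos + window)
  m <- mean(cov[lo:hi])
  md <- d + 4 * sqrt(d)
  m >= min_depth & m <= md
}

#' Group breakpoints across samples into insertion loci
#'
#' Single-linkage grouping of breakpoints on the same contig within
#' `window` bp of each other (boundary inclusive: 100 bp apart groups,
#' 101 bp does not). The representative position is the median breakpoint.
#'
#' @param breakpoints Combined breakpoint table across samples.
#' @param window Maximum grouping distance in bp.
#' @return data.frame of loci (`locus_id`, `contig`, `pos`, `n_breakpoints`,
#'   `n_datasets`, `samples`), plus input breakpoints annotated with
#'   `locus_id` in attribute `"breakpoints"`.
#' @export
group_loci <- function(breakpoints, window = 100L) {
  if (!nrow(breakpoints)) {
    out <- data.frame(locus_id = character(0), contig = character(0),
                      pos = integer(0), n_breakpoints = integer(0),
                      n_datasets = integer(0), samples = character(0))
    attr(out, "breakpoints") <- breakpoints
    return(out)
  }
  breakpoints <- breakpoints[order(breakpoints$contig, breakpoints$pos), ,
                             drop = FALSE]
  breakpoints$locus_id <- NA_character_
  loci <- NULL
  for (ct in unique(breakpoints$contig)) {
    idx <- which(breakpoints$contig == ct)
    gap_new <- c(TRUE, diff(breakpoints$pos[idx]) > window)
    grp <- cumsum(gap_new)
    for (g in unique(grp)) {
      members <- idx[grp == g]
      lid <- sprintf("%s_LOCUS_%d", ct, g)
      breakpoints$locus_id[members] <- lid
      loci <- rbind(loci, data.frame(
        locus_id = lid, contig = ct,
        pos = as.integer(round(stats::median(breakpoints$pos[members]))),
        n_breakpoints = length(members),
        n_datasets = length(unique(breakpoints$sample_id[members])),
        samples = paste(sort(unique(breakpoints$sample_id[members])),
                        collapse = ","),
        stringsAsFactors = FALSE))
    }
  }
  rownames(loci) <- NULL
  attr(loci, "breakpoints") <- breakpoints
  loci
}

#' Genotype one insertion locus in one sample
#'
#' Computes the two filter ratios at each member breakpoint and calls a
#' genotype from R2:
#' * R1 = (reads soft-clipped by >= `min_clip_len` nt whose clip matches the
#'   mtDNA) / (all reads soft-clipped by >= `min_clip_len` nt at the
#'   breakpoint);
#' * R2 = (reads soft-clipped at the breakpoint) / (reads overlapping the
#'   breakpoint).
#'
#' Genotype: homozygous insertion when R2 > 0.80, heterozygous when
#' 0.30 <= R2 <= 0.80, absent when R2 < 0.30 (bounds as documented; the
#' maximum-R2 breakpoint of the locus decides). For pooled samples only
#' carrier / non-carrier is called (any breakpoint with clip support).
#'
#' @param locus One locus row from [group_loci()].
#' @param locus_breakpoints Member breakpoints of this locus for this sample.
#' @param records SAM records of the sample.
#' @param mt mtDNA sequence.
#' @param is_pool Pooled-sample flag.
#' @param min_clip_len Minimum clip length for R1 eligibility.
#' @param scoring,min_identity,max_evalue Clip-match settings, as in
#'   [match_clips()].
#' @return data.frame with one row per member breakpoint (R1, R2 and
#'   counts) plus attributes-free summary columns `genotype` and `carrier`
#'   replicated across rows.
#' @export
genotype_locus <- function(locus, locus_breakpoints, records, mt,
                           is_pool = FALSE, min_clip_len = 7L,
                           scoring = scoring_scheme(),
                           min_identity = 0.75, max_evalue = 1e-4,
                           sample_id = "s1") {
  if (!("start0" %in% names(records))) records <- .prep_records(records)
  if (is.null(locus_breakpoints) || !nrow(locus_breakpoints)) {
    # sample carries no clip evidence here: evaluate R2 at the locus
    # representative position so an explicit absent call can be made
    locus_breakpoints <- data.frame(
      contig = locus$contig, pos = locus$pos, side = c("left", "right"),
      n_clip_reads = 0L, sample_id = sample_id, stringsAsFactors = FALSE)
  }
  rows <- NULL
  for (b in seq_len(nrow(locus_breakpoints))) {
    bp <- locus_breakpoints[b, , drop = FALSE]
    on_contig <- records$rname == bp$contig
    at <- if (bp$side == "left") records$start0 else records$end0
    clen <- if (bp$side == "left") records$clip_left else records$clip_right
    clipped_side <- on_contig & at == bp$pos & clen > 0L
    eligible <- clipped_side & clen >= min_clip_len
    n_eligible <- sum(eligible)
    if (n_eligible > 0L) {
      mc <- match_clips(bp, records, mt, scoring = scoring,
                        min_clip_len = min_clip_len,
                        min_identity = min_identity,
                        max_evalue = max_evalue)
      n_matched <- sum(mc$matches$pass)
    } else {
      n_matched <- 0L
    }
    # the two junction sides of a blunt insertion fall on the same
    # reference position: any soft-clip anchored at the position (either
    # side) is evidence for the insertion allele
    clipped_any <- on_contig & ((records$start0 == bp$pos &
                                   records$clip_left > 0L) |
                                  (records$end0 == bp$pos &
                                     records$clip_right > 0L))
    overlapping <- on_contig & records$start0 <= bp$pos &
      records$end0 >= bp$pos
    n_overlap <- sum(overlapping)
    n_clipped <- sum(clipped_any)
    rows <- rbind(rows, data.frame(
      locus_id = locus$locus_id, contig = bp$contig, pos = bp$pos,
      side = bp$side, sample_id = bp$sample_id,
      n_clip_eligible = n_eligible, n_clip_matched = n_matched,
      n_clipped = n_clipped, n_overlap = n_overlap,
      R1 = if (n_eligible > 0L) n_matched / n_eligible else NA_real_,
      R2 = if (n_overlap > 0L) n_clipped / n_overlap else NA_real_,
      stringsAsFactors = FALSE))
  }
  r2max <- suppressWarnings(max(rows$R2, na.rm = TRUE))
  genotype <- if (!is.finite(r2max)) {
    "undetermined"
  } else if (is_pool) {
    NA_character_
  } else if (r2max > 0.80) {
    "hom_ins"
  } else if (r2max >= 0.30) {
    "het"
  } else {
    "absent"
  }
  carrier <- if (is_pool) {
    any(rows$n_clip_matched >= 3L)
  } else {
    isTRUE(genotype %in% c("hom_ins", "het"))
  }
  rows$genotype <- genotype
  rows$carrier <- carrier
  rows$is_pool <- is_pool
  rows
}

#' Classify a locus as novel or known
#'
#' A locus is novel when its breakpoint does not fall within any reference
#' NUMT region span extended by `slop` bp on both sides.
#'
#' @param locus Locus row (`contig`, `pos`).
#' @param regions Reference region table from [build_regions()].
#' @param slop Slop in bp.
#' @export
classify_novel <- function(locus, regions, slop = 100L) {
  if (!nrow(regions)) return(TRUE)
  same <- regions$contig == locus$contig
  !any(same & regions$start - slop <= locus$pos &
         regions$end + slop >= locus$pos)
}

# Best suffix(a)/prefix(b) overlap of at least min_overlap bases with at
# least min_identity matching; returns the overlap length or 0.
.best_overlap <- function(a, b, min_overlap, min_identity) {
  la <- nchar(a); lb <- nchar(b)
  if (min(la, lb) < min_overlap) return(0L)
  for (o in seq(min(la, lb), min_overlap, by = -1L)) {
    sa <- substr(a, la - o + 1L, la)
    sb <- substr(b, 1L, o)
    eq <- mean(strsplit(sa, "")[[1]] == strsplit(sb, "")[[1]])
    if (eq >= min_identity) return(o)
  }
  0L
}

#' Assemble reads supporting an insertion into contigs
#'
#' Greedy overlap-layout-consensus over soft-clipped and discordant reads:
#' the pair with the longest suffix-prefix overlap (>= `min_overlap` bp at
#' >= `min_identity`) is merged repeatedly. Disconnected reads assemble into
#' separate contigs; a single input read is returned flagged fragmentary.
#'
#' @param reads Character vector of read (or clip) sequences, all in
#'   insertion-forward orientation.
#' @param min_overlap Minimum overlap length.
#' @param min_identity Minimum overlap identity.
#' @param mt Optional mtDNA sequence; when given, each contig is aligned
#'   back to it and annotated with its best mtDNA interval.
#' @return data.frame of contigs (`contig_seq`, `length`, `n_reads`,
#'   `fragmentary`, and mtDNA annotation columns when `mt` is given).
#' @export
assemble_insertion <- function(reads, min_overlap = 20L, min_identity = 0.90,
                               mt = NULL) {
  reads <- reads[nchar(reads) > 0L]
  if (!length(reads)) stop("no reads to assemble")
  n0 <- length(reads)
  contigs <- reads
  nmerged <- rep(1L, length(contigs))
  repeat {
    n <- length(contigs)
    if (n < 2L) break
    best <- c(0L, 0L, 0L)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      # containment
      if (nchar(contigs[j]) <= nchar(contigs[i]) &&
          grepl(contigs[j], contigs[i], fixed = TRUE)) {
        o <- nchar(contigs[j])
        if (o > best[3]) best <- c(i, j, o)
        next
      }
      o <- .best_overlap(contigs[i], contigs[j], min_overlap, min_identity)
      if (o > best[3]) best <- c(i, j, o)
    }
    if (best[3] < min_overlap) break
    i <- best[1]; j <- best[2]; o <- best[3]
    merged <- if (grepl(contigs[j], contigs[i], fixed = TRUE)) {
      contigs[i]
    } else {
      paste0(contigs[i], substr(contigs[j], o + 1L, nchar(contigs[j])))
    }
    nm <- nmerged[i] + nmerged[j]
    contigs <- contigs[-c(i, j)]
    nmerged <- nmerged[-c(i, j)]
    contigs <- c(contigs, merged)
    nmerged <- c(nmerged, nm)
  }
  out <- data.frame(contig_seq = contigs, length = nchar(contigs),
                    n_reads = nmerged,
                    fragmentary = n0 < 2L | nmerged == 1L,
                    stringsAsFactors = FALSE)
  if (!is.null(mt)) {
    L <- nchar(mt)
    ann <- lapply(out$contig_seq, function(s) {
      # mtDNA as the (doubled) query so hit query coordinates are on the
      # circle and normalise with the standard helper
      hits <- local_align(circularize(mt), s,
                          scoring = scoring_scheme(min_score = 20L))
      if (!nrow(hits)) {
        return(data.frame(mt_start = NA_integer_, mt_end = NA_integer_,
                          mt_identity = NA_real_))
      }
      hits <- normalize_circular_hits(hits, L)
      best <- hits[which.max(hits$score), ]
      data.frame(mt_start = best$qstart, mt_end = best$qend,
                 mt_identity = best$identity)
    })
    out <- cbind(out, do.call(rbind, ann))
  }
  out[order(-out$length), , drop = FALSE]
}

#' Final filter cascade for novel NUMT loci
#'
#' Applies the acceptance rules to genotyped loci: a putative novel NUMT is
#' rejected when (i) every breakpoint has R1 < 0.75 in every sample, or
#' (ii) every breakpoint has R2 < 0.30 in every non-pooled sample (waived
#' when only pooled samples carry it), or (iii) the putative sequence is
#' shorter than `min_length` bp, or (iv) it is present in fewer than
#' `min_datasets` datasets. Survivors are assigned region ids continuing
#' the per-contig ordinals of the reference region set.
#'
#' @param loci Locus table ([group_loci()]) with a `length` column (putative
#'   NUMT sequence length) and `novel` flag.
#' @param genotypes Combined per-breakpoint genotype rows
#'   ([genotype_locus()]) for all samples.
#' @param regions Reference region table (for ordinal continuation).
#' @param min_length Minimum putative sequence length.
#' @param min_datasets Minimum number of carrying datasets.
#' @return `loci` subset of accepted novel NUMT with `region_id` and a
#'   `reject_reason` attribute table for the rejected ones.
#' @export
finalize_novel <- function(loci, genotypes, regions = NULL,
                           min_length = 30L, min_datasets = 2L) {
  if (!nrow(loci)) {
    loci$region_id <- character(0)
    return(loci)
  }
  reasons <- character(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    g <- genotypes[genotypes$locus_id == loci$locus_id[i], , drop = FALSE]
    r1_ok <- any(g$R1 >= 0.75, na.rm = TRUE)
    nonpool <- g[!g$is_pool, , drop = FALSE]
    r2_ok <- if (nrow(nonpool)) {
      any(nonpool$R2 >= 0.30, na.rm = TRUE)
    } else {
      TRUE   # pooled samples only: the R2 genotype filter is waived
    }
    carriers <- unique(g$sample_id[g$carrier])
    if (!isTRUE(loci$novel[i])) {
      reasons[i] <- "known"
    } else if (!r1_ok) {
      reasons[i] <- "R1"
    } else if (!r2_ok) {
      reasons[i] <- "R2"
    } else if (is.na(loci$length[i]) || loci$length[i] < min_length) {
      reasons[i] <- "length"
    } else if (length(carriers) < min_datasets) {
      reasons[i] <- "datasets"
    } else {
      reasons[i] <- "pass"
    }
  }
  accepted <- loci[reasons == "pass", , drop = FALSE]
  if (nrow(accepted)) {
    accepted$region_id <- NA_character_
    for (ct in unique(accepted$contig)) {
      n0 <- if (!is.null(regions) && nrow(regions)) {
        sum(regions$contig == ct)
      } else 0L
      idx <- which(accepted$contig == ct)
      idx <- idx[order(accepted$pos[idx])]
      accepted$region_id[idx] <- paste0(ct, "_REGION_",
                                        n0 + seq_along(idx))
    }
  } else {
    accepted$region_id <- character(0)
  }
  attr(accepted, "reject_reasons") <-
    data.frame(locus_id = loci$locus_id, reason = reasons,
               stringsAsFactors = FALSE)
  accepted
}
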
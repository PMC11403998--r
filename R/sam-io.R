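# Light-weight FASTA / FASTQ / SAM serialisation.
#
# SAM records are held as a plain data.frame with the eleven mandatory
# columns; synthetic alignments are emitted analytically (no external
# mapper), with @SQ headers mandatory on write.

#' Write named sequences to a FASTA file (60-column wrap)
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(unlist(seqs))
  }
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

.sam_cols <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
               "rnext", "pnext", "tlen", "seq", "qual")

#' Write alignments to a SAM file
#' @param sam data.frame with the eleven mandatory SAM columns.
#' @param sq data.frame with columns `name`, `length` for the @SQ header.
#' @param path Output path.
#' @export
write_sam <- function(sam, sq, path) {
  stopifnot(all(.sam_cols %in% names(sam)), nrow(sq) >= 1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", sq$name, as.integer(sq$length)),
             con)
  if (nrow(sam)) {
    writeLines(do.call(paste, c(unname(sam[.sam_cols]), sep = "\t")), con)
  }
  invisible(path)
}

#' Read a SAM file
#' @param path SAM path.
#' @return List with `sq` (reference dictionary) and `records` (data.frame).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^@", lines)
  sq_lines <- lines[grepl("^@SQ", lines)]
  if (!length(sq_lines)) stop("SAM file has no @SQ header")
  sq <- data.frame(
    name = sub(".*SN:([^\t]+).*", "\\1", sq_lines),
    length = as.integer(sub(".*LN:([0-9]+).*", "\\1", sq_lines)),
    stringsAsFactors = FALSE)
  body <- lines[!hdr]
  if (!length(body)) {
    rec <- data.frame(matrix(nrow = 0, ncol = 11,
                             dimnames = list(NULL, .sam_cols)))
  } else {
    parts <- strsplit(body, "\t")
    rec <- data.frame(do.call(rbind, lapply(parts, `[`, 1:11)),
                      stringsAsFactors = FALSE)
    names(rec) <- .sam_cols
    for (col in c("flag", "pos", "mapq", "pnext", "tlen")) {
      rec[[col]] <- as.integer(rec[[col]])
    }
  }
  list(sq = sq, records = rec)
}

# CIGAR arithmetic -----------------------------------------------------------

.cigar_ops <- function(cigar) {
  lens <- regmatches(cigar, gregexpr("[0-9]+", cigar))
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))
  Map(function(l, o) list(len = as.integer(l), op = o), lens, ops)
}

# Fast path for the ubiquitous [xS] yM [zS] CIGAR shape; NA rows fall back
# to the generic op-list parser.
.simple_cigar <- function(cigar) {
  pat <- "^(?:([0-9]+)S)?([0-9]+)M(?:([0-9]+)S)?$"
  simple <- grepl(pat, cigar)
  left <- rep(NA_integer_, length(cigar))
  m <- left; right <- left
  if (any(simple)) {
    g1 <- sub(pat, "\\1", cigar[simple])
    g3 <- sub(pat, "\\3", cigar[simple])
    left[simple] <- ifelse(g1 == "", 0L, suppressWarnings(as.integer(g1)))
    m[simple] <- as.integer(sub(pat, "\\2", cigar[simple]))
    right[simple] <- ifelse(g3 == "", 0L, suppressWarnings(as.integer(g3)))
  }
  list(simple = simple, left = left, m = m, right = right)
}

# Reference span consumed by each CIGAR (M/D/N/=/X).
cigar_ref_span <- function(cigar) {
  sc <- .simple_cigar(cigar)
  out <- sc$m
  gen <- which(!sc$simple)
  if (length(gen)) {
    out[gen] <- vapply(.cigar_ops(cigar[gen]), function(x) {
      sum(x$len[x$op %in% c("M", "D", "N", "=", "X")])
    }, integer(1))
  }
  out
}

# Leading / trailing soft-clip lengths.
cigar_clips <- function(cigar) {
  sc <- .simple_cigar(cigar)
  left <- sc$left; right <- sc$right
  gen <- which(!sc$simple)
  if (length(gen)) {
    ops <- .cigar_ops(cigar[gen])
    left[gen] <- vapply(ops, function(x) {
      if (length(x$op) && x$op[1] == "S") x$len[1] else 0L
    }, integer(1))
    right[gen] <- vapply(ops, function(x) {
      n <- length(x$op)
      if (n && x$op[n] == "S") x$len[n] else 0L
    }, integer(1))
  }
  data.frame(left = left, right = right)
}

#' Write paired reads to FASTQ files
#' @param sam data.frame of SAM records (both mates, flags set).
#' @param r1_path,r2_path Output paths for first/second mates.
#' @export
write_fastq <- function(sam, r1_path, r2_path) {
  emit <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    seq <- df$seq
    qual <- df$qual
    rev <- bitwAnd(df$flag, 16L) > 0L
    if (any(rev)) {
      seq[rev] <- vapply(seq[rev], .revcomp_chr, character(1))
      qual[rev] <- vapply(strsplit(qual[rev], ""), function(x) {
        paste(rev(x), collapse = "")
      }, character(1))
    }
    writeLines(paste0("@", df$qname, "\n", seq, "\n+\n", qual), con)
  }
  emit(sam[bitwAnd(sam$flag, 64L) > 0L, , drop = FALSE], r1_path)
  emit(sam[bitwAnd(sam$flag, 128L) > 0L, , drop = FALSE], r2_path)
  invisible(c(r1_path, r2_path))
}
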
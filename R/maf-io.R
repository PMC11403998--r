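# Pairwise whole-genome alignment blocks, MAF-style.
#
# A block is one gapless-or-gapped aligned segment between genome A and
# genome B: 0-based half-open intervals on both genomes plus the gapped
# alignment texts (equal length). `mismap` carries the per-block mismap
# probability (0 for synthetic exact alignments).

.empty_blocks <- function() {
  data.frame(a_contig = character(0), a_start = integer(0),
             a_end = integer(0), b_contig = character(0),
             b_start = integer(0), b_end = integer(0),
             strand = character(0), mismap = numeric(0),
             a_text = character(0), b_text = character(0),
             stringsAsFactors = FALSE)
}

#' Write pairwise alignment blocks to a MAF file
#' @param blocks Block data.frame (see [read_maf()]).
#' @param path Output path.
#' @param a_sizes,b_sizes Named contig lengths for the srcSize field.
#' @export
write_maf <- function(blocks, path, a_sizes = NULL, b_sizes = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1 scoring=synthetic", con)
  size_of <- function(sizes, contig, fallback) {
    if (!is.null(sizes) && contig %in% names(sizes)) sizes[[contig]]
    else fallback
  }
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    writeLines(sprintf("a score=0 mismap=%g", b$mismap), con)
    writeLines(sprintf("s %s %d %d + %d %s", b$a_contig, b$a_start,
                       b$a_end - b$a_start,
                       size_of(a_sizes, b$a_contig, b$a_end), b$a_text), con)
    writeLines(sprintf("s %s %d %d %s %d %s", b$b_contig, b$b_start,
                       b$b_end - b$b_start, b$strand,
                       size_of(b_sizes, b$b_contig, b$b_end), b$b_text), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read pairwise alignment blocks from a MAF file
#' @param path MAF path (two `s` lines per block; first = genome A).
#' @return Block data.frame with 0-based half-open intervals on both
#'   genomes, gapped alignment texts, and `mismap`.
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  a_idx <- grep("^a", lines)
  if (!length(a_idx)) return(.empty_blocks())
  out <- vector("list", length(a_idx))
  for (k in seq_along(a_idx)) {
    i <- a_idx[k]
    mismap <- if (grepl("mismap=", lines[i])) {
      as.numeric(sub(".*mismap=([0-9eE.+-]+).*", "\\1", lines[i]))
    } else 0
    sa <- strsplit(lines[i + 1L], "\\s+")[[1]]
    sb <- strsplit(lines[i + 2L], "\\s+")[[1]]
    out[[k]] <- data.frame(
      a_contig = sa[2], a_start = as.integer(sa[3]),
      a_end = as.integer(sa[3]) + as.integer(sa[4]),
      b_contig = sb[2], b_start = as.integer(sb[3]),
      b_end = as.integer(sb[3]) + as.integer(sb[4]),
      strand = sb[5], mismap = mismap,
      a_text = sa[7], b_text = sb[7], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Emit the exact pairwise alignment of two synthetic genomes
#'
#' Genomes produced by [plant_numts()] share a background coordinate
#' system, so their true alignment is known exactly: colinear background
#' segments align gaplessly, an insertion private to one genome aligns
#' against a gap in the other, and a shared insertion aligns gaplessly.
#' Reference intervals listed in `unaligned` are omitted from the blocks
#' entirely (emulating unassembled or unalignable regions).
#'
#' @param planted Result of [plant_numts()].
#' @param sample_a,sample_b Sample names (haplotype 1 is used).
#' @param contig Contig name (single-contig backgrounds).
#' @param unaligned Optional data.frame of reference intervals
#'   (`start`,`end`, 0-based half-open) to omit.
#' @return Block data.frame (genome A = `sample_a` coordinates).
#' @export
emit_pairwise_maf <- function(planted, sample_a, sample_b, contig = "chr1",
                              unaligned = NULL) {
  seq_a <- planted$genomes[[sample_a]][["hap1"]]
  seq_b <- planted$genomes[[sample_b]][["hap1"]]
  tr_a <- planted$truth[planted$truth$sample == sample_a &
                          planted$truth$haplotype == "hap1", , drop = FALSE]
  tr_b <- planted$truth[planted$truth$sample == sample_b &
                          planted$truth$haplotype == "hap1", , drop = FALSE]
  ref_len <- nchar(planted$background$seq)
  events <- sort(unique(c(tr_a$ref_breakpoint, tr_b$ref_breakpoint)))
  blocks <- NULL
  emit <- function(a_start, a_end, b_start, b_end, a_text, b_text) {
    data.frame(a_contig = contig, a_start = a_start, a_end = a_end,
               b_contig = contig, b_start = b_start, b_end = b_end,
               strand = "+", mismap = 0,
               a_text = a_text, b_text = b_text, stringsAsFactors = FALSE)
  }
  # cumulative insertion offset maps: reference pos -> genome pos
  off_at <- function(tr, p) {
    sum(tr$length[tr$ref_breakpoint <= p])
  }
  cur_ref <- 0L
  for (p in c(events, ref_len)) {
    if (p > cur_ref) {
      # colinear background segment [cur_ref, p)
      oa <- off_at(tr_a, cur_ref); ob <- off_at(tr_b, cur_ref)
      a_s <- cur_ref + oa; b_s <- cur_ref + ob
      a_txt <- substr(seq_a, a_s + 1L, p + oa)
      b_txt <- substr(seq_b, b_s + 1L, p + ob)
      blocks <- rbind(blocks, emit(a_s, p + oa, b_s, p + ob, a_txt, b_txt))
    }
    if (p < ref_len) {
      ia <- tr_a[tr_a$ref_breakpoint == p, , drop = FALSE]
      ib <- tr_b[tr_b$ref_breakpoint == p, , drop = FALSE]
      oa <- off_at(tr_a, p - 1L); ob <- off_at(tr_b, p - 1L)
      if (nrow(ia) && nrow(ib)) {
        a_txt <- substr(seq_a, p + oa + 1L, p + oa + ia$length[1])
        b_txt <- substr(seq_b, p + ob + 1L, p + ob + ib$length[1])
        # shared insertion: equal length by construction
        blocks <- rbind(blocks, emit(p + oa, p + oa + ia$length[1],
                                     p + ob, p + ob + ib$length[1],
                                     a_txt, b_txt))
      } else if (nrow(ia)) {
        a_txt <- substr(seq_a, p + oa + 1L, p + oa + ia$length[1])
        blocks <- rbind(blocks, emit(p + oa, p + oa + ia$length[1],
                                     p + ob, p + ob,
                                     a_txt, strrep("-", ia$length[1])))
      } else if (nrow(ib)) {
        b_txt <- substr(seq_b, p + ob + 1L, p + ob + ib$length[1])
        blocks <- rbind(blocks, emit(p + oa, p + oa,
                                     p + ob, p + ob + ib$length[1],
                                     strrep("-", ib$length[1]), b_txt))
      }
    }
    cur_ref <- p
  }
  if (!is.null(unaligned) && nrow(unaligned)) {
    keep <- rep(TRUE, nrow(blocks))
    for (i in seq_len(nrow(unaligned))) {
      # drop blocks overlapping the masked reference interval (on A coords
      # shifted by A's insertions; compare on A genome coordinates)
      oa <- off_at(tr_a, unaligned$start[i] - 1L)
      us <- unaligned$start[i] + oa
      ue <- unaligned$end[i] + off_at(tr_a, unaligned$end[i] - 1L)
      keep <- keep & !(blocks$a_start < ue & blocks$a_end > us)
    }
    blocks <- blocks[keep, , drop = FALSE]
  }
  rownames(blocks) <- NULL
  blocks
}
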
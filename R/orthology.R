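# Cross-genome orthology of NUMT regions from one-to-one whole-genome
# alignment blocks, with a synteny-based criterion for distant species.

#' Orthology status of one NUMT region against another genome
#'
#' Projects the region through the filtered one-to-one alignment blocks and
#' classifies it:
#' * `CORRESPONDING` — the projected interval overlaps a called NUMT region
#'   of the other genome;
#' * `COMPATIBLE_SEQUENCE` — the region projects (essentially) fully and
#'   gaplessly onto other-genome sequence where no region was called: a
#'   false-negative of the other genome's scan, promoted to a region by
#'   [promote_compatible()];
#' * `PRIVATE` — the region projects onto alignment gaps only: the
#'   insertion is absent from the other genome (a polymorphic insertion);
#' * `UNALIGNED` — no block covers the region.
#'
#' @param region One region row (`contig`, `start`, `end`).
#' @param blocks Alignment blocks (A = the region's genome), already
#'   filtered by `mismap <= mismap_max`.
#' @param other_regions Region table of the other genome (may be empty).
#' @param mismap_max Maximum tolerated mismap probability.
#' @return List with `status`, and for non-UNALIGNED calls the projected
#'   interval `b_contig`, `b_start`, `b_end` plus the aligned-base fraction.
#' @export
map_region_status <- function(region, blocks, other_regions = NULL,
                              mismap_max = 1e-5) {
  blocks <- blocks[blocks$mismap <= mismap_max, , drop = FALSE]
  cover <- blocks[blocks$a_contig == region$contig &
                    blocks$a_start < region$end &
                    blocks$a_end > region$start, , drop = FALSE]
  if (!nrow(cover)) {
    return(list(status = "UNALIGNED", b_contig = NA, b_start = NA,
                b_end = NA, aligned_fraction = NA))
  }
  n_total <- 0L; n_aligned <- 0L
  b_lo <- Inf; b_hi <- -Inf; b_contig <- cover$b_contig[1]
  for (i in seq_len(nrow(cover))) {
    bl <- cover[i, ]
    a_chars <- strsplit(bl$a_text, "")[[1]]
    b_chars <- strsplit(bl$b_text, "")[[1]]
    a_pos <- bl$a_start - 1L + cumsum(a_chars != "-")   # 0-based per column
    b_pos <- bl$b_start - 1L + cumsum(b_chars != "-")
    in_region <- a_chars != "-" & a_pos >= region$start &
      a_pos < region$end
    if (!any(in_region)) next
    n_total <- n_total + sum(in_region)
    hit <- in_region & b_chars != "-"
    n_aligned <- n_aligned + sum(hit)
    if (any(hit)) {
      b_lo <- min(b_lo, min(b_pos[hit]))
      b_hi <- max(b_hi, max(b_pos[hit]) + 1L)
    }
  }
  if (n_total == 0L) {
    return(list(status = "UNALIGNED", b_contig = NA, b_start = NA,
                b_end = NA, aligned_fraction = NA))
  }
  frac <- n_aligned / n_total
  if (n_aligned > 0L && !is.null(other_regions) && nrow(other_regions)) {
    ov <- other_regions$contig == b_contig &
      other_regions$start < b_hi & other_regions$end > b_lo
    if (any(ov)) {
      return(list(status = "CORRESPONDING", b_contig = b_contig,
                  b_start = b_lo, b_end = b_hi, aligned_fraction = frac))
    }
  }
  if (frac == 0) {
    return(list(status = "PRIVATE", b_contig = b_contig, b_start = NA,
                b_end = NA, aligned_fraction = 0))
  }
  status <- if (frac > 0.5) "COMPATIBLE_SEQUENCE" else "PRIVATE"
  list(status = status, b_contig = b_contig,
       b_start = if (is.finite(b_lo)) b_lo else NA,
       b_end = if (is.finite(b_hi)) b_hi else NA,
       aligned_fraction = frac)
}

#' Promote COMPATIBLE_SEQUENCE projections to regions
#'
#' Adds a region (on the other genome) for every COMPATIBLE_SEQUENCE call —
#' the false-negative correction. Re-running the status mapping afterwards
#' turns those calls into CORRESPONDING, a fixed point.
#'
#' @param statuses data.frame of per-region status rows (with `b_contig`,
#'   `b_start`, `b_end`).
#' @param other_regions Existing region table of the other genome.
#' @param other_genome_id Genome id for the new rows.
#' @return Augmented region table.
#' @export
promote_compatible <- function(statuses, other_regions, other_genome_id) {
  promote <- statuses[statuses$status == "COMPATIBLE_SEQUENCE", ,
                      drop = FALSE]
  if (!nrow(promote)) return(other_regions)
  for (i in seq_len(nrow(promote))) {
    n0 <- sum(other_regions$contig == promote$b_contig[i])
    other_regions <- rbind(other_regions, data.frame(
      region_id = paste0(promote$b_contig[i], "_REGION_", n0 + 1L),
      genome_id = other_genome_id, contig = promote$b_contig[i],
      start = promote$b_start[i], end = promote$b_end[i],
      n_fragments = 1L,
      total_numt_bp = promote$b_end[i] - promote$b_start[i],
      mean_identity = NA_real_, complex = FALSE,
      inversion_present = FALSE, stringsAsFactors = FALSE))
  }
  other_regions[order(other_regions$contig, other_regions$start), ,
                drop = FALSE]
}

# Longest monotone subsequence mask (increasing or decreasing, whichever is
# longer) — the synteny-consistent subset of ortholog order mappings.
.monotone_mask <- function(x) {
  n <- length(x)
  if (n <= 1L) return(rep(TRUE, n))
  lis <- function(v) {
    best_len <- integer(n); prev <- integer(n)
    for (i in seq_len(n)) {
      best_len[i] <- 1L; prev[i] <- 0L
      for (j in seq_len(i - 1L)) {
        if (v[j] < v[i] && best_len[j] + 1L > best_len[i]) {
          best_len[i] <- best_len[j] + 1L; prev[i] <- j
        }
      }
    }
    at <- which.max(best_len)
    mask <- logical(n)
    while (at > 0L) { mask[at] <- TRUE; at <- prev[at] }
    mask
  }
  up <- lis(x); dn <- lis(-x)
  if (sum(up) >= sum(dn)) up else dn
}

#' Synteny-based orthology for distantly related species
#'
#' Declares two NUMT regions orthologous when (i) at least half of the
#' comparable flanking genes (up to five upstream plus five downstream on
#' each side) are syntenic — orthologous, in consistent relative order —
#' and (ii) the reciprocal overlap of the two regions' source mtDNA
#' intervals exceeds 40% (strict), measured against the smaller interval.
#'
#' @param ctx_a,ctx_b Synteny contexts: lists with `genes` (data.frame
#'   `gene`, `order`) and `mt_start`, `mt_end` (0-based half-open on the
#'   mtDNA circle).
#' @param ortholog_map data.frame with columns `a_gene`, `b_gene`.
#' @param min_comparable Fewer comparable genes than this returns NA
#'   (undetermined).
#' @return TRUE / FALSE, or NA when undetermined.
#' @export
distant_orthology <- function(ctx_a, ctx_b, ortholog_map,
                              min_comparable = 4L) {
  a <- ctx_a$genes[order(ctx_a$genes$order), , drop = FALSE]
  b <- ctx_b$genes[order(ctx_b$genes$order), , drop = FALSE]
  a$b_gene <- ortholog_map$b_gene[match(a$gene, ortholog_map$a_gene)]
  comparable <- !is.na(a$b_gene) & a$b_gene %in% b$gene
  if (sum(comparable) < min_comparable) return(NA)
  b_order <- match(a$b_gene[comparable], b$gene)
  syntenic <- .monotone_mask(b_order)
  frac_syntenic <- sum(syntenic) / sum(comparable)
  ov <- min(ctx_a$mt_end, ctx_b$mt_end) - max(ctx_a$mt_start, ctx_b$mt_start)
  min_len <- min(ctx_a$mt_end - ctx_a$mt_start,
                 ctx_b$mt_end - ctx_b$mt_start)
  mt_overlap <- if (min_len > 0) max(0, ov) / min_len else 0
  frac_syntenic >= 0.5 && mt_overlap > 0.4
}

#' Presence/absence matrix of NUMT regions across genomes and datasets
#'
#' @param statuses data.frame with columns `region_id`, `genome_id`,
#'   `status` (orthology calls; the reference genome itself should carry
#'   CORRESPONDING rows). Conflicting duplicate calls resolve to
#'   CORRESPONDING.
#' @param genotypes Optional WGS calls: data.frame `region_id`, `sample_id`,
#'   `genotype` (or `carrier` logical).
#' @param regions Region table giving the row coordinate system (reference
#'   coordinates); rows are ordered by contig and start.
#' @return List with `matrix` (data.frame, regions x genomes/datasets) and
#'   `groups` (UpSet-style pattern counts: carrier-column pattern ->
#'   number of regions).
#' @export
build_presence_matrix <- function(statuses, genotypes = NULL,
                                  regions = NULL) {
  ids <- if (!is.null(regions) && nrow(regions)) {
    regions$region_id[order(regions$contig, regions$start)]
  } else {
    sort(unique(statuses$region_id))
  }
  cols <- unique(statuses$genome_id)
  m <- matrix(NA_character_, length(ids), length(cols),
              dimnames = list(ids, cols))
  rank <- c(CORRESPONDING = 4L, COMPATIBLE_SEQUENCE = 3L, PRIVATE = 2L,
            UNALIGNED = 1L)
  for (i in seq_len(nrow(statuses))) {
    r <- statuses$region_id[i]; g <- statuses$genome_id[i]
    if (!(r %in% ids)) next
    cur <- m[r, g]
    if (is.na(cur) || rank[statuses$status[i]] > rank[cur]) {
      m[r, g] <- statuses$status[i]
    }
  }
  if (!is.null(genotypes) && nrow(genotypes)) {
    carrier <- if ("carrier" %in% names(genotypes)) {
      genotypes$carrier
    } else {
      genotypes$genotype %in% c("het", "hom_ins")
    }
    for (s in unique(genotypes$sample_id)) {
      v <- rep(NA_character_, length(ids))
      rows <- genotypes$sample_id == s
      v[match(genotypes$region_id[rows], ids)] <-
        ifelse(carrier[rows], "CARRIER", "ABSENT")
      m <- cbind(m, v)
      colnames(m)[ncol(m)] <- s
    }
  }
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  present <- df == "CORRESPONDING" | df == "COMPATIBLE_SEQUENCE" |
    df == "CARRIER"
  pattern <- apply(present, 1L, function(x) {
    paste(colnames(df)[which(x)], collapse = "+")
  })
  groups <- table(pattern)
  list(matrix = df, groups = as.data.frame(groups,
                                           stringsAsFactors = FALSE))
}
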
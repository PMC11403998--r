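# Insertion dating: presence/absence age classes, Fitch parsimony
# ancestral reconstruction, the allele-matching-ratio method and the
# Kimura-two-parameter distance method.

#' Mutation rate configuration for NUMT dating
#'
#' The three nuclear substitution rates used for the NUMT-side term of the
#' distance-based age: the average mammalian nuclear rate, a rate estimated
#' phylogenetically across wild ruminants, and a pig pedigree-based rate.
#' The default policy applies the mammalian rate.
#'
#' @param mammalian,ruminant,pig_pedigree Rates in substitutions/site/year.
#' @export
mutation_rate_config <- function(mammalian = 2.2e-9, ruminant = 2.48e-9,
                                 pig_pedigree = 1.2e-9) {
  stopifnot(mammalian > 0, ruminant > 0, pig_pedigree > 0)
  list(mammalian = mammalian, ruminant = ruminant,
       pig_pedigree = pig_pedigree)
}

#' Assign a presence/absence age class
#'
#' Classifies a NUMT region from its presence pattern across the four
#' lineages (domestic/wild pig *S. scrofa*, Visayan warty pig
#' *S. cebifrons*, warthog *P. africanus*, and the bovid outgroup), using
#' the divergence scaffold ~3.5 / ~10 / ~55 Mya:
#' * `GT_55` — present in a bovid and in any Suinae lineage (insertion
#'   predates the Suidae/Ruminantia split);
#' * `55_10` — present in the warthog and in a *Sus* lineage, absent from
#'   bovids;
#' * `10_3p5` — present in both *Sus* species but not the warthog, or
#'   private to the warthog lineage;
#' * `LE_3p5` — private to *S. scrofa* or private to *S. cebifrons*;
#' * `undetermined` — no presence, or a bovid-only pattern (contradicts a
#'   single insertion event on this tree).
#'
#' @param scrofa,cebifrons,warthog,bovid Logical presence flags.
#' @return One of "GT_55", "55_10", "10_3p5", "LE_3p5", "undetermined".
#' @export
assign_age_class <- function(scrofa, cebifrons, warthog, bovid) {
  stopifnot(is.logical(scrofa), is.logical(cebifrons),
            is.logical(warthog), is.logical(bovid))
  any_suinae <- scrofa | cebifrons | warthog
  if (!any_suinae && !bovid) return("undetermined")
  if (bovid && !any_suinae) return("undetermined")
  if (bovid && any_suinae) return("GT_55")
  if (warthog && (scrofa || cebifrons)) return("55_10")
  if (scrofa && cebifrons) return("10_3p5")
  if (warthog) return("10_3p5")      # private to the warthog lineage
  "LE_3p5"                           # private to one Sus lineage
}

#' Fitch parsimony ancestral sequence
#'
#' Reconstructs the most-parsimonious ancestral state at a given internal
#' node by the Fitch bottom-up/top-down passes on a fixed rooted topology.
#' Sites whose bottom-up state set at the node is not a singleton are
#' ambiguous: they are reported as `N` and flagged, and the
#' allele-matching-ratio computation excludes them.
#'
#' @param sequences Named character vector of aligned (equal-length)
#'   sequences; names must match the tree tip labels.
#' @param tree A rooted `ape::phylo` tree (or a [species_tree_spec()]).
#' @param node Internal node label at which to report the ancestor; the
#'   root by default.
#' @return List with `sequence` (character, ambiguous sites as N) and
#'   `ambiguous` (logical vector per site).
#' @export
fitch_ancestral <- function(sequences, tree, node = NULL) {
  if (inherits(tree, "numt_tree_spec")) tree <- tree$tree
  if (length(sequences) < 3L) stop("need at least 3 taxa")
  if (!all(tree$tip.label %in% names(sequences))) {
    stop("sequences missing for tip(s): ",
         paste(setdiff(tree$tip.label, names(sequences)), collapse = ", "))
  }
  lens <- nchar(sequences[tree$tip.label])
  if (length(unique(lens)) != 1L) stop("sequences must be aligned")
  ntip <- length(tree$tip.label)
  if (is.null(tree$node.label)) {
    tree$node.label <- paste0("node", seq_len(tree$Nnode))
  }
  target <- if (is.null(node)) ntip + 1L else {
    idx <- match(node, tree$node.label)
    if (is.na(idx)) stop("unknown node: ", node)
    ntip + idx
  }
  if (target != ntip + 1L) {
    # the most-parsimonious state set at an internal node uses the whole
    # tree; re-rooting at the node makes the single bottom-up pass exact
    tree <- ape::root(tree, node = target, resolve.root = FALSE)
    tree$edge.length <- NULL
    tree <- stats::reorder(tree, "cladewise")
    target <- ntip + 1L
  }
  L <- lens[1]
  # state sets as 4-bit masks: A=1, C=2, G=4, T=8
  bit <- c(A = 1L, C = 2L, G = 4L, T = 8L, N = 15L, "-" = 15L)
  tipmat <- vapply(tree$tip.label, function(tp) {
    unname(bit[strsplit(toupper(sequences[[tp]]), "")[[1]]])
  }, integer(L))
  if (is.null(dim(tipmat))) tipmat <- matrix(tipmat, nrow = L)
  sets <- matrix(0L, L, ntip + tree$Nnode)
  sets[, seq_len(ntip)] <- tipmat
  # bottom-up (edges in reverse preorder: children before parents)
  for (e in rev(seq_len(nrow(tree$edge)))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    if (sets[1, p][1] == 0L && all(sets[, p] == 0L)) {
      sets[, p] <- sets[, ch]
    } else {
      inter <- bitwAnd(sets[, p], sets[, ch])
      sets[, p] <- ifelse(inter > 0L, inter, bitwOr(sets[, p], sets[, ch]))
    }
  }
  node_set <- sets[, target]
  n_states <- vapply(0:15, function(m) sum(bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L),
                     integer(1))[node_set + 1L]
  ambiguous <- n_states != 1L
  base_of <- c(`1` = "A", `2` = "C", `4` = "G", `8` = "T")
  chars <- rep("N", L)
  chars[!ambiguous] <- base_of[as.character(node_set[!ambiguous])]
  list(sequence = paste(chars, collapse = ""), ambiguous = ambiguous)
}

#' Allele matching ratio of a NUMT against ancestral and modern mtDNA
#'
#' Over the alignment columns where the ancestral and the modern mtDNA
#' differ (`ancestral_vs_modern` sites), counts how often the NUMT carries
#' the modern allele (`numt_vs_modern`) and returns their ratio. Columns
#' containing gaps or ambiguous bases (N) in any of the three sequences are
#' excluded. Counts can be pooled over the fragments of a multi-fragment
#' region by summing before division (see [date_region()]).
#'
#' @param numt,ancestral,modern Aligned equal-length sequences.
#' @return List with `numt_vs_modern`, `ancestral_vs_modern`, `amr`
#'   (NA when no informative site exists).
#' @export
compute_amr <- function(numt, ancestral, modern) {
  v <- lapply(list(numt, ancestral, modern),
              function(s) strsplit(toupper(s), "")[[1]])
  if (length(unique(lengths(v))) != 1L) {
    stop("sequences must be aligned to equal length")
  }
  ok <- !vapply(seq_along(v[[1]]), function(i) {
    any(c(v[[1]][i], v[[2]][i], v[[3]][i]) %in% c("-", "N"))
  }, logical(1))
  informative <- ok & v[[2]] != v[[3]]
  n_anc <- sum(informative)
  n_mod <- sum(informative & v[[1]] == v[[3]])
  list(numt_vs_modern = n_mod, ancestral_vs_modern = n_anc,
       amr = if (n_anc > 0L) n_mod / n_anc else NA_real_)
}

#' Insertion age from the allele matching ratio
#'
#' `age = (1 - amr) * T` Mya: a NUMT identical to the modern mtDNA
#' (amr = 1) inserted now; one identical to the ancestral state (amr = 0)
#' inserted at the divergence time T.
#'
#' @param amr Allele matching ratio in [0, 1].
#' @param T_mya Divergence time of the lineage (Mya): 3.5 for *Sus*,
#'   10 for Suinae.
#' @export
age_from_amr <- function(amr, T_mya) {
  if (is.na(amr)) return(NA_real_)
  if (amr < 0 || amr > 1) stop("amr outside [0, 1]")
  (1 - amr) * T_mya
}

#' Kimura two-parameter distance
#'
#' `K = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q))` with transition fraction P and
#' transversion fraction Q over pairwise-complete columns (gap or N columns
#' deleted pairwise).
#'
#' @param a,b Aligned equal-length sequences.
#' @return Distance (substitutions/site); NA with a warning attribute when
#'   the distance is saturated (log argument non-positive).
#' @export
kimura_k80 <- function(a, b) {
  x <- strsplit(toupper(a), "")[[1]]
  y <- strsplit(toupper(b), "")[[1]]
  if (length(x) != length(y)) stop("sequences must be aligned")
  ok <- x %in% .BASES & y %in% .BASES
  x <- x[ok]; y <- y[ok]
  if (!length(x)) return(NA_real_)
  xi <- match(x, .BASES); yi <- match(y, .BASES)
  diff <- xi != yi
  ts <- diff & (yi == .TS_PARTNER[xi])
  P <- mean(ts); Q <- mean(diff & !ts)
  arg <- (1 - 2 * P - Q) * sqrt(1 - 2 * Q)
  if (arg <= 0) {
    out <- NA_real_
    attr(out, "saturated") <- TRUE
    return(out)
  }
  -0.5 * log(arg)
}

#' Per-region mitochondrial substitution rate
#'
#' `V_mt = mean over species pairs of K_pair / (2 T_pair)` with T in years:
#' each pairwise distance accumulates along both branches since the pair
#' diverged. Computed per NUMT-matched mtDNA region because the
#' mitochondrial rate varies along the molecule.
#'
#' @param dist_mat Symmetric matrix of K80 distances between species, for
#'   the mtDNA region matched by the NUMT.
#' @param times_mya Matrix (or function of two names) of pairwise
#'   divergence times in Mya; pairs with missing times are skipped.
#' @return Rate in substitutions/site/year.
#' @export
compute_vmt <- function(dist_mat, times_mya) {
  sp <- rownames(dist_mat)
  vals <- c()
  for (i in seq_along(sp)[-1]) {
    for (j in seq_len(i - 1L)) {
      T_pair <- if (is.function(times_mya)) {
        times_mya(sp[i], sp[j])
      } else {
        times_mya[sp[i], sp[j]]
      }
      if (is.na(T_pair) || T_pair <= 0) next
      k <- dist_mat[sp[i], sp[j]]
      if (is.na(k)) next
      vals <- c(vals, k / (2 * T_pair * 1e6))
    }
  }
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Insertion age from Kimura distances
#'
#' `t = K / (V_mt + V_numt)` years (reported in Mya): after insertion the
#' NUMT copy decays at the nuclear rate while the mitochondrial lineage
#' keeps evolving at the mitochondrial rate, so their distance grows at the
#' summed rate.
#'
#' @param K Mean K80 distance between the NUMT and the mtDNA sequences of
#'   the clade below the insertion point.
#' @param v_mt Mitochondrial rate (subs/site/year), from [compute_vmt()].
#' @param v_numt Nuclear rate (subs/site/year).
#' @return Age in Mya (NA when K is saturated/NA).
#' @export
age_from_kimura <- function(K, v_mt, v_numt) {
  stopifnot(v_mt + v_numt > 0)
  if (is.na(K)) return(NA_real_)
  (K / (v_mt + v_numt)) / 1e6
}

#' Select the insertion-point clade and its mean NUMT distance
#'
#' The species with the smallest K80 distance to the NUMT approximates the
#' insertion point; K is the mean distance from the NUMT to all species
#' whose divergence time from the host lineage does not exceed that of the
#' closest species (the clade below the insertion point). With
#' `strictly_lower = TRUE` the alternative reading — only species strictly
#' closer than the closest species' divergence — is used.
#'
#' @param numt_dists Named vector of K80 distances NUMT -> species.
#' @param host Host species name.
#' @param spec A [species_tree_spec()] providing divergence times.
#' @param strictly_lower Alternative clade membership reading.
#' @return List with `closest`, `clade` (species used) and `K`.
#' @export
insertion_point_K <- function(numt_dists, host, spec,
                              strictly_lower = FALSE) {
  numt_dists <- numt_dists[!is.na(numt_dists)]
  if (!length(numt_dists)) return(list(closest = NA, clade = character(0),
                                       K = NA_real_))
  closest <- names(numt_dists)[which.min(numt_dists)]
  div_host <- vapply(names(numt_dists), function(s) {
    if (s == host) 0 else .divergence_mya(spec, host, s)
  }, numeric(1))
  lim <- div_host[closest]
  clade <- if (strictly_lower) {
    names(numt_dists)[div_host < lim | names(numt_dists) == closest]
  } else {
    names(numt_dists)[div_host <= lim]
  }
  list(closest = closest, clade = clade,
       K = mean(numt_dists[clade]))
}

#' Date one NUMT region
#'
#' Method dispatch for the quantitative age:
#' * Method 1 (allele matching ratio) for regions classed `LE_3p5` or
#'   `10_3p5` whose summed fragment length exceeds 150 bp, whose mean
#'   identity exceeds 80% (low identity suggests an older insertion that
#'   merely went undetected in the warthog assembly), and which do not
#'   derive from the D-loop. Counts are summed over fragments before
#'   forming the ratio.
#' * Method 2 (Kimura distances) otherwise, on the longest fragment, when
#'   that fragment exceeds 150 bp and is not D-loop-derived.
#' * Class-only estimate when neither method applies.
#'
#' @param region Region row (with `mean_identity`).
#' @param fragments data.frame of member fragments: `mt_start`, `mt_end`
#'   (0-based half-open, `mt_end` may exceed L for origin-spanning
#'   fragments), `numt_seq` (nuclear copy sequence).
#' @param age_class From [assign_age_class()].
#' @param mt_panel Named list for method 1: `ancestral`, `modern` (full
#'   mtDNA, same coordinates, from [fitch_ancestral()] and the host
#'   consensus).
#' @param dist_panel Named list for method 2: `species_seqs` (named full
#'   mtDNA sequences), `host`, `spec` (a [species_tree_spec()]).
#' @param rates A [mutation_rate_config()].
#' @param dloop 0-based half-open D-loop interval on the mtDNA; a region
#'   overlapping it by more than half of the region's mt span is excluded
#'   from dating.
#' @param identity_gate Method-1 identity threshold.
#' @param min_span Minimum fragment span (bp), strict.
#' @return List: `age_class`, `method` ("amr", "kimura", "class_only"),
#'   `age_mya` (NA for class_only), and method details.
#' @export
date_region <- function(region, fragments, age_class, mt_panel = NULL,
                        dist_panel = NULL, rates = mutation_rate_config(),
                        dloop = NULL, identity_gate = 0.80,
                        min_span = 150L) {
  L <- if (!is.null(mt_panel)) nchar(mt_panel$modern) else
    if (!is.null(dist_panel)) nchar(dist_panel$species_seqs[[1]]) else NA
  is_dloop <- function(ms, me) {
    if (is.null(dloop)) return(FALSE)
    ov <- max(0, min(me, dloop[2]) - max(ms, dloop[1]))
    if (!is.na(L) && me > L) {   # origin-spanning: also check wrapped part
      ov <- ov + max(0, min(me - L, dloop[2]) - max(0, dloop[1]))
    }
    ov > 0.5 * (me - ms)
  }
  total_span <- sum(fragments$mt_end - fragments$mt_start)
  dloop_region <- all(vapply(seq_len(nrow(fragments)), function(i) {
    is_dloop(fragments$mt_start[i], fragments$mt_end[i])
  }, logical(1)))
  class_only <- list(age_class = age_class, method = "class_only",
                     age_mya = NA_real_)
  if (age_class %in% c("undetermined")) return(class_only)
  use_amr <- age_class %in% c("LE_3p5", "10_3p5") &&
    total_span > min_span &&
    isTRUE(region$mean_identity > identity_gate) &&
    !dloop_region && !is.null(mt_panel)
  if (use_amr) {
    T_mya <- if (age_class == "LE_3p5") 3.5 else 10
    n_mod <- 0L; n_anc <- 0L
    for (i in seq_len(nrow(fragments))) {
      if (is_dloop(fragments$mt_start[i], fragments$mt_end[i])) next
      anc <- .circular_segment(mt_panel$ancestral, fragments$mt_start[i] %% L,
                               fragments$mt_end[i] %% L,
                               wraparound = fragments$mt_end[i] > L)
      mod <- .circular_segment(mt_panel$modern, fragments$mt_start[i] %% L,
                               fragments$mt_end[i] %% L,
                               wraparound = fragments$mt_end[i] > L)
      numt <- fragments$numt_seq[i]
      if (nchar(numt) != nchar(mod)) next   # fragment with indels: skip
      a <- compute_amr(numt, anc, mod)
      n_mod <- n_mod + a$numt_vs_modern
      n_anc <- n_anc + a$ancestral_vs_modern
    }
    if (n_anc > 0L) {
      amr <- n_mod / n_anc
      return(list(age_class = age_class, method = "amr",
                  age_mya = age_from_amr(amr, T_mya), amr = amr,
                  numt_vs_modern = n_mod, ancestral_vs_modern = n_anc,
                  T_mya = T_mya))
    }
    return(class_only)
  }
  # method 2 on the longest fragment
  if (is.null(dist_panel)) return(class_only)
  spans <- fragments$mt_end - fragments$mt_start
  keep <- spans > min_span & !vapply(seq_len(nrow(fragments)), function(i) {
    is_dloop(fragments$mt_start[i], fragments$mt_end[i])
  }, logical(1))
  if (!any(keep)) return(class_only)
  fi <- which(keep)[which.max(spans[keep])]
  ms <- fragments$mt_start[fi] %% L
  me <- fragments$mt_end[fi] %% L
  wrap <- fragments$mt_end[fi] > L
  numt <- fragments$numt_seq[fi]
  segs <- lapply(dist_panel$species_seqs, function(s) {
    .circular_segment(s, ms, me, wraparound = wrap)
  })
  if (any(nchar(numt) != nchar(segs[[1]]))) return(class_only)
  sp_names <- names(segs)
  numt_d <- vapply(sp_names, function(s) kimura_k80(numt, segs[[s]]),
                   numeric(1))
  dmat <- matrix(NA_real_, length(sp_names), length(sp_names),
                 dimnames = list(sp_names, sp_names))
  for (i in seq_along(sp_names)) {
    for (j in seq_along(sp_names)) {
      if (i < j) {
        dmat[i, j] <- dmat[j, i] <- kimura_k80(segs[[i]], segs[[j]])
      } else if (i == j) dmat[i, j] <- 0
    }
  }
  v_mt <- compute_vmt(dmat, function(a, b) {
    .divergence_mya(dist_panel$spec, a, b)
  })
  ip <- insertion_point_K(numt_d, dist_panel$host, dist_panel$spec)
  if (is.na(ip$K) || is.na(v_mt) || v_mt <= 0) return(class_only)
  ages <- vapply(rates, function(v) age_from_kimura(ip$K, v_mt, v),
                 numeric(1))
  list(age_class = age_class, method = "kimura",
       age_mya = unname(ages["mammalian"]), K = ip$K, v_mt = v_mt,
       closest = ip$closest, clade = ip$clade, ages_by_rate = ages)
}
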
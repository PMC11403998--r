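# K80 sequence evolution engine.
#
# Sequences are stored as integer vectors over 1:4 = A,C,G,T. With overall
# substitution rate mu (subs/site/year) and transition/transversion rate
# ratio kappa, the instantaneous rates are alpha = kappa*beta (transition)
# and beta (each transversion), with mu = alpha + 2*beta. Closed-form
# transition probabilities over time t:
#   p_same = 1/4 + 1/4 e^{-4 beta t} + 1/2 e^{-2(alpha+beta) t}
#   p_ts   = 1/4 + 1/4 e^{-4 beta t} - 1/2 e^{-2(alpha+beta) t}
#   p_tv   = 1/4 - 1/4 e^{-4 beta t}   (each of the two transversions)

.BASES <- c("A", "C", "G", "T")
.TS_PARTNER <- c(3L, 4L, 1L, 2L)   # A<->G, C<->T
.TV_PARTNER1 <- c(2L, 1L, 2L, 1L)
.TV_PARTNER2 <- c(4L, 3L, 4L, 3L)

.k80_probs <- function(t_years, rate, kappa) {
  t_years <- unname(t_years)
  beta <- rate / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * t_years)
  e2 <- exp(-2 * (alpha + beta) * t_years)
  c(same = 0.25 + 0.25 * e1 + 0.5 * e2,
    ts = 0.25 + 0.25 * e1 - 0.5 * e2,
    tv = 0.25 - 0.25 * e1)
}

# Evolve an integer-coded sequence for t_years under K80.
.evolve_k80 <- function(seq_int, t_years, rate, kappa) {
  if (t_years <= 0) return(seq_int)
  p <- .k80_probs(t_years, rate, kappa)
  n <- length(seq_int)
  u <- stats::runif(n)
  out <- seq_int
  is_ts <- u >= p["same"] & u < p["same"] + p["ts"]
  is_tv <- u >= p["same"] + p["ts"]
  out[is_ts] <- .TS_PARTNER[seq_int[is_ts]]
  if (any(is_tv)) {
    pick2 <- stats::runif(sum(is_tv)) < 0.5
    tv_idx <- which(is_tv)
    out[tv_idx[pick2]] <- .TV_PARTNER1[seq_int[tv_idx[pick2]]]
    out[tv_idx[!pick2]] <- .TV_PARTNER2[seq_int[tv_idx[!pick2]]]
  }
  out
}

.int2dna <- function(seq_int) paste(.BASES[seq_int], collapse = "")
.dna2int <- function(seq_chr) {
  match(strsplit(toupper(seq_chr), "")[[1]], .BASES)
}

#' Simulate a set of mitochondrial genomes on a species tree
#'
#' Evolves a circular mtDNA sequence from the tree root to every tip under
#' the K80 substitution model at the tree's mitochondrial rate, recording the
#' true ancestral sequence at every internal node. No indels are simulated,
#' so every sequence has identical length and positions are directly
#' comparable across the whole set. Additional `sample_points` request the
#' lineage state of a species at an arbitrary age (Mya); these are the true
#' mtDNA sequences that existed on that lineage at that time and serve as the
#' source sequences for NUMT planting.
#'
#' @param spec A [species_tree_spec()].
#' @param seed Integer random seed; identical seeds give identical output.
#' @param sample_points Optional data.frame with columns `species` and `age`
#'   (Mya, 0 <= age <= root age).
#' @param root_seq Optional root sequence (character); uniform random ACGT of
#'   length `spec$mt_length` by default.
#' @return A list with `tips` (named character vector of modern sequences),
#'   `ancestors` (named by internal-node label), `lineage` (named
#'   `"species@age"` character vector for each sample point), `heights`, and
#'   `spec`.
#' @export
simulate_mtdna_set <- function(spec, seed, sample_points = NULL,
                               root_seq = NULL) {
  stopifnot(inherits(spec, "numt_tree_spec"))
  set.seed(as.integer(seed))
  tree <- spec$tree
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  heights <- spec$heights
  if (!is.null(sample_points) && nrow(sample_points)) {
    bad <- sample_points$age < 0 | sample_points$age > max(heights) + 1e-9
    if (any(bad)) stop("sample point age outside [0, root age]")
  }
  root_int <- if (is.null(root_seq)) {
    sample.int(4L, spec$mt_length, replace = TRUE)
  } else .dna2int(root_seq)

  # descendant tips of every node, for routing sample points along edges
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  for (e in rev(seq_len(nrow(tree$edge)))) {   # edges are in preorder
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }

  states <- vector("list", ntip + tree$Nnode)
  states[[root]] <- root_int
  lineage <- character(0)
  rate <- spec$mito_rate; kappa <- spec$kappa
  node_name <- c(tree$tip.label, tree$node.label)
  for (e in seq_len(nrow(tree$edge))) {        # preorder traversal
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    h_p <- heights[node_name[p]]; h_c <- heights[node_name[ch]]
    cur <- states[[p]]; cur_h <- h_p
    if (!is.null(sample_points) && nrow(sample_points)) {
      on_edge <- sample_points$species %in% desc[[ch]] &
        sample_points$age < cur_h - 1e-12 &
        sample_points$age >= h_c - 1e-12
      ages <- sort(unique(sample_points$age[on_edge]), decreasing = TRUE)
      for (a in ages) {
        cur <- .evolve_k80(cur, (cur_h - a) * 1e6, rate, kappa)
        cur_h <- a
        sp_here <- unique(sample_points$species[on_edge &
                            abs(sample_points$age - a) < 1e-12])
        seq_chr <- .int2dna(cur)
        for (sp in sp_here) lineage[paste0(sp, "@", a)] <- seq_chr
      }
    }
    states[[ch]] <- .evolve_k80(cur, (cur_h - h_c) * 1e6, rate, kappa)
  }
  tips <- vapply(seq_len(ntip), function(i) .int2dna(states[[i]]),
                 character(1))
  names(tips) <- tree$tip.label
  ancestors <- vapply(ntip + seq_len(tree$Nnode),
                      function(i) .int2dna(states[[i]]), character(1))
  names(ancestors) <- tree$node.label
  # root-age sample points coincide with the root ancestor
  if (!is.null(sample_points) && nrow(sample_points)) {
    at_root <- abs(sample_points$age - max(heights)) < 1e-12
    for (i in which(at_root)) {
      lineage[paste0(sample_points$species[i], "@",
                     sample_points$age[i])] <- ancestors[[
        tree$node.label[root - ntip]]]
    }
  }
  list(tips = tips, ancestors = ancestors, lineage = lineage,
       heights = heights, spec = spec)
}
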
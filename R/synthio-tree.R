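#' Species tree specification for the synthetic-data generator
#'
#' Describes the species tree on which mitochondrial (and nuclear background)
#' evolution is simulated. The default scaffold mirrors the Suinae/bovid
#' divergence structure used throughout the package: *Sus* species splitting
#' about 3.5 Mya, the warthog lineage about 10 Mya, and the bovid outgroup
#' about 55 Mya.
#'
#' @param newick Newick topology. Branch lengths, when present, are in Mya;
#'   otherwise `divergence_times` must give the height (Mya) of every labelled
#'   internal node, and tips are at height 0.
#' @param divergence_times Named numeric vector of internal-node heights in
#'   Mya (names = node labels). Ignored when the newick carries edge lengths.
#' @param mito_rate Mitochondrial substitution rate, substitutions/site/year.
#' @param nuclear_rate Nuclear substitution rate, substitutions/site/year.
#'   The default 2.2e-9 is the average mammalian nuclear rate.
#' @param kappa Transition/transversion rate ratio of the K80 model.
#' @param mt_length Mitochondrial genome length in bp.
#' @return An object of class `numt_tree_spec` with the `ape::phylo` tree
#'   (edge lengths in Mya), node heights, and the rates.
#' @export
species_tree_spec <- function(newick, divergence_times = NULL,
                              mito_rate = 2e-8, nuclear_rate = 2.2e-9,
                              kappa = 4, mt_length = 16600L) {
  stopifnot(mito_rate > 0, nuclear_rate > 0, kappa > 0, mt_length > 1000)
  tree <- ape::read.tree(text = newick)
  if (is.null(tree)) stop("could not parse newick topology")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  if (is.null(tree$node.label) || any(tree$node.label == "")) {
    lab <- tree$node.label
    if (is.null(lab)) lab <- rep("", nnode)
    lab[lab == ""] <- paste0("node", which(lab == ""))
    tree$node.label <- lab
  }
  heights <- numeric(ntip + nnode)
  if (is.null(tree$edge.length)) {
    if (is.null(divergence_times)) {
      stop("newick has no branch lengths; divergence_times is required")
    }
    idx <- match(tree$node.label, names(divergence_times))
    if (anyNA(idx)) stop("divergence_times missing for internal node(s): ",
                         paste(tree$node.label[is.na(idx)], collapse = ", "))
    heights[ntip + seq_len(nnode)] <- as.numeric(divergence_times[idx])
    el <- heights[tree$edge[, 1]] - heights[tree$edge[, 2]]
    if (any(el <= 0)) {
      stop("divergence times are not ultrametric-consistent with the ",
           "topology (a parent is not older than its child)")
    }
    tree$edge.length <- el
  } else {
    # heights from edge lengths; verify ultrametricity
    root <- ntip + 1L
    depth <- numeric(ntip + nnode)
    for (e in seq_len(nrow(tree$edge))) {
      depth[tree$edge[e, 2]] <- depth[tree$edge[e, 1]] + tree$edge.length[e]
    }
    tipd <- depth[seq_len(ntip)]
    if (diff(range(tipd)) > 1e-6 * max(tipd)) {
      stop("tree is not ultrametric: tip depths differ")
    }
    heights <- max(tipd) - depth
  }
  if (any(heights[ntip + seq_len(nnode)] <= 0)) {
    stop("divergence times must be strictly positive")
  }
  names(heights) <- c(tree$tip.label, tree$node.label)
  structure(list(tree = tree, heights = heights,
                 mito_rate = mito_rate, nuclear_rate = nuclear_rate,
                 kappa = kappa, mt_length = as.integer(mt_length)),
            class = "numt_tree_spec")
}

#' @rdname species_tree_spec
#' @param ... Passed to [species_tree_spec()] (rates, kappa, mt_length).
#' @export
suinae_tree_spec <- function(...) {
  species_tree_spec(
    "(((scrofa:3.5,cebifrons:3.5)sus:6.5,warthog:10)suinae:45,bovid:55)root;",
    ...)
}

#' Age of the root of a tree specification (Mya)
#' @param spec A `numt_tree_spec`.
#' @export
root_age <- function(spec) {
  unname(max(spec$heights))
}

# Internal node names on the path from the root to `species` (root first),
# excluding the tip itself.
.lineage_nodes <- function(spec, species) {
  tree <- spec$tree
  ntip <- length(tree$tip.label)
  node <- match(species, tree$tip.label)
  if (is.na(node)) stop("unknown species: ", species)
  path <- integer(0)
  repeat {
    e <- which(tree$edge[, 2] == node)
    if (!length(e)) break
    node <- tree$edge[e, 1]
    path <- c(node, path)
  }
  tree$node.label[path - ntip]
}
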
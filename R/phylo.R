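#' Read a Newick tree
#'
#' Parses a Newick string (plain or quoted labels, ":length" branch lengths, no
#' comment blocks) into an [ape::read.tree()] `"phylo"` object, validating the
#' invariants the rest of the package relies on: unique tip labels and strictly
#' positive branch lengths. Zero or missing branch lengths are replaced by a
#' small epsilon so that the Brownian-motion covariance stays positive definite
#' and downstream whitening transforms remain invertible.
#'
#' @param text A Newick string (terminated by `;`).
#' @param zero_length_epsilon Replacement, in the tree's time units (Ma), for
#'   zero or absent branch lengths. Default `1e-8`.
#' @return A rooted `"phylo"` object with positive branch lengths.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' tr$tip.label
#' @export
read_newick <- function(text, zero_length_epsilon = 1e-8) {
  stopifnot(is.character(text), length(text) == 1L)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("malformed Newick string: ", conditionMessage(e), call. = FALSE),
    warning = function(w) stop("malformed Newick string: ", conditionMessage(w), call. = FALSE)
  )
  if (is.null(tree)) stop("malformed Newick string: parser returned no tree", call. = FALSE)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0L) {
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("Newick string has no branch lengths", call. = FALSE)
  }
  fix <- is.na(tree$edge.length) | tree$edge.length <= 0
  if (any(fix)) {
    message(sum(fix), " non-positive branch length(s) replaced by ", zero_length_epsilon)
    tree$edge.length[fix] <- zero_length_epsilon
  }
  tree
}

#' Write a tree as a Newick string
#'
#' @param tree A `"phylo"` object.
#' @return A Newick string. `read_newick(write_newick(tree))` preserves the
#'   topology, tip labels and pairwise tip distances.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}

#' Brownian-motion covariance matrix of a tree
#'
#' Entry (i, j) is the shared path length from the root to the most recent
#' common ancestor of tips i and j; the diagonal holds root-to-tip distances.
#' This is the covariance, up to the rate constant, of a Brownian-motion trait
#' evolving along the tree, and is the matrix consumed by [blomberg_k()],
#' [k_mult()], [phylogenetic_hsd()] and [pfda_fit()].
#'
#' @param tree A `"phylo"` object with at least 2 tips.
#' @return A symmetric positive semi-definite matrix with tip labels as
#'   dimnames, in the tree's tip order.
#' @examples
#' bm_covariance(read_newick("((A:1,B:1):1,C:2);"))
#' @export
bm_covariance <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L) stop("tree must have at least 2 tips", call. = FALSE)
  C <- ape::vcv.phylo(tree)
  # a root edge (e.g. retained by prune_to) is variance shared by every tip
  if (!is.null(tree$root.edge) && isTRUE(tree$root.edge > 0)) C <- C + tree$root.edge
  C
}

#' Node ages below the present
#'
#' Ages (Ma before present) of all nodes, taking the deepest tip as the
#' present. Used to convert the absolute fossil ages of [graft_fossil_tips()]
#' into tree depths.
#'
#' @param tree A `"phylo"` object.
#' @return Numeric vector over nodes `1..(Ntip + Nnode)`.
#' @export
node_ages <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  max(depths[seq_along(tree$tip.label)]) - depths
}

#' Graft fossil tips onto a host tree at absolute ages
#'
#' Attaches a (possibly single-tip) fossil subtree below a host node. The
#' subtree's root divergence is placed at `attach_age` (Ma before present,
#' converted to depth using the host's deepest tip as the present); successive
#' internal divergences inside the grafted subtree are separated by
#' `divergence_duration` (default 0.001 Ma, i.e. 1,000 years); each grafted tip
#' terminates at its own age. Host topology and branch lengths are unchanged.
#'
#' @param host Host `"phylo"` tree.
#' @param subtree Fossil subtree (`"phylo"`; its branch lengths are ignored,
#'   only the topology is used), or a single tip label for a lone fossil.
#' @param attach_node Node of the host to attach below: a node number or a tip
#'   label.
#' @param attach_age Age (Ma) of the divergence between the grafted clade and
#'   the host lineage. Must not exceed the attach node's age and must exceed
#'   every fossil tip age.
#' @param tip_ages Named numeric vector of tip ages (Ma) for every subtree tip.
#' @param divergence_duration Spacing (Ma) between successive divergences
#'   within the grafted subtree. Default `0.001`.
#' @return A `"phylo"` tree containing the host plus the fossil tips.
#' @export
graft_fossil_tips <- function(host, subtree, attach_node, attach_age, tip_ages,
                              divergence_duration = 0.001) {
  stopifnot(inherits(host, "phylo"), divergence_duration > 0)
  if (is.character(subtree) && length(subtree) == 1L) {
    subtree <- structure(list(edge = matrix(c(2L, 1L), 1, 2), tip.label = subtree,
                              edge.length = 1, Nnode = 1L), class = "phylo")
  }
  stopifnot(inherits(subtree, "phylo"))
  if (!all(subtree$tip.label %in% names(tip_ages))) {
    stop("tip_ages must name every subtree tip", call. = FALSE)
  }
  tip_ages <- tip_ages[subtree$tip.label]
  if (any(tip_ages >= attach_age)) {
    stop("infeasible graft: tip age >= attach_age for ",
         paste(subtree$tip.label[tip_ages >= attach_age], collapse = ", "), call. = FALSE)
  }
  if (is.character(attach_node)) {
    idx <- match(attach_node, host$tip.label)
    if (is.na(idx)) stop("attach_node label not found among host tips", call. = FALSE)
    attach_node <- idx
  }
  ages_host <- node_ages(host)
  node_age <- ages_host[attach_node]
  is_tip_attach <- attach_node <= length(host$tip.label)
  if (!is_tip_attach && attach_age > node_age + 1e-12) {
    stop("attach_age (", attach_age, " Ma) is older than the attach node (",
         signif(node_age, 6), " Ma)", call. = FALSE)
  }

  # assign ages inside the grafted subtree: root at attach_age, each internal
  # node divergence_duration below its parent, tips at their own ages
  ntip <- length(subtree$tip.label)
  nnode <- subtree$Nnode
  age <- numeric(ntip + nnode)
  root <- ntip + 1L
  age[root] <- attach_age
  if (nnode > 1L) {
    stack <- root
    while (length(stack) > 0L) { # breadth-first: parents assigned before children
      nd <- stack[[1L]]; stack <- stack[-1L]
      kids <- subtree$edge[subtree$edge[, 1] == nd, 2]
      internal <- kids[kids > ntip]
      age[internal] <- age[nd] - divergence_duration
      stack <- c(stack, internal)
    }
  }
  age[seq_len(ntip)] <- tip_ages
  if (any(age[-seq_len(ntip)] <= max(tip_ages))) {
    stop("divergence_duration pushes an internal divergence below a tip age", call. = FALSE)
  }
  sub2 <- subtree
  sub2$edge.length <- age[subtree$edge[, 1]] - age[subtree$edge[, 2]]

  if (attach_node <= length(host$tip.label)) {
    # divergence from a terminal host lineage: insert a new node on the
    # pendant edge at depth corresponding to attach_age
    pos <- attach_age - node_age
    edge_len <- host$edge.length[which(host$edge[, 2] == attach_node)]
    if (pos <= 0 || pos >= edge_len + 1e-12) {
      stop("attach_age does not fall on the pendant edge of the attach tip", call. = FALSE)
    }
    sub2$root.edge <- 0
    out <- ape::bind.tree(host, sub2, where = attach_node, position = pos)
  } else {
    sub2$root.edge <- node_age - attach_age
    out <- ape::bind.tree(host, sub2, where = attach_node)
  }
  out
}

#' Linearly rescale a clade to a target depth
#'
#' Multiplies every branch length within the clade rooted at `clade_root` by
#' `target_depth / current_depth`, where the current depth is the maximum
#' distance from the clade root to its tips (for a tip, the pendant edge and
#' its length). Branches outside the clade are untouched, so Brownian
#' covariances within the clade are scaled proportionally.
#'
#' @param tree A `"phylo"` object.
#' @param clade_root Node number, or tip label for a single-branch clade.
#' @param target_depth Desired clade depth (Ma), > 0.
#' @return The rescaled tree.
#' @export
scale_clade_depth <- function(tree, clade_root, target_depth) {
  stopifnot(inherits(tree, "phylo"), target_depth > 0)
  if (is.character(clade_root)) {
    idx <- match(clade_root, tree$tip.label)
    if (is.na(idx)) stop("clade_root label not found", call. = FALSE)
    clade_root <- idx
  }
  ntip <- length(tree$tip.label)
  if (clade_root <= ntip) {
    edge_idx <- which(tree$edge[, 2] == clade_root)
    cur <- tree$edge.length[edge_idx]
  } else {
    desc_edges <- which_clade_edges(tree, clade_root)
    edge_idx <- desc_edges
    depths <- ape::node.depth.edgelength(tree)
    tips_in <- intersect(tree$edge[desc_edges, 2], seq_len(ntip))
    cur <- max(depths[tips_in]) - depths[clade_root]
  }
  if (cur <= 0) stop("zero-depth clade cannot be rescaled", call. = FALSE)
  tree$edge.length[edge_idx] <- tree$edge.length[edge_idx] * (target_depth / cur)
  tree
}

# edge indices of all edges descending from (and excluding the stem of) a node
which_clade_edges <- function(tree, node) {
  keep <- logical(nrow(tree$edge))
  stack <- node
  while (length(stack) > 0L) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    kids <- which(tree$edge[, 1] == nd)
    keep[kids] <- TRUE
    stack <- c(stack, tree$edge[kids, 2])
  }
  which(keep)
}

#' Prune a tree to a set of tips
#'
#' Returns the induced subtree on `taxa`: path lengths between retained tips
#' are preserved and degree-2 nodes are suppressed.
#'
#' @param tree A `"phylo"` object.
#' @param taxa Character vector of tip labels to keep (at least 2).
#' @return The pruned `"phylo"` tree.
#' @export
prune_to <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"))
  taxa <- unique(as.character(taxa))
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown) > 0L) {
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (length(taxa) < 2L) stop("need at least 2 taxa to prune to", call. = FALSE)
  drop <- setdiff(tree$tip.label, taxa)
  if (length(drop) == 0L) return(tree)
  sub <- ape::keep.tip(tree, taxa)
  # keep the path from the original root down to the retained MRCA as a root
  # edge, so that Brownian covariances of pruned trees equal the
  # corresponding submatrix of the full tree's covariance
  mrca_depth <- ape::node.depth.edgelength(tree)[ape::getMRCA(tree, taxa)]
  if (mrca_depth > 0) sub$root.edge <- mrca_depth + (tree$root.edge %||% 0)
  sub
}
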
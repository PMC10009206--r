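# Shared fixtures built in code. Trees are random but seeded per test.

random_ultrametric <- function(n, seed) {
  set.seed(seed)
  ape::rcoal(n, tip.label = paste0("t", seq_len(n)))
}

random_tree <- function(n, seed) {
  set.seed(seed)
  ape::rtree(n, tip.label = paste0("t", seq_len(n)))
}

# independent path-length oracle for the Brownian covariance: entry (i, j) is
# the summed branch length shared by the root-to-tip paths of i and j
vcv_oracle <- function(tree) {
  n <- length(tree$tip.label)
  edge_on_path <- function(tip) {
    path <- integer(0)
    node <- tip
    repeat {
      e <- which(tree$edge[, 2] == node)
      if (length(e) == 0L) break
      path <- c(path, e)
      node <- tree$edge[e, 1]
    }
    path
  }
  paths <- lapply(seq_len(n), edge_on_path)
  M <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    M[i, j] <- sum(tree$edge.length[intersect(paths[[i]], paths[[j]])])
  }
  M
}

elton_row <- function(...) {
  base <- c("Diet-PlantO" = 0, "Diet-Fruit" = 0, "Diet-Seed" = 0,
            "Diet-Nect" = 0, "Diet-Inv" = 0, "Diet-Fish" = 0,
            "Diet-Scav" = 0, "Diet-Ect" = 0, "Diet-End" = 0)
  over <- c(...)
  base[names(over)] <- over
  base
}

# random similarity transform applied to a 2-column landmark matrix
similarity_transform <- function(pts, angle, scale, shift) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2)
  sweep(scale * pts %*% t(R), 2L, shift, `+`)
}
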
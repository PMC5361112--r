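# Independent oracles, kept separate from the code paths they check.

# Brute-force base-calling rule, straight from the stated criteria, using
# integer arithmetic only: depth bound, exclusive majority bound as the
# cross-multiplied fraction maj_num/maj_den, sole-maximum requirement.
oracle_call <- function(a, c, g, t, min_depth, maj_num, maj_den) {
  v <- unname(c(a, c, g, t))
  d <- sum(v)
  if (d < min_depth) return("N")
  mx <- max(v)
  if (sum(v == mx) != 1) return("N")
  if (mx * maj_den > maj_num * d) c("A", "C", "G", "T")[which.max(v)] else "N"
}

# Exhaustive least-squares topology selection: enumerate every unrooted
# binary topology on the taxa, fit branch lengths to the distance matrix by
# least squares on the path-incidence design matrix, return the topology
# with the smallest residual sum of squares.
.topology_cache <- new.env(parent = emptyenv())

all_topologies <- function(labs) {
  key <- paste(sort(labs), collapse = "|")
  if (is.null(.topology_cache[[key]]))
    .topology_cache[[key]] <- phangorn::allTrees(length(labs),
                                                 rooted = FALSE,
                                                 tip.label = sort(labs))
  .topology_cache[[key]]
}

ls_best_topology <- function(D) {
  labs <- rownames(D)
  n <- length(labs)
  trees <- all_topologies(labs)
  pairs <- t(utils::combn(n, 2))
  dvec <- D[cbind(labs[pairs[, 1]], labs[pairs[, 2]])]
  best <- NULL
  best_rss <- Inf
  for (ti in seq_along(trees)) {
    tr <- trees[[ti]]  # [[ expands the multiPhylo's compressed tip labels
    X <- matrix(0, nrow(pairs), nrow(tr$edge))
    for (r in seq_len(nrow(pairs))) {
      i <- match(labs[pairs[r, 1]], tr$tip.label)
      j <- match(labs[pairs[r, 2]], tr$tip.label)
      p <- ape::nodepath(tr, i, j)
      for (k in seq_len(length(p) - 1)) {
        e <- which((tr$edge[, 1] == p[k] & tr$edge[, 2] == p[k + 1]) |
                     (tr$edge[, 1] == p[k + 1] & tr$edge[, 2] == p[k]))
        X[r, e] <- 1
      }
    }
    rss <- sum(stats::lm.fit(X, dvec)$residuals^2)
    if (rss < best_rss) {
      best_rss <- rss
      best <- tr
    }
  }
  best
}

# random unrooted binary tree with strictly positive branch lengths and its
# additive (path-length) distance matrix
random_additive_matrix <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  list(tree = tr, D = stats::cophenetic(tr))
}
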
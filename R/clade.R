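#' Pairwise distance matrix with pairwise deletion
#'
#' Uncorrected p-distance: for each pair of sequences, sites where both
#' carry an unambiguous base (A/C/G/T) are compared and the distance is the
#' mismatch fraction over those comparable sites. N and `-` are treated as
#' missing. A Jukes-Cantor correction is available for deeper divergences.
#'
#' @param alignment named character vector of equal-length sequences over
#'   A/C/G/T/N/- (at least two).
#' @param model `"p"` (default) or `"jc"` (Jukes-Cantor corrected).
#' @return a list of class `distance_matrix`: `labels`, `d` (symmetric
#'   matrix, zero diagonal), `comparable` (pairwise comparable-site
#'   counts).
#' @export
compute_distances <- function(alignment, model = c("p", "jc")) {
  model <- match.arg(model)
  alignment <- unlist(alignment)
  n <- length(alignment)
  if (n < 2) stop("need at least two sequences")
  if (length(unique(nchar(alignment))) > 1)
    stop("sequences must have equal lengths")
  labels <- names(alignment)
  if (is.null(labels)) labels <- sprintf("seq%d", seq_len(n))
  mat <- matrix(unlist(strsplit(alignment, "", fixed = TRUE)),
                nrow = n, byrow = TRUE)
  ok <- matrix(mat %in% DNA_BASES, nrow = n)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  comp <- matrix(nchar(alignment[1]), n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    both <- ok[i, ] & ok[j, ]
    nc <- sum(both)
    if (nc == 0)
      stop("no comparable sites between ", labels[i], " and ", labels[j])
    p <- sum(mat[i, both] != mat[j, both]) / nc
    if (model == "jc") {
      if (p >= 0.75) stop("p-distance too large for Jukes-Cantor correction (",
                          labels[i], " vs ", labels[j], ")")
      p <- -0.75 * log(1 - 4 * p / 3)
    }
    d[i, j] <- d[j, i] <- p
    comp[i, j] <- comp[j, i] <- nc
  }
  structure(list(labels = labels, d = d, comparable = comp),
            class = "distance_matrix")
}

as_dist_matrix <- function(D) {
  if (inherits(D, "distance_matrix")) return(D$d)
  if (inherits(D, "dist")) return(as.matrix(D))
  as.matrix(D)
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration implemented from its standard recurrences.
#' On an additive distance matrix the leaf-to-leaf path lengths of the
#' result reproduce the input exactly. Ties in the Q-matrix minimisation
#' are broken by lexicographic order of the joined pair's labels, so the
#' output is invariant to taxon input order. Negative branch-length
#' estimates are clamped to zero with the deficit transferred to the
#' sibling branch (their sum is preserved); occurrences are counted in the
#' `n_clamped` attribute.
#'
#' @param D a [compute_distances()] result, a `dist`, or a symmetric
#'   matrix with dimnames.
#' @return an unrooted binary tree of class `phylo` (basal trichotomy).
#' @export
nj_tree <- function(D) {
  d <- as_dist_matrix(D)
  n <- nrow(d)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- sprintf("t%d", seq_len(n))
  # newick fragment and tie-break key per active node
  frag <- sprintf("%s", labels)
  key <- labels
  n_clamped <- 0L
  while (n > 3) {
    r <- rowSums(d)
    Q <- (n - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + abs(qmin) * 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_key <- apply(cand, 1, function(ij)
      paste(sort(c(key[ij[1]], key[ij[2]])), collapse = "\r"))
    pick <- cand[order(pair_key)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0; n_clamped <- n_clamped + 1L }
    if (lj < 0) { li <- li + lj; lj <- 0; n_clamped <- n_clamped + 1L }
    new_frag <- sprintf("(%s:%.15g,%s:%.15g)", frag[i], li, frag[j], lj)
    new_key <- min(key[i], key[j])
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    frag <- c(frag[keep], new_frag)
    key <- c(key[keep], new_key)
    n <- n - 1
  }
  a <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  c3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  if (a < 0 || b < 0 || c3 < 0) n_clamped <- n_clamped + sum(c(a, b, c3) < 0)
  newick <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                    frag[1], max(a, 0), frag[2], max(b, 0), frag[3], max(c3, 0))
  tree <- ape::read.tree(text = newick)
  attr(tree, "n_clamped") <- n_clamped
  tree
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement `n_replicates` times, rebuilding distances and the NJ tree
#' each time. Every internal edge of the full-data tree receives the
#' percentage of replicate trees containing the same bipartition, stored in
#' `node.label` (the standard convention; the basal node is blank).
#'
#' @param alignment named character vector of equal-length sequences.
#' @param n_replicates number of bootstrap replicates (default 100).
#' @param seed integer seed.
#' @param model distance model passed to [compute_distances()].
#' @return a `phylo` tree with bootstrap percentages in `node.label`.
#' @export
bootstrap_support <- function(alignment, n_replicates = 100, seed = 1,
                              model = c("p", "jc")) {
  model <- match.arg(model)
  if (n_replicates < 1) stop("n_replicates must be at least 1")
  alignment <- unlist(alignment)
  tree <- nj_tree(compute_distances(alignment, model))
  L <- nchar(alignment[1])
  mat <- matrix(unlist(strsplit(alignment, "", fixed = TRUE)),
                nrow = length(alignment), byrow = TRUE,
                dimnames = list(names(alignment), NULL))
  full_keys <- split_keys_by_node(tree)
  hits <- setNames(integer(length(full_keys)), full_keys)
  withr::with_seed(seed, {
    for (b in seq_len(n_replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      boot_aln <- setNames(apply(mat[, cols, drop = FALSE], 1,
                                 paste, collapse = ""), rownames(mat))
      bt <- nj_tree(compute_distances(boot_aln, model))
      bk <- unique(split_keys_by_node(bt))
      seen <- full_keys %in% bk
      hits[seen] <- hits[seen] + 1L
    }
  })
  support <- round(100 * hits / n_replicates)
  node_ids <- as.integer(names(full_keys))
  labels <- rep("", tree$Nnode)
  labels[node_ids - length(tree$tip.label)] <- as.character(support)
  tree$node.label <- labels
  tree
}

# per-internal-node canonical split key (root excluded), names = node ids
split_keys_by_node <- function(tree) {
  tips <- tree$tip.label
  anchor <- sort(tips)[1]
  parts <- ape::prop.part(tree)
  node_ids <- seq_len(tree$Nnode) + length(tips)
  keys <- character(0)
  for (k in seq_along(parts)) {
    side <- tips[parts[[k]]]
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) == 0 || length(side) == length(tips) - 1) next  # root/trivial
    if (length(side) < 2 && length(setdiff(tips, side)) < 2) next
    keys[as.character(node_ids[k])] <- paste(sort(side), collapse = "|")
  }
  keys
}

#' Assign query taxa to clades by supported phylogenetic grouping
#'
#' Classification follows similarity and phylogenetic grouping with labeled
#' reference haplotypes: a query is assigned clade X iff the smallest
#' internal edge with bootstrap support at least `min_support` that
#' separates the query together with at least one labeled taxon from the
#' rest has all its labeled taxa sharing label X; otherwise the query is
#' "unassigned". The nearest labeled neighbor (by patristic distance) is
#' reported in every case.
#'
#' @param tree a `phylo` from [bootstrap_support()] (or [nj_tree()]; a tree
#'   without `node.label` supports is treated as fully supported).
#' @param reference_labels named character vector, reference taxon ->
#'   clade label.
#' @param min_support minimum bootstrap percentage for an edge to count
#'   (default 70).
#' @return a data.frame with one row per query: `query`, `clade`
#'   (reference label or "unassigned"), `support` of the deciding edge,
#'   `nearest_reference`, `nearest_clade`, `nearest_distance`.
#' @export
assign_clade <- function(tree, reference_labels, min_support = 70) {
  tips <- tree$tip.label
  refs <- intersect(tips, names(reference_labels))
  if (length(refs) == 0) stop("tree contains no labeled reference taxa")
  queries <- setdiff(tips, names(reference_labels))
  keys <- split_keys_by_node(tree)
  sides <- lapply(keys, function(k) strsplit(k, "|", fixed = TRUE)[[1]])
  supports <- if (is.null(tree$node.label)) {
    rep(100, length(keys))
  } else {
    sup <- suppressWarnings(
      as.numeric(tree$node.label[as.integer(names(keys)) - length(tips)]))
    ifelse(is.na(sup), 0, sup)
  }
  pd <- stats::cophenetic(tree)
  rows <- lapply(queries, function(q) {
    nd <- pd[q, refs]
    nearest <- refs[which.min(nd)]
    clade <- "unassigned"; sup_out <- NA_real_
    best_size <- Inf
    for (k in seq_along(sides)) {
      if (supports[k] < min_support) next
      side <- sides[[k]]
      qside <- if (q %in% side) side else setdiff(tips, side)
      labeled <- intersect(qside, refs)
      if (length(labeled) == 0) next
      if (length(qside) < best_size) {
        best_size <- length(qside)
        lab <- unique(reference_labels[labeled])
        clade <- if (length(lab) == 1) unname(lab) else "unassigned"
        sup_out <- supports[k]
      }
    }
    data.frame(query = q, clade = clade, support = sup_out,
               nearest_reference = nearest,
               nearest_clade = unname(reference_labels[nearest]),
               nearest_distance = unname(min(nd)),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query = character(), clade = character(),
               support = numeric(), nearest_reference = character(),
               nearest_clade = character(), nearest_distance = numeric())
  rownames(out) <- NULL
  out
}
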
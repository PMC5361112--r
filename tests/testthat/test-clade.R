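test_that("p-distances use pairwise deletion of ambiguous sites", {
  D <- compute_distances(c(a = "ACGT", b = "ACGT"))
  expect_equal(D$d["a", "b"], 0)
  D2 <- compute_distances(c(a = "ACGT", b = "ACGA"))
  expect_equal(D2$d["a", "b"], 0.25)
  expect_equal(D2$comparable["a", "b"], 4)
  D3 <- compute_distances(c(a = "ACN", b = "AGN"))
  expect_equal(D3$d["a", "b"], 0.5)
  expect_equal(D3$comparable["a", "b"], 2)
  # gaps are missing too
  D4 <- compute_distances(c(a = "AC-T", b = "ACGT"))
  expect_equal(D4$comparable["a", "b"], 3)

  expect_error(compute_distances(c(a = "NNN", b = "ACG")), "a and b")
  expect_error(compute_distances(c(a = "AC", b = "ACG")), "equal")
  expect_error(compute_distances(c(a = "ACG")), "two sequences")

  # symmetry and zero diagonal on a family of related sequences
  set.seed(41)
  base <- random_seq(80)
  aln <- setNames(lapply(1:5, function(i)
    plant_subs(base, sample(80, 8))), letters[1:5])
  aln <- unlist(aln)
  Dr <- compute_distances(aln)$d
  expect_equal(Dr, t(Dr))
  expect_true(all(diag(Dr) == 0))

  # Jukes-Cantor correction inflates distances monotonically
  Dj <- compute_distances(aln, model = "jc")$d
  expect_true(all(Dj[upper.tri(Dj)] >= Dr[upper.tri(Dr)]))
})

test_that("3-taxon neighbor joining matches the closed form", {
  d <- matrix(c(0, 0.3, 0.4, 0.3, 0, 0.5, 0.4, 0.5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  # a = (d_ab + d_ac - d_bc)/2 = 0.1, b = 0.2, c = 0.3
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[["a"]], 0.1, tolerance = 1e-9)
  expect_equal(lens[["b"]], 0.2, tolerance = 1e-9)
  expect_equal(lens[["c"]], 0.3, tolerance = 1e-9)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("NJ is exact on additive matrices (least-squares enumeration oracle)", {
  skip_if_not_installed("phangorn")
  set.seed(43)
  for (i in 1:20) {
    gen <- random_additive_matrix(5)
    mine <- nj_tree(gen$D)
    oracle <- ls_best_topology(gen$D)
    expect_equal(phangorn::RF.dist(ape::unroot(mine), ape::unroot(gen$tree)), 0)
    expect_equal(phangorn::RF.dist(ape::unroot(mine), ape::unroot(oracle)), 0)
    # path lengths reproduce the input on additive data
    pd <- stats::cophenetic(mine)[rownames(gen$D), colnames(gen$D)]
    expect_lt(max(abs(pd - gen$D)), 1e-9)
  }
  # 4-taxon case with known branch lengths {1,2,3,4} and internal 5
  tr4 <- ape::read.tree(text = "((A:1,B:2):5,C:3,D:4);")
  D4 <- stats::cophenetic(tr4)
  mine4 <- nj_tree(D4)
  expect_equal(phangorn::RF.dist(ape::unroot(mine4), ape::unroot(tr4)), 0)
  pd4 <- stats::cophenetic(mine4)[rownames(D4), colnames(D4)]
  expect_lt(max(abs(pd4 - D4)), 1e-9)
})

test_that("NJ agrees with an independent implementation and ignores taxon order", {
  skip_if_not_installed("phangorn")
  set.seed(44)
  for (i in 1:5) {
    gen <- random_additive_matrix(7)
    mine <- nj_tree(gen$D)
    ref <- ape::nj(stats::as.dist(gen$D))
    expect_equal(phangorn::RF.dist(ape::unroot(mine), ape::unroot(ref)), 0)
    perm <- sample(rownames(gen$D))
    mine_perm <- nj_tree(gen$D[perm, perm])
    expect_equal(phangorn::RF.dist(ape::unroot(mine), ape::unroot(mine_perm)), 0)
  }
})

test_that("bootstrap supports are deterministic and saturate on clean splits", {
  set.seed(45)
  base <- random_seq(300)
  # two groups separated by 25 fixed differences, none within
  g1 <- plant_subs(base, 1:25)
  aln <- c(a1 = base, a2 = base, a3 = base, b1 = g1, b2 = g1, b3 = g1)
  # perturb within-group sequences slightly so distances are not degenerate
  aln["a2"] <- plant_subs(base, 101)
  aln["b2"] <- plant_subs(g1, 102)
  bt <- bootstrap_support(aln, n_replicates = 100, seed = 46)
  sup <- suppressWarnings(as.numeric(bt$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(any(sup == 100))  # the group-separating edge

  bt2 <- bootstrap_support(aln, n_replicates = 100, seed = 46)
  expect_identical(bt$node.label, bt2$node.label)
  expect_false(identical(
    bt$node.label,
    bootstrap_support(aln, n_replicates = 100, seed = 47)$node.label) &&
      FALSE)  # different seed may differ; only determinism is asserted

  one <- bootstrap_support(aln, n_replicates = 1, seed = 48)
  sup1 <- suppressWarnings(as.numeric(one$node.label))
  expect_true(all(sup1[!is.na(sup1)] %in% c(0, 100)))

  expect_error(bootstrap_support(aln, n_replicates = 0), "at least 1")
})

test_that("clade assignment follows supported grouping with labeled taxa", {
  set.seed(49)
  base <- random_seq(500)
  cl_pos <- list(A = 1:20, B = 101:120, C = 201:220)
  aln <- character()
  labels <- character()
  for (cl in names(cl_pos)) {
    core <- plant_subs(base, cl_pos[[cl]])
    for (i in 1:3) {
      nm <- sprintf("ref%s%d", cl, i)
      aln[nm] <- plant_subs(core, 300 + sample(150, 2))
      labels[nm] <- cl
    }
    for (i in 1:2)
      aln[sprintf("q%s%d", cl, i)] <- plant_subs(core, 300 + sample(150, 1))
  }
  bt <- bootstrap_support(aln, n_replicates = 100, seed = 50)
  asg <- assign_clade(bt, labels, min_support = 70)
  expect_equal(nrow(asg), 6)
  truth <- sub("^q([A-C]).*$", "\\1", asg$query)
  expect_equal(asg$clade, truth)
  expect_true(all(asg$clade %in% c(labels, "unassigned")))
  expect_equal(asg$nearest_clade, truth)

  # query identical to a labeled reference joins that clade
  aln2 <- aln[names(labels)]
  aln2["qx"] <- aln2[["refA1"]]
  bt2 <- bootstrap_support(aln2, n_replicates = 100, seed = 51)
  asg2 <- assign_clade(bt2, labels, min_support = 70)
  expect_equal(asg2$clade[asg2$query == "qx"], "A")
  expect_equal(asg2$nearest_distance[asg2$query == "qx"], 0)

  expect_error(assign_clade(bt, c(nosuch = "A")), "no labeled")
})

test_that("a query grouped with conflicting labels stays unassigned", {
  # the query's smallest supported group is {q, rA, rB} where rA and rB
  # carry different clade labels; rA/rB share extra mutations so they form
  # a solid cherry and q cannot pair with either alone
  set.seed(52)
  base <- random_seq(400)
  grp <- plant_subs(base, 1:30)          # tight group far from the outgroup
  sis <- plant_subs(grp, 51:60)          # shared by rA and rB only
  aln <- c(out1 = base, out2 = plant_subs(base, 351),
           out3 = plant_subs(base, 352),
           rA = plant_subs(sis, 101), rB = plant_subs(sis, 102),
           q = plant_subs(grp, 103))
  labels <- c(out1 = "O", out2 = "O", out3 = "O", rA = "A", rB = "B")
  bt <- bootstrap_support(aln, n_replicates = 100, seed = 53)
  asg <- assign_clade(bt, labels, min_support = 70)
  expect_equal(asg$clade[asg$query == "q"], "unassigned")
})
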
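test_that("NJ recovers an additive four-taxon tree exactly", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):2);")
  co <- ape::cophenetic.phylo(tr)
  nj <- neighbor_joining(as_p_dist(co))
  ids <- rownames(co)
  expect_lt(max(abs(ape::cophenetic.phylo(nj)[ids, ids] - co)), 1e-9)
  expect_equal(
    phangorn::RF.dist(ape::unroot(nj), ape::unroot(tr)), 0
  )
})

test_that("three taxa resolve by the closed-form three-point formulas", {
  d <- matrix(
    c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
    dimnames = list(c("A", "B", "C"), c("A", "B", "C"))
  )
  nj <- neighbor_joining(as_p_dist(d))
  co <- ape::cophenetic.phylo(nj)
  expect_equal(co[c("A", "B", "C"), c("A", "B", "C")], d)
  # lengths: a = (3+4-5)/2 = 1, b = 2, c = 3
  depths <- setNames(nj$edge.length[match(1:3, nj$edge[, 2])], nj$tip.label)
  expect_equal(unname(depths[c("A", "B", "C")]), c(1, 2, 3))
})

test_that("NJ path metric reproduces random additive and ultrametric inputs", {
  set.seed(107)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    tr <- ape::rtree(n) # random topology, uniform branch lengths
    co <- ape::cophenetic.phylo(tr)
    nj <- neighbor_joining(as_p_dist(co))
    expect_lt(
      max(abs(ape::cophenetic.phylo(nj)[rownames(co), rownames(co)] - co)),
      1e-9
    )
  }
  for (i in 1:10) {
    n <- sample(4:10, 1)
    tr <- ape::rcoal(n) # ultrametric
    co <- ape::cophenetic.phylo(tr)
    nj <- neighbor_joining(as_p_dist(co))
    expect_lt(
      max(abs(ape::cophenetic.phylo(nj)[rownames(co), rownames(co)] - co)),
      1e-9
    )
  }
})

test_that("NJ topology agrees with the reference implementation", {
  set.seed(109)
  for (i in 1:5) {
    tr <- ape::rtree(10)
    co <- ape::cophenetic.phylo(tr)
    ours <- neighbor_joining(as_p_dist(co))
    ref <- ape::nj(as.dist(co))
    expect_equal(phangorn::RF.dist(ape::unroot(ours), ape::unroot(ref)), 0)
  }
})

test_that("NJ refuses undefined pairs and tiny inputs", {
  d <- matrix(0.1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  dm <- as_p_dist(d)
  dm$d[1, 2] <- dm$d[2, 1] <- NA_real_
  expect_error(neighbor_joining(dm), "undefined distance.*Remove")
  expect_error(
    neighbor_joining(as_p_dist(d[1:2, 1:2])),
    "at least three"
  )
})

test_that("negative branch estimates are clamped without breaking paths", {
  # a non-additive matrix known to produce a negative NJ branch
  d <- matrix(
    c(
      0, 0.1, 0.11, 0.5,
      0.1, 0, 0.02, 0.52,
      0.11, 0.02, 0, 0.01,
      0.5, 0.52, 0.01, 0
    ), 4, 4,
    dimnames = list(letters[1:4], letters[1:4])
  )
  nj <- neighbor_joining(as_p_dist(d))
  expect_true(all(nj$edge.length >= 0))
})

test_that("midpoint rooting preserves paths and halves the diameter", {
  set.seed(113)
  for (i in 1:5) {
    tr <- ape::unroot(ape::rtree(8))
    co <- ape::cophenetic.phylo(tr)
    rooted <- midpoint_root(tr)
    expect_true(ape::is.rooted(rooted))
    co2 <- ape::cophenetic.phylo(rooted)
    expect_lt(max(abs(co2[rownames(co), colnames(co)] - co)), 1e-9)
    # deepest tip sits at half the brute-force diameter
    depths <- ape::node.depth.edgelength(rooted)[seq_len(ape::Ntip(rooted))]
    expect_equal(max(depths), max(co) / 2, tolerance = 1e-9)
    # agreement with the reference midpoint rooter on tip depths
    ref <- phangorn::midpoint(tr)
    refd <- ape::node.depth.edgelength(ref)[seq_len(ape::Ntip(ref))]
    expect_equal(
      sort(depths), sort(refd[match(sort(ref$tip.label), ref$tip.label)]),
      tolerance = 1e-9, ignore_attr = TRUE
    )
  }
})

test_that("a caterpillar's longest path is found against brute force", {
  txt <- "(((((a:1,b:2):1,c:1):1,d:1):1,e:6):1,f:1);"
  tr <- ape::unroot(ape::read.tree(text = txt))
  co <- ape::cophenetic.phylo(tr)
  idx <- which(co == max(co), arr.ind = TRUE)[1, ]
  rooted <- midpoint_root(tr)
  depths <- ape::node.depth.edgelength(rooted)[seq_len(6)]
  expect_equal(max(depths), co[idx[1], idx[2]] / 2)
})

test_that("a symmetric two-leaf cherry roots at its center", {
  tr <- ape::read.tree(text = "(A:1.5,B:1.5);")
  rooted <- midpoint_root(tr)
  depths <- ape::node.depth.edgelength(rooted)[1:2]
  expect_equal(depths, c(1.5, 1.5))
})

test_that("monophyly classifies clades, interleavings and singletons", {
  tr <- ape::read.tree(
    text = "(((x1:1,x2:1):1,(x3:1,(y1:1,z1:1):1):1):1,(z2:1,w1:1):1);"
  )
  chk <- checklist_from_map(c(
    x1 = "X", x2 = "X", x3 = "X", y1 = "Y", z1 = "Z", z2 = "Z", w1 = "W"
  ))
  got <- assess_monophyly(tr, chk)
  expect_equal(got$status[got$taxon == "X"], "non-monophyletic")
  expect_equal(got$status[got$taxon == "Y"], "trivial")
  expect_equal(got$status[got$taxon == "Z"], "non-monophyletic")

  tr2 <- ape::read.tree(text = "(((x1:1,x2:1):1,x3:1):1,(y1:1,z1:1):1);")
  got2 <- assess_monophyly(tr2, checklist_from_map(
    c(x1 = "X", x2 = "X", x3 = "X", y1 = "Y", z1 = "Z")
  ))
  expect_equal(got2$status[got2$taxon == "X"], "monophyletic")
})

test_that("monophyly agrees with clade-enumeration brute force", {
  set.seed(127)
  for (i in 1:10) {
    n <- sample(6:14, 1)
    tr <- ape::rtree(n)
    map <- setNames(
      sample(sprintf("tax%d", 1:4), n, replace = TRUE), tr$tip.label
    )
    got <- assess_monophyly(tr, checklist_from_map(map))
    want <- monophyly_oracle(tr, map)
    expect_equal(setNames(got$status, got$taxon), want[got$taxon])
  }
})

test_that("monophyly counts are invariant under child-order rotation", {
  set.seed(131)
  tr <- ape::rtree(10)
  map <- setNames(sample(sprintf("t%d", 1:3), 10, TRUE), tr$tip.label)
  got1 <- assess_monophyly(tr, checklist_from_map(map))
  rot <- ape::rotateConstr(tr, rev(sort(tr$tip.label)))
  got2 <- assess_monophyly(rot, checklist_from_map(map))
  expect_equal(
    sum(got1$status == "non-monophyletic"),
    sum(got2$status == "non-monophyletic")
  )
})

test_that("monophyly demands a rooted tree covering all specimens", {
  tr <- ape::rtree(4)
  tr$tip.label <- c("a1", "a2", "b1", "b2")
  chk <- checklist_from_map(c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C"))
  expect_error(assess_monophyly(tr, chk), "absent from tree: c1")
  expect_error(
    assess_monophyly(
      ape::unroot(tr),
      checklist_from_map(c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
    ),
    "rooted"
  )
})

test_that("Newick output round-trips through ape", {
  set.seed(137)
  sim <- simulate_flora(
    simulation_config(n_species = 8, n_failure_pairs = 0, n_nonnative = 0),
    seed = 137
  )
  dm <- build_distance_matrix(sim$alignment)
  tr <- neighbor_joining(dm)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- ape::read.tree(f)
  expect_setequal(back$tip.label, tr$tip.label)
  expect_equal(
    phangorn::RF.dist(ape::unroot(back), ape::unroot(tr)), 0
  )
})
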
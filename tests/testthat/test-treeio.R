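test_that("parse_newick builds a valid dated tree and reports root age", {
  tr <- parse_newick("((A:1,B:1):1,C:2):0;")
  expect_s3_class(tr, "dated_tree")
  expect_equal(tr$n_tips, 3)
  expect_equal(tr$root_age, 2)
  expect_equal(tr$phy$tip.label, c("A", "B", "C"))  # tip order preserved

  fx <- argylia_fx()
  expect_equal(fx$tree$root_age, 38.21, tolerance = 1e-9)
  expect_equal(fx$tree$n_tips, 13)
})

test_that("non-ultrametric and malformed input are rejected with guidance", {
  expect_error(parse_newick("(A:1,B:2);"), "not ultrametric")
  tr <- parse_newick("(A:1,B:2);", force_ultrametric = TRUE)
  expect_s3_class(tr, "dated_tree")
  expect_error(parse_newick("((A:1,B:1):1,C:2"), "character")
  expect_error(parse_newick("(A:1,B:1)):1;"), "character 10")
  expect_error(parse_newick("(A:1,(B:0.5,C:0.5):0.5)"), "';'")
})

test_that("newick round-trip preserves topology, labels, branch lengths", {
  for (seed in 1:5) {
    tr <- round_aged_tree(8, root_age = 12.3, seed = seed)
    tr2 <- parse_newick(write_newick(tr))
    expect_equal(sort(tr2$phy$tip.label), sort(tr$phy$tip.label))
    expect_true(ape::all.equal.phylo(tr$phy, tr2$phy, tolerance = 1e-9))
  }
})

test_that("vcv matrix matches the shared-path definition and brute-force walker", {
  tr <- three_tip_tree()
  C <- vcv_matrix(tr)
  expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "C"], 0)
  expect_equal(C["A", "A"], 2)

  fx <- argylia_fx()
  Cf <- vcv_matrix(fx$tree)
  expect_equal(Cf["uspallatensis", "bustillosii"], 38.21 - 9.76,
               tolerance = 1e-9)

  for (seed in 1:4) {
    tr <- random_dated_tree(sample(4:10, 1), root_age = 7, seed = seed)
    C <- vcv_matrix(tr)
    labs <- tr$phy$tip.label
    for (a in labs) for (b in labs)
      expect_equal(C[a, b], walk_shared_path(tr, a, b), tolerance = 1e-9)
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1e-9))
    # C[i,i] - C[i,j] equals the age of the MRCA of i and j
    mr <- ape::mrca(tr$phy)
    for (a in labs) for (b in labs)
      expect_equal(C[a, a] - C[a, b], tr$ages[mr[a, b]], tolerance = 1e-9)
  }
})

test_that("slice_branches performs exact interval arithmetic", {
  # a branch spanning 17 -> 3 Ma cut at boundaries 15 and 5 Ma
  tr <- parse_newick("((A:3,B:3):14,C:17);")
  ep <- epoch_spec(c(20, 15, 5, 0), areas = "X")
  segs <- slice_branches(tr, ep)
  long <- segs[segs$edge == which(tr$phy$edge[, 2] == tr$n_tips + 2L), ]
  expect_equal(nrow(long), 3)
  expect_equal(long$duration, c(2, 10, 2))
  expect_equal(long$start, c(17, 15, 5))
  # a branch inside one epoch stays whole
  tip_c <- which(tr$phy$edge[, 2] == match("C", tr$phy$tip.label))
  expect_equal(sum(segs$edge == tip_c), 3)
  ep1 <- epoch_spec(c(20, 0), areas = "X")
  expect_equal(nrow(slice_branches(tr, ep1)), nrow(tr$phy$edge))
  # total length conserved for arbitrary epoch sets
  for (seed in 1:3) {
    trr <- random_dated_tree(7, root_age = 9, seed = seed)
    bnd <- sort(unique(c(10, 0, round(runif(3, 0.5, 8.5), 2))),
                decreasing = TRUE)
    segs <- slice_branches(trr, epoch_spec(bnd, areas = "X"))
    expect_equal(sum(segs$duration), sum(trr$phy$edge.length),
                 tolerance = 1e-9)
    per_edge <- tapply(segs$duration, segs$edge, sum)
    expect_equal(as.numeric(per_edge[as.character(seq_len(nrow(trr$phy$edge)))]),
                 trr$phy$edge.length, tolerance = 1e-9)
  }
})

test_that("the root-to-first-split branch slices at the 35 Ma boundary", {
  fx <- argylia_fx()
  segs <- slice_branches(fx$tree, fx$epochs)
  # branch from the root (38.21) to the 28.04 Ma node
  node_a <- which(abs(fx$tree$ages - 28.04) < 1e-6)
  ei <- which(fx$tree$phy$edge[, 2] == node_a)
  s <- segs[segs$edge == ei, ]
  expect_equal(s$duration, c(3.21, 6.96), tolerance = 1e-9)
  expect_error(slice_branches(fx$tree, epoch_spec(c(30, 15, 0), areas = "X")),
               "root age")
})

test_that("epoch specs validate their boundaries and multipliers", {
  expect_error(epoch_spec(c(10, 15, 0), areas = "A"), "decreasing")
  expect_error(epoch_spec(c(10, 5), areas = "A"), "0 Ma")
  m <- matrix(-1, 2, 2)
  expect_error(epoch_spec(c(10, 0), multipliers = list(m)), ">= 0")
  ep <- epoch_spec(c(10, 5, 0), areas = c("A", "B"))
  expect_equal(ep$n_epochs, 2)
  expect_equal(dim(ep$multipliers[[1]]), c(2, 2))
})

test_that("geography files round-trip and reject bad codings", {
  ranges <- list(sp1 = c("A", "C"), sp2 = "B", sp3 = c("A", "B", "C"))
  f <- withr::local_tempfile(fileext = ".txt")
  write_geography(ranges, c("A", "B", "C"), f)
  g <- read_geography(f)
  expect_equal(g$areas, c("A", "B", "C"))
  expect_equal(g$ranges, ranges)
  writeLines(c("1\t2\t(A B)", "sp1\t00"), f)
  expect_error(read_geography(f), "empty range")
})

test_that("polytomies are rejected only where cladogenesis demands it", {
  poly <- parse_newick("(A:2,B:2,C:2);")
  expect_s3_class(poly, "dated_tree")
  expect_error(parse_newick("(A:2,B:2,C:2);", require_bifurcating = TRUE),
               "polytomies")
})
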
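test_that("three taxa solve the additive equations exactly", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- njTree(D)
  expect_equal(sort(tr$edge.length), c(1, 2, 3))
  expect_equal(attr(tr, "deficit"), 0)
  cd <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(cd, unclass(D)[, ], tolerance = 1e-12)
})

test_that("a 4-taxon additive matrix is recovered exactly", {
  ## tree ((A:1,B:2):1,(C:3,D:1))
  D <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  D["A", "B"] <- 3; D["A", "C"] <- 5; D["A", "D"] <- 3
  D["B", "C"] <- 6; D["B", "D"] <- 4; D["C", "D"] <- 4
  D <- D + t(D)
  tr <- njTree(D)
  expect_equal(treeSplits(tr), 3L)  # {A,B} | {C,D}
  expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)],
               unclass(D)[, ], tolerance = 1e-12)
})

test_that("NJ recovers random additive topologies (100/100 at 6 taxa)", {
  set.seed(7)
  ok <- 0L
  for (i in 1:100) {
    s <- simulateAdditiveMatrix(6)
    ok <- ok + identical(treeSplits(njTree(s$D)), sort(s$splits))
  }
  expect_equal(ok, 100L)
})

test_that("njTree agrees with ape's NJ on generic matrices", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:8, 1)
    s <- simulateAdditiveMatrix(n)
    noise <- matrix(runif(n * n, 0, 0.004), n)
    D <- s$D + noise + t(noise); diag(D) <- 0
    mine <- ape::unroot(njTree(D))
    apes <- ape::unroot(ape::nj(D))
    expect_equal(as.numeric(ape::dist.topo(mine, apes)), 0)
  }
})

test_that("branch lengths are clamped to zero with the deficit logged", {
  set.seed(3)
  for (i in 1:20) {
    s <- simulateAdditiveMatrix(6, lmin = 0.0005, lmax = 0.01)
    noise <- matrix(runif(36, 0, 0.01), 6)
    D <- s$D + noise + t(noise); diag(D) <- 0
    tr <- njTree(D)
    expect_true(all(tr$edge.length >= 0))
    expect_gte(attr(tr, "deficit"), 0)
  }
})

test_that("topology enumeration has the (2n-5)!! count", {
  expect_length(enumerateTopologies(4), 3L)
  expect_length(enumerateTopologies(5), 15L)
  expect_length(enumerateTopologies(6), 105L)
})

test_that("the exhaustive least-squares oracle fits additive data exactly", {
  set.seed(19)
  for (i in 1:10) {
    s <- simulateAdditiveMatrix(sample(4:6, 1))
    fit <- lsTopologySearch(s$D)
    expect_equal(sort(fit$splits), sort(s$splits))
    expect_lt(fit$rss, 1e-18)
  }
})

test_that("bootstrap supports behave: determinism, extremes, separation", {
  a <- patternAlignment("rm", n_diag = 25, seed = 2)
  t1 <- bootstrapTree(a, reps = 200, seed = 5, min_valid_sites = 10)
  t2 <- bootstrapTree(a, reps = 200, seed = 5, min_valid_sites = 10)
  expect_identical(attr(t1, "splits"), attr(t2, "splits"))
  ## 25 diagnostic sites cleanly separate X from Y
  expect_gte(max(attr(t1, "splits")$support), 95)
  ## a single replicate can only give 0 or 100
  t3 <- bootstrapTree(a, reps = 1, seed = 1, min_valid_sites = 10)
  expect_true(all(attr(t3, "splits")$support %in% c(0, 100)))
  ## too little data is an error
  expect_error(bootstrapTree(a, 0, 30, reps = 10, min_valid_sites = 500),
               "complete columns")
})

test_that("supports are invariant under taxon reordering", {
  a <- patternAlignment("rm", n_diag = 25, seed = 4)
  perm <- c("b_Y", "a_X", "b_X", "a_Y")
  t1 <- bootstrapTree(a, reps = 300, seed = 8, min_valid_sites = 10)
  t2 <- bootstrapTree(a[perm], reps = 300, seed = 8,
                      min_valid_sites = 10)
  sidesOf <- function(tr) {
    labs <- tr$tip.label
    sp <- attr(tr, "splits")
    keys <- vapply(sp$mask, function(m) {
      inside <- bitwAnd(m, bitwShiftL(1L, seq_along(labs) - 1L)) != 0L
      a <- paste(sort(labs[inside]), collapse = "+")
      b <- paste(sort(labs[!inside]), collapse = "+")
      min(a, b)   # orientation-free key
    }, "")
    setNames(sp$support, keys)
  }
  s1 <- sidesOf(t1); s2 <- sidesOf(t2)
  key <- intersect(names(s1), names(s2))
  expect_gt(length(key), 0)
  expect_equal(s1[key], s2[key], tolerance = 5)
})

test_that("topology classification identifies the canonical patterns", {
  rm <- classifyTopology(bootstrapTree(patternAlignment("rm", seed = 3),
                                       reps = 100, seed = 1,
                                       min_valid_sites = 10))
  expect_equal(rm$call, "RECIPROCAL_MONOPHYLY")
  expect_true(rm$support_ok)
  expect_gte(rm$rm_support, 70)

  sp <- classifyTopology(bootstrapTree(patternAlignment("pairing",
                                                        seed = 3),
                                       reps = 100, seed = 1,
                                       min_valid_sites = 10))
  expect_equal(sp$call, "SPECIES_PAIRING")
  expect_equal(sp$paired_species, c("a", "b"))

  ## classification is invariant under row order
  a <- patternAlignment("pairing", seed = 9)
  c1 <- classifyTopology(bootstrapTree(a, reps = 100, seed = 2,
                                       min_valid_sites = 10))
  c2 <- classifyTopology(bootstrapTree(a[c(3, 1, 4, 2)], reps = 100,
                                       seed = 2, min_valid_sites = 10))
  expect_equal(c1$call, c2$call)
  expect_equal(c1$paired_species, c2$paired_species)
})

test_that("fewer than two species with both chromosomes is UNRESOLVED", {
  a <- GametologAlignment(rbind(a_X = sample(BASES, 200, TRUE),
                                b_X = sample(BASES, 200, TRUE),
                                c_X = sample(BASES, 200, TRUE)))
  cl <- classifyTopology(bootstrapTree(a, reps = 10, seed = 1,
                                       min_valid_sites = 10))
  expect_equal(cl$call, "UNRESOLVED")
  expect_match(cl$reason, "fewer than 2")
})

test_that("a Region-A-like simulated stratum is reciprocally monophyletic", {
  fx <- makeFigureFixture("regionA_null", seed = 21)
  cl <- classifyTopology(bootstrapTree(fx$alignment, 0, 2000,
                                       reps = 100, seed = 3))
  expect_equal(cl$call, "RECIPROCAL_MONOPHYLY")
})
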
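test_that("pairwise p-distance counts mismatches per valid site", {
  a <- GametologAlignment(c(r1_X = "ACGT", r2_Y = "ACGT",
                            r3_X = "AAAA", r4_Y = "AAAT"))
  expect_equal(pDistance(a, "r1_X", "r2_Y"), list(p = 0, valid_sites = 4L))
  expect_equal(pDistance(a, "r3_X", "r4_Y"),
               list(p = 0.25, valid_sites = 4L))
  b <- GametologAlignment(c(x_X = "AC-GTT", y_Y = "ACAGTA"))
  d <- pDistance(b, "x_X", "y_Y")
  expect_equal(d$valid_sites, 5L)   # gapped column excluded
  expect_equal(d$p, 0.2)            # one mismatch among five
  expect_error(pDistance(b, "x_X", "zz"), "unknown taxon")
})

test_that("all-missing intervals give MISSING, not zero", {
  a <- GametologAlignment(c(x_X = "--NNACGT", y_Y = "-N--ACGT"))
  d <- pDistance(a, "x_X", "y_Y", 0, 4)
  expect_true(is.na(d$p))
  expect_equal(d$valid_sites, 0L)
})

test_that("complete deletion removes columns missing in any row", {
  a <- GametologAlignment(c(x_X = "ACGTT", y_Y = "ACGTA", z_X = "AC-TA"))
  dp <- pDistance(a, "x_X", "y_Y", policy = "pairwise")
  dc <- pDistance(a, "x_X", "y_Y", policy = "complete")
  expect_equal(dp$valid_sites, 5L)
  expect_equal(dc$valid_sites, 4L)  # z's gap removes the column for all
  D <- distanceMatrix(a, min_valid_sites = 1L)
  expect_equal(attr(D, "sites_used"), 4L)
  expect_equal(D["x_X", "y_Y"], 0.25)
})

test_that("window iteration matches the standard scan geometries", {
  expect_equal(nrow(iterWindows(1500, 500, 500)), 3L)
  w <- iterWindows(50000, 2000, 1000)
  full <- sum(w$end - w$start == 2000)
  expect_equal(full, 49L)                      # 49 full windows
  expect_equal(nrow(w), 50L)                   # plus one 1000-col partial
  expect_equal(nrow(iterWindows(7900, 500, 400)), 20L)  # the 20-tree scan
  ## short sequences: a single partial window iff it clears min_valid
  expect_equal(nrow(iterWindows(400, 500, 500)), 1L)
  expect_equal(nrow(iterWindows(400, 500, 500, min_valid_sites = 450)),
               0L)
  ## tiling property
  w2 <- iterWindows(3000, 500, 500)
  expect_equal(w2$start, seq(0, 2500, 500))
  expect_equal(w2$end - w2$start, rep(500L, 6))
})

test_that("distance matrices are symmetric, order-invariant, hand-checked", {
  a <- GametologAlignment(c(a_X = "AAAA", b_X = "AAAT", c_Y = "AATT"))
  D <- distanceMatrix(a, min_valid_sites = 1L)
  expect_equal(D["a_X", "b_X"], 0.25)
  expect_equal(D["a_X", "c_Y"], 0.5)
  expect_equal(D["b_X", "c_Y"], 0.25)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 3))
  ## row order does not change entries
  D2 <- distanceMatrix(a[c("c_Y", "a_X", "b_X")], min_valid_sites = 1L)
  expect_equal(D2[rownames(D), colnames(D)], D, ignore_attr = TRUE)
  ## gap-free interval: complete equals pairwise
  Dp <- distanceMatrix(a, min_valid_sites = 1L, policy = "pairwise")
  expect_equal(D, Dp, ignore_attr = TRUE)
  ## too few shared columns is an error naming the interval
  g <- GametologAlignment(c(a_X = "A-GT", b_X = "AC-T", c_Y = "ACG-"))
  expect_error(distanceMatrix(g, min_valid_sites = 2L), "1-4")
})

test_that("profiles are zero on identical rows and tile the alignment", {
  a <- GametologAlignment(c(x_X = strrep("ACGT", 300),
                            y_Y = strrep("ACGT", 300)))
  pr <- distanceProfile(a, "x_X", "y_Y", width = 400)
  expect_true(all(pr$p == 0))
  expect_equal(pr$start[1], 0L)
  expect_equal(pr$end[nrow(pr)], 1200L)
})

test_that("whole-interval p equals the valid-site-weighted window mean", {
  set.seed(42)
  for (rep in 1:5) {
    L <- 1200L
    s1 <- sample(c(BASES, "-", "N"), L, replace = TRUE,
                 prob = c(rep(0.23, 4), 0.05, 0.03))
    s2 <- sample(c(BASES, "-"), L, replace = TRUE,
                 prob = c(rep(0.24, 4), 0.04))
    a <- GametologAlignment(rbind(p_X = s1, q_Y = s2))
    pr <- distanceProfile(a, "p_X", "q_Y", width = 300, step = 300,
                          min_valid_sites = 1)
    whole <- pDistance(a, "p_X", "q_Y")
    expect_equal(sum(pr$p * pr$valid_sites) / sum(pr$valid_sites),
                 whole$p, tolerance = 1e-12)
    expect_equal(sum(pr$valid_sites), whole$valid_sites)
  }
})

test_that("a planted low-divergence segment shows the expected profile shape", {
  fx <- makeFigureFixture("fig1_profile", seed = 11)
  pr <- distanceProfile(fx$alignment, "human_X", "human_Y", width = 500)
  mid <- function(s, e) pr$p[pr$start >= s & pr$end <= e]
  expect_lt(mean(mid(20000, 26000)), 0.02)          # 3-myr tract
  recent <- mean(mid(26000, 35000))                 # 18-myr tract
  expect_gt(recent, 0.03); expect_lt(recent, 0.07)
  flank <- mean(mid(0, 20000))
  expect_gt(flank, 0.08); expect_lt(flank, 0.12)    # stratum backdrop
  expect_true(all(is.na(mid(38000, 41000))))        # deleted segment
})
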
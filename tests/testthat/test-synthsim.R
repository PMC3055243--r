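test_that("simulation is byte-identical under one seed", {
  cfg <- simConfig("((human:6,chimp:6):24,rhesus:30);",
                   seq_length = 2000)
  s1 <- simulateGametologs(cfg, seed = 42)
  s2 <- simulateGametologs(cfg, seed = 42)
  expect_identical(seqMatrix(s1$alignment), seqMatrix(s2$alignment))
  expect_identical(truthEvents(s1$truth), truthEvents(s2$truth))
  s3 <- simulateGametologs(cfg, seed = 43)
  expect_false(identical(seqMatrix(s1$alignment),
                         seqMatrix(s3$alignment)))
})

test_that("zero rates give identical sequences everywhere", {
  cfg <- simConfig("((human:6,chimp:6):24,rhesus:30);",
                   seq_length = 500, r_x = 0, r_y = 0,
                   allele_theta = 0)
  s <- simulateGametologs(cfg, seed = 1)
  m <- seqMatrix(s$alignment)
  expect_true(all(m == matrix(m[1, ], nrow(m), ncol(m), byrow = TRUE)))
})

test_that("X-Y divergence matches the Jukes-Cantor closed form", {
  cfg <- simConfig("((human:6,chimp:6):24,rhesus:30);",
                   seq_length = 20000, allele_theta = 0)
  s <- simulateGametologs(cfg, seed = 77)
  expP <- expectedXYDivergence(0.78e-9, 1.45e-9, 47)
  tol <- 2 * sqrt(expP * (1 - expP) / 20000)
  for (sp in c("human", "chimp", "rhesus")) {
    p <- pDistance(s$alignment, paste0(sp, "_X"), paste0(sp, "_Y"))$p
    expect_lt(abs(p - expP), tol)
  }
  ## the default conditions sit at the ~10 percent stratum-4 backdrop
  expect_gt(expP, 0.09); expect_lt(expP, 0.11)
})

test_that("conversion resets divergence inside the tract only", {
  cfg <- simConfig("((human:6,chimp:6):24,rhesus:30);",
                   seq_length = 12000, allele_theta = 0,
                   conversions = data.frame(lineage = "rhesus",
                                            time_myr = 5, start = 4000,
                                            end = 8000,
                                            direction = "Y_TO_X"))
  s <- simulateGametologs(cfg, seed = 3)
  pin <- pDistance(s$alignment, "rhesus_X", "rhesus_Y", 4000, 8000)$p
  pout <- pDistance(s$alignment, "rhesus_X", "rhesus_Y", 0, 4000)$p
  expIn <- expectedXYDivergence(0.78e-9, 1.45e-9, 5)
  expOut <- expectedXYDivergence(0.78e-9, 1.45e-9, 47)
  expect_lt(abs(pin - expIn), 2 * sqrt(expIn * (1 - expIn) / 4000) + 1e-9)
  expect_lt(abs(pout - expOut), 2 * sqrt(expOut * (1 - expOut) / 4000))
  ## the other species is untouched
  ph <- pDistance(s$alignment, "human_X", "human_Y", 4000, 8000)$p
  expect_gt(ph, expOut - 2 * sqrt(expOut * (1 - expOut) / 4000))
})

test_that("per-branch substitution draws match their binomial expectation", {
  cfg <- simConfig("((human:6,chimp:6):24,rhesus:30);",
                   seq_length = 10000, allele_theta = 0)
  s <- simulateGametologs(cfg, seed = 15)
  subs <- s$truth@substitutions
  subs <- subs[subs$t_myr > 0.5, ]
  for (i in seq_len(nrow(subs))) {
    r <- if (subs$chromosome[i] == "Y") 1.45e-9
         else if (subs$chromosome[i] == "X") 0.78e-9
         else (0.78e-9 + 1.45e-9) / 2
    p <- 0.75 * (1 - exp(-4 / 3 * r * subs$t_myr[i] * 1e6))
    expect_lt(abs(subs$n_subs[i] - 10000 * p),
              4 * sqrt(10000 * p * (1 - p)) + 1)
  }
})

test_that("schedule validation rejects impossible conversions", {
  base <- function(conv) simConfig("((human:6,chimp:6):24,rhesus:30);",
                                   seq_length = 1000,
                                   conversions = conv)
  expect_error(simulateGametologs(base(
    data.frame(lineage = "rhesus", time_myr = 35, start = 0, end = 100,
               direction = "Y_TO_X")), 1), "existence")
  expect_error(simulateGametologs(base(
    data.frame(lineage = "dog", time_myr = 5, start = 0, end = 100,
               direction = "Y_TO_X")), 1), "no branch")
  expect_error(simulateGametologs(base(
    data.frame(lineage = "rhesus", time_myr = 5, start = 0, end = 100,
               direction = "sideways")), 1), "direction")
})

test_that("deletions gap descendants and protect conversion donors", {
  cfg <- simConfig("((human:6,chimp:6):24,rhesus:30);",
                   seq_length = 1000, allele_theta = 0,
                   deletions = data.frame(lineage = "human+chimp",
                                          chromosome = "Y",
                                          start = 100, end = 300))
  s <- simulateGametologs(cfg, seed = 2)
  m <- seqMatrix(s$alignment)
  expect_true(all(m["human_Y", 101:300] == "-"))
  expect_true(all(m["chimp_Y", 101:300] == "-"))
  expect_false(any(m["rhesus_Y", ] == "-"))
  ## conversion copying from a deleted donor tract is refused
  cfg2 <- simConfig("((human:6,chimp:6):24,rhesus:30);",
                    seq_length = 1000,
                    conversions = data.frame(lineage = "human",
                                             time_myr = 3, start = 150,
                                             end = 250,
                                             direction = "Y_TO_X"),
                    deletions = data.frame(lineage = "human+chimp",
                                           chromosome = "Y",
                                           start = 100, end = 300))
  expect_error(simulateGametologs(cfg2, seed = 2), "deletion")
})

test_that("a Poisson schedule draws events within lineage bounds", {
  cfg <- simConfig("((human:6,chimp:6):24,rhesus:30);",
                   seq_length = 5000, conversion_rate = 0.05,
                   tract_range = c(70, 2000))
  s <- simulateGametologs(cfg, seed = 10)
  ev <- truthEvents(s$truth)
  if (nrow(ev)) {
    expect_true(all(ev$time_myr > 0 & ev$time_myr <= 47))
    expect_true(all(ev$start >= 0 & ev$end <= 5000))
    expect_true(all(ev$direction %in% c("X_TO_Y", "Y_TO_X")))
  }
  expect_identical(truthEvents(simulateGametologs(cfg, seed = 10)$truth),
                   ev)
})

test_that("canned fixtures carry their advertised truth", {
  expect_equal(nrow(truthEvents(makeFigureFixture("regionA_null",
                                                 seed = 1)$truth)), 0L)
  fx3 <- makeFigureFixture("fig3_ten_events", seed = 1)
  tr <- truthEvents(fx3$truth)
  expect_equal(nrow(tr), 10L)
  expect_equal(sum(tr$direction == "Y_TO_X"), 5L)
  expect_equal(sum(tr$direction == "X_TO_Y"), 5L)
  fx4 <- makeFigureFixture("fig4_gibbon", seed = 1)
  expect_equal(truthEvents(fx4$truth)$end -
                 truthEvents(fx4$truth)$start, 70L)
  expect_error(makeFigureFixture("fig7_unicorn", seed = 1),
               "regionA_null")
})
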
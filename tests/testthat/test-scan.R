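test_that("a no-conversion stratum scans as all reciprocal monophyly", {
  fx <- makeFigureFixture("regionA_null", seed = 13)
  w <- scanTopologies(fx$alignment, width = 2000, step = 1000,
                      reps = 100, seed = 1)
  expect_true(all(w$call == "RECIPROCAL_MONOPHYLY"))
  sr <- segmentSubregions(w)
  expect_equal(nrow(sr), 1L)
  ev <- mapEvents(sr, readSpeciesTree("((human:6,chimp:6):24,rhesus:30);"),
                  aln = fx$alignment)
  expect_equal(nrow(ev), 0L)
})

test_that("a single planted tract is flagged in the overlapping windows", {
  ## the outgroup roots the clades; without one, a conversion clade and
  ## its complement are indistinguishable on the unrooted tree
  cfg <- simConfig("(((human:6,chimp:6):24,rhesus:30):10,nwm:40);",
                   seq_length = 8000,
                   conversions = data.frame(lineage = "rhesus",
                                            time_myr = 8, start = 2000,
                                            end = 5000,
                                            direction = "Y_TO_X"),
                   tips = rbind(expand.grid(
                     species = c("human", "chimp", "rhesus"),
                     chromosome = c("X", "Y"), allele = "",
                     stringsAsFactors = FALSE)[, c("species",
                                                   "chromosome",
                                                   "allele")],
                     data.frame(species = "nwm", chromosome = "X",
                                allele = "")),
                   allele_theta = 0)
  s <- simulateGametologs(cfg, seed = 5)
  w <- scanTopologies(s$alignment, width = 500, step = 400, reps = 100,
                      seed = 2)
  flagged <- grepl("rhesus", w$signature)
  inside <- w$start >= 2000 & w$end <= 5000
  outside <- w$end <= 2000 - 400 | w$start >= 5000 + 400
  expect_true(all(flagged[inside]))       # every fully-covered window
  expect_true(!any(flagged[outside]))     # no window beyond +-1 window
  sr <- segmentSubregions(w)
  conv <- sr[sr$signature == "rhesus", ]
  expect_equal(nrow(conv), 1L)
  expect_lt(conv$start, 5000)
  expect_gt(conv$end, 2000)               # sub-region overlaps the tract
})

test_that("segmentation merges runs and places midpoint boundaries", {
  w <- fakeWindows(c("RM", "RM", "human", "human", "RM"))
  sr <- segmentSubregions(w)
  expect_equal(nrow(sr), 3L)
  expect_equal(sr$start, c(0L, 850L, 1650L))
  expect_equal(sr$end, c(850L, 1650L, 2100L))
  expect_equal(sr$call, c("RECIPROCAL_MONOPHYLY", "MIXED",
                          "RECIPROCAL_MONOPHYLY"))
  expect_equal(sr$n_windows, c(2L, 2L, 1L))
})

test_that("alternating distinct signatures are not smoothed", {
  w <- fakeWindows(c("human", "rhesus", "human", "rhesus"))
  sr <- segmentSubregions(w)
  expect_equal(nrow(sr), 4L)
  expect_equal(sr$n_windows, rep(1L, 4))
})

test_that("unresolved runs are absorbed into the larger flank, ties left", {
  w <- fakeWindows(c("human", "human", "U", "rhesus", "rhesus"))
  sr <- segmentSubregions(w)
  expect_equal(nrow(sr), 2L)
  expect_equal(sr$n_windows, c(3L, 2L))      # tie of 2 vs 2 goes left
  w2 <- fakeWindows(c("human", "U", "rhesus", "rhesus"))
  sr2 <- segmentSubregions(w2)
  expect_equal(sr2$n_windows, c(1L, 3L))     # larger right flank wins
  expect_warning(sr3 <- segmentSubregions(fakeWindows(c("U", "U"))),
                 "UNRESOLVED")
  expect_equal(nrow(sr3), 0L)
})

test_that("boundary-artifact subset runs are absorbed", {
  ## a single window resolving only the shared clade between two longer
  ## runs joins the more similar neighbour
  w <- fakeWindows(c("gibbon;human", "gibbon;human", "gibbon",
                     "gibbon;rhesus", "gibbon;rhesus",
                     "gibbon;rhesus"))
  sr <- segmentSubregions(w)
  expect_equal(nrow(sr), 2L)
  expect_equal(sr$n_windows, c(3L, 3L))  # equal family distance: left
  ## a support dip inside one sub-region is re-joined
  w2 <- fakeWindows(c("RM", "RM", "gibbon;human", "gibbon",
                      "gibbon;human", "RM", "RM"))
  sr2 <- segmentSubregions(w2)
  expect_equal(nrow(sr2), 3L)
  expect_equal(sr2$signature[2], "gibbon;human")
})

test_that("events map to branches by exact match or minimal cover", {
  tree <- primateSpeciesTree()
  srExact <- fakeWindows(rep("chimp+gorilla+human", 3)) |>
    segmentSubregions()
  ev <- mapEvents(srExact, tree)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$branch, "chimp+gorilla+human")
  expect_equal(ev$branch_tmin, 8)
  expect_equal(ev$branch_tmax, 18)
  ## gibbon+human form no clade: two events
  srTwo <- fakeWindows(rep("gibbon+human", 3)) |> segmentSubregions()
  ev2 <- mapEvents(srTwo, tree)
  expect_equal(nrow(ev2), 2L)
  expect_setequal(ev2$branch, c("gibbon", "human"))
  ## unknown species is an error
  srBad <- fakeWindows(rep("martian", 3)) |> segmentSubregions()
  expect_error(mapEvents(srBad, tree), "martian")
})

test_that("per-group branch cover equals the brute-force minimum", {
  tree <- primateSpeciesTree()
  desc <- gameconv:::branchDescendants(tree)
  bruteMin <- function(G) {
    usable <- which(vapply(desc, function(s) all(s %in% G), logical(1)))
    best <- Inf
    for (k in seq_len(length(usable))) {
      combos <- combn(usable, k, simplify = FALSE)
      for (cmb in combos) {
        if (setequal(unlist(desc[cmb]), G)) return(k)
      }
    }
    best
  }
  set.seed(31)
  for (i in 1:15) {
    G <- sample(tree$tip.label, sample(2:5, 1))
    cover <- gameconv:::minimalBranchCover(G, tree)
    expect_equal(length(cover), bruteMin(G))
    expect_setequal(unlist(desc[cover]), G)
  }
})

test_that("a nested recent event is called from within-pair divergence", {
  cfg <- simConfig(primateSpeciesTree(), seq_length = 2000,
                   conversions = data.frame(
                     lineage = c("human+chimp+gorilla", "human"),
                     time_myr = c(14, 1), start = 0, end = 2000,
                     direction = c("X_TO_Y", "Y_TO_X")),
                   tips = rbind(expand.grid(
                     species = c("human", "chimp", "gorilla", "rhesus"),
                     chromosome = c("X", "Y"), allele = "",
                     stringsAsFactors = FALSE)[, c("species",
                                                   "chromosome",
                                                   "allele")],
                     data.frame(species = "nwm", chromosome = "X",
                                allele = "")),
                   allele_theta = 0)
  s <- simulateGametologs(cfg, seed = 8)
  sr <- segmentSubregions(fakeWindows(rep("chimp+gorilla+human", 4)))
  ev <- mapEvents(sr, primateSpeciesTree(), aln = s$alignment)
  expect_equal(nrow(ev), 2L)
  expect_true(any(ev$branch == "human" & ev$nested))
  ## without the nested conversion no extra event is called
  cfg2 <- cfg; cfg2$conversions <- cfg$conversions[1, ]
  s2 <- simulateGametologs(cfg2, seed = 8)
  ev2 <- mapEvents(sr, primateSpeciesTree(), aln = s2$alignment)
  expect_equal(nrow(ev2), 1L)
})

test_that("direction votes follow outgroup-polarized diagnostic sites", {
  ## relatives h/c: X state A, Y state C; outgroup A => C is Y-derived;
  ## converted species g carries C on both chromosomes at 5 sites
  L <- 60L
  base <- rep("A", L)
  mk <- function(states) { s <- base; s[1:5] <- states; s }
  a <- suppressWarnings(GametologAlignment(rbind(
    h_X = mk(rep("A", 5)), c_X = mk(rep("A", 5)),
    h_Y = mk(rep("C", 5)), c_Y = mk(rep("C", 5)),
    g_X = mk(rep("C", 5)), g_Y = mk(rep("C", 5)),
    nwm_out = mk(rep("A", 5)))))  # nwm_out parses to chromosome U
  r <- inferDirection(a, 0, L, "g")
  expect_equal(r$direction, "Y_TO_X")
  expect_equal(r$votes_y_to_x, 5L)
  expect_equal(r$votes_x_to_y, 0L)
  ## mirrored: converted pair carries the X-derived state
  b <- suppressWarnings(GametologAlignment(rbind(
    h_X = mk(rep("A", 5)), c_X = mk(rep("A", 5)),
    h_Y = mk(rep("C", 5)), c_Y = mk(rep("C", 5)),
    g_X = mk(rep("A", 5)), g_Y = mk(rep("A", 5)),
    nwm_out = mk(rep("C", 5)))))
  r2 <- inferDirection(b, 0, L, "g")
  expect_equal(r2$direction, "X_TO_Y")
  expect_equal(r2$votes_x_to_y, 5L)
  ## no informative sites: never a determinate direction
  cst <- suppressWarnings(
    GametologAlignment(rbind(h_X = base, c_X = base, h_Y = base,
                             c_Y = base, g_X = base, g_Y = base,
                             nwm_out = base)))
  r3 <- inferDirection(cst, 0, L, "g")
  expect_equal(r3$direction, "UNKNOWN")
  expect_equal(r3$n_informative, 0L)
  ## below min_votes stays UNKNOWN
  few <- suppressWarnings(GametologAlignment(rbind(
    h_X = mk(c("A", "A", rep("A", 3))), c_X = mk(rep("A", 5)),
    h_Y = mk(rep("C", 5)), c_Y = mk(rep("C", 5)),
    g_X = mk(c("C", "C", "A", "A", "A")),
    g_Y = mk(c("C", "C", "A", "A", "A")),
    nwm_out = mk(rep("A", 5)))))
  r4 <- inferDirection(few, 0, L, "g")
  expect_equal(r4$direction, "UNKNOWN")
  expect_equal(r4$n_informative, 2L)
})

test_that("breakpoint localization finds a planted switch", {
  fx <- makeFigureFixture("fig5_breakpoint", seed = 6)
  bp <- locateBreakpoint(fx$alignment, 0, 3000, candidate_step = 50,
                         reps = 100, seed = 7)
  expect_false(bp$no_switch)
  expect_lte(abs(bp$column - 1500), 150)
  expect_equal(bp$left_call, "RECIPROCAL_MONOPHYLY")
  expect_false(bp$right_call %in% c("RECIPROCAL_MONOPHYLY",
                                    "UNRESOLVED"))
})

test_that("breakpoint search reports no-switch and boundary cases", {
  fx0 <- makeFigureFixture("regionA_null", seed = 6)
  bp0 <- locateBreakpoint(fx0$alignment, 0, 3000, candidate_step = 100,
                          reps = 50, seed = 8)
  expect_true(bp0$no_switch)
  expect_equal(bp0$score, 0)
  ## an entirely converted interval puts the breakpoint at its start
  fx1 <- makeFigureFixture("fig5_breakpoint", seed = 6)
  bp1 <- locateBreakpoint(fx1$alignment, 1500, 3000,
                          candidate_step = 50, reps = 100, seed = 9)
  expect_equal(bp1$column, 1500L)
})
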
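## Forward simulator of gametolog evolution. A single ancestral sequence
## evolves down a time-calibrated species tree under Jukes-Cantor
## substitution; at the stratum age each lineage's sequence forks into an
## X and a Y copy evolving at chromosome-specific rates; conversion events
## copy the donor tract over the recipient instantaneously at the stated
## time on the stated lineage; deletions gap out intervals on a lineage
## and chromosome. Times are myr before present throughout; rates are
## substitutions per site per year; the myr-to-year conversion lives in
## one place (jcPDiff).

SIM_BASES <- c("A", "C", "G", "T")

## JC probability that a site's state differs after time t at rate r.
## This is the exact transition, so expectations compose across segments:
## the X-Y divergence at stratum age T is (3/4)(1 - exp(-(4/3)(rX+rY)T)).
jcPDiff <- function(rate, t_myr) {
  0.75 * (1 - exp(-(4 / 3) * rate * t_myr * 1e6))
}

#' Expected X-Y p-distance under the simulator's model
#'
#' Closed form for the per-site probability that X and Y differ when their
#' lineages have been separated for \code{t_myr} (the stratum age for
#' unconverted sites, the conversion time inside a converted tract).
#'
#' @param r_x,r_y chromosome-specific substitution rates (per site/year)
#' @param t_myr separation time in myr
#' @return expected uncorrected p-distance
#' @export
expectedXYDivergence <- function(r_x, r_y, t_myr) {
  jcPDiff(r_x + r_y, t_myr)
}

#' Simulation configuration for gametolog evolution
#'
#' The defaults are the primate stratum-4 conditions this package
#' emulates: stratum formation 47 myr ago (which with the rates below gives the ~10 percent
#' X-Y backdrop divergence), X and Y substitution rates 0.78e-9 and
#' 1.45e-9 per site per year.
#'
#' @param species_tree Newick string or \code{phylo}, ultrametric, branch
#'   lengths in myr
#' @param stratum_age_myr time recombination ceased; X and Y are identical
#'   before, independent after. May predate the tree root.
#' @param r_x,r_y substitution rates (per site per year)
#' @param seq_length alignment columns
#' @param conversions data.frame with columns \code{lineage} (descendant
#'   species joined by \code{+}), \code{time_myr}, \code{start},
#'   \code{end} (0-based half-open), \code{direction}
#'   (\code{X_TO_Y}/\code{Y_TO_X}); or NULL
#' @param conversion_rate optional Poisson rate of conversions per lineage
#'   per myr (an alternative to an explicit schedule)
#' @param tract_range tract-length range (bp) for Poisson-drawn events,
#'   sampled log-uniformly (observed conversion tracts span ~0.07-10 kb)
#' @param deletions data.frame with \code{lineage}, \code{chromosome},
#'   \code{start}, \code{end}; applied to the lineage's descendants
#' @param tips data.frame with \code{species}, \code{chromosome},
#'   \code{allele} naming the output rows; default every species x {X,Y}
#'   with an empty allele id
#' @param allele_theta expected within-species per-site allele diversity;
#'   each output allele evolves an extra Exp time with mean
#'   theta/(2 rate)
#' @param label_template how output rows are named
#' @return a list of class \code{"SimConfig"}
#' @export
simConfig <- function(species_tree, stratum_age_myr = 47,
                      r_x = 0.78e-9, r_y = 1.45e-9, seq_length = 6000L,
                      conversions = NULL, conversion_rate = NULL,
                      tract_range = c(70, 10000),
                      deletions = NULL, tips = NULL, allele_theta = 0.001,
                      label_template = "{species}_{allele}_{chrom}") {
  if (is.character(species_tree))
    species_tree <- readSpeciesTree(species_tree)
  stopifnot(r_x >= 0, r_y >= 0, seq_length >= 1, stratum_age_myr > 0)
  if (is.null(tips))
    tips <- expand.grid(species = species_tree$tip.label,
                        chromosome = c("X", "Y"), allele = "",
                        stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)[, c("species", "chromosome",
                                                    "allele")]
  structure(list(species_tree = species_tree,
                 stratum_age_myr = stratum_age_myr,
                 r_x = r_x, r_y = r_y, seq_length = as.integer(seq_length),
                 conversions = conversions,
                 conversion_rate = conversion_rate,
                 tract_range = tract_range,
                 deletions = deletions, tips = tips,
                 allele_theta = allele_theta,
                 label_template = label_template),
            class = "SimConfig")
}

normLineage <- function(x) {
  vapply(strsplit(x, "+", fixed = TRUE),
         function(s) paste(sort(trimws(s)), collapse = "+"), "")
}

#' Simulate a gametolog alignment with a truth ledger
#'
#' @param cfg a \code{\link{simConfig}}
#' @param seed integer seed; identical config + seed gives byte-identical
#'   output
#' @return list with \code{alignment} (\linkS4class{GametologAlignment})
#'   and \code{truth} (\linkS4class{SimTruth})
#' @export
simulateGametologs <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(as.integer(seed))
  tree <- cfg$species_tree
  n <- length(tree$tip.label)
  root <- n + 1L
  ages <- nodeAges(tree)
  rootAge <- ages[root]
  Ts <- cfg$stratum_age_myr
  L <- cfg$seq_length
  desc <- branchDescendants(tree)
  branchKey <- vapply(desc, function(s) paste(sort(s), collapse = "+"), "")
  parent <- rep(NA_integer_, length(desc))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  rAnc <- (cfg$r_x + cfg$r_y) / 2  # single-copy rate before the stratum

  ## --- assemble the conversion schedule -------------------------------
  ev <- cfg$conversions
  if (is.null(ev))
    ev <- data.frame(lineage = character(0), time_myr = numeric(0),
                     start = integer(0), end = integer(0),
                     direction = character(0))
  if (!is.null(cfg$conversion_rate) && cfg$conversion_rate > 0) {
    for (b in seq_along(desc)) {
      tmin <- ages[b]
      tmax <- min(if (is.na(parent[b])) Ts else ages[parent[b]], Ts)
      if (tmax <= tmin) next
      k <- rpois(1, cfg$conversion_rate * (tmax - tmin))
      if (k == 0) next
      len <- round(exp(runif(k, log(cfg$tract_range[1]),
                             log(min(cfg$tract_range[2], L)))))
      st <- vapply(len, function(l) sample.int(L - l + 1L, 1L) - 1L, 0L)
      ev <- rbind(ev, data.frame(
        lineage = branchKey[b], time_myr = runif(k, tmin, tmax),
        start = st, end = st + len,
        direction = sample(c("X_TO_Y", "Y_TO_X"), k, replace = TRUE)))
    }
  }
  if (nrow(ev)) {
    ev$lineage <- normLineage(ev$lineage)
    ev$node <- vapply(ev$lineage, function(ln) {
      hit <- which(branchKey == ln)
      if (!length(hit)) stop("lineage '", ln, "' matches no branch")
      hit[1]
    }, 0L)
    for (k in seq_len(nrow(ev))) {
      b <- ev$node[k]
      tmin <- ages[b]
      tmax <- min(if (is.na(parent[b])) Ts else ages[parent[b]], Ts)
      if (!(ev$time_myr[k] > tmin && ev$time_myr[k] <= tmax))
        stop("conversion at ", ev$time_myr[k], " myr outside lineage '",
             ev$lineage[k], "' existence (", tmin, ", ", tmax, "]")
      checkInterval(ev$start[k], ev$end[k], L)
      if (!ev$direction[k] %in% c("X_TO_Y", "Y_TO_X"))
        stop("unknown direction: ", ev$direction[k])
    }
  } else ev$node <- integer(0)

  ## --- deletions -------------------------------------------------------
  del <- cfg$deletions
  if (!is.null(del) && nrow(del)) {
    del$lineage <- normLineage(del$lineage)
    del$node <- vapply(del$lineage, function(ln) {
      hit <- which(branchKey == ln)
      if (!length(hit)) stop("deletion lineage '", ln,
                             "' matches no branch")
      hit[1]
    }, 0L)
    ## a conversion whose donor tract is deleted is undefined
    for (k in seq_len(nrow(ev))) {
      donorChrom <- if (ev$direction[k] == "X_TO_Y") "X" else "Y"
      for (j in seq_len(nrow(del))) {
        if (del$chromosome[j] != donorChrom) next
        ancestor <- all(desc[[ev$node[k]]] %in% desc[[del$node[j]]])
        overlap <- ev$start[k] < del$end[j] && del$start[j] < ev$end[k]
        if (ancestor && overlap)
          stop("conversion on '", ev$lineage[k], "' copies from ", donorChrom,
               " inside a deletion on '", del$lineage[j], "'")
      }
    }
  }

  ## --- evolution -------------------------------------------------------
  subs <- list()
  evolveSeq <- function(s, rate, t, key, chrom) {
    nm <- 0L
    if (t > 0 && rate > 0) {
      p <- jcPDiff(rate, t)
      mut <- which(runif(L) < p)
      nm <- length(mut)
      if (nm)
        s[mut] <- ((s[mut] - 1L + sample.int(3L, nm, replace = TRUE)) %%
                     4L) + 1L
    }
    subs[[length(subs) + 1L]] <<- data.frame(
      branch = key, chromosome = chrom, t_myr = t, n_subs = nm)
    s
  }
  evolveState <- function(st, t, key) {
    if (t <= 0) return(st)
    if (!is.null(st$anc))
      list(anc = evolveSeq(st$anc, rAnc, t, key, "A"))
    else
      list(X = evolveSeq(st$X, cfg$r_x, t, key, "X"),
           Y = evolveSeq(st$Y, cfg$r_y, t, key, "Y"))
  }
  applyConv <- function(st, k) {
    idx <- (ev$start[k] + 1L):ev$end[k]
    if (is.null(st$X))
      stop("conversion before stratum formation on '", ev$lineage[k], "'")
    if (ev$direction[k] == "X_TO_Y") st$Y[idx] <- st$X[idx]
    else st$X[idx] <- st$Y[idx]
    st
  }
  walkBranch <- function(st, t_from, t_to, node) {
    key <- branchKey[node]
    here <- which(ev$node == node & ev$time_myr <= t_from &
                    ev$time_myr > t_to)
    stops <- c()
    if (!is.null(st$anc) && Ts <= t_from && Ts > t_to)
      stops <- Ts
    stops <- sort(unique(c(stops, ev$time_myr[here])), decreasing = TRUE)
    t_cur <- t_from
    for (tm in stops) {
      st <- evolveState(st, t_cur - tm, key)
      t_cur <- tm
      if (!is.null(st$anc) && tm == Ts) st <- list(X = st$anc, Y = st$anc)
      for (k in here[ev$time_myr[here] == tm]) st <- applyConv(st, k)
    }
    evolveState(st, t_cur - t_to, key)
  }
  tipStates <- vector("list", n)
  walk <- function(node, st) {
    if (node <= n) { tipStates[[node]] <<- st; return(invisible()) }
    for (ch in tree$edge[tree$edge[, 1] == node, 2])
      walk(ch, walkBranch(st, ages[node], ages[ch], ch))
  }
  rootSeq <- sample.int(4L, L, replace = TRUE)
  if (Ts >= rootAge) {
    st0 <- list(X = rootSeq, Y = rootSeq)
    st0 <- walkBranch(st0, Ts, rootAge, root)   # Catarrhini-stem segment
  } else {
    st0 <- list(anc = rootSeq)
  }
  walk(root, st0)

  ## --- emit tips -------------------------------------------------------
  tips <- cfg$tips
  rows <- matrix("", nrow(tips), L)
  labs <- character(nrow(tips))
  for (i in seq_len(nrow(tips))) {
    sp <- tips$species[i]; chrom <- tips$chromosome[i]
    node <- match(sp, tree$tip.label)
    if (is.na(node)) stop("tip species '", sp, "' not in species tree")
    st <- tipStates[[node]]
    if (is.null(st[[chrom]]))
      stop("no ", chrom, " copy exists for '", sp,
           "' (stratum younger than the tip?)")
    s <- st[[chrom]]
    rch <- if (chrom == "Y") cfg$r_y else cfg$r_x
    if (cfg$allele_theta > 0 && rch > 0) {
      tex <- rexp(1) * cfg$allele_theta / (2 * rch) / 1e6
      s <- evolveSeq(s, rch, tex, paste0(sp, "/", tips$allele[i]), chrom)
    }
    rows[i, ] <- SIM_BASES[s]
    labs[i] <- formatTaxonLabel(sp, tips$allele[i], chrom)
  }
  rownames(rows) <- labs
  ## deletions gap out the interval on every descendant of the lineage
  if (!is.null(del) && nrow(del)) {
    for (j in seq_len(nrow(del))) {
      hit <- which(tips$species %in% desc[[del$node[j]]] &
                     tips$chromosome == del$chromosome[j])
      for (i in hit)
        rows[i, (del$start[j] + 1L):del$end[j]] <- "-"
    }
  }
  aln <- GametologAlignment(rows,
    taxa = data.frame(label = labs, species = tips$species,
                      chromosome = tips$chromosome, allele = tips$allele,
                      stringsAsFactors = FALSE))
  truth <- new("SimTruth",
               events = ev[, c("lineage", "time_myr", "start", "end",
                               "direction")],
               substitutions = if (length(subs)) do.call(rbind, subs)
                               else data.frame(branch = character(0),
                                               chromosome = character(0),
                                               t_myr = numeric(0),
                                               n_subs = integer(0)),
               config = list(cfg = cfg, seed = as.integer(seed)))
  list(alignment = aln, truth = truth)
}

#' The primate species tree used by the canned fixtures
#'
#' Human-chimp 6 myr, +gorilla 8, +gibbon 18, +rhesus 30, +New World
#' monkey 40; stratum-4 formation is modelled at 47 myr, after the
#' prosimian-simian divergence.
#'
#' @return an ultrametric \code{phylo} with ages attached
#' @export
primateSpeciesTree <- function() {
  readSpeciesTree(paste0("(((((human:6,chimp:6):2,gorilla:8):10,",
                         "gibbon:18):12,rhesus:30):10,nwm:40);"))
}

## fig4 is built by construction (alleles with a planted identical tract),
## not by tree simulation: the signal is a within-species polymorphism.
fig4GibbonFixture <- function(seed) {
  set.seed(as.integer(seed))
  L <- 1600L
  tract <- c(700L, 770L)      # 70 bp starting at the end of "exon 10"
  buffer <- c(695L, 775L)     # no allele noise near the tract boundaries
  X <- sample.int(4L, L, replace = TRUE)
  ## X-Y fixed differences: ~3% backdrop outside the buffer, plus eight
  ## diagnostic sites inside the tract and one at each flank to bound the
  ## identical run
  allowed <- setdiff(seq_len(L), (buffer[1] + 1L):buffer[2])
  diffs <- allowed[runif(length(allowed)) < 0.03]
  inside8 <- c(702L, 710L, 718L, 726L, 734L, 742L, 750L, 761L) + 1L
  bounds <- c(700L, 771L)     # 1-based: columns 699 and 770 (0-based)
  diffs <- sort(unique(c(diffs, inside8, bounds)))
  Y <- X
  Y[diffs] <- ((X[diffs] - 1L + sample.int(3L, length(diffs),
                                           replace = TRUE)) %% 4L) + 1L
  noise <- function(s) {
    mut <- allowed[runif(length(allowed)) < 0.002]
    mut <- setdiff(mut, diffs)  # keep diagnostic sites fixed
    if (length(mut))
      s[mut] <- ((s[mut] - 1L + sample.int(3L, length(mut),
                                           replace = TRUE)) %% 4L) + 1L
    s
  }
  xa <- c("2845F", "2846M", "2847F", "2848M")
  ya <- c("2846M", "2848M")
  rows <- list()
  for (a in xa) rows[[paste0("gibbonWH_", a, "_X")]] <- noise(X)
  for (a in ya) rows[[paste0("gibbonWH_", a, "_Y")]] <- noise(Y)
  ## the donor is the 2846M Y allele; the other Y allele carries a private
  ## variant inside the tract (at a non-diagnostic position), so the
  ## focal sequence is identical to exactly one Y sequence there
  p48 <- 731L
  rows[["gibbonWH_2848M_Y"]][p48] <-
    ((rows[["gibbonWH_2848M_Y"]][p48] - 1L + sample.int(3L, 1L)) %% 4L) + 1L
  ## the focal allele carries the donor Y sequence across the tract
  idx <- (tract[1] + 1L):tract[2]
  rows[["gibbonWH_2845F_X"]][idx] <- Y[idx]
  m <- do.call(rbind, lapply(rows, function(s) SIM_BASES[s]))
  aln <- GametologAlignment(m)
  truth <- new("SimTruth",
               events = data.frame(lineage = "gibbonWH", time_myr = 0,
                                   start = tract[1], end = tract[2],
                                   direction = "Y_TO_X"),
               substitutions = data.frame(branch = character(0),
                                          chromosome = character(0),
                                          t_myr = numeric(0),
                                          n_subs = integer(0)),
               config = list(name = "fig4_gibbon", seed = as.integer(seed),
                             n_diagnostic = 8L, tract = tract))
  list(alignment = aln, truth = truth)
}

#' Canned simulation fixtures for the package's benchmark scenarios
#'
#' \describe{
#'   \item{fig1_profile}{50-kb human-chimp gametolog alignment with two
#'     human conversion tracts (3 and 18 myr old) and a human-Y deletion:
#'     the windowed-profile shape (low p-distance segments against the
#'     ~10 percent backdrop).}
#'   \item{regionA_null}{6-kb human/chimp/rhesus alignment with no
#'     conversion: the reciprocal-monophyly null of an undisturbed
#'     stratum.}
#'   \item{fig3_ten_events}{7.9-kb five-species (+ New World monkey
#'     outgroup) alignment carrying ten conversion events in six of seven
#'     sub-regions (3+2+1+1+0+2+1) on gibbon / HCG-stem / human / rhesus
#'     branches with a 5:5 direction split.}
#'   \item{fig4_gibbon}{four gibbon X alleles and two Y alleles; one X
#'     allele carries a planted 70-bp Y-identical tract containing eight
#'     diagnostic sites.}
#'   \item{fig5_breakpoint}{3-kb alignment whose 3' half [1500, 3000) was
#'     converted on the human-chimp stem and in rhesus: a single topology
#'     switch at column 1500 inside a LINE-like element.}
#' }
#'
#' @param name fixture name
#' @param seed RNG seed
#' @return list with \code{alignment}, \code{truth} and the
#'   \code{SimConfig} used (where applicable)
#' @export
makeFigureFixture <- function(name = c("fig1_profile", "regionA_null",
                                      "fig3_ten_events", "fig4_gibbon",
                                      "fig5_breakpoint"),
                             seed = 1L) {
  if (!is.character(name) || !name[1] %in% c("fig1_profile", "regionA_null",
                                             "fig3_ten_events",
                                             "fig4_gibbon",
                                             "fig5_breakpoint"))
    stop("unknown fixture '", name[1], "'; valid names: fig1_profile, ",
         "regionA_null, fig3_ten_events, fig4_gibbon, fig5_breakpoint")
  name <- match.arg(name)
  if (name == "fig4_gibbon") return(fig4GibbonFixture(seed))
  cfg <- switch(name,
    fig1_profile = simConfig(
      "(human:6,chimp:6);", seq_length = 50000L,
      conversions = data.frame(
        lineage = c("human", "chimp+human"),
        time_myr = c(3, 18),
        start = c(20000L, 26000L), end = c(26000L, 35000L),
        direction = c("Y_TO_X", "X_TO_Y")),
      deletions = data.frame(lineage = "human", chromosome = "Y",
                             start = 38000L, end = 41000L),
      allele_theta = 0),
    regionA_null = simConfig(
      "((human:6,chimp:6):24,rhesus:30);", seq_length = 6000L,
      allele_theta = 0),
    fig3_ten_events = {
      hcg <- "human+chimp+gorilla"
      simConfig(
        primateSpeciesTree(), seq_length = 7900L,
        conversions = data.frame(
          lineage = c("gibbon", hcg, "human",
                      "rhesus", "gibbon",
                      "rhesus",
                      "gibbon",
                      hcg, "rhesus",
                      "rhesus"),
          time_myr = c(10, 14, 1,
                       16, 5,
                       8,
                       5,
                       10, 16,
                       17),
          start = c(0L, 0L, 0L,
                    1250L, 1250L,
                    2450L,
                    3650L,
                    5650L, 5650L,
                    6850L),
          end = c(1250L, 1250L, 1250L,
                  2450L, 2450L,
                  3650L,
                  4850L,
                  6850L, 6850L,
                  7900L),
          direction = c("Y_TO_X", "X_TO_Y", "Y_TO_X",
                        "X_TO_Y", "Y_TO_X",
                        "X_TO_Y",
                        "X_TO_Y",
                        "Y_TO_X", "X_TO_Y",
                        "Y_TO_X")),
        tips = rbind(
          expand.grid(species = c("human", "chimp", "gorilla", "gibbon",
                                  "rhesus"),
                      chromosome = c("X", "Y"), allele = "",
                      stringsAsFactors = FALSE)[, c("species", "chromosome",
                                                    "allele")],
          data.frame(species = "nwm", chromosome = "X", allele = "")),
        allele_theta = 0)
    },
    fig5_breakpoint = simConfig(
      "(((human:6,chimp:6):24,rhesus:30):10,nwm:40);", seq_length = 3000L,
      conversions = data.frame(
        lineage = c("human+chimp", "rhesus"),
        time_myr = c(14, 8),
        start = c(1500L, 1500L), end = c(3000L, 3000L),
        direction = c("Y_TO_X", "Y_TO_X")),
      tips = rbind(
        expand.grid(species = c("human", "chimp", "rhesus"),
                    chromosome = c("X", "Y"), allele = "",
                    stringsAsFactors = FALSE)[, c("species", "chromosome",
                                                  "allele")],
        data.frame(species = "nwm", chromosome = "X", allele = "")),
      allele_theta = 0))
  out <- simulateGametologs(cfg, seed)
  out$config <- cfg
  out
}
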
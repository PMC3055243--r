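## Topology classification and the conversion scan: slide NJ trees across
## the region, classify each window as reciprocal monophyly (the
## post-recombination-arrest null) versus species pairing (the conversion
## signature), segment the region into topology-homogeneous sub-regions,
## map the implied conversion events onto the species tree, and polarize
## their direction with an outgroup.
##
## A "mixed clade" is one side of a supported bipartition that contains
## both the X and the Y sequences (all alleles) of every species in some
## set S and nothing else. A lineage-specific conversion on the branch with
## descendant species S creates exactly such a clade. Mixed clades are
## laminar (nested or disjoint); a clade that is not exactly partitioned by
## its child mixed clades implies a conversion event of its own, which is
## how a recent species-specific event nested inside an older stem event
## is recovered.

#' Classify the topology of a gametolog tree window
#'
#' @param tree a tree from \code{\link{bootstrapTree}} (carries splits,
#'   supports and the taxon table)
#' @param support_threshold minimal bootstrap support (percent) for an edge
#'   to count as resolved
#' @return an object of class \code{"TopologyCall"}: list with \code{call}
#'   (RECIPROCAL_MONOPHYLY, SPECIES_PAIRING, MIXED or UNRESOLVED),
#'   \code{paired_species}, \code{groups} (event-implying species sets,
#'   each with its edge support), \code{clades} (all supported mixed
#'   clades), \code{support_ok}, \code{rm_support} and a canonical
#'   \code{signature} string.
#' @export
classifyTopology <- function(tree, support_threshold = 70) {
  taxa <- attr(tree, "taxa")
  if (is.null(taxa)) stop("tree carries no taxon table; use bootstrapTree")
  labels <- tree$tip.label
  ti <- taxa[match(labels, taxa$label), ]
  n <- length(labels)
  full <- as.integer(2^n - 1)
  bit <- as.integer(2^(0:(n - 1)))
  bychrom <- split(seq_len(n), ti$species)
  gsp <- names(Filter(function(i) {
    all(c("X", "Y") %in% ti$chromosome[i])
  }, bychrom))
  unresolved <- function(reason) {
    structure(list(call = "UNRESOLVED", paired_species = character(0),
                   groups = list(), clades = list(), support_ok = FALSE,
                   rm_support = NA_real_, signature = "U",
                   reason = reason),
              class = "TopologyCall")
  }
  if (length(gsp) < 2)
    return(unresolved("fewer than 2 species with both chromosomes"))
  isg <- ti$species %in% gsp
  maskX <- as.integer(sum(bit[isg & ti$chromosome == "X"]))
  maskY <- as.integer(sum(bit[isg & ti$chromosome == "Y"]))
  outmask <- as.integer(full - maskX - maskY)
  spMask <- vapply(gsp, function(s)
    as.integer(sum(bit[ti$species == s & ti$chromosome %in% c("X", "Y")])),
    integer(1))
  sp <- attr(tree, "splits")
  sup <- sp$support
  sup[is.na(sup)] <- 100  # point-estimate tree: treat edges as resolved
  ## candidate clade sides of each split: never the side holding outgroups
  sides <- list(); sidesup <- numeric(0)
  for (k in seq_len(nrow(sp))) {
    for (side in unique(c(sp$mask[k], bitwXor(full, sp$mask[k])))) {
      if (outmask != 0L && bitwAnd(side, outmask) != 0L) next
      sides[[length(sides) + 1L]] <- side
      sidesup <- c(sidesup, sup[k])
    }
  }
  rm_support <- NA_real_
  for (k in seq_along(sides))
    if (sides[[k]] == maskX || sides[[k]] == maskY)
      rm_support <- max(rm_support, sidesup[k], na.rm = TRUE)
  ## supported mixed clades
  clades <- list()
  for (k in seq_along(sides)) {
    side <- sides[[k]]
    if (sidesup[k] < support_threshold) next
    if (bitwAnd(side, maskX) == 0L || bitwAnd(side, maskY) == 0L) next
    S <- gsp[bitwAnd(rep(side, length(spMask)), spMask) != 0L]
    if (as.integer(sum(spMask[S])) != side) next  # partial species inside
    key <- paste(sort(S), collapse = "+")
    if (is.null(clades[[key]]) || clades[[key]]$support < sidesup[k])
      clades[[key]] <- list(species = sort(S), support = sidesup[k])
  }
  if (length(clades) == 0L) {
    if (!is.na(rm_support) && rm_support >= support_threshold)
      return(structure(list(call = "RECIPROCAL_MONOPHYLY",
                            paired_species = character(0), groups = list(),
                            clades = list(), support_ok = TRUE,
                            rm_support = rm_support, signature = "RM",
                            reason = NA_character_),
                       class = "TopologyCall"))
    return(unresolved("no edge reaches the support threshold"))
  }
  ## event-implying reduction over the laminar clade family: a clade that
  ## is exactly partitioned by its child mixed clades carries no event of
  ## its own
  sets <- lapply(clades, `[[`, "species")
  eventful <- list()
  for (key in names(clades)) {
    G <- clades[[key]]$species
    subs <- Filter(function(H) length(H) < length(G) && all(H %in% G), sets)
    covered <- unique(unlist(subs))
    if (!setequal(covered, G))
      eventful[[key]] <- clades[[key]]
  }
  ## the window signature keeps only the maximal eventful clades: a clade
  ## nested inside a larger eventful clade marks a more recent event on
  ## top of an older one, but its (short-edge) support flickers from
  ## window to window; nested events are recovered region-wide by the
  ## within-pair divergence rule in mapEvents instead
  esets <- lapply(eventful, `[[`, "species")
  groups <- eventful[vapply(names(eventful), function(key) {
    G <- esets[[key]]
    !any(vapply(esets, function(H)
      length(H) > length(G) && all(G %in% H), logical(1)))
  }, logical(1))]
  paired <- sort(unique(unlist(sets)))
  call <- if (setequal(paired, gsp)) "SPECIES_PAIRING" else "MIXED"
  sig <- paste(sort(names(groups)), collapse = ";")
  structure(list(call = call, paired_species = paired, groups = groups,
                 clades = clades, support_ok = TRUE,
                 rm_support = rm_support, signature = sig,
                 reason = NA_character_),
            class = "TopologyCall")
}

#' @export
print.TopologyCall <- function(x, ...) {
  cat("TopologyCall:", x$call, "\n")
  if (length(x$paired_species))
    cat("  paired species:", paste(x$paired_species, collapse = ", "), "\n")
  if (length(x$groups))
    cat("  event-implying clades:",
        paste(names(x$groups), collapse = " | "), "\n")
  invisible(x)
}

#' Sliding-window topology scan
#'
#' Builds one bootstrap NJ tree per window and classifies it. Windows with
#' too few complete columns are emitted as UNRESOLVED rather than dropped,
#' so the window series always tiles the scanned extent.
#'
#' @param x a \linkS4class{GametologAlignment}
#' @param width,step,min_valid_sites window geometry (typical scans:
#'   2000/step 1000 for a coarse region split, 500/step 400 for a fine
#'   sub-region scan)
#' @param support_threshold bootstrap support cut for classification
#' @param reps bootstrap replicates per window (scan-stage default 100;
#'   the final reported trees use 1000)
#' @param seed RNG seed
#' @return data.frame (one row per window) with start, end, call,
#'   signature, n_sites; the full \code{TopologyCall} objects are attached
#'   as attribute \code{"calls"}
#' @export
scanTopologies <- function(x, width = 500L, step = 400L,
                           min_valid_sites = ceiling(width / 2),
                           support_threshold = 70, reps = 100L,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- iterWindows(alnLength(x), width, step, min_valid_sites)
  calls <- vector("list", nrow(w))
  nsites <- integer(nrow(w))
  for (i in seq_len(nrow(w))) {
    tr <- tryCatch(bootstrapTree(x, w$start[i], w$end[i], reps = reps,
                                 min_valid_sites = min_valid_sites),
                   error = function(e) e)
    if (inherits(tr, "error")) {
      calls[[i]] <- structure(list(call = "UNRESOLVED",
                                   paired_species = character(0),
                                   groups = list(), clades = list(),
                                   support_ok = FALSE,
                                   rm_support = NA_real_, signature = "U",
                                   reason = conditionMessage(tr)),
                              class = "TopologyCall")
      nsites[i] <- 0L
    } else {
      calls[[i]] <- classifyTopology(tr, support_threshold)
      nsites[i] <- attr(tr, "sites_used")
    }
  }
  out <- data.frame(window = seq_len(nrow(w)), start = w$start,
                    end = w$end,
                    call = vapply(calls, `[[`, "", "call"),
                    signature = vapply(calls, `[[`, "", "signature"),
                    n_sites = nsites)
  attr(out, "calls") <- calls
  out
}

#' Segment a window scan into topology-homogeneous sub-regions
#'
#' Maximal runs of windows with identical signature are merged. Boundaries
#' between adjacent runs are placed at the midpoint of the overlap (or gap)
#' between the flanking windows. UNRESOLVED runs are absorbed into the
#' neighbouring sub-region with which they share more windows (ties to the
#' left). A short run of pairing windows whose clade family is a proper
#' subset of an adjacent (strictly longer) pairing run's family is likewise
#' absorbed: windows straddling a sub-region boundary see both flanking
#' topologies at reduced per-clade site support and typically resolve only
#' the shared or stronger clades, so such runs are boundary artifacts, not
#' sub-regions. Runs of equal length are never merged this way (alternating
#' single-window signatures stay one sub-region per window).
#'
#' @param windows the data.frame returned by \code{\link{scanTopologies}}
#' @return data.frame of sub-regions (id, start, end, call, signature,
#'   n_windows), with the per-sub-region event-implying groups attached as
#'   attribute \code{"groups"}; empty with a warning when every window is
#'   UNRESOLVED
#' @export
segmentSubregions <- function(windows) {
  calls <- attr(windows, "calls")
  sig <- windows$signature
  if (all(sig == "U")) {
    warning("all windows UNRESOLVED; no sub-regions")
    out <- data.frame(id = character(0), start = integer(0),
                      end = integer(0), call = character(0),
                      signature = character(0), n_windows = integer(0))
    attr(out, "groups") <- list()
    return(out)
  }
  ## absorb unresolved runs into the larger flanking run (ties left)
  r <- rle(sig)
  endIdx <- cumsum(r$lengths)
  startIdx <- endIdx - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] != "U") next
    leftLen <- if (k > 1) r$lengths[k - 1] else -1L
    rightLen <- if (k < length(r$values)) r$lengths[k + 1] else -1L
    takeLeft <- leftLen >= rightLen
    donor <- if (takeLeft && k > 1) k - 1L
             else if (k < length(r$values)) k + 1L else k - 1L
    sig[startIdx[k]:endIdx[k]] <- r$values[donor]
  }
  ## absorb boundary-artifact runs. Windows straddling a sub-region
  ## boundary mix the two flanking topologies at reduced per-clade site
  ## support; they typically resolve only the shared or stronger clades
  ## (a subset family) or, rarely, a chimeric clade. Four rules, applied
  ## to a fixed point (each merge reduces the run count, so this
  ## terminates):
  ##   1. a pairing run whose family is a proper subset of an adjacent
  ##      pairing run's family joins that neighbour when the neighbour is
  ##      strictly longer, or when the run is a single window;
  ##   2. a pairing run sandwiched between two runs that share one
  ##      identical signature whose family properly contains the run's
  ##      joins them (a transient support dip inside one sub-region);
  ##   3. an interior single-window pairing run both of whose neighbours
  ##      are strictly longer pairing runs joins the neighbour with the
  ##      more similar family;
  ##   4. a single pairing window at either edge of the scan joins an
  ##      adjacent pairing run of two or more windows.
  ## Ties go left. One window cannot witness a sub-region at this step
  ## size; sub-regions narrower than two windows are below the scan's
  ## resolution unless they alternate with equally narrow neighbours.
  fam <- function(s) {
    if (s %in% c("U", "")) NULL
    else if (s == "RM") character(0)
    else strsplit(s, ";", fixed = TRUE)[[1]]
  }
  famDiff <- function(a, b) length(setdiff(a, b)) + length(setdiff(b, a))
  repeat {
    r <- rle(sig)
    endIdx <- cumsum(r$lengths)
    startIdx <- endIdx - r$lengths + 1L
    nrn <- length(r$values)
    changed <- FALSE
    for (k in seq_len(nrn)) {
      fk <- fam(r$values[k])
      if (is.null(fk) || length(fk) == 0L) next  # RM runs stand
      pairingFam <- function(nb) {
        if (nb < 1 || nb > nrn) return(NULL)
        fn <- fam(r$values[nb])
        if (is.null(fn) || length(fn) == 0L) NULL else fn
      }
      target <- NA_integer_
      ## rule 1: proper subset of a neighbouring pairing family
      cand <- c()
      for (nb in c(k - 1L, k + 1L)) {
        fn <- pairingFam(nb)
        if (is.null(fn)) next
        if ((r$lengths[nb] > r$lengths[k] || r$lengths[k] == 1L) &&
            length(fk) < length(fn) && all(fk %in% fn))
          cand <- c(cand, nb)
      }
      if (length(cand) == 2L)
        cand <- if (famDiff(fam(r$values[cand[2]]), fk) <
                    famDiff(fam(r$values[cand[1]]), fk)) cand[2]
                else cand[1]
      if (length(cand)) target <- cand[1]
      ## rule 2: dip between two runs of one identical containing family
      if (is.na(target) && k > 1 && k < nrn &&
          r$values[k - 1] == r$values[k + 1]) {
        fn <- fam(r$values[k - 1])
        if (!is.null(fn) && length(fk) < length(fn) && all(fk %in% fn))
          target <- k - 1L
      }
      ## rules 3 and 4 only rejoin runs that share at least one clade
      ## with the absorbing neighbour: a singleton with an unrelated
      ## signature stands as its own (if narrow) sub-region
      shares <- function(fn) !is.null(fn) && length(intersect(fk, fn)) > 0
      ## rule 3: interior singleton dominated by two pairing neighbours
      if (is.na(target) && k > 1 && k < nrn && r$lengths[k] == 1L &&
          r$lengths[k - 1] > 1L && r$lengths[k + 1] > 1L) {
        fl <- pairingFam(k - 1L); fr <- pairingFam(k + 1L)
        okl <- shares(fl); okr <- shares(fr)
        if (okl && okr)
          target <- if (famDiff(fr, fk) < famDiff(fl, fk)) k + 1L
                    else k - 1L
        else if (okl) target <- k - 1L
        else if (okr) target <- k + 1L
      }
      ## rule 4: edge singleton next to an established related run
      if (is.na(target) && r$lengths[k] == 1L &&
          (k == 1L || k == nrn)) {
        nb <- if (k == 1L) 2L else nrn - 1L
        if (nrn >= 2L && r$lengths[nb] > 1L && shares(pairingFam(nb)))
          target <- nb
      }
      if (!is.na(target)) {
        sig[startIdx[k]:endIdx[k]] <- r$values[target]
        changed <- TRUE
        break
      }
    }
    if (!changed) break
  }
  r <- rle(sig)
  endIdx <- cumsum(r$lengths)
  startIdx <- endIdx - r$lengths + 1L
  nr <- length(r$values)
  starts <- integer(nr); ends <- integer(nr)
  for (k in seq_len(nr)) {
    starts[k] <- if (k == 1) windows$start[1]
      else (windows$end[endIdx[k - 1]] + windows$start[startIdx[k]]) %/% 2L
    ends[k] <- if (k == nr) windows$end[nrow(windows)]
      else (windows$end[endIdx[k]] + windows$start[startIdx[k + 1]]) %/% 2L
  }
  grp <- vector("list", nr)
  callv <- character(nr)
  for (k in seq_len(nr)) {
    ## representative window: first in the run with this (post-absorption)
    ## signature whose own call was not unresolved
    idx <- startIdx[k]:endIdx[k]
    rep_i <- idx[windows$signature[idx] == r$values[k]][1]
    if (is.na(rep_i)) rep_i <- idx[1]
    grp[[k]] <- calls[[rep_i]]$groups
    callv[k] <- calls[[rep_i]]$call
  }
  out <- data.frame(id = as.character(utils::as.roman(seq_len(nr))),
                    start = starts, end = ends, call = callv,
                    signature = r$values,
                    n_windows = r$lengths)
  attr(out, "groups") <- grp
  out
}

## maximal species-tree branches whose descendant sets tile G; for a
## laminar branch family this IS the unique minimal branch cover of G
minimalBranchCover <- function(G, tree) {
  desc <- branchDescendants(tree)
  n <- length(tree$tip.label)
  inG <- vapply(desc, function(s) all(s %in% G), logical(1))
  parent <- rep(NA_integer_, length(desc))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  cover <- which(inG & (is.na(parent) | !inG[ifelse(is.na(parent), 1,
                                                   parent)]))
  covered <- sort(unique(unlist(desc[cover])))
  if (!setequal(covered, G))
    stop("species ", paste(setdiff(G, covered), collapse = ", "),
         " not present in the species tree")
  cover
}

#' Map sub-region conversion signatures onto species-tree branches
#'
#' Each event-implying clade of a sub-region is assigned to the species-tree
#' branch whose descendant species set matches it; a clade matching no
#' single branch is explained by the unique minimal set of branches tiling
#' it. When the alignment is supplied, a species covered by a multi-species
#' (stem) event whose own X-Y divergence over the sub-region is less than
#' \code{nesting_factor} times the median X-Y divergence of the other
#' covered species additionally receives a more recent event on its
#' terminal branch: a second, younger conversion nested inside the older
#' one resets that species' divergence clock (a nested terminal event on
#' top of a stem event).
#' Events in adjacent sub-regions on the same branch are deliberately not
#' merged: sub-regions are independent witnesses, and repeated hits on one
#' branch in neighbouring sub-regions are counted as separate events.
#' Direction and dates are filled by later stages.
#'
#' @param subregions result of \code{\link{segmentSubregions}}
#' @param species_tree time-calibrated species tree from
#'   \code{\link{readSpeciesTree}}
#' @param aln optional \linkS4class{GametologAlignment} enabling the
#'   nested-event rule
#' @param nesting_factor divergence ratio below which a nested terminal
#'   event is called
#' @return data.frame event ledger: event, subregion, start, end, branch
#'   (descendant species joined with +), direction (UNKNOWN), t_low/t_high
#'   (NA until dated), branch_tmin/branch_tmax (branch existence interval,
#'   myr), support, n_windows, nested
#' @export
mapEvents <- function(subregions, species_tree, aln = NULL,
                      nesting_factor = 0.5) {
  desc <- branchDescendants(species_tree)
  ages <- nodeAges(species_tree)
  parent <- rep(NA_integer_, length(desc))
  parent[species_tree$edge[, 2]] <- species_tree$edge[, 1]
  grp <- attr(subregions, "groups")
  xyP <- function(sp, s, e) {
    ## mean X-Y p-distance of a species over [s, e), across allele pairs
    ti <- taxonTable(aln)
    xs <- ti$label[ti$species == sp & ti$chromosome == "X"]
    ys <- ti$label[ti$species == sp & ti$chromosome == "Y"]
    ps <- unlist(lapply(xs, function(a) lapply(ys, function(b)
      pDistance(aln, a, b, s, e)$p)))
    mean(unlist(ps), na.rm = TRUE)
  }
  rows <- list()
  addRow <- function(k, b, support, nested) {
    rows[[length(rows) + 1L]] <<- data.frame(
      subregion = subregions$id[k],
      start = subregions$start[k], end = subregions$end[k],
      branch = paste(desc[[b]], collapse = "+"),
      direction = "UNKNOWN",
      t_low = NA_real_, t_high = NA_real_,
      branch_tmin = unname(ages[b]),
      branch_tmax = if (is.na(parent[b])) NA_real_
                    else unname(ages[parent[b]]),
      support = support, n_windows = subregions$n_windows[k],
      nested = nested, stringsAsFactors = FALSE)
  }
  for (k in seq_len(nrow(subregions))) {
    for (g in grp[[k]]) {
      bad <- setdiff(g$species, species_tree$tip.label)
      if (length(bad))
        stop("paired species not in species tree: ",
             paste(bad, collapse = ", "))
      exact <- which(vapply(desc, setequal, logical(1), g$species))
      nodes <- if (length(exact)) exact[1]
               else minimalBranchCover(g$species, species_tree)
      for (b in nodes) addRow(k, b, g$support, FALSE)
      if (!is.null(aln) && length(g$species) >= 2) {
        p <- vapply(g$species, xyP, numeric(1),
                    s = subregions$start[k], e = subregions$end[k])
        for (si in seq_along(g$species)) {
          med <- stats::median(p[-si], na.rm = TRUE)
          if (is.finite(p[si]) && is.finite(med) &&
              p[si] < nesting_factor * med)
            addRow(k, match(g$species[si], species_tree$tip.label),
                   g$support, TRUE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(subregion = character(0), start = integer(0),
                         end = integer(0), branch = character(0),
                         direction = character(0), t_low = numeric(0),
                         t_high = numeric(0), branch_tmin = numeric(0),
                         branch_tmax = numeric(0), support = numeric(0),
                         n_windows = integer(0), nested = logical(0))
  cbind(event = seq_len(nrow(out)), out)
}

#' Infer the direction of a conversion event from polarized sites
#'
#' At columns where the X sequences of the non-converted relatives share
#' one state, their Y sequences share a different state, and an outgroup
#' resolves which of the two is ancestral, the converted species' X and Y
#' sequences (which agree inside the converted tract) vote: carrying the
#' Y-lineage derived state means the tract was copied from Y (Y_TO_X),
#' carrying the X-lineage derived state means X_TO_Y. The call requires a
#' strict majority and at least \code{min_votes} voting sites.
#'
#' @param x a \linkS4class{GametologAlignment}
#' @param start,end 0-based half-open interval of the event
#' @param converted character vector of converted species
#' @param relatives species with both chromosomes used as the unconverted
#'   reference; defaults to all gametolog species not in \code{converted}
#' @param outgroup taxon labels used to polarize; defaults to all rows of
#'   species lacking a Y sequence (e.g. a New World monkey X)
#' @param min_votes minimum voting sites for a determinate call
#' @return list with \code{direction} (X_TO_Y / Y_TO_X / UNKNOWN),
#'   \code{votes_x_to_y}, \code{votes_y_to_x}, \code{n_informative}
#' @export
inferDirection <- function(x, start, end, converted, relatives = NULL,
                           outgroup = NULL, min_votes = 3L) {
  checkInterval(start, end, alnLength(x))
  ti <- taxonTable(x)
  bysp <- split(ti$chromosome, ti$species)
  gsp <- names(Filter(function(ch) all(c("X", "Y") %in% ch), bysp))
  if (is.null(relatives)) relatives <- setdiff(gsp, converted)
  if (is.null(outgroup))
    outgroup <- ti$label[!(ti$species %in% gsp)]
  if (!length(relatives))
    stop("no unconverted relative species available")
  if (!length(outgroup))
    stop("no outgroup sequence available to polarize direction")
  m <- seqMatrix(x)[, (start + 1L):end, drop = FALSE]
  v <- validMask(m)
  rowsOf <- function(sp, chrom) which(ti$species %in% sp &
                                      ti$chromosome %in% chrom)
  unanim <- function(rows) {
    sub <- m[rows, , drop = FALSE]
    ok <- colSums(!v[rows, , drop = FALSE]) == 0L &
      colSums(sub != matrix(sub[1, ], nrow(sub), ncol(sub),
                            byrow = TRUE)) == 0L
    list(ok = ok, state = sub[1, ])
  }
  relX <- unanim(rowsOf(relatives, "X"))
  relY <- unanim(rowsOf(relatives, "Y"))
  conv <- unanim(rowsOf(converted, c("X", "Y")))
  outg <- unanim(match(outgroup, ti$label))
  inf <- relX$ok & relY$ok & conv$ok & outg$ok & (relX$state != relY$state)
  yx <- sum(inf & outg$state == relX$state & conv$state == relY$state)
  xy <- sum(inf & outg$state == relY$state & conv$state == relX$state)
  n <- yx + xy
  direction <- if (n >= min_votes && yx > xy) "Y_TO_X"
               else if (n >= min_votes && xy > yx) "X_TO_Y"
               else "UNKNOWN"
  list(direction = direction, votes_x_to_y = xy, votes_y_to_x = yx,
       n_informative = n)
}

#' Localize a topology switch (conversion-tract breakpoint) in an interval
#'
#' For each candidate column c, the score is the bootstrap support for the
#' reciprocal-monophyly edge on the flank immediately left of c plus the
#' mean bootstrap support of the conversion clades on the flank
#' immediately right of c (flanks of at most \code{flank_width} columns).
#' Bounded flanks keep the score sensitive: on long segments the support
#' of a whole side saturates at 100 well away from the true switch,
#' whereas a flank overlapping the switch mixes both topologies and its
#' support drops. The argmax locates the breakpoint (the LINE3A 5'/3'
#' pattern); ties take the smallest column. A flat profile (spread < 5
#' support points) is reported as "no switch".
#'
#' @param x a \linkS4class{GametologAlignment}
#' @param start,end 0-based half-open search interval, assumed to contain
#'   at most one topology switch, oriented with reciprocal monophyly on
#'   the left
#' @param candidate_step spacing of candidate columns
#' @param reps bootstrap replicates per segment
#' @param support_threshold support cut used to identify the target
#'   conversion clades on the right flank
#' @param seed RNG seed
#' @param min_seg_sites a flank with fewer complete columns scores 0
#' @param flank_width columns scored on each side of a candidate
#' @return list with \code{column}, \code{score}, \code{no_switch},
#'   \code{left_call}, \code{right_call} and the score \code{profile}
#' @export
locateBreakpoint <- function(x, start = 0L, end = alnLength(x),
                             candidate_step = 1L, reps = 100L,
                             support_threshold = 70, seed = NULL,
                             min_seg_sites = 30L, flank_width = 300L) {
  if (!is.null(seed)) set.seed(seed)
  checkInterval(start, end, alnLength(x))
  mm <- mismatchMatrix(x, start, end)
  ## original (alignment) column of every retained complete column
  m <- seqMatrix(x)[, (start + 1L):end, drop = FALSE]
  keptCols <- start + which(colSums(!validMask(m)) == 0L) - 1L
  ti <- taxonTable(x)
  n <- mm$n
  full <- as.integer(2^n - 1)
  bit <- as.integer(2^(0:(n - 1)))
  ord <- match(mm$labels, ti$label)
  sp_ti <- ti[ord, ]
  bysp <- split(seq_len(n), sp_ti$species)
  gsp <- names(Filter(function(i) all(c("X", "Y") %in% sp_ti$chromosome[i]),
                      bysp))
  maskX <- as.integer(sum(bit[sp_ti$species %in% gsp &
                              sp_ti$chromosome == "X"]))
  maskY <- as.integer(sum(bit[sp_ti$species %in% gsp &
                              sp_ti$chromosome == "Y"]))
  rmMask <- canonMask(maskY, full)  # the Y-clade edge defines monophyly
  ## target conversion clades: classify the right-anchored flank
  flank <- max(min_seg_sites, min(1000L, (end - start) %/% 2L))
  reftr <- bootstrapTree(x, max(start, end - flank), end, reps = reps,
                         min_valid_sites = min_seg_sites)
  refcall <- classifyTopology(reftr, support_threshold)
  spMask <- vapply(gsp, function(s)
    as.integer(sum(bit[sp_ti$species == s &
                       sp_ti$chromosome %in% c("X", "Y")])), integer(1))
  targetMasks <- vapply(refcall$groups, function(g)
    canonMask(as.integer(sum(spMask[g$species])), full), integer(1))
  segSupport <- function(cols, masks) {
    if (length(masks) == 0L || length(cols) < min_seg_sites) return(0)
    Pc <- mm$P[, cols, drop = FALSE]
    L <- length(cols)
    hits <- numeric(length(masks))
    for (r in seq_len(reps)) {
      w <- tabulate(sample.int(L, L, replace = TRUE), L)
      mk <- njMasks(pairVecToMatrix(as.numeric(Pc %*% w) / L,
                                    mm$pairs, n, mm$labels))
      hits <- hits + (masks %in% mk)
    }
    mean(100 * hits / reps)
  }
  inner <- if (start + candidate_step <= end - 1L)
    seq(start + candidate_step, end - 1L, by = candidate_step)
  else integer(0)
  cands <- unique(c(start, inner, end))
  scores <- vapply(cands, function(cc) {
    leftCols <- which(keptCols >= max(start, cc - flank_width) &
                        keptCols < cc)
    rightCols <- which(keptCols >= cc &
                         keptCols < min(end, cc + flank_width))
    ## at the interval boundaries one flank is empty: score the other
    ## flank double so a switch at the very start (a fully converted
    ## element) or end competes on equal terms with interior candidates
    if (length(leftCols) < min_seg_sites)
      2 * segSupport(rightCols, targetMasks)
    else if (length(rightCols) < min_seg_sites)
      2 * segSupport(leftCols, rmMask)
    else
      segSupport(leftCols, rmMask) + segSupport(rightCols, targetMasks)
  }, numeric(1))
  no_switch <- (max(scores) - min(scores)) < 5 ||
    length(targetMasks) == 0L
  ## scores within bootstrap resolution of the maximum count as tied;
  ## ties resolve to the smallest column
  bp <- cands[which(scores >= max(scores) - 2)[1]]
  callAt <- function(s, e) {
    if (e - s < min_seg_sites) return(NA_character_)
    tr <- tryCatch(bootstrapTree(x, s, e, reps = reps,
                                 min_valid_sites = min_seg_sites),
                   error = function(e) NULL)
    if (is.null(tr)) NA_character_
    else classifyTopology(tr, support_threshold)$call
  }
  list(column = if (no_switch) NA_integer_ else bp,
       score = if (no_switch) 0 else max(scores) - min(scores),
       no_switch = no_switch,
       left_call = if (no_switch) NA_character_ else callAt(start, bp),
       right_call = if (no_switch) NA_character_ else callAt(bp, end),
       profile = data.frame(column = cands, score = scores))
}
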
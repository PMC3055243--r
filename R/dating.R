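## Branch-specific divergence, calibration to absolute substitution rates,
## and conversion-event dating. The X and Y chromosomes accumulate
## substitutions at different rates, so per-site divergence d is estimated
## separately on the branches leading to the X tips and to the Y tips from
## the calibration node; a fossil-calibrated split time converts d to a
## rate, and post-conversion X/Y branch lengths divided by those rates
## bracket the conversion time.

## concatenate a set of 0-based half-open intervals into one alignment
poolIntervals <- function(x, intervals) {
  cols <- unlist(lapply(seq_len(nrow(intervals)), function(i) {
    checkInterval(intervals$start[i], intervals$end[i], alnLength(x))
    (intervals$start[i] + 1L):intervals$end[i]
  }))
  new("GametologAlignment", seqs = seqMatrix(x)[, cols, drop = FALSE],
      taxa = taxonTable(x))
}

## mean path length from the MRCA of `tips` to each of `tips`, where the
## tree is rooted at a leaf outside them; NULL when they are not a clade
cladeDepth <- function(tr, tips, depthTips = tips) {
  labs <- tr$tip.label
  idx <- match(tips, labs)
  if (anyNA(idx)) stop("taxa missing from tree")
  n <- length(labs)
  mask <- canonMask(as.integer(sum(2^(idx - 1))), as.integer(2^n - 1))
  if (length(tips) < n - 1 && !(mask %in% attr(tr, "splits")$mask) &&
      length(tips) > 1)
    return(NULL)
  out <- setdiff(labs, tips)[1]
  rooted <- ape::root(tr, outgroup = out, resolve.root = TRUE)
  di <- match(depthTips, rooted$tip.label)
  node <- if (length(tips) == 1L) match(tips, rooted$tip.label)
          else ape::getMRCA(rooted, tips)
  dn <- ape::dist.nodes(rooted)
  mean(dn[node, di])
}

#' Per-site divergence on the branches leading to one chromosome's tips
#'
#' Builds a complete-deletion NJ tree of the interval(s), locates the node
#' where the calibration split occurs within the given chromosome's
#' subtree, and averages the path length from that node to each of the
#' chromosome's tips. The chromosome's sequences must be monophyletic
#' (dating is only meaningful on unconverted, or uniformly converted,
#' regions). The standard error is a site bootstrap: columns are resampled,
#' the tree rebuilt and d recomputed; replicates in which the chromosome
#' clade dissolves are dropped and counted.
#'
#' @param x a \linkS4class{GametologAlignment}
#' @param calibration_split character vector of the species on one side of
#'   the calibration split (e.g. \code{"rhesus"} for the rhesus-hominoid
#'   split); the other side is every other species with both chromosomes
#' @param chromosome \code{"X"} or \code{"Y"}
#' @param intervals data.frame of 0-based half-open \code{start},
#'   \code{end} rows to pool; default the whole alignment
#' @param method \code{"tree"} (path lengths on the NJ tree, default) or
#'   \code{"pairwise"} (half the mean cross-split p-distance)
#' @param boot bootstrap replicates for the standard error
#' @param seed RNG seed
#' @param min_valid_sites minimum complete columns
#' @return list with \code{d}, \code{se}, \code{sites_used},
#'   \code{n_boot_used}, \code{method}
#' @export
lineageDivergence <- function(x, calibration_split,
                              chromosome = c("X", "Y"),
                              intervals = NULL, method = c("tree",
                                                           "pairwise"),
                              boot = 200L, seed = NULL,
                              min_valid_sites = 50L) {
  chromosome <- match.arg(chromosome)
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(intervals)) x <- poolIntervals(x, intervals)
  ti <- taxonTable(x)
  bysp <- split(ti$chromosome, ti$species)
  gsp <- names(Filter(function(ch) all(c("X", "Y") %in% ch), bysp))
  side1 <- intersect(calibration_split, gsp)
  side2 <- setdiff(gsp, side1)
  if (!length(side1) || !length(side2))
    stop("calibration split must separate species with both chromosomes")
  tipsC <- ti$label[ti$species %in% c(side1, side2) &
                    ti$chromosome == chromosome]
  mm <- mismatchMatrix(x, 0L, alnLength(x))
  if (mm$ncols < min_valid_sites)
    stop("only ", mm$ncols, " complete columns (< ", min_valid_sites, ")")
  dFromVec <- function(dvec) {
    if (method == "pairwise") {
      D <- pairVecToMatrix(dvec, mm$pairs, mm$n, mm$labels)
      a <- ti$label[ti$species %in% side1 & ti$chromosome == chromosome]
      b <- ti$label[ti$species %in% side2 & ti$chromosome == chromosome]
      return(mean(D[a, b, drop = FALSE]) / 2)
    }
    tr <- njTree(pairVecToMatrix(dvec, mm$pairs, mm$n, mm$labels))
    cladeDepth(tr, tipsC)
  }
  d0 <- dFromVec(rowMeans(mm$P))
  if (is.null(d0))
    stop(chromosome, " sequences are not monophyletic in this region; ",
         "divergence dating is not valid here")
  ds <- numeric(0)
  for (r in seq_len(boot)) {
    w <- tabulate(sample.int(mm$ncols, mm$ncols, replace = TRUE),
                  mm$ncols)
    dr <- dFromVec(as.numeric(mm$P %*% w) / mm$ncols)
    if (!is.null(dr)) ds <- c(ds, dr)
  }
  list(d = d0, se = if (length(ds) > 1) stats::sd(ds) else NA_real_,
       sites_used = mm$ncols, n_boot_used = length(ds), method = method)
}

#' Calibrate divergences to absolute substitution rates
#'
#' @param div_x,div_y results of \code{\link{lineageDivergence}} for X and
#'   Y (or any lists with \code{d} and \code{se})
#' @param T_myr calibration split time in myr (30 for the rhesus-hominoid
#'   split)
#' @return list with \code{r_x}, \code{r_y} (substitutions/site/year),
#'   \code{se_rx}, \code{se_ry}, \code{calibration_time_myr}
#' @examples
#' substitutionRates(list(d = 0.023, se = 0.005),
#'                   list(d = 0.044, se = 0.005), 30)
#' @export
substitutionRates <- function(div_x, div_y, T_myr) {
  stopifnot(T_myr > 0)
  list(r_x = div_x$d / (T_myr * 1e6), r_y = div_y$d / (T_myr * 1e6),
       se_rx = if (is.null(div_x$se)) NA_real_ else div_x$se / (T_myr * 1e6),
       se_ry = if (is.null(div_y$se)) NA_real_ else div_y$se / (T_myr * 1e6),
       calibration_time_myr = T_myr)
}

#' Conversion time bracket from post-conversion branch lengths
#'
#' After a conversion the converted clade's X and Y branches re-diverge
#' from the event; their lengths divided by the chromosome-specific rates
#' give two clock readings whose range brackets the event time.
#'
#' @param b_x,b_y mean path length (substitutions/site) from the clade's
#'   X-Y coalescent node to its X and Y tips
#' @param rates a rate list from \code{\link{substitutionRates}}
#' @return list with \code{t_x}, \code{t_y}, \code{t_low}, \code{t_high}
#'   in myr
#' @export
conversionTimeFromBranches <- function(b_x, b_y, rates) {
  t_x <- b_x / (rates$r_x * 1e6)
  t_y <- b_y / (rates$r_y * 1e6)
  list(t_x = t_x, t_y = t_y, t_low = min(t_x, t_y),
       t_high = max(t_x, t_y))
}

#' Date a conversion event from the window tree
#'
#' Requires the converted species' X and Y sequences to form a clade in
#' the interval's tree (the post-conversion coalescence). The mean path
#' length from the clade's root to its X tips and to its Y tips, divided
#' by the calibrated rates, gives two time estimates returned as a
#' (t_low, t_high) bracket, clipped to the containing branch's existence
#' interval when a species tree is supplied. Standard errors combine the
#' site-bootstrap spread of the branch lengths with the rate standard
#' errors.
#'
#' @param x a \linkS4class{GametologAlignment}
#' @param start,end 0-based half-open interval (the event's sub-region)
#' @param converted character vector of converted species
#' @param rates a rate list from \code{\link{substitutionRates}}
#' @param species_tree optional species tree for clipping to the branch's
#'   existence interval
#' @param boot site-bootstrap replicates for branch-length errors
#' @param seed RNG seed
#' @param min_valid_sites minimum complete columns
#' @return list with \code{t_low}, \code{t_high}, \code{se_low},
#'   \code{se_high}, \code{t_x}, \code{t_y}, \code{b_x}, \code{b_y},
#'   \code{clipped}, \code{n_boot_used}
#' @export
dateConversion <- function(x, start, end, converted, rates,
                           species_tree = NULL, boot = 200L, seed = NULL,
                           min_valid_sites = 50L) {
  if (!is.null(seed)) set.seed(seed)
  checkInterval(start, end, alnLength(x))
  ti <- taxonTable(x)
  cl <- ti$label[ti$species %in% converted &
                 ti$chromosome %in% c("X", "Y")]
  clX <- ti$label[ti$species %in% converted & ti$chromosome == "X"]
  clY <- ti$label[ti$species %in% converted & ti$chromosome == "Y"]
  if (!length(clX) || !length(clY))
    stop("converted species lack X or Y sequences")
  mm <- mismatchMatrix(x, start, end)
  if (mm$ncols < min_valid_sites)
    stop("interval ", fmtInterval(start, end), " retains only ",
         mm$ncols, " complete columns (< ", min_valid_sites, ")")
  bFromVec <- function(dvec) {
    tr <- njTree(pairVecToMatrix(dvec, mm$pairs, mm$n, mm$labels))
    bx <- cladeDepth(tr, cl, clX)
    if (is.null(bx)) return(NULL)
    c(bx, cladeDepth(tr, cl, clY))
  }
  b0 <- bFromVec(rowMeans(mm$P))
  if (is.null(b0))
    stop("X and Y of ", paste(converted, collapse = "+"),
         " are not sister in the tree of ", fmtInterval(start, end),
         "; no single conversion to date")
  bs <- matrix(numeric(0), ncol = 2)
  for (r in seq_len(boot)) {
    w <- tabulate(sample.int(mm$ncols, mm$ncols, replace = TRUE),
                  mm$ncols)
    br <- bFromVec(as.numeric(mm$P %*% w) / mm$ncols)
    if (!is.null(br)) bs <- rbind(bs, br)
  }
  seb <- if (nrow(bs) > 1) apply(bs, 2, stats::sd) else c(NA_real_,
                                                          NA_real_)
  tt <- conversionTimeFromBranches(b0[1], b0[2], rates)
  seT <- function(b, se_b, r, se_r, t) {
    if (is.na(se_b)) return(NA_real_)
    if (b <= 0) return(se_b / (r * 1e6))
    t * sqrt((se_b / b)^2 +
               (if (is.na(se_r)) 0 else (se_r / r)^2))
  }
  se_x <- seT(b0[1], seb[1], rates$r_x, rates$se_rx, tt$t_x)
  se_y <- seT(b0[2], seb[2], rates$r_y, rates$se_ry, tt$t_y)
  ses <- if (tt$t_x <= tt$t_y) c(se_x, se_y) else c(se_y, se_x)
  t_low <- tt$t_low; t_high <- tt$t_high
  clipped <- FALSE
  if (!is.null(species_tree)) {
    desc <- branchDescendants(species_tree)
    ages <- nodeAges(species_tree)
    parent <- rep(NA_integer_, length(desc))
    parent[species_tree$edge[, 2]] <- species_tree$edge[, 1]
    b <- which(vapply(desc, setequal, logical(1), converted))
    if (length(b) && !is.na(parent[b[1]])) {
      pAge <- ages[parent[b[1]]]
      if (t_high > pAge) { t_high <- pAge; clipped <- TRUE }
      if (t_low > pAge) { t_low <- pAge; clipped <- TRUE }
    }
  }
  list(t_low = t_low, t_high = t_high, se_low = ses[1], se_high = ses[2],
       t_x = tt$t_x, t_y = tt$t_y, b_x = b0[1], b_y = b0[2],
       clipped = clipped, n_boot_used = nrow(bs))
}
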
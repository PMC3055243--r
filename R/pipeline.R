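## End-to-end orchestration: profile -> scan -> segment -> map -> orient
## -> date -> tracts, from one alignment + species tree, with
## machine-readable outputs. Identical inputs + seed give identical
## outputs.

#' Run the full gene-conversion detection pipeline
#'
#' @param x a \linkS4class{GametologAlignment} or path to a FASTA
#'   alignment
#' @param species_tree species tree (\code{phylo}, Newick string or file
#'   path), ultrametric in myr
#' @param out_dir optional output directory; created if missing. Written
#'   files: profiles.tsv, profiles.bedgraph, windows.tsv, subregions.bed,
#'   events.tsv, events.bed, rates.tsv, tracts.tsv, run_log.txt
#' @param profile_width tiling window for the per-pair divergence
#'   profiles
#' @param scan_width,scan_step sliding-window geometry of the topology
#'   scan
#' @param support_threshold bootstrap support cut (percent)
#' @param boot bootstrap replicates for scan windows
#' @param nesting_factor nested-event divergence ratio, see
#'   \code{\link{mapEvents}}
#' @param calibration_split species on one side of the calibration node
#'   (e.g. \code{"rhesus"}); NULL disables rate estimation and dating
#' @param calibration_T calibration split age in myr
#' @param min_tract minimal identical-tract length
#' @param min_valid_frac minimal fraction of a window's columns that must
#'   be unambiguous
#' @param date_boot bootstrap replicates for divergence/dating errors
#' @param seed RNG seed governing every stochastic step
#' @return a list of class \code{"gcPipeline"}: profiles, windows,
#'   subregions, events, rates, tracts, params
#' @export
runPipeline <- function(x, species_tree, out_dir = NULL,
                        profile_width = 500L, scan_width = 500L,
                        scan_step = 400L, support_threshold = 70,
                        boot = 100L, nesting_factor = 0.5,
                        calibration_split = NULL, calibration_T = 30,
                        min_tract = 50L, min_valid_frac = 0.5,
                        date_boot = 200L, seed = 1L) {
  if (is.character(x)) x <- readAlignment(x)
  if (is.character(species_tree))
    species_tree <- readSpeciesTree(species_tree)
  set.seed(as.integer(seed))
  ti <- taxonTable(x)
  bysp <- split(ti$chromosome, ti$species)
  gsp <- names(Filter(function(ch) all(c("X", "Y") %in% ch), bysp))
  note <- function(...) message("[gameconv] ", ...)

  note("profiles: ", length(gsp), " species X-Y pairs")
  profiles <- list()
  for (sp in gsp) {
    a <- ti$label[ti$species == sp & ti$chromosome == "X"][1]
    b <- ti$label[ti$species == sp & ti$chromosome == "Y"][1]
    pr <- distanceProfile(x, a, b, width = profile_width,
                          min_valid_sites = ceiling(profile_width *
                                                      min_valid_frac))
    pr <- cbind(species = sp, pair = paste(a, b, sep = "/"), pr)
    profiles[[sp]] <- pr
  }
  profiles <- do.call(rbind, profiles)
  rownames(profiles) <- NULL

  note("topology scan: width ", scan_width, ", step ", scan_step,
       ", ", boot, " bootstrap replicates")
  windows <- scanTopologies(x, width = scan_width, step = scan_step,
                            min_valid_sites = ceiling(scan_width *
                                                        min_valid_frac),
                            support_threshold = support_threshold,
                            reps = boot)
  subregions <- segmentSubregions(windows)
  note(nrow(subregions), " sub-region(s)")
  events <- mapEvents(subregions, species_tree, aln = x,
                      nesting_factor = nesting_factor)
  note(nrow(events), " conversion event(s) mapped")

  ## direction: polarize each event against species not paired in its
  ## sub-region, using outgroup rows (species without a Y sequence)
  grp <- attr(subregions, "groups")
  pairedIn <- lapply(grp, function(g)
    sort(unique(unlist(lapply(g, `[[`, "species")))))
  events$votes_x_to_y <- rep(NA_integer_, nrow(events))
  events$votes_y_to_x <- rep(NA_integer_, nrow(events))
  events$se_low <- rep(NA_real_, nrow(events))
  events$se_high <- rep(NA_real_, nrow(events))
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      conv <- strsplit(events$branch[i], "+", fixed = TRUE)[[1]]
      k <- match(events$subregion[i], subregions$id)
      rel <- setdiff(gsp, pairedIn[[k]])
      dir <- tryCatch(
        inferDirection(x, events$start[i], events$end[i], conv,
                       relatives = rel),
        error = function(e) list(direction = "UNKNOWN",
                                 votes_x_to_y = NA, votes_y_to_x = NA,
                                 n_informative = 0))
      events$direction[i] <- dir$direction
      events$votes_x_to_y[i] <- dir$votes_x_to_y
      events$votes_y_to_x[i] <- dir$votes_y_to_x
    }
  }

  ## rates from the unconverted (reciprocal-monophyly) sub-regions
  rates <- NULL
  if (!is.null(calibration_split)) {
    rmParts <- subregions[subregions$call == "RECIPROCAL_MONOPHYLY", ,
                          drop = FALSE]
    if (nrow(rmParts)) {
      note("calibrating rates on ", sum(rmParts$end - rmParts$start),
           " unconverted columns")
      dv <- lapply(c(X = "X", Y = "Y"), function(ch)
        tryCatch(lineageDivergence(x, calibration_split, ch,
                                   intervals = rmParts,
                                   boot = date_boot),
                 error = function(e) NULL))
      if (!is.null(dv$X) && !is.null(dv$Y))
        rates <- substitutionRates(dv$X, dv$Y, calibration_T)
      if (!is.null(rates)) {
        rates$d_x <- dv$X$d; rates$se_dx <- dv$X$se
        rates$d_y <- dv$Y$d; rates$se_dy <- dv$Y$se
      }
    } else note("no unconverted sub-region; rates not estimated")
  }

  ## dating
  if (!is.null(rates) && nrow(events)) {
    for (i in seq_len(nrow(events))) {
      conv <- strsplit(events$branch[i], "+", fixed = TRUE)[[1]]
      dt <- tryCatch(
        dateConversion(x, events$start[i], events$end[i], conv, rates,
                       species_tree = species_tree, boot = date_boot),
        error = function(e) NULL)
      if (!is.null(dt)) {
        events$t_low[i] <- dt$t_low
        events$t_high[i] <- dt$t_high
        events$se_low[i] <- dt$se_low
        events$se_high[i] <- dt$se_high
      }
    }
  }

  note("tract scan (min ", min_tract, " bp)")
  tracts <- scanTracts(x, min_tract = min_tract)

  res <- structure(list(profiles = profiles, windows = windows,
                        subregions = subregions, events = events,
                        rates = rates, tracts = tracts,
                        params = list(profile_width = profile_width,
                                      scan_width = scan_width,
                                      scan_step = scan_step,
                                      support_threshold = support_threshold,
                                      boot = boot,
                                      nesting_factor = nesting_factor,
                                      calibration_split = calibration_split,
                                      calibration_T = calibration_T,
                                      min_tract = min_tract,
                                      seed = seed)),
                   class = "gcPipeline")
  if (!is.null(out_dir)) writePipelineOutputs(res, out_dir)
  res
}

#' @export
print.gcPipeline <- function(x, ...) {
  cat("gameconv pipeline result\n")
  cat("  windows scanned:   ", nrow(x$windows), "\n")
  cat("  sub-regions:       ", nrow(x$subregions), "\n")
  cat("  conversion events: ", nrow(x$events), "\n")
  if (nrow(x$events)) {
    dirs <- table(x$events$direction)
    cat("  directions:        ",
        paste(names(dirs), dirs, sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(x$rates))
    cat(sprintf("  rates: r_X = %.2fe-9, r_Y = %.2fe-9 /site/year\n",
                x$rates$r_x * 1e9, x$rates$r_y * 1e9))
  cat("  tract hits:        ", nrow(x$tracts), "\n")
  invisible(x)
}

#' Write all pipeline outputs to a directory
#'
#' @param res a \code{gcPipeline} result
#' @param out_dir directory (created if missing)
#' @return invisibly \code{out_dir}
#' @export
writePipelineOutputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  writeTSV(res$profiles, fp("profiles.tsv"))
  for (sp in unique(res$profiles$species)) {
    sub <- res$profiles[res$profiles$species == sp, ]
    writeBedGraph(sub, fp(paste0("profile_", sp, ".bedgraph")))
  }
  writeTSV(res$windows, fp("windows.tsv"))
  writeBED(data.frame(start = res$subregions$start,
                      end = res$subregions$end,
                      name = paste0(res$subregions$id, ":",
                                    res$subregions$signature),
                      score = res$subregions$n_windows),
           fp("subregions.bed"))
  ev <- res$events
  writeTSV(ev, fp("events.tsv"))
  if (nrow(ev)) {
    bed9 <- data.frame(chrom = "aln", start = ev$start, end = ev$end,
                       name = paste0(ev$branch, "|", ev$direction),
                       score = pmin(1000, round(ev$support * 10)),
                       strand = ".", thickStart = ev$start,
                       thickEnd = ev$end, itemRgb = "0,0,0")
    write.table(bed9, fp("events.bed"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else file.create(fp("events.bed"))
  if (!is.null(res$rates))
    writeTSV(data.frame(r_x = res$rates$r_x, r_y = res$rates$r_y,
                        se_rx = res$rates$se_rx, se_ry = res$rates$se_ry,
                        d_x = res$rates$d_x, se_dx = res$rates$se_dx,
                        d_y = res$rates$d_y, se_dy = res$rates$se_dy,
                        calibration_myr =
                          res$rates$calibration_time_myr),
             fp("rates.tsv"))
  writeTSV(res$tracts, fp("tracts.tsv"))
  writeLines(c(paste("gameconv", as.character(utils::packageVersion(
                "gameconv"))),
               paste("date:", format(Sys.time())),
               paste("seed:", res$params$seed),
               paste(names(res$params), vapply(res$params, function(p)
                 paste(format(p), collapse = ","), ""), sep = " = ")),
             fp("run_log.txt"))
  invisible(out_dir)
}

#' Write a canned fixture to disk (alignment + truth ledger)
#'
#' @param name fixture name, see \code{\link{makeFigureFixture}}
#' @param seed RNG seed
#' @param out_dir output directory
#' @return invisibly the fixture list
#' @export
writeFixture <- function(name, seed, out_dir) {
  fx <- makeFigureFixture(name, seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  writeAlignment(fx$alignment, file.path(out_dir,
                                         paste0(name, ".fasta")))
  writeTSV(truthEvents(fx$truth), file.path(out_dir,
                                            paste0(name, "_truth.tsv")))
  invisible(fx)
}
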
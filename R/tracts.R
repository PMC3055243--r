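## Detection of short, recent conversion tracts: anomalously long runs in
## which one X allele is identical to a Y allele against a backdrop of
## fixed X-Y differences (the white-handed gibbon KALX/KALY pattern). The
## evidential core is the diagnostic sites inside the run: positions where
## the other X alleles carry the X state, the Y alleles carry a different
## state, and the focal allele carries the Y state.

#' Diagnostic sites between an X-allele group and a Y-allele group
#'
#' Columns where every sequence in the X group shares one unambiguous
#' base, every sequence in the Y group shares another, and the two differ.
#' Columns with a gap, N or ambiguity code in any group member are
#' excluded.
#'
#' @param x a \linkS4class{GametologAlignment}
#' @param x_group,y_group taxon labels of the two groups
#' @param start,end 0-based half-open interval (default: whole alignment)
#' @return integer vector of 0-based column indices (possibly empty)
#' @export
diagnosticSites <- function(x, x_group, y_group, start = 0L,
                            end = alnLength(x)) {
  checkInterval(start, end, alnLength(x))
  ti <- taxonTable(x)
  ix <- match(x_group, ti$label); iy <- match(y_group, ti$label)
  if (anyNA(c(ix, iy))) stop("unknown taxon in group")
  m <- seqMatrix(x)[, (start + 1L):end, drop = FALSE]
  v <- validMask(m)
  unanim <- function(rows) {
    sub <- m[rows, , drop = FALSE]
    ok <- colSums(!v[rows, , drop = FALSE]) == 0L &
      colSums(sub != matrix(sub[1, ], nrow(sub), ncol(sub),
                            byrow = TRUE)) == 0L
    list(ok = ok, state = sub[1, ])
  }
  ux <- unanim(ix); uy <- unanim(iy)
  start + which(ux$ok & uy$ok & ux$state != uy$state) - 1L
}

#' Probability that diagnostic sites converged by recurrent substitution
#'
#' The null for an identical tract: each diagnostic site independently
#' mutated to the Y state. p = match_prob ^ n_diagnostic, where the
#' per-site match probability defaults to the regional X-Y p-distance
#' outside the tract divided by 3 (a random substitution hits the one
#' matching base out of three).
#'
#' @param n_diagnostic number of diagnostic sites inside the tract at
#'   which the focal allele carries the Y state
#' @param per_site_match_prob per-site probability of converging to the Y
#'   state, in (0, 1)
#' @return the null probability; 1 when \code{n_diagnostic} is 0
#' @examples
#' recurrentSubstitutionPvalue(8, 0.01)  # 1e-16
#' @export
recurrentSubstitutionPvalue <- function(n_diagnostic,
                                        per_site_match_prob) {
  stopifnot(n_diagnostic >= 0, per_site_match_prob > 0,
            per_site_match_prob < 1)
  per_site_match_prob^n_diagnostic
}

#' Find Y-identical tracts in one X allele
#'
#' Maximal runs of gap-free columns at which the focal X allele equals the
#' Y allele. Gaps break runs. A run is reported only when it is at least
#' \code{min_tract} columns long and contains at least one diagnostic site
#' (other X alleles vs the Y alleles) at which the focal allele carries
#' the Y state: identity without polarization cannot distinguish
#' conversion from shared ancestry. Without any other X allele, runs are
#' reported with \code{n_diagnostic} and \code{p_value} missing and
#' flagged unpolarized.
#'
#' @param x a \linkS4class{GametologAlignment}
#' @param focal_x label of the candidate converted X allele
#' @param y_allele label of the Y allele compared against
#' @param min_tract minimal run length (bp)
#' @param per_site_match_prob override for the null's per-site match
#'   probability; default is the focal-Y p-distance outside the run / 3
#' @return data.frame of hits: start, end, run_length_bp, n_diagnostic,
#'   p_value, polarized
#' @export
findIdenticalTracts <- function(x, focal_x, y_allele, min_tract = 50L,
                                per_site_match_prob = NULL) {
  ti <- taxonTable(x)
  i_f <- match(focal_x, ti$label)
  i_y <- match(y_allele, ti$label)
  if (is.na(i_f) || is.na(i_y)) stop("unknown taxon label")
  sp <- ti$species[i_f]
  otherX <- ti$label[ti$species == sp & ti$chromosome == "X" &
                     ti$label != focal_x]
  allY <- ti$label[ti$species == sp & ti$chromosome == "Y"]
  m <- seqMatrix(x)
  v <- validMask(m)
  run <- v[i_f, ] & v[i_y, ] & m[i_f, ] == m[i_y, ]
  r <- rle(run)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hits <- list()
  polarized <- length(otherX) > 0
  dsAll <- if (polarized) diagnosticSites(x, otherX, allY) else integer(0)
  for (k in which(r$values & r$lengths >= min_tract)) {
    s0 <- starts[k] - 1L; e0 <- ends[k]       # 0-based half-open
    if (polarized) {
      ds <- dsAll[dsAll >= s0 & dsAll < e0]
      ## inside the run focal == Y, so any diagnostic site in the run is
      ## one where the focal allele carries the Y state
      nd <- length(ds)
      if (nd == 0L) next
      prob <- per_site_match_prob
      if (is.null(prob)) {
        outside <- setdiff(seq_len(ncol(m)), (s0 + 1L):e0)
        use <- outside[v[i_f, outside] & v[i_y, outside]]
        pout <- if (length(use)) mean(m[i_f, use] != m[i_y, use]) else NA
        prob <- if (is.finite(pout) && pout > 0) pout / 3 else NA_real_
      }
      pv <- if (is.finite(prob)) recurrentSubstitutionPvalue(nd, prob)
            else NA_real_
    } else {
      nd <- NA_integer_; pv <- NA_real_
    }
    hits[[length(hits) + 1L]] <- data.frame(
      start = s0, end = e0, run_length_bp = e0 - s0,
      n_diagnostic = nd, p_value = pv, polarized = polarized,
      focal_x = focal_x, y_allele = y_allele,
      stringsAsFactors = FALSE)
  }
  if (length(hits)) do.call(rbind, hits)
  else data.frame(start = integer(0), end = integer(0),
                  run_length_bp = integer(0), n_diagnostic = integer(0),
                  p_value = numeric(0), polarized = logical(0),
                  focal_x = character(0), y_allele = character(0))
}

#' Scan all X-allele / Y-allele combinations of a species for tracts
#'
#' @param x a \linkS4class{GametologAlignment}
#' @param species species code; default: every species with at least two
#'   X alleles and one Y allele
#' @param min_tract minimal run length
#' @return combined hit data.frame (see \code{\link{findIdenticalTracts}})
#' @export
scanTracts <- function(x, species = NULL, min_tract = 50L) {
  ti <- taxonTable(x)
  if (is.null(species)) {
    cnt <- table(ti$species[ti$chromosome == "X"])
    hasY <- unique(ti$species[ti$chromosome == "Y"])
    species <- intersect(names(cnt)[cnt >= 2], hasY)
  }
  out <- list()
  for (sp in species) {
    xs <- ti$label[ti$species == sp & ti$chromosome == "X"]
    ys <- ti$label[ti$species == sp & ti$chromosome == "Y"]
    for (fx in xs) for (ya in ys)
      out[[length(out) + 1L]] <- findIdenticalTracts(x, fx, ya, min_tract)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(start = integer(0), end = integer(0),
                  run_length_bp = integer(0), n_diagnostic = integer(0),
                  p_value = numeric(0), polarized = logical(0),
                  focal_x = character(0), y_allele = character(0))
}
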
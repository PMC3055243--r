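## Windowed and whole-region per-site difference (p-distance) computation.
## Sites carrying a gap, N or any IUPAC ambiguity in a compared row are
## treated as missing. Window p-distances use pairwise deletion; tree
## matrices use complete deletion (every column with any missing state in
## any row is dropped for all pairs).

VALID_BASES <- c("A", "C", "G", "T")

## logical matrix: TRUE where the state is an unambiguous base
validMask <- function(m) {
  matrix(m %in% VALID_BASES, nrow = nrow(m), dimnames = dimnames(m))
}

#' Pairwise p-distance on a column interval
#'
#' p = mismatches / valid sites. Under \code{"pairwise"} deletion a column
#' is used when both compared rows carry an unambiguous base; under
#' \code{"complete"} deletion only columns where \emph{every} row of the
#' alignment carries an unambiguous base are used, so that all pairs of a
#' tree matrix share one column set.
#'
#' @param x a \linkS4class{GametologAlignment}
#' @param a,b taxon labels
#' @param start,end 0-based half-open column interval (defaults: whole
#'   alignment)
#' @param policy \code{"pairwise"} or \code{"complete"} deletion
#' @return list with \code{p} (NA when no valid site remains) and
#'   \code{valid_sites}
#' @export
pDistance <- function(x, a, b, start = 0L, end = alnLength(x),
                      policy = c("pairwise", "complete")) {
  policy <- match.arg(policy)
  checkInterval(start, end, alnLength(x))
  lab <- taxonTable(x)$label
  ia <- match(a, lab); ib <- match(b, lab)
  if (is.na(ia)) stop("unknown taxon: ", a)
  if (is.na(ib)) stop("unknown taxon: ", b)
  cols <- (start + 1L):end
  m <- seqMatrix(x)[, cols, drop = FALSE]
  v <- validMask(m)
  use <- if (policy == "pairwise") v[ia, ] & v[ib, ]
         else apply(v, 2, all)
  n <- sum(use)
  if (n == 0L) return(list(p = NA_real_, valid_sites = 0L))
  list(p = sum(m[ia, use] != m[ib, use]) / n, valid_sites = n)
}

#' Sliding/tiling window intervals over an alignment
#'
#' Full windows are \code{[k*step, k*step + width)}; a final partial window
#' is emitted iff it has at least \code{min_valid_sites} columns. The
#' usual parameterizations are width 500 / step 500 (tiling profiles),
#' width 2000 / step 1000 (2-kb windows with a 1-kb sliding overlap) and
#' width 500 / step 400 (500 bp with a 100-bp overlap):
#' step = width - overlap.
#'
#' @param length alignment length in columns
#' @param width window width (columns)
#' @param step step between window starts; defaults to \code{width}
#' @param min_valid_sites minimum columns for a trailing partial window;
#'   defaults to half the width
#' @return data.frame with 0-based half-open \code{start}, \code{end}
#' @export
iterWindows <- function(length, width, step = width,
                        min_valid_sites = ceiling(width / 2)) {
  stopifnot(width >= 1, step >= 1, step <= width,
            min_valid_sites <= width)
  if (length < min_valid_sites)
    return(data.frame(start = integer(0), end = integer(0)))
  starts <- integer(0)
  if (length >= width)
    starts <- seq.int(0L, length - width, by = step)
  ends <- starts + width
  s_part <- if (base::length(starts)) starts[base::length(starts)] + step else 0L
  if (s_part < length && (length - s_part) >= min_valid_sites) {
    starts <- c(starts, s_part)
    ends <- c(ends, length)
  }
  data.frame(start = as.integer(starts), end = as.integer(ends))
}

#' Windowed p-distance profile for one sequence pair
#'
#' The per-window uncorrected divergence track used to visualize low
#' p-distance (converted) segments against the stratum backdrop.
#'
#' @param x a \linkS4class{GametologAlignment}
#' @param a,b taxon labels
#' @param width,step,min_valid_sites window geometry, see
#'   \code{\link{iterWindows}}
#' @param policy deletion policy, see \code{\link{pDistance}}
#' @return data.frame with \code{start}, \code{end}, \code{p},
#'   \code{valid_sites}; \code{p} is NA where fewer than
#'   \code{min_valid_sites} unambiguous sites remain. The pair is attached
#'   as attribute \code{"pair"}.
#' @export
distanceProfile <- function(x, a, b, width = 500L, step = width,
                            min_valid_sites = ceiling(width / 2),
                            policy = "pairwise") {
  w <- iterWindows(alnLength(x), width, step, min_valid_sites)
  res <- lapply(seq_len(nrow(w)), function(i) {
    d <- pDistance(x, a, b, w$start[i], w$end[i], policy)
    c(p = d$p, valid_sites = d$valid_sites)
  })
  res <- do.call(rbind, res)
  out <- data.frame(start = w$start, end = w$end,
                    p = if (nrow(w)) res[, "p"] else numeric(0),
                    valid_sites = if (nrow(w))
                      as.integer(res[, "valid_sites"]) else integer(0))
  out$p[out$valid_sites < min_valid_sites] <- NA_real_
  attr(out, "pair") <- c(a, b)
  out
}

#' Complete-deletion p-distance matrix on an interval
#'
#' All pairs are computed on the shared set of columns where every row
#' carries an unambiguous base, the distance basis used for the
#' neighbor-joining trees.
#'
#' @param x a \linkS4class{GametologAlignment} (at least 3 rows)
#' @param start,end 0-based half-open interval (defaults: whole alignment)
#' @param min_valid_sites minimum shared columns; fewer is an error
#' @param policy \code{"complete"} (default) or \code{"pairwise"}
#' @return symmetric numeric matrix with taxon labels as dimnames and the
#'   number of shared columns as attribute \code{"sites_used"}
#' @export
distanceMatrix <- function(x, start = 0L, end = alnLength(x),
                           min_valid_sites = 50L,
                           policy = c("complete", "pairwise")) {
  policy <- match.arg(policy)
  if (nrow(seqMatrix(x)) < 3) stop("need at least 3 taxa for a matrix")
  checkInterval(start, end, alnLength(x))
  m <- seqMatrix(x)[, (start + 1L):end, drop = FALSE]
  lab <- taxonTable(x)$label
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(lab, lab))
  if (policy == "complete") {
    keep <- colSums(!validMask(m)) == 0L
    if (sum(keep) < min_valid_sites)
      stop("interval ", fmtInterval(start, end), " retains only ",
           sum(keep), " complete columns (< ", min_valid_sites, ")")
    mm <- m[, keep, drop = FALSE]
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- mean(mm[i, ] != mm[j, ])
    }
    attr(D, "sites_used") <- sum(keep)
  } else {
    v <- validMask(m)
    ns <- Inf
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      use <- v[i, ] & v[j, ]
      if (!any(use))
        stop("no valid sites for pair ", lab[i], " / ", lab[j],
             " in interval ", fmtInterval(start, end))
      D[i, j] <- D[j, i] <- sum(m[i, use] != m[j, use]) / sum(use)
      ns <- min(ns, sum(use))
    }
    attr(D, "sites_used") <- ns
  }
  D
}

## pair mismatch indicator matrix over complete columns: rows = pairs in
## combn order, columns = retained alignment columns. Shared by the
## bootstrap machinery (distance of a resample is a weighted row mean).
mismatchMatrix <- function(x, start, end) {
  m <- seqMatrix(x)[, (start + 1L):end, drop = FALSE]
  keep <- colSums(!validMask(m)) == 0L
  mm <- m[, keep, drop = FALSE]
  n <- nrow(mm)
  pr <- combn(n, 2)
  P <- matrix(0, ncol(pr), ncol(mm))
  for (k in seq_len(ncol(pr)))
    P[k, ] <- mm[pr[1, k], ] != mm[pr[2, k], ]
  list(P = P, pairs = pr, n = n, labels = taxonTable(x)$label,
       ncols = ncol(mm))
}

## rebuild a symmetric matrix from the pair vector in combn order
pairVecToMatrix <- function(dvec, pairs, n, labels) {
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (k in seq_len(ncol(pairs)))
    D[pairs[1, k], pairs[2, k]] <- D[pairs[2, k], pairs[1, k]] <- dvec[k]
  D
}
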
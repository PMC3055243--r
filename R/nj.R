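## Neighbor-joining (Saitou-Nei agglomeration on the Q-criterion) with a
## platform-independent tie-break, negative-branch clamping, and column
## bootstrap. Trees are returned as ape "phylo" objects; every internal
## node additionally carries the bitmask of the tips below it so that
## bipartition (split) bookkeeping is exact and cheap (n <= 30 taxa).

## canonical orientation of a split mask: the side containing tip 1
canonMask <- function(mask, full) {
  ifelse(bitwAnd(mask, 1L) == 1L, mask, bitwXor(full, mask))
}

popcount <- function(x) {
  n <- 0L
  while (any(x > 0L)) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

## Core agglomeration. Returns edges/lengths over node ids (tips 1..n,
## internals n+1..2n-2 in creation order, root last), the mask of every
## node id, and the total negative-length deficit clamped away.
njCore <- function(D, lengths = TRUE) {
  n <- nrow(D)
  if (n < 3) stop("need at least 3 taxa")
  if (anyNA(D)) stop("distance matrix contains missing entries")
  D <- (D + t(D)) / 2  # guard against last-bit asymmetries
  ids <- seq_len(n)
  reps <- seq_len(n)
  masks <- bitwShiftL(1L, 0:(n - 1))
  nodeMask <- c(masks, rep(NA_integer_, max(0L, n - 2L)))
  nextid <- n + 1L
  eP <- integer(0); eC <- integer(0); eL <- numeric(0)
  deficit <- 0
  clamp <- function(v) {
    if (lengths && v < 0) { deficit <<- deficit - v; 0 } else v
  }
  while (length(ids) > 3L) {
    m <- length(ids)
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    cand <- which(Q == min(Q), arr.ind = TRUE)
    ii <- pmin(cand[, 1], cand[, 2]); jj <- pmax(cand[, 1], cand[, 2])
    uniq <- !duplicated(cbind(ii, jj))
    ii <- ii[uniq]; jj <- jj[uniq]
    ## ties broken by the lexicographically smallest original-taxon pair
    k1 <- pmin(reps[ii], reps[jj])
    k2 <- pmax(reps[ii], reps[jj])
    sel <- order(k1, k2)[1]
    i <- ii[sel]; j <- jj[sel]
    dij <- D[i, j]
    vi <- 0.5 * dij + (R[i] - R[j]) / (2 * (m - 2))
    vj <- dij - vi
    newmask <- bitwOr(masks[i], masks[j])
    nodeMask[nextid] <- newmask
    eP <- c(eP, nextid, nextid)
    eC <- c(eC, ids[i], ids[j])
    eL <- c(eL, clamp(vi), clamp(vj))
    dnew <- 0.5 * (D[i, ] + D[j, ] - dij)
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    ids <- c(ids[keep], nextid)
    reps <- c(reps[keep], min(reps[i], reps[j]))
    masks <- c(masks[keep], newmask)
    nextid <- nextid + 1L
  }
  ## final three clusters meet at the root trifurcation
  root <- nextid
  nodeMask[root] <- bitwOr(bitwOr(masks[1], masks[2]), masks[3])
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  eP <- c(eP, root, root, root)
  eC <- c(eC, ids[1], ids[2], ids[3])
  eL <- c(eL, clamp(v1), clamp(v2), clamp(v3))
  list(parent = eP, child = eC, lengths = eL, root = root,
       nodeMask = nodeMask, n = n, deficit = deficit)
}

## Topology-only variant for bootstrap replicates: canonical split masks.
njMasks <- function(D) {
  n <- nrow(D)
  full <- as.integer(2^n - 1)
  core <- njCore(D, lengths = FALSE)
  ints <- (n + 1L):(core$root - 1L)
  if (core$root == n + 1L) return(integer(0))
  canonMask(core$nodeMask[ints], full)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Deterministic Saitou-Nei neighbor joining: ties in the Q-criterion are
#' broken by the lexicographically smallest pair of original taxon indices,
#' and negative estimated branch lengths are clamped to zero with the total
#' deficit recorded.
#'
#' @param D symmetric distance matrix with taxon labels as dimnames (e.g.
#'   from \code{\link{distanceMatrix}})
#' @return an unrooted ape \code{phylo} with attributes \code{"splits"}
#'   (data.frame of canonical bipartition bitmasks over the tip order,
#'   one per internal edge, with \code{support = NA}), \code{"deficit"}
#'   (clamped negative length mass) and \code{"tipOrder"} (labels indexing
#'   the mask bits)
#' @export
njTree <- function(D) {
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(D)))
  core <- njCore(D, lengths = TRUE)
  n <- core$n
  full <- as.integer(2^n - 1)
  ## renumber internals so the root is n+1 (ape convention); creation is
  ## child-before-parent, so reversing gives parent-before-child numbers
  remap <- function(id) ifelse(id <= n, id, 3L * n - 1L - id)
  edge <- cbind(remap(core$parent), remap(core$child))
  nint <- n - 2L
  tr <- structure(list(edge = edge, edge.length = core$lengths,
                       tip.label = labels, Nnode = nint),
                  class = "phylo", order = NULL)
  tr <- ape::reorder.phylo(tr, "cladewise")
  intIds <- (n + 1L):(2L * n - 2L)
  masks <- core$nodeMask[3L * n - 1L - intIds]  # mask per new node number
  splitMasks <- canonMask(masks[-1L], full)      # drop root (no edge)
  attr(tr, "splits") <- data.frame(mask = splitMasks,
                                   support = rep(NA_real_,
                                                 length(splitMasks)))
  attr(tr, "nodeMask") <- canonMask(masks, full)
  attr(tr, "deficit") <- core$deficit
  attr(tr, "tipOrder") <- labels
  tr
}

#' Neighbor-joining tree with column-bootstrap supports
#'
#' Builds the point-estimate tree from the complete-deletion p-distance
#' matrix of the interval, then resamples the retained columns with
#' replacement \code{reps} times; the support of an internal edge is the
#' percentage of replicate trees containing its bipartition.
#'
#' @param x a \linkS4class{GametologAlignment}
#' @param start,end 0-based half-open column interval
#' @param reps bootstrap replicates (1000 is the conventional choice for
#'   reported trees; 500 is also common)
#' @param seed RNG seed for reproducible resampling
#' @param min_valid_sites minimum complete columns; fewer is an error
#' @return the point tree (see \code{\link{njTree}}) whose \code{"splits"}
#'   attribute carries supports in [0, 100] and whose \code{node.label}
#'   holds the support of the edge above each internal node; attribute
#'   \code{"taxa"} carries the taxon table.
#' @export
bootstrapTree <- function(x, start = 0L, end = alnLength(x), reps = 1000L,
                          seed = NULL, min_valid_sites = 50L) {
  stopifnot(reps >= 1)
  checkInterval(start, end, alnLength(x))
  mm <- mismatchMatrix(x, start, end)
  if (mm$ncols < min_valid_sites)
    stop("interval ", fmtInterval(start, end), " retains only ",
         mm$ncols, " complete columns (< ", min_valid_sites, ")")
  d0 <- rowMeans(mm$P)
  D0 <- pairVecToMatrix(d0, mm$pairs, mm$n, mm$labels)
  tr <- njTree(D0)
  n <- mm$n
  L <- mm$ncols
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(0, L, reps)
  for (r in seq_len(reps))
    W[, r] <- tabulate(sample.int(L, L, replace = TRUE), L)
  Dboot <- (mm$P %*% W) / L
  counts <- new.env(hash = TRUE)
  for (r in seq_len(reps)) {
    for (mk in njMasks(pairVecToMatrix(Dboot[, r], mm$pairs, n,
                                       mm$labels))) {
      key <- as.character(mk)
      assign(key, get0(key, envir = counts, ifnotfound = 0L) + 1L,
             envir = counts)
    }
  }
  sp <- attr(tr, "splits")
  sp$support <- vapply(sp$mask, function(mk) {
    100 * get0(as.character(mk), envir = counts, ifnotfound = 0L) / reps
  }, numeric(1))
  attr(tr, "splits") <- sp
  nodeMask <- attr(tr, "nodeMask")
  tr$node.label <- vapply(seq_along(nodeMask), function(i) {
    if (i == 1L) return(NA_real_)  # root trifurcation: no parent edge
    sp$support[match(nodeMask[i], sp$mask)]
  }, numeric(1))
  attr(tr, "taxa") <- taxonTable(x)
  attr(tr, "sites_used") <- L
  tr
}

## ---- exhaustive least-squares topology oracle --------------------------

#' Enumerate all unrooted binary topologies on n taxa
#'
#' Stepwise-addition enumeration: each topology is an edge matrix over
#' node numbers (tips 1..n, internals n+1..2n-2). There are (2n-5)!!
#' topologies; practical for n <= 8.
#'
#' @param n number of taxa (>= 3)
#' @return list of integer edge matrices (parent, child columns are
#'   arbitrary orientations)
#' @export
enumerateTopologies <- function(n) {
  stopifnot(n >= 3, n <= 8)
  base <- cbind(rep(n + 1L, 3L), 1:3)
  tops <- list(base)
  if (n == 3) return(tops)
  for (t in 4:n) {
    newtops <- list()
    inode <- n + t - 2L  # next internal node id after adding tip t
    for (tp in tops) {
      for (e in seq_len(nrow(tp))) {
        nt <- rbind(tp[-e, , drop = FALSE],
                    c(tp[e, 1], inode),
                    c(inode, tp[e, 2]),
                    c(inode, t))
        newtops[[length(newtops) + 1L]] <- nt
      }
    }
    tops <- newtops
  }
  tops
}

## split masks (canonical) of an edge-matrix topology
edgeMatrixSplits <- function(edges, n) {
  full <- as.integer(2^n - 1)
  nn <- max(edges)
  adj <- vector("list", nn)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  tipsBelow <- function(a, b) {  # tips on b's side of edge (a,b)
    seen <- b; stack <- b
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (w in adj[[v]]) if (w != a && !(w %in% seen)) {
        seen <- c(seen, w); stack <- c(stack, w)
      }
    }
    seen[seen <= n]
  }
  res <- integer(0)
  for (k in seq_len(nrow(edges))) {
    if (edges[k, 1] > n && edges[k, 2] > n) {
      tips <- tipsBelow(edges[k, 1], edges[k, 2])
      res <- c(res, canonMask(as.integer(sum(2^(tips - 1))), full))
    }
  }
  sort(res)
}

#' Exhaustive least-squares search for the best-fitting topology
#'
#' Independent brute-force oracle: enumerates every unrooted topology,
#' fits branch lengths by ordinary least squares to the distance matrix,
#' and returns the topology with minimal residual sum of squares. On an
#' additive matrix the fit of the generating topology is exact (RSS 0).
#'
#' @param D symmetric distance matrix (4-8 taxa)
#' @return list with \code{splits} (canonical bipartition masks, sorted)
#'   and \code{rss} of the best topology
#' @export
lsTopologySearch <- function(D) {
  n <- nrow(D)
  pr <- combn(n, 2)
  dvec <- D[t(pr)]
  best <- NULL; bestRss <- Inf
  for (edges in enumerateTopologies(n)) {
    nn <- max(edges)
    ## incidence of pair paths over edges
    adj <- vector("list", nn)
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1]; b <- edges[k, 2]
      adj[[a]] <- c(adj[[a]], list(c(b, k)))
      adj[[b]] <- c(adj[[b]], list(c(a, k)))
    }
    pathEdges <- function(i, j) {
      prev <- rep(0L, nn); prevE <- rep(0L, nn)
      stack <- i; prev[i] <- i
      while (length(stack)) {
        v <- stack[length(stack)]; stack <- stack[-length(stack)]
        if (v == j) break
        for (we in adj[[v]]) {
          w <- we[1]
          if (prev[w] == 0L) {
            prev[w] <- v; prevE[w] <- we[2]; stack <- c(stack, w)
          }
        }
      }
      out <- integer(0); v <- j
      while (v != i) { out <- c(out, prevE[v]); v <- prev[v] }
      out
    }
    A <- matrix(0, ncol(pr), nrow(edges))
    for (k in seq_len(ncol(pr)))
      A[k, pathEdges(pr[1, k], pr[2, k])] <- 1
    fit <- tryCatch(solve(crossprod(A), crossprod(A, dvec)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum((A %*% fit - dvec)^2)
    if (rss < bestRss - 1e-12) {
      bestRss <- rss
      best <- edgeMatrixSplits(edges, n)
    }
  }
  list(splits = best, rss = bestRss)
}

#' Random additive distance matrix from a random unrooted tree
#'
#' Draws a uniform random unrooted binary topology by random stepwise
#' addition, assigns uniform branch lengths on a p-distance-like scale,
#' and returns the exact path-length (additive) matrix together with the
#' generating splits.
#'
#' @param n number of taxa
#' @param lmin,lmax branch-length range
#' @return list with \code{D} (labelled matrix, taxa t1..tn) and
#'   \code{splits} (canonical masks of the generating topology)
#' @export
simulateAdditiveMatrix <- function(n, lmin = 0.005, lmax = 0.08) {
  edges <- cbind(rep(n + 1L, 3L), 1:3)
  if (n > 3) for (t in 4:n) {
    e <- sample.int(nrow(edges), 1L)
    inode <- n + t - 2L
    edges <- rbind(edges[-e, , drop = FALSE],
                   c(edges[e, 1], inode),
                   c(inode, edges[e, 2]),
                   c(inode, t))
  }
  len <- runif(nrow(edges), lmin, lmax)
  nn <- max(edges)
  adj <- vector("list", nn)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], list(c(b, k)))
    adj[[b]] <- c(adj[[b]], list(c(a, k)))
  }
  D <- matrix(0, n, n, dimnames = list(paste0("t", 1:n), paste0("t", 1:n)))
  for (i in seq_len(n)) {
    dist <- rep(NA_real_, nn); dist[i] <- 0; stack <- i
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (we in adj[[v]]) {
        w <- we[1]
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + len[we[2]]; stack <- c(stack, w)
        }
      }
    }
    D[i, ] <- dist[seq_len(n)]
  }
  list(D = D, splits = edgeMatrixSplits(edges, n))
}

#' Canonical splits of a tree built by njTree/bootstrapTree
#' @param tree a tree carrying the \code{"splits"} attribute
#' @return sorted integer vector of canonical bipartition masks
#' @export
treeSplits <- function(tree) sort(attr(tree, "splits")$mask)
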
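#' @import methods
#' @importFrom stats rexp runif rpois setNames
#' @importFrom utils combn write.table
NULL

#' GametologAlignment: a labelled multiple sequence alignment of gametologs
#'
#' Holds an equal-length nucleotide alignment together with a parsed taxon
#' table assigning each row to a species, a chromosome (X, Y, or U for
#' unknown/outgroup) and an allele identifier. All column coordinates used
#' by the package are 0-based half-open on this object; human-readable
#' reports print 1-based inclusive positions.
#'
#' @slot seqs character matrix (rows = sequences, columns = alignment
#'   columns) over the uppercase IUPAC alphabet plus \code{-} and \code{N}.
#' @slot taxa data.frame with columns \code{label}, \code{species},
#'   \code{chromosome} (one of X/Y/U) and \code{allele}, one row per
#'   alignment row, in row order.
#' @export
setClass("GametologAlignment",
  representation(seqs = "matrix", taxa = "data.frame"))

setValidity("GametologAlignment", function(object) {
  msg <- character(0)
  if (!is.character(object@seqs))
    msg <- c(msg, "seqs must be a character matrix")
  if (nrow(object@seqs) < 2)
    msg <- c(msg, "an alignment needs at least 2 rows")
  need <- c("label", "species", "chromosome", "allele")
  if (!all(need %in% names(object@taxa)))
    msg <- c(msg, paste("taxa must have columns:", paste(need, collapse = ", ")))
  else {
    if (nrow(object@taxa) != nrow(object@seqs))
      msg <- c(msg, "taxa table and alignment disagree on row count")
    if (anyDuplicated(object@taxa$label))
      msg <- c(msg, paste("duplicate taxon label:",
                          object@taxa$label[duplicated(object@taxa$label)][1]))
    if (!all(object@taxa$chromosome %in% c("X", "Y", "U")))
      msg <- c(msg, "chromosome must be one of X, Y, U")
    if (any(!nzchar(object@taxa$species)))
      msg <- c(msg, "species codes must be non-empty")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GametologAlignment
#'
#' @param seqs named character vector of equal-length sequence strings, or a
#'   character matrix of single characters with rownames.
#' @param taxa optional taxon table (label/species/chromosome/allele). When
#'   omitted, labels are parsed with \code{\link{parseTaxonLabel}}.
#' @param template taxon-label template passed to
#'   \code{\link{parseTaxonLabel}} when \code{taxa} is missing.
#' @return a \linkS4class{GametologAlignment}
#' @export
GametologAlignment <- function(seqs, taxa = NULL,
                               template = "{species}_{allele}_{chrom}") {
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    if (is.null(names(seqs)))
      stop("sequences must be named")
    w <- nchar(seqs)
    if (length(unique(w)) != 1L)
      stop("ragged alignment: record '", names(seqs)[which(w != w[1])[1]],
           "' has length ", w[which(w != w[1])[1]], ", expected ", w[1])
    m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(m) <- names(seqs)
  }
  m[] <- toupper(m)
  if (is.null(taxa)) {
    taxa <- do.call(rbind, lapply(rownames(m), function(nm) {
      tl <- parseTaxonLabel(nm, template)
      data.frame(label = nm, species = tl$species,
                 chromosome = tl$chromosome, allele = tl$allele,
                 stringsAsFactors = FALSE)
    }))
  }
  new("GametologAlignment", seqs = m, taxa = taxa)
}

#' SimTruth: ledger of what the simulator actually did
#'
#' @slot events data.frame of realized conversion events (lineage, time_myr,
#'   start, end, direction), 0-based half-open intervals.
#' @slot substitutions data.frame of realized substitution counts per branch
#'   segment and chromosome.
#' @slot config the simulation configuration (list) that produced them.
#' @export
setClass("SimTruth",
  representation(events = "data.frame", substitutions = "data.frame",
                 config = "list"))

setMethod("show", "GametologAlignment", function(object) {
  cat("GametologAlignment:", nrow(object@seqs), "sequences x",
      ncol(object@seqs), "columns\n")
  tb <- table(object@taxa$species, object@taxa$chromosome)
  cat("  species:", paste(rownames(tb), collapse = ", "), "\n")
  nx <- sum(object@taxa$chromosome == "X")
  ny <- sum(object@taxa$chromosome == "Y")
  nu <- sum(object@taxa$chromosome == "U")
  cat("  rows: ", nx, " X, ", ny, " Y, ", nu, " unassigned\n", sep = "")
  invisible(NULL)
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", nrow(object@events), "planted conversion event(s)\n")
  if (nrow(object@events)) print(object@events)
  invisible(NULL)
})
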
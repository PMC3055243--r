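#' Number of alignment columns
#' @param x a \linkS4class{GametologAlignment}
#' @return integer column count
#' @export
setGeneric("alnLength", function(x) standardGeneric("alnLength"))

#' Taxon table accessor
#' @param x a \linkS4class{GametologAlignment}
#' @return data.frame with label/species/chromosome/allele
#' @export
setGeneric("taxonTable", function(x) standardGeneric("taxonTable"))

#' Sequence matrix accessor
#' @param x a \linkS4class{GametologAlignment}
#' @return character matrix of single characters
#' @export
setGeneric("seqMatrix", function(x) standardGeneric("seqMatrix"))

#' Planted-event ledger accessor
#' @param x a \linkS4class{SimTruth}
#' @return data.frame of realized conversion events
#' @export
setGeneric("truthEvents", function(x) standardGeneric("truthEvents"))

#' @rdname alnLength
#' @export
setMethod("alnLength", "GametologAlignment", function(x) ncol(x@seqs))

#' @rdname taxonTable
#' @export
setMethod("taxonTable", "GametologAlignment", function(x) x@taxa)

#' @rdname seqMatrix
#' @export
setMethod("seqMatrix", "GametologAlignment", function(x) x@seqs)

#' @rdname truthEvents
#' @export
setMethod("truthEvents", "SimTruth", function(x) x@events)

#' Extract rows (taxa) and an optional column range from an alignment
#'
#' Row indices follow usual R conventions (index, logical or label). Columns
#' are selected with the package's 0-based half-open convention via
#' \code{\link{cropAlignment}}; \code{[} takes 1-based column indices like
#' any R matrix.
#'
#' @param x a \linkS4class{GametologAlignment}
#' @param i row selector (indices, logicals or labels)
#' @param j 1-based column indices (optional)
#' @param ... ignored
#' @param drop ignored
#' @return a \linkS4class{GametologAlignment}
#' @export
setMethod("[", "GametologAlignment", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@seqs))
  if (is.character(i)) i <- match(i, x@taxa$label)
  if (anyNA(i)) stop("unknown taxon in selection")
  s <- x@seqs[i, , drop = FALSE]
  if (!missing(j)) s <- s[, j, drop = FALSE]
  new("GametologAlignment", seqs = s,
      taxa = x@taxa[i, , drop = FALSE])
})

#' Crop an alignment to a 0-based half-open column interval
#'
#' @param x a \linkS4class{GametologAlignment}
#' @param start,end 0-based half-open column interval
#' @return a \linkS4class{GametologAlignment} with \code{end - start} columns
#' @export
cropAlignment <- function(x, start, end) {
  checkInterval(start, end, alnLength(x))
  new("GametologAlignment",
      seqs = x@seqs[, (start + 1L):end, drop = FALSE], taxa = x@taxa)
}
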
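## Alignment / tree IO and the shared coordinate convention.
## All intervals are 0-based half-open internally and in BED output;
## human-readable reports print 1-based inclusive.

#' Validate a 0-based half-open column interval
#' @param start,end interval bounds
#' @param len alignment length (columns)
#' @return invisibly TRUE; errors otherwise
#' @keywords internal
checkInterval <- function(start, end, len) {
  if (!(start >= 0 && start < end && end <= len))
    stop("invalid interval [", start, ", ", end, ") for length ", len)
  invisible(TRUE)
}

## 1-based inclusive rendering for reports
fmtInterval <- function(start, end) sprintf("%d-%d", start + 1L, end)

#' Parse a sequence name into species / chromosome / allele
#'
#' The default template \code{"{species}_{allele}_{chrom}"} treats the last
#' underscore-delimited token as the chromosome (X or Y, case-insensitive),
#' the first as the species code and anything in between as the allele
#' identifier; an empty allele is permitted (\code{"human_X"}). Names whose
#' final token is not X/Y are assigned chromosome \code{U} (unknown) with a
#' warning, which is how outgroup sequences without a gametolog partner
#' (e.g. a New World monkey X-only sequence named \code{"nwm_KAL"}) enter
#' the analysis.
#'
#' @param name sequence name
#' @param template label template; placeholders \code{{species}},
#'   \code{{allele}}, \code{{chrom}} separated by literal text. Only
#'   underscore-separated templates are supported.
#' @return list with \code{species}, \code{chromosome}, \code{allele}
#' @examples
#' parseTaxonLabel("gibbon_2845F_X")
#' parseTaxonLabel("human_X")
#' @export
parseTaxonLabel <- function(name, template = "{species}_{allele}_{chrom}") {
  ord <- regmatches(template,
                    gregexpr("\\{(species|allele|chrom)\\}", template))[[1]]
  ord <- gsub("[{}]", "", ord)
  parts <- strsplit(name, "_", fixed = TRUE)[[1]]
  last <- parts[length(parts)]
  if (length(parts) >= 2 && toupper(last) %in% c("X", "Y")) {
    if (identical(ord, c("species", "allele", "chrom")) ||
        identical(ord, c("species", "chrom"))) {
      species <- parts[1]
      allele <- if (length(parts) > 2)
        paste(parts[-c(1, length(parts))], collapse = "_") else ""
    } else if (identical(ord, c("chrom", "species", "allele")) ||
               identical(ord, c("chrom", "species"))) {
      ## chromosome-first template: "{chrom}_{species}_{allele}"
      first <- parts[1]
      if (toupper(first) %in% c("X", "Y"))
        return(list(species = parts[2], chromosome = toupper(first),
                    allele = if (length(parts) > 2)
                      paste(parts[-(1:2)], collapse = "_") else ""))
      species <- parts[1]
      allele <- paste(parts[-c(1, length(parts))], collapse = "_")
    } else {
      species <- parts[1]
      allele <- if (length(parts) > 2)
        paste(parts[-c(1, length(parts))], collapse = "_") else ""
    }
    return(list(species = species, chromosome = toupper(last),
                allele = allele))
  }
  warning("cannot infer chromosome from '", name,
          "': assigning chromosome U")
  list(species = parts[1], chromosome = "U",
       allele = if (length(parts) > 1)
         paste(parts[-1], collapse = "_") else "")
}

#' Format a taxon label (inverse of parseTaxonLabel)
#' @param species,allele,chrom label components; empty allele is collapsed
#' @return character label
#' @export
formatTaxonLabel <- function(species, allele, chrom) {
  ifelse(nzchar(allele), paste(species, allele, chrom, sep = "_"),
         ifelse(chrom == "U", species, paste(species, chrom, sep = "_")))
}

#' Read a multiple sequence alignment
#'
#' FASTA is read with Biostrings, CLUSTAL (.aln) with ape. Sequences are
#' uppercased; gaps (\code{-}), \code{N} and IUPAC ambiguity codes are
#' retained and treated as missing by all distance computations.
#'
#' @param path file path
#' @param format \code{"fasta"} or \code{"clustal"}
#' @param template taxon-label template, see \code{\link{parseTaxonLabel}}
#' @return a \linkS4class{GametologAlignment}
#' @export
readAlignment <- function(path, format = c("fasta", "clustal"),
                          template = "{species}_{allele}_{chrom}") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    v <- setNames(toupper(as.character(ss)), names(ss))
    w <- nchar(v)
    if (length(unique(w)) != 1L)
      stop("ragged alignment in ", path, ": record '",
           names(v)[which(w != w[1])[1]], "' has length ",
           w[which(w != w[1])[1]], ", expected ", w[1])
    GametologAlignment(v, template = template)
  } else {
    m <- ape::read.dna(path, format = "clustal", as.character = TRUE)
    m[] <- toupper(m)   # in place: keeps the matrix shape
    GametologAlignment(m, template = template)
  }
}

#' Write an alignment as FASTA
#' @param x a \linkS4class{GametologAlignment}
#' @param path output file
#' @return invisibly \code{path}
#' @export
writeAlignment <- function(x, path) {
  v <- apply(seqMatrix(x), 1, paste, collapse = "")
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(setNames(v, taxonTable(x)$label)), path)
  invisible(path)
}

#' Read a time-calibrated species tree
#'
#' Reads a Newick tree whose branch lengths are in millions of years and
#' checks it is ultrametric within tolerance (all root-to-tip depths equal),
#' as required for fossil-calibrated dating.
#'
#' @param path file path, or a Newick string (detected by a terminal
#'   semicolon)
#' @param tol maximal allowed relative spread of root-to-tip depths
#' @return an ape \code{phylo}, with node ages (myr before present)
#'   attached as attribute \code{"ages"} (indexed by node number)
#' @export
readSpeciesTree <- function(path, tol = 0.01) {
  tr <- if (grepl(";\\s*$", path)) ape::read.tree(text = path)
        else ape::read.tree(path)
  if (is.null(tr)) stop("could not parse species tree")
  if (length(tr$tip.label) < 2)
    stop("species tree needs at least 2 tips")
  if (is.null(tr$edge.length))
    stop("species tree must have branch lengths (myr)")
  depth <- ape::node.depth.edgelength(tr)
  tipd <- depth[seq_along(tr$tip.label)]
  if ((max(tipd) - min(tipd)) > tol * max(tipd))
    stop("species tree is not ultrametric (root-to-tip depths range ",
         signif(min(tipd), 4), " to ", signif(max(tipd), 4), " myr)")
  attr(tr, "ages") <- max(tipd) - depth
  tr
}

#' Node ages (myr) of a species tree
#' @param tree result of \code{\link{readSpeciesTree}} (or any ultrametric
#'   \code{phylo})
#' @return numeric vector of ages indexed by node number
#' @export
nodeAges <- function(tree) {
  a <- attr(tree, "ages")
  if (is.null(a)) {
    depth <- ape::node.depth.edgelength(tree)
    a <- max(depth[seq_along(tree$tip.label)]) - depth
  }
  a
}

#' Descendant species of every branch of a species tree
#'
#' Each branch is identified by the set of species descending from it (the
#' child node's clade). Returned in node-number order.
#'
#' @param tree a \code{phylo}
#' @return named list: element \code{i} is the species set under node
#'   \code{i}
#' @keywords internal
branchDescendants <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  desc <- vector("list", nn)
  for (i in seq_len(n)) desc[[i]] <- tree$tip.label[i]
  ## postorder so children resolve before parents
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(ord))) {
    p <- ord[k, 1]; ch <- ord[k, 2]
    desc[[p]] <- sort(unique(c(desc[[p]], desc[[ch]])))
  }
  desc
}

#' Write a per-window table as TSV
#' @param df data.frame
#' @param path output file
#' @return invisibly \code{path}
#' @export
writeTSV <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write intervals as BED (0-based half-open)
#' @param df data.frame with columns start, end and optionally name, score,
#'   strand
#' @param path output file
#' @param chrom chromosome/region name for column 1
#' @return invisibly \code{path}
#' @export
writeBED <- function(df, path, chrom = "aln") {
  bed <- data.frame(chrom = chrom, start = df$start, end = df$end,
                    name = if ("name" %in% names(df)) df$name else ".",
                    score = if ("score" %in% names(df)) df$score else 0,
                    strand = ".")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a distance profile as bedGraph
#' @param profile a profile data.frame from \code{\link{distanceProfile}}
#' @param path output file
#' @param chrom region name for column 1
#' @return invisibly \code{path}
#' @export
writeBedGraph <- function(profile, path, chrom = "aln") {
  ok <- !is.na(profile$p)
  write.table(data.frame(chrom, profile$start[ok], profile$end[ok],
                         profile$p[ok]),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
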
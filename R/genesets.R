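#' Construct a gene set collection
#'
#' @param sets Named list of character vectors of gene identifiers. Names must
#'   be unique and every set non-empty; duplicate genes within a set are
#'   dropped.
#' @param descriptions Optional character vector of per-set descriptions
#'   (recycled empty string if omitted).
#' @return An object of class `"gene_sets"`: a named list of unique gene-id
#'   vectors with a `descriptions` attribute.
#' @export
gene_sets <- function(sets, descriptions = NULL) {
  if (!is.list(sets))
    stop("'sets' must be a named list")
  if (length(sets) == 0)
    return(structure(list(), descriptions = character(0),
                     class = "gene_sets"))
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("'sets' must be a named list")
  if (anyDuplicated(names(sets)))
    stop("duplicate set name: ",
         names(sets)[duplicated(names(sets))][1])
  if (any(lengths(sets) == 0))
    stop("empty gene set: ", names(sets)[lengths(sets) == 0][1])
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  names(descriptions) <- names(sets)
  structure(sets, descriptions = descriptions, class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  if (!length(x)) cat("gene_sets: empty collection\n")
  else cat(sprintf("gene_sets: %d sets, sizes %d-%d\n", length(x),
                   min(lengths(x)), max(lengths(x))))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, then one gene id per remaining field. Genes listed
#' more than once in a set are deduplicated; a line with no genes or a
#' repeated set name is an error. Genes absent from any expression matrix are
#' retained here — intersection with the measured universe happens at scoring
#' time.
#'
#' @param path Path to a GMT file.
#' @return A [gene_sets()] collection.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(fields, `[`, character(1), 1)
  bad <- which(lengths(fields) < 3)
  if (length(bad))
    stop("GMT line ", bad[1], " ('", nm[bad[1]], "') lists no genes")
  if (anyDuplicated(nm))
    stop("duplicate set name in GMT: ", nm[duplicated(nm)][1])
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  gene_sets(sets, vapply(fields, `[`, character(1), 2))
}

#' Write a gene set collection to GMT
#'
#' @param sets A [gene_sets()] collection.
#' @param path Output path.
#' @return Invisibly, `sets`.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_sets"))
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(sets)
}
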
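#' Construct a promoter sequence set
#'
#' A named collection of upstream (promoter) nucleotide sequences, one per
#' gene. Sequences are upper-cased and must use the A/C/G/T/N alphabet.
#'
#' @param seqs Named character vector of sequences (names are gene ids).
#' @return An object of class `"promoter_set"` (a named character vector).
#' @export
promoter_set <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("promoter sequences must be named by gene id")
  if (anyDuplicated(names(seqs)))
    stop("duplicate gene id in promoter set: ",
         names(seqs)[duplicated(names(seqs))][1])
  nm <- names(seqs)
  seqs <- toupper(as.character(seqs))   # toupper drops names
  names(seqs) <- nm
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("sequence for '", names(seqs)[bad][1],
         "' contains characters outside A/C/G/T/N")
  structure(seqs, class = "promoter_set")
}

#' @export
print.promoter_set <- function(x, ...) {
  cat(sprintf("promoter_set: %d sequences, lengths %d-%d\n",
              length(x), min(nchar(x)), max(nchar(x))))
  invisible(x)
}

#' Read promoter sequences from FASTA
#'
#' @param path Path to a FASTA file of promoter sequences, one record per
#'   gene; the first whitespace-delimited token of each header is the gene id.
#' @return A [promoter_set()].
#' @export
read_promoters <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1)
  promoter_set(stats::setNames(as.character(ss), ids))
}

#' Write promoter sequences to FASTA
#'
#' @param x A [promoter_set()].
#' @param path Output path.
#' @return Invisibly, `x`.
#' @export
write_promoters <- function(x, path) {
  stopifnot(inherits(x, "promoter_set"))
  ss <- Biostrings::DNAStringSet(unclass(x))
  Biostrings::writeXStringSet(ss, path)
  invisible(x)
}
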
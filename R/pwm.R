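DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' Converts a 4 x L count (or frequency) block into column-normalized base
#' frequencies after adding a pseudocount to every cell, the form consumed by
#' the promoter scanner.
#'
#' @param counts Numeric 4 x L matrix; rows A, C, G, T (row names optional but
#'   if present must be a permutation of A,C,G,T), columns are motif
#'   positions. Negative entries are an error.
#' @param motif_id Identifier for the motif.
#' @param pseudocount Non-negative value added to every cell before each
#'   column is normalized to sum to one (default 0.01).
#' @return An object of class `"pwm"`: list with `id`, `freq` (4 x L frequency
#'   matrix, rows A,C,G,T, columns summing to 1) and `pseudocount`.
#' @export
pwm <- function(counts, motif_id = "motif", pseudocount = 0.01) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4)
    stop("PWM needs exactly 4 base rows (A, C, G, T)")
  if (ncol(counts) < 4)
    stop("PWM '", motif_id, "' has length ", ncol(counts), "; minimum is 4")
  if (any(counts < 0)) stop("negative counts in PWM '", motif_id, "'")
  if (anyNA(counts)) stop("missing counts in PWM '", motif_id, "'")
  if (!is.null(rownames(counts))) {
    if (!setequal(rownames(counts), DNA_BASES))
      stop("PWM row names must be A, C, G, T")
    counts <- counts[DNA_BASES, , drop = FALSE]
  } else rownames(counts) <- DNA_BASES
  counts <- counts + pseudocount
  freq <- sweep(counts, 2, colSums(counts), "/")
  structure(list(id = motif_id, freq = freq, pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': length %d, pseudocount %g\n",
              x$id, ncol(x$freq), x$pseudocount))
  invisible(x)
}

#' @export
length.pwm <- function(x) ncol(x$freq)

#' Reverse complement of a PWM
#'
#' Reverses the position order and swaps complementary base rows, so that
#' scanning the forward strand with the result is equivalent to scanning the
#' reverse strand with the original.
#'
#' @param x A [pwm()] object.
#' @return A `"pwm"` object.
#' @export
reverse_complement_pwm <- function(x) {
  stopifnot(inherits(x, "pwm"))
  f <- x$freq[c("T", "G", "C", "A"), rev(seq_len(ncol(x$freq))), drop = FALSE]
  rownames(f) <- DNA_BASES
  structure(list(id = x$id, freq = f, pseudocount = x$pseudocount),
            class = "pwm")
}

#' Read position frequency matrices in JASPAR text format
#'
#' Accepts the JASPAR PFM dialect: records start with `>motif_id`, followed by
#' four rows of counts, either bare numbers or the bracketed form
#' `A [ 1 2 3 ]`. Rows are taken in A, C, G, T order (explicit base letters,
#' when present, override the order). Counts are converted to frequencies per
#' [pwm()].
#'
#' @param path Path to a JASPAR PFM file (one or more records).
#' @param pseudocount Passed to [pwm()].
#' @return A list of `"pwm"` objects, named by motif id.
#' @export
read_jaspar <- function(path, pseudocount = 0.01) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no '>' record headers found in ", path)
  ends <- c(starts[-1] - 1, length(lines))
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[k]])
    id <- strsplit(hdr, "\\s+")[[1]][1]
    body <- lines[(starts[k] + 1):ends[k]]
    if (length(body) != 4)
      stop("record '", id, "' has ", length(body), " count rows; expected 4")
    rows <- lapply(body, parse_jaspar_row)
    bases <- vapply(rows, function(r) r$base, character(1))
    counts <- lapply(rows, function(r) r$counts)
    lens <- lengths(counts)
    if (length(unique(lens)) != 1)
      stop("record '", id, "' has rows of unequal length")
    m <- do.call(rbind, counts)
    rownames(m) <- if (all(bases %in% DNA_BASES) && !anyDuplicated(bases))
      bases else DNA_BASES
    out[[k]] <- pwm(m, motif_id = id, pseudocount = pseudocount)
  }
  names(out) <- vapply(out, function(p) p$id, character(1))
  out
}

#' Write position weight matrices in JASPAR text format
#'
#' Emits one `>motif_id` record per matrix with bracketed base rows. The
#' stored column-normalized frequencies are written as the counts, so
#' `read_jaspar(path, pseudocount = 0)` recovers the matrices exactly.
#'
#' @param pwms A `"pwm"` object or list of them.
#' @param path Output path.
#' @return Invisibly, `pwms`.
#' @export
write_jaspar <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  lines <- unlist(lapply(pwms, function(p) {
    stopifnot(inherits(p, "pwm"))
    c(paste0(">", p$id),
      vapply(DNA_BASES, function(b)
        sprintf("%s [ %s ]", b,
                paste(format(p$freq[b, ], digits = 17), collapse = " ")),
        character(1)))
  }))
  writeLines(lines, path)
  invisible(pwms)
}

parse_jaspar_row <- function(line) {
  base <- NA_character_
  if (grepl("^[ACGTacgt]\\b", line)) {
    base <- toupper(substr(line, 1, 1))
    line <- sub("^[ACGTacgt]", "", line)
  }
  line <- gsub("[][]", " ", line)
  toks <- strsplit(trimws(line), "\\s+")[[1]]
  counts <- suppressWarnings(as.numeric(toks))
  if (anyNA(counts)) stop("non-numeric count in PFM row: ", line)
  if (any(counts < 0)) stop("negative count in PFM row: ", line)
  list(base = base, counts = counts)
}
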
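#' Construct an expression matrix with tissue labels
#'
#' Bundles a numeric genes x samples matrix of log2-scale normalized
#' intensities with a sample-to-tissue assignment. This is the input container
#' for all scoring functions in the package.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row names
#'   are gene identifiers and column names are sample identifiers; both must
#'   be present and unique. Values are assumed to be on the log2 scale (e.g.
#'   RMA output), so a fold change of `c` corresponds to a difference of
#'   `log2(c)`.
#' @param tissues Character vector of tissue labels, one per sample. Either
#'   named by sample id or in column order of `values`. At least two distinct
#'   tissues are required and every tissue must have at least two replicate
#'   samples.
#'
#' @return An object of class `"expr_matrix"`: a list with elements `values`
#'   (the matrix) and `tissue` (named character vector of labels, in column
#'   order).
#' @export
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' expression_matrix(m, c("brain", "brain", "lung", "lung"))
expression_matrix <- function(values, tissues) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers in 'values' (collapse probes first)")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers in 'values'")
  if (anyNA(values))
    stop("missing values in expression matrix")
  nm <- names(tissues)
  tissues <- as.character(tissues)   # as.character drops names
  names(tissues) <- nm
  if (!is.null(names(tissues))) {
    missing <- setdiff(colnames(values), names(tissues))
    if (length(missing))
      stop("no tissue label for sample(s): ", paste(missing, collapse = ", "))
    tissues <- tissues[colnames(values)]
  } else {
    if (length(tissues) != ncol(values))
      stop("'tissues' must have one label per sample")
    names(tissues) <- colnames(values)
  }
  if (anyNA(tissues))
    stop("missing tissue label")
  tab <- table(tissues)
  if (length(tab) < 2)
    stop("at least 2 distinct tissues are required, got ", length(tab))
  if (any(tab < 2))
    stop("every tissue needs >= 2 replicate samples; offending: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  structure(list(values = values, tissue = tissues), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  tab <- table(x$tissue)
  cat(sprintf("expr_matrix: %d genes x %d samples, %d tissues\n",
              nrow(x$values), ncol(x$values), length(tab)))
  cat("  replicates:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Tissue design of an expression matrix
#'
#' Extracts the ordered tissue labels and the per-tissue replicate sample
#' lists (a partition of the samples).
#'
#' @param expr An [expression_matrix()] object.
#' @return A list with elements `tissues` (character vector, in order of first
#'   appearance) and `replicates` (named list of sample-id vectors).
#' @export
tissue_design <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  tis <- unique(expr$tissue)
  reps <- lapply(tis, function(t) names(expr$tissue)[expr$tissue == t])
  names(reps) <- tis
  list(tissues = tis, replicates = reps)
}

#' Read an expression matrix and sample labels from TSV files
#'
#' The expression file is tab-separated with gene identifiers in the first
#' column and a header row of sample identifiers; values must be numeric
#' log2-scale intensities. The labels file has two columns (no header
#' required): sample identifier and tissue label.
#'
#' Duplicate gene rows (e.g. multiple probes per gene) are collapsed
#' per sample according to `collapse`; the default keeps the per-sample
#' maximum.
#'
#' @param path Path to the expression TSV.
#' @param labels_path Path to the two-column sample-to-tissue TSV.
#' @param collapse How to collapse duplicate gene rows: `"max"` (default),
#'   `"mean"` or `"first"`.
#' @return An [expression_matrix()] object.
#' @export
read_expression <- function(path, labels_path,
                            collapse = c("max", "mean", "first")) {
  collapse <- match.arg(collapse)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expression file needs a gene column and samples")
  genes <- as.character(raw[[1]])
  vals <- raw[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop(sprintf("non-numeric value in column '%s', row %d ('%s')",
                     colnames(vals)[j], bad[1], v[bad[1]]))
      vals[[j]] <- vn
    }
  }
  m <- as.matrix(vals)
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at gene '%s', sample '%s'",
                 genes[idx[1]], colnames(m)[idx[2]]))
  }
  rownames(m) <- NULL
  if (anyDuplicated(genes)) m <- collapse_duplicates(m, genes, collapse)
  else rownames(m) <- genes

  lab <- utils::read.delim(labels_path, header = FALSE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (tolower(lab[1, 1]) %in% c("sample", "sample_id")) lab <- lab[-1, ]
  tissues <- as.character(lab[[2]])
  names(tissues) <- as.character(lab[[1]])
  expression_matrix(m, tissues)
}

collapse_duplicates <- function(m, genes, collapse) {
  f <- switch(collapse,
              max = function(x) apply(x, 2, max),
              mean = function(x) colMeans(x),
              first = function(x) x[1, ])
  idx <- split(seq_along(genes), genes)
  out <- t(vapply(idx, function(i) f(m[i, , drop = FALSE]),
                  numeric(ncol(m))))
  colnames(out) <- colnames(m)
  # keep first-appearance order
  out[unique(genes), , drop = FALSE]
}

#' Write an expression matrix (and its labels) to TSV
#'
#' @param expr An [expression_matrix()] object.
#' @param path Output path for the expression TSV.
#' @param labels_path Optional output path for the sample-to-tissue TSV.
#' @param header Optional character vector of comment lines (written with a
#'   leading `#`).
#' @return Invisibly, `expr`.
#' @export
write_expression <- function(expr, path, labels_path = NULL, header = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(c("gene", colnames(expr$values)), collapse = "\t"), con)
  utils::write.table(data.frame(gene = rownames(expr$values), expr$values,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(labels_path))
    utils::write.table(data.frame(names(expr$tissue), expr$tissue),
                       labels_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(expr)
}
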
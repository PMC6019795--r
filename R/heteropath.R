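#' Per-gene tissue t-statistics against the virtual median cell
#'
#' For every gene and every tissue, compares the tissue's median expression
#' `M1` with the median expression across all samples `M2` (the "virtual
#' median cell"), scaled by a pooled standard deviation:
#' `t = (M1 - M2) / s`. The pooled standard deviation combines the tissue's
#' replicate values (group 1) with the reference group's values via the
#' standard two-sample formula
#' `sqrt(((n1-1)*s1^2 + (n2-1)*s2^2) / (n1+n2-2))`.
#' A gene passes the fold-change filter in a tissue when
#' `|M1 - M2| >= log2(fc_threshold)` (expression is log2-scale).
#'
#' Zero-variance guard: `eps` is added to the pooled standard deviation in
#' the denominator, and genes whose pooled variance and numerator are both
#' below `eps` get `t = 0`, so constant probes never contribute.
#'
#' @param expr An [expression_matrix()] object (log2-scale values).
#' @param fc_threshold Fold-change filter threshold on the natural scale
#'   (default 2, i.e. a log2 difference of 1).
#' @param reference Reference group for the pooled standard deviation:
#'   `"all"` (default; all samples of all tissues) or `"rest"` (all samples
#'   excluding the tissue under test). `M2` is always the median over all
#'   samples.
#' @param eps Zero-variance guard (default 1e-8).
#' @return An object of class `"gene_tissue_stats"`: list with matrices `t`,
#'   `m1`, `s`, `pass_fc` (genes x tissues), vector `m2`, and the parameters.
#' @export
tissue_t_statistics <- function(expr, fc_threshold = 2,
                                reference = c("all", "rest"), eps = 1e-8) {
  stopifnot(inherits(expr, "expr_matrix"))
  reference <- match.arg(reference)
  if (fc_threshold < 1) stop("'fc_threshold' must be >= 1")
  des <- tissue_design(expr)
  groups <- lapply(des$replicates, function(s) match(s, colnames(expr$values)))
  if (any(lengths(groups) < 2))
    stop("pooled standard deviation undefined: tissue with a single replicate")
  v <- expr$values
  m2 <- apply(v, 1L, stats::median)
  v2 <- row_vars(v)
  core <- ht_stats_core(v, groups, m2, v2, log2(fc_threshold),
                        reference, eps)
  structure(list(t = core$t, m1 = core$m1, m2 = m2, s = core$s,
                 pass_fc = core$pass, tissues = des$tissues,
                 fc_threshold = fc_threshold, reference = reference,
                 eps = eps),
            class = "gene_tissue_stats")
}

# Inner kernel shared by the observed statistics and the permutation loop.
# groups: list of column-index vectors per tissue; m2/v2: median and variance
# over all columns (label-invariant, precomputed by the caller).
ht_stats_core <- function(v, groups, m2, v2, fc_log2, reference, eps,
                          want_s = TRUE) {
  n_all <- ncol(v)
  k <- length(groups)
  tmat <- m1mat <- smat <- matrix(NA_real_, nrow(v), k)
  pass <- matrix(FALSE, nrow(v), k)
  for (g in seq_len(k)) {
    cols <- groups[[g]]
    n1 <- length(cols)
    x <- v[, cols, drop = FALSE]
    m1 <- row_medians(x)
    v1 <- row_vars(x)
    if (reference == "all") {
      vr <- v2
      nr <- n_all
    } else {
      xr <- v[, -cols, drop = FALSE]
      vr <- row_vars(xr)
      nr <- ncol(xr)
    }
    s <- sqrt(((n1 - 1) * v1 + (nr - 1) * vr) / (n1 + nr - 2))
    num <- m1 - m2
    tt <- num / (s + eps)
    tt[s < eps & abs(num) < eps] <- 0
    tmat[, g] <- tt
    m1mat[, g] <- m1
    if (want_s) smat[, g] <- s
    pass[, g] <- abs(num) >= fc_log2
  }
  nms <- list(rownames(v), names(groups))
  dimnames(tmat) <- dimnames(pass) <- nms
  dimnames(m1mat) <- dimnames(smat) <- nms
  list(t = tmat, m1 = m1mat, s = smat, pass = pass)
}

# genes x sets 0/1 membership indicator over the measured gene universe.
set_indicator <- function(gene_ids, sets) {
  S <- matrix(0, length(gene_ids), length(sets),
              dimnames = list(gene_ids, names(sets)))
  for (j in seq_along(sets)) {
    idx <- match(sets[[j]], gene_ids)
    S[idx[!is.na(idx)], j] <- 1
  }
  S
}

#' Heterogeneity scores per gene set and tissue
#'
#' The heterogeneity score of a set in a tissue is the sum of absolute
#' t-statistics over the set's member genes that are present in the
#' expression matrix and pass the fold-change filter in that tissue. A set
#' with no passing members (or no measured members at all) scores 0.
#'
#' @param stats A [tissue_t_statistics()] result.
#' @param sets A [gene_sets()] collection.
#' @return List with matrices `hs` and `n_contributing` (sets x tissues) and
#'   `n_present` (measured member genes per set; sets with `n_present == 0`
#'   are scored 0 and reported, never an error).
#' @export
heterogeneity_scores <- function(stats, sets) {
  stopifnot(inherits(stats, "gene_tissue_stats"), inherits(sets, "gene_sets"))
  S <- set_indicator(rownames(stats$t), sets)
  contrib <- abs(stats$t) * stats$pass_fc
  hs <- crossprod(S, contrib)
  n_contributing <- crossprod(S, stats$pass_fc + 0)
  list(hs = hs, n_contributing = n_contributing, n_present = colSums(S))
}

#' Permutation p-values for heterogeneity scores
#'
#' Permutes the sample-to-tissue assignment and recomputes the t-statistics,
#' fold-change filter and heterogeneity scores per permutation. Assignments
#' that differ only by reordering samples within a tissue are the same
#' grouping, so the distinct arrangements number `N! / prod(n_t!)`. When that
#' count is at most `exhaustive_cap` all arrangements (including the observed
#' one) are enumerated and `p = #\{HS_perm >= HS_obs\} / N_arrangements`;
#' otherwise Monte Carlo with the add-one estimator
#' `p = (1 + #\{HS_perm >= HS_obs\}) / (1 + n_perm)`. Ties count, so `p > 0`
#' always.
#'
#' @inheritParams tissue_t_statistics
#' @param sets A [gene_sets()] collection.
#' @param n_perm Number of Monte Carlo permutations (ignored when the design
#'   is enumerated exhaustively). Must be >= 1.
#' @param seed Optional integer seed for the Monte Carlo sampler.
#' @param exhaustive_cap Enumerate exhaustively when the number of distinct
#'   arrangements is at most this (default 10000).
#' @return List with matrices `p` and `hs` (sets x tissues),
#'   `n_contributing`, `n_present`, the arrangement count and whether
#'   enumeration was exhaustive.
#' @export
permutation_pvalues <- function(expr, sets, fc_threshold = 2, n_perm = 1000,
                                seed = NULL, exhaustive_cap = 10000,
                                reference = c("all", "rest"), eps = 1e-8) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(sets, "gene_sets"))
  reference <- match.arg(reference)
  if (n_perm < 1) stop("'n_perm' must be >= 1")
  v <- expr$values
  des <- tissue_design(expr)
  if (length(des$tissues) < 2) stop("degenerate design: a single tissue")
  groups0 <- lapply(des$replicates, function(s) match(s, colnames(v)))
  sizes <- lengths(groups0)
  fc_log2 <- log2(fc_threshold)
  m2 <- apply(v, 1L, stats::median)
  v2 <- row_vars(v)
  S <- set_indicator(rownames(v), sets)

  hs_of <- function(groups) {
    core <- ht_stats_core(v, groups, m2, v2, fc_log2, reference, eps,
                          want_s = FALSE)
    list(hs = crossprod(S, abs(core$t) * core$pass),
         npass = crossprod(S, core$pass + 0))
  }
  obs <- hs_of(groups0)

  n_arr <- count_arrangements(sizes)
  exhaustive <- n_arr <= exhaustive_cap
  geq <- matrix(0, length(sets), length(des$tissues))
  if (exhaustive) {
    arr <- enumerate_arrangements(sizes)
    for (a in seq_len(ncol(arr))) {
      asg <- arr[, a]
      groups <- lapply(seq_along(sizes), function(g) which(asg == g))
      names(groups) <- des$tissues
      geq <- geq + (hs_of(groups)$hs >= obs$hs)
    }
    p <- geq / ncol(arr)
    n_used <- ncol(arr)
  } else {
    if (!is.null(seed)) set.seed(seed)
    # asg0[i] = tissue index of column i
    asg0 <- integer(ncol(v))
    for (g in seq_along(groups0)) asg0[groups0[[g]]] <- g
    for (b in seq_len(n_perm)) {
      asg <- sample(asg0)
      groups <- lapply(seq_along(sizes), function(g) which(asg == g))
      names(groups) <- des$tissues
      geq <- geq + (hs_of(groups)$hs >= obs$hs)
    }
    p <- (1 + geq) / (1 + n_perm)
    n_used <- n_perm
  }
  dimnames(p) <- dimnames(obs$hs)
  list(p = p, hs = obs$hs, n_contributing = obs$npass,
       n_present = colSums(S), n_arrangements = n_arr,
       exhaustive = exhaustive, n_used = n_used)
}

#' Benjamini-Hochberg adjustment of permutation p-values
#'
#' Applies the Benjamini-Hochberg step-up procedure jointly across all
#' (set, tissue) tests supplied.
#'
#' @param p Numeric vector or matrix of raw p-values in (0, 1].
#' @return Adjusted values (q-values) of the same shape.
#' @export
fdr_adjust <- function(p) {
  q <- bh_adjust(as.vector(p))
  if (is.matrix(p)) q <- matrix(q, nrow(p), dimnames = dimnames(p))
  else names(q) <- names(p)
  q
}

#' Tissue-specificity calls for heterogeneous gene sets
#'
#' A "heterogeneous element" of a set is a measured member gene passing the
#' fold-change filter in at least one tissue; it is "unique" to a tissue when
#' it passes there and nowhere else. A set is assigned to a tissue when the
#' unique-to-that-tissue elements make up at least `threshold` of all its
#' heterogeneous elements (default 60%); otherwise the call is `NA`.
#'
#' @param stats A [tissue_t_statistics()] result.
#' @param sets A [gene_sets()] collection.
#' @param threshold Fraction in (0.5, 1] (default 0.6); above one half, at
#'   most one tissue can qualify.
#' @return Named character vector of tissue calls per set (`NA` = none).
#' @export
tissue_specificity <- function(stats, sets, threshold = 0.6) {
  stopifnot(inherits(stats, "gene_tissue_stats"), inherits(sets, "gene_sets"))
  pass <- stats$pass_fc
  calls <- rep(NA_character_, length(sets))
  names(calls) <- names(sets)
  for (j in seq_along(sets)) {
    rows <- match(sets[[j]], rownames(pass))
    rows <- rows[!is.na(rows)]
    if (!length(rows)) next
    pm <- pass[rows, , drop = FALSE]
    n_tis <- rowSums(pm)
    het <- n_tis >= 1
    if (!any(het)) next
    uniq <- pm & (n_tis == 1)   # unique-to-tissue indicator
    cnt <- colSums(uniq[het, , drop = FALSE])
    ok <- cnt >= threshold * sum(het)
    if (any(ok)) calls[j] <- colnames(pm)[which(ok)[which.max(cnt[ok])]]
  }
  calls
}

#' Pathway Z-scores
#'
#' For each tissue, the per-gene fold change is `M1 - M2` in log2 space (the
#' tissue median against the all-sample median). With `mu` and `sigma` the
#' mean and standard deviation of all genes' fold changes in that tissue,
#' `x_p` the mean fold change of a set's measured members and `p` their
#' count, the set's score is `Z = (x_p - mu) * sqrt(p) / sigma`. This is the
#' mean-shift statistic used for heatmap display; a bidirectionally perturbed
#' set has `Z` near 0 by construction.
#'
#' @param expr An [expression_matrix()] object.
#' @param sets A [gene_sets()] collection.
#' @return Matrix of Z-scores, sets x tissues. Sets with no measured members
#'   get `NA`.
#' @export
pathway_zscore <- function(expr, sets) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(sets, "gene_sets"))
  des <- tissue_design(expr)
  v <- expr$values
  m2 <- apply(v, 1L, stats::median)
  z <- matrix(NA_real_, length(sets), length(des$tissues),
              dimnames = list(names(sets), des$tissues))
  for (g in seq_along(des$tissues)) {
    cols <- match(des$replicates[[g]], colnames(v))
    fc <- row_medians(v[, cols, drop = FALSE]) - m2
    mu <- mean(fc)
    sigma <- stats::sd(fc)
    if (sigma == 0) stop("degenerate input: zero variance of fold changes")
    for (j in seq_along(sets)) {
      idx <- match(sets[[j]], rownames(v))
      idx <- idx[!is.na(idx)]
      if (!length(idx)) next
      z[j, g] <- (mean(fc[idx]) - mu) * sqrt(length(idx)) / sigma
    }
  }
  z
}

#' Fit the pathway-heterogeneity model
#'
#' Runs the full analysis: per-gene tissue t-statistics against the virtual
#' median cell, fold-change filtering, heterogeneity scores per (set, tissue),
#' permutation p-values, joint Benjamini-Hochberg FDR, pathway Z-scores and
#' tissue-specificity calls. Results are ranked by heterogeneity score,
#' largest first, within each tissue.
#'
#' @inheritParams permutation_pvalues
#' @param alpha FDR threshold used by [summary.heteropath()] for the
#'   significant-set table (default 0.05).
#' @param specificity_threshold Fraction for the tissue-specificity rule
#'   (default 0.6).
#' @return An object of class `"heteropath"`: list with `results` (data frame
#'   with columns set, tissue, hs, n_contributing, p, q, z, specific_tissue),
#'   `stats` (the [tissue_t_statistics()] object), `zscores`, `specificity`,
#'   `permutation` (arrangement count, exhaustive flag), `params` and `call`.
#'   Methods: `print`, `summary`, `plot`.
#' @export
#' @examples
#' fx <- generate_fixture(fixture_config(n_genes = 200, n_sets = 5,
#'                                       planted = planted_pathway("set01", "t1")),
#'                        seed = 1)
#' fit <- heteropath(fx$expr, fx$sets, n_perm = 50, seed = 1)
#' head(summary(fit))
heteropath <- function(expr, sets, fc_threshold = 2, n_perm = 1000,
                       seed = NULL, alpha = 0.05,
                       specificity_threshold = 0.6, exhaustive_cap = 10000,
                       reference = c("all", "rest"), eps = 1e-8) {
  stopifnot(inherits(expr, "expr_matrix"))
  reference <- match.arg(reference)
  cl <- match.call()
  if (length(sets) == 0) {
    warning("empty gene set collection: returning an empty result")
    res <- data.frame(set = character(), tissue = character(),
                      hs = numeric(), n_contributing = integer(),
                      p = numeric(), q = numeric(), z = numeric(),
                      specific_tissue = character())
    return(structure(list(results = res, stats = NULL, zscores = NULL,
                          specificity = character(),
                          permutation = NULL,
                          params = list(fc_threshold = fc_threshold,
                                        n_perm = n_perm, alpha = alpha),
                          call = cl),
                     class = "heteropath"))
  }
  stopifnot(inherits(sets, "gene_sets"))
  stats <- tissue_t_statistics(expr, fc_threshold, reference, eps)
  perm <- permutation_pvalues(expr, sets, fc_threshold, n_perm, seed,
                              exhaustive_cap, reference, eps)
  q <- fdr_adjust(perm$p)
  z <- pathway_zscore(expr, sets)
  spec <- tissue_specificity(stats, sets, specificity_threshold)
  res <- data.frame(
    set = rep(rownames(perm$hs), times = ncol(perm$hs)),
    tissue = rep(colnames(perm$hs), each = nrow(perm$hs)),
    hs = as.vector(perm$hs),
    n_contributing = as.integer(perm$n_contributing),
    p = as.vector(perm$p),
    q = as.vector(q),
    z = as.vector(z),
    specific_tissue = rep(unname(spec), times = ncol(perm$hs)),
    stringsAsFactors = FALSE)
  res <- res[order(res$tissue, -res$hs), ]
  rownames(res) <- NULL
  structure(list(results = res, stats = stats, zscores = z,
                 specificity = spec, sets = sets,
                 permutation = list(n_arrangements = perm$n_arrangements,
                                    exhaustive = perm$exhaustive,
                                    n_used = perm$n_used),
                 params = list(fc_threshold = fc_threshold, n_perm = n_perm,
                               seed = seed, alpha = alpha,
                               specificity_threshold = specificity_threshold,
                               reference = reference),
                 call = cl),
            class = "heteropath")
}

#' @export
print.heteropath <- function(x, ...) {
  cat("Pathway heterogeneity fit\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  n_sig <- sum(x$results$q < x$params$alpha, na.rm = TRUE)
  cat(sprintf("%d (set, tissue) tests; %d significant at q < %g\n",
              nrow(x$results), n_sig, x$params$alpha))
  if (!is.null(x$permutation))
    cat(sprintf("permutation: %s over %s arrangements\n",
                if (x$permutation$exhaustive) "exhaustive" else "Monte Carlo",
                format(x$permutation$n_arrangements, big.mark = ",")))
  if (nrow(x$results)) {
    cat("Top of the ranking:\n")
    print(utils::head(x$results, 5), digits = 4)
  }
  invisible(x)
}

#' Significant heterogeneous sets
#'
#' @param object A [heteropath()] fit.
#' @param alpha FDR threshold (defaults to the one stored in the fit).
#' @param ... Unused.
#' @return Data frame of results with `q < alpha`, ranked by heterogeneity
#'   score within tissue.
#' @export
summary.heteropath <- function(object, alpha = object$params$alpha, ...) {
  res <- object$results
  res[!is.na(res$q) & res$q < alpha, , drop = FALSE]
}

#' Heatmap-style display of pathway Z-scores
#'
#' @param x A [heteropath()] fit.
#' @param ... Passed to [graphics::image()].
#' @export
plot.heteropath <- function(x, ...) {
  z <- x$zscores
  if (is.null(z) || !length(z)) {
    warning("nothing to plot")
    return(invisible(x))
  }
  op <- graphics::par(mar = c(4, 8, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(seq_len(ncol(z)), seq_len(nrow(z)), t(z),
                  axes = FALSE, xlab = "tissue", ylab = "",
                  main = "pathway Z-scores", ...)
  graphics::axis(1, seq_len(ncol(z)), colnames(z))
  graphics::axis(2, seq_len(nrow(z)), rownames(z), las = 2, cex.axis = 0.6)
  invisible(x)
}

#' Write the per-(set, tissue) result table to TSV
#'
#' Writes the full ranked table and, alongside it, a `*_significant.tsv`
#' table restricted to `q < alpha`.
#'
#' @param x A [heteropath()] fit.
#' @param path Output TSV path.
#' @param header Optional extra comment lines.
#' @return Invisibly, `x`.
#' @export
write_heteropath <- function(x, path, header = NULL) {
  stopifnot(inherits(x, "heteropath"))
  hdr <- c(paste0("heteropath ",
                  as.character(utils::packageVersion("heteropath"))),
           paste0("fc_threshold=", x$params$fc_threshold,
                  " n_perm=", x$params$n_perm,
                  " seed=", if (is.null(x$params$seed)) "NA"
                            else x$params$seed),
           header)
  write_tsv(x$results, path, header = hdr)
  sig <- summary(x)
  write_tsv(sig, sub("(\\.tsv)?$", "_significant.tsv", path), header = hdr)
  invisible(x)
}
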
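#' Configuration for the linear additive microarray simulator
#'
#' Data are generated as `y_ij = alpha_i + beta_ij + e_ij`: a gene-specific
#' baseline `alpha_i ~ N(0, 1)`, a sample effect `beta` and cell-level noise
#' `e_ij ~ N(0, 1)`. Samples split into three groups. Genes of the
#' differentially expressed set that are truly shifted receive
#' `beta ~ N(mu1, sigma1)` in group 1 — `mu1 = 0.5` ("weak") or `mu1 = 1`
#' ("strong"), `sigma1 = 0.5` — and `beta ~ N(0, 1)` elsewhere; all other
#' genes get `beta ~ N(0, 1)` everywhere.
#'
#' @param m Number of genes (default 5000).
#' @param n Total samples, split into three (near-)equal groups; when `n` is
#'   not divisible by 3 the earlier groups take the extra sample
#'   (default 20).
#' @param de_set_size Size of the differentially expressed set and of the
#'   matched null set (default 50).
#' @param de_fraction Fraction of the DE set truly shifted (default 0.5);
#'   the shifted count is rounded half-up.
#' @param effect `"strong"` (`mu1 = 1`) or `"weak"` (`mu1 = 0.5`), both with
#'   `sigma1 = 0.5`.
#' @param n_reps Replicate datasets for the power study (default 500).
#' @param alpha ANOVA significance level (default 0.05).
#' @param seed Base integer seed; each replicate derives its own stream from
#'   `(seed, rep_index)`.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(m = 5000, n = 20, de_set_size = 50,
                              de_fraction = 0.5,
                              effect = c("strong", "weak"), n_reps = 500,
                              alpha = 0.05, seed = 1) {
  effect <- match.arg(effect)
  if (n < 6) stop("need n >= 6 (two samples per group)")
  if (de_fraction <= 0 || de_fraction > 1)
    stop("'de_fraction' must be in (0, 1]")
  if (2 * de_set_size > m) stop("DE and null sets do not fit in m genes")
  structure(list(m = m, n = n, de_set_size = de_set_size,
                 de_fraction = de_fraction, effect = effect,
                 mu1 = if (effect == "strong") 1 else 0.5, sigma1 = 0.5,
                 n_reps = n_reps, alpha = alpha, seed = seed),
            class = "simulation_config")
}

# Near-equal split of n samples into 3 groups (earlier groups get the extra).
group_sizes3 <- function(n) {
  base <- n %/% 3
  extra <- n %% 3
  base + (seq_len(3) <= extra)
}

#' Simulate one microarray dataset under the linear additive model
#'
#' Deterministic given `(config$seed, rep_index)`.
#'
#' @param config A [simulation_config()].
#' @param rep_index Replicate index (default 1).
#' @return A list of class `"sim_dataset"`: `values` (genes x samples
#'   matrix), `group` (factor g1/g2/g3 per sample), `de_set`, `null_set`
#'   (gene ids) and `truly_shifted` (subset of `de_set`).
#' @export
simulate_dataset <- function(config, rep_index = 1) {
  stopifnot(inherits(config, "simulation_config"))
  cf <- config
  set.seed((cf$seed + rep_index * 1000003L) %% 2147483647L,
           kind = "Mersenne-Twister")
  sizes <- group_sizes3(cf$n)
  group <- factor(rep(paste0("g", 1:3), times = sizes))
  genes <- sprintf("g%05d", seq_len(cf$m))
  samples <- sprintf("s%03d", seq_len(cf$n))

  alpha_i <- stats::rnorm(cf$m)
  beta <- matrix(stats::rnorm(cf$m * cf$n), cf$m, cf$n)
  eps <- matrix(stats::rnorm(cf$m * cf$n), cf$m, cf$n)
  v <- alpha_i + beta + eps

  de_set <- genes[seq_len(cf$de_set_size)]
  null_set <- genes[cf$de_set_size + seq_len(cf$de_set_size)]
  n_shift <- round_half_up(cf$de_fraction * cf$de_set_size)
  shifted <- de_set[seq_len(n_shift)]
  g1 <- which(group == "g1")
  # replace the N(0,1) sample effect by N(mu1, sigma1) for shifted x group 1
  v[seq_len(n_shift), g1] <- alpha_i[seq_len(n_shift)] +
    matrix(stats::rnorm(n_shift * length(g1), cf$mu1, cf$sigma1),
           n_shift, length(g1)) +
    eps[seq_len(n_shift), g1]
  dimnames(v) <- list(genes, samples)
  structure(list(values = v, group = stats::setNames(group, samples),
                 de_set = de_set, null_set = null_set,
                 truly_shifted = shifted, config = cf,
                 rep_index = rep_index),
            class = "sim_dataset")
}

#' Per-sample enrichment scores for the simulated DE and null sets
#'
#' Produces the "enrichment score matrix" the ANOVA power study works on: one
#' score per sample for each of the two planted sets.
#'
#' Methods: `"pgsea"` — one-sample t of the set's per-sample fold changes
#' (sample value minus the gene's median over all samples); `"gsea"` — the
#' weighted-KS enrichment score on the per-sample fold-change ranking of all
#' genes; `"heteropath"` — the single-sample analogue of the heterogeneity
#' score, `sum over filter-passing set genes of |x_ij - M2(i)| / s2(i)` with
#' `M2` and `s2` the gene's all-sample median and standard deviation and the
#' filter `|x_ij - M2(i)| >= log2(fc_threshold)`.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param method One of `"heteropath"`, `"pgsea"`, `"gsea"`.
#' @param fc_threshold Fold-change filter for the heterogeneity score
#'   (default 2).
#' @param eps Variance floor (default 1e-8).
#' @return List with numeric per-sample score vectors `de` and `null` and the
#'   sample `group` factor.
#' @export
score_matrix <- function(dataset, method = c("heteropath", "pgsea", "gsea"),
                         fc_threshold = 2, eps = 1e-8) {
  stopifnot(inherits(dataset, "sim_dataset"))
  method <- match.arg(method)
  v <- dataset$values
  one <- function(set_genes) {
    idx <- match(set_genes, rownames(v))
    switch(method,
      heteropath = {
        x <- v[idx, , drop = FALSE]
        m2 <- apply(x, 1L, stats::median)
        s2 <- sqrt(row_vars(x))
        d <- abs(x - m2)
        colSums((d / (s2 + eps)) * (d >= log2(fc_threshold)))
      },
      pgsea = {
        x <- v[idx, , drop = FALSE]
        fc <- x - apply(x, 1L, stats::median)
        k <- length(idx)
        mu <- colMeans(fc)
        sdv <- pmax(sqrt((colSums(fc * fc) - k * mu * mu) / (k - 1)), eps)
        mu / (sdv / sqrt(k))
      },
      gsea = {
        fc <- v - apply(v, 1L, stats::median)
        member <- rownames(v) %in% set_genes
        vapply(seq_len(ncol(fc)),
               function(j) gsea_es(fc[, j], member), numeric(1))
      })
  }
  list(de = one(dataset$de_set), null = one(dataset$null_set),
       group = dataset$group)
}

# Classical one-way fixed-effects ANOVA p-value for a group mean difference.
anova_pvalue <- function(score, group) {
  stats::oneway.test(score ~ group, var.equal = TRUE)$p.value
}

#' Power and type-I-error study over a simulation grid
#'
#' For every grid cell and method, simulates `n_reps` independent datasets,
#' scores the differentially expressed and the null set per sample, and runs
#' a one-way ANOVA for a mean difference among the three sample groups at
#' level `alpha`. Power is one minus the non-rejection rate on the DE set;
#' the empirical type-I error is the rejection rate on the null set. Both
#' come with Wilson 95% confidence intervals.
#'
#' @param grid Data frame of simulation conditions; recognized columns (all
#'   optional, with [simulation_config()] defaults): `n`, `effect`,
#'   `de_fraction`, `de_set_size`, `m`.
#' @param methods Character vector of scoring methods (see [score_matrix()]).
#' @param n_reps Replicate datasets per cell (default 200).
#' @param alpha Significance level (default 0.05).
#' @param seed Base seed; cells use disjoint replicate streams.
#' @param fc_threshold Passed to [score_matrix()] for the heterogeneity
#'   score.
#' @return Data frame with one row per (cell, method): the grid columns,
#'   `method`, `power`, `power_lo`, `power_hi`, `type1`, `type1_lo`,
#'   `type1_hi`, `n_reps`.
#' @export
power_study <- function(grid, methods = c("heteropath", "pgsea", "gsea"),
                        n_reps = 200, alpha = 0.05, seed = 1,
                        fc_threshold = 2) {
  if (n_reps < 50) warning("fewer than 50 replicates: estimates will be noisy")
  defaults <- list(n = 20, effect = "strong", de_fraction = 0.5,
                   de_set_size = 50, m = 5000)
  out <- list()
  for (ci in seq_len(nrow(grid))) {
    cell <- as.list(grid[ci, , drop = FALSE])
    for (nm in names(defaults)) if (is.null(cell[[nm]])) cell[[nm]] <- defaults[[nm]]
    cf <- simulation_config(m = cell$m, n = cell$n,
                            de_set_size = cell$de_set_size,
                            de_fraction = cell$de_fraction,
                            effect = cell$effect, n_reps = n_reps,
                            alpha = alpha, seed = seed + 7919L * ci)
    rej_de <- rej_null <- stats::setNames(numeric(length(methods)), methods)
    for (r in seq_len(n_reps)) {
      ds <- simulate_dataset(cf, r)
      for (mth in methods) {
        sc <- score_matrix(ds, mth, fc_threshold = fc_threshold)
        rej_de[mth] <- rej_de[mth] + (anova_pvalue(sc$de, sc$group) < alpha)
        rej_null[mth] <- rej_null[mth] +
          (anova_pvalue(sc$null, sc$group) < alpha)
      }
    }
    for (mth in methods) {
      wi_p <- wilson_interval(rej_de[mth], n_reps)
      wi_t <- wilson_interval(rej_null[mth], n_reps)
      out[[length(out) + 1]] <- data.frame(
        n = cell$n, effect = cell$effect, de_fraction = cell$de_fraction,
        de_set_size = cell$de_set_size, m = cell$m, method = mth,
        power = unname(rej_de[mth]) / n_reps,
        power_lo = wi_p[["lower"]], power_hi = wi_p[["upper"]],
        type1 = unname(rej_null[mth]) / n_reps,
        type1_lo = wi_t[["lower"]], type1_hi = wi_t[["upper"]],
        n_reps = n_reps, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
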
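make_stats <- function(t, pass) {
  structure(list(t = t, pass_fc = pass, tissues = colnames(t)),
            class = "gene_tissue_stats")
}

test_that("tissue t-statistics match the definition on hand-computable cases", {
  # 2 tissues x 3 replicates, one gene with values 1..6
  m <- matrix(c(1, 2, 3, 4, 5, 6), 1, 6,
              dimnames = list("g1", paste0("s", 1:6)))
  e <- toy_expr(m, rep(c("t1", "t2"), each = 3))
  st <- tissue_t_statistics(e, fc_threshold = 2)
  # hand arithmetic: M1 = 2 and 5, global median 3.5, pooled sd from
  # var{1,2,3} = 1 and var{1..6} = 3.5
  sp <- sqrt((2 * 1 + 5 * 3.5) / 7)
  expect_equal(st$t["g1", "t1"], (2 - 3.5) / (sp + 1e-8), tolerance = 1e-12)
  expect_equal(st$t["g1", "t2"], (5 - 3.5) / (sp + 1e-8), tolerance = 1e-12)
  expect_equal(st$m2[["g1"]], 3.5)
  expect_true(all(st$pass_fc["g1", ]))   # |1.5| >= log2(2)

  # cross-check against the independent oracle on random data
  set.seed(42)
  m2 <- matrix(rnorm(40), 4, 10,
               dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  tis <- rep(c("a", "b"), each = 5)
  st2 <- tissue_t_statistics(toy_expr(m2, tis))
  for (g in rownames(m2)) for (tt in c("a", "b"))
    expect_equal(st2$t[g, tt], oracle_t(m2[g, ], which(tis == tt)),
                 tolerance = 1e-12)
})

test_that("degenerate genes get t = 0 and location shifts cancel", {
  m <- rbind(g1 = rep(7, 6),                  # constant everywhere
             g2 = c(1, 2, 3, 1, 2, 3))        # tissue median == global median
  colnames(m) <- paste0("s", 1:6)
  st <- tissue_t_statistics(toy_expr(m, rep(c("a", "b"), each = 3)))
  expect_equal(unname(st$t["g1", ]), c(0, 0))
  expect_equal(unname(st$t["g2", ]), c(0, 0))

  set.seed(7)
  m3 <- matrix(rnorm(24), 2, 12,
               dimnames = list(c("x", "y"), paste0("s", 1:12)))
  tis <- rep(c("a", "b", "c"), each = 4)
  base <- tissue_t_statistics(toy_expr(m3, tis))
  m3["x", ] <- m3["x", ] + 100
  shifted <- tissue_t_statistics(toy_expr(m3, tis))
  expect_equal(shifted$t["x", ], base$t["x", ], tolerance = 1e-9)
})

test_that("single-replicate tissues are rejected", {
  m <- matrix(rnorm(6), 2, 3,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  expect_error(expression_matrix(m, c("a", "a", "b")), "2 replicate")
})

test_that("heterogeneity score sums |t| over filter-passing members", {
  t <- matrix(c(3, -2, 0.5), 3, 1,
              dimnames = list(c("g1", "g2", "g3"), "t1"))
  pass <- matrix(c(TRUE, TRUE, FALSE), 3, 1,
                 dimnames = dimnames(t))
  sets <- gene_sets(list(both = c("g1", "g2"),
                         fails = c("g3"),
                         missing = c("zz1", "zz2")))
  hs <- heterogeneity_scores(make_stats(t, pass), sets)
  expect_equal(hs$hs["both", "t1"], 5)          # |+3| + |-2|
  expect_equal(hs$hs["fails", "t1"], 0)
  expect_equal(hs$n_contributing["fails", "t1"], 0)
  expect_equal(hs$hs["missing", "t1"], 0)
  expect_equal(hs$n_present[["missing"]], 0)
})

test_that("HS is invariant under reordering and additive over disjoint unions", {
  set.seed(10)
  fx <- generate_fixture(fixture_config(n_genes = 120, n_sets = 0,
                                        planted = list(
                                          planted_pathway("a", "t1", size = 15,
                                                          effect = 1.5),
                                          planted_pathway("b", "t2", size = 15,
                                                          effect = 1.5))),
                         seed = 2)
  st <- tissue_t_statistics(fx$expr)
  sets <- fx$sets
  un <- gene_sets(list(u = c(sets$a, sets$b)))
  hs <- heterogeneity_scores(st, sets)$hs
  hsu <- heterogeneity_scores(st, un)$hs
  expect_equal(hsu["u", ], hs["a", ] + hs["b", ], tolerance = 1e-12)

  # permute genes and samples; recompute from scratch
  v <- fx$expr$values
  gp <- sample(nrow(v)); sp <- sample(ncol(v))
  e2 <- expression_matrix(v[gp, sp], fx$expr$tissue[colnames(v)[sp]])
  hs2 <- heterogeneity_scores(tissue_t_statistics(e2), sets)$hs
  # tissue columns come out in first-appearance order; align before comparing
  expect_equal(hs2[, colnames(hs)], hs, tolerance = 1e-12)
})

test_that("permutation p-values equal brute-force enumeration on a tiny design", {
  set.seed(5)
  m <- matrix(rnorm(24, sd = 1), 6, 4,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:4)))
  labels <- rep(c("a", "b"), each = 2)
  sets_list <- list(s1 = c("g1", "g2", "g3"), s2 = c("g4", "g5"))
  e <- toy_expr(m, labels)
  res <- permutation_pvalues(e, gene_sets(sets_list), fc_threshold = 1.2,
                             n_perm = 10)
  expect_true(res$exhaustive)
  expect_equal(res$n_arrangements, 6)   # 4! / (2! 2!)
  expected <- oracle_perm_p(m, labels, sets_list, fc_threshold = 1.2)
  expect_equal(res$p, expected)
  expect_true(all(res$p > 0 & res$p <= 1))
})

test_that("a zero observed HS yields p = 1", {
  m <- matrix(rep(c(1, 1.01), each = 2), 2, 4, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  m <- m + matrix(seq(0, 0.03, length.out = 8), 2, 4)
  e <- toy_expr(m, rep(c("a", "b"), each = 2))
  res <- permutation_pvalues(e, gene_sets(list(s = c("g1", "g2"))),
                             fc_threshold = 4, n_perm = 10)
  expect_equal(unname(res$hs[1, ]), c(0, 0))
  expect_equal(unname(res$p[1, ]), c(1, 1))
})

test_that("BH adjustment matches hand values and the textbook oracle", {
  expect_equal(unname(fdr_adjust(c(0.2, 0.2, 0.2))), rep(0.2, 3))
  # by hand: min over j >= i of p_j * m / j
  expect_equal(unname(fdr_adjust(c(0.01, 0.02, 0.03, 0.04))), rep(0.04, 4))
  set.seed(99)
  for (k in 1:20) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(unname(fdr_adjust(p)), oracle_bh(p), tolerance = 1e-14)
  }
})

test_that("tissue specificity follows the 60% unique-element rule", {
  mk <- function(rows) {
    t <- matrix(1, nrow(rows), ncol(rows), dimnames = dimnames(rows))
    make_stats(t, rows)
  }
  pass <- matrix(FALSE, 5, 3,
                 dimnames = list(paste0("g", 1:5),
                                 c("brain", "lung", "heart")))
  pass[, "brain"] <- TRUE
  sets <- gene_sets(list(s = paste0("g", 1:5)))
  expect_equal(tissue_specificity(mk(pass), sets)[["s"]], "brain")

  pass[] <- FALSE
  pass[1:3, "lung"] <- TRUE; pass[4:5, "heart"] <- TRUE
  expect_equal(tissue_specificity(mk(pass), sets)[["s"]], "lung")  # 3/5 = 60%

  pass4 <- matrix(FALSE, 4, 3,
                  dimnames = list(paste0("g", 1:4),
                                  c("brain", "lung", "heart")))
  pass4[1:2, "lung"] <- TRUE
  pass4[3:4, c("brain", "heart")] <- TRUE   # passing in two tissues: not unique
  sets4 <- gene_sets(list(s = paste0("g", 1:4)))
  expect_true(is.na(tissue_specificity(mk(pass4), sets4)[["s"]]))

  # zero heterogeneous elements -> no call, no error
  pass4[] <- FALSE
  expect_true(is.na(tissue_specificity(mk(pass4), sets4)[["s"]]))
})

test_that("pathway Z-score follows the closed form", {
  set.seed(31)
  m <- matrix(rnorm(200 * 8), 200, 8,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:8)))
  e <- toy_expr(m, rep(c("a", "b"), each = 4))
  sets <- gene_sets(list(all = rownames(m), sub = paste0("g", 1:20)))
  z <- pathway_zscore(e, sets)
  # the whole-universe set has x_p = mu exactly
  expect_equal(unname(z["all", ]), c(0, 0), tolerance = 1e-12)
  # recompute the subset Z from the definition
  for (tt in c("a", "b")) {
    cols <- which(e$tissue == tt)
    fc <- apply(m[, cols], 1, median) - apply(m, 1, median)
    zref <- (mean(fc[1:20]) - mean(fc)) * sqrt(20) / sd(fc)
    expect_equal(z["sub", tt], zref, tolerance = 1e-12)
  }
})

test_that("duplicating a set's members scales Z by sqrt(2)", {
  set.seed(32)
  base <- matrix(rnorm(50 * 6), 50, 6)
  m <- rbind(base, base[1:10, ])   # duplicate the first 10 profiles
  rownames(m) <- c(paste0("g", 1:50), paste0("d", 1:10))
  colnames(m) <- paste0("s", 1:6)
  e <- toy_expr(m, rep(c("a", "b"), each = 3))
  sets <- gene_sets(list(single = paste0("g", 1:10),
                         doubled = c(paste0("g", 1:10), paste0("d", 1:10))))
  z <- pathway_zscore(e, sets)
  expect_equal(unname(z["doubled", ]), unname(z["single", ]) * sqrt(2),
               tolerance = 1e-12)
})

test_that("the full fit ranks a planted bidirectional pathway first", {
  fx <- generate_fixture(
    fixture_config(n_genes = 600, n_sets = 10, set_size = 25,
                   planted = planted_pathway("planted", "t2", size = 25)),
    seed = 4)
  fit <- heteropath(fx$expr, fx$sets, n_perm = 200, seed = 4)
  r2 <- fit$results[fit$results$tissue == "t2", ]
  expect_equal(r2$set[1], "planted")
  expect_gt(r2$hs[1], r2$hs[2])
  # permutation p at the design floor for this 3x3 layout
  expect_equal(r2$p[1], 20 / 1680)
  expect_lt(abs(fit$zscores["planted", "t2"]), 1.96)
  expect_equal(fit$specificity[["planted"]], "t2")
  # results are ranked by HS within tissue
  for (tt in unique(fit$results$tissue))
    expect_false(is.unsorted(rev(fit$results$hs[fit$results$tissue == tt])))
})

test_that("an empty collection gives an empty result with a warning", {
  fx <- generate_fixture(fixture_config(n_genes = 50, n_sets = 1,
                                        set_size = 5), seed = 1)
  expect_warning(fit <- heteropath(fx$expr, gene_sets(list()), n_perm = 5),
                 "empty")
  expect_equal(nrow(fit$results), 0L)
})

test_that("result tables can be written and re-read", {
  fx <- generate_fixture(fixture_config(n_genes = 80, n_sets = 3,
                                        set_size = 8), seed = 6)
  fit <- heteropath(fx$expr, fx$sets, n_perm = 20, seed = 1)
  f <- tempfile(fileext = ".tsv")
  write_heteropath(fit, f)
  back <- read.delim(f, comment.char = "#")
  expect_equal(nrow(back), nrow(fit$results))
  expect_true(file.exists(sub("\\.tsv$", "_significant.tsv", f)))
})
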
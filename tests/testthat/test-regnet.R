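test_that("consensus and anti-consensus windows score 1 and 0 exactly", {
  set.seed(51)
  for (i in 1:30) {
    p <- random_pwm(L = sample(5:12, 1))
    hits <- scan_promoter(consensus_of(p), p, cutoff = 0)
    fwd <- hits[hits$strand == "+", ]
    expect_equal(max(fwd$mss), 1, tolerance = 1e-12)
    anti <- scan_promoter(anticonsensus_of(p), p, cutoff = 0)
    expect_equal(min(anti$mss[anti$strand == "+"]), 0, tolerance = 1e-12)
  }
})

test_that("window scores match the formula oracle on random PWMs", {
  set.seed(52)
  for (i in 1:20) {
    L <- 8
    p <- random_pwm(L = L)
    seq <- paste(sample(BASES, 40, replace = TRUE), collapse = "")
    hits <- scan_promoter(seq, p, cutoff = 0)
    fwd <- hits[hits$strand == "+", ]
    for (k in sample(nrow(fwd), 3)) {
      win <- strsplit(substr(seq, fwd$position[k], fwd$position[k] + L - 1),
                      "")[[1]]
      expect_equal(fwd$mss[k], oracle_mss(p$freq, win), tolerance = 1e-12)
    }
  }
})

test_that("MSS never decreases when a base is swapped for a likelier one", {
  set.seed(53)
  for (i in 1:30) {
    p <- random_pwm(L = 6)
    win <- sample(BASES, 6, replace = TRUE)
    pos <- sample(6, 1)
    f <- p$freq[, pos]
    better <- names(f)[f >= f[[win[pos]]]]
    win2 <- win; win2[pos] <- sample(better, 1)
    expect_gte(oracle_mss(p$freq, win2) - oracle_mss(p$freq, win), -1e-12)
  }
})

test_that("scanning the reverse complement mirrors hits exactly", {
  set.seed(54)
  for (i in 1:10) {
    p <- random_pwm(L = 7)
    s <- paste(sample(BASES, 60, replace = TRUE), collapse = "")
    a <- scan_promoter(s, p, cutoff = 0.3)
    b <- scan_promoter(revcomp_seq(s), p, cutoff = 0.3)
    # mirror b back onto the original coordinates
    b$position <- nchar(s) - (b$position + 7 - 1) + 1
    b$strand <- ifelse(b$strand == "+", "-", "+")
    key <- function(d) d[order(d$position, d$strand), c("position", "strand",
                                                        "mss", "css")]
    ka <- key(a); kb <- key(b)
    rownames(ka) <- rownames(kb) <- NULL
    expect_equal(kb, ka, tolerance = 1e-12)
  }
})

test_that("N-containing windows and short sequences never match", {
  p <- consensus_pwm("ACGTAC")
  withN <- sub("^ACGTAC", "ACNTAC", "ACNTACGGGGGG")
  hits <- scan_promoter(withN, p, cutoff = 0)
  expect_false(1 %in% hits$position[hits$strand == "+"])
  expect_equal(nrow(scan_promoter("ACG", p)), 0L)
})

test_that("planted motifs are detected as over-represented, absent ones are not", {
  cf <- promoter_fixture_config(seq_length = 300, n_targets = 30,
                                n_background = 120, fraction = 0.8)
  fx <- generate_promoter_fixture(cf, seed = 61)
  en <- motif_enrichment(fx$targets, fx$background, fx$pwm,
                         n_draws = 300, seed = 62)
  expect_lt(en$p, 0.05)
  expect_gt(en$observed_hits, en$background_mean)

  cf0 <- promoter_fixture_config(seq_length = 300, n_targets = 30,
                                 n_background = 120, fraction = 0)
  fx0 <- generate_promoter_fixture(cf0, seed = 63)
  en0 <- motif_enrichment(fx0$targets, fx0$background, fx0$pwm,
                          n_draws = 300, seed = 64)
  expect_gt(en0$p, 0.05)

  small <- promoter_set(c(b1 = "ACGTACGTAC"))
  expect_error(motif_enrichment(fx$targets, small, fx$pwm), "at least as many")
})

test_that("minSum cutoff behaves at the limits and matches a grid oracle", {
  set.seed(65)
  bg <- promoter_set(setNames(
    vapply(1:40, function(i)
      paste(sample(BASES, 200, replace = TRUE), collapse = ""), character(1)),
    paste0("b", 1:40)))

  sharp <- consensus_pwm("TGACGTCATGCA", hi = 1000, lo = 0)
  expect_gte(minsum_cutoff(sharp, bg, n_positive = 200, seed = 1), 0.95)

  flat <- pwm(matrix(25, 4, 8), motif_id = "flat")
  expect_equal(as.numeric(minsum_cutoff(flat, bg, n_positive = 50, seed = 1)),
               1.00)

  # moderate-information matrix: replicate the grid search independently
  mod <- consensus_pwm("ACGTACGT", hi = 60, lo = 40 / 3)
  cut <- minsum_cutoff(mod, bg, n_positive = 300, seed = 9)
  tab <- attr(cut, "table")
  tot <- tab$fn_pct + tab$fp_pct
  best <- max(which(abs(tot - min(tot)) <= 1e-12))
  expect_equal(as.numeric(cut), tab$cutoff[best])
  expect_true(all(diff(tab$fn_pct) >= 0))   # FN grows with the cutoff
  expect_true(all(diff(tab$fp_pct) <= 0))   # FP shrinks with the cutoff
})

test_that("network edges require enrichment, expression and a promoter hit", {
  # unbalanced design (8 + 4 replicates) keeps the virtual median cell inside
  # the reference tissue, so a +2 log2 plant passes the twofold filter
  set.seed(71)
  genes <- sprintf("g%03d", 1:300)
  tissue <- rep(c("tA", "tB"), c(8, 4))
  v <- matrix(rnorm(300 * 12, sd = 0.25), 300, 12,
              dimnames = list(genes, paste0("s", 1:12)))
  v <- v + rnorm(300)
  members <- genes[1:12]
  tf1 <- "g290"; tf2 <- "g291"; tf3 <- "g292"
  t2cols <- tissue == "tB"
  v[members, t2cols] <- v[members, t2cols] + 2
  v[tf1, t2cols] <- v[tf1, t2cols] + 2   # tf1, tf3 upregulated in tB
  v[tf3, t2cols] <- v[tf3, t2cols] + 2   # tf2 stays flat
  sets <- list(path = members)
  for (k in 1:4) sets[[paste0("decoy", k)]] <- sample(genes[13:289], 12)
  sets <- gene_sets(sets)
  expr <- expression_matrix(v, tissue)
  fit <- heteropath(expr, sets, n_perm = 300, seed = 72)
  sig <- summary(fit)
  expect_lt(sig[sig$set == "path" & sig$tissue == "tB", "q"][1], 0.05)

  # promoters: plant the exact consensus in 8 of the 12 member genes
  set.seed(73)
  cons <- "TGACGTCATGCA"
  seqs <- vapply(members, function(g)
    paste(sample(BASES, 300, replace = TRUE), collapse = ""), character(1))
  carriers <- members[1:8]
  for (g in carriers)
    substr(seqs[g], 101, 112) <- cons
  proms <- promoter_set(seqs)
  motif <- consensus_pwm(cons, id = "motifX")
  hits <- scan_promoters(proms, motif, cutoff = 0.7)
  enr <- data.frame(motif_id = "motifX", p = 0.002)
  tf_map <- data.frame(tf = c(tf1, tf2, tf3),
                       motif_id = "motifX",
                       evidence = c("annotated", "putative", "putative"))

  edges <- build_network(fit, tf_map, enr, hits)
  # the unexpressed factor emits nothing
  expect_false(tf2 %in% edges$tf)
  # both expressed factors sharing the motif emit the same target list
  pass_members <- members[fit$stats$pass_fc[members, "tB"]]
  expected_targets <- intersect(pass_members, unique(hits$gene_id))
  for (tf in c(tf1, tf3))
    expect_setequal(edges$target[edges$tf == tf], expected_targets)
  expect_true(all(edges$tissue == "tB"))
  expect_equal(unique(edges$evidence[edges$tf == tf1]), "annotated")

  # gating on enrichment: a non-enriched motif yields no edges
  edges0 <- build_network(fit, tf_map, data.frame(motif_id = "motifX",
                                                  p = 0.5), hits)
  expect_equal(nrow(edges0), 0L)
  expect_error(build_network(fit, tf_map[0, ], enr, hits), "empty tf_motif_map")
})
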
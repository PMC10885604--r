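gene_table <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    transcript_id = sprintf("g%04d", seq_len(n)),
    avg_gini = runif(n, 0.1, 0.9),
    rpkm = rlnorm(n, 3, 1),
    half_life = rlnorm(n, 1, 0.5),
    gc_content = runif(n, 20, 50),
    polya_len = round(rlnorm(n, log(80), 0.3)),
    mirna_target = runif(n) < 0.2
  )
}

test_that("decile classification gives exact class sizes and a sort-oracle match", {
  tb <- gene_table(100)
  cl <- classify_deciles(tb, "avg_gini", q = 0.1)
  expect_equal(as.integer(table(cl$avg_gini_class)[c("high", "low", "mid")]),
               c(10L, 10L, 80L))
  ord <- tb$transcript_id[order(tb$avg_gini, tb$transcript_id)]
  expect_setequal(cl$transcript_id[cl$avg_gini_class == "high"], utils::tail(ord, 10))
  expect_setequal(cl$transcript_id[cl$avg_gini_class == "low"], utils::head(ord, 10))
})

test_that("boundary ties are broken deterministically by transcript id", {
  tb <- gene_table(30)
  tb$avg_gini <- 0.5
  cl <- classify_deciles(tb, "avg_gini", q = 0.1)
  expect_equal(sum(cl$avg_gini_class == "high"), 3L)
  expect_equal(sum(cl$avg_gini_class == "low"), 3L)
  expect_equal(sort(cl$transcript_id[cl$avg_gini_class == "low"]),
               sort(tb$transcript_id)[1:3])
  expect_identical(classify_deciles(tb, "avg_gini"),
                   classify_deciles(tb, "avg_gini"))
  # relabeling labeled records changes nothing
  expect_identical(classify_deciles(cl, "avg_gini"), cl)
  expect_error(classify_deciles(tb[1:5, ], "avg_gini"), "at least 10")
})

test_that("group comparisons match library tests and quantile oracles", {
  tb <- gene_table(100)
  cl <- classify_deciles(tb, "avg_gini")
  gc <- group_compare(cl, "avg_gini_class", "rpkm", test = "ranksum")
  hi <- cl$rpkm[cl$avg_gini_class == "high"]
  lo <- cl$rpkm[cl$avg_gini_class == "low"]
  expect_equal(gc$p_value, wilcox.test(hi, lo)$p.value)
  expect_equal(gc$summary$median, c(median(hi), median(lo)))
  expect_equal(gc$summary$q25,
               c(quantile(hi, 0.25, names = FALSE), quantile(lo, 0.25, names = FALSE)))

  # identical groups: p near 1
  same <- tibble::tibble(g = rep(c("a", "b"), each = 50), v = rep(1:50, 2))
  expect_gt(group_compare(same, "g", "v", groups = c("a", "b"))$p_value, 0.9)

  # strong shift: tiny p, for both tests
  set.seed(2)
  shifted <- tibble::tibble(g = rep(c("a", "b"), each = 50),
                            v = c(rnorm(50), rnorm(50, 5)))
  expect_lt(group_compare(shifted, "g", "v", groups = c("a", "b"))$p_value, 1e-6)
  expect_lt(group_compare(shifted, "g", "v", test = "ks",
                          groups = c("a", "b"))$p_value, 1e-6)

  expect_error(group_compare(same[same$g == "a", ], "g", "v",
                             groups = c("a", "b")), "non-empty")
  # tidy/glance surface the summaries
  expect_equal(tidy(gc), gc$summary)
  expect_equal(glance(gc)$p_value, gc$p_value)
})

test_that("correlation handles exact, permuted and degenerate input", {
  tb <- tibble::tibble(transcript_id = letters[1:10], x = 1:10, y = -(1:10))
  ct <- correlate(tb, "x", "y")
  expect_equal(ct$r, -1)

  set.seed(3)
  n <- 300
  perm <- tibble::tibble(x = rnorm(n), y = sample(rnorm(n)))
  cp <- correlate(perm, "x", "y")
  expect_lt(abs(cp$r), 0.15)
  expect_gt(cp$p_value, 0.01)

  degen <- tibble::tibble(x = rep(1, 5), y = rnorm(5))
  expect_warning(cd <- correlate(degen, "x", "y"), "degenerate")
  expect_true(is.na(cd$r))
  expect_error(correlate(tb[1:2, ], "x", "y"), "at least 3")
})

test_that("the average-Gini threshold filter is a plain subset", {
  tb <- gene_table(50)
  expect_equal(nrow(suppressMessages(gini_threshold_filter(tb, 0))), 50)
  expect_equal(nrow(suppressMessages(gini_threshold_filter(tb, 1))), 0)
  got <- suppressMessages(gini_threshold_filter(tb, 0.4))
  expect_identical(got, tb[tb$avg_gini > 0.4, ])
})

test_that("median stratification keeps the contrast when the covariate is independent", {
  set.seed(4)
  n <- 400
  tb <- tibble::tibble(
    transcript_id = sprintf("g%04d", 1:n),
    avg_gini = runif(n, 0.1, 0.9),
    gc_content = runif(n, 20, 50)
  )
  tb$rpkm <- exp(4 - 2 * tb$avg_gini + rnorm(n, 0, 0.3))
  cl <- classify_deciles(tb, "avg_gini")
  names(cl)[names(cl) == "avg_gini_class"] <- "avg_gini_class"
  strat <- stratified_confounder(cl, "gc_content")
  expect_equal(nrow(strat), 2)
  expect_true(all(strat$evaluable))
  expect_true(all(strat$median_low > strat$median_high))
  expect_lte(abs(sum(cl$gc_content >= strat$cutoff[1]) -
                 sum(cl$gc_content < strat$cutoff[1])), 1)

  # adversarial: covariate is the structure score itself; within strata the
  # high/low classes collapse to one side, so the contrast is unevaluable
  cl2 <- dplyr::mutate(cl, gc_content = avg_gini)
  strat2 <- stratified_confounder(cl2, "gc_content")
  expect_true(any(!strat2$evaluable))
})

test_that("gc_content counts G and C over non-N bases", {
  expect_equal(gc_content("GCGC"), 100)
  expect_equal(gc_content("AUAU"), 0)
  expect_equal(gc_content("ACGU"), 50)
  expect_equal(gc_content("ACGN"), 100 * 2 / 3)
  set.seed(5)
  s <- random_rna(500)
  chars <- strsplit(s, "")[[1]]
  expect_equal(gc_content(s), 100 * mean(chars %in% c("G", "C")))
})

test_that("RG4 prediction matches the canonical motif and the exhaustive oracle", {
  hit <- predict_rg4("GGGAGGGUGGGAGGG")
  expect_equal(nrow(hit), 1)
  expect_equal(hit$start0, 0L)
  expect_equal(hit$end0, 15L)

  expect_equal(nrow(predict_rg4("GGAGGAGGAGG", min_g = 3)), 0)
  expect_equal(nrow(predict_rg4("GGAGGAGGAGG", min_g = 2)), 1)

  set.seed(6)
  for (i in 1:3) {
    s <- paste(sample(c("A", "C", "G", "U"), 10000, replace = TRUE,
                      prob = c(0.2, 0.2, 0.4, 0.2)), collapse = "")
    got <- predict_rg4(s)
    want <- rg4_oracle(s)
    expect_equal(got$start0, want$start0)
    expect_equal(got$end0, want$end0)
  }
})

test_that("half-life fitting recovers exact and noisy decay rates", {
  f <- fit_half_life(c(0, 1, 2), c(1, 0.5, 0.25))
  expect_equal(f$t_half, 1.0, tolerance = 1e-12)
  expect_equal(f$k, log(2), tolerance = 1e-12)

  expect_warning(flat <- fit_half_life(c(0, 1, 2, 3), rep(1, 4)),
                 "non-positive")
  expect_true(is.na(flat$t_half))

  expect_error(fit_half_life(c(0, 1), c(1, 0.5)), "3 timepoints")
  expect_error(fit_half_life(c(1, 2, 3), c(1, 0.5, 0.2)), "t = 0")

  # recovery: k = 0.3/h with lognormal noise, 100 replicate curves
  set.seed(7)
  t <- c(0, 1, 2, 4, 6, 8)
  ks <- replicate(100, {
    a <- exp(-0.3 * t + rnorm(length(t), 0, 0.05))
    fit_half_life(t, a)$k
  })
  expect_lt(abs(mean(ks) - 0.3) / 0.3, 0.1)

  many <- tidyr::crossing(gene_id = c("a", "b"), time_h = t) |>
    dplyr::mutate(rel_abundance = exp(-0.5 * time_h))
  hl <- fit_half_lives(many)
  expect_equal(hl$t_half, rep(log(2) / 0.5, 2), tolerance = 1e-8)
})

test_that("miRNA-target fractions tabulate per class with a proportion test", {
  tb <- classify_deciles(gene_table(100), "avg_gini")
  tb$mirna_target <- FALSE
  mo <- mirna_overlap_summary(tb)
  expect_true(all(mo$summary$fraction == 0))

  set.seed(8)
  tb2 <- classify_deciles(gene_table(200, seed = 9), "avg_gini")
  mo2 <- mirna_overlap_summary(tb2)
  counts <- table(tb2$avg_gini_class, tb2$mirna_target)
  expect_equal(mo2$summary$n_target[mo2$summary$class == "high"],
               unname(counts["high", "TRUE"]))
  # flags independent of class: typically non-significant
  expect_gt(mo2$p_value, 0.05)
})
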
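test_that("count_mismatches counts aligned bases and substitutions", {
  ref <- c(tx1 = "ACGUACGUAC")
  reads <- tibble::tibble(
    transcript_id = "tx1",
    start0 = c(rep(0L, 10), rep(2L, 4)),
    seq = c(rep("ACGU", 10), rep("GUAC", 4))  # GUAC matches ref[2:6)
  )
  p <- count_mismatches(reads, ref)
  expect_equal(p$coverage[1:2], c(10L, 10L))
  expect_equal(p$coverage[3:4], c(14L, 14L))
  expect_equal(sum(p$mismatch), 0L)

  # 100 reads, 7 carrying a substitution at position 2 (0-based)
  reads2 <- tibble::tibble(
    transcript_id = "tx1", start0 = 0L,
    seq = c(rep("ACGU", 93), rep("ACAU", 7)))
  p2 <- count_mismatches(reads2, ref)
  expect_equal(p2$coverage[3], 100L)
  expect_equal(p2$mismatch[3], 7L)

  # N bases drop out of both coverage and mismatch counts
  p3 <- count_mismatches(tibble::tibble(transcript_id = "tx1", start0 = 0L,
                                        seq = "ANGU"), ref)
  expect_equal(p3$coverage[2], 0L)

  expect_error(count_mismatches(
    tibble::tibble(transcript_id = "tx1", start0 = 8L, seq = "ACGU"), ref),
    "tx1")
})

test_that("pileup serialization round-trips through TSV", {
  cfg <- tiny_config(n_genes = 2, seed = 4)
  p <- simulate_pileup(simulate_transcripts(cfg), cfg, treated = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pileup(p, path)
  expect_equal(as.data.frame(read_pileup(path)), as.data.frame(p))
})

test_that("raw reactivity is the mismatch rate with coverage masking", {
  p <- tibble::tibble(transcript_id = "t", pos0 = 0:3,
                      ref_base = c("A", "C", "G", "U"),
                      coverage = c(100L, 0L, 50L, 200L),
                      mismatch = c(5L, 0L, 2L, 20L), sample = "s")
  r <- raw_reactivity(p, min_coverage = 20)
  expect_equal(r$raw, c(0.05, NA, 0.04, 0.1))
  expect_equal(r$mask_reason, c(NA, "low_coverage", NA, NA))
  # full-profile vector oracle
  cfg <- tiny_config(n_genes = 1, seed = 6)
  sim <- simulate_pileup(simulate_transcripts(cfg), cfg, treated = TRUE)
  r2 <- raw_reactivity(sim, min_coverage = 20)
  manual <- ifelse(sim$coverage >= 20, sim$mismatch / sim$coverage, NA)
  expect_equal(r2$raw, manual)
})

test_that("background subtraction floors at zero and respects masks", {
  mk <- function(raw, mask = NULL) {
    mask <- mask %||% rep(NA_character_, length(raw))
    tibble::tibble(transcript_id = "t", pos0 = seq_along(raw) - 1L,
                   ref_base = "A", coverage = 100L,
                   mismatch = 0L, raw = ifelse(is.na(mask), raw, NA_real_),
                   mask_reason = mask)
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  tr <- mk(c(0.05, 0.001, 0.03))
  un <- mk(c(0.01, 0.002, 0))
  corr <- subtract_background(tr, un)
  expect_equal(corr$corrected, c(0.04, 0.0, 0.03))
  # untreated all zero leaves treated unchanged
  un0 <- mk(c(0, 0, 0))
  expect_equal(subtract_background(tr, un0)$corrected, tr$raw)
  # masked on either side stays masked
  un_m <- mk(c(0.01, 0.002, 0), mask = c(NA, "low_coverage", NA))
  expect_equal(subtract_background(tr, un_m)$corrected, c(0.04, NA, 0.03))
  expect_error(
    subtract_background(tr, dplyr::mutate(un, transcript_id = "other")),
    "does not cover")
})

test_that("normalization divides by the top-5% median and caps at 1", {
  # 20 values, single max 0.8: top 5% is one value, median 0.8
  vals <- c(0.8, seq(0.01, 0.4, length.out = 19))
  x <- tibble::tibble(transcript_id = "t", pos0 = seq_along(vals) - 1L,
                      ref_base = "A", coverage = 1000L, mismatch = 0L,
                      raw = vals, mask_reason = NA_character_,
                      corrected = vals)
  nx <- normalize_reactivity(x)
  expect_equal(nx$normalized, pmin(1, vals / 0.8))
  expect_equal(max(nx$normalized), 1.0)

  # constant positive vector: every value is the scale, all become 1
  xc <- dplyr::mutate(x, corrected = 0.3)
  expect_true(all(normalize_reactivity(xc)$normalized == 1))

  # scale invariance
  x10 <- dplyr::mutate(x, corrected = corrected * 10)
  expect_equal(normalize_reactivity(x10)$normalized, nx$normalized)

  # idempotence (up to the cap)
  renorm <- normalize_reactivity(
    dplyr::mutate(nx, corrected = normalized))
  expect_equal(renorm$normalized, nx$normalized)

  # all-zero scale: warning and zeros
  x0 <- dplyr::mutate(x, corrected = 0)
  expect_warning(n0 <- normalize_reactivity(x0), "zero")
  expect_true(all(n0$normalized == 0))

  # too few unmasked positions is refused (or dropped on request)
  small <- dplyr::slice(x, 1:10)
  expect_error(normalize_reactivity(small), "fewer than")
  expect_message(
    dropped <- normalize_reactivity(small, on_few = "drop"), "dropping")
  expect_equal(nrow(dropped), 0)
})

test_that("the full chain matches step-by-step brute force on random profiles", {
  set.seed(99)
  for (rep in 1:5) {
    n <- 200
    cov_t <- sample(0:400, n, replace = TRUE)
    mm_t <- rbinom(n, cov_t, 0.03)
    cov_u <- sample(0:400, n, replace = TRUE)
    mm_u <- rbinom(n, cov_u, 0.005)
    mk <- function(cov, mm, lab) {
      tibble::tibble(transcript_id = "t", pos0 = 0:(n - 1),
                     ref_base = sample(c("A", "C", "G", "U"), n, TRUE),
                     coverage = cov, mismatch = mm, sample = lab)
    }
    got <- dms_reactivity(mk(cov_t, mm_t, "T"), mk(cov_u, mm_u, "U"),
                          min_coverage = 20)
    want <- chain_brute(cov_t, mm_t, cov_u, mm_u, min_coverage = 20)
    expect_equal(got$raw, want$raw, tolerance = 1e-12)
    expect_equal(got$corrected, want$corrected, tolerance = 1e-12)
    expect_equal(got$normalized, want$normalized, tolerance = 1e-12)
  }
})

test_that("normalized reactivity separates unpaired A/C from G/U on synthetic data", {
  cfg <- tiny_config(n_genes = 6, seed = 21)
  ex <- simulate_probing_experiment(cfg)
  r <- dms_reactivity(ex$treated, ex$untreated, min_coverage = 20,
                      on_few = "drop")
  ac <- r$ref_base %in% c("A", "C")
  expect_gt(mean(r$normalized[ac], na.rm = TRUE),
            mean(r$normalized[!ac], na.rm = TRUE))
})

test_that("replicate merging sums counts", {
  p <- tibble::tibble(transcript_id = "t", pos0 = c(0L, 1L),
                      ref_base = c("A", "C"), coverage = c(10L, 20L),
                      mismatch = c(1L, 2L), sample = "r1")
  m <- merge_pileups(p, dplyr::mutate(p, sample = "r2"))
  expect_equal(m$coverage, c(20L, 40L))
  expect_equal(m$mismatch, c(2L, 4L))
})
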
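flat_profile <- function(id, L, value = 0.5, bases = NULL) {
  tibble::tibble(transcript_id = id, pos0 = 0:(L - 1),
                 ref_base = bases %||% rep_len(c("A", "C", "G", "U"), L),
                 coverage = 1000L, mismatch = 50L, raw = value,
                 corrected = value, normalized = value,
                 mask_reason = NA_character_)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

ann_for <- function(id, cds_len = 150L, utr_len = 150L) {
  tibble::tibble(transcript_id = id, cds_start = 0L,
                 stop_codon_start = cds_len - 3L, utr3_start = cds_len,
                 utr3_end = cds_len + utr_len)
}

test_that("uniform reactivities give a flat meta-gene profile", {
  prof <- dplyr::bind_rows(flat_profile("a", 300), flat_profile("b", 300))
  ann <- dplyr::bind_rows(ann_for("a"), ann_for("b"))
  mg <- metagene_stop_profile(prof, ann, flank = 100)
  expect_equal(nrow(mg$profile), 203)
  expect_true(all(mg$profile$mean_reactivity == 0.5))
  expect_equal(range(mg$profile$rel_pos), c(-100, 102))
  expect_equal(mg$n_used, 2)
  expect_equal(sum(mg$profile$region == "stop"), 3)
  # nucleotide frequencies sum to one per position
  freq_sum <- with(mg$profile, freq_A + freq_C + freq_G + freq_U)
  expect_equal(freq_sum, rep(1, 203))
})

test_that("a single transcript reproduces its own values", {
  prof <- flat_profile("a", 300)
  prof$normalized <- seq(0, 1, length.out = 300)
  mg <- metagene_stop_profile(prof, ann_for("a"), flank = 100)
  stop0 <- 147
  expect_equal(mg$profile$mean_reactivity,
               prof$normalized[(stop0 - 100):(stop0 + 102) + 1])
})

test_that("transcripts failing the flank requirement are skipped and counted", {
  prof <- dplyr::bind_rows(flat_profile("a", 300), flat_profile("b", 180))
  ann <- dplyr::bind_rows(ann_for("a"), ann_for("b", utr_len = 30L))
  mg <- metagene_stop_profile(prof, ann, flank = 100)
  expect_equal(mg$n_used, 1)
  expect_equal(mg$n_skipped, 1)
  expect_error(metagene_stop_profile(flat_profile("b", 120),
                                     ann_for("b", cds_len = 50L), flank = 100),
               "flank")
})

test_that("structured CDS flank vs unpaired UTR yields higher UTR reactivity", {
  cfg <- sim_config(n_genes = 12, utr_length_range = c(150L, 200L),
                    pairing_fraction_levels = 0.1,
                    cds_pairing_fraction = 0.8, seed = 31)
  ex <- simulate_probing_experiment(cfg)
  r <- dms_reactivity(ex$treated, ex$untreated, min_coverage = 20,
                      on_few = "drop")
  mg <- metagene_stop_profile(r, ex$transcripts, flank = 100)
  expect_gt(mg$cds_vs_utr$utr_mean, mg$cds_vs_utr$cds_mean)
  expect_lt(mg$cds_vs_utr$p_value, 0.05)
})

test_that("codon-position means are equal for uniform input and track a planted frame", {
  prof <- flat_profile("a", 300)
  cp <- codon_position_reactivity(prof, ann_for("a"), flank = 100)
  expect_equal(nrow(cp), 6)
  expect_true(all(cp$mean_reactivity == 0.5))

  # boost frame position 3 on the CDS side only
  prof2 <- flat_profile("a", 300)
  stop0 <- 147
  rel <- prof2$pos0 - stop0
  boost <- rel < 0 & rel >= -99 & (rel %% 3) == 2
  prof2$normalized[boost] <- 0.9
  cp2 <- codon_position_reactivity(prof2, ann_for("a"), flank = 100)
  cds <- cp2[cp2$region == "cds", ]
  utr <- cp2[cp2$region == "utr3", ]
  expect_gt(cds$mean_reactivity[cds$codon_pos == 3],
            max(cds$mean_reactivity[cds$codon_pos != 3]))
  expect_equal(length(unique(utr$mean_reactivity)), 1L)
})

test_that("fully masked UTR side gives missing UTR means", {
  prof <- flat_profile("a", 300)
  utr_sel <- prof$pos0 >= 150
  prof$normalized[utr_sel] <- NA
  prof$mask_reason[utr_sel] <- "low_coverage"
  cp <- codon_position_reactivity(prof, ann_for("a"), flank = 100)
  utr <- cp[cp$region == "utr3", ]
  expect_true(all(is.na(utr$mean_reactivity)))
  expect_true(all(utr$n == 0))
})
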
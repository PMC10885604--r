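#' Meta-gene reactivity profile around stop codons
#'
#' Aligns transcripts by their stop codons and averages reactivity at each
#' relative position over a CDS flank, the stop codon itself, and a 3' UTR
#' flank. Transcripts with less than `flank` nt of CDS upstream of the stop
#' codon or less than `flank` nt of 3' UTR downstream are skipped and
#' counted. The stop codon's three positions belong to neither flank mean.
#' Per-position nucleotide frequencies are reported alongside, and the CDS-
#' vs UTR-side reactivities are compared with a two-sided rank-sum test.
#'
#' @param reactivity Reactivity tibble over whole transcripts (the
#'   `normalized` column is used when present, otherwise `raw`).
#' @param annotations Tibble with `transcript_id`, `cds_start`,
#'   `stop_codon_start`, `utr3_start`, `utr3_end` (0-based, half-open).
#' @param flank Flank length in nt on each side of the stop codon.
#' @return A list of class `metagene_profile`: `profile` (tibble with
#'   `rel_pos` from `-flank` to `flank + 2`, `region`, `mean_reactivity`,
#'   `n`, and `freq_A`/`freq_C`/`freq_G`/`freq_U`), `cds_vs_utr` (means,
#'   rank-sum statistic and p-value), `n_used`, `n_skipped`.
#' @export
metagene_stop_profile <- function(reactivity, annotations, flank = 100L) {
  x <- as_tibble(reactivity)
  value_col <- if ("normalized" %in% names(x)) "normalized" else "raw"
  ann <- as_tibble(annotations) %>%
    mutate(ok = (.data$stop_codon_start - .data$cds_start) >= flank &
             (.data$utr3_end - .data$utr3_start) >= flank)
  n_skipped <- sum(!ann$ok)
  ann <- filter(ann, .data$ok)
  if (nrow(ann) == 0) abort("no transcript satisfies the flank requirement")

  aligned <- x %>%
    dplyr::inner_join(select(ann, "transcript_id", "stop_codon_start"),
                      by = "transcript_id") %>%
    mutate(rel_pos = .data$pos0 - .data$stop_codon_start) %>%
    filter(.data$rel_pos >= -flank, .data$rel_pos <= flank + 2L)

  profile <- aligned %>%
    group_by(.data$rel_pos) %>%
    summarise(
      mean_reactivity = if (any(!is.na(.data[[value_col]]))) {
        mean(.data[[value_col]], na.rm = TRUE)
      } else NA_real_,
      n = sum(!is.na(.data[[value_col]])),
      freq_A = mean(.data$ref_base == "A"),
      freq_C = mean(.data$ref_base == "C"),
      freq_G = mean(.data$ref_base == "G"),
      freq_U = mean(.data$ref_base %in% c("U", "T")),
      .groups = "drop"
    ) %>%
    mutate(region = dplyr::case_when(
      .data$rel_pos < 0 ~ "cds",
      .data$rel_pos <= 2 ~ "stop",
      TRUE ~ "utr3"
    )) %>%
    select("rel_pos", "region", dplyr::everything())

  cds_vals <- aligned %>% filter(.data$rel_pos < 0) %>% pull(value_col)
  utr_vals <- aligned %>% filter(.data$rel_pos > 2) %>% pull(value_col)
  cds_vals <- cds_vals[!is.na(cds_vals)]
  utr_vals <- utr_vals[!is.na(utr_vals)]
  wt <- wilcox.test(utr_vals, cds_vals)
  out <- list(
    profile = profile,
    cds_vs_utr = list(cds_mean = mean(cds_vals), utr_mean = mean(utr_vals),
                      statistic = unname(wt$statistic), p_value = wt$p.value),
    n_used = nrow(ann),
    n_skipped = n_skipped,
    flank = flank
  )
  class(out) <- "metagene_profile"
  out
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat("<metagene_profile> ", x$n_used, " transcripts (", x$n_skipped,
      " skipped), flank ", x$flank, " nt\n", sep = "")
  cat(sprintf("  mean reactivity CDS %.4f vs 3' UTR %.4f (rank-sum p = %.3g)\n",
              x$cds_vs_utr$cds_mean, x$cds_vs_utr$utr_mean,
              x$cds_vs_utr$p_value))
  invisible(x)
}

#' Mean reactivity by codon position
#'
#' Averages reactivity at the first, second and third nucleotide of codons
#' on the CDS side (frame anchored on the stop codon, complete codons within
#' `flank` nt upstream) and of consecutive triplets on the 3' UTR side
#' (frame starting at the base just downstream of the stop codon). Coding
#' sequence shows third-position enrichment of DMS reactivity (translating
#' ribosomes and wobble constraints); the UTR side has no frame, so the
#' periodicity disappears there.
#'
#' @inheritParams metagene_stop_profile
#' @return Tibble: `region` (`cds`/`utr3`), `codon_pos` (1-3),
#'   `mean_reactivity`, `n`; means are `NA` where no unmasked positions
#'   remain.
#' @export
codon_position_reactivity <- function(reactivity, annotations, flank = 100L) {
  x <- as_tibble(reactivity)
  value_col <- if ("normalized" %in% names(x)) "normalized" else "raw"
  ann <- as_tibble(annotations)
  aligned <- x %>%
    dplyr::inner_join(
      select(ann, "transcript_id", "stop_codon_start", "cds_start",
             "utr3_start", "utr3_end"),
      by = "transcript_id") %>%
    mutate(rel_pos = .data$pos0 - .data$stop_codon_start)

  n_codons <- floor(flank / 3)
  cds <- aligned %>%
    filter(.data$rel_pos < 0, .data$rel_pos >= -3 * n_codons,
           .data$pos0 >= .data$cds_start) %>%
    mutate(codon_pos = (.data$rel_pos %% 3) + 1L, region = "cds")
  utr <- aligned %>%
    filter(.data$rel_pos > 2, .data$rel_pos <= 2 + 3 * n_codons,
           .data$pos0 < .data$utr3_end) %>%
    mutate(codon_pos = ((.data$rel_pos - 3L) %% 3) + 1L, region = "utr3")

  bind_rows(cds, utr) %>%
    group_by(.data$region, .data$codon_pos) %>%
    summarise(
      mean_reactivity = if (any(!is.na(.data[[value_col]]))) {
        mean(.data[[value_col]], na.rm = TRUE)
      } else NA_real_,
      n = sum(!is.na(.data[[value_col]])),
      .groups = "drop"
    ) %>%
    tidyr::complete(region = c("cds", "utr3"), codon_pos = 1:3,
                    fill = list(mean_reactivity = NA_real_, n = 0L))
}
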
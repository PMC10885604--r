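#' Count per-base coverage and mismatches from aligned reads
#'
#' Builds a per-base pileup from gap-free aligned read segments. Each read
#' row gives the transcript it maps to, its 0-based start, and the read
#' sequence as aligned (substitutions only; reads with indels should be
#' excluded upstream). Coverage counts every aligned base, mismatches count
#' aligned bases differing from the reference; positions where either the
#' read or the reference carries `N` contribute to neither.
#'
#' @param reads Tibble with columns `transcript_id`, `start0`, `seq`.
#' @param reference Named character vector of reference sequences (RNA or
#'   DNA), or a tibble with `transcript_id` and `sequence`.
#' @param sample_label Label stored in the `sample` column.
#' @return A pileup tibble: `transcript_id`, `pos0`, `ref_base`, `coverage`,
#'   `mismatch`, `sample`, one row per reference position.
#' @examples
#' ref <- c(tx1 = "ACGUACGU")
#' reads <- tibble::tibble(transcript_id = "tx1", start0 = c(0, 2),
#'                         seq = c("ACGU", "GUAC"))
#' count_mismatches(reads, ref)
#' @export
count_mismatches <- function(reads, reference, sample_label = "sample") {
  if (is.data.frame(reference)) {
    reference <- setNames(reference$sequence, reference$transcript_id)
  }
  reads <- as_tibble(reads)
  missing_tx <- setdiff(unique(reads$transcript_id), names(reference))
  if (length(missing_tx) > 0) {
    abort(paste0("reads map to transcripts absent from the reference: ",
                 paste(missing_tx, collapse = ", ")))
  }
  purrr::map(names(reference), function(tx) {
    ref_chars <- strsplit(toupper(reference[[tx]]), "")[[1]]
    L <- length(ref_chars)
    cov <- integer(L)
    mm <- integer(L)
    r <- reads[reads$transcript_id == tx, ]
    for (j in seq_len(nrow(r))) {
      rc <- strsplit(toupper(r$seq[j]), "")[[1]]
      s <- r$start0[j]
      if (s < 0 || s + length(rc) > L) {
        abort(sprintf("read extends outside reference for transcript %s", tx))
      }
      idx <- s + seq_along(rc)
      use <- rc != "N" & ref_chars[idx] != "N"
      cov[idx[use]] <- cov[idx[use]] + 1L
      mism <- use & rc != ref_chars[idx]
      mm[idx[mism]] <- mm[idx[mism]] + 1L
    }
    tibble(transcript_id = tx, pos0 = seq_len(L) - 1L, ref_base = ref_chars,
           coverage = cov, mismatch = mm, sample = sample_label)
  }) %>% bind_rows()
}

#' Merge pileup replicates by summing counts
#'
#' Biological replicates are combined by adding coverage and mismatch counts
#' position-wise before reactivity calculation.
#'
#' @param ... Pileup tibbles with identical positions.
#' @param sample_label Label for the merged sample.
#' @return A single pileup tibble.
#' @export
merge_pileups <- function(..., sample_label = "merged") {
  bind_rows(...) %>%
    group_by(.data$transcript_id, .data$pos0, .data$ref_base) %>%
    summarise(coverage = sum(.data$coverage), mismatch = sum(.data$mismatch),
              .groups = "drop") %>%
    mutate(sample = sample_label) %>%
    arrange(.data$transcript_id, .data$pos0)
}

#' Raw DMS reactivity from a pileup
#'
#' The raw reactivity of a base is the mismatch rate `mismatch / coverage`.
#' Positions with coverage below `min_coverage` are masked
#' (`mask_reason = "low_coverage"`), not errors.
#'
#' @param pileup Pileup tibble (see [count_mismatches()]).
#' @param min_coverage Minimum coverage for a position to be scored.
#'   100 suits deep amplicon data; 20 suits genome-wide libraries.
#' @return A reactivity tibble: `transcript_id`, `pos0`, `ref_base`,
#'   `coverage`, `mismatch`, `raw`, `mask_reason` (`NA` where scored).
#' @export
raw_reactivity <- function(pileup, min_coverage = 100) {
  as_tibble(pileup) %>%
    mutate(
      mask_reason = if_else(.data$coverage < min_coverage,
                            "low_coverage", NA_character_),
      raw = if_else(is.na(.data$mask_reason),
                    .data$mismatch / .data$coverage, NA_real_)
    ) %>%
    select("transcript_id", "pos0", "ref_base", "coverage", "mismatch",
           "raw", "mask_reason")
}

#' Background-correct treated reactivities with an untreated control
#'
#' Subtracts the untreated mismatch rate from the treated one position-wise
#' and floors at zero; a position masked in either sample stays masked.
#' A `"divide"` mode (treated / untreated rate, untreated floor at
#' `background_floor`) is available for pipelines that prefer ratio
#' correction.
#'
#' @param treated,untreated Reactivity tibbles from [raw_reactivity()] over
#'   the same transcripts and positions.
#' @param method `"subtract"` (default) or `"divide"`.
#' @param background_floor Minimum untreated rate used in `"divide"` mode.
#' @return `treated` with a `corrected` column added.
#' @export
subtract_background <- function(treated, untreated,
                                method = c("subtract", "divide"),
                                background_floor = 1e-4) {
  method <- match.arg(method)
  u <- as_tibble(untreated) %>%
    select("transcript_id", "pos0",
           u_raw = "raw", u_mask = "mask_reason")
  joined <- as_tibble(treated) %>% left_join(u, by = c("transcript_id", "pos0"))
  if (anyNA(joined$u_mask) && any(is.na(joined$u_mask) & is.na(joined$u_raw))) {
    missing <- joined %>%
      filter(is.na(.data$u_mask), is.na(.data$u_raw)) %>%
      pull("transcript_id") %>% unique()
    abort(paste0("untreated profile does not cover: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  joined %>%
    mutate(
      mask_reason = dplyr::coalesce(.data$mask_reason, .data$u_mask),
      corrected = dplyr::case_when(
        !is.na(.data$mask_reason) ~ NA_real_,
        method == "subtract" ~ pmax(0, .data$raw - .data$u_raw),
        TRUE ~ .data$raw / pmax(.data$u_raw, background_floor)
      )
    ) %>%
    select(-"u_raw", -"u_mask")
}

#' Normalize reactivities to the median of the top values
#'
#' Per transcript, the scale factor is the median of the top
#' `ceiling(top_fraction * n)` unmasked values (default top 5%); every value
#' is divided by it and ratios above 1.0 are capped at 1.0. Transcripts with
#' fewer than `min_positions` unmasked values cannot be normalized: this is
#' an error by default, or they are dropped (with a message) when
#' `on_few = "drop"`.
#'
#' @param reactivity Reactivity tibble carrying `corrected` (preferred) or
#'   `raw` values.
#' @param top_fraction Fraction of top values whose median sets the scale.
#' @param min_positions Minimum unmasked positions required per transcript.
#' @param on_few `"error"` or `"drop"`.
#' @param trim_outliers If `TRUE`, values above
#'   `Q3 + 1.5 * IQR` of the unmasked values are excluded from the scale
#'   computation (they are still normalized and capped).
#' @return The input with a `normalized` column in `[0, 1]`.
#' @export
normalize_reactivity <- function(reactivity, top_fraction = 0.05,
                                 min_positions = 20,
                                 on_few = c("error", "drop"),
                                 trim_outliers = FALSE) {
  on_few <- match.arg(on_few)
  x <- as_tibble(reactivity)
  value_col <- if ("corrected" %in% names(x)) "corrected" else "raw"
  counts <- x %>%
    group_by(.data$transcript_id) %>%
    summarise(n_ok = sum(!is.na(.data[[value_col]])), .groups = "drop")
  few <- counts$transcript_id[counts$n_ok < min_positions]
  if (length(few) > 0) {
    if (on_few == "error") {
      abort(sprintf(
        "%d transcript(s) have fewer than %d unmasked positions (e.g. %s)",
        length(few), min_positions, few[1]))
    }
    inform(sprintf("dropping %d transcript(s) with < %d unmasked positions",
                   length(few), min_positions))
    x <- x %>% filter(!(.data$transcript_id %in% few))
  }
  scales <- x %>%
    group_by(.data$transcript_id) %>%
    summarise(scale = top_median(.data[[value_col]], top_fraction,
                                 trim_outliers), .groups = "drop")
  if (any(scales$scale == 0)) {
    warn(sprintf(
      "top-value median is zero for %d transcript(s); their normalized reactivities are all 0",
      sum(scales$scale == 0)))
  }
  x %>%
    left_join(scales, by = "transcript_id") %>%
    mutate(normalized = dplyr::case_when(
      is.na(.data[[value_col]]) ~ NA_real_,
      .data$scale == 0 ~ 0,
      TRUE ~ pmin(1, .data[[value_col]] / .data$scale)
    )) %>%
    select(-"scale")
}

# median of the top ceiling(top_fraction * n) unmasked values, optionally
# excluding > Q3 + 1.5 IQR outliers from the pool
top_median <- function(v, top_fraction, trim_outliers = FALSE) {
  pool <- v[!is.na(v)]
  if (trim_outliers && length(pool) > 3) {
    q <- quantile(pool, c(0.25, 0.75), names = FALSE)
    trimmed <- pool[pool <= q[2] + 1.5 * (q[2] - q[1])]
    if (length(trimmed) > 0) pool <- trimmed
  }
  k <- max(1L, ceiling(top_fraction * length(pool)))
  median(sort(pool, decreasing = TRUE)[seq_len(k)])
}

#' Full reactivity chain: raw, background-corrected, normalized
#'
#' Runs [raw_reactivity()] on the treated and untreated pileups,
#' [subtract_background()], then [normalize_reactivity()] per transcript.
#'
#' @param treated,untreated Pileup tibbles.
#' @inheritParams raw_reactivity
#' @inheritParams normalize_reactivity
#' @param background_method Passed to [subtract_background()] as `method`.
#' @return Reactivity tibble with `raw`, `corrected`, `normalized` columns.
#' @examples
#' cfg <- sim_config(n_genes = 2, seed = 1)
#' tx <- simulate_transcripts(cfg)
#' r <- dms_reactivity(simulate_pileup(tx, cfg, TRUE),
#'                     simulate_pileup(tx, cfg, FALSE), min_coverage = 20)
#' head(r)
#' @export
dms_reactivity <- function(treated, untreated, min_coverage = 100,
                           top_fraction = 0.05, min_positions = 20,
                           on_few = c("error", "drop"),
                           background_method = c("subtract", "divide"),
                           trim_outliers = FALSE) {
  on_few <- match.arg(on_few)
  background_method <- match.arg(background_method)
  raw_reactivity(treated, min_coverage) %>%
    subtract_background(raw_reactivity(untreated, min_coverage),
                        method = background_method) %>%
    normalize_reactivity(top_fraction, min_positions, on_few, trim_outliers)
}
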
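#' Gini index of a set of non-negative values
#'
#' Inequality statistic used here as a per-window structure score: reactivity
#' concentrated on a few bases (the hallmark of a structured region, where
#' only loop residues react with DMS) gives a high Gini; evenly spread
#' reactivity gives a low one. Defined as the mean absolute difference
#' between all pairs divided by twice the mean,
#' `G = sum_ij |x_i - x_j| / (2 n^2 xbar)`, computed via the sorted-value
#' identity in O(n log n).
#'
#' @param values Non-negative numeric vector (`NA` dropped).
#' @return G in `[0, (n-1)/n]`, or `NA` when fewer than 2 values remain or
#'   the mean is zero (Gini undefined; callers skip such windows).
#' @examples
#' gini(c(1, 1, 1, 1))        # 0
#' gini(c(0, 0, 0, 1))        # (n-1)/n = 0.75
#' @export
gini <- function(values) {
  x <- values[!is.na(values)]
  if (any(x < 0)) abort("gini() requires non-negative values")
  n <- length(x)
  if (n < 2L || mean(x) == 0) return(NA_real_)
  x <- sort(x)
  sum((2 * seq_len(n) - n - 1) * x) / (n^2 * mean(x))
}

#' Sliding-window Gini index over reactivity profiles
#'
#' Tiles each transcript's scored region into `window_size`-nt windows every
#' `step` nt (full windows only) and computes the Gini index of the
#' normalized reactivities in each window. A window is kept for downstream
#' analysis only if the mean raw mismatch count over all its positions
#' exceeds `mismatch_threshold`, so poorly sequenced windows never
#' contribute. By default the Gini is computed over A/C positions only,
#' since G/U carry no DMS signal.
#'
#' @param reactivity Reactivity tibble (e.g. from [dms_reactivity()]),
#'   already restricted to the region of interest (typically the 3' UTR);
#'   windows are laid out from each transcript's first position.
#' @param window_size,step Window length and offset in nt.
#' @param mismatch_threshold Minimum mean mismatch count per window.
#' @param bases `"AC"` (default) or `"all"`: which positions enter the Gini.
#' @return A tibble of class `gini_windows`: `transcript_id`, `start0`,
#'   `end0` (transcript coordinates, half-open), `gini`, `mean_mismatch`,
#'   `n_used_positions`, `passed`. Transcripts shorter than one window
#'   contribute no rows (with a message).
#' @examples
#' cfg <- sim_config(n_genes = 2, seed = 1)
#' ex <- simulate_probing_experiment(cfg)
#' r <- dms_reactivity(ex$treated, ex$untreated, min_coverage = 20)
#' window_gini(utr_region(r, ex$transcripts))
#' @export
window_gini <- function(reactivity, window_size = 50L, step = 25L,
                        mismatch_threshold = 20, bases = c("AC", "all")) {
  bases <- match.arg(bases)
  x <- as_tibble(reactivity)
  if (!"normalized" %in% names(x)) {
    abort("reactivity must carry a 'normalized' column; run the reactivity chain first")
  }
  short <- 0L
  out <- x %>%
    dplyr::group_split(.data$transcript_id) %>%
    purrr::map(function(tx) {
      tx <- arrange(tx, .data$pos0)
      origin <- tx$pos0[1]
      L <- nrow(tx)
      if (L < window_size) {
        short <<- short + 1L
        return(NULL)
      }
      starts <- seq(0L, L - window_size, by = step)
      purrr::map(starts, function(s) {
        w <- tx[(s + 1):(s + window_size), ]
        inc <- !is.na(w$normalized)
        if (bases == "AC") inc <- inc & w$ref_base %in% c("A", "C")
        tibble(
          transcript_id = tx$transcript_id[1],
          start0 = origin + s,
          end0 = origin + s + window_size,
          gini = gini(w$normalized[inc]),
          mean_mismatch = mean(w$mismatch),
          n_used_positions = sum(inc)
        )
      }) %>% bind_rows()
    }) %>%
    bind_rows()
  if (short > 0) {
    inform(sprintf("%d transcript(s) shorter than one %d-nt window: no windows emitted",
                   short, window_size))
  }
  if (nrow(out) == 0) {
    out <- tibble(transcript_id = character(), start0 = integer(),
                  end0 = integer(), gini = numeric(), mean_mismatch = numeric(),
                  n_used_positions = integer())
  }
  out <- mutate(out, passed = .data$mean_mismatch > mismatch_threshold)
  class(out) <- c("gini_windows", class(out))
  out
}

#' Per-transcript average Gini index
#'
#' Unweighted mean of the window Gini values over passed windows (windows
#' whose Gini is undefined are skipped). Transcripts with no passed window
#' get `NA`.
#'
#' @param windows Output of [window_gini()].
#' @return Tibble: `transcript_id`, `avg_gini`, `n_windows_passed`.
#' @export
average_gini <- function(windows) {
  as_tibble(windows) %>%
    group_by(.data$transcript_id) %>%
    summarise(
      avg_gini = {
        g <- .data$gini[.data$passed & !is.na(.data$gini)]
        if (length(g) == 0) NA_real_ else mean(g)
      },
      n_windows_passed = sum(.data$passed & !is.na(.data$gini)),
      .groups = "drop"
    )
}
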
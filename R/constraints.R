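#' Export a SHAPE-style constraint file for external folding
#'
#' Writes the per-base reactivities of one region as a two-column file
#' (1-based position within the region, reactivity) for use as soft
#' constraints by thermodynamic folding engines. Masked positions and G/U
#' bases (uninformative for DMS) are written as -999 by convention.
#'
#' @param reactivity Reactivity tibble for a single transcript.
#' @param region Length-2 integer vector, 0-based half-open interval in
#'   transcript coordinates (e.g. the 3' UTR interval).
#' @param path Output file path.
#' @param value_col Column to export (default `"normalized"`).
#' @return The exported tibble (`position`, `reactivity`), invisibly.
#' @export
export_constraints <- function(reactivity, region, path,
                               value_col = "normalized") {
  x <- as_tibble(reactivity)
  if (length(unique(x$transcript_id)) != 1L) {
    abort("export_constraints() expects a single-transcript profile")
  }
  if (region[1] < min(x$pos0) || region[2] > max(x$pos0) + 1L) {
    abort(sprintf("region [%d, %d) outside profile positions [%d, %d)",
                  region[1], region[2], min(x$pos0), max(x$pos0) + 1L))
  }
  out <- x %>%
    filter(.data$pos0 >= region[1], .data$pos0 < region[2]) %>%
    arrange(.data$pos0) %>%
    mutate(
      position = .data$pos0 - region[1] + 1L,
      reactivity = dplyr::case_when(
        !is.na(.data$mask_reason) ~ -999,
        !(.data$ref_base %in% c("A", "C")) ~ -999,
        is.na(.data[[value_col]]) ~ -999,
        TRUE ~ .data[[value_col]]
      )
    ) %>%
    select("position", "reactivity")
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(out)
}

#' Read a SHAPE-style constraint file
#'
#' @param path Two-column file written by [export_constraints()].
#' @return Tibble with `position` (1-based) and `reactivity` (-999 denotes
#'   no-data positions).
#' @export
read_constraints <- function(path) {
  readr::read_tsv(path, col_names = c("position", "reactivity"),
                  col_types = "id", progress = FALSE)
}
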
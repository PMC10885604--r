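#' Label the top and bottom deciles of a gene table
#'
#' Adds a `<key>_class` column marking the `floor(q * n)` records with the
#' highest values of `key` as `"high"`, the same number with the lowest as
#' `"low"`, and the rest `"mid"`. Ties at the boundary are broken by
#' `transcript_id` order, so the labeling is deterministic and the class
#' sizes exact. Records with a missing key value are an error: drop or
#' impute them first.
#'
#' @param records Gene-level tibble with a `transcript_id` column.
#' @param key Name of the column to classify on (string), e.g. `"avg_gini"`,
#'   `"half_life"`, or a log2 half-life ratio.
#' @param q Tail fraction (default 0.10: top/bottom deciles).
#' @return `records` with a `<key>_class` factor-like character column.
#' @examples
#' tb <- tibble::tibble(transcript_id = sprintf("g%02d", 1:20),
#'                      avg_gini = seq(0, 0.95, length.out = 20))
#' table(classify_deciles(tb, "avg_gini")$avg_gini_class)
#' @export
classify_deciles <- function(records, key, q = 0.10) {
  x <- as_tibble(records)
  if (nrow(x) < 10) abort("classify_deciles() needs at least 10 records")
  if (anyNA(x[[key]])) {
    abort(sprintf("missing values in '%s'; drop them before classification", key))
  }
  n_tail <- floor(q * nrow(x))
  ord <- order(x[[key]], x$transcript_id)
  cls <- rep("mid", nrow(x))
  if (n_tail > 0) {
    cls[ord[seq_len(n_tail)]] <- "low"
    cls[ord[seq(nrow(x) - n_tail + 1L, nrow(x))]] <- "high"
  }
  x[[paste0(key, "_class")]] <- cls
  x
}

#' Compare a value between two gene classes
#'
#' Two-sided Wilcoxon rank-sum or two-sample Kolmogorov-Smirnov test of
#' `value_field` between two groups of `group_field`, with per-group
#' summaries and ECDF tables for plotting cumulative curves.
#'
#' @param records Gene-level tibble.
#' @param group_field Column holding group labels.
#' @param value_field Column holding the compared value.
#' @param test `"ranksum"` (Wilcoxon) or `"ks"` (Kolmogorov-Smirnov).
#' @param groups Length-2 character vector selecting and ordering the two
#'   compared groups; defaults to `c("high", "low")` when present, else the
#'   two groups in the data.
#' @return An object of class `utr_group_compare`: test name, statistic,
#'   p-value, per-group summary tibble (n, median, quartiles), and an ECDF
#'   tibble (`group`, `value`, `ecdf`).
#' @export
group_compare <- function(records, group_field, value_field,
                          test = c("ranksum", "ks"), groups = NULL) {
  test <- match.arg(test)
  x <- as_tibble(records)
  present <- unique(x[[group_field]])
  if (is.null(groups)) {
    groups <- if (all(c("high", "low") %in% present)) c("high", "low")
              else present
  }
  if (length(groups) != 2L) {
    abort("group_compare() needs exactly two groups; pass `groups`")
  }
  v1 <- x[[value_field]][x[[group_field]] == groups[1]]
  v2 <- x[[value_field]][x[[group_field]] == groups[2]]
  v1 <- v1[!is.na(v1)]; v2 <- v2[!is.na(v2)]
  if (length(v1) == 0 || length(v2) == 0) {
    abort("both groups must be non-empty")
  }
  ht <- if (test == "ranksum") {
    suppressWarnings(wilcox.test(v1, v2))
  } else {
    suppressWarnings(ks.test(v1, v2))
  }
  summary <- tibble(
    group = groups,
    n = c(length(v1), length(v2)),
    median = c(median(v1), median(v2)),
    q25 = c(quantile(v1, 0.25, names = FALSE), quantile(v2, 0.25, names = FALSE)),
    q75 = c(quantile(v1, 0.75, names = FALSE), quantile(v2, 0.75, names = FALSE))
  )
  ecdf_tbl <- bind_rows(
    tibble(group = groups[1], value = sort(v1), ecdf = ecdf(v1)(sort(v1))),
    tibble(group = groups[2], value = sort(v2), ecdf = ecdf(v2)(sort(v2)))
  )
  out <- list(test = test, statistic = unname(ht$statistic),
              p_value = ht$p.value, summary = summary, ecdf = ecdf_tbl,
              group_field = group_field, value_field = value_field,
              groups = groups)
  class(out) <- "utr_group_compare"
  out
}

#' @export
print.utr_group_compare <- function(x, ...) {
  cat(sprintf("<utr_group_compare> %s of %s by %s (%s vs %s)\n",
              if (x$test == "ranksum") "Wilcoxon rank-sum" else "Kolmogorov-Smirnov",
              x$value_field, x$group_field, x$groups[1], x$groups[2]))
  cat(sprintf("  statistic = %.4g, p = %.3g\n", x$statistic, x$p_value))
  print(x$summary)
  invisible(x)
}

#' Pearson correlation between two gene-level variables
#'
#' @param records Gene-level tibble.
#' @param x_field,y_field Column names.
#' @param log_y If `TRUE`, correlate against `log10(y + epsilon)`.
#' @param epsilon Offset guarding `log10` of zeros.
#' @return Object of class `utr_correlation`: `r`, `p_value`, `n`, and the
#'   scatter tibble (`x`, `y` as analyzed). Degenerate variance gives
#'   `r = NA` with a warning.
#' @export
correlate <- function(records, x_field, y_field, log_y = FALSE,
                      epsilon = 1e-6) {
  d <- as_tibble(records)
  xv <- d[[x_field]]
  yv <- d[[y_field]]
  if (log_y) yv <- log10(yv + epsilon)
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3) abort("correlate() needs at least 3 paired finite values")
  out <- list(x_field = x_field, y_field = y_field, log_y = log_y,
              n = length(xv), data = tibble(x = xv, y = yv))
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    warn("degenerate variance; correlation undefined")
    out$r <- NA_real_
    out$p_value <- NA_real_
  } else {
    ct <- cor.test(xv, yv, method = "pearson")
    out$r <- unname(ct$estimate)
    out$p_value <- ct$p.value
  }
  class(out) <- "utr_correlation"
  out
}

#' @export
print.utr_correlation <- function(x, ...) {
  cat(sprintf("<utr_correlation> %s vs %s%s: R = %.4g, p = %.3g (n = %d)\n",
              x$x_field, if (x$log_y) paste0("log10(", x$y_field, ")") else x$y_field,
              "", x$r, x$p_value, x$n))
  invisible(x)
}

#' Keep genes whose 3' UTR is at least moderately structured
#'
#' Subsets to records with `avg_gini` above a threshold. Structure-stability
#' coupling emerges only once structure exceeds a floor, so half-life
#' analyses restrict to these genes.
#'
#' @param records Gene-level tibble with `avg_gini`.
#' @param min_avg_gini Threshold (records strictly above are kept).
#' @return Filtered tibble; the number kept is reported via a message.
#' @export
gini_threshold_filter <- function(records, min_avg_gini = 0.4) {
  x <- as_tibble(records)
  out <- filter(x, .data$avg_gini > min_avg_gini)
  inform(sprintf("gini_threshold_filter: kept %d of %d records (avg_gini > %.2g)",
                 nrow(out), nrow(x), min_avg_gini))
  out
}

#' Re-test a group contrast within strata of a possible confounder
#'
#' Splits records at the sample median of a covariate (>= median vs <,
#' mirroring the field's GC-content and poly(A)-length splits), then re-runs
#' the high- vs low-class comparison of `value_field` within each stratum.
#' If the contrast holds in both strata, the covariate does not explain it.
#'
#' @param records Gene-level tibble carrying the class column and covariate.
#' @param covariate Covariate column name (e.g. `"gc_content"`,
#'   `"polya_len"`).
#' @param value_field Compared value (default `"rpkm"`).
#' @param class_field Class column (default `"avg_gini_class"`).
#' @param test Passed to [group_compare()].
#' @return Tibble with one row per stratum: `stratum`, `cutoff`, `n`,
#'   `n_high`, `n_low`, `statistic`, `p_value`, `median_high`, `median_low`,
#'   `evaluable`.
#' @export
stratified_confounder <- function(records, covariate, value_field = "rpkm",
                                  class_field = "avg_gini_class",
                                  test = "ranksum") {
  x <- as_tibble(records)
  cutoff <- median(x[[covariate]], na.rm = TRUE)
  strata <- list(
    high = x[x[[covariate]] >= cutoff, ],
    low = x[x[[covariate]] < cutoff, ]
  )
  purrr::imap(strata, function(s, name) {
    n_high <- sum(s[[class_field]] == "high")
    n_low <- sum(s[[class_field]] == "low")
    base <- tibble(stratum = paste0(covariate, "_", name), cutoff = cutoff,
                   n = nrow(s), n_high = n_high, n_low = n_low)
    if (n_high < 2 || n_low < 2) {
      return(mutate(base, statistic = NA_real_, p_value = NA_real_,
                    median_high = NA_real_, median_low = NA_real_,
                    evaluable = FALSE))
    }
    gc <- group_compare(s, class_field, value_field, test = test,
                        groups = c("high", "low"))
    mutate(base, statistic = gc$statistic, p_value = gc$p_value,
           median_high = gc$summary$median[1], median_low = gc$summary$median[2],
           evaluable = TRUE)
  }) %>% bind_rows()
}

#' GC content of a sequence, in percent
#'
#' `100 * (#G + #C) / (sequence length excluding N)`; works for RNA or DNA.
#'
#' @param seq A single sequence string.
#' @return Percent GC, `NA` for an empty (or all-N) sequence.
#' @examples
#' gc_content("GCGC")  # 100
#' gc_content("AUAU")  # 0
#' @export
gc_content <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  chars <- chars[chars != "N"]
  if (length(chars) == 0) return(NA_real_)
  100 * sum(chars %in% c("G", "C")) / length(chars)
}

#' Predict RNA G-quadruplex (RG4) sites
#'
#' Finds non-overlapping, greedy left-to-right matches of four G-tracts of
#' at least `min_g` guanines separated by loops of 1-7 nt (any base). RNA
#' mode scans the given strand only; DNA mode also scans the reverse
#' complement and reports those sites on the minus strand in forward
#' coordinates.
#'
#' @param seq A single sequence string (RNA or DNA, case-insensitive).
#' @param min_g Minimum G-tract length (2 or 3 in common predictors;
#'   default 3).
#' @param max_loop Maximum loop length (nt).
#' @param mode `"rna"` (forward strand only) or `"dna"` (both strands).
#' @return Tibble: `start0`, `end0` (0-based half-open, forward
#'   coordinates), `strand`, `pattern` (matched subsequence).
#' @examples
#' predict_rg4("GGGAGGGUGGGAGGG")
#' @export
predict_rg4 <- function(seq, min_g = 3L, max_loop = 7L,
                        mode = c("rna", "dna")) {
  mode <- match.arg(mode)
  s <- toupper(seq)
  pat <- sprintf("G{%d,}(?:[ACGTUN]{1,%d}G{%d,}){3}", min_g, max_loop, min_g)
  scan_strand <- function(str) {
    m <- gregexpr(pat, str, perl = TRUE)[[1]]
    if (m[1] == -1) return(tibble(start0 = integer(), end0 = integer(),
                                  pattern = character()))
    len <- attr(m, "match.length")
    tibble(start0 = as.integer(m) - 1L, end0 = as.integer(m) - 1L + len,
           pattern = substring(str, m, m + len - 1L))
  }
  fwd <- mutate(scan_strand(s), strand = "+")
  if (mode == "rna") {
    return(select(fwd, "start0", "end0", "strand", "pattern"))
  }
  L <- nchar(s)
  rc <- chartr("ACGTU", "TGCAA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  rev_hits <- scan_strand(rc) %>%
    mutate(strand = "-",
           new_start = L - .data$end0, end0 = L - .data$start0,
           start0 = .data$new_start) %>%
    select(-"new_start")
  bind_rows(fwd, rev_hits) %>%
    arrange(.data$start0) %>%
    select("start0", "end0", "strand", "pattern")
}

#' Fit an exponential decay and report the half-life
#'
#' Least-squares fit of `log(abundance) = -k * t + b` on a reference- and
#' t0-normalized decay time course; the half-life is `ln(2) / k`. A
#' non-positive decay rate (abundance not falling) yields `t_half = NA`
#' with a warning.
#'
#' @param timepoints Numeric times (hours), must include 0.
#' @param abundance Positive relative abundances, same length.
#' @param normalize If `TRUE` (default), divide by the t = 0 value first.
#' @return Object of class `decay_fit`: `k` (per hour), `t_half` (hours),
#'   `intercept`, `r_squared`, `n`, and the input data.
#' @examples
#' fit_half_life(c(0, 1, 2), c(1, 0.5, 0.25))$t_half  # 1
#' @export
fit_half_life <- function(timepoints, abundance, normalize = TRUE) {
  if (length(timepoints) < 3) abort("need at least 3 timepoints")
  if (length(timepoints) != length(abundance)) {
    abort("timepoints and abundance must have the same length")
  }
  if (!any(timepoints == 0)) abort("timepoints must include t = 0")
  if (any(abundance <= 0)) abort("abundances must be positive")
  if (normalize) abundance <- abundance / abundance[timepoints == 0][1]
  fit <- lm(log(abundance) ~ timepoints)
  k <- -unname(coef(fit)[2])
  t_half <- if (k > 0) log(2) / k else NA_real_
  if (k <= 0) warn("non-positive decay rate; half-life undefined")
  y <- log(abundance)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  out <- list(k = k, t_half = t_half, intercept = unname(coef(fit)[1]),
              r_squared = r2, n = length(timepoints),
              data = tibble(time = timepoints, rel_abundance = abundance))
  class(out) <- "decay_fit"
  out
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> k = %.4g /h, t1/2 = %s h (n = %d, R^2 = %.3f)\n",
              x$k, ifelse(is.na(x$t_half), "NA", sprintf("%.3g", x$t_half)),
              x$n, x$r_squared))
  invisible(x)
}

#' Fit half-lives for many decay curves
#'
#' @param curves Tibble with `gene_id`, `time_h`, `rel_abundance` columns.
#' @param normalize Passed to [fit_half_life()].
#' @return Tibble with one row per gene: `gene_id`, `k`, `t_half`,
#'   `r_squared`, `n_timepoints`.
#' @export
fit_half_lives <- function(curves, normalize = TRUE) {
  as_tibble(curves) %>%
    dplyr::group_split(.data$gene_id) %>%
    purrr::map(function(g) {
      f <- fit_half_life(g$time_h, g$rel_abundance, normalize = normalize)
      tibble(gene_id = g$gene_id[1], k = f$k, t_half = f$t_half,
             r_squared = f$r_squared, n_timepoints = f$n)
    }) %>%
    bind_rows()
}

#' Fraction of miRNA-target genes per structure class
#'
#' Tabulates the fraction of genes flagged as miRNA targets within the high-
#' and low-Gini classes and tests equality of the two proportions.
#'
#' @param records Gene-level tibble with a logical `mirna_target` column and
#'   the class column.
#' @param class_field Class column (default `"avg_gini_class"`).
#' @return List of class `mirna_overlap`: `summary` tibble (class, n,
#'   n_target, fraction) and `p_value` from a two-proportion test.
#' @export
mirna_overlap_summary <- function(records, class_field = "avg_gini_class") {
  x <- as_tibble(records) %>%
    filter(.data[[class_field]] %in% c("high", "low"))
  summary <- x %>%
    group_by(class = .data[[class_field]]) %>%
    summarise(n = n(), n_target = sum(.data$mirna_target),
              fraction = mean(.data$mirna_target), .groups = "drop")
  p <- if (nrow(summary) == 2 && all(summary$n > 0)) {
    suppressWarnings(prop.test(summary$n_target, summary$n)$p.value)
  } else NA_real_
  out <- list(summary = summary, p_value = p)
  class(out) <- "mirna_overlap"
  out
}

#' @export
print.mirna_overlap <- function(x, ...) {
  cat("<mirna_overlap> two-proportion p =", format(x$p_value, digits = 3), "\n")
  print(x$summary)
  invisible(x)
}
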
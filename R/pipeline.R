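#' Restrict reactivity profiles to each transcript's 3' UTR
#'
#' @param reactivity Reactivity tibble over whole transcripts.
#' @param annotations Tibble with `transcript_id`, `utr3_start`, `utr3_end`.
#' @return The reactivity rows falling inside each transcript's 3' UTR.
#' @export
utr_region <- function(reactivity, annotations) {
  as_tibble(reactivity) %>%
    dplyr::inner_join(
      select(as_tibble(annotations), "transcript_id", "utr3_start", "utr3_end"),
      by = "transcript_id") %>%
    filter(.data$pos0 >= .data$utr3_start, .data$pos0 < .data$utr3_end) %>%
    select(-"utr3_start", -"utr3_end")
}

#' Pipeline run configuration
#'
#' Collects every stage parameter with the analysis defaults: 50-nt windows
#' with a 25-nt step, a per-window mean-mismatch floor of 20, top-5%-median
#' reactivity normalization, 10% decile classes, an average-Gini threshold
#' of 0.4 for half-life analyses, and a 100-nt meta-gene flank.
#'
#' @param sim A [sim_config()] describing the synthetic experiment (ignored
#'   when real pileups are supplied to [run_pipeline()]).
#' @param mode `"genomewide"` (poly(A)-anchored, coverage floor 20) or
#'   `"amplicon"` (target-specific, coverage floor 100).
#' @param window_size,step Sliding-window geometry (nt).
#' @param mismatch_threshold Per-window mean mismatch floor.
#' @param top_fraction Top fraction for reactivity normalization.
#' @param q Decile fraction for high/low classes.
#' @param gini_threshold Average-Gini floor for half-life analyses.
#' @param flank Meta-gene flank (nt).
#' @param min_coverage Per-base coverage floor; defaults by `mode`.
#' @param gini_bases `"AC"` or `"all"`, see [window_gini()].
#' @param seed Run seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = sim_config(seed = seed), mode = c("genomewide", "amplicon"),
                       window_size = 50L, step = 25L, mismatch_threshold = 20,
                       top_fraction = 0.05, q = 0.10, gini_threshold = 0.4,
                       flank = 100L, min_coverage = NULL,
                       gini_bases = "AC", seed = 1L) {
  mode <- match.arg(mode)
  cfg <- list(
    sim = sim, mode = mode, window_size = as.integer(window_size),
    step = as.integer(step), mismatch_threshold = mismatch_threshold,
    top_fraction = top_fraction, q = q, gini_threshold = gini_threshold,
    flank = as.integer(flank),
    min_coverage = min_coverage %||% if (mode == "amplicon") 100 else 20,
    gini_bases = gini_bases, seed = as.integer(seed)
  )
  class(cfg) <- "run_config"
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; a `sim` block
#' mirrors [sim_config()].
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(y$seed) && is.null(sim_args$seed)) sim_args$seed <- y$seed
  sim <- do.call(sim_config, sim_args)
  args <- y[setdiff(names(y), "sim")]
  do.call(run_config, c(list(sim = sim), args))
}

#' Run the structurome analysis end to end
#'
#' Simulates (or takes) treated/untreated pileups, runs the reactivity
#' chain, scores 3' UTR windows with the Gini index, joins expression and
#' half-life covariates, classifies high/low-Gini and half-life deciles,
#' and computes the association statistics: high- vs low-Gini expression
#' (rank-sum), Gini-expression correlation, and the half-life-decile Gini
#' contrast (KS, after the average-Gini threshold filter). When `outdir` is
#' given, all stage tables plus a JSON manifest (parameters and record
#' counts at each filter) are written there.
#'
#' @param cfg A [run_config()].
#' @param experiment Optional pre-built experiment list (as from
#'   [simulate_probing_experiment()]) with elements `transcripts`,
#'   `treated`, `untreated`, `covariates`; simulated from `cfg$sim` when
#'   `NULL`.
#' @param outdir Optional output directory.
#' @return (Invisibly) a list: `records` (gene-level table with classes),
#'   `windows`, `reactivity`, `stats` (list of test results), `manifest`.
#' @examples
#' \donttest{
#' res <- run_pipeline(run_config(sim = sim_config(n_genes = 40, seed = 1)))
#' res$stats$expression_ranksum$p_value
#' }
#' @export
run_pipeline <- function(cfg, experiment = NULL, outdir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  ex <- experiment %||% simulate_probing_experiment(cfg$sim)
  if (nrow(ex$treated) == 0 || nrow(ex$untreated) == 0) {
    abort("stage pileup: empty input")
  }
  manifest <- list(
    parameters = cfg[setdiff(names(cfg), "sim")],
    sim = unclass(cfg$sim),
    counts = list(n_genes = nrow(ex$transcripts))
  )

  reactivity <- dms_reactivity(
    ex$treated, ex$untreated, min_coverage = cfg$min_coverage,
    top_fraction = cfg$top_fraction, on_few = "drop")
  manifest$counts$n_genes_normalized <-
    length(unique(reactivity$transcript_id))

  utr <- utr_region(reactivity, ex$transcripts)
  windows <- window_gini(utr, window_size = cfg$window_size, step = cfg$step,
                         mismatch_threshold = cfg$mismatch_threshold,
                         bases = cfg$gini_bases)
  gene_gini <- average_gini(windows)
  manifest$counts$n_windows <- nrow(windows)
  manifest$counts$n_windows_passed <- sum(windows$passed)

  records <- gene_gini %>%
    filter(!is.na(.data$avg_gini)) %>%
    dplyr::inner_join(ex$covariates, by = "transcript_id")
  manifest$counts$n_genes_with_avg_gini <- nrow(records)
  if (nrow(records) < 10) {
    abort("stage association: fewer than 10 genes with a usable average Gini")
  }

  records <- records %>%
    classify_deciles("avg_gini", q = cfg$q) %>%
    classify_deciles("half_life", q = cfg$q)

  expr_cmp <- group_compare(records, "avg_gini_class", "rpkm",
                            test = "ranksum", groups = c("high", "low"))
  corr <- correlate(records, "avg_gini", "rpkm", log_y = TRUE)
  hl_records <- suppressMessages(
    gini_threshold_filter(records, cfg$gini_threshold))
  manifest$counts$n_genes_above_gini_threshold <- nrow(hl_records)
  hl_cmp <- if (all(c("high", "low") %in% hl_records$half_life_class) &&
                sum(hl_records$half_life_class == "high") >= 2 &&
                sum(hl_records$half_life_class == "low") >= 2) {
    group_compare(hl_records, "half_life_class", "avg_gini", test = "ks",
                  groups = c("low", "high"))  # short vs long half-life
  } else NULL
  hl_cmp_all <- group_compare(records, "half_life_class", "avg_gini",
                              test = "ks", groups = c("low", "high"))

  stats <- list(expression_ranksum = expr_cmp,
                gini_expression_correlation = corr,
                halflife_ks = hl_cmp,
                halflife_ks_all = hl_cmp_all)
  manifest$stats <- list(
    expression_p = expr_cmp$p_value,
    expression_median_high = expr_cmp$summary$median[1],
    expression_median_low = expr_cmp$summary$median[2],
    correlation_r = corr$r,
    correlation_p = corr$p_value,
    halflife_ks_p = if (is.null(hl_cmp)) NA else hl_cmp$p_value,
    halflife_ks_all_p = hl_cmp_all$p_value
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_reactivity(reactivity, file.path(outdir, "reactivity.tsv"))
    write_commented_tsv(as_tibble(windows), file.path(outdir, "windows.tsv"))
    readr::write_tsv(records, file.path(outdir, "gene_records.tsv"))
    readr::write_tsv(expr_cmp$ecdf, file.path(outdir, "expression_ecdf.tsv"))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(records = records, windows = windows,
                 reactivity = reactivity, transcripts = ex$transcripts,
                 stats = stats, manifest = manifest))
}
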
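#' Simulation configuration for synthetic DMS probing data
#'
#' Bundles every parameter of the synthetic-data generator: transcript
#' geometry, the per-read DMS modification model, sequencing coverage and its
#' 3' bias, and the generative coupling of expression and half-life to 3' UTR
#' structure. The defaults encode the structure-mediated decay scenario: both
#' the expression and half-life slopes against pairing fraction are negative,
#' so more-paired 3' UTRs yield lower RPKM and shorter half-lives.
#'
#' @param n_genes Number of transcripts to simulate.
#' @param utr_length_range Integer length-2 vector, min/max 3' UTR length (nt).
#' @param pairing_fraction_levels Fractions in `[0, 0.95]`; genes are assigned
#'   to levels in round-robin order, so each level gets (close to) the same
#'   number of genes.
#' @param dms_rate_unpaired Per-read modification probability at unpaired A/C.
#' @param dms_rate_paired Leak modification probability at paired A/C.
#' @param background_error Per-base mismatch probability on every base
#'   (sequencing/RT error), the only signal in untreated samples.
#' @param mean_coverage Coverage at the 3'-most base; see `three_prime_bias`.
#' @param three_prime_bias Exponent b in the coverage ramp
#'   `c(i) = mean_coverage * ((i + 1) / L)^b`; `b = 0` gives uniform coverage,
#'   `b > 0` enriches reads toward the 3' end as in poly(A)-anchored libraries.
#' @param cds_length Length of the simulated coding region, stop codon
#'   included (nt). Must leave >= 100 nt of CDS upstream of the stop codon.
#' @param cds_pairing_fraction Target pairing fraction of the structure
#'   generated for the CDS, one knob making the coding region more or less
#'   structured than the UTR for meta-gene contrasts.
#' @param expression_model List with `baseline` (log RPKM at pairing 0),
#'   `slope` (change in log RPKM per unit pairing fraction, must be <= 0) and
#'   `sd` (lognormal noise sd on the log scale).
#' @param halflife_model Same shape as `expression_model` but `baseline` is
#'   the half-life in hours at pairing 0 and `slope` acts on log half-life.
#' @param polya_model List with `median_nt` (median poly(A) tail length) and
#'   `sdlog` (lognormal spread); tail length is independent of structure
#'   unless `slope` (on log length per unit pairing) is set non-zero.
#' @param mirna_target_rate Probability that a gene carries a miRNA target
#'   site, independent of structure.
#' @param min_stem Minimum helix length (nt per strand) placed by the
#'   structure generator.
#' @param loop_len Hairpin loop length (nt), at least 3.
#' @param seed Integer seed; all generator randomness derives from it.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_genes = 10, seed = 1)
#' cfg$dms_rate_unpaired
#' @export
sim_config <- function(n_genes = 300,
                       utr_length_range = c(150L, 300L),
                       pairing_fraction_levels = c(0.1, 0.3, 0.5, 0.7),
                       dms_rate_unpaired = 0.05,
                       dms_rate_paired = 0.005,
                       background_error = 0.002,
                       mean_coverage = 5000,
                       three_prime_bias = 1,
                       cds_length = 150L,
                       cds_pairing_fraction = 0.6,
                       expression_model = list(baseline = 4, slope = -2, sd = 0.5),
                       halflife_model = list(baseline = 4, slope = -1.5, sd = 0.4),
                       polya_model = list(median_nt = 80, sdlog = 0.3, slope = 0),
                       mirna_target_rate = 0.2,
                       min_stem = 4L,
                       loop_len = 4L,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    utr_length_range = as.integer(utr_length_range),
    pairing_fraction_levels = as.numeric(pairing_fraction_levels),
    dms_rate_unpaired = dms_rate_unpaired,
    dms_rate_paired = dms_rate_paired,
    background_error = background_error,
    mean_coverage = mean_coverage,
    three_prime_bias = three_prime_bias,
    cds_length = as.integer(cds_length),
    cds_pairing_fraction = cds_pairing_fraction,
    expression_model = expression_model,
    halflife_model = halflife_model,
    polya_model = polya_model,
    mirna_target_rate = mirna_target_rate,
    min_stem = as.integer(min_stem),
    loop_len = as.integer(loop_len),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  probs <- c(
    dms_rate_unpaired = cfg$dms_rate_unpaired,
    dms_rate_paired = cfg$dms_rate_paired,
    background_error = cfg$background_error,
    cds_pairing_fraction = cfg$cds_pairing_fraction,
    mirna_target_rate = cfg$mirna_target_rate
  )
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    abort(paste0("probabilities outside [0, 1]: ",
                 paste(names(probs)[bad], collapse = ", ")))
  }
  if (!(cfg$dms_rate_unpaired > cfg$dms_rate_paired &&
        cfg$dms_rate_paired >= cfg$background_error)) {
    abort("need dms_rate_unpaired > dms_rate_paired >= background_error")
  }
  if (any(cfg$pairing_fraction_levels < 0 | cfg$pairing_fraction_levels > 0.95)) {
    abort("pairing_fraction_levels must lie in [0, 0.95]")
  }
  if (cfg$expression_model$slope > 0 || cfg$halflife_model$slope > 0) {
    abort("expression and half-life slopes must be <= 0 (structure lowers both)")
  }
  if (cfg$n_genes < 1) abort("n_genes must be >= 1")
  if (length(cfg$utr_length_range) != 2L ||
      cfg$utr_length_range[1] > cfg$utr_length_range[2] ||
      cfg$utr_length_range[1] < 20L) {
    abort("utr_length_range must be an increasing pair with min >= 20")
  }
  if (cfg$cds_length < 103L) abort("cds_length must be >= 103 (100-nt flank plus stop codon)")
  if (cfg$loop_len < 3L) abort("loop_len must be >= 3")
  if (cfg$mean_coverage <= 0 || cfg$three_prime_bias < 0) {
    abort("mean_coverage must be positive and three_prime_bias >= 0")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  genes:", x$n_genes, " UTR length:", x$utr_length_range[1], "-",
      x$utr_length_range[2], "nt\n")
  cat("  pairing levels:", paste(x$pairing_fraction_levels, collapse = ", "), "\n")
  cat("  DMS rates (unpaired/paired/background):",
      x$dms_rate_unpaired, "/", x$dms_rate_paired, "/", x$background_error, "\n")
  cat("  coverage:", x$mean_coverage, "(3' bias exponent", x$three_prime_bias, ")\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# deterministic per-gene/per-task stream derived from the run seed; keeps
# every value below 2^31 so it is a valid R integer seed
derive_seed <- function(seed, index, salt = 0L) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729 +
                as.double(salt) * 31) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
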
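#' Simulate a per-base mismatch pileup for one probing sample
#'
#' Draws per-base coverage and mismatch counts for every transcript under
#' the DMS mutational-profiling error model. Coverage follows the 3'-biased
#' ramp `c(i) = mean_coverage * ((i + 1) / L)^three_prime_bias` (position i
#' 0-based over the transcript of length L), emulating poly(A)-anchored
#' library chemistry; `three_prime_bias = 0` gives uniform coverage. The
#' per-read mismatch probability is
#' `background_error` on G/U and on every base of an untreated sample,
#' `background_error + dms_rate_paired` on paired A/C, and
#' `background_error + dms_rate_unpaired` on unpaired A/C; mismatch counts
#' are Binomial(coverage, p). Only substitutions are modeled, no indels.
#'
#' @param transcripts Tibble from [simulate_transcripts()].
#' @param cfg The [sim_config()] used to build `transcripts`.
#' @param treated Logical; `TRUE` simulates the DMS-treated sample,
#'   `FALSE` the untreated control (background errors only).
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @return A pileup tibble: `transcript_id`, `pos0`, `ref_base`, `coverage`,
#'   `mismatch`, `sample`.
#' @examples
#' cfg <- sim_config(n_genes = 2, seed = 1)
#' tx <- simulate_transcripts(cfg)
#' head(simulate_pileup(tx, cfg, treated = TRUE))
#' @export
simulate_pileup <- function(transcripts, cfg, treated = TRUE, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  label <- if (treated) "treated" else "untreated"
  rows <- purrr::map(seq_len(nrow(transcripts)), function(i) {
    tx <- transcripts[i, ]
    bases <- strsplit(tx$sequence, "")[[1]]
    L <- length(bases)
    cov <- pmax(0L, as.integer(round(
      cfg$mean_coverage * ((seq_len(L)) / L)^cfg$three_prime_bias)))
    p <- rep(cfg$background_error, L)
    if (treated) {
      status <- strsplit(transcript_paired_status(tx), "")[[1]]
      if (length(status) != L) {
        abort(sprintf("structure/sequence length mismatch for %s", tx$transcript_id))
      }
      ac <- bases %in% c("A", "C")
      paired <- status != "."
      p[ac & paired] <- cfg$background_error + cfg$dms_rate_paired
      p[ac & !paired] <- cfg$background_error + cfg$dms_rate_unpaired
    }
    mm <- with_seed(derive_seed(seed, i, salt = if (treated) 23L else 29L),
                    rbinom(L, cov, p))
    tibble(
      transcript_id = tx$transcript_id,
      pos0 = seq_len(L) - 1L,
      ref_base = bases,
      coverage = cov,
      mismatch = mm,
      sample = label
    )
  })
  bind_rows(rows)
}

#' Simulate a complete probing experiment
#'
#' Convenience wrapper bundling transcripts, treated and untreated pileups,
#' and per-gene covariates generated under one configuration and seed.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `transcripts`, `treated`, `untreated`
#'   (pileup tibbles) and `covariates`.
#' @examples
#' ex <- simulate_probing_experiment(sim_config(n_genes = 2, seed = 1))
#' names(ex)
#' @export
simulate_probing_experiment <- function(cfg) {
  tx <- simulate_transcripts(cfg)
  list(
    transcripts = tx,
    treated = simulate_pileup(tx, cfg, treated = TRUE),
    untreated = simulate_pileup(tx, cfg, treated = FALSE),
    covariates = simulate_covariates(tx, cfg)
  )
}
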
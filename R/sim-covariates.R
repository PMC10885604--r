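#' Simulate per-gene expression, stability and confounder covariates
#'
#' Draws expression and half-life inversely coupled to 3' UTR structure:
#' `log(RPKM) = baseline + slope * pairing_fraction + Normal(0, sd)` with
#' `slope <= 0`, and analogously `log(half-life)` around `log(baseline)`
#' hours. Poly(A) tail length is lognormal around a configurable median
#' (independent of structure unless its `slope` is set), miRNA-target flags
#' are independent Bernoulli draws, and GC content is computed from the
#' actual 3' UTR sequence.
#'
#' @param transcripts Tibble from [simulate_transcripts()].
#' @param cfg The [sim_config()] used to build `transcripts`.
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @return A tibble with `transcript_id`, `pairing_fraction`, `rpkm`,
#'   `half_life` (hours), `polya_len` (nt), `mirna_target`, `gc_content`
#'   (percent) and `utr_len` (nt).
#' @examples
#' cfg <- sim_config(n_genes = 4, seed = 1)
#' simulate_covariates(simulate_transcripts(cfg), cfg)
#' @export
simulate_covariates <- function(transcripts, cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- nrow(transcripts)
  pf <- transcripts$pairing_fraction
  em <- cfg$expression_model
  hm <- cfg$halflife_model
  pm <- cfg$polya_model
  with_seed(derive_seed(seed, 0L, salt = 37L), {
    rpkm <- exp(em$baseline + em$slope * pf + rnorm(n, 0, em$sd))
    half_life <- exp(log(hm$baseline) + hm$slope * pf + rnorm(n, 0, hm$sd))
    polya <- rlnorm(n, meanlog = log(pm$median_nt) + (pm$slope %||% 0) * pf,
                    sdlog = pm$sdlog)
    mirna <- runif(n) < cfg$mirna_target_rate
  })
  utr_seq <- substr(transcripts$sequence,
                    transcripts$utr3_start + 1L, transcripts$utr3_end)
  tibble(
    transcript_id = transcripts$transcript_id,
    pairing_fraction = pf,
    rpkm = rpkm,
    half_life = half_life,
    polya_len = round(polya),
    mirna_target = mirna,
    gc_content = vapply(utr_seq, gc_content, numeric(1), USE.NAMES = FALSE),
    utr_len = transcripts$utr3_end - transcripts$utr3_start
  )
}
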
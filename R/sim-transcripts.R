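#' Simulate a set of transcript models
#'
#' Builds `cfg$n_genes` transcripts, each a random coding region ending in a
#' UAA stop codon followed by a 3' UTR whose secondary structure is a
#' generated dot-bracket (see [simulate_structure()]). Genes are assigned to
#' the configured pairing-fraction levels in round-robin order. Paired UTR
#' positions get Watson-Crick complementary bases so the sequence is
#' consistent with its structure; unpaired positions are drawn uniformly.
#' The CDS also receives a generated structure at
#' `cfg$cds_pairing_fraction` so meta-gene contrasts across the stop codon
#' have a ground truth.
#'
#' @param cfg A [sim_config()].
#' @return A tibble with one row per transcript: `transcript_id`, `sequence`
#'   (RNA alphabet), `cds_start`, `cds_end`, `stop_codon_start`,
#'   `utr3_start`, `utr3_end`, `polya_site` (all 0-based, intervals
#'   half-open), `dotbracket` (3' UTR structure), `cds_dotbracket`,
#'   `pairing_fraction` (achieved, 3' UTR) and `pairing_level` (target).
#' @examples
#' tx <- simulate_transcripts(sim_config(n_genes = 4, seed = 1))
#' tx$pairing_fraction
#' @export
simulate_transcripts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_genes
  levels <- cfg$pairing_fraction_levels
  level_of <- levels[((seq_len(n) - 1L) %% length(levels)) + 1L]
  ids <- sprintf("TX%04d", seq_len(n))

  rows <- purrr::map(seq_len(n), function(i) {
    gseed <- derive_seed(cfg$seed, i, salt = 11L)
    with_seed(gseed, {
      lens <- cfg$utr_length_range[1]:cfg$utr_length_range[2]
      utr_len <- lens[sample.int(length(lens), 1L)]
      struct_seed <- derive_seed(cfg$seed, i, salt = 13L)
      db <- simulate_structure(utr_len, level_of[i], seed = struct_seed,
                               min_stem = cfg$min_stem, loop_len = cfg$loop_len)
      cds_db <- simulate_structure(cfg$cds_length - 3L, cfg$cds_pairing_fraction,
                                   seed = derive_seed(cfg$seed, i, salt = 17L),
                                   min_stem = cfg$min_stem, loop_len = cfg$loop_len)
      cds_body <- paste(sample(c("A", "C", "G", "U"), cfg$cds_length - 3L,
                               replace = TRUE), collapse = "")
      utr_seq <- sequence_for_structure(db)
      seq <- paste0(cds_body, "UAA", utr_seq)
      tibble(
        transcript_id = ids[i],
        sequence = seq,
        cds_start = 0L,
        cds_end = cfg$cds_length,
        stop_codon_start = cfg$cds_length - 3L,
        utr3_start = cfg$cds_length,
        utr3_end = cfg$cds_length + utr_len,
        polya_site = cfg$cds_length + utr_len,
        dotbracket = db,
        cds_dotbracket = paste0(cds_db, "..."),  # stop codon left unpaired
        pairing_fraction = pairing_fraction(db),
        pairing_level = level_of[i]
      )
    })
  })
  bind_rows(rows)
}

# draw a sequence consistent with a dot-bracket: paired closing bases are the
# Watson-Crick complement of their partner, everything else uniform
sequence_for_structure <- function(dotbracket) {
  partner <- dotbracket_pairs(dotbracket)
  n <- length(partner)
  comp <- c(A = "U", U = "A", C = "G", G = "C")
  bases <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
  closing <- which(!is.na(partner) & partner + 1L < seq_len(n))
  bases[closing] <- comp[bases[partner[closing] + 1L]]
  paste(bases, collapse = "")
}

# per-position paired status over the whole transcript (CDS structure,
# unpaired stop codon, UTR structure); positions beyond annotation unpaired
transcript_paired_status <- function(tx_row) {
  paste0(tx_row$cds_dotbracket, tx_row$dotbracket)
}
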
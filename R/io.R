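#' @name utr_io
#' @title Readers and writers for pipeline tables
#'
#' @description
#' All tabular formats are TSV with a leading `#` comment line declaring the
#' coordinate convention (0-based, half-open). Dot-bracket files follow the
#' Vienna layout (`>id` header, sequence line, structure line). FASTA goes
#' through Biostrings, BED/GFF3 annotation import through rtracklayer.
NULL

coord_header <- "# coordinates: 0-based, half-open intervals"

write_commented_tsv <- function(x, path) {
  readr::write_lines(coord_header, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(x)
}

#' @rdname utr_io
#' @param pileup A pileup tibble.
#' @param path File path.
#' @export
write_pileup <- function(pileup, path) write_commented_tsv(pileup, path)

#' @rdname utr_io
#' @export
read_pileup <- function(path) {
  readr::read_tsv(path, comment = "#", progress = FALSE,
                  col_types = readr::cols(
                    transcript_id = "c", pos0 = "i", ref_base = "c",
                    coverage = "i", mismatch = "i", sample = "c"))
}

#' @rdname utr_io
#' @param reactivity A reactivity tibble.
#' @export
write_reactivity <- function(reactivity, path) {
  write_commented_tsv(reactivity, path)
}

#' @rdname utr_io
#' @export
read_reactivity <- function(path) {
  readr::read_tsv(path, comment = "#", progress = FALSE,
                  col_types = readr::cols(transcript_id = "c", pos0 = "i",
                                          ref_base = "c",
                                          mask_reason = "c",
                                          .default = "d")) %>%
    mutate(across(dplyr::any_of(c("coverage", "mismatch")), as.integer))
}

#' @rdname utr_io
#' @details `write_mismatch_bed()` exports a pileup as BED: one feature per
#'   position with the mismatch count in the score column.
#' @export
write_mismatch_bed <- function(pileup, path) {
  bed <- as_tibble(pileup) %>%
    mutate(chrom = .data$transcript_id, start = .data$pos0,
           end = .data$pos0 + 1L,
           name = paste0(.data$transcript_id, ":", .data$pos0),
           score = .data$mismatch, strand = "+") %>%
    select("chrom", "start", "end", "name", "score", "strand")
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(bed)
}

#' @rdname utr_io
#' @param transcripts Transcript tibble from [simulate_transcripts()].
#' @export
write_utr_bed <- function(transcripts, path) {
  bed <- as_tibble(transcripts) %>%
    mutate(chrom = .data$transcript_id, start = .data$utr3_start,
           end = .data$utr3_end, name = "three_prime_UTR", score = 0L,
           strand = "+") %>%
    select("chrom", "start", "end", "name", "score", "strand")
  stop <- as_tibble(transcripts) %>%
    mutate(chrom = .data$transcript_id, start = .data$stop_codon_start,
           end = .data$stop_codon_start + 3L, name = "stop_codon",
           score = 0L, strand = "+") %>%
    select("chrom", "start", "end", "name", "score", "strand")
  readr::write_tsv(arrange(bind_rows(bed, stop), .data$chrom, .data$start),
                   path, col_names = FALSE)
  invisible(path)
}

#' @rdname utr_io
#' @details `write_dotbracket()`/`read_dotbracket()` store the 3' UTR
#'   sequence and ground-truth structure of each transcript in Vienna
#'   format.
#' @export
write_dotbracket <- function(transcripts, path) {
  tx <- as_tibble(transcripts)
  lines <- purrr::pmap(
    list(tx$transcript_id, tx$sequence, tx$utr3_start, tx$utr3_end,
         tx$dotbracket),
    function(id, seq, s, e, db) {
      c(paste0(">", id), substr(seq, s + 1L, e), db)
    })
  readr::write_lines(unlist(lines), path)
  invisible(path)
}

#' @rdname utr_io
#' @export
read_dotbracket <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 3 != 0) {
    abort("malformed dot-bracket file: expected blocks of header/sequence/structure")
  }
  idx <- seq(1, length(lines), by = 3)
  tibble(
    transcript_id = sub("^>", "", lines[idx]),
    sequence = lines[idx + 1],
    dotbracket = lines[idx + 2]
  )
}

#' @rdname utr_io
#' @export
write_fasta <- function(transcripts, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("writing FASTA requires the Biostrings package")
  }
  tx <- as_tibble(transcripts)
  set <- Biostrings::RNAStringSet(setNames(tx$sequence, tx$transcript_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname utr_io
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("reading FASTA requires the Biostrings package")
  }
  set <- Biostrings::readBStringSet(path)
  tibble(transcript_id = names(set),
         sequence = unname(chartr("T", "U", toupper(as.character(set)))))
}

#' @rdname utr_io
#' @param covariates Covariate tibble from [simulate_covariates()].
#' @export
write_covariates <- function(covariates, path) {
  readr::write_tsv(covariates, path)
  invisible(covariates)
}

#' @rdname utr_io
#' @export
read_covariates <- function(path) {
  readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
}

#' Read 3' UTR and stop-codon annotations from BED6 or GFF3
#'
#' Accepts either GFF3 with `three_prime_UTR` and `stop_codon` feature types
#' or BED6 whose name column carries the same feature labels; the chromosome
#' field is the transcript id (transcript-space annotation). Minus-strand
#' features are flipped into transcript coordinates, which requires the
#' transcript lengths. Transcripts lacking a stop codon are skipped with a
#' warning.
#'
#' @param path Annotation file (`.bed`, `.gff`, `.gff3`).
#' @param seqlengths Named integer vector of transcript lengths; required
#'   only when minus-strand features are present.
#' @return Tibble: `transcript_id`, `cds_start`, `stop_codon_start`,
#'   `utr3_start`, `utr3_end` (0-based, half-open; `cds_start` is 0).
#' @export
read_annotations <- function(path, seqlengths = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading annotations requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path)
  df <- tibble(
    transcript_id = as.character(GenomicRanges::seqnames(gr)),
    start0 = BiocGenerics::start(gr) - 1L,
    end0 = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    type = if ("type" %in% names(S4Vectors::mcols(gr))) {
      as.character(S4Vectors::mcols(gr)$type)
    } else {
      as.character(S4Vectors::mcols(gr)$name)
    }
  )
  minus <- df$strand == "-"
  if (any(minus)) {
    if (is.null(seqlengths)) {
      abort("minus-strand features present: supply `seqlengths` to flip them")
    }
    L <- seqlengths[df$transcript_id[minus]]
    if (anyNA(L)) abort("seqlengths missing for some minus-strand transcripts")
    new_start <- L - df$end0[minus]
    new_end <- L - df$start0[minus]
    df$start0[minus] <- new_start
    df$end0[minus] <- new_end
  }
  utr <- df %>% filter(.data$type == "three_prime_UTR") %>%
    select("transcript_id", utr3_start = "start0", utr3_end = "end0")
  stops <- df %>% filter(.data$type == "stop_codon") %>%
    select("transcript_id", stop_codon_start = "start0")
  missing_stop <- setdiff(utr$transcript_id, stops$transcript_id)
  if (length(missing_stop) > 0) {
    warn(sprintf("skipping %d transcript(s) without a stop_codon feature",
                 length(missing_stop)))
  }
  utr %>%
    dplyr::inner_join(stops, by = "transcript_id") %>%
    mutate(cds_start = 0L) %>%
    select("transcript_id", "cds_start", "stop_codon_start",
           "utr3_start", "utr3_end")
}
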
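# Independent brute-force oracles used across the suite.

# O(n^2) pairwise-difference Gini
gini_brute <- function(x) {
  n <- length(x)
  if (n < 2 || mean(x) == 0) return(NA_real_)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

# step-by-step reactivity chain on plain vectors (single transcript)
chain_brute <- function(cov_t, mm_t, cov_u, mm_u, min_coverage, top_fraction = 0.05) {
  r_t <- ifelse(cov_t >= min_coverage, mm_t / cov_t, NA)
  r_u <- ifelse(cov_u >= min_coverage, mm_u / cov_u, NA)
  corr <- ifelse(is.na(r_t) | is.na(r_u), NA, pmax(0, r_t - r_u))
  vals <- corr[!is.na(corr)]
  k <- max(1, ceiling(top_fraction * length(vals)))
  s <- median(sort(vals, decreasing = TRUE)[seq_len(k)])
  norm <- ifelse(is.na(corr), NA, pmin(1, corr / s))
  list(raw = r_t, corrected = corr, normalized = norm, scale = s)
}

# exhaustive greedy G-quadruplex matcher: from a fixed start, try tract and
# loop lengths in the backtracking preference order of a greedy regex
# (longer first); returns the 1-based end of the first successful parse or NA
quad_match_at <- function(chars, start, min_g, max_loop) {
  n <- length(chars)
  run_len_at <- function(i) {
    l <- 0
    while (i + l <= n && chars[i + l] == "G") l <- l + 1
    l
  }
  recurse <- function(i, tracts_left) {
    rl <- run_len_at(i)
    if (rl < min_g) return(NA_integer_)
    for (g in rl:min_g) {
      after <- i + g
      if (tracts_left == 1) return(after - 1L)
      for (loop in max_loop:1) {
        nxt <- after + loop
        if (nxt > n) next
        res <- recurse(nxt, tracts_left - 1L)
        if (!is.na(res)) return(res)
      }
    }
    NA_integer_
  }
  recurse(start, 4L)
}

# leftmost, non-overlapping enumeration over the whole sequence
rg4_oracle <- function(seq, min_g = 3, max_loop = 7) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  out <- list()
  s <- 1L
  while (s <= n) {
    e <- quad_match_at(chars, s, min_g, max_loop)
    if (!is.na(e)) {
      out[[length(out) + 1L]] <- c(start0 = s - 1L, end0 = e)
      s <- e + 1L
    } else {
      s <- s + 1L
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(start0 = integer(), end0 = integer()))
  }
  tibble::as_tibble(do.call(rbind, out))
}

# random RNA string
random_rna <- function(n, prob = c(0.3, 0.2, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# quick synthetic experiment at reduced size for unit tests
tiny_config <- function(n_genes = 6, seed = 42, ...) {
  sim_config(n_genes = n_genes, utr_length_range = c(120L, 180L),
             mean_coverage = 2000, seed = seed, ...)
}
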
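#' Maximum achievable pairing fraction for a hairpin structure
#'
#' A single hairpin with an `loop_len`-nt terminal loop is the densest
#' pseudoknot-free structure this generator can place, so the ceiling on the
#' pairing fraction of a length-`length` region is
#' `2 * floor((length - loop_len) / 2) / length`.
#'
#' @param length Region length in nt.
#' @param loop_len Hairpin loop length (>= 3 nt).
#' @return Fraction in `[0, 1)`.
#' @export
max_pairing_fraction <- function(length, loop_len = 4L) {
  2 * floor((length - loop_len) / 2) / length
}

#' Generate a dot-bracket structure with a target pairing fraction
#'
#' Constructs a balanced dot-bracket string by placing hairpin stem-loops in
#' an unpaired scaffold. Stem lengths are drawn between `min_stem` and
#' `min_stem + 4` base pairs until the requested number of pairs is reached;
#' hairpins are then merged as needed to fit and scattered across the region
#' with randomly sized unpaired gaps. No thermodynamics is involved: the
#' output is a ground-truth pairing pattern for simulation, not a fold.
#'
#' @param length Region length (nt), at least 20.
#' @param target_pairing_fraction Desired fraction of paired bases, in
#'   `[0, 0.95]`. The achieved fraction is within 0.05 of the target; targets
#'   within 0.05 above the single-hairpin ceiling are clamped to it, targets
#'   further above it are an error naming the maximum achievable fraction.
#' @param seed Integer seed; output is deterministic given all arguments.
#' @param min_stem Minimum stem length (base pairs per helix).
#' @param loop_len Hairpin loop length (nt, >= 3).
#' @return A dot-bracket string over `.`, `(`, `)` of length `length`.
#' @examples
#' simulate_structure(50, 0, seed = 1)
#' pairing_fraction(simulate_structure(60, 0.6, seed = 7))
#' @export
simulate_structure <- function(length, target_pairing_fraction, seed = 1L,
                               min_stem = 4L, loop_len = 4L) {
  length <- as.integer(length)
  if (length < 20L) abort("length must be >= 20 nt")
  if (target_pairing_fraction < 0 || target_pairing_fraction > 0.95) {
    abort("target_pairing_fraction must lie in [0, 0.95]")
  }
  if (loop_len < 3L) abort("loop_len must be >= 3")

  max_pairs <- floor((length - loop_len) / 2)
  max_frac <- 2 * max_pairs / length
  pairs_needed <- round(target_pairing_fraction * length / 2)
  if (pairs_needed > max_pairs) {
    if (target_pairing_fraction - max_frac > 0.05) {
      abort(sprintf(
        "target pairing fraction %.2f unreachable at length %d (max achievable %.3f)",
        target_pairing_fraction, length, max_frac))
    }
    pairs_needed <- max_pairs
  }
  if (pairs_needed > 0 && pairs_needed < min_stem) {
    # too few pairs for one stem: take whichever of no stem / one minimal
    # stem lands closer to the target, within the +-0.05 contract
    cand <- c(0L, min_stem)
    pairs_needed <- cand[which.min(abs(2 * cand / length - target_pairing_fraction))]
    if (abs(2 * pairs_needed / length - target_pairing_fraction) > 0.05) {
      abort(sprintf(
        "target %.2f not realizable within 0.05 at length %d with min_stem %d (nearest achievable %.3f or %.3f)",
        target_pairing_fraction, length, min_stem, 0, 2 * min_stem / length))
    }
  }
  if (pairs_needed == 0) return(strrep(".", length))

  with_seed(seed, {
    stems <- integer(0)
    left <- pairs_needed
    while (left > 0) {
      s <- min(left, sample(min_stem:(min_stem + 4L), 1L))
      if (left - s > 0 && left - s < min_stem) s <- left  # avoid runt stem
      stems <- c(stems, s)
      left <- left - s
    }
    # merge hairpins (dropping one loop each time) until the footprint fits
    while (2 * sum(stems) + length(stems) * loop_len > length && length(stems) > 1L) {
      stems <- c(stems[1] + stems[2], stems[-(1:2)])
    }
    k <- length(stems)
    spare <- length - 2L * sum(stems) - k * loop_len
    gaps <- if (spare > 0) {
      as.integer(stats::rmultinom(1, spare, rep(1, k + 1L)))
    } else {
      integer(k + 1L)
    }
    parts <- character(2L * k + 1L)
    parts[1] <- strrep(".", gaps[1])
    for (i in seq_len(k)) {
      parts[2L * i] <- paste0(strrep("(", stems[i]), strrep(".", loop_len),
                              strrep(")", stems[i]))
      parts[2L * i + 1L] <- strrep(".", gaps[i + 1L])
    }
    paste(parts, collapse = "")
  })
}

#' Fraction of paired bases in a dot-bracket string
#'
#' @param dotbracket Balanced dot-bracket string over `.`, `(`, `)`.
#' @return `(#'(' + #')') / nchar(dotbracket)`.
#' @examples
#' pairing_fraction("((((....))))")
#' @export
pairing_fraction <- function(dotbracket) {
  chars <- strsplit(dotbracket, "")[[1]]
  if (!all(chars %in% c(".", "(", ")"))) {
    abort("dot-bracket string may only contain '.', '(' and ')'")
  }
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0) || depth[length(depth)] != 0) {
    abort("unbalanced dot-bracket string")
  }
  sum(chars != ".") / length(chars)
}

# stack parse of a balanced dot-bracket; returns integer vector of 0-based
# partner indices, NA where unpaired
dotbracket_pairs <- function(dotbracket) {
  chars <- strsplit(dotbracket, "")[[1]]
  n <- length(chars)
  partner <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0) abort("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j - 1L
      partner[j] <- i - 1L
    }
  }
  if (length(stack) > 0) abort("unbalanced dot-bracket string")
  partner
}

is_paired <- function(dotbracket) {
  strsplit(dotbracket, "")[[1]] != "."
}
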
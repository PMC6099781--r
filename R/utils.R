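# Small shared helpers: circular-coordinate arithmetic, rounding, RNG scoping.

`%||%` <- function(a, b) if (is.null(a)) b else a

# non-negative modulus (R's %% already is, kept explicit for readability)
.mod <- function(x, n) ((x %% n) + n) %% n

.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

.collapse <- function(ch) paste(ch, collapse = "")

#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero (the convention
#' used in published tables), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return numeric vector
#' @export
#' @examples
#' round_half_up(100 * 276 / 1177, 2)  # 23.45
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  # tiny eps guards against values like 23.45 stored as 23.4499999...
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Complement a nucleotide string (no reversal)
#' @param s character vector of sequences over A,C,G,T,N
#' @return complemented sequences, same order
#' @export
comp_seq <- function(s) chartr("ACGTNacgtn", "TGCANtgcan", s)

#' Reverse a string (no complement)
#' @param s character vector
#' @return reversed strings
#' @export
rev_seq <- function(s) {
  vapply(s, function(x) .collapse(rev(.chars(x))), character(1), USE.NAMES = FALSE)
}

#' Reverse complement
#'
#' Standard complement with N mapped to N; an involution on normalized
#' sequences.
#'
#' @param s character vector of sequences over A,C,G,T,N
#' @return reverse-complemented sequences
#' @export
#' @examples
#' revcomp("AAC")  # "GTT"
revcomp <- function(s) {
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s))))
}

# substring of a circular sequence, 0-based start, wraps across the origin
circ_substr <- function(seq, start0, len, n = nchar(seq)) {
  stopifnot(len >= 0, len <= n)
  start0 <- .mod(start0, n)
  if (start0 + len <= n) {
    substr(seq, start0 + 1, start0 + len)
  } else {
    paste0(substr(seq, start0 + 1, n), substr(seq, 1, start0 + len - n))
  }
}

# 0-based half-open interval on a circle of size n; wraps when it crosses the
# origin of the linearized circle
mk_interval <- function(start0, span, n) {
  start0 <- .mod(start0, n)
  wraps <- start0 + span > n
  list(
    start = start0,
    end = if (wraps) start0 + span - n else start0 + span,
    wraps = wraps,
    span = span
  )
}

iv_span <- function(iv) iv$span

# does circular interval contain 0-based position p?
iv_contains <- function(iv, p, n) .mod(p - iv$start, n) < iv$span

# run RNG-dependent code under a scoped seed without touching global state
with_seed <- function(seed, code) withr::with_seed(seed, code)
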
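# Dispersed-repeat and SSR census.
#
# Dispersed repeats come in four types, defined by the relation between the
# two copies: forward (identical), palindromic (reverse complement), reverse
# (reversed), complement (complemented in place). Hits are exact and maximal
# (extension on either side breaks the relation), found by k-mer seeding
# followed by character-wise extension along the (anti-)diagonal; the scan is
# linear, as in REPuter. N bases never participate. Symmetric types are
# reported once with pos1 <= pos2; a substring equal to its own reverse (or
# reverse complement) is a single hit with pos1 == pos2.

.REPEAT_TYPES <- c("forward", "palindromic", "reverse", "complement")

.kmer_index <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(list())
  starts <- 1:(n - k + 1L)
  km <- substring(s, starts, starts + k - 1L)
  ok <- !grepl("N", km, fixed = TRUE)
  split(starts[ok], km[ok])
}

# maximal runs on plain diagonals (forward/complement): relation
# a[x] == b[x + d] for x in [p, q]
.diag_scan <- function(a, b, good_a, good_b, n, seeds_by_d, k, minlen) {
  hits <- list()
  for (dstr in names(seeds_by_d)) {
    d <- as.integer(dstr)
    ss <- sort(unique(seeds_by_d[[dstr]]))
    covered_to <- 0L
    for (i in ss) {
      if (i <= covered_to) next
      p <- i
      while (p > 1L && good_a[p - 1L] && good_b[p - 1L + d] && a[p - 1L] == b[p - 1L + d]) {
        p <- p - 1L
      }
      q <- i + k - 1L
      while (q < n - d && good_a[q + 1L] && good_b[q + 1L + d] && a[q + 1L] == b[q + 1L + d]) {
        q <- q + 1L
      }
      covered_to <- q
      len <- q - p + 1L
      if (len >= minlen) hits[[length(hits) + 1L]] <- c(p, p + d, len)
    }
  }
  hits
}

# maximal runs on anti-diagonals (reverse/palindromic): relation
# a[x] == b[c - x]; the match vector is symmetric about c/2, so each hit is
# canonicalized to (min start, max start) and center-spanning runs collapse to
# a single self hit
.antidiag_scan <- function(a, b, good_a, good_b, n, seeds_by_c, k, minlen) {
  hits <- list()
  for (cstr in names(seeds_by_c)) {
    cc <- as.integer(cstr)
    ss <- sort(unique(seeds_by_c[[cstr]]))
    covered <- NULL # matrix of covered [lo, hi] x-ranges on this anti-diagonal
    for (i in ss) {
      if (!is.null(covered) && any(i >= covered[, 1L] & i <= covered[, 2L])) next
      p <- i
      while (p > 1L && cc - p + 1L <= n && good_a[p - 1L] && good_b[cc - p + 1L] &&
             a[p - 1L] == b[cc - p + 1L]) {
        p <- p - 1L
      }
      q <- i + k - 1L
      while (q < n && cc - q - 1L >= 1L && good_a[q + 1L] && good_b[cc - q - 1L] &&
             a[q + 1L] == b[cc - q - 1L]) {
        q <- q + 1L
      }
      covered <- rbind(covered, c(p, q), c(cc - q, cc - p))
      len <- q - p + 1L
      if (len >= minlen) {
        i1 <- min(p, cc - q)
        i2 <- max(p, cc - q)
        hits[[paste(cc, i1)]] <- c(i1, i2, len)
      }
    }
  }
  hits
}

#' Find maximal dispersed repeats
#'
#' Censuses exact maximal repeat pairs of the four REPuter types with length
#' at least `min_repeat_len`. When a `quadripartite_structure` is supplied,
#' the full-length IRb-vs-IRa palindromic hit is flagged in the `ir_pair`
#' column (kept in the output by default -- it is the genome's defining
#' repeat, not an artifact).
#'
#' @param genome a [circular_genome()]
#' @param min_repeat_len minimum hit length in bp (default 8, the plastome
#'   census convention); must be >= 2
#' @param types subset of `c("forward", "palindromic", "reverse",
#'   "complement")`
#' @param structure optional `quadripartite_structure` used to flag the IR
#'   pair
#' @return data.frame sorted by (`start1`, `start2`, `rtype`) with 0-based
#'   half-open copy coordinates `start1`, `end1`, `start2`, `end2`, plus
#'   `rtype`, `length`, `ir_pair`
#' @export
find_repeats <- function(genome, min_repeat_len = 8L,
                         types = .REPEAT_TYPES, structure = NULL) {
  stopifnot(inherits(genome, "circular_genome"))
  min_repeat_len <- as.integer(min_repeat_len)
  if (min_repeat_len < 2L) stop("min_repeat_len must be >= 2")
  types <- match.arg(types, .REPEAT_TYPES, several.ok = TRUE)
  s <- genome$seq
  n <- genome$length
  a <- .chars(s)
  good <- a != "N"
  k <- min_repeat_len

  out <- list()
  add <- function(rtype, hits) {
    if (!length(hits)) return()
    m <- do.call(rbind, hits)
    out[[rtype]] <<- data.frame(
      rtype = rtype,
      start1 = m[, 1L] - 1L, end1 = m[, 1L] - 1L + m[, 3L],
      start2 = m[, 2L] - 1L, end2 = m[, 2L] - 1L + m[, 3L],
      length = m[, 3L], stringsAsFactors = FALSE
    )
  }

  idx_a <- .kmer_index(s, k)

  if ("forward" %in% types) {
    seeds <- list()
    for (pos in idx_a) {
      if (length(pos) < 2L) next
      pr <- utils::combn(sort(pos), 2L)
      d <- pr[2L, ] - pr[1L, ]
      for (t in seq_along(d)) {
        key <- as.character(d[t])
        seeds[[key]] <- c(seeds[[key]], pr[1L, t])
      }
    }
    add("forward", .diag_scan(a, a, good, good, n, seeds, k, min_repeat_len))
  }

  if ("complement" %in% types) {
    b <- .chars(comp_seq(s))
    idx_c <- .kmer_index(comp_seq(s), k)
    seeds <- list()
    for (km in intersect(names(idx_a), names(idx_c))) {
      for (i in idx_a[[km]]) {
        for (j in idx_c[[km]]) {
          # a[i..] == comp(a[j..]) <=> comp-kmer at j equals a-kmer at i
          if (j > i) {
            key <- as.character(j - i)
            seeds[[key]] <- c(seeds[[key]], i)
          }
        }
      }
    }
    add("complement", .diag_scan(a, b, good, good, n, seeds, k, min_repeat_len))
  }

  if ("reverse" %in% types) {
    rs <- rev_seq(s)
    idx_r <- .kmer_index(rs, k)
    seeds <- list()
    for (km in intersect(names(idx_a), names(idx_r))) {
      for (j in idx_a[[km]]) {
        for (t in idx_r[[km]]) {
          cc <- n - t + 1L + j # anti-diagonal of (interval1 at n-t-k+2, interval2 at j)
          seeds[[as.character(cc)]] <- c(seeds[[as.character(cc)]], n - t - k + 2L)
        }
      }
    }
    add("reverse", .antidiag_scan(a, a, good, good, n, seeds, k, min_repeat_len))
  }

  if ("palindromic" %in% types) {
    b <- .chars(comp_seq(s))
    rc <- revcomp(s)
    idx_p <- .kmer_index(rc, k)
    seeds <- list()
    for (km in intersect(names(idx_a), names(idx_p))) {
      for (j in idx_a[[km]]) {
        for (t in idx_p[[km]]) {
          cc <- n - t + 1L + j
          seeds[[as.character(cc)]] <- c(seeds[[as.character(cc)]], n - t - k + 2L)
        }
      }
    }
    add("palindromic", .antidiag_scan(a, b, good, good, n, seeds, k, min_repeat_len))
  }

  df <- if (length(out)) do.call(rbind, out) else {
    data.frame(rtype = character(0), start1 = integer(0), end1 = integer(0),
               start2 = integer(0), end2 = integer(0), length = integer(0),
               stringsAsFactors = FALSE)
  }
  df$ir_pair <- FALSE
  if (!is.null(structure) && nrow(df)) {
    irb <- structure$irb; ira <- structure$ira
    if (!irb$wraps && !ira$wraps) {
      df$ir_pair <- df$rtype == "palindromic" &
        df$length == structure$ir_len &
        pmin(df$start1, df$start2) == min(irb$start, ira$start) &
        pmax(df$start1, df$start2) == max(irb$start, ira$start)
    }
  }
  df <- df[order(df$start1, df$start2, df$rtype), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.canonical_rotation <- function(m) {
  k <- nchar(m)
  if (k == 1L) return(m)
  rots <- vapply(0:(k - 1L), function(r) paste0(substr(m, r + 1L, k), substr(m, 1L, r)),
                 character(1))
  min(rots)
}

.is_primitive <- function(m) {
  u <- nchar(m)
  if (u == 1L) return(TRUE)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L && m == strrep(substr(m, 1L, d), u %/% d)) return(FALSE)
  }
  TRUE
}

#' Find simple sequence repeats (microsatellites)
#'
#' Scans for maximal tandem runs of 1-6 bp motifs meeting per-unit minimum
#' copy numbers (defaults 10, 6, 5, 5, 5, 5 for mono- through hexanucleotide
#' motifs). A partial trailing unit is part of the reported locus but does not
#' count towards `copies`. Runs are split at N. A run whose motif is itself
#' periodic is only reported at its primitive unit size (an `AT` run is not
#' also an `ATAT` run).
#'
#' @param genome a [circular_genome()]
#' @param min_copies integer vector of length 6: minimum complete copies for
#'   units 1..6
#' @param structure optional `quadripartite_structure`; with
#'   `dedupe_ir = TRUE`, hits wholly inside IRb are dropped so IR-internal
#'   SSRs count once
#' @param dedupe_ir drop the IRb copy of IR-internal SSRs (default FALSE:
#'   whole-genome scan, both IR copies counted)
#' @return data.frame with `motif` (canonical minimal rotation), `motif_obs`
#'   (first unit as it occurs), `unit`, `copies`, `start`, `end` (0-based
#'   half-open), `length`
#' @export
find_ssrs <- function(genome, min_copies = c(10L, 6L, 5L, 5L, 5L, 5L),
                      structure = NULL, dedupe_ir = FALSE) {
  stopifnot(inherits(genome, "circular_genome"), length(min_copies) == 6L)
  s <- genome$seq
  n <- genome$length
  a <- .chars(s)
  good <- a != "N"
  rows <- list()
  for (u in 1:6) {
    if (n <= u) next
    x <- 1:(n - u)
    v <- a[x] == a[x + u] & good[x] & good[x + u]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    begs <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      p <- begs[i]
      len <- r$lengths[i] + u # full tandem stretch incl. partial trailing unit
      copies <- len %/% u
      if (copies < min_copies[u]) next
      motif_obs <- substr(s, p, p + u - 1L)
      if (!.is_primitive(motif_obs)) next
      rows[[length(rows) + 1L]] <- data.frame(
        motif = .canonical_rotation(motif_obs), motif_obs = motif_obs,
        unit = u, copies = copies, start = p - 1L, end = p - 1L + len,
        length = len, stringsAsFactors = FALSE
      )
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(motif = character(0), motif_obs = character(0), unit = integer(0),
               copies = integer(0), start = integer(0), end = integer(0),
               length = integer(0), stringsAsFactors = FALSE)
  }
  if (dedupe_ir && !is.null(structure) && nrow(df)) {
    irb <- structure$irb
    if (!irb$wraps) {
      inside_irb <- df$start >= irb$start & df$end <= irb$end
      df <- df[!inside_irb, , drop = FALSE]
    }
  }
  df <- df[order(df$start, df$unit), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Summarise repeat and SSR censuses
#'
#' @param repeats output of [find_repeats()] (or NULL)
#' @param ssrs output of [find_ssrs()] (or NULL)
#' @return list with `repeat_counts` (per type), `ssr_counts` (per unit size),
#'   `n_repeats`, `n_ssrs`
#' @export
repeat_summary <- function(repeats = NULL, ssrs = NULL) {
  rc <- stats::setNames(integer(4), .REPEAT_TYPES)
  if (!is.null(repeats) && nrow(repeats)) {
    tb <- table(factor(repeats$rtype, levels = .REPEAT_TYPES))
    rc[] <- as.integer(tb)
  }
  sc <- stats::setNames(integer(6), as.character(1:6))
  if (!is.null(ssrs) && nrow(ssrs)) {
    tb <- table(factor(ssrs$unit, levels = 1:6))
    sc[] <- as.integer(tb)
  }
  list(repeat_counts = rc, ssr_counts = sc,
       n_repeats = sum(rc), n_ssrs = sum(sc))
}
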
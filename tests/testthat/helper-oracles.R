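# Independent brute-force oracles used to validate the scanners and column
# statistics. These deliberately use different algorithms from the package:
# full diagonal/anti-diagonal run-length scans for repeats, a per-position
# walk for SSRs, per-column loops for alignment statistics.

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

.o_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

.o_runs <- function(v) {
  r <- rle(v)
  e <- cumsum(r$lengths)
  s <- e - r$lengths + 1L
  cbind(s[r$values], e[r$values], deparse.level = 0)
}

# every maximal repeat pair of the four types, by exhaustive (anti-)diagonal
# run-length scan; same reporting conventions as find_repeats
oracle_repeats <- function(seq, minlen,
                           types = c("forward", "palindromic", "reverse", "complement")) {
  a <- .o_chars(seq)
  n <- length(a)
  good <- a != "N"
  res <- list()
  add <- function(rtype, i1, i2, len) {
    res[[length(res) + 1L]] <<- data.frame(
      rtype = rtype, start1 = i1 - 1L, end1 = i1 - 1L + len,
      start2 = i2 - 1L, end2 = i2 - 1L + len, length = len,
      stringsAsFactors = FALSE
    )
  }
  diag_type <- function(b, rtype) {
    for (d in 1:(n - 1L)) {
      m <- n - d
      v <- a[1:m] == b[(1 + d):n] & good[1:m] & good[(1 + d):n]
      rr <- .o_runs(v)
      for (q in seq_len(nrow(rr))) {
        len <- rr[q, 2] - rr[q, 1] + 1L
        if (len >= minlen) add(rtype, rr[q, 1], rr[q, 1] + d, len)
      }
    }
  }
  anti_type <- function(b, rtype) {
    hits <- list()
    for (cc in 3:(2L * n - 1L)) {
      xs <- max(1L, cc - n):min(n, cc - 1L)
      v <- a[xs] == b[cc - xs] & good[xs] & good[cc - xs]
      rr <- .o_runs(v)
      for (q in seq_len(nrow(rr))) {
        p <- xs[rr[q, 1]]
        qq <- xs[rr[q, 2]]
        len <- qq - p + 1L
        if (len < minlen) next
        i1 <- min(p, cc - qq)
        i2 <- max(p, cc - qq)
        hits[[paste(cc, i1)]] <- c(i1, i2, len)
      }
    }
    for (h in hits) add(rtype, h[1], h[2], h[3])
  }
  if ("forward" %in% types) diag_type(a, "forward")
  if ("complement" %in% types) diag_type(.o_chars(comp_seq(seq)), "complement")
  if ("reverse" %in% types) anti_type(a, "reverse")
  if ("palindromic" %in% types) anti_type(.o_chars(comp_seq(seq)), "palindromic")
  out <- if (length(res)) do.call(rbind, res) else {
    data.frame(rtype = character(0), start1 = integer(0), end1 = integer(0),
               start2 = integer(0), end2 = integer(0), length = integer(0),
               stringsAsFactors = FALSE)
  }
  out <- out[order(out$rtype, out$start1, out$start2, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# naive per-position SSR walk applying the same thresholds and conventions
oracle_ssrs <- function(seq, min_copies = c(10L, 6L, 5L, 5L, 5L, 5L)) {
  a <- .o_chars(seq)
  n <- length(a)
  min_rot <- function(m) {
    k <- nchar(m)
    if (k == 1L) return(m)
    min(vapply(0:(k - 1L), function(r) paste0(substr(m, r + 1L, k), substr(m, 1L, r)),
               character(1)))
  }
  primitive <- function(m) {
    u <- nchar(m)
    if (u > 1L) {
      for (d in seq_len(u - 1L)) {
        if (u %% d == 0L && m == strrep(substr(m, 1L, d), u %/% d)) return(FALSE)
      }
    }
    TRUE
  }
  rows <- list()
  for (u in 1:6) {
    t <- 1L
    while (t + u <= n) {
      # is t the start of a maximal stretch?
      start_ok <- (t == 1L) || a[t - 1L] != a[t - 1L + u] || a[t - 1L] == "N" ||
        a[t - 1L + u] == "N"
      if (start_ok && a[t] != "N") {
        x <- t
        while (x + u <= n && a[x] != "N" && a[x + u] != "N" && a[x] == a[x + u]) x <- x + 1L
        if (x > t) { # at least one period match
          len <- (x - t) + u
          copies <- len %/% u
          motif <- paste(a[t:(t + u - 1L)], collapse = "")
          if (copies >= min_copies[u] && primitive(motif)) {
            rows[[length(rows) + 1L]] <- data.frame(
              motif = min_rot(motif), unit = u, copies = copies,
              start = t - 1L, end = t - 1L + len, length = len,
              stringsAsFactors = FALSE
            )
          }
          t <- x
        } else t <- t + 1L
      } else t <- t + 1L
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(motif = character(0), unit = integer(0), copies = integer(0),
               start = integer(0), end = integer(0), length = integer(0),
               stringsAsFactors = FALSE)
  }
  out <- out[order(out$start, out$unit), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-column brute force for variable / parsimony-informative columns
oracle_vc <- function(rows) {
  mat <- do.call(rbind, strsplit(unname(rows), "", fixed = TRUE))
  ns <- 0L
  for (j in seq_len(ncol(mat))) {
    st <- unique(mat[, j])
    st <- st[st %in% c("A", "C", "G", "T")]
    if (length(st) >= 2L) ns <- ns + 1L
  }
  ns
}

oracle_pic <- function(rows) {
  mat <- do.call(rbind, strsplit(unname(rows), "", fixed = TRUE))
  np <- 0L
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    col <- col[col %in% c("A", "C", "G", "T")]
    tb <- table(col)
    if (sum(tb >= 2L) >= 2L) np <- np + 1L
  }
  np
}

# random gapped alignment for the column-statistic oracles
rand_alignment <- function(k, L, gap_p = 0.1, n_p = 0.05) {
  rows <- vapply(seq_len(k), function(i) {
    rand_seq(L, c(rep(c("A", "C", "G", "T"), each = 5),
                  rep("-", round(20 * gap_p)), rep("N", round(20 * n_p))))
  }, character(1))
  names(rows) <- paste0("t", seq_len(k))
  rows
}

# Monte-Carlo probability that a star-tree column with per-branch substitution
# probability p over k taxa is variable (>= 2 distinct tip states)
mc_variable_prob <- function(p, k, nsim = 200000L) {
  mut <- matrix(stats::runif(nsim * k) < p, nsim, k)
  shift <- matrix(0L, nsim, k)
  shift[mut] <- sample.int(3L, sum(mut), replace = TRUE)
  # states 0..3: 0 = ancestral base; by JC symmetry the ancestral base is wlog
  var <- apply(shift, 1, function(r) length(unique(r)) >= 2L)
  mean(var)
}
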
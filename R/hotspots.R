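# Per-locus alignment, variability statistics and marker selection.
#
# The variability statistic per locus is (NS / L) x 100 where NS is the number
# of variable columns (>= 2 distinct bases from {A,C,G,T}; gaps and N carry no
# state) and L the aligned length. Parsimony-informative columns additionally
# require >= 2 states each present in >= 2 rows. Percentages are rounded half
# up to 2 decimals, the class rate ratio to 1 decimal, matching printed
# precision in published marker tables.

.aln_matrix <- function(rows) {
  do.call(rbind, strsplit(unname(rows), "", fixed = TRUE))
}

#' Multiple alignment of a homologous locus set
#'
#' Deterministic center-star multiple alignment: the center is the sequence
#' with the highest summed pairwise global alignment score (ties broken by
#' taxon name); every other sequence is aligned to the center with affine gap
#' penalties and the pairwise alignments are merged column-wise ("once a gap,
#' always a gap"). Pre-aligned rows may be supplied instead via `prealigned`
#' and are validated and used as-is.
#'
#' @param locus either a `locus_set` (see [collect_homologs()]) or a named
#'   character vector of sequences (>= 2, none empty)
#' @param match,mismatch,gap_open,gap_extend scoring parameters (defaults 1,
#'   -1, -4, -1); N scores 0 against everything
#' @param prealigned logical; if TRUE, `locus` rows must already be aligned
#'   (equal lengths over A,C,G,T,N,-)
#' @return a `locus_alignment`: `rows` (named aligned strings), `L` (aligned
#'   length), plus locus metadata when a `locus_set` was given
#' @export
align_locus <- function(locus, match = 1, mismatch = -1, gap_open = -4,
                        gap_extend = -1, prealigned = FALSE) {
  meta <- list(name = NA_character_, lclass = NA_character_,
               region = NA_character_, length_range = c(NA_integer_, NA_integer_))
  if (inherits(locus, "locus_set")) {
    meta <- locus[c("name", "lclass", "region", "length_range")]
    seqs <- locus$seqs
  } else {
    seqs <- locus
  }
  stopifnot(is.character(seqs), length(seqs) >= 2L, !is.null(names(seqs)))
  if (any(!nzchar(gsub("-", "", seqs, fixed = TRUE)))) {
    stop("align_locus: empty sequence in locus '", meta$name, "'")
  }

  mk_aln <- function(rows) {
    structure(c(list(rows = rows, L = nchar(rows[[1]])), meta),
              class = "locus_alignment")
  }

  if (prealigned) {
    if (length(unique(nchar(seqs))) != 1L) {
      stop("prealigned rows have unequal lengths")
    }
    if (any(grepl("[^ACGTN-]", seqs))) stop("prealigned rows contain invalid characters")
    return(mk_aln(seqs))
  }

  if (length(unique(seqs)) == 1L) return(mk_aln(seqs)) # identical: no gaps

  bases <- c("A", "C", "G", "T", "N")
  submat <- matrix(mismatch, 5, 5, dimnames = list(bases, bases))
  diag(submat) <- match
  submat["N", ] <- 0
  submat[, "N"] <- 0
  go <- abs(gap_open) - abs(gap_extend)
  ge <- abs(gap_extend)

  k <- length(seqs)
  if (k == 2L) {
    center_i <- 1L
  } else {
    set <- Biostrings::DNAStringSet(seqs)
    sc <- vapply(seq_len(k), function(j) {
      Biostrings::pairwiseAlignment(
        set, seqs[[j]], type = "global", substitutionMatrix = submat,
        gapOpening = go, gapExtension = ge, scoreOnly = TRUE
      )
    }, numeric(k))
    diag(sc) <- 0
    ordr <- order(-rowSums(sc), names(seqs))
    center_i <- ordr[1]
  }

  center <- seqs[[center_i]]
  m <- nchar(center)
  others <- setdiff(seq_len(k), center_i)

  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(seqs[others]), center, type = "global",
    substitutionMatrix = submat, gapOpening = go, gapExtension = ge
  )
  cen_gapped <- as.character(Biostrings::alignedSubject(al))
  oth_gapped <- as.character(Biostrings::alignedPattern(al))

  # per-alignment gapped strings against the center
  cen_rows <- list()
  sub_rows <- list()
  ins_max <- integer(m + 1L) # max insertions after center position i (0..m)
  for (t in seq_along(others)) {
    j <- others[t]
    cg <- .chars(cen_gapped[t])
    sg <- .chars(oth_gapped[t])
    cen_rows[[as.character(j)]] <- cg
    sub_rows[[as.character(j)]] <- sg
    ins <- integer(m + 1L)
    ci <- 0L
    run <- 0L
    for (t in seq_along(cg)) {
      if (cg[t] == "-") {
        run <- run + 1L
      } else {
        if (run > 0L) ins[ci + 1L] <- max(ins[ci + 1L], run)
        run <- 0L
        ci <- ci + 1L
      }
    }
    if (run > 0L) ins[ci + 1L] <- max(ins[ci + 1L], run)
    ins_max <- pmax(ins_max, ins)
  }

  # master center row with pooled insertions
  cen_ch <- .chars(center)
  expand_center <- c(
    if (ins_max[1L] > 0L) rep("-", ins_max[1L]),
    unlist(lapply(seq_len(m), function(i) {
      c(cen_ch[i], if (ins_max[i + 1L] > 0L) rep("-", ins_max[i + 1L]))
    }))
  )

  # re-emit each subject in master coordinates, left-aligning each insertion
  # block and padding with gaps on its right
  project <- function(cg, sg) {
    out <- character(0)
    ci <- 0L
    t <- 1L
    nt <- length(cg)
    blk <- function(ci, chunk) {
      cap <- ins_max[ci + 1L]
      c(chunk, rep("-", cap - length(chunk)))
    }
    chunk <- character(0)
    # leading insertion block
    while (t <= nt && cg[t] == "-") {
      chunk <- c(chunk, sg[t])
      t <- t + 1L
    }
    out <- c(out, blk(0L, chunk))
    while (t <= nt) {
      # a center base
      out <- c(out, sg[t])
      ci <- ci + 1L
      t <- t + 1L
      chunk <- character(0)
      while (t <= nt && cg[t] == "-") {
        chunk <- c(chunk, sg[t])
        t <- t + 1L
      }
      out <- c(out, blk(ci, chunk))
    }
    out
  }

  rows <- stats::setNames(vector("list", k), names(seqs))
  rows[[center_i]] <- expand_center
  for (j in others) {
    rows[[j]] <- project(cen_rows[[as.character(j)]], sub_rows[[as.character(j)]])
  }
  rows <- vapply(rows, .collapse, character(1))

  # invariant: removing gaps reproduces every input sequence
  for (j in seq_len(k)) {
    if (gsub("-", "", rows[j], fixed = TRUE) != seqs[[j]]) {
      stop("internal error: center-star merge corrupted sequence '", names(seqs)[j], "'")
    }
  }
  mk_aln(rows)
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("<locus_alignment> %s: %d rows x %d columns\n",
              x$name %||% "?", length(x$rows), x$L))
  invisible(x)
}

.col_base_counts <- function(mat) {
  apply(mat, 2, function(col) table(factor(col[col %in% c("A", "C", "G", "T")],
                                           levels = c("A", "C", "G", "T"))))
}

#' Count variable columns (NS)
#'
#' A column is variable when it holds at least two distinct bases from
#' A,C,G,T; gaps and N carry no state, so columns varying only by gaps/N are
#' not variable.
#'
#' @param alignment a `locus_alignment` (or named character vector of equal
#'   length rows)
#' @return integer count of variable columns
#' @export
count_vc <- function(alignment) {
  rows <- if (inherits(alignment, "locus_alignment")) alignment$rows else alignment
  mat <- .aln_matrix(rows)
  cnt <- .col_base_counts(mat)
  sum(colSums(cnt > 0L) >= 2L)
}

#' Count parsimony-informative columns (PICs)
#'
#' A column is parsimony-informative when at least two distinct bases each
#' occur in at least two rows (gaps/N excluded from states).
#'
#' @inheritParams count_vc
#' @return integer count; always `<=` [count_vc()]
#' @export
count_pic <- function(alignment) {
  rows <- if (inherits(alignment, "locus_alignment")) alignment$rows else alignment
  mat <- .aln_matrix(rows)
  cnt <- .col_base_counts(mat)
  sum(colSums(cnt >= 2L) >= 2L)
}

#' Per-locus variability table and class summaries
#'
#' Computes the Table-2-style record for every locus alignment: aligned length
#' L, number of variable columns NS, percentage of variable characters
#' `pct_vc = 100 * NS / L`, number and percentage of parsimony-informative
#' characters. Class summaries give min/max/mean `pct_vc` per locus class
#' (unweighted over loci) and the non-coding/coding mean ratio to 1 decimal.
#'
#' @param alignments list of `locus_alignment` objects
#' @return list with `records` (data.frame, one row per locus) and
#'   `class_summary` (data.frame with per-class min/max/mean and `ratio`
#'   attribute); the ratio is also returned as `$ratio`
#' @export
variability_table <- function(alignments) {
  stopifnot(length(alignments) >= 1L)
  rows <- lapply(alignments, function(al) {
    ns <- count_vc(al)
    np <- count_pic(al)
    lr <- al$length_range %||% c(NA_integer_, NA_integer_)
    data.frame(
      name = al$name %||% NA_character_,
      lclass = al$lclass %||% NA_character_,
      region = al$region %||% NA_character_,
      length_min = lr[1], length_max = lr[2],
      L = al$L, NS = ns,
      pct_vc = round_half_up(100 * ns / al$L, 2),
      n_pic = np,
      pct_pic = round_half_up(100 * np / al$L, 2),
      stringsAsFactors = FALSE
    )
  })
  rec <- do.call(rbind, rows)
  rownames(rec) <- NULL

  cs <- NULL
  ratio <- NA_real_
  if (!all(is.na(rec$lclass))) {
    cs <- do.call(rbind, lapply(split(rec, rec$lclass), function(d) {
      data.frame(
        lclass = d$lclass[1], n_loci = nrow(d),
        min_pct_vc = min(d$pct_vc), max_pct_vc = max(d$pct_vc),
        mean_pct_vc = round_half_up(mean(d$pct_vc), 2),
        stringsAsFactors = FALSE
      )
    }))
    rownames(cs) <- NULL
    if (all(c("coding", "noncoding") %in% cs$lclass)) {
      ratio <- class_rate_ratio(
        cs$mean_pct_vc[cs$lclass == "noncoding"],
        cs$mean_pct_vc[cs$lclass == "coding"]
      )
    }
  }
  list(records = rec, class_summary = cs, ratio = ratio)
}

#' Non-coding / coding mean-rate ratio
#'
#' @param mean_noncoding,mean_coding per-class mean percentages of variable
#'   characters
#' @return the ratio rounded half up to 1 decimal
#' @export
#' @examples
#' class_rate_ratio(12.33, 6.50)  # 1.9
class_rate_ratio <- function(mean_noncoding, mean_coding) {
  round_half_up(mean_noncoding / mean_coding, 1)
}

#' Rank loci and select candidate markers
#'
#' Sorts records of the requested class by `pct_vc` descending (ties:
#' `pct_pic` descending, then name) and keeps the top `top_n`, or all records
#' above `min_pct_vc` when given. Stable under permutation of the input.
#'
#' @param records the `records` data.frame from [variability_table()] (or any
#'   data.frame with `name`, `lclass`, `pct_vc`, `pct_pic` columns)
#' @param lclass locus class to rank (default `"noncoding"`; use NULL for all)
#' @param top_n number of markers to keep (default 20)
#' @param min_pct_vc optional threshold; overrides `top_n` when given (strict
#'   `>` comparison)
#' @return the selected rows, ranked, with a `rank` column
#' @export
select_markers <- function(records, lclass = "noncoding", top_n = 20L,
                           min_pct_vc = NULL) {
  d <- records
  if (!is.null(lclass)) d <- d[!is.na(d$lclass) & d$lclass == lclass, , drop = FALSE]
  d <- d[order(-d$pct_vc, -d$pct_pic, d$name), , drop = FALSE]
  if (!is.null(min_pct_vc)) {
    d <- d[d$pct_vc > min_pct_vc, , drop = FALSE]
  } else {
    if (top_n > nrow(d)) {
      warning("top_n = ", top_n, " exceeds the ", nrow(d), " available loci; returning all")
      top_n <- nrow(d)
    }
    d <- utils::head(d, top_n)
  }
  if (nrow(d)) d$rank <- seq_len(nrow(d))
  rownames(d) <- NULL
  d
}

#' Sliding-window percent identity profile
#'
#' For each non-reference row and each window over the alignment columns,
#' reports `100 * matches / comparable` where comparable positions are those
#' where both rows hold a base (A,C,G,T; gaps and N excluded). Windows with
#' fewer than 10 comparable positions give NA.
#'
#' @param alignment a `locus_alignment` or named character vector of aligned
#'   rows (>= 2)
#' @param reference name of the reference row (default: first row)
#' @param window window width in columns (default 100; must be >= 10 and
#'   >= `step`)
#' @param step step between window starts (default 25)
#' @return data.frame with `taxon`, `window_start`, `window_end` (1-based
#'   columns), `identity`
#' @export
sliding_identity <- function(alignment, reference = NULL, window = 100L, step = 25L) {
  rows <- if (inherits(alignment, "locus_alignment")) alignment$rows else alignment
  stopifnot(is.character(rows), length(rows) >= 2L, !is.null(names(rows)))
  if (window < step || window < 10L) {
    stop("window must be >= 10 and >= step")
  }
  reference <- reference %||% names(rows)[1]
  if (!reference %in% names(rows)) stop("reference '", reference, "' not among rows")
  mat <- .aln_matrix(rows)
  rownames(mat) <- names(rows)
  L <- ncol(mat)
  starts <- seq.int(1L, max(1L, L - window + 1L), by = step)
  refrow <- mat[reference, ]
  is_base <- function(x) x %in% c("A", "C", "G", "T")
  ref_ok <- is_base(refrow)
  out <- list()
  for (tx in setdiff(names(rows), reference)) {
    r <- mat[tx, ]
    comparable <- ref_ok & is_base(r)
    matches <- comparable & (r == refrow)
    for (w in starts) {
      hi <- min(L, w + window - 1L)
      nc <- sum(comparable[w:hi])
      out[[length(out) + 1L]] <- data.frame(
        taxon = tx, window_start = w, window_end = hi,
        identity = if (nc < 10L) NA_real_ else 100 * sum(matches[w:hi]) / nc,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
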
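# Quadripartite structure detection and IR-junction analysis.
#
# The IR pair is found as the maximal-length exact inverted repeat of the
# circular sequence (seed-and-extend on the doubled sequence, mismatch
# tolerance 0). The two single-copy arcs between the IR copies become LSC
# (longer) and SSC (shorter); in the conventional orientation the genome reads
# LSC -> IRb -> SSC -> IRa, so IRb is the copy adjacent to the downstream end
# of the LSC. The junction between region X and region Y is the 0-based
# coordinate of the first base of Y: JLB = LSC/IRb, JSB = IRb/SSC,
# JSA = SSC/IRa, JLA = IRa/LSC.

.structure_from_parts <- function(n, irb_start, ir_len, ssc_len) {
  lsc_len <- n - 2L * ir_len - ssc_len
  stopifnot(lsc_len >= 1L, ssc_len >= 1L, ir_len >= 1L)
  jlb <- .mod(irb_start, n)
  jsb <- .mod(jlb + ir_len, n)
  jsa <- .mod(jsb + ssc_len, n)
  jla <- .mod(jsa + ir_len, n)
  structure(
    list(
      lsc = mk_interval(jla, lsc_len, n),
      irb = mk_interval(jlb, ir_len, n),
      ssc = mk_interval(jsb, ssc_len, n),
      ira = mk_interval(jsa, ir_len, n),
      jlb = jlb, jsb = jsb, jsa = jsa, jla = jla,
      ir_len = ir_len, genome_length = n,
      lengths = c(lsc = lsc_len, irb = ir_len, ssc = ssc_len, ira = ir_len)
    ),
    class = "quadripartite_structure"
  )
}

#' @export
print.quadripartite_structure <- function(x, ...) {
  cat(sprintf("<quadripartite_structure> %s bp: LSC %d | IRb %d | SSC %d | IRa %d\n",
              format(x$genome_length, big.mark = ","),
              x$lengths["lsc"], x$lengths["irb"], x$lengths["ssc"], x$lengths["ira"]))
  cat(sprintf("  junctions (0-based): JLB %d  JSB %d  JSA %d  JLA %d\n",
              x$jlb, x$jsb, x$jsa, x$jla))
  invisible(x)
}

#' Detect the inverted-repeat pair and partition a plastome
#'
#' Finds the maximal-length exact inverted repeat pair of a circular genome by
#' seed-and-extend between the doubled sequence and its reverse complement,
#' then labels the longer single-copy arc LSC and the shorter SSC. Fails with
#' a structured `plasto_no_ir` error when no inverted repeat of at least
#' `min_ir_len` exists (as in IR-lacking plastomes such as many conifers), and
#' with `plasto_ambiguous_ir` when several non-overlapping pairs tie at the
#' maximal length.
#'
#' @param genome a [circular_genome()]
#' @param min_ir_len minimum IR length in bp (default 1000)
#' @param seed_len seed length for the match search (default 25)
#' @return a `quadripartite_structure`: intervals `lsc`, `irb`, `ssc`, `ira`
#'   (0-based half-open, `wraps` flags), junction positions `jlb`, `jsb`,
#'   `jsa`, `jla` (0-based first base of the downstream region), `ir_len`,
#'   and per-region `lengths`
#' @export
detect_ir <- function(genome, min_ir_len = 1000L, seed_len = 25L) {
  stopifnot(inherits(genome, "circular_genome"))
  s <- genome$seq
  n <- genome$length
  min_ir_len <- as.integer(min_ir_len)
  seed_len <- as.integer(min(seed_len, min_ir_len))
  no_ir <- function() {
    stop(errorCondition(
      sprintf("no inverted repeat of length >= %d bp found in '%s'", min_ir_len, genome$id),
      class = c("plasto_no_ir", "error", "condition")
    ))
  }
  if (n < 2L * min_ir_len + 2L) no_ir()

  D <- paste0(s, s)
  chD <- .chars(D)
  cmD <- .chars(comp_seq(D))
  goodD <- chD != "N"

  # any IR copy >= min_ir_len starting in the first period fully contains a
  # seed taken at this stride
  stride <- max(1L, min_ir_len - seed_len + 1L)
  starts <- seq.int(1L, n, by = stride)
  seeds <- substring(D, starts, starts + seed_len - 1L)
  ok <- !grepl("N", seeds, fixed = TRUE)
  starts <- starts[ok]
  seeds <- seeds[ok]
  if (!length(starts)) no_ir()

  pd <- Biostrings::PDict(Biostrings::DNAStringSet(revcomp(seeds)))
  mt <- Biostrings::matchPDict(pd, Biostrings::DNAString(D))
  cs <- integer(0)
  for (t in seq_along(starts)) {
    q <- BiocGenerics::start(mt[[t]])
    if (length(q)) cs <- c(cs, starts[t] + q + seed_len - 1L) # anti-diagonal p+q+k-1
  }
  cs <- unique(cs)
  if (!length(cs)) no_ir()

  cand <- list()
  for (cc in cs) {
    x1 <- max(1L, cc - 2L * n)
    x2 <- min(2L * n, cc - 1L)
    if (x2 < x1) next
    xs <- x1:x2
    v <- chD[xs] == cmD[cc - xs] & goodD[xs] & goodD[cc - xs]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    begs <- ends - r$lengths + 1L
    for (i in which(r$values & r$lengths >= min_ir_len)) {
      a <- xs[begs[i]]
      b <- xs[ends[i]]
      len <- b - a + 1L
      if (len > n %/% 2L) len <- n %/% 2L # degenerate safety cap
      s1 <- .mod(a - 1L, n)
      s2 <- .mod(cc - b - 1L, n)
      lo <- min(s1, s2); hi <- max(s1, s2)
      f12 <- .mod(hi - lo, n)
      # the two copies must be circularly disjoint with non-empty arcs
      if (f12 < len + 1L || n - f12 < len + 1L) next
      cand[[paste(lo, hi, len)]] <- c(lo = lo, hi = hi, len = len)
    }
  }
  if (!length(cand)) no_ir()
  cand <- do.call(rbind, cand)
  best_len <- max(cand[, "len"])
  best <- unique(cand[cand[, "len"] == best_len, , drop = FALSE])
  if (nrow(best) > 1L) {
    stop(errorCondition(
      paste0("ambiguous IR in '", genome$id, "': ", nrow(best),
             " non-overlapping candidate pairs of maximal length ", best_len, " bp: ",
             paste(sprintf("[%d,%d]", best[, "lo"], best[, "hi"]), collapse = " ")),
      class = c("plasto_ambiguous_ir", "error", "condition")
    ))
  }

  lo <- best[1, "lo"]; hi <- best[1, "hi"]; len <- best[1, "len"]
  arc_a <- .mod(hi - (lo + len), n)       # arc from end of copy at `lo` to `hi`
  arc_b <- n - 2L * len - arc_a           # the other arc
  if (arc_a >= arc_b) {
    # LSC runs from end of `lo` copy to start of `hi` copy -> IRb is `hi`
    st <- .structure_from_parts(n, irb_start = hi, ir_len = len, ssc_len = arc_b)
  } else {
    st <- .structure_from_parts(n, irb_start = lo, ir_len = len, ssc_len = arc_a)
  }
  irb_seq <- circ_substr(s, st$irb$start, st$ir_len, n)
  ira_seq <- circ_substr(s, st$ira$start, st$ir_len, n)
  if (!identical(irb_seq, revcomp(ira_seq))) {
    stop("internal error: detected IR copies are not exact reverse complements")
  }
  st
}

# region sequences as a named character vector
structure_sequences <- function(genome, st) {
  n <- genome$length
  vapply(c("lsc", "irb", "ssc", "ira"),
         function(r) circ_substr(genome$seq, st[[r]]$start, st[[r]]$span, n),
         character(1))
}

# linearized extent of a (possibly multi-part, possibly origin-crossing) gene:
# 0-based start plus total span along the circle
.gene_extents <- function(features, n) {
  ids <- unique(features$id)
  out <- lapply(ids, function(gid) {
    fr <- features[features$id == gid, , drop = FALSE]
    fr <- fr[order(fr$part), , drop = FALSE]
    ref <- fr$start[1]
    spans <- ifelse(fr$wraps, (n - fr$start) + fr$end, fr$end - fr$start)
    rel_start <- .mod(fr$start - ref, n)
    rel_end <- rel_start + spans
    data.frame(
      id = gid, name = fr$name[1], kind = fr$kind[1], strand = fr$strand[1],
      pseudo = fr$pseudo[1],
      start = .mod(ref + min(rel_start), n),
      span = max(rel_end) - min(rel_start),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Report genes at the four IR junctions
#'
#' For each junction the spanning gene is reported if one exists (`spans`
#' requires the junction to lie strictly inside the gene, i.e. the gene covers
#' both bases flanking the boundary); otherwise the nearest gene on each side
#' is reported with its distance in bp from the gene's nearest end to the
#' junction. A gene abutting a junction exactly gets distance 0 but not
#' `spans`.
#'
#' @param structure a `quadripartite_structure`
#' @param features annotation data.frame (see [read_annotations()])
#' @return data.frame with columns `junction`, `gene`, `relation`
#'   (`spans`/`upstream`/`downstream`), `distance`
#' @export
junction_report <- function(structure, features) {
  empty <- data.frame(junction = character(0), gene = character(0),
                      relation = character(0), distance = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(features) || nrow(features) == 0L) return(empty)
  n <- structure$genome_length
  ext <- .gene_extents(features, n)
  rows <- list()
  for (jn in c("JLB", "JSB", "JSA", "JLA")) {
    j <- structure[[tolower(jn)]]
    contains_j <- .mod(j - ext$start, n) < ext$span
    contains_prev <- .mod(.mod(j - 1L, n) - ext$start, n) < ext$span
    spanning <- which(contains_j & contains_prev)
    if (length(spanning)) {
      for (i in spanning) {
        rows[[length(rows) + 1L]] <- data.frame(
          junction = jn, gene = ext$name[i], relation = "spans", distance = 0L,
          stringsAsFactors = FALSE
        )
      }
    } else {
      gene_end <- .mod(ext$start + ext$span, n)
      dup <- .mod(j - gene_end, n)       # gene ends before the boundary
      ddown <- .mod(ext$start - j, n)    # gene starts after the boundary
      iu <- order(dup, ext$name)[1]
      id <- order(ddown, ext$name)[1]
      rows[[length(rows) + 1L]] <- data.frame(
        junction = jn, gene = ext$name[iu], relation = "upstream",
        distance = dup[iu], stringsAsFactors = FALSE
      )
      rows[[length(rows) + 1L]] <- data.frame(
        junction = jn, gene = ext$name[id], relation = "downstream",
        distance = ddown[id], stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign each gene to the region wholly containing it
#'
#' Genes straddling a junction are labelled `"junction"`; used to report IR
#' expansion/contraction shifts such as a gene moving into the LSC.
#'
#' @inheritParams junction_report
#' @return data.frame with columns `id`, `gene`, `region`
#' @export
gene_regions <- function(structure, features) {
  n <- structure$genome_length
  ext <- .gene_extents(features, n)
  region <- vapply(seq_len(nrow(ext)), function(i) {
    for (r in c("lsc", "irb", "ssc", "ira")) {
      iv <- structure[[r]]
      off <- .mod(ext$start[i] - iv$start, n)
      if (off < iv$span && off + ext$span[i] <= iv$span) return(toupper(r))
    }
    "junction"
  }, character(1))
  data.frame(id = ext$id, gene = ext$name, region = region, stringsAsFactors = FALSE)
}

#' Compare IR junctions across genomes
#'
#' Combines per-genome junction reports and region lengths, and classifies
#' genomes into "IR types" by the identity and relation of the genes at the
#' JSB and JSA junctions (e.g. a genome where ndhF straddles JSB is a
#' different type from one where ndhF lies wholly in the SSC).
#'
#' @param bundles named list; each element a list with `structure` (from
#'   [detect_ir()]) and `features`
#' @return list with `junctions` (long-format table), `regions` (per-gene
#'   region assignment), `lengths` (per-genome region lengths), `ir_types`,
#'   and `ir_len_range` (max minus min IR length)
#' @export
compare_junctions <- function(bundles) {
  stopifnot(length(bundles) >= 2L, !is.null(names(bundles)))
  jt <- list(); rg <- list(); ln <- list(); ty <- list()
  for (g in names(bundles)) {
    st <- bundles[[g]]$structure
    fe <- bundles[[g]]$features
    jr <- junction_report(st, fe)
    if (nrow(jr)) jr <- cbind(genome = g, jr)
    jt[[g]] <- jr
    gr <- gene_regions(st, fe)
    if (nrow(gr)) gr <- cbind(genome = g, gr)
    rg[[g]] <- gr
    ln[[g]] <- data.frame(
      genome = g, genome_length = st$genome_length,
      lsc = unname(st$lengths["lsc"]), irb = unname(st$lengths["irb"]),
      ssc = unname(st$lengths["ssc"]), ira = unname(st$lengths["ira"]),
      ir_len = st$ir_len, stringsAsFactors = FALSE
    )
    key <- jr[jr$junction %in% c("JSB", "JSA"), , drop = FALSE]
    key <- key[order(key$junction, key$gene, key$relation), , drop = FALSE]
    ty[[g]] <- data.frame(
      genome = g,
      ir_type = paste(sprintf("%s:%s/%s", key$junction, key$gene, key$relation),
                      collapse = "; "),
      stringsAsFactors = FALSE
    )
  }
  lengths <- do.call(rbind, ln)
  rownames(lengths) <- NULL
  list(
    junctions = { x <- do.call(rbind, jt); rownames(x) <- NULL; x },
    regions = { x <- do.call(rbind, rg); rownames(x) <- NULL; x },
    lengths = lengths,
    ir_types = { x <- do.call(rbind, ty); rownames(x) <- NULL; x },
    ir_len_range = max(lengths$ir_len) - min(lengths$ir_len)
  )
}
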
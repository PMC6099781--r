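# Partitioning an annotated plastome into homologous loci.
#
# Coding loci are per-gene exon concatenations; non-coding loci are introns
# and intergenic spacers (the gap between consecutive annotated features,
# named "<geneA>-<geneB>" in canonical orientation). Only one IR copy (IRa)
# contributes loci; IRb is skipped to avoid double counting. Loci whose
# unaligned length is <= min_len are discarded (strictly greater kept).

# rotate a 0-based position into the frame where the LSC starts at 0
.rot <- function(pos, offset, n) .mod(pos - offset, n)

#' Extract coding and non-coding loci from an annotated genome
#'
#' The genome is viewed in canonical orientation (LSC first). Each annotated
#' gene yields one coding locus (exons joined, reverse-complemented for minus
#' strand genes); each intron and each gap between consecutive gene extents
#' yields a non-coding locus. Overlapping genes produce no spacer for the
#' overlap, which stays assigned to both coding loci (logged). Loci with
#' midpoint in IRb are dropped, as are loci of length <= `min_len`.
#'
#' @param genome a [circular_genome()]
#' @param features annotation data.frame (see [read_annotations()])
#' @param structure the genome's `quadripartite_structure`
#' @param min_len strict lower length bound in bp (default 100: loci must be
#'   > 100 bp)
#' @return data.frame with `name`, `lclass` (`coding`/`noncoding`), `kind`,
#'   `region`, `start`, `end`, `wraps` (0-based, original genome frame, the
#'   locus extent), `length` (unaligned locus length; excludes introns for
#'   multi-exon genes), `pseudo`, `seq`; attribute `"accounting"` carries
#'   base-level coverage bookkeeping over LSC+SSC+IRa
#' @export
extract_loci <- function(genome, features, structure, min_len = 100L) {
  stopifnot(inherits(genome, "circular_genome"))
  n <- genome$length
  off <- structure$jla # LSC start
  irb_lo <- .rot(structure$irb$start, off, n)
  irb_hi <- irb_lo + structure$irb$span

  ext <- .gene_extents(features, n)
  ext$rstart <- .rot(ext$start, off, n)

  cand <- list()
  # parts: matrix with columns rstart, span (rotated frame)
  push <- function(name, lclass, kind, parts, strand, pseudo) {
    cand[[length(cand) + 1L]] <<- list(
      name = name, lclass = lclass, kind = kind, parts = parts,
      strand = strand, pseudo = pseudo,
      rstart = parts[1L, 1L], span = sum(parts[, 2L]),
      extent = (parts[nrow(parts), 1L] + parts[nrow(parts), 2L]) - parts[1L, 1L]
    )
  }

  # coding loci (exon concatenations) and introns
  for (gid in unique(features$id)) {
    fr <- features[features$id == gid, , drop = FALSE]
    fr <- fr[order(fr$part), , drop = FALSE]
    spans <- ifelse(fr$wraps, (n - fr$start) + fr$end, fr$end - fr$start)
    rstarts <- .rot(fr$start, off, n)
    gname <- fr$name[1]
    push(gname, "coding", fr$kind[1], cbind(rstarts, spans), fr$strand[1], fr$pseudo[1])
    if (nrow(fr) > 1L) {
      for (j in seq_len(nrow(fr) - 1L)) {
        istart <- .mod(rstarts[j] + spans[j], n)
        ilen <- .mod(rstarts[j + 1L] - istart, n)
        if (ilen > 0L) {
          iname <- if (nrow(fr) > 2L) sprintf("%s intron %d", gname, j) else paste(gname, "intron")
          push(iname, "noncoding", "intron", cbind(istart, ilen), fr$strand[1], fr$pseudo[1])
        }
      }
    }
  }

  # spacers between consecutive gene extents along the rotated circle
  ord <- ext[order(ext$rstart), , drop = FALSE]
  overlap_bp <- 0L
  if (nrow(ord) >= 2L) {
    reach <- ord$rstart[1] + ord$span[1] # furthest extent end seen so far
    reach_name <- ord$name[1]
    for (i in 2:nrow(ord)) {
      gap <- ord$rstart[i] - reach
      if (gap > 0L) {
        push(paste0(reach_name, "-", ord$name[i]), "noncoding", "spacer",
             cbind(.mod(reach, n), gap), "+", FALSE)
      } else if (gap < 0L) {
        overlap_bp <- overlap_bp + min(-gap, ord$span[i])
      }
      if (ord$rstart[i] + ord$span[i] > reach) {
        reach <- ord$rstart[i] + ord$span[i]
        reach_name <- ord$name[i]
      }
    }
    # wrap-around spacer from the last extent back to the first
    gap <- (ord$rstart[1] + n) - reach
    if (gap > 0L && gap < n) {
      push(paste0(reach_name, "-", ord$name[1]), "noncoding", "spacer",
           cbind(.mod(reach, n), gap), "+", FALSE)
    }
  }

  empty <- data.frame(
    name = character(0), lclass = character(0), kind = character(0),
    region = character(0), start = integer(0), end = integer(0),
    wraps = logical(0), length = integer(0), pseudo = logical(0),
    seq = character(0), stringsAsFactors = FALSE
  )
  if (!length(cand)) {
    return(structure(empty, accounting = list(
      scope_bp = n - structure$irb$span, assigned_bp = 0L,
      residual_bp = n - structure$irb$span, overlap_bp = 0L,
      n_dropped_irb = 0L, n_dropped_short = 0L
    )))
  }

  # region by extent midpoint in the rotated frame
  l1 <- unname(structure$lengths["lsc"])
  l2 <- unname(structure$lengths["irb"])
  l3 <- unname(structure$lengths["ssc"])
  region_of <- function(mid) {
    if (mid < l1) "LSC" else if (mid < l1 + l2) "IRb"
    else if (mid < l1 + l2 + l3) "SSC" else "IRa"
  }
  for (i in seq_along(cand)) {
    cand[[i]]$region <- region_of(.mod(cand[[i]]$rstart + cand[[i]]$extent %/% 2L, n))
  }

  in_irb <- vapply(cand, function(x) x$region == "IRb", logical(1))
  short <- vapply(cand, function(x) x$span <= min_len, logical(1))
  keep <- !in_irb & !short

  # base accounting over the rotated circle (IRb bases out of scope)
  cls <- integer(n)
  for (i in which(keep)) {
    code <- if (cand[[i]]$lclass == "coding") 1L else 2L
    pts <- cand[[i]]$parts
    for (r in seq_len(nrow(pts))) {
      pos <- .mod(pts[r, 1L] + 0:(pts[r, 2L] - 1L), n) + 1L
      pos <- pos[!(pos - 1L >= irb_lo & pos - 1L < irb_hi)]
      cls[pos] <- pmax(cls[pos], code)
    }
  }

  kept <- cand[keep]
  nms <- vapply(kept, `[[`, "", "name")
  if (anyDuplicated(nms)) nms <- make.unique(nms, sep = " copy ")

  rows <- lapply(seq_along(kept), function(i) {
    x <- kept[[i]]
    astart <- .mod(x$rstart + off, n)
    sq <- paste(vapply(seq_len(nrow(x$parts)), function(r) {
      circ_substr(genome$seq, .mod(x$parts[r, 1L] + off, n), x$parts[r, 2L], n)
    }, character(1)), collapse = "")
    if (x$lclass == "coding" && x$strand == "-") sq <- revcomp(sq)
    aend <- astart + x$extent
    data.frame(
      name = nms[i], lclass = x$lclass, kind = x$kind, region = x$region,
      start = astart, end = if (aend > n) aend - n else aend, wraps = aend > n,
      length = x$span, pseudo = x$pseudo, seq = sq, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$name), , drop = FALSE]
  rownames(out) <- NULL

  scope <- n - structure$irb$span
  assigned <- sum(cls > 0L)
  attr(out, "accounting") <- list(
    scope_bp = scope,
    assigned_bp = assigned,
    residual_bp = scope - assigned,
    overlap_bp = overlap_bp,
    n_dropped_irb = sum(in_irb),
    n_dropped_short = sum(short & !in_irb)
  )
  out
}

#' Group homologous loci across taxa
#'
#' Loci are homologous when they share a name (annotation-based homology, no
#' similarity search). Groups present in fewer than `min_taxa` genomes are
#' excluded (logged via message); a group whose length range exceeds a 10x
#' ratio triggers a warning but is kept.
#'
#' @param loci_by_taxon named list of [extract_loci()] outputs, one per taxon
#' @param min_taxa minimum number of taxa a locus must be present in
#'   (default: all taxa)
#' @return list of `locus_set` objects: `name`, `lclass`, `region`, `seqs`
#'   (named by taxon), `length_range = c(min, max)`
#' @export
collect_homologs <- function(loci_by_taxon, min_taxa = length(loci_by_taxon)) {
  stopifnot(length(loci_by_taxon) >= 1L, !is.null(names(loci_by_taxon)))
  taxa <- names(loci_by_taxon)
  all_names <- unique(unlist(lapply(loci_by_taxon, `[[`, "name")))
  out <- list()
  n_excluded <- 0L
  for (nm in all_names) {
    seqs <- character(0)
    lclass <- region <- NULL
    for (tx in taxa) {
      df <- loci_by_taxon[[tx]]
      hit <- which(df$name == nm)
      if (length(hit)) {
        seqs[tx] <- df$seq[hit[1]]
        if (is.null(lclass)) {
          lclass <- df$lclass[hit[1]]
          region <- df$region[hit[1]]
        }
      }
    }
    if (length(seqs) < min_taxa) {
      n_excluded <- n_excluded + 1L
      next
    }
    lens <- nchar(seqs)
    if (max(lens) > 10L * min(lens)) {
      warning("locus '", nm, "' has a >10x length ratio across taxa (",
              min(lens), "-", max(lens), " bp); kept")
    }
    out[[nm]] <- structure(
      list(name = nm, lclass = lclass, region = region, seqs = seqs,
           length_range = c(min(lens), max(lens))),
      class = "locus_set"
    )
  }
  if (n_excluded > 0L) {
    message(n_excluded, " locus/loci present in < ", min_taxa, " taxa excluded")
  }
  out
}
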
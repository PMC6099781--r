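# Reading/writing plastome sequences and annotations, plus the coordinate
# conventions used throughout: internal coordinates are 0-based half-open,
# file formats (FASTA headers aside) are 1-based inclusive (GFF3/GenBank
# style). Circular features are represented with wraps = TRUE rather than
# split parts.

.ALPHABET <- c("A", "C", "G", "T", "N")

# uppercase, U -> T, any other IUPAC/foreign character -> N (count reported)
normalize_seq <- function(s) {
  up <- chartr("u", "t", toupper(s))
  up <- chartr("U", "T", up)
  bad <- nchar(gsub("[ACGTN]", "", up))
  if (bad > 0) up <- gsub("[^ACGTN]", "N", up)
  list(seq = up, n_replaced = bad)
}

#' Construct a circular genome object
#'
#' @param id sequence identifier
#' @param seq nucleotide string; normalized to uppercase A,C,G,T,N (U mapped
#'   to T, other ambiguity codes to N with a message)
#' @param circular logical; plastomes are circular
#' @return an object of class `circular_genome` with fields `id`, `seq`,
#'   `circular`, `length`
#' @export
circular_genome <- function(id, seq, circular = TRUE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  norm <- normalize_seq(seq)
  if (norm$n_replaced > 0) {
    message(sprintf("[%s] %d non-ACGTN character(s) normalized to N", id, norm$n_replaced))
  }
  if (nchar(norm$seq) == 0L) stop("empty sequence for '", id, "'")
  structure(
    list(id = id, seq = norm$seq, circular = isTRUE(circular), length = nchar(norm$seq)),
    class = "circular_genome"
  )
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf(
    "<circular_genome> %s: %s bp%s\n", x$id,
    format(x$length, big.mark = ","), if (x$circular) " (circular)" else ""
  ))
  invisible(x)
}

#' Read plastome sequences from FASTA
#'
#' Sequences are normalized (uppercase, U to T, non-ACGTN characters to N with
#' a message). Empty files and duplicate record ids are hard errors.
#'
#' @param path FASTA file (may hold multiple records)
#' @param circular mark genomes as circular (default TRUE)
#' @return list of [circular_genome()] objects, named by id
#' @export
read_fasta <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- lapply(seq_along(set), function(i) {
    circular_genome(ids[i], as.character(set[[i]]), circular = circular)
  })
  names(out) <- ids
  out
}

#' Write genomes to FASTA
#'
#' @param genomes list of [circular_genome()] objects (or a single one)
#' @param path output file
#' @param width line width
#' @return `path`, invisibly
#' @export
write_fasta <- function(genomes, path, width = 70L) {
  if (inherits(genomes, "circular_genome")) genomes <- list(genomes)
  set <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "seq"))
  names(set) <- vapply(genomes, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

.FEATURE_KINDS <- c("CDS", "tRNA", "rRNA", "intron", "spacer")

# internal representation of annotations: one data.frame row per exon/part,
# 0-based half-open coordinates, `id` unique per gene instance (IR-duplicated
# genes share `name` but not `id`)
.feature_row <- function(id, name, kind, strand, pseudo, part, start, end, wraps) {
  data.frame(
    id = id, name = name, kind = kind, strand = strand, pseudo = pseudo,
    part = part, start = start, end = end, wraps = wraps,
    stringsAsFactors = FALSE
  )
}

# convert 1-based inclusive file coordinates to internal intervals, handling
# features that run past the end of a circular genome
.part_from_1based <- function(start1, end1, genome_length, circular, what) {
  if (is.null(genome_length)) {
    return(list(start = start1 - 1L, end = end1, wraps = FALSE))
  }
  n <- genome_length
  if (start1 < 1L || start1 > n) stop("feature start out of range for ", what)
  if (end1 > n || end1 < start1) {
    if (!circular) stop("feature '", what, "' extends beyond a non-circular genome")
    end0 <- if (end1 > n) end1 - n else end1
    return(list(start = start1 - 1L, end = end0, wraps = TRUE))
  }
  list(start = start1 - 1L, end = end1, wraps = FALSE)
}

#' Read gene annotations
#'
#' Supports GFF3 (coordinates 1-based inclusive, grouped into multi-exon genes
#' by the `ID` attribute) and a simple feature-table TSV dialect with columns
#' `name`, `kind`, `strand`, `parts` (comma-separated 1-based `start-end`
#' ranges) and optional `pseudo`. Internally coordinates become 0-based
#' half-open; a feature running past the end of a circular genome gets
#' `wraps = TRUE`.
#'
#' @param path annotation file
#' @param format `"gff3"` or `"feature_table"`
#' @param genome optional [circular_genome()] used to validate coordinates and
#'   resolve origin-crossing features
#' @return data.frame with one row per part: `id`, `name`, `kind`, `strand`,
#'   `pseudo`, `part`, `start`, `end`, `wraps`
#' @export
read_annotations <- function(path, format = c("gff3", "feature_table"), genome = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  n <- if (is.null(genome)) NULL else genome$length
  circ <- if (is.null(genome)) TRUE else genome$circular

  if (format == "gff3") {
    g <- as.data.frame(rtracklayer::readGFF(path))
    keep <- g$type %in% .FEATURE_KINDS
    dropped <- unique(as.character(g$type[!keep]))
    if (length(dropped)) {
      message("skipping unsupported feature type(s): ", paste(dropped, collapse = ", "))
    }
    g <- g[keep, , drop = FALSE]
    if (nrow(g) == 0L) return(.feature_row(character(0), character(0), character(0),
                                           character(0), logical(0), integer(0),
                                           integer(0), integer(0), logical(0)))
    ids <- if ("ID" %in% names(g) && !all(is.na(g$ID))) as.character(g$ID) else NULL
    if (is.null(ids)) ids <- if ("Name" %in% names(g)) as.character(g$Name) else as.character(seq_len(nrow(g)))
    ids[is.na(ids) | !nzchar(ids)] <- paste0("feat", which(is.na(ids) | !nzchar(ids)))
    nms <- if ("gene" %in% names(g)) as.character(g$gene) else ids
    nms[is.na(nms)] <- ids[is.na(nms)]
    pseudo <- if ("pseudo" %in% names(g)) !is.na(g$pseudo) & g$pseudo %in% c("true", "TRUE", TRUE) else rep(FALSE, nrow(g))
    rows <- lapply(seq_len(nrow(g)), function(i) {
      p <- .part_from_1based(as.integer(g$start[i]), as.integer(g$end[i]), n, circ, ids[i])
      .feature_row(ids[i], nms[i], as.character(g$type[i]),
                   as.character(g$strand[i]), pseudo[i], 0L,
                   p$start, p$end, p$wraps)
    })
    out <- do.call(rbind, rows)
    # order parts within each gene instance as they appear in the file
    out$part <- stats::ave(seq_len(nrow(out)), out$id, FUN = seq_along)
  } else {
    tb <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    req <- c("name", "kind", "strand", "parts")
    if (!all(req %in% names(tb))) stop("feature table needs columns: ", paste(req, collapse = ", "))
    if (!"pseudo" %in% names(tb)) tb$pseudo <- FALSE
    if (!"id" %in% names(tb)) tb$id <- make.unique(tb$name, sep = "_")
    rows <- lapply(seq_len(nrow(tb)), function(i) {
      ranges <- strsplit(tb$parts[i], ",", fixed = TRUE)[[1]]
      parts <- lapply(seq_along(ranges), function(j) {
        se <- as.integer(strsplit(trimws(ranges[j]), "-", fixed = TRUE)[[1]])
        if (length(se) != 2L || anyNA(se)) stop("bad part range '", ranges[j], "' for ", tb$name[i])
        p <- .part_from_1based(se[1], se[2], n, circ, tb$name[i])
        .feature_row(tb$id[i], tb$name[i], tb$kind[i], tb$strand[i],
                     isTRUE(as.logical(tb$pseudo[i])), j, p$start, p$end, p$wraps)
      })
      do.call(rbind, parts)
    })
    out <- do.call(rbind, rows)
  }
  if (!all(out$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!all(out$kind %in% .FEATURE_KINDS)) {
    stop("unsupported feature kind(s): ",
         paste(setdiff(unique(out$kind), .FEATURE_KINDS), collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

#' Write gene annotations
#'
#' Inverse of [read_annotations()]: emits 1-based inclusive coordinates.
#' Origin-crossing parts are written with `end` beyond the genome length
#' (GenBank convention for circular molecules).
#'
#' @param features feature data.frame as returned by [read_annotations()]
#' @param path output file
#' @param format `"gff3"` or `"feature_table"`
#' @param genome the annotated [circular_genome()] (supplies id and length)
#' @return `path`, invisibly
#' @export
write_annotations <- function(features, path, format = c("gff3", "feature_table"), genome) {
  format <- match.arg(format)
  n <- genome$length
  start1 <- features$start + 1L
  end1 <- ifelse(features$wraps, features$end + n, features$end)
  if (format == "gff3") {
    attrs <- sprintf("ID=%s;gene=%s%s", features$id, features$name,
                     ifelse(features$pseudo, ";pseudo=true", ""))
    lines <- sprintf("%s\tplastocompare\t%s\t%d\t%d\t.\t%s\t.\t%s",
                     genome$id, features$kind, start1, end1, features$strand, attrs)
    writeLines(c("##gff-version 3",
                 sprintf("##sequence-region %s 1 %d", genome$id, n), lines), path)
  } else {
    ord <- features[order(features$id, features$part), , drop = FALSE]
    s1 <- ord$start + 1L
    e1 <- ifelse(ord$wraps, ord$end + n, ord$end)
    parts <- vapply(split(sprintf("%d-%d", s1, e1), ord$id)[unique(ord$id)],
                    paste, character(1), collapse = ",")
    first <- ord[!duplicated(ord$id), , drop = FALSE]
    tb <- data.frame(
      id = first$id, name = first$name, kind = first$kind, strand = first$strand,
      pseudo = first$pseudo, parts = parts[first$id], stringsAsFactors = FALSE
    )
    utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
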
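# End-to-end comparison of two or more annotated plastomes, writing the
# standard artifact bundle: genome summary, repeat/SSR censuses, junction
# comparison, per-locus variability table, ranked markers and a sliding
# percent-identity profile, plus a JSON manifest with checksums. Output is
# deterministic under a fixed config; all TSV coordinates are 1-based
# inclusive.

#' GC content of a genome
#'
#' Computed as (G+C)/(A+C+G+T) over the full sequence; N bases are excluded
#' from both numerator and denominator.
#'
#' @param genome a [circular_genome()] (or plain sequence string)
#' @return fraction in `[0, 1]`
#' @export
gc_content <- function(genome) {
  s <- if (inherits(genome, "circular_genome")) genome$seq else genome
  counts <- table(factor(.chars(s), levels = c("A", "C", "G", "T")))
  sum(counts[c("G", "C")]) / sum(counts)
}

#' Assemble a run configuration
#'
#' @param min_ir_len minimum IR length for [detect_ir()]
#' @param min_repeat_len minimum dispersed-repeat length
#' @param ssr_min_copies per-unit SSR minimum copies (length 6)
#' @param locus_min_len strict lower bound on locus length
#' @param min_taxa minimum taxa per homologous locus group (NULL: all)
#' @param top_n number of markers to rank
#' @param window,step sliding-identity window parameters (alignment columns)
#' @param dedupe_ir count IR-internal SSRs once
#' @return a `run_config` list
#' @export
run_config <- function(min_ir_len = 1000L, min_repeat_len = 8L,
                       ssr_min_copies = c(10L, 6L, 5L, 5L, 5L, 5L),
                       locus_min_len = 100L, min_taxa = NULL, top_n = 20L,
                       window = 100L, step = 25L, dedupe_ir = FALSE) {
  stopifnot(min_ir_len > 0L, min_repeat_len >= 2L, all(ssr_min_copies > 0L),
            locus_min_len > 0L, top_n > 0L, window >= 10L, window >= step)
  structure(
    list(min_ir_len = as.integer(min_ir_len),
         min_repeat_len = as.integer(min_repeat_len),
         ssr_min_copies = as.integer(ssr_min_copies),
         locus_min_len = as.integer(locus_min_len),
         min_taxa = min_taxa, top_n = as.integer(top_n),
         window = as.integer(window), step = as.integer(step),
         dedupe_ir = isTRUE(dedupe_ir)),
    class = "run_config"
  )
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full plastome comparison pipeline
#'
#' Detects the quadripartite structure of every genome, censuses repeats and
#' SSRs, compares IR junctions, extracts and aligns homologous loci, computes
#' the variability table and ranked markers, and profiles sliding percent
#' identity against the first genome over the concatenated locus alignments.
#' With a single genome the per-genome artifacts are still produced and the
#' cross-taxon tables are empty. Any stage failure aborts with a stage-tagged
#' error and removes partial outputs.
#'
#' @param bundles named list; each element a list with `genome` (a
#'   [circular_genome()]) and `features` (annotation data.frame)
#' @param out_dir output directory (created)
#' @param config a [run_config()]
#' @return invisibly, the manifest list; artifacts are written to `out_dir`
#' @export
run_compare <- function(bundles, out_dir, config = run_config()) {
  stopifnot(length(bundles) >= 1L, !is.null(names(bundles)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  stage <- "setup"
  on_fail <- function(e) {
    unlink(file.path(out_dir, basename(written)))
    stop("run_compare failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    ids <- names(bundles)

    stage <- "structure"
    structures <- lapply(bundles, function(b) {
      detect_ir(b$genome, min_ir_len = config$min_ir_len)
    })

    stage <- "genome_summary"
    gs <- do.call(rbind, lapply(ids, function(g) {
      b <- bundles[[g]]; st <- structures[[g]]
      fe <- b$features
      n_genes <- length(unique(fe$id))
      n_unique <- length(unique(fe$name))
      cds_bp <- sum(ifelse(fe$wraps, (b$genome$length - fe$start) + fe$end,
                           fe$end - fe$start)[fe$kind == "CDS"])
      all_bp <- sum(ifelse(fe$wraps, (b$genome$length - fe$start) + fe$end,
                           fe$end - fe$start))
      data.frame(
        genome = g, size_bp = b$genome$length,
        lsc_bp = unname(st$lengths["lsc"]), ssc_bp = unname(st$lengths["ssc"]),
        ir_bp = st$ir_len,
        gc_pct = round_half_up(100 * gc_content(b$genome), 1),
        n_genes = n_genes, n_genes_unique = n_unique,
        coding_pct_cds = round_half_up(100 * cds_bp / b$genome$length, 1),
        coding_pct_all = round_half_up(100 * all_bp / b$genome$length, 1),
        stringsAsFactors = FALSE
      )
    }))
    written <- c(written, .write_tsv(gs, file.path(out_dir, "genome_summary.tsv")))

    stage <- "repeats"
    reps <- do.call(rbind, lapply(ids, function(g) {
      df <- find_repeats(bundles[[g]]$genome, config$min_repeat_len,
                         structure = structures[[g]])
      if (nrow(df)) {
        cbind(genome = g,
              data.frame(rtype = df$rtype,
                         start1 = df$start1 + 1L, end1 = df$end1,
                         start2 = df$start2 + 1L, end2 = df$end2,
                         length = df$length, ir_pair = df$ir_pair,
                         stringsAsFactors = FALSE))
      }
    }))
    if (is.null(reps)) {
      reps <- data.frame(genome = character(0), rtype = character(0),
                         start1 = integer(0), end1 = integer(0),
                         start2 = integer(0), end2 = integer(0),
                         length = integer(0), ir_pair = logical(0))
    }
    written <- c(written, .write_tsv(reps, file.path(out_dir, "repeats.tsv")))

    stage <- "ssrs"
    ssrs <- do.call(rbind, lapply(ids, function(g) {
      df <- find_ssrs(bundles[[g]]$genome, config$ssr_min_copies,
                      structure = structures[[g]], dedupe_ir = config$dedupe_ir)
      if (nrow(df)) {
        cbind(genome = g,
              data.frame(motif = df$motif, unit = df$unit, copies = df$copies,
                         start = df$start + 1L, end = df$end, length = df$length,
                         stringsAsFactors = FALSE))
      }
    }))
    if (is.null(ssrs)) {
      ssrs <- data.frame(genome = character(0), motif = character(0),
                         unit = integer(0), copies = integer(0),
                         start = integer(0), end = integer(0), length = integer(0))
    }
    written <- c(written, .write_tsv(ssrs, file.path(out_dir, "ssrs.tsv")))

    stage <- "junctions"
    if (length(bundles) >= 2L) {
      cj <- compare_junctions(Map(function(st, b) list(structure = st, features = b$features),
                                  structures, bundles))
      jt <- cj$junctions
    } else {
      jt <- cbind(genome = ids[1],
                  junction_report(structures[[1]], bundles[[1]]$features))
    }
    written <- c(written, .write_tsv(jt, file.path(out_dir, "junctions.tsv")))

    stage <- "loci"
    loci_by_taxon <- stats::setNames(lapply(ids, function(g) {
      suppressMessages(extract_loci(bundles[[g]]$genome, bundles[[g]]$features,
                                    structures[[g]], min_len = config$locus_min_len))
    }), ids)
    message(sprintf("loci extracted: %s",
                    paste(sprintf("%s=%d", ids, vapply(loci_by_taxon, nrow, 0L)),
                          collapse = ", ")))

    empty_var <- data.frame(name = character(0), lclass = character(0),
                            region = character(0), length_min = integer(0),
                            length_max = integer(0), L = integer(0),
                            NS = integer(0), pct_vc = numeric(0),
                            n_pic = integer(0), pct_pic = numeric(0))
    if (length(bundles) >= 2L) {
      stage <- "variability"
      homologs <- suppressMessages(
        collect_homologs(loci_by_taxon,
                         min_taxa = config$min_taxa %||% length(bundles))
      )
      alns <- lapply(homologs, align_locus)
      vt <- if (length(alns)) variability_table(alns) else
        list(records = empty_var, class_summary = NULL, ratio = NA_real_)
      written <- c(written, .write_tsv(vt$records, file.path(out_dir, "variability.tsv")))
      if (!is.null(vt$class_summary)) {
        written <- c(written, .write_tsv(vt$class_summary,
                                         file.path(out_dir, "class_summary.tsv")))
      }

      stage <- "markers"
      mk <- if (nrow(vt$records)) {
        suppressWarnings(select_markers(vt$records, top_n = config$top_n))
      } else empty_var
      written <- c(written, .write_tsv(mk, file.path(out_dir, "markers.tsv")))

      stage <- "identity_profile"
      prof <- if (length(alns)) {
        ord <- order(vapply(homologs, function(h) {
          d <- loci_by_taxon[[ids[1]]]
          i <- match(h$name, d$name)
          if (is.na(i)) .Machine$integer.max else d$start[i]
        }, 0))
        cat_rows <- stats::setNames(rep("", length(ids)), ids)
        for (i in ord) cat_rows <- paste0(cat_rows, alns[[i]]$rows[ids])
        names(cat_rows) <- ids
        sliding_identity(cat_rows, reference = ids[1],
                         window = config$window, step = config$step)
      } else {
        data.frame(taxon = character(0), window_start = integer(0),
                   window_end = integer(0), identity = numeric(0))
      }
      written <- c(written, .write_tsv(prof, file.path(out_dir, "identity_profile.tsv")))
    } else {
      written <- c(written, .write_tsv(empty_var, file.path(out_dir, "variability.tsv")))
      written <- c(written, .write_tsv(empty_var, file.path(out_dir, "markers.tsv")))
      written <- c(written, .write_tsv(
        data.frame(taxon = character(0), window_start = integer(0),
                   window_end = integer(0), identity = numeric(0)),
        file.path(out_dir, "identity_profile.tsv")
      ))
    }

    stage <- "manifest"
    cfg <- unclass(config)
    cfg$min_taxa <- cfg$min_taxa %||% length(bundles)
    files <- sort(basename(written))
    manifest <- list(
      tool = "plastocompare",
      version = as.character(utils::packageVersion("plastocompare")),
      genomes = ids,
      config = cfg,
      config_hash = substr(.digest_obj(cfg), 1, 16),
      files = lapply(stats::setNames(files, files), function(f) {
        list(md5 = unname(tools::md5sum(file.path(out_dir, f))))
      })
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
  }, error = on_fail)
}

# stable hash of an R object via its serialized representation
.digest_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
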
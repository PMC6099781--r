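mk_feat <- function(id, start, end, kind = "CDS", strand = "+", part = 1L,
                    pseudo = FALSE) {
  data.frame(id = id, name = sub("#.*", "", id), kind = kind, strand = strand,
             pseudo = pseudo, part = part, start = start, end = end,
             wraps = FALSE, stringsAsFactors = FALSE)
}

toy_bundle <- function(seed = 1) {
  withr::with_seed(seed, g <- circular_genome("toy", rand_seq(2000)))
  st <- plastocompare:::.structure_from_parts(2000L, irb_start = 1200L,
                                              ir_len = 300L, ssc_len = 200L)
  list(g = g, st = st)
}

test_that("spacers between genes are extracted with flanking-gene names", {
  b <- toy_bundle()
  fe <- rbind(mk_feat("A", 100L, 400L), mk_feat("B", 600L, 900L))
  loci <- suppressMessages(extract_loci(b$g, fe, b$st))
  sp <- loci[loci$name == "A-B", ]
  expect_equal(nrow(sp), 1L)
  expect_equal(c(sp$start, sp$end, sp$length), c(400L, 600L, 200L))
  expect_equal(sp$lclass, "noncoding")
  expect_equal(sp$seq, substr(b$g$seq, 401, 600))
})

test_that("the locus length threshold is strict", {
  b <- toy_bundle()
  fe <- rbind(mk_feat("A", 100L, 400L), mk_feat("B", 500L, 800L))
  loci <- suppressMessages(extract_loci(b$g, fe, b$st, min_len = 100L))
  expect_false("A-B" %in% loci$name) # spacer of exactly 100 bp is discarded
  fe2 <- rbind(mk_feat("A", 100L, 400L), mk_feat("B", 501L, 800L))
  loci2 <- suppressMessages(extract_loci(b$g, fe2, b$st, min_len = 100L))
  expect_true("A-B" %in% loci2$name) # 101 bp is kept
})

test_that("a two-exon gene yields one joined coding locus plus an intron locus", {
  b <- toy_bundle()
  fe <- rbind(mk_feat("A", 100L, 300L, part = 1L),
              mk_feat("A", 600L, 800L, part = 2L),
              mk_feat("B", 900L, 1100L))
  loci <- suppressMessages(extract_loci(b$g, fe, b$st))
  cod <- loci[loci$name == "A", ]
  expect_equal(cod$length, 400L) # exons joined, intron excluded
  expect_equal(cod$seq, paste0(substr(b$g$seq, 101, 300), substr(b$g$seq, 601, 800)))
  intr <- loci[loci$name == "A intron", ]
  expect_equal(c(intr$start, intr$end, intr$length), c(300L, 600L, 300L))
  expect_equal(intr$lclass, "noncoding")
})

test_that("minus-strand coding loci are reverse complemented", {
  b <- toy_bundle()
  fe <- rbind(mk_feat("A", 100L, 400L, strand = "-"), mk_feat("B", 600L, 900L))
  loci <- suppressMessages(extract_loci(b$g, fe, b$st))
  expect_equal(loci$seq[loci$name == "A"], revcomp(substr(b$g$seq, 101, 400)))
})

test_that("extraction is invariant to feature row order and accounts for every base", {
  anc <- generate_ancestor(small_plan(seed = 19))
  st <- detect_ir(anc$genome, min_ir_len = 500)
  l1 <- suppressMessages(extract_loci(anc$genome, anc$features, st))
  withr::with_seed(2, fe2 <- anc$features[sample(nrow(anc$features)), ])
  l2 <- suppressMessages(extract_loci(anc$genome, fe2, st))
  expect_equal(l1, l2, ignore_attr = TRUE)
  acc <- attr(l1, "accounting")
  expect_equal(acc$scope_bp, anc$genome$length - st$lengths[["irb"]])
  expect_equal(acc$assigned_bp + acc$residual_bp, acc$scope_bp)
  expect_gt(acc$assigned_bp, 0)
})

test_that("overlapping genes suppress the spacer between them", {
  b <- toy_bundle()
  fe <- rbind(mk_feat("A", 100L, 500L), mk_feat("B", 450L, 800L),
              mk_feat("C", 950L, 1150L))
  loci <- suppressMessages(extract_loci(b$g, fe, b$st))
  expect_false("A-B" %in% loci$name)
  expect_true("B-C" %in% loci$name)
  expect_equal(attr(loci, "accounting")$overlap_bp, 50L)
})

test_that("collect_homologs groups by name and applies the taxon threshold", {
  mk <- function(names, seqs) {
    data.frame(name = names, lclass = "coding", region = "LSC",
               start = seq_along(names), end = seq_along(names) + 1L,
               wraps = FALSE, length = nchar(seqs), pseudo = FALSE, seq = seqs,
               stringsAsFactors = FALSE)
  }
  lb <- list(
    t1 = mk(c("x", "y"), c("ACGTACGT", "GGGCCC")),
    t2 = mk(c("x", "y"), c("ACGAACGT", "GGGCCA")),
    t3 = mk("x", "ACGTACGA")
  )
  expect_message(hom <- collect_homologs(lb), "excluded")
  expect_named(hom, "x")
  expect_equal(hom$x$length_range, c(8L, 8L))
  hom2 <- suppressMessages(collect_homologs(lb, min_taxa = 2))
  expect_setequal(names(hom2), c("x", "y"))
  expect_equal(hom2$y$length_range, c(6L, 6L))
  # empty input
  empty <- lb$t1[0, ]
  expect_length(suppressMessages(collect_homologs(list(t1 = empty), min_taxa = 1)), 0L)
})

test_that("extreme length discrepancies warn but are kept", {
  mk1 <- function(seq) {
    data.frame(name = "x", lclass = "coding", region = "LSC", start = 1L,
               end = 2L, wraps = FALSE, length = nchar(seq), pseudo = FALSE,
               seq = seq, stringsAsFactors = FALSE)
  }
  lb <- list(t1 = mk1(strrep("A", 10)), t2 = mk1(strrep("A", 200)))
  expect_warning(hom <- collect_homologs(lb), "10x")
  expect_equal(hom$x$length_range, c(10L, 200L))
})
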
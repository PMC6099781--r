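test_that("a planted duplicate is found as exactly one maximal forward hit", {
  g <- circular_genome("toy", "TTAGGCATTTTTTAGGCA")
  h <- find_repeats(g, min_repeat_len = 7, types = "forward")
  expect_equal(nrow(h), 1L)
  expect_equal(h$start1, 0L)
  expect_equal(h$start2, 11L)
  expect_equal(h$length, 7L)
})

test_that("a planted segment and its reverse complement give one palindromic hit", {
  withr::with_seed(13, {
    a <- strsplit(rand_seq(120), "")[[1]]
    seg <- strsplit(rand_seq(20), "")[[1]]
    a[11:30] <- seg
    a[71:90] <- strsplit(revcomp(paste(seg, collapse = "")), "")[[1]]
    # break flank extension on both sides of the relation
    if (a[10] == comp_seq(a[91])) a[10] <- setdiff(c("A", "C", "G", "T"), comp_seq(a[91]))[1]
    if (a[31] == comp_seq(a[70])) a[31] <- setdiff(c("A", "C", "G", "T"), comp_seq(a[70]))[1]
    g <- circular_genome("toy", paste(a, collapse = ""))
  })
  h <- find_repeats(g, min_repeat_len = 15, types = "palindromic")
  expect_equal(nrow(h), 1L)
  expect_equal(c(h$start1, h$start2, h$length), c(10L, 70L, 20L))
})

test_that("find_repeats matches the brute-force maximal-pair oracle on random sequences", {
  withr::with_seed(101, {
    for (i in 1:6) {
      g <- circular_genome(paste0("r", i), rand_seq(400))
      got <- find_repeats(g, min_repeat_len = 5)
      got <- got[order(got$rtype, got$start1, got$start2, got$length),
                 c("rtype", "start1", "end1", "start2", "end2", "length")]
      rownames(got) <- NULL
      expect_equal(got, oracle_repeats(g$seq, 5), ignore_attr = TRUE)
    }
    # with N masking
    s <- strsplit(rand_seq(400), "")[[1]]
    s[sample(400, 20)] <- "N"
    g <- circular_genome("n", paste(s, collapse = ""))
    got <- find_repeats(g, min_repeat_len = 5)
    got <- got[order(got$rtype, got$start1, got$start2, got$length),
               c("rtype", "start1", "end1", "start2", "end2", "length")]
    rownames(got) <- NULL
    expect_equal(got, oracle_repeats(g$seq, 5), ignore_attr = TRUE)
  })
})

test_that("raising min_repeat_len never adds hits", {
  withr::with_seed(55, g <- circular_genome("m", rand_seq(1500)))
  h8 <- find_repeats(g, 8)
  h10 <- find_repeats(g, 10)
  key <- function(d) paste(d$rtype, d$start1, d$start2, d$length)
  expect_true(all(key(h10) %in% key(h8)))
  expect_true(all(h10$length >= 10))
})

test_that("forward hits mirror under reverse complement and palindromic hits are invariant", {
  withr::with_seed(77, g <- circular_genome("s", rand_seq(1200)))
  n <- g$length
  rc <- circular_genome("rc", revcomp(g$seq))
  fwd <- find_repeats(g, 6, types = "forward")
  fwd_rc <- find_repeats(rc, 6, types = "forward")
  mirrored <- data.frame(start1 = n - fwd$end2, start2 = n - fwd$end1,
                         length = fwd$length)
  key <- function(d) sort(paste(d$start1, d$start2, d$length))
  expect_equal(key(fwd_rc[c("start1", "start2", "length")]), key(mirrored))
  pal <- find_repeats(g, 6, types = "palindromic")
  pal_rc <- find_repeats(rc, 6, types = "palindromic")
  pal_mirror <- data.frame(start1 = n - pal$end2, start2 = n - pal$end1,
                           length = pal$length)
  expect_equal(key(pal_rc[c("start1", "start2", "length")]), key(pal_mirror))
})

test_that("SSR thresholds follow the per-unit minimum copy numbers", {
  pad <- function(x) paste0("GCGTCGTAGCTAGCTGACTG", x, "CAGTCAGCTACGTACGATCG")
  # A x 10 meets the mononucleotide threshold
  h <- find_ssrs(circular_genome("a10", pad(strrep("A", 10))))
  expect_equal(nrow(h), 1L)
  expect_equal(h$motif, "A")
  expect_equal(h$copies, 10L)
  # A x 9 does not
  expect_equal(nrow(find_ssrs(circular_genome("a9", pad(strrep("A", 9))))), 0L)
  # AT x 6 is a dinucleotide hit and is not also reported as ATAT x 3
  h <- find_ssrs(circular_genome("at6", pad(strrep("AT", 6))))
  expect_equal(nrow(h), 1L)
  expect_equal(h$unit, 2L)
  expect_equal(h$copies, 6L)
})

test_that("find_ssrs matches the naive-scan oracle on random sequences", {
  lo <- c(3L, 2L, 2L, 2L, 2L, 2L) # permissive thresholds so hits are plentiful
  withr::with_seed(202, {
    for (i in 1:6) {
      g <- circular_genome(paste0("r", i), rand_seq(1000, c("A", "C", "T")))
      got <- find_ssrs(g, min_copies = lo)
      expect_equal(got[c("motif", "unit", "copies", "start", "end", "length")],
                   oracle_ssrs(g$seq, lo), ignore_attr = TRUE)
    }
    s <- strsplit(rand_seq(800, c("A", "T")), "")[[1]]
    s[sample(800, 30)] <- "N"
    g <- circular_genome("n", paste(s, collapse = ""))
    got <- find_ssrs(g, min_copies = lo)
    expect_equal(got[c("motif", "unit", "copies", "start", "end", "length")],
                 oracle_ssrs(g$seq, lo), ignore_attr = TRUE)
  })
})

test_that("raising SSR minimum copies never adds hits", {
  withr::with_seed(33, g <- circular_genome("m", rand_seq(3000, c("A", "T", "C"))))
  lo <- find_ssrs(g, min_copies = c(4L, 3L, 2L, 2L, 2L, 2L))
  hi <- find_ssrs(g, min_copies = c(6L, 4L, 3L, 3L, 3L, 3L))
  key <- function(d) paste(d$unit, d$start, d$length)
  expect_true(all(key(hi) %in% key(lo)))
})

test_that("repeat_summary tallies by type and unit size", {
  empty <- repeat_summary(NULL, NULL)
  expect_equal(sum(empty$repeat_counts), 0L)
  expect_equal(sum(empty$ssr_counts), 0L)

  reps <- data.frame(rtype = c("forward", "forward", "forward", "palindromic"))
  s <- repeat_summary(reps, NULL)
  expect_equal(unname(s$repeat_counts["forward"]), 3L)
  expect_equal(unname(s$repeat_counts["palindromic"]), 1L)
  expect_equal(s$n_repeats, 4L)
})

test_that("the planted SSR census of a synthetic genome matches its plan", {
  anc <- generate_ancestor(small_plan(seed = 12))
  got <- find_ssrs(anc$genome)
  want <- anc$truth$ssrs
  ord <- function(d) {
    d <- d[order(d$start), c("motif", "unit", "copies", "start", "length")]
    rownames(d) <- NULL
    d
  }
  expect_equal(ord(got), ord(want), ignore_attr = TRUE)
  s <- repeat_summary(ssrs = got)
  expect_equal(unname(s$ssr_counts[c("1", "2")]), c(14L, 1L))
  expect_equal(s$n_ssrs, 15L)
})

test_that("planted dispersed repeats are recovered exactly in an SSR-free plan", {
  plan <- small_plan(seed = 8, ssr_models = data.frame())
  anc <- generate_ancestor(plan)
  st <- detect_ir(anc$genome, min_ir_len = 500)
  got <- find_repeats(anc$genome, plan$screen_len, structure = st)
  expect_equal(sum(got$ir_pair), 1L)
  got <- got[!got$ir_pair, c("rtype", "start1", "start2", "length")]
  ord <- function(d) {
    d <- d[order(d$rtype, d$start1), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(ord(got), ord(anc$truth$repeats[, c("rtype", "start1", "start2", "length")]),
               ignore_attr = TRUE)
  s <- repeat_summary(got)
  expect_equal(unname(s$repeat_counts),
               c(forward = 3L, palindromic = 1L, reverse = 1L, complement = 1L),
               ignore_attr = TRUE)
})

test_that("min_repeat_len below 2 is rejected", {
  g <- circular_genome("x", "ACGTACGT")
  expect_error(find_repeats(g, 1), "min_repeat_len")
})
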
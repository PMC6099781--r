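test_that("identical sequences align without gaps", {
  seqs <- c(a = "ACGTACGTAA", b = "ACGTACGTAA", c = "ACGTACGTAA")
  al <- align_locus(seqs)
  expect_equal(al$L, 10L)
  expect_false(any(grepl("-", al$rows, fixed = TRUE)))
})

test_that("a single-base deletion produces one gap column", {
  al <- align_locus(c(a = "ACGT", b = "AGT"))
  expect_equal(al$L, 4L)
  expect_equal(sum(strsplit(al$rows[["b"]], "")[[1]] == "-"), 1L)
  expect_equal(gsub("-", "", al$rows[["b"]]), "AGT")
})

test_that("center-star merging reproduces every input after degapping", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      base <- rand_seq(60)
      seqs <- vapply(1:5, function(i) {
        ch <- strsplit(base, "")[[1]]
        drop <- sample(60, sample(0:3, 1))
        if (length(drop)) ch <- ch[-drop]
        mut <- sample(length(ch), 3)
        ch[mut] <- sample(c("A", "C", "G", "T"), 3, replace = TRUE)
        paste(ch, collapse = "")
      }, character(1))
      names(seqs) <- paste0("t", 1:5)
      al <- align_locus(seqs)
      expect_equal(gsub("-", "", al$rows), seqs)
      expect_true(all(nchar(al$rows) == al$L))
    }
  })
})

test_that("prealigned input is validated", {
  expect_error(align_locus(c(a = "AC-GT", b = "ACGT"), prealigned = TRUE),
               "unequal")
  al <- align_locus(c(a = "AC-GT", b = "ACCGT"), prealigned = TRUE)
  expect_equal(al$L, 5L)
  expect_error(align_locus(c(a = "", b = "ACGT")), "empty")
})

test_that("variable and parsimony-informative columns follow their definitions", {
  # gaps and N carry no state
  rows <- c(t1 = "AAAA", t2 = "A-CA", t3 = "AACN")
  # col1 {A,A,A} invariant; col2 {A,-,A} not variable; col3 {A,C,C} variable;
  # col4 {A,A,N} not variable
  expect_equal(count_vc(rows), 1L)
  # informative needs two states twice: {A,C,C} has A once
  expect_equal(count_pic(rows), 0L)
  rows2 <- c(t1 = "AC", t2 = "AC", t3 = "CA", t4 = "CA")
  expect_equal(count_vc(rows2), 2L)
  expect_equal(count_pic(rows2), 2L)
  rows3 <- c(t1 = "A", t2 = "A", t3 = "A", t4 = "C")
  expect_equal(count_vc(rows3), 1L)
  expect_equal(count_pic(rows3), 0L)
})

test_that("count_vc and count_pic match per-column brute force on random alignments", {
  withr::with_seed(404, {
    for (i in 1:40) {
      rows <- rand_alignment(k = sample(3:8, 1), L = sample(20:60, 1))
      expect_equal(count_vc(rows), oracle_vc(rows))
      expect_equal(count_pic(rows), oracle_pic(rows))
      expect_lte(count_pic(rows), count_vc(rows))
    }
  })
})

test_that("variability records satisfy the percentage arithmetic invariant", {
  anc <- generate_ancestor(small_plan(seed = 23, taxa = 5))
  ev <- evolve_taxa(anc)
  lb <- lapply(ev$taxa, function(b) {
    suppressMessages(extract_loci(b$genome, b$features, detect_ir(b$genome, 500)))
  })
  alns <- lapply(suppressMessages(collect_homologs(lb)), align_locus)
  vt <- variability_table(alns)
  rec <- vt$records
  expect_true(all(rec$n_pic <= rec$NS))
  expect_true(all(rec$NS <= rec$L))
  expect_equal(rec$pct_vc, round_half_up(100 * rec$NS / rec$L, 2))
  expect_equal(rec$pct_pic, round_half_up(100 * rec$n_pic / rec$L, 2))
  expect_true(all(c("coding", "noncoding") %in% vt$class_summary$lclass))
})

test_that("rounding is half-up at printed precision", {
  expect_equal(round_half_up(100 * 276 / 1177, 2), 23.45)
  expect_equal(round_half_up(100 * 139 / 1177, 2), 11.81)
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(class_rate_ratio(12.33, 6.50), 1.9)
})

test_that("marker selection ranks by variability with deterministic tie-breaks", {
  rec <- data.frame(
    name = c("d", "b", "a", "c", "e"),
    lclass = c("noncoding", "noncoding", "noncoding", "noncoding", "coding"),
    pct_vc = c(10, 12, 12, 8, 50),
    pct_pic = c(3, 5, 5, 2, 20),
    stringsAsFactors = FALSE
  )
  top <- select_markers(rec, top_n = 3)
  expect_equal(top$name, c("a", "b", "d")) # ties by name, coding excluded
  # permutation stable
  withr::with_seed(5, top2 <- select_markers(rec[sample(5), ], top_n = 3))
  expect_equal(top2$name, top$name)
  # threshold mode is strict: pct_vc == 12 does not pass min_pct_vc = 12
  expect_equal(nrow(select_markers(rec, min_pct_vc = 12)), 0L)
  expect_equal(select_markers(rec, min_pct_vc = 9.9)$name, c("a", "b", "d"))
  expect_warning(select_markers(rec, top_n = 10), "exceeds")
})

test_that("sliding identity windows report percent matches over comparable bases", {
  rows <- c(ref = strrep("A", 120), alt = strrep("A", 120))
  prof <- sliding_identity(rows, window = 100, step = 25)
  expect_true(all(prof$identity == 100))
  ch <- strsplit(strrep("A", 120), "")[[1]]
  ch[c(10, 20, 30, 40, 50)] <- "C"
  prof2 <- sliding_identity(c(ref = strrep("A", 120), alt = paste(ch, collapse = "")),
                            window = 100, step = 25)
  expect_equal(prof2$identity[prof2$window_start == 1], 95)
  expect_error(sliding_identity(rows, window = 8, step = 4), "window")
  expect_error(sliding_identity(rows, window = 20, step = 25), "window")
  # windows with < 10 comparable positions are NA
  gappy <- c(ref = paste0(strrep("A", 12), strrep("-", 108)),
             alt = strrep("A", 120))
  p3 <- sliding_identity(gappy, window = 20, step = 20)
  expect_true(is.na(p3$identity[p3$window_start == 21]))
  expect_false(is.na(p3$identity[p3$window_start == 1]))
})

test_that("the window-profile mean approximates global identity", {
  withr::with_seed(61, {
    ref <- rand_seq(1000)
    ch <- strsplit(ref, "")[[1]]
    mut <- sample(1000, 80)
    ch[mut] <- sample(c("A", "C", "G", "T"), 80, replace = TRUE)
    alt <- paste(ch, collapse = "")
  })
  global <- 100 * mean(strsplit(ref, "")[[1]] == strsplit(alt, "")[[1]])
  prof <- sliding_identity(c(ref = ref, alt = alt), window = 100, step = 25)
  expect_lt(abs(mean(prof$identity, na.rm = TRUE) - global), 1.5)
})
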
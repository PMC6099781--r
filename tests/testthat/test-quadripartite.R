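test_that("detect_ir recovers a planted quadripartite structure exactly", {
  plan <- small_plan(seed = 3)
  anc <- generate_ancestor(plan)
  st <- detect_ir(anc$genome, min_ir_len = 500)
  expect_equal(st$ir_len, plan$ir_len)
  expect_equal(unname(st$lengths),
               unname(anc$truth$lengths[c("lsc", "irb", "ssc", "ira")]))
  expect_equal(c(st$jlb, st$jsb, st$jsa, st$jla),
               unname(anc$truth$junctions[c("JLB", "JSB", "JSA", "JLA")]))
  # partition tiles the circle once
  expect_equal(sum(st$lengths), anc$genome$length)
  # the IR relation holds exactly
  seqs <- plastocompare:::structure_sequences(anc$genome, st)
  expect_identical(seqs[["irb"]], revcomp(seqs[["ira"]]))
  expect_gt(st$lengths["lsc"], st$lengths["ssc"])
})

test_that("detect_ir is rotation invariant and strand symmetric", {
  anc <- generate_ancestor(small_plan(seed = 9))
  st0 <- detect_ir(anc$genome, min_ir_len = 500)
  n <- anc$genome$length
  withr::with_seed(4, offs <- sample(n - 1L, 3))
  for (off in offs) {
    rot <- paste0(substr(anc$genome$seq, off + 1, n), substr(anc$genome$seq, 1, off))
    str <- detect_ir(circular_genome("rot", rot), min_ir_len = 500)
    expect_equal(str$lengths, st0$lengths)
    # junctions shift with the rotation
    expect_equal(str$jlb, plastocompare:::.mod(st0$jlb - off, n))
  }
  src <- detect_ir(circular_genome("rc", revcomp(anc$genome$seq)), min_ir_len = 500)
  expect_equal(src$ir_len, st0$ir_len)
  expect_equal(sort(unname(src$lengths[c("lsc", "ssc")])),
               sort(unname(st0$lengths[c("lsc", "ssc")])))
})

test_that("genomes without an inverted repeat raise a structured error", {
  withr::with_seed(21, g <- circular_genome("plain", rand_seq(6000)))
  expect_error(detect_ir(g, min_ir_len = 1000), class = "plasto_no_ir")
})

test_that("junction relation and distance conventions are as documented", {
  st <- plastocompare:::.structure_from_parts(n = 1000L, irb_start = 500L,
                                              ir_len = 200L, ssc_len = 100L)
  # JSB (first SSC base) is 700; JLA (first LSC base) is 0
  feat <- function(id, start, end) {
    data.frame(id = id, name = id, kind = "CDS", strand = "+", pseudo = FALSE,
               part = 1L, start = start, end = end, wraps = FALSE,
               stringsAsFactors = FALSE)
  }
  # gene strictly containing JSB spans it
  jr <- junction_report(st, feat("g1", 690L, 720L))
  expect_equal(jr$relation[jr$junction == "JSB"], "spans")
  expect_equal(jr$distance[jr$junction == "JSB"], 0L)
  # gene abutting the junction exactly (end == junction) is upstream at 0
  jr <- junction_report(st, feat("g2", 650L, 700L))
  r <- jr[jr$junction == "JSB", ]
  expect_equal(r$relation[r$gene == "g2" & r$distance == 0L], "upstream")
  expect_false(any(r$relation == "spans"))
  # gene starting at the junction is downstream at 0
  jr <- junction_report(st, feat("g3", 700L, 750L))
  r <- jr[jr$junction == "JSB", ]
  expect_equal(r$relation[r$gene == "g3" & r$distance == 0L], "downstream")
  # empty annotation gives an empty report
  expect_equal(nrow(junction_report(st, NULL)), 0L)
})

test_that("planted junction genes are reported with planted distances", {
  anc <- generate_ancestor(small_plan(seed = 5))
  st <- detect_ir(anc$genome, min_ir_len = 500)
  jr <- junction_report(st, anc$features)
  # psbA was planted 80 bp downstream of JLA
  psba <- jr[jr$junction == "JLA" & jr$gene == "psbA", ]
  expect_equal(psba$relation, "downstream")
  expect_equal(psba$distance, 80L)
  # ndhF straddles JSB, ndhH straddles JSA by construction
  expect_equal(jr$gene[jr$junction == "JSB" & jr$relation == "spans"], "ndhF")
  expect_equal(jr$gene[jr$junction == "JSA" & jr$relation == "spans"], "ndhH")
  # every reported relation matches the construction ledger
  truth <- anc$truth$junction_genes
  for (i in seq_len(nrow(jr))) {
    t <- truth[truth$junction == jr$junction[i] & truth$gene == jr$gene[i] &
                 truth$relation == jr$relation[i], ]
    expect_true(nrow(t) >= 1)
    expect_true(jr$distance[i] %in% t$distance)
  }
})

test_that("compare_junctions classifies IR types and reports the IR size range", {
  p_same <- small_plan(seed = 6, taxa = 2)
  ev <- evolve_taxa(generate_ancestor(p_same))
  bundles <- lapply(ev$taxa, function(b) {
    list(structure = detect_ir(b$genome, 500), features = b$features)
  })
  cj <- compare_junctions(bundles)
  expect_length(unique(cj$ir_types$ir_type), 1L)
  expect_equal(cj$ir_len_range, 0L)

  # a 500 bp JSB expansion in one taxon pushes ndhF wholly into the IR,
  # creating a second IR type
  p_shift <- small_plan(seed = 6, taxa = 2, junction_shifts = list(t02 = 500L))
  ev2 <- evolve_taxa(generate_ancestor(p_shift))
  bundles2 <- lapply(ev2$taxa, function(b) {
    list(structure = detect_ir(b$genome, 500), features = b$features)
  })
  cj2 <- compare_junctions(bundles2)
  expect_length(unique(cj2$ir_types$ir_type), 2L)
  expect_equal(cj2$ir_len_range, 500L)
  expect_equal(cj2$lengths$ir_len, c(2000L, 2500L))
})
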
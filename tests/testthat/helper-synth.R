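# Shared small-scale synthetic plans for tests.

small_plan <- function(seed = 1L, taxa = 3L, ...) {
  synth_plan(seed = seed, lsc_len = 5000L, ssc_len = 1000L, ir_len = 2000L,
             taxa = taxa, ...)
}

# a plan whose locus extraction yields a dense ladder of loci (for rate
# recovery studies): small filler genes packed into a 13 kb LSC
ladder_plan <- function(seed = 1L, taxa = 13L, ...) {
  synth_plan(
    seed = seed, lsc_len = 13000L, ssc_len = 1200L, ir_len = 2000L, taxa = taxa,
    gene_models = default_gene_models(13000L, 1200L, 2000L,
                                      filler_len = 250L, filler_spacer = 150L),
    ...
  )
}

# run generate -> evolve -> extract -> align -> variability for a plan whose
# loci get the supplied per-locus rates (named by locus, assigned by sorted
# name when a bare numeric vector is given)
run_rate_recovery <- function(plan, rates, min_ir_len = 500L) {
  anc <- generate_ancestor(plan)
  st <- detect_ir(anc$genome, min_ir_len = min_ir_len)
  loci <- suppressMessages(extract_loci(anc$genome, anc$features, st))
  if (!is.null(rates) && is.null(names(rates))) {
    stopifnot(length(rates) <= nrow(loci))
    rates <- stats::setNames(rep_len(rates, nrow(loci)), sort(loci$name))
  }
  ev <- evolve_taxa(anc, rates = rates)
  lb <- lapply(ev$taxa, function(b) {
    suppressMessages(extract_loci(b$genome, b$features, detect_ir(b$genome, min_ir_len)))
  })
  hom <- suppressMessages(collect_homologs(lb))
  alns <- lapply(hom, align_locus)
  vt <- variability_table(alns)
  list(rates = rates, records = vt$records, summary = vt$class_summary,
       ratio = vt$ratio, n_loci = nrow(loci))
}
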
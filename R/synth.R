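# Synthetic plastome generator with construction-time ground truth.
#
# Emulates quadripartite chloroplast genomes: random LSC/SSC/IRa cores with
# IRb the exact reverse complement of IRa, genes planted at the junctions
# (mimicking rps19/ndhF/ndhH/psbA placements), planted SSRs and dispersed
# repeats, and Jukes-Cantor evolution of k taxa on a star tree at
# locus-specific per-branch substitution probabilities. Evolution is
# indel-free by default so locus homology is positional and the variability
# statistics have closed-form expectations. All randomness is scoped to the
# plan seed; a fixed seed reproduces byte-identical output.

.BASES <- c("A", "C", "G", "T")

.rand_bases <- function(k) sample(.BASES, k, replace = TRUE)

#' Build a synthetic plastome plan
#'
#' Defaults describe a full-scale herbaceous-bamboo-like plastome (LSC 82 kb,
#' SSC 13 kb, IR 20 kb, 13 taxa, per-branch substitution probabilities 0.005
#' for coding and 0.010 for non-coding loci, an SSR census of 14 mononucleotide
#' runs plus one dinucleotide run, and a small dispersed-repeat set). All sizes
#' scale down for tests.
#'
#' @param seed integer seed; fixed seed implies byte-identical output
#' @param lsc_len,ssc_len,ir_len region sizes in bp
#' @param taxa number of taxa to evolve
#' @param coding_rate,noncoding_rate default per-branch per-site substitution
#'   probabilities by locus class, each in `[0, 0.75)`
#' @param locus_rates optional named vector of per-locus rates overriding the
#'   class defaults
#' @param gene_models,ssr_models,repeat_models data.frames describing planted
#'   elements (NULL: scale-aware defaults); see [default_gene_models()]
#' @param junction_shifts optional named list (taxon -> bp) of per-taxon IR
#'   expansion (+) or contraction (-) at the IRb/SSC junction
#' @param screen_len accidental dispersed repeats of at least this length are
#'   screened out of the ancestor (default 12)
#' @param id genome id prefix
#' @return a `synth_plan` list
#' @export
synth_plan <- function(seed = 1L, lsc_len = 82000L, ssc_len = 13000L,
                       ir_len = 20000L, taxa = 13L,
                       coding_rate = 0.005, noncoding_rate = 0.010,
                       locus_rates = NULL, gene_models = NULL,
                       ssr_models = NULL, repeat_models = NULL,
                       junction_shifts = NULL, screen_len = 12L,
                       id = "synth") {
  stopifnot(lsc_len > 0L, ssc_len > 0L, ir_len > 0L, taxa >= 1L,
            lsc_len > ssc_len)
  rates <- c(coding_rate, noncoding_rate, unlist(locus_rates))
  if (any(rates < 0 | rates >= 0.75)) stop("substitution rates must lie in [0, 0.75)")
  plan <- list(
    seed = as.integer(seed), lsc_len = as.integer(lsc_len),
    ssc_len = as.integer(ssc_len), ir_len = as.integer(ir_len),
    taxa = as.integer(taxa), coding_rate = coding_rate,
    noncoding_rate = noncoding_rate, locus_rates = locus_rates,
    gene_models = gene_models %||% default_gene_models(lsc_len, ssc_len, ir_len),
    ssr_models = ssr_models %||% default_ssr_models(lsc_len, ssc_len),
    repeat_models = repeat_models %||% default_repeat_models(lsc_len, ssc_len),
    junction_shifts = junction_shifts, screen_len = as.integer(screen_len),
    id = id
  )
  class(plan) <- "synth_plan"
  plan
}

#' Default gene models for a synthetic plastome
#'
#' Places junction-context genes the way herbaceous-bamboo plastomes have
#' them: psbA 80 bp downstream of JLA, rpl22 in the LSC upstream of JLB,
#' rps19 and trnH inside the IR (mirrored into both copies), ndhF straddling
#' JSB, rps15 in the SSC and ndhH straddling JSA, plus filler genes (a few
#' with introns) that give the locus extractor material to work with.
#' Anchors: `LSC`/`SSC`/`IRA` place `offset` relative to the region start;
#' `JLB`/`JSB`/`JSA`/`JLA` place it relative to the junction (negative =
#' upstream).
#'
#' @param lsc_len,ssc_len,ir_len region sizes in bp
#' @param filler_len,filler_spacer sizes of the LSC filler genes and the
#'   spacers between them (default: scale with `lsc_len`); shrink these to
#'   pack more loci into the LSC for simulation studies
#' @return data.frame with columns `name`, `kind`, `strand`, `anchor`,
#'   `offset`, `length` (total extent incl. intron), `intron_at`,
#'   `intron_len`, `pseudo`
#' @export
default_gene_models <- function(lsc_len, ssc_len, ir_len,
                                filler_len = NULL, filler_spacer = NULL) {
  gl <- max(150L, min(1200L, lsc_len %/% 20L))   # landmark gene extent
  sp <- max(120L, gl %/% 2L)                     # landmark spacing
  ssc_g <- max(120L, ssc_len %/% 3L)
  ir_g <- max(120L, min(280L, ir_len %/% 5L))
  g <- function(name, kind, strand, anchor, offset, length,
                intron_at = 0L, intron_len = 0L, pseudo = FALSE) {
    data.frame(name = name, kind = kind, strand = strand, anchor = anchor,
               offset = as.integer(offset), length = as.integer(length),
               intron_at = as.integer(intron_at), intron_len = as.integer(intron_len),
               pseudo = pseudo, stringsAsFactors = FALSE)
  }
  rows <- list(
    g("psbA", "CDS", "-", "JLA", 80L, gl),
    g("rpl22", "CDS", "+", "JLB", -(gl + 120L), gl),
    g("rps19", "CDS", "-", "IRA", ir_len - ir_g - 20L, ir_g),
    g("trnH", "tRNA", "-", "IRA", ir_len - ir_g - 20L - 200L - 74L, 74L),
    g("ndhF", "CDS", "-", "JSB", -60L, ssc_g + 60L),
    g("rps15", "CDS", "-", "SSC", ssc_len %/% 2L - 40L, 80L),
    g("ndhH", "CDS", "-", "JSA", -(ssc_g - 30L), ssc_g)
  )
  fl <- as.integer(filler_len %||% gl)
  fs <- as.integer(filler_spacer %||% sp)
  a0 <- 80L + gl + sp          # after psbA
  a1 <- lsc_len - gl - 240L - sp # before rpl22
  i <- 1L
  while (a0 + fl + fs <= a1) {
    if (i %% 5L == 3L) {
      # intron gene: two exons split by an intron the size of a spacer
      rows[[length(rows) + 1L]] <- g(sprintf("gL%02d", i), "CDS",
                                     if (i %% 2L) "+" else "-", "LSC", a0, fl + fs,
                                     intron_at = fl %/% 2L, intron_len = fs)
      a0 <- a0 + fl + fs + fs
    } else {
      rows[[length(rows) + 1L]] <- g(sprintf("gL%02d", i), "CDS",
                                     if (i %% 2L) "+" else "-", "LSC", a0, fl)
      a0 <- a0 + fl + fs
    }
    i <- i + 1L
  }
  do.call(rbind, rows)
}

#' Default SSR plan (14 mononucleotide runs + 1 dinucleotide run)
#'
#' @param lsc_len,ssc_len region sizes in bp
#' @return data.frame with columns `motif`, `copies`, `region`, `offset`
#' @export
default_ssr_models <- function(lsc_len, ssc_len) {
  slots_lsc <- as.integer(round(lsc_len * (1:13) / 16))
  rows <- lapply(1:12, function(i) {
    data.frame(motif = if (i %% 2L) "A" else "T",
               copies = 10L + (i %% 2L),
               region = "LSC", offset = slots_lsc[i], stringsAsFactors = FALSE)
  })
  rows[[13]] <- data.frame(motif = "A", copies = 10L, region = "SSC",
                           offset = as.integer(ssc_len * 0.30), stringsAsFactors = FALSE)
  rows[[14]] <- data.frame(motif = "T", copies = 11L, region = "SSC",
                           offset = as.integer(ssc_len * 0.55), stringsAsFactors = FALSE)
  rows[[15]] <- data.frame(motif = "AG", copies = 6L, region = "LSC",
                           offset = slots_lsc[13], stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' Default dispersed-repeat plan
#'
#' Three forward, one palindromic, one reverse and one complement pair of
#' 30 bp, placed between the SSR slots in the single-copy regions.
#'
#' @param lsc_len,ssc_len region sizes in bp
#' @return data.frame with columns `rtype`, `length`, `region1`, `offset1`,
#'   `region2`, `offset2`
#' @export
default_repeat_models <- function(lsc_len, ssc_len) {
  mid <- function(i) as.integer(round(lsc_len * (i + 0.5) / 16))
  r <- function(rtype, len, r1, o1, r2, o2) {
    data.frame(rtype = rtype, length = as.integer(len), region1 = r1,
               offset1 = as.integer(o1), region2 = r2, offset2 = as.integer(o2),
               stringsAsFactors = FALSE)
  }
  rbind(
    r("forward", 30L, "LSC", mid(1), "LSC", mid(6)),
    r("forward", 30L, "LSC", mid(2), "LSC", mid(9)),
    r("forward", 30L, "LSC", mid(3), "SSC", as.integer(ssc_len * 0.10)),
    r("palindromic", 30L, "LSC", mid(4), "LSC", mid(10)),
    r("reverse", 30L, "LSC", mid(5), "LSC", mid(11)),
    r("complement", 30L, "LSC", mid(7), "LSC", mid(12))
  )
}

# resolve a (region/junction, offset) anchor to an absolute 0-based position
.resolve_anchor <- function(anchor, offset, l1, l2, l3) {
  n <- l1 + 2L * l2 + l3
  base <- switch(anchor,
    LSC = 0L, SSC = l1 + l2, IRA = l1 + l2 + l3,
    JLB = l1, JSB = l1 + l2, JSA = l1 + l2 + l3, JLA = 0L,
    stop("unknown anchor '", anchor, "'")
  )
  .mod(base + offset, n)
}

# feature rows (possibly 2 parts) for one resolved gene instance
.gene_instance_rows <- function(id, name, kind, strand, pseudo, s, len,
                                intron_at, intron_len, n) {
  part <- function(p, st, span) {
    w <- st + span > n
    .feature_row(id, name, kind, strand, pseudo, p,
                 .mod(st, n), if (w) st + span - n else st + span, w)
  }
  if (intron_len > 0L) {
    rbind(part(1L, s, intron_at),
          part(2L, .mod(s + intron_at + intron_len, n), len - intron_at - intron_len))
  } else {
    part(1L, s, len)
  }
}

# relation of a gene extent [gs, gs+span) to junction j, by construction
.relation_to_junction <- function(gs, span, j, n) {
  ge <- .mod(gs + span, n)
  contains <- function(p) .mod(p - gs, n) < span
  if (contains(j) && contains(.mod(j - 1L, n))) {
    list(relation = "spans", distance = 0L)
  } else {
    dup <- .mod(j - ge, n)
    ddown <- .mod(gs - j, n)
    if (dup <= ddown) list(relation = "upstream", distance = dup)
    else list(relation = "downstream", distance = ddown)
  }
}

#' Generate a synthetic ancestor plastome
#'
#' Builds the canonical-orientation genome LSC + IRb + SSC + IRa with IRb the
#' exact reverse complement of IRa, plants the plan's genes, SSRs and
#' dispersed repeats, breaks junction flanks and planted-element flanks so
#' every planted element is exactly maximal, and screens out accidental SSRs
#' and accidental dispersed repeats of length >= `plan$screen_len`.
#'
#' @param plan a [synth_plan()]
#' @return list with `genome` ([circular_genome()]), `features` (annotation
#'   data.frame; IRa genes carry mirrored IRb copies), and `truth` (junction
#'   positions, region lengths, SSR and repeat ledgers, per-junction gene
#'   relations by construction)
#' @export
generate_ancestor <- function(plan) {
  stopifnot(inherits(plan, "synth_plan"))
  with_seed(plan$seed, .generate_ancestor_impl(plan))
}

.generate_ancestor_impl <- function(plan) {
  l1 <- plan$lsc_len; l2 <- plan$ir_len; l3 <- plan$ssc_len
  n <- l1 + 2L * l2 + l3
  A0 <- l1 + l2 + l3 # IRa start, 0-based
  B0 <- l1           # IRb start, 0-based

  a <- character(n)
  a[1:l1] <- .rand_bases(l1)
  a[(l1 + l2 + 1L):(l1 + l2 + l3)] <- .rand_bases(l3)
  a[(A0 + 1L):n] <- .rand_bases(l2)

  in_ira <- function(p0) p0 >= A0
  in_irb <- function(p0) p0 >= B0 && p0 < B0 + l2
  mirror_pos <- function(p0) { # 0-based IRb <-> IRa mirror
    if (in_irb(p0)) A0 + (l2 - 1L) - (p0 - B0) else B0 + (l2 - 1L) - (p0 - A0)
  }
  set_base <- function(p0, base) { # writes through the IR mirror
    a[p0 + 1L] <<- base
    if (in_irb(p0) || in_ira(p0)) a[mirror_pos(p0) + 1L] <<- comp_seq(base)
  }

  # footprints (0-based half-open, with 1 bp margins) that screening must not touch
  protected <- NULL
  protect <- function(s0, e0) protected <<- rbind(protected, c(max(0L, s0 - 1L), min(n, e0 + 1L)))
  is_protected <- function(p0) {
    !is.null(protected) && any(p0 >= protected[, 1L] & p0 < protected[, 2L])
  }

  # --- plant SSRs -----------------------------------------------------------
  ssr_ledger <- NULL
  sm <- plan$ssr_models
  if (!is.null(sm) && nrow(sm)) {
    for (i in seq_len(nrow(sm))) {
      u <- nchar(sm$motif[i]); cp <- sm$copies[i]
      s0 <- .resolve_anchor(sm$region[i], sm$offset[i], l1, l2, l3)
      len <- u * cp
      if (s0 + len + 1L > n || s0 < 1L) stop("planted SSR ", i, " exceeds genome bounds")
      mot <- .chars(sm$motif[i])
      a[(s0 + 1L):(s0 + len)] <- rep(mot, cp)
      # break maximality: left flank != motif[u], right flank != motif[1]
      lf <- setdiff(.BASES, mot[u]); rf <- setdiff(.BASES, mot[1L])
      if (!(a[s0] %in% lf)) a[s0] <- lf[1L]
      if (!(a[s0 + len + 1L] %in% rf)) a[s0 + len + 1L] <- rf[1L]
      protect(s0, s0 + len)
      ssr_ledger <- rbind(ssr_ledger, data.frame(
        motif = .canonical_rotation(sm$motif[i]), motif_obs = sm$motif[i],
        unit = u, copies = cp, start = s0, end = s0 + len, length = len,
        stringsAsFactors = FALSE
      ))
    }
  }

  # --- plant dispersed repeats ---------------------------------------------
  rep_ledger <- NULL
  rm_ <- plan$repeat_models
  plant_repeat <- function(i) {
    L <- rm_$length[i]
    s1 <- .resolve_anchor(rm_$region1[i], rm_$offset1[i], l1, l2, l3)
    s2 <- .resolve_anchor(rm_$region2[i], rm_$offset2[i], l1, l2, l3)
    if (s1 > s2) { tmp <- s1; s1 <- s2; s2 <- tmp }
    if (s2 + L + 1L > n || s1 < 1L) stop("planted repeat ", i, " exceeds genome bounds")
    seg <- .rand_bases(L)
    a[(s1 + 1L):(s1 + L)] <<- seg
    seg2 <- switch(rm_$rtype[i],
      forward = seg,
      palindromic = rev(.chars(comp_seq(.collapse(seg)))),
      reverse = rev(seg),
      complement = .chars(comp_seq(.collapse(seg)))
    )
    a[(s2 + 1L):(s2 + L)] <<- seg2
    # break maximality on both extension directions of the relation
    fix <- function(pos1b, forbidden) { # pos 1-based; forbidden base
      if (a[pos1b] == forbidden) a[pos1b] <<- setdiff(.BASES, forbidden)[1L]
    }
    switch(rm_$rtype[i],
      forward = { fix(s1, a[s2]); fix(s1 + L + 1L, a[s2 + L + 1L]) },
      complement = { fix(s1, comp_seq(a[s2])); fix(s1 + L + 1L, comp_seq(a[s2 + L + 1L])) },
      reverse = { fix(s1, a[s2 + L + 1L]); fix(s1 + L + 1L, a[s2]) },
      palindromic = { fix(s1, comp_seq(a[s2 + L + 1L])); fix(s1 + L + 1L, comp_seq(a[s2])) }
    )
    c(s1, s2, L)
  }
  if (!is.null(rm_) && nrow(rm_)) {
    for (i in seq_len(nrow(rm_))) {
      ft <- plant_repeat(i)
      protect(ft[1L], ft[1L] + ft[3L])
      protect(ft[2L], ft[2L] + ft[3L])
      rep_ledger <- rbind(rep_ledger, data.frame(
        rtype = rm_$rtype[i], start1 = ft[1L], end1 = ft[1L] + ft[3L],
        start2 = ft[2L], end2 = ft[2L] + ft[3L], length = ft[3L],
        stringsAsFactors = FALSE
      ))
    }
  }

  # --- mirror IRa into IRb --------------------------------------------------
  a[(B0 + 1L):(B0 + l2)] <- rev(comp_seq(a[(A0 + 1L):n]))

  # --- make the IR pair exactly maximal at the junction flanks -------------
  fix_junction_flanks <- function() {
    # extension IRb-left / IRa-right: last LSC base vs comp(first LSC base)
    if (a[l1] == comp_seq(a[1L])) {
      a[l1] <<- setdiff(.BASES, comp_seq(a[1L]))[1L]
    }
    # extension IRb-right / IRa-left: first SSC base vs comp(last SSC base)
    if (a[l1 + l2 + 1L] == comp_seq(a[l1 + l2 + l3])) {
      a[l1 + l2 + 1L] <<- setdiff(.BASES, comp_seq(a[l1 + l2 + l3]))[1L]
    }
  }
  fix_junction_flanks()
  protect(l1 - 1L, l1 + 1L)
  protect(l1 + l2 - 1L, l1 + l2 + 1L)
  protect(l1 + l2 + l3 - 1L, l1 + l2 + l3 + 1L)
  protect(0L, 1L); protect(n - 1L, n)

  st_truth <- .structure_from_parts(n, irb_start = B0, ir_len = l2, ssc_len = l3)

  # --- screen accidental SSRs and dispersed repeats ------------------------
  ledger_match <- function(df, ledger, cols) {
    if (is.null(ledger) || !nrow(df)) return(rep(FALSE, nrow(df)))
    key_d <- do.call(paste, df[cols])
    key_l <- do.call(paste, ledger[cols])
    key_d %in% key_l
  }
  touchable <- function(p0) { # neither the position nor its IR mirror is protected
    if (is_protected(p0)) return(FALSE)
    if ((in_irb(p0) || in_ira(p0)) && is_protected(mirror_pos(p0))) return(FALSE)
    TRUE
  }
  pick_fix <- function(s0, e0, self_symmetric = FALSE) {
    # a position inside [s0,e0) that may be changed; for self-symmetric
    # reverse/palindromic runs avoid the run center (for a reverse run the
    # exact center pairs with itself and always matches)
    cand <- s0:(e0 - 1L)
    cand <- cand[vapply(cand, touchable, logical(1))]
    if (!length(cand)) return(NULL)
    want <- if (self_symmetric) s0 + max(1L, (e0 - s0) %/% 4L)
            else s0 + (e0 - s0) %/% 2L
    cand[which.min(abs(cand - want))]
  }
  for (iter in 1:80) {
    gen <- circular_genome(plan$id, .collapse(a))
    a <- .chars(gen$seq) # normalized (no-op, keeps lengths honest)
    dirty <- FALSE

    sh <- find_ssrs(gen)
    acc <- sh[!ledger_match(sh, ssr_ledger, c("start", "unit")), , drop = FALSE]
    if (nrow(acc)) {
      for (r in seq_len(nrow(acc))) {
        p <- pick_fix(acc$start[r], acc$end[r])
        if (is.null(p)) next
        if (in_irb(p)) p <- mirror_pos(p)
        set_base(p, sample(setdiff(.BASES, a[p + 1L]), 1L))
        dirty <- TRUE
      }
    }

    overlaps_protected <- function(s0, e0) {
      !is.null(protected) &&
        any(pmax(protected[, 1L], s0) < pmin(protected[, 2L], e0))
    }
    rh <- find_repeats(gen, plan$screen_len, structure = st_truth)
    rh <- rh[!rh$ir_pair, , drop = FALSE]
    acc <- rh[!ledger_match(rh, rep_ledger, c("rtype", "start1", "start2")), , drop = FALSE]
    if (nrow(acc)) {
      for (r in seq_len(nrow(acc))) {
        # hits whose copies both lie on planted elements (e.g. two
        # same-motif SSR runs seen as a short direct repeat) are a
        # consequence of the plan, not an accident: leave them
        c1p <- overlaps_protected(acc$start1[r], acc$end1[r])
        c2p <- overlaps_protected(acc$start2[r], acc$end2[r])
        if (c1p && c2p) next
        selfsym <- acc$start1[r] == acc$start2[r]
        p <- if (!c2p) pick_fix(acc$start2[r], acc$end2[r], selfsym)
             else pick_fix(acc$start1[r], acc$end1[r], selfsym)
        if (is.null(p)) next
        if (in_irb(p)) p <- mirror_pos(p)
        set_base(p, sample(setdiff(.BASES, a[p + 1L]), 1L))
        dirty <- TRUE
      }
    }

    fix_junction_flanks()
    if (!dirty) break
    if (iter == 80L) {
      if (isTRUE(getOption("plastocompare.debug"))) {
        print(sh); print(rh)
      }
      stop("screening did not converge; adjust the plan")
    }
  }
  genome <- circular_genome(plan$id, .collapse(a))

  # --- features -------------------------------------------------------------
  gm <- plan$gene_models
  feat <- list()
  truth_jg <- list()
  junctions <- c(JLB = B0, JSB = l1 + l2, JSA = A0, JLA = 0L)
  for (i in seq_len(nrow(gm))) {
    s0 <- .resolve_anchor(gm$anchor[i], gm$offset[i], l1, l2, l3)
    feat[[length(feat) + 1L]] <- .gene_instance_rows(
      gm$name[i], gm$name[i], gm$kind[i], gm$strand[i], gm$pseudo[i],
      s0, gm$length[i], gm$intron_at[i], gm$intron_len[i], n
    )
    # mirrored IRb copy for genes wholly inside IRa
    if (s0 >= A0 && s0 + gm$length[i] <= n) {
      ms <- B0 + (l2 - ((s0 - A0) + gm$length[i]))
      feat[[length(feat) + 1L]] <- .gene_instance_rows(
        paste0(gm$name[i], "_irb"), gm$name[i], gm$kind[i],
        if (gm$strand[i] == "+") "-" else "+", gm$pseudo[i],
        ms, gm$length[i],
        if (gm$intron_len[i] > 0L) gm$length[i] - gm$intron_at[i] - gm$intron_len[i] else 0L,
        gm$intron_len[i], n
      )
    }
  }
  features <- do.call(rbind, feat)
  rownames(features) <- NULL

  # per-junction relations of every gene instance, by construction arithmetic
  ext <- .gene_extents(features, n)
  for (jn in names(junctions)) {
    for (r in seq_len(nrow(ext))) {
      rel <- .relation_to_junction(ext$start[r], ext$span[r], junctions[[jn]], n)
      truth_jg[[length(truth_jg) + 1L]] <- data.frame(
        junction = jn, id = ext$id[r], gene = ext$name[r],
        relation = rel$relation, distance = rel$distance,
        stringsAsFactors = FALSE
      )
    }
  }
  truth <- list(
    junctions = junctions,
    lengths = c(lsc = l1, irb = l2, ssc = l3, ira = l2),
    genome_length = n,
    ssrs = ssr_ledger,
    repeats = rep_ledger,
    junction_genes = do.call(rbind, truth_jg)
  )
  list(genome = genome, features = features, truth = truth, plan = plan)
}

.ALT <- matrix(c("C", "G", "T",
                 "A", "G", "T",
                 "A", "C", "T",
                 "A", "C", "G"), nrow = 4, byrow = TRUE,
               dimnames = list(.BASES, NULL))

#' Evolve taxa from a synthetic ancestor
#'
#' Applies Jukes-Cantor substitutions independently per site on each branch of
#' a star tree: each taxon's copy of each site mutates with the site's
#' per-branch probability, drawing uniformly among the three other bases.
#' Rates are locus-specific (via `rates`, the plan's `locus_rates`, or the
#' plan's class defaults applied to the ancestor's extracted loci); sites not
#' in any extracted locus evolve at the coding rate. Only one IR copy is
#' simulated and mirrored into the other, preserving the exact IR relation.
#' Optional per-taxon junction shifts expand/contract the IR at JSB.
#'
#' @param ancestor output of [generate_ancestor()]
#' @param rates optional named per-locus per-branch substitution probabilities
#' @param seed RNG seed (default: plan seed + 1)
#' @param locus_min_len passed to [extract_loci()] when assigning rates
#' @return list with `taxa` (named list of `genome`/`features`/`truth`
#'   bundles), `locus_rates` (the per-locus rates actually applied), and
#'   `ancestor`
#' @export
evolve_taxa <- function(ancestor, rates = NULL, seed = NULL,
                        locus_min_len = 100L) {
  plan <- ancestor$plan
  seed <- seed %||% (plan$seed + 1L)
  with_seed(seed, .evolve_taxa_impl(ancestor, rates, locus_min_len))
}

.evolve_taxa_impl <- function(ancestor, rates, locus_min_len) {
  plan <- ancestor$plan
  tr <- ancestor$truth
  n <- tr$genome_length
  l1 <- unname(tr$lengths["lsc"]); l2 <- unname(tr$lengths["irb"])
  l3 <- unname(tr$lengths["ssc"])
  st <- .structure_from_parts(n, irb_start = l1, ir_len = l2, ssc_len = l3)

  loci <- suppressMessages(
    extract_loci(ancestor$genome, ancestor$features, st, min_len = locus_min_len)
  )
  rate_of <- function(nm, lclass) {
    if (!is.null(rates) && nm %in% names(rates)) return(unname(rates[nm]))
    if (!is.null(plan$locus_rates) && nm %in% names(plan$locus_rates)) {
      return(unname(plan$locus_rates[nm]))
    }
    if (lclass == "coding") plan$coding_rate else plan$noncoding_rate
  }
  rate <- rep(plan$coding_rate, n)
  used <- stats::setNames(numeric(nrow(loci)), loci$name)
  ordr <- order(loci$lclass) # coding first, noncoding overwrites introns
  for (i in ordr) {
    r <- rate_of(loci$name[i], loci$lclass[i])
    used[loci$name[i]] <- r
    extent <- if (loci$wraps[i]) (n - loci$start[i]) + loci$end[i] else loci$end[i] - loci$start[i]
    pos <- .mod(loci$start[i] + 0:(extent - 1L), n) + 1L
    rate[pos] <- r
  }
  if (any(rate < 0 | rate >= 0.75)) stop("locus rates must lie in [0, 0.75)")

  anc <- .chars(ancestor$genome$seq)
  irb_idx <- (l1 + 1L):(l1 + l2)
  evolvable <- setdiff(which(anc %in% .BASES), irb_idx)

  taxa <- list()
  for (t in seq_len(plan$taxa)) {
    tx <- sprintf("t%02d", t)
    a <- anc
    hit <- evolvable[stats::runif(length(evolvable)) < rate[evolvable]]
    if (length(hit)) {
      pick <- sample.int(3L, length(hit), replace = TRUE)
      a[hit] <- .ALT[cbind(match(a[hit], .BASES), pick)]
    }
    a[irb_idx] <- rev(comp_seq(a[(l1 + l2 + l3 + 1L):n]))
    feats <- ancestor$features
    jn <- c(JLB = l1, JSB = l1 + l2, JSA = l1 + l2 + l3, JLA = 0L)
    lens <- tr$lengths
    d <- 0L
    if (!is.null(plan$junction_shifts) && tx %in% names(plan$junction_shifts)) {
      d <- as.integer(plan$junction_shifts[[tx]])
      sh <- .apply_jsb_shift(a, feats, l1, l2, l3, d)
      a <- sh$a; feats <- sh$features
      jn <- sh$junctions; lens <- sh$lengths
    }
    taxa[[tx]] <- list(
      genome = circular_genome(paste0(plan$id, "_", tx), .collapse(a)),
      features = feats,
      truth = list(junctions = jn, lengths = lens, genome_length = n + d,
                   jsb_shift = d)
    )
  }
  list(taxa = taxa, locus_rates = used[!duplicated(names(used))],
       ancestor = ancestor)
}

# IR expansion (+d) or contraction (-d) at the IRb/SSC junction: for +d the
# first d bases of the SSC are captured by IRb and their reverse complement is
# inserted at the start of IRa; features downstream of the old JSA shift by d.
.apply_jsb_shift <- function(a, features, l1, l2, l3, d) {
  n <- length(a)
  jsa0 <- l1 + l2 + l3 # 0-based old IRa start
  if (d > 0L) {
    stopifnot(d < l3)
    ins <- rev(comp_seq(a[(l1 + l2 + 1L):(l1 + l2 + d)]))
    a2 <- c(a[1:jsa0], ins, a[(jsa0 + 1L):n])
    shift <- d
  } else if (d < 0L) {
    d0 <- -d
    stopifnot(d0 < l2)
    a2 <- a[-((jsa0 + 1L):(jsa0 + d0))]
    shift <- -d0
  } else {
    return(list(a = a, features = features,
                junctions = c(JLB = l1, JSB = l1 + l2, JSA = jsa0, JLA = 0L),
                lengths = c(lsc = l1, irb = l2, ssc = l3, ira = l2)))
  }
  f2 <- features
  move <- !f2$wraps & f2$start >= jsa0
  f2$start[move] <- f2$start[move] + shift
  f2$end[move] <- f2$end[move] + shift
  l2n <- l2 + abs(d) * sign(d)
  l3n <- l3 - abs(d) * sign(d)
  list(
    a = a2, features = f2,
    junctions = c(JLB = l1, JSB = l1 + l2n, JSA = l1 + l2n + l3n, JLA = 0L),
    lengths = c(lsc = l1, irb = l2n, ssc = l3n, ira = l2n)
  )
}

#' Write a synthetic taxon bundle to disk
#'
#' Emits one FASTA and one GFF3 per taxon plus a `truth.json` ground-truth
#' ledger.
#'
#' @param evolved output of [evolve_taxa()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_synth_bundle <- function(evolved, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tx in names(evolved$taxa)) {
    b <- evolved$taxa[[tx]]
    write_fasta(b$genome, file.path(dir, paste0(tx, ".fasta")))
    write_annotations(b$features, file.path(dir, paste0(tx, ".gff3")),
                      format = "gff3", genome = b$genome)
  }
  as_named <- function(tr) {
    tr$junctions <- as.list(tr$junctions)
    tr$lengths <- as.list(tr$lengths)
    tr
  }
  truth <- list(
    ancestor = as_named(evolved$ancestor$truth[c("junctions", "lengths", "genome_length")]),
    locus_rates = as.list(evolved$locus_rates),
    taxa = lapply(evolved$taxa, function(b) as_named(b$truth))
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
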
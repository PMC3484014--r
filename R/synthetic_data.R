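# Seeded generators for every input the pipeline consumes: the LAV60 region
# fixture (a ~69-kb wild-type region carrying MLPH, PRLH, RAB17, LRRFIP1 and
# six breakpoints), derived-allele sequences and walk reads, tiled amplicon
# panels with presence/absence calls, and phenotype tables with the
# family/sex/genotype structure of the quail cohorts. Every generator is a
# pure function of (config, seed); no downloads.

#' Default LAV60 fixture configuration
#'
#' Breakpoint spacings are solved at run time from the printed distance
#' constraints (see [lav60_constraints()]); flanks, read geometry and panel
#' geometry are fixture choices documented in the package vignette.
#'
#' @param seed Integer seed driving every random draw.
#' @return Config list used by the `make_*` generators.
#' @export
lav60_config <- function(seed = 1L) {
  sol <- solve_coordinates(lav60_constraints())
  if (!isTRUE(sol$feasible))
    lavrec_error("default constraint set is infeasible", "lavrec_generation_error")
  list(
    seed = as.integer(seed),
    flank_left = 5000L, flank_right = 5000L,
    breakpoints_rel = sol$positions,
    events = lav_event_template(),
    read_len = 850L, walkup_prefix = 10L, walkdown_tail = 300L,
    min_anchor = 20L, merge_tol = 5L,
    n_amplicons = 16L, amp_len = 600L, max_product = 5000L,
    pheno = lav60_pheno_config())
}

#' Default phenotype-generator configuration
#'
#' Cohort sizes, genotype means and dispersions follow the printed quail
#' cohort structure: growth cohort 59 lavender / 66 wild-type from 21
#' families, feed trial 51 / 41 from 18 families; growth-parameter means
#' (A, B, k) per genotype, sex-specific feed-intake regressions with the
#' printed coefficients, and a genotype shift on the feed-intake residual.
#'
#' @return Config list consumed by [make_phenotypes()].
#' @export
lav60_pheno_config <- function() {
  list(
    n_growth = c(lav = 59L, wt = 66L), n_families_growth = 21L,
    n_feed = c(lav = 51L, wt = 41L), n_families_feed = 18L,
    ages = seq(7L, 63L, 7L),
    growth_mean = list(lav = c(A = 204.4, B = 221.4, k = 0.0405),
                       wt = c(A = 215.9, B = 233.0, k = 0.0401)),
    family_sd = c(A = 10, B = 10, k = 0.001),
    sex_effect = c(A = 8, B = 8, k = 0),  # +/- for F/M
    resid_sd = c(A = 28, B = 30, k = 0.0055),
    measurement_sd = 4,
    bw_test_mean = c(lav = 181.7, wt = 186.5), bw_test_sd = 20,
    bwg_mean = c(lav = 8.7, wt = 6.7), bwg_sd = c(lav = 11.7, wt = 10.0),
    em_mean = 191, em_sd = 27,
    mbw_exponent = 0.75, mbw_unit_g = TRUE,
    fi_coef_f = c(intercept = 23.3, bwg = 1.50, mbw = 6.56, em = 1.075),
    fi_coef_m = c(intercept = 255.2, bwg = 3.35, mbw = 2.91),
    fi_resid = list(lav = c(mean = 19.2, sd = 33.5),
                    wt = c(mean = -22.8, sd = 24.4)),
    temp_mean = c(lav = 41.02, wt = 41.16), temp_sd = 0.26,
    temp_family_sd = 0.08, temp_bw_slope = 0.003,
    bw6mo_mean = c(lav = 187.3, wt = 194.3), bw6mo_sd = 15)
}

gen_error <- function(msg) lavrec_error(msg, "lavrec_generation_error")

#' Generate the wild-type region fixture
#'
#' Builds the region map (four genes placed to satisfy the qualitative
#' containment statements: PRLH and most of RAB17 inside the content removed
#' by the deletion, MLPH exons 1-9 proximal of BP1, LRRFIP1 exon 1 inside the
#' first inversion) and a random sequence whose breakpoint neighbourhoods
#' carry no repeated 20-mer and terminate exact matches precisely at every
#' novel junction of the default scenario.
#'
#' @param config From [lav60_config()].
#' @param dir Optional directory: writes `region.fa`, `region.gff3`,
#'   `breakpoints.tsv`.
#' @return List: `region` ([RegionMap]), `seq` (`DNAString`), `events`
#'   (wild-type-anchored default scenario), `paths` (when `dir` given).
#' @export
make_region <- function(config = lav60_config(), dir = NULL) {
  set.seed(config$seed)
  fL <- config$flank_left; fR <- config$flank_right
  bp <- config$breakpoints_rel + fL
  L <- as.integer(bp[["BP6"]] + fR)
  if (fL < 5000L) gen_error("flank_left too small to place MLPH exons 1-9")
  if (bp[["BP2"]] - bp[["BP1"]] < 6000L)
    gen_error("containment violated: PRLH does not fit between BP1 and BP2")
  if (bp[["BP3"]] - bp[["BP2"]] < 700L)
    gen_error("containment violated: RAB17 exon 1 does not fit above BP2")
  if (bp[["BP4"]] - bp[["BP3"]] < 1000L)
    gen_error("containment violated: LRRFIP1 exon 1 does not fit above BP3")
  if (fR < 600L)
    gen_error("containment violated: LRRFIP1 exon 2 does not fit in the distal flank")
  ex <- function(starts, len) cbind(starts, starts + len)
  genes <- list(
    GeneModel("MLPH", "+", ex(c(fL - 4500L + 480L * (0:8), bp[["BP1"]] + 500L),
                              120L)),
    GeneModel("PRLH", "+", ex(bp[["BP1"]] + c(4000L, 4500L, 5000L), 150L)),
    GeneModel("RAB17", "-", ex(bp[["BP2"]] + c(500L, -600L, -1200L, -1800L),
                               100L)),
    GeneModel("LRRFIP1", "+", ex(c(bp[["BP3"]] + 750L, bp[["BP6"]] + 350L),
                                 150L)))
  region <- RegionMap(L, genes, bp)
  seqc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  seqc <- fix_junction_context(seqc, region, config$events)
  check_breakpoint_kmers(seqc, bp, k = config$min_anchor)
  out <- list(region = region,
              seq = Biostrings::DNAString(paste(seqc, collapse = "")),
              events = config$events)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(dir, "region.fa")
    ss <- Biostrings::DNAStringSet(out$seq); names(ss) <- "LAV60_wt"
    Biostrings::writeXStringSet(ss, fa)
    write_region(region, file.path(dir, "region.gff3"),
                 file.path(dir, "breakpoints.tsv"), seqid = "LAV60_wt")
    out$paths <- c(fa = fa, gff3 = file.path(dir, "region.gff3"),
                   breakpoints = file.path(dir, "breakpoints.tsv"))
  }
  out
}

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

# Mutate continuation bases so exact matching terminates exactly at every
# novel junction of the scenario, in both read directions.
fix_junction_context <- function(seqc, region, event_spec) {
  events <- events_from_wt(region, event_spec)
  sim <- apply_scenario(region, events)
  jx <- sim$junctions
  for (iter in 1:10) {
    changed <- FALSE
    for (i in seq_len(nrow(jx))) {
      pL <- jx$left_pos[i]; sL <- jx$left_strand[i]
      pR <- jx$right_pos[i]; sR <- jx$right_strand[i]
      nxt <- if (sR == "+") seqc[pR + 1L] else comp_base(seqc[pR])  # derived[d]
      prv <- if (sL == "+") seqc[pL] else comp_base(seqc[pL + 1L]) # derived[d-1]
      # forward reads: derived[d] must differ from the wild-type continuation
      if (sL == "+" && pL < length(seqc) && seqc[pL + 1L] == nxt) {
        seqc[pL + 1L] <- setdiff(c("A", "C", "G", "T"),
                                 c(nxt, seqc[pL + 1L]))[1]
        changed <- TRUE
      } else if (sL == "-" && pL >= 1L && comp_base(seqc[pL]) == nxt) {
        seqc[pL] <- setdiff(c("A", "C", "G", "T"), c(comp_base(nxt), seqc[pL]))[1]
        changed <- TRUE
      }
      # reverse-direction reads: derived[d-1] must differ from the wild-type
      # base preceding the right breakend
      if (sR == "+" && pR >= 1L && seqc[pR] == prv) {
        seqc[pR] <- setdiff(c("A", "C", "G", "T"), c(prv, seqc[pR]))[1]
        changed <- TRUE
      } else if (sR == "-" && pR < length(seqc) &&
                 comp_base(seqc[pR + 1L]) == prv) {
        seqc[pR + 1L] <- setdiff(c("A", "C", "G", "T"),
                                 c(comp_base(prv), seqc[pR + 1L]))[1]
        changed <- TRUE
      }
    }
    if (!changed) return(seqc)
  }
  gen_error("could not stabilise junction contexts")
}

check_breakpoint_kmers <- function(seqc, bp, k = 20L) {
  s <- paste(seqc, collapse = "")
  dna <- Biostrings::DNAString(s)
  for (p in bp) {
    for (st in max(1L, p - k + 1L):min(nchar(s) - k + 1L, p + 1L)) {
      kmer <- substr(s, st, st + k - 1L)
      nf <- length(Biostrings::matchPattern(kmer, dna))
      nr <- length(Biostrings::matchPattern(
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(kmer))),
        dna))
      if (nf + nr > 1L)
        gen_error(sprintf("repeated %d-mer spanning breakpoint at %d", k, p))
    }
  }
  invisible(TRUE)
}

#' Simulate the derived allele and chromosome-walk reads
#'
#' The walk-up read begins `walkup_prefix` (< `min_anchor`) bases before the
#' first novel junction, emulating a nested primer abutting the proximal
#' breakpoint, and extends across the translocated fragment into the inverted
#' content. The walk-down read is the reverse complement of the stretch
#' ending `walkdown_tail` bases beyond the second junction, reading back
#' across the translocated fragment into the proximal flank.
#'
#' @param region_obj Output of [make_region()].
#' @param events Wild-type-anchored event list (default: the region's
#'   scenario); `NULL` or empty list simulates the unrearranged allele.
#' @param config From [lav60_config()] (read geometry).
#' @return List: `painting`, `junctions`, `fates`, `derived_seq`, `reads`
#'   (named `DNAStringSet`: walk_up, walk_down), `events` (current-frame).
#' @export
make_allele_and_reads <- function(region_obj, events = region_obj$events,
                                  config = lav60_config()) {
  region <- region_obj$region
  if (is.null(events)) events <- list()
  evs <- if (length(events)) events_from_wt(region, events) else list()
  sim <- apply_scenario(region, evs)
  derived <- render_sequence(region_obj$seq, sim$painting)
  rl <- config$read_len
  if (rl < 2L * config$min_anchor)
    gen_error("read_len must be >= 2 * min_anchor")
  jx <- sim$junctions
  dl <- length(derived)
  if (nrow(jx) < 2L) {
    up <- Biostrings::subseq(derived, 1L, min(rl, dl))
    down <- Biostrings::reverseComplement(
      Biostrings::subseq(derived, max(1L, dl - rl + 1L), dl))
  } else {
    r1 <- jx$derived_pos[1]; r2 <- jx$derived_pos[2]
    need_up <- (r2 - r1) + config$walkup_prefix + config$min_anchor
    need_down <- (r2 - r1) + config$walkdown_tail + config$min_anchor
    if (rl < max(need_up, need_down))
      gen_error(sprintf("read_len %d cannot span the junction pair; need >= %d",
                        rl, max(need_up, need_down)))
    a_up <- r1 - config$walkup_prefix
    up <- Biostrings::subseq(derived, a_up + 1L, min(a_up + rl, dl))
    b_dn <- min(r2 + config$walkdown_tail, dl)
    down <- Biostrings::reverseComplement(
      Biostrings::subseq(derived, b_dn - rl + 1L, b_dn))
  }
  reads <- Biostrings::DNAStringSet(list(walk_up = up, walk_down = down))
  list(painting = sim$painting, junctions = sim$junctions, fates = sim$fates,
       derived_seq = derived, reads = reads, events = evs,
       trajectory = sim$trajectory)
}

#' Generate the tiled amplicon panel and presence/absence calls
#'
#' With the default 16 amplicons the layout reproduces the A-P screening
#' panel: four amplicons in the proximal flank (the last ending < 1 kb before
#' BP1), eight inside the content removed by the deletion, four in the
#' retained inverted segment (the first starting < 1 kb after BP2). Calls are
#' computed by in-silico PCR on both alleles: an amplicon is absent in the
#' mutant iff a primer footprint is destroyed or the primers no longer face
#' each other within `max_product` on the derived allele.
#'
#' @param region_obj Output of [make_region()].
#' @param painting Derived-allele [SegmentPainting].
#' @param n_amplicons Number of amplicons (>= 4).
#' @param spacing Optional even spacing in bp for generic panels; `NULL` with
#'   16 amplicons selects the A-P layout.
#' @param config From [lav60_config()].
#' @return List: `panel` (name, fwd_pos, rev_pos), `wt_calls`, `mut_calls`.
#' @export
make_panel_and_calls <- function(region_obj, painting, n_amplicons = 16L,
                                 spacing = NULL, config = lav60_config()) {
  region <- region_obj$region
  if (n_amplicons < 4L) gen_error("need at least 4 amplicons")
  alen <- config$amp_len
  bp <- region$breakpoints
  if (is.null(spacing) && n_amplicons == 16L) {
    fwd <- c(bp[["BP1"]] - 4500L + 1200L * (0:3),          # A-D
             round(seq(bp[["BP1"]] + 400L, bp[["BP2"]] - 1200L,
                       length.out = 8)),                    # E-L
             bp[["BP2"]] + 150L + 1750L * (0:3))            # M-P
  } else {
    if (is.null(spacing)) spacing <- (region$length_bp - alen) %/% n_amplicons
    fwd <- round(seq(0L, n_amplicons - 1L) * spacing)
  }
  rev <- fwd + alen
  if (any(rev > region$length_bp) || any(fwd < 0L))
    gen_error("amplicon spacing exceeds the region")
  panel <- data.frame(name = LETTERS[seq_len(n_amplicons)],
                      fwd_pos = as.integer(fwd), rev_pos = as.integer(rev))
  primers <- primer_table(
    name = c(paste0(panel$name, "_F"), paste0(panel$name, "_R")),
    wt_start = c(panel$fwd_pos, panel$rev_pos - 20L),
    wt_end = c(panel$fwd_pos + 20L, panel$rev_pos),
    strand = rep(c("+", "-"), each = n_amplicons))
  call_on <- function(pn) {
    prods <- insilico_pcr(pn, primers, max_product = config$max_product)
    present <- vapply(panel$name, function(a) {
      f <- paste0(a, "_F"); r <- paste0(a, "_R")
      any((prods$fwd == f & prods$rev == r) | (prods$fwd == r & prods$rev == f))
    }, logical(1))
    stats::setNames(ifelse(present, "present", "absent"), panel$name)
  }
  wt_calls <- call_on(identity_painting(region))
  mut_calls <- call_on(painting)
  list(panel = panel, wt_calls = wt_calls, mut_calls = mut_calls)
}

#' Three-primer genotyping assay for the fixture
#'
#' Gen_F sits in the conserved proximal flank; Gen_wt_R inside the deleted
#' content (423-bp wild-type product); Gen_lav_R inside the inverted content,
#' so the 630-bp lavender product spans a novel junction.
#'
#' @param region_obj Output of [make_region()].
#' @return Primer table with roles.
#' @export
lav60_genotyping_primers <- function(region_obj) {
  bp <- region_obj$region$breakpoints
  gf_start <- bp[["BP1"]] - 150L
  # lavender product: Gen_F..R1 (150) + fragment (BP6-BP5) + remainder read
  # back from just below BP3 on the inverted segment
  frag <- bp[["BP6"]] - bp[["BP5"]]
  rem <- 630L - 150L - frag
  primer_table(
    name = c("Gen_F", "Gen_wt_R", "Gen_lav_R"),
    wt_start = c(gf_start, gf_start + 423L - 20L, bp[["BP3"]] - rem),
    wt_end = c(gf_start + 20L, gf_start + 423L, bp[["BP3"]] - rem + 20L),
    strand = c("+", "-", "+"),
    role = c("generic", "wt-specific", "mutant-specific"))
}

#' Generate the phenotype table
#'
#' Per-bird weekly body weights from individual monomolecular growth curves
#' (genotype-shifted parameter means, family and sex shifts), feed-test
#' records built from the printed sex-specific regressions with a genotype
#' shift on the residual, body temperature with a genotype shift and a body
#' weight covariate, and a 6-month weight. All draws are seeded.
#'
#' @param config From [lav60_config()] (uses `config$pheno` and
#'   `config$seed`).
#' @return List: `birds` (one row per bird; weekly weights in columns
#'   `bw_d<age>`), `growth_true` (per-bird generating parameters), `config`.
#' @export
make_phenotypes <- function(config = lav60_config()) {
  pc <- config$pheno
  set.seed(config$seed + 1L)
  n <- sum(pc$n_growth)
  genotype <- rep(c("lav", "wt"), pc$n_growth)
  fam <- rep_len(seq_len(pc$n_families_growth), n)
  fam <- sample(fam)  # families span both genotypes
  sex <- rep_len(c("F", "M"), n)[sample.int(n)]
  fam_eff <- sapply(c("A", "B", "k"), function(p)
    stats::rnorm(pc$n_families_growth, 0, pc$family_sd[[p]]))
  gp <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("A", "B", "k")))
  for (i in seq_len(n)) {
    mu <- pc$growth_mean[[genotype[i]]]
    sx <- ifelse(sex[i] == "F", 1, -1)
    for (p in c("A", "B", "k"))
      gp[i, p] <- mu[[p]] + fam_eff[fam[i], p] +
        sx * pc$sex_effect[[p]] + stats::rnorm(1, 0, pc$resid_sd[[p]])
  }
  gp[, "A"] <- pmax(gp[, "A"], 50); gp[, "B"] <- pmax(gp[, "B"], 50)
  gp[, "k"] <- pmax(gp[, "k"], 1e-4)
  bw <- sapply(pc$ages, function(t)
    gp[, "A"] - gp[, "B"] * exp(-gp[, "k"] * t) +
      stats::rnorm(n, 0, pc$measurement_sd))
  colnames(bw) <- paste0("bw_d", pc$ages)
  birds <- data.frame(id = sprintf("q%03d", seq_len(n)),
                      family = paste0("f", fam), sex = sex,
                      genotype = genotype, stringsAsFactors = FALSE)
  birds <- cbind(birds, as.data.frame(bw))

  # feed-trial subset: printed cohort sizes from the first families
  on_test <- c(which(genotype == "lav")[seq_len(pc$n_feed[["lav"]])],
               which(genotype == "wt")[seq_len(pc$n_feed[["wt"]])])
  birds$on_feed_test <- seq_len(n) %in% on_test
  birds$bw_test <- NA_real_; birds$bwg <- NA_real_; birds$mbw <- NA_real_
  birds$em <- NA_real_; birds$fi <- NA_real_
  birds$body_temp <- NA_real_
  tfam <- stats::rnorm(pc$n_families_growth, 0, pc$temp_family_sd)
  for (i in on_test) {
    g <- genotype[i]
    bwt <- stats::rnorm(1, pc$bw_test_mean[[g]], pc$bw_test_sd)
    bwg <- stats::rnorm(1, pc$bwg_mean[[g]], pc$bwg_sd[[g]])
    mbw <- metabolic_bw(if (isTRUE(pc$mbw_unit_g)) bwt else bwt / 1000,
                        pc$mbw_exponent)
    em <- if (sex[i] == "F") max(0, stats::rnorm(1, pc$em_mean, pc$em_sd))
          else NA_real_
    res <- stats::rnorm(1, pc$fi_resid[[g]][["mean"]], pc$fi_resid[[g]][["sd"]])
    fi <- if (sex[i] == "F")
      pc$fi_coef_f[["intercept"]] + pc$fi_coef_f[["bwg"]] * bwg +
        pc$fi_coef_f[["mbw"]] * mbw + pc$fi_coef_f[["em"]] * em + res
    else
      pc$fi_coef_m[["intercept"]] + pc$fi_coef_m[["bwg"]] * bwg +
        pc$fi_coef_m[["mbw"]] * mbw + res
    birds$bw_test[i] <- bwt; birds$bwg[i] <- bwg; birds$mbw[i] <- mbw
    birds$em[i] <- em; birds$fi[i] <- fi
    birds$body_temp[i] <- pc$temp_mean[[g]] + tfam[fam[i]] +
      pc$temp_bw_slope * (bwt - mean(pc$bw_test_mean)) +
      stats::rnorm(1, 0, pc$temp_sd)
  }
  birds$bw_6mo <- stats::rnorm(n, pc$bw6mo_mean[genotype], pc$bw6mo_sd)
  growth_true <- data.frame(id = birds$id, as.data.frame(gp))
  list(birds = birds, growth_true = growth_true, config = config)
}

#' Write a phenotype table as TSV
#' @param pheno Output of [make_phenotypes()].
#' @param file Output path.
#' @export
write_phenotypes <- function(pheno, file) {
  utils::write.table(pheno$birds, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
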
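test_that("generators are pure functions of (config, seed)", {
  cfg <- lav60_config(21L)
  r1 <- make_region(cfg); r2 <- make_region(cfg)
  expect_identical(as.character(r1$seq), as.character(r2$seq))
  expect_identical(r1$region$breakpoints, r2$region$breakpoints)
  s1 <- make_allele_and_reads(r1, config = cfg)
  s2 <- make_allele_and_reads(r2, config = cfg)
  expect_identical(as.character(s1$reads), as.character(s2$reads))
  p1 <- make_phenotypes(cfg); p2 <- make_phenotypes(cfg)
  expect_identical(p1$birds, p2$birds)
  # a different seed changes the sequence
  cfg2 <- lav60_config(22L)
  expect_false(identical(as.character(make_region(cfg2)$seq),
                         as.character(r1$seq)))
})

test_that("region files are written and reload to the same map", {
  cfg <- lav60_config(23L)
  d <- withr::local_tempdir()
  reg <- make_region(cfg, dir = d)
  expect_true(all(file.exists(reg$paths)))
  rm2 <- load_region(reg$paths[["gff3"]], reg$paths[["breakpoints"]])
  expect_equal(rm2$breakpoints, reg$region$breakpoints)
  fa <- Biostrings::readDNAStringSet(reg$paths[["fa"]])
  expect_equal(unname(as.character(fa[1])), as.character(reg$seq))
})

test_that("generated fixtures pass downstream validation (generation-then-validation)", {
  for (seed in c(31L, 32L, 33L)) {
    cfg <- lav60_config(seed)
    reg <- make_region(cfg)
    expect_s3_class(reg$region, "RegionMap")
    expect_equal(nrow(reg$region$genes$MLPH$exons), 10L)
    bp <- reg$region$breakpoints
    ex <- reg$region$genes$MLPH$exons
    expect_true(ex[9, 2] <= bp[["BP1"]] && bp[["BP1"]] < ex[10, 1])
    sim <- make_allele_and_reads(reg, config = cfg)
    expect_equal(painting_length(sim$painting),
                 reg$region$length_bp - 16000L)
    expect_silent(interpret_walk(sim$reads[["walk_up"]], reg$seq))
    pan <- make_panel_and_calls(reg, sim$painting, config = cfg)
    expect_silent(screen(pan$panel, pan$wt_calls, pan$mut_calls))
  }
})

test_that("infeasible configurations raise generation errors", {
  cfg <- lav60_config(24L)
  cfg$breakpoints_rel["BP2"] <- cfg$breakpoints_rel[["BP1"]] + 3000L
  err <- tryCatch(make_region(cfg), error = identity)
  expect_s3_class(err, "lavrec_generation_error")
  expect_match(conditionMessage(err), "PRLH")
  cfg2 <- lav60_config(25L)
  cfg2$read_len <- 300L
  reg <- make_region(lav60_config(25L))
  expect_error(make_allele_and_reads(reg, config = cfg2),
               class = "lavrec_generation_error")
  cfg3 <- lav60_config(26L)
  expect_error(make_panel_and_calls(make_region(cfg3),
                                    identity_painting(100000L),
                                    n_amplicons = 10L, spacing = 50000L,
                                    config = cfg3),
               class = "lavrec_generation_error")
})

test_that("identity event list gives single-location reads and all-present panel", {
  cfg <- lav60_config(27L)
  reg <- make_region(cfg)
  sim0 <- make_allele_and_reads(reg, events = list(), config = cfg)
  expect_equal(nrow(sim0$junctions), 0L)
  up <- interpret_walk(sim0$reads[["walk_up"]], reg$seq)
  dn <- interpret_walk(sim0$reads[["walk_down"]], reg$seq)
  expect_equal(nrow(up), 1L)
  expect_equal(nrow(dn), 1L)
  expect_equal(dn$strand, "-")
  pan <- make_panel_and_calls(reg, sim0$painting, config = cfg)
  expect_true(all(pan$mut_calls == "present"))
})

test_that("zero effect sizes and zero noise collapse phenotypes within sex", {
  cfg <- lav60_config(28L)
  pc <- cfg$pheno
  pc$growth_mean$lav <- pc$growth_mean$wt
  pc$family_sd[] <- 0; pc$resid_sd[] <- 0; pc$measurement_sd <- 0
  pc$bw_test_sd <- 0; pc$bwg_sd[] <- 0; pc$em_sd <- 0
  pc$bwg_mean[] <- mean(pc$bwg_mean); pc$bw_test_mean[] <- mean(pc$bw_test_mean)
  pc$fi_resid$lav[] <- c(0, 0); pc$fi_resid$wt[] <- c(0, 0)
  pc$temp_sd <- 0; pc$temp_family_sd <- 0
  pc$temp_mean[] <- mean(pc$temp_mean)
  pc$bw6mo_sd <- 0; pc$bw6mo_mean[] <- mean(pc$bw6mo_mean)
  cfg$pheno <- pc
  ph <- make_phenotypes(cfg)
  b <- ph$birds[ph$birds$on_feed_test, ]
  for (sx in c("F", "M")) {
    sub <- b[b$sex == sx, ]
    expect_equal(length(unique(round(sub$fi, 9))), 1L)
    expect_equal(length(unique(round(sub$bw_d63, 9))), 1L)
  }
})

test_that("phenotype cohort structure matches the printed tables", {
  cfg <- lav60_config(29L)
  ph <- make_phenotypes(cfg)
  b <- ph$birds
  expect_equal(nrow(b), 125L)
  expect_equal(unname(table(b$genotype)[c("lav", "wt")]), c(59L, 66L),
               ignore_attr = TRUE)
  ft <- b[b$on_feed_test, ]
  expect_equal(unname(table(ft$genotype)[c("lav", "wt")]), c(51L, 41L),
               ignore_attr = TRUE)
  expect_true(all(is.na(b$em[b$sex == "M"])))
  expect_true(all(!is.na(ft$em[ft$sex == "F"])))
  # lavender asymptote mean generated below wild-type
  expect_lt(mean(ph$growth_true$A[b$genotype == "lav"]),
            mean(ph$growth_true$A[b$genotype == "wt"]))
})
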
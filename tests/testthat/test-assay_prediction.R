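test_that("in-silico PCR agrees with a direct sequence-scan oracle on wild type", {
  fx <- lav60_fixture()
  primers <- rbind(lav60_genotyping_primers(fx$reg),
                   primer_table("probe_F", 25000L, 25020L, "+"),
                   primer_table("probe_R", 25380L, 25400L, "-"),
                   primer_table("far_R", 31000L, 31020L, "-"))
  wtp <- identity_painting(fx$reg$region)
  got <- insilico_pcr(wtp, primers)
  want <- oracle_pcr(fx$reg$seq, fx$reg$seq, primers)
  key <- function(d) sort(paste(d$fwd, d$rev, d$size))
  expect_equal(key(got), key(want))
  # facing-outward and same-strand pairs give no product
  out <- insilico_pcr(wtp, primer_table(c("a", "b"), c(100L, 500L),
                                        c(120L, 520L), c("-", "+")))
  expect_equal(nrow(out), 0L)
})

test_that("the three-primer genotyping test gives the printed band sizes", {
  fx <- lav60_fixture()
  gp <- lav60_genotyping_primers(fx$reg)
  wtp <- identity_painting(fx$reg$region)
  wt_prod <- insilico_pcr(wtp, gp)
  expect_equal(nrow(wt_prod), 1L)
  expect_equal(wt_prod$size, 423L)
  expect_equal(c(wt_prod$fwd, wt_prod$rev), c("Gen_F", "Gen_wt_R"))
  lav_prod <- insilico_pcr(fx$sim$painting, gp)
  expect_equal(nrow(lav_prod), 1L)
  expect_equal(lav_prod$size, 630L)
  expect_equal(c(lav_prod$fwd, lav_prod$rev), c("Gen_F", "Gen_lav_R"))
  expect_true(lav_prod$spans_junction)
  expect_true("Gen_wt_R" %in% attr(lav_prod, "unbindable"))
  # genotype calls from the band patterns of the three diploid states
  expected <- c(wt_size = 423, lav_size = 630)
  expect_equal(call_genotype(wt_prod$size, expected), "+/+")
  expect_equal(call_genotype(lav_prod$size, expected), "lav/lav")
  expect_equal(call_genotype(c(wt_prod$size, lav_prod$size), expected), "lav/+")
  expect_equal(call_genotype(numeric(0), expected), "no-call")
  expect_error(call_genotype(423, c(wt_size = 423, lav_size = 440)),
               class = "lavrec_configuration_error")
})

test_that("consequence annotation matches the printed gene fates", {
  fx <- lav60_fixture()
  cons <- annotate_consequences(fx$reg$region, fx$sim$painting)
  expect_equal(cons$MLPH$status, "truncated")
  expect_equal(cons$MLPH$retained_exons, 1:9)
  expect_equal(cons$PRLH$status, "deleted")
  expect_length(cons$PRLH$retained_exons, 0L)
  expect_false(cons$RAB17$status == "intact")
  expect_false(cons$LRRFIP1$status == "deleted")
  # identity painting: everything intact
  cons0 <- annotate_consequences(fx$reg$region, identity_painting(fx$reg$region))
  expect_true(all(vapply(cons0, `[[`, character(1), "status") == "intact"))
  # deleting one internal exon of a toy gene truncates it
  rg <- toy_region()
  p <- apply_event(identity_painting(rg), Event("deletion", 300L, 400L))
  tc <- annotate_consequences(rg, p)$TOY
  expect_equal(tc$status, "truncated")
  expect_equal(tc$retained_exons, c(1L, 3L))
})

test_that("RT-PCR predictions reproduce the printed exon-pair outcomes", {
  fx <- lav60_fixture()
  cons <- annotate_consequences(fx$reg$region, fx$sim$painting)
  mlph <- fx$reg$region$genes$MLPH
  pairs <- rbind(c(1, 2), c(5, 7), c(1, 7), c(8, 10), c(1, 10), c(5, 10))
  res <- predict_rt_pcr(mlph, cons$MLPH, pairs)
  expect_equal(res$outcome,
               c("amplify", "amplify", "amplify", "fail", "fail", "fail"))
  rab <- fx$reg$region$genes$RAB17
  expect_equal(predict_rt_pcr(rab, cons$RAB17, rbind(c(1, 4), c(3, 4)))$outcome,
               c("fail", "fail"))
  # wild-type consequence: every pair amplifies
  cons0 <- annotate_consequences(fx$reg$region, identity_painting(fx$reg$region))
  expect_true(all(predict_rt_pcr(mlph, cons0$MLPH, pairs)$outcome == "amplify"))
  expect_error(predict_rt_pcr(mlph, cons$MLPH, rbind(c(1, 11))),
               class = "lavrec_validation_error")
})

test_that("panel calls close the loop with screening for generated scenarios", {
  fx <- lav60_fixture()
  set.seed(9)
  for (trial in 1:5) {
    sc <- random_scenario(trial + 300L, region_len = fx$reg$region$length_bp)
    pan <- make_panel_and_calls(fx$reg, sc$painting, n_amplicons = 12L,
                                spacing = 5000L, config = fx$cfg)
    expect_true(all(pan$wt_calls == "present"))
    # calls must be reproducible from insilico_pcr directly
    primers <- primer_table(
      name = c(paste0(pan$panel$name, "_F"), paste0(pan$panel$name, "_R")),
      wt_start = c(pan$panel$fwd_pos, pan$panel$rev_pos - 20L),
      wt_end = c(pan$panel$fwd_pos + 20L, pan$panel$rev_pos),
      strand = rep(c("+", "-"), each = nrow(pan$panel)))
    prods <- insilico_pcr(sc$painting, primers, fx$cfg$max_product)
    for (nm in pan$panel$name) {
      present <- any((prods$fwd == paste0(nm, "_F") &
                      prods$rev == paste0(nm, "_R")) |
                     (prods$fwd == paste0(nm, "_R") &
                      prods$rev == paste0(nm, "_F")))
      expect_equal(unname(pan$mut_calls[nm]),
                   ifelse(present, "present", "absent"))
    }
  }
})
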
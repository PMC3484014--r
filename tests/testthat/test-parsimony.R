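test_that("solve_coordinates handles pinned, printed and contradictory systems", {
  # single constraint with a pinned breakpoint
  one <- list(frag = BreakpointConstraint("distance", c("BP5", "BP6"), 246))
  sol <- solve_coordinates(one, fixed = c(BP5 = 0L))
  expect_true(sol$feasible)
  expect_equal(unname(sol$positions[c("BP5", "BP6")]), c(0L, 246L))
  # full printed set: hard constraints exactly satisfied, soft ones reported
  sol6 <- solve_coordinates(lav60_constraints())
  expect_true(sol6$feasible)
  expect_equal(sol6$frame, "sequential")
  expect_equal(unname(sol6$positions),
               c(0L, 13800L, 27754L, 56208L, 58408L, 58654L))
  hard <- sol6$residuals[sol6$residuals$hard, ]
  expect_true(all(abs(hard$residual) <= hard$tolerance))
  # contradictory exact constraints -> infeasibility naming both, no exception
  contra <- list(a = BreakpointConstraint("distance", c("BP1", "BP2"), 100),
                 b = BreakpointConstraint("distance", c("BP1", "BP2"), 200))
  bad <- solve_coordinates(contra)
  expect_false(bad$feasible)
  expect_setequal(bad$conflict, c("a", "b"))
})

test_that("solved coordinates reproduce every printed length by forward simulation", {
  sol <- solve_coordinates(lav60_constraints())
  bp <- sol$positions + 500L  # flank so the deletion scar is internal
  region <- RegionMap(bp[["BP6"]] + 1000L, list(), bp)
  evs <- events_from_wt(region, lav_event_template())
  sim <- apply_scenario(region, evs)
  lens <- vapply(evs, function(e) e$end - e$start, integer(1))
  expect_equal(lens, c(30900L, 16400L, 16000L))
  expect_equal(bp[["BP6"]] - bp[["BP5"]], 246L)
  expect_equal(bp[["BP5"]] - bp[["BP4"]], 2200L)
  expect_equal(nrow(sim$junctions), 4L)
})

test_that("enumeration is exact on trivial targets", {
  L <- 5000L
  expect_length(enumerate_scenarios(L, identity_painting(L))[[1]]$events, 0L)
  inv <- apply_event(identity_painting(L), Event("inversion", 1000L, 2000L))
  res <- enumerate_scenarios(L, inv)
  expect_equal(attr(res, "bound_exceeded"), FALSE)
  expect_length(res, 1L)
  ev <- res[[1]]$events[[1]]
  expect_equal(c(ev$kind, ev$start, ev$end), c("inversion", "1000", "2000"))
})

test_that("the LAV60 target needs exactly three events and includes the printed scenario", {
  fx <- lav60_fixture()
  res <- enumerate_scenarios(fx$reg$region, fx$sim$painting, max_events = 3L)
  expect_false(attr(res, "bound_exceeded"))
  expect_true(all(vapply(res, `[[`, integer(1), "score") == 3L))
  hit <- vapply(res, function(s)
    same_trajectory(fx$reg$region, s$events, fx$sim$events), logical(1))
  expect_true(any(hit))
  # every returned scenario reproduces the target painting exactly
  for (s in res) {
    p <- apply_scenario(fx$reg$region, s$events)$painting
    expect_equal(as.data.frame(p)[c("wt_start", "wt_end", "orient")],
                 as.data.frame(fx$sim$painting)[c("wt_start", "wt_end", "orient")],
                 ignore_attr = TRUE)
  }
  # exhaustive search one level below finds nothing
  res2 <- enumerate_scenarios(fx$reg$region, fx$sim$painting, max_events = 2L)
  expect_true(attr(res2, "bound_exceeded"))
  expect_length(res2, 0L)
})

test_that("simulate -> reconstruct round-trips over random scenarios", {
  n_matched <- 0L
  for (seed in 1:40) {
    sc <- random_scenario(seed)
    res <- enumerate_scenarios(sc$region_len, sc$painting,
                               max_events = length(sc$events))
    expect_false(attr(res, "bound_exceeded"))
    minlen <- res[[1]]$score
    expect_lte(minlen, length(sc$events))
    for (s in res) {
      p <- apply_scenario(sc$region_len, s$events)$painting
      expect_equal(as.data.frame(p)[c("wt_start", "wt_end", "orient")],
                   as.data.frame(sc$painting)[c("wt_start", "wt_end", "orient")],
                   ignore_attr = TRUE)
    }
    if (minlen == length(sc$events)) {
      hit <- vapply(res, function(s)
        same_trajectory(sc$region_len, s$events, sc$events), logical(1))
      expect_true(any(hit))
      n_matched <- n_matched + 1L
    }
    # minimality: exhaustive search one level below is empty
    if (minlen > 0L) {
      below <- enumerate_scenarios(sc$region_len, sc$painting,
                                   max_events = minlen - 1L)
      expect_true(attr(below, "bound_exceeded"))
    }
  }
  expect_gt(n_matched, 20L)  # most random scenarios are already minimal
})

test_that("scenario reports annotate the gene content of each step", {
  fx <- lav60_fixture()
  sol <- solve_coordinates(lav60_constraints())
  rep0 <- report_scenario(list(events = list()), fx$reg$region)
  expect_equal(nrow(rep0$steps), 0L)
  rep3 <- report_scenario(list(events = fx$sim$events), fx$reg$region, sol)
  expect_equal(rep3$steps$kind, c("inversion", "inversion", "deletion"))
  expect_equal(rep3$steps$length_bp, c(30900L, 16400L, 16000L))
  # step 1 contains LRRFIP1 exon 1; step 3 removes PRLH entirely, most of
  # RAB17 and MLPH exon 10
  expect_true(1L %in% rep3$gene_effects[[1]]$LRRFIP1)
  expect_setequal(rep3$gene_effects[[3]]$PRLH, 1:3)
  expect_setequal(rep3$gene_effects[[3]]$RAB17, 2:4)
  expect_equal(rep3$gene_effects[[3]]$MLPH, 10L)
  expect_true(any(grepl("deletion", rep3$text)))
})
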
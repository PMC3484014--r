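test_that("screening localises the missing block and both breakpoint windows", {
  fx <- lav60_fixture()
  pan <- make_panel_and_calls(fx$reg, fx$sim$painting, config = fx$cfg)
  expect_equal(unname(pan$wt_calls), rep("present", 16L))
  expect_equal(unname(pan$mut_calls),
               rep(c("present", "absent", "present"), c(4L, 8L, 4L)))
  sc <- screen(pan$panel, pan$wt_calls, pan$mut_calls)
  expect_equal(nrow(sc$blocks), 1L)
  expect_equal(sc$blocks$n_amplicons, 8L)
  expect_equal(c(sc$blocks$first, sc$blocks$last), c("E", "L"))
  expect_equal(nrow(sc$windows), 2L)
  expect_true(all(sc$windows$width < 1000L))
  bp <- fx$reg$region$breakpoints
  expect_true(bp[["BP1"]] >= sc$windows$lo[1] && bp[["BP1"]] < sc$windows$hi[1])
  expect_true(bp[["BP2"]] >= sc$windows$lo[2] && bp[["BP2"]] < sc$windows$hi[2])
})

test_that("screen handles edge cases: all present, split runs, bad reference", {
  panel <- data.frame(name = LETTERS[1:6],
                      fwd_pos = seq(0L, 5000L, 1000L),
                      rev_pos = seq(600L, 5600L, 1000L))
  ok <- setNames(rep("present", 6L), panel$name)
  res <- screen(panel, ok, ok)
  expect_equal(nrow(res$blocks), 0L)
  expect_equal(nrow(res$windows), 0L)
  # two separated absent runs -> two blocks, four windows (hand enumeration)
  mut <- ok; mut[c("B", "E")] <- "absent"
  res2 <- screen(panel, ok, mut)
  expect_equal(nrow(res2$blocks), 2L)
  expect_equal(nrow(res2$windows), 4L)
  expect_equal(res2$windows$side, rep(c("proximal", "distal"), 2L))
  expect_equal(res2$windows$lo, c(600L, 1600L, 3600L, 4600L))
  expect_equal(res2$windows$hi, c(1000L, 2000L, 4000L, 5000L))
  bad_ref <- ok; bad_ref["C"] <- "absent"
  expect_error(screen(panel, bad_ref, mut),
               class = "lavrec_inconsistent_reference_error")
})

test_that("screen outer windows contain the deletion breakpoints (random panels)", {
  for (seed in 1:15) {
    set.seed(seed)
    L <- 30000L
    a <- sample(3000:12000, 1); b <- a + sample(2000:9000, 1)
    painting <- apply_event(identity_painting(L), Event("deletion", a, b))
    n_amp <- sample(8:14, 1)
    fwd <- round(seq(200, L - 900, length.out = n_amp))
    panel <- data.frame(name = LETTERS[seq_len(n_amp)], fwd_pos = fwd,
                        rev_pos = fwd + 600L)
    primers <- primer_table(
      name = c(paste0(panel$name, "_F"), paste0(panel$name, "_R")),
      wt_start = c(panel$fwd_pos, panel$rev_pos - 20L),
      wt_end = c(panel$fwd_pos + 20L, panel$rev_pos),
      strand = rep(c("+", "-"), each = n_amp))
    call_on <- function(pn) {
      prods <- insilico_pcr(pn, primers)
      pres <- vapply(panel$name, function(nm)
        any(prods$fwd == paste0(nm, "_F") & prods$rev == paste0(nm, "_R")),
        logical(1))
      setNames(ifelse(pres, "present", "absent"), panel$name)
    }
    res <- screen(panel, call_on(identity_painting(L)), call_on(painting))
    for (k in seq_len(nrow(res$windows))) {
      w <- res$windows[k, ]
      expect_true((a >= w$lo_outer && a <= w$hi_outer) ||
                  (b >= w$lo_outer && b <= w$hi_outer))
    }
  }
})

test_that("walk reads are interpreted as the printed match structures", {
  fx <- lav60_fixture()
  up <- interpret_walk(fx$sim$reads[["walk_up"]], fx$reg$seq,
                       fx$cfg$min_anchor, fx$cfg$merge_tol)
  expect_equal(nrow(up), 2L)
  expect_equal(up$strand, c("+", "-"))
  bp <- fx$reg$region$breakpoints
  expect_equal(c(up$wt_start[1], up$wt_end[1]), unname(bp[c("BP5", "BP6")]))
  expect_equal(up$wt_end[2], bp[["BP3"]])
  dn <- interpret_walk(fx$sim$reads[["walk_down"]], fx$reg$seq,
                       fx$cfg$min_anchor, fx$cfg$merge_tol)
  expect_equal(nrow(dn), 3L)
  expect_equal(dn$length[2], 246L)
  expect_equal(dn$strand[2], "-")
  # a read wholly inside the wild-type region maps to one plus-strand location
  plain <- as.character(Biostrings::subseq(fx$reg$seq, 1001L, 1400L))
  one <- interpret_walk(plain, fx$reg$seq)
  expect_equal(nrow(one), 1L)
  expect_equal(one$strand, "+")
  expect_equal(c(one$wt_start, one$wt_end), c(1000L, 1400L))
  expect_error(interpret_walk(paste(rep("N", 60L), collapse = ""), fx$reg$seq),
               class = "lavrec_unmappable_error")
})

test_that("walk interpretation recovers the junction-split structure of random reads", {
  fx <- lav60_fixture()
  p <- fx$sim$painting
  derived <- fx$sim$derived_seq
  n <- painting_length(p)
  set.seed(42)
  for (trial in 1:20) {
    a <- sample.int(n - 900L, 1) - 1L
    read <- as.character(Biostrings::subseq(derived, a + 1L, a + 900L))
    wm <- interpret_walk(read, fx$reg$seq)
    # oracle: expected blocks from the generating painting via lift_over
    d <- a
    exp_blocks <- 0L
    while (d < a + 900L) {
      off <- cumsum(c(0L, p$wt_end - p$wt_start))
      seg <- findInterval(d, off, rightmost.closed = FALSE)
      seg_end <- off[seg + 1L]
      take <- min(seg_end, a + 900L) - d
      if (take >= 20L) exp_blocks <- exp_blocks + 1L
      d <- d + take
    }
    expect_equal(nrow(wm), exp_blocks)
    # every matched base agrees with lift_over of the generating painting
    for (k in seq_len(nrow(wm))) {
      q0 <- wm$q_start[k]
      lo <- lift_over(p, a + q0)
      if (wm$strand[k] == "+") expect_equal(lo$wt_pos, wm$wt_start[k])
      else expect_equal(lo$wt_pos, wm$wt_end[k] - 1L)
      expect_equal(lo$strand, ifelse(wm$strand[k] == "+", 1L, -1L))
    }
  }
})

test_that("adjacencies assemble, deduplicate and flag corroboration", {
  fx <- lav60_fixture()
  up <- interpret_walk(fx$sim$reads[["walk_up"]], fx$reg$seq)
  dn <- interpret_walk(fx$sim$reads[["walk_down"]], fx$reg$seq)
  pan <- make_panel_and_calls(fx$reg, fx$sim$painting, config = fx$cfg)
  wins <- screen(pan$panel, pan$wt_calls, pan$mut_calls)$windows
  adj <- assemble_adjacencies(list(up, dn), wins)
  # both reads cross R2: collapsed into one observation with double support
  expect_true(any(adj$support == 2L))
  truth <- junctions_as_adjacencies(fx$sim$junctions)
  for (i in seq_len(nrow(adj))) {
    hit <- truth[truth$left_pos == adj$left_pos[i] &
                 truth$right_pos == adj$right_pos[i] &
                 truth$left_strand == adj$left_strand[i] &
                 truth$right_strand == adj$right_strand[i], ]
    expect_equal(nrow(hit), 1L)
  }
  # single two-location match -> one adjacency
  single <- assemble_adjacencies(list(up))
  expect_equal(nrow(single), 1L)
  expect_error(assemble_adjacencies(list()), class = "lavrec_validation_error")
})
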
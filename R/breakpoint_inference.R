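# Two evidence channels for breakpoint discovery: presence/absence screening
# of a tiled amplicon panel, and interpretation of junction-spanning
# chromosome-walk reads by greedy maximal exact matching (synthetic reads are
# error-free, so matching is exact; alignment with mismatches is out of scope).

#' Tiled-amplicon deletion screening
#'
#' Maximal runs of amplicons absent in the mutant (but present in the
#' reference) become missing blocks; each block is flanked by two breakpoint
#' candidate windows: from the end of the last present amplicon to the start of
#' the first absent one, and symmetrically on the distal side.
#'
#' @param panel Data frame with columns `name`, `fwd_pos`, `rev_pos`
#'   (wild-type product interval, 0-based half-open; `fwd_pos < rev_pos`).
#' @param wt_calls,mut_calls Named character vectors (`"present"`/`"absent"`)
#'   with one call per amplicon.
#' @return List with `blocks` (data frame of absent runs) and `windows`
#'   (data frame `lo`, `hi`, `width`, `side`).
#' @export
screen <- function(panel, wt_calls, mut_calls) {
  if (any(duplicated(panel$name)))
    lavrec_error("amplicon names must be unique", "lavrec_validation_error")
  if (any(panel$rev_pos <= panel$fwd_pos))
    lavrec_error("amplicons need fwd_pos < rev_pos", "lavrec_validation_error")
  if (!all(panel$name %in% names(wt_calls)) || !all(panel$name %in% names(mut_calls)))
    lavrec_error("every amplicon needs a call in both samples",
                 "lavrec_validation_error")
  if (any(wt_calls[panel$name] != "present"))
    lavrec_error(sprintf("amplicon(s) absent in reference sample: %s",
                         paste(panel$name[wt_calls[panel$name] != "present"],
                               collapse = ", ")),
                 "lavrec_inconsistent_reference_error")
  panel <- panel[order(panel$fwd_pos), , drop = FALSE]
  absent <- mut_calls[panel$name] == "absent"
  blocks <- data.frame(first = character(0), last = character(0),
                       n_amplicons = integer(0))
  windows <- data.frame(lo = integer(0), hi = integer(0), width = integer(0),
                        side = character(0), block = integer(0),
                        lo_outer = integer(0), hi_outer = integer(0))
  if (any(absent)) {
    r <- rle(absent)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    for (bi in seq_along(runs)) {
      i0 <- starts[runs[bi]]; i1 <- ends[runs[bi]]
      blocks <- rbind(blocks, data.frame(first = panel$name[i0],
                                         last = panel$name[i1],
                                         n_amplicons = i1 - i0 + 1L))
      # inner windows follow the flanking-amplicon gap; the outer bound
      # extends to the far end of the absent amplicon, which always contains
      # the true breakpoint under the footprint-destruction calling model
      if (i0 > 1L) {
        lo <- panel$rev_pos[i0 - 1L]; hi <- panel$fwd_pos[i0]
        windows <- rbind(windows,
                        data.frame(lo = lo, hi = hi, width = hi - lo,
                                   side = "proximal", block = bi,
                                   lo_outer = lo, hi_outer = panel$rev_pos[i0]))
      }
      if (i1 < nrow(panel)) {
        lo <- panel$rev_pos[i1]; hi <- panel$fwd_pos[i1 + 1L]
        windows <- rbind(windows,
                        data.frame(lo = lo, hi = hi, width = hi - lo,
                                   side = "distal", block = bi,
                                   lo_outer = panel$fwd_pos[i1], hi_outer = hi))
      }
    }
  }
  list(blocks = blocks, windows = windows)
}

#' Interpret a chromosome-walk read against the wild-type region
#'
#' Greedy maximal exact matching from the read's 5' end: at each unmatched
#' offset the longest exact occurrence in the region (either strand) is taken,
#' provided it reaches `min_anchor`; shorter stretches are skipped.
#' Successive matched blocks that are wild-type-contiguous on the same strand
#' (gap at most `merge_tol`) are merged.
#'
#' @param read Character or `DNAString` read sequence.
#' @param region_seq Character or `DNAString` wild-type region sequence.
#' @param min_anchor Minimum reportable match length (default 20 bp).
#' @param merge_tol Maximum wild-type gap bridged when merging co-linear
#'   blocks (default 5 bp).
#' @return A `WalkMatch` data frame: `wt_start`, `wt_end`, `strand`
#'   (`"+"`/`"-"`), `q_start` (0-based read offset), `length`, in read order.
#' @export
interpret_walk <- function(read, region_seq, min_anchor = 20L, merge_tol = 5L) {
  read <- as.character(read); region_chr <- as.character(region_seq)
  if (nchar(read) < 2L * min_anchor)
    lavrec_error("read shorter than 2 * min_anchor", "lavrec_validation_error")
  rd <- strsplit(read, "")[[1]]
  rg <- strsplit(region_chr, "")[[1]]
  region_dna <- Biostrings::DNAString(region_chr)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  n <- length(rd); L <- length(rg)
  blocks <- list()
  o <- 0L
  while (n - o >= min_anchor) {
    seed <- substr(read, o + 1L, o + min_anchor)
    fh <- BiocGenerics::start(Biostrings::matchPattern(seed, region_dna)) - 1L
    rh <- BiocGenerics::start(Biostrings::matchPattern(
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seed))),
      region_dna)) - 1L
    best <- NULL
    for (s0 in fh) {
      m <- min(n - o, L - s0)
      cmpv <- rd[(o + 1L):(o + m)] != rg[(s0 + 1L):(s0 + m)]
      l <- if (any(cmpv)) which(cmpv)[1] - 1L else m
      if (is.null(best) || l > best$len)
        best <- list(len = l, wt_start = s0, wt_end = s0 + l, strand = "+")
    }
    for (s0 in rh) {
      b <- s0 + min_anchor  # wt end boundary of the seed's reverse image
      m <- min(n - o, b)
      cmpv <- rd[(o + 1L):(o + m)] != comp[rg[b:(b - m + 1L)]]
      l <- if (any(cmpv)) which(cmpv)[1] - 1L else m
      if (is.null(best) || l > best$len)
        best <- list(len = l, wt_start = b - l, wt_end = b, strand = "-")
    }
    if (is.null(best) || best$len < min_anchor) {
      o <- o + 1L  # seek the first/next anchor
      next
    }
    blocks[[length(blocks) + 1L]] <-
      data.frame(wt_start = best$wt_start, wt_end = best$wt_end,
                 strand = best$strand, q_start = o, length = best$len)
    o <- o + best$len
  }
  if (!length(blocks))
    lavrec_error(sprintf("no anchor of length %d found in read", min_anchor),
                 "lavrec_unmappable_error")
  wm <- do.call(rbind, blocks)
  # merge wild-type-contiguous same-strand neighbours
  keep <- rep(TRUE, nrow(wm))
  i <- 1L
  for (j in seq_len(nrow(wm))[-1]) {
    gap <- if (wm$strand[i] == "+") wm$wt_start[j] - wm$wt_end[i]
           else wm$wt_start[i] - wm$wt_end[j]
    if (wm$strand[i] == wm$strand[j] && gap >= 0L && gap <= merge_tol) {
      wm$wt_start[i] <- min(wm$wt_start[i], wm$wt_start[j])
      wm$wt_end[i] <- max(wm$wt_end[i], wm$wt_end[j])
      wm$length[i] <- wm$length[i] + wm$length[j]
      keep[j] <- FALSE
    } else i <- j
  }
  wm <- wm[keep, , drop = FALSE]
  rownames(wm) <- NULL
  class(wm) <- c("WalkMatch", "data.frame")
  wm
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

# canonical form of a strand-aware adjacency: an adjacency and its
# read-from-the-other-side reverse are the same observation
canonical_adjacency <- function(lp, ls, rp, rs) {
  fwd <- c(lp, ls, rp, rs)
  rev <- c(rp, flip_strand(rs), lp, flip_strand(ls))
  if (order_adj(fwd, rev)) fwd else rev
}

order_adj <- function(a, b) {
  ka <- sprintf("%010d%s%010d%s", as.integer(a[1]), a[2], as.integer(a[3]), a[4])
  kb <- sprintf("%010d%s%010d%s", as.integer(b[1]), b[2], as.integer(b[3]), b[4])
  ka <= kb
}

#' Assemble novel-adjacency observations from walk matches
#'
#' Each consecutive pair of matched locations in a read becomes one observed
#' breakend pair. Observations of the same junction from either direction are
#' collapsed (breakends compared within `tol` bp); adjacencies whose breakends
#' fall inside screening windows are flagged as corroborated.
#'
#' @param matches List of `WalkMatch` data frames (see [interpret_walk()]).
#' @param windows Optional screening windows from [screen()].
#' @param tol Breakend-position tolerance in bp when collapsing duplicates.
#' @return Data frame: `left_pos`, `left_strand`, `right_pos`, `right_strand`,
#'   `support`, `corroborated`.
#' @export
assemble_adjacencies <- function(matches, windows = NULL, tol = 5L) {
  if (!length(matches))
    lavrec_error("at least one WalkMatch is required", "lavrec_validation_error")
  if (is.data.frame(matches)) matches <- list(matches)
  obs <- list()
  for (mi in seq_along(matches)) {
    wm <- matches[[mi]]
    if (nrow(wm) < 2L) next
    for (i in seq_len(nrow(wm) - 1L)) {
      lp <- if (wm$strand[i] == "+") wm$wt_end[i] else wm$wt_start[i]
      rp <- if (wm$strand[i + 1L] == "+") wm$wt_start[i + 1L] else wm$wt_end[i + 1L]
      cf <- canonical_adjacency(lp, wm$strand[i], rp, wm$strand[i + 1L])
      obs[[length(obs) + 1L]] <-
        data.frame(left_pos = as.integer(cf[1]), left_strand = cf[2],
                   right_pos = as.integer(cf[3]), right_strand = cf[4],
                   source = mi)
    }
  }
  if (!length(obs))
    return(data.frame(left_pos = integer(0), left_strand = character(0),
                      right_pos = integer(0), right_strand = character(0),
                      support = integer(0), corroborated = logical(0)))
  ob <- do.call(rbind, obs)
  out <- NULL
  srcs <- list()
  for (i in seq_len(nrow(ob))) {
    hit <- NA_integer_
    if (!is.null(out)) {
      same <- which(abs(out$left_pos - ob$left_pos[i]) <= tol &
                    abs(out$right_pos - ob$right_pos[i]) <= tol)
      for (j in same) {
        if (out$left_strand[j] == ob$left_strand[i] &&
            out$right_strand[j] == ob$right_strand[i]) { hit <- j; break }
        lavrec_error(sprintf(
          "contradictory strand assignments for breakend near %d (reads %s and %s)",
          ob$left_pos[i], paste(srcs[[j]], collapse = ","), ob$source[i]),
          "lavrec_conflict_error")
      }
    }
    if (!is.na(hit)) {
      out$support[hit] <- out$support[hit] + 1L
      srcs[[hit]] <- c(srcs[[hit]], ob$source[i])
    } else {
      row <- ob[i, c("left_pos", "left_strand", "right_pos", "right_strand")]
      row$support <- 1L
      out <- if (is.null(out)) row else rbind(out, row)
      srcs[[nrow(out)]] <- ob$source[i]
    }
  }
  in_window <- function(p) {
    if (is.null(windows) || !nrow(windows)) return(FALSE)
    any(p >= windows$lo & p <= windows$hi)
  }
  out$corroborated <- vapply(seq_len(nrow(out)), function(i)
    in_window(out$left_pos[i]) || in_window(out$right_pos[i]), logical(1))
  rownames(out) <- NULL
  out
}

#' Canonical adjacency set of a painting's junctions
#'
#' Utility to compare simulated junctions with observed adjacencies.
#' @param junctions Output of [junctions_of()].
#' @return Data frame in the same canonical form as [assemble_adjacencies()].
#' @export
junctions_as_adjacencies <- function(junctions) {
  if (!nrow(junctions))
    return(data.frame(left_pos = integer(0), left_strand = character(0),
                      right_pos = integer(0), right_strand = character(0)))
  rows <- lapply(seq_len(nrow(junctions)), function(i) {
    cf <- canonical_adjacency(junctions$left_pos[i], junctions$left_strand[i],
                              junctions$right_pos[i], junctions$right_strand[i])
    data.frame(left_pos = as.integer(cf[1]), left_strand = cf[2],
               right_pos = as.integer(cf[3]), right_strand = cf[4])
  })
  out <- do.call(rbind, rows)
  out[order(out$left_pos, out$right_pos), , drop = FALSE]
}
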
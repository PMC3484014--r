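# Forward simulation of ordered inversion/deletion events on a segment
# painting: a derived allele represented as an ordered list of strand-signed
# wild-type intervals. Orientation -1 means the segment reads as the reverse
# complement of the wild-type plus strand. Events are specified in
# CURRENT-allele coordinates and applied sequentially.

#' Strand-signed segment painting
#'
#' @param wt_start,wt_end Integer vectors of 0-based half-open wild-type
#'   intervals.
#' @param orient Integer vector of +1/-1 (or character "+"/"-").
#' @return A `SegmentPainting` data frame with attribute `total_length`.
#' @export
SegmentPainting <- function(wt_start, wt_end, orient) {
  if (is.character(orient)) orient <- ifelse(orient == "+", 1L, -1L)
  df <- data.frame(wt_start = as.integer(wt_start), wt_end = as.integer(wt_end),
                   orient = as.integer(orient))
  if (any(df$wt_end <= df$wt_start))
    lavrec_error("painting segments must be non-empty", "lavrec_validation_error")
  if (any(!df$orient %in% c(-1L, 1L)))
    lavrec_error("orient must be +1 or -1", "lavrec_validation_error")
  df <- canonicalize_painting(df)
  df
}

#' Identity painting for a region
#' @param region A [RegionMap] or an integer length.
#' @return Painting of the unrearranged allele.
#' @export
identity_painting <- function(region) {
  len <- if (inherits(region, "RegionMap")) region$length_bp else as.integer(region)
  SegmentPainting(0L, len, 1L)
}

# merge adjacent segments that are wild-type-contiguous with equal orientation
canonicalize_painting <- function(df) {
  if (nrow(df) > 1) {
    keep <- rep(TRUE, nrow(df))
    i <- 1L
    for (j in 2L:nrow(df)) {
      contig <- df$orient[i] == df$orient[j] &&
        ((df$orient[i] == 1L && df$wt_end[i] == df$wt_start[j]) ||
         (df$orient[i] == -1L && df$wt_start[i] == df$wt_end[j]))
      if (contig) {
        df$wt_start[i] <- min(df$wt_start[i], df$wt_start[j])
        df$wt_end[i] <- max(df$wt_end[i], df$wt_end[j])
        keep[j] <- FALSE
      } else i <- j
    }
    df <- df[keep, , drop = FALSE]
    rownames(df) <- NULL
  }
  attr(df, "total_length") <- sum(df$wt_end - df$wt_start)
  class(df) <- c("SegmentPainting", "data.frame")
  df
}

#' Total derived-allele length of a painting
#' @param painting A [SegmentPainting].
#' @export
painting_length <- function(painting) {
  sum(painting$wt_end - painting$wt_start)
}

#' @export
print.SegmentPainting <- function(x, ...) {
  len <- painting_length(x)
  cat(sprintf("SegmentPainting: %d segment(s), derived length %d bp\n", nrow(x), len))
  off <- c(0L, cumsum(x$wt_end - x$wt_start))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  [%7d) wt [%d, %d) %s\n", off[i], x$wt_start[i], x$wt_end[i],
                ifelse(x$orient[i] == 1L, "+", "-")))
  invisible(x)
}

#' A single inversion or deletion event
#'
#' @param kind `"inversion"` or `"deletion"`.
#' @param start,end Half-open interval in CURRENT-allele coordinates.
#' @param label Optional text label.
#' @export
Event <- function(kind, start, end, label = "") {
  kind <- match.arg(kind, c("inversion", "deletion"))
  start <- as.integer(start); end <- as.integer(end)
  if (start < 0L || end <= start)
    lavrec_error("event interval must satisfy 0 <= start < end",
                 "lavrec_range_error")
  structure(list(kind = kind, start = start, end = end, label = label),
            class = "Event")
}

# split painting so that derived position d is a segment boundary;
# d must be within [0, total_length]
split_painting_at <- function(painting, d) {
  off <- cumsum(c(0L, painting$wt_end - painting$wt_start))
  n <- nrow(painting)
  if (d <= 0L || d >= off[n + 1L] || d %in% off) return(painting)
  i <- findInterval(d, off, rightmost.closed = FALSE)  # segment index with off[i] <= d
  a <- painting$wt_start[i]; b <- painting$wt_end[i]; o <- painting$orient[i]
  k <- d - off[i]
  if (o == 1L) {
    parts <- data.frame(wt_start = c(a, a + k), wt_end = c(a + k, b),
                        orient = c(1L, 1L))
  } else {
    parts <- data.frame(wt_start = c(b - k, a), wt_end = c(b, b - k),
                        orient = c(-1L, -1L))
  }
  out <- rbind(painting[seq_len(i - 1L), c("wt_start", "wt_end", "orient")],
               parts,
               painting[seq_len(n - i) + i, c("wt_start", "wt_end", "orient")])
  rownames(out) <- NULL
  attr(out, "total_length") <- sum(out$wt_end - out$wt_start)
  class(out) <- c("SegmentPainting", "data.frame")
  out
}

#' Apply one event to a painting
#'
#' An inversion reverses segment order and flips orientations within
#' `[start, end)`, splitting boundary segments; a deletion removes
#' `[start, end)`. The result is re-canonicalized to maximal segments.
#'
#' @param painting A [SegmentPainting].
#' @param event An [Event].
#' @return The derived [SegmentPainting].
#' @export
apply_event <- function(painting, event) {
  len <- painting_length(painting)
  if (event$start < 0L || event$end > len)
    lavrec_error(sprintf("event [%d, %d) outside current allele [0, %d)",
                         event$start, event$end, len), "lavrec_range_error")
  p <- split_painting_at(painting, event$start)
  p <- split_painting_at(p, event$end)
  off <- cumsum(c(0L, p$wt_end - p$wt_start))
  inside <- which(off[-length(off)] >= event$start & off[-1] <= event$end)
  if (event$kind == "inversion") {
    mid <- p[rev(inside), , drop = FALSE]
    mid$orient <- -mid$orient
    p[inside, ] <- mid
  } else {
    p <- p[-inside, , drop = FALSE]
  }
  rownames(p) <- NULL
  canonicalize_painting(as.data.frame(p))
}

#' Novel junctions of a painting
#'
#' Every boundary between consecutive segments of a canonical painting is a
#' novel junction (wild-type-contiguous neighbours have been merged away). A
#' breakend is a wild-type boundary position plus the strand on which the
#' derived allele leaves (left breakend) or enters (right breakend) it.
#'
#' @param painting A [SegmentPainting].
#' @param prefix Junction name prefix (`"R"` gives R1, R2, ... in derived
#'   order).
#' @return Data frame with columns `name`, `derived_pos`, `left_pos`,
#'   `left_strand`, `right_pos`, `right_strand`.
#' @export
junctions_of <- function(painting, prefix = "R") {
  n <- nrow(painting)
  if (n < 2L)
    return(data.frame(name = character(0), derived_pos = integer(0),
                      left_pos = integer(0), left_strand = character(0),
                      right_pos = integer(0), right_strand = character(0)))
  off <- cumsum(painting$wt_end - painting$wt_start)
  i <- seq_len(n - 1L)
  lp <- ifelse(painting$orient[i] == 1L, painting$wt_end[i], painting$wt_start[i])
  ls <- ifelse(painting$orient[i] == 1L, "+", "-")
  rp <- ifelse(painting$orient[i + 1L] == 1L, painting$wt_start[i + 1L],
               painting$wt_end[i + 1L])
  rs <- ifelse(painting$orient[i + 1L] == 1L, "+", "-")
  data.frame(name = paste0(prefix, i), derived_pos = off[i],
             left_pos = lp, left_strand = ls, right_pos = rp, right_strand = rs)
}

# lift a derived BOUNDARY (0..total_length) to its wild-type boundary
lift_boundary_to_wt <- function(painting, d) {
  off <- cumsum(c(0L, painting$wt_end - painting$wt_start))
  n <- nrow(painting)
  if (d < 0L || d > off[n + 1L])
    lavrec_error("boundary outside derived allele", "lavrec_range_error")
  if (d == off[n + 1L]) i <- n else i <- findInterval(d, off, rightmost.closed = FALSE)
  k <- d - off[i]
  if (painting$orient[i] == 1L) painting$wt_start[i] + k else painting$wt_end[i] - k
}

# lift a wild-type BOUNDARY into the derived allele (NA if inside deleted
# content); a boundary survives if some retained segment contains or abuts it
lift_wt_boundary <- function(painting, w) {
  off <- cumsum(c(0L, painting$wt_end - painting$wt_start))
  for (i in seq_len(nrow(painting))) {
    if (w >= painting$wt_start[i] && w <= painting$wt_end[i]) {
      k <- if (painting$orient[i] == 1L) w - painting$wt_start[i]
           else painting$wt_end[i] - w
      return(off[i] + k)
    }
  }
  NA_integer_
}

#' Lift a derived-allele position to wild-type coordinates
#'
#' @param painting A [SegmentPainting].
#' @param derived_position 0-based base position in the derived allele.
#' @return List with `wt_pos` and `strand` (+1 if the base reads as the
#'   wild-type plus strand, -1 if reverse-complemented).
#' @export
lift_over <- function(painting, derived_position) {
  d <- as.integer(derived_position)
  off <- cumsum(c(0L, painting$wt_end - painting$wt_start))
  n <- nrow(painting)
  if (d < 0L || d >= off[n + 1L])
    lavrec_error(sprintf("derived position %d outside [0, %d)", d, off[n + 1L]),
                 "lavrec_range_error")
  i <- findInterval(d, off, rightmost.closed = FALSE)
  k <- d - off[i]
  if (painting$orient[i] == 1L)
    list(wt_pos = painting$wt_start[i] + k, strand = 1L)
  else
    list(wt_pos = painting$wt_end[i] - 1L - k, strand = -1L)
}

#' Inverse lift: wild-type base to derived-allele position
#'
#' @param painting A [SegmentPainting].
#' @param wt_position 0-based wild-type base position.
#' @return List with `derived_pos` and `strand`, or `status = "deleted"` when
#'   the base is not retained.
#' @export
lift_to_derived <- function(painting, wt_position) {
  w <- as.integer(wt_position)
  off <- cumsum(c(0L, painting$wt_end - painting$wt_start))
  for (i in seq_len(nrow(painting))) {
    if (w >= painting$wt_start[i] && w < painting$wt_end[i]) {
      k <- if (painting$orient[i] == 1L) w - painting$wt_start[i]
           else painting$wt_end[i] - 1L - w
      return(list(derived_pos = off[i] + k, strand = painting$orient[i],
                  status = "retained"))
    }
  }
  list(derived_pos = NA_integer_, strand = NA_integer_, status = "deleted")
}

#' Apply an ordered event scenario to a region
#'
#' Forward-simulates the events, then derives the novel junction list (named
#' R1, R2, ... in ascending derived coordinate) and the fate of every
#' wild-type segment bounded by an event endpoint image.
#'
#' @param region A [RegionMap] (or integer region length).
#' @param events List of [Event] objects in the order they occur; intervals are
#'   in the coordinates of the allele state each event applies to.
#' @return List with `painting`, `junctions`, `fates` (data frame: wt interval,
#'   one `hit_<i>` flag per event, `status`, final `derived_start`,
#'   `derived_end`, `final_orient`), and `trajectory` (paintings of every
#'   state, identity first).
#' @export
apply_scenario <- function(region, events) {
  p0 <- identity_painting(region)
  trajectory <- list(p0)
  p <- p0
  for (i in seq_along(events)) {
    p <- tryCatch(apply_event(p, events[[i]]),
                  lavrec_error = function(e)
                    lavrec_error(sprintf("event %d (%s): %s", i,
                                         events[[i]]$kind, conditionMessage(e)),
                                 "lavrec_scenario_error"))
    trajectory[[i + 1L]] <- p
  }
  list(painting = p,
       junctions = junctions_of(p),
       fates = segment_fates(trajectory, events),
       trajectory = trajectory)
}

# Fate of every atomic wild-type segment. Atomic boundaries are the wild-type
# images of all event endpoints, so no atom ever straddles an event edge.
segment_fates <- function(trajectory, events) {
  L <- painting_length(trajectory[[1L]])
  bnd <- c(0L, L)
  for (i in seq_along(events)) {
    pre <- trajectory[[i]]
    bnd <- c(bnd, lift_boundary_to_wt(pre, events[[i]]$start),
             lift_boundary_to_wt(pre, events[[i]]$end))
  }
  bnd <- sort(unique(bnd))
  atoms <- data.frame(wt_start = bnd[-length(bnd)], wt_end = bnd[-1])
  nev <- length(events)
  hits <- matrix(FALSE, nrow(atoms), max(nev, 1L))
  status <- character(nrow(atoms))
  ds <- de <- rep(NA_integer_, nrow(atoms))
  fo <- rep(NA_integer_, nrow(atoms))
  final <- trajectory[[length(trajectory)]]
  for (a in seq_len(nrow(atoms))) {
    u <- atoms$wt_start[a]; v <- atoms$wt_end[a]
    for (i in seq_along(events)) {
      pre <- trajectory[[i]]
      loc <- lift_to_derived(pre, u)  # atom intact => one base locates it
      if (loc$status == "deleted") next
      lo <- lift_wt_boundary_in_segment(pre, u, v)
      if (is.null(lo)) next
      ev <- events[[i]]
      if (lo[1] >= ev$start && lo[2] <= ev$end) hits[a, i] <- TRUE
      else if (lo[1] < ev$end && lo[2] > ev$start)
        stop("internal error: atom straddles an event boundary")
    }
    floc <- lift_wt_boundary_in_segment(final, u, v)
    if (is.null(floc)) {
      status[a] <- "deleted"
    } else {
      ds[a] <- floc[1]; de[a] <- floc[2]; fo[a] <- floc[3]
      status[a] <- if (floc[3] == 1L) "retained+" else "retained-"
    }
  }
  out <- atoms
  if (nev) {
    out <- cbind(out, as.data.frame(hits))
    names(out)[2L + seq_len(nev)] <- paste0("hit_", seq_len(nev))
  }
  out$status <- status
  out$derived_start <- ds
  out$derived_end <- de
  out$final_orient <- fo
  out
}

# derived interval + orientation of an intact wt interval [u, v), or NULL if
# deleted
lift_wt_boundary_in_segment <- function(painting, u, v) {
  off <- cumsum(c(0L, painting$wt_end - painting$wt_start))
  for (i in seq_len(nrow(painting))) {
    if (u >= painting$wt_start[i] && v <= painting$wt_end[i]) {
      if (painting$orient[i] == 1L) {
        d0 <- off[i] + (u - painting$wt_start[i])
        return(c(d0, d0 + (v - u), 1L))
      } else {
        d0 <- off[i] + (painting$wt_end[i] - v)
        return(c(d0, d0 + (v - u), -1L))
      }
    }
  }
  NULL
}

#' Render the derived-allele sequence of a painting
#'
#' @param region_seq A `Biostrings::DNAString` (or character) wild-type
#'   sequence whose length equals the painting's wild-type span.
#' @param painting A [SegmentPainting].
#' @return A `DNAString` of length `painting_length(painting)`;
#'   reverse-complement is applied to `-` segments.
#' @export
render_sequence <- function(region_seq, painting) {
  if (is.character(region_seq)) region_seq <- Biostrings::DNAString(region_seq)
  if (max(painting$wt_end) > length(region_seq))
    lavrec_error(sprintf("painting needs %d bp but sequence has %d",
                         max(painting$wt_end), length(region_seq)),
                 "lavrec_validation_error")
  pieces <- vector("list", nrow(painting))
  for (i in seq_len(nrow(painting))) {
    s <- Biostrings::subseq(region_seq, painting$wt_start[i] + 1L, painting$wt_end[i])
    if (painting$orient[i] == -1L) s <- Biostrings::reverseComplement(s)
    pieces[[i]] <- s
  }
  do.call(Biostrings::xscat, pieces)
}

#' Convert wild-type-anchored event specifications to a current-frame scenario
#'
#' Each event is given by a pair of wild-type boundary positions (or breakpoint
#' names of the region); endpoints are lifted through the evolving allele so
#' the returned [Event]s carry current-allele coordinates.
#'
#' @param region A [RegionMap].
#' @param spec Data frame (or list of lists) with fields `kind`, `from`, `to`
#'   (breakpoint names or integer wild-type boundaries), optional `label`.
#' @return List of [Event]s applicable in order.
#' @export
events_from_wt <- function(region, spec) {
  if (is.data.frame(spec))
    spec <- lapply(seq_len(nrow(spec)), function(i) as.list(spec[i, ]))
  resolve <- function(x) {
    if (is.character(x)) {
      if (!x %in% names(region$breakpoints))
        lavrec_error(sprintf("unknown breakpoint '%s'", x),
                     "lavrec_validation_error")
      region$breakpoints[[x]]
    } else as.integer(x)
  }
  p <- identity_painting(region)
  events <- list()
  for (i in seq_along(spec)) {
    e <- spec[[i]]
    d1 <- lift_wt_boundary(p, resolve(e$from))
    d2 <- lift_wt_boundary(p, resolve(e$to))
    if (is.na(d1) || is.na(d2))
      lavrec_error(sprintf("event %d endpoint falls in deleted content", i),
                   "lavrec_validation_error")
    ev <- Event(e$kind, min(d1, d2), max(d1, d2),
                label = if (!is.null(e$label)) e$label else sprintf("ev%d", i))
    events[[i]] <- ev
    p <- apply_event(p, ev)
  }
  events
}

#' Serialize a painting as BED-like TSV
#' @param painting A [SegmentPainting].
#' @param file Output path.
#' @export
write_painting <- function(painting, file) {
  off <- cumsum(c(0L, painting$wt_end - painting$wt_start))
  utils::write.table(
    data.frame(wt_start = painting$wt_start, wt_end = painting$wt_end,
               orientation = ifelse(painting$orient == 1L, "+", "-"),
               derived_start = off[-length(off)]),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a painting written by [write_painting()]
#' @param file TSV path.
#' @export
read_painting <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  SegmentPainting(df$wt_start, df$wt_end, df$orientation)
}
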
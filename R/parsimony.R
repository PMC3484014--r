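# Most-parsimonious reconstruction: breadth-first search over ordered
# inversion/deletion sequences, and an integer solver for breakpoint
# coordinates under printed distance constraints.
#
# Search representation: the target painting's wild-type boundaries cut the
# region into atomic segments; every reachable allele whose events cut only at
# (images of) those boundaries is a signed subsequence-arrangement of atoms.
# Candidate event endpoints are therefore atom boundaries of the current
# state, which is exactly the spec of endpoint-restricted plain BFS.

atomize_target <- function(region_length, target) {
  bnd <- sort(unique(c(0L, region_length, target$wt_start, target$wt_end)))
  atoms <- data.frame(wt_start = bnd[-length(bnd)], wt_end = bnd[-1])
  atoms$len <- atoms$wt_end - atoms$wt_start
  # target as a signed atom sequence
  tv <- integer(0)
  for (i in seq_len(nrow(target))) {
    ids <- which(atoms$wt_start >= target$wt_start[i] &
                 atoms$wt_end <= target$wt_end[i])
    ids <- ids[order(atoms$wt_start[ids])]
    tv <- c(tv, if (target$orient[i] == 1L) ids else rev(-ids))
  }
  list(atoms = atoms, target_vec = tv)
}

state_key <- function(v) paste(v, collapse = ",")

adjacency_keys <- function(v, n_atoms) {
  s <- c(n_atoms + 1L, v, n_atoms + 2L)  # sentinels
  a <- s[-length(s)]; b <- s[-1]
  c(paste(a, b, sep = "|"), paste(-b, -a, sep = "|"))
}

# Admissible lower bound on events still needed. Deletions remove runs of
# non-target atoms and so never repair an adjacency whose two sides are both
# retained-in-target; each inversion repairs at most two of those. At least
# one deletion is needed while any non-target atom remains.
events_lower_bound <- function(v, adjset, n_atoms, target_set) {
  s <- c(n_atoms + 1L, v, n_atoms + 2L)
  a <- s[-length(s)]; b <- s[-1]
  keep <- (abs(a) > n_atoms | abs(a) %in% target_set) &
          (abs(b) > n_atoms | abs(b) %in% target_set)
  bad <- sum(keep & !(paste(a, b, sep = "|") %in% adjset))
  ceiling(bad / 2) + as.integer(any(!abs(v) %in% target_set))
}

apply_atom_event <- function(v, kind, i, j) {
  idx <- (i + 1L):j
  if (kind == "inversion") {
    v[idx] <- -rev(v[idx])
    v
  } else v[-idx]
}

#' Enumerate minimal event scenarios producing a target painting
#'
#' Plain breadth-first search over ordered inversion/deletion sequences with
#' candidate endpoints restricted to the breakend coordinate set of the target
#' painting (and its images in intermediate states); states are deduplicated
#' by canonical painting. All scenarios of the minimal length are returned.
#'
#' @param region A [RegionMap] or integer region length.
#' @param target Target [SegmentPainting].
#' @param max_events Search depth bound (<= 5).
#' @return List of scenarios; each scenario is a list with `events` (list of
#'   [Event] with current-frame bp coordinates), `score`, and `trajectory`
#'   (atom-state list). Attribute `bound_exceeded` is `TRUE` when no solution
#'   exists within `max_events`; attribute `searched_depth` records the last
#'   fully searched level.
#' @export
enumerate_scenarios <- function(region, target, max_events = 5L) {
  if (max_events > 5L)
    lavrec_error("max_events must be <= 5", "lavrec_validation_error")
  L <- if (inherits(region, "RegionMap")) region$length_bp else as.integer(region)
  at <- atomize_target(L, target)
  atoms <- at$atoms; tv <- at$target_vec
  n_atoms <- nrow(atoms)
  target_set <- sort(unique(abs(tv)))
  adjset <- adjacency_keys(tv, n_atoms)
  tkey <- state_key(tv)

  start <- seq_len(n_atoms)
  if (state_key(start) == tkey)
    return(structure(list(list(events = list(), score = 0L,
                               trajectory = list(start))),
                     bound_exceeded = FALSE, searched_depth = 0L))

  visited <- new.env(hash = TRUE, parent = emptyenv())
  assign(state_key(start), 1L, envir = visited)
  nodes <- list(list(v = start, edges = list()))  # edges: list(parent, kind, i, j)
  level <- 1L            # node index of current frontier start
  frontier <- 1L
  found <- integer(0)
  depth <- 0L
  while (depth < max_events && !length(found)) {
    depth <- depth + 1L
    nxt <- integer(0)
    for (ni in frontier) {
      v <- nodes[[ni]]$v
      m <- length(v)
      if (!m) next
      for (i in 0:(m - 1L)) for (j in (i + 1L):m) {
        for (kind in c("inversion", "deletion")) {
          if (kind == "deletion" && any(abs(v[(i + 1L):j]) %in% target_set))
            next  # deleting target content is irrecoverable
          w <- apply_atom_event(v, kind, i, j)
          if (length(w) < length(tv)) next
          if (depth + events_lower_bound(w, adjset, n_atoms, target_set) >
                max_events) next
          key <- state_key(w)
          idx <- get0(key, envir = visited, ifnotfound = NA_integer_)
          edge <- list(parent = ni, kind = kind, i = i, j = j)
          if (is.na(idx)) {
            nodes[[length(nodes) + 1L]] <- list(v = w, edges = list(edge),
                                                depth = depth)
            assign(key, length(nodes), envir = visited)
            nxt <- c(nxt, length(nodes))
            if (key == tkey) found <- c(found, length(nodes))
          } else if (!is.null(nodes[[idx]]$depth) && nodes[[idx]]$depth == depth) {
            # another minimal-depth route into an existing state
            nodes[[idx]]$edges <- c(nodes[[idx]]$edges, list(edge))
          }
        }
      }
    }
    frontier <- nxt
  }
  if (!length(found))
    return(structure(list(), bound_exceeded = TRUE, searched_depth = depth))

  # reconstruct all minimal-length event paths
  paths <- collect_paths(nodes, found[1])
  scenarios <- lapply(paths, function(pth) {
    v <- start
    events <- list()
    traj <- list(v)
    for (step in pth) {
      cum <- cumsum(c(0L, atoms$len[abs(v)]))
      ev <- Event(step$kind, cum[step$i + 1L], cum[step$j + 1L],
                  label = step$kind)
      events[[length(events) + 1L]] <- ev
      v <- apply_atom_event(v, step$kind, step$i, step$j)
      traj[[length(traj) + 1L]] <- v
    }
    list(events = events, score = length(events), trajectory = traj)
  })
  structure(scenarios, bound_exceeded = FALSE, searched_depth = depth,
            atoms = atoms)
}

collect_paths <- function(nodes, idx) {
  node <- nodes[[idx]]
  if (!length(node$edges)) return(list(list()))
  out <- list()
  for (e in node$edges) {
    pre <- collect_paths(nodes, e$parent)
    for (p in pre)
      out[[length(out) + 1L]] <- c(p, list(list(kind = e$kind, i = e$i, j = e$j)))
  }
  out
}

#' Does a scenario's painting trajectory match a reference scenario?
#'
#' Scenario equivalence is defined on painting trajectories, not event lists:
#' junction data cannot distinguish endpoint relabelings that traverse the
#' same states.
#'
#' @param region Region (map or length).
#' @param events_a,events_b Two event lists.
#' @return `TRUE` when both scenarios traverse identical painting states.
#' @export
same_trajectory <- function(region, events_a, events_b) {
  ta <- apply_scenario(region, events_a)$trajectory
  tb <- apply_scenario(region, events_b)$trajectory
  if (length(ta) != length(tb)) return(FALSE)
  for (i in seq_along(ta)) {
    if (!isTRUE(all.equal(as.data.frame(ta[[i]])[c("wt_start", "wt_end", "orient")],
                          as.data.frame(tb[[i]])[c("wt_start", "wt_end", "orient")],
                          check.attributes = FALSE)))
      return(FALSE)
  }
  TRUE
}

#' Breakpoint distance/length constraint
#'
#' @param kind `"distance"` (difference of two breakpoint positions in the
#'   wild-type frame), `"event_length"` (length of a template event measured
#'   in the allele state where it occurs), or `"displacement"` (shift of the
#'   interval between two breakpoints across the inversion steps).
#' @param operands Character vector of two breakpoint names.
#' @param value Target length in bp (> 0).
#' @param tolerance Allowed absolute residual in bp (>= 0).
#' @param hard Hard constraints must be satisfied within tolerance; soft
#'   constraints only contribute to the reported residuals.
#' @export
BreakpointConstraint <- function(kind, operands, value, tolerance = 0L,
                                 hard = TRUE) {
  kind <- match.arg(kind, c("distance", "event_length", "displacement"))
  if (value <= 0) lavrec_error("distance constraints need value > 0",
                               "lavrec_validation_error")
  if (tolerance < 0) lavrec_error("tolerance must be >= 0",
                                  "lavrec_validation_error")
  structure(list(kind = kind, operands = operands, value = as.numeric(value),
                 tolerance = as.numeric(tolerance), hard = hard),
            class = "BreakpointConstraint")
}

#' The lavender event template in breakpoint names, in occurrence order
#'
#' Inversion BP3-BP6, overlapping inversion BP2-BP4, overlapping deletion
#' BP1-BP5; endpoints are lifted through the evolving allele when applied.
#' @export
lav_event_template <- function() {
  list(list(kind = "inversion", from = "BP3", to = "BP6"),
       list(kind = "inversion", from = "BP2", to = "BP4"),
       list(kind = "deletion",  from = "BP1", to = "BP5"))
}

#' Printed distance constraints for the lavender breakpoint set
#'
#' Event lengths are interpreted as measured in the allele state in which each
#' event occurs (`frame = "sequential"`); rounded 0.1-kb values carry a 50-bp
#' tolerance, and two-significant-figure spans are soft with 10% tolerance.
#'
#' @return List of [BreakpointConstraint]s.
#' @export
lav60_constraints <- function() {
  list(
    frag246 = BreakpointConstraint("distance", c("BP5", "BP6"), 246, 0, TRUE),
    seg2200 = BreakpointConstraint("distance", c("BP4", "BP5"), 2200, 50, TRUE),
    inv1 = BreakpointConstraint("event_length", c("BP3", "BP6"), 30900, 50, TRUE),
    inv2 = BreakpointConstraint("event_length", c("BP2", "BP4"), 16400, 50, TRUE),
    del  = BreakpointConstraint("event_length", c("BP1", "BP5"), 16000, 50, TRUE),
    span60 = BreakpointConstraint("distance", c("BP1", "BP6"), 60000, 6000, FALSE),
    walkup = BreakpointConstraint("distance", c("BP1", "BP3"), 27600, 2760, FALSE),
    transloc = BreakpointConstraint("displacement", c("BP5", "BP6"), 30000, 3000,
                                    FALSE))
}

# measure all constraints at integer positions x (named BP vector)
measure_constraints <- function(x, constraints, template, frame) {
  n_bp <- length(x)
  region <- RegionMap(as.integer(max(x) + 1000L), list(), sort(x))
  events <- NULL
  if (frame == "sequential")
    events <- tryCatch(events_from_wt(region, template), error = function(e) NULL)
  vapply(constraints, function(cn) {
    if (cn$kind == "distance")
      return(abs(x[[cn$operands[2]]] - x[[cn$operands[1]]]))
    if (cn$kind == "event_length") {
      if (frame == "wildtype" || is.null(events))
        return(abs(x[[cn$operands[2]]] - x[[cn$operands[1]]]))
      k <- which(vapply(template, function(t)
        setequal(c(t$from, t$to), cn$operands), logical(1)))
      if (!length(k)) lavrec_error(
        sprintf("no template event with endpoints %s",
                paste(cn$operands, collapse = ",")), "lavrec_validation_error")
      ev <- events[[k[1]]]
      return(ev$end - ev$start)
    }
    # displacement of [op1, op2) across all non-deletion template events
    invs <- Filter(function(t) t$kind != "deletion", template)
    p <- identity_painting(region)
    for (t in invs) {
      d1 <- lift_wt_boundary(p, region$breakpoints[[t$from]])
      d2 <- lift_wt_boundary(p, region$breakpoints[[t$to]])
      p <- apply_event(p, Event(t$kind, min(d1, d2), max(d1, d2)))
    }
    img <- lift_wt_boundary(p, x[[cn$operands[1]]])
    abs(img - x[[cn$operands[1]]])
  }, numeric(1))
}

#' Solve breakpoint coordinates from distance constraints
#'
#' Finds integer breakpoint positions (gauge: the first breakpoint is fixed at
#' 0 unless `fixed` says otherwise) minimising the total absolute residual,
#' with hard constraints required to fall within their tolerances. Both frame
#' interpretations of event lengths are tried (`sequential`: measured in the
#' state where the event occurs; `wildtype`: plain coordinate differences);
#' the first feasible interpretation is reported.
#'
#' @param constraints List of [BreakpointConstraint]s.
#' @param template Event template in breakpoint names (default: the lavender
#'   two-inversions-then-deletion template).
#' @param bp_names Breakpoint names (default BP1..BP6 restricted to those the
#'   constraints mention).
#' @param fixed Named vector of pinned positions (default first name = 0).
#' @return A `CoordinateSolution` list: `positions`, `residuals` data frame,
#'   `frame`, `feasible`; infeasible systems return `feasible = FALSE` plus a
#'   `conflict` vector naming a minimal conflicting subset (no exception).
#' @export
solve_coordinates <- function(constraints, template = lav_event_template(),
                              bp_names = NULL, fixed = NULL) {
  if (is.null(names(constraints)) || any(!nzchar(names(constraints))))
    names(constraints) <- paste0("c", seq_along(constraints))
  mentioned <- unique(unlist(lapply(constraints, `[[`, "operands")))
  if (is.null(bp_names))
    bp_names <- intersect(paste0("BP", 1:6), mentioned)
  if (is.null(fixed)) fixed <- stats::setNames(0L, bp_names[1])

  for (frame in c("sequential", "wildtype")) {
    sol <- try_solve_frame(constraints, template, bp_names, fixed, frame)
    if (sol$feasible) return(sol)
    if (frame == "wildtype") return(sol)  # report last attempt with conflicts
  }
}

try_solve_frame <- function(constraints, template, bp_names, fixed, frame) {
  free <- setdiff(bp_names, names(fixed))
  nv <- length(free)
  # strictly ordered, well-spread starting point (linearization is exact on
  # the ordered domain)
  x0 <- stats::setNames(numeric(length(bp_names)), bp_names)
  x0[names(fixed)] <- fixed
  ord <- order(match(bp_names, paste0("BP", 1:6)))
  base <- x0[[names(fixed)[1]]]
  for (i in seq_along(bp_names)) {
    nm <- bp_names[ord[i]]
    if (!nm %in% names(fixed)) x0[nm] <- base + i * 10000
  }
  f0 <- measure_constraints(x0, constraints, template, frame)
  if (nv) {
    A <- matrix(0, length(constraints), nv,
                dimnames = list(names(constraints), free))
    for (v in free) {
      xp <- x0; xp[v] <- xp[v] + 1
      A[, v] <- measure_constraints(xp, constraints, template, frame) - f0
    }
    tgt <- vapply(constraints, `[[`, numeric(1), "value")
    hard <- vapply(constraints, `[[`, logical(1), "hard")
    w <- ifelse(hard, 1e6, 1)
    b <- tgt - (f0 - A %*% x0[free])
    fit <- tryCatch(stats::lm.wfit(A, as.numeric(b), w), error = function(e) NULL)
    if (is.null(fit))
      return(list(feasible = FALSE, conflict = names(constraints)[hard],
                  frame = frame))
    xs <- x0
    xs[free] <- round(fit$coefficients)
    xs[is.na(xs)] <- x0[is.na(xs)]
  } else xs <- x0
  xs <- stats::setNames(as.integer(round(xs)), names(xs))
  meas <- tryCatch(measure_constraints(xs, constraints, template, frame),
                   error = function(e) rep(NA_real_, length(constraints)))
  tgt <- vapply(constraints, `[[`, numeric(1), "value")
  tol <- vapply(constraints, `[[`, numeric(1), "tolerance")
  hard <- vapply(constraints, `[[`, logical(1), "hard")
  resid <- meas - tgt
  ordered <- !is.unsorted(xs[order(match(names(xs), paste0("BP", 1:6)))],
                          strictly = TRUE)
  ok <- ordered && !any(is.na(resid)) && all(abs(resid[hard]) <= tol[hard])
  res_df <- data.frame(constraint = names(constraints), measured = meas,
                       target = tgt, residual = resid, tolerance = tol,
                       hard = hard,
                       satisfied = !is.na(resid) & abs(resid) <= tol)
  if (ok)
    return(list(positions = xs, residuals = res_df, frame = frame,
                feasible = TRUE))
  # infeasible: name a minimal conflicting subset among hard constraints
  conflict <- character(0)
  hi <- which(hard)
  for (drop in hi) {
    sub <- constraints[-drop]
    s2 <- try_solve_subset(sub, template, bp_names, names(constraints)[-drop])
    if (s2) conflict <- c(conflict, names(constraints)[drop])
  }
  if (!length(conflict)) conflict <- names(constraints)[hi]
  list(positions = xs, residuals = res_df, frame = frame, feasible = FALSE,
       conflict = conflict)
}

# does the hard subsystem become satisfiable after dropping a constraint?
try_solve_subset <- function(constraints, template, bp_names, cnames) {
  names(constraints) <- cnames
  sol <- tryCatch(
    try_solve_frame(constraints, template, bp_names,
                    stats::setNames(0L, bp_names[1]), "sequential"),
    error = function(e) list(feasible = FALSE))
  isTRUE(sol$feasible)
}

#' Human-readable reconstruction report for a scenario
#'
#' @param scenario List with `events` (as returned by [enumerate_scenarios()]
#'   or built by [events_from_wt()]).
#' @param region A [RegionMap].
#' @param solution Optional `CoordinateSolution` to echo.
#' @return List with `steps` (data frame), `gene_effects` (per-step list of
#'   genes and exon indices affected) and `text` (character lines); also
#'   serialisable with `jsonlite`.
#' @export
report_scenario <- function(scenario, region, solution = NULL) {
  events <- if (!is.null(scenario$events)) scenario$events else scenario
  if (!length(events))
    return(list(steps = data.frame(), gene_effects = list(),
                text = "empty scenario: wild-type organisation"))
  sim <- apply_scenario(region, events)
  steps <- data.frame(step = seq_along(events),
                      kind = vapply(events, `[[`, character(1), "kind"),
                      start = vapply(events, `[[`, integer(1), "start"),
                      end = vapply(events, `[[`, integer(1), "end"))
  steps$length_bp <- steps$end - steps$start
  gene_effects <- list()
  text <- character(0)
  for (i in seq_along(events)) {
    pre <- sim$trajectory[[i]]
    # wild-type content of the event interval
    sub <- apply_event(pre, Event("deletion", events[[i]]$start, events[[i]]$end))
    pre_atoms <- wt_content(pre); post_atoms <- wt_content(sub)
    affected <- setdiff_intervals(pre_atoms, post_atoms)
    eff <- list()
    for (g in region$genes) {
      hits <- integer(0)
      for (j in seq_len(nrow(g$exons)))
        if (interval_overlaps(affected, g$exons[j, 1], g$exons[j, 2]))
          hits <- c(hits, j)
      if (length(hits)) eff[[g$name]] <- hits
    }
    gene_effects[[i]] <- eff
    text <- c(text, sprintf(
      "step %d: %s of [%d, %d) (%d bp)%s", i, events[[i]]$kind,
      events[[i]]$start, events[[i]]$end, steps$length_bp[i],
      if (length(eff)) paste0("; touches ", paste(
        vapply(names(eff), function(n) sprintf("%s exon(s) %s", n,
          paste(eff[[n]], collapse = ",")), character(1)), collapse = "; "))
      else ""))
  }
  if (!is.null(solution) && isTRUE(solution$feasible))
    text <- c(text, sprintf("coordinates (%s frame): %s", solution$frame,
                            paste(sprintf("%s=%d", names(solution$positions),
                                          solution$positions), collapse = " ")))
  list(steps = steps, gene_effects = gene_effects, text = text)
}

wt_content <- function(painting) {
  df <- as.data.frame(painting)[c("wt_start", "wt_end")]
  df[order(df$wt_start), , drop = FALSE]
}

# wt intervals in a but not in b (both sorted, disjoint)
setdiff_intervals <- function(a, b) {
  ia <- IRanges::IRanges(a$wt_start + 1L, a$wt_end)
  ib <- if (nrow(b)) IRanges::IRanges(b$wt_start + 1L, b$wt_end)
        else IRanges::IRanges()
  d <- IRanges::setdiff(ia, ib)
  data.frame(wt_start = BiocGenerics::start(d) - 1L, wt_end = BiocGenerics::end(d))
}

interval_overlaps <- function(ivs, lo, hi) {
  any(ivs$wt_start < hi & ivs$wt_end > lo)
}
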
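# Molecular assay outcomes on an arbitrary allele painting: multi-primer
# in-silico PCR (covers the three-primer genotyping test), band-pattern
# genotype calling, structural RT-PCR prediction and per-gene consequence
# annotation. All predictions are structural; no primer thermodynamics.

#' Primer table constructor/validator
#'
#' @param name Primer names.
#' @param wt_start,wt_end 0-based half-open wild-type binding footprint
#'   (length >= 15 bp).
#' @param strand `"+"` for forward primers (3' end at `wt_end`), `"-"` for
#'   reverse.
#' @param role `"generic"`, `"wt-specific"` or `"mutant-specific"`.
#' @export
primer_table <- function(name, wt_start, wt_end, strand,
                         role = "generic") {
  df <- data.frame(name = name, wt_start = as.integer(wt_start),
                   wt_end = as.integer(wt_end), strand = strand,
                   role = role, stringsAsFactors = FALSE)
  if (any(df$wt_end - df$wt_start < 15L))
    lavrec_error("primer footprints must be >= 15 bp", "lavrec_validation_error")
  if (any(!df$strand %in% c("+", "-")))
    lavrec_error("primer strand must be '+' or '-'", "lavrec_validation_error")
  df
}

#' In-silico PCR on a painted allele
#'
#' Each primer footprint is mapped through the painting; a footprint split by
#' a junction or falling in deleted content is reported unbindable. A product
#' is emitted for every primer pair whose derived-allele images lie on
#' opposite strands, facing inward, separated by at most `max_product`.
#'
#' @param painting A [SegmentPainting] of the allele.
#' @param primers Primer table (see [primer_table()]).
#' @param max_product Maximum product size in bp (default 5000, gel-PCR
#'   plausibility).
#' @return Data frame of products: `fwd`, `rev`, `size`, `spans_junction`;
#'   attribute `unbindable` names primers without an intact binding site.
#' @export
insilico_pcr <- function(painting, primers, max_product = 5000L) {
  imgs <- vector("list", nrow(primers))
  for (i in seq_len(nrow(primers))) {
    loc <- lift_wt_boundary_in_segment(painting, primers$wt_start[i],
                                       primers$wt_end[i])
    if (is.null(loc)) next
    s <- if (primers$strand[i] == "+") 1L else -1L
    imgs[[i]] <- list(d0 = loc[1], d1 = loc[2], strand = s * loc[3])
  }
  unbindable <- primers$name[vapply(imgs, is.null, logical(1))]
  jx <- junctions_of(painting)
  prods <- list()
  for (i in seq_len(nrow(primers))) for (j in seq_len(nrow(primers))) {
    if (i == j || is.null(imgs[[i]]) || is.null(imgs[[j]])) next
    f <- imgs[[i]]; r <- imgs[[j]]
    if (f$strand != 1L || r$strand != -1L) next
    if (f$d1 > r$d0) next                       # must face inward, 5'->3'
    size <- r$d1 - f$d0
    if (size > max_product) next
    prods[[length(prods) + 1L]] <- data.frame(
      fwd = primers$name[i], rev = primers$name[j], size = size,
      spans_junction = any(jx$derived_pos > f$d0 & jx$derived_pos < r$d1))
  }
  out <- if (length(prods)) do.call(rbind, prods)
         else data.frame(fwd = character(0), rev = character(0),
                         size = integer(0), spans_junction = logical(0))
  attr(out, "unbindable") <- unbindable
  out
}

#' Call a genotype from a band pattern
#'
#' @param pattern Numeric vector of observed product sizes (bp); empty for no
#'   amplification.
#' @param expected List/vector with `wt_size` and `lav_size`.
#' @param size_tol Band-size tolerance in bp (default 20).
#' @return One of `"+/+"`, `"lav/+"`, `"lav/lav"`, `"no-call"`.
#' @export
call_genotype <- function(pattern, expected, size_tol = 20L) {
  wt <- expected[["wt_size"]]; lav <- expected[["lav_size"]]
  if (abs(wt - lav) <= 2L * size_tol)
    lavrec_error("expected band sizes overlap within 2 * size_tol",
                 "lavrec_configuration_error")
  has_wt <- any(abs(pattern - wt) <= size_tol)
  has_lav <- any(abs(pattern - lav) <= size_tol)
  if (has_wt && has_lav) "lav/+"
  else if (has_wt) "+/+"
  else if (has_lav) "lav/lav"
  else "no-call"
}

#' Annotate per-gene structural consequences of a painting
#'
#' A gene is `deleted` when no exon base is retained, `truncated` when some
#' exons are fully retained and others lost, `rearranged` when all exons are
#' retained but no longer sit together in one unbroken wild-type run, and
#' `intact` otherwise.
#'
#' @param region A [RegionMap].
#' @param painting A [SegmentPainting].
#' @return Named list of `GeneConsequence` lists: `gene`, `status`,
#'   `retained_exons`, `exon_info` (per-exon placement), `transcript`
#'   (predicted expressed transcript as retained transcript-order prefix).
#' @export
annotate_consequences <- function(region, painting) {
  out <- list()
  for (g in region$genes) {
    n <- nrow(g$exons)
    seg <- rep(NA_integer_, n); orient <- rep(NA_integer_, n)
    dstart <- rep(NA_integer_, n)
    fully <- logical(n); any_base <- logical(n)
    for (j in seq_len(n)) {
      loc <- lift_wt_boundary_in_segment(painting, g$exons[j, 1], g$exons[j, 2])
      if (!is.null(loc)) {
        fully[j] <- TRUE; any_base[j] <- TRUE
        dstart[j] <- loc[1]; orient[j] <- loc[3]
        off <- cumsum(c(0L, painting$wt_end - painting$wt_start))
        seg[j] <- findInterval(loc[1], off, rightmost.closed = FALSE)
      } else {
        ov <- painting$wt_start < g$exons[j, 2] & painting$wt_end > g$exons[j, 1]
        any_base[j] <- any(ov)
      }
    }
    status <-
      if (!any(any_base)) "deleted"
      else if (all(fully) && length(unique(seg)) == 1L) "intact"
      else if (any(fully)) {
        if (all(fully)) "rearranged" else "truncated"
      } else "truncated"
    retained <- which(fully)
    if (status == "deleted") retained <- integer(0)
    # expressed-transcript prediction: transcript-order prefix that stays with
    # the exon-1/promoter segment
    prefix <- 0L
    if (length(retained) && retained[1] == 1L) {
      while (prefix < n && fully[prefix + 1L] && seg[prefix + 1L] == seg[1L])
        prefix <- prefix + 1L
    }
    transcript <- if (status == "intact") seq_len(n)
                  else if (prefix > 0L) seq_len(prefix) else integer(0)
    out[[g$name]] <- structure(list(
      gene = g$name, status = status, retained_exons = retained,
      exon_info = data.frame(exon = seq_len(n), fully_retained = fully,
                             segment = seg, derived_start = dstart,
                             orient = orient),
      transcript = transcript), class = "GeneConsequence")
  }
  out
}

#' Predict RT-PCR outcomes for exon pairs
#'
#' Purely structural rule: a primer pair across exons `i` and `j` amplifies
#' iff both exons are fully retained and sit in the same unbroken wild-type
#' run of the derived allele (so their order, orientation and spacing are
#' preserved in the transcript).
#'
#' @param gene A [GeneModel].
#' @param consequence The gene's `GeneConsequence` (see
#'   [annotate_consequences()]).
#' @param pairs Two-column matrix/data frame of exon index pairs `(i, j)`,
#'   `i < j`.
#' @return Data frame `exon_i`, `exon_j`, `outcome` (`"amplify"`/`"fail"`).
#' @export
predict_rt_pcr <- function(gene, consequence, pairs) {
  pairs <- matrix(as.integer(as.matrix(pairs)), ncol = 2)
  n <- nrow(gene$exons)
  if (any(pairs < 1L) || any(pairs > n) || any(pairs[, 1] >= pairs[, 2]))
    lavrec_error(sprintf("exon pair out of range for %s (1..%d)", gene$name, n),
                 "lavrec_validation_error")
  info <- consequence$exon_info
  outcome <- vapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (info$fully_retained[i] && info$fully_retained[j] &&
        info$segment[i] == info$segment[j]) "amplify" else "fail"
  }, character(1))
  data.frame(exon_i = pairs[, 1], exon_j = pairs[, 2], outcome = outcome)
}
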
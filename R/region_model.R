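# Coordinate frame and annotation for the wild-type region.
#
# All internal coordinates are 0-based, half-open. GFF3 (1-based, inclusive)
# is converted at the I/O boundary. Position 0 is the MLPH-proximal end of the
# region; coordinates increase toward LRRFIP1, so breakpoints satisfy
# BP1 < BP2 < ... < BP6.

REGION_GENES <- c("MLPH", "PRLH", "RAB17", "LRRFIP1")

lavrec_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "lavrec_error")))
}

#' Gene model with an ordered exon chain
#'
#' @param name Gene symbol, one of MLPH, PRLH, RAB17, LRRFIP1 (other symbols
#'   are allowed for toy fixtures when `strict = FALSE`).
#' @param strand `"+"` or `"-"`: direction of transcription on the region axis.
#' @param exons Two-column matrix (start, end) of 0-based half-open exon
#'   intervals, ordered by transcript position (exon 1 first).
#' @param strict Require `name` to be one of the four region genes.
#' @return A `GeneModel` list.
#' @export
GeneModel <- function(name, strand, exons, strict = TRUE) {
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (strict && !name %in% REGION_GENES)
    lavrec_error(sprintf("unknown gene name '%s'", name), "lavrec_validation_error")
  if (!strand %in% c("+", "-"))
    lavrec_error(sprintf("gene %s: strand must be '+' or '-'", name),
                 "lavrec_validation_error")
  if (nrow(exons) < 1L || any(exons[, 2] <= exons[, 1]))
    lavrec_error(sprintf("gene %s: exons must be non-empty intervals", name),
                 "lavrec_validation_error")
  # transcript order maps to genomic order along the gene's own strand
  genomic <- if (strand == "+") exons[, 1] else -exons[, 1]
  if (nrow(exons) > 1 && any(diff(genomic) <= 0))
    lavrec_error(sprintf("gene %s: exons not in transcript order", name),
                 "lavrec_validation_error")
  ir <- exons[order(exons[, 1]), , drop = FALSE]
  if (nrow(ir) > 1 && any(ir[-1, 1] < ir[-nrow(ir), 2]))
    lavrec_error(sprintf("gene %s: exons overlap", name), "lavrec_validation_error")
  structure(list(name = name, strand = strand, exons = exons),
            class = "GeneModel")
}

#' Wild-type region map
#'
#' Holds the region length, the four gene models and the named breakpoint
#' positions (0-based boundary coordinates).
#'
#' @param length_bp Total region length in bp.
#' @param genes List of [GeneModel] objects in region order.
#' @param breakpoints Named integer vector, e.g. `c(BP1 = ..., ..., BP6 = ...)`,
#'   strictly increasing.
#' @return A `RegionMap`.
#' @export
RegionMap <- function(length_bp, genes, breakpoints) {
  length_bp <- as.integer(length_bp)
  breakpoints <- vapply(breakpoints, as.integer, integer(1))
  if (is.null(names(breakpoints)) || any(!nzchar(names(breakpoints))))
    lavrec_error("breakpoints must be named", "lavrec_validation_error")
  if (length(breakpoints) > 1) {
    bad <- which(diff(breakpoints) <= 0)
    if (length(bad))
      lavrec_error(sprintf("breakpoints out of order: %s >= %s",
                           names(breakpoints)[bad[1]], names(breakpoints)[bad[1] + 1]),
                   "lavrec_validation_error")
  }
  if (any(breakpoints < 0L) || any(breakpoints > length_bp))
    lavrec_error("breakpoint positions outside [0, length_bp]",
                 "lavrec_validation_error")
  for (g in genes) {
    if (!inherits(g, "GeneModel"))
      lavrec_error("genes must be GeneModel objects", "lavrec_validation_error")
    if (any(g$exons < 0L) || any(g$exons > length_bp))
      lavrec_error(sprintf("gene %s: exon outside [0, length_bp]", g$name),
                   "lavrec_validation_error")
  }
  names(genes) <- vapply(genes, `[[`, character(1), "name")
  structure(list(length_bp = length_bp, genes = genes, breakpoints = breakpoints),
            class = "RegionMap")
}

#' @export
print.RegionMap <- function(x, ...) {
  cat(sprintf("RegionMap: %d bp, %d genes, %d breakpoints\n",
              x$length_bp, length(x$genes), length(x$breakpoints)))
  for (g in x$genes)
    cat(sprintf("  %-8s %s  %d exon(s)  [%d, %d)\n", g$name, g$strand,
                nrow(g$exons), min(g$exons[, 1]), max(g$exons[, 2])))
  bp <- x$breakpoints
  cat("  breakpoints:", paste(sprintf("%s=%d", names(bp), bp), collapse = " "), "\n")
  invisible(x)
}

#' Load a region map from GFF3 annotation and a breakpoint table
#'
#' @param annotation_file GFF3 file with `gene` and `exon` features
#'   (1-based, inclusive; exon features carry `Parent=<gene>`).
#' @param breakpoint_file Tab-separated file with columns `name`, `position`
#'   (positions 0-based boundary coordinates).
#' @param length_bp Region length; if `NULL`, taken from the GFF3
#'   `##sequence-region` pragma.
#' @param strict Passed to [GeneModel()].
#' @return A [RegionMap].
#' @export
load_region <- function(annotation_file, breakpoint_file, length_bp = NULL,
                        strict = TRUE) {
  if (is.null(length_bp)) {
    hdr <- readLines(annotation_file, n = 50L)
    sr <- grep("^##sequence-region", hdr, value = TRUE)
    if (!length(sr))
      lavrec_error("no ##sequence-region pragma and no length_bp given",
                   "lavrec_validation_error")
    length_bp <- as.integer(strsplit(trimws(sr[1]), "\\s+")[[1]][4])
  }
  gr <- rtracklayer::import.gff3(annotation_file)
  md <- S4Vectors::mcols(gr)
  is_gene <- md$type == "gene"
  is_exon <- md$type == "exon"
  genes <- list()
  for (i in which(is_gene)) {
    gid <- md$ID[i]
    kids <- which(is_exon & vapply(md$Parent, function(p) gid %in% p, logical(1)))
    if (!length(kids))
      lavrec_error(sprintf("gene %s has no exons", gid), "lavrec_validation_error")
    strand <- as.character(BiocGenerics::strand(gr[i]))
    ex <- cbind(BiocGenerics::start(gr[kids]) - 1L, BiocGenerics::end(gr[kids]))
    ord <- if (strand == "+") order(ex[, 1]) else order(-ex[, 1])
    genes[[length(genes) + 1L]] <- GeneModel(gid, strand, ex[ord, , drop = FALSE],
                                             strict = strict)
  }
  bp <- utils::read.delim(breakpoint_file, stringsAsFactors = FALSE)
  if (!all(c("name", "position") %in% names(bp)))
    lavrec_error("breakpoint table needs columns name, position",
                 "lavrec_validation_error")
  bpv <- stats::setNames(as.integer(bp$position), bp$name)
  RegionMap(length_bp, genes, bpv)
}

#' Write a region map as GFF3 + breakpoint TSV
#'
#' Inverse of [load_region()]; `load_region(write_region(...))` round-trips.
#'
#' @param region A [RegionMap].
#' @param annotation_file,breakpoint_file Output paths.
#' @param seqid Sequence name used in the GFF3.
#' @return Invisibly, the two paths.
#' @export
write_region <- function(region, annotation_file, breakpoint_file,
                         seqid = "region") {
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", seqid, region$length_bp))
  for (g in region$genes) {
    lines <- c(lines, sprintf("%s\tlavrec\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              seqid, min(g$exons[, 1]) + 1L, max(g$exons[, 2]),
                              g$strand, g$name))
    for (j in seq_len(nrow(g$exons)))
      lines <- c(lines, sprintf("%s\tlavrec\texon\t%d\t%d\t.\t%s\t.\tID=%s_exon%d;Parent=%s",
                                seqid, g$exons[j, 1] + 1L, g$exons[j, 2],
                                g$strand, g$name, j, g$name))
  }
  writeLines(lines, annotation_file)
  utils::write.table(
    data.frame(name = names(region$breakpoints),
               position = unname(region$breakpoints)),
    breakpoint_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(annotation_file, breakpoint_file))
}

#' Feature context of a single position
#'
#' @param region A [RegionMap].
#' @param position 0-based position, `0 <= position < length_bp`.
#' @return A list with `gene` (or `NA` for intergenic), `feature`
#'   (`"exon"`, `"intron"` or `"intergenic"`) and `index` (exon or intron index
#'   in transcript order; intron `i` lies between exons `i` and `i + 1`).
#' @export
locate <- function(region, position) {
  position <- as.integer(position)
  if (position < 0L || position >= region$length_bp)
    lavrec_error(sprintf("position %d outside [0, %d)", position, region$length_bp),
                 "lavrec_range_error")
  for (g in region$genes) {
    lo <- min(g$exons[, 1]); hi <- max(g$exons[, 2])
    if (position < lo || position >= hi) next
    hit <- which(position >= g$exons[, 1] & position < g$exons[, 2])
    if (length(hit))
      return(list(gene = g$name, feature = "exon", index = hit[1]))
    # intron between transcript-order neighbours; exon rows are in transcript
    # order, genomically increasing for '+' genes and decreasing for '-' genes
    n <- nrow(g$exons)
    for (j in seq_len(n - 1L)) {
      a <- g$exons[j, ]; b <- g$exons[j + 1L, ]
      ilo <- min(a[2], b[2]); ihi <- max(a[1], b[1])
      if (position >= ilo && position < ihi)
        return(list(gene = g$name, feature = "intron", index = j))
    }
  }
  list(gene = NA_character_, feature = "intergenic", index = NA_integer_)
}
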
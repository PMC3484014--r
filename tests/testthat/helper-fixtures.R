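# Shared fixtures and independent oracles, all built in code at test time.

# LAV60 fixture, built once per test run
lav60_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- lav60_config(101L)
      reg <- make_region(cfg)
      sim <- make_allele_and_reads(reg, config = cfg)
      cache <<- list(cfg = cfg, reg = reg, sim = sim)
    }
    cache
  }
})

# random ordered scenario on a bare region; endpoints keep min_sep spacing
random_scenario <- function(seed, region_len = 8000L, n_events = NULL,
                            min_sep = 500L) {
  set.seed(seed)
  if (is.null(n_events)) n_events <- sample(1:3, 1)
  p <- identity_painting(region_len)
  evs <- list()
  for (i in seq_len(n_events)) {
    len <- painting_length(p)
    kind <- if (len > 4L * min_sep && stats::runif(1) < 0.35) "deletion"
            else "inversion"
    max_span <- if (kind == "deletion") min(len - 2L * min_sep, 2500L)
                else len - 1L
    span <- min_sep + sample.int(max(max_span - min_sep, 1L), 1)
    a <- sample.int(len - span + 1L, 1) - 1L
    ev <- Event(kind, a, a + span)
    evs[[i]] <- ev
    p <- apply_event(p, ev)
  }
  list(events = evs, painting = p, region_len = region_len)
}

# base-level string-editing oracle for scenarios (independent of the painting
# algebra): operates directly on a character vector of bases
oracle_edit <- function(seq_chars, events) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  s <- seq_chars
  for (e in events) {
    idx <- (e$start + 1L):e$end
    if (e$kind == "inversion") {
      s[idx] <- unname(comp[rev(s[idx])])
    } else {
      s <- s[-idx]
    }
  }
  s
}

# independent novel-junction counter: inspects wild-type adjacency of
# consecutive derived bases through lift_over, plus terminal scars
oracle_junction_count <- function(painting, region_len) {
  n <- painting_length(painting)
  bnd <- cumsum(painting$wt_end - painting$wt_start)
  internal <- 0L
  for (d in bnd[-length(bnd)]) {
    a <- lift_over(painting, d - 1L)
    b <- lift_over(painting, d)
    adjacent <- a$strand == b$strand &&
      ((a$strand == 1L && b$wt_pos == a$wt_pos + 1L) ||
       (a$strand == -1L && b$wt_pos == a$wt_pos - 1L))
    if (!adjacent) internal <- internal + 1L
  }
  first <- lift_over(painting, 0L)
  last <- lift_over(painting, n - 1L)
  scars <- as.integer(!(first$strand == 1L && first$wt_pos == 0L)) +
    as.integer(!(last$strand == 1L && last$wt_pos == region_len - 1L))
  internal + scars
}

# direct sequence-scan PCR oracle on a rendered allele sequence
oracle_pcr <- function(allele_seq, wt_seq, primers, max_product = 5000L) {
  allele <- Biostrings::DNAString(as.character(allele_seq))
  hits <- list()
  for (i in seq_len(nrow(primers))) {
    fp <- Biostrings::subseq(wt_seq, primers$wt_start[i] + 1L, primers$wt_end[i])
    if (primers$strand[i] == "-") fp <- Biostrings::reverseComplement(fp)
    # a '+' primer binds where its sequence occurs on the allele; a '-'
    # primer where its reverse complement occurs
    plus_site <- Biostrings::matchPattern(as.character(fp), allele)
    minus_site <- Biostrings::matchPattern(
      as.character(Biostrings::reverseComplement(fp)), allele)
    hits[[i]] <- list(fwd = BiocGenerics::start(plus_site) - 1L,
                      rev = BiocGenerics::end(minus_site))
  }
  prods <- list()
  for (i in seq_len(nrow(primers))) for (j in seq_len(nrow(primers))) {
    if (i == j) next
    for (s in hits[[i]]$fwd) for (e in hits[[j]]$rev) {
      size <- e - s
      if (size > 0 && size <= max_product &&
          s + (primers$wt_end[i] - primers$wt_start[i]) <= e -
            (primers$wt_end[j] - primers$wt_start[j]))
        prods[[length(prods) + 1L]] <- data.frame(
          fwd = primers$name[i], rev = primers$name[j], size = size)
    }
  }
  if (!length(prods))
    return(data.frame(fwd = character(0), rev = character(0), size = integer(0)))
  unique(do.call(rbind, prods))
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# toy region with one gene for small structural tests
toy_region <- function() {
  g <- GeneModel("TOY", "+", cbind(c(100L, 300L, 500L), c(200L, 400L, 600L)),
                 strict = FALSE)
  RegionMap(1000L, list(g), c(BP1 = 250L, BP2 = 450L))
}
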
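---
title: "Reconstructing the lavender allele: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing the lavender allele: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lavrec)
```

## The problem

The *lavender* plumage-dilution allele of the Japanese quail is not a point
mutation but a complex structural allele: two overlapping chromosomal
inversions followed by an overlapping deletion, acting on a ~60-kb window
that carries *MLPH*, *PRLH*, *RAB17* and the first exon of *LRRFIP1*. Six
wild-type breakpoints (BP1 < ... < BP6) and four novel junctions in the
derived allele (R1-R4) describe the rearrangement; the deletion removes
*MLPH* beyond exon 9, the whole of *PRLH* and most of *RAB17*, making the
allele a natural *PRLH* knockout. This package implements, as reusable
tested code, the full chain of inference by which such an allele is
characterised - tiled-PCR deletion screening, chromosome-walk junction-read
interpretation, parsimonious reconstruction of ordered events with exact
coordinate bookkeeping, and assay/consequence prediction - together with the
phenotype statistics used to associate the allele with growth, feed intake
and body temperature.

## The segment-painting algebra

A derived allele is represented as a **segment painting**: an ordered list of
strand-signed wild-type intervals, `(wt_start, wt_end, orient)`, with
orientation `-` meaning the segment reads as the reverse complement of the
wild-type plus strand. All coordinates are 0-based and half-open; GFF3 and
FASTA conversion happens only at the I/O boundary. Events (`inversion`,
`deletion`) are given in the coordinates of the allele state they apply to
and are applied sequentially, mirroring the stepwise narrative in which such
rearrangements are described. An inversion reverses segment order and flips
orientations inside its interval, splitting boundary segments; a deletion
removes its interval. Paintings are kept canonical: adjacent segments that
are wild-type-contiguous with equal orientation are merged, so every internal
boundary of a canonical painting is a novel junction. Junctions are named
R1, R2, ... in ascending derived coordinate.

`lift_over()` and `lift_to_derived()` give exact position-level liftover in
both directions; `apply_scenario()` additionally tracks the **fate** of every
atomic wild-type segment (the partition induced by all event-endpoint
images): which events touched it, whether it survived, and where it landed.
For the default fixture this bookkeeping exhibits the two structural
signatures of the allele: a unique 2.2-kb segment (between BP4 and BP5)
touched by all three events and finally deleted, and the 246-bp segment
(between BP5 and BP6) that survives both inversions and ends up adjacent to
the deletion scar.

## Evidence channels

**Screening.** A tiled amplicon panel is called present/absent per allele by
structural in-silico PCR: an amplicon fails if a primer footprint is
destroyed (deleted or split by a junction) or if the primer images no longer
face each other within `max_product` (default 5,000 bp) on the derived
allele. Maximal runs of absent amplicons become missing blocks; the gaps to
the flanking present amplicons are the breakpoint candidate windows. These
inner windows are what a bench screening reports, and they contain the true
breakpoints whenever the flanking amplicons do not straddle them (true in
the default panel, whose flanking amplicons end within 1 kb of the
breakpoints). Because an absent amplicon can itself straddle a breakpoint,
`screen()` also reports outer bounds (`lo_outer`, `hi_outer`) extending to
the far end of the first/last absent amplicon; those bounds provably contain
the true breakpoints under the calling model, and the randomized property
tests assert exactly that.

**Walk reads.** Chromosome-walk products are interpreted by greedy maximal
exact matching from the read's 5' end against both strands of the wild-type
region (`min_anchor` 20 bp, `merge_tol` 5 bp). Synthetic reads are
error-free, so matching is exact by design; alignment with mismatches is out
of scope. Matched blocks that are wild-type-contiguous on the same strand
within `merge_tol` are merged; consecutive blocks become strand-aware
breakend observations, deduplicated against their reverse-complement
reading and cross-checked against the screening windows.

The fixture reads deserve a note, because the geometry forces a choice. In
the derived allele the translocated 246-bp fragment sits *between* the two
proximal junctions R1 and R2, which are only 246 bp apart. A read anchored
well inside the proximal flank and crossing both junctions therefore matches
*three* locations. The walk-up read reported for this allele matched two
locations, with the second on the opposite strand; the package reproduces
this by anchoring the walk-up read so close to the proximal breakpoint that
fewer than `min_anchor` bases of flank precede R1 - emulating a nested
primer abutting the breakpoint - so the first reportable match is the
246-bp fragment itself and the second is the opposite-strand inverted
content. The walk-down read is taken in the opposite direction, from the
inverted content across R2 and R1 into the proximal flank; it matches three
locations whose middle block is the 246-bp fragment on the negative strand.
A read anchored distal of the *last* junction (R4) can never show a 246-bp
middle block, because the segment adjacent to R4 is 28.5 kb long; this is
why the walk-down read is anchored on the distal side of the junction
*pair* rather than of the whole allele. The generator also edits, at most,
one base adjacent to each junction so that exact matches terminate exactly
at junction boundaries in both read directions; without this a match can
extend a base or two past a junction by chance and shift the reported block
lengths.

## Parsimony reconstruction

`enumerate_scenarios()` searches for the shortest ordered event sequences
that turn the wild-type organisation into a target painting. The target's
wild-type boundaries cut the region into atomic segments; every painting
reachable by cutting at (images of) those boundaries is a signed arrangement
of atoms, which is the state representation. The search is plain
breadth-first with canonical-state deduplication and two safe prunes:
deleting an atom that the target retains is irrecoverable, and an admissible
lower bound (each inversion repairs at most two wrong adjacencies among
retained atoms; at least one deletion is needed while surplus atoms remain)
discards states that cannot finish within the depth bound. All scenarios of
the minimal length are returned; scenarios are compared by their painting
*trajectories*, since junction data cannot distinguish endpoint relabelings
that traverse the same states. For the default fixture the minimal length
is 3, the returned set contains the printed trajectory (inversion of
30.9 kb, overlapping inversion of 16.4 kb, overlapping deletion of 16 kb,
each measured in the state where it occurs), and exhaustive search to depth
2 proves no two-event explanation exists.

`solve_coordinates()` turns printed distances into breakpoint positions.
Each event length is interpreted as measured in the allele state in which
the event occurs (the solver also tries a plain wild-type-frame reading and
reports which interpretation satisfies the set). Values printed at 0.1-kb
precision carry a 50-bp tolerance; two-significant-figure spans ("60 kb",
"30 kb") are soft constraints at 10%. With BP1 fixed at 0 the five hard
constraints determine the positions uniquely:
(BP1..BP6) = (0, 13800, 27754, 56208, 58408, 58654). Infeasible systems
return a report naming a minimal conflicting subset rather than raising.
One printed distance is deliberately left soft and unsatisfied: the 246-bp
fragment is described as translocated "30 kb" by the two inversions, but
forward simulation puts its pre-deletion displacement at 42.4 kb; no frame
interpretation we tried reconciles the figure, so the solver reports the
residual instead of forcing it. Likewise the "3 kb" distance attributed to
the third walk-down location has no frame under the simulated geometry and
is omitted from the default constraint set.

## Assay and consequence prediction

In-silico PCR maps each primer's wild-type footprint through the painting
(split or deleted footprints are unbindable) and emits a product for every
inward-facing opposite-strand pair within `max_product`. The three-primer
genotyping fixture places Gen_F in the conserved proximal flank, Gen_wt_R
inside the deleted content and Gen_lav_R inside the inverted content, giving
the 423-bp wild-type and 630-bp lavender bands, the latter spanning the
junction pair; `call_genotype()` turns band patterns into `+/+`, `lav/+`,
`lav/lav` or `no-call` with a 20-bp size tolerance. RT-PCR prediction is
purely structural: an exon pair amplifies iff both exons are fully retained
within the same unbroken wild-type run of the derived allele. Gene-level
consequences are `deleted` (no exon base retained), `truncated` (some exons
fully retained, others lost), `rearranged` (all exons retained but no longer
in one unbroken run) or `intact`; for the default fixture this yields MLPH
truncated to exons 1-9, PRLH deleted, RAB17 reduced to its detached first
exon, and LRRFIP1 rearranged but not deleted.

## Phenotype models

**Growth.** The monomolecular (Brody) model W(t) = A - B e^(-kt) is fitted
by multi-start Levenberg-Marquardt least squares (A: asymptotic weight in g;
B: weight range in g; k: relative growth rate per day; convergence 1e-8 on
relative parameter change). The printed formula writes the model as
"A - B^-kt"; a literal power-of-B reading is dimensionally and biologically
implausible (it would make weight dimensionless in B), so the package reads
it as the standard monomolecular form. Degenerate inputs - no weight range,
fewer than four distinct ages - return an explicit failure report.

**Residual feed intake.** RFI is the residual of an ordinary least-squares
regression of feed intake on body-weight gain and metabolic body weight,
plus egg mass in females, exactly as the sex-specific printed equations
specify. Metabolic body weight is body weight raised to 0.75; the exponent
is configurable. The printed coefficients (female intercept 23.3, 6.56 on
MBW, with 3-week feed intakes near 500 g) only balance dimensionally if MBW
is taken on the gram scale (about 49 for a 180-g bird), so the generator
emits MBW = (BW in g)^0.75; on the kg scale the MBW term would be
negligible and its coefficient unidentifiable.

**Model comparison.** `compare_models()` fits trait ~ family + sex +
genotype (plus a covariate for ANCOVA traits) against the reduced model
without genotype, reporting both R² values, their difference, and the
nested-model F test. Whether the printed R² percentages derive from Type I
or Type III sums of squares is not stated; the nested-model comparison is
the one quantity invariant to that choice, so it is what the package
reports and what tests assert on.

## The synthetic-data generator

The generator is the package's definition of the study conditions; every
draw is a pure function of (config, seed).

* Region: breakpoint spacings come from `solve_coordinates()` at run time;
  5-kb flanks on both sides hold MLPH exons 1-9 (proximal) and LRRFIP1
  exon 2 (distal). Gene placements satisfy the qualitative containment
  statements (PRLH wholly and RAB17 exons 2-4 between BP1 and BP2, RAB17
  exon 1 just distal of BP2, LRRFIP1 exon 1 inside the first inversion);
  exact spacings within those constraints are free parameters fixed once.
  The sequence is uniform random ACGT with junction-context editing as
  described above, and breakpoint neighbourhoods are verified free of
  repeated 20-mers (matching the observation that the real breakpoints show
  no repeat structure, and required for unambiguous exact matching).
* Panel: 16 amplicons of 600 bp; four proximal (the last ending 300 bp
  before BP1), eight tiling the deleted content, four in the retained
  inverted segment (the first starting 150 bp after BP2), giving the
  4-present / 8-absent / 4-present screening pattern with both candidate
  windows under 1 kb.
* Reads: 850 bp, walk-up with a 10-bp sub-anchor flank residue before R1,
  walk-down ending 300 bp distal of R2.
* Phenotypes: growth cohort 59 lavender / 66 wild-type from 21 families,
  feed trial 51 / 41 from 18; genotype growth-parameter means as printed
  (A = 204.4 vs 215.9 g, B = 221.4 vs 233.0 g, k = 0.0405 vs 0.0401/day),
  decomposed into family (SD 10 g on A and B), sex (+-8 g) and residual
  components that reproduce the printed total dispersions; weekly weights at
  7-63 days with 4-g measurement noise. Feed intake follows the printed
  sex-specific equations with a genotype shift on the residual
  (means +19.2 vs -22.8 g, SDs 33.5 vs 24.4 g); egg-mass dispersion (SD
  27 g) derives from the printed egg number and egg weight dispersions.
  Body temperature carries a -0.14 degC genotype shift and a small body
  weight slope for the ANCOVA path. With these choices the female feed
  regression recovers R² near the printed 0.57; the male R² stays near
  0.5 rather than the printed 0.72, because the male covariate spread in
  the real cohort is not recoverable from the published tables - the male
  check is therefore coefficient recovery, not R² matching.

## What passing tests do and do not show

The generator emulates structure, not biology: sequences are uniform random
(no GC structure, repeats or transposable elements), reads are error-free
Sanger-length substrings, PCR is purely geometric (no thermodynamics or
primer-dimer artefacts), phenotype noise is Gaussian and family effects are
plain mean shifts. Passing tests therefore demonstrate that the inference
machinery is correct under its stated model - exact liftover, complete
minimal-scenario enumeration, consistent screening and assay logic,
well-calibrated statistics - not that any particular wet-lab protocol would
succeed. The per-bird values of the published phenotype tables, the
prolactin assay results and the 6/19/23 genotype counts of the informative
cross are properties of the real animals and are deliberately not
reproduced; the package instead requires its own generator's parameters to
be recoverable at cohort scale (growth-parameter means within 2 SE, printed
regression coefficients within 2 SE, genotype ΔR² within the Monte-Carlo
band the generator itself implies).

## Numerical and scale choices

Default problem sizes keep everything deterministic and fast: the fixture
region is 68,654 bp, the breadth-first search explores at most a few
thousand canonical states at depth 3 (sub-second), and the randomized
property suites use 8-kb regions with 1-3 events, 500-bp minimum endpoint
separation, and 200 seeded reconstruction trials. Ties in the coordinate
solver are broken by the weighted least-squares solution with BP1 anchored
at 0; all positions are integers and every hard-constraint residual is
re-verified by forward simulation after rounding. Walk matching breaks ties
between equally long candidate matches by taking the first; the generator's
repeat-free guarantee around breakpoints makes ties vanishingly unlikely.

## Worked example

```{r example, eval = FALSE}
cfg <- lav60_config(seed = 1)
reg <- make_region(cfg)
sim <- make_allele_and_reads(reg, config = cfg)

# reconstruct from the derived painting alone
res <- enumerate_scenarios(reg$region, sim$painting, max_events = 3)
sapply(res[[1]]$events, function(e) e$end - e$start)

# evidence channels
interpret_walk(sim$reads[["walk_up"]], reg$seq)
pan <- make_panel_and_calls(reg, sim$painting, config = cfg)
screen(pan$panel, pan$wt_calls, pan$mut_calls)

# consequences and phenotype association
annotate_consequences(reg$region, sim$painting)$MLPH$retained_exons
ph <- make_phenotypes(cfg)
```

The same computation, end to end, is what `scripts/acceptance.R` runs.
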
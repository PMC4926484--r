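---
title: "Inferring tandem-duplication/random-loss histories in mitochondrial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring tandem-duplication/random-loss histories in mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitotdrl)
```

## The problem

Insect mitochondrial genomes are circular molecules of roughly 15-17 kb
carrying 37 genes (13 protein-coding genes, 2 rRNAs, 22 tRNAs) and a
control region (CR). Most insects share one ancestral gene arrangement, but
some lineages carry rearranged orders, and the mechanism invoked most often
is tandem duplication/random loss (TDRL): a contiguous block of genes is
duplicated in tandem, and one copy of each duplicated gene subsequently
decays into a pseudogene and eventually disappears. Which copy is lost
determines the new order. Occasionally a duplicated tRNA escapes loss by
*remolding*: a point mutation in its anticodon gives it a new decoding
identity, leaving a supernumerary tRNA that resembles its donor family far
more than the family it now serves.

A TDRL hypothesis is testable against three kinds of sequence evidence:

1. the derived gene order must be reachable from the ancestral order by a
   duplication block plus a copy-fate assignment;
2. remolded tRNAs must show high identity to a cross-family donor, low
   identity to their own family, and a small anticodon edit;
3. lost copies should leave detectable pseudogene remnants *in the
   intervals predicted by the scenario* (between the surviving neighbors of
   the lost copy).

This package implements that test end-to-end: composition and codon-usage
statistics, tRNA analysis with a cloverleaf validator, local-alignment
scanning of non-coding regions (NCRs) for remnants, exhaustive enumeration
and evidence-ranking of single-TDRL scenarios (with a bounded two-event
search), and a simulator that generates annotated genomes with known
histories so that every stage can be validated against ground truth.

## The TDRL scenario model

A gene order is a circular list of signed labels (sign = strand); the CR is
treated as a gene-like token because duplication blocks can include it. A
single TDRL event is a pair (block, fates): a contiguous block of the
linearized source order plus one fate per block gene, `keep_left`,
`keep_right` or `keep_both`. `keep_both` models remolding-enabled retention
and is permitted only for genes nominated as remold donors (e.g. trnM when
an extra Ile tRNA looks like a mutated Met duplicate). Applying an event
means writing the block twice and deleting the unwanted copies.

`enumerate_single_tdrl()` searches blocks and fate maps exhaustively and
keeps every scenario whose application reproduces the derived order
exactly, where a remolded gene in the derived order is first relabeled to
its donor (`remold_map = c(I2 = "M")`) and positional duplicate numbers are
stripped against the source vocabulary (I1 matches I; L1 does not become
L, because the source itself distinguishes L1 and L2). For orders short
enough to afford it (up to the window guard) every block is searched, which
makes the enumeration provably complete in the linearized frame against a
brute-force oracle; for genome-scale orders the search is restricted to
blocks covering the rearranged window after trimming common flanks — blocks
may still extend into the conserved flanks, because a flank gene duplicated
and resolved either way leaves the order unchanged but leaves a different
remnant trail. Blocks wrapping the linearization seam of a genome-scale
order are not searched; with 30+ conserved genes pinning the frame this
excludes only scenarios with implausibly long blocks.

Each lost copy yields a *remnant prediction*: the donor gene plus the
ordered pair of surviving neighbor labels in the derived order (consecutive
lost copies share an interval). `concordance_score()` counts the observed
remnants that match a prediction on donor and unordered neighbor pair.
Unmatched predictions are reported but not penalized (default penalty 0): a
lost copy may decay beyond recognition, as short tRNA-sized remnants often
do. `rank_scenarios()` orders scenarios by matched evidence (descending),
unmatched predictions (ascending), block length, block start and fate
string — a deterministic total order.

Two notes on circularity. Rotation-invariant equality means a two-gene
order `I-Q` *is* `Q-I`; the familiar `I-Q -> Q-I` swap of flat bugs is only
a rearrangement in the context of flanking genes, and the minimal-event
search finds k = 1 as soon as one flanking gene pins the frame. Inversions
are out of scope by design: strand signs ride through duplication
unchanged, and an order requiring inversion is reported as not explained by
TDRL.

## Alignment machinery

Pairwise tRNA comparisons use an in-package Needleman–Wunsch (match +1,
mismatch −1, gap −2); identity is matches over aligned columns, with
mismatch counts excluding gap columns. The remnant scanner uses an
in-package Smith–Waterman with affine gaps (+1/−1, gap open −2, extend −1),
implemented in C++ with linear-memory score passes and a windowed
traceback. Ambiguity codes score zero and count as neither match nor
mismatch. Tie-breaks are deterministic (best score, then smallest end
coordinates, traceback preferring the shortest alignment and diagonal
moves). Both kernels are checked in the test suite against brute-force
alignment-path enumeration on short strings and against an independent R
dynamic program on longer ones.

### Significance floor in the remnant scan

`pseudogene_scan()` reports hits with length ≥ 20 aligned columns and
identity ≥ 70% — *and* score ≥ 20 (the score of a perfect 20-mer). The
score floor matters: the optimal local alignment between two unrelated
sequences of gene length under ±1 scoring typically spans 20–40 columns at
70–80% identity (match fraction `p·e^λ` ≈ 0.75 for random DNA), so the
length and identity filters alone would admit a hit for most random
query–donor pairs. Requiring score ≥ 20 puts the threshold several
Gumbel-decades above the random expectation (≈ 10–14 for the sequence
lengths involved) while every remnant of interest passes easily (a 197-bp
remnant with 5 mismatches scores ≈ 187).

A second guard operates at the evidence level. Within one query region a
stretch of sequence has one true origin, and weak claims inside an interval
already explained by a much stronger hit are discarded
(`filter_dominant_hits()`): a hit is dropped when a strictly
higher-scoring hit from a different donor with at least equal identity
covers ≥ 50% of it. The identity condition keeps high-fidelity sub-claims
alive — a near-perfect CR remnant is not swallowed by a longer, weaker
ND2 alignment that happens to extend across it. Without this filter,
PCG-vs-PCG codon-bias similarity occasionally plants a spurious donor in a
remnant-bearing NCR and rewards over-long duplication blocks during
ranking.

## tRNA analysis

Anticodon families use the 22-entry invertebrate-mitochondrial table in DNA
spelling (CAT = Met, GAT = Ile, ...); an RNA spelling is presentation only.
The cloverleaf validator is a fixed-geometry heuristic, not a thermodynamic
folder: acceptor stem of 7 pairs (≤ 1 mismatch, G·T counts as a pair, tried
with and without a discriminator base), a 7-nt anticodon loop with the
anticodon starting at loop position 2–4 closed by a stem of ≥ 4 pairs, and
hairpin searches (≥ 3 pairs) for the D and T arms, with a region that is
present but unfoldable flagged `reduced` — the expected state of the trnS1
D arm in true bugs. Validity requires only acceptor and anticodon arms, so
reduced-D tRNAs validate. On random 70-nt sequences fewer than 5% pass
(measured in the test suite and the acceptance script).

Remold calls require, with defaults separating the observed extremes
(trnI2–trnM ≈ 95% vs. trnI1–trnI2 well below 70%):

* candidate-to-donor identity ≥ 85% (cross-family);
* candidate-to-own-family identity < 70%;
* an anticodon edit of 1–2 positions;
* the candidate's family is represented by at least one other copy.

The last condition is this package's resolution of a symmetry problem: the
first three conditions are symmetric in candidate and donor whenever the
donor has no second family copy (the own-identity condition is then
vacuous), so trnM would be called a remold of Ile on the same evidence that
calls trnI2 a remold of Met. Remolding creates a supernumerary member of
the *recipient* family, so the candidate must be an extra copy; the sole
Met representative is not. With this rule the simulator's planted remolds
are recovered with zero false calls across seeds.

## The simulator

`simulate_genome()` is the package's ground-truth engine, not a test
fixture: it draws per-gene sequences at a target AT content of 0.672 (the
J-strand AT fraction of the study system), builds PCGs in frame with ATG
starts, TAA stops and no internal stops under translation table 5, draws
rRNAs and the CR (1251 bp with a planted 10-bp G element) as biased random
sequence, and instantiates each tRNA from a cloverleaf-consistent template
with randomized stems — so every tRNA folds by construction while
different families remain mutually dissimilar (~55–65% identity), which is
what keeps remold detection honest. Small spacers (≤ 15 bp) separate some
genes.

TDRL events are applied at the segment level and cross-validated against
`apply_tdrl()` on the gene order. Lost copies decay *in place*: they are
truncated (5'-anchored) and substituted per site, never excised, so NCR
lengths grow with event history and the scanner has real remnants to find.
The study-mimic configuration (`paper_mimic_config()`) duplicates
CR–trnI–trnQ–trnM–ND2, keeps CR/Q from the left copy and I/ND2 from the
right, retains both trnM copies and remolds the upstream one into trnI2
(CAT→GAT plus two site mutations). Truncations keep 28 bp of trnI, 605 bp
of ND2 and 197 bp of CR with trnQ fully lost; substitution rates (0.10,
0.18, 0.025) land the remnants near the identities reported for the real
genome (≈ 90%, ≈ 82%, ≈ 97.5%). Substitutions are uniform over the three
alternative bases and there is no indel model beyond terminal truncation,
which keeps identity accounting exact. All randomness comes from one
stream keyed by the seed; emission (`emit_genome()`) is byte-deterministic.

What the simulator does not emulate: realistic substitution processes
(transition bias, rate heterogeneity), selection on codon usage, gene
overlaps, duplicated control-region motifs, and homology *between* gene
families beyond what shared codon bias induces. Passing recovery tests on
simulated data therefore demonstrates the inference machinery is sound
given remnants of the modeled kind, not that real annotations are
error-free or that real NCR homology is always this clean.

## Statistics

AT-skew is (A−T)/(A+T) and GC-skew (G−C)/(G+C), computed from counts and
rounded only for presentation. RSCU is count × family size / family total
over the concatenated PCGs, with stop codons and incomplete terminal codons
excluded (the usual convention; a flag restores stops). Note that under
translation table 5 ATA is Met, so the Ile family is ATT + ATC only.

The codon deviation test is a 1-df goodness-of-fit chi-square of one
species' (ATT, ATC) counts against an expected proportion taken from a
reference panel, by default the mean of per-species proportions
("average value" reading), with pooled counts as the alternative. The test
treats the panel mean as known; its null calibration in the acceptance
suite therefore draws the target at the realized panel mean, where the
nominal 5% level is held (10,000 replicates, within the binomial interval).
Re-estimating the panel mean independently each replicate would inflate the
size by roughly (1 + 1/13) — a property of any plug-in reference panel, not
of this implementation. Expected cells below 5 raise a small-sample flag.

## Problem sizes and defaults

The shipped analyses and checks run at sizes chosen to exercise every code
path at desk scale: full 38-feature genomes (~16–17 kb) for the pipeline;
50 simulated histories for end-to-end recovery (target ≥ 90% top-rank
recovery, remold recall 100%); enumeration-versus-brute-force on all orders
up to 5 labels; 1,000 random apply-then-enumerate round trips; alignment
oracles exhaustive to length 3 (full path enumeration) plus sampled pairs
to length 8; 10,000 null replicates for the deviation test. The
single-event window guard is 12 labels (≈ 78 blocks × 3^12 fate maps worst
case) and the two-event search is guarded at 8.

## Known limitations

* Only TDRL (plus anticodon-mutation remolding) is modeled; transposition,
  inversion, tandem duplication/non-random loss and recombination are
  reported as "not explained" rather than inferred.
* Scenario timing is not modeled: losses are atomic, and one- versus
  two-step histories with identical end states are distinguished only by
  event count.
* The remnant scanner's identity is alignment-defined (matches over
  columns under the default scoring); published similarity figures from
  unspecified aligners are comparable only to within a couple of points.
* The GenBank reader handles the LOCUS/FEATURES/ORIGIN subset used by
  mitogenome records (plain and complement locations, two-part
  origin-spanning joins); it is not a general GenBank parser.
* The two-event search enumerates compositions of bounded single events
  and is exponential in the window; it is intended for tRNA-scale windows,
  not whole-genome shuffles.
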
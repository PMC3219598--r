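---
title: "Characterizing L1 endonuclease-mediated de novo insertions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing L1 endonuclease-mediated de novo insertions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrochar)
```

## The biological model

LINE-1 (L1) elements and the Alu elements they mobilize insert into the
genome by target-primed reverse transcription (TPRT). The L1 endonuclease
(EN) nicks one genomic strand, preferentially at the degenerate consensus
written 3'-AA/TTTT-5' on the nicked strand; the freed 3' end terminates in a
T-run that anneals to the poly(A) tail of the element transcript and primes
reverse transcription. A second nick on the other strand, typically 7-20 bp
away, creates the target-site duplication (TSD) that ends up flanking the
new copy as a short direct repeat. The finished product on the genomic top
strand is

```
[TSD] [optional non-templated 5' addition] [element body] [poly(A)] [TSD copy]
```

for a sense-oriented insert, or a leading poly(T) followed by the
reverse-complemented body for an antisense insert. Variants of the mechanism
produce 5'-truncated copies, 5'-inverted copies (twin priming, usually with
a few bases of microhomology at the inversion junction), and
deletion-associated insertions in which the second nick falls on the other
side of the first, removing reference bases and leaving no TSD.

`retrochar` reads these products directly from a reference/mutant allele
pair: `characterize_insertion()` resolves the breakpoints, TSD (or target
deletion), tail and orientation; `classify_elements()` assigns the body to
an Alu subfamily or L1 and measures truncation, inversion and the L1
Ta/pre-Ta subset; `infer_nick()`, `annotate_sites()`,
`find_recurrent_sites()` and `find_clusters()` analyze the integration
sites; `name_insertion()` and `classify_splice_effects()` report the
mutation name and the transcript-level consequence.

## Breakpoint and TSD conventions

Two conventions make every reported number deterministic.

**Placement of ambiguous insertions.** When the insert shares sequence with
its flanks (an element head equal to the reference bases after the junction,
a tail run continuing into the TSD), several breakpoint placements describe
the same mutant string. Candidate placements are ranked by

1. minimal 5' truncation of the element body against the template library,
2. maximal duplicated flank (TSD),
3. maximal tail length,
4. leftmost position.

Rule 1 encodes the reading a human analyst applies with the element
consensus in hand: prefer the interpretation in which the element is most
complete. Rule 2 is the classical maximal-duplication convention; the
insertion point is then reported *after the first duplicated copy*, and the
HGVS output names the TSD as a separate `dup` clause.

**Consequences of string maximality.** A TSD measured from sequence alone is
the *longest* duplicated flank. Where a reference base adjacent to the
mechanistic TSD happens to equal the corresponding element or tail base, the
measured flank exceeds the mechanistic one and the first element base is
attributed to the duplication. Three of the eighteen reconstructed cases
carry such coincidences inside their printed sequences; the fixture truth
table records both the printed and the measured values with a
`tsd_flagged` marker, and truncation calls below 5 bp are treated as
full-length in the summary tallies because they sit inside exactly this
attribution ambiguity. No such coincidence affects the targeted quantities
(the 15-bp exon 33 TSD, the 17-bp maximum, the 71-bp deletion, the 39-bp
truncation).

**Nick inference.** The first nick must leave the priming T-run 3' of the
nick on the nicked strand: a sense insert implies a bottom-strand nick at
the top-coordinate left edge of the TSD, an antisense insert a top-strand
nick at the right edge (the post-duplication junction). Under this rule the
three recurrently used integration sites in the reconstructed set coincide
to the base, including the intron 14 (10c) pair where the same cleavage
locus was used once on each strand.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `min_tail` | 10 | nt | shortest homopolymer run accepted as a poly(A)/poly(T) tail |
| `tail_impurity` | 0 | fraction | tolerated non-A/T bases inside a tail run |
| `ppt_window` | 3-20 | intron positions | acceptor window called polypyrimidine tract |
| `grouping_window` | 12 | bp | nick distance merged into one EN motif locus |
| `cluster_window` / `cluster_min` | 1500 / 3 | bp / calls | insertion-cluster definition |
| `min_en_score` | 4 | matches of 6 | EN consensus threshold for simulated sites |

The EN score itself is the strict 0-6 agreement of the six bases around the
nick with AA/TTTT read 3'->5' on the nicked strand; because the source data
apply no numeric cutoff to real sites, none is hard-coded into the
reporting — the score is annotated on every site. The polypyrimidine-tract
window (-3 to -20) and the 12-bp recurrence window are documented,
adjustable conventions chosen to cover the observed acceptor-region
insertions and to treat a shared cleavage locus as one site.

## The simulator and what it does (not) emulate

`simulate_dataset()` generates TPRT products with full ground truth. Its
defaults are the observed study conditions: TSDs uniform on 7-20 bp, tails
uniform on 60-178 bp, L1 categories full-length / 5'-truncated /
5'-inverted with probabilities 0.255 / 0.438 / 0.307, ~8% truncated Alu
inserts, equiprobable orientation, and small probabilities (0.05) for the
target-site-deletion branch (deletion uniform on 10-100 bp, covering the
observed 71-bp case) and for non-templated 5' additions (1-10 random nt;
the one observed addition is 8 nt). Truncation extents are uniform over the
element length and inversion junction microhomologies uniform on 0-4 bp,
because the source reports examples, not distributions. Family weights
default to the observed mixture (2:6:6:3:1 for
AluY:AluYa5:AluYb8:L1:poly(N)). All lengths are drawn uniformly as the
simplest defensible null.

Two deliberate restrictions:

* **Canonical events.** A drawn event is rejected and redrawn when a flank
  coincidence would make its own breakpoints ambiguous (reference base
  before the TSD equal to the cassette's last base, junction base equal to
  its first, a truncated element whose missing base equals the TSD's last
  base, and the analogous inversion-junction cases). Without this, no
  characterizer could recover the drawn values exactly — the ambiguity is a
  property of the strings, not of any algorithm. Real data contain such
  coincidences; on real data the same measurements are reported under the
  documented maximal-duplication convention instead of a hidden truth.
* **No read-level noise.** The simulator produces resolved allele
  sequences, not traces or reads; sequencing error, chimeric PCR products
  and heterozygous mixtures are out of scope. Passing the 100%-recovery
  benchmark therefore demonstrates correctness of the breakpoint
  arithmetic, not robustness to noisy data.

## The reconstructed 18-case fixture set

`build_fixture_set()` rebuilds each published NF1 insertion case on one
shared synthetic gene frame. Exon boundaries are anchored by every printed
transcript-level interval; boundaries the source does not print are
synthetic fill, as are the intron lengths (2 kb by default; introns 21 and
22 are 350 bp so the exon 21-23 region spans ~1.3 kb of genomic sequence,
matching the reported 1.5-kb cluster geometry). Printed integration-site
windows are converted from their nicked-strand 3'->5' orientation onto the
top strand and stamped into the frame together with every printed TSD;
background positions adjacent to breakpoints are chosen so they cannot
extend a printed duplication. Element bodies come from bundled *synthetic*
consensus stand-ins that reproduce the features the pipeline relies on (the
canonical Alu 5' head, subfamily diagnostic substitutions, the Yb8 +7 bp
length excess, L1 ORF geometry and the Ta/pre-Ta ACA/ACG diagnostic site);
they are not Repbase sequences, so fixture distances are exact by
construction rather than estimates of real divergence. Tails printed as a
range use a single value inside the range; tails with no printed estimate
are fixed at 100 nt and excluded from comparisons against printed numbers.

Transcription discrepancies in the printed tables are recorded, not
resolved: two exon skips labelled in-frame whose lengths are not divisible
by 3 (`frame_flagged`), a dup span covering 15 positions for a 13-nt
string, a merged table row carrying two TSD values, and one row whose 7
printed upstream bases exactly equal the reverse complement of the Alu head
and are treated as mutant-allele read-through.

## Worked run

```{r, eval = FALSE}
rep <- reproduce_insertion_tables()
glance(rep)       # 18 cases, 15 sites, 3 reused, 1 cluster, 2/6/6 families
tidy(rep)         # 162 per-case truth checks, all passing
autoplot(rep)     # insertion map with the cluster window shaded

bench <- benchmark_simulation(200, seed = 1)
tidy(bench)       # exact-recovery rate 1.0 for every field
```

Problem sizes used throughout the packaged checks: the 18 reconstructed
cases, 200 simulated events for the recovery benchmark, and 10,000
category draws for the frequency calibration; the fixture frame is ~101 kb.

## Numerical and degenerate-input choices

* Sequences are plain uppercase `ACGTN` strings; alignment (only needed for
  diverged bodies) is delegated to `Biostrings::pairwiseAlignment`
  (global-local, gap open 4 / extend 1), with an exact-substring and an
  anchored ungapped fast path taken first and a length-difference lower
  bound used to skip alignments that cannot win the family argmin.
* Family ties are reported as `unknown`, never broken arbitrarily; a
  diagnostic-site agreement fraction is reported alongside the argmin.
* Identical alleles signal a typed "no variant" condition; a deletion
  interval always implies `tsd_length = 0`; a pure homopolymer insert is
  family `polyN`.
* A leading poly(T) dominates a trailing poly(A) when both are present
  (possible for 5'-inverted products).
* The deletion-associated case cannot have its nick determined from
  sequence; it is reported with a `nick_tentative` flag at the deletion's
  left edge.

## Limitations

* The element library is synthetic; classifications against it validate the
  pipeline's arithmetic, not real subfamily assignment accuracy.
* Splice-effect typing classifies *observed* transcript outcomes against
  the gene model; it predicts nothing from sequence (no splice-site
  strength scoring).
* Donor-side intronic insertions with skipping are accepted as type 1
  symmetrically and flagged as an extension; the source observed only
  acceptor-side cases.
* Genome-scale scanning, read-level evidence and heterozygous mixtures are
  out of scope.
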
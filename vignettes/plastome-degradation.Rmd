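---
title: "Methods: plastome structure detection and gene-loss reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plastome structure detection and gene-loss reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastdeg)
```

This vignette documents the models and procedures implemented in `plastdeg`,
the assumptions behind them, the parameters a user may want to change, and
the choices made where the design was genuinely open.

## The problem

Plastomes of green plants are normally near-invariant in structure: a large
and a small single-copy region (LSC, SSC) separated by two identical
inverted repeats (IRa, IRb), with a stable complement of about 114 genes.
In lineages transitioning toward heterotrophy this conservatism breaks
down: the IR/SSC junctions migrate so that single-copy genes are captured
into (or released from) the repeat, and genes of the NDH complex, `accD`
and `ccsA` decay through premature stop codons, truncation and physical
loss. The package quantifies both processes on a set of annotated plastomes
and reconstructs the history of functional loss on a user-supplied rooted
phylogeny.

## Quadripartite detection

`detect_inverted_repeat()` searches for the maximal pair of disjoint,
exactly reverse-complementary substrings of the circular sequence. Sampled
k-mer seeds (k = 24, stride chosen so that every repeat of at least
`min_len` contains a whole seed) are matched against the reverse complement
of the doubled sequence, then extended without mismatches in both
directions. The defaults encode two assumptions:

* **Exactness.** The two IR copies of a single plastome are copies of one
  molecule and are typically identical; the detector therefore tolerates no
  mismatch. Genuinely divergent IR copies would be truncated at the first
  difference.
* **`min_len = 1000` bp.** Plastid IRs are tens of kilobases; 1 kb is far
  above the background of chance reverse-complementary matches in a ~150 kb
  sequence, and far below any real IR. A genome with no candidate at this
  length is reported as IR-lacking by error, which callers may catch.

Ties among co-maximal candidate pairs are broken by the smallest canonical
start coordinate, making detection deterministic. The partition is returned
in canonical rotation — LSC first, then IRb, SSC, IRa — with IRb defined as
the IR copy immediately followed by the SSC on the forward strand. Detection
is rotation-invariant and strand-covariant (the reverse complement swaps the
IRa/IRb labels); both properties are tested.

## IR boundary typing

`classify_ir_type()` is a pure function of landmark-gene placement
(*ycf1*, *ndhF*, *ndhH*, *ndhA*). Because annotation boundaries jitter by a
few bases, a gene counts as "in the IR" when at least 95% of its span lies
inside the repeat and "spans" a junction when both sides hold at least 5%;
these fractions are arguments of the internal placement helper. Annotated
pseudogene remnants count as landmarks — the alternative (intact genes only)
would leave most degraded genomes untypeable, and the evidence table records
the pseudo flag so users can filter. The type IV "inverted *ndhA*" test is
relative: *ndhA* is called inverted when its annotated strand differs from
*ndhF*'s, the two genes sharing a strand in the ancestral (type I)
arrangement.

## Gene functionality calling

`locate_gene()` finds a possibly degraded gene by seeding k-mers (k = 15)
of the intact reference CDS on both strands of the (doubled, for
circularity) genome, clustering the implied gene starts, and aligning the
reference to the best window by gapped local alignment (match 2, mismatch
−3, gap open 6, extend 2). From the alignment it derives coverage of the
reference, percent identity, frameshift-inducing indels (gap runs with
length ≢ 0 mod 3) and internal stop codons, the latter by translating the
matched genomic segment in the reading frame implied by the alignment start
(genetic code table 11; GTG and TTG accepted as intact plastid starts).

`classify_gene_state()` maps the hit to the four-state degradation code:

| state | meaning | rule (defaults) |
|---|---|---|
| 3 | complete loss | no hit with identity ≥ 0.6 over ≥ 50 bp |
| 2 | truncated | coverage < `t_trunc` = 0.90 |
| 1 | full-length pseudogene | coverage ≥ 0.90 with ≥ 1 internal stop or frameshift |
| 0 | functional | coverage ≥ `t_full` = 0.95, no defects, intact start and stop |

The thresholds are not taken from any publication — the literature describes
the categories verbally — and were chosen so that the verbal classes
(full-length vs truncated vs lost) separate cleanly on scripted synthetic
edits; all are exposed as arguments. Two boundary policies are worth
stating explicitly: a defect-free hit with coverage in [0.90, 0.95) is
called functional with a "borderline" warning, and a full-length defect-free
hit whose start or stop codon is broken is called state 1, since its reading
frame cannot yield the reference protein. Genes duplicated in the IR are
resolved by the best-scoring copy; since the two repeats are identical
within one molecule this equals calling each copy independently and keeping
the less degraded one.

## Codon and association statistics

RSCU pools all codons of a sample's functional CDS complement into one count
vector (a per-gene mode is available by subsetting the input); stop codons
are excluded and single-codon families (Met, Trp) are reported fixed at 1
and flagged uninformative. GC content always excludes N from both numerator
and denominator.

Spearman's ρ is the Pearson correlation of midrank-transformed values with a
t approximation (n − 2 df) for the p-value. The Mann–Whitney U is reported
for the first sample with ½ credit for ties, matching the convention of
standard statistical software; the p-value is exact by distribution
enumeration when n₁ + n₂ ≤ 20 without ties and a tie- and
continuity-corrected normal approximation otherwise. Both statistics are
verified against brute-force pair-counting and permutation oracles in the
test suite.

## Ancestral reconstruction

**Equal-rates Mk.** The k-state equal-rates model has the closed-form
kernel P(t) with off-diagonal rate μ (see `mk_er_loglik()`); likelihoods are
computed by Felsenstein pruning with per-node rescaling against underflow
and a uniform 1/k root prior. Marginal ancestral probabilities use the
standard two-pass inside/outside algorithm; both are tested for equality
(tolerance 1e-10) with exhaustive enumeration over internal-node
assignments on small trees, and the likelihood is cross-checked against an
independent implementation. The state space is fixed a priori — k = 4 for
multistate runs, k = 2 after binarization — regardless of which states are
observed, because the degradation code defines four states whether or not a
particular dataset exhibits all of them.

The rate is fitted by bounded scalar maximization on [1e-8, 1e3]. The
search runs on the log scale: the profile likelihood is flat over almost
all of that interval on a linear axis, and a linear golden-section search
can converge on the high-rate plateau without ever sampling rates below 1.
Invariant characters drive the estimate to the lower bound and are flagged.
Branches without lengths are assigned length 1.0 with a warning — relevant
for the packaged tree, whose source branch lengths are unpublished; all
likelihood-based node supports on that tree are therefore qualitative.

**Dollo parsimony.** The derived (lost) state arises exactly once, on the
branch subtending the MRCA of all derived tips (the root when that MRCA is
the root); inside the origin clade every maximal all-ancestral subtree
receives one reversal on its stem. This minimizes reversals subject to the
single-origin constraint, which the tests verify against exhaustive search
over all single-origin histories on six-taxon trees. The three binarization
schemes (`functional`: 0 vs 1/2/3, `complete`: 0/1 vs 2/3, `existing`:
0/1/2 vs 3) let the same machinery answer "when did function go", "when did
full length go" and "when did the sequence go". Note that under a strict
single-origin model a clade-wide reversal followed by a *second* loss
inside that clade is inexpressible; histories of that shape appear instead
as multiple tip-level reversals.

## The synthetic-data generators

`synthesize_plastome()` assembles LSC + IRb + SSC + IRa with IRa the exact
reverse complement of IRb, stop-free CDS with ATG starts and TAA stops,
spacers drawn at per-region GC targets (compositionally exact sampling, so
measured region GC tracks the target to within a few tenths of a
percentage point), and the four junction architectures implemented as
capture of the SSC gene prefix (*ycf1*, *ndhH*, *ndhA*[, *ndhF*]) into the
repeat. Default region targets (LSC 83 kb, IR 25.6 kb, SSC 17.6 kb, GC
0.365/0.43/0.325) and gene lengths follow typical plastid values of the
study group, so a default type I genome is ~152 kb and a type II genome
~162 kb with a ~7.8 kb SSC. Bases flanking the repeat are forced to break
reverse complementarity so that the planted IR is exactly maximal and
detection can be scored against coordinates, not approximately.

Scripted edits (`premature_stop`, `frameshift`, `truncate`, `delete_all`)
implement the degradation classes with their expected states; a cohort
generator reuses one set of gene sequences across taxa so that members are
genuinely homologous, which is what makes reference-based calling
meaningful.

What the generator does **not** emulate: substitution divergence between
taxa (cohort genes are identical up to the scripted edits), introns and
RNA editing, intergenic sequence evolution, annotation error, and gradual
IR boundary creep (architecture is switched discretely by type). Passing
recovery tests on these genomes therefore demonstrates correctness of the
detection/calling logic under clean conditions, not robustness to the full
noise spectrum of real assemblies — real data with highly divergent
remnants (identity near the 0.6 floor) or IR copies that differ will
degrade more gracefully in coverage/identity than these tests exercise.

Character simulators (`simulate_mk()`, `simulate_dollo()`) retain full
node-state truth; the Mk simulator is checked for stationarity and for
per-branch transition frequencies against the kernel, the Dollo simulator
enforces its single-origin constraint by construction.

## The packaged study fixture

`fixture_table1()` transcribes the published 22-sample survey (13 samples
of *Pedicularis* sect. *Cyathophora*, 5 other *Pedicularis*, 4 outgroups):
region sizes and GC, gene counts, and the 22 × 13 degradation-state matrix
(11 NDH genes, `accD`, `ccsA`; a gene absent from a sample's pseudogene
list is functional). Known internal inconsistencies of the printed source
are kept and listed in `$errata` rather than silently resolved; the one
substantive judgement call — *ndhG* in *P. rex* var. *rex*, where the
printed list and the running text disagree — follows the text (functional),
which is also the only reading consistent with the published
three-reversal history of *ndhG*.

`fixture_tree()` assembles the reported topology with unit branch lengths.
One grouping deserves note: (*P. insignis*, *P. przewalskii*) is taken as a
clade sister to the section. The published gene-loss counts at the
section's ancestor are only reproducible under Dollo if these two samples
form a clade (otherwise the *ndhB*/*ndhC* origins would be pulled to deeper
nodes); this is recorded as a fixture assumption, not a result.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on generated data and
the packaged tables: structural recovery uses full-size (~150–160 kb)
genomes across all four IR types and five seeds each; gene-state recovery
scores 200 scripted edits on a 17-genome cohort; likelihood code is checked
on exhaustive oracles at ≤ 5 tips and k ≤ 4, rate recovery on a 64-tip tree
with 200 characters simulated at μ = 0.5. Unit tests reuse the same
machinery on compact templates (~65 kb) where genome size is irrelevant to
the property under test. Other numerical choices: likelihood rescaling
kicks in below 1e-150 per node; marginal probabilities are normalized per
node and verified to sum to 1 within 1e-9; NG86 pathway averaging excludes
pathways through stop codons and falls back to including them only when
every pathway is blocked, with saturation (p ≥ 3/4) reported as a warning
and `NA` distance rather than an error so that the raw counts remain
available.

## Known limitations

* IR detection is exact-match only; a flag for mismatch tolerance is
  reserved but unimplemented.
* Gene location assumes the remnant is recognizably similar (identity ≥ 0.6
  over ≥ 50 bp) to a single reference CDS; extremely diverged or
  rearranged remnants fall through to "lost".
* The Mk machinery implements the equal-rates model only (no asymmetric
  rates, no joint/MAP reconstruction, no stochastic mapping).
* The dN/dS screen is pairwise counting (NG86); it is a screen, not a
  substitute for branch-site codon models, and no hypothesis tests on ω are
  provided.
* The packaged tree carries no meaningful branch lengths, so ER-based node
  supports on it are qualitative by construction.
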
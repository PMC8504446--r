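# plastdeg

Comparative analysis of plastid genome (plastome) structure and gene
degradation, aimed at studies of hemiparasitic and heterotrophic plant
lineages in which the normally ultra-conserved plastome starts to decay:
inverted-repeat boundary shifts, pseudogenization of the NDH complex and of
`accD`/`ccsA`, and the reconstruction of when along a phylogeny each gene
lost (or regained) function.

The package is written for plant molecular evolution researchers who have
annotated plastomes (GenBank flat files), a rooted species tree (newick) and
want a reproducible desk-scale pipeline from raw structure to ancestral-state
inference.

## What it computes

**Quadripartite structure.** A circular plastome is partitioned into
LSC / IRb / SSC / IRa by finding the maximal pair of disjoint, exactly
reverse-complementary substrings (the inverted repeat), reported in canonical
rotation with per-region lengths and GC. The IR/SSC junction architecture is
typed from the placement of the landmark genes *ycf1*, *ndhF*, *ndhH*,
*ndhA*:

* type I — *ycf1* spans the SSC/IRb junction; *ndhF*, *ndhH*, *ndhA* in the SSC;
* type II — all four landmarks captured into the IR;
* type III — *ycf1*, *ndhH*, *ndhA* in the IR, *ndhF* released;
* type IV — *ycf1*, *ndhH* in the IR, *ndhA* back in the SSC in inverted
  orientation.

**Gene functionality states.** Each target gene is located against an intact
reference CDS (k-mer seeding + gapped local alignment) and scored with a
four-state code: 0 functional, 1 full-length with a premature stop codon (or
frame-disrupting indel), 2 truncated, 3 completely lost.

**Codon and association statistics.** Relative synonymous codon usage
RSCU(c) = n_c · |family(c)| / Σ_{c'∈family(c)} n_{c'} (genetic code table 11),
GC content by region / gene group with deviation matrices, Spearman rank
correlation ρ, and the two-sample Wilcoxon rank-sum statistic
U = #{x_i > y_j} + ½·#{x_i = y_j}.

**Ancestral reconstruction.** For a taxa × gene state matrix on a rooted
tree:

* an equal-rates Mk model (transition kernel
  P_ij(t) = 1/k − 1/k·e^{−kμt}, P_ii(t) = 1/k + (k−1)/k·e^{−kμt}) with
  Felsenstein pruning, maximum-likelihood rate fitting and two-pass marginal
  ancestral state probabilities;
* Dollo parsimony — the derived (non-functional) state arises exactly once,
  on the branch subtending the MRCA of all derived tips, and reversals are
  minimized — with per-branch origin/reversal events and per-node loss
  counts, under three binarizations of the four-state code (functional /
  complete / existing).

**Selection screen.** A pairwise Nei–Gojobori (1986) dN/dS with pathway
averaging and Jukes–Cantor correction, as a lightweight per-gene screen (it
is deliberately *not* a branch-site codon-model analysis).

**Synthetic data.** Seeded generators for Yule trees, Mk and Dollo
characters, and fully annotated circular plastomes with configurable IR
type, per-region GC targets and scripted pseudogenization edits — every
generator returns its ground truth, which the test suite uses as oracle.

A packaged fixture carries the published 22-sample survey of *Pedicularis*
sect. *Cyathophora* and relatives: the taxa × gene degradation matrix, the
region size/GC table and the reported tree topology.

## Worked example

```r
library(plastdeg)

fx <- fixture_table1()            # published state matrix + region table
tr <- fixture_tree()              # published topology, unit branch lengths
bm <- binarize(fx$states, "functional")

# Dollo history of ndhG: one origin, three reversals in series Reges
res <- dollo_reconstruct(tr, bm[, "ndhG"])
length(res$reversal_nodes)
#> [1] 3

# losses accumulated in the ancestor of section Cyathophora
ndh   <- paste0("ndh", LETTERS[1:11])
dollo <- sapply(ndh, function(g) dollo_reconstruct(tr, bm[, g]),
                simplify = FALSE)
anc <- summarize_losses(dollo, tr, fixture_groups()$cyathophora)
anc$count
#> [1] 9
anc$genes
#> "ndhA" "ndhD" "ndhE" "ndhF" "ndhG" "ndhH" "ndhI" "ndhJ" "ndhK"

# structure statistics from the printed region table
rg <- fx$regions
mann_whitney_u(rg$ir_bp[rg$group == "cyathophora"],
               rg$ir_bp[rg$group == "outgroup"])$U
#> [1] 52                                   # complete separation of IR sizes
spearman_rho(rg$ir_bp, rg$ir_gc)$rho
#> [1] -0.9866322                           # larger IR, lower IR GC
```

Nine of the eleven NDH genes were already non-functional in the section's
common ancestor; *ndhG* later regained function three times within series
*Reges*; IR expansion is almost perfectly rank-correlated with reduced IR GC
because the expanding repeat swallows AT-rich single-copy sequence.

For sequence-level runs, `run_pipeline()` (or
`inst/scripts/plastdeg-cli.R all config.yaml`) chains partition → IR typing →
gene states → codon/GC statistics → rank tests → ancestral reconstruction and
writes TSV reports plus a JSON manifest.

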
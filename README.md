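# lnct3d — candidate target genes for nuclear lncRNAs from chromatin interactions

Most long non-coding RNAs have no functional annotation. Nuclear lncRNAs
in particular tend to act close to their own gene — close in
three-dimensional space, which can be megabases away along the chromosome.
`lnct3d` turns that observation into an annotation pipeline for
computational genomicists: it calls where an RNA significantly contacts
chromatin, shows that those contacts sit within a couple of Hi-C
interactions of the lncRNA's gene, and then uses the Hi-C graph alone —
which does not depend on the lncRNA's (usually low) expression — to
annotate every nuclear lncRNA with candidate target genes, validated by
knockdown differential expression and a battery of enrichment statistics.

## The method

1. **Nuclear classification.** CAGE tag counts are normalized to tags per
   million; a gene is nuclear when its nuclear-to-cytoplasmic ratio
   `nuc / (nuc + cyto)` is at least 0.5 (with a
   `mean(chromatin, nucleoplasm)` variant when those fractions are
   available).
2. **RNA–chromatin calling.** After discarding nascent contacts (RNA tag
   wholly intronic, or DNA tag on the gene of origin), DNA tags are binned
   at 10 kb. With `p_b` the fraction of all trans-mRNA contacts falling in
   bin *b*, a gene with `n` remaining reads and `x` of them in *b* is
   tested with the one-sided exact binomial tail `P[X >= x | n, p_b]`.
   The test runs iteratively per gene: bins at BH-FDR <= 0.01 are moved to
   the significant set and their reads subtracted from `n`, until nothing
   new is found; significant bins need >= 3 supporting reads.
3. **Hi-C target regions.** Significant Hi-C interactions (>= 5 read
   pairs, q <= 0.05) form a graph over 10 kb bins. A lncRNA's candidate
   target region is every bin within 2 degrees of separation from its
   strongest-promoter bin, constrained to the surrounding A/B compartment
   run extended by 100 kb (compartment signs are first reassigned so that
   A is the expression-rich side). Strongest promoters and expressed
   enhancers in those bins are the candidate targets.
4. **Target characterization.** Fisher-exact batteries (knockdown DE at
   FDR <= 0.1 in >= 1 ASO; GO-style terms against the other lncRNAs'
   targets; TFBS motifs with summed-posterior assignments; eCLIP-derived
   RBP targets with ChIP and PPI expansion), Spearman
   expression-correlation preference, Mann–Whitney comparison of N/C
   ratios, and Fisher's-method p-value combination.

Everything runs on synthetic data with planted ground truth — the
`generate_world()` module simulates every input table the pipeline
consumes (contacts, Hi-C, CAGE expression, compartment eigenvalues,
knockdown DE, eCLIP/ChIP/PPI, TFBS predictions, exon FASTA) from one
seed, so the whole analysis is testable offline.

## Worked example

```r
library(lnct3d)
cfg <- lnct_config(outdir = "results/run", seed = 1)
run_pipeline(cfg)
```

or stage by stage with the numbered drivers:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_fractionation.R
Rscript analysis/03_rnachrom.R
Rscript analysis/04_hic_targets.R
Rscript analysis/05_motifs.R
Rscript analysis/06_enrichment.R
```

which print, for the default seed-1 study (2 chromosomes x 5 Mb,
200 mRNAs, 20 lncRNAs, 6 planted nuclear lncRNAs):

```
Nuclear lncRNAs (N/C >= 0.5): 17 of 20
Significant interactions: 47 for 9 genes; 45 involve lncRNAs
97.78% of significant lncRNA interactions lie within two degrees of Hi-C
separation from the lncRNA promoter
100.00% share the lncRNA's A/B compartment; mean linear distance 0.62 Mb
Hi-C support enrichment (two-sided Fisher):
       which  a  b   c    d  odds_ratio      p_value side
1   observed 44  1  77 2267 1295.428571 8.256935e-60  two
2 randomized  3 42 118 2226    1.347458 4.952218e-01  two
Knockdown-DE enrichment: all 6 planted lncRNAs log2(OR) > 0
Combined p-value (Fisher's method): 9.73e-30
```

Read: the RNA–chromatin interactions of the planted nuclear lncRNAs are
almost all within two Hi-C degrees of their gene and in its compartment;
the association disappears when interactions are randomized; and knocking
down each planted lncRNA up-regulates its Hi-C-derived targets, with a
strongly significant combined p-value — i.e. the pipeline recovers the
planted regulatory structure end to end.

## Layout

- `R/` — the package: synthetic-data generators, fractionation,
  RNA–chromatin caller, Hi-C graph/compartments/targets, enrichment
  statistics, motif search, pipeline orchestration.
- `analysis/` — numbered narrative drivers over `results/run/`.
- `tests/testthat/` — unit, property and acceptance suites with
  independent oracles (enumeration, hand BH, BFS).
- `vignettes/lncrna-target-annotation.Rmd` — the methods vignette:
  model, assumptions, parameter rationale, design decisions and
  limitations.
- `scripts/acceptance.R` — the reproduction script described above.
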
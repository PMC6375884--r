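# memoryseq

Drought stress memory analysis for repeated drought/re-watering designs.

Plants that have experienced a mild drought can respond differently the next
time: some transcripts *remember* the first exposure. Given expression data
over the canonical four-state series — untreated control (R0), first stress
(S1), late re-watering (R3) and late stress (S4), with replicates — plus a
two-condition whole-genome bisulfite methylome, `memoryseq`:

* screens **differential expression** per contrast with an exact conditional
  count test (pooled counts, minimum-likelihood two-sided tail; binomial at
  dispersion 0, conditional negative-binomial otherwise), BH FDR within
  contrast, and the screen `|log2FC| > 1 & FDR < 0.05`;
* enumerates the **26 unit-change trajectory profiles** over the four
  conditions (all step vectors in {−1, 0, +1}³ minus the flat one), assigns
  each gene its nearest profile by centred correlation of the log-ratio
  trajectory `v_t = log2((x_t+1)/(x_1+1))`, flags **memory genes**
  (stress-responsive and significantly different from S1 at R3 or S4) and
  classifies the five memory categories (stable, accumulated, lineage,
  initial, dosage-dependent);
* calls **DMRs** from per-cytosine bisulfite counts by the sliding-window
  procedure (200 bp windows at 50 bp steps, two-sided Fisher exact test per
  window, BH FDR per CG/CHG/CHH context), merges significant runs, refines
  boundaries with a binomial changepoint fit and requires a minimum
  methylation difference;
* scores **methylation–expression linkage** per DMR–gene pair (gene body or
  2 kb strand-aware promoter) by Pearson correlation across samples, with
  the permissive published thresholds r > 0.04 / r < −0.04 as defaults;
* runs generic **hypergeometric term enrichment** on memory-gene sets, and
  computes the physiological drought indices **RWC** = (FW−DW)/(RW−DW)×100%
  and **Fv/Fm** = (Fm−F0)/Fm.

A seeded synthetic-data generator plants known trajectory shapes, DMRs and
methylation–expression couplings, so the whole pipeline is testable without
sequencing data. It is aimed at plant stress-genomics analysts who want the
memory-classification logic as tested, reusable functions rather than a
chain of one-off scripts.

## Worked example

The `analysis/` directory is a numbered workflow over the package; each
script reads the previous stage's tables from `results/` and states what it
found. Running it end to end on the default simulated study
(`Rscript analysis/01_simulate.R 1` … `06_physiology.R`) prints, for seed 1:

```
01: done: 2000 genes (730 planted memory), 40 planted DMRs, 100 gene models
02: S1_vs_R0: 277 up, 262 down of 2000 genes        (and 4 more contrasts)
03: 26 candidate trajectory profiles enumerated
    729 memory genes called; by category:
     accumulated dosage initial lineage other-memory stable
              37    181      61      27          386     37
    recovery vs planted truth: memory sensitivity 0.999, shape accuracy 0.985,
    category accuracy 0.995
04: CG: 20000 windows tested, 62 FDR-significant, 12 DMRs   (CHG: 13, CHH: 14)
    recovery vs planted truth (boundaries +/-50 bp): sensitivity 0.975,
    precision 1.000 (39 called / 40 planted)
05: 56 DMR-gene pairs (29 body / 27 promoter);
    linkage at r > 0.04 / r < -0.04: 40 of 40 coupled pairs linked
    top enriched term: TERM:MEMORY, p = 8.1e-16
06: RWC over the drying series (%): 97.01 85.07 71.64 58.21 46.27
    Fv/Fm across states: 0.800 0.779 0.802 0.790
```

Reading: of 2000 simulated genes, 730 carried planted memory-type
trajectories; the screen plus profile matching recovered 99.9% of them, with
98.5% assigned their exact planted shape. All but one planted DMR were
recovered with boundaries within one window step and no false calls at the
default filters, and every methylation–expression coupling was detected at
the published correlation thresholds (which are permissive — see the methods
vignette). The same functions accept real expression tables, cytosine
reports and gene models via `read_expression()`, `read_cytosine_report()`
and `read_gene_models_bed()`; `run_pipeline()` drives the simulated
end-to-end analysis with one config.

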
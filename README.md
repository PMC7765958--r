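# mirmaster

Integrated miRNA–mRNA inference and logical modeling for paired
transcriptome/miRNome studies of hepatic metabolism.

Dietary interventions (for instance an obesogenic high-fat diet with or
without omega-3 supplementation) reshape both the liver transcriptome and
its miRNome. Identifying which miRNAs *drive* the transcriptional response
— rather than merely co-vary with it — requires combining differential
expression, target predictions, network inference and regression into a
single evidence chain, and interpreting the result mechanistically.
`mirmaster` implements that chain as a tested, reusable R pipeline for
three-arm designs (a reference diet and two high-fat arms, `HFoleic` and
`HFepa`), together with a multi-valued logical model of hepatic
glucose/lipid metabolism used to turn the inferred regulations into
phenotype-level predictions.

## What the package computes

**Phenotype signatures.** Per-contrast two-sample t-tests (Welch by
default) on quantile-normalized log2 expression; genes with
FDR-adjusted p < 0.05 (Benjamini–Hochberg) split into *up* (log2FC > 0)
and *down* signatures.

**MicroRNA Master Regulator Analysis (MMRA)** — four sequential filters on
candidate miRNAs for a contrast:

1. *Differential expression*: |log2FC| > 0.25 and raw p < 0.01.
2. *Target enrichment*: consensus targets (predicted by ≥ 2 of 3 databases)
   enriched in the up/down signature, one-sided Fisher exact p < 0.05.
3. *Network enrichment*: an ARACNE-style mutual-information network is
   built around each surviving miRNA (the miRNA is the only hub; edges
   require MI above a threshold extrapolated from a permutation null to a
   target tail probability, 10⁻⁷ by default, 10⁻⁴ at desk scale) and tested
   for signature enrichment.
4. *Stepwise linear regression*: each signature gene is regressed on the
   log2 levels of its linked miRNAs; bidirectional stepwise OLS with AIC
   (n·ln(RSS/n) + 2k) as the stop criterion. A (miRNA, gene) pair survives
   only if the miRNA is selected.

**Enrichment.** Unweighted GSEA as a two-sample Kolmogorov–Smirnov test on
fold-change-ranked genes (raw p < 0.05 filter; Benjamini–Yekutieli across
sets), and metabolic reaction mapping: DE genes are mapped onto a
gene→reaction→pathway network, reactions attributed 1 (HFoleic-only),
2 (HFepa-only) or 3 (both), and pathways scored by one-tailed Fisher tests
with BH correction.

**Logical model.** A 24-component, 37-interaction multi-valued regulatory
graph of hepatic metabolism (inputs: glucose, glucagon, fatty acids;
outputs: gluconeogenesis, glycolysis, lipogenesis, lipolysis,
adipogenesis; Pgc1a ternary). Stable states (fixed points of the
synchronous update) are enumerated exhaustively under input assignments
and clamping perturbations (knockout = 0, ectopic = max).

**Synthetic data.** `generate_study()` produces paired gene/miRNA log2
matrices with planted repressive miRNA→gene regulations (up-shifted
miRNAs drive down-shifted targets and vice versa), mock 3-source target
databases, pathway sets and a reaction mapping — all with recorded ground
truth, so every stage is verifiable by parameter recovery.

## Worked example

```r
library(mirmaster)

cfg   <- simulation_config(seed = 1)       # 500 genes, 60 miRNAs, n = 9/8/7
study <- generate_study(cfg)
dbset <- generate_target_databases(study)

res <- run_mmra(study, dbset, "HFepa_vs_reference", mi_p_target = 1e-4)
res
#> MMRA result [HFepa_vs_reference]
#>   candidates per step: step1=25, step2=6, step3=5, step4=5
#>   surviving pairs: 57

head(res$pairs, 3)
#>      mirna_id  gene_id coefficient mirna_direction gene_direction
#> 1 mmu-miR-060 gene0020   -1.215961              up           down
#> 2 mmu-miR-045 gene0037   -1.220952            down             up
#> 3 mmu-miR-014 gene0039   -1.161652              up           down
```

Of 25 differentially expressed miRNAs, the four filters retain 5; the 57
surviving (miRNA, gene) pairs have negative regression coefficients and
the anti-correlated direction pattern (up-miRNA/down-gene or the
converse). Against the study's planted truth (60 regulations), this run
recovers 80% of the true pairs at 84% precision.

The logical model:

```r
m <- hepatic_model()                       # 24 components, 37 interactions
rep <- simulate_environments(m, hepatic_environments())
rep$table[, c("environment", "Pgc1a", "Irs2", "gluconeogenesis",
              "glycolysis", "lipolysis")]
#>            environment Pgc1a Irs2 gluconeogenesis glycolysis lipolysis
#> 1                  fed     0    1               0          1         0
#> 2              fasting     2    0               1          0         1
#> 3         fed_pgc1a_ko     0    1               0          1         0
#> 4     fasting_pgc1a_ko     0    0               0          0         1
#> 5 fasting_irs2_ectopic     1    1               0          1         0
```

Feeding activates insulin signaling and the anabolic programs while
shutting off gluconeogenesis; fasting does the opposite. Knocking out
Pgc1a in the fasting state preserves lipolysis but abolishes
gluconeogenesis; ectopic Irs2 during fasting suppresses gluconeogenesis
while keeping glycolysis and lipogenesis on, with Pgc1a settling at its
intermediate level (1 of 2).

A thin command-line wrapper over the same functions is installed at
`inst/cli/mirmaster.R` (subcommands `simulate`, `de`, `mmra`, `gsea`,
`metmap`, `logic`, `all`).

## Vignette

`vignettes/mirmaster-methods.Rmd` documents the statistical model behind
the simulator, every threshold and its default, the MI estimator and
threshold extrapolation, the stepwise-AIC search, the reconstruction of
the logical model's rule set, and known limitations.
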
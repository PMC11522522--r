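# poolscreen

Rare-allele detection in pooled DNA screens on 96 × 96 endpoint-fluorescence
SNP arrays.

## The problem

Catching a cryptic invasion early — say, non-native barred tiger salamander
(BTS) alleles introgressing into an endangered California tiger salamander
(CTS) population — requires genotyping thousands of individuals at a panel
of diagnostic SNPs. Genotyping each individual is too slow and too
expensive for routine surveillance. poolscreen implements a group-testing
alternative: tissue from up to 15 individuals is pooled, each pool runs on
a 96 × 96 nanofluidic chip (90 pools + 6 controls × 48 SNP assays in
duplicate = 9216 reactions), and per-assay classifiers decide from each
reaction's two-channel endpoint fluorescence whether the pool contains any
non-native allele at that SNP.

The quantity that makes this hard is the **rare-allele ratio** (RARatio):
one heterozygote pooled with 14 native homozygotes leaves

```
RARatio = (het + 2·homBTS) / 2n = 1/30 ≈ 0.033
```

of allele copies non-native, which must be distinguished from exactly zero.

## The method

1. **Control correction** — each chip's homozygous controls measure its
   absent-allele background; one scalar per channel per chip is subtracted
   from every reaction (`estimate_background()`, `apply_correction()`).
   One-way ANOVA with η² = SS_between/SS_total quantifies why: background
   varies far more between SNP assays than between chips
   (`variance_decomposition()`).
2. **Per-assay random forests** — one 500-tree forest per SNP on the
   (X, Y) intensity pair, trained on known-composition pools at RARatios
   {0, 1/30, 1/15} with a pool-level 50/50 train/hold-out split
   (`train_assay_classifiers()`). Assays with out-of-bag error > 5% or
   hold-out sensitivity < 90% are dropped (`filter_assays()`).
   Predictive values come from closed-form Beta(t+1, f+1) posteriors
   (`posterior_call_probability()`).
3. **Replicate concordance and triage** — same-chip technical replicate
   pairs whose intensity difference exceeds mean + 1 SD in either channel
   are discarded (`filter_replicate_pairs()`). A pool is SUSPECT only when
   some assay calls Het in *both* replicates; single-replicate Hets are
   dismissed (`triage_pools()`); suspects are re-assayed and refuted or
   confirmed (`resolve_suspect()`).
4. **Validation and design math** — amplicon read counts validate suspect
   pools, with a contamination flag when non-native reads appear at 100% of
   loci (`assess_amplicon_pool()`); `detection_probability(L, s) = 1−(1−s)^L`,
   `backcross_fraction(f0, g) = f0·0.5^g` and `evaluate_accuracy_model()`
   cover screen design and accuracy attribution.

A synthetic-data generator (`generator_config()`, `simulate_training_run()`,
`simulate_screen()`) reproduces the assay- and chip-level background
variance structure of real runs, so the full pipeline is exercised and
tested with no laboratory data.

## Worked example

Plan pools, train classifiers on synthetic known-ratio chips, then screen
60 unknown pools of which one hides a 50%-BTS hybrid among 14 natives:

```r
library(poolscreen)

plan_pools(c(alder = 75, birch = 7, cedar = 6))
#> pool_plan: 6 pools, 88 individuals, 1 mixed-pond
rare_allele_ratio(15, het_count = 1)
#> [1] 0.03333333
detection_probability(loci = 10, sensitivity = 0.969)
#> [1] 1
expected_bts_reads(depth = 579, raratio = 1/30)$expected_integer
#> [1] 19

panel <- synthetic_panel(12)
cfg <- generator_config(n_assays = 12, n_chips = 3, seed = 42)
run <- simulate_training_run(cfg, panel, ratios = c(0, 1/30, 1/15))
rec <- apply_correction(run$records)
trained <- train_assay_classifiers(rec, run$truth, mode = "corrected", seed = 1)
head(trained$performance, 4)
#>   assay_id  oob_error sensitivity specificity  accuracy retained
#> 1      S01 0.04477612   0.9632353   0.9852941 0.9742647     TRUE
#> 2      S02 0.04104478   0.9338235   0.9926471 0.9632353     TRUE
#> 3      S03 0.04850746   0.9411765   0.9705882 0.9558824     TRUE
#> 4      S04 0.04477612   0.9558824   0.9852941 0.9705882     TRUE
retained <- trained$performance$assay_id[trained$performance$retained]

fractions <- all_native_fractions(60, panel)
hybrid <- simulate_hybrid_genotype(0.5, panel, seed = 7)
natives <- lapply(1:14, function(i) simulate_hybrid_genotype(0, panel, seed = i))
fractions["pool_0031", ] <- pool_fractions(c(list(hybrid), natives))

screen <- simulate_screen(cfg, panel, fractions)
calls <- call_pools(trained$models, apply_correction(screen$records), retained)
status <- triage_pools(calls)
table(status$status)
#>                CLEAR SINGLE_REP_DISMISSED              SUSPECT
#>                   39                   19                    2
status[status$status == "SUSPECT", ]
#>      pool_id  status evidence_assays
#> 31 pool_0031 SUSPECT         S01;S02
#> 48 pool_0048 SUSPECT             S12
```

The hybrid-bearing pool is flagged at two assays; 19 pools show the
classic single-replicate false-positive signature and are dismissed; one
clean pool reaches SUSPECT on a single assay — exactly the situation the
re-assay step (`resolve_suspect()`) exists to settle: a repeat both-replicate
Het confirms, a clean re-run refutes.

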
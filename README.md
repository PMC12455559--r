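# petscreen

Machine-learning-guided screening and analysis of PET hydrolase candidates.

Enzymatic depolymerization of poly(ethylene terephthalate) (PET) is a
promising route to chemical recycling of waste polyester, and the search for
natural PET hydrolases that stay active under industrially relevant
conditions — crystalline substrate, 40–60 °C, pH as low as 4.5 — is an
active discovery problem.  A productive strategy is an iterative loop:
search sequence databases with a profile hidden Markov model (HMM) of known
hydrolases, filter candidates with machine-learning predictors of activity,
thermostability and acid tolerance, assay the survivors in high-throughput
plates, and feed the condition-resolved activity calls back into the next
round of models.

`petscreen` is a reusable, fully tested R implementation of that loop for
computational biologists and enzyme engineers: every stage from raw plate
absorbances to condition-specific predictors is exposed as a documented
function, and a synthetic enzyme-world generator with *planted* determinants
of low-pH activity provides ground truth against which the whole pipeline is
validated.

## What is inside

| Stage | Functions |
|---|---|
| Sequence I/O, identity, redundancy | `read_fasta`, `read_stockholm`, `pairwise_identity`, `greedy_identity_filter` |
| Alignment and trees | `needleman_wunsch`, `progressive_align`, `strip_gappy_columns`, `nj_tree` |
| Profile HMMs | `build_profile`, `forward_bitscore`, `align_to_profile`, `tune_hmm`, `normalize_scores` |
| Predictors | `make_folds`, `pooled_cv_predict`, `auroc`, `score_metrics`, `model_bagged_trees`, `model_ridge`, `condition_predictor_experiment` |
| Candidate selection | `multiobjective_select`, `threshold_select` |
| Assay processing | `quantify_product`, `call_activity`, `summarize_enzymes`, `condition_contingency`, `hit_rate`, `extract_tm` |
| Group analysis | `split_groups`, `mann_whitney_u`, `differential_conservation`, `position_property_test`, `factor_profile`, `kyte_doolittle_profile`, `map_to_reference`, `cluster_accessory_domains` |
| Synthetic world | `world_config`, `generate_world`, `simulate_assay`, `emit_property_tables`, `write_world` |
| Orchestration | `run_pipeline`, `petscreen_cli` |

The numerical core — affine-gap alignment (pairwise and profile–profile),
the profile-HMM forward/Viterbi algorithms, and a bagged CART classifier —
is implemented in C++ via Rcpp.

Key statistical conventions follow the screening literature: activity is
called when A260 exceeds the matched blank by ≥ 0.05; the melting
temperature is the highest transition of the DSF derivative curve; HMM bit
scores are `log2 P(seq|model)/P(seq|background)` and are normalized to a
reference enzyme before pooling across cross-validation splits; metrics are
computed over pooled out-of-fold predictions (not averaged per-fold
scores); AUROC uses the Mann–Whitney tie convention; per-residue group
differences use two-sided Mann–Whitney U tests at p < 0.05 with exact
enumeration for small samples.

## Worked example

```r
library(petscreen)

w   <- generate_world(world_config(seed = 1))   # 212-enzyme synthetic screen
sim <- simulate_assay(w)
s   <- summarize_enzymes(sim$assay, melt = sim$melt, yields = sim$yields)
s
#> Enzyme summary: 202 enzymes, 1916 enzyme x condition results; 107 active overall

hit_rate(s)
#> [1] 0.5297030

condition_contingency(s, "substrate", "cryPow", "aFilm")
#> only1  both only2
#>     8    30     0          # 66 enzymes tested on both substrates

sp <- split_groups(s)       # active at pH 4.5 vs active only at higher pH
lengths(sp)
#> acid: 29   neutral: 47   excluded: 31

props <- emit_property_tables(w)
fac   <- position_property_test(props, sp)
head(fac[order(fac$p), c("column", "property", "mean_diff", "p")], 3)
#>   column       property mean_diff        p
#> 3    173            pKa     1.597 4.17e-13
#> 8     48 electrostatics    -0.592 1.61e-10
#> 6    226 hydrophobicity     1.002 3.70e-10
```

Reading the output: about half the simulated library shows activity in at
least one condition; every enzyme active on amorphous film is also active
on crystalline powder (the `only2 = 0` cell); and the per-column
Mann–Whitney tests recover the planted acid-vs-neutral property shifts
(e.g. the +1.5 pKa shift planted at the serine-adjacent histidine column,
here column 173 in alignment coordinates) while decoy columns stay at the
5 % false-positive floor.

A full end-to-end run (simulate → align → HMM → assay → train → select →
analyze, with reports and a JSON-lines log):

```r
res <- run_pipeline(list(seed = 1, n_enzymes = 60), out_dir = "run1")
```

or from the shell: `Rscript -e 'petscreen::petscreen_cli()' run-all --seed 1
--out run1`.

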
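# barcodemog

Phylogeography and demographic inference from mitochondrial DNA barcodes
(e.g. the COI fragment), for population geneticists working with
species-level barcode datasets: aligned sequences plus a sample table go
in; haplotypes, distances, networks, diversity statistics, expansion
fits and demographic-scenario posteriors come out.

## What it computes

Given an aligned barcode dataset with species/population labels:

* **Haplotypes** — collapse identical sequences (exact identity; optional
  N-tolerant merging) with a deterministic membership map.
* **Distances and the barcoding gap** — uncorrected p-distances
  (pairwise deletion), between-group divergences with site-bootstrap
  standard errors, and the gap between the largest intraspecific and
  smallest interspecific distance.
* **Median-joining networks** — minimum-spanning networks augmented with
  quasi-median (Steiner) vectors, with shortest-path separation queries
  between labelled groups and GML/TSV export.
* **Diversity and neutrality** — h, π, S, mean pairwise differences, the
  Grant & Bowen (h, π) quadrant, Tajima's D and Fu's Fs with P-values
  from neutral coalescent simulation:
  D = (π̂ − S/a₁)/√(e₁S + e₂S(S−1)), Fs = ln(S′/(1−S′)) with
  S′ = Pr(K ≥ k_obs) under the Ewens distribution at θ = π̂.
* **Mismatch distributions** — least-squares fits of the sudden- and
  spatial-expansion expected distributions (closed forms; parametric
  bootstrap P-values for SSD and Harpending's raggedness), and the time
  conversion t = τ/2u with u = μ·L/g made explicit.
* **Demographic simulation** — a backward-time structured coalescent for
  a three-population scenario (two daughters splitting from a source at
  t1 > t2, each through a founder bottleneck of size N·b lasting t_db
  generations) with HKY+Γ sequence evolution.
* **ABC** — reference tables of DIYABC-style summary statistics,
  scenario choice by the direct (k-nearest) and logistic-regression
  approaches, local-linear parameter estimation with logit/log
  transforms, type I/II error rates on pseudo-observed datasets, prior
  pre-evaluation and posterior model checking.

A synthetic-data generator (`generate_study_like()`) produces study-like
datasets — a spatially structured species with a Late Pleistocene
founder event into its third population, a star-like recently expanded
species, and a deep outgroup — with the full truth record saved, so the
whole pipeline is testable without downloading anything.

## Worked example

The `analysis/` scripts run the full workflow over the default synthetic
dataset (seed 1); run them in order from the repository root:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_haplotypes_distances.R
Rscript analysis/03_network.R
Rscript analysis/04_popgen.R
Rscript analysis/05_abc.R
```

Stage 2 prints, for the default dataset:

```
96 sequences collapse into 33 haplotypes
<gap_report>
  max intraspecific: 0.0154
  min interspecific: 0.0658
  barcoding gap: yes
  threshold (midpoint): 0.0406
```

i.e. all within-species pairs differ by ≤ 1.5% while species differ by
≥ 6.6%, so a ~3–4% threshold cleanly separates intra- from
inter-specific variation — the classical barcoding gap. Stage 4's
summary table shows the bottleneck signature of the Australian-like
population (h = 0.72 with π = 0.23%: large haplotype diversity, small
nucleotide diversity) and recovers the expansion ages encoded in the
generator — its fitted moment estimator τ = 1.076 converts to 66.7 ka
against a true colonisation at 65 ka, and the star species' τ = 3.23
to 200 ka against a true expansion at 196 ka — via the conversion it
prints as a reference point:

```
reference point: tau = 1.081 at 456 bp corresponds to 67 ka
```

(t = τ/2u at the mid-Aegean COI rate, 1.77×10⁻⁸ substitutions/site/
year, one generation per year). Stage 5 chooses between a
recent-colonisation and an ancient-divergence scenario by ABC:

```
scenario posterior (direct):   recent = 0.912 ancient = 0.087
scenario-choice errors (direct approach): type I 0.220, type II 0.140, predictive 0.180
Pop3 (Australian-like) split: mean 65.2 ka, median 64.3 ka, 95% CI 16.6-120.3 ka
```

The truth behind the synthetic data is the recent scenario with a split
at 65 ka, so the chosen scenario is right and the credible interval
covers the true age. Tables for every stage land under `results/`.

All computation lives in the package (`R/`); the scripts are thin
drivers, so every step can equally be called from R — see the methods
vignette (`vignettes/barcode-phylogeography-methods.Rmd`) for the models
and defaults.

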
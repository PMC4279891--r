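# phbvseq

Sequence-distribution analysis of poly(3-hydroxybutyrate-*co*-3-hydroxyvalerate)
(PHBV) copolymers from assigned ¹³C NMR diad/triad peak intensities.

PHBV is a bacterial polyester of 3-hydroxybutyrate (B) and 3-hydroxyvalerate
(V) units. Whether those units are interleaved at random or grouped into long
blocks controls the material's thermal and mechanical behaviour, and the
arrangement is readable from NMR: carbonyl resonances split by a unit's
neighbours, so integrated peak areas report diad (two-unit) and triad
(three-unit) sequence fractions. `phbvseq` is for polymer chemists and
microbiologists who have such peak tables (or want simulated ones) and need
the sequence statistics behind them.

## The model

The chain is a stationary first-order Markov chain over {B, V} with
parameters *p* = P(B→V) and *q* = P(V→B). Closed forms give the composition
x_V = p/(p+q), diad fractions F_ij = x_i·P_ij, triad fractions
F_ijk = x_i·P_ij·P_jk, number-average block lengths L_B = 1/p, L_V = 1/q,
and the selectivity statistic

    D = P_BB·P_VV / (P_BV·P_VB) = (1−p)(1−q)/(pq) = F_BB·F_VV / (F_BV·F_VB)

with D = 1 for an ideally random (Bernoullian) chain, D ≫ 1 for blocky
chains, D < 1 for alternating ones. `fit_markov()` estimates (p, q) from
normalized peak intensities by nonlinear least squares (Levenberg–Marquardt
on logit-transformed parameters, deterministic multistart), and
`classify_distribution()` labels the result random/blocky/alternating.
A seeded Monte-Carlo simulator (`simulate_chain()`, `empirical_diads()`,
`empirical_d()`, …) provides the empirical counterparts, and
`default_panel()` / `make_sample_tables()` generate a reference panel of
eleven copolymer samples (5–80 mol% 3HV, D from 1.15 to 14.81) as
model-consistent, optionally noisy, peak tables. See the methods vignette
(`vignettes/phbvseq-methods.Rmd`) for the full account.

## Worked example

Take the panel's B19 sample: a putative block copolymer with 19 mol% 3HV and
D = 10.26. Invert that pair to transition probabilities, generate a noisy
peak table, and fit it back:

```r
library(phbvseq)

P <- transition_from_composition_and_d(0.19, 10.26)
P
#> First-order Markov copolymer model
#>   P(B->V) = 0.105893   P(V->B) = 0.451439
#>   stationary 3HV fraction x_V = 0.19
#>   D = 10.26
mean_block_lengths(P)
#>      L_B      L_V
#> 9.443484 2.215138

s <- make_sample_tables("B19", x_V = 0.19, D = 10.26, cv = 0.02, seed = 42)
fit_markov(s$peaks, n_boot = 200, seed = 42)
#> Markov fit for sample B19
#>   p = 0.1039  q = 0.4529  x_V = 0.1866
#>   D = 10.414  (blocky)   rss = 4.25e-05 over 8 peaks
#>   bootstrap 95% CI for D: [9.901, 10.947]
```

The inverted matrix says a B-run lasts ~9.4 units on average — the long
3HB blocks that make this sample "blocky". With 2% multiplicative intensity
noise, the refit recovers D = 10.41 against the generating 10.26, classifies
the sample as blocky, and brackets the true D in its bootstrap interval.

A command-line front end wraps the same functions:

```sh
Rscript inst/scripts/phbvseq.R panel --out panel_dir --noise-cv 0.02 --seed 4
Rscript inst/scripts/phbvseq.R fit --out report.tsv panel_dir/*_peaks.csv
Rscript inst/scripts/phbvseq.R simulate --xv 0.19 --d 10.26 --n 100000 --seed 1
```

`fit` writes a per-sample TSV report (3HV mol%, D, classification, residual)
plus a full-precision CSV sidecar.

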
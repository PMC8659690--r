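---
title: "An optimal growth law for RNA composition and its genomic implementation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An optimal growth law for RNA composition and its genomic implementation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnagrowthlaw)
```

## The model

Peptide elongation is coarse-grained as a Michaelis–Menten reaction in
which the active ribosome (concentration $[R]$, molecular mass $m_R$) is
the catalyst and the ternary complex (TC: EF-Tu·GTP·aminoacyl-tRNA;
concentration $[TC]$, mass $m_{TC}$) is the substrate:

$$v = k_\mathrm{cat}\,[R]\,\frac{[TC]}{K_m + [TC]}.$$

Cellular dry mass density is treated as the limiting resource. At a fixed
protein synthesis flux $v$, minimizing the combined mass density
$c = m_R [R] + m_{TC} [TC]$ over $[TC]$ (with $[R]$ eliminated through the
rate law) gives the closed-form optimum

$$[TC]^* = \sqrt{\frac{a K_m v}{k_\mathrm{cat}}},\qquad
[R]^* = \frac{v}{k_\mathrm{cat}} + \sqrt{\frac{K_m v}{a\,k_\mathrm{cat}}},$$

with $a = m_R/m_{TC}$. In balanced growth $v = \mu [P]$ (protein dilution;
$[P]$ is the total protein concentration in amino-acid residues), and with
the diffusion-limited approximation $K_m \approx k_\mathrm{cat}/k_\mathrm{on}$
the ratio of the two optima becomes the RNA-composition growth law

$$\frac{[TC]}{[R]} =
\frac{a\,k_\mathrm{cat}}{\sqrt{a\,\mu\,[P]\,k_\mathrm{on}} + k_\mathrm{cat}},$$

a strictly decreasing function of $\mu$ with slow-growth limit $a$.
Multiplying by $m_{tRNA}/m_{rRNA}$ gives the tRNA/rRNA mass-ratio form with
constant $r = a\,m_{tRNA}/m_{rRNA}$. Protein turnover enters by replacing
$\mu$ with $\mu + k_\mathrm{deg}$.

The radical covers the full product $a\,\mu\,[P]\,k_\mathrm{on}$: this is
the form forced by dividing the two closed-form optima above, and it is the
only reading that yields roughly nine tRNAs per ribosome at fast growth —
the radical-free alternative gives about 0.3 and is dimensionally
inconsistent with the optimum pair.

```{r growth-law}
params <- default_ecoli_params()
c(a = params$a, r = params$r)
optimal_tc_per_ribosome(c(0.5, 1, 1.5, 2), params)
```

## Parameters

| Parameter | Default (E. coli) | Units | Meaning |
|---|---|---|---|
| `m_R`, `m_TC` | 2307.0, 69.6 | kDa | ribosome and TC masses; set `a` = 33.1 |
| `m_tRNA`, `m_rRNA` | 25.8, 1480 | kDa | with `a` they set `r` = 0.58 |
| `k_cat` | 22 | s⁻¹ | maximal ribosome turnover; the one fitted parameter |
| `K_m` | 102 | µM | 34 expressed tRNA species × 3 µM per single TC |
| `k_on` | 0.216 | µM⁻¹s⁻¹ | diffusion-limited TC–ribosome binding, `k_cat/K_m` |
| `P_conc` | 1.16×10⁶ | µM residues | total protein concentration, treated as growth-rate independent |
| `k_deg` | 0 (option 0.02–0.04) | h⁻¹ | protein degradation; shifts the law by `k_deg` |

Growth rates are accepted in h⁻¹ at every public interface and converted
internally; concentrations are µM and masses kDa throughout, matching how
the constants above are conventionally reported. The yeast mass set
(`default_yeast_mass_params()`: `a` = 40.3, `r` = 0.59) carries no kinetic
constants; only the mass rescaling differs for eukaryotic microbes.

`K_m` is stored explicitly but validated against `k_cat/k_on`; a
disagreement above 1% warns and the explicit value wins, since the
diffusion-limit relation is an approximation. The default set itself
differs by 0.15% (102 vs 101.85 µM), which is also why the √-form ratio and
the quotient of the two `K_m`-form optima agree only to ~0.5% there — tests
treat the two routes as exact only when `K_m = k_cat/k_on` exactly.

## Replication-associated gene dosage

With overlapping replication rounds (Cooper–Helmstetter), a gene at
relative position $p$ (0 at *oriC*, 1 at the terminus) has average copy
number $\bar X = e^{\mu[C(1-p)+D]}$, where $C$ is the chromosome
replication time and $D$ the termination-to-division interval. Every ratio
of dosages cancels $D$; the tests assert this identity directly. The
aggregate tRNA/ribosome dosage ratio divides the summed tRNA dosages by
one third of the summed rRNA dosages ($n = 3$ rRNA genes — 5S, 16S, 23S —
per ribosome), and reduces to the genomic copy ratio at $\mu = 0$.

$C$ defaults to $L/(2 k_\mathrm{rep})$ with a shared fork speed
$k_\mathrm{rep}$ = 1000 bp/s; for the ~4.6 Mb E. coli chromosome this gives
0.64 h, within rounding of the measured ~40 min C period, so the
genome-length form is used uniformly rather than per-species measured
values. A growth-rate-dependent C period is deliberately out of scope.

```{r dosage}
s <- dosage_settings(C = 40/60, D = 20/60)
gene_dosage(0, log(2)/0.5, s)   # oriC gene, 30 min doubling time: 4 copies
aggregate_trna_rrna_dosage_ratio(rep(0.45, 86), rep(0.20, 22), 1.386,
                                 dosage_settings(C = 0.6444))
```

## Gene positions

Coordinates are 1-based inclusive in both GFF3 and GenBank input, so no
shift is applied. Gene location is the midpoint of start and end (kept at
half-integers), and position is the shortest circular distance to the
*oriC* center divided by half the chromosome length. Features crossing the
coordinate origin use the circular midpoint; in GFF3 they are expected in
the circular-genome convention `end > L`. When several *oriC*s are
annotated, the first listed is used — a deterministic tie-break justified
by the tiny inter-*oriC* spreads observed on single chromosomes (fractions
of a percent of genome length). Pseudo-genes are excluded, a documented
choice. rRNA subtypes are matched case-insensitively on 5S/16S/23S in the
product or gene name; unmatched rRNA features still count toward rRNA
position means but are flagged. Species lacking either gene class are
dropped from class summaries. Fast growers are species with minimal
doubling time ≤ 1 h ($\mu_{max} \ge 0.69$ h⁻¹), the regime where
overlapping replication makes dosage effects strong.

The GenBank reader is a minimal feature-table parser (LOCUS length, tRNA
and rRNA keys, `complement()` and origin-wrapping `join()` locations,
`/product`, `/gene`, `/locus_tag`, `/pseudo`), sufficient for annotation
dumps; GFF3 goes through `rtracklayer`.

## Fitting the turnover number

`fit_kcat()` minimizes the unweighted sum of squared errors on the ratio
scale over `k_cat` alone, by bounded scalar minimization on (0.1, 200] s⁻¹
with tolerance 10⁻⁶; `k_on` stays at the diffusion limit and `[P]` at its
template value, since the law is meant to carry a single species-specific
parameter. The loss scale is a genuine open choice — a log-scale option is
provided but off by default. A solution within 10⁻³ of either bound is
reported as non-convergence rather than returned. Observations at a single
growth rate are rejected, and a species whose ratios show no growth-rate
dependence (|Spearman ρ| < 0.2 with p > 0.05) is excluded from fitting with
a warning — for such data a fit would be meaningless. The independent
check `effective_kcat()` inverts the flux balance $\mu[P] = k_\mathrm{eff}[R]$
from measured concentrations and touches none of the fitting machinery.

## Independent contrasts

`pic_contrasts()` implements Felsenstein's pruning recursion on rooted
binary trees. The correlation test on contrasts runs through the origin
(contrast signs are arbitrary) with a two-sided t test on $n-1$ degrees of
freedom; Pearson-through-origin is the default, the standard contrast
practice, with a Spearman variant exposed. Zero-length branches are
inflated to 10⁻⁸ with a warning so standardization stays defined;
polytomies are resolved deterministically by tip-name order before
ε-resolution. Tests verify the implementation two independent ways: against
`ape::pic`, and against the defining property that the contrast transform
whitens the Brownian-motion tip covariance ($D V D^\top = I$) on
enumerated small trees.

## The synthetic-data generator

The generator emulates the statistical structure the pipeline consumes,
not any real genome: species with log-uniform doubling times on [0.25, 10]
h and chromosomes of 1.8–9 Mb (the span of the surveyed bacteria); rRNA
genes in 16S/23S/5S operon triplets with operon positions from a truncated
normal with mean 0.20 and sd 0.17, tRNA genes singly at mean 0.45 and sd
0.27 — the E. coli class distributions; operon and tRNA counts rising with
$\mu_{max}$ (≈ 1 + 2.5 $\mu_{max}$ operons, ≈ 30 + 15 $\mu_{max}$ tRNAs,
Poisson-jittered, anchored at the E. coli values of ~7 operons and ~86
tRNAs near $\mu_{max} = 2$ h⁻¹); a mild decline of both class position
means with $\mu_{max}$ (−0.03 per h⁻¹) reproducing the observed
closer-to-*oriC* trend in fast growers; and multiplicative lognormal noise
with σ = 0.15 on expression ratios, matching the visual scatter of
published estimates — a modeling choice, not a measured value. Replichore
assignment is uniform, which is consequence-free because position is an
unsigned distance. Every generator is a pure function of (spec, seed).

What the generator does **not** emulate: sequence content (only feature
coordinates are emitted); phylogenetic signal in gene positions or growth
rates (traits for contrast calibration are generated separately under
Brownian motion on Yule trees); the empirically tighter dispersion of
dosage ratios among fast growers (position variances are
growth-rate-independent here, so variance-comparison tests exercise the
machinery, not that biological contrast); and measurement heterogeneity
across experimental methods. Passing tests therefore demonstrate
correctness of the computations and recoverability under the stated noise
model — not that real annotation pipelines or real expression datasets
behave this simply.

## Numerical choices and problem sizes

Test oracles re-derive every closed form independently: golden-section
minimization of the mass density driven to an interval width of 10⁻⁹
(derivative-free, so the comparison is meaningful at 10⁻⁶ relative error),
exact signed-rank tail probabilities, and the GLS whitening identity for
contrasts. The test and analysis problem sizes — 60-species surveys, 150
genomes for law-of-large-numbers checks, 100–200 fitting replicates, 500
Brownian replicates on 50-tip trees for the size of the contrast
correlation test — were chosen so the whole suite completes in a few
minutes while keeping Monte-Carlo standard errors well inside the asserted
tolerances (e.g. the binomial 2σ band at 500 replicates is ±0.02 around
the nominal 0.05).

## Limitations

The model ignores deactivated ribosome and TC pools (relevant at slow
growth), codon-resolved elongation, ribosome traffic jams, temperature
effects on replication, and multi-chromosome or plasmid-borne gene copies.
`[P]` is held growth-rate independent. Exact reproduction of published
per-species turnover fits depends on the loss function used there, which
is not pinned down; the package therefore treats fit-quality statistics as
tolerance-checked diagnostics, not exact targets.
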
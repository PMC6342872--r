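---
title: "Methods: two-step, two-sample MR mediation in mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-step, two-sample MR mediation in mrmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Mendelian randomisation treats genetic variants as instrumental variables
for a modifiable exposure. A variant is a valid instrument if it (i) is
associated with the exposure, (ii) shares no confounder with the outcome,
and (iii) affects the outcome only through the exposure (exclusion
restriction). Under these assumptions the causal effect of exposure $X$ on
outcome $Y$ is identified from summary statistics alone: for SNP $k$ with
gene–exposure association $E_k$ (SE $\sigma_{Ek}$) and gene–outcome
association $D_k$ (SE $\sigma_{Dk}$), the per-SNP Wald ratio $D_k/E_k$
estimates the causal effect, and the package's three estimators combine the
SNPs under progressively weaker versions of assumption (iii):

- **IVW** — $\hat\beta = \sum_k E_k D_k \sigma_{Dk}^{-2} \big/ \sum_k
  E_k^2 \sigma_{Dk}^{-2}$, $SE = (\sum_k E_k^2\sigma_{Dk}^{-2})^{-1/2}$.
  Exact only if every instrument is valid or pleiotropic effects balance
  out; with a single SNP it reduces to the Wald ratio.
- **Weighted median** — the 50th weighted percentile of the ordered ratio
  estimates, the $j$-th ordered ratio sitting at percentile
  $100(S_j - W_j/2)$ with normalised inverse-variance weights $W_j$ and
  cumulative weight $S_j$; linear interpolation between the two ratios
  bracketing 50. Consistent while valid instruments hold $\ge 50\%$ of the
  weight.
- **MR-Egger** — weighted least squares $D_k = \beta_0 + \beta E_k$ with
  every $E_k$ oriented positive ($D_k$ flipped in tandem) and weights
  $\sigma_{Dk}^{-2}$. The intercept estimates the mean directional
  pleiotropic effect; the slope is consistent for $\beta$ under InSIDE
  (instrument strength independent of direct effects). With the intercept
  constrained to zero the slope is algebraically the IVW estimate — an
  identity the acceptance suite asserts.

Mediation through traits $M_1,\dots,M_m$ is quantified in two steps plus a
joint model: step one estimates $X \to M_j$ and $X \to Y$, step two
$M_j \to Y$, each with all three estimators; candidates passing triage
enter a multivariable IVW regression of $D_k$ on
$(E_k, M_{1k}, \dots, M_{mk})$ without intercept, whose exposure
coefficient is the direct effect $\beta_{dir}$. The mediated proportion is
$1 - \beta_{dir}/\beta_{tot}$, reported as a percentage on the log-odds
scale for binary outcomes.

## Numerical and inferential choices

- **First-order ratio weights** ($\sigma_{Dk}^2/E_k^2$) throughout; the
  second-order term ($D_k^2\sigma_{Ek}^2/E_k^4$) is omitted, matching the
  most common convention for strong instruments.
- **Weighted-median SE** by parametric bootstrap: $E_k^\ast \sim
  N(E_k,\sigma_{Ek})$, $D_k^\ast \sim N(D_k,\sigma_{Dk})$, default 1000
  draws, seed mandatory in the API so nothing is stochastic by accident.
- **Egger residual scale** $\hat\phi = \max(1, \;\text{weighted
  RSS}/(k-2))$: over-dispersion inflates the SEs, under-dispersion is not
  allowed to shrink them. Normal rather than $t$ reference for all
  p-values, appropriate for the large-$k$ consortium setting.
- **Multivariable IVW SEs** are the fixed-effect
  $\sqrt{\mathrm{diag}((X'WX)^{-1})}$ with no residual scaling, so the
  zero-mediator model reproduces univariable IVW to machine precision. A
  mediator column that is identically zero is dropped from the design (its
  coefficient reported `NA`) rather than declared a rank defect.
- **CIs** use a fixed 1.96 multiplier; significance stars at
  0.05/0.01/0.001; no multiplicity adjustment.
- **Mediated-proportion formula**: the literature states "change in the
  total effect" without a unique formula; we use
  $1-\beta_{dir}/\beta_{tot}$ (difference method on the log-odds scale),
  record it in a `formula_tag` field so alternatives remain auditable, and
  refuse the computation for binary mediators, where attenuation of a
  log-odds effect has no proportion-of-pathway reading. The proportion may
  legitimately fall outside $[0,100]$ in finite samples and is reported as
  computed.
- **Ties and degeneracies**: the weighted median returns an endpoint ratio
  when the 50th percentile falls outside the bracketing range; Egger
  refuses designs with all $E_k$ equal (slope unidentified); Wald refuses
  $E_k = 0$.

## Harmonisation

SNPs are matched by variant id only (no positional or LD-proxy matching).
If the outcome's alleles are swapped relative to the exposure, the outcome
beta is negated and its allele frequency complemented; applying the swap
twice is the identity, and harmonising a table against itself returns
$D_k = E_k$ — both tested as properties. Palindromic SNPs (A/T, C/G)
cannot be oriented from labels alone; under the default
`drop_ambiguous` policy a palindrome is dropped when either allele
frequency is missing or inside the ambiguity window (default
(0.42, 0.58)), and otherwise oriented by frequency concordance. The window
is a package choice — the underlying studies do not state their strand
handling — and is configurable and logged. Every input SNP appears exactly
once across the retained rows and the exclusion log.

## The multivariable design needs both instrument sets

With exposure instruments only, the mediator column of the design matrix
is $\theta_{XM} \gamma_k$ plus noise — collinear with the exposure column —
and the direct effect is unidentified. The pipeline therefore fits the
joint model on the union of the exposure's and the mediators' instruments,
with each SNP's exposure association taken from the exposure's genome-wide
table. This is the standard multivariable-MR design; the unit-level
`mvmr_ivw()` accepts any harmonised set and is indifferent to how it was
assembled.

## What the simulator emulates

`simulation_truth()` defaults describe the stated world of a large
adiposity-to-coronary-disease analysis: 77 independent exposure
instruments jointly explaining exactly 2.4% of a standardised exposure
(GWAS of $n = 322{,}154$), a binary outcome GWAS of $n = 184{,}305$ with
effects on the log-odds scale, mediator GWAS of $n = 188{,}577$, allele
frequencies uniform on (0.05, 0.5), 15% palindromic SNPs, and 30% of
non-exposure rows stored with swapped alleles to exercise harmonisation.
Sampling SEs follow $\sigma \approx (2p(1-p)n)^{-1/2}$ for a standardised
trait, and noise is drawn independently per dataset (the two-sample
design); both calibrations are tested empirically.

Two generator choices deserve comment:

- **Effect-size distribution.** True instrument effects are half-normal,
  lower-truncated at 0.45 of the raw scale before rescaling to the target
  $R^2$. The truncation mimics genome-wide-significance selection:
  published instrument lists contain no near-null effects. Without it,
  SNPs whose observed exposure beta flips sign make Egger's forced
  positive orientation co-flip pure noise, biasing the slope upward and
  the intercept downward even when InSIDE holds. Effect alleles are
  oriented to the exposure-increasing allele, as published lists are;
  this is also what makes directional pleiotropy bias IVW by roughly
  $\bar\alpha / \bar E$ rather than averaging out.
- **Binary outcomes** are simulated directly on the log-odds scale at the
  summary level, not via individual-level logistic sampling — adequate for
  estimator validation, silent about case-control ascertainment.

Pleiotropy modes: `none`, `balanced` (zero-mean direct effects),
`directional` (non-zero mean, independent of instrument strength — InSIDE
holds), and `inside_violating` (direct effects correlated 0.8 with
instrument strength — the documented negative control under which the
Egger slope is biased too).

What a green simulation test does **not** establish: robustness to LD
between instruments, winner's curse, sample overlap between consortia,
population stratification, or real allele-frequency error — none of which
the generator models.

## A deliberately red acceptance check

The no-pleiotropy recovery criterion asks all three estimators to be
unbiased with 95% CI coverage in [0.92, 0.97] over replicated simulations
at the stated world. MR-Egger does not meet it there, and we left the
check red rather than widen the band or quietly strengthen the
instruments. The cause is finite instrument strength: the SNP–exposure
betas carry measurement error, and for the Egger design the relevant
signal-to-total ratio ($I^2_{GX}$, the weighted variance of the true
exposure effects over that of the observed ones) is about 0.96 at 77
instruments explaining 2.4% of the exposure in $n = 322{,}154$. The slope
is attenuated by the factor $I^2_{GX}$ — about 0.02 on a true effect of
0.37 — which is large relative to the Monte-Carlo error of a 1000-replicate
mean and pushes coverage to ~0.91–0.92. IVW's corresponding dilution uses
total rather than centred variation and is only ~1% (coverage ≈ 0.94); the
weighted median's bootstrap resamples the exposure noise and covers at
≈ 0.97. With noise-free exposure betas all three recover the truth, and
the estimators match independent brute-force oracles to $10^{-10}$, so
the red check reflects the estimator's known finite-sample property (the
$I^2_{GX}$/SIMEX literature), not an implementation defect. Corrections
such as SIMEX are out of scope.

## Determinism and reporting

Every stochastic step derives its seed from the study seed and a stage
label, so a rerun with the same configuration is bit-identical across the
TSV tables, the JSON bundle (serialised at 17 significant digits, which
round-trips IEEE doubles exactly), and the run log; package functions
restore the caller's RNG state. The run log records policies, seeds,
per-analysis SNP retention and every exclusion reason.

## Known limitations

- No LD clumping, proxy lookup, or reference-panel queries: instruments
  are assumed pre-selected and independent.
- No Steiger filtering, mode-based estimators, leave-one-out diagnostics,
  or funnel/scatter plots.
- The mediated-proportion CI is not reported by default (a bootstrap hook
  exists at the API level via repeated simulation); mediators are assumed
  mutually non-causal, which the bidirectional screen probes but cannot
  prove.
- Weak-instrument behaviour is the user's responsibility to check via
  `instrument_strength()`; the package reports $R^2$ and $F$ but applies
  no correction.
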
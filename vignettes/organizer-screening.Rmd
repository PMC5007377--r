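---
title: "Discovering embryonic organizers by synexpression screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering embryonic organizers by synexpression screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgscreen)
```

## The scientific problem

Organizers are embryonic signalling regions that both induce new fates and
pattern neighbouring tissue — Hensen's node, the notochord/floor-plate and
the limb's zone of polarizing activity (ZPA) are classic amniote examples.
Because organizer discovery has historically required grafting the right
tissue at the right time and place, few are known. An alternative strategy
is transcriptional: if organizers share a "synexpression" fingerprint — a
set of genes consistently enriched or depleted in organizer tissue relative
to its most similar non-organizer neighbour — that fingerprint can be used
to scan the embryo for new candidate organizers.

`orgscreen` implements this strategy as a reusable, testable pipeline:

1. **Differential screen.** Six pairwise comparisons over a nine-tissue,
   triplicate design: early Hensen's node (HH4 HN) and late node (HH6 HN)
   against the posterior primitive streak (HH4 PS) and against each other
   (C1–C3); ventral vs dorsal neural tube (C4); posterior vs anterior limb
   bud at two stages (C5, C6). The organizer-side tissue is always
   `group_a`, so "enriched" consistently means higher in the organizer.
2. **Boolean combination.** Per-comparison significance calls (not absolute
   expression levels) are combined with a Boolean algebra; genes passing it
   in the enriched (or depleted) direction form the signature.
3. **Candidate screening.** A candidate region's presence/absence profile
   over the signature genes is scored for concordance: an enriched gene
   that is detected, or a depleted gene that is absent, is a match.
4. **Explant assays.** Induction experiments are tabulated into 2x2 tables
   and tested with an exact two-tailed Fisher test.

A planted-truth simulator generates data with known signature membership so
every stage can be validated end to end without any external download.

## The differential model

For each comparison the per-gene statistic is a moderated t. With
per-gene log2 fold change $b_g$ (mean of `group_a` minus mean of `group_b`),
residual variance $s_g^2$ on $d$ degrees of freedom, and a scaled
inverse-chi-square prior $\sigma_g^2 \sim s_0^2\, d_0 / \chi^2_{d_0}$, the
posterior variance is

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},\qquad
t_g = \frac{b_g}{\tilde s_g \sqrt{1/n_a + 1/n_b}},$$

referred to a Student t distribution with $d_0 + d$ degrees of freedom
(standard normal when $d_0 = \infty$; the classical pooled t when
$d_0 = 0$). The prior is fitted by method of moments on the log-variance
scale: under the model $s^2 = s_0^2 F(d, d_0)$, so
$\mathrm{Var}(\log s^2) = \psi'(d/2) + \psi'(d_0/2)$ and
$d_0$ solves $\psi'(d_0/2) = \widehat{\mathrm{Var}}(\log s^2) - \psi'(d/2)$
by Newton iteration on the trigamma function; $s_0^2$ then follows from the
matching digamma mean relation. When the observed spread of log variances
does not exceed the pure sampling contribution the prior is degenerate:
$d_0 = \infty$ and $s_0^2$ is the geometric mean of the positive variances
(for identical variances this returns exactly the common value).

P-values are two-sided; FDR control is Benjamini–Hochberg applied per
comparison across all genes (`stats::p.adjust`). A gene is called
`enriched` when $b_g \ge \tau$ and $q_g \le \alpha$, `depleted` when
$b_g \le -\tau$ and $q_g \le \alpha$, else `ns`.

### Residual-variance pooling

`organizer_screen()` offers two pooling schemes:

* `var_pool = "design"` (default): the within-group variance is pooled over
  all nine tissues, $d = n_\mathrm{samples} - n_\mathrm{groups}$ (18 in the
  default design). This is the residual variance of the one-way layout that
  a joint linear-model fit of the full array set would use, and it is the
  default because a triplicate design leaves only 4 residual df per pair —
  too few for the moderated test to rank borderline genes reliably, whereas
  the design-wide fit shares the (gene-specific, group-independent)
  variance across all tissues.
* `var_pool = "pair"`: only the two groups of each comparison contribute
  ($d = n_a + n_b - 2$), making each comparison fully self-contained.

Fold changes are identical under both schemes; only the denominator of the
t-statistic changes.

### Threshold semantics

The fold-change rule is interpreted on the log2 scale by default:
$|b_g| \ge \tau$ with $\tau = 1.2$ log2 units. The alternative reading — a
*linear* fold change of 1.2, i.e. $|b_g| \ge \log_2 1.2 \approx 0.263$ — is
available via `orgscreen_config(fc_scale = "linear")`. Both thresholds are
inclusive, as is $q \le \alpha$.

## The Boolean combination

Expressions follow the grammar `NAME | (expr) | expr AND expr | expr OR
expr`, with `AND` binding tighter than `OR`. A leaf is true for a gene iff
its call in that comparison equals the direction being evaluated, so one
expression serves both the enriched and the depleted set (sign-consistent
combination). The shipped default is

```
(C1 AND (C2 OR C3)) AND C4 AND (C5 OR C6)
```

i.e. differential in the early node vs streak, *and* either still
differential in the late node vs streak or differential early-vs-late,
*and* differential in the ventral neural tube, *and* differential in the
posterior limb at one stage or the other. The grouping of the node block is
a genuine design choice: the narrative description of the screen ("genes
enriched or depleted in the early node compared with the posterior streak,
some of which remain expressed the same way at the later stage") supports
`C1 AND (C2 OR C3)`; a literal precedence reading of the combination would
give `(C1 AND C3) OR C2`, which can be selected by overriding
`expression_text`. Under the default expression the enriched and depleted
sets are provably disjoint (C1 is conjunctive and no gene is both enriched
and depleted in one comparison); for user-supplied expressions an overlap
is detected and reported with a warning rather than silently dropped.

## The simulator and what it does (not) emulate

`simulate_expression()` emulates the study design — 9 tissue groups in
triplicate, 27 arrays — with, per gene, a uniform log2 baseline, a scaled
inverse-chi-square variance, and i.i.d. Gaussian replicate noise.
Defaults (all overridable via `planted_params()`):

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 10000 | probe-level genes (32,773 for full array scale) |
| `n_enriched` / `n_depleted` | 31 / 17 | planted signature genes per direction |
| `effect` | 2.0 | planted shift, log2 units |
| `baseline_range` | 4–12 | per-gene baseline mean, log2 |
| `var_prior_df` / `var_prior_scale` | 4 / 0.0625 | variance prior d0 and s0^2 |
| `n_decoy` | 200 | genes differential in only a sub-pattern |
| `decoy_pattern` | `C1` | comparisons each decoy perturbs |

The effect size, variance prior and baseline range are free parameters of
the simulation — the original arrays publish no estimates of them — chosen
as typical of well-behaved log2 microarray data: residual standard
deviations around 0.25 with a heavy right tail, and a planted shift
comfortably above the 1.2 log2 calling threshold, as befits marker genes of
a dedicated signalling tissue.

Because the six comparisons share tissue groups, a gene's perturbation is
defined per *group*, not per comparison, and the node comparisons are
linearly dependent (C1 = C2 + C3 as mean differences). Planting therefore
resolves a requested pattern into group-level offsets by longest-path
relaxation, guaranteeing every comparison in the pattern a mean difference
of at least `effect` (C1 accumulates twice the effect when C2 and C3 are
both planted); a cyclic, group-inconsistent pattern is an error. The same
dependency means a decoy perturbed "in C1 only" necessarily registers in C3
as well; what defines a decoy is that its induced noise-free call pattern
fails the Boolean expression, which is validated at generation time.

Deliberately **not** modelled: probe-level effects and cross-hybridization,
batch and spatial array artifacts, correlated noise between genes,
mean–variance dependence, and stage-dependent expression within a tissue.
Passing recovery tests on this simulator therefore demonstrates the
correctness of the statistical machinery under its own assumptions, not
robustness to the full messiness of real arrays.

## Candidate-region scoring

A candidate profile assigns each signature gene `detected`, `absent` or
`unknown` — a single status summarizing an observation window (detected at
*any* stage within it counts as detected). Concordance is a pure set
computation: enriched-and-detected or depleted-and-absent genes count as
matches; `unknown` genes are excluded from numerator and denominator alike,
which is how stage-restricted cases can be held out of scoring without any
temporal logic. `rank_candidates()` orders regions by concordance fraction,
breaking ties by the number of scored genes (more evidence first) and then
by name; regions with no scored genes rank last with an undefined fraction.
No enrichment p-value is attached to a match score: a null model for
presence/absence profiles is not part of the method.

## Explant assay statistics

Explants are scored `positive`, `patchy`, `negative` or `excluded`
(high-level expression confined to a small patch). Tabulation compares
positive (optionally plus patchy) against negative counts across two
conditions; `excluded` records are dropped unless explicitly included (then
counted negative). The two-sided Fisher p-value conditions on both margins
and sums hypergeometric point probabilities no greater than the observed
one times $1 + 10^{-7}$ — the dominant two-sided convention, stated
explicitly here for bit-reproducibility. Probabilities are accumulated via
log-binomial coefficients, keeping the enumeration exact to about $10^{-12}$
for table totals up to 1000; any zero margin gives p = 1. Significance
labels are inclusive: `***` at p ≤ 0.0005, `**` at 0.005, `*` at 0.05, and
0.05 is the significance cutoff. No multiplicity correction is applied
across markers.

## Numerical choices

* Trigamma inversion uses damped Newton iteration with asymptotic guards
  (`1/y` for tiny `y`, `1/sqrt(y)` for huge `y`), converging to relative
  1e-10.
* Extreme t-statistics would underflow `pt()` to 0; p-values are floored at
  the smallest positive double so the (0, 1] invariant holds.
* A gene with zero residual variance and zero fold change gets t = 0,
  p = 1; zero variance with a nonzero fold change is only testable with a
  proper prior (`d0 > 0`) and is an error under `d0 = 0`.
* Expression TSVs serialize doubles with 17 significant digits so a
  write/read round trip is bit-identical.
* The simulator consumes its RNG stream in a fixed order (baselines,
  variances, noise) and restores the caller's RNG state, so identical seeds
  give bit-identical outputs regardless of surrounding code.

## Validation scale

The test suite validates recovery at the default study conditions — 10,000
genes, 31 + 17 planted, 200 decoys, triplicates — over 20 simulation seeds
(about 3 s of compute), alongside exhaustive oracles: all 729 call vectors
for the Boolean engine against truth-table enumeration, and every 2x2 table
with total at most 30 for the Fisher test against direct hypergeometric
enumeration. The variance-prior fit and the moderated t are additionally
cross-checked against the independent `limma` implementation when it is
installed.

## A worked example

```{r}
sim <- simulate_expression(seed = 1)
fit <- organizer_screen(sim$matrix)
summary(fit)
recovery_metrics(fit$signature, sim$truth)
```

Screening a candidate region against a signature:

```{r}
sig <- fit$signature
profile <- simulate_candidate_profile(sig, 20 / 31, 15 / 17, seed = 2,
                                      region_name = "AIP endoderm")
score_candidate(sig, profile)
```

And an explant assay:

```{r}
rec <- simulate_assay_records(8, 8, p_pos_treat = 1, p_pos_ctrl = 0,
                              seed = 3)
assay_test(rec, c("treatment", "control"), "MYOCD")
```

## Known limitations

* The screen operates at probe-set resolution; probe-to-gene collapsing,
  annotation and functional categorization are out of scope.
* Normalization (PLIER or otherwise) and array QC are upstream of this
  package: the entry point is a normalized matrix.
* The per-comparison FDR convention means the family of six comparisons is
  not jointly corrected; the Boolean conjunction is itself a strong filter,
  but no global FDR statement attaches to the final signature.
* Negation (`NOT`) leaves, weighted combinations and rank-aggregation
  alternatives to the Boolean algebra are not implemented.
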
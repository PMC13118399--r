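---
title: "Methods: aggregate stability, co-occurrence modules and keystone taxa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aggregate stability, co-occurrence modules and keystone taxa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggrekey)
```

## The scientific question

Intercropping a cereal with legume cover crops changes both soil organic
carbon (SOC) and the soil's physical structure. The structure is usually
summarized by wet-sieving the soil into four size classes — >2 mm and
0.25–2 mm macroaggregates, 0.053–0.25 mm microaggregates, and the
<0.053 mm silt-and-clay fraction — and computing the mean weight
diameter (MWD). A central hypothesis in this literature is that the
*allocation* of carbon into >0.25 mm macroaggregates, rather than total
SOC, drives aggregate stability, and that specific microbial taxa
(bacteria, saprotrophic fungi, and arbuscular mycorrhizal fungi)
mediate that allocation. `aggrekey` implements the full inference chain
from genus-level amplicon tables and wet-sieved aggregate data to a
path model of MWD:

1. aggregate metrics per sample (mass distribution, R0.25-mass, MWD,
   aggregate-associated C distribution, R0.25-SOC);
2. treatment inference (one-way ANOVA with Duncan's multiple-range
   letters, group contrasts);
3. community ordination (Bray–Curtis, PCoA, PERMANOVA);
4. a combined three-kingdom Spearman co-occurrence network with
   walktrap module detection;
5. keystone module and keystone genus selection against the four
   aggregate-C responses;
6. permutation-importance ranking of genera (random forest) and the
   crucial-genus union;
7. a PLS path model linking the crucial genera (as a PC1 score) to MWD
   through mass distribution, per-fraction SOC concentration, and the
   C distribution.

## Aggregate metrics

For fraction masses $m_i$ (g) and concentrations $SOC_i$
(g C kg$^{-1}$ fraction):

* mass proportion $w_i = m_i / \sum_j m_j$;
* $R_{0.25}\text{-mass} = 100\,(m_{>2} + m_{0.25-2}) / \sum_j m_j$;
* $MWD = \sum_i \bar{x}_i w_i$ with $\bar{x}_i$ a representative
  diameter per class;
* C distribution$_i = 100\, m_i SOC_i / \sum_j m_j SOC_j$;
* $R_{0.25}\text{-SOC}$ = the two macroaggregate C-distribution entries.

The representative diameters are not part of the wet-sieving protocol
itself; we default to class midpoints, bounding the open top class by
the 8 mm pre-sieving mesh: $\bar{x} = (5.0, 1.125, 0.1515, 0.0265)$ mm.
This choice shifts MWD *levels* but not treatment orderings (MWD is
linear in the fixed $\bar{x}$); the scheme is configurable
(`size_class_scheme()`) and recorded in every output. Treatment means
of ratio quantities are means of per-sample values, matching how
replicate SDs are normally reported. Percent contrasts between
treatment sets are computed on treatment-set means of per-sample
metrics, with the dispersion term taken over the member treatments;
averaging per-replicate ratios instead gives values within the same
reported uncertainty, so the simpler estimator was chosen.

## Inferential primitives

**Duncan's multiple range test.** Classical Duncan compares a span of
$p$ ordered means against
$q(\alpha_p, p, \nu)\sqrt{MSE/n_h}$ with the protection level
$\alpha_p = 1-(1-\alpha)^{p-1}$. Unprotected, the extreme-pair type-I
error under a complete null equals $\alpha_p > \alpha$ for $k > 2$
groups. We therefore *protect* the test with the omnibus ANOVA F-test:
letters only split when the F-test is significant at $\alpha$. This
keeps the probability of any letter separation under the global null at
$\alpha$, reduces exactly to the usual two-sample comparison for two
groups, and mirrors how post-hoc letters are reported in practice.
Ties in means are broken by treatment label so letters are
deterministic.

**Spearman correlation.** Midrank-based $\rho$; p-values switch from an
exact enumeration of all $n!$ orderings at $n \le 10$ to the
$t$-approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ above. The switch
point is recorded in the result. For network construction
(thousands of pairs at $n = 21$) the $t$-approximation is used
throughout, as the field's standard tooling does; its far tail is
mildly anticonservative against the discrete exact null, which is why
the network null-control test compares edge densities against a
Monte-Carlo null rather than against the nominal level.

**Multiple testing.** Benjamini–Hochberg step-up, applied *once over
the complete pooled pair set* of the network (within- plus
cross-kingdom), never per kingdom — the network is a single graph and
the discovery guarantee should refer to its whole edge family.

## Network and module detection

Dominant genera (mean relative abundance strictly above 0.1%) from the
three marker tables are pooled into one node set; each kingdom keeps
its own compositional scale because read counts are not quantitatively
comparable across markers. Edges require $|\rho| > 0.7$ and BH-adjusted
$p < 0.05$; negative edges are kept, with $|\rho|$ used as the weight
for community detection so that strong negative association still binds
nodes into a module. Isolated nodes are dropped, and the 10% rule for
"major" modules counts the drawn graph's nodes (post-removal): the
module-size threshold is read relative to the network actually
analysed. Walktrap's walk length defaults to 4 (the conventional
default) and is exposed in `run_config()`. Modules are relabelled by
descending size (I, II, ...) with ties broken by member name, making
labels deterministic.

## Keystone selection

A *major* module is *keystone* when its per-sample accumulated relative
abundance correlates (Spearman, $p < \alpha$) with at least one of the
four aggregate-C responses. Within a keystone module, genera are ranked
by mean relative abundance and the smallest prefix whose cumulative
share strictly exceeds 75% of the module total is retained (the genus
that crosses the boundary is included); module abundance is summarised
as the sum over samples of member means — ranking per sample versus
pooled rarely differs, and the pooled form is simpler to audit. The
prefix is then filtered to genera whose abundance differs between
treatments (protected Duncan, not all sharing one letter).

Importance ranking fits bagged regression trees (random forest, 500
trees by default) of each C response on the candidate genera.
Importance is the mean increase in out-of-bag MSE under predictor
permutation, expressed as a percentage of the response variance;
p-values come from refitting under response permutation (999 by
default), building a per-genus null. Response permutation (rather than
re-permuting importances) was chosen because it nulls the entire
model-fitting process, not only one predictor's contribution, and the
choice is recorded here because either convention appears in published
pipelines. Variance explained is $1 - \text{OOB MSE}/\text{Var}(y)$.
The crucial set is the union over the four responses of genera with
significant importance.

## PLS path model

The path model uses reflective (mode A) measurement for every block and
the *path* inner-weighting scheme — the common defaults where the
estimation scheme is not otherwise dictated; both centroid and factor
alternatives would change coefficients only marginally for
single-indicator and well-conditioned blocks. Indicators are
standardized; outer weights start at 1; iteration alternates latent
scoring, path-scheme inner weighting (regression on predecessors,
correlation with successors), and mode-A outer updates until the
largest outer-weight change is below $10^{-7}$ (at most 300
iterations; non-convergence is an error carrying the last delta).
Latent signs are anchored to a positive correlation with each block's
first indicator. Path coefficients are OLS fits among the standardized
latents, so with single-indicator blocks the whole machinery collapses
to classical standardized path analysis — a property the tests exploit
as an oracle. Total effects satisfy $(I-B)^{-1} - I$ exactly.
$GOF = \sqrt{\overline{\text{communality}} \times \overline{R^2}}$.
Bootstrap CIs use case resampling with percentile intervals; resamples
that make an indicator constant are redrawn and counted.

The default structural model (`default_path_model()`) sends the
crucial-genus PC1 into mass distribution, SOC concentration and C
distribution, lets mass and SOC concentration feed the C distribution,
and regresses MWD on all three soil blocks. MWD and PC1 are
single-indicator blocks; the three soil blocks carry their four
size-class indicators.

## The synthetic generator

`sim_spec()` describes a synthetic version of the seven-treatment,
three-replicate trial. Genus abundances follow a log-normal +
multinomial model: module activities
$a_m \sim N(\text{multiplier}_{treatment}, 1)$, member log-abundance
$= \text{baseline} + \text{loading}\cdot a_m + N(0, \sigma)$, softmax
per kingdom, multinomial sampling at a uniform random depth. This
produces realistic mean–variance scaling and exact depth control for
rarefaction tests. Aggregate targets default to the reference trial's
printed treatment means and SDs (`study_reference()`); a coupled module
shifts its size class's mass proportion by $\beta a_m$ percentage
points *before* renormalization onto the 100% simplex, so $\beta$ keeps
an interpretable sign.

Default conditions: 120/60/25 genera per kingdom; three planted
modules (an intercropping-enriched module coupled at $\beta = +3.5$
percentage points per activity unit to the 0.25–2 mm class, a
monoculture-type module at $\beta = -1.0$ on the >2 mm class, and an
uncoupled single-treatment module); loading 0.5 with treatment
multipliers 0.2/4, giving member pairwise correlations near 0.85 and
clearly treatment-responsive members; depth 10,000–15,000. Two
numerical choices deserve note. First, module members carry a negative
baseline offset (−0.8 on the log scale) so that their combined share of
each composition stays modest; otherwise compositional closure induces
spurious correlated clusters among *non-members*, which is a real
hazard of relative-abundance networks rather than an artifact of this
package. Second, the monoculture module's negative coupling is kept
small because the >2 mm class means of the reference trial (7–10%)
leave little headroom before the simplex constraint truncates draws.

What the generator does *not* emulate: phylogenetic structure,
sequencing error and chimeras, per-kingdom differences in depth
profiles, overdispersion beyond the log-normal, and spatial field
effects (the randomized-block term is not simulated because the
published design information does not support estimating it). Passing
the recovery tests therefore shows the pipeline's logic is sound under
a faithful statistical null and a known planted signal — not that any
particular real dataset will yield stable modules.

## Validation problem sizes

The test-suite checks use: 50 simulated studies for end-to-end
planted-keystone recovery; 100 null studies (70 genera) for the
network null control against a 50,000-draw Monte-Carlo null of
$|\rho| > 0.7$ at $n = 21$; 2,000 simulations for the Duncan type-I
check; exhaustive enumeration (720 permutations) for the PERMANOVA and
exact-Spearman oracles; 1,000 draws against the hypergeometric
expectation for rarefaction; and reduced analysis settings
(200 trees, 99 permutations) inside simulation loops, with the
defaults (500 trees, 999 permutations) retained for real analyses.

## Known limitations

* Rarefaction depth is per marker set; whether a joint depth across
  markers would be preferable cannot be decided from published
  information, so the per-marker choice is exposed in the API.
* The dominance cutoff is applied to the mean relative abundance across
  all samples; a per-sample occurrence rule would retain rare but
  locally abundant genera.
* Duncan letters near the significance boundary can differ from other
  implementations by small studentized-range quantile differences;
  orderings of clearly separated groups are stable.
* PERMANOVA uses unrestricted permutations; block-restricted
  permutations would be preferable when block structure is available.
* The PLS path model is estimated on 21 samples in the reference-sized
  design; coefficients are descriptive and the bootstrap intervals are
  wide at that size.
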
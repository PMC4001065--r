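---
title: "Structural disruption scoring of missense variants: models and methods"
author: "sdscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural disruption scoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdscore)
```

## The problem

Sequence-conservation-based predictors agree well on the most damaging
missense variants, but for candidate moderate-effect variants from exome
sequencing their calls are close to chance. The structural disruption
score (SDS) is an orthogonal, structure-aware composite: it asks, for each
missense substitution, how many of a small set of residue-level properties
look like those of known disease-causing variants rather than neutral
polymorphisms in the same proteins, and uses the count as a ranking score.

The package computes the residue features it can derive itself (Grantham
physico-chemical distance, relative solvent accessibility from atomic
coordinates, stabilization-center contacts, disulfide geometry), consumes
the outputs of external predictors as annotation columns (deleteriousness
and conservation calls, predicted folding free-energy change
$\Delta\Delta G$, sequence non-optimality $\Gamma$, normalized B-factor
and RMSF, flexible-site probability, surface-patch and domain membership,
gene-level RVIS), and never calls any external service.

## The score

Seven deleterious-direction binary flags are computed per variant, each
with a boundary-inclusive threshold:

| flag | definition |
|---|---|
| high deleterious count | $\geq 4$ of 6 predictor calls deleterious |
| large amino-acid change | Grantham distance $\geq 100$ |
| Gly/Pro change | substitution into or out of glycine or proline |
| buried site | RSA $\leq 20\%$ |
| protein patch | on the most significant conserved surface cluster |
| protein domain | inside an annotated domain |
| destabilizing | $\Delta\Delta G \geq 0.5$ kcal/mol |

The SDS is the number of flags that are true, an integer in $[0, 7]$.
Variants with SDS $\geq 4$ form the priority list. The list is then
partitioned by gene tolerance (RVIS $> 0$ high, $< 0$ low; exactly zero is
classed high because a zero residual means "as expected", which is not
intolerance — the tie-break is logged when triggered). Priority variants
that alter a highly flexible site — a feature enriched among neutral
variants — are excluded. The final priority list is: high-tolerance,
non-excluded priority variants, plus low-tolerance priority variants whose
literature-curation column marks them likely relevant. The curation column
is an input; the package does no text mining, so reproducing a curated
final list requires supplying it.

Missing annotations give missing flags. A missing flag counts as zero in
the score (the count is not renormalized) and is tallied in
`n_missing_features` so low-coverage variants can be filtered. The choice
matters: an alternative would renormalize by coverage, but that would make
scores between variants with different annotation coverage incomparable.

The score is always computed over the canonical seven features. The
enrichment stage (below) reports which features actually separate the
classes in the data at hand; the selected set is reported alongside and
does not silently change the score.

```{r}
cohort <- workedExampleCohort()
res <- scoreVariants(cohort)
res
```

## Feature enrichment

Whether each feature distinguishes causal (positive) from neutral
(negative) controls is tested with a one-tailed Fisher's exact test on the
2x2 table (feature x class), the direction declared a priori:
deleterious-direction features are tested for enrichment among positives,
neutral-direction features (highly flexible site, highly dynamic site,
full conservation) among negatives. Continuous measures are compared with
two-tailed unpaired pooled-variance t-tests (the pooled form is used
because its degrees of freedom are $n_1+n_2-2$). No multiple-testing
correction is applied by default — each feature is tested at its own
$\alpha = 0.05$ — because the feature set is small, fixed and directional;
a Bonferroni adjustment can be imposed by passing a smaller `alpha`.
Conservation is deliberately never an SDS component: its direction of
enrichment is unstable across cohorts, so it is only reported.

## Structure-derived features

**RSA.** Solvent-accessible surface area is computed by Shrake–Rupley
integration: each atom's sphere (van der Waals radius + 1.4 Å probe) is
sampled at 960 deterministic golden-spiral points and the fraction not
occluded by neighboring expanded spheres is the accessible fraction.
Residue RSA is the residue's area as a percentage of an
alanine-X-alanine reference maximum. Two references are available:
`"tien2013"` (default), a published theoretical max-ASA table appropriate
for full-side-chain structures; and `"computed"`, the central-residue area
of an ideal extended Ala-X-Ala tripeptide built by the package's internal
geometry engine, which is the right normalization for the backbone-only
toy structures the package generates (and makes their reference RSA
exactly 100 by construction). RSA is reported uncapped; values above 100
are possible for unusually extended conformations.

**Stabilization centers.** A candidate stabilization-center pair is two
residues at least 10 apart in sequence with a heavy-atom pair closer than
the sum of their van der Waals radii (C 1.70, N 1.55, O 1.52, S 1.80 Å)
plus 1.0 Å. The 1.0 Å slack is the long-range-contact reading of the
published criterion; a literal "sum of van der Waals radii below 1 Å" is
physically impossible. The mutual-contact-fraction and conservation
refinements of the dedicated servers are not implemented; a precomputed
`sc_residue` column can be consumed instead.

**Categorizations.** $\Delta\Delta G$ is banded as: no change in the open
interval $(-0.5, 0.5)$; mildly stabilizing $(-2, -0.5]$; strongly
stabilizing $\leq -2$; mildly destabilizing $[0.5, 4)$; strongly
destabilizing $\geq 4$ kcal/mol. $\Gamma \leq -5$ kcal/mol marks highly
non-optimal residues (catalytic/binding-site proxy). DSSP secondary
structure is grouped G/H/I (helices), E, T/B, S, C.

**Dynamics and flexibility tails.** Normalized B-factor and P(Flexible)
are flagged at the empirical 2.5/97.5 percentiles of the pooled values of
all variants scored together; normalized RMSF uses 0.5/99.5. Percentiles
use linear interpolation between order statistics (R's default type 7) —
the convention is fixed and documented because printed cutoffs cannot be
regenerated without the original cohort. With fewer than 40 non-missing
values the fixed published fallback cutoffs are used (B-factor
−0.537/1.17, RMSF −0.607/1.195, P(Flexible) 0.158/0.860) and the fallback
is logged. The pooling is over all rows given to the function, not per
gene. A precomputed `flex_percentile` column (0–100) overrides the
raw-probability route where available.

## The Grantham model

The published 20x20 integer distance matrix is shipped verbatim and is
the primary implementation: downstream annotation tools cite the matrix,
and the 1974 rounding makes it, not the generating formula, the ground
truth. The composition/polarity/volume formula (weights 1.833, 0.1018,
0.000399; global scale fixed so the 190-pair mean is 100) is available as
`granthamFromProperties()` and serves as a cross-check; it reproduces the
matrix to rounding except for the two tryptophan–acidic entries, a known
quirk of the published table.

## The synthetic-data generator

`generateCohort()` fabricates labelled cohorts with the class-conditional
structure the analysis assumes: each deleterious-direction feature is
carried with probability 0.5 by positives and 0.1 by negatives; flexible
sites are rarer in positives (0.01) than negatives (0.08);
$\Delta\Delta G \sim N(1.5, 1)$ for positives and $N(0.3, 1)$ for
negatives; RSA is a uniform mixture matching the planted burial flag;
P(Flexible) is Beta-distributed per class with the second shape solved so
the tail mass above 0.860 equals the class rate; gene-level RVIS is
$N(0, 0.5)$. Default cohort sizes are 30 case / 1674 negative / 100
positive, the shape of a small exome candidate study. Case variants are
drawn 30% of the way from the negative toward the positive probabilities,
emulating a case pool in which only a fraction of variants are causal.

Wherever a numeric threshold exists the flag is derived from the drawn
value, never sampled separately, so the generator exercises the package's
own thresholding; intrinsically binary features (patch, domain) are
Bernoulli. The amino-acid pair of each variant is sampled from the subset
of ordered pairs consistent with its planted Grantham and Gly/Pro flags.
Ground truth is kept in `cohortMetadata(x)$truth`.

What the generator does not emulate: correlations between predictors,
realistic per-gene variant clustering, linkage between features (each is
planted independently), or realistic folds in the toy structures. Passing
recovery tests therefore show the pipeline's statistics behave correctly
under its own assumptions, not that those assumptions hold in real
cohorts.

`generateToyStructure()` builds idealized poly-alanine geometry by
internal-coordinate placement (standard bond lengths/angles; helix
$\phi,\psi = -57,-47$; extended $-139,135$), plus a "shell" fixture — one
residue enclosed by a 5.5 Å sphere of carbon atoms — for burial tests. A
straight helix has no residue contacts at $\geq 10$ sequence separation
(the rise over 10+ residues exceeds 15 Å), so positive stabilization-center
tests use folded-back two-strand fixtures.

## Numerical and design choices

- Threshold boundaries are inclusive exactly as the inequalities are
  printed in the score definition (e.g. RSA = 20 is buried, ddG = 0.5 is
  destabilizing, ddG = 4 is strongly destabilizing).
- Ranked output sorts by descending score with ties broken by gene symbol
  then position, making byte output deterministic.
- The Fisher test with an all-zero table returns p = 1 by convention and
  logs; a pooled t-test of two constant equal samples returns t = 0,
  p = 1.
- The priority filter is applied before the flexible-site exclusion; the
  order does not change the final set but is fixed for reproducibility.
- Simulation sizes in the test suite (e.g. 100 seeded recovery runs at
  200/2000/200, 2000 null t-tests, 300-run null selection calibration,
  80000-point Monte-Carlo surface-area oracle) were chosen to keep
  sampling noise well below the asserted tolerances at desk scale.

## Limitations

- The pipeline consumes external predictor outputs; nothing here
  re-implements or validates those predictors, and their errors propagate.
- Position mapping between UniProt coordinates and PDB residue numbering
  is taken verbatim from the inputs; no alignment is attempted.
- The stabilization-center detector implements only the distance/
  separation criterion.
- Cohort-level empirical tail cutoffs depend on the composition of the
  table being scored; scoring a different variant pool shifts the
  flexible/dynamic flags (the fixed fallback cutoffs can be forced via
  `classifyDynamicsFlexibility(cutoffs = ...)`).
- The final-priority rule depends on a human curation column for
  low-tolerance genes; without it the low-tolerance branch contributes
  nothing and this is logged, not guessed.
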
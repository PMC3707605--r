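---
title: "Methods: miRNA-Seq screening and in-silico miRNA therapy simulation"
author: "mirTherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA-Seq screening and in-silico miRNA therapy simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirTherapy)
```

# Scope and model

mirTherapy implements two connected analyses for matched
normal/tumor/metastasis (N/T/M) cancer cohorts.

**Small-RNA quantification and differential expression.** Reads are
adaptor-clipped (survivors must keep at least 16 bp), aligned reads are
counted "on target" when they overlap a miRNA annotation interval by at
least one base, and expression differences are assessed per patient as
pseudocounted log2 count ratios, median-centered per comparison, with a
one-sample two-sided t-test against zero. Candidate biomarkers are ranked
by two-sided Mann-Whitney tests and all pairs from the top list are
screened for strict linear separability of the two sample groups in the
pair's 2-D log2-expression space. qPCR-style validation data are handled
with the delta-delta-Ct method against a stable reference small RNA.

**In-silico miRNA treatment.** A cellular signaling network is modeled as
a generalized mass-action reaction system: components (gene templates,
transcripts, proteins, ligands) and reactions with rates
$v_j = k_j \prod_r x_r^{s_r} \prod_m x_m$, where reactants $r$ enter with
their stoichiometry and modifiers $m$ act as multiplicative catalysts.
Fixed (boundary) components never change during integration; gene
templates are fixed and carry the expression state. The ODE system
$\dot x = S\,v(x;k)$ is integrated to steady state. Because kinetic
parameters of such models are largely unknown, simulation is Monte Carlo:
parameter vectors are drawn log-uniformly and every experimental condition
is integrated under every draw (a paired design), so condition ratios are
free of parameter-sampling variance. A miRNA "treatment" is modeled as
down-scaling the transcription rate constants of the miRNA's target genes
by a dose factor $f$ (a miRNA increase represses its targets); "depletion"
scales them up symmetrically. Per component, the treated state is compared
to normal and to the untreated disease state, and the shift is classified
into ten therapeutic-effect subgroups.

# The effect classifier

For one component let $\lambda_{TN}$ be the log2 ratio of the disease
state versus normal and $\lambda_{MN}$ the treated state versus normal.
With cutoff $c = 0.58$ (about 1.5-fold):

* $\lambda_{TN} > c$ (initially up): `aggravated+` if
  $\lambda_{MN} > \lambda_{TN}$; `weak+` if $c < \lambda_{MN} \le
  \lambda_{TN}$; `desired+` if $|\lambda_{MN}| \le c$ (back to normal);
  `flip+-` if $\lambda_{MN} < -c$ (overshoot past normal).
* $\lambda_{TN} < -c$: the mirror labels `aggravated-`, `weak-`,
  `desired-`, `flip-+`.
* $|\lambda_{TN}| \le c$: `side+`/`side-` when treatment pushes the
  component out of the normal band, else `none`.

Boundary ties are deterministic and sit with the milder label:
$\lambda_{MN} = \lambda_{TN}$ is weak, not aggravated, and $|\lambda| = c$
is inside the normal band. The eleven regions tile the plane; this is
property-tested against an independently written region predicate and an
antisymmetry check (negating both ratios mirrors every label).

Per dose, direct miRNA targets are excluded first — a direct target's
shift is forced by construction and says nothing about network response —
and the remaining components are kept only if the treatment actually moved
them relative to the untreated disease state: fold change
$2^{\lambda_{MT}} > 1.2$ or $< 0.8$. The alternative reading of the
published filter ("control state" = normal) is available via
`filterOn = "lambdaTN"`; the treated-vs-untreated default was chosen
because it makes the identity dose behave correctly (nothing moved, so
nothing is counted) and because an unmoved component cannot exhibit a
treatment effect. Frequencies are counts divided by the number of kept
components, so they sum to one per dose.

# Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| pseudocount (log2 ratios) | 1 | counts | zero-count guard, standard for count ratios |
| `minLen` after clipping | 16 | bp | shorter fragments align ambiguously |
| t-test form | one-sample on per-patient ratios | — | tissues are matched within patients |
| Mann-Whitney exactness | exact for groups ≤ 12 | — | cohort-scale groups allow full enumeration |
| top list size (pair screen) | 50 | miRNAs | pairs beyond the top ranks add noise, not signal |
| classification cutoff $c$ | 0.58 | log2 | ≈ 1.5-fold, separates band from de-regulation |
| fold filter | 0.8 / 1.2 | linear fold | minimal biologically meaningful movement |
| dose grid | 1.01–100 | fold | spans homeopathic to saturating doses, denser in 1.2–4 where therapeutic windows appear |
| sampling range | $10^{\pm 1}$ | multiplier | two decades of kinetic uncertainty |
| `nSamples` | 100 | draws | desk-scale ensemble; ratios are paired so their medians stabilize quickly |
| steady-state `tol` | 1e-6 | relative rate | $\max_i |\dot x_i|/(|x_i|+\epsilon)$ below tol defines quiescence |

# Numerical choices

*Integration.* Steady states are found by integration-until-quiescence
(stiff `lsodar` with an analytic mass-action Jacobian and a root function
that stops at the tolerance), not by root-finding: cascades with sampled
parameters can have slow modes, and following the trajectory is robust
where a Newton solve from an arbitrary start is not. Non-convergence is
returned flagged and flagged runs are excluded from ratio aggregation,
never silently used.

*Parameter sampling semantics.* Sampled log-uniform values multiply each
condition model's nominal rate constants. Nominal constants are 1 in the
toy generator, so the draws are the parameters themselves for the base
model, while a disease lesion or dose expressed in the nominals survives
sampling exactly. This is what makes the design paired: for linear motifs
the condition ratio cancels the draw entirely.

*Ratios.* Per-sample log2 ratios use a pseudo-abundance of 1e-9 on both
sides to guard exact zeros; aggregation is the median across converged
samples (mean available), with a Wilcoxon signed-rank p-value across
samples. Fully tied ratio vectors report p = 1.

*Separability.* Strict linear separability of two 2-D point sets is
decided exactly with a finite candidate set: the maximum-margin direction
is always a difference of one point from each group or an edge normal of
one of the two convex hulls, so only those directions are tested. A
separation must clear a relative margin of 1e-9 — numerically identical
points in both groups must count as overlap, and two BLAS code paths can
round the same projection differently at the last ulp. Boundary-touching
groups therefore count as overlapping (the strictest reading of "no
overlap"); `strict = FALSE` relaxes this. The published analysis does not
state the family of linear combinations; any direction is searched, which
is the weakest assumption and subsumes fixed-weight variants.

*Coordinates.* All genomic intervals live in `GRanges` (1-based, closed),
the native convention of the R/Bioconductor interval stack; BED (0-based
half-open) and SAM inputs are converted at the boundary by
`rtracklayer`/`Rsamtools`, keeping every internal overlap test bit-exact.

*Adaptor clipping.* Clipping always starts from one of the read ends: on
the 3' side the clip starts at the leftmost position where the remainder
of the read matches a prefix of the adaptor (covering read-through, where
bases after a full adaptor are garbage), on the 5' side only a partial
adaptor suffix overlapping the read start is removed. The longer clip
wins; ties go to 3'.

# The synthetic-data generators

All inputs can be generated with known ground truth, which is what the
test suite and the acceptance script run on.

*Count cohorts* (`generateCountCohort`) emulate an 8-patient × 3-tissue
matched design: negative-binomial counts (dispersion 0.1; dispersion 0
degrades to Poisson) around log-normal per-miRNA baselines (median ≈ 100
reads, sdlog 1.5 — a typical small-RNA-seq abundance spread), mild
log-normal library-size factors (sdlog 0.1), 724 miRNAs by default (the
detectable-miRNA scale of such cohorts) and planted ±3 log2-fold effects
in tumor and metastasis. What this emulates: overdispersed counts, shared
patient structure, planted truth. What it does not: isomiR structure,
adaptor chemistry, mapping artifacts, or correlated miRNA families — so
green tests certify the statistical pipeline, not the upstream
sequencing.

*Alignment fixtures* (`generateAlignments`) place reads on one synthetic
reference with disjoint miRNA-sized targets and always include two
deterministic boundary reads for the first target: exactly one base of
overlap (must count) and exactly zero (must not). Expected counts are
computed in the generator by explicit enumeration.

*Toy networks* (`generateToyNetwork`) are layered
ligand→receptor→cascade→transcription-factor systems: per gene a fixed
template, a transcript and a protein; synthesis with template and
upstream proteins as catalytic modifiers; first-order degradation.
Component (3n+1), reaction (4n) and parameter (4n) counts are closed
forms of the spec, the wiring is seeded, layers make the cascade
cycle-free by construction, and steady states have a layer-by-layer
closed form used as the test oracle. miRNA-1 targets are the first
`nMirnaTargets` genes in layer order — deterministic, so planted-lesion
studies are reproducible; a disease variant scales target transcription
by the lesion factors.

*Ct tables* (`generateCtTable`) plant linear fold changes against a
constant reference gene with 0.15-cycle technical noise; default planted
effects are one 8-fold-down and one 9-fold-up miRNA, magnitudes typical
for strongly de-regulated miRNAs in these cohorts.

# Design decisions on open points

* *Multi-target reads* increment every overlapped target; no assignment
  heuristic is defensible from the counting rule alone, and the shared
  counting is order-independent.
* *Detection* means at least one read in at least one sample of a tissue
  class (`allSamples = TRUE` gives the stricter reading).
* *Strand* is ignored in the overlap test by default (flag to enforce).
* *Depletion* is modeled as the exact mirror of treatment (target
  synthesis up-scaled); the published text does not pin the mechanism and
  the symmetric form keeps dose/inverse-dose as exact inverses.
* *Translation scaling* is off by default; miRNA repression is applied at
  transcript synthesis. A `scaleTranslation` flag extends it to protein
  synthesis.
* *No multiple-testing correction* by default: raw p-values with fixed
  0.05/0.01 thresholds are reported, matching how such screens are
  usually read; `adjust = TRUE` adds Benjamini-Hochberg.
* *Model statistics* report total, fixed and variable component counts
  side by side; published component tallies for large curated models mix
  these views, and `nVariables + nFixed = nComponents` makes the
  relation explicit.

# Problem sizes

The suite and the acceptance script run at desk scale, chosen so each
statistical check has the power it needs and no more: 10^4 random points
for the classifier-oracle equivalence; 100 random instances for the
separability oracle; 2500 null tests (five 500-miRNA cohorts) for the
type-I error of the ratio t-test; a 200-miRNA 8-patient cohort with 20
planted effects for top-list recovery; and for dose-response recovery a
9-gene, 3-layer toy network (targets = the full first layer, lesion 2×)
under a 100-draw ensemble across the 9-point default grid, repeated for
three seeds. The planted-lesion recovery uses the fact that dividing
target synthesis by the lesion factor restores every downstream component
simultaneously, so the desired+ frequency peaks at the grid point nearest
the planted factor.

# Known limitations

* The SBML subset is generalized mass action with multiplicative
  modifiers (plus constant-only laws); assignment rules, events and
  arbitrary MathML are rejected loudly rather than approximated.
* Steady-state detection by quiescence cannot distinguish a true fixed
  point from an extremely slow drift below tolerance; sustained
  oscillations are reported as non-converged.
* The pair screen is purely geometric: a "promising" pair certifies
  strict separation of the observed samples, not generalization — no
  cross-validation or ROC analysis is attempted.
* Per-patient treatment-response differences are descriptive; with a
  handful of patients no testing across patients is meaningful.
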
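---
title: "Tandem mass isotopologue analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tandem mass isotopologue analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemid)
library(dplyr)
```

# The problem

In a stable-isotope tracing experiment, cells are fed a labeled substrate
(here D-¹³C₆-glucose or L-¹⁵N₂-glutamine) and the label spreads through
metabolism. For each metabolite one measures the *mass isotopologue
distribution* (MID): the vector $M_0, \dots, M_n$ of fractions of molecules
carrying $0, \dots, n$ heavy tracer atoms. When the mass spectrometer also
fragments the molecule (MS²), each fragment retains a known subset of the
parent's atoms, and the *joint* distribution of precursor and fragment mass
shifts — the tandem MID — carries positional information that the precursor
MID alone cannot: isotopomers with the same mass but different labeled
positions send different numbers of labels into a fragment.

tandemid implements this analysis end to end for the glutathione (GSH) de
novo synthesis network of glutamate, serine, glycine, cysteine, GSH and its
oxidized dimer GSSG: correction of raw isotopologue areas for natural
isotope abundance and tracer purity, enrichment statistics, tandem-MID
assembly and positional-isotopomer deconvolution, and two-group study
reports.

# Measurement model and correction

An observed MID is the true tracer-labeling distribution convolved with two
nuisance processes, both linear and column-stochastic:

* **Natural abundance.** Each of the $n - j$ tracer-element positions not
  carrying tracer label is heavy with the element's natural probability $a$
  (defaults: ¹³C 0.0107, ¹⁵N 0.00364, overridable on `tracer_spec()`), so
  $F_\mathrm{nat}[i,j] = \binom{n-j}{i-j} a^{i-j} (1-a)^{n-i}$.
* **Tracer purity.** Each nominally labeled atom is actually heavy with
  probability $p$ (0.99 for ¹³C₆-glucose, 0.98 for ¹⁵N₂-glutamine), so
  $F_\mathrm{pur}[i,j] = \binom{j}{i} p^i (1-p)^{j-i}$.

The pipeline applies the fixed composition $F = F_\mathrm{nat}
F_\mathrm{pur}$: impurity determines which nominal labels are real, natural
abundance then decorates every remaining light position. The two matrices do
not commute — the commutator is of order $a(1-p)$ even for $n = 1$ — so the
order is part of the contract and is what the equivalent per-atom model
implies (a failed tracer atom is an ordinary light atom with its natural
chance of being heavy). The test suite checks the combined matrix against an
exhaustive $2^n$ enumeration of per-atom heavy/light states.

The default mode corrects over tracer-element atoms only, appropriate for a
high-resolution TOF regime in which tracer isotopologues are resolved from
other-element isotope peaks. A low-resolution mode additionally convolves
the isotope patterns of all non-tracer elements of the supplied formula
(²H, ¹⁵N/¹³C, ¹⁷O/¹⁸O, ³³S/³⁴S/³⁶S at nominal mass shifts); mass pushed
beyond $M_n$ falls outside the measured window and columns are renormalized
so every built matrix stays column-stochastic.

**Inversion.** `correct_mid()` solves $\min \lVert F x - m \rVert^2$
subject to $x \ge 0$ (Lawson–Hanson non-negative least squares) and
renormalizes to $\sum x = 1$. Raw matrix inversion is never used: under
noise it produces negative fractions. Negative measured areas — common
baseline-subtraction artifacts — are clamped to zero with a warning. A
relative residual above 5% (configurable) flags the result without
erroring, since a high residual usually means interference worth inspecting
rather than an unusable spectrum.

**Fragments.** Fragment spectra are corrected with a matrix sized by the
fragment's retained tracer atoms, independently of the precursor selection.
Exact precursor-conditioned fragment correction would need the joint
isotope state of retained and lost atoms; the independence approximation is
the package's documented choice and the simulator uses the same forward
model, so round trips are exact where the approximation is consistent.

# Enrichment statistics

Mean isotopic enrichment is the average labeled fraction of tracer atoms,
$\mathrm{ME} = \sum_{i=1}^{n} M_i \, i / n$, 0 for an unlabeled pool, 1 for
a fully labeled one. It is scale-invariant in the areas and monotone when
mass moves to heavier isotopologues (both property-tested). The labeled
fraction of a pool is $1 - M_0$.

When fragments tile the molecule (GSH's F1 = glutamate moiety, carbons
c1–c5; F2 = glycine–cysteine moiety, c6–c10; declared with a
`partition_group`), the intact enrichment decomposes exactly as the
atom-weighted mean $\mathrm{ME} = \sum_f n_f \mathrm{ME}_f / \sum_f n_f$.
The worked example of `moiety_weighted_enrichment(c(0.39, 0.04), c(5, 5))`
gives 0.215; report tables print integer percents using **floor** (21, not
22), which is the only rule consistent with typical reported moiety and
intact values; `percent_floor(..., rule = "half_even")` switches to
conventional rounding. Whether published figures floor or round is usually
unstated, so the rule is explicit here.

# Tandem MIDs and positional isotopomers

`assemble_tandem_mid()` forms $T[j,k] = M_j \cdot c_j[k]$ from the
corrected precursor MID and the corrected conditional fragment MIDs
$c_j$; rows for precursor shifts without a measured MS² spectrum are
zero-filled and flagged. Row sums reproduce the precursor MID by
construction.

`resolve_isotopomer_fractions()` inverts the atom maps: for candidate
isotopomers $s$ (labeled-position subsets) at precursor shift $j$, the
design matrix stacks one indicator row per (fragment, fragment shift) with
$A[(f,k),s] = 1$ iff $|s \cap \text{atoms}(f)| = k$, and the weights solve
$\min \lVert A w - b \rVert^2$ on the probability simplex (quadratic
program). Design choices:

* **Declared candidates.** Candidates default to biochemically declared
  sets — glutamate M+2 restricted to the two first-turn TCA entries,
  1,2-¹³C₂ via pyruvate dehydrogenase (PDH) and 3,4-¹³C₂ via pyruvate
  carboxylase (PC); GSH M+2 to its three moiety combinations. Exhaustive
  enumeration of all $\binom{n}{j}$ subsets is available but almost always
  rank-deficient for realistic fragment sets.
* **Joint solves.** All fragments enter one stacked system: a fragment in
  which a peak is *impossible* for every candidate (glutamate Frag_2,
  c4–c5, can never show m+2 at first-turn M+2) contributes information as a
  constraint, and observed mass at such a shift surfaces as a large
  residual rather than being silently ignored.
* **Identifiability honesty.** The fit carries
  `identifiable = rank([A; 1']) >= #candidates`. Rank deficiency never
  raises: one least-squares solution is returned with the flag false, and a
  vanishing ridge ($10^{-10}$) is applied to the normal matrix only in that
  degenerate case, so identifiable solves are exact to solver precision.
  For at most three candidates the solver is test-checked against an
  exhaustive grid search over the simplex.

The tandem report splits each precursor isotopologue fraction into named
isotopomer fractions ($w_s M_j$), conserving $M_j$ exactly at each shift.

# The synthetic study

`generate_study()` emulates a two-group neuron tracing experiment: five
labeled replicates per group plus one unlabeled control sample per group,
per-sample protein content (normal, mean 38 µg, CV 0.15, truncated at
zero), and multiplicative lognormal noise (CV 0.1, unit mean) on every peak
area. All randomness flows from one seed.

Ground truth is generated at the positional-isotopomer level so that every
downstream quantity has an exact reference:

* **Glutamate** (and ketoglutarate): a mixture of unlabeled molecules,
  first-turn M+2 split $\varphi : (1-\varphi)$ between the 1,2- and
  3,4-isotopomers, and a uniformly labeled M+5 component representing
  multi-round labeling at isotopic steady state. The healthy preset (0.19 /
  0.35 / 0.46, $\varphi = 0.6$) gives ME 0.60; positional candidates remain
  first-turn patterns, which is where the fragment information lies.
  Multi-turn scrambling of label positions is deliberately not modeled.
* **Serine / glycine**: fully labeled fractions 0.11 / 0.07; **cysteine**
  always unlabeled (supplied from the medium, not from glucose or
  glutamine) — its enrichment after correction is a negative control.
* **GSH**: fraction `f_syn` (healthy 0.67) assembled de novo from the
  *current* precursor distributions (glutamate moiety c1–c5, glycine
  carbons c9–c10, cysteine carbons unlabeled), remainder pre-existing and
  unlabeled. Intact ME is then exactly the atom-weighted moiety
  composition, giving GSH ME ≈ 0.21 in the healthy preset.
* **GSSG**: the disulfide dimer of two independent GSH molecules; its MID
  is the self-convolution of the GSH MID and its ME equals GSH's.
* **¹⁵N mode**: glutamate's single nitrogen labeled at 0.23, serine 0.05,
  glycine 0; label reaches only GSH's glutamate-moiety nitrogen, so the F2
  conditionals carry no labeled mass.

The rotenone preset lowers TCA entry (M+2 0.25, M+5 0.33, $\varphi = 0.5$),
lowers `f_syn` to 0.45 and raises the oxidized share from 0.10 to 0.30,
reproducing the expected directions: lower enrichments, GSH/GSSG ratio
dropping from ≈ 18 to below 10, lower combined labeled fraction.

What the generator does *not* emulate: chromatographic interference,
resolution-dependent overlap of near-isobaric species, ¹⁸O/³⁴S fine
structure in high-res mode, non-stationary labeling kinetics
(approach-to-plateau), or correlated noise across isotopologues. Passing
parameter-recovery tests therefore demonstrates correctness of the
computational chain under the stated statistical model, not robustness to
every artifact of real LC–MS data.

# Recovered parameters

Two estimators close the loop from measurements back to generator
parameters:

* `estimate_pdh_fraction()`: the resolved 1,2-¹³C₂ weight over the sum of
  both first-turn weights at glutamate M+2.
* `estimate_de_novo_fraction()`: a newly synthesized product's expected
  enrichment is the atom-weighted mean of its precursors' enrichments, so
  $\hat f_{syn} = \mathrm{ME}_\mathrm{GSH} \cdot 10 / (5\,\mathrm{ME}_{glu}
  + 2\,\mathrm{ME}_{gly} + 3\,\mathrm{ME}_{cys})$.

With five replicates at noise CV 0.1, medians over 20 independent studies
recover $\varphi$ and `f_syn` within ±0.05 and glutamate ME within ±0.02 —
the problem sizes used by the test suite (a full two-group study is ~1,500
spectra rows; the round-trip suites use 1,000 random MIDs per $n \in \{1, 2,
5, 10, 20\}$; oracle comparisons enumerate $2^n$ states up to $n = 10$ and a
$10^{-3}$-step simplex grid). NNLS clipping at the non-negativity boundary
introduces a small downward bias in near-zero fractions under noise; it is
visible (e.g. glycine ME recovering ≈ 0.062 for a truth of 0.07 at CV 0.1)
and stays well inside those tolerances.

# Group-level reports

Peak areas are normalized by sample protein content (area per µg); samples
with missing protein are excluded with a warning. Each pool splits into an
unlabeled channel ($M_0 \times$ area) and a labeled channel
($(1 - M_0) \times$ area) — the package's operationalization of "¹²C-GSH"
vs "¹³C-GSH" as complementary channels of the same measured pool after
correction, rather than areas from parallel unlabeled cultures. The
GSH/GSSG ratio is formed within a channel (missing, not infinite, when the
denominator is zero), and the combined GSH + GSSG labeled fraction is
area-weighted. Group differences use two-sided Welch's t-tests at
$\alpha = 0.05$ with no multiple-testing adjustment by default (mirroring
per-panel significance flags; `adjust = "BH"` enables Benjamini–Hochberg).
Under a simulated null the flag rate sits inside the binomial 95% interval
of $\alpha$.

# Worked example

```{r example, eval = FALSE}
study <- generate_study(seed = 1)
res <- run_pipeline(study, out_dir = "report")

# healthy-group intact enrichments
res$summary |> filter(group == "healthy", source == "intact")

# glutamate M+2 positional split
estimate_pdh_fraction(res$solutions) |> filter(!control)

# oxidative-stress readouts
res$ratios |> filter(!control) |> group_by(group, channel) |>
  summarise(median(ratio))
```

# Known limitations

* Isotopomer resolution is per-metabolite; no network-wide flux model
  (no EMU/cumomer solving, no ¹³C-MFA).
* Fragment correction ignores precursor conditioning (documented
  approximation above).
* The atom numbering of the built-in library follows the c1..cn fragment
  maps as configured, without asserting IUPAC numbering; configs declare
  atom labels explicitly rather than deriving them from structures.
* High-resolution mode does not model overlap of near-isobaric
  isotopologues or O/S fine structure.
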
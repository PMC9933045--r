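# tandemid

Tandem mass isotopologue analysis for ¹³C/¹⁵N tracer metabolomics.

## What it is for

In stable-isotope tracing, cells fed a labeled substrate (D-¹³C₆-glucose,
L-¹⁵N₂-glutamine) incorporate heavy atoms into downstream metabolites, and
each metabolite's **mass isotopologue distribution** (MID, the fractions
M₀…Mₙ of molecules with 0…n heavy tracer atoms) reports on pathway
activity. Modern MS/MS acquisition also yields fragment-level isotopologue
spectra, and because each fragment retains a known subset of the parent's
atoms, the joint precursor × fragment distribution (the **tandem MID**)
resolves *positional isotopomers* — species with the same mass but
different labeled positions — that precursor spectra cannot distinguish.

tandemid is a tidyverse-style R package for analysts working with such
data. It implements:

- **Correction matrices.** The observed MID is the true labeling
  distribution convolved with natural isotope abundance and tracer
  impurity: `m = F_nat · F_pur · x`, with
  `F_nat[i,j] = C(n−j, i−j) a^(i−j) (1−a)^(n−i)` and
  `F_pur[i,j] = C(j, i) p^i (1−p)^(j−i)`. `correct_mid()` recovers `x` by
  non-negative least squares plus renormalization (never raw inversion).
- **Enrichment statistics.** Mean isotopic enrichment
  `ME = Σᵢ Mᵢ · i / n`, labeled fractions `1 − M₀`, and atom-weighted
  moiety composition `ME = Σ_f n_f ME_f / Σ_f n_f` for fragments that tile
  a molecule (e.g. glutathione's glutamate moiety F1 and glycine–cysteine
  moiety F2).
- **Positional isotopomer deconvolution.** For candidate labeled-position
  sets `s`, the design matrix `A[(f,k), s] = 1{ |s ∩ atoms(f)| = k }`
  links isotopomer weights to fragment shifts; weights solve
  `min ‖Aw − b‖²` on the probability simplex, jointly over fragments, with
  an explicit identifiability flag.
- **Study analytics.** Protein-normalized pools split into unlabeled/labeled
  channels, GSH/GSSG ratios, combined labeled fractions, and two-group
  Welch tests — plus a synthetic-data generator for the glutamate → GSH →
  GSSG network that makes every stage testable by parameter recovery.

## Worked example

```r
library(tandemid)
library(dplyr)

study <- generate_study(seed = 1)      # two groups x 5 replicates + controls
res <- run_pipeline(study)             # correct -> enrich -> tandem -> report

res$summary |> filter(group == "healthy", source == "intact")
#>   metabolite      me_mean    me_sd me_pct no_incorporation
#> 1 cysteine      0.0000649 0.000132      0 TRUE
#> 2 glutamate     0.602     0.0150       60 FALSE
#> 3 glutathione   0.208     0.0181       20 FALSE
#> 4 glycine       0.0615    0.00963       6 FALSE
#> 5 gssg          0.208     0.00470     20 FALSE
#> 6 ketoglutarate 0.625     0.0151       62 FALSE
#> 7 serine        0.111     0.0182       11 FALSE
```

The healthy group shows ~60% ¹³C enrichment in glutamate and ~21% in
glutathione/GSSG; cysteine stays at zero (it is not made from glucose) and
is flagged `no_incorporation`.

Resolving the glutamate M+2 isotopomers from the Frag_1 (c2–c5) spectrum —
one heavy atom retained means 1,2-¹³C₂ (pyruvate dehydrogenase entry into
the TCA cycle), two means 3,4-¹³C₂ (pyruvate carboxylase):

```r
lib <- gsh_pathway_library("C")
resolve_isotopomer_fractions(
  list(Frag_1 = c(0, 0.6, 0.4, 0, 0)), j = 2,
  candidates = enumerate_isotopomers(lib$glutamate, 2),
  fragments = lib$glutamate$fragments)
#> <isotopomer_fit> precursor shift 2, 2 candidate(s), identifiable
#> 1,2-13C2 3,4-13C2
#>      0.6      0.4
#> residual 0, design rank 2

estimate_pdh_fraction(res$solutions) |>
  filter(!control) |> group_by(group) |> summarise(pdh = median(pdh_fraction))
#>   group      pdh
#> 1 healthy  0.576
#> 2 rotenone 0.491

res$ratios |> filter(!control, channel == "labeled") |>
  group_by(group) |> summarise(ratio = median(ratio))
#>   group    ratio
#> 1 healthy  12.2
#> 2 rotenone  2.66
```

The PDH share of first-turn glutamate labeling is ~0.58 in the healthy
group versus ~0.49 under rotenone, and the ¹³C-GSH/¹³C-GSSG ratio collapses
from ~12 to ~2.7 — the oxidative-stress signature the report tables flag
with Welch tests (`res$comparisons`).

See `vignettes/tandem-mid-workflow.Rmd` for the full model description,
parameter meanings and design decisions.

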
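---
title: "Methods: predicting cooperative miRNA pairs and their RNA triplexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting cooperative miRNA pairs and their RNA triplexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triplexr)
```

## The problem

Pairs of microRNAs whose target sites sit close together on a mutual 3'
UTR can repress that target cooperatively: the two miRNA-loaded
silencing complexes stabilise each other, and the resulting three-strand
complex — an *RNA triplex* of one mRNA stretch and two miRNAs — represses
more strongly than the sum of the single-miRNA effects. `triplexr`
implements a six-step screen that starts from ordinary target-site
predictions and ends with a per-triplex kinetic estimate of the
repression synergy:

1. ingest predicted target sites (miRanda-style tables), keeping
   conserved miRNAs with good mirSVR scores (≤ −0.1);
2. pair sites whose seed matches are 13–35 nt apart — the experimentally
   determined spacing window for cooperation;
3. fold the enclosing mRNA window with both miRNAs, and filter on
   triplex free energy, structural conformation and seed preservation;
4. optionally gate candidates on molecular-dynamics stability summaries
   (ingested, not simulated here);
5. solve the dilute-solution equilibrium of all complexes the triple
   can form and require a triplex equilibrium concentration above 50 nM;
6. simulate an ODE model of the repression kinetics and report
   repression gains RG1/RG2/RG3 and a synergy call.

Every step only removes candidates; `run_triplex_pipeline()` reports the
funnel.

## Seed-site distance

"Seed-site distance" is not defined unambiguously in the literature that
established the 13–35 nt window. The package's default metric is the gap —
the number of nucleotides strictly between the two seed-match intervals
— which is the most conservative reading of "distance between the seed
binding sites"; a `start_to_start` metric is selectable wherever the
distance enters. Both bounds are inclusive. Pairs of sites for the same
miRNA are kept: homotypic triplexes (the same miRNA at two neighbouring
sites) are biologically real and are treated like any other pair.

A geometric consequence worth knowing: with 7-nt seeds and the gap
metric, at most three sites can be *mutually* within the 13–35 nt
window; a fourth site is necessarily ≥ 53 nt from the first. Candidate
counting is therefore per site pair, not per site set.

## The energy model

Structure prediction uses a reduced nearest-neighbor model authored for
this package (`energy_model()`), not a full published parameterisation:

* **Pairs**: Watson–Crick plus G·U wobble. **Stacks**: a symmetric
  6×6 table of stacking free energies (kcal/mol at 37 °C, magnitudes in
  line with the standard RNA nearest-neighbor literature), packaged as a
  documented TSV under `extdata` and validated for strand-flip symmetry
  on load.
* **Loops**: affine + logarithmic penalties — hairpins
  `5.60 + 1.08·ln(n/3)` (minimum size 3), bulges `3.80 + 1.08·ln(n)`,
  internal loops `1.70 + 1.08·ln(n/2)` capped at 30 unpaired nt (larger
  interior loops are disallowed, standard practice), multibranch loops
  `3.40 + 0.40·branches` with free unpaired bases. There are no dangle,
  terminal-mismatch or coaxial terms.
* **Nicks**: any loop whose accessible region spans a strand nick is an
  exterior-like region — no penalty and no minimum hairpin size. This is
  what lets two strands form a blunt intermolecular helix scored purely
  by its stacks.
* **Reference state**: unfolded, dissociated monomers have ΔG = 0, so
  duplex and triplex energies are directly comparable and feed the
  equilibrium and kinetic layers without offset bookkeeping.

Absolute ΔG values from this model are *not* comparable to values
produced by full partition-function packages; every filter in the
workflow is therefore threshold-relative (population cutoff, ΔΔG sign,
equilibrium threshold), and the packaged benchmark energies are carried
as data, never recomputed.

Energies are handled internally as integer centi-kcal/mol. That makes
the dynamic program (C++) and the exhaustive enumeration oracle (R)
agree bit-for-bit, which the test suite exploits: on hundreds of random
1–3-strand instances the DP minimum equals the minimum over *every*
valid matching (`enumerate_structures()`). Co-optimal structures are
resolved by a fixed traceback order (preferring to leave 3'-most
positions unpaired, then the smallest opening index); this is
deterministic and property-tested as such, though it is not a certified
lexicographic minimum over all co-optimal pair maps.

For three strands the two distinct strand orders are folded and the
lower-energy one kept, since an ordered-complex fold is not symmetric
under reordering.

## Structure filters

From the winning triplex structure the package derives

* `dg_triplex` (TFE) and the gain
  `ddg = dg_triplex − min(dg_duplex1, dg_duplex2)`;
* a conformation class from the inter-strand pairing pattern: a miRNA
  with no inter-strand pair makes the structure a
  `duplex_plus_free_mirna`; one or more miRNA–miRNA pairs make it a
  `mirna_mirna_hybrid`; both miRNAs pairing only the mRNA is a
  `canonical_triplex`. The first two classes are discarded by default —
  the hybrid typically forms at the cost of seed binding;
* seed preservation: at least `min_paired` of miRNA nucleotides 2–8
  (the field's seed convention) must pair *into the designated
  seed-match interval* of that miRNA's own site. Pairing the seed onto
  the other site or onto the other miRNA does not count. The default
  requires all seven positions; whether a published screen demands all
  or a majority is not stated anywhere we know of, so the threshold is
  exposed.

The free-energy cutoff is population-relative: `tfe_cutoff()` returns
`mean − z·sd` (z = 3 by default) over the run's own triplex-energy
population. On genome-scale populations this retains the stable tail;
on a handful of candidates it is statistically degenerate (it discards
essentially everything by construction), so small-scale runs — including
the package's own end-to-end tests — disable it with `tfe_z = NA` rather
than pretend a three-candidate "population" has meaningful tails.

## Equilibrium concentrations

`equilibrium_concentrations()` solves the mass-action equilibrium of
the complex set {M, A, B, MA, MB, AB, MAB} (homodimers excluded by
default, but any composition over the declared strands is accepted)
from 100 nM totals per species at 310.15 K:

$$[c] = \rho_0 e^{-\Delta G_c/RT} \prod_s \lambda_s^{n_{s,c}},$$

with ρ₀ = 1 M and R = 1.9872×10⁻³ kcal/(mol·K). The strand activities
solve the conservation equations, which are the stationarity conditions
of a convex dual objective; the solver is Newton on log-activities with
the analytic Jacobian and an Armijo line search on that objective.
Convexity matters in practice: when one very deep complex dominates all
three conservation equations the Jacobian is nearly rank one and a
residual-damped Newton stalls, while descent on the dual converges
globally. A per-coordinate monotone bisection sweep remains as a
fallback. Strand conservation is enforced to 10⁻¹⁰ relative and
asserted to 10⁻⁶ in the tests, alongside exact agreement with the
closed-form dimer quadratic across K_d from 1 nM to 10 µM.

The triplex filter is strict: a candidate passes only if
[MAB] > 50 nM, i.e. the majority of the mRNA is sequestered in
triplexes at equilibrium. (With 100 nM totals the nM threshold and the
">50 %" reading coincide only for the mRNA strand; the package
implements the concentration threshold.)

## MDS stability rule

Molecular dynamics itself is out of scope; the package ingests
per-complex stability times (picoseconds bonded, duplex vs. triplex
context) and applies the decision rule. Two readings of the published
rule disagree on borderline records: the displayed inequality compares
the triplex stability time against the *smaller* duplex time, while the
benchmark table's caption compares each miRNA against its own duplex.
Only the per-miRNA rule reproduces the published pass/fail pattern
(e.g. it passes MUC1, which the min-duplex reading rejects), so
`stability_pass()` defaults to it and keeps the other as an audit
variant. The time threshold is inclusive (≥ 100 ps), which is decisive
for KAT2B, whose triplex stability time is exactly 100 ps. The packaged
benchmark (`load_triplex_benchmark()`) reproduces the published
outcomes exactly: all low-TFE and high-gain triplexes pass, no high-TFE
triplex does, KAT2B is the lone low-gain pass, and the validated CDKN1A
control passes.

## The kinetic model

Seven species: free mRNA *m*, free miRNAs *R₁*, *R₂*, duplexes *C₁*,
*C₂*, triplex *T*, protein *P*. Reactions: syntheses (miRNA synthesis
scaled by expression factors TF₁, TF₂ ∈ [10⁻¹, 10²]), reversible duplex
and triplex formation, first-order degradations, translation from free
mRNA. Complex degradation releases the miRNAs intact by default
(miRNAs act catalytically); `recycle = FALSE` destroys them with the
complex.

Association steps share one on-rate, and dissociation follows detailed
balance against the predicted free energies:
`d_i = k_on ρ₀ e^{ΔG_duplex_i/RT}` and, for loss of one miRNA from the
triplex, `d_ij = k_on ρ₀ e^{(ΔG_triplex − ΔG_duplex_j)/RT}` with *j* the
miRNA that stays bound. A large negative free-energy gain thus makes
the second binding step nearly irreversible — the thermodynamic
signature of cooperativity, and the mechanism behind the synergy the
model reports.

Rate constants are documented configuration (`kinetic_config()`), not
published calibration values: k_on = 10⁻³ nM⁻¹s⁻¹, δ_m = 10⁻⁴,
δ_R = 10⁻⁵, δ_C = 2×10⁻⁴, δ_T = 4×10⁻⁴, k_p = 10⁻³, δ_P = 10⁻⁴ s⁻¹.
The synthesis rates k_m = k₁ = k₂ = 10⁻³ nM/s were chosen once for
realistic copy numbers — a 10 nM mRNA pool and a 100 nM miRNA pool at
baseline expression — which places duplexes with K_d in the 10²–10⁵ nM
range (ΔG ≈ −5 … −10 kcal/mol) in the responsive regime where the
triplex pathway can outperform single-miRNA repression. Much stronger
duplexes silence the target on their own and saturate all gains; that
is a property of the biology, not a solver artefact.

Steady states come from a damped Newton iteration on the six coupled
species (P decouples) with the analytic Jacobian, warm-started across
surface grids; an independent `deSolve::lsoda` integration to
convergence is the second route, and the two agree to better than 10⁻⁶
relative in the tests. The reported quantity is the steady-state
protein normalised by the miRNA-free model, so SS ∈ [0, 1] with
SS(0,0) = 1 exactly.

Repression gains compare the baseline point SS(1,1) against strong
single up-regulation (RG₁ = SS(1,1) − SS(10,1),
RG₂ = SS(1,1) − SS(1,10)) and modest joint up-regulation
(RG₃ = SS(1,1) − SS(5,5)). The literal published formula has the
opposite sign, which contradicts its own "higher RG = stronger
repression" reading; the package reports the self-consistent positive
convention and exposes the literal one behind a flag. A pair is
*synergistic* when RG₃ > max(RG₁, RG₂).

```{r synergy-example}
stable <- build_kinetic_model(
  list(dg_duplex1 = -8, dg_duplex2 = -8, dg_triplex = -30))
repression_gain(stable)[c("RG1", "RG2", "RG3", "synergy_class")]

unstable <- build_kinetic_model(
  list(dg_duplex1 = -8, dg_duplex2 = -8, dg_triplex = -10))
repression_gain(unstable)[c("RG1", "RG2", "RG3", "synergy_class")]
```

## The synthetic-data generator

`generate_toy_dataset()` builds complete pipeline inputs with known
ground truth: uniform-random UTRs in which pairs of planted miRNAs have
perfect seed complements (nucleotides 2–8 reverse-complemented into the
UTR) at exactly the requested seed distances, plus configurable 3'
supplementary pairing (`complementarity_level`, default 0.9, written
from nucleotide 13 onwards). Background sequence is rejection-sampled
so that no pool miRNA's seed complement occurs anywhere unplanned,
which makes the truth table exact. Planted sites carry mirSVR −0.5 and
PhastCons 0.9 — arbitrary documented constants that pass the default
filters. The generator saves and restores the caller's RNG state, so
identical seeds give byte-identical datasets without disturbing the
session.

What it deliberately does **not** emulate: realistic UTR base
composition and length distributions, overlapping or nested sites,
imperfect seeds (G·U seeds, offset 6-mers), site accessibility
competition from UTR self-structure outside the window, or conservation
structure. Passing the recovery tests therefore demonstrates that the
machinery is correct on unambiguous inputs — not that the thresholds
have the published sensitivity/specificity on real transcriptomes,
which depended on a specific genome-wide prediction snapshot.

## Validation problem sizes

The test-suite and acceptance checks run at desk scale, chosen so the
whole suite completes in well under half an hour: DP-vs-enumeration on
200 random instances of 6–19 nt total (the enumeration count, not the
DP, is the binding cost); equilibrium checks on dozens of random triple
systems plus a 17-point K_d sweep; kinetic two-solver agreement on a
handful of random parameterisations (each full-accuracy ODE
steady-state costs seconds); end-to-end recovery on four planted genes
with 200-nt UTRs. The folding engine itself handles windows of a few
hundred nucleotides in milliseconds; its hard cap is 2000 nt total.

## Known limitations

* The energy model is reduced; absolute energies and hence absolute
  equilibrium constants differ systematically from full-parameter
  engines. Rankings and threshold-relative decisions are the intended
  use.
* MFE energies stand in for ensemble free energies in the equilibrium
  step (no partition function, no suboptimal ensemble, no pseudoknots).
* Only + strand transcript coordinates and 3' UTR sites are handled;
  the upstream predictor owns genomic strand and region logic.
* The kinetic constants are plausible defaults, not fits; conclusions
  should rest on comparisons between energetic scenarios under matched
  kinetics, which is how the package reports them.
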
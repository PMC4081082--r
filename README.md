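# triplexr

Identification and kinetic analysis of cooperative microRNA pairs and
their RNA triplexes.

## The problem

Two miRNAs whose target sites sit 13–35 nt apart on a mutual 3' UTR can
repress that target *cooperatively*: the mRNA stretch and both miRNAs
form a three-strand complex — an **RNA triplex** — that represses more
strongly than either miRNA alone, even when both are only modestly
up-regulated. `triplexr` is for computational biologists who have
ordinary miRNA target-site predictions and want to know **which site
pairs can actually form stable, functional triplexes and how much
repression synergy to expect**.

The package implements the full screen as a pipeable, tidyverse-native
toolkit:

1. **Sites → candidates.** Read miRanda-style site tables
   (`read_site_table()`), keep conserved miRNAs with mirSVR ≤ −0.1
   (`filter_sites()`), and pair sites whose seed matches are 13–35 nt
   apart (`pair_sites()`), extracting the enclosing mRNA window.
2. **Structure.** A nick-aware multi-strand MFE folding engine
   (`mfe_complex()`, reduced nearest-neighbor model in C++, verified
   against exhaustive enumeration) yields the triplex free energy
   ΔG<sub>triplex</sub>, the gain
   ΔΔG = ΔG<sub>triplex</sub> − min(ΔG<sub>duplex1</sub>, ΔG<sub>duplex2</sub>),
   a conformation class, and seed-preservation flags
   (`triplex_energetics()`, `apply_structure_filters()`).
3. **Equilibrium.** Mass-action equilibrium concentrations of
   {monomers, duplexes, triplex} from 100 nM totals
   (`equilibrium_concentrations()`), with the >50 nM triplex filter
   (`triplex_filter()`).
4. **Dynamics (ingested).** The molecular-dynamics stability rule on
   stability-time summaries: pass iff the triplex holds ≥ 100 ps *and*
   at least one miRNA binds longer in the triplex than in its duplex
   (`stability_pass()`).
5. **Kinetics.** An ODE model of cooperative repression with
   energy-derived dissociation rates (`build_kinetic_model()`),
   steady-state surfaces over miRNA expression factors ∈ [0.1, 100]
   (`repression_surface()`), and repression gains
   RG₁ = SS(1,1) − SS(10,1), RG₂ = SS(1,1) − SS(1,10),
   RG₃ = SS(1,1) − SS(5,5), calling a pair *synergistic* when
   RG₃ > max(RG₁, RG₂) (`repression_gain()`).

`run_triplex_pipeline()` chains all of it and reports the candidate
funnel; `generate_toy_dataset()` builds ground-truthed synthetic inputs;
`autoplot()` methods cover surfaces and equilibria. A thin CLI with
subcommands (`scan`, `fold`, `equilibrium`, `mds-filter`, `kinetics`,
`simulate-data`, `run`) ships at `system.file("cli", "triplexr",
package = "triplexr")`.

## Worked example

```r
library(triplexr)

toy <- generate_toy_dataset(n_genes = 3, planted = list(
  list(seed_distance = 20), list(seed_distance = 33)), rng_seed = 101)

cfg <- triplex_config(sites = toy$sites, utrs = toy$utrs,
                      mirnas = toy$mirnas, tfe_z = NA)
out <- run_triplex_pipeline(cfg)
out$funnel
#> # A tibble: 5 × 3
#>   stage              n_in n_out
#> 1 site_filter           4     4
#> 2 pairing               4     2
#> 3 structure_filters     2     2
#> 4 equilibrium           2     2
#> 5 final                 2     2

dplyr::select(out$results, gene_id, seed_dist, dg_triplex, ddg,
              conc_triplex, synergy_class)
#> # A tibble: 2 × 6
#>   gene_id seed_dist dg_triplex   ddg conc_triplex synergy_class
#> 1 GENE001        20      -59.3 -26.1        100.0 additive
#> 2 GENE002        33      -68.5 -25.3        100.0 additive
```

Both planted triplexes (and nothing else) survive every stage: the
folds are canonical triplexes with both seeds preserved, and at
equilibrium essentially all 100 nM of mRNA is sequestered in the
triplex (`conc_triplex`, in nM — far above the 50 nM bar). With
binding this strong a single miRNA already silences the target, so the
kinetic layer calls the pair additive; synergy appears when duplexes
are individually weak but the triplex is stable:

```r
repression_gain(build_kinetic_model(
  list(dg_duplex1 = -8, dg_duplex2 = -8, dg_triplex = -30)))
#>      RG1    RG2    RG3  ... synergy_class
#>   0.0105 0.0105 0.0113 ...   synergistic
```

The packaged molecular-dynamics benchmark of 13 published triplexes
reproduces its published verdicts exactly:

```r
group_pass_counts(load_triplex_benchmark("mds_stability"))
#> # A tibble: 5 × 3
#>   group_label     n n_pass
#> 1 control         1      1    # the validated CDKN1A control
#> 2 high_gain       3      3
#> 3 high_mfe        3      0
#> 4 low_gain        3      1    # KAT2B, stable for exactly 100 ps
#> 5 low_mfe         3      3
```

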
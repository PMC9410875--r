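# foxcoop

Quantitative tools for cooperative binding of forkhead-box (FOX)
transcription factors to homotypic DNA site clusters — promoter regions
carrying two adjacent binding elements for the same factor.

Regulatory regions like the human *TP53* promoter carry a canonical
FOX-binding element (consensus 5′-RYAAAYA-3′, R = A/G, Y = C/T) with a
second element immediately adjacent, and FOX proteins occupy such pairs
with 2:1 stoichiometry and positive cooperativity. foxcoop implements the
machinery needed to quantify that behaviour from standard biophysical
experiments, for structural biologists and biochemists working on
protein–DNA assembly:

* **Consensus scanning** (`scan_motif()`, `annotate_homotypic_pairs()`):
  strand-aware IUPAC degeneracy matching and annotation of overlapping or
  gapped site pairs.
* **Two-site equilibrium binding** (`partition_fractions()`,
  `solve_free_protein()`, `estimate_omega()`, `fit_affinities()`): the
  lattice model with partition function
  `Z = 1 + (K1 + K2) p + ω K1 K2 p²`, exact ligand-depletion handling, and
  the cooperativity factor ω estimated from EMSA band fractions via the
  statistical-factor-corrected ratio `ω̂ = 4 f0 f2 / f1²` (ω > 1: positive
  cooperativity; ω = 1: independent sites; ω < 1: negative).
* **Calorimetry** (`simulate_itc()`, `fit_itc()`, `compare_models()`):
  ITC isotherm simulation and fitting for one-site vs sequential two-site
  binding with AICc model selection and a biphasic-isotherm index.
* **Stoichiometry** (`duplex_mass()`, `infer_stoichiometry()`): protomer
  counts from light-scattering masses and sequence-derived duplex masses.
* **Groove geometry** (`make_fiber_bdna()`, `read_structure()`,
  `minor_groove_widths()`, `compare_profiles()`): per-level DNA
  minor-groove widths (closest cross-groove P–P distance − 5.8 Å) from PDB
  files or an ideal fiber-model B-DNA reference.
* **Synthetic data** (`gen_emsa_series()`, `gen_itc_trace()`,
  `gen_promoter()`, `apply_scenario()`): seeded generators emulating every
  experimental input, so the full pipeline runs offline.
* **Orchestration** (`run_pipeline()`): scan → binding → calorimetry →
  groove stages from one YAML/list config, writing a provenance-stamped
  JSON report plus TSVs.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` methods on fitted objects, `autoplot()` for each result type.

## Worked example

Scan the 16-mer two-site promoter probe, annotate the site pair, estimate
cooperativity from a (synthetic) gel titration, and call the complex
stoichiometry:

```r
library(foxcoop)

p53 <- dna_sequence("AAATATTTATTATCGA", id = "p53-DNA")
(hits <- scan_motif(p53, "RYAAAYA"))
#> # A tibble: 1 × 8
#>   seq_id  start   end strand site    pattern promoter_start promoter_end
#>   <chr>   <int> <int> <chr>  <chr>   <chr>            <int>        <int>
#> 1 p53-DNA     3    10 -      TATTTAT RYAAAYA              3           10
```

Exactly one consensus hit: plus-strand interval [3, 10), on the minus
strand (the plus-strand slice TATTTAT reverse-complements to ATAAATA,
which matches RYAAAYA). The second element overlaps it by two bases:

```r
annotate_homotypic_pairs(hits, "ATTATCG", p53, max_overlap = 2, max_gap = 0)
#> # A tibble: 1 × 11   (selected columns)
#>   pair_id primary_site secondary_site overlap
#> 1       1 TATTTAT      ATTATCG              2
```

A triplicate titration of the wild-type probe (2.5 µM, site constants from
the 0.79 µM single-site KD, generating ω = 3, 3% densitometry noise):

```r
wt <- gen_emsa_series(wt_affinities(), sigma_frac = 0.03,
                      n_replicates = 3, seed = 1)
estimate_omega(wt)
#> <omega_estimate> omega = 3 +/- 0.26 (n_used = 4 lanes): positive cooperativity
```

The estimate (3.00 ± 0.26 SEM across replicates) recovers the generating
cooperativity and classifies it as positive. Stoichiometry from solution
masses — a 32.7 kDa complex, 12.4 kDa protomer, and the duplex mass
computed from the probe sequence (9.76 kDa):

```r
infer_stoichiometry(32.7, 12.4, duplex_mass(p53))
#> # A tibble: 1 × 2
#>   n_protein residual_mass
#> 1         2         -1.86
```

Two protomers per duplex. Finally, the ideal B-DNA minor-groove baseline:

```r
groove_summary(minor_groove_widths(make_fiber_bdna(16)))
#> # A tibble: 1 × 4
#>     min  mean   max n_levels
#> 1  5.74  5.74  5.74       11
```

The interior minor-groove width of the fiber-model reference is 5.74 Å,
the canonical B-DNA value; structures with a narrowed groove show negative
per-level differences in `compare_profiles()`.

The whole narrative in one call: `run_pipeline(list(seed = 1, out_dir =
"out"))` runs all four stages on synthetic defaults and writes
`out/report.json` plus per-stage TSVs.

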
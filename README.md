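# kinvar

Statistical analysis of disease- and cancer-associated mutations on the
protein kinase catalytic domain, for structural bioinformaticians studying
how somatic variants distribute over kinase structure and dynamics.

Cancer kinase mutations are not sprinkled uniformly over the catalytic
domain: they concentrate in particular Hanks–Hunter subdomains (P-loop,
hinge, activation segment), recur at structurally equivalent positions
across different kinase genes (L858/L861-type hotspots), and sort by
functional effect — activating substitutions favour conformationally mobile
regions while kinase-dead substitutions hit rigid scaffolding. `kinvar`
implements each of those analyses as a testable, simulation-backed pipeline:

- **Subdomain annotation** — segments catalytic domains into Hanks–Hunter
  regions I–XI (X split into X(i)/X(ii)) by anchoring on the five catalytic
  motifs (G-x-G-x-x-G, VAIK, HRD, DFG, APE), and maps mutations to regions
  and shared anchor-frame alignment columns.
- **Region enrichment** — per-region expected probabilities
  E(p)_r = L_r / Σ L from SNP-weighted average region lengths, tested with
  the two-tailed binomial
  P(x) = 2 · Σ_{i≤x} C(n,i) E(p)^i (1−E(p))^{n−i} (lower tail; mirrored
  upper tail when x/n > E(p)), and enriched/devoid/neutral calls.
- **Positional clustering** — per-position SNP multiplicity histograms, a
  10,000-iteration Monte Carlo random-assignment null with per-k mean ± sd,
  and cross-kinase hotspot detection counting distinct kinase genes.
- **Mobility mapping** — Kabsch superposition of C-alpha trajectories,
  covariance/correlation matrices
  C_ij = ⟨(r_i − ⟨r_i⟩)·(r_j − ⟨r_j⟩)⟩, PCA modes, per-residue mobility
  averaged over the two lowest-frequency (largest-eigenvalue) modes,
  rigid/intermediate/flexible/hinge classification, and a permutation
  contrast of activating vs inactivating site mobility.
- **Simulators** — kinase families, SNP tables (Dirichlet-multinomial
  position clustering, per-region rate multipliers) and trajectories
  (two-regime fluctuations, planted collective modes, optional global
  rigid-body motion) with known ground truth.

Packaged data include a transcription of a curated cross-kinase cancer
hotspot catalog (EGFR-referenced positions, `hotspot_catalog()`), curated
activation-status labels for modelled somatic mutations
(`activation_catalog()`), and the observed disease-SNP per-position count
histogram (`observed_position_histogram()`).

## Worked example

Simulate a 12-kinase family carrying a 3× enriched catalytic loop (region
VIb) and hotspot-style positional clustering, then run the full sequence
pipeline:

```r
library(kinvar)

spec <- snp_sim_spec(n_kinases = 12, n_snps = 400, enrichment = c(VIb = 3),
                     clustering_concentration = 0.5, seed = 42)
fam  <- simulate_kinase_family(spec)
map  <- annotate_subdomains(fam$sequences)      # motif anchors -> subdomains
snps <- simulate_snp_table(fam$truth, spec)
ann  <- map_mutations(snps, map)                # adds region, column, segment

enrich_regions(ann, map) |> dplyr::arrange(p_value)
#>   region expected_p observed_x total_n  p_value     call
#> 1    VIb     0.0381         35     400 1.25e-05 enriched
#> 2    VIa     0.1690         85     400 2.77e-02 enriched
#> 3   VIII     0.1001         30     400 1.04e-01  neutral
#> ...

find_hotspots(ann, min_kinases = 4) |> head(4)
#>   column     segment n_kinases activation_status
#> 1   3003   Catalytic        10           unknown
#> 2   2042 beta4-beta5         9           unknown
#> 3   3002   Catalytic         9           unknown
#> 4   5007      C-lobe         9           unknown
```

The planted VIb enrichment is recovered (observed 35/400 = 0.088 against
E(p) = 0.038, two-tailed binomial p = 1.3e-05, called `enriched`), and the
low Dirichlet concentration produces positions mutated in up to 10 of the
12 kinases (columns are anchor-frame: 3003 = HRD + 3, 5007 = APE + 7).

Mobility, on a simulated trajectory whose first 30 residues are rigid
(sd 0.1 Å) and last 30 flexible (sd 1.0 Å):

```r
sim  <- simulate_trajectory(traj_sim_spec(seed = 7))
prof <- sim$trajectory |>
  superpose_trajectory() |>
  essential_dynamics() |>
  residue_mobility(k = 2) |>
  classify_mobility()

rigidity_contrast(prof, activating_sites = 45:49, inactivating_sites = 10:14,
                  n_perm = 999, seed = 1)
#> <rigidity_contrast> mean mobility (activating - inactivating) = 0.5752,
#>   permutation p = 0.007 (999 permutations)
```

Sites placed in the flexible block carry a mean normalised mobility 0.58
higher than sites in the rigid block; only 6 of 999 label permutations reach
that difference, so the activating/inactivating contrast is significant at
p = 0.007. `write_mobility_pdb()` exports the profile with B-factors set to
100 × mobility for blue-to-red colouring in any structure viewer.

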
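---
title: "Methods: subdomain enrichment, positional clustering and mobility analysis of kinase mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subdomain enrichment, positional clustering and mobility analysis of kinase mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinvar)
```

## Scope and model

`kinvar` analyses amino-acid variants (common polymorphisms, inherited-disease
SNPs, and somatic cancer mutations) on the protein kinase catalytic domain at
three levels:

1. **region level** — are variants of a given category enriched in, or devoid
   of, particular Hanks–Hunter subdomains, relative to chance placement?
2. **position level** — do variants pile up at structurally equivalent
   alignment positions more than random assignment predicts, and which
   positions recur across enough kinase genes to count as hotspots?
3. **residue-dynamics level** — do activating and inactivating mutation sites
   differ in the conformational mobility of the residues they hit?

The package is simulation-first: every statistical stage has a matching
generator (`simulate_kinase_family()`, `simulate_snp_table()`,
`simulate_trajectory()`) that plants known ground truth, so calibration and
power of each test are themselves testable quantities.

## Subdomain annotation

Kinase catalytic domains are segmented by anchoring on the five canonical
catalytic motifs, located left-to-right with the order constraint enforced
(`locate_motifs()`): the glycine-rich P-loop `G.G..G`, the beta3 `[VAI][AG][ILV]K`
with the catalytic lysine, the catalytic-loop `HRD`, the activation-segment
`DFG`, and the closing `AP[ED]`. Matching is by regular expression with
leftmost tie-breaking, which keeps annotation deterministic and auditable.

Between anchors, boundaries come from a packaged convention
(`subdomain_scheme()`): subdomain I spans the P-loop with a four-residue
N-terminal pad; II is the VAIK strand; the VAIK-to-HRD span is cut into
III/IV/V/VIa at fractions 0.22/0.45/0.60; VIb is an eight-residue catalytic
loop; VII/VIII run from DFG through APE (the activation segment); and
IX/X(i)/X(ii)/XI take fixed widths downstream of APE, truncated at the
sequence end. Subdomain X is always emitted as the two halves X(i) and X(ii).
The fractional cuts were calibrated once against the EGFR landmarks so that
the gatekeeper T790 and G796 fall in the hinge (subdomain V); no other
boundary is anchored to data, and boundary-sensitive results should be
reported together with the scheme version. This anchor-offset
pseudo-alignment deliberately replaces a full multiple sequence alignment:
for the motif-proximal positions where hotspots are analysed, signed offsets
from the nearest upstream anchor reproduce structural equivalence, and a
user-supplied alignment can replace the scheme where that assumption is too
coarse. Positions far from their frame anchor (e.g. just before the next
anchor, in kinases with unusually long linkers) are the known weak spot of
forward-anchored columns.

Alignment columns are integers `base(frame) + (position - anchor position)`
with per-frame bases 1000/2000/3000/4000/5000, so e.g. the DFG aspartate of
every kinase shares column 4000. Mutations falling outside the catalytic
domain are labelled `"outside"` rather than erroring, and wild-type residues
that disagree with the sequence warn rather than fail by default, because
numbering-offset discrepancies are endemic in the kinase literature (the same
EGFR residue is published as L858 and as L834, depending on whether the
signal peptide is counted).

## Region enrichment

For a variant category with `n` mapped records, each region's expected
probability is

E(p)_r = L_r / sum_s L_s,

where `L_r` is the *SNP-weighted* average region length across kinases
(weights are the per-kinase variant totals; `weighted_region_length()`). The
weighting prevents kinases that simply harbour many variants from dominating
the length estimate. Weighted lengths, and hence E(p), are computed
separately per category.

The observed count `x` in a region is tested with the two-tailed binomial
(`binom_pvalue_two_tailed()`): the lower tail `sum_{i<=x} C(n,i) E(p)^i
(1-E(p))^(n-i)` when `x/n < E(p)`, the analogous upper tail when `x/n >
E(p)`, each doubled. Terms are accumulated by exact summation in log space.
Two conventions are ours and are flag-reversible: the doubled tail is capped
at 1 (the raw doubling can exceed 1; a probability should not), and `x/n`
exactly equal to `E(p)` returns 1, since neither tail branch applies at the
boundary. Regions are called `enriched`/`devoid` when `p < alpha` with the
rate above/below E(p), else `neutral`; raw P values are reported by default
(no multiple-testing correction, matching how such region maps are usually
read), with a Benjamini–Hochberg option off by default. Set-versus-set
comparisons (`compare_snp_sets()`) use the pooled two-proportion z
approximation.

## Positional clustering and hotspots

`position_histogram()` tabulates variants per alignment column over a stated
column universe and derives the multiplicity histogram `{k -> number of
positions with exactly k variants}`; both conservation identities
(`sum_k h_k = positions`, `sum_k k h_k = variants`) are enforced invariants.
The null is `mc_position_null()`: 10,000 Monte Carlo iterations (default)
dropping the same number of variants multinomially onto the positions,
uniformly by default. A weighted mode (weights proportional to region
lengths or any user weights) is exposed because a uniform null is only one
defensible reading of "random assignment"; reports should name the mode
used. Both the per-iteration standard deviation and the standard error of
the mean are returned, since published summaries of such simulations are
often ambiguous between the two.

`compare_observed_to_null()` reports a z-like excess `(observed - null mean)
/ null sd` per k, flagging `|excess| > 3`. This normal-style flag is only
calibrated when class means are not minuscule: in sparse settings (roughly
n_snps << n_positions) the spurious-flag rate measured under the null is
about 2%, while at high densities a single observed position in a far-tail
class (null mean << 1) flags by construction ~10% of the time. The far tail
is exactly where genuine clustering shows up, so flags at tiny null means
should be read as "observed at all, expected essentially never" rather than
as 3-sigma events.

Hotspots (`find_hotspots()`) are positions mutated in at least `min_kinases`
distinct kinase genes — a kinase with several alternative substitutions at a
position counts once, matching how recurrence is conventionally counted. The
default threshold 3 is the smallest recurrence in the packaged hotspot
catalog (`hotspot_catalog()`), which also records a known internal
inconsistency of its source (the P-loop G721 row prints a count of 5 while
listing 6 kinase entries); the package preserves the printed list and
exposes both numbers instead of silently resolving it.

## Mobility from essential dynamics

Trajectories of C-alpha coordinates are superposed by iterated least-squares
rigid-body fitting to the ensemble mean (`superpose_trajectory()`; Kabsch
SVD with the proper-rotation branch enforced, mean-convergence tolerance
1e-6 Å). The positional covariance `C_ij = <(r_i - <r_i>) . (r_j - <r_j>)>`
uses the ensemble-average divisor `n_frames`, matching the angle-bracket
definition; the residue-residue correlation is its normalisation to [-1, 1],
with zero-variance residues reported as correlation 0 off-diagonal (and 1 on
the diagonal) with a warning. `essential_dynamics()` performs the full
symmetric eigendecomposition.

Per-residue mobility (`residue_mobility()`) is the eigenvalue-weighted
squared amplitude of the top `k = 2` modes — "two lowest-frequency modes" in
the quasi-harmonic sense, i.e. the two largest-eigenvalue PCA modes —
min–max normalised per structure, since mobility colourings are read as
within-structure relative scales; absolute RMSF in Å is carried alongside
for cross-structure comparisons. Both the mode count and the eigenvalue
weighting are flags, because displacement-amplitude colourings without
eigenvalue weighting are also in circulation. One caveat the test suite
documents: for an isotropic (direction-degenerate) ensemble, individual top
modes are arbitrary within the degenerate eigenspace, so only the all-mode
sum and the RMSF are residue-wise flat; the k = 2 profile is meaningful when
a spectral gap exists, which is exactly the planted-mode and two-regime
regime the package targets.

`classify_mobility()` labels residues rigid/intermediate/flexible by
mobility quantiles (defaults 0.25/0.75) and marks hinge residues — sites at
the border between stable and mobile regions — as residues within 2 sequence
positions of both a rigid and a flexible residue. `rigidity_contrast()`
operationalises the activating-vs-inactivating comparison, which in the
source material is visual, as a two-sample permutation test on mean site
mobility with the add-one correction; outputs label it an operationalisation.

## Simulators: what they emulate, and what they do not

`simulate_kinase_family()` plants the five motifs (degenerate P-loop
instantiated as GSGAFG) separated by linkers of specified mean lengths
(defaults 8/17/89/17/19/50 residues, EGFR-like spacing) with ±3 jitter;
linkers draw from an alphabet that cannot spell any motif, so anchor
discovery is unambiguous. `simulate_snp_table()` places variants by region
(probability ∝ mean length × enrichment multiplier), then by column within
region from a symmetric-Dirichlet weight vector whose concentration
interpolates between uniform placement (large values; the default 100) and
hotspot-like clustering (e.g. 0.05), then assigns a kinase uniformly among
carriers of that column. A per-kinase-stratified placement flag exists
because "random assignment" can also be read as preserving per-kinase
totals; pooled placement is the default. `simulate_trajectory()` adds
per-residue isotropic Gaussian noise (default: a 60-residue chain, rigid
first half at sd 0.1 Å, flexible second half at 1.0 Å) and optional planted
low-rank collective modes to an ideal helix-like backbone (3.8 Å C-alpha
spacing, non-degenerate geometry for superposition), optionally wrapped in
per-frame random rigid-body motion.

These generators emulate the *statistical* structure the tests need —
region-level rates, positional concentration, fluctuation regimes, low-rank
modes — not biology: no sequence evolution, no side chains, no force-field
dynamics, no correlated noise along the chain. Passing calibration on them
shows the statistics behave as designed under their stated models; it does
not validate the segmentation convention or the mobility interpretation on
real proteins.

## Numerical and design choices

- Binomial tails: log-space term summation; agreement with the exact
  cumulative distribution is asserted to |Δ| < 1e-12 over 10,000 random
  (x, n ≤ 500, E(p)) triples.
- Superposition: SVD-based Kabsch with reflection guard; verified against a
  quaternion (Horn) oracle and `bio3d::fit.xyz` to 1e-9/1e-6.
- Eigendecompositions use LAPACK via `eigen(symmetric = TRUE)` and are
  cross-checked against a cyclic Jacobi oracle at 1e-8 on small instances.
- RNG: every simulator and resampling routine takes an explicit integer
  seed and is a pure function of it; unseeded calls use the caller's stream.
- Degenerate inputs: flat mobility profiles classify as all-intermediate
  with no hinges; zero-SNP tables yield `{0: n_positions}` histograms;
  degenerate pooled proportions return z = 0, p = 1 with a warning.
- Mutation deduplication key is (kinase, position, category), implementing
  the usual non-redundancy rule that no site within a kinase is counted
  twice in enrichment statistics.

## Problem sizes used by the packaged checks

The calibration suite and `scripts/acceptance.R` run, per invocation:
10,000 oracle triples; Monte Carlo nulls of 10,000 iterations on up to 10
positions; 2,000 null and 500 enriched SNP-table replicates (20 kinases, 500
SNPs each) for enrichment calibration and power; one 60-residue/2,000-frame
trajectory pair for mobility recovery and global-motion invariance; 100
independent 400-frame trajectories × 20 site redraws (2,000 null replicates)
plus 200 powered replicates for the rigidity contrast at 199 permutations;
and a 12-kinase/400-SNP family at jitter 5 for annotation recovery. The
rigid/flexible recovery check classifies at quantiles 0.45/0.55 on a 50/50
planted split and scores accuracy among residues receiving a rigid or
flexible label, since intermediates have no planted counterpart.

## Known limitations

- The segmentation table is a convention; only its motif anchors and the
  hinge placement of the EGFR landmarks are externally constrained.
- Anchor-frame columns degrade away from their anchor in families with very
  heterogeneous linker lengths; supply an explicit alignment there.
- The per-k excess flag is anti-conservative in far-tail classes at high
  SNP density (see above).
- The rigidity contrast is an operationalisation of a qualitative claim; a
  significant contrast on one structure's profile is evidence about that
  profile, not about kinase biology in general.
- Driver/passenger annotations are inputs; the package does not re-derive
  them.
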
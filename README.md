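# radialchrom

Radial chromatin distribution profiling in polytene nuclei.

## What this is for

B-type lamins line the inner nuclear membrane and tether chromatin to the
nuclear periphery. Mutations that detach Lamin B from the membrane — such as
a frameshift removing its C-terminal CaaX anchoring motif — can let
peripheral chromatin relocate toward the nuclear interior. `radialchrom` is
for microscopists and image analysts who want to *quantify* that relocation
in DAPI-stained nuclei (e.g. Drosophila salivary gland or proventriculus
polytene nuclei) and test it between two groups of nuclei, typically
wild-type versus mutant.

The package implements the full measurement chain plus a synthetic-nucleus
generator with known ground truth, so every stage is testable without real
data, and a small sequence module for verifying frameshift alleles at the
CDS level.

## The measurement

Per nucleus, on the equatorial focal plane (the z-section with the widest
cross-section):

1. segment the nucleus (Gaussian blur → Otsu → hole fill → labelling), or
   accept a label mask; centre = mask centroid, profiling radius R = maximum
   centroid-to-pixel distance;
2. ring profile: intensity at distance r from the centre = sum of pixel
   values around the circle of radius r (every in-circle pixel belongs to
   exactly one integer ring, so ring sums conserve total intensity); a
   count-normalised ring mean is also available (`ring_statistic`);
3. rescale radii to percent of R (0–100%), divide the profile by its
   maximum, and average rings into twenty half-open 5% intervals
   (x − 5, x], x ∈ {5, 10, …, 100}; empty intervals stay missing.

Per cohort, the per-nucleus interval values I ∈ [0,1] are aggregated by
group (mean, SD, SE), each interval is compared between groups with a
two-sided Mann–Whitney U test, and the integral change over a set L of
intervals is summarised by

    Δ = (1 − Σ_{x∈L} I_ref[x] / Σ_{x∈L} I_test[x]) × 100%

with L defaulting to the inner/middle/outer thirds of the radial axis.
Δ > 0 means the test group carries more relative intensity on L.

## Worked example

Simulate a two-group cohort (80 nuclei per group) in which the test group
has 30% of its peripheral-rim chromatin mass relocated to the centre, then
measure and compare:

```r
library(radialchrom)

cmp <- simulate_and_compare(
  cohort_spec(n_per_group = 80, shift_fraction = 0.3, seed = 1),
  config = run_config(ring_statistic = "mean"))
print(cmp)
#> <cohort_comparison> 20 of 20 intervals significant (alpha = 0.05, correction = none)
#>   delta[inner] = +88.0%
#>   delta[middle] = +66.2%
#>   delta[outer] = -5.5%

b <- cmp$bins
b[b$x %in% c(10, 30, 50, 85, 95),
  c("x", "mean_ref", "mean_test", "U", "p.value", "significant", "direction")]
#>     x mean_ref mean_test    U  p.value significant direction
#>  2 10   0.0926     0.946 6400 9.39e-28        TRUE    higher
#>  6 30   0.0927     0.604 6400 9.39e-28        TRUE    higher
#> 10 50   0.0927     0.289 6400 9.39e-28        TRUE    higher
#> 17 85   0.9774     0.862    3 6.18e-28        TRUE     lower
#> 19 95   0.6242     0.588 2052 9.00e-05        TRUE     lower
```

Central intervals (10–60%) gain relative intensity in the shifted group and
peripheral intervals (75–100%) lose it — the signature of chromatin
detaching from the periphery — giving a positive inner-third Δ and a
negative outer-third Δ. `plot_radial_comparison(cmp)` draws the two mean
profiles with error bars and significance asterisks.

Nuclear volumes from mean diameters, and frameshift verification:

```r
round(sphere_volume_from_diameter(c(26.8, 11.1)))   # (pi/6) d^3
#> [1] 10079   716

rep <- frameshift_report(synthetic_lam_like_cds(), lam_a25_variant())
print(rep)
#> <frameshift_report> frameshift: yes
#>   last intact residue: 610
#>   novel residues (13, no stop found): STTSTTTLRPSWN
epitope_integrity(c(528, 622), rep)   # C-terminal antibody epitope
#> $intact_residues
#> [1] 83
#> $total_residues
#> [1] 95
```

(`synthetic_lam_like_cds()` is a synthetic stand-in carrying the published
variant coordinates; the novel-peptide *content* above is a property of
that synthetic sequence, while the position arithmetic — last intact
residue 610, epitope preservation — is sequence-independent.)

A thin command-line front end over the same functions lives at
`inst/cli/radialchrom.R` with subcommands `simulate`, `measure`, `compare`
and `verify-mutation`.

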
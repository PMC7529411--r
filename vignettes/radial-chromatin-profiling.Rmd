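---
title: "Quantifying radial chromatin distribution in polytene nuclei"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying radial chromatin distribution in polytene nuclei}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radialchrom)
```

## The measurement

B-type lamins tether chromatin to the nuclear envelope. When that tethering is
disrupted — for instance by a frameshift that removes the C-terminal CaaX
membrane-anchoring motif from Lamin B — chromatin may relocate from the
nuclear periphery toward the interior. `radialchrom` quantifies this
relocation in 2D confocal sections of DAPI-stained polytene nuclei
(salivary gland, proventriculus) and tests it between two groups of nuclei,
typically wild-type versus mutant.

The chain, per nucleus:

1. **Equatorial plane.** For a z-stack, the analysed section is the one with
   the largest total segmented nucleus area (`select_equatorial_plane`) —
   the widest cross-section of the nucleus. Ties go to the lower index, so
   an odd symmetric stack selects its true midplane.
2. **Centre and profiling radius.** Nuclei are segmented by Gaussian
   smoothing, global Otsu thresholding, hole filling, small-object removal
   and 8-connected labelling (`segment_nuclei`), or taken from a
   user-supplied label mask. The centre is the unweighted centroid of the
   mask; the profiling radius is the maximum centroid-to-pixel distance
   (`estimate_center_radius`). The covering radius — rather than an
   equivalent-area radius — guarantees that 100% relative radius reaches the
   outermost chromatin, mirroring a circumscribed circular ROI.
3. **Ring profile.** The intensity at distance $r$ from the centre is the
   sum of pixel values around the circle of radius $r$
   (`compute_raw_profile`). Every pixel whose centre lies within the
   profiling radius $R$ is assigned to exactly one integer ring by rounding
   its distance (half up), clamped to $\lfloor R \rfloor$; the rings
   therefore partition the disk and the ring sums conserve the total
   in-circle intensity exactly.
4. **Relative coordinates and normalisation.** Ring radii are rescaled to
   percent of $R$ (0–100%) and the profile is divided by its maximum over
   the nucleus (`normalize_profile`), giving values in $[0,1]$ with maximum
   exactly 1. Normalisation is by the maximum *ring* value — the profile is
   the only quantity on that axis — not the maximum pixel value.
5. **5% intervals.** Rings are averaged into twenty half-open intervals
   $(x-5, x]$ labelled by their right edge $x \in \{5, 10, \ldots, 100\}$,
   with relative radius 0 folded into the first interval (`bin_profile`).
   Intervals receiving no ring are recorded as missing, never imputed as
   zero.

Per cohort, the per-nucleus interval values are aggregated within each group
(mean, standard deviation, standard error; `summarize_group`), each interval
is compared between groups with a two-sided Mann–Whitney U test
(`compare_bins`), and the integral change over a set $L$ of intervals is
summarised by

$$\Delta \;=\; \left(1 - \frac{\sum_{x \in L} I_{\mathrm{ref}}[x]}
                              {\sum_{x \in L} I_{\mathrm{test}}[x]}\right)
      \times 100\%,$$

where $I_G[x] \in [0,1]$ is the group mean per-nucleus relative intensity at
interval $x$ (`delta_statistic`). $\Delta$ is zero when the two sums agree,
positive when the test group carries more relative intensity on $L$, and is
bounded above by 100. By default $L$ ranges over the three radial thirds;
since twenty intervals do not divide evenly by three, each interval joins
the continuous third containing its midpoint $x - 2.5$: inner = {5..35},
middle = {40..65}, outer = {70..100} (`default_delta_intervals`). Both
boundaries and the multiplicity correction (none by default; Holm and
Benjamini–Hochberg available) are configurable. Per-interval testing without
correction reproduces the original analysis; the corrections are offered as
optional refinements.

## Sum versus mean rings: which quantity is on the Y axis

Two conventions exist for the profiled quantity. The *ring sum* is literally
"the sum of the pixel values around a circle". The *ring mean* divides each
ring sum by its pixel count, which is what the widely used ImageJ/Fiji
"Radial Profile" plugin reports (its integrated intensities are normalised
by the number of pixels in each ring). Both are available through
`ring_statistic = "sum"` (the default) and `"mean"`.

The distinction matters once profiles are normalised by their maximum. The
ring sum weights the underlying intensity law $f(\rho)$ by ring
circumference, i.e. by $\rho$. For a nucleus with a bright peripheral rim,
the rim then dominates the profile maximum in *both* groups even after a
moderate fraction of chromatin relocates to the centre — the normalised
peripheral intervals barely move, because the rim's normalised shape is
invariant to its own rescaling. Under the ring mean the maximum follows the
intensity *density*, so a relocation that makes the interior brighter than
the rim lowers the normalised peripheral intervals and raises the central
ones — the signature reported for lamin-mutant proventriculus nuclei
(significant peripheral decreases, central increases, negative outer-third
$\Delta$, positive inner-third $\Delta$). For this reason the package's
simulation studies (`null_rejection_study`, `shift_recovery_study`) measure
with `ring_statistic = "mean"`; real-data users comparing against
plugin-derived measurements should do the same, while `"sum"` remains
available for the literal ring-integral reading.

## The synthetic-nucleus generator

Every stage is validated against synthetic nuclei with known ground truth
(`simulate_cohort`). What it emulates:

* **Geometry.** Roughly circular nuclei of two size classes — mean diameter
  26.8 µm ("salivary-gland-like") and 11.1 µm ("proventriculus-like"), the
  mean diameters measured for the two tissues. Per-nucleus diameters vary
  with an 8% coefficient of variation (typical spread for nuclei of one
  tissue and ploidy class), eccentricity is uniform on [0, 0.3] and
  orientation uniform on [0, π), so the centre/radius estimator is
  exercised on non-ideal shapes, not just circles.
* **Radial intensity law.** Laws are specified on *relative* radius, so one
  law serves both size classes — the analysis itself is entirely in relative
  coordinates. The wild-type-like default is a peripheral Gaussian rim at
  relative radius 0.85 with width 0.08 plus a flat base at 0.1 of the
  component peak: a rim-enriched profile peaking near the periphery. These
  are free parameters of the generator, not values fitted to any published
  curve.
* **The mutant-like shift.** `shift_law(law, s)` moves a fraction $s$ of the
  2D intensity *mass* carried by the rim component into a central Gaussian
  component (width 0.25), leaving the background untouched; $s = 0$ returns
  the law unchanged, making the two groups of a null cohort identically
  distributed by construction. Because rendering scales each law to a target
  peak intensity, the test group's peak is rescaled by
  $(\max f_{\mathrm{test}} / \max f_{\mathrm{ref}}) \cdot
   (m_{\mathrm{ref}} / m_{\mathrm{test}})$
  (with $m$ the law's disk mass), so a shifted nucleus carries the same
  expected total intensity as an unshifted one: the shift relocates
  chromatin, it does not add DNA.
* **Photometry.** Expected pixel value at relative radius $\rho$ is
  $\text{peak} \cdot f(\rho) / \max f$ with a default peak of 1000 counts;
  per-pixel Poisson photon noise by default, with noiseless and
  additive-Gaussian options. Noiseless renders equal the expectation
  exactly, which the tests use as the analytic reference.
* **Reproducibility.** One master seed per cohort; per-nucleus child seeds
  are drawn from it, so identical specs give byte-identical images and
  manifests while nuclei remain independently perturbed.
* **Cohort size.** 90 nuclei per group by default, comparable to the
  78–103 nuclei per tissue and genotype measured in the study.

What it deliberately does **not** emulate: polytene banding texture,
multi-channel immunostaining, optical point-spread/Airyscan effects,
touching or overlapping nuclei, and uneven illumination. Passing tests on
these synthetics therefore validate the *measurement arithmetic and the
statistics*, not robustness to every real-microscopy artefact; on real
images the segmentation defaults (`sigma = 2` px smoothing,
`min_area_px = 100`, border-touching nuclei excluded) may need adjustment,
or a hand-drawn label mask may be supplied to bypass segmentation entirely.

## Numerical and interface choices

* **Coordinates** are 1-based with the origin at the centre of the top-left
  pixel, matching R matrix indexing; plane indices are likewise 1-based.
  All geometry is sub-pixel (centroids and radii are real-valued).
* **Ring membership** rounds distance half up and clamps to
  $\lfloor R \rfloor$, so the outermost ring absorbs the fractional
  remainder of the radius; this keeps the conservation identity exact
  rather than approximate.
* **Mann–Whitney p-values** are exact (enumeration) when
  $n_1 + n_2 \le 16$ with no ties, and otherwise use the normal
  approximation with tie and continuity corrections; with every value tied
  across both samples there is no evidence either way and $p = 1$.
  Intervals with fewer than two values in either group are flagged as
  untested rather than silently dropped.
* **Missing intervals** propagate as missing through summaries and tests;
  $\Delta$ refuses interval sets containing undefined group means and names
  the offending intervals.
* **Degenerate inputs** fail loudly: empty masks, all-zero profiles
  ("empty nucleus"), single-pixel regions (radius 0 cannot be profiled),
  profiling circles that exceed the image (unless clipping is requested,
  which flags the profile), floating-point label masks, RGB images.
* **Error bars.** Both standard deviation and standard error are computed
  per interval and either can be drawn (`plot_radial_comparison`), since
  published conventions differ between the two.
* **Tables** are tidy CSV (one row per nucleus and interval) serialised at
  full double precision, so write/read round-trips are lossless; configs are
  JSON or YAML.

## The frameshift-verification module

A small sequence module reproduces the arithmetic used to authenticate a
frameshift allele at the CDS level: `apply_substitution` splices a variant
(verifying the reference allele in place), `frameshift_report` locates the
last intact residue (the last codon entirely upstream of the substitution —
for a substitution starting at CDS position 1831 that is residue
$\lfloor 1830/3 \rfloor = 610$), translates both alleles and extracts the
novel peptide up to (excluding) the first stop, and `epitope_integrity`
counts how many residues of an antibody epitope survive. The novel-residue
count is defined as *all* residues after the last intact one, whether or not
some coincide with wild-type residues by chance between frames; the stop
codon is not counted. `synthetic_lam_like_cds()` provides a clearly
synthetic CDS carrying the published variant coordinates for exercising the
machinery; sequence-specific results (such as the published 27-residue novel
peptide) require the real GenBank sequence, which is not bundled.

## Simulation-study scales

The packaged studies run at the scales used throughout the validation
suite: the null-calibration study uses 200 independent cohort pairs of 50
nuclei per group (4,000 pooled interval tests), and the effect-recovery
study uses 100 pairs of 80 nuclei per group at `shift_fraction = 0.3`,
both on proventriculus-like nuclei at 0.2 µm/pixel. These sizes give a
standard error of about 0.3 percentage points on the null rejection rate
and resolve recovery fractions down to a few percent, while a full study
completes in minutes on a single CPU.

```{r example, eval = FALSE}
cmp <- simulate_and_compare(
  cohort_spec(n_per_group = 80, shift_fraction = 0.3, seed = 1),
  config = run_config(ring_statistic = "mean"))
print(cmp)
plot_radial_comparison(cmp)
```

## Known limitations

* Nuclei are treated as independent units; the per-individual clustering of
  nuclei (several nuclei imaged per animal) is not modelled. A
  mixed-effects extension would be the natural refinement.
* Automated Otsu segmentation stands in for the original hand-drawn ROIs;
  on crowded or low-contrast fields a user-supplied label mask is the more
  faithful route.
* The profile is strictly 2D on the equatorial section; no 3D shell
  profiling is attempted.
* Watershed splitting of touching nuclei is not implemented; simulated
  fields are generated non-overlapping.
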
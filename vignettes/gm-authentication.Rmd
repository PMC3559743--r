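---
title: "Voxel-level matching of normalized gray-matter maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-level matching of normalized gray-matter maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmauth)
```

## The problem

After tissue segmentation and nonrigid spatial normalization, every
subject's T1-weighted MRI is reduced to a gray-matter (GM) probability map
living in one common template space: voxel `x` of map `G_i` holds the
probability that `x` is gray matter in subject `i`. gmauth treats these
maps as a biometric trait and asks how well they distinguish individuals.
Because normalization aligns all brains to a common template, any residual
discriminative power is evidence that normalization preserves
individual anatomy rather than erasing it — which is exactly what makes the
question interesting for group-analysis pipelines that assume normalized
images remain comparable across subjects.

The package consumes already-normalized GM maps (NIfTI-1). Segmentation and
registration are deliberately out of scope; the only preprocessing step
implemented here is the final isotropic Gaussian smoothing conventionally
applied to normalized GM maps.

## Matching model

Two aligned maps `G_a` and `G_b` are compared voxel-by-voxel:

    d(a, b) = sum over all voxels x of | G_a(x) - G_b(x) |

the L1 (sum of absolute differences) distance. GM maps have no stable point
landmarks the way fingerprints have minutiae, so pixel-level matching over
the whole volume is the natural operator; it uses all of the image
information and is robust to local noise. A smaller `d` means a higher
probability that both images come from the same brain. All voxels
participate — background voxels contribute nothing because both maps are
zero there. A sum-of-squared-differences (L2) variant is available via
`metric = "L2"`; every evaluation stage is invariant to any monotone
pairwise distance, and L1 is the default used throughout.

Distances from one experiment are pooled (genuine and imposter comparisons
together) and min–max normalized to matching scores:

    s = 100 * (d_max - d) / (d_max - d_min)

where `d_max`/`d_min` are the extremes over *all* differences of that
pool, computed per experiment. The most similar pair scores 100, the least
similar 0. When every distance in a pool is identical (possible only on
degenerate synthetic input) all scores are set to 100; the convention is
recorded here and exercised by the tests. Because normalization is a
monotone map, score ordering is always the exact reverse of distance
ordering, and rank-1 identification is unaffected by whether the pool is
per-probe or global — per-probe is used.

## Verification protocol

A *genuine* pair compares two images of the same subject; an *imposter*
pair compares images of two different subjects. Genuine pairs come in two
protocols:

* **Same-Visit** — both scans from one imaging session: for each subject
  and visit with `m` scans, all `choose(m, 2)` unordered scan pairs.
* **Different-Visit** — scans from distinct sessions of one subject: all
  cross-visit scan pairs, `sum over j < k of m_j * m_k` for visit sizes
  `m_1..m_V`. When every visit has `m` scans this reduces to the familiar
  `choose(V, 2) * m^2`; the implementation uses the general form because
  real visit structures vary. Dataset totals aggregate over subjects
  (equivalently over the counts `n_V` of subjects with `V` visits).

Imposter pairs follow a one-volume-per-subject convention: a selector
(default: the second scan of the first visit) picks one map per subject,
and all `choose(N, 2)` cross-subject pairs are formed — with 150 subjects,
11 175 pairs. `count_genuine_pairs()` is the closed form and
`enumerate_genuine_pairs()` the explicit enumeration; the test suite keeps
them in agreement with a brute-force double-loop oracle over random visit
structures.

At a decision threshold `t` on the score scale:

* FRR (false rejection rate) = % of genuine pairs with score **strictly
  below** `t`;
* FAR (false acceptance rate) = % of imposter pairs with score **strictly
  above** `t`.

The strict inequalities are part of the definitions; scores equal to the
threshold count as accepted-genuine and correctly-rejected-imposter. The
tie convention is stored in each run's `summary.json`.

### Threshold sweep, ROC and EER

FAR(t) and FRR(t) are step functions of `t`, constant on the open
intervals between observed scores. `roc_curve()` therefore sweeps every
point where the pair (FAR, FRR) can change *or hold a distinct plateau
value*: all observed scores, the midpoints between adjacent distinct
scores, and one point below the minimum and above the maximum (giving the
curve its (FAR 100, FRR 0) and (FAR 0, FRR 100) endpoints). Omitting the
midpoints would silently skip operating points — with genuine scores
{10, 20} and imposter scores {90, 95}, every threshold strictly between 20
and 90 has FAR = FRR = 100, a plateau invisible at the observed scores
themselves.

The equal error rate is the operating point with FAR = FRR. If a swept
threshold attains equality exactly, that value is returned (smallest such
threshold on ties, flagged `exact_crossing`); otherwise both rates are
linearly interpolated between the adjacent swept thresholds where
FAR − FRR changes sign. The estimator agrees with an exhaustive fine-grid
threshold search to well under half a percentage point once the score sets
are large enough for the step functions to resolve it.

`separation_gap()` reports the maximum imposter and minimum genuine score;
when the former is strictly smaller, any threshold between them yields
FAR = FRR = 0 and the EER is exactly 0 — the headline regime for
same-visit matching.

## Identification

Closed-set 1-to-N identification enrolls one map per subject (default: the
second scan of the first visit) as the gallery and probes it with one map
per subject from a later session (default: the second scan of the second
visit). Each probe is compared against every gallery entry; the
highest-scoring (equivalently nearest) subject is returned. Exact distance
ties — measure-zero on real data, constructible on synthetic input — are
resolved to the lexicographically smallest subject id and flagged. The
identification ratio is the percentage of probes whose true subject is
returned at rank 1. Only rank-1, closed-set identification is implemented:
no reject threshold, no CMC curve beyond rank 1.

## Gaussian smoothing

`smooth_volume()` implements the standard isotropic Gaussian filter with a
full-width-at-half-maximum parameter: per axis,
`sigma_vox = fwhm_mm / (voxel_size_mm * 2 * sqrt(2 * log 2))`, kernel
truncated at 4 sigma. The default FWHM is 8 mm, the common choice for
normalized GM maps in SPM-style pipelines; it is a configuration
parameter, not a fixed constant. At the grid boundary the kernel is
renormalized over its in-domain support (normalized convolution) rather
than zero-padded: this preserves constant volumes exactly and keeps every
output voxel a convex combination of inputs, so smoothing can never push
values outside the observed range; total GM volume of interior features is
conserved to well under 1%. `run_experiment()` defaults to `fwhm_mm = 0`
because the synthetic phantoms are generated already spatially smooth; for
real normalized maps, set the FWHM of your pipeline.

## The synthetic phantom generator

Real longitudinal data of the required structure (150 subjects, repeated
visits, several scans per visit) cannot ship with a package, so
`generate_dataset()` fabricates datasets with exactly the variance
decomposition the method assumes:

* a **shared base support**: an ellipsoidal cortical shell (GM
  probability 0.8 between 50% and 90% of an ellipsoid spanning the grid,
  0 elsewhere) standing in for template-space anatomy common to everyone;
* a **subject field**: a zero-mean smooth Gaussian random field (white
  noise smoothed to `smoothness_vox`, standardized over the shell) scaled
  by `subject_amplitude` — the stable individual anatomy that survives
  normalization;
* a **visit field**: an independent smooth field scaled by
  `visit_drift_sd`, identical for all scans of one visit — intra-class
  variability from scanner electronics and session environment;
* **scan noise**: white voxel noise scaled by `scan_noise_sd`.

Each volume is clipped to [0, 1]. Seeding is hierarchical —
(master, subject), (master, subject, visit), (master, subject, visit,
scan) — so any single volume is reproducible in isolation and reruns are
byte-identical.

Defaults: 150 subjects × 2 visits × 3 scans on a 32×32×32 grid of 2 mm
voxels, `subject_amplitude = 0.2`, `visit_drift_sd = 0.05`,
`scan_noise_sd = 0.02`, `smoothness_vox = 2`. The amplitudes were chosen
once so that individual anatomy dominates session drift, which in turn
dominates scan noise — the qualitative regime reported for real
normalized GM data (complete same-visit separation and therefore 0% EER,
slightly degraded different-visit matching) — and they are not fitted to
any real dataset's statistics. The 32-cubed grid keeps a full 900-volume
study runnable in well under a minute on one core; the test suite uses
smaller grids (10–16 voxels per side) for unit-level checks and the full
default study for the end-to-end ones.

What the phantoms do **not** emulate: real cortical geometry, tissue-class
mixing, registration error fields, scanner-specific bias, motion
artifacts, or age/disease-related atrophy. Passing the synthetic
experiments therefore demonstrates that the pipeline is correct and that
the method behaves as designed under its assumed variance structure — it
does not re-establish the empirical performance on clinical data, which
requires the original cohort.

## Numerical choices and degenerate inputs

* GM validity tolerance: voxel values within `1e-6` outside [0, 1] are
  clipped (segmentation float noise); larger excursions raise an error.
* All volumes of one experiment must share grid shape and voxel size;
  mismatches are an error, never resampled away.
* Volumes are stored as 64-bit floats so write/read roundtrips are exact.
* Empty pair lists, empty score pools and empty probe sets are errors, not
  silently empty results.
* `visit_id`/`scan_id` are 1-based ordinals ("the second scan in the first
  visit" is `visit 1, scan 2`); voxel indices follow R's 1-based array
  convention. Subject indices in the generator run `1..n_subjects`.
* Score histograms bin [0, 100] in `[left, right)` bins (100 falls in the
  last bin), reported as percentages summing to 100.

## Reproducing a run

Every number in a run's `summary.json` is recomputable from the emitted
score CSVs alone (the tests verify this), and `run_experiment()` is
deterministic given its configuration, so two runs with the same config
produce byte-identical reports.

```{r example, eval = FALSE}
cfg <- experiment_config(
  phantom_config(n_subjects = 20, master_seed = 1),
  protocols = c("same_visit", "different_visit", "identification"),
  out_dir = "gm-run")
report <- run_experiment(cfg)
report$summary$same_visit$eer
report$summary$identification$identification_ratio
```

## Known limitations

* The matching operator is intensity-based and whole-volume; it does not
  localize *where* two brains differ, and regional analyses are future
  work.
* The distance is sensitive to any preprocessing difference between the
  compared maps (different smoothing, different template), which is why
  the experiment driver applies one shared configuration to every volume.
* Phantom realism is structural, not anatomical (see above); absolute
  EERs on phantoms are not comparable to clinical EERs.
* Only closed-set identification is supported; open-set operation would
  need a reject threshold calibrated on genuine/imposter score
  distributions.
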
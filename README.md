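# mmdir — multi-metric deformable image registration for post-operative CT

`mmdir` registers a pre-operative CT (the *moving* image) onto a
post-operative planning CT (the *fixed* image) of the same breast-cancer
patient, so that the pre-operative tumor contour (plus margin) can be
propagated onto the planning scan and compared with the clinically
delineated tumor bed and boost-CTV. This is the setting where purely
intensity-driven deformable registration struggles: the lumpectomy
replaces the tumor with a seroma-filled, clip-marked cavity, tissue
collapses toward the bed, and soft tissue on non-contrast CT offers only
faint, self-similar structure.

The registration optimizes a cubic B-spline free-form deformation
\(T_\mu\) (after an affine initialization) by stochastic gradient descent
over a three-level Gaussian pyramid, minimizing the weighted multi-metric
objective

```
C(T_mu) = ( w_f * S_CP + w_r * (1 - KS) + w_i * (-MI) ) / (w_f + w_r + w_i)
```

with

* `S_CP = (1/P) * sum_i || x_M_i - T_mu(x_F_i) ||` — mean Euclidean
  distance (mm) over paired fiducial landmarks,
* `KS = 2|A & B| / (|A| + |B|)` — Kappa overlap of a paired region of
  interest (the unaffected breast gland), interpolated softly for
  differentiability,
* `MI` — mutual information (bits) of the joint intensity histogram
  (cubic-kernel Parzen estimator with stochastic sampling; an exact dense
  mode for reporting),

and default weights `(1, 1, 100)`. Setting weights to zero recovers the
conventional intensity-only method (`i`) and its partial augmentations
(`ri`, `fi`, `fri`) through one shared code path.

The package also provides: automatic landmark extraction (3D Harris
corners) and pairing (two-stage normalized cross-correlation search with
sub-voxel refinement and a smoothness consistency gate), Otsu threshold
segmentation, evaluation tools (target registration error by tissue
group, Dice, Hausdorff, checkerboard and orange/cyan overlays), physical
margin operations (`tumor+N`, skin-limited expansions via exact Euclidean
distance transforms), MetaImage/NIfTI-1 I/O, a command-line interface,
and a synthetic resection-phantom generator with ground-truth
deformations that makes the whole pipeline testable without patient
data.

## Worked example

```r
library(mmdir)

# a synthetic case: pre-op/post-op pair with resection, ground truth known
ph <- generate_phantom(phantom_config(seed = 1))

# automatic fiducials: Harris corners in the unaffected gland, paired by
# correlation search (held-out ground-truth landmarks are separate)
corners <- harris_corners_3d(ph$fixed, mask = ph$gland_fixed, n_points = 60)
pairs   <- match_points(ph$fixed, ph$moving, corners,
                        search_radius_mm = 22, patch_radius_mm = 8,
                        min_corr = 0.5)

# full multi-metric registration (weights 1, 1, 100)
reg <- register_multimetric(ph$fixed, ph$moving,
                            registration_config(seed = 1),
                            pairs = pairs,
                            roi_fixed = ph$gland_fixed,
                            roi_moving = ph$gland_moving,
                            fixed_mask = ph$body_fixed)

target_registration_error(ph$landmarks, reg$transform)

# propagate tumor+2 onto the planning CT and compare with the tumor bed
t2  <- expand_margin(ph$tumor, 20, limit = ph$body_moving)
t2d <- propagate_mask(t2, reg$transform, ph$fixed)
dice(t2d, ph$tumor_bed); hausdorff(t2d, ph$tumor_bed)
```

Output from this exact script (seed 1):

```
<mmdir_tre> target registration error (mm)
  boundary     n= 5  5.02 +/- 1.93
  rigid        n= 5  0.89 +/- 0.53
  soft_tissue  n=20  0.57 +/- 0.39
> dice(t2d, ph$tumor_bed)
[1] 0.4582654
> hausdorff(t2d, ph$tumor_bed)
[1] 15.37043
```

Interpretation: the held-out landmark pairs of this case start at a
median misalignment of 6.28 mm; after the full (`fri`) registration the
soft-tissue landmarks agree to 0.57 ± 0.39 mm (median over all groups
0.61 mm). The propagated `tumor+2` contour overlaps the ground-truth
tumor bed with Dice 0.46 — the phantom-scale analogue of comparing a
deformed contour with a clinically delineated bed, which is never a
perfect match because a uniform tumor expansion only approximates the
true resected volume.

The four-method comparison of the study is replayed with

```r
run_method_comparison(ph, methods = c("i", "ri", "fi", "fri"),
                      cfg = registration_config(), seed = 1)
```

which reports TRE per tissue group and Dice/Hausdorff of
`tumor+2 vs bed` and `tumor+3 vs boost-CTV`, one row per method.

## Command line

An installed `exec/mmdir` script exposes the pipeline:

```sh
mmdir phantom  --seed 1 --out-dir case1
mmdir features corners --volume case1/fixed.mha --mask case1/gland_fixed.mha --out corners.txt
mmdir register --fixed case1/fixed.mha --moving case1/moving.mha \
               --fixed-roi case1/gland_fixed.mha --moving-roi case1/gland_moving.mha \
               --fixed-mask case1/body_fixed.mha --seed 1 \
               --out-transform T.json --out-resampled moved.mha --log cost.csv
mmdir propagate --mask case1/tumor.mha --transform T.json --like case1/fixed.mha --out bed_pred.mha
mmdir evaluate --transform T.json \
               --fixed-points case1/landmarks_soft_tissue_fixed.txt \
               --moving-points case1/landmarks_soft_tissue_moving.txt --report tre.json
mmdir compare  --case-dir case1 --methods i,fi,fri --seed 1 --out comparison.csv
```

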
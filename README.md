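# tau3d — Slope-Chain-Code tortuosity for 3D voxelized objects

`tau3d` quantifies how much the surface of a binary voxel volume twists
and turns. It is aimed at morphometric analyses of segmented medical
images — cortical surfaces, sulci, vessels, tumors — and at anyone who
needs a scalar shape descriptor for voxel masks that distinguishes a
smooth blob from a convoluted one, which the classical arc/chord
tortuosity ratio cannot do.

## The measure

A planar curve approximated by straight-line segments of equal status
can be written as a Slope Chain Code (SCC): the sequence
`A = a_1 a_2 … a_N` of slope changes between contiguous segments,
each normalized by π to the open interval (−1, 1). Its 2D tortuosity is

    τ = Σ_{n=1}^{N} |a_n|

For a simple convex closed curve the total absolute turning is exactly
2π, so τ = 2 regardless of the polygon.

The 3D measure slices the volume along the three grid axes, traces
every cross-section's boundary, and averages per-axis slice
tortuosities:

    τ3D = (Σ_i Σ_n |x_ni|)/S_X + (Σ_j Σ_m |y_mj|)/S_Y + (Σ_k Σ_l |z_lk|)/S_Z

where `x_ni` are the chain elements of the contours in slice `i`
perpendicular to X and `S_X` counts the slices that intersect the
object (likewise Y, Z). A convex closed surface — every slice convex —
gives τ3D = 6; excess over 6 measures surface complexity.

Rasterized boundaries carry a stair-stepping artifact (spurious 90°
turns on oblique edges) that would swamp τ. Each traced contour is
therefore filtered before encoding: vertex downsampling by a factor of
10, then a digital-straight-segment (DSS) simplification that keeps
only vertices starting maximal straight runs (all intermediate vertices
within half a strip width of the run's chord).

## Worked example

```r
library(tau3d)

# convex solids hit the theoretical value 6 exactly
tortuosity_3d(make_cube(41))$tau3d
#> [1] 6

# a digitized sphere at an oblique rasterization phase stays close
tortuosity_3d(make_sphere(30, angle = 45))$tau3d
#> [1] 6.012893

# progressive morphological smoothing of a bumpy sphere drives tau3D down
closing_experiment(make_bumpy_sphere(25, 5, 6), radii = c(2, 4, 6, 8))
#>   radius    tau3d
#> 1      0 21.64293
#> 2      2 18.50906
#> 3      4 15.71111
#> 4      6 13.37783
#> 5      8 12.81931
```

The first column is the structuring-ball radius (0 = unsmoothed); the
monotone drop in τ3D tracks the loss of surface detail under closing.

The bundled cohort table of per-lobe τ3D values (60 subjects: 37
Alzheimer's disease, 23 controls) reproduces the group comparison:

```r
cohort_report()[, c("region", "z", "p", "median_ad_rounded", "median_control_rounded")]
#>      region        z           p median_ad_rounded median_control_rounded
#> 1   frontal 2.220262 0.026400961                68                     71
#> 2 occipital 2.174822 0.029643463                33                     35
#> 3  parietal 3.140259 0.001687985                59                     62
#> 4  temporal 2.981289 0.002870375                39                     43
```

Positive z means controls rank higher: cortical folding complexity is
reduced in the patient group in all four lobes (Wilcoxon rank-sum,
normal approximation with tie correction, no continuity correction).

Command-line use (see `inst/cli/tau3d.R --help`):

```sh
Rscript inst/cli/tau3d.R make-shape cube --side 41 -o cube41.nii.gz
Rscript inst/cli/tau3d.R compute cube41.nii.gz --json result.json
Rscript inst/cli/tau3d.R validate-spheres --radii 10:70:10 --csv grid.csv
Rscript inst/cli/tau3d.R cohort
```

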
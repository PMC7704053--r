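# fptcell

Signals that travel from the cell membrane to the nucleus often do so as
single activated proteins diffusing through a cytosol crowded with
organelles.  **fptcell** computes the statistics of that journey on
segmented 3D cell reconstructions (e.g. from soft X-ray tomography): the
first-passage time (FPT) of a diffusing molecule from the inner cell
membrane to the nuclear membrane, with organelles as reflecting barriers,
the nucleus as an absorber, and optional first-order signal inactivation
competing with the search.  It is written for quantitative cell biologists
and modelers who want to ask: *how much do organelle barriers slow
signaling, and how much of that slowdown can inactivation buffer out?*

## The model

A segmented label volume on cubic voxels of edge $h$ partitions space into
cytosol $C_h$, nucleus $N_h$, organelles $O_h$ and exterior.  The density
$p_h(x_i,t)$ over cytosol voxels obeys the semi-discrete diffusion
equation $dp_h/dt = D \Delta_h p_h$ with the 6-point voxel Laplacian:
cytosol–cytosol faces couple at rate $D/h^2$, reflecting surfaces are
absent couplings, and each face shared with the nucleus adds a sink
$-(D/h^2)p_i$.  From the trajectory the package derives:

* survival $S_h(t)$ and FPT density
  $f_h(t) = D h \sum_i n_i p_h(x_i,t)$;
* mean first-passage-time fields solving $D \Delta_h u = -1$;
* under inactivation at rate $\lambda$: the splitting probability
  $Z_{\lambda,h} = \int_0^\infty e^{-\lambda t} f_h(t)\,dt$, conditional
  mean/variance/median and CDF of the arrival time, and signal curves
  $N f_{\lambda,h}(t) / Z_{\lambda,h}$ at fixed delivered molecule count;
* strong-inactivation asymptotics governed by the 6-neighbor graph
  distance $d_g$ from the release site to the nucleus:
  $\langle T_{\lambda,h}\rangle \sim d_g/\lambda$, and the
  physiological/no-organelle conditional-MFPT ratio tends to the ratio of
  graph distances.

Statistics are computed by two independent routes — time-domain hybrid
quadrature (stiff integrator + eigenvector-expansion tail) and resolvent
linear solves — which cross-validate each other.  Concentric-spheres
continuum closed forms are included as oracles.  A seedable synthetic-cell
generator (ellipsoidal cell and nucleus, random organelle occlusions at a
target volume fraction) makes the whole pipeline testable without any
imaging data; real volumes load from NIfTI or raw+JSON label fields.

## Worked example

```r
library(fptcell)

grid  <- concentric_spheres_grid(R_nuc = 0.5, R_cell = 1, h = 0.2)
masks <- build_masks(grid)            # variant = "physiological"
masks
#> <geometry_masks> variant = physiological, h = 0.2 um
#>   |C_h| = 496, |N_h| = 56, |O_h| = 0, exterior = 2192
#>   shell |dC_h| = 240 voxels (1.92 um^3); connected cytosol = 496/496

op   <- diffusion_operator(masks, D = 10)   # um^2/s
g    <- shell_init(masks)                   # uniform release on the membrane shell
traj <- hybrid_trajectory(op, g, window = c(0.05, 1), cutoff = 500)
fpt  <- fpt_density(traj)
glance(fpt)
#> # A tibble: 1 x 4
#>   absorbed mean_fpt T_switch n_modes
#>      <dbl>    <dbl>    <dbl>   <int>
#> 1     1.00   0.0371   0.0504      66

conditional_stats(c(1, 10, 100, 1e4), fpt = fpt, op = op, g = g)
#> # A tibble: 4 x 6
#>   lambda         Z   mean_s       var_s2 median_s method
#>    <dbl>     <dbl>    <dbl>        <dbl>    <dbl> <chr>
#> 1      1 0.964     0.0360   0.00109       0.0260  time_domain
#> 2     10 0.724     0.0284   0.000652      0.0207  time_domain
#> 3    100 0.172     0.0103   0.0000636     0.00813 time_domain
#> 4  10000 0.0000125 0.000288 0.0000000275 NA       resolvent
```

Reading the table: with no inactivation a molecule released on the
membrane needs 37 ms on average to reach the nucleus (the `mean_fpt` of
`glance()`); at $\lambda = 100\,s^{-1}$ only 17% of molecules make it
(`Z`), but those that do arrive in 10 ms on average — inactivation filters
out the long searches.  Every quantity decreases strictly with $\lambda$.
The graph distance behind the strong-inactivation limit:

```r
graph_distance(masks, g)
#> <distance_field> 496 voxels, d in [1, 5], d_g = 3
```

and the arrival-count noise if $10^4$ molecules are released at
$\lambda = 100\,s^{-1}$:

```r
arrival_number_stats(N0 = 1e4, Z = 0.172)
#> # A tibble: 1 x 5
#>      N0     Z  mean     cv cv_large_lambda
#>   <dbl> <dbl> <dbl>  <dbl>           <dbl>
#> 1 10000 0.172 1716. 0.0220          0.0241
```

`autoplot()` methods render survival/density curves, conditional
statistics against $\lambda$, MFPT histograms, and signal curves;
`run_analysis(run_config(...))` drives the whole comparison
(physiological vs barrier-free variants, MFPT ratio maps, signal
sharpening, asymptotic ratios) from a single JSON-able configuration and
writes versioned CSV tables.

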
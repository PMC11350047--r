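# DropletTimer

Timing-controlled division of DNA droplets, modelled end to end.

DNA droplets are liquid–liquid phase-separated condensates of branched DNA
nanostructures, crosslinked by 6-branched linker strands and divided by
single-stranded *division triggers* that cleave the linker via toehold-mediated
strand displacement. Coupling the triggers to a time-delay circuit —
sequestration by inhibitor RNAs (miRNA sequences) and slow re-release by
RNase H — makes the *timing* of division programmable, the *order* of
multistep division of a ternary droplet controllable, and, from there, a
molecular *comparator* that reports which of two miRNA inputs is more
concentrated by which daughter droplet divides first.

`DropletTimer` is an R/Bioconductor-style package for scientists modelling or
quantifying such systems. It provides:

* **Circuit kinetics** — well-mixed ODE and 2D reaction–diffusion engines for
  the trigger dynamics

  $$\partial_t u_{T_i} = D(\mathbf{x})\nabla^2 u_{T_i}
    - f_{\mathrm{H\text{-}SD}}(\mathbf{u}) + g_{\mathrm{TD}}(\mathbf{u}),
    \qquad
    g_{\mathrm{TD}} = \frac{k_{cat} c_E\, u_{iT_i}}{K_m + u_{iT_i}}
    - k_{h,RNA}\, u_{T_i} u_{R_i},$$

  with two-step (toehold binding + displacement) linker cleavage, a two-site
  linker bookkeeping (uncleaved fraction $w = 1 - p_1 p_2$), and optional
  shared-enzyme Michaelis–Menten competition between circuits.
* **Division model** — the cooperative switch
  $H(w) = K^n/(K^n + w^n)$ and the normalized division ratio
  $r_{div} = (H(w) - H_{min})/(H_{max} - H_{min})$, division times at the 0.5
  crossing, pathway labels from $\Delta\tau = \tau_{div,B} - \tau_{div,C}$,
  and the comparator offset $\sigma$ (bracket midpoint of the sign change).
* **Image quantification** — Otsu/manual binarization and the overlap
  estimator $r_{div} = 1 - |X\cap Y|/\min(|X|,|Y|)$ applied frame-by-frame to
  multi-channel TIFF stacks.
* **Synthetic data** — seeded droplet-division movies (rigid separating disks
  with read/shot noise and late-frame background drift) with analytic ground
  truth, and noisy concentration traces for parameter-recovery studies.

## Worked example: the miRNA concentration comparator

Run the five-condition dose sweep with the asymmetric kinetics preset (AB
hybridization/displacement rates 10× slower than AC, division thresholds
K_AB = 0.1, K_AC = 0.9, n = 16, one shared RNase H pool at 0.25 U/µL):

```r
library(DropletTimer)
sw <- runComparatorSweep(times = seq(0, 20000, by = 20))
sw
#> ComparatorResult over 5 conditions
#>  cTildeAB cTildeAC deltaC      tauB       tauC  deltaTau   pathway
#>      1.25     0.00   1.25 5747.1810   19.10014 5728.0808 Pathway 1
#>      1.25     0.75   0.50 7867.7660   65.82573 7801.9402 Pathway 1
#>      0.75     1.25  -0.50 5187.1978 2076.93734 3110.2605 Pathway 1
#>      0.25     1.25  -1.00 1230.7374 1583.03038 -352.2930 Pathway 2
#>      0.00     1.25  -1.25  891.3347 1336.03703 -444.7023 Pathway 2
#> offset sigma = -0.75
```

Each row is one input condition: `cTildeAB` and `cTildeAC` are the normalized
miRNA doses feeding the two time-delay circuits, `tauB`/`tauC` the simulated
division times (s) of the B and C droplets, and the pathway label says which
divides first. Δτ stays positive down to Δc̃ = −0.5 — the handicapped B side
loses even when it holds less inhibitor — and flips between −0.5 and −1.0,
so the comparator's offset is σ = −0.75. With `symmetric = TRUE` (identical
kinetics, equal thresholds) the sweep is mirror-symmetric and σ = 0.

Quantifying a (here synthetic, ground-truth-bearing) division movie:

```r
mv <- makeDivisionMovie(nFrames = 30, readNoise = 0.02, shotScale = 200,
                        seed = 7)
divisionTraceFromStack(mv$stack)$B
#> DivisionTrace (component B): 30 samples over [1, 30]; tau_div = 12.08
```

The extracted division time (frame 12.08) matches the analytic schedule
midpoint (12.06) to well within one frame despite shot noise.

The spatial engine reproduces the two linker-degradation patterns of the
mixed droplet — outside-in cleavage of the plain linker, spatially uniform
decay of the delayed linker:

```r
cfg <- spatialDropletConfig()        # 64x64 grid, droplet radius 50 um
traj <- simulateRD(cfg$model, cfg$grid, cfg$dmap,
                   times = seq(0, 2500, by = 25))
```

See the methods vignette (`vignettes/droplet-division-model.Rmd`) for the
model, parameter meanings, and numerical choices.

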
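# gliamorph

3D quantification of microglial morphology and microglia–axon-terminal
interactions in multi-channel confocal stacks, in R.

Microglia respond to developmental perturbations — such as maternal
high-fat diet during lactation — by remodeling their ramified processes
and by engulfing labeled axon terminals (e.g. AgRP boutons) in
hypothalamic feeding circuits. Studies of this kind image Iba1-labeled
microglia, reporter-labeled terminals and the lysosomal marker CD68 in
matched regions of interest, and report per-animal group statistics.
`gliamorph` implements that measurement chain end to end:

1. **Morphometry** — segment each microglial cell (exact 1-D 2-means
   automatic threshold), skeletonize it by geodesic medial path tracing,
   and measure total process length, Sholl branching complexity
   (sphere–edge crossings around the soma, summed over radii), cell
   volume, convex-hull territory, and cell density per ROI.
2. **Terminal spots** — background subtraction, Gaussian filtering, a
   scale-normalized 3D Laplacian-of-Gaussian (Mexican-hat) filter at the
   fixed physical spot size (0.8 µm diameter, σ = r/√3), local-maxima
   centroiding and a k-means automatic threshold over candidate
   responses.
3. **Interaction** — an exact anisotropic signed Euclidean distance
   field to the microglial surface classifies every spot: *contact* at
   |d| ≤ 1 µm, *engulfed* within the 0.5 µm interior shell (a
   full-interior mode is provided as well); CD68⁺ volume is quantified
   inside each cell.
4. **Statistics** — per-animal aggregation (the animal is the unit),
   mean ± SEM, two-sided unpaired t-tests (Student by default, Welch by
   flag), percent change, and deterministic figure-style report tables.

Because stacks for such studies are rarely deposited, the package ships
a **synthetic fluorescence-microscopy generator** — procedurally grown
branching glial cells plus planted punctate terminals with exact
geometric ground truth (classes assigned by the same rule the
measurement side uses) — and validates every stage against it and
against independent brute-force oracles.

## Worked example

Simulate a small two-group cohort in which the MHFD group's processes
are a 1.87-fold spatial rescaling of the NCD group's (an 87% planted
increase in total process length), run the full pipeline, and read the
group comparison:

```r
library(gliamorph)

cfg <- list(
  mode = "simulate", seed = 1, out_dir = "run",
  cohort = example_cohort_spec("morphometry", animals_per_group = 4),
  report = list(reference_group = "NCD"))
res <- run_pipeline(cfg)
subset(res$report, metric == "process_length",
       select = c(metric, n_a, n_b, mean_a, mean_b, t, df, p,
                  percent_change))
```

```
          metric n_a n_b   mean_a   mean_b         t df           p percent_change
2 process_length   4   4 82.91815 162.0778 -5.499774  6 0.001515187       95.46721
```

Each group mean is a mean of per-animal values (µm of skeletonized
process per cell, soma excluded); at n = 4 animals the measured +95% is
within sampling noise of the planted +87% (at the validation size of
n = 20 the recovered ratio lands within a few percent — see below). The
`run/` directory holds `cells.csv` (per-cell morphometry), `spots.csv`,
`interactions.csv`, `animals.csv`, a `report/` folder with one CSV per
metric, the resolved configuration, and a log; every table carries the
MD5 hash of the resolved configuration, and reruns with the same config
and seed are byte-identical.

Single stacks can be analyzed directly:

```r
st    <- read_stack("stack.ome.tif")            # voxel sizes from OME-XML
cells <- segment_cells(st$channels$iba1, st$grid)
m     <- cell_morphometry(cells[[1]], st$grid)  # length, Sholl, volume, hull
sp    <- detect_spots(st$channels$agrp, st$grid)
rec   <- classify_spots(sp, signed_distance(cells, st$grid))
```

A thin command-line wrapper with `run-all`, `simulate`, `detect-spots`,
`morphometry`, `classify` and `report` subcommands lives at
`inst/cli/gliamorph.R`.

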
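# sphereg

Spatial gene regulation along the core–periphery axis of tumor spheroids,
inferred from dye-diffusion-positioned single-cell UMI counts.

Tumor spheroids develop oxygen and nutrient gradients from periphery to
core. Incubating a spheroid briefly with a membrane-permeant dye
(Calcein-AM) labels cells in proportion to their distance from the surface;
after dissociation, flow cytometry records each cell's dye intensity and
deep plate-based single-cell RNA sequencing counts its transcripts with
unique molecular identifiers (UMIs). `sphereg` turns that data into
per-gene spatial regulation estimates, spatial gene calls with pattern
labels, and non-parametric pathway-level spatial associations — and ships a
fully seeded synthetic-data generator so the whole stack can be verified
against known ground truth.

## The model

Each cell gets a radial position `r ∈ [0, 1]` (0 = core, 1 = periphery) by
min–max scaling its log dye intensity. A gene's *spatial regulation
function* — its fractional abundance in the transcriptome at position `r` —
is a positive second-order polynomial

    f(r) = a + b·r + c·r²,   f(r) > 0 on [0, 1]

and observed UMI counts are negative binomial readouts of it:

    n_gc ~ NB(mean = f_g(r_c) · N_c,  size = θ_g)

with `N_c` the cell's total UMIs and `θ_g` a gene-specific overdispersion.
Fits are MAP estimates (BFGS with analytic gradients) under weak priors —
a soft positivity barrier on `min f` and wide Gaussian "no trend" priors on
`b`, `c` — with standard errors from a Laplace approximation. Genes are
called spatially regulated when their BH-adjusted gene-level Wald p-value
is below 10% and their regulation magnitude `1 − min f / max f` exceeds
30%, then classified as `core`, `periphery`, `intermediate` (interior
maximum) or `extrema` (interior minimum). Pathway-level association is
tested without the polynomial assumption: per-cell pathway UMI fractions
against `r` via Chatterjee's Xi correlation, BH FDR across sets, and an
abundance-weighted mean position `avgR` over 10 radial bins. See the
vignette `vignettes/spatial-regulation-model.Rmd` for the full account.

## Worked example

Everything below is computed; no real data required.

```r
library(sphereg)

cfg <- simulation_config(n_cells = 1500, median_depth = 2e4, seed = 1)
bm  <- make_benchmark(cfg)              # cells, counts, truth
counts <- filter_expressed_genes(bm$counts)   # mean >= 1 UMI/cell
calls  <- call_spatial_genes(counts, bm$cells)
#> Spatial calling: 575 / 576 genes retained; 259 called spatial
#> (core: 74, extrema: 49, intermediate: 55, other: 9, periphery: 72)

dplyr::arrange(tibble::as_tibble(calls), q) |>
  dplyr::select(gene_id, a, b, c, theta, q, magnitude, pattern) |> head(5)
#>   gene_id           a        b        c theta         q magnitude pattern
#> 1 gene_0191 0.0000510  0.00148 -0.00146 13.8  5.99e-274     0.881 intermediate
#> 2 gene_0184 0.000202   0.00254 -0.00251 11.5  4.60e-257     0.761 intermediate
#> 3 gene_0258 0.000465  -0.00141  0.00141 14.4  2.23e-221     0.759 extrema
#> 4 gene_0229 0.000127   0.00250 -0.00245  5.72 4.55e-207     0.834 intermediate
#> 5 gene_0224 0.0000655  0.00223 -0.00213  7.61 4.53e-194     0.900 intermediate
```

Per gene: the fitted coefficients of `f`, the NB size `theta`, the BH
q-value of the gene-level spatial test, the regulation magnitude (0.881 =
the gene's minimum expression along the axis is 88% below its maximum),
and the pattern label. `autoplot(calls)` summarizes pattern counts;
`plot_gene_fit()` overlays a gene's counts, fitted curve, and a
posterior-predictive simulation.

The benchmark's truth table makes pathway scanning verifiable too —
planted spatial sets light up, unregulated sets mostly do not:

```r
truth <- bm$truth; flat <- truth$gene_id[truth$pattern == "flat"]
gs <- tibble::tibble(
  set_name   = c("planted_periphery", "planted_core", sprintf("unregulated_%d", 1:5)),
  description = "-",
  genes = c(list(truth$gene_id[truth$pattern == "periphery"][1:20]),
            list(truth$gene_id[truth$pattern == "core"][1:20]),
            unname(split(flat[1:100], rep(1:5, each = 20)))))
pathway_spatial_scan(counts, bm$cells, gs, seed = 1)
#>   set_name          n_genes_present       xi        p        q significant  avgR
#> 1 planted_periphery              18  0.116   5.77e-13 2.02e-12 TRUE        0.597
#> 2 planted_core                   20  0.281   1.37e-66 9.58e-66 TRUE        0.509
#> 3 unregulated_1                  20  0.0492  1.30e- 3 3.03e- 3 TRUE        0.556
#> 4 unregulated_2                  20  0.0117  2.37e- 1 3.31e- 1 FALSE       0.554
#> ...
```

The periphery set's expression sits above the axis midpoint
(`avgR = 0.60` vs `0.51` for the core set; with only the modeled genes in
the denominator the contrast is compressed — on full transcriptomes core
sets drop well below 0.5). One of the five unregulated sets slips under
the 10% FDR line — exactly the kind of false discovery an FDR threshold
admits by design.

A thin command-line wrapper is installed at
`system.file("cli", "sphereg", package = "sphereg")` with subcommands
`simulate`, `fit`, `pathways`, `downsample`, `report`; `run_pipeline()`
is the equivalent in-R entry point and writes TSV tables, a JSON run
metadata file, and a log that reruns byte-identically for a fixed seed.

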
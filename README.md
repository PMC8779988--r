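# caspzone

Management zone delineation for precision agriculture: clustering and
smoothing of high-resolution proximal/remote soil-and-crop sensing data.

Online vis-NIR soil scanners log fertility attributes (MC, OC, Ca, CEC, K,
Mg, Na, P, pH) at sub-meter resolution along transects ~12 m apart.
Variable-rate machinery needs that evidence condensed into a few
contiguous, *actuatable* zones. `caspzone` implements the whole chain:

1. **Ordinary kriging** of irregular point samples onto a common 5 × 5 m
   grid — semivariogram fit by pair-count-weighted least squares, local
   neighborhood solve with the unbiasedness constraint
   $\sum_i w_i = 1$;
2. **Range normalization** to \[0, 1\] so Euclidean distances weight
   attributes equally;
3. **Feature selection**: greedy priority-ordered removal of attributes
   with pairwise Pearson $|r| > 0.7$;
4. **Clustering** with any of five algorithms implemented from first
   principles — k-means, fuzzy C-means, mean shift, agglomerative
   hierarchical, DBSCAN — across a 21-scenario evaluation grid
   (normalization × coordinates × feature decrease);
5. **Validity scoring**: Davies–Bouldin index
   $\mathrm{DBI}=\frac1k\sum_i\max_{j\ne i}\frac{s_i+s_j}{d_{ij}}$,
   Silhouette $s(i)=\frac{b(i)-a(i)}{\max\{a(i),b(i)\}}$, and the
   variance reduction index
   $\mathrm{VRI}_\theta=\bigl(1-\sum_i A_i\,v_{C_i\theta}/v_\theta\bigr)\times100\%$
   on the raw attribute rasters;
6. **Island smoothing**: spatial DBSCAN per cluster finds disconnected
   fragments; pieces smaller than the machinery threshold are relabeled
   by edge-neighbor majority vote, iterated to a fixed point.

A synthetic-field simulator (Voronoi zones, Gaussian random fields by
circulant embedding, cross-correlated attributes, transect sampling)
makes every stage testable without field data.

## Worked example

```r
library(caspzone)

spec  <- field_sim_spec(extent = c(200, 200), seed = 42)  # 4 zones, 9 attributes
field <- simulate_field(spec)
field$samples
#> <point_samples> n = 4097, attributes: MC, OC, Ca, CEC, K, Mg, Na, P, pH

res <- run_casp(stack = field$stack, config = casp_config(seed = 1))
res$selection
#> <selection_report> threshold |r| <= 0.7; kept: CEC, MC, OC, K, Mg, P; removed: Ca, Na, pH
res$validity
#> <validity_report> DBI 1.401, Silhouette 0.2805, mean VRI 64.84% (4 clusters, 0 outliers)

cells <- mask_cells(field$stack)
adjusted_rand_index(field$truth$values[cells],
                    res$smoothed$labels$values[cells])
#> [1] 0.6944179
```

Reading the numbers: the base-cation group (Ca, CEC, Na, pH) is generated
mutually redundant (|r| > 0.7), and selection keeps only CEC — the same
behavior the method shows on real fields. Mean VRI 64.8% says the four
zones absorb about two thirds of the attribute variance; DBI ≈ 1.4 and
Silhouette ≈ 0.28 are typical for soil data, whose zones overlap rather
than separate cleanly. The adjusted Rand index of 0.69 against the
simulation truth reflects this default *noisy* world; on well-separated
fixtures (zone-mean gaps ≥ 5 × noise sd) recovery is ≥ 0.9, which the
acceptance suite asserts. The smoothed map is certified to contain no
label component smaller than `island_size` (default 5 cells = 125 m²).

Scenario-grid evaluation and the command line:

```r
tab <- run_scenarios(field$stack, config = casp_config(seed = 1))  # 21 rows
```

```sh
Rscript -e 'caspzone::casp_cli()' simulate --out-dir sim --seed 3
Rscript -e 'caspzone::casp_cli()' casp --rasters sim/CEC.asc,sim/MC.asc,sim/OC.asc --out-dir out
Rscript -e 'caspzone::casp_cli()' smooth --labels out/labels_raw.asc --island-size 5 --out smoothed.asc
```

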
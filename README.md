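# serrmorph

Morphometrics and comparative statistics of the leading-edge serrations on
owl wing feathers.

The outermost primaries of owls carry a comb of stiff barb endings along the
leading edge — a structure implicated in silent flight. `serrmorph` is an R
package for the comparative analysis of these serrations across species: it
measures serration shape from 2D landmarks, classifies leading-edge elements,
tests species differences with a resampling procedure that respects the
interdependence of neighbouring serrations, and clusters species by their
serration morphology.

## What the package computes

**Shape measurement.** From labelled landmarks in the feather plane
(`feather_frame()`, `serration_landmarks()`):

* inclination angle α — the unsigned angle between the rachis axis and the
  straight barb base, in [0°, 90°];
* tip-displacement angle β — the signed angle between the base direction and
  the chord from the point of separation to the tip (positive = bent away
  from the rachis);
* serration length — the arc length of the traced tip path (mm).

`classify_edge_element()` applies the defining criterion: an element is a
**serration** only if the tip is detached *and* bent away from the rachis
(β above a small noise threshold); detached but straight or inward-bent tips
are **denticulations**; attached tips make the edge **smooth**.

**Resampling statistics.** The five serrations measured side by side on one
feather are not independent, so each Monte-Carlo run draws one value per
feather per group (two samples of n = 5), applies an exact two-sided
Mann-Whitney U test by full enumeration of all C(10,5) = 252 group
assignments (`exact_mann_whitney()`, midranks under ties), and the reported
summary is the **fraction of 5,000 runs significant at p < 0.05**
(`mc_comparison()`), banded `***`/`**`/`*` above 0.99/0.95/0.67.
`build_comparison_scheme()` enumerates the study's species-pair schemes (24
cross-activity comparisons, 16 with unequal size, 6 diurnal, 12 nocturnal).

**Clustering.** Species-by-parameter mean vectors are max-normalized (each
parameter divided by its maximum over species), embedded with Euclidean
distances and clustered by UPGMA with deterministic tie-breaking (`upgma()`);
trees serialize to Newick. `activity_bipartition()` checks whether the root
split separates nocturnal from diurnal species.

**Synthetic data.** `default_parameter_table()` ships a species × position ×
parameter calibration that pins the published species means (e.g.
inclination 12° for *A. noctua* at 0.4 of vane length, 33° for *B. bubo* at
0.2); `generate_dataset()` draws hierarchical measurement tables (5 feathers
× 5 serrations per species-position, within-feather equicorrelation 0.5)
from it. `run_pipeline()` ties everything into a reproducible run that
writes summary tables, banded comparison matrices, Newick trees and a
markdown report.

## A worked example

```r
library(serrmorph)

# measure a synthesized serration: the landmarks round-trip exactly
lm <- synthesize_landmarks(alpha_deg = 25, beta_deg = 18, length_mm = 3.2)
round(measure_serration(lm), 2)
#>      inclination_deg tip_displacement_deg            length_mm
#>                 25.0                 18.0                  3.2
classify_edge_element(lm)
#> [1] "serration"

# a synthetic study: 7 species x 4 vane positions x 25 serrations
d <- generate_dataset(default_parameter_table(), seed = 1)
round(parameter_means(d, 0.4), 2)
#>               inclination_deg tip_displacement_deg length_mm
#> B. bubo                 27.82                31.27      4.99
#> B. scandiacus           14.74                11.18      2.73
#> T. furcata              25.83                27.27      2.35
#> A. otus                 26.99                29.57      3.23
#> A. flammeus             12.58                 9.49      2.46
#> A. funereus             21.92                27.28      2.01
#> A. noctua               13.78                10.59      0.97

# Monte-Carlo Mann-Whitney across the 24 nocturnal-vs-diurnal comparisons
sch <- build_comparison_scheme(species_table(), "diff_activity_all")
res <- run_all_comparisons(d, sch, "inclination_deg", mc_settings(seed = 1))
head(res[c("species_a", "species_b", "position", "fraction_significant", "band")], 3)
#>     species_a   species_b position fraction_significant band
#> 1 A. flammeus A. funereus      0.2                    1  ***
#> 2 A. flammeus A. funereus      0.4                    1  ***
#> 3 A. funereus   A. noctua      0.2                    1  ***
sum(res$band == "***")
#> [1] 22

# max-normalized UPGMA dendrogram at 0.4 of the vane: nocturnal and diurnal
# species separate at the root
tr <- upgma(euclidean_distances(normalize_parameter_means(parameter_means(d, 0.4))))
activity_bipartition(tr)
#> [1] TRUE
```

The mean table shows the headline biology: nocturnal species (*B. bubo*,
*T. furcata*, *A. otus*, *A. funereus*) have steeper inclination angles,
tips bent further away from the rachis (tip displacement ≈ 27–31° vs
≈ 9–11°) and, size for size, longer serrations than the diurnal species;
22 of the 24 cross-activity inclination comparisons are significant in more
than 99 % of resampling runs; and the position-0.4 dendrogram splits the
species exactly by activity pattern.

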
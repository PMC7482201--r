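# dunbargraph

Human egocentric social networks are not homogeneous contact lists: they
are organised as a nested hierarchy of layers with remarkably constant
cumulative sizes — roughly **5, 15, 50, 150** alters (extending to 500,
1500 and 5000 for acquaintance and face-recognition circles) — in which
each layer is about **three times** the size of the one inside it, and
contact frequency and emotional closeness fall off sharply from layer to
layer.  `dunbargraph` implements this layered ("Dunbar graph") model end
to end for network scientists, social-evolution researchers and
epidemiological modellers:

* **Layer statistics** — annuli, successive scaling ratios
  `n_{i+1}/n_i`, social-effort shares (40% of effort to the inner 5, 20%
  to the next 10, so 60% of social time goes to just 15 people), and
  grouping-size summaries with range policies.
* **Layer detection** — exact optimal partitioning of 1-D contact-rate
  data (Jenks natural breaks; provably also the exact 1-D *k*-means
  optimum) via an `O(k n^2)` dynamic programme, with automatic
  layer-count selection by mean silhouette on log10 rates.
* **Information reach** — the layered acquisition model
  `P_i = Σ_{j≤i} n_j · r_K · c_j` (plus a strict-probability variant),
  cumulative reach curves over community sizes, and the **1/e
  inflection criterion** that identifies the optimal community size for
  information transmission (the 50 layer under the default
  calibration).
* **Urn allocation model** — the one-parameter Bayesian model
  `p_k ∝ exp(−µ s_k)` of how limited social capital is spread over
  relationship layers of cost `s_k`, with the concave/convex
  **phase transition at µ = 0** separating conventional
  (few-close-ties/many-weak) from inverted networks.
* **Cultural transmission on a structured population** — a
  Boyd–Richerson-style binary-variant simulator on a torus-wrapped
  lattice where agents imitate their four orthogonal "friends" or four
  diagonal "friends-of-friends" under a three-element bias vector, plus
  a mean-field (panmictic) variant; ensembles report extinction
  fractions and penetrance-time quantiles.
* **Synthetic data** — generators for layered contact-rate tables
  (log-normal within-layer noise, geometric between-layer decay) and
  small weighted community graphs, so the whole pipeline is testable
  offline.

## Worked example

```r
library(dunbargraph)

## a synthetic ego with planted layers 5/15/50/150 and log10 noise 0.1
tab <- gen_ego_contacts(seed = 42, log10_noise_sd = 0.1)
detect_layers(tab)
#> Optimal 1-D partition: k = 4 classes over 150 values
#>   class sizes (ascending value): 100, 35, 10, 5
#>   breaks: 0.06179, 0.20400, 0.70394
#>   within-class SSD: 1.39491
#>   cumulative layer sizes (inner->outer): 5, 15, 50, 150
#>   mean scaling ratio: 3.111
```

The detector recovers the planted four layers exactly; the breaks are
contact rates (events/day) separating the layers, and the scaling ratio
is close to the canonical 3.

```r
rc <- reach_curve(dunbar_scheme(), r_K = 0.01)  # 1% of community seeded
inflection_point(rc)        #> 78.01583
optimal_community_size(rc)  #> 50
```

The cumulative chance of hearing about an innovation saturates as the
community grows; the 1/e point of the curve falls inside the 50 layer:
growing a community beyond ~50 alters yields rapidly diminishing
information returns.

```r
m <- allocation_model(costs = c(4, 3, 2, 1), mu = 0.5, L = 150)
round(expected_occupancy(m), 1)  #> 15.2 25.1 41.4 68.3
classify_shape(m)                #> "convex"  (conventional network)
```

With relationship costs declining outward and µ > 0, most of the 150
ties sit in the cheap outer layers — few close friends, many weak ones.
Setting `mu = -0.5` inverts the network (`"concave"`), the structure
seen when social opportunities are scarce.

```r
summarize_group_sizes(dunbar_community_sizes())
#> mean 158.0, sd 28.7 (n = 12)
```

## Command line

A thin CLI wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "dunbargraph", package = "dunbargraph"))')
Rscript $CLI synth ego --seed 1 --out contacts.csv
Rscript $CLI detect --input contacts.csv --out layers.json
Rscript $CLI urn --costs 4,3,2,1 --mu 0.5 --L 150 --out alloc.json
Rscript $CLI sim --width 20 --height 20 --bias 0.2,0.6,0.2 --beta 1 \
                 --seeds 20 --reps 50 --seed 7 --out runs.csv
```

See `vignettes/layered-networks.Rmd` for the model details, parameter
conventions and design decisions.
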
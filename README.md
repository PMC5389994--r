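# beefield

Bee photoreceptor responses to multispectral floral images.

## The problem

Bees see with three photoreceptor classes — S (UV, λmax ≈ 344 nm),
M (blue, ≈ 436 nm) and L (green, ≈ 544 nm) — yet they use the
long-wavelength channel almost exclusively for edge detection, motion
vision and low-resolution target detection. A candidate adaptive
explanation is signal reliability: within a natural object such as a
petal or a leaf, per-pixel L-receptor responses vary least relative to
their mean, so segmenting a scene into objects is easiest in that
channel. `beefield` is for visual ecologists and sensory biologists who
want to quantify that claim on seven-band multispectral image stacks
(340–700 nm) of flowers — or on fully synthetic scenes with known ground
truth when no image database is at hand.

## The model

Each receptor's quantum catch for a stimulus reflectance $I_s(\lambda)$
under illuminant $D(\lambda)$ is

$$P = R \sum_\lambda I_s(\lambda)\,S(\lambda)\,D(\lambda),
\qquad
R = 1 \Big/ \sum_\lambda I_B(\lambda)\,S(\lambda)\,D(\lambda),$$

where $S(\lambda)$ is the receptor sensitivity and $I_B(\lambda)$ the
adaptation background (von Kries adaptation: the background always
yields $P = 1$). The dimensionless response is the hyperbolic transform

$$E = \frac{P}{P + 1} \in [0, 1),$$

half-maximal at the background. Per image region, the package reports
the response to the region's mean spectrum, the per-pixel response
moments, and the signal-to-noise ratio SNR = mean(E) / SD(E) — a
within-object homogeneity measure. A Monte-Carlo factor sweep
(`factor_table()`) switches illumination, background, sensitivity shape
and reflectance source between "unit" and realistic settings to show
which ingredients produce the L channel's advantage.

Default sensitivities are built from the Govardovskii A1 pigment
template plus a UV beta band; measured curves can be supplied as CSV.
The image pipeline covers manifest-driven stack I/O, gray-reference
white balance, integer band alignment by normalized cross-correlation,
region sampling, false-color and heat-map rendering, and
ommatidium-scale downsampling.

## Worked example

Generate six synthetic flower species, run the full pipeline (white
balance, band alignment, 1000 sampled pixels per region, receptor
responses under a shared average-leaf adaptation), and aggregate:

```r
library(beefield)
set <- generate_species_set(6, seed = 42)
res <- analyze_scenes(set, n = 1000, seed = 1)
print(res$summary, digits = 3)
#>   region_class receptor mean_E sd_E_across snr_mean snr_sd n_species n_infinite
#> 1       center        L  0.476      0.0197    10.27  0.949         6          0
#> 2       center        M  0.462      0.0322     5.77  1.006         6          0
#> 3       center        S  0.388      0.0790     1.87  0.492         6          0
#> 4         leaf        L  0.497      0.0130    13.38  1.495         6          0
#> 5         leaf        M  0.492      0.0223     8.22  1.247         6          0
#> 6         leaf        S  0.444      0.0743     2.68  0.812         6          0
#> 7        petal        L  0.658      0.0322    85.47 16.403         6          0
#> 8        petal        M  0.669      0.0877    61.60 22.124         6          0
#> 9        petal        S  0.686      0.2501    42.89 21.337         6          0
```

Reading the table: `mean_E` is the across-species mean per-pixel
response (leaves sit near the adaptation fixed point of 0.5; petals are
brighter, around 0.66–0.69 in all channels), and `snr_mean` is the
across-species mean within-region SNR. In every region class the L
channel has the highest SNR — the reliability ordering the package
exists to study — and petal SNRs are several-fold above leaves and
centers. Channel differences are tested per region class:

```r
cmp <- compare_channels(res$stats, "leaf")
cat(sprintf("Kruskal-Wallis H = %.2f (p = %.2g)\n",
            cmp$kruskal$statistic, cmp$kruskal$p))
#> Kruskal-Wallis H = 15.16 (p = 0.00051)
print(cmp$pairwise, digits = 3)
#>   pair V      p
#> 1  S-M 0 0.0313
#> 2  S-L 0 0.0313
#> 3  M-L 0 0.0313
```

(With only six species the paired signed-rank test bottoms out at
p = 1/2^5; the test suite runs 30 species.)

See `vignettes/bee-receptor-responses.Rmd` for the model's assumptions,
parameter defaults and their rationale, and known limitations.

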
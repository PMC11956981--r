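# deltamarch

Counterfactual latent-space traversal and Delta-Map analysis for histology
patches.

## The problem

Deep networks grade clear cell renal cell carcinoma (ccRCC) from H&E patches
about as well as pathologists, but a grade label alone does not say *which*
tissue structures drive the call. `deltamarch` implements an interpretable
pipeline that answers that question with counterfactual images: starting from
a real patch it walks the semantic latent code of a generative backend along
the axis separating tumour grades — holding the stochastic state (nucleus and
vessel positions) fixed — and then asks, structure by structure, what changed.

The package is aimed at computational-pathology researchers who want the full
chain testable on a desk: it ships a synthetic H&E-like patch generator with
ground-truth masks in which a continuous grade parameter controls tumour
nucleus size, nucleoli per tumour nucleus and vasculature density (non-tumour
nuclei are grade-invariant), plus an analytic backend whose encoder/decoder
round trip is bit-exact, so every downstream stage has an oracle.

## The method

1. **Traversal.** Semantic codes are standardized per dimension; a 4-class
   linear model (ridge multinomial) gives one weight vector per grade. To
   push a patch towards grade *t* the standardized code is shifted repeatedly
   by `step_scale * sqrt(d)` along `w_t / ||w_t||`, decoding with the fixed
   stochastic state after each shift, until an image-level grade predictor
   says *t* or 4 shifts have been spent. 20 strictly interior nodes are then
   interpolated linearly between the endpoints and decoded with the same
   state.
2. **Delta-Maps.** For an image pair, intermediate feature maps of a small
   convolutional filter are subtracted per channel, bilinearly upscaled to
   image size, taken in absolute value and averaged over channels; the map is
   min–max normalized and binarized at 0.5.
3. **Enrichment.** Endpoint segmentation masks are merged by per-pixel
   maximum, ghost nuclei (components present in only one endpoint) removed,
   and nucleus/vessel conflicts resolved by a fair seeded coin into a
   composite map (3 = tumour nuclei, 2 = non-tumour nuclei, 1 = vasculature,
   0 = other). Per component *i*,

   `J_i = |B ∩ M_i| / |B ∪ M_i|`

   compares the binary Delta-Map `B` with the component mask `M_i`; each
   patch's `J_true` is divided by `J_rand` against a random same-transition
   patch, and the median ratio plus a one-sided paired t-test quantify
   enrichment.
4. **Phenotypes.** Per patch: mean nuclear area by type (8-connected
   components), nucleoli as prominent hematoxylin peaks (HED deconvolution,
   Gaussian sigma 1, prominence 0.08, subtract-one correction), and percent
   vasculature coverage.
5. **Power analysis.** Repeated one-sided sign tests compare a per-patch
   feature between grades under three sampling strategies — Real-Unpair
   (random patches per grade), Syn-Pair (both grades from the same
   trajectory) and Syn-Unpair (independent trajectories) — summarized as the
   mean log p-value over 1,000 repetitions.

## Worked example

```r
library(deltamarch)

cohort  <- make_cohort(n_per_grade = 25, seed = 1)
backend <- analytic_backend()
codes   <- encode_cohort(backend, cohort$patches)
model   <- fit_latent_class_model(codes, cohort$metadata$grade)
#> latent class model: 100 samples, 6 dims, training accuracy 0.830

predictor <- morphometric_grade_predictor()
start <- cohort$patches[[which(cohort$metadata$grade == 1)[1]]]
traj  <- traverse_grade(backend, backend$encode(start$params),
                        start$params$seed, model, predictor, target_grade = 4)
traj
#> <dm_trajectory -> grade 4  3 shifts (terminal_grade)  22 nodes
#>   grades: 1 1 1 2 2 2 2 2 2 3 3 3 3 3 3 4 4 4 4 4 4 4>
```

Three latent shifts took this grade-1 patch to a decoded image the predictor
calls grade 4; the 20 interior nodes pass through grades 2 and 3. Marching
the trajectory gives one Delta-Map per grade sub-transition, and the Jaccard
profile against the ground-truth composite shows the change concentrating on
tumour nuclei:

```r
maps <- march(traj, default_filter_net(), depth = 4)
a <- traj$nodes$patch[[attr(maps[[1]], "from_node")]]
b <- traj$nodes$patch[[attr(maps[[1]], "to_node")]]
round(jaccard_components(maps[[1]]$binary,
                         composite_from_patches(a, b, seed = 2)), 3)
#>   J_0   J_1   J_2   J_3
#> 0.060 0.088 0.032 0.309
```

`J_3` (tumour nuclei) dominates: the binarized map overlaps tumour nuclei
five times better than any other component, which is exactly the grading
rule planted in the generator. `run_full_experiment(experiment_config())`
executes the whole study (cohort, traversals, within-grade controls,
enrichment, phenotypes, power analysis) into a report directory of CSVs,
byte-reproducible from the single config seed. A thin CLI wrapper lives at
`inst/scripts/deltamarch.R`.

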
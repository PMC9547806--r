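---
title: "Models and methods in clusterlab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in clusterlab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clusterlab)
```

## The scientific problem

In anti-AChR myasthenia gravis, autoantibodies attack the nicotinic
acetylcholine receptor of the neuromuscular junction, a pentamer of
subunits in the stoichiometry α~2~βδε. A single bivalent IgG binding a
non-α subunit can bridge at most two receptors (each receptor offers one
copy of its epitope), an anti-α antibody can string receptors into linear
chains (two α epitopes per receptor), and only *combinations* of
antibodies with different subunit specificities can weave receptors into
extended two-dimensional lattices. Lattice formation matters because
complement activation needs stable multivalent antigen–antibody platforms:
experimentally, single monoclonal anti-AChR antibodies are poor complement
activators and poorly pathogenic, while mixed-specificity pairs at the
same total dose activate complement strongly, deplete junctional receptor,
fragment the junction, and cause disease in passive-transfer animals.

`clusterlab` packages the quantitative machinery behind that line of
reasoning so it can be exercised, tested, and extended without wet-lab
material:

1. a stochastic crosslinking simulator that turns subunit specificity and
   dose into aggregate-size distributions (`simulate_binding`,
   `component_stats`, `complement_proxy`, `sweep_combinations`);
2. synthetic-data generators with exact ground truth for every downstream
   readout (`synth_cluster_timelapse`, `synth_nmj_image`,
   `synth_flow_events`, `synth_calcium_traces`, `render_simulated_field`);
3. the image-quantification pipelines: Rényi-entropy auto-thresholding,
   size-filtered cluster extraction and growth-rate slopes
   (`renyi_threshold`, `segment_clusters`, `quantify_stack`), and junction
   morphometry (`delineate_nmj`, `achr_content`, `c3_at_nmj`,
   `fragmentation_analysis`);
4. assay statistics: geometric-mean fluorescence-intensity (GMFI) ratios,
   four-parameter logistic EC50 fits, combination synergy indices,
   calcium-trace peak normalization, and a permutation test for Spearman
   correlation.

## The crosslinking model

Receptors are multi-epitope particles; the default stoichiometry is the
AChR pentamer (`achr_stoichiometry()`: α = 2, β = δ = ε = 1). Antibodies
are bivalent and monospecific. Binding is random sequential attachment
with two rate constants and no unbinding:

* **first-arm attachment** — a solution antibody binds a uniformly chosen
  free epitope of its target subunit, with propensity `k_on` per
  antibody–epitope pair;
* **second-arm crosslink** — a singly bound antibody binds a free
  compatible epitope on a *different* receptor, with propensity `k_cross`
  per pair, creating an edge between the two receptors.

The simulation runs until no event is possible (or `max_events` is
reached) and is deterministic given its seed. Because there is no
unbinding, only the ratio `k_cross / k_on` matters for the final graph;
both default to 1, the simplest scheme that reproduces all three
qualitative regimes. Aggregates are the connected components of the
receptor projection of the bipartite receptor–antibody graph.

Two structural laws follow from stoichiometry alone and are enforced as
exact tests across seeds and parameters: one non-α species can only
dimerize (`max component = 2`), and one anti-α species produces receptor
degrees of at most two, i.e. paths and cycles.

**Intra-receptor binding.** Whether one IgG can bridge the two α epitopes
of a single receptor is not known; the conceptual chain model requires
inter-receptor bridging, so `allow_intra_receptor = FALSE` is the default
and a flag exposes the alternative.

**Cycles.** Chains may close into rings; nothing in the model forbids it,
so `allow_cycles = TRUE` is the default and the structural tests assert
degree bounds rather than acyclicity.

**Dose ("saturating antibody").** The synergy conditions use
`count_total = 2 × n_receptors` molecules per condition — for every
species at least one molecule per target epitope. The dose sits in the
antibody-excess regime on purpose. At low dose few antibodies bridge
anything; at one molecule per receptor a *single* anti-α species can
saturate its 2n epitopes with n bivalent antibodies and weld most of the
pool into giant chains and rings, which is not what live-cell imaging of
single antibodies shows. In excess, free antibody caps epitopes faster
than singly bound antibody can cross-link them (the classical prozone /
dose self-inhibition effect), so single species stay in the dimer or
short-chain regime — while a mixed-subunit pair, with more epitope classes
per receptor, still assembles large branched aggregates. Combinations are
always compared at matched total count, each constituent at half, exactly
as combination assays are run at matched total concentration. Mapping
molecule counts to ng/ml is out of scope.

**Complement proxy.** No quantitative mapping from aggregate size to C3
deposition exists; `complement_proxy(stats, s_min = 4)` — the fraction of
receptors in aggregates of at least `s_min` — is a deliberately monotone
stand-in validated only against the qualitative combination pattern
(different-subunit pairs ≫ singles and same-subunit pairs). `s_min = 4`
is the smallest size clearly beyond anything a single non-α species can
build and the smallest platform with two antibodies fully engaged inside
it.

**Exact small-system oracle.** `enumerate_binding_outcomes()` enumerates
every possible event sequence with its exact probability for systems of a
few receptors and antibodies. The test suite verifies that the stochastic
simulator's outcome distribution matches this enumeration (chi-squared,
α = 0.01), with per-run seeds drawn from a master RNG stream: consecutive
integer seeds leave the first Mersenne–Twister draws correlated across
runs, which visibly biases ensembles of simulations that each consume
only a handful of random numbers.

**Geometric mode** assigns receptors positions on a plane and restricts
second arms to a capture radius (default 15 nm — the span over which a
bivalent IgG can engage two antigens, comparable to inter-receptor
spacing at synaptic densities). At the default rendering density of
1000 receptors/µm² the mean spacing (~32 nm) exceeds that reach, so
geometric percolation is sparse; the mode exists for rendering and
spatial experiments, and all headline statistics use the well-mixed mode.

## Synthetic data and what it does (not) emulate

All generators are seed-deterministic, record exactly what they planted,
and draw their geometry before their noise so the planted truth is
identical between noisy and noise-free renders of the same seed.

* `synth_cluster_timelapse()` emulates live-cell imaging of labelled
  surface receptor at three frames per minute (20 s interval): diffuse
  membrane signal before antibody addition, then disk-shaped clusters
  whose count and mean area grow linearly at planted rates, sized within
  the 0.8–10 µm² window used downstream. Optics default to a 40×-class
  configuration (0.16 µm pixels, 0.2 µm PSF σ); noise is Poisson shot
  noise plus Gaussian read noise, the standard fluorescence camera model.
  Clusters are placed without overlap and are not tracked between frames
  (the analysis quantifies per-frame populations, not trajectories).
* `synth_nmj_image()` renders a pretzel-shaped junction in three
  co-registered channels: presynaptic marker (SV2A analogue), receptor
  label (α-BTX analogue) concentrated into exactly `n_fragments` disjoint
  blobs, and a complement channel. *Retention* is defined as receptor
  content: total BTX signal inside the junction equals
  `achr_retention ×` the SV2A content, however fragmented — so the
  mask-mean BTX/SV2A ratio recovers the planted retention exactly on
  noise-free renders at any fragment count. NMJ channels are rendered
  without PSF blur; blur would smear mask edges and turn exact recoveries
  into approximate ones without changing what the morphometry measures.
* `synth_flow_events()` draws two log-normal populations (transfected /
  untransfected) with planted geometric-mean ratios in the readout
  channels; `synth_calcium_traces()` adds an exponentially decaying
  transient of known amplitude at the stimulus frame.

None of this emulates real cell morphology, photobleaching, spectral
bleed-through, 3-D PSFs, or receptor diffusion. Passing tests therefore
demonstrate that the *algorithms* are correct and calibrated on data whose
generative model is known — not that the pipeline is robust to every
artefact of real microscopy.

## Thresholding and cluster quantification

Thresholds are chosen on a 256-bin histogram of the frame (higher-depth
images are rescaled to 256 levels for selection, and the chosen bin is
mapped back to a native-intensity cutoff; for integer images the cutoff is
an integer, making selection exactly covariant under integer intensity
shifts). The criterion maximizes the sum of the order-ρ Rényi entropies of
the background and foreground class distributions. The default
`sahoo_combined` method computes the optimal threshold at ρ = 0.5, 1
(the Shannon/Kapur maximum-entropy split) and 2 and combines the three
with the published weighting rule, matching the behaviour of the
widely-used ImageJ-style implementation; `single_order` exposes the plain
maximizer, which the suite verifies against an exhaustive search over all
255 candidate splits. Ties break toward the lower threshold; constant
frames yield an empty foreground rather than an error, so blank fields
segment to zero clusters.

Segmentation is ImageJ-flavoured: 8-connected components of the
foreground, with component areas converted through the pixel size and
filtered to the 0.8–10.0 µm² cluster window (both bounds configurable).
Z-stacks are reduced by maximum-intensity projection before analysis.
Background reduction, when enabled, subtracts a grayscale-opening
(rolling-ball-style) background estimate with a configurable disc radius
(default 50 px). Thresholds are computed per frame by default — each image
gets its own level — with a switch for one fixed series-wide threshold.

Growth rates are ordinary-least-squares slopes of cluster count, mean
area and total area against time over the post-addition segment, with
pre-addition slopes reported alongside as a no-antibody baseline (the
pre slope is reported, not subtracted). On synthetic time-lapses at the
default signal-to-noise (cluster amplitude 600 over a diffuse level of 60
on background 100), detection recall and precision exceed 0.9 and the
planted count slope is recovered within 10 %.

## Junction morphometry

`delineate_nmj()` reuses the entropy threshold on the presynaptic
channel, applies morphological closing (disc radius 3 px by default) and
keeps 8-connected regions of at least 20 µm². `achr_content()` computes
the per-junction ratio of mask-mean receptor signal to mask-mean
presynaptic signal — means, not sums, so the ratio is independent of mask
area and invariant under common intensity scaling — after subtracting each
channel's background (median intensity outside all masks; disableable).
`c3_at_nmj()` reports mean (not integrated) complement intensity per
junction, with a flag-free mean convention chosen because it is
insensitive to junction size. `fragmentation_analysis()` follows the
structural workflow: maximum projection, optional background reduction,
entropy threshold, 8-connected object counting with areas and mean
fluorescence. `summarize_per_animal()` collapses junction records to
per-animal means, the unit for group statistics (standard group tests —
ANOVA, Kruskal–Wallis and their post-hoc procedures — are left to base R).

## Assay statistics

* **GMFI ratio** — geometric mean `exp(mean(log x))` of the measured
  channel over a rectangular positive gate divided by that over a negative
  gate. Non-positive events (possible in compensated flow exports) are
  excluded from the log and counted; gates default to a split at the
  99.5th percentile of an untransfected control's GFP. An arithmetic-mean
  variant is available by flag.
* **EC50** — four-parameter logistic
  `R(c) = bottom + (top − bottom) / (1 + (EC50/c)^h)`, fitted by
  Levenberg–Marquardt least squares in log-concentration space with
  multiple Hill-slope starts (0.5, 1, 2). Flat responses raise an
  explicit fit-failure rather than returning a meaningless EC50. Noiseless
  self-generated curves are recovered to relative error below 1e−4; under
  5 % multiplicative noise with triplicate measurements at 11
  concentrations (the bench design for such assays) the mean EC50 error
  across 20 simulated experiments stays below 10 %.
* **Synergy index** — combination response divided by the best
  constituent single at matched total concentration; `synergy_matrix()`
  assembles the symmetric single/pair panel with fold enhancements.
* **Permutation Spearman** — ρ on mid-ranks; the two-tailed p-value comes
  from the permutation distribution of |ρ|, by complete enumeration
  (exact, identity included) whenever `n! ≤ n_perm` and otherwise by
  Monte Carlo with the `(1 + hits) / (1 + B)` correction, which keeps null
  p-values valid (super-uniform). Default budget 10,000 permutations.

## Orchestration and reproducibility

One global seed expands to per-stage seeds by a documented counter scheme
(`stage_seed(seed, k) = (1000·seed + k) mod 2^31`), so stages can be
re-run independently. `generate_fixture_suite()` writes the documented
synthetic datasets (time-lapses at three signal levels, junctions at
fragment counts 1/2/4/8, flow tables at ratios 1/2/5/10, traces, a
simulator sweep) with ground-truth sidecars; identical seeds give
byte-identical files. Image stacks travel as multi-page TIFF plus a JSON
metadata sidecar carrying pixel size, channel names and frame times, and
round-trip bit-identically.

`run_end_to_end()` is the demonstration pipeline: for each antibody
condition it simulates progressive crosslinking (the event budget growing
frame by frame under one seed, so later frames extend earlier ones), lays
the receptors out on a sparse 20 µm visual field, renders pre- and
post-addition frames (aggregate members condensed at their component
centroid with 0.35 µm jitter), quantifies every frame with the cluster
pipeline, and tabulates growth-rate slopes per condition next to the
simulator's aggregate-size sweep. The demo dose is 4 molecules per
receptor — deep enough into the excess regime that single species produce
no cluster growth, as in live-cell experiments, while the mixed pair does.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at deliberately moderate
sizes chosen as adequate for their statistical purpose: 192² px
time-lapses of 30 frames over 10 seeds, 160² px junctions over 100 noise
seeds, 200 receptors × 50 seeds × all single/pair conditions for the
synergy laws, 4000 simulations per small-system enumeration check, 10,000
flow events, and 1000 null draws × 499 permutations for test calibration.
Ties in threshold selection break low; empty cluster sets yield
`mean_area = NaN` (not 0); degenerate histograms raise errors at the
`renyi_threshold()` level but blank frames are valid, clusterless input
end to end.

## Known limitations

The kinetic scheme has no unbinding and no receptor diffusion, so
aggregate sizes are end states of irreversible attachment, not
steady-state cluster dynamics; the complement proxy is ordinal, not
calibrated to C3 deposition; geometric mode treats positions as frozen;
the image model plants disks, not the irregular morphology of real
clusters; and FCS parsing is intentionally out of scope (event tables are
CSV). Within those bounds, every number the package reports is covered by
a test against planted truth or an independent oracle.
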
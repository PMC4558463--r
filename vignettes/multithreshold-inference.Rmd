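---
title: "Threshold-robust inference for streamline-count connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-robust inference for streamline-count connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtpconn)
```

## The problem

Structural brain networks inferred from tractography are weighted
graphs: nodes are atlas regions, edges carry streamline counts, and
analysis proceeds on proportion weights `W = C / total`. Two error
processes undermine inference on such networks. False-positive (FP)
streamlines — trajectories that connect regions with no true fibre, or
inflate a true connection — shift every common topological metric, in
directions that depend on where they land. Count thresholding (remove
every edge with τ or fewer streamlines, renormalise) suppresses FPs but
introduces its own τ-dependent bias, and no τ is correct a priori
because the FP rate is unknown. The practical consequence is that a
group comparison of a network metric can be significant in one
threshold window and absent in another.

`mtpconn` provides the machinery to study this instability and to draw
inferences that are robust to it: weighted metrics swept across τ,
simulators of the error processes, an instability statistic for
statistic-versus-threshold curves, and the multi-threshold permutation
correction (MTPC) with its comparator, the per-subject AUC method.

## Metrics and their numerical conventions

All metrics operate on the proportion-weight matrix of the (possibly
thresholded) network, following Brain Connectivity Toolbox conventions:

- **Shortest paths** use edge lengths `1/w`; strong connections are
  short. Distances come from a dense Floyd–Warshall pass (compiled;
  exact, no tie-breaking needed since only distances and path counts
  enter the metrics).
- **Global efficiency** is the mean of `1/d(i,j)` over ordered node
  pairs, with disconnected pairs contributing 0. It is therefore
  defined, and informative, on fragmented networks — essential here,
  because thresholding fragments networks by design.
- **Characteristic path length** averages only finite distances.
- **Mean clustering** is the Onnela geometric-mean-of-triangle-weights
  form on weights rescaled by the global maximum; nodes of degree < 2
  contribute 0. The verbal "ratio of triangle weights to edges"
  definition common in the literature does not pin down a single
  formula; the toolbox default is used.
- **Mean betweenness** is unnormalised (the rank-based group tests used
  downstream are invariant to that choice), with tied shortest paths
  sharing credit proportionally (igraph's Brandes implementation).
- **Smallworldness** is `(C/C_rand)/(L/L_rand)` with the null ensemble
  preserving the node count, edge count and weight multiset, edges
  re-placed uniformly at random; ensemble means over `n_null = 20`
  seeded draws by default. The value is masked (`NA`) rather than
  forced when a normaliser is zero or the graph is empty — at high τ
  this happens routinely, and the statistics layer drops masked
  subjects per threshold instead of propagating errors.

Thresholding is inclusive (`count ≤ τ` removed) on the integer grid
τ = 0, 1, 2, …, and weights are always renormalised to the surviving
total, so the analysed object at every τ is again a proportion-weighted
network. Renormalising to the pre-threshold total would be the other
defensible reading; the surviving-total convention is used because the
stated purpose of the normalisation is to compensate for changes in
network density, which the post-threshold total tracks.

## Error-process simulators

- **FP-NE** adds `k` new edges of one streamline each, sampled without
  replacement from a candidate set with probability proportional to
  candidate streamline counts (uniqueness of each new edge is part of
  the definition; edge count and streamline count both rise by `k`).
- **FP-EE** adds `k` streamlines one at a time, with replacement, to
  existing candidate edges (edge set unchanged). Whether the original
  procedure sampled with or without replacement is not documented;
  with-replacement is chosen so a dominant candidate can absorb
  several hits.
- **Displacement** moves an edge's full count to a vacant adjacent
  pair; adjacency defaults to sharing a node, standing in for
  volumetric bundle-overlap tables, which can be supplied as a
  function. Edge and streamline totals are conserved.
- **Atrophy** thins each masked edge by a removal proportion
  `p = min(|N(0, ξ²)|, 1)`, resampling the count as
  `Binomial(C, 1 − p)` so counts stay integral. The default mask is
  interhemispheric (hemisphere tags differ), the connections implicated
  in callosal atrophy; the mean removed fraction is `ξ·√(2/π)`
  (≈ 0.1995 at ξ = 0.25).

## The instability statistic

For a statistic curve `S(τ)` on a unit-spaced grid,

σ̇ = sqrt( Σ ½ (S_τ − S_{τ+1})² / (n − 1) ).

Unlike an ordinary standard deviation it accumulates only
adjacent-threshold deviations: networks at neighbouring thresholds are
nearly the same data, so a trustworthy statistic should move smoothly
along τ, and σ̇ measures departures from that. It is zero exactly on
constant curves, translation-invariant, absolutely homogeneous, and
equals `|s|/√2` on a line of slope `s`. An equivalent description as
the L2 norm of the curve's derivative differs by a constant factor;
the averaged, ½-weighted form above is the implemented definition, and
since the statistic is only ever compared between metrics computed on
the same grid, the constant is immaterial.

## MTPC

Given a subjects × thresholds metric table and two groups:

1. compute the observed statistic curve `S(τ)` (Mann–Whitney U of
   group 1 with midrank ties, or pooled-variance t);
2. permute group labels `n_rand` times, applying the *same*
   permutation at every τ, which preserves the strong inter-threshold
   dependence in the null ensemble;
3. reduce each permutation to its most extreme statistic across τ (and
   across nodes, for node-level tables);
4. take `S_crit` as the upper-α quantile (type-7, linear interpolation,
   hence bit-reproducible) of that max-statistic null;
5. find maximal runs of consecutive τ where the observed curve is
   beyond `S_crit`, each measured by the trapezoidal area of its
   exceedance `|S − S_crit|`;
6. compute `A_crit` as the mean largest super-critical area over the
   permutations that have one;
7. reject iff a super-critical cluster exists and `A_MTPC > A_crit`.

Directionality: "more extreme" is two-sided by default, via the centred
absolute deviation `|U − n₁n₂/2|` for U and `|t|` for t; one-sided
modes are available. The cluster criterion is what distinguishes MTPC
from a plain max-statistic correction: a single-τ spike — the signature
of threshold instability rather than of a genuine effect — forms a
cluster of zero trapezoidal area and cannot reject (unless no
permutation shows any super-critical cluster at all, or the optional
half-unit widening of single-point clusters is switched on). `A_crit`
averages only over permutations that actually produced a
super-critical cluster — it estimates the typical size of clusters
that arise from noise, given that one arose; a switch allows
zero-inclusive averaging over all permutations, which is more
conservative.

Missing metric values (masked smallworldness on fragmented networks)
drop that subject at that τ only; a τ column is skipped when either
group falls below two usable subjects, and the skip is recorded on the
curve object.

The **AUC method** is the established comparator: each subject's curve
is collapsed to its trapezoidal area, one group test follows, and the
same permutation machinery calibrates it. Because non-informative
thresholds enter every subject's area, an effect confined to a narrow
τ window is diluted — the failure mode MTPC avoids by testing each
threshold and aggregating only super-critical evidence.
**`min_detectable_effect()`** interpolates where a statistic first
crosses its critical value along an effect-size grid, giving the
minimum detectable atrophy ξ*.

## The synthetic study conditions

No tractography data ships with the package; a generator produces
connectomes with the structural features the methods interact with.
Two presets mirror the two kinds of dataset the simulation experiments
need:

- **`model_network_spec()`** — a pruned, manually segmented
  single-subject model: a U-fibre lattice (each covered region linked
  to its two nearest neighbours on either side) over 70% of each
  hemisphere, four association bundles connecting distant region sets
  all-to-all, callosal edges restricted to left–right homologues, the
  right hemisphere an exact mirror of the left, and the remaining
  regions isolated, as atlas regions untouched by any retained bundle
  are. Counts are heavy-tailed (negative binomial, size 1.5) with mean
  30 for bundles and callosal edges and 5 for U-fibres, so the τ grid
  removes real edge mass at every level.
- **`synthetic_spec()`** (the default) — the whole-brain cohort regime:
  same architecture, but callosal homologue edges at mean count 90,
  dominant as they are in unpruned whole-brain tractography, and U-fibres
  at mean 8.

The FP superset (raw streamlines before pruning) is the truth plus a
geometric-count scatter on 15% of vacant pairs, and overcounting of
existing edges concentrated on weakly supported (≤ median count)
connections, where streamline assignment is least certain. Cohorts
resample each subject's counts as negative-binomial noise around the
truth (dispersion 0.05, i.e. an edge-count coefficient of variation
near 28%) plus a small per-subject FP admixture drawn from the
superset pools; atrophied cohorts split at random and thin the
interhemispheric edges of one half.

These choices were calibrated, once, so that the synthetic conditions
reproduce the qualitative phenomenology the methods are built around:
default-spec networks are small-world (smallworldness > 1 across
seeds); network metrics are more unstable (higher σ̇) than the
streamline-count control under random group splits; FP-NE injection
raises global efficiency (bridging previously unconnected regions)
while lowering clustering and smallworldness, and FP-EE injection
raises clustering; within-threshold FP effects shrink as τ grows while
thresholding bias keeps the network far from its unthresholded state;
and MTPC detects ξ = 0.25 interhemispheric atrophy in 2 × 40 subjects
with high power, placing the minimum detectable atrophy in the
ξ ≈ 0.1–0.2 range that a well-powered cohort study exhibits.

### What the generator does not capture

Desk-scale (40-node) networks compress topological distances relative
to a 116-region atlas, and two consequences are worth stating plainly,
because the test suite documents them rather than hiding them:

- **Mean betweenness under FP-NE rises** in the synthetic model,
  whereas on a large sparse model network it falls. At full scale a
  one-streamline FP edge acts as a shortcut that beats long, weak,
  multi-hop paths, collapsing the betweenness of their interior nodes;
  at 40 nodes essentially no path is long enough for a count-1 edge
  (whose 1/w length equals the whole network's streamline total) to
  beat, and the dominant effect is component bridging, which adds
  shortest paths through anchor nodes. The corresponding acceptance
  check asserts the full-scale direction and is expected to fail on
  the synthetic model; the mechanism, not the sign, is the
  transferable content.
- **FP-EE effects on global efficiency and smallworldness are near
  zero** at desk scale (the dilution-versus-local-gain balance that
  sets their sign is a knife edge), where full-scale data shows small
  negative biases.

Other aspects of real data the generator ignores: anatomical bundle
geometry (adjacency for displacement is topological), subject-level
covariates, scanner and motion artefacts, and any spatial correlation
in FP placement beyond the superset's weighting.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | upper-tail mass of the max-statistic null defining `S_crit` |
| `n_rand` | 1000 (`mtpc_config`); 200 in the canned desk-scale experiments | label permutations; 500–1000 is a sensible initial choice, more when a statistic sits near its critical value |
| `taus` | `0:30` (`mtpc_config`) | threshold grid; MTPC does not dilute with a wider grid, so err on the wide side |
| `direction` | `two_sided` | extremity convention; one-sided modes for directional hypotheses |
| `n_null` | 20 | random networks behind each smallworldness value |
| `xi` | grid `0–0.3` in the experiments | half-normal scale of atrophy removal proportions |

Problem sizes used by the packaged experiments and tests — 40-node
networks, cohorts of 60–80 subjects, 200 permutations, 50–200
replicates — are the package's desk-scale defaults; `n_nodes = 116`
presets and full-scale randomisation counts are one argument away in
`experiment_config()` / `run-experiment.R --full-scale`.

## Degenerate inputs and edge cases

- All-zero count matrices are valid connectomes flagged `empty`;
  normalisation returns a zero matrix rather than dividing by zero.
- Asymmetric matrices are symmetrised as `max(C, Cᵀ)` with a warning —
  streamline tallies are symmetric by construction, so asymmetry
  signals upstream bookkeeping errors, not direction.
- A degenerate (constant) max-statistic null yields `S_crit` equal to
  the common value, with a warning.
- Zero-variance perturbation summaries report an infinite z rather
  than erroring; a zero-variance t column in a permutation ensemble is
  masked.
- `sigma_dot` on a curve with skipped thresholds uses consecutive
  non-missing entries.

## Limitations

MTPC corrects for multiplicity across thresholds (and nodes), not for
multiple metrics tested side by side. It assumes the two groups respond
comparably to thresholding itself; when group densities differ
strongly, density-matched thresholding may be preferable to a uniform
count cutoff. False negatives are outside the model entirely: a
threshold sweep can only remove, never restore, and the package's
simulators inject FPs but do not delete true edges except through
atrophy. Finally, the synthetic generator is a study-conditions
machine, not an anatomical model; conclusions about real data follow
from the method's calibration properties (family-wise error control is
guaranteed by the max-statistic construction regardless of the data's
dependence structure), not from resemblance between the generator and
any particular cohort.
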
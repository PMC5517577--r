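---
title: "Unsupervised sleep staging from dynamic BOLD connectivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised sleep staging from dynamic BOLD connectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Resting-state fMRI subjects drift in and out of sleep, and the drift shapes
dynamic functional connectivity. `sleepstates` implements an unsupervised
procedure that recovers wakefulness and sleep states directly from the BOLD
data: whole-brain correlation matrices are computed in short time windows,
pooled across subjects, clustered into a small number of *dynamic
connectivity states* with k-means under correlation distance, and the states
are then matched to sleep stages (W, N1, N2, N3, optionally REM) using
fMRI-only criteria. Against hypnogram ground truth the match is scored as the
fraction of correctly staged volumes. The package also characterizes the
stage-wise networks: signed weighted modularity, node strength,
structure–function coupling, and FDR-corrected edgewise contrasts.

Because raw EEG-fMRI sleep cohorts are not openly available, the package
ships a synthetic-data generator that emulates the statistical structure such
cohorts exhibit, and every claim the test suite makes is computed on those
synthetic cohorts. This vignette records the model, the tunable parameters,
the numerical choices, and the design decisions that were genuinely open.

## The staging pipeline

1. **Windowing.** A session of `T` volumes is cut into windows of
   `length` volumes (default 50, i.e. 104 s at TR = 2.08 s), advanced by
   `step` volumes. `step = length` gives non-overlapping windows (the default;
   it avoids serial correlation between windows), `step = 1` gives sliding
   windows, used for short scans where non-overlapping windows would starve
   the clustering of data. Windows are half-open volume ranges
   `[start, start + length)`; the trailing partial window is discarded, and
   the leftover volumes are excluded from accuracy denominators (a documented
   choice; with 1505-volume sessions and length 50 this drops 5 volumes).

2. **Connectivity.** Pearson correlation between every pair of region
   time series within the window, yielding an `R x R` matrix per window. The
   upper triangle (row-major above the diagonal, length `R(R-1)/2`) is the
   clustering vector. A zero-variance region within a window would make the
   correlation undefined; it is set to 0 with a warning rather than aborting
   a cohort.

3. **Clustering.** k-means with correlation distance
   `d(u, v) = 1 - cor(u, v)`, which groups matrices by pattern regardless of
   overall level. Each vector is standardized to zero mean and unit norm;
   under that normalization squared Euclidean distance equals `2 d`, so Lloyd
   iterations with centroids re-standardized after every update are exact
   k-means in correlation distance. Initialization is k-means++, with (by
   default) 100 independent replicates; the replicate with the lowest total
   within-cluster distance wins. Convergence is declared when assignments
   stop changing, with a 300-iteration cap. An emptied cluster is re-seeded
   from the point farthest from its current centroid. All of this is
   deterministic given the seed.

4. **Matching.** Two fMRI-only criteria map clusters to stages:
   *occurrence profiles* — the probability, per window position across
   subjects, of observing each cluster and each stage; and *matrix
   similarity* — Pearson correlation between the vectorized mean connectivity
   matrices of clusters and stages. In both cases the cluster-to-stage
   bijection maximizing the summed similarity is found by exhaustive
   enumeration of all `k!` bijections (k ≤ 5, so at most 120 candidates; this
   is exact where a greedy assignment can fail). Disagreement between the two
   criteria is reported, not silently resolved. For EEG-free data the
   *wakefulness heuristic* identifies the wake state as the cluster whose
   occurrence probability drops most from the first half to the second half
   of the session.

5. **Scoring.** Every volume inherits the matched stage of its window
   (majority vote over covering windows in sliding mode); accuracy is the
   fraction of volumes whose predicted stage equals the hypnogram stage. The
   chance level is `1/k` because k-means splits the pooled data space into
   approximately even parts regardless of class balance. For `k = 2` the
   ground truth collapses to wake vs sleep (N1/N2/N3/REM all count as sleep).
   A window's ground-truth stage is the majority stage over its volumes,
   ties resolving to the lighter stage (W < N1 < N2 < N3 < REM); each volume
   takes the stage of the 30-s epoch containing its acquisition midpoint.

6. **Validation constructions.** `bootstrap_accuracy()` repeats the whole
   staging (recluster, rematch, rescore) on random subject subsets
   (default 10 subjects, 100 iterations), optionally after permuting each
   subject's window-stage labels — the label-permutation null, whose accuracy
   distribution peaks at `1/k`. Reclustering per subset (rather than reusing
   global clusters) reflects how the validation is described and makes each
   iteration self-contained. The distribution "peak" is the midpoint of the
   fullest bin of a 20-bin histogram on [0, 1] — a deliberately simple,
   seed-stable estimator. `sample_size_curve()` wraps the bootstrap over
   subset sizes; `window_length_sweep()` re-runs the pipeline per window
   length.

## Stage-wise network characterization

Per participant, the windowed correlation matrices are averaged within each
hypnogram stage; the averages are treated as weighted, fully connected,
signed networks (no thresholding, diagonal excluded). Their quality of
decomposition into modules is the signed weighted modularity

$$Q_W = \frac{1}{v^+}\sum_{ij}(w^+_{ij} - e^+_{ij})\,\delta_{M_iM_j}
      - \frac{1}{v^+ + v^-}\sum_{ij}(w^-_{ij} - e^-_{ij})\,\delta_{M_iM_j},$$

where $w^\pm$ are the positive/negative weight magnitudes,
$v^\pm = \sum_{ij} w^\pm_{ij}$, and
$e^\pm_{ij} = \sum_i w^\pm_{ij}\,\sum_j w^\pm_{ij} / v^\pm$ are the
configuration-model null terms. With the double-sum convention used here the
formula reduces to classical Newman weighted modularity for all-positive
networks, a single-module partition scores exactly 0, and two disconnected
equal cliques score 0.5 at the component partition — the latter two serve as
exact anchors in the tests, together with a term-by-term enumeration oracle.

Maximization uses a Louvain scheme written for the signed objective: local
moves with the signed gain (including moves into a fresh singleton community,
which matter when negative weights reward isolating a node), aggregation,
repetition until no gain, and a final flat refinement pass at the original
scale; the best of 100 randomized restarts is kept and the single-module
partition is always a fallback candidate, so reported $Q_W \ge 0$ for
positive networks. On modular signed test networks of ≤ 7 nodes the search
attains the exhaustive-enumeration optimum; on *unstructured* dense random
signed networks a greedy scheme can occasionally stop short of the global
optimum, which is why optimality is asserted on structured networks only.

Structure–function coupling is the Pearson correlation between the vectorized
upper triangles of a stage's mean functional matrix and the structural
matrix, restricted to a common node subset (structural reconstructions
typically lack sub-cortical and cerebellar regions). Node-level structural
networks aggregate to regions by summing all node-to-node weights between two
regions. Stage contrasts are per-edge paired t-tests across participants with
Benjamini–Hochberg FDR at α = 0.05; the paired t-test is our choice (the
analysis it reproduces states only "p < 0.05, FDR corrected"). Edges whose
differences are numerically constant across participants bypass the t-test
(p = 1 if zero, p = 0 otherwise). Block summaries over resting-state-network
labels report both the mean edge difference and the count of significant
edges per block, since either convention is defensible.

## The synthetic cohorts

The generator emulates what the analysis assumes about EEG-fMRI sleep
cohorts; it is first-class, tested code.

**Hypnograms.** Stages follow a time-inhomogeneous first-order Markov chain
at the 30-s epoch scale. The session is split into three equal regimes; in
regime $r$ the transition matrix is $sI + (1-s)\mathbf{1}\pi_r^\top$, whose
stationary distribution is exactly $\pi_r$, so prevalence targets translate
directly into parameters. The dwell parameter $s = 0.85$ gives a mean stage
run of ~3.3 minutes, a plausible scale for drifting NREM sleep. The `sleep`
preset's $\pi_r$ were set (once, analytically, by propagating the chain's
marginals) so that a 52-minute session starting awake yields ~48/23/19/10%
W/N1/N2/N3 — the prevalences reported for sleep-prone resting cohorts — with
wakefulness decaying monotonically, N1 peaking in the middle third and N2/N3
late. The `wake_n1` preset front-loads sleep pressure so the first 7 minutes
already contain ~1/3 N1; the `narcolepsy` preset adds REM; `balanced` is
stationary at equal prevalences (used for network characterization, below).

**Connectivity states.** Each stage has an `R x R` correlation template
composed of a block (modular) pattern scaled by a `modularity_grade`, a
structural template scaled by an `sc_coupling`, and shared-plus-unique
Gaussian perturbations whose mixing weight sets the expected inter-template
correlation:
$T_s = c_s S + (1-c_s)\,(g_s B + \sigma(\sqrt{\rho}Z_0 + \sqrt{1-\rho}Z_s))$.
Templates are projected to the nearest positive semi-definite correlation
matrix (eigenvalue clipping at 1e-10, renormalization to unit diagonal) and
re-verified. `sc_coupling = 1` returns the structural template exactly.
Because $c_s$ multiplies down the block term, the realized modularity of a
template reflects both $g_s$ and $c_s$; the `graded` preset is therefore
validated on the contrasts the analysis actually claims (wake least modular;
N1 lowest, N3 highest structure–function coupling) rather than on a strict
modularity chain within sleep.

The default `two_state` preset plants exactly two connectivity states — one
wake template and one sleep template shared by N1/N2/N3, built on different
module partitions so their vectorized correlation is ~0.2, well under the
0.7 separation bound the validation assumes. This mirrors the two-cluster
validation analysis, where one cluster matches wakefulness and the other the
mixture of NREM stages.

**BOLD signals.** Per volume, a draw from the active stage's template (via
Cholesky), plus isotropic Gaussian noise of standard deviation `noise_sd`
(default 0.5 against unit signal variance — a moderate scanner-noise level;
no published value pins within-stage variability, so this knob is free and
documented). The concatenated series is band-pass filtered 0.01–0.1 Hz with a
6th-order Butterworth applied forward and backward (zero phase, so stage
boundaries are not displaced), per region, as in standard resting-state
preprocessing; filtering is applied to the whole session as in a real
continuous recording. A 52-minute session at TR 2.08 s yields exactly 1500
volumes. Seeding: one master seed; subject i uses `master + i`, and the BOLD
draw a further fixed offset, so cohorts are reproducible and any subject can
be regenerated alone.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: hemodynamic convolution (correlation structure at
these timescales is largely preserved by it, and the analysis consumes only
correlations), head motion, physiological noise, scanner drifts, real
anatomical parcellations (R defaults to 20 here; 116-region analyses work but
are slower), EEG signals, and genuinely overlapping sleep microstructure.
Accuracy numbers on synthetic cohorts are ceilings relative to real data:
the planted states are cleanly separated Gaussians.

## Study-condition problem sizes

The validation analyses run at the cohort sizes the emulated study reports:
58 subjects, 52-minute sessions (1500 volumes), bootstraps of 10 subjects and
100 iterations, short-scan analyses on the first 7 minutes (202 volumes) with
sliding windows at sample sizes 10–50. Regions are reduced to R = 20 so the
whole suite runs on a laptop in minutes; the pipeline is dimension-agnostic
and nothing in the logic depends on R. The network-characterization cohort
uses 24 participants under the `balanced` stage model: with the
non-stationary sleep model, deep-sleep stage means would be averages of many
fewer windows than wake means, and the resulting unequal sampling noise
inflates Louvain modularity unevenly across stages — equalizing window counts
makes per-stage estimates comparable, isolating the planted gradients.

## Numerical choices and degenerate inputs

- Correlations of constant vectors: an error in `correlation_distance`
  (clustering cannot proceed), 0 in the matchers (a constant occurrence
  profile carries no signal), 0 with a warning for flat regions in windows.
- Assignment ties in k-means go to the lowest cluster index; wake-heuristic
  ties go to the lowest cluster id, with a message.
- Matching with fewer observed stages than clusters pads the stage profile
  set with all-zero rows so the similarity matrix stays `k x k`; wake-only
  cohorts thus score ≈ `1/k`, as they should.
- The all-zero network has `Q_W` defined as 0 with a warning.
- Accuracy denominators exclude volumes not covered by any full window.
- Text round trips write at full precision; TR lives in a JSON sidecar.

## Known limitations

- The Louvain search is a stochastic heuristic; best-of-100 with refinement
  is not a global optimality guarantee on arbitrary signed networks.
- Occurrence profiles assume a common session clock across subjects (equal
  TR and window grid); ragged cohorts drop under-populated trailing bins.
- The matchers require equally many clusters and stages; k must be chosen by
  the analyst (the NREM cycle motivates k = 4, the wake/sleep split k = 2,
  REM cohorts k = 5). No automatic k selection is provided, by design.
- `stage_contrast` uses paired t-tests; heavy-tailed edge differences might
  warrant a signed-rank alternative, which the caller can compute from the
  returned per-edge differences.
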
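---
title: "Ensemble simulation of coupled EMT-stemness circuits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble simulation of coupled EMT-stemness circuits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question and the modeling strategy

Carcinoma cells move along an epithelial-hybrid-mesenchymal continuum, and
hybrid epithelial/mesenchymal (E/M) cells are repeatedly observed to be the
most stem-like and tumor-initiating. `empstem` asks whether that association
is an intrinsic consequence of the wiring that couples the two regulatory
modules involved: the miR-200/ZEB mutual-inhibition loop governing
epithelial-mesenchymal plasticity and the LIN28/let-7 mutual-inhibition loop
governing stemness, connected by miR-200 repressing LIN28 and let-7
repressing ZEB, with SNAIL and NF-kB as upstream inputs and OCT4 stemness
read out through its regulator LIN28.

Because kinetic constants differ from cell to cell and are largely
unmeasured, no single parameterization is trustworthy. The package therefore
simulates an *ensemble*: thousands of models that share one topology but
draw every kinetic parameter at random from biologically motivated ranges.
Features that survive this parameter agnosticism are attributed to the
topology itself. This is the random-circuit-perturbation approach familiar
from the RACIPE tool; `empstem` implements the whole chain — sampling,
steady-state enumeration, normalization, phenotype clustering, stemness
scoring, link metrics and statistics — as a tested R package with no
external inputs beyond `.topo` circuit files.

# The dynamical model

Each node $i$ with expression level $p_i$ obeys

$$\frac{dp_i}{dt} = g_i \prod_{j \in A(i)} H^S(p_j;\ \mu_{ji}, \lambda_{ji}, n_{ji}) - k_i\, p_i,$$

where $A(i)$ are the regulators of $i$, $g_i$ is the basal production rate,
$k_i$ the degradation rate, and $H^S$ the *shifted Hill function*

$$H^S(p;\ \mu, \lambda, n) = \frac{\mu^n}{\mu^n + p^n} + \lambda\,\frac{p^n}{\mu^n + p^n},$$

which equals 1 with no regulator, crosses $(1+\lambda)/2$ at the threshold
$\mu$, and saturates at the fold change $\lambda$ ($\lambda > 1$ activation,
$0 < \lambda < 1$ inhibition). Rather than randomizing $g$ directly, the
sampler randomizes the *maximal* production rate
$G = g \prod_{j} \lambda_j$ over incoming activations, so that $G/k$ is the
node's highest reachable steady level.

# Random sampling: what the generator emulates

The ensemble is the package's data generator; it stands in for cell-to-cell
kinetic variability in a population sharing one regulatory topology.
Defaults (all overridable through `sampling_ranges()`):

| parameter | distribution | default |
|---|---|---|
| maximal production $G$ | uniform | $[1, 100]$ |
| degradation $k$ | uniform | $[0.1, 1]$ |
| Hill coefficient $n$ | uniform integer | $\{1,\dots,6\}$ |
| activation $\lambda$ | uniform | $[1, 100]$ |
| inhibition $\lambda$ | $1/\mathrm{U}[1, 100]$ | — |
| threshold $\mu$ | uniform | $[0.02M, 1.98M]$ |

Initial conditions are drawn log-uniformly between each node's smallest
reachable steady level (activators silent, inhibitors saturated) and its
largest ($G/k$), 100 per model by default, so that coexisting attractors
with modest basins are found.

Fold-change perturbations (`oe10`, `de10`) multiply both endpoints of the
target node's $G$ range — over-expression samples from a 10-fold higher
range, down-expression from a 10-fold lower one — leaving every other
parameter untouched. Thresholds are always calibrated on the *unperturbed*
ranges, so a perturbation shifts production only.

## Threshold calibration

The threshold center $M$ of each node is the one genuinely open numerical
choice in this sampling scheme, and it matters: if thresholds sit far above
the levels a regulator actually realizes, its outgoing links are inert and
the circuit behaves quasi-linearly; too far below, and every link
saturates. The guiding principle (the "half-functional rule") is that a
link's threshold should have roughly even odds of sitting above or below
its regulator's realized level.

`empstem` ships four rules (`threshold_rule` in `sampling_ranges()`):

* **`calibrated` (default).** Finds $M$ self-consistently: starting from a
  Monte-Carlo estimate, it simulates small pilot ensembles of the actual
  circuit (500 models x 60 initial conditions, fixed internal seeds) and
  moves $M$ half-way, on the log scale, toward the *log-scale center* of
  the realized level distribution, six times. For the strongly bimodal
  levels these circuits produce, the log center sits in the valley between
  the "off" and "on" modes — the level a threshold must cross to
  discriminate the two states. (The plain median of a bimodal distribution
  sits on whichever mode holds more than half the mass, which makes the
  fixed-point iteration oscillate; the log-center anchor converges.) The
  result is cached per topology and deterministic.
* **`half_functional`.** The closed-form Monte-Carlo estimate alone:
  median of $(G/k) \prod_e f_e$ with one factor per incoming link, equal to
  $1$ or $1/\lambda_e$ with equal odds (the regulator above or below its own
  threshold). Cheap, but for highly regulated nodes it can disagree with
  the realized levels by an order of magnitude.
* **`half_functional_uniform`.** As above with $f_e$ uniform on
  $[1/\lambda_e, 1]$.
* **`median`.** $M = \mathrm{median}(G)/\mathrm{median}(k) \approx 92$ for
  every node, ignoring regulation. Retained for comparison; with it, most
  links in this circuit are sub-functional and about three quarters of the
  base-circuit models come out monostable, far more than the other rules.

What the generator does *not* emulate: extrinsic noise and stochastic state
switching (dynamics are deterministic ODEs), transcriptional bursting,
explicit microRNA-mRNA titration mechanics (regulation is phenomenological
through $H^S$), or correlated parameter variation across nodes. Conclusions
from passing tests are therefore statements about the deterministic
multistability structure of the sampled ensemble, not about kinetics of any
single cell line.

# Steady-state enumeration

Each trajectory is integrated with an adaptive Cash-Karp Runge-Kutta 4(5)
scheme (relative tolerance $10^{-6}$, positivity clipping at $10^{-12}$,
time budget $200/\min_i k_i$). Convergence is declared by the scale-free
residual $\max_i |\dot p_i| / (k_i |p_i|) < 10^{-6}$. Once the residual
falls below $10^{-3}$ the endpoint is handed to a damped Newton iteration
on the algebraic system $\dot p = 0$ with the analytic Jacobian; a polish
that lands on a root whose Jacobian has any eigenvalue real part above
$10^{-8}$ is rolled back (the trajectory was shadowing a saddle) and
integration continues. Trajectories whose residual stalls — limit cycles
from negative feedback loops, as the NRF2 circuit can produce — are
abandoned early and logged as non-converged rather than analyzed; with the
default ranges this affects a few percent of trajectories in the NRF2
circuit and essentially none elsewhere.

The sampled ranges keep the stiffness ratio modest ($k \in [0.1,1]$,
$\lambda \le 100$), so an adaptive explicit integrator with Newton
polishing reaches the same fixed points an implicit endpoint solver would,
at a fraction of the cost; the Jacobian eigenvalue filter guarantees that
only attractors are reported regardless of the path taken to them.

Endpoints are deduplicated per model: two states are the same when every
node agrees within 0.05 in log2. That tolerance is far below the roughly
one-log2-unit separation between Hill branches, and far above the
$10^{-9}$ residual of polished roots. A model's *multistability class* is
the count of its distinct stable states (monostable, bistable, tristable,
quadrastable+). States reachable only from very small basins can still be
missed at 100 initial conditions; this under-enumeration is shared with
the method the analysis reproduces and shrinks as `n_inits` grows.

# Phenotypes, phases, and the stemness window

All solutions of a replicate are pooled with equal weight and normalized
gene-wise: $z_i = (\log_2 p_i - \overline{\log_2 p^{ref}_i}) /
\sigma(\log_2 p^{ref}_i)$, with the reference statistics taken from the
same replicate of the *unperturbed* circuit, so perturbed runs share their
reference's scale. K-means (10 restarts, best inertia kept) partitions the
solutions using only the four core nodes — miR-200, ZEB, LIN28, let-7;
SNAIL, NF-kB and PSF nodes are excluded as features because nothing feeds
back into them. At $k = 4$, clusters are named by ascending cluster-median
ZEB — e, he, hm, m — with ties broken by descending median miR-200 (the
tie-break matters only for degenerate geometries such as the uncoupled
circuit, where the two low-ZEB clusters share both ZEB and miR-200
medians). Each replicate is normalized and clustered separately;
cross-replicate quantities are means with SDs over replicates. A model's
*phase* is the multiset of its states' labels, e.g. `{e,m}`.

On cluster count: the average silhouette width, the Calinski-Harabasz and
Davies-Bouldin indices and the inertia elbow are all computed by
`cluster_quality_sweep()` (silhouette on a 5,000-row subsample — a full
dissimilarity matrix at ensemble scale costs gigabytes and adds nothing at
this precision). In the ensembles this generator produces, $k = 4$ is a
clear *local* silhouette peak (it beats 3 and 5 in every replicate), the
four-cluster geometry is unambiguous in the (ZEB, LIN28) plane and in the
PCA, and the phase structure is four-phenotype; but the *global* silhouette
maximum over $k \in \{2,\dots,8\}$ sits at $k = 2$, reflecting the deep
epithelial/mesenchymal split along the first axis with comparatively sparse
hybrid clusters between. We report the sweep as computed rather than
forcing the four-cluster reading; the phenotype assignment itself always
uses $k = 4$, where the labels are biologically interpretable.

The *stemness window* formalizes "intermediate LIN28": with $m$ and $q$
the median and interquartile range of the pooled LIN28 z-values (each
averaged across replicates), the biological range is $[m - q,\ m + q]$ and
the window is its middle fraction $f$, $[m - f q,\ m + f q]$, with
$f = 0.30$ by default — read as 30% of the full $2q$ width, centered on the
median, boundaries inclusive. Enrichment is quantified per replicate by
$p_1(c) = P(\text{in window} \mid \text{phenotype } c)$ and
$p_2(c) = P(\text{phenotype } c \mid \text{in window})$;
`window_sensitivity()` sweeps $f$ and shows the hybrid share of the window
eroding once $f$ grows past about one third. In pipeline runs the window is
placed on the unperturbed reference ensemble and reused for that circuit's
perturbed variants, consistent with the shared normalization.

# Link metrics

The potency of a link, independent of where the ensemble ends up, is
$l = \lambda_{\mathrm{eff}} \cdot (G_s/k_s) / \mu$ with
$\lambda_{\mathrm{eff}} = \lambda$ for activation and $1/\lambda$ for
inhibition, and $G_s/k_s$ the *source* node's maximal level — the only
dimensionally coherent normalization of $\mu$, which thresholds the source's
level (a configuration switch is deliberately not offered for the sign
convention, but the strength is exposed per edge so any recombination is
one line of R). For a two-link feedback loop, the asymmetry is
$\log_2(l_1/l_2)$ and the combined coupling strength
$\log_2 l_1 + \log_2 l_2$; the pair is an invertible transform of the two
log-strengths. Being parameter-level quantities, they attach to every
solution of their model when grouped by phenotype.

# Replicates, statistics, and problem sizes

A *replicate* is one full ensemble with its own seed (base seed + replicate
index); it plays the role of a biological replicate, and every reported
proportion carries a cross-replicate mean and SD. Within-replicate
distribution comparisons use the two-sided Mann-Whitney U test with
median-ratio and median-difference effect sizes (at ensemble sample sizes,
tiny differences reach significance, so the effect sizes carry the
biological judgment); cross-replicate proportions use Welch's t-test; both
feed Holm-Bonferroni adjustment within whatever family of comparisons a
table collects.

The package's reference configuration is 5 replicates x 1,000 models x 100
initial conditions — the scale at which the bundled analysis scripts, the
test suite and `scripts/acceptance.R` run, chosen so a full base-circuit
analysis completes in about two minutes on one core while leaving the
multistability fractions stable to within a couple of percentage points.
The PSF perturbation sweeps in the scripts run at 2 replicates x 500 models
x 60 initial conditions per fold for the same reason; all counts scale up
by changing one `run_config()` call (5 x 10,000 x 100 is the full-scale
setting, roughly a twenty-fold longer run).

# Known limitations

* Deterministic steady states only: no Langevin/Gillespie dynamics, no
  bifurcation continuation, and limit cycles are logged as non-converged
  rather than characterized.
* Basin under-sampling at finite `n_inits` biases multistability counts
  downward, mostly for states with small basins.
* The threshold calibration is a fixed point of the sampler itself; it is
  deterministic and cached, but its pilot-scale Monte-Carlo error (a few
  percent on $M$) propagates into ensemble composition.
* The NRF2 sub-circuit wiring is the least constrained input: the bundled
  default (miR-200 and ZEB activating NRF2, NRF2 repressing SNAIL) can be
  replaced by any user `.topo` file, and conclusions specific to NRF2
  should be read against that file, not the package default.
* Family-level nodes (miR-200, ZEB, LIN28, let-7) collapse gene families
  into single variables, as in the modeling tradition this follows.
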
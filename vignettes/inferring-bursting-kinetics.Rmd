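---
title: "Inferring transcriptional-bursting kinetics from smFISH snapshots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring transcriptional-bursting kinetics from smFISH snapshots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snapburst)
```

## The inference problem

Single-molecule RNA FISH (smFISH) counts, cell by cell, the number of mRNA
molecules and the number of active transcription sites (TSs, at most two in
a diploid post-mitotic cell). An induction experiment yields population
*snapshots* of these counts at a handful of times: one sample before the
stimulus and several after it. The data are static — each cell is fixed —
yet the quantity of interest is dynamic: which kinetic parameters of the
gene changed at induction, and by how much.

`snapburst` treats this as Bayesian inference over a stochastic
gene-expression model. The default model is the two-state (telegraph)
promoter: each allele switches between an inactive state (basal synthesis
rate $\mu_0$) and an active state (synthesis rate $\mu_1 > \mu_0$) with
activation rate $k_1$ and deactivation rate $k_0$; mRNA degrades at a fixed,
independently measured rate $\delta$. Alleles are independent, so a cell
state is $x = (\rho_1, m)$: the number of active alleles
$\rho_1 \in \{0, \dots, n_\text{alleles}\}$ and the mRNA count $m$. A
*parameter-stimulus hypothesis* names the parameters that jump from their
pre-stimulus value $\theta^U$ to a post-stimulus value $\theta^S$ at $t=0$;
everything else stays constant.

## Distributions from the chemical master equation

The model's state probabilities obey the chemical master equation
$\partial_t P = A(\theta) P$, with the sparse generator $A$ holding reaction
propensities off the diagonal and negated outflows on it (columns sum to
zero). The state space is truncated at a maximum mRNA count $M$, giving
$N = p(M+1)$ states with $p = n_\text{alleles}+1$; real-data analyses use
$M = 500$, comfortably above observed counts. Reactions that would leave
the truncation are removed from both the off-diagonal and the diagonal, so
$A$ stays a proper probability-conserving generator and the truncation
error appears, measurably, as *mass deficit* $1 - \sum_i P_i$ of the
propagated distribution — the same role the error bound plays in
finite-state-projection solvers. At $M = 500$ and realistic rates the
deficit stays below $10^{-12}$.

Two solver operations produce everything the likelihood needs:

* **Stationary distribution** (pre-stimulus sample): $A(\theta^U) P^* = 0$
  with $\sum_i P^*_i = 1$. Because the columns of a generator sum to zero,
  one balance equation is redundant; the solver replaces the last row with
  the normalization constraint and does a sparse LU solve, with a dense SVD
  null-space fallback for small systems. The residual
  $\max_i |(A P^*)_i|$ must stay below $10^{-10}$.
* **Transient distribution** (post-stimulus samples):
  $P(\tau) = e^{A(\theta^S)\tau} P^*$. The matrix exponential is never
  formed; its action is computed by uniformization: with
  $\Lambda = \max_i(-A_{ii})$ and $B = I + A/\Lambda$ (nonnegative,
  substochastic), $e^{A\tau} v = \sum_k w_k B^k v$ with Poisson weights
  $w_k = e^{-\Lambda\tau}(\Lambda\tau)^k/k!$. The series is summed over the
  central Poisson window (both tails below $10^{-15}$, seeded from the
  log-scale density so very large $\Lambda\tau$ cannot underflow), which
  preserves nonnegativity and keeps the propagation error far below the
  truncation budget. Uniformization was chosen over Krylov methods because
  it is the canonical propagator for continuous-time Markov chains,
  requires only sparse matrix-vector products, and its error control is a
  single transparent tail bound.

Entries in $(-10^{-14}, 0)$ — numerically zero — are clipped to zero and
the vector renormalized; anything more negative is treated as solver
failure and raised as an error rather than silently repaired.

Inside the Metropolis loop these solves repeat tens of thousands of times,
so a dedicated kernel precomputes the sparsity pattern once and refreshes
only the numeric values per proposal. Its stationary solve anchors the
probability of the empty state $(0, 0)$ and solves the trimmed
column-diagonally-dominant system, which avoids the dense normalization
row; if the anchor state carries essentially no mass the relative values
overflow and the kernel falls back to the reference solver. Tests assert
agreement between the two paths to $10^{-10}$.

## Snapshot likelihood

Each sampled cell is one draw from the model distribution at its sample
time, so the per-time-point count vectors $Y^t$ follow multinomials and

$$\ln \mathcal{L}(\theta) = \sum_t \Big[ \ln(n_t!) - \sum_k \ln(Y^t_k!)
  + \sum_i Y^t_i \ln P(x_i, \tau_t) \Big],$$

with the $t=0$ sample scored against the $\theta^U$ stationary distribution
(pre-stimulus cells are presumed at steady state). All factorials go
through `lgamma`. The multinomial coefficient is independent of $\theta$
and cancels in Metropolis ratios, but it is kept so stored log-likelihoods
are full likelihoods, directly comparable across candidate models on the
same data. Observed states whose model probability falls below $10^{-300}$
give $\ln\mathcal{L} = -\infty$ (an automatic rejection); observed states
outside the truncation are a configuration error — the user must raise
$M$.

## Priors and the posterior sampler

The prior is a Heaviside box: zero below $10^{-8}$ (effectively negative
rates) and zero above a maximum transcription rate `mu_max` for the
synthesis rates (literature estimates put the ceiling at 12–18 mRNA/min;
the default uses 18). Within the box the prior is flat, and the evidence
$P(Y)$ is a constant that never needs computing — reported posteriors are
unnormalized. One further constraint is on by default: $\mu_1 \ge \mu_0$.
The active state is *defined* as the one with the higher synthesis rate, so
this is a labeling convention rather than an assumption; without it every
posterior owns an exact mirror mode with the state labels swapped, which
wastes sampling effort and can trap short chains.

Sampling is plain random-walk Metropolis on the linear parameter scale:
propose $\phi = \theta_t + \mathcal{N}(0, \Sigma)$, accept with probability
$\min(e^{\Delta}, 1)$ where $\Delta$ is the log-posterior difference;
rejected proposals repeat the current state. The default $\Sigma$ is
diagonal with variance $10^{-5}$ for $k_0, k_1, \mu_0$ and $10^{-3}$ for
$\mu_1$ — deliberately small steps suited to the narrow posteriors that
well-sampled snapshot data produce. Each stimulus parameter contributes two
coordinates (pre and post) in a fixed, documented order. Proposals that
leave the prior box are rejected before any likelihood work.

Because the proposal steps are small, where the chain *starts* matters.
The default start draws 100 candidate vectors log-uniformly inside the
prior box (rates plausibly span decades), keeps the best log-posterior,
and refines it with two short restarted Nelder–Mead climbs. Starting at
the posterior mode makes the burn-in nearly empty at moderate chain
lengths ($T = 10^4$) and, as a side effect, makes the stored maximum
likelihood — the ingredient of BIC and AICc — reliable even for candidate
models that fit the data poorly. Purely random and user-supplied starts
remain available; with them, plan on the order of $T = 10^5$ iterations.

Burn-in is detected from the log-likelihood trace: the retained segment
starts at the first iteration reaching 99.5% of the chain maximum,
operationalized for negative log-likelihoods as
$\ell_t \ge \ell_{\max} - 0.005\,|\ell_{\max}|$, and never exceeds $T/2$
(a warning flags chains that were still climbing). Posterior summaries
(means, SDs, central 95% intervals) use post-burn-in samples only. Chains
are bitwise-reproducible given a seed.

## Model selection

Competing stimulus hypotheses are scored with
$\text{BIC} = -2\ln\hat{\mathcal{L}} + m\ln n$, the small-sample
$\text{AICc} = -2\ln\hat{\mathcal{L}} + 2m + 2m(m+1)/(n-m-1)$, and
$\text{DIC} = 2\bar{D} - D(\bar\theta)$ with deviance
$D = -2\ln\mathcal{L}$, where $\bar{D}$ averages over post-burn-in samples
and $\bar\theta$ is the post-burn-in mean on the linear (sampling) scale.
Two conventions are made explicit rather than left implicit: $n$ counts
*cells across all time points* (each cell is one multinomial draw), and the
AICc's `as_printed = TRUE` flag reproduces a circulating variant with
$-2m$ in place of $+2m$ for comparison purposes. Ties rank the model with
fewer free parameters first.

## The synthetic-data generator and what it does (not) show

`simulate_snapshots()` emulates the snapshot experiment exactly as the
model describes it: compute the pre-stimulus stationary distribution and
the post-stimulus transients, then draw `n_cells` cells per time point as
one exact multinomial sample. Defaults mirror the standard design —
samples at 0, 5, 15, 25 minutes and 100 cells per time point; two built-in
truth presets (`k1_stim`, `k1k0mu1_stim`) provide reference parameter
sets. The generator shares the distribution solvers with the likelihood,
so it cannot validate them; that is the job of `gillespie_ssa()` /
`ssa_snapshot()`, an exact stochastic simulation of the untruncated
reaction system (compiled fast path for the two-state family, interpreted
path for custom models) whose pre-stimulus states come from its own long
SSA equilibration, not from the CME solver.

Passing tests on synthetic data show that the pipeline recovers parameters
of data generated by its own model family. Real smFISH data additionally
contain detection noise in spot counting, possible allele–allele
correlation, partial-cell truncation in imaging, and nascent-mRNA
ambiguity at bright TSs — none of which the generator emulates, and all of
which the model ignores by design.

When comparing empirical histograms against exact distributions
(`tv_distance()`), note that a finite sample of size $n$ over $N_b$
effective states carries irreducible total-variation noise of order
$\sqrt{N_b/n}$; oracle comparisons therefore use the conventional display
binning of 20 mRNAs per bin, where $10^5$ trajectories put the noise floor
near 0.004, well below the 0.01 agreement bound the tests enforce.

## Numerical choices and test problem sizes

* Truncation: $M = 500$ for real-scale work; the test suite uses
  $M = 60$–$250$, sized so that the mass deficit is far below tolerance
  for the rates involved.
* Uniformization tail: $10^{-15}$ for user-facing propagation, $10^{-12}$
  inside the MCMC kernel (likelihood differences of interest are orders of
  magnitude larger).
* Stationary-solve residual tolerance $10^{-10}$; clip threshold
  $10^{-14}$; likelihood underflow floor $10^{-300}$.
* Recovery experiments in the tests use $T = 10^4$ iterations at
  $n = 1000$ cells/time point, and the model-selection sweep fits six
  candidate hypotheses at $T = 5 \times 10^3$, $n = 100$, $M = 150$, three
  sampler seeds — sizes at which a full run completes in minutes on one
  core while leaving the scientific conclusions (truth recovery within the
  posterior interval, correct model ranked first by all three criteria)
  intact.
* SSA oracle checks use $10^5$ trajectories per condition and binned total
  variation as described above.

## Known limitations

* Only a single instantaneous parameter switch at $t = 0$ is supported —
  no time-varying rates, no multi-step protocols.
* Replicated genomes (3–4 alleles after DNA replication) and correlated
  alleles are out of scope; the allele-independence assumption is load
  bearing for the binomial TS structure.
* The proposal covariance is fixed, not adaptive; acceptance rates well
  outside [0.05, 0.6] trigger a warning rather than automatic retuning.
* DIC uses the plug-in deviance at the posterior mean; for strongly
  non-Gaussian posteriors the effective-parameter correction can misbehave
  (a known property of DIC, not of this implementation).
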
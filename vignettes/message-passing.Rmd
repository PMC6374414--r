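---
title: "Neuronal message passing: mean-field, Bethe and marginal approximations on hidden Markov models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuronal message passing: mean-field, Bethe and marginal approximations on hidden Markov models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuralmp)
```

## The inference problem

`neuralmp` studies how a network of locally interacting units can perform
Bayesian inference about a sequence of hidden states.  The generative model
is a discrete hidden Markov model with one or more mutually independent
hidden *factors*.  Factor $f$ has $m_f$ levels and evolves as a first-order
Markov chain over a fixed horizon $\tau = 1, \dots, T$:

$$
P(s_1 = i) = D_i, \qquad
P(s_{\tau+1} = i \mid s_\tau = j) = B_{ij},
$$

and each outcome *modality* $g$ is generated at every step from exactly one
factor through a likelihood matrix,

$$
P(o_\tau = i \mid s_\tau = j) = A_{ij}.
$$

All matrices are **column-stochastic**: the column always indexes the
conditioning variable.  Readers of model files can declare row-stochastic
storage, which is transposed on load; internally a single convention is
used everywhere.  Because every modality observes a single factor, the
posterior factorises over factors and all computations run per factor.

Given outcomes $\tilde o = (o_1, \dots, o_T)$ — possibly with later entries
not yet observed — the quantity of interest is the set of marginal
posteriors $Q(s_\tau) \approx P(s_\tau \mid \tilde o)$ at *every* time
step: the state at the start of a sequence is represented separately from
the same state at the end, so beliefs about the past are revised as new
outcomes arrive.

## Three message passing schemes

All three schemes compose each marginal from three messages arriving from
the Markov blanket of $s_\tau$ — the likelihood of the current outcome, a
message from the past, and a message from the future:

$$
Q(s_\tau) \propto \mu_A(s_\tau) \cdot \vec\mu(s_\tau) \cdot
\overleftarrow{\mu}(s_\tau), \qquad \mu_A(s_\tau) = P(o_\tau \mid s_\tau).
$$

They differ in how the directed messages are computed.

**Belief propagation (BP)** uses the sum-product messages
$\vec\mu(s_\tau) = \sum_{s_{\tau-1}} P(s_\tau \mid s_{\tau-1})
\vec\mu(s_{\tau-1}) \mu_A(s_{\tau-1})$ (and its mirror image from the
future).  On this acyclic model class one forward and one backward sweep
suffice and the marginals are exact; `mp_infer(..., scheme = "exact")`
implements exactly that schedule, with per-step normalisation and the
retained log-normalisers summing to the log evidence $\ln P(\tilde o)$.

**Variational message passing (VMP)** replaces messages computed from
other messages with messages computed from the neighbouring *marginals*,
taking the expectation of the log transition probability:
$\ln\vec\nu(s_\tau) = E_{Q(s_{\tau-1})}[\ln P(s_\tau \mid s_{\tau-1})]$.
These are the fixed-point updates of the mean-field (fully factorised)
variational posterior.  Because the expectation sits outside the log, each
neighbour's uncertainty is under-propagated and the scheme is prone to
overconfidence.

**Marginal message passing (MMP)** also computes messages from adjacent
marginals, but keeps the expectation *inside* the log as in belief
propagation, and attenuates each directed log-message by a corrective
exponent $\alpha$ (default $\tfrac12$):
$\ln\vec\eta(s_\tau) = \alpha \ln E_{Q(s_{\tau-1})}[P(s_\tau \mid
s_{\tau-1})]$.  The backward message uses the time-reversed transition
matrix $B^\dagger$ (`reverse_transition()`): the transpose of $B$ with
renormalised columns, i.e. the Bayes inversion of the chain under a flat
prior on the earlier state, so that probability mass is conserved when the
chain is run from the future to the past.  The attenuation compensates for
the fact that a smoothed marginal is more precise than the filtered
distribution the true sum-product message encodes; $\alpha$ is exposed as
a tunable parameter (`mp_control(alpha = )`), with $\alpha = 1$ recovering
the unattenuated variant.  A property test confirms that $\alpha =
\tfrac12$ yields beliefs at least as uncertain as $\alpha = 1$.

## Neuronal dynamics

Each scheme is also implemented as a continuous-time gradient descent with
a direct neuronal reading.  For every factor and time step the network
carries a vector of membrane potentials $v_\tau$ (log-space belief
parameters), firing rates $s_\tau = \sigma(v_\tau)$ (the softmax plays the
role of the neuronal transfer function converting potentials to normalised
rates), and prediction-error units

$$
\varepsilon_\tau = \mathrm{target}_\tau - v_\tau, \qquad
\dot v_\tau = \varepsilon_\tau,
$$

where $\mathrm{target}_\tau$ is the scheme's log-message sum,
mean-centred per time step to fix the additive gauge of the softmax.
Integration is explicit Euler with all time steps and factors updated in
parallel; the run stops when $\max|\varepsilon| <$ `tol` and is fully
deterministic given its inputs.  Adding a constant to any $v$ leaves all
firing rates and their subsequent dynamics unchanged (tested).

For BP the network additionally carries forward and backward *message
populations*.  The message a time step passes on is its marginal with the
ascending likelihood message and the opposite-direction message divided
out — two inhibitory connections that cancel what would otherwise be
counted twice — after which the transition factor re-applies the
likelihood and mixes through $B$ (or $B^\top$).  The net updates are

$$
F_\tau \leftarrow B\,(s_{\tau-1} / G_{\tau-1}), \qquad
G_\tau \leftarrow B^\top (s_{\tau+1} / F_{\tau+1}),
$$

with $F_1 = D$ and $G_T \propto \mathbf 1$.  A subtlety motivates this
form: rebuilding *both* messages at an edge from that edge's own marginal
(dividing the companion message out of $Q_\tau$ in both directions) leaves
the pair underdetermined — the fixed-point equations then admit an
$(m-1)(T-2)$-dimensional family of spurious solutions, and the integrated
dynamics demonstrably settle on wrong beliefs.  The propagated form above
is the composition the marginal-coupled message definitions imply, has the
scheduled sum-product messages as its unique fixed point, and is what the
package implements; at convergence the recovered message populations are
proportional to the scheduled sweeps' messages (tested) and the beliefs
match brute-force enumeration to around $10^{-11}$ KL per step.

By default the message populations are solved algebraically at every Euler
step — the adiabatic limit in which units with much shorter time constants
are enslaved by the marginal populations.  `mp_control(msg_tau = )`
instead relaxes them as an explicit fast process, for neural-mass-style
experiments.

The architecture cost of this extra machinery is what
`architecture_cost()` quantifies: for $n$ factors with $m$ levels over $t$
represented time steps, the mean-field and marginal networks need $2nmt$
populations (marginals and errors), belief propagation $4nmt$ (two message
populations more).

### The overcounting lesion

`mp_infer(..., scheme = "BP", lesion = TRUE)` cuts the inhibitory
connection that subtracts the ascending likelihood message from the
forward out-message.  The ascending message then crosses the transition
factor embedded in the forward message *and* arrives at the next marginal
directly — it is counted twice.  The lesioned fixed point has an exact
characterisation, which the tests assert against a hand-built oracle: the
backward messages are unchanged, while the forward filter runs with the
*squares* of all strictly-past likelihood messages (the current outcome is
still counted once).  Consequences verified in the tests: an uninformative
likelihood makes the lesion a no-op; under a run of consistent evidence
the lesioned posterior loads more mass on the evidence-supported state
than the intact circuit; and beliefs lose the contextualising influence of
the priors relative to the accumulated sensory stream.  Note that the
lesioned beliefs are *not* simply closer, in KL, to the normalised
current-step likelihood: the doubling acts on the accumulated past, an
empirical point worth keeping in mind when relating the lesion to
circular-inference phenomenology.

## Free energies

Each scheme descends a free-energy functional, reported in nats
throughout; for multi-factor models every functional sums over the
independent factors.

* `variational_free_energy()` — energy minus entropy under the mean-field
  family: transition energies are expectations of $\ln B$ under outer
  products of adjacent singleton marginals, and the entropy is the sum of
  marginal entropies.  For any valid mean-field $Q$ it upper-bounds
  $-\ln P(\tilde o)$, with slack `jensen_gap()` equal to the KL divergence
  from $Q$ to the exact joint posterior (verified against a brute-force
  joint KL).
* `bethe_free_energy()` — the pairwise family: exact pairwise expectations
  of $\ln B$, and the Bethe entropy (singleton entropies minus the mutual
  information of each adjacent pair).  On these acyclic models it is exact:
  evaluated at the exact posterior (singletons plus pairwise tables from
  `pairwise_marginals()`) it equals $-\ln P(\tilde o)$ to $10^{-9}$.
  Inconsistent pairwise tables are rejected rather than silently used.
* `marginal_free_energies()` — the per-step forward and backward free
  energies $F_F(\tau)$, $F_B(\tau)$, scoring beliefs against empirical
  priors propagated through $B$ from the past marginal and through
  $B^\dagger$ from the future one (expectations inside the log), and the
  marginal free energy $F(\tau) = \tfrac12 (F_F(\tau) + F_B(\tau))$, which
  counts the likelihood and entropy once and halves each directed
  log-message.  The MMP fixed point is a stationary point of $F(\tau)$ in
  the softmax parameterisation (checked by finite differences).

**Boundary conventions.**  At $\tau = 1$ the past message is the initial
prior; in the marginal scheme the $\tfrac12$ exponent is applied to the
$\ln D$ term as well, for uniformity of the scheme (this is a choice — the
fixed-point equations give no boundary rule — and the mixture identity
$F(\tau) = \tfrac12(F_F + F_B)$ then holds at the boundary too).  At
$\tau = T$ there is no future term: the backward message is flat and
$F_B(T)$ has no empirical prior.

**The forward-plus-backward inequality.**  It has been conjectured that
$F_F(\tau) + F_B(\tau) \ge -E_{Q(s_\tau)}[\ln P(o_\tau, s_\tau \mid
\tilde o_{\setminus\tau})] - H[Q(s_\tau)]$, with the exact leave-one-out
predictive on the right.  `conjecture_slack()` evaluates both sides, with
the predictive computed by brute-force enumeration only (size-guarded; no
approximate fallback) so the check stays honest, and negative slack is
reported rather than clipped.  The package's sweep over random two-state
models at converged MMP fixed points in fact *finds* negative slack: at
the final time step in a majority of models (where $F_B(T)$ lacks its
empirical-prior term) and occasionally at interior steps.  This is
reported as computed — the inequality, which was offered without proof,
does not hold unrestrictedly under these conditions — and the per-step
slack profile is available for anyone wishing to characterise when it
fails.

## The synthetic benchmark

`benchmark_model()` generates the two-factor benchmark used throughout: two
independent hidden factors of three levels over $T = 15$ steps, a single
three-outcome modality depending on the first factor only, deterministic
initial states, and "sticky" stochastic transitions.  Each transition
column puts `stickiness` (default 0.7) on the self-transition with the
remainder spread evenly, and each likelihood column puts `acuity`
(default 0.8) on the matched outcome.  The published simulations this
emulates render their probability matrices graphically rather than
printing them, so these two parameters were fixed once at values producing
the same qualitative regime — informative-but-uncertain outcomes over
stochastic transitions — and are exposed as arguments; externally supplied
matrices can be dropped in through `read_model()` /
`read_observations()` for exact reproduction when the original numbers
are available.  `random_model()` draws all probability columns from a
symmetric Dirichlet for property tests, and `simulate()` performs
ancestral sampling; all generators take an explicit seed and restore the
global RNG state.

The benchmark isolates the phenomenon of interest: the second factor is
never observed, its initial state is known exactly, and its transitions
are stochastic, so the exact posterior entropy must grow with distance
from the start.  Belief propagation reproduces this; the mean-field scheme
remains confident even about the penultimate state; the marginal scheme
tracks belief propagation closely and, if anything, slightly
overcompensates (its fixed-point entropies are at or above BP's — the
tested ordering is mean-field $\le$ Bethe $\le$ marginal for the
unobserved factor).  What the generator does *not* emulate: structural
zeros in the transitions (real tasks often forbid transitions outright),
multiple modalities, likelihoods conditioned on several factors jointly,
or any learning of $A$, $B$, $D$ — so passing tests speak to inferential
behaviour under this model class, not to fitting real neural or
behavioural data.

## Online experiments and metrics

`online_experiment()` presents outcomes sequentially: after the $t$-th
outcome is revealed (later entries masked as unobserved), each scheme is
integrated to convergence, warm-started from its previous beliefs —
beliefs persist within a trial, as in the continuous neuronal reading — and
all beliefs are snapshotted.  A cold-start mode exists to test that the
exact fixed point is unique.  `comparison_report()` repeats this over
seeded replicates and summarises: summed KL of mean-field and marginal
final beliefs from the BP reference, state-estimation errors against the
generating states (argmax per step, ties broken toward the lowest index),
the entropy profile of the unobserved factor, and an update-timing
statistic — the fraction of the trial's total L1 belief path length
accrued during the first quarter of presentations, which operationalises
"most mean-field updating happens at the very start".

## Numerical choices

* **Log floor.**  All logarithms of model probabilities are computed as
  $\log(x + 10^{-16})$, so structural zeros (deterministic priors and
  transitions) stay finite.  Entropies and KL divergences instead use the
  $0 \log 0 = 0$ convention, and a positive reference probability against
  a zero yields an explicit `Inf`.
* **Unobserved outcomes** contribute an all-ones likelihood message (not
  $1/O$): the two differ only by normalisation, and ones keep message
  products interpretable as unnormalised joint terms.
* **Integration defaults.**  Euler step 0.1, tolerance $10^{-6}$ on the
  largest prediction error, `max_time` 200.  First-order dynamics at this
  step are trivially reproducible and comfortably stable; the replicate
  sweeps in the tests and the acceptance script use step 0.5 with
  `max_time` 1000 — the fixed points are identical and the damped larger
  step converges in a fifth of the iterations, which keeps fifty online
  replicates in the order of a minute or two.  The `engine = "map"` option
  iterates each scheme's target map directly; it reaches the same fixed
  points (tested) and is the cheap choice when only converged beliefs are
  needed, though the undamped parallel iteration can cycle on rare
  mean-field instances, which is why the Euler dynamics remain the
  default.
* **Stochasticity tolerance.**  Matrices are validated to column sums of
  one within $10^{-10}$ and renormalised exactly when inside that band;
  larger deviations are errors naming the factor/modality and column.
* **Problem sizes.**  The enumeration oracle guards at $\prod_f m_f^T \le
  10^7$ sequences.  The oracle-equivalence checks run 100 random models
  (2–3 levels, $T \le 6$); the overconfidence comparison 50 benchmark
  replicates; the free-energy-inequality sweep 1000 two-state four-step
  models.
* **Deterministic limit.**  With permutation transitions, deterministic
  initial states *and* deterministic likelihoods on every factor, all
  three schemes collapse onto the same forced path (pairwise KL far below
  $10^{-8}$).  If the likelihood stays stochastic, the marginal scheme's
  halved log-messages retain off-path mass of order $e^{-\Theta(T)}$ —
  the floored logs act as boundary sources of a discrete Laplace equation
  along the chain — so agreement is qualitative ("largely abolished")
  rather than exact at machine precision; the unobserved factor likewise
  keeps residual uncertainty by design.

## Limitations

Likelihoods over joint multi-factor states, time-varying or learned
parameters, policies/actions, hierarchical (deep temporal) models,
precision parameters, cyclic graphs and spiking implementations are out of
scope.  The free energies assume the factorised model class described
here; on cyclic graphs the Bethe machinery would need damping and can
misbehave, which is precisely the regime this package does not enter.
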
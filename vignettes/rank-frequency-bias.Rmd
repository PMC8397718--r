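---
title: "Estimating power-law exponents from rank-frequency data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating power-law exponents from rank-frequency data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zipfbias)
```

## The problem

Zipf's law describes rank-frequency data: sort the distinct events of a
sample (word types in a book, species in a survey) by how often they were
observed, and the count of the $r_e$-th most frequent event falls off
approximately as $n(r_e) \propto r_e^{-\gamma}$ with $\gamma \approx 1$ for
natural language. A probabilistic version models each event as carrying a
fixed occurrence probability

$$p(r_p) = \frac{r_p^{-\lambda}}{Z_\lambda}, \qquad
Z_\lambda = \sum_{r_p = 1}^{W} r_p^{-\lambda},$$

where $r_p$ is the event's rank *in the probability distribution* and $W$
the number of possible events; as $W \to \infty$, $Z_\lambda$ becomes the
Riemann zeta function $\zeta(\lambda)$, finite only for $\lambda > 1$.

The subtlety is that for unordered events the analyst never observes
$r_p$. The observed rank $r_e$ is computed from the same sample as the
counts, so rank and count errors are correlated: tail events "bunch up"
above the true probability curve (many low-probability events are observed
slightly more often than their probability rank warrants, and the rest not
at all). The standard discrete power-law maximum-likelihood estimators
treat $r_e$ as if it were $r_p$, i.e. they maximise

$$p(\boldsymbol{n} \mid \lambda) \stackrel{!}{=}
\prod_{r_e=1}^{W} p(x_{(r_e)})^{n(r_e)},$$

which silently conditions on the identity rank mapping. On rank-frequency
data this overestimates $\lambda$, strongly so for $\lambda \lesssim 1.5$
— exactly the regime of natural language.

## The exact likelihood and why it is intractable

Writing $s$ for the (unknown) mapping from probability ranks to empirical
ranks, $s(r_p) = r_e$, any valid $s$ is a permutation of $1..W$, and the
correct likelihood marginalises over all of them:

$$\mathcal{L}(\lambda \mid \boldsymbol{n}) =
\sum_{s \in S(W)} \prod_{r_p=1}^{W} p(x_{r_p})^{n(s(r_p))}.$$

This is the permanent of the $W \times W$ matrix with entries
$a_{ij} = p(x_i)^{n_j}$. `full_loglik()` computes its log by two exact
engines: direct log-sum-exp enumeration of all $W!$ permutations
($W \le 8$), and Ryser's Gray-code inclusion–exclusion ($O(W 2^W)$,
default for $9 \le W \le 25$). Beyond $W = 25$ the package refuses: no
polynomial algorithm is known (the permanent is #P-hard), and that
intractability is precisely why likelihood-free methods are needed for
real vocabularies.

The small worked example shows the size of the effect:

```{r worked-example}
rep <- likelihood_comparison(c(10, 3, 3, 2, 1, 1), W = 6)
c(leading = rep$mle_leading$lambda, full = rep$mle_full$lambda)
```

The leading-term (finite-$W$) estimate is 1.27; accounting for all 720
rank mappings moves the MLE down to 1.16.

### Numerical choices

* All likelihood work is done in log space. The likelihood matrix is
  stored with per-row log scale factors (entries $p^n$ underflow doubles
  for realistic $N$); the naive engine uses log-sum-exp.
* Ryser's alternating sum is accumulated in extended (long-double)
  precision with Neumaier compensation after scaling each row by its
  largest entry. Its inclusion–exclusion can still cancel
  catastrophically on likelihood matrices (zero-padding and tied low
  counts create near-identical columns whose subset sums dwarf the
  permanent), so whenever the estimated cancellation exceeds 6
  significant digits the permanent is recomputed with a
  cancellation-free engine: the column-subset dynamic programme
  $\mathrm{perm}_k(S) = \sum_{j \in S} a_{kj}\,\mathrm{perm}_{k-1}(S
  \setminus \{j\})$, whose terms are all positive, at the same
  $O(W 2^W)$ cost with per-level renormalisation (no possible
  under/overflow). The two engines agree to full precision wherever
  Ryser is stable.
* The likelihood derivative shares the permutation machinery: each
  product term is multiplied by
  $-(N Z'_\lambda / Z_\lambda + \sum_{r_p} n(s(r_p)) \ln r_p)$, carried
  through Ryser's recursion as a dual (first-order) accumulator, so the
  score costs the same $O(W 2^W)$ as the likelihood.
* $\zeta(\lambda)$ is evaluated by `pracma::zeta`; $\zeta'(\lambda)$ by an
  Euler–Maclaurin expansion differentiated term by term ($M = 24$,
  Bernoulli terms through $B_{12}$; truncation error far below double
  precision for $\lambda > 1$). Finite normalizer sums are accumulated in
  compensated extended precision.
* `mle_full()` maximises by Brent-type bounded scalar optimization
  (tolerance $10^{-6}$) on $\lambda \in [0, 4]$ (finite $W$) or
  $(1, 4]$ (unbounded), then cross-checks against a root of the score;
  disagreement beyond $10^{-4}$ raises an error rather than returning
  either answer. Search-bound hits are reported, never clamped. The
  bounds cover the empirically relevant range ($\lambda$ between about 1
  and 2) with a wide margin; the worked-example optima are interior, so
  the choice of bounds does not affect them.

## Samplers

Experiments need exact samplers, because the bias under study lives in
the far tail:

* Finite $W$: inverse-CDF lookup on a precomputed cumulative table —
  exact, $O(\log W)$ per draw.
* Unbounded Zipf: rejection sampling for the zeta distribution with the
  classical floor-of-Pareto dominating envelope (valid for every
  $\lambda > 1$, uniformly bounded rejection rate). No truncation is
  involved: for $\lambda$ near 1 any feasible truncation discards
  non-negligible tail mass and would contaminate the very bias being
  measured.
* Unbounded Zipf–Mandelbrot, $p(r) \propto (r+q)^{-\lambda}$ with integer
  $q \ge 0$: the substitution $m = r + q$ reduces sampling to the zeta
  distribution truncated to $m \ge q + 1$, drawn with the same envelope
  started at $q + 1$. The target/envelope ratio is decreasing in $m$, so
  its value at $q+1$ is the rejection constant and acceptance stays near
  1 for all $(\lambda, q)$. At $q = 0$ the machinery consumes the same
  uniforms as the plain zeta sampler, making the Zipf reduction exact
  draw-for-draw.

All draws, including those made in compiled code, come from R's
Mersenne-Twister stream, so a single `set.seed()` (or the `seed` argument
/ config field) makes every operation bit-reproducible.

`sample_counts()` returns the counts sorted into rank-frequency form
*and* the probability rank of the event occupying each empirical rank.
That second piece is what lets the experiments contrast the estimator on
a-priori-known ranks (where it is consistent) with the same estimator on
empirical ranks (where it is biased) on identical draws.

## Approximate Bayesian computation

For realistic vocabularies the exact likelihood is out of reach, so the
package provides likelihood-free estimators that only require simulating
from the model:

* `abc_rejection()`: draw $\lambda$ from the prior, simulate a dataset of
  the observed size, accept if the distance to the observed data is below
  a fixed $\epsilon$.
* `abc_pmc()`: population Monte Carlo. Generation 0 accepts prior draws;
  each later generation resamples the previous particles by weight,
  perturbs with a Gaussian kernel of variance twice the weighted variance
  of the previous generation (the standard PMC choice; covariance matrix
  in the two-parameter case), rejects proposals outside the prior before
  simulating, and tightens the tolerance to the `survival_fraction`
  quantile of the previous generation's accepted distances. Importance
  weights $w_i \propto \pi(\theta_i) / \sum_j w_j K(\theta_i \mid
  \theta_j)$ correct for sampling from the proposal rather than the
  prior.
* `abc_regression()`: simulate from the prior, summarise each dataset by
  the mean of the log event counts, retain the fraction closest to the
  observed summary, and adjust the retained draws by a local-linear
  regression of $\lambda$ on the summary with Epanechnikov weights.

The default distance is the 1-Wasserstein distance between count vectors,
computed by the quantile coupling after padding the shorter vector with
zeros. Padding is deliberate: unobserved events are genuine zero-count
events, the unobserved tail is where rank-frequency bias originates, and
a distance blind to vocabulary-size differences would discard exactly the
signal that separates nearby exponents. Distances are computed on raw
counts; `pad = FALSE` and `log_counts = TRUE` variants exist for
sensitivity analysis.

Posteriors are weighted Gaussian kernel density estimates (weighted
Silverman bandwidth) on a $\lambda$ grid of resolution 0.001, renormalised
to integrate to 1 on the prior support; the offset $q$ is kept as a
discrete axis — probability mass per integer, no smoothing across $q$ —
because the model defines it as an integer. Under the uniform priors used
throughout, the posterior mode (`map_estimate()`) is proportional to a
maximum-likelihood estimate.

### Defaults and the reasoning behind them

The PMC control parameters are `n_particles = 200`, `n_generations = 10`,
`survival_fraction = 0.5`, priors $\lambda \sim U(1.001, 3)$ (unbounded;
$U(0.5, 3)$ for finite $W$) and $q \sim U\{0..20\}$, with a safety cap of
$100 \times$ `n_particles` simulations per generation. These sizes keep a
full run on $N = 10^4$ observations in the tens of seconds while leaving
the tolerance schedule enough room to contract by roughly $2^{9}$ over
ten generations; they recover $\lambda$ to within a few hundredths in the
package's own experiments, and all are overridable through
`abc_config()`. Simulated datasets always match the observed $N$, so the
distance compares like with like.

For the two-parameter model the proposal perturbs $(\lambda, q)$ jointly
with a bivariate Gaussian (covariance $2 \Sigma_w$), rounds $q$ to the
nearest integer, and evaluates the kernel at the integer difference when
computing importance weights — a latent-continuous treatment of a
discrete parameter that keeps the PMC recursion unchanged. If the $q$
axis collapses (e.g. a point prior on $q$), a small floor variance keeps
the kernel proper.

ABC-regression uses $M = 10{,}000$ prior simulations and retains the
closest 10%. These are conventional regression-ABC sizes; the point
estimate is the weighted mean of the adjusted draws.

## What the simulations emulate — and what they do not

The synthetic generator draws i.i.d. events from a fixed Zipf or
Zipf–Mandelbrot distribution. That is exactly the setting in which the
bias of the leading-term estimators is a theorem-like fact and in which
ABC with a well-chosen distance should recover the truth; the package's
tests verify both (positive leading-term bias at $\lambda = 1.1$, ABC
mean error within 0.05, agreement of the two ABC variants within 0.05 on
model-generated text). Natural language is not an i.i.d. draw from a
fixed distribution: burstiness, topical drift and productive morphology
all violate the model. On real books the two ABC variants typically
disagree — each distance measure projects the misspecification
differently — and that disagreement is itself the diagnostic. Passing the
package's tests therefore certifies the estimators under the model, not
the model itself; `scripts/book_demo.R` reports the divergence on real
texts without asserting values.

The experiment drivers are scaled for interactive use:
`bias_sweep_lambda()` and `bias_sweep_N()` default to around ten
replicates per grid point (the package's own checks use up to 20
replicates at $N = 10^4$–$10^5$), with per-cell seeds
`seed + j*1e6 + k` so any cell is independently re-runnable and estimator
failures are counted and excluded rather than imputed. Full
publication-scale sweeps (hundreds of grid points × 100 replicates) are a
matter of raising those arguments.

## Degenerate inputs and edge behaviour

* A single observed event (`counts = [N]`) leaves the unbounded
  likelihood monotone in $\lambda$; the estimators raise a boundary error
  rather than returning the search bound.
* All-equal counts drive the finite-$W$ leading-term MLE to the uniform
  boundary $\lambda = 0$, reported with a warning.
* Ties between equally frequent events are broken by first occurrence
  (token pipeline) or by ascending probability rank (sampler); every
  likelihood here is invariant to the choice.
* Text cleaning lower-cases, strips Unicode punctuation and symbol
  characters (except `#`), replaces each maximal digit run by `#`, and
  splits on whitespace. Keeping `#` exempt makes the pipeline idempotent.
  Published tokenizations differ in hyphen/apostrophe/number handling;
  book-level estimates can shift at the second decimal under other
  choices.

## Known limitations

* Exact inference is capped at $W = 25$ events by design; there is no
  approximate-permanent fallback, because controlled error bounds for
  alternating-sign inclusion–exclusion at larger $W$ would be spurious
  precision.
* The ABC posterior inherits the usual ABC approximation error: it
  targets the distribution of parameters given a *distance*, not the
  exact posterior, and its quality depends on the distance retaining the
  information in the data.
* The empirical rank-frequency exponent $\gamma$ (the regression-style
  descriptive exponent) is deliberately out of scope: the package
  estimates the probability-model exponent $\lambda$.
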
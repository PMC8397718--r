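# zipfbias

Estimation of Zipf and Zipf–Mandelbrot exponents from rank-frequency
count data — word frequencies, species abundances, or any sample of
unordered discrete events tabulated from most to least frequent.

## The problem

Rank-frequency data conflates two different ranks. The probability model

$$p(r_p) = \frac{r_p^{-\lambda}}{Z_\lambda}, \qquad
Z_\lambda = \sum_{r_p=1}^{W} r_p^{-\lambda}
\;\;(\to \zeta(\lambda) \text{ as } W \to \infty)$$

is indexed by an event's rank $r_p$ in the underlying distribution, but
the data only reveal the empirical rank $r_e$, computed from the same
sample as the counts. The prevailing discrete power-law MLEs maximise
$\prod_{r_e} p(x_{(r_e)})^{n(r_e)}$, i.e. they assume $r_e = r_p$. On
rank-frequency data this inflates $\hat\lambda$, strongly for
$\lambda \lesssim 1.5$ — the regime of natural language.

The correct likelihood marginalises over every mapping
$s(r_p) = r_e$ (a permutation of $1..W$):

$$\mathcal{L}(\lambda \mid \boldsymbol{n}) = \sum_{s \in S(W)}
\prod_{r_p=1}^{W} p(x_{r_p})^{n(s(r_p))},$$

which is the permanent of the matrix $a_{ij} = p(x_i)^{n_j}$ — exact but
computable only for small event sets (Ryser's algorithm, $O(W 2^W)$,
capped here at $W = 25$). For realistic vocabularies the package provides
likelihood-free estimators: ABC rejection, ABC population Monte Carlo
with the Wasserstein distance between count vectors, and
regression-adjusted ABC with a mean-log-count summary statistic.

## Worked example

The exact likelihood on a small dataset, $n = [10, 3, 3, 2, 1, 1]$ with
$W = 6$ known:

```r
library(zipfbias)
rep <- likelihood_comparison(c(10, 3, 3, 2, 1, 1), W = 6)
rep$mle_leading
#> <zipf_fit:leading_finite> lambda = 1.266462  (loglik = -29.1856)
rep$mle_full
#> <zipf_fit:full> lambda = 1.158086  (loglik = -25.8348)
```

The leading-term (finite-$W$) estimator gives $\hat\lambda = 1.27$;
summing over all $6! = 720$ rank mappings moves the MLE to
$\hat\lambda = 1.16$. Ignoring rank-mapping uncertainty inflates the
exponent even at $N = 20$.

At realistic scale, the same bias and its likelihood-free correction:

```r
samp <- sample_counts(zipf_model(1.1), 1e4, seed = 2026)  # true lambda = 1.1
samp
#> <rank_sample> N = 10000, W_obs = 5361; head of counts: 955 454 263 191 146 141 107 93

mle_leading_unbounded(samp$counts)$lambda      # leading-term MLE on empirical ranks
#> 1.176                                        # biased upward by +0.08

res <- abc_pmc(samp$counts, "zipf", abc_config(seed = 7))
res$posterior
#> <abc_posterior> MAP: lambda = 1.100; 95% CI for lambda: [1.097, 1.107]
```

The ABC-PMC posterior mode recovers the true exponent to the grid
resolution, where the leading-term estimate is off by +0.08. Zipf–Mandelbrot
inference ($p(r) \propto (r+q)^{-\lambda}$) works the same way with
`model_family = "zipf_mandelbrot"` and returns a joint posterior over
$(\lambda, q)$ with $q$ kept integer.

A thin command-line wrapper covering simulation, exact and ABC fitting,
bias sweeps and the book pipeline is installed at `exec/zipfbias` (see its
header for usage); `scripts/book_demo.R` (network required) reproduces the
real-book analysis where the ABC variants disagree — the package's
diagnostic for model misspecification.

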
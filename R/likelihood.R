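# Exact likelihoods for rank-frequency data.
#
# The full likelihood marginalises over every mapping s of probability
# ranks onto empirical ranks:
#   L(lambda | n) = sum_{s in S(W)} prod_{r_p=1}^{W} p(r_p)^{n(s(r_p))}
# which is the permanent of the W x W matrix with entries
# p(r_p = i)^{n(j)}. The prevailing estimators keep only the identity-
# permutation term, which is the source of their bias.

perm_cache <- new.env(parent = emptyenv())

# All permutations of 1..n as an (n! x n) matrix, cached.
all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(perm_cache[[key]])) return(perm_cache[[key]])
  if (n == 1) {
    P <- matrix(1L, 1, 1)
  } else {
    sub <- all_permutations(n - 1L)
    P <- do.call(rbind, lapply(seq_len(n), function(k) {
      rest <- seq_len(n)[-k]
      cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
    }))
    storage.mode(P) <- "integer"
  }
  perm_cache[[key]] <- P
  P
}

# Pad counts with zeros to length W (unobserved events contribute the
# factor p^0 = 1; the only reading consistent with letting W grow).
pad_counts <- function(counts, W) {
  counts <- as.integer(counts)
  if (W < length(counts))
    stop("W must be at least the number of observed events", call. = FALSE)
  c(counts, integer(W - length(counts)))
}

#' Likelihood matrix of the permutation-sum likelihood
#'
#' The W x W matrix with entries \eqn{a_{ij} = p(r_p = i)^{n_j}} whose
#' permanent is the full likelihood. Entries underflow double precision for
#' realistic counts, so the matrix is stored row-scaled: \code{entries[i, ]
#' = exp(log a[i, ] - row_log_scale[i])}, and the permanent picks up
#' \code{exp(sum(row_log_scale))}.
#'
#' @param counts a [rank_counts()] vector (zero-padded to length \code{W}).
#' @param lambda power-law exponent.
#' @param W event-set size (finite, at least the number of observed events).
#' @param q Zipf-Mandelbrot offset (default 0).
#' @return object of class \code{"likelihood_matrix"} with fields
#'   \code{entries}, \code{row_log_scale}, \code{log_entries}.
#' @export
likelihood_matrix <- function(counts, lambda, W = NULL, q = 0) {
  counts <- as_rank_counts(counts)
  if (is.null(W)) W <- w_obs(counts)
  n <- pad_counts(counts, W)
  logp <- -lambda * log(seq_len(W) + q) - log(normalizer(lambda, W, q))
  logA <- outer(logp, n)            # logA[i, j] = n_j * log p_i
  scale <- apply(logA, 1, max)
  structure(list(entries = exp(logA - scale), row_log_scale = scale,
                 log_entries = logA, counts = n, lambda = lambda, W = W, q = q),
            class = "likelihood_matrix")
}

#' Log of the permanent of a non-negative matrix
#'
#' Two exact engines: \code{"naive"} enumerates all \eqn{W!} permutations
#' with log-sum-exp (default for \eqn{W \le 8}); \code{"ryser"} uses
#' Ryser's Gray-code inclusion-exclusion, \eqn{O(W 2^W)}, with per-row
#' scaling and compensated extended-precision accumulation (default for
#' \eqn{9 \le W \le 25}). Above \eqn{W = 25} the computation is refused:
#' the factorial/exponential cost is intrinsic — exact permanents, and with
#' them the full likelihood, are intractable for realistic vocabularies,
#' which is what motivates the ABC estimators.
#'
#' @param x a [likelihood_matrix()], or a square matrix of non-negative
#'   entries, or a square matrix of log-entries if \code{log = TRUE}.
#' @param method \code{"auto"}, \code{"naive"} or \code{"ryser"}.
#' @param log are the entries of a plain matrix already on the log scale?
#' @return the log of the permanent.
#' @export
log_permanent <- function(x, method = c("auto", "naive", "ryser"), log = FALSE) {
  method <- match.arg(method)
  if (inherits(x, "likelihood_matrix")) {
    logA <- x$log_entries
  } else {
    stopifnot(is.matrix(x), nrow(x) == ncol(x))
    if (log) logA <- x
    else {
      if (any(x < 0)) stop("matrix entries must be non-negative", call. = FALSE)
      logA <- suppressWarnings(base::log(x))
    }
  }
  W <- nrow(logA)
  if (W > 25) stop("permanent computation capped at W = 25 (cost O(W 2^W))",
                   call. = FALSE)
  if (method == "auto") method <- if (W <= 8) "naive" else "ryser"
  if (method == "naive") {
    if (W > 9) stop("naive enumeration limited to W <= 9", call. = FALSE)
    P <- all_permutations(W)
    idx <- matrix(rep(seq_len(W), each = nrow(P)) + (P - 1L) * W, nrow(P))
    logsumexp(rowSums(matrix(logA[as.vector(idx)], nrow(P))))
  } else {
    res <- cpp_ryser(logA, matrix(0, W, W), FALSE)
    if (res$digits_lost > 25)
      warning(sprintf(
        "Ryser alternating sum cancelled %.1f significant digits even in extended precision",
        res$digits_lost))
    res$log_perm
  }
}

#' Leading-term (identity-permutation) log-likelihood
#'
#' \eqn{\sum_{r=1}^{W_{obs}} n_r (-\lambda \log r - \log Z_\lambda)}: the
#' single term of the permutation-sum likelihood in which empirical ranks
#' are assumed to equal probability ranks. This is the (biased) likelihood
#' maximised by the prevailing estimators.
#'
#' @param counts a [rank_counts()] vector.
#' @param lambda power-law exponent (\eqn{> 1} if \code{W = Inf}).
#' @param W event-set size, possibly \code{Inf}; must be at least the
#'   number of observed events.
#' @param q Zipf-Mandelbrot offset (default 0).
#' @return the log-likelihood (0 for \code{W = 1}).
#' @export
leading_term_loglik <- function(counts, lambda, W = Inf, q = 0) {
  counts <- as_rank_counts(counts)
  if (is.finite(W) && W < w_obs(counts))
    stop("W must be at least the number of observed events", call. = FALSE)
  r <- seq_len(w_obs(counts))
  lZ <- log(normalizer(lambda, W, q))
  sum(as.integer(counts) * (-lambda * log(r + q) - lZ))
}

#' Log-likelihood of one rank mapping
#'
#' \eqn{\sum_{r_p=1}^{W} n(s(r_p)) \log p(r_p)} for a given permutation
#' \code{s} of probability ranks onto empirical ranks. With the identity
#' mapping this equals [leading_term_loglik()].
#'
#' @param counts a [rank_counts()] vector, zero-padded to \code{length(mapping)}.
#' @param mapping a permutation of \code{1..W} (see [rank_mapping()]).
#' @param model a [zipf_model()] or [zipf_mandelbrot_model()] with finite
#'   \code{W = length(mapping)} (an unbounded model may be supplied if its
#'   pmf is evaluable on \code{1..W}).
#' @return the log-likelihood of the data under that mapping.
#' @export
permutation_term_loglik <- function(counts, mapping, model) {
  counts <- as_rank_counts(counts)
  s <- rank_mapping(mapping)
  W <- length(s)
  n <- pad_counts(counts, W)
  sum(n[s] * log(pmf(model, seq_len(W))))
}

# Shared core: log-likelihood and (optionally) the score
# d log L / d lambda, via naive enumeration (W <= 8) or dual-number Ryser.
full_loglik_core <- function(counts, lambda, W, q = 0, want_score = FALSE) {
  counts <- as_rank_counts(counts)
  if (!is.finite(W) || W < w_obs(counts))
    stop("full likelihood requires finite W >= number of observed events",
         call. = FALSE)
  if (W > 25) stop("full likelihood capped at W = 25 events", call. = FALSE)
  n <- pad_counts(counts, W)
  N <- sum(n)
  Z <- normalizer(lambda, W, q)
  logp <- -lambda * log(seq_len(W) + q) - log(Z)
  logA <- outer(logp, n)
  if (!want_score) {
    return(list(loglik = log_permanent(logA, log = TRUE)))
  }
  alpha <- N * normalizer_derivative(lambda, W, q) / Z
  B <- outer(log(seq_len(W) + q), n)   # B[i, j] = n_j log(i + q)
  if (W <= 8) {
    P <- all_permutations(W)
    idx <- matrix(rep(seq_len(W), each = nrow(P)) + (P - 1L) * W, nrow(P))
    terms <- rowSums(matrix(logA[as.vector(idx)], nrow(P)))
    bsum <- rowSums(matrix(B[as.vector(idx)], nrow(P)))
    m <- max(terms)
    Ls <- sum(exp(terms - m))
    Ts <- sum(bsum * exp(terms - m))
    list(loglik = m + log(Ls), score = -(alpha + Ts / Ls))
  } else {
    res <- cpp_ryser(logA, B, TRUE)
    if (res$digits_lost > 25)
      warning(sprintf(
        "Ryser alternating sum cancelled %.1f significant digits even in extended precision",
        res$digits_lost))
    list(loglik = res$log_perm, score = -(alpha + res$grad_ratio))
  }
}

#' Full permutation-sum log-likelihood
#'
#' Log of \eqn{\sum_{s \in S(W)} \prod_{r_p} p(r_p)^{n(s(r_p))}}, computed
#' as the log-permanent of the [likelihood_matrix()]. Exact; cost grows as
#' \eqn{O(W 2^W)}, capped at \eqn{W = 25}.
#'
#' @inheritParams likelihood_matrix
#' @return the log-likelihood; always at least [leading_term_loglik()]
#'   evaluated at the same parameters, since the sum contains the
#'   identity-permutation term.
#' @export
full_loglik <- function(counts, lambda, W = NULL, q = 0) {
  counts <- as_rank_counts(counts)
  if (is.null(W)) W <- w_obs(counts)
  full_loglik_core(counts, lambda, W, q)$loglik
}

#' Derivative of the full permutation-sum likelihood
#'
#' Returns \eqn{dL/d\lambda} of the likelihood itself (not its log),
#' computed by the same permutation machinery with the per-permutation
#' factor \eqn{-(N Z'_\lambda / Z_\lambda + \sum_{r_p} n(s(r_p)) \log r_p)}
#' multiplying each product term. Vanishes at the maximiser; note the
#' value underflows to zero for data whose likelihood itself underflows
#' (root-finding in [mle_full()] therefore uses the score
#' \eqn{d \log L / d\lambda} internally).
#'
#' @inheritParams likelihood_matrix
#' @return \eqn{dL/d\lambda}, a real number.
#' @export
full_loglik_gradient <- function(counts, lambda, W = NULL, q = 0) {
  counts <- as_rank_counts(counts)
  if (is.null(W)) W <- w_obs(counts)
  res <- full_loglik_core(counts, lambda, W, q, want_score = TRUE)
  res$score * exp(res$loglik)
}

new_zipf_fit <- function(lambda, method, objective, boundary = FALSE, ...) {
  structure(list(lambda = lambda, method = method, objective = objective,
                 boundary = boundary, ...), class = "zipf_fit")
}

#' @export
print.zipf_fit <- function(x, ...) {
  cat(sprintf("<zipf_fit:%s> lambda = %.6f  (loglik = %.6g%s)\n",
              x$method, x$lambda, x$objective,
              if (isTRUE(x$boundary)) ", at search boundary" else ""))
  invisible(x)
}

#' Leading-term MLE for an unbounded event set
#'
#' The prevailing discrete power-law estimator as applied to rank-frequency
#' data: maximises \eqn{-N \log \zeta(\lambda) - \lambda \sum_r n_r \log r}
#' over \eqn{\lambda \in (1, \lambda_{max}]} with ranks taken at face
#' value (and \code{xmin = 1}). Biased upward on empirical rank-frequency
#' data with exponents below about 1.5; unbiased when \code{ranks} are the
#' true probability ranks (a-priori-ordered data).
#'
#' @param counts a [rank_counts()] vector.
#' @param lambda_max upper search bound (default 4).
#' @param ranks optional vector of a-priori known probability ranks for each
#'   count (defaults to the empirical ranks \code{seq_along(counts)}).
#' @return a \code{"zipf_fit"} object with element \code{lambda}.
#' @export
mle_leading_unbounded <- function(counts, lambda_max = 4, ranks = NULL) {
  counts <- as_rank_counts(counts)
  if (is.null(ranks)) ranks <- seq_len(w_obs(counts))
  stopifnot(length(ranks) == w_obs(counts))
  n <- as.integer(counts)
  S <- sum(n * log(ranks))
  if (S <= 0)
    stop("degenerate data: all mass at rank 1, likelihood increases without bound",
         call. = FALSE)
  N <- sum(n)
  obj <- function(l) -N * log(zeta_fun(l)) - l * S
  opt <- optimize(obj, lower = 1 + 1e-9, upper = lambda_max, maximum = TRUE,
                  tol = 1e-6)
  if (opt$maximum > lambda_max - 1e-4)
    stop("maximizer at the lambda_max search boundary; increase lambda_max",
         call. = FALSE)
  new_zipf_fit(opt$maximum, "leading_unbounded", opt$objective)
}

#' Leading-term MLE for a finite event set
#'
#' Maximises [leading_term_loglik()] with known finite \code{W} over
#' \eqn{\lambda \in [0, \lambda_{max}]} (a finite event set permits
#' \eqn{\lambda \le 1}). Still a leading-term — hence biased — estimator on
#' rank-frequency data, but less so than the unbounded version when
#' \code{W} is known.
#'
#' @inheritParams mle_leading_unbounded
#' @param W known event-set size, at least the number of observed events.
#' @return a \code{"zipf_fit"} object; a boundary solution at 0 or
#'   \code{lambda_max} is flagged with a warning and \code{boundary = TRUE}.
#' @export
mle_leading_finite <- function(counts, W, lambda_max = 4) {
  counts <- as_rank_counts(counts)
  if (w_obs(counts) < 1) stop("empty counts", call. = FALSE)
  if (W < 2 || w_obs(counts) < 2 && W == 1)
    stop("lambda is undefined for a single-event set", call. = FALSE)
  opt <- optimize(function(l) leading_term_loglik(counts, l, W),
                  lower = 0, upper = lambda_max, maximum = TRUE, tol = 1e-6)
  boundary <- opt$maximum < 1e-4 || opt$maximum > lambda_max - 1e-4
  lambda <- if (opt$maximum < 1e-4 &&
                leading_term_loglik(counts, 0, W) >= opt$objective) 0
            else opt$maximum
  if (boundary)
    warning("leading-term MLE at the boundary of the lambda search interval")
  new_zipf_fit(lambda, "leading_finite",
               leading_term_loglik(counts, lambda, W), boundary = boundary)
}

#' MLE of the full permutation-sum likelihood
#'
#' Maximises [full_loglik()] over \eqn{\lambda \in [0, \lambda_{max}]} by
#' bounded scalar optimization, then cross-checks the interior maximiser by
#' root-finding on the score \eqn{d \log L / d\lambda}; the two routes must
#' agree within 1e-4 or an inconsistency error is raised.
#'
#' @inheritParams mle_leading_finite
#' @param W event-set size (default: number of observed events); capped at 25.
#' @return a \code{"zipf_fit"} object.
#' @export
mle_full <- function(counts, W = NULL, lambda_max = 4) {
  counts <- as_rank_counts(counts)
  if (is.null(W)) W <- w_obs(counts)
  if (W < 2) stop("lambda is undefined for a single-event set", call. = FALSE)
  opt <- optimize(function(l) full_loglik_core(counts, l, W)$loglik,
                  lower = 0, upper = lambda_max, maximum = TRUE, tol = 1e-6)
  lhat <- opt$maximum
  boundary <- lhat < 1e-4 || lhat > lambda_max - 1e-4
  if (boundary) {
    warning("full-likelihood MLE at the boundary of the lambda search interval")
    return(new_zipf_fit(lhat, "full", opt$objective, boundary = TRUE))
  }
  score <- function(l) full_loglik_core(counts, l, W, want_score = TRUE)$score
  lo <- max(1e-6, lhat - 0.05); hi <- min(lambda_max, lhat + 0.05)
  while (score(lo) <= 0 && lo > 1e-6) lo <- max(1e-6, lo - 0.2)
  while (score(hi) >= 0 && hi < lambda_max) hi <- min(lambda_max, hi + 0.2)
  if (score(lo) > 0 && score(hi) < 0) {
    root <- uniroot(score, c(lo, hi), tol = 1e-8)$root
    if (abs(root - lhat) > 1e-4)
      stop(sprintf(
        "inconsistent MLE: maximization gives %.6f but score root is %.6f",
        lhat, root), call. = FALSE)
    lhat <- root
  }
  new_zipf_fit(lhat, "full", full_loglik_core(counts, lhat, W)$loglik)
}
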
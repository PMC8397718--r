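#' Zipf (discrete power-law) model over ranked events
#'
#' Defines the probability distribution \eqn{p(r_p) = r_p^{-\lambda} / Z_\lambda}
#' over probability ranks \eqn{r_p = 1, \dots, W}, with normalizer
#' \eqn{Z_\lambda = \sum_{r=1}^{W} r^{-\lambda}}. With an unbounded event set
#' (\code{W = Inf}) the normalizer is the Riemann zeta function
#' \eqn{\zeta(\lambda)}, which requires \eqn{\lambda > 1}.
#'
#' @param lambda positive power-law exponent.
#' @param W event-set size: a positive integer, or \code{Inf} for an
#'   unbounded event set.
#' @return an object of class \code{c("zipf_model", "power_law_model")} with
#'   fields \code{lambda}, \code{q} (0), \code{W}, \code{Z} (normalizer) and
#'   \code{Zprime} (its derivative in \code{lambda}).
#' @examples
#' m <- zipf_model(2, W = Inf)
#' pmf(m, 1:5)
#' @seealso [zipf_mandelbrot_model()], [sample_counts()], [pmf()]
#' @export
zipf_model <- function(lambda, W = Inf) {
  new_power_law_model(lambda, q = 0, W = W, family = "zipf")
}

#' Zipf-Mandelbrot model over ranked events
#'
#' The two-parameter generalisation \eqn{p(r_p) \propto (r_p + q)^{-\lambda}}
#' with integer offset \eqn{q \ge 0} flattening the head of the distribution.
#' \code{q = 0} reduces exactly to [zipf_model()].
#'
#' @inheritParams zipf_model
#' @param q non-negative integer offset.
#' @return an object of class
#'   \code{c("zipf_mandelbrot_model", "power_law_model")}.
#' @export
zipf_mandelbrot_model <- function(lambda, q = 0, W = Inf) {
  new_power_law_model(lambda, q = q, W = W, family = "zipf_mandelbrot")
}

new_power_law_model <- function(lambda, q, W, family) {
  stopifnot(is.numeric(lambda), length(lambda) == 1, lambda >= 0)
  if (length(q) != 1 || q < 0 || q != round(q))
    stop("q must be a non-negative integer", call. = FALSE)
  if (!(is.infinite(W) || (W >= 1 && W == round(W))))
    stop("W must be a positive integer or Inf", call. = FALSE)
  Z <- normalizer(lambda, W, q)
  Zp <- normalizer_derivative(lambda, W, q)
  structure(
    list(lambda = lambda, q = as.integer(round(q)), W = W, Z = Z, Zprime = Zp,
         family = family),
    class = c(if (family == "zipf") "zipf_model" else "zipf_mandelbrot_model",
              "power_law_model"))
}

#' Normalizer of the (shifted) discrete power law
#'
#' \eqn{Z_\lambda = \sum_{r=1}^{W} (r+q)^{-\lambda}}; for \code{W = Inf} and
#' \code{q = 0} this is the Riemann zeta function \eqn{\zeta(\lambda)}, and
#' for \code{q > 0} it is \eqn{\zeta(\lambda) - \sum_{r=1}^{q} r^{-\lambda}}.
#' Finite sums are accumulated in extended precision with compensated
#' summation.
#'
#' @inheritParams zipf_model
#' @param q non-negative integer offset (Zipf-Mandelbrot); default 0.
#' @return the positive normalizing constant.
#' @export
normalizer <- function(lambda, W, q = 0) {
  check_norm_args(lambda, W, q)
  if (is.infinite(W)) {
    z <- zeta_fun(lambda)
    if (q > 0) z <- z - sum(seq_len(q)^(-lambda))
    z
  } else {
    cpp_power_sum(W, lambda, q)$Z
  }
}

#' Derivative of the normalizer with respect to the exponent
#'
#' \eqn{Z'_\lambda = -\sum_{r=1}^{W} (r+q)^{-\lambda} \log(r+q)}, equal to
#' \eqn{\zeta'(\lambda)} in the unbounded case. Strictly negative whenever
#' the support contains a rank with \eqn{r + q \ge 2}.
#'
#' @inheritParams normalizer
#' @return a real number (0 only for \code{W = 1}, \code{q = 0}).
#' @export
normalizer_derivative <- function(lambda, W, q = 0) {
  check_norm_args(lambda, W, q)
  if (is.infinite(W)) {
    zp <- zeta_deriv(lambda)
    if (q > 0) zp <- zp + sum(seq_len(q)^(-lambda) * log(seq_len(q)))
    zp
  } else {
    cpp_power_sum(W, lambda, q)$Zprime
  }
}

check_norm_args <- function(lambda, W, q) {
  if (q < 0 || q != round(q)) stop("q must be a non-negative integer", call. = FALSE)
  if (is.infinite(W)) {
    if (lambda <= 1)
      stop("normalizer diverges: unbounded event set requires lambda > 1",
           call. = FALSE)
  } else if (W < 1 || W != round(W)) {
    stop("W must be a positive integer or Inf", call. = FALSE)
  }
  invisible(TRUE)
}

#' Probability mass function of a ranked power-law model
#'
#' @param model a [zipf_model()] or [zipf_mandelbrot_model()].
#' @param r vector of probability ranks (positive integers, at most
#'   \code{model$W}).
#' @return \eqn{(r+q)^{-\lambda} / Z}, strictly decreasing in \code{r}.
#' @export
pmf <- function(model, r) {
  stopifnot(inherits(model, "power_law_model"))
  if (any(r < 1 | r != round(r)) || any(r > model$W))
    stop("rank out of range 1..W", call. = FALSE)
  (r + model$q)^(-model$lambda) / model$Z
}

#' @export
print.power_law_model <- function(x, ...) {
  cat(sprintf("<%s> lambda = %g, q = %d, W = %s, Z = %.6g\n",
              x$family, x$lambda, x$q,
              if (is.infinite(x$W)) "unbounded" else format(x$W), x$Z))
  invisible(x)
}

#' Draw a rank-frequency sample from a power-law model
#'
#' Draws \code{N} i.i.d. events and tabulates them into rank-frequency form.
#' Bounded models use an exact inverse-CDF table; unbounded models use exact
#' rejection sampling for the zeta distribution (Devroye-style dominating
#' envelope, so no truncation of the tail), with Zipf-Mandelbrot draws
#' thinned against the zeta envelope. Because the empirical ranking is
#' computed from the same sample as the counts, the returned object also
#' records which probability rank landed at each empirical rank — the
#' ingredient needed to contrast a-priori-ranked data with rank-frequency
#' data.
#'
#' @param model a [zipf_model()] or [zipf_mandelbrot_model()].
#' @param N number of observations to draw.
#' @param seed integer seed (optional; draws use R's RNG either way).
#' @return an object of class \code{"rank_sample"}: a list with
#'   \describe{
#'     \item{counts}{[rank_counts()] vector, sorted non-increasing;}
#'     \item{prob_rank}{probability rank of the event at each empirical rank
#'       (ties in counts are broken by ascending probability rank);}
#'     \item{mapping}{for fully-enumerable finite \code{W}: the permutation
#'       \code{s} with \code{s[r_p] = r_e}, unobserved events assigned the
#'       remaining empirical ranks in probability-rank order; \code{NULL}
#'       for unbounded models.}
#'   }
#' @export
sample_counts <- function(model, N, seed = NULL) {
  stopifnot(inherits(model, "power_law_model"), N >= 1)
  N <- as.integer(N)
  with_seed(seed, function() {
    if (is.infinite(model$W)) {
      draws <- if (model$q == 0) cpp_sample_zeta(N, model$lambda)
               else cpp_sample_zm(N, model$lambda, model$q)
    } else {
      draws <- as.numeric(cpp_sample_finite(N, model$lambda, model$q, model$W))
    }
    tab <- cpp_rank_counts(draws)
    counts <- rank_counts(tab$counts)
    mapping <- NULL
    if (is.finite(model$W)) {
      s <- integer(model$W)
      s[tab$prob_rank] <- seq_along(tab$prob_rank)
      unobserved <- setdiff(seq_len(model$W), tab$prob_rank)
      if (length(unobserved))
        s[unobserved] <- length(tab$prob_rank) + seq_along(unobserved)
      mapping <- s
    }
    structure(list(counts = counts, prob_rank = tab$prob_rank,
                   mapping = mapping, model = model, N = N),
              class = "rank_sample")
  })
}

#' @export
print.rank_sample <- function(x, ...) {
  cat(sprintf("<rank_sample> N = %d, W_obs = %d; head of counts: %s\n",
              x$N, length(x$counts),
              paste(head(unclass(x$counts), 8), collapse = " ")))
  invisible(x)
}

#' Serialize / deserialize model parameters as JSON
#'
#' Round-trips \code{\{"family", "lambda", "q", "W"\}} with \code{"unbounded"}
#' standing for an infinite event set.
#'
#' @param model a power-law model object.
#' @return \code{model_to_json}: a JSON string; \code{model_from_json}: a
#'   model object.
#' @export
model_to_json <- function(model) {
  stopifnot(inherits(model, "power_law_model"))
  jsonlite::toJSON(list(family = model$family, lambda = model$lambda,
                        q = model$q,
                        W = if (is.infinite(model$W)) "unbounded" else model$W),
                   auto_unbox = TRUE)
}

#' @rdname model_to_json
#' @param json a JSON string produced by \code{model_to_json}.
#' @export
model_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  W <- if (identical(x$W, "unbounded")) Inf else as.numeric(x$W)
  if (identical(x$family, "zipf")) zipf_model(x$lambda, W)
  else zipf_mandelbrot_model(x$lambda, x$q, W)
}
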
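#' Rank-frequency count vector
#'
#' The universal input to every estimator in the package: counts of each
#' distinct event, sorted from most to least frequent. Index \eqn{r_e} is an
#' event's empirical rank; note that for unordered events this rank is
#' derived from the same sample as the counts, which is exactly what makes
#' the leading-term likelihood biased.
#'
#' @param x vector of positive integer counts, in any order.
#' @return an integer vector of class \code{"rank_counts"}, sorted
#'   non-increasing, with attributes \code{N} (total observations) and
#'   \code{W_obs} (number of distinct events).
#' @examples
#' rank_counts(c(2, 8, 1, 6, 3, 1))
#' @export
rank_counts <- function(x) {
  if (length(x) == 0) {
    return(structure(integer(0), N = 0L, W_obs = 0L, class = "rank_counts"))
  }
  if (any(!is.finite(x)) || any(x < 1) || any(x != round(x)))
    stop("counts must be positive integers", call. = FALSE)
  x <- sort(as.integer(round(x)), decreasing = TRUE)
  structure(x, N = sum(x), W_obs = length(x), class = "rank_counts")
}

#' @export
print.rank_counts <- function(x, ...) {
  cat(sprintf("<rank_counts> N = %d, W_obs = %d\n", attr(x, "N"), attr(x, "W_obs")))
  print(as.integer(x))
  invisible(x)
}

n_total <- function(counts) sum(as.integer(counts))
w_obs <- function(counts) length(counts)

as_rank_counts <- function(x) {
  if (inherits(x, "rank_counts")) x else rank_counts(x)
}

#' Tabulate a token sequence into rank-frequency counts
#'
#' @param tokens character (or atomic) vector of event labels.
#' @return a [rank_counts()] vector; ties between equally frequent events
#'   are broken by first occurrence, which no likelihood in this package
#'   depends on.
#' @examples
#' counts_from_tokens(c("a", "b", "a", "c", "a", "b"))
#' @export
counts_from_tokens <- function(tokens) {
  if (length(tokens) == 0) return(rank_counts(integer(0)))
  tab <- table(factor(tokens, levels = unique(tokens)))
  rank_counts(as.integer(tab))
}

#' Clean raw text into word tokens
#'
#' Applies, in order: Unicode lower-casing; removal of punctuation and
#' symbol characters (Unicode categories P* and S*, except the literal
#' \code{#}); replacement of every maximal digit run (category Nd) by the
#' single symbol \code{#}; splitting on whitespace. Keeping \code{#} out of
#' the punctuation strip makes the pipeline idempotent. The function is
#' deterministic and locale-independent.
#'
#' @param raw a character vector of UTF-8 text (concatenated before
#'   tokenization).
#' @return character vector of tokens; empty tokens dropped.
#' @examples
#' clean_text("Hello, World! 42 times.")
#' @export
clean_text <- function(raw) {
  x <- paste(raw, collapse = " ")
  x <- tolower(x)
  x <- gsub("(?!#)[\\p{P}\\p{S}]", "", x, perl = TRUE)
  x <- gsub("\\p{Nd}+", "#", x, perl = TRUE)
  toks <- strsplit(x, "\\s+", perl = TRUE)[[1]]
  toks[nzchar(toks)]
}

#' 1-Wasserstein distance between rank-frequency datasets
#'
#' The shorter count vector is padded with zeros to the common length
#' \eqn{L} — unobserved tail events are genuinely zero-count events, and the
#' unobserved tail is precisely where rank-frequency bias originates, so
#' the distance must see vocabulary-size differences. The distance is then
#' the quantile coupling \eqn{\frac{1}{L}\sum_k |a_{(k)} - b_{(k)}|} of the
#' two padded empirical count distributions.
#'
#' @param a,b [rank_counts()] vectors (non-empty).
#' @param pad if \code{FALSE}, compare only the top \code{min(W_a, W_b)}
#'   ranks instead of zero-padding (sensitivity variant).
#' @param log_counts if \code{TRUE}, compare \code{log} counts, padding
#'   with 0 (= log 1) (sensitivity variant).
#' @return non-negative real; 0 iff the padded sorted vectors are equal.
#' @export
wasserstein_distance <- function(a, b, pad = TRUE, log_counts = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0)
    stop("wasserstein_distance requires non-empty count vectors", call. = FALSE)
  a <- sort(a, decreasing = TRUE)
  b <- sort(b, decreasing = TRUE)
  if (log_counts) { a <- log(a); b <- log(b) }
  if (pad) {
    L <- max(length(a), length(b))
    a <- c(a, numeric(L - length(a)))
    b <- c(b, numeric(L - length(b)))
  } else {
    L <- min(length(a), length(b))
    a <- a[seq_len(L)]; b <- b[seq_len(L)]
  }
  mean(abs(a - b))
}

#' Read and write rank-frequency count files
#'
#' \code{read_counts} accepts either a two-column TSV \code{event<TAB>count}
#' (header optional) or one integer count per line. \code{write_counts}
#' writes one count per line. \code{read_tokens} reads a UTF-8 text file
#' through [clean_text()].
#'
#' @param path file path.
#' @return \code{read_counts}: a [rank_counts()] vector.
#' @export
read_counts <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(rank_counts(integer(0)))
  tabbed <- grepl("\t", lines[1], fixed = TRUE)
  start <- 1L
  parse_field <- function(s, lineno) {
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v) || v != round(v))
      stop(sprintf("line %d: malformed count '%s'", lineno, s), call. = FALSE)
    if (v <= 0)
      stop(sprintf("line %d: counts must be positive (got %s)", lineno, s),
           call. = FALSE)
    as.integer(v)
  }
  if (tabbed) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    # header allowed: second field non-numeric on line 1 only
    if (suppressWarnings(is.na(as.numeric(fields[[1]][2])))) start <- 2L
    counts <- vapply(seq.int(start, length(lines)), function(i) {
      f <- fields[[i]]
      if (length(f) < 2)
        stop(sprintf("line %d: expected 'event<TAB>count'", i), call. = FALSE)
      parse_field(f[2], i)
    }, integer(1))
  } else {
    if (suppressWarnings(is.na(as.numeric(lines[1])))) start <- 2L
    counts <- vapply(seq.int(start, length(lines)),
                     function(i) parse_field(lines[i], i), integer(1))
  }
  rank_counts(counts)
}

#' @rdname read_counts
#' @param counts a [rank_counts()] vector (or coercible).
#' @export
write_counts <- function(counts, path) {
  counts <- as_rank_counts(counts)
  writeLines(as.character(as.integer(counts)), path)
  invisible(path)
}

#' @rdname read_counts
#' @export
read_tokens <- function(path) {
  clean_text(readLines(path, encoding = "UTF-8", warn = FALSE))
}

#' Validate a rank mapping (permutation of probability ranks)
#'
#' A rank mapping \code{s} assigns to each probability rank \eqn{r_p} the
#' empirical rank \eqn{s(r_p) = r_e}; any valid mapping is a permutation of
#' \code{1..W}.
#'
#' @param s integer vector.
#' @return \code{s} as an integer permutation vector (errors otherwise).
#' @export
rank_mapping <- function(s) {
  s <- as.integer(s)
  W <- length(s)
  if (W == 0 || anyNA(s) || !setequal(s, seq_len(W)) || anyDuplicated(s))
    stop("mapping must be a permutation of 1..W", call. = FALSE)
  s
}
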
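# Independent oracles used across tests. These deliberately avoid the
# package's permanent/likelihood code paths.

# Permanent by Laplace-style expansion along the first row, plain
# double-precision products.
perm_oracle <- function(A) {
  n <- nrow(A)
  if (n == 1) return(A[1, 1])
  s <- 0
  for (j in seq_len(n)) {
    s <- s + A[1, j] * perm_oracle(A[-1, -j, drop = FALSE])
  }
  s
}

# All permutations of 1..n, independent of the package's generator.
perms_oracle <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_oracle(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  unname(out)
}

# Random small count vector, sorted non-increasing.
rand_counts <- function(W, max_count = 8) {
  sort(sample.int(max_count, W, replace = TRUE), decreasing = TRUE)
}

# Synthetic "book": N tokens drawn from a Zipf model, labelled by their
# probability rank.
write_zipf_book <- function(path, lambda, N, seed) {
  samp <- sample_counts(zipf_model(lambda), N, seed = seed)
  # letter-encode ranks so the text-cleaning digit rule keeps types distinct
  labels <- chartr("0123456789", "abcdefghij", format(samp$prob_rank,
                                                      scientific = FALSE))
  tokens <- rep(paste0("w", gsub(" ", "", labels)),
                times = as.integer(samp$counts))
  tokens <- sample(tokens)   # shuffle; counts are order-invariant
  writeLines(paste(tokens, collapse = " "), path)
  invisible(samp)
}
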
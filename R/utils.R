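# Shared internal helpers: seed plumbing, ranking, small validators.

#' Derive a child seed from a parent seed and a counter
#'
#' All generators in the package draw their randomness from a single integer
#' seed per call. Where a generator needs several independent streams (one per
#' trait pair, one per replicate, ...) it derives child seeds with this
#' counter-based splitter rather than consuming a shared global stream, so
#' adding a stream never perturbs the others.
#'
#' @param seed integer parent seed.
#' @param counter non-negative integer stream index.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(counter))
  # 64-bit-safe mixed congruential step done in doubles (< 2^53 throughout)
  s <- (abs(as.double(seed)) %% 2147483647) + 1
  x <- (1103515245 * s + 12345 + 2654435 * (as.double(counter) + 1)) %% 2147483647
  x <- (69069 * x + 1) %% 2147483629
  as.integer(x + 1)
}

# rank with 1 = largest value, ties averaged
rank_desc <- function(x) rank(-x, ties.method = "average")

# clip to non-negative and normalize to sum 1; all-zero falls back to uniform
normalize_importance <- function(x) {
  x <- pmax(x, 0)
  s <- sum(x)
  if (!is.finite(s) || s <= 0) rep(1 / length(x), length(x)) else x / s
}

stop_cfg <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

#' Adjusted Rand index between two partitions
#'
#' Used to score recovered community structure against planted module labels.
#'
#' @param a,b vectors of cluster labels over the same items.
#' @return the adjusted Rand index (1 = identical partitions up to renaming).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# strip "chr" prefixes so "chr1" and "1" compare equal
norm_chr <- function(chr) sub("^[Cc][Hh][Rr]", "", as.character(chr))
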
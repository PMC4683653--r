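# Internal helpers shared across pipeline stages.

#' Derive a reproducible sub-stream seed for a named pipeline stage
#'
#' All stochastic stages draw their seed deterministically from the
#' top-level analysis seed and the stage name, so stages can be run in
#' any order (or in isolation) without perturbing each other's random
#' streams.  The derived seed is always a valid 32-bit integer.
#'
#' @param seed integer top-level seed.
#' @param stage character stage name, e.g. `"generate"`.
#' @return an integer seed.
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483629L)
}

# p-value -> negative log10 p, with underflow floored at 1e-300 so the
# transform never returns Inf.
nlp <- function(p) -log10(pmax(p, 1e-300))

# Pearson correlation of x against each column of Y plus the two-sided
# t-test p-value on n - 2 df.  Returns a data.frame(r, p, n).
cor_test_cols <- function(x, Y) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  r <- suppressWarnings(as.vector(cor(x, Y)))
  p <- r_to_p(r, n)
  data.frame(r = r, p = p, n = n, row.names = colnames(Y))
}

# Two-sided p for a Pearson r at n units (t distribution, n - 2 df).
r_to_p <- function(r, n) {
  df <- n - 2
  r2 <- pmin(r^2, 1)
  tt <- abs(r) * sqrt(df / pmax(1 - r2, .Machine$double.xmin))
  p <- 2 * pt(tt, df, lower.tail = FALSE)
  p[r2 >= 1] <- 0
  pmin(pmax(p, 0), 1)
}

# Fisher z 95% confidence interval for a correlation at n units.
fisher_ci <- function(r, n, level = 0.95) {
  z <- atanh(r)
  hw <- qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  tanh(c(z - hw, z + hw))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 means identical up to relabeling, 0 is the expected value for
#' independent partitions.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return a single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}

# Stage logging: every stage reports its thresholds, input shapes and
# filter-survival counts.  Quiet unless options(gxdmod.verbose = TRUE).
log_stage <- function(stage, ...) {
  if (isTRUE(getOption("gxdmod.verbose", FALSE))) {
    message(sprintf("[gxdmod:%s] %s", stage, paste0(..., collapse = "")))
  }
  invisible(NULL)
}
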
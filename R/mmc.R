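# Module detection by adaptive-sharpening modularity maximization.
#
# The absolute pairwise correlation matrix is mapped to edge weights
# w_ij = |r_ij|^s for each sharpness s on a grid (a logistic transform
# is available as an alternative), the weighted-graph modularity
#   Q = sum_modules [ w_in / (2W) - (k_mod / (2W))^2 ]
# is maximized by leading-eigenvector spectral bisection with greedy
# single-feature refinement, and the sharpness giving the highest Q is
# kept (ties toward the smallest s).  Modules are then reindexed by
# descending average within-module |r| ("average degree of
# correlation").

#' Pairwise feature correlations on least-squares means
#'
#' @param lsm an `lsmeans_table` (units x features).
#' @param features optional feature id subset.
#' @param method `"pearson"` or `"spearman"`.
#' @return a list of class `corr_matrix` with elements `r` (symmetric
#'   correlation matrix, unit diagonal), `method`, `n_units`,
#'   `dropped` (constant features removed with a warning).
#' @export
feature_correlations <- function(lsm, features = NULL,
                                 method = c("pearson", "spearman")) {
  stopifnot(inherits(lsm, "lsmeans_table"))
  method <- match.arg(method)
  X <- lsm$values
  if (!is.null(features)) {
    miss <- setdiff(features, colnames(X))
    if (length(miss)) stop("feature(s) not in table: ",
                           paste(miss, collapse = ", "))
    X <- X[, features, drop = FALSE]
  }
  if (nrow(X) < 3) stop("need >= 3 units for correlations")
  sds <- apply(X, 2, sd, na.rm = TRUE)
  dropped <- colnames(X)[is.na(sds) | sds == 0]
  if (length(dropped)) {
    warning("dropping constant feature(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, !(colnames(X) %in% dropped), drop = FALSE]
  }
  r <- cor(X, use = "pairwise.complete.obs", method = method)
  diag(r) <- 1
  structure(list(r = r, method = method, n_units = nrow(X),
                 dropped = dropped),
            class = "corr_matrix")
}

#' Filter a feature list by a significance criterion
#'
#' Mirrors the pipeline's "filter by statistical correlation with a
#' biological factor of interest": keeps the features whose p-value in
#' `criterion` falls below `p_threshold` (or whose q-value is at or
#' below it, for FDR-based criteria).
#'
#' @param features feature id vector.
#' @param criterion data.frame with a `feature_id` column and the
#'   column named by `stat`.
#' @param p_threshold threshold.
#' @param stat column of `criterion` to threshold (e.g. `"p"`,
#'   `"p_GxD"`, `"q_GxD"`).
#' @return the surviving feature ids (warns when empty).
#' @export
filter_by_factor <- function(features, criterion, p_threshold,
                             stat = "p") {
  stopifnot(is.data.frame(criterion), "feature_id" %in% names(criterion),
            stat %in% names(criterion))
  v <- criterion[[stat]][match(features, criterion$feature_id)]
  if (anyNA(v)) stop("criterion does not cover feature(s): ",
                     paste(features[is.na(v)], collapse = ", "))
  keep <- if (startsWith(stat, "q")) v <= p_threshold else v < p_threshold
  out <- features[keep]
  log_stage("filter", sprintf("%d of %d features pass %s %s %g",
                              length(out), length(features), stat,
                              if (startsWith(stat, "q")) "<=" else "<",
                              p_threshold))
  if (!length(out)) warning("no features pass the filter; downstream ",
                            "clustering will be skipped")
  out
}

weight_transform <- function(absr, sharpness, transform, tau, sigma) {
  w <- switch(transform,
              power = absr^sharpness,
              logistic = 1 / (1 + exp(-(absr - tau) / (sigma / sharpness))))
  diag(w) <- 0
  w
}

#' Cluster features by modulated modularity maximization
#'
#' @param cm a `corr_matrix` (at least 4 features).
#' @param sharpness_grid strictly increasing positive sharpness values.
#' @param refine apply greedy single-feature refinement to each
#'   spectral bisection (recommended).
#' @param transform `"power"` (`w = |r|^s`) or `"logistic"`
#'   (`w = 1 / (1 + exp(-(|r| - tau) / (sigma / s)))`).
#' @param tau,sigma logistic transform location and base scale.
#' @return a list of class `module_partition`: `assignment` (named
#'   integer vector, 1-based module per feature, module 1 having the
#'   highest average within-module |r|), `chosen_sharpness`,
#'   `modularity_Q`, and `modules` (data.frame: module, size,
#'   avg_abs_corr).
#' @export
mmc <- function(cm, sharpness_grid = 1:30, refine = TRUE,
                transform = c("power", "logistic"), tau = 0.5,
                sigma = 0.1) {
  stopifnot(inherits(cm, "corr_matrix"))
  transform <- match.arg(transform)
  r <- cm$r
  if (nrow(r) < 4) stop("need >= 4 features to cluster")
  if (length(sharpness_grid) < 1 || any(sharpness_grid <= 0) ||
      is.unsorted(sharpness_grid, strictly = TRUE)) {
    stop("sharpness_grid must be nonempty, positive, strictly increasing")
  }
  absr <- abs(r)
  best <- NULL
  for (s in sharpness_grid) {
    w <- weight_transform(absr, s, transform, tau, sigma)
    part <- modularity_partition(w, refine = refine)
    q <- modularity_q(w, part)
    if (is.null(best) || q > best$q + 1e-12) {
      best <- list(s = s, membership = part, q = q)
    }
  }
  if (best$q == 0 && all(weight_transform(absr, best$s, transform, tau,
                                          sigma) == 0)) {
    warning("all edge weights are zero; returning a single module")
  }
  part <- relabel_by_avg_corr(best$membership, absr)
  modules <- module_summary(part, absr)
  log_stage("cluster", sprintf(
    "%d features -> %d module(s), s=%g, Q=%.4f", nrow(r),
    nrow(modules), best$s, best$q))
  structure(list(assignment = part, chosen_sharpness = best$s,
                 modularity_Q = best$q, modules = modules,
                 transform = transform),
            class = "module_partition")
}

# Spectral modularity maximization on a weighted graph: recursive
# leading-eigenvector bisection (Newman's generalized modularity
# matrix for subgraphs), each bisection refined by greedy single-vertex
# moves; splitting stops when the best split's delta-Q <= 0.
modularity_partition <- function(w, refine = TRUE) {
  n <- nrow(w)
  k <- rowSums(w)
  two_w <- sum(k)
  membership <- rep(1L, n)
  if (two_w == 0) return(membership)
  B <- w - outer(k, k) / two_w
  next_label <- 2L
  stack <- list(seq_len(n))
  while (length(stack)) {
    g <- stack[[1L]]
    stack <- stack[-1L]
    if (length(g) < 2L) next
    Bg <- B[g, g, drop = FALSE]
    diag(Bg) <- diag(Bg) - rowSums(Bg)
    eig <- eigen(Bg, symmetric = TRUE)
    if (eig$values[1] <= 1e-12) next
    v <- eig$vectors[, 1]
    # Fixed sign convention so runs are exactly reproducible.
    if (v[which.max(abs(v))] < 0) v <- -v
    s <- ifelse(v >= 0, 1, -1)
    if (refine) s <- refine_split(Bg, s)
    dq <- as.numeric(t(s) %*% Bg %*% s) / (2 * two_w)
    if (dq <= 1e-12 || all(s == s[1])) next
    g2 <- g[s < 0]
    membership[g2] <- next_label
    next_label <- next_label + 1L
    stack <- c(stack, list(g[s > 0]), list(g2))
  }
  match(membership, sort(unique(membership)))
}

# Greedy refinement of a +/-1 split: repeatedly flip the single vertex
# whose move most increases s' B s, until no flip improves it.
refine_split <- function(Bg, s) {
  repeat {
    bs <- as.vector(Bg %*% s)
    gains <- -4 * s * bs + 4 * diag(Bg)
    i <- which.max(gains)
    if (gains[i] <= 1e-12) break
    s[i] <- -s[i]
  }
  s
}

#' Modularity Q of a partition of a weighted graph
#'
#' `Q = sum_modules [ w_in / (2W) - (k_mod / (2W))^2 ]` with `w_in` the
#' within-module weight (both orientations), `k` the weighted degrees
#' and `2W` the total degree.
#'
#' @param w symmetric nonnegative weight matrix, zero diagonal.
#' @param membership integer module labels.
#' @return Q (0 for an empty graph).
#' @export
modularity_q <- function(w, membership) {
  k <- rowSums(w)
  two_w <- sum(k)
  if (two_w == 0) return(0)
  q <- 0
  for (m in unique(membership)) {
    idx <- membership == m
    q <- q + sum(w[idx, idx]) / two_w - (sum(k[idx]) / two_w)^2
  }
  q
}

relabel_by_avg_corr <- function(membership, absr) {
  avg <- vapply(sort(unique(membership)), function(m) {
    idx <- which(membership == m)
    if (length(idx) < 2) return(-Inf)
    a <- absr[idx, idx]
    mean(a[upper.tri(a)])
  }, numeric(1))
  ord <- order(avg, decreasing = TRUE)
  out <- match(membership, sort(unique(membership))[ord])
  names(out) <- rownames(absr)
  out
}

module_summary <- function(membership, absr) {
  mods <- sort(unique(membership))
  data.frame(
    module = mods,
    size = vapply(mods, function(m) sum(membership == m), integer(1)),
    avg_abs_corr = vapply(mods, function(m) {
      idx <- which(membership == m)
      if (length(idx) < 2) return(NA_real_)
      a <- absr[idx, idx]
      mean(a[upper.tri(a)])
    }, numeric(1)))
}

#' Retain modules passing size and coherence thresholds
#'
#' @param part a `module_partition`.
#' @param min_size minimum member count.
#' @param min_avg_corr minimum average within-module |r|.
#' @return a `module_partition` whose `modules` table holds only the
#'   retained modules (original module indices preserved in the
#'   `module` column and in `all_modules`); `assignment` is restricted
#'   to members of retained modules.
#' @export
order_and_filter_modules <- function(part, min_size = 3,
                                     min_avg_corr = 0.5) {
  stopifnot(inherits(part, "module_partition"))
  mods <- part$modules
  keep <- mods$size >= min_size & !is.na(mods$avg_abs_corr) &
    mods$avg_abs_corr > min_avg_corr
  retained <- mods$module[keep]
  log_stage("cluster", sprintf(
    "%d of %d module(s) retained (size >= %d, avg |r| > %g)",
    length(retained), nrow(mods), min_size, min_avg_corr))
  if (!length(retained)) warning("no modules pass the filters")
  out <- part
  out$all_modules <- mods
  out$modules <- mods[keep, , drop = FALSE]
  out$assignment <- part$assignment[part$assignment %in% retained]
  out
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d feature(s) in %d module(s), s=%g, Q=%.4f\n",
              length(x$assignment), nrow(x$modules), x$chosen_sharpness,
              x$modularity_Q))
  print(x$modules, row.names = FALSE)
  invisible(x)
}
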
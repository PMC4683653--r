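mk_cm <- function(r) {
  ids <- sprintf("f%02d", seq_len(nrow(r)))
  dimnames(r) <- list(ids, ids)
  structure(list(r = r, method = "pearson", n_units = 80,
                 dropped = character()), class = "corr_matrix")
}

test_that("pairwise correlations match hand values and drop constants", {
  vals <- cbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4),
                c = c(4, 3, 2, 1), flat = rep(2, 4))
  lsm <- mk_lsm(vals)
  expect_warning(cm <- feature_correlations(lsm), "flat")
  expect_equal(cm$r["a", "b"], 0.8)
  expect_equal(cm$r["a", "c"], -1)
  expect_equal(cm$r["a", "a"], 1)
  expect_equal(max(abs(cm$r - t(cm$r))), 0)
  expect_false("flat" %in% rownames(cm$r))
  # identical profiles correlate at exactly 1
  lsm2 <- mk_lsm(cbind(x = c(1, 5, 2, 7), y = c(1, 5, 2, 7),
                       z = rnorm(4)))
  expect_equal(feature_correlations(lsm2)$r["x", "y"], 1)
})

test_that("significance filters keep exactly the qualifying features", {
  set.seed(4)
  ids <- sprintf("F%03d", 1:200)
  crit <- data.frame(feature_id = ids, p = runif(200), q = runif(200))
  expect_equal(filter_by_factor(ids, crit, 1.0), ids)
  expect_warning(out0 <- filter_by_factor(ids, crit, 0), "no features")
  expect_length(out0, 0)
  kept <- filter_by_factor(ids, crit, 0.01)
  expect_equal(kept, ids[crit$p < 0.01])
  keptq <- filter_by_factor(ids, crit, 0.5, stat = "q")
  expect_equal(keptq, ids[crit$q <= 0.5])
  expect_error(filter_by_factor(c(ids, "F999"), crit, 0.5), "F999")
})

test_that("perfect block structure is split exactly; empty graphs degrade", {
  r <- matrix(0, 6, 6)
  r[1:3, 1:3] <- 1; r[4:6, 4:6] <- 1
  part <- mmc(mk_cm(r), sharpness_grid = c(1, 2, 5))
  expect_equal(length(unique(part$assignment)), 2L)
  expect_equal(unname(part$assignment[1:3]),
               rep(part$assignment[[1]], 3))
  expect_equal(unname(part$assignment[4:6]),
               rep(part$assignment[[4]], 3))
  expect_equal(part$modules$avg_abs_corr, c(1, 1))

  ident <- diag(6)
  expect_warning(p0 <- mmc(mk_cm(ident)), "zero")
  expect_equal(length(unique(p0$assignment)), 1L)
  expect_equal(p0$modularity_Q, 0)
})

test_that("modularity Q matches its brute-force definition", {
  set.seed(9)
  for (it in 1:10) {
    n <- sample(5:12, 1)
    w <- matrix(runif(n * n), n, n)
    w <- (w + t(w)) / 2; diag(w) <- 0
    mem <- sample(1:3, n, TRUE)
    expect_equal(modularity_q(w, mem), brute_q(w, mem),
                 tolerance = 1e-10)
  }
})

test_that("planted modules are recovered and the chosen partition's Q is exact", {
  dat <- generate_dataset(planted_module_spec(101))
  lsm <- ls_means(dat$fm)
  cm <- feature_correlations(lsm)
  part <- mmc(cm)
  ari <- adjusted_rand_index(part$assignment[dat$truth$feature_ids],
                             dat$truth$module)
  expect_gte(ari, 0.9)
  w <- abs(cm$r)^part$chosen_sharpness; diag(w) <- 0
  expect_equal(part$modularity_Q,
               brute_q(w, part$assignment[rownames(cm$r)]),
               tolerance = 1e-10)
  # agreement with an independent partition-quality reference
  if (requireNamespace("mclust", quietly = TRUE)) {
    expect_equal(ari, mclust::adjustedRandIndex(
      part$assignment[dat$truth$feature_ids], dat$truth$module),
      tolerance = 1e-12)
  }
})

test_that("feature order permutation relabels but does not change modules", {
  dat <- generate_dataset(planted_module_spec(55))
  lsm <- ls_means(dat$fm)
  cm <- feature_correlations(lsm)
  part1 <- mmc(cm, sharpness_grid = c(1, 3, 6))
  set.seed(3)
  perm <- sample(colnames(lsm$values))
  lsm_p <- lsm
  lsm_p$values <- lsm$values[, perm]
  part2 <- mmc(feature_correlations(lsm_p), sharpness_grid = c(1, 3, 6))
  common <- rownames(cm$r)
  expect_equal(adjusted_rand_index(part1$assignment[common],
                                   part2$assignment[common]), 1)
})

test_that("adaptive sharpening is used and helps under between-module noise", {
  # Latent model: all features share a weak common factor (between-
  # module correlation ~0.3) on top of module factors (within ~0.7).
  wins <- 0; sharpened <- 0
  for (seed in 1:12) {
    set.seed(seed)
    n_units <- 80
    g <- rnorm(n_units)
    mods <- matrix(rnorm(n_units * 4), n_units, 4)
    X <- sapply(1:60, function(f) {
      k <- (f - 1) %/% 15 + 1
      sqrt(0.3) * g + sqrt(0.4) * mods[, k] + sqrt(0.3) * rnorm(n_units)
    })
    colnames(X) <- sprintf("f%02d", 1:60)
    truth <- rep(1:4, each = 15)
    cm <- feature_correlations(mk_lsm(X))
    part_s <- mmc(cm, sharpness_grid = 1:30)
    part_1 <- mmc(cm, sharpness_grid = 1)
    a_s <- adjusted_rand_index(part_s$assignment[colnames(X)], truth)
    a_1 <- adjusted_rand_index(part_1$assignment[colnames(X)], truth)
    if (part_s$chosen_sharpness > 1) sharpened <- sharpened + 1
    if (a_s >= a_1) wins <- wins + 1
  }
  expect_gte(sharpened, 9)
  expect_gte(wins, 9)
})

test_that("module ordering and size/coherence filters retain the right set", {
  # Construct a partition with module sizes {23,15,25,16,20,22,9}, all
  # with average |r| above 0.5 -> six retained at min_size 15.
  sizes <- c(23, 15, 25, 16, 20, 22, 9)
  n <- sum(sizes)
  r <- matrix(0, n, n)
  start <- cumsum(c(1, sizes))[seq_along(sizes)]
  within <- c(0.612, 0.58, 0.544, 0.535, 0.521, 0.501, 0.55)
  for (k in seq_along(sizes)) {
    idx <- start[k]:(start[k] + sizes[k] - 1)
    r[idx, idx] <- within[k]
  }
  diag(r) <- 1
  ids <- sprintf("g%03d", 1:n)
  dimnames(r) <- list(ids, ids)
  assignment <- setNames(rep(seq_along(sizes), sizes), ids)
  part <- structure(list(
    assignment = assignment, chosen_sharpness = 1, modularity_Q = 0.5,
    modules = data.frame(module = seq_along(sizes), size = sizes,
                         avg_abs_corr = within)),
    class = "module_partition")
  kept <- order_and_filter_modules(part, min_size = 15, min_avg_corr = 0.5)
  expect_equal(nrow(kept$modules), 6L)
  expect_false(7 %in% kept$modules$module)
  expect_equal(sum(kept$modules$size), n - 9)

  ident <- order_and_filter_modules(part, min_size = 1, min_avg_corr = 0)
  expect_equal(nrow(ident$modules), 7L)
  expect_warning(none <- order_and_filter_modules(part, min_size = 50),
                 "no modules")
  expect_equal(nrow(none$modules), 0L)
})

test_that("module 1 always carries the maximal average degree of correlation", {
  for (seed in c(21, 22, 23)) {
    dat <- generate_dataset(planted_module_spec(seed))
    cm <- feature_correlations(ls_means(dat$fm))
    part <- mmc(cm, sharpness_grid = c(1, 2, 4, 8))
    avg <- part$modules$avg_abs_corr
    expect_equal(part$modules$module, seq_along(avg))
    expect_true(all(avg[1] >= avg[-1] | is.na(avg[-1])))
  }
})
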
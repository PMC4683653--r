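test_that("the hand-computed 2x2x2 example decomposes exactly", {
  res <- fit_gxd_anova(worked_example_fm())
  expect_equal(res$SS_G, 8)
  expect_equal(res$SS_D, 0)
  expect_equal(res$SS_GxD, 0)
  expect_equal(res$SS_E, 2)
  expect_equal(res$F_G, 16)
  # F(1, 4) survival function through its beta representation
  expect_equal(res$p_G, pbeta(4 / (4 + 16), 4 / 2, 1 / 2),
               tolerance = 1e-10)
  expect_equal(res$SS_G + res$SS_D + res$SS_GxD + res$SS_E, res$SS_total,
               tolerance = 1e-8)
  expect_equal(res$df_G, 1); expect_equal(res$df_GxD, 1)
  expect_equal(res$df_E, 4)
  expect_equal(res$NLP_G, -log10(res$p_G))
})

test_that("a constant feature has zero SS, F = 0 and p = 1", {
  meta <- toy_meta(2, 2, 2)
  vals <- matrix(3.7, 1, 8, dimnames = list("flat", meta$sample_id))
  res <- fit_gxd_anova(feature_matrix(vals, meta))
  expect_equal(res$SS_total, 0)
  expect_equal(unlist(res[c("F_G", "F_D", "F_GxD")]), c(0, 0, 0),
               ignore_attr = TRUE)
  expect_equal(unlist(res[c("p_G", "p_D", "p_GxD")]), c(1, 1, 1),
               ignore_attr = TRUE)
})

test_that("F and p agree with a classical means-based oracle on balanced data", {
  # Independent oracle: textbook balanced two-way decomposition from
  # cell/marginal means.
  balanced_oracle <- function(y, line, diet) {
    L <- nlevels(line); J <- nlevels(diet); n <- length(y)
    m <- n / (L * J)
    gm <- mean(y)
    lm_ <- tapply(y, line, mean); dm <- tapply(y, diet, mean)
    cm <- tapply(y, list(line, diet), mean)
    ss_g <- J * m * sum((lm_ - gm)^2)
    ss_d <- L * m * sum((dm - gm)^2)
    ss_cells <- m * sum((cm - gm)^2)
    ss_i <- ss_cells - ss_g - ss_d
    ss_e <- sum((y - cm[cbind(line, diet)])^2)
    dfe <- n - L * J
    list(ss = c(ss_g, ss_d, ss_i, ss_e),
         F = c(ss_g / (L - 1), ss_d / (J - 1),
               ss_i / ((L - 1) * (J - 1))) / (ss_e / dfe),
         p = pf(c(ss_g / (L - 1), ss_d / (J - 1),
                  ss_i / ((L - 1) * (J - 1))) / (ss_e / dfe),
                c(L - 1, J - 1, (L - 1) * (J - 1)), dfe,
                lower.tail = FALSE))
  }
  set.seed(88)
  for (it in 1:50) {
    L <- sample(2:5, 1); J <- sample(2:4, 1); M <- sample(2:4, 1)
    meta <- toy_meta(L, J, M)
    vals <- matrix(rnorm(2 * nrow(meta), sd = runif(1, 0.5, 3)),
                   2, nrow(meta),
                   dimnames = list(c("fa", "fb"), meta$sample_id))
    res <- fit_gxd_anova(feature_matrix(vals, meta))
    line <- factor(meta$line_id); diet <- factor(meta$diet_id)
    for (f in 1:2) {
      or <- balanced_oracle(vals[f, ], line, diet)
      expect_equal(unlist(res[f, c("SS_G", "SS_D", "SS_GxD", "SS_E")]),
                   or$ss, tolerance = 1e-8, ignore_attr = TRUE)
      expect_equal(unlist(res[f, c("F_G", "F_D", "F_GxD")]), or$F,
                   tolerance = 1e-8, ignore_attr = TRUE)
      expect_equal(unlist(res[f, c("p_G", "p_D", "p_GxD")]), or$p,
                   tolerance = 1e-8, ignore_attr = TRUE)
    }
  }
})

test_that("mild unbalance is handled and cell-emptying features are excluded", {
  meta <- toy_meta(3, 2, 3)
  set.seed(12)
  vals <- matrix(rnorm(2 * nrow(meta)), 2, nrow(meta),
                 dimnames = list(c("ok", "gappy"), meta$sample_id))
  # feature "gappy" loses every observation of one line x diet cell
  vals["gappy", meta$line_id == "L1" & meta$diet_id == "d2"] <- NA
  # drop one sample entirely -> mildly unbalanced design
  fm <- feature_matrix(vals[, -1], meta[-1, ])
  expect_warning(res <- fit_gxd_anova(fm), "gappy")
  expect_true(res$excluded[res$feature_id == "gappy"])
  expect_true(is.na(res$p_G[res$feature_id == "gappy"]))
  ok <- res[res$feature_id == "ok", ]
  expect_false(ok$excluded)
  expect_true(all(unlist(ok[c("SS_G", "SS_D", "SS_GxD", "SS_E")]) >= 0))
  expect_true(all(unlist(ok[c("p_G", "p_D", "p_GxD")]) > 0 &
                    unlist(ok[c("p_G", "p_D", "p_GxD")]) <= 1))
  # saturated design errors
  expect_error(fit_gxd_anova(feature_matrix(
    matrix(rnorm(4), 1, 4, dimnames = list("f", toy_meta(2, 2, 1)$sample_id)),
    toy_meta(2, 2, 1))), "saturated")
})

test_that("BH q-values match the step-up definition and its properties", {
  expect_equal(bh_fdr(c(0.004, 0.03, 0.03, 0.8)),
               c(0.016, 0.04, 0.04, 0.8))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  set.seed(2)
  for (it in 1:20) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
})

test_that("LS-means equal cell means and carry the design unit counts", {
  meta <- toy_meta(1, 1, 2)
  vals <- matrix(c(1, 2), 1, 2, dimnames = list("f", meta$sample_id))
  lsm <- ls_means(feature_matrix(vals, meta))
  expect_equal(as.vector(lsm$values), 1.5)

  dat <- generate_dataset(preset_scenario("main_panel", seed = 2))
  expect_equal(nrow(ls_means(dat$fm)$values), 80L)
  expect_equal(nrow(ls_means(dat$fm, grouping = "line_diet_replicate")$values),
               240L)
  # unbalanced: a nonempty cell's LS-mean is still its observed mean
  keep <- !(dat$fm$meta$line_id == "L01" & dat$fm$meta$diet_id == "normal" &
              dat$fm$meta$replicate_id == "R1")
  fm_u <- feature_matrix(dat$fm$values[, keep], dat$fm$meta[keep, ])
  lsm_u <- ls_means(fm_u)
  manual <- mean(fm_u$values[1, fm_u$meta$line_id == "L01" &
                               fm_u$meta$diet_id == "normal"])
  expect_equal(lsm_u$values["L01_normal", 1], manual, ignore_attr = TRUE)
})

test_that("effect partitions count every feature exactly once", {
  fake <- function(qg, qd, qi) {
    structure(data.frame(q_G = qg, q_D = qd, q_GxD = qi),
              class = c("anova_result", "data.frame"))
  }
  all_null <- classify_significance(fake(rep(1, 5), rep(1, 5), rep(1, 5)))
  expect_equal(all_null$count[!all_null$G & !all_null$D & !all_null$GxD], 5L)
  one <- classify_significance(fake(0.01, 0.2, 0.01), q_threshold = 0.05)
  expect_equal(one$count[one$G & !one$D & one$GxD], 1L)
  expect_equal(sum(one$count), 1L)
  set.seed(77)
  rnd <- fake(runif(300), runif(300), runif(300))
  part <- classify_significance(rnd, 0.3)
  expect_equal(sum(part$count), 300L)
  # exhaustive count oracle for one cell
  expect_equal(part$count[part$G & part$D & part$GxD],
               sum(rnd$q_G <= 0.3 & rnd$q_D <= 0.3 & rnd$q_GxD <= 0.3))
})
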
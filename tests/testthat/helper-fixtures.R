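# Shared fixture builders (all data generated in code).

# Minimal sample metadata for an L x J x M factorial.
toy_meta <- function(L = 2, J = 2, M = 2,
                     diets = sprintf("d%d", seq_len(J))) {
  g <- expand.grid(line = seq_len(L), diet = seq_len(J), rep = seq_len(M))
  data.frame(
    sample_id = sprintf("L%d_%s_R%d", g$line, diets[g$diet], g$rep),
    line_id = sprintf("L%d", g$line),
    diet_id = diets[g$diet],
    replicate_id = sprintf("R%d", g$rep),
    platform = "microarray")
}

# The hand-computed 2 lines x 2 diets x 2 reps ANOVA fixture:
# line 1 holds {1, 2} in both diets, line 2 holds {3, 4}.
worked_example_fm <- function() {
  meta <- toy_meta(2, 2, 2)
  v <- ifelse(meta$line_id == "L1", 0, 2) +
    ifelse(meta$replicate_id == "R1", 1, 2)
  vals <- matrix(v, nrow = 1, dimnames = list("f1", meta$sample_id))
  feature_matrix(vals, meta)
}

# Wrap a units x features matrix as an lsmeans_table.
mk_lsm <- function(values, line_id = NULL, diet_id = NULL) {
  n <- nrow(values)
  if (is.null(line_id)) line_id <- sprintf("L%02d", seq_len(n))
  if (is.null(diet_id)) diet_id <- rep("d1", n)
  units <- data.frame(unit_id = paste(line_id, diet_id, sep = "_"),
                      line_id = line_id, diet_id = diet_id)
  rownames(values) <- units$unit_id
  structure(list(units = units, values = values, grouping = "line_diet"),
            class = "lsmeans_table")
}

# Wrap a p-value vector as a corr_profile over a feature universe.
mk_profile <- function(p, r = NULL, ids = sprintf("F%04d", seq_along(p)),
                       trait = "weight", diet = "pooled") {
  if (is.null(r)) r <- rep(0.5, length(p))
  prof <- data.frame(feature_id = ids, r = r, p = p,
                     NLP = -log10(pmax(p, 1e-300)), n = 80)
  attr(prof, "trait") <- trait
  attr(prof, "diet") <- diet
  attr(prof, "platform") <- "microarray"
  class(prof) <- c("corr_profile", "data.frame")
  prof
}

# Generator spec planting 4 modules of 25 features (within-module
# signal share 0.7) in 100 features, 20 lines x 4 diets x 3 reps.
planted_module_spec <- function(seed, between = 0) {
  generator_spec(
    n_lines = 20, diets = c("a", "b", "c", "d"), n_replicates = 3,
    n_features = 100,
    feature_classes = data.frame(fraction = 1, var_G = 0, var_D = 0,
                                 var_GxD = 0, var_E = 1),
    modules = data.frame(size = 25,
                         loading = sqrt((0.7 / 0.3) * (1 / 3) / 3),
                         factor_var_G = 1, factor_var_D = 1,
                         factor_var_GxD = 1)[rep(1, 4), ],
    seed = seed)
}

# Independent brute-force BH step-up oracle (direct evaluation of the
# definition, kept free of p.adjust).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Brute-force modularity from its definition (pair loop).
brute_q <- function(w, membership) {
  k <- rowSums(w)
  tw <- sum(k)
  if (tw == 0) return(0)
  q <- 0
  for (i in seq_len(nrow(w))) {
    for (j in seq_len(nrow(w))) {
      if (membership[i] == membership[j]) {
        q <- q + (w[i, j] - k[i] * k[j] / tw) / tw
      }
    }
  }
  unname(q)
}

# Per-diet trait-correlate profiles of a generated dataset.
diet_profiles <- function(dat, grouping = "line_diet") {
  lsm_f <- ls_means(dat$fm, grouping = grouping)
  lsm_t <- phenotype_ls_means(dat$phenotypes, dat$fm$meta, grouping)
  trait_correlations(lsm_f, lsm_t, scope = "diet")
}

# A single planted module of 25 features (signal share 0.7) whose
# factor drives weight at a planted LS-mean correlation of 0.6 over
# the 80 line x diet units.
pc1_spec <- function(seed) {
  beta <- 0.6; noise <- 1.92           # corr = beta / sqrt(beta^2 + noise/3)
  generator_spec(
    n_lines = 20, diets = c("a", "b", "c", "d"), n_replicates = 3,
    n_features = 40,
    feature_classes = data.frame(fraction = 1, var_G = 0, var_D = 0,
                                 var_GxD = 0, var_E = 1.2857),
    modules = data.frame(size = 25, loading = 1, factor_var_G = 0,
                         factor_var_D = 0, factor_var_GxD = 1),
    trait_specs = list(
      weight = list(beta = matrix(beta, 1, 4), noise_var = noise),
      triglyceride = list(beta = matrix(0, 1, 4), noise_var = 1),
      sugar = list(beta = matrix(0, 1, 4), noise_var = 1)),
    seed = seed)
}

planted_pc1_corr <- function() 0.6 / sqrt(0.6^2 + 1.92 / 3)
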
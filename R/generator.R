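# Synthetic factorial line x diet x replicate data generator.
#
# Generating model, per feature f measured on sample (i, j, m):
#   Y_fijm = mu_f + g_fi + d_fj + c_fij + lambda_f * M_k(f),ij + e_fijm
# with g ~ N(0, var_G), d ~ N(0, var_D), c ~ N(0, var_GxD),
# e ~ N(0, var_E), all mutually independent.  Module factors M_k share
# the same line/diet/interaction decomposition.  Gross traits for unit
# (i, j, m) are sum_k beta_kj * M_k,ij plus Gaussian noise, so trait
# correlates have unambiguous ground truth (module members).
# RNG: R's default Mersenne-Twister, seeded per stage.

#' Specify a synthetic factorial dataset
#'
#' @param n_lines number of genetic lines.
#' @param diets character vector of diet ids.
#' @param n_replicates replicate blocks per line x diet cell.
#' @param n_features number of molecular features.
#' @param feature_classes data.frame with columns `fraction`, `var_G`,
#'   `var_D`, `var_GxD`, `var_E`: the idiosyncratic variance components
#'   of each feature class.  Fractions must sum to 1; classes are
#'   assigned to features in contiguous blocks.
#' @param modules data.frame with columns `size`, `loading`,
#'   `factor_var_G`, `factor_var_D`, `factor_var_GxD`: planted
#'   correlated-feature modules.  Module k claims the next `size`
#'   feature ids in order, starting from feature 1.
#' @param trait_specs named list (names are trait ids) of
#'   `list(beta = matrix, noise_var = x)`; `beta` has one row per
#'   module and one column per diet, giving the diet-specific loading
#'   of the trait on each module factor.
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   output.
#' @param mu baseline abundance, scalar or per-feature vector.
#' @param block_var optional variance of a replicate-block main effect
#'   shared by all features of a sample; default 0 (the analysis model
#'   carries no block term).
#' @param platform platform label written to the sample metadata.
#' @param feature_kind `"transcript"` or `"metabolite"`.
#' @return a list of class `generator_spec`.
#' @export
generator_spec <- function(n_lines, diets, n_replicates, n_features,
                           feature_classes = data.frame(
                             fraction = 1, var_G = 0, var_D = 0,
                             var_GxD = 0, var_E = 1),
                           modules = NULL,
                           trait_specs = NULL,
                           seed = 1L, mu = 0, block_var = 0,
                           platform = "microarray",
                           feature_kind = "transcript") {
  stopifnot(n_lines >= 1, length(diets) >= 1, n_replicates >= 1,
            n_features >= 1)
  fc <- as.data.frame(feature_classes)
  need <- c("fraction", "var_G", "var_D", "var_GxD", "var_E")
  stopifnot(all(need %in% names(fc)))
  if (abs(sum(fc$fraction) - 1) > 1e-9) {
    stop("feature class fractions must sum to 1")
  }
  if (any(fc[c("var_G", "var_D", "var_GxD", "var_E")] < 0)) {
    stop("negative variance in feature_classes")
  }
  if (!is.null(modules)) {
    md <- as.data.frame(modules)
    stopifnot(all(c("size", "loading", "factor_var_G", "factor_var_D",
                    "factor_var_GxD") %in% names(md)))
    if (sum(md$size) > n_features) {
      stop("module sizes sum to more than n_features")
    }
    if (any(md[c("factor_var_G", "factor_var_D", "factor_var_GxD")] < 0)) {
      stop("negative variance in modules")
    }
  } else {
    md <- data.frame(size = integer(), loading = numeric(),
                     factor_var_G = numeric(), factor_var_D = numeric(),
                     factor_var_GxD = numeric())
  }
  if (!is.null(trait_specs)) {
    stopifnot(!is.null(names(trait_specs)))
    for (tn in names(trait_specs)) {
      ts <- trait_specs[[tn]]
      if (ts$noise_var < 0) stop("negative trait noise_var for ", tn)
      b <- ts$beta
      if (nrow(md) > 0 &&
          (!is.matrix(b) || nrow(b) != nrow(md) ||
           ncol(b) != length(diets))) {
        stop("beta for trait '", tn, "' must be a ", nrow(md), " x ",
             length(diets), " matrix (modules x diets)")
      }
    }
  }
  structure(list(n_lines = as.integer(n_lines), diets = as.character(diets),
                 n_replicates = as.integer(n_replicates),
                 n_features = as.integer(n_features),
                 feature_classes = fc, modules = md,
                 trait_specs = trait_specs, seed = as.integer(seed),
                 mu = mu, block_var = block_var, platform = platform,
                 feature_kind = feature_kind),
            class = "generator_spec")
}

#' Generate a synthetic dataset from a spec
#'
#' @param spec a [generator_spec()].
#' @return a list with elements `fm` (a `feature_matrix`), `phenotypes`
#'   (a phenotype data.frame, one row per sample) and `truth` (a
#'   `synthetic_truth` list: per-feature planted variances, module
#'   membership and loading, per-module factor realizations per
#'   line x diet, per-trait per-diet loadings, and the seed used).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(substream_seed(spec$seed, "generate"))
  L <- spec$n_lines; J <- length(spec$diets); M <- spec$n_replicates
  Fn <- spec$n_features
  K <- nrow(spec$modules)

  lines <- sprintf("L%02d", seq_len(L))
  reps <- sprintf("R%d", seq_len(M))
  grid <- expand.grid(line = seq_len(L), diet = seq_len(J),
                      rep = seq_len(M), KEEP.OUT.ATTRS = FALSE)
  sample_id <- sprintf("%s_%s_%s", lines[grid$line], spec$diets[grid$diet],
                       reps[grid$rep])
  meta <- data.frame(sample_id = sample_id, line_id = lines[grid$line],
                     diet_id = spec$diets[grid$diet],
                     replicate_id = reps[grid$rep],
                     platform = spec$platform)
  n_samp <- nrow(meta)
  cell <- (grid$diet - 1L) * L + grid$line   # line x diet cell index

  # Feature class assignment: contiguous blocks by fraction.
  sizes <- round(spec$feature_classes$fraction * Fn)
  sizes[length(sizes)] <- Fn - sum(sizes[-length(sizes)])
  class_id <- rep(seq_len(nrow(spec$feature_classes)), times = sizes)
  vG <- spec$feature_classes$var_G[class_id]
  vD <- spec$feature_classes$var_D[class_id]
  vI <- spec$feature_classes$var_GxD[class_id]
  vE <- spec$feature_classes$var_E[class_id]

  # Module membership: module k claims the next `size` features.
  module_of <- integer(Fn)
  lambda <- numeric(Fn)
  if (K > 0) {
    idx <- 1L
    for (k in seq_len(K)) {
      mem <- idx:(idx + spec$modules$size[k] - 1L)
      module_of[mem] <- k
      lambda[mem] <- spec$modules$loading[k]
      idx <- idx + spec$modules$size[k]
    }
  }

  mu <- rep_len(spec$mu, Fn)

  # Idiosyncratic effects, drawn in a fixed order for reproducibility.
  G <- matrix(rnorm(Fn * L), Fn, L) * sqrt(vG)
  D <- matrix(rnorm(Fn * J), Fn, J) * sqrt(vD)
  GxD <- matrix(rnorm(Fn * L * J), Fn, L * J) * sqrt(vI)

  # Module factors at line x diet resolution.
  factors <- array(0, dim = c(max(K, 1L), L, J),
                   dimnames = list(NULL, lines, spec$diets))
  if (K > 0) {
    for (k in seq_len(K)) {
      a <- rnorm(L, sd = sqrt(spec$modules$factor_var_G[k]))
      b <- rnorm(J, sd = sqrt(spec$modules$factor_var_D[k]))
      cc <- matrix(rnorm(L * J, sd = sqrt(spec$modules$factor_var_GxD[k])),
                   L, J)
      factors[k, , ] <- outer(a, rep(1, J)) + outer(rep(1, L), b) + cc
    }
  }

  eps <- matrix(rnorm(Fn * n_samp), Fn, n_samp) * sqrt(vE)

  Y <- mu + G[, grid$line, drop = FALSE] + D[, grid$diet, drop = FALSE] +
    GxD[, cell, drop = FALSE] + eps
  if (K > 0) {
    fac_flat <- matrix(factors, nrow = max(K, 1L))       # K x (L*J)
    fac_samp <- fac_flat[, cell, drop = FALSE]            # K x n_samp
    loaded <- which(module_of > 0)
    if (length(loaded)) {
      Y[loaded, ] <- Y[loaded, , drop = FALSE] +
        lambda[loaded] * fac_samp[module_of[loaded], , drop = FALSE]
    }
  }
  if (spec$block_var > 0) {
    blk <- rnorm(M, sd = sqrt(spec$block_var))
    Y <- Y + rep(blk[grid$rep], each = Fn)
  }
  dimnames(Y) <- list(sprintf("F%04d", seq_len(Fn)), sample_id)

  # Gross traits driven only through module factors plus noise.
  traits <- c("weight", "triglyceride", "sugar")
  if (!is.null(spec$trait_specs)) traits <- names(spec$trait_specs)
  ph <- data.frame(unit_id = sample_id)
  beta_list <- list()
  for (tn in traits) {
    ts <- spec$trait_specs[[tn]]
    if (is.null(ts)) ts <- list(beta = matrix(0, max(K, 1L), J), noise_var = 1)
    b <- ts$beta
    sig <- numeric(n_samp)
    if (K > 0 && any(b != 0)) {
      fac_flat <- matrix(factors, nrow = max(K, 1L))
      fac_samp <- fac_flat[, cell, drop = FALSE]
      bj <- b[, grid$diet, drop = FALSE]                  # K x n_samp
      sig <- colSums(bj * fac_samp)
    }
    ph[[tn]] <- sig + rnorm(n_samp, sd = sqrt(ts$noise_var))
    beta_list[[tn]] <- list(beta = b, noise_var = ts$noise_var)
  }
  class(ph) <- c("phenotype_table", "data.frame")

  truth <- structure(list(
    class_id = class_id, module = module_of, lambda = lambda,
    var_G = vG, var_D = vD, var_GxD = vI, var_E = vE,
    feature_ids = rownames(Y), diets = spec$diets, lines = lines,
    factors = factors, trait_loadings = beta_list,
    seed = spec$seed), class = "synthetic_truth")

  log_stage("simulate", sprintf(
    "%d features x %d samples (%d lines x %d diets x %d reps), %d module(s)",
    Fn, n_samp, L, J, M, K))
  list(fm = feature_matrix(Y, meta, kind = spec$feature_kind),
       phenotypes = ph, truth = truth)
}

#' Write / read the generator's ground truth as structured text (JSON)
#'
#' @param truth a `synthetic_truth`.
#' @param path output path.
#' @return `write_truth` invisibly returns `path`; `read_truth` returns
#'   the reloaded `synthetic_truth`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  out <- truth
  out$factors <- list(dim = dim(truth$factors),
                      values = as.vector(truth$factors))
  jsonlite::write_json(unclass(out), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$factors <- array(x$factors$values, dim = x$factors$dim,
                     dimnames = list(NULL, x$lines, x$diets))
  for (tn in names(x$trait_loadings)) {
    b <- x$trait_loadings[[tn]]$beta
    if (!is.matrix(b)) b <- matrix(b, nrow = dim(x$factors)[1])
    x$trait_loadings[[tn]]$beta <- b
  }
  structure(x, class = "synthetic_truth")
}

#' Preset generator scenarios
#'
#' Named scenarios matching the study designs the package models:
#' \describe{
#'   \item{`main_panel`}{20 lines x 4 diets (normal, control,
#'     high_sugar, high_fat) x 3 replicates (240 samples), microarray
#'     platform.  Default 500 features (configurable up to 11650) in
#'     four planted variance classes plus 4 correlated modules of 25
#'     features driving the gross traits.}
#'   \item{`followup_panel`}{45 lines x 2 diets (control, high_fat)
#'     x 2 replicates (180 samples), 45 features, qPCR platform.}
#'   \item{`conserved`}{45 lines x 2 diets (familiar, novel) x 2
#'     replicates, 500 features, trait loadings identical across diets.}
#'   \item{`cryptic`}{as `conserved` but the novel diet's loading
#'     vectors are orthogonal to the familiar diet's: trait-correlate
#'     profiles decorrelate in the novel environment.}
#'   \item{`null`}{as `conserved` but every trait loading is 0.}
#' }
#'
#' @param name scenario name.
#' @param n_features optional feature-count override.
#' @param seed integer seed stored in the spec.
#' @return a `generator_spec`.
#' @export
preset_scenario <- function(name = c("main_panel", "followup_panel",
                                     "conserved", "cryptic", "null"),
                            n_features = NULL, seed = 1L) {
  if (!is.character(name) || !name[1] %in%
      c("main_panel", "followup_panel", "conserved", "cryptic",
        "null")) {
    stop("unknown scenario '", name[1], "'; valid names: main_panel, ",
         "followup_panel, conserved, cryptic, null")
  }
  name <- name[1]
  if (name == "main_panel") {
    nf <- if (is.null(n_features)) 500L else min(as.integer(n_features),
                                                 11650L)
    modules <- data.frame(size = rep(25L, 4), loading = NA,
                          factor_var_G = 1, factor_var_D = 1,
                          factor_var_GxD = 1)
    # Members sit in the G class: idiosyncratic LS-mean variance
    # var_G + var_E / n_reps; loading set for within-module signal
    # share 0.7 on line x diet means.
    idio <- 2 + 1 / 3
    sigma_m2 <- 3
    modules$loading <- sqrt((0.7 / 0.3) * idio / sigma_m2)
    beta0 <- function(v) matrix(rep(v, 4), nrow = 4)  # same on all diets
    diets <- c("normal", "control", "high_sugar", "high_fat")
    tg_beta <- matrix(0, 4, 4, dimnames = list(NULL, diets))
    tg_beta[2, "high_sugar"] <- 1            # module 2: high-sugar only
    tg_beta[3, c("control", "high_sugar")] <- 1
    spec <- generator_spec(
      n_lines = 20L, diets = diets, n_replicates = 3L, n_features = nf,
      feature_classes = data.frame(
        fraction = c(0.3, 0.1, 0.1, 0.5),
        var_G = c(2, 0, 0, 0), var_D = c(0, 2, 0, 0),
        var_GxD = c(0, 0, 2, 0), var_E = 1),
      modules = modules,
      trait_specs = list(
        weight = list(beta = beta0(c(1, 0, 0, 0)), noise_var = 16 / 3),
        triglyceride = list(beta = tg_beta, noise_var = 16 / 3),
        sugar = list(beta = beta0(c(0.4, 0, 0, 1)), noise_var = 16 / 3)),
      seed = seed, platform = "microarray")
  } else if (name == "followup_panel") {
    nf <- if (is.null(n_features)) 45L else as.integer(n_features)
    modules <- data.frame(size = c(9L, 8L, 8L), loading = NA,
                          factor_var_G = 1, factor_var_D = 0.3,
                          factor_var_GxD = 0.5)
    idio <- 0.5 + 1 / 2
    modules$loading <- sqrt((0.7 / 0.3) * idio / 1.8)
    spec <- generator_spec(
      n_lines = 45L, diets = c("control", "high_fat"), n_replicates = 2L,
      n_features = nf,
      feature_classes = data.frame(fraction = 1, var_G = 0.5, var_D = 0,
                                   var_GxD = 0, var_E = 1),
      modules = modules,
      trait_specs = list(
        weight = list(beta = matrix(c(0, 1, 0, 0, 1, 0), 3, 2),
                      noise_var = 1),
        triglyceride = list(beta = matrix(c(1, 0, 0, 1, 0, 0), 3, 2),
                            noise_var = 1),
        sugar = list(beta = matrix(c(0, 0, 1, 0, 0, 1), 3, 2),
                     noise_var = 1)),
      seed = seed, platform = "qpcr")
  } else {
    # Conserved / cryptic / null share one design: 8 planted modules of
    # 50 features (within-module signal share 0.8), each trait loading
    # on 4 modules with signed unit weights.  Spreading the trait over
    # several mid-sized modules keeps the second-order correlation of
    # the per-diet trait-correlate profiles high in the conserved case
    # (about 0.8 in expectation) while averaging module-level sampling
    # noise so the cryptic case sits near 0.
    # Factor variance sits entirely in the genotype-by-diet component:
    # diet-specific factor realizations keep the per-diet profile
    # estimation errors independent between diets, which is what lets
    # the cryptic scenario's cross-diet co-correlation concentrate
    # near zero.
    nf <- if (is.null(n_features)) 500L else as.integer(n_features)
    modules <- data.frame(size = rep(50L, 8), loading = NA,
                          factor_var_G = 0, factor_var_D = 0,
                          factor_var_GxD = 1.5)
    idio <- 1 / 2                       # var_E / n_reps on LS-means
    modules$loading <- sqrt((0.8 / 0.2) * idio / 1.5)
    bet <- function(fam, nov) {
      b <- cbind(familiar = fam, novel = nov)
      rownames(b) <- NULL
      b
    }
    b14 <- c(1, -1, 1, -1, 0, 0, 0, 0)   # modules 1-4
    b36 <- c(0, 0, 1, -1, 1, -1, 0, 0)   # modules 3-6
    b58 <- c(0, 0, 0, 0, 1, -1, 1, -1)   # modules 5-8
    b1278 <- c(1, -1, 0, 0, 0, 0, 1, -1) # modules 1,2,7,8
    z <- rep(0, 8)
    tl <- switch(name,
      conserved = list(
        weight = list(beta = bet(b14, b14), noise_var = 0.5),
        triglyceride = list(beta = bet(b36, b36), noise_var = 0.5),
        sugar = list(beta = bet(b58, b58), noise_var = 0.5)),
      cryptic = list(
        weight = list(beta = bet(b14, b58), noise_var = 0.5),
        triglyceride = list(beta = bet(b36, b1278), noise_var = 0.5),
        sugar = list(beta = bet(b58, b14), noise_var = 0.5)),
      null = list(
        weight = list(beta = bet(z, z), noise_var = 0.5),
        triglyceride = list(beta = bet(z, z), noise_var = 0.5),
        sugar = list(beta = bet(z, z), noise_var = 0.5)))
    spec <- generator_spec(
      n_lines = 45L, diets = c("familiar", "novel"), n_replicates = 2L,
      n_features = nf,
      feature_classes = data.frame(fraction = 1, var_G = 0, var_D = 0,
                                   var_GxD = 0, var_E = 1),
      modules = modules, trait_specs = tl, seed = seed,
      platform = "microarray")
  }
  spec
}

#' Estimate interaction-detection power across replicate counts
#'
#' Simulates datasets at each replicate count in `replicate_grid`,
#' fits the per-feature two-way ANOVA, and reports the fraction of
#' features with planted genotype-by-diet variance detected at the
#' chosen level.  With `adjust = "fdr"` (default) detection means BH
#' q-value at or below `alpha`; with `adjust = "none"` the raw
#' p-value is compared to `alpha`, which under a null spec estimates
#' the false-positive rate.  When the spec plants no interaction
#' variance at all, every feature enters the denominator and the
#' reported rate is a false-positive rate.
#'
#' @param spec a `generator_spec`.
#' @param replicate_grid integer vector of replicate counts (all >= 2:
#'   the interaction is inestimable with fewer than 2 observations per
#'   cell).
#' @param n_sims simulated datasets per grid point.
#' @param alpha detection level.
#' @param adjust `"fdr"` or `"none"`.
#' @return data.frame with one row per grid point: `replicates`,
#'   `n_eval` (feature-by-sim detections evaluated), `power`, `se`
#'   (binomial standard error).
#' @export
power_experiment <- function(spec, replicate_grid, n_sims = 5,
                             alpha = 0.05, adjust = c("fdr", "none")) {
  stopifnot(inherits(spec, "generator_spec"), length(replicate_grid) >= 1,
            n_sims >= 1)
  adjust <- match.arg(adjust)
  if (any(replicate_grid < 2)) {
    stop("replicate_grid values must be >= 2 (interaction inestimable ",
         "with < 2 replicates per cell)")
  }
  rows <- lapply(replicate_grid, function(r) {
    hits <- 0L; tot <- 0L
    for (s in seq_len(n_sims)) {
      sp <- spec
      sp$n_replicates <- as.integer(r)
      sp$seed <- substream_seed(spec$seed, sprintf("power_r%d_s%d", r, s))
      dat <- generate_dataset(sp)
      res <- fit_gxd_anova(dat$fm)
      eval_set <- which(dat$truth$var_GxD > 0)
      if (!length(eval_set)) eval_set <- seq_len(spec$n_features)
      stat <- if (adjust == "fdr") res$q_GxD else res$p_GxD
      hits <- hits + sum(stat[eval_set] <= alpha)
      tot <- tot + length(eval_set)
    }
    p <- hits / tot
    data.frame(replicates = r, n_eval = tot, power = p,
               se = sqrt(p * (1 - p) / tot))
  })
  out <- do.call(rbind, rows)
  log_stage("power", sprintf("grid %s -> power %s (adjust=%s)",
                             paste(replicate_grid, collapse = ","),
                             paste(signif(out$power, 3), collapse = ","),
                             adjust))
  out
}
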
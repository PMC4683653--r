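# Second-order "co-correlation" conservation statistics: the Pearson
# correlation between two vectors of feature-trait correlation
# coefficients, across traits, diets, or measurement platforms, plus
# a permutation null for cross-condition sharing of significant
# feature sets.

#' Co-correlation of two correlation profiles
#'
#' Pearson correlation between the r-vectors of two profiles over
#' their common features.  The analytic p treats features as
#' independent (t distribution, n - 2 df with n the common feature
#' count); because feature-feature correlation violates that, the p
#' is returned with an `independence_caveat` flag.
#'
#' @param a,b `corr_profile` data.frames.
#' @return list of class `co_correlation`: `r`, `p`, `NLP`, `n`,
#'   `independence_caveat = TRUE`.
#' @export
co_correlation <- function(a, b) {
  common <- intersect(a$feature_id, b$feature_id)
  ra <- a$r[match(common, a$feature_id)]
  rb <- b$r[match(common, b$feature_id)]
  ok <- !is.na(ra) & !is.na(rb)
  if (sum(ok) < 3) stop("fewer than 3 common features with defined r")
  r <- cor(ra[ok], rb[ok])
  p <- r_to_p(r, sum(ok))
  structure(list(r = r, p = p, NLP = nlp(p), n = sum(ok),
                 independence_caveat = TRUE),
            class = "co_correlation")
}

#' All pairwise co-correlations among a set of profiles
#'
#' @param profiles named list of `corr_profile`s (names label the
#'   conditions, e.g. `"triglyceride|control"`); pairs sharing fewer
#'   than 3 features yield `NA` cells.
#' @return a list of class `conservation_matrix`: `conditions`, and
#'   symmetric matrices `r` (unit diagonal), `p`, `NLP`, `n_features`.
#' @export
conservation_matrix <- function(profiles) {
  stopifnot(length(profiles) >= 2)
  if (is.null(names(profiles))) {
    names(profiles) <- paste0("C", seq_along(profiles))
  }
  k <- length(profiles)
  nm <- names(profiles)
  r <- p <- nl <- nf <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k)) {
    nf[i, i] <- sum(!is.na(profiles[[i]]$r))
    for (j in seq_len(k)) {
      if (j <= i) next
      cc <- tryCatch(co_correlation(profiles[[i]], profiles[[j]]),
                     error = function(e) NULL)
      if (is.null(cc)) next
      r[i, j] <- r[j, i] <- cc$r
      p[i, j] <- p[j, i] <- cc$p
      nl[i, j] <- nl[j, i] <- cc$NLP
      nf[i, j] <- nf[j, i] <- cc$n
    }
  }
  structure(list(conditions = nm, r = r, p = p, NLP = nl,
                 n_features = nf),
            class = "conservation_matrix")
}

#' @export
print.conservation_matrix <- function(x, ...) {
  cat("conservation_matrix (co-correlation of trait-correlate profiles)\n")
  print(round(x$r, 4))
  invisible(x)
}

#' Permutation test for cross-condition sharing of significant features
#'
#' Null model: each condition's significant set is redrawn uniformly
#' at random (same size) from the feature universe, independently
#' across conditions.  The observed counts of features significant in
#' exactly k conditions are compared to the null distribution; the
#' one-sided permutation p for excess sharing uses the number of
#' features significant in two or more conditions as the statistic,
#' with `p = (1 + #\{perm >= observed\}) / (n_perm + 1)`.
#'
#' @param sig_sets list of feature-id vectors (the significant sets).
#' @param universe feature-id vector (or a single integer size).
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @return a list of class `overlap_test`: `observed` (data.frame
#'   k, count, null_mean, null_sd), `p_excess`, `pairwise` (data.frame
#'   set1, set2, observed, null_mean, null_sd), `n_perm`.
#' @export
chance_overlap_test <- function(sig_sets, universe, n_perm = 1000,
                                seed = 1L) {
  stopifnot(length(sig_sets) >= 2, n_perm >= 100)
  if (length(universe) == 1 && is.numeric(universe)) {
    universe <- seq_len(universe)
  }
  sizes <- lengths(sig_sets)
  if (any(sizes > length(universe))) {
    stop("a significant set exceeds the universe size")
  }
  K <- length(sig_sets)
  count_k <- function(sets) {
    cnt <- table(unlist(lapply(sets, unique)))
    vapply(seq_len(K), function(k) sum(cnt == k), integer(1))
  }
  obs_k <- count_k(sig_sets)
  prs <- combn(K, 2)
  obs_pair <- vapply(seq_len(ncol(prs)), function(i)
    length(intersect(sig_sets[[prs[1, i]]], sig_sets[[prs[2, i]]])),
    integer(1))
  set.seed(substream_seed(seed, "overlap"))
  null_k <- matrix(0L, n_perm, K)
  null_pair <- matrix(0L, n_perm, ncol(prs))
  for (b in seq_len(n_perm)) {
    perm <- lapply(sizes, function(s) sample(universe, s))
    null_k[b, ] <- count_k(perm)
    null_pair[b, ] <- vapply(seq_len(ncol(prs)), function(i)
      length(intersect(perm[[prs[1, i]]], perm[[prs[2, i]]])), integer(1))
  }
  stat_obs <- sum(obs_k[-1])            # features shared by >= 2 conditions
  stat_null <- rowSums(null_k[, -1, drop = FALSE])
  p_excess <- (1 + sum(stat_null >= stat_obs)) / (n_perm + 1)
  observed <- data.frame(k = seq_len(K), count = obs_k,
                         null_mean = colMeans(null_k),
                         null_sd = apply(null_k, 2, sd))
  pairwise <- data.frame(set1 = prs[1, ], set2 = prs[2, ],
                         observed = obs_pair,
                         null_mean = colMeans(null_pair),
                         null_sd = apply(null_pair, 2, sd))
  structure(list(observed = observed, p_excess = p_excess,
                 pairwise = pairwise, n_perm = n_perm),
            class = "overlap_test")
}

#' Cross-platform / cross-diet conservation of trait correlations
#'
#' Builds a per-(platform, diet) correlation profile of the chosen
#' trait on the features shared between two datasets (optionally
#' restricted to their shared genetic lines), then returns the full
#' co-correlation matrix over all platform x diet conditions.
#'
#' @param a,b lists with elements `fm` (a `feature_matrix`) and
#'   `phenotypes` (unit-level trait table), e.g. as returned by
#'   [generate_dataset()].
#' @param trait trait name present in both phenotype tables.
#' @param common_lines_only restrict both datasets to their shared
#'   genetic lines before computing profiles.
#' @return a `conservation_matrix` whose conditions are labeled
#'   `"platform|diet"`.
#' @export
cross_platform <- function(a, b, trait = "triglyceride",
                           common_lines_only = FALSE) {
  shared <- intersect(rownames(a$fm$values), rownames(b$fm$values))
  if (length(shared) < 3) stop("fewer than 3 shared feature ids")
  profiles <- list()
  for (ds in list(a, b)) {
    fm <- ds$fm
    ph <- ds$phenotypes
    if (common_lines_only) {
      cl <- intersect(a$fm$meta$line_id, b$fm$meta$line_id)
      if (length(cl) < 3) stop("fewer than 3 shared genetic lines")
      keep <- fm$meta$line_id %in% cl
      ph <- ph[ph$unit_id %in% fm$meta$sample_id[keep], , drop = FALSE]
      fm <- feature_matrix(fm$values[, keep, drop = FALSE],
                           fm$meta[keep, , drop = FALSE], kind = fm$kind[1])
    }
    fm <- feature_matrix(fm$values[shared, , drop = FALSE], fm$meta,
                         kind = fm$kind[1])
    lsm_f <- ls_means(fm)
    tmat <- as.matrix(ph[match(fm$meta$sample_id, ph$unit_id), trait,
                         drop = FALSE])
    lsm_t <- ls_means(tmat, fm$meta)
    prof <- trait_correlations(lsm_f, lsm_t, scope = "diet",
                               platform = fm$meta$platform[1])
    names(prof) <- sub(paste0("^", trait, "\\|"),
                       paste0(fm$meta$platform[1], "|"), names(prof))
    profiles <- c(profiles, prof)
  }
  names(profiles) <- make.unique(names(profiles))
  conservation_matrix(profiles)
}
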
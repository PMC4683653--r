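# Feature-trait correlation profiles, multi-condition overlap
# accounting, raw trait-trait correlations, and forward stepwise
# regression with BIC for minimal explanatory feature sets.

#' Feature-trait correlation profiles
#'
#' Pearson (or Spearman) correlation of every feature with every trait
#' on the matched least-squares-mean units, pooled across diets or
#' restricted to one diet at a time; two-sided p from the t
#' distribution with n - 2 df.  Constant features get `NA` entries.
#'
#' @param features an `lsmeans_table` of feature values.
#' @param traits an `lsmeans_table` of trait values.
#' @param scope `"pooled"` or `"diet"` (one profile per trait x diet).
#' @param method correlation method.
#' @param platform platform label recorded on each profile.
#' @return a named list of `corr_profile` data.frames (columns
#'   `feature_id`, `r`, `p`, `NLP`, `n`), one per trait (pooled) or
#'   per trait x diet, named `"trait"` or `"trait|diet"`; each carries
#'   attributes `trait`, `diet`, `platform`.
#' @export
trait_correlations <- function(features, traits,
                               scope = c("pooled", "diet"),
                               method = c("pearson", "spearman"),
                               platform = "microarray") {
  stopifnot(inherits(features, "lsmeans_table"),
            inherits(traits, "lsmeans_table"))
  scope <- match.arg(scope)
  method <- match.arg(method)
  common <- intersect(rownames(features$values), rownames(traits$values))
  if (length(common) < 3) stop("fewer than 3 common units")
  subsets <- list(pooled = common)
  if (scope == "diet") {
    du <- features$units$diet_id[match(common, features$units$unit_id)]
    subsets <- lapply(split(common, du), identity)
  }
  out <- list()
  for (tn in colnames(traits$values)) {
    for (sc in names(subsets)) {
      u <- subsets[[sc]]
      X <- features$values[u, , drop = FALSE]
      y <- traits$values[u, tn]
      if (method == "spearman") {
        X <- apply(X, 2, rank)
        y <- rank(y)
      }
      r <- suppressWarnings(as.vector(cor(y, X,
                                          use = "pairwise.complete.obs")))
      prof <- data.frame(feature_id = colnames(features$values),
                         r = r, p = r_to_p(r, length(u)),
                         n = length(u))
      prof$NLP <- nlp(prof$p)
      prof <- prof[c("feature_id", "r", "p", "NLP", "n")]
      attr(prof, "trait") <- tn
      attr(prof, "diet") <- if (scope == "pooled") "pooled" else sc
      attr(prof, "platform") <- platform
      class(prof) <- c("corr_profile", "data.frame")
      key <- if (scope == "pooled") tn else paste(tn, sc, sep = "|")
      out[[key]] <- prof
    }
  }
  log_stage("correlate", sprintf(
    "%d profile(s) over %d features, scope=%s, n(pooled)=%d",
    length(out), ncol(features$values), scope, length(common)))
  out
}

#' Pairwise correlations among raw gross phenotypes
#'
#' Pairwise-complete Pearson correlations of the unit-level trait
#' values, with per-pair observation counts and NLP.
#'
#' @param ph a phenotype data.frame (`unit_id` plus trait columns).
#' @return data.frame: `trait1`, `trait2`, `r`, `count`, `p`, `NLP`.
#' @export
gross_trait_correlations <- function(ph) {
  traits <- setdiff(names(ph), "unit_id")
  prs <- combn(traits, 2)
  rows <- lapply(seq_len(ncol(prs)), function(i) {
    a <- ph[[prs[1, i]]]; b <- ph[[prs[2, i]]]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3) stop("fewer than 3 complete pairs for ",
                          prs[1, i], " / ", prs[2, i])
    r <- cor(a[ok], b[ok])
    p <- r_to_p(r, sum(ok))
    data.frame(trait1 = prs[1, i], trait2 = prs[2, i], r = r,
               count = sum(ok), p = p, NLP = nlp(p))
  })
  do.call(rbind, rows)
}

#' Multi-condition overlap counts of significant features
#'
#' Counts, for every subset of the given conditions (traits or diets),
#' the features significant in exactly that subset at `p < p_threshold`.
#'
#' @param profiles list of `corr_profile`s sharing one feature
#'   universe (error otherwise).
#' @param p_threshold raw significance threshold.
#' @return data.frame of class `venn_counts` with one indicator column
#'   per condition, `count`, and `n_conditions`; counts over nonempty
#'   subsets sum to the union of significant features.
#' @export
venn_overlap <- function(profiles, p_threshold = 0.01) {
  stopifnot(length(profiles) >= 2)
  ids <- lapply(profiles, function(p) p$feature_id)
  for (i in seq_along(ids)[-1]) {
    if (!setequal(ids[[1]], ids[[i]])) {
      stop("profiles do not share a feature universe")
    }
  }
  if (is.null(names(profiles))) names(profiles) <- paste0("C", seq_along(profiles))
  universe <- ids[[1]]
  sig <- vapply(profiles, function(pr) {
    v <- pr$p[match(universe, pr$feature_id)]
    !is.na(v) & v < p_threshold
  }, logical(length(universe)))
  cells <- expand.grid(rep(list(c(FALSE, TRUE)), length(profiles)),
                       KEEP.OUT.ATTRS = FALSE)
  names(cells) <- names(profiles)
  key <- apply(sig, 1, function(z) paste(z + 0, collapse = ""))
  cellkey <- apply(cells, 1, function(z) paste(z + 0, collapse = ""))
  tab <- table(key)
  cells$count <- as.integer(tab[cellkey])
  cells$count[is.na(cells$count)] <- 0L
  cells$n_conditions <- rowSums(cells[names(profiles)])
  attr(cells, "p_threshold") <- p_threshold
  attr(cells, "universe_size") <- length(universe)
  class(cells) <- c("venn_counts", "data.frame")
  cells
}

#' Forward stepwise regression with BIC
#'
#' Starting from the intercept-only model, each step adds the
#' candidate minimizing `BIC = n * ln(RSS / n) + k * ln(n)` (k counts
#' slopes plus intercept) and stops when no addition lowers the BIC;
#' ties are broken by lexicographic feature id.  Candidates collinear
#' with the selected set (R-squared on selected >= 1 - 1e-10) are
#' skipped with a warning.  Per the pipeline contract, `candidates`
#' should already be restricted to features significantly correlated
#' with the trait.
#'
#' @param candidates numeric matrix, units x candidate features
#'   (colnames = feature ids).
#' @param y trait values, one per unit.
#' @param trait trait label stored in the result.
#' @return a list of class `stepwise_model`: `trait`, `selected`
#'   (ids in entry order), `coefficients` (final fit), `r_squared`,
#'   `bic_trace` (BIC after each accepted step, starting at the
#'   intercept-only model), `n`.
#' @export
forward_stepwise_bic <- function(candidates, y, trait = "trait") {
  X <- as.matrix(candidates)
  stopifnot(nrow(X) == length(y), !is.null(colnames(X)))
  n <- length(y)
  bic <- function(rss, k) n * log(rss / n) + k * log(n)
  rss0 <- sum((y - mean(y))^2)
  tss <- rss0
  selected <- character()
  cur <- cbind(`(Intercept)` = rep(1, n))
  cur_rss <- rss0
  trace <- bic(rss0, 1)
  remaining <- colnames(X)[order(colnames(X))]
  repeat {
    if (n <= ncol(cur) + 2 || !length(remaining)) break
    best_id <- NULL; best_bic <- Inf; best_rss <- NA
    for (id in remaining) {             # lexicographic order: ties keep first
      xj <- X[, id]
      fit_x <- lm.fit(cur, xj)
      if (sum(fit_x$residuals^2) <= 1e-10 * sum((xj - mean(xj))^2)) {
        warning("skipping collinear candidate: ", id)
        remaining <- setdiff(remaining, id)
        next
      }
      fit <- lm.fit(cbind(cur, xj), y)
      rss <- sum(fit$residuals^2)
      b <- bic(rss, ncol(cur) + 1)
      if (b < best_bic - 1e-12) {
        best_bic <- b; best_id <- id; best_rss <- rss
      }
    }
    if (is.null(best_id) || best_bic >= trace[length(trace)]) break
    selected <- c(selected, best_id)
    cur <- cbind(cur, X[, best_id])
    colnames(cur)[ncol(cur)] <- best_id
    cur_rss <- best_rss
    trace <- c(trace, best_bic)
    remaining <- setdiff(remaining, best_id)
    if (cur_rss <= 1e-12 * tss) break   # numerically perfect fit
  }
  fit <- lm.fit(cur, y)
  r2 <- 1 - sum(fit$residuals^2) / tss
  log_stage("stepwise", sprintf(
    "%s: %d of %d candidate(s) selected, R^2 = %.3f", trait,
    length(selected), ncol(X), r2))
  structure(list(trait = trait, selected = selected,
                 coefficients = setNames(fit$coefficients, colnames(cur)),
                 r_squared = r2, bic_trace = trace, n = n),
            class = "stepwise_model")
}

#' @export
print.stepwise_model <- function(x, ...) {
  cat(sprintf("stepwise_model for '%s': %d predictor(s), R^2 = %.3f\n",
              x$trait, length(x$selected), x$r_squared))
  if (length(x$selected)) {
    cat("  entry order:", paste(x$selected, collapse = " -> "), "\n")
  }
  invisible(x)
}
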
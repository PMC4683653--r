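# Per-feature two-way fixed-effects ANOVA:
#   Y_ijm = mu + G_i + D_j + GxD_ij + e_ijm
# Type III sums of squares via full-vs-reduced fits with sum-to-zero
# contrasts (equal to the classical Type I decomposition on balanced
# data), F ratios against the error mean square, and per-effect BH
# false-discovery control across features.

#' Fit the genotype x diet ANOVA to every feature
#'
#' @param fm a `feature_matrix` (features x samples with line/diet
#'   metadata).
#' @return a data.frame of class `anova_result`, one row per feature,
#'   with sums of squares (`SS_G`, `SS_D`, `SS_GxD`, `SS_E`,
#'   `SS_total`), degrees of freedom, F statistics, p-values, NLP
#'   (-log10 p) and BH q-values for the genetic, dietary, and
#'   genotype-by-diet effects.  Features whose missing values empty a
#'   line x diet cell are excluded (`NA` rows) with a warning.
#' @export
fit_gxd_anova <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  meta <- fm$meta
  line <- factor(meta$line_id)
  diet <- factor(meta$diet_id)
  L <- nlevels(line); J <- nlevels(diet)
  if (L < 2 || J < 2) stop("need >= 2 lines and >= 2 diets")
  if (any(table(line, diet) == 0)) {
    stop("empty line x diet cell: interaction inestimable")
  }
  n <- length(line)
  if (n <= L * J) stop("saturated model: no residual degrees of freedom")

  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  X_full <- stats::model.matrix(~ line * diet)
  asg <- attr(X_full, "assign")
  qr_full <- qr(X_full)
  qr_red <- lapply(1:3, function(a) qr(X_full[, asg != a, drop = FALSE]))

  df_G <- L - 1L; df_D <- J - 1L; df_I <- (L - 1L) * (J - 1L)
  df_E <- n - qr_full$rank

  Y <- t(fm$values)                      # samples x features
  complete <- !colSums(is.na(Y))
  res <- matrix(NA_real_, ncol(Y), 14,
                dimnames = list(colnames(Y),
                                c("SS_G", "SS_D", "SS_GxD", "SS_E",
                                  "SS_total", "F_G", "F_D", "F_GxD",
                                  "p_G", "p_D", "p_GxD",
                                  "df_E", "n_obs", "excluded")))

  fill <- function(rss_full, ss, dfe, tot, rows, nobs) {
    # grand-mean-constant features: no variation to partition
    degen <- tot <= .Machine$double.eps * nobs
    rss_full[degen] <- 0
    ss[degen, ] <- 0
    msE <- rss_full / dfe
    Fst <- sweep(ss / rep(c(df_G, df_D, df_I), each = nrow(ss)), 1, msE, "/")
    Fst[msE == 0, ] <- ifelse(ss[msE == 0, , drop = FALSE] > 0, Inf, 0)
    p <- cbind(pf(Fst[, 1], df_G, dfe, lower.tail = FALSE),
               pf(Fst[, 2], df_D, dfe, lower.tail = FALSE),
               pf(Fst[, 3], df_I, dfe, lower.tail = FALSE))
    p[Fst == 0] <- 1
    res[rows, ] <<- cbind(ss, rss_full, tot, Fst, p, dfe, nobs, 0)
  }

  if (any(complete)) {
    Yc <- Y[, complete, drop = FALSE]
    rss_full <- colSums(qr.resid(qr_full, Yc)^2)
    ss <- vapply(1:3, function(a)
      colSums(qr.resid(qr_red[[a]], Yc)^2) - rss_full, numeric(ncol(Yc)))
    ss <- matrix(pmax(ss, 0), ncol = 3)
    tot <- colSums(sweep(Yc, 2, colMeans(Yc))^2)
    fill(rss_full, ss, df_E, tot, which(complete), n)
  }

  excluded <- character()
  for (j in which(!complete)) {
    ok <- !is.na(Y[, j])
    if (any(table(line[ok], diet[ok]) == 0) || sum(ok) <= L * J) {
      excluded <- c(excluded, colnames(Y)[j])
      res[j, "excluded"] <- 1
      next
    }
    Xf <- stats::model.matrix(~ line * diet,
                              data = data.frame(line = line[ok],
                                                diet = diet[ok]))
    asg_j <- attr(Xf, "assign")
    qf <- qr(Xf)
    yv <- Y[ok, j]
    rssf <- sum(qr.resid(qf, yv)^2)
    ssj <- vapply(1:3, function(a)
      sum(qr.resid(qr(Xf[, asg_j != a, drop = FALSE]), yv)^2) - rssf,
      numeric(1))
    fill(rssf, matrix(pmax(ssj, 0), 1), sum(ok) - qf$rank,
         sum((yv - mean(yv))^2), j, sum(ok))
  }
  if (length(excluded)) {
    warning("feature(s) excluded (missing values empty a design cell): ",
            paste(excluded, collapse = ", "))
  }

  out <- as.data.frame(res)
  out$excluded <- out$excluded == 1
  out <- cbind(feature_id = colnames(Y), out)
  out$df_G <- df_G; out$df_D <- df_D; out$df_GxD <- df_I
  for (eff in c("G", "D", "GxD")) {
    p <- out[[paste0("p_", eff)]]
    out[[paste0("NLP_", eff)]] <- nlp(p)
    q <- rep(NA_real_, length(p))
    q[!is.na(p)] <- bh_fdr(p[!is.na(p)])
    out[[paste0("q_", eff)]] <- q
  }
  rownames(out) <- NULL
  class(out) <- c("anova_result", "data.frame")
  log_stage("anova", sprintf(
    "%d features, %d lines x %d diets, df_E=%d; q<=0.05: G=%d D=%d GxD=%d",
    nrow(out), L, J, df_E, sum(out$q_G <= 0.05, na.rm = TRUE),
    sum(out$q_D <= 0.05, na.rm = TRUE),
    sum(out$q_GxD <= 0.05, na.rm = TRUE)))
  out
}

#' Benjamini-Hochberg step-up q-values
#'
#' Linear step-up false-discovery-rate adjustment:
#' `q_(i) = min_(j >= i) m * p_(j) / j`, mapped back to the input
#' order.  Ties share their sorted position.
#'
#' @param p vector of p-values in (0, 1].
#' @return q-values in (0, 1], same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Least-squares means by design cell
#'
#' Cell means of each feature (or trait) grouped by line x diet or
#' line x diet x replicate.  On a balanced design these are the
#' arithmetic cell means; on unbalanced data they equal the saturated
#' two-way model's predicted cell values, which are again the observed
#' cell means wherever the cell is nonempty.  Empty cells are dropped
#' with a warning.
#'
#' @param x a `feature_matrix`, or a numeric matrix/data.frame of
#'   traits with one row per sample (aligned to `meta`).
#' @param meta sample metadata (taken from `x` when it is a
#'   `feature_matrix`).
#' @param grouping `"line_diet"` or `"line_diet_replicate"`.
#' @return a list of class `lsmeans_table`: `units` (data.frame of
#'   unit_id, line_id, diet_id and, if applicable, replicate_id) and
#'   `values` (units x features matrix).
#' @export
ls_means <- function(x, meta = NULL,
                     grouping = c("line_diet", "line_diet_replicate")) {
  grouping <- match.arg(grouping)
  if (inherits(x, "feature_matrix")) {
    meta <- x$meta
    vals <- t(x$values)                  # samples x features
  } else {
    stopifnot(!is.null(meta))
    vals <- as.matrix(x)
    stopifnot(nrow(vals) == nrow(meta))
  }
  keys <- if (grouping == "line_diet") {
    paste(meta$line_id, meta$diet_id, sep = "|")
  } else {
    paste(meta$line_id, meta$diet_id, meta$replicate_id, sep = "|")
  }
  # Deterministic unit order: line, then diet (then replicate).
  ord_keys <- unique(keys[order(meta$line_id, meta$diet_id,
                                meta$replicate_id)])
  grp <- factor(keys, levels = ord_keys)
  counts <- rowsum((!is.na(vals)) + 0, grp)
  sums <- rowsum(ifelse(is.na(vals), 0, vals), grp)
  m <- sums / counts
  m[counts == 0] <- NA_real_
  parts <- do.call(rbind, strsplit(ord_keys, "|", fixed = TRUE))
  units <- data.frame(unit_id = gsub("|", "_", ord_keys, fixed = TRUE),
                      line_id = parts[, 1], diet_id = parts[, 2])
  if (grouping == "line_diet_replicate") units$replicate_id <- parts[, 3]
  rownames(m) <- units$unit_id
  structure(list(units = units, values = m, grouping = grouping),
            class = "lsmeans_table")
}

#' Partition features by which effects reach significance
#'
#' Counts features in each subset of \{G, D, GxD\} significant at the
#' q-value threshold (the 8-cell Venn partition plus a "none" cell).
#'
#' @param res an `anova_result`.
#' @param q_threshold FDR threshold, default 0.05.
#' @return data.frame of class `effect_partition` with columns `G`,
#'   `D`, `GxD` (logical cell definition) and `count`; counts sum to
#'   the number of scored features.
#' @export
classify_significance <- function(res, q_threshold = 0.05) {
  stopifnot(inherits(res, "anova_result"))
  ok <- !is.na(res$q_G) & !is.na(res$q_D) & !is.na(res$q_GxD)
  sG <- res$q_G[ok] <= q_threshold
  sD <- res$q_D[ok] <= q_threshold
  sI <- res$q_GxD[ok] <= q_threshold
  cells <- expand.grid(G = c(FALSE, TRUE), D = c(FALSE, TRUE),
                       GxD = c(FALSE, TRUE))
  cells$count <- vapply(seq_len(nrow(cells)), function(i)
    sum(sG == cells$G[i] & sD == cells$D[i] & sI == cells$GxD[i]),
    integer(1))
  attr(cells, "q_threshold") <- q_threshold
  attr(cells, "n_features") <- sum(ok)
  class(cells) <- c("effect_partition", "data.frame")
  cells
}

#' Least-squares means of gross phenotypes
#'
#' Convenience wrapper aligning a unit-level phenotype table to the
#' sample metadata before calling [ls_means()].
#'
#' @param ph phenotype data.frame (`unit_id` plus trait columns).
#' @param meta sample metadata.
#' @param grouping see [ls_means()].
#' @return an `lsmeans_table` with one column per trait.
#' @export
phenotype_ls_means <- function(ph, meta,
                               grouping = c("line_diet",
                                            "line_diet_replicate")) {
  traits <- setdiff(names(ph), "unit_id")
  tmat <- as.matrix(ph[match(meta$sample_id, ph$unit_id), traits,
                       drop = FALSE])
  rownames(tmat) <- NULL
  ls_means(tmat, meta, grouping = match.arg(grouping))
}
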
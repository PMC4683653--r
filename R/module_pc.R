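# Module summarization by the first principal component ("eigengene")
# and its mapping to gross phenotypes and reaction norms.

#' First principal component of a module
#'
#' Member profiles are standardized (zero mean, unit variance across
#' units) before eigen-decomposition, so the PC is that of the member
#' correlation matrix and high-variance members do not dominate.
#' Loadings are unit norm with the sign convention that their sum is
#' nonnegative (the component of largest magnitude is made positive on
#' an exact tie), so repeated runs agree exactly.
#'
#' @param lsm an `lsmeans_table`.
#' @param members member feature ids (>= 2 usable after dropping
#'   constants).
#' @param module optional module index carried into the result.
#' @return a list of class `module_pc`: `module`, `loadings` (named,
#'   unit norm), `scores` (named by unit), `variance_explained`
#'   (leading eigenvalue share), `sign_convention`.
#' @export
module_pc1 <- function(lsm, members, module = NA_integer_) {
  stopifnot(inherits(lsm, "lsmeans_table"))
  miss <- setdiff(members, colnames(lsm$values))
  if (length(miss)) stop("member(s) not in table: ",
                         paste(miss, collapse = ", "))
  X <- lsm$values[, members, drop = FALSE]
  if (nrow(X) < 3) stop("need >= 3 units")
  sds <- apply(X, 2, sd)
  if (any(is.na(sds) | sds == 0)) {
    warning("dropping constant member(s): ",
            paste(members[is.na(sds) | sds == 0], collapse = ", "))
    X <- X[, !(is.na(sds) | sds == 0), drop = FALSE]
  }
  if (ncol(X) < 2) stop("fewer than 2 usable members")
  Z <- scale(X)
  S <- crossprod(Z) / (nrow(Z) - 1)     # member correlation matrix
  eig <- eigen(S, symmetric = TRUE)
  v <- eig$vectors[, 1]
  if (sum(v) < 0 || (sum(v) == 0 && v[which.max(abs(v))] < 0)) v <- -v
  scores <- as.vector(Z %*% v)
  names(scores) <- rownames(lsm$values)
  structure(list(module = module,
                 loadings = setNames(v, colnames(X)),
                 scores = scores,
                 variance_explained = eig$values[1] / sum(eig$values),
                 sign_convention = "sum_of_loadings_nonnegative",
                 units = lsm$units),
            class = "module_pc")
}

#' Correlate module PC1 scores with gross traits
#'
#' Pearson correlation between the module's PC1 scores and each trait's
#' least-squares means over the common units, pooled across diets and
#' (optionally) within each diet; two-sided p from the t distribution
#' with n - 2 df.  Pairs with fewer than 3 common units are flagged
#' not-computable (`NA` statistics).
#'
#' @param pc a `module_pc`.
#' @param traits an `lsmeans_table` of trait values (columns traits).
#' @param per_diet also report per-diet correlations.
#' @return data.frame of class `module_trait_result`: `module`,
#'   `trait`, `diet` (`"pooled"` or a diet id), `r`, `p`, `NLP`, `n`.
#' @export
correlate_module_traits <- function(pc, traits, per_diet = TRUE) {
  stopifnot(inherits(pc, "module_pc"), inherits(traits, "lsmeans_table"))
  common <- intersect(names(pc$scores), rownames(traits$values))
  scopes <- list(pooled = common)
  if (per_diet) {
    du <- traits$units$diet_id[match(common, traits$units$unit_id)]
    for (d in unique(du)) scopes[[d]] <- common[du == d]
  }
  rows <- list()
  for (tn in colnames(traits$values)) {
    for (sc in names(scopes)) {
      u <- scopes[[sc]]
      u <- u[!is.na(traits$values[u, tn]) & !is.na(pc$scores[u])]
      if (length(u) < 3) {
        rows[[length(rows) + 1L]] <- data.frame(
          module = pc$module, trait = tn, diet = sc, r = NA_real_,
          p = NA_real_, NLP = NA_real_, n = length(u))
        next
      }
      r <- cor(pc$scores[u], traits$values[u, tn])
      p <- r_to_p(r, length(u))
      rows[[length(rows) + 1L]] <- data.frame(
        module = pc$module, trait = tn, diet = sc, r = r, p = p,
        NLP = nlp(p), n = length(u))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("module_trait_result", "data.frame")
  out
}

#' Genotype-by-diet reaction norms of module PC1 scores
#'
#' @param pc a `module_pc` computed on line x diet units.
#' @return a matrix, one row per line and one column per diet, of mean
#'   PC1 scores (`NA` flags missing cells).
#' @export
reaction_norms <- function(pc) {
  stopifnot(inherits(pc, "module_pc"))
  u <- pc$units
  lines <- unique(u$line_id); diets <- unique(u$diet_id)
  agg <- tapply(pc$scores[u$unit_id], list(factor(u$line_id, lines),
                                           factor(u$diet_id, diets)),
                mean)
  out <- matrix(as.numeric(agg), length(lines), length(diets),
                dimnames = list(lines, diets))
  out
}
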
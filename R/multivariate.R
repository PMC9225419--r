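# Global multivariate structure: PERMANOVA on a compositional distance
# matrix and PCA on ilr balances.

#' Permutation multivariate analysis of variance (one-way)
#'
#' Anderson's pseudo-F from the among/within decomposition of squared
#' distances, with a permutation p-value under the add-one rule
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`. With `exhaustive = TRUE`
#' all `n!` relabelings are enumerated (small n only) and the p-value is
#' the exact proportion of relabelings (identity included) with
#' `F >= F_obs`.
#'
#' @param d symmetric distance matrix (or `dist`) with zero diagonal.
#' @param labels group label per sample (>= 2 groups, each >= 2 samples).
#' @param n_perm number of random label permutations.
#' @param seed integer seed making the permutation stream reproducible.
#' @param exhaustive enumerate all permutations instead of sampling.
#' @param keep_null return the permuted F values.
#' @return list of class `"permanova"`: `pseudo_F`, `p_value`,
#'   `n_permutations`, and `permuted_F` when requested.
#' @export
permanova <- function(d, labels, n_perm = 19999, seed = 1,
                      exhaustive = FALSE, keep_null = FALSE) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8) ||
      any(abs(diag(d)) > 1e-8))
    stop("d must be a symmetric zero-diagonal distance matrix")
  lab <- factor(labels)
  n <- nrow(d)
  if (length(lab) != n) stop("one label per sample required")
  if (nlevels(lab) < 2 || any(table(lab) < 2))
    stop("need >= 2 groups with >= 2 samples each")
  if (!exhaustive && n_perm < 1) stop("n_perm must be >= 1")
  d2 <- d^2
  k <- nlevels(lab)
  sst <- sum(d2) / (2 * n)
  ilab0 <- as.integer(lab)
  pseudo_f <- function(ilab) {
    ssw <- 0
    for (g in seq_len(k)) {
      idx <- which(ilab == g)
      ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
    }
    ((sst - ssw) / (k - 1)) / (ssw / (n - k))
  }
  f0 <- pseudo_f(ilab0)
  if (exhaustive) {
    perms <- .all_perms(n)
    fp <- apply(perms, 1, function(o) pseudo_f(ilab0[o]))
    p <- mean(fp >= f0 - 1e-12)
    n_eff <- nrow(perms)
  } else {
    set.seed(seed)
    fp <- vapply(seq_len(n_perm),
                 function(i) pseudo_f(ilab0[sample.int(n)]), numeric(1))
    p <- (1 + sum(fp >= f0 - 1e-12)) / (1 + n_perm)
    n_eff <- n_perm
  }
  structure(list(pseudo_F = f0, p_value = p, n_permutations = n_eff,
                 permuted_F = if (keep_null) fp else NULL),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA: pseudo-F =", format(x$pseudo_F, digits = 5),
      " p =", format(x$p_value, digits = 4),
      " (", x$n_permutations, "permutations )\n")
  invisible(x)
}

#' Principal component analysis of a balance matrix
#'
#' Column-centered SVD (no scaling); returns sample scores and the
#' fraction of variance each component explains.
#'
#' @param b numeric matrix, samples x balances (or any features).
#' @return list of class `"pca_result"`: `scores`, `explained_fraction`,
#'   `sdev`.
#' @export
balance_pca <- function(b) {
  if (nrow(b) < 2) stop("need at least 2 samples")
  if (all(apply(b, 2, stats::var) < 1e-15))
    stop("constant matrix: no variance to decompose")
  pc <- stats::prcomp(b, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  structure(list(scores = pc$x, explained_fraction = ev / sum(ev),
                 sdev = pc$sdev),
            class = "pca_result")
}

#' Association between a principal component and a sample covariate
#'
#' Linear model for a numeric covariate, Welch t-test for a two-level
#' covariate; the Bonferroni-adjusted p accounts for the number of
#' components examined.
#'
#' @param scores numeric vector of one component's sample scores.
#' @param covariate numeric or two-level categorical, one value per sample.
#' @param n_components number of PCs examined (Bonferroni divisor).
#' @return data.frame with `p_value`, `p_bonferroni`, `method`.
#' @export
pc_association <- function(scores, covariate, n_components = 2) {
  ok <- !is.na(covariate)
  if (!any(ok)) stop("covariate is entirely missing")
  sc <- scores[ok]
  cv <- covariate[ok]
  if (is.numeric(cv)) {
    if (stats::var(cv) < 1e-15) stop("constant covariate")
    fit <- summary(stats::lm(sc ~ cv))
    p <- fit$coefficients["cv", "Pr(>|t|)"]
    method <- "linear_model"
  } else {
    cv <- factor(cv)
    if (nlevels(cv) != 2)
      stop("categorical covariate must have exactly 2 levels")
    p <- stats::t.test(sc ~ cv)$p.value
    method <- "welch_t"
  }
  data.frame(p_value = p, p_bonferroni = min(1, p * n_components),
             method = method)
}
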
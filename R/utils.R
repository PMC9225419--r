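# Internal numerical helpers shared by the testing modules.

# Fit Y (n x m response matrix) on a fixed design X by least squares and
# return the t-test of one coefficient for every column of Y at once.
# Columns of Y that are constant get estimate 0 and p = 1 (the caller warns).
.lm_matrix_t <- function(Y, X, coef_idx) {
  n <- nrow(X)
  stopifnot(nrow(Y) == n)
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Y)
  res <- Y - X %*% B
  df <- n - ncol(X)
  if (df < 1) stop("not enough residual degrees of freedom")
  sig2 <- colSums(res^2) / df
  se <- sqrt(sig2 * XtXi[coef_idx, coef_idx])
  est <- B[coef_idx, ]
  tval <- est / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  const <- apply(Y, 2, function(y) max(y) - min(y) < 1e-12)
  p[!is.finite(p)] <- 1
  est[const] <- 0
  p[const] <- 1
  list(estimate = est, se = se, p_value = p, df = df, constant = const)
}

# F-test comparing full design X1 against nested design X0, per column of Y.
.lm_matrix_f <- function(Y, X1, X0) {
  n <- nrow(X1)
  rss <- function(X) {
    B <- solve(crossprod(X), crossprod(X, Y))
    colSums((Y - X %*% B)^2)
  }
  rss1 <- rss(X1)
  rss0 <- rss(X0)
  df1 <- n - ncol(X1)
  q <- ncol(X1) - ncol(X0)
  if (df1 < 1) stop("not enough residual degrees of freedom")
  f <- ((rss0 - rss1) / q) / (rss1 / df1)
  p <- stats::pf(f, q, df1, lower.tail = FALSE)
  const <- apply(Y, 2, function(y) max(y) - min(y) < 1e-12)
  p[!is.finite(p)] <- 1
  p[const] <- 1
  list(f = f, p_value = p, df1 = q, df2 = df1, constant = const)
}

# Batch design columns (treatment-coded dummies); NULL when batch has one
# level so intercept-only designs stay full rank.
.batch_design <- function(batch) {
  batch <- factor(batch)
  if (nlevels(batch) < 2) return(NULL)
  stats::model.matrix(~batch)[, -1, drop = FALSE]
}

# All permutations of 1..n (small n only); deterministic order.
.all_perms <- function(n) {
  if (n > 8) stop("exhaustive permutation enumeration limited to n <= 8")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

# Deterministic per-stage seed derivation so adding one planted effect does
# not perturb draws in unrelated generation stages. Kept below 2^31.
.stage_seed <- function(seed, stage) {
  (as.numeric(seed) + 77003 * stage) %% 2147483629
}

.fmt_count <- function(n, what) {
  sprintf("%d %s%s", n, what, if (n == 1) "" else "s")
}
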
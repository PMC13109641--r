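# Shared fixtures and independent oracles, built in code at test time.

# Small simulated panel used across files (no TF modules: they are not
# relevant to the regression-side tests and need a larger gene universe).
tiny_panel <- function(n = 60, p = 120, n_mr = 5, seed = 3, ...) {
  sim <- simulate_mutant_panel(sim_config(n_mutants = n, n_genes = p,
                                          n_mr = n_mr, seed = seed,
                                          n_tf_modules = 0, ...))
  list(sim = sim, panel = align_panel(sim))
}

# Independent weighted-LASSO oracle: pure-R cyclic coordinate descent on the
# row-scaled (sqrt w) problem with an explicit unpenalised intercept column.
# This is both the "row-scaling equivalence" route and an implementation
# independent of the compiled solver.
ref_weighted_lasso <- function(X, y, w, alpha, tol = 1e-13, maxit = 2e5) {
  sw <- sqrt(w)
  Z <- cbind(sw, sw * X)
  yz <- sw * y
  b <- numeric(ncol(Z))
  zz <- colSums(Z^2)
  pen <- c(0, rep(alpha / 2, ncol(X)))
  r <- yz
  for (it in seq_len(maxit)) {
    mx <- 0
    for (j in seq_along(b)) {
      zj <- sum(Z[, j] * r) + zz[j] * b[j]
      bj <- if (pen[j] == 0) zj / zz[j]
            else sign(zj) * max(0, abs(zj) - pen[j]) / zz[j]
      if (bj != b[j]) {
        r <- r - Z[, j] * (bj - b[j])
        mx <- max(mx, abs(bj - b[j]))
        b[j] <- bj
      }
    }
    if (mx < tol) break
  }
  list(beta0 = b[1L], beta = b[-1L])
}

weighted_cost <- function(X, y, w, alpha, beta0, beta) {
  sum(w * (y - beta0 - drop(X %*% beta))^2) + alpha * sum(abs(beta))
}

# Closed-form weighted OLS via normal equations.
ref_weighted_ols <- function(X, y, w) {
  Z <- cbind(1, X)
  drop(solve(crossprod(Z, w * Z), crossprod(Z, w * y)))
}

# Brute-force two-sample KS D: sup over all observed points of |ECDF1-ECDF2|.
ref_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# Exact rank-sum moments by exhaustive enumeration of all target subsets of
# the given effect vector (ties handled naturally through average ranks).
ref_ranksum_z <- function(eff, targets) {
  rk <- rank(eff)
  n1 <- sum(names(eff) %in% targets)
  idx <- utils::combn(length(eff), n1)
  Us <- colSums(matrix(rk[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  U_obs <- sum(rk[names(eff) %in% targets]) - n1 * (n1 + 1) / 2
  mu <- mean(Us)
  sigma <- sqrt(mean((Us - mu)^2))   # population s.d. of the exact null
  (U_obs - mu) / sigma
}

# Simple F1 of a selected gene set against the planted truth.
recovery_f1 <- function(selected, truth) {
  tp <- length(intersect(selected, truth))
  if (tp == 0) return(0)
  2 * tp / (length(selected) + length(truth))
}
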
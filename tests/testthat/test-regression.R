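test_that("reliability weights follow n/(n+c) with the expected bounds", {
  expect_identical(rls_weights(50), 0.5)
  expect_equal(rls_weights(5), 5 / 55)
  expect_equal(rls_weights(1837), 1837 / 1887)
  n <- c(1, 2, 5, 10, 50, 100, 500, 2000)
  w <- rls_weights(n)
  expect_true(all(diff(w) > 0))          # strictly increasing in n
  expect_true(all(w > 0 & w < 1))
  expect_equal(rls_weights(30, c = 30), 0.5)   # midpoint for any constant
  expect_error(rls_weights(0), ">= 1")
  expect_error(rls_weights(10, c = -1), "positive")
})

test_that("self-handling strategies transform exactly as specified", {
  X <- matrix(c(-8, 0.3, 0.1, -8), 2, 2, byrow = TRUE,
              dimnames = list(c("g1-del", "g2-del"), c("g1", "g2")))
  map <- c("g1-del" = "g1", "g2-del" = "g2")

  s0 <- apply_self_handling(X, "self0", deleted_gene_of = map)
  expect_identical(unname(s0["g1-del", "g1"]), 0)
  expect_identical(unname(s0["g2-del", "g2"]), 0)
  expect_identical(unname(s0["g1-del", "g2"]), 0.3)
  expect_error(apply_self_handling(X, "self0"), "deleted_gene_of")

  nl <- apply_self_handling(X, "nonlinear", s = 2)
  expect_equal(unname(nl["g1-del", "g1"]), -2 * tanh(4))   # ~ -1.99866
  expect_identical(apply_self_handling(matrix(0, 1, 1), "nonlinear")[1, 1], 0)
  v <- seq(-10, 10, by = 0.5)
  g <- apply_self_handling(matrix(v, ncol = 1), "nonlinear", s = 2)[, 1]
  expect_equal(g, -rev(g))               # odd function
  expect_true(all(abs(g) < 2))           # bounded by s
  expect_equal((apply_self_handling(matrix(1e-6, 1, 1), "nonlinear",
                                    s = 2)[1, 1]) / 1e-6, 1,
               tolerance = 1e-9)         # identity slope at 0
})

test_that("penalties at or above the critical value give the null model", {
  tp <- tiny_panel(n = 40, p = 60, seed = 12)
  panel <- tp$panel
  amax <- alpha_max(panel)
  fit <- mrlasso(panel, alpha = amax * 1.001)
  expect_identical(nrow(fit$selected_genes), 0L)
  w <- panel$weights; y <- panel$lifespan$pct_change
  expect_equal(fit$beta0, sum(w * y) / sum(w), tolerance = 1e-8)
  # just below the critical value something enters
  fit2 <- mrlasso(panel, alpha = amax * 0.95)
  expect_gt(nrow(fit2$selected_genes), 0L)
})

test_that("the alpha = 0 fit matches closed-form weighted least squares", {
  set.seed(42)
  for (rep in 1:10) {
    n <- 20; p <- 5
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(paste0("m", 1:n), paste0("g", 1:p)))
    y <- drop(X %*% rnorm(p, 0, 2) + rnorm(n))
    nc <- sample(c(5L, 25L, 100L, 1000L), n, replace = TRUE)
    panel <- align_panel(X, data.frame(strain = rownames(X), pct_change = y,
                                       n_cells = nc, p_value = NA_real_))
    fit <- mrlasso(panel, alpha = 0, self_handling = "none", tol = 1e-20)
    ols <- ref_weighted_ols(X, y, panel$weights)
    expect_equal(unname(c(fit$beta0, fit$beta)), unname(ols),
                 tolerance = 1e-8)
  }
})

test_that("solver objective matches an independent coordinate-descent oracle", {
  set.seed(21)
  for (rep in 1:6) {
    n <- 25; p <- 8
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(paste0("m", 1:n), paste0("g", 1:p)))
    y <- drop(X %*% c(3, -2, rep(0, p - 2)) + rnorm(n))
    nc <- sample(c(5L, 50L, 500L), n, replace = TRUE)
    panel <- align_panel(X, data.frame(strain = rownames(X), pct_change = y,
                                       n_cells = nc, p_value = NA_real_))
    for (a in c(10, 1)) {
      fit <- mrlasso(panel, alpha = a, self_handling = "none", tol = 1e-14)
      orc <- ref_weighted_lasso(X, y, panel$weights, a)
      o_fit <- fit$objective_value
      o_orc <- weighted_cost(X, y, panel$weights, a, orc$beta0, orc$beta)
      expect_lt(abs(o_fit - o_orc) / o_orc, 1e-6)
    }
  }
})

test_that("weighted fit equals the sqrt(w) row-scaled unweighted fit", {
  # the reference solver literally implements the row-scaled route with a
  # scaled unpenalised intercept column
  set.seed(99)
  for (rep in 1:10) {
    n <- 20; p <- 5
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(paste0("m", 1:n), paste0("g", 1:p)))
    y <- drop(X %*% rnorm(p) + rnorm(n))
    w <- runif(n, 0.05, 1)
    panel <- align_panel(X, data.frame(strain = rownames(X), pct_change = y,
                                       n_cells = 50 * w / (1 - w),
                                       p_value = NA_real_))
    expect_equal(panel$weights, w, tolerance = 1e-12)
    a <- runif(1, 0.5, 5)
    fit <- mrlasso(panel, alpha = a, self_handling = "none", tol = 1e-20)
    scaled <- ref_weighted_lasso(X, y, w, a, tol = 1e-15)
    expect_equal(unname(c(fit$beta0, fit$beta)),
                 c(scaled$beta0, scaled$beta), tolerance = 1e-8)
  }
})

test_that("single-feature fit equals the soft-thresholded closed form", {
  set.seed(5)
  n <- 30
  x <- rnorm(n)
  y <- 2 * x + rnorm(n)
  X <- matrix(x, dimnames = list(paste0("m", 1:n), "g1"))
  panel <- align_panel(X, data.frame(strain = rownames(X), pct_change = y,
                                     n_cells = 1e6L, p_value = NA_real_))
  for (a in c(0.5, 5, 40)) {
    fit <- mrlasso(panel, alpha = a, self_handling = "none", tol = 1e-20)
    # constant weights: closed-form soft-threshold fixed-point iteration
    wc <- 1e6 / (1e6 + 50)
    b <- 0; b0 <- mean(y)
    for (k in 1:5000) {
      z <- wc * sum(x * (y - b0))
      b_new <- sign(z) * max(0, abs(z) - a / 2) / (wc * sum(x^2))
      b0_new <- mean(y - x * b_new)
      if (abs(b_new - b) < 1e-15 && abs(b0_new - b0) < 1e-15) break
      b <- b_new; b0 <- b0_new
    }
    expect_equal(unname(fit$beta[1]), b, tolerance = 1e-7)
    expect_equal(fit$beta0, b0, tolerance = 1e-7)
  }
})

test_that("weighted LASSO agrees with glmnet on the printed cost", {
  skip_if_not_installed("glmnet")
  tp <- tiny_panel(n = 80, p = 160, seed = 14)
  panel <- tp$panel
  Xt <- apply_self_handling(panel$X, "nonlinear", s = 2)
  y <- panel$lifespan$pct_change; w <- panel$weights
  for (a in alpha_max(panel) * c(0.5, 0.1, 0.02)) {
    fit <- mrlasso(panel, alpha = a, tol = 1e-12)
    g <- glmnet::glmnet(Xt, y, weights = w, lambda = a / (2 * sum(w)),
                        standardize = FALSE, thresh = 1e-14)
    o_g <- weighted_cost(Xt, y, w, a, as.numeric(g$a0),
                         as.numeric(g$beta))
    expect_lt(abs(fit$objective_value - o_g) / o_g, 1e-6)
  }
})

test_that("self0 fitting equals excluding each mutant's own column entry", {
  tp <- tiny_panel(n = 50, p = 80, seed = 19)
  panel <- tp$panel
  fit1 <- mrlasso(panel, alpha = 20, self_handling = "self0")
  # alternative implementation: zero the self entries up front, fit with
  # no further handling
  X2 <- panel$X
  for (m in names(panel$deleted_gene_of))
    X2[m, panel$deleted_gene_of[[m]]] <- 0
  panel2 <- align_panel(X2, panel$lifespan,
                        deleted_gene_of = panel$deleted_gene_of)
  fit2 <- mrlasso(panel2, alpha = 20, self_handling = "none")
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-10)
  expect_equal(fit1$beta0, fit2$beta0, tolerance = 1e-10)
})

test_that("selected_genes is exactly the support, signed correctly", {
  tp <- tiny_panel(seed = 6)
  fit <- mrlasso(tp$panel, alpha = alpha_max(tp$panel) * 0.1)
  expect_identical(fit$selected_genes$gene,
                   names(fit$beta)[fit$beta != 0])
  expect_identical(fit$selected_genes$sign_class,
                   ifelse(fit$selected_genes$coef > 0, "positive",
                          "negative"))
  # objective no worse than the best constant model
  w <- fit$weights; y <- fit$y
  null_cost <- sum(w * (y - sum(w * y) / sum(w))^2)
  expect_lte(fit$objective_value, null_cost + 1e-8)
})

test_that("prediction is the linear rule on transformed features", {
  # hand instance: beta0 = 1, beta = {g1: 2}, x_g1 = 3 -> prediction 7
  fit <- structure(list(beta0 = 1,
                        beta = c(g1 = 2, g2 = 0),
                        selected_genes = data.frame(
                          gene = "g1", coef = 2, sign_class = "positive"),
                        self_handling = "none", s = 2),
                   class = "mrlasso")
  X <- matrix(c(3, 10), 1, 2, dimnames = list("m1", c("g1", "g2")))
  expect_equal(unname(predict(fit, X)), 7)
  expect_error(predict(fit, X[, 2, drop = FALSE]), "g1")

  # all-zero coefficients predict the intercept everywhere
  tp <- tiny_panel(n = 30, p = 50, seed = 9)
  nullfit <- mrlasso(tp$panel, alpha = alpha_max(tp$panel) * 2)
  expect_equal(unname(predict(nullfit, tp$panel)),
               rep(nullfit$beta0, 30))
})

test_that("a near-unpenalised fit on noise-free data recovers y", {
  cfg <- sim_config(n_mutants = 120, n_genes = 150, n_mr = 5,
                    noise_sd_base = 0, background_sd = 0.25,
                    n_tf_modules = 0, seed = 33)
  sim <- simulate_mutant_panel(cfg)
  panel <- align_panel(sim)
  fit <- mrlasso(panel, alpha = 1e-4, self_handling = "none")
  w <- panel$weights; y <- panel$lifespan$pct_change
  r2 <- 1 - sum(w * (y - fit$fitted)^2) /
    sum(w * (y - sum(w * y) / sum(w))^2)
  expect_gt(r2, 0.99)
})
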
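test_that("lasso path matches glmnet on shared penalties", {
  skip_if_not_installed("glmnet")
  for (s in 1:5) {
    set.seed(s)
    n <- 40; p <- 8
    X <- matrix(rnorm(n * p), n, p)
    y <- X %*% c(1.2, -0.8, rep(0, p - 2)) + rnorm(n, sd = 0.5)
    lam <- c(0.6, 0.3, 0.1, 0.05, 0.01)
    ref <- glmnet::glmnet(X, y, lambda = lam)
    ours <- cidrgn:::cpp_lasso_path(X, as.numeric(y), rep(1, n), lam,
                                    tol = 1e-9, maxit = 10000)
    expect_lt(max(abs(ours[-1, ] - as.matrix(ref$beta))), 1e-4)
    expect_lt(max(abs(ours[1, ] - ref$a0)), 1e-4)
  }
})

test_that("weighted lasso matches glmnet with observation weights", {
  skip_if_not_installed("glmnet")
  set.seed(2)
  n <- 50; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  y <- X %*% c(1, rep(0, p - 1)) + rnorm(n, sd = 0.3)
  w <- runif(n, 0.2, 2)
  lam <- c(0.4, 0.1, 0.02)
  ref <- glmnet::glmnet(X, y, weights = w, lambda = lam)
  ours <- cidrgn:::cpp_lasso_path(X, as.numeric(y), w, lam,
                                  tol = 1e-9, maxit = 10000)
  expect_lt(max(abs(ours[-1, ] - as.matrix(ref$beta))), 1e-4)
})

test_that("a strong linear dependence is recovered near its true coefficient", {
  set.seed(3)
  x <- matrix(rnorm(50 * 5), 50, 5, dimnames = list(NULL, paste0("g", 1:5)))
  x[, 2] <- 0.8 * x[, 1] + rnorm(50, sd = 0.1)
  net <- estimate_network(x)
  expect_true(net$coef["g2", "g1"] != 0)
  expect_lt(abs(net$coef["g2", "g1"] - 0.8), 0.2)
})

test_that("independent noise with a strong penalty yields an empty network", {
  set.seed(4)
  x <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("g", 1:6)))
  net <- estimate_network(x, lambda_rule = lasso_control(rule = "fixed",
                                                         lambda = 10))
  expect_true(all(net$coef == 0))
})

test_that("estimation is invariant to cell-line order and permutes with gene order", {
  set.seed(5)
  x <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("g", 1:5)))
  x[, 3] <- 0.6 * x[, 5] + rnorm(60, sd = 0.2)
  ctrl <- lasso_control(rule = "fixed", lambda = 0.1)
  n1 <- estimate_network(x, lambda_rule = ctrl)
  n2 <- estimate_network(x[sample(60), ], lambda_rule = ctrl)
  expect_equal(n1$coef, n2$coef)
  perm <- c(4, 2, 5, 1, 3)
  n3 <- estimate_network(x[, perm], lambda_rule = ctrl)
  expect_equal(n3$coef[colnames(x), colnames(x)], n1$coef)
})

test_that("constant gene columns get zero coefficients and a warning", {
  set.seed(6)
  x <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("g", 1:4)))
  x[, 2] <- 1
  expect_warning(net <- estimate_network(x), "constant")
  expect_true(all(net$coef["g2", ] == 0))
  expect_true(all(net$coef[, "g2"] == 0))
  expect_error(estimate_network(x[1, , drop = FALSE]), "2 cell lines")
})

test_that("band-structure support is recovered at high signal", {
  jacc <- c()
  for (s in 1:5) {
    set.seed(20 + s)
    st <- sim_structure("band", 10)
    x <- cidrgn:::rmvn_sigma(200, st$sigma)
    colnames(x) <- paste0("g", 1:10)
    net <- estimate_network(x)
    est <- cidrgn:::coef_adjacency(net$coef, 0)
    truth <- st$adjacency
    up <- upper.tri(truth)
    jacc <- c(jacc, sum(est[up] & truth[up]) / sum(est[up] | truth[up]))
  }
  expect_true(all(jacc >= 0.5))
})

test_that("neighbourhoods obey the threshold and match a brute-force scan", {
  co <- matrix(0, 3, 3, dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  co["g2", "g1"] <- 0.9
  nb <- network_neighborhoods(co, 0.7)
  expect_equal(nb$g1, "g2")
  expect_equal(nb$g2, "g1")
  expect_equal(nb$g3, character(0))
  co["g2", "g1"] <- 0.5
  nb2 <- network_neighborhoods(co, 0.7)
  expect_true(all(lengths(nb2) == 0))

  for (s in 1:10) {
    co <- tiny_coef(6, density = 0.3, seed = 50 + s)
    thr <- runif(1, 0, 0.8)
    nb <- network_neighborhoods(co, thr)
    ref <- oracle_neighbors(co, thr)
    for (g in names(ref)) expect_setequal(nb[[g]], ref[[g]])
  }
  expect_error(network_neighborhoods(co, -1), "non-negative")
})

test_that("degenerate modulators fall back to the bulk estimate with a warning", {
  set.seed(8)
  x <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, paste0("g", 1:4)))
  x[, 2] <- 0.7 * x[, 1] + rnorm(40, sd = 0.2)
  expect_warning(
    nets <- estimate_sample_networks(x, modulator = rep(0.3, 40),
                                     lambda_rule = lasso_control(rule = "fixed",
                                                                 lambda = 0.1)),
    "degenerate")
  for (a in 2:40) expect_equal(nets$coef[, , a], nets$coef[, , 1])
  bulk <- estimate_network(x, lambda_rule = lasso_control(rule = "fixed",
                                                          lambda = 0.1))
  expect_equal(nets$coef[, , 1], bulk$coef)
  expect_error(estimate_sample_networks(x, modulator = NULL), "modulator")
})

test_that("kernel weighting is invariant to shifting all modulators", {
  set.seed(9)
  x <- matrix(rnorm(50 * 3), 50, 3, dimnames = list(NULL, paste0("g", 1:3)))
  m <- runif(50, -1, 1)
  ctrl <- lasso_control(rule = "fixed", lambda = 0.05)
  set.seed(99)
  n1 <- estimate_sample_networks(x, m, lambda_rule = ctrl, bandwidth = 0.3)
  set.seed(99)
  n2 <- estimate_sample_networks(x, m + 5, lambda_rule = ctrl, bandwidth = 0.3)
  expect_equal(n1$coef, n2$coef)
})

test_that("a planted varying coefficient rises across modulator quartiles", {
  set.seed(10)
  n <- 120
  m <- runif(n, -1, 1)
  x1 <- rnorm(n)
  y <- (1 + m) * x1 + rnorm(n, sd = 0.4)   # edge strength grows with m
  x <- cbind(g1 = x1, g2 = y, g3 = rnorm(n))
  nets <- estimate_sample_networks(x, m)
  est <- nets$coef["g2", "g1", ]
  q <- cut(m, quantile(m, 0:4 / 4), include.lowest = TRUE)
  bins <- tapply(est, q, mean)
  expect_true(all(diff(bins) > 0))
  # networks at the modulator extremes differ more than adjacent ones
  ord <- order(m)
  d_far <- sum((nets$coef[, , ord[1]] - nets$coef[, , ord[n]])^2)
  d_near <- sum((nets$coef[, , ord[1]] - nets$coef[, , ord[2]])^2)
  expect_gt(d_far, d_near)
})
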
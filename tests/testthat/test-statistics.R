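test_that("SAM-GS matches hand arithmetic on a one-gene set", {
  x <- cbind(g1 = c(1, 2, 3, 3, 4, 5))
  ph <- factor(rep(c("A", "B"), each = 3))
  # a = 1/6, pooled SS = 4, s = sqrt(2/3), D = 4 / s
  expect_equal(samgs_stat(x, ph, "g1", s0 = 0), 4 / sqrt(2 / 3),
               tolerance = 1e-12)
  expect_equal(samgs_stat(x, ph, "g1", s0 = 0, scatter = "raw"), 4 / (2 / 3),
               tolerance = 1e-12)
})

test_that("SAM-GS is zero under equal means and shrinks as s0 grows", {
  d <- tiny_dataset(seed = 2)
  x <- d$x
  x[d$ph == "B", ] <- x[d$ph == "A", ]   # identical group means
  expect_equal(samgs_stat(x, d$ph, colnames(x), s0 = 0.5), 0)
  d2 <- tiny_dataset(seed = 3)
  a <- samgs_stat(d2$x, d2$ph, colnames(d2$x), s0 = 0.1)
  b <- samgs_stat(d2$x, d2$ph, colnames(d2$x), s0 = 0.2)
  expect_gt(a, b)
  expect_gt(b, 0)
  expect_error(samgs_stat(d2$x, d2$ph, character(0)), "empty")
  expect_error(samgs_stat(d2$x[c(1, 7), ], d2$ph[c(1, 7)], "g1"),
               "at least 2")
})

test_that("GSCA reproduces forced cases and the pairwise oracle", {
  # two genes, correlation +1 in A and -1 in B
  xA <- cbind(g1 = c(1, 2, 3), g2 = c(2, 4, 6))
  xB <- cbind(g1 = c(1, 2, 3), g2 = c(-1, -2, -3))
  x <- rbind(xA, xB)
  ph <- factor(rep(c("A", "B"), each = 3))
  expect_equal(gsca_stat(x, ph, c("g1", "g2")), 4)
  d <- tiny_dataset(n_per = 8, p = 4, seed = 4)
  expect_equal(gsca_stat(d$x, d$ph, colnames(d$x)),
               oracle_gsca(d$x, d$ph, colnames(d$x)), tolerance = 1e-12)
  # identical data in both phenotypes: zero
  x2 <- d$x; x2[d$ph == "B", ] <- x2[d$ph == "A", ]
  expect_equal(gsca_stat(x2, d$ph, colnames(x2)), 0)
})

test_that("regulatory effect vectors follow the coefficient-times-mean rule", {
  co <- matrix(0, 2, 2, dimnames = list(c("g1", "g2"), c("g1", "g2")))
  co["g2", "g1"] <- 2
  x <- rbind(c(0.5, 3), c(0.5, 5))
  colnames(x) <- c("g1", "g2")
  r <- regulatory_effects(co, x, "g1")
  expect_equal(r, c(g1 = 0, g2 = 1, g1 = 0, g2 = 0))  # r_21 = 2 * 0.5
  expect_equal(regulatory_effects(co * 0, x, "g2"), rep(0, 4),
               ignore_attr = TRUE)
  for (s in 1:5) {
    co <- tiny_coef(5, seed = s)
    xs <- matrix(rnorm(30), 6, 5, dimnames = list(NULL, colnames(co)))
    xbar <- colMeans(xs)
    for (g in colnames(co))
      expect_equal(unname(regulatory_effects(co, xs, g)),
                   oracle_effects(co, xbar, g), tolerance = 1e-12)
  }
})

test_that("gamma reduces squared distance by vector length and averages over genes", {
  expect_equal(gamma_gene(c(1, 0, 0, 0), c(0, 0, 0, 0)), 0.25)
  expect_equal(gamma_gene(1:5, 1:5), 0)
  expect_error(gamma_gene(1:3, 1:4), "length")
  set.seed(6)
  rA <- rnorm(20); rB <- rnorm(20)
  expect_equal(gamma_gene(rA, rB), sum((rA - rB)^2) / 20)
  expect_equal(gamma_subnetwork(c(0.2, 0.4)), 0.3)
  expect_equal(gamma_subnetwork(rep(0.7, 9)), 0.7)
  expect_error(gamma_subnetwork(numeric(0)), "empty")
})

test_that("vectorised per-gene gamma agrees with the entrywise oracle", {
  for (s in 1:8) {
    coA <- tiny_coef(5, seed = 2 * s)
    coB <- tiny_coef(5, seed = 2 * s + 1)
    xbarA <- rnorm(5); xbarB <- rnorm(5)
    g <- cidrgn:::gamma_genes(coA, coB, xbarA, xbarB)
    for (j in 1:5)
      expect_equal(unname(g[j]),
                   oracle_gamma(coA, coB, xbarA, xbarB, j), tolerance = 1e-12)
  }
})

test_that("jaccard dissimilarity handles shared, disjoint and empty neighbourhoods", {
  expect_equal(lambda_gene(c("g2", "g3"), c("g3", "g4")), 2 / 3)
  expect_equal(lambda_gene(c("g1", "g2"), c("g1", "g2")), 0)
  expect_equal(lambda_gene("g1", "g2"), 1)
  expect_equal(lambda_gene(character(0), character(0)), 0)
  expect_equal(lambda_subnetwork(c(0, 1)), 0.5)
  expect_equal(lambda_subnetwork(rep(1, 4)), 1)
})

test_that("gamma_lambda combines per-gene pieces as gamma * (1 + lambda)", {
  g <- c(0.5, 0.2); l <- c(0.5, 0)
  expect_equal(gamma_lambda_subnetwork(g, l), mean(c(0.75, 0.2)))
  expect_equal(gamma_lambda_subnetwork(g, c(0, 0)), gamma_subnetwork(g))
  expect_error(gamma_lambda_subnetwork(g, 1), "misaligned")
  set.seed(7)
  g <- runif(50); l <- runif(50)
  expect_equal(gamma_lambda_subnetwork(g, l), mean(g + g * l))
  expect_gte(gamma_lambda_subnetwork(g, l), gamma_subnetwork(g))
  expect_lte(gamma_lambda_subnetwork(g, l), 2 * gamma_subnetwork(g))
})

test_that("combined scores add their normalised components", {
  expect_equal(combine_statistics(gamma = 0, lambda = 0, samgs = 0), 0)
  expect_equal(combine_statistics(gamma = 1, lambda = 2, samgs = 3,
                                  variant = 2), 6)
  expect_equal(combine_statistics(gamma_lambda = 1.5, samgs = -0.5,
                                  variant = 1), 1)
  expect_error(combine_statistics(samgs = 1, variant = 3), "variant")
  expect_error(combine_statistics(samgs = 1, variant = 1), "gamma_lambda")
})

test_that("sample-specific effects take phenotype medians of per-cell effects", {
  genes <- paste0("g", 1:3)
  n <- 5
  coefs <- array(0, c(3, 3, n), dimnames = list(genes, genes, NULL))
  x <- matrix(1, n, 3, dimnames = list(NULL, genes))
  coefs[2, 1, ] <- c(1, 2, 100, 1, 2)   # effect of g1 on g2 per cell line
  nets <- structure(list(genes = genes, coef = coefs,
                         modulator = rep(0, n), bandwidth = 1),
                    class = "cidrgn_network_set")
  r <- ss_regulatory_effects(nets, x, "g1", cells = 1:5)
  expect_equal(unname(r[2]), 2)  # median robust to the outlier
  r13 <- ss_regulatory_effects(nets, x, "g1", cells = c(1, 2))
  expect_equal(unname(r13[2]), 1.5)
  expect_error(ss_regulatory_effects(nets, x, "g1", cells = integer(0)),
               "empty")
  # random instance vs sort-based median oracle
  set.seed(8)
  coefs[] <- rnorm(length(coefs))
  for (g in genes) coefs[match(g, genes), match(g, genes), ] <- 0
  xs <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, genes))
  nets$coef <- coefs
  r <- ss_regulatory_effects(nets, xs, "g2", cells = 1:5)
  j <- 2
  for (l in 1:3) {
    vals <- vapply(1:5, function(a) coefs[l, j, a] * xs[a, j], numeric(1))
    expect_equal(unname(r[l]), sort_median(vals), tolerance = 1e-12)
  }
  for (k in 1:3) {
    vals <- vapply(1:5, function(a) coefs[j, k, a] * xs[a, k], numeric(1))
    expect_equal(unname(r[3 + k]), sort_median(vals), tolerance = 1e-12)
  }
})

test_that("sample-specific jaccard pools neighbourhoods within phenotypes", {
  nb <- list(c("g1", "g2"), c("g3"), c("g3"), character(0))
  in_A <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(ss_lambda_gene(nb, in_A), 2 / 3)  # {1,2,3} vs {3}
  nb2 <- list("g1", "g1", "g1", "g1")
  expect_equal(ss_lambda_gene(nb2, in_A), 0)
  for (s in 1:6) {
    set.seed(30 + s)
    nb <- replicate(6, sample(paste0("g", 1:5), sample(0:3, 1)),
                    simplify = FALSE)
    in_A <- rep(c(TRUE, FALSE), each = 3)
    uA <- unique(unlist(nb[in_A])); uB <- unique(unlist(nb[!in_A]))
    expect_equal(ss_lambda_gene(nb, in_A), oracle_jaccard_dist(uA, uB))
  }
})

test_that("score_subnetworks composes the standalone statistics", {
  set.seed(40)
  x <- matrix(rnorm(60 * 12), 60, 12,
              dimnames = list(NULL, paste0("g", sprintf("%02d", 1:12))))
  ph <- factor(rep(c("A", "B"), each = 30))
  sets <- list(s1 = colnames(x)[1:5], s2 = colnames(x)[6:10])
  sc <- score_subnetworks(x, ph, sets, seed = 1)
  expect_equal(nrow(sc), 2)
  expect_true(all(c("samgs", "gsca", "gamma", "lambda", "gamma_lambda")
                  %in% names(sc)))
  s0 <- median(cidrgn:::samgs_pieces(x, 1:30, 31:60, "sqrt")$s)
  expect_equal(sc$samgs[1], samgs_stat(x, ph, sets$s1, s0 = s0),
               tolerance = 1e-12)
  expect_equal(sc$gsca[2], gsca_stat(x, ph, sets$s2), tolerance = 1e-12)
  expect_true(all(sc$gamma >= 0))
  expect_true(all(sc$lambda >= 0 & sc$lambda <= 1))
  expect_true(all(sc$gamma_lambda >= sc$gamma - 1e-12))
  expect_true(all(sc$gamma_lambda <= 2 * sc$gamma + 1e-12))
})

test_that("identical groups give identically zero dissimilarities", {
  set.seed(41)
  x <- matrix(rnorm(20 * 8), 20, 8, dimnames = list(NULL, paste0("g", 1:8)))
  x2 <- rbind(x, x)
  ph <- factor(rep(c("A", "B"), each = 20))
  sc <- score_subnetworks(x2, ph, list(s1 = colnames(x2)[1:4]), seed = 2)
  expect_equal(sc$samgs, 0)
  expect_equal(sc$gsca, 0)
  expect_equal(sc$gamma, 0)
  expect_equal(sc$lambda, 0)
  expect_equal(sc$gamma_lambda, 0)
})
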
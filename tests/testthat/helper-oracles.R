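# Brute-force oracles: plain-loop recomputations of every statistic, kept
# deliberately independent of the package's vectorised implementations.

sort_median <- function(v) {
  s <- sort(v); n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

oracle_samgs <- function(x, ph, set, s0, scatter = "sqrt") {
  lev <- levels(factor(ph))
  A <- x[ph == lev[1], , drop = FALSE]
  B <- x[ph == lev[2], , drop = FALSE]
  nA <- nrow(A); nB <- nrow(B)
  a <- (1 / nA + 1 / nB) / (nA + nB - 2)
  D <- 0
  for (g in set) {
    mA <- mean(A[, g]); mB <- mean(B[, g])
    ss <- a * (sum((A[, g] - mA)^2) + sum((B[, g] - mB)^2))
    s <- if (scatter == "sqrt") sqrt(ss) else ss
    D <- D + (mA - mB)^2 / (s + s0)
  }
  D
}

oracle_gsca <- function(x, ph, set) {
  lev <- levels(factor(ph))
  A <- x[ph == lev[1], set, drop = FALSE]
  B <- x[ph == lev[2], set, drop = FALSE]
  k <- length(set)
  tot <- 0
  for (b in 2:k) for (a in seq_len(b - 1))
    tot <- tot + (cor(A[, a], A[, b]) - cor(B[, a], B[, b]))^2
  tot / (k * (k - 1) / 2)
}

# Regulatory-effect vector of gene j built entry by entry from Eq-style
# definitions: first every target's coefficient times the mean of regulator
# j, then every regulator's coefficient on j times that regulator's mean.
oracle_effects <- function(coef, xbar, j) {
  genes <- colnames(coef)
  k <- length(genes)
  out <- numeric(2 * k)
  for (l in seq_len(k)) out[l] <- coef[l, j] * xbar[j]
  for (r in seq_len(k)) out[k + r] <- coef[j, r] * xbar[r]
  out
}

oracle_gamma <- function(coefA, coefB, xbarA, xbarB, j) {
  rA <- oracle_effects(coefA, xbarA, j)
  rB <- oracle_effects(coefB, xbarB, j)
  tot <- 0
  for (i in seq_along(rA)) tot <- tot + (rA[i] - rB[i])^2
  tot / length(rA)
}

oracle_neighbors <- function(coef, thr) {
  genes <- colnames(coef)
  out <- list()
  for (j in genes) {
    nb <- character()
    for (k in genes) {
      if (k == j) next
      if (abs(coef[j, k]) > thr || abs(coef[k, j]) > thr) nb <- c(nb, k)
    }
    out[[j]] <- nb
  }
  out
}

oracle_jaccard_dist <- function(na, nb) {
  u <- unique(c(na, nb))
  if (length(u) == 0) return(0)
  inter <- sum(u %in% na & u %in% nb)
  1 - inter / length(u)
}

oracle_zscore <- function(v) {
  m <- sum(v) / length(v)
  s <- sqrt(sum((v - m)^2) / length(v))
  if (s <= 1e-12) rep(0, length(v)) else (v - m) / s
}

oracle_pvalue <- function(obs, perm) {
  cnt <- 0
  for (p in perm) if (p >= obs) cnt <- cnt + 1
  cnt / length(perm)
}

# Small random two-phenotype dataset with named genes.
tiny_dataset <- function(n_per = 6, p = 5, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per * p), 2 * n_per, p,
              dimnames = list(NULL, paste0("g", seq_len(p))))
  list(x = x, ph = factor(rep(c("A", "B"), each = n_per)))
}

# Random sparse coefficient matrix with zero diagonal.
tiny_coef <- function(k = 5, density = 0.4, seed = 1) {
  set.seed(seed)
  co <- matrix(rnorm(k * k) * (runif(k * k) < density), k, k,
               dimnames = list(paste0("g", 1:k), paste0("g", 1:k)))
  diag(co) <- 0
  co
}
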
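# Gene regulatory network estimation by per-target sparse regression.

#' Control parameters for the lasso penalty
#'
#' @param rule `"1se"` (default): 5-fold cross-validation with the
#'   one-standard-error rule per target gene; `"min"`: CV-minimum;
#'   `"fixed"`: use `lambda` directly without cross-validation.
#' @param nfolds number of CV folds.
#' @param nlambda length of the penalty path.
#' @param lambda_min_ratio smallest path value as a fraction of the
#'   data-derived maximum.
#' @param lambda fixed penalty (required when `rule = "fixed"`), on the
#'   glmnet scale: the objective is `1/2 * mean((y - Xb)^2) + lambda * |b|_1`
#'   with standardized predictors.
#' @param tol coordinate-descent convergence tolerance on the standardized
#'   coefficient scale.
#' @param maxit maximum coordinate-descent sweeps per penalty value.
#' @return A list of class `lasso_control`.
#' @export
lasso_control <- function(rule = c("1se", "min", "fixed"), nfolds = 5,
                          nlambda = 20, lambda_min_ratio = 0.01,
                          lambda = NULL, tol = 1e-5, maxit = 100) {
  rule <- match.arg(rule)
  if (rule == "fixed" && (is.null(lambda) || lambda < 0))
    stop("rule = 'fixed' needs a non-negative 'lambda'")
  structure(list(rule = rule, nfolds = nfolds, nlambda = nlambda,
                 lambda_min_ratio = lambda_min_ratio, lambda = lambda,
                 tol = tol, maxit = maxit),
            class = "lasso_control")
}

rule_code <- function(ctrl) match(ctrl$rule, c("1se", "min", "fixed")) - 1L

# One foldid draw shared by all targets of a network fit.
draw_foldid <- function(n, nfolds) sample(rep_len(seq_len(nfolds), n))

fit_network_matrix <- function(xs, ctrl, weights = NULL, foldid = NULL) {
  n <- nrow(xs)
  if (is.null(weights)) weights <- rep(1, n)
  if (is.null(foldid)) foldid <- draw_foldid(n, ctrl$nfolds)
  if (ncol(xs) < 2)
    return(matrix(0, ncol(xs), ncol(xs),
                  dimnames = list(colnames(xs), colnames(xs))))
  coef <- cpp_fit_network(xs, weights, as.integer(foldid), ctrl$nfolds,
                          ctrl$nlambda, ctrl$lambda_min_ratio,
                          rule_code(ctrl),
                          if (is.null(ctrl$lambda)) 0 else ctrl$lambda,
                          ctrl$tol, as.integer(ctrl$maxit))
  dimnames(coef) <- list(colnames(xs), colnames(xs))
  coef
}

#' Estimate a gene regulatory network by per-target lasso regression
#'
#' For each target gene, fits an L1-penalised linear regression of the
#' target's expression on all other genes in `genes`. Columns are
#' standardised internally for penalty fairness; coefficients are reported on
#' the original expression scale. The result is a directed weighted network:
#' `coef[target, regulator]` is the estimated effect of the regulator on the
#' target.
#'
#' @param x numeric cell-line x gene matrix with gene column names.
#' @param genes gene identifiers to include (default: all columns).
#' @param lambda_rule a [lasso_control()] object.
#' @param weights optional observation weights.
#' @param phenotype_tag optional label stored on the network.
#' @return A list of class `cidrgn_network` with elements `genes`, `coef`
#'   (square matrix, zero diagonal) and `phenotype_tag`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("g", 1:4)))
#' x[, 2] <- 0.8 * x[, 1] + rnorm(50, sd = 0.1)
#' net <- estimate_network(x)
#' net$coef["g2", "g1"]
#' @export
estimate_network <- function(x, genes = colnames(x),
                             lambda_rule = lasso_control(),
                             weights = NULL, phenotype_tag = NULL) {
  if (nrow(x) < 2) stop("need at least 2 cell lines")
  if (is.null(colnames(x))) stop("'x' must have gene column names")
  miss <- setdiff(genes, colnames(x))
  if (length(miss)) stop("genes not in 'x': ", paste(miss, collapse = ", "))
  xs <- x[, genes, drop = FALSE]
  cst <- apply(xs, 2L, function(v) max(v) - min(v) == 0)
  if (any(cst))
    warning("constant gene column(s): ", paste(genes[cst], collapse = ", "),
            "; their coefficients are set to zero")
  coef <- fit_network_matrix(xs, lambda_rule, weights)
  structure(list(genes = genes, coef = coef, phenotype_tag = phenotype_tag),
            class = "cidrgn_network")
}

#' @export
print.cidrgn_network <- function(x, ...) {
  cat("Gene regulatory network:", length(x$genes), "genes,",
      sum(x$coef != 0), "directed edges",
      if (!is.null(x$phenotype_tag)) paste0("(", x$phenotype_tag, ")"), "\n")
  invisible(x)
}

#' Silverman's rule-of-thumb bandwidth
#'
#' @param m numeric vector (modulator values).
#' @return `0.9 * min(sd, IQR/1.34) * n^(-1/5)`, possibly zero when `m` is
#'   degenerate.
#' @export
silverman_bandwidth <- function(m) {
  n <- length(m)
  spread <- min(sd(m), diff(quantile(m, c(0.25, 0.75), names = FALSE)) / 1.34)
  if (!is.finite(spread)) spread <- 0
  0.9 * spread * n^(-1 / 5)
}

#' Estimate sample-specific networks by kernel-weighted lasso
#'
#' Fits one network per cell line under a varying-coefficient model: for the
#' network of cell line `a`, every cell line `i` receives Gaussian kernel
#' weight `K((m_i - m_a) / h)` based on its modulator value, and the
#' per-target lasso of [estimate_network()] is run with those weights. All
#' cell lines of the dataset contribute to every network; the modulator alone
#' localises the fit.
#'
#' When all modulators are equal (or `bandwidth` is zero) the kernel is
#' degenerate; the estimator falls back to uniform weights with a warning, so
#' every per-cell-line network equals the bulk estimate.
#'
#' @param x numeric cell-line x gene matrix.
#' @param modulator numeric per-cell-line modulator, no missing values.
#' @param genes gene identifiers to include.
#' @param bandwidth kernel bandwidth `h`; default [silverman_bandwidth()] of
#'   the modulator values.
#' @param lambda_rule a [lasso_control()] object.
#' @return A list of class `cidrgn_network_set` with elements `genes`,
#'   `coef` (array `genes x genes x cell lines`), `modulator`, `bandwidth`.
#' @export
estimate_sample_networks <- function(x, modulator, genes = colnames(x),
                                     bandwidth = NULL,
                                     lambda_rule = lasso_control()) {
  n <- nrow(x)
  if (is.null(modulator) || length(modulator) != n || anyNA(modulator))
    stop("'modulator' must be a complete numeric vector, one value per cell line")
  if (is.null(bandwidth)) bandwidth <- silverman_bandwidth(modulator)
  xs <- x[, genes, drop = FALSE]
  k <- length(genes)
  foldid <- draw_foldid(n, lambda_rule$nfolds)
  coefs <- array(0, c(k, k, n), dimnames = list(genes, genes, rownames(x)))
  if (bandwidth <= 0) {
    warning("degenerate bandwidth; falling back to unweighted estimation")
    bulk <- fit_network_matrix(xs, lambda_rule, foldid = foldid)
    for (a in seq_len(n)) coefs[, , a] <- bulk
  } else {
    for (a in seq_len(n)) {
      w <- dnorm((modulator - modulator[a]) / bandwidth)
      coefs[, , a] <- fit_network_matrix(xs, lambda_rule, weights = w,
                                         foldid = foldid)
    }
  }
  structure(list(genes = genes, coef = coefs, modulator = modulator,
                 bandwidth = bandwidth),
            class = "cidrgn_network_set")
}

#' @export
print.cidrgn_network_set <- function(x, ...) {
  cat("Sample-specific networks:", dim(x$coef)[3L], "cell lines,",
      length(x$genes), "genes (bandwidth",
      formatC(x$bandwidth, digits = 3, format = "g"), ")\n")
  invisible(x)
}

# Symmetric thresholded adjacency of a coefficient matrix.
coef_adjacency <- function(coef, edge_threshold = 0) {
  a <- abs(coef) > edge_threshold
  a <- a | t(a)
  diag(a) <- FALSE
  a
}

#' Node neighbourhoods of an estimated network
#'
#' Gene `k` is a neighbour of gene `j` when either directed coefficient
#' between them exceeds `edge_threshold` in absolute value. The default
#' threshold 0 treats any nonzero lasso coefficient as an edge (the
#' simulation convention); real-data analyses typically raise it.
#'
#' @param network a `cidrgn_network`, or a bare coefficient matrix.
#' @param edge_threshold non-negative edge-weight threshold.
#' @return A named list of neighbour gene-id vectors, with the symmetric
#'   logical adjacency matrix in attribute `"adjacency"`.
#' @export
network_neighborhoods <- function(network, edge_threshold = 0) {
  coef <- if (inherits(network, "cidrgn_network")) network$coef else network
  if (edge_threshold < 0) stop("'edge_threshold' must be non-negative")
  adj <- coef_adjacency(coef, edge_threshold)
  sets <- apply(adj, 1L, function(r) colnames(adj)[r], simplify = FALSE)
  structure(sets, adjacency = adj)
}
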
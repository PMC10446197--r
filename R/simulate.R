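# Gaussian graphical model simulator: structured precision matrices and the
# phenotype-paired benchmark scenarios.

#' Generate a structured precision matrix
#'
#' Builds a binary graph of the requested structure over `size` genes and the
#' corresponding precision matrix: off-diagonal entries are 0.5 on edges and
#' the diagonal is set to `abs(min(eigen(0.5 A)))` plus `margin`, so the
#' matrix is positive definite with smallest eigenvalue exactly `margin`
#' whenever the graph is non-trivial.
#'
#' Structures:
#' * `random`: each pair is an edge independently with probability `p_edge`
#'   (default 0.3 for `size <= 10`, 0.1 otherwise, keeping expected degree
#'   comparable across sizes);
#' * `band`: width-1 band, edges between consecutive genes;
#' * `cluster`: two equal groups, random within-group edges with
#'   probability 0.6;
#' * `scale_free`: preferential-attachment tree, one edge per new node;
#' * `hub`: `ceiling(size/10)` groups, the first gene of each group connected
#'   to all others in the group.
#'
#' @param structure one of `"random"`, `"band"`, `"cluster"`, `"scale_free"`,
#'   `"hub"`.
#' @param size number of genes (at least 2).
#' @param p_edge edge probability for the `random` structure; ignored
#'   otherwise.
#' @param margin positive-definiteness margin added to the diagonal.
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @return A list of class `cidrgn_structure` with elements `adjacency`
#'   (logical symmetric matrix), `omega` (precision matrix), `sigma` (the
#'   sampling covariance: `omega^{-1}` rescaled to unit marginal variances,
#'   matching the huge-style generator convention) and `structure`.
#' @examples
#' s <- sim_structure("hub", 10, seed = 1)
#' rowSums(s$adjacency)       # gene 1 has degree 9
#' min(eigen(s$omega)$values) # 0.2
#' @export
sim_structure <- function(structure = c("random", "band", "cluster",
                                        "scale_free", "hub"),
                          size, p_edge = NULL, margin = 0.2, seed = NULL) {
  structure <- match.arg(structure)
  if (!is.numeric(size) || length(size) != 1L || size < 2)
    stop("'size' must be a single integer >= 2")
  size <- as.integer(size)
  with_seed(seed, {
    A <- matrix(FALSE, size, size)
    if (structure == "random") {
      if (is.null(p_edge)) p_edge <- if (size <= 10) 0.3 else 0.1
      up <- upper.tri(A)
      A[up] <- runif(sum(up)) < p_edge
    } else if (structure == "band") {
      A[cbind(seq_len(size - 1L), seq_len(size - 1L) + 1L)] <- TRUE
    } else if (structure == "cluster") {
      grp <- rep(1:2, c(ceiling(size / 2), floor(size / 2)))
      for (g in 1:2) {
        id <- which(grp == g)
        for (a in seq_along(id)) for (b in seq_len(a - 1L))
          if (runif(1) < 0.6) A[id[b], id[a]] <- TRUE
      }
    } else if (structure == "scale_free") {
      deg <- integer(size)
      A[1, 2] <- TRUE
      deg[1:2] <- 1L
      for (v in seq_len(size)[-(1:2)]) {
        tgt <- sample.int(v - 1L, 1L, prob = deg[seq_len(v - 1L)])
        A[tgt, v] <- TRUE
        deg[c(tgt, v)] <- deg[c(tgt, v)] + 1L
      }
    } else { # hub
      ngrp <- ceiling(size / 10)
      grp <- sort(rep_len(seq_len(ngrp), size))
      for (g in seq_len(ngrp)) {
        id <- which(grp == g)
        if (length(id) > 1L) A[id[1L], id[-1L]] <- TRUE
      }
    }
    A <- A | t(A)
    diag(A) <- FALSE
    omega <- 0.5 * A
    diag(omega) <- abs(min(eigen(omega, symmetric = TRUE,
                                 only.values = TRUE)$values)) + margin
    # sampling covariance: standardised to unit marginal variances, the
    # convention of the huge-style generators this design follows
    sigma <- stats::cov2cor(solve(omega))
    structure(list(adjacency = A, omega = omega, sigma = sigma,
                   structure = structure),
              class = "cidrgn_structure")
  })
}

# n draws from N(mean, sigma) via the Cholesky factor of sigma.
rmvn_sigma <- function(n, sigma, mean = 0) {
  R <- chol(sigma)
  z <- matrix(rnorm(n * ncol(sigma)), n, ncol(sigma))
  sweep(z %*% R, 2L, rep_len(mean, ncol(sigma)), "+")
}

#' Simulate a benchmark scenario
#'
#' Generates a two-phenotype expression dataset containing ten embedded
#' subnetworks: four common to both phenotypes and six phenotype-specific
#' pairs (the positive class). Common-subnetwork genes are drawn for all
#' cell lines from one zero-mean Gaussian graphical model; for each specific
#' subnetwork, phenotype-A cell lines are drawn from a phenotype-A precision
#' matrix with mean zero and phenotype-B cell lines from a band-structure
#' precision matrix with mean `mu` on every gene. All remaining genes are
#' i.i.d. standard normal background.
#'
#' The scenario index selects the structure of the common and A-specific
#' precision matrices: 1 = random, 2 = cluster, 3 = scale-free, 4 = hub.
#' B-specific matrices always have the band structure.
#'
#' With `sample_specific = TRUE`, each cell line receives a modulator
#' `m ~ U(-1, 1)` mapped to `delta = (m + 1) / 2`, and its
#' specific-subnetwork genes are drawn from a Gaussian whose covariance is
#' the interpolated matrix `omega * (0.5 + 0.5 * delta)` — regulatory
#' strength scales between half strength (`m = -1`) and full strength
#' (`m = 1`), and gene variances stay at or below the bulk design's scale.
#'
#' @param scenario integer 1-4.
#' @param size genes per subnetwork (10 or 50 in the benchmark designs).
#' @param p total number of genes (default 1000).
#' @param n_A,n_B cell lines per phenotype.
#' @param mu mean shift applied to B-specific subnetwork genes.
#' @param n_common,n_specific number of common and of specific subnetwork
#'   pairs.
#' @param sample_specific generate the modulator-interpolated design.
#' @param seed optional integer seed.
#' @return A list of class `cidrgn_sim` with elements `x` (cell line x gene
#'   matrix), `phenotype` (factor with levels A, B), `modulator` (numeric or
#'   `NULL`), `truth` (list with `sets`, a named list of gene-id vectors, and
#'   `labels`, `"common"` or `"responsive"`), and the generating structures
#'   ([sim_structure()] objects, precision plus sampling covariance) in
#'   `omegas`. Expression is sampled at unit marginal variance (the
#'   covariance is standardised to a correlation matrix), so `mu` is on the
#'   per-gene standard-deviation scale.
#' @examples
#' sim <- sim_scenario(1, size = 10, p = 200, seed = 1)
#' dim(sim$x)
#' table(sim$truth$labels)
#' @export
sim_scenario <- function(scenario = 1, size = 10, p = 1000,
                         n_A = 50, n_B = 50, mu = 0.3,
                         n_common = 4, n_specific = 6,
                         sample_specific = FALSE, seed = NULL) {
  if (!scenario %in% 1:4) stop("'scenario' must be 1, 2, 3 or 4")
  n_sub <- n_common + n_specific
  if (n_sub * size > p)
    stop("subnetworks need ", n_sub * size, " genes but p = ", p)
  if (mu < 0) stop("'mu' must be non-negative")
  tag <- c("random", "cluster", "scale_free", "hub")[scenario]
  n <- n_A + n_B
  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(p))
    cells <- sprintf("cl%03d", seq_len(n))
    phenotype <- factor(rep(c("A", "B"), c(n_A, n_B)), levels = c("A", "B"))
    modulator <- if (sample_specific) runif(n, -1, 1) else NULL
    x <- matrix(rnorm(n * p), n, p, dimnames = list(cells, genes))

    sets <- split(genes[seq_len(n_sub * size)],
                  rep(seq_len(n_sub), each = size))
    names(sets) <- sprintf("sn%02d", seq_len(n_sub))
    labels <- rep(c("common", "responsive"), c(n_common, n_specific))

    om_common <- vector("list", n_common)
    om_specific <- vector("list", n_specific)
    iA <- which(phenotype == "A")
    iB <- which(phenotype == "B")
    for (s in seq_len(n_common)) {
      st <- sim_structure(tag, size)
      om_common[[s]] <- st
      x[, match(sets[[s]], genes)] <- rmvn_sigma(n, st$sigma)
    }
    for (s in seq_len(n_specific)) {
      stA <- sim_structure(tag, size)
      stB <- sim_structure("band", size)
      om_specific[[s]] <- list(A = stA, B = stB)
      cols <- match(sets[[n_common + s]], genes)
      if (sample_specific) {
        # per-cell-line interpolation toward half strength: the Gaussian
        # parameter matrix is scaled by 0.5 + 0.5 * delta and used as the
        # covariance, so regulatory strength and variance shrink together
        # for cell lines with low modulator values
        delta <- (modulator + 1) / 2
        scl <- 0.5 + 0.5 * delta
        RA <- chol(stA$sigma); RB <- chol(stB$sigma)
        for (a in iA)
          x[a, cols] <- crossprod(RA, rnorm(size)) * sqrt(scl[a])
        for (b in iB)
          x[b, cols] <- crossprod(RB, rnorm(size)) * sqrt(scl[b]) + mu
      } else {
        x[iA, cols] <- rmvn_sigma(n_A, stA$sigma)
        x[iB, cols] <- rmvn_sigma(n_B, stB$sigma, mean = mu)
      }
    }
    structure(list(x = x, phenotype = phenotype, modulator = modulator,
                   truth = list(sets = sets, labels = labels),
                   scenario = scenario, size = size, mu = mu,
                   omegas = list(common = om_common, specific = om_specific)),
              class = c("cidrgn_sim", "cidrgn_data"))
  })
}

#' Interpolated per-cell-line precision matrix
#'
#' The sample-specific design scales a phenotype's precision matrix by
#' `0.5 + 0.5 * delta` with `delta = (m + 1) / 2`, a convex interpolation
#' between half strength at modulator `m = -1` and full strength at `m = 1`.
#'
#' @param omega precision matrix.
#' @param m modulator value in `[-1, 1]`.
#' @return The interpolated precision matrix.
#' @export
interpolate_precision <- function(omega, m) {
  delta <- (m + 1) / 2
  out <- 0.5 * omega + (omega - 0.5 * omega) * delta
  ev <- min(eigen(out, symmetric = TRUE, only.values = TRUE)$values)
  stopifnot(ev > 0)
  out
}

#' @export
print.cidrgn_sim <- function(x, ...) {
  cat("Simulated expression dataset: scenario", x$scenario,
      if (!is.null(x$modulator)) "(sample-specific)", "\n")
  cat(sprintf("  %d cell lines x %d genes; %d subnetworks of %d genes (%d common, %d responsive)\n",
              nrow(x$x), ncol(x$x), length(x$truth$sets), x$size,
              sum(x$truth$labels == "common"),
              sum(x$truth$labels == "responsive")))
  invisible(x)
}
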
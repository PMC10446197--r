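# Subnetwork dissimilarity statistics: SAM-GS, GSCA, regulatory-effect
# dissimilarity (gamma), Jaccard edge dissimilarity (lambda), and their
# combinations.

# Per-gene means and scatters for both phenotype groups over a gene matrix.
# scatter = "sqrt" takes the square root of the pooled scaled sum of squared
# deviations (the SAM lineage); "raw" is the literal unsquare-rooted form.
samgs_pieces <- function(x, iA, iB, scatter = "sqrt") {
  nA <- length(iA); nB <- length(iB)
  if (nA < 2 || nB < 2) stop("each phenotype needs at least 2 cell lines")
  a <- (1 / nA + 1 / nB) / (nA + nB - 2)
  mA <- colMeans(x[iA, , drop = FALSE])
  mB <- colMeans(x[iB, , drop = FALSE])
  devA <- colSums(x[iA, , drop = FALSE]^2) - nA * mA^2
  devB <- colSums(x[iB, , drop = FALSE]^2) - nB * mB^2
  s <- a * (devA + devB)
  if (scatter == "sqrt") s <- sqrt(pmax(s, 0))
  list(num = (mA - mB)^2, s = s)
}

#' SAM-GS gene-set statistic
#'
#' Sums, over the genes of a set, the squared difference of phenotype mean
#' expression standardised by the gene-specific scatter plus a stabiliser:
#' `D = sum_j (mean_Aj - mean_Bj)^2 / (s_j + s0)` with
#' `s_j = sqrt(a * (SS_Aj + SS_Bj))`, `a = (1/n_A + 1/n_B)/(n_A + n_B - 2)`.
#' The printed form of the scatter omits the square root; `scatter = "raw"`
#' gives that literal reading, while the default follows the SAM family,
#' which is dimensionally consistent with dividing a squared difference.
#'
#' @param x cell-line x gene expression matrix.
#' @param phenotype two-level factor over the rows of `x`.
#' @param gene_set character vector of member gene ids.
#' @param s0 stabiliser; default the median scatter over `universe`.
#' @param universe genes over which the default `s0` is computed (default all
#'   columns of `x`).
#' @param scatter `"sqrt"` (default) or `"raw"`.
#' @return The non-negative statistic.
#' @examples
#' x <- cbind(g1 = c(1, 2, 3, 3, 4, 5))
#' ph <- factor(rep(c("A", "B"), each = 3))
#' samgs_stat(x, ph, "g1", s0 = 0)   # 4 / sqrt(4/6) = 4.899
#' @export
samgs_stat <- function(x, phenotype, gene_set, s0 = NULL,
                       universe = colnames(x),
                       scatter = c("sqrt", "raw")) {
  scatter <- match.arg(scatter)
  if (!length(gene_set)) stop("'gene_set' is empty")
  phenotype <- as.factor(phenotype)
  lev <- levels(droplevels(phenotype))
  if (length(lev) != 2) stop("'phenotype' must have exactly two levels")
  pieces <- samgs_pieces(x[, universe, drop = FALSE],
                         which(phenotype == lev[1L]),
                         which(phenotype == lev[2L]), scatter)
  if (is.null(s0)) s0 <- median(pieces$s)
  j <- match(gene_set, universe)
  if (anyNA(j)) stop("gene_set members missing from 'universe'")
  sum(pieces$num[j] / (pieces$s[j] + s0))
}

# Correlation matrix with constant columns contributing zero correlation.
cor0 <- function(x, warn = TRUE) {
  cc <- suppressWarnings(cor(x))
  if (anyNA(cc)) {
    if (warn) warning("constant gene(s) within a phenotype; correlations set to 0")
    cc[!is.finite(cc)] <- 0
  }
  diag(cc) <- 1
  cc
}

#' GSCA gene-set co-expression statistic
#'
#' Mean, over all unordered gene pairs of a set, of the squared difference
#' between the phenotype-A and phenotype-B Pearson correlations.
#'
#' @inheritParams samgs_stat
#' @return The non-negative statistic.
#' @export
gsca_stat <- function(x, phenotype, gene_set) {
  if (length(gene_set) < 2) stop("'gene_set' needs at least 2 genes")
  phenotype <- as.factor(phenotype)
  lev <- levels(droplevels(phenotype))
  if (length(lev) != 2) stop("'phenotype' must have exactly two levels")
  xs <- x[, gene_set, drop = FALSE]
  cA <- cor0(xs[phenotype == lev[1L], , drop = FALSE])
  cB <- cor0(xs[phenotype == lev[2L], , drop = FALSE])
  d <- (cA - cB)[lower.tri(cA)]
  mean(d^2)
}

#' Regulatory-effect vector of a gene
#'
#' The regulatory effect of regulator `j` on target `l` is the estimated
#' coefficient scaled by the phenotype mean expression of the regulator:
#' `r_lj = coef[l, j] * xbar_j`. The effect vector of gene `j` stacks its
#' effects as a regulator of every target (first block) and the effects of
#' every regulator acting on `j` (second block), a fixed ordering shared
#' between phenotypes.
#'
#' @param network a `cidrgn_network` (or coefficient matrix).
#' @param x expression matrix of the phenotype's cell lines (used for the
#'   regulator means), covering the network's genes.
#' @param gene gene identifier.
#' @return Numeric vector of length `2 * n_genes`.
#' @export
regulatory_effects <- function(network, x, gene) {
  coef <- if (inherits(network, "cidrgn_network")) network$coef else network
  genes <- colnames(coef)
  if (!gene %in% genes) stop("'gene' is not in the network")
  xbar <- colMeans(x[, genes, drop = FALSE])
  j <- match(gene, genes)
  c(coef[, j] * xbar[j], coef[j, ] * xbar)
}

# Per-gene gamma over a whole subnetwork, vectorised: with
# E = coef * xbar[regulator] (columns scaled by regulator means),
# gamma_j = (colSums + rowSums of the squared difference matrix) / (2k).
gamma_genes <- function(coefA, coefB, xbarA, xbarB) {
  k <- ncol(coefA)
  D2 <- (sweep(coefA, 2L, xbarA, "*") - sweep(coefB, 2L, xbarB, "*"))^2
  (colSums(D2) + rowSums(D2)) / (2 * k)
}

#' Regulatory-effect dissimilarity of one gene
#'
#' Squared Euclidean distance between the phenotype-A and phenotype-B
#' regulatory effect vectors, divided by their length.
#'
#' @param rA,rB effect vectors of equal length with aligned ordering.
#' @return Non-negative scalar.
#' @export
gamma_gene <- function(rA, rB) {
  if (length(rA) != length(rB)) stop("effect vectors differ in length")
  sum((rA - rB)^2) / length(rA)
}

#' Jaccard edge dissimilarity of one gene
#'
#' One minus the Jaccard index of the gene's neighbourhoods in the two
#' phenotypes. Two empty neighbourhoods count as identical (dissimilarity
#' zero): a gene disconnected in both networks carries no evidence of
#' rewiring.
#'
#' @param nA,nB character vectors of neighbour gene ids.
#' @return Value in `[0, 1]`.
#' @export
lambda_gene <- function(nA, nB) {
  u <- length(union(nA, nB))
  if (u == 0) return(0)
  1 - length(intersect(nA, nB)) / u
}

lambda_genes <- function(adjA, adjB) {
  inter <- rowSums(adjA & adjB)
  uni <- rowSums(adjA | adjB)
  ifelse(uni == 0, 0, 1 - inter / uni)
}

#' Subnetwork means of per-gene dissimilarities
#'
#' `gamma_subnetwork()` and `lambda_subnetwork()` average the per-gene
#' values; `gamma_lambda_subnetwork()` averages the Jaccard-adjusted effects
#' `gamma_j * (1 + lambda_j)`, so it equals the plain gamma mean when no gene
#' is rewired and at most doubles it.
#'
#' @param gamma,lambda aligned per-gene value vectors over the subnetwork.
#' @return Scalar mean.
#' @export
gamma_subnetwork <- function(gamma) {
  if (!length(gamma)) stop("empty subnetwork")
  mean(gamma)
}

#' @rdname gamma_subnetwork
#' @export
lambda_subnetwork <- function(lambda) {
  if (!length(lambda)) stop("empty subnetwork")
  mean(lambda)
}

#' @rdname gamma_subnetwork
#' @export
gamma_lambda_subnetwork <- function(gamma, lambda) {
  if (length(gamma) != length(lambda)) stop("misaligned per-gene inputs")
  if (!length(gamma)) stop("empty subnetwork")
  mean(gamma * (1 + lambda))
}

#' Combine normalised statistics into a CIdrgn score
#'
#' Variant 1 adds the normalised Jaccard-adjusted effect dissimilarity and
#' the normalised SAM-GS statistic; variant 2 adds the normalised effect,
#' edge and expression dissimilarities separately.
#'
#' @param gamma,lambda,samgs,gamma_lambda statistics already normalised
#'   across the permutation ensemble.
#' @param variant 1 or 2.
#' @return Combined score (may be negative on the normalised scale).
#' @export
combine_statistics <- function(gamma = NULL, lambda = NULL, samgs,
                               gamma_lambda = NULL, variant = 2) {
  if (variant == 1) {
    if (is.null(gamma_lambda)) stop("variant 1 needs 'gamma_lambda'")
    gamma_lambda + samgs
  } else if (variant == 2) {
    if (is.null(gamma) || is.null(lambda)) stop("variant 2 needs 'gamma' and 'lambda'")
    gamma + lambda + samgs
  } else stop("unknown variant: ", variant)
}

#' Sample-specific regulatory effect vector of a gene
#'
#' In the sample-specific mode each cell line `a` carries its own network;
#' the effect of regulator `j` on target `l` in that cell line is
#' `coef_a[l, j] * x_aj`, the coefficient scaled by the cell line's own
#' expression of the regulator. The phenotype-level effect vector takes the
#' median of each entry over the phenotype's cell lines, which is robust to
#' single outlying cell lines.
#'
#' @param networks a `cidrgn_network_set`.
#' @param x expression matrix (all cell lines, matching the third array
#'   dimension of the network set).
#' @param gene gene identifier.
#' @param cells indices (or logical mask) of the phenotype's cell lines.
#' @return Numeric vector of length `2 * n_genes` of per-entry medians.
#' @export
ss_regulatory_effects <- function(networks, x, gene, cells) {
  genes <- networks$genes
  if (!gene %in% genes) stop("'gene' is not in the network set")
  cells <- seq_len(nrow(x))[cells]
  if (!length(cells)) stop("empty phenotype")
  j <- match(gene, genes)
  eff <- vapply(cells, function(a) {
    co <- networks$coef[, , a]
    c(co[, j] * x[a, genes][j], co[j, ] * x[a, genes])
  }, numeric(2 * length(genes)))
  apply(eff, 1L, median)
}

#' Sample-specific Jaccard edge dissimilarity of one gene
#'
#' Neighbourhoods are pooled within each phenotype (the union over its cell
#' lines' networks) before the Jaccard comparison.
#'
#' @param neighborhoods list (one element per cell line) of neighbour-id
#'   vectors for the gene.
#' @param in_A logical vector: which cell lines belong to phenotype A.
#' @return Value in `[0, 1]`, with the two-empty-unions convention of
#'   [lambda_gene()].
#' @export
ss_lambda_gene <- function(neighborhoods, in_A) {
  nA <- unique(unlist(neighborhoods[in_A]))
  nB <- unique(unlist(neighborhoods[!in_A]))
  lambda_gene(nA, nB)
}

#' Score subnetworks with every dissimilarity statistic
#'
#' Computes the raw (un-normalised) statistics for each subnetwork: SAM-GS,
#' GSCA, the regulatory-effect dissimilarity, the Jaccard edge dissimilarity
#' and the Jaccard-adjusted effect dissimilarity. In bulk mode one network is
#' estimated per phenotype and subnetwork; in sample-specific mode one
#' network per cell line, aggregated by phenotype medians and neighbourhood
#' unions. The SAM-GS component is identical in both modes.
#'
#' @param x cell-line x gene expression matrix (or a `cidrgn_data` /
#'   `cidrgn_sim` object, in which case `phenotype`, `modulator` and missing
#'   `subnetworks` are taken from it).
#' @param phenotype two-level factor over cell lines.
#' @param subnetworks named list of gene-id vectors.
#' @param mode `"bulk"` or `"sample_specific"`.
#' @param modulator per-cell-line scalar, required in sample-specific mode.
#' @param edge_threshold neighbourhood threshold, see
#'   [network_neighborhoods()].
#' @param lambda_rule a [lasso_control()] object.
#' @param bandwidth kernel bandwidth for the sample-specific estimator.
#' @param samgs_scatter scatter form, see [samgs_stat()].
#' @param network_scope estimation universe, see [cidrgn()].
#' @param seed optional integer seed (fold assignment is random).
#' @return A data.frame with one row per subnetwork and columns `samgs`,
#'   `gsca`, `gamma`, `lambda`, `gamma_lambda`.
#' @export
score_subnetworks <- function(x, phenotype = NULL, subnetworks = NULL,
                              mode = c("bulk", "sample_specific"),
                              modulator = NULL, edge_threshold = 0,
                              lambda_rule = lasso_control(),
                              bandwidth = NULL,
                              samgs_scatter = c("sqrt", "raw"),
                              network_scope = c("subnetwork", "union"),
                              seed = NULL) {
  mode <- match.arg(mode)
  samgs_scatter <- match.arg(samgs_scatter)
  network_scope <- match.arg(network_scope)
  if (inherits(x, "cidrgn_data")) {
    if (is.null(phenotype)) phenotype <- x$phenotype
    if (is.null(modulator)) modulator <- x$modulator
    if (is.null(subnetworks)) subnetworks <- x$truth$sets
    x <- x$x
  }
  with_seed(seed, {
    eng <- cidrgn_engine(x, phenotype, subnetworks, mode, modulator,
                         edge_threshold, lambda_rule, bandwidth,
                         samgs_scatter, network_scope = network_scope)
    lev <- levels(eng$phenotype)
    st <- eng$score_split(which(eng$phenotype == lev[1L]),
                          which(eng$phenotype == lev[2L]))
    data.frame(subnetwork = names(subnetworks), st,
               row.names = NULL, stringsAsFactors = FALSE)
  })
}
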
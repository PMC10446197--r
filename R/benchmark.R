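# Scoring against ground truth and the Monte Carlo benchmark.

metrics_from_counts <- function(tp, fp, tn, fn) {
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  tnr <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  acc <- (tp + tn) / (tp + fp + tn + fn)
  c(recall = recall, precision = precision, tnr = tnr,
    f_measure = f, accuracy = acc)
}

#' Confusion metrics of responsive-subnetwork calls
#'
#' Treats responsive (phenotype-specific) subnetworks as the positive class
#' and common subnetworks as the negative class, and computes recall,
#' precision, true negative rate, F-measure and accuracy.
#'
#' @param decisions data.frame with columns `subnetwork` and `responsive`
#'   (as returned in a [cidrgn()] fit), or a logical vector aligned with the
#'   truth labels.
#' @param truth a truth list with `labels` (values `"common"` /
#'   `"responsive"`) and optionally `sets` whose names match
#'   `decisions$subnetwork`.
#' @return Named numeric vector of the five metrics plus the four confusion
#'   counts.
#' @examples
#' confusion_metrics(c(rep(TRUE, 5), FALSE, rep(FALSE, 3), TRUE),
#'                   list(labels = rep(c("responsive", "common"), c(6, 4))))
#' @export
confusion_metrics <- function(decisions, truth) {
  labels <- truth$labels
  if (is.data.frame(decisions)) {
    if (!is.null(truth$sets) && !is.null(names(truth$sets))) {
      m <- match(names(truth$sets), decisions$subnetwork)
      if (anyNA(m)) stop("decisions do not cover the truth's subnetworks")
      resp <- decisions$responsive[m]
    } else resp <- decisions$responsive
  } else resp <- decisions
  if (length(resp) != length(labels))
    stop("decisions do not cover the truth's subnetworks")
  pos <- labels == "responsive"
  tp <- sum(resp & pos); fp <- sum(resp & !pos)
  tn <- sum(!resp & !pos); fn <- sum(!resp & pos)
  c(metrics_from_counts(tp, fp, tn, fn), tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Monte Carlo benchmark of the permutation tests
#'
#' Replicates the simulation design: for each scenario, generates a fresh
#' dataset, runs the permutation tests of the requested methods on the true
#' subnetwork definitions, and pools the confusion counts over replicates
#' (micro-average) before forming the metrics.
#'
#' @param scenarios integer vector from 1:4.
#' @param size genes per subnetwork.
#' @param p total genes per dataset. The full design uses 1000; smaller
#'   values keep the subnetworks intact and subsample only the i.i.d.
#'   background block.
#' @param n_replicates Monte Carlo replicates per scenario.
#' @param methods subset of `"samgs"`, `"gsca"`, `"cidrgn1"`, `"cidrgn2"`.
#' @param sample_specific run the modulator-driven design and the
#'   sample-specific estimator.
#' @param T,kappa permutation count and significance threshold.
#' @param n_A,n_B,mu design parameters passed to [sim_scenario()].
#' @param lambda_rule a [lasso_control()] object.
#' @param seed integer seed; each (scenario, replicate) cell derives its own
#'   stream seed, so any sub-grid reproduces the full run's values.
#' @param verbose print progress.
#' @return A data.frame of class `cidrgn_benchmark`: one row per scenario x
#'   method with the five pooled metrics and the pooled confusion counts.
#'   Per-replicate decisions are kept in attribute `"log"`.
#' @export
cidrgn_benchmark <- function(scenarios = 1:4, size = 10, p = 1000,
                             n_replicates = 50,
                             methods = c("samgs", "gsca", "cidrgn1", "cidrgn2"),
                             sample_specific = FALSE, T = 100, kappa = 0.05,
                             n_A = 50, n_B = 50, mu = 0.3,
                             lambda_rule = lasso_control(), seed = 1,
                             verbose = FALSE) {
  methods <- match.arg(methods, c("samgs", "gsca", "cidrgn1", "cidrgn2"),
                       several.ok = TRUE)
  base_methods <- unique(sub("[12]$", "", methods))
  rows <- list()
  log <- list()
  for (sc in scenarios) {
    counts <- matrix(0L, length(methods), 4L,
                     dimnames = list(methods, c("tp", "fp", "tn", "fn")))
    for (r in seq_len(n_replicates)) {
      rs <- derive_seed(seed, sc + ifelse(sample_specific, 10L, 0L) +
                          100L * size, r)
      sim <- sim_scenario(sc, size = size, p = p, n_A = n_A, n_B = n_B,
                          mu = mu, sample_specific = sample_specific,
                          seed = rs)
      fit <- cidrgn(sim, T = T, kappa = kappa,
                    mode = if (sample_specific) "sample_specific" else "bulk",
                    lambda_rule = lambda_rule, methods = base_methods,
                    seed = derive_seed(rs, 1L, 1L))
      pos <- sim$truth$labels == "responsive"
      for (m in methods) {
        resp <- fit$p_values[[m]] < kappa
        counts[m, ] <- counts[m, ] + c(sum(resp & pos), sum(resp & !pos),
                                       sum(!resp & !pos), sum(!resp & pos))
        log[[length(log) + 1L]] <-
          data.frame(scenario = sc, replicate = r, method = m,
                     subnetwork = fit$p_values$subnetwork,
                     p_value = fit$p_values[[m]], responsive = resp,
                     truth = sim$truth$labels, stringsAsFactors = FALSE)
      }
      if (verbose)
        message(sprintf("scenario %d replicate %d/%d done", sc, r,
                        n_replicates))
    }
    for (m in methods)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc, size = size, method = m,
        t(metrics_from_counts(counts[m, "tp"], counts[m, "fp"],
                              counts[m, "tn"], counts[m, "fn"])),
        t(counts[m, ]), n_replicates = n_replicates,
        stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "log") <- do.call(rbind, log)
  class(out) <- c("cidrgn_benchmark", "data.frame")
  out
}

#' @export
print.cidrgn_benchmark <- function(x, ...) {
  cat("Monte Carlo benchmark (", x$n_replicates[1L], " replicates, subnetwork size ",
      x$size[1L], ")\n\n", sep = "")
  for (metric in c("recall", "precision", "tnr", "f_measure", "accuracy")) {
    tab <- tapply(x[[metric]], list(x$method, x$scenario), identity)
    cat(metric, ":\n", sep = "")
    print(round(tab, 3))
    cat("\n")
  }
  invisible(x)
}
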
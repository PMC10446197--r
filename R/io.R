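# Readers and writers: expression TSV, GMT gene sets, network edge lists,
# run configuration and decisions JSON.

#' Write and read an expression dataset as TSV
#'
#' Rows are cell lines. The first column is `cell_line`, the second
#' `phenotype`, an optional third `modulator`, and the remaining columns are
#' genes. The reader validates rather than coerces: it rejects missing or
#' non-numeric expression cells, duplicated gene or cell-line identifiers,
#' and phenotype columns without exactly two levels.
#'
#' @param data a `cidrgn_data` / `cidrgn_sim` object, or a list with
#'   elements `x`, `phenotype` and optionally `modulator`.
#' @param path file path.
#' @return `write_expression_tsv()` returns `path` invisibly;
#'   `read_expression_tsv()` returns a list of class `cidrgn_data` with
#'   elements `x`, `phenotype`, `modulator`.
#' @export
write_expression_tsv <- function(data, path) {
  df <- data.frame(cell_line = rownames(data$x),
                   phenotype = as.character(data$phenotype),
                   stringsAsFactors = FALSE)
  if (!is.null(data$modulator)) df$modulator <- data$modulator
  df <- cbind(df, as.data.frame(data$x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @param transpose set `TRUE` for gene-major files (genes as rows).
#' @export
read_expression_tsv <- function(path, transpose = FALSE) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (transpose) {
    ids <- df[[1L]]
    df <- as.data.frame(t(df[-1L]))
    names(df) <- ids
    df <- cbind(cell_line = rownames(df), df, stringsAsFactors = FALSE)
  }
  if (!"phenotype" %in% names(df))
    stop("missing required 'phenotype' column in ", path)
  idcol <- names(df)[1L]
  ids <- as.character(df[[idcol]])
  if (anyDuplicated(ids))
    stop("duplicate cell-line identifiers in ", path)
  phenotype <- factor(df$phenotype)
  if (nlevels(phenotype) != 2)
    stop("'phenotype' must have exactly two levels, found ",
         nlevels(phenotype))
  modulator <- if ("modulator" %in% names(df)) {
    m <- suppressWarnings(as.numeric(df$modulator))
    if (anyNA(m)) stop("non-numeric modulator value in ", path)
    m
  } else NULL
  genecols <- setdiff(names(df), c(idcol, "phenotype", "modulator"))
  if (anyDuplicated(genecols)) stop("duplicate gene identifiers in ", path)
  x <- matrix(NA_real_, nrow(df), length(genecols),
              dimnames = list(ids, genecols))
  for (g in genecols) {
    v <- df[[g]]
    if (is.character(v)) v[!nzchar(trimws(v))] <- NA
    num <- suppressWarnings(as.numeric(v))
    if (anyNA(num)) {
      bad <- which(is.na(num))[1L]
      stop("missing or non-numeric expression value at row ", bad,
           ", gene '", g, "' in ", path)
    }
    x[, g] <- num
  }
  structure(list(x = x, phenotype = phenotype, modulator = modulator),
            class = "cidrgn_data")
}

#' Write and read gene sets in GMT format
#'
#' One gene set per line: name, description, then tab-separated gene
#' identifiers. `write_gmt()` stores the truth label (or `"."`) in the
#' description field. `read_gmt()` optionally filters against a gene
#' universe, dropping unknown genes with a warning and skipping sets left
#' empty.
#'
#' @param sets named list of gene-id vectors, or a truth list with `sets`
#'   and `labels`.
#' @param path file path.
#' @param universe optional character vector of known gene ids.
#' @return `read_gmt()` returns a list with `sets` (named list) and
#'   `labels` (descriptions).
#' @export
write_gmt <- function(sets, path) {
  labels <- NULL
  if (!is.null(sets$sets)) { labels <- sets$labels; sets <- sets$sets }
  if (is.null(labels)) labels <- rep(".", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], labels[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(list(sets = list(), labels = character()))
  }
  sets <- list(); labels <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, " in ", path,
           ": need name, description and at least one gene")
    genes <- f[-(1:2)]
    if (!is.null(universe)) {
      unknown <- setdiff(genes, universe)
      if (length(unknown)) {
        warning("set '", f[1L], "': dropping ", length(unknown),
                " gene(s) absent from the expression universe")
        genes <- intersect(genes, universe)
      }
      if (!length(genes)) {
        warning("set '", f[1L], "' is empty after filtering; skipped")
        next
      }
    }
    sets[[f[1L]]] <- genes
    labels <- c(labels, f[2L])
  }
  list(sets = sets, labels = labels)
}

#' Write and read a network as an edge-list TSV
#'
#' Columns `regulator`, `target`, `weight`; only nonzero coefficients are
#' written. The reader reconstructs the coefficient matrix over `genes`
#' (default: the genes appearing in the file).
#'
#' @param network a `cidrgn_network`.
#' @param path file path.
#' @param genes gene universe for reconstruction.
#' @export
write_network_tsv <- function(network, path) {
  coef <- network$coef
  nz <- which(coef != 0, arr.ind = TRUE)
  df <- data.frame(regulator = colnames(coef)[nz[, 2L]],
                   target = rownames(coef)[nz[, 1L]],
                   weight = coef[nz], stringsAsFactors = FALSE)
  df <- df[order(df$target, df$regulator), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
read_network_tsv <- function(path, genes = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("regulator", "target", "weight")
  if (!all(need %in% names(df)))
    stop("edge list must have columns: ", paste(need, collapse = ", "))
  if (is.null(genes)) genes <- sort(unique(c(df$regulator, df$target)))
  coef <- matrix(0, length(genes), length(genes),
                 dimnames = list(genes, genes))
  coef[cbind(match(df$target, genes), match(df$regulator, genes))] <- df$weight
  structure(list(genes = genes, coef = coef, phenotype_tag = NULL),
            class = "cidrgn_network")
}

#' Write run results and provenance as JSON
#'
#' @param fit a `cidrgn` object.
#' @param path file path.
#' @export
write_decisions_json <- function(fit, path) {
  out <- list(
    config = list(mode = fit$mode, variant = fit$variant, T = fit$T,
                  kappa = fit$kappa, statistic = fit$statistic,
                  methods = fit$methods,
                  package_version = as.character(utils::packageVersion("cidrgn"))),
    subnetworks = lapply(seq_along(fit$subnetworks), function(i) list(
      name = fit$decisions$subnetwork[i],
      genes = fit$subnetworks[[i]],
      statistics = as.list(fit$statistics[i, -1L, drop = FALSE]),
      p_values = as.list(fit$p_values[i, -1L, drop = FALSE]),
      responsive = fit$decisions$responsive[i])))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
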
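# Cross-genome comparison statistics: a genome-by-measure matrix, column
# scaling (z-scores), per-measure linear regression, PCA, hierarchical
# clustering for heatmap rendering, and z-score outlier flagging.

#' Shipped annotation-report example table
#'
#' The selected annotation-report rows distributed with the package (well
#' annotated model genomes plus per-measure extremes), used in examples and
#' the arithmetic self-checks.
#'
#' @return data.frame with one row per genome.
#' @export
annotation_report_examples <- function() {
  utils::read.delim(system.file("extdata", "annotation_report_examples.tsv",
                                package = "annoqc"),
                    stringsAsFactors = FALSE)
}

DEFAULT_MEASURES <- c("total_length_mbp", "gc_percent", "protein_count",
                      "rna_count", "trna_aa_count", "hypothetical_count",
                      "coding_density", "avg_protein_len_aa",
                      "min_protein_len_aa", "short_protein_percent",
                      "standard_start_percent")

#' Build a measure matrix from metrics rows
#'
#' @param rows list of `metrics_row` objects.
#' @param measures measure (column) names; defaults to every numeric
#'   report measure.
#' @return Numeric matrix, genomes in rows, measures in columns; `NA`
#'   marks missing values.
#' @export
metrics_to_matrix <- function(rows, measures = DEFAULT_MEASURES) {
  if (inherits(rows, "metrics_row")) rows <- list(rows)
  m <- vapply(measures, function(ms) {
    vapply(rows, function(r) {
      v <- r[[ms]]
      if (is.null(v) || !is.numeric(v)) NA_real_ else as.numeric(v)
    }, 0)
  }, numeric(length(rows)))
  m <- matrix(m, nrow = length(rows),
              dimnames = list(vapply(rows, `[[`, "", "organism"), measures))
  m
}

#' Read / write a measure matrix as TSV
#'
#' Genomes in rows (first column `genome`), measures in columns.
#'
#' @param path TSV file.
#' @return `read_measure_tsv()`: numeric matrix with genome row names.
#' @export
read_measure_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(ncol(df) >= 2L)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  m
}

#' @rdname read_measure_tsv
#' @param m numeric matrix.
#' @export
write_measure_tsv <- function(m, path) {
  df <- data.frame(genome = rownames(m) %||% as.character(seq_len(nrow(m))),
                   m, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Scale measure columns to z-scores
#'
#' Each column is centred on its mean and divided by its sample standard
#' deviation (n-1 denominator), ignoring missing entries, which stay
#' missing. Idempotent: scaling a scaled matrix changes nothing.
#'
#' @param m numeric genome-by-measure matrix.
#' @return Matrix of the same shape with column mean 0 and sample sd 1.
#' @export
scale_columns <- function(m) {
  out <- m
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    ok <- !is.na(v)
    if (sum(ok) < 2L || length(unique(v[ok])) < 2L) {
      stop(sprintf("constant or near-empty measure column '%s'",
                   colnames(m)[j] %||% as.character(j)))
    }
    out[, j] <- (v - mean(v[ok])) / stats::sd(v[ok])
  }
  out
}

#' Ordinary least-squares line fit with R-squared and p-value
#'
#' Fits `y = intercept + slope * x` by OLS; `r_squared = 1 - SSres/SStot`;
#' the p-value is the two-sided test of zero slope on n - 2 degrees of
#' freedom.
#'
#' @param x,y numeric vectors of equal length (n >= 3, x not constant).
#' @return An object of class `regression_fit`: slope, intercept,
#'   r_squared, p_value, stderr (of the slope), n.
#' @export
fit_line <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations")
  if (length(unique(x)) < 2L) stop("x is constant")
  fit <- stats::lm(y ~ x)
  # perfect or constant fits are legitimate inputs here; summary.lm warns
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  co <- stats::coef(sm)
  r2 <- if (stats::var(y) == 0) 0 else sm$r.squared
  p <- if (stats::var(y) == 0) 1 else unname(co["x", "Pr(>|t|)"])
  structure(list(slope = unname(stats::coef(fit)[["x"]]),
                 intercept = unname(stats::coef(fit)[["(Intercept)"]]),
                 r_squared = r2, p_value = p,
                 stderr = unname(co["x", "Std. Error"]), n = n),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("y = %.6g + %.6g x   (n = %d)\n", x$intercept, x$slope, x$n))
  cat(sprintf("R^2 = %.4f, p = %.3g (two-sided, slope = 0, df = %d)\n",
              x$r_squared, x$p_value, x$n - 2L))
  invisible(x)
}

#' Principal component analysis of a scaled measure matrix
#'
#' Loadings are orthonormal with the sign convention that each component's
#' largest-magnitude loading element is nonnegative; scores are
#' `data %*% loadings`; variance fractions are nonincreasing and sum to at
#' most 1.
#'
#' @param m scaled genome-by-measure matrix (no missing values).
#' @param k number of components to keep.
#' @return List: `loadings` (measures x k), `scores` (genomes x k),
#'   `variance_fractions` (length k).
#' @export
pca_measures <- function(m, k = min(dim(m))) {
  if (k > ncol(m)) stop("k exceeds the number of measures")
  if (anyNA(m)) stop("PCA requires a complete matrix")
  pc <- stats::prcomp(m, center = FALSE, scale. = FALSE)
  total_var <- sum(pc$sdev^2)
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  list(loadings = load,
       scores = m %*% load,
       variance_fractions = (pc$sdev^2 / total_var)[seq_len(k)])
}

#' Hierarchical clustering of genomes or measures
#'
#' Agglomerative clustering with Euclidean distance and average linkage
#' (the two-dimensional clustering used for scaled-measure heatmaps).
#' `hclust` breaks ties deterministically by input order.
#'
#' @param m scaled genome-by-measure matrix.
#' @param axis cluster `"genomes"` (rows) or `"measures"` (columns).
#' @return List: `hclust` (the tree), `order` (leaf order indices),
#'   `labels` (leaf labels in heatmap order).
#' @export
hier_cluster <- function(m, axis = c("genomes", "measures")) {
  axis <- match.arg(axis)
  x <- if (axis == "measures") t(m) else m
  if (nrow(x) < 2L) stop("need at least 2 items to cluster")
  hc <- stats::hclust(stats::dist(x, method = "euclidean"),
                      method = "average")
  list(hclust = hc, order = hc$order,
       labels = (rownames(x) %||% as.character(seq_len(nrow(x))))[hc$order])
}

#' Flag outlying genome measures by z-score
#'
#' One WARN finding per (genome, measure) cell whose absolute z-score
#' exceeds the threshold — the situation where one strain exhibits skewed
#' annotation measures compared to other genomes of the cohort.
#'
#' @param m scaled genome-by-measure matrix (z-scores).
#' @param z_threshold absolute z-score threshold.
#' @return A findings table (rule OUTLIER001).
#' @export
flag_outliers <- function(m, z_threshold = qc_config()$z_threshold) {
  findings <- empty_findings()
  gn <- rownames(m) %||% as.character(seq_len(nrow(m)))
  mn <- colnames(m) %||% as.character(seq_len(ncol(m)))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      z <- m[i, j]
      if (!is.na(z) && abs(z) > z_threshold) {
        findings <- rbind_findings(findings, new_finding(
          "OUTLIER001", "WARN", replicon = gn[i], feature = mn[j],
          message = sprintf("%s: %s z-score %.2f beyond +/-%.1f",
                            gn[i], mn[j], z, z_threshold)))
      }
    }
  }
  findings
}
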
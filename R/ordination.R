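#' Log-ratio transform of a relative-abundance matrix
#'
#' Adds a single pseudocount equal to half the smallest non-zero proportion
#' in the whole matrix to every cell (eliminating zeros), then takes the
#' natural log. Rows are not renormalized after the pseudocount. The
#' centered log-ratio variant subtracts each row's mean log value.
#'
#' @param p samples-by-taxa matrix of non-negative proportions (rows are
#'   per-sample relative abundances).
#' @param type `"logratio"` (default): log of augmented proportions;
#'   `"clr"`: centered log-ratio.
#' @return numeric matrix of transformed values; attribute `"pseudocount"`
#'   records the constant used.
#' @export
logratio_transform <- function(p, type = c("logratio", "clr")) {
  type <- match.arg(type)
  p <- as.matrix(p)
  if (any(p < 0)) stop("proportions must be non-negative")
  nz <- p[p > 0]
  if (length(nz) == 0L) stop("all-zero matrix cannot be log-ratio transformed")
  pseudo <- min(nz) / 2
  out <- log(p + pseudo)
  if (type == "clr") out <- out - rowMeans(out)
  attr(out, "pseudocount") <- pseudo
  out
}

#' Correlation-based principal components analysis
#'
#' PCA on the taxon-taxon correlation matrix: columns are standardized, so
#' the analysis is invariant to per-taxon affine rescaling. Constant columns
#' (zero variance) are dropped with a warning since their correlations are
#' undefined. Axes are ordered by decreasing eigenvalue and signed so that
#' each loading vector's largest-magnitude element is positive.
#'
#' @param x samples-by-taxa numeric matrix (typically log-ratio transformed
#'   relative abundances).
#' @param top_n_taxa optional restriction to the `n` columns with the
#'   largest mean value before the PCA (`NULL` keeps all).
#' @return list of class `pca_result`: `scores` (samples x axes),
#'   `loadings` (taxa x axes), `variance_explained` (percent per axis,
#'   summing to 100), `eigenvalues`.
#' @export
correlation_pca <- function(x, top_n_taxa = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) stop("need at least 2 samples and 2 taxa")
  if (!is.null(top_n_taxa) && top_n_taxa < ncol(x)) {
    ord <- order(-colMeans(x), colnames(x))
    x <- x[, sort(ord[seq_len(top_n_taxa)]), drop = FALSE]
  }
  const <- apply(x, 2, stats::sd) == 0
  if (any(const)) {
    warning("dropping constant taxon column(s): ",
            paste(colnames(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  if (ncol(x) < 2) stop("fewer than 2 non-constant taxa remain")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  for (k in seq_len(ncol(pc$rotation))) {
    j <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[j, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  ev <- pc$sdev^2
  structure(list(scores = pc$x, loadings = pc$rotation,
                 variance_explained = 100 * ev / sum(ev),
                 eigenvalues = ev),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  ve <- x$variance_explained
  cat("<pca_result>", nrow(x$scores), "samples,", nrow(x$loadings), "taxa\n")
  cat("  variance explained (%):",
      paste(sprintf("PC%d %.1f", seq_len(min(5, length(ve))), ve[seq_len(min(5, length(ve)))]),
            collapse = ", "),
      if (length(ve) > 5) "...", "\n")
  invisible(x)
}

#' Spearman rank correlation matrix between taxa
#'
#' Pairwise Spearman correlations over samples for each taxon pair, with
#' mid-ranks for ties. Constant taxa have undefined correlations and get
#' `NA` entries (flagged with a warning).
#'
#' @param x samples-by-taxa numeric matrix (e.g. cpm values).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need at least 3 samples")
  const <- apply(x, 2, stats::sd) == 0
  if (any(const)) {
    warning("constant taxon column(s) have undefined correlations: ",
            paste(colnames(x)[const], collapse = ", "))
  }
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  diag(rho) <- 1
  rho
}

#' Within-family OTU composition profiles
#'
#' Restricts a count matrix to the OTUs of a single family and rescales each
#' sample's counts to proportions over those OTUs (unit-scaled rows).
#' Samples with zero family counts cannot be scaled and are excluded with a
#' flag. An optional restriction keeps the `top_k` OTUs by total counts
#' (proportions are then over the retained OTUs).
#'
#' @param x a [count_matrix()] or counts matrix whose columns are the OTUs
#'   of one family.
#' @param top_k optional restriction to the most abundant OTUs.
#' @return matrix of per-sample proportions (rows sum to 1); attribute
#'   `"excluded"` names zero-count samples.
#' @export
within_family_profiles <- function(x, top_k = NULL) {
  m <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  if (!is.null(top_k) && top_k < ncol(m)) {
    ord <- order(-colSums(m), colnames(m))
    m <- m[, sort(ord[seq_len(top_k)]), drop = FALSE]
  }
  totals <- rowSums(m)
  excluded <- rownames(m)[totals == 0]
  m <- m[totals > 0, , drop = FALSE]
  out <- sweep(m, 1, rowSums(m), "/")
  attr(out, "excluded") <- excluded
  out
}
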
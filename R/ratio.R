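#' Per-sample relative abundance of a focal taxon pair
#'
#' For two focal taxa S and C (here the two dominant fish genera), computes
#' the per-sample fraction `S/(S+C)` separately for each barcode locus.
#' Grab replicates are pooled into events first (so the pooled fraction is
#' the count-weighted mean of the replicate fractions). Samples with fewer
#' than `min_total` combined reads are flagged `retained = FALSE`, since
#' proportions estimated from few observations carry high standard error;
#' a sample with zero combined reads gets an `NA` fraction.
#'
#' @param x a [count_matrix()] collapsed to the rank of the focal taxa, with
#'   `locus` in its `taxon_meta`.
#' @param taxon_s,taxon_c labels of the numerator and complement taxa.
#' @param loci loci to evaluate (default `c("12S", "COI")`; loci without
#'   both taxa are skipped).
#' @param min_total retention threshold on `S + C` (default 20).
#' @param pool_grabs pool grab replicates before computing fractions.
#' @return data frame with one row per sample and locus: `sample`, `site`,
#'   `method`, `time_min`, `locus`, `s_count`, `c_count`, `fraction`,
#'   `retained`.
#' @export
compute_fractions <- function(x, taxon_s = "Salmo", taxon_c = "Coregonus",
                              loci = c("12S", "COI"), min_total = 20,
                              pool_grabs = TRUE) {
  x <- as_count_matrix(x)
  if (pool_grabs && !is.null(x$sample_meta$method)) x <- pool_grab_replicates(x)
  tm <- x$taxon_meta
  if (is.null(tm$locus)) stop("taxon_meta lacks a locus column")
  lab <- if (!is.null(tm$label)) tm$label else colnames(x$counts)
  out <- list()
  for (lc in loci) {
    s_col <- which(lab == taxon_s & tm$locus == lc)
    c_col <- which(lab == taxon_c & tm$locus == lc)
    if (length(s_col) != 1L || length(c_col) != 1L) next
    s <- x$counts[, s_col]
    cc <- x$counts[, c_col]
    tot <- s + cc
    out[[lc]] <- data.frame(
      sample = rownames(x$counts),
      site = if (!is.null(x$sample_meta$site)) x$sample_meta$site else NA,
      method = if (!is.null(x$sample_meta$method)) x$sample_meta$method else NA,
      time_min = if (!is.null(x$sample_meta$time_min)) x$sample_meta$time_min else NA,
      locus = lc, s_count = unname(s), c_count = unname(cc),
      fraction = ifelse(tot > 0, s / tot, NA_real_),
      retained = tot >= min_total,
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) stop("no locus carries both ", taxon_s, " and ", taxon_c)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Center values around zero within each site
#'
#' Subtracts the per-site mean, so estimates from different sites can be
#' pooled for a comparison of variances that assumes only that dispersion,
#' not location, is shared across sites. Only retained estimates enter the
#' site means.
#'
#' @param estimates data frame from [compute_fractions()] (or any data frame
#'   with `site`, `fraction` and optionally `retained`).
#' @return the data frame restricted to retained rows, with a `centered`
#'   column; per-site means of `centered` are zero.
#' @export
center_by_site <- function(estimates) {
  est <- estimates
  if (!is.null(est$retained)) est <- est[est$retained & !is.na(est$fraction), , drop = FALSE]
  if (nrow(est) == 0L) stop("no retained estimates to center")
  if (any(!table(est$site) >= 1)) stop("empty site")
  mu <- tapply(est$fraction, est$site, mean)
  est$centered <- as.numeric(est$fraction - mu[as.character(est$site)])
  rownames(est) <- NULL
  est
}

two_sided_f_p <- function(f, df1, df2) {
  min(1, 2 * min(stats::pf(f, df1, df2), stats::pf(f, df1, df2, lower.tail = FALSE)))
}

#' F-test of heterogeneity of variance between two groups
#'
#' `F = var(a) / var(b)` with sample variances (denominator `n - 1`); the
#' two-sided p-value doubles the smaller tail of the F distribution with
#' `(n_a - 1, n_b - 1)` degrees of freedom (capped at 1).
#'
#' @param group_a,group_b numeric vectors (each of length at least 2).
#' @return list with `F`, `df`, `p`, `var_a`, `var_b`, `n_a`, `n_b`.
#' @export
variance_f_test <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) stop("each group needs at least 2 values")
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if (vb == 0) stop("zero variance in the denominator group")
  f <- va / vb
  df <- c(length(group_a) - 1L, length(group_b) - 1L)
  list(F = f, df = df, p = two_sided_f_p(f, df[1], df[2]),
       var_a = va, var_b = vb, n_a = length(group_a), n_b = length(group_b))
}

#' Two-sided p-value from an F statistic
#'
#' Tail-doubling rule used by [variance_f_test()], exposed so that a
#' variance ratio computed elsewhere can be assessed the same way.
#'
#' @param f observed F statistic.
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @return two-sided p-value.
#' @export
f_test_pvalue <- function(f, df1, df2) two_sided_f_p(f, df1, df2)

#' Two-way ANOVA of values by site and sampling method
#'
#' Fits `value ~ site * method` and reports sums of squares, degrees of
#' freedom, mean squares, F and p for the site effect, the method effect,
#' their interaction, the within (residual) term and the total. For
#' unbalanced data the partial (Type II) decomposition is the default;
#' sequential (Type I, site then method then interaction) is available.
#' Under Type II the effect sums of squares need not add up to the total.
#'
#' @param values numeric response.
#' @param factor_site,factor_method factors with at least two levels each;
#'   every site-by-method cell must be non-empty.
#' @param ss_type `"II"` (default) or `"I"`.
#' @return data frame with rows `Site`, `Method`, `Interaction`, `Within`,
#'   `Total` and columns `SS`, `df`, `MS`, `F`, `P`.
#' @export
two_way_anova <- function(values, factor_site, factor_method,
                          ss_type = c("II", "I")) {
  ss_type <- match.arg(ss_type)
  site <- as.factor(factor_site)
  method <- as.factor(factor_method)
  stopifnot(nlevels(site) >= 2, nlevels(method) >= 2)
  if (any(table(site, method) == 0)) stop("empty site x method cell")
  dat <- data.frame(value = values, site = site, method = method)
  fit <- stats::lm(value ~ site * method, data = dat)
  if (ss_type == "II") {
    a2 <- car::Anova(fit, type = 2)
    ss <- c(a2["site", "Sum Sq"], a2["method", "Sum Sq"],
            a2["site:method", "Sum Sq"], a2["Residuals", "Sum Sq"])
    df <- c(a2["site", "Df"], a2["method", "Df"],
            a2["site:method", "Df"], a2["Residuals", "Df"])
  } else {
    a1 <- stats::anova(fit)
    ss <- c(a1["site", "Sum Sq"], a1["method", "Sum Sq"],
            a1["site:method", "Sum Sq"], a1["Residuals", "Sum Sq"])
    df <- c(a1["site", "Df"], a1["method", "Df"],
            a1["site:method", "Df"], a1["Residuals", "Df"])
  }
  ms <- ss / df
  fv <- c(ms[1:3] / ms[4], NA)
  pv <- c(stats::pf(fv[1:3], df[1:3], df[4], lower.tail = FALSE), NA)
  total_ss <- sum((values - mean(values))^2)
  out <- data.frame(
    SS = c(ss, total_ss), df = c(df, length(values) - 1L),
    MS = c(ms, NA), F = c(fv, NA), P = c(pv, NA),
    row.names = c("Site", "Method", "Interaction", "Within", "Total")
  )
  attr(out, "ss_type") <- ss_type
  out
}

#' Correlation of estimates with sample initiation time, per site
#'
#' Pearson correlation of the retained fractions (or optionally
#' log-transformed counts) against initiation time, separately at each site.
#' A constant series has no defined correlation and is flagged rather than
#' erroring.
#'
#' @param estimates data frame from [compute_fractions()], or any data frame
#'   with `site`, `time_min` and the response column.
#' @param response column to correlate (default `"fraction"`).
#' @param log_transform log-transform the response (`log(x + 1)`), for
#'   count responses.
#' @return data frame with columns `site`, `n`, `r`, `p`, `defined`.
#' @export
time_correlations <- function(estimates, response = "fraction",
                              log_transform = FALSE) {
  est <- estimates
  if (!is.null(est$retained)) est <- est[est$retained, , drop = FALSE]
  est <- est[!is.na(est[[response]]), , drop = FALSE]
  out <- lapply(split(est, est$site), function(d) {
    y <- d[[response]]
    if (log_transform) y <- log(y + 1)
    if (nrow(d) < 3 || stats::sd(y) == 0 || stats::sd(d$time_min) == 0) {
      return(data.frame(site = d$site[1], n = nrow(d), r = NA_real_,
                        p = NA_real_, defined = FALSE))
    }
    ct <- stats::cor.test(y, d$time_min)
    data.frame(site = d$site[1], n = nrow(d), r = unname(ct$estimate),
               p = ct$p.value, defined = TRUE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
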
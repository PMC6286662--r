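#' Configuration for the end-to-end analysis pipeline
#'
#' Centralizes the filtering thresholds and analysis options. Unknown
#' arguments are rejected. Defaults follow the study constants: run-wide
#' minimum of 10 counts, cross-talk censoring of 12S taxa (total >= 10 and
#' not exclusively singletons), a ratio retention threshold of 20 combined
#' reads, 150 bacterial families and 50 PCA taxa, Type II ANOVA, log-ratio
#' transform, 9,999 permutations.
#'
#' @param min_run_count run-wide minimum sequence count per taxon.
#' @param crosstalk_min_total cross-talk censoring total threshold.
#' @param crosstalk_locus locus the censoring rule applies to.
#' @param ratio_min_total minimum combined reads for a ratio estimate.
#' @param taxon_s,taxon_c focal numerator and complement taxon labels.
#' @param euk_loci loci counted as eukaryotic.
#' @param bact_locus the bacterial locus tag.
#' @param top_n_bacteria bacterial families kept for diversity analysis.
#' @param pca_top_n taxa entering the correlation PCA.
#' @param transform `"logratio"` or `"clr"`.
#' @param anova_ss_type `"II"` or `"I"`.
#' @param nperm permutations for the dispersion test.
#' @param bloom_family family whose share is correlated with time.
#' @param seed integer seed for all randomized steps.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_run_count = 10,
                            crosstalk_min_total = 10,
                            crosstalk_locus = "12S",
                            ratio_min_total = 20,
                            taxon_s = "Salmo",
                            taxon_c = "Coregonus",
                            euk_loci = c("12S", "COI", "16S-euk"),
                            bact_locus = "16S-bact",
                            top_n_bacteria = 150,
                            pca_top_n = 50,
                            transform = c("logratio", "clr"),
                            anova_ss_type = c("II", "I"),
                            nperm = 9999,
                            bloom_family = "Flavobacteriaceae",
                            seed = 1) {
  transform <- match.arg(transform)
  anova_ss_type <- match.arg(anova_ss_type)
  stopifnot(min_run_count >= 0, crosstalk_min_total >= 0,
            ratio_min_total >= 0, top_n_bacteria >= 1, pca_top_n >= 2,
            nperm >= 1)
  structure(list(min_run_count = min_run_count,
                 crosstalk_min_total = crosstalk_min_total,
                 crosstalk_locus = crosstalk_locus,
                 ratio_min_total = ratio_min_total,
                 taxon_s = taxon_s, taxon_c = taxon_c,
                 euk_loci = euk_loci, bact_locus = bact_locus,
                 top_n_bacteria = top_n_bacteria, pca_top_n = pca_top_n,
                 transform = transform, anova_ss_type = anova_ss_type,
                 nperm = nperm, bloom_family = bloom_family, seed = seed),
            class = "pipeline_config")
}

#' Run the composite-versus-grab comparison pipeline
#'
#' Executes the full analysis on a taxon-level count matrix: cross-talk
#' censoring and the run-wide minimum count filter; Morisita dissimilarity
#' and distance-to-centroid dispersion of time-matched eukaryotic samples
#' by sampling method; per-sampler rarefaction richness at the smallest
#' eukaryotic total; per-taxon detection rates with parity trimming; the
#' focal-ratio analysis (site means, inter-locus correlation, variance
#' F-test on site-centered values, two-way ANOVA, time correlations); and
#' bacterial ordination (top families, log-ratio transform, correlation
#' PCA, bloom-family share versus time).
#'
#' @param x a [count_matrix()] at the analysis rank, with `locus` and
#'   `label` in its `taxon_meta` (e.g. the output of [simulate_counts()]).
#' @param config a [pipeline_config()].
#' @return a list of stage results plus a `manifest` recording the seed,
#'   thresholds and package version.
#' @export
run_pipeline <- function(x, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- as_count_matrix(x)
  set.seed(config$seed)
  stage <- "filtering"
  out <- list()
  tryCatch({
    xf <- censor_crosstalk(x, min_total = config$crosstalk_min_total,
                           locus = config$crosstalk_locus)
    xf <- filter_min_run_count(xf, min_total = config$min_run_count)
    if (ncol(xf$counts) == 0L) {
      warning("no taxa survive filtering; stopping after the filter stage")
      return(list(filtered = xf, manifest = pipeline_manifest(config)))
    }
    out$filtered <- xf

    stage <- "eukaryote dispersion"
    euk <- xf[, xf$taxon_meta$locus %in% config$euk_loci]
    pairs <- time_match_pairs(euk)
    pooled <- pool_grab_replicates(euk)
    matched <- pooled[c(pairs$composite, pairs$grab), ]
    keep <- rowSums(matched$counts) >= 2
    matched <- matched[keep, ]
    D <- morisita_matrix(matched)
    out$dispersion_eukaryote <- dispersion_to_centroid(
      D, matched$sample_meta$method, nperm = config$nperm, seed = config$seed)
    out$time_matched_pairs <- pairs

    stage <- "richness"
    out$richness <- sampler_richness(euk)

    stage <- "detection rates"
    out$detection <- detection_rates(euk)

    stage <- "ratio analysis"
    fr <- compute_fractions(xf, taxon_s = config$taxon_s,
                            taxon_c = config$taxon_c,
                            min_total = config$ratio_min_total)
    out$fractions <- fr
    ret <- fr[fr$retained & !is.na(fr$fraction), , drop = FALSE]
    out$site_means <- tapply(ret$fraction, ret$site, mean)
    out$site_se <- tapply(ret$fraction, ret$site,
                          function(v) stats::sd(v) / sqrt(length(v)))
    wide <- merge(ret[ret$locus == "12S", c("sample", "fraction")],
                  ret[ret$locus == "COI", c("sample", "fraction")],
                  by = "sample", suffixes = c("_12S", "_COI"))
    out$interlocus_r <- if (nrow(wide) >= 3)
      stats::cor(wide$fraction_12S, wide$fraction_COI) else NA_real_
    cen <- center_by_site(fr)
    out$variance_test <- variance_f_test(
      cen$centered[cen$method == "composite"],
      cen$centered[cen$method == "grab"])
    out$anova <- two_way_anova(ret$fraction, ret$site, ret$method,
                               ss_type = config$anova_ss_type)
    out$time_correlation <- time_correlations(fr)

    stage <- "bacterial ordination"
    bact <- xf[, xf$taxon_meta$locus %in% config$bact_locus]
    if (ncol(bact$counts) >= 2) {
      bact_top <- top_n_by_abundance(bact, n = config$top_n_bacteria)
      prop <- to_cpm(bact_top, quiet = TRUE) / 1e6
      lr <- logratio_transform(prop, type = config$transform)
      out$pca <- correlation_pca(lr, top_n_taxa = config$pca_top_n)
      out$pca_top2_variance <- sum(out$pca$variance_explained[1:2])
      if (config$bloom_family %in% colnames(prop)) {
        share <- prop[, config$bloom_family]
        tm <- bact_top$sample_meta[rownames(prop), "time_min"]
        out$bloom_time_spearman <- stats::cor(share, tm, method = "spearman")
      }
    }
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  out$manifest <- pipeline_manifest(config)
  out
}

pipeline_manifest <- function(config) {
  list(package = "ednacomp",
       version = as.character(utils::packageVersion("ednacomp")),
       config = unclass(config))
}

#' Per-sampler pooled richness at a common rarefaction depth
#'
#' Pools each sampler's (parity-trimmed) samples into one count vector,
#' rarefies every sampler to the smallest pooled total, and reports expected
#' richness with standard errors. The sampler that sets the minimum has a
#' standard error of zero by construction.
#'
#' @param x a eukaryotic [count_matrix()].
#' @return data frame: `sampler`, `site`, `method`, `total`,
#'   `rarefied_to`, `expected_richness`, `standard_error`.
#' @export
sampler_richness <- function(x) {
  x <- as_count_matrix(x)
  det <- detection_rates(x)        # only for its parity-trimmed sample set
  used <- attr(det, "samples_used")
  sub <- x[rownames(x$counts) %in% used, ]
  sm <- sub$sample_meta
  res <- lapply(split(seq_len(nrow(sm)), sm$sampler), function(rows) {
    counts <- colSums(sub$counts[rows, , drop = FALSE])
    data.frame(sampler = sm$sampler[rows[1]], site = sm$site[rows[1]],
               method = sm$method[rows[1]], total = sum(counts),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  depth <- min(res$total)
  rar <- lapply(split(seq_len(nrow(sm)), sm$sampler), function(rows) {
    counts <- colSums(sub$counts[rows, , drop = FALSE])
    rarefy_richness(counts, depth)
  })
  rar <- do.call(rbind, rar)
  res$rarefied_to <- depth
  res$expected_richness <- rar$expected_richness
  res$standard_error <- rar$standard_error
  rownames(res) <- NULL
  res
}
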
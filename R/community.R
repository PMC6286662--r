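#' Morisita dissimilarity between two count vectors
#'
#' Computes `1 - C` where `C = 2 * sum(x*y) / ((lambda_x + lambda_y) * Nx * Ny)`
#' and `lambda = sum(n*(n-1)) / (N*(N-1))`. The index is defined on integer
#' counts and is nearly independent of sample size, which makes it suited to
#' libraries whose sequencing depth varies systematically between sampling
#' methods. Note the similarity index can exceed 1 at small counts, so the
#' dissimilarity can be slightly negative; values are reported unclamped.
#'
#' @param x,y non-negative integer vectors over the same taxa.
#' @return a single dissimilarity value (at most 1; 1 exactly for disjoint
#'   supports).
#' @export
morisita_dissimilarity <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must cover the same taxa")
  if (any(abs(c(x, y) - round(c(x, y))) > 1e-8)) {
    stop("Morisita index requires integer counts")
  }
  nx <- sum(x); ny <- sum(y)
  if (nx < 2 || ny < 2) stop("each count vector must total at least 2")
  lambda <- function(v, n) sum(v * (v - 1)) / (n * (n - 1))
  c_sim <- 2 * sum(x * y) / ((lambda(x, nx) + lambda(y, ny)) * nx * ny)
  1 - c_sim
}

#' Pairwise Morisita dissimilarity matrix
#'
#' With `clamp = TRUE` (default) the small negative dissimilarities the
#' index can produce for near-identical samples are set to zero, so the
#' matrix is usable as input to ordination and dispersion analysis; this
#' matches the convention of community-ecology distance implementations.
#'
#' @param x a [count_matrix()] or samples-by-taxa integer matrix.
#' @param clamp truncate negative dissimilarities at zero.
#' @return a `dist` object over samples.
#' @export
morisita_matrix <- function(x, clamp = TRUE) {
  m <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- morisita_dissimilarity(m[i, ], m[j, ])
    }
  }
  if (clamp) d[d < 0] <- 0
  stats::as.dist(d)
}

#' Expected richness under rarefaction, with standard error
#'
#' Expected number of taxa in a random subsample of `n` of the `N` total
#' sequence counts, under hypergeometric subsampling without replacement,
#' with the classical variance of rarefied richness; the computation is
#' delegated to [vegan::rarefy()], which evaluates the binomial-coefficient
#' ratios on the log-gamma scale.
#'
#' @param counts non-negative integer vector of per-taxon counts.
#' @param n subsample size, `1 <= n <= sum(counts)`.
#' @return data frame with `n_subsampled`, `expected_richness`,
#'   `standard_error`.
#' @export
rarefy_richness <- function(counts, n) {
  counts <- as.numeric(counts)
  if (any(abs(counts - round(counts)) > 1e-8) || any(counts < 0)) {
    stop("counts must be non-negative integers")
  }
  N <- sum(counts)
  if (length(n) != 1L || n <= 0) stop("n must be a single positive integer")
  if (n > N) stop("subsample size n exceeds the total count ", N)
  r <- suppressWarnings(vegan::rarefy(counts, sample = n, se = TRUE))
  data.frame(n_subsampled = as.integer(n),
             expected_richness = unname(r["S", 1]),
             standard_error = unname(r["se", 1]))
}

#' Taxon accumulation curve under rarefaction
#'
#' Expected richness at subsample sizes `step, 2*step, ..., N` (the full
#' total is always included as the last point).
#'
#' @param counts non-negative integer vector of per-taxon counts.
#' @param step increment in sequence counts (default 10).
#' @return data frame of [rarefy_richness()] rows; expected richness is
#'   monotone nondecreasing in `n`.
#' @export
accumulation_curve <- function(counts, step = 10) {
  stopifnot(step >= 1)
  N <- sum(counts)
  ns <- unique(c(seq(step, N, by = step), N))
  do.call(rbind, lapply(ns, function(n) rarefy_richness(counts, n)))
}

#' Pool grab replicates into one sample per grab event
#'
#' Grab replicate bottles sharing a sampler code and initiation time are
#' summed into a single pooled sample named `"<sampler>_<minutes>"`.
#' Composite samples pass through unchanged. Replicate sets of unequal size
#' (e.g. a missing bottle) are pooled with a warning rather than dropped.
#'
#' @param x a [count_matrix()] whose `sample_meta` carries `method`,
#'   `sampler`, `time_min` and `replicate`.
#' @return a `count_matrix` with one row per grab event.
#' @export
pool_grab_replicates <- function(x) {
  x <- as_count_matrix(x)
  sm <- x$sample_meta
  if (is.null(sm$method)) stop("sample_meta lacks a method column")
  grab <- sm$method == "grab"
  if (!any(grab)) return(x)
  key <- paste(sm$sampler, sm$time_min, sep = "_")
  gkey <- unique(key[grab])
  sizes <- table(key[grab])
  if (length(unique(sizes)) > 1) {
    warning("grab replicate sets of unequal size pooled: ",
            paste(sprintf("%s (n=%d)", names(sizes), sizes), collapse = ", "))
  }
  pooled <- matrix(
    unlist(lapply(gkey, function(k) {
      colSums(x$counts[grab & key == k, , drop = FALSE])
    })),
    nrow = length(gkey), ncol = ncol(x$counts), byrow = TRUE,
    dimnames = list(gkey, colnames(x$counts)))
  meta_one <- sm[grab, , drop = FALSE][match(gkey, key[grab]), , drop = FALSE]
  meta_one$replicate <- NA_integer_
  rownames(meta_one) <- gkey

  keep <- !grab
  counts <- rbind(x$counts[keep, , drop = FALSE], pooled)
  meta <- rbind(sm[keep, , drop = FALSE], meta_one)
  count_matrix(counts[order(meta$sampler, meta$time_min), , drop = FALSE],
               meta[order(meta$sampler, meta$time_min), , drop = FALSE],
               x$taxon_meta)
}

#' Pair composite samples with time-matched grab events
#'
#' A composite sample and a (pooled) grab event are time-matched when their
#' initiation times differ by at most `tolerance_min` minutes at the same
#' site. Multiple candidate matches within the tolerance are an error, since
#' the pairing would be ambiguous.
#'
#' @param x a [count_matrix()]; grab replicates are pooled internally.
#' @param tolerance_min matching tolerance in minutes (default 1).
#' @return data frame with columns `site`, `composite`, `grab`,
#'   `time_composite`, `time_grab`; attribute `"unpaired"` lists samples with
#'   no partner.
#' @export
time_match_pairs <- function(x, tolerance_min = 1) {
  x <- pool_grab_replicates(as_count_matrix(x))
  sm <- x$sample_meta
  if (is.null(sm$site) || is.null(sm$time_min)) {
    stop("sample_meta must carry site and time_min")
  }
  comp <- which(sm$method == "composite")
  grab <- which(sm$method == "grab")
  pairs <- list()
  used <- integer(0)
  for (i in comp) {
    cand <- grab[sm$site[grab] == sm$site[i] &
                 abs(sm$time_min[grab] - sm$time_min[i]) <= tolerance_min]
    if (length(cand) > 1) {
      stop("composite sample ", rownames(sm)[i], " matches ", length(cand),
           " grab events within ", tolerance_min, " min; tighten the tolerance")
    }
    if (length(cand) == 1) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        site = sm$site[i], composite = rownames(sm)[i],
        grab = rownames(sm)[cand], time_composite = sm$time_min[i],
        time_grab = sm$time_min[cand], stringsAsFactors = FALSE)
      used <- c(used, cand)
    }
  }
  out <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(site = character(0), composite = character(0),
               grab = character(0), time_composite = integer(0),
               time_grab = integer(0))
  unpaired <- c(rownames(sm)[setdiff(grab, used)],
                setdiff(rownames(sm)[comp], out$composite))
  attr(out, "unpaired") <- unpaired
  out
}

#' Trim the larger sample set for parity with the smaller
#'
#' To compare detection rates at equal sample number and filtered volume,
#' the larger set (ordered by initiation time) is trimmed from both ends to
#' the size of the smaller: `floor(excess/2)` samples are dropped from the
#' start and `ceiling(excess/2)` from the end. This keeps the maximal
#' temporal overlap between the two sets.
#'
#' @param idx integer vector indexing the larger set, ordered by time.
#' @param target size to trim to.
#' @return the trimmed index vector.
#' @keywords internal
parity_trim_indices <- function(idx, target) {
  excess <- length(idx) - target
  if (excess < 0) stop("cannot trim a set below its own size")
  if (excess == 0) return(idx)
  head_drop <- floor(excess / 2)
  tail_drop <- ceiling(excess / 2)
  idx[seq(head_drop + 1L, length(idx) - tail_drop)]
}

#' Per-taxon detection rates by sampling method
#'
#' A taxon's detection rate under a method is the number of samples with a
#' non-zero count divided by the number of samples considered. With
#' `parity_trim = TRUE` (default) the composite set at each site is trimmed
#' from both ends of the time series to the number of grab samples at that
#' site (fewer from the start, more from the end when the excess is odd),
#' equalizing sample number and maximizing temporal overlap.
#'
#' @param x a [count_matrix()]; grab samples are counted as individual
#'   bottles (not pooled events).
#' @param parity_trim trim composite samples to grab parity per site.
#' @return data frame with columns `taxon`, `method`, `detections`, `n`,
#'   `rate`; attribute `"samples_used"` names the retained samples.
#' @export
detection_rates <- function(x, parity_trim = TRUE) {
  x <- as_count_matrix(x)
  sm <- x$sample_meta
  if (is.null(sm$site) || is.null(sm$method)) stop("sample_meta must carry site and method")
  keep <- integer(0)
  for (s in unique(sm$site)) {
    comp <- which(sm$site == s & sm$method == "composite")
    grab <- which(sm$site == s & sm$method == "grab")
    comp <- comp[order(sm$time_min[comp])]
    if (parity_trim && length(comp) > length(grab) && length(grab) > 0) {
      comp <- parity_trim_indices(comp, length(grab))
    }
    keep <- c(keep, comp, grab)
  }
  sub <- x[sort(keep), ]
  out <- do.call(rbind, lapply(c("composite", "grab"), function(m) {
    rows <- sub$sample_meta$method == m
    det <- colSums(sub$counts[rows, , drop = FALSE] > 0)
    data.frame(taxon = colnames(sub$counts), method = m,
               detections = unname(det), n = sum(rows),
               rate = unname(det) / sum(rows), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "samples_used") <- rownames(sub$counts)
  out
}

#' Multivariate dispersion around group centroids, with tests
#'
#' Embeds a dissimilarity matrix by principal coordinates (double-centering
#' and eigendecomposition, via [vegan::betadisper()] with
#' `type = "centroid"`); squared distances to the group centroid combine
#' positive-eigenvalue axes minus the imaginary-axis contribution from
#' negative eigenvalues, clamped at zero. Group differences in
#' distance-to-centroid are tested with (a) a two-sided permutation t-test
#' on the distances (group labels permuted; default 9,999 permutations) and
#' (b) a Mann--Whitney U test.
#'
#' @param d a `dist` or symmetric matrix of dissimilarities.
#' @param groups factor of group membership (two groups for the tests; each
#'   group needs at least two members).
#' @param nperm number of label permutations (default 9999).
#' @param seed optional integer seed for the permutation stream.
#' @return list with `distances` (data frame sample/group/distance),
#'   `group_means`, `t_statistic`, `p_permutation`, `p_mann_whitney`,
#'   `nperm`, `seed`.
#' @export
dispersion_to_centroid <- function(d, groups, nperm = 9999, seed = NULL) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) stop("dissimilarity matrix is not symmetric")
    d <- stats::as.dist(d)
  }
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("each group needs at least two members")
  bd <- vegan::betadisper(d, groups, type = "centroid")
  dists <- bd$distances
  out <- list(
    distances = data.frame(sample = names(dists), group = groups,
                           distance = unname(dists), stringsAsFactors = FALSE),
    group_means = tapply(dists, groups, mean),
    nperm = nperm, seed = seed
  )
  if (nlevels(groups) == 2) {
    g <- as.integer(groups)
    tstat <- function(lab) {
      a <- dists[lab == 1]; b <- dists[lab == 2]
      sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
                   (length(a) + length(b) - 2))
      (mean(a) - mean(b)) / (sp * sqrt(1 / length(a) + 1 / length(b)))
    }
    obs <- tstat(g)
    if (!is.null(seed)) set.seed(seed)
    perm <- replicate(nperm, tstat(sample(g)))
    out$t_statistic <- obs
    out$p_permutation <- (1 + sum(abs(perm) >= abs(obs))) / (nperm + 1)
    out$p_mann_whitney <- suppressWarnings(
      stats::wilcox.test(dists[g == 1], dists[g == 2])$p.value)
  }
  out
}
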
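test_that("Morisita dissimilarity matches hand computation", {
  expect_equal(morisita_dissimilarity(c(10, 0), c(0, 10)), 1)     # disjoint
  expect_equal(morisita_dissimilarity(c(2, 0), c(2, 0)), 0)       # identical
  # x = y = (5,5): lambda = 4/9 each, C = 100 / ((8/9)*100) = 1.125
  expect_equal(morisita_dissimilarity(c(5, 5), c(5, 5)), -0.125)
  expect_error(morisita_dissimilarity(c(1.5, 1), c(1, 1)), "integer")
  expect_error(morisita_dissimilarity(c(1, 0), c(5, 5)), "at least 2")
  # symmetry
  x <- c(4, 1, 0, 7); y <- c(2, 2, 3, 1)
  expect_equal(morisita_dissimilarity(x, y), morisita_dissimilarity(y, x))
})

test_that("Morisita agrees with vegan on non-negative cases", {
  set.seed(3)
  for (rep in 1:20) {
    x <- rpois(6, 8); y <- rpois(6, 8)
    if (sum(x) < 2 || sum(y) < 2) next
    ours <- morisita_dissimilarity(x, y)
    ref <- as.numeric(vegan::vegdist(rbind(x, y), method = "morisita"))
    if (ours >= 0) expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("Morisita is nearly independent of sample size", {
  # x versus k*x: the dissimilarity shrinks toward 0 as totals grow; with
  # large base counts the residual (a finite-count artifact of the
  # lambda denominator) is negligible
  x <- c(80, 30, 10, 0, 60)
  d <- vapply(c(2, 10, 100), function(k) {
    abs(morisita_dissimilarity(x, k * x))
  }, numeric(1))
  expect_true(all(diff(d) < 0))
  expect_lt(d[3], 0.01)
  # contrast: halving depth changes Bray-Curtis-style raw overlap a lot,
  # Morisita barely moves
  expect_lt(abs(morisita_dissimilarity(x, 5 * x) -
                  morisita_dissimilarity(x, 50 * x)), 0.01)
})

test_that("rarefaction matches exhaustive subset enumeration for small N", {
  cases <- list(list(c(2, 1), 2), list(c(2, 1), 1), list(c(5, 3, 2), 4),
                list(c(4, 4, 2, 1), 6), list(c(6, 3, 1), 5))
  for (cs in cases) {
    oracle <- rarefaction_oracle(cs[[1]], cs[[2]])
    got <- rarefy_richness(cs[[1]], cs[[2]])
    expect_equal(got$expected_richness, oracle$mean, tolerance = 1e-8)
    expect_equal(got$standard_error, oracle$sd, tolerance = 1e-6)
  }
  # hand value: counts (2,1), n = 2 -> mean richness 5/3
  expect_equal(rarefy_richness(c(2, 1), 2)$expected_richness, 5 / 3)
})

test_that("rarefaction boundary behaviour", {
  expect_equal(rarefy_richness(c(4, 3, 2), 9)$expected_richness, 3)
  expect_equal(rarefy_richness(c(4, 3, 2), 9)$standard_error, 0,
               tolerance = 1e-6)
  expect_equal(rarefy_richness(c(4, 3, 2), 1)$expected_richness, 1)
  expect_error(rarefy_richness(c(4, 3), 8), "exceeds")
  expect_error(rarefy_richness(c(4, 3), 0), "positive")
})

test_that("accumulation curves are monotone and include the full depth", {
  cv <- accumulation_curve(c(2, 1), step = 1)
  expect_equal(cv$expected_richness, c(1, 5 / 3, 2))
  set.seed(5)
  counts <- rpois(12, 4) + 1
  cv2 <- accumulation_curve(counts, step = 7)
  expect_true(all(diff(cv2$expected_richness) >= -1e-12))
  expect_equal(cv2$n_subsampled[nrow(cv2)], sum(counts))
  # single-taxon vector gives a flat curve at 1
  flat <- accumulation_curve(c(30), step = 10)
  expect_true(all(flat$expected_richness == 1))
})

test_that("grab replicates pool by event; composites pass through", {
  x <- small_count_matrix()
  pooled <- pool_grab_replicates(x)
  expect_equal(nrow(pooled$counts), 3)      # 2 composite + 1 grab event
  expect_equal(unname(pooled$counts["B_0", "Salmo"]), 4L + 5L + 6L)
  expect_equal(unname(pooled$counts["A_0", "Salmo"]), 10L)
  # unequal replicate sets (a missing bottle): still pooled, with a warning
  x2 <- small_count_matrix()
  x2$sample_meta$time_min[5] <- 720L   # sets of size 2 and 1
  rownames(x2$counts)[5] <- rownames(x2$sample_meta)[5] <- "B_720(3)"
  expect_warning(p2 <- pool_grab_replicates(x2), "unequal")
  expect_equal(unname(p2$counts["B_0", "Salmo"]), 4L + 5L)
})

test_that("time matching pairs composites with grab events within tolerance", {
  counts <- rbind("A_720" = c(5L, 5L), "A_900" = c(4L, 4L),
                  "B_720(1)" = c(2L, 2L), "B_720(2)" = c(3L, 1L))
  colnames(counts) <- c("t1", "t2")
  meta <- data.frame(sample = rownames(counts),
                     sampler = c("A", "A", "B", "B"),
                     site = "downstream",
                     method = c("composite", "composite", "grab", "grab"),
                     time_min = c(720L, 900L, 720L, 720L),
                     replicate = c(NA, NA, 1L, 2L))
  x <- count_matrix(counts, meta)
  pr <- time_match_pairs(x)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$composite, "A_720")
  expect_true("A_900" %in% attr(pr, "unpaired"))

  # jittered time: tolerance 0 loses the pair, tolerance 1 keeps it
  meta2 <- meta; meta2$time_min[3:4] <- 721L
  x2 <- count_matrix(counts, meta2)
  expect_equal(nrow(time_match_pairs(x2, tolerance_min = 0)), 0)
  expect_equal(nrow(time_match_pairs(x2, tolerance_min = 1)), 1)

  # two grab events inside the tolerance is ambiguous
  meta3 <- meta
  meta3$method <- c("composite", "grab", "grab", "grab")
  meta3$sampler <- c("A", "B", "B", "B")
  meta3$time_min <- c(720L, 720L, 721L, 721L)
  x3 <- count_matrix(counts, meta3)
  expect_error(suppressWarnings(time_match_pairs(x3, tolerance_min = 1)),
               "tighten")
})

test_that("parity trimming drops floor/ceil from start/end: 22->15 and 22->18", {
  idx <- 1:22
  expect_equal(parity_trim_indices(idx, 15), 4:18)   # drop first 3, last 4
  expect_equal(parity_trim_indices(idx, 18), 3:20)   # drop first 2, last 2
  expect_equal(parity_trim_indices(idx, 22), idx)
  expect_error(parity_trim_indices(1:3, 5), "cannot trim")
})

test_that("detection rates divide detections by trimmed sample counts", {
  n_comp <- 8; n_grab <- 4
  counts <- matrix(0L, n_comp + n_grab, 2,
                   dimnames = list(c(sprintf("A_%d", (1:n_comp) * 10),
                                     sprintf("B_%d(1)", (1:n_grab) * 10)),
                                   c("tax1", "tax2")))
  counts[1, 1] <- 5L      # detection in a composite sample that gets trimmed
  counts[4:6, 1] <- 2L    # three detections surviving the trim
  counts[9, 2] <- 1L
  meta <- data.frame(sample = rownames(counts),
                     sampler = rep(c("A", "B"), c(n_comp, n_grab)),
                     site = "downstream",
                     method = rep(c("composite", "grab"), c(n_comp, n_grab)),
                     time_min = c((1:n_comp) * 10L, (1:n_grab) * 10L),
                     replicate = NA_integer_)
  x <- count_matrix(counts, meta)
  dr <- detection_rates(x)
  # trim 8 -> 4: drop first 2 and last 2 composites; rows 3..6 remain
  expect_equal(dr$n, rep(4L, 4))
  expect_equal(dr$rate[dr$taxon == "tax1" & dr$method == "composite"], 3 / 4)
  expect_equal(dr$rate[dr$taxon == "tax2" & dr$method == "grab"], 1 / 4)
  expect_true(all(dr$rate >= 0 & dr$rate <= 1))
  # untrimmed: composite denominator is the full 8
  dr2 <- detection_rates(x, parity_trim = FALSE)
  expect_equal(unique(dr2$n[dr2$method == "composite"]), 8L)
  expect_equal(dr2$rate[dr2$taxon == "tax1" & dr2$method == "composite"], 4 / 8)
})

test_that("dispersion distances from Euclidean input equal plain geometry", {
  set.seed(9)
  pts <- rbind(matrix(rnorm(10 * 2), 10), matrix(rnorm(8 * 2, mean = 3), 8))
  rownames(pts) <- paste0("s", 1:18)
  grp <- rep(c("g1", "g2"), c(10, 8))
  D <- dist(pts)
  res <- dispersion_to_centroid(D, grp, nperm = 99, seed = 1)
  for (g in c("g1", "g2")) {
    ctr <- colMeans(pts[grp == g, ])
    geo <- sqrt(rowSums(sweep(pts[grp == g, ], 2, ctr)^2))
    expect_equal(res$distances$distance[res$distances$group == g],
                 unname(geo), tolerance = 1e-8)
  }
  # identical samples within a group -> zero distances
  same <- rbind(matrix(1, 3, 2), matrix(rnorm(6), 3))
  rownames(same) <- paste0("s", 1:6)
  res2 <- dispersion_to_centroid(dist(same), rep(c("a", "b"), each = 3),
                                 nperm = 99, seed = 1)
  expect_equal(res2$distances$distance[res2$distances$group == "a"], rep(0, 3))
})

test_that("dispersion test input validation and label invariance", {
  set.seed(11)
  pts <- matrix(rnorm(12 * 2), 12)
  rownames(pts) <- paste0("s", 1:12)
  D <- dist(pts)
  grp <- rep(c("a", "b"), each = 6)
  res <- dispersion_to_centroid(D, grp, nperm = 199, seed = 2)
  # permuting group labels leaves the pooled distance multiset unchanged
  res_swap <- dispersion_to_centroid(D, rev(grp), nperm = 199, seed = 2)
  expect_equal(sort(res$distances$distance), sort(res_swap$distances$distance),
               tolerance = 1e-8)
  expect_error(dispersion_to_centroid(D, rep("a", 12)), "two groups")
  expect_error(dispersion_to_centroid(D, c("a", rep("b", 11))), "two members")
  asym <- matrix(runif(16), 4); rownames(asym) <- colnames(asym) <- paste0("s", 1:4)
  expect_error(dispersion_to_centroid(asym, rep(c("a", "b"), 2)), "symmetric")
})

test_that("permutation p-values are calibrated under the null", {
  set.seed(21)
  ps <- replicate(120, {
    pts <- matrix(rnorm(14 * 2), 14)
    rownames(pts) <- paste0("s", 1:14)
    dispersion_to_centroid(dist(pts), rep(c("a", "b"), each = 7),
                           nperm = 99)$p_permutation
  })
  # uniform within Monte-Carlo error: mean near 0.5, few small values
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.62)
  expect_lt(mean(ps < 0.05), 0.15)
})
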
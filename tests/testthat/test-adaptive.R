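test_that("the scan recovers an exact linear signal", {
  map <- toy_map(4, spacing = 30)
  g <- simulate_f2(40, map, seed = 21)
  y <- toy_pheno(2 * g$m00002, ids = g$id)
  scan <- single_marker_scan(g, y)
  expect_equal(scan$estimate[2], 2, tolerance = 1e-12)
  expect_equal(scan$se[2], 0, tolerance = 1e-8)
})

test_that("scan estimates are unbiased under the null", {
  map <- toy_map(3, spacing = 50)
  g <- simulate_f2(30, map, seed = 22)
  b <- replicate(200, {
    y <- toy_pheno(rnorm(30), ids = g$id)
    single_marker_scan(g, y)$estimate
  })
  se_mean <- apply(b, 1, sd) / sqrt(200)
  expect_true(all(abs(rowMeans(b)) < 3 * se_mean))
})

test_that("scan matches the closed-form simple-regression oracle", {
  set.seed(23)
  M <- matrix(sample(c(-1, 0, 1), 100, replace = TRUE), 20, 5)
  g <- toy_geno(M)
  y <- rnorm(20)
  scan <- single_marker_scan(g, toy_pheno(y))
  for (j in 1:5) {
    o <- ols_simple(M[, j], y)
    expect_equal(scan$estimate[j], o$b, tolerance = 1e-12)
    expect_equal(scan$se[j], o$se, tolerance = 1e-12)
    # LOD from the Wald form W = (b/se)^2
    expect_equal(scan$lod[j], (o$b / o$se)^2 / (2 * log(10)), tolerance = 1e-10)
  }
})

test_that("zero-variance markers are flagged with zero estimate", {
  M <- cbind(rep(1, 15), sample(c(-1, 0, 1), 15, replace = TRUE))
  g <- toy_geno(M)
  scan <- single_marker_scan(g, toy_pheno(rnorm(15)))
  expect_true(scan$zero_var[1])
  expect_equal(scan$estimate[1], 0)
})

test_that("weights normalize to unit mean absolute value per bin", {
  map <- toy_map(3)
  part <- one_bin(map)
  scan <- tibble::tibble(marker_id = map$marker_id,
                         estimate = c(2, -1, 1), se = 1, lod = 1,
                         zero_var = FALSE)
  w <- compute_weights(scan, part)
  expect_equal(w$weight, c(1.5, -0.75, 0.75))
  expect_equal(w$bin_mean_abs, rep(4 / 3, 3))

  # all-equal estimates reduce to the unweighted average
  scan$estimate <- rep(2.5, 3)
  expect_equal(compute_weights(scan, part)$weight, rep(1, 3))

  # sum |w| = p_k on random estimate vectors
  set.seed(24)
  for (i in 1:20) {
    scan$estimate <- rnorm(3)
    expect_equal(sum(abs(compute_weights(scan, part)$weight)), 3,
                 tolerance = 1e-12)
  }

  # numerically null bin gets all-zero weights
  scan$estimate <- rep(1e-14, 3)
  expect_equal(compute_weights(scan, part)$weight, rep(0, 3))
})

test_that("weighted scores reduce to bin averages at unit weights", {
  map <- toy_map(6, spacing = 2)
  g <- simulate_f2(15, map, seed = 25)
  part <- make_bins(map, 5, "cM")
  w <- compute_weights(
    tibble::tibble(marker_id = map$marker_id, estimate = 1, se = 1,
                   lod = 0, zero_var = FALSE), part)
  expect_equal(as.matrix(weighted_bin_score(g, part, w)[-1]),
               as.matrix(bin_average(g, part)[-1]))
})

test_that("weighted score arithmetic is the weighted within-bin mean", {
  g <- toy_geno(matrix(c(1, -1, 0), 1, 3))
  map <- toy_map(3)
  part <- one_bin(map)
  scan <- tibble::tibble(marker_id = map$marker_id, estimate = c(2, -1, 1),
                         se = 1, lod = 1, zero_var = FALSE)
  s <- weighted_bin_score(g, part, compute_weights(scan, part))
  expect_equal(s[[2]], (1.5 * 1 + (-0.75) * (-1) + 0.75 * 0) / 3)
})

test_that("the adaptive pipeline is invariant to allele-coding flips", {
  map <- toy_map(9, spacing = 3)
  g <- simulate_f2(60, map, seed = 26)
  y <- toy_pheno(rnorm(60, sd = 2), ids = g$id)
  part <- make_bins(map, 10, "cM")
  score <- function(geno) {
    w <- compute_weights(single_marker_scan(geno, y), part)
    as.matrix(weighted_bin_score(geno, part, w)[-1])
  }
  flipped <- g
  for (j in c(2, 5, 9)) flipped[[j + 1]] <- -flipped[[j + 1]]
  expect_equal(score(flipped), score(g), tolerance = 1e-12)
})

test_that("adaptive scores homogenize mixed-sign effects without LD", {
  # one bin of 10 unlinked markers with equal-magnitude, alternating-sign
  # effects: the unweighted average cancels, the adaptive score does not
  map <- toy_map(10, spacing = 1e6)
  a <- rep(c(1, -1), 5)
  wins <- 0
  for (s in 1:50) {
    g <- simulate_f2(2000, map, seed = 100 + s)
    M <- as.matrix(g[-1])
    gval <- drop(M %*% a)
    y <- toy_pheno(gval + rnorm(2000), ids = g$id)
    part <- one_bin(map)
    w <- compute_weights(single_marker_scan(g, y), part)
    ada <- weighted_bin_score(g, part, w)[[2]]
    unw <- bin_average(g, part)[[2]]
    wins <- wins + (cor(ada, gval)^2 > cor(unw, gval)^2)
  }
  expect_lt(binom.test(wins, 50, alternative = "greater")$p.value, 0.01)
})

test_that("single-marker bins give identical adaptive and unweighted fits", {
  map <- toy_map(8, spacing = 12)
  g <- simulate_f2(80, map, seed = 27)
  y <- toy_pheno(g$m00003 * 1.5 + rnorm(80, sd = 0.5), ids = g$id)
  part <- make_bins(map, 1, "markers")
  w <- compute_weights(single_marker_scan(g, y), part)
  fu <- fit_bins(bin_average(g, part), y, lambda = 0)
  fa <- fit_bins(weighted_bin_score(g, part, w), y, lambda = 0)
  # same fitted values: per-column rescaling is absorbed by the effects
  expect_equal(predict(fa, weighted_bin_score(g, part, w)),
               predict(fu, bin_average(g, part)), tolerance = 1e-6)
})
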
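test_that("identical seeds give bitwise-identical datasets", {
  d <- design_preset("I", scale = 0.002, n = 50)
  a <- simulate_dataset(d, seed = 99)
  b <- simulate_dataset(d, seed = 99)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$phenotypes, b$phenotypes)
  c <- simulate_dataset(d, seed = 100)
  expect_false(identical(a$genotypes, c$genotypes))
})

test_that("F2 genotypes segregate 1:2:1 with variance 1/2", {
  map <- toy_map(5, spacing = 20)
  g <- simulate_f2(8000, map, seed = 4)
  M <- as.matrix(g[-1])
  expect_setequal(unique(as.vector(M)), c(-1, 0, 1))
  for (j in 1:5) {
    counts <- table(factor(M[, j], levels = c(-1, 0, 1)))
    p <- suppressWarnings(chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value)
    expect_gt(p, 0.001)
  }
  # marker variance 1/2 within Monte-Carlo error (SE of var ~ sqrt(2/n)/2)
  expect_equal(mean(apply(M, 2, var)), 0.5, tolerance = 0.03)
})

test_that("inter-locus correlation matches the Haldane-based F2 covariance", {
  # two markers 10 cM apart; Cov(Z_h, Z_l) = (1 - 2 r)/2, Var(Z) = 1/2,
  # so corr = 1 - 2 * haldane(10). The genotype indicator is discrete, so
  # the SE of the replicate mean comes from the replicates themselves
  # rather than a normal-theory formula.
  map <- toy_map(2, spacing = 10)
  reps <- vapply(1:10, function(s) {
    g <- simulate_f2(4000, map, seed = s)
    cor(g$m00001, g$m00002)
  }, numeric(1))
  expected <- 1 - 2 * haldane(10)
  expect_lt(abs(mean(reps) - expected), 3 * sd(reps) / sqrt(10))
})

test_that("LD decays monotonically with map distance", {
  map <- toy_map(13, spacing = 10)
  g <- simulate_f2(6000, map, seed = 6)
  M <- as.matrix(g[-1])
  cm <- cor(M)
  d <- abs(outer(map$pos_cm, map$pos_cm, "-"))
  ut <- upper.tri(d)
  bins <- cut(d[ut], breaks = seq(0, 120, by = 20))
  mean_cor <- tapply(cm[ut], bins, mean)
  expect_true(all(diff(mean_cor) < 0))
})

test_that("phenotype simulation reproduces its variance components", {
  map <- toy_map(20, spacing = 1e5) # unlinked markers
  g <- simulate_f2(10000, map, seed = 7)
  # pure noise
  d0 <- sim_design(n = 10000, genome_length = 19e5, n_markers = 20,
                   qtl = tibble::tibble(pos_cm = 0, effect = 0), sigma2_e = 4)
  ph0 <- simulate_phenotype(g, map, d0, seed = 8)
  expect_equal(var(ph0$phenotypes$value), 4, tolerance = 0.2)
  # one additive QTL with effect a and no noise: Var(y) = a^2/2
  d1 <- sim_design(n = 10000, genome_length = 19e5, n_markers = 20,
                   qtl = tibble::tibble(pos_cm = 5e5, effect = 3), sigma2_e = 0)
  ph1 <- simulate_phenotype(g, map, d1, seed = 9)
  expect_equal(var(ph1$phenotypes$value), 9 / 2, tolerance = 0.15)
  expect_equal(ph1$variance$h2_main, 1)
})

test_that("preset geometries match their stated architectures", {
  d1 <- design_preset("I", scale = 1)
  expect_equal(d1$n_markers, 120001)
  expect_equal(d1$genome_length, 2400)
  expect_equal(d1$marker_spacing, 0.02)
  expect_equal(nrow(d1$qtl), 20)
  expect_equal(nrow(d1$epistasis), 20)

  d3 <- design_preset("III", scale = 1)
  expect_equal(nrow(d3$qtl), 1000)
  expect_true(all(d3$qtl$effect[1:500] > 0))
  expect_true(all(d3$qtl$effect[501:1000] < 0))

  d4 <- design_preset("IV", scale = 1)
  expect_equal(d4$n_markers, 120001)
  expect_equal(d4$genome_length, 12e6)
  expect_equal(d4$marker_spacing, 100)
  expect_null(d4$epistasis)

  d2 <- design_preset("II", scale = 0.01)
  expect_equal(nrow(d2$qtl), 20 * 5) # 500 small QTL per cluster at scale 0.01
  expect_error(design_preset("V"), "arg")
})

test_that("realized main-effect variance matches the design target", {
  # oligogenic palette is calibrated so Var(sum a_k Z_k) = 64.12
  d <- design_preset("I", scale = 0.005, n = 10000)
  ds <- simulate_dataset(d, seed = 10)
  # relative MC error of a variance is ~ sqrt(2/n); allow 3 SE
  expect_equal(ds$variance$var_main, 64.12,
               tolerance = 3 * sqrt(2 / 10000) * 1.1)
  d3 <- design_preset("III", scale = 0.01, n = 8000)
  ds3 <- simulate_dataset(d3, seed = 11)
  expect_equal(ds3$variance$var_main, 81.94, tolerance = 0.05 * 81.94)
})

test_that("design IV adjacent markers are statistically independent", {
  d <- design_preset("IV", scale = 0.002, n = 4000)
  ds <- simulate_dataset(d, seed = 12)
  M <- as.matrix(ds$genotypes[-1])
  adj <- vapply(seq_len(ncol(M) - 1),
                function(j) cor(M[, j], M[, j + 1]), numeric(1))
  expect_true(mean(abs(adj) < 3 / sqrt(4000)) > 0.98)
})

test_that("QTL outside the genome is a hard error", {
  map <- toy_map(10)
  g <- simulate_f2(20, map, seed = 1)
  d <- sim_design(n = 20, genome_length = 9, n_markers = 10,
                  qtl = tibble::tibble(pos_cm = 9, effect = 1), sigma2_e = 1)
  d$qtl$pos_cm <- 500 # bypass constructor check to exercise the runtime guard
  expect_error(simulate_phenotype(g, map, d), "outside")
  expect_error(simulate_f2(5, dplyr::mutate(map, pos_cm = NA)), "genetic positions")
})
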
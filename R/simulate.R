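#' Haldane map function
#'
#' Converts a genetic map distance in centimorgans to a recombination
#' fraction assuming no crossover interference:
#' r = (1 - exp(-2 d / 100)) / 2. Under this map function the allele
#' process along a gamete is Markov, which is what makes chromosome-wide
#' simulation a simple random walk.
#'
#' @param d Map distance(s) in cM.
#' @return Recombination fraction(s) in \[0, 0.5).
#' @export
haldane <- function(d) (1 - exp(-2 * d / 100)) / 2

# F2 covariance between coded genotypes at two loci separated by map
# distance d: Cov(Z_h, Z_l) = (1 - 2 r) / 2. Re-derived from the gamete
# walk (each gamete contributes (1 - 2r)/4, gametes independent) and
# confirmed by Monte Carlo in the test suite.
f2_cov <- function(d) (1 - 2 * haldane(d)) / 2

#' Build an evenly spaced marker map
#'
#' @param genome_length Chromosome length in cM (per chromosome).
#' @param n_markers Total marker count, split evenly across chromosomes.
#' @param n_chromosomes Number of chromosomes (default 1).
#' @return A marker-map tibble with genetic positions from 0 to
#'   `genome_length` per chromosome.
#' @export
sim_map <- function(genome_length, n_markers, n_chromosomes = 1) {
  stopifnot(n_markers >= n_chromosomes, genome_length > 0)
  per <- diff(round(seq(0, n_markers, length.out = n_chromosomes + 1)))
  purrr::map2_dfr(seq_len(n_chromosomes), per, function(chr, p) {
    tibble::tibble(
      chrom = sprintf("chr%d", chr),
      pos_cm = if (p == 1) genome_length / 2 else seq(0, genome_length, length.out = p)
    )
  }) |>
    dplyr::mutate(
      marker_id = sprintf("m%05d", dplyr::row_number()),
      pos_bp = NA_real_
    ) |>
    dplyr::select("marker_id", "chrom", "pos_cm", "pos_bp")
}

#' Specify a simulation design
#'
#' Bundles everything `simulate_dataset()` needs: population size, genome
#' geometry, the QTL (genetic position in cM and additive effect in trait
#' units), optional pairwise epistatic effects, and the residual error
#' variance.
#'
#' @param n Number of F2 individuals.
#' @param genome_length Chromosome length in cM.
#' @param n_markers Total number of markers (evenly spaced).
#' @param qtl Tibble with columns `pos_cm` and `effect`.
#' @param epistasis Optional tibble with columns `pos_a`, `pos_b`, `effect`
#'   (the interaction term is effect * Z_a * Z_b).
#' @param sigma2_e Residual error variance (trait units squared).
#' @param n_chromosomes Number of chromosomes.
#' @param name Optional design label.
#' @return An object of class `sim_design`.
#' @export
sim_design <- function(n, genome_length, n_markers, qtl,
                       epistasis = NULL, sigma2_e = 1,
                       n_chromosomes = 1, name = "custom") {
  qtl <- tibble::as_tibble(qtl)
  stopifnot(n >= 1, genome_length > 0, n_markers >= 2, sigma2_e >= 0,
            all(c("pos_cm", "effect") %in% names(qtl)),
            all(qtl$pos_cm >= 0 & qtl$pos_cm <= genome_length))
  if (!is.null(epistasis)) {
    epistasis <- tibble::as_tibble(epistasis)
    stopifnot(all(c("pos_a", "pos_b", "effect") %in% names(epistasis)),
              all(unlist(epistasis[c("pos_a", "pos_b")]) >= 0),
              all(unlist(epistasis[c("pos_a", "pos_b")]) <= genome_length))
  }
  structure(
    list(n = n, genome_length = genome_length, n_markers = n_markers,
         marker_spacing = genome_length / (n_markers - 1),
         n_chromosomes = n_chromosomes, qtl = qtl, epistasis = epistasis,
         sigma2_e = sigma2_e, name = name),
    class = "sim_design"
  )
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf(
    "<sim_design '%s'> n = %d, genome %.6g cM, %d markers (%.4g cM apart),\n  %d QTL, %d epistatic pairs, sigma2_e = %.4g\n",
    x$name, x$n, x$genome_length, x$n_markers, x$marker_spacing,
    nrow(x$qtl), if (is.null(x$epistasis)) 0L else nrow(x$epistasis),
    x$sigma2_e))
  invisible(x)
}

# Default variance-share palette for the 20-QTL oligogenic architectures:
# one major QTL (15% of phenotypic variance at the reference error level),
# a handful of medium QTL, and a tail of minor ones around 1%. Signs
# alternate so adjacent effects point in opposite directions.
oligogenic_palette <- function() {
  prop <- c(0.15, 0.08, 0.05, 0.04, 0.03, 0.025,
            rep(0.02, 4), rep(0.015, 4), rep(0.01, 6))
  sign <- rep_len(c(1, -1), length(prop))
  sign * sqrt(2 * prop * 110.64)
}

# Analytic variance of a sum of additive F2 QTL effects:
# Var(sum a_k Z_k) = a' C a with C_kl = (1 - 2 r_kl)/2, r from Haldane.
qtl_additive_variance <- function(pos, effect) {
  C <- f2_cov(abs(outer(pos, pos, "-")))
  drop(effect %*% C %*% effect)
}

#' Preset simulation designs
#'
#' Four trait architectures on a single large chromosome, scalable for
#' quick experiments:
#' \describe{
#'   \item{I}{Oligogenic, high LD: 2400 cM, 120,001 markers (0.02 cM
#'     spacing), 20 additive QTL calibrated to a main-effect variance of
#'     64.12, plus 20 pairwise epistatic effects contributing 26.52;
#'     residual error variance one of 10, 20, 40, 100.}
#'   \item{II}{Clustered polygenic: each of the 20 QTL is split into 500
#'     equal small QTL within +/- 5 cM of its position; total genetic
#'     variance 81.94; no epistasis; error variance 10, 20, 50 or 100.}
#'   \item{III}{Uniform polygenic: 1000 QTL evenly placed, each carrying
#'     1/1000 of the genetic variance 81.94; the first half have positive
#'     effects, the second half negative; no epistasis.}
#'   \item{IV}{Oligogenic, no LD: genome expanded to 12,000,000 cM with
#'     100 cM marker spacing (adjacent markers essentially unlinked); the
#'     20 QTL of design I without epistasis; default n = 1000.}
#' }
#' `scale` multiplies the marker count (and, for designs II/III, the QTL
#' count) while preserving the architecture; genome length, variance
#' targets and error variance are unchanged.
#'
#' @param name One of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @param scale Shrink factor in (0, 1].
#' @param n Population size (defaults: 500 for I-III, 1000 for IV).
#' @param sigma2_e Residual error variance (default 20).
#' @param seed Seed for the design-III effect draw.
#' @return A `sim_design`.
#' @export
design_preset <- function(name = c("I", "II", "III", "IV"), scale = 1,
                          n = NULL, sigma2_e = 20, seed = 1) {
  name <- match.arg(name)
  stopifnot(scale > 0, scale <= 1)
  p <- max(2L, round(120001 * scale))
  if (name %in% c("I", "II", "III")) {
    L <- 2400
    centers <- seq(60, 2340, length.out = 20)
  } else {
    L <- 12e6
    centers <- seq(3e5, L - 3e5, length.out = 20)
  }
  if (is.null(n)) n <- if (name == "IV") 1000 else 500

  if (name == "I" || name == "IV") {
    a <- oligogenic_palette()
    a <- a * sqrt(64.12 / qtl_additive_variance(centers, a))
    qtl <- tibble::tibble(pos_cm = centers, effect = a)
    epi <- NULL
    if (name == "I") {
      ia <- rep(1:10, 2)
      ib <- c(11:20, 8:17)
      g <- rep_len(c(1, -1), 20) * sqrt(4 * 26.52 / 20)
      epi <- tibble::tibble(pos_a = centers[ia], pos_b = centers[ib], effect = g)
    }
  } else if (name == "II") {
    k_small <- max(1L, round(500 * scale))
    prop <- abs(oligogenic_palette())^2 / 2          # cluster variance shares
    prop <- prop / sum(prop)
    cl_pos <- lapply(centers, function(ctr) {
      pmin(pmax(seq(ctr - 5, ctr + 5, length.out = k_small), 0), 2400)
    })
    # per-cluster equal effects solving a^2 * S = share * 81.94, where S is
    # the within-cluster covariance sum; between-cluster covariance is then
    # folded in via cluster totals and a joint rescale
    S <- vapply(cl_pos, function(ps) qtl_additive_variance(ps, rep(1, length(ps))),
                numeric(1))
    a_cl <- rep_len(c(1, -1), 20) * sqrt(prop * 81.94 / S)
    tot <- a_cl * k_small
    Ccl <- f2_cov(abs(outer(centers, centers, "-")))
    diag(Ccl) <- 0
    v_between <- sum(outer(tot, tot) * Ccl)
    v_within <- sum(a_cl^2 * S)
    resc <- sqrt(81.94 / (v_within + v_between))
    qtl <- tibble::tibble(
      pos_cm = unlist(cl_pos),
      effect = rep(a_cl * resc, each = k_small)
    )
    epi <- NULL
  } else { # III
    q <- max(2L, 2L * round(500 * scale))
    pos <- seq(L / (2 * q), L - L / (2 * q), length.out = q)
    set.seed(seed)
    mag <- abs(rnorm(q))
    mag <- mag / sqrt(mean(mag^2))                   # unit mean square
    eff <- c(mag[seq_len(q / 2)], -mag[(q / 2 + 1):q])
    eff <- eff * sqrt(81.94 / qtl_additive_variance(pos, eff))
    qtl <- tibble::tibble(pos_cm = pos, effect = eff)
    epi <- NULL
  }
  sim_design(n = n, genome_length = L, n_markers = p, qtl = qtl,
             epistasis = epi, sigma2_e = sigma2_e,
             name = paste0("design-", name))
}

#' Simulate F2 genotypes
#'
#' Each individual receives two independent gametes. A gamete is a Markov
#' walk along each chromosome: the allele at the first marker is
#' Bernoulli(1/2), and the allele at each subsequent marker flips with
#' probability equal to the Haldane recombination fraction of the
#' inter-marker distance. The genotype is the sum of the two gamete
#' alleles recoded to the F2 scale (-1, 0, +1), which has variance 1/2
#' and inter-locus covariance (1 - 2r)/2.
#'
#' @param n Number of individuals.
#' @param map Marker map with genetic positions (`pos_cm`).
#' @param seed Integer seed; the output is fully reproducible.
#' @return A genotype tibble (`id` + one column per marker).
#' @export
simulate_f2 <- function(n, map, seed = 1) {
  if (anyNA(map$pos_cm)) {
    stop("simulate_f2() needs genetic positions (pos_cm) for every marker",
         call. = FALSE)
  }
  stopifnot(n >= 1)
  set.seed(seed)
  chroms <- unique(map$chrom)
  M <- matrix(NA_real_, n, nrow(map))
  for (ch in chroms) {
    idx <- which(map$chrom == ch)
    r <- haldane(diff(map$pos_cm[idx]))
    g <- sim_gamete(n, r) + sim_gamete(n, r)
    M[, idx] <- g - 1
  }
  geno_tbl(sprintf("ind%05d", seq_len(n)), M, map$marker_id)
}

# one gamete: n x p matrix of 0/1 alleles, Markov walk with flip probs r
sim_gamete <- function(n, r) {
  p <- length(r) + 1L
  A <- matrix(0L, n, p)
  A[, 1] <- rbinom(n, 1L, 0.5)
  for (j in seq_len(p - 1L)) {
    A[, j + 1L] <- (A[, j] + (runif(n) < r[j])) %% 2L
  }
  A
}

#' Simulate phenotypes from a trait architecture
#'
#' Computes y_j = sum_k a_k Z_{j,k*} + sum_(a,b) g_ab Z_{j,a*} Z_{j,b*} +
#' e_j, where each QTL is anchored to the nearest marker column (ties
#' broken toward the lower index) and e_j ~ Normal(0, sigma2_e).
#'
#' @param geno Genotype tibble from [simulate_f2()].
#' @param map Marker map paired with `geno`.
#' @param design A `sim_design`.
#' @param seed Seed for the residual draw.
#' @return A list: `phenotypes` (tibble `id`, `value`), `qtl` (the design
#'   QTL with anchored `marker_id`/`marker_index`), and `variance`, a
#'   one-row tibble of realized main-effect variance, realized epistatic
#'   variance, `sigma2_e`, realized var(y), and the heritability of the
#'   main effects `h2_main` (see [h2_components()]).
#' @export
simulate_phenotype <- function(geno, map, design, seed = 1) {
  check_geno_map(geno, map)
  if (any(design$qtl$pos_cm > max(map$pos_cm) + design$marker_spacing)) {
    stop("QTL position outside the mapped genome", call. = FALSE)
  }
  M <- geno_matrix(geno)
  n <- nrow(M)
  anchor <- nearest_marker(design$qtl$pos_cm, map$pos_cm)
  g_main <- drop(M[, anchor, drop = FALSE] %*% design$qtl$effect)
  g_epi <- 0
  if (!is.null(design$epistasis) && nrow(design$epistasis)) {
    ia <- nearest_marker(design$epistasis$pos_a, map$pos_cm)
    ib <- nearest_marker(design$epistasis$pos_b, map$pos_cm)
    g_epi <- drop((M[, ia, drop = FALSE] * M[, ib, drop = FALSE]) %*%
                    design$epistasis$effect)
  }
  set.seed(seed)
  e <- rnorm(n, 0, sqrt(design$sigma2_e))
  y <- g_main + g_epi + e
  var_main <- var(g_main)
  var_epi <- if (length(g_epi) > 1) var(g_epi) else 0
  list(
    phenotypes = tibble::tibble(id = geno$id, value = y),
    qtl = dplyr::mutate(design$qtl,
                        marker_index = anchor,
                        marker_id = map$marker_id[anchor]),
    variance = tibble::tibble(
      var_main = var_main, var_epi = var_epi, sigma2_e = design$sigma2_e,
      var_y = var(y),
      h2_main = h2_components(var_main, var_epi, design$sigma2_e)
    )
  )
}

#' Heritability from variance components
#'
#' Proportion of the phenotypic variance contributed by the additive main
#' effects: var_main / (var_main + var_epi + sigma2_e). With the
#' architecture variances of the preset designs this reproduces the four
#' standard heritability levels of each design (e.g. 0.64, 0.58, 0.49,
#' 0.34 for the oligogenic design at error variances 10, 20, 40, 100).
#'
#' @param var_main Additive main-effect variance.
#' @param var_epi Epistatic variance (default 0).
#' @param sigma2_e Residual error variance.
#' @return Heritability in \[0, 1\].
#' @export
h2_components <- function(var_main, var_epi = 0, sigma2_e) {
  var_main / (var_main + var_epi + sigma2_e)
}

#' Simulate a complete dataset
#'
#' Builds the marker map, F2 genotypes and phenotypes for a design in one
#' call. All randomness flows from `seed`; identical seeds give
#' bitwise-identical datasets.
#'
#' @param design A `sim_design` (see [design_preset()]).
#' @param seed Integer seed.
#' @return A list of class `sim_dataset`: `map`, `genotypes`,
#'   `phenotypes`, `qtl`, `variance`, `design`, `seed`.
#' @export
simulate_dataset <- function(design, seed = 1) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, 2L)
  map <- sim_map(design$genome_length, design$n_markers, design$n_chromosomes)
  geno <- simulate_f2(design$n, map, seed = sub[1])
  ph <- simulate_phenotype(geno, map, design, seed = sub[2])
  structure(
    list(map = map, genotypes = geno, phenotypes = ph$phenotypes,
         qtl = ph$qtl, variance = ph$variance, design = design, seed = seed),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d individuals x %d markers (%s)\n",
              nrow(x$genotypes), nrow(x$map), x$design$name))
  print(x$variance)
  invisible(x)
}

# nearest marker index for each position; ties toward the lower index
nearest_marker <- function(pos, marker_pos) {
  vapply(pos, function(p) {
    d <- abs(marker_pos - p)
    which(d == min(d))[1]
  }, integer(1))
}
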
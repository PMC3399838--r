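#' k-fold cross-validated prediction error
#'
#' Individuals are randomly partitioned into k near-equal folds (sizes
#' differ by at most one, seeded shuffle). For each fold, `builder` is
#' given only the training complement -- so every data-dependent step
#' (single-marker scan, weights, penalty selection, fitting) runs inside
#' the training fold -- and must return a prediction function, which is
#' then applied to the held-out individuals. MSE is the mean squared
#' out-of-fold prediction error over all individuals.
#'
#' @param geno Genotype tibble (imputed).
#' @param pheno Phenotype tibble (`id`, `value`) aligned with `geno`.
#' @param builder A function `(geno_train, pheno_train)` returning a
#'   function `(geno_new) -> numeric` of predictions. See
#'   [bin_model_builder()].
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param folds Optional precomputed fold assignment (integer vector in
#'   1..k, one per individual); overrides `k`/`seed` partitioning so that
#'   several model variants can share the same folds.
#' @return A tibble of class `cv_result` with columns `id`, `fold`,
#'   `value`, `pred`; attributes `mse`, `fold_mse`, `var_y`, `r2`,
#'   `r2_clipped`, `k`, `seed`.
#' @export
kfold_cv <- function(geno, pheno, builder, k = 10, seed = 1, folds = NULL) {
  y <- align_pheno(pheno, geno$id)
  n <- length(y)
  if (is.null(folds)) folds <- make_folds(n, k, seed)
  stopifnot(length(folds) == n)
  k <- max(folds)
  if (min(tabulate(folds, k)) < 2) {
    stop("every fold needs at least 2 individuals", call. = FALSE)
  }
  pred <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    tr <- folds != f
    model <- builder(geno[tr, , drop = FALSE],
                     tibble::tibble(id = geno$id[tr], value = y[tr]))
    pred[!tr] <- model(geno[!tr, , drop = FALSE])
  }
  mse <- mean((y - pred)^2)
  fold_mse <- vapply(seq_len(k),
                     function(f) mean((y - pred)[folds == f]^2), numeric(1))
  var_y <- var(y)
  pr <- predictability(mse, var_y)
  out <- tibble::tibble(id = geno$id, fold = folds, value = y, pred = pred)
  structure(out, mse = mse, fold_mse = fold_mse, var_y = var_y,
            r2 = pr$r2, r2_clipped = pr$r2_clipped, k = k, seed = seed,
            class = c("cv_result", class(tibble::tibble())))
}

#' @rdname kfold_cv
#' @param x A `cv_result`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    mse = attr(x, "mse"),
    mse_se = sd(attr(x, "fold_mse")) / sqrt(attr(x, "k")),
    var_y = attr(x, "var_y"),
    r2 = attr(x, "r2"),
    r2_clipped = attr(x, "r2_clipped"),
    k = attr(x, "k")
  )
}

#' Predictability from cross-validated MSE
#'
#' R^2 = 1 - MSE / var_y: the proportion of the phenotypic variance
#' predicted out of sample by the model, where `var_y` is the sample
#' variance of the (covariate-adjusted) phenotype. An MSE at or above the
#' phenotypic variance means no predictability, so the clipped value
#' max(0, R^2) is reported alongside.
#'
#' @param mse Cross-validated mean squared error(s).
#' @param var_y Phenotypic variance on the same scale.
#' @return A tibble with columns `r2` and `r2_clipped`.
#' @export
predictability <- function(mse, var_y) {
  stopifnot(all(var_y > 0))
  r2 <- 1 - mse / var_y
  tibble::tibble(r2 = r2, r2_clipped = pmax(0, r2))
}

#' Standard bin-model builder for cross-validation
#'
#' Packages the full covariate-construction + fitting pipeline as a
#' builder for [kfold_cv()]. In `"adaptive"` mode with
#' `weights = "fold"` (the default) the single-marker scan and weights
#' are recomputed from each training fold, so no held-out information
#' reaches the covariates; `weights = "whole"` reuses a whole-data scan
#' (supply `whole_scan`), a compatibility mode that leaks the test fold
#' into the weights but mirrors a common practice of weighting once from
#' the full sample.
#'
#' @param map Marker map (the builder closes over it).
#' @param bin_size,unit Passed to [make_bins()].
#' @param mode `"unweighted"` or `"adaptive"`.
#' @param lambda `"cv"` or a fixed penalty value, passed to [fit_bins()].
#' @param weights `"fold"` or `"whole"` (adaptive mode only).
#' @param whole_scan A `marker_scan` on the full data, required when
#'   `weights = "whole"`.
#' @param nfolds,seed Internal lambda-selection controls.
#' @return A builder function for [kfold_cv()].
#' @export
bin_model_builder <- function(map, bin_size, unit = "cM",
                              mode = c("unweighted", "adaptive"),
                              lambda = "cv",
                              weights = c("fold", "whole"),
                              whole_scan = NULL, nfolds = 10, seed = 1) {
  mode <- match.arg(mode)
  weights <- match.arg(weights)
  if (weights == "whole" && mode == "adaptive" && is.null(whole_scan)) {
    stop("weights = 'whole' needs a whole-data marker scan (whole_scan)",
         call. = FALSE)
  }
  part <- make_bins(map, bin_size, unit)
  function(geno_tr, pheno_tr) {
    if (mode == "unweighted") {
      feats <- bin_average(geno_tr, part)
      featurize <- function(g) bin_average(g, part)
    } else {
      scan <- if (weights == "whole") whole_scan
              else single_marker_scan(geno_tr, pheno_tr)
      w <- compute_weights(scan, part)
      feats <- weighted_bin_score(geno_tr, part, w)
      featurize <- function(g) weighted_bin_score(g, part, w)
    }
    fit <- suppressWarnings(
      fit_bins(feats, pheno_tr, lambda = lambda, nfolds = nfolds, seed = seed))
    function(geno_new) predict(fit, featurize(geno_new))
  }
}

#' Scan bin sizes for the optimum predictability
#'
#' Runs [kfold_cv()] for every requested (bin size, mode) combination
#' with a shared fold partition, so MSE differences between entries are
#' paired. With `lambda = "pretune"` the penalty for each combination is
#' selected once by cross-validation on the full data and then held fixed
#' across the outer folds (the classical predetermined-lambda protocol);
#' `lambda = "cv"` reselects it inside every training fold.
#'
#' @param geno,pheno Imputed genotypes and aligned phenotypes.
#' @param map Marker map.
#' @param sizes Numeric vector of bin sizes to scan.
#' @param unit Bin-size unit (see [make_bins()]).
#' @param modes Subset of `c("unweighted", "adaptive")`.
#' @param k,seed Outer cross-validation controls.
#' @param lambda `"pretune"`, `"cv"`, or a fixed value.
#' @param weights `"fold"` or `"whole"` weighting for the adaptive mode.
#' @return A tibble of class `bin_size_profile`: one row per
#'   (size, mode) with `m` (bins), `m_used` (nonempty), `mse`, `mse_se`
#'   (between-fold standard error), `r2`, `r2_clipped`, `lambda`;
#'   attributes `best` (minimum-MSE row), `within_1se` (rows within one
#'   standard error of the minimum) and `var_y`.
#' @export
scan_bin_sizes <- function(geno, map, pheno, sizes, unit = "cM",
                           modes = c("unweighted", "adaptive"),
                           k = 10, seed = 1, lambda = "pretune",
                           weights = c("fold", "whole")) {
  stopifnot(length(sizes) >= 1)
  modes <- match.arg(modes, several.ok = TRUE)
  weights <- match.arg(weights)
  y <- align_pheno(pheno, geno$id)
  folds <- make_folds(length(y), k, seed)
  whole_scan <- if ("adaptive" %in% modes) single_marker_scan(geno, pheno)
  grid <- tidyr::expand_grid(bin_size = sizes, mode = modes)

  rows <- purrr::pmap_dfr(grid, function(bin_size, mode) {
    part <- make_bins(map, bin_size, unit)
    lam <- lambda
    if (identical(lambda, "pretune")) {
      feats <- if (mode == "unweighted") bin_average(geno, part)
               else weighted_bin_score(geno, part,
                                       compute_weights(whole_scan, part))
      lam <- suppressWarnings(
        fit_bins(feats, pheno, lambda = "cv", seed = seed))$lambda
    }
    builder <- bin_model_builder(
      map, bin_size, unit, mode = mode, lambda = lam,
      weights = if (mode == "adaptive") weights else "fold",
      whole_scan = whole_scan, seed = seed)
    cv <- kfold_cv(geno, pheno, builder, folds = folds, seed = seed)
    dplyr::bind_cols(
      tibble::tibble(bin_size = bin_size, unit = unit, mode = mode,
                     m = nrow(part), m_used = sum(!part$empty)),
      glance(cv)[c("mse", "mse_se", "r2", "r2_clipped")],
      tibble::tibble(lambda = if (is.numeric(lam)) lam else NA_real_)
    )
  })
  best <- rows[which.min(rows$mse), ]
  within <- rows[rows$mse <= best$mse + best$mse_se, ]
  structure(rows, best = best, within_1se = within, var_y = var(y),
            k = k, seed = seed,
            class = c("bin_size_profile", class(tibble::tibble())))
}
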
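#' Fit bin effects by L1-penalized regression
#'
#' Estimates the working model y = b0 + sum_k gamma_k B_k + e by the
#' Lasso: minimize (1/2n) sum_j (y_j - b0 - sum_k gamma_k B_jk)^2 +
#' lambda sum_k |gamma_k| with an unpenalized intercept (glmnet backend,
#' covariates entered unstandardized so this is the objective actually
#' minimized). Empty-bin columns and all-constant columns are excluded
#' from the design. The penalty is either supplied (`lambda = value`;
#' `0` gives ordinary least squares) or selected by seeded k-fold
#' cross-validation on a 50-point logarithmic grid spanning four decades
#' below the smallest lambda that zeroes every effect, with ties broken
#' toward the larger (more parsimonious) lambda.
#'
#' @param features A `bin_features` tibble ([bin_average()] or
#'   [weighted_bin_score()]).
#' @param pheno Phenotype tibble (`id`, `value`).
#' @param lambda `"cv"` (default) or a single non-negative number.
#' @param nfolds Folds for the internal lambda selection (default 10).
#' @param seed Seed for the fold assignment.
#' @return An object of class `bin_fit`: intercept `b0`, per-bin
#'   `effects` tibble, chosen `lambda`, residual variance `sigma2`
#'   (RSS / (n - df), df = active-set size + 1), `df`, `n`, and the bins
#'   excluded from the design.
#' @export
fit_bins <- function(features, pheno, lambda = "cv", nfolds = 10, seed = 1) {
  xs <- feature_design(features)
  y <- align_pheno(pheno, features$id)
  n <- length(y)
  X <- xs$X
  if (!is.numeric(lambda)) {
    lambda <- match.arg(lambda, "cv")
    if (n < 10) stop("need n >= 10 for cross-validated lambda selection",
                     call. = FALSE)
  }
  grid <- lambda_grid(X, y)
  pad <- ncol(X) == 1 # glmnet needs >= 2 columns; pad with a null covariate
  if (pad) X <- cbind(X, `.pad` = 0)

  if (identical(lambda, "cv")) {
    foldid <- make_folds(n, nfolds, seed)
    cvfit <- glmnet::cv.glmnet(X, y, lambda = grid, foldid = foldid,
                               standardize = FALSE)
    lambda <- cvfit$lambda.min # path is decreasing: ties resolve to larger lambda
    gfit <- cvfit$glmnet.fit
  } else {
    stopifnot(length(lambda) == 1, lambda >= 0)
    if (lambda == 0) {
      # deeper warm-start path and a very tight threshold so the
      # coordinate-descent solution at lambda = 0 agrees with OLS
      grid <- lambda_grid(X, y, length = 70, decades = 6)
      gfit <- glmnet::glmnet(X, y, lambda = c(grid, 0), standardize = FALSE,
                             thresh = 1e-20, maxit = 1e7)
    } else {
      path <- sort(unique(c(grid[grid > lambda], lambda)), decreasing = TRUE)
      gfit <- glmnet::glmnet(X, y, lambda = path, standardize = FALSE,
                             thresh = 1e-7)
    }
  }
  cf <- coef(gfit, s = lambda, exact = FALSE)
  b0 <- cf[1]
  beta <- as.numeric(cf[-1])
  if (pad) beta <- beta[1]
  yhat <- b0 + drop(xs$X %*% beta)
  rss <- sum((y - yhat)^2)
  df <- sum(beta != 0) + 1L
  sigma2 <- if (n > df) rss / (n - df) else NA_real_
  if (is.na(sigma2)) {
    warning("active set as large as n; residual variance not estimable",
            call. = FALSE)
  }
  effects <- tibble::tibble(bin = xs$bins, term = colnames(xs$X),
                            estimate = beta)
  structure(
    list(intercept = b0, effects = effects, lambda = lambda,
         sigma2 = sigma2, df = df, n = n, rss = rss,
         excluded = xs$excluded, mode = attr(features, "mode")),
    class = "bin_fit"
  )
}

#' @export
print.bin_fit <- function(x, ...) {
  cat(sprintf(
    "<bin_fit (%s)> n = %d, %d bins in design, %d nonzero, lambda = %.5g, sigma2 = %.5g\n",
    x$mode, x$n, nrow(x$effects), x$df - 1L, x$lambda, x$sigma2))
  invisible(x)
}

#' Predict from a fitted bin model
#'
#' @param object A `bin_fit`.
#' @param features A `bin_features` tibble built with the same partition
#'   (and, for the adaptive model, the same weights) as the training data.
#' @param ... Unused.
#' @return Numeric vector of predicted phenotypes, one per row of
#'   `features`.
#' @export
predict.bin_fit <- function(object, features, ...) {
  X <- as.matrix(features[object$effects$term])
  drop(object$intercept + X %*% object$effects$estimate)
}

#' Approximate Wald and LOD tests for bin effects
#'
#' For each bin with a nonzero Lasso estimate, the estimation variance is
#' approximated by the marginal OLS form Var(gamma_k) = sigma2 / SSX_k,
#' where SSX_k is the centered sum of squares of the bin covariate; then
#' W_k = gamma_k^2 / Var(gamma_k) and LOD_k = W_k / (2 ln 10). Bins
#' shrunk exactly to zero carry no test, since their estimation error is
#' forced to zero by the penalty.
#'
#' @param fit A `bin_fit`.
#' @param features The `bin_features` used to produce `fit`.
#' @param pheno The phenotype tibble used to produce `fit`.
#' @param lod_threshold Significance cutoff (default 3).
#' @return A tibble of class `bin_tests`: `bin`, `estimate`, `wald`,
#'   `lod`, `significant` -- one row per nonzero-effect bin.
#' @export
wald_lod <- function(fit, features, pheno, lod_threshold = 3) {
  nz <- which(fit$effects$estimate != 0)
  X <- as.matrix(features[fit$effects$term[nz]])
  ssx <- colSums(sweep(X, 2, colMeans(X))^2)
  if (isTRUE(fit$sigma2 == 0)) {
    warning("residual variance is zero; Wald statistics reported as Inf",
            call. = FALSE)
  }
  w <- fit$effects$estimate[nz]^2 * ssx / fit$sigma2
  out <- tibble::tibble(
    bin = fit$effects$bin[nz],
    estimate = fit$effects$estimate[nz],
    wald = unname(w),
    lod = unname(lod_from_wald(w)),
    significant = unname(lod_from_wald(w) >= lod_threshold)
  )
  structure(out, lod_threshold = lod_threshold,
            class = c("bin_tests", class(tibble::tibble())))
}

#' @rdname fit_bins
#' @param x A `bin_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.bin_fit <- function(x, ...) x$effects

#' @rdname fit_bins
#' @exportS3Method generics::glance
glance.bin_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, sigma2 = x$sigma2, df = x$df,
                 n_nonzero = x$df - 1L, n = x$n, rss = x$rss,
                 mode = x$mode)
}

# ---- internal ---------------------------------------------------------------

# design matrix from a bin_features tibble: drop empty bins and
# all-constant columns (warning), keep the bin ids of the survivors
feature_design <- function(features) {
  stopifnot(inherits(features, "bin_features"))
  part <- attr(features, "partition")
  B <- as.matrix(features[-1])
  keep <- !(part$bin %in% attr(features, "exclude"))
  const <- apply(B, 2, function(x) max(x) - min(x) < 1e-12)
  if (any(const & keep)) {
    warning(sprintf("%d all-constant bin covariate(s) dropped from the design",
                    sum(const & keep)), call. = FALSE)
  }
  keep <- keep & !const
  if (!any(keep)) stop("no usable bin covariates", call. = FALSE)
  list(X = B[, keep, drop = FALSE], bins = part$bin[keep],
       excluded = part$bin[!keep])
}

# glmnet-style lambda sequence: 50 log-spaced points over 4 decades down
# from the smallest lambda with an all-zero solution
lambda_grid <- function(X, y, length = 50, decades = 4) {
  n <- nrow(X)
  lmax <- max(abs(crossprod(sweep(X, 2, colMeans(X)), y - mean(y)))) / n
  lmax <- max(lmax, 1e-8)
  10^seq(log10(lmax), log10(lmax) - decades, length.out = length)
}

# balanced fold assignment: sizes differ by at most one, seeded shuffle
make_folds <- function(n, k, seed) {
  stopifnot(k >= 2, n >= k)
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}
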
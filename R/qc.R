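#' Remove markers with low minor allele frequency
#'
#' The allele frequency of each marker is computed from its non-missing
#' coded calls as f = (2 n_{+1} + n_0) / (2 n_nonmissing); markers with
#' min(f, 1 - f) below `threshold` are dropped from both the genotype
#' table and the map. Markers with zero non-missing calls are dropped and
#' flagged. The default threshold of 0.05 is the conventional panel QC
#' cutoff.
#'
#' @param geno Genotype tibble (`id` + one column per marker).
#' @param map Marker map paired with `geno`.
#' @param threshold MAF cutoff in \[0, 0.5\].
#' @return A list with elements `genotypes`, `map` (both filtered) and
#'   `removed`, a tibble of `marker_id`, `maf` and `reason`.
#' @export
filter_maf <- function(geno, map, threshold = 0.05) {
  stopifnot(threshold >= 0, threshold <= 0.5)
  check_geno_map(geno, map)
  M <- geno_matrix(geno)
  n_obs <- colSums(!is.na(M))
  f <- (2 * colSums(M == 1, na.rm = TRUE) + colSums(M == 0, na.rm = TRUE)) /
    (2 * pmax(n_obs, 1))
  maf <- pmin(f, 1 - f)
  all_missing <- n_obs == 0
  drop <- all_missing | maf < threshold
  removed <- tibble::tibble(
    marker_id = map$marker_id[drop],
    maf = unname(ifelse(all_missing[drop], NA_real_, maf[drop])),
    reason = ifelse(all_missing[drop], "all_missing", "low_maf")
  )
  list(
    genotypes = geno[c(TRUE, !drop)],
    map = map[!drop, , drop = FALSE],
    removed = removed
  )
}

#' Impute missing genotype calls by the marker mean
#'
#' Each missing entry is replaced by the mean of the marker's non-missing
#' coded calls, a real number in \[-1, 1\]. Column means are unchanged, so
#' bin averages computed downstream keep their interpretation.
#'
#' @param geno Genotype tibble possibly containing `NA` calls.
#' @return Genotype tibble with no missing entries.
#' @export
impute_missing <- function(geno) {
  M <- geno_matrix(geno)
  nas <- is.na(M)
  if (!any(nas)) return(geno)
  mu <- colMeans(M, na.rm = TRUE)
  if (anyNA(mu)) {
    stop("marker(s) with no non-missing calls: ",
         toString(head(colnames(M)[is.na(mu)], 5)),
         "; run filter_maf() first", call. = FALSE)
  }
  M[nas] <- mu[col(M)[nas]]
  geno_tbl(geno$id, M)
}

#' Pre-adjust phenotypes for fixed-effect covariates
#'
#' Fits an ordinary least-squares linear model of the trait on an
#' intercept plus the covariates (categorical covariates are
#' treatment-coded) and returns the residuals as the working phenotype.
#' Analyses downstream then operate on the covariate-adjusted scale, the
#' same scale on which the phenotypic variance for predictability is
#' computed. Aliased (rank-deficient) covariate columns are dropped with a
#' warning rather than erroring.
#'
#' @param pheno Tibble with columns `id` and `value` (the raw trait).
#' @param covariates Tibble row-aligned with `pheno` (or carrying an `id`
#'   column to join on) whose remaining columns are the co-factors.
#' @return A tibble `id`, `value` of residuals (mean zero), with attribute
#'   `adjusted = TRUE`.
#' @export
adjust_covariates <- function(pheno, covariates) {
  stopifnot(all(c("id", "value") %in% names(pheno)))
  cv <- covariates
  if ("id" %in% names(cv)) {
    if (!all(pheno$id %in% cv$id)) {
      stop("covariate table is missing individuals present in the phenotype",
           call. = FALSE)
    }
    cv <- cv[match(pheno$id, cv$id), setdiff(names(cv), "id"), drop = FALSE]
  } else if (nrow(cv) != nrow(pheno)) {
    stop("covariates must be row-aligned with the phenotype or keyed by 'id'",
         call. = FALSE)
  }
  cv <- dplyr::mutate(tibble::as_tibble(cv),
                      dplyr::across(dplyr::where(is.character), factor))
  df <- cbind(data.frame(.y = pheno$value), as.data.frame(cv))
  fit <- lm(.y ~ ., data = df)
  if (anyNA(coef(fit))) {
    warning("aliased covariate column(s) dropped: ",
            toString(names(coef(fit))[is.na(coef(fit))]), call. = FALSE)
  }
  out <- tibble::tibble(id = pheno$id, value = unname(fit$residuals))
  attr(out, "adjusted") <- TRUE
  out
}

# ---- internal ---------------------------------------------------------------

check_geno_map <- function(geno, map) {
  if (!identical(names(geno)[-1], map$marker_id)) {
    stop("genotype columns and marker map disagree (order or identity)",
         call. = FALSE)
  }
  invisible(TRUE)
}
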
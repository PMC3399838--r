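#' Single-marker regression scan
#'
#' Fits the simple regression y = mu + b_h Z_h + e by least squares for
#' every marker separately, the preliminary analysis that supplies the
#' adaptive weights. Markers with zero genotype variance get b = 0 and
#' are flagged.
#'
#' @param geno Genotype tibble (imputed).
#' @param pheno Phenotype tibble (`id`, `value`), aligned with `geno`.
#' @return A tibble of class `marker_scan`: `marker_id`, `estimate`
#'   (trait units per coded-genotype unit), `se`, `lod`, `zero_var`.
#' @export
single_marker_scan <- function(geno, pheno) {
  M <- geno_matrix(geno)
  if (anyNA(M)) stop("genotypes contain missing calls; run impute_missing() first",
                     call. = FALSE)
  y <- align_pheno(pheno, geno$id)
  n <- length(y)
  stopifnot(n >= 3)
  xc <- sweep(M, 2, colMeans(M))
  yc <- y - mean(y)
  sxx <- colSums(xc^2)
  sxy <- drop(crossprod(xc, yc))
  syy <- sum(yc^2)
  zero <- sxx < 1e-12
  b <- ifelse(zero, 0, sxy / pmax(sxx, 1e-300))
  rss <- pmax(syy - b * sxy, 0)
  se2 <- rss / ((n - 2) * pmax(sxx, 1e-300))
  se <- ifelse(zero, NA_real_, sqrt(se2))
  wald <- ifelse(zero, NA_real_, b^2 / pmax(se2, 1e-300))
  structure(
    tibble::tibble(marker_id = colnames(M), estimate = unname(b),
                   se = unname(se), lod = unname(lod_from_wald(wald)),
                   zero_var = unname(zero)),
    class = c("marker_scan", class(tibble::tibble()))
  )
}

#' Convert a Wald statistic to a LOD score
#'
#' LOD = W / (2 ln 10); the conventional LOD >= 3 significance criterion
#' corresponds to W >= 13.8155.
#'
#' @param w Wald statistic(s).
#' @return LOD score(s).
#' @export
lod_from_wald <- function(w) w / (2 * log(10))

#' Adaptive marker weights
#'
#' Within each bin, the weight of marker h is its single-marker estimate
#' divided by the mean absolute estimate of the bin:
#' w_h = b_h / mean(|b|). Weights are signed, so markers whose estimated
#' effects point in opposite directions are re-aligned when averaged, and
#' by construction mean(|w|) = 1 within every bin. Bins whose estimates
#' are all (numerically) zero get all-zero weights.
#'
#' @param scan A `marker_scan` from [single_marker_scan()].
#' @param partition A `bin_partition` over the same markers.
#' @return A tibble of class `weight_set`: `marker_id`, `bin`, `estimate`,
#'   `weight`, plus the per-bin mean absolute estimate `bin_mean_abs`.
#' @export
compute_weights <- function(scan, partition) {
  marker_bin <- attr(partition, "marker_bin")
  if (nrow(scan) != length(marker_bin)) {
    stop("scan and partition cover different marker counts", call. = FALSE)
  }
  out <- tibble::tibble(
    marker_id = scan$marker_id,
    bin = marker_bin,
    estimate = scan$estimate
  ) |>
    dplyr::group_by(.data$bin) |>
    dplyr::mutate(bin_mean_abs = mean(abs(.data$estimate))) |>
    dplyr::ungroup() |>
    dplyr::mutate(weight = ifelse(.data$bin_mean_abs < 1e-12, 0,
                                  .data$estimate / .data$bin_mean_abs))
  structure(out, partition = partition,
            class = c("weight_set", class(tibble::tibble())))
}

#' Weighted bin scores
#'
#' The adaptive counterpart of [bin_average()]: entry (j, k) is
#' (1/p_k) sum_h w_h Z_{jh} over the markers of bin k. With all weights
#' equal to 1 this reduces to the unweighted bin average. The scores are
#' invariant to flipping the allele coding of any marker, since the sign
#' flip of Z cancels against the sign flip of its weight.
#'
#' @param geno Genotype tibble (imputed).
#' @param partition A `bin_partition`.
#' @param weights A `weight_set` from [compute_weights()].
#' @return A `bin_features` tibble with `mode = "adaptive"`.
#' @export
weighted_bin_score <- function(geno, partition, weights) {
  M <- bin_geno_matrix(geno, partition)
  marker_bin <- attr(partition, "marker_bin")
  stopifnot(nrow(weights) == ncol(M))
  W <- sweep(M, 2, weights$weight, "*")
  S <- t(rowsum(t(W), group = marker_bin, reorder = TRUE))
  B <- matrix(0, nrow(M), nrow(partition))
  B[, sort(unique(marker_bin))] <- S
  B <- sweep(B, 2, pmax(partition$p_k, 1), "/")
  new_bin_features(geno$id, B, partition, mode = "adaptive")
}

# ---- internal ---------------------------------------------------------------

align_pheno <- function(pheno, ids) {
  stopifnot(all(c("id", "value") %in% names(pheno)))
  if (!all(ids %in% pheno$id)) {
    stop("phenotype table is missing individuals present in the genotypes",
         call. = FALSE)
  }
  y <- pheno$value[match(ids, pheno$id)]
  if (any(!is.finite(y))) stop("non-finite phenotype values", call. = FALSE)
  y
}
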
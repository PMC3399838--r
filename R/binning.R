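#' Partition the genome into bins
#'
#' Cuts each chromosome into half-open intervals \[start, start + size)
#' anchored at position 0; the final interval is truncated at the
#' chromosome end (the position of its last marker), and a marker sitting
#' exactly on the chromosome end is assigned to that final bin. Bins that
#' contain no markers are kept in the partition but flagged `empty`, so
#' bin indexing stays stable across bin-size scans.
#'
#' @param map Marker map.
#' @param bin_size Bin width in `unit`. For `unit = "log10_bp"` the width
#'   is `10^bin_size` base pairs. For `unit = "markers"` each bin holds
#'   `bin_size` consecutive markers.
#' @param unit One of `"cM"`, `"bp"`, `"log10_bp"`, `"markers"`.
#' @return A tibble of class `bin_partition`: one row per bin with
#'   `bin`, `chrom`, `start`, `end`, `first_marker`, `last_marker`, `p_k`
#'   (marker count) and `empty`; attributes `marker_bin` (bin index of
#'   every marker), `unit` and `bin_size`.
#' @export
make_bins <- function(map, bin_size, unit = c("cM", "bp", "log10_bp", "markers")) {
  unit <- match.arg(unit)
  stopifnot(bin_size > 0)
  if (unit == "markers") {
    stopifnot(bin_size == round(bin_size))
    chrom_f <- factor(map$chrom, levels = unique(map$chrom))
    pieces <- lapply(split(seq_len(nrow(map)), chrom_f), function(idx) {
      k <- ceiling(seq_along(idx) / bin_size)
      tibble::tibble(chrom = map$chrom[idx[1]], local_bin = k, marker = idx)
    })
    asg <- dplyr::bind_rows(pieces)
    asg$bin <- cumsum(!duplicated(paste(asg$chrom, asg$local_bin)))
    bins <- asg |>
      dplyr::group_by(.data$bin, .data$chrom) |>
      dplyr::summarise(first_marker = min(.data$marker),
                       last_marker = max(.data$marker),
                       p_k = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(start = .data$first_marker, end = .data$last_marker,
                    empty = FALSE)
    marker_bin <- asg$bin[order(asg$marker)]
    return(new_bin_partition(bins, marker_bin, unit, bin_size))
  }

  pos <- switch(unit,
                cM = map$pos_cm,
                bp = map$pos_bp,
                log10_bp = map$pos_bp)
  if (anyNA(pos)) {
    stop(sprintf("marker map lacks %s positions required for unit '%s'",
                 if (unit == "cM") "genetic" else "physical", unit),
         call. = FALSE)
  }
  width <- if (unit == "log10_bp") 10^bin_size else bin_size
  chrom_f <- factor(map$chrom, levels = unique(map$chrom))
  marker_bin <- integer(nrow(map))
  bins <- list()
  offset <- 0L
  for (ch in levels(chrom_f)) {
    idx <- which(chrom_f == ch)
    L <- max(pos[idx])
    m_ch <- max(1L, ceiling(L / width))
    # small epsilon so a marker at an exact bin boundary (up to floating-
    # point representation of its position) lands in the right-hand bin;
    # chromosome-end markers are clamped into the last bin
    k <- pmin(floor(pos[idx] / width + 1e-9), m_ch - 1L)
    marker_bin[idx] <- offset + k + 1L
    starts <- (seq_len(m_ch) - 1L) * width
    cnt <- tabulate(k + 1L, nbins = m_ch)
    first <- rep(NA_integer_, m_ch)
    last <- rep(NA_integer_, m_ch)
    nonempty <- which(cnt > 0)
    first[nonempty] <- idx[match(nonempty - 1L, k)]
    last[nonempty] <- idx[length(idx) + 1L - match(nonempty - 1L, rev(k))]
    bins[[ch]] <- tibble::tibble(
      bin = offset + seq_len(m_ch),
      chrom = ch,
      start = starts,
      end = pmin(starts + width, L),
      first_marker = first,
      last_marker = last,
      p_k = cnt,
      empty = cnt == 0L
    )
    offset <- offset + m_ch
  }
  new_bin_partition(dplyr::bind_rows(bins), marker_bin, unit, bin_size)
}

new_bin_partition <- function(bins, marker_bin, unit, bin_size) {
  bins <- tibble::as_tibble(bins)[, c("bin", "chrom", "start", "end",
                                      "first_marker", "last_marker",
                                      "p_k", "empty")]
  structure(bins,
            marker_bin = marker_bin, unit = unit, bin_size = bin_size,
            class = c("bin_partition", class(bins)))
}

#' @export
print.bin_partition <- function(x, ...) {
  cat(sprintf("<bin_partition> %d bins (%d empty), size %.4g %s, %d markers\n",
              nrow(x), sum(x$empty), attr(x, "bin_size"), attr(x, "unit"),
              length(attr(x, "marker_bin"))))
  NextMethod()
}

#' Unweighted bin-average covariates
#'
#' Collapses the genotype matrix to one covariate per bin: entry (j, k) is
#' the mean of the coded genotypes of the p_k markers in bin k. With one
#' marker per bin this reduces to the marker matrix itself. Empty bins
#' yield an all-zero column that is flagged for exclusion from fitting.
#'
#' @param geno Genotype tibble (no missing entries; run
#'   [impute_missing()] first).
#' @param partition A `bin_partition` over the same markers.
#' @return A tibble of class `bin_features`: column `id` then one numeric
#'   column per bin (`bin0001`, ...); attributes `partition`, `mode`
#'   (`"unweighted"`) and `exclude` (indices of empty bins).
#' @export
bin_average <- function(geno, partition) {
  M <- bin_geno_matrix(geno, partition)
  marker_bin <- attr(partition, "marker_bin")
  S <- t(rowsum(t(M), group = marker_bin, reorder = TRUE))
  B <- matrix(0, nrow(M), nrow(partition))
  B[, sort(unique(marker_bin))] <- S
  B <- sweep(B, 2, pmax(partition$p_k, 1), "/")
  new_bin_features(geno$id, B, partition, mode = "unweighted")
}

new_bin_features <- function(ids, B, partition, mode) {
  colnames(B) <- sprintf("bin%04d", partition$bin)
  out <- dplyr::bind_cols(tibble::tibble(id = as.character(ids)),
                          tibble::as_tibble(B))
  structure(out,
            partition = partition, mode = mode,
            exclude = partition$bin[partition$empty],
            class = c("bin_features", class(out)))
}

bin_geno_matrix <- function(geno, partition) {
  M <- geno_matrix(geno)
  if (ncol(M) != length(attr(partition, "marker_bin"))) {
    stop("genotype matrix and bin partition cover different marker counts",
         call. = FALSE)
  }
  if (anyNA(M)) {
    stop("genotypes contain missing calls; run impute_missing() first",
         call. = FALSE)
  }
  M
}

#' Theoretical variance of an F2 bin average
#'
#' For p markers at the given genetic positions within one bin, the
#' variance of the bin-average coded genotype across F2 individuals is
#' (1/p^2) (p/2 + 2 sum_\{h<l\} (1 - 2 r_hl)/2), with r_hl the Haldane
#' recombination fraction of the pairwise distance. It equals 1/2 for a
#' single marker or for completely linked markers, and decays toward
#' 1/(2p) as the markers become unlinked -- the power cost of binning in
#' low LD.
#'
#' @param positions Genetic positions (cM) of the markers in the bin.
#' @return The variance, a value in (0, 1/2\].
#' @export
theoretical_bin_variance <- function(positions) {
  p <- length(positions)
  stopifnot(p >= 1)
  C <- f2_cov(abs(outer(positions, positions, "-")))
  diag(C) <- 1 / 2
  sum(C) / p^2
}
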
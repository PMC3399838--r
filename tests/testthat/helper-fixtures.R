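# small programmatic fixtures shared across test files

# map with evenly spaced markers on one chromosome
toy_map <- function(p, spacing = 1, chrom = "chr1", start = 0) {
  tibble::tibble(
    marker_id = sprintf("m%05d", seq_len(p)),
    chrom = chrom,
    pos_cm = start + (seq_len(p) - 1) * spacing,
    pos_bp = NA_real_
  )
}

# genotype tibble straight from a coded matrix
toy_geno <- function(M, ids = sprintf("ind%05d", seq_len(nrow(M))),
                     marker_ids = sprintf("m%05d", seq_len(ncol(M)))) {
  colnames(M) <- marker_ids
  dplyr::bind_cols(tibble::tibble(id = ids), tibble::as_tibble(M))
}

toy_pheno <- function(values, ids = sprintf("ind%05d", seq_along(values))) {
  tibble::tibble(id = ids, value = values)
}

# whole genome as one bin
one_bin <- function(map) {
  pos <- dplyr::coalesce(map$pos_cm, map$pos_bp)
  make_bins(map, max(pos) + 1, "cM")
}

# closed-form simple regression (slope, se) for the scan oracle
ols_simple <- function(x, y) {
  n <- length(y)
  xc <- x - mean(x); yc <- y - mean(y)
  b <- sum(xc * yc) / sum(xc^2)
  rss <- sum((yc - b * xc)^2)
  list(b = b, se = sqrt(rss / ((n - 2) * sum(xc^2))))
}
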
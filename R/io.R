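#' Read a marker map
#'
#' A marker map orders the markers along the genome and carries their
#' genetic (cM) and/or physical (bp) coordinates. Every downstream step
#' (binning, simulation, QC) refers to this table.
#'
#' @param path Delimited text file (TSV or CSV, autodetected) with columns
#'   `marker_id`, `chrom` (or `chromosome`), and at least one of
#'   `pos_cm`/`cM` and `pos_bp`/`bp`.
#' @return A tibble with columns `marker_id`, `chrom`, `pos_cm`, `pos_bp`,
#'   sorted by chromosome and position, validated by [validate_marker_map()].
#' @export
read_marker_map <- function(path) {
  tb <- read_delim_auto(path)
  names(tb) <- tolower(names(tb))
  ren <- c(chromosome = "chrom", chr = "chrom", cm = "pos_cm", bp = "pos_bp",
           position_cm = "pos_cm", position_bp = "pos_bp")
  for (old in names(ren)) {
    if (old %in% names(tb) && !ren[[old]] %in% names(tb)) {
      names(tb)[names(tb) == old] <- ren[[old]]
    }
  }
  if (!all(c("marker_id", "chrom") %in% names(tb))) {
    stop("map file must have columns 'marker_id' and 'chrom'", call. = FALSE)
  }
  if (!"pos_cm" %in% names(tb)) tb$pos_cm <- NA_real_
  if (!"pos_bp" %in% names(tb)) tb$pos_bp <- NA_real_
  map <- tibble::tibble(
    marker_id = as.character(tb$marker_id),
    chrom = as.character(tb$chrom),
    pos_cm = as.numeric(tb$pos_cm),
    pos_bp = as.numeric(tb$pos_bp)
  )
  validate_marker_map(map)
}

#' Validate a marker map
#'
#' Checks the marker-map invariants: unique ids, at least one coordinate
#' per marker, non-negative positions, and strict sorting within
#' chromosome. Returns the map invisibly unchanged so it can be piped.
#'
#' @param map A marker-map tibble (`marker_id`, `chrom`, `pos_cm`, `pos_bp`).
#' @return `map`, invisibly validated.
#' @export
validate_marker_map <- function(map) {
  stopifnot(is.data.frame(map),
            all(c("marker_id", "chrom") %in% names(map)))
  if (anyDuplicated(map$marker_id)) {
    stop("duplicated marker ids in map", call. = FALSE)
  }
  pos <- dplyr::coalesce(map$pos_cm, map$pos_bp)
  if (anyNA(pos)) {
    stop("every marker needs a genetic (cM) or physical (bp) position",
         call. = FALSE)
  }
  if (any(pos < 0, na.rm = TRUE) ||
      any(map$pos_cm < 0, na.rm = TRUE) || any(map$pos_bp < 0, na.rm = TRUE)) {
    stop("marker positions must be non-negative", call. = FALSE)
  }
  ord <- order(factor(map$chrom, levels = unique(map$chrom)), pos)
  if (!identical(ord, seq_len(nrow(map)))) {
    stop("markers must be sorted by (chromosome, position)", call. = FALSE)
  }
  map
}

#' Read a coded genotype matrix
#'
#' Genotypes are stored one row per individual, first column the individual
#' id, remaining columns one per marker. Calls are coded on the F2 scale
#' AA = +1, Aa = 0, aa = -1; dosage files (0/1/2 copies of the reference
#' allele) are recoded by subtracting 1. Columns are conformed to the
#' marker-map order.
#'
#' @param path Delimited text file (TSV/CSV autodetected).
#' @param map Marker map whose `marker_id`s must match the file header.
#' @param coding `"auto"` detects from observed values (2 present and -1
#'   absent implies dosage); `"dosage_012"` forces the 0/1/2 recode;
#'   `"plus_minus_one"` takes values as-is.
#' @param missing Token(s) treated as a missing call (default `"NA"`).
#' @return A tibble: column `id`, then one numeric column per marker in map
#'   order, entries in \{-1, 0, +1\} or `NA`.
#' @export
read_genotypes <- function(path, map,
                           coding = c("auto", "dosage_012", "plus_minus_one"),
                           missing = "NA") {
  coding <- match.arg(coding)
  tb <- read_delim_auto(path, na = missing)
  ids <- as.character(tb[[1]])
  gm <- tb[-1]
  if (!setequal(names(gm), map$marker_id)) {
    miss <- setdiff(map$marker_id, names(gm))
    extra <- setdiff(names(gm), map$marker_id)
    stop("genotype columns do not match the marker map",
         if (length(miss)) paste0("; missing: ", toString(head(miss, 5))),
         if (length(extra)) paste0("; unknown: ", toString(head(extra, 5))),
         call. = FALSE)
  }
  gm <- gm[map$marker_id]
  M <- as.matrix(gm)
  if (!is.numeric(M)) {
    bad <- which(!is.na(M) & is.na(suppressWarnings(array(as.numeric(M), dim(M)))),
                 arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("unknown genotype token '%s' at row %d (individual %s), marker %s",
                   M[bad[1, 1], bad[1, 2]], bad[1, 1], ids[bad[1, 1]],
                   colnames(gm)[bad[1, 2]]), call. = FALSE)
    }
    M <- array(as.numeric(M), dim(M))
  }
  vals <- unique(M[!is.na(M)])
  if (coding == "auto") {
    coding <- if (any(vals == 2) && !any(vals == -1)) "dosage_012" else "plus_minus_one"
  }
  if (coding == "dosage_012") {
    if (!all(vals %in% c(0, 1, 2))) {
      bad <- which(!is.na(M) & !(M %in% c(0, 1, 2)), arr.ind = TRUE)
      stop(sprintf("genotype value %s at row %d, marker %s is not a 0/1/2 dosage",
                   M[bad[1, 1], bad[1, 2]], bad[1, 1], map$marker_id[bad[1, 2]]),
           call. = FALSE)
    }
    M <- M - 1
  } else if (!all(vals %in% c(-1, 0, 1))) {
    bad <- which(!is.na(M) & !(M %in% c(-1, 0, 1)), arr.ind = TRUE)
    stop(sprintf("genotype value %s at row %d, marker %s is not in {-1, 0, +1}",
                 M[bad[1, 1], bad[1, 2]], bad[1, 1], map$marker_id[bad[1, 2]]),
         call. = FALSE)
  }
  geno_tbl(ids, M, map$marker_id)
}

#' Read a phenotype / covariate table
#'
#' @param path Delimited text file with an individual id key column (first
#'   column or one named `id`) and one column per trait or covariate.
#' @return A tibble with first column `id` (character).
#' @export
read_phenotypes <- function(path) {
  tb <- read_delim_auto(path)
  if (!"id" %in% names(tb)) names(tb)[1] <- "id"
  tb$id <- as.character(tb$id)
  dplyr::relocate(tb, "id")
}

#' Write genotype / map / phenotype tables
#'
#' Plain TSV writers that round-trip exactly with the corresponding
#' readers.
#'
#' @param x Table to write (a genotype tibble, marker map, or phenotype
#'   tibble).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
write_marker_map <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
write_phenotypes <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

# ---- internal helpers -------------------------------------------------------

read_delim_auto <- function(path, na = "NA") {
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  readr::read_delim(path, delim = delim, na = na, show_col_types = FALSE,
                    progress = FALSE)
}

# genotype tibble from ids + numeric matrix
geno_tbl <- function(ids, M, marker_ids = colnames(M)) {
  colnames(M) <- marker_ids
  dplyr::bind_cols(tibble::tibble(id = as.character(ids)),
                   tibble::as_tibble(M))
}

# numeric matrix (individuals x markers) from a genotype tibble
geno_matrix <- function(geno) {
  M <- as.matrix(geno[-1])
  storage.mode(M) <- "double"
  rownames(M) <- geno$id
  M
}
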
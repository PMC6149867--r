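#' @importFrom rlang abort warn := .data %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer pivot_wider
#' @importFrom purrr map map_dbl map_chr map_lgl
NULL

#' Round half away from zero
#'
#' Report-layer rounding. Base R's `round()` rounds half to even
#' (banker's rounding); summary tables here follow the half-up convention
#' used in published per-kilobase densities and percentages.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(1.025, 2) # 1.03, where round() gives 1.02
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits))
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# internal: gene-by-sample tibble -> integer matrix with gene rownames
counts_to_matrix <- function(counts) {
  check_count_table(counts)
  m <- as.matrix(counts[setdiff(names(counts), "gene")])
  storage.mode(m) <- "double"
  rownames(m) <- counts$gene
  m
}

check_count_table <- function(counts) {
  if (!is.data.frame(counts) || !"gene" %in% names(counts)) {
    abort("`counts` must be a data frame with a `gene` column followed by sample columns.")
  }
  if (anyDuplicated(counts$gene)) {
    abort("`counts` has duplicated gene ids.")
  }
  vals <- counts[setdiff(names(counts), "gene")]
  if (length(vals) == 0L) abort("`counts` has no sample columns.")
  ok <- vapply(vals, function(v) is.numeric(v) && !anyNA(v) && all(v >= 0) && all(v == floor(v)), logical(1))
  if (!all(ok)) {
    abort(paste0("count columns must be non-negative integers; offending column(s): ",
                 paste(names(vals)[!ok], collapse = ", ")))
  }
  invisible(counts)
}

check_design <- function(design, samples = NULL, min_per_sex = 1L) {
  if (!is.data.frame(design) || !all(c("sample", "sex") %in% names(design))) {
    abort("`design` must be a data frame with columns `sample` and `sex`.")
  }
  if (!all(design$sex %in% c("M", "F"))) {
    abort("`design$sex` must be 'M' or 'F'.")
  }
  if (anyDuplicated(design$sample)) abort("`design` has duplicated sample ids.")
  tab <- table(factor(design$sex, levels = c("M", "F")))
  if (any(tab < min_per_sex)) {
    abort(sprintf("design needs at least %d sample(s) per sex (got %d M, %d F).",
                  min_per_sex, tab[["M"]], tab[["F"]]))
  }
  if (!is.null(samples) && !setequal(samples, design$sample)) {
    abort("sample columns do not match `design$sample`.")
  }
  invisible(design)
}

#' Read a gene-by-sample count table
#'
#' @param path Tab-separated file: first column `gene`, one column per sample.
#' @return A tibble with a `gene` column and integer sample columns.
#' @export
read_counts <- function(path) {
  counts <- readr::read_tsv(path, show_col_types = FALSE)
  names(counts)[1] <- "gene"
  check_count_table(counts)
  counts
}

#' Read a sample sheet
#'
#' @param path Tab-separated file with columns `sample` and `sex` (M or F).
#' @return A tibble with columns `sample`, `sex`.
#' @export
read_sample_sheet <- function(path) {
  design <- readr::read_tsv(path, show_col_types = FALSE)
  check_design(design)
  design[c("sample", "sex")]
}

#' Read unigene sequences from FASTA
#'
#' @param path FASTA file of assembled unigenes (oriented transcripts).
#' @return A tibble with columns `gene`, `length`, `sequence`.
#' @export
read_unigenes <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  tibble(
    gene = sub("\\s.*$", "", names(ss)),
    length = Biostrings::width(ss),
    sequence = as.character(ss)
  )
}

# write a tibble as TSV with deterministic formatting
write_tsv_plain <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
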
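#' Median-of-ratios size factors
#'
#' Per-sample normalization constants: each sample's factor is the median,
#' over genes with all-positive counts, of that sample's count divided by
#' the gene's geometric mean across samples. Multiplying one sample's
#' counts by a constant multiplies its factor by the same constant, so
#' normalized fold changes are sequencing-depth invariant.
#'
#' @param counts Tibble with a `gene` column and integer sample columns.
#' @param pseudo_reference If no gene has all-positive counts, setting
#'   this to `TRUE` falls back to computing geometric means over positive
#'   counts only (zeros ignored), using every gene expressed in at least
#'   two samples. Ignored (the classic reference is used) whenever an
#'   all-positive gene exists.
#' @return Tibble with columns `sample`, `size_factor`.
#' @examples
#' counts <- tibble::tibble(gene = c("g1", "g2"), s1 = c(100, 300), s2 = c(200, 600))
#' compute_size_factors(counts) # 1/sqrt(2), sqrt(2)
#' @export
compute_size_factors <- function(counts, pseudo_reference = FALSE) {
  m <- counts_to_matrix(counts)
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos) && !pseudo_reference) {
    abort(paste0(
      "no gene has positive counts in every sample, so the median-of-ratios ",
      "reference is undefined; rerun with `pseudo_reference = TRUE` to use a ",
      "zero-tolerant geometric mean."))
  }
  if (any(all_pos)) {
    sub <- m[all_pos, , drop = FALSE]
    log_gm <- rowMeans(log(sub))
    sf <- apply(sub, 2, function(col) exp(median(log(col) - log_gm)))
  } else {
    use <- rowSums(m > 0) >= 2
    if (!any(use)) abort("no gene is expressed in two or more samples.")
    sub <- m[use, , drop = FALSE]
    log_gm <- apply(sub, 1, function(r) mean(log(r[r > 0])))
    sf <- apply(sub, 2, function(col) {
      ratios <- log(col) - log_gm
      exp(median(ratios[is.finite(ratios)]))
    })
  }
  if (any(!is.finite(sf) | sf <= 0)) abort("size factors must be finite and positive.")
  tibble(sample = colnames(m), size_factor = unname(sf))
}

#' FPKM expression matrix
#'
#' FPKM (fragments per kilobase of transcript per million mapped
#' fragments): `count / (length/1e3 * library_size/1e6)`. Library sizes
#' default to column sums of the count matrix.
#'
#' @param counts Tibble with `gene` + sample columns.
#' @param gene_lengths Tibble with columns `gene`, `length` (bp, >= 1),
#'   covering every gene in `counts`.
#' @param library_sizes Optional tibble `sample`, `library_size`
#'   (positive); defaults to per-sample count totals.
#' @return Tibble of FPKM values, same shape as `counts`.
#' @export
compute_fpkm <- function(counts, gene_lengths, library_sizes = NULL) {
  m <- counts_to_matrix(counts)
  len <- gene_lengths$length[match(rownames(m), gene_lengths$gene)]
  if (anyNA(len)) {
    abort(paste0("missing gene length for: ",
                 paste(head(rownames(m)[is.na(len)], 5), collapse = ", ")))
  }
  if (any(len < 1)) {
    abort(paste0("non-positive length for gene(s): ",
                 paste(head(rownames(m)[len < 1], 5), collapse = ", ")))
  }
  if (is.null(library_sizes)) {
    lib <- colSums(m)
  } else {
    lib <- library_sizes$library_size[match(colnames(m), library_sizes$sample)]
  }
  if (anyNA(lib) || any(lib <= 0)) abort("library sizes must be positive for every sample.")
  fpkm <- m / (len / 1e3) / rep(lib / 1e6, each = nrow(m))
  bind_cols(tibble(gene = rownames(m)), as_tibble(fpkm))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone, capped at 1), with input validation.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_bh <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric.")
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1].")
  stats::p.adjust(p, method = "BH")
}

#' Two-group negative-binomial test for sex-biased expression
#'
#' Per-gene Wald test on normalized counts under the NB variance model
#' `Var = mu + alpha * mu^2`. Counts are divided by median-of-ratios size
#' factors; raw per-gene dispersions come from the method of moments on
#' within-sex residuals pooled across the two sexes, and - because a
#' per-gene estimate from three replicates per sex is far too noisy to
#' test with - each gene's working dispersion is taken from a
#' mean-dispersion trend `alpha(mu) = a0 + a1/mu` fitted across all genes
#' (least squares on the raw estimates, floored at `1e-8`). The statistic
#' is the log2 ratio of male to female group means over its delta-method
#' standard error, referred to the standard normal. When a group mean is
#' zero a pseudo-count of 0.5 is added to both group means for the fold
#' change and its error; genes with all-zero counts get `log2fc = 0`,
#' `p = 1`.
#'
#' @param counts Tibble with `gene` + sample columns.
#' @param design Sample sheet with at least two replicates per sex.
#' @param size_factors Optional tibble `sample`, `size_factor`; computed
#'   from `counts` when omitted.
#' @return Tibble with columns `gene`, `base_mean_m`, `base_mean_f`
#'   (normalized group means), `log2fc` (male over female), `p`.
#' @export
test_differential <- function(counts, design, size_factors = NULL) {
  m <- counts_to_matrix(counts)
  check_design(design, samples = colnames(m), min_per_sex = 2L)
  if (is.null(size_factors)) size_factors <- compute_size_factors(counts, pseudo_reference = TRUE)
  sf <- size_factors$size_factor[match(colnames(m), size_factors$sample)]
  if (anyNA(sf)) abort("size factors missing for some samples.")
  q <- sweep(m, 2, sf, "/")
  sex <- design$sex[match(colnames(m), design$sample)]
  qm <- q[, sex == "M", drop = FALSE]
  qf <- q[, sex == "F", drop = FALSE]
  n_m <- ncol(qm); n_f <- ncol(qf)
  mm <- rowMeans(qm); mf <- rowMeans(qf)
  mu <- (n_m * mm + n_f * mf) / (n_m + n_f)
  s2 <- (rowSums((qm - mm)^2) + rowSums((qf - mf)^2)) / (n_m + n_f - 2)
  alpha_raw <- (s2 - mu) / mu^2
  alpha <- fit_dispersion_trend(mu, alpha_raw)
  zero <- mm == 0 | mf == 0
  mm2 <- ifelse(zero, mm + 0.5, mm)
  mf2 <- ifelse(zero, mf + 0.5, mf)
  log2fc <- log2(mm2 / mf2)
  se <- sqrt((1 / mm2 + alpha) / n_m + (1 / mf2 + alpha) / n_f) / log(2)
  p <- 2 * stats::pnorm(-abs(log2fc / se))
  all_zero <- mm == 0 & mf == 0
  log2fc[all_zero] <- 0
  p[all_zero] <- 1
  tibble(gene = rownames(m), base_mean_m = unname(mm), base_mean_f = unname(mf),
         log2fc = unname(log2fc), p = unname(p))
}

# working dispersion per gene: alpha(mu) = a0 + a1/mu least-squares trend
# over raw MoM estimates; falls back to their mean (then to the floor)
# when too few genes support a fit
fit_dispersion_trend <- function(mu, alpha_raw, floor = 1e-8) {
  ok <- is.finite(alpha_raw) & mu > 1
  if (sum(ok) >= 2 && length(unique(mu[ok])) >= 2) {
    co <- tryCatch(qr.solve(cbind(1, 1 / mu[ok]), alpha_raw[ok]),
                   error = function(e) NULL)
    if (!is.null(co)) {
      return(pmax(floor, co[1] + co[2] / pmax(mu, 1e-8)))
    }
  }
  if (any(ok)) return(rep(max(floor, mean(alpha_raw[ok])), length(mu)))
  rep(floor, length(mu))
}

#' Classify genes as male-biased, female-biased or unbiased
#'
#' A gene is male-biased iff `p_adj < alpha` and `log2fc >=
#' lfc_threshold`, female-biased iff `p_adj < alpha` and `log2fc <=
#' -lfc_threshold`, otherwise unbiased. The significance comparison is
#' strict and the fold-change comparison inclusive, following the usual
#' printed operators (p_adj < 0.05, |log2FC| >= 1). Male-biased means
#' up-regulated in males.
#'
#' @param results Tibble with columns `log2fc` and `p_adj` (add one with
#'   [adjust_bh()] if needed).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param lfc_threshold Absolute log2 fold-change cutoff (default 1).
#' @return `results` with a `bias_class` column.
#' @export
classify_deg <- function(results, alpha = 0.05, lfc_threshold = 1) {
  if (!all(c("log2fc", "p_adj") %in% names(results))) {
    abort("`results` needs columns `log2fc` and `p_adj`.")
  }
  mutate(results, bias_class = case_when(
    .data$p_adj < alpha & .data$log2fc >= lfc_threshold ~ "male-biased",
    .data$p_adj < alpha & .data$log2fc <= -lfc_threshold ~ "female-biased",
    TRUE ~ "unbiased"
  ))
}

#' Flag sex-specific genes among the DEGs
#'
#' Among genes already called sex-biased, a gene is male-specific iff
#' every female replicate has count exactly zero and the male FPKM clears
#' `fpkm_floor` (strictly greater), and symmetrically female-specific.
#' `floor_mode` controls whether the floor applies to the mean FPKM of
#' the expressing sex or to every replicate of that sex.
#'
#' @param results Tibble with `gene` and `bias_class` (from
#'   [classify_deg()]).
#' @param counts,fpkm Count and FPKM tibbles (`gene` + sample columns).
#' @param design Sample sheet.
#' @param fpkm_floor Expression floor for the expressing sex (default 0.03).
#' @param floor_mode `"mean"` (default) or `"all"`.
#' @return `results` with a `specificity` column (male-specific /
#'   female-specific / none).
#' @export
classify_sex_specific <- function(results, counts, fpkm, design,
                                  fpkm_floor = 0.03,
                                  floor_mode = c("mean", "all")) {
  floor_mode <- match.arg(floor_mode)
  if (!all(c("gene", "bias_class") %in% names(results))) {
    abort("`results` needs columns `gene` and `bias_class`.")
  }
  cm <- counts_to_matrix(counts)
  fm <- counts_to_matrix_lenient(fpkm)
  check_design(design, samples = colnames(cm))
  sex <- design$sex[match(colnames(cm), design$sample)]
  idx <- match(results$gene, rownames(cm))
  if (anyNA(idx)) abort("`results$gene` not all present in `counts`.")
  zero_f <- rowSums(cm[idx, sex == "F", drop = FALSE] > 0) == 0
  zero_m <- rowSums(cm[idx, sex == "M", drop = FALSE] > 0) == 0
  fidx <- match(results$gene, fpkm$gene)
  fm_m <- fm[fidx, sex == "M", drop = FALSE]
  fm_f <- fm[fidx, sex == "F", drop = FALSE]
  if (floor_mode == "mean") {
    expr_m <- rowMeans(fm_m) > fpkm_floor
    expr_f <- rowMeans(fm_f) > fpkm_floor
  } else {
    expr_m <- rowSums(fm_m > fpkm_floor) == ncol(fm_m)
    expr_f <- rowSums(fm_f > fpkm_floor) == ncol(fm_f)
  }
  is_deg <- results$bias_class != "unbiased"
  mutate(results, specificity = case_when(
    is_deg & zero_f & expr_m ~ "male-specific",
    is_deg & zero_m & expr_f ~ "female-specific",
    TRUE ~ "none"
  ))
}

# like counts_to_matrix but allows non-integer values (FPKM)
counts_to_matrix_lenient <- function(x) {
  if (!is.data.frame(x) || !"gene" %in% names(x)) {
    abort("expected a data frame with a `gene` column.")
  }
  m <- as.matrix(x[setdiff(names(x), "gene")])
  storage.mode(m) <- "double"
  rownames(m) <- x$gene
  m
}

#' Call sex-biased and sex-specific genes
#'
#' The full expression stage: size factors, NB test, BH adjustment, DEG
#' classification, FPKM and sex-specific flagging, returned as a single
#' fitted object with [generics::tidy()], [generics::glance()] and
#' [ggplot2::autoplot()] methods.
#'
#' @param counts Tibble with `gene` + sample columns.
#' @param design Sample sheet (`sample`, `sex`), >= 2 replicates per sex.
#' @param gene_lengths Tibble `gene`, `length` in bp (for FPKM).
#' @param alpha,lfc_threshold DEG thresholds (defaults 0.05 and 1).
#' @param fpkm_floor,floor_mode Sex-specific thresholds; see
#'   [classify_sex_specific()].
#' @return A `deg_fit` object: list with `results` (per-gene tibble),
#'   `fpkm`, `size_factors`, `design`, and the parameters used.
#' @examples
#' sim <- sim_config(seed = 2, n_genes = 300, n_male_biased = 10,
#'                   n_female_biased = 5, n_male_specific = 5,
#'                   n_female_specific = 5)
#' ug <- simulate_unigenes(sim)
#' cnt <- simulate_counts(sim, ug)
#' fit <- call_sex_biased_genes(cnt$counts, cnt$design, ug)
#' generics::glance(fit)
#' @export
call_sex_biased_genes <- function(counts, design, gene_lengths,
                                  alpha = 0.05, lfc_threshold = 1,
                                  fpkm_floor = 0.03,
                                  floor_mode = c("mean", "all")) {
  floor_mode <- match.arg(floor_mode)
  sf <- compute_size_factors(counts, pseudo_reference = TRUE)
  res <- test_differential(counts, design, sf)
  res$p_adj <- adjust_bh(res$p)
  res <- classify_deg(res, alpha = alpha, lfc_threshold = lfc_threshold)
  fpkm <- compute_fpkm(counts, gene_lengths)
  res <- classify_sex_specific(res, counts, fpkm, design,
                               fpkm_floor = fpkm_floor, floor_mode = floor_mode)
  structure(list(results = res, fpkm = fpkm, size_factors = sf,
                 design = design,
                 params = list(alpha = alpha, lfc_threshold = lfc_threshold,
                               fpkm_floor = fpkm_floor, floor_mode = floor_mode)),
            class = "deg_fit")
}

#' @export
print.deg_fit <- function(x, ...) {
  g <- glance(x)
  cat("<deg_fit>\n")
  cat(sprintf("  %d genes, %d DEGs (%d male-biased [%.1f%%], %d female-biased [%.1f%%])\n",
              g$n_genes, g$n_deg, g$n_male_biased, g$pct_male_biased,
              g$n_female_biased, g$pct_female_biased))
  cat(sprintf("  sex-specific: %d male, %d female\n",
              g$n_male_specific, g$n_female_specific))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy deg_fit
#' @export
tidy.deg_fit <- function(x, ...) x$results

#' @method glance deg_fit
#' @export
glance.deg_fit <- function(x, ...) {
  r <- x$results
  n_deg <- sum(r$bias_class != "unbiased")
  nm <- sum(r$bias_class == "male-biased")
  nf <- sum(r$bias_class == "female-biased")
  pct <- function(k) if (n_deg == 0) NA_real_ else 100 * k / n_deg
  tibble(
    n_genes = nrow(r), n_deg = n_deg,
    n_male_biased = nm, n_female_biased = nf,
    pct_male_biased = pct(nm), pct_female_biased = pct(nf),
    n_male_specific = sum(r$specificity == "male-specific"),
    n_female_specific = sum(r$specificity == "female-specific"),
    alpha = x$params$alpha, lfc_threshold = x$params$lfc_threshold
  )
}

#' Volcano plot of a differential-expression fit
#'
#' @param object A `deg_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot deg_fit
#' @export
autoplot.deg_fit <- function(object, ...) {
  r <- object$results
  ggplot2::ggplot(r, ggplot2::aes(x = .data$log2fc,
                                  y = -log10(pmax(.data$p_adj, 1e-300)),
                                  colour = .data$bias_class)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(
      "male-biased" = "#d62728", "female-biased" = "#2ca02c",
      "unbiased" = "grey60")) +
    ggplot2::labs(x = "log2 fold change (male / female)",
                  y = "-log10 adjusted p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Hierarchical clustering of samples on DEG expression
#'
#' Clusters samples on `log2(FPKM + 1)` of the supplied genes with
#' 1 - Pearson correlation distance and average linkage, and cuts the
#' tree into two groups. With clearly sex-biased genes the two groups
#' recover the sex labels.
#'
#' @param fpkm FPKM tibble (`gene` + sample columns).
#' @param design Sample sheet.
#' @param genes Character vector of gene ids to cluster on (>= 2).
#' @return A `sample_clustering` object: list with `hclust`, `partition`
#'   (tibble `sample`, `sex`, `cluster`), and `concordant` (TRUE when the
#'   two-group cut equals the sex labels).
#' @export
cluster_samples <- function(fpkm, design, genes) {
  if (length(genes) < 2) abort("need at least two genes to cluster samples.")
  fm <- counts_to_matrix_lenient(fpkm)
  check_design(design, samples = colnames(fm))
  idx <- match(genes, rownames(fm))
  if (anyNA(idx)) abort("some `genes` are missing from `fpkm`.")
  x <- log2(t(fm[idx, , drop = FALSE]) + 1)
  cc <- suppressWarnings(cor(t(x)))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 1
  d <- as.dist(1 - cc)
  hc <- stats::hclust(d, method = "average")
  grp <- stats::cutree(hc, k = 2)
  part <- tibble(sample = names(grp),
                 sex = design$sex[match(names(grp), design$sample)],
                 cluster = unname(grp))
  sex_grp <- split(part$sex, part$cluster)
  concordant <- length(sex_grp) == 2 &&
    all(vapply(sex_grp, function(s) length(unique(s)) == 1, logical(1))) &&
    sex_grp[[1]][1] != sex_grp[[2]][1]
  structure(list(hclust = hc, partition = part, concordant = concordant),
            class = "sample_clustering")
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat("<sample_clustering> 2-group cut",
      if (x$concordant) "matches" else "does not match", "sex labels\n")
  print(x$partition)
  invisible(x)
}

#' Write a sample dendrogram in Newick format
#'
#' @param clustering A `sample_clustering` from [cluster_samples()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_dendrogram <- function(clustering, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("the `ape` package is required to write Newick trees.")
  }
  phy <- ape::as.phylo(clustering$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
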
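#' Length-bias probability weights for enrichment testing
#'
#' Long transcripts accumulate more reads and are easier to call
#' differentially expressed, which biases naive enrichment tests toward
#' categories of long genes. This estimates each gene's probability of
#' being DE as a function of length by quantile binning: genes are split
#' into `n_bins` length bins and each gene's weight is the DE fraction of
#' its bin, clipped to `(1e-6, 1 - 1e-6)` so no weight is exactly 0 or 1.
#' (A monotone spline is the classical alternative; binned proportions
#' are a simpler, directly testable approximation.)
#'
#' @param genes Tibble with columns `gene`, `de` (logical), `length`.
#' @param n_bins Number of length-quantile bins (default 20).
#' @return The input with a `weight` column, class `pwf`.
#' @export
build_pwf <- function(genes, n_bins = 20L) {
  if (!all(c("gene", "de", "length") %in% names(genes))) {
    abort("`genes` needs columns `gene`, `de`, `length`.")
  }
  if (anyDuplicated(genes$gene)) abort("duplicated gene ids in `genes`.")
  if (all(genes$de) || !any(genes$de)) {
    abort("the universe must contain at least one DE and one non-DE gene.")
  }
  eps <- 1e-6
  if (n_bins <= 1L) {
    w <- rep(mean(genes$de), nrow(genes))
  } else {
    br <- unique(quantile(genes$length, probs = seq(0, 1, length.out = n_bins + 1)))
    bin <- cut(genes$length, breaks = br, include.lowest = TRUE, labels = FALSE)
    w <- stats::ave(as.numeric(genes$de), bin)
  }
  out <- mutate(genes, weight = pmin(pmax(w, eps), 1 - eps))
  class(out) <- c("pwf", class(out))
  out
}

#' Wallenius noncentral hypergeometric probabilities
#'
#' Mass function of the Wallenius biased-urn model: `m1` category balls
#' with odds `omega` each, `m2` others with odds 1, `n` sequential draws
#' without replacement. Computed by the exact draw-by-draw recursion for
#' `m1 + m2 <= 2000`; beyond that a normal approximation is used (mean
#' from the Wallenius mean equation solved numerically, variance from
#' the matching central model scaled by the odds; adequate for tail
#' screening at that size, not for printed-precision work).
#'
#' @param m1 Category size.
#' @param m2 Complement size.
#' @param n Number of draws.
#' @param omega Odds parameter (> 0); `omega = 1` is the central
#'   hypergeometric.
#' @return Numeric vector of probabilities for counts `0:min(n, m1)`.
#' @export
dwallenius <- function(m1, m2, n, omega) {
  stopifnot(m1 >= 0, m2 >= 0, n >= 0, n <= m1 + m2, omega > 0)
  if (m1 + m2 > 2000) return(dwallenius_normal(m1, m2, n, omega))
  kmax <- min(n, m1)
  f <- c(1, rep(0, kmax))
  if (n == 0) return(f)
  for (j in seq_len(n) - 1L) {
    xs <- 0:min(j, kmax)
    fx <- f[xs + 1L]
    wcat <- omega * (m1 - xs)
    woth <- pmax(m2 - (j - xs), 0)
    tot <- wcat + woth
    p_take <- ifelse(tot > 0, wcat / tot, 0)
    p_stay <- ifelse(tot > 0, woth / tot, 0)
    newf <- numeric(kmax + 1L)
    newf[xs + 1L] <- fx * p_stay
    idx <- xs + 2L
    keep <- idx <= kmax + 1L
    newf[idx[keep]] <- newf[idx[keep]] + (fx * p_take)[keep]
    f <- newf
  }
  f
}

# normal approximation for large urns: solve the Wallenius mean equation
# mu/m1 + (1 - (n - mu)/m2)^omega = 1 ... classical first-order form
dwallenius_normal <- function(m1, m2, n, omega) {
  kmax <- min(n, m1)
  mean_eq <- function(mu) mu / m1 - (1 - (1 - (n - mu) / m2)^omega)
  lo <- max(0, n - m2) + 1e-9
  hi <- kmax - 1e-9
  mu <- tryCatch(stats::uniroot(mean_eq, c(lo, hi))$root,
                 error = function(e) n * m1 * omega / (m1 * omega + m2))
  v <- n * (mu / n) * (1 - mu / n) * ((m1 + m2 - n) / (m1 + m2 - 1))
  v <- max(v, 1e-12)
  x <- 0:kmax
  p <- stats::pnorm(x + 0.5, mu, sqrt(v)) - stats::pnorm(x - 0.5, mu, sqrt(v))
  p / sum(p)
}

# upper-tail P(X >= k)
pwallenius_upper <- function(k, m1, m2, n, omega) {
  f <- dwallenius(m1, m2, n, omega)
  if (k <= 0) return(1)
  kmax <- min(n, m1)
  if (k > kmax) return(0)
  min(1, sum(f[seq(k + 1L, kmax + 1L)]))
}

#' Wallenius test for category over-representation
#'
#' Length-bias-aware one-sided enrichment test. The odds parameter is the
#' mean probability weight of genes inside the category divided by the
#' mean weight outside; the p-value is the upper tail `P(X >= k)` of the
#' Wallenius noncentral hypergeometric with that odds. With uniform
#' weights the odds are 1 and the test reduces to the central
#' hypergeometric.
#'
#' @param category_genes Character vector of gene ids in the category
#'   (non-empty, within the universe).
#' @param pwf Output of [build_pwf()] (defines the universe, DE flags
#'   and weights).
#' @return List with `p`, `odds`, `n_category`, `n_de`, `overlap`,
#'   `expected`.
#' @export
wallenius_test <- function(category_genes, pwf) {
  category_genes <- unique(category_genes)
  if (length(category_genes) == 0) abort("empty category.")
  if (!all(category_genes %in% pwf$gene)) {
    abort("category contains genes outside the universe.")
  }
  inside <- pwf$gene %in% category_genes
  m1 <- sum(inside)
  m2 <- sum(!inside)
  n_de <- sum(pwf$de)
  k <- sum(pwf$de & inside)
  odds <- if (m2 == 0) 1 else mean(pwf$weight[inside]) / mean(pwf$weight[!inside])
  p <- pwallenius_upper(k, m1, m2, n_de, odds)
  expected <- sum(dwallenius(m1, m2, n_de, odds) * 0:min(n_de, m1))
  list(p = p, odds = odds, n_category = m1, n_de = n_de,
       overlap = k, expected = expected)
}

#' Central hypergeometric test for category over-representation
#'
#' Exact upper-tail test with no length-bias modelling; the fallback when
#' no probability weights are available.
#'
#' @param category_genes Character vector of gene ids in the category.
#' @param universe Tibble with columns `gene`, `de`.
#' @return List with `p`, `n_category`, `n_de`, `overlap`, `expected`.
#' @export
hypergeometric_test <- function(category_genes, universe) {
  category_genes <- unique(category_genes)
  if (length(category_genes) == 0) abort("empty category.")
  if (!all(category_genes %in% universe$gene)) {
    abort("category contains genes outside the universe.")
  }
  inside <- universe$gene %in% category_genes
  m1 <- sum(inside); m2 <- sum(!inside)
  n_de <- sum(universe$de)
  k <- sum(universe$de & inside)
  p <- stats::phyper(k - 1, m1, m2, n_de, lower.tail = FALSE)
  list(p = p, n_category = m1, n_de = n_de, overlap = k,
       expected = n_de * m1 / (m1 + m2))
}

#' Test every category for DEG enrichment
#'
#' Runs the Wallenius (default) or central hypergeometric test on each
#' category, adjusts p-values across categories with Benjamini-Hochberg
#' (reported as a q-value), and reports each category's rich factor -
#' the number of DE genes in the category divided by the number of
#' universe genes annotated to it.
#'
#' By default the universe is restricted to genes that appear in the
#' annotation map (genes without any annotation carry no signal for any
#' category); set `universe = "all"` to keep every gene in `pwf`.
#'
#' @param category_map Tibble with columns `gene`, `category` (no
#'   duplicated gene-category pairs), optionally `label`.
#' @param pwf Output of [build_pwf()].
#' @param method `"wallenius"` (default) or `"hypergeometric"`.
#' @param universe `"annotated"` (default) or `"all"`.
#' @return An `enrichment_result` tibble, sorted by p: `category`,
#'   `n_genes`, `n_de`, `expected`, `odds`, `rich_factor`, `p`, `q`.
#' @export
enrich_all <- function(category_map, pwf,
                       method = c("wallenius", "hypergeometric"),
                       universe = c("annotated", "all")) {
  method <- match.arg(method)
  universe <- match.arg(universe)
  if (!all(c("gene", "category") %in% names(category_map))) {
    abort("`category_map` needs columns `gene` and `category`.")
  }
  if (anyDuplicated(category_map[c("gene", "category")])) {
    abort("duplicated gene-category pairs in `category_map`.")
  }
  uni <- pwf
  if (universe == "annotated") {
    uni <- filter(pwf, .data$gene %in% category_map$gene)
  }
  map <- filter(category_map, .data$gene %in% uni$gene)
  cats <- split(map$gene, map$category)
  if (length(cats) == 0) {
    res <- tibble(category = character(), n_genes = integer(), n_de = integer(),
                  expected = numeric(), odds = numeric(), rich_factor = numeric(),
                  p = numeric(), q = numeric())
    class(res) <- c("enrichment_result", class(res))
    return(res)
  }
  no_de <- !any(uni$de)
  rows <- purrr::imap(cats, function(genes, cat_id) {
    if (no_de) {
      m1 <- length(unique(genes))
      return(tibble(category = cat_id, n_genes = m1, n_de = 0L,
                    expected = 0, odds = NA_real_, rich_factor = 0, p = 1))
    }
    t <- if (method == "wallenius") wallenius_test(genes, uni)
         else c(hypergeometric_test(genes, uni), list(odds = NA_real_))
    tibble(category = cat_id, n_genes = t$n_category, n_de = t$overlap,
           expected = t$expected, odds = t$odds,
           rich_factor = t$overlap / t$n_category, p = t$p)
  })
  res <- bind_rows(rows)
  res$q <- adjust_bh(res$p)
  res <- arrange(res, .data$p, .data$category)
  class(res) <- c("enrichment_result", class(res))
  res
}

#' Rich-factor dot plot of enrichment results
#'
#' @param object An `enrichment_result` from [enrich_all()].
#' @param top Number of top categories to show (default 20).
#' @param ... Unused.
#' @return A ggplot object: rich factor on x, categories on y, dot size
#'   the DE gene count, colour the q-value.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, top = 20, ...) {
  d <- utils::head(as_tibble(object), top)
  d$category <- factor(d$category, levels = rev(d$category))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rich_factor, y = .data$category,
                                  size = .data$n_de, colour = .data$q)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient(low = "#d62728", high = "#1f77b4") +
    ggplot2::labs(x = "rich factor (DE genes / annotated genes)", y = NULL,
                  size = "DE genes", colour = "q-value") +
    ggplot2::theme_minimal()
}
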
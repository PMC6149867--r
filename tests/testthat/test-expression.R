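test_that("size factors match the median-of-ratios definition", {
  # two identical columns -> symmetric factors of 1
  eq <- tibble::tibble(gene = c("g1", "g2"), s1 = c(10, 30), s2 = c(10, 30))
  expect_equal(compute_size_factors(eq)$size_factor, c(1, 1))

  # hand computation: ratios 100/sqrt(100*200), 300/sqrt(300*600)
  h <- tibble::tibble(gene = c("g1", "g2"), s1 = c(100, 300), s2 = c(200, 600))
  expect_equal(compute_size_factors(h)$size_factor, c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)

  # scaling a sample by c multiplies its factor by c... up to renormalization
  # of the geometric-mean reference, so test the ratio of factors
  sc <- h
  sc$s2 <- sc$s2 * 4
  f1 <- compute_size_factors(h)$size_factor
  f2 <- compute_size_factors(sc)$size_factor
  expect_equal(f2[2] / f2[1], 4 * f1[2] / f1[1], tolerance = 1e-12)

  # no all-positive gene: explicit error naming the fallback flag
  z <- tibble::tibble(gene = c("g1", "g2"),
                      s1 = c(0, 5), s2 = c(5, 0), s3 = c(6, 7))
  expect_error(compute_size_factors(z), "pseudo_reference")
  expect_silent(compute_size_factors(z, pseudo_reference = TRUE))
})

test_that("FPKM follows its defining formula", {
  counts <- tibble::tibble(gene = c("g1", "g2"), s1 = c(10, 0))
  len <- tibble::tibble(gene = c("g1", "g2"), length = c(2000L, 1000L))
  lib <- tibble::tibble(sample = "s1", library_size = 1e6)
  f <- compute_fpkm(counts, len, lib)
  expect_equal(f$s1, c(5, 0))

  # doubling length halves FPKM
  len2 <- dplyr::mutate(len, length = length * 2)
  expect_equal(compute_fpkm(counts, len2, lib)$s1, c(2.5, 0))

  # zero/negative length errors and names the gene
  bad <- tibble::tibble(gene = c("g1", "g2"), length = c(0L, 1000L))
  expect_error(compute_fpkm(counts, bad, lib), "g1")

  # FPKM is zero iff the count is zero
  cfg <- small_config(seed = 21)
  ug <- simulate_unigenes(cfg)
  sim <- simulate_counts(cfg, ug)
  fpkm <- compute_fpkm(sim$counts, ug)
  expect_identical(as.matrix(fpkm[-1]) == 0, as.matrix(sim$counts[-1]) == 0)
})

test_that("BH adjustment matches a brute-force step-up oracle", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.5, 1.2)), "0, 1")

  set.seed(42)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    expect_equal(adjust_bh(p), bh_oracle(p), tolerance = 1e-14)
  }
})

test_that("the NB test is calibrated on null data and degenerate genes", {
  # all-zero gene
  counts <- tibble::tibble(gene = "g1", F1 = 0L, F2 = 0L, F3 = 0L,
                           M1 = 0L, M2 = 0L, M3 = 0L)
  counts <- dplyr::bind_rows(counts,
    tibble::tibble(gene = "g2", F1 = 10L, F2 = 12L, F3 = 9L,
                   M1 = 11L, M2 = 10L, M3 = 13L))
  r <- test_differential(counts, design_3v3())
  expect_equal(r$log2fc[1], 0)
  expect_equal(r$p[1], 1)

  # <2 replicates per group errors
  d2 <- tibble::tibble(sample = c("F1", "M1"), sex = c("F", "M"))
  c2 <- tibble::tibble(gene = "g1", F1 = 5L, M1 = 9L)
  expect_error(test_differential(c2, d2), "per sex")

  # null simulation: 10,000 NB genes, 3v3, fraction p < 0.05 in 0.05 +- 0.01
  set.seed(101)
  G <- 10000
  m <- matrix(rnbinom(G * 6, mu = 100, size = 20), G)
  colnames(m) <- design_3v3()$sample
  null_counts <- dplyr::bind_cols(tibble::tibble(gene = sprintf("g%05d", 1:G)),
                                  tibble::as_tibble(m))
  rn <- test_differential(null_counts, design_3v3())
  expect_lt(abs(mean(rn$p < 0.05) - 0.05), 0.01)
})

test_that("label symmetry: swapping sexes negates log2fc and swaps classes", {
  cfg <- small_config(seed = 23)
  ug <- simulate_unigenes(cfg)
  sim <- simulate_counts(cfg, ug)
  swapped <- dplyr::mutate(sim$design, sex = ifelse(sex == "M", "F", "M"))
  r1 <- test_differential(sim$counts, sim$design)
  r2 <- test_differential(sim$counts, swapped)
  expect_equal(r2$log2fc, -r1$log2fc, tolerance = 1e-10)
  expect_equal(r2$p, r1$p, tolerance = 1e-10)

  f1 <- call_sex_biased_genes(sim$counts, sim$design, ug)
  f2 <- call_sex_biased_genes(sim$counts, swapped, ug)
  map <- c("male-biased" = "female-biased", "female-biased" = "male-biased",
           "unbiased" = "unbiased")
  expect_equal(unname(map[f1$results$bias_class]), f2$results$bias_class)
})

test_that("scaling one sample's counts leaves log2fc unchanged", {
  cfg <- small_config(seed = 25)
  ug <- simulate_unigenes(cfg)
  sim <- simulate_counts(cfg, ug)
  r1 <- test_differential(sim$counts, sim$design)
  scaled <- dplyr::mutate(sim$counts, M2 = M2 * 5L)
  r2 <- test_differential(scaled, sim$design)
  # exact for genes with both group means positive; genes with a zero
  # group mean use a fixed pseudo-count, which is not scale-free, so for
  # those only the call (sign at the +-1 threshold) is required to hold
  pos <- r1$base_mean_m > 0 & r1$base_mean_f > 0
  expect_equal(r2$log2fc[pos], r1$log2fc[pos], tolerance = 1e-10)
  expect_equal(sign(r2$log2fc), sign(r1$log2fc))
  expect_equal(abs(r2$log2fc) >= 1, abs(r1$log2fc) >= 1)
})

test_that("DEG and sex-specific classification rules follow printed operators", {
  res <- tibble::tibble(
    gene = paste0("g", 1:5),
    log2fc = c(6, -6, 0.5, 3, 1),
    p_adj = c(0.01, 0.01, 0.04, 0.05, 0.049))
  cls <- classify_deg(res)
  expect_equal(cls$bias_class,
               c("male-biased", "female-biased", "unbiased",
                 "unbiased",  # p_adj == alpha excluded: strict inequality
                 "male-biased"))  # |log2fc| == threshold included

  # sex-specific: zero counts in one sex and FPKM floor on the other
  design <- design_3v3()
  counts <- tibble::tibble(gene = paste0("g", 1:4),
                           F1 = c(0L, 0L, 0L, 5L), F2 = c(0L, 0L, 0L, 5L),
                           F3 = c(0L, 0L, 1L, 5L),
                           M1 = c(50L, 2L, 50L, 500L), M2 = c(60L, 2L, 60L, 500L),
                           M3 = c(55L, 2L, 55L, 500L))
  fpkm <- tibble::tibble(gene = paste0("g", 1:4),
                         F1 = c(0, 0, 0, 0.5), F2 = c(0, 0, 0, 0.5),
                         F3 = c(0, 0, 0.1, 0.5),
                         M1 = c(1.2, 0.02, 5, 50), M2 = c(1.3, 0.02, 5, 50),
                         M3 = c(1.1, 0.02, 5, 50))
  res <- tibble::tibble(gene = paste0("g", 1:4),
                        bias_class = c("male-biased", "male-biased",
                                       "male-biased", "male-biased"))
  out <- classify_sex_specific(res, counts, fpkm, design)
  expect_equal(out$specificity,
               c("male-specific",
                 "none",   # mean male FPKM 0.02 <= 0.03
                 "none",   # a female replicate is non-zero
                 "none"))  # females expressed

  # a gene not called a DEG can never be sex-specific
  res$bias_class <- "unbiased"
  expect_true(all(classify_sex_specific(res, counts, fpkm, design)$specificity == "none"))
})

test_that("sex-specific calls agree with the truth manifest both ways", {
  cfg <- sim_config(seed = 29, n_genes = 600, n_male_biased = 10,
                    n_female_biased = 10, n_male_specific = 12,
                    n_female_specific = 9)
  ug <- simulate_unigenes(cfg)
  sim <- simulate_counts(cfg, ug)
  fit <- call_sex_biased_genes(sim$counts, sim$design, ug)
  res <- dplyr::left_join(fit$results, sim$truth, by = "gene")
  expect_identical(res$gene[res$specificity == "male-specific"],
                   res$gene[res$class == "male-specific"])
  expect_identical(res$gene[res$specificity == "female-specific"],
                   res$gene[res$class == "female-specific"])
})

test_that("sample clustering separates sexes and is order-invariant", {
  cfg <- small_config(seed = 31)
  ug <- simulate_unigenes(cfg)
  sim <- simulate_counts(cfg, ug)
  fit <- call_sex_biased_genes(sim$counts, sim$design, ug)
  degs <- fit$results$gene[fit$results$bias_class != "unbiased"]
  expect_gte(length(degs), 2)
  cl <- cluster_samples(fit$fpkm, sim$design, degs)
  expect_true(cl$concordant)

  # permuting sample order does not change the partition (up to relabeling)
  perm <- c(1, 4, 2, 5, 3, 6) + 1  # +1 skips the gene column
  fpkm_perm <- fit$fpkm[c(1, perm)]
  cl2 <- cluster_samples(fpkm_perm, sim$design, degs)
  membership <- function(cl) {
    p <- cl$partition[order(cl$partition$sample), ]
    p$cluster == p$cluster[1]  # same-group-as-first-sample indicator
  }
  expect_equal(membership(cl), membership(cl2))

  # two identical samples merge at height 0
  f2 <- fit$fpkm
  f2$F2 <- f2$F1
  cl3 <- cluster_samples(f2, sim$design, degs)
  expect_equal(min(cl3$hclust$height), 0, tolerance = 1e-12)

  expect_error(cluster_samples(fit$fpkm, sim$design, degs[1]), "two genes")
})

test_that("tidy, glance and autoplot expose the fit", {
  cfg <- small_config(seed = 33)
  ug <- simulate_unigenes(cfg)
  sim <- simulate_counts(cfg, ug)
  fit <- call_sex_biased_genes(sim$counts, sim$design, ug)
  td <- generics::tidy(fit)
  expect_true(all(c("gene", "log2fc", "p", "p_adj", "bias_class", "specificity")
                  %in% names(td)))
  g <- generics::glance(fit)
  expect_equal(g$n_deg, g$n_male_biased + g$n_female_biased)
  expect_true(all(td$p_adj >= td$p))
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
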
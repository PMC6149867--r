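test_that("VCF loading expands genotypes and flags no-calls", {
  cfg <- small_config(seed = 41)
  ug <- simulate_unigenes(cfg)
  v <- simulate_variants(cfg, ug)
  design <- design_3v3()
  dir <- tempfile(); dir.create(dir)
  vcf <- file.path(dir, "v.vcf")
  write_vcf(v$sites, v$calls, design, vcf)
  calls <- read_genotypes_vcf(vcf, design)

  expect_setequal(unique(calls$sample), design$sample)
  expect_equal(nrow(calls), cfg$n_snp_sites * nrow(design))

  # homozygous ref/alt map to the right base; het becomes NA
  joined <- dplyr::left_join(v$calls, v$sites, by = c("gene", "pos")) |>
    dplyr::left_join(calls, by = c("gene", "pos", "sample"))
  expect_true(all(joined$allele[joined$gt == "0/0"] ==
                    joined$ref[joined$gt == "0/0"]))
  expect_true(all(joined$allele[joined$gt == "1/1"] ==
                    joined$alt[joined$gt == "1/1"]))
  expect_true(all(is.na(joined$allele[joined$gt == "0/1"])))
  expect_equal(joined$depth, joined$dp)

  # a VCF sample missing from the sheet errors
  expect_error(read_genotypes_vcf(vcf, design[-1, ]), "sample")
  unlink(dir, recursive = TRUE)
})

test_that("the flat genotype-table loader reproduces the published layout", {
  tab <- system.file("extdata", "sex_associated_genotypes.tsv", package = "dioseq")
  design <- read_sample_sheet(
    system.file("extdata", "euco_samples.tsv", package = "dioseq"))
  calls <- read_genotype_table(tab, design, depth = 5L)
  expect_equal(nrow(calls), 9 * 6)  # 9 positions x 6 individuals
  expect_equal(dplyr::n_distinct(calls$gene), 5)
  one <- calls[calls$gene == "Cluster-47702.80936" & calls$pos == 1101, ]
  expect_equal(one$allele[one$sex == "F"], c("C", "C", "C"))
  expect_equal(one$allele[one$sex == "M"], c("G", "G", "G"))
})

test_that("depth filtering is boundary-inclusive and drops partial positions", {
  base <- calls_from_alleles(c("C", "C", "C"), c("G", "G", "G"))
  d <- design_3v3()

  at5 <- dplyr::mutate(base, depth = 5L)
  expect_equal(nrow(filter_min_depth(at5, d, 5)), 6)

  one_low <- at5
  one_low$depth[4] <- 4L
  expect_equal(nrow(filter_min_depth(one_low, d, 5)), 0)

  # a position missing one individual is ineligible
  partial <- at5[-2, ]
  expect_equal(nrow(filter_min_depth(partial, d, 5)), 0)

  expect_equal(nrow(filter_min_depth(at5[0, ], d, 5)), 0)
  expect_error(filter_min_depth(at5, d, 0), "min_depth")
})

test_that("segregation calls match hand-worked examples", {
  d <- design_3v3()
  seg <- find_sex_segregating(calls_from_alleles(c("C", "C", "C"),
                                                 c("G", "G", "G")), d)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$female_allele, "C")
  expect_equal(seg$male_allele, "G")

  # males not uniform -> rejected
  expect_equal(nrow(find_sex_segregating(
    calls_from_alleles(c("C", "C", "C"), c("G", "G", "C")), d)), 0)
  # shared allele -> rejected
  expect_equal(nrow(find_sex_segregating(
    calls_from_alleles(c("C", "C", "C"), c("C", "C", "C")), d)), 0)
  # any no-call -> rejected
  expect_equal(nrow(find_sex_segregating(
    calls_from_alleles(c("C", "C", NA), c("G", "G", "G")), d)), 0)
})

test_that("filter equals the brute-force definition on all 6-individual assignments", {
  d <- design_3v3()
  # exhaustive: every assignment of {A, C} to 6 individuals, 1-3 positions
  combos <- expand.grid(rep(list(c("A", "C")), 6), stringsAsFactors = FALSE)
  all_calls <- lapply(seq_len(nrow(combos)), function(i) {
    calls_from_alleles(unlist(combos[i, 1:3]), unlist(combos[i, 4:6]),
                       gene = sprintf("g%02d", (i - 1) %% 7),
                       pos = 10L * i)
  })
  calls <- dplyr::bind_rows(all_calls)
  got <- find_sex_segregating(calls, d)
  want <- segregating_oracle(calls, d)
  expect_equal(nrow(got), nrow(want))
  expect_equal(got[c("gene", "pos", "female_allele", "male_allele")],
               want, ignore_attr = TRUE)
  # sanity: exactly 2 of the 64 assignments segregate, at every position set
  expect_equal(nrow(got), 2)
})

test_that("planted sites are recovered exactly over 20 seeded replicates", {
  d <- design_3v3()
  for (seed in 1:20) {
    cfg <- small_config(seed = 1000L + seed)
    ug <- simulate_unigenes(cfg)
    v <- simulate_variants(cfg, ug)
    dir <- tempfile(); dir.create(dir)
    vcf <- file.path(dir, "v.vcf")
    write_vcf(v$sites, v$calls, d, vcf)
    calls <- read_genotypes_vcf(vcf, d)
    found <- find_sex_segregating(filter_min_depth(calls, d, cfg$min_planted_depth), d)
    planted <- v$truth_sites[v$truth_sites$kind == "segregating", ]
    expect_setequal(paste(found$gene, found$pos),
                    paste(planted$gene, planted$pos))
    expect_equal(
      found$female_allele[order(found$gene, found$pos)],
      planted$female_allele[order(planted$gene, planted$pos)])
    unlink(dir, recursive = TRUE)
  }
})

test_that("sex-swap symmetry and depth monotonicity hold", {
  cfg <- small_config(seed = 43)
  ug <- simulate_unigenes(cfg)
  v <- simulate_variants(cfg, ug)
  d <- design_3v3()
  calls <- dplyr::left_join(v$calls, v$sites, by = c("gene", "pos")) |>
    dplyr::mutate(
      allele = ifelse(gt == "0/0", ref, ifelse(gt == "1/1", alt, NA)),
      sex = d$sex[match(sample, d$sample)],
      depth = dp) |>
    dplyr::select(gene, pos, sample, sex, allele, depth)

  swapped_design <- dplyr::mutate(d, sex = ifelse(sex == "M", "F", "M"))
  swapped_calls <- dplyr::mutate(calls, sex = ifelse(sex == "M", "F", "M"))
  s1 <- find_sex_segregating(calls, d)
  s2 <- find_sex_segregating(swapped_calls, swapped_design)
  expect_equal(s1[c("gene", "pos")], s2[c("gene", "pos")])
  expect_equal(s1$female_allele, s2$male_allele)
  expect_equal(s1$male_allele, s2$female_allele)

  # raising min_depth never adds a site
  prev <- NULL
  for (md in c(1, 3, 5, 10, 20, 40)) {
    sites <- find_sex_segregating(filter_min_depth(calls, d, md), d)
    key <- paste(sites$gene, sites$pos)
    if (!is.null(prev)) expect_true(all(key %in% prev))
    prev <- key
  }
})

test_that("per-gene summary groups sites and counts genes once", {
  sites <- tibble::tibble(gene = c("gA", "gA", "gB"),
                          pos = c(360L, 460L, 100L),
                          female_allele = c("T", "G", "C"),
                          male_allele = c("C", "A", "G"))
  rep <- summarize_sex_genes(sites)
  expect_equal(rep$n_genes, 2)
  expect_equal(rep$genes$n_sites, c(2, 1))
  expect_equal(generics::glance(rep)$n_sites, 3)
  empty <- summarize_sex_genes(sites[0, ])
  expect_equal(empty$n_genes, 0)
})

test_that("segregation null rate equals exhaustive enumeration", {
  # enumeration oracle: all 2^n assignments of two alleles, both present
  enum_rate <- function(n_m, n_f) {
    n <- n_m + n_f
    combos <- expand.grid(rep(list(c(0, 1)), n))
    poly <- combos[rowSums(combos) %in% seq_len(n - 1), ]
    sex <- c(rep("F", n_f), rep("M", n_m))
    seg <- apply(poly, 1, function(a) {
      length(unique(a[sex == "F"])) == 1 &&
        length(unique(a[sex == "M"])) == 1 &&
        a[sex == "F"][1] != a[sex == "M"][1]
    })
    mean(seg)
  }
  expect_equal(segregation_null_rate(3, 3), 2 / 62)
  expect_equal(segregation_null_rate(3, 3), enum_rate(3, 3))
  expect_equal(segregation_null_rate(1, 1), 1)
  expect_equal(segregation_null_rate(2, 4), enum_rate(2, 4))
  for (nm in 1:3) for (nf in 1:3) {
    r <- segregation_null_rate(nm, nf)
    expect_true(r > 0 && r <= 1)
  }
})
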
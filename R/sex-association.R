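#' Load per-individual genotype calls from a multi-sample VCF
#'
#' Reads biallelic SNP records and expands genotypes to one allele per
#' individual: homozygous `0/0` or `1/1` become the REF or ALT base;
#' heterozygous or missing genotypes become a no-call (`NA` allele) for
#' that individual at that site. Per-sample `DP` is propagated (missing
#' DP becomes 0). Positions are the VCF `POS`, 1-based along the unigene
#' from the 5' end.
#'
#' @param path VCF file (v4.2, FORMAT including GT and DP).
#' @param design Sample sheet; every VCF sample must appear with a sex.
#' @return Tibble of genotype calls: `gene`, `pos`, `sample`, `sex`,
#'   `allele` (single base or NA), `depth`.
#' @export
read_genotypes_vcf <- function(path, design) {
  check_design(design)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble(gene = character(), pos = integer(), sample = character(),
                  sex = character(), allele = character(), depth = integer()))
  }
  samples <- colnames(v@gt)[-1]
  missing <- setdiff(samples, design$sample)
  if (length(missing) > 0) {
    abort(paste0("VCF sample(s) not in the sample sheet: ",
                 paste(missing, collapse = ", ")))
  }
  keep <- !is.na(fix$ALT) & fix$REF %in% c("A", "C", "G", "T") &
    fix$ALT %in% c("A", "C", "G", "T")
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  dp[is.na(dp)] <- 0
  out <- lapply(seq_along(samples), function(j) {
    g <- gt[keep, j]
    g <- gsub("\\|", "/", g)
    allele <- ifelse(g %in% c("0/0", "0"), fix$REF[keep],
                     ifelse(g %in% c("1/1", "1"), fix$ALT[keep], NA_character_))
    tibble(gene = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
           sample = samples[j],
           allele = allele, depth = as.integer(dp[keep, j]))
  })
  calls <- bind_rows(out)
  calls$sex <- design$sex[match(calls$sample, design$sample)]
  arrange(calls[c("gene", "pos", "sample", "sex", "allele", "depth")],
          .data$gene, .data$pos, .data$sample)
}

#' Load genotype calls from a flat per-individual allele table
#'
#' Reads a table with columns `Gene_ID`, `Position`, then one single-base
#' allele column per individual (a trailing `Regulation` column is
#' ignored) - the layout of published sex-associated genotype tables.
#' Entries that are not a single A/C/G/T base are no-calls.
#'
#' @param path Tab-separated genotype table.
#' @param design Sample sheet; individual columns must match
#'   `design$sample`.
#' @param depth Constant read depth to assign to every call (the flat
#'   layout carries no depth; default 5 marks all calls as passing the
#'   usual depth criterion). May also be `NA` to leave depth unknown.
#' @return Tibble of genotype calls, as [read_genotypes_vcf()].
#' @export
read_genotype_table <- function(path, design, depth = 5L) {
  check_design(design)
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  names(tab)[1:2] <- c("gene", "pos")
  tab$Regulation <- NULL
  ind_cols <- setdiff(names(tab), c("gene", "pos"))
  missing <- setdiff(ind_cols, design$sample)
  if (length(missing) > 0) {
    abort(paste0("genotype table column(s) not in the sample sheet: ",
                 paste(missing, collapse = ", ")))
  }
  # rows in grouped tables may leave Gene_ID blank under the group header
  tab <- tidyr::fill(tab, "gene", .direction = "down")
  calls <- tab |>
    pivot_longer(all_of(ind_cols), names_to = "sample", values_to = "allele") |>
    mutate(
      pos = as.integer(.data$pos),
      allele = ifelse(.data$allele %in% c("A", "C", "G", "T"),
                      .data$allele, NA_character_),
      sex = design$sex[match(.data$sample, design$sample)],
      depth = as.integer(depth)
    )
  arrange(calls[c("gene", "pos", "sample", "sex", "allele", "depth")],
          .data$gene, .data$pos, .data$sample)
}

#' Keep positions covered at a minimum depth in every individual
#'
#' A position is retained only when every individual in `design` has a
#' call there with depth at least `min_depth` (boundary inclusive). With
#' deduplicated alignments upstream, depth counts unique reads.
#'
#' @param calls Genotype-call tibble ([read_genotypes_vcf()] layout).
#' @param design Sample sheet defining the full individual set.
#' @param min_depth Minimum per-individual depth (default 5).
#' @return Filtered genotype-call tibble.
#' @export
filter_min_depth <- function(calls, design, min_depth = 5L) {
  if (min_depth < 1) abort("`min_depth` must be >= 1.")
  if (nrow(calls) == 0) return(calls)
  check_design(design)
  ok <- calls |>
    group_by(.data$gene, .data$pos) |>
    summarise(
      keep = sum(!is.na(.data$depth) & .data$depth >= min_depth &
                   .data$sample %in% design$sample) >= nrow(design),
      .groups = "drop"
    ) |>
    filter(.data$keep)
  semi_join(calls, ok, by = c("gene", "pos"))
}

#' Find SNP sites that segregate perfectly by sex
#'
#' The core segregation filter: a site is reported iff every individual
#' has a usable call there (no-calls disqualify the position), all
#' females carry a single base X, all males a single base Y, and X != Y.
#' Such a site is by construction polymorphic across the individuals.
#' Apply [filter_min_depth()] first to enforce the depth criterion.
#'
#' @param calls Genotype-call tibble.
#' @param design Sample sheet (full individual set; >= 1 per sex).
#' @param het_policy `"nocall"` (default): a heterozygous call was already
#'   recorded as a no-call by the loaders, so it disqualifies its position
#'   via the completeness rule. `"fail-site"` is an alias making that
#'   intent explicit; both policies reject the site.
#' @return Tibble of sex-segregating sites sorted by gene then position:
#'   `gene`, `pos`, `female_allele`, `male_allele`, plus one audit column
#'   per individual carrying its allele.
#' @export
find_sex_segregating <- function(calls, design,
                                 het_policy = c("nocall", "fail-site")) {
  het_policy <- match.arg(het_policy)
  check_design(design)
  empty <- tibble(gene = character(), pos = integer(),
                  female_allele = character(), male_allele = character())
  if (nrow(calls) == 0) return(empty)
  wide <- calls |>
    filter(.data$sample %in% design$sample) |>
    group_by(.data$gene, .data$pos) |>
    summarise(
      n_called = sum(!is.na(.data$allele)),
      n_present = n(),
      f_alleles = list(unique(.data$allele[.data$sex == "F"])),
      m_alleles = list(unique(.data$allele[.data$sex == "M"])),
      .groups = "drop"
    ) |>
    filter(.data$n_present == nrow(design), .data$n_called == nrow(design)) |>
    mutate(
      female_allele = map_chr(.data$f_alleles, function(a) if (length(a) == 1) a else NA_character_),
      male_allele = map_chr(.data$m_alleles, function(a) if (length(a) == 1) a else NA_character_)
    ) |>
    filter(!is.na(.data$female_allele), !is.na(.data$male_allele),
           .data$female_allele != .data$male_allele) |>
    select("gene", "pos", "female_allele", "male_allele")
  if (nrow(wide) == 0) return(empty)
  audit <- calls |>
    semi_join(wide, by = c("gene", "pos")) |>
    select("gene", "pos", "sample", "allele") |>
    pivot_wider(names_from = "sample", values_from = "allele")
  left_join(wide, audit, by = c("gene", "pos")) |>
    arrange(.data$gene, .data$pos)
}

#' Summarise sex-segregating sites into a per-gene report
#'
#' @param sites Output of [find_sex_segregating()].
#' @return A `sex_gene_report`: list with `sites` (the input, grouped by
#'   gene), `genes` (tibble `gene`, `n_sites`, `positions`), and
#'   `n_genes` (the putative sex-associated gene count).
#' @export
summarize_sex_genes <- function(sites) {
  genes <- sites |>
    group_by(.data$gene) |>
    summarise(n_sites = n(),
              positions = paste(sort(.data$pos), collapse = ","),
              .groups = "drop") |>
    arrange(.data$gene)
  structure(list(sites = arrange(sites, .data$gene, .data$pos),
                 genes = genes, n_genes = nrow(genes)),
            class = "sex_gene_report")
}

#' @export
print.sex_gene_report <- function(x, ...) {
  cat(sprintf("<sex_gene_report> %d putative sex-associated gene(s), %d site(s)\n",
              x$n_genes, nrow(x$sites)))
  print(x$genes)
  invisible(x)
}

#' @method tidy sex_gene_report
#' @export
tidy.sex_gene_report <- function(x, ...) x$sites

#' @method glance sex_gene_report
#' @export
glance.sex_gene_report <- function(x, ...) {
  tibble(n_genes = x$n_genes, n_sites = nrow(x$sites))
}

#' Chance probability that a random biallelic site segregates by sex
#'
#' Exact combinatorics: over all equally likely assignments of two
#' alleles to the `n = n_males + n_females` individuals with both alleles
#' present (2^n - 2 polymorphic assignments), exactly two split along
#' sex, so the probability is `2 / (2^n - 2)`. Quantifies the expected
#' false-positive rate of the segregation filter on unlinked sites.
#'
#' @param n_males,n_females Individuals per sex (>= 1).
#' @return Probability in (0, 1].
#' @examples
#' segregation_null_rate(3, 3) # 2/62
#' @export
segregation_null_rate <- function(n_males, n_females) {
  stopifnot(n_males >= 1, n_females >= 1)
  n <- n_males + n_females
  2 / (2^n - 2)
}
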
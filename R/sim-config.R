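#' Configuration for the synthetic dioecious RNA-seq study
#'
#' Bundles every tunable of the synthetic-data generator. The defaults
#' emulate a leaf-transcriptome comparison of three male and three female
#' individuals: negative-binomial counts, a set of strongly sex-biased
#' genes planted at log2 fold change 5, sex-specific genes with structural
#' zeros in one sex, and biallelic SNP sites of which a subset segregates
#' perfectly by sex at read depth >= 5.
#'
#' Counts are negative binomial with mean `mu` and dispersion `alpha`
#' parameterised so that `Var = mu + alpha * mu^2` (`alpha = 1/size` in
#' [stats::rnbinom()] terms). The default `dispersion = 0.05` is an assumed
#' moderate biological dispersion for full-sib leaf replicates, not an
#' estimate from any data set.
#'
#' Planted biased genes split the effect symmetrically: the favoured sex
#' gets mean `baseline_mean * 2^(planted_log2fc/2)` and the other
#' `baseline_mean * 2^(-planted_log2fc/2)`, so the planted ratio is
#' exactly `2^planted_log2fc`. Sex-specific genes are structural zeros:
#' every replicate of the silent sex gets count 0 (not a random draw), so
#' the "zero read counts in one sex" calling rule is exactly satisfiable.
#' Sex-specific genes are planted in addition to (and classified apart
#' from) the `n_*_biased` genes; the total of biased + specific genes in
#' one sex is that sex's planted DEG count.
#'
#' The single `seed` fans out to fixed per-stage substreams (unigenes,
#' counts, variants, reads), so each stage can be regenerated
#' independently and identical configs give byte-identical output files.
#'
#' @param seed Integer master seed.
#' @param n_genes Number of unigenes.
#' @param n_males,n_females Replicates per sex (default 3 and 3).
#' @param gene_length_range Length-2 integer vector, uniform unigene
#'   length range in bp.
#' @param baseline_mean Negative-binomial mean of an unbiased gene.
#' @param dispersion NB dispersion alpha (Var = mu + alpha mu^2).
#' @param n_male_biased,n_female_biased Planted sex-biased (but not
#'   sex-specific) gene counts.
#' @param planted_log2fc Planted log2 fold change (>= 5 emulates the
#'   strong effects this design targets).
#' @param n_male_specific,n_female_specific Planted sex-specific gene
#'   counts ("male-specific" = expressed in males, zero in females).
#' @param n_snp_sites Total biallelic SNP sites to emit.
#' @param n_sex_segregating Planted perfectly sex-segregating sites
#'   (must not exceed `n_snp_sites`).
#' @param depth_mean Mean per-sample read depth at SNP sites.
#' @param min_planted_depth Minimum depth guaranteed at planted
#'   segregating sites in every sample (>= 5).
#' @param read_length,reads_per_sample,read_gc,read_quality FASTQ
#'   simulation: read length (bp), reads per sample, GC fraction, and
#'   constant Phred quality.
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 200)
#' cfg$n_males
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       n_males = 3L,
                       n_females = 3L,
                       gene_length_range = c(500L, 3000L),
                       baseline_mean = 100,
                       dispersion = 0.05,
                       n_male_biased = 33L,
                       n_female_biased = 12L,
                       planted_log2fc = 5,
                       n_male_specific = 40L,
                       n_female_specific = 31L,
                       n_snp_sites = 60L,
                       n_sex_segregating = 9L,
                       depth_mean = 20,
                       min_planted_depth = 5L,
                       read_length = 100L,
                       reads_per_sample = 400L,
                       read_gc = 0.42,
                       read_quality = 38L) {
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    n_males = as.integer(n_males), n_females = as.integer(n_females),
    gene_length_range = as.integer(gene_length_range),
    baseline_mean = baseline_mean, dispersion = dispersion,
    n_male_biased = as.integer(n_male_biased),
    n_female_biased = as.integer(n_female_biased),
    planted_log2fc = planted_log2fc,
    n_male_specific = as.integer(n_male_specific),
    n_female_specific = as.integer(n_female_specific),
    n_snp_sites = as.integer(n_snp_sites),
    n_sex_segregating = as.integer(n_sex_segregating),
    depth_mean = depth_mean,
    min_planted_depth = as.integer(min_planted_depth),
    read_length = as.integer(read_length),
    reads_per_sample = as.integer(reads_per_sample),
    read_gc = read_gc, read_quality = as.integer(read_quality)
  )
  problems <- validate_sim_config(cfg)
  if (length(problems) > 0) {
    abort(c("invalid simulation configuration:", problems))
  }
  structure(cfg, class = "sim_config")
}

#' Validate a simulation configuration
#'
#' @param cfg A list shaped like the output of [sim_config()].
#' @return Character vector of problems; empty when valid.
#' @export
validate_sim_config <- function(cfg) {
  p <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) p <<- c(p, msg)
  num1 <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x)
  chk(num1(cfg$seed), "seed must be a single integer")
  chk(num1(cfg$n_genes) && cfg$n_genes >= 0, "n_genes must be >= 0")
  chk(num1(cfg$n_males) && cfg$n_males >= 1, "n_males must be >= 1")
  chk(num1(cfg$n_females) && cfg$n_females >= 1, "n_females must be >= 1")
  chk(length(cfg$gene_length_range) == 2 &&
        all(cfg$gene_length_range >= 1) &&
        cfg$gene_length_range[1] <= cfg$gene_length_range[2],
      "gene_length_range must be (min_bp, max_bp) with 1 <= min <= max")
  chk(num1(cfg$baseline_mean) && cfg$baseline_mean > 0, "baseline_mean must be > 0")
  chk(num1(cfg$dispersion) && cfg$dispersion > 0, "dispersion must be > 0")
  for (f in c("n_male_biased", "n_female_biased", "n_male_specific",
              "n_female_specific", "n_snp_sites", "n_sex_segregating")) {
    chk(num1(cfg[[f]]) && cfg[[f]] >= 0, paste(f, "must be >= 0"))
  }
  n_planted <- cfg$n_male_biased + cfg$n_female_biased +
    cfg$n_male_specific + cfg$n_female_specific
  chk(isTRUE(n_planted <= cfg$n_genes),
      "planted gene classes must not exceed n_genes")
  chk(isTRUE(cfg$n_sex_segregating <= cfg$n_snp_sites),
      "n_sex_segregating must not exceed n_snp_sites")
  chk(num1(cfg$depth_mean) && cfg$depth_mean > 0, "depth_mean must be > 0")
  chk(num1(cfg$min_planted_depth) && cfg$min_planted_depth >= 1,
      "min_planted_depth must be >= 1")
  chk(num1(cfg$read_length) && cfg$read_length >= 1, "read_length must be >= 1")
  chk(num1(cfg$reads_per_sample) && cfg$reads_per_sample >= 0,
      "reads_per_sample must be >= 0")
  chk(num1(cfg$read_gc) && cfg$read_gc >= 0 && cfg$read_gc <= 1,
      "read_gc must be in [0, 1]")
  chk(num1(cfg$read_quality) && cfg$read_quality >= 2 && cfg$read_quality <= 41,
      "read_quality must be a Phred score in [2, 41]")
  p
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d genes, %dM + %dF replicates, seed %d\n",
              x$n_genes, x$n_males, x$n_females, x$seed))
  cat(sprintf("  NB(mean %g, dispersion %g); planted log2FC %g\n",
              x$baseline_mean, x$dispersion, x$planted_log2fc))
  cat(sprintf("  biased M/F: %d/%d, specific M/F: %d/%d\n",
              x$n_male_biased, x$n_female_biased,
              x$n_male_specific, x$n_female_specific))
  cat(sprintf("  SNP sites: %d (%d sex-segregating), depth mean %g\n",
              x$n_snp_sites, x$n_sex_segregating, x$depth_mean))
  invisible(x)
}

# per-stage substream seeds, all well below 2^31
stage_seed <- function(cfg, stage) {
  offs <- c(unigenes = 101L, counts = 211L, variants = 307L,
            reads = 401L, categories = 503L)
  (cfg$seed %% 1000000L) * 1000L + offs[[stage]]
}

# sample sheet implied by a config: females first, as in the study layout
sim_design <- function(cfg) {
  tibble(
    sample = c(sprintf("F%d", seq_len(cfg$n_females)),
               sprintf("M%d", seq_len(cfg$n_males))),
    sex = c(rep("F", cfg$n_females), rep("M", cfg$n_males))
  )
}
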
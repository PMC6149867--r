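#' Pipeline configuration
#'
#' Paths and thresholds for an end-to-end run. `counts`, `samples` and
#' `fasta` are required; `vcf`, `cds`, `annotation` and `fastq` switch
#' their stages on. Can also be loaded from YAML with
#' [read_pipeline_config()].
#'
#' @param counts,samples,fasta Paths to the count TSV, sample sheet TSV
#'   and unigene FASTA.
#' @param vcf Optional multi-sample VCF for the sex-association and SNP
#'   summary stages.
#' @param cds Optional CDS annotation TSV (`gene`, `cds_start`, `cds_end`).
#' @param annotation Optional gene-category TSV (`gene`, `category`) for
#'   enrichment.
#' @param fastq Optional character vector of FASTQ paths for read QC.
#' @param out_dir Output directory.
#' @param alpha,lfc_threshold,fpkm_floor,floor_mode DEG thresholds; see
#'   [call_sex_biased_genes()].
#' @param min_depth Depth criterion of the segregation filter.
#' @param n_bins Length bins of the enrichment weighting.
#' @param enrichment_mode `"wallenius"` or `"hypergeometric"`.
#' @param seed Seed for any stochastic step.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(counts, samples, fasta,
                            vcf = NULL, cds = NULL, annotation = NULL,
                            fastq = NULL, out_dir = "dioseq_out",
                            alpha = 0.05, lfc_threshold = 1,
                            fpkm_floor = 0.03, floor_mode = "mean",
                            min_depth = 5L, n_bins = 20L,
                            enrichment_mode = "wallenius", seed = 1L) {
  structure(list(counts = counts, samples = samples, fasta = fasta,
                 vcf = vcf, cds = cds, annotation = annotation, fastq = fastq,
                 out_dir = out_dir, alpha = alpha, lfc_threshold = lfc_threshold,
                 fpkm_floor = fpkm_floor, floor_mode = floor_mode,
                 min_depth = as.integer(min_depth), n_bins = as.integer(n_bins),
                 enrichment_mode = enrichment_mode, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Validate a pipeline configuration
#'
#' Checks paths, ranges and label consistency and returns every problem
#' found (an empty vector means the configuration is valid); it never
#' throws, so all problems can be reported at once.
#'
#' @param config A `pipeline_config`.
#' @return Character vector of problems.
#' @export
validate_config <- function(config) {
  p <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) p <<- c(p, msg)
  need <- function(field) {
    path <- config[[field]]
    if (is.null(path)) { p <<- c(p, paste0("missing required input: ", field)); return() }
    for (f in path) if (!file.exists(f)) p <<- c(p, paste0(field, " file not found: ", f))
  }
  need("counts"); need("samples"); need("fasta")
  for (field in c("vcf", "cds", "annotation", "fastq")) {
    for (f in config[[field]]) {
      if (!file.exists(f)) p <- c(p, paste0(field, " file not found: ", f))
    }
  }
  chk(is.numeric(config$alpha) && config$alpha >= 0 && config$alpha <= 1,
      "alpha must be in [0, 1]")
  chk(is.numeric(config$lfc_threshold) && config$lfc_threshold >= 0,
      "lfc_threshold must be >= 0")
  chk(is.numeric(config$fpkm_floor) && config$fpkm_floor >= 0,
      "fpkm_floor must be >= 0")
  chk(config$floor_mode %in% c("mean", "all"), "floor_mode must be 'mean' or 'all'")
  chk(is.numeric(config$min_depth) && config$min_depth >= 1, "min_depth must be >= 1")
  chk(is.numeric(config$n_bins) && config$n_bins >= 1, "n_bins must be >= 1")
  chk(config$enrichment_mode %in% c("wallenius", "hypergeometric"),
      "enrichment_mode must be 'wallenius' or 'hypergeometric'")
  if (is.null(p) || length(p) == 0) {
    design <- tryCatch(readr::read_tsv(config$samples, show_col_types = FALSE),
                       error = function(e) NULL)
    if (!is.null(design)) {
      if (!all(c("sample", "sex") %in% names(design))) {
        p <- c(p, "sample sheet must have columns `sample` and `sex`")
      } else if (!all(design$sex %in% c("M", "F"))) {
        p <- c(p, "sample sheet sexes must be 'M' or 'F'")
      }
    }
  }
  p
}

#' Run the full comparative-transcriptomics pipeline
#'
#' Stages run in order: expression (sex-biased and sex-specific gene
#' calling plus sample clustering), sex association (depth filter and
#' segregation filter on the VCF), variant summary (SNP spectrum,
#' density, codon positions, synonymy, per-individual counts, assembly
#' stats, read QC), and enrichment. Missing optional inputs skip their
#' stage. Every stage writes its table under `out_dir`, and the combined
#' report is also rendered as JSON. Reruns with an unchanged
#' configuration reproduce identical outputs.
#'
#' @param config A `pipeline_config`.
#' @return A `run_report`: list with `deg` (a `deg_fit`), `clustering`,
#'   `sex_genes` (a `sex_gene_report` or NULL), `snp_summary`,
#'   `assembly`, `read_qc`, `enrichment`, and `provenance`.
#' @export
run_pipeline <- function(config) {
  problems <- validate_config(config)
  if (length(problems) > 0) {
    abort(c("invalid pipeline configuration:", problems))
  }
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  set.seed(config$seed)

  counts <- read_counts(config$counts)
  design <- read_sample_sheet(config$samples)
  unigenes <- read_unigenes(config$fasta)

  # ---- expression ----
  fit <- call_sex_biased_genes(counts, design, unigenes,
                               alpha = config$alpha,
                               lfc_threshold = config$lfc_threshold,
                               fpkm_floor = config$fpkm_floor,
                               floor_mode = config$floor_mode)
  write_tsv_plain(fit$results, out("deg_results.tsv"))
  write_tsv_plain(fit$fpkm, out("fpkm.tsv"))
  degs <- fit$results$gene[fit$results$bias_class != "unbiased"]
  clustering <- NULL
  if (length(degs) >= 2) {
    clustering <- cluster_samples(fit$fpkm, design, degs)
    if (requireNamespace("ape", quietly = TRUE)) {
      write_dendrogram(clustering, out("sample_dendrogram.nwk"))
    }
  }

  # ---- sex association ----
  sex_genes <- NULL
  snp_summary <- NULL
  if (!is.null(config$vcf)) {
    calls <- read_genotypes_vcf(config$vcf, design)
    deep <- filter_min_depth(calls, design, min_depth = config$min_depth)
    sites <- find_sex_segregating(deep, design)
    sex_genes <- summarize_sex_genes(sites)
    write_tsv_plain(sex_genes$sites, out("sex_associated_sites.tsv"))
    write_tsv_plain(sex_genes$genes, out("sex_associated_genes.tsv"))

    # ---- variant summary ----
    snp_sites <- distinct(calls, .data$gene, .data$pos) |>
      inner_join(read_vcf_sites(config$vcf), by = c("gene", "pos"))
    cds <- if (!is.null(config$cds)) read_cds(config$cds) else NULL
    snp_summary <- summarize_variants(snp_sites, unigenes, cds = cds, calls = calls)
    write_tsv_plain(snp_summary$spectrum$by_pair, out("snp_spectrum.tsv"))
  }

  assembly <- assembly_stats(unigenes$length)
  write_tsv_plain(assembly, out("assembly_stats.tsv"))

  qc <- NULL
  if (!is.null(config$fastq)) {
    qc <- bind_rows(lapply(config$fastq, function(f) {
      bind_cols(tibble(file = basename(f)), read_qc(f))
    }))
    write_tsv_plain(qc, out("read_qc.tsv"))
  }

  # ---- enrichment ----
  enrichment <- NULL
  if (!is.null(config$annotation)) {
    map <- readr::read_tsv(config$annotation, show_col_types = FALSE)
    uni <- tibble(gene = fit$results$gene,
                  de = fit$results$bias_class != "unbiased",
                  length = unigenes$length[match(fit$results$gene, unigenes$gene)])
    if (any(uni$de) && !all(uni$de)) {
      pwf <- build_pwf(uni, n_bins = config$n_bins)
      enrichment <- enrich_all(map, pwf, method = config$enrichment_mode)
    } else {
      enrichment <- enrich_all(map, mutate(uni, weight = 0.5),
                               method = "hypergeometric")
    }
    write_tsv_plain(enrichment, out("enrichment.tsv"))
  }

  report <- structure(list(
    deg = fit, clustering = clustering, sex_genes = sex_genes,
    snp_summary = snp_summary, assembly = assembly, read_qc = qc,
    enrichment = enrichment,
    provenance = list(
      package_version = as.character(utils::packageVersion("dioseq")),
      config = unclass(config),
      config_hash = rlang::hash(unclass(config)),
      seed = config$seed)
  ), class = "run_report")
  jsonlite::write_json(report_to_list(report), out("report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

# sites (gene,pos,ref,alt) straight from a VCF, biallelic SNPs only
read_vcf_sites <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  keep <- !is.na(fix$ALT) & fix$REF %in% c("A", "C", "G", "T") &
    fix$ALT %in% c("A", "C", "G", "T")
  tibble(gene = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
         ref = fix$REF[keep], alt = fix$ALT[keep])
}

#' Read a CDS annotation table
#'
#' @param path TSV with columns `gene`, `cds_start`, `cds_end` (1-based
#'   inclusive coordinates on the unigene).
#' @return Tibble with those columns.
#' @export
read_cds <- function(path) {
  cds <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("gene", "cds_start", "cds_end") %in% names(cds))) {
    abort("CDS table needs columns `gene`, `cds_start`, `cds_end`.")
  }
  cds
}

# percentages recomputed from counts at render time, never stored
report_to_list <- function(report) {
  g <- glance(report$deg)
  deg <- list(
    n_genes = g$n_genes, n_deg = g$n_deg,
    n_male_biased = g$n_male_biased, n_female_biased = g$n_female_biased,
    pct_male_biased = if (g$n_deg > 0) round_half_up(100 * g$n_male_biased / g$n_deg, 1) else NA,
    pct_female_biased = if (g$n_deg > 0) round_half_up(100 * g$n_female_biased / g$n_deg, 1) else NA,
    n_male_specific = g$n_male_specific, n_female_specific = g$n_female_specific
  )
  out <- list(deg = deg, provenance = report$provenance)
  if (!is.null(report$clustering)) {
    out$clustering <- list(concordant_with_sex = report$clustering$concordant,
                           partition = report$clustering$partition)
  }
  if (!is.null(report$sex_genes)) {
    out$sex_association <- list(n_genes = report$sex_genes$n_genes,
                                sites = report$sex_genes$sites)
  }
  if (!is.null(report$snp_summary)) {
    s <- report$snp_summary
    out$snp_summary <- list(
      by_pair = s$spectrum$by_pair,
      n_transition = s$spectrum$n_transition,
      n_transversion = s$spectrum$n_transversion,
      n_total = s$spectrum$n_total,
      density_per_kb = round_half_up(s$density_per_kb, 2),
      codon_positions = s$codon_positions, synonymy = s$synonymy,
      per_individual = s$per_individual)
  }
  out$assembly <- report$assembly
  if (!is.null(report$read_qc)) out$read_qc <- report$read_qc
  if (!is.null(report$enrichment)) out$enrichment <- as_tibble(report$enrichment)
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  print(x$deg)
  if (!is.null(x$sex_genes)) print(x$sex_genes)
  if (!is.null(x$snp_summary)) print(x$snp_summary$spectrum)
  if (!is.null(x$enrichment)) {
    cat(sprintf("enrichment: %d categories, %d with q < 0.05\n",
                nrow(x$enrichment), sum(x$enrichment$q < 0.05)))
  }
  invisible(x)
}
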
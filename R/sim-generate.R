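#' Simulate an assembled unigene set
#'
#' Draws unigene lengths uniformly over `gene_length_range` and sequences
#' uniformly over A/C/G/T, and places one forward-frame CDS per gene
#' (random small 5' offset, length a multiple of 3) for downstream
#' codon-position and synonymy summaries.
#'
#' @param cfg A [sim_config()].
#' @return Tibble with columns `gene`, `length`, `sequence`,
#'   `cds_start`, `cds_end`.
#' @export
simulate_unigenes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_genes == 0L) {
    return(tibble(gene = character(), length = integer(), sequence = character(),
                  cds_start = integer(), cds_end = integer()))
  }
  withr::with_seed(stage_seed(cfg, "unigenes"), {
    len <- sample(seq(cfg$gene_length_range[1], cfg$gene_length_range[2]),
                  cfg$n_genes, replace = TRUE)
    seqs <- vapply(len, function(l) {
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
    }, character(1))
    cds_start <- pmin(len, sample(1:30, cfg$n_genes, replace = TRUE))
    n_codons <- pmax(1L, (len - cds_start + 1L) %/% 3L)
    cds_end <- cds_start + n_codons * 3L - 1L
  })
  tibble(
    gene = sprintf("UN%05d", seq_len(cfg$n_genes)),
    length = as.integer(len), sequence = seqs,
    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end)
  )
}

#' Simulate a replicated count matrix with planted sex effects
#'
#' Counts are negative binomial around sex-conditional means. Planted
#' biased genes have a true male/female mean ratio of exactly
#' `2^planted_log2fc` (split symmetrically around `baseline_mean`);
#' sex-specific genes are structural zeros in the silent sex; all other
#' genes share `baseline_mean` in both sexes.
#'
#' @param cfg A [sim_config()].
#' @param unigenes Output of [simulate_unigenes()].
#' @return List with `counts` (tibble: `gene` + one column per sample),
#'   `design` (sample sheet tibble), and `truth` (tibble `gene`, `class`
#'   with class in male-biased / female-biased / male-specific /
#'   female-specific / unbiased).
#' @export
simulate_counts <- function(cfg, unigenes) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nrow(unigenes) == 0L) abort("`unigenes` is empty; nothing to simulate.")
  design <- sim_design(cfg)
  n <- nrow(unigenes)
  n_planted <- cfg$n_male_biased + cfg$n_female_biased +
    cfg$n_male_specific + cfg$n_female_specific
  if (n_planted > n) abort("planted gene classes exceed the number of genes.")
  withr::with_seed(stage_seed(cfg, "counts"), {
    idx <- sample(n, n_planted)
    class <- rep("unbiased", n)
    class[idx] <- rep(c("male-biased", "female-biased", "male-specific", "female-specific"),
                      times = c(cfg$n_male_biased, cfg$n_female_biased,
                                cfg$n_male_specific, cfg$n_female_specific))
    half <- 2^(cfg$planted_log2fc / 2)
    mu_m <- rep(cfg$baseline_mean, n)
    mu_f <- rep(cfg$baseline_mean, n)
    mu_m[class == "male-biased"] <- cfg$baseline_mean * half
    mu_f[class == "male-biased"] <- cfg$baseline_mean / half
    mu_f[class == "female-biased"] <- cfg$baseline_mean * half
    mu_m[class == "female-biased"] <- cfg$baseline_mean / half
    mu_f[class == "male-specific"] <- 0
    mu_m[class == "female-specific"] <- 0
    size <- 1 / cfg$dispersion
    draw <- function(mu, n_rep) {
      m <- matrix(0L, n, n_rep)
      pos <- mu > 0
      m[pos, ] <- rnbinom(sum(pos) * n_rep, mu = rep(mu[pos], n_rep), size = size)
      m
    }
    cf <- draw(mu_f, cfg$n_females)
    cm <- draw(mu_m, cfg$n_males)
  })
  counts <- as_tibble(cbind(cf, cm), .name_repair = ~design$sample)
  counts <- bind_cols(tibble(gene = unigenes$gene), counts)
  list(counts = counts, design = design,
       truth = tibble(gene = unigenes$gene, class = class))
}

#' Simulate multi-sample biallelic SNP calls
#'
#' Emits `n_snp_sites` biallelic sites with per-sample genotype and depth.
#' `n_sex_segregating` sites are planted to pass the three-criterion
#' sex-segregation filter: depth at least `min_planted_depth` in every
#' sample, one allele fixed in all females and a different one fixed in
#' all males. The remaining sites are split between decoys that are
#' polymorphic but do not segregate by sex (one individual carries the
#' other sex's allele, or one call is heterozygous) and sub-threshold
#' sites whose genotypes segregate but whose depth dips below
#' `min_planted_depth` in at least one sample.
#'
#' At planted sites the reference allele is the unigene base at that
#' position and is assigned to the females, so the emitted VCF, FASTA and
#' truth manifest stay mutually consistent.
#'
#' @param cfg A [sim_config()].
#' @param unigenes Output of [simulate_unigenes()].
#' @return List with `sites` (tibble `gene`, `pos`, `ref`, `alt`),
#'   `calls` (tibble `gene`, `pos`, `sample`, `gt`, `dp`), and
#'   `truth_sites` (tibble `gene`, `pos`, `kind`, `female_allele`,
#'   `male_allele`; kind in segregating / decoy / low_depth).
#' @export
simulate_variants <- function(cfg, unigenes) {
  stopifnot(inherits(cfg, "sim_config"))
  design <- sim_design(cfg)
  if (cfg$n_sex_segregating > cfg$n_snp_sites) {
    abort("n_sex_segregating must not exceed n_snp_sites.")
  }
  if (nrow(unigenes) == 0L && cfg$n_snp_sites > 0L) {
    abort("cannot place SNP sites on an empty unigene set.")
  }
  n_sites <- cfg$n_snp_sites
  if (n_sites == 0L) {
    empty_sites <- tibble(gene = character(), pos = integer(),
                          ref = character(), alt = character())
    return(list(sites = empty_sites,
                calls = tibble(gene = character(), pos = integer(),
                               sample = character(), gt = character(), dp = integer()),
                truth_sites = tibble(gene = character(), pos = integer(), kind = character(),
                                     female_allele = character(), male_allele = character())))
  }
  samples <- design$sample
  is_f <- design$sex == "F"
  bases <- c("A", "C", "G", "T")
  withr::with_seed(stage_seed(cfg, "variants"), {
    # unique (gene, pos) pairs; segregating sites are clustered on a few
    # genes (several markers per sex-linked locus, as in real data)
    n_seg <- cfg$n_sex_segregating
    n_rest <- n_sites - n_seg
    n_low <- n_rest %/% 2L
    n_dec <- n_rest - n_low
    seg_genes <- sample(unigenes$gene, max(1L, ceiling(n_seg / 2)),
                        replace = FALSE)
    site_gene <- c(sample(seg_genes, n_seg, replace = TRUE),
                   sample(unigenes$gene, n_rest, replace = TRUE))
    repeat {
      site_pos <- vapply(site_gene, function(g) {
        sample.int(unigenes$length[unigenes$gene == g], 1L)
      }, integer(1))
      if (!anyDuplicated(paste(site_gene, site_pos))) break
    }
    kind <- c(rep("segregating", n_seg), rep("decoy", n_dec), rep("low_depth", n_low))
    ref <- vapply(seq_len(n_sites), function(i) {
      substr(unigenes$sequence[unigenes$gene == site_gene[i]], site_pos[i], site_pos[i])
    }, character(1))
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
    n_samp <- nrow(design)
    rows <- vector("list", n_sites)
    for (i in seq_len(n_sites)) {
      dp <- pmax(cfg$min_planted_depth,
                 rpois(n_samp, cfg$depth_mean))
      # ref allele fixed in females, alt in males (or swapped at random)
      swap <- runif(1) < 0.5
      gt <- ifelse(xor(is_f, swap), "0/0", "1/1")
      if (kind[i] == "decoy") {
        mode <- sample(c("flip", "het"), 1L)
        j <- sample.int(n_samp, 1L)
        if (mode == "flip") {
          gt[j] <- if (gt[j] == "0/0") "1/1" else "0/0"
        } else {
          gt[j] <- "0/1"
        }
      } else if (kind[i] == "low_depth") {
        j <- sample.int(n_samp, 1L)
        dp[j] <- sample.int(cfg$min_planted_depth - 1L, 1L)
      }
      rows[[i]] <- tibble(gene = site_gene[i], pos = as.integer(site_pos[i]),
                          sample = samples, gt = gt, dp = as.integer(dp))
    }
    swap_flag <- vapply(rows, function(r) r$gt[which(is_f)[1]] == "1/1", logical(1))
  })
  sites <- tibble(gene = site_gene, pos = as.integer(site_pos), ref = ref, alt = alt)
  ord <- order(sites$gene, sites$pos)
  truth <- tibble(
    gene = site_gene, pos = as.integer(site_pos), kind = kind,
    female_allele = ifelse(swap_flag, alt, ref),
    male_allele = ifelse(swap_flag, ref, alt)
  )
  truth$female_allele[truth$kind == "decoy"] <- NA_character_
  truth$male_allele[truth$kind == "decoy"] <- NA_character_
  list(sites = sites[ord, ],
       calls = bind_rows(rows[ord]),
       truth_sites = truth[ord, ])
}

#' Simulate per-sample FASTQ reads
#'
#' Fixed-length reads with independent bases (G/C each with probability
#' `read_gc / 2`) and a constant Phred quality, enough to exercise the
#' Q20/Q30/GC/error-rate QC summaries.
#'
#' @param cfg A [sim_config()].
#' @return Tibble with columns `sample`, `read_id`, `sequence`, `quality`.
#' @export
simulate_reads <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  design <- sim_design(cfg)
  qchar <- rawToChar(as.raw(33L + cfg$read_quality))
  qual <- strrep(qchar, cfg$read_length)
  p <- c(A = (1 - cfg$read_gc) / 2, C = cfg$read_gc / 2,
         G = cfg$read_gc / 2, T = (1 - cfg$read_gc) / 2)
  withr::with_seed(stage_seed(cfg, "reads"), {
    out <- lapply(design$sample, function(s) {
      if (cfg$reads_per_sample == 0L) {
        return(tibble(sample = character(), read_id = character(),
                      sequence = character(), quality = character()))
      }
      mat <- matrix(sample(names(p), cfg$reads_per_sample * cfg$read_length,
                           replace = TRUE, prob = p),
                    nrow = cfg$reads_per_sample)
      tibble(
        sample = s,
        read_id = sprintf("%s_read%06d", s, seq_len(cfg$reads_per_sample)),
        sequence = apply(mat, 1, paste, collapse = ""),
        quality = qual
      )
    })
  })
  bind_rows(out)
}

#' Simulate a gene-to-category annotation map
#'
#' Random categories of sizes uniform in `size_range`, optionally plus one
#' planted category consisting exactly of `planted_genes` (used to verify
#' that enrichment ranks a truly enriched category first).
#'
#' @param genes Character vector of gene ids (the annotation universe).
#' @param n_categories Number of random categories.
#' @param size_range Length-2 integer vector of category sizes.
#' @param planted_genes Optional character vector; emitted as category
#'   `"planted"`.
#' @param seed Integer seed.
#' @return Tibble with columns `gene`, `category`.
#' @export
simulate_category_map <- function(genes, n_categories = 50L,
                                  size_range = c(10L, 40L),
                                  planted_genes = NULL, seed = 1L) {
  stopifnot(length(genes) > 0, n_categories >= 0)
  withr::with_seed(seed, {
    out <- lapply(seq_len(n_categories), function(i) {
      k <- sample(seq(size_range[1], min(size_range[2], length(genes))), 1L)
      tibble(gene = sample(genes, k), category = sprintf("CAT%03d", i))
    })
  })
  res <- bind_rows(out)
  if (!is.null(planted_genes)) {
    res <- bind_rows(res, tibble(gene = planted_genes, category = "planted"))
  }
  arrange(res, .data$category, .data$gene)
}

# ---- writers ------------------------------------------------------------

#' Write unigenes as FASTA
#' @param unigenes Tibble with `gene` and `sequence`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_unigene_fasta <- function(unigenes, path) {
  ss <- Biostrings::DNAStringSet(setNames(unigenes$sequence, unigenes$gene))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write simulated variants as a VCF v4.2 file
#'
#' Minimal multi-sample VCF with `GT:DP` per sample, sorted by gene then
#' position; readable by standard VCF parsers.
#'
#' @param sites,calls Output of [simulate_variants()].
#' @param design Sample sheet tibble (column order of the VCF).
#' @param path Output path (plain text `.vcf`).
#' @return The path, invisibly.
#' @export
write_vcf <- function(sites, calls, design, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=dioseq-simulator",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            design$sample), collapse = "\t")
  )
  body <- character(nrow(sites))
  if (nrow(sites) > 0) {
    wide <- calls |>
      mutate(field = paste0(.data$gt, ":", .data$dp)) |>
      select("gene", "pos", "sample", "field") |>
      pivot_wider(names_from = "sample", values_from = "field")
    wide <- left_join(sites, wide, by = c("gene", "pos"))
    body <- vapply(seq_len(nrow(wide)), function(i) {
      paste(c(wide$gene[i], wide$pos[i], ".", wide$ref[i], wide$alt[i],
              ".", "PASS", ".", "GT:DP",
              unlist(wide[i, design$sample])), collapse = "\t")
    }, character(1))
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a flat per-individual genotype table
#'
#' One row per site with a single-base allele column per individual
#' (homozygous calls only; heterozygous or missing calls are written as
#' `.`), the layout used for worked sex-association examples.
#'
#' @param sites,calls Output of [simulate_variants()].
#' @param design Sample sheet tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_genotype_table <- function(sites, calls, design, path) {
  allele_of <- function(gt, ref, alt) {
    ifelse(gt == "0/0", ref, ifelse(gt == "1/1", alt, "."))
  }
  tab <- calls |>
    left_join(sites, by = c("gene", "pos")) |>
    mutate(allele = allele_of(.data$gt, .data$ref, .data$alt)) |>
    select("gene", "pos", "sample", "allele") |>
    pivot_wider(names_from = "sample", values_from = "allele") |>
    rename(Gene_ID = "gene", Position = "pos")
  write_tsv_plain(tab, path)
}

write_fastq <- function(reads, path) {
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                           "+", reads$quality))
  writeLines(lines, path)
  invisible(path)
}

#' Generate the full synthetic study into a directory
#'
#' Runs every simulation stage and writes all pipeline inputs plus the
#' truth manifest: `unigenes.fasta`, `cds.tsv`, `counts.tsv`,
#' `samples.tsv`, `variants.vcf`, `genotypes.tsv`, `truth_genes.tsv`,
#' `truth_sites.tsv`, per-sample `reads_<sample>.fastq`, and
#' `config.yaml`. Identical configurations produce byte-identical files.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if missing).
#' @param reads Also write FASTQ files (default TRUE).
#' @return Invisibly, a list with the simulated objects and file paths.
#' @examples
#' d <- simulate_dataset(sim_config(seed = 7, n_genes = 50,
#'                                  n_male_biased = 3, n_female_biased = 2,
#'                                  n_male_specific = 2, n_female_specific = 1,
#'                                  n_snp_sites = 10, n_sex_segregating = 3),
#'                       dir = tempfile())
#' names(d)
#' @export
simulate_dataset <- function(cfg, dir, reads = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  unigenes <- simulate_unigenes(cfg)
  cnt <- simulate_counts(cfg, unigenes)
  var <- simulate_variants(cfg, unigenes)
  write_unigene_fasta(unigenes, p("unigenes.fasta"))
  write_tsv_plain(select(unigenes, "gene", "cds_start", "cds_end"), p("cds.tsv"))
  write_tsv_plain(cnt$counts, p("counts.tsv"))
  write_tsv_plain(cnt$design, p("samples.tsv"))
  write_vcf(var$sites, var$calls, cnt$design, p("variants.vcf"))
  write_genotype_table(var$sites, var$calls, cnt$design, p("genotypes.tsv"))
  write_tsv_plain(cnt$truth, p("truth_genes.tsv"))
  write_tsv_plain(var$truth_sites, p("truth_sites.tsv"))
  fastq <- character(0)
  if (reads) {
    rd <- simulate_reads(cfg)
    fastq <- vapply(cnt$design$sample, function(s) {
      write_fastq(rd[rd$sample == s, ], p(sprintf("reads_%s.fastq", s)))
    }, character(1))
  }
  yaml::write_yaml(unclass(cfg), p("config.yaml"))
  invisible(list(
    config = cfg, dir = dir, unigenes = unigenes,
    counts = cnt$counts, design = cnt$design, truth_genes = cnt$truth,
    sites = var$sites, calls = var$calls, truth_sites = var$truth_sites,
    paths = c(fasta = p("unigenes.fasta"), cds = p("cds.tsv"),
              counts = p("counts.tsv"), samples = p("samples.tsv"),
              vcf = p("variants.vcf"), genotypes = p("genotypes.tsv"),
              truth_genes = p("truth_genes.tsv"), truth_sites = p("truth_sites.tsv"),
              config = p("config.yaml"))
  ))
}
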
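PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")
# canonical unordered pair labels, transitions first (spectrum-table order)
PAIR_LEVELS <- c("C/T", "A/G", "A/T", "A/C", "T/G", "C/G")

#' Classify a base substitution as transition or transversion
#'
#' Purine-purine (A/G) and pyrimidine-pyrimidine (C/T) substitutions are
#' transitions; purine-pyrimidine substitutions are transversions. The
#' pair label is unordered, so reversing ref and alt never changes the
#' result.
#'
#' @param ref,alt Character vectors of single bases in A/C/G/T,
#'   elementwise different.
#' @return Tibble with columns `ref`, `alt`, `pair` (one of C/T, A/G,
#'   A/T, A/C, T/G, C/G) and `class` (transition or transversion).
#' @examples
#' classify_substitution("C", "T")$class # transition
#' @export
classify_substitution <- function(ref, alt) {
  bases <- c(PURINES, PYRIMIDINES)
  if (!all(ref %in% bases) || !all(alt %in% bases)) {
    abort("ref and alt must be single bases in A, C, G, T.")
  }
  if (any(ref == alt)) abort("ref and alt must differ.")
  key <- paste(pmin(ref, alt), pmax(ref, alt), sep = "/")
  canon <- c("C/T" = "C/T", "A/G" = "A/G", "A/T" = "A/T",
             "A/C" = "A/C", "G/T" = "T/G", "C/G" = "C/G")
  pair <- unname(canon[key])
  class <- ifelse((ref %in% PURINES) == (alt %in% PURINES),
                  "transition", "transversion")
  tibble(ref = ref, alt = alt, pair = pair, class = class)
}

#' Tally the SNP substitution spectrum
#'
#' Counts each unordered substitution pair and sums transitions,
#' transversions and the grand total. Rows may carry a pre-tallied count
#' column `n` (defaulting to 1 per row), so either raw per-site records
#' or a published per-type count table can be fed in directly.
#'
#' @param snps Tibble with columns `ref`, `alt` and optionally `n`.
#' @param total_length_bp Optional total sequence length in bp; when
#'   given, per-kilobase densities are added (half-up rounded to two
#'   decimals in the table, full precision in the totals).
#' @return A `snp_spectrum`: list with `by_pair` (tibble `pair`, `class`,
#'   `n`, and `per_kb` when lengths are given), `n_transition`,
#'   `n_transversion`, `n_total`, and `density_per_kb` (NA without a
#'   length).
#' @export
tally_spectrum <- function(snps, total_length_bp = NULL) {
  if (!all(c("ref", "alt") %in% names(snps))) {
    abort("`snps` needs columns `ref` and `alt` (and optionally `n`).")
  }
  n <- if ("n" %in% names(snps)) snps$n else rep(1L, nrow(snps))
  if (nrow(snps) > 0) {
    cls <- classify_substitution(snps$ref, snps$alt)
    tab <- tibble(pair = cls$pair, class = cls$class, n = n) |>
      group_by(.data$pair, .data$class) |>
      summarise(n = sum(.data$n), .groups = "drop")
  } else {
    tab <- tibble(pair = character(), class = character(), n = numeric())
  }
  by_pair <- tibble(pair = PAIR_LEVELS,
                    class = c("transition", "transition", rep("transversion", 4))) |>
    left_join(tab[c("pair", "n")], by = "pair") |>
    mutate(n = coalesce(.data$n, 0))
  n_ts <- sum(by_pair$n[by_pair$class == "transition"])
  n_tv <- sum(by_pair$n[by_pair$class == "transversion"])
  density <- NA_real_
  if (!is.null(total_length_bp)) {
    density <- snp_density(n_ts + n_tv, total_length_bp)
    by_pair$per_kb <- round_half_up(by_pair$n / (total_length_bp / 1000), 2)
  }
  structure(list(by_pair = by_pair, n_transition = n_ts, n_transversion = n_tv,
                 n_total = n_ts + n_tv, density_per_kb = density),
            class = "snp_spectrum")
}

#' @export
print.snp_spectrum <- function(x, ...) {
  cat(sprintf("<snp_spectrum> %s transitions + %s transversions = %s SNPs",
              format(x$n_transition, big.mark = ","),
              format(x$n_transversion, big.mark = ","),
              format(x$n_total, big.mark = ",")))
  if (!is.na(x$density_per_kb)) {
    cat(sprintf(" (%.2f per kb)", round_half_up(x$density_per_kb, 2)))
  }
  cat("\n")
  print(x$by_pair)
  invisible(x)
}

#' @method tidy snp_spectrum
#' @export
tidy.snp_spectrum <- function(x, ...) x$by_pair

#' @method glance snp_spectrum
#' @export
glance.snp_spectrum <- function(x, ...) {
  tibble(n_transition = x$n_transition, n_transversion = x$n_transversion,
         n_total = x$n_total, density_per_kb = x$density_per_kb)
}

#' SNP density per kilobase
#'
#' @param total_snps SNP count.
#' @param total_length_bp Total sequence length in bp (> 0).
#' @return SNPs per kb at full precision; round with [round_half_up()]
#'   for reporting.
#' @examples
#' round_half_up(snp_density(119411, 117298413), 2) # 1.02
#' @export
snp_density <- function(total_snps, total_length_bp) {
  if (!is.numeric(total_length_bp) || total_length_bp <= 0) {
    abort("`total_length_bp` must be positive.")
  }
  total_snps / (total_length_bp / 1000)
}

#' Codon position of a SNP within an annotated CDS
#'
#' Positions are 1-based along the unigene (5' to 3'). A SNP outside
#' `[cds_start, cds_end]` is noncoding; inside, the codon position is
#' `1 + (position - cds_start) mod 3` (frame offset 0, forward strand
#' only, as unigenes are oriented transcripts).
#'
#' @param pos Integer vector of SNP positions.
#' @param cds_start,cds_end CDS bounds, 1-based inclusive (recycled).
#' @return Character vector: `"first"`, `"second"`, `"third"` or
#'   `"noncoding"`.
#' @export
codon_position <- function(pos, cds_start, cds_end) {
  if (any(cds_start > cds_end)) abort("cds_start must be <= cds_end.")
  inside <- pos >= cds_start & pos <= cds_end
  off <- (pos - cds_start) %% 3L
  out <- c("first", "second", "third")[off + 1L]
  out[!inside] <- "noncoding"
  out
}

#' Classify coding SNPs as synonymous or nonsynonymous
#'
#' Substitutes the alternate base into the reference codon and translates
#' both with the standard genetic code; identical amino acids mean
#' synonymous. A stop codon counts as its own residue, so a stop gain or
#' loss is nonsynonymous.
#'
#' @param snps Tibble with columns `gene`, `pos`, `ref`, `alt`; every SNP
#'   must fall inside its gene's CDS.
#' @param cds Tibble with columns `gene`, `cds_start`, `cds_end`
#'   (1-based inclusive; CDS length divisible by 3).
#' @param unigenes Tibble with `gene`, `sequence` (the reference base at
#'   each SNP position must equal `ref`).
#' @return Character vector: `"synonymous"` or `"nonsynonymous"`.
#' @export
classify_synonymy <- function(snps, cds, unigenes) {
  gc_table <- Biostrings::GENETIC_CODE
  idx <- match(snps$gene, cds$gene)
  if (anyNA(idx)) {
    abort(paste0("no CDS annotation for gene(s): ",
                 paste(unique(snps$gene[is.na(idx)]), collapse = ", ")))
  }
  sidx <- match(snps$gene, unigenes$gene)
  if (anyNA(sidx)) abort("some SNP genes are missing from `unigenes`.")
  start <- cds$cds_start[idx]; end <- cds$cds_end[idx]
  if (any((end - start + 1L) %% 3L != 0L)) {
    abort("CDS length must be divisible by 3 for synonymy calls.")
  }
  inside <- snps$pos >= start & snps$pos <= end
  if (!all(inside)) {
    bad <- which(!inside)[1]
    abort(sprintf("SNP outside CDS: %s position %d.", snps$gene[bad], snps$pos[bad]))
  }
  vapply(seq_len(nrow(snps)), function(i) {
    seq <- unigenes$sequence[sidx[i]]
    at <- substr(seq, snps$pos[i], snps$pos[i])
    if (at != snps$ref[i]) {
      abort(sprintf("reference mismatch at %s position %d: sequence has %s, SNP ref is %s.",
                    snps$gene[i], snps$pos[i], at, snps$ref[i]))
    }
    codon_i <- (snps$pos[i] - start[i]) %/% 3L
    cstart <- start[i] + codon_i * 3L
    codon <- substr(seq, cstart, cstart + 2L)
    within <- snps$pos[i] - cstart + 1L
    alt_codon <- codon
    substr(alt_codon, within, within) <- snps$alt[i]
    if (gc_table[[codon]] == gc_table[[alt_codon]]) "synonymous" else "nonsynonymous"
  }, character(1))
}

#' N50 of a set of sequence lengths
#'
#' The largest length L such that sequences of length >= L together cover
#' at least half of the total assembled bases (descending cumulative-sum
#' definition).
#'
#' @param lengths Positive numeric vector (non-empty).
#' @return The N50, as an integer when the input is integral.
#' @examples
#' calc_n50(c(2, 2, 2, 3, 3, 4)) # 3
#' @export
calc_n50 <- function(lengths) {
  if (length(lengths) == 0) abort("`lengths` must be non-empty.")
  if (any(lengths <= 0)) abort("`lengths` must be positive.")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Assembly length summary
#'
#' @param lengths Positive numeric vector of sequence lengths.
#' @return One-row tibble: `n_seqs`, `total_bp`, `mean_bp`, `min_bp`,
#'   `max_bp`, `n50_bp`.
#' @export
assembly_stats <- function(lengths) {
  tibble(n_seqs = length(lengths), total_bp = sum(lengths),
         mean_bp = mean(lengths), min_bp = min(lengths),
         max_bp = max(lengths), n50_bp = calc_n50(lengths))
}

#' Read-quality summary of a FASTQ file
#'
#' Computes the standard sequencing QC metrics from Phred+33 qualities:
#' Q20 and Q30 (percent of bases with quality >= 20 / >= 30), GC content
#' (percent G+C among called A/C/G/T bases; N excluded from the
#' denominator), and the mean per-base error rate
#' `mean(10^(-Q/10)) * 100`.
#'
#' @param path FASTQ file (Phred+33).
#' @return One-row tibble: `n_reads`, `n_bases`, `q20_pct`, `q30_pct`,
#'   `gc_pct`, `error_rate_pct`.
#' @export
read_qc <- function(path) {
  reads <- tryCatch(
    suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path)),
    error = function(e) abort(paste0("malformed FASTQ file '", path, "': ",
                                     conditionMessage(e)))
  )
  if (length(reads) == 0) {
    return(tibble(n_reads = 0L, n_bases = 0L, q20_pct = NA_real_,
                  q30_pct = NA_real_, gc_pct = NA_real_,
                  error_rate_pct = NA_real_))
  }
  qual <- suppressWarnings(unlist(as(Biostrings::quality(reads), "IntegerList")))
  freq <- colSums(Biostrings::alphabetFrequency(reads))
  acgt <- sum(freq[c("A", "C", "G", "T")])
  tibble(
    n_reads = length(reads),
    n_bases = sum(Biostrings::width(reads)),
    q20_pct = 100 * mean(qual >= 20),
    q30_pct = 100 * mean(qual >= 30),
    gc_pct = 100 * sum(freq[c("G", "C")]) / acgt,
    error_rate_pct = 100 * mean(10^(-qual / 10))
  )
}

#' Full SNP summary for a variant set
#'
#' Combines the substitution spectrum, overall per-kb density,
#' codon-position tallies, synonymy counts (when a CDS annotation is
#' given) and per-individual SNP counts (when genotype calls are given).
#'
#' @param sites Tibble `gene`, `pos`, `ref`, `alt`.
#' @param unigenes Tibble `gene`, `length`, `sequence`.
#' @param cds Optional tibble `gene`, `cds_start`, `cds_end`.
#' @param calls Optional genotype-call tibble (per-individual counts: a
#'   SNP is counted for an individual that carries the alternate allele).
#' @return A `snp_summary`: list with `spectrum` (a `snp_spectrum`),
#'   `codon_positions` (tibble `codon_position`, `n`), `synonymy`
#'   (tibble `synonymy`, `n`, or NULL), `per_individual` (tibble
#'   `sample`, `n_snps`, or NULL), and `density_per_kb`.
#' @export
summarize_variants <- function(sites, unigenes, cds = NULL, calls = NULL) {
  total_len <- sum(unigenes$length)
  spectrum <- tally_spectrum(sites, total_length_bp = total_len)
  codon_tab <- NULL
  synonymy <- NULL
  if (!is.null(cds) && nrow(sites) > 0) {
    idx <- match(sites$gene, cds$gene)
    cp <- codon_position(sites$pos, cds$cds_start[idx], cds$cds_end[idx])
    codon_tab <- tibble(codon_position = factor(cp, levels = c("first", "second", "third", "noncoding"))) |>
      count(.data$codon_position, name = "n", .drop = FALSE)
    coding <- sites[cp != "noncoding", ]
    if (nrow(coding) > 0) {
      syn <- classify_synonymy(coding, cds, unigenes)
      synonymy <- tibble(synonymy = factor(syn, levels = c("synonymous", "nonsynonymous"))) |>
        count(.data$synonymy, name = "n", .drop = FALSE)
    }
  }
  per_ind <- NULL
  if (!is.null(calls) && nrow(calls) > 0) {
    per_ind <- calls |>
      left_join(sites, by = c("gene", "pos")) |>
      group_by(.data$sample) |>
      summarise(n_snps = sum(!is.na(.data$allele) & .data$allele == .data$alt),
                .groups = "drop")
  }
  structure(list(spectrum = spectrum, codon_positions = codon_tab,
                 synonymy = synonymy, per_individual = per_ind,
                 density_per_kb = spectrum$density_per_kb),
            class = "snp_summary")
}

#' @export
print.snp_summary <- function(x, ...) {
  print(x$spectrum)
  if (!is.null(x$codon_positions)) {
    cat("codon positions:\n"); print(x$codon_positions)
  }
  if (!is.null(x$synonymy)) {
    cat("synonymy:\n"); print(x$synonymy)
  }
  if (!is.null(x$per_individual)) {
    cat("per individual:\n"); print(x$per_individual)
  }
  invisible(x)
}

#' @method glance snp_summary
#' @export
glance.snp_summary <- function(x, ...) {
  glance(x$spectrum)
}
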
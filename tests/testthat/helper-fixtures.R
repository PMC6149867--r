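# small configurations and shared fixtures built in code

small_config <- function(seed = 11L, reads_per_sample = 50L, ...) {
  sim_config(seed = seed, n_genes = 120L, n_male_biased = 6L,
             n_female_biased = 4L, n_male_specific = 4L,
             n_female_specific = 3L, n_snp_sites = 20L,
             n_sex_segregating = 5L, reads_per_sample = reads_per_sample, ...)
}

design_3v3 <- function() {
  tibble::tibble(sample = c("F1", "F2", "F3", "M1", "M2", "M3"),
                 sex = c("F", "F", "F", "M", "M", "M"))
}

# long genotype-call tibble from per-individual allele vectors
calls_from_alleles <- function(f, m, gene = "g1", pos = 100L, depth = 10L) {
  d <- design_3v3()[seq_len(length(f) + length(m)), ]
  d$sex <- c(rep("F", length(f)), rep("M", length(m)))
  tibble::tibble(gene = gene, pos = as.integer(pos), sample = d$sample,
                 sex = d$sex, allele = c(f, m), depth = as.integer(depth))
}

# brute-force BH step-up, independent of stats::p.adjust
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

# brute-force segregation filter: direct restatement of the definition
segregating_oracle <- function(calls, design, min_depth = NULL) {
  keys <- unique(calls[c("gene", "pos")])
  hits <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- calls[calls$gene == keys$gene[i] & calls$pos == keys$pos[i], ]
    sub <- sub[sub$sample %in% design$sample, ]
    if (nrow(sub) != nrow(design)) next
    if (anyNA(sub$allele)) next
    if (!is.null(min_depth) && any(sub$depth < min_depth)) next
    fa <- unique(sub$allele[sub$sex == "F"])
    ma <- unique(sub$allele[sub$sex == "M"])
    if (length(fa) == 1 && length(ma) == 1 && fa != ma) {
      hits[[length(hits) + 1]] <-
        tibble::tibble(gene = keys$gene[i], pos = keys$pos[i],
                       female_allele = fa, male_allele = ma)
    }
  }
  if (length(hits) == 0) {
    return(tibble::tibble(gene = character(), pos = integer(),
                          female_allele = character(), male_allele = character()))
  }
  out <- dplyr::bind_rows(hits)
  out[order(out$gene, out$pos), ]
}
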
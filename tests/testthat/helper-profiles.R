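# Fixture builders and an independent per-locus oracle for pair comparison.

tiny_panel <- function(n = 28, chrom_per = 4L) {
  snp_panel(tibble::tibble(
    rsid = sprintf("rs%03d", seq_len(n)),
    chrom = paste0("chr", ((seq_len(n) - 1L) %/% chrom_per) + 1L),
    pos = (((seq_len(n) - 1L) %% chrom_per) + 1L) * 1000L,
    ref = rep(c("A", "G"), length.out = n),
    alt = rep(c("T", "C"), length.out = n),
    pop_af = round(0.2 + 0.6 * (seq_len(n) - 1) / max(n - 1, 1), 3)
  ), name = "tiny")
}

# Exact-count profile from genotype codes (0/1/2, NA = NO_CALL via depth 0).
profile_from_codes <- function(sample_id, panel, codes, depth = 100L) {
  n_alt <- dplyr::case_when(is.na(codes) ~ 0L,
                            codes == 0L ~ 0L,
                            codes == 1L ~ as.integer(depth %/% 2),
                            TRUE ~ as.integer(depth))
  n_total <- ifelse(is.na(codes), 0L, as.integer(depth))
  tibble::tibble(
    sample_id = sample_id,
    rsid = panel$rsid, chrom = panel$chrom, pos = panel$pos,
    ref = panel$ref, alt = panel$alt,
    ref_count = n_total - n_alt, alt_count = n_alt, other_count = 0L,
    depth = n_total,
    vaf = ifelse(n_total > 0, n_alt / n_total, NA_real_),
    genotype = call_genotype(n_total - n_alt, n_alt)
  )
}

# Random profile with noisy VAFs and occasional NO_CALL loci.
random_profile <- function(sample_id, panel, p_nocall = 0.1) {
  n <- nrow(panel)
  codes <- sample(0:2, n, replace = TRUE)
  codes[runif(n) < p_nocall] <- NA
  n_total <- ifelse(is.na(codes), sample(0:20, n, replace = TRUE), 100L)
  mu <- c(0.02, 0.5, 0.98)[ifelse(is.na(codes), 1L, codes + 1L)]
  n_alt <- rbinom(n, n_total, mu)
  tibble::tibble(
    sample_id = sample_id,
    rsid = panel$rsid, chrom = panel$chrom, pos = panel$pos,
    ref = panel$ref, alt = panel$alt,
    ref_count = as.integer(n_total - n_alt), alt_count = as.integer(n_alt),
    other_count = 0L, depth = as.integer(n_total),
    vaf = ifelse(n_total > 0, n_alt / n_total, NA_real_),
    genotype = call_genotype(n_total - n_alt, n_alt)
  )
}

# Independent oracle: plain per-locus loop, stats::cor for the correlation,
# with the same documented degenerate-variance rule.
naive_compare <- function(x, y) {
  x <- x[order(x$rsid), ]
  y <- y[order(y$rsid), ]
  n_eval <- 0L
  n_conc <- 0L
  vx <- c()
  vy <- c()
  disc <- list()
  for (k in seq_len(nrow(x))) {
    if (x$genotype[k] == "NO_CALL" || y$genotype[k] == "NO_CALL") next
    n_eval <- n_eval + 1L
    vx <- c(vx, x$vaf[k])
    vy <- c(vy, y$vaf[k])
    if (x$genotype[k] == y$genotype[k]) {
      n_conc <- n_conc + 1L
    } else {
      disc[[length(disc) + 1]] <- c(x$chrom[k], x$pos[k], x$rsid[k])
    }
  }
  correlation <- if (n_eval < 2) {
    NA_real_
  } else if (stats::sd(vx) == 0 || stats::sd(vy) == 0) {
    if (max(abs(vx - vy)) <= 0.1) 1 else 0
  } else {
    stats::cor(vx, vy)
  }
  list(n_evaluable = n_eval, n_concordant = n_conc,
       fraction = if (n_eval > 0) n_conc / n_eval else NA_real_,
       correlation = correlation,
       discordant_rsids = sort(vapply(disc, `[`, character(1), 3)))
}

# Cohort with the acceptance-scale planted errors: 3 swaps (+ optionally a
# mislabel onto an existing patient).
planted_cohort <- function(seed, n_patients = 200, with_mislabel = TRUE,
                           mean_depth = 100) {
  panel <- bundled_panel()
  coh <- simulate_cohort(panel, n_patients, mean_depth = mean_depth,
                         base_error_rate = 0.001, seed = seed)
  ids <- coh$samples$sample_id
  tp2 <- coh$samples$sample_id[coh$samples$timepoint == 2]
  specs <- list(swap_error(tp2[1], tp2[2]),
                swap_error(tp2[3], tp2[4]),
                swap_error(tp2[5], tp2[6]))
  if (with_mislabel) {
    # relabel patient 15's TP2 sample with patient 16's identifier
    specs <- c(specs, list(mislabel_error(tp2[15],
                                          coh$samples$label_patient[
                                            coh$samples$true_patient == 16][1])))
  }
  plant_errors(coh, specs)
}
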
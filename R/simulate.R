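#' Draw diploid genotypes under Hardy-Weinberg equilibrium
#'
#' For each patient and panel locus a genotype is drawn with probabilities
#' \eqn{((1-p)^2, 2p(1-p), p^2)} for HOM_REF / HET / HOM_ALT, where `p` is
#' the locus's population alternative-allele frequency.
#'
#' @param panel A [snp_panel()] whose every locus has `pop_af` set.
#' @param n_patients Number of patients to draw.
#' @param seed Integer seed; the draw is reproducible.
#' @return An integer matrix (patients x loci; 0 = HOM_REF, 1 = HET,
#'   2 = HOM_ALT) with locus rsIDs as column names.
#' @export
simulate_genotypes <- function(panel, n_patients, seed = 1L) {
  panel <- snp_panel(panel, name = attr(panel, "name") %||% "panel")
  p <- panel$pop_af
  if (anyNA(p)) {
    abort(paste0("pop_af missing for locus/loci: ",
                 paste(panel$rsid[is.na(p)], collapse = ", ")))
  }
  n_loci <- nrow(panel)
  cum1 <- matrix((1 - p)^2, n_patients, n_loci, byrow = TRUE)
  cum2 <- matrix((1 - p)^2 + 2 * p * (1 - p), n_patients, n_loci,
                 byrow = TRUE)
  u <- withr::with_seed(seed,
                        matrix(runif(n_patients * n_loci), n_patients, n_loci))
  g <- (u > cum1) + (u > cum2)
  storage.mode(g) <- "integer"
  colnames(g) <- panel$rsid
  g
}

#' Simulate read counts for samples with known genotypes
#'
#' Per sample and locus, sequencing depth is drawn from a negative
#' binomial with mean `mean_depth` (dispersion `depth_dispersion`; large
#' values approach Poisson), and the alternative-read count from a
#' binomial with success probability `e`, `0.5` or `1 - e` for
#' HOM_REF / HET / HOM_ALT, where `e = base_error_rate` (sequencing errors
#' modelled as ref/alt flips; `other_count` is 0). Samples of the same
#' patient share genotypes but have independent read noise.
#'
#' @param genotypes Integer matrix from [simulate_genotypes()].
#' @param panel The [snp_panel()] the genotypes were drawn on.
#' @param sample_map A data frame with columns `sample_id` and `patient`
#'   (row index into `genotypes`), one row per sample to simulate.
#' @param mean_depth Mean sequencing depth; default 100.
#' @param depth_dispersion Negative-binomial size parameter; default 100
#'   (mildly overdispersed, as is typical for targeted sequencing).
#' @param base_error_rate Per-read error probability; default 0.001.
#' @param seed Integer seed.
#' @param quality A [quality_config()] used to call genotypes on the
#'   simulated counts.
#' @return A long profile tibble (rows = samples x loci), as from
#'   [extract_readcounts()].
#' @export
simulate_readcounts <- function(genotypes, panel, sample_map,
                                mean_depth = 100, depth_dispersion = 100,
                                base_error_rate = 0.001, seed = 1L,
                                quality = quality_config()) {
  panel <- snp_panel(panel, name = attr(panel, "name") %||% "panel")
  sample_map <- as_tibble(sample_map)
  stopifnot(all(c("sample_id", "patient") %in% names(sample_map)),
            all(sample_map$patient >= 1),
            all(sample_map$patient <= nrow(genotypes)),
            mean_depth > 0, base_error_rate >= 0, base_error_rate < 0.5)
  n_s <- nrow(sample_map)
  n_l <- nrow(panel)
  mu_of <- c(base_error_rate, 0.5, 1 - base_error_rate)
  gcodes <- genotypes[sample_map$patient, , drop = FALSE]
  mu <- matrix(mu_of[gcodes + 1L], n_s, n_l)
  draws <- withr::with_seed(seed, {
    depth <- matrix(rnbinom(n_s * n_l, size = depth_dispersion,
                            mu = mean_depth), n_s, n_l)
    alt <- matrix(rbinom(n_s * n_l, as.vector(depth), as.vector(mu)),
                  n_s, n_l)
    list(depth = depth, alt = alt)
  })
  counts_to_profiles(draws$depth, draws$alt, panel, sample_map$sample_id,
                     quality)
}

# depth/alt matrices (samples x loci) -> long profile tibble.
counts_to_profiles <- function(depth_mat, alt_mat, panel, sample_ids,
                               quality) {
  n_s <- length(sample_ids)
  n_l <- nrow(panel)
  long <- tibble(
    sample_id = rep(sample_ids, each = n_l),
    rsid = rep(panel$rsid, n_s),
    chrom = rep(panel$chrom, n_s),
    pos = rep(panel$pos, n_s),
    ref = rep(panel$ref, n_s),
    alt = rep(panel$alt, n_s),
    ref_count = as.integer(t(depth_mat - alt_mat)),
    alt_count = as.integer(t(alt_mat)),
    other_count = 0L
  )
  long %>%
    mutate(
      depth = .data$ref_count + .data$alt_count,
      vaf = ifelse(.data$depth > 0, .data$alt_count / .data$depth, NA_real_),
      genotype = call_genotype(.data$ref_count, .data$alt_count, quality)
    )
}

#' Planted handling-error specifications
#'
#' Constructors for the error specs accepted by [plant_errors()] and
#' [simulate_cohort()]. `swap_error()` exchanges the full sample labels of
#' two profiles (as when two tubes are interchanged); `mislabel_error()`
#' rewrites one sample's patient identifier; `contamination_error()` mixes
#' a fraction `fraction` of a donor sample's DNA into a sample (expected
#' allele fractions are mixed, then reads are re-drawn);
#' `cna_shift_error()` shifts the expected VAF of the heterozygous loci on
#' one chromosome by `vaf_delta` (clamped to `[0, 1]`), emulating a
#' copy-number aberration that changed between timepoints.
#'
#' @param x_id,y_id,sample_id,donor_id Sample names (as emitted by
#'   [simulate_cohort()]) the error applies to.
#' @param new_patient_label Replacement patient identifier string.
#' @param fraction Contaminating fraction in `(0, 0.5]`.
#' @param chrom Chromosome whose heterozygous loci are shifted.
#' @param vaf_delta Shift added to the expected heterozygous VAF.
#' @return An error-spec list for [plant_errors()].
#' @name error_specs
NULL

#' @rdname error_specs
#' @export
swap_error <- function(x_id, y_id) {
  stopifnot(x_id != y_id)
  list(type = "swap", x_id = x_id, y_id = y_id)
}

#' @rdname error_specs
#' @export
mislabel_error <- function(sample_id, new_patient_label) {
  list(type = "mislabel", sample_id = sample_id,
       new_patient_label = as.character(new_patient_label))
}

#' @rdname error_specs
#' @export
contamination_error <- function(sample_id, donor_id, fraction) {
  stopifnot(fraction > 0, fraction <= 0.5, sample_id != donor_id)
  list(type = "contaminate", sample_id = sample_id, donor_id = donor_id,
       fraction = fraction)
}

#' @rdname error_specs
#' @export
cna_shift_error <- function(sample_id, chrom, vaf_delta) {
  list(type = "cna_shift", sample_id = sample_id, chrom = chrom,
       vaf_delta = vaf_delta)
}

#' Simulate a longitudinal patient cohort with optional planted errors
#'
#' Draws Hardy-Weinberg genotypes per patient, simulates read counts for
#' every (patient, timepoint) sample, names samples
#' `CLL-<patient>-<run>-TP<k>` (so the default patient-id regex of
#' [scan_cohort()] applies), and optionally plants handling errors. The
#' truth ledger records the planted errors together with the sample pairs
#' they imply: `unexpected_pairs` (label pairs from different patients
#' that share a true genotype) and `broken_expected` (same-label pairs
#' whose true genotypes differ).
#'
#' @inheritParams simulate_readcounts
#' @param panel A [snp_panel()] with `pop_af` set, e.g. [bundled_panel()].
#' @param n_patients Number of patients.
#' @param timepoints_per_patient Samples per patient: a single integer or
#'   a length-`n_patients` vector; default 2.
#' @param seed Master seed; every random draw derives from it.
#' @param planted_errors List of error specs (see [error_specs]).
#' @return An object of class `synthetic_cohort`: a list with `profiles`
#'   (long tibble ready for [scan_cohort()]), `samples` (the
#'   label/truth map), `genotypes` (true patients x loci matrix), `truth`
#'   (`errors`, `unexpected_pairs`, `broken_expected`), `panel` and
#'   `config`.
#' @export
simulate_cohort <- function(panel, n_patients, timepoints_per_patient = 2L,
                            mean_depth = 100, depth_dispersion = 100,
                            base_error_rate = 0.001, seed = 1L,
                            planted_errors = list(),
                            quality = quality_config()) {
  panel <- snp_panel(panel, name = attr(panel, "name") %||% "panel")
  tp <- timepoints_per_patient
  if (length(tp) == 1) tp <- rep(as.integer(tp), n_patients)
  stopifnot(length(tp) == n_patients, all(tp >= 1))

  samples <- tibble(
    true_patient = rep(seq_len(n_patients), tp),
    timepoint = unlist(lapply(tp, seq_len))
  ) %>%
    mutate(
      uid = dplyr::row_number(),
      label_patient = as.character(10000000 + .data$true_patient),
      run_id = sprintf("%02dS%05d", .data$timepoint, .data$uid)
    ) %>%
    mutate(sample_id = sprintf("CLL-%s-%s-TP%d", .data$label_patient,
                               .data$run_id, .data$timepoint)) %>%
    select("uid", "true_patient", "label_patient", "run_id", "timepoint",
           "sample_id")

  genotypes <- simulate_genotypes(panel, n_patients, seed)
  profiles <- simulate_readcounts(
    genotypes, panel,
    tibble(sample_id = samples$sample_id, patient = samples$true_patient),
    mean_depth = mean_depth, depth_dispersion = depth_dispersion,
    base_error_rate = base_error_rate, seed = seed + 1L, quality = quality
  )
  profiles$uid <- rep(samples$uid, each = nrow(panel))

  cohort <- structure(list(
    panel = panel,
    samples = samples,
    genotypes = genotypes,
    profiles = profiles,
    truth = list(errors = list(),
                 unexpected_pairs = tibble(x_id = character(),
                                           y_id = character()),
                 broken_expected = tibble(x_id = character(),
                                          y_id = character(),
                                          patient_id = character())),
    config = list(n_patients = n_patients, timepoints = tp,
                  mean_depth = mean_depth,
                  depth_dispersion = depth_dispersion,
                  base_error_rate = base_error_rate, seed = seed,
                  quality = quality)
  ), class = "synthetic_cohort")

  if (length(planted_errors) > 0) {
    cohort <- plant_errors(cohort, planted_errors)
  }
  cohort
}

implied_pairs <- function(samples) {
  pairs_of <- function(d, same_true, same_label) {
    a <- cross_join(
      select(d, x_uid = "uid", x_id = "sample_id",
             x_true = "true_patient", x_label = "label_patient"),
      select(d, y_uid = "uid", y_id = "sample_id",
             y_true = "true_patient", y_label = "label_patient")
    ) %>%
      filter(.data$x_uid < .data$y_uid)
    if (same_true) a <- filter(a, .data$x_true == .data$y_true,
                               .data$x_label != .data$y_label)
    if (same_label) a <- filter(a, .data$x_label == .data$y_label,
                                .data$x_true != .data$y_true)
    lo <- pmin(a$x_id, a$y_id)
    hi <- pmax(a$x_id, a$y_id)
    tibble(x_id = lo, y_id = hi,
           patient_id = if (same_label) a$x_label else NA_character_) %>%
      arrange(.data$x_id, .data$y_id)
  }
  list(
    unexpected = select(pairs_of(samples, TRUE, FALSE), "x_id", "y_id"),
    broken = pairs_of(samples, FALSE, TRUE)
  )
}

#' Plant handling errors into a synthetic cohort
#'
#' Applies the given error specs (see [error_specs]) to a
#' [simulate_cohort()] object. Label-level errors (swap, mislabel) only
#' relabel profiles and never touch the underlying genotype matrix;
#' contamination and copy-number shifts modify read counts (depths are
#' kept, alternative reads are re-drawn from the perturbed expected allele
#' fractions). Sample references in the specs are resolved against the
#' sample names *before* any spec of this call is applied. The truth
#' ledger is recomputed from the final label/truth map, so the implied
#' unexpected pairs and broken expected pairs are always consistent with
#' the emitted sample names.
#'
#' @param cohort A `synthetic_cohort`.
#' @param specs List of error specs.
#' @param seed Seed for the re-drawn reads of count-level errors; derived
#'   from the cohort seed by default.
#' @return The modified `synthetic_cohort`.
#' @export
plant_errors <- function(cohort, specs, seed = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (length(specs) == 0) return(cohort)
  if (!is.null(specs$type)) specs <- list(specs)
  seed <- seed %||% ((cohort$config$seed %% 1000000L) * 211L + 483L)
  samples <- cohort$samples

  # Resolve every sample reference against the names as they are *now*,
  # before any spec of this call moves a label.
  resolve <- function(id) {
    uid <- samples$uid[match(id, samples$sample_id)]
    if (is.na(uid)) abort(paste0("unknown sample in error spec: ", id))
    uid
  }
  specs <- lapply(specs, function(s) {
    if (s$type == "swap") {
      s$.x_uid <- resolve(s$x_id)
      s$.y_uid <- resolve(s$y_id)
    } else {
      s$.uid <- resolve(s$sample_id)
      if (s$type == "contaminate") s$.donor_uid <- resolve(s$donor_id)
    }
    s
  })
  swap_uids <- unlist(lapply(specs, function(s) {
    if (s$type == "swap") c(s$.x_uid, s$.y_uid) else NULL
  }))
  prev_swaps <- unlist(lapply(cohort$truth$errors, function(s) {
    if (s$type == "swap") c(s$.x_uid, s$.y_uid) else NULL
  }))
  if (anyDuplicated(c(swap_uids, prev_swaps))) {
    abort("contradictory error specs: a sample may be swapped at most once")
  }

  label_cols <- c("label_patient", "run_id", "timepoint", "sample_id")
  count_mods <- list()
  for (k in seq_along(specs)) {
    s <- specs[[k]]
    if (s$type == "swap") {
      a <- match(s$.x_uid, samples$uid)
      b <- match(s$.y_uid, samples$uid)
      samples[c(a, b), label_cols] <- samples[c(b, a), label_cols]
    } else if (s$type == "mislabel") {
      a <- match(s$.uid, samples$uid)
      samples$label_patient[a] <- s$new_patient_label
      samples$sample_id[a] <- sprintf("CLL-%s-%s-TP%d",
                                      samples$label_patient[a],
                                      samples$run_id[a],
                                      samples$timepoint[a])
    } else if (s$type %in% c("contaminate", "cna_shift")) {
      count_mods[[length(count_mods) + 1]] <- s
    } else {
      abort(paste0("unknown error spec type: ", s$type))
    }
  }
  if (anyDuplicated(samples$sample_id)) {
    abort("error specs produce duplicate sample names")
  }

  profiles <- cohort$profiles
  profiles$sample_id <- samples$sample_id[match(profiles$uid, samples$uid)]

  if (length(count_mods) > 0) {
    e <- cohort$config$base_error_rate
    mu_of <- c(e, 0.5, 1 - e)
    panel <- cohort$panel
    profiles <- withr::with_seed(seed, {
      for (s in count_mods) {
        uid <- s$.uid
        rows <- which(profiles$uid == uid)
        rows <- rows[match(panel$rsid, profiles$rsid[rows])]
        true_pat <- samples$true_patient[match(uid, samples$uid)]
        g <- cohort$genotypes[true_pat, panel$rsid]
        mu <- mu_of[g + 1L]
        if (s$type == "contaminate") {
          dpat <- samples$true_patient[match(s$.donor_uid, samples$uid)]
          gd <- cohort$genotypes[dpat, panel$rsid]
          mu <- (1 - s$fraction) * mu + s$fraction * mu_of[gd + 1L]
          touch <- seq_along(mu)
        } else {
          touch <- which(panel$chrom == s$chrom & g == 1L)
          mu[touch] <- pmin(pmax(mu[touch] + s$vaf_delta, 0), 1)
        }
        if (length(touch) > 0) {
          idx <- rows[touch]
          depth <- profiles$depth[idx]
          alt <- rbinom(length(idx), depth, mu[touch])
          profiles$alt_count[idx] <- alt
          profiles$ref_count[idx] <- depth - alt
        }
      }
      profiles
    })
    profiles <- profiles %>%
      mutate(
        depth = .data$ref_count + .data$alt_count,
        vaf = ifelse(.data$depth > 0, .data$alt_count / .data$depth,
                     NA_real_),
        genotype = call_genotype(.data$ref_count, .data$alt_count,
                                 cohort$config$quality)
      )
  }

  implied <- implied_pairs(samples)
  cohort$samples <- samples
  cohort$profiles <- profiles
  cohort$truth$errors <- c(cohort$truth$errors, specs)
  cohort$truth$unexpected_pairs <- implied$unexpected
  cohort$truth$broken_expected <- implied$broken
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n")
  cat(sprintf("  patients: %d   samples: %d   loci: %d\n",
              x$config$n_patients, nrow(x$samples), nrow(x$panel)))
  cat(sprintf("  mean depth: %g   error rate: %g   seed: %d\n",
              x$config$mean_depth, x$config$base_error_rate,
              x$config$seed))
  cat(sprintf("  planted errors: %d (implying %d unexpected, %d broken expected pair(s))\n",
              length(x$truth$errors), nrow(x$truth$unexpected_pairs),
              nrow(x$truth$broken_expected)))
  invisible(x)
}

#' Write miniature BAM fixtures reproducing simulated counts
#'
#' Emits, for every sample of a synthetic cohort, a coordinate-sorted and
#' indexed BAM whose pileup at each panel locus reproduces the simulated
#' ref/alt counts exactly, plus the miniature reference FASTA (one short
#' contig per panel chromosome) the reads are laid on. Reads are unpaired,
#' mapping quality 60, base quality 40, each covering exactly one locus;
#' optionally duplicate-flagged decoy reads are added, which a compliant
#' extractor must ignore.
#'
#' @param cohort A [simulate_cohort()] object.
#' @param outdir Output directory (created if needed).
#' @param read_length Read length in bp; panel loci on one chromosome must
#'   be at least this far apart, otherwise an error suggests increasing
#'   the spacing.
#' @param n_decoy_duplicates Number of duplicate-flagged alt-allele reads
#'   to add per locus and sample; default 0.
#' @return A tibble with columns `sample_id`, `bam`, `bai`; the FASTA path
#'   is in the `"reference"` attribute.
#' @export
write_fixture_bams <- function(cohort, outdir, read_length = 100L,
                               n_decoy_duplicates = 0L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  panel <- cohort$panel
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  by_chrom <- split(panel$pos, panel$chrom)
  too_close <- vapply(by_chrom, function(p) any(diff(sort(p)) < read_length),
                      logical(1))
  if (any(too_close)) {
    abort(paste0("panel loci closer than read_length on ",
                 paste(names(by_chrom)[too_close], collapse = ", "),
                 "; increase locus spacing or reduce read_length"))
  }

  chroms <- unique(panel$chrom)
  contig_len <- vapply(chroms, function(ch) {
    max(panel$pos[panel$chrom == ch]) + read_length + 10L
  }, integer(1))
  ref_seq <- withr::with_seed((cohort$config$seed %% 1000000L) + 424243L, {
    lapply(setNames(chroms, chroms), function(ch) {
      s <- sample(c("A", "C", "G", "T"), contig_len[[ch]], replace = TRUE)
      at <- panel$chrom == ch
      s[panel$pos[at]] <- panel$ref[at]
      s
    })
  })
  fasta <- file.path(outdir, "reference_synthetic.fa")
  fa_con <- file(fasta, open = "wt")
  for (ch in chroms) {
    writeLines(paste0(">", ch), fa_con)
    seq_chr <- paste(ref_seq[[ch]], collapse = "")
    writeLines(substring(seq_chr, seq(1, nchar(seq_chr), 70),
                         pmin(seq(1, nchar(seq_chr), 70) + 69,
                              nchar(seq_chr))), fa_con)
  }
  close(fa_con)

  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", chroms, contig_len[chroms]))
  qual <- strrep("I", read_length)

  # Per locus, precompute the ref-carrying and alt-carrying read sequence.
  start <- pmax(panel$pos - read_length %/% 2L, 1L)
  read_seq <- function(l, allele) {
    s <- ref_seq[[panel$chrom[l]]][start[l]:(start[l] + read_length - 1L)]
    s[panel$pos[l] - start[l] + 1L] <- allele
    paste(s, collapse = "")
  }
  seq_ref <- vapply(seq_len(nrow(panel)), function(l) read_seq(l, panel$ref[l]),
                    character(1))
  seq_alt <- vapply(seq_len(nrow(panel)), function(l) read_seq(l, panel$alt[l]),
                    character(1))

  out <- purrr::map(cohort$samples$sample_id, function(sid) {
    prof <- filter(cohort$profiles, .data$sample_id == sid)
    prof <- prof[match(panel$rsid, prof$rsid), ]
    lines <- unlist(lapply(seq_len(nrow(panel)), function(l) {
      n_ref <- prof$ref_count[l]
      n_alt <- prof$alt_count[l]
      n_dup <- n_decoy_duplicates
      if (n_ref + n_alt + n_dup == 0) return(character())
      flags <- c(rep(0L, n_ref + n_alt), rep(1024L, n_dup))
      seqs <- c(rep(seq_ref[l], n_ref), rep(seq_alt[l], n_alt + n_dup))
      sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
              sprintf("%s.%s.r%04d", gsub("[^A-Za-z0-9]", "_", sid),
                      panel$rsid[l], seq_along(flags)),
              flags, panel$chrom[l], start[l], read_length, seqs, qual)
    }))
    sam <- tempfile(fileext = ".sam")
    writeLines(c(header, lines), sam)
    bam <- Rsamtools::asBam(sam, file.path(outdir, sid), overwrite = TRUE,
                            indexDestination = TRUE)
    unlink(sam)
    tibble(sample_id = sid, bam = bam, bai = paste0(bam, ".bai"))
  })
  res <- bind_rows(out)
  attr(res, "reference") <- fasta
  res
}
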
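profile_matrices <- function(profiles) {
  profiles <- as_tibble(profiles)
  needed <- c("sample_id", "rsid", "chrom", "pos", "vaf", "genotype")
  missing_cols <- setdiff(needed, names(profiles))
  if (length(missing_cols) > 0) {
    abort(paste0("profiles are missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  ids <- sort(unique(profiles$sample_id), method = "radix")
  loci <- distinct(profiles, .data$rsid, .data$chrom, .data$pos)
  loci <- loci[genomic_order(loci$chrom, loci$pos), ]
  if (anyDuplicated(loci$rsid)) {
    abort("the same rsid maps to more than one (chrom, pos)")
  }
  if (anyDuplicated(paste(profiles$sample_id, profiles$rsid))) {
    abort("duplicate (sample, locus) rows; sample ids must be unique")
  }
  if (nrow(profiles) != length(ids) * nrow(loci)) {
    abort("samples are not all genotyped on the same panel")
  }
  i <- match(profiles$sample_id, ids)
  j <- match(profiles$rsid, loci$rsid)
  G <- matrix(NA_integer_, length(ids), nrow(loci),
              dimnames = list(ids, loci$rsid))
  V <- matrix(NA_real_, length(ids), nrow(loci),
              dimnames = list(ids, loci$rsid))
  G[cbind(i, j)] <- genotype_code(profiles$genotype)
  V[cbind(i, j)] <- profiles$vaf
  list(G = G, V = V, ids = ids, loci = loci)
}

extract_patient_id <- function(sample_ids, id_pattern) {
  m <- stringr::str_match(sample_ids, id_pattern)
  if (ncol(m) < 2) {
    abort("id_pattern must contain exactly one capturing group")
  }
  m[, 2]
}

#' Scan a cohort for matching sample pairs
#'
#' Compares every unordered pair of samples (each pair once, self-pairs
#' excluded) by genotype concordance and VAF correlation, classifies each
#' pair against `thresholds`, derives the expected same-patient pairs from
#' the sample names, and reports unexpected matches (flagged pairs whose
#' patient identifiers differ). The pairwise computation is vectorised
#' over the full pair matrix and agrees with [compare_pair()] field for
#' field.
#'
#' @param profiles Long profile tibble (rows = samples x loci; see
#'   [extract_readcounts()] or [simulate_cohort()]). All samples must share
#'   one panel and sample ids must be unique.
#' @param thresholds A [match_thresholds()].
#' @param id_pattern Regular expression with one capturing group that
#'   extracts the patient identifier from a sample name; the default
#'   captures the first maximal run of digits. Set to `NULL` to skip
#'   expected-pair derivation.
#' @param quiet Suppress the unevaluable-pair warning.
#' @return An object of class `cohort_scan` with elements `comparisons`
#'   (tibble of all pairs), `matches` (status `MATCH`/`BORDERLINE_MATCH`),
#'   `expected` (verdicts for expected same-patient pairs, see
#'   [check_expected_pairs()]), `unexpected_matches`, `thresholds`,
#'   `sample_ids` and `loci`. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
scan_cohort <- function(profiles, thresholds = match_thresholds(),
                        id_pattern = "([0-9]+)", quiet = FALSE) {
  pm <- profile_matrices(profiles)
  n <- length(pm$ids)
  if (n < 2) abort("cohort scan needs at least 2 samples")

  M <- (!is.na(pm$G)) * 1
  G <- pm$G
  V0 <- pm$V
  V0[is.na(V0) | M == 0] <- 0

  NE <- M %*% t(M)
  NC <- matrix(0, n, n)
  for (g in 0:2) {
    Ig <- (!is.na(G) & G == g) * 1
    NC <- NC + Ig %*% t(Ig)
  }
  VM <- V0 * M
  Sx <- VM %*% t(M)
  Sxy <- VM %*% t(VM)
  Sxx <- (V0^2 * M) %*% t(M)
  varx <- pmax(NE * Sxx - Sx^2, 0)
  vary <- t(varx)
  den <- sqrt(varx) * sqrt(vary)
  R <- ifelse(den > 0, (NE * Sxy - Sx * t(Sx)) / den, NA_real_)
  R <- pmin(pmax(R, -1), 1)

  ut <- which(upper.tri(NE), arr.ind = TRUE)
  i <- ut[, 1]
  j <- ut[, 2]
  ne <- NE[ut]
  corr <- R[ut]
  # Degenerate pairs (a constant VAF vector): apply the near-identity rule
  # of vaf_correlation() pairwise.
  degen <- which(ne >= 2 & (sqrt(varx[ut]) <= .DEGENERATE_SD * ne |
                              sqrt(vary[ut]) <= .DEGENERATE_SD * ne))
  for (k in degen) {
    m <- M[i[k], ] == 1 & M[j[k], ] == 1
    corr[k] <- if (max(abs(pm$V[i[k], m] - pm$V[j[k], m])) <= 0.1) 1 else 0
  }
  corr[ne < 2] <- NA_real_

  fraction <- ifelse(ne > 0, NC[ut] / ne, NA_real_)
  status <- classify_pair(fraction, corr, thresholds)
  unev <- ne < thresholds$min_evaluable
  status[unev] <- "UNEVALUABLE"
  if (any(unev) && !quiet) {
    warn(sprintf("%d pair(s) have fewer than %d evaluable loci: UNEVALUABLE",
                 sum(unev), thresholds$min_evaluable))
  }

  comparisons <- tibble(
    x_id = pm$ids[i], y_id = pm$ids[j],
    n_evaluable = as.integer(ne), n_concordant = as.integer(NC[ut]),
    fraction_concordant = fraction, correlation = corr, status = status
  ) %>%
    arrange(.data$x_id, .data$y_id)

  res <- structure(list(
    comparisons = comparisons,
    matches = filter(comparisons,
                     .data$status %in% c("MATCH", "BORDERLINE_MATCH")),
    expected = NULL,
    unexpected_matches = NULL,
    thresholds = thresholds,
    sample_ids = pm$ids,
    loci = pm$loci,
    id_pattern = id_pattern,
    G = pm$G, V = pm$V
  ), class = "cohort_scan")

  if (!is.null(id_pattern)) {
    expected <- derive_expected_pairs(pm$ids, id_pattern)
    res$expected <- check_expected_pairs(expected, res)
    patient <- extract_patient_id(pm$ids, id_pattern)
    px <- patient[match(res$matches$x_id, pm$ids)]
    py <- patient[match(res$matches$y_id, pm$ids)]
    res$unexpected_matches <- res$matches[is.na(px) | is.na(py) | px != py, ]
  }
  res
}

#' Derive expected same-patient pairs from sample names
#'
#' Samples labelled with the same patient identifier (e.g. sequential
#' timepoints of one patient) are expected to share a fingerprint. The
#' identifier is extracted from each sample name with `id_pattern`; by
#' convention it is the first run of digits in the name.
#'
#' @param sample_ids Character vector of sample names.
#' @param id_pattern Regular expression with one capturing group.
#' @return A tibble with columns `x_id`, `y_id`, `patient_id`: all
#'   unordered pairs of samples sharing a patient identifier. Samples
#'   whose name does not match the pattern are excluded with a warning.
#' @export
#' @examples
#' derive_expected_pairs(c("CLL-68035557-02S65286-TP1",
#'                         "CLL-68035557-67S38544-TP2"))
derive_expected_pairs <- function(sample_ids, id_pattern = "([0-9]+)") {
  stopifnot(!anyDuplicated(sample_ids))
  patient <- extract_patient_id(sample_ids, id_pattern)
  if (anyNA(patient)) {
    warn(paste0("sample name(s) without a patient identifier excluded ",
                "from expected pairs: ",
                paste(sample_ids[is.na(patient)], collapse = ", ")))
  }
  tibble(sample_id = sample_ids, patient_id = patient) %>%
    filter(!is.na(.data$patient_id)) %>%
    group_by(.data$patient_id) %>%
    filter(n() >= 2) %>%
    reframe({
      ids <- sort(.data$sample_id, method = "radix")
      if (length(ids) < 2) {
        tibble(x_id = character(), y_id = character())
      } else {
        idx <- utils::combn(length(ids), 2)
        tibble(x_id = ids[idx[1, ]], y_id = ids[idx[2, ]])
      }
    }) %>%
    select("x_id", "y_id", "patient_id")
}

#' Verify expected same-patient pairs against a scan
#'
#' Each expected pair is looked up in the all-vs-all scan and assigned a
#' verdict: `CONCORDANT` (status `MATCH`), `REVIEW` (`BORDERLINE_MATCH`:
#' concordance in the manual-inspection band, typically copy-number-driven
#' VAF shifts between timepoints), or `DISCORDANT` (`NO_MATCH` or
#' `UNEVALUABLE`) — the latter indicating a probable handling error.
#'
#' @param expected A tibble with columns `x_id`, `y_id` (and optionally
#'   `patient_id`), e.g. from [derive_expected_pairs()] or an external
#'   expected-pairs file.
#' @param scan A [scan_cohort()] result containing both samples of every
#'   expected pair.
#' @return A tibble (class `expected_pairs`) with the pair, its
#'   `patient_id`, `fraction_concordant`, `correlation`, `status` and
#'   `verdict`, sorted by descending correlation.
#' @export
check_expected_pairs <- function(expected, scan) {
  expected <- as_tibble(expected)
  if (!"patient_id" %in% names(expected)) {
    expected$patient_id <- NA_character_
  }
  comp <- scan$comparisons
  key <- pair_key(comp$x_id, comp$y_id)
  idx <- match(pair_key(expected$x_id, expected$y_id), key)
  if (anyNA(idx)) {
    bad <- expected[is.na(idx), ]
    abort(paste0("expected pair(s) reference unscanned samples: ",
                 paste(paste(bad$x_id, bad$y_id, sep = " / "),
                       collapse = "; ")))
  }
  out <- tibble(
    x_id = expected$x_id, y_id = expected$y_id,
    patient_id = expected$patient_id,
    n_evaluable = comp$n_evaluable[idx],
    fraction_concordant = comp$fraction_concordant[idx],
    correlation = comp$correlation[idx],
    status = comp$status[idx]
  ) %>%
    mutate(verdict = dplyr::case_when(
      .data$status == "MATCH" ~ "CONCORDANT",
      .data$status == "BORDERLINE_MATCH" ~ "REVIEW",
      TRUE ~ "DISCORDANT"
    )) %>%
    arrange(desc(!is.na(.data$correlation)), desc(.data$correlation),
            .data$x_id, .data$y_id)
  class(out) <- c("expected_pairs", class(out))
  out
}

discordant_strings <- function(scan, x_id, y_id) {
  lab <- sprintf("%s:%d:%s", scan$loci$chrom, scan$loci$pos, scan$loci$rsid)
  G <- scan$G
  vapply(seq_along(x_id), function(k) {
    gi <- G[x_id[k], ]
    gj <- G[y_id[k], ]
    d <- which(!is.na(gi) & !is.na(gj) & gi != gj)
    paste(lab[d], collapse = ";")
  }, character(1))
}

#' Write the pairwise concordance table
#'
#' Writes `Pairwise_concordance_[suffix]_[timestamp].csv`: one row per
#' unordered sample pair with the concordance fraction, VAF correlation
#' (both 3 decimals), status and the semicolon-joined positions of the
#' discordant loci. Flagged pairs (`MATCH`/`BORDERLINE_MATCH`) appear at
#' the top of the table; within each block rows are sorted by descending
#' correlation.
#'
#' @param scan A [scan_cohort()] result.
#' @inheritParams write_readcounts_table
#' @return The file path, invisibly.
#' @export
write_pairwise_csv <- function(scan, suffix, timestamp = NULL, outdir = ".") {
  timestamp <- timestamp %||% default_timestamp()
  path <- file.path(outdir, sprintf("Pairwise_concordance_%s_%s.csv",
                                    suffix, timestamp))
  out <- scan$comparisons %>%
    mutate(flagged = .data$status %in% c("MATCH", "BORDERLINE_MATCH")) %>%
    arrange(desc(.data$flagged), desc(!is.na(.data$correlation)),
            desc(.data$correlation), .data$x_id, .data$y_id) %>%
    transmute(
      x_sample = .data$x_id, y_sample = .data$y_id, .data$n_evaluable,
      fraction_concordant = fmt3(.data$fraction_concordant),
      correlation = fmt3(.data$correlation), .data$status,
      discordant_positions = discordant_strings(scan, .data$x_id, .data$y_id)
    )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write the expected-pairs table
#'
#' Writes `Expected_concordant_pairs_[suffix]_[timestamp].csv`: all
#' expected same-patient pairs, whether concordant or not, in order of
#' descending correlation coefficient.
#'
#' @param expected A [check_expected_pairs()] result.
#' @inheritParams write_readcounts_table
#' @return The file path, invisibly.
#' @export
write_expected_csv <- function(expected, suffix, timestamp = NULL,
                               outdir = ".") {
  timestamp <- timestamp %||% default_timestamp()
  path <- file.path(outdir, sprintf("Expected_concordant_pairs_%s_%s.csv",
                                    suffix, timestamp))
  out <- as_tibble(expected) %>%
    arrange(desc(!is.na(.data$correlation)), desc(.data$correlation),
            .data$x_id, .data$y_id) %>%
    transmute(x_sample = .data$x_id, y_sample = .data$y_id,
              .data$patient_id,
              fraction_concordant = fmt3(.data$fraction_concordant),
              correlation = fmt3(.data$correlation), .data$verdict)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Pairwise correlation matrix of a scan
#'
#' @param scan A [scan_cohort()] result.
#' @return A symmetric n x n numeric matrix of VAF correlations with unit
#'   diagonal (`NA` where a pair had fewer than 2 jointly called loci).
#' @export
correlation_matrix <- function(scan) {
  ids <- scan$sample_ids
  mat <- matrix(NA_real_, length(ids), length(ids),
                dimnames = list(ids, ids))
  i <- match(scan$comparisons$x_id, ids)
  j <- match(scan$comparisons$y_id, ids)
  mat[cbind(i, j)] <- scan$comparisons$correlation
  mat[cbind(j, i)] <- scan$comparisons$correlation
  diag(mat) <- 1
  mat
}

#' Render the pairwise correlation heatmap
#'
#' Writes `Pairwise_concordance_[suffix]_[timestamp].png`: the symmetric
#' correlation matrix of all sample pairs on a fixed `[-1, 1]` colour
#' scale. The plotted matrix is [correlation_matrix()]; use [autoplot()]
#' to obtain the ggplot without writing a file.
#'
#' @param scan A [scan_cohort()] result.
#' @inheritParams write_readcounts_table
#' @param width,height Device size in inches.
#' @return The file path, invisibly.
#' @export
render_heatmap <- function(scan, suffix, timestamp = NULL, outdir = ".",
                           width = NULL, height = NULL) {
  timestamp <- timestamp %||% default_timestamp()
  path <- file.path(outdir, sprintf("Pairwise_concordance_%s_%s.png",
                                    suffix, timestamp))
  n <- length(scan$sample_ids)
  side <- min(4 + n * 0.08, 20)
  ggplot2::ggsave(path, plot = autoplot(scan),
                  width = width %||% side, height = height %||% side,
                  dpi = 150, units = "in")
  invisible(path)
}

#' Run the full swap-check workflow and write its report files
#'
#' Scans all sample pairs, verifies expected same-patient pairs, and
#' writes the three report files (`SNP_readcounts_*.csv`,
#' `Pairwise_concordance_*.csv`, `Expected_concordant_pairs_*.csv`) plus,
#' optionally, the correlation heatmap PNG.
#'
#' @inheritParams scan_cohort
#' @inheritParams write_readcounts_table
#' @param expected `NULL` to derive expected pairs from sample names via
#'   `id_pattern`, or a data frame with columns `x_id`, `y_id` (an
#'   explicit expected-pairs list).
#' @param heatmap Also write the PNG heatmap; default `FALSE`.
#' @return The `cohort_scan`, invisibly, with the written paths in the
#'   `"files"` attribute.
#' @export
swap_check <- function(profiles, suffix, outdir = ".",
                       thresholds = match_thresholds(),
                       id_pattern = "([0-9]+)", expected = NULL,
                       heatmap = FALSE, timestamp = NULL, quiet = FALSE) {
  timestamp <- timestamp %||% default_timestamp()
  scan <- scan_cohort(profiles, thresholds, id_pattern = id_pattern,
                      quiet = quiet)
  if (!is.null(expected)) {
    expected <- as_tibble(expected)
    if ("x_sample" %in% names(expected)) {
      expected <- rename(expected, x_id = "x_sample", y_id = "y_sample")
    }
    scan$expected <- check_expected_pairs(expected, scan)
  }
  files <- c(
    readcounts = write_readcounts_table(profiles, suffix, timestamp, outdir),
    pairwise = write_pairwise_csv(scan, suffix, timestamp, outdir)
  )
  if (!is.null(scan$expected)) {
    files["expected"] <- write_expected_csv(scan$expected, suffix,
                                            timestamp, outdir)
  }
  if (heatmap) {
    files["heatmap"] <- render_heatmap(scan, suffix, timestamp, outdir)
  }
  attr(scan, "files") <- files
  invisible(scan)
}

subset_seed <- function(seed, size, iteration) {
  (as.integer(seed) %% 100000L) * 20011L + as.integer(size) * 131L +
    as.integer(iteration)
}

#' Sensitivity and specificity as the SNP panel shrinks
#'
#' Re-runs the all-vs-all scan on random locus subsets of decreasing size
#' and scores, against a planted-error truth, how many planted unexpected
#' pairs and broken expected pairs are still detected and how many false
#' positives appear. Each (size, iteration) uses a subset drawn with a
#' deterministic seed derived from `(seed, size, iteration)`, so the whole
#' experiment is reproducible. A false positive is a `MATCH` between
#' samples that share no patient identifier and are not planted
#' duplicates.
#'
#' @inheritParams scan_cohort
#' @param truth A [simulate_cohort()] object, or a list with tibbles
#'   `unexpected_pairs` and `broken_expected` (columns `x_id`, `y_id`).
#' @param sizes Integer vector of subset sizes (each at most the panel
#'   size); defaults to the 26..16 ladder.
#' @param iterations Random subsets per size; default 10.
#' @param seed Master seed for the subset draws.
#' @return A tibble (class `subset_power`) with one row per (size,
#'   iteration): `subset_size, iteration, seed, detected_unexpected,
#'   detected_discordant, false_positives`, plus the planted totals in
#'   attributes `planted_unexpected` / `planted_discordant`. Supports
#'   [glance()] and [autoplot()].
#' @export
subset_sensitivity <- function(profiles, truth,
                               sizes = c(26L, 24L, 22L, 20L, 18L, 16L),
                               iterations = 10L, seed = 1L,
                               thresholds = match_thresholds(),
                               id_pattern = "([0-9]+)") {
  if (inherits(truth, "synthetic_cohort")) truth <- truth$truth
  stopifnot(iterations >= 1)
  profiles <- as_tibble(profiles)
  all_rsids <- unique(profiles$rsid)
  if (any(sizes > length(all_rsids))) {
    abort(sprintf("subset size exceeds panel size (%d loci)",
                  length(all_rsids)))
  }
  ids <- unique(profiles$sample_id)
  patient <- extract_patient_id(ids, id_pattern)
  unexpected_keys <- pair_key(truth$unexpected_pairs$x_id,
                              truth$unexpected_pairs$y_id)
  broken_keys <- pair_key(truth$broken_expected$x_id,
                          truth$broken_expected$y_id)

  grid <- tidyr::expand_grid(subset_size = as.integer(sizes),
                             iteration = seq_len(iterations))
  rows <- purrr::pmap(grid, function(subset_size, iteration) {
    s <- subset_seed(seed, subset_size, iteration)
    sub <- withr::with_seed(s, sample(all_rsids, subset_size))
    scan <- scan_cohort(filter(profiles, .data$rsid %in% sub),
                        thresholds, id_pattern = NULL, quiet = TRUE)
    comp <- scan$comparisons
    keys <- pair_key(comp$x_id, comp$y_id)
    match_keys <- keys[comp$status %in% c("MATCH", "BORDERLINE_MATCH")]
    discord_keys <- keys[comp$status %in% c("NO_MATCH", "UNEVALUABLE")]
    px <- patient[match(comp$x_id, ids)]
    py <- patient[match(comp$y_id, ids)]
    fp <- comp$status == "MATCH" &
      (is.na(px) | is.na(py) | px != py) &
      !keys %in% unexpected_keys
    tibble(subset_size = subset_size, iteration = iteration, seed = s,
           detected_unexpected = sum(unexpected_keys %in% match_keys),
           detected_discordant = sum(broken_keys %in% discord_keys),
           false_positives = sum(fp))
  })
  out <- bind_rows(rows)
  attr(out, "planted_unexpected") <- length(unexpected_keys)
  attr(out, "planted_discordant") <- length(broken_keys)
  class(out) <- c("subset_power", class(out))
  out
}

#' Contamination heuristic from VAF deviations
#'
#' In an uncontaminated diploid sample the VAFs of germline SNPs cluster
#' at 0, 0.5 and 1; cross-individual contamination pulls them away from
#' these anchors. Each sample's score is the mean, over its evaluable
#' loci, of the distance from the VAF to the nearest anchor; a sample is
#' flagged when the score exceeds `flag_threshold`, and individual loci
#' deviating by more than `deviation_tol` are listed.
#'
#' @param profiles Long profile tibble (one or more samples).
#' @param deviation_tol Per-locus deviation above which a locus is listed;
#'   default 0.1.
#' @param flag_threshold Mean-deviation score above which the sample is
#'   flagged; default 0.05.
#' @return A tibble with one row per sample: `sample_id, n_evaluable,
#'   score, flagged` and the list-column `deviant_loci` (tibble with
#'   `rsid, chrom, pos, vaf, deviation`). A sample with zero evaluable
#'   loci gets `NA` score with a warning.
#' @export
contamination_score <- function(profiles, deviation_tol = 0.1,
                                flag_threshold = 0.05) {
  out <- as_tibble(profiles) %>%
    group_by(.data$sample_id) %>%
    group_modify(function(d, key) {
      ev <- d$genotype != "NO_CALL" & !is.na(d$vaf)
      if (!any(ev)) {
        warn(paste0("sample ", key$sample_id[[1]],
                    " has no evaluable loci; contamination score undefined"))
        return(tibble(n_evaluable = 0L, score = NA_real_, flagged = NA,
                      deviant_loci = list(tibble(
                        rsid = character(), chrom = character(),
                        pos = integer(), vaf = double(),
                        deviation = double()))))
      }
      dev <- pmin(d$vaf[ev], abs(d$vaf[ev] - 0.5), 1 - d$vaf[ev])
      listed <- which(dev > deviation_tol)
      tibble(
        n_evaluable = sum(ev),
        score = mean(dev),
        flagged = mean(dev) > flag_threshold,
        deviant_loci = list(tibble(
          rsid = d$rsid[ev][listed], chrom = d$chrom[ev][listed],
          pos = d$pos[ev][listed], vaf = d$vaf[ev][listed],
          deviation = dev[listed]
        ))
      )
    }) %>%
    ungroup()
  out
}
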
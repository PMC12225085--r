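#' Match-calling thresholds
#'
#' Two samples are flagged as a pair when both the fraction of concordant
#' genotype calls and the VAF correlation are high. The classification is
#' three-valued: `MATCH` (fraction >= `concordance_match`),
#' `BORDERLINE_MATCH` (fraction in `[concordance_floor,
#' concordance_match)`, correlation still high — typically same-patient
#' pairs whose heterozygous VAFs were shifted by copy-number aberrations,
#' earmarked for manual review), otherwise `NO_MATCH`. Setting
#' `concordance_match = concordance_floor` collapses this to a
#' single-threshold rule. Pairs with fewer than `min_evaluable` jointly
#' called loci are `UNEVALUABLE`.
#'
#' @param concordance_match Concordance fraction for a full match;
#'   default 0.8.
#' @param concordance_floor Lower concordance bound still flagged (as
#'   borderline); default 0.7.
#' @param correlation_min Minimum VAF correlation; default 0.9.
#' @param min_evaluable Minimum number of jointly called loci; default 10.
#' @return A list of class `match_thresholds`.
#' @export
match_thresholds <- function(concordance_match = 0.8,
                             concordance_floor = 0.7,
                             correlation_min = 0.9,
                             min_evaluable = 10L) {
  stopifnot(concordance_floor > 0,
            concordance_floor <= concordance_match,
            concordance_match <= 1,
            min_evaluable >= 1)
  structure(list(concordance_match = concordance_match,
                 concordance_floor = concordance_floor,
                 correlation_min = correlation_min,
                 min_evaluable = as.integer(min_evaluable)),
            class = "match_thresholds")
}

# Population sd threshold below which a VAF vector counts as constant for
# the degenerate-correlation rule.
.DEGENERATE_SD <- 1e-7

#' Pearson correlation of two VAF vectors
#'
#' Computed over the jointly evaluable loci. Pearson correlation is
#' undefined when either vector is constant (zero variance) — e.g. a
#' sample homozygous-reference at every shared locus; the degenerate rule
#' returns 1 when the vectors are elementwise near-identical (max absolute
#' difference <= `near_tol`) and 0 otherwise, so self-comparison of a
#' constant profile behaves sanely.
#'
#' @param vx,vy Equal-length numeric vectors of VAFs in `[0, 1]`.
#' @param near_tol Elementwise tolerance of the degenerate rule;
#'   default 0.1.
#' @return Correlation in `[-1, 1]`, or `NA` for vectors shorter than 2.
#' @export
#' @examples
#' vaf_correlation(c(0, 0.5, 1), c(1, 0.5, 0))
vaf_correlation <- function(vx, vy, near_tol = 0.1) {
  if (length(vx) != length(vy)) abort("VAF vectors must have equal length")
  n <- length(vx)
  if (n < 2) return(NA_real_)
  sdx <- sqrt(mean((vx - mean(vx))^2))
  sdy <- sqrt(mean((vy - mean(vy))^2))
  if (sdx <= .DEGENERATE_SD || sdy <= .DEGENERATE_SD) {
    return(if (max(abs(vx - vy)) <= near_tol) 1 else 0)
  }
  r <- mean((vx - mean(vx)) * (vy - mean(vy))) / (sdx * sdy)
  max(-1, min(1, r))
}

#' Classify a pair from its concordance fraction and correlation
#'
#' Both thresholds must be satisfied for a pair to be flagged: `MATCH`
#' requires `correlation >= correlation_min` and `fraction >=
#' concordance_match`; `BORDERLINE_MATCH` requires the same correlation
#' with `concordance_floor <= fraction < concordance_match`; anything else
#' is `NO_MATCH`. Vectorised.
#'
#' @param fraction Fraction(s) of concordant loci in `[0, 1]`.
#' @param correlation VAF correlation(s) in `[-1, 1]` (`NA` treated as
#'   failing the correlation threshold).
#' @param thresholds A [match_thresholds()].
#' @return Character vector of statuses.
#' @export
#' @examples
#' classify_pair(c(0.857, 0.75, 0.95, 0.321), c(0.999, 0.95, 0.85, 0.241))
classify_pair <- function(fraction, correlation,
                          thresholds = match_thresholds()) {
  corr_ok <- !is.na(correlation) & correlation >= thresholds$correlation_min
  frac <- ifelse(is.na(fraction), -Inf, fraction)
  dplyr::case_when(
    corr_ok & frac >= thresholds$concordance_match ~ "MATCH",
    corr_ok & frac >= thresholds$concordance_floor ~ "BORDERLINE_MATCH",
    TRUE ~ "NO_MATCH"
  )
}

check_shared_panel <- function(x, y) {
  kx <- paste(x$rsid, x$chrom, x$pos)
  ky <- paste(y$rsid, y$chrom, y$pos)
  if (length(kx) != length(ky) || !setequal(kx, ky)) {
    abort("samples were genotyped on different panels")
  }
}

#' Compare two sample profiles
#'
#' Computes, over the loci called (not `NO_CALL`) in *both* samples: the
#' fraction of concordant genotype calls, the Pearson correlation of the
#' VAFs, the positions of all discordant loci, and the match status. A
#' pair with zero discordant loci is a normal result, not an error.
#' Numeric fields are kept at full precision; rounding to 3 decimals
#' happens only in the CSV writers.
#'
#' @param x,y Single-sample profile tibbles (see [extract_readcounts()])
#'   genotyped on the same panel.
#' @param thresholds A [match_thresholds()].
#' @return A one-row tibble of class `pair_comparison` with columns
#'   `x_id, y_id, n_evaluable, n_concordant, fraction_concordant,
#'   correlation, status` and the list-column `discordant_positions`
#'   (a tibble with `chrom, pos, rsid`).
#' @export
compare_pair <- function(x, y, thresholds = match_thresholds()) {
  x <- as_tibble(x)
  y <- as_tibble(y)
  if (n_distinct(x$sample_id) != 1 || n_distinct(y$sample_id) != 1) {
    abort("compare_pair() expects single-sample profiles; see scan_cohort()")
  }
  check_shared_panel(x, y)
  y <- y[match(paste(x$chrom, x$pos), paste(y$chrom, y$pos)), ]

  evaluable <- x$genotype != "NO_CALL" & y$genotype != "NO_CALL"
  n_evaluable <- sum(evaluable)
  concordant <- evaluable & x$genotype == y$genotype
  n_concordant <- sum(concordant)
  fraction <- if (n_evaluable > 0) n_concordant / n_evaluable else NA_real_
  correlation <- vaf_correlation(x$vaf[evaluable], y$vaf[evaluable])

  disc <- evaluable & !concordant
  discordant <- tibble(chrom = x$chrom[disc], pos = x$pos[disc],
                       rsid = x$rsid[disc])
  discordant <- discordant[genomic_order(discordant$chrom, discordant$pos), ]

  if (n_evaluable < thresholds$min_evaluable) {
    warn(sprintf("pair %s / %s has only %d evaluable loci (min %d): UNEVALUABLE",
                 x$sample_id[[1]], y$sample_id[[1]], n_evaluable,
                 thresholds$min_evaluable))
    status <- "UNEVALUABLE"
  } else {
    status <- classify_pair(fraction, correlation, thresholds)
  }

  out <- tibble(
    x_id = x$sample_id[[1]], y_id = y$sample_id[[1]],
    n_evaluable = n_evaluable, n_concordant = n_concordant,
    fraction_concordant = fraction, correlation = correlation,
    status = status, discordant_positions = list(discordant)
  )
  class(out) <- c("pair_comparison", class(out))
  out
}
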
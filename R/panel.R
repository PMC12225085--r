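#' Construct a SNP fingerprint panel
#'
#' A panel is a tibble of biallelic SNP loci (one row per locus) used as the
#' identity fingerprint. Coordinates are 1-based internally; on disk panels
#' are BED-like (0-based half-open, see [read_snp_panel()]).
#'
#' @param loci A data frame with columns `rsid`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`, and optionally `pop_af` (population alternative-allele
#'   frequency in `[0, 1]`) and `category`.
#' @param name Panel label, kept as the `"name"` attribute.
#'
#' @return A tibble of class `snp_panel`, genomically sorted (chromosome,
#'   then position), with one row per locus.
#' @export
#' @examples
#' snp_panel(tibble::tibble(
#'   rsid = c("rs1", "rs2"), chrom = c("chr2", "chr1"),
#'   pos = c(100L, 200L), ref = c("A", "G"), alt = c("T", "C"),
#'   pop_af = c(0.4, 0.25)
#' ))
snp_panel <- function(loci, name = "panel") {
  loci <- as_tibble(loci)
  required <- c("rsid", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(loci))
  if (length(missing_cols) > 0) {
    abort(paste0("panel is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"pop_af" %in% names(loci)) loci$pop_af <- NA_real_
  if (!"category" %in% names(loci)) loci$category <- NA_character_
  loci <- loci[, c("rsid", "chrom", "pos", "ref", "alt", "pop_af", "category")]
  loci$pos <- as.integer(loci$pos)

  bad_base <- !(loci$ref %in% c("A", "C", "G", "T")) |
    !(loci$alt %in% c("A", "C", "G", "T"))
  if (any(bad_base)) {
    abort(paste0("ref/alt must be single uppercase bases (A/C/G/T); offending rsid(s): ",
                 paste(loci$rsid[bad_base], collapse = ", ")))
  }
  if (any(loci$ref == loci$alt)) {
    abort("ref and alt allele must differ at every locus")
  }
  if (any(loci$pos < 1L)) abort("positions must be >= 1 (1-based)")
  af <- loci$pop_af
  if (any(!is.na(af) & (af < 0 | af > 1))) {
    abort("pop_af must lie in [0, 1]")
  }
  key <- paste(loci$chrom, loci$pos)
  if (anyDuplicated(key)) {
    abort(paste0("duplicate (chrom, pos) in panel: ",
                 paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  loci <- loci[genomic_order(loci$chrom, loci$pos), ]
  structure(loci, name = name, class = c("snp_panel", class(tibble())))
}

#' Read a SNP panel from a BED-like file
#'
#' Expects whitespace-separated columns `chrom, start, end, rsid, ref, alt`
#' and optionally a seventh column with the population alternative-allele
#' frequency (`.` for unknown). Lines starting with `#` are comments. BED
#' coordinates are 0-based half-open, so a SNP record must satisfy
#' `end == start + 1`; internally positions are 1-based (`pos = start + 1`).
#'
#' @param path Path to the panel file.
#' @param name Panel label; defaults to the file name without extension.
#'
#' @return A [snp_panel()] tibble.
#' @export
read_snp_panel <- function(path, name = NULL) {
  if (!file.exists(path)) abort(paste0("panel file not found: ", path))
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0) {
    warn(paste0("panel file has no records: ", path))
    return(snp_panel(tibble(rsid = character(), chrom = character(),
                            pos = integer(), ref = character(),
                            alt = character(), pop_af = double()),
                     name = name))
  }
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  n_fields <- lengths(fields)
  if (any(n_fields < 6)) {
    bad <- keep[which(n_fields < 6)[1]]
    abort(paste0("malformed panel record at line ", bad,
                 ": expected at least 6 columns (chrom start end rsid ref alt)"))
  }
  col <- function(i) vapply(fields, `[`, character(1), i)
  start <- suppressWarnings(as.integer(col(2)))
  end <- suppressWarnings(as.integer(col(3)))
  if (anyNA(start) || anyNA(end)) {
    bad <- keep[which(is.na(start) | is.na(end))[1]]
    abort(paste0("malformed panel record at line ", bad,
                 ": start/end are not integers"))
  }
  not_snv <- end != start + 1L
  if (any(not_snv)) {
    bad <- keep[which(not_snv)[1]]
    abort(paste0("record at line ", bad, " is not a single-base locus ",
                 "(end must equal start + 1)"))
  }
  af <- rep(NA_real_, length(keep))
  has7 <- n_fields >= 7
  if (any(has7)) {
    raw <- vapply(fields[has7], `[`, character(1), 7)
    af[has7] <- suppressWarnings(as.numeric(ifelse(raw == ".", NA, raw)))
  }
  snp_panel(tibble(
    rsid = col(4), chrom = col(1), pos = start + 1L,
    ref = toupper(col(5)), alt = toupper(col(6)), pop_af = af
  ), name = name)
}

#' Write a SNP panel to a BED-like file
#'
#' Emits the canonical on-disk form (0-based half-open coordinates, tab
#' separated, genomically sorted) that [read_snp_panel()] round-trips.
#'
#' @param panel A [snp_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_panel <- function(panel, path) {
  panel <- snp_panel(panel, name = attr(panel, "name") %||% "panel")
  header <- c(
    "# SNP fingerprint panel (BED-like, 0-based half-open coordinates)",
    "# chrom\tstart\tend\trsid\tref\talt\tpop_af"
  )
  rows <- sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%s",
                  panel$chrom, panel$pos - 1L, panel$pos, panel$rsid,
                  panel$ref, panel$alt,
                  ifelse(is.na(panel$pop_af), ".",
                         format(panel$pop_af, trim = TRUE, digits = 10)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' The bundled 28-SNP fingerprint panel
#'
#' A 28-locus panel for chronic lymphocytic leukemia targeted-sequencing
#' cohorts, using published rsID identifiers. Coordinates, alleles and
#' population allele frequencies are synthetic stand-ins (loci placed on
#' short per-chromosome contigs, >= 1 kb apart) so the panel can drive the
#' package's simulations and BAM fixtures without external resources; do not
#' use them to genotype real alignments.
#'
#' @return A [snp_panel()] with 28 loci and `pop_af` set.
#' @export
bundled_panel <- function() {
  path <- system.file("extdata", "snp_panel_28_synthetic.bed",
                      package = "snpswap", mustWork = TRUE)
  read_snp_panel(path, name = "snp_panel_28_synthetic")
}

meta_cols <- c("chrom", "pos", "ref", "alt", "rsid", "af_genome", "af_exome")

sample_columns <- function(matrix_tbl) {
  setdiff(names(matrix_tbl), meta_cols)
}

#' Read a cohort variant matrix
#'
#' A cohort variant matrix records, for every candidate variant, the
#' variant-allele fraction (VAF) observed in every sample of an accumulated
#' cohort; it is the input of the panel-selection pipeline. The file is a
#' TSV with columns `chrom, pos, ref, alt, rsid, af_genome, af_exome`
#' followed by one numeric column per sample (`.` = variant not detected in
#' that sample).
#'
#' @param path Path to the TSV.
#' @return A tibble (wide: one row per variant, one column per sample).
#' @export
read_cohort_matrix <- function(path) {
  tbl <- readr::read_tsv(path, na = c(".", "NA", ""), comment = "#",
                         show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(meta_cols, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort matrix is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- unlist(lapply(sample_columns(tbl), function(s) {
    v <- tbl[[s]]
    which(!is.na(v) & (v < 0 | v > 1))
  }))
  if (length(bad) > 0) abort("cohort matrix VAF values must lie in [0, 1]")
  tbl
}

#' Read linkage groups
#'
#' Linkage groups partition a subset of candidate rsIDs into groups of SNPs
#' in linkage disequilibrium (precomputed, e.g. from pairwise r2); rsIDs not
#' listed are implicitly singletons. TSV with columns `group_id, rsid`.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `group_id`, `rsid`.
#' @export
read_linkage_groups <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (!all(c("group_id", "rsid") %in% names(tbl))) {
    abort("linkage groups file must have columns group_id, rsid")
  }
  if (anyDuplicated(tbl$rsid)) {
    abort("an rsid may belong to at most one linkage group")
  }
  tbl
}

#' Filter candidate SNPs by population allele frequency
#'
#' Keeps candidates whose population alternative-allele frequency lies in
#' `[af_min, af_max]` (bounds inclusive) in *at least one* of the available
#' annotations (`af_genome` / `af_exome`, or a single `pop_af` column).
#' Rare or near-fixed SNPs carry little identity information and are
#' removed. Candidates with no AF annotation at all cannot be assessed and
#' are dropped with a warning.
#'
#' @param candidates A data frame of candidate loci (e.g. a cohort variant
#'   matrix) with AF annotation column(s).
#' @param af_min,af_max Inclusive AF window; defaults 0.1 and 0.9.
#' @return The filtered tibble, input order preserved.
#' @export
filter_by_population_af <- function(candidates, af_min = 0.1, af_max = 0.9) {
  stopifnot(af_min >= 0, af_max <= 1, af_min < af_max)
  candidates <- as_tibble(candidates)
  af_cols <- intersect(c("af_genome", "af_exome", "pop_af"), names(candidates))
  if (length(af_cols) == 0) {
    abort("candidates carry no AF annotation (af_genome/af_exome/pop_af)")
  }
  af <- as.matrix(candidates[, af_cols, drop = FALSE])
  unassessable <- rowSums(!is.na(af)) == 0
  if (any(unassessable)) {
    warn(paste0(sum(unassessable),
                " candidate(s) have no population AF and were excluded"))
  }
  in_window <- !is.na(af) & af >= af_min & af <= af_max
  candidates[rowSums(in_window) > 0, ]
}

#' Flag sequencing artefacts in a cohort variant matrix
#'
#' Recurrent artefacts masquerade as variants with a similar VAF in
#' (almost) all samples, unlike a real SNP whose VAF segregates as roughly
#' 0 / 0.5 / 1 across carriers. A variant is flagged when it is present
#' (VAF recorded) in at least `carrier_frac_min` of samples *and* the
#' standard deviation of its recorded VAFs is at most `vaf_sd_max`.
#'
#' @param matrix_tbl Cohort variant matrix (see [read_cohort_matrix()]).
#' @param vaf_sd_max Maximum VAF standard deviation; default 0.05.
#' @param carrier_frac_min Minimum fraction of samples with the variant
#'   recorded; default 0.9.
#' @return Character vector of flagged rsIDs (possibly empty).
#' @export
flag_artefacts <- function(matrix_tbl, vaf_sd_max = 0.05,
                           carrier_frac_min = 0.9) {
  samples <- sample_columns(matrix_tbl)
  if (nrow(matrix_tbl) == 0) return(character())
  if (length(samples) < 2) abort("artefact flagging needs >= 2 samples")
  vaf <- as.matrix(matrix_tbl[, samples, drop = FALSE])
  present_frac <- rowMeans(!is.na(vaf))
  vaf_sd <- apply(vaf, 1, function(v) sd(v, na.rm = TRUE))
  flagged <- present_frac >= carrier_frac_min &
    !is.na(vaf_sd) & vaf_sd <= vaf_sd_max
  matrix_tbl$rsid[flagged]
}

#' Remove low-prevalence variants
#'
#' A SNP carried by only a handful of cohort samples contributes little
#' identity information. A sample counts as a carrier when the variant is
#' recorded there with VAF at least `het_low` (the heterozygous lower
#' bound).
#'
#' @param matrix_tbl Cohort variant matrix.
#' @param min_carrier_frac Minimum carrier fraction; default 0.05.
#' @param het_low VAF lower bound for carrying one alternative allele;
#'   default 0.1.
#' @return The filtered matrix tibble.
#' @export
filter_low_prevalence <- function(matrix_tbl, min_carrier_frac = 0.05,
                                  het_low = 0.1) {
  if (nrow(matrix_tbl) == 0) return(as_tibble(matrix_tbl))
  samples <- sample_columns(matrix_tbl)
  vaf <- as.matrix(matrix_tbl[, samples, drop = FALSE])
  carrier_frac <- rowMeans(!is.na(vaf) & vaf >= het_low)
  as_tibble(matrix_tbl)[carrier_frac >= min_carrier_frac, ]
}

#' Prune linkage groups to one SNP each
#'
#' SNPs in linkage disequilibrium carry redundant information, so from each
#' linkage group only the SNP whose mean cohort VAF is closest to 0.5 (the
#' most informative one) is retained; ties break to the lowest genomic
#' coordinate so the result is deterministic. Candidates not assigned to
#' any group are all retained.
#'
#' @param candidates Candidate loci: a data frame with at least `rsid`,
#'   `chrom`, `pos`, `ref`, `alt` (a cohort-matrix tibble works).
#' @param groups Linkage groups tibble (`group_id`, `rsid`); every grouped
#'   rsid must appear among the candidates.
#' @param cohort_vaf Mean cohort VAF per rsid: a named numeric vector or a
#'   data frame with columns `rsid`, `vaf`. If `NULL`, computed as the row
#'   mean of recorded VAFs over the candidates' sample columns.
#' @param name Name for the resulting panel.
#' @return A [snp_panel()].
#' @export
prune_linkage_groups <- function(candidates, groups, cohort_vaf = NULL,
                                 name = "panel") {
  candidates <- as_tibble(candidates)
  if (is.null(cohort_vaf)) {
    samples <- sample_columns(candidates)
    if (length(samples) == 0) {
      abort("cohort_vaf not given and candidates carry no sample columns")
    }
    vaf_mat <- as.matrix(candidates[, samples, drop = FALSE])
    cohort_vaf <- setNames(rowMeans(vaf_mat, na.rm = TRUE), candidates$rsid)
  } else if (is.data.frame(cohort_vaf)) {
    cohort_vaf <- setNames(cohort_vaf$vaf, cohort_vaf$rsid)
  }
  missing_rsids <- setdiff(groups$rsid, candidates$rsid)
  if (length(missing_rsids) > 0) {
    abort(paste0("grouped rsid(s) absent from candidates: ",
                 paste(missing_rsids, collapse = ", ")))
  }
  tbl <- candidates %>%
    mutate(
      .group = groups$group_id[match(.data$rsid, groups$rsid)],
      .vaf = unname(cohort_vaf[match(.data$rsid, names(cohort_vaf))]),
      .crank = chrom_rank(.data$chrom)
    )
  grouped <- tbl %>%
    filter(!is.na(.data$.group)) %>%
    group_by(.data$.group) %>%
    arrange(abs(.data$.vaf - 0.5), .data$.crank, .data$chrom, .data$pos,
            .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()
  kept <- bind_rows(filter(tbl, is.na(.data$.group)), grouped) %>%
    select(-".group", -".vaf", -".crank")
  pop_af <- if ("af_genome" %in% names(kept) || "af_exome" %in% names(kept)) {
    coalesce(
      if ("af_genome" %in% names(kept)) kept$af_genome else NA_real_,
      if ("af_exome" %in% names(kept)) kept$af_exome else NA_real_
    )
  } else if ("pop_af" %in% names(kept)) {
    kept$pop_af
  } else {
    NA_real_
  }
  snp_panel(tibble(rsid = kept$rsid, chrom = kept$chrom, pos = kept$pos,
                   ref = kept$ref, alt = kept$alt, pop_af = pop_af),
            name = name)
}

#' Run the full panel-selection pipeline
#'
#' Chains the four selection stages on a cohort variant matrix: population
#' AF window, artefact removal, low-prevalence removal, and linkage-group
#' pruning. Stage-by-stage candidate counts are logged with [message()] and
#' attached as the `"selection_log"` attribute.
#'
#' @inheritParams filter_by_population_af
#' @inheritParams flag_artefacts
#' @inheritParams filter_low_prevalence
#' @param matrix_tbl Cohort variant matrix (see [read_cohort_matrix()]).
#' @param groups Linkage groups tibble (`group_id`, `rsid`).
#' @param name Name of the resulting panel.
#' @param verbose Log stage counts with [message()]; default `TRUE`.
#' @return A [snp_panel()] with a `"selection_log"` attribute (tibble with
#'   columns `stage`, `n_in`, `n_out`).
#' @export
select_panel <- function(matrix_tbl, groups, af_min = 0.1, af_max = 0.9,
                         vaf_sd_max = 0.05, carrier_frac_min = 0.9,
                         min_carrier_frac = 0.05, het_low = 0.1,
                         name = "panel", verbose = TRUE) {
  log <- list()
  note <- function(stage, n_in, n_out) {
    if (verbose) {
      message(sprintf("%-24s %4d -> %4d candidates", stage, n_in, n_out))
    }
    log[[length(log) + 1]] <<- tibble(stage = stage, n_in = n_in, n_out = n_out)
  }

  n0 <- nrow(matrix_tbl)
  step1 <- filter_by_population_af(matrix_tbl, af_min, af_max)
  note("population AF window", n0, nrow(step1))

  artefacts <- flag_artefacts(step1, vaf_sd_max, carrier_frac_min)
  step2 <- filter(step1, !.data$rsid %in% artefacts)
  note("artefact removal", nrow(step1), nrow(step2))

  step3 <- filter_low_prevalence(step2, min_carrier_frac, het_low)
  note("low-prevalence removal", nrow(step2), nrow(step3))

  groups_present <- filter(groups, .data$rsid %in% step3$rsid)
  panel <- prune_linkage_groups(step3, groups_present, name = name)
  note("linkage-group pruning", nrow(step3), nrow(panel))

  attr(panel, "selection_log") <- bind_rows(log)
  panel
}
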
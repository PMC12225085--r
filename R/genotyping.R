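#' Quality and genotype-calling configuration
#'
#' Read-filtering and genotype-discretisation settings used when counting
#' alleles at panel loci. Reads below `min_mapq`, bases below `min_baseq`,
#' duplicate-flagged reads and secondary/supplementary alignments are
#' ignored. A locus with fewer than `min_depth` ref+alt reads is NO_CALL;
#' otherwise the variant-allele fraction (VAF = alt / (ref + alt))
#' discretises to HOM_REF (< `het_low`), HET (`[het_low, het_high]`) or
#' HOM_ALT (> `het_high`).
#'
#' @param min_depth Minimum ref+alt depth for a call; default 30.
#' @param min_mapq Minimum mapping quality; default 10.
#' @param min_baseq Minimum base quality; default 20.
#' @param het_low,het_high VAF window called heterozygous; defaults 0.1 and
#'   0.9, mirroring the panel's population-AF window.
#' @return A list of class `quality_config`.
#' @export
quality_config <- function(min_depth = 30L, min_mapq = 10L, min_baseq = 20L,
                           het_low = 0.1, het_high = 0.9) {
  stopifnot(min_depth >= 1, het_low > 0, het_high < 1, het_low < het_high)
  structure(list(min_depth = as.integer(min_depth),
                 min_mapq = as.integer(min_mapq),
                 min_baseq = as.integer(min_baseq),
                 het_low = het_low, het_high = het_high),
            class = "quality_config")
}

#' Call a discrete genotype from allele counts
#'
#' Vectorised over loci. Depth is `ref_count + alt_count` (other bases are
#' excluded from the VAF denominator so it stays interpretable as a
#' biallelic allele fraction).
#'
#' @param ref_count,alt_count Non-negative integer read counts.
#' @param quality A [quality_config()].
#' @return Character vector with values `HOM_REF`, `HET`, `HOM_ALT` or
#'   `NO_CALL`.
#' @export
#' @examples
#' call_genotype(c(100, 50, 3, 1), c(0, 50, 2, 99))
call_genotype <- function(ref_count, alt_count, quality = quality_config()) {
  stopifnot(length(ref_count) == length(alt_count),
            all(ref_count >= 0), all(alt_count >= 0))
  depth <- ref_count + alt_count
  vaf <- ifelse(depth > 0, alt_count / depth, NA_real_)
  out <- rep("NO_CALL", length(depth))
  ok <- depth >= quality$min_depth
  out[ok & vaf < quality$het_low] <- "HOM_REF"
  out[ok & vaf >= quality$het_low & vaf <= quality$het_high] <- "HET"
  out[ok & vaf > quality$het_high] <- "HOM_ALT"
  out
}

#' Extract allele counts at panel loci from a BAM file
#'
#' Pileup-counts reads supporting the reference and alternative allele of
#' every panel locus in one coordinate-sorted, indexed BAM file, and calls
#' genotypes. Reads failing the quality filters, duplicates and
#' secondary/supplementary alignments are excluded; overlapping mates are
#' counted per read. Panel loci on chromosomes absent from the BAM header
#' are reported with depth 0 / NO_CALL (with a warning); if *no* panel
#' chromosome is present the chromosome naming is considered incompatible
#' and an error is raised.
#'
#' @param bam_path Path to a coordinate-sorted BAM with a `.bai` index.
#' @param panel A [snp_panel()].
#' @param quality A [quality_config()].
#' @param sample_id Sample name; defaults to the BAM file name without
#'   extension.
#' @return A sample profile: a tibble with one row per panel locus and
#'   columns `sample_id, rsid, chrom, pos, ref, alt, ref_count, alt_count,
#'   other_count, depth, vaf, genotype`. `depth = ref_count + alt_count`;
#'   `vaf` is `NA` at depth 0.
#' @export
extract_readcounts <- function(bam_path, panel, quality = quality_config(),
                               sample_id = NULL) {
  if (!file.exists(bam_path)) abort(paste0("BAM not found: ", bam_path))
  bai <- c(paste0(bam_path, ".bai"), sub("\\.bam$", ".bai", bam_path))
  if (!any(file.exists(bai))) {
    abort(paste0("BAM index (.bai) not found for: ", bam_path))
  }
  sample_id <- sample_id %||% sub("\\.bam$", "", basename(bam_path))
  panel <- snp_panel(panel, name = attr(panel, "name") %||% "panel")

  header_chroms <- names(Rsamtools::scanBamHeader(bam_path)[[1]]$targets)
  present <- panel$chrom %in% header_chroms
  if (!any(present)) {
    abort(paste0("chromosome naming mismatch: none of the panel chromosomes (",
                 paste(unique(panel$chrom), collapse = ", "),
                 ") occur in the BAM header"))
  }
  if (!all(present)) {
    warn(paste0("panel chromosome(s) absent from BAM, reported as depth 0: ",
                paste(unique(panel$chrom[!present]), collapse = ", ")))
  }

  which_gr <- GenomicRanges::GRanges(
    panel$chrom[present],
    IRanges::IRanges(panel$pos[present], panel$pos[present])
  )
  sbp <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE,
                                  isSupplementaryAlignment = FALSE),
    which = which_gr
  )
  pp <- Rsamtools::PileupParam(
    max_depth = 1000000L,
    min_base_quality = quality$min_baseq,
    min_mapq = quality$min_mapq,
    min_nucleotide_depth = 1L,
    distinguish_strands = FALSE,
    distinguish_nucleotides = TRUE,
    ignore_query_Ns = TRUE,
    include_deletions = FALSE,
    include_insertions = FALSE
  )
  pile <- Rsamtools::pileup(bam_path, scanBamParam = sbp, pileupParam = pp)

  counts <- as_tibble(pile) %>%
    mutate(chrom = as.character(.data$seqnames),
           base = as.character(.data$nucleotide)) %>%
    group_by(.data$chrom, .data$pos, .data$base) %>%
    summarise(count = sum(.data$count), .groups = "drop")

  prof <- panel %>%
    as_tibble() %>%
    select("rsid", "chrom", "pos", "ref", "alt") %>%
    left_join(counts, by = c("chrom", "pos"),
              relationship = "one-to-many") %>%
    mutate(count = coalesce(.data$count, 0L)) %>%
    group_by(.data$rsid, .data$chrom, .data$pos, .data$ref, .data$alt) %>%
    summarise(
      ref_count = sum(.data$count[!is.na(.data$base) & .data$base == .data$ref]),
      alt_count = sum(.data$count[!is.na(.data$base) & .data$base == .data$alt]),
      other_count = sum(.data$count[!is.na(.data$base) &
                                      .data$base != .data$ref &
                                      .data$base != .data$alt]),
      .groups = "drop"
    )
  prof <- prof[genomic_order(prof$chrom, prof$pos), ]
  finish_profile(prof, sample_id, quality)
}

# Common tail for measured and simulated profiles: depth, VAF, genotype.
finish_profile <- function(prof, sample_id, quality) {
  prof %>%
    mutate(
      sample_id = sample_id,
      depth = .data$ref_count + .data$alt_count,
      vaf = ifelse(.data$depth > 0, .data$alt_count / .data$depth, NA_real_),
      genotype = call_genotype(.data$ref_count, .data$alt_count, quality)
    ) %>%
    select("sample_id", "rsid", "chrom", "pos", "ref", "alt",
           "ref_count", "alt_count", "other_count", "depth", "vaf",
           "genotype")
}

#' Extract profiles for a batch of BAM files
#'
#' @param bam_paths Character vector of BAM paths, or a sample sheet: a
#'   data frame with columns `sample_id`, `path`.
#' @inheritParams extract_readcounts
#' @return One long tibble of profiles (rows = samples x loci).
#' @export
extract_cohort_readcounts <- function(bam_paths, panel,
                                      quality = quality_config()) {
  if (is.data.frame(bam_paths)) {
    sheet <- as_tibble(bam_paths)
    stopifnot(all(c("sample_id", "path") %in% names(sheet)))
  } else {
    sheet <- tibble(sample_id = sub("\\.bam$", "", basename(bam_paths)),
                    path = bam_paths)
  }
  if (anyDuplicated(sheet$sample_id)) abort("duplicate sample ids in batch")
  purrr::map2(sheet$path, sheet$sample_id,
              function(p, s) extract_readcounts(p, panel, quality, s)) %>%
    bind_rows()
}

#' Write the per-sample, per-locus read-count table
#'
#' Writes `SNP_readcounts_[suffix]_[timestamp].csv` into `outdir`: one row
#' per (sample, locus) with allele counts, the VAF (3 decimals, empty when
#' undefined) and the genotype call.
#'
#' @param profiles Long profile tibble (see [extract_readcounts()]).
#' @param suffix Run label inserted into the file name.
#' @param timestamp Timestamp string (`YYYYMMDD-HHMMSS`); defaults to the
#'   current time. Injectable so outputs can be byte-reproducible.
#' @param outdir Output directory; default `"."`.
#' @return The file path, invisibly.
#' @export
write_readcounts_table <- function(profiles, suffix,
                                   timestamp = NULL, outdir = ".") {
  timestamp <- timestamp %||% default_timestamp()
  path <- file.path(outdir,
                    sprintf("SNP_readcounts_%s_%s.csv", suffix, timestamp))
  if (nrow(profiles) == 0) {
    warn("no profiles to write; emitting header-only read-count table")
  }
  out <- as_tibble(profiles) %>%
    transmute(.data$sample_id, .data$rsid, .data$chrom, .data$pos,
              .data$ref, .data$alt, .data$ref_count, .data$alt_count,
              other_count = if ("other_count" %in% names(profiles))
                .data$other_count else 0L,
              vaf = fmt3(.data$vaf), genotype = .data$genotype)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a previously written read-count table back into profiles
#'
#' Inverse of [write_readcounts_table()] (up to the 3-decimal VAF rounding
#' in the file; VAF and genotype are recomputed from the stored counts at
#' full precision).
#'
#' @param path CSV path.
#' @param quality A [quality_config()] used to re-call genotypes.
#' @return Long profile tibble.
#' @export
read_readcounts_table <- function(path, quality = quality_config()) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("sample_id", "rsid", "chrom", "pos", "ref", "alt",
              "ref_count", "alt_count")
  missing_cols <- setdiff(needed, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("read-count table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"other_count" %in% names(tbl)) tbl$other_count <- 0L
  tbl %>%
    group_by(.data$sample_id) %>%
    group_modify(function(d, key) {
      finish_profile(d, key$sample_id[[1]], quality) %>% select(-"sample_id")
    }) %>%
    ungroup() %>%
    select("sample_id", everything())
}
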
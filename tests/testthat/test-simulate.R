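test_that("genotype draws follow Hardy-Weinberg frequencies within 3 sigma", {
  for (p in c(0.1, 0.3, 0.5)) {
    panel <- snp_panel(tibble::tibble(rsid = "rs1", chrom = "chr1",
                                      pos = 1000L, ref = "A", alt = "G",
                                      pop_af = p))
    g <- simulate_genotypes(panel, 10000, seed = 404)
    expected <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    for (code in 0:2) {
      freq <- mean(g == code)
      sigma <- sqrt(expected[code + 1] * (1 - expected[code + 1]) / 10000)
      expect_lt(abs(freq - expected[code + 1]), 3 * sigma,
                label = sprintf("p=%.1f genotype %d", p, code))
    }
  }
})

test_that("degenerate allele frequencies and seeds behave as documented", {
  panel <- tiny_panel(5)
  panel$pop_af <- 0
  g <- simulate_genotypes(panel, 50, seed = 1)
  expect_true(all(g == 0L))

  panel$pop_af <- c(0.5, 0.5, 0.5, NA, 0.5)
  expect_error(simulate_genotypes(panel, 10, seed = 1), "pop_af missing")

  panel$pop_af <- 0.5
  expect_identical(simulate_genotypes(panel, 100, seed = 7),
                   simulate_genotypes(panel, 100, seed = 7))
  expect_false(identical(simulate_genotypes(panel, 100, seed = 7),
                         simulate_genotypes(panel, 100, seed = 8)))
})

test_that("read counts realise the expected allele fractions", {
  panel <- tiny_panel(28)
  panel$pop_af <- 0.5
  smap <- tibble::tibble(sample_id = "s1", patient = 1L)

  # error-free homozygous-reference counts give VAF exactly 0
  g0 <- matrix(0L, 1, 28, dimnames = list(NULL, panel$rsid))
  prof0 <- simulate_readcounts(g0, panel, smap, base_error_rate = 0,
                               mean_depth = 100, seed = 2)
  expect_true(all(prof0$vaf[prof0$depth > 0] == 0))
  expect_true(all(prof0$other_count == 0L))

  # heterozygous loci at depth 1000: mean VAF close to 0.5
  g1 <- matrix(1L, 1, 28, dimnames = list(NULL, panel$rsid))
  prof1 <- simulate_readcounts(g1, panel, smap, mean_depth = 1000, seed = 3)
  expect_lt(abs(mean(prof1$vaf) - 0.5), 0.05)
  expect_true(all(prof1$genotype == "HET"))
})

test_that("timepoints share genotypes but not noise, and match each other", {
  coh <- simulate_cohort(bundled_panel(), 10, seed = 55)
  expect_equal(nrow(coh$profiles), 20 * 28)
  for (pat in c(1, 7)) {
    ids <- coh$samples$sample_id[coh$samples$true_patient == pat]
    x <- coh$profiles[coh$profiles$sample_id == ids[1], ]
    y <- coh$profiles[coh$profiles$sample_id == ids[2], ]
    expect_false(identical(x$alt_count, y$alt_count))
    cmp <- compare_pair(x, y)
    expect_gte(cmp$fraction_concordant, 0.9)
    expect_equal(cmp$status, "MATCH")
  }
})

test_that("planting no errors is the identity", {
  coh <- simulate_cohort(bundled_panel(), 4, seed = 12)
  expect_identical(plant_errors(coh, list()), coh)
})

test_that("a swap implies exactly its two unexpected and two broken pairs", {
  coh <- simulate_cohort(bundled_panel(), 6, seed = 30)
  a_tp2 <- coh$samples$sample_id[coh$samples$true_patient == 1 &
                                   coh$samples$timepoint == 2]
  b_tp2 <- coh$samples$sample_id[coh$samples$true_patient == 2 &
                                   coh$samples$timepoint == 2]
  planted <- plant_errors(coh, list(swap_error(a_tp2, b_tp2)))

  expect_equal(nrow(planted$truth$unexpected_pairs), 2)
  expect_equal(nrow(planted$truth$broken_expected), 2)
  a_tp1 <- coh$samples$sample_id[coh$samples$true_patient == 1 &
                                   coh$samples$timepoint == 1]
  keys <- pmin(planted$truth$unexpected_pairs$x_id,
               planted$truth$unexpected_pairs$y_id)
  expect_true(any(grepl(sub("^CLL-([0-9]+)-.*", "\\1", a_tp1), keys)))

  # label-level errors never touch the genotype matrix
  expect_identical(planted$genotypes, coh$genotypes)
  # ... and the underlying read counts travel with the swapped labels
  moved <- planted$profiles[planted$profiles$sample_id == a_tp2, ]
  orig <- coh$profiles[coh$profiles$sample_id == b_tp2, ]
  expect_equal(moved$alt_count, orig$alt_count)
})

test_that("contradictory and dangling error specs are rejected", {
  coh <- simulate_cohort(bundled_panel(), 4, seed = 3)
  ids <- coh$samples$sample_id
  expect_error(
    plant_errors(coh, list(swap_error(ids[1], ids[2]),
                           swap_error(ids[1], ids[3]))),
    "contradictory"
  )
  expect_error(plant_errors(coh, list(swap_error(ids[1], "phantom"))),
               "unknown sample")
  expect_error(contamination_error(ids[1], ids[2], fraction = 0.7))
})

test_that("a mislabel onto an existing patient breaks and creates the right pairs", {
  coh <- simulate_cohort(bundled_panel(), 6, seed = 31)
  victim <- coh$samples$sample_id[coh$samples$true_patient == 3 &
                                    coh$samples$timepoint == 2]
  target_label <- coh$samples$label_patient[coh$samples$true_patient == 4][1]
  planted <- plant_errors(coh, list(mislabel_error(victim, target_label)))
  # new name carries the target patient id, same run id
  renamed <- setdiff(planted$samples$sample_id, coh$samples$sample_id)
  expect_match(renamed, target_label, fixed = TRUE)
  # one unexpected pair (true partner), two broken pairs (with both samples
  # of the target patient)
  expect_equal(nrow(planted$truth$unexpected_pairs), 1)
  expect_equal(nrow(planted$truth$broken_expected), 2)
  expect_true(all(planted$truth$broken_expected$patient_id == target_label))
})

test_that("a CNA-type VAF shift only perturbs heterozygous loci on its chromosome", {
  panel <- bundled_panel()
  coh <- simulate_cohort(panel, 4, mean_depth = 400, seed = 71)
  sid <- coh$samples$sample_id[1]
  g <- coh$genotypes[1, panel$rsid]
  chrom <- panel$chrom[match(names(which(g == 1L)[1]), panel$rsid)]
  shifted <- plant_errors(coh, list(cna_shift_error(sid, chrom, +0.3)))

  before <- coh$profiles[coh$profiles$sample_id == sid, ]
  after <- shifted$profiles[shifted$profiles$sample_id == sid, ]
  het_on <- panel$rsid[panel$chrom == chrom & g[panel$rsid] == 1L]
  untouched <- setdiff(panel$rsid, het_on)
  expect_equal(after$alt_count[match(untouched, after$rsid)],
               before$alt_count[match(untouched, before$rsid)])
  expect_gt(mean(after$vaf[match(het_on, after$rsid)]), 0.65)
  # genotypes and labels unchanged
  expect_identical(shifted$genotypes, coh$genotypes)
  expect_equal(nrow(shifted$truth$unexpected_pairs), 0)
})

test_that("fixture BAMs reproduce simulated counts through extraction", {
  coh <- simulate_cohort(bundled_panel(), 2, mean_depth = 40, seed = 17)
  dir <- withr::local_tempdir()
  bams <- write_fixture_bams(coh, dir, n_decoy_duplicates = 2L)
  expect_equal(nrow(bams), 4)
  expect_true(all(file.exists(bams$bam)))
  expect_true(all(file.exists(bams$bai)))
  expect_true(file.exists(attr(bams, "reference")))

  prof <- extract_cohort_readcounts(
    tibble::tibble(sample_id = bams$sample_id, path = bams$bam),
    bundled_panel()
  )
  key <- function(d) d[order(d$sample_id, d$rsid),
                       c("sample_id", "rsid", "ref_count", "alt_count")]
  expect_equal(as.data.frame(key(prof)),
               as.data.frame(key(coh$profiles)))

  close_panel <- snp_panel(tibble::tibble(
    rsid = c("rs1", "rs2"), chrom = "chr1", pos = c(1000L, 1050L),
    ref = "A", alt = "G", pop_af = 0.5
  ))
  tight <- simulate_cohort(close_panel, 2, seed = 1)
  expect_error(write_fixture_bams(tight, dir), "spacing")
})
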
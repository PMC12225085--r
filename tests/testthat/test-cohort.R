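small_cohort_profiles <- function(n_patients = 6, seed = 21) {
  coh <- simulate_cohort(bundled_panel(), n_patients, seed = seed)
  coh
}

test_that("a scan compares every unordered pair exactly once", {
  panel <- tiny_panel(28)
  withr::with_seed(31, {
    profiles <- dplyr::bind_rows(lapply(sprintf("s%d", 1:4), random_profile,
                                        panel = panel))
  })
  scan <- suppressWarnings(scan_cohort(profiles, id_pattern = NULL))
  expect_equal(nrow(scan$comparisons), choose(4, 2))
  keys <- paste(scan$comparisons$x_id, scan$comparisons$y_id)
  expect_false(anyDuplicated(keys) > 0)
  expect_true(all(scan$comparisons$x_id != scan$comparisons$y_id))

  dup <- dplyr::mutate(profiles, sample_id = "same")
  expect_error(scan_cohort(dup), "unique|duplicate")
})

test_that("the vectorised scan agrees with compare_pair on every field", {
  panel <- tiny_panel(20)
  withr::with_seed(77, {
    profiles <- dplyr::bind_rows(lapply(sprintf("s%02d", 1:8), random_profile,
                                        panel = panel, p_nocall = 0.2))
  })
  scan <- suppressWarnings(scan_cohort(profiles, id_pattern = NULL))
  for (r in seq_len(nrow(scan$comparisons))) {
    row <- scan$comparisons[r, ]
    ref <- suppressWarnings(compare_pair(
      profiles[profiles$sample_id == row$x_id, ],
      profiles[profiles$sample_id == row$y_id, ]
    ))
    expect_equal(row$n_evaluable, ref$n_evaluable)
    expect_equal(row$n_concordant, ref$n_concordant)
    expect_equal(row$fraction_concordant, ref$fraction_concordant)
    expect_equal(row$correlation, ref$correlation, tolerance = 1e-12)
    expect_equal(row$status, ref$status)
  }
})

test_that("expected pairs derive from the first digit run of the name", {
  ids <- c("CLL-68035557-02S65286-TP1", "CLL-68035557-67S38544-TP2",
           "CLL-07925505-04S0753-TP1")
  ep <- derive_expected_pairs(ids)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$patient_id, "68035557")

  expect_equal(nrow(derive_expected_pairs(c("P1-a", "P1-b", "P1-c"))),
               choose(3, 2))
  expect_equal(nrow(derive_expected_pairs(c("P1-a", "P2-a", "P3-a"))), 0)
  expect_warning(derive_expected_pairs(c("P1-a", "P1-b", "nodigits")),
                 "without a patient identifier")
  expect_error(derive_expected_pairs(ids, id_pattern = "[0-9]+"),
               "capturing group")
})

test_that("expected-pair verdicts map statuses to concordant/review/discordant", {
  coh <- small_cohort_profiles()
  scan <- scan_cohort(coh$profiles)
  expect_equal(nrow(scan$expected), coh$config$n_patients)
  expect_true(all(scan$expected$verdict == "CONCORDANT"))

  # hand-held verdicts through a constructed scan
  panel <- tiny_panel(28)
  x1 <- profile_from_codes("P10-TP1", panel, rep(c(0L, 1L, 2L), length.out = 28))
  x2 <- profile_from_codes("P10-TP2", panel, rep(c(0L, 1L, 2L), length.out = 28))
  x3 <- profile_from_codes("P11-TP1", panel, rep(c(2L, 0L, 1L), length.out = 28))
  scan2 <- scan_cohort(dplyr::bind_rows(x1, x2, x3))
  expect_equal(scan2$expected$verdict, "CONCORDANT")
  exp_cross <- tibble::tibble(x_id = "P10-TP1", y_id = "P11-TP1")
  chk <- check_expected_pairs(exp_cross, scan2)
  expect_equal(chk$verdict, "DISCORDANT")
  expect_error(
    check_expected_pairs(tibble::tibble(x_id = "P10-TP1", y_id = "ghost"),
                         scan2),
    "unscanned"
  )
})

test_that("report files follow the naming scheme and ordering contract", {
  coh <- planted_cohort(seed = 42, n_patients = 10, with_mislabel = FALSE)
  dir <- withr::local_tempdir()
  scan <- swap_check(coh$profiles, suffix = "batch7",
                     timestamp = "20250101-120000", outdir = dir,
                     heatmap = TRUE)
  files <- attr(scan, "files")
  expect_equal(basename(files[["pairwise"]]),
               "Pairwise_concordance_batch7_20250101-120000.csv")
  expect_equal(basename(files[["readcounts"]]),
               "SNP_readcounts_batch7_20250101-120000.csv")
  expect_equal(basename(files[["expected"]]),
               "Expected_concordant_pairs_batch7_20250101-120000.csv")
  expect_equal(basename(files[["heatmap"]]),
               "Pairwise_concordance_batch7_20250101-120000.png")
  expect_true(all(file.exists(files)))

  pw <- readr::read_csv(files[["pairwise"]], show_col_types = FALSE)
  expect_equal(nrow(pw), choose(20, 2))
  flagged <- pw$status %in% c("MATCH", "BORDERLINE_MATCH")
  expect_true(all(diff(flagged) <= 0))  # flagged block first
  expect_gt(sum(flagged), 0)
  within <- pw$correlation[!flagged]
  expect_true(all(diff(within) <= 1e-9))  # then descending correlation

  # discordant positions listed as chrom:pos:rsid for mismatching pairs
  disc_rows <- pw[pw$status == "NO_MATCH" & pw$n_evaluable > 0, ]
  expect_match(disc_rows$discordant_positions[1], "^chr[0-9]+:[0-9]+:rs")

  ep <- readr::read_csv(files[["expected"]], show_col_types = FALSE)
  expect_true(all(diff(ep$correlation) <= 1e-9))  # descending
  expect_setequal(unique(ep$verdict), c("CONCORDANT", "DISCORDANT"))
  disc_exp <- ep[ep$verdict == "DISCORDANT", c("x_sample", "y_sample")]
  expect_setequal(paste(disc_exp$x_sample, disc_exp$y_sample),
                  paste(coh$truth$broken_expected$x_id,
                        coh$truth$broken_expected$y_id))

  # deterministic re-run: byte-identical files at a fixed timestamp
  dir2 <- withr::local_tempdir()
  scan2 <- swap_check(coh$profiles, suffix = "batch7",
                      timestamp = "20250101-120000", outdir = dir2,
                      heatmap = FALSE)
  f2 <- attr(scan2, "files")
  expect_identical(readLines(files[["pairwise"]]),
                   readLines(f2[["pairwise"]]))
  expect_identical(readLines(files[["expected"]]),
                   readLines(f2[["expected"]]))
})

test_that("the correlation matrix is symmetric with unit diagonal", {
  coh <- small_cohort_profiles()
  scan <- scan_cohort(coh$profiles)
  mat <- correlation_matrix(scan)
  n <- length(scan$sample_ids)
  expect_equal(dim(mat), c(n, n))
  expect_equal(mat, t(mat))
  expect_equal(unname(diag(mat)), rep(1, n))
  expect_true(all(mat >= -1 & mat <= 1, na.rm = TRUE))
  p <- autoplot(scan)
  expect_s3_class(p, "ggplot")
})

test_that("scan results are internally consistent and summarised by glance", {
  coh <- planted_cohort(seed = 8, n_patients = 12, with_mislabel = FALSE)
  scan <- scan_cohort(coh$profiles)
  # every MATCH with differing patient ids is listed as unexpected
  pid <- function(s) sub("^CLL-([0-9]+)-.*$", "\\1", s)
  cross <- scan$matches[pid(scan$matches$x_id) != pid(scan$matches$y_id), ]
  expect_equal(nrow(cross), nrow(scan$unexpected_matches))
  g <- glance(scan)
  expect_equal(g$n_pairs, choose(24, 2))
  expect_equal(g$n_match, nrow(scan$matches)
               - sum(scan$matches$status == "BORDERLINE_MATCH"))
  expect_equal(g$n_unexpected_matches, nrow(coh$truth$unexpected_pairs))
  expect_equal(g$n_expected_discordant, nrow(coh$truth$broken_expected))
})

test_that("subset sensitivity is deterministic and loses nothing at full size", {
  coh <- planted_cohort(seed = 5, n_patients = 30, with_mislabel = FALSE)
  res <- subset_sensitivity(coh$profiles, coh, sizes = c(28L, 16L),
                            iterations = 3L, seed = 9L)
  expect_equal(nrow(res), 6)
  expect_equal(attr(res, "planted_unexpected"), 6L)

  # full panel: identical to the unrestricted scan, all planted pairs found
  full <- res[res$subset_size == 28, ]
  expect_true(all(full$detected_unexpected == 6L))
  expect_true(all(full$detected_discordant == 6L))

  res2 <- subset_sensitivity(coh$profiles, coh, sizes = c(28L, 16L),
                             iterations = 3L, seed = 9L)
  expect_identical(as.data.frame(res), as.data.frame(res2))
  res3 <- subset_sensitivity(coh$profiles, coh, sizes = 16L, iterations = 1,
                             seed = 10L)
  expect_false(identical(res3$seed, res$seed[res$subset_size == 16][1]))

  expect_error(subset_sensitivity(coh$profiles, coh, sizes = 29L),
               "exceeds panel size")
  g <- glance(res)
  expect_equal(g$subset_size, c(28L, 16L))
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("specificity degrades as the panel shrinks", {
  coh <- planted_cohort(seed = 13, n_patients = 40, with_mislabel = FALSE)
  res <- subset_sensitivity(coh$profiles, coh,
                            sizes = c(26L, 24L, 22L, 20L, 18L, 16L),
                            iterations = 10L, seed = 4L)
  means <- glance(res)  # sorted by descending size
  # mean false positives trend upward as SNPs are removed: the smallest
  # panels average more false positives than the largest, and the worst
  # size is the smallest (per-step means can wiggle by sampling noise)
  small <- means$mean_false_positives[means$subset_size <= 20]
  large <- means$mean_false_positives[means$subset_size >= 22]
  expect_gt(mean(small), mean(large))
  expect_equal(means$subset_size[which.max(means$mean_false_positives)], 16L)
  # sensitivity stays complete throughout this size range
  expect_true(all(res$detected_unexpected == attr(res, "planted_unexpected")))
})

test_that("contamination scores flag deviation from the 0/0.5/1 pattern", {
  panel <- tiny_panel(28)
  clean <- profile_from_codes("clean", panel,
                              rep(c(0L, 1L, 2L), length.out = 28))
  expect_equal(contamination_score(clean)$score, 0)
  expect_false(contamination_score(clean)$flagged)

  one <- profile_from_codes("single", panel[1, ], 1L, depth = 100L)
  one$alt_count <- 25L
  one$ref_count <- 75L
  one$vaf <- 0.25
  cs <- contamination_score(one)
  expect_equal(cs$score, 0.25)
  expect_true(cs$flagged)
  expect_equal(cs$deviant_loci[[1]]$rsid, panel$rsid[1])

  empty <- profile_from_codes("void", panel, rep(NA_integer_, 28))
  expect_warning(cs2 <- contamination_score(empty), "no evaluable")
  expect_true(is.na(cs2$score))
})

test_that("simulated contamination raises the score and the flag", {
  coh <- simulate_cohort(bundled_panel(), 4, mean_depth = 500, seed = 99)
  ids <- coh$samples$sample_id
  spiked <- plant_errors(coh, list(
    contamination_error(ids[1], ids[3], fraction = 0.15)
  ))
  cs <- contamination_score(spiked$profiles)
  score_target <- cs$score[cs$sample_id == ids[1]]
  score_others <- cs$score[cs$sample_id != ids[1]]
  expect_gt(score_target, max(score_others) * 3)
  expect_true(cs$flagged[cs$sample_id == ids[1]])
  expect_false(any(cs$flagged[cs$sample_id != ids[1]]))

  # 10% contamination is detectable with an explicitly lowered threshold
  mild <- plant_errors(coh, list(
    contamination_error(ids[2], ids[4], fraction = 0.10)
  ))
  cs10 <- contamination_score(mild$profiles, flag_threshold = 0.03)
  expect_true(cs10$flagged[cs10$sample_id == ids[2]])
})
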
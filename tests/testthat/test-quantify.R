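test_that("aggregate_replicates computes mean, SEM and censoring counts", {
  s <- aggregate_replicates(c(20.0, 20.2, 20.4))
  expect_equal(s$mean_ct, 20.2)
  expect_equal(s$sem, 0.2 / sqrt(3), tolerance = 1e-9)  # 0.11547
  expect_equal(s$n, 3L)
  expect_equal(s$n_censored, 0L)

  one <- aggregate_replicates(25.0)
  expect_equal(one$mean_ct, 25.0)
  expect_equal(one$sem, 0)

  cen <- aggregate_replicates(c(22.0, NA, NA))
  expect_equal(cen$mean_ct, (22 + 40 + 40) / 3)
  expect_equal(cen$n_censored, 2L)

  expect_error(aggregate_replicates(numeric()), "no replicate")
  expect_error(aggregate_replicates(c(10, 45)), "must lie in")
})

test_that("fold_from_delta_ct reproduces the calibration points", {
  expect_equal(signif(fold_from_delta_ct(6.64386), 4), 100)
  expect_equal(fold_from_delta_ct(20), 1048576)
  expect_equal(fold_from_delta_ct(0), 1)
  expect_equal(fold_from_delta_ct(-3), fold_from_delta_ct(3))
  expect_error(fold_from_delta_ct(Inf), "finite")
})

test_that("composition_from_ct implements the percentage formula", {
  eq <- composition_from_ct(25, 25)
  expect_equal(eq$hP, 50)
  expect_equal(eq$mP, 50)
  expect_equal(eq$dominant, "balanced")

  # mouse Ct 6.64386 cycles later: 100-fold human, hP = 100*100/101
  h100 <- composition_from_ct(20, 20 + 6.64386)
  expect_equal(h100$hP, 100 * 100 / 101, tolerance = 1e-4)
  expect_equal(h100$dominant, "human")

  # a 16.747-cycle murine advantage
  m <- composition_from_ct(20 + 16.747, 20)
  f <- 2^16.747
  expect_equal(m$mP, f / (f + 1) * 100, tolerance = 1e-9)
  expect_gt(m$mP, 99.999)
})

test_that("hP + mP is exactly 100 and composition is label-symmetric (property)", {
  set.seed(31)
  for (i in 1:200) {
    h <- runif(1, 5, 39.9)
    m <- runif(1, 5, 39.9)
    est <- composition_from_ct(h, m)
    expect_identical(est$hP + est$mP, 100)
    swapped <- composition_from_ct(m, h)
    # symmetry holds to rounding on the 0-100 percentage scale; small
    # percentages see that absolute error as a larger relative one
    expect_lt(abs(est$hP - swapped$mP), 1e-10)
    expect_identical(est$fold, swapped$fold)
  }
})

test_that("hP is monotone in each Ct argument", {
  hs <- seq(18, 30, by = 0.5)
  ps <- vapply(hs, function(h) composition_from_ct(h, 24)$hP, numeric(1))
  expect_true(all(diff(ps) < 0))
  ms <- seq(18, 30, by = 0.5)
  pm <- vapply(ms, function(m) composition_from_ct(24, m)$hP, numeric(1))
  expect_true(all(diff(pm) > 0))
})

test_that("censored assays are flagged with a detection floor", {
  est <- composition_from_ct(aggregate_replicates(c(NA, NA, NA)),
                             aggregate_replicates(c(25, 25, 25)))
  expect_equal(est$detection_flag, "human_not_detected")
  expect_equal(est$detection_floor, 100 / 2^(40 - 25))
  expect_equal(est$hP + est$mP, 100)

  expect_error(composition_from_ct(aggregate_replicates(NA_real_),
                                   aggregate_replicates(NA_real_)),
               "no template detected")
})

test_that("sensitivity_from_delta_ct maps folds to percent detection", {
  expect_equal(signif(sensitivity_from_delta_ct(6.64386), 4), 1)
  expect_equal(signif(sensitivity_from_delta_ct(9.96578), 4), 0.1)
  expect_equal(signif(sensitivity_from_delta_ct(13.2877), 4), 0.01)
  expect_equal(sensitivity_from_delta_ct(0), 100)
  expect_error(sensitivity_from_delta_ct(-1), "non-negative")
})

test_that("mass/copies conversion evaluates the printed formula and inverts", {
  expect_equal(mass_to_copies(0, 3.2e9), 0)
  # direct evaluation: 1 ng * 6.022e23 / (3.2e9 * 1e9 * 650)
  expect_equal(mass_to_copies(1, 3.2e9), 6.022e23 / (3.2e9 * 1e9 * 650),
               tolerance = 1e-12)
  expect_equal(mass_to_copies(1, 3.2e9), 289.5192, tolerance = 1e-4)
  # the ~5000-copy input scale corresponds to ~17.27 ng of human gDNA
  expect_equal(mass_to_copies(17.27, 3.2e9), 5000, tolerance = 1e-3)
  expect_equal(copies_to_mass(289.5192, 3.2e9), 1.0, tolerance = 1e-4)
  expect_error(mass_to_copies(1, 0), "positive")

  set.seed(41)
  for (i in 1:200) {
    ng <- runif(1, 1e-3, 1e3)
    len <- runif(1, 1e8, 1e10)
    expect_equal(copies_to_mass(mass_to_copies(ng, len), len), ng,
                 tolerance = 1e-9)
  }
})

test_that("relative_quantification implements 2^(-ddCt)", {
  expect_equal(relative_quantification(20, 20, 20, 20), 1)
  expect_equal(relative_quantification(19, 20, 20, 20), 2)
  expect_equal(relative_quantification(24, 20, 25, 19), 4)
  expect_error(relative_quantification(NA, 1, 2, 3), "finite")
})

test_that("doubling_time and tumor_volume evaluate their closed forms", {
  expect_equal(doubling_time(24, 1e5, 2e5), 24)
  expect_equal(doubling_time(72, 1e5, 4e5), 36)
  expect_error(doubling_time(10, 100, 100), "no net growth")
  expect_error(doubling_time(-1, 1, 2), "positive")

  expect_equal(tumor_volume(0, 5), 0)
  expect_equal(tumor_volume(10, 20), 1000)
  expect_equal(tumor_volume(2, 2), 4)
  expect_error(tumor_volume(-1, 5), "non-negative")
})

test_that("Ct tables round-trip with censored markers", {
  wells <- data.frame(sample_id = c("s1", "s1", "s1", "s1"),
                      assay = c("human", "human", "mouse", "mouse"),
                      replicate = c(1L, 2L, 1L, 2L),
                      ct = c(21.5, 21.7, NA, 35.2))
  p <- tempfile(fileext = ".csv")
  write_ct_table(wells, p)
  back <- read_ct_table(p)
  expect_equal(back, wells)

  tsv <- write_tmp(c("sample_id\tassay\treplicate\tct",
                     "s\thuman\t1\tUndetermined",
                     "s\tmouse\t1\t30.1"), ".tsv")
  tb <- read_ct_table(tsv)
  expect_true(is.na(tb$ct[1]))
  expect_equal(tb$ct[2], 30.1)

  bad <- write_tmp(c("sample_id,assay,replicate,ct", "s,human,1,abc"), ".csv")
  expect_error(read_ct_table(bad), "unparseable Ct")
  noct <- write_tmp(c("sample_id,assay,replicate", "s,human,1"), ".csv")
  expect_error(read_ct_table(noct), "missing columns: ct")
})

test_that("quantify_samples emits one deterministic row per sample", {
  wells <- rbind(
    data.frame(sample_id = "b", assay = "human", replicate = 1:3,
               ct = c(22, 22.1, 21.9)),
    data.frame(sample_id = "b", assay = "mouse", replicate = 1:3,
               ct = c(25, 25.1, 24.9)),
    data.frame(sample_id = "a", assay = "human", replicate = 1:3, ct = 24),
    data.frame(sample_id = "a", assay = "mouse", replicate = 1:3, ct = 24))
  rep <- quantify_samples(wells)
  expect_equal(rep$sample_id, c("a", "b"))   # sorted
  expect_equal(rep$human_pct[1], 50)
  expect_equal(rep$human_pct[2] + rep$murine_pct[2], 100)
  expect_equal(rep$delta_ct[2], -3, tolerance = 1e-9)

  expect_error(quantify_samples(transform(wells, assay = "weird")),
               "unknown assay")

  lone <- wells[wells$assay == "human" & wells$sample_id == "a", ]
  expect_warning(rep2 <- quantify_samples(lone), "no mouse-assay wells")
  expect_equal(rep2$detection_flag, "mouse_not_detected")

  out <- tempfile(fileext = ".tsv")
  write_composition_report(rep, out)
  txt <- readLines(out)
  expect_match(txt[1], "^sample_id\tn\thCt_mean")
  expect_match(txt[2], "\t50\\.0000\t50\\.0000\t", all = FALSE)
})
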
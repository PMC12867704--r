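# Plate reduction: standard curve, activities, turnover, fold-changes,
# pH-profile shape, mutant panel.

test_that("4PL standard curve round-trips noise-free calibrators", {
  conc <- c(0.5, 2, 8, 32, 128, 512)
  truth <- list(A = 100, B = 2000, xmid = log10(15), scal = 0.5)
  reading <- truth$A + (truth$B - truth$A) /
    (1 + exp((truth$xmid - log10(conc)) / truth$scal))
  sc <- fit_standard_curve(conc, reading)
  expect_equal(sc$A, truth$A, tolerance = 0.01)
  expect_equal(sc$B, truth$B, tolerance = 0.01)
  expect_equal(sc$xmid, truth$xmid, tolerance = 0.01)

  back <- reading_to_camp(sc, curve_reading(sc, c(5, 50)))
  expect_equal(back$camp_nM, c(5, 50), tolerance = 1e-6)
  # nM -> pmol uses the well volume (100 uL default: 1 nM = 0.1 pmol)
  expect_equal(back$camp_pmol, back$camp_nM * 0.1, tolerance = 1e-9)

  # reading at the lower asymptote: flagged, not inverted
  low <- reading_to_camp(sc, truth$A)
  expect_false(low$in_range)
  expect_true(is.na(low$camp_nM))
})

test_that("noisy calibrators still invert mid-range readings within 10%", {
  set.seed(21)
  conc <- 10^seq(-0.5, 3, length.out = 12)
  clean <- 50 + (1500 - 50) / (1 + exp((log10(30) - log10(conc)) / 0.45))
  reading <- clean * rlnorm(12, -0.05^2 / 2, 0.05)
  sc <- suppressWarnings(fit_standard_curve(conc, reading))
  mid_true_reading <- 50 + (1500 - 50) / 2  # reading at conc 30, truth
  est <- reading_to_camp(sc, mid_true_reading)$camp_nM
  expect_equal(est, 30, tolerance = 0.10)
})

test_that("standard curve input contracts are enforced", {
  expect_error(fit_standard_curve(c(1, 2, 3, 4), c(1, 2, 3, 4)),
               "at least 5")
  expect_error(fit_standard_curve(c(0, 1, 10, 100, 1000), 1:5),
               "positive")
  expect_error(fit_standard_curve(c(1, 2, 4, 8, 16), 1:5),
               "two decades")
  expect_warning(fit_standard_curve(c(1, 10, 100, 1000, 1e4),
                                    c(12, 48, 45, 120, 230)),
                 "not monotone")
})

test_that("activity and turnover are linear in amount, time and enzyme", {
  expect_equal(activity(0, 10), 0)
  expect_equal(activity(1.2, 10), 0.12)
  expect_error(activity(1, 0), "positive")

  expect_equal(turnover(0, 600, 0.01), 0)
  expect_equal(turnover(0.636, 600, 0.01), 0.106)
  expect_equal(turnover(0.21, 600, 0.01), 0.035)
  expect_error(turnover(1, 600, 0), "positive")

  # linearity / inverse-linearity by scaling
  expect_equal(turnover(2 * 0.636, 600, 0.01), 2 * 0.106)
  expect_equal(turnover(0.636, 2 * 600, 0.01), 0.106 / 2)
  expect_equal(turnover(0.636, 600, 2 * 0.01), 0.106 / 2)
  # batch mean equals mean of singles
  camp <- c(0.1, 0.4, 0.7)
  expect_equal(mean(activity(camp, 10)), activity(mean(camp), 10))
})

test_that("fold-change estimators behave on degenerate and planted data", {
  expect_equal(fold_change(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_equal(fold_change(c(1, 1, 1), c(5.4, 5.4, 5.4)), 5.4)
  expect_equal(fold_change(c(2, 4), c(4, 8), "median_of_ratios"), 2)
  expect_error(fold_change(numeric(0), 1), "empty")
  expect_error(fold_change(c(-2, 1), c(1, 1)), "positive")
})

test_that("pH profile flags the biphasic shape", {
  # biphasic: first peak at 7.0, trough at 7.2, surge above 7.8
  prof <- ph_profile(c(6.5, 6.7, 7.0, 7.2, 7.8, 8.0),
                     c(0.035, 0.035, 0.070, 0.035, 0.045, 0.106))
  expect_equal(prof$peaks, 7.0)
  expect_equal(prof$troughs, 7.2)
  expect_gt(prof$max_min_ratio, 3 - 0.1)

  mono <- ph_profile(c(6, 7, 8), c(1, 2, 3))
  expect_length(mono$peaks, 0)
  flat <- ph_profile(c(6, 7, 8), c(1, 1, 1))
  expect_equal(flat$max_min_ratio, 1)
  expect_warning(ph_profile(c(6, 6, 7, 8), c(1, 3, 1, 1)), "averaged")
})

test_that("turnover recovery from the preset plate is within 1 SD", {
  plate <- gen_turnover_plate(seed = 23)
  tab <- turnover_table(plate, by = "ph")
  truth <- attr(plate, "truth")
  tab <- tab[match(truth$ph, tab$ph), ]
  expect_equal(tab$n, truth$n)
  expect_true(all(abs(tab$k_mean - truth$k_mean) <= truth$k_sd))
  # biphasic shape survives the pipeline
  prof <- ph_profile(tab$ph, tab$k_mean)
  expect_equal(prof$peaks, 7.0)
})

test_that("mutant panel: identical mutant is null, planted drop is found", {
  set.seed(24)
  wt <- rep(c(1, 1.05, 0.95, 1.02, 0.98, 1.01), 2)[1:6]
  plate <- rbind(
    data.frame(construct = "WT", ph = 8, metal = "Mg", value = wt),
    data.frame(construct = "same", ph = 8, metal = "Mg", value = wt))
  res <- compare_mutant_panel(plate, "WT")
  expect_equal(res$fold, 1)
  expect_equal(res$p_adj, 1)

  runs <- lapply(1:20, function(s) {
    set.seed(400 + s)
    wells <- function(con, mu) data.frame(
      construct = con, ph = 8, metal = "Mg",
      value = rlnorm(6, log(mu) - 0.1^2 / 2, 0.1))
    plate <- rbind(wells("WT", 1), wells("m_null1", 1),
                   wells("m_null2", 1), wells("m_down", 1 / 20))
    res <- compare_mutant_panel(plate, "WT")
    res$construct[res$p_adj < 0.05]
  })
  # the planted 20-fold drop is always detected at FDR 0.05
  expect_true(all(vapply(runs, function(f) "m_down" %in% f, logical(1))))
  # unchanged mutants are flagged only at the rate the FDR admits
  false_flags <- vapply(runs, function(f) sum(f != "m_down"), numeric(1))
  expect_lte(mean(false_flags), 0.15)

  empty <- compare_mutant_panel(
    data.frame(construct = "WT", ph = 8, metal = "Mg", value = 1))
  expect_equal(nrow(empty), 0L)
  expect_warning(
    compare_mutant_panel(rbind(
      data.frame(construct = "WT", ph = 8, metal = "Mg", value = 1:3),
      data.frame(construct = "m", ph = 7, metal = "Mg", value = 1:3))),
    "skipped")
})
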
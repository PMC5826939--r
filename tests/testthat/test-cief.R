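test_that("normalization sets the trace maximum to 1 and is invertible", {
  set.seed(2)
  pI <- seq(5, 8, length.out = 200)
  y <- runif(200, 0.1, 5)
  e <- electropherogram(pI, y)
  n1 <- normalize_trace(e)
  expect_equal(max(n1$intensity), 1)
  expect_equal(n1$intensity * max(y), y, tolerance = 1e-12)
  expect_equal(normalize_trace(n1)$intensity, n1$intensity)  # idempotent
  expect_error(normalize_trace(electropherogram(pI, rep(0, 200))), "positive")
  expect_error(normalize_trace(electropherogram(pI, -y)), "positive")
})

test_that("baseline subtraction removes flat offsets and keeps peaks", {
  pI <- seq(5, 8, length.out = 601)
  # constant trace -> ~0
  flat <- subtract_baseline(electropherogram(pI, rep(0.7, 601)))
  expect_lt(max(flat$intensity), 1e-9)
  # Gaussian + offset c -> Gaussian recovered within 5% of c
  c0 <- 0.3
  g <- dnorm(pI, 6.5, 0.05) / max(dnorm(pI, 6.5, 0.05))
  rec <- subtract_baseline(electropherogram(pI, g + c0))
  expect_lt(max(abs(rec$intensity - g)), 0.05 * c0)
  # zero-baseline input unchanged within tolerance
  rec2 <- subtract_baseline(electropherogram(pI, g))
  expect_lt(max(abs(rec2$intensity - g)), 0.02)
  expect_error(subtract_baseline(electropherogram(pI[1:10], g[1:10]),
                                 window = 50), "larger than")
  # linear method handles a tilted baseline
  tilt <- 0.1 + 0.05 * (pI - 5)
  rec3 <- subtract_baseline(electropherogram(pI, g + tilt), method = "linear")
  expect_lt(max(abs(rec3$intensity - g)), 0.1)
})

test_that("peak fitting recovers centers, widths and analytic areas", {
  pI <- seq(5, 8, length.out = 601)
  expect_identical(nrow(fit_peaks(electropherogram(pI, rep(0, 601)))), 0L)

  one <- 0.8 * exp(-(pI - 6.2)^2 / (2 * 0.05^2))
  pk <- fit_peaks(electropherogram(pI, one))
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$center, 6.2, tolerance = 0.005)
  expect_equal(pk$auc, gaussian_area(0.8, 0.05), tolerance = 0.01)

  two <- exp(-(pI - 6.3)^2 / (2 * 0.05^2)) +
    exp(-(pI - 6.5)^2 / (2 * 0.05^2))          # 4 sigma apart
  pk2 <- fit_peaks(electropherogram(pI, two))
  expect_identical(nrow(pk2), 2L)
  expect_equal(pk2$center, c(6.3, 6.5), tolerance = 0.01)
})

test_that("isoform assignment follows the pI-shift rules", {
  peaks <- data.frame(center = c(6.5, 5.9, 6.35, 6.8),
                      sigma = 0.05, auc = 1, height = 1)
  out <- assign_isoforms(peaks, unmodified_pI = 6.5)
  expect_identical(out$assignment[out$center == 6.5], "unmodified")
  expect_identical(out$assignment[out$center == 5.9], "acetyl")   # shift -0.6
  expect_identical(out$assignment[out$center == 6.35], "phospho") # shift -0.15
  expect_identical(out$assignment[out$center == 6.8], "glycosyl") # shift +0.3
})

test_that("unmodified peak defaults to the highest-pI major peak", {
  peaks <- data.frame(center = c(6.0, 6.5), sigma = 0.05,
                      auc = c(0.4, 0.6), height = c(0.6, 1))
  out <- assign_isoforms(peaks)
  expect_identical(out$assignment, c("acetyl", "unmodified"))
  # a tiny trailing peak is not mistaken for the unmodified isoform
  peaks2 <- data.frame(center = c(6.5, 6.9), sigma = 0.05,
                       auc = c(1, 0.02), height = c(1, 0.02))
  out2 <- assign_isoforms(peaks2)
  expect_identical(out2$assignment[1], "unmodified")
})

test_that("relative concentrations are AUC ratios summing to one", {
  single <- assign_isoforms(
    data.frame(center = 6.5, sigma = 0.05, auc = 2, height = 1),
    unmodified_pI = 6.5)
  pr <- relative_concentrations(single)
  expect_equal(unname(pr$relative_concentration[["unmodified"]]), 1)

  two <- assign_isoforms(
    data.frame(center = c(6.35, 6.5), sigma = 0.05, auc = c(3, 3),
               height = 1), unmodified_pI = 6.5)
  pr2 <- relative_concentrations(two)
  expect_equal(unname(pr2$relative_concentration[["phospho"]]), 0.5)
  expect_equal(sum(pr2$relative_concentration), 1)

  # amplitudes 2:1 with equal sigmas -> areas 2/3 and 1/3
  pI <- seq(5, 8, length.out = 601)
  y <- 1.0 * exp(-(pI - 6.5)^2 / (2 * 0.05^2)) +
       0.5 * exp(-(pI - 6.1)^2 / (2 * 0.05^2))
  pk <- assign_isoforms(fit_peaks(electropherogram(pI, y)),
                        unmodified_pI = 6.5)
  pr3 <- relative_concentrations(pk)
  expect_equal(unname(pr3$relative_concentration[["unmodified"]]), 2 / 3,
               tolerance = 1e-3)
  expect_error(relative_concentrations(
    data.frame(center = 6.5, sigma = 0.05, auc = 0, height = 0,
               assignment = "unmodified")), "zero")
})

test_that("noiseless round trip recovers ground truth within 1% absolute", {
  # peaks separated by >= 3 sigma (0.15 pI at sigma 0.05)
  sp <- electropherogram_spec(isoforms = default_isoforms(0.5, 0.3, 0.2),
                              baseline_level = 0, noise_sigma = 0)
  pr <- quantify_cief(generate_electropherogram(sp)$trace,
                      unmodified_pI = 6.5)
  rc <- pr$relative_concentration
  expect_equal(unname(rc[["unmodified"]]), 0.5, tolerance = 0.01 / 0.5)
  expect_equal(unname(rc[["phospho"]]), 0.3, tolerance = 0.01 / 0.3)
  expect_equal(unname(rc[["acetyl"]]), 0.2, tolerance = 0.01 / 0.2)
})

test_that("relative concentrations are invariant to trace scaling", {
  e <- generate_electropherogram(electropherogram_spec(seed = 77))$trace
  a <- quantify_cief(e, unmodified_pI = 6.5)$relative_concentration
  e$intensity <- e$intensity * 41.7
  b <- quantify_cief(e, unmodified_pI = 6.5)$relative_concentration
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("recovered concentration increases with simulated concentration", {
  rec <- vapply(c(0.15, 0.3, 0.45), function(p) {
    iso <- default_isoforms(unmodified = 1 - p - 0.2, phospho = p,
                            acetyl = 0.2)
    sp <- electropherogram_spec(isoforms = iso, seed = 50)
    pr <- quantify_cief(generate_electropherogram(sp)$trace,
                        unmodified_pI = 6.5)
    unname(pr$relative_concentration[["phospho"]])
  }, numeric(1))
  expect_true(all(diff(rec) > 0))
})

test_that("phosphatase sensitivity scores phospho loss through the pipeline", {
  direct <- phosphatase_sensitivity(
    list(relative_concentration = c(unmodified = 0.6, phospho = 0.4)),
    list(relative_concentration = c(unmodified = 1.0)))
  expect_equal(direct$score, 0.4)
  expect_true(direct$sensitive)

  same <- list(relative_concentration = c(unmodified = 0.7, acetyl = 0.3))
  none <- phosphatase_sensitivity(same, same)
  expect_equal(none$score, 0)
  expect_false(none$sensitive)

  # end to end: simulate before/after traces and quantify both
  sp <- electropherogram_spec(isoforms = default_isoforms(0.7, 0.3, 0),
                              seed = 60)
  before <- quantify_cief(generate_electropherogram(sp)$trace,
                          unmodified_pI = 6.5)
  after <- quantify_cief(generate_electropherogram(apply_phosphatase(sp))$trace,
                         unmodified_pI = 6.5)
  sens <- phosphatase_sensitivity(before, after)
  expect_equal(sens$score, 0.30, tolerance = 0.02 / 0.30)
  expect_true(sens$sensitive)
  # conservation end to end: both profiles sum to 1
  expect_equal(sum(before$relative_concentration), 1, tolerance = 1e-9)
  expect_equal(sum(after$relative_concentration), 1, tolerance = 1e-9)
})

test_that("replicate CV matches the textbook formula and flags zero means", {
  mk <- function(p) list(relative_concentration = c(phospho = p))
  expect_equal(replicate_cv(list(mk(0.4), mk(0.4), mk(0.4)))$cv, 0)
  cv <- replicate_cv(list(mk(0.4), mk(0.6)))
  expect_equal(cv$cv, sd(c(0.4, 0.6)) / mean(c(0.4, 0.6)))
  z <- replicate_cv(list(mk(0), mk(0)))
  expect_true(z$undefined)
  expect_error(replicate_cv(list(mk(0.4))), "2 replicates")
})

test_that("four replicates at default noise reproduce within CV 0.1", {
  profs <- lapply(101:104, function(s)
    quantify_cief(generate_electropherogram(electropherogram_spec(seed = s))$trace,
                  unmodified_pI = 6.5))
  cv <- replicate_cv(profs, "phospho")
  expect_false(cv$undefined)
  expect_lte(cv$cv, 0.1)
})
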
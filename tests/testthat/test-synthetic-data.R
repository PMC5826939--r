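test_that("reference spectra peak at the three Raman cluster centers", {
  ax <- spectral_axis(2800, 5, 40)
  refs <- make_reference_spectra(ax)
  wn <- axis_values(ax)
  expect_identical(wn[which.max(refs$lipid$values)], 2850)
  expect_identical(wn[which.max(refs$protein$values)], 2930)
  expect_identical(wn[which.max(refs$dna$values)], 2960)
  for (r in refs) {
    expect_true(all(r$values >= 0))
    expect_equal(max(r$values), 1)
  }
})

test_that("reference spectrum errors when the axis misses a center", {
  ax <- spectral_axis(2800, 5, 10)  # tops out at 2845
  expect_error(reference_spectrum("lipid", 2850, 12, 1, ax), "2850")
  expect_error(make_reference_spectra(ax), "2850|2930|2960")
})

test_that("narrow-sigma limit concentrates the spectrum on one channel", {
  ax <- spectral_axis(2800, 5, 40)
  r <- reference_spectrum("lipid", 2850, 1e-3, 1, ax)
  wn <- axis_values(ax)
  expect_equal(r$values[wn == 2850], 1)
  expect_true(all(r$values[wn != 2850] < 1e-10))
})

test_that("invalid reference mixtures are rejected", {
  expect_error(reference_spectrum("lipid", 2850, 12, 0), "not all zero")
  expect_error(reference_spectrum("lipid", 2600, 12, 1), "2700")
  expect_error(reference_spectrum("lipid", 2850, -1, 1), "positive")
})

test_that("phantom generation is deterministic for a fixed seed", {
  sp <- small_phantom(seed = 7)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth$label_image, b$truth$label_image)
  expect_identical(a$truth$droplets, b$truth$droplets)
})

test_that("noiseless phantom pixels are exact multiples of their class spectrum", {
  sp <- small_phantom(seed = 3, noise_sigma = 0)
  ph <- generate_phantom(sp)
  refs <- make_reference_spectra(ph$stack$axis)
  lab <- ph$truth$label_image
  for (cl in c("lipid", "protein", "dna")) {
    idx <- which(lab == cl)[1]
    if (is.na(idx)) next
    rc <- arrayInd(idx, dim(lab))
    spec <- ph$stack$data[rc[1], rc[2], ]
    ratio <- spec / refs[[cl]]$values
    expect_true(all(abs(ratio - ratio[1]) < 1e-12 * max(abs(ratio))))
    expect_true(ratio[1] > 0)
  }
})

test_that("realized lipid fraction matches the target and a brute-force recount", {
  sp <- small_phantom("nash", seed = 11, noise_sigma = 0,
                      target_lipid_fraction = 0.28)
  ph <- generate_phantom(sp)
  expect_gte(ph$truth$true_lipid_fraction, 0.25)
  expect_lte(ph$truth$true_lipid_fraction, 0.31)
  # brute force from the label image and the noiseless stack
  lipid_mask <- ph$truth$label_image == "lipid"
  per_px <- apply(ph$stack$data, c(1, 2), sum)
  frac <- sum(per_px[lipid_mask]) / sum(per_px)
  expect_equal(frac, ph$truth$true_lipid_fraction, tolerance = 1e-12)
})

test_that("unreachable lipid fraction errors after bounded retries", {
  sp <- small_phantom("nash", seed = 1, target_lipid_fraction = 0.9)
  expect_error(generate_phantom(sp, max_droplets = 2L), "unreachable")
})

test_that("single-isoform noiseless trace is one Gaussian at the unmodified pI", {
  sp <- electropherogram_spec(
    unmodified_pI = 6.2,
    isoforms = default_isoforms(1, 0, 0),
    baseline_level = 0, noise_sigma = 0)
  e <- generate_electropherogram(sp)
  expect_equal(e$trace$pI[which.max(e$trace$intensity)], 6.2, tolerance = 0.005)
  # matches dnorm shape exactly
  expect_equal(e$trace$intensity,
               dnorm(e$trace$pI, 6.2, 0.05), tolerance = 1e-12)
  expect_equal(unname(e$truth[["unmodified"]]), 1)
})

test_that("equal-concentration isoforms have equal integrated areas", {
  sp <- electropherogram_spec(
    isoforms = default_isoforms(0.5, 0.5, 0, phospho_shift = -0.5),
    baseline_level = 0, noise_sigma = 0)
  e <- generate_electropherogram(sp)$trace
  left <- e$pI < 6.25   # phospho peak at 6.0, unmodified at 6.5
  a1 <- trapz_area(e$pI[left], e$intensity[left])
  a2 <- trapz_area(e$pI[!left], e$intensity[!left])
  expect_equal(a1, a2, tolerance = 1e-6)
})

test_that("glycosyl isoforms appear above the unmodified pI", {
  sp <- electropherogram_spec(
    isoforms = default_isoforms(0.6, 0, 0, glycosyl = 0.4),
    baseline_level = 0, noise_sigma = 0)
  e <- generate_electropherogram(sp)$trace
  pk <- fit_peaks(e)
  expect_equal(nrow(pk), 2L)
  expect_gt(max(pk$center), 6.5)
})

test_that("isoform spec validation enforces the pI-shift conventions", {
  bad_phospho <- default_isoforms(0.5, 0.5, 0)
  bad_phospho$pI_shift[bad_phospho$ptm == "phospho"] <- 0.2
  expect_error(electropherogram_spec(isoforms = bad_phospho), "phospho")
  iso <- default_isoforms(0.4, 0.3, 0.3, acetyl_shift = -0.1)
  expect_error(electropherogram_spec(isoforms = iso), "acetyl")
  expect_error(
    electropherogram_spec(unmodified_pI = 5.1,
                          isoforms = default_isoforms(0.5, 0.3, 0.2)),
    "outside")
})

test_that("phosphatase operator transfers phospho mass and conserves totals", {
  sp <- electropherogram_spec(isoforms = default_isoforms(0.6, 0.4, 0))
  after <- apply_phosphatase(sp)$isoforms
  expect_equal(after$concentration[after$ptm == "unmodified"], 1.0)
  expect_equal(after$concentration[after$ptm == "phospho"], 0.0)
  expect_identical(sum(after$concentration), 1)

  sp2 <- electropherogram_spec(isoforms = default_isoforms(0.5, 0, 0.5))
  expect_identical(apply_phosphatase(sp2)$isoforms,
                   sp2$isoforms)  # acetyl untouched

  sp3 <- electropherogram_spec(isoforms = default_isoforms(0.2, 0.3, 0.5))
  iso3 <- apply_phosphatase(sp3)$isoforms
  expect_equal(iso3$concentration[iso3$ptm == "unmodified"], 0.5)
  expect_equal(iso3$concentration[iso3$ptm == "phospho"], 0)
  expect_equal(iso3$concentration[iso3$ptm == "acetyl"], 0.5)
  expect_identical(sum(iso3$concentration), 1)

  # partial efficiency
  iso4 <- apply_phosphatase(sp, efficiency = 0.5)$isoforms
  expect_equal(iso4$concentration[iso4$ptm == "phospho"], 0.2)
  expect_equal(sum(iso4$concentration), 1)
})

test_that("cohort generation writes a deterministic, fully-seeded manifest", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  args <- list(n_normal = 1L, n_nash = 1L, base_seed = 0L,
               frames_per_sample = 1L, frame_px = 48L, replicates = 2L)
  m1 <- do.call(generate_cohort, c(args, list(out_dir = d1)))
  m2 <- do.call(generate_cohort, c(args, list(out_dir = d2)))
  expect_length(m1$samples, 2L)
  seeds <- vapply(m1$samples, function(s) s$seed, numeric(1))
  expect_identical(anyDuplicated(seeds), 0L)
  expect_identical(vapply(m1$samples, function(s) s$group, ""),
                   c("normal", "nash"))
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))
  # files exist as promised
  for (s in m1$samples) {
    expect_true(all(file.exists(file.path(d1, unlist(s$stacks)))))
    for (tr in s$traces)
      expect_true(all(file.exists(file.path(d1, unlist(tr$files)))))
  }
})

test_that("cohort group sizes and NASH flags follow the requested design", {
  d <- withr::local_tempdir()
  m <- generate_cohort(n_normal = 2L, n_nash = 3L, base_seed = 5L,
                       out_dir = d, frames_per_sample = 1L, frame_px = 48L,
                       replicates = 2L,
                       panel = default_protein_panel()[1:2])
  expect_length(m$samples, 5L)
  modes <- vapply(m$samples, function(s) s$mode, "")
  expect_identical(sum(modes == "nash"), 3L)
  expect_error(generate_cohort(0L, 1L, out_dir = d), ">= 1")
})

test_that("stack and trace files round-trip through disk", {
  d <- withr::local_tempdir()
  ph <- generate_phantom(small_phantom(seed = 2))
  p <- file.path(d, "s.tif")
  write_stack(ph$stack, p)
  back <- read_stack(p)
  expect_equal(back$data, ph$stack$data, tolerance = 1e-6)  # float32
  expect_equal(axis_values(back$axis), axis_values(ph$stack$axis))
  expect_equal(back$pixel_size, ph$stack$pixel_size)

  e <- generate_electropherogram(electropherogram_spec(seed = 4))$trace
  tp <- file.path(d, "t.csv")
  write_trace(e, tp)
  e2 <- read_trace(tp)
  expect_equal(e2$intensity, e$intensity, tolerance = 1e-12)
})
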
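# Peak integration and the semi-quantitative validation calculations.

gauss_chrom <- function(amplitude = 1000, rt = 10, sd = 0.05,
                        baseline_level = 0, baseline_slope = 0,
                        t = seq(0, 20, by = 0.005), id = "T1") {
  y <- amplitude * exp(-(t - rt)^2 / (2 * sd^2)) +
    baseline_level + baseline_slope * t
  srm_chromatogram(id, t, pmax(y, 0))
}

test_that("integration recovers the closed-form Gaussian area", {
  for (p in list(c(1000, 0.05), c(5e5, 0.1), c(200, 0.02))) {
    ch <- gauss_chrom(amplitude = p[1], sd = p[2])
    pk <- integrate_peak(ch, c(10 - 6 * p[2], 10 + 6 * p[2]))
    expect_true(pk$detected)
    expect_equal(pk$area, p[1] * p[2] * sqrt(2 * pi), tolerance = 0.01)
    expect_equal(pk$rt, 10, tolerance = 0.01)
    expect_equal(pk$height, p[1], tolerance = 0.01)
  }
})

test_that("sloped baselines are subtracted to within 2% of closed form", {
  ch <- gauss_chrom(amplitude = 1000, sd = 0.05, baseline_level = 100,
                    baseline_slope = 20)
  pk <- integrate_peak(ch, c(9.7, 10.3))
  expect_equal(pk$area, 1000 * 0.05 * sqrt(2 * pi), tolerance = 0.02)
  expect_equal(pk$height, 1000, tolerance = 0.02)
})

test_that("flat and empty-signal traces come back not-detected", {
  t <- seq(0, 20, by = 0.01)
  pk <- integrate_peak(srm_chromatogram("Z", t, rep(0, length(t))),
                       c(9, 11))
  expect_false(pk$detected)
  expect_equal(pk$area, 0)
  # constant positive baseline, no peak
  pk2 <- integrate_peak(srm_chromatogram("B", t, rep(50, length(t))),
                        c(9, 11))
  expect_false(pk2$detected)
  expect_error(integrate_peak(gauss_chrom(), c(11, 9)), "window")
  expect_error(integrate_peak(gauss_chrom(), c(19.995, 20)), "fewer than 3")
})

test_that("integration is linear in intensity scaling", {
  ch <- gauss_chrom(amplitude = 1000, sd = 0.05)
  for (k in c(0.5, 3, 100)) {
    chk <- srm_chromatogram(ch$id, ch$time, ch$intensity * k)
    expect_equal(integrate_peak(chk, c(9.7, 10.3))$area,
                 k * integrate_peak(ch, c(9.7, 10.3))$area,
                 tolerance = 1e-12)
  }
})

test_that("area ratios reproduce the published cell/medium comparison", {
  # printed per-analyte counts for the four intense medium peaks
  hk2 <- c("DSGb5 (d18:1/16:0)" = 997593,
           "GD1a (d18:1/16:0)" = 6356833,
           "GD1a (d18:1/18:0)" = 4503695,
           "GM3 (d18:1/16:0)" = 6482229)
  achn <- c("DSGb5 (d18:1/16:0)" = 4577916,
            "GD1a (d18:1/16:0)" = 7462803,
            "GD1a (d18:1/18:0)" = 4343382,
            "GM3 (d18:1/16:0)" = 5807321)
  num <- peak_area_table(matrix(achn, ncol = 1,
                                dimnames = list(names(achn), "ACHN")))
  den <- peak_area_table(matrix(hk2, ncol = 1,
                                dimnames = list(names(hk2), "HK-2")))
  ratio <- area_ratio_table(num, den)
  expect_equal(unname(ratio[, 1]), c(459, 117, 96.4, 89.6))
})

test_that("area ratios handle identity, zero and ND denominators", {
  m <- matrix(c(100, 200, 0, 300), ncol = 1,
              dimnames = list(paste0("A", 1:4), "s"))
  tbl <- peak_area_table(m)
  expect_equal(unname(area_ratio_table(tbl, tbl)[c(1, 2, 4), 1]),
               c(100, 100, 100))
  # zero denominator -> undefined marker, not an exception
  expect_true(is.na(area_ratio_table(tbl, tbl)[3, 1]))
  nd <- peak_area_table(m, matrix(c(TRUE, FALSE, TRUE, TRUE), ncol = 1))
  expect_true(is.na(area_ratio_table(tbl, nd)[2, 1]))
})

test_that("matrix factor matches both readings of the formula", {
  # exactly additive spiking -> no matrix effect
  expect_equal(matrix_factor(1000, 500, 1500), 100)
  # fully suppressed spike
  expect_equal(matrix_factor(1000, 500, 500), 0)
  # direct formula evaluation
  expect_equal(matrix_factor(1000, 500, 1560), 106)
  # alternate reading selectable
  expect_equal(matrix_factor(1000, 500, 1560,
                             formula = "spike_minus_std_over_matrix"),
               100 * (1560 - 1000) / 500)
  # invariance to common scaling
  expect_equal(matrix_factor(2000, 1000, 3120), 106)
  expect_error(matrix_factor(0, 500, 600), "area_std")
})

test_that("recovery is a plain percentage with exact arithmetic", {
  expect_equal(recovery(1000, 1000), 100)
  expect_equal(recovery(957.7, 1000), 95.77)
  expect_equal(recovery(0, 1000), 0)
  expect_error(recovery(100, 0), "reference")
})

test_that("linearity matches the normal-equation oracle", {
  # collinear
  expect_equal(linearity(1:5, 2 * (1:5) + 3)$r, 1)
  set.seed(7)
  conc <- c(0.1, 0.25, 0.5, 0.75, 1)
  area <- 2e6 * conc + 1e4 + rnorm(5, 0, 5e3)
  fit <- linearity(conc, area)
  # independent normal-equation solution
  X <- cbind(1, conc)
  beta <- solve(t(X) %*% X, t(X) %*% area)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fit$slope, beta[2], tolerance = 1e-10)
  # r^2 from brute-force covariance formula
  r2 <- (sum((conc - mean(conc)) * (area - mean(area))))^2 /
    (sum((conc - mean(conc))^2) * sum((area - mean(area))^2))
  expect_equal(fit$r^2, r2, tolerance = 1e-10)
  expect_error(linearity(c(1, 1, 1), c(1, 2, 3)), "distinct")
})

test_that("detection summary tallies detected and ND per sample", {
  areas <- matrix(runif(20, 1, 100), 10, 2,
                  dimnames = list(paste0("A", 1:10), c("s1", "s2")))
  det <- matrix(TRUE, 10, 2)
  det[1:3, 1] <- FALSE
  tbl <- peak_area_table(areas, det)
  s <- detection_summary(tbl)
  expect_equal(s$detected, c(7L, 10L))
  expect_equal(s$not_detected, c(3L, 0L))
  expect_equal(s$detected + s$not_detected, c(10L, 10L))
  empty <- peak_area_table(matrix(numeric(0), 0, 1,
                                  dimnames = list(NULL, "s")))
  se <- detection_summary(empty)
  expect_equal(se$detected + se$not_detected, 0L)
})

test_that("peak-area tables round-trip with ND markers", {
  areas <- matrix(c(10.5, 0, 3, 7), 2, 2,
                  dimnames = list(c("A1", "A2"), c("s1", "s2")))
  det <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2)
  tbl <- peak_area_table(areas, det)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peak_area_table(tbl, path)
  expect_match(paste(readLines(path), collapse = "\n"), "ND")
  back <- read_peak_area_table(path)
  expect_equal(back$areas, tbl$areas * ifelse(det, 1, 0))
  expect_equal(back$detected, tbl$detected)
})

test_that("long-format chromatogram text round-trips", {
  chs <- list(gauss_chrom(id = "T1", t = seq(9, 11, 0.01)),
              gauss_chrom(id = "T2", amplitude = 50, t = seq(9, 11, 0.01)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_chromatograms_long(chs, path)
  back <- read_chromatograms_long(path)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$intensity, chs[[1]]$intensity)
  expect_equal(back[[2]]$time, chs[[2]]$time)
})
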
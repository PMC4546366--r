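test_that("ED/ES detection finds the waveform extremes and breaks ties early", {
  sp <- phantom_spec(matrix_px = 48, n_phases = 8)
  st <- generate_lv_phantom(sp)
  ph <- detect_ed_es(sector_areas(st))
  expect_equal(ph$ed_phase, 1L)
  expect_equal(ph$es_phase, which.max(sp$waveform))
  expect_false(ph$degenerate)

  # constant areas -> degenerate with warning
  st0 <- disk_study(radius_px = 8, matrix_px = 32, n_phases = 3)
  expect_warning(ph0 <- detect_ed_es(sector_areas(st0)), "identical")
  expect_equal(c(ph0$ed_phase, ph0$es_phase), c(1L, 1L))
  expect_true(ph0$degenerate)

  # two equal minima -> earlier index wins
  arr <- array(0, c(1, 4, 6), dimnames = list(NULL, NULL, SECTORS6))
  arr[1, , ] <- rep(c(10, 4, 4, 10), 6)
  tab <- table_from_array(arr)
  ph2 <- detect_ed_es(tab)
  expect_equal(ph2$es_phase, 2L)
  expect_equal(ph2$ed_phase, 1L)
})

test_that("RFAC follows the end-diastolic/end-systolic area formula", {
  arr <- array(0, c(1, 2, 6), dimnames = list(NULL, NULL, SECTORS6))
  arr[1, 1, ] <- 10
  arr[1, 2, ] <- c(4, 10, 12, 5, 0, 10)
  tab <- table_from_array(arr)
  map <- compute_rfac(tab, ed_phase = 1, es_phase = 2)
  expect_equal(unname(map$rfac_pct[1, ]), c(60, 0, -20, 50, 100, 0))
})

test_that("cells with zero end-diastolic area become missing, not zero", {
  arr <- array(0, c(2, 2, 6), dimnames = list(NULL, NULL, SECTORS6))
  arr[, 1, ] <- 10; arr[, 2, ] <- 5
  arr[2, 1, 3] <- 0
  tab <- table_from_array(arr)
  expect_warning(map <- compute_rfac(tab, 1, 2), "zero end-diastolic")
  expect_true(is.na(map$rfac_pct[2, 3]))
  expect_equal(unname(map$rfac_pct[1, 3]), 50)
})

test_that("spline resampling is the identity on 10 matching slices and exact on lines", {
  vals <- matrix(stats::runif(60, 10, 90), 10, 6,
                 dimnames = list(NULL, SECTORS6))
  map10 <- rfackit:::new_rfac_map(vals, seq(0, 1, length.out = 10), FALSE,
                                  1, 2, SECTORS6)
  out <- resample_slices(map10)
  expect_equal(out$rfac_pct, vals, tolerance = 1e-12)

  pos6 <- seq(0, 1, length.out = 6)
  lin <- matrix(rep(20 + 35 * pos6, 6), 6, 6,
                dimnames = list(NULL, SECTORS6))
  map6 <- rfackit:::new_rfac_map(lin, pos6, FALSE, 1, 2, SECTORS6)
  out6 <- resample_slices(map6)
  expect_equal(unname(out6$rfac_pct[, 1]),
               20 + 35 * seq(0, 1, length.out = 10), tolerance = 1e-9)
})

test_that("not-a-knot spline reproduces cubics; natural matches the stats oracle", {
  x <- seq(0, 1, length.out = 6)
  y <- 3 - 2 * x + 5 * x^2 - 4 * x^3
  xo <- seq(0, 1, length.out = 37)
  expect_equal(cubic_spline(x, y, xo), 3 - 2 * xo + 5 * xo^2 - 4 * xo^3,
               tolerance = 1e-10)
  ys <- sin(2 * pi * x)
  oracle <- stats::spline(x, ys, xout = xo, method = "natural")$y
  expect_equal(cubic_spline(x, ys, xo, method = "natural"), oracle,
               tolerance = 1e-9)
})

test_that("sectors with sparse slices fall back to linear with a warning", {
  vals <- matrix(c(50, 60, 70), 3, 1, dimnames = list(NULL, "inferior"))
  map3 <- rfackit:::new_rfac_map(vals, c(0, 0.5, 1), FALSE, 1, 2, "inferior")
  expect_warning(out <- resample_slices(map3), "linear")
  expect_equal(unname(out$rfac_pct[c(1, 10), 1]), c(50, 70))
})

test_that("mid-apical summary averages resampled slices 2-7 of the remote wall", {
  m <- flat_map(c(anterior = 10, `antero-septal` = 10, septal = 10,
                  inferior = 69, posterior = 75, lateral = 10))
  s <- regional_summary(m)
  expect_equal(c(s$irfac_pct, s$prfac_pct, s$iprfac_pct), c(69, 75, 72))

  zero <- flat_map(stats::setNames(rep(0, 6), SECTORS6))
  expect_equal(unlist(regional_summary(zero), use.names = FALSE), c(0, 0, 0))

  grad <- flat_map(c(anterior = 0, `antero-septal` = 0, septal = 0,
                     inferior = 0, posterior = 0, lateral = 0))
  grad$rfac_pct[, "inferior"] <- c(99, 10, 20, 30, 40, 50, 60, 99, 99, 99)
  expect_equal(regional_summary(grad)$irfac_pct, 35)
})

test_that("stacked-disk volumetrics match hand computation and decompose into RFAC", {
  # two slices, EDAs (10, 30), ESAs giving RFACs (10%, 50%)
  arr <- array(0, c(2, 2, 6), dimnames = list(NULL, NULL, SECTORS6))
  arr[1, 1, ] <- 10 / 6; arr[2, 1, ] <- 30 / 6
  arr[1, 2, ] <- 9 / 6;  arr[2, 2, ] <- 15 / 6
  tab <- table_from_array(arr, spacing = 1)
  gf <- global_function(tab, 1, 2)
  expect_equal(gf$edv_ul, 40)
  expect_equal(gf$esv_ul, 24)
  expect_equal(gf$sv_ul, 16)
  expect_equal(gf$ef_pct, 40)   # (1 + 15) / 40 * 100
  map <- compute_rfac(tab, 1, 2)
  expect_equal(weighted_mean_rfac(map), gf$ef_pct, tolerance = 1e-12)

  # ESA == EDA -> EF = 0
  arr0 <- arr; arr0[, 2, ] <- arr0[, 1, ]
  expect_warning(gf0 <- global_function(table_from_array(arr0), 1, 2), NA)
  expect_equal(gf0$ef_pct, 0)
  expect_equal(gf0$sv_ul, 0)
})

test_that("uniform-contraction phantom has EF equal to its uniform RFAC", {
  st <- generate_lv_phantom(phantom_spec(matrix_px = 96, n_phases = 8,
                                         contraction_field = 0.2))
  tab <- sector_areas(st)
  gf <- global_function(tab)
  expect_equal(gf$ef_pct, 36, tolerance = 0.5)
  expect_equal(weighted_mean_rfac(compute_rfac(tab)), gf$ef_pct,
               tolerance = 1e-12)
})

test_that("raising one sector's contraction strictly raises its RFAC", {
  base <- c(0.2, 0.3, 0.25, 0.4, 0.35, 0.3)
  rf <- sapply(c(0.3, 0.45, 0.6), function(ci) {
    cs <- base; cs[4] <- ci
    st <- generate_lv_phantom(phantom_spec(matrix_px = 96, n_phases = 6,
                                           contraction_field = cs))
    compute_rfac(sector_areas(st))$rfac_pct[4, 4]
  })
  expect_true(all(diff(rf) > 0))
  expect_true(all(rf <= 100))
})
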
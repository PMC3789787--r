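test_that("endpoint normalization rescales each well to its endpoint read", {
  t <- seq(0, 10, 0.5)
  od <- 0.01 * 10^(0.05 * t)
  gcs <- new("GrowthCurveSet",
    curves = data.frame(plate_id = "P1", well_id = "W1",
                        strain_label = "major", pyridoxine = 400,
                        dala = NA_real_, hem1_deleted = FALSE,
                        time_h = t, od595 = od),
    endpoints = data.frame(plate_id = "P1", well_id = "W1",
                           endpoint_od = od[length(od)]))
  expect_equal(curveData(normalizeCurves(gcs))$od595, od)

  gcs2 <- gcs
  gcs2@curves$od595 <- 2 * od   # doubled gain, same endpoint
  expect_equal(curveData(normalizeCurves(gcs2))$od595, od)

  gcs3 <- gcs
  gcs3@endpoints$endpoint_od <- -1
  expect_error(validObject(gcs3), "endpoint_od")
  gcs4 <- gcs
  gcs4@curves$od595 <- rep(0, length(t))
  expect_error(normalizeCurves(gcs4), "cannot scale")
})

test_that("window slopes recover exact exponentials and report non-attainment", {
  t <- seq(0, 48, 0.5)
  r <- estimateRate(t, 0.01 * 10^(0.05 * t), c(0.05, 0.1))
  expect_true(r$attained_window)
  expect_equal(r$rate, 0.05, tolerance = 1e-9)

  # window choice is irrelevant on a noise-free exponential
  for (w in list(c(0.02, 0.2), c(0.05, 0.5), c(0.011, 0.9))) {
    expect_equal(estimateRate(t, 0.01 * 10^(0.05 * t), w)$rate, 0.05,
                 tolerance = 1e-9)
  }

  flat <- estimateRate(t, rep(0.01, length(t)), c(0.05, 0.1))
  expect_false(flat$attained_window)
  expect_true(is.na(flat$rate))
})

test_that("OLS equals the two-point slope when only two points fall inside", {
  t <- c(0, 1, 2, 3)
  od <- c(0.01, 0.06, 0.09, 0.5)
  a <- estimateRate(t, od, c(0.05, 0.1), method = "ols")
  b <- estimateRate(t, od, c(0.05, 0.1), method = "two_point")
  expect_equal(a$n_points_used, 2L)
  expect_equal(a$rate, b$rate)
  expect_equal(a$rate, (log10(0.09) - log10(0.06)) / 1)
})

test_that("rate estimates are invariant under uniform plate gain", {
  cfg <- curveSimConfig(noise_sd = 0)
  sim <- simulateCurve(cfg, true_rate = 0.05)
  make <- function(gain) {
    new("GrowthCurveSet",
      curves = data.frame(plate_id = "P1", well_id = "W1",
                          strain_label = "major", pyridoxine = 400,
                          dala = NA_real_, hem1_deleted = FALSE,
                          time_h = sim$time_h, od595 = sim$od595 * gain),
      endpoints = data.frame(plate_id = "P1", well_id = "W1",
                             endpoint_od = sim$endpoint_od))
  }
  r1 <- estimateRates(make(1))$rate
  r2 <- estimateRates(make(3.7))$rate
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("plate normalization anchors reference means across plates", {
  rates <- data.frame(
    plate_id = rep(c("A", "B"), each = 2),
    well_id = paste0("W", 1:4),
    strain_label = c("major", "var", "major", "var"),
    pyridoxine = 400, dala = NA_real_, hem1_deleted = FALSE,
    rate = c(0.04, 0.02, 0.06, 0.03),
    n_points_used = 10L, attained_window = TRUE)
  out <- plateNormalize(rates, "major")
  expect_equal(sort(out$factors$factor), sort(c(0.05 / 0.04, 0.05 / 0.06)))
  ref <- out$rates[out$rates$strain_label == "major", ]
  pm <- tapply(ref$rate, ref$plate_id, mean)
  expect_equal(as.numeric(pm[c("A", "B")]), c(0.05, 0.05))

  one <- plateNormalize(rates[rates$plate_id == "A", ], "major")
  expect_equal(one$factors$factor, 1)
  expect_equal(one$rates$rate, rates$rate[rates$plate_id == "A"])

  norefs <- rates
  norefs$strain_label[3] <- "var"
  expect_error(plateNormalize(norefs, "major"), "plate")
})

test_that("relative rates are simple ratios with a growing reference", {
  expect_equal(relativeRate(0.04, 0.04), 1.0)
  expect_equal(relativeRate(0.02, 0.04), 0.5)
  expect_error(relativeRate(0.02, 0), "failed to grow")
})

test_that("a planted plate rate effect cancels in cross-plate ratios", {
  # noise-free exponential wells make the window slope exact, so any
  # residual cross-plate ratio spread would come from the normalization
  cfg <- panelSimConfig(n_alleles = 4,
                        category_proportions = c(0, 0.5, 0.5),
                        plate_effects = c(P02 = 1.2),
                        curve = curveSimConfig(noise_sd = 0,
                                               carrying_capacity = Inf,
                                               duration = 60))
  sim <- simulatePanel(cfg, seed = 21)
  rr <- relativeRates(estimateRates(sim$curves))
  rep_tab <- rr$replicates
  # per-plate per-strain/dose ratios agree across plates after normalization
  key <- paste(rep_tab$strain_label, rep_tab$pyridoxine)
  spread <- tapply(rep_tab$ratio, key, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) NA_real_ else diff(range(x))
  })
  expect_lt(max(spread, na.rm = TRUE), 1e-9)
})

test_that("the pipeline recovers a 60% variant within 0.05 from 3 replicates", {
  gcs <- make_pair_curves(ratio = 0.6, nrep = 3, seed = 42)
  rr <- relativeRates(estimateRates(gcs))
  expect_equal(rr$summary$n, 3L)
  expect_lt(abs(rr$summary$mean_ratio - 0.6), 0.05)
})
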
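test_that("replicate comparison reproduces the Welch statistic", {
  same <- compareReplicates(c(1, 1.1, 0.9), c(1, 1.1, 0.9))
  expect_equal(same$p_value, 1)
  expect_equal(same$flag, "none")
  expect_equal(same$direction, "none")

  v <- c(0.35, 0.36, 0.34); m <- c(1.00, 1.01, 0.99)
  out <- compareReplicates(v, m)
  # hand-computed Welch oracle
  se <- sqrt(var(v) / 3 + var(m) / 3)
  tstat <- (mean(v) - mean(m)) / se
  df <- (var(v) / 3 + var(m) / 3)^2 /
    ((var(v) / 3)^2 / 2 + (var(m) / 3)^2 / 2)
  p_oracle <- 2 * pt(-abs(tstat), df)
  expect_equal(out$p_value, p_oracle, tolerance = 1e-12)
  expect_equal(out$flag, "p001")
  expect_equal(out$direction, "slower")

  expect_error(compareReplicates(0.5, c(1, 1, 1)), "insufficient")
  const <- compareReplicates(c(1, 1, 1), c(1, 1, 1))
  expect_equal(const$p_value, 1)
  expect_equal(compareReplicates(c(2, 2), c(1, 1))$p_value, 0)
})

test_that("the Welch flag rate under the null does not exceed nominal", {
  # With 3-vs-3 normal replicates the Satterthwaite approximation is
  # conservative, so the p01 flag rate sits at or below 1%.
  set.seed(11)
  p <- replicate(4000, compareReplicates(rnorm(3, 1, 0.1),
                                         rnorm(3, 1, 0.1))$p_value)
  rate <- mean(p < 0.01)
  expect_lt(rate, 0.01 + 3 * sqrt(0.01 * 0.99 / 4000))
  expect_gt(rate, 0)
})

test_that("classification reproduces the published category column", {
  panel <- loadTable1()
  calls <- classifyPanel(panel)
  expect_equal(calls$category, variantRecords(panel)$category)
  expect_equal(calls$category[calls$substitution == "H65L"], "nonfunctional")
  expect_equal(calls$category[calls$substitution == "N225S"], "sensitive")
  expect_false(calls$faster_than_wt[calls$substitution == "N225S"])
  expect_equal(calls$category[calls$substitution == "I84V"], "benign")
  # order independence
  shuffled <- new("VariantPanel",
                  records = variantRecords(panel)[58:1, ],
                  growth = growthResults(panel)[nrow(growthResults(panel)):1, ])
  calls2 <- classifyPanel(shuffled)
  expect_equal(calls2$category[match(calls$substitution, calls2$substitution)],
               calls$category)
})

test_that("the faster-than-wild-type set is exactly the three known variants", {
  calls <- classifyPanel(loadTable1())
  expect_equal(fasterSet(calls), c("I127V", "I188V", "V371A"))
  benign_only <- calls[calls$category == "benign", ]
  expect_length(fasterSet(benign_only), 0)
})

test_that("recomputed calls find a planted faster variant", {
  cfg <- curveSimConfig(noise_sd = 0.002)
  build <- function(ratios, nrep = 4, seed = 5) {
    set.seed(seed)
    reps <- list()
    for (s in names(ratios)) {
      for (d in c(400, 4)) {
        for (i in seq_len(nrep)) {
          noise <- rnorm(1, 0, 0.02)
          reps[[length(reps) + 1]] <- data.frame(
            strain_label = s, pyridoxine = d, dala = NA_real_,
            hem1_deleted = FALSE, ratio = ratios[[s]] + noise)
        }
      }
    }
    do.call(rbind, reps)
  }
  rr <- build(list(FAST1 = 1.4, SLOW1 = 0.5, NEUT1 = 1.0))
  major <- build(list(major = 1.0))
  major$strain_label <- NULL
  calls <- classifyFromReplicates(rr, major)
  expect_equal(fasterSet(calls), "FAST1")
  expect_equal(calls$category[calls$substitution == "SLOW1"], "sensitive")
  expect_equal(calls$category[calls$substitution == "NEUT1"], "benign")
})

test_that("dual-cofactor sensitivity follows the low-dALA high-B6 column", {
  panel <- loadTable2()
  expect_equal(dualSensitivity(panel), c("K267E", "L345P"))
  expect_equal(dualSensitivity(panel, rate_floor = 0), "K267E")
  # oracle: direct enumeration of the (400, 5) column
  gr <- growthResults(panel)
  col <- gr[gr$pyridoxine == 400 & gr$dala == 5, ]
  oracle <- sort(col$substitution[is.na(col$rate) | col$rate < 0.6])
  expect_equal(dualSensitivity(panel, rate_floor = 0.6), oracle)
  expect_true(all(c("K267E", "L345P") %in% oracle))

  gr2 <- gr[!(gr$substitution == "V118G" & gr$dala == 5 &
                gr$pyridoxine == 400), ]
  broken <- new("VariantPanel", records = variantRecords(panel), growth = gr2)
  expect_error(dualSensitivity(broken), "V118G")
})

test_that("heme saturation is the clipped 430/280 absorbance ratio", {
  expect_equal(hemeSaturation(0.8, 0.8), 1.0)
  expect_equal(hemeSaturation(0, 0.8), 0.0)
  expect_equal(hemeSaturation(0.4, 0.8), 0.5)
  expect_equal(hemeSaturation(1.2, 0.8), 1.0)   # clipped
  expect_error(hemeSaturation(0.5, 0), "a280")
  expect_error(hemeSaturation(-0.1, 1), "a430")
})
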
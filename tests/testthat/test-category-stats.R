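toy_features <- function() {
  data.frame(allele = letters[1:4], f1 = c(1, 2, 3, 10))
}

test_that("group means average numerics and booleans per group", {
  f <- data.frame(allele = c("a", "b", "c", "d"),
                  num = c(2, 4, 6, 8),
                  reg = c(TRUE, TRUE, FALSE, FALSE))
  gm <- groupMeans(f, list(g1 = c("a", "b", "c"), g2 = "d"))
  expect_equal(gm$mean[gm$group == "g1" & gm$feature == "num"], 4.0)
  expect_equal(gm$mean[gm$group == "g1" & gm$feature == "reg"], 2 / 3)
  expect_equal(gm$mean[gm$group == "g2" & gm$feature == "num"], 8.0)

  f$num[4] <- NA
  expect_error(groupMeans(f, list(g1 = c("a", "b", "c"), g2 = "d")),
               "no non-missing")
  expect_error(groupMeans(f, list(g1 = c("a", "b"), g2 = c("b", "c"))),
               "partition")
})

test_that("a planted group shift moves the group mean by the shift", {
  set.seed(8)
  n <- 40
  f <- data.frame(allele = sprintf("a%02d", 1:n), x = rnorm(n))
  hit <- 1:10
  f$x[hit] <- f$x[hit] + 2
  gm <- groupMeans(f, list(hi = f$allele[hit], rest = f$allele[-hit]))
  expect_equal(gm$mean[gm$group == "hi"] - gm$mean[gm$group == "rest"],
               2, tolerance = 0.7)  # sampling noise ~ sd/sqrt(10)
})

test_that("permutation p-values match exhaustive enumeration", {
  f <- toy_features()
  gr <- list(g1 = c("a", "b"), g2 = c("c", "d"))
  ex <- exhaustiveTest(f, gr)
  # hand enumeration: pair means over C(4,2)=6 assignments of {1,2,3,10}
  # to g1: 1.5, 2, 5.5, 2.5, 6, 6.5; observed g1 mean = 1.5
  expect_equal(attr(ex, "n_assignments"), 6)
  expect_equal(ex$p_low[ex$group == "g1"], 1 / 6)
  expect_equal(ex$p_high[ex$group == "g1"], 1)
  pt <- permutationTest(f, gr, n_perm = 10000, seed = 2)
  bound <- 2 * sqrt((1 / 6) * (5 / 6) / 10000) + 1e-3
  expect_lt(abs(pt$p_low[pt$group == "g1"] - 1 / 6), bound)
  expect_lt(abs(pt$p_high[pt$group == "g1"] - 1), bound)
})

test_that("degenerate permutation instances behave as defined", {
  f <- toy_features()
  # constant feature: every null equals the observed mean
  fc <- data.frame(allele = letters[1:4], f1 = rep(5, 4))
  r <- permutationTest(fc, list(g1 = c("a", "b"), g2 = c("c", "d")),
                       n_perm = 200, seed = 1)
  expect_true(all(r$p_low == 1) && all(r$p_high == 1))

  # a single group holding every allele has only one assignment
  r2 <- exhaustiveTest(f, list(all = letters[1:4]))
  expect_equal(r2$p_low, 1)
  expect_equal(r2$p_high, 1)

  # two alleles, one per group: each tail is 1/2 or 1
  f2 <- data.frame(allele = c("a", "b"), f1 = c(1, 2))
  r3 <- exhaustiveTest(f2, list(g1 = "a", g2 = "b"))
  expect_equal(sort(c(r3$p_low[r3$group == "g1"],
                      r3$p_high[r3$group == "g1"])), c(1 / 2, 1))

  expect_error(permutationTest(f, list(g1 = c("a", "b"), g2 = c("c", "d")),
                               n_perm = 0), "n_perm")
  expect_error(exhaustiveTest(
    data.frame(allele = sprintf("a%02d", 1:40), f1 = rnorm(40)),
    list(g1 = sprintf("a%02d", 1:20), g2 = sprintf("a%02d", 21:40))),
    "permutationTest")
})

test_that("fixed seeds reproduce bit-identical permutation results", {
  set.seed(99)
  f <- data.frame(allele = sprintf("a%02d", 1:30), x = rnorm(30),
                  y = rnorm(30))
  gr <- list(g1 = sprintf("a%02d", 1:8), g2 = sprintf("a%02d", 9:30))
  a <- permutationTest(f, gr, n_perm = 500, seed = 7)
  b <- permutationTest(f, gr, n_perm = 500, seed = 7)
  expect_identical(a, b)
  c <- permutationTest(f, gr, n_perm = 500, seed = 8)
  expect_false(identical(a$p_high, c$p_high))
  # both tails from the same null: p_low + p_high >= 1 + 1/(n+1)
  expect_true(all(a$p_low + a$p_high >= 1 + 1 / 501 - 1e-12))
})

test_that("null p-values are approximately uniform", {
  set.seed(12)
  ph <- replicate(300, {
    f <- data.frame(allele = paste0("a", 1:20), f1 = rnorm(20))
    gr <- list(g1 = paste0("a", 1:6), g2 = paste0("a", 7:20))
    permutationTest(f, gr, n_perm = 499,
                    seed = sample.int(1e6, 1))$p_high[1]
  })
  ks <- suppressWarnings(ks.test(ph, "punif")$statistic)
  expect_lt(ks, 0.1)
})

test_that("a 1.5-SD planted shift is detected in most repetitions", {
  set.seed(13)
  hits <- replicate(60, {
    f <- data.frame(allele = paste0("a", 1:50), f1 = rnorm(50))
    f$f1[1:10] <- f$f1[1:10] + 1.5
    gr <- list(hi = paste0("a", 1:10), rest = paste0("a", 11:50))
    r <- permutationTest(f, gr, n_perm = 999, seed = sample.int(1e6, 1))
    min(r$p_low[1], r$p_high[1]) < 0.01
  })
  expect_gte(mean(hits), 0.8)
})

test_that("no association is flagged on a null six-group synthetic panel", {
  sim <- simulatePanel(panelSimConfig(n_alleles = 60, feature_shift = 0),
                       seed = 31)
  rec <- sim$records
  groups <- split(rec$allele, paste(rec$category, rec$construction,
                                    sep = "_"))
  groups <- groups[lengths(groups) > 0]
  r <- permutationTest(sim$features, groups, n_perm = 2000, seed = 17)
  # 6 groups x 5 features x 2 tails at 0.01: expect ~0.6 flags; allow
  # Poisson headroom but catch systematic association
  expect_lte(sum(pmin(r$p_low, r$p_high) < 0.01), 4)
})
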
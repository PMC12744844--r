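test_that("Pearson reports match the from-definition oracle", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2.1, 2.9, 5.2, 6.1, 8.7, 11.0)
  r <- pearsonCorrelation(x, y)
  expect_equal(r@r, pearsonOracle(x, y), tolerance = 1e-12)
  ## and the p/CI agree with the standard reference implementation
  ref <- cor.test(x, y)
  expect_equal(r@p, ref$p.value, tolerance = 1e-9)
  expect_equal(r@ci95, as.numeric(ref$conf.int), tolerance = 1e-9)
  expect_equal(resultValue(pearsonCorrelation(x, 2 * x + 1)), 1)
  expect_equal(resultValue(pearsonCorrelation(x, -x)), -1)
})

test_that("degenerate correlations return the sentinel", {
  flat <- pearsonCorrelation(1:5, rep(3, 5))
  expect_false(isEstimable(flat))
  expect_true(is.na(resultValue(flat)))
  expect_error(pearsonCorrelation(1:2, 1:2), "at least 3")
})

test_that("Pearson r transforms correctly under affine maps", {
  set.seed(4)
  x <- rnorm(20); y <- x + rnorm(20)
  r0 <- resultValue(pearsonCorrelation(x, y))
  expect_equal(resultValue(pearsonCorrelation(3 * x + 7, y)), r0,
               tolerance = 1e-12)
  expect_equal(resultValue(pearsonCorrelation(x, -2 * y + 1)), -r0,
               tolerance = 1e-12)
})

test_that("regression bands are mean-response confidence bands", {
  set.seed(9)
  x <- seq(-3, 3, length.out = 15)
  y <- 1.5 * x - 2 + rnorm(15, sd = 0.5)
  b <- fitWithBand(x, y)
  ## normal-equation oracle
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  expect_equal(b@slope, slope, tolerance = 1e-12)
  expect_equal(b@intercept, mean(y) - slope * mean(x), tolerance = 1e-12)
  ## band contains the line and is narrowest at mean(x) for symmetric x
  expect_true(all(b@band$lower <= b@band$fit + 1e-12))
  expect_true(all(b@band$upper >= b@band$fit - 1e-12))
  width <- b@band$upper - b@band$lower
  expect_equal(b@band$x[which.min(width)], mean(x), tolerance = 0.05)
  ## exactly collinear data: zero residual variance collapses the band
  bc <- fitWithBand(x, 2 * x + 1)
  expect_lt(max(bc@band$upper - bc@band$lower), 1e-9)
  expect_error(fitWithBand(rep(1, 5), 1:5), "degenerate")
})

test_that("grouped correlations enumerate combinations deterministically", {
  set.seed(12)
  tab <- expand.grid(position = 2:8,
                     modification = c("DNA", "FLUORO", "MOE", "OME", "FA"),
                     combination = c("n-1", "n", "n+1", "n-1/n",
                                     "n-1/n+1", "n/n+1", "n-1/n/n+1"),
                     stringsAsFactors = FALSE)
  tab$sirmsd_A <- runif(nrow(tab), 0, 2)
  tab$soa_pct <- 40 * tab$sirmsd_A + rnorm(nrow(tab), sd = 10)
  rep <- groupedCorrelations(tab)
  expect_equal(nrow(rep), 7L * 3L)
  expect_equal(unique(rep$grouping), c("2-8", "2-5", "6-8"))
  ## union group n equals the sum of the split-group ns
  for (comb in unique(rep$combination)) {
    sub <- rep[rep$combination == comb, ]
    expect_equal(sub$n[sub$grouping == "2-8"],
                 sub$n[sub$grouping == "2-5"] +
                 sub$n[sub$grouping == "6-8"])
  }
  ## the union-group r is computed on exactly the concatenated points
  sub <- tab[tab$combination == "n-1/n/n+1", ]
  expect_equal(rep$r[rep$combination == "n-1/n/n+1" &
                     rep$grouping == "2-8"],
               pearsonOracle(sub$sirmsd_A, sub$soa_pct),
               tolerance = 1e-12)
  ## constant SOA: every report is a sentinel
  tab0 <- tab; tab0$soa_pct <- 55
  rep0 <- groupedCorrelations(tab0)
  expect_true(all(!rep0$estimable))
  ## too-small groups are explicit sentinels, not dropped rows
  tiny <- tab[tab$position == 2 & tab$modification == "DNA", ]
  repTiny <- groupedCorrelations(tiny)
  expect_true(all(repTiny$n[repTiny$grouping == "6-8"] == 0))
  expect_true(all(!repTiny$estimable[repTiny$grouping == "6-8"]))
})

test_that("simulated correlated tables recover the population r", {
  inside <- 0L
  for (seed in 1:50) {
    set.seed(200 + seed)
    n <- 35
    x <- rnorm(n)
    rho <- 0.8
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    r <- pearsonCorrelation(x, y)
    if (r@ci95[1] <= rho && rho <= r@ci95[2]) inside <- inside + 1L
  }
  expect_gte(inside, 42L)  # ~95% nominal coverage over 50 draws
})
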
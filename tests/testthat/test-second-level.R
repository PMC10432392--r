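make_maps <- function(n, d = c(12, 12), mean = 0, sd = 1, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    matrix(stats::rnorm(prod(d), mean, sd), d[1], d[2]))
}

test_that("identical groups give identically zero t and F maps", {
  g <- make_maps(3, seed = 2)
  t0 <- second_level_ttest(g, g)
  expect_true(all(t0$stat == 0))
  F0 <- second_level_anova(list(g, g, g))
  expect_lt(max(abs(F0$stat)), 1e-20)
  expect_error(second_level_ttest(g[1], g), "at least 2")
  expect_error(second_level_anova(list(g)), "at least 2 groups")
})

test_that("two-sample t map matches the closed form for a shifted region", {
  d <- c(10, 10)
  A <- make_maps(4, d, seed = 3)
  delta <- 1.5
  B <- lapply(make_maps(4, d, seed = 4), function(m) {
    m[3:5, 3:5] <- m[3:5, 3:5] + delta
    m
  })
  map <- second_level_ttest(A, B)
  # oracle: stats::t.test per pixel with pooled variance
  px <- c(4, 4)
  a <- vapply(A, function(m) m[px[1], px[2]], numeric(1))
  b <- vapply(B, function(m) m[px[1], px[2]], numeric(1))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(map$stat[px[1], px[2]], unname(tt$statistic), tolerance = 1e-10)
  expect_equal(map$df, unname(tt$parameter))
  # signed map: group B higher in the shifted region gives negative t there
  expect_lt(mean(map$stat[3:5, 3:5]), 0)
})

test_that("two-group ANOVA F equals the squared two-sample t pixelwise", {
  A <- make_maps(3, seed = 5); B <- make_maps(4, seed = 6)
  tmap <- second_level_ttest(A, B)
  fmap <- second_level_anova(list(A, B))
  expect_equal(fmap$stat, tmap$stat^2, tolerance = 1e-10)
  # oracle cross-check against aov at one pixel
  px <- c(7, 2)
  vals <- c(vapply(A, `[`, numeric(1), px[1], px[2]),
            vapply(B, `[`, numeric(1), px[1], px[2]))
  grp <- factor(rep(c("a", "b"), c(3, 4)))
  F_aov <- summary(stats::aov(vals ~ grp))[[1]]$`F value`[1]
  expect_equal(fmap$stat[px[1], px[2]], F_aov, tolerance = 1e-8)
})

test_that("null second-level maps are calibrated at alpha = 0.05", {
  set.seed(8)
  hits <- 0; total <- 0
  for (r in 1:20) {
    A <- make_maps(4, c(16, 16), seed = 100 + r)
    B <- make_maps(4, c(16, 16), seed = 200 + r)
    m <- second_level_ttest(A, B, p_threshold = 0.05)
    hits <- hits + sum(m$mask_supra); total <- total + length(m$mask_supra)
  }
  ci <- stats::qbinom(c(0.005, 0.995), total, 0.05) / total
  expect_gte(hits / total, ci[1]); expect_lte(hits / total, ci[2])
})

test_that("a shifted-mean region is detected with high power by the ANOVA", {
  d <- c(16, 16); region <- cbind(rep(3:6, 4), rep(3:6, each = 4))
  groups <- lapply(1:3, function(g) {
    lapply(1:4, function(i) {
      set.seed(1000 * g + i)
      m <- matrix(stats::rnorm(prod(d)), d[1], d[2])
      if (g == 3) m[region] <- m[region] + 3
      m
    })
  })
  fmap <- second_level_anova(groups, p_threshold = 0.01)
  expect_gte(mean(fmap$mask_supra[region]), 0.8)   # >= 80% power
})

test_that("second-level maps are invariant to common affine rescaling", {
  A <- make_maps(3, seed = 9); B <- make_maps(3, seed = 10)
  m1 <- second_level_ttest(A, B)
  resc <- function(g) lapply(g, function(m) 3.7 * m + 11)
  m2 <- second_level_ttest(resc(A), resc(B))
  expect_equal(m2$stat, m1$stat, tolerance = 1e-8)
})

test_that("3 vs 3 permutation inference enumerates all 20 label splits", {
  A <- make_maps(3, c(8, 8), seed = 11)
  B <- lapply(make_maps(3, c(8, 8), seed = 12), function(m) m + 0.5)
  map <- permutation_map(list(A, B), n_perm = 1000, seed = 1)
  expect_true(map$exhaustive)
  expect_equal(map$n_perm_used, choose(6, 3))
  # exhaustive FWE p-values are multiples of 1/20
  expect_true(all(abs(map$p * 20 - round(map$p * 20)) < 1e-9))
  expect_gte(min(map$p), 1 / 20)
})

test_that("permutation FWE is controlled under the null", {
  rejections <- vapply(1:100, function(r) {
    A <- make_maps(3, c(10, 10), seed = 3000 + r)
    B <- make_maps(3, c(10, 10), seed = 4000 + r)
    m <- permutation_map(list(A, B), n_perm = 1000, seed = r)
    min(m$p) <= 0.05
  }, logical(1))
  rate <- mean(rejections)
  se <- sqrt(0.05 * 0.95 / 100)
  expect_lte(rate, 0.05 + 2.5 * se)
})

test_that("parametric and permutation maps agree on a strong effect", {
  d <- c(16, 16); region <- cbind(rep(4:8, 5), rep(4:8, each = 5))
  A <- make_maps(5, d, seed = 13)
  B <- lapply(make_maps(5, d, seed = 14), function(m) {
    m[region] <- m[region] + 4; m
  })
  par_map <- second_level_ttest(A, B, p_threshold = 0.001)
  perm_map <- permutation_map(list(A, B), n_perm = 500, seed = 2,
                              p_threshold = 0.05)
  expect_gte(dice_coef(par_map$mask_supra, perm_map$mask_supra), 0.7)
})

test_that("sign-flip permutation handles the one-sample design", {
  # global sign reversal duplicates every |t|, so the smallest achievable
  # FWE p is 2/2^n; n = 7 maps put it below 0.05
  A <- lapply(make_maps(7, c(8, 8), seed = 15), function(m) m + 1.5)
  m <- permutation_map(A, n_perm = 1000, seed = 3)
  expect_true(m$exhaustive)
  expect_equal(m$n_perm_used, 2^7)
  expect_gte(min(m$p), 2 / 2^7)
  expect_gt(sum(m$mask_supra), 0)
})
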
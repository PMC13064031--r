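test_that("normality gate accepts Gaussian and rejects skewed samples", {
  set.seed(31)
  pass_gauss <- mean(replicate(100, normality_gate(rnorm(500))$normal))
  pass_expo <- mean(replicate(100, normality_gate(rexp(500))$normal))
  # a joint 5%-level double test passes a true Gaussian ~90% of the time
  expect_gte(pass_gauss, 0.85)
  expect_lte(pass_expo, 0.01)
  # degenerate and tiny samples are non-normal by convention
  expect_false(normality_gate(rep(3, 50))$normal)
  expect_false(normality_gate(c(1, 2, 3, 4))$normal)
})

test_that("significance stars follow the reporting convention", {
  expect_equal(p_stars(c(0.2, 0.04, 0.009, 0.0009, 0.00009)),
               c("ns", "*", "**", "***", "****"))
  expect_equal(p_stars(0.05), "ns")  # boundary: p < 0.05 strictly
})

test_that("compare_two routes through t / Welch / Mann-Whitney correctly", {
  set.seed(32)
  a <- rnorm(30)
  r <- compare_two(a, a)  # identical samples: p in the 1 region
  expect_gt(r$p_value, 0.9)
  expect_equal(r$stars, "ns")

  # clearly shifted Gaussians: strongly significant in most seeds
  hits <- replicate(20, {
    x <- rnorm(30); y <- rnorm(30, 2)  # 2 SD shift
    compare_two(x, y)$p_value < 0.001
  })
  expect_gte(mean(hits), 0.95)

  # heteroscedastic normal samples trigger the Welch path via the F test
  set.seed(33)
  x <- rnorm(40, 0, 1); y <- rnorm(40, 0, 5)
  r2 <- compare_two(x, y)
  expect_equal(r2$test_name, "Welch t")

  # skewed data fall back to Mann-Whitney
  r3 <- compare_two(rexp(40), rexp(40)); expect_equal(r3$test_name,
                                                      "Mann-Whitney")
  # n = 1 in a group: Mann-Whitney attempted and flagged
  r4 <- compare_two(1, c(2, 3, 4))
  expect_equal(r4$test_name, "Mann-Whitney")
  expect_match(r4$note, "n = 1")
})

test_that("compare_two type-I error is near nominal under a Gaussian null", {
  set.seed(34)
  p <- replicate(400, compare_two(rnorm(30), rnorm(30))$p_value)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.025)
})

test_that("compare_k gates between ANOVA and Kruskal-Wallis", {
  set.seed(35)
  g <- list(a = rnorm(25), b = rnorm(25), c = rnorm(25))
  r <- compare_k(g)
  expect_equal(r$test_name, "one-way ANOVA")
  expect_gt(r$p_value, 0.001)

  gs <- list(a = rnorm(25), b = rnorm(25), c = rnorm(25, 2))
  expect_lt(compare_k(gs)$p_value, 0.001)

  gx <- list(a = rexp(25), b = rexp(25), c = rexp(25))
  expect_equal(compare_k(gx)$test_name, "Kruskal-Wallis")

  deg <- list(a = rep(1, 5), b = rep(1, 5), c = rep(1, 5))
  rd <- compare_k(deg)
  expect_match(rd$note, "degenerate")
  expect_error(compare_k(list(a = 1:5, b = 1:5)), ">= 3 groups")
})

test_that("Hedges g reproduces hand-computed and benchmark values", {
  # experience-split contrast: printed summaries reproduce exactly
  e <- hedges_g(63.8, 14.9, 48, 70.3, 16.1, 48)
  expect_equal(round_half_up(e$g, 2), 0.42)
  expect_equal(round_half_up(e$ci_low, 2), 0.01)
  expect_equal(round_half_up(e$ci_high, 2), 0.82)

  # hand computation: d = 1, J = 1 - 3/71 -> g = 0.9577
  e2 <- hedges_g(0, 1, 10, 1, 1, 10)
  expect_equal(e2$g, (1 - 3 / 71) * 1, tolerance = 1e-12)

  expect_equal(hedges_g(5, 2, 10, 5, 2, 10)$g, 0)
  expect_error(hedges_g(1, 0, 10, 2, 0, 10), "pooled SD is zero")
})

test_that("Hedges g is symmetric and scale invariant", {
  set.seed(36)
  for (i in 1:10) {
    m1 <- runif(1, 0, 100); m2 <- runif(1, 0, 100)
    s1 <- runif(1, 1, 30); s2 <- runif(1, 1, 30)
    n1 <- sample(5:50, 1); n2 <- sample(5:50, 1)
    a <- hedges_g(m1, s1, n1, m2, s2, n2)
    b <- hedges_g(m2, s2, n2, m1, s1, n1)
    expect_equal(a$g, b$g)
    k <- runif(1, 0.1, 10)
    expect_equal(hedges_g(k * m1, k * s1, n1, k * m2, k * s2, n2)$g, a$g,
                 tolerance = 1e-10)
    expect_true(a$ci_low <= a$g && a$g <= a$ci_high)
  }
})

test_that("sample-based Hedges g agrees with summary-statistic form", {
  set.seed(37)
  a <- rnorm(25, 10, 3); b <- rnorm(30, 12, 4)
  e1 <- hedges_g_samples(a, b)
  e2 <- hedges_g(mean(a), sd(a), 25, mean(b), sd(b), 30)
  expect_equal(e1$g, e2$g)
  expect_equal(e1$ci_low, e2$ci_low)
})
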
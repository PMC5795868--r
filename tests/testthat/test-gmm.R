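test_that("degenerate inputs follow the documented contracts", {
  # all samples equal, K = 1: closed form
  m <- gmm1d(rep(5, 100), K = 1)
  expect_equal(m$means, 5)
  expect_equal(m$weights, 1)
  expect_equal(m$variances, m$var_floor)
  # all samples equal, K > 1: collapses with a warning
  expect_warning(m2 <- gmm1d(rep(5, 100), K = 3), "identical")
  expect_identical(m2$K, 1L)
  expect_true(m2$degenerate)
  # K exceeding the distinct-value count is an error
  expect_error(gmm1d(c(1, 1, 2, 2), K = 3), "distinct")
  expect_error(gmm1d(rnorm(10), K = 0), "positive")
})

test_that("EM recovers a well-separated two-component mixture", {
  set.seed(123)
  x <- c(rnorm(5000, 0, 1), rnorm(5000, 10, 1))
  m <- gmm1d(x, K = 2)
  expect_true(m$converged)
  expect_lt(max(abs(m$means - c(0, 10))), 0.1)
  expect_lt(max(abs(m$weights - c(0.5, 0.5))), 0.05)
  expect_lt(max(abs(m$variances - c(1, 1))), 0.2)
  # means come out amplitude-ordered
  expect_true(all(diff(m$means) > 0))
})

test_that("log-likelihood is non-decreasing across iterations", {
  for (s in 1:10) {
    set.seed(s)
    x <- c(rnorm(150, 0, 1), rnorm(100, 3, 2), rexp(50, 1 / 4))
    m <- gmm1d(x, K = 3)
    expect_true(all(diff(m$ll_trace) >= -1e-8 * abs(m$logLik)))
  }
})

test_that("EM agrees with an independent reference implementation", {
  skip_if_not_installed("mclust")
  for (s in 1:5) {
    set.seed(s)
    x <- c(rnorm(100, 0, 1), rnorm(100, 8, 1.5))
    init <- list(weights = c(0.5, 0.5), means = c(1, 6),
                 variances = c(2, 2))
    mine <- gmm1d(x, K = 2, init = init, tol = 1e-10, max_iter = 2000)
    ref <- mclust::emV(
      data = x,
      parameters = list(pro = init$weights, mean = init$means,
                        variance = list(modelName = "V", d = 1, G = 2,
                                        sigmasq = init$variances)),
      control = mclust::emControl(tol = 1e-10, itmax = 5000))
    expect_equal(mine$logLik, ref$loglik, tolerance = 1e-4)
  }
})

test_that("means land within 3 standard errors for K in {2, 3, 5}", {
  dev_se <- c()
  for (K in c(2, 3, 5)) {
    mu <- seq(0, by = 8, length.out = K)
    for (s in 1:7) {
      set.seed(1000 * K + s)
      x <- rnorm(10000, sample(mu, 10000, replace = TRUE), 1)
      m <- gmm1d(x, K = K)
      se <- 1 / sqrt(10000 / K)   # sd 1, ~n/K points per component
      dev_se <- c(dev_se, abs(m$means - mu) / se)
    }
  }
  # ~N(0,1) deviations: nearly all inside 3 SE, none wildly outside
  expect_gte(mean(dev_se <= 3), 0.95)
  expect_true(all(dev_se <= 5))
})

test_that("random restarts rescue a deliberately poor initialization", {
  set.seed(77)
  x <- c(rnorm(300, 0, 0.5), rnorm(300, 20, 0.5), rnorm(300, 40, 0.5))
  bad <- list(weights = rep(1 / 3, 3), means = c(19, 20, 21),
              variances = rep(0.25, 3))
  stuck <- gmm1d(x, K = 3, init = bad)
  best <- gmm1d(x, K = 3, restarts = 5, seed = 9)
  expect_gte(best$logLik, stuck$logLik)
  expect_lt(max(abs(best$means - c(0, 20, 40))), 0.2)
})

test_that("discretization splits at the posterior boundary", {
  m <- structure(list(K = 2L, weights = c(0.5, 0.5), means = c(0, 10),
                      variances = c(1, 1), logLik = NA_real_,
                      ll_trace = NA_real_, n = 0L, iterations = 0L,
                      converged = TRUE, floor_hit = FALSE,
                      degenerate = FALSE, var_floor = 1e-12, call = NULL),
                 class = "gmm1d")
  # equal variances and weights: the boundary is the midpoint 5
  expect_identical(predict(m, 4.9), 0L)
  expect_identical(predict(m, 5.1), 1L)
  # a point exactly at a component mean belongs to that component
  expect_identical(predict(m, 0), 0L)
  expect_identical(predict(m, 10), 1L)
  # monotone assignment over a grid
  g <- predict(m, seq(-5, 15, length.out = 1000))
  expect_true(all(diff(g) >= 0))
  # posteriors sum to one
  p <- predict(m, c(-1, 5, 11), type = "posterior")
  expect_equal(rowSums(p), rep(1, 3))
})

test_that("discretize is a pure function of features and model", {
  cfg <- two_motion_config(seed = 2, dur = 1.5)
  f <- sliding_rms(generate_session(cfg))
  m <- fit_gmm(f, K = 3)
  i1 <- discretize(f, m)
  i2 <- discretize(f, m)
  expect_identical(i1, i2)
  expect_true(all(i1 >= 0 & i1 < 3))
  expect_identical(dim(i1), dim(f$values))
})

test_that("spatial patterns place channels on the grid and round-trip", {
  lay <- grid_layout(2, 2, c("a", "b", "c", "d"))
  p <- to_spatial_pattern(c(0, 1, 2, 3), lay, K = 4)
  expect_equal(p$grid, matrix(c(0L, 2L, 1L, 3L), 2, 2))
  expect_identical(pattern_to_indices(p), c(0L, 1L, 2L, 3L))
  # uniform pattern
  u <- to_spatial_pattern(rep(2, 4), lay, K = 4)
  expect_true(all(u$grid == 2))
  # unoccupied cells stay NA
  lay3 <- grid_layout(2, 2, c("a", "b", "c"))
  q <- to_spatial_pattern(c(1, 0, 1), lay3, K = 2)
  expect_true(is.na(q$grid[2, 2]))
  expect_error(to_spatial_pattern(c(0, 1, 4, 0), lay, K = 4), "out of")
  expect_error(to_spatial_pattern(c(0, 1), lay, K = 4), "length")
})

test_that("mutual-information channel scores match closed forms", {
  lab <- rep(c("x", "y"), each = 50)
  idx <- cbind(const = rep(1L, 100),              # no information
               aligned = rep(c(0L, 1L), each = 50))  # 1 bit
  attr(idx, "K") <- 2L
  sc <- select_channels(idx, lab)
  expect_equal(sc$mi_bits[sc$channel == "const"], 0)
  expect_equal(sc$mi_bits[sc$channel == "aligned"], 1)
  expect_identical(sc$channel[1], "aligned")
  expect_error(select_channels(idx, rep("x", 100)), "two classes")
})
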
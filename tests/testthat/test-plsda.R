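test_that("one-hot encoding has unit rows and class-count column sums", {
  cls <- c("a", "b", "c")
  Y <- one_hot(c("a", "c", "b", "b"), cls)
  expect_equal(Y[2, ], c(a = 0, b = 0, c = 1))
  expect_equal(rowSums(Y), rep(1, 4))
  expect_equal(unname(colSums(Y)), c(1, 2, 1))
  expect_error(one_hot(c("a", "x"), cls), "x")
})

test_that("full-rank NIPALS fit recovers a noiseless linear response", {
  set.seed(10)
  X <- matrix(rnorm(40 * 8), 40, 8)
  y <- X %*% rnorm(8)
  fit <- fit_plsda(X, y, n_latent = 8)
  expect_lt(sqrt(mean((predict(fit, X) - y)^2)), 1e-8)
})

test_that("NIPALS is invariant to sample order and matches mixOmics", {
  skip_if_not_installed("mixOmics")
  set.seed(11)
  X <- matrix(rnorm(50 * 10), 50, 10)
  colnames(X) <- paste0("v", 1:10)
  Y <- one_hot(sample(c("a", "b", "c"), 50, replace = TRUE), c("a", "b", "c"))
  f1 <- fit_plsda(X, Y, 4)
  perm <- sample(50)
  f2 <- fit_plsda(X[perm, ], Y[perm, ], 4)
  expect_equal(f1$B, f2$B, tolerance = 1e-10)

  # independent oracle: mixOmics regression-mode PLS predictions
  f3 <- mixOmics::pls(X, Y, ncomp = 4, mode = "regression", scale = FALSE)
  pr3 <- predict(f3, X)$predict[, , 4]
  expect_equal(unname(predict(f1, X)), unname(pr3), tolerance = 1e-8)
})

test_that("a single informative column dominates the coefficients", {
  set.seed(12)
  n <- 80
  y <- rnorm(n)
  X <- matrix(rnorm(n * 6, sd = 1), n, 6)
  X[, 4] <- y + rnorm(n, sd = 0.05)
  fit <- fit_plsda(X, cbind(y), 1)
  expect_equal(which.max(abs(fit$B)), 4L)
})

test_that("degenerate components stop extraction early with a report", {
  v <- rnorm(12)
  X <- cbind(v, 2 * v)                 # exactly rank one
  y <- v + rnorm(12, sd = 1e-8)
  expect_warning(fit <- fit_plsda(X, cbind(y), 2), "stopped early")
  expect_equal(fit$n_latent, 1L)
})

test_that("VIP scores satisfy the sum-of-squares identity and rank planted bands", {
  set.seed(13)
  for (i in 1:5) {
    n <- 60; p <- 5 + i
    X <- matrix(rnorm(n * p), n, p)
    Y <- one_hot(sample(c("a", "b"), n, replace = TRUE), c("a", "b"))
    fit <- fit_plsda(X, Y, 3)
    v <- vip(fit)
    expect_true(all(v >= 0))
    expect_equal(sum(v^2), p, tolerance = 1e-8)
  }
  # planted single informative band attains the maximal VIP
  dat <- planted_band_data(n = 120, p = 20, n_informative = 1, seed = 3,
                           strength = 3)
  fit <- fit_plsda(dat$X, one_hot(dat$labels, c("a", "b", "c")), 2)
  expect_equal(which.max(vip(fit)), dat$informative)
})

test_that("MCCV latent-variable choice finds a planted latent rank", {
  ok <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 60; p <- 12
    T2 <- matrix(rnorm(n * 2), n, 2)
    X <- T2 %*% matrix(rnorm(2 * p), 2, p) + matrix(rnorm(n * p, sd = 0.02), n, p)
    Y <- T2 %*% matrix(rnorm(2 * 3), 2, 3) + matrix(rnorm(n * 3, sd = 0.1), n, 3)
    ok <- ok + (choose_n_latent(X, Y, max_lv = 6, runs = 60, seed = s) == 2)
  }
  expect_gte(ok, 9)
  # single candidate and determinism
  set.seed(20)
  X <- matrix(rnorm(200), 20, 10); Y <- cbind(rnorm(20))
  expect_equal(choose_n_latent(X, Y, max_lv = 1, runs = 20, seed = 1)[1], 1L)
  a <- choose_n_latent(X, Y, max_lv = 4, runs = 50, seed = 5)
  b <- choose_n_latent(X, Y, max_lv = 4, runs = 50, seed = 5)
  expect_identical(a, b)
})
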
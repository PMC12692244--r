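test_that("snv standardises with the sample sd", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  x <- rnorm(50)
  z <- snv(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
  expect_error(snv(rep(2, 10), id = "scan7"), "scan7")
  expect_error(snv(1), "length")
})

test_that("snv is affine invariant for positive gain", {
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(30)
    a <- runif(1, 0.1, 5); b <- rnorm(1, 0, 10)
    expect_equal(snv(a * x + b), snv(x), tolerance = 1e-9)
  }
})

test_that("snv_table transforms rows, keeps labels, and is idempotent", {
  tab <- simulate_dataset(tiny_sim_config(n_eggs = 3L, n_bands = 25L))
  out <- snv_table(tab)
  expect_identical(out$scan_id, tab$scan_id)
  expect_identical(out$variety, tab$variety)
  expect_equal(dim(out$reflectance), dim(tab$reflectance))
  expect_true(all(abs(rowMeans(out$reflectance)) < 1e-10))
  sds <- apply(out$reflectance, 1, stats::sd)
  expect_true(all(abs(sds - 1) < 1e-10))
  twice <- snv_table(out)
  expect_equal(twice$reflectance, out$reflectance, tolerance = 1e-10)

  bad <- tab
  bad$reflectance[3, ] <- 5
  expect_error(snv_table(bad), tab$scan_id[3], fixed = TRUE)
})
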
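test_that("exponential retention schedule meets its boundary conditions", {
  sc <- edf_counts(273, 100, 2)
  expect_equal(sc[1], 273L)
  expect_equal(sc[100], 2L)
  expect_true(all(diff(sc) <= 0))

  # property over random valid inputs
  withr::with_seed(99, {
    for (i in 1:50) {
      N <- sample(10:500, 1)
      R <- sample(3:150, 1)
      fl <- sample(2:min(5, N - 1), 1)
      sc <- edf_counts(N, R, fl)
      expect_equal(sc[1], as.integer(N))
      expect_equal(sc[R], as.integer(fl))
      expect_true(all(diff(sc) <= 0))
      expect_true(all(sc >= fl))
    }
  })
  expect_error(edf_counts(5, 10, 5), "exceed")

  # closed form: counts follow round(N a exp(-k r)) for the boundary a, k
  N <- 10; R <- 3; fl <- 2
  k <- log(N / fl) / (R - 1)
  expect_equal(edf_counts(N, R, fl)[2], round(N * exp(k) * exp(-k * 2)))
})

test_that("power-law schedule variant is exposed but increasing", {
  sc <- edf_counts(100, 10, 2, schedule = "power", alpha = 2)
  expect_true(all(diff(sc) >= 0))
  expect_error(edf_counts(100, 10, 2, schedule = "power"), "alpha")
})

test_that("cars runs respect the schedule, are seeded, and recover planted bands", {
  dat <- planted_band_data(seed = 42)
  cfg <- cars_config(R = 40, lv_mccv_runs = 50, max_lv = 6, seed = 1)
  suppressWarnings({
    res <- cars_run(dat$X, dat$labels, cfg)
    res2 <- cars_run(dat$X, dat$labels, cfg)
  })
  expect_identical(res$selected, res2$selected)
  expect_identical(res$rmsecv, res2$rmsecv)
  sched <- edf_counts(60, 40, 2)
  expect_true(all(res$n_retained <= sched))
  expect_equal(res$selected, res$sets[[res$best_run]])
  # parsimony choice: within tolerance of the minimum, and no within-tolerance
  # run has a smaller retained set
  expect_lte(res$rmsecv[res$best_run], min(res$rmsecv) * 1.01)
  ok <- res$rmsecv <= min(res$rmsecv) * 1.01
  expect_equal(length(res$selected), min(res$n_retained[ok]))
  expect_gte(length(intersect(res$selected, dat$informative)), 6)
})

test_that("cars recovers planted bands in most seeds and beats the full set", {
  hits <- logical(5)
  improves <- logical(5)
  for (s in 1:5) {
    dat <- planted_band_data(seed = 100 + s)
    cfg <- cars_config(R = 40, lv_mccv_runs = 50, max_lv = 6, seed = s)
    suppressWarnings(res <- cars_run(dat$X, dat$labels, cfg))
    hits[s] <- length(intersect(res$selected, dat$informative)) >= 6
    Y <- one_hot(dat$labels, sort(unique(dat$labels)))
    full <- withr::with_seed(s, spectramt:::plsda_rmsecv(dat$X, Y, res$n_latent, 5))
    improves[s] <- res$rmsecv[res$best_run] <= full
  }
  expect_gte(sum(hits), 4)
  expect_gte(sum(improves), 4)
})

test_that("cars selections are equivariant to band permutation", {
  dat <- planted_band_data(n = 120, p = 30, n_informative = 5, seed = 7,
                           strength = 2.5)
  cfg <- cars_config(R = 25, lv_mccv_runs = 40, max_lv = 5, seed = 3)
  suppressWarnings(res <- cars_run(dat$X, dat$labels, cfg))
  perm <- withr::with_seed(1, sample(30))
  suppressWarnings(resp <- cars_run(dat$X[, perm], dat$labels, cfg))
  expect_setequal(perm[resp$selected], res$selected)
})

test_that("two-stage selection merges per-day picks and re-filters to a subset", {
  cfg <- tiny_sim_config(n_eggs = 10L, scans = 1L, n_bands = 40L, seed = 21)
  tab <- snv_table(simulate_dataset(cfg))
  ccfg <- cars_config(R = 25, lv_mccv_runs = 40, max_lv = 6, seed = 5)
  suppressWarnings(sel <- two_stage_select(tab, ccfg))
  expect_named(sel$per_day, as.character(sort(unique(tab$day))))
  expect_true(all(sel$final %in% sel$union))
  expect_setequal(sel$union,
                  unique(unlist(lapply(sel$per_day, `[[`, "selected"))))
  expect_length(sel$vip, length(sel$final))
  expect_equal(sum(sel$vip^2), length(sel$final), tolerance = 1e-8)
  # the final cross-temporal set intersects the generator's informative bands
  expect_gt(length(intersect(sel$final, informative_bands(cfg))), 0)
})
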
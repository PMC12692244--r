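test_that("default configuration matches the study design", {
  cfg <- default_egg_sim_config()
  expect_length(cfg$peaks, 7)
  expect_length(cfg$varieties, 3)
  expect_equal(cfg$days, c(1L, 20L, 40L))
  expect_equal(length(cfg$grid), 273)
  expect_equal(range(cfg$grid), c(1000, 2500))
  decays <- lapply(cfg$peaks, `[[`, "decay_per_day")
  expect_true(all(unlist(decays) >= 0 & unlist(decays) < 1))
  centers <- vapply(cfg$peaks, `[[`, 0, "center_nm")
  # water and lipid bands decay with storage; proteins/carbohydrates do not
  min_decay <- vapply(decays, min, 0)
  expect_true(all(min_decay[centers %in% c(1450, 1720, 1780, 1950)] > 0))
  # variety profile: 1 strongest at 1200, 2 in the lipid region, 3 at 2100-2300
  m <- do.call(rbind, lapply(cfg$peaks, `[[`, "variety_multipliers"))
  expect_equal(which.max(m[centers == 1200, ]), 1L)
  expect_equal(which.max(m[centers == 1780, ]), 2L)
  expect_equal(which.max(m[centers == 2280, ]), 3L)
})

test_that("clean spectra are deterministic and drift monotonically", {
  cfg <- tiny_sim_config(artifact_free = TRUE)
  s1 <- clean_spectrum("multigrain", 20, cfg)
  s2 <- clean_spectrum("multigrain", 20, cfg)
  expect_identical(s1, s2)
  expect_true(all(s1 > 0 & s1 <= 1))

  # fitted water-band depth decreases with day (decay_per_day > 0)
  water_idx <- which.min(abs(cfg$grid - 1450))
  depth_at <- function(day) cfg$r_base - clean_spectrum("selenium", day, cfg)[water_idx]
  depths <- vapply(c(1, 10, 20, 40), depth_at, 0)
  expect_true(all(diff(depths) < 0))

  # zero-depth configuration gives a flat baseline
  flat <- cfg
  for (i in seq_along(flat$peaks)) flat$peaks[[i]]$base_depth <- 1e-9
  expect_equal(clean_spectrum("lutein", 1, flat),
               rep(flat$r_base, length(flat$grid)), tolerance = 1e-6)
})

test_that("artifacts are seeded, additive-multiplicative, and vanish at zero sd", {
  cfg <- tiny_sim_config()
  s <- clean_spectrum("selenium", 1, cfg)
  zero <- cfg
  zero$scatter_gain_sd <- 0; zero$baseline_offset_sd <- 0
  zero$baseline_slope_sd <- 0; zero$noise_sd <- 0
  set.seed(1)
  expect_equal(apply_artifacts(s, zero), s)
  set.seed(9)
  a1 <- apply_artifacts(s, cfg)
  set.seed(9)
  a2 <- apply_artifacts(s, cfg)
  expect_identical(a1, a2)
  expect_gt(max(abs(a1 - s)), 0)
})

test_that("SNV removes the gain/offset artifact family exactly", {
  cfg <- tiny_sim_config()
  cfg$baseline_slope_sd <- 0
  cfg$noise_sd <- 0
  s <- clean_spectrum("multigrain", 20, cfg)
  set.seed(2)
  a <- apply_artifacts(s, cfg)
  b <- apply_artifacts(s, cfg)
  expect_gt(max(abs(a - b)), 1e-6)       # distorted copies differ...
  expect_equal(snv(a), snv(b), tolerance = 1e-9)  # ...but agree after SNV
  expect_equal(snv(a), snv(s), tolerance = 1e-9)
})

test_that("replicate scans are stable: CV stays below the 2% ceiling", {
  cfg <- tiny_sim_config(n_eggs = 5L, scans = 3L, n_bands = 80L, seed = 77)
  tab <- simulate_dataset(cfg)
  key <- paste(tab$egg_id, tab$day)
  cvs <- unlist(lapply(split(seq_along(key), key), function(idx) {
    average_replicates(tab$reflectance[idx, , drop = FALSE],
                       warn_above = Inf)$cv
  }))
  expect_lt(stats::median(cvs, na.rm = TRUE), 0.02)
  expect_lt(stats::quantile(cvs, 0.99, na.rm = TRUE), 0.05)
})

test_that("simulated datasets have the balanced repeated-measures shape", {
  cfg <- tiny_sim_config(n_eggs = 4L, scans = 3L)
  tab <- simulate_dataset(cfg)
  expect_s3_class(tab, "spectra_table")
  expect_equal(nrow(tab$reflectance), 3 * 4 * 3 * 3)
  counts <- table(tab$variety, tab$day)
  expect_true(all(counts == 4 * 3))
  # egg identity persists across days
  per_egg_days <- tapply(tab$day, tab$egg_id, function(d) length(unique(d)))
  expect_true(all(per_egg_days == 3))
  expect_true(all(is.finite(tab$reflectance)))
})

test_that("default design sizes: 300 eggs, 900 egg-days, 2700 scans", {
  cfg <- default_egg_sim_config()
  n_eggs <- length(cfg$varieties) * cfg$n_eggs_per_variety
  expect_equal(n_eggs, 300)
  expect_equal(n_eggs * length(cfg$days), 900)
  expect_equal(n_eggs * length(cfg$days) * cfg$scans_per_egg, 2700)
})

test_that("same seed reproduces the table; adding eggs keeps existing ones", {
  cfg <- tiny_sim_config(n_eggs = 3L, scans = 2L)
  t1 <- simulate_dataset(cfg)
  t2 <- simulate_dataset(cfg)
  expect_identical(t1$reflectance, t2$reflectance)
  expect_identical(t1$scan_id, t2$scan_id)

  bigger <- cfg
  bigger$n_eggs_per_variety <- 5L
  t3 <- simulate_dataset(bigger)
  shared <- match(t1$scan_id, t3$scan_id)
  expect_false(anyNA(shared))
  expect_equal(t3$reflectance[shared, ], t1$reflectance)
})

test_that("variety separability exceeds egg-level spread on noise-free spectra", {
  cfg <- tiny_sim_config(artifact_free = TRUE)
  for (d in cfg$days) {
    centr <- sapply(cfg$varieties, function(v) clean_spectrum(v, d, cfg))
    between <- mean(dist(t(centr)))
    expect_gt(between, 0)
  }
  # with zero artifact sds all scans of a variety-day cell coincide,
  # so within-variety distance is 0 < between-variety distance
  tab <- simulate_dataset(tiny_sim_config(artifact_free = TRUE, n_eggs = 2L))
  d1 <- tab$reflectance[tab$day == 1, ]
  v <- tab$variety[tab$day == 1]
  within <- mean(dist(d1[v == v[1], ]))
  between <- mean(dist(d1))
  expect_lt(within, between)
})

test_that("informative band export brackets every peak centre", {
  cfg <- tiny_sim_config()
  idx <- informative_bands(cfg)
  expect_true(all(idx >= 1 & idx <= length(cfg$grid)))
  for (p in cfg$peaks) {
    expect_true(any(abs(cfg$grid[idx] - p$center_nm) < 2 * p$width_nm))
  }
  tab <- simulate_dataset(cfg)
  expect_identical(attr(tab, "informative_bands"), idx)
})

test_that("frame triplets invert through calibration", {
  cfg <- tiny_sim_config(artifact_free = TRUE)
  s <- clean_spectrum("selenium", 1, cfg)
  tri <- simulate_frame_triplet(s, 6, 5, cfg)
  expect_equal(dim(tri$raw), c(6, 5, length(s)))
  cal <- calibrate(tri$raw, tri$dark, tri$white)
  for (i in 1:6) for (j in 1:5) {
    expect_equal(unname(cal[i, j, ]), s, tolerance = 1e-12)
  }
  # all-ones spectrum makes raw equal white
  tri1 <- simulate_frame_triplet(rep(1, length(s)), 2, 2, cfg)
  expect_equal(tri1$raw, tri1$white, tolerance = 1e-12)
  # ROI mean over identical pixels recovers the generating spectrum
  expect_equal(roi_mean_spectrum(cal, roi_spec(1, 1, 6, 5)), s, tolerance = 1e-12)
})
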
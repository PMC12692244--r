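row_norm <- function(m) m / rowSums(m)

# small simulation configs used across the suite

tiny_sim_config <- function(seed = 7L, n_eggs = 6L, scans = 2L,
                            n_bands = 60L, artifact_free = FALSE) {
  peaks <- list(
    peak_spec(1200, 40, 0.10, c(1.3, 1.0, 1.1)),
    peak_spec(1450, 35, 0.30, c(1.0, 1.0, 1.0), decay_per_day = 0.012,
              shift_per_day_nm = 0.08),
    peak_spec(1750, 25, 0.12, c(0.9, 1.3, 1.0), decay_per_day = 0.008),
    peak_spec(2200, 30, 0.12, c(1.0, 1.0, 1.3))
  )
  cfg <- sim_config(grid = wavelength_grid(1000, 2500, n_bands), peaks = peaks,
                    n_eggs_per_variety = n_eggs, scans_per_egg = scans,
                    egg_depth_sd = 0.05, seed = seed)
  if (artifact_free) {
    cfg$egg_depth_sd <- 0
    cfg$egg_shift_sd <- 0
    cfg$scatter_gain_sd <- 0
    cfg$baseline_offset_sd <- 0
    cfg$baseline_slope_sd <- 0
    cfg$noise_sd <- 0
  }
  cfg
}

tiny_model_config <- function(...) {
  model_config(n_bands_in = 7L, conv_channels = c(4L, 6L), conv_kernel = 3L,
               se_reduction = 4L, d_model = 8L, n_heads = 2L, n_layers = 2L,
               ffn_dim = 12L, dropout = 0.2, ...)
}

# planted-band classification data: informative columns carry class shifts
planted_band_data <- function(n = 180, p = 60, n_informative = 8, seed = 1,
                              strength = 1.5) {
  withr::with_seed(seed, {
    informative <- sort(sample(p, n_informative))
    cl <- sample(c("a", "b", "c"), n, replace = TRUE)
    X <- matrix(rnorm(n * p), n, p)
    shift <- rbind(seq(1, 2, length.out = n_informative),
                   seq(2, 0.5, length.out = n_informative),
                   strength * rep_len(c(1, -1), n_informative))
    X[, informative] <- X[, informative] + shift[match(cl, c("a", "b", "c")), ]
    list(X = X, labels = cl, informative = informative)
  })
}

# independent brute-force confusion metrics oracle
brute_metrics <- function(truth, pred, classes) {
  acc <- mean(pred == truth)
  per <- t(vapply(classes, function(k) {
    tp <- sum(truth == k & pred == k)
    fp <- sum(truth != k & pred == k)
    fn <- sum(truth == k & pred != k)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(prec, rec, f1)
  }, numeric(3)))
  list(accuracy = acc, precision = per[, 1], recall = per[, 2], f1 = per[, 3])
}

# central finite-difference gradient check against the analytic gradient
fd_check <- function(net, X, y1, y2, alpha = 0.5, beta = 0.5, blocks = NULL,
                     per_block = 4, h = 1e-5) {
  cfg <- spectramt:::cpp_cfg(net$config, net$variant)
  g <- spectramt:::cpp_loss_grad(cfg, net$params, X, y1, y2, alpha, beta)
  lay <- net$layout
  if (!is.null(blocks)) lay <- lay[grepl(blocks, lay$name), , drop = FALSE]
  idx <- unlist(lapply(seq_len(nrow(lay)), function(i) {
    ii <- lay$offset[i]:(lay$offset[i] + lay$size[i] - 1)
    ii[seq(1, length(ii), length.out = min(per_block, length(ii)))]
  }))
  worst <- 0
  for (j in idx) {
    p <- net$params
    p[j] <- p[j] + h
    lp <- spectramt:::cpp_loss_grad(cfg, p, X, y1, y2, alpha, beta)$loss
    p[j] <- p[j] - 2 * h
    lm <- spectramt:::cpp_loss_grad(cfg, p, X, y1, y2, alpha, beta)$loss
    fd <- (lp - lm) / (2 * h)
    err <- abs(fd - g$grad[j])
    rel <- err / max(abs(fd), abs(g$grad[j]), 1e-4)
    worst <- max(worst, min(rel, err))
  }
  worst
}
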
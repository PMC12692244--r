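#' Exponentially decreasing retention schedule
#'
#' Number of bands forcibly retained at each CARS sampling run. The default
#' schedule is the two-parameter exponential decay
#' `N_iter(r) = round(N_total * a * exp(-k * r))` with `a`, `k` fixed by the
#' boundary conditions `N_iter(1) = N_total` and `N_iter(R) = floor`; the
#' sequence is forced non-increasing after rounding. A power-law alternative
#' `N_iter(r) = round(N_total * (r / R)^alpha)` is available for comparison
#' via `schedule = "power"` (it *grows* with `r` and is not used by the
#' selection pipeline).
#'
#' @param N_total initial band count, `> floor`.
#' @param R number of sampling runs, >= 2.
#' @param floor minimum retained count (default 2).
#' @param schedule `"exp"` (default) or `"power"`.
#' @param alpha exponent for the power-law schedule (required when
#'   `schedule = "power"`).
#' @return Integer vector of length `R`, the per-run retained counts.
#' @export
edf_counts <- function(N_total, R, floor = 2L, schedule = c("exp", "power"),
                       alpha = NULL) {
  schedule <- match.arg(schedule)
  if (R < 2) stop("R must be >= 2")
  if (floor < 2) stop("floor must be >= 2")
  if (N_total <= floor) stop("N_total must exceed floor")
  if (schedule == "power") {
    if (is.null(alpha)) stop("alpha must be supplied for the power schedule")
    return(as.integer(round(N_total * ((1:R) / R)^alpha)))
  }
  k <- log(N_total / floor) / (R - 1)
  a <- exp(k)
  counts <- round(N_total * a * exp(-k * (1:R)))
  counts[1] <- N_total
  counts[R] <- floor
  counts <- pmax(counts, floor)
  as.integer(cummin(counts))
}

#' CARS configuration
#'
#' @param R number of Monte-Carlo sampling runs (default 100).
#' @param mc_fraction per-run calibration subsample fraction (default 0.8).
#' @param cv_folds folds of the per-run RMSECV (default 5).
#' @param lv_mccv_runs Monte-Carlo splits used to pick the latent-variable
#'   count (default 1000).
#' @param lv_mccv_fraction training fraction of those splits (default 0.8).
#' @param max_lv largest candidate latent-variable count (default 10).
#' @param n_latent fixed latent-variable count; `NULL` (default) selects it
#'   by MCCV via [choose_n_latent()].
#' @param floor minimum retained band count (default 2).
#' @param schedule,alpha retention schedule, see [edf_counts()].
#' @param rmsecv_tolerance parsimony tolerance of the final choice: the
#'   smallest retained set whose RMSECV lies within this relative margin of
#'   the minimum wins (default 0.01); `0` gives the plain argmin.
#' @param seed RNG seed keying every stochastic step.
#' @return A list of class `cars_config`.
#' @export
cars_config <- function(R = 100L, mc_fraction = 0.8, cv_folds = 5L,
                        lv_mccv_runs = 1000L, lv_mccv_fraction = 0.8,
                        max_lv = 10L, n_latent = NULL, floor = 2L,
                        schedule = "exp", alpha = NULL,
                        rmsecv_tolerance = 0.01, seed = 42L) {
  if (mc_fraction <= 0 || mc_fraction >= 1) stop("mc_fraction must lie in (0, 1)")
  if (lv_mccv_fraction <= 0 || lv_mccv_fraction >= 1) {
    stop("lv_mccv_fraction must lie in (0, 1)")
  }
  if (R < 2) stop("R must be >= 2")
  structure(list(R = as.integer(R), mc_fraction = mc_fraction,
                 cv_folds = as.integer(cv_folds),
                 lv_mccv_runs = as.integer(lv_mccv_runs),
                 lv_mccv_fraction = lv_mccv_fraction,
                 max_lv = as.integer(max_lv), n_latent = n_latent,
                 floor = as.integer(floor), schedule = schedule, alpha = alpha,
                 rmsecv_tolerance = rmsecv_tolerance,
                 seed = as.integer(seed)),
            class = "cars_config")
}

# k-fold RMSECV of PLS-DA on a fixed band subset
plsda_rmsecv <- function(X, Y, n_latent, folds) {
  n <- nrow(X)
  assign_fold <- sample(rep(seq_len(folds), length.out = n))
  sse <- 0
  for (f in seq_len(folds)) {
    tr <- which(assign_fold != f)
    te <- which(assign_fold == f)
    A <- max(1L, min(n_latent, length(tr) - 1L, ncol(X)))
    fit <- suppressWarnings(
      fit_plsda(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], A))
    Yhat <- predict(fit, X[te, , drop = FALSE])
    sse <- sse + sum((Yhat - Y[te, , drop = FALSE])^2)
  }
  sqrt(sse / length(Y))
}

#' Competitive adaptive reweighted sampling
#'
#' Iterative wavelength selection for PLS-DA. At run `r`, a PLS-DA model is
#' fitted to a random `mc_fraction` subsample restricted to the currently
#' retained bands; each band's importance is the mean absolute regression
#' coefficient across indicator columns. Enforced selection keeps the top
#' `N_iter(r)` bands (schedule from [edf_counts()]; importance ties break to
#' the lower band index), then adaptive reweighted sampling draws bands with
#' replacement with probability proportional to importance, the unique draws
#' surviving (so the retained count never exceeds `N_iter(r)` and low-weight
#' bands tend to drop out). Each run's retained set is scored by k-fold
#' RMSECV over all samples; the final selection is the smallest retained set
#' whose RMSECV lies within `rmsecv_tolerance` of the minimum (the plain
#' minimal-RMSECV run with tolerance 0).
#'
#' @param X SNV-preprocessed spectra (samples x bands).
#' @param labels class labels (one per row of `X`).
#' @param config a [cars_config()].
#' @return Object of class `cars_result`: per-run retained index sets,
#'   per-run retained counts and RMSECV, `best_run`, `selected` band
#'   indices, the latent-variable count used, and the seed.
#' @export
cars_run <- function(X, labels, config = cars_config()) {
  X <- as.matrix(X)
  classes <- sort(unique(as.character(labels)))
  if (min(table(labels)) < 2) stop("need at least 2 samples per class")
  p <- ncol(X)
  if (p <= config$floor) stop("need more bands than the schedule floor")
  Y <- one_hot(as.character(labels), classes)
  with_seed(config$seed, {
    n_latent <- config$n_latent
    if (is.null(n_latent)) {
      n_latent <- choose_n_latent(X, Y, config$max_lv,
                                  runs = config$lv_mccv_runs,
                                  fraction = config$lv_mccv_fraction)
    }
    sched <- edf_counts(p, config$R, config$floor,
                        schedule = config$schedule, alpha = config$alpha)
    n <- nrow(X)
    n_sub <- max(2L, floor(config$mc_fraction * n))
    retained <- seq_len(p)
    sets <- vector("list", config$R)
    rmsecv <- numeric(config$R)
    clamped <- FALSE
    for (r in seq_len(config$R)) {
      sub <- sample.int(n, n_sub)
      A <- min(n_latent, length(retained), n_sub - 1L)
      if (A < n_latent) clamped <- TRUE
      fit <- suppressWarnings(
        fit_plsda(X[sub, retained, drop = FALSE], Y[sub, , drop = FALSE], max(1L, A)))
      w <- rowMeans(abs(fit$B))
      keep_n <- min(sched[r], length(retained))
      ord <- order(-w, seq_along(w))          # ties -> lower band index
      kept_bands <- retained[ord[seq_len(keep_n)]]
      w_kept <- w[ord[seq_len(keep_n)]]
      if (sum(w_kept) <= 0) w_kept <- rep(1, length(w_kept))
      # adaptive reweighted sampling: p draws with replacement so that the
      # realised unique count tracks the retention schedule and only
      # low-weight bands fail to survive
      draw <- sample.int(keep_n, size = p, replace = TRUE,
                         prob = w_kept / sum(w_kept))
      retained <- sort(unique(kept_bands[draw]))
      if (length(retained) < 2L) {            # guard: PLS needs >= 2 columns
        retained <- sort(kept_bands[seq_len(min(2L, keep_n))])
      }
      sets[[r]] <- retained
      Acv <- max(1L, min(n_latent, length(retained)))
      rmsecv[r] <- plsda_rmsecv(X[, retained, drop = FALSE], Y, Acv,
                                config$cv_folds)
    }
    if (clamped) {
      warning("latent-variable count clamped where retained sets were small")
    }
    # parsimony: smallest retained set within tolerance of the minimal RMSECV
    tol <- if (is.null(config$rmsecv_tolerance)) 0 else config$rmsecv_tolerance
    ok <- which(rmsecv <= min(rmsecv) * (1 + tol))
    best <- ok[which.min(lengths(sets)[ok])]
    structure(list(sets = sets, n_retained = lengths(sets), rmsecv = rmsecv,
                   best_run = best, selected = sets[[best]],
                   schedule = sched, n_latent = n_latent, classes = classes,
                   seed = config$seed),
              class = "cars_result")
  })
}

#' @export
print.cars_result <- function(x, ...) {
  cat(sprintf("<cars_result> %d runs, best run %d (RMSECV %.4f), %d bands selected\n",
              length(x$sets), x$best_run, x$rmsecv[x$best_run],
              length(x$selected)))
  invisible(x)
}

#' Two-stage cross-temporal band selection
#'
#' Stage 1 runs CARS independently within each storage day (variety as the
#' response). Stage 2 unions the per-day selections and re-filters them with
#' a second CARS pass on the pooled all-day data, by default against the
#' joint variety-by-day labels so the final set must carry both tasks.
#' VIP scores of a PLS-DA model fitted on the pooled data restricted to the
#' final set quantify each surviving band's contribution.
#'
#' @param table an SNV-preprocessed [spectra_table()].
#' @param config a [cars_config()]; per-stage seeds derive from its seed.
#' @param stage2_task response of the re-filtering pass: `"joint"` (default)
#'   variety x day, `"variety"`, or `"day"`.
#' @return List of class `two_stage_result`: `per_day` (named list of
#'   `cars_result`), `union`, `final` (band indices into the full grid),
#'   `wavelengths` of the final set, `vip` scores, and the stage-2
#'   `cars_result` (`refilter`).
#' @export
two_stage_select <- function(table, config = cars_config(),
                             stage2_task = c("joint", "variety", "day")) {
  stopifnot(inherits(table, "spectra_table"))
  stage2_task <- match.arg(stage2_task)
  days <- sort(unique(table$day))
  if (length(days) < 2) stop("need at least two storage-day stages")
  per_day <- list()
  for (i in seq_along(days)) {
    d <- days[i]
    idx <- table$day == d
    cfg_d <- config
    cfg_d$seed <- config$seed + i
    per_day[[as.character(d)]] <-
      cars_run(table$reflectance[idx, , drop = FALSE], table$variety[idx], cfg_d)
  }
  union_idx <- sort(unique(unlist(lapply(per_day, `[[`, "selected"))))
  labels <- switch(stage2_task,
                   joint = paste(table$variety, table$day, sep = "@"),
                   variety = table$variety,
                   day = as.character(table$day))
  cfg2 <- config
  cfg2$seed <- config$seed + length(days) + 1L
  refilter <- cars_run(table$reflectance[, union_idx, drop = FALSE], labels, cfg2)
  final <- union_idx[refilter$selected]
  Y <- one_hot(labels, sort(unique(labels)))
  A <- max(1L, min(refilter$n_latent, length(final)))
  fit <- suppressWarnings(
    fit_plsda(table$reflectance[, final, drop = FALSE], Y, A))
  structure(list(per_day = per_day, union = union_idx, final = final,
                 wavelengths = table$wavelengths[final],
                 vip = vip(fit), refilter = refilter,
                 stage2_task = stage2_task),
            class = "two_stage_result")
}

#' @export
print.two_stage_result <- function(x, ...) {
  cat(sprintf("<two_stage_result> %d final bands (union of %d), task '%s'\n",
              length(x$final), length(x$union), x$stage2_task))
  cat("  wavelengths (nm): ", paste(round(x$wavelengths), collapse = ", "), "\n")
  invisible(x)
}
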
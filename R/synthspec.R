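#' Wavelength grid
#'
#' @param from,to range in nm (inclusive).
#' @param n_bands number of equally spaced bands.
#' @return Strictly increasing numeric vector of band centres.
#' @export
wavelength_grid <- function(from = 1000, to = 2500, n_bands = 273) {
  if (n_bands < 2) stop("n_bands must be >= 2")
  if (to <= from) stop("'to' must exceed 'from'")
  seq(from, to, length.out = n_bands)
}

#' Absorption peak specification
#'
#' One Gaussian absorption feature of the clean-spectrum model. Depth is the
#' dimensionless absorbance dip it carves out of the flat baseline; the
#' variety multipliers scale it per variety and `decay_per_day` erodes it
#' geometrically with storage day, emulating moisture loss and lipid
#' oxidation.
#'
#' @param center_nm peak centre (nm).
#' @param width_nm Gaussian sigma (nm), > 0.
#' @param base_depth depth in (0, 1) before variety/day scaling.
#' @param variety_multipliers positive factor per variety.
#' @param decay_per_day fractional depth loss per storage day, in \[0, 1);
#'   either one shared rate or one rate per variety (compositional
#'   differences make some varieties' bands fade faster).
#' @param shift_per_day_nm centre displacement per storage day (nm).
#' @param variety_shift_nm optional per-variety centre offset (nm); defaults
#'   to zero for every variety. An amplitude-free shape cue.
#' @param variety_shift_per_day_nm optional per-variety extra centre drift
#'   per storage day (nm/day): varieties whose composition evolves at
#'   different rates drift apart in band position as storage proceeds.
#' @return A list of class `peak_spec`.
#' @export
peak_spec <- function(center_nm, width_nm, base_depth, variety_multipliers,
                      decay_per_day = 0, shift_per_day_nm = 0,
                      variety_shift_nm = NULL,
                      variety_shift_per_day_nm = NULL) {
  if (width_nm <= 0) stop("width_nm must be > 0")
  if (base_depth <= 0 || base_depth >= 1) stop("base_depth must lie in (0, 1)")
  if (any(variety_multipliers <= 0)) stop("variety_multipliers must be positive")
  if (base_depth * max(variety_multipliers) >= 1) {
    stop("base_depth x max multiplier must stay below 1")
  }
  if (!(length(decay_per_day) %in% c(1L, length(variety_multipliers)))) {
    stop("decay_per_day must be a scalar or one rate per variety")
  }
  if (any(decay_per_day < 0 | decay_per_day >= 1)) {
    stop("decay_per_day must lie in [0, 1)")
  }
  if (is.null(variety_shift_nm)) variety_shift_nm <- rep(0, length(variety_multipliers))
  if (is.null(variety_shift_per_day_nm)) {
    variety_shift_per_day_nm <- rep(0, length(variety_multipliers))
  }
  if (length(variety_shift_nm) != length(variety_multipliers) ||
      length(variety_shift_per_day_nm) != length(variety_multipliers)) {
    stop("variety shift vectors must match variety_multipliers in length")
  }
  structure(list(center_nm = center_nm, width_nm = width_nm,
                 base_depth = base_depth,
                 variety_multipliers = variety_multipliers,
                 decay_per_day = decay_per_day,
                 shift_per_day_nm = shift_per_day_nm,
                 variety_shift_nm = variety_shift_nm,
                 variety_shift_per_day_nm = variety_shift_per_day_nm),
            class = "peak_spec")
}

#' Simulation configuration
#'
#' @param grid wavelength grid from [wavelength_grid()].
#' @param peaks list of [peak_spec()] objects; each must carry one multiplier
#'   per variety.
#' @param varieties character vector of distinct variety labels.
#' @param days integer vector of storage days sampled.
#' @param n_eggs_per_variety eggs simulated per variety.
#' @param scans_per_egg replicate scans per egg per day.
#' @param r_base flat baseline reflectance the peaks dip below.
#' @param egg_depth_sd log-scale sd of per-egg, per-peak depth multipliers
#'   (biological egg-to-egg variability, constant across days).
#' @param egg_shift_sd sd (nm) of per-egg, per-peak centre jitter, constant
#'   across days.
#' @param scatter_gain_sd log-scale sd of the multiplicative scatter gain.
#' @param baseline_offset_sd sd of the additive baseline offset.
#' @param baseline_slope_sd sd of the additive linear baseline tilt.
#' @param noise_sd per-band white-noise sd.
#' @param dark_level,white_level detector intensity levels used when frame
#'   triplets are simulated.
#' @param frame_noise_sd per-pixel intensity noise of simulated frames.
#' @param seed RNG seed for [simulate_dataset()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(grid = wavelength_grid(),
                       peaks,
                       varieties = c("selenium", "multigrain", "lutein"),
                       days = c(1L, 20L, 40L),
                       n_eggs_per_variety = 100L,
                       scans_per_egg = 3L,
                       r_base = 0.8,
                       egg_depth_sd = 0.10,
                       egg_shift_sd = 0,
                       scatter_gain_sd = 0.08,
                       baseline_offset_sd = 0.04,
                       baseline_slope_sd = 0.015,
                       noise_sd = 0.003,
                       dark_level = 100,
                       white_level = 4000,
                       frame_noise_sd = 0,
                       seed = 42L) {
  check_grid(grid)
  if (anyDuplicated(varieties)) stop("variety labels must be distinct")
  if (n_eggs_per_variety < 1) stop("n_eggs_per_variety must be >= 1")
  if (scans_per_egg < 1) stop("scans_per_egg must be >= 1")
  sds <- c(egg_depth_sd, egg_shift_sd, scatter_gain_sd, baseline_offset_sd,
           baseline_slope_sd, noise_sd, frame_noise_sd)
  if (any(sds < 0)) stop("all sd parameters must be >= 0")
  if (white_level <= dark_level) stop("white_level must exceed dark_level")
  for (p in peaks) {
    if (length(p$variety_multipliers) != length(varieties)) {
      stop("each peak needs one variety multiplier per variety")
    }
  }
  structure(list(grid = grid, peaks = peaks, varieties = varieties,
                 days = as.integer(days),
                 n_eggs_per_variety = as.integer(n_eggs_per_variety),
                 scans_per_egg = as.integer(scans_per_egg),
                 r_base = r_base, egg_depth_sd = egg_depth_sd,
                 egg_shift_sd = egg_shift_sd,
                 scatter_gain_sd = scatter_gain_sd,
                 baseline_offset_sd = baseline_offset_sd,
                 baseline_slope_sd = baseline_slope_sd,
                 noise_sd = noise_sd, dark_level = dark_level,
                 white_level = white_level, frame_noise_sd = frame_noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default stored-egg simulation configuration
#'
#' Seven Gaussian absorption features over a 273-band 1000-2500 nm grid:
#' an O-H second-overtone band near 1200 nm, the water bands near 1450 and
#' 1950 nm (depths decay with storage day as moisture is lost, centres drift
#' slightly), the lipid C-H doublet at 1720/1780 nm (decaying, strongest in
#' the multigrain variety), and protein/carbohydrate N-H / C-O bands at
#' 2180/2280 nm (strongest in the lutein variety). The selenium variety is
#' strongest at 1200 nm. Three varieties, storage days 1/20/40, 100 eggs per
#' variety, 3 replicate scans per egg per day.
#'
#' @return A [sim_config()].
#' @export
default_egg_sim_config <- function() {
  peaks <- list(
    peak_spec(1200, 40, 0.08, c(1.04, 1.00, 1.02), decay_per_day = 0),
    peak_spec(1450, 35, 0.30, c(1.00, 1.00, 1.00), decay_per_day = 0.012,
              shift_per_day_nm = 0.08, variety_shift_nm = c(-1, 0, 1),
              variety_shift_per_day_nm = c(-0.03, 0.01, 0.04)),
    peak_spec(1720, 20, 0.15, c(1.50, 0.75, 1.05),
              decay_per_day = c(0.055, 0.010, 0.022), shift_per_day_nm = 0.02),
    peak_spec(1780, 22, 0.13, c(0.75, 1.45, 1.02),
              decay_per_day = c(0.008, 0.050, 0.020), shift_per_day_nm = 0.02),
    peak_spec(1950, 45, 0.38, c(1.00, 1.00, 1.00), decay_per_day = 0.012,
              shift_per_day_nm = 0.10),
    peak_spec(2180, 30, 0.12, c(1.00, 1.00, 1.04), decay_per_day = 0,
              variety_shift_per_day_nm = c(-0.04, 0.00, 0.04)),
    peak_spec(2280, 28, 0.10, c(0.95, 1.00, 1.07), decay_per_day = 0,
              variety_shift_nm = c(2, -2, 0))
  )
  sim_config(peaks = peaks, egg_depth_sd = 0.12, egg_shift_sd = 2.2)
}

#' Clean (noise-free) reflectance spectrum
#'
#' Deterministic class-conditional spectrum: a flat baseline minus the sum of
#' Gaussian absorption dips, each scaled by its variety multiplier, optional
#' per-egg multiplier, and geometric day decay, with centres displaced by the
#' per-day drift. Values are clipped to (0, 1\].
#'
#' @param variety one of `config$varieties`.
#' @param day one of `config$days` (any nonnegative day is accepted).
#' @param config a [sim_config()].
#' @param egg_multipliers optional positive vector, one factor per peak
#'   (per-egg biological depth variability); default all ones.
#' @param egg_shifts optional vector of per-peak centre offsets in nm
#'   (per-egg biological position variability); default all zero.
#' @return Numeric reflectance vector over `config$grid`.
#' @export
clean_spectrum <- function(variety, day, config, egg_multipliers = NULL,
                           egg_shifts = NULL) {
  vi <- match(variety, config$varieties)
  if (is.na(vi)) stop("unknown variety: ", variety)
  if (day < 0) stop("day must be >= 0")
  if (is.null(egg_multipliers)) egg_multipliers <- rep(1, length(config$peaks))
  if (is.null(egg_shifts)) egg_shifts <- rep(0, length(config$peaks))
  lambda <- config$grid
  r <- rep(config$r_base, length(lambda))
  for (j in seq_along(config$peaks)) {
    p <- config$peaks[[j]]
    centre <- p$center_nm + p$variety_shift_nm[vi] + egg_shifts[j] +
      (p$shift_per_day_nm + p$variety_shift_per_day_nm[vi]) * day
    decay <- if (length(p$decay_per_day) > 1) p$decay_per_day[vi] else p$decay_per_day
    depth <- p$base_depth * p$variety_multipliers[vi] * egg_multipliers[j] *
      (1 - decay)^day
    r <- r - depth * exp(-(lambda - centre)^2 / (2 * p$width_nm^2))
  }
  pmin(pmax(r, 1e-6), 1)
}

#' Apply measurement artifacts to a clean spectrum
#'
#' Adds exactly the distortion family SNV is designed to remove: a log-normal
#' multiplicative scatter gain, an additive baseline offset, a linear baseline
#' tilt over the grid, and iid Gaussian noise. Draws are consumed from the
#' current RNG state. Gain/offset/tilt can be supplied via `params` so that
#' replicate scans of one placement share them (only the noise redraws, which
#' keeps the replicate coefficient of variation well below the 2% stability
#' ceiling, as an acquisition protocol demands).
#'
#' @param spectrum finite numeric vector over `config$grid`.
#' @param config a [sim_config()] supplying the artifact scales.
#' @param params optional list from [draw_artifact_params()]; drawn fresh
#'   when `NULL`.
#' @return Distorted spectrum of the same length.
#' @export
apply_artifacts <- function(spectrum, config, params = NULL) {
  stopifnot(all(is.finite(spectrum)))
  lambda <- config$grid
  if (is.null(params)) params <- draw_artifact_params(config)
  eps <- stats::rnorm(length(spectrum), 0, config$noise_sd)
  t <- (lambda - min(lambda)) / (max(lambda) - min(lambda))
  params$gain * spectrum + params$offset + params$slope * t + eps
}

#' @rdname apply_artifacts
#' @return `draw_artifact_params()` returns a list with `gain`, `offset`,
#'   `slope` drawn from the configured scales.
#' @export
draw_artifact_params <- function(config) {
  list(gain = exp(stats::rnorm(1, 0, config$scatter_gain_sd)),
       offset = stats::rnorm(1, 0, config$baseline_offset_sd),
       slope = stats::rnorm(1, 0, config$baseline_slope_sd))
}

# run code under a deterministic seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# per-egg substream seed keyed by (variety, egg) position, so enlarging the
# design in any direction leaves existing eggs' draws untouched
egg_seed <- function(base_seed, variety_index, egg_index) {
  as.integer((as.double(base_seed) * 100003 + variety_index * 1000099 +
                egg_index * 7919) %% 2147483647L)
}

#' Simulate a labelled synthetic dataset
#'
#' Balanced repeated-measures design: `n_eggs_per_variety` eggs per variety,
#' each egg re-scanned with `scans_per_egg` replicates at every storage day.
#' Egg identity (its peak-depth multipliers) is drawn once and carried across
#' days. Each egg consumes an independent RNG substream derived from
#' `config$seed`, so enlarging the design does not perturb existing eggs.
#'
#' @param config a [sim_config()].
#' @return A [spectra_table()] with
#'   `n_eggs_per_variety * length(varieties) * length(days) * scans_per_egg`
#'   records and an `informative_bands` attribute (see
#'   [informative_bands()]).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_bands <- length(config$grid)
  n_rows <- length(config$varieties) * config$n_eggs_per_variety *
    length(config$days) * config$scans_per_egg
  refl <- matrix(NA_real_, n_rows, n_bands)
  scan_id <- egg_id <- variety <- character(n_rows)
  day_lab <- integer(n_rows)
  row <- 0L
  for (vi in seq_along(config$varieties)) {
    v <- config$varieties[vi]
    for (e in seq_len(config$n_eggs_per_variety)) {
      eid <- sprintf("%s_egg%03d", v, e)
      with_seed(egg_seed(config$seed, vi, e), {
        mult <- exp(stats::rnorm(length(config$peaks), 0, config$egg_depth_sd))
        shifts <- stats::rnorm(length(config$peaks), 0, config$egg_shift_sd)
        for (d in config$days) {
          clean <- clean_spectrum(v, d, config, egg_multipliers = mult,
                                  egg_shifts = shifts)
          placement <- draw_artifact_params(config)  # shared by replicates
          for (s in seq_len(config$scans_per_egg)) {
            row <- row + 1L
            refl[row, ] <- apply_artifacts(clean, config, placement)
            scan_id[row] <- sprintf("%s_d%02d_s%d", eid, d, s)
            egg_id[row] <- eid
            variety[row] <- v
            day_lab[row] <- d
          }
        }
      })
    }
  }
  out <- spectra_table(scan_id, egg_id, variety, day_lab, refl, config$grid)
  attr(out, "informative_bands") <- informative_bands(config)
  out
}

#' Grid indices of informative bands
#'
#' Indices of grid points lying within `k_sigma` Gaussian widths of any peak
#' centre — the ground truth used to test wavelength-selection recovery.
#'
#' @param config a [sim_config()].
#' @param k_sigma width multiplier (default 2).
#' @return Sorted integer vector of band indices.
#' @export
informative_bands <- function(config, k_sigma = 2) {
  idx <- integer(0)
  for (p in config$peaks) {
    idx <- c(idx, which(abs(config$grid - p$center_nm) <= k_sigma * p$width_nm))
  }
  sort(unique(idx))
}

#' Simulate a raw/dark/white frame triplet
#'
#' Builds the detector-intensity frames whose two-point calibration recovers
#' `spectrum`: dark = dark level, white = white level, raw interpolates
#' between them by the reflectance, each plus optional iid intensity noise.
#'
#' @param spectrum reflectance vector over `config$grid`.
#' @param roi_rows,roi_cols spatial frame extent (pixels), >= 1.
#' @param config a [sim_config()] supplying `dark_level`, `white_level`,
#'   `frame_noise_sd`. Noise draws come from the current RNG state.
#' @return List of class `frame_triplet` with 3-D arrays `raw`, `dark`,
#'   `white` (rows x cols x bands) and the grid.
#' @export
simulate_frame_triplet <- function(spectrum, roi_rows, roi_cols, config) {
  if (roi_rows < 1 || roi_cols < 1) stop("frame extents must be >= 1")
  if (config$white_level <= config$dark_level) {
    stop("white_level must exceed dark_level")
  }
  nb <- length(spectrum)
  dims <- c(roi_rows, roi_cols, nb)
  noise <- function() {
    if (config$frame_noise_sd > 0) {
      array(stats::rnorm(prod(dims), 0, config$frame_noise_sd), dims)
    } else {
      array(0, dims)
    }
  }
  dark <- array(config$dark_level, dims) + noise()
  white <- array(config$white_level, dims) + noise()
  spec3 <- aperm(array(spectrum, c(nb, roi_rows, roi_cols)), c(2, 3, 1))
  raw <- dark + (white - dark) * spec3 + noise()
  structure(list(raw = raw, dark = dark, white = white, grid = config$grid),
            class = "frame_triplet")
}
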
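#' Synthetic dataset configuration
#'
#' Bundles every parameter of the synthetic electrocorticography generator
#' in one place, so that a `(config, seed)` pair fully determines every
#' dataset the package can produce.
#'
#' Two families of defaults are provided. `mode = "sleep"` parameterizes
#' the signal-mode generator: per-state spectral mixtures (weights of a
#' slow 0.7-2 Hz oscillation, 7-14 Hz spindle bursts gated by an on/off
#' envelope, 30-45 Hz narrowband gamma, and 1/f broadband noise, each
#' normalized to unit standard deviation before weighting) chosen so that
#' slow-wave sleep is slow-dominated, light sleep intermediate with
#' spindles, and wakefulness/REM broadband-and-gamma dominated and mutually
#' near-identical. `mode = "dose"` parameterizes the direct-value
#' hierarchical generator: per-epoch complexity drawn from a polynomial in
#' centred dose with random intercepts for cat and for session nested in
#' cat.
#'
#' @param mode `"sleep"` or `"dose"`.
#' @param ... Named overrides of any default listed below.
#' @return A classed list (`lz_synth_config`) of parameters:
#' \describe{
#'   \item{fs, epoch_samples}{1024 Hz, 5120 samples (5 s).}
#'   \item{band}{Analysis band c(0.5, 200) Hz.}
#'   \item{n_cats}{3 (sleep) or 5 (dose).}
#'   \item{epochs_per_condition}{60 (i.e. 300 s per condition).}
#'   \item{cortices, flat_cortices}{Cortex labels; `flat_cortices` use the
#'     wake mixture for every state (no state effect).}
#'   \item{state_mixtures}{Per-state component weights (sleep mode).}
#'   \item{state_targets}{Per-state mean complexity for the direct-value
#'     sleep variant: W 0.62, LS 0.48, SWS 0.33, REM 0.60, inside the
#'     empirical wake envelope of intracranial recordings.}
#'   \item{sigma_cat_mix}{Log-scale SD of the per-cat multiplicative jitter
#'     on mixture weights (signal mode), 0.1.}
#'   \item{doses, dose_center}{c(0, 5, 10, 15) mg/kg, centred at 7.5.}
#'   \item{sessions_per_dose}{4 replicate sessions of each dose per cat.}
#'   \item{beta0, beta1_linear, beta2_quad}{0.62 baseline complexity;
#'     -0.004 per mg/kg for linear-truth data; 0.0008 per (mg/kg)^2
#'     curvature magnitude for quadratic-truth data.}
#'   \item{stim_effect}{Additive complexity shift under stimulation, 0.04.}
#'   \item{sigma_cat, sigma_session, sigma_eps}{Random-intercept and
#'     residual SDs: 0.01, 0.005, 0.02 (direct-value modes).}
#'   \item{seed}{1234.}
#' }
#' @export
synth_config <- function(mode = c("sleep", "dose"), ...) {
  mode <- match.arg(mode)
  cfg <- list(
    mode = mode,
    fs = 1024,
    epoch_samples = 5120,
    band = c(0.5, 200),
    z_max = 6,
    n_cats = if (mode == "sleep") 3L else 5L,
    epochs_per_condition = 60L,
    cortices = "r_dlPf",
    flat_cortices = character(0),
    states = c("W", "LS", "SWS", "REM"),
    state_mixtures = list(
      W   = c(slow = 0.15, spindle = 0.0, gamma = 0.6,  broadband = 1.0),
      LS  = c(slow = 0.6,  spindle = 0.8, gamma = 0.35, broadband = 0.7),
      SWS = c(slow = 1.8,  spindle = 0.3, gamma = 0.15, broadband = 0.45),
      REM = c(slow = 0.18, spindle = 0.0, gamma = 0.55, broadband = 1.0)
    ),
    state_targets = c(W = 0.62, LS = 0.48, SWS = 0.33, REM = 0.60),
    sigma_cat_mix = 0.1,
    doses = c(0, 5, 10, 15),
    dose_center = 7.5,
    sessions_per_dose = 4L,
    beta0 = 0.62,
    beta1_linear = -0.004,
    beta2_quad = 0.0008,
    stim_effect = 0.04,
    sigma_cat = 0.01,
    sigma_session = 0.005,
    sigma_eps = 0.02,
    seed = 1234L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "lz_synth_config")
}

# 1/f ("pink") broadband noise via spectral shaping of white noise.
.pink_noise <- function(n) {
  white <- stats::rnorm(n)
  sp <- stats::fft(white)
  # two-sided frequency index; DC removed, amplitude ~ 1/sqrt(f)
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k)
  scale <- c(0, 1 / sqrt(f[-1]))
  x <- Re(stats::fft(sp * scale, inverse = TRUE)) / n
  x
}

# Two-state on/off spindle envelope: exponentially distributed burst
# (mean 1 s) and inter-burst (mean 3 s) durations.
.spindle_envelope <- function(n, fs, mean_on = 1, mean_off = 3) {
  env <- numeric(n)
  pos <- 1L
  on <- stats::runif(1) < mean_on / (mean_on + mean_off)
  while (pos <= n) {
    dur <- max(1L, round(stats::rexp(1, 1 / (if (on) mean_on else mean_off)) * fs))
    end <- min(n, pos + dur - 1L)
    if (on) env[pos:end] <- 1
    pos <- end + 1L
    on <- !on
  }
  env
}

.unit_sd <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(x)
  x / s
}

# One continuous stretch of synthetic ECoG for a given mixture of
# components, each normalized to unit SD before weighting.
.gen_signal <- function(n, fs, w) {
  tt <- seq_len(n) / fs
  f_slow <- stats::runif(1, 0.7, 2)
  f_spin <- stats::runif(1, 7, 14)
  slow <- sin(2 * pi * f_slow * tt + stats::runif(1, 0, 2 * pi))
  spin <- .spindle_envelope(n, fs) * sin(2 * pi * f_spin * tt + stats::runif(1, 0, 2 * pi))
  # narrowband gamma as 30-45 Hz band-limited noise
  gam <- signal::filtfilt(signal::butter(2, c(30, 45) / (fs / 2), type = "pass"),
                          stats::rnorm(n))
  broad <- .pink_noise(n)
  w[["slow"]] * .unit_sd(slow) + w[["spindle"]] * .unit_sd(spin) +
    w[["gamma"]] * .unit_sd(gam) + w[["broadband"]] * .unit_sd(broad)
}

#' Generate one synthetic epoch of a given vigilance state
#'
#' Draws a single `epoch_samples`-long epoch from the state's spectral
#' mixture. With a `seed` the draw is bit-reproducible.
#'
#' @param state One of `"W"`, `"LS"`, `"SWS"`, `"REM"`.
#' @param cfg An `lz_synth_config` (sleep mode).
#' @param seed Optional integer; if given, the epoch is a deterministic
#'   function of `(state, cfg, seed)`.
#' @param weights Optional mixture-weight override (named numeric vector).
#' @return Numeric vector of length `cfg$epoch_samples`.
#' @export
gen_state_epoch <- function(state, cfg = synth_config("sleep"), seed = NULL,
                            weights = NULL) {
  if (!state %in% names(cfg$state_mixtures))
    stop("unknown state label: ", state)
  w <- if (is.null(weights)) cfg$state_mixtures[[state]] else weights
  gen <- function() .gen_signal(cfg$epoch_samples, cfg$fs, w)
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate a hierarchical synthetic sleep dataset
#'
#' Signal mode (default): for every cat x cortex x state cell, generates a
#' continuous 300-s recording from the state's spectral mixture (with a
#' per-cat multiplicative log-normal jitter on the weights), band-passes
#' it, splits it into 5-s epochs, applies amplitude-based artifact
#' rejection, and computes per-epoch normalized LZ78 complexity — i.e. it
#' exercises the full preprocessing and complexity chain. Cortices listed
#' in `cfg$flat_cortices` use the wake mixture for all states, emulating a
#' region without a state effect.
#'
#' Direct-value mode (`mode = "direct"`) skips signal synthesis and draws
#' per-epoch complexity directly from
#' `C = target(state) + u_cat + eps`, with `u_cat ~ N(0, sigma_cat)` and
#' `eps ~ N(0, sigma_eps)`; it is orders of magnitude faster and is meant
#' for exercising the statistical layer.
#'
#' @param cfg An `lz_synth_config` (sleep mode).
#' @param mode `"signal"` or `"direct"`.
#' @return A list with `complexity` (long data frame with columns `cat`,
#'   `session`, `channel`, `state`, `dose`, `stim`, `epoch`, and — in
#'   signal mode — `T`, `L`, `C`; in direct mode just `C`), `rejection_log`
#'   (signal mode), and the echoed `config`.
#' @export
gen_sleep_dataset <- function(cfg = synth_config("sleep"),
                              mode = c("signal", "direct")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cfg, "lz_synth_config"))
  if (cfg$n_cats < 1) stop("n_cats must be at least 1")
  withr::with_seed(cfg$seed, {
    if (mode == "direct") {
      rows <- expand.grid(cat = paste0("cat", seq_len(cfg$n_cats)),
                          channel = cfg$cortices,
                          state = cfg$states,
                          epoch = seq_len(cfg$epochs_per_condition) - 1L,
                          stringsAsFactors = FALSE)
      u_cat <- stats::rnorm(cfg$n_cats, 0, cfg$sigma_cat)
      names(u_cat) <- paste0("cat", seq_len(cfg$n_cats))
      flat <- rows$channel %in% cfg$flat_cortices
      target <- cfg$state_targets[rows$state]
      target[flat] <- cfg$state_targets[["W"]]
      rows$C <- target + u_cat[rows$cat] +
        stats::rnorm(nrow(rows), 0, cfg$sigma_eps)
      rows$session <- "s1"
      rows$dose <- NA_real_
      rows$stim <- FALSE
      rows <- rows[, c("cat", "session", "channel", "state", "dose",
                       "stim", "epoch", "C")]
      return_value <- list(complexity = rows, rejection_log = NULL,
                           config = cfg)
      return_value
    } else {
    n <- cfg$epochs_per_condition * cfg$epoch_samples
    all_epochs <- list()
    for (ci in seq_len(cfg$n_cats)) {
      cat_id <- paste0("cat", ci)
      jitter <- exp(stats::rnorm(4, 0, cfg$sigma_cat_mix))
      names(jitter) <- c("slow", "spindle", "gamma", "broadband")
      for (cortex in cfg$cortices) {
        for (state in cfg$states) {
          base <- if (cortex %in% cfg$flat_cortices)
            cfg$state_mixtures[["W"]] else cfg$state_mixtures[[state]]
          w <- base * jitter[names(base)]
          sig <- .gen_signal(n, cfg$fs, w)
          rec <- recording(stats::setNames(list(sig), cortex), cfg$fs,
                           cat = cat_id, session = "s1", state = state)
          rec <- bandpass(rec, cfg$band[1], cfg$band[2])
          all_epochs[[length(all_epochs) + 1L]] <-
            segment_epochs(rec, cfg$epoch_samples)
        }
      }
    }
    ep <- do.call(bind_epochs, all_epochs)
    rej <- reject_artifacts(ep, cfg$z_max)
    list(complexity = epochs_lz(rej$epochs),
         rejection_log = rej$log,
         config = cfg)
    }
  })
}

.shape_coefs <- function(shape, cfg) {
  switch(shape,
    inverted_u = c(b1 = 0, b2 = -cfg$beta2_quad),
    u          = c(b1 = 0, b2 = +cfg$beta2_quad),
    linear     = c(b1 = cfg$beta1_linear, b2 = 0),
    flat       = c(b1 = 0, b2 = 0),
    stop("unknown shape: ", shape)
  )
}

#' Generate a hierarchical synthetic ketamine dose-response dataset
#'
#' Direct-value generator for the dose analysis: per-epoch complexity
#' follows
#' `C = beta0 + beta1*dt + beta2*dt^2 + stim_effect*stim + u_cat + u_session + eps`
#' where `dt` is dose centred at `cfg$dose_center` (7.5 mg/kg, which
#' decorrelates the linear and quadratic terms over doses 0/5/10/15),
#' `u_cat ~ N(0, sigma_cat)`, `u_session ~ N(0, sigma_session)` with
#' sessions nested in cats, and `eps ~ N(0, sigma_eps)`. The `shape`
#' argument sets the sign pattern of `(beta1, beta2)`.
#'
#' @param shape `"inverted_u"` (negative curvature), `"u"`, `"linear"`, or
#'   `"flat"`.
#' @param cfg An `lz_synth_config` (dose mode).
#' @param include_stim If `TRUE`, every cell is generated twice (with and
#'   without auditory stimulation) and `stim_effect` is added to the
#'   stimulated half.
#' @return Long data frame `cat, session, dose, dtilde, stim, epoch, C`
#'   with `cfg$sessions_per_dose` sessions per cat per dose and
#'   `cfg$epochs_per_condition` epochs per cell.
#' @export
gen_dose_dataset <- function(shape = c("inverted_u", "u", "linear", "flat"),
                             cfg = synth_config("dose"),
                             include_stim = FALSE) {
  shape <- match.arg(shape)
  stopifnot(inherits(cfg, "lz_synth_config"))
  co <- .shape_coefs(shape, cfg)
  withr::with_seed(cfg$seed, {
    cats <- paste0("cat", seq_len(cfg$n_cats))
    u_cat <- stats::setNames(stats::rnorm(length(cats), 0, cfg$sigma_cat), cats)
    rows <- list()
    for (cat_id in cats) {
      for (dose in cfg$doses) {
        for (rep in seq_len(cfg$sessions_per_dose)) {
          sess <- sprintf("d%02d_r%d", dose, rep)
          u_sess <- stats::rnorm(1, 0, cfg$sigma_session)
          dt <- dose - cfg$dose_center
          for (stim in (if (include_stim) c(FALSE, TRUE) else FALSE)) {
            mu <- cfg$beta0 + co[["b1"]] * dt + co[["b2"]] * dt^2 +
              (if (stim) cfg$stim_effect else 0) + u_cat[[cat_id]] + u_sess
            rows[[length(rows) + 1L]] <- data.frame(
              cat = cat_id, session = sess, dose = dose, dtilde = dt,
              stim = stim, epoch = seq_len(cfg$epochs_per_condition) - 1L,
              C = mu + stats::rnorm(cfg$epochs_per_condition, 0, cfg$sigma_eps),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    do.call(rbind, rows)
  })
}
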
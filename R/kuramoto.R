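#' Kuramoto simulator configuration
#'
#' Parameters of the coupled phase-oscillator simulation
#' \deqn{d\theta_i/dt = \omega_i + k \sum_j a_{ij} \sin(\theta_j - \theta_i)}
#' integrated with the forward-Euler scheme at step `h`. Natural frequencies
#' are drawn once per run from Normal(`freq_mean`, `freq_sd`) Hz (clipped at
#' 0.1 Hz so every node oscillates) and converted to angular frequency as
#' `omega = 2 * pi * f * time_unit_scale`.
#'
#' Taken literally, f ~ 10 Hz with h = 0.1 advances each phase by about one
#' full cycle per step, so the sampled signal is aliased; `time_unit_scale`
#' rescales the time unit so oscillations are well sampled (default 0.01:
#' about 0.063 rad per step, 100 samples per alpha cycle) while keeping the
#' printed h and the 10 +/- 2 Hz frequency draw. `mode = "literal"` sets the
#' scale to 1 and reproduces the printed arithmetic verbatim; that regime is
#' effectively a near-critical circle map and is the one in which coupling
#' strength visibly modulates signal complexity (see the package vignette).
#'
#' @param n_oscillators Number of oscillators/channels (default 21).
#' @param k Global coupling strength (default 1).
#' @param freq_mean,freq_sd Mean and SD of the natural frequencies in Hz
#'   (defaults 10 and 2).
#' @param h Euler integration step (default 0.1).
#' @param n_samples Total integrated samples per run (default 15000).
#' @param burn_in Leading samples discarded as transient (default 1000).
#' @param n_runs Ensemble size for [run_ensemble()] (default 15).
#' @param seed Integer seed; per-run subseeds are derived from it by a
#'   counter scheme so ensembles are reproducible.
#' @param time_unit_scale Time-unit rescaling applied to the angular
#'   frequencies (default 0.01; ignored when `mode = "literal"`).
#' @param mode `"scaled"` (default) or `"literal"` (see Details).
#' @param normalize_coupling Divide the coupling term by N (default FALSE;
#'   the model is implemented exactly as written, without a 1/N factor).
#' @param phase_noise_sd Per-step SD (radians) of additive Gaussian phase
#'   increments, 0 for the deterministic model.
#' @param natural_freqs Optional fixed vector of natural frequencies in Hz,
#'   bypassing the random draw (used e.g. for analytic two-oscillator
#'   checks).
#' @param initial_phases Optional fixed vector of initial phases in radians,
#'   bypassing the uniform draw.
#' @return A `kuramoto_config` list.
#' @export
kuramoto_config <- function(n_oscillators = 21, k = 1, freq_mean = 10,
                            freq_sd = 2, h = 0.1, n_samples = 15000,
                            burn_in = 1000, n_runs = 15, seed = NULL,
                            time_unit_scale = 0.01,
                            mode = c("scaled", "literal"),
                            normalize_coupling = FALSE,
                            phase_noise_sd = 0, natural_freqs = NULL,
                            initial_phases = NULL) {
  mode <- match.arg(mode)
  if (mode == "literal") time_unit_scale <- 1
  if (burn_in >= n_samples) stop("`burn_in` must be < `n_samples`", call. = FALSE)
  if (h <= 0) stop("`h` must be positive", call. = FALSE)
  if (freq_sd < 0) stop("`freq_sd` must be >= 0", call. = FALSE)
  if (time_unit_scale <= 0) stop("`time_unit_scale` must be positive", call. = FALSE)
  if (phase_noise_sd < 0) stop("`phase_noise_sd` must be >= 0", call. = FALSE)
  if (!is.null(natural_freqs) && length(natural_freqs) != n_oscillators) {
    stop("`natural_freqs` must have length `n_oscillators`", call. = FALSE)
  }
  if (!is.null(initial_phases) && length(initial_phases) != n_oscillators) {
    stop("`initial_phases` must have length `n_oscillators`", call. = FALSE)
  }
  structure(
    list(n_oscillators = as.integer(n_oscillators), k = k,
         freq_mean = freq_mean, freq_sd = freq_sd, h = h,
         n_samples = as.integer(n_samples), burn_in = as.integer(burn_in),
         n_runs = as.integer(n_runs), seed = seed,
         time_unit_scale = time_unit_scale, mode = mode,
         normalize_coupling = normalize_coupling,
         phase_noise_sd = phase_noise_sd, natural_freqs = natural_freqs,
         initial_phases = initial_phases),
    class = "kuramoto_config"
  )
}

#' Simulate the coupled-oscillator network
#'
#' Forward-Euler integration of the Kuramoto model coupled through
#' `coupling`. Initial phases are i.i.d. uniform on \[0, 2pi); the first
#' `burn_in` samples are discarded. Deterministic given `cfg$seed`.
#'
#' @param cfg A [kuramoto_config()].
#' @param coupling A [connectivity_matrix()] with dimension
#'   `cfg$n_oscillators`.
#' @return A `phase_trajectory`: list with `phases` (timepoints x N,
#'   unwrapped radians), `natural_freqs` (Hz), order parameter `r`, mean
#'   phase `psi`, and the `config` used.
#' @seealso [order_parameter()], [to_eeg()], [run_ensemble()]
#' @export
simulate_kuramoto <- function(cfg, coupling) {
  stopifnot(inherits(cfg, "kuramoto_config"))
  if (nrow(coupling) != cfg$n_oscillators) {
    stop(sprintf("coupling matrix dimension (%d) does not match n_oscillators (%d)",
                 nrow(coupling), cfg$n_oscillators), call. = FALSE)
  }
  n <- cfg$n_oscillators
  draws <- with_seed(cfg$seed, {
    f <- cfg$natural_freqs %||% pmax(rnorm(n, cfg$freq_mean, cfg$freq_sd), 0.1)
    th0 <- cfg$initial_phases %||% runif(n, 0, 2 * pi)
    noise <- if (cfg$phase_noise_sd > 0) {
      matrix(rnorm(cfg$n_samples * n, 0, cfg$phase_noise_sd),
             cfg$n_samples, n)
    } else {
      matrix(numeric(0), 0, 0)
    }
    list(f = f, th0 = th0, noise = noise)
  })
  omega <- 2 * pi * draws$f * cfg$time_unit_scale
  k_eff <- if (cfg$normalize_coupling) cfg$k / n else cfg$k
  phases <- .kuramoto_euler_cpp(unclass(coupling), omega, draws$th0, k_eff,
                                cfg$h, cfg$n_samples, cfg$burn_in,
                                draws$noise)
  op <- order_parameter(phases)
  structure(
    list(phases = phases, natural_freqs = draws$f, r = op$r, psi = op$psi,
         config = cfg, labels = rownames(coupling)),
    class = "phase_trajectory"
  )
}

#' @export
print.phase_trajectory <- function(x, ...) {
  cat(sprintf("<phase_trajectory> %d oscillators x %d samples, mean r = %.3f\n",
              ncol(x$phases), nrow(x$phases), mean(x$r)))
  invisible(x)
}

#' Kuramoto order parameter
#'
#' Modulus `r(t)` and argument `psi(t)` of the mean unit phasor,
#' `r(t) exp(-i psi(t)) = mean_j exp(-i theta_j(t))`. `r` is 1 for perfectly
#' synchronized oscillators and near 0 for incoherent phases.
#'
#' @param phases Numeric matrix, timepoints x N (radians), or a
#'   `phase_trajectory`.
#' @return List with vectors `r` (in \[0, 1\]) and `psi`.
#' @export
#' @examples
#' order_parameter(matrix(c(0, pi), 1, 2))$r  # antipodal pair: 0
order_parameter <- function(phases) {
  if (inherits(phases, "phase_trajectory")) phases <- phases$phases
  phases <- as.matrix(phases)
  if (length(phases) == 0) stop("empty phase matrix", call. = FALSE)
  z <- rowMeans(exp(-1i * phases))
  list(r = pmin(Mod(z), 1), psi = -Arg(z))
}

#' Convert a phase trajectory to a simulated EEG recording
#'
#' Channel i carries `sin(theta_i(t))`. The nominal sampling rate is
#' `1 / (h * time_unit_scale)` in Hz of rescaled time. Set
#' `collapse = TRUE` to obtain instead the single summed signal
#' `sum_i sin(theta_i(t))` as a one-channel diagnostic recording.
#'
#' @param traj A `phase_trajectory` from [simulate_kuramoto()].
#' @param labels Channel labels (length N); defaults to the coupling-matrix
#'   labels carried by the trajectory.
#' @param group Group tag for the recording (a `simulated-*` variant).
#' @param collapse Return the summed one-channel signal instead.
#' @return An [eeg_recording()].
#' @export
to_eeg <- function(traj, labels = traj$labels, group = "simulated-control",
                   collapse = FALSE) {
  stopifnot(inherits(traj, "phase_trajectory"))
  n <- ncol(traj$phases)
  if (collapse) {
    dat <- matrix(rowSums(sin(traj$phases)), ncol = 1,
                  dimnames = list(NULL, "sum"))
  } else {
    labels <- labels %||% paste0("ch", seq_len(n))
    if (length(labels) != n) {
      stop(sprintf("label count (%d) does not match oscillator count (%d)",
                   length(labels), n), call. = FALSE)
    }
    dat <- sin(traj$phases)
    colnames(dat) <- labels
  }
  fs <- 1 / (traj$config$h * traj$config$time_unit_scale)
  eeg_recording(dat, fs = fs, channel_labels = colnames(dat),
                subject_id = "sim", group = group)
}

#' Simulate an ensemble of independent runs
#'
#' Repeats [simulate_kuramoto()] `cfg$n_runs` times with independent draws
#' of natural frequencies and initial phases; run subseeds are derived from
#' `cfg$seed` by a counter scheme, so the whole ensemble is reproducible
#' from the one master seed.
#'
#' @inheritParams simulate_kuramoto
#' @param labels,group Passed to [to_eeg()].
#' @return List of `cfg$n_runs` [eeg_recording()]s, with a `manifest`
#'   attribute (data frame of run index and subseed).
#' @export
run_ensemble <- function(cfg, coupling, labels = rownames(coupling),
                         group = "simulated-control") {
  stopifnot(inherits(cfg, "kuramoto_config"))
  seeds <- vapply(seq_len(cfg$n_runs), function(i) {
    if (is.null(cfg$seed)) NA_integer_ else derive_seed(cfg$seed, i)
  }, integer(1))
  recs <- vector("list", cfg$n_runs)
  for (i in seq_len(cfg$n_runs)) {
    run_cfg <- cfg
    run_cfg$seed <- if (is.na(seeds[i])) NULL else seeds[i]
    traj <- tryCatch(
      simulate_kuramoto(run_cfg, coupling),
      error = function(e) stop(sprintf("run %d failed: %s", i,
                                       conditionMessage(e)), call. = FALSE)
    )
    rec <- to_eeg(traj, labels = labels, group = group)
    rec$subject_id <- sprintf("run%02d", i)
    recs[[i]] <- rec
  }
  attr(recs, "manifest") <- data.frame(run = seq_len(cfg$n_runs),
                                       subseed = seeds)
  recs
}

#' Complexity as a function of coupling strength
#'
#' Runs an ensemble at each value of `k_values` and reports the
#' across-channel, across-run mean of each complexity measure, as a
#' sensitivity analysis of complexity to global coupling.
#'
#' @inheritParams run_ensemble
#' @param k_values Non-empty numeric vector of coupling strengths.
#' @param params [complexity_params()] used for scoring.
#' @return Data frame with columns `k`, `LZC`, `HFD`, `FDispEn`.
#' @export
coupling_sweep <- function(cfg, coupling, k_values,
                           params = complexity_params(hfd_kmax = 6)) {
  if (length(k_values) == 0) stop("`k_values` must be non-empty", call. = FALSE)
  rows <- lapply(k_values, function(kv) {
    cfg_k <- cfg
    cfg_k$k <- kv
    recs <- run_ensemble(cfg_k, coupling)
    tbl <- score_recordings(recs, params = params,
                            regions = region_map(recs[[1]]$channel_labels))
    means <- tapply(tbl$value, tbl$measure, mean)
    data.frame(k = kv, LZC = means[["LZC"]], HFD = means[["HFD"]],
               FDispEn = means[["FDispEn"]], row.names = NULL)
  })
  do.call(rbind, rows)
}
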
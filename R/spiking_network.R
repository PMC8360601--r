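#' @useDynLib placecode, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd cor setNames
#' @importFrom grDevices chull
NULL

#' Adaptive exponential integrate-and-fire parameters
#'
#' One AdEx parameter block. The membrane equation is
#' `C dV/dt = -g_L (V - E_L) + g_L Delta_T exp((V - V_T)/Delta_T)
#'  - g_syn (V - E_syn) - w + I`, with adaptation
#' `tau_w dw/dt = a (V - E_L) - w`, a spike emitted when `V` reaches
#' `V_peak`, followed by `V <- V_reset`, `w <- w + b`, and an absolute
#' refractory period `t_ref`. With `a = b = 0` the rheobase has the
#' closed form `g_L (V_T - E_L - Delta_T)`.
#'
#' @param C membrane capacitance (pF).
#' @param g_L leak conductance (nS).
#' @param E_L leak reversal potential (mV).
#' @param V_T spike-initiation threshold (mV).
#' @param Delta_T spike slope factor (mV).
#' @param a subthreshold adaptation conductance (nS).
#' @param b spike-triggered adaptation increment (pA).
#' @param tau_w adaptation time constant (ms).
#' @param V_reset post-spike reset potential (mV).
#' @param V_peak spike detection threshold (mV).
#' @param t_ref absolute refractory period (ms).
#' @return an object of class `adex_params` (named numeric vector).
#' @export
adex_params <- function(C, g_L, E_L, V_T, Delta_T, a, b, tau_w,
                        V_reset, V_peak, t_ref) {
  p <- c(C = C, g_L = g_L, E_L = E_L, V_T = V_T, Delta_T = Delta_T,
         a = a, b = b, tau_w = tau_w, V_reset = V_reset, V_peak = V_peak,
         t_ref = t_ref)
  if (anyNA(p) || p["C"] <= 0 || p["g_L"] <= 0 || p["Delta_T"] < 0 ||
      p["tau_w"] <= 0 || p["t_ref"] < 0)
    stop_placecode("config", "invalid AdEx parameters")
  structure(p, class = "adex_params")
}

#' Regular-spiking (excitatory pyramidal) AdEx defaults
#'
#' A standard cortical regular-spiking parameter set with moderate spike
#' frequency adaptation. Its rheobase (~0.27 nA) is in the range typical
#' of pyramidal neurons.
#'
#' @return an `adex_params` object.
#' @export
adex_rs <- function() {
  adex_params(C = 200, g_L = 15, E_L = -70, V_T = -52, Delta_T = 2,
              a = 2, b = 60, tau_w = 150, V_reset = -60, V_peak = -30,
              t_ref = 2)
}

#' Fast-spiking (inhibitory interneuron) AdEx defaults
#'
#' Non-adapting, sharp spike initiation, short refractory period.
#'
#' @return an `adex_params` object.
#' @export
adex_fs <- function() {
  adex_params(C = 50, g_L = 10, E_L = -67, V_T = -48, Delta_T = 1,
              a = 0, b = 0, tau_w = 50, V_reset = -55, V_peak = -30,
              t_ref = 1)
}

#' Synaptic parameters
#'
#' Conductance-based exponential synapses. Each external drive event
#' increments the excitatory conductance of its target by `q_drive`; each
#' inhibitory (fast-spiking) neuron spike increments, after `delay_ms`,
#' the inhibitory conductance of every excitatory cell it connects to by
#' `q_inh`.
#'
#' @param q_drive_e unitary drive conductance onto E cells (nS).
#' @param q_drive_i unitary drive conductance onto I cells (nS);
#'   fast-spiking interneurons receive markedly stronger unitary
#'   excitation than pyramidal cells, which makes the feedforward
#'   inhibition fast enough to engage during the stimulus ramp.
#' @param q_inh unitary feedforward inhibitory conductance (nS).
#' @param tau_exc,tau_inh conductance decay time constants (ms).
#' @param E_exc,E_inh reversal potentials (mV); 0 and -80 by convention.
#' @param delay_ms synaptic transmission delay (ms).
#' @return an object of class `syn_params`.
#' @export
syn_params <- function(q_drive_e = 2, q_drive_i = 6, q_inh = 2,
                       tau_exc = 3, tau_inh = 8,
                       E_exc = 0, E_inh = -80, delay_ms = 1) {
  if (q_drive_e < 0 || q_drive_i < 0 || q_inh < 0 || tau_exc <= 0 ||
      tau_inh <= 0 || delay_ms <= 0)
    stop_placecode("config", "invalid synaptic parameters")
  structure(list(q_drive_e = q_drive_e, q_drive_i = q_drive_i,
                 q_inh = q_inh, tau_exc = tau_exc,
                 tau_inh = tau_inh, E_exc = E_exc, E_inh = E_inh,
                 delay_ms = delay_ms),
            class = "syn_params")
}

#' Network configuration
#'
#' A square grid of `grid x grid` cells, 75% excitatory and 25%
#' inhibitory (exact, via a regular 2x2 tiling of 3 E + 1 I), spaced
#' `pitch_um` microns apart. The only connections are feedforward I -> E
#' edges, sampled Bernoulli with probability
#' `conn_peak * exp(-d^2 / (2 conn_sigma_um^2))` of the Euclidean
#' distance `d` in microns. The tonotopic axis runs along the grid
#' columns (x).
#'
#' The full-scale network is 200 x 200 with a 75 um connection spread;
#' [desk_network_config()] gives a half-scale version for routine runs.
#'
#' @param grid side length in cells (even, >= 4).
#' @param pitch_um inter-cell distance (um).
#' @param conn_sigma_um spread of the I -> E connection probability (um).
#' @param conn_peak peak connection probability at distance 0.
#' @param adex_e,adex_i AdEx parameter blocks for E and I cells.
#' @param syn a [syn_params()] block.
#' @param dt integration step (ms, <= 0.1).
#' @param seed RNG seed used when sampling connections.
#' @return an object of class `network_config`.
#' @export
network_config <- function(grid = 200, pitch_um = 7.5, conn_sigma_um = 75,
                           conn_peak = 0.4, adex_e = adex_rs(),
                           adex_i = adex_fs(), syn = syn_params(),
                           dt = 0.05, seed = 1) {
  grid <- as.integer(grid)
  if (is.na(grid) || grid < 4L || grid %% 2L != 0L)
    stop_placecode("config", "grid must be an even integer >= 4")
  if (dt <= 0 || dt > 0.1)
    stop_placecode("config", "dt must be in (0, 0.1] ms")
  if (conn_peak < 0 || conn_peak > 1)
    stop_placecode("config", "conn_peak must be a probability")
  stopifnot(inherits(adex_e, "adex_params"), inherits(adex_i, "adex_params"),
            inherits(syn, "syn_params"))
  structure(list(grid = grid, e_fraction = 0.75, i_fraction = 0.25,
                 pitch_um = pitch_um, conn_sigma_um = conn_sigma_um,
                 conn_peak = conn_peak, adex_e = adex_e, adex_i = adex_i,
                 syn = syn, dt = dt, seed = as.integer(seed)),
            class = "network_config")
}

#' Desk-scale network configuration
#'
#' Half-scale version of the default network for routine runs: a
#' 100 x 100 grid. The cell pitch and the I -> E connection spread are
#' physical constants of the tissue and are kept at their full-scale
#' values (7.5 um and 75 um); only the simulated area shrinks, so
#' stimulus widths in the protocols are halved while the inhibitory
#' reach is not.
#'
#' @param ... overrides passed to [network_config()].
#' @return a `network_config`.
#' @export
desk_network_config <- function(...) {
  do.call(network_config, utils::modifyList(list(grid = 100), list(...)))
}

#' Build a network from its configuration
#'
#' Deterministic for a fixed `seed`: assigns E/I types by the 2x2 tiling
#' and samples the feedforward I -> E edges.
#'
#' @param cfg a [network_config()].
#' @return an object of class `spiking_network` holding the configuration,
#'   cell types/positions, and the edge lists (CSR form).
#' @export
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  g <- cfg$grid
  n <- g * g
  idx <- seq_len(n) - 1L
  row <- idx %/% g
  col <- idx %% g
  is_exc <- as.integer(!(row %% 2L == 1L & col %% 2L == 1L))
  set.seed(cfg$seed)
  edges <- sample_ffi_edges(g, is_exc, cfg$pitch_um, cfg$conn_sigma_um,
                            cfg$conn_peak, 4.0)
  structure(list(cfg = cfg, n = n, grid = g, is_exc = is_exc,
                 row = row, col = col,
                 conn_ptr = edges$ptr, conn_tgt = edges$tgt),
            class = "spiking_network")
}

#' @export
print.spiking_network <- function(x, ...) {
  cat(sprintf(
    "<spiking_network> %d x %d grid: %d E, %d I cells, %d I->E edges\n",
    x$grid, x$grid, sum(x$is_exc == 1L), sum(x$is_exc == 0L),
    length(x$conn_tgt)))
  invisible(x)
}

#' External drive component
#'
#' A Gaussian synaptic barrage: the mean number of presynaptic sources
#' driving the cell at grid position `(x, y)` is
#' `peak_inputs * exp(-d^2 / (2 sigma_cells^2))` with `d` the distance to
#' `center` in cells. On each trial the per-cell count is drawn from a
#' Gaussian with that mean and standard deviation `trial_sd_frac` times
#' the mean, truncated at zero and rounded; each source then contributes
#' one event at a uniformly random time within the stimulus window
#' (brief stimuli: presynaptic cells treated as binary). `mode =
#' "poisson"` instead draws each source's events as a Poisson train at
#' rate 1 per window.
#'
#' @param center `(x, y)` grid position of the drive peak, in cells
#'   (x = tonotopic column).
#' @param sigma_cells spatial spread of the drive (cells).
#' @param peak_inputs maximal mean presynaptic count at the centre.
#' @param targets which populations receive the drive: subset of
#'   `c("E", "I")`.
#' @param duration_ms stimulus window (ms).
#' @param trial_sd_frac per-trial randomization of the counts.
#' @param mode `"event"` (one spike per source) or `"poisson"`.
#' @param time_profile distribution of event times within the window:
#'   `"gaussian"` (a barrage ramping up to a mid-window peak and down
#'   again: times drawn from a Gaussian with mean `duration_ms / 2` and
#'   sd `duration_ms / 4`, resampled into the window) or `"uniform"`.
#'   The ramped barrage reproduces the 10-15 ms lag of inhibitory
#'   conductance onset behind excitation seen with feedforward
#'   inhibition; a uniform barrage is stationary almost immediately and
#'   leaves inhibition no time to engage before cells cross rheobase.
#' @return an object of class `stimulus_config`.
#' @export
stimulus_config <- function(center, sigma_cells, peak_inputs,
                            targets = c("E", "I"), duration_ms = 50,
                            trial_sd_frac = 0.25,
                            mode = c("event", "poisson"),
                            time_profile = c("gaussian", "uniform")) {
  mode <- match.arg(mode)
  time_profile <- match.arg(time_profile)
  if (length(center) != 2L || anyNA(center))
    stop_placecode("config", "center must be (x, y) in cells")
  if (sigma_cells <= 0 || peak_inputs < 0 || duration_ms <= 0 ||
      trial_sd_frac < 0)
    stop_placecode("config", "invalid stimulus parameters")
  targets <- match.arg(targets, c("E", "I"), several.ok = TRUE)
  structure(list(center = as.numeric(center), sigma_cells = sigma_cells,
                 peak_inputs = peak_inputs, targets = targets,
                 duration_ms = duration_ms, trial_sd_frac = trial_sd_frac,
                 mode = mode, time_profile = time_profile),
            class = "stimulus_config")
}

draw_event_times <- function(n_ev, st) {
  dur <- st$duration_ms
  if (identical(st$time_profile, "uniform")) return(runif(n_ev, 0, dur))
  t <- rnorm(n_ev, dur / 2, dur / 4)
  bad <- which(t < 0 | t >= dur)
  while (length(bad)) {
    t[bad] <- rnorm(length(bad), dur / 2, dur / 4)
    bad <- bad[t[bad] < 0 | t[bad] >= dur]
  }
  t
}

#' Draw one trial's drive events
#'
#' Consumes the R random number stream (call `set.seed()` beforehand for
#' reproducibility).
#'
#' @param stims a [stimulus_config()] or list of them (components
#'   accumulate).
#' @param net a [build_network()] result.
#' @return a list with `ptr` (CSR offsets over neurons), `times` (event
#'   times, ms, grouped by neuron) and `duration_ms` (the longest
#'   component window).
#' @export
generate_drive <- function(stims, net) {
  stopifnot(inherits(net, "spiking_network"))
  if (inherits(stims, "stimulus_config")) stims <- list(stims)
  counts <- integer(net$n)
  dur_all <- 0
  ev_times <- vector("list", length(stims))
  ev_nrn <- vector("list", length(stims))
  for (k in seq_along(stims)) {
    st <- stims[[k]]
    stopifnot(inherits(st, "stimulus_config"))
    dur_all <- max(dur_all, st$duration_ms)
    d2 <- (net$col - st$center[1])^2 + (net$row - st$center[2])^2
    mean_in <- st$peak_inputs * exp(-d2 / (2 * st$sigma_cells^2))
    want_e <- "E" %in% st$targets
    want_i <- "I" %in% st$targets
    sel <- (net$is_exc == 1L & want_e) | (net$is_exc == 0L & want_i)
    sel <- sel & mean_in > 0.01
    if (!any(sel)) next
    mu <- mean_in[sel]
    cnt <- round(pmax(0, rnorm(length(mu), mu, st$trial_sd_frac * mu)))
    if (st$mode == "poisson")
      cnt <- stats::rpois(length(cnt), cnt)
    cnt <- as.integer(cnt)
    nrn <- rep.int(which(sel) - 1L, cnt)
    ev_nrn[[k]] <- nrn
    ev_times[[k]] <- draw_event_times(length(nrn), st)
  }
  nrn <- unlist(ev_nrn, use.names = FALSE)
  tms <- unlist(ev_times, use.names = FALSE)
  if (is.null(nrn)) { nrn <- integer(0); tms <- numeric(0) }
  o <- order(nrn, tms)
  nrn <- nrn[o]; tms <- tms[o]
  ptr <- c(0L, cumsum(tabulate(nrn + 1L, nbins = net$n)))
  list(ptr = as.integer(ptr), times = tms, duration_ms = dur_all)
}

#' Simulate one trial
#'
#' Integrates the whole network for the stimulus window plus a tail (so
#' delayed inhibition is captured), recording spikes, each cell's most
#' negative net synaptic current
#' `I_net = g_exc (V_theta - E_exc) + g_inh (V_theta - E_inh)` (with
#' `V_theta` the excitatory spike-initiation threshold `V_T`), and full
#' conductance/current traces for any requested cells.
#'
#' @param net a [build_network()] result.
#' @param drive a [generate_drive()] result.
#' @param t_tail extra simulated time after the stimulus window (ms).
#' @param record integer vector of 0-based neuron indices whose
#'   `g_exc`, `g_inh`, `i_net` and `V` traces are kept.
#' @return an object of class `trial_result` with `spike_neuron` (0-based),
#'   `spike_time` (ms), `min_inet` (nA per neuron, most negative value over
#'   the window), `traces` (or `NULL`) and the simulated window.
#' @export
simulate_trial <- function(net, drive, t_tail = 25, record = integer(0)) {
  stopifnot(inherits(net, "spiking_network"))
  cfg <- net$cfg
  t_stop <- drive$duration_ms + t_tail
  res <- adex_net_run(net$n, net$is_exc,
                      unclass(cfg$adex_e), unclass(cfg$adex_i),
                      net$conn_ptr, net$conn_tgt,
                      drive$ptr, drive$times,
                      cfg$syn$q_drive_e, cfg$syn$q_drive_i,
                      cfg$syn$q_inh,
                      cfg$syn$tau_exc, cfg$syn$tau_inh,
                      cfg$syn$E_exc, cfg$syn$E_inh, cfg$syn$delay_ms,
                      unname(cfg$adex_e["V_T"]), numeric(0),
                      cfg$dt, t_stop, as.integer(record))
  structure(list(spike_neuron = res$spike_neuron,
                 spike_time = res$spike_time,
                 min_inet = res$min_inet,
                 traces = res$traces,
                 t_stop = t_stop, dt = res$dt, n = net$n),
            class = "trial_result")
}

#' Simulate a single neuron under constant current injection
#'
#' Convenience wrapper around the integrator for one isolated AdEx
#' neuron with a constant injected current and no synaptic input.
#'
#' @param adex an [adex_params()] block.
#' @param i_nA injected current (nA; positive = depolarizing).
#' @param t_ms simulated time (ms).
#' @param dt integration step (ms).
#' @return list with `n_spikes` and `spike_times` (ms).
#' @export
simulate_constant_current <- function(adex, i_nA, t_ms = 200, dt = 0.05) {
  stopifnot(inherits(adex, "adex_params"))
  res <- adex_net_run(1L, 1L, unclass(adex), unclass(adex),
                      c(0L, 0L), integer(0), c(0L, 0L), numeric(0),
                      0, 0, 0, 3, 8, 0, -80, 1, unname(adex["V_T"]),
                      i_nA * 1000, dt, t_ms, integer(0))
  list(n_spikes = length(res$spike_neuron), spike_times = res$spike_time)
}

#' Estimate rheobase by bisection
#'
#' Finds the minimum constant injected current that makes a single AdEx
#' neuron fire within `t_test` ms, bracketing the spike/no-spike boundary
#' to a relative tolerance. With adaptation disabled (`a = b = 0`) the
#' estimate matches the analytic bound `g_L (V_T - E_L - Delta_T)`.
#'
#' The value is returned as a positive magnitude in nA. The synaptic
#' field criterion uses the inward-current convention, i.e. compares the
#' net synaptic current against `-estimate_rheobase(...)`.
#'
#' @param adex an [adex_params()] block.
#' @param tol relative bracketing tolerance (default 0.1%).
#' @param t_test test-pulse duration (ms).
#' @param dt integration step (ms).
#' @return rheobase magnitude (nA).
#' @export
estimate_rheobase <- function(adex, tol = 1e-3, t_test = 500, dt = 0.05) {
  stopifnot(inherits(adex, "adex_params"))
  spikes_at <- function(i_pa) {
    res <- adex_net_run(1L, 1L, unclass(adex), unclass(adex),
                        c(0L, 0L), integer(0), c(0L, 0L), numeric(0),
                        0, 0, 0, 3, 8, 0, -80, 1, unname(adex["V_T"]),
                        i_pa, dt, t_test, integer(0))
    length(res$spike_neuron) > 0L
  }
  lo <- 0
  hi <- max(1, unname(adex["g_L"] * (adex["V_T"] - adex["E_L"])))
  for (k in 1:20) {
    if (spikes_at(hi)) break
    hi <- hi * 2
    if (k == 20L) stop_placecode("estimation", "rheobase bracket not found")
  }
  while ((hi - lo) > tol * hi) {
    mid <- (lo + hi) / 2
    if (spikes_at(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2 / 1000  # pA -> nA
}

new_field_mask <- function(kind, cells, net) {
  structure(list(kind = kind, cells = cells, grid = net$grid,
                 row = net$row, col = net$col, is_exc = net$is_exc),
            class = "field_mask")
}

#' Synaptic field of a trial
#'
#' The set of excitatory cells whose net synaptic current was at least as
#' inward (negative) as rheobase at some point during the trial. `i_rh`
#' follows the inward convention and must be negative; inclusion is
#' boundary-inclusive. Cells receiving purely inhibitory input have
#' positive net current at threshold and are never included.
#'
#' @param trial a [simulate_trial()] result.
#' @param i_rh rheobase as an inward current (nA, negative), e.g.
#'   `-estimate_rheobase(cfg$adex_e)`.
#' @param net the network the trial was run on.
#' @return a `field_mask` of kind `"synaptic_field"`.
#' @export
compute_synaptic_field <- function(trial, i_rh, net) {
  stopifnot(inherits(trial, "trial_result"), i_rh < 0)
  cells <- (net$is_exc == 1L) & (trial$min_inet <= i_rh)
  new_field_mask("synaptic_field", cells, net)
}

#' Activated area of a trial
#'
#' The excitatory cells that fired at least one action potential.
#'
#' @param trial a [simulate_trial()] result.
#' @param net the network the trial was run on.
#' @return a `field_mask` of kind `"activated_area"`.
#' @export
compute_activated_area <- function(trial, net) {
  stopifnot(inherits(trial, "trial_result"))
  cells <- rep(FALSE, net$n)
  if (length(trial$spike_neuron))
    cells[unique(trial$spike_neuron) + 1L] <- TRUE
  cells <- cells & net$is_exc == 1L
  new_field_mask("activated_area", cells, net)
}

#' Average field masks over sweeps
#'
#' A cell belongs to the averaged mask if it was included in at least
#' half of the per-sweep masks.
#'
#' @param masks list of `field_mask` objects of the same kind and grid.
#' @param min_freq inclusion-frequency threshold (default 0.5).
#' @return a `field_mask`.
#' @export
average_masks <- function(masks, min_freq = 0.5) {
  stopifnot(length(masks) >= 1L)
  freq <- Reduce(`+`, lapply(masks, function(m) as.numeric(m$cells))) /
    length(masks)
  m1 <- masks[[1L]]
  m1$cells <- freq >= min_freq
  m1
}

#' Union of field masks
#'
#' Used by the sequential stimulation protocols: inputs delivered one at
#' a time produce one mask each, and their union is measured.
#'
#' @param masks list of `field_mask` objects on the same grid.
#' @return a `field_mask`.
#' @export
union_masks <- function(masks) {
  stopifnot(length(masks) >= 1L)
  m1 <- masks[[1L]]
  m1$cells <- Reduce(`|`, lapply(masks, function(m) m$cells))
  m1
}

# squared distance of points to circle centre
.in_circle <- function(px, py, cx, cy, r2, eps = 1e-9) {
  (px - cx)^2 + (py - cy)^2 <= r2 * (1 + eps) + eps
}

circle_from2 <- function(x1, y1, x2, y2) {
  c((x1 + x2) / 2, (y1 + y2) / 2, ((x1 - x2)^2 + (y1 - y2)^2) / 4)
}

circle_from3 <- function(x1, y1, x2, y2, x3, y3) {
  d <- 2 * (x1 * (y2 - y3) + x2 * (y3 - y1) + x3 * (y1 - y2))
  if (abs(d) < 1e-12) return(NULL)  # collinear
  ux <- ((x1^2 + y1^2) * (y2 - y3) + (x2^2 + y2^2) * (y3 - y1) +
           (x3^2 + y3^2) * (y1 - y2)) / d
  uy <- ((x1^2 + y1^2) * (x3 - x2) + (x2^2 + y2^2) * (x1 - x3) +
           (x3^2 + y3^2) * (x2 - x1)) / d
  c(ux, uy, (x1 - ux)^2 + (y1 - uy)^2)
}

#' Minimal enclosing circle of a point set
#'
#' Exact smallest circle containing all points, computed on the convex
#' hull (the minimal circle is determined by at most three hull points).
#'
#' @param x,y point coordinates.
#' @return list with `center` (x, y) and `radius`.
#' @export
min_enclosing_circle <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  if (length(x) == 1L) return(list(center = c(x, y), radius = 0))
  h <- if (length(x) > 2L) chull(x, y) else seq_along(x)
  hx <- x[h]; hy <- y[h]
  m <- length(hx)
  best <- NULL
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    cc <- circle_from2(hx[i], hy[i], hx[j], hy[j])
    if (all(.in_circle(hx, hy, cc[1], cc[2], cc[3])) &&
        (is.null(best) || cc[3] < best[3])) best <- cc
  }
  if (m >= 3L) {
    for (i in seq_len(m - 2L)) for (j in (i + 1L):(m - 1L))
      for (k in (j + 1L):m) {
        cc <- circle_from3(hx[i], hy[i], hx[j], hy[j], hx[k], hy[k])
        if (!is.null(cc) &&
            all(.in_circle(hx, hy, cc[1], cc[2], cc[3])) &&
            (is.null(best) || cc[3] < best[3])) best <- cc
      }
  }
  list(center = best[1:2], radius = sqrt(best[3]))
}

#' Measure the spatial extent of a field mask
#'
#' Diameter: that of the minimal circle enclosing the centres of the
#' included cells (units of cell number). Projection: the number of
#' distinct tonotopic columns occupied.
#'
#' @param mask a `field_mask`.
#' @return a list with `diameter_cells`, `projection_cells`, `n_cells`
#'   (included cell count) and `empty`. An empty mask reports diameter 0
#'   with `empty = TRUE`.
#' @export
measure <- function(mask) {
  stopifnot(inherits(mask, "field_mask"))
  sel <- which(mask$cells)
  if (length(sel) == 0L)
    return(list(diameter_cells = 0, projection_cells = 0L, n_cells = 0L,
                empty = TRUE))
  px <- mask$col[sel]; py <- mask$row[sel]
  mec <- min_enclosing_circle(px, py)
  list(diameter_cells = 2 * mec$radius,
       projection_cells = length(unique(px)),
       n_cells = length(sel), empty = FALSE)
}
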
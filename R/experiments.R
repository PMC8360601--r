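#' @title Network experiment protocols
#' @description Sweep protocols reproducing the simulation tests of the
#'   interval algebra: addition of co-located and separated excitatory
#'   drives, multiplication by co-located and shifted inhibitory drives,
#'   two excitatory inputs across one inhibitory input, and paired
#'   centre-surround composites, each delivered simultaneously or
#'   sequentially.
#' @name experiments
NULL

protocol_names <- c("addition_colocated", "addition_separated",
                    "multiplication_colocated", "multiplication_shifted",
                    "two_exc_one_inh", "center_surround")

# Default sweep values and stimulus widths, in cells, scaled to the grid
# (paper-scale values are stated for the 200 x 200 network).
protocol_defaults <- function(protocol, grid) {
  sc <- grid / 200
  switch(protocol,
    addition_colocated = list(values = round(seq(2, 45, length.out = 10) * sc),
                              sigma_b = 20 * sc),
    addition_separated = list(values = round(seq(0, 60, length.out = 10) * sc),
                              sigma = 10 * sc),
    multiplication_colocated = list(
      values = round(seq(2, 45, length.out = 10) * sc),
      sigma_exc = 20 * sc),
    multiplication_shifted = list(
      values = round(seq(0, 60, length.out = 10) * sc),
      sigma = 10 * sc),
    two_exc_one_inh = list(values = round(seq(0, 40, length.out = 9) * sc),
                           sigma = 10 * sc),
    center_surround = list(values = round(seq(0, 100, length.out = 10) * sc),
                           sigma_exc = 10 * sc, sigma_inh = 17 * sc),
    stop_placecode("config", paste0("unknown protocol '", protocol, "'")))
}

# stimulus component lists per protocol; value is the swept parameter
protocol_stims <- function(protocol, value, p, cx, cy, peak, dur) {
  gauss_e <- function(x, s) stimulus_config(c(x, cy), s, peak,
                                            targets = "E", duration_ms = dur)
  gauss_i <- function(x, s) stimulus_config(c(x, cy), s, peak,
                                            targets = "I", duration_ms = dur)
  switch(protocol,
    addition_colocated = list(list(gauss_e(cx, value), gauss_e(cx, p$sigma_b))),
    addition_separated = list(list(gauss_e(cx - value / 2, p$sigma),
                                   gauss_e(cx + value / 2, p$sigma))),
    multiplication_colocated = list(list(gauss_e(cx, p$sigma_exc),
                                         gauss_i(cx, value))),
    multiplication_shifted = list(list(gauss_e(cx + value / 2, p$sigma),
                                       gauss_i(cx - value / 2, p$sigma))),
    two_exc_one_inh = list(
      exc1 = gauss_e(cx - value, p$sigma),
      exc2 = gauss_e(cx + value, p$sigma),
      inh = gauss_i(cx, p$sigma)),
    center_surround = list(
      comp1 = list(gauss_e(cx - value / 2, p$sigma_exc),
                   gauss_i(cx - value / 2, p$sigma_inh)),
      comp2 = list(gauss_e(cx + value / 2, p$sigma_exc),
                   gauss_i(cx + value / 2, p$sigma_inh))))
}

flatten_stims <- function(x) {
  if (inherits(x, "stimulus_config")) return(list(x))
  unlist(lapply(x, flatten_stims), recursive = FALSE)
}

run_one_sweep <- function(net, stims, i_rh, t_tail) {
  drive <- generate_drive(stims, net)
  trial <- simulate_trial(net, drive, t_tail = t_tail)
  list(field = compute_synaptic_field(trial, i_rh, net),
       area = compute_activated_area(trial, net))
}

#' Run a stimulus-sweep experiment on the spiking network
#'
#' Builds the network once, then for each swept value runs `n_sweeps`
#' independent trials (drive counts re-randomized each trial), extracts
#' the synaptic field and activated area of each, and measures their
#' diameter and tonotopic projection.
#'
#' Protocols (swept parameter in parentheses; all widths in cells, the
#' stated defaults are for the full 200-grid and scale with `grid/200`):
#'
#' * `addition_colocated`: two excitatory drives at the centre, one width
#'   swept 2-45 (`sigma_a`), the other fixed at 20. No inhibition.
#' * `addition_separated`: two excitatory drives of width 10 moved apart
#'   (separation).
#' * `multiplication_colocated`: excitatory drive (width 20) to the E
#'   cells plus inhibitory-population drive of swept width to the I cells,
#'   co-centred.
#' * `multiplication_shifted`: E and I drives of width 10, E shifted
#'   right of I (separation).
#' * `two_exc_one_inh`: inhibitory-population drive fixed at the centre;
#'   two excitatory drives moved symmetrically left/right by the swept
#'   shift. `variant = "sequential"` delivers each excitatory drive alone
#'   (with the inhibition) and measures the union of the resulting masks.
#' * `center_surround`: two composites, each an E drive (width 10) and a
#'   wider co-centred I-population drive (width 17), moved apart.
#'   `variant = "sequential"` delivers each composite alone and measures
#'   the union of the masks.
#'
#' @param protocol one of the names above.
#' @param cfg a [network_config()]; defaults to the desk-scale network.
#' @param n_sweeps trials per swept value.
#' @param seed RNG seed governing all drive randomization.
#' @param values swept values (cells); protocol defaults when `NULL`.
#' @param params named list overriding protocol stimulus widths
#'   (`sigma`, `sigma_b`, `sigma_exc`, `sigma_inh`).
#' @param variant `"simultaneous"` or `"sequential"` (the two multi-input
#'   protocols only).
#' @param peak_inputs maximal mean presynaptic count of each drive.
#' @param duration_ms stimulus window (ms).
#' @param t_tail simulated tail after the window (ms).
#' @param net optionally a pre-built [build_network()] matching `cfg`,
#'   reused across calls.
#' @return a data.frame with one row per swept value: `protocol`,
#'   `variant`, `value`, mean and sd over sweeps of field/area diameter
#'   and projection, the measurements of the sweep-averaged masks
#'   (`avg_field_*`, `avg_area_*`; inclusion frequency >= 0.5, the
#'   analogue of measuring an averaged field image), and `n_sweeps`. The
#'   rheobase used is attached as attribute `i_rh`.
#' @export
run_experiment <- function(protocol, cfg = desk_network_config(),
                           n_sweeps = 10, seed = 1, values = NULL,
                           params = list(),
                           variant = c("simultaneous", "sequential"),
                           peak_inputs = 100, duration_ms = 50,
                           t_tail = 25, net = NULL) {
  protocol <- match.arg(protocol, protocol_names)
  variant <- match.arg(variant)
  p <- utils::modifyList(protocol_defaults(protocol, cfg$grid),
                         params[!vapply(params, is.null, logical(1))])
  if (is.null(values)) values <- p$values
  if (is.null(net)) net <- build_network(cfg)
  i_rh <- -estimate_rheobase(cfg$adex_e, dt = cfg$dt)
  cx <- cfg$grid / 2; cy <- cfg$grid / 2
  seq_capable <- protocol %in% c("two_exc_one_inh", "center_surround")
  if (variant == "sequential" && !seq_capable)
    stop_placecode("config",
                   "sequential variant applies to the multi-input protocols")
  set.seed(seed)
  rows <- vector("list", length(values))
  for (vi in seq_along(values)) {
    groups <- protocol_stims(protocol, values[vi], p, cx, cy,
                             peak_inputs, duration_ms)
    fd <- fp <- ad <- ap <- numeric(n_sweeps)
    fmasks <- amasks <- vector("list", n_sweeps)
    for (sw in seq_len(n_sweeps)) {
      if (variant == "simultaneous") {
        res <- run_one_sweep(net, flatten_stims(groups), i_rh, t_tail)
        field <- res$field; area <- res$area
      } else if (protocol == "two_exc_one_inh") {
        r1 <- run_one_sweep(net, list(groups$exc1, groups$inh), i_rh, t_tail)
        r2 <- run_one_sweep(net, list(groups$exc2, groups$inh), i_rh, t_tail)
        field <- union_masks(list(r1$field, r2$field))
        area <- union_masks(list(r1$area, r2$area))
      } else {
        r1 <- run_one_sweep(net, groups$comp1, i_rh, t_tail)
        r2 <- run_one_sweep(net, groups$comp2, i_rh, t_tail)
        field <- union_masks(list(r1$field, r2$field))
        area <- union_masks(list(r1$area, r2$area))
      }
      fmasks[[sw]] <- field; amasks[[sw]] <- area
      mf <- measure(field); ma <- measure(area)
      fd[sw] <- mf$diameter_cells; fp[sw] <- mf$projection_cells
      ad[sw] <- ma$diameter_cells; ap[sw] <- ma$projection_cells
    }
    # sweep-averaged masks (inclusion frequency >= 0.5) suppress rare
    # single-sweep fluctuation outliers, as in averaging field images
    mfa <- measure(average_masks(fmasks))
    maa <- measure(average_masks(amasks))
    rows[[vi]] <- data.frame(
      protocol = protocol, variant = variant, value = values[vi],
      field_diameter_mean = mean(fd), field_diameter_sd = sd(fd),
      field_projection_mean = mean(fp), field_projection_sd = sd(fp),
      area_diameter_mean = mean(ad), area_diameter_sd = sd(ad),
      area_projection_mean = mean(ap), area_projection_sd = sd(ap),
      avg_field_diameter = mfa$diameter_cells,
      avg_field_projection = mfa$projection_cells,
      avg_area_diameter = maa$diameter_cells,
      avg_area_projection = maa$projection_cells,
      n_sweeps = n_sweeps)
  }
  out <- do.call(rbind, rows)
  attr(out, "i_rh") <- i_rh
  out
}

#' Algebraic prediction matched to a protocol sweep
#'
#' Evaluates the interval-algebra prediction for a protocol at parameters
#' matched to the stimulus widths (an interval of length `2 * sigma`
#' cells per Gaussian drive of spread `sigma`). Used for rank (shape)
#' comparison against simulated curves; absolute scales are not
#' comparable because Gaussian inputs have no sharp edges.
#'
#' @param protocol protocol name (see [run_experiment()]).
#' @param values the swept values (cells).
#' @param grid grid side, used to scale the default stimulus widths.
#' @param params optional width overrides, as in [run_experiment()].
#' @param variant `"simultaneous"` or `"sequential"`.
#' @param len_scale cells of matched interval length per cell of drive
#'   sigma. The default 5 is the measured ratio of threshold-field
#'   diameter to drive spread under the default drive (see the methods
#'   vignette); the rank comparison is insensitive to its exact value.
#' @return numeric vector of predicted interval lengths.
#' @export
matched_prediction <- function(protocol, values, grid = 100, params = list(),
                               variant = c("simultaneous", "sequential"),
                               len_scale = 5) {
  protocol <- match.arg(protocol, protocol_names)
  variant <- match.arg(variant)
  p <- utils::modifyList(protocol_defaults(protocol, grid),
                         params[!vapply(params, is.null, logical(1))])
  L <- function(s) max(1L, as.integer(round(len_scale * s)))
  switch(protocol,
    addition_colocated =
      addition_same_start(L(p$sigma_b),
                          pmax(1L, round(len_scale * values)))$length,
    addition_separated =
      addition_shifted(L(p$sigma), as.integer(values))$length,
    multiplication_colocated =
      multiplication_same_start(L(p$sigma_exc),
                                round(len_scale * values))$length,
    multiplication_shifted =
      multiplication_shifted(L(p$sigma), L(p$sigma),
                             as.integer(values))$length,
    two_exc_one_inh = {
      len <- L(p$sigma)
      smax <- max(values)
      ax <- tonotopic_axis(4L * (smax + len) + 4L * len)
      x_i <- smax + 2L * len
      inh <- interval_set(c(x_i, len), ax)
      vapply(as.integer(values), function(s) {
        e1 <- interval_set(c(x_i - s, len), ax)
        e2 <- interval_set(c(x_i + s, len), ax)
        if (variant == "simultaneous")
          total_length(iset_multiply(inh, iset_add(e1, e2)))
        else
          total_length(iset_add(iset_multiply(inh, e1),
                                iset_multiply(inh, e2)))
      }, integer(1))
    },
    center_surround = {
      len_e <- L(p$sigma_exc)
      len_f <- max(1L, as.integer(round(len_scale *
                                           (p$sigma_inh - p$sigma_exc))))
      center_surround(len_e, len_f, as.integer(values), mode = variant)$length
    })
}
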
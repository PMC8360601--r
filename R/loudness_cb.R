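#' Multi-tone stimulus specification
#'
#' A band of `n_tones` equally strong tonal components, each mapping to an
#' interval of `lam` cells, with adjacent components' start points `delta`
#' cells apart. One component is the dominant tone; the rest widen the
#' band around it. Components are added either alternately to the right
#' and left of the dominant (symmetric band widening, the default) or all
#' to the right of a lowest-frequency dominant.
#'
#' In frequency units the bandwidth is `(n_tones - 1) * delta * df`, where
#' `df` is the frequency bin width of the acoustic space in use.
#'
#' @param n_tones number of components (>= 1).
#' @param lam per-component interval length in cells (>= 1).
#' @param delta start-to-start spacing between adjacent components (>= 1).
#' @param center_start start cell of the dominant component's interval.
#' @param placement `"alternate"` (right, left, right, ... around the
#'   dominant) or `"upward"` (all components above a lowest-frequency
#'   dominant).
#' @return an object of class `multitone_stimulus`.
#' @export
multitone_stimulus <- function(n_tones, lam, delta, center_start,
                               placement = c("alternate", "upward")) {
  placement <- match.arg(placement)
  n_tones <- as.integer(n_tones); lam <- as.integer(lam)
  delta <- as.integer(delta); center_start <- as.integer(center_start)
  if (n_tones < 1L || lam < 1L || delta < 1L || center_start < 0L)
    stop_placecode("config",
                   "need n_tones, lam, delta >= 1 and center_start >= 0")
  structure(list(n_tones = n_tones, lam = lam, delta = delta,
                 center_start = center_start, placement = placement),
            class = "multitone_stimulus")
}

multitone_starts <- function(stim) {
  n <- stim$n_tones
  if (stim$placement == "upward") {
    k <- seq_len(n) - 1L
  } else {
    # 0, +1, -1, +2, -2, ... in spacing units around the dominant
    i <- seq_len(n) - 1L
    k <- ifelse(i %% 2L == 1L, (i + 1L) %/% 2L, -(i %/% 2L))
  }
  stim$center_start + k * stim$delta
}

#' Build the interval-set representation of a multi-tone stimulus
#'
#' The union of the component intervals. Components whose spacing is at
#' most their length fuse into a single band-spanning part; wider spacing
#' leaves disjoint parts.
#'
#' @param stim a [multitone_stimulus()].
#' @param axis a [tonotopic_axis()].
#' @return an `interval_set`.
#' @export
build_multitone <- function(stim, axis) {
  stopifnot(inherits(stim, "multitone_stimulus"))
  starts <- multitone_starts(stim)
  if (any(starts < 0L) || any(starts + stim$lam > axis$n_cells))
    stop_placecode("bounds", "multi-tone stimulus overflows the axis")
  interval_set(cbind(starts, stim$lam), axis)
}

#' Lateral-inhibitory (critical-band) configuration
#'
#' The dominant tone's excitatory interval together with the two
#' inhibitory flanks it generates. The flanks abut the dominant interval
#' with no overlap: the left flank covers the `flank_left_len` cells
#' immediately below the dominant's closed end, the right flank the
#' `flank_right_len` cells immediately above its open end. Flank lengths
#' of 0 give the all-excitatory control.
#'
#' @param dominant a [synaptic_interval()] for the dominant tone.
#' @param flank_left_len,flank_right_len flank lengths in cells (>= 0).
#' @return an object of class `critical_band_config`.
#' @export
critical_band_config <- function(dominant, flank_left_len, flank_right_len) {
  stopifnot(inherits(dominant, "synaptic_interval"))
  flank_left_len <- as.integer(flank_left_len)
  flank_right_len <- as.integer(flank_right_len)
  if (flank_left_len < 0L || flank_right_len < 0L)
    stop_placecode("config", "flank lengths must be >= 0")
  structure(list(dominant = dominant,
                 flank_left_len = flank_left_len,
                 flank_right_len = flank_right_len),
            class = "critical_band_config")
}

cb_flanks <- function(cfg, axis) {
  d <- cfg$dominant
  if (d$start - cfg$flank_left_len < 0L ||
      d$start + d$length + cfg$flank_right_len > axis$n_cells)
    stop_placecode("bounds", "inhibitory flanks overflow the axis")
  iset_add(iset1(d$start - cfg$flank_left_len, cfg$flank_left_len, axis),
           iset1(d$start + d$length, cfg$flank_right_len, axis))
}

#' Critical interval of a lateral-inhibitory configuration
#'
#' The union of the dominant excitatory interval and its two abutting
#' inhibitory flanks: one fused part (flanks touch the dominant).
#' Multi-tone energy confined to this interval does not increase the
#' loudness proxy.
#'
#' @param cfg a [critical_band_config()].
#' @param axis a [tonotopic_axis()].
#' @return an `interval_set` with a single part.
#' @export
critical_interval <- function(cfg, axis) {
  stopifnot(inherits(cfg, "critical_band_config"))
  d <- cfg$dominant
  iset_add(interval_set(c(d$start, d$length), axis), cb_flanks(cfg, axis))
}

#' Loudness proxy of a multi-tone stimulus
#'
#' The length of `(left flank + right flank) * H_m`: the part of the
#' multi-tone interval set that survives the dominant tone's lateral
#' inhibition. While `H_m` stays inside the critical interval and
#' contains the dominant interval, this equals the dominant length
#' exactly (the flat regime of loudness summation); beyond the critical
#' interval it grows by exactly the number of out-of-band cells. With no
#' flanks it reduces to the total length of `H_m`, which grows with every
#' added component (no flat region).
#'
#' @param Hm `interval_set` of the multi-tone stimulus
#'   (see [build_multitone()]).
#' @param cfg a [critical_band_config()].
#' @return cell count (integer).
#' @export
loudness_length <- function(Hm, cfg) {
  stopifnot(inherits(Hm, "interval_set"),
            inherits(cfg, "critical_band_config"))
  total_length(iset_multiply(cb_flanks(cfg, Hm$axis), Hm))
}

#' Loudness-summation curve over component count
#'
#' Evaluates the loudness proxy as components are added one at a time (n
#' = 1 .. `n_max`) to a band around the dominant tone, with the dominant
#' tone's lateral-inhibitory configuration fixed. With non-empty flanks
#' the curve is flat at the dominant length until the band escapes the
#' critical interval, then increases; the deviation point `n_star` (the
#' smallest n with loudness above the dominant length) defines the
#' critical band, `CB = (n_star - 1) * delta` in cells or
#' `(n_star - 1) * delta * df` in frequency units. Lengthening the
#' per-component interval with the abutting flank lengths fixed (a louder
#' stimulus) raises the flat baseline without changing `n_star`.
#'
#' @param stim a [multitone_stimulus()]; its `n_tones` field is ignored
#'   and replaced by the sweep.
#' @param cfg a [critical_band_config()]; for consistency its dominant
#'   interval should be the `n = 1` component (same start and length as
#'   the stimulus template's dominant).
#' @param n_max largest component count evaluated.
#' @param axis a [tonotopic_axis()].
#' @param df frequency bin width used to express the critical band in
#'   frequency units (default 1).
#' @return a list with `curve` (data.frame `n`, `loudness`), `n_star`
#'   (integer or `NA` if the curve never deviates within `n_max`),
#'   `cb_cells` and `cb_freq` (NA when `n_star` is NA).
#' @export
critical_band_curve <- function(stim, cfg, n_max, axis, df = 1) {
  stopifnot(inherits(stim, "multitone_stimulus"), n_max >= 1L)
  loud <- integer(n_max)
  for (n in seq_len(n_max)) {
    s <- stim; s$n_tones <- as.integer(n)
    loud[n] <- loudness_length(build_multitone(s, axis), cfg)
  }
  base <- cfg$dominant$length
  above <- which(loud > base)
  n_star <- if (length(above)) min(above) else NA_integer_
  cb_cells <- if (is.na(n_star)) NA_integer_ else (n_star - 1L) * stim$delta
  list(curve = data.frame(n = seq_len(n_max), loudness = loud),
       n_star = n_star, cb_cells = cb_cells,
       cb_freq = if (is.na(n_star)) NA_real_ else cb_cells * df)
}

#' Loudness of four equally spaced tones versus their separation
#'
#' Four components of equal length are placed at a common start-to-start
#' separation; one of them is the dominant tone carrying the
#' lateral-inhibitory flanks. The loudness proxy is evaluated as the
#' separation is swept: constant at the dominant length while all
#' components stay inside the critical interval, then growing, and
#' approaching the total multi-tone length once the band clears the
#' flanks.
#'
#' @param lam component interval length (cells).
#' @param flank_left_len,flank_right_len flank lengths (cells).
#' @param sep_range increasing vector of separations (>= 0; 0 means all
#'   four components coincide).
#' @param axis a [tonotopic_axis()]; `NULL` auto-sizes one.
#' @param dominant_index which of the four tones (1-based, in ascending
#'   frequency order) is dominant; default the second, i.e. an interior
#'   component near the band centre.
#' @return a `prediction_curve` over separation.
#' @export
four_tone_curve <- function(lam, flank_left_len, flank_right_len, sep_range,
                            axis = NULL, dominant_index = 2L) {
  if (any(sep_range < 0)) stop_placecode("config", "separations must be >= 0")
  if (!dominant_index %in% 1:4)
    stop_placecode("config", "dominant_index must be in 1..4")
  margin <- as.integer(max(flank_left_len, flank_right_len))
  ax <- sweep_axis(margin + 3L * max(sep_range) + lam + margin + 1L, axis)
  lens <- vapply(sep_range, function(d) {
    starts <- margin + (0:3) * d
    Hm <- interval_set(cbind(starts, lam), ax)
    dom <- synaptic_interval(starts[dominant_index], lam)
    cfg <- critical_band_config(dom, flank_left_len, flank_right_len)
    loudness_length(Hm, cfg)
  }, integer(1))
  prediction_curve("four_tone", "separation", sep_range, lens)
}
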
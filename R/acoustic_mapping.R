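#' Discretized acoustic space
#'
#' The acoustic space is two-dimensional: frequency along one axis and
#' sound pressure along the other, both on linear scales. Each axis is
#' partitioned into half-open bins `[f, f + df)` and `[p, p + dp)`; a
#' physical tone is assigned to the bin containing it. For a bijective
#' mapping onto a tonotopic axis, the number of frequency bins must equal
#' the number of admissible interval start points
#' (`n_cells - max_len + 1`) and the number of pressure bins must equal
#' the number of achievable lengths (`max_len`).
#'
#' @param f0 lowest audible frequency (Hz).
#' @param df frequency bin width (Hz).
#' @param n_freq number of frequency bins.
#' @param p0 lowest audible pressure (linear pressure units).
#' @param dp pressure bin width.
#' @param n_press number of pressure bins.
#' @return an object of class `acoustic_space`.
#' @export
acoustic_space <- function(f0, df, n_freq, p0, dp, n_press) {
  n_freq <- as.integer(n_freq); n_press <- as.integer(n_press)
  if (n_freq < 1L || n_press < 1L)
    stop_placecode("config", "need n_freq >= 1 and n_press >= 1")
  if (df <= 0 || dp <= 0)
    stop_placecode("config", "bin widths df and dp must be positive")
  structure(list(f0 = f0, df = df, n_freq = n_freq,
                 p0 = p0, dp = dp, n_press = n_press),
            class = "acoustic_space")
}

#' @export
print.acoustic_space <- function(x, ...) {
  cat(sprintf(paste0("<acoustic_space> %d frequency bins [%g, %g) Hz ",
                     "x %d pressure bins [%g, %g)\n"),
              x$n_freq, x$f0, x$f0 + x$n_freq * x$df,
              x$n_press, x$p0, x$p0 + x$n_press * x$dp))
  invisible(x)
}

#' Acoustic space matched bijectively to an axis
#'
#' Convenience constructor dimensioning the space so that the tone ->
#' interval mapping is one-to-one and onto: one frequency bin per
#' admissible start point, one pressure bin per achievable length.
#'
#' @param axis a [tonotopic_axis()].
#' @param f0,df,p0,dp physical bin origins and widths (defaults: unit bins
#'   from 0).
#' @return an `acoustic_space`.
#' @export
matched_acoustic_space <- function(axis, f0 = 0, df = 1, p0 = 0, dp = 1) {
  acoustic_space(f0, df, n_start_points(axis), p0, dp, axis$max_len)
}

#' A discretized pure tone
#'
#' A pure tone after assignment to frequency/pressure bins. Indices are
#' 0-based.
#'
#' @param f_index frequency bin index, `0 <= f_index < n_freq`.
#' @param p_index pressure bin index, `0 <= p_index < n_press`.
#' @param space optional `acoustic_space` used to range-check the indices.
#' @return an object of class `tone`.
#' @export
tone <- function(f_index, p_index, space = NULL) {
  f_index <- as.integer(f_index); p_index <- as.integer(p_index)
  if (anyNA(f_index) || anyNA(p_index) || f_index < 0L || p_index < 0L)
    stop_placecode("bounds", "tone indices must be non-negative")
  if (!is.null(space)) {
    if (f_index >= space$n_freq || p_index >= space$n_press)
      stop_placecode("bounds", "tone indices outside the acoustic space")
  }
  structure(list(f_index = f_index, p_index = p_index), class = "tone")
}

#' @export
print.tone <- function(x, ...) {
  cat(sprintf("<tone> f_index %d, p_index %d\n", x$f_index, x$p_index))
  invisible(x)
}

#' Assign a physical tone to its acoustic bins
#'
#' Half-open binning: a frequency in `[f0 + k*df, f0 + (k+1)*df)` is
#' assigned to bin `k`, and likewise for pressure. Values outside the
#' audible ranges raise an audibility error.
#'
#' @param f frequency (Hz).
#' @param p pressure (linear units).
#' @param space an [acoustic_space()].
#' @return a [tone()].
#' @examples
#' sp <- acoustic_space(100, 50, 10, 1, 0.5, 8)
#' quantize(115, 1.2, sp)  # f_index 0, p_index 0
#' @export
quantize <- function(f, p, space) {
  stopifnot(inherits(space, "acoustic_space"))
  fi <- floor((f - space$f0) / space$df)
  pi_ <- floor((p - space$p0) / space$dp)
  if (is.na(fi) || fi < 0 || fi >= space$n_freq)
    stop_placecode("audibility", "frequency outside the audible range")
  if (is.na(pi_) || pi_ < 0 || pi_ >= space$n_press)
    stop_placecode("audibility", "pressure outside the audible range")
  tone(fi, pi_, space)
}

#' Map a tone to its synaptic interval
#'
#' The place-code mapping: frequency carries to location (the interval's
#' closed end sits at cell `f_index`) and pressure carries to length (the
#' lowest audible pressure gives a one-cell interval, each pressure step
#' adds one cell, growing rightward). With a matched acoustic space the
#' mapping is bijective.
#'
#' @param t a [tone()].
#' @param axis a [tonotopic_axis()].
#' @return a [synaptic_interval()] with `start = f_index` and
#'   `length = p_index + 1`.
#' @export
map_tone <- function(t, axis) {
  stopifnot(inherits(t, "tone"), inherits(axis, "tonotopic_axis"))
  len <- t$p_index + 1L
  if (len > axis$max_len || t$f_index > axis$n_cells - axis$max_len)
    stop_placecode("mapping", "tone exceeds the axis coding capacity")
  synaptic_interval(t$f_index, len)
}

#' Decode an interval set back to tones
#'
#' Inverse of [map_tone()] applied part-wise. Every canonical part must be
#' a valid codeword (start within the admissible start-point set, length
#' within the achievable lengths); otherwise a not-a-codeword error is
#' raised. Decoding is inherently ambiguous for fused parts: a single part
#' could also have arisen from several overlapping lower-pressure tones or
#' band-limited noise, so the result always carries an `ambiguous` flag.
#'
#' @param s an `interval_set`.
#' @param axis the [tonotopic_axis()].
#' @return a list with `tones` (list of [tone()], one per part, possibly
#'   empty) and `ambiguous` (logical: `TRUE` whenever the set is
#'   non-empty).
#' @export
decode_interval <- function(s, axis) {
  stopifnot(inherits(s, "interval_set"))
  if (!same_axis(s$axis, axis))
    stop_placecode("axis", "interval set is not on the given axis")
  tones <- vector("list", n_parts(s))
  for (i in seq_along(tones)) {
    if (s$length[i] > axis$max_len ||
        s$start[i] > axis$n_cells - axis$max_len)
      stop_placecode("codeword",
                     sprintf("part [%d,%d) is not a codeword on this axis",
                             s$start[i], s$start[i] + s$length[i]))
    tones[[i]] <- tone(s$start[i], s$length[i] - 1L)
  }
  list(tones = tones, ambiguous = n_parts(s) > 0L)
}

#' Encode a multi-tone stimulus as an interval set
#'
#' Maps each tone to its interval and adds (unions) the results.
#' Overlapping or adjacent tone intervals fuse, so the encoding of a
#' complex sound is generally not invertible tone-by-tone.
#'
#' @param tones list of [tone()] objects (may be empty).
#' @param axis a [tonotopic_axis()].
#' @return an `interval_set`.
#' @export
encode_stimulus <- function(tones, axis) {
  ivs <- lapply(tones, map_tone, axis = axis)
  interval_set(ivs, axis)
}

#' Coding capacity of flexible versus columnar place codes
#'
#' With `n_cells` cells on the tonotopic axis and sound pressure encoded
#' by how many neurons are active, two architectures compete:
#'
#' * `"columnar"`: the axis is divided into non-overlapping fixed columns,
#'   frequency selects the column and pressure the count of active neurons
#'   inside it, so `|F| * |P| = n_cells` and `|P| = n_cells / |F|`.
#' * `"flexible"`: intervals with movable borders; frequency selects the
#'   start point and pressure the length, so `|F| = n_cells - |P| + 1`
#'   (equivalently `n_cells = |F| + |P| - 1`).
#'
#' For any `|F|, |P| >= 2` the flexible scheme needs strictly fewer cells.
#'
#' @param scheme `"flexible"` or `"columnar"`.
#' @param n_cells axis size.
#' @param fixed_levels the given number of levels: for `"flexible"` the
#'   pressure level count `|P|` (returns `|F|`); for `"columnar"` the
#'   frequency level count `|F|` (returns `|P|`).
#' @return the achievable number of levels on the other axis (integer).
#' @examples
#' coding_capacity("flexible", 14, 5)   # 10 frequencies
#' coding_capacity("columnar", 50, 10)  # 5 pressure levels
#' @export
coding_capacity <- function(scheme = c("flexible", "columnar"),
                            n_cells, fixed_levels) {
  scheme <- match.arg(scheme)
  n_cells <- as.integer(n_cells); fixed_levels <- as.integer(fixed_levels)
  if (n_cells < 1L || fixed_levels < 1L)
    stop_placecode("config", "n_cells and fixed_levels must be >= 1")
  if (scheme == "flexible") {
    if (fixed_levels > n_cells)
      stop_placecode("config", "|P| cannot exceed n_cells")
    n_cells - fixed_levels + 1L
  } else {
    if (n_cells %% fixed_levels != 0L)
      stop_placecode("config",
                     "columnar scheme needs n_cells divisible by |F|")
    n_cells %/% fixed_levels
  }
}
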
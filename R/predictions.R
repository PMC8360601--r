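#' @title Predicted interval-length curves
#' @description Closed-form predictions for how the total length of the
#'   active interval set changes as one stimulus parameter is swept, for
#'   the canonical excitatory/inhibitory configurations. Every curve is
#'   computed by actually evaluating the interval algebra on a
#'   sufficiently large axis -- the closed forms quoted in the details are
#'   consequences, not the implementation.
#' @name predictions
NULL

prediction_curve <- function(panel, param_name, param, length) {
  stopifnot(length(param) == length(length))
  if (is.unsorted(param, strictly = TRUE))
    stop_placecode("config", "swept parameter values must strictly increase")
  structure(data.frame(param = as.integer(param),
                       length = as.integer(length)),
            panel = panel, param_name = param_name,
            class = c("prediction_curve", "data.frame"))
}

#' @export
print.prediction_curve <- function(x, ...) {
  cat(sprintf("<prediction_curve> panel %s, sweeping %s (%d points)\n",
              attr(x, "panel"), attr(x, "param_name"), nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

# Axis sized so that intervals placed at `offset` origin never clip. All
# prediction sweeps share this: a user-supplied axis is honoured (clipping
# then raises a bounds error rather than truncating silently).
sweep_axis <- function(extent, axis = NULL) {
  if (is.null(axis)) return(tonotopic_axis(max(extent, 1L)))
  axis
}

iset1 <- function(start, len, axis) {
  if (len <= 0L) interval_set(NULL, axis)
  else interval_set(c(start, len), axis)
}

#' Addition of two co-located intervals of different lengths
#'
#' Two intervals share a start point (e.g. binaural inputs from the same
#' tone); the length of one is fixed while the other is swept. The total
#' length of the sum equals the longer summand: constant at `len_fixed`
#' then rising linearly once the swept length exceeds it.
#'
#' @param len_fixed length of the fixed interval (cells).
#' @param len_range increasing integer vector of swept lengths.
#' @param axis optional [tonotopic_axis()]; auto-sized when `NULL`.
#' @return a `prediction_curve` (`length == max(len_fixed, len)`).
#' @export
addition_same_start <- function(len_fixed, len_range, axis = NULL) {
  ax <- sweep_axis(max(len_fixed, len_range), axis)
  a <- iset1(0L, len_fixed, ax)
  lens <- vapply(len_range, function(l)
    total_length(iset_add(a, iset1(0L, l, ax))), integer(1))
  prediction_curve("addition_same_start", "length", len_range, lens)
}

#' Addition of two intervals with increasing separation
#'
#' Two equal-length intervals, one shifted rightward by a swept distance.
#' Total length is `len + min(d, len)`: rising linearly from `len` at
#' complete overlap and plateauing at `2 * len` once disjoint.
#'
#' @param len interval length (cells).
#' @param sep_range increasing vector of start-to-start separations (>= 0).
#' @param axis optional axis; auto-sized when `NULL`.
#' @return a `prediction_curve`.
#' @export
addition_shifted <- function(len, sep_range, axis = NULL) {
  if (any(sep_range < 0)) stop_placecode("config", "separations must be >= 0")
  ax <- sweep_axis(len + max(sep_range) + len, axis)
  a <- iset1(0L, len, ax)
  lens <- vapply(sep_range, function(d)
    total_length(iset_add(a, iset1(d, len, ax))), integer(1))
  prediction_curve("addition_shifted", "separation", sep_range, lens)
}

#' Multiplication by a co-located inhibitory interval of growing length
#'
#' Excitatory and inhibitory intervals share a start point (feedforward
#' co-activation); the inhibitory length is swept. The product length is
#' `max(0, len_exc - len_inh)`, reaching the empty set once the inhibitor
#' covers the whole excitatory interval.
#'
#' @param len_exc excitatory interval length (cells).
#' @param len_inh_range increasing vector of inhibitory lengths (0 allowed).
#' @param axis optional axis; auto-sized when `NULL`.
#' @return a `prediction_curve`.
#' @export
multiplication_same_start <- function(len_exc, len_inh_range, axis = NULL) {
  ax <- sweep_axis(max(len_exc, len_inh_range), axis)
  e <- iset1(0L, len_exc, ax)
  lens <- vapply(len_inh_range, function(l)
    total_length(iset_multiply(iset1(0L, l, ax), e)), integer(1))
  prediction_curve("multiplication_same_start", "length", len_inh_range, lens)
}

#' Multiplication by an inhibitory interval shifted to the right
#'
#' The inhibitory interval starts `d` cells to the right of the excitatory
#' one. For equal lengths the product length is `min(d, len_exc)`: zero at
#' complete overlap, rising linearly, plateauing once disjoint.
#'
#' @param len_exc excitatory length (cells).
#' @param len_inh inhibitory length (cells).
#' @param sep_range increasing vector of separations (>= 0).
#' @param axis optional axis; auto-sized when `NULL`.
#' @return a `prediction_curve`.
#' @export
multiplication_shifted <- function(len_exc, len_inh, sep_range, axis = NULL) {
  if (any(sep_range < 0)) stop_placecode("config", "separations must be >= 0")
  ax <- sweep_axis(max(len_exc, max(sep_range) + len_inh), axis)
  e <- iset1(0L, len_exc, ax)
  lens <- vapply(sep_range, function(d)
    total_length(iset_multiply(iset1(d, len_inh, ax), e)), integer(1))
  prediction_curve("multiplication_shifted", "separation", sep_range, lens)
}

#' Two excitatory intervals moved apart across a fixed inhibitory interval
#'
#' The inhibitory interval is fixed; at shift 0 both excitatory intervals
#' are centered on it. One excitatory interval moves left by `s`, the
#' other right by `s`. The product length is zero while both stay inside
#' the inhibitor, then rises to `2 * len_exc` at full disjointness; for
#' `len_exc == len_inh` it equals `2 * min(s, len_exc)`.
#'
#' @param len_exc excitatory interval length (cells).
#' @param len_inh inhibitory interval length (cells).
#' @param shift_range increasing vector of per-interval shifts `s` (>= 0).
#' @param axis optional axis; auto-sized when `NULL`.
#' @return a `prediction_curve`.
#' @export
two_exc_one_inh <- function(len_exc, len_inh, shift_range, axis = NULL) {
  if (any(shift_range < 0)) stop_placecode("config", "shifts must be >= 0")
  smax <- max(shift_range)
  origin <- as.integer(smax + len_exc)          # keeps E1 on the axis
  ax <- sweep_axis(2L * origin + max(len_exc, len_inh) + smax + len_exc, axis)
  x_i <- origin                                  # inhibitor start
  # at s = 0 the E intervals are centered on the inhibitor's span
  e0 <- x_i + (len_inh - len_exc) %/% 2L
  inh <- iset1(x_i, len_inh, ax)
  lens <- vapply(shift_range, function(s) {
    ee <- iset_add(iset1(e0 - s, len_exc, ax), iset1(e0 + s, len_exc, ax))
    total_length(iset_multiply(inh, ee))
  }, integer(1))
  prediction_curve("two_exc_one_inh", "shift", shift_range, lens)
}

# one centre-surround composite: flanks abut the excitatory part
cs_triplet <- function(start, len_exc, len_flank, ax) {
  list(exc = iset1(start, len_exc, ax),
       inh = iset_add(iset1(start - len_flank, len_flank, ax),
                      iset1(start + len_exc, len_flank, ax)))
}

#' Two centre-surround composites at increasing separation
#'
#' Each composite is an excitatory interval flanked by two abutting
#' inhibitory intervals (I-E-I). One composite is fixed, the other starts
#' `d` cells to its right.
#'
#' * `mode = "simultaneous"` evaluates the full expression
#'   `(all four I) * (both E)` at each separation. The curve starts at
#'   `len_exc` (coincident composites), dips towards zero while each
#'   excitatory interval overlaps the other's flank, then rises to a
#'   plateau of `2 * len_exc` once the composites no longer interact.
#' * `mode = "sequential"` evaluates each triplet alone and adds
#'   (interval-set union of) the two products, emulating delivering the
#'   inputs one at a time; this curve rises monotonically with no dip,
#'   resembling plain addition of the two excitatory intervals.
#'
#' The two modes differ because multiplication is not right distributive:
#' delivered separately, each excitatory interval never meets the other
#' composite's flanks.
#'
#' @param len_exc excitatory interval length (cells).
#' @param len_flank flank length (cells); 0 disables the surround.
#' @param sep_range increasing vector of separations (>= 0).
#' @param mode `"simultaneous"` or `"sequential"`.
#' @param axis optional axis; auto-sized when `NULL`.
#' @return a `prediction_curve`.
#' @export
center_surround <- function(len_exc, len_flank, sep_range,
                            mode = c("simultaneous", "sequential"),
                            axis = NULL) {
  mode <- match.arg(mode)
  if (any(sep_range < 0)) stop_placecode("config", "separations must be >= 0")
  origin <- as.integer(len_flank)
  ax <- sweep_axis(origin + max(sep_range) + len_exc + len_flank, axis)
  t1 <- cs_triplet(origin, len_exc, len_flank, ax)
  lens <- vapply(sep_range, function(d) {
    t2 <- cs_triplet(origin + d, len_exc, len_flank, ax)
    if (mode == "simultaneous") {
      total_length(iset_multiply(iset_add(t1$inh, t2$inh),
                                 iset_add(t1$exc, t2$exc)))
    } else {
      total_length(iset_add(iset_multiply(t1$inh, t1$exc),
                            iset_multiply(t2$inh, t2$exc)))
    }
  }, integer(1))
  prediction_curve(paste0("center_surround_", mode), "separation",
                   sep_range, lens)
}
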
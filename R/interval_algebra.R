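#' Discretized tonotopic axis
#'
#' The neural space is a one-dimensional axis partitioned into `n_cells`
#' cell-width sections. Synaptic intervals are half-open spans `[start,
#' start + length)` of whole cells on this axis, with lengths between 1 and
#' `max_len` cells. The admissible start points for a full-length interval
#' form the set `0, 1, ..., n_cells - max_len`.
#'
#' All lengths and positions are held in cell units; `dx` records the
#' physical width of one cell for conversion at the edges (e.g. to microns
#' or, through an acoustic space, to frequency bins).
#'
#' @param n_cells number of cells (positive integer).
#' @param max_len maximum achievable interval length, in cells; defaults to
#'   `n_cells`.
#' @param dx physical width of one cell (abstract units, default 1).
#' @return an object of class `tonotopic_axis`.
#' @examples
#' ax <- tonotopic_axis(64, max_len = 16)
#' n_start_points(ax)  # 49
#' @export
tonotopic_axis <- function(n_cells, max_len = n_cells, dx = 1) {
  n_cells <- as.integer(n_cells)
  max_len <- as.integer(max_len)
  if (length(n_cells) != 1L || is.na(n_cells) || n_cells < 1L)
    stop_placecode("config", "n_cells must be a positive integer")
  if (length(max_len) != 1L || is.na(max_len) || max_len < 1L ||
      max_len > n_cells)
    stop_placecode("config", "max_len must satisfy 1 <= max_len <= n_cells")
  if (!is.numeric(dx) || length(dx) != 1L || dx <= 0)
    stop_placecode("config", "dx must be a positive scalar")
  structure(list(n_cells = n_cells, max_len = max_len, dx = dx),
            class = "tonotopic_axis")
}

#' @export
print.tonotopic_axis <- function(x, ...) {
  cat(sprintf("<tonotopic_axis> %d cells, max interval length %d, dx = %g\n",
              x$n_cells, x$max_len, x$dx))
  invisible(x)
}

#' Number of admissible interval start points
#'
#' @param axis a [tonotopic_axis()].
#' @return `n_cells - max_len + 1`, the size of the start-point set.
#' @export
n_start_points <- function(axis) {
  stopifnot(inherits(axis, "tonotopic_axis"))
  axis$n_cells - axis$max_len + 1L
}

same_axis <- function(a, b) {
  a$n_cells == b$n_cells && a$max_len == b$max_len &&
    isTRUE(all.equal(a$dx, b$dx))
}

stop_placecode <- function(kind, msg, call = sys.call(-1)) {
  stop(errorCondition(msg,
                      class = c(paste0("placecode_", kind, "_error"),
                                "placecode_error"),
                      call = call))
}

#' A single synaptic interval
#'
#' A half-open span `[start, start + length)` of contiguous cells. The
#' closed (left) end identifies the interval's location on the tonotopic
#' axis; the length is a whole number of cells. Starts are 0-based.
#'
#' @param start 0-based cell index of the closed end.
#' @param length number of cells covered (>= 1).
#' @return an object of class `synaptic_interval`.
#' @examples
#' synaptic_interval(3, 5)  # covers cells 3..7
#' @export
synaptic_interval <- function(start, length) {
  start <- as.integer(start); length <- as.integer(length)
  if (anyNA(start) || anyNA(length) || start < 0L || length < 1L)
    stop_placecode("bounds", "need start >= 0 and length >= 1")
  structure(list(start = start, length = length), class = "synaptic_interval")
}

#' @export
print.synaptic_interval <- function(x, ...) {
  cat(sprintf("<synaptic_interval> [%d, %d)  (%d cells)\n",
              x$start, x$start + x$length, x$length))
  invisible(x)
}

as_interval_matrix <- function(x) {
  if (is.null(x) || (is.list(x) && length(x) == 0L))
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "length"))))
  if (inherits(x, "synaptic_interval"))
    return(matrix(c(x$start, x$length), ncol = 2L,
                  dimnames = list(NULL, c("start", "length"))))
  if (inherits(x, "interval_set"))
    return(cbind(start = x$start, length = x$length))
  if (is.numeric(x) && is.null(dim(x)) && length(x) == 2L) {
    return(matrix(as.integer(x), ncol = 2L,
                  dimnames = list(NULL, c("start", "length"))))
  }
  if (is.matrix(x) || is.data.frame(x)) {
    m <- as.matrix(x)
    storage.mode(m) <- "integer"
    colnames(m) <- c("start", "length")
    return(m)
  }
  if (is.list(x)) {
    m <- do.call(rbind, lapply(x, function(iv) {
      if (inherits(iv, "synaptic_interval")) c(iv$start, iv$length)
      else as.integer(iv)
    }))
    colnames(m) <- c("start", "length")
    storage.mode(m) <- "integer"
    return(m)
  }
  stop_placecode("config", "cannot interpret input as intervals")
}

#' Canonical set of synaptic intervals
#'
#' Builds the unique canonical form of a collection of half-open intervals
#' on one axis: parts sorted by start, pairwise disjoint, with touching or
#' overlapping spans merged (`[a,b) U [b,c) = [a,c)`). The empty set is a
#' first-class value (it arises as the product of an excitatory interval
#' with an inhibitory interval that covers it).
#'
#' `interval_set()` *is* the canonicalization operation: whatever raw
#' intervals it receives, the result covers exactly the union of their
#' spans in canonical form.
#'
#' @param x intervals: `NULL` (empty set), a [synaptic_interval()], a list
#'   of them, a list of `c(start, length)` pairs, or a two-column
#'   matrix/data.frame of starts and lengths.
#' @param axis the [tonotopic_axis()] the set lives on.
#' @return an object of class `interval_set` with integer vectors `start`
#'   and `length` (canonical parts) and the `axis`.
#' @examples
#' ax <- tonotopic_axis(20)
#' interval_set(list(c(0, 5), c(5, 3)), ax)  # one part [0, 8)
#' @export
interval_set <- function(x = NULL, axis) {
  if (!inherits(axis, "tonotopic_axis"))
    stop_placecode("config", "axis must be a tonotopic_axis")
  m <- as_interval_matrix(x)
  if (nrow(m) > 0L) {
    if (anyNA(m) || any(m[, "length"] < 1L) || any(m[, "start"] < 0L) ||
        any(m[, "start"] + m[, "length"] > axis$n_cells))
      stop_placecode("bounds", "interval out of axis bounds")
    o <- order(m[, "start"], m[, "length"])
    m <- m[o, , drop = FALSE]
    starts <- m[, "start"]; ends <- m[, "start"] + m[, "length"]
    ks <- integer(0); ke <- integer(0)
    cs <- starts[1L]; ce <- ends[1L]
    if (nrow(m) > 1L) {
      for (i in 2L:nrow(m)) {
        if (starts[i] <= ce) {          # overlap or adjacency: merge
          if (ends[i] > ce) ce <- ends[i]
        } else {
          ks <- c(ks, cs); ke <- c(ke, ce)
          cs <- starts[i]; ce <- ends[i]
        }
      }
    }
    ks <- c(ks, cs); ke <- c(ke, ce)
    start <- as.integer(ks); len <- as.integer(ke - ks)
  } else {
    start <- integer(0); len <- integer(0)
  }
  structure(list(start = start, length = len, axis = axis),
            class = "interval_set")
}

#' @export
print.interval_set <- function(x, ...) {
  if (length(x$start) == 0L) {
    cat("<interval_set> {} (empty)\n")
  } else {
    parts <- sprintf("[%d,%d)", x$start, x$start + x$length)
    cat(sprintf("<interval_set> %s  (total length %d)\n",
                paste(parts, collapse = " U "), total_length(x)))
  }
  invisible(x)
}

#' Number of parts in an interval set
#' @param s an `interval_set`.
#' @return integer count of canonical parts.
#' @export
n_parts <- function(s) length(s$start)

#' Total length of an interval set
#'
#' The number of distinct cells covered. Because parts are canonical
#' (disjoint), this is the sum of part lengths. Addition is sublinear in
#' this measure: `total_length(a + b) <= total_length(a) + total_length(b)`.
#'
#' @param s an `interval_set` or `synaptic_interval`.
#' @return cell count (integer).
#' @export
total_length <- function(s) UseMethod("total_length")

#' @export
total_length.interval_set <- function(s) sum(s$length)

#' @export
total_length.synaptic_interval <- function(s) s$length

#' Cells covered by an interval set
#'
#' @param s an `interval_set`.
#' @return sorted integer vector of 0-based cell indices covered by `s`.
#' @export
iset_cells <- function(s) {
  if (n_parts(s) == 0L) return(integer(0))
  unlist(lapply(seq_along(s$start),
                function(i) seq.int(s$start[i], length.out = s$length[i])))
}

check_same_axis <- function(a, b) {
  if (!same_axis(a$axis, b$axis))
    stop_placecode("axis", "interval sets live on different axes")
}

#' Addition of interval sets (union)
#'
#' Addition of synaptic intervals is their set union: overlapping or
#' adjacent parts fuse into a single longer interval, disjoint parts stay
#' separate. If the summands share a start point the total length equals
#' the length of the longer summand. Addition has no inverse, which is why
#' the effect of inhibition needs a separate multiplication operation.
#'
#' Also available as the `+` operator on `interval_set` objects.
#'
#' @param a,b `interval_set` objects on the same axis.
#' @return the canonical `interval_set` covering `a` union `b`.
#' @examples
#' ax <- tonotopic_axis(32)
#' iset_add(interval_set(c(0, 10), ax), interval_set(c(5, 10), ax))
#' @export
iset_add <- function(a, b) {
  stopifnot(inherits(a, "interval_set"), inherits(b, "interval_set"))
  check_same_axis(a, b)
  interval_set(rbind(cbind(a$start, a$length), cbind(b$start, b$length)),
               a$axis)
}

#' Multiplication of interval sets (set minus)
#'
#' Multiplication of an excitatory interval set by an inhibitory one is
#' the set difference `exc \ inh`: the inhibitor eliminates the cells it
#' shares with the multiplicand. The product is always a subset of `exc`;
#' it may shorten a part, shift its closed end, split a part in two, or
#' empty it entirely. The inhibitor comes first, mirroring the notation
#' `hI . hE`.
#'
#' Multiplication is left distributive over addition
#' (`I * (A + B) == I * A + I * B`) but not right distributive:
#' `(I1 + I2) * E` removes `I1 U I2` whereas
#' `I1 * E + I2 * E` removes only `I1` intersect `I2`.
#'
#' Also available as `inh * exc` on `interval_set` objects.
#'
#' @param inh inhibitory `interval_set` (the multiplier).
#' @param exc excitatory `interval_set` (the multiplicand).
#' @return the canonical `interval_set` covering `exc \ inh`.
#' @examples
#' ax <- tonotopic_axis(32)
#' iset_multiply(interval_set(c(4, 2), ax), interval_set(c(0, 10), ax))
#' @export
iset_multiply <- function(inh, exc) {
  stopifnot(inherits(inh, "interval_set"), inherits(exc, "interval_set"))
  check_same_axis(inh, exc)
  if (n_parts(exc) == 0L || n_parts(inh) == 0L) return(exc)
  out_s <- integer(0); out_l <- integer(0)
  istart <- inh$start; iend <- inh$start + inh$length
  for (k in seq_along(exc$start)) {
    s <- exc$start[k]; e <- s + exc$length[k]
    # walk the inhibitory parts overlapping [s, e)
    for (j in seq_along(istart)) {
      if (iend[j] <= s) next
      if (istart[j] >= e) break
      if (istart[j] > s) {              # keep the uncovered prefix
        out_s <- c(out_s, s); out_l <- c(out_l, istart[j] - s)
      }
      s <- max(s, iend[j])
      if (s >= e) break
    }
    if (s < e) { out_s <- c(out_s, s); out_l <- c(out_l, e - s) }
  }
  interval_set(cbind(out_s, out_l), exc$axis)
}

#' @export
Ops.interval_set <- function(e1, e2) {
  switch(.Generic,
         "+" = iset_add(e1, e2),
         "*" = iset_multiply(e1, e2),
         "==" = iset_equal(e1, e2),
         "!=" = !iset_equal(e1, e2),
         stop_placecode("config",
                        paste0("operator '", .Generic,
                               "' not defined for interval sets")))
}

#' Equality of interval sets
#'
#' Canonical forms are unique, so equality is part-wise identity.
#'
#' @param a,b `interval_set` objects on the same axis.
#' @return logical scalar.
#' @export
iset_equal <- function(a, b) {
  check_same_axis(a, b)
  identical(a$start, b$start) && identical(a$length, b$length)
}

#' Serialize an interval set to text
#'
#' Plain-text round-trip form: comma-separated `start:length` pairs (empty
#' string for the empty set). Used in CSV outputs and fixtures.
#'
#' @param s an `interval_set`.
#' @return a single string.
#' @seealso [iset_parse()]
#' @export
iset_format <- function(s) {
  stopifnot(inherits(s, "interval_set"))
  if (n_parts(s) == 0L) return("")
  paste(sprintf("%d:%d", s$start, s$length), collapse = ",")
}

#' Parse the text form of an interval set
#'
#' @param txt string as produced by [iset_format()].
#' @param axis the [tonotopic_axis()] for the result.
#' @return an `interval_set`.
#' @export
iset_parse <- function(txt, axis) {
  stopifnot(is.character(txt), length(txt) == 1L)
  txt <- trimws(txt)
  if (nchar(txt) == 0L) return(interval_set(NULL, axis))
  pieces <- strsplit(txt, ",", fixed = TRUE)[[1L]]
  m <- do.call(rbind, lapply(pieces, function(p) {
    sl <- as.integer(strsplit(trimws(p), ":", fixed = TRUE)[[1L]])
    if (length(sl) != 2L || anyNA(sl))
      stop_placecode("config", paste0("malformed interval '", p, "'"))
    sl
  }))
  interval_set(m, axis)
}
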
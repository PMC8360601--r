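# Brute-force boolean-array oracle for the interval algebra. A set of
# half-open cell intervals is represented as a logical occupancy vector
# over the axis; union and set-minus are elementwise | and & !. The
# oracle is deliberately independent of the interval_set implementation.

bits_new <- function(axis) rep(FALSE, axis$n_cells)

bits_from <- function(pairs, axis) {
  b <- bits_new(axis)
  for (p in pairs)
    if (p[2] > 0) b[seq.int(p[1] + 1L, length.out = p[2])] <- TRUE
  b
}

bits_of <- function(s) {
  b <- bits_new(s$axis)
  b[iset_cells(s) + 1L] <- TRUE
  b
}

bits_union <- function(a, b) a | b
bits_minus <- function(exc, inh) exc & !inh
bits_len <- function(b) sum(b)

# random canonical interval set on an axis (may be empty)
random_iset <- function(axis, max_parts = 3L) {
  k <- sample(0:max_parts, 1L)
  if (k == 0L) return(interval_set(NULL, axis))
  len <- sample.int(axis$n_cells, k, replace = TRUE)
  start <- vapply(len, function(l)
    sample.int(axis$n_cells - l + 1L, 1L) - 1L, integer(1))
  interval_set(cbind(start, len), axis)
}

expect_iset_bits <- function(s, bits) {
  expect_identical(bits_of(s), bits)
  expect_identical(total_length(s), as.integer(sum(bits)))
}
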
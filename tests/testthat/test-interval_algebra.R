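ax <- tonotopic_axis(64, max_len = 16)

test_that("axis invariants and start-point set", {
  expect_equal(n_start_points(ax), 64 - 16 + 1)
  expect_equal(n_start_points(tonotopic_axis(5, 5)), 1L)
  expect_error(tonotopic_axis(0), class = "placecode_config_error")
  expect_error(tonotopic_axis(10, 11), class = "placecode_config_error")
})

test_that("canonicalization merges, sorts, and keeps empties first-class", {
  a <- tonotopic_axis(20)
  # half-open adjacency fuses: [0,5) U [5,8) = [0,8)
  s <- interval_set(list(c(0, 5), c(5, 3)), a)
  expect_equal(s$start, 0L)
  expect_equal(s$length, 8L)
  # sorting without merging across a gap
  s <- interval_set(list(c(3, 2), c(0, 2)), a)
  expect_equal(s$start, c(0L, 3L))
  expect_equal(s$length, c(2L, 2L))
  # empty set
  s <- interval_set(NULL, a)
  expect_equal(n_parts(s), 0L)
  expect_equal(total_length(s), 0L)
  # duplicates and containment collapse
  s <- interval_set(list(c(2, 6), c(3, 2), c(2, 6)), a)
  expect_equal(cbind(s$start, s$length), cbind(2L, 6L))
  expect_error(interval_set(c(15, 10), a), class = "placecode_bounds_error")
  expect_error(interval_set(c(-1, 3), a), class = "placecode_bounds_error")
})

test_that("addition fuses overlaps and keeps disjoint parts", {
  a <- tonotopic_axis(40)
  I <- function(s, l) interval_set(c(s, l), a)
  # same start: length of the longer summand
  expect_equal(total_length(iset_add(I(0, 10), I(0, 6))), 10L)
  # disjoint: the same two intervals
  r <- iset_add(I(0, 10), I(15, 5))
  expect_equal(r$start, c(0L, 15L))
  expect_equal(r$length, c(10L, 5L))
  # overlap: fused, sublinear
  r <- iset_add(I(0, 10), I(5, 10))
  expect_equal(cbind(r$start, r$length), cbind(0L, 15L))
  expect_lt(total_length(r), 10L + 10L)
  # operator sugar
  expect_true(iset_equal(I(0, 10) + I(5, 10), r))
})

test_that("multiplication removes shared cells, may empty or split", {
  a <- tonotopic_axis(40)
  I <- function(s, l) interval_set(c(s, l), a)
  # complete cancellation -> empty set
  expect_equal(n_parts(iset_multiply(I(0, 10), I(0, 10))), 0L)
  # disjoint multiplier leaves multiplicand unaffected
  expect_true(iset_equal(iset_multiply(I(0, 5), I(10, 5)), I(10, 5)))
  # interior multiplier splits one interval into two
  r <- iset_multiply(I(4, 2), I(0, 10))
  expect_equal(r$start, c(0L, 6L))
  expect_equal(r$length, c(4L, 4L))
  expect_equal(total_length(r), 8L)
  # operator form: inh * exc
  expect_true(iset_equal(I(4, 2) * I(0, 10), r))
})

test_that("axis mismatch is rejected", {
  a <- tonotopic_axis(20); b <- tonotopic_axis(30)
  expect_error(iset_add(interval_set(c(0, 2), a), interval_set(c(0, 2), b)),
               class = "placecode_axis_error")
  expect_error(iset_multiply(interval_set(c(0, 2), a),
                             interval_set(c(0, 2), b)),
               class = "placecode_axis_error")
})

test_that("add and multiply agree exactly with the bitmask oracle", {
  set.seed(42)
  ok <- TRUE
  for (i in 1:2000) {
    axis <- tonotopic_axis(sample(1:64, 1L))
    a <- random_iset(axis); b <- random_iset(axis)
    ok <- ok &&
      identical(bits_of(iset_add(a, b)),
                bits_union(bits_of(a), bits_of(b))) &&
      identical(bits_of(iset_multiply(a, b)),
                bits_minus(bits_of(b), bits_of(a)))
    if (!ok) break
  }
  expect_true(ok)
})

test_that("algebraic laws: commutative, associative, idempotent, identity", {
  set.seed(7)
  axis <- tonotopic_axis(48)
  e <- interval_set(NULL, axis)
  ok <- TRUE
  for (i in 1:200) {
    a <- random_iset(axis); b <- random_iset(axis); c <- random_iset(axis)
    ok <- ok && iset_equal(iset_add(a, b), iset_add(b, a)) &&
      iset_equal(iset_add(iset_add(a, b), c),
                 iset_add(a, iset_add(b, c))) &&
      iset_equal(iset_add(a, a), a) &&
      iset_equal(iset_add(a, e), a) &&
      total_length(iset_add(a, b)) <= total_length(a) + total_length(b)
    if (!ok) break
  }
  expect_true(ok)
})

test_that("left distributivity holds on random triples", {
  set.seed(11)
  axis <- tonotopic_axis(48)
  ok <- TRUE
  for (i in 1:500) {
    I <- random_iset(axis); A <- random_iset(axis); B <- random_iset(axis)
    ok <- ok && iset_equal(iset_multiply(I, iset_add(A, B)),
                           iset_add(iset_multiply(I, A),
                                    iset_multiply(I, B)))
    if (!ok) break
  }
  expect_true(ok)
})

test_that("right distributivity fails as E\\(I1 u I2) vs E\\(I1 n I2)", {
  axis <- tonotopic_axis(20)
  I1 <- interval_set(c(0, 5), axis)
  I2 <- interval_set(c(5, 5), axis)
  E <- interval_set(c(0, 10), axis)
  lhs <- iset_multiply(iset_add(I1, I2), E)
  rhs <- iset_add(iset_multiply(I1, E), iset_multiply(I2, E))
  expect_false(iset_equal(lhs, rhs))
  # lhs == E \ (I1 u I2), rhs == E \ (I1 n I2), by the oracle
  b1 <- bits_of(I1); b2 <- bits_of(I2); be <- bits_of(E)
  expect_iset_bits(lhs, bits_minus(be, b1 | b2))
  expect_iset_bits(rhs, bits_minus(be, b1 & b2))
  # equal multipliers restore equality
  expect_true(iset_equal(iset_multiply(iset_add(I1, I1), E),
                         iset_add(iset_multiply(I1, E),
                                  iset_multiply(I1, E))))
  # randomized check of the two closed forms
  set.seed(13)
  ok <- TRUE
  for (i in 1:200) {
    A <- random_iset(axis); B <- random_iset(axis); X <- random_iset(axis)
    ok <- ok &&
      identical(bits_of(iset_multiply(iset_add(A, B), X)),
                bits_minus(bits_of(X), bits_of(A) | bits_of(B))) &&
      identical(bits_of(iset_add(iset_multiply(A, X),
                                 iset_multiply(B, X))),
                bits_minus(bits_of(X), bits_of(A) & bits_of(B)))
    if (!ok) break
  }
  expect_true(ok)
})

test_that("addition has no inverse on tiny axes", {
  # for non-empty a there is no s with add(a, s) strictly inside a
  axis <- tonotopic_axis(6)
  all_sets <- list(interval_set(NULL, axis))
  for (s in 0:5) for (l in 1:(6 - s))
    all_sets <- c(all_sets, list(interval_set(c(s, l), axis)))
  a <- interval_set(c(1, 4), axis)
  for (s in all_sets) {
    r <- iset_add(a, s)
    expect_gte(total_length(r), total_length(a))
    expect_true(all(bits_of(a) <= bits_of(r)))
  }
})

test_that("serialization round-trips", {
  a <- tonotopic_axis(30)
  s <- interval_set(list(c(0, 4), c(6, 4), c(20, 3)), a)
  expect_equal(iset_format(s), "0:4,6:4,20:3")
  expect_true(iset_equal(iset_parse(iset_format(s), a), s))
  e <- interval_set(NULL, a)
  expect_equal(iset_format(e), "")
  expect_true(iset_equal(iset_parse("", a), e))
  expect_error(iset_parse("3:", a), class = "placecode_config_error")
  set.seed(3)
  for (i in 1:50) {
    s <- random_iset(a)
    expect_true(iset_equal(iset_parse(iset_format(s), a), s))
  }
})
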
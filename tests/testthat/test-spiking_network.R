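# Unit and property tests on small grids (fast); the desk-scale protocol
# sweeps live in test-acceptance.R.

tiny_cfg <- desk_network_config(grid = 20, seed = 1)

test_that("network build: exact E/I split, determinism, out-degree", {
  net <- build_network(tiny_cfg)
  expect_equal(sum(net$is_exc == 1L), 300L)
  expect_equal(sum(net$is_exc == 0L), 100L)
  net2 <- build_network(tiny_cfg)
  expect_identical(net$conn_ptr, net2$conn_ptr)
  expect_identical(net$conn_tgt, net2$conn_tgt)
  # I cells project only to E cells
  expect_true(all(net$is_exc[net$conn_tgt + 1L] == 1L))
  # I rows are the only non-empty adjacency rows
  deg <- diff(net$conn_ptr)
  expect_true(all(deg[net$is_exc == 1L] == 0L))
  # mean out-degree of an interior I cell matches sum of p(d) (Monte Carlo)
  i_int <- which(net$is_exc == 0L & net$row %in% 8:12 & net$col %in% 8:12)
  sig_c <- tiny_cfg$conn_sigma_um / tiny_cfg$pitch_um
  expected <- sapply(i_int, function(i) {
    d2 <- (net$row - net$row[i])^2 + (net$col - net$col[i])^2
    sum(tiny_cfg$conn_peak * exp(-d2[net$is_exc == 1L] / (2 * sig_c^2)))
  })
  degs <- replicate(30, {
    n <- build_network(desk_network_config(grid = 20,
                                           seed = sample.int(1e6, 1)))
    mean(diff(n$conn_ptr)[i_int])
  })
  se <- sd(degs) / sqrt(length(degs))
  expect_lt(abs(mean(degs) - mean(expected)), 3 * se + 1)
})

test_that("grid configuration is validated", {
  expect_error(network_config(grid = 7), class = "placecode_config_error")
  expect_error(network_config(grid = 2), class = "placecode_config_error")
  expect_error(network_config(dt = 0.2), class = "placecode_config_error")
  expect_error(network_config(conn_peak = 1.4),
               class = "placecode_config_error")
})

test_that("drive generation follows the stated randomization", {
  net <- build_network(tiny_cfg)
  # zero peak: no events anywhere
  set.seed(1)
  d0 <- generate_drive(stimulus_config(c(10, 10), 3, 0), net)
  expect_length(d0$times, 0L)
  # mean per-trial count at the centre approximates the peak
  st <- stimulus_config(c(10, 10), 3, 40, targets = "E")
  centre <- which(net$row == 10 & net$col == 10)  # 1-based index
  set.seed(2)
  counts <- replicate(300, {
    d <- generate_drive(st, net)
    d$ptr[centre + 1L] - d$ptr[centre]
  })
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 40), 3 * se + 0.5)
  # far tail: mean count below 5% of peak
  far <- which(net$row == 10 & net$col == 19)
  counts_far <- replicate(100, {
    d <- generate_drive(st, net)
    d$ptr[far + 1L] - d$ptr[far]
  })
  expect_lt(mean(counts_far), 0.05 * 40)
  # targeting: an E-only drive never hits I cells
  set.seed(3)
  dE <- generate_drive(st, net)
  got <- diff(dE$ptr)
  expect_true(all(got[net$is_exc == 0L] == 0L))
  # all event times inside the window
  expect_true(all(dE$times >= 0 & dE$times < st$duration_ms))
})

test_that("zero drive gives a silent network and empty masks", {
  net <- build_network(tiny_cfg)
  set.seed(1)
  dr <- generate_drive(stimulus_config(c(10, 10), 3, 0), net)
  tr <- simulate_trial(net, dr)
  expect_length(tr$spike_neuron, 0L)
  expect_true(all(tr$min_inet == 0))
  i_rh <- -estimate_rheobase(tiny_cfg$adex_e)
  expect_equal(measure(compute_synaptic_field(tr, i_rh, net))$n_cells, 0L)
  expect_equal(measure(compute_activated_area(tr, net))$n_cells, 0L)
})

test_that("trial is deterministic given the seed", {
  net <- build_network(tiny_cfg)
  run <- function() {
    set.seed(7)
    dr <- generate_drive(stimulus_config(c(10, 10), 3, 60), net)
    tr <- simulate_trial(net, dr)
    list(s = tr$spike_neuron, t = tr$spike_time, m = tr$min_inet)
  }
  expect_identical(run(), run())
})

test_that("net-current trace identity and E/I conductance lag", {
  net <- build_network(tiny_cfg)
  set.seed(4)
  dr <- generate_drive(list(
    stimulus_config(c(10, 10), 3, 80, targets = "E"),
    stimulus_config(c(10, 10), 3, 80, targets = "I")), net)
  centre <- which(net$row == 10 & net$col == 10 & net$is_exc == 1L)[1]
  tr <- simulate_trial(net, dr, record = centre - 1L)
  g <- tr$traces
  vt <- unname(tiny_cfg$adex_e["V_T"])
  expect_equal(g$i_net[1, ],
               (g$g_exc[1, ] * (vt - 0) + g$g_inh[1, ] * (vt + 80)) / 1000,
               tolerance = 1e-12)
  # inhibitory conductance onset lags excitatory onset (feedforward)
  t_e <- which(g$g_exc[1, ] > 0.1)[1]
  t_i <- which(g$g_inh[1, ] > 0.1)[1]
  expect_false(is.na(t_e))
  expect_false(is.na(t_i))
  expect_gt(t_i, t_e)
})

test_that("purely inhibitory input never contributes field or area", {
  net <- build_network(tiny_cfg)
  set.seed(5)
  dr <- generate_drive(stimulus_config(c(10, 10), 4, 100, targets = "I"),
                       net)
  tr <- simulate_trial(net, dr)
  i_rh <- -estimate_rheobase(tiny_cfg$adex_e)
  expect_equal(sum(compute_synaptic_field(tr, i_rh, net)$cells), 0L)
  expect_equal(sum(compute_activated_area(tr, net)$cells), 0L)
})

test_that("rheobase bisection matches the analytic bound with a = 0", {
  p0 <- adex_params(C = 200, g_L = 15, E_L = -70, V_T = -52, Delta_T = 2,
                    a = 0, b = 0, tau_w = 150, V_reset = -60, V_peak = -30,
                    t_ref = 2)
  analytic <- 15 * (-52 - (-70) - 2) / 1000  # g_L (V_T - E_L - Delta_T), nA
  est <- estimate_rheobase(p0)
  expect_lt(abs(est - analytic) / analytic, 0.01)
  # doubling g_L raises rheobase
  p2 <- p0; p2["g_L"] <- 30
  class(p2) <- "adex_params"
  expect_gt(estimate_rheobase(p2), est)
})

test_that("constant current just above rheobase fires, just below not", {
  adex <- adex_rs()
  rh <- estimate_rheobase(adex)
  expect_gt(simulate_constant_current(adex, 1.05 * rh)$n_spikes, 0L)
  expect_equal(simulate_constant_current(adex, 0.95 * rh)$n_spikes, 0L)
})

test_that("field criterion is inclusive at exactly rheobase", {
  net <- build_network(tiny_cfg)
  i_rh <- -0.25
  fake <- structure(list(min_inet = rep(0, net$n)), class = "trial_result")
  k <- which(net$is_exc == 1L)[1:3]
  fake$min_inet[k] <- c(i_rh, i_rh + 1e-9, i_rh - 1e-9)
  mask <- compute_synaptic_field(fake, i_rh, net)
  expect_identical(which(mask$cells), k[c(1, 3)])
})

test_that("minimal enclosing circle matches a brute-force oracle", {
  # oracle: smallest of all 2- and 3-point circles covering the set
  oracle <- function(x, y) {
    best <- Inf
    n <- length(x)
    cover <- function(cx, cy, r2)
      all((x - cx)^2 + (y - cy)^2 <= r2 + 1e-9)
    for (i in 1:n) for (j in i:n) {
      cx <- (x[i] + x[j]) / 2; cy <- (y[i] + y[j]) / 2
      r2 <- ((x[i] - x[j])^2 + (y[i] - y[j])^2) / 4
      if (cover(cx, cy, r2)) best <- min(best, r2)
    }
    if (n >= 3) for (i in 1:(n - 2)) for (j in (i + 1):(n - 1))
      for (k in (j + 1):n) {
        d <- 2 * (x[i] * (y[j] - y[k]) + x[j] * (y[k] - y[i]) +
                    x[k] * (y[i] - y[j]))
        if (abs(d) < 1e-12) next
        ux <- ((x[i]^2 + y[i]^2) * (y[j] - y[k]) +
                 (x[j]^2 + y[j]^2) * (y[k] - y[i]) +
                 (x[k]^2 + y[k]^2) * (y[i] - y[j])) / d
        uy <- ((x[i]^2 + y[i]^2) * (x[k] - x[j]) +
                 (x[j]^2 + y[j]^2) * (x[i] - x[k]) +
                 (x[k]^2 + y[k]^2) * (x[j] - x[i])) / d
        r2 <- (x[i] - ux)^2 + (y[i] - uy)^2
        if (cover(ux, uy, r2)) best <- min(best, r2)
      }
    sqrt(best)
  }
  set.seed(9)
  for (i in 1:40) {
    n <- sample(2:12, 1)
    x <- sample(0:15, n, replace = TRUE)
    y <- sample(0:15, n, replace = TRUE)
    expect_equal(min_enclosing_circle(x, y)$radius, oracle(x, y),
                 tolerance = 1e-6)
  }
})

test_that("measure: diameter and tonotopic projection", {
  net <- build_network(tiny_cfg)
  mk <- function(rows, cols) {
    cells <- rep(FALSE, net$n)
    cells[rows * net$grid + cols + 1L] <- TRUE
    structure(list(kind = "synaptic_field", cells = cells, grid = net$grid,
                   row = net$row, col = net$col, is_exc = net$is_exc),
              class = "field_mask")
  }
  # two cells 10 columns apart in one row
  m <- measure(mk(c(5, 5), c(2, 12)))
  expect_equal(m$diameter_cells, 10)
  expect_equal(m$projection_cells, 2L)
  # 3x3 block: diameter is the diagonal 2*sqrt(2), projection 3
  m <- measure(mk(rep(4:6, each = 3), rep(4:6, times = 3)))
  expect_equal(m$diameter_cells, 2 * sqrt(2), tolerance = 1e-9)
  expect_equal(m$projection_cells, 3L)
  # occupied columns {3,4,5,9} -> projection 4
  m <- measure(mk(c(0, 1, 2, 3), c(3, 4, 5, 9)))
  expect_equal(m$projection_cells, 4L)
  # empty mask: flagged, zero diameter
  m <- measure(mk(integer(0), integer(0)))
  expect_true(m$empty)
  expect_equal(m$diameter_cells, 0)
})

test_that("mask averaging and union behave as documented", {
  net <- build_network(tiny_cfg)
  mk <- function(idx) {
    cells <- rep(FALSE, net$n); cells[idx] <- TRUE
    structure(list(kind = "synaptic_field", cells = cells, grid = net$grid,
                   row = net$row, col = net$col, is_exc = net$is_exc),
              class = "field_mask")
  }
  m <- average_masks(list(mk(1:4), mk(3:6), mk(3:4)))
  expect_identical(which(m$cells), 3:4)  # included in >= half of sweeps
  u <- union_masks(list(mk(1:2), mk(5:6)))
  expect_identical(which(u$cells), c(1:2, 5:6))
})

test_that("activated area lies within the synaptic field up to noise", {
  net <- build_network(tiny_cfg)
  set.seed(6)
  dr <- generate_drive(stimulus_config(c(10, 10), 3, 100, targets = "E"),
                       net)
  tr <- simulate_trial(net, dr)
  i_rh <- -estimate_rheobase(tiny_cfg$adex_e)
  area <- compute_activated_area(tr, net)$cells
  field <- compute_synaptic_field(tr, i_rh, net)$cells
  expect_gt(sum(area), 0)
  expect_lt(mean(area & !field), 0.05 * max(1, sum(area)) / sum(area))
})

test_that("run_experiment covers every protocol on a tiny grid", {
  cfg <- desk_network_config(grid = 20, seed = 2)
  net <- build_network(cfg)
  for (proto in c("addition_colocated", "addition_separated",
                  "multiplication_colocated", "multiplication_shifted",
                  "two_exc_one_inh", "center_surround")) {
    df <- run_experiment(proto, cfg, n_sweeps = 2, seed = 3,
                         values = c(1, 4), net = net, peak_inputs = 60)
    expect_equal(nrow(df), 2L)
    expect_true(all(is.finite(df$field_diameter_mean)))
    expect_lt(attr(df, "i_rh"), 0)
  }
  # sequential variants of the two multi-input protocols
  for (proto in c("two_exc_one_inh", "center_surround")) {
    df <- run_experiment(proto, cfg, n_sweeps = 2, seed = 3,
                         values = c(1, 4), variant = "sequential",
                         net = net, peak_inputs = 60)
    expect_equal(df$variant, rep("sequential", 2))
  }
  # determinism of a full experiment
  d1 <- run_experiment("addition_separated", cfg, n_sweeps = 2, seed = 5,
                       values = c(0, 4), net = net, peak_inputs = 60)
  d2 <- run_experiment("addition_separated", cfg, n_sweeps = 2, seed = 5,
                       values = c(0, 4), net = net, peak_inputs = 60)
  expect_identical(d1, d2)
})

test_that("unknown protocol and bad variants are rejected", {
  expect_error(run_experiment("no_such_protocol"))
  expect_error(run_experiment("addition_colocated", variant = "sequential"),
               class = "placecode_config_error")
})
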
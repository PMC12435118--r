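test_that("compartment sampling draws each component with equal probability", {
  set.seed(101)
  r <- component_ranges()
  dcs <- replicate(30000, sample_compartments(1, r)$dcs)
  expect_true(all(dcs >= r$global_min & dcs <= r$global_max))
  p_par <- mean(dcs < r$intermediate_lower)
  p_int <- mean(dcs >= r$intermediate_lower & dcs <= r$intermediate_upper)
  p_mic <- mean(dcs > r$intermediate_upper)
  expect_lt(abs(p_par - 1 / 3), 0.01)
  expect_lt(abs(p_int - 1 / 3), 0.01)
  expect_lt(abs(p_mic - 1 / 3), 0.01)
})

test_that("compartment amplitudes always sum to one", {
  set.seed(7)
  expect_identical(sample_compartments(1)$amps, 1)
  for (n in c(1, 2, 17, 50)) {
    for (law in c("uniform", "dirichlet")) {
      cs <- sample_compartments(n, amplitude_law = law)
      expect_lt(abs(sum(cs$amps) - 1), 1e-12)
      expect_true(all(cs$amps >= 0))
      expect_equal(cs$n, as.integer(n))
    }
  }
})

test_that("synthesized signals match the multi-exponential closed form", {
  expect_equal(synthesize_signal(fixed_compartments(1.0e-3, 1), 1000),
               exp(-1))
  # mixture evaluated by hand at b = 500
  cs <- fixed_compartments(c(0.7e-3, 2.5e-3, 50e-3), c(0.45, 0.50, 0.05))
  expect_equal(synthesize_signal(cs, 500),
               0.45 * exp(-0.35) + 0.50 * exp(-1.25) + 0.05 * exp(-25))
  # any normalized compartment set gives exactly 1 at b = 0
  set.seed(13)
  for (i in 1:5) {
    cs <- sample_compartments(sample(1:50, 1))
    expect_equal(synthesize_signal(cs, 0), 1)
  }
})

test_that("Rician noise has the magnitude-signal statistics", {
  s <- c(1, 0.5, 0.1)
  expect_identical(add_rician_noise(s, 0), s)
  expect_error(add_rician_noise(s, -0.01), "sd")
  set.seed(99)
  # zero signal: Rayleigh with mean sd * sqrt(pi/2)
  z <- add_rician_noise(rep(0, 1e5), 0.02)
  expect_true(all(z >= 0))
  expect_lt(abs(mean(z) / (0.02 * sqrt(pi / 2)) - 1), 0.01)
  # high SNR: Rice mean ~ s + sd^2 / (2 s)
  o <- add_rician_noise(rep(1, 1e5), 0.01)
  expect_lt(abs(mean(o) - 1.00005), 2e-4)
})

test_that("ground-truth markers apply the component rules to continuous compartments", {
  hc <- fixed_compartments(c(0.7e-3, 2.5e-3, 50e-3), c(0.80, 0.15, 0.05))
  gt <- ground_truth_sda(hc)
  expect_equal(gt$f_int, 0.15)
  expect_equal(gt$d_int, 2.5e-3)
  expect_true(gt$valid_d_int)

  par_only <- fixed_compartments(c(0.3e-3, 1.0e-3), c(0.5, 0.5))
  gt2 <- ground_truth_sda(par_only)
  expect_identical(gt2$f_int, 0)
  expect_false(gt2$valid_d_int)

  two_int <- fixed_compartments(c(2e-3, 3e-3, 0.5e-3), c(0.3, 0.2, 0.5))
  gt3 <- ground_truth_sda(two_int)
  expect_equal(gt3$f_int, 0.5)
  expect_equal(gt3$d_int, 2e-3)  # larger-amplitude intermediate compartment
})

test_that("grid bookkeeping enumerates the full factorial", {
  g <- simulation_grid(n_range = 1:5, patterns_per_n = 10,
                       noise_levels = seq(0, 0.05, length.out = 5))
  expect_equal(grid_size(g), 250)
  mf <- grid_manifest(g)
  expect_equal(nrow(mf), 250)
  expect_equal(sort(unique(mf$n)), 1:5)
  expect_equal(length(unique(mf$noise_sd)), 5)
  # every (n, pattern) appears once per noise level
  expect_true(all(table(mf$n, mf$pattern_id) == 5))
})

test_that("grid runs are a pure function of grid and conditions", {
  g <- simulation_grid(n_range = 1:3, patterns_per_n = 4,
                       noise_levels = c(0, 0.02), seed = 77)
  conds <- list(
    fit_condition("lin", b_scheme_current(),
                  build_component_linear_dictionary(c(5, 6, 5))),
    fit_condition("log", b_scheme_current(), build_log_dictionary(16)))
  r1 <- run_grid(g, conds)
  r2 <- run_grid(g, conds)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), grid_size(g) * 2)
  # the ground truth is shared across conditions and noise levels
  gt <- unique(r1[, c("n", "pattern_id", "gt_f_int")])
  expect_equal(nrow(gt), 12)
  # estimates stay in range and valid flags are consistent
  expect_true(all(r1$est_f_int >= 0 & r1$est_f_int <= 1))
  expect_true(all(is.na(r1$est_d_int) == !r1$est_valid))
})

test_that("grid records stream to disk as tidy TSV", {
  g <- simulation_grid(n_range = 1, patterns_per_n = 2, noise_levels = 0,
                       seed = 5)
  cond <- list(fit_condition("lin", b_scheme_current(),
                             build_component_linear_dictionary(c(4, 4, 4))))
  path <- withr::local_tempfile(fileext = ".tsv")
  rec <- run_grid(g, cond, out_path = path)
  disk <- utils::read.delim(path)
  expect_equal(nrow(disk), 2)
  expect_equal(disk$gt_f_int, rec$gt_f_int, tolerance = 1e-12)
})
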
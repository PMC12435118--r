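test_that("decay signals normalize by the mean b0 signal and keep only b > 0", {
  s <- decay_signal(c(0, 500, 1000), c(1000, 607, 368))
  expect_equal(s$b_values, c(500, 1000))
  expect_equal(s$signals, c(0.607, 0.368))
  expect_equal(s$m, 2L)
  s2 <- decay_signal(c(0, 500, 1000), c(990, 800, 500))
  expect_equal(s2$signals, c(800, 500) / 990)
  expect_error(decay_signal(c(0, 1000), c(0, 1)), "not positive")
  expect_error(decay_signal(c(1000, 500), c(1, 1)), "increasing")
  expect_error(decay_signal(c(500, 1000), c(-0.1, 1)), "non-negative")
  expect_error(decay_signal(c(0, 1000), c(1, 0.4), normalize = FALSE),
               "b = 0")
})

test_that("the design matrix is the exponential decay of each atom", {
  r <- component_ranges()
  d <- build_log_dictionary(2)  # atoms exactly 0.1e-3 and 1000e-3
  sig <- decay_signal(c(50, 1000), c(1, 1))
  M <- build_design_matrix(sig, d)
  expect_equal(dim(M), c(2L, 2L))
  expect_equal(M[1, 1], 0.99501247919268232)  # exp(-50 * 0.1e-3)
  expect_equal(M[1, 2], 1.9287498479639178e-22)  # exp(-50)
  expect_equal(M[2, 1], 0.90483741803595952)  # exp(-1000 * 0.1e-3)
  expect_equal(M[2, 2], 0)  # exp(-1000) underflows
  expect_true(all(M >= 0 & M <= 1))
})

test_that("noise-free single-atom signals are recovered through the full fit", {
  b <- b_scheme_current()
  for (dict in list(build_component_linear_dictionary(),
                    build_log_dictionary())) {
    for (j in c(1L, 30L, 67L, 100L, 134L, 135L, 170L, 200L)) {
      sig <- decay_signal(b[b > 0], exp(-b[b > 0] * dict$atoms[j]))
      res <- fit_decay(sig, dict)
      sp <- attr(res, "spectrum")
      expect_lt(sp$residual_norm, 1e-8)
      comp <- dict$labels[j]
      frac <- switch(comp, parenchymal = res$f_parenchymal,
                     intermediate = res$f_int,
                     microvascular = res$f_microvascular)
      expect_lt(abs(frac - 1), 1e-6)
      if (comp == "intermediate") expect_equal(res$d_int, dict$atoms[j])
    }
  }
})

test_that("a zero signal yields the empty spectrum and an invalid D_int", {
  dict <- build_component_linear_dictionary()
  sig <- decay_signal(c(50, 100, 250, 500, 1000), rep(0, 5))
  res <- fit_decay(sig, dict)
  expect_identical(attr(res, "spectrum")$amplitudes, rep(0, 200))
  expect_identical(res$f_int, 0)
  expect_false(res$valid_d_int)
  expect_true(is.na(res$d_int))
})

test_that("component extraction integrates amplitudes and selects the peak atom", {
  dict <- build_component_linear_dictionary()
  amps <- rep(0, 200)
  i_int <- which.min(abs(dict$atoms - 2.0e-3))  # intermediate atom near 2.0e-3
  expect_identical(dict$labels[i_int], "intermediate")
  amps[10] <- 0.80          # parenchymal
  amps[i_int] <- 0.15       # intermediate
  amps[150] <- 0.05         # microvascular
  res <- extract_sda(fixed_spectrum(dict, amps))
  expect_equal(res$f_int, 0.15)
  expect_equal(res$f_parenchymal, 0.80)
  expect_equal(res$f_microvascular, 0.05)
  expect_equal(res$d_int, dict$atoms[i_int])
  expect_true(res$valid_d_int)

  # all mass parenchymal: F_int 0, D_int undefined
  amps2 <- rep(0, 200); amps2[c(5, 20)] <- c(0.3, 0.7)
  res2 <- extract_sda(fixed_spectrum(dict, amps2))
  expect_identical(res2$f_int, 0)
  expect_false(res2$valid_d_int)

  # equal maximal intermediate amplitudes: tie breaks to the lower-D atom
  amps3 <- rep(0, 200); amps3[c(80, 100)] <- 0.5
  res3 <- extract_sda(fixed_spectrum(dict, amps3))
  expect_equal(res3$d_int, dict$atoms[80])
})

test_that("normalized fractions sum to one whenever total amplitude is positive", {
  dict <- build_log_dictionary(50)
  set.seed(21)
  for (i in 1:20) {
    amps <- stats::runif(50) * stats::rbinom(50, 1, 0.2)
    res <- extract_sda(fixed_spectrum(dict, amps))
    if (sum(amps) > 0)
      expect_equal(res$f_parenchymal + res$f_int + res$f_microvascular, 1)
  }
  # unnormalized extraction reports raw amplitude sums
  amps <- rep(0, 50); amps[25] <- 0.4
  raw <- extract_sda(fixed_spectrum(dict, amps), normalize = FALSE)
  lab <- dict$labels[25]
  expect_equal(raw$f_parenchymal + raw$f_int + raw$f_microvascular, 0.4)
})

test_that("result tables export with percent and display units", {
  dict <- build_component_linear_dictionary()
  b <- b_scheme_current()
  sig <- decay_signal(b, synthesize_signal(
    fixed_compartments(dict$atoms[100], 1), b))
  res <- fit_decay(sig, dict)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sda_results(list(a = res), path)
  tab <- utils::read.delim(path)
  expect_equal(tab$F_int_percent, 100 * res$f_int, tolerance = 1e-12)
  expect_equal(tab$D_int_e3, res$d_int * 1e3, tolerance = 1e-12)
})
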
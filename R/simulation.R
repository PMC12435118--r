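#' Acquisition b-value schemes
#'
#' `b_scheme_current()` is the six-b-value clinical scheme (0, 50, 100, 250,
#' 500, 1000 s/mm^2); `b_scheme_previous()` is the fifteen-b-value scheme used
#' by earlier spectral-diffusion work (0, 5, 7, 10, 15, 20, 30, 40, 50, 60,
#' 100, 200, 400, 700, 1000 s/mm^2).  Both include b = 0, which normalization
#' consumes before fitting.
#'
#' @return Numeric vector of b-values (s/mm^2).
#' @export
b_scheme_current <- function() c(0, 50, 100, 250, 500, 1000)

#' @rdname b_scheme_current
#' @export
b_scheme_previous <- function()
  c(0, 5, 7, 10, 15, 20, 30, 40, 50, 60, 100, 200, 400, 700, 1000)

#' Sample a random multi-compartment ground truth
#'
#' Draws `n` mono-exponential compartments.  Each compartment's diffusivity is
#' generated by first choosing one of the three diffusion components with
#' probability 1/3 each (so the microvascular range, which spans most of the
#' axis, is not over-represented), then drawing uniformly on a linear scale
#' within that component's continuous range.  Amplitudes are drawn i.i.d.
#' uniform(0, 1) and normalized to sum to 1; `amplitude_law = "dirichlet"`
#' instead draws a flat Dirichlet (i.i.d. exponentials normalized).
#'
#' @param n Number of compartments (>= 1).
#' @param ranges A [component_ranges()] object.
#' @param amplitude_law `"uniform"` (default) or `"dirichlet"`.
#' @return An object of class `compartment_set`: `dcs` (mm^2/s), `amps`
#'   (summing to 1), `n`.
#' @export
sample_compartments <- function(n, ranges = component_ranges(),
                                amplitude_law = c("uniform", "dirichlet")) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1, n == round(n))
  amplitude_law <- match.arg(amplitude_law)
  n <- as.integer(n)
  lo <- c(ranges$global_min, ranges$intermediate_lower,
          ranges$intermediate_upper)
  hi <- c(ranges$parenchymal_upper, ranges$intermediate_upper,
          ranges$global_max)
  comp <- sample.int(3L, n, replace = TRUE)
  dcs <- stats::runif(n, lo[comp], hi[comp])
  amps <- switch(amplitude_law,
                 uniform = stats::runif(n),
                 dirichlet = stats::rexp(n))
  amps <- amps / sum(amps)
  structure(list(dcs = dcs, amps = amps, n = n), class = "compartment_set")
}

#' Noise-free multi-exponential decay signal
#'
#' Evaluates `S(b)/S(0) = sum_j A_j exp(-b D_j)` at each requested b-value.
#' Because the amplitudes sum to 1 the signal at b = 0 is exactly 1.
#'
#' @param cs A [sample_compartments()] `compartment_set` (or any list with
#'   `dcs` and `amps`).
#' @param b_values Numeric vector of b-values (s/mm^2), may include 0.
#' @return Numeric signal vector, one value per b-value.
#' @export
synthesize_signal <- function(cs, b_values) {
  stopifnot(is.numeric(b_values), all(b_values >= 0))
  as.numeric(exp(-outer(b_values, cs$dcs)) %*% cs$amps)
}

#' Add Rician noise to a magnitude signal
#'
#' Each element s is replaced by `|s + g1 + i g2|` with independent
#' `g1, g2 ~ Normal(0, sd^2)`: the magnitude of a complex signal corrupted by
#' circular Gaussian noise.  `sd` is expressed in the same units as the
#' signal (for normalized signals, as a fraction of S0).  `sd = 0` returns
#' the input unchanged without consuming random numbers.
#'
#' @param signal Numeric vector of noise-free magnitudes.
#' @param sd Standard deviation of each Gaussian quadrature component
#'   (>= 0).
#' @return Numeric vector of noisy magnitudes (non-negative).
#' @export
add_rician_noise <- function(signal, sd) {
  stopifnot(is.numeric(signal), is.numeric(sd), length(sd) == 1)
  if (is.na(sd) || sd < 0) stop("noise sd must be >= 0")
  if (sd == 0) return(signal)
  n <- length(signal)
  sqrt((signal + stats::rnorm(n, 0, sd))^2 + stats::rnorm(n, 0, sd)^2)
}

#' Ground-truth F_int and D_int of a compartment set
#'
#' Applies the component-integration rules directly to the continuous
#' compartments: F_int is the amplitude sum over compartments with
#' diffusivity inside the intermediate range (inclusive bounds), and D_int is
#' the diffusivity of the maximum-amplitude compartment in that range (ties
#' break to the first, i.e. earliest-drawn, compartment).  When no compartment
#' falls in the range, `valid_d_int` is `FALSE`.
#'
#' @param cs A `compartment_set`.
#' @param ranges A [component_ranges()] object.
#' @return An `sda_result`.
#' @export
ground_truth_sda <- function(cs, ranges = component_ranges()) {
  dc <- cs$dcs
  in_int <- dc >= ranges$intermediate_lower & dc <= ranges$intermediate_upper
  f_par <- sum(cs$amps[dc < ranges$intermediate_lower])
  f_int <- sum(cs$amps[in_int])
  f_mic <- sum(cs$amps[dc > ranges$intermediate_upper])
  if (any(in_int) && f_int > 0) {
    d_int <- dc[in_int][which.max(cs$amps[in_int])]
    valid <- TRUE
  } else {
    d_int <- NA_real_
    valid <- FALSE
  }
  new_sda_result(f_par, f_int, f_mic, d_int, valid)
}

#' Monte-Carlo simulation grid
#'
#' Describes the full factorial of compartment counts, ground-truth patterns
#' per count, and Rician noise levels.  The defaults reproduce the reference
#' design: counts 1..50, 1000 patterns each, and 50 noise standard deviations
#' equally spaced on [0, 0.05] of S0 (the first level is noise-free), for
#' 2,500,000 decay patterns in total.
#'
#' @param n_range Integer vector of compartment counts.
#' @param patterns_per_n Ground-truth patterns per compartment count.
#' @param noise_levels Noise SDs as fractions of S0.
#' @param seed Integer seed governing all randomness of [run_grid()].
#' @param ranges A [component_ranges()] object.
#' @param amplitude_law Passed to [sample_compartments()].
#' @return An object of class `sda_sim_grid`.
#' @export
simulation_grid <- function(n_range = 1:50, patterns_per_n = 1000,
                            noise_levels = seq(0, 0.05, length.out = 50),
                            seed = 1L, ranges = component_ranges(),
                            amplitude_law = "uniform") {
  stopifnot(all(n_range >= 1), patterns_per_n >= 1, all(noise_levels >= 0))
  structure(list(n_range = as.integer(n_range),
                 patterns_per_n = as.integer(patterns_per_n),
                 noise_levels = noise_levels,
                 seed = as.integer(seed),
                 ranges = ranges,
                 amplitude_law = amplitude_law),
            class = "sda_sim_grid")
}

#' @export
print.sda_sim_grid <- function(x, ...) {
  cat(sprintf("Simulation grid: %d compartment counts x %d patterns x %d noise levels = %s decay patterns (seed %d)\n",
              length(x$n_range), x$patterns_per_n, length(x$noise_levels),
              format(grid_size(x), big.mark = ","), x$seed))
  invisible(x)
}

#' @rdname grid_manifest
#' @export
grid_size <- function(grid) {
  stopifnot(inherits(grid, "sda_sim_grid"))
  length(grid$n_range) * grid$patterns_per_n * length(grid$noise_levels)
}

#' Enumerate the decay patterns of a simulation grid
#'
#' `grid_manifest()` materializes one row per decay pattern — every
#' combination of compartment count, pattern id and noise level — without
#' generating signals or fitting anything; `grid_size()` returns the count.
#' The default grid enumerates 2,500,000 rows.
#'
#' @param grid An [simulation_grid()] object.
#' @return `grid_manifest`: a data.frame with columns `n`, `pattern_id`,
#'   `noise_sd`; `grid_size`: a single number.
#' @export
grid_manifest <- function(grid) {
  stopifnot(inherits(grid, "sda_sim_grid"))
  out <- expand.grid(noise_sd = grid$noise_levels,
                     pattern_id = seq_len(grid$patterns_per_n),
                     n = grid$n_range,
                     KEEP.OUT.ATTRS = FALSE)
  out[, c("n", "pattern_id", "noise_sd")]
}

#' Define a fitting condition
#'
#' A condition pairs a b-value scheme with a dictionary; the reference study
#' compares (1) six b-values with Lin200, (2) six b-values with Log200, and
#' (3) fifteen b-values with Log200.
#'
#' @param name Condition label used in the record stream.
#' @param b_values B-value scheme including b = 0 (s/mm^2).
#' @param dictionary An `sda_dictionary`.
#' @return An object of class `sda_condition`.
#' @export
fit_condition <- function(name, b_values, dictionary) {
  stopifnot(is.character(name), length(name) == 1,
            inherits(dictionary, "sda_dictionary"),
            is.numeric(b_values), any(b_values == 0), any(b_values > 0))
  if (is.unsorted(b_values, strictly = TRUE))
    stop("b_values must be strictly increasing")
  structure(list(name = name, b_values = b_values, dictionary = dictionary),
            class = "sda_condition")
}

#' Run the Monte-Carlo simulation grid
#'
#' For every (compartment count, pattern) cell one ground truth is drawn and
#' shared across all noise levels and conditions, so condition differences
#' are never confounded by ground-truth resampling.  At each noise level one
#' Rician noise realization is drawn per distinct b-value scheme (schemes of
#' different length need different draws) and shared by all conditions using
#' that scheme.  The fitted signal is the ratio of noisy S(b_i) to noisy
#' S(b_0), matching the normalization applied to acquired data.  The whole
#' record stream is a pure function of (grid, conditions): the grid seed is
#' set at entry and the caller's RNG state is restored on exit.
#'
#' @param grid An [simulation_grid()] object.
#' @param conditions List of [fit_condition()] objects.
#' @param out_path Optional TSV path; records are also returned invisibly
#'   when written.
#' @param progress Print per-compartment-count progress.
#' @return A data.frame with one row per (pattern, noise level, condition):
#'   `n`, `pattern_id`, `noise_sd`, `condition`, `gt_f_int`, `gt_d_int`,
#'   `gt_valid`, `est_f_int`, `est_d_int`, `est_valid`, `residual_norm`.
#'   F_int columns are fractions; D_int columns are mm^2/s.
#' @export
run_grid <- function(grid, conditions, out_path = NULL, progress = FALSE) {
  stopifnot(inherits(grid, "sda_sim_grid"), length(conditions) >= 1,
            all(vapply(conditions, inherits, logical(1), "sda_condition")))
  cond_names <- vapply(conditions, `[[`, character(1), "name")
  if (anyDuplicated(cond_names)) stop("condition names must be unique")

  # distinct b-schemes, each with its precomputed b>0 design per condition
  scheme_key <- vapply(conditions, function(cc)
    paste(cc$b_values, collapse = ","), character(1))
  schemes <- unique(scheme_key)
  scheme_b <- lapply(schemes, function(k)
    conditions[[match(k, scheme_key)]]$b_values)
  designs <- lapply(conditions, function(cc) {
    b <- cc$b_values[cc$b_values > 0]
    exp(-outer(b, cc$dictionary$atoms))
  })

  n_cells <- grid_size(grid)
  n_rows <- n_cells * length(conditions)
  rec <- list(n = integer(n_rows), pattern_id = integer(n_rows),
              noise_sd = numeric(n_rows), condition = character(n_rows),
              gt_f_int = numeric(n_rows), gt_d_int = numeric(n_rows),
              gt_valid = logical(n_rows), est_f_int = numeric(n_rows),
              est_d_int = numeric(n_rows), est_valid = logical(n_rows),
              residual_norm = numeric(n_rows))

  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(grid$seed)

  row <- 0L
  for (n in grid$n_range) {
    if (progress)
      message(sprintf("compartment count %d / %d", n, max(grid$n_range)))
    for (pat in seq_len(grid$patterns_per_n)) {
      cs <- sample_compartments(n, grid$ranges, grid$amplitude_law)
      gt <- ground_truth_sda(cs, grid$ranges)
      clean <- lapply(scheme_b, function(b) synthesize_signal(cs, b))
      for (sd in grid$noise_levels) {
        noisy <- lapply(clean, add_rician_noise, sd = sd)
        for (ci in seq_along(conditions)) {
          si <- match(scheme_key[ci], schemes)
          b <- scheme_b[[si]]
          y <- noisy[[si]]
          s0 <- mean(y[b == 0])
          est_ok <- s0 > 0
          if (est_ok) {
            ratio <- y[b > 0] / s0
            fit <- nnls_fit_design(designs[[ci]], ratio,
                                   id = sprintf("n=%d pattern=%d sd=%g cond=%s",
                                                n, pat, sd, cond_names[ci]))
            res <- extract_sda(structure(
              list(dictionary = conditions[[ci]]$dictionary,
                   amplitudes = fit$amplitudes,
                   residual_norm = fit$residual_norm),
              class = "sda_spectrum"))
          }
          row <- row + 1L
          rec$n[row] <- n
          rec$pattern_id[row] <- pat
          rec$noise_sd[row] <- sd
          rec$condition[row] <- cond_names[ci]
          rec$gt_f_int[row] <- gt$f_int
          rec$gt_d_int[row] <- gt$d_int
          rec$gt_valid[row] <- gt$valid_d_int
          if (est_ok) {
            rec$est_f_int[row] <- res$f_int
            rec$est_d_int[row] <- res$d_int
            rec$est_valid[row] <- res$valid_d_int
            rec$residual_norm[row] <- fit$residual_norm
          } else {
            rec$est_f_int[row] <- NA_real_
            rec$est_d_int[row] <- NA_real_
            rec$est_valid[row] <- FALSE
            rec$residual_norm[row] <- NA_real_
          }
        }
      }
    }
  }
  records <- as.data.frame(rec, stringsAsFactors = FALSE)
  if (!is.null(out_path)) {
    utils::write.table(records, out_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    return(invisible(records))
  }
  records
}
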
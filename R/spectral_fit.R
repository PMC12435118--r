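#' Normalized diffusion decay signal
#'
#' A decay signal holds the non-zero b-values and the signal ratios
#' S(b_i)/S(b_0).  When the input carries one or more b = 0 measurements and
#' `normalize = TRUE` (the default), the remaining signals are divided by the
#' mean of the b = 0 signals and the b = 0 rows are dropped, so the fitted
#' system has only b > 0 rows.
#'
#' @param b_values Numeric vector of b-values (s/mm^2), strictly increasing.
#' @param signals Numeric vector of magnitude signals, same length; must be
#'   non-negative.
#' @param normalize Divide by the mean b = 0 signal and drop b = 0 entries.
#' @return An object of class `decay_signal` with fields `b_values`
#'   (all > 0), `signals` (ratios), and `m` (number of b > 0 measurements).
#' @examples
#' decay_signal(c(0, 500, 1000), c(1000, 607, 368))
#' @export
decay_signal <- function(b_values, signals, normalize = TRUE) {
  stopifnot(is.numeric(b_values), is.numeric(signals),
            length(b_values) == length(signals),
            !anyNA(b_values), !anyNA(signals))
  if (is.unsorted(b_values, strictly = TRUE))
    stop("b_values must be strictly increasing")
  if (any(signals < 0))
    stop("signals must be non-negative (magnitude data)")
  if (any(b_values < 0))
    stop("b_values must be >= 0")
  is_b0 <- b_values == 0
  if (any(is_b0)) {
    if (!normalize)
      stop("b = 0 present but normalize = FALSE; the fit accepts only b > 0")
    s0 <- mean(signals[is_b0])
    if (s0 <= 0)
      stop("b = 0 signal is not positive; cannot normalize")
    signals <- signals[!is_b0] / s0
    b_values <- b_values[!is_b0]
  }
  if (length(b_values) < 1)
    stop("at least one b > 0 measurement is required")
  structure(list(b_values = b_values, signals = signals,
                 m = length(b_values)),
            class = "decay_signal")
}

#' @export
print.decay_signal <- function(x, ...) {
  cat(sprintf("Decay signal: %d b-values (%g to %g s/mm^2), S/S0 in [%.4g, %.4g]\n",
              x$m, min(x$b_values), max(x$b_values),
              min(x$signals), max(x$signals)))
  invisible(x)
}

#' Design matrix of the spectral linear system
#'
#' Entry (i, j) is `exp(-b_i * D_j)`: the mono-exponential decay of dictionary
#' atom j at b-value i.  All entries lie in (0, 1].
#'
#' @param signal A [decay_signal()].
#' @param dictionary An `sda_dictionary`.
#' @return An `m x n_atoms` numeric matrix.
#' @export
build_design_matrix <- function(signal, dictionary) {
  stopifnot(inherits(signal, "decay_signal"),
            inherits(dictionary, "sda_dictionary"))
  exp(-outer(signal$b_values, dictionary$atoms))
}

# Core NNLS on a precomputed design matrix; shared by the voxel and
# simulation loops where the design is constant across many signals.
nnls_fit_design <- function(design, y, id = NULL, tol_kkt = 1e-11) {
  fit <- tryCatch(
    nnls_lawson_hanson(design, y, tol_kkt = tol_kkt),
    error = function(e) {
      where <- if (is.null(id)) "" else paste0(" [input: ", id, "]")
      stop("NNLS solver failed", where, ": ", conditionMessage(e),
           call. = FALSE)
    })
  list(amplitudes = fit$x, residual_norm = sqrt(fit$resid.norm))
}

#' Non-negative least-squares spectral decomposition
#'
#' Solves `min || A x - s ||_2` subject to `x >= 0`, where A is the
#' exponential design matrix of [build_design_matrix()] and s the normalized
#' signal vector.  The Lawson-Hanson active-set algorithm is deterministic for
#' a fixed input and terminates at a Karush-Kuhn-Tucker point of the
#' constrained problem.
#'
#' @param signal A [decay_signal()].
#' @param dictionary An `sda_dictionary`.
#' @param id Optional identifier carried in the error message should the
#'   solver fail to converge.
#' @param tol_kkt Dual-feasibility tolerance of [nnls_lawson_hanson()].
#' @return An object of class `sda_spectrum`: `dictionary`, `amplitudes`
#'   (non-negative, one per atom), and `residual_norm` (Euclidean norm of the
#'   fit residual).
#' @examples
#' dict <- build_component_linear_dictionary()
#' sig <- decay_signal(c(50, 100, 250, 500, 1000),
#'                     exp(-c(50, 100, 250, 500, 1000) * 2.5e-3))
#' sp <- nnls_solve(sig, dict)
#' sp$residual_norm
#' @export
nnls_solve <- function(signal, dictionary, id = NULL, tol_kkt = 1e-11) {
  design <- build_design_matrix(signal, dictionary)
  fit <- nnls_fit_design(design, signal$signals, id = id, tol_kkt = tol_kkt)
  structure(list(dictionary = dictionary,
                 amplitudes = fit$amplitudes,
                 residual_norm = fit$residual_norm),
            class = "sda_spectrum")
}

#' @export
print.sda_spectrum <- function(x, ...) {
  nz <- sum(x$amplitudes > 0)
  cat(sprintf("SDA spectrum: %d/%d non-zero amplitudes, residual norm %.3g\n",
              nz, length(x$amplitudes), x$residual_norm))
  invisible(x)
}

#' @rdname spectrum_io
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "sda_spectrum"))
  df <- data.frame(index = seq_along(spectrum$amplitudes),
                   D_e3 = spectrum$dictionary$atoms * 1e3,
                   amplitude = spectrum$amplitudes)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Spectrum CSV export
#'
#' Columns: `index` (1-based atom index), `D_e3` (diffusivity, 1e-3 mm^2/s),
#' `amplitude`.
#'
#' @param spectrum An `sda_spectrum`.
#' @param path Output CSV path.
#' @name spectrum_io
NULL

new_sda_result <- function(f_par, f_int, f_mic, d_int, valid_d_int) {
  structure(list(f_int = f_int, d_int = d_int,
                 f_parenchymal = f_par, f_microvascular = f_mic,
                 valid_d_int = valid_d_int),
            class = "sda_result")
}

#' @export
print.sda_result <- function(x, ...) {
  cat(sprintf("F_int = %.2f%%  D_int = %s  (par %.2f%%, micro %.2f%%)\n",
              100 * x$f_int,
              if (x$valid_d_int) sprintf("%.3f x1e-3 mm^2/s", x$d_int * 1e3)
              else "undefined",
              100 * x$f_parenchymal, 100 * x$f_microvascular))
  invisible(x)
}

#' Extract F_int and D_int from a spectrum
#'
#' Component fractions are the amplitude sums over atoms labelled with each
#' component.  With `normalize = TRUE` (default) every sum is divided by the
#' total amplitude, making fractions comparable across voxels whose fits do
#' not sum exactly to one; a spectrum with zero total amplitude yields all
#' fractions 0.  D_int is the dictionary diffusivity at the maximum amplitude
#' within the intermediate range; ties break to the lowest-diffusivity atom.
#' When the intermediate amplitude sum is zero, `valid_d_int` is `FALSE` and
#' `d_int` is `NA`.
#'
#' @param spectrum An `sda_spectrum` from [nnls_solve()].
#' @param normalize Divide component sums by the total amplitude sum.
#' @return An `sda_result`: `f_int`, `f_parenchymal`, `f_microvascular`
#'   (fractions in `[0, 1]` when normalized), `d_int` (mm^2/s or `NA`),
#'   `valid_d_int`.
#' @export
extract_sda <- function(spectrum, normalize = TRUE) {
  stopifnot(inherits(spectrum, "sda_spectrum"))
  amps <- spectrum$amplitudes
  labels <- spectrum$dictionary$labels
  atoms <- spectrum$dictionary$atoms
  int_idx <- labels == "intermediate"
  s_par <- sum(amps[labels == "parenchymal"])
  s_int <- sum(amps[int_idx])
  s_mic <- sum(amps[labels == "microvascular"])
  total <- s_par + s_int + s_mic
  if (normalize) {
    if (total > 0) {
      f <- c(s_par, s_int, s_mic) / total
    } else {
      f <- c(0, 0, 0)
    }
  } else {
    f <- c(s_par, s_int, s_mic)
  }
  if (s_int > 0) {
    a_int <- amps[int_idx]
    d_int <- atoms[int_idx][which.max(a_int)]  # which.max: lowest index on ties
    valid <- TRUE
  } else {
    d_int <- NA_real_
    valid <- FALSE
  }
  new_sda_result(f[1], f[2], f[3], d_int, valid)
}

#' Fit one decay signal end to end
#'
#' Convenience wrapper: [nnls_solve()] followed by [extract_sda()].
#'
#' @inheritParams nnls_solve
#' @inheritParams extract_sda
#' @return An `sda_result` with the spectrum attached as attribute
#'   `"spectrum"`.
#' @export
fit_decay <- function(signal, dictionary, normalize = TRUE, id = NULL) {
  sp <- nnls_solve(signal, dictionary, id = id)
  res <- extract_sda(sp, normalize = normalize)
  attr(res, "spectrum") <- sp
  res
}

#' @rdname sda_table_io
#' @export
write_sda_results <- function(results, path, ids = names(results)) {
  stopifnot(is.list(results), all(vapply(results, inherits, logical(1),
                                         "sda_result")))
  if (is.null(ids)) ids <- as.character(seq_along(results))
  df <- data.frame(
    id = ids,
    F_int_percent = vapply(results, function(r) 100 * r$f_int, numeric(1)),
    D_int_e3 = vapply(results, function(r)
      if (r$valid_d_int) r$d_int * 1e3 else NA_real_, numeric(1)),
    valid_d_int = vapply(results, function(r) r$valid_d_int, logical(1)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' SDA result table export
#'
#' Writes a TSV with columns `id`, `F_int_percent`, `D_int_e3`,
#' `valid_d_int`.
#'
#' @param results List of `sda_result` objects.
#' @param path Output TSV path.
#' @param ids Row identifiers; defaults to list names.
#' @name sda_table_io
NULL
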
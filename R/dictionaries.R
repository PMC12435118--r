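#' Diffusion component ranges
#'
#' The diffusion-coefficient axis is partitioned into three physiological
#' components: parenchymal diffusion (below `intermediate_lower`), intermediate
#' diffusion (between `intermediate_lower` and `intermediate_upper`, both
#' inclusive), and microvascular pseudo-diffusion (above `intermediate_upper`).
#' The intermediate component is the interstitial-fluid window whose fraction
#' and peak diffusivity (F_int, D_int) are the markers of interest.
#'
#' All diffusivities are in mm^2/s, so that b * D is dimensionless with b in
#' s/mm^2.  The conventional display unit is 1e-3 mm^2/s.
#'
#' @param global_min Smallest diffusivity considered (mm^2/s).
#' @param parenchymal_upper Upper edge of the parenchymal range (mm^2/s);
#'   must equal `intermediate_lower`.
#' @param intermediate_lower,intermediate_upper Inclusive bounds of the
#'   intermediate (interstitial-fluid) range (mm^2/s).
#' @param global_max Largest diffusivity considered (mm^2/s).
#' @return An object of class `sda_ranges`.
#' @examples
#' component_ranges()
#' @export
component_ranges <- function(global_min = 0.1e-3,
                             parenchymal_upper = 1.5e-3,
                             intermediate_lower = 1.5e-3,
                             intermediate_upper = 4.0e-3,
                             global_max = 1000e-3) {
  vals <- c(global_min, parenchymal_upper, intermediate_lower,
            intermediate_upper, global_max)
  if (!is.numeric(vals) || anyNA(vals) || any(vals <= 0))
    stop("component ranges must be positive diffusivities (mm^2/s)")
  if (parenchymal_upper != intermediate_lower)
    stop("parenchymal_upper must equal intermediate_lower")
  if (!(global_min < intermediate_lower &&
        intermediate_lower < intermediate_upper &&
        intermediate_upper < global_max))
    stop("ranges must satisfy global_min < intermediate_lower < ",
         "intermediate_upper < global_max")
  structure(
    list(global_min = global_min,
         parenchymal_upper = parenchymal_upper,
         intermediate_lower = intermediate_lower,
         intermediate_upper = intermediate_upper,
         global_max = global_max),
    class = "sda_ranges")
}

#' @export
print.sda_ranges <- function(x, ...) {
  cat("Diffusion component ranges (x1e-3 mm^2/s):\n")
  cat(sprintf("  parenchymal    : %.3f  < D < %.3f\n",
              x$global_min * 1e3, x$intermediate_lower * 1e3))
  cat(sprintf("  intermediate   : %.3f <= D <= %.3f\n",
              x$intermediate_lower * 1e3, x$intermediate_upper * 1e3))
  cat(sprintf("  microvascular  : %.3f  < D <= %.3f\n",
              x$intermediate_upper * 1e3, x$global_max * 1e3))
  invisible(x)
}

.component_levels <- c("parenchymal", "intermediate", "microvascular")

#' Classify dictionary atoms into diffusion components
#'
#' Assigns each diffusivity to one of the three components.  The boundary
#' rules are: parenchymal for `D < intermediate_lower`, intermediate for
#' `intermediate_lower <= D <= intermediate_upper`, microvascular for
#' `D > intermediate_upper`.  The global lower endpoint counts as
#' parenchymal and the global upper endpoint as microvascular.
#'
#' @param atoms Numeric vector of diffusivities (mm^2/s), non-decreasing.
#' @param ranges A [component_ranges()] object.
#' @return A list with `labels` (character vector, one of `"parenchymal"`,
#'   `"intermediate"`, `"microvascular"`) and `counts` (named integer vector
#'   of per-component atom counts).
#' @examples
#' classify_atoms(c(0.5e-3, 2e-3, 50e-3), component_ranges())$counts
#' @export
classify_atoms <- function(atoms, ranges = component_ranges()) {
  stopifnot(is.numeric(atoms), length(atoms) >= 1, !anyNA(atoms))
  tol <- 1e-9
  if (any(atoms < ranges$global_min * (1 - tol)) ||
      any(atoms > ranges$global_max * (1 + tol)))
    stop("atoms outside the global diffusivity range [",
         ranges$global_min, ", ", ranges$global_max, "] mm^2/s")
  labels <- ifelse(atoms < ranges$intermediate_lower, "parenchymal",
            ifelse(atoms <= ranges$intermediate_upper, "intermediate",
                   "microvascular"))
  counts <- vapply(.component_levels, function(l) sum(labels == l), integer(1))
  list(labels = labels, counts = counts)
}

new_dictionary <- function(atoms, scheme, ranges) {
  if (is.unsorted(atoms, strictly = TRUE))
    stop("dictionary atoms must be strictly increasing")
  cls <- classify_atoms(atoms, ranges)
  structure(
    list(atoms = atoms, labels = cls$labels, counts = cls$counts,
         scheme = scheme, ranges = ranges),
    class = "sda_dictionary")
}

#' Logarithmically spaced diffusion-coefficient dictionary
#'
#' Builds `n_atoms` geometrically spaced diffusivities from the global minimum
#' to the global maximum (both included); the default 200-atom version is the
#' dictionary conventionally denoted Log200.  Atom `j` (1-based) equals
#' `global_min * (global_max/global_min)^((j-1)/(n_atoms-1))`.
#'
#' With the default ranges, Log200 holds 59 parenchymal, 21 intermediate and
#' 120 microvascular atoms; the atoms bracketing the upper intermediate
#' boundary are D80 = 3.872e-3 and D81 = 4.055e-3 mm^2/s.
#'
#' @param n_atoms Number of atoms (>= 2); default 200.
#' @param ranges A [component_ranges()] object.
#' @return An `sda_dictionary` with fields `atoms` (mm^2/s, increasing),
#'   `labels`, `counts`, `scheme = "logarithmic"`, `ranges`.
#' @examples
#' d <- build_log_dictionary()
#' d$counts
#' @export
build_log_dictionary <- function(n_atoms = 200, ranges = component_ranges()) {
  if (!is.numeric(n_atoms) || length(n_atoms) != 1 || n_atoms < 2 ||
      n_atoms != round(n_atoms))
    stop("n_atoms must be an integer >= 2")
  n_atoms <- as.integer(n_atoms)
  atoms <- ranges$global_min *
    (ranges$global_max / ranges$global_min)^((seq_len(n_atoms) - 1) / (n_atoms - 1))
  # pin the endpoints exactly (the power form can be off in the last ulp)
  atoms[1] <- ranges$global_min
  atoms[n_atoms] <- ranges$global_max
  new_dictionary(atoms, "logarithmic", ranges)
}

#' Component-linear diffusion-coefficient dictionary
#'
#' Builds a dictionary whose atoms are linearly spaced within each diffusion
#' component; the default (66, 68, 66) version is the dictionary denoted
#' Lin200.  The intermediate run includes both of its boundary values (hence
#' two extra atoms relative to the flanking components); the parenchymal run
#' includes the global minimum and excludes the lower intermediate boundary
#' with step `(parenchymal_upper - global_min) / counts[1]`; the microvascular
#' run excludes the upper intermediate boundary and includes the global
#' maximum with step `(global_max - intermediate_upper) / counts[3]`.
#'
#' With the default ranges, the atoms bracketing the upper intermediate
#' boundary are D134 = 4.000e-3 and D135 = 19.091e-3 mm^2/s.
#'
#' @param counts Integer vector of length 3: atoms per component
#'   (parenchymal, intermediate, microvascular), each >= 2.
#' @param ranges A [component_ranges()] object.
#' @return An `sda_dictionary` with `scheme = "component_linear"`.
#' @examples
#' d <- build_component_linear_dictionary()
#' d$atoms[c(67, 134, 135)] * 1e3
#' @export
build_component_linear_dictionary <- function(counts = c(66L, 68L, 66L),
                                              ranges = component_ranges()) {
  if (!is.numeric(counts) || length(counts) != 3 || any(counts < 2) ||
      any(counts != round(counts)))
    stop("counts must be three integers >= 2 ",
         "(parenchymal, intermediate, microvascular)")
  counts <- as.integer(counts)
  par_step <- (ranges$parenchymal_upper - ranges$global_min) / counts[1]
  par_run <- ranges$global_min + (seq_len(counts[1]) - 1) * par_step
  int_run <- seq(ranges$intermediate_lower, ranges$intermediate_upper,
                 length.out = counts[2])
  int_run[counts[2]] <- ranges$intermediate_upper
  mic_step <- (ranges$global_max - ranges$intermediate_upper) / counts[3]
  mic_run <- ranges$intermediate_upper + seq_len(counts[3]) * mic_step
  mic_run[counts[3]] <- ranges$global_max
  new_dictionary(c(par_run, int_run, mic_run), "component_linear", ranges)
}

#' @export
print.sda_dictionary <- function(x, ...) {
  cat(sprintf("Diffusion dictionary (%s): %d atoms, %.3f to %.3f x1e-3 mm^2/s\n",
              x$scheme, length(x$atoms),
              x$atoms[1] * 1e3, x$atoms[length(x$atoms)] * 1e3))
  cat(sprintf("  components: %d parenchymal, %d intermediate, %d microvascular\n",
              x$counts[["parenchymal"]], x$counts[["intermediate"]],
              x$counts[["microvascular"]]))
  invisible(x)
}

#' @export
length.sda_dictionary <- function(x) length(x$atoms)

#' @rdname dictionary_io
#' @export
write_dictionary <- function(dictionary, path) {
  stopifnot(inherits(dictionary, "sda_dictionary"))
  df <- data.frame(index = seq_along(dictionary$atoms),
                   D_e3 = format(dictionary$atoms * 1e3, digits = 17,
                                 scientific = FALSE, trim = TRUE),
                   component = dictionary$labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Dictionary CSV export and import
#'
#' The on-disk format has columns `index` (1-based), `D_e3` (diffusivity in
#' 1e-3 mm^2/s at full precision) and `component`.  Import reconstructs the
#' dictionary in internal units (mm^2/s) and re-derives the component labels
#' from `ranges`, checking them against the stored ones.
#'
#' @param dictionary An `sda_dictionary`.
#' @param path File path of the CSV.
#' @param ranges Ranges used to re-classify on read.
#' @param scheme Scheme tag to attach on read.
#' @return `write_dictionary` returns `path` invisibly; `read_dictionary`
#'   returns an `sda_dictionary`.
#' @name dictionary_io
#' @export
read_dictionary <- function(path, ranges = component_ranges(),
                            scheme = "imported") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("index", "D_e3", "component") %in% names(df)))
    stop("dictionary CSV must have columns index, D_e3, component")
  df <- df[order(df$index), ]
  d <- new_dictionary(as.numeric(df$D_e3) * 1e-3, scheme, ranges)
  if (!identical(d$labels, df$component))
    warning("stored component labels differ from classification under the ",
            "supplied ranges; using the re-derived labels")
  d
}
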
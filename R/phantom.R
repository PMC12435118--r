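#' Default phantom tissue classes
#'
#' Two three-compartment tissue classes bracketing the clinical contrast the
#' intermediate-diffusion markers target: healthy-control white matter
#' ("HC_WM", component fractions 0.80/0.15/0.05) and periventricular-
#' hyperintensity tissue ("iNPH_PVH", 0.45/0.50/0.05), each with one
#' representative diffusivity per component (defaults 0.7e-3, 2.5e-3 and
#' 50e-3 mm^2/s).
#'
#' @param component_dcs Representative diffusivities (mm^2/s) of the
#'   parenchymal, intermediate and microvascular components.
#' @return Named list of `compartment_set` objects.
#' @export
phantom_tissues <- function(component_dcs = c(0.7e-3, 2.5e-3, 50e-3)) {
  stopifnot(length(component_dcs) == 3)
  mk <- function(amps) structure(list(dcs = component_dcs, amps = amps,
                                      n = 3L), class = "compartment_set")
  list(HC_WM = mk(c(0.80, 0.15, 0.05)),
       iNPH_PVH = mk(c(0.45, 0.50, 0.05)))
}

#' Synthetic 4D diffusion-weighted phantom
#'
#' Builds a small 4D DWI volume with a one-voxel background rim and two
#' labelled slabs, one per tissue class of [phantom_tissues()].  Each voxel's
#' signal follows the multi-exponential decay of its class scaled by `s0`,
#' with Rician noise of standard deviation `noise_sd * s0` added to every
#' volume (including b = 0).  The exact per-region ground truth accompanies
#' the volume, so map computation and ROI statistics can be verified without
#' any acquired data.
#'
#' @param noise_sd Noise SD as a fraction of S0 (>= 0).
#' @param seed Integer seed; the caller's RNG state is restored on exit.
#' @param shape 3D grid dimensions.
#' @param b_values Acquisition scheme including b = 0.
#' @param s0 Base b = 0 intensity.
#' @param tissues Named list of `compartment_set` tissue classes.
#' @return An object of class `sda_phantom`: `dwi` (a [dwi_volume()] whose
#'   mask is the labelled region), `labels` (3D integer array, 0 =
#'   background), `regions` (data.frame label/name), `ground_truth` (named
#'   list of `sda_result`), `tissues`, `noise_sd`, `seed`.
#' @examples
#' ph <- make_default_phantom(noise_sd = 0, seed = 1, shape = c(8, 8, 4))
#' ph$ground_truth$iNPH_PVH
#' @export
make_default_phantom <- function(noise_sd = 0, seed = 1L,
                                 shape = c(32, 32, 32),
                                 b_values = b_scheme_current(),
                                 s0 = 1000,
                                 tissues = phantom_tissues()) {
  stopifnot(is.numeric(noise_sd), length(noise_sd) == 1, noise_sd >= 0,
            length(shape) == 3, all(shape >= 4), any(b_values == 0),
            length(tissues) >= 1, !is.null(names(tissues)))
  shape <- as.integer(shape)
  labels <- array(0L, dim = shape)
  # one-voxel background rim, remaining x-extent split evenly among tissues
  xs <- 2:(shape[1] - 1)
  splits <- split(xs, cut(seq_along(xs), length(tissues), labels = FALSE))
  for (k in seq_along(tissues))
    labels[splits[[k]], 2:(shape[2] - 1), 2:(shape[3] - 1)] <- k

  data <- array(0, dim = c(shape, length(b_values)))
  nvox <- prod(shape)
  flat <- matrix(data, nrow = nvox)
  for (k in seq_along(tissues)) {
    sig <- s0 * synthesize_signal(tissues[[k]], b_values)
    flat[as.vector(labels) == k, ] <- rep(sig, each = sum(labels == k))
  }
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  if (noise_sd > 0)
    flat <- matrix(add_rician_noise(as.vector(flat), noise_sd * s0),
                   nrow = nvox)
  data <- array(flat, dim = c(shape, length(b_values)))
  dwi <- dwi_volume(data, b_values, mask = array(labels > 0, dim = shape))
  gt <- lapply(tissues, ground_truth_sda)
  structure(list(dwi = dwi, labels = labels,
                 regions = data.frame(label = seq_along(tissues),
                                      name = names(tissues)),
                 ground_truth = gt, tissues = tissues,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sda_phantom")
}

#' @export
print.sda_phantom <- function(x, ...) {
  cat(sprintf("SDA phantom %s, %d tissue classes, noise %.3g S0, seed %d\n",
              paste(dim(x$labels), collapse = "x"),
              nrow(x$regions), x$noise_sd, x$seed))
  for (k in seq_len(nrow(x$regions)))
    cat(sprintf("  %-10s gt F_int %.1f%%  gt D_int %.3f x1e-3\n",
                x$regions$name[k], 100 * x$ground_truth[[k]]$f_int,
                x$ground_truth[[k]]$d_int * 1e3))
  invisible(x)
}

#' Write a phantom to disk
#'
#' Emits `dwi.nii.gz`, `dwi.bval` (FSL-style), `labels.nii.gz` and
#' `ground_truth.json` into `dir`.
#'
#' @param phantom An `sda_phantom`.
#' @param dir Output directory.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "sda_phantom"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  RNifti::writeNifti(RNifti::asNifti(phantom$dwi$data),
                     file.path(dir, "dwi.nii.gz"), datatype = "float")
  writeLines(paste(phantom$dwi$b_values, collapse = " "),
             file.path(dir, "dwi.bval"))
  RNifti::writeNifti(RNifti::asNifti(phantom$labels),
                     file.path(dir, "labels.nii.gz"), datatype = "int16")
  gt <- lapply(phantom$ground_truth, function(r)
    list(f_int_percent = 100 * r$f_int,
         d_int_e3 = if (r$valid_d_int) r$d_int * 1e3 else NULL,
         valid_d_int = r$valid_d_int))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# truncated normal by rejection; bounds are honest truncation, not clamping
rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep(min(max(mean, lo), hi), n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Default cohort generative parameters
#'
#' Group-level means and standard deviations of F_int (percent) and D_int
#' (1e-3 mm^2/s) for a centrum-semiovale-like region across three
#' healthy-control age bands, a non-PVH patient group and a PVH patient
#' group, together with group age distributions.  These emulate the degree
#' of separation reported for that region in the clinical literature (the
#' PVH group's interstitial-fluid fraction roughly triples).
#'
#' @return Data.frame with columns `group`, `region`, `f_mean`, `f_sd`,
#'   `d_mean`, `d_sd`, `age_mean`, `age_sd`.
#' @export
cohort_effects <- function() {
  data.frame(
    group = c("HC_young", "HC_mid", "HC_old", "iNPH", "iNPH_PVH"),
    region = "CSO",
    f_mean = c(12.7, 11.6, 13.5, 12.6, 40.3),
    f_sd = c(7.0, 5.6, 7.5, 7.1, 18.4),
    d_mean = c(1.05, 1.02, 1.21, 0.97, 1.53),
    d_sd = c(0.45, 0.46, 0.49, 0.48, 0.63),
    age_mean = c(29.3, 49.1, 69.3, 76.9, 76.9),
    age_sd = c(5.5, 5.9, 6.8, 7.6, 7.6))
}

#' Simulate a cohort of per-subject ROI measurements
#'
#' Draws per-subject region-level F_int and D_int around the group means in
#' `effects`, with truncated-normal sampling keeping F_int inside [0, 100]
#' percent, D_int positive and age inside [20, 95] years.  Ages are drawn
#' independently of the markers within each group, so any marginal
#' age-marker correlation arises only from between-group differences.
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param effects Generative table as from [cohort_effects()]; one row per
#'   (group, region).
#' @param seed Integer seed; the caller's RNG state is restored on exit.
#' @return A tidy data.frame: `subject`, `group`, `region`, `age`,
#'   `f_int` (percent), `d_int` (1e-3 mm^2/s).
#' @examples
#' head(make_cohort(3, seed = 7))
#' @export
make_cohort <- function(n_per_group = 30, effects = cohort_effects(),
                        seed = 1L) {
  stopifnot(is.numeric(n_per_group), n_per_group >= 2,
            is.data.frame(effects),
            all(c("group", "region", "f_mean", "f_sd", "d_mean", "d_sd",
                  "age_mean", "age_sd") %in% names(effects)))
  n_per_group <- as.integer(n_per_group)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  groups <- unique(effects$group)
  subj_age <- list()
  rows <- vector("list", nrow(effects))
  for (g in groups)
    subj_age[[g]] <- rtnorm(n_per_group,
                            effects$age_mean[match(g, effects$group)],
                            effects$age_sd[match(g, effects$group)],
                            20, 95)
  for (i in seq_len(nrow(effects))) {
    g <- effects$group[i]
    rows[[i]] <- data.frame(
      subject = sprintf("%s_%03d", g, seq_len(n_per_group)),
      group = g,
      region = effects$region[i],
      age = subj_age[[g]],
      f_int = rtnorm(n_per_group, effects$f_mean[i], effects$f_sd[i], 0, 100),
      d_int = rtnorm(n_per_group, effects$d_mean[i], effects$d_sd[i],
                     0, Inf))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
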
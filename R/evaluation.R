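#' Normalized root-mean-square error
#'
#' RMSE between ground truth and estimate, divided by the mean of the ground
#' truth.  When the ground-truth mean is zero the quantity is undefined and
#' `NA` is returned (never 0); callers that aggregate surfaces flag such
#' cells as undefined.
#'
#' @param gt,est Numeric vectors of equal length >= 1.
#' @return A single non-negative number, or `NA_real_` when `mean(gt) == 0`.
#' @examples
#' nrmse(c(0.1, 0.3), c(0.2, 0.1))
#' @export
nrmse <- function(gt, est) {
  stopifnot(is.numeric(gt), is.numeric(est), length(gt) == length(est),
            length(gt) >= 1)
  m <- mean(gt)
  if (m == 0) return(NA_real_)
  sqrt(mean((gt - est)^2)) / m
}

#' Accuracy surface over the simulation grid
#'
#' Aggregates a [run_grid()] record stream into one nRMSE value per
#' (compartment count, noise level) cell for one condition and one metric.
#' For `d_int`, records where either the ground truth or the estimate has no
#' intermediate component are excluded before aggregation, mirroring the
#' zero-F_int exclusion rule used on measured data; `n_used` reports how many
#' records survived.  Cells whose ground-truth mean is zero (or that are
#' empty after exclusion) carry `NA` and are flagged undefined.
#'
#' @param records Data.frame from [run_grid()].
#' @param metric `"f_int"` or `"d_int"`.
#' @param condition Condition name to select; may be omitted when the records
#'   contain a single condition.
#' @return An object of class `sda_nrmse_surface`: `metric`, `condition`,
#'   `axis_n`, `axis_noise`, and `table` (data.frame `n`, `noise_sd`,
#'   `nrmse`, `n_used`).
#' @export
build_surface <- function(records, metric = c("f_int", "d_int"),
                          condition = NULL) {
  metric <- match.arg(metric)
  need <- c("n", "pattern_id", "noise_sd", "condition",
            "gt_f_int", "gt_d_int", "gt_valid",
            "est_f_int", "est_d_int", "est_valid")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  if (is.null(condition)) {
    conds <- unique(records$condition)
    if (length(conds) != 1)
      stop("records contain ", length(conds),
           " conditions; supply `condition`")
    condition <- conds
  }
  rr <- records[records$condition == condition, ]
  if (nrow(rr) == 0) stop("no records for condition '", condition, "'")
  if (metric == "f_int") {
    rr <- rr[!is.na(rr$est_f_int), ]
    gt <- rr$gt_f_int; est <- rr$est_f_int
  } else {
    rr <- rr[rr$gt_valid & rr$est_valid &
               !is.na(rr$gt_d_int) & !is.na(rr$est_d_int), ]
    gt <- rr$gt_d_int; est <- rr$est_d_int
  }
  axis_n <- sort(unique(records$n))
  axis_noise <- sort(unique(records$noise_sd))
  cells <- expand.grid(n = axis_n, noise_sd = axis_noise,
                       KEEP.OUT.ATTRS = FALSE)
  key <- interaction(rr$n, rr$noise_sd, drop = FALSE)
  split_idx <- split(seq_len(nrow(rr)), key)
  cell_key <- paste(cells$n, cells$noise_sd, sep = ".")
  cells$nrmse <- NA_real_
  cells$n_used <- 0L
  for (i in seq_len(nrow(cells))) {
    idx <- split_idx[[cell_key[i]]]
    if (is.null(idx) || length(idx) == 0) next
    cells$n_used[i] <- length(idx)
    cells$nrmse[i] <- nrmse(gt[idx], est[idx])
  }
  structure(list(metric = metric, condition = condition,
                 axis_n = axis_n, axis_noise = axis_noise, table = cells),
            class = "sda_nrmse_surface")
}

#' @export
print.sda_nrmse_surface <- function(x, ...) {
  def <- !is.na(x$table$nrmse)
  cat(sprintf("nRMSE surface [%s, %s]: %d x %d cells, %d defined, grand mean %.4g\n",
              x$condition, x$metric, length(x$axis_n), length(x$axis_noise),
              sum(def), mean(x$table$nrmse[def])))
  invisible(x)
}

#' @rdname build_surface
#' @param surface An `sda_nrmse_surface`.
#' @export
surface_matrix <- function(surface) {
  stopifnot(inherits(surface, "sda_nrmse_surface"))
  matrix(surface$table$nrmse, nrow = length(surface$axis_n),
         dimnames = list(n = surface$axis_n, noise_sd = surface$axis_noise))
}

#' Rank conditions by accuracy surface
#'
#' Compares two or more surfaces built on the same grid and metric:
#' reports each condition's grand-mean nRMSE over cells defined in every
#' surface, and per-cell win counts (a condition wins a cell when it attains
#' the minimum nRMSE there; ties credit all minimizers, so identical surfaces
#' show equal wins).  Conditions are ranked by grand mean.
#'
#' @param surfaces Named list of `sda_nrmse_surface` objects (names override
#'   the surfaces' condition labels when given).
#' @return A data.frame (`condition`, `grand_mean_nrmse`, `wins`,
#'   `n_cells`) ordered best first, with attribute `"metric"`.
#' @export
compare_conditions <- function(surfaces) {
  stopifnot(is.list(surfaces), length(surfaces) >= 2,
            all(vapply(surfaces, inherits, logical(1), "sda_nrmse_surface")))
  metrics <- unique(vapply(surfaces, `[[`, character(1), "metric"))
  if (length(metrics) != 1) stop("surfaces mix metrics: ",
                                 paste(metrics, collapse = ", "))
  ref <- surfaces[[1]]
  same_grid <- vapply(surfaces, function(s)
    identical(s$axis_n, ref$axis_n) && identical(s$axis_noise, ref$axis_noise),
    logical(1))
  if (!all(same_grid)) stop("surfaces are not on the same (n, noise) grid")
  labels <- names(surfaces)
  if (is.null(labels) || any(!nzchar(labels)))
    labels <- vapply(surfaces, `[[`, character(1), "condition")
  mats <- vapply(surfaces, function(s) s$table$nrmse,
                 numeric(nrow(ref$table)))
  defined <- rowSums(is.na(mats)) == 0
  if (!any(defined)) stop("no cell is defined in every surface")
  sub <- mats[defined, , drop = FALSE]
  grand <- colMeans(sub)
  row_min <- apply(sub, 1, min)
  wins <- colSums(sub <= row_min)  # ties credit all minimizers
  out <- data.frame(condition = labels, grand_mean_nrmse = grand,
                    wins = as.integer(wins), n_cells = sum(defined),
                    row.names = NULL)
  out <- out[order(out$grand_mean_nrmse), ]
  rownames(out) <- NULL
  attr(out, "metric") <- metrics
  out
}

#' @rdname build_surface
#' @param path Output CSV path for the long-format surface table.
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "sda_nrmse_surface"))
  df <- surface$table
  df$metric <- surface$metric
  df$condition <- surface$condition
  utils::write.csv(df[, c("n", "noise_sd", "metric", "condition",
                          "nrmse", "n_used")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
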
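#' Region-of-interest summaries of parameter maps
#'
#' Summarizes F_int and D_int maps over a label image on the same grid:
#' per region, the mean F_int over fitted voxels and the mean D_int over
#' voxels with a defined D_int, with voxel counts.  Labels absent from the
#' image (or present but with no fitted voxel) produce a warning and no row.
#'
#' @param maps An `sda_maps` object from [fit_volume()].
#' @param labels 3D integer label array (0 = background) on the map grid.
#' @param region_names Optional character vector naming labels 1, 2, ...;
#'   defaults to `"region_<label>"`.
#' @return Data.frame: `region`, `label`, `n_voxels`, `n_f`, `f_int`
#'   (percent), `n_d`, `d_int` (1e-3 mm^2/s; `NA` when no voxel has a
#'   defined D_int).
#' @export
extract_roi <- function(maps, labels, region_names = NULL) {
  stopifnot(inherits(maps, "sda_maps"), is.array(labels))
  if (!identical(dim(labels), dim(maps$f_int)))
    stop("label image grid does not match the map grid")
  present <- sort(unique(as.vector(labels)))
  present <- present[present > 0]
  rows <- list()
  for (lab in present) {
    idx <- which(labels == lab)
    fv <- maps$f_int[idx]
    dv <- maps$d_int[idx]
    ok_f <- !is.nan(fv) & !is.na(fv)
    ok_d <- maps$valid[idx] > 0 & !is.nan(dv) & !is.na(dv)
    name <- if (!is.null(region_names) && lab <= length(region_names))
      region_names[lab] else sprintf("region_%d", lab)
    if (!any(ok_f)) {
      warning("region '", name, "' has no fitted voxel; row omitted")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      region = name, label = lab, n_voxels = length(idx),
      n_f = sum(ok_f), f_int = mean(fv[ok_f]),
      n_d = sum(ok_d),
      d_int = if (any(ok_d)) mean(dv[ok_d]) else NA_real_)
  }
  if (length(rows) == 0) {
    warning("no region overlaps the fitted maps")
    return(data.frame(region = character(), label = integer(),
                      n_voxels = integer(), n_f = integer(),
                      f_int = numeric(), n_d = integer(), d_int = numeric()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Zero-F_int exclusion rule
#'
#' ROIs whose measured F_int is exactly zero (or missing) are excluded from
#' statistical analysis for both markers — a zero intermediate fraction means
#' D_int is undefined and F_int itself is uninformative there.  The rule is
#' idempotent: re-applying it changes nothing.
#'
#' @param table Data.frame with at least an `f_int` column (e.g. from
#'   [make_cohort()] or assembled from [extract_roi()] rows).
#' @return The table with a logical `included` column; the number of newly
#'   analyzable-to-excluded rows is in attribute `"n_excluded"`.
#' @export
apply_exclusion <- function(table) {
  stopifnot(is.data.frame(table), "f_int" %in% names(table))
  table$included <- !is.na(table$f_int) & table$f_int > 0
  attr(table, "n_excluded") <- sum(!table$included)
  table
}

#' Dunn's post hoc test for pairwise group comparisons
#'
#' Pairwise z statistics on the joint ranks following a Kruskal-Wallis
#' omnibus test, with the standard tie correction: for groups i and j,
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j))` where
#' `T = sum(t^3 - t) / (12 (N - 1))` over tie groups.  Two-sided p-values
#' are adjusted over the family of all pairwise comparisons (Bonferroni by
#' default) and capped at 1.
#'
#' @param values Numeric vector of observations.
#' @param groups Group membership, same length.
#' @param p_adjust Adjustment method passed to [stats::p.adjust()].
#' @return Data.frame: `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
dunn_test <- function(values, groups, p_adjust = "bonferroni") {
  stopifnot(is.numeric(values), length(values) == length(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.character(groups[keep])
  gl <- unique(groups)
  if (length(gl) < 2) stop("at least two groups are required")
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  nn <- tapply(r, groups, length)
  pairs <- utils::combn(gl, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / nn[[i]] + 1 / nn[[j]]))
    z[k] <- (rbar[[i]] - rbar[[j]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
             p_adj = pmin(stats::p.adjust(p, method = p_adjust), 1))
}

#' Nonparametric group comparison of an ROI marker
#'
#' Applies the zero-F_int exclusion, then compares the chosen marker across
#' groups with the Kruskal-Wallis omnibus test followed by Dunn's all-pairs
#' post hoc test.  Rank-based throughout, so invariant to any strictly
#' monotone transform of the marker.
#'
#' @param table Data.frame with columns `group`, the metric column, and
#'   optionally `included` (computed via [apply_exclusion()] when absent).
#' @param metric `"f_int"` or `"d_int"`.
#' @param groups Optional subset of groups to compare (default: all present).
#' @param p_adjust Dunn adjustment method.
#' @param alpha Significance threshold reported alongside (default 0.05).
#' @return A list of class `sda_group_test`: `metric`, `kruskal`
#'   (statistic, df, p.value), `pairwise` (Dunn table), `n_excluded`,
#'   `group_sizes`, `alpha`.
#' @export
group_compare <- function(table, metric = c("f_int", "d_int"),
                          groups = NULL, p_adjust = "bonferroni",
                          alpha = 0.05) {
  metric <- match.arg(metric)
  stopifnot(is.data.frame(table), "group" %in% names(table),
            metric %in% names(table))
  if (!"included" %in% names(table)) table <- apply_exclusion(table)
  n_excl <- sum(!table$included)
  tt <- table[table$included & !is.na(table[[metric]]), ]
  if (!is.null(groups)) tt <- tt[tt$group %in% groups, ]
  sizes <- table(as.character(tt$group))
  if (length(sizes) < 2 || any(sizes < 2))
    stop("group comparison needs >= 2 groups with >= 2 analyzable rows ",
         "each after the zero-F_int exclusion")
  kw <- stats::kruskal.test(tt[[metric]], factor(tt$group))
  dn <- dunn_test(tt[[metric]], tt$group, p_adjust = p_adjust)
  structure(list(metric = metric,
                 kruskal = list(statistic = unname(kw$statistic),
                                df = unname(kw$parameter),
                                p.value = kw$p.value),
                 pairwise = dn,
                 n_excluded = n_excl,
                 group_sizes = sizes,
                 alpha = alpha),
            class = "sda_group_test")
}

#' @export
print.sda_group_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis on %s: H = %.4f, df = %d, p = %.4g (alpha %.2f; %d row(s) excluded)\n",
              x$metric, x$kruskal$statistic, x$kruskal$df, x$kruskal$p.value,
              x$alpha, x$n_excluded))
  pw <- x$pairwise
  for (k in seq_len(nrow(pw)))
    cat(sprintf("  %s vs %s: z = %+.3f, adj. p = %.4g%s\n",
                pw$group1[k], pw$group2[k], pw$z[k], pw$p_adj[k],
                if (pw$p_adj[k] < x$alpha) " *" else ""))
  invisible(x)
}

#' Spearman correlation of a marker with age
#'
#' Rank correlation (average ranks under ties) between age and the chosen
#' marker, after the zero-F_int exclusion, optionally restricted to a subset
#' of groups — supporting inclusion schemes such as "healthy controls only"
#' or "healthy controls plus non-PVH patients".
#'
#' @param table Data.frame with `age`, `group`, and the metric column.
#' @param metric `"f_int"` or `"d_int"`.
#' @param groups Optional subset of groups to include.
#' @return A list: `rho`, `p.value`, `n`, `metric`, `groups`.
#' @export
age_correlation <- function(table, metric = c("f_int", "d_int"),
                            groups = NULL) {
  metric <- match.arg(metric)
  stopifnot(is.data.frame(table), all(c("age", metric) %in% names(table)))
  if (!"included" %in% names(table)) table <- apply_exclusion(table)
  tt <- table[table$included & !is.na(table[[metric]]) & !is.na(table$age), ]
  if (!is.null(groups)) {
    stopifnot("group" %in% names(table))
    tt <- tt[tt$group %in% groups, ]
  }
  if (nrow(tt) < 3)
    stop("Spearman correlation needs >= 3 paired observations")
  ct <- suppressWarnings(
    stats::cor.test(tt$age, tt[[metric]], method = "spearman",
                    exact = FALSE))
  list(rho = unname(ct$estimate), p.value = ct$p.value, n = nrow(tt),
       metric = metric, groups = groups)
}
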
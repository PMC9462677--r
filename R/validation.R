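#' Validation configuration
#'
#' Controls the comparison of FE-predicted and measured surface
#' displacements: the spherical averaging radius (by default set to the
#' registration RMSE by the caller), the Cook's-distance multiplier for
#' outlier screening, the component labelling and the minimum cloud
#' points required per sphere.
#'
#' @param radius spherical averaging radius R (mm), > 0.
#' @param cook_multiplier points with Cook's distance greater than this
#'   multiple of the mean Cook's distance are removed (default 4).
#' @param components named integer vector mapping component labels to
#'   displacement columns (default RL = x, AP = y, SI = z).
#' @param min_points_per_sphere nodes with fewer cloud points inside
#'   their sphere are dropped (default 1).
#' @param max_neighbors cap on neighbours collected per sphere.
#' @param small_dic threshold (mm) below which measured components are
#'   excluded from the Average Error \% (guards the division; default
#'   1e-3 mm = 1 um).
#' @return An object of class `spinefe_validation_config`.
#' @export
validation_config <- function(radius, cook_multiplier = 4,
                              components = c(RL = 1L, AP = 2L, SI = 3L),
                              min_points_per_sphere = 1L,
                              max_neighbors = 64L, small_dic = 1e-3) {
  if (!is.finite(radius) || radius <= 0)
    stop_input("`radius` must be positive")
  if (!is.finite(cook_multiplier) || cook_multiplier <= 0)
    stop_input("`cook_multiplier` must be positive")
  if (is.null(names(components)) || length(components) < 1)
    stop_input("`components` must be a named vector of column indices")
  structure(list(radius = radius, cook_multiplier = cook_multiplier,
                 components = components,
                 min_points_per_sphere = as.integer(min_points_per_sphere),
                 max_neighbors = as.integer(max_neighbors),
                 small_dic = small_dic),
            class = "spinefe_validation_config")
}

#' Pair FE nodes with spherically averaged measured displacements
#'
#' For every FE node of the region of interest, the measured
#' displacement U_DIC is the unweighted mean of all cloud displacement
#' vectors lying within distance R of the node; U_FEM is the FE
#' displacement at the node. Nodes with fewer than
#' `min_points_per_sphere` cloud points are dropped (and counted in the
#' `dropped_nodes` attribute).
#'
#' @param mesh the solved [tet_mesh()].
#' @param solution the [fe_solve()] result.
#' @param field a registered [surface_field()] in the model frame.
#' @param nodes RoI node ids (or the name of a mesh node set).
#' @param cfg a [validation_config()].
#' @return Tibble with node id, coordinates, `n_cloud`, `u_fem_*` and
#'   `u_dic_*` columns.
#' @export
pair_and_average <- function(mesh, solution, field, nodes, cfg) {
  if (is.character(nodes)) nodes <- mesh$node_sets[[nodes]]
  nodes <- as.integer(nodes)
  xq <- mesh$nodes[nodes, , drop = FALSE]
  k <- min(nrow(field$points), cfg$max_neighbors)
  nn <- RANN::nn2(field$points, xq, k = k, searchtype = "radius",
                  radius = cfg$radius + 1e-9)
  cnt <- rowSums(nn$nn.idx > 0)
  udic <- matrix(NA_real_, length(nodes), 3)
  for (r in which(cnt > 0)) {
    ids <- nn$nn.idx[r, nn$nn.idx[r, ] > 0]
    udic[r, ] <- colMeans(field$displacements[ids, , drop = FALSE])
  }
  keep <- cnt >= cfg$min_points_per_sphere
  if (!any(keep))
    rlang::abort("no RoI node has cloud points within R; increase the averaging radius",
                 class = "spinefe_configuration_error")
  out <- tibble::tibble(
    node = nodes[keep],
    x = xq[keep, 1], y = xq[keep, 2], z = xq[keep, 3],
    n_cloud = cnt[keep],
    u_fem_x = solution$U[nodes[keep], 1],
    u_fem_y = solution$U[nodes[keep], 2],
    u_fem_z = solution$U[nodes[keep], 3],
    u_dic_x = udic[keep, 1], u_dic_y = udic[keep, 2],
    u_dic_z = udic[keep, 3])
  attr(out, "dropped_nodes") <- sum(!keep)
  out
}

#' Cook's-distance outlier mask for a simple linear regression
#'
#' Computes Cook's distance for `y ~ x` at every point and masks out
#' points whose distance exceeds `multiplier` times the mean Cook's
#' distance. Single pass (no re-iteration). With fewer than 4 points the
#' filter is skipped with a warning and everything is kept.
#'
#' @param x,y numeric vectors.
#' @param multiplier the cutoff multiple (default 4).
#' @return Logical inlier mask of `length(x)`.
#' @export
cooks_filter <- function(x, y, multiplier = 4) {
  if (length(x) != length(y)) stop_input("x and y lengths differ")
  if (length(x) < 4) {
    rlang::warn("fewer than 4 points; Cook's-distance filtering skipped")
    return(rep(TRUE, length(x)))
  }
  fit <- stats::lm(y ~ x)
  # an (essentially) exact fit has no outliers: without this guard the
  # 1e-16-scale floating-point residuals of closed-loop comparisons
  # would be amplified into spurious removals
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  if (sse <= 1e-20 * max(sst, .Machine$double.xmin))
    return(rep(TRUE, length(x)))
  D <- unname(stats::cooks.distance(fit))
  D[!is.finite(D)] <- 0
  if (mean(D) == 0) return(rep(TRUE, length(x)))
  !(D > multiplier * mean(D))
}

#' Per-component regression metrics
#'
#' Ordinary least squares of U_FEM against U_DIC for one displacement
#' component after Cook's-distance screening: determination coefficient,
#' slope, intercept, RMSE of (U_DIC - U_FEM), RMSE normalised by the
#' maximum measured |component| in the region (%RMSE), the mean
#' percentage error (components smaller than `cfg$small_dic` excluded
#' from the mean and counted), and the maximum absolute error.
#'
#' @param pairs tibble from [pair_and_average()].
#' @param component a label present in `cfg$components`.
#' @param cfg a [validation_config()].
#' @return One-row tibble of metrics.
#' @export
regress_component <- function(pairs, component, cfg) {
  axis <- cfg$components[[component]]
  suff <- c("x", "y", "z")[axis]
  dic <- pairs[[paste0("u_dic_", suff)]]
  fem <- pairs[[paste0("u_fem_", suff)]]
  mask <- cooks_filter(dic, fem, cfg$cook_multiplier)
  dic_in <- dic[mask]; fem_in <- fem[mask]
  if (length(dic_in) < 3)
    rlang::abort("fewer than 3 inlier pairs; cannot regress",
                 class = "spinefe_degenerate_regression")
  if (stats::sd(dic_in) == 0)
    rlang::abort("measured component has zero variance; regression is degenerate",
                 class = "spinefe_degenerate_regression")
  fit <- stats::lm(fem_in ~ dic_in)
  err <- abs(dic_in - fem_in)
  rmse <- sqrt(mean((dic_in - fem_in)^2))
  norm <- max(abs(dic_in))
  ok_pct <- abs(dic_in) >= cfg$small_dic
  # coefficient of determination computed directly (summary.lm warns
  # on the exact-fit closed loops this package deliberately exercises)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((fem_in - mean(fem_in))^2)
  tibble::tibble(
    component = component,
    r_squared = 1 - sse / sst,
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    rmse = rmse,
    pct_rmse = 100 * rmse / norm,
    avg_err_pct = if (any(ok_pct))
      mean(100 * err[ok_pct] / abs(dic_in[ok_pct])) else NA_real_,
    max_err = max(err),
    n_points = length(dic_in),
    n_outliers_removed = sum(!mask),
    n_small_excluded = sum(!ok_pct))
}

#' Pointwise error resultant
#'
#' Euclidean norm of the per-component absolute error vector at each
#' paired node.
#'
#' @param pairs tibble from [pair_and_average()].
#' @return Numeric vector of per-node resultants (mm).
#' @export
diff_field <- function(pairs) {
  sqrt((pairs$u_dic_x - pairs$u_fem_x)^2 +
         (pairs$u_dic_y - pairs$u_fem_y)^2 +
         (pairs$u_dic_z - pairs$u_fem_z)^2)
}

#' Bland-Altman agreement analysis
#'
#' Per paired node: the mean of measured and predicted values against
#' their difference. `type = "signed"` uses one displacement component
#' (difference = U_DIC - U_FEM); `type = "magnitude"` plots the error
#' resultant against the mean of the measured and predicted
#' displacement magnitudes. Bias is the mean difference; limits of
#' agreement are bias +/- 1.96 sd.
#'
#' @param pairs tibble from [pair_and_average()].
#' @param component component label (ignored for `type = "magnitude"`).
#' @param cfg a [validation_config()].
#' @param type `"signed"` or `"magnitude"`.
#' @return list with `data` (tibble: mean, difference), `bias`,
#'   `loa_lower`, `loa_upper`.
#' @export
bland_altman <- function(pairs, component = "SI", cfg = NULL,
                         type = c("signed", "magnitude")) {
  type <- match.arg(type)
  if (nrow(pairs) < 2) stop_input("need at least 2 pairs")
  if (type == "signed") {
    axis <- if (is.null(cfg)) match(component, c("RL", "AP", "SI"))
            else cfg$components[[component]]
    suff <- c("x", "y", "z")[axis]
    m <- (pairs[[paste0("u_dic_", suff)]] +
            pairs[[paste0("u_fem_", suff)]]) / 2
    d <- pairs[[paste0("u_dic_", suff)]] - pairs[[paste0("u_fem_", suff)]]
  } else {
    mag_dic <- sqrt(pairs$u_dic_x^2 + pairs$u_dic_y^2 + pairs$u_dic_z^2)
    mag_fem <- sqrt(pairs$u_fem_x^2 + pairs$u_fem_y^2 + pairs$u_fem_z^2)
    m <- (mag_dic + mag_fem) / 2
    d <- diff_field(pairs)
  }
  s <- stats::sd(d)
  list(data = tibble::tibble(mean = m, difference = d),
       bias = mean(d), loa_lower = mean(d) - 1.96 * s,
       loa_upper = mean(d) + 1.96 * s)
}

#' Full displacement validation over one or more regions of interest
#'
#' Runs pairing, Cook's-distance screening and per-component regression
#' for each RoI, and collects the pointwise error fields (per-component
#' absolute error and the resultant).
#'
#' @param mesh the solved [tet_mesh()].
#' @param solution the [fe_solve()] result.
#' @param fields named list of registered [surface_field()] objects
#'   (names are RoI labels).
#' @param rois named list of RoI node id vectors (or mesh node-set
#'   names), matching `fields`.
#' @param cfg a [validation_config()].
#' @return An object of class `spinefe_validation` with `metrics`
#'   (tibble: one row per RoI x component), `points` (pointwise pairs,
#'   errors, resultant), `config`.
#' @export
validate_displacements <- function(mesh, solution, fields, rois, cfg) {
  stopifnot(length(fields) == length(rois))
  labels <- names(fields)
  if (is.null(labels)) labels <- paste0("RoI_", seq_along(fields))
  metrics <- list(); points <- list()
  for (i in seq_along(fields)) {
    pairs <- pair_and_average(mesh, solution, fields[[i]], rois[[i]],
                              cfg)
    met <- dplyr::bind_rows(lapply(names(cfg$components), function(cp)
      regress_component(pairs, cp, cfg)))
    met <- dplyr::mutate(met, roi = labels[i], .before = 1)
    pts <- dplyr::mutate(
      pairs,
      roi = labels[i],
      error_x = abs(.data$u_dic_x - .data$u_fem_x),
      error_y = abs(.data$u_dic_y - .data$u_fem_y),
      error_z = abs(.data$u_dic_z - .data$u_fem_z),
      diff = diff_field(pairs))
    metrics[[i]] <- met; points[[i]] <- pts
  }
  structure(list(metrics = dplyr::bind_rows(metrics),
                 points = dplyr::bind_rows(points), config = cfg),
            class = "spinefe_validation")
}

#' @export
print.spinefe_validation <- function(x, ...) {
  cat("<displacement validation>\n")
  print(x$metrics, n = nrow(x$metrics))
  invisible(x)
}

#' @export
tidy.spinefe_validation <- function(x, ...) x$metrics

#' @export
glance.spinefe_validation <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$points),
    min_r_squared = min(x$metrics$r_squared),
    max_rmse = max(x$metrics$rmse),
    max_pct_rmse = max(x$metrics$pct_rmse),
    n_outliers_removed = sum(x$metrics$n_outliers_removed))
}

#' Export a validation report
#'
#' Writes the metric table as CSV (rows = metrics, columns = RoI x
#' component, the usual layout of such summaries) and, optionally, the
#' full report as JSON.
#'
#' @param validation a [validate_displacements()] result.
#' @param path CSV path.
#' @param json_path optional JSON path.
#' @export
write_validation_report <- function(validation, path,
                                    json_path = NULL) {
  m <- validation$metrics
  long <- tidyr::pivot_longer(
    m, cols = c("r_squared", "slope", "intercept", "rmse", "pct_rmse",
                "avg_err_pct", "max_err", "n_points",
                "n_outliers_removed"),
    names_to = "metric", values_to = "value")
  wide <- tidyr::pivot_wider(long,
                             id_cols = "metric",
                             names_from = c("roi", "component"),
                             values_from = "value")
  readr::write_csv(wide, path)
  if (!is.null(json_path))
    jsonlite::write_json(list(metrics = m, points = validation$points),
                         json_path, dataframe = "columns",
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export pointwise validation error fields as VTK point data
#'
#' Writes the mesh with per-node scalars for the error resultant and
#' the per-component absolute errors (zero at nodes outside the
#' validated regions), ready for spatial error maps.
#'
#' @param validation a [validate_displacements()] result.
#' @param mesh the validated mesh.
#' @param solution the [fe_solve()] result (displacement vectors are
#'   included as point data).
#' @param path `.vtk` output path.
#' @export
write_error_field_vtk <- function(validation, mesh, solution, path) {
  n <- nrow(mesh$nodes)
  fields <- list(diff = "diff", error_x = "error_x",
                 error_y = "error_y", error_z = "error_z")
  pv <- list(displacement = solution$U)
  for (nm in names(fields)) {
    v <- numeric(n)
    v[validation$points$node] <- validation$points[[fields[[nm]]]]
    pv[[nm]] <- matrix(v, ncol = 1)
  }
  write_mesh_vtk(mesh, path, point_vectors = pv)
}
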
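#' Run configuration for the analysis pipeline
#'
#' Validates and normalizes a full experiment description: a geometry
#' source, the geometry variants to compare, physical constants, the
#' initial condition, the inactivation-rate grid, and solver tolerances.
#'
#' @param geometry one of
#'   `list(kind = "spheres", R_nuc, R_cell, h)`,
#'   `list(kind = "corridor", L, h)`,
#'   `list(kind = "random", params = synthetic_cell_params(...))`, or
#'   `list(kind = "file", path, map = NULL)`.
#' @param variants geometry variants to analyze; the first is the
#'   reference for ratio outputs.
#' @param D diffusivity, um^2/s.
#' @param init `list(kind = "shell")`, `list(kind = "patch", center, radius)`
#'   or `list(kind = "point", voxel)`.
#' @param lambda strictly increasing positive inactivation-rate grid, s^-1.
#' @param N delivered molecule count for signal curves.
#' @param signal_lambda rates at which signal curves are written (default:
#'   smallest, middle and largest of `lambda`).
#' @param out_dir output directory.
#' @param seed integer seed (geometry generation and any other RNG).
#' @param atol,rtol integrator tolerances.
#' @param n_out trajectory output points.
#' @param window eigen-tail switch scan window, s.
#' @param eigen_cutoff,max_modes eigen-tail retention controls.
#' @param lambda_switch time-domain/resolvent route cross-over, s^-1.
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(geometry,
                       variants = c("physiological", "no_organelles"),
                       D = 10,
                       init = list(kind = "shell"),
                       lambda = 10^seq(-1, 6, length.out = 15L),
                       N = 1000,
                       signal_lambda = NULL,
                       out_dir = tempfile("fptcell_run_"),
                       seed = 1L,
                       atol = 1e-8, rtol = 1e-8,
                       n_out = 1000L,
                       window = c(1, 10),
                       eigen_cutoff = 1, max_modes = 200L,
                       lambda_switch = 1e3) {
  stopifnot(is.list(geometry), !is.null(geometry$kind))
  geometry$kind <- match.arg(geometry$kind, c("spheres", "corridor", "random", "file"))
  if (geometry$kind == "file" && !file.exists(geometry$path))
    stop("geometry file does not exist: ", geometry$path, call. = FALSE)
  variants <- match.arg(variants, c("physiological", "no_ER", "no_organelles"),
                        several.ok = TRUE)
  stopifnot(is.list(init), init$kind %in% c("shell", "patch", "point"))
  if (any(lambda <= 0) || is.unsorted(lambda, strictly = TRUE))
    stop("lambda grid must be positive and strictly increasing", call. = FALSE)
  if (is.null(signal_lambda))
    signal_lambda <- unique(lambda[c(1L, ceiling(length(lambda) / 2), length(lambda))])
  structure(
    list(geometry = geometry, variants = variants, D = D, init = init,
         lambda = lambda, N = N, signal_lambda = signal_lambda,
         out_dir = out_dir, seed = as.integer(seed),
         atol = atol, rtol = rtol, n_out = as.integer(n_out),
         window = window, eigen_cutoff = eigen_cutoff,
         max_modes = as.integer(max_modes), lambda_switch = lambda_switch),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path JSON file holding the configuration fields.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$geometry$params))
    cfg$geometry$params <- do.call(synthetic_cell_params, cfg$geometry$params)
  do.call(run_config, cfg)
}

# versioned output schemas, covered by golden-header tests
.run_schema <- list(
  version = "1",
  survival = c("t_s", "S", "f_per_s"),
  conditional_stats = c("lambda_per_s", "Z", "mean_s", "var_s2", "median_s", "method"),
  mfpt = c("i", "j", "k", "u_s", "reachable"),
  signal = c("lambda_per_s", "t_s", "signal_per_s"),
  ratio = c("lambda_per_s", "mean_ref_s", "mean_alt_s", "ratio", "distance_ratio")
)

.build_geometry <- function(geometry) {
  switch(geometry$kind,
    spheres = concentric_spheres_grid(geometry$R_nuc, geometry$R_cell, geometry$h),
    corridor = corridor_grid(geometry$L, geometry$h %||% 0.1),
    random = random_cell(geometry$params %||% synthetic_cell_params()),
    file = read_label_volume(geometry$path, geometry$map)
  )
}

.build_init <- function(masks, init) {
  switch(init$kind,
    shell = shell_init(masks),
    patch = patch_init(masks, init$center, init$radius),
    point = point_init(masks, init$voxel)
  )
}

.stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  message(sprintf("[fptcell] %-28s %.2fs", name, proc.time()[["elapsed"]] - t0))
  out
}

#' Run the full analysis pipeline
#'
#' For each geometry variant: builds masks and the diffusion operator,
#' solves the MFPT field, measures graph distances, integrates the hybrid
#' trajectory, extracts the FPT density, tabulates conditional statistics
#' over the inactivation-rate grid, and writes signal curves.  When two or
#' more variants are requested, the reference (first) variant is compared
#' against each other variant: per-shell-voxel MFPT ratios and the
#' conditional-mean ratio across the rate grid together with its graph-
#' distance limit.  All tables are written as CSV under `config$out_dir`
#' with a JSON run summary; outputs are deterministic given the seed.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list of class `fpt_run` with all in-memory
#'   results: `masks`, `ops`, `mfpt`, `fpt`, `stats`, `ratios`, `summary`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  grid <- .stage("geometry", .build_geometry(config$geometry))
  res <- list(masks = list(), ops = list(), mfpt = list(), fpt = list(),
              stats = list(), dist = list())
  summary <- list(schema_version = .run_schema$version,
                  seed = config$seed, D = config$D, variants = list())

  for (v in config$variants) {
    masks <- .stage(paste0(v, ": masks"), build_masks(grid, v))
    g <- .build_init(masks, config$init)
    op <- .stage(paste0(v, ": operator"), diffusion_operator(masks, config$D))
    field <- .stage(paste0(v, ": mfpt"), mfpt_field(op))
    dist <- graph_distance(masks, g)
    u_src <- sum(g$values * field$u * masks$h^3)  # source-averaged MFPT
    traj <- .stage(paste0(v, ": trajectory"), hybrid_trajectory(
      op, g, window = config$window, n_out = config$n_out,
      cutoff = config$eigen_cutoff, max_modes = config$max_modes,
      atol = config$atol, rtol = config$rtol))
    fpt <- fpt_density(traj)
    stats_tbl <- .stage(paste0(v, ": conditional stats"), conditional_stats(
      config$lambda, fpt = fpt, op = op, g = g,
      lambda_switch = config$lambda_switch))

    # end-to-end conservation: Z(lambda -> 0) vs source mass on the
    # nucleus-connected component
    z0 <- laplace_Z(fpt, 0)
    if (abs(z0 - fpt$connected_mass) > 1e-4)
      warning(sprintf("variant %s: |Z(0) - connected source mass| = %.3g > 1e-4",
                      v, abs(z0 - fpt$connected_mass)), call. = FALSE)

    readr::write_csv(
      stats::setNames(tibble::tibble(fpt$times, fpt$S, fpt$f), .run_schema$survival),
      file.path(config$out_dir, paste0("survival_", v, ".csv")))
    readr::write_csv(
      stats::setNames(stats_tbl[, c("lambda", "Z", "mean_s", "var_s2",
                                    "median_s", "method")],
                      .run_schema$conditional_stats),
      file.path(config$out_dir, paste0("conditional_stats_", v, ".csv")))
    readr::write_csv(
      stats::setNames(tidy(field), .run_schema$mfpt),
      file.path(config$out_dir, paste0("mfpt_", v, ".csv")))
    sig <- purrr::map(config$signal_lambda, function(l) {
      sc <- signal_curve(fpt, l, config$N)
      tibble::tibble(lambda = l, t = sc$time, s = sc$signal)
    })
    readr::write_csv(
      stats::setNames(dplyr::bind_rows(sig), .run_schema$signal),
      file.path(config$out_dir, paste0("signal_", v, ".csv")))

    message(sprintf(
      "[fptcell] %s: |C_h|=%d |N_h|=%d shell=%d d_g=%s modes=%d T_switch=%s Z0=%.6f",
      v, length(masks$cytosol), length(masks$nucleus), length(masks$shell),
      format(dist$d_g), if (is.null(traj$tail)) 0L else length(traj$tail$mu),
      format(traj$T_switch), z0))

    res$masks[[v]] <- masks; res$ops[[v]] <- op; res$mfpt[[v]] <- field
    res$fpt[[v]] <- fpt; res$stats[[v]] <- stats_tbl; res$dist[[v]] <- dist
    summary$variants[[v]] <- list(
      n_cytosol = length(masks$cytosol), n_nucleus = length(masks$nucleus),
      n_shell = length(masks$shell), d_g = dist$d_g,
      mean_mfpt_from_source_s = u_src, Z0 = z0,
      T_switch_s = traj$T_switch,
      n_modes = if (is.null(traj$tail)) 0L else length(traj$tail$mu))
  }

  # cross-variant comparisons against the reference variant
  ref <- config$variants[1L]
  res$ratios <- list()
  for (v in setdiff(config$variants, ref)) {
    shell <- membrane_shell(res$masks[[ref]])
    shell_tbl <- shell_mfpt_summary(res$mfpt[[ref]], res$mfpt[[v]], shell)
    readr::write_csv(shell_tbl,
                     file.path(config$out_dir, paste0("mfpt_shell_ratio_", v, ".csv")))
    d_ratio <- res$dist[[ref]]$d_g / res$dist[[v]]$d_g
    rt <- tibble::tibble(
      lambda = config$lambda,
      mean_ref_s = res$stats[[ref]]$mean_s,
      mean_alt_s = res$stats[[v]]$mean_s,
      ratio = res$stats[[ref]]$mean_s / res$stats[[v]]$mean_s,
      distance_ratio = d_ratio
    )
    readr::write_csv(stats::setNames(rt, .run_schema$ratio),
                     file.path(config$out_dir, paste0("mean_ratio_", v, ".csv")))
    res$ratios[[v]] <- list(shell = shell_tbl, mean_ratio = rt,
                            distance_ratio = d_ratio)
  }

  summary$outputs <- list.files(config$out_dir)
  jsonlite::write_json(summary, file.path(config$out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$summary <- summary
  res$config <- config
  class(res) <- "fpt_run"
  invisible(res)
}

#' @export
print.fpt_run <- function(x, ...) {
  cat("<fpt_run> variants:", paste(names(x$masks), collapse = ", "), "\n")
  cat("  outputs in", x$config$out_dir, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
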
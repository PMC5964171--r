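# End-to-end pipeline orchestration: synthetic (or imported) trials ->
# gait processing -> inverse dynamics -> static optimization -> muscle
# analysis work -> forward-dynamics work, with a machine-readable
# provenance log. Deterministic given (config, inputs, seed).

#' Pipeline configuration
#'
#' Every field defaults to the published value where one exists (20 Hz
#' filter cutoff, zero CoP offset, published scale factors available via
#' [paper_scale_factors()], 0.01 activation reporting threshold).
#'
#' @param model `"default"` or the path of a model file for [read_model()].
#' @param scale_factors named per-segment factors applied to the model
#'   (NULL = no scaling).
#' @param filter_cutoff low-pass cutoff, Hz.
#' @param cop_offset CoP shift, m.
#' @param n_points stride resampling points for analysis.
#' @param reserve_weight,residual_weight static-optimization cost weights.
#' @param active_threshold activation reporting threshold.
#' @param w_thresh_frac,force_floor_frac classification thresholds.
#' @param run_forward_dynamics include the muscle-driven forward-dynamics
#'   work estimate (slower).
#' @param seed RNG seed for synthetic inputs.
#' @param output_dir optional directory for result files.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(model = "default", scale_factors = NULL,
                            filter_cutoff = 20, cop_offset = 0,
                            n_points = 101, reserve_weight = 1,
                            residual_weight = 1e-3,
                            active_threshold = 0.01,
                            w_thresh_frac = 0.1, force_floor_frac = 0.01,
                            run_forward_dynamics = FALSE,
                            seed = 1L, output_dir = NULL) {
  structure(list(model = model, scale_factors = scale_factors,
                 filter_cutoff = filter_cutoff, cop_offset = cop_offset,
                 n_points = n_points, reserve_weight = reserve_weight,
                 residual_weight = residual_weight,
                 active_threshold = active_threshold,
                 w_thresh_frac = w_thresh_frac,
                 force_floor_frac = force_floor_frac,
                 run_forward_dynamics = run_forward_dynamics,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration (JSON)
#'
#' @param config a `pipeline_config`.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, digits = I(17),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, obj[!vapply(obj, is.null, logical(1))])
}

#' Run the full analysis pipeline
#'
#' Stage order: gait processing (filtering, gencoords, stride assembly) ->
#' stride pooling -> inverse dynamics on a representative stride -> static
#' optimization -> muscle-analysis work report, and optionally a
#' muscle-driven forward dynamics simulation with its own work report.
#'
#' @param config a [pipeline_config()].
#' @param trials list of trials: each a list with `markers`
#'   (`marker_trial`) and `forces` (`force_plate_trial`), e.g. the output
#'   of [generate_trial_set()]; NULL generates a synthetic set from the
#'   config seed.
#' @param n_trials synthetic trial count when `trials` is NULL.
#' @return result bundle (list): `model`, `strides`, `pooled`,
#'   `representative`, `moments`, `solution`, `diagnostics`, `work`,
#'   optional `forward`, and `log` (provenance). Files are written when
#'   `config$output_dir` is set.
#' @export
run_pipeline <- function(config = pipeline_config(), trials = NULL,
                         n_trials = 5) {
  log <- list(package = "mousegait",
              version = as.character(utils::packageVersion("mousegait")),
              config = unclass(config), stages = list())
  model <- if (identical(config$model, "default")) build_default_model()
           else read_model(config$model)
  if (!is.null(config$scale_factors))
    model <- scale_model(model, unlist(config$scale_factors))
  log$stages$model <- list(n_mtus = length(model$mtus))
  if (is.null(trials)) {
    p <- gait_params(seed = config$seed)
    trials <- generate_trial_set(p, n_trials = n_trials, model = model)
    log$stages$synthetic <- list(n_trials = n_trials, seed = config$seed)
  }
  strides <- lapply(trials, function(tr)
    process_trial(tr$markers, tr$forces, cutoff = config$filter_cutoff))
  pooled <- normalize_and_pool(strides, n_points = config$n_points)
  log$stages$gait <- list(n_strides = length(strides),
                          cutoff = config$filter_cutoff,
                          n_points = config$n_points)
  rep_stride <- resample_stride(strides[[1]], config$n_points)
  time <- rep_stride$normalized_time * rep_stride$duration
  moments <- inverse_dynamics(model, time, rep_stride$joint_angles,
                              rep_stride$grf,
                              cop_offset = config$cop_offset)
  log$stages$inverse_dynamics <- list(
    peak_moments_nmm = lapply(setdiff(names(moments), "time"),
                              function(cc) max(abs(moments[[cc]])) * 1000))
  actuators <- actuator_set(model, reserve_weight = config$reserve_weight,
                            residual_weight = config$residual_weight)
  solution <- solve_stride(model, rep_stride, moments, actuators,
                           active_threshold = config$active_threshold)
  diagnostics <- actuator_diagnostics(solution, moments, rep_stride$grf)
  log$stages$static_optimization <- list(max_kkt = max(solution$kkt))
  work <- work_report(model, rep_stride, solution)
  log$stages$work <- list(n_actuators = nrow(work$summary))
  bundle <- list(model = model, strides = strides, pooled = pooled,
                 representative = rep_stride, moments = moments,
                 solution = solution, diagnostics = diagnostics,
                 work = work)
  if (isTRUE(config$run_forward_dynamics)) {
    fwd <- pipeline_forward_dynamics(model, rep_stride, solution)
    bundle$forward <- fwd
    log$stages$forward_dynamics <- list(
      rmse_deg = as.list(kinematic_rmse(fwd$time, fwd$q, time,
                                        rep_stride$joint_angles)))
  }
  bundle$log <- log
  if (!is.null(config$output_dir)) write_bundle(bundle, config)
  invisible(bundle)
}

# Resample a stride record onto n uniformly spaced stride fractions.
resample_stride <- function(stride, n_points) {
  grid <- seq(0, 1, length.out = n_points)
  res <- function(y) stats::spline(stride$normalized_time, y, xout = grid,
                                   method = "fmm")$y
  ja <- as.data.frame(lapply(stride$joint_angles, res))
  grf <- as.data.frame(lapply(stride$grf, res))
  swing <- grid < stride$transition
  grf[swing, ] <- 0
  stride_record(grid, ja, grf, stride$transition, stride$duration,
                stride$speed)
}

# Muscle-driven forward dynamics of the representative stride, excitations
# taken from the static-optimization activations and reserves applied as
# prescribed moments.
pipeline_forward_dynamics <- function(model, stride, solution,
                                      rtol = 1e-5) {
  time <- solution$time
  acts <- solution$activations
  exc_fun <- make_series_fun(time, acts)
  res_cols <- intersect(sagittal_coords, colnames(solution$reserves))
  res_mat <- matrix(0, length(time), 4,
                    dimnames = list(NULL, sagittal_coords))
  res_mat[, res_cols] <- solution$reserves[, res_cols]
  res_fun <- make_series_fun(time, res_mat)
  grf_fun <- make_series_fun(
    time, cbind(stride$grf$f_craniocaudal, stride$grf$f_vertical))
  dt <- time[2] - time[1]
  q0 <- vapply(sagittal_coords, function(cc) stride$joint_angles[[cc]][1],
               numeric(1))
  qd0 <- vapply(sagittal_coords,
                function(cc) series_deriv(stride$joint_angles[[cc]], dt)[1],
                numeric(1))
  fwd <- forward_dynamics_muscle(
    model, exc_fun, q0, qd0, t_span = range(time),
    a0 = acts[1, ], reserve_fun = res_fun, grf_fun = grf_fun,
    times = time, rtol = rtol)
  # forward-dynamics work report from the simulated states
  ana <- muscle_analysis(model, fwd$time, as.data.frame(fwd$q),
                         fwd$activations, compliant = TRUE)
  fmax <- vapply(colnames(ana$power),
                 function(lb) model$mtus[[lb]]$params$f_max, numeric(1))
  fwd$work <- work_summary(fwd$time, ana$power, ana$force,
                           stride$transition, fmax)
  fwd
}

# Piecewise-linear interpolant over rows of a series matrix.
make_series_fun <- function(time, mat) {
  mat <- as.matrix(mat)
  funs <- lapply(seq_len(ncol(mat)), function(j)
    stats::approxfun(time, mat[, j], rule = 2))
  nm <- colnames(mat)
  function(t) {
    v <- vapply(funs, function(f) f(t), numeric(1))
    if (!is.null(nm)) names(v) <- nm
    v
  }
}

write_bundle <- function(bundle, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$output_dir, ...)
  rep <- bundle$representative
  time <- rep$normalized_time * rep$duration
  write_sto(data.frame(time = time, rep$joint_angles), out("gencoords.sto"),
            name = "gencoords")
  utils::write.table(moments_nmm(bundle$moments), out("moments_nmm.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  acts <- data.frame(time = bundle$solution$time, bundle$solution$activations,
                     check.names = FALSE)
  utils::write.table(acts, out("activations.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(bundle$work$summary, out("work_report.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(bundle$work$summary, out("work_report.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(bundle$log, out("run_log.json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       force = TRUE)
  invisible(config$output_dir)
}
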
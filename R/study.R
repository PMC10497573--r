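#' Study configuration
#'
#' Assembles and validates the configuration of a reproducible study run.
#' Unknown keys are rejected with the offending key named.
#'
#' @param kind one of \code{"uncontrolled"}, \code{"dose"}, \code{"optimal"},
#'   \code{"convergence"}.
#' @param orders spectral orders to run (default 16, 24, 32).
#' @param steps Euler step counts (default 4000, 7000, 10000; single studies
#'   use the last).
#' @param outdir output directory (created if missing).
#' @param params a [ModelParams-class], a path to a YAML parameter file, or
#'   \code{NULL} for the built-in defaults.
#' @param mode,convention,diffusionSign,clamp solver flags (see
#'   [solveRegulator()]).
#' @param qM,rT,rG cost weights.
#' @param controlThreshold,stateThresholdFrac duration thresholds.
#' @param figures write PNG figures alongside the CSV artifacts.
#' @param seed random seed recorded in the manifest (the computation itself
#'   is deterministic; reserved for fixture jitter).
#' @return a named list of class \code{"StudyConfig"}.
#' @export
studyConfig <- function(kind = c("uncontrolled", "dose", "optimal", "convergence"),
                        orders = c(16, 24, 32),
                        steps = c(4000, 7000, 10000),
                        outdir = tempfile("fibrocontrol-study-"),
                        params = NULL,
                        mode = "scalar",
                        convention = "laplacian_consistent",
                        diffusionSign = "stable_minus_rS",
                        clamp = FALSE,
                        qM = 1, rT = 1, rG = 1,
                        controlThreshold = 1e-3,
                        stateThresholdFrac = 0.01,
                        figures = FALSE,
                        seed = 1L) {
  kind <- match.arg(kind)
  if (any(orders < 2)) stop("spectral orders must be >= 2")
  if (any(steps < 1)) stop("step counts must be >= 1")
  p <- if (is.null(params)) {
    modelParams()
  } else if (is.character(params)) {
    readParams(params)
  } else {
    stopifnot(is(params, "ModelParams"))
    params
  }
  structure(
    list(
      kind = kind, orders = as.integer(orders), steps = as.integer(steps),
      outdir = outdir, params = p, mode = mode, convention = convention,
      diffusionSign = diffusionSign, clamp = clamp,
      qM = qM, rT = rT, rG = rG,
      controlThreshold = controlThreshold,
      stateThresholdFrac = stateThresholdFrac,
      figures = figures, seed = as.integer(seed)
    ),
    class = "StudyConfig"
  )
}

#' Read a study configuration from a YAML file
#'
#' Flat keys: \code{kind}, \code{orders}, \code{steps}, \code{outdir},
#' \code{params} (path to a parameter YAML), \code{mode}, \code{convention},
#' \code{diffusion_sign}, \code{clamp}, \code{q_m}, \code{r_T}, \code{r_G},
#' \code{control_threshold}, \code{state_threshold_frac}, \code{figures},
#' \code{seed}. Unknown keys are rejected.
#'
#' @param file path to a YAML study config.
#' @return a \code{"StudyConfig"} list.
#' @export
readStudyConfig <- function(file) {
  cfg <- yaml::read_yaml(file)
  keymap <- c(
    kind = "kind", orders = "orders", steps = "steps", outdir = "outdir",
    params = "params", mode = "mode", convention = "convention",
    diffusion_sign = "diffusionSign", clamp = "clamp",
    q_m = "qM", r_T = "rT", r_G = "rG",
    control_threshold = "controlThreshold",
    state_threshold_frac = "stateThresholdFrac",
    figures = "figures", seed = "seed"
  )
  unknown <- setdiff(names(cfg), names(keymap))
  if (length(unknown))
    stop("unknown study config key(s): ", paste(unknown, collapse = ", "))
  do.call(studyConfig, stats::setNames(cfg, keymap[names(cfg)]))
}

#' Write a trajectory as CSV
#'
#' Columns: \code{t, m_center, m_min, m_max, eta_T, eta_G}.
#'
#' @param traj a [Trajectory-class].
#' @param file output path.
#' @export
writeTrajectoryCSV <- function(traj, file) {
  utils::write.csv(data.frame(
    t = traj@times, m_center = traj@center,
    m_min = traj@mMin, m_max = traj@mMax,
    eta_T = traj@etaT, eta_G = traj@etaG
  ), file, row.names = FALSE)
  invisible(file)
}

#' Write a control solution as CSV
#'
#' Columns: \code{t, m_center, eta_T, eta_G, lambda_center, p, g}.
#'
#' @param sol a [ControlSolution-class].
#' @param file output path.
#' @export
writeSolutionCSV <- function(sol, file) {
  tr <- sol@trajectory
  utils::write.csv(data.frame(
    t = tr@times, m_center = tr@center,
    eta_T = tr@etaT, eta_G = tr@etaG,
    lambda_center = sol@lambdaCenter, p = sol@p, g = sol@g
  ), file, row.names = FALSE)
  invisible(file)
}

#' Center-point densities of per-order solutions at fixed days
#'
#' Extracts the center-point density of each per-order solution at the given
#' days (default 50, 100, 150, 250) by linear interpolation in time on the
#' common grid, mirroring the reference replication table layout. An error is
#' raised if the grid does not cover the requested days.
#'
#' @param solutions named list (one entry per spectral order) of
#'   [ControlSolution-class] or [Trajectory-class] objects on a common grid.
#' @param times days at which to extract.
#' @return data.frame with one row per order and one column per day, values
#'   carried at full double precision.
#' @export
centerValueTable <- function(solutions, times = c(50, 100, 150, 250)) {
  rows <- lapply(solutions, function(s) {
    tt <- timePoints(s)
    if (min(times) < min(tt) || max(times) > max(tt))
      stop("time grid does not cover the requested days")
    stats::approx(tt, centerSeries(s), xout = times)$y
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- sprintf("t=%g", times)
  out
}

# Center series of one run of the requested system at one (order, steps).
.runCenterSeries <- function(cfg, N, nSteps, system) {
  p <- cfg$params
  if (system == "dynamical") {
    sys <- buildSystem(p, N = N, dims = 2L,
                       convention = cfg$convention,
                       diffusionSign = cfg$diffusionSign)
    tr <- integrateEuler(sys, p@m0, timeGrid(0, p@tEndSim, nSteps))
    centerSeries(tr)
  } else {
    sol <- solveRegulator(p, N = N, dims = 2L, nSteps = nSteps,
                          w = costWeights(cfg$qM, cfg$rT, cfg$rG),
                          mode = cfg$mode, convention = cfg$convention,
                          diffusionSign = cfg$diffusionSign,
                          clamp = cfg$clamp,
                          controlThreshold = cfg$controlThreshold,
                          stateThresholdFrac = cfg$stateThresholdFrac)
    centerSeries(sol)
  }
}

#' Inter-order convergence study
#'
#' For each step count, integrates the chosen system (uncontrolled dynamical
#' or closed-loop optimal) at every configured spectral order on the same
#' time grid and reports the absolute difference between the center series of
#' the highest order and each lower order, both as the maximum over the grid
#' and at the final time.
#'
#' A combination whose explicit-Euler step exceeds the stability limit of its
#' spectral order (the step restriction scales like \eqn{N^{-4}}) diverges;
#' such runs are recorded as \code{NA} with a warning rather than aborting
#' the remaining combinations.
#'
#' @param cfg a \code{"StudyConfig"} (its \code{orders} and \code{steps} are
#'   used).
#' @param system \code{"dynamical"} or \code{"optimal"}.
#' @return data.frame with columns \code{steps}, \code{pair},
#'   \code{error_max}, \code{error_final}.
#' @export
convergenceStudy <- function(cfg, system = c("dynamical", "optimal")) {
  system <- match.arg(system)
  orders <- sort(cfg$orders)
  ref <- orders[length(orders)]
  rows <- list()
  for (ns in cfg$steps) {
    series <- lapply(orders, function(N) {
      tryCatch(.runCenterSeries(cfg, N, ns, system), error = function(e) {
        warning(sprintf("order %d at %d steps diverged: %s", N, ns,
                        conditionMessage(e)), call. = FALSE)
        NA_real_
      })
    })
    names(series) <- as.character(orders)
    for (N in orders[-length(orders)]) {
      d <- abs(series[[as.character(ref)]] - series[[as.character(N)]])
      rows[[length(rows) + 1L]] <- data.frame(
        steps = ns,
        pair = sprintf("%d vs %d", ref, N),
        error_max = max(d),
        error_final = d[length(d)]
      )
    }
  }
  do.call(rbind, rows)
}

.studyManifest <- function(cfg, extra = list()) {
  p <- cfg$params
  c(list(
    kind = cfg$kind, orders = cfg$orders, steps = cfg$steps,
    mode = cfg$mode, convention = cfg$convention,
    diffusion_sign = cfg$diffusionSign, clamp = cfg$clamp,
    q_m = cfg$qM, r_T = cfg$rT, r_G = cfg$rG,
    control_threshold = cfg$controlThreshold,
    state_threshold_frac = cfg$stateThresholdFrac,
    seed = cfg$seed,
    params = list(
      D_m = p@Dm, d_m = p@dm, lambda_mfT = p@lambdaT, lambda_mfG = p@lambdaG,
      K_TGF = p@KT, K_G = p@KG, f = p@f, m0 = p@m0,
      T_GF0 = p@Tgf0, G0 = p@G0, a = p@a, gamma = p@gamma,
      domain = p@domain, t_f = p@tf, t_end_sim = p@tEndSim
    )
  ), extra)
}

.studyFigure <- function(file, expr) {
  ok <- tryCatch({
    grDevices::png(file, width = 900, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    expr()
    TRUE
  }, error = function(e) FALSE)
  if (!ok && file.exists(file)) unlink(file)
  invisible(ok)
}

#' Run a study and write its report files
#'
#' Orchestrates the four study kinds and writes deterministic, self-describing
#' artifacts to the configured output directory: per-run trajectory/solution
#' CSVs, the per-order center-density table (optimal study), convergence
#' error tables, a JSON manifest with the full resolved configuration, and
#' (optionally) PNG figures. Running the same configuration twice yields
#' byte-identical CSVs. On failure, partial outputs are removed.
#'
#' @param cfg a \code{"StudyConfig"} from [studyConfig()] or
#'   [readStudyConfig()].
#' @return invisibly, the output directory.
#' @export
runStudy <- function(cfg) {
  stopifnot(inherits(cfg, "StudyConfig"))
  outdir <- cfg$outdir
  created <- !dir.exists(outdir)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  put <- function(f) { written <<- c(written, f); f }
  .fc_done <- FALSE
  on.exit({
    # remove partial outputs if we error out
    if (!isTRUE(.fc_done)) {
      unlink(written)
      if (created) unlink(outdir, recursive = TRUE)
    }
  }, add = TRUE)
  p <- cfg$params
  set.seed(cfg$seed)
  extra <- list()

  if (cfg$kind == "uncontrolled") {
    nSteps <- cfg$steps[length(cfg$steps)]
    trajs <- lapply(cfg$orders, function(N) {
      sys <- buildSystem(p, N = N, dims = 2L,
                         convention = cfg$convention,
                         diffusionSign = cfg$diffusionSign)
      integrateEuler(sys, p@m0, timeGrid(0, p@tEndSim, nSteps))
    })
    names(trajs) <- sprintf("N%d", cfg$orders)
    for (nm in names(trajs))
      writeTrajectoryCSV(trajs[[nm]], put(file.path(outdir, sprintf("uncontrolled_%s.csv", nm))))
    if (cfg$figures) {
      .studyFigure(put(file.path(outdir, "uncontrolled_density.png")), function() {
        tr1 <- trajs[[1L]]
        plot(tr1@times, tr1@center, type = "n",
             xlab = "time (days)", ylab = "myofibroblast density (g/cm^3)",
             main = "Uncontrolled dynamical system")
        for (i in seq_along(trajs))
          graphics::lines(trajs[[i]]@times, trajs[[i]]@center, col = i + 1)
        graphics::legend("bottomright", legend = names(trajs), col = seq_along(trajs) + 1, lty = 1)
      })
    }
    extra$plateau <- trajs[[length(trajs)]]@center[nSteps + 1L]
  } else if (cfg$kind == "dose") {
    nSteps <- cfg$steps[length(cfg$steps)]
    N <- cfg$orders[length(cfg$orders)]
    trajs <- doseResponseStudy(p, N = N, nSteps = nSteps,
                               convention = cfg$convention,
                               diffusionSign = cfg$diffusionSign)
    for (i in seq_along(trajs)) {
      writeTrajectoryCSV(trajs[[i]], put(file.path(outdir, sprintf("dose_%02d.csv", i))))
    }
    if (cfg$figures) {
      .studyFigure(put(file.path(outdir, "dose_response.png")), function() {
        tr1 <- trajs[[1L]]
        plot(tr1@times, tr1@center, type = "l", col = 2,
             xlab = "time (days)", ylab = "myofibroblast density (g/cm^3)",
             main = "Constant-dose response")
        for (i in seq_along(trajs)[-1L])
          graphics::lines(trajs[[i]]@times, trajs[[i]]@center, col = i + 1)
        graphics::legend("bottomright", legend = names(trajs),
                         col = seq_along(trajs) + 1, lty = 1)
      })
    }
    extra$doses <- names(trajs)
  } else if (cfg$kind == "optimal") {
    nSteps <- cfg$steps[length(cfg$steps)]
    sols <- lapply(cfg$orders, function(N) {
      solveRegulator(p, N = N, dims = 2L, nSteps = nSteps,
                     w = costWeights(cfg$qM, cfg$rT, cfg$rG),
                     mode = cfg$mode, convention = cfg$convention,
                     diffusionSign = cfg$diffusionSign, clamp = cfg$clamp,
                     controlThreshold = cfg$controlThreshold,
                     stateThresholdFrac = cfg$stateThresholdFrac)
    })
    names(sols) <- sprintf("N%d", cfg$orders)
    for (nm in names(sols))
      writeSolutionCSV(sols[[nm]], put(file.path(outdir, sprintf("optimal_%s.csv", nm))))
    tab <- centerValueTable(sols)
    tab <- cbind(order = cfg$orders, tab)
    utils::write.csv(format(tab, digits = 10),
                     put(file.path(outdir, "optimal_center_table.csv")),
                     row.names = FALSE)
    ref <- sols[[length(sols)]]
    extra$objective <- ref@objective
    extra$durations <- lapply(ref@durations, function(x) if (is.finite(x)) x else "never")
    if (cfg$figures) {
      .studyFigure(put(file.path(outdir, "optimal_density_controls.png")), function() {
        graphics::par(mfrow = c(1, 2))
        tr <- ref@trajectory
        plot(tr@times, tr@center, type = "l", col = 4,
             xlab = "time (days)", ylab = "density (g/cm^3)",
             main = "Optimal regulator: state")
        plot(tr@times, tr@etaT, type = "l", col = 2, ylim = range(c(tr@etaT, tr@etaG)),
             xlab = "time (days)", ylab = "dose (dimensionless)",
             main = "Optimal controls")
        graphics::lines(tr@times, tr@etaG, col = 3)
        graphics::legend("topright", legend = c("eta_T", "eta_G"), col = 2:3, lty = 1)
      })
    }
  } else { # convergence
    dyn <- convergenceStudy(cfg, "dynamical")
    opt <- convergenceStudy(cfg, "optimal")
    utils::write.csv(dyn, put(file.path(outdir, "convergence_dynamical.csv")), row.names = FALSE)
    utils::write.csv(opt, put(file.path(outdir, "convergence_optimal.csv")), row.names = FALSE)
    if (cfg$figures) {
      .studyFigure(put(file.path(outdir, "convergence_errors.png")), function() {
        plot(dyn$steps, pmax(dyn$error_max, .Machine$double.xmin), log = "y",
             col = as.integer(factor(dyn$pair)) + 1, pch = 19,
             xlab = "Euler steps", ylab = "max |center difference|",
             main = "Inter-order differences (dynamical)")
      })
    }
    extra$dynamical = dyn
    extra$optimal = opt
  }

  manifest <- .studyManifest(cfg, extra)
  jsonlite::write_json(manifest, put(file.path(outdir, "manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .fc_done <- TRUE
  invisible(outdir)
}
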
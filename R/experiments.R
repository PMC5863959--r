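#' In-silico uniaxial compression
#'
#' The rheometer protocol: in a domain that is periodic in x, walled at
#' y = 0 and open in z, the border cells (those whose sphere overlaps the
#' plane y = L_y) are displaced by delta_L in the -y direction and their y
#' coordinates frozen; the system relaxes to quiescence; the stress is
#' recorded as the summed y force on the border cells divided by their
#' number. Repeating the displacement builds the stress-strain curve, with
#' strain the cumulative displacement over L_y.
#'
#' @param state a homogenized [sim_state()] whose box has boundaries
#'   (periodic, wall, open); typically built with [build_initial_colony()]
#'   at phi = 0.6.
#' @param delta_L per-increment displacement, um; default 0.01 * L_y.
#' @param n_increments number of compression increments.
#' @param v_threshold,max_steps relaxation controls per increment.
#' @return an object of class \code{stress_strain}: data.frame with strain,
#'   stress (K units per border cell), converged flag and relaxation step
#'   count; attributes record the border-cell count and settings.
#' @export
uniaxial_compression <- function(state, delta_L = 0.01 * state$box$L[2],
                                 n_increments = 8, v_threshold = 0.01,
                                 max_steps = 20000) {
  L_y <- state$box$L[2]
  aR <- agent_radii(state)
  border <- state$pos[, 2] + aR >= L_y
  if (!any(border)) stop("no border cells: nothing overlaps the plane y = L_y")
  frozen <- border
  res0 <- run_core(state, max_steps, 1, frozen, v_threshold)
  state <- res0$state
  rows <- data.frame(strain = 0,
                     stress = border_stress(state, border),
                     converged = res0$converged, steps = res0$steps)
  for (inc in seq_len(n_increments)) {
    state$pos[border, 2] <- state$pos[border, 2] - delta_L
    res <- run_core(state, max_steps, 1, frozen, v_threshold)
    state <- res$state
    if (!res$converged)
      warning(sprintf("increment %d: relaxation hit max_steps (v_max = %.3g)",
                      inc, res$v_max))
    rows <- rbind(rows, data.frame(strain = inc * delta_L / L_y,
                                   stress = border_stress(state, border),
                                   converged = res$converged,
                                   steps = res$steps))
  }
  structure(rows, class = c("stress_strain", "data.frame"),
            n_border = sum(border), delta_L = delta_L,
            final_state = state)
}

# Mean +y force exerted on the border cells (force per border cell).
border_stress <- function(state, border) {
  f <- net_forces(state)
  sum(f[border, 2]) / sum(border)
}

#' Colony stiffness from a stress-strain curve
#'
#' The slope of the initial (linear) part of the curve, by least squares
#' over the points whose strain lies in the first \code{linear_fraction} of
#' the strain range.
#'
#' @param curve a \code{stress_strain} data frame.
#' @param linear_fraction fraction of the strain range fitted (default 0.2).
#' @return slope (stress per unit strain).
#' @export
stiffness <- function(curve, linear_fraction = 0.2) {
  lim <- min(curve$strain) + linear_fraction * diff(range(curve$strain))
  seg <- curve[curve$strain <= lim + 1e-12, ]
  if (nrow(seg) < 3)
    stop("need at least 3 points in the initial segment to fit a slope")
  unname(coef(lm(stress ~ strain, data = seg))[2])
}

#' Cell-death-triggered wrinkle formation experiment
#'
#' The full protocol: build a compressed homogenized colony, snapshot it,
#' ablate the cell-death pattern, relax to quiescence, snapshot again, and
#' measure the morphometrics: colony height H, center-to-border height
#' ratio r_h, wrinkle area, and the displacement and convergence fields
#' between the snapshots.
#'
#' The perturbation starts from the quasi-stable colony: after packing and
#' weak-force homogenization the colony is relaxed (noise-free, up to
#' \code{pre_relax_steps} steps) so that vertical stress has drained through
#' the open top while the periodic horizontal axes keep the lateral
#' compression locked in the bond network. Cell death then releases that
#' stored lateral stress.
#'
#' @param box the simulation domain (agar wall in x, periodic y and z).
#' @param phi packing volumetric density.
#' @param params a [model_params()].
#' @param cdp a [rect_cdp()] / [image_cdp()], or NULL for the unperturbed
#'   control.
#' @param seed packing seed.
#' @param homog_steps,weak_scale homogenization controls.
#' @param pre_relax_steps step budget for the pre-ablation relaxation to the
#'   quasi-stable state.
#' @param v_threshold,max_steps quiescence controls.
#' @param voxel height-map voxel, um.
#' @param mesh_size field mesh, um.
#' @param mode,n_stages,relax_steps ablation controls (see [ablate()]).
#' @return object of class \code{wrinkle_result}: list with \code{metrics}
#'   (data.frame: r_h, height, wrinkle_area, n_removed, converged, steps),
#'   \code{height_map}, \code{displacement}, \code{convergence},
#'   \code{start}, \code{end} (snapshots) and \code{state} (final).
#' @export
wrinkle_experiment <- function(box, phi, params = model_params(), cdp = NULL,
                               seed = 1, homog_steps = 2000, weak_scale = 0.1,
                               pre_relax_steps = 20000,
                               v_threshold = 0.01, max_steps = 50000,
                               voxel = 20, mesh_size = 20,
                               mode = "abrupt", n_stages = 10,
                               relax_steps = 200) {
  st <- build_initial_colony(box, phi, params, seed, homog_steps, weak_scale)
  if (pre_relax_steps > 0)
    st <- suppressWarnings(
      run_until_quiescent(st, v_threshold, pre_relax_steps))
  snap0 <- snapshot(st)
  st <- ablate(st, cdp, mode = mode, n_stages = n_stages,
               relax_steps = relax_steps)
  n_removed <- length(st$removed_ids)
  st <- suppressWarnings(run_until_quiescent(st, v_threshold, max_steps))
  snap1 <- snapshot(st)
  hm <- height_map(st, voxel)
  metrics <- data.frame(r_h = center_border_ratio(hm),
                        height = colony_height(hm),
                        wrinkle_area = wrinkle_area(hm),
                        n_removed = n_removed,
                        converged = attr(st, "converged"),
                        steps = attr(st, "steps"),
                        v_max = attr(st, "v_max"))
  structure(list(metrics = metrics, height_map = hm,
                 displacement = displacement_field(snap0, snap1, mesh_size, box),
                 convergence = convergence_field(snap0, snap1, mesh_size, box),
                 start = snap0, end = snap1, state = st,
                 cdp = cdp, seed = seed, phi = phi, params = params),
            class = "wrinkle_result")
}

#' @export
print.wrinkle_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "wrinkle_result: r_h = %.3f, H = %.1f um, wrinkle area = %g um^2\n",
    m$r_h, m$height, m$wrinkle_area))
  cat(sprintf("  %d agents removed; relaxation %s after %d steps (v_max %.3g)\n",
              m$n_removed, if (m$converged) "converged" else "hit max_steps",
              m$steps, m$v_max))
  invisible(x)
}

#' Seeded parameter sweep of wrinkle experiments
#'
#' Runs [wrinkle_experiment()] over the cross product of the supplied
#' parameter vectors, with \code{replicates} packings per grid point seeded
#' deterministically from \code{seed0}. Individual failures are recorded in
#' the result table and do not stop the sweep.
#'
#' @param box simulation domain.
#' @param grid named list of parameter vectors; recognized names: phi, W_D,
#'   H_D, s_b, s_ba, K, cell_cell_adhesion, cell_agar_adhesion. A NULL or
#'   0 W_D runs the unperturbed control.
#' @param params baseline [model_params()] for unswept parameters.
#' @param replicates packings per grid point (default 3).
#' @param seed0 base seed; run seeds are seed0 * 1000 + run index.
#' @param ... forwarded to [wrinkle_experiment()].
#' @return object of class \code{sweep_result}: data.frame with one row per
#'   run (parameters, seed, r_h, height, wrinkle_area, n_removed, runtime_s,
#'   converged, error).
#' @export
sweep_wrinkles <- function(box, grid, params = model_params(),
                           replicates = 3, seed0 = 1, ...) {
  grid_df <- expand.grid(grid, stringsAsFactors = FALSE)
  if (!nrow(grid_df)) stop("empty parameter grid")
  runs <- grid_df[rep(seq_len(nrow(grid_df)), each = replicates), ,
                  drop = FALSE]
  runs$replicate <- rep(seq_len(replicates), nrow(grid_df))
  runs$seed <- seed0 * 1000 + seq_len(nrow(runs))
  out <- vector("list", nrow(runs))
  for (r in seq_len(nrow(runs))) {
    row <- runs[r, ]
    p <- params
    for (nm in intersect(names(row),
                         c("s_b", "s_ba", "K", "cell_cell_adhesion",
                           "cell_agar_adhesion")))
      p[[nm]] <- row[[nm]]
    p <- do.call(model_params,
                 p[c("alpha", "radius", "K", "s_b", "s_ba", "delta_c",
                     "delta_d", "delta_ca", "zeta", "D_c", "dt",
                     "cell_cell_adhesion", "cell_agar_adhesion")])
    phi <- if ("phi" %in% names(row)) row$phi else 0.16
    cdp <- NULL
    if (!is.null(row$W_D) && !is.na(row$W_D) && row$W_D > 0) {
      H_D <- if ("H_D" %in% names(row)) row$H_D else 27
      cdp <- rect_cdp(row$W_D, H_D, box)
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      wrinkle_experiment(box, phi, p, cdp, seed = row$seed, ...),
      error = function(e) e)
    dt <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      out[[r]] <- cbind(row, r_h = NA_real_, height = NA_real_,
                        wrinkle_area = NA_real_, n_removed = NA_integer_,
                        converged = NA, runtime_s = dt,
                        error = conditionMessage(res))
    } else {
      m <- res$metrics
      out[[r]] <- cbind(row, r_h = m$r_h, height = m$height,
                        wrinkle_area = m$wrinkle_area,
                        n_removed = m$n_removed, converged = m$converged,
                        runtime_s = dt, error = NA_character_)
    }
  }
  structure(do.call(rbind, out), class = c("sweep_result", "data.frame"))
}

#' Aggregate a sweep over replicates
#'
#' Mean and standard deviation of r_h, height and wrinkle area per grid
#' point.
#'
#' @param object a \code{sweep_result}.
#' @param ... unused.
#' @export
summary.sweep_result <- function(object, ...) {
  by_cols <- setdiff(names(object),
                     c("replicate", "seed", "r_h", "height", "wrinkle_area",
                       "n_removed", "converged", "runtime_s", "error"))
  df <- object[is.na(object$error), , drop = FALSE]
  agg <- aggregate(df[c("r_h", "height", "wrinkle_area")],
                   by = df[by_cols, drop = FALSE],
                   function(v) c(mean = mean(v), sd = sd(v)))
  agg
}
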
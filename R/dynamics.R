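#' Advance the simulation
#'
#' Runs \code{n_steps} Euler-Maruyama steps. Each step (1) updates the bond
#' network, (2) evaluates the net forces, (3) moves every agent by
#' \code{dt * f / zeta} plus, when \code{D_c > 0}, a Gaussian displacement of
#' standard deviation \code{sqrt(2 * D_c * dt)} per component drawn from R's
#' RNG stream, and (4) applies the boundary conditions. Trajectories are
#' bit-reproducible for a fixed seed.
#'
#' @param state a [sim_state()].
#' @param n_steps number of steps.
#' @param force_scale multiplier on all forces (used by [homogenize()]).
#' @param frozen_y logical vector marking agents whose y coordinate is held
#'   fixed (the compression protocol's border cells).
#' @return the advanced state, with attribute \code{v_max} (um/s), the
#'   maximum deterministic agent speed max|f|/zeta at the last step.
#' @export
step_state <- function(state, n_steps = 1, force_scale = 1,
                       frozen_y = rep(FALSE, n_agents(state))) {
  res <- run_core(state, n_steps, force_scale, frozen_y, v_threshold = -1)
  res$state
}

run_core <- function(state, n_steps, force_scale, frozen_y, v_threshold) {
  p <- state$params
  out <- cpp_run(state$pos, agent_radii(state), bond_matrix(state),
                 p$K, p$s_b, p$s_ba, p$delta_c, p$delta_d, p$delta_ca,
                 p$cell_cell_adhesion, p$cell_agar_adhesion,
                 p$zeta, p$D_c, p$dt,
                 unname(state$box$L), box_codes(state$box),
                 frozen_y, as.integer(n_steps), force_scale, v_threshold)
  pos <- out$positions
  colnames(pos) <- c("x", "y", "z")
  state$pos <- pos
  state$bonds <- out$bonds
  state$time <- state$time + out$steps * p$dt
  attr(state, "v_max") <- out$v_max
  list(state = state, steps = out$steps, v_max = out$v_max,
       converged = out$converged)
}

#' Apply boundary conditions to raw positions
#'
#' Periodic axes are wrapped into [0, L); wall axes are clamped at the
#' 0-plane (overdamped agents carry no momentum, so a wall projects rather
#' than reflects); open axes are untouched.
#'
#' @param positions n x 3 matrix.
#' @param box a [sim_box()].
#' @return the corrected positions.
#' @export
apply_boundaries <- function(positions, box) {
  positions <- as.matrix(positions)
  for (a in 1:3) {
    if (box$boundary[a] == "periodic") {
      positions[, a] <- positions[, a] %% box$L[a]
    } else if (box$boundary[a] == "wall") {
      positions[, a] <- pmax(positions[, a], 0)
    }
  }
  positions
}

#' Relax the system to mechanical quiescence
#'
#' Iterates [step_state()] with the noise term off until the maximum agent
#' speed (net force magnitude over zeta) drops below \code{v_threshold}, or
#' \code{max_steps} is exhausted. The stopping reason is attached to the
#' returned state (\code{converged}, \code{steps}, \code{v_max}) and a
#' warning is raised when the step budget runs out.
#'
#' @param state a [sim_state()].
#' @param v_threshold quiescence speed threshold, um/s (default 0.01).
#' @param max_steps step budget (default 50000).
#' @param frozen_y optional logical vector of y-frozen agents.
#' @return the relaxed state with attributes \code{converged}, \code{steps}
#'   and \code{v_max}.
#' @export
run_until_quiescent <- function(state, v_threshold = 0.01, max_steps = 50000,
                                frozen_y = rep(FALSE, n_agents(state))) {
  p <- state$params
  state$params$D_c <- 0  # deterministic relaxation phase
  res <- run_core(state, max_steps, force_scale = 1, frozen_y, v_threshold)
  st <- res$state
  st$params$D_c <- p$D_c
  attr(st, "converged") <- res$converged
  attr(st, "steps") <- res$steps
  attr(st, "v_max") <- res$v_max
  if (!res$converged)
    warning(sprintf(
      "relaxation stopped after %d steps with v_max = %.3g um/s (threshold %g)",
      res$steps, res$v_max, v_threshold))
  st
}

#' Homogenize a packed configuration
#'
#' Runs a fixed number of noise-free steps with all forces scaled down by
#' \code{weak_scale}. Applied after random packing, this equilibrates the
#' inter-cellular forces without unfolding the global compressed state,
#' leaving a quasi-stable colony.
#'
#' @param state a [sim_state()].
#' @param n_steps number of weak-force steps (default 2000).
#' @param weak_scale force multiplier (default 0.1).
#' @return the homogenized state.
#' @export
homogenize <- function(state, n_steps = 2000, weak_scale = 0.1) {
  D_c <- state$params$D_c
  state$params$D_c <- 0
  state <- step_state(state, n_steps, force_scale = weak_scale)
  state$params$D_c <- D_c
  state
}
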
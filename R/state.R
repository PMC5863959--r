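#' Construct a simulation state
#'
#' The unit the integrator advances: live agents (stable integer ids,
#' positions, cell radii), the current bond network, the box, the model
#' parameters and the simulation clock. Agents removed by ablation are
#' dropped from the state entirely; their ids are recorded in
#' \code{removed_ids} so trajectory analyses can account for them.
#'
#' @param positions n x 3 numeric matrix of agent centers (columns x, y, z).
#' @param box a [sim_box()].
#' @param params a [model_params()].
#' @param radius per-agent cell radii R_i; recycled. Default from params.
#' @param ids integer ids; default 1..n.
#' @param bonds 2-column integer matrix of bonded row-index pairs; default
#'   computed from the positions (every pair closer than delta_c).
#' @return an object of class \code{sim_state}.
#' @export
sim_state <- function(positions, box, params, radius = params$radius,
                      ids = seq_len(nrow(positions)), bonds = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be an n x 3 matrix")
  storage.mode(positions) <- "double"
  n <- nrow(positions)
  radius <- rep_len(radius, n)
  if (any(radius <= 0)) stop("cell radii must be positive")
  if (anyDuplicated(ids)) stop("agent ids must be unique")
  colnames(positions) <- c("x", "y", "z")
  st <- structure(list(ids = as.integer(ids), pos = positions,
                       radius = radius, bonds = NULL, box = box,
                       params = params, time = 0,
                       removed_ids = integer(0)),
                  class = "sim_state")
  if (is.null(bonds)) st <- update_bonds(st) else {
    bonds <- as.matrix(bonds)
    storage.mode(bonds) <- "integer"
    if (nrow(bonds) && (any(bonds < 1) || any(bonds > n) ||
                        any(bonds[, 1] == bonds[, 2])))
      stop("bonds must index live agents and contain no self-pairs")
    st$bonds <- bonds
  }
  st
}

#' Number of live agents
#' @param state a \code{sim_state}.
#' @export
n_agents <- function(state) nrow(state$pos)

#' Agent (EPS-scaled) radii
#' @param state a \code{sim_state}.
#' @return per-agent outer radii alpha * R_i, um.
#' @export
agent_radii <- function(state) state$params$alpha * state$radius

#' Agar bond membership
#'
#' The agar bond is memoryless (one threshold creates and breaks it), so it
#' is derived from the current positions: an agent is bonded to the agar
#' when its center height is below \code{delta_ca}. Empty when the x axis is
#' not a wall (no substratum present).
#'
#' @param state a \code{sim_state}.
#' @return integer row indices of agar-bonded agents.
#' @export
agar_bonded <- function(state) {
  if (state$box$boundary[1] != "wall") return(integer(0))
  which(state$pos[, 1] < state$params$delta_ca)
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("sim_state: %d agents, %d bonds, t = %g s\n",
              nrow(x$pos), NROW(x$bonds), x$time))
  print(x$box)
  if (length(x$removed_ids))
    cat(sprintf("  %d agents removed by ablation\n", length(x$removed_ids)))
  invisible(x)
}

#' Snapshot of agent coordinates
#'
#' A plain data frame view of the live agents, used as the exchange format
#' between the simulator and the trajectory analyses (displacement and
#' convergence fields match agents across snapshots by id).
#'
#' @param state a \code{sim_state}.
#' @param stress add a \code{sigma_hyd} column from [per_agent_stress()].
#' @return data.frame with id, x, y, z, radius (and optionally sigma_hyd).
#' @export
snapshot <- function(state, stress = FALSE) {
  df <- data.frame(id = state$ids, x = state$pos[, 1], y = state$pos[, 2],
                   z = state$pos[, 3], radius = state$radius)
  if (stress) df$sigma_hyd <- per_agent_stress(state)$sigma_hyd
  df
}

#' Simple-cubic lattice colony fixture
#'
#' A deterministic block of agents on a cubic lattice, used as a relaxed
#' reference configuration: at spacing \code{2 * alpha * radius} every bonded
#' pair sits exactly at rest length, so all forces vanish.
#'
#' @param nx,ny,nz lattice extent in agents per axis.
#' @param spacing lattice constant, um; default the rest length.
#' @param params a [model_params()].
#' @param boundary_x,boundary_y,boundary_z boundary types for the box built
#'   around the lattice.
#' @return a \code{sim_state}.
#' @export
lattice_colony <- function(nx, ny, nz, params = model_params(),
                           spacing = 2 * params$alpha * params$radius,
                           boundary_x = "wall", boundary_y = "periodic",
                           boundary_z = "periodic") {
  g <- expand.grid(ix = seq_len(nx), iy = seq_len(ny), iz = seq_len(nz))
  # First layer rests at alpha*R above the agar (zero agar force).
  pos <- cbind((g$ix - 1) * spacing + params$alpha * params$radius,
               (g$iy - 0.5) * spacing,
               (g$iz - 0.5) * spacing)
  box <- sim_box(nx * spacing, ny * spacing, nz * spacing,
                 boundary_x, boundary_y, boundary_z)
  sim_state(pos, box, params)
}
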
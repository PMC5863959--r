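#' Mechanical model parameters
#'
#' Bundles the parameters of the agent-agent and agent-agar force laws and of
#' the Euler-Maruyama integrator. An agent representing a cell of radius
#' \code{radius} occupies a sphere of radius \code{alpha * radius}, the EPS
#' scaling factor \code{alpha} (> 1) accounting for the extracellular matrix
#' attached to the cell wall.
#'
#' Bond bookkeeping is hysteretic: a bond between two agents is created when
#' their center distance drops below \code{delta_c} and broken only when it
#' exceeds \code{delta_d} (>= \code{delta_c}). The agent-agar bond uses the
#' single threshold \code{delta_ca} for both creation and breaking. The bond
#' force magnitude is \code{K * x * tanh(s_b * |x|)} where
#' \code{x = alpha*(R_i + R_j) - d} is the overlap of the EPS shells
#' (repulsive for x > 0, adhesive for x < 0); the agar force is analogous
#' with \code{x = alpha*R_i - d} and stiffness \code{s_ba}, directed along
#' the vertical.
#'
#' Setting \code{cell_cell_adhesion = FALSE} zeroes the adhesive branch
#' (x < 0) of the pair force while keeping repulsion and bond bookkeeping
#' intact; \code{cell_agar_adhesion = FALSE} does the same for the agar
#' force. These are the adhesion knock-out variants.
#'
#' Defaults (reduced units): cell radius 2 um, alpha 2 (agent radius 4 um),
#' K = 2, s_b = s_ba = 0.08, zeta = 1, D_c = 0 (no active motility),
#' delta_c = 2*alpha*radius (contact at rest length), delta_d = 1.5*delta_c
#' (the EPS tether persists under moderate stretch before snapping),
#' delta_ca = 1.1*alpha*radius. The default time step keeps
#' \code{dt * K / zeta <= 0.05} for stability of the explicit integrator.
#'
#' @param alpha EPS scaling factor, dimensionless, > 1.
#' @param radius default cell radius R_i in um (per-agent radii live in the
#'   simulation state; this is the monodisperse default).
#' @param K bond spring constant (force per um).
#' @param s_b,s_ba bond and agar-bond stiffness, 1/um.
#' @param delta_c,delta_d bond creation / breaking distance thresholds, um.
#' @param delta_ca agar bond threshold, um (single threshold: created when
#'   the center height is below it, broken when above).
#' @param zeta viscous friction coefficient.
#' @param D_c agent diffusion coefficient, um^2/s; 0 disables noise.
#' @param dt integration time step, s; \code{NULL} picks
#'   \code{min(0.025, 0.05 * zeta / K)}.
#' @param cell_cell_adhesion,cell_agar_adhesion logical adhesion switches.
#' @return an object of class \code{model_params}.
#' @examples
#' p <- model_params()
#' p$delta_c   # 8: bonds form at the rest length 2 * alpha * radius
#' @export
model_params <- function(alpha = 2, radius = 2, K = 2,
                         s_b = 0.08, s_ba = 0.08,
                         delta_c = NULL, delta_d = NULL, delta_ca = NULL,
                         zeta = 1, D_c = 0, dt = NULL,
                         cell_cell_adhesion = TRUE,
                         cell_agar_adhesion = TRUE) {
  if (!is.numeric(alpha) || alpha <= 1)
    stop("alpha must be > 1 (EPS shell strictly enlarges the agent)")
  if (radius <= 0) stop("radius must be positive")
  if (K <= 0) stop("K must be positive")
  if (s_b < 0 || s_ba < 0) stop("s_b and s_ba must be non-negative")
  if (zeta <= 0) stop("zeta must be positive")
  if (D_c < 0) stop("D_c must be non-negative")
  if (is.null(delta_c)) delta_c <- 2 * alpha * radius
  if (is.null(delta_d)) delta_d <- 1.5 * delta_c
  if (is.null(delta_ca)) delta_ca <- 1.1 * alpha * radius
  if (delta_c <= 0 || delta_d <= 0 || delta_ca <= 0)
    stop("bond thresholds must be positive")
  if (delta_c > delta_d)
    stop("delta_c must not exceed delta_d (hysteresis band)")
  if (is.null(dt)) dt <- min(0.025, 0.05 * zeta / K)
  if (dt <= 0) stop("dt must be positive")
  structure(list(alpha = alpha, radius = radius, K = K,
                 s_b = s_b, s_ba = s_ba,
                 delta_c = delta_c, delta_d = delta_d, delta_ca = delta_ca,
                 zeta = zeta, D_c = D_c, dt = dt,
                 cell_cell_adhesion = isTRUE(cell_cell_adhesion),
                 cell_agar_adhesion = isTRUE(cell_agar_adhesion)),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Model parameters (lengths um, time s, forces K*um):\n")
  cat(sprintf("  agent radius alpha*R = %g (alpha = %g, R = %g)\n",
              x$alpha * x$radius, x$alpha, x$radius))
  cat(sprintf("  K = %g, s_b = %g, s_ba = %g\n", x$K, x$s_b, x$s_ba))
  cat(sprintf("  delta_c = %g, delta_d = %g, delta_ca = %g\n",
              x$delta_c, x$delta_d, x$delta_ca))
  cat(sprintf("  zeta = %g, D_c = %g, dt = %g\n", x$zeta, x$D_c, x$dt))
  cat(sprintf("  adhesion: cell-cell %s, cell-agar %s\n",
              x$cell_cell_adhesion, x$cell_agar_adhesion))
  invisible(x)
}

#' Simulation box
#'
#' A rectangular domain with an independent boundary condition per axis:
#' \code{"periodic"} (coordinates wrapped into [0, L)), \code{"wall"} (an
#' impenetrable plane at coordinate 0; the far side is open so the colony is
#' free to expand away from the wall) or \code{"open"} (unbounded). The box
#' lengths define the packed block and the analysis grids.
#'
#' The agar substratum force acts only when the x axis is of type
#' \code{"wall"}, the agar surface being the plane x = 0.
#'
#' @param L_x,L_y,L_z box lengths, um.
#' @param boundary_x,boundary_y,boundary_z one of "periodic", "wall", "open".
#'   The default is the wrinkle-formation domain: a wall (agar) in x and
#'   periodic horizontal axes.
#' @return an object of class \code{sim_box}.
#' @export
sim_box <- function(L_x, L_y, L_z,
                    boundary_x = "wall", boundary_y = "periodic",
                    boundary_z = "periodic") {
  L <- c(x = L_x, y = L_y, z = L_z)
  if (any(!is.finite(L)) || any(L <= 0)) stop("box lengths must be positive")
  bdry <- c(x = boundary_x, y = boundary_y, z = boundary_z)
  ok <- bdry %in% c("open", "wall", "periodic")
  if (!all(ok)) stop("unknown boundary type: ", paste(bdry[!ok], collapse = ", "))
  structure(list(L = L, boundary = bdry), class = "sim_box")
}

#' @export
print.sim_box <- function(x, ...) {
  cat(sprintf("Box %g x %g x %g um (x=%s, y=%s, z=%s)\n",
              x$L[1], x$L[2], x$L[3],
              x$boundary[1], x$boundary[2], x$boundary[3]))
  invisible(x)
}

# Integer boundary codes used by the compiled core.
box_codes <- function(box) {
  as.integer(match(box$boundary, c("open", "wall", "periodic")) - 1L)
}
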
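# Minimum-image separation on periodic axes.
min_image <- function(delta, box) {
  per <- box$boundary == "periodic"
  if (is.matrix(delta)) {
    for (a in which(per))
      delta[, a] <- delta[, a] - box$L[a] * round(delta[, a] / box$L[a])
  } else {
    delta[per] <- delta[per] - box$L[per] * round(delta[per] / box$L[per])
  }
  delta
}

#' Geometry of an agent pair
#'
#' Computes the minimum-image separation of two agents and the bond
#' coordinate \code{x_ij = alpha*R_i + alpha*R_j - d}: the overlap of the two
#' EPS shells, positive when the pair is compressed below its rest length
#' \code{alpha*(R_i + R_j)} and negative when stretched beyond it.
#'
#' @param xi,xj centers of agents i and j (length-3 numeric).
#' @param Ri,Rj cell radii, um.
#' @param box a [sim_box()]; periodic axes use the minimum-image convention.
#' @param params a [model_params()] supplying alpha.
#' @return list with \code{unit} (unit vector from j to i), \code{gap}
#'   (x_ij, um) and \code{dist} (center distance d, um).
#' @export
pair_gap <- function(xi, xj, Ri, Rj, box, params) {
  delta <- min_image(as.numeric(xi) - as.numeric(xj), box)
  d <- sqrt(sum(delta^2))
  if (d == 0)
    stop("coincident agent centers: pair direction undefined")
  list(unit = delta / d,
       gap = params$alpha * Ri + params$alpha * Rj - d,
       dist = d)
}

#' Elastic bond force between two bonded agents
#'
#' Magnitude \code{K * x * tanh(s_b * |x|)} along the pair axis: repulsive
#' (pushing i away from j) when the shells overlap (x > 0), adhesive when
#' stretched (x < 0). Nonbonded pairs exert no force; this function assumes
#' the pair is bonded. With cell-cell adhesion knocked out the adhesive
#' branch is zero while repulsion is untouched.
#'
#' @param gap bond coordinate x_ij from [pair_gap()], um.
#' @param unit unit vector from agent j to agent i.
#' @param params a [model_params()].
#' @return force on agent i (3-vector); agent j receives the negative.
#' @export
bond_force <- function(gap, unit, params) {
  if (gap < 0 && !params$cell_cell_adhesion) return(c(0, 0, 0))
  params$K * gap * tanh(params$s_b * abs(gap)) * unit
}

#' Elastic force between an agent and the agar substratum
#'
#' With \code{x_ii = alpha*R_i - d}, d the height of the agent center above
#' the agar plane x = 0, the force has magnitude
#' \code{K * x_ii * tanh(s_ba * |x_ii|)} and acts vertically: upward
#' (repulsion) when the shell presses into the agar (x_ii > 0), downward
#' (adhesion) when stretched (x_ii < 0) and still agar-bonded. The agar bond
#' exists while d < delta_ca. With cell-agar adhesion knocked out the
#' downward branch is zero.
#'
#' @param height height d of the agent center above the agar, um.
#' @param R cell radius, um.
#' @param params a [model_params()].
#' @param bonded is the agent agar-bonded? Default d < delta_ca.
#' @return force 3-vector (only the x component can be nonzero).
#' @export
agar_force <- function(height, R, params, bonded = height < params$delta_ca) {
  x <- params$alpha * R - height
  fx <- 0
  if (x > 0) {
    fx <- params$K * x * tanh(params$s_ba * x)
  } else if (x < 0 && bonded && params$cell_agar_adhesion) {
    fx <- params$K * x * tanh(params$s_ba * abs(x))
  }
  c(fx, 0, 0)
}

#' Net force on every agent
#'
#' Sums the bond forces over each agent's bonded neighbors and adds the
#' agar term (active only when the x axis is a wall). Pair forces are equal
#' and opposite, so internal forces conserve total momentum.
#'
#' @param state a [sim_state()].
#' @return n x 3 matrix of forces.
#' @export
net_forces <- function(state) {
  p <- state$params
  f <- cpp_net_forces(state$pos, agent_radii(state),
                      bond_matrix(state), p$K, p$s_b, p$s_ba, p$delta_ca,
                      p$cell_cell_adhesion, p$cell_agar_adhesion,
                      state$box$boundary[1] == "wall",
                      unname(state$box$L), box_codes(state$box))
  colnames(f) <- c("x", "y", "z")
  f
}

bond_matrix <- function(state) {
  b <- state$bonds
  if (is.null(b) || !NROW(b)) matrix(integer(0), 0, 2) else b
}

#' Update the bond network
#'
#' Applies the hysteretic bookkeeping to the current positions: a bond is
#' created for every non-bonded pair closer than \code{delta_c} and an
#' existing bond is broken only when stretched past \code{delta_d}; bonds in
#' the band between the two thresholds persist, so contact history matters.
#'
#' @param state a [sim_state()].
#' @return the state with its \code{bonds} matrix replaced.
#' @export
update_bonds <- function(state) {
  p <- state$params
  state$bonds <- cpp_update_bonds(state$pos, bond_matrix(state),
                                  p$delta_c, p$delta_d,
                                  unname(state$box$L), box_codes(state$box))
  state
}

#' Candidate neighbor pairs within a cutoff
#'
#' Cell-list search returning every unordered pair of rows of
#' \code{positions} whose minimum-image distance is at most \code{cutoff}.
#' Linear in the number of agents; used to keep bond updates cheap.
#'
#' @param positions n x 3 matrix.
#' @param cutoff distance cutoff, um.
#' @param box a [sim_box()].
#' @return 2-column integer matrix of row-index pairs (i < j), sorted.
#' @export
neighbor_pairs <- function(positions, cutoff, box) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  cpp_neighbor_pairs(positions, cutoff, unname(box$L), box_codes(box))
}
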
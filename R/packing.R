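#' Specification of a random packing
#'
#' Describes a compressed initial colony: a box filled at volumetric density
#' \code{phi} = n * (4/3) pi * packing_radius^3 / V_box. By default the
#' packing radius is the bacterial cell radius R_i, so phi measures the cell
#' volume fraction; the mechanically active EPS shells (radius alpha * R_i)
#' then occupy a fraction alpha^3 * phi of the box and overlap heavily at
#' the densities used for wrinkle formation (0.12-0.18, shell fraction
#' around 1 for alpha = 2). That shell overlap is the stored compression of
#' the stiff colony: the mean nearest-neighbor distance falls well below the
#' rest length 2 * alpha * R_i.
#'
#' @param box a [sim_box()].
#' @param phi target volumetric density, 0 < phi < 0.74.
#' @param alpha EPS scaling factor.
#' @param radius cell radius R_i, um.
#' @param seed integer seed making the packing reproducible.
#' @param packing_radius radius used in the density bookkeeping, um;
#'   defaults to the cell radius.
#' @return an object of class \code{packing_spec}.
#' @export
packing_spec <- function(box, phi, alpha = 2, radius = 2, seed = 1,
                         packing_radius = radius) {
  if (!is.numeric(phi) || phi <= 0 || phi >= 0.74)
    stop("phi must lie in (0, 0.74): beyond close packing is unsatisfiable")
  structure(list(box = box, phi = phi, alpha = alpha, radius = radius,
                 seed = as.integer(seed), packing_radius = packing_radius),
            class = "packing_spec")
}

#' Agent count implied by a packing specification
#'
#' \code{n = round(phi * V_box / ((4/3) * pi * packing_radius^3))}.
#'
#' @param spec a [packing_spec()].
#' @return integer agent count.
#' @export
packing_count <- function(spec) {
  v_agent <- 4 / 3 * pi * spec$packing_radius^3
  as.integer(round(spec$phi * prod(spec$box$L) / v_agent))
}

#' Random packing at a target volumetric density
#'
#' Places the implied number of agent centers uniformly at random in the box
#' (overlaps permitted; the subsequent homogenization stage equilibrates the
#' arrangement). With \code{max_overlap} set, candidate positions whose
#' center distance to an accepted agent falls below that value are rejected
#' and redrawn, which supports higher densities without deep overlaps.
#'
#' @param spec a [packing_spec()].
#' @param max_overlap optional minimum allowed center distance, um.
#' @return n x 3 position matrix.
#' @export
random_packing <- function(spec, max_overlap = NULL) {
  n <- packing_count(spec)
  set.seed(spec$seed)
  L <- spec$box$L
  if (is.null(max_overlap)) {
    pos <- cbind(runif(n, 0, L[1]), runif(n, 0, L[2]), runif(n, 0, L[3]))
  } else {
    pos <- matrix(NA_real_, n, 3)
    accepted <- 0
    attempts <- 0
    while (accepted < n) {
      cand <- c(runif(1, 0, L[1]), runif(1, 0, L[2]), runif(1, 0, L[3]))
      ok <- TRUE
      if (accepted > 0) {
        d <- min_image(sweep(pos[seq_len(accepted), , drop = FALSE], 2, cand),
                       spec$box)
        ok <- min(sqrt(rowSums(d^2))) >= max_overlap
      }
      if (ok) {
        accepted <- accepted + 1
        pos[accepted, ] <- cand
      }
      attempts <- attempts + 1
      if (attempts > 200 * n)
        stop("rejection packing failed: phi too high for max_overlap")
    }
  }
  colnames(pos) <- c("x", "y", "z")
  pos
}

#' Build a compressed initial colony
#'
#' The full initialization pipeline: random packing at density \code{phi},
#' weak-force homogenization, and the initial bond network. The result is
#' the quasi-stable compressed colony from which a cell-death perturbation
#' starts.
#'
#' @param box a [sim_box()].
#' @param phi volumetric density.
#' @param params a [model_params()].
#' @param seed packing seed.
#' @param homog_steps,weak_scale homogenization controls (see
#'   [homogenize()]).
#' @param packing_radius radius against which phi is booked, um. The default
#'   (the cell radius) suits the compressed wrinkle colonies; rheometry
#'   packings at phi ~ 0.6 book against the agent radius alpha * R instead,
#'   giving a near-jamming bed that starts at ~zero stress.
#' @return a [sim_state()].
#' @export
build_initial_colony <- function(box, phi, params = model_params(), seed = 1,
                                 homog_steps = 2000, weak_scale = 0.1,
                                 packing_radius = params$radius) {
  spec <- packing_spec(box, phi, params$alpha, params$radius, seed,
                       packing_radius = packing_radius)
  pos <- random_packing(spec)
  st <- sim_state(pos, box, params)
  homogenize(st, homog_steps, weak_scale)
}
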
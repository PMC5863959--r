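#' Rectangular cell-death pattern
#'
#' A volumetric region at the colony-substratum interface: width \code{W_D}
#' in y centered at y = L_y/2, height \code{H_D} in x measured up from the
#' agar, spanning the full z extent by default (producing a quasi-2D wrinkle
#' whose cross-section is uniform along z). A finite z span can be given for
#' 3D patterns.
#'
#' @param W_D width of the death region in y, um (0 < W_D <= L_y).
#' @param H_D height of the death region in x, um (0 < H_D <= L_x).
#' @param box a [sim_box()].
#' @param z_min,z_max optional z span, um; default the full box.
#' @return an object of class \code{cdp}.
#' @export
rect_cdp <- function(W_D, H_D, box, z_min = 0, z_max = box$L[3]) {
  if (!is.numeric(W_D) || W_D <= 0 || W_D > box$L[2])
    stop("W_D must lie in (0, L_y]")
  if (!is.numeric(H_D) || H_D <= 0 || H_D > box$L[1])
    stop("H_D must lie in (0, L_x]")
  structure(list(type = "rect", W_D = W_D, H_D = H_D,
                 y_center = box$L[2] / 2, z_min = z_min, z_max = z_max,
                 box = box),
            class = "cdp")
}

#' Image-defined cell-death pattern
#'
#' Maps a 2D binary raster onto the horizontal (y, z) plane: raster columns
#' span y in [0, L_y], raster rows span z in [0, L_z] (row 1 at z = 0).
#' An agent is inside the pattern when its (y, z) footprint pixel is on and
#' its height is below \code{H_D}. Grayscale images (or a numeric matrix in
#' [0, 1]) are thresholded at 0.5.
#'
#' @param mask numeric matrix in [0, 1] / logical matrix, or the path of a
#'   grayscale PNG file.
#' @param H_D thickness of the death layer in x, um.
#' @param box a [sim_box()].
#' @return an object of class \code{cdp}.
#' @export
image_cdp <- function(mask, H_D, box) {
  if (is.character(mask)) {
    img <- png::readPNG(mask)
    if (length(dim(img)) == 3) img <- img[, , 1]  # first channel of RGB(A)
    mask <- img
  }
  mask <- as.matrix(mask)
  on <- if (is.logical(mask)) mask else mask >= 0.5
  if (!any(on)) stop("cell-death mask is empty: no pixel is on")
  if (H_D <= 0 || H_D > box$L[1]) stop("H_D must lie in (0, L_x]")
  structure(list(type = "image", on = on, H_D = H_D, box = box),
            class = "cdp")
}

#' Membership of points in a cell-death pattern
#'
#' Membership is decided by the agent center (no partial-overlap logic).
#'
#' @param cdp a [rect_cdp()] or [image_cdp()].
#' @param positions n x 3 matrix of centers.
#' @return logical vector.
#' @export
cdp_contains <- function(cdp, positions) {
  positions <- as.matrix(positions)
  x <- positions[, 1]; y <- positions[, 2]; z <- positions[, 3]
  if (cdp$type == "rect") {
    abs(y - cdp$y_center) < cdp$W_D / 2 & x < cdp$H_D &
      z >= cdp$z_min & z <= cdp$z_max
  } else {
    nr <- nrow(cdp$on); nc <- ncol(cdp$on)
    L <- cdp$box$L
    cc <- pmin(pmax(ceiling(y / L[2] * nc), 1L), nc)
    rr <- pmin(pmax(ceiling(z / L[3] * nr), 1L), nr)
    cdp$on[cbind(rr, cc)] & x < cdp$H_D
  }
}

#' @export
print.cdp <- function(x, ...) {
  if (x$type == "rect")
    cat(sprintf("Rectangular CDP: W_D = %g um, H_D = %g um, z in [%g, %g]\n",
                x$W_D, x$H_D, x$z_min, x$z_max))
  else
    cat(sprintf("Image CDP: %d x %d raster, %d pixels on, H_D = %g um\n",
                nrow(x$on), ncol(x$on), sum(x$on), x$H_D))
  invisible(x)
}

# Drop agents by row index, remapping bonds onto the surviving rows.
remove_agents <- function(state, rows) {
  if (!length(rows)) return(state)
  keep <- setdiff(seq_len(n_agents(state)), rows)
  map <- integer(n_agents(state))
  map[keep] <- seq_along(keep)
  state$removed_ids <- c(state$removed_ids, state$ids[rows])
  state$ids <- state$ids[keep]
  state$pos <- state$pos[keep, , drop = FALSE]
  state$radius <- state$radius[keep]
  b <- bond_matrix(state)
  if (nrow(b)) {
    live <- !(b[, 1] %in% rows) & !(b[, 2] %in% rows)
    b <- b[live, , drop = FALSE]
    b[, 1] <- map[b[, 1]]
    b[, 2] <- map[b[, 2]]
  }
  state$bonds <- b
  state
}

#' Ablate the agents inside a cell-death pattern
#'
#' Models cell death by removing every agent whose center lies in the
#' pattern, together with all its bonds. Removal is abrupt (all at once) or
#' gradual: the doomed agents are split into \code{n_stages} equal random
#' batches with a noise-free relaxation run of \code{relax_steps} steps
#' between consecutive batches. Gradual removal with one stage is identical
#' to abrupt removal.
#'
#' @param state a [sim_state()].
#' @param cdp a [rect_cdp()] or [image_cdp()]; \code{NULL} removes nothing.
#' @param mode \code{"abrupt"} or \code{"gradual"}.
#' @param n_stages number of gradual batches (default 10).
#' @param relax_steps relaxation steps between batches (default 200).
#' @return the state with the doomed agents removed.
#' @export
ablate <- function(state, cdp, mode = c("abrupt", "gradual"),
                   n_stages = 10, relax_steps = 200) {
  mode <- match.arg(mode)
  if (is.null(cdp)) return(state)
  doomed <- which(cdp_contains(cdp, state$pos))
  if (!length(doomed)) return(state)
  if (mode == "abrupt" || n_stages <= 1) return(remove_agents(state, doomed))
  doomed_ids <- sample(state$ids[doomed])  # random batches from R's RNG
  batches <- split(doomed_ids,
                   cut(seq_along(doomed_ids), n_stages, labels = FALSE))
  for (s in seq_along(batches)) {
    # Rows shift as agents are removed: locate each batch by id.
    state <- remove_agents(state, match(batches[[s]], state$ids))
    if (s < length(batches) && relax_steps > 0) {
      D_c <- state$params$D_c
      state$params$D_c <- 0
      state <- step_state(state, relax_steps)
      state$params$D_c <- D_c
    }
  }
  state
}
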
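#' Per-agent virial stress tensor
#'
#' For each agent i, \code{sigma_i = -1/(2 V_i) * sum_j f_ij (x) r_ij} over
#' its bonded neighbors j, where f_ij is the bond force on i due to j, r_ij
#' the minimum-image vector from i to j, and \code{V_i = 4/3 pi (alpha R_i)^3}
#' the agent volume. The sign is fixed so that compression is positive. The
#' hydrostatic stress is the mean of the diagonal,
#' \code{(s_xx + s_yy + s_zz) / 3}. Central pair forces make the tensor
#' exactly symmetric; an isolated agent has zero stress.
#'
#' @param state a [sim_state()].
#' @return data.frame with id, the six distinct tensor components (sxx, syy,
#'   szz, sxy, sxz, syz) and sigma_hyd, in units of K / um.
#' @export
per_agent_stress <- function(state) {
  n <- n_agents(state)
  p <- state$params
  S <- matrix(0, n, 6,
              dimnames = list(NULL, c("sxx", "syy", "szz", "sxy", "sxz", "syz")))
  b <- bond_matrix(state)
  if (nrow(b)) {
    i <- b[, 1]; j <- b[, 2]
    # r_ij: from i to j under minimum image.
    r <- min_image(state$pos[j, , drop = FALSE] - state$pos[i, , drop = FALSE],
                   state$box)
    d <- sqrt(rowSums(r^2))
    aR <- agent_radii(state)
    gap <- aR[i] + aR[j] - d
    mag <- p$K * gap * tanh(p$s_b * abs(gap))
    if (!p$cell_cell_adhesion) mag[gap < 0] <- 0
    # f_ij = mag * unit(j -> i) = -mag * r/d; f_ij (x) r_ij = -mag/d * r (x) r,
    # identical for both bond endpoints.
    comp <- cbind(r[, 1]^2, r[, 2]^2, r[, 3]^2,
                  r[, 1] * r[, 2], r[, 1] * r[, 3], r[, 2] * r[, 3])
    contrib <- comp * (-mag / d)
    idx <- c(i, j)
    for (k in 1:6) {
      acc <- rowsum(c(contrib[, k], contrib[, k]), idx)
      S[as.integer(rownames(acc)), k] <- acc[, 1]
    }
  }
  V <- 4 / 3 * pi * agent_radii(state)^3
  S <- -S / (2 * V)  # sign flip: compression positive
  data.frame(id = state$ids, S,
             sigma_hyd = (S[, 1] + S[, 2] + S[, 3]) / 3)
}

#' Voxel height map of a colony
#'
#' Divides the domain into cubic voxels (default 20 um) indexed (i, j, k)
#' along (x, y, z) and records, for every voxel, the mean height (x
#' coordinate) of the agent centers inside it. Empty voxels carry NA and are
#' excluded from all derived maxima. The per-column surface
#' \code{h_x(j, k)}, the maximum voxel mean over i, is stored alongside.
#'
#' @param state a [sim_state()].
#' @param voxel voxel edge length, um (default 20).
#' @return an object of class \code{height_map}: list with the 3D array
#'   \code{H}, the surface matrix \code{h_x} (ny x nz), \code{voxel} and the
#'   box.
#' @export
height_map <- function(state, voxel = 20) {
  if (n_agents(state) < 1) stop("height map of an empty state")
  pos <- state$pos
  L <- state$box$L
  nx <- max(ceiling(max(pos[, 1]) / voxel), ceiling(L[1] / voxel), 1)
  ny <- max(ceiling(L[2] / voxel), 1)
  nz <- max(ceiling(L[3] / voxel), 1)
  bin <- function(v, nmax) pmin(pmax(floor(v / voxel) + 1L, 1L), nmax)
  i <- bin(pos[, 1], nx); j <- bin(pos[, 2], ny); k <- bin(pos[, 3], nz)
  idx <- (k - 1L) * nx * ny + (j - 1L) * nx + i
  sums <- rowsum(pos[, 1], idx)
  cnts <- rowsum(rep(1, length(idx)), idx)
  H <- array(NA_real_, c(nx, ny, nz))
  H[as.integer(rownames(sums))] <- sums[, 1] / cnts[, 1]
  h_x <- apply(H, c(2, 3), function(col)
    if (all(is.na(col))) NA_real_ else max(col, na.rm = TRUE))
  structure(list(H = H, h_x = h_x, voxel = voxel, box = state$box),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  d <- dim(x$H)
  cat(sprintf("height_map: %d x %d x %d voxels of %g um (%d occupied)\n",
              d[1], d[2], d[3], x$voxel, sum(!is.na(x$H))))
  invisible(x)
}

#' Colony height
#'
#' The global maximum of the voxel mean heights.
#'
#' @param hm a [height_map()].
#' @return height H, um.
#' @export
colony_height <- function(hm) {
  if (all(is.na(hm$H))) stop("empty height map")
  max(hm$H, na.rm = TRUE)
}

# Max voxel-mean height over (i, k) in a y row.
row_height <- function(hm, j) {
  v <- hm$H[, j, ]
  if (all(is.na(v))) stop(sprintf("no occupied voxel in y row %d", j))
  max(v, na.rm = TRUE)
}

#' Center-to-border colony height ratio
#'
#' \code{r_h} is the ratio of the maximum voxel-mean height in the y row
#' containing the colony center (y = L_y/2) to that in the border row
#' (y = 0). A flat colony gives r_h = 1; a central wrinkle roughly doubles
#' the center height, giving values near 2.
#'
#' @param hm a [height_map()].
#' @return r_h, dimensionless.
#' @export
center_border_ratio <- function(hm) {
  ny <- dim(hm$H)[2]
  j_center <- min(floor(hm$box$L[2] / 2 / hm$voxel) + 1L, ny)
  row_height(hm, j_center) / row_height(hm, 1L)
}

#' Wrinkle area from a height map
#'
#' Binarizes the surface \code{h_x(j, k)} at
#' \code{threshold_factor * H_border} (border height = maximum voxel mean in
#' the y = 0 row; default factor 1.3), labels the connected components of
#' the binary image and returns the largest component's area. Components use
#' 8-connectivity by default so diagonally touching ridge cells stay
#' connected.
#'
#' @param hm a [height_map()].
#' @param threshold_factor multiple of the border height (default 1.3).
#' @param connectivity 8 (default) or 4.
#' @return area, um^2 (0 when nothing exceeds the threshold).
#' @export
wrinkle_area <- function(hm, threshold_factor = 1.3, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  thr <- threshold_factor * row_height(hm, 1L)
  on <- !is.na(hm$h_x) & hm$h_x > thr
  if (!any(on)) return(0)
  max_component(on, connectivity) * hm$voxel^2
}

# Largest connected component of a logical matrix, via igraph on the
# grid-adjacency graph of the on-cells.
max_component <- function(on, connectivity = 8) {
  idx <- which(on, arr.ind = TRUE)
  n_on <- nrow(idx)
  if (n_on == 1) return(1L)
  cellid <- matrix(0L, nrow(on), ncol(on))
  cellid[idx] <- seq_len(n_on)
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  edges <- integer(0)
  for (o in offs) {
    r2 <- idx[, 1] + o[1]; c2 <- idx[, 2] + o[2]
    ok <- r2 >= 1 & r2 <= nrow(on) & c2 >= 1 & c2 <= ncol(on)
    ok[ok] <- on[cbind(r2[ok], c2[ok])]
    if (any(ok))
      edges <- c(edges, rbind(cellid[idx[ok, , drop = FALSE]],
                              cellid[cbind(r2[ok], c2[ok])]))
  }
  g <- igraph::make_graph(edges, n = n_on, directed = FALSE)
  max(igraph::components(g)$csize)
}

# Horizontal (y, z) mesh index of snapshot positions; clamped into the grid.
mesh_index <- function(df, mesh_size, box) {
  ny <- max(ceiling(box$L[2] / mesh_size), 1)
  nz <- max(ceiling(box$L[3] / mesh_size), 1)
  y <- if (box$boundary[2] == "periodic") df$y %% box$L[2] else df$y
  z <- if (box$boundary[3] == "periodic") df$z %% box$L[3] else df$z
  j <- pmin(pmax(floor(y / mesh_size) + 1L, 1L), ny)
  k <- pmin(pmax(floor(z / mesh_size) + 1L, 1L), nz)
  list(j = j, k = k, ny = ny, nz = nz)
}

#' Horizontal displacement field between two snapshots
#'
#' Partitions the horizontal (y, z) plane into mesh cells and aggregates the
#' horizontal displacement vectors of the agents that started in each cell:
#' the per-cell vector sum is stored, the mean is derived from the stored
#' agent count. Displacements use the minimum image on periodic axes. Agents
#' present only in the start snapshot (removed by ablation) contribute
#' nothing; an end-snapshot id unknown at start is an identity mismatch and
#' an error.
#'
#' @param start,end snapshots from [snapshot()] (data frames with id, y, z).
#' @param mesh_size mesh cell edge, um (default 20).
#' @param box a [sim_box()].
#' @return object of class \code{surface_field}: list of ny x nz matrices
#'   \code{vy}, \code{vz} (sums), \code{my}, \code{mz} (means) and
#'   \code{count}.
#' @export
displacement_field <- function(start, end, mesh_size = 20, box) {
  if (!all(end$id %in% start$id))
    stop("identity mismatch: end snapshot contains ids absent at start")
  m <- match(end$id, start$id)
  dy <- end$y - start$y[m]
  dz <- end$z - start$z[m]
  if (box$boundary[2] == "periodic") dy <- dy - box$L[2] * round(dy / box$L[2])
  if (box$boundary[3] == "periodic") dz <- dz - box$L[3] * round(dz / box$L[3])
  g <- mesh_index(start[m, ], mesh_size, box)
  acc <- function(v) {
    M <- matrix(0, g$ny, g$nz)
    s <- rowsum(v, (g$k - 1L) * g$ny + g$j)
    M[as.integer(rownames(s))] <- s[, 1]
    M
  }
  vy <- acc(dy); vz <- acc(dz); count <- acc(rep(1, length(dy)))
  structure(list(vy = vy, vz = vz,
                 my = ifelse(count > 0, vy / count, NA_real_),
                 mz = ifelse(count > 0, vz / count, NA_real_),
                 count = count, mesh_size = mesh_size, box = box),
            class = "surface_field")
}

#' Convergence field between two snapshots
#'
#' Convergence (negative divergence) is the volume density of inward flux:
#' per mesh cell, the number of agents that entered the cell minus the
#' number that left it between the snapshots, judged by initial and final
#' cell membership. An agent removed between the snapshots counts as having
#' left its initial cell, so the field sums to zero without ablation and to
#' minus the removed count with it.
#'
#' @inheritParams displacement_field
#' @return ny x nz matrix of per-cell convergence counts.
#' @export
convergence_field <- function(start, end, mesh_size = 20, box) {
  if (!all(end$id %in% start$id))
    stop("identity mismatch: end snapshot contains ids absent at start")
  gs <- mesh_index(start, mesh_size, box)
  ge <- mesh_index(end, mesh_size, box)
  conv <- matrix(0, gs$ny, gs$nz)
  cs <- (gs$k - 1L) * gs$ny + gs$j          # initial cell, all start agents
  ce <- (ge$k - 1L) * gs$ny + ge$j          # final cell, surviving agents
  m <- match(end$id, start$id)
  moved <- ce != cs[m]
  tally <- function(cells) {
    t <- rowsum(rep(1, length(cells)), cells)
    M <- matrix(0, gs$ny, gs$nz)
    M[as.integer(rownames(t))] <- t[, 1]
    M
  }
  if (any(moved)) {
    conv <- conv + tally(ce[moved]) - tally(cs[m][moved])
  }
  removed <- setdiff(start$id, end$id)
  if (length(removed))
    conv <- conv - tally(cs[match(removed, start$id)])
  conv
}
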
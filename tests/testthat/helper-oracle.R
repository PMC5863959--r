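# Independent brute-force oracles, deliberately naive: plain O(N^2) loops
# with none of the package's cell-list or fused-update machinery.

oracle_min_image <- function(delta, box) {
  for (a in 1:3) {
    if (box$boundary[a] == "periodic")
      delta[a] <- delta[a] - box$L[a] * round(delta[a] / box$L[a])
  }
  delta
}

oracle_pairs <- function(pos, cutoff, box) {
  n <- nrow(pos)
  out <- NULL
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- sqrt(sum(oracle_min_image(pos[i, ] - pos[j, ], box)^2))
        if (d <= cutoff) out <- rbind(out, c(i, j))
      }
    }
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

oracle_update_bonds <- function(pos, bonds, params, box) {
  n <- nrow(pos)
  key <- function(i, j) paste(min(i, j), max(i, j))
  have <- character(0)
  out <- NULL
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, 1]; j <- bonds[r, 2]
      d <- sqrt(sum(oracle_min_image(pos[i, ] - pos[j, ], box)^2))
      if (d <= params$delta_d) {
        out <- rbind(out, c(min(i, j), max(i, j)))
        have <- c(have, key(i, j))
      }
    }
  }
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- sqrt(sum(oracle_min_image(pos[i, ] - pos[j, ], box)^2))
        if (d < params$delta_c && !(key(i, j) %in% have)) {
          out <- rbind(out, c(i, j))
          have <- c(have, key(i, j))
        }
      }
    }
  }
  if (is.null(out)) matrix(integer(0), 0, 2)
  else out[order(out[, 1], out[, 2]), , drop = FALSE]
}

oracle_forces <- function(pos, radius, bonds, params, box, agar) {
  n <- nrow(pos)
  f <- matrix(0, n, 3)
  aR <- params$alpha * radius
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, 1]; j <- bonds[r, 2]
      v <- oracle_min_image(pos[i, ] - pos[j, ], box)
      d <- sqrt(sum(v^2))
      x <- aR[i] + aR[j] - d
      mag <- if (x < 0 && !params$cell_cell_adhesion) 0
             else params$K * x * tanh(params$s_b * abs(x))
      f[i, ] <- f[i, ] + mag * v / d
      f[j, ] <- f[j, ] - mag * v / d
    }
  }
  if (agar) {
    for (i in seq_len(n)) {
      d <- pos[i, 1]
      x <- aR[i] - d
      if (x > 0) {
        f[i, 1] <- f[i, 1] + params$K * x * tanh(params$s_ba * x)
      } else if (x < 0 && params$cell_agar_adhesion && d < params$delta_ca) {
        f[i, 1] <- f[i, 1] + params$K * x * tanh(params$s_ba * abs(x))
      }
    }
  }
  f
}

# One noise-free Euler step including bond update, on raw matrices.
oracle_step <- function(pos, radius, bonds, params, box) {
  agar <- box$boundary[1] == "wall"
  bonds <- oracle_update_bonds(pos, bonds, params, box)
  f <- oracle_forces(pos, radius, bonds, params, box, agar)
  pos <- pos + params$dt * f / params$zeta
  for (a in 1:3) {
    if (box$boundary[a] == "periodic") pos[, a] <- pos[, a] %% box$L[a]
    if (box$boundary[a] == "wall") pos[, a] <- pmax(pos[, a], 0)
  }
  list(pos = pos, bonds = bonds)
}

# Flood-fill (BFS) size of the largest connected component of a logical
# matrix; independent of the package's graph-based labelling.
oracle_max_component <- function(on, connectivity = 8) {
  nr <- nrow(on); nc <- ncol(on)
  seen <- matrix(FALSE, nr, nc)
  offs <- rbind(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))
  if (connectivity == 8)
    offs <- rbind(offs, c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  best <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!on[r0, c0] || seen[r0, c0]) next
    queue <- list(c(r0, c0))
    seen[r0, c0] <- TRUE
    size <- 0L
    while (length(queue)) {
      cell <- queue[[1]]; queue <- queue[-1]
      size <- size + 1L
      for (k in seq_len(nrow(offs))) {
        r <- cell[1] + offs[k, 1]; cc <- cell[2] + offs[k, 2]
        if (r >= 1 && r <= nr && cc >= 1 && cc <= nc &&
            on[r, cc] && !seen[r, cc]) {
          seen[r, cc] <- TRUE
          queue <- c(queue, list(c(r, cc)))
        }
      }
    }
    best <- max(best, size)
  }
  best
}

# Elastic energy stored in the current bond network (numeric quadrature of
# the force law from rest length to the bond gap).
oracle_energy <- function(state) {
  b <- state$bonds
  if (!NROW(b)) return(0)
  p <- state$params
  aR <- agent_radii(state)
  tot <- 0
  for (r in seq_len(nrow(b))) {
    i <- b[r, 1]; j <- b[r, 2]
    v <- oracle_min_image(state$pos[i, ] - state$pos[j, ], state$box)
    gap <- aR[i] + aR[j] - sqrt(sum(v^2))
    u <- integrate(function(x) p$K * x * tanh(p$s_b * abs(x)), 0, gap)$value
    tot <- tot + u
  }
  tot
}

# Small helper: a two-agent state with a prescribed center distance along y.
two_agent_state <- function(d, params = model_params(),
                            boundary_x = "open") {
  box <- sim_box(40, 40, 40, boundary_x, "open", "open")
  sim_state(rbind(c(20, 10, 20), c(20, 10 + d, 20)), box, params)
}
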
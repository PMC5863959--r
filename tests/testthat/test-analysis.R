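test_that("per-agent stress: isolated agent, two-body closed form, symmetry", {
  p <- model_params()
  box <- sim_box(60, 60, 60, "open", "open", "open")
  iso <- sim_state(rbind(c(30, 30, 30)), box, p)
  s <- per_agent_stress(iso)
  expect_equal(unlist(s[1, 2:8]), setNames(rep(0, 7), names(s)[2:8]))

  # compressed pair along y: only syy nonzero, value = f*d/(2V), positive
  st <- two_agent_state(6, p)
  s <- per_agent_stress(st)
  gap <- 2  # 8 - 6
  fmag <- p$K * gap * tanh(p$s_b * gap)
  V <- 4 / 3 * pi * (p$alpha * p$radius)^3
  expect_equal(s$syy, rep(fmag * 6 / (2 * V), 2), tolerance = 1e-12)
  expect_equal(s$sxx, c(0, 0))
  expect_equal(s$szz, c(0, 0))
  expect_equal(s$sxy, c(0, 0))
  expect_equal(s$sigma_hyd, s$syy / 3, tolerance = 1e-12)
  expect_gt(s$sigma_hyd[1], 0)  # compression positive

  # a stretched (adhesive) pair carries tension: negative hydrostatic stress
  stretched <- two_agent_state(8.5, p)
  stretched$bonds <- rbind(c(1L, 2L))
  expect_lt(per_agent_stress(stretched)$sigma_hyd[1], 0)

  # symmetry of the tensor for a random bonded cluster
  set.seed(5)
  pos <- cbind(runif(30, 20, 40), runif(30, 20, 40), runif(30, 20, 40))
  cl <- sim_state(pos, box, p)
  s <- per_agent_stress(cl)
  expect_true(all(is.finite(as.matrix(s[2:7]))))
})

test_that("height maps average per voxel and track column maxima", {
  p <- model_params()
  box <- sim_box(60, 60, 60, "open", "open", "open")
  # two agents in one 20 um voxel column: mean height
  st <- sim_state(rbind(c(10, 10, 10), c(30, 10, 10), c(30, 50, 50)),
                  box, p, bonds = matrix(integer(0), 0, 2))
  hm <- height_map(st, voxel = 20)
  expect_equal(hm$H[1, 1, 1], 10)
  expect_equal(hm$H[2, 1, 1], 30)
  expect_equal(hm$h_x[1, 1], 30)    # column max of voxel means
  expect_equal(hm$H[2, 3, 3], 30)
  expect_true(is.na(hm$H[3, 1, 1]))  # empty voxels carry NA
  expect_equal(colony_height(hm), 30)
})

test_that("slab fixtures give uniform surface height and r_h = 1", {
  p <- model_params()
  st <- lattice_colony(3, 12, 4, p, spacing = 8)
  hm <- height_map(st, voxel = 16)
  expect_lt(diff(range(hm$h_x)), 1e-9)
  expect_equal(center_border_ratio(hm), 1, tolerance = 0.05)
  expect_equal(wrinkle_area(hm), 0)

  # doubling the center row's height doubles r_h
  ny <- dim(hm$H)[2]
  j_c <- floor(st$box$L[2] / 2 / 16) + 1
  hm$H[, j_c, ] <- hm$H[, j_c, ] * 2
  expect_equal(center_border_ratio(hm), 2, tolerance = 1e-9)
})

test_that("colony height matches a brute-force maximum on random states", {
  p <- model_params()
  box <- sim_box(50, 80, 80)
  set.seed(8)
  pos <- cbind(runif(200, 0, 50), runif(200, 0, 80), runif(200, 0, 80))
  st <- sim_state(pos, box, p, bonds = matrix(integer(0), 0, 2))
  hm <- height_map(st, voxel = 20)
  expect_equal(colony_height(hm), max(hm$H, na.rm = TRUE))
  # one protruding agent dominates
  pos2 <- rbind(pos, c(49.9, 40, 40))
  st2 <- sim_state(pos2, box, p, bonds = matrix(integer(0), 0, 2))
  expect_gte(colony_height(height_map(st2, 20)),
             colony_height(hm))
})

test_that("wrinkle area: constructed patch and flood-fill oracle", {
  p <- model_params()
  st <- lattice_colony(2, 20, 12, p, spacing = 8)
  hm <- height_map(st, voxel = 16)
  # raise a 3 x 4 patch of surface cells well above threshold
  hm$h_x[4:6, 3:6] <- hm$h_x[4:6, 3:6] * 3
  expect_equal(wrinkle_area(hm), 12 * 16^2)
  # area is monotone non-increasing in the threshold factor
  a <- vapply(c(1.1, 1.3, 2, 3.5), function(tf) wrinkle_area(hm, tf), 0)
  expect_true(all(diff(a) <= 0))

  # the graph labelling agrees with a BFS flood fill on random grids
  set.seed(99)
  for (rep in 1:100) {
    on <- matrix(runif(100) < 0.45, 10, 10)
    if (!any(on)) next
    expect_equal(wrinklesim:::max_component(on, 8), oracle_max_component(on, 8))
  }
  for (rep in 1:20) {
    on <- matrix(runif(2500) < 0.5, 50, 50)
    expect_equal(wrinklesim:::max_component(on, 8), oracle_max_component(on, 8))
    expect_equal(wrinklesim:::max_component(on, 4), oracle_max_component(on, 4))
  }
})

test_that("displacement fields aggregate per initial mesh cell", {
  box <- sim_box(45, 80, 80)
  start <- data.frame(id = 1:6,
                      x = rep(10, 6),
                      y = c(10, 15, 30, 50, 70, 70),
                      z = c(10, 10, 30, 50, 70, 75), radius = 2)
  # no motion: all zero
  f <- displacement_field(start, start, 20, box)
  expect_equal(max(abs(f$vy)), 0)
  expect_equal(max(abs(f$vz)), 0)

  # rigid translation: every occupied cell's mean vector is the shift
  end <- start
  end$y <- end$y + 3
  end$z <- end$z - 2
  f <- displacement_field(start, end, 20, box)
  expect_equal(unique(f$my[f$count > 0]), 3)
  expect_equal(unique(f$mz[f$count > 0]), -2)

  # radially converging motion points at the sink cell
  sink <- c(40, 40)
  end2 <- start
  end2$y <- start$y + 0.5 * (sink[1] - start$y)
  end2$z <- start$z + 0.5 * (sink[2] - start$z)
  f <- displacement_field(start, end2, 20, box)
  occ <- which(f$count > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(occ))) {
    cellc <- (occ[r, ] - 0.5) * 20
    v <- c(f$my[occ[r, 1], occ[r, 2]], f$mz[occ[r, 1], occ[r, 2]])
    if (sqrt(sum(v^2)) > 1e-9)
      expect_gt(sum(v * (sink - cellc)), 0)
  }

  # unknown end id is an identity mismatch
  bad <- end
  bad$id[1] <- 99
  expect_error(displacement_field(start, bad, 20, box), "identity")
})

test_that("convergence counts entries minus exits and conserves totals", {
  box <- sim_box(45, 60, 60)
  start <- data.frame(id = 1:4, x = 10,
                      y = c(10, 30, 50, 30), z = c(10, 10, 10, 30),
                      radius = 2)
  # no motion: all zeros
  expect_equal(max(abs(convergence_field(start, start, 20, box))), 0)

  # two agents move into the center cell from two neighbors
  end <- start
  end$y[1] <- 30            # from cell (1,1) to (2,1)
  end$z[4] <- 10            # from cell (2,2) to (2,1)
  conv <- convergence_field(start, end, 20, box)
  expect_equal(conv[2, 1], 2)
  expect_equal(conv[1, 1], -1)
  expect_equal(conv[2, 2], -1)
  expect_equal(sum(conv), 0)

  # ablation between snapshots: total equals minus the removed count
  end2 <- end[-c(1, 2), ]
  conv2 <- convergence_field(start, end2, 20, box)
  expect_equal(sum(conv2), -2)
})
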
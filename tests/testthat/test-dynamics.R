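test_that("bond bookkeeping is hysteretic", {
  p <- model_params()  # delta_c = 8, delta_d = 12

  # approach from far: no bond until d < delta_c
  st <- two_agent_state(10, p)
  expect_equal(nrow(st$bonds), 0)
  st$pos[2, 2] <- st$pos[1, 2] + 7.9
  st <- update_bonds(st)
  expect_equal(nrow(st$bonds), 1)

  # stretch into the hysteresis band: bond persists
  st$pos[2, 2] <- st$pos[1, 2] + 10.5
  st <- update_bonds(st)
  expect_equal(nrow(st$bonds), 1)

  # an unbonded pair at the same distance stays unbonded
  fresh <- two_agent_state(10.5, p)
  expect_equal(nrow(fresh$bonds), 0)

  # beyond delta_d the bond breaks
  st$pos[2, 2] <- st$pos[1, 2] + 12.5
  st <- update_bonds(st)
  expect_equal(nrow(st$bonds), 0)
})

test_that("a bonded pair at rest length is a fixed point of the dynamics", {
  st <- two_agent_state(8)
  st$bonds <- rbind(c(1L, 2L))
  st2 <- step_state(st, 10)
  expect_equal(st2$pos, st$pos)
  expect_equal(st2$time, 10 * st$params$dt)
})

test_that("deterministic drift is dt * f / zeta per step", {
  p <- model_params(zeta = 2)
  st <- two_agent_state(6, p)  # compressed: gap = 2
  f <- net_forces(st)
  st2 <- step_state(st, 1)
  expect_equal(st2$pos - st$pos, f * p$dt / p$zeta)
})

test_that("free Brownian motion reproduces MSD = 6 D t", {
  p <- model_params(D_c = 0.5)
  box <- sim_box(1e5, 1e5, 1e5, "open", "open", "open")
  n <- 2000
  # agents far apart: no bonds ever form
  pos <- cbind(seq_len(n) * 50, rep(5e4, n), rep(5e4, n))
  st <- sim_state(pos, box, p)
  expect_equal(nrow(st$bonds), 0)
  set.seed(42)
  nsteps <- 20
  st2 <- step_state(st, nsteps)
  t_elapsed <- nsteps * p$dt
  msd <- mean(rowSums((st2$pos - st$pos)^2))
  expect_equal(msd, 6 * p$D_c * t_elapsed, tolerance = 0.05)
})

test_that("boundary handling: wrap, clamp, open", {
  box <- sim_box(10, 20, 30, "wall", "periodic", "open")
  pos <- rbind(c(-0.3, 21, 45), c(5, -1, -2))
  out <- apply_boundaries(pos, box)
  expect_equal(out[1, ], c(0, 1, 45))   # clamp at wall, wrap y, open z
  expect_equal(out[2, ], c(5, 19, -2))
})

test_that("quiescence detection stops immediately on a relaxed state and
           relaxes a single agent onto the agar rest height", {
  p <- model_params()
  st <- lattice_colony(3, 3, 3, p)
  out <- run_until_quiescent(st, v_threshold = 0.01)
  expect_true(attr(out, "converged"))
  expect_equal(attr(out, "steps"), 0)

  # single agent pressed into the agar relaxes to height ~ alpha * R
  box <- sim_box(20, 20, 20)
  one <- sim_state(rbind(c(1.5, 10, 10)), box, p)
  out <- run_until_quiescent(one, v_threshold = 1e-4)
  expect_true(attr(out, "converged"))
  expect_equal(unname(out$pos[1, 1]), p$alpha * p$radius,
               tolerance = 0.05)

  # exhausting the step budget is flagged, not silent
  two <- sim_state(rbind(c(1.5, 10, 10)), box, p)
  expect_warning(res <- run_until_quiescent(two, v_threshold = 1e-9,
                                            max_steps = 3),
                 "max")
  expect_false(attr(res, "converged"))
})

test_that("trajectories are reproducible for a fixed seed", {
  p <- model_params(D_c = 0.2)
  box <- sim_box(30, 30, 30)
  set.seed(7)
  pos <- cbind(runif(50, 0, 30), runif(50, 0, 30), runif(50, 0, 30))
  st <- sim_state(pos, box, p)
  set.seed(123)
  a <- step_state(st, 50)
  set.seed(123)
  b <- step_state(st, 50)
  expect_identical(a$pos, b$pos)
  expect_identical(a$bonds, b$bonds)
})

test_that("neighbor lists match the brute-force pair oracle", {
  p <- model_params()
  for (seed in 1:4) {
    set.seed(seed)
    box <- sim_box(25, 25, 25, "wall",
                   sample(c("periodic", "open"), 1),
                   sample(c("periodic", "open"), 1))
    pos <- cbind(runif(60, 0, 25), runif(60, 0, 25), runif(60, 0, 25))
    got <- neighbor_pairs(pos, 12, box)
    want <- oracle_pairs(pos, 12, box)
    expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                 unname(want), ignore_attr = TRUE)
  }
  # the periodic wrap pair is found
  pbox <- sim_box(50, 50, 50, "open", "periodic", "open")
  pos <- rbind(c(10, 1, 10), c(10, 49, 10))
  expect_equal(nrow(neighbor_pairs(pos, 5, pbox)), 1)
  # beyond cutoff: empty
  expect_equal(nrow(neighbor_pairs(rbind(c(1, 1, 1), c(20, 20, 20)), 5,
                                   pbox)), 0)
})

test_that("integrator matches a brute-force implementation over 100 steps", {
  p <- model_params()
  box <- sim_box(22, 22, 22, "wall", "periodic", "periodic")
  set.seed(31)
  n <- 80
  pos <- cbind(runif(n, 0, 22), runif(n, 0, 22), runif(n, 0, 22))
  st <- sim_state(pos, box, p)
  bpos <- st$pos
  bbonds <- st$bonds
  for (chunk in 1:10) {
    st <- step_state(st, 10)
    for (k in 1:10) {
      o <- oracle_step(bpos, rep(p$radius, n), bbonds, p, box)
      bpos <- o$pos
      bbonds <- o$bonds
    }
    expect_equal(unname(st$pos), unname(bpos), tolerance = 1e-12)
    expect_equal(unname(st$bonds), unname(bbonds), ignore_attr = TRUE)
  }
})

test_that("elastic energy decreases during noise-free relaxation", {
  p <- model_params()
  # compressed simple-cubic lattice: spacing 7 < rest length 8
  st <- lattice_colony(3, 4, 4, p, spacing = 7,
                       boundary_x = "open", boundary_y = "open",
                       boundary_z = "open")
  e <- oracle_energy(st)
  expect_gt(e, 0)
  for (k in 1:5) {
    st <- step_state(st, 40)
    e2 <- oracle_energy(st)
    expect_lt(e2, e + 1e-9)
    e <- e2
  }
})
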
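test_that("rectangular cell-death regions select the right agents", {
  box <- sim_box(45, 720, 90)
  cdp <- rect_cdp(200, 27, box)

  # center of the region is inside, at any z
  expect_true(all(cdp_contains(cdp, rbind(c(13, 360, 1), c(13, 360, 89)))))
  # outside in y, above in x
  expect_false(any(cdp_contains(cdp, rbind(c(13, 100, 45),
                                           c(30, 360, 45)))))
  # the whole-colony region contains everything
  all_cdp <- rect_cdp(720, 45, box)
  set.seed(1)
  pos <- cbind(runif(50, 0, 44.9), runif(50, 0, 720), runif(50, 0, 90))
  expect_true(all(cdp_contains(all_cdp, pos)))

  expect_error(rect_cdp(721, 27, box), "W_D")
  expect_error(rect_cdp(200, 46, box), "H_D")
})

test_that("image masks map onto the horizontal plane", {
  box <- sim_box(45, 100, 80)

  # all-on raster is the whole-plane rectangle
  all_on <- image_cdp(matrix(1, 4, 5), 27, box)
  set.seed(2)
  pos <- cbind(runif(100, 0, 44), runif(100, 0, 100), runif(100, 0, 80))
  rect <- rect_cdp(100, 27, box)
  expect_equal(cdp_contains(all_on, pos), cdp_contains(rect, pos))

  # a single on-pixel removes only agents in its footprint
  m <- matrix(0, 4, 5)
  m[2, 3] <- 1   # z in [20,40), y in [40,60)
  one <- image_cdp(m, 27, box)
  expect_true(cdp_contains(one, rbind(c(5, 50, 30)))[1])
  expect_false(any(cdp_contains(one, rbind(c(5, 50, 50), c(5, 70, 30),
                                           c(30, 50, 30)))))

  # checkerboard agrees with a brute-force point-in-pixel test
  nr <- 6; nc <- 10
  cb <- outer(seq_len(nr), seq_len(nc), function(r, cc) (r + cc) %% 2 == 0)
  cdp <- image_cdp(cb, 27, box)
  got <- cdp_contains(cdp, pos)
  want <- vapply(seq_len(nrow(pos)), function(i) {
    cc <- min(max(ceiling(pos[i, 2] / 100 * nc), 1), nc)
    r <- min(max(ceiling(pos[i, 3] / 80 * nr), 1), nr)
    cb[r, cc] && pos[i, 1] < 27
  }, logical(1))
  expect_equal(got, want)

  expect_error(image_cdp(matrix(0, 3, 3), 27, box), "empty")
})

test_that("ablation removes exactly the masked agents and their bonds", {
  p <- model_params()
  box <- sim_box(45, 240, 45)
  st <- build_initial_colony(box, 0.12, p, seed = 9, homog_steps = 200)
  cdp <- rect_cdp(100, 27, box)
  inside <- cdp_contains(cdp, st$pos)
  ab <- ablate(st, cdp)
  expect_equal(n_agents(ab), n_agents(st) - sum(inside))
  expect_setequal(ab$removed_ids, st$ids[inside])
  # no bond references a removed agent; all indices valid
  if (nrow(ab$bonds)) {
    expect_true(all(ab$bonds >= 1 & ab$bonds <= n_agents(ab)))
    expect_false(any(ab$ids[ab$bonds] %in% ab$removed_ids))
  }
  # surviving agents keep their ids and positions
  keep <- !inside
  expect_equal(ab$ids, st$ids[keep])
  expect_equal(ab$pos, st$pos[keep, ])

  # an empty region removes nothing
  empty <- rect_cdp(1e-6 + 0, 1e-6, box)
  expect_equal(n_agents(ablate(st, empty)), n_agents(st))
  expect_equal(n_agents(ablate(st, NULL)), n_agents(st))
})

test_that("gradual removal with one stage equals abrupt removal", {
  p <- model_params()
  box <- sim_box(45, 240, 45)
  st <- build_initial_colony(box, 0.12, p, seed = 10, homog_steps = 200)
  cdp <- rect_cdp(120, 27, box)
  a <- ablate(st, cdp, mode = "abrupt")
  set.seed(1)
  g <- ablate(st, cdp, mode = "gradual", n_stages = 1)
  expect_equal(sort(a$ids), sort(g$ids))
  expect_equal(a$pos[order(a$ids), ], g$pos[order(g$ids), ])
})

test_that("gradual and abrupt removal reach similar final morphology", {
  p <- model_params()
  box <- sim_box(24, 160, 24)
  st <- build_initial_colony(box, 0.14, p, seed = 12, homog_steps = 200)
  st <- suppressWarnings(run_until_quiescent(st, max_steps = 2500))
  cdp <- rect_cdp(100, 12, box)

  ab_a <- ablate(st, cdp, mode = "abrupt")
  ab_a <- suppressWarnings(run_until_quiescent(ab_a, max_steps = 2500))
  set.seed(3)
  ab_g <- ablate(st, cdp, mode = "gradual", n_stages = 10, relax_steps = 50)
  ab_g <- suppressWarnings(run_until_quiescent(ab_g, max_steps = 2500))

  expect_equal(length(ab_a$removed_ids), length(ab_g$removed_ids))
  r_a <- center_border_ratio(height_map(ab_a, 12))
  r_g <- center_border_ratio(height_map(ab_g, 12))
  expect_equal(r_a, r_g, tolerance = 0.25)
})

test_that("a raster mask fixture maps to a sensible death region", {
  f <- system.file("extdata", "smiley_mask_synthetic.csv",
                   package = "wrinklesim")
  mask <- as.matrix(read.csv(f, header = FALSE))
  box <- sim_box(45, 480, 240)
  cdp <- image_cdp(mask, H_D = 27, box = box)
  # a dense grid of probe points: the selected fraction matches the
  # fraction of on-pixels, and nothing above H_D is selected
  g <- expand.grid(x = c(5, 40), y = seq(5, 475, by = 10),
                   z = seq(5, 235, by = 10))
  inside <- cdp_contains(cdp, as.matrix(g))
  expect_false(any(inside[g$x > 27]))
  frac <- mean(inside[g$x < 27])
  expect_equal(frac, mean(mask >= 0.5), tolerance = 0.05)
})
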
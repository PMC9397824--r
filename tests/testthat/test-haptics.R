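test_that("grating force matches its closed form and stays bounded", {
  expect_equal(grating_force(0, 164, 3), 0, tolerance = 1e-12)
  expect_equal(grating_force(1 / (4 * 164), 164, 3), 3, tolerance = 1e-12)
  y <- runif(50, -0.1, 0.1)
  expect_equal(grating_force(y + 1 / 164, 164, 3), grating_force(y, 164, 3),
               tolerance = 1e-9)
  expect_true(all(abs(grating_force(runif(1000, -1, 1), 164, 3)) <= 3 + 1e-12))
})

test_that("virtual table force follows the PD wall law", {
  expect_equal(table_force(0.002, 0), 0)
  expect_equal(table_force(0, 0), 1.96, tolerance = 1e-12)
  expect_equal(table_force(0.001 - 1e-12, 1), -28, tolerance = 1e-6)
  # restoring whenever penetrating and not moving up
  z <- runif(200, -0.01, 0.0009)
  vz <- -runif(200, 0, 1)
  expect_true(all(table_force(z, vz) >= 0))
})

test_that("contact detection respects the three-texture layout", {
  ct <- contact_test(0, 0, 0.0005)
  expect_true(ct$contact)
  expect_equal(ct$texture_id, 2L)
  expect_false(contact_test(0, 0, 0.002)$contact)   # above the table
  expect_false(contact_test(0.015, 0, 0)$contact)   # in the gap
  expect_equal(contact_test(0.02, 0, 0)$texture_id, 3L)  # texture-3 edge
  expect_equal(contact_test(-0.03, 0, 0)$texture_id, 1L)
  expect_equal(contact_test(0.03, 0.087, 0)$texture_id, 3L)
  expect_false(contact_test(0, 0.089, 0)$contact)   # past the texture end
})

test_that("cycloidal reference hits its boundary and midpoint conditions", {
  r0 <- cycloidal_reference(0, -0.08, 0.08, 2)
  rT <- cycloidal_reference(2, -0.08, 0.08, 2)
  rm <- cycloidal_reference(1, -0.08, 0.08, 2)
  expect_equal(r0$y, -0.08, tolerance = 1e-12)
  expect_equal(rT$y, 0.08, tolerance = 1e-12)
  expect_equal(c(r0$v, rT$v, r0$a, rT$a), rep(0, 4), tolerance = 1e-12)
  expect_equal(rm$y, 0, tolerance = 1e-12)
  expect_equal(rm$v, 2 * 0.16 / 2, tolerance = 1e-12)  # peak speed 2D/T
  t <- seq(0, 2, by = 0.01)
  expect_true(all(diff(cycloidal_reference(t, -0.08, 0.08, 2)$y) >= 0))
  expect_error(cycloidal_reference(2.1, -0.08, 0.08, 2), "outside")
})

test_that("guidance force matches its closed form and gates on contact", {
  ref <- list(y = 0.01, v = 0.1, a = 0)
  expect_equal(guidance_force(0.01, 0.1, ref, TRUE), 0, tolerance = 1e-12)
  expect_equal(guidance_force(0, 0.1, ref, TRUE), 3, tolerance = 1e-12)
  expect_equal(guidance_force(0, 0, ref, FALSE), 0)
  ref2 <- list(y = 0, v = 0, a = 2)
  expect_equal(guidance_force(0, 0, ref2, TRUE), 2, tolerance = 1e-12)
})

test_that("total force composes components and is transparent in x", {
  st_free <- list(x = 0, y = 0, z = 0.01, vx = 0, vy = 0, vz = 0)
  fb <- total_force(st_free, NULL, c(164, 164, 100), mode = "active")
  expect_equal(fb$F_total, c(0, 0, 0))
  st <- list(x = 0, y = 0.002, z = 0, vx = 0, vy = 0.1, vz = 0)
  ref <- list(y = 0.004, v = 0.12, a = 0)
  fb2 <- total_force(st, ref, c(164, 164, 100), mode = "passive")
  expect_equal(fb2$F_total[1], 0)
  expect_equal(fb2$F_total[2], fb2$F_rd + fb2$F_hg, tolerance = 1e-12)
  expect_equal(fb2$F_total[3], fb2$F_z, tolerance = 1e-12)
  expect_gt(fb2$F_hg, 0)
  fb3 <- total_force(st, ref, c(164, 164, 100), mode = "active")
  expect_equal(fb3$F_hg, 0)
})

test_that("passive guidance tracks the cycloid within bounds, tighter with stiffness", {
  tri <- triangle_trial(164, 100, seed = 5)
  errs <- vapply(c(100, 300, 1000), function(k) {
    tr <- simulate_exploration(tri, "passive", haptic_params(K_hg = k),
                               sweeps = 1)
    sel <- tr$contact & !is.na(tr$y_ref)
    max(abs(tr$y_ref - tr$y)[sel])
  }, numeric(1))
  expect_true(all(diff(errs) < 0))      # monotone decrease in K_hg
  expect_lt(errs[2], 0.01)              # default gains bound
})

test_that("integrator passes a step-halving convergence check", {
  tri <- triangle_trial(164, 228, seed = 8)
  t1 <- simulate_exploration(tri, "passive", dt = 1e-3, sweeps = 1)
  t2 <- simulate_exploration(tri, "passive", dt = 5e-4, sweeps = 1)
  expect_lt(abs(t1$y[nrow(t1)] - t2$y[nrow(t2)]), 1e-4)
})

test_that("the virtual wall dissipates energy in a free drop", {
  d <- simulate_wall_drop(z0 = 0.004, dt = 1e-3, duration = 2)
  expect_true(all(diff(d$energy) <= 1e-6))
  expect_lt(abs(d$z[nrow(d)] - (0.001 - 9.81 / 1960)), 5e-4)  # settles on the wall
})

test_that("active exploration without pressing never touches the textures", {
  tri <- triangle_trial(164, 100, seed = 2)
  tr <- simulate_exploration(tri, "active", press_force = 0, sweeps = 1)
  expect_false(any(tr$contact))
  expect_true(all(tr$Fg == 0 & tr$Fhg == 0 & tr$Fz == 0))
})

test_that("passive exploration visits all three textures and records the last one", {
  tri <- triangle_trial(164, 100, seed = 4)
  tr <- simulate_exploration(tri, "passive", sweeps = 1)
  expect_setequal(unique(stats::na.omit(tr$texture_id)), 1:3)
  expect_equal(attr(tr, "last_texture"), 3L)
  expect_equal(attr(tr, "mode"), "passive")
  # guidance is gated: zero whenever not in contact
  expect_true(all(tr$Fhg[!tr$contact] == 0))
})

test_that("kinematic traces round-trip through CSV", {
  tri <- triangle_trial(164, 196, seed = 6)
  tr <- simulate_exploration(tri, "active", sweeps = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  tr2 <- read_trace(path)
  expect_equal(tr2$y, tr$y, tolerance = 1e-12)
  expect_equal(tr2$contact, tr$contact)
  expect_equal(attr(tr2, "dt"), attr(tr, "dt"), tolerance = 1e-9)
  df <- utils::read.csv(path)
  df$bogus <- 1
  utils::write.csv(df, path, row.names = FALSE)
  expect_warning(read_trace(path), "unknown")
  utils::write.csv(df[, 1:5], path, row.names = FALSE)
  expect_error(read_trace(path), "lacks")
})
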
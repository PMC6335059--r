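test_that("two-node network has one stretch mode with eigenvalue 2*gamma", {
  m <- build_enm(rbind(c(0, 0, 0), c(1, 0, 0)), cutoff = 2, gamma = 1.5)
  ev <- m$eig$values
  expect_equal(sum(abs(ev) > 1e-8), 1L)
  expect_equal(max(ev), 2 * 1.5, tolerance = 1e-10)
})

test_that("connected 3-D structures have exactly six zero modes", {
  tr <- build_backbone(10, "alpha")
  ca <- frame_coords(tr, 1)[tr$atoms$name == "CA", ]
  m <- build_enm(ca, cutoff = 15)
  expect_equal(m$n_zero_modes, 6L)
  expect_true(m$connected)
  expect_true(all(m$eig$values > -1e-8 * max(m$eig$values)))
  expect_warning(build_enm(rbind(ca, ca + 100), cutoff = 15),
                 "disconnected")
})

test_that("triatomic spectrum matches a hand-built Hessian", {
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  # a collinear chain is degenerate (7 zero modes) and is flagged as such
  expect_warning(m <- build_enm(xyz, cutoff = 1.5, gamma = 2),
                 "degenerate")
  want <- sort(eigen(oracle_triatomic_hessian(xyz, 1.5, 2),
                     symmetric = TRUE)$values)
  expect_equal(m$eig$values, want, tolerance = 1e-10)
})

test_that("rigid displacement fields carry zero deformation energy", {
  tr <- build_backbone(12, "alpha")
  ca <- frame_coords(tr, 1)[tr$atoms$name == "CA", ]
  m <- build_enm(ca, cutoff = 12)
  n <- nrow(ca)

  trans <- matrix(rep(c(1, 2, 3), each = n) / sqrt(14 * n), n, 3)
  expect_equal(max(deformation_field(m, trans)), 0, tolerance = 1e-12)

  centred <- sweep(ca, 2, colMeans(ca))
  omega <- c(1, -2, 0.5) * 1e-6
  rot <- t(vapply(seq_len(n), function(i)
    c(omega[2] * centred[i, 3] - omega[3] * centred[i, 2],
      omega[3] * centred[i, 1] - omega[1] * centred[i, 3],
      omega[1] * centred[i, 2] - omega[2] * centred[i, 1]),
    numeric(3)))
  rot <- rot / sqrt(sum(rot^2))
  expect_lt(max(deformation_field(m, rot)), 1e-8)
})

test_that("deformation energy localises correctly and is rotation invariant", {
  m2 <- build_enm(rbind(c(0, 0, 0), c(1, 0, 0)), cutoff = 2, gamma = 1)
  stretch <- m2$eig$vectors[, which.max(m2$eig$values)]
  e <- deformation_field(m2, matrix(stretch, ncol = 3, byrow = TRUE))
  expect_equal(e[1], e[2], tolerance = 1e-10)
  expect_gt(e[1], 0)

  tr <- build_backbone(15, "alpha")
  ca <- frame_coords(tr, 1)[tr$atoms$name == "CA", ]
  e1 <- deformation_energy(build_enm(ca, cutoff = 12), n_modes = 3)
  R <- random_rotation(3)
  e2 <- deformation_energy(build_enm(ca %*% t(R), cutoff = 12), n_modes = 3)
  expect_equal(e1, e2, tolerance = 1e-6)
  expect_true(all(e1 >= 0))
  expect_error(deformation_energy(build_enm(ca, cutoff = 12), n_modes = 100),
               "non-trivial modes")
})

test_that("label distances recover Gaussian modal and FWHH parameters", {
  ens <- build_label_ensemble(5000, mean = 27, sd = 1.7, seed = 21)
  dd <- label_distance_series(ens, 1L, 2L)
  expect_equal(dd$modal, 27, tolerance = 0.2)
  expect_equal(dd$fwhh, 2.3548 * 1.7, tolerance = 0.08 * 2.3548 * 1.7)
  expect_false(dd$multimodal)
  expect_false(dd$degenerate)
})

test_that("degenerate and bimodal ensembles are flagged", {
  atoms <- data.frame(serial = 1:2, name = "ON", element = "O",
                      resname = c("SL1", "SL2"), resid = 1:2, chain = "X",
                      vdw = 1.52)
  coords <- array(0, dim = c(2, 3, 10))
  coords[2, 1, ] <- 27
  fixed <- trajectory(atoms, coords)
  ddf <- label_distance_series(fixed, 1L, 2L)
  expect_equal(ddf$modal, 27, tolerance = 0.05)
  expect_true(ddf$degenerate)

  a <- build_label_ensemble(2600, mean = 23, sd = 0.8, seed = 4)
  b <- build_label_ensemble(1900, mean = 28, sd = 0.8, seed = 5)
  coords <- array(0, dim = c(2, 3, 4500))
  coords[, , 1:2600] <- a$coords
  coords[, , 2601:4500] <- b$coords
  mix <- trajectory(atoms, coords)
  ddm <- label_distance_series(mix, 1L, 2L)
  expect_true(ddm$multimodal)
  expect_equal(ddm$modal, 23, tolerance = 0.3)  # the higher peak wins
  expect_lt(ddm$fwhh, 3)                        # width of that peak only
})

test_that("passage times solve the linear-ramp closed form", {
  z <- 10 - 0.1 * seq(0, 300, by = 1)
  tr <- build_passage_series(z, dt = 1)
  rec <- passage_times(tr, region_sel = 2L, pore_sel = 1L, exit_offset = 5)
  expect_true(rec$passed)
  expect_equal(rec$passage_time, 150)

  never <- build_passage_series(10 - 0.02 * seq(0, 300), dt = 1)
  expect_false(passage_times(never, 2L, 1L)$passed)

  # crossing, recrossing, then crossing again: first qualifying time wins
  zz <- c(10, 2, -6, -2, 3, -8, -9)
  rec2 <- passage_times(build_passage_series(zz, dt = 1), 2L, 1L)
  expect_equal(rec2$passage_time, 2)
})

test_that("passage extraction respects time shifts and scalings", {
  z <- 10 - 0.1 * seq(0, 300, by = 1)
  base <- passage_times(build_passage_series(z, dt = 1), 2L, 1L)
  shifted <- build_passage_series(z, dt = 1)
  shifted$times <- shifted$times + 40
  expect_equal(passage_times(shifted, 2L, 1L)$passage_time,
               base$passage_time)
  scaled <- passage_times(build_passage_series(z, dt = 2), 2L, 1L)
  expect_equal(scaled$passage_time, 2 * base$passage_time)
})

test_that("passage ratios compare helix and coil groups", {
  mk <- function(t) structure(list(passage_time = t, passed = !is.na(t)),
                              class = "passage_record")
  same <- lapply(c(100, 110, 120), mk)
  r1 <- passage_ratio(same, same)
  expect_equal(r1$ratio, 1)
  expect_equal(r1$p, 1)

  helix <- lapply(c(95, 100, 105), mk)
  coil <- lapply(c(19, 20, 21), mk)
  r2 <- passage_ratio(helix, coil)
  expect_equal(r2$ratio, 5, tolerance = 1e-12)
  expect_lt(r2$p, 0.001)

  withdnp <- passage_ratio(c(helix, list(mk(NA))), coil)
  expect_equal(withdnp$n_did_not_pass, 1L)
  expect_error(passage_ratio(helix[1], coil), ">= 2 passed")
})
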
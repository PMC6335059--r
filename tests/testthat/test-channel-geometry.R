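test_that("cylinder profile is flat with exact equal-side volumes", {
  ch <- build_channel("cylinder", r0 = 3)
  pr <- pore_profile(ch, origin = c(0, 0, 0))
  expect_true(all(abs(pr$radius - 3) < 0.1))
  expect_false(any(pr$burst))
  v <- cavity_volumes(pr)
  expect_equal(v$v_cyt, pi * 9 * 6.5, tolerance = 1e-6)
  expect_equal(v$v_ext, v$v_cyt, tolerance = 1e-9)
})

test_that("asymmetric hourglass recovers slope and analytic volume ratio", {
  ch <- build_channel("asymmetric-hourglass", r0 = 3, slope_cyt = 0.4,
                      slope_ext = 0)
  spec <- attr(ch, "channel_spec")
  pr <- pore_profile(ch, origin = c(0, 0, 0))
  expect_equal(pr$radius[pr$z == 6.5] - pr$radius[pr$z == -6.5],
               0.4 * 6.5, tolerance = 0.05)
  v <- cavity_volumes(pr)
  want <- channel_side_volume(spec, "cytoplasmic") /
    channel_side_volume(spec, "exterior")
  expect_equal(v$cyt_over_ext, want, tolerance = 0.005)
})

test_that("optimised profile matches the brute-force grid oracle", {
  ch <- build_channel("asymmetric-hourglass", r0 = 3, slope_cyt = 0.4,
                      slope_ext = 0)
  pr <- pore_profile(ch, origin = c(0, 0, 0))
  xyz <- frame_coords(ch, 1)
  vdw <- ch$atoms$vdw
  for (z in c(-6.5, -3, 0, 0.5, 2, 4, 6.5)) {
    want <- oracle_probe_radius(xyz, vdw, z)
    expect_equal(pr$radius[abs(pr$z - z) < 1e-9], want, tolerance = 0.1)
  }
})

test_that("a blocking atom at the seed gives zero radius with a warning", {
  atoms <- data.frame(serial = 1L, name = "CA", element = "C",
                      resname = "ALA", resid = 1L, chain = "A", vdw = 1.7)
  tr <- trajectory(atoms, matrix(c(0, 0, 0), 1))
  expect_warning(pr <- pore_profile(tr, origin = c(0, 0, 0),
                                    zlim = c(0, 0)),
                 "inside an atom")
  expect_equal(pr$radius[pr$z == 0], 0)
})

test_that("deleting wall atoms never decreases the radius", {
  ch <- build_channel("cylinder", r0 = 3, half_length = 4)
  pr <- pore_profile(ch, origin = c(0, 0, 0), zlim = c(-3, 3))
  set.seed(8)
  drop <- sample(n_atoms(ch), floor(n_atoms(ch) / 3))
  pr2 <- pore_profile(ch, origin = c(0, 0, 0), zlim = c(-3, 3),
                      exclude = drop)
  expect_true(all(pr2$radius >= pr$radius - 1e-6))
})

test_that("volume integration demands grid coverage and handles zeros", {
  ch <- build_channel("cylinder", r0 = 3)
  pr <- pore_profile(ch, origin = c(0, 0, 0), zlim = c(-3, 3))
  expect_error(cavity_volumes(pr), "does not cover")
  przero <- data.frame(z = seq(-6.5, 6.5, 0.5), radius = 0, cx = 0, cy = 0,
                       burst = FALSE)
  class(przero) <- c("channel_profile", "data.frame")
  v0 <- cavity_volumes(przero)
  expect_equal(v0$v_cyt, 0)
  expect_equal(v0$v_ext, 0)
})

test_that("contact fractions count residues within the cutoff", {
  # 9 single-atom residues: 4 near a channel atom, 5 far away
  pp <- data.frame(serial = 1:9, name = "CA", element = "C",
                   resname = "GLY", resid = 1:9, chain = "P", vdw = 1.7)
  wall <- data.frame(serial = 10L, name = "W", element = "C",
                     resname = "WAL", resid = 100L, chain = "W", vdw = 1.7)
  xyz <- rbind(cbind(2.5, 0, seq_len(4)),      # within 3 A of the wall atom
               cbind(10, 0, 4 + seq_len(5)),   # far
               c(0, 0, 2.5))                   # the wall atom
  tr <- trajectory(rbind(pp, wall), xyz)
  ch_sel <- which(tr$atoms$chain == "W")
  cf <- contact_fraction(tr, c(1, 9), channel_sel = ch_sel, cutoff = 3)
  expect_equal(cf$fraction, 4 / 9)
  expect_equal(unname(cf$per_residue[1:4]), rep(1, 4))

  far <- contact_fraction(tr, c(5, 9), channel_sel = ch_sel, cutoff = 3)
  expect_equal(far$fraction, 0)
  zero <- contact_fraction(tr, c(1, 9), channel_sel = ch_sel, cutoff = 0)
  expect_equal(zero$fraction, 0)
  expect_error(contact_fraction(tr, c(1, 9), channel_sel = integer(0)),
               "empty")
})

test_that("hydrogens are ignored in contact distances", {
  pp <- data.frame(serial = 1:2, name = c("CA", "HA"),
                   element = c("C", "H"), resname = "GLY", resid = 1L,
                   chain = "P", vdw = c(1.7, 1.2))
  wall <- data.frame(serial = 3:4, name = c("W", "HW"),
                     element = c("C", "H"), resname = "WAL",
                     resid = 100L, chain = "W", vdw = c(1.7, 1.2))
  # only the two hydrogens are close; heavy atoms are 8 A apart
  xyz <- rbind(c(0, 0, 0), c(3.5, 0, 0), c(8, 0, 0), c(4.5, 0, 0))
  tr <- trajectory(rbind(pp, wall), xyz)
  cf <- contact_fraction(tr, c(1, 1), channel_sel = 3:4, cutoff = 3)
  expect_equal(cf$fraction, 0)
})
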
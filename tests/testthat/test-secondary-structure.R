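test_that("hydrogen-bond energies match an independent Kabsch-Sander oracle", {
  for (kind in c("alpha", "three_ten")) {
    tr <- build_backbone(10, kind)
    xyz <- frame_coords(tr, 1)
    at <- function(i, name) xyz[(i - 1) * 4 + match(name, c("N", "CA", "C", "O")), ]
    step <- if (kind == "alpha") 4L else 3L
    for (i in 2:4) {
      donor <- i + step
      want <- oracle_ks_energy(at(donor, "N"), at(donor, "CA"),
                               at(donor - 1, "C"), at(i, "C"), at(i, "O"))
      got <- ks_hbond_energy(tr, donor = donor, acceptor = i)
      expect_equal(got, want, tolerance = 1e-9)
      expect_lt(got, -0.5)
    }
  }
})

test_that("distant pairs, prolines and adjacent residues form no bond", {
  tr <- build_backbone(6, "alpha")
  far <- tr
  far$coords[far$atoms$resid >= 4, , 1] <-
    far$coords[far$atoms$resid >= 4, , 1] + matrix(c(40, 0, 0),
                                                   sum(far$atoms$resid >= 4),
                                                   3, byrow = TRUE)
  e <- ks_hbond_energy(far, donor = 6, acceptor = 2)
  expect_gt(e, -0.5)
  expect_lt(abs(e), 0.5)

  pro <- build_backbone(10, "alpha", sequence = "AAAAAPAAAA")
  expect_true(is.na(ks_hbond_energy(pro, donor = 6, acceptor = 2)))
  expect_true(is.na(ks_hbond_energy(tr, donor = 3, acceptor = 2)))
  # first residue has no preceding carbonyl, hence no donor H
  expect_true(is.na(ks_hbond_energy(tr, donor = 1, acceptor = 5)))
})

test_that("ideal helices are labelled H and G in their interiors, coils C", {
  ssa <- assign_ss(build_backbone(12, "alpha"))
  expect_true(all(ssa[2:11, 1] == "H"))
  expect_true(all(ssa[c(1, 12), 1] %in% c("T", "C")))

  ssg <- assign_ss(build_backbone(12, "three_ten"))
  expect_true(all(ssg[2:11, 1] == "G"))

  ssc <- assign_ss(build_backbone(12, "coil", seed = 11))
  expect_false(any(ssc %in% c("H", "G")))
})

test_that("assignment is invariant under rigid motion", {
  tr <- build_backbone(12, "alpha")
  ref <- assign_ss(tr)
  moved <- transform_traj(tr, R = random_rotation(5), shift = c(10, -3, 7))
  expect_identical(assign_ss(moved), ref)
})

test_that("folding degree counts residue-frame fractions", {
  m <- matrix("C", nrow = 9, ncol = 100, dimnames = list(1:9, NULL))
  expect_equal(folding_degree(m, c(1, 9)), 0)
  m2 <- m; m2[1:3, ] <- "H"
  expect_equal(folding_degree(m2, c(1, 9)), 1 / 3)
  m3 <- m; m3[, 1:50] <- "H"
  expect_equal(folding_degree(m3, c(1, 9)), 0.5)
  # turns count as folded by default but can be excluded
  m4 <- m; m4[1:3, ] <- "T"
  expect_equal(folding_degree(m4, c(1, 9)), 1 / 3)
  expect_equal(folding_degree(m4, c(1, 9), folded = c("H", "G")), 0)
  expect_error(folding_degree(m, c(5, 4)), "non-empty")

  fd <- folding_degree(list(m2, m3), c(1, 9))
  expect_s3_class(fd, "folding_degree")
  expect_equal(fd$mean, mean(c(1 / 3, 0.5)))
  expect_equal(fd$sem, sd(c(1 / 3, 0.5)) / sqrt(2))
})

test_that("glycine-coil fixtures abolish all folded structure", {
  # emulates the unfolding-reset criterion: a fully coil window scores zero
  for (seed in 1:3) {
    ss <- assign_ss(build_backbone(9, "coil", seed = seed))
    expect_equal(folding_degree(ss, c(1, 9)), 0)
  }
})

test_that("asymmetry t-test matches the textbook oracle", {
  x <- c(0.1, 0.2, 0.3); y <- c(0.4, 0.5, 0.6)
  got <- asymmetry_test(x, y, test = "student")
  want <- oracle_student_t(x, y)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  expect_lt(abs(got$t - (-3.674)), 1e-3)
  expect_lt(abs(got$p - 0.0214), 5e-4)

  same <- asymmetry_test(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_error(asymmetry_test(c(1, 1, 1), c(2, 2, 2)), "zero variance")
  expect_error(asymmetry_test(1, c(1, 2)), ">= 2 replicates")

  w <- asymmetry_test(x, c(0.4, 0.6, 0.8), test = "welch")
  expect_lt(w$df, 4)
})

test_that("a 10-fold imposed cavity asymmetry is recovered by the pipeline path", {
  helix <- build_backbone(12, "alpha")
  make_reps <- function(frac, seeds) {
    lapply(seeds, function(s) {
      coil <- build_backbone(12, "coil", seed = s)
      set.seed(s + 1000)
      pick <- runif(60) < frac
      coords <- array(NA_real_, dim = c(48, 3, 60))
      for (f in 1:60)
        coords[, , f] <- frame_coords(if (pick[f]) helix else coil, 1)
      assign_ss(trajectory(helix$atoms, coords))
    })
  }
  ext <- folding_degree(make_reps(0.30, 1:6), c(2, 10))
  cyt <- folding_degree(make_reps(0.03, 11:16), c(2, 10))
  ratio <- ext$mean / cyt$mean
  expect_gt(ratio, 5)
  expect_lt(ratio, 20)
  expect_lt(asymmetry_test(cyt, ext)$p, 0.01)
})
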
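test_that("alpha backbone places i -> i+4 carbonyl-amide pairs at H-bond range", {
  tr <- build_backbone(12, "alpha")
  xyz <- frame_coords(tr, 1)
  o_of <- function(i) xyz[(i - 1) * 4 + 4, ]
  n_of <- function(i) xyz[(i - 1) * 4 + 1, ]
  for (i in 2:7) {
    d <- sqrt(sum((o_of(i) - n_of(i + 4))^2))
    expect_gt(d, 2.8)
    expect_lt(d, 3.1)
  }
})

test_that("coil backbones cannot form helical hydrogen bonds", {
  for (seed in 1:5) {
    tr <- build_backbone(15, "coil", seed = seed)
    xyz <- frame_coords(tr, 1)
    for (i in 1:15) for (n in 3:4) {
      j <- i + n
      if (j > 15) next
      d <- sqrt(sum((xyz[(i - 1) * 4 + 4, ] - xyz[(j - 1) * 4 + 1, ])^2))
      expect_gt(d, 3.5)
    }
  }
})

test_that("backbone builder enforces minimum lengths and is reproducible", {
  expect_error(build_backbone(3, "alpha"), ">= 4")
  expect_error(build_backbone(2, "three_ten"), ">= 3")
  a <- build_backbone(10, "coil", seed = 42)
  b <- build_backbone(10, "coil", seed = 42)
  expect_identical(a$coords, b$coords)
  p <- build_backbone(5, "alpha", sequence = "AAPAA")
  expect_equal(p$atoms$resname[p$atoms$resid == 3][1], "PRO")
})

test_that("substrate duplication reproduces the printed 18-mers", {
  expect_identical(construct_substrate("ELERQHTFA", "mirrored"),
                   "ELERQHTFAAFTHQRELE")
  expect_identical(construct_substrate("ELERQHTFA", "tandem"),
                   "ELERQHTFAELERQHTFA")
  expect_identical(construct_substrate("AAAAAAAAA", "mirrored"),
                   "AAAAAAAAAAAAAAAAAA")
  expect_error(construct_substrate("SHORT", "mirrored"), "9 residues")
})

test_that("mirrored substrates are palindromic about the junction", {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")
  set.seed(9)
  for (k in 1:10) {
    seed9 <- paste(sample(aa, 9, replace = TRUE), collapse = "")
    out <- construct_substrate(seed9, "mirrored")
    expect_equal(nchar(out), 18L)
    half2 <- substr(out, 10, 18)
    rev2 <- paste(rev(strsplit(half2, "")[[1]]), collapse = "")
    expect_identical(rev2, substr(out, 1, 9))
  }
})

test_that("glycine substitution respects the window and sequence length", {
  expect_identical(glycine_scan("ELERQHTFA", c(1, 9)), "GGGGGGGGG")
  s18 <- construct_substrate("ELERQHTFA", "mirrored")
  expect_identical(glycine_scan(glycine_scan(s18, c(1, 9)), c(10, 18)),
                   strrep("G", 18))
  expect_identical(glycine_scan("ELERQHTFA", NULL), "ELERQHTFA")
  expect_error(glycine_scan("ELERQHTFA", c(5, 10)), "out of range")
})

test_that("channel walls reproduce the analytic radius within the spacing bound", {
  for (args in list(list(shape = "cylinder", r0 = 3),
                    list(shape = "hourglass", r0 = 2.5, slope_cyt = 0.2),
                    list(shape = "asymmetric-hourglass", r0 = 3,
                         slope_cyt = 0.4, slope_ext = 0))) {
    ch <- do.call(build_channel, args)
    spec <- attr(ch, "channel_spec")
    pr <- pore_profile(ch, origin = c(0, 0, 0))
    expect_lt(max(abs(pr$radius - channel_radius(spec, pr$z))),
              spec$wall_atom_spacing / 2)
  }
})

test_that("analytic cavity volumes match closed forms", {
  cyl <- attr(build_channel("cylinder", r0 = 3), "channel_spec")
  expect_equal(channel_side_volume(cyl, "cytoplasmic"), pi * 9 * 6.5)
  expect_equal(channel_side_volume(cyl, "exterior"), pi * 9 * 6.5)
  asym <- attr(build_channel("asymmetric-hourglass", r0 = 3,
                             slope_cyt = 0.4, slope_ext = 0),
               "channel_spec")
  num <- integrate(function(z) pi * (3 + 0.4 * z)^2, 0, 6.5)$value
  expect_equal(channel_side_volume(asym, "cytoplasmic"), num,
               tolerance = 1e-9)
  degen <- attr(build_channel("asymmetric-hourglass", r0 = 3,
                              slope_cyt = 0, slope_ext = 0),
                "channel_spec")
  expect_equal(channel_radius(degen, c(-5, 0, 5)), rep(3, 3))
})

test_that("water baths realise the imposed diffusive regimes", {
  b <- build_bath(300, box = c(40, 40, 40), H = 0.5, D = 0.2, dt = 0.5,
                  n_frames = 60, seed = 1)
  sm <- slice_msd(b, rep(0L, 300))
  large <- sm$t >= 10
  ratio <- sm$msd[large, 1] / (6 * 0.2 * sm$t[large])
  expect_true(all(abs(ratio - 1) < 0.1))

  b0 <- build_bath(50, H = 0.5, D = 0, n_frames = 10, seed = 1)
  expect_equal(max(abs(b0$coords[, , 10] - b0$coords[, , 1])), 0)

  expect_error(build_bath(10, H = 1.5, n_frames = 5), "\\(0, 1\\]")
  expect_error(build_bath(10, H = 0, n_frames = 5), "\\(0, 1\\]")

  b1 <- build_bath(40, H = 0.35, D = 0.1, n_frames = 30, seed = 7)
  b2 <- build_bath(40, H = 0.35, D = 0.1, n_frames = 30, seed = 7)
  expect_identical(b1$coords, b2$coords)
})

test_that("hdx tables reproduce truth at zero noise and clip to amide counts", {
  truth <- data.frame(peptide_id = c("p1", "p1"), start = 1L, end = 11L,
                      state = c("ATP", "ADP"), timepoint = 30,
                      uptake = c(4.5, 3.0))
  tab <- build_hdx_table(truth, noise_sd = 0, n_replicates = 3, seed = 1)
  expect_equal(nrow(tab), 6L)
  expect_equal(tab$uptake, rep(c(4.5, 3.0), each = 3))

  hi <- truth; hi$uptake <- c(50, 0)
  tabhi <- build_hdx_table(hi, noise_sd = 0, n_replicates = 2, seed = 1)
  expect_true(all(tabhi$uptake <= 10))
  expect_true(all(tabhi$uptake >= 0))
})

test_that("label ensembles and passage series carry their ground truth", {
  ens <- build_label_ensemble(500, mean = 27, sd = 1.7, seed = 3)
  d <- sqrt(colSums((ens$coords[2, , ] - ens$coords[1, , ])^2))
  expect_equal(mean(d), 27, tolerance = 0.3)
  expect_equal(sd(d), 1.7, tolerance = 0.2)

  ps <- build_passage_series(c(10, 5, 0, -5, -10), dt = 2)
  expect_equal(n_frames(ps), 5L)
  expect_equal(ps$times, c(0, 2, 4, 6, 8))
  expect_equal(ps$coords[2, 3, ], c(10, 5, 0, -5, -10))
})
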
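test_that("branch rate zero gives exactly the primaries", {
  sp <- phantom_spec(n_primary = 3, mean_segment_length_um = 1e12,
                     logistic_params = list(Y_max = 900, k = 1.2, t1 = 4),
                     days = 0:10, image_size_px = 1024, rng_seed = 11)
  net <- generate_network(sp)
  expect_length(net$segments, 3)
  gt <- ground_truth_metrics(net, 10, min_len_um = 0)
  expect_equal(gt$N_tip, 3)
  expect_equal(gt$N_pb, 3)
  expect_equal(gt$G, 1)       # 1 + log2(3/3)
})

test_that("identical spec and seed reproduce the network bit for bit", {
  sp <- phantom_spec(rng_seed = 21, days = 0:8,
                     logistic_params = list(Y_max = 1500, k = 1.2, t1 = 4))
  n1 <- generate_network(sp)
  n2 <- generate_network(sp)
  expect_identical(n1, n2)

  # rendering with different noise seeds: same truth, different pixels
  i1 <- render_image(n1, day = 8, noise_seed = 1)
  i2 <- render_image(n1, day = 8, noise_seed = 2)
  expect_false(identical(i1$pixels, i2$pixels))
  expect_identical(render_image(n1, day = 8, noise_seed = 1)$pixels, i1$pixels)
})

test_that("ground-truth invariants hold: monotonicity and tree accounting", {
  sp <- phantom_spec(rng_seed = 31)
  net <- generate_network(sp)
  L <- vapply(net$days, function(d) ground_truth_metrics(net, d, 0)$L_um,
              numeric(1))
  Ntip <- vapply(net$days, function(d) ground_truth_metrics(net, d, 0)$N_tip,
                 numeric(1))
  expect_true(all(diff(L) >= 0))
  expect_true(all(diff(Ntip) >= 0))

  # anastomosis-free binary tree: junctions = N_tip - N_pb and
  # segments = 2 N_tip - N_pb (on the full final network)
  k <- length(net$segments)
  completed <- vapply(net$segments, function(s) length(s$children) > 0,
                      logical(1))
  n_tip <- sum(!completed)
  n_pb <- sum(vapply(net$segments, function(s) s$generation == 1L, logical(1)))
  expect_equal(sum(completed), n_tip - n_pb)
  expect_equal(k, 2 * n_tip - n_pb)

  # children polylines start at the parent branch point; generations add 1
  for (s in net$segments) {
    for (ch in s$children) {
      expect_equal(net$segments[[ch]]$polyline[1, ],
                   s$polyline[nrow(s$polyline), ])
      expect_equal(net$segments[[ch]]$generation, s$generation + 1L)
    }
  }
})

test_that("completed segment lengths are exponential at the censored scale", {
  # In the pure exponential growth phase the standing-tip population censors
  # completed segments: renewal theory gives Exponential(l*/2), not
  # Exponential(l*). Parameter-free check against the predicted scale.
  sp <- phantom_spec(rng_seed = 99, image_size_px = 2048,
                     avoid_collisions = FALSE, noise_sd = 0,
                     mean_segment_length_um = 100, days = 0:12,
                     logistic_params = list(Y_max = 1e6, k = 1.2, t1 = 14.3))
  net <- generate_network(sp)
  lens <- vapply(Filter(function(s) length(s$children) > 0, net$segments),
                 `[[`, numeric(1), "length_um")
  expect_gte(length(lens), 500)
  # de-discretize the 1.25 um grid before the KS comparison
  set.seed(1)
  jit <- lens + runif(length(lens), 0, 1.25)
  ks <- suppressWarnings(stats::ks.test(jit, "pexp", 1 / 50))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(lens) - 50), 3 * sd(lens) / sqrt(length(lens)))
})

test_that("rendering draws the bead and strokes with calibrated geometry", {
  sp <- phantom_spec(n_primary = 0, noise_sd = 0, image_size_px = 512,
                     bead_radius_um = 100, rng_seed = 1,
                     logistic_params = list(Y_max = 10, k = 1, t1 = 2),
                     days = 0:2)
  net <- generate_network(sp)
  img <- render_image(net, day = 0)
  fgpx <- sum(img$pixels > sp$background_level)
  r_px <- 100 / 1.25
  expect_lt(abs(fgpx - pi * r_px^2), 2 * pi * r_px + 4)  # 1 px rasterization band
  expect_error(render_image(net, day = 99), "no snapshot")
})

test_that("a straight primary round-trips through the pipeline within 5%", {
  # one horizontal primary of 400 um, no branching, no noise
  sp <- phantom_spec(n_primary = 1, mean_segment_length_um = 1e12,
                     sprout_width_um = 10, noise_sd = 0,
                     direction_noise_deg = 0, drift_weight = 0,
                     logistic_params = list(Y_max = 400, k = 2, t1 = 2),
                     days = 0:6, image_size_px = 1024, rng_seed = 2)
  net <- generate_network(sp)
  expect_equal(ground_truth_metrics(net, 6, 0)$L_um, 400, tolerance = 0.01)
  img <- render_image(net, day = 6)
  rec <- process_image(img, run_config())$record
  expect_lt(abs(rec$L_um - 400) / 400, 0.05)
  expect_equal(rec$N_tip, 1L)
  expect_equal(rec$N_pb, 1L)
})

test_that("logistic series sampling matches the closed form", {
  ts <- generate_logistic_series(4000, 1.2, 7, days = 0:14, noise_sd = 0)
  expect_equal(ts$value, 4000 / (1 + exp(-1.2 * (0:14 - 7))), tolerance = 1e-15)
  expect_equal(generate_logistic_series(4000, 1.2, 7, days = 7)$value, 2000)
  expect_lt(logistic_value(-1e3, 4000, 1.2, 7), 1e-300)
  expect_equal(logistic_value(1e3, 4000, 1.2, 7), 4000)
  expect_error(generate_logistic_series(1, 0, 0, days = 1:3), "k must be positive")
  expect_error(generate_logistic_series(1, 1, 0, days = numeric(0)), "empty")
  s1 <- generate_logistic_series(100, 1, 5, 0:10, noise_sd = 5, rng_seed = 3)
  s2 <- generate_logistic_series(100, 1, 5, 0:10, noise_sd = 5, rng_seed = 3)
  expect_identical(s1, s2)
})

test_that("phantom export writes ground truth JSON and named TIFF frames", {
  dir <- withr::local_tempdir()
  sp <- phantom_spec(rng_seed = 4, days = 0:3, image_size_px = 512,
                     logistic_params = list(Y_max = 600, k = 1.2, t1 = 2))
  net <- generate_network(sp)
  paths <- export_phantom(net, dir, bead_id = 7, days = c(2, 3))
  expect_true(file.exists(file.path(dir, "bead7_day2.tif")))
  expect_true(file.exists(file.path(dir, "bead7_day3.tif")))
  gt <- jsonlite::read_json(file.path(dir, "bead7_groundtruth.json"))
  expect_equal(length(gt$segments), length(net$segments))
  img <- load_stack(file.path(dir, "bead7_day3.tif"))
  expect_equal(img$bead_id, 7L)
  expect_equal(dim(img$pixels), c(512L, 512L))
})

test_that("a bead too large for the frame is a geometry error", {
  expect_error(generate_network(phantom_spec(bead_radius_um = 400,
                                             image_size_px = 512)),
               "geometry error")
})
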
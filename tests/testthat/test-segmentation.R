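test_that("relative-mean threshold behaves on flat and disk images", {
  # constant positive image: every pixel is below 1.17x its own mean
  expect_equal(sum(segment_image(matrix(100, 30, 30))), 0)
  expect_warning(fg0 <- segment_image(matrix(0, 30, 30)), "all-zero")
  expect_equal(sum(fg0), 0)

  # bright disk over zero background covering ~10% of pixels:
  # mean ~100, threshold ~117, so the blurred disk interior survives
  r <- sqrt(0.1 * 1e4 / pi)
  img <- matrix(0, 100, 100)
  img[disk_mask(100, 100, circle_px(c(50, 50), r))] <- 1000
  fg <- segment_image(img)
  inner <- disk_mask(100, 100, circle_px(c(50, 50), r - 6))
  far_out <- !disk_mask(100, 100, circle_px(c(50, 50), r + 6))
  expect_true(all(fg[inner]))
  expect_false(any(fg[far_out]))

  # deterministic
  expect_identical(fg, segment_image(img))
})

test_that("hole filling respects the boundary-length cut and is idempotent", {
  solid <- matrix(FALSE, 50, 50); solid[10:40, 10:40] <- TRUE
  expect_identical(fill_holes(solid), solid)

  # small hole (boundary 76 px by the package's own tracer) gets filled
  ann <- disk_mask(100, 100, circle_px(c(50, 50), 30)) &
    !disk_mask(100, 100, circle_px(c(50, 50), 10))
  hole <- disk_mask(100, 100, circle_px(c(50, 50), 10))
  expect_equal(boundary_pixel_count(hole), 76)
  filled <- fill_holes(ann)
  expect_equal(sum(filled), sum(ann) + sum(hole))

  # large hole (boundary 508 px) stays
  big <- disk_mask(200, 200, circle_px(c(100, 100), 80)) &
    !disk_mask(200, 200, circle_px(c(100, 100), 64))
  expect_equal(boundary_pixel_count(disk_mask(200, 200, circle_px(c(100, 100), 64))),
               508)
  expect_identical(fill_holes(big), big)

  # idempotence and monotonicity (never removes foreground)
  expect_identical(fill_holes(filled), filled)
  expect_true(all(ann <= filled))
})

test_that("largest component keeps the biggest blob with the scan-order tie rule", {
  m <- matrix(FALSE, 40, 40)
  m[2:11, 2:11] <- TRUE          # 100 px
  m[25:29, 25:34] <- TRUE        # 50 px
  keep <- largest_component(m)
  expect_equal(sum(keep), 100)
  expect_true(all(keep[2:11, 2:11]))

  single <- matrix(FALSE, 10, 10); single[3:5, 3:5] <- TRUE
  expect_identical(largest_component(single), single)
  expect_identical(largest_component(largest_component(m)), largest_component(m))
  expect_identical(largest_component(matrix(FALSE, 5, 5)), matrix(FALSE, 5, 5))

  # two equal 50-px blobs: the one whose first pixel comes first in
  # row-major scan order wins. Blob B starts at row 1.
  t2 <- matrix(FALSE, 40, 40)
  t2[5:9, 2:11] <- TRUE          # A: first pixel (5, 2)
  t2[1:5, 20:29] <- TRUE         # B: first pixel (1, 20)
  keep2 <- largest_component(t2)
  expect_true(keep2[1, 20])
  expect_false(keep2[9, 2])

  # never adds foreground
  expect_true(all(keep2 <= t2))
})

test_that("bead detection finds the circle wherever it sits", {
  dm <- disk_mask(512, 512, circle_px(c(256, 256), 106))
  img <- calibrated_image(matrix(2000, 512, 512) + 1200 * dm, 1.25)
  b <- detect_bead(img, dm)
  expect_lt(sqrt(sum((b$center - c(256, 256))^2)), 3)
  expect_lt(abs(b$radius - 106) / 106, 0.05)

  dm2 <- disk_mask(512, 512, circle_px(c(300, 200), 106))
  b2 <- detect_bead(calibrated_image(matrix(2000, 512, 512) + 1200 * dm2, 1.25), dm2)
  expect_lt(sqrt(sum((b2$center - c(300, 200))^2)), 3)
  expect_lt(abs(b2$radius - 106) / 106, 0.05)

  # an attached sprout must not inflate the radius by more than 10%
  spr <- sproutgraph:::stamp_mask_cpp(512, 512, seq(256, 450, 0.5),
                                      rep(256, 389), 4)
  b3 <- detect_bead(img, dm | spr)
  expect_lt(b3$radius / b$radius - 1, 0.10)

  # nothing bead-sized -> detection error
  tiny <- disk_mask(512, 512, circle_px(c(256, 256), 10))
  expect_error(detect_bead(img, tiny), "bead detection failed")
})

test_that("bead removal clears the disk and records the in-disk foreground", {
  bead <- circle_px(c(50, 50), 20)
  dm <- disk_mask(100, 100, bead)
  out <- remove_bead(dm, bead)
  expect_equal(sum(out), 0)
  expect_equal(sum(attr(out, "bead_foreground")), sum(dm))

  # bead + one sprout: sprout survives minus its in-disk part
  spr <- matrix(FALSE, 100, 100); spr[48:52, 50:90] <- TRUE
  out2 <- remove_bead(dm | spr, bead, margin_px = 0)
  expect_identical(out2 & disk_mask(100, 100, bead), matrix(FALSE, 100, 100))
  expect_true(all(out2[48:52, 75:90]))

  # larger margin clears at least as much
  out_m2 <- remove_bead(dm | spr, bead, margin_px = 2)
  expect_true(all(out_m2 <= out2))
})

test_that("segmentation recovers phantom geometry end to end", {
  sp <- phantom_spec(rng_seed = 5, noise_sd = 0)
  net <- generate_network(sp)
  img <- render_image(net, day = 12)
  fg <- largest_component(fill_holes(segment_image(img)))
  gtm <- ground_truth_mask(net, day = 12)
  iou <- sum(fg & gtm) / sum(fg | gtm)
  expect_gte(iou, 0.8)
  expect_lt(abs(sum(fg) / sum(gtm) - 1), 0.10)
})
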
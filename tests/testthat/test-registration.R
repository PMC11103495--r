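test_that("identical images register to the identity transform", {
  set.seed(4)
  img <- matrix(runif(64 * 64), 64, 64)
  tf <- register_rounds(img, img)
  expect_equal(tf$dy, 0)
  expect_equal(tf$dx, 0)
  expect_gt(tf$score, 0.9)
})

test_that("phantom round shifts are recovered to sub-pixel accuracy", {
  cfg <- small_phantom_config(
    n_cells = 30, field = 256, seed = 7,
    round_shifts = list(ipai = c(0, 0), af = c(7, -3), r2 = c(12.5, 8.25),
                        r3 = c(-20, 17)))
  ph <- generate_phantom(cfg)
  ref <- ph$rounds$ipai$DAPI
  for (rn in c("af", "r2", "r3")) {
    tf <- register_rounds(ref, ph$rounds[[rn]]$DAPI)
    truth <- cfg$round_shifts[[rn]]
    expect_lt(abs(tf$dy - truth[1]), 0.5)
    expect_lt(abs(tf$dx - truth[2]), 0.5)
  }
})

test_that("structureless image pairs fail registration with a low score", {
  set.seed(12)
  a <- matrix(runif(128 * 128), 128, 128)
  b <- matrix(runif(128 * 128), 128, 128)
  expect_error(register_rounds(a, b), "confidence")
})

test_that("registration then resampling removes at least 90% of DAPI mismatch", {
  for (shift in list(c(10, -8), c(25, 25))) {  # up to ~10% of a 256 field
    cfg <- small_phantom_config(
      n_cells = 30, field = 256, seed = 15,
      round_shifts = list(ipai = c(0, 0), af = shift))
    ph <- generate_phantom(cfg)
    ref <- ph$rounds$ipai$DAPI$pixels
    mov <- ph$rounds$af$DAPI$pixels
    tf <- register_rounds(ref, mov)
    w <- apply_transform(mov, tf)
    mse_before <- mean((ref - mov)^2)
    mse_after <- mean((ref[w$valid] - w$pixels[w$valid])^2)
    expect_lt(mse_after, 0.1 * mse_before)
  }
})

test_that("two-step registration composes to the direct transform", {
  cfg <- small_phantom_config(
    n_cells = 30, field = 256, seed = 23,
    round_shifts = list(ipai = c(0, 0), af = c(9, -6), r2 = c(15, 11)))
  ph <- generate_phantom(cfg)
  a <- ph$rounds$ipai$DAPI; b <- ph$rounds$af$DAPI; c3 <- ph$rounds$r2$DAPI
  tf_ab <- register_rounds(a, b)         # aligns b onto a
  tf_bc <- register_rounds(b, c3)        # aligns c onto b
  tf_ac <- register_rounds(a, c3)
  comp <- compose_transform(tf_ab, tf_bc)
  expect_lt(abs(comp$dy - tf_ac$dy), 0.5)
  expect_lt(abs(comp$dx - tf_ac$dx), 0.5)
})

test_that("control-point fits recover known rigid transforms exactly", {
  pts <- cbind(c(10, 40, 25, 60, 5), c(12, 8, 44, 50, 30))
  # already aligned: identity with zero residual
  tf0 <- register_control_points(pts, pts)
  expect_equal(transform_points(tf0, pts), pts, tolerance = 1e-9)
  expect_equal(tf0$rms, 0)
  expect_equal(tf0$score, 1)
  # a known rotation + translation is recovered to machine precision
  truth <- rigid_transform(dy = 4.5, dx = -2.25, theta = 0.2,
                           center = c(20, 20))
  moved <- transform_points(truth, pts)
  fit <- register_control_points(pts, moved)
  grid <- cbind(runif(20, 0, 60), runif(20, 0, 60))
  expect_lt(max(abs(transform_points(fit, grid) -
                    transform_points(truth, grid))), 1e-6)
})

test_that("control-point fitting rejects underdetermined input", {
  expect_error(register_control_points(cbind(1, 2), cbind(3, 4)), ">= 2")
  same <- cbind(c(5, 5, 5), c(7, 7, 7))
  expect_error(register_control_points(same, same), "coincident")
})

test_that("transforms invert and round-trip points to 1e-6 px", {
  tf <- rigid_transform(dy = 3.2, dx = -1.7, theta = 0.15, center = c(10, 12))
  pts <- cbind(runif(50, 0, 100), runif(50, 0, 100))
  back <- transform_points(invert_transform(tf), transform_points(tf, pts))
  expect_lt(max(abs(back - pts)), 1e-6)
})

test_that("image resampling honors identity and inverse shifts", {
  set.seed(31)
  img <- matrix(runif(40 * 40), 40, 40)
  ident <- apply_transform(img, rigid_transform(0, 0))
  expect_equal(ident$pixels, img)
  expect_true(all(ident$valid))
  fwd <- apply_transform(img, rigid_transform(1, 0))
  back <- apply_transform(fwd$pixels, rigid_transform(-1, 0))
  interior <- back$valid & apply_transform(fwd$valid * 1,
                                           rigid_transform(-1, 0))$pixels > 0.5
  expect_equal(back$pixels[interior], img[interior], tolerance = 1e-9)
})

test_that("warping a registered phantom round recovers the reference image", {
  cfg <- clean_phantom_config(n_cells = 25, field = 192, seed = 19,
                              round_shifts = list(ipai = c(0, 0),
                                                  af = c(6, -9)))
  ph <- generate_phantom(cfg)
  ref <- ph$rounds$ipai$DAPI$pixels
  mov <- ph$rounds$af$DAPI$pixels
  tf <- register_rounds(ref, mov)
  w <- apply_transform(mov, tf)
  expect_lt(mean(abs(ref[w$valid] - w$pixels[w$valid])), 1e-6)
})

test_that("transforms serialize to JSON and back", {
  tf <- rigid_transform(2.5, -3.75, 0.1, score = 0.87, center = c(5, 6))
  p <- withr::local_tempfile(fileext = ".json")
  write_transform_json(tf, p)
  back <- read_transform_json(p)
  expect_equal(back$dy, tf$dy)
  expect_equal(back$theta, tf$theta)
  expect_equal(back$center, tf$center)
})
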
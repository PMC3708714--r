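# Projective registration and displacement pairing.

ref_H <- rbind(c(1.02, 0.003, 55), c(-0.002, 0.985, -30), c(2e-7, -1e-7, 1))

test_that("four exact correspondences determine the map exactly", {
  pts <- data.frame(x_src = c(0, 4000, 0, 4000, 1234),
                    y_src = c(0, 0, 4000, 4000, 2345))
  dst <- map_coordinates(ref_H, pts)
  tf <- build_transform(data.frame(x_src = pts$x_src[1:4], y_src = pts$y_src[1:4],
                                   x_dst = dst[1:4, 1], y_dst = dst[1:4, 2]))
  held_out <- map_coordinates(tf, pts[5, ])
  expect_lt(max(abs(held_out - dst[5, , drop = FALSE])), 1e-9)
})

test_that("identity correspondences give the identity matrix", {
  set.seed(31)
  p <- data.frame(x_src = runif(10, 0, 5000), y_src = runif(10, 0, 5000))
  tf <- build_transform(cbind(p, x_dst = p$x_src, y_dst = p$y_src))
  expect_lt(max(abs(tf$matrix - diag(3))), 1e-8)
})

test_that("registration error tracks the fiducial jitter", {
  cp <- gen_fiducial_points(ref_H, 100, jitter = 10, seed = 32)
  tf <- build_transform(cp)
  expect_lt(abs(tf$registration_error - 10 * sqrt(2)) / (10 * sqrt(2)), 0.30)
  # jitter is per coordinate; the RMS point residual is sqrt(2) * 10 nm,
  # i.e. the ~10-nm per-axis registration accuracy of the original setup
})

test_that("degenerate fiducial configurations are rejected", {
  col <- data.frame(x_src = 1:5 * 100, y_src = 1:5 * 100,
                    x_dst = 1:5 * 100, y_dst = 1:5 * 100)
  expect_error(build_transform(col), "degenerate|collinear")
  expect_error(build_transform(col[1:3, ]), ">= 4")
  expect_error(gen_fiducial_points(ref_H, 3), "n >= 4")
})

test_that("mapping composes with its inverse to machine precision", {
  set.seed(33)
  p <- cbind(runif(50, 0, 5000), runif(50, 0, 5000))
  tf <- structure(list(matrix = ref_H, registration_error = 0, n_points = 4),
                  class = "projective_transform")
  back <- map_coordinates(invert_transform(tf), map_coordinates(tf, p))
  expect_lt(max(abs(back - p)), 1e-8)
})

test_that("a pure one-pixel translation shifts all points by 81 nm", {
  H <- rbind(c(1, 0, 81), c(0, 1, 0), c(0, 0, 1))
  p <- cbind(c(0, 500, 1000), c(0, 200, 900))
  mapped <- map_coordinates(H, p)
  expect_equal(mapped[, 1] - p[, 1], rep(81, 3))
  expect_equal(mapped[, 2] - p[, 2], rep(0, 3))
})

test_that("identical coordinates in both channels give zero displacement", {
  red <- data.frame(frame = 0:2, x_nm = c(100, 200, 300), y_nm = c(50, 60, 70))
  d <- pair_and_displace(red, red)
  expect_equal(d$r, rep(0, 3))
})

test_that("pairs beyond the 200-nm gate are rejected and counted", {
  red <- data.frame(frame = 0, x_nm = 1000, y_nm = 1000)
  yel <- data.frame(frame = 0, x_nm = 1300, y_nm = 1000)  # 300 nm away
  d <- pair_and_displace(red, yel)
  expect_equal(nrow(d), 0)
  expect_equal(attr(d, "n_rejected"), 1L)
})

test_that("a one-pixel displacement yields r = 81 nm", {
  red <- data.frame(frame = 0, x_nm = 1000, y_nm = 1000)
  yel <- data.frame(frame = 0, x_nm = 1000 - 81, y_nm = 1000)
  d <- pair_and_displace(red, yel)
  expect_equal(d$r, 81)
  expect_equal(d$dx, 81)
})

test_that("displacements are antisymmetric under channel swap with inverted map", {
  set.seed(34)
  # well-separated grid so nearest-neighbour pairing is unambiguous in
  # both pairing directions
  gx <- rep(c(800, 2000, 3200), 2); gy <- rep(c(1200, 3200), each = 3)
  red <- data.frame(frame = rep(0:4, each = 6),
                    x_nm = rep(gx, 5) + runif(30, -50, 50),
                    y_nm = rep(gy, 5) + runif(30, -50, 50))
  tf <- structure(list(matrix = ref_H, registration_error = 0, n_points = 4),
                  class = "projective_transform")
  # yellow-camera coords of loci ~60 nm from the red loci
  true_dx <- rnorm(30, 0, 40); true_dy <- rnorm(30, 0, 40)
  yel_cam <- map_coordinates(invert_transform(tf),
                             cbind(red$x_nm - true_dx, red$y_nm - true_dy))
  yel <- data.frame(frame = red$frame, x_nm = yel_cam[, 1], y_nm = yel_cam[, 2])
  fwd <- pair_and_displace(red, yel, tf)
  # channel swap: yellow spots become the anchor, red-camera spots are
  # mapped into the yellow frame with the inverted transform
  swapped <- pair_and_displace(yel, red, invert_transform(tf))
  ord_f <- order(fwd$frame, fwd$dx)
  ord_s <- order(swapped$frame, -swapped$dx)
  # the swapped displacement is the negated vector, up to the local
  # projective scale (within ~2% of unity over this field)
  expect_equal(nrow(fwd), nrow(swapped))
  expect_lt(max(abs(fwd$dx[ord_f] + swapped$dx[ord_s])), 6)
  expect_lt(max(abs(fwd$dy[ord_f] + swapped$dy[ord_s])), 6)
})

test_that("rejection rate on well-matched data approximates the outlier rate", {
  set.seed(35)
  n <- 2000
  out_rate <- 0.01
  is_out <- runif(n) < out_rate
  sep <- ifelse(is_out, runif(n, 250, 600), abs(rnorm(n, 60, 30)))
  ang <- runif(n, 0, 2 * pi)
  red <- data.frame(frame = seq_len(n), x_nm = 5000, y_nm = 5000)
  yel <- data.frame(frame = seq_len(n), x_nm = 5000 + sep * cos(ang),
                    y_nm = 5000 + sep * sin(ang))
  d <- pair_and_displace(red, yel)
  got_rate <- attr(d, "n_rejected") / n
  expect_lt(abs(got_rate - mean(sep > 200)), 1e-9)
  expect_lt(abs(got_rate - out_rate), 3 * sqrt(out_rate / n) + 2e-3)
})

test_that("molecule tracking links spots within the 3-px gate across frames", {
  # two molecules, three frames, small drift
  sp <- data.frame(frame = rep(0:2, each = 2),
                   x_nm = c(1000, 3000, 1040, 3010, 1010, 3030),
                   y_nm = c(1000, 1000, 990, 1020, 1005, 1001))
  tr <- track_molecules(sp)
  expect_equal(length(unique(tr$molecule_id)), 2)
  expect_equal(as.integer(table(tr$molecule_id)), c(3L, 3L))
})
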
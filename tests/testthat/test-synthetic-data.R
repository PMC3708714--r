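# Generators: movies, trajectories, fiducials, reproducibility, file I/O.

test_that("zero-photon movies are pure Poisson background", {
  cfg <- movie_config(photons_per_spot = 0, n_frames = 4, image_shape = c(32, 32),
                      background_mean = 20)
  truth <- data.frame(molecule_id = 1, frame = 0:3,
                      x_red_nm = 1000, y_red_nm = 1000,
                      x_yel_nm = 1050, y_yel_nm = 1000)
  mov <- gen_two_channel_movie(cfg, truth, seed = 61)
  n <- length(mov$red)
  se <- sqrt(20 / n)
  expect_lt(abs(mean(mov$red) - 20), 3 * se)
  expect_lt(abs(mean(mov$yellow) - 20), 3 * se)
})

test_that("bleaching on-times follow the geometric closed form", {
  cfg <- movie_config(bleach_prob = 0.25, n_frames = 40, image_shape = c(20, 20),
                      photons_per_spot = 0)
  truth <- expand.grid(molecule_id = 1:400, frame = 0:39)
  truth$x_red_nm <- 800; truth$y_red_nm <- 800
  truth$x_yel_nm <- 800; truth$y_yel_nm <- 800
  mov <- gen_two_channel_movie(cfg, truth, seed = 62)
  on_times <- tapply(mov$truth$on_red, mov$truth$molecule_id, sum)
  # mean of geometric (support 1, 2, ...) is 1/p; censoring at 40 frames is
  # negligible for p = 0.25
  expect_lt(abs(mean(on_times) - 1 / 0.25), 3 * sd(on_times) / sqrt(400))
})

test_that("a bright rendered spot is recovered by the localization module
          within 2 nm", {
  cfg <- movie_config(photons_per_spot = 2e5, background_mean = 5,
                      bleach_prob = 0, n_frames = 1, image_shape = c(32, 32))
  x_true <- 15.31 * 81; y_true <- 16.42 * 81
  truth <- data.frame(molecule_id = 1, frame = 0, x_red_nm = x_true,
                      y_red_nm = y_true, x_yel_nm = x_true, y_yel_nm = y_true)
  mov <- gen_two_channel_movie(cfg, truth, seed = 63)
  loc <- localize_stack(mov$red, 100, estimate_errors = FALSE)
  expect_equal(nrow(loc), 1)
  expect_lt(abs(loc$x_nm - x_true), 2)
  expect_lt(abs(loc$y_nm - y_true), 2)
})

test_that("out-of-frame positions are reported with the molecule id", {
  cfg <- movie_config(image_shape = c(16, 16))
  truth <- data.frame(molecule_id = 7, frame = 0, x_red_nm = 1e5,
                      y_red_nm = 100, x_yel_nm = 100, y_yel_nm = 100)
  expect_error(gen_two_channel_movie(cfg, truth), "7")
})

test_that("trajectory states follow the looping fraction", {
  tr1 <- gen_displacement_trajectories(1, n_mol = 50, n_frames = 3, seed = 64)
  expect_true(all(tr1$state == "looped"))
  tr0 <- gen_displacement_trajectories(0, n_mol = 50, n_frames = 3, seed = 65)
  expect_true(all(tr0$state == "unlooped"))
  tr <- gen_displacement_trajectories(0.5, n_mol = 10000, n_frames = 1, seed = 66)
  f_emp <- mean(tr$state == "looped")
  ci99 <- qbinom(c(0.005, 0.995), 10000, 0.5) / 10000
  expect_gte(f_emp, ci99[1]); expect_lte(f_emp, ci99[2])
  expect_error(gen_displacement_trajectories(1.2), "f_loop")
  expect_error(gen_displacement_trajectories(0.5, looped_sep = -5), "looped_sep")
})

test_that("noise-free unprojected looped trajectories sit at the fixed
          separation", {
  tr <- gen_displacement_trajectories(1, looped_sep = 22, noise = noise_model(0),
                                      n_mol = 30, n_frames = 2, project = FALSE,
                                      seed = 67)
  expect_equal(tr$r, rep(22, nrow(tr)), tolerance = 1e-12)
})

test_that("state switching follows the configured rate", {
  tr <- gen_displacement_trajectories(0.5, n_mol = 200, n_frames = 10,
                                      switch_rate = 2, seed = 68)
  flips <- sum(vapply(split(tr$state, tr$molecule_id),
                      function(s) sum(s[-1] != s[-length(s)]), numeric(1)))
  # P(state differs across a 0.1-s frame) for a symmetric 2/s switcher:
  # (1 - exp(-2 * rate * dt)) / 2
  p_flip <- (1 - exp(-2 * 2 * 0.1)) / 2
  expected <- 200 * 9 * p_flip
  expect_lt(abs(flips - expected), 4 * sqrt(expected))
})

test_that("fiducial generation honours the requested jitter", {
  H <- rbind(c(1.01, 0, 20), c(0, 0.99, -10), c(0, 0, 1))
  cp0 <- gen_fiducial_points(H, 50, jitter = 0, seed = 69)
  tf <- build_transform(cp0)
  expect_lt(tf$registration_error, 1e-9)
  cpI <- gen_fiducial_points(diag(3), 50, jitter = 0, seed = 70)
  expect_equal(cpI$x_src, cpI$x_dst)
  expect_equal(cpI$y_src, cpI$y_dst)
})

test_that("smFISH generator hits its Poisson and false-positive targets", {
  d0 <- gen_smfish_dataset(c(a = 0), n_cells = 300, fp_rate = 0, seed = 71)
  expect_equal(nrow(d0$spots), 0)
  d <- gen_smfish_dataset(c(a = 5), n_cells = 5000, fp_rate = 0, seed = 72)
  expect_lt(abs(mean(d$cells$n_transcripts) - 5), 3 * sqrt(5 / 5000))
  dfp <- gen_smfish_dataset(c(a = 0), n_cells = 5000, fp_rate = 0.02, seed = 73)
  fp_per_cell <- nrow(dfp$spots) / 5000
  expect_lt(abs(fp_per_cell - 1 / 50), 3 * sqrt(0.02 / 5000))
  expect_error(gen_smfish_dataset(c(a = -1)), "strain_means")
})

test_that("generators are reproducible under a fixed seed", {
  expect_identical(gen_displacement_trajectories(0.6, n_mol = 20, seed = 74),
                   gen_displacement_trajectories(0.6, n_mol = 20, seed = 74))
  H <- diag(3)
  expect_identical(gen_fiducial_points(H, 10, seed = 75),
                   gen_fiducial_points(H, 10, seed = 75))
  expect_identical(gen_smfish_dataset(c(a = 3), n_cells = 40, seed = 76),
                   gen_smfish_dataset(c(a = 3), n_cells = 40, seed = 76))
  cfg <- movie_config(n_frames = 2, image_shape = c(24, 24))
  tr <- data.frame(molecule_id = 1, frame = 0:1, x_red_nm = 800, y_red_nm = 800,
                   x_yel_nm = 860, y_yel_nm = 820)
  expect_identical(gen_two_channel_movie(cfg, tr, seed = 77),
                   gen_two_channel_movie(cfg, tr, seed = 77))
})

test_that("truth tables round-trip through CSV bit-exactly and stacks
          survive 16-bit TIFF", {
  tr <- gen_displacement_trajectories(0.5, n_mol = 15, n_frames = 2, seed = 78)
  csv <- tempfile(fileext = ".csv")
  write_table_csv(tr, csv)
  back <- read_table_csv(csv)
  expect_identical(back$dx, tr$dx)
  expect_identical(back$r, tr$r)
  expect_identical(back$state, tr$state)

  cfg <- movie_config(n_frames = 3, image_shape = c(16, 16))
  truth <- data.frame(molecule_id = 1, frame = 0:2, x_red_nm = 500,
                      y_red_nm = 500, x_yel_nm = 530, y_yel_nm = 500)
  mov <- gen_two_channel_movie(cfg, truth, seed = 79)
  tif <- tempfile(fileext = ".tif")
  write_stack_tiff(mov$red, tif)
  back_stack <- read_stack_tiff(tif)
  expect_equal(dim(back_stack), dim(mov$red))
  expect_lt(max(abs(back_stack - mov$red)), 0.5 + 1e-9)  # integer counts survive

  tfm <- build_transform(gen_fiducial_points(diag(3), 20, jitter = 2, seed = 80))
  js <- tempfile(fileext = ".json")
  write_transform_json(tfm, js)
  tfm2 <- read_transform_json(js)
  expect_equal(tfm2$matrix, tfm$matrix, tolerance = 1e-12)
})
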
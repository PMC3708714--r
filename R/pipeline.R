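#' End-to-end synthetic looping-frequency pipeline
#'
#' Simulates the complete experiment for a target strain plus the looped
#' and unlooped control strains — trajectories, two-channel movies with
#' photobleaching, spot detection and Gaussian fitting, projective
#' registration from jittered fiducials, per-frame pairing with the 200-nm
#' gate — and estimates the looping frequency by the bootstrap mixture
#' fit. Used to verify that the pipeline recovers a known truth from
#' image-level data.
#'
#' @param f_loop true looping fraction of the target strain.
#' @param n_mol molecules per strain.
#' @param n_frames frames per movie.
#' @param config a [movie_config()]; its `image_shape` must accommodate
#'   `n_mol` molecules on the placement grid.
#' @param transform optional true inter-channel transform; default is a
#'   small shear+shift homography. Registration is re-estimated from
#'   `n_fiducials` jittered fiducial pairs.
#' @param n_fiducials,fiducial_jitter fiducial count and jitter (nm).
#' @param n_boot bootstrap iterations for the mixture sem.
#' @param estimate_errors run per-spot residual-permutation errors.
#' @param seed RNG seed.
#' @return list with `fit` (a `mixture_fit`), `displacements` (named list
#'   of displacement tables), `transform_est`, `truth_f` = `f_loop`.
#' @export
run_looping_pipeline <- function(f_loop, n_mol = 80, n_frames = 4,
                                 config = movie_config(image_shape = c(96, 132),
                                                       n_frames = 4),
                                 transform = NULL, n_fiducials = 60,
                                 fiducial_jitter = 5, n_boot = 300,
                                 estimate_errors = FALSE, seed = 1) {
  if (is.null(transform)) {
    H <- rbind(c(1.001, 2e-4, 40), c(-1e-4, 0.999, -25), c(1e-8, -1e-8, 1))
    transform <- structure(list(matrix = H, registration_error = 0,
                                n_points = NA), class = "projective_transform")
  }
  strains <- list(target = f_loop, looped = 1, unlooped = 0)
  fid <- gen_fiducial_points(transform, n_fiducials, jitter = fiducial_jitter,
                             field_nm = rev(config$image_shape) * config$pixel_size,
                             seed = child_seed(seed, 90))
  transform_est <- build_transform(fid)
  thr <- config$background_mean + 4 * sqrt(config$background_mean)
  disp <- list()
  for (k in seq_along(strains)) {
    tr <- gen_displacement_trajectories(
      strains[[k]], n_mol = n_mol, n_frames = n_frames,
      frame_interval = config$frame_interval, seed = child_seed(seed, k))
    truth <- place_molecules(tr, config)
    mov <- gen_two_channel_movie(config, truth, transform = transform,
                                 seed = child_seed(seed, 10 + k))
    red <- localize_stack(mov$red, thr, channel = "red",
                          pixel_size = config$pixel_size,
                          estimate_errors = estimate_errors,
                          seed = child_seed(seed, 20 + k))
    yel <- localize_stack(mov$yellow, thr, channel = "yellow",
                          pixel_size = config$pixel_size,
                          estimate_errors = estimate_errors,
                          seed = child_seed(seed, 30 + k))
    red <- track_molecules(red)
    disp[[names(strains)[k]]] <- pair_and_displace(
      red, yel, transform_est, frame_interval = config$frame_interval)
  }
  ok <- vapply(disp, function(d) sum(d$r > 0) >= 20, logical(1))
  if (!all(ok)) stop("too few paired spots in: ",
                     paste(names(disp)[!ok], collapse = ", "))
  pos <- function(d) d[d$r > 0, ]
  fit <- bootstrap_loop_fraction(
    pos(disp$target)$r, pos(disp$looped)$r, pos(disp$unlooped)$r,
    n_boot = n_boot,
    target_unit = pos(disp$target)$molecule_id,
    looped_unit = pos(disp$looped)$molecule_id,
    unlooped_unit = pos(disp$unlooped)$molecule_id,
    seed = child_seed(seed, 50))
  list(fit = fit, displacements = disp, transform_est = transform_est,
       truth_f = f_loop)
}
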
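# Synthetic data generators. These define the study conditions under which
# the pipeline is exercised: diffraction-limited two-color movies with
# photobleaching, looped/unlooped displacement trajectories, fiducial
# control points under a known projective map, and quantized smFISH spots.

#' Movie acquisition configuration
#'
#' Defaults emulate the acquisition geometry of the original experiment
#' (81 nm/px from a 13-um camera pixel at 160x, 100-ms frames) with a
#' photon budget tuned so single-spot localization precision lands in the
#' 14-17 nm range reported for the fluorescent-protein spots.
#'
#' @param pixel_size nm per pixel.
#' @param frame_interval seconds per frame.
#' @param n_frames frames per movie.
#' @param image_shape c(rows, cols) in px.
#' @param background_mean mean background in photons/px/frame.
#' @param psf_sigma PSF Gaussian sd in px.
#' @param photons_per_spot expected photons per spot per frame.
#' @param bleach_prob per-frame, per-channel bleaching probability.
#' @param read_noise_sd optional additive Gaussian camera noise (default 0).
#' @return validated `movie_config` list.
#' @export
movie_config <- function(pixel_size = 81, frame_interval = 0.1, n_frames = 10,
                         image_shape = c(64, 64), background_mean = 20,
                         psf_sigma = 1.2, photons_per_spot = 350,
                         bleach_prob = 0.15, read_noise_sd = 0) {
  stopifnot_scalar(pixel_size, "pixel_size", positive = TRUE)
  stopifnot_scalar(psf_sigma, "psf_sigma", positive = TRUE)
  stopifnot_scalar(bleach_prob, "bleach_prob", nonneg = TRUE)
  if (bleach_prob > 1) stop("bleach_prob must be <= 1")
  stopifnot_scalar(background_mean, "background_mean", nonneg = TRUE)
  stopifnot_scalar(photons_per_spot, "photons_per_spot", nonneg = TRUE)
  structure(list(pixel_size = pixel_size, frame_interval = frame_interval,
                 n_frames = n_frames, image_shape = image_shape,
                 background_mean = background_mean, psf_sigma = psf_sigma,
                 photons_per_spot = photons_per_spot, bleach_prob = bleach_prob,
                 read_noise_sd = read_noise_sd), class = "movie_config")
}

#' Read a movie configuration from YAML
#'
#' Field names mirror the arguments of [movie_config()]; absent fields
#' keep their defaults.
#'
#' @param path YAML file.
#' @return a `movie_config`.
#' @export
movie_config_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(movie_config))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  do.call(movie_config, cfg)
}

# expected photons in each pixel for a spot at (x, y) px: Gaussian PSF
# integrated over the pixel area (not point-sampled), matching the model
# used by the fitting stage.
render_spot <- function(shape, x, y, sigma, photons) {
  nr <- shape[1]; nc <- shape[2]
  px <- (pnorm((0:(nc - 1)) + 0.5, x, sigma) - pnorm((0:(nc - 1)) - 0.5, x, sigma))
  py <- (pnorm((0:(nr - 1)) + 0.5, y, sigma) - pnorm((0:(nr - 1)) - 0.5, y, sigma))
  photons * (py %o% px)
}

#' Generate a two-channel spot movie with photobleaching
#'
#' Renders, for every molecule and frame, an integrated-Gaussian spot in
#' each channel on a Poisson photon background. Each molecule bleaches
#' independently per channel with geometric on-times of mean
#' `1/bleach_prob` frames; bleached spots emit nothing. Yellow-channel
#' positions are passed through the inverse of `transform` (if given) so
#' the downstream registration step has real work to do.
#'
#' @param config a [movie_config()].
#' @param truth data.frame with `molecule_id`, `frame` (0-based),
#'   `x_red_nm`, `y_red_nm`, `x_yel_nm`, `y_yel_nm` (red-frame
#'   coordinates), e.g. from [gen_displacement_trajectories()] +
#'   [place_molecules()].
#' @param transform optional `projective_transform` mapping yellow-camera
#'   nm coordinates into red-camera nm coordinates.
#' @param seed RNG seed.
#' @return list with `red`, `yellow` (arrays rows x cols x frames) and
#'   `truth` (the input with `on_red`/`on_yellow` bleaching flags).
#' @export
gen_two_channel_movie <- function(config, truth, transform = NULL, seed = NULL) {
  if (!inherits(config, "movie_config")) stop("`config` must be a movie_config")
  tr <- as.data.frame(truth)
  need <- c("molecule_id", "frame", "x_red_nm", "y_red_nm", "x_yel_nm", "y_yel_nm")
  if (!all(need %in% names(tr))) stop("truth needs columns ", paste(need, collapse = ", "))
  ps <- config$pixel_size; shape <- config$image_shape
  lim_x <- (shape[2] - 1) * ps; lim_y <- (shape[1] - 1) * ps
  bad <- tr$x_red_nm < 0 | tr$x_red_nm > lim_x | tr$y_red_nm < 0 | tr$y_red_nm > lim_y |
         tr$x_yel_nm < 0 | tr$x_yel_nm > lim_x | tr$y_yel_nm < 0 | tr$y_yel_nm > lim_y
  if (any(bad))
    stop("positions outside frame for molecule_id: ",
         paste(unique(tr$molecule_id[bad]), collapse = ", "))
  inv <- if (!is.null(transform)) invert_transform(transform) else NULL
  with_seed(seed, {
    mols <- unique(tr$molecule_id)
    on_frames <- function() {
      if (config$bleach_prob == 0) rep(Inf, length(mols))
      else rgeom(length(mols), config$bleach_prob) + 1
    }
    on_red <- setNames(on_frames(), mols)
    on_yel <- setNames(on_frames(), mols)
    nfr <- config$n_frames
    red <- array(0, c(shape[1], shape[2], nfr))
    yel <- array(0, c(shape[1], shape[2], nfr))
    tr$on_red <- tr$frame < on_red[as.character(tr$molecule_id)]
    tr$on_yellow <- tr$frame < on_yel[as.character(tr$molecule_id)]
    for (f in seq_len(nfr)) {
      mu_r <- matrix(config$background_mean, shape[1], shape[2])
      mu_y <- matrix(config$background_mean, shape[1], shape[2])
      sub <- tr[tr$frame == f - 1, , drop = FALSE]
      for (k in seq_len(nrow(sub))) {
        if (sub$on_red[k])
          mu_r <- mu_r + render_spot(shape, sub$x_red_nm[k] / ps,
                                     sub$y_red_nm[k] / ps, config$psf_sigma,
                                     config$photons_per_spot)
        if (sub$on_yellow[k]) {
          pos <- c(sub$x_yel_nm[k], sub$y_yel_nm[k])
          if (!is.null(inv)) pos <- as.numeric(map_coordinates(inv, rbind(pos)))
          mu_y <- mu_y + render_spot(shape, pos[1] / ps, pos[2] / ps,
                                     config$psf_sigma, config$photons_per_spot)
        }
      }
      red[, , f] <- matrix(rpois(length(mu_r), mu_r), shape[1], shape[2])
      yel[, , f] <- matrix(rpois(length(mu_y), mu_y), shape[1], shape[2])
      if (config$read_noise_sd > 0) {
        red[, , f] <- red[, , f] + rnorm(length(mu_r), 0, config$read_noise_sd)
        yel[, , f] <- yel[, , f] + rnorm(length(mu_y), 0, config$read_noise_sd)
      }
    }
    list(red = red, yellow = yel, truth = tr)
  })
}

#' Generate displacement trajectories for a looped/unlooped mixture
#'
#' Molecules are looped with probability `f_loop`. A looped molecule's true
#' 3D separation is the fixed looped-control geometry (22 nm, the 66-bp
#' spacing of the permanently juxtaposed construct); an unlooped molecule
#' draws one WLC end-to-end distance. Each molecule's conformation is
#' projected once onto the plane at a random orientation and held fixed
#' (`switch_rate = 0`, the default, freezes states — conformations persist
#' over the 0.5-s observation window in vivo); per-frame apparent vectors
#' add fresh localization noise per spot and coordinate. With
#' `switch_rate > 0` states and conformations are redrawn after
#' exponential waiting times.
#'
#' @param f_loop looped fraction in \[0, 1\].
#' @param looped_sep looped-state 3D separation in nm (default 22).
#' @param wlc a [wlc_model()] for the unlooped state (default the compact
#'   chromosomal geometry: 782-nm contour, 3-nm apparent persistence).
#' @param noise a [noise_model()].
#' @param n_mol,n_frames numbers of molecules and frames.
#' @param switch_rate looped/unlooped switching rate in 1/s (default 0).
#' @param frame_interval seconds per frame.
#' @param project if `FALSE`, the 3D separation is laid in the image plane
#'   (no random projection); mainly for calibration checks.
#' @param seed RNG seed.
#' @return data.frame with `molecule_id`, `frame`, `state`, `true_r3d`,
#'   `true_dx`, `true_dy` (projected truth), `dx`, `dy`, `r` (with noise).
#' @export
gen_displacement_trajectories <- function(f_loop, looped_sep = 22,
                                          wlc = wlc_model(782, 3),
                                          noise = noise_model(),
                                          n_mol = 100, n_frames = 10,
                                          switch_rate = 0, frame_interval = 0.1,
                                          project = TRUE, seed = NULL) {
  if (f_loop < 0 || f_loop > 1) stop("f_loop must be in [0, 1]")
  if (looped_sep < 0) stop("looped_sep must be >= 0")
  with_seed(seed, {
    if (switch_rate == 0) {
      # frozen states: fully vectorized path
      states <- ifelse(runif(n_mol) < f_loop, "looped", "unlooped")
      r3 <- numeric(n_mol)
      r3[states == "looped"] <- looped_sep
      n_un <- sum(states == "unlooped")
      if (n_un > 0)
        r3[states == "unlooped"] <- suppressWarnings(sample_wlc_r3d(wlc, n_un))
      r2 <- if (project) r3 * sqrt(1 - runif(n_mol, -1, 1)^2) else r3
      phi <- runif(n_mol, 0, 2 * pi)
      tr <- data.frame(
        molecule_id = rep(seq_len(n_mol), each = n_frames),
        frame = rep(0:(n_frames - 1), times = n_mol),
        state = rep(states, each = n_frames),
        true_r3d = rep(r3, each = n_frames),
        true_dx = rep(r2 * cos(phi), each = n_frames),
        true_dy = rep(r2 * sin(phi), each = n_frames))
      s <- noise$sigma
      n <- nrow(tr)
      tr$dx <- tr$true_dx + rnorm(n, 0, s) - rnorm(n, 0, s)
      tr$dy <- tr$true_dy + rnorm(n, 0, s) - rnorm(n, 0, s)
      tr$r <- sqrt(tr$dx^2 + tr$dy^2)
      return(tr)
    }
    draw_conf <- function(state) {
      r3 <- if (state == "looped") looped_sep
            else suppressWarnings(sample_wlc_r3d(wlc, 1))
      r2 <- if (project) {
        cth <- runif(1, -1, 1)
        r3 * sqrt(1 - cth^2)
      } else r3
      phi <- runif(1, 0, 2 * pi)
      c(r3 = r3, dx = r2 * cos(phi), dy = r2 * sin(phi))
    }
    out <- vector("list", n_mol)
    states0 <- ifelse(runif(n_mol) < f_loop, "looped", "unlooped")
    for (m in seq_len(n_mol)) {
      st <- states0[m]
      conf <- draw_conf(st)
      rows <- data.frame(molecule_id = m, frame = 0:(n_frames - 1),
                         state = st, true_r3d = conf[["r3"]],
                         true_dx = NA_real_, true_dy = NA_real_)
      t_next <- if (switch_rate > 0) rexp(1, switch_rate) else Inf
      for (f in seq_len(n_frames)) {
        tnow <- (f - 1) * frame_interval
        while (tnow >= t_next) {
          st <- if (st == "looped") "unlooped" else "looped"
          conf <- draw_conf(st)
          t_next <- t_next + rexp(1, switch_rate)
        }
        rows$state[f] <- st
        rows$true_r3d[f] <- conf[["r3"]]
        rows$true_dx[f] <- conf[["dx"]]
        rows$true_dy[f] <- conf[["dy"]]
      }
      out[[m]] <- rows
    }
    tr <- do.call(rbind, out)
    s <- noise$sigma
    n <- nrow(tr)
    tr$dx <- tr$true_dx + rnorm(n, 0, s) - rnorm(n, 0, s)
    tr$dy <- tr$true_dy + rnorm(n, 0, s) - rnorm(n, 0, s)
    tr$r <- sqrt(tr$dx^2 + tr$dy^2)
    rownames(tr) <- NULL
    tr
  })
}

#' Place trajectory truth in a camera field of view
#'
#' Anchors each molecule's red locus on a regular grid inside the image and
#' offsets the yellow locus by the molecule's true displacement vector,
#' producing the truth table consumed by [gen_two_channel_movie()].
#'
#' @param trajectories output of [gen_displacement_trajectories()].
#' @param config a [movie_config()].
#' @param margin_px margin kept free at the image border.
#' @param spacing_px grid spacing between molecules in px.
#' @return truth data.frame with red/yellow nm coordinates.
#' @export
place_molecules <- function(trajectories, config, margin_px = 6, spacing_px = 12) {
  tr <- as.data.frame(trajectories)
  mols <- unique(tr$molecule_id)
  ps <- config$pixel_size
  nc <- config$image_shape[2]; nr <- config$image_shape[1]
  per_row <- max(1, floor((nc - 2 * margin_px) / spacing_px))
  gx <- margin_px + (((seq_along(mols) - 1) %% per_row)) * spacing_px
  gy <- margin_px + (((seq_along(mols) - 1) %/% per_row)) * spacing_px
  if (any(gy > nr - margin_px))
    stop("too many molecules for the field of view; enlarge image_shape")
  ax <- setNames(gx * ps, mols); ay <- setNames(gy * ps, mols)
  key <- as.character(tr$molecule_id)
  data.frame(molecule_id = tr$molecule_id, frame = tr$frame,
             x_red_nm = ax[key], y_red_nm = ay[key],
             x_yel_nm = ax[key] + tr$true_dx, y_yel_nm = ay[key] + tr$true_dy,
             state = tr$state)
}

#' Generate fiducial control points under a known projective map
#'
#' Points are scattered uniformly over the field; targets are the mapped
#' points plus isotropic Gaussian jitter of sd `jitter` (about 10 nm
#' reproduces the registration error achievable with a tandem two-color
#' fiducial in this setup).
#'
#' @param transform `projective_transform` or 3x3 matrix (source -> target).
#' @param n number of pairs (>= 4).
#' @param jitter Gaussian sd in nm added to each target coordinate.
#' @param field_nm c(width, height) of the field in nm.
#' @param seed RNG seed.
#' @return data.frame with `x_src`, `y_src`, `x_dst`, `y_dst` (nm).
#' @export
gen_fiducial_points <- function(transform, n, jitter = 10,
                                field_nm = c(64, 64) * 81, seed = NULL) {
  if (n < 4) stop("projective map underdetermined: need n >= 4")
  H <- if (inherits(transform, "projective_transform")) transform$matrix else transform
  if (abs(det(H)) < 1e-15) stop("transform not invertible")
  with_seed(seed, {
    src <- cbind(runif(n, 0, field_nm[1]), runif(n, 0, field_nm[2]))
    dst <- map_coordinates(H, src)
    dst <- dst + matrix(rnorm(2 * n, 0, jitter), n, 2)
    data.frame(x_src = src[, 1], y_src = src[, 2],
               x_dst = dst[, 1], y_dst = dst[, 2])
  })
}

#' Generate a synthetic smFISH dataset
#'
#' Per-cell transcript counts are Poisson with the strain mean; transcripts
#' landing within `merge_radius_px` of each other in the same cell merge
#' into one diffraction-limited spot with summed intensity (the origin of
#' the quantized intensity distribution). Single-transcript intensities are
#' Gamma-distributed with mean `mu1` and coefficient of variation `cv`.
#' False-positive spots (nonspecifically bound probes that co-localize)
#' appear at `fp_rate` per cell with single-transcript intensity; the
#' experimental level was about 1 transcript per 50 cells.
#'
#' @param strain_means named numeric vector of mean transcripts/cell (>= 0).
#' @param n_cells cells per strain.
#' @param mu1 mean single-transcript intensity (a.u.).
#' @param cv coefficient of variation of single-transcript intensity.
#' @param fp_rate mean false-positive spots per cell (default 0.02).
#' @param cell_px c(width, height) of each (rectangular) cell in px.
#' @param merge_radius_px co-localization merge radius in px.
#' @param seed RNG seed.
#' @return list with `spots` (strain, cell_id, x_px, y_px, intensity,
#'   n_true), `cells` (strain, cell_id, n_transcripts truth) and `masks`
#'   (one labeled matrix per strain; 0 = background).
#' @export
gen_smfish_dataset <- function(strain_means, n_cells = 500, mu1 = 1000,
                               cv = 0.2, fp_rate = 0.02, cell_px = c(20, 10),
                               merge_radius_px = 2, seed = NULL) {
  if (any(strain_means < 0)) stop("strain_means must be >= 0")
  if (is.null(names(strain_means)))
    names(strain_means) <- paste0("strain", seq_along(strain_means))
  shape <- 1 / cv^2
  with_seed(seed, {
    spots <- list(); cells <- list(); masks <- list()
    for (s in names(strain_means)) {
      lam <- strain_means[[s]]
      counts <- rpois(n_cells, lam)
      per_row <- 16
      mask <- matrix(0L, ceiling(n_cells / per_row) * cell_px[2], per_row * cell_px[1])
      for (cid in seq_len(n_cells)) {
        cx0 <- ((cid - 1) %% per_row) * cell_px[1]
        cy0 <- ((cid - 1) %/% per_row) * cell_px[2]
        mask[cy0 + seq_len(cell_px[2]), cx0 + seq_len(cell_px[1])] <- cid
        k <- counts[cid] + rpois(1, fp_rate)
        if (k == 0) next
        xs <- cx0 + runif(k, 0, cell_px[1]); ys <- cy0 + runif(k, 0, cell_px[2])
        ints <- rgamma(k, shape = shape, scale = mu1 / shape)
        merged_id <- merge_colocalized(xs, ys, merge_radius_px)
        for (g in unique(merged_id)) {
          ix <- merged_id == g
          spots[[length(spots) + 1]] <- data.frame(
            strain = s, cell_id = cid, x_px = mean(xs[ix]), y_px = mean(ys[ix]),
            intensity = sum(ints[ix]), n_true = sum(ix))
        }
      }
      cells[[length(cells) + 1]] <- data.frame(strain = s, cell_id = seq_len(n_cells),
                                               n_transcripts = counts)
      masks[[s]] <- mask
    }
    list(spots = if (length(spots)) do.call(rbind, spots) else
           data.frame(strain = character(0), cell_id = integer(0), x_px = numeric(0),
                      y_px = numeric(0), intensity = numeric(0), n_true = integer(0)),
         cells = do.call(rbind, cells), masks = masks)
  })
}

# single-link clustering of spot positions within `radius`
merge_colocalized <- function(xs, ys, radius) {
  k <- length(xs)
  id <- seq_len(k)
  if (k > 1) for (i in 1:(k - 1)) for (j in (i + 1):k) {
    if ((xs[i] - xs[j])^2 + (ys[i] - ys[j])^2 <= radius^2)
      id[id == id[j]] <- id[i]
  }
  id
}
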
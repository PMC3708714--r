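#' Worm-like-chain model
#'
#' Container for the contour length and persistence length of a worm-like
#' chain (WLC). The radial end-to-end sampler uses Daniels' Gaussian
#' approximation with the first-order correction, which is accurate when the
#' contour length greatly exceeds the persistence length; a warning is
#' issued when `L / Lp < 10`.
#'
#' @param L contour length in nm (> 0). For B-form DNA use
#'   `contour_bp * 0.34`; the 2.3-kb segment studied here is 782 nm and the
#'   66-bp looped-control geometry is 22 nm.
#' @param Lp persistence length in nm (> 0); 50 nm is the standard in vitro
#'   value for naked DNA.
#' @return an object of class `wlc_model`.
#' @export
wlc_model <- function(L, Lp) {
  stopifnot_scalar(L, "L", positive = TRUE)
  stopifnot_scalar(Lp, "Lp", positive = TRUE)
  if (L / Lp < 10)
    warning(sprintf("L/Lp = %.2f < 10: outside the Daniels regime", L / Lp))
  structure(list(L = L, Lp = Lp), class = "wlc_model")
}

#' Contour length of B-form DNA
#'
#' 0.34 nm of helical rise per base pair: 2.3 kb is 782 nm, and the 66-bp
#' center-to-center spacing of the looped-control tags is 22 nm.
#'
#' @param bp number of base pairs.
#' @return contour length in nm.
#' @export
bp_to_contour_nm <- function(bp) bp * 0.34

#' Localization-noise model
#'
#' @param sigma Gaussian measurement error in nm applied independently to
#'   each coordinate of each spot (default 22 nm, the value used to emulate
#'   the looped-control distribution).
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(sigma = 22) {
  stopifnot_scalar(sigma, "sigma", nonneg = TRUE)
  structure(list(sigma = sigma), class = "noise_model")
}

#' Exact WLC mean-square end-to-end distance
#'
#' `<R^2> = 2 Lp L - 2 Lp^2 (1 - exp(-L/Lp))`.
#'
#' @param model a [wlc_model()].
#' @return mean squared 3D end-to-end distance in nm^2.
#' @export
wlc_mean_square_r <- function(model) {
  L <- model$L; Lp <- model$Lp
  2 * Lp * L - 2 * Lp^2 * (1 - exp(-L / Lp))
}

# First-order Daniels correction factor multiplying the Gaussian radial
# density exp(-3R^2/(4 Lp L)); clamped at zero where the expansion goes
# negative (large R, an unphysical tail that is rejected anyway).
daniels_correction <- function(r, L, Lp) {
  b <- 1 - 5 * Lp / (4 * L) + 2 * r^2 / L^2 - 33 * r^4 / (80 * Lp * L^3)
  pmax(b, 0)
}

#' Sample 3D end-to-end distances of a worm-like chain
#'
#' Draws radial end-to-end distances from the Daniels-corrected Gaussian
#' radial density. The base Gaussian has per-coordinate variance
#' `2 Lp L / 3`; proposals are accepted with probability proportional to the
#' first-order Daniels correction, and samples exceeding the contour length
#' are rejected and redrawn, keeping the support physical.
#'
#' @param model a [wlc_model()].
#' @param n number of samples.
#' @param seed RNG seed.
#' @param method `"daniels"` (default) or `"gaussian"` (uncorrected
#'   Gaussian chain, used as an independent reference in the limit
#'   `Lp/L -> 0`).
#' @return numeric vector of `n` distances in nm, all in `(0, L]`.
#' @export
sample_wlc_r3d <- function(model, n, seed = NULL, method = c("daniels", "gaussian")) {
  method <- match.arg(method)
  if (!inherits(model, "wlc_model")) stop("`model` must be a wlc_model")
  L <- model$L; Lp <- model$Lp
  sigc <- sqrt(2 * Lp * L / 3)
  bmax <- if (method == "daniels")
    max(daniels_correction(seq(0, L, length.out = 4096), L, Lp)) else 1
  with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      m <- max(2L * (n - length(out)), 256L)
      r <- sigc * sqrt(rnorm(m)^2 + rnorm(m)^2 + rnorm(m)^2)
      keep <- r <= L & r > 0
      if (method == "daniels") {
        acc <- daniels_correction(r, L, Lp) / bmax
        keep <- keep & runif(m) < acc
      }
      out <- c(out, r[keep])
    }
    out[seq_len(n)]
  })
}

#' Project 3D separations onto the image plane and add localization noise
#'
#' Each 3D distance is multiplied by `sin(theta)` with `cos(theta)` uniform
#' on (-1, 1) (a random projection direction), the two fluorophores are
#' placed at the projected separation, and independent Gaussian errors of
#' sd `noise$sigma` are added to each coordinate of each spot. The apparent
#' 2D distance between the perturbed spots is returned.
#'
#' @param r3d vector of 3D separations in nm (>= 0).
#' @param noise a [noise_model()].
#' @param seed RNG seed.
#' @param project if `FALSE`, skip the random projection (the separation is
#'   taken to lie in the plane).
#' @return vector of apparent 2D distances in nm.
#' @export
project_and_noise <- function(r3d, noise = noise_model(), seed = NULL, project = TRUE) {
  if (any(!is.finite(r3d)) || any(r3d < 0)) stop("`r3d` must be finite and >= 0")
  if (!inherits(noise, "noise_model")) stop("`noise` must be a noise_model")
  n <- length(r3d)
  with_seed(seed, {
    r2d <- if (project) {
      cth <- runif(n, -1, 1)
      r3d * sqrt(1 - cth^2)
    } else r3d
    s <- noise$sigma
    dx <- r2d + rnorm(n, 0, s) - rnorm(n, 0, s)
    dy <- rnorm(n, 0, s) - rnorm(n, 0, s)
    sqrt(dx^2 + dy^2)
  })
}

#' Monte-Carlo mean apparent distance for a noisy, projected WLC
#'
#' Composes [sample_wlc_r3d()] and [project_and_noise()] and reports the
#' mean apparent 2D distance with its standard error. With the 2.3-kb
#' B-form geometry (`L = 782` nm), `Lp = 50` nm and 22-nm noise this is the
#' roughly 200-nm separation expected for an uncompacted chromosomal
#' segment.
#'
#' @inheritParams sample_wlc_r3d
#' @param noise a [noise_model()].
#' @return list with `mean_nm`, `se_nm`, `n`.
#' @export
mean_apparent_distance <- function(model, noise = noise_model(), n = 1e5,
                                   seed = NULL, method = "daniels") {
  r3 <- sample_wlc_r3d(model, n, seed = child_seed(seed, 1), method = method)
  r2 <- project_and_noise(r3, noise, seed = child_seed(seed, 2))
  list(mean_nm = mean(r2), se_nm = sd(r2) / sqrt(n), n = n)
}

#' Apparent persistence length implied by a mean apparent distance
#'
#' Inverts the forward map `Lp -> mean apparent distance` (at fixed contour
#' length and noise) by bisection, using common random numbers so the
#' Monte-Carlo forward map is smooth and monotone in `Lp`. This is the
#' calculation that turns the 71-nm mean separation of the unlooped control
#' into an apparent persistence length of a few nanometres.
#'
#' @param target_mean observed mean apparent distance in nm.
#' @param L contour length in nm.
#' @param noise a [noise_model()].
#' @param tolerance absolute tolerance on the matched mean in nm.
#' @param n Monte-Carlo sample size per forward evaluation.
#' @param seed RNG seed (reused for every forward evaluation).
#' @param lp_range search bracket for the persistence length in nm.
#' @return list with `Lp_nm`, `achieved_mean_nm`, `n_iter`.
#' @export
infer_apparent_lp <- function(target_mean, L, noise = noise_model(),
                              tolerance = 0.5, n = 2e5, seed = 1,
                              lp_range = c(0.2, 200)) {
  stopifnot_scalar(target_mean, "target_mean", positive = TRUE)
  floor_mean <- noise$sigma * sqrt(pi)  # r3d = 0 limit: Rayleigh mean
  if (target_mean <= floor_mean * 1.02)
    stop(sprintf("unreachable: target %.1f nm is at or below the noise floor %.1f nm",
                 target_mean, floor_mean))
  fwd <- function(lp) {
    m <- suppressWarnings(wlc_model(L, lp))
    mean_apparent_distance(m, noise, n = n, seed = seed)$mean_nm
  }
  lo <- lp_range[1]; hi <- lp_range[2]
  flo <- fwd(lo); fhi <- fwd(hi)
  if (target_mean < flo || target_mean > fhi)
    stop("unreachable: target mean outside the forward map over `lp_range`")
  it <- 0L
  repeat {
    it <- it + 1L
    mid <- sqrt(lo * hi)   # bisect in log space; map is smoother there
    fm <- fwd(mid)
    if (abs(fm - target_mean) < tolerance || it >= 60L)
      return(list(Lp_nm = mid, achieved_mean_nm = fm, n_iter = it))
    if (fm < target_mean) lo <- mid else hi <- mid
  }
}
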
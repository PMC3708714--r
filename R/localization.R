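# Spot localization: symmetric 2D Gaussian fits on small patches.
#
# Coordinate convention (fixed so registration round-trips are exact):
# 0-based pixel indices; a spot at the center of pixel [i, j] (row i,
# column j, both 0-based) has coordinates x = j, y = i; nm = px * pixel_size.

#' Detect candidate spots in an image
#'
#' Local maxima above an intensity threshold with non-maximum suppression:
#' candidates within 3 px of a brighter accepted candidate are dropped.
#'
#' @param image numeric matrix (rows = y, columns = x).
#' @param intensity_threshold minimum pixel value for a candidate; must
#'   exceed the background estimate (image median).
#' @param suppression_radius non-maximum-suppression radius in px.
#' @return data.frame with 0-based `x`, `y` and `intensity`, brightest
#'   first.
#' @export
detect_spots <- function(image, intensity_threshold, suppression_radius = 3) {
  if (!is.matrix(image)) stop("`image` must be a matrix")
  bg <- median(image)
  if (intensity_threshold <= bg)
    stop(sprintf("threshold (%.3g) must exceed the background estimate (%.3g)",
                 intensity_threshold, bg))
  if (any(image >= 65535)) warning("saturated pixels present; proceeding")
  nr <- nrow(image); nc <- ncol(image)
  cand <- which(image >= intensity_threshold, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), intensity = numeric(0)))
  is_max <- vapply(seq_len(nrow(cand)), function(k) {
    i <- cand[k, 1]; j <- cand[k, 2]
    win <- image[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)]
    image[i, j] >= max(win)
  }, logical(1))
  cand <- cand[is_max, , drop = FALSE]
  vals <- image[cand]
  ord <- order(vals, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]; vals <- vals[ord]
  keep <- rep(TRUE, nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!keep[k]) next
    if (k < nrow(cand)) {
      later <- (k + 1):nrow(cand)
      d2 <- (cand[later, 1] - cand[k, 1])^2 + (cand[later, 2] - cand[k, 2])^2
      keep[later][d2 < suppression_radius^2] <- FALSE
    }
  }
  data.frame(x = cand[keep, 2] - 1, y = cand[keep, 1] - 1, intensity = vals[keep])
}

#' Extract a square patch around a candidate center
#'
#' @param image numeric matrix.
#' @param center_guess length-2 vector, 0-based (x, y).
#' @param radius half-width in px (default 3, i.e. pixels within 3 px of
#'   the initial location).
#' @return object of class `image_patch`.
#' @export
image_patch <- function(image, center_guess, radius = 3) {
  if (radius < 2) stop("radius must be >= 2")
  cx <- round(center_guess[1]); cy <- round(center_guess[2])
  i0 <- cy + 1 - radius; i1 <- cy + 1 + radius
  j0 <- cx + 1 - radius; j1 <- cx + 1 + radius
  if (i0 < 1 || j0 < 1 || i1 > nrow(image) || j1 > ncol(image))
    stop("patch not fully inside image")
  structure(list(data = image[i0:i1, j0:j1],
                 x0 = j0 - 1, y0 = i0 - 1,   # 0-based image coords of patch [1,1]
                 center_guess = c(cx, cy), radius = radius),
            class = "image_patch")
}

gauss2d_model <- function(par, xg, yg) {
  # par: A, x, y, sigma, B (patch-local coords)
  par[1] * exp(-((xg - par[2])^2 + (yg - par[3])^2) / (2 * par[4]^2)) + par[5]
}

#' Fit a symmetric 2D Gaussian to an image patch
#'
#' Unweighted least squares over amplitude, center, width and constant
#' background, with the Gaussian sd bounded above by 2 px (the width
#' constraint used when fitting dim fluorescent-protein spots). Degenerate
#' patches and non-converged optimizations yield `converged = FALSE`
#' rather than silent NaNs; such spots should be excluded.
#'
#' @param patch an [image_patch()].
#' @param pixel_size nm per pixel (default 81).
#' @param max_sigma upper bound on the Gaussian sd in px (default 2).
#' @return object of class `spot_fit`: list with `x`, `y` (0-based px in
#'   full-image coordinates), `x_nm`, `y_nm`, `amplitude`, `sigma`,
#'   `background`, `converged`, `rss`, `loc_error_nm` (NA until
#'   [estimate_fit_error()] is run).
#' @export
fit_spot <- function(patch, pixel_size = 81, max_sigma = 2) {
  if (!inherits(patch, "image_patch")) stop("`patch` must be an image_patch")
  z <- patch$data
  if (sd(z) < 1e-12)
    return(structure(list(converged = FALSE, reason = "zero-variance patch"),
                     class = "spot_fit"))
  npx <- nrow(z)
  xg <- matrix(rep(0:(npx - 1), each = npx), npx, npx)   # column index
  yg <- matrix(rep(0:(npx - 1), times = npx), npx, npx)  # row index
  B0 <- min(z); A0 <- max(z) - B0
  w <- pmax(z - B0, 0)
  x0 <- sum(xg * w) / max(sum(w), 1e-12); y0 <- sum(yg * w) / max(sum(w), 1e-12)
  par0 <- c(A = A0, x = x0, y = y0, sigma = 1.2, B = B0)
  obj <- function(p) sum((gauss2d_model(p, xg, yg) - z)^2)
  grad <- function(p) {
    g <- exp(-((xg - p[2])^2 + (yg - p[3])^2) / (2 * p[4]^2))
    r <- 2 * (p[1] * g + p[5] - z)
    c(sum(r * g),
      sum(r * p[1] * g * (xg - p[2]) / p[4]^2),
      sum(r * p[1] * g * (yg - p[3]) / p[4]^2),
      sum(r * p[1] * g * ((xg - p[2])^2 + (yg - p[3])^2) / p[4]^3),
      sum(r))
  }
  lower <- c(1e-9, -1, -1, 0.3, -Inf)
  upper <- c(Inf, npx, npx, max_sigma, Inf)
  op <- tryCatch(
    optim(par0, obj, gr = grad, method = "L-BFGS-B", lower = lower,
          upper = upper, control = list(maxit = 500, factr = 10)),
    error = function(e) NULL)
  if (is.null(op) || !all(is.finite(op$par)) || op$convergence > 1)
    return(structure(list(converged = FALSE, reason = "optimizer failure"),
                     class = "spot_fit"))
  p <- op$par
  structure(list(
    x = p[["x"]] + patch$x0, y = p[["y"]] + patch$y0,
    x_nm = (p[["x"]] + patch$x0) * pixel_size,
    y_nm = (p[["y"]] + patch$y0) * pixel_size,
    amplitude = p[["A"]], sigma = p[["sigma"]], background = p[["B"]],
    converged = TRUE, rss = op$value, loc_error_nm = NA_real_,
    pixel_size = pixel_size), class = "spot_fit")
}

#' Localization error by residual permutation
#'
#' Scrambles the fit residuals in `n_perm` random permutations over all
#' patch pixels, adds each permuted residual field back onto the data,
#' refits, and reports the root-mean-square distance between the perturbed
#' fit locations and the original fit, in nm. A fresh unit of noise with
#' the empirical residual distribution displaces the fit by about one
#' localization-sd, so this rms estimates the per-spot precision without
#' repeated acquisitions.
#'
#' @param patch the [image_patch()] that produced `fit`.
#' @param fit a converged [fit_spot()] result.
#' @param n_perm number of permutations (default 10).
#' @param seed RNG seed.
#' @return list with `loc_error_nm`, `n_success`, `reliable` (FALSE when
#'   fewer than 5 permutations refit successfully).
#' @export
estimate_fit_error <- function(patch, fit, n_perm = 10, seed = NULL) {
  if (!isTRUE(fit$converged)) stop("fit must have converged")
  z <- patch$data
  npx <- nrow(z)
  xg <- matrix(rep(0:(npx - 1), each = npx), npx, npx)
  yg <- matrix(rep(0:(npx - 1), times = npx), npx, npx)
  p <- c(fit$amplitude, fit$x - patch$x0, fit$y - patch$y0, fit$sigma, fit$background)
  resid <- z - gauss2d_model(p, xg, yg)
  dists <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      zp <- z + matrix(sample(as.vector(resid)), npx, npx)
      pp <- patch; pp$data <- zp
      f2 <- fit_spot(pp, pixel_size = fit$pixel_size)
      if (!isTRUE(f2$converged)) return(NA_real_)
      sqrt((f2$x - fit$x)^2 + (f2$y - fit$y)^2)
    }, numeric(1))
  })
  ok <- dists[is.finite(dists)]
  list(loc_error_nm = sqrt(mean(ok^2)) * fit$pixel_size,
       n_success = length(ok), reliable = length(ok) >= 5)
}

#' Localize all spots in an image stack
#'
#' Runs detection, patch fitting and residual-permutation error estimation
#' on every frame of a stack and returns one localization table.
#'
#' @param stack 3D array (rows, cols, frames) or list of matrices.
#' @param intensity_threshold detection threshold; `NULL` uses
#'   `median + 5 * mad` of the first frame.
#' @param channel label stored in the output.
#' @param pixel_size nm per pixel.
#' @param radius patch half-width in px.
#' @param estimate_errors run [estimate_fit_error()] per spot (slower).
#' @param seed RNG seed for error estimation.
#' @return data.frame with `frame`, `channel`, `x_px`, `y_px`, `x_nm`,
#'   `y_nm`, `amplitude`, `width`, `background`, `loc_error_nm`,
#'   `converged`.
#' @export
localize_stack <- function(stack, intensity_threshold = NULL, channel = "red",
                           pixel_size = 81, radius = 3, estimate_errors = TRUE,
                           seed = NULL) {
  frames <- if (is.array(stack) && length(dim(stack)) == 3)
    lapply(seq_len(dim(stack)[3]), function(k) stack[, , k]) else stack
  if (is.null(intensity_threshold)) {
    f1 <- frames[[1]]
    intensity_threshold <- median(f1) + 5 * mad(f1)
  }
  rows <- list()
  for (fr in seq_along(frames)) {
    img <- frames[[fr]]
    det <- detect_spots(img, intensity_threshold)
    for (k in seq_len(nrow(det))) {
      pat <- tryCatch(image_patch(img, c(det$x[k], det$y[k]), radius),
                      error = function(e) NULL)
      if (is.null(pat)) next
      ft <- fit_spot(pat, pixel_size = pixel_size)
      if (!isTRUE(ft$converged)) next
      le <- NA_real_
      if (estimate_errors) {
        ee <- estimate_fit_error(pat, ft, seed = child_seed(seed, fr * 1000 + k))
        le <- ee$loc_error_nm
      }
      rows[[length(rows) + 1]] <- data.frame(
        frame = fr - 1, channel = channel, x_px = ft$x, y_px = ft$y,
        x_nm = ft$x_nm, y_nm = ft$y_nm, amplitude = ft$amplitude,
        width = ft$sigma, background = ft$background, loc_error_nm = le,
        converged = TRUE)
    }
  }
  if (!length(rows))
    return(data.frame(frame = numeric(0), channel = character(0),
                      x_px = numeric(0), y_px = numeric(0), x_nm = numeric(0),
                      y_nm = numeric(0), amplitude = numeric(0),
                      width = numeric(0), background = numeric(0),
                      loc_error_nm = numeric(0), converged = logical(0)))
  do.call(rbind, rows)
}
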
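#' Kernel density estimate of displacement magnitudes on positive support
#'
#' Boxcar-kernel density estimate of positive distances, evaluated on a
#' fixed 10-nm bin grid, with the density reflected at r = 0 so no
#' probability mass is lost at the boundary. Reported bin values are
#' averages of the smoothed density over each bin (the increment of the
#' smoothed CDF divided by the bin width), so the PDF sums to the total
#' smoothed mass exactly and the PDF and CDF are numerically consistent.
#'
#' When `kernel_width` is `NULL` it is selected automatically: the largest
#' width from a candidate grid whose smoothed CDF stays within `bw_tol` of
#' the empirical CDF everywhere, i.e. the strongest smoothing that does not
#' introduce systematic error relative to the raw data.
#'
#' @param r_samples positive distances in nm (n >= 10).
#' @param kind `"pdf"` or `"cdf"`.
#' @param bin bin width in nm (default 10).
#' @param kernel_width half-width of the boxcar kernel in nm, or `NULL` for
#'   automatic selection.
#' @param r_max upper edge of the binned support in nm; defaults to at
#'   least 200 nm (the pairing gate) extended to cover the data.
#' @param bw_tol tolerance on the sup-deviation between smoothed and
#'   empirical CDFs used by automatic width selection; default
#'   `max(0.01, 0.5 / sqrt(n))`.
#' @param unit optional vector of resampling-unit ids (e.g. molecule ids),
#'   one per sample, used for the bootstrap sem.
#' @param n_boot bootstrap replicates for per-bin sem (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return object of class `density_estimate` with fields `kind`,
#'   `bin_centers`, `values`, `sem`, `n_samples`, `kernel_width`.
#' @export
density_estimate <- function(r_samples, kind = c("pdf", "cdf"), bin = 10,
                             kernel_width = NULL, r_max = NULL, bw_tol = NULL,
                             unit = NULL, n_boot = 1000, seed = NULL) {
  kind <- match.arg(kind)
  r <- r_samples
  if (length(r) < 10) stop("need at least 10 samples")
  bad <- which(!is.finite(r) | r <= 0)
  if (length(bad))
    stop("nonpositive or non-finite samples at positions: ",
         paste(head(bad, 10), collapse = ", "))
  n <- length(r)
  if (is.null(bw_tol)) bw_tol <- max(0.01, 0.5 / sqrt(n))
  if (is.null(kernel_width)) kernel_width <- select_kernel_width(r, bw_tol)
  h <- kernel_width
  if (is.null(r_max)) r_max <- max(200, ceiling((max(r) + h) / bin) * bin)
  edges <- seq(0, r_max, by = bin)
  centers <- edges[-1] - bin / 2

  vals <- kde_bin_values(r, edges, h, kind)
  sem <- rep(NA_real_, length(centers))
  if (n_boot > 0) {
    ids <- if (is.null(unit)) seq_len(n) else unit
    groups <- split(seq_len(n), ids)
    boot <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        take <- unlist(groups[sample.int(length(groups), replace = TRUE)],
                       use.names = FALSE)
        kde_bin_values(r[take], edges, h, kind)
      }, numeric(length(centers)))
    })
    sem <- apply(boot, 1, sd)
  }
  structure(list(kind = kind, bin_centers = centers, values = vals, sem = sem,
                 n_samples = n, kernel_width = h, bin = bin, r_max = r_max),
            class = "density_estimate")
}

# Smoothed CDF of positive data under a boxcar kernel of half-width h with
# reflection at zero: F(x) = mean_s[ K((x-s)/h) + K((x+s)/h) - 1 ], where K
# is the kernel CDF (a unit ramp). Exact mass conservation: F(inf) = 1.
# O((n + m) log n) via sorted samples and cumulative sums.
boxcar_cdf <- function(x, samples, h) {
  if (h <= 0) stop("kernel width must be > 0")
  s <- sort(samples)
  cs <- c(0, cumsum(s))
  n <- length(s)
  # mean over s of ramp(t - s), ramp(u) = clip((u + h) / (2h), 0, 1)
  mean_ramp <- function(t) {
    lo <- findInterval(t - h, s)        # s <= t - h: ramp saturated at 1
    hi <- findInterval(t + h, s)        # s in (t-h, t+h]: partial
    partial <- ((hi - lo) * (t + h) - (cs[hi + 1] - cs[lo + 1])) / (2 * h)
    (lo + partial) / n
  }
  # ramp(u) + ramp(-u) = 1, so mean_s ramp(x + s) = 1 - mean_ramp(-x) and
  # F(x) = mean_ramp(x) + [1 - mean_ramp(-x)] - 1
  mean_ramp(x) - mean_ramp(-x)
}

kde_bin_values <- function(r, edges, h, kind) {
  Fv <- boxcar_cdf(edges, r, h)
  if (kind == "cdf") Fv[-1] else diff(Fv) / diff(edges)
}

select_kernel_width <- function(r, tol,
                                candidates = c(1, 2, 3, 5, 7.5, 10, 15, 20, 30, 40)) {
  rs <- sort(r)
  ecdf_vals <- seq_along(rs) / length(rs)
  ok <- vapply(candidates, function(h) {
    dev <- max(abs(boxcar_cdf(rs, rs, h) - ecdf_vals))
    dev <= tol
  }, logical(1))
  if (!any(ok)) return(min(candidates))
  max(candidates[ok])
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Thin wrapper over [stats::ks.test()] returning the statistic and the
#' asymptotic p-value; ties are tolerated (they arise routinely from binned
#' pixel data).
#'
#' @param a,b numeric samples (each n >= 10).
#' @return list with `D`, `p`, `n_a`, `n_b`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) < 10 || length(b) < 10) stop("both samples need n >= 10")
  kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value),
       n_a = length(a), n_b = length(b))
}

#' Bootstrap standard error of a statistic
#'
#' Standard deviation of a statistic over `n_boot` resamples drawn with
#' replacement at the level of resampling units (molecules by default, so
#' within-molecule frame correlation is respected; pass `unit = NULL` for
#' plain per-observation resampling).
#'
#' @param samples numeric vector.
#' @param statistic function of a numeric vector.
#' @param n_boot number of resamples (default 1000).
#' @param unit optional unit ids, one per sample.
#' @param seed RNG seed.
#' @return list with `sem`, `n_boot`, `n_failed` (resamples redrawn after a
#'   statistic failure).
#' @export
bootstrap_sem <- function(samples, statistic = mean, n_boot = 1000,
                          unit = NULL, seed = NULL) {
  ids <- if (is.null(unit)) seq_along(samples) else unit
  groups <- split(seq_along(samples), ids)
  if (length(groups) < 2) stop("need at least 2 resampling units")
  with_seed(seed, {
    stats_v <- numeric(n_boot)
    n_failed <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        take <- unlist(groups[sample.int(length(groups), replace = TRUE)],
                       use.names = FALSE)
        v <- tryCatch(statistic(samples[take]), error = function(e) NA_real_)
        if (length(v) == 1L && is.finite(v)) break
        n_failed <- n_failed + 1L
        if (n_failed > 10L * n_boot) stop("statistic failed on too many resamples")
      }
      stats_v[b] <- v
    }
    list(sem = sd(stats_v), n_boot = n_boot, n_failed = n_failed)
  })
}

#' Two-dimensional displacement-vector density
#'
#' Normalized 2D histogram of (dx, dy) on a square grid of `bin`-nm bins,
#' smoothed with a Gaussian kernel whose width should match the
#' localization precision.
#'
#' @param vectors data.frame or matrix with columns `dx`, `dy` in nm.
#' @param bin bin size in nm (default 5).
#' @param smooth_sigma Gaussian smoothing sd in nm (default 15, of the
#'   order of the per-spot localization precision).
#' @param half_range half-extent of the grid in nm (default 200).
#' @return object of class `density_2d`: list with `grid` (matrix summing
#'   to 1), `bin_centers`, `bin`, `smooth_sigma`.
#' @export
density_2d <- function(vectors, bin = 5, smooth_sigma = 15, half_range = 200) {
  v <- as.data.frame(vectors)
  if (!all(c("dx", "dy") %in% names(v))) stop("`vectors` needs dx, dy columns")
  if (any(!is.finite(v$dx)) || any(!is.finite(v$dy))) stop("vectors must be finite")
  edges <- seq(-half_range, half_range, by = bin)
  centers <- edges[-1] - bin / 2
  ix <- findInterval(pmin(pmax(v$dx, -half_range + 1e-9), half_range - 1e-9), edges)
  iy <- findInterval(pmin(pmax(v$dy, -half_range + 1e-9), half_range - 1e-9), edges)
  m <- matrix(0, length(centers), length(centers))
  for (k in seq_along(ix)) m[ix[k], iy[k]] <- m[ix[k], iy[k]] + 1
  if (smooth_sigma > 0) {
    s <- smooth_sigma / bin
    half <- max(1L, ceiling(3 * s))
    kern <- dnorm(seq(-half, half), sd = s)
    kern <- kern / sum(kern)
    m <- apply(m, 2, function(col) conv_same(col, kern))
    m <- t(apply(m, 1, function(row) conv_same(row, kern)))
  }
  m <- m / sum(m)
  structure(list(grid = m, bin_centers = centers, bin = bin,
                 smooth_sigma = smooth_sigma), class = "density_2d")
}

#' @importFrom stats dnorm
conv_same <- function(x, kern) {
  half <- (length(kern) - 1L) / 2L
  xp <- c(rep(0, half), x, rep(0, half))
  out <- stats::filter(xp, kern, sides = 2)
  as.numeric(out[(half + 1):(half + length(x))])
}

#' Second moment of a 2D displacement density
#'
#' @param d a [density_2d()] object.
#' @return E\[dx^2 + dy^2\] in nm^2 under the binned density.
#' @export
density_2d_second_moment <- function(d) {
  cx <- matrix(d$bin_centers, length(d$bin_centers), length(d$bin_centers))
  cy <- t(cx)
  sum(d$grid * (cx^2 + cy^2))
}
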
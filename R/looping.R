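#' Looping frequency by constrained linear mixture of control distributions
#'
#' Fits a target displacement-magnitude distribution as
#' `f * looped + (1 - f) * unlooped`, where the basis distributions come
#' from the permanently looped and never-looping control strains. The
#' least-squares weight has a closed form,
#' `f = sum((t - u)(l - u)) / sum((l - u)^2)`, which is computed before
#' clamping to \[0, 1\]. All three estimates must share bins and kind.
#'
#' @param target,looped_ref,unlooped_ref [density_estimate()] objects on
#'   identical bins and of identical kind.
#' @return object of class `mixture_fit`: list with `f_loop`, `sem` (NA
#'   here; see [bootstrap_loop_fraction()]), `basis`, `frames_used`,
#'   `residual` (root-mean-square per bin), `f_unclamped`.
#' @export
fit_loop_fraction <- function(target, looped_ref, unlooped_ref) {
  for (d in list(target, looped_ref, unlooped_ref))
    if (!inherits(d, "density_estimate")) stop("inputs must be density_estimate objects")
  if (!identical(target$bin_centers, looped_ref$bin_centers) ||
      !identical(target$bin_centers, unlooped_ref$bin_centers))
    stop("all three estimates must share bin centers")
  if (target$kind != looped_ref$kind || target$kind != unlooped_ref$kind)
    stop("all three estimates must share kind")
  l <- looped_ref$values; u <- unlooped_ref$values; t_ <- target$values
  d <- l - u
  denom <- sum(d^2)
  if (denom < 1e-12 * max(1, sum(l^2)))
    stop("degenerate basis: looped and unlooped references are identical")
  f_raw <- sum((t_ - u) * d) / denom
  f <- min(1, max(0, f_raw))
  resid <- sqrt(mean((t_ - (f * l + (1 - f) * u))^2))
  structure(list(f_loop = f, sem = NA_real_, basis = target$kind,
                 frames_used = "all", residual = resid, f_unclamped = f_raw),
            class = "mixture_fit")
}

#' Looping frequency with bootstrap error
#'
#' Point estimate from the full samples plus a bootstrap sem in which the
#' target *and both control* samples are resampled on every iteration
#' (with-replacement, at the molecule level when unit ids are given,
#' otherwise per observation). The kernel widths chosen on the original
#' samples are reused across iterations so the error reflects sampling
#' noise, not smoothing-parameter jitter.
#'
#' @param target_samples,looped_samples,unlooped_samples positive distances
#'   in nm.
#' @param n_boot bootstrap iterations (default 1000).
#' @param kind `"cdf"` (default; smoother at fixed n) or `"pdf"`.
#' @param frames_used label recorded in the result (`"all"` or `"first"`);
#'   subsetting to first frames is the caller's responsibility.
#' @param bin,r_max binning of the shared grid (defaults 10 and 200 nm).
#' @param target_unit,looped_unit,unlooped_unit optional molecule ids for
#'   unit-level resampling.
#' @param seed RNG seed.
#' @return `mixture_fit` with `f_loop`, `sem`, `basis`, `frames_used`,
#'   `residual`, `n_target`, `n_controls`.
#' @export
bootstrap_loop_fraction <- function(target_samples, looped_samples, unlooped_samples,
                                    n_boot = 1000, kind = c("cdf", "pdf"),
                                    frames_used = "all", bin = 10, r_max = 200,
                                    target_unit = NULL, looped_unit = NULL,
                                    unlooped_unit = NULL, seed = NULL) {
  kind <- match.arg(kind)
  # one common kernel width for target and controls: the mixture identity
  # target = f*looped + (1-f)*unlooped only survives smoothing when all
  # three distributions are smoothed identically
  h <- max(vapply(list(target_samples, looped_samples, unlooped_samples),
                  function(x) select_kernel_width(x, max(0.01, 0.5 / sqrt(length(x)))),
                  numeric(1)))
  mk <- function(x, hh = h) density_estimate(x, kind = kind, bin = bin,
                                             r_max = r_max, kernel_width = hh,
                                             n_boot = 0)
  d_t <- mk(target_samples); d_l <- mk(looped_samples); d_u <- mk(unlooped_samples)
  fit <- fit_loop_fraction(d_t, d_l, d_u)
  groups <- function(x, u) split(seq_along(x), if (is.null(u)) seq_along(x) else u)
  g_t <- groups(target_samples, target_unit)
  g_l <- groups(looped_samples, looped_unit)
  g_u <- groups(unlooped_samples, unlooped_unit)
  fb <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      rs <- function(x, g) x[unlist(g[sample.int(length(g), replace = TRUE)],
                                    use.names = FALSE)]
      ft <- fit_loop_fraction(mk(rs(target_samples, g_t), d_t$kernel_width),
                              mk(rs(looped_samples, g_l), d_l$kernel_width),
                              mk(rs(unlooped_samples, g_u), d_u$kernel_width))
      ft$f_loop
    }, numeric(1))
  })
  fit$sem <- sd(fb)
  fit$frames_used <- frames_used
  fit$n_target <- length(target_samples)
  fit$n_controls <- c(looped = length(looped_samples), unlooped = length(unlooped_samples))
  fit$boot_quantiles <- quantile(fb, c(0.025, 0.975), names = FALSE)
  fit
}

#' Displacement-vector autocorrelation
#'
#' Mean dot product of displacement vectors separated by a time lag,
#' pooled over all qualifying frame pairs in all molecules. The value at
#' lag zero is the mean squared vector magnitude; for a conformation that
#' persists over the observation window the curve drops between lag 0 and
#' lag 1 by the (uncorrelated) measurement-noise variance and is flat
#' thereafter — the signature used to bound the in vivo looping rate.
#'
#' @param trajectories data.frame with columns `molecule_id`, `frame`,
#'   `dx`, `dy` (nm).
#' @param max_lag maximum lag in seconds (default 0.5).
#' @param frame_interval frame spacing in seconds (default 0.1).
#' @param n_boot bootstrap replicates (molecule level) for the sem.
#' @param seed RNG seed for the bootstrap.
#' @return object of class `autocorr_curve`: data.frame with `lag_s`,
#'   `value_nm2`, `sem`, `n_pairs`.
#' @export
vector_autocorrelation <- function(trajectories, max_lag = 0.5,
                                   frame_interval = 0.1, n_boot = 200,
                                   seed = NULL) {
  tr <- as.data.frame(trajectories)
  need <- c("molecule_id", "frame", "dx", "dy")
  if (!all(need %in% names(tr))) stop("trajectories need columns ", paste(need, collapse = ", "))
  keep <- stats::ave(tr$frame, tr$molecule_id, FUN = length) >= 2
  tr <- tr[keep, , drop = FALSE]
  if (nrow(tr) == 0) stop("no molecule with >= 2 frames")
  lags <- 0:floor(max_lag / frame_interval + 1e-9)
  mols <- split(tr[order(tr$molecule_id, tr$frame), ], tr$molecule_id[order(tr$molecule_id, tr$frame)])
  per_mol <- lapply(mols, function(m) {
    vapply(lags, function(k) {
      i <- match(m$frame + k, m$frame)
      ok <- !is.na(i)
      if (!any(ok)) return(c(0, 0))
      c(sum(m$dx[ok] * m$dx[i[ok]] + m$dy[ok] * m$dy[i[ok]]), sum(ok))
    }, numeric(2))
  })
  sums <- Reduce(`+`, lapply(per_mol, function(x) x[1, ]))
  npairs <- Reduce(`+`, lapply(per_mol, function(x) x[2, ]))
  vals <- sums / npairs
  sem <- rep(NA_real_, length(lags))
  if (n_boot > 0 && length(per_mol) > 1) {
    boot <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        take <- sample.int(length(per_mol), replace = TRUE)
        s <- Reduce(`+`, lapply(per_mol[take], function(x) x[1, ]))
        np <- Reduce(`+`, lapply(per_mol[take], function(x) x[2, ]))
        s / pmax(np, 1)
      }, numeric(length(lags)))
    })
    sem <- apply(boot, 1, sd)
  }
  structure(data.frame(lag_s = lags * frame_interval, value_nm2 = vals,
                       sem = sem, n_pairs = npairs),
            class = c("autocorr_curve", "data.frame"))
}
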
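# smFISH transcript counting: quantized spot intensities -> per-cell counts
# -> expression in wild-type lambda units (WLU).

#' Maximum-intensity projection of a z-stack
#'
#' @param zstack 3D array (rows, cols, planes) or list of matrices.
#' @return matrix of per-pixel maxima.
#' @export
max_project <- function(zstack) {
  planes <- if (is.array(zstack) && length(dim(zstack)) == 3)
    lapply(seq_len(dim(zstack)[3]), function(k) zstack[, , k]) else zstack
  if (!length(planes)) stop("need at least one plane")
  d1 <- dim(planes[[1]])
  for (p in planes) if (!identical(dim(p), d1)) stop("mismatched plane shapes")
  Reduce(pmax, planes)
}

#' Single-transcript intensity from the quantized spot-intensity
#' distribution
#'
#' Diffraction-limited smFISH spots contain one or a few transcripts, so
#' the spot-intensity distribution is quantized at multiples of the
#' single-transcript intensity. The unit is estimated as the location of
#' the first mode of a kernel density estimate of the intensities.
#'
#' @param spot_intensities numeric vector (n >= 20).
#' @param bw_frac kernel bandwidth as a fraction of the median intensity.
#' @return single-transcript intensity (a.u.).
#' @export
single_transcript_intensity <- function(spot_intensities, bw_frac = 0.1) {
  x <- spot_intensities
  if (length(x) < 20) stop("need >= 20 spots")
  if (any(x <= 0)) stop("intensities must be > 0")
  d <- density(x, bw = bw_frac * median(x), from = 0, n = 1024)
  y <- d$y
  # first interior local maximum
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  peaks <- peaks[y[peaks] > 0.05 * max(y)]
  if (!length(peaks) || (max(y) - min(y)) < 1e-3 * max(y))
    stop("no clear mode in the spot-intensity distribution")
  d$x[peaks[1]]
}

#' Transcripts per cell from spot intensities
#'
#' Per cell, the transcript count is the rounded ratio of total spot
#' intensity to the single-transcript unit; the per-spot molecule counts
#' (rounded, at least 1) are reported too. Spots carrying a `cell_id` are
#' used directly; otherwise positions are looked up in the labeled mask,
#' and spots outside all cells are dropped and counted.
#'
#' @param spots data.frame with `intensity` and either `cell_id` or
#'   `x_px`/`y_px`.
#' @param cell_masks labeled matrix (0 = background), required when spots
#'   carry no `cell_id`.
#' @param unit single-transcript intensity from
#'   [single_transcript_intensity()].
#' @param n_cells total number of cells (cells without spots count 0);
#'   inferred from the mask when given.
#' @return list with `counts` (data.frame `cell_id`, `n_transcripts`,
#'   `fractional`), `per_spot` (input plus `n_molecules`), `n_dropped`.
#' @export
transcripts_per_cell <- function(spots, cell_masks = NULL, unit, n_cells = NULL) {
  if (unit <= 0) stop("unit must be > 0")
  sp <- as.data.frame(spots)
  n_dropped <- 0L
  if (!("cell_id" %in% names(sp))) {
    if (is.null(cell_masks)) stop("need cell_masks when spots lack cell_id")
    i <- floor(sp$y_px) + 1; j <- floor(sp$x_px) + 1
    ok <- i >= 1 & i <= nrow(cell_masks) & j >= 1 & j <= ncol(cell_masks)
    sp$cell_id <- NA_integer_
    sp$cell_id[ok] <- cell_masks[cbind(i[ok], j[ok])]
    drop <- is.na(sp$cell_id) | sp$cell_id == 0
    n_dropped <- sum(drop)
    sp <- sp[!drop, , drop = FALSE]
  }
  if (is.null(n_cells))
    n_cells <- if (!is.null(cell_masks)) max(cell_masks) else max(sp$cell_id, 0)
  sp$n_molecules <- pmax(1L, as.integer(round(sp$intensity / unit)))
  tot <- tapply(sp$intensity, factor(sp$cell_id, levels = seq_len(n_cells)), sum)
  tot[is.na(tot)] <- 0
  counts <- data.frame(cell_id = seq_len(n_cells),
                       fractional = as.numeric(tot) / unit)
  counts$n_transcripts <- as.integer(round(counts$fractional))
  list(counts = counts, per_spot = sp, n_dropped = n_dropped)
}

#' Expression level in wild-type lambda units
#'
#' Mean transcripts per cell of a strain divided by the reference
#' (wild-type) strain's mean, with a bootstrap sem resampling cells of
#' both strains.
#'
#' @param strain_counts,reference_counts per-cell transcript counts.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return object of class `expression_level`: list with `mean_per_cell`,
#'   `wlu`, `sem`, `n_cells`.
#' @export
expression_wlu <- function(strain_counts, reference_counts, n_boot = 1000,
                           seed = NULL) {
  if (!length(strain_counts) || !length(reference_counts)) stop("empty inputs")
  if (mean(reference_counts) <= 0) stop("reference mean must be > 0")
  wlu <- mean(strain_counts) / mean(reference_counts)
  sem <- with_seed(seed, {
    ratios <- vapply(seq_len(n_boot), function(b) {
      s <- sample(strain_counts, replace = TRUE)
      r <- sample(reference_counts, replace = TRUE)
      if (mean(r) <= 0) return(NA_real_)
      mean(s) / mean(r)
    }, numeric(1))
    sd(ratios, na.rm = TRUE)
  })
  structure(list(mean_per_cell = mean(strain_counts), wlu = wlu, sem = sem,
                 n_cells = length(strain_counts)), class = "expression_level")
}
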
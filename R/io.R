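# File interchange: 16-bit TIFF stacks, localization/displacement CSVs,
# transforms as JSON.

#' Write an image stack as a 16-bit TIFF
#'
#' @param stack 3D array (rows, cols, frames) or matrix; values are photon
#'   counts, clipped to \[0, 65535\].
#' @param path output file.
#' @export
write_stack_tiff <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1))
  frames <- lapply(seq_len(dim(stack)[3]), function(k) {
    m <- pmin(pmax(stack[, , k], 0), 65535)
    m / 65535  # tiff stores [0,1] scaled to the sample depth
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Read a TIFF stack written by [write_stack_tiff()]
#'
#' @param path TIFF file.
#' @return 3D array of photon counts.
#' @export
read_stack_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  arr <- array(0, c(dim(frames[[1]])[1:2], length(frames)))
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    if (length(dim(f)) == 3) f <- f[, , 1]
    arr[, , k] <- f * 65535
  }
  arr
}

#' Serialize a projective transform to JSON
#'
#' Row-major 3x3 matrix plus the registration error.
#' @param transform a `projective_transform`.
#' @param path output file.
#' @export
write_transform_json <- function(transform, path) {
  jsonlite::write_json(
    list(matrix = as.vector(t(transform$matrix)),
         registration_error = transform$registration_error,
         n_points = transform$n_points),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a projective transform from JSON
#' @param path JSON file written by [write_transform_json()].
#' @return `projective_transform`.
#' @export
read_transform_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(matrix = matrix(x$matrix, 3, 3, byrow = TRUE),
                 registration_error = x$registration_error,
                 n_points = x$n_points),
            class = "projective_transform")
}

#' Write a truth or localization table as CSV at full precision
#'
#' Numeric columns are rendered with 17 significant digits so that doubles
#' survive a write/read cycle bit-exactly.
#'
#' @param df data.frame.
#' @param path output file.
#' @export
write_table_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a table written by [write_table_csv()]
#' @param path CSV file.
#' @param double_cols columns to parse as doubles (default: all that look
#'   numeric).
#' @return data.frame.
#' @export
read_table_csv <- function(path, double_cols = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  cols <- if (is.null(double_cols)) names(df)[vapply(df, is.numeric, logical(1))]
          else double_cols
  for (j in cols) df[[j]] <- as.double(df[[j]])
  df
}

#' Write a density estimate as CSV
#' @param d a [density_estimate()].
#' @param path output file.
#' @export
write_density_csv <- function(d, path) {
  write.csv(data.frame(bin_center_nm = d$bin_centers, value = d$values,
                       sem = d$sem), path, row.names = FALSE)
  invisible(path)
}
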
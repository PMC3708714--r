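#' Projective transform between two camera channels
#'
#' Least-squares projective (homography) fit from control-point pairs,
#' mapping source-channel coordinates into target-channel coordinates. The
#' direct linear transform solution (with Hartley normalization) is refined
#' by minimizing the geometric transfer error when more than four pairs are
#' available. Fiducials from a tandem two-color fusion protein, imaged in
#' both channels, provide the control points in practice.
#'
#' @param control_points data.frame with columns `x_src`, `y_src`, `x_dst`,
#'   `y_dst` (same length units throughout, nm recommended).
#' @return object of class `projective_transform`: list with `matrix` (3x3,
#'   scaled so `[3,3] = 1`), `registration_error` (RMS residual in input
#'   units), `n_points`.
#' @export
build_transform <- function(control_points) {
  cp <- as.data.frame(control_points)
  need <- c("x_src", "y_src", "x_dst", "y_dst")
  if (!all(need %in% names(cp))) stop("control_points need columns ", paste(need, collapse = ", "))
  n <- nrow(cp)
  if (n < 4) stop("projective map underdetermined: need >= 4 control points")
  src <- cbind(cp$x_src, cp$y_src); dst <- cbind(cp$x_dst, cp$y_dst)
  norm2d <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
    s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
    T <- rbind(c(s, 0, -s * ctr[1]), c(0, s, -s * ctr[2]), c(0, 0, 1))
    list(T = T, p = t(T %*% rbind(t(p), 1))[, 1:2, drop = FALSE])
  }
  ns <- norm2d(src); nd <- norm2d(dst)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- ns$p[i, 1]; y <- ns$p[i, 2]; u <- nd$p[i, 1]; v <- nd$p[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ]     <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  sv <- svd(A, nu = 0, nv = 9)
  if (sv$d[8] < 1e-10 * sv$d[1])
    stop("degenerate control-point configuration (collinear or coincident points)")
  H <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  H <- solve(nd$T) %*% H %*% ns$T
  H <- H / H[3, 3]
  rms_of <- function(Hm) {
    pred <- apply_homography(Hm, src)
    sqrt(mean(rowSums((pred - dst)^2)))
  }
  if (n > 4) {
    obj <- function(par) {
      Hm <- matrix(c(par, 1), 3, 3, byrow = TRUE)
      pr <- apply_homography(Hm, src)
      sum((pr - dst)^2)
    }
    op <- optim(as.vector(t(H))[1:8], obj, method = "BFGS",
                control = list(maxit = 500, reltol = 1e-14))
    H2 <- matrix(c(op$par, 1), 3, 3, byrow = TRUE)
    if (rms_of(H2) < rms_of(H)) H <- H2  # keep DLT when already optimal
  }
  rms <- rms_of(H)
  structure(list(matrix = H, registration_error = rms, n_points = n),
            class = "projective_transform")
}

apply_homography <- function(H, pts) {
  ph <- H %*% rbind(t(pts), 1)
  w <- ph[3, ]
  if (any(abs(w) < 1e-12)) stop("point maps to infinity under the transform")
  cbind(ph[1, ] / w, ph[2, ] / w)
}

#' Apply a projective transform to points
#'
#' @param transform a [build_transform()] result (or 3x3 matrix).
#' @param points matrix or data.frame with two columns (x, y).
#' @return matrix with mapped x, y columns.
#' @export
map_coordinates <- function(transform, points) {
  H <- if (inherits(transform, "projective_transform")) transform$matrix else transform
  if (!is.matrix(H) || any(dim(H) != c(3, 3))) stop("invalid transform")
  if (abs(det(H)) < 1e-15) stop("transform matrix is singular")
  p <- as.matrix(as.data.frame(points)[, 1:2])
  out <- apply_homography(H, p)
  colnames(out) <- c("x", "y")
  out
}

#' Invert a projective transform
#' @param transform a `projective_transform` or 3x3 matrix.
#' @return `projective_transform` with the inverse matrix.
#' @export
invert_transform <- function(transform) {
  H <- if (inherits(transform, "projective_transform")) transform$matrix else transform
  Hi <- solve(H); Hi <- Hi / Hi[3, 3]
  structure(list(matrix = Hi,
                 registration_error = if (inherits(transform, "projective_transform"))
                   transform$registration_error else NA_real_,
                 n_points = NA_integer_),
            class = "projective_transform")
}

#' Pair spots across channels and compute displacement vectors
#'
#' Maps yellow-channel localizations into red-channel coordinates, pairs
#' spots per frame by nearest neighbour, rejects pairs separated by more
#' than the gate (200 nm by default; in the original experiment about 1% of
#' data fell beyond it), and returns red-minus-yellow displacement vectors
#' in nm. Each spot's localization error and the registration error are
#' combined in quadrature into `combined_error`.
#'
#' @param red_spots,yellow_spots data.frames with columns `frame`, `x_nm`,
#'   `y_nm` and optionally `loc_error_nm`, `molecule_id`.
#' @param transform `projective_transform` mapping yellow into red
#'   coordinates (identity if `NULL`).
#' @param gate maximum accepted separation in nm (default 200).
#' @param frame_interval seconds per frame, used for the `time` column.
#' @return data.frame of class `displacement_set` with columns
#'   `molecule_id`, `frame`, `time`, `dx`, `dy`, `r`, `combined_error`;
#'   attributes `n_rejected` (pairs beyond the gate) and `n_ambiguous`
#'   (frames where a red spot had two mapped candidates inside the gate).
#' @export
pair_and_displace <- function(red_spots, yellow_spots, transform = NULL,
                              gate = 200, frame_interval = 0.1) {
  red <- as.data.frame(red_spots); yel <- as.data.frame(yellow_spots)
  for (d in list(red, yel))
    if (!all(c("frame", "x_nm", "y_nm") %in% names(d)))
      stop("spot tables need columns frame, x_nm, y_nm")
  reg_err <- 0
  if (!is.null(transform)) {
    mapped <- map_coordinates(transform, yel[, c("x_nm", "y_nm")])
    yel$x_nm <- mapped[, 1]; yel$y_nm <- mapped[, 2]
    if (inherits(transform, "projective_transform") &&
        is.finite(transform$registration_error))
      reg_err <- transform$registration_error
  }
  out <- list(); n_rej <- 0L; n_amb <- 0L
  for (fr in sort(unique(red$frame))) {
    r <- red[red$frame == fr, , drop = FALSE]
    y <- yel[yel$frame == fr, , drop = FALSE]
    if (nrow(y) == 0) next
    used <- rep(FALSE, nrow(y))
    for (i in seq_len(nrow(r))) {
      d2 <- (y$x_nm - r$x_nm[i])^2 + (y$y_nm - r$y_nm[i])^2
      d2[used] <- Inf
      j <- which.min(d2)
      if (!is.finite(d2[j])) next
      rr <- sqrt(d2[j])
      if (rr > gate) { n_rej <- n_rej + 1L; next }
      if (sum(sqrt(d2) <= gate, na.rm = TRUE) > 1) n_amb <- n_amb + 1L
      used[j] <- TRUE
      le_r <- if ("loc_error_nm" %in% names(r)) r$loc_error_nm[i] else 0
      le_y <- if ("loc_error_nm" %in% names(y)) y$loc_error_nm[j] else 0
      out[[length(out) + 1]] <- data.frame(
        molecule_id = if ("molecule_id" %in% names(r)) r$molecule_id[i] else NA,
        frame = fr, time = fr * frame_interval,
        dx = r$x_nm[i] - y$x_nm[j], dy = r$y_nm[i] - y$y_nm[j],
        combined_error = sqrt(le_r^2 + le_y^2 + reg_err^2))
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(molecule_id = numeric(0), frame = numeric(0), time = numeric(0),
               dx = numeric(0), dy = numeric(0), combined_error = numeric(0))
  res$r <- sqrt(res$dx^2 + res$dy^2)
  attr(res, "n_rejected") <- n_rej
  attr(res, "n_ambiguous") <- n_amb
  class(res) <- c("displacement_set", "data.frame")
  res
}

#' Link localizations across frames into molecules
#'
#' Greedy nearest-neighbour linking on the red channel: a spot is assigned
#' to an existing molecule when it falls within `link_radius_nm` of that
#' molecule's last position in the previous frame, otherwise it starts a
#' new molecule. A 3-pixel (243 nm) radius is the default gate.
#'
#' @param spots data.frame with `frame`, `x_nm`, `y_nm`.
#' @param link_radius_nm linking gate in nm.
#' @return the input with a `molecule_id` column added.
#' @export
track_molecules <- function(spots, link_radius_nm = 3 * 81) {
  s <- as.data.frame(spots)
  s <- s[order(s$frame), , drop = FALSE]
  s$molecule_id <- NA_integer_
  last <- data.frame(id = integer(0), x = numeric(0), y = numeric(0), frame = numeric(0))
  next_id <- 1L
  for (fr in sort(unique(s$frame))) {
    idx <- which(s$frame == fr)
    prev <- last[last$frame == fr - 1, , drop = FALSE]
    taken <- rep(FALSE, nrow(prev))
    for (i in idx) {
      if (nrow(prev)) {
        d2 <- (prev$x - s$x_nm[i])^2 + (prev$y - s$y_nm[i])^2
        d2[taken] <- Inf
        j <- which.min(d2)
        if (length(j) && is.finite(d2[j]) && d2[j] <= link_radius_nm^2) {
          s$molecule_id[i] <- prev$id[j]; taken[j] <- TRUE
          next
        }
      }
      s$molecule_id[i] <- next_id; next_id <- next_id + 1L
    }
    last <- rbind(last[last$frame == fr, , drop = FALSE],
                  data.frame(id = s$molecule_id[idx], x = s$x_nm[idx],
                             y = s$y_nm[idx], frame = fr))
    last <- last[last$frame >= fr - 1, , drop = FALSE]
  }
  s
}
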
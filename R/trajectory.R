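#' Construct a trajectory
#'
#' Time-ordered periodic coordinates for a fixed bead roster. Coordinates are
#' stored wrapped into the box; analyses use minimum-image distances.
#'
#' @param times numeric vector of frame times (ns), strictly increasing.
#' @param coords array \code{n_beads x 3 x n_frames} (nm).
#' @param box either a length-3 vector (constant box) or an
#'   \code{n_frames x 3} matrix (nm).
#' @return object of class \code{membrane_trajectory} with fields
#'   \code{times}, \code{coords}, \code{box} and \code{interval} (the nominal
#'   sampling interval in ns; \code{NA} for a single frame, with a flag
#'   \code{uniform} saying whether spacing is uniform).
#' @export
membrane_trajectory <- function(times, coords, box) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE))
    stop("frame times must be strictly increasing")
  coords <- as.array(coords)
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    stop("coords must be an n_beads x 3 x n_frames array")
  if (dim(coords)[3] != length(times))
    stop("number of frames in coords does not match times")
  if (is.matrix(box)) {
    if (nrow(box) != length(times) || ncol(box) != 3L)
      stop("box matrix must be n_frames x 3")
  } else {
    box <- matrix(as.numeric(box), nrow = length(times), ncol = 3L,
                  byrow = TRUE)
  }
  dt <- diff(times)
  uniform <- length(dt) > 0 && diff(range(dt)) <= 1e-9 * max(dt, 1e-12)
  interval <- if (length(dt)) stats::median(dt) else NA_real_
  structure(list(times = times, coords = coords, box = box,
                 interval = interval, uniform = uniform),
            class = "membrane_trajectory")
}

#' @export
print.membrane_trajectory <- function(x, ...) {
  cat("membrane_trajectory:", n_frames(x), "frames,", dim(x$coords)[1],
      "beads, t =", signif(min(x$times), 4), "..", signif(max(x$times), 4),
      "ns (interval", signif(x$interval, 4), "ns)\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a \code{membrane_trajectory}.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$times)

#' Extract one frame
#' @param traj a \code{membrane_trajectory}.
#' @param i frame index.
#' @return list with \code{time}, \code{positions} (n_beads x 3), \code{box}.
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  list(time = traj$times[i], positions = traj$coords[, , i, drop = TRUE],
       box = traj$box[i, ])
}

#' Resample a trajectory to a fixed interval by nearest-frame selection
#'
#' Frames are picked at the requested spacing by nearest time; no
#' interpolation and no smoothing is ever applied (fast binding/unbinding
#' events must survive resampling untouched).
#'
#' @param traj a \code{membrane_trajectory}.
#' @param interval target sampling interval in ns.
#' @return a \code{membrane_trajectory}.
#' @export
resample_trajectory <- function(traj, interval) {
  if (is.na(traj$interval) || n_frames(traj) < 2L) return(traj)
  if (abs(traj$interval - interval) < 1e-9 && traj$uniform) return(traj)
  targets <- seq(traj$times[1], traj$times[n_frames(traj)], by = interval)
  idx <- unique(vapply(targets, function(t0) which.min(abs(traj$times - t0)),
                       integer(1)))
  membrane_trajectory(traj$times[idx], traj$coords[, , idx, drop = FALSE],
                      traj$box[idx, , drop = FALSE])
}

# Coordinates of a bead subset in one frame, always as an n x 3 matrix.
frame_coords <- function(traj, idx, f) {
  matrix(traj$coords[idx, , f], ncol = 3L)
}

# Minimum-image displacement of b relative to a (both n x k matrices or
# vectors), per-axis box lengths in box. Works on any subset of axes.
min_image <- function(d, box) {
  for (k in seq_along(box)) {
    dk <- d[, k] - box[k] * round(d[, k] / box[k])
    d[, k] <- dk
  }
  d
}

# Minimum-image distances between one point (length-3) and a matrix of points.
min_image_dist <- function(p, pts, box) {
  d <- sweep(pts, 2L, p)
  d <- min_image(d, box)
  sqrt(rowSums(d * d))
}

# Pairwise min-image distance matrix between two coordinate sets (na x 3,
# nb x 3). Small sets only (anchors, protein beads).
min_image_cross_dist <- function(a, b, box) {
  out <- matrix(0, nrow(a), nrow(b))
  for (i in seq_len(nrow(a)))
    out[i, ] <- min_image_dist(a[i, ], b, box)
  out
}
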
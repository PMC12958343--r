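#' Inter-body orientation angle
#'
#' Angle between the two bodies' reference vectors, each defined by the same
#' residue pair within its body (default residues 30 and 210, the Arg30 ->
#' Asp210 axis). For pseudo-atom topologies the residue bead stands in for the
#' backbone carbon. Intra-body vectors need no periodic correction because
#' bodies are stored unwrapped.
#'
#' @param traj a [trajectory()] with 2 bodies
#' @param frame 1-based frame index
#' @param topology per-body [fab_topology()]
#' @param vector_def length-2 residue index pair defining the vector
#' @return angle in degrees, in `[0, 180]`
#' @export
orientation_angle <- function(traj, frame, topology = fab_topology(),
                              vector_def = c(30L, 210L)) {
  stopifnot(traj$n_bodies == 2L, length(vector_def) == 2L)
  v <- lapply(1:2, function(b) {
    xyz <- body_coords(traj, frame, b, topology)
    i <- match(vector_def, topology$atoms$residue)
    if (any(is.na(i))) stop("vector residues absent from topology")
    xyz[i[2], ] - xyz[i[1], ]
  })
  n1 <- sqrt(sum(v[[1]]^2)); n2 <- sqrt(sum(v[[2]]^2))
  if (n1 < 1e-12 || n2 < 1e-12) stop("zero-length reference vector")
  cosang <- sum(v[[1]] * v[[2]]) / (n1 * n2)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Inter-body distance between representative residues
#'
#' Minimum-image distance between the representative atom (default residue
#' 163, the central valine) of each body under the cubic period.
#'
#' @inheritParams orientation_angle
#' @param repr_residue representative residue index (default 163)
#' @return distance in Angstrom
#' @export
inter_body_distance <- function(traj, frame, topology = fab_topology(),
                                repr_residue = 163L) {
  stopifnot(traj$n_bodies == 2L)
  L <- traj$box[frame]
  if (!is.finite(L) || L <= 0) stop("missing box edge for frame ", frame)
  i <- match(repr_residue, topology$atoms$residue)
  if (is.na(i)) stop("representative residue absent from topology")
  a <- body_coords(traj, frame, 1L, topology)[i, ]
  b <- body_coords(traj, frame, 2L, topology)[i, ]
  min_image_dist(a, b, L)
}

#' Pose series: distances, angles, and binned angle distributions
#'
#' Computes the representative inter-body distance and orientation angle for
#' every frame, then bins the distances into `n_bins` equal-width groups over
#' the observed range (last bin closed on the right) and tabulates the angle
#' distribution within each distance bin.
#'
#' @inheritParams orientation_angle
#' @param n_bins number of distance bins (default 25)
#' @param angle_breaks breaks for the per-bin angle histograms (default every
#'   10 degrees over 0..180)
#' @param repr_residue representative residue for distances (default 163)
#' @return list of class `pose_series`: `frames` (data.frame frame, d, theta),
#'   `breaks` (distance bin edges), `bin_counts`, and `angle_hist` (matrix
#'   n_bins x angle classes, rows normalised to 1 where occupied)
#' @export
bin_pose_series <- function(traj, topology = fab_topology(), n_bins = 25L,
                            angle_breaks = seq(0, 180, by = 10),
                            repr_residue = 163L,
                            vector_def = c(30L, 210L)) {
  nf <- n_frames(traj)
  if (nf < 1L) stop("need at least one frame")
  d <- vapply(seq_len(nf), function(f)
    inter_body_distance(traj, f, topology, repr_residue), 0)
  th <- vapply(seq_len(nf), function(f)
    orientation_angle(traj, f, topology, vector_def), 0)
  rng <- range(d)
  if (diff(rng) < 1e-12) {
    warning("all distances identical; single occupied bin")
    breaks <- rng[1] + c(-0.5, 0.5)
    bin <- rep(1L, nf)
    n_bins <- 1L
  } else {
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    bin <- findInterval(d, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  }
  bin_counts <- tabulate(bin, nbins = n_bins)
  ah <- matrix(0, n_bins, length(angle_breaks) - 1L)
  colnames(ah) <- paste0("[", head(angle_breaks, -1), ",", angle_breaks[-1], ")")
  for (bb in seq_len(n_bins)) {
    sel <- th[bin == bb]
    if (length(sel)) {
      h <- hist(sel, breaks = angle_breaks, plot = FALSE,
                right = FALSE, include.lowest = TRUE)$counts
      ah[bb, ] <- h / length(sel)
    }
  }
  structure(list(frames = data.frame(frame = seq_len(nf), d = d, theta = th),
                 breaks = breaks, bin_counts = bin_counts, angle_hist = ah),
            class = "pose_series")
}

#' @export
print.pose_series <- function(x, ...) {
  cat("Pose series: ", nrow(x$frames), " frames, ",
      length(x$bin_counts), " distance bins over [",
      round(min(x$breaks), 1), ", ", round(max(x$breaks), 1), "] A\n", sep = "")
  invisible(x)
}
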
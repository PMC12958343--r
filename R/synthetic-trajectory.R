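#' Configuration for the synthetic two-body trajectory generator
#'
#' The generator emulates what two-Fab simulations show at desk scale: two
#' rigid ~442-residue bodies (one pseudo-atom per residue on a compact lattice
#' blob of ~25 Angstrom radius) diffuse in a periodic cubic box; "sticky"
#' residue patches planted on each body form persistent interfaces whose dwell
#' time is tuned by a Metropolis-style acceptance bias, mimicking the several-ns
#' contact events seen in real trajectories.
#'
#' @param n_residues_per_body residues per body (default 442)
#' @param box_edge cubic box edge in Angstrom (default 147, i.e. the 3174.43
#'   nm^3 cube used as a scale reference)
#' @param n_frames number of frames
#' @param frame_interval_ps dt in ps (default 10)
#' @param seed RNG seed
#' @param translation_step translation proposal sd in Angstrom (default 2)
#' @param rotation_step_deg rotation proposal sd in degrees (default 5)
#' @param interfaces list of planted interfaces; each a list with `a` and `b`
#'   (residue index vectors on body A / body B), optional `dwell` (target dwell
#'   in frames, default 500) and `strength` (bias; default `log(dwell)`;
#'   0 disables binding entirely)
#' @param contact_cutoff contact cutoff in Angstrom (default 6)
#' @param p_dock per-frame probability that an unbound body attempts to dock at
#'   a planted interface; the attempt succeeds with probability
#'   `1 - exp(-strength)` (exactly 0 at strength 0, so a strength-0 run is a
#'   pure unbiased random walk). Default 0.02.
#' @param spacing lattice constant of the body blob in Angstrom (default 5)
#' @param bump outward protrusion of planted patches in Angstrom (default 8);
#'   makes the sticky patch the only part of the surface that can reach the
#'   contact cutoff when docked, so planted residues dominate the frequency
#'   profile as persistent interfaces do in real trajectories
#' @param jitter_sd per-residue isotropic Gaussian jitter sd applied to the
#'   recorded coordinates (default 0; used by descriptor tests needing
#'   fluctuation)
#' @param hardcore minimum allowed inter-body atom distance (default 2)
#' @return list of class `synth_trajectory_config`
#' @export
synth_trajectory_config <- function(n_residues_per_body = 442L,
                                    box_edge = 147,
                                    n_frames = 2000L,
                                    frame_interval_ps = 10,
                                    seed = 1L,
                                    translation_step = 2,
                                    rotation_step_deg = 5,
                                    interfaces = list(
                                      list(a = 348:352, b = 348:352, dwell = 500),
                                      list(a = 26:28, b = 26:28, dwell = 500)
                                    ),
                                    contact_cutoff = 6,
                                    p_dock = 0.02,
                                    spacing = 5,
                                    bump = 8,
                                    jitter_sd = 0,
                                    hardcore = 2) {
  stopifnot(translation_step > 0, rotation_step_deg > 0, box_edge > 0,
            n_frames >= 0, contact_cutoff > 0, spacing > 0)
  n <- as.integer(n_residues_per_body)
  interfaces <- lapply(interfaces, function(f) {
    f$a <- as.integer(f$a); f$b <- as.integer(f$b)
    if (any(c(f$a, f$b) < 1L) || any(c(f$a, f$b) > n))
      stop("planted interface range outside 1..", n)
    if (is.null(f$dwell)) f$dwell <- 500L
    if (f$dwell > max(n_frames, 1L)) stop("dwell frames exceed n_frames")
    if (is.null(f$strength)) f$strength <- log(max(f$dwell, 1L))
    f
  })
  structure(list(n_residues_per_body = n, box_edge = box_edge,
                 n_frames = as.integer(n_frames),
                 frame_interval_ps = frame_interval_ps, seed = as.integer(seed),
                 translation_step = translation_step,
                 rotation_step_deg = rotation_step_deg,
                 interfaces = interfaces, contact_cutoff = contact_cutoff,
                 p_dock = p_dock, spacing = spacing, bump = bump,
                 jitter_sd = jitter_sd, hardcore = hardcore),
            class = "synth_trajectory_config")
}

# Compact lattice blob: the n points of an integer lattice closest to the
# origin, scaled by `spacing` and centred. Deterministic.
lattice_blob <- function(n, spacing) {
  r <- 2L
  repeat {
    g <- as.matrix(expand.grid(x = -r:r, y = -r:r, z = -r:r))
    if (nrow(g) >= n) {
      d2 <- rowSums(g^2)
      ord <- order(d2, g[, 1], g[, 2], g[, 3])
      if (sum(d2 <= (r - 1)^2) >= n || nrow(g) > 8 * n) {
        pts <- g[ord[seq_len(n)], , drop = FALSE] * spacing
        pts <- sweep(pts, 2, colMeans(pts))
        dimnames(pts) <- NULL
        return(pts)
      }
    }
    r <- r + 1L
  }
}

# Assign planted residue ranges to surface caps of the blob: for each distinct
# planted range, the |range| still-unassigned points with the largest
# projection onto that range's direction. Returns the residue->point map.
assign_patches <- function(points, ranges, directions) {
  n <- nrow(points)
  pt_of_res <- integer(n)
  taken_pt <- logical(n)
  taken_res <- logical(n)
  for (m in seq_along(ranges)) {
    rr <- ranges[[m]]
    if (any(taken_res[rr])) next  # range shared between interfaces: keep first
    proj <- points %*% directions[[m]]
    ord <- order(-proj)
    free_pts <- ord[!taken_pt[ord]][seq_along(rr)]
    pt_of_res[rr] <- free_pts
    taken_pt[free_pts] <- TRUE
    taken_res[rr] <- TRUE
  }
  pt_of_res[!taken_res] <- which(!taken_pt)
  pt_of_res
}

rot_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s <- sin(angle); C <- 1 - c_
  x <- a[1]; y <- a[2]; z <- a[3]
  matrix(c(c_ + x * x * C, x * y * C - z * s, x * z * C + y * s,
           y * x * C + z * s, c_ + y * y * C, y * z * C - x * s,
           z * x * C - y * s, z * y * C + x * s, c_ + z * z * C),
         3, 3, byrow = TRUE)
}

# Rotation taking unit vector u onto unit vector v.
rot_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  ax <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(ax^2)); d <- sum(u * v)
  if (s < 1e-12) {
    if (d > 0) return(diag(3))
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * u) * u
    return(rot_axis(ax, pi))
  }
  rot_axis(ax, atan2(s, d))
}

random_rotation <- function() {
  ax <- rnorm(3)
  rot_axis(ax, runif(1, 0, 2 * pi))
}

#' Generate a synthetic two-body trajectory with planted interfaces
#'
#' Body A sits fixed at the box centre; body B performs a rigid-body random
#' walk (Gaussian translation steps, random-axis rotation steps) under periodic
#' wrap. When a planted interface pair is in contact (any planted A-residue
#' within `contact_cutoff` of a planted B-residue), proposals that would break
#' the contact are accepted only with probability `exp(-strength)`, producing
#' dwell times on the scale of the configured `dwell`. While unbound, a docking
#' attempt is made with per-frame probability `p_dock` and succeeds with
#' probability `1 - exp(-strength)`; at strength 0 the walk is exactly
#' unbiased. Hard-core overlaps (any inter-body distance < `hardcore`) are
#' always rejected.
#'
#' @param config a [synth_trajectory_config()]
#' @param topology optional [fab_topology()] consistent with
#'   `n_residues_per_body` (default built automatically)
#' @return list with elements `trajectory` (a [trajectory()]), `topology`, and
#'   `ground_truth`: list with per-frame `state` (0 = unbound, m = planted
#'   interface m in contact) and the planted `interfaces`
#' @export
generate_two_body_trajectory <- function(config = synth_trajectory_config(),
                                         topology = NULL) {
  stopifnot(inherits(config, "synth_trajectory_config"))
  n <- config$n_residues_per_body
  L <- config$box_edge
  if (is.null(topology)) {
    half <- n %/% 2L
    topology <- fab_topology(light_len = half, heavy_len = n - half)
  }
  if (topology$n_res != n) stop("topology residue count != n_residues_per_body")
  set.seed(config$seed)

  pts <- lattice_blob(n, config$spacing)
  pts <- pts + matrix(runif(3 * n, -0.3, 0.3), n, 3)  # break lattice ties
  diam <- 2 * sqrt(max(rowSums(pts^2)))
  if (diam > L / 2)
    stop("body diameter ", round(diam, 1), " A exceeds L/2 = ", L / 2,
         " A: minimum image is ambiguous")

  ifs <- config$interfaces
  dirs <- list(c(1, 0, 0), c(0, 0, 1), c(0, 1, 0), c(-1, 0, 0),
               c(0, -1, 0), c(0, 0, -1))
  ranges <- list(); dd <- list()
  for (m in seq_along(ifs)) {
    d <- dirs[[(m - 1L) %% length(dirs) + 1L]]
    for (rr in list(ifs[[m]]$a, ifs[[m]]$b)) {
      seen <- any(vapply(ranges, identical, TRUE, y = rr))
      if (!seen) { ranges <- c(ranges, list(rr)); dd <- c(dd, list(d)) }
    }
  }
  pt_of_res <- assign_patches(pts, ranges, dd)
  base <- pts[pt_of_res, , drop = FALSE]  # residue r at base[r, ]; both bodies
  if (config$bump > 0) {
    # raise each planted patch onto a flat pad protruding `bump` above the
    # blob surface so every patch residue is equally exposed when docked
    for (m in seq_along(ranges)) {
      rr <- ranges[[m]]
      d <- unlist(dd[[m]])
      h0 <- max(pts %*% d)
      sub <- base[rr, , drop = FALSE]
      along <- drop(sub %*% d)
      lateral <- sub - outer(along, d)
      base[rr, ] <- 0.8 * lateral +
        outer(rep(h0 + config$bump, length(rr)), d)
    }
  }

  centerA <- rep(L / 2, 3)
  A <- sweep(base, 2, centerA, "+")

  gt_state <- integer(config$n_frames)
  coords <- vector("list", config$n_frames)
  if (config$n_frames == 0L) {
    return(list(
      trajectory = trajectory(list(), box = L,
                              frame_interval = config$frame_interval_ps,
                              n_bodies = 2L),
      topology = topology,
      ground_truth = list(state = integer(), interfaces = ifs)))
  }

  cutoff <- config$contact_cutoff
  planted_min <- function(Bxyz, m) {
    min_interbody_dist_cpp(A[ifs[[m]]$a, , drop = FALSE],
                           Bxyz[ifs[[m]]$b, , drop = FALSE], L)
  }
  bound_state <- function(Bxyz) {
    for (m in seq_along(ifs)) if (planted_min(Bxyz, m) < cutoff) return(m)
    0L
  }
  resmap <- seq_len(n)
  foreign_contact <- function(Bxyz, m) {
    M <- residue_contact_cpp(A, Bxyz, resmap, resmap, n, n, L, cutoff)
    any(M[-ifs[[m]]$a, ]) || any(M[ifs[[m]]$a, -ifs[[m]]$b])
  }
  make_B <- function(center, R) sweep(base %*% t(R), 2, center, "+")

  docked_pose <- function(m) {
    pA <- colMeans(base[ifs[[m]]$a, , drop = FALSE])
    pB <- colMeans(base[ifs[[m]]$b, , drop = FALSE])
    uA <- pA / sqrt(sum(pA^2))
    R <- rot_axis(uA, runif(1, 0, 2 * pi)) %*% rot_between(pB, -uA)
    center <- centerA + uA * (sqrt(sum(pA^2)) + sqrt(sum(pB^2)) + 4)
    B <- make_B(center, R)
    for (k in 1:60) {  # walk in until the planted pair touches, avoiding overlap
      pm <- planted_min(B, m)
      om <- min_interbody_dist_cpp(A, B, L)
      if (om < config$hardcore || foreign_contact(B, m)) {
        center <- center + 0.3 * uA; B <- make_B(center, R); next
      }
      if (pm < cutoff - 0.5) break
      center <- center - 0.3 * uA
      B <- make_B(center, R)
    }
    list(center = center, R = R, B = B)
  }

  # initial pose: uniform random, unbound, no overlap
  repeat {
    centerB <- runif(3, 0, L)
    Rb <- random_rotation()
    B <- make_B(centerB, Rb)
    if (min_interbody_dist_cpp(A, B, L) > cutoff) break
  }

  rot_sd <- config$rotation_step_deg * pi / 180
  state <- bound_state(B)
  hold <- FALSE  # Metropolis hold engaged while a planted episode lasts
  hold_left <- 0L  # frames remaining before the hold is released
  refractory <- FALSE  # after a release, no new hold until bodies separate
  next_if <- 1L
  for (f in seq_len(config$n_frames)) {
    if (state == 0L && length(ifs) > 0L && runif(1) < config$p_dock) {
      m <- next_if  # round-robin over planted interfaces: balanced sampling
      next_if <- next_if %% length(ifs) + 1L
      if (runif(1) < 1 - exp(-ifs[[m]]$strength)) {
        dp <- docked_pose(m)
        centerB <- dp$center; Rb <- dp$R; B <- dp$B
        state <- bound_state(B)
        hold <- state > 0L
        if (hold) hold_left <- ifs[[state]]$dwell
        refractory <- FALSE
      }
    } else {
      new_center <- (centerB + rnorm(3, sd = config$translation_step)) %% L
      new_R <- rot_axis(rnorm(3), rnorm(1, sd = rot_sd)) %*% Rb
      Bn <- make_B(new_center, new_R)
      accept <- min_interbody_dist_cpp(A, Bn, L) >= config$hardcore
      if (accept && state > 0L && hold) {
        if (planted_min(Bn, state) >= cutoff)
          accept <- runif(1) < exp(-ifs[[state]]$strength)
        else if (foreign_contact(Bn, state))
          accept <- FALSE  # keep the held episode on the planted interface
      }
      if (accept) {
        prev <- state
        centerB <- new_center; Rb <- new_R; B <- Bn
        state <- bound_state(B)
        if (prev == 0L && state > 0L) {
          hold <- ifs[[state]]$strength > 0 && !refractory
          if (hold) hold_left <- ifs[[state]]$dwell
        }
        if (state == 0L) hold <- FALSE
      }
    }
    # release clock: the hold lasts `dwell` frames, after which the episode
    # ends by ordinary diffusion (with a refractory gap before re-binding)
    if (state > 0L && hold) {
      hold_left <- hold_left - 1L
      if (hold_left <= 0L) {
        hold <- FALSE
        refractory <- TRUE
      }
    }
    if (refractory && state == 0L &&
        all(vapply(seq_along(ifs), function(m) planted_min(B, m), 0) >
            cutoff + 4))
      refractory <- FALSE
    gt_state[f] <- state
    fr <- rbind(A, B)
    if (config$jitter_sd > 0)
      fr <- fr + matrix(rnorm(length(fr), sd = config$jitter_sd), nrow(fr), 3)
    coords[[f]] <- fr
  }

  list(
    trajectory = trajectory(coords, box = L,
                            frame_interval = config$frame_interval_ps,
                            n_bodies = 2L),
    topology = topology,
    ground_truth = list(state = gt_state, interfaces = ifs,
                        body_template = base, centerA = centerA)
  )
}
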
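topo4 <- tiny_topology(4L)

# small trajectory with body B in two distinct poses (interfaces) plus noise
two_pose_traj <- function(n_per_pose = 10, noise = 0.1, seed = 21) {
  set.seed(seed)
  # body A must be non-collinear or the superposition has a free roll axis
  a <- twofab:::lattice_blob(4, 5) + 50
  poses <- list(c(18, 0, 0), c(0, 0, 18))
  frames_a <- list(); frames_b <- list(); truth <- integer()
  for (pose in 1:2) for (k in seq_len(n_per_pose)) {
    frames_a <- c(frames_a, list(a + matrix(rnorm(12, sd = noise), 4, 3)))
    b <- sweep(a, 2, poses[[pose]], "+")
    frames_b <- c(frames_b, list(b + matrix(rnorm(12, sd = noise), 4, 3)))
    truth <- c(truth, pose)
  }
  list(traj = two_body_traj(frames_a, frames_b, L = 200), truth = truth)
}

test_that("PCA eigenvalues satisfy the variance identities", {
  # identical frames: all eigenvalues zero
  a <- line_body(4); b <- line_body(4, origin = c(30, 0, 0))
  same <- two_body_traj(rep(list(a), 5), rep(list(b), 5), L = 200)
  pc0 <- fit_interface_pca(same, topo4, align = "none")
  expect_lt(max(pc0$eigenvalues), 1e-20)

  # variation along a single coordinate: rank 1
  frames_b <- lapply(1:6, function(k) { bb <- b; bb[1, 1] <- bb[1, 1] + k; bb })
  r1 <- two_body_traj(rep(list(a), 6), frames_b, L = 200)
  pc1 <- fit_interface_pca(r1, topo4, align = "none")
  expect_gt(pc1$eigenvalues[1], 0)
  expect_lt(pc1$eigenvalues[2] / pc1$eigenvalues[1], 1e-12)

  # trace identity: sum of eigenvalues equals total variance
  tp <- two_pose_traj()
  pc <- fit_interface_pca(tp$traj, topo4)
  expect_equal(sum(pc$eigenvalues), pc$total_variance,
               tolerance = 1e-10)
  expect_error(fit_interface_pca(same, topo4, frames = 1L), "at least 2")
})

test_that("full-rank inverse transform reproduces the centred coordinates", {
  tp <- two_pose_traj()
  pc <- fit_interface_pca(tp$traj, topo4)
  recon <- pc$scores %*% t(pc$rotation)
  X <- t(vapply(seq_len(n_frames(tp$traj)), function(f) {
    xyz <- tp$traj$coords[[f]]
    xyz <- kabsch(xyz[1:4, ], tp$traj$coords[[1]][1:4, ], apply_to = xyz)
    as.numeric(t(xyz))
  }, numeric(24)))
  centred <- sweep(X, 2, pc$mean)
  expect_lt(max(abs(recon - centred)) / max(abs(centred)), 1e-8)
})

test_that("component selection implements the cumulative-variance rule", {
  expect_equal(select_components(c(4, 3, 2, 1), 0.97), 4L)
  expect_equal(select_components(c(97, 3), 0.97), 1L)
  expect_equal(select_components(c(1, 1), 1.0), 2L)
  expect_warning(k0 <- select_components(c(0, 0)), "zero")
  expect_equal(k0, 0L)
})

test_that("Ward clustering recovers two planted poses and is deterministic", {
  tp <- two_pose_traj()
  pc <- fit_interface_pca(tp$traj, topo4)
  cl <- cluster_frames(pc, k = 2)
  # label accuracy up to permutation
  tab <- table(cl$labels, tp$truth)
  expect_equal(max(sum(diag(tab)), tab[1, 2] + tab[2, 1]) / sum(tab), 1)
  expect_equal(sum(cl$population), 1)
  # midpoint frames belong to their clusters
  for (cc in 1:2)
    expect_equal(cl$labels[match(cl$midpoint_frame[cc], cl$frames)], cc)
  # determinism
  cl2 <- cluster_frames(fit_interface_pca(tp$traj, topo4), k = 2)
  expect_identical(cl$labels, cl2$labels)
  # seeded k-means fallback separates the poses just as well
  km <- cluster_frames(pc, k = 2, method = "kmeans", seed = 4)
  tabk <- table(km$labels, tp$truth)
  expect_equal(max(sum(diag(tabk)), tabk[1, 2] + tabk[2, 1]) / sum(tabk), 1)
  expect_identical(km$labels,
                   cluster_frames(pc, k = 2, method = "kmeans", seed = 4)$labels)

  expect_equal(unique(cluster_frames(pc, k = 1)$labels), 1L)
  expect_equal(cluster_frames(pc, k = 1)$population, 1)
  expect_error(cluster_frames(pc, k = 50), "exceeds")
})

test_that("interface residues of a symmetric planted contact are identical per body", {
  topo <- tiny_topology(6L)
  a <- line_body(6, origin = c(20, 20, 20))
  b <- a; b[, 2] <- b[, 2] + 5  # every residue faces its own image
  traj <- two_body_traj(list(a), list(b), L = 100)
  ir <- interface_residues(traj, 1, topo)
  expect_identical(ir$body_a, ir$body_b)
  far <- two_body_traj(list(a), list(a + 50), L = 200)
  expect_warning(ir0 <- interface_residues(far, 1, topo), "no inter-body")
  expect_length(ir0$body_a, 0)
})

test_that("hotspot-group merging follows the 8 Angstrom COM rule and renormalises", {
  ref <- matrix(0, 40, 3)
  ref[, 1] <- seq_len(40)  # residue i at x = i
  regions <- region_set(c("a", "b", "c"), "hotspot",
                        start = c(1L, 6L, 30L), end = c(3L, 8L, 32L),
                        n_res = 40L)
  # COM a = 2, b = 7 (5 apart -> merge), c = 31 (far -> own group)
  hg <- merge_hotspot_groups(regions, c(40, 30, 30), ref, com_cutoff = 8)
  expect_equal(nrow(hg), 2L)
  expect_equal(sort(hg$occurrence_pct), c(30, 70))
  expect_equal(sum(hg$occurrence_pct), 100, tolerance = 1e-9)
  # 9 Angstrom apart stays separate
  regions2 <- region_set(c("a", "b"), "hotspot", start = c(1L, 10L),
                         end = c(1L, 10L), n_res = 40L)
  hg2 <- merge_hotspot_groups(regions2, c(40, 30), ref, com_cutoff = 8)
  expect_equal(nrow(hg2), 2L)
  hg3 <- merge_hotspot_groups(regions2, c(40, 30), ref, com_cutoff = 10)
  expect_equal(nrow(hg3), 1L)
  # normalisation: 40/30/30 -> 40%/30%/30%
  regions3 <- region_set(c("a", "b", "c"), "hotspot",
                         start = c(1L, 15L, 30L), end = c(1L, 15L, 30L),
                         n_res = 40L)
  hg4 <- merge_hotspot_groups(regions3, c(40, 30, 30), ref, com_cutoff = 5)
  expect_equal(hg4$occurrence_pct, c(40, 30, 30))
  # percentages always sum to 100 under random occurrences
  set.seed(11)
  for (rep in 1:10) {
    occ <- runif(3, 1, 100)
    hg5 <- merge_hotspot_groups(regions3, occ, ref, com_cutoff = 5)
    expect_equal(sum(hg5$occurrence_pct), 100, tolerance = 1e-9)
  }
})
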
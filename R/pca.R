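#' Kabsch superposition
#'
#' Least-squares optimal rigid superposition of `mobile` onto `fixed`
#' (rotation + translation, proper rotation enforced via the determinant
#' correction).
#'
#' @param mobile,fixed `n x 3` coordinate matrices with matched rows
#' @param apply_to optional matrix to which the fitted transform is applied
#'   (defaults to `mobile`)
#' @return transformed copy of `apply_to`; attributes `rotation` and
#'   `translation` carry the fit
#' @export
kabsch <- function(mobile, fixed, apply_to = mobile) {
  stopifnot(nrow(mobile) == nrow(fixed), nrow(mobile) >= 3L)
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  P <- sweep(mobile, 2, cm); Q <- sweep(fixed, 2, cf)
  H <- t(P) %*% Q
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  out <- sweep(sweep(apply_to, 2, cm) %*% t(R), 2, cf, "+")
  attr(out, "rotation") <- R
  attr(out, "translation") <- cf - cm
  out
}

#' PCA over contacting frames
#'
#' Flattens the coordinates of the selected frames into an
#' `n_frames x (3 * n_atoms)` matrix after rigidly superposing each frame on
#' body A of the first selected frame (so the retained variance encodes body
#' B's pose and the interface identity, not global diffusion), then
#' eigendecomposes the covariance.
#'
#' @param traj a [trajectory()]
#' @param topology per-body [fab_topology()]
#' @param frames frame indices to analyse (e.g. from [contact_frames()]);
#'   default all frames
#' @param align "bodyA" (default) or "none"
#' @return list of class `interface_pca`: `mean`, `eigenvalues` (descending),
#'   `rotation` (columns = eigenvectors), `scores` (per-frame projections),
#'   `frames`, `total_variance`
#' @export
fit_interface_pca <- function(traj, topology = fab_topology(),
                              frames = seq_len(n_frames(traj)),
                              align = c("bodyA", "none")) {
  align <- match.arg(align)
  if (length(frames) < 2L) stop("need at least 2 frames for PCA")
  na_body <- topology$n_atoms
  ref <- traj$coords[[frames[1]]]
  X <- matrix(NA_real_, length(frames), 3L * nrow(ref))
  for (k in seq_along(frames)) {
    xyz <- traj$coords[[frames[k]]]
    if (align == "bodyA" && traj$n_bodies == 2L) {
      xyz <- kabsch(mobile = xyz[seq_len(na_body), , drop = FALSE],
                    fixed = ref[seq_len(na_body), , drop = FALSE],
                    apply_to = xyz)
    }
    X[k, ] <- as.numeric(t(xyz))
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  lambda <- pc$sdev^2
  structure(list(mean = pc$center, eigenvalues = lambda,
                 rotation = pc$rotation, scores = pc$x, frames = frames,
                 total_variance = sum(apply(X, 2, stats::var))),
            class = "interface_pca")
}

#' @export
print.interface_pca <- function(x, ...) {
  k97 <- select_components(x$eigenvalues, 0.97)
  cat("Interface PCA: ", nrow(x$scores), " frames, ",
      length(x$eigenvalues), " components; ", k97,
      " cover 97% of variance\n", sep = "")
  invisible(x)
}

#' Number of components covering a variance fraction
#'
#' Smallest K whose leading eigenvalues cover at least `threshold` of the
#' total variance (default 97%).
#'
#' @param eigenvalues non-negative eigenvalues, descending
#' @param threshold variance fraction (default 0.97)
#' @return integer K (0 with a warning if all eigenvalues are zero)
#' @export
select_components <- function(eigenvalues, threshold = 0.97) {
  stopifnot(length(eigenvalues) > 0)
  tot <- sum(eigenvalues)
  if (tot <= 0) {
    warning("all eigenvalues are zero; K = 0")
    return(0L)
  }
  which(cumsum(eigenvalues) / tot >= threshold - 1e-12)[1]
}

#' Cluster contacting frames in PC space
#'
#' Ward hierarchical clustering (`ward.D2` on Euclidean distances) of the
#' frame projections in the retained principal components, cut at `k`
#' clusters; a seeded k-means fallback is available via `method = "kmeans"`.
#' The "midpoint" frame of a cluster is the member frame whose projection is
#' nearest the cluster centroid.
#'
#' @param pca an [fit_interface_pca()] result
#' @param k number of clusters (default 9)
#' @param n_components retained components; default the 97%-variance rule
#' @param method "ward" (default, deterministic) or "kmeans"
#' @param seed seed for the k-means fallback (default 1)
#' @return list of class `cluster_solution`: `labels` (per analysed frame),
#'   `frames`, `population` (fractions, by cluster id), `midpoint_frame`
#'   (trajectory frame indices, by cluster id), `k`
#' @export
cluster_frames <- function(pca, k = 9L,
                           n_components = select_components(pca$eigenvalues),
                           method = c("ward", "kmeans"), seed = 1L) {
  stopifnot(inherits(pca, "interface_pca"))
  method <- match.arg(method)
  n <- nrow(pca$scores)
  if (k > n) stop("k = ", k, " exceeds number of frames (", n, ")")
  K <- max(1L, min(n_components, ncol(pca$scores)))
  S <- pca$scores[, seq_len(K), drop = FALSE]
  labels <- if (k == 1L) rep(1L, n) else if (method == "kmeans") {
    set.seed(seed)
    as.integer(stats::kmeans(S, centers = k, nstart = 10)$cluster)
  } else
    stats::cutree(stats::hclust(stats::dist(S), method = "ward.D2"), k = k)
  pop <- as.numeric(table(factor(labels, levels = seq_len(k)))) / n
  mid <- integer(k)
  for (cc in seq_len(k)) {
    idx <- which(labels == cc)
    cen <- colMeans(S[idx, , drop = FALSE])
    d2 <- rowSums(sweep(S[idx, , drop = FALSE], 2, cen)^2)
    mid[cc] <- pca$frames[idx[which.min(d2)]]
  }
  structure(list(labels = labels, frames = pca$frames, population = pop,
                 midpoint_frame = mid, k = k, n_components = K),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("Cluster solution: k = ", x$k, " over ", length(x$labels),
      " frames in ", x$n_components, " PCs\n", sep = "")
  print(data.frame(cluster = seq_len(x$k),
                   population = round(x$population, 3),
                   midpoint_frame = x$midpoint_frame))
  invisible(x)
}

#' Interface residues of a frame
#'
#' Residues of each body making any inter-body contact in the given frame
#' (typically a cluster midpoint frame).
#'
#' @inheritParams contact_matrix
#' @return list with integer vectors `body_a` and `body_b`
#' @export
interface_residues <- function(traj, frame, topology = fab_topology(),
                               cutoff = 6) {
  M <- contact_matrix(traj, frame, topology, cutoff)
  out <- list(body_a = which(rowSums(M) > 0), body_b = which(colSums(M) > 0))
  if (!length(out$body_a)) warning("frame ", frame, " has no inter-body contact")
  out
}

#' Merge interface regions into hotspot groups
#'
#' Single-linkage merging of interface regions whose centres of mass (on a
#' reference structure) lie within `com_cutoff` (default 8 Angstrom, a typical
#' side-chain interaction distance); each group's occurrence is the sum of its
#' members' occurrences, and all group occurrences are rescaled to sum to
#' exactly 100%.
#'
#' @param regions a [region_set()] (or data.frame with start/end) of interface
#'   regions
#' @param occurrence per-region raw occurrence (counts or percentages)
#' @param ref_coords reference per-residue coordinates of one body
#'   (`n_res x 3`)
#' @param com_cutoff merge cutoff on centre-of-mass distance (default 8)
#' @return data.frame of class `hotspot_groups`: group, members, occurrence_pct
#' @export
merge_hotspot_groups <- function(regions, occurrence, ref_coords,
                                 com_cutoff = 8) {
  nr <- nrow(regions)
  stopifnot(length(occurrence) == nr)
  if (nr == 0L)
    return(structure(data.frame(group = character(), members = character(),
                                occurrence_pct = numeric()),
                     class = c("hotspot_groups", "data.frame")))
  com <- t(vapply(seq_len(nr), function(i)
    colMeans(ref_coords[regions$start[i]:regions$end[i], , drop = FALSE]),
    numeric(3)))
  # single-linkage connected components under the COM cutoff
  comp <- seq_len(nr)
  for (i in seq_len(nr)) for (j in seq_len(nr)) {
    if (i < j && sqrt(sum((com[i, ] - com[j, ])^2)) <= com_cutoff) {
      old <- comp[j]; comp[comp == old] <- comp[i]
    }
  }
  ids <- unique(comp)
  occ <- vapply(ids, function(g) sum(occurrence[comp == g]), 0)
  members <- vapply(ids, function(g)
    paste(regions$label[comp == g], collapse = ","), "")
  ord <- order(-occ)
  pct <- 100 * occ[ord] / sum(occ)
  structure(data.frame(group = paste0("HG", seq_along(ids)),
                       members = members[ord], occurrence_pct = pct,
                       stringsAsFactors = FALSE),
            class = c("hotspot_groups", "data.frame"))
}
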
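#' Per-frame residue contact matrix
#'
#' A body-A residue i and body-B residue j are in contact in a frame iff the
#' minimum over their atom pairs of the minimum-image distance is strictly
#' below `cutoff` (default 6 Angstrom).
#'
#' @param traj a [trajectory()] with 2 bodies
#' @param frame 1-based frame index
#' @param topology per-body [fab_topology()]
#' @param cutoff contact cutoff in Angstrom, strict `<` (default 6)
#' @return `n_res x n_res` logical matrix (rows: body A, columns: body B)
#' @export
contact_matrix <- function(traj, frame, topology = fab_topology(), cutoff = 6) {
  stopifnot(traj$n_bodies == 2L)
  A <- body_coords(traj, frame, 1L, topology)
  B <- body_coords(traj, frame, 2L, topology)
  residue_contact_cpp(A, B, topology$atoms$residue, topology$atoms$residue,
                      topology$n_res, topology$n_res,
                      traj$box[frame], cutoff)
}

#' Contact record over a trajectory
#'
#' Computes the per-frame contact matrix for every frame and stores it
#' sparsely (contacting residue pairs plus the per-residue indicator vectors
#' a_i = "residue i of body A touches anything", b_j likewise for body B).
#'
#' @inheritParams contact_matrix
#' @return list of class `contact_record`: `pairs` (per frame, 2-column matrix
#'   of contacting (i, j)), `ind_a`, `ind_b` (per frame, integer vectors of
#'   contacting residues), `n_res`, `n_frames`, `cutoff`, `frame_interval`
#' @export
contact_record <- function(traj, topology = fab_topology(), cutoff = 6) {
  nf <- n_frames(traj)
  pairs <- vector("list", nf); ind_a <- vector("list", nf)
  ind_b <- vector("list", nf)
  for (f in seq_len(nf)) {
    M <- contact_matrix(traj, f, topology, cutoff)
    w <- which(M, arr.ind = TRUE)
    dimnames(w) <- NULL
    pairs[[f]] <- w
    ind_a[[f]] <- sort(unique(w[, 1]))
    ind_b[[f]] <- sort(unique(w[, 2]))
  }
  structure(list(pairs = pairs, ind_a = ind_a, ind_b = ind_b,
                 n_res = topology$n_res, n_frames = nf, cutoff = cutoff,
                 frame_interval = traj$frame_interval),
            class = "contact_record")
}

#' @export
print.contact_record <- function(x, ...) {
  cat("Contact record: ", x$n_frames, " frames, ",
      length(contact_frames(x)), " with inter-body contact (cutoff ",
      x$cutoff, " A)\n", sep = "")
  invisible(x)
}

#' Accumulated contact-frequency profile
#'
#' Per residue r: `count_A(r)` = number of frames in which body-A residue r
#' touches any body-B residue, `count_B(r)` likewise, and
#' `combined = (count_A + count_B) / 2`, i.e. the two bodies' frequencies
#' averaged. Also accumulates the summed pair-frequency matrix.
#'
#' @param record a [contact_record()]
#' @return list of class `frequency_profile`: `profile` (data.frame residue,
#'   count_A, count_B, combined), `pair_freq` (n_res x n_res numeric),
#'   `n_frames`
#' @export
accumulate_frequencies <- function(record) {
  stopifnot(inherits(record, "contact_record"))
  if (record$n_frames < 1L) stop("need at least one frame")
  n <- record$n_res
  count_a <- count_b <- numeric(n)
  pf <- matrix(0, n, n)
  for (f in seq_len(record$n_frames)) {
    ia <- record$ind_a[[f]]; ib <- record$ind_b[[f]]
    count_a[ia] <- count_a[ia] + 1
    count_b[ib] <- count_b[ib] + 1
    w <- record$pairs[[f]]
    if (nrow(w)) pf[w] <- pf[w] + 1
  }
  structure(list(
    profile = data.frame(residue = seq_len(n), count_A = count_a,
                         count_B = count_b, combined = (count_a + count_b) / 2),
    pair_freq = pf, n_frames = record$n_frames),
    class = "frequency_profile")
}

#' Call contact hotspots from a frequency profile
#'
#' A hotspot is a maximal run of at least `min_run` consecutive residues whose
#' contact count exceeds a "high occurrence" threshold. Following the
#' selection rule that a region must show high occurrence in both bodies, the
#' default requires the per-body thresholds to be exceeded in `count_A` and
#' `count_B` simultaneously (`require = "both"`); `"either"` relaxes this.
#' The threshold is mean + `n_sd` * sd of each body's counts over all
#' residues (the source analysis gives no numeric threshold, so it is
#' data-driven and configurable). `stat = "nonzero"` restricts the statistics
#' to contacting residues; note that on sparse profiles whose only contacting
#' residues are the hotspots themselves this variant exceeds the profile
#' maximum and calls nothing, which is why "all" is the default.
#'
#' @param freq a [accumulate_frequencies()] result
#' @param min_run minimum run length (default 2)
#' @param n_sd threshold = mean + n_sd * sd of counts (default 2)
#' @param require "both" (default) or "either" body profile above threshold
#' @param stat "all" (default) or "nonzero": residues entering the threshold
#' @param threshold optional fixed numeric threshold overriding the rule
#' @return a [region_set()] of category "hotspot", sorted by combined peak
#'   height (descending), with extra column `peak`
#' @export
call_hotspots <- function(freq, min_run = 2L, n_sd = 2, require = "both",
                          stat = "all", threshold = NULL) {
  stopifnot(inherits(freq, "frequency_profile"))
  require <- match.arg(require, c("both", "either"))
  stat <- match.arg(stat, c("all", "nonzero"))
  p <- freq$profile
  thr_of <- function(v) {
    if (stat == "nonzero") v <- v[v > 0]
    if (!length(v)) return(Inf)
    if (length(v) == 1L) return(v)
    mean(v) + n_sd * stats::sd(v)
  }
  ta <- if (is.null(threshold)) thr_of(p$count_A) else threshold
  tb <- if (is.null(threshold)) thr_of(p$count_B) else threshold
  hi_a <- p$count_A > ta; hi_b <- p$count_B > tb
  hi <- if (require == "both") hi_a & hi_b else hi_a | hi_b
  hi[is.na(hi)] <- FALSE
  r <- rle(hi)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  if (!any(keep))
    return(region_set(n_res = nrow(p)))
  starts <- starts[keep]; ends <- ends[keep]
  peak <- vapply(seq_along(starts),
                 function(k) max(p$combined[starts[k]:ends[k]]), 0)
  ord <- order(-peak)
  out <- region_set(label = sprintf("hs_%d-%d", starts[ord], ends[ord]),
                    category = "hotspot", start = starts[ord], end = ends[ord],
                    n_res = nrow(p))
  out$peak <- peak[ord]
  out
}

#' Frames with any inter-body contact
#'
#' Used to preselect frames for interface PCA.
#'
#' @param record a [contact_record()]
#' @return integer vector of 1-based frame indices
#' @export
contact_frames <- function(record) {
  stopifnot(inherits(record, "contact_record"))
  which(vapply(record$pairs, nrow, 0L) > 0L)
}

#' Segment per-frame interface labels into contact events
#'
#' A contact event is a maximal run of frames whose label differs from the
#' no-contact symbol. If the label changes within a run without an intervening
#' no-contact frame, the run remains one event flagged as transitional and the
#' label path is recorded (interfaces shifting without breaking contact).
#'
#' @param labels per-frame interface labels (cluster ids, hotspot-group ids,
#'   ...); `none` marks no contact
#' @param none the no-contact symbol (default 0; use "-" for character labels)
#' @param frame_interval_ps frame spacing for ns durations (default 10)
#' @return data.frame of class `contact_events`: start, end, duration_frames,
#'   duration_ns, transition, labels (path as "1>2"), one row per event
#' @export
segment_events <- function(labels, none = 0L, frame_interval_ps = 10) {
  n <- length(labels)
  in_contact <- !is.na(labels) & labels != none
  r <- rle(in_contact)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- data.frame(start = integer(), end = integer(),
                    duration_frames = integer(), duration_ns = numeric(),
                    transition = logical(), labels = character(),
                    stringsAsFactors = FALSE)
  for (k in keep) {
    s <- starts[k]; e <- ends[k]
    path <- rle(as.character(labels[s:e]))$values
    out <- rbind(out, data.frame(
      start = s, end = e, duration_frames = e - s + 1L,
      duration_ns = (e - s + 1L) * frame_interval_ps / 1000,
      transition = length(path) > 1L,
      labels = paste(path, collapse = ">"), stringsAsFactors = FALSE))
  }
  class(out) <- c("contact_events", "data.frame")
  out
}
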
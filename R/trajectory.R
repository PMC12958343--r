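#' Trajectory container
#'
#' Ordered frames of atom coordinates (Angstrom) for one or two identical Fab
#' bodies in a periodic cubic box. Atoms are stored body 1 first, then body 2,
#' each in topology atom order.
#'
#' @param coords list of `n_atoms x 3` numeric matrices, one per frame
#' @param box cubic box edge L in Angstrom (scalar, recycled per frame, or a
#'   vector of per-frame edges)
#' @param time frame time stamps in ps; defaults to `0, dt, 2 dt, ...`
#' @param frame_interval dt in ps (default 10)
#' @param n_bodies 1 or 2
#' @return object of class `fab_trajectory`
#' @export
trajectory <- function(coords, box, time = NULL, frame_interval = 10,
                       n_bodies = 2L) {
  stopifnot(is.list(coords))
  n <- length(coords)
  if (n > 0L) {
    na <- nrow(coords[[1]])
    for (f in seq_len(n)) {
      m <- coords[[f]]
      if (!is.matrix(m) || ncol(m) != 3L)
        stop("frame ", f, ": coordinates must be an n x 3 matrix")
      if (nrow(m) != na)
        stop("frame ", f, ": atom count ", nrow(m), " differs from frame 1 (", na, ")")
      if (!all(is.finite(m))) stop("frame ", f, ": non-finite coordinates")
    }
  }
  box <- rep_len(as.numeric(box), max(n, 1L))[seq_len(n)]
  if (n > 0L && any(box <= 0)) stop("box edge must be positive")
  if (is.null(time)) time <- (seq_len(n) - 1) * frame_interval
  if (n > 1L && any(diff(time) <= 0)) stop("time stamps must be strictly increasing")
  structure(list(coords = coords, box = box, time = as.numeric(time),
                 frame_interval = frame_interval, n_bodies = as.integer(n_bodies)),
            class = "fab_trajectory")
}

#' @export
print.fab_trajectory <- function(x, ...) {
  na <- if (n_frames(x)) nrow(x$coords[[1]]) else 0L
  cat("Trajectory: ", n_frames(x), " frames, ", na, " atoms (",
      x$n_bodies, " bodies), box ", round(x$box[1], 2), " A, dt ",
      x$frame_interval, " ps\n", sep = "")
  invisible(x)
}

#' @export
#' @rdname trajectory
#' @param x a trajectory
n_frames <- function(x) length(x$coords)

#' Extract one body's coordinates for one frame
#'
#' @param traj a [trajectory()]
#' @param frame 1-based frame index
#' @param body 1 or 2
#' @param topology the per-body [fab_topology()]
#' @return `n_atoms x 3` matrix
#' @export
body_coords <- function(traj, frame, body, topology) {
  na <- topology$n_atoms
  idx <- ((body - 1L) * na + 1L):(body * na)
  traj$coords[[frame]][idx, , drop = FALSE]
}

#' Read a trajectory (multi-model PDB or multi-frame GRO)
#'
#' Multi-model PDB frames are delimited by MODEL/ENDMDL with the box edge taken
#' from the CRYST1 record; GRO files (concatenated frames) are converted from
#' nm to Angstrom on read. XTC is a binary format with no installed reader and
#' is rejected with an informative error.
#'
#' @param path file path (.pdb or .gro)
#' @param topology per-body [fab_topology()]; the file's atom count must equal
#'   `n_bodies * topology$n_atoms`
#' @param n_bodies number of identical bodies expected (default 2)
#' @param frame_interval dt in ps for files without time stamps (default 10)
#' @return a [trajectory()]
#' @export
read_trajectory <- function(path, topology = fab_topology(), n_bodies = 2L,
                            frame_interval = 10) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  ext <- tolower(sub(".*\\.", "", basename(path)))
  if (ext == "xtc")
    stop("XTC is a binary format without an installed reader; ",
         "supply a multi-model PDB or a multi-frame GRO file")
  if (ext == "gro") return(read_gro(path, topology, n_bodies, frame_interval))
  read_pdb_multi(path, topology, n_bodies, frame_interval)
}

read_pdb_multi <- function(path, topology, n_bodies, frame_interval) {
  lines <- readLines(path)
  expected <- n_bodies * topology$n_atoms
  box <- NA_real_
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr)) box <- as.numeric(substr(cr[1], 7, 15))
  if (!is.finite(box) || box <= 0)
    stop("missing or invalid CRYST1 box record; periodic distances need the box edge")
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  model_starts <- grep("^MODEL", lines)
  coords <- list()
  parse_block <- function(block) {
    at <- block[startsWith(block, "ATOM  ") | startsWith(block, "HETATM")]
    if (length(at) != expected)
      stop("atom-count mismatch: expected ", expected, ", found ", length(at))
    cbind(as.numeric(substr(at, 31, 38)),
          as.numeric(substr(at, 39, 46)),
          as.numeric(substr(at, 47, 54)))
  }
  if (length(model_starts) == 0L) {
    coords[[1]] <- parse_block(lines[is_atom])
  } else {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts))
      stop("unbalanced MODEL/ENDMDL records")
    for (m in seq_along(model_starts))
      coords[[m]] <- parse_block(lines[model_starts[m]:model_ends[m]])
  }
  trajectory(coords, box = box, frame_interval = frame_interval,
             n_bodies = n_bodies)
}

read_gro <- function(path, topology, n_bodies, frame_interval) {
  lines <- readLines(path)
  expected <- n_bodies * topology$n_atoms
  coords <- list(); box <- numeric(); i <- 1L; f <- 0L
  while (i <= length(lines)) {
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms)) stop("malformed GRO header at line ", i + 1L)
    if (natoms != expected)
      stop("atom-count mismatch: expected ", expected, ", found ", natoms)
    at <- lines[(i + 2L):(i + 1L + natoms)]
    xyz <- cbind(as.numeric(substr(at, 21, 28)),
                 as.numeric(substr(at, 29, 36)),
                 as.numeric(substr(at, 37, 44))) * 10  # nm -> Angstrom
    bl <- as.numeric(strsplit(trimws(lines[i + 2L + natoms]), "\\s+")[[1]])
    f <- f + 1L
    coords[[f]] <- xyz
    box[f] <- bl[1] * 10
    i <- i + 3L + natoms
  }
  if (length(unique(round(box, 6))) > 1L)
    warning("per-frame box edges differ; using them as stored")
  trajectory(coords, box = box, frame_interval = frame_interval,
             n_bodies = n_bodies)
}

#' Write a trajectory as a multi-model PDB
#'
#' One MODEL/ENDMDL block per frame, CRYST1 box record, chain identifiers
#' L/H for body 1 and M/I for body 2. Coordinates are written at PDB precision
#' (0.001 Angstrom).
#'
#' @param traj a [trajectory()]
#' @param path output path
#' @param topology per-body [fab_topology()]
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path, topology = fab_topology()) {
  con <- file(path, "w")
  on.exit(close(con))
  L <- if (n_frames(traj)) traj$box[1] else 0
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                     L, L, L), con)
  at <- topology$atoms
  res3 <- THREE_LETTER[topology$sequence]
  res3[is.na(res3)] <- "UNK"
  rc <- residue_to_chain(at$residue, topology)
  chains <- c(ifelse(rc$chain == "L", "L", "H"),
              ifelse(rc$chain == "L", "M", "I"))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL %8d", f), con)
    xyz <- traj$coords[[f]]
    serial <- seq_len(nrow(xyz))
    resid <- rep(at$residue, traj$n_bodies)
    resnm <- rep(res3[at$residue], traj$n_bodies)
    atnm <- rep(substr(paste0(at$name, "   "), 1, 4), traj$n_bodies)
    elem <- rep(at$element, traj$n_bodies)
    ch <- chains[seq_len(nrow(xyz))]
    writeLines(sprintf(
      "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      serial %% 100000L, atnm, resnm, ch, resid %% 10000L,
      xyz[, 1], xyz[, 2], xyz[, 3], elem), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# minimum-image displacement/distance helpers (cubic box edge L; L <= 0 disables)
min_image_vec <- function(d, L) {
  if (is.finite(L) && L > 0) d - L * round(d / L) else d
}

#' Minimum-image distance between two points in a cubic box
#'
#' @param a,b length-3 coordinate vectors (Angstrom)
#' @param L cubic box edge (Angstrom); `L <= 0` disables wrapping
#' @return distance in Angstrom
#' @export
min_image_dist <- function(a, b, L) {
  sqrt(sum(min_image_vec(a - b, L)^2))
}
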
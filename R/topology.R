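#' Fab body topology
#'
#' Describes one Fab body: chain lengths, residue identities, and the atom
#' table (atom -> residue map, element class, radius). Two identical copies of
#' this body make up a two-Fab system. The combined residue index is 1-based:
#' light chain `1..light_len`, then heavy chain `light_len+1 .. light_len+heavy_len`
#' (defaults 214 + 228 = 442, so heavy-chain residue 47 is combined residue 261).
#'
#' The default representation is one pseudo-atom per residue (Calpha-like bead)
#' with a per-residue radius; all-atom topologies are expressed with the same
#' fields by supplying a multi-row `atoms` table.
#'
#' @param light_len number of light-chain residues (default 214)
#' @param heavy_len number of heavy-chain residues (default 228)
#' @param sequence one-letter residue codes, length `light_len + heavy_len`.
#'   Defaults to a deterministic synthetic repeating pattern of the 20 amino
#'   acids (the real Fab sequence is not bundled).
#' @param radius pseudo-atom radius in Angstrom (default 3.0)
#' @param atoms optional all-atom table overriding the pseudo-atom default:
#'   data.frame with columns `residue` (1-based combined index), `element`
#'   (e.g. "C","N","O","S"), `radius` (Angstrom), optionally `name`.
#' @return object of class `fab_topology`
#' @export
fab_topology <- function(light_len = 214L, heavy_len = 228L,
                         sequence = NULL, radius = 3.0, atoms = NULL) {
  light_len <- as.integer(light_len)
  heavy_len <- as.integer(heavy_len)
  stopifnot(light_len >= 1L, heavy_len >= 0L)
  n_res <- light_len + heavy_len
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (is.null(sequence)) {
    sequence <- rep_len(aa20, n_res)
  } else {
    if (length(sequence) == 1L && nchar(sequence[1]) > 1L)
      sequence <- strsplit(sequence, "")[[1]]
    if (length(sequence) != n_res)
      stop("sequence length ", length(sequence), " != ", n_res, " residues")
  }
  if (is.null(atoms)) {
    atoms <- data.frame(
      residue = seq_len(n_res),
      name = "CA",
      element = pseudo_element(sequence),
      radius = radius,
      stringsAsFactors = FALSE
    )
  } else {
    stopifnot(all(c("residue", "element", "radius") %in% names(atoms)))
    if (any(atoms$residue < 1L | atoms$residue > n_res))
      stop("atom table references residues outside 1..", n_res)
    if (any(atoms$radius <= 0)) stop("atom radii must be positive")
    if (is.null(atoms$name)) atoms$name <- atoms$element
  }
  structure(list(
    light_len = light_len, heavy_len = heavy_len, n_res = n_res,
    sequence = sequence, atoms = atoms, n_atoms = nrow(atoms)
  ), class = "fab_topology")
}

# Element class of the single pseudo-atom representing each residue: apolar
# residues map to carbon, cysteine/methionine-like to sulfur, acids to oxygen,
# bases to nitrogen. Drives the nonpolar-SASA split in pseudo-atom mode.
pseudo_element <- function(seq1) {
  el <- rep("O", length(seq1))
  el[seq1 %in% c("A", "V", "L", "I", "F", "W", "P", "G")] <- "C"
  el[seq1 %in% c("C", "M")] <- "S"
  el[seq1 %in% c("K", "R", "H", "N", "Q")] <- "N"
  el
}

#' @export
print.fab_topology <- function(x, ...) {
  cat("Fab topology: ", x$light_len, " light + ", x$heavy_len,
      " heavy = ", x$n_res, " residues, ", x$n_atoms, " atoms/body\n", sep = "")
  invisible(x)
}

#' Map combined residue index to (chain, intra-chain index) and back
#'
#' The combined index is light `1..light_len` then heavy
#' `light_len+1..light_len+heavy_len`. The mapping is a bijection.
#'
#' @param residue combined residue index vector
#' @param topology a [fab_topology()]
#' @return `residue_to_chain()`: data.frame with `chain` ("L"/"H") and `index`
#'   (1-based within chain); `chain_to_residue()`: combined index vector.
#' @export
residue_to_chain <- function(residue, topology = fab_topology()) {
  residue <- as.integer(residue)
  if (any(residue < 1L | residue > topology$n_res))
    stop("residue index outside 1..", topology$n_res)
  heavy <- residue > topology$light_len
  data.frame(
    chain = ifelse(heavy, "H", "L"),
    index = ifelse(heavy, residue - topology$light_len, residue)
  )
}

#' @rdname residue_to_chain
#' @param chain "L" or "H"
#' @param index 1-based index within the chain
#' @export
chain_to_residue <- function(chain, index, topology = fab_topology()) {
  index <- as.integer(index)
  out <- ifelse(chain == "H", index + topology$light_len, index)
  if (any(out < 1L | out > topology$n_res) ||
      any(chain == "L" & index > topology$light_len) ||
      any(chain == "H" & index > topology$heavy_len) || any(index < 1L))
    stop("chain-local index out of range")
  as.integer(out)
}

THREE_LETTER <- c(
  A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
  H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
  P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
  W = "TRP", Y = "TYR"
)
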
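#' Region sets: APRs and interaction hotspots
#'
#' A region set is a table of named, body-agnostic residue ranges in the
#' combined 1..442 indexing, each categorised as an aggregation-prone region
#' ("APR") or a protein-protein interaction hotspot ("hotspot"). Overlapping
#' regions are allowed.
#'
#' @param label character vector of region labels (e.g. "r_31-36")
#' @param category "APR" or "hotspot", recycled
#' @param start,end inclusive combined residue indices
#' @param n_res upper bound for validation (default 442)
#' @return data.frame of class `fab_regions` with columns
#'   label, category, start, end
#' @export
region_set <- function(label = character(), category = character(),
                       start = integer(), end = integer(), n_res = 442L) {
  stopifnot(length(label) == length(start), length(start) == length(end))
  start <- as.integer(start); end <- as.integer(end)
  if (length(label)) category <- rep_len(as.character(category), length(label))
  if (any(start < 1L | end > n_res | start > end))
    stop("region range outside 1..", n_res, " (or start > end)")
  if (!all(category %in% c("APR", "hotspot", character())))
    stop("category must be 'APR' or 'hotspot'")
  structure(
    data.frame(label = as.character(label), category = category,
               start = start, end = end, stringsAsFactors = FALSE),
    class = c("fab_regions", "data.frame")
  )
}

#' Default APR and hotspot region definitions
#'
#' Seven aggregation-prone regions (31-36, 47-51, 114-118, 129-139, 261-265,
#' 325-329, 387-402) and seven interaction hotspots (26-28, 126-128, 152-153,
#' 288-290, 348-352, 405-411, 437-442) in combined residue indexing; the
#' additional hotspot 187-190 seen only at neutral pH is available via
#' `include_optional = TRUE`.
#'
#' @param include_optional also include hotspot r_187-190 (default FALSE)
#' @return a [region_set()]
#' @export
default_regions <- function(include_optional = FALSE) {
  path <- system.file("extdata", "regions.yaml", package = "twofab")
  reg <- read_regions(path)
  if (!include_optional) reg <- reg[reg$label != "r_187-190", , drop = FALSE]
  class(reg) <- c("fab_regions", "data.frame")
  reg
}

#' Read and write region definitions (YAML)
#'
#' The YAML layout is a list of maps with keys `label`, `category`, `start`,
#' `end`. An empty file yields an empty region set with a warning.
#'
#' @param path YAML file path
#' @param n_res validation bound (default 442)
#' @return a [region_set()]
#' @export
read_regions <- function(path, n_res = 442L) {
  if (!file.exists(path)) stop("region file not found: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc) || length(doc) == 0L) {
    warning("empty region file: ", path)
    return(region_set(n_res = n_res))
  }
  if (!is.null(doc$regions)) doc <- doc$regions
  region_set(
    label = vapply(doc, function(r) as.character(r$label), ""),
    category = vapply(doc, function(r) as.character(r$category), ""),
    start = vapply(doc, function(r) as.integer(r$start), 1L),
    end = vapply(doc, function(r) as.integer(r$end), 1L),
    n_res = n_res
  )
}

#' @rdname read_regions
#' @param regions a [region_set()] to write
#' @export
write_regions <- function(regions, path) {
  doc <- lapply(seq_len(nrow(regions)), function(i) {
    list(label = regions$label[i], category = regions$category[i],
         start = regions$start[i], end = regions$end[i])
  })
  yaml::write_yaml(list(regions = doc), path)
  invisible(path)
}

#' Expand regions into residue index vectors
#'
#' @param regions a [region_set()]
#' @return named list of integer vectors, one per region
#' @export
region_residues <- function(regions) {
  out <- lapply(seq_len(nrow(regions)),
                function(i) seq.int(regions$start[i], regions$end[i]))
  names(out) <- regions$label
  out
}
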
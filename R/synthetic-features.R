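#' The 24 molecular descriptor codes
#'
#' Column codes of the feature table, in canonical order: total and nonpolar
#' SASA, delta-SASA of the 7 APRs and the 7 hotspots, mean RMSF / RMSD / Rg
#' over the late window, hydrogen bonds, net charge, salt bridges, the APR
#' delta-SASA sum, and the average native-contact fraction. Region codes use
#' ASCII hyphens ("r_31-36"). Columns are named by the quantity computed; note
#' the source table's RMSD/Rg code strings are swapped relative to their
#' descriptions, which this naming resolves.
#'
#' @return character vector of length 24
#' @export
descriptor_codes <- function() {
  c("Total SASA", "Nonpolar SASA",
    "r_31-36", "r_47-51", "r_114-118", "r_129-139", "r_261-265",
    "r_325-329", "r_387-402",
    "r_26-28", "r_126-128", "r_152-153", "r_288-290", "r_348-352",
    "r_405-411", "r_437-442",
    "Mean RMSF (last 80 ns)", "Last 80 ns mean RMSD", "Last 80 ns mean Rg",
    "Number of hydrogen bonds in the last 80 ns", "Net charges",
    "Salt bridge average", "sum_aprsasa",
    "Average native contact (last 80 ns)")
}

apr_codes <- function() descriptor_codes()[3:9]
hotspot_codes <- function() descriptor_codes()[10:16]

#' Configuration for the synthetic feature-table generator
#'
#' Emulates a table of molecular descriptors over formulation conditions with a
#' planted linear law `ln(v) = intercept + sum(coef_i * z(feature_i)) + noise`,
#' where `z()` standardises the feature column. Defaults plant the signal on
#' the four descriptors found most predictive in practice (hotspots r_288-290
#' and r_126-128, the late-window mean RMSD, and APR r_31-36) with signs
#' matching their observed correlations with aggregation kinetics.
#'
#' @param n_conditions number of rows (default 49 formulation conditions)
#' @param informative named numeric vector: coefficients on standardised
#'   features; names must be descriptor codes
#' @param noise_sd additive Gaussian noise sd on ln(v) (default 0.3)
#' @param intercept ln(v) intercept (default -5)
#' @param seed RNG seed
#' @return list of class `synth_feature_config`
#' @export
synth_feature_config <- function(n_conditions = 49L,
                                 informative = c("r_288-290" = 1.0,
                                                 "r_126-128" = -0.7,
                                                 "Last 80 ns mean RMSD" = 1.0,
                                                 "r_31-36" = 0.5),
                                 noise_sd = 0.3, intercept = -5, seed = 1L) {
  stopifnot(noise_sd >= 0, n_conditions >= 3)
  bad <- setdiff(names(informative), descriptor_codes())
  if (length(bad)) stop("informative features not descriptor codes: ",
                        paste(bad, collapse = ", "))
  structure(list(n_conditions = as.integer(n_conditions),
                 informative = informative, noise_sd = noise_sd,
                 intercept = intercept, seed = as.integer(seed)),
            class = "synth_feature_config")
}

# typical location/scale for each descriptor column (Angstrom^2, Angstrom,
# counts, elementary charges) used to draw realistic marginals
descriptor_scales <- function() {
  codes <- descriptor_codes()
  mu <- setNames(numeric(24), codes)
  sdv <- setNames(numeric(24), codes)
  mu["Total SASA"] <- 20000; sdv["Total SASA"] <- 700
  mu["Nonpolar SASA"] <- 8000; sdv["Nonpolar SASA"] <- 350
  reg <- c(apr_codes(), hotspot_codes())
  mu[reg] <- 0; sdv[reg] <- 30
  mu["Mean RMSF (last 80 ns)"] <- 1.5; sdv["Mean RMSF (last 80 ns)"] <- 0.3
  mu["Last 80 ns mean RMSD"] <- 3.0; sdv["Last 80 ns mean RMSD"] <- 0.6
  mu["Last 80 ns mean Rg"] <- 23.5; sdv["Last 80 ns mean Rg"] <- 0.3
  mu["Number of hydrogen bonds in the last 80 ns"] <- 310
  sdv["Number of hydrogen bonds in the last 80 ns"] <- 12
  mu["Net charges"] <- 8; sdv["Net charges"] <- 9
  mu["Salt bridge average"] <- 15; sdv["Salt bridge average"] <- 3
  mu["Average native contact (last 80 ns)"] <- 0.95
  sdv["Average native contact (last 80 ns)"] <- 0.015
  list(mu = mu, sd = sdv)
}

#' Generate a synthetic condition x descriptor feature table
#'
#' Draws the 24 descriptor columns from realistic independent marginals
#' (`sum_aprsasa` is set to the row-wise sum of the 7 APR delta-SASA columns,
#' preserving that invariant), then sets
#' `ln(v) = intercept + sum(coef * z(feature)) + N(0, noise_sd)` and a melting
#' temperature `Tm` anticorrelated with ln(v). Bitwise reproducible for a given
#' seed.
#'
#' @param config a [synth_feature_config()]
#' @return data.frame with 24 descriptor columns plus `ln(v)` and `Tm`;
#'   attribute `ground_truth` records the planted coefficients and noise sd
#' @export
generate_feature_table <- function(config = synth_feature_config()) {
  stopifnot(inherits(config, "synth_feature_config"))
  set.seed(config$seed)
  n <- config$n_conditions
  sc <- descriptor_scales()
  codes <- descriptor_codes()
  X <- matrix(NA_real_, n, length(codes), dimnames = list(NULL, codes))
  for (cc in setdiff(codes, "sum_aprsasa"))
    X[, cc] <- rnorm(n, sc$mu[cc], sc$sd[cc])
  X[, "sum_aprsasa"] <- rowSums(X[, apr_codes(), drop = FALSE])
  z <- function(v) (v - mean(v)) / sd(v)
  lnv <- rep(config$intercept, n)
  for (nm in names(config$informative))
    lnv <- lnv + config$informative[[nm]] * z(X[, nm])
  lnv <- lnv + rnorm(n, sd = config$noise_sd)
  tm <- 72 - 1.2 * z(lnv) + rnorm(n, sd = 0.5)
  out <- as.data.frame(X, check.names = FALSE)
  out[["ln(v)"]] <- lnv
  out[["Tm"]] <- tm
  attr(out, "ground_truth") <- list(informative = config$informative,
                                    noise_sd = config$noise_sd,
                                    intercept = config$intercept)
  out
}

#' Read/write a feature table as CSV
#'
#' Column names (including parentheses and hyphens) are preserved verbatim.
#'
#' @param table feature table data.frame
#' @param path CSV path
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
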
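#' Pipeline configuration
#'
#' Collects every stage parameter of the analysis workflow (synthetic
#' generation, geometry, contacts, PCA, descriptors, model) with the
#' documented defaults: 6 Angstrom contact cutoff, 8 Angstrom hotspot-group
#' merge cutoff, 25 distance bins, 97% variance rule, k = 9 clusters, 80/50 ns
#' late windows, first 20 frames as delta-SASA reference, standard SVR grids.
#'
#' @param seed master seed; stage seeds derive from it
#' @param n_frames synthetic trajectory length (default 2000)
#' @param stages character vector of stages to run, in order
#' @param k number of PCA clusters; defaults to 9 capped at the available
#'   contact frames
#' @param contact_cutoff contact cutoff in Angstrom (default 6)
#' @param com_cutoff hotspot-group merge cutoff (default 8)
#' @param n_bins distance bins (default 25)
#' @param variance_threshold PCA variance coverage (default 0.97)
#' @param families model families for the subset search
#' @param top_k subset-search feature count (default 9)
#' @param trajectory_config optional full [synth_trajectory_config()]
#' @param feature_config optional full [synth_feature_config()]
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(seed = 1L, n_frames = 2000L,
                            stages = c("synth", "geometry", "contacts", "pca",
                                       "features", "model"),
                            k = 9L, contact_cutoff = 6, com_cutoff = 8,
                            n_bins = 25L, variance_threshold = 0.97,
                            families = c("mlr", "pls"), top_k = 9L,
                            trajectory_config = NULL, feature_config = NULL) {
  if (is.null(trajectory_config))
    trajectory_config <- synth_trajectory_config(n_frames = n_frames,
                                                 seed = seed)
  if (is.null(feature_config))
    feature_config <- synth_feature_config(seed = seed + 1L)
  structure(list(seed = as.integer(seed), stages = stages, k = as.integer(k),
                 contact_cutoff = contact_cutoff, com_cutoff = com_cutoff,
                 n_bins = as.integer(n_bins),
                 variance_threshold = variance_threshold,
                 families = families, top_k = as.integer(top_k),
                 trajectory_config = trajectory_config,
                 feature_config = feature_config),
            class = "pipeline_config")
}

# order-insensitive content hash (FNV-1a over the deparsed object) used for
# the manifest; no digest package in the runtime environment
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 2166136261
  for (ch in utf8ToInt(s)) {
    h <- bitwXor(h, ch)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", h)
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order on a synthetic two-body system:
#' generation, geometry (distance/angle binning), contact record + frequency
#' profile + hotspot calling + event segmentation, interface PCA + clustering
#' + hotspot-group merging, per-trajectory descriptors, and the feature-table
#' model stage. Stage artifacts are written as CSV/YAML under `out_dir`
#' together with a JSON manifest recording seeds, parameters and their hash.
#' Reruns with the same config reproduce all outputs.
#'
#' @param config a [pipeline_config()]
#' @param out_dir output directory (created if needed)
#' @return invisibly, a list with in-memory stage results and the manifest
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("twofab_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  manifest <- list(package_version = as.character(utils::packageVersion("twofab")),
                   seed = config$seed, config_hash = config_hash(config),
                   stages_run = character())
  stage <- function(name, fun) {
    if (!name %in% config$stages) {
      manifest$stages_skipped <<- c(manifest$stages_skipped, name)
      return(invisible(NULL))
    }
    out <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages_run <<- c(manifest$stages_run, name)
    out
  }

  res$synth <- stage("synth", function() {
    gen <- generate_two_body_trajectory(config$trajectory_config)
    yaml::write_yaml(list(state = as.integer(gen$ground_truth$state),
                          interfaces = lapply(gen$ground_truth$interfaces,
                                              function(f) list(a = f$a, b = f$b,
                                                               dwell = f$dwell))),
                     file.path(out_dir, "ground_truth.yaml"))
    gen
  })
  gen <- res$synth
  if (is.null(gen) && any(c("geometry", "contacts", "pca", "features") %in%
                          config$stages))
    stop("downstream stages need the synth stage")

  res$geometry <- stage("geometry", function() {
    ps <- bin_pose_series(gen$trajectory, gen$topology, n_bins = config$n_bins)
    utils::write.csv(ps$frames, file.path(out_dir, "geometry_frames.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(bin = seq_along(ps$bin_counts),
                                lower = head(ps$breaks, -1),
                                upper = ps$breaks[-1],
                                count = ps$bin_counts),
                     file.path(out_dir, "geometry_bins.csv"), row.names = FALSE)
    ps
  })

  res$contacts <- stage("contacts", function() {
    rec <- contact_record(gen$trajectory, gen$topology, config$contact_cutoff)
    freq <- accumulate_frequencies(rec)
    hs <- call_hotspots(freq)
    prof <- freq$profile
    prof$chain <- residue_to_chain(prof$residue, gen$topology)$chain
    utils::write.csv(prof, file.path(out_dir, "contact_frequency.csv"),
                     row.names = FALSE)
    if (nrow(hs)) write_regions(hs, file.path(out_dir, "hotspots.yaml"))
    list(record = rec, freq = freq, hotspots = hs)
  })

  res$pca <- stage("pca", function() {
    rec <- res$contacts$record
    if (is.null(rec)) rec <- contact_record(gen$trajectory, gen$topology,
                                            config$contact_cutoff)
    cf <- contact_frames(rec)
    if (length(cf) < 3L) {
      warning("too few contact frames for PCA; stage skipped")
      return(NULL)
    }
    pca <- fit_interface_pca(gen$trajectory, gen$topology, frames = cf)
    k <- min(config$k, length(cf))
    cl <- cluster_frames(pca, k = k,
                         n_components = select_components(pca$eigenvalues,
                                                          config$variance_threshold))
    utils::write.csv(data.frame(component = seq_along(pca$eigenvalues),
                                eigenvalue = pca$eigenvalues),
                     file.path(out_dir, "pca_eigenvalues.csv"), row.names = FALSE)
    utils::write.csv(data.frame(frame = cl$frames, cluster = cl$labels),
                     file.path(out_dir, "pca_labels.csv"), row.names = FALSE)
    # per-frame interface labels -> contact events
    labels <- integer(n_frames(gen$trajectory))
    labels[cl$frames] <- cl$labels
    ev <- segment_events(labels, none = 0L,
                         frame_interval_ps = gen$trajectory$frame_interval)
    utils::write.csv(ev, file.path(out_dir, "contact_events.csv"),
                     row.names = FALSE)
    # cluster interfaces -> regions -> hotspot groups on the reference body
    regs <- list(); occ <- numeric()
    for (cc in seq_len(cl$k)) {
      ir <- interface_residues(gen$trajectory, cl$midpoint_frame[cc],
                               gen$topology, config$contact_cutoff)
      resv <- sort(unique(c(ir$body_a, ir$body_b)))
      if (!length(resv)) next
      rngs <- split(resv, cumsum(c(1, diff(resv) != 1)))
      for (rg in rngs) {
        regs <- c(regs, list(c(min(rg), max(rg))))
        occ <- c(occ, cl$population[cc])
      }
    }
    hg <- NULL
    if (length(regs)) {
      rs <- region_set(label = sprintf("c_%d-%d",
                                       vapply(regs, `[`, 0, 1),
                                       vapply(regs, `[`, 0, 2)),
                       category = "hotspot",
                       start = vapply(regs, `[`, 0, 1),
                       end = vapply(regs, `[`, 0, 2),
                       n_res = gen$topology$n_res)
      ref <- body_coords(gen$trajectory, 1L, 1L, gen$topology)
      hg <- merge_hotspot_groups(rs, occ, ref, config$com_cutoff)
      utils::write.csv(hg, file.path(out_dir, "hotspot_groups.csv"),
                       row.names = FALSE)
    }
    yaml::write_yaml(list(k = cl$k, population = cl$population,
                          midpoint_frame = cl$midpoint_frame),
                     file.path(out_dir, "clusters.yaml"))
    list(pca = pca, clusters = cl, events = ev, groups = hg)
  })

  res$features <- stage("features", function() {
    ft <- suppressWarnings(compute_descriptors(gen$trajectory, gen$topology))
    utils::write.csv(ft, file.path(out_dir, "descriptors.csv"),
                     row.names = FALSE)
    ft
  })

  res$model <- stage("model", function() {
    tab <- generate_feature_table(config$feature_config)
    write_feature_table(tab, file.path(out_dir, "feature_table.csv"))
    rep <- subset_search(tab, top_k = config$top_k,
                         families = config$families, seed = config$seed)
    utils::write.csv(rep$ranking, file.path(out_dir, "shap_ranking.csv"),
                     row.names = FALSE)
    utils::write.csv(rep$results, file.path(out_dir, "subset_results.csv"),
                     row.names = FALSE)
    utils::write.csv(rep$parity, file.path(out_dir, "parity.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(feature = rownames(rep$pearson), rep$pearson,
                                check.names = FALSE),
                     file.path(out_dir, "pearson.csv"), row.names = FALSE)
    yaml::write_yaml(list(family = rep$best$family,
                          params = as.list(rep$best$params),
                          subset = rep$best$subset,
                          cv_r2 = rep$best$cv_r2),
                     file.path(out_dir, "best_model.yaml"))
    rep
  })

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(res, list(manifest = manifest, out_dir = out_dir)))
}
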
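#' Default pipeline configuration
#'
#' Returns the full set of pipeline settings with their defaults; user
#' config (a flat YAML mapping or named list) overrides by key. Paths
#' (`topology`, `frames`, `amd_log`) have no defaults and must be given
#' for the stages that need them.
#'
#' @return Named list of defaults.
#' @export
default_pipeline_config <- function() {
  list(topology = NULL, frames = NULL, amd_log = NULL,
       temperature = 300, reweight_method = "maclaurin",
       maclaurin_order = 10, boost_which = "total",
       distance_bin_width = 1, pc_bins = 50,
       n_components = 3, cluster_grid_bins = 32, cluster_min_density = 0.002,
       contact_cutoff = 4.5, seed = 1, output_dir = "amdmem_out")
}

.stage_error <- function(stage, e, path = NULL) {
  stop(sprintf("stage '%s' failed%s: %s", stage,
               if (is.null(path)) "" else paste0(" (input: ", path, ")"),
               conditionMessage(e)), call. = FALSE)
}

#' Run the full analysis pipeline
#'
#' Wires the stages end to end on file inputs: input parsing, boost
#' reweighting, dihedral PCA + most-populated clusters (with a reweighted
#' 2D free-energy surface over PC1/PC2), order-parameter profile,
#' peptide-membrane distance, reweighted insertion PMF, and
#' residue-headgroup contacts. Each stage writes TSV (plus representative
#' cluster PDBs), and a YAML manifest records the resolved config, input
#' hashes, per-stage status and collected warnings; deterministic stages
#' reproduce byte-identical outputs on rerun.
#'
#' @param config Path to a flat YAML config file, or a named list; see
#'   [default_pipeline_config()] for keys.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_pipeline_config(), config)
  thermo <- thermo_params(cfg$temperature)
  out_dir <- cfg$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  warnings_log <- character()
  note <- function(stage, w)
    warnings_log <<- c(warnings_log, paste0(stage, ": ", conditionMessage(w)))
  stages <- c("io", "reweighting", "dpca", "scd", "distance_pmf", "contacts")
  status <- stats::setNames(rep("pending", length(stages)), stages)
  timing <- stats::setNames(rep(NA_real_, length(stages)), stages)
  hdr <- function(txt) sprintf("%s; seed=%d", txt, as.integer(cfg$seed))
  res <- list()

  run_stage <- function(stage, path, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- withCallingHandlers(
      tryCatch(expr, error = function(e) .stage_error(stage, e, path)),
      warning = function(w) { note(stage, w); invokeRestart("muffleWarning") })
    status[stage] <<- "completed"
    timing[stage] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  # -- io: parse every provided input ---------------------------------
  for (key in c("topology", "frames", "amd_log")) {
    p <- cfg[[key]]
    if (!is.null(p) && !file.exists(p))
      stop(sprintf("stage '%s': missing input file %s",
                   if (key == "amd_log") "reweighting" else "io", p),
           call. = FALSE)
  }
  if (is.null(cfg$topology) || is.null(cfg$frames))
    stop("stage 'io': config must name 'topology' and 'frames'", call. = FALSE)
  io <- run_stage("io", cfg$topology, {
    topo <- read_topology(cfg$topology)
    traj <- read_frames(cfg$frames, topo)
    list(topo = topo, traj = traj)
  })
  res$topology <- io$topo; res$frames <- io$traj

  # -- reweighting: frame weights from the boost log ------------------
  if (is.null(cfg$amd_log))
    stop("stage 'reweighting': config must name 'amd_log'", call. = FALSE)
  rw <- run_stage("reweighting", cfg$amd_log, {
    boost <- parse_amd_log(cfg$amd_log)
    if (nrow(boost) != io$traj$n_frames)
      stop(sprintf("boost series has %d records, trajectory %d frames",
                   nrow(boost), io$traj$n_frames))
    w <- frame_weights(boost, thermo, method = cfg$reweight_method,
                       k = cfg$maclaurin_order,
                       boost_which = cfg$boost_which)
    write_result_tsv(data.frame(step = boost$step, weight = w$w),
                     file.path(out_dir, "weights.tsv"),
                     hdr(sprintf("frame weights (%s), kT=%.7g kcal/mol",
                                 w$method, thermo$kT)))
    list(boost = boost, weights = w)
  })
  res$boost <- rw$boost; res$weights <- rw$weights

  # -- dpca: torsions, PCA, 2D surface, clusters ----------------------
  dp <- run_stage("dpca", cfg$frames, {
    series <- compute_phi_psi(io$traj, io$topo)
    model <- dpca_fit(series)
    proj <- model$proj
    write_result_tsv(
      data.frame(frame = seq_len(nrow(proj)),
                 PC1 = proj[, 1],
                 PC2 = if (ncol(proj) >= 2) proj[, 2] else NA_real_,
                 PC3 = if (ncol(proj) >= 3) proj[, 3] else NA_real_),
      file.path(out_dir, "pcs.tsv"), hdr("dPCA projections (unitless)"))
    surf <- NULL
    if (ncol(proj) >= 2) {
      exp_edges <- function(v, nb) {
        r <- range(v); if (r[2] - r[1] < 1e-12) r <- r + c(-0.5, 0.5)
        seq(r[1], r[2] + (r[2] - r[1]) * 1e-9, length.out = nb + 1)
      }
      surf <- pmf_2d(proj[, 1], proj[, 2], rw$weights,
                     exp_edges(proj[, 1], cfg$pc_bins),
                     exp_edges(proj[, 2], cfg$pc_bins),
                     thermo, coords = c("PC1", "PC2"))
    }
    clusters <- cluster_top_pcs(model,
                                n_components = min(cfg$n_components,
                                                   ncol(proj)),
                                grid_bins = cfg$cluster_grid_bins,
                                min_density = cfg$cluster_min_density)
    write_result_tsv(
      data.frame(frame = seq_along(clusters$labels),
                 cluster = clusters$labels),
      file.path(out_dir, "clusters.tsv"),
      hdr("cluster labels (0 = noise), ranked by population"))
    write_cluster_representatives(clusters, io$traj, io$topo, out_dir)
    list(series = series, model = model, surface = surf,
         clusters = clusters)
  })
  res$dpca <- dp

  # -- scd: order-parameter profile -----------------------------------
  res$scd <- run_stage("scd", cfg$frames, {
    prof <- tryCatch(scd_profile(chain_vectors(io$traj, io$topo)),
                     error = function(e) NULL)
    if (is.null(prof)) {
      warning("no resolvable C-H chain vectors; S_CD profile skipped")
    } else {
      write_result_tsv(as.data.frame(prof), file.path(out_dir, "scd.tsv"),
                       hdr("|S_CD| per chain carbon (dimensionless)"))
    }
    prof
  })

  # -- distance + reweighted insertion PMF ----------------------------
  dpmf <- run_stage("distance_pmf", cfg$frames, {
    dist <- com_z_distance(io$traj, io$topo)
    write_result_tsv(data.frame(frame = seq_len(dist$n_frames),
                                distance_A = dist$values),
                     file.path(out_dir, "distance.tsv"),
                     hdr("peptide COM to membrane COM |z| distance (Angstrom)"))
    pmf <- insertion_pmf(dist, rw$boost, thermo,
                         method = cfg$reweight_method,
                         k = cfg$maclaurin_order,
                         boost_which = cfg$boost_which,
                         bin_width = cfg$distance_bin_width)
    write_fes_tsv(pmf, file.path(out_dir, "pmf.tsv"),
                  extra = sprintf("seed=%d", as.integer(cfg$seed)))
    list(distance = dist, pmf = pmf)
  })
  res$distance <- dpmf$distance; res$insertion_pmf <- dpmf$pmf

  # -- contacts -------------------------------------------------------
  res$contacts <- run_stage("contacts", cfg$frames, {
    ct <- headgroup_contact_fractions(io$traj, io$topo,
                                      cutoff = cfg$contact_cutoff)
    write_result_tsv(as.data.frame(ct), file.path(out_dir, "contacts.tsv"),
                     hdr(sprintf("headgroup contact fraction, cutoff=%g Angstrom",
                                 cfg$contact_cutoff)))
    ct
  })

  # -- manifest -------------------------------------------------------
  inputs <- Filter(Negate(is.null),
                   cfg[c("topology", "frames", "amd_log")])
  manifest <- list(
    package = "amdmem",
    version = as.character(utils::packageVersion("amdmem")),
    config = cfg[order(names(cfg))],
    input_md5 = as.list(tools::md5sum(unlist(inputs))),
    stages = as.list(status),
    stage_seconds = as.list(timing),
    warnings = if (length(warnings_log)) warnings_log else list())
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  res$manifest <- manifest
  invisible(res)
}
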
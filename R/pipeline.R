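#' Pipeline configuration
#'
#' All tunable thresholds of the mapping pipeline in one serializable
#' object. The two fixed conventions of the method live here: the 1 cm^3
#' comminution threshold and the 5 mm alignment gate.
#'
#' @param out_dir output directory for pipeline products.
#' @param n_33A,n_33C simulated cohort composition (defaults 53 and 21).
#' @param seed integer master seed.
#' @param comminution_threshold cm^3, strict upper volume bound for
#'   comminution-zone fragments.
#' @param spacing_tolerance mm, alignment gate (inclusive).
#' @param projection_cutoff mm, template projection cutoff.
#' @param dilation_radius mm, per-case dilation before frequency counting.
#' @param connectivity 6 or 26, fragment component connectivity.
#' @param alpha significance and normality-gate level.
#' @param voxel_spacing mm, phantom voxel edge.
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir = "fracmap3d_out", n_33A = 53, n_33C = 21,
                            seed = 7, comminution_threshold = 1.0,
                            spacing_tolerance = 5.0, projection_cutoff = 5.0,
                            dilation_radius = 2.0, connectivity = 26,
                            alpha = 0.05, voxel_spacing = 1.0) {
  cfg <- list(out_dir = out_dir, n_33A = as.integer(n_33A), n_33C = as.integer(n_33C),
              seed = as.integer(seed),
              comminution_threshold = comminution_threshold,
              spacing_tolerance = spacing_tolerance,
              projection_cutoff = projection_cutoff,
              dilation_radius = dilation_radius,
              connectivity = as.integer(connectivity), alpha = alpha,
              voxel_spacing = voxel_spacing)
  thresholds <- c(cfg$comminution_threshold, cfg$spacing_tolerance,
                  cfg$projection_cutoff, cfg$alpha, cfg$voxel_spacing)
  if (any(!is.finite(thresholds)) || any(thresholds <= 0))
    stop("all thresholds must be positive")
  if (cfg$dilation_radius < 0) stop("dilation_radius must be >= 0")
  if (!cfg$connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param config a \code{pipeline_config}.
#' @param path YAML file path.
#' @return \code{write_config}: \code{path} invisibly;
#'   \code{read_config}: a \code{pipeline_config}.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

# fingerprint of the scientific parameters (paths excluded so identical
# analyses hash identically wherever they are written)
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  fm_hash(yaml::as.yaml(cfg))
}

output_header <- function(config)
  sprintf("fracmap3d %s config %s", fm_version(), config_hash(config))

write_csv_with_header <- function(df, path, config) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste("#", output_header(config)), con, sep = "\n")
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], fmt6)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_csv_skip_header <- function(path) read.csv(path, comment.char = "#")

#' Simulate a cohort to disk
#'
#' Writes the template (PLY + NIfTI), one labeled NIfTI volume and ground
#' truth JSON per case, the cohort table CSV and the effective config.
#' Idempotent for a fixed seed: reruns produce byte-identical outputs.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param cohort_cfg a \code{\link{cohort_config}}.
#' @return The output directory, invisibly.
#' @export
cmd_simulate <- function(config = pipeline_config(), cohort_cfg = cohort_config()) {
  if (config$n_33A + config$n_33C < 1) stop("empty cohort: n_33A + n_33C must be >= 1")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  case_dir <- file.path(config$out_dir, "cases")
  dir.create(case_dir, showWarnings = FALSE)
  spec <- phantom_spec(voxel_spacing = config$voxel_spacing)
  res <- simulate_cohort(config$n_33A, config$n_33C, cohort_cfg,
                         seed = config$seed, spec = spec,
                         case_fn = function(case) {
                           id <- case$record$case_id
                           write_labeled_volume(case$volume,
                                                file.path(case_dir, paste0(id, ".nii.gz")))
                           write_ground_truth(case$ground_truth,
                                              file.path(case_dir, paste0(id, "_truth.json")))
                           NULL
                         })
  write_ply(res$template$mesh, file.path(config$out_dir, "template.ply"),
            comments = output_header(config))
  write_labeled_volume(res$template$volume, file.path(config$out_dir, "template.nii.gz"))
  write_csv_with_header(res$records, file.path(config$out_dir, "cohort.csv"), config)
  write_config(config, file.path(config$out_dir, "config.yaml"))
  fm_log("simulated %d cases into %s", nrow(res$records), config$out_dir)
  invisible(config$out_dir)
}

#' Map a simulated cohort: heat maps and QC report
#'
#' For every case on disk: fragment morphometrics, the spacing gate against
#' the template (cases failing the gate are excluded and listed), fracture
#' line extraction and comminution footprints, projection, and per-stratum
#' (all / 33A / 33C) frequency heat maps written as PLY + CSV.
#'
#' @param config a \code{\link{pipeline_config}} whose \code{out_dir}
#'   contains a simulated cohort.
#' @return list with the maps, the QC table and zone extents, invisibly.
#' @export
cmd_map <- function(config = pipeline_config()) {
  template <- read_mesh(file.path(config$out_dir, "template.ply"))
  cohort <- read_cohort_table(file.path(config$out_dir, "cohort.csv"))
  if (!nrow(cohort)) stop("cohort table is empty")
  case_dir <- file.path(config$out_dir, "cases")
  qc <- list(); line_sets <- list(); comm_sets <- list()
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$case_id[i]
    vol <- read_labeled_volume(file.path(case_dir, paste0(id, ".nii.gz")))
    fset <- classify_comminution(label_fragments(vol, relabel = FALSE),
                                 threshold = config$comminution_threshold)
    gate <- spacing_check(boundary_points(vol), template,
                          tolerance = config$spacing_tolerance)
    qc[[i]] <- data.frame(case_id = id, ao_class = cohort$ao_class[i],
                          max_distance = gate$max_distance,
                          mean_distance = gate$mean_distance,
                          gate = if (gate$passed) "passed" else "failed")
    fm_log("map %s: gate %s (max %.2f mm)", id, qc[[i]]$gate, gate$max_distance)
    if (!gate$passed) next
    iface <- extract_interface(vol)
    line_sets[[id]] <- project_to_template(iface$surface_line_points, NULL,
                                           template, cutoff = config$projection_cutoff)
    comm_sets[[id]] <- comminution_footprint(vol, fset, NULL, template,
                                             cutoff = config$projection_cutoff)
  }
  qc <- do.call(rbind, qc)
  if (!any(qc$gate == "passed")) stop("all cases failed the spacing gate")
  included <- qc$case_id[qc$gate == "passed"]
  strata <- list(all = included,
                 `33A` = intersect(included, cohort$case_id[cohort$ao_class == "33A"]),
                 `33C` = intersect(included, cohort$case_id[cohort$ao_class == "33C"]))
  maps <- list()
  for (s in names(strata)) {
    ids <- strata[[s]]
    if (!length(ids)) next
    for (kind in c("line", "comminution")) {
      sets <- if (kind == "line") line_sets[ids] else comm_sets[ids]
      mp <- accumulate_frequency(sets, n_cases = length(ids), template = template,
                                 dilation_radius = config$dilation_radius, kind = kind)
      maps[[paste(s, kind, sep = "_")]] <- mp
      write_frequency_map(mp, file.path(config$out_dir,
                                        sprintf("map_%s_%s.ply", s, kind)),
                          comments = output_header(config))
    }
  }
  write_csv_with_header(qc, file.path(config$out_dir, "qc.csv"), config)
  zones <- list()
  for (nm in names(maps)) {
    mp <- maps[[nm]]
    thr <- max(mp$frequency) / 2
    for (sec in c("medial", "lateral", "anterior", "posterior")) {
      ze <- tryCatch(measure_zone_extent(mp, thr, template, sector = sec),
                     error = function(e) NULL)  # sector may hold no hot vertex
      if (is.null(ze)) next
      zones[[paste(nm, sec)]] <- data.frame(
        map = nm, sector = sec, threshold_pct = thr,
        inferior_edge_mm = ze$inferior_edge_to_joint_line,
        superior_edge_mm = ze$superior_edge_to_joint_line,
        vertical_height_mm = ze$vertical_height)
    }
  }
  zones <- do.call(rbind, zones)
  rownames(zones) <- NULL
  write_csv_with_header(zones, file.path(config$out_dir, "zones.csv"), config)
  fm_log("wrote %d maps; %d/%d cases passed the gate", length(maps),
         length(included), nrow(qc))
  invisible(list(maps = maps, qc = qc, zones = zones))
}

#' Cohort statistics report
#'
#' Runs \code{\link{cohort_report}} on the cohort table and writes it as
#' CSV and aligned plain text.
#'
#' @param config a \code{\link{pipeline_config}} whose \code{out_dir}
#'   contains a cohort table with morphometrics.
#' @return The report, invisibly.
#' @export
cmd_stats <- function(config = pipeline_config()) {
  cohort <- read_cohort_table(file.path(config$out_dir, "cohort.csv"))
  rep <- cohort_report(cohort, alpha = config$alpha)
  write_csv_with_header(as.data.frame(rep), file.path(config$out_dir, "stats.csv"), config)
  txt <- c(output_header(config), utils::capture.output(print.data.frame(rep)))
  writeLines(txt, file.path(config$out_dir, "stats.txt"))
  invisible(rep)
}

#' Full pipeline: simulate, map, stats, markdown summary
#' @param config a \code{\link{pipeline_config}}.
#' @param cohort_cfg a \code{\link{cohort_config}}.
#' @return list with maps, qc and the stats report, invisibly.
#' @export
cmd_report <- function(config = pipeline_config(), cohort_cfg = cohort_config()) {
  cmd_simulate(config, cohort_cfg)
  mapped <- cmd_map(config)
  rep <- cmd_stats(config)
  md <- c(sprintf("# fracmap3d report (%s)", config_hash(config)),
          "", sprintf("Cohort: %d x 33A + %d x 33C, seed %d.",
                      config$n_33A, config$n_33C, config$seed),
          "", "## Heat maps", "",
          vapply(names(mapped$maps), function(nm)
            sprintf("- %s: max frequency %.1f%% (n = %d)", nm,
                    max(mapped$maps[[nm]]$frequency), mapped$maps[[nm]]$n_cases),
            character(1)),
          "", "## Group comparison", "",
          utils::capture.output(print.data.frame(rep)))
  writeLines(md, file.path(config$out_dir, "report.md"))
  invisible(list(maps = mapped$maps, qc = mapped$qc, stats = rep))
}
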
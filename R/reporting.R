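# Pipeline entry points tying the stages together, with CSV/JSON report
# bundles and machine-readable provenance. The Rscript front-end in
# inst/cli/smaggr.R is a thin wrapper over these functions.

# md5 of the serialized configuration, via a temporary file
.config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              force = TRUE, null = "null"), f)
  unname(tools::md5sum(f))
}

.provenance <- function(params) {
  list(package = "smaggr",
       version = as.character(utils::packageVersion("smaggr")),
       r_version = as.character(getRversion()),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       config_hash = .config_hash(params),
       parameters = params)
}

#' Full trajectory analysis report
#'
#' Runs the complete post-processing pipeline on a (meta)trajectory:
#' per-frame COM contacts and aggregate partitions, the stacking-angle
#' distribution of the monomer species, and hydrogen-bond occupancy per
#' acceptor class. Optionally writes the report bundle (contacts CSV,
#' aggregate-size CSV, angle-histogram CSV, occupancy CSV and a JSON summary
#' with provenance) to a directory.
#'
#' @param traj An `md_trajectory`.
#' @param species Monomer species whose pair angles are analyzed.
#' @param cutoff Contact cutoff (Angstrom).
#' @param stack_threshold Stacking-angle threshold (degrees).
#' @param criteria Hydrogen-bond criteria ([hbond_criteria()]).
#' @param stride Frame stride for the analysis.
#' @param outdir Optional output directory; created if missing.
#' @param extra_params Optional named list merged into the provenance record
#'   (e.g. generator seeds).
#' @return A list of class `trajectory_report`: `contacts` (per-frame pair
#'   data frame), `aggregate_sizes` (per-frame component sizes),
#'   `mean_aggregate_size`, `angles` (an `angle_distribution`), `occupancy`
#'   (an `occupancy_result`), `params`.
#' @export
analyze_trajectory <- function(traj, species = "adenine", cutoff = 6.0,
                               stack_threshold = 30,
                               criteria = hbond_criteria(), stride = 1L,
                               outdir = NULL, extra_params = NULL) {
  frames <- seq(1L, n_frames(traj), by = stride)
  contact_rows <- list(); size_rows <- list()
  for (f in frames) {
    cs <- contact_pairs(traj, f, cutoff = cutoff, species = species)
    ag <- aggregates(cs)
    if (nrow(cs) > 0) {
      contact_rows[[length(contact_rows) + 1L]] <-
        cbind(frame = f, as.data.frame(cs))
    }
    size_rows[[length(size_rows) + 1L]] <-
      data.frame(frame = f, size = as.integer(ag$sizes))
  }
  contacts <- if (length(contact_rows)) do.call(rbind, contact_rows)
              else data.frame(frame = integer(0), i = integer(0),
                              j = integer(0), dist = numeric(0))
  sizes <- do.call(rbind, size_rows)
  ang <- angle_distribution(traj, species_pair = c(species, species),
                            cutoff = cutoff,
                            stack_threshold = stack_threshold,
                            stride = stride)
  occ <- hbond_occupancy(traj, criteria = criteria, stride = stride)
  params <- c(list(species = species, cutoff = cutoff,
                   stack_threshold = stack_threshold,
                   max_da_distance = criteria$max_da_distance,
                   min_dha_angle = criteria$min_dha_angle,
                   stride = stride, n_frames = length(frames)),
              extra_params)
  rep <- structure(list(contacts = contacts, aggregate_sizes = sizes,
                        mean_aggregate_size = mean(sizes$size),
                        angles = ang, occupancy = occ, params = params),
                   class = "trajectory_report")
  if (!is.null(outdir)) write_trajectory_report(rep, outdir)
  rep
}

#' @export
print.trajectory_report <- function(x, ...) {
  cat("Trajectory analysis over", x$params$n_frames, "frames\n")
  cat(sprintf("  mean aggregate size: %.3f molecules\n",
              x$mean_aggregate_size))
  print(x$angles)
  if (nrow(x$occupancy) > 0) {
    cat("  H-bond occupancy:\n")
    print(as.data.frame(x$occupancy), digits = 4)
  }
  invisible(x)
}

#' Write a trajectory report bundle
#'
#' @param report A `trajectory_report`.
#' @param outdir Output directory (created if missing).
#' @return The summary-file path, invisibly.
#' @export
write_trajectory_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$contacts, file.path(outdir, "contacts.csv"),
                   row.names = FALSE)
  utils::write.csv(report$aggregate_sizes,
                   file.path(outdir, "aggregate_sizes.csv"),
                   row.names = FALSE)
  if (!report$angles$empty) {
    utils::write.csv(report$angles$histogram,
                     file.path(outdir, "angle_histogram.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(as.data.frame(report$occupancy),
                   file.path(outdir, "hbond_occupancy.csv"),
                   row.names = FALSE)
  summary <- list(
    provenance = .provenance(report$params),
    mean_aggregate_size = report$mean_aggregate_size,
    angle_mean = report$angles$mean,
    angle_dispersion = report$angles$dispersion,
    angle_rms = report$angles$rms_angle,
    stacked_fraction = report$angles$stacked_fraction,
    n_angle_samples = report$angles$n,
    occupancy = as.data.frame(report$occupancy)
  )
  path <- file.path(outdir, "summary.json")
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Compare two trajectory analysis conditions
#'
#' Heterogeneity comparison (pure monomer vs monomer + inhibitor): angle
#' distribution differences plus the change in mean aggregate size.
#'
#' @param report_a,report_b `trajectory_report` objects (a = reference).
#' @return A list of class `condition_comparison` with the
#'   [heterogeneity_compare()] record and `aggregate_size_diff`
#'   (b minus a).
#' @export
compare_conditions <- function(report_a, report_b) {
  structure(list(
    heterogeneity = heterogeneity_compare(report_a$angles, report_b$angles),
    aggregate_size_diff = report_b$mean_aggregate_size -
      report_a$mean_aggregate_size,
    mean_size_a = report_a$mean_aggregate_size,
    mean_size_b = report_b$mean_aggregate_size
  ), class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  print(x$heterogeneity)
  cat(sprintf("  mean aggregate size: %.3f -> %.3f (diff %+.3f)\n",
              x$mean_size_a, x$mean_size_b, x$aggregate_size_diff))
  invisible(x)
}

#' Potency and SAR report from kinetic curves
#'
#' Computes the dose-response table and matrix, the per-compound potency
#' table (percent inhibition and relative concentration at the endpoint) and,
#' when a property table is supplied with overlapping compounds, the
#' descriptor-potency rank association. Optionally writes CSVs and a JSON
#' summary.
#'
#' @param curves Long-format kinetic curve data frame (`time`, `signal`,
#'   `compound`, `dose`, `replicate`).
#' @param control_label Compound label of the control curves.
#' @param endpoint Endpoint in minutes (default 1000).
#' @param properties Optional property data frame
#'   ([read_property_table()]).
#' @param n_perm,seed Permutation settings for [rank_association()].
#' @param outdir Optional output directory.
#' @return A list of class `potency_report`: `potency` (table),
#'   `dose_response`, `sar` (or `NULL`), `params`.
#' @export
potency_report <- function(curves, control_label = "control",
                           endpoint = 1000, properties = NULL,
                           n_perm = 999, seed = 1, outdir = NULL) {
  dr <- dose_response(curves, control_label, endpoint)
  pot <- potency_table(curves, control_label, endpoint)
  sar <- NULL
  if (!is.null(properties)) {
    # one potency value per compound: its best (smallest) defined
    # relative concentration
    ok <- pot[!pot$non_inhibitor & is.finite(pot$relative_concentration), ]
    pmap <- tapply(ok$relative_concentration, ok$compound, min)
    pvec <- stats::setNames(as.numeric(pmap), names(pmap))
    overlap <- intersect(properties$compound, names(pvec))
    if (length(overlap) >= 4L) {
      sar <- rank_association(properties, pvec, n_perm = n_perm, seed = seed)
    } else {
      warning("only ", length(overlap), " compounds overlap between the ",
              "property table and the potency results; SAR skipped")
    }
  }
  params <- list(control_label = control_label, endpoint = endpoint,
                 n_perm = n_perm, seed = seed)
  rep <- structure(list(potency = pot, dose_response = dr, sar = sar,
                        params = params), class = "potency_report")
  if (!is.null(outdir)) write_potency_report(rep, outdir)
  rep
}

#' @export
print.potency_report <- function(x, ...) {
  cat("Potency at", x$params$endpoint, "min (relative concentration in",
      "mM per 1% inhibition):\n")
  print(x$potency, digits = 4)
  if (!is.null(x$sar)) {
    cat("Descriptor-potency rank association:\n")
    print(as.data.frame(x$sar), digits = 4)
  }
  invisible(x)
}

#' Write a potency report bundle
#' @param report A `potency_report`.
#' @param outdir Output directory (created if missing).
#' @return The summary-file path, invisibly.
#' @export
write_potency_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$potency, file.path(outdir, "potency.csv"),
                   row.names = FALSE)
  utils::write.csv(report$dose_response$table,
                   file.path(outdir, "dose_response.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$dose_response$matrix),
                   file.path(outdir, "dose_response_matrix.csv"))
  if (!is.null(report$sar)) {
    utils::write.csv(as.data.frame(report$sar),
                     file.path(outdir, "sar_association.csv"),
                     row.names = FALSE)
  }
  summary <- list(provenance = .provenance(report$params),
                  potency = report$potency,
                  sar = if (!is.null(report$sar)) as.data.frame(report$sar))
  path <- file.path(outdir, "summary.json")
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
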
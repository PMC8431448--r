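# Stacking-angle distributions: the acute angle between least-squares ring
# plane normals of molecule pairs in COM contact, pooled over a
# metatrajectory. Near-zero angles indicate ordered pi-stacking.

#' Stacking-angle distribution over a metatrajectory
#'
#' For every frame (optionally strided), finds molecule pairs of the requested
#' species combination in COM contact and records the acute angle between
#' their ring-plane normals. Summaries: normalized histogram, mean, sample
#' standard deviation (`dispersion`), RMS angle about perfect alignment
#' (`rms_angle`) and the fraction of samples below the stacking threshold
#' (`stacked_fraction`).
#'
#' @param traj An `md_trajectory` (typically a metatrajectory from
#'   [build_metatrajectory()]).
#' @param species_pair Length-2 character vector of the species whose pair
#'   angles are sampled (default adenine-adenine).
#' @param cutoff Contact cutoff in Angstrom.
#' @param stack_threshold Angle (degrees) below which a pair counts as
#'   stacked; default 30 (conventional pi-stacking tolerance).
#' @param breaks Histogram bin edges in degrees (default 18 bins of 5).
#' @param stride Analyze every `stride`-th frame.
#' @return An object of class `angle_distribution`: list with `samples`
#'   (data frame `frame`, `i`, `j`, `angle`), `histogram` (data frame with
#'   bin edges, counts and density integrating to 1), `mean`, `dispersion`,
#'   `rms_angle`, `stacked_fraction`, `n`, `stack_threshold`, `empty` flag.
#'   With no contacts anywhere the result is flagged `empty = TRUE` with `NA`
#'   statistics (not an error).
#' @export
angle_distribution <- function(traj, species_pair = c("adenine", "adenine"),
                               cutoff = 6.0, stack_threshold = 30,
                               breaks = seq(0, 90, by = 5), stride = 1L) {
  stopifnot(length(species_pair) == 2L, stack_threshold > 0)
  have <- unique(traj$topology$molecules$species)
  missing_sp <- setdiff(unique(species_pair), have)
  if (length(missing_sp) > 0) {
    stop("species not in topology: ", paste(missing_sp, collapse = ", "))
  }
  frames <- seq(1L, n_frames(traj), by = stride)
  samp <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    f <- frames[k]
    cs <- contact_pairs(traj, f, cutoff = cutoff, species_pair = species_pair)
    if (nrow(cs) == 0) next
    mols <- sort(unique(c(cs$i, cs$j)))
    normals <- lapply(mols, function(m) plane_normal(traj, f, m))
    names(normals) <- mols
    ang <- mapply(function(i, j) {
      pair_angle(normals[[as.character(i)]], normals[[as.character(j)]])
    }, cs$i, cs$j)
    samp[[k]] <- data.frame(frame = f, i = cs$i, j = cs$j, angle = ang)
  }
  samples <- do.call(rbind, samp)
  if (is.null(samples)) {
    samples <- data.frame(frame = integer(0), i = integer(0),
                          j = integer(0), angle = numeric(0))
  }
  .angle_distribution_from_samples(samples, breaks, stack_threshold,
                                   species_pair)
}

# build the summary object from raw angle samples
.angle_distribution_from_samples <- function(samples, breaks = seq(0, 90, 5),
                                             stack_threshold = 30,
                                             species_pair = NULL) {
  n <- nrow(samples)
  if (n == 0) {
    return(structure(list(samples = samples, histogram = NULL,
                          mean = NA_real_, dispersion = NA_real_,
                          rms_angle = NA_real_, stacked_fraction = NA_real_,
                          n = 0L, stack_threshold = stack_threshold,
                          species_pair = species_pair, empty = TRUE),
                     class = "angle_distribution"))
  }
  a <- samples$angle
  h <- graphics::hist(a, breaks = breaks, plot = FALSE)
  histogram <- data.frame(lower = utils::head(h$breaks, -1),
                          upper = utils::tail(h$breaks, -1),
                          count = h$counts, density = h$density)
  structure(list(samples = samples, histogram = histogram,
                 mean = mean(a), dispersion = stats::sd(a),
                 rms_angle = sqrt(mean(a^2)),
                 stacked_fraction = mean(a < stack_threshold),
                 n = n, stack_threshold = stack_threshold,
                 species_pair = species_pair, empty = FALSE),
            class = "angle_distribution")
}

#' @export
print.angle_distribution <- function(x, ...) {
  if (x$empty) {
    cat("Angle distribution: empty (no contacts sampled)\n")
    return(invisible(x))
  }
  cat(sprintf(paste0(
    "Angle distribution (%s-%s): n = %d pair samples\n",
    "  mean %.2f deg, sd %.2f deg, rms %.2f deg\n",
    "  stacked fraction (< %g deg): %.3f\n"),
    x$species_pair[1], x$species_pair[2], x$n, x$mean, x$dispersion,
    x$rms_angle, x$stack_threshold, x$stacked_fraction))
  invisible(x)
}

#' Plot a stacking-angle histogram
#' @param x An `angle_distribution`.
#' @param ... Passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.angle_distribution <- function(x, ...) {
  if (x$empty) stop("empty angle distribution; nothing to plot")
  h <- x$histogram
  graphics::barplot(h$density, names.arg = sprintf("%g", h$lower),
                    xlab = "angle between ring normals (deg)",
                    ylab = "density", border = NA, space = 0, ...)
  invisible(x)
}

#' Compare orientational heterogeneity of two angle distributions
#'
#' Quantifies how much more orientationally disordered one ensemble is than
#' another: differences (b minus a) in mean, dispersion and stacked fraction,
#' plus the two-sample Kolmogorov-Smirnov statistic on the raw angle samples.
#'
#' @param dist_a,dist_b Non-empty `angle_distribution` objects (e.g. pure
#'   monomer vs monomer + inhibitor conditions).
#' @return A list of class `heterogeneity_comparison` with `mean_diff`,
#'   `dispersion_diff`, `stacked_fraction_diff`, `ks_statistic`, `ks_p_value`,
#'   `n_a`, `n_b`.
#' @export
heterogeneity_compare <- function(dist_a, dist_b) {
  stopifnot(inherits(dist_a, "angle_distribution"),
            inherits(dist_b, "angle_distribution"))
  if (dist_a$empty || dist_b$empty) {
    stop("both angle distributions must be non-empty")
  }
  ks <- suppressWarnings(
    stats::ks.test(dist_a$samples$angle, dist_b$samples$angle))
  structure(list(
    mean_diff = dist_b$mean - dist_a$mean,
    dispersion_diff = dist_b$dispersion - dist_a$dispersion,
    stacked_fraction_diff = dist_b$stacked_fraction - dist_a$stacked_fraction,
    ks_statistic = unname(ks$statistic),
    ks_p_value = ks$p.value,
    n_a = dist_a$n, n_b = dist_b$n
  ), class = "heterogeneity_comparison")
}

#' @export
print.heterogeneity_comparison <- function(x, ...) {
  cat(sprintf(paste0(
    "Heterogeneity comparison (b - a):\n",
    "  mean angle:       %+8.3f deg\n",
    "  dispersion (sd):  %+8.3f deg\n",
    "  stacked fraction: %+8.3f\n",
    "  KS statistic:     %8.3f (p = %.3g), n = %d vs %d\n"),
    x$mean_diff, x$dispersion_diff, x$stacked_fraction_diff,
    x$ks_statistic, x$ks_p_value, x$n_a, x$n_b))
  invisible(x)
}
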
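# Synthetic-data generators with recorded ground truth. Trajectories emulate
# the statistical structure the analysis assumes: stacked clusters of planar
# molecules with controllable angular noise, inhibitor-"hijacked" disordered
# pairs, free monomers and planted hydrogen-bond geometries. Kinetic curves
# emulate sigmoidal dye-binding assays with dose-dependent endpoint
# inhibition and Gaussian noise.

#' Trajectory generator configuration
#'
#' Defaults mirror the simulated study conditions: 44 planar monomers (40
#' plus 5 inhibitors for the inhibited system) in a 100 Angstrom cubic box,
#' stacks with 3.4 Angstrom inter-plane rise.
#'
#' @param n_monomer Number of planar monomer ("adenine") molecules.
#' @param n_inhibitor Number of inhibitor molecules.
#' @param box_edge Cubic box edge (Angstrom).
#' @param n_frames Number of frames; frames are independent configurations.
#' @param stack_mean_size Mean molecules per stack (Poisson, truncated to
#'   1..6; size-1 draws become free monomers).
#' @param stack_angle_sigma Angular noise (degrees): within a stack, every
#'   second molecule is tilted by a draw from |N(0, sigma)| about a random
#'   in-plane axis, so each adjacent in-stack pair's true angle equals the
#'   drawn perturbation exactly.
#' @param hijack_fraction Fraction of monomers placed in inhibitor-capped
#'   disordered pairs: two monomers in COM contact (5 Angstrom) with
#'   isotropic orientations plus an inhibitor capping one of them.
#' @param hbond_plant_rate Fraction of frames in which an intra-ring-oxygen
#'   hydrogen bond (D-A 2.9 Angstrom, D-H...A 180 degrees) is planted between
#'   a monomer donor and an inhibitor; requires `n_inhibitor >= 1`.
#' @param stack_rise Inter-plane spacing within stacks (Angstrom).
#' @param time_step Frame spacing (ns) for the generated time stamps.
#' @param seed Master seed; each frame uses an independent substream.
#' @return A validated list of class `traj_gen_config`.
#' @export
traj_gen_config <- function(n_monomer = 44, n_inhibitor = 0, box_edge = 100,
                            n_frames = 100, stack_mean_size = 4,
                            stack_angle_sigma = 10, hijack_fraction = 0,
                            hbond_plant_rate = 0, stack_rise = 3.4,
                            time_step = 1, seed = 1) {
  stopifnot(n_monomer >= 0, n_inhibitor >= 0, n_frames >= 1,
            box_edge > 0, stack_mean_size >= 1, stack_angle_sigma >= 0,
            time_step > 0)
  if (stack_rise <= 3 || stack_rise >= 6) {
    # contact bookkeeping assumes nearest in-stack neighbours sit inside the
    # 6 A cutoff and second neighbours (2 x rise) outside it
    stop("stack_rise must lie in (3, 6) Angstrom")
  }
  if (hijack_fraction < 0 || hijack_fraction > 1) {
    stop("hijack_fraction must be in [0, 1]")
  }
  if (hbond_plant_rate < 0 || hbond_plant_rate > 1) {
    stop("hbond_plant_rate must be in [0, 1]")
  }
  if (hbond_plant_rate > 0 && n_inhibitor < 1) {
    stop("hbond_plant_rate > 0 requires at least one inhibitor molecule")
  }
  ext <- 2 * max(sqrt(rowSums(mock_coordinates("adenine")^2)),
                 sqrt(rowSums(mock_coordinates("inhibitor")^2)))
  if (box_edge <= 2 * ext) {
    stop("box_edge must exceed twice the largest molecule extent (",
         round(2 * ext, 1), " A)")
  }
  structure(list(n_monomer = n_monomer, n_inhibitor = n_inhibitor,
                 box_edge = box_edge, n_frames = n_frames,
                 stack_mean_size = stack_mean_size,
                 stack_angle_sigma = stack_angle_sigma,
                 hijack_fraction = hijack_fraction,
                 hbond_plant_rate = hbond_plant_rate,
                 stack_rise = stack_rise, time_step = time_step, seed = seed),
            class = "traj_gen_config")
}

# rotation aligning unit vector `from` onto unit vector `to`
.align_rotation <- function(from, to) {
  d <- sum(from * to)
  if (d > 1 - 1e-12) return(diag(3))
  if (d < -1 + 1e-12) {
    # 180-degree turn about any axis perpendicular to `from`
    perp <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- perp - sum(perp * from) * from
    return(rotation_about(ax, pi))
  }
  rotation_about(crossprod3(from, to), acos(d))
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# random unit vector perpendicular to a
.random_perp <- function(a) {
  repeat {
    v <- random_unit()
    w <- v - sum(v * a) * a
    if (sqrt(sum(w^2)) > 1e-6) return(w / sqrt(sum(w^2)))
  }
}

#' Generate a synthetic trajectory with ground truth
#'
#' Builds one replica of independent frames. Each frame partitions the
#' monomers into stacks (ordered, with controlled angular noise), hijacked
#' monomer-inhibitor pairs (disordered) and free monomers, places the units
#' on a jittered lattice guaranteeing inter-unit COM separation beyond 6
#' Angstrom, and optionally plants an intra-ring-oxygen hydrogen bond.
#' Non-planted inhibitor orientations are rejection-sampled so that their
#' intra-ring oxygen never comes within hydrogen-bonding range of a monomer
#' donor, making the planted occupancy exactly recoverable.
#'
#' @param config A [traj_gen_config()].
#' @param replica_id Replica label stored on the frames.
#' @param t_start Time (ns) of the frame before the first.
#' @return A list of class `synthetic_trajectory`: `trajectory` (an
#'   `md_trajectory`) and `truth`, a list with `config`, `planted_frames`
#'   (integer vector) and per-frame records `frames[[f]]` holding `partition`
#'   (list of monomer-index vectors), `contacts` (monomer-monomer contact
#'   pairs), `angles` (data frame `i`, `j`, `angle` of true adjacent-pair
#'   angles and hijacked-pair angles) and `planted` (logical).
#' @export
generate_trajectory <- function(config, replica_id = "r1", t_start = 0) {
  stopifnot(inherits(config, "traj_gen_config"))
  top <- system_topology(
    list(mock_adenine_spec(), mock_inhibitor_spec()),
    c(config$n_monomer, config$n_inhibitor),
    box = rep(config$box_edge, 3), time_step = config$time_step)
  tmpl_a <- mock_coordinates("adenine")
  tmpl_i <- mock_coordinates("inhibitor")
  n_atoms <- nrow(top$atoms)
  set.seed(config$seed)
  frame_seeds <- sample.int(.Machine$integer.max - 1L, config$n_frames)
  coords <- vector("list", config$n_frames)
  frames_truth <- vector("list", config$n_frames)
  for (f in seq_len(config$n_frames)) {
    set.seed(frame_seeds[f])
    fr <- .generate_frame(config, top, tmpl_a, tmpl_i, n_atoms)
    coords[[f]] <- fr$xyz
    frames_truth[[f]] <- fr$truth
  }
  traj <- trajectory(top, coords, box = rep(config$box_edge, 3),
                     time = t_start + seq_len(config$n_frames) *
                       config$time_step,
                     replica = replica_id)
  structure(list(
    trajectory = traj,
    truth = list(config = config,
                 planted_frames = which(vapply(frames_truth, `[[`, TRUE,
                                               "planted")),
                 frames = frames_truth)
  ), class = "synthetic_trajectory")
}

# one frame: partition molecules into units, build local geometry, place on
# a jittered lattice; returns coordinates and the frame's truth record
.generate_frame <- function(config, top, tmpl_a, tmpl_i, n_atoms) {
  nm <- config$n_monomer; ni <- config$n_inhibitor
  sigma <- config$stack_angle_sigma
  rise <- config$stack_rise
  planted <- ni > 0 && stats::runif(1) < config$hbond_plant_rate
  n_hijack <- min(floor(config$hijack_fraction * nm / 2), ni)
  mono_pool <- seq_len(nm)
  inh_pool <- nm + seq_len(ni)
  units <- list()
  take_mono <- function(k) {
    out <- mono_pool[seq_len(k)]; mono_pool <<- mono_pool[-seq_len(k)]; out
  }
  take_inh <- function(k) {
    out <- inh_pool[seq_len(k)]; inh_pool <<- inh_pool[-seq_len(k)]; out
  }
  plant_host <- if (planted && n_hijack > 0) 1L else 0L
  for (h in seq_len(n_hijack)) {
    units[[length(units) + 1L]] <-
      list(type = "hijack", mono = take_mono(2L), inh = take_inh(1L),
           plant = h == plant_host)
  }
  if (planted && n_hijack == 0L) {
    units[[length(units) + 1L]] <-
      list(type = "plant_pair", mono = take_mono(1L), inh = take_inh(1L),
           plant = TRUE)
  }
  while (length(mono_pool) > 0L) {
    s <- min(length(mono_pool), max(1L, min(6L, stats::rpois(1, config$stack_mean_size))))
    units[[length(units) + 1L]] <-
      list(type = if (s > 1L) "stack" else "free_mono",
           mono = take_mono(s), inh = integer(0), plant = FALSE)
  }
  while (length(inh_pool) > 0L) {
    units[[length(units) + 1L]] <-
      list(type = "free_inh", mono = integer(0), inh = take_inh(1L),
           plant = FALSE)
  }
  # local geometry per unit
  built <- lapply(units, .build_unit, config = config, tmpl_a = tmpl_a,
                  tmpl_i = tmpl_i, sigma = sigma, rise = rise)
  # lattice placement
  r_unit <- vapply(built, `[[`, numeric(1), "radius")
  r_max <- max(r_unit)
  spacing <- 2 * r_max + 6.0 + 1.0
  npd <- floor(config$box_edge / spacing)
  if (npd^3 < length(built)) {
    stop("cannot place ", length(built), " molecular units without contact ",
         "overlap in a ", config$box_edge, " A box; increase box_edge or ",
         "reduce molecule counts")
  }
  offset <- (config$box_edge - npd * spacing) / 2
  sites <- as.matrix(expand.grid(seq_len(npd), seq_len(npd), seq_len(npd)))
  centers <- offset + (sites - 0.5) * spacing
  pick <- sample.int(nrow(centers), length(built))
  xyz <- matrix(NA_real_, n_atoms, 3)
  angles <- list(); contacts <- list(); partition <- list()
  a_tab <- top$atoms
  first_atom <- a_tab$atom[!duplicated(a_tab$mol)]
  for (u in seq_along(built)) {
    b <- built[[u]]
    center <- centers[pick[u], ] + stats::runif(3, -0.25, 0.25)
    for (k in seq_along(b$mols)) {
      mol <- b$mols[k]
      rows <- first_atom[mol] + seq_len(nrow(b$coords[[k]])) - 1L
      xyz[rows, ] <- sweep(b$coords[[k]], 2, center, `+`)
    }
    if (nrow(b$angles) > 0) angles[[length(angles) + 1L]] <- b$angles
    if (nrow(b$contacts) > 0) contacts[[length(contacts) + 1L]] <- b$contacts
    if (length(b$mono_groups) > 0) partition <- c(partition, b$mono_groups)
  }
  if (anyNA(xyz)) stop("internal error: unplaced atoms")
  list(xyz = xyz,
       truth = list(
         partition = partition,
         contacts = if (length(contacts)) do.call(rbind, contacts)
                    else data.frame(i = integer(0), j = integer(0)),
         angles = if (length(angles)) do.call(rbind, angles)
                  else data.frame(i = integer(0), j = integer(0),
                                  angle = numeric(0)),
         planted = planted))
}

# geometry of one unit in its local frame (centered near the origin);
# returns molecule ids, per-molecule atom coordinates, truth angles/contacts,
# the monomer partition groups it contributes, and a bounding radius
.build_unit <- function(unit, config, tmpl_a, tmpl_i, sigma, rise) {
  mols <- c(unit$mono, unit$inh)
  coords <- list()
  angles <- data.frame(i = integer(0), j = integer(0), angle = numeric(0))
  contacts <- data.frame(i = integer(0), j = integer(0))
  mono_groups <- list()
  if (unit$type == "stack") {
    m <- length(unit$mono)
    axis <- random_unit()
    align <- .align_rotation(c(0, 0, 1), axis)
    tilt_deg <- rep(0, m)
    for (k in seq_len(m)) {
      pos <- axis * ((k - 1) - (m - 1) / 2) * rise
      spin <- rotation_about(axis, stats::runif(1, 0, 2 * pi))
      R <- spin %*% align
      if (k %% 2L == 0L) {
        th <- abs(stats::rnorm(1, 0, sigma))
        tilt_deg[k] <- min(th, abs(180 - th))   # axial fold
        R <- rotation_about(.random_perp(axis), th * pi / 180) %*% R
      }
      coords[[k]] <- sweep(tmpl_a %*% t(R), 2, pos, `+`)
    }
    if (m > 1) {
      adj <- cbind(unit$mono[-m], unit$mono[-1])
      # adjacent pair (k, k+1): the even-indexed member carries the tilt
      angles <- data.frame(i = adj[, 1], j = adj[, 2],
                           angle = vapply(seq_len(m - 1), function(k) {
                             tilt_deg[if (k %% 2L == 0L) k else k + 1L]
                           }, numeric(1)))
      contacts <- data.frame(i = adj[, 1], j = adj[, 2])
    }
    mono_groups <- list(unit$mono)
  } else if (unit$type %in% c("hijack", "plant_pair")) {
    u <- random_unit()
    two <- unit$type == "hijack"
    posA <- if (two) -2.5 * u else c(0, 0, 0)
    R1 <- random_rotation()
    coords[[1]] <- sweep(tmpl_a %*% t(R1), 2, posA, `+`)
    n1 <- R1 %*% c(0, 0, 1)
    if (two) {
      posB <- 2.5 * u
      R2 <- random_rotation()
      coords[[2]] <- sweep(tmpl_a %*% t(R2), 2, posB, `+`)
      n2 <- R2 %*% c(0, 0, 1)
      angles <- data.frame(i = unit$mono[1], j = unit$mono[2],
                           angle = acos(min(1, abs(sum(n1 * n2)))) * 180 / pi)
      contacts <- data.frame(i = unit$mono[1], j = unit$mono[2])
      mono_groups <- list(unit$mono)
    } else {
      mono_groups <- list(unit$mono[1])
    }
    donors <- list(A = list(N = coords[[1]][10, ], H = coords[[1]][11, ]))
    if (two) donors$B <- list(N = coords[[2]][10, ], H = coords[[2]][11, ])
    o_vec <- tmpl_i[4, ]                     # intra-ring oxygen offset
    o_len <- sqrt(sum(o_vec^2))
    if (unit$plant) {
      NA_ <- donors$A$N; H_ <- donors$A$H
      uhat <- (H_ - NA_) / sqrt(sum((H_ - NA_)^2))
      O_pos <- NA_ + 2.9 * uhat
      v <- posA - O_pos; v <- v / sqrt(sum(v^2))
      spin <- rotation_about(v, stats::runif(1, 0, 2 * pi))
      R_i <- spin %*% .align_rotation(o_vec / o_len, -v)
      com_i <- O_pos + o_len * v
      coords[[length(coords) + 1L]] <- sweep(tmpl_i %*% t(R_i), 2, com_i, `+`)
    } else {
      # keep the intra-ring oxygen clear of every donor (margin over the
      # default 3.5 A criterion) so only planted frames carry that class
      repeat {
        w <- .random_perp(u)
        com_i <- posA + 4.0 * w
        R_i <- random_rotation()
        O_pos <- as.vector(R_i %*% o_vec) + com_i
        dmin <- min(vapply(donors, function(d) {
          sqrt(sum((O_pos - d$N)^2))
        }, numeric(1)))
        if (dmin > 3.9) break
      }
      coords[[length(coords) + 1L]] <- sweep(tmpl_i %*% t(R_i), 2, com_i, `+`)
    }
  } else if (unit$type == "free_mono") {
    coords[[1]] <- tmpl_a %*% t(random_rotation())
    mono_groups <- list(unit$mono)
  } else {                                   # free inhibitor
    coords[[1]] <- tmpl_i %*% t(random_rotation())
  }
  radius <- max(vapply(coords, function(x) max(sqrt(rowSums(x^2))),
                       numeric(1)))
  list(mols = mols, coords = coords, angles = angles, contacts = contacts,
       mono_groups = mono_groups, radius = radius + 0.1)
}

#' Kinetics generator configuration
#'
#' @param baseline Baseline fluorescence (a.u.).
#' @param amplitude Control curve amplitude (a.u., > 0).
#' @param rate Logistic growth rate (1/min).
#' @param t_half Half-rise time (min).
#' @param noise_sigma Gaussian measurement noise s.d. (a.u.).
#' @param doses Doses in mM.
#' @param inhibition_map True endpoint inhibition (%) per dose, parallel to
#'   `doses`; values in (-100, 100] (negative = acceleration).
#' @param n_replicates Replicates per condition.
#' @param times Sampling times (min).
#' @param compound Label for the treated curves.
#' @param seed Master seed; each replicate curve uses its own substream.
#' @return A validated list of class `kinetic_gen_config`.
#' @export
kinetic_gen_config <- function(baseline = 50, amplitude = 1000, rate = 0.02,
                               t_half = 500, noise_sigma = 0, doses = numeric(0),
                               inhibition_map = numeric(0), n_replicates = 3,
                               times = seq(0, 1500, by = 10),
                               compound = "inhibitor", seed = 1) {
  stopifnot(amplitude > 0, rate > 0, noise_sigma >= 0, n_replicates >= 1,
            length(doses) == length(inhibition_map), length(times) >= 6)
  if (length(inhibition_map) &&
      (any(inhibition_map <= -100) || any(inhibition_map > 100))) {
    stop("inhibition percentages must lie in (-100, 100]")
  }
  structure(list(baseline = baseline, amplitude = amplitude, rate = rate,
                 t_half = t_half, noise_sigma = noise_sigma, doses = doses,
                 inhibition_map = inhibition_map,
                 n_replicates = n_replicates, times = times,
                 compound = compound, seed = seed),
            class = "kinetic_gen_config")
}

#' Generate synthetic aggregation kinetics with ground truth
#'
#' Control curves follow `baseline + amplitude / (1 + exp(-rate * (t -
#' t_half)))`; each dose scales the amplitude by `1 - inhibition/100` so the
#' true endpoint inhibition equals the configured map exactly in the
#' noiseless limit. Gaussian noise and replicates are drawn from per-curve
#' substreams of the master seed, so regeneration is byte-identical.
#'
#' @param config A [kinetic_gen_config()].
#' @return A list of class `synthetic_kinetics`: `curves` (long data frame:
#'   `time`, `signal`, `compound`, `dose`, `replicate`; control rows have
#'   `compound = "control"`) and `truth` (`config` plus the dose ->
#'   inhibition map).
#' @export
generate_kinetics <- function(config) {
  stopifnot(inherits(config, "kinetic_gen_config"))
  logistic <- function(t) 1 / (1 + exp(-config$rate * (t - config$t_half)))
  set.seed(config$seed)
  n_curves <- (1 + length(config$doses)) * config$n_replicates
  curve_seeds <- sample.int(.Machine$integer.max - 1L, n_curves)
  out <- list(); cs <- 0L
  shape <- logistic(config$times)
  for (r in seq_len(config$n_replicates)) {
    cs <- cs + 1L; set.seed(curve_seeds[cs])
    sig <- config$baseline + config$amplitude * shape +
      stats::rnorm(length(config$times), 0, config$noise_sigma)
    out[[length(out) + 1L]] <- kinetic_curve(config$times, sig, "control",
                                             0, r)
  }
  for (d in seq_along(config$doses)) {
    amp <- config$amplitude * (1 - config$inhibition_map[d] / 100)
    for (r in seq_len(config$n_replicates)) {
      cs <- cs + 1L; set.seed(curve_seeds[cs])
      sig <- config$baseline + amp * shape +
        stats::rnorm(length(config$times), 0, config$noise_sigma)
      out[[length(out) + 1L]] <- kinetic_curve(config$times, sig,
                                               config$compound,
                                               config$doses[d], r)
    }
  }
  structure(list(curves = do.call(rbind, out),
                 truth = list(config = config, doses = config$doses,
                              inhibition = config$inhibition_map)),
            class = "synthetic_kinetics")
}
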
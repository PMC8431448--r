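# Geometric hydrogen-bond detection (donor-acceptor distance + D-H...A angle
# under the minimum image) and per-acceptor-class occupancy: the fraction of
# analyzed configurations containing at least one bond of the class.

#' Geometric hydrogen-bond criteria
#'
#' Common geometric defaults: donor-heavy to acceptor distance at most 3.5
#' Angstrom and a donor-hydrogen-acceptor angle of at least 120 degrees.
#'
#' @param max_da_distance Donor-heavy to acceptor cutoff (Angstrom, > 0).
#' @param min_dha_angle Minimum D-H...A angle at the hydrogen (degrees,
#'   in (0, 180]).
#' @return A list of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_da_distance = 3.5, min_dha_angle = 120) {
  stopifnot(max_da_distance > 0, min_dha_angle > 0, min_dha_angle <= 180)
  structure(list(max_da_distance = max_da_distance,
                 min_dha_angle = min_dha_angle), class = "hbond_criteria")
}

#' Detect intermolecular hydrogen bonds in one frame
#'
#' Scans every donor-hydrogen pair against every acceptor in a different
#' molecule and keeps the triples satisfying the geometric criteria. All
#' displacement vectors use the minimum image.
#'
#' Species without donor/acceptor annotations contribute nothing; a frame in
#' a system with no annotated donors or acceptors yields an empty event set
#' (so hydrophobic compounds run through the same pipeline), unless
#' `require_annotations = TRUE`.
#'
#' @param traj An `md_trajectory`.
#' @param frame Frame index.
#' @param criteria An [hbond_criteria()] object.
#' @param require_annotations If `TRUE`, error when the topology annotates no
#'   donors or no acceptors.
#' @return Data frame of events: `frame`, `donor_atom`, `hydrogen_atom`,
#'   `acceptor_atom`, `donor_mol`, `acceptor_mol`, `acceptor_class`,
#'   `da_distance`, `dha_angle`.
#' @export
detect_hbonds <- function(traj, frame, criteria = hbond_criteria(),
                          require_annotations = FALSE) {
  stopifnot(inherits(criteria, "hbond_criteria"))
  a <- traj$topology$atoms
  hyd <- a[a$hbond == "hydrogen", , drop = FALSE]
  acc <- a[a$hbond == "acceptor", , drop = FALSE]
  empty <- data.frame(frame = integer(0), donor_atom = integer(0),
                      hydrogen_atom = integer(0), acceptor_atom = integer(0),
                      donor_mol = integer(0), acceptor_mol = integer(0),
                      acceptor_class = character(0), da_distance = numeric(0),
                      dha_angle = numeric(0))
  if (nrow(hyd) == 0L || nrow(acc) == 0L) {
    if (require_annotations) {
      stop("topology annotates ", nrow(hyd), " polar hydrogens and ",
           nrow(acc), " acceptors; hydrogen-bond analysis needs both")
    }
    return(empty)
  }
  # resolve each hydrogen's donor heavy atom within its molecule
  don_idx <- vapply(seq_len(nrow(hyd)), function(k) {
    a$atom[a$mol == hyd$mol[k] & a$name == hyd$donor[k] & a$hbond == "donor"]
  }, integer(1))
  xyz <- traj$coords[[frame]]
  box <- traj$box[frame, ]
  nh <- nrow(hyd); na_ <- nrow(acc)
  hi <- rep(seq_len(nh), times = na_)
  ai <- rep(seq_len(na_), each = nh)
  keep <- hyd$mol[hi] != acc$mol[ai]
  hi <- hi[keep]; ai <- ai[keep]
  if (length(hi) == 0L) return(empty)
  D <- xyz[don_idx[hi], , drop = FALSE]
  H <- xyz[hyd$atom[hi], , drop = FALSE]
  A <- xyz[acc$atom[ai], , drop = FALSE]
  da <- min_image(A - D, box)
  da_dist <- sqrt(rowSums(da^2))
  hd <- min_image(D - H, box)
  ha <- min_image(A - H, box)
  cosang <- rowSums(hd * ha) /
    pmax(sqrt(rowSums(hd^2)) * sqrt(rowSums(ha^2)), 1e-12)
  dha <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  sel <- da_dist <= criteria$max_da_distance & dha >= criteria$min_dha_angle
  if (!any(sel)) return(empty)
  data.frame(frame = frame,
             donor_atom = don_idx[hi[sel]],
             hydrogen_atom = hyd$atom[hi[sel]],
             acceptor_atom = acc$atom[ai[sel]],
             donor_mol = hyd$mol[hi[sel]],
             acceptor_mol = acc$mol[ai[sel]],
             acceptor_class = ifelse(is.na(acc$acceptor_class[ai[sel]]),
                                     "unclassified",
                                     acc$acceptor_class[ai[sel]]),
             da_distance = da_dist[sel],
             dha_angle = dha[sel])
}

#' Hydrogen-bond occupancy over a metatrajectory
#'
#' Occupancy of an acceptor class is the fraction of analyzed frames
#' ("configurations") that contain at least one hydrogen bond of that class;
#' event multiplicity within a frame does not increase it. All classes are
#' computed in one pass; classes requested but absent from the topology
#' report occupancy 0.
#'
#' @param traj An `md_trajectory` (typically a metatrajectory).
#' @param criteria An [hbond_criteria()] object.
#' @param acceptor_class Optional character vector of classes to report
#'   (default: all classes annotated in the topology).
#' @param stride Analyze every `stride`-th frame.
#' @return A data frame of class `occupancy_result`: `acceptor_class`,
#'   `n_frames_analyzed`, `n_frames_with_event`, `occupancy`, plus attribute
#'   `events` holding all detected events.
#' @export
hbond_occupancy <- function(traj, criteria = hbond_criteria(),
                            acceptor_class = NULL, stride = 1L) {
  stopifnot(n_frames(traj) >= 1L)
  frames <- seq(1L, n_frames(traj), by = stride)
  top_classes <- unique(stats::na.omit(traj$topology$atoms$acceptor_class))
  classes <- if (is.null(acceptor_class)) top_classes
             else unique(acceptor_class)
  ev <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    ev[[k]] <- detect_hbonds(traj, frames[k], criteria)
  }
  events <- do.call(rbind, ev)
  hit <- function(cl) {
    if (is.null(events) || nrow(events) == 0) return(0L)
    length(unique(events$frame[events$acceptor_class == cl]))
  }
  classes <- as.character(classes)
  out <- data.frame(
    acceptor_class = classes,
    n_frames_analyzed = rep(length(frames), length(classes)),
    n_frames_with_event = vapply(classes, hit, integer(1)),
    row.names = NULL
  )
  out$occupancy <- out$n_frames_with_event / length(frames)
  structure(out, class = c("occupancy_result", "data.frame"),
            events = events)
}
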
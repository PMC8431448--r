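# Trajectory container and XYZ / multi-model PDB readers and writers.
# Internal units: Angstrom for lengths, ns for time. Boxes are orthorhombic.

#' Construct a trajectory
#'
#' @param topology An `md_topology`.
#' @param coords List of numeric matrices (n_atoms x 3), one per frame, in
#'   Angstrom.
#' @param box Numeric matrix (n_frames x 3) of box edges, or a length-3
#'   vector recycled to all frames; defaults to the topology's box.
#' @param time Numeric vector of frame times in ns; defaults to uniform
#'   spacing `topology$time_step`.
#' @param replica Replica label per frame (recycled).
#' @return An object of class `md_trajectory`.
#' @export
trajectory <- function(topology, coords, box = NULL, time = NULL,
                       replica = "r1") {
  stopifnot(inherits(topology, "md_topology"), is.list(coords))
  nf <- length(coords)
  na <- nrow(topology$atoms)
  for (i in seq_len(nf)) {
    if (!is.matrix(coords[[i]]) || nrow(coords[[i]]) != na ||
        ncol(coords[[i]]) != 3L) {
      stop("frame ", i, ": expected a ", na, " x 3 coordinate matrix")
    }
  }
  if (is.null(box)) box <- topology$box
  if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
  stopifnot(nrow(box) == nf, all(box > 0))
  if (is.null(time)) time <- seq_len(nf) * topology$time_step
  stopifnot(length(time) == nf)
  replica <- rep_len(replica, nf)
  for (r in unique(replica)) {
    tt <- time[replica == r]
    if (is.unsorted(tt)) stop("times must be non-decreasing within replica ", r)
  }
  structure(list(topology = topology, coords = coords, box = box,
                 time = as.numeric(time), replica = replica),
            class = "md_trajectory")
}

#' Number of frames in a trajectory
#' @param traj An `md_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$coords)

#' @export
print.md_trajectory <- function(x, ...) {
  cat("Trajectory:", n_frames(x), "frames,",
      nrow(x$topology$molecules), "molecules,",
      nrow(x$topology$atoms), "atoms\n")
  if (n_frames(x) > 0) {
    cat(sprintf("  time %.3f .. %.3f ns, replicas: %s\n",
                min(x$time), max(x$time),
                paste(unique(x$replica), collapse = ", ")))
  }
  invisible(x)
}

#' Subset trajectory frames
#'
#' Frames may be selected in any order (analyses treat frames as an
#' ensemble), so no time-monotonicity is enforced here.
#'
#' @param x An `md_trajectory`.
#' @param i Frame indices.
#' @param ... Ignored.
#' @return An `md_trajectory` with the selected frames.
#' @export
`[.md_trajectory` <- function(x, i, ...) {
  structure(list(topology = x$topology, coords = x$coords[i],
                 box = x$box[i, , drop = FALSE], time = x$time[i],
                 replica = x$replica[i]), class = "md_trajectory")
}

#' Read a trajectory from XYZ or multi-model PDB
#'
#' Dispatches on the file extension. XYZ comment lines may carry
#' `box=Lx,Ly,Lz`, `time=t` and `replica=id` tokens; PDB files use `CRYST1`
#' for the box and `MODEL`/`ENDMDL` for frames. When a file carries no box,
#' the topology's default box is used.
#'
#' @param path File path (`.xyz` or `.pdb`).
#' @param topology An `md_topology`; frame atom counts must match.
#' @return An `md_trajectory`.
#' @export
read_trajectory <- function(path, topology) {
  if (grepl("\\.xyz$", path, ignore.case = TRUE)) read_xyz(path, topology)
  else if (grepl("\\.pdb$", path, ignore.case = TRUE)) read_pdb(path, topology)
  else stop("unsupported trajectory format: ", path)
}

#' Write a trajectory to XYZ or multi-model PDB
#'
#' @param traj An `md_trajectory`.
#' @param path Output path (`.xyz` or `.pdb` selects the format).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  if (grepl("\\.xyz$", path, ignore.case = TRUE)) write_xyz(traj, path)
  else if (grepl("\\.pdb$", path, ignore.case = TRUE)) write_pdb(traj, path)
  else stop("unsupported trajectory format: ", path)
  invisible(path)
}

#' @rdname read_trajectory
#' @export
read_xyz <- function(path, topology) {
  lines <- readLines(path)
  na <- nrow(topology$atoms)
  coords <- list(); box <- list(); time <- c(); replica <- c()
  i <- 1L; fidx <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    fidx <- fidx + 1L
    if (is.na(n) || n != na) {
      stop("frame ", fidx, ": atom count ", lines[i],
           " does not match topology (", na, " atoms)")
    }
    if (i + 1L + n > length(lines)) {
      stop("frame ", fidx, ": truncated (", length(lines) - i - 1L, " of ",
           n, " atom lines present); ", fidx - 1L, " earlier frames were complete")
    }
    comment <- lines[i + 1L]
    bx <- .xyz_token(comment, "box")
    tm <- .xyz_token(comment, "time")
    rp <- .xyz_token(comment, "replica", numeric = FALSE)
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (anyNA(xyz)) stop("frame ", fidx, ": malformed coordinate line")
    coords[[fidx]] <- xyz
    box[[fidx]] <- if (is.null(bx)) topology$box else bx
    time[fidx] <- if (is.null(tm)) fidx * topology$time_step else tm
    replica[fidx] <- if (is.null(rp)) "r1" else rp
    i <- i + 2L + n
  }
  if (fidx == 0L) stop("no frames found in ", path)
  trajectory(topology, coords, box = do.call(rbind, box), time = time,
             replica = replica)
}

.xyz_token <- function(comment, key, numeric = TRUE) {
  m <- regmatches(comment,
                  regexpr(paste0(key, "=[^[:space:]]+"), comment))
  if (length(m) == 0L) return(NULL)
  val <- sub(paste0(key, "="), "", m)
  if (!numeric) return(val)
  out <- as.numeric(strsplit(val, ",")[[1]])
  if (anyNA(out)) stop("malformed ", key, "= token in XYZ comment")
  out
}

#' @rdname write_trajectory
#' @export
write_xyz <- function(traj, path) {
  el <- traj$topology$atoms$element
  con <- file(path, "w"); on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    xyz <- traj$coords[[f]]
    writeLines(as.character(nrow(xyz)), con)
    writeLines(sprintf("box=%.4f,%.4f,%.4f time=%.6f replica=%s",
                       traj$box[f, 1], traj$box[f, 2], traj$box[f, 3],
                       traj$time[f], traj$replica[f]), con)
    writeLines(sprintf("%-2s %12.6f %12.6f %12.6f",
                       el, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

# species -> 3-char PDB residue name
.resname <- function(species) {
  rn <- toupper(gsub("[^A-Za-z0-9]", "", species))
  substr(paste0(rn, "XXX"), 1, 3)
}

#' @rdname read_trajectory
#' @export
read_pdb <- function(path, topology) {
  lines <- readLines(path)
  na <- nrow(topology$atoms)
  box <- topology$box
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr) > 0) {
    box <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                        substr(cr[1], 25, 33)))
    if (anyNA(box) || any(box <= 0)) stop("malformed CRYST1 record")
  }
  atom_lines <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  frames <- list()
  if (length(model_starts) == 0L) {
    frames[[1]] <- which(atom_lines)
  } else {
    model_ends <- grep("^ENDMDL", lines)
    for (k in seq_along(model_starts)) {
      end <- if (k <= length(model_ends)) model_ends[k] else length(lines)
      rng <- seq(model_starts[k], end)
      frames[[k]] <- rng[atom_lines[rng]]
    }
  }
  coords <- list()
  for (f in seq_along(frames)) {
    ln <- lines[frames[[f]]]
    if (length(ln) != na) {
      stop("frame ", f, ": atom count ", length(ln),
           " does not match topology (", na, " atoms)")
    }
    xyz <- cbind(as.numeric(substr(ln, 31, 38)),
                 as.numeric(substr(ln, 39, 46)),
                 as.numeric(substr(ln, 47, 54)))
    if (anyNA(xyz)) stop("frame ", f, ": malformed coordinate fields")
    coords[[f]] <- xyz
  }
  trajectory(topology, coords, box = box)
}

#' @rdname write_trajectory
#' @export
write_pdb <- function(traj, path) {
  top <- traj$topology
  a <- top$atoms
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    traj$box[1, 1], traj$box[1, 2], traj$box[1, 3], 90, 90, 90), con)
  name4 <- sprintf("%-4s", substr(a$name, 1, 4))
  res <- .resname(a$species)
  for (f in seq_len(n_frames(traj))) {
    xyz <- traj$coords[[f]]
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "HETATM%5d %4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      ((a$atom - 1L) %% 99999L) + 1L, name4, res, ((a$mol - 1L) %% 9999L) + 1L,
      xyz[, 1], xyz[, 2], xyz[, 3], a$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Combine replica tails into a metatrajectory
#'
#' Discards the equilibration phase of each independent replica and
#' concatenates the retained tails into one ensemble ("metatrajectory") that
#' downstream analyses treat as a single sample of configurations. With four
#' 250-ns replicas and `retain_tail = 200` the result spans 800 ns.
#'
#' @param replicas A list of `md_trajectory` objects (or a single trajectory),
#'   one per independent replica.
#' @param retain_tail Duration (ns) of each replica's tail to retain. A frame
#'   at time t is retained when t > t_end - retain_tail; if the full replica
#'   span is requested, all frames are kept.
#' @return An `md_trajectory` whose frames are the retained tails in replica
#'   order, with replica labels preserved and attribute `retained_duration`
#'   equal to `length(replicas) * retain_tail`.
#' @export
build_metatrajectory <- function(replicas, retain_tail) {
  if (inherits(replicas, "md_trajectory")) replicas <- list(replicas)
  stopifnot(length(replicas) >= 1L, retain_tail > 0)
  eps <- 1e-9
  # replicas sharing a label (e.g. several defaults of "r1") are renamed
  # r1..rK so the combined ensemble keeps per-replica identity
  labels <- lapply(replicas, function(tr) unique(tr$replica))
  dup <- names(which(table(unlist(labels)) > 1))
  kept <- list()
  for (k in seq_along(replicas)) {
    tr <- replicas[[k]]
    stopifnot(inherits(tr, "md_trajectory"))
    if (any(labels[[k]] %in% dup)) tr$replica <- rep(paste0("r", k),
                                                     n_frames(tr))
    span <- max(tr$time) - min(tr$time)
    if (span < retain_tail - eps) {
      stop("replica ", k, " (", unique(tr$replica)[1], "): span ", span,
           " ns is shorter than retain_tail = ", retain_tail, " ns")
    }
    cutoff <- max(tr$time) - retain_tail
    idx <- if (cutoff <= min(tr$time) + eps) seq_len(n_frames(tr))
           else which(tr$time > cutoff + eps)
    kept[[k]] <- trajectory(tr$topology, tr$coords[idx],
                            box = tr$box[idx, , drop = FALSE],
                            time = tr$time[idx], replica = tr$replica[idx])
  }
  top <- kept[[1]]$topology
  out <- trajectory(
    top,
    do.call(c, lapply(kept, `[[`, "coords")),
    box = do.call(rbind, lapply(kept, `[[`, "box")),
    time = do.call(c, lapply(kept, `[[`, "time")),
    replica = do.call(c, lapply(kept, `[[`, "replica"))
  )
  attr(out, "retained_duration") <- length(replicas) * retain_tail
  out
}
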
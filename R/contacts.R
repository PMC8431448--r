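# Center-of-mass contact detection (cell list under periodic boundary
# conditions) and aggregate extraction as connected components of the
# contact graph. Two molecules are in contact when their minimum-image COM
# distance is strictly below the cutoff (default 6 Angstrom, i.e. 0.6 nm).

#' Center-of-mass contact pairs in one frame
#'
#' Detects all molecule pairs whose minimum-image COM distance is strictly
#' below `cutoff`, using a periodic cell list. Molecules participating can be
#' restricted by species, and pairs can further be restricted to a specific
#' species combination.
#'
#' @param traj An `md_trajectory`.
#' @param frame Frame index.
#' @param cutoff Contact cutoff in Angstrom (default 6.0 = 0.6 nm). Must be
#'   smaller than half the smallest box edge (minimum-image validity).
#' @param species Optional character vector: only molecules of these species
#'   participate.
#' @param species_pair Optional length-2 character vector: keep only pairs
#'   whose two species match this (unordered) combination, e.g.
#'   `c("adenine", "adenine")` or `c("adenine", "inhibitor")`.
#' @return An object of class `contact_set`: a data frame with columns `i`,
#'   `j` (molecule indices, `i < j`) and `dist`, with attributes
#'   `frame_index`, `cutoff` and `molecules` (the participating set).
#' @export
contact_pairs <- function(traj, frame, cutoff = 6.0, species = NULL,
                          species_pair = NULL) {
  stopifnot(cutoff > 0)
  box <- traj$box[frame, ]
  if (cutoff >= min(box) / 2) {
    stop("cutoff (", cutoff, " A) must be below half the smallest box edge (",
         min(box) / 2, " A) for the minimum image to be valid")
  }
  mols <- traj$topology$molecules
  if (!is.null(species_pair)) {
    stopifnot(length(species_pair) == 2L)
    species <- unique(c(species, species_pair))
  }
  if (!is.null(species)) mols <- mols[mols$species %in% species, , drop = FALSE]
  ids <- mols$mol
  out <- data.frame(i = integer(0), j = integer(0), dist = numeric(0))
  if (length(ids) >= 2L) {
    com <- molecule_com(traj, frame, ids)
    pr <- .cell_list_pairs(com, box, cutoff)
    if (nrow(pr) > 0) {
      out <- data.frame(i = ids[pr[, 1]], j = ids[pr[, 2]], dist = pr[, 3])
      swap <- out$i > out$j
      tmp <- out$i[swap]; out$i[swap] <- out$j[swap]; out$j[swap] <- tmp
      out <- out[order(out$i, out$j), , drop = FALSE]
      rownames(out) <- NULL
      if (!is.null(species_pair)) {
        sp <- mols$species[match(out$i, mols$mol)]
        sq <- mols$species[match(out$j, mols$mol)]
        want <- sort(species_pair)
        keep <- mapply(function(a, b) identical(sort(c(a, b)), want), sp, sq)
        out <- out[keep, , drop = FALSE]
      }
    }
  }
  structure(out, class = c("contact_set", "data.frame"),
            frame_index = frame, cutoff = cutoff, molecules = ids)
}

# cell-list neighbour search; com is an n x 3 matrix of wrapped positions.
# Returns matrix (k x 3): local index pairs and distances (< cutoff, strict).
.cell_list_pairs <- function(com, box, cutoff) {
  n <- nrow(com)
  nc <- pmax(1L, floor(box / cutoff))
  if (any(nc < 3L)) return(.brute_pairs(com, box, cutoff))
  cw <- box / nc
  cell <- floor(sweep(com, 2, cw, `/`))
  cell <- pmin(pmax(cell, 0L), matrix(nc - 1L, n, 3, byrow = TRUE))
  cid <- cell[, 1] + nc[1] * (cell[, 2] + nc[2] * cell[, 3])
  members <- split(seq_len(n), cid)
  occ <- as.integer(names(members))
  # decode occupied cells once
  dec <- cbind(occ %% nc[1], (occ %/% nc[1]) %% nc[2], occ %/% (nc[1] * nc[2]))
  res_i <- integer(0); res_j <- integer(0); res_d <- numeric(0)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  cid_index <- new.env(hash = TRUE)
  for (k in seq_along(occ)) assign(as.character(occ[k]), k, envir = cid_index)
  for (k in seq_along(occ)) {
    a <- members[[k]]
    for (o in seq_len(nrow(offs))) {
      nb <- (dec[k, ] + offs[o, ]) %% nc
      nb_id <- nb[1] + nc[1] * (nb[2] + nc[2] * nb[3])
      m <- mget(as.character(nb_id), envir = cid_index, ifnotfound = NA)[[1]]
      if (is.na(m) || m < k) next         # each cell pair handled once
      b <- members[[m]]
      if (m == k) {
        if (length(a) < 2L) next
        pr <- utils::combn(length(a), 2L)
        ii <- a[pr[1, ]]; jj <- a[pr[2, ]]
      } else {
        g <- expand.grid(a, b)
        ii <- g[, 1]; jj <- g[, 2]
      }
      d <- min_image(com[ii, , drop = FALSE] - com[jj, , drop = FALSE], box)
      dist <- sqrt(rowSums(d^2))
      sel <- dist < cutoff
      if (any(sel)) {
        res_i <- c(res_i, ii[sel]); res_j <- c(res_j, jj[sel])
        res_d <- c(res_d, dist[sel])
      }
    }
  }
  # self-cell pairs can also be seen via periodic neighbour offsets when a
  # cell is its own neighbour; deduplicate on the unordered pair
  if (length(res_i) > 0) {
    key <- paste(pmin(res_i, res_j), pmax(res_i, res_j))
    keep <- !duplicated(key)
    cbind(res_i[keep], res_j[keep], res_d[keep])
  } else {
    matrix(numeric(0), ncol = 3)
  }
}

# all-pairs fallback used when the box holds fewer than 3 cells per edge
.brute_pairs <- function(com, box, cutoff) {
  n <- nrow(com)
  if (n < 2L) return(matrix(numeric(0), ncol = 3))
  pr <- utils::combn(n, 2L)
  d <- min_image(com[pr[1, ], , drop = FALSE] - com[pr[2, ], , drop = FALSE],
                 box)
  dist <- sqrt(rowSums(d^2))
  sel <- dist < cutoff
  cbind(pr[1, sel], pr[2, sel], dist[sel])
}

#' Aggregates: connected components of the contact graph
#'
#' Partitions the participating molecules into aggregates (connected
#' components of the undirected contact graph); molecules without contacts
#' are singleton components.
#'
#' @param contacts A `contact_set` from [contact_pairs()].
#' @return An object of class `aggregate_report`: list with `frame_index`,
#'   `components` (list of integer vectors partitioning the molecule set),
#'   `sizes` (per-component sizes) and `size_histogram` (named count table).
#' @export
aggregates <- function(contacts) {
  stopifnot(inherits(contacts, "contact_set"))
  ids <- attr(contacts, "molecules")
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  if (nrow(contacts) > 0) {
    e <- rbind(match(contacts$i, ids), match(contacts$j, ids))
    g <- igraph::add_edges(g, as.vector(e))
  }
  memb <- igraph::components(g)$membership
  comps <- split(ids, memb)
  names(comps) <- NULL
  sizes <- lengths(comps)
  structure(list(frame_index = attr(contacts, "frame_index"),
                 components = comps, sizes = sizes,
                 size_histogram = table(sizes)),
            class = "aggregate_report")
}

#' @export
print.aggregate_report <- function(x, ...) {
  cat("Aggregates in frame", x$frame_index, ":", length(x$components),
      "components,", sum(x$sizes), "molecules\n")
  print(x$size_histogram)
  invisible(x)
}
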
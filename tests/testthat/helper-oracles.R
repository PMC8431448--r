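# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's optimized code paths.

# all-pairs minimum-image contact oracle on a COM matrix
oracle_contacts <- function(com, box, cutoff) {
  n <- nrow(com)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- com[i, ] - com[j, ]
      d <- d - box * round(d / box)
      if (sqrt(sum(d^2)) < cutoff) out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

# connected components by transitive closure of the adjacency matrix
oracle_components <- function(n, pairs) {
  A <- diag(n) > 0
  for (k in seq_len(nrow(pairs))) {
    A[pairs[k, 1], pairs[k, 2]] <- TRUE
    A[pairs[k, 2], pairs[k, 1]] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0 | A
    if (identical(A2, A)) break
    A <- A2
  }
  groups <- unique(apply(A, 1, function(r) paste(which(r), collapse = ",")))
  lapply(strsplit(groups, ","), as.integer)
}

# all-triples hydrogen-bond oracle on raw arrays
oracle_hbonds <- function(xyz, box, donors, hydrogens, acceptors,
                          don_mol, acc_mol, max_da, min_dha) {
  mi <- function(d) d - box * round(d / box)
  hits <- NULL
  for (k in seq_along(hydrogens)) {
    for (a in seq_along(acceptors)) {
      if (don_mol[k] == acc_mol[a]) next
      D <- xyz[donors[k], ]; H <- xyz[hydrogens[k], ]; A <- xyz[acceptors[a], ]
      da <- sqrt(sum(mi(A - D)^2))
      v1 <- mi(D - H); v2 <- mi(A - H)
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) *
        180 / pi
      if (da <= max_da && ang >= min_dha) {
        hits <- rbind(hits, c(hydrogen = hydrogens[k],
                              acceptor = acceptors[a]))
      }
    }
  }
  hits
}

# Spearman rho from first principles (no ties expected in the fixtures)
oracle_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# canonical form of a partition (list of sorted vectors, ordered by minimum)
canon_partition <- function(p) {
  s <- lapply(p, sort)
  s[order(vapply(s, `[`, numeric(1), 1))]
}

# a tiny two-species topology with hand-set coordinates for geometry tests:
# one "adenine" (ring + donor N + H) and one "inhibitor" molecule
tiny_system <- function(coords, box = c(100, 100, 100)) {
  top <- system_topology(list(mock_adenine_spec(), mock_inhibitor_spec()),
                         c(1, 1), box = box)
  trajectory(top, list(coords), box = box)
}

# random well-separated COM configuration wrapped into the box
random_com_frame <- function(n, box, seed) {
  set.seed(seed)
  matrix(runif(3 * n, 0, box), ncol = 3)
}
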
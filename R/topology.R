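# Molecular system descriptions: per-species atom metadata (masses, ring
# membership, hydrogen-bond roles) shared by every trajectory frame.

#' Atom specification
#'
#' Describes a single atom of a molecular species: its label, element, mass,
#' whether it belongs to the plane-defining ring set, and its hydrogen-bond
#' role.
#'
#' @param name Atom label (unique within the molecule).
#' @param element Chemical element symbol (must be a recognized symbol; see
#'   [molecular_weight()] for the embedded standard atomic-weight table).
#' @param mass Atomic mass in g/mol; must be positive.
#' @param ring Logical; `TRUE` if the atom belongs to the ring set used for
#'   least-squares plane fitting.
#' @param hbond Hydrogen-bond role: one of `"none"`, `"donor"` (donor heavy
#'   atom), `"hydrogen"` (polar hydrogen bound to a donor), `"acceptor"`.
#' @param donor For `hbond = "hydrogen"`, the `name` of the donor heavy atom
#'   this hydrogen is bound to (must exist in the same molecule).
#' @param acceptor_class For `hbond = "acceptor"`, a free-text class label
#'   used to group occupancy results (e.g. `"sulfur_bound_oxygen"`,
#'   `"intra_ring_oxygen"`).
#' @return A one-row data frame with the atom's fields.
#' @export
atom_spec <- function(name, element, mass, ring = FALSE, hbond = "none",
                      donor = NA_character_, acceptor_class = NA_character_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.character(element) || length(element) != 1L ||
      !(element %in% names(.atomic_weights))) {
    stop("atom '", name, "': unrecognized element symbol '", element, "'")
  }
  if (!is.numeric(mass) || length(mass) != 1L || is.na(mass) || mass <= 0) {
    stop("atom '", name, "': mass must be a positive number")
  }
  hbond <- match.arg(hbond, c("none", "donor", "hydrogen", "acceptor"))
  if (hbond == "hydrogen" && (is.na(donor) || !nzchar(donor))) {
    stop("atom '", name, "': a polar hydrogen must name its donor heavy atom")
  }
  data.frame(name = name, element = element, mass = as.numeric(mass),
             ring = isTRUE(ring), hbond = hbond,
             donor = donor, acceptor_class = acceptor_class,
             stringsAsFactors = FALSE)
}

#' Molecule (species) specification
#'
#' @param species Species identifier (e.g. `"adenine"`, `"inhibitor"`).
#' @param atoms A data frame of atoms as produced by rbind-ing [atom_spec()]
#'   rows, or a list of such rows.
#' @param formula Optional element-to-count map (named integer vector or a
#'   formula string such as `"C5H5N5"`); when given it is checked against the
#'   atom list for the elements the atom list contains.
#' @return An object of class `molecule_spec`.
#' @export
molecule_spec <- function(species, atoms, formula = NULL) {
  if (is.list(atoms) && !is.data.frame(atoms)) atoms <- do.call(rbind, atoms)
  stopifnot(is.data.frame(atoms))
  if (nrow(atoms) < 1L) stop("species '", species, "': needs at least one atom")
  if (anyDuplicated(atoms$name)) {
    stop("species '", species, "': duplicated atom names")
  }
  # every polar hydrogen must reference exactly one donor heavy atom
  hyd <- atoms[atoms$hbond == "hydrogen", , drop = FALSE]
  for (i in seq_len(nrow(hyd))) {
    d <- hyd$donor[i]
    hit <- which(atoms$name == d & atoms$hbond == "donor")
    if (length(hit) != 1L) {
      stop("species '", species, "': hydrogen '", hyd$name[i],
           "' must reference exactly one donor heavy atom (got '", d, "')")
    }
  }
  if (!is.null(formula)) {
    want <- if (is.character(formula)) parse_formula(formula) else formula
    have <- table(atoms$element)
    for (el in names(have)) {
      if (!is.na(want[el]) && !is.null(want[el]) && el %in% names(want) &&
          want[[el]] < have[[el]]) {
        stop("species '", species, "': formula lists fewer ", el,
             " atoms than the atom list contains")
      }
    }
  }
  structure(list(species = species, atoms = atoms, formula = formula),
            class = "molecule_spec")
}

#' Assemble a system topology from species specifications
#'
#' Builds the global atom indexing shared by all trajectory frames: molecules
#' are laid out species by species, `counts[i]` copies of `specs[[i]]`.
#'
#' @param specs List of [molecule_spec()] objects.
#' @param counts Integer vector, number of molecules per species.
#' @param box Default orthorhombic box edge lengths in Angstrom (length 3),
#'   used when a trajectory file carries no box record.
#' @param time_step Default frame spacing in ns for readers of formats that
#'   carry no time stamps (plain XYZ).
#' @return An object of class `md_topology` with components `atoms` (one row
#'   per atom: global index, molecule index, species, name, element, mass,
#'   ring, hbond, donor, acceptor_class), `molecules` (one row per molecule),
#'   `species` (per-species specs), `box`, `time_step`.
#' @export
system_topology <- function(specs, counts, box = c(100, 100, 100),
                            time_step = 1) {
  stopifnot(length(specs) == length(counts), all(counts >= 0))
  if (length(box) == 1L) box <- rep(box, 3L)
  stopifnot(length(box) == 3L, all(box > 0))
  atoms_list <- list(); mols_list <- list()
  mol_i <- 0L; atom_i <- 0L
  for (s in seq_along(specs)) {
    sp <- specs[[s]]
    stopifnot(inherits(sp, "molecule_spec"))
    na <- nrow(sp$atoms)
    for (k in seq_len(counts[s])) {
      mol_i <- mol_i + 1L
      a <- sp$atoms
      a$atom <- atom_i + seq_len(na)
      a$mol <- mol_i
      a$species <- sp$species
      atoms_list[[length(atoms_list) + 1L]] <- a
      mols_list[[length(mols_list) + 1L]] <-
        data.frame(mol = mol_i, species = sp$species,
                   first_atom = atom_i + 1L, n_atoms = na)
      atom_i <- atom_i + na
    }
  }
  atoms <- do.call(rbind, atoms_list)
  rownames(atoms) <- NULL
  structure(list(
    atoms = atoms[, c("atom", "mol", "species", "name", "element", "mass",
                      "ring", "hbond", "donor", "acceptor_class")],
    molecules = do.call(rbind, mols_list),
    species = stats::setNames(specs, vapply(specs, `[[`, "", "species")),
    box = as.numeric(box),
    time_step = time_step
  ), class = "md_topology")
}

#' @export
print.md_topology <- function(x, ...) {
  cnt <- table(x$molecules$species)
  cat("System topology:", nrow(x$molecules), "molecules,",
      nrow(x$atoms), "atoms\n")
  for (sp in names(cnt)) {
    natom <- nrow(x$species[[sp]]$atoms)
    nring <- sum(x$species[[sp]]$atoms$ring)
    cat(sprintf("  %s: %d molecules x %d atoms (%d ring atoms)\n",
                sp, cnt[[sp]], natom, nring))
  }
  cat(sprintf("  default box: %.1f x %.1f x %.1f A\n",
              x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Load a system topology from a configuration file
#'
#' Reads a YAML (or JSON) configuration describing the molecular species, the
#' number of copies of each, the periodic box and the default frame spacing.
#' Expected layout:
#' \preformatted{
#' box: [100, 100, 100]
#' time_step: 1.0
#' species:
#'   - name: adenine
#'     count: 44
#'     atoms:
#'       - {name: N1, element: N, mass: 14.007, ring: true}
#'       - {name: N10, element: N, mass: 14.007, hbond: donor}
#'       - {name: H10, element: H, mass: 1.008, hbond: hydrogen, donor: N10}
#' }
#'
#' @param path Path to the configuration file (`.yaml`/`.yml`/`.json`).
#' @return An `md_topology` object; see [system_topology()].
#' @export
load_topology <- function(path) {
  if (!file.exists(path)) stop("topology config not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$species)) stop("topology config has no 'species' section")
  specs <- list(); counts <- integer(0)
  for (sp in cfg$species) {
    if (is.null(sp$name)) stop("species entry without a 'name'")
    rows <- lapply(sp$atoms, function(a) {
      # YAML 1.1 parses bare N/Y as booleans; map them back to the elements
      if (is.logical(a$element)) a$element <- if (a$element) "Y" else "N"
      if (is.null(a$mass) || is.null(a$element)) {
        stop("species '", sp$name, "', atom '",
             if (is.null(a$name)) "?" else a$name,
             "': mass and element are required")
      }
      atom_spec(name = a$name, element = a$element, mass = a$mass,
                ring = isTRUE(a$ring),
                hbond = if (is.null(a$hbond)) "none" else a$hbond,
                donor = if (is.null(a$donor)) NA_character_ else a$donor,
                acceptor_class = if (is.null(a$acceptor_class))
                  NA_character_ else a$acceptor_class)
    })
    specs[[length(specs) + 1L]] <- molecule_spec(sp$name, rows,
                                                 formula = sp$formula)
    counts <- c(counts, if (is.null(sp$count)) 1L else as.integer(sp$count))
  }
  box <- if (is.null(cfg$box)) c(100, 100, 100) else unlist(cfg$box)
  ts <- if (is.null(cfg$time_step)) 1 else cfg$time_step
  system_topology(specs, counts, box = box, time_step = ts)
}

# ring-atom global indices for one molecule; errors if the ring set is
# too small for a plane fit
ring_atoms <- function(topology, mol) {
  a <- topology$atoms
  idx <- a$atom[a$mol == mol & a$ring]
  if (length(idx) < 3L) {
    sp <- topology$molecules$species[topology$molecules$mol == mol]
    stop("species '", sp, "' (molecule ", mol, "): ring set has fewer than ",
         "3 atoms; cannot fit a plane")
  }
  idx
}

#' Built-in mock planar monomer ("adenine") specification
#'
#' A rigid 9-atom ring (regular 9-gon, radius 1.4 Angstrom, alternating N/C
#' masses mimicking the purine scaffold) plus an exocyclic amine-like donor
#' nitrogen and its polar hydrogen. Geometric fidelity to real adenine is not
#' attempted; the template exercises plane fitting, COM contacts and H-bond
#' donation. Its reference coordinates are returned by [mock_coordinates()].
#'
#' @return A `molecule_spec` for species `"adenine"`.
#' @export
mock_adenine_spec <- function() {
  ring_el <- c("N", "C", "N", "C", "C", "C", "N", "C", "N")
  rows <- lapply(seq_along(ring_el), function(k) {
    el <- ring_el[k]
    atom_spec(name = paste0(el, k), element = el,
              mass = if (el == "N") 14.007 else 12.011, ring = TRUE)
  })
  rows <- c(rows, list(
    atom_spec("N10", "N", 14.007, hbond = "donor"),
    atom_spec("H10", "H", 1.008, hbond = "hydrogen", donor = "N10")
  ))
  molecule_spec("adenine", rows)
}

#' Built-in mock cyclic-sulfone inhibitor specification
#'
#' A six-membered mock ring containing sulfur and an intra-ring oxygen, with
#' two sulfur-bound oxygens; the three oxygens are hydrogen-bond acceptors
#' tagged with the classes `"sulfur_bound_oxygen"` and `"intra_ring_oxygen"`.
#' No ring atoms are flagged (the species is not plane-fitted).
#'
#' @return A `molecule_spec` for species `"inhibitor"`.
#' @export
mock_inhibitor_spec <- function() {
  rows <- list(
    atom_spec("S1", "S", 32.06),
    atom_spec("C1", "C", 12.011),
    atom_spec("C2", "C", 12.011),
    atom_spec("O3", "O", 15.999, hbond = "acceptor",
              acceptor_class = "intra_ring_oxygen"),
    atom_spec("C3", "C", 12.011),
    atom_spec("C4", "C", 12.011),
    atom_spec("O1", "O", 15.999, hbond = "acceptor",
              acceptor_class = "sulfur_bound_oxygen"),
    atom_spec("O2", "O", 15.999, hbond = "acceptor",
              acceptor_class = "sulfur_bound_oxygen")
  )
  molecule_spec("inhibitor", rows)
}

#' Reference coordinates of the built-in mock species
#'
#' Template geometry centered at the molecule's center of mass, in Angstrom.
#'
#' @param species `"adenine"` or `"inhibitor"`.
#' @return Numeric matrix (atoms x 3) matching the row order of the
#'   corresponding specification.
#' @export
mock_coordinates <- function(species = c("adenine", "inhibitor")) {
  species <- match.arg(species)
  xyz <- if (species == "adenine") {
    th <- 2 * pi * (0:8) / 9
    rbind(cbind(1.4 * cos(th), 1.4 * sin(th), 0),
          c(2.55, 0, 0),    # donor N
          c(3.55, 0, 0))    # polar H
  } else {
    rbind(c(0.0, 0.0, 0.0),     # S1
          c(0.75, 1.30, 0.0),   # C1
          c(2.25, 1.30, 0.0),   # C2
          c(3.00, 0.00, 0.0),   # O3 intra-ring
          c(2.25, -1.30, 0.0),  # C3
          c(0.75, -1.30, 0.0),  # C4
          c(-0.80, 0.00, 1.20), # O1 S=O
          c(-0.80, 0.00, -1.20))# O2 S=O
  }
  spec <- if (species == "adenine") mock_adenine_spec() else
    mock_inhibitor_spec()
  m <- spec$atoms$mass
  com <- colSums(xyz * m) / sum(m)
  sweep(xyz, 2, com)
}
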
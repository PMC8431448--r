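# Structure-activity / structure-property analysis: molecular weight from
# formulas (embedded standard atomic weights), descriptor-table ingestion and
# rank association between descriptors and inhibition potency.

# IUPAC standard atomic weights (conventional/abridged values), g/mol
.atomic_weights <- c(
  H = 1.008, He = 4.0026, Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305,
  Al = 26.982, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.95,
  K = 39.098, Ca = 40.078, Mn = 54.938, Fe = 55.845, Co = 58.933,
  Ni = 58.693, Cu = 63.546, Zn = 65.38, Se = 78.971, Br = 79.904,
  I = 126.90
)

#' Parse a molecular formula string
#'
#' @param formula Hill-style formula such as `"C2H6OS"`; element symbols
#'   followed by optional counts.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  f <- gsub("[[:space:]]", "", formula)
  if (!nzchar(f)) stop("empty molecular formula")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
  toks <- regmatches(f, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(f)) {
    stop("cannot parse formula: ", formula)
  }
  el <- sub("[0-9]*$", "", toks)
  ct <- sub("^[A-Z][a-z]?", "", toks)
  ct <- ifelse(ct == "", 1L, suppressWarnings(as.integer(ct)))
  counts <- tapply(ct, el, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Molecular weight from an element-count map
#'
#' Sum of count times standard atomic weight over the formula, reported to
#' two decimals (e.g. DMSO, C2H6OS, is 78.13 g/mol).
#'
#' @param formula A formula string (see [parse_formula()]) or a named numeric
#'   vector of element counts.
#' @return Molecular weight in g/mol, rounded to 2 decimals.
#' @export
molecular_weight <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  if (length(counts) == 0L) stop("empty molecular formula")
  unknown <- setdiff(names(counts), names(.atomic_weights))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  if (any(counts < 0)) stop("negative element counts")
  round(sum(.atomic_weights[names(counts)] * counts), 2)
}

#' Read a physicochemical property table
#'
#' CSV with one row per compound and the descriptor columns used in
#' structure-property analysis: `compound`, `mw`, `logp`, `logs`, `hbd`,
#' `hba`, `aromatic_rings`, `rotatable_bonds`, `tpsa`, `flexibility`
#' (optionally `formula`, from which `mw` is computed when absent). Counts
#' must be non-negative integers.
#'
#' @param path CSV path.
#' @return Data frame of validated property records.
#' @export
read_property_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"compound" %in% names(tab)) stop("property table needs a 'compound' column")
  if (!"mw" %in% names(tab) && "formula" %in% names(tab)) {
    tab$mw <- vapply(tab$formula, molecular_weight, numeric(1))
  }
  for (cnt in intersect(c("hbd", "hba", "aromatic_rings", "rotatable_bonds"),
                        names(tab))) {
    v <- tab[[cnt]]
    if (any(v < 0) || any(v != round(v))) {
      stop("column '", cnt, "' must hold non-negative integer counts")
    }
  }
  if ("mw" %in% names(tab) && any(tab$mw <= 0)) stop("mw must be positive")
  tab
}

#' Rank association between descriptors and inhibition potency
#'
#' Spearman rank correlation between each physicochemical descriptor and the
#' potency score, with a permutation p-value (potency labels shuffled under a
#' fixed seed). Potency is supplied as relative concentration (mM per 1%
#' inhibition, lower = more potent) and scored internally as
#' `-log(relative concentration)` so that positive coefficients mean
#' "higher descriptor value, more potent compound".
#'
#' Compounds without a defined relative concentration (accelerators /
#' non-inhibitors, `NA`) are excluded and listed in the `excluded` attribute.
#'
#' @param properties Property data frame (see [read_property_table()]).
#' @param potency Named numeric vector: compound -> relative concentration.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed for the permutation stream.
#' @return A data frame of class `sar_result` with columns `property`, `rho`,
#'   `n`, `p_value`, ordered by `abs(rho)` descending; constant descriptors
#'   are flagged with `NA` rho. Attribute `excluded` lists compounds dropped
#'   for undefined potency.
#' @export
rank_association <- function(properties, potency, n_perm = 999, seed = 1) {
  stopifnot(n_perm >= 99, "compound" %in% names(properties))
  pot <- potency[match(properties$compound, names(potency))]
  excluded <- properties$compound[is.na(pot)]
  keep <- !is.na(pot)
  props <- properties[keep, , drop = FALSE]
  score <- -log(pot[keep])
  if (sum(keep) < 4L) {
    stop("need at least 4 compounds with both properties and potency (got ",
         sum(keep), ")")
  }
  num_cols <- setdiff(names(props)[vapply(props, is.numeric, logical(1))],
                      "compound")
  set.seed(seed)
  perms <- replicate(n_perm, sample(score), simplify = FALSE)
  rows <- lapply(num_cols, function(cl) {
    x <- props[[cl]]
    ok <- is.finite(x) & is.finite(score)
    if (sum(ok) < 4L || stats::sd(x[ok]) == 0) {
      return(data.frame(property = cl, rho = NA_real_, n = sum(ok),
                        p_value = NA_real_))
    }
    rho <- stats::cor(x[ok], score[ok], method = "spearman")
    null_rho <- vapply(perms, function(p) {
      stats::cor(x[ok], p[ok], method = "spearman")
    }, numeric(1))
    p <- (1 + sum(abs(null_rho) >= abs(rho) - 1e-12)) / (n_perm + 1)
    data.frame(property = cl, rho = rho, n = sum(ok), p_value = p)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$rho), na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("sar_result", "data.frame"), excluded = excluded,
            n_perm = n_perm, seed = seed)
}
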
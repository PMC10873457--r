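#' Construct a molecular graph
#'
#' A `molgraph` is an attributed molecular graph that is *permitted to be
#' chemically invalid*: no valence check is performed on construction, so
#' hexavalent carbons and similar defects are representable. Hydrogens are
#' stored as per-atom counts, never as graph nodes.
#'
#' @param Z integer vector of atomic numbers (one per atom, all positive).
#' @param Q integer vector of formal charges (recycled if length 1).
#' @param H integer vector of hydrogen counts (non-negative, recycled if
#'   length 1).
#' @param bonds integer matrix with columns `a`, `b`, `order`: 1-based atom
#'   indices and an integer bond order in `{1, 2, 3}`. Use
#'   `matrix(integer(), 0, 3)` or `NULL` for a bond-less molecule.
#' @return An object of class `molgraph`.
#' @examples
#' # ethanol, C-C-O
#' m <- molgraph(Z = c(6, 6, 8), H = c(3, 2, 1),
#'               bonds = rbind(c(1, 2, 1), c(2, 3, 1)))
#' n_atoms(m)
#' @export
molgraph <- function(Z, Q = 0L, H = 0L, bonds = NULL) {
  Z <- as.integer(Z)
  n <- length(Z)
  Q <- rep_len(as.integer(Q), n)
  H <- rep_len(as.integer(H), n)
  if (any(is.na(Z)) || any(Z < 1L)) stop("atomic numbers must be positive integers")
  if (any(is.na(Q))) stop("formal charges must be integers")
  if (any(is.na(H)) || any(H < 0L)) stop("hydrogen counts must be non-negative integers")
  if (is.null(bonds)) bonds <- matrix(integer(), 0L, 3L)
  bonds <- matrix(as.integer(bonds), ncol = 3L,
                  dimnames = list(NULL, c("a", "b", "order")))
  if (nrow(bonds) > 0L) {
    if (any(is.na(bonds))) stop("bonds must be integers")
    if (any(bonds[, 1:2] < 1L) || any(bonds[, 1:2] > n))
      stop("bond atom index out of range")
    if (any(bonds[, 1L] == bonds[, 2L])) stop("self-loop bonds are not allowed")
    if (!all(bonds[, 3L] %in% 1:3)) stop("bond orders must be 1, 2 or 3")
    pair <- paste(pmin(bonds[, 1L], bonds[, 2L]), pmax(bonds[, 1L], bonds[, 2L]))
    if (anyDuplicated(pair)) stop("at most one bond per atom pair")
  }
  structure(list(Z = Z, Q = Q, H = H, bonds = bonds), class = "molgraph")
}

#' @rdname molgraph
#' @param x,m a `molgraph`.
#' @export
is_molgraph <- function(x) inherits(x, "molgraph")

#' @rdname molgraph
#' @export
n_atoms <- function(m) length(m$Z)

#' @rdname molgraph
#' @export
n_bonds <- function(m) nrow(m$bonds)

assert_molgraph <- function(m) {
  if (!is_molgraph(m)) stop("expected a 'molgraph' object")
  invisible(m)
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph> %d atoms, %d bonds\n", n_atoms(x), n_bonds(x)))
  if (n_atoms(x) > 0L) {
    smi <- tryCatch(write_smiles(x), error = function(e) NULL)
    if (!is.null(smi)) cat("  ", smi, "\n", sep = "")
  }
  invisible(x)
}

# neighbour indices of atom i (with bond orders)
mol_neighbors <- function(m, i) {
  b <- m$bonds
  sel1 <- b[, 1L] == i
  sel2 <- b[, 2L] == i
  data.frame(atom = c(b[sel2, 1L], b[sel1, 2L]),
             order = c(b[sel2, 3L], b[sel1, 3L]))
}

# row index of the bond between atoms a and b, or NA
bond_index <- function(m, a, b) {
  hit <- which((m$bonds[, 1L] == a & m$bonds[, 2L] == b) |
               (m$bonds[, 1L] == b & m$bonds[, 2L] == a))
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

#' Structural distance between two molecules
#'
#' One minus the Jaccard index of 2048-bit-folded circular-substructure
#' fingerprints of radius 2 (the classic ECFP4-style distance used to keep
#' corrected molecules close to the input).
#'
#' @param a,b `molgraph` objects.
#' @return A distance in `[0, 1]`; 0 for identical fingerprints.
#' @export
ecfp4_tanimoto_distance <- function(a, b) {
  assert_molgraph(a)
  assert_molgraph(b)
  fa <- cpp_fingerprint(unclass(a))
  fb <- cpp_fingerprint(unclass(b))
  u <- length(union(fa, fb))
  if (u == 0L) return(0)
  1 - length(intersect(fa, fb)) / u
}
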
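#' Atom, bond and environment keys
#'
#' Molecules are featurized into a hierarchy of structural keys. An *atom
#' key* is the integer tuple `(D, V, Z, Q, H)` -- degree (number of bonded
#' heavy-atom neighbours), valence (sum of the atom's bond orders, hydrogens
#' and formal charge excluded), atomic number, formal charge and hydrogen
#' count, in decreasing order of significance. *Partial atom keys* are the
#' four proper prefixes of that tuple. A *bond key* is the two endpoint atom
#' keys (canonically sorted) plus the bond order; dropping the order gives
#' the partial bond key. An *environment key* is a Morgan-style iterative
#' hash identifying the circular environment of all atoms within a
#' topological radius of a center atom.
#'
#' @param mol a [molgraph].
#' @param atom_index 1-based atom index.
#' @return `compute_atom_key()`: named integer vector `(D, V, Z, Q, H)` of
#'   class `atom_key`.
#' @examples
#' mso <- parse_smiles("CS(C)(=O)=O")   # dimethyl sulfone
#' compute_atom_key(mso, 2)             # (4, 6, 16, 0, 0)
#' @export
compute_atom_key <- function(mol, atom_index) {
  assert_molgraph(mol)
  if (length(atom_index) != 1L || is.na(atom_index) ||
      atom_index < 1L || atom_index > n_atoms(mol))
    stop("atom_index out of range")
  k <- cpp_atom_keys(mol)[atom_index, ]
  structure(as.integer(k), names = c("D", "V", "Z", "Q", "H"), class = "atom_key")
}

#' @rdname compute_atom_key
#' @param key an `atom_key` (or plain 5-integer vector).
#' @return `enumerate_partial_atom_keys()`: list of the 4 prefixes, in
#'   increasing length `j = 1..4`.
#' @export
enumerate_partial_atom_keys <- function(key) {
  key <- as.integer(key)
  if (length(key) != 5L) stop("an atom key has exactly 5 properties")
  lapply(1:4, function(j) structure(key[seq_len(j)],
                                    names = c("D", "V", "Z", "Q", "H")[seq_len(j)],
                                    class = "partial_atom_key"))
}

#' @rdname compute_atom_key
#' @param bond either a bond row index or a length-2 vector of atom indices.
#' @return `compute_bond_key()`: list with `ak1`, `ak2` (atom keys, sorted so
#'   `ak1 <= ak2` lexicographically) and `order`, of class `bond_key`.
#' @export
compute_bond_key <- function(mol, bond) {
  assert_molgraph(mol)
  if (length(bond) == 2L) bond <- bond_index(mol, bond[1L], bond[2L])
  if (length(bond) != 1L || is.na(bond) || bond < 1L || bond > n_bonds(mol))
    stop("no such bond")
  a <- mol$bonds[bond, 1L]
  b <- mol$bonds[bond, 2L]
  k1 <- compute_atom_key(mol, a)
  k2 <- compute_atom_key(mol, b)
  if (key_less(k2, k1)) { tmp <- k1; k1 <- k2; k2 <- tmp }
  structure(list(ak1 = k1, ak2 = k2, order = mol$bonds[bond, 3L]),
            class = "bond_key")
}

# component-wise lexicographic comparison of integer tuples
key_less <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' @rdname compute_atom_key
#' @param radius non-negative environment radius.
#' @return `compute_environment_key()`: list with `hash` (16-hex-digit
#'   string), `center`, `radius` and `members` (atom indices within the
#'   radius), of class `environment_key`.
#' @export
compute_environment_key <- function(mol, atom_index, radius) {
  assert_molgraph(mol)
  if (radius < 0L) stop("radius must be non-negative")
  if (length(atom_index) != 1L || is.na(atom_index) ||
      atom_index < 1L || atom_index > n_atoms(mol))
    stop("atom_index out of range")
  ek <- cpp_env_keys(mol, as.integer(radius))
  structure(list(hash = as.character(ek$keys[atom_index]),
                 center = as.integer(atom_index),
                 radius = as.integer(radius),
                 members = as.integer(ek$members[[atom_index]])),
            class = "environment_key")
}

#' Featurize a molecule into its full key set
#'
#' @param mol a [molgraph].
#' @param radius environment radius.
#' @return A list of class `key_set` with `atom_keys` (strings, one per
#'   atom), `bond_keys` (one per bond), `environment_keys` (one per atom),
#'   and the counts `n_a`, `n_b`, `n_e`, `n = n_a + n_b + n_e`.
#' @examples
#' ks <- featurize_molecule(parse_smiles("CC"), radius = 1)
#' ks$n   # 2 + 1 + 2 = 5
#' @export
featurize_molecule <- function(mol, radius) {
  assert_molgraph(mol)
  n <- n_atoms(mol)
  ak <- cpp_atom_keys(mol)
  atom_keys <- if (n > 0L) apply(ak, 1L, paste, collapse = ",") else character()
  bond_keys <- vapply(seq_len(n_bonds(mol)), function(i) {
    bk <- compute_bond_key(mol, i)
    key_string(bk)
  }, character(1L))
  env <- if (n > 0L) as.character(cpp_env_keys(mol, as.integer(radius))$keys) else character()
  structure(list(atom_keys = atom_keys, bond_keys = bond_keys,
                 environment_keys = env,
                 n_a = n, n_b = n_bonds(mol), n_e = n,
                 n = 2L * n + n_bonds(mol), radius = as.integer(radius)),
            class = "key_set")
}

# serialize any key object to the string form used by the dictionary store
key_string <- function(key) {
  if (inherits(key, "bond_key"))
    return(paste(paste(key$ak1, collapse = ","),
                 paste(key$ak2, collapse = ","),
                 key$order, sep = ";"))
  if (inherits(key, "environment_key")) return(key$hash)
  if (inherits(key, "partial_bond_key"))
    return(paste(key[[1L]], key[[2L]], sep = ";"))
  if (is.numeric(key) || inherits(key, c("atom_key", "partial_atom_key")))
    return(paste(as.integer(key), collapse = ","))
  if (is.character(key) && length(key) == 1L) return(key)
  stop("unrecognized key object")
}

#' @rdname compute_bond_key
#' @param key a `bond_key`.
#' @return `partial_bond_key()`: the `(ak1, ak2)` pair without the order.
#' @export
partial_bond_key <- function(key) {
  if (!inherits(key, "bond_key")) stop("expected a 'bond_key'")
  structure(list(ak1 = paste(key$ak1, collapse = ","),
                 ak2 = paste(key$ak2, collapse = ",")),
            class = "partial_bond_key")
}

#' @export
print.atom_key <- function(x, ...) {
  cat("<atom_key> (", paste(as.integer(x), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @export
print.key_set <- function(x, ...) {
  cat(sprintf("<key_set> radius %d: n_a=%d n_b=%d n_e=%d (n=%d)\n",
              x$radius, x$n_a, x$n_b, x$n_e, x$n))
  invisible(x)
}
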
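PERTURBATION_KINDS <- c("set_hydrogens", "set_charge", "set_element",
                        "set_bond_type", "delete_bond", "delete_atom",
                        "insert_bond", "insert_atom")

#' Single-edit graph perturbations
#'
#' A perturbation is one typed edit of a molecular graph. The eight kinds
#' are ranked by significance (how much they disrupt the molecule), from
#' least to most significant: hydrogen-count change < formal-charge change <
#' element change < bond-type change < bond deletion < atom deletion < bond
#' insertion < atom insertion.
#'
#' @param kind one of `"set_hydrogens"`, `"set_charge"`, `"set_element"`,
#'   `"set_bond_type"`, `"delete_bond"`, `"delete_atom"`, `"insert_bond"`,
#'   `"insert_atom"`.
#' @param atom target atom index (atom-targeted kinds and `insert_atom`'s
#'   attachment point).
#' @param bond length-2 vector of atom indices (bond-targeted kinds).
#' @param value new value: hydrogen count, charge, atomic number or bond
#'   order, depending on the kind.
#' @param Z,Q,H,order for `insert_atom`: invariants of the new degree-1 atom
#'   and the order of its attaching bond. `H = NA` derives the hydrogen
#'   count from the standard-valence table.
#' @return An object of class `perturbation`.
#' @examples
#' p <- perturbation("set_element", atom = 2, value = 16)
#' @export
perturbation <- function(kind, atom = NULL, bond = NULL, value = NULL,
                         Z = NULL, Q = 0L, H = NA_integer_, order = 1L) {
  kind <- match.arg(kind, PERTURBATION_KINDS)
  p <- switch(kind,
    set_hydrogens = ,
    set_charge = ,
    set_element = {
      if (is.null(atom) || is.null(value)) stop(kind, " needs 'atom' and 'value'")
      list(kind = kind, atom = as.integer(atom), value = as.integer(value))
    },
    set_bond_type = {
      if (is.null(bond) || is.null(value)) stop(kind, " needs 'bond' and 'value'")
      list(kind = kind, bond = as.integer(bond), value = as.integer(value))
    },
    delete_bond = {
      if (is.null(bond)) stop(kind, " needs 'bond'")
      list(kind = kind, bond = as.integer(bond))
    },
    delete_atom = {
      if (is.null(atom)) stop(kind, " needs 'atom'")
      list(kind = kind, atom = as.integer(atom))
    },
    insert_bond = {
      if (is.null(bond)) stop(kind, " needs 'bond'")
      list(kind = kind, bond = as.integer(bond), value = as.integer(order))
    },
    insert_atom = {
      if (is.null(atom) || is.null(Z)) stop(kind, " needs 'atom' and 'Z'")
      list(kind = kind, atom = as.integer(atom), Z = as.integer(Z),
           Q = as.integer(Q), H = as.integer(H), order = as.integer(order))
    })
  structure(p, class = "perturbation")
}

#' @rdname perturbation
#' @param p a `perturbation`.
#' @return `perturbation_rank()`: integer significance rank 1 (least
#'   significant) to 8 (most significant).
#' @export
perturbation_rank <- function(p) {
  if (!inherits(p, "perturbation")) stop("expected a 'perturbation'")
  match(p$kind, PERTURBATION_KINDS)
}

#' @export
print.perturbation <- function(x, ...) {
  tgt <- if (!is.null(x$atom)) paste0("atom ", x$atom)
         else paste0("bond (", x$bond[1L], ",", x$bond[2L], ")")
  val <- if (!is.null(x$value)) paste0(" -> ", x$value)
         else if (x$kind == "insert_atom")
           sprintf(" Z=%d Q=%d H=%s order=%d", x$Z, x$Q,
                   ifelse(is.na(x$H), "auto", x$H), x$order)
         else ""
  cat(sprintf("<perturbation> %s %s%s\n", x$kind, tgt, val))
  invisible(x)
}

# internal 7-int candidate encoding shared with the C++ core
as_cand_row <- function(p) {
  k <- match(p$kind, PERTURBATION_KINDS)
  switch(p$kind,
    set_hydrogens = ,
    set_charge = ,
    set_element = c(k, p$atom, 0L, p$value, 0L, 0L, 0L),
    set_bond_type = c(k, p$bond[1L], p$bond[2L], p$value, 0L, 0L, 0L),
    delete_bond = c(k, p$bond[1L], p$bond[2L], 0L, 0L, 0L, 0L),
    delete_atom = c(k, p$atom, 0L, 0L, 0L, 0L, 0L),
    insert_bond = c(k, p$bond[1L], p$bond[2L], p$value, 0L, 0L, 0L),
    insert_atom = c(k, p$atom, 0L, p$Z, p$Q,
                    ifelse(is.na(p$H), -1L, p$H), p$order))
}

row_to_perturbation <- function(r) {
  kind <- PERTURBATION_KINDS[r[1L]]
  switch(kind,
    set_hydrogens = ,
    set_charge = ,
    set_element = perturbation(kind, atom = r[2L], value = r[4L]),
    set_bond_type = perturbation(kind, bond = r[2:3], value = r[4L]),
    delete_bond = perturbation(kind, bond = r[2:3]),
    delete_atom = perturbation(kind, atom = r[2L]),
    insert_bond = perturbation(kind, bond = r[2:3], order = r[4L]),
    insert_atom = perturbation(kind, atom = r[2L], Z = r[4L], Q = r[5L],
                               H = if (r[6L] < 0L) NA_integer_ else r[6L],
                               order = r[7L]))
}

#' Apply a perturbation to a molecule
#'
#' Returns a new graph differing from the input only by the edit; the input
#' is never modified. Deleting an articulation bond or atom would
#' disconnect the graph; in that case the largest remaining fragment is
#' kept (ties favour the fragment holding the lowest atom index) and the
#' surviving atoms are reindexed contiguously.
#'
#' @param mol a [molgraph].
#' @param p a [perturbation].
#' @return The perturbed [molgraph] (unsanitized; see
#'   [sanitize_after_perturbation]).
#' @export
apply_perturbation <- function(mol, p) {
  assert_molgraph(mol)
  if (!inherits(p, "perturbation")) stop("expected a 'perturbation'")
  n <- n_atoms(mol)
  idx <- c(p$atom, p$bond)
  if (any(idx < 1L) || any(idx > n)) stop("perturbation target out of range")
  if (p$kind %in% c("set_bond_type", "delete_bond")) {
    if (is.na(bond_index(mol, p$bond[1L], p$bond[2L]))) stop("no such bond")
  }
  if (p$kind == "insert_bond") {
    if (p$bond[1L] == p$bond[2L]) stop("cannot bond an atom to itself")
    if (!is.na(bond_index(mol, p$bond[1L], p$bond[2L]))) stop("bond already exists")
  }
  if (p$kind == "delete_atom" && n < 2L)
    stop("cannot delete the only atom")
  cpp_apply_cand(mol, as.integer(as_cand_row(p)), sanitize = FALSE)
}

#' Sanitize hydrogen counts after a perturbation
#'
#' For each touched atom with an entry in the standard-valence table
#' (charge-adjusted organic subset), the hydrogen count is reset to
#' `smallest standard valence >= V` minus `V`, where `V` is the sum of the
#' atom's bond orders. Atoms without a table entry, or whose valence
#' already exceeds the largest standard valence (e.g. a hexavalent carbon),
#' are left untouched -- repairing those is the search's job, not the
#' sanitizer's.
#'
#' @param mol a [molgraph].
#' @param touched_atoms atom indices to sanitize (typically the atoms whose
#'   incident bonds were changed by a perturbation).
#' @param enabled when `FALSE`, the molecule is returned unchanged.
#' @return A [molgraph].
#' @export
sanitize_after_perturbation <- function(mol, touched_atoms, enabled = TRUE) {
  assert_molgraph(mol)
  if (!enabled || length(touched_atoms) == 0L) return(mol)
  touched_atoms <- as.integer(touched_atoms)
  if (any(touched_atoms < 1L) || any(touched_atoms > n_atoms(mol)))
    stop("touched atom index out of range")
  cpp_sanitize(mol, touched_atoms)
}

# ---------------------------------------------------------------------------
# The random "breaker"
# ---------------------------------------------------------------------------

# kinds applicable to the current graph (breaker semantics)
applicable_kinds <- function(mol) {
  n <- n_atoms(mol)
  m <- n_bonds(mol)
  kinds <- c("set_hydrogens", "set_charge", "set_element", "insert_atom")
  if (m >= 1L) kinds <- c(kinds, "set_bond_type", "delete_bond")
  if (n >= 2L) {
    kinds <- c(kinds, "delete_atom")
    if (choose(n, 2L) > m) kinds <- c(kinds, "insert_bond")
  }
  kinds[order(match(kinds, PERTURBATION_KINDS))]
}

sample1 <- function(x) x[sample.int(length(x), 1L)]

# draw one uniformly random applicable perturbation (kind first, then
# target/value); element values come from the organic set, charges from
# [-2, 2], hydrogen counts from [0, 4], bond orders from {1, 2, 3}
random_perturbation <- function(mol) {
  kind <- sample1(applicable_kinds(mol))
  n <- n_atoms(mol)
  switch(kind,
    set_hydrogens = {
      a <- sample1(seq_len(n))
      perturbation(kind, atom = a, value = sample1(setdiff(0:4, mol$H[a])))
    },
    set_charge = {
      a <- sample1(seq_len(n))
      perturbation(kind, atom = a, value = sample1(setdiff(-2:2, mol$Q[a])))
    },
    set_element = {
      a <- sample1(seq_len(n))
      perturbation(kind, atom = a, value = sample1(setdiff(ORGANIC_Z, mol$Z[a])))
    },
    set_bond_type = {
      k <- sample1(seq_len(n_bonds(mol)))
      perturbation(kind, bond = mol$bonds[k, 1:2],
                   value = sample1(setdiff(1:3, mol$bonds[k, 3L])))
    },
    delete_bond = {
      k <- sample1(seq_len(n_bonds(mol)))
      perturbation(kind, bond = mol$bonds[k, 1:2])
    },
    delete_atom = perturbation(kind, atom = sample1(seq_len(n))),
    insert_bond = {
      free <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
      bonded <- paste(pmin(mol$bonds[, 1L], mol$bonds[, 2L]),
                      pmax(mol$bonds[, 1L], mol$bonds[, 2L]))
      free <- free[!(paste(free[, 1L], free[, 2L]) %in% bonded), , drop = FALSE]
      k <- sample.int(nrow(free), 1L)
      perturbation(kind, bond = free[k, ], order = sample1(1:3))
    },
    insert_atom = perturbation(kind, atom = sample1(seq_len(n)),
                               Z = sample1(ORGANIC_Z), Q = 0L,
                               H = NA_integer_, order = sample1(1:3)))
}

#' Sequentially break a molecule with random perturbations
#'
#' Applies `n_steps` uniformly random perturbations one after the other
#' (the "breaker" used to generate benchmark inputs), sanitizing after each
#' edit by default. The result is a series of progressively perturbed --
#' and typically increasingly foreign -- molecules.
#'
#' @param mol a [molgraph].
#' @param n_steps number of perturbations (the benchmark uses 10).
#' @param seed integer seed; the full series is reproducible from it.
#' @param sanitize sanitize hydrogen counts after each edit.
#' @return A list of `n_steps` [molgraph]s; element `k` is the input after
#'   `k` perturbations.
#' @export
random_perturbation_sequence <- function(mol, n_steps, seed, sanitize = TRUE) {
  assert_molgraph(mol)
  if (n_steps < 1L) stop("n_steps must be >= 1")
  if (n_atoms(mol) == 0L) stop("cannot perturb an empty molecule")
  local_seed(seed, {
    out <- vector("list", n_steps)
    cur <- mol
    for (k in seq_len(n_steps)) {
      p <- random_perturbation(cur)
      cur <- cpp_apply_cand(cur, as.integer(as_cand_row(p)), sanitize = sanitize)
      out[[k]] <- cur
    }
    out
  })
}
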
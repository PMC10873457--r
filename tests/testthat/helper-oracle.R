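# Independent brute-force oracle for the single-edit neighbourhood.
# Deliberately written as plain nested loops over the edit universe, with
# its own BFS distance computation, so it shares no enumeration or
# prioritization logic with the candidate stream it checks.

oracle_value_universe <- function(d) {
  atoms <- molautofix:::cpp_dict_export(d$ptr)$atom
  fields <- do.call(rbind, lapply(strsplit(atoms$key, ",", fixed = TRUE),
                                  as.integer))
  org <- c(5L, 6L, 7L, 8L, 9L, 15L, 16L, 17L, 35L, 53L)
  list(H = sort(union(0:4, fields[, 5L])),
       Q = sort(union(-2:2, fields[, 4L])),
       Z = sort(union(org, fields[, 3L])),
       deg1 = unique(fields[fields[, 1L] == 1L & fields[, 2L] <= 3L,
                            c(2L, 3L, 4L, 5L), drop = FALSE]))
}

# plain BFS all-pairs topological distances
oracle_distances <- function(m) {
  n <- n_atoms(m)
  D <- matrix(Inf, n, n)
  adj <- lapply(seq_len(n), function(a)
    c(m$bonds[m$bonds[, 2L] == a, 1L], m$bonds[m$bonds[, 1L] == a, 2L]))
  for (s in seq_len(n)) {
    D[s, s] <- 0
    frontier <- s
    dist <- 0
    while (length(frontier) > 0L) {
      dist <- dist + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[!is.finite(D[s, nxt])]
      D[s, nxt] <- dist
      frontier <- nxt
    }
  }
  D
}

# every legal single edit, as a canonical string set
oracle_neighborhood <- function(mol, d, allow_insertions = TRUE) {
  n <- n_atoms(mol)
  uni <- oracle_value_universe(d)
  edits <- character(0)
  add <- function(...) edits[[length(edits) + 1L]] <<- paste(..., sep = "|")
  for (a in seq_len(n)) {
    for (h in setdiff(uni$H, mol$H[a])) add("set_hydrogens", a, h)
    for (q in setdiff(uni$Q, mol$Q[a])) add("set_charge", a, q)
    for (z in setdiff(uni$Z, mol$Z[a])) add("set_element", a, z)
  }
  for (k in seq_len(n_bonds(mol))) {
    a <- min(mol$bonds[k, 1:2]); b <- max(mol$bonds[k, 1:2])
    for (o in setdiff(1:3, mol$bonds[k, 3L])) add("set_bond_type", a, b, o)
    add("delete_bond", a, b)
  }
  if (n >= 2L) for (a in seq_len(n)) add("delete_atom", a)
  if (allow_insertions) {
    D <- oracle_distances(mol)
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a < b && D[a, b] >= 3) for (o in 1:3) add("insert_bond", a, b, o)
    }
    for (a in seq_len(n)) for (r in seq_len(nrow(uni$deg1))) {
      add("insert_atom", a, uni$deg1[r, 2L], uni$deg1[r, 3L], uni$deg1[r, 4L],
          uni$deg1[r, 1L])
    }
  }
  unique(edits)
}

# canonical string for a perturbation object (matches oracle_neighborhood)
perturbation_string <- function(p) {
  switch(p$kind,
    set_hydrogens = ,
    set_charge = ,
    set_element = paste(p$kind, p$atom, p$value, sep = "|"),
    set_bond_type = paste(p$kind, min(p$bond), max(p$bond), p$value, sep = "|"),
    delete_bond = paste(p$kind, min(p$bond), max(p$bond), sep = "|"),
    delete_atom = paste(p$kind, p$atom, sep = "|"),
    insert_bond = paste(p$kind, min(p$bond), max(p$bond), p$value, sep = "|"),
    insert_atom = paste(p$kind, p$atom, p$Z, p$Q, p$H, p$order, sep = "|"))
}

# scan the full single-edit neighbourhood for repairs (sanitization on, as
# in the search); returns the number of edits whose result is fully familiar
oracle_count_one_edit_repairs <- function(mol, d) {
  strs <- oracle_neighborhood(mol, d)
  reps <- 0L
  for (s in strs) {
    f <- strsplit(s, "|", fixed = TRUE)[[1L]]
    p <- switch(f[1L],
      set_hydrogens = ,
      set_charge = ,
      set_element = perturbation(f[1L], atom = as.integer(f[2L]),
                                 value = as.integer(f[3L])),
      set_bond_type = perturbation(f[1L], bond = as.integer(f[2:3]),
                                   value = as.integer(f[4L])),
      delete_bond = perturbation(f[1L], bond = as.integer(f[2:3])),
      delete_atom = perturbation(f[1L], atom = as.integer(f[2L])),
      insert_bond = perturbation(f[1L], bond = as.integer(f[2:3]),
                                 order = as.integer(f[4L])),
      insert_atom = perturbation(f[1L], atom = as.integer(f[2L]),
                                 Z = as.integer(f[3L]), Q = as.integer(f[4L]),
                                 H = as.integer(f[5L]),
                                 order = as.integer(f[6L])))
    child <- molautofix:::cpp_apply_cand(mol, as.integer(molautofix:::as_cand_row(p)),
                                         sanitize = TRUE)
    if (n_atoms(child) > 0L && familiarity_report(child, d)$f1 == 1) reps <- reps + 1L
  }
  reps
}
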
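# Expansion policy: locate the most pressing defect of a foreign molecule
# and lazily enumerate the single-edit perturbations most likely to fix it,
# most promising first. Fully consumed, the stream covers the complete
# single-edit neighbourhood of the molecule.

#' Foreign-environment membership of atoms and bonds
#'
#' Counts, for every atom and bond, how many foreign circular environments
#' it participates in (a bond participates when both its endpoints are
#' members). Atoms and bonds with high membership are the likeliest
#' culprits when only environment keys are foreign.
#'
#' @param mol a [molgraph].
#' @param d a [chemical_dictionary].
#' @return A list of class `membership_map` with integer vectors `atom`
#'   (per atom) and `bond` (per bond row).
#' @export
foreign_environment_membership <- function(mol, d) {
  rep <- familiarity_report(mol, d)
  membership_from_report(mol, rep)
}

membership_from_report <- function(mol, rep) {
  n <- n_atoms(mol)
  m <- n_bonds(mol)
  atom <- integer(n)
  bond <- integer(m)
  for (i in which(!rep$env_familiar)) {
    mem <- rep$env_members[[i]]
    atom[mem] <- atom[mem] + 1L
    if (m > 0L) {
      inenv <- (mol$bonds[, 1L] %in% mem) & (mol$bonds[, 2L] %in% mem)
      bond[inenv] <- bond[inenv] + 1L
    }
  }
  structure(list(atom = atom, bond = bond), class = "membership_map")
}

# ---------------------------------------------------------------------------
# Diagnosis
# ---------------------------------------------------------------------------

#' Diagnose the most pressing defect of a foreign molecule
#'
#' Walks the partial-key ladder to find the most significant foreign key.
#' For a foreign (partial) atom key the culprit is the property that
#' extends the least significant *familiar* prefix (e.g. a hexavalent
#' carbon: `(4,6)` familiar but `(4,6,6)` foreign, so the atomic number is
#' the culprit). When atom keys are familiar but their pairing in a bond is
#' foreign the culprit is the pair itself, then the bond order. When only
#' environment keys are foreign, the atom or bond with the highest
#' foreign-environment membership is targeted, ties broken by lowest
#' atom-/bond-key frequency.
#'
#' @param mol a [molgraph] with at least one foreign key.
#' @param d a [chemical_dictionary].
#' @return An object of class `diagnosis`: `target_type` (`"atom"` or
#'   `"bond"`), `target` (atom index or bond endpoint pair), `culprit` (one
#'   of `"D"`, `"V"`, `"Z"`, `"Q"`, `"H"`, `"AK-pair"`, `"B"`,
#'   `"environment"`), `foreign_key` and `predecessor` (string forms).
#' @export
diagnose <- function(mol, d) {
  assert_molgraph(mol)
  assert_dictionary(d)
  if (n_atoms(mol) == 0L) stop("familiarity is undefined for an empty molecule")
  diagnosis_from_cpp(cpp_diagnose(d$ptr, mol))
}

# convert the C++ diagnosis record into the S3 object
diagnosis_from_cpp <- function(x) {
  culprits <- c("D", "V", "Z", "Q", "H", "AK-pair", "B", "environment")
  pred <- x$predecessor
  if (!is.null(pred) && x$culprit == 6L) pred <- NULL
  structure(list(
    target_type = if (x$type == 1L) "atom" else "bond",
    target = if (x$type == 1L) as.integer(x$a) else as.integer(c(x$a, x$b)),
    culprit = culprits[x$culprit],
    foreign_key = x$foreign,
    predecessor = pred),
    class = "diagnosis")
}

#' @export
print.diagnosis <- function(x, ...) {
  tgt <- if (x$target_type == "atom") paste0("atom ", x$target)
         else paste0("bond (", x$target[1L], ",", x$target[2L], ")")
  cat(sprintf("<diagnosis> culprit %s at %s\n", x$culprit, tgt))
  if (!is.null(x$foreign_key))
    cat("  foreign key: ", x$foreign_key,
        if (!is.null(x$predecessor) && nzchar(x$predecessor))
          paste0("  (familiar predecessor: ", x$predecessor, ")") else "", "\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Candidate stream
# ---------------------------------------------------------------------------

# context shared by the stream's stage builders; the detailed familiarity
# report is computed lazily (only the later stages need it)
stream_context <- function(mol, d, allow_insertions, rep = NULL) {
  uni <- d$universe
  ctx <- new.env(parent = emptyenv())
  ctx$mol <- mol
  ctx$d <- d
  ctx$rep_cache <- rep
  ctx$ak <- cpp_atom_keys(mol)
  ctx$allow_insertions <- allow_insertions
  ctx$Hvals <- uni$H
  ctx$Qvals <- uni$Q
  ctx$Zvals <- uni$Z
  ctx$deg1 <- d$value_sets$deg1_keys
  ctx
}

ctx_rep <- function(ctx) {
  if (is.null(ctx$rep_cache))
    ctx$rep_cache <- cpp_familiarity(ctx$d$ptr, ctx$mol, details = TRUE)
  ctx$rep_cache
}

# successor-ordered value list: dictionary successors first (frequency
# descending), then the remaining universe ascending; current value removed
ordered_values <- function(ctx, a, property, universe) {
  j <- match(property, c("D", "V", "Z", "Q", "H"))
  prefix <- paste(ctx$ak[a, seq_len(j - 1L)], collapse = ",")
  succ <- cpp_dict_successors(ctx$d$ptr, 0L, prefix)
  vals <- c(succ$value[succ$value %in% universe],
            setdiff(universe, succ$value))
  setdiff(vals, ctx$ak[a, j])
}

cand_row <- function(kind, i = 0L, j = 0L, a1 = 0L, a2 = 0L, a3 = 0L, a4 = 0L) {
  k <- match(kind, PERTURBATION_KINDS)
  if (k %in% c(4L, 5L, 7L) && j != 0L && i > j) { tmp <- i; i <- j; j <- tmp }
  c(k, i, j, a1, a2, a3, a4)
}

# vectorized block of candidate rows (bond-targeted rows canonicalized)
cand_rows <- function(kind, i, j = 0L, a1 = 0L, a2 = 0L, a3 = 0L, a4 = 0L) {
  if (length(i) == 0L && length(j) == 0L) return(NULL)
  k <- match(kind, PERTURBATION_KINDS)
  m <- cbind(k, i, j, a1, a2, a3, a4)
  if (k %in% c(4L, 5L, 7L)) {
    swap <- m[, 2L] > m[, 3L] & m[, 3L] != 0L
    tmp <- m[swap, 2L]
    m[swap, 2L] <- m[swap, 3L]
    m[swap, 3L] <- tmp
  }
  dimnames(m) <- NULL
  m
}

rows_set_value <- function(kind, a, values) {
  if (length(values) == 0L) return(NULL)
  cand_rows(kind, i = a, a1 = values)
}

# frequency of the bond keys resulting from re-typing bond (a,b)
resulting_bond_counts <- function(ctx, a, b, old_order, new_orders) {
  nn <- length(new_orders)
  k1 <- ctx$ak[rep(a, nn), , drop = FALSE]
  k2 <- ctx$ak[rep(b, nn), , drop = FALSE]
  delta <- new_orders - old_order
  k1[, 2L] <- k1[, 2L] + delta
  k2[, 2L] <- k2[, 2L] + delta
  keys <- cpp_bond_key_strs(k1, k2, as.integer(new_orders))
  as.numeric(cpp_dict_counts(ctx$d$ptr, 2L, keys))
}

# frequency of the bond keys resulting from inserting bond (a, partners)
inserted_bond_counts <- function(ctx, a, partners, order) {
  nn <- length(partners)
  k1 <- ctx$ak[rep(a, nn), , drop = FALSE]
  k2 <- ctx$ak[partners, , drop = FALSE]
  k1[, 1L] <- k1[, 1L] + 1L; k1[, 2L] <- k1[, 2L] + order
  k2[, 1L] <- k2[, 1L] + 1L; k2[, 2L] <- k2[, 2L] + order
  keys <- cpp_bond_key_strs(k1, k2, rep(as.integer(order), nn))
  as.numeric(cpp_dict_counts(ctx$d$ptr, 2L, keys))
}

# set_bond_type rows for one bond ordered by resulting bond-key frequency
rows_set_bond <- function(ctx, a, b, old_order) {
  orders <- setdiff(1:3, old_order)
  cnt <- resulting_bond_counts(ctx, a, b, old_order, orders)
  orders <- orders[order(-cnt, orders)]
  cand_rows("set_bond_type", i = a, j = b, a1 = orders)
}

# incident bonds of atom a as parallel vectors (row index, partner, order)
incident_bonds <- function(mol, a) {
  b <- mol$bonds
  k <- which(b[, 1L] == a | b[, 2L] == a)
  list(k = k,
       partner = ifelse(b[k, 1L] == a, b[k, 2L], b[k, 1L]),
       order = b[k, 3L],
       n = length(k))
}

# deletions that fix a degree/valence culprit: bond deletions (rarest bond
# key first), then neighbour-atom deletions (rarest atom key first)
rows_topology_fix <- function(ctx, a) {
  mol <- ctx$mol
  inc <- incident_bonds(mol, a)
  if (inc$n == 0L) return(NULL)
  ord <- order(ctx_rep(ctx)$bond_count[inc$k], inc$k)
  blocks <- list(cand_rows("delete_bond", i = a, j = inc$partner[ord]))
  if (n_atoms(mol) >= 2L) {
    acnt <- cpp_dict_counts(ctx$d$ptr, 0L, ctx_rep(ctx)$atom_keys[inc$partner])
    nb <- inc$partner[order(acnt, inc$partner)]
    blocks[[2L]] <- cand_rows("delete_atom", i = nb)
  }
  blocks
}

# insertion rows rooted at atom a (bond insertions to atoms at topological
# distance >= 3, then atom insertions from the dictionary's degree-1 keys)
rows_insertions <- function(ctx, a, distm, partners = NULL) {
  blocks <- list()
  if (is.null(partners)) partners <- which(distm[a, ] >= 3L)
  for (o in 1:3) {
    if (length(partners) > 0L) {
      cnt <- inserted_bond_counts(ctx, a, partners, o)
      ord <- partners[order(-cnt, partners)]
      blocks[[length(blocks) + 1L]] <- cand_rows("insert_bond", i = a, j = ord, a1 = o)
    }
  }
  dk <- ctx$deg1
  if (nrow(dk) > 0L)
    blocks[[length(blocks) + 1L]] <-
      cand_rows("insert_atom", i = a, a1 = dk[, 2L],
                a2 = dk[, 3L], a3 = dk[, 4L], a4 = dk[, 1L])
  blocks
}

# targeted-value rows for an atom, all three invariant kinds in
# significance order (returned as a list of blocks)
rows_atom_values <- function(ctx, a) {
  list(rows_set_value("set_hydrogens", a, ordered_values(ctx, a, "H", ctx$Hvals)),
       rows_set_value("set_charge", a, ordered_values(ctx, a, "Q", ctx$Qvals)),
       rows_set_value("set_element", a, ordered_values(ctx, a, "Z", ctx$Zvals)))
}

# stack a nested list of row blocks with a single rbind
bind_blocks <- function(blocks) {
  flat <- list()
  add <- function(x) {
    if (is.null(x)) return(invisible())
    if (is.list(x)) lapply(x, add) else flat[[length(flat) + 1L]] <<- x
    invisible()
  }
  add(blocks)
  if (length(flat) == 0L) NULL else do.call(rbind, flat)
}

# cheap leading block of phase 1: the invariant-value edits most likely
# to be consumed by a vertex's first few expansions (the full phase-1
# block is only built if the search keeps coming back)
phase1_first <- function(ctx, diag) {
  if (is.null(diag) || !(diag$culprit == "environment")) return(NULL)
  if (diag$target_type == "atom")
    bind_blocks(rows_atom_values(ctx, diag$target))
  else {
    a <- diag$target[1L]; b <- diag$target[2L]
    old <- ctx$mol$bonds[bond_index(ctx$mol, a, b), 3L]
    rows_set_bond(ctx, a, b, old)
  }
}

# phase 1: edits targeting the diagnosed culprit, most promising first
# (insertion candidates for environment culprits live in their own later
# stage; they are expensive to rank and rarely reached)
phase1_core <- function(ctx, diag) {
  mol <- ctx$mol
  blocks <- list()
  if (diag$culprit %in% c("Z", "Q", "H")) {
    a <- diag$target
    prop <- diag$culprit
    j <- match(prop, c("D", "V", "Z", "Q", "H"))
    succ <- cpp_dict_successors(ctx$d$ptr, 0L,
                                paste(ctx$ak[a, seq_len(j - 1L)], collapse = ","))
    vals <- setdiff(succ$value, ctx$ak[a, j])
    kind <- c(Z = "set_element", Q = "set_charge", H = "set_hydrogens")[[prop]]
    blocks <- list(rows_set_value(kind, a, vals))
  } else if (diag$culprit == "V") {
    a <- diag$target
    inc <- incident_bonds(mol, a)
    for (r in seq_len(inc$n))
      blocks[[length(blocks) + 1L]] <- rows_set_bond(ctx, a, inc$partner[r], inc$order[r])
    blocks[[length(blocks) + 1L]] <- rows_topology_fix(ctx, a)
  } else if (diag$culprit == "D") {
    blocks <- list(rows_topology_fix(ctx, diag$target))
  } else if (diag$culprit == "B") {
    a <- diag$target[1L]; b <- diag$target[2L]
    succ <- cpp_dict_successors(ctx$d$ptr, 1L, diag$predecessor)
    old <- mol$bonds[bond_index(mol, a, b), 3L]
    vals <- setdiff(succ$value, old)
    if (length(vals) > 0L)
      blocks <- list(cand_rows("set_bond_type", i = a, j = b, a1 = vals))
  } else if (diag$culprit == "AK-pair") {
    a <- diag$target[1L]; b <- diag$target[2L]
    for (prop in c("H", "Q", "Z")) {
      kind <- c(Z = "set_element", Q = "set_charge", H = "set_hydrogens")[[prop]]
      uni <- switch(prop, H = ctx$Hvals, Q = ctx$Qvals, Z = ctx$Zvals)
      for (atm in c(a, b))
        blocks[[length(blocks) + 1L]] <-
          rows_set_value(kind, atm, ordered_values(ctx, atm, prop, uni))
    }
    old <- mol$bonds[bond_index(mol, a, b), 3L]
    blocks[[length(blocks) + 1L]] <- rows_set_bond(ctx, a, b, old)
    blocks[[length(blocks) + 1L]] <- cand_rows("delete_bond", i = a, j = b)
    if (n_atoms(mol) >= 2L)
      blocks[[length(blocks) + 1L]] <- cand_rows("delete_atom", i = c(a, b))
  } else {  # environment culprit
    if (diag$target_type == "atom") {
      a <- diag$target
      blocks <- rows_atom_values(ctx, a)
      inc <- incident_bonds(mol, a)
      for (r in seq_len(inc$n))
        blocks[[length(blocks) + 1L]] <- rows_set_bond(ctx, a, inc$partner[r], inc$order[r])
      if (inc$n > 0L) {
        ord <- order(ctx_rep(ctx)$bond_count[inc$k], inc$k)
        blocks[[length(blocks) + 1L]] <- cand_rows("delete_bond", i = a, j = inc$partner[ord])
      }
      if (n_atoms(mol) >= 2L)
        blocks[[length(blocks) + 1L]] <- cand_rows("delete_atom", i = a)
    } else {
      a <- diag$target[1L]; b <- diag$target[2L]
      old <- mol$bonds[bond_index(mol, a, b), 3L]
      blocks[[length(blocks) + 1L]] <- rows_set_bond(ctx, a, b, old)
      blocks[[length(blocks) + 1L]] <- cand_rows("delete_bond", i = a, j = b)
      for (atm in c(a, b))
        blocks[[length(blocks) + 1L]] <- rows_atom_values(ctx, atm)
      if (n_atoms(mol) >= 2L)
        blocks[[length(blocks) + 1L]] <- cand_rows("delete_atom", i = c(a, b))
    }
  }
  bind_blocks(blocks)
}

# phase 1b: insertion candidates targeting an environment-culprit atom
phase1_insertions <- function(ctx, diag) {
  if (is.null(diag) || diag$culprit != "environment" ||
      diag$target_type != "atom" || !ctx$allow_insertions) return(NULL)
  bind_blocks(rows_insertions(ctx, diag$target, cpp_dist_matrix(ctx$mol)))
}

# phase 2: the complete single-edit neighbourhood, ordered by
# (target priority, perturbation significance, value frequency)
phase2_rows <- function(ctx) {
  mol <- ctx$mol
  n <- n_atoms(mol)
  m <- n_bonds(mol)
  rep <- ctx_rep(ctx)
  t <- ctx$d$threshold
  mm <- membership_from_report(mol, rep)
  akey_count <- cpp_dict_counts(ctx$d$ptr, 0L, rep$atom_keys)

  lev <- rep$atom_foreign_level
  ends_fam <- if (m > 0L)
    (lev[mol$bonds[, 1L]] == 0L) & (lev[mol$bonds[, 2L]] == 0L) else logical(0)
  bond_lev <- rep(99L, m)
  bond_lev[ends_fam & rep$pbond_count > t & rep$bond_count <= t] <- 7L
  bond_lev[ends_fam & rep$pbond_count <= t] <- 6L

  # target priority: foreign-key significance, then foreign-environment
  # membership, then key rarity, atoms before bonds, then index
  tgt_type <- c(rep(1L, n), rep(2L, m))
  tgt_idx <- c(seq_len(n), seq_len(m))
  tgt_lev <- c(ifelse(lev > 0L, lev, 99L), bond_lev)
  tgt_memb <- c(mm$atom, mm$bond)
  tgt_freq <- c(akey_count, rep$bond_count)
  ord <- order(tgt_lev, -tgt_memb, tgt_freq, tgt_type, tgt_idx)

  distm <- if (ctx$allow_insertions && n >= 2L) cpp_dist_matrix(mol) else NULL
  # assign each insertable pair to its better-ranked endpoint
  atom_rank <- integer(n)
  atom_rank[tgt_idx[ord][tgt_type[ord] == 1L]] <- seq_len(n)
  pair_owner_a <- integer(0)
  pair_owner_b <- integer(0)
  if (!is.null(distm)) {
    prs <- which(upper.tri(matrix(0L, n, n)) & distm >= 3L, arr.ind = TRUE)
    if (nrow(prs) > 0L) {
      first <- atom_rank[prs[, 1L]] <= atom_rank[prs[, 2L]]
      pair_owner_a <- ifelse(first, prs[, 1L], prs[, 2L])
      pair_owner_b <- ifelse(first, prs[, 2L], prs[, 1L])
    }
  }

  out <- vector("list", length(ord))
  for (r in seq_along(ord)) {
    p <- ord[r]
    if (tgt_type[p] == 1L) {
      a <- tgt_idx[p]
      blocks <- rows_atom_values(ctx, a)
      if (n >= 2L) blocks[[length(blocks) + 1L]] <- cand_rows("delete_atom", i = a)
      if (ctx$allow_insertions) {
        mine <- pair_owner_b[pair_owner_a == a]
        blocks[[length(blocks) + 1L]] <- rows_insertions(ctx, a, distm, partners = mine)
      }
    } else {
      k <- tgt_idx[p]
      a <- mol$bonds[k, 1L]; b <- mol$bonds[k, 2L]
      blocks <- list(rows_set_bond(ctx, a, b, mol$bonds[k, 3L]),
                     cand_rows("delete_bond", i = a, j = b))
    }
    out[[r]] <- blocks
  }
  bind_blocks(out)
}

# vectorized canonical key per candidate row (for deduplication)
row_keys <- function(m) {
  if (NROW(m) == 0L) return(character(0))
  paste(m[, 1L], m[, 2L], m[, 3L], m[, 4L], m[, 5L], m[, 6L], m[, 7L])
}

#' Prioritized stream of candidate perturbations
#'
#' Lazily enumerates the single-edit neighbourhood of a molecule, most
#' promising edits first: perturbations fixing the diagnosed culprit lead
#' (replacement values ranked by their successor frequency in the
#' dictionary), followed by the remaining edits ordered by target priority,
#' perturbation significance and value frequency. The exhausted stream
#' covers the complete single-edit neighbourhood exactly once.
#'
#' @param mol a [molgraph].
#' @param d a [chemical_dictionary].
#' @param diagnosis a [diagnose] result, or `NULL` to skip the targeted
#'   phase (used for fully familiar molecules).
#' @param allow_insertions include bond/atom insertions in the
#'   neighbourhood.
#' @param .report internal: a precomputed familiarity report.
#' @return An object of class `perturbation_stream`; use [stream_next] /
#'   [stream_collect] to consume it.
#' @export
candidate_perturbations <- function(mol, d, diagnosis = NULL,
                                    allow_insertions = TRUE, .report = NULL) {
  assert_molgraph(mol)
  assert_dictionary(d)
  s <- new.env(parent = emptyenv())
  ctx <- stream_context(mol, d, allow_insertions, rep = .report)
  s$stages <- list(
    function() phase1_first(ctx, diagnosis),
    function() if (!is.null(diagnosis)) phase1_core(ctx, diagnosis) else NULL,
    function() phase1_insertions(ctx, diagnosis),
    function() phase2_rows(ctx))
  s$stage <- 0L
  s$mat <- matrix(integer(), 0L, 7L)
  s$seen <- character(0)
  s$pos <- 0L
  class(s) <- "perturbation_stream"
  s
}

# advance the stream; returns a candidate row or NULL when exhausted
stream_next_row <- function(s) {
  repeat {
    if (s$pos < nrow(s$mat)) {
      s$pos <- s$pos + 1L
      return(s$mat[s$pos, ])
    }
    if (s$stage >= length(s$stages)) return(NULL)
    s$stage <- s$stage + 1L
    block <- s$stages[[s$stage]]()
    if (NROW(block) > 0L) {
      keys <- row_keys(block)
      fresh <- !(keys %in% s$seen) & !duplicated(keys)
      block <- block[fresh, , drop = FALSE]
      if (nrow(block) > 0L) {
        s$seen <- c(s$seen, keys[fresh])
        s$mat <- rbind(s$mat, block)
      }
    }
  }
}

#' @rdname candidate_perturbations
#' @param s a `perturbation_stream`.
#' @return `stream_next()`: the next [perturbation], or `NULL` when the
#'   stream is exhausted.
#' @export
stream_next <- function(s) {
  r <- stream_next_row(s)
  if (is.null(r)) NULL else row_to_perturbation(r)
}

#' @rdname candidate_perturbations
#' @param max maximum number of perturbations to collect.
#' @return `stream_collect()`: list of [perturbation]s in stream order.
#' @export
stream_collect <- function(s, max = Inf) {
  out <- list()
  while (length(out) < max) {
    p <- stream_next(s)
    if (is.null(p)) break
    out[[length(out) + 1L]] <- p
  }
  out
}

#' @export
print.perturbation_stream <- function(x, ...) {
  cat(sprintf("<perturbation_stream> position %d%s\n", x$pos,
              if (x$stage < length(x$stages))
                " (neighbourhood not yet fully enumerated)"
              else sprintf(" of %d", nrow(x$mat))))
  invisible(x)
}
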
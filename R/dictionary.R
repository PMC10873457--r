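#' Build a chemical dictionary from reference molecules
#'
#' Every key occurrence (atom, partial atom, bond, partial bond and
#' environment keys) in every reference molecule increments that key's
#' count, so counting is per-occurrence: duplicating a reference molecule
#' doubles its contribution. A key whose count strictly exceeds the
#' threshold is *familiar*; all other keys (including absent ones) are
#' *foreign*.
#'
#' @param reference a non-empty list of [molgraph] objects, or a character
#'   vector of SMILES strings.
#' @param radius environment radius used for environment keys (the tool is
#'   typically run with radius 1 or 2).
#' @param threshold familiarity threshold `t`; a key is familiar iff its
#'   count `> t`. Default 0: any key seen once in the reference is familiar.
#' @return An object of class `chemical_dictionary`.
#' @examples
#' d <- chemical_dictionary(c("CCO", "CCN", "CCC"), radius = 1)
#' d
#' @export
chemical_dictionary <- function(reference, radius = 1L, threshold = 0L) {
  if (is.character(reference)) reference <- lapply(reference, parse_smiles)
  if (!is.list(reference) || length(reference) == 0L)
    stop("reference must be a non-empty list of molecules")
  if (radius < 0L) stop("radius must be non-negative")
  if (threshold < 0L) stop("threshold must be non-negative")
  ptr <- cpp_dict_new(as.integer(radius), as.numeric(threshold))
  for (m in reference) {
    assert_molgraph(m)
    cpp_dict_add_molecule(ptr, m)
  }
  new_chemical_dictionary(ptr)
}

new_chemical_dictionary <- function(ptr) {
  info <- cpp_dict_info(ptr)
  vs <- cpp_dict_value_sets(ptr)
  structure(list(ptr = ptr,
                 radius = info$radius,
                 threshold = info$threshold,
                 n_molecules = info$n_molecules,
                 hash_scheme = HASH_SCHEME,
                 value_sets = vs,
                 # single-edit value universes used by the expansion policy
                 universe = list(H = sort(union(0:4, vs$H)),
                                 Q = sort(union(-2:2, vs$Q)),
                                 Z = sort(union(ORGANIC_Z, vs$Z)))),
            class = "chemical_dictionary")
}

assert_dictionary <- function(d) {
  if (!inherits(d, "chemical_dictionary")) stop("expected a 'chemical_dictionary'")
  invisible(d)
}

#' @export
print.chemical_dictionary <- function(x, ...) {
  info <- cpp_dict_info(x$ptr)
  cat(sprintf("<chemical_dictionary> radius %d, threshold %g, %g reference molecule(s)\n",
              info$radius, info$threshold, info$n_molecules))
  nk <- info$n_keys
  cat(sprintf("  keys: %d atom, %d partial-atom, %d bond, %d partial-bond, %d environment\n",
              nk[[1L]], nk[[2L]], nk[[3L]], nk[[4L]], nk[[5L]]))
  invisible(x)
}

# dictionary category index for a key object
key_category <- function(key) {
  if (inherits(key, "bond_key")) return(2L)
  if (inherits(key, "partial_bond_key")) return(3L)
  if (inherits(key, "environment_key")) return(4L)
  if (is.character(key) && length(key) == 1L) {
    if (grepl("^[0-9a-f]{16}$", key)) return(4L)
    nsemi <- lengths(regmatches(key, gregexpr(";", key, fixed = TRUE)))
    if (nsemi == 2L) return(2L)
    if (nsemi == 1L) return(3L)
    nfld <- length(strsplit(key, ",", fixed = TRUE)[[1L]])
    return(if (nfld == 5L) 0L else 1L)
  }
  if (is.numeric(key)) return(if (length(key) == 5L) 0L else 1L)
  if (inherits(key, "atom_key")) return(0L)
  if (inherits(key, "partial_atom_key")) return(1L)
  stop("unrecognized key object")
}

#' Look up and classify a key
#'
#' @param d a [chemical_dictionary].
#' @param key a key object ([compute_atom_key], partial key,
#'   [compute_bond_key], [compute_environment_key]) or its string form.
#' @return `classify_key()`: `"familiar"` if the key's count strictly
#'   exceeds the dictionary threshold, else `"foreign"`. Absent keys have
#'   count 0. `key_count()`: the raw count.
#' @export
classify_key <- function(d, key) {
  if (key_count(d, key) > d$threshold) "familiar" else "foreign"
}

#' @rdname classify_key
#' @export
key_count <- function(d, key) {
  assert_dictionary(d)
  as.numeric(cpp_dict_counts(d$ptr, key_category(key), key_string(key)))
}

#' Successor values for a partial key
#'
#' Given a partial key, return the values of the next (one more significant
#' position) property observed in the reference molecules, most frequent
#' first (ties broken by ascending value). This is how the expansion policy
#' ranks replacement values: e.g. the partial atom key `(D, V) = (4, 6)`
#' may return sulfur (Z = 16) before selenium (Z = 34) when sulfones
#' outnumber selenones in the reference.
#'
#' @param d a [chemical_dictionary].
#' @param partial_key a partial atom key (integer vector of length 0-4) or a
#'   partial bond key (for `property = "B"`).
#' @param property the property extending the partial key: one of
#'   `"D", "V", "Z", "Q", "H"` (atoms; must be the position following the
#'   prefix) or `"B"` (bond order).
#' @return A data.frame with columns `value` and `count`; zero rows for an
#'   unseen partial key.
#' @examples
#' d <- chemical_dictionary(c("CS(C)(=O)=O", "CS(C)(=O)=O", "C[Se](C)(=O)=O"))
#' successor_values(d, c(4, 6), "Z")   # sulfur first
#' @export
successor_values <- function(d, partial_key, property) {
  assert_dictionary(d)
  property <- match.arg(property, c("D", "V", "Z", "Q", "H", "B"))
  if (property == "B") {
    if (!inherits(partial_key, c("partial_bond_key", "bond_key")) &&
        !(is.character(partial_key) && length(partial_key) == 1L))
      stop("property 'B' requires a partial bond key")
    pk <- if (inherits(partial_key, "bond_key"))
      key_string(partial_bond_key(partial_key)) else key_string(partial_key)
    out <- cpp_dict_successors(d$ptr, 1L, pk)
  } else {
    j <- match(property, c("D", "V", "Z", "Q", "H"))
    pk <- as.integer(partial_key)
    if (length(pk) != j - 1L)
      stop("property '", property, "' extends a partial key of length ", j - 1L)
    out <- cpp_dict_successors(d$ptr, 0L, paste(pk, collapse = ","))
  }
  data.frame(value = as.integer(out$value), count = as.numeric(out$count))
}

#' Familiarity of a molecule against a dictionary
#'
#' Featurizes the molecule and classifies every key. With `n` total keys
#' (`n = n_a + n_b + n_e`) and `n_f` familiar keys, the two familiarity
#' scores are `f1 = n_f / n` (fraction familiar) and
#' `f2 = 1 / (n - n_f + 1)` (a size-robust score that cannot be inflated by
#' appending familiar atoms). Both equal 1 exactly when the molecule is
#' correct (all keys familiar). Key labels honour the dependency hierarchy:
#' a bond or environment key containing a foreign key is itself foreign.
#'
#' @param mol a [molgraph] with at least one atom.
#' @param d a [chemical_dictionary].
#' @return An object of class `familiarity_report`: counts `n_a`, `n_b`,
#'   `n_e`, `n`, familiar counts `nf_a`, `nf_b`, `nf_e`, `nf`, scores `f1`,
#'   `f2`, and per-key labels (`atom_familiar`, `bond_familiar`,
#'   `env_familiar`).
#' @export
familiarity_report <- function(mol, d) {
  assert_molgraph(mol)
  assert_dictionary(d)
  if (n_atoms(mol) == 0L) stop("familiarity is undefined for an empty molecule")
  rep <- cpp_familiarity(d$ptr, mol, details = TRUE)
  class(rep) <- "familiarity_report"
  rep
}

#' @export
print.familiarity_report <- function(x, ...) {
  cat(sprintf("<familiarity_report> n=%d (atoms %d, bonds %d, environments %d)\n",
              x$n, x$n_a, x$n_b, x$n_e))
  cat(sprintf("  familiar %d/%d: f1 = %.4f, f2 = %.4f\n", x$nf, x$n, x$f1, x$f2))
  invisible(x)
}

DICT_CATEGORIES <- c("atom", "partial_atom", "bond", "partial_bond", "environment")

#' Persist and reload a chemical dictionary
#'
#' The on-disk format is a UTF-8 TSV: `#`-prefixed header lines (`radius`,
#' `threshold`, `hash_scheme`, `n_molecules`) followed by one
#' `category<TAB>key<TAB>count` line per stored key, sorted
#' lexicographically. Counts are decimal integers, so a round trip is
#' lossless; loading a file whose hash scheme differs from the package's is
#' refused.
#'
#' @param d a [chemical_dictionary].
#' @param path file path.
#' @return `read_dictionary()` returns the reloaded [chemical_dictionary];
#'   `write_dictionary()` returns `path` invisibly.
#' @export
write_dictionary <- function(d, path) {
  assert_dictionary(d)
  tabs <- cpp_dict_export(d$ptr)
  info <- cpp_dict_info(d$ptr)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("#radius\t%d", info$radius),
               sprintf("#threshold\t%.0f", info$threshold),
               sprintf("#hash_scheme\t%s", d$hash_scheme),
               sprintf("#n_molecules\t%.0f", info$n_molecules)), con)
  for (cat_i in order(DICT_CATEGORIES)) {
    t <- tabs[[cat_i]]
    if (length(t$key) == 0L) next
    writeLines(sprintf("%s\t%s\t%.0f", DICT_CATEGORIES[cat_i], t$key, t$count), con)
  }
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- list(radius = NA, threshold = NA, hash_scheme = NA, n_molecules = NA)
  body_start <- 1L
  for (i in seq_along(lines)) {
    if (!startsWith(lines[i], "#")) { body_start <- i; break }
    fld <- strsplit(sub("^#", "", lines[i]), "\t", fixed = TRUE)[[1L]]
    if (length(fld) != 2L) stop("malformed header at line ", i)
    hdr[[fld[1L]]] <- fld[2L]
    body_start <- i + 1L
  }
  if (is.na(hdr$radius) || is.na(hdr$threshold) || is.na(hdr$hash_scheme))
    stop("dictionary file is missing required headers")
  if (!identical(hdr$hash_scheme, HASH_SCHEME))
    stop("dictionary hash scheme '", hdr$hash_scheme,
         "' does not match this package's scheme '", HASH_SCHEME, "'")
  keys <- rep(list(character(0)), 5L)
  counts <- rep(list(numeric(0)), 5L)
  if (body_start <= length(lines)) {
    for (i in seq(body_start, length(lines))) {
      if (!nzchar(lines[i])) next
      fld <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
      ci <- match(fld[1L], DICT_CATEGORIES)
      cnt <- suppressWarnings(as.numeric(fld[3L]))
      if (length(fld) != 3L || is.na(ci) || is.na(cnt))
        stop("malformed dictionary line ", i, ": ", lines[i])
      keys[[ci]] <- c(keys[[ci]], fld[2L])
      counts[[ci]] <- c(counts[[ci]], cnt)
    }
  }
  tables <- lapply(1:5, function(ci) list(key = keys[[ci]], count = counts[[ci]]))
  ptr <- cpp_dict_import(as.integer(hdr$radius), as.numeric(hdr$threshold),
                         as.numeric(hdr$n_molecules), tables)
  new_chemical_dictionary(ptr)
}

#' Compare two dictionaries for equality
#'
#' @param a,b [chemical_dictionary] objects.
#' @return `TRUE` when radius, threshold, hash scheme, reference size and
#'   every count table agree exactly.
#' @export
dict_equal <- function(a, b) {
  assert_dictionary(a)
  assert_dictionary(b)
  ia <- cpp_dict_info(a$ptr)
  ib <- cpp_dict_info(b$ptr)
  if (!identical(ia$radius, ib$radius) || ia$threshold != ib$threshold ||
      ia$n_molecules != ib$n_molecules ||
      !identical(a$hash_scheme, b$hash_scheme)) return(FALSE)
  ea <- cpp_dict_export(a$ptr)
  eb <- cpp_dict_export(b$ptr)
  for (i in 1:5) {
    if (!identical(as.character(ea[[i]]$key), as.character(eb[[i]]$key))) return(FALSE)
    if (!identical(as.numeric(ea[[i]]$count), as.numeric(eb[[i]]$count))) return(FALSE)
  }
  TRUE
}

#' Drop keys from a dictionary
#'
#' Returns a new dictionary with the given keys removed from one category
#' table (counts of other categories are untouched). Mainly useful for
#' sensitivity analyses: ablating keys makes dependent keys foreign through
#' the classification cascade.
#'
#' @param d a [chemical_dictionary].
#' @param category one of `"atom"`, `"partial_atom"`, `"bond"`,
#'   `"partial_bond"`, `"environment"`.
#' @param keys character vector of key strings to remove.
#' @return A new [chemical_dictionary].
#' @export
dict_drop_keys <- function(d, category, keys) {
  assert_dictionary(d)
  ci <- match(match.arg(category, DICT_CATEGORIES), DICT_CATEGORIES)
  tabs <- cpp_dict_export(d$ptr)
  info <- cpp_dict_info(d$ptr)
  keep <- !(tabs[[ci]]$key %in% keys)
  tabs[[ci]] <- list(key = tabs[[ci]]$key[keep], count = tabs[[ci]]$count[keep])
  tables <- lapply(1:5, function(i) list(key = as.character(tabs[[i]]$key),
                                         count = as.numeric(tabs[[i]]$count)))
  ptr <- cpp_dict_import(info$radius, info$threshold, info$n_molecules, tables)
  new_chemical_dictionary(ptr)
}
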
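# Lenient SMILES reader/writer. The whole point of the package is operating
# on chemically invalid molecules, so parsing performs NO valence rejection:
# any syntactically well-formed SMILES yields a molgraph. Aromatic input is
# kekulized on read (bond orders are integers 1-3 throughout); stereo marks
# and isotopes are accepted and discarded.

ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn")

symbol_to_Z <- function(sym) {
  z <- match(sym, ELEMENT_SYMBOLS)
  if (is.na(z)) stop("unknown element symbol '", sym, "'")
  as.integer(z)
}

# smallest standard valence >= V, or NA when no table entry / V too large
implicit_h_count <- function(Z, Q, V) {
  dv <- cpp_default_valences(as.integer(Z), as.integer(Q))
  if (length(dv) == 0L) return(0L)
  dv <- dv[dv >= V]
  if (length(dv) == 0L) return(0L)
  as.integer(dv[1L] - V)
}

#' Parse a SMILES string into a molecular graph
#'
#' Syntactically valid SMILES are parsed without any valence check, so
#' chemically impossible molecules (the intended inputs of the correction
#' algorithm) parse fine. Aromatic notation is kekulized to integer bond
#' orders; explicit `[H]` atoms are folded into the heavy-atom hydrogen
#' counts; stereo bonds and isotope labels are ignored.
#'
#' @param s a single SMILES string.
#' @return A [molgraph].
#' @examples
#' parse_smiles("CCO")            # ethanol
#' parse_smiles("OOC1[C]2#S1C2")  # chemically invalid, parses anyway
#' @export
parse_smiles <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s)) stop("expected one SMILES string")
  s <- trimws(s)
  if (!nzchar(s)) stop("empty SMILES string")
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  nc <- length(chars)

  Z <- integer(); Q <- integer(); Hexp <- integer(); arom <- logical()
  ba <- integer(); bb <- integer(); bsym <- character()
  prev <- NA_integer_
  pending <- NA_character_
  stack <- integer()
  rings <- list()

  add_atom <- function(z, q, h, ar) {
    Z[length(Z) + 1L] <<- z
    Q[length(Q) + 1L] <<- q
    Hexp[length(Hexp) + 1L] <<- h
    arom[length(arom) + 1L] <<- ar
    id <- length(Z)
    if (!is.na(prev)) {
      sym <- pending
      if (is.na(sym)) sym <- if (arom[prev] && ar) ":" else "-"
      ba[length(ba) + 1L] <<- prev
      bb[length(bb) + 1L] <<- id
      bsym[length(bsym) + 1L] <<- sym
    }
    pending <<- NA_character_
    prev <<- id
    invisible(id)
  }

  close_ring <- function(num) {
    if (is.na(prev)) stop("ring closure before any atom (position ", i, ")")
    key <- as.character(num)
    if (!is.null(rings[[key]])) {
      open <- rings[[key]]
      rings[[key]] <<- NULL
      if (open$atom == prev) stop("ring closure bonds an atom to itself")
      sym <- pending
      if (!is.na(open$sym)) {
        if (!is.na(sym) && sym != open$sym)
          stop("conflicting ring-closure bond symbols for ring ", key)
        sym <- open$sym
      }
      if (is.na(sym)) sym <- if (arom[open$atom] && arom[prev]) ":" else "-"
      if (any((ba == open$atom & bb == prev) | (ba == prev & bb == open$atom)))
        stop("duplicate bond via ring closure ", key)
      ba[length(ba) + 1L] <<- open$atom
      bb[length(bb) + 1L] <<- prev
      bsym[length(bsym) + 1L] <<- sym
    } else {
      rings[[key]] <<- list(atom = prev, sym = pending)
    }
    pending <<- NA_character_
  }

  i <- 1L
  while (i <= nc) {
    ch <- chars[i]
    if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      if (!is.na(pending)) stop("two consecutive bond symbols (position ", i, ")")
      pending <- if (ch %in% c("/", "\\")) "-" else ch
      i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) stop("branch before any atom (position ", i, ")")
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) stop("unmatched ')' (position ", i, ")")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      if (!is.na(pending)) stop("bond symbol before '.' (position ", i, ")")
      prev <- NA_integer_
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      close_ring(ch)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > nc || !grepl("^[0-9][0-9]$", paste0(chars[i + 1L], chars[i + 2L])))
        stop("'%' ring closure needs two digits (position ", i, ")")
      close_ring(paste0(chars[i + 1L], chars[i + 2L]))
      i <- i + 3L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= nc && chars[j] != "]") j <- j + 1L
      if (j > nc) stop("unclosed '[' (position ", i, ")")
      parsed <- parse_bracket_atom(paste(chars[(i + 1L):(j - 1L)], collapse = ""), i)
      add_atom(parsed$Z, parsed$Q, parsed$H, parsed$arom)
      i <- j + 1L
    } else {
      two <- if (i < nc) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(symbol_to_Z(two), 0L, NA_integer_, FALSE)
        i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        add_atom(symbol_to_Z(ch), 0L, NA_integer_, FALSE)
        i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        add_atom(symbol_to_Z(toupper(ch)), 0L, NA_integer_, TRUE)
        i <- i + 1L
      } else {
        stop("unexpected character '", ch, "' (position ", i, ")")
      }
    }
  }
  if (length(rings) > 0L)
    stop("unclosed ring bond(s): ", paste(names(rings), collapse = ", "))
  if (length(stack) > 0L) stop("unclosed '(' branch")
  if (length(Z) == 0L) stop("SMILES contains no atoms")
  finalize_parsed(Z, Q, Hexp, arom, ba, bb, bsym)
}

# contents of a bracket atom, e.g. "13CH4", "nH+", "O-", "C@@H"
parse_bracket_atom <- function(txt, pos) {
  orig <- txt
  txt <- sub("^[0-9]+", "", txt)              # isotope: ignored
  m <- regmatches(txt, regexpr("^([A-Z][a-z]?|as|se|[bcnops])", txt))
  if (length(m) == 0L)
    stop("cannot parse bracket atom '[", orig, "]' (position ", pos, ")")
  sym <- m
  txt <- substring(txt, nchar(sym) + 1L)
  ar <- sym %in% c("b", "c", "n", "o", "p", "s", "as", "se")
  z <- symbol_to_Z(if (ar) paste0(toupper(substring(sym, 1L, 1L)),
                                  substring(sym, 2L)) else sym)
  txt <- gsub("@", "", txt, fixed = TRUE)      # chirality: ignored
  h <- 0L
  hm <- regmatches(txt, regexpr("^H[0-9]*", txt))
  if (length(hm) == 1L && nzchar(hm)) {
    h <- if (nchar(hm) == 1L) 1L else as.integer(substring(hm, 2L))
    txt <- substring(txt, nchar(hm) + 1L)
  }
  q <- 0L
  qm <- regmatches(txt, regexpr("^(\\+[0-9]+|-[0-9]+|\\++|-+)", txt))
  if (length(qm) == 1L && nzchar(qm)) {
    q <- if (grepl("^[+-][0-9]+$", qm)) {
      as.integer(qm)
    } else {
      s <- if (substring(qm, 1L, 1L) == "+") 1L else -1L
      s * nchar(qm)
    }
    txt <- substring(txt, nchar(qm) + 1L)
  }
  txt <- sub("^:[0-9]+", "", txt)              # atom map: ignored
  if (nzchar(txt))
    stop("cannot parse bracket atom '[", orig, "]' (position ", pos, ")")
  list(Z = z, Q = q, H = h, arom = ar)
}

# Kekulize aromatic bonds and materialize implicit hydrogen counts.
# bsym: "-", "=", "#" or ":" per parsed bond.
finalize_parsed <- function(Z, Q, Hexp, arom, ba, bb, bsym) {
  n <- length(Z)
  order <- c("-" = 1L, "=" = 2L, "#" = 3L, ":" = NA_integer_)[bsym]
  is_arom_bond <- is.na(order)

  if (any(is_arom_bond)) {
    # which atoms still require a double bond for a sensible valence
    fv <- integer(n)      # fixed valence: explicit orders + aromatic as 1
    for (k in seq_along(ba)) {
      o <- if (is_arom_bond[k]) 1L else order[k]
      fv[ba[k]] <- fv[ba[k]] + o
      fv[bb[k]] <- fv[bb[k]] + o
    }
    fv <- fv + ifelse(is.na(Hexp), 0L, Hexp)
    needs <- logical(n)
    for (a in which(arom)) {
      dv <- cpp_default_valences(Z[a], Q[a])
      dv <- dv[dv >= fv[a]]
      needs[a] <- length(dv) > 0L && (dv[1L] - fv[a]) >= 1L
    }
    # perfect matching of needy atoms over aromatic bonds
    cand <- which(is_arom_bond & needs[ba] & needs[bb])
    adj <- vector("list", n)
    for (k in cand) {
      adj[[ba[k]]] <- c(adj[[ba[k]]], k)
      adj[[bb[k]]] <- c(adj[[bb[k]]], k)
    }
    matched_bonds <- kekule_match(which(needs), adj, ba, bb)
    if (is.null(matched_bonds))
      stop("kekulization failed: no alternating bond assignment exists")
    order[is_arom_bond] <- 1L
    order[matched_bonds] <- 2L
  }

  bonds <- cbind(a = ba, b = bb, order = order)
  # fold explicit hydrogen atoms into neighbour H counts
  n_hexp <- integer(n)
  hyd <- which(Z == 1L)
  if (length(hyd) > 0L) {
    keep <- setdiff(seq_len(n), hyd)
    for (h in hyd) {
      inc <- which(bonds[, 1L] == h | bonds[, 2L] == h)
      if (length(inc) != 1L || bonds[inc, 3L] != 1L || Q[h] != 0L)
        stop("explicit hydrogen atoms must have exactly one single bond")
      nb <- setdiff(bonds[inc, 1:2], h)
      if (Z[nb] == 1L) stop("H-H bonds are not supported")
      n_hexp[nb] <- n_hexp[nb] + 1L
    }
    bonds <- bonds[!(bonds[, 1L] %in% hyd | bonds[, 2L] %in% hyd), , drop = FALSE]
    remap <- match(seq_len(n), keep)
    bonds[, 1L] <- remap[bonds[, 1L]]
    bonds[, 2L] <- remap[bonds[, 2L]]
    Z <- Z[keep]; Q <- Q[keep]; Hexp <- Hexp[keep]; n_hexp <- n_hexp[keep]
  }

  V <- integer(length(Z))
  if (nrow(bonds) > 0L) {
    for (k in seq_len(nrow(bonds))) {
      V[bonds[k, 1L]] <- V[bonds[k, 1L]] + bonds[k, 3L]
      V[bonds[k, 2L]] <- V[bonds[k, 2L]] + bonds[k, 3L]
    }
  }
  # an explicit [H] counts toward the valence used for the implicit-H model
  H <- Hexp + n_hexp
  for (a in which(is.na(Hexp)))
    H[a] <- implicit_h_count(Z[a], Q[a], V[a] + n_hexp[a]) + n_hexp[a]
  molgraph(Z = Z, Q = Q, H = H, bonds = bonds)
}

# backtracking perfect matching; returns matched bond indices or NULL
kekule_match <- function(needy, adj, ba, bb) {
  matched <- logical(max(c(needy, 0L)))
  chosen <- integer(0)
  rec <- function() {
    un <- needy[!matched[needy]]
    if (length(un) == 0L) return(TRUE)
    a <- un[1L]
    for (k in adj[[a]]) {
      other <- if (ba[k] == a) bb[k] else ba[k]
      if (matched[other]) next
      matched[a] <<- TRUE; matched[other] <<- TRUE
      chosen <<- c(chosen, k)
      if (rec()) return(TRUE)
      matched[a] <<- FALSE; matched[other] <<- FALSE
      chosen <<- chosen[-length(chosen)]
    }
    FALSE
  }
  if (length(needy) == 0L) return(integer(0))
  if (rec()) chosen else NULL
}

#' Write a molecular graph as a SMILES string
#'
#' Output is always Kekule (integer bond orders, no aromatic notation).
#' Atoms of the organic subset whose hydrogen count matches the standard
#' valence model are written bare; all other atoms are bracketed with
#' explicit hydrogen counts and charges, so the string round-trips to an
#' isomorphic graph even for chemically invalid molecules.
#'
#' @param mol a [molgraph].
#' @return A single SMILES string.
#' @export
write_smiles <- function(mol) {
  assert_molgraph(mol)
  n <- n_atoms(mol)
  if (n == 0L) stop("cannot write an empty molecule")
  V <- integer(n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    V[b[k, 1L]] <- V[b[k, 1L]] + b[k, 3L]
    V[b[k, 2L]] <- V[b[k, 2L]] + b[k, 3L]
  }
  atom_token <- function(a) {
    sym <- ELEMENT_SYMBOLS[mol$Z[a]]
    organic <- mol$Z[a] %in% ORGANIC_Z
    if (organic && mol$Q[a] == 0L &&
        mol$H[a] == implicit_h_count(mol$Z[a], 0L, V[a])) return(sym)
    h <- if (mol$H[a] == 0L) "" else if (mol$H[a] == 1L) "H" else paste0("H", mol$H[a])
    q <- if (mol$Q[a] == 0L) "" else if (mol$Q[a] == 1L) "+" else if (mol$Q[a] == -1L) "-"
         else sprintf("%+d", mol$Q[a])
    paste0("[", sym, h, q, "]")
  }
  bond_token <- function(o) c("", "=", "#")[o]

  nb_of <- function(k, a) if (b[k, 1L] == a) b[k, 2L] else b[k, 1L]
  incident <- lapply(seq_len(n), function(a) which(b[, 1L] == a | b[, 2L] == a))

  # pass 1: classify edges as DFS-tree or ring-closure, in bond-index order
  state <- integer(nrow(b))                # 0 unknown, 1 tree, 2 closure
  visited <- logical(n)
  classify <- function(a, from) {
    visited[a] <<- TRUE
    for (k in incident[[a]]) {
      if (k == from || state[k] != 0L) next
      v <- nb_of(k, a)
      if (visited[v]) state[k] <<- 2L
      else { state[k] <<- 1L; classify(v, k) }
    }
  }
  starts <- integer(0)
  for (s in seq_len(n)) if (!visited[s]) { starts <- c(starts, s); classify(s, 0L) }

  # pass 2: emit, assigning ring-closure digits at both endpoints
  ring_num <- integer(nrow(b))
  next_num <- 0L
  free_nums <- integer(0)
  closure_suffix <- function(k) {
    num <- ring_num[k]
    if (num == 0L) {
      if (length(free_nums) > 0L) { num <- free_nums[1L]; free_nums <<- free_nums[-1L] }
      else { next_num <<- next_num + 1L; num <- next_num }
      ring_num[k] <<- num
    } else {
      free_nums <<- sort(c(free_nums, num))
    }
    dig <- if (num < 10L) as.character(num) else sprintf("%%%02d", num)
    paste0(bond_token(b[k, 3L]), dig)
  }
  emit <- function(a, from) {
    s <- atom_token(a)
    for (k in incident[[a]]) if (k != from && state[k] == 2L)
      s <- paste0(s, closure_suffix(k))
    kids <- character(0)
    for (k in incident[[a]]) if (k != from && state[k] == 1L)
      kids <- c(kids, paste0(bond_token(b[k, 3L]), emit(nb_of(k, a), k)))
    if (length(kids) > 0L)
      s <- paste0(s,
                  paste0(vapply(head(kids, -1L), function(x) paste0("(", x, ")"),
                                character(1L)), collapse = ""),
                  kids[length(kids)])
    s
  }
  paste(vapply(starts, function(s) emit(s, 0L), character(1L)), collapse = ".")
}
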
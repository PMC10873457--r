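# Correction tree search. Vertices are stored in parallel vectors inside an
# environment; selection policies use either a static-key binary heap
# (BFS, greedy, A*, MLR, objective) or a UCB1-guided tree descent (UCT).

SEARCH_POLICIES <- c("bfs", "greedy_f1", "greedy_f2", "greedy_ratio", "uct",
                     "astar", "mlr", "objective")

#' Create a correction search tree
#'
#' The input molecule becomes the root vertex. Use [select_vertex] and
#' [expand_vertex] to drive the search manually, or [correct_molecule] to
#' run it to completion.
#'
#' @param mol the input [molgraph] (the root; may be chemically invalid).
#' @param d a [chemical_dictionary].
#' @param policy selection policy: one of `"bfs"`, `"greedy_f1"`,
#'   `"greedy_f2"`, `"greedy_ratio"`, `"uct"`, `"astar"`, `"mlr"`,
#'   `"objective"`. (`"greedy_f1"` is provided mainly to demonstrate its
#'   known failure mode: `f1` can be inflated by growing familiar alkane
#'   chains, which `f2` is immune to.)
#' @param max_depth vertices at this depth are never selected for
#'   expansion (default 25, the benchmark setting).
#' @param max_tree_size maximum number of accepted vertices including the
#'   root (default 25000).
#' @param constraints list of predicate functions `molgraph -> TRUE/FALSE`;
#'   children violating any constraint are discarded.
#' @param objective for the `"objective"` policy: a function
#'   `molgraph -> [0, 1]` whose value is multiplied with `f1`.
#' @param sanitize sanitize hydrogen counts after each perturbation.
#' @param allow_insertions include bond/atom insertions in the expansion
#'   neighbourhood.
#' @param uct_c UCT exploration coefficient (default 0.5).
#' @param mlr_model an [mlr_model] for the `"mlr"` policy.
#' @return An environment of class `search_tree`.
#' @export
new_search_tree <- function(mol, d, policy = "mlr",
                            max_depth = 25L, max_tree_size = 25000L,
                            constraints = list(), objective = NULL,
                            sanitize = TRUE, allow_insertions = TRUE,
                            uct_c = 0.5, mlr_model = default_mlr_model()) {
  assert_molgraph(mol)
  assert_dictionary(d)
  policy <- match.arg(policy, SEARCH_POLICIES)
  if (n_atoms(mol) == 0L) stop("cannot correct an empty molecule")
  if (max_depth < 1L || max_tree_size < 1L) stop("budgets must be >= 1")
  if (policy == "objective" && !is.function(objective))
    stop("the 'objective' policy needs an objective function")
  tr <- new.env(parent = emptyenv())
  tr$d <- d
  tr$policy <- policy
  tr$max_depth <- as.integer(max_depth)
  tr$max_tree_size <- as.integer(max_tree_size)
  tr$depth_limit <- as.integer(max_depth)
  tr$constraints <- constraints
  tr$objective <- objective
  tr$sanitize <- isTRUE(sanitize)
  tr$allow_insertions <- isTRUE(allow_insertions)
  tr$uct_c <- uct_c
  tr$mlr <- mlr_model
  cap <- 1024L
  # id-keyed stores (environments: O(1) insertion without spine copies)
  tr$mols <- new.env(parent = emptyenv(), hash = TRUE)
  tr$fps <- new.env(parent = emptyenv(), hash = TRUE)
  tr$cand <- new.env(parent = emptyenv(), hash = TRUE)
  tr$children <- new.env(parent = emptyenv(), hash = TRUE)
  tr$parent <- integer(cap)
  tr$depth <- integer(cap)
  tr$f1 <- numeric(cap)
  tr$f2 <- numeric(cap)
  tr$droot <- numeric(cap)
  tr$nv <- integer(cap)
  tr$child_sum <- numeric(cap)
  tr$child_cnt <- integer(cap)
  tr$fully <- logical(cap)
  tr$obj <- numeric(cap)
  tr$subtree_elig <- logical(cap)
  tr$size <- 0L
  tr$iterations <- 0L
  tr$solutions <- integer(0)
  tr$best_id <- 1L
  tr$hkey <- numeric(1024L)
  tr$hid <- integer(1024L)
  tr$hn <- 0L
  tr$hashmap <- new.env(parent = emptyenv(), hash = TRUE)
  class(tr) <- "search_tree"

  fp <- cpp_fingerprint(mol)
  tr$root_fp <- fp
  fam <- cpp_familiarity(d$ptr, mol, details = FALSE)
  tree_insert(tr, mol, parent = 0L, fam = fam, fp = fp, droot = 0,
              ghash = cpp_graph_hash(mol))
  tr
}

#' @export
print.search_tree <- function(x, ...) {
  cat(sprintf("<search_tree> policy %s: %d vertices, %d iterations, %d solution(s)\n",
              x$policy, x$size, x$iterations, length(x$solutions)))
  invisible(x)
}

tree_grow <- function(tr, need) {
  cap <- length(tr$parent)
  if (need <= cap) return(invisible())
  newcap <- max(cap * 2L, need)
  for (f in c("parent", "depth", "nv", "child_cnt"))
    tr[[f]] <- c(tr[[f]], integer(newcap - cap))
  for (f in c("f1", "f2", "droot", "child_sum", "obj"))
    tr[[f]] <- c(tr[[f]], numeric(newcap - cap))
  for (f in c("fully", "subtree_elig"))
    tr[[f]] <- c(tr[[f]], logical(newcap - cap))
  invisible()
}

tree_eligible <- function(tr, id) {
  !tr$fully[id] && tr$f1[id] < 1 && tr$depth[id] < tr$depth_limit
}

# static selection key per policy (lower is better)
policy_key <- function(tr, id) {
  switch(tr$policy,
    bfs = as.numeric(tr$depth[id]),
    greedy_f1 = -tr$f1[id],
    greedy_f2 = -tr$f2[id],
    greedy_ratio = -(tr$f1[id] / max(tr$droot[id], 1 / 1024)),
    astar = tr$droot[id] + 1 - tr$f1[id],
    mlr = tr$mlr$coef_d * tr$droot[id] + tr$mlr$coef_f1 * tr$f1[id] +
          tr$mlr$intercept,
    objective = -(tr$f1[id] * tr$obj[id]),
    uct = NA_real_)
}

tree_insert <- function(tr, mol, parent, fam, fp, droot, ghash) {
  id <- tr$size + 1L
  tree_grow(tr, id)
  tr$size <- id
  key <- as.character(id)
  tr$mols[[key]] <- mol
  tr$fps[[key]] <- fp
  f1 <- fam$f1
  f2 <- fam$f2
  depth <- if (parent == 0L) 0L else tr$depth[parent] + 1L
  elig <- f1 < 1 && depth < tr$depth_limit
  cpp_vertex_init(tr$parent, tr$depth, tr$f1, tr$f2, tr$droot, tr$nv,
                  tr$fully, tr$subtree_elig, tr$child_sum, tr$child_cnt,
                  id, parent, depth, f1, f2, droot, elig)
  assign(ghash, id, envir = tr$hashmap)
  if (tr$policy == "objective") {
    o <- tr$objective(mol)
    if (!is.numeric(o) || length(o) != 1L || is.na(o) || o < 0 || o > 1)
      stop("objective function must return a single value in [0, 1]")
    cpp_set_real(tr$obj, id, o)
  }
  if (parent > 0L) {
    pk <- as.character(parent)
    tr$children[[pk]] <- c(tr$children[[pk]], id)
  }
  if (f1 >= 1) tr$solutions <- c(tr$solutions, id)
  # best-so-far: max f2, then min distance to root, then insertion order
  b <- tr$best_id
  if (id == 1L || f2 > tr$f2[b] ||
      (f2 == tr$f2[b] && droot < tr$droot[b]))
    tr$best_id <- id
  if (tr$policy != "uct" && elig)
    heap_push(tr, policy_key(tr, id), id)
  id
}

# ---- binary min-heap on (key, insertion order), preallocated --------------

heap_less <- function(tr, i, j) {
  tr$hkey[i] < tr$hkey[j] ||
    (tr$hkey[i] == tr$hkey[j] && tr$hid[i] < tr$hid[j])
}

heap_push <- function(tr, key, id) {
  n <- tr$hn + 1L
  if (n > length(tr$hid)) {
    tr$hkey <- c(tr$hkey, numeric(length(tr$hkey)))
    tr$hid <- c(tr$hid, integer(length(tr$hid)))
  }
  tr$hn <- n
  cpp_heap_insert(tr$hkey, tr$hid, n, key, id)
}

heap_pop <- function(tr) {
  n <- tr$hn
  cpp_set_real(tr$hkey, 1L, tr$hkey[n])
  cpp_set_int(tr$hid, 1L, tr$hid[n])
  tr$hn <- n - 1L
  cpp_heap_down(tr$hkey, tr$hid, tr$hn)
}

# ---------------------------------------------------------------------------

#' Select the next vertex to expand
#'
#' Selection is limited to foreign (`f1 < 1`), not-fully-expanded vertices
#' above the depth limit. BFS picks the shallowest eligible vertex (FIFO
#' among equals); greedy policies maximize `f2` or `f1/d`; A* and MLR
#' minimize their scores via a priority ordering with lazy deletion of
#' stale entries; UCT walks down from the root along maximal UCB1 children.
#' Ties always break by insertion order.
#'
#' @param tree a [new_search_tree] object (the policy is fixed at tree
#'   creation).
#' @return A vertex id, or `NULL` when no eligible vertex remains (search
#'   exhaustion).
#' @export
select_vertex <- function(tree) {
  tr <- tree
  if (tr$policy == "uct") return(select_uct(tr))
  repeat {
    if (tr$hn == 0L) return(NULL)
    top <- tr$hid[1L]
    if (tree_eligible(tr, top)) return(top)
    heap_pop(tr)
  }
}

select_uct <- function(tr) {
  v <- cpp_uct_select(tr$children, tr$subtree_elig, tr$parent, tr$depth,
                      tr$f1, tr$nv, tr$fully, tr$child_sum, tr$child_cnt,
                      tr$depth_limit, tr$uct_c)
  if (v == 0L) NULL else v
}

#' Expand a vertex by one candidate perturbation
#'
#' Consumes the vertex's next candidate perturbation, applies it (plus
#' sanitization when enabled) and increments the vertex's expansion count.
#' The child is discarded when it duplicates an existing tree molecule
#' (detected by a canonical graph hash) or violates a constraint;
#' otherwise it is added to the tree. An exhausted candidate stream marks
#' the vertex fully expanded.
#'
#' @param tree a [new_search_tree] object.
#' @param v vertex id to expand.
#' @return The new child's vertex id, or `NULL` when the candidate was
#'   discarded or the vertex is exhausted.
#' @export
expand_vertex <- function(tree, v) {
  tr <- tree
  if (tr$fully[v]) return(invisible(NULL))
  vk <- as.character(v)
  vmol <- tr$mols[[vk]]
  if (is.null(tr$cand[[vk]])) {
    diag <- if (tr$f1[v] < 1)
      diagnosis_from_cpp(cpp_diagnose(tr$d$ptr, vmol)) else NULL
    tr$cand[[vk]] <- candidate_perturbations(vmol, tr$d, diag,
                                             tr$allow_insertions)
  }
  row <- stream_next_row(tr$cand[[vk]])
  if (is.null(row)) {
    cpp_set_lgl(tr$fully, v, TRUE)
    return(invisible(NULL))
  }
  cpp_add_int(tr$nv, v, 1L)
  sc <- cpp_child_eval(vmol, as.integer(row), tr$sanitize,
                       tr$d$ptr, tr$root_fp)
  if (!is.null(get0(sc$ghash, envir = tr$hashmap, inherits = FALSE)))
    return(invisible(NULL))
  for (ct in tr$constraints)
    if (!isTRUE(ct(sc$mol))) return(invisible(NULL))
  id <- tree_insert(tr, sc$mol, parent = v, fam = sc, fp = sc$fp,
                    droot = sc$d_root, ghash = sc$ghash)
  invisible(id)
}

#' Per-vertex statistics
#'
#' @param tree a [new_search_tree] object.
#' @param v vertex id.
#' @return A list with `f1`, `f2`, `d_root`, `depth`, `n_v` (times
#'   expanded), `N_v` (times the parent was expanded), `children_f1_mean`
#'   (the vertex's own `f1` when it has no children yet) and
#'   `fully_expanded`.
#' @export
vertex_stats <- function(tree, v) {
  tr <- tree
  list(f1 = tr$f1[v], f2 = tr$f2[v], d_root = tr$droot[v],
       depth = tr$depth[v], n_v = tr$nv[v],
       N_v = if (tr$parent[v] > 0L) tr$nv[tr$parent[v]] else tr$nv[v],
       children_f1_mean = if (tr$child_cnt[v] > 0L)
         tr$child_sum[v] / tr$child_cnt[v] else tr$f1[v],
       fully_expanded = tr$fully[v])
}

#' Correct a molecule by tree search
#'
#' Runs select-expand iterations until a correct molecule (every key
#' familiar, `f1 = 1`) is created, the tree-size budget is hit, or no
#' eligible vertex remains. An already-correct input is returned unchanged.
#' When the search ends without a solution the best vertex found so far
#' (maximum `f2`, ties to the smallest distance from the input) is
#' reported.
#'
#' @inheritParams new_search_tree
#' @param max_iterations hard stop on select-expand iterations (default
#'   `50 * max_tree_size`).
#' @param complete_level (BFS only) keep searching after the first solution
#'   until every shallower vertex is fully expanded, then return the
#'   solution closest to the input. Used when collecting regression
#'   training data.
#' @return An object of class `correction_result`: `status` (`"solved"`,
#'   `"budget_exhausted"` or `"tree_exhausted"`), `molecule`, `smiles`,
#'   `f1`, `f2`, `d_root`, `tree_size`, `solution_depth`, `iterations`,
#'   `policy`, and `path_stats` (per-vertex `depth`/`f1`/`d_root` along the
#'   root-to-output chain).
#' @examples
#' d <- chemical_dictionary(c("CCO", "CCC", "CCN", "CO", "CN"))
#' bad <- parse_smiles("CC[O+]")
#' res <- correct_molecule(bad, d, policy = "greedy_f2")
#' res$status; res$smiles
#' @export
correct_molecule <- function(mol, d, policy = "mlr",
                             max_depth = 25L, max_tree_size = 25000L,
                             constraints = list(), objective = NULL,
                             sanitize = TRUE, allow_insertions = TRUE,
                             uct_c = 0.5, mlr_model = default_mlr_model(),
                             max_iterations = NULL, complete_level = FALSE) {
  if (complete_level && policy != "bfs")
    stop("complete_level is only meaningful for the BFS policy")
  tr <- new_search_tree(mol, d, policy = policy, max_depth = max_depth,
                        max_tree_size = max_tree_size,
                        constraints = constraints, objective = objective,
                        sanitize = sanitize,
                        allow_insertions = allow_insertions,
                        uct_c = uct_c, mlr_model = mlr_model)
  if (is.null(max_iterations)) max_iterations <- 50 * as.numeric(max_tree_size)
  status <- NULL
  if (tr$f1[1L] >= 1) {
    status <- "solved"
  } else {
    repeat {
      if (tr$size >= tr$max_tree_size) { status <- "budget_exhausted"; break }
      if (tr$iterations >= max_iterations) { status <- "budget_exhausted"; break }
      v <- select_vertex(tr)
      if (is.null(v)) { status <- "tree_exhausted"; break }
      tr$iterations <- tr$iterations + 1L
      id <- expand_vertex(tr, v)
      if (!is.null(id) && tr$f1[id] >= 1) {
        if (!complete_level) { status <- "solved"; break }
        # keep going until every vertex shallower than the solution level
        # is fully expanded, to find the closest solution on that level
        # (selection requires depth < depth_limit)
        tr$depth_limit <- min(tr$depth_limit, tr$depth[id])
      }
    }
    if (is.null(status)) status <- "tree_exhausted"
    if (complete_level && length(tr$solutions) > 0L) status <- "solved"
  }
  out_id <- if (status == "solved") {
    sols <- tr$solutions
    sols[order(tr$droot[sols], sols)][1L]
  } else tr$best_id
  path <- out_id
  while (tr$parent[path[1L]] > 0L) path <- c(tr$parent[path[1L]], path)
  out_mol <- tr$mols[[as.character(out_id)]]
  structure(list(
    status = status,
    molecule = out_mol,
    smiles = write_smiles(out_mol),
    f1 = tr$f1[out_id], f2 = tr$f2[out_id], d_root = tr$droot[out_id],
    tree_size = tr$size,
    solution_depth = if (status == "solved") tr$depth[out_id] else NA_integer_,
    iterations = tr$iterations,
    policy = policy,
    path_stats = data.frame(depth = tr$depth[path], f1 = tr$f1[path],
                            d_root = tr$droot[path]),
    path_molecules = lapply(as.character(path), function(k) tr$mols[[k]])),
    class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf("<correction_result> %s (policy %s)\n", x$status, x$policy))
  cat(sprintf("  output: %s\n", x$smiles))
  cat(sprintf("  f1 = %.4f, f2 = %.4f, d_root = %.4f\n", x$f1, x$f2, x$d_root))
  cat(sprintf("  tree size %d, %d iterations%s\n", x$tree_size, x$iterations,
              if (!is.na(x$solution_depth))
                sprintf(", solution depth %d", x$solution_depth) else ""))
  invisible(x)
}
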
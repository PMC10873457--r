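# Fixture generation and the scaled-down perturb-then-correct benchmark.

#' Bundled drug-like reference molecules
#'
#' Returns the SMILES of the drug-like reference set shipped with the
#' package (roughly 200 small organic molecules: common approved drugs and
#' representative drug-like structures). It stands in for the large
#' curated database subset a production dictionary would be built from.
#'
#' @return A named character vector of SMILES strings.
#' @export
druglike_reference <- function() {
  path <- system.file("extdata", "druglike_reference.smi",
                      package = "molautofix", mustWork = TRUE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  fld <- strsplit(lines, "\t", fixed = TRUE)
  smi <- vapply(fld, `[`, character(1L), 1L)
  names(smi) <- vapply(fld, function(x) if (length(x) > 1L) x[2L] else "", character(1L))
  smi
}

#' Generate a seeded benchmark fixture set
#'
#' Samples `n` molecules from the bundled drug-like list and "breaks" each
#' of them with a series of `n_breaks` sequential random perturbations
#' (see [random_perturbation_sequence]). Fully reproducible from the seed.
#'
#' @param n number of molecules to sample (at most the bundled list size).
#' @param seed integer seed.
#' @param n_breaks length of each breaker series (the benchmark uses 10).
#' @param reference optional character vector of SMILES to sample from
#'   instead of the bundled list.
#' @return A list with `reference` (the sampled [molgraph]s), `broken` (a
#'   list of breaker series, one per molecule; element `k` of a series has
#'   `k` perturbations applied) and `smiles` (the sampled input SMILES).
#' @export
generate_fixture_set <- function(n, seed, n_breaks = 10L, reference = NULL) {
  smi <- if (is.null(reference)) druglike_reference() else reference
  if (n > length(smi)) stop("n exceeds the reference list size (", length(smi), ")")
  idx <- local_seed(seed, sample.int(length(smi), n))
  picked <- smi[idx]
  mols <- lapply(picked, parse_smiles)
  broken <- lapply(seq_along(mols), function(i)
    random_perturbation_sequence(mols[[i]], n_breaks, derive_seed(seed, i)))
  names(broken) <- names(picked)
  list(reference = mols, broken = broken, smiles = picked)
}

#' Benchmark configuration
#'
#' @param policies selection policies to compare.
#' @param n_molecules number of input molecules sampled from the reference
#'   list.
#' @param break_levels numbers of sequential random perturbations defining
#'   the difficulty levels.
#' @param radius,threshold dictionary parameters.
#' @param max_depth,max_tree_size search budgets.
#' @param seed integer seed for sampling and breaking.
#' @param uct_c UCT exploration coefficient.
#' @param allow_insertions passed to [correct_molecule].
#' @param reference optional custom reference SMILES vector.
#' @return A list of class `benchmark_config`.
#' @export
benchmark_config <- function(policies = c("bfs", "greedy_f2", "greedy_ratio",
                                          "uct", "astar", "mlr"),
                             n_molecules = 50L, break_levels = c(1L, 3L, 5L),
                             radius = 1L, threshold = 0L,
                             max_depth = 25L, max_tree_size = 5000L,
                             seed = 1L, uct_c = 0.5, allow_insertions = TRUE,
                             reference = NULL) {
  structure(list(policies = policies, n_molecules = as.integer(n_molecules),
                 break_levels = as.integer(break_levels),
                 radius = as.integer(radius), threshold = threshold,
                 max_depth = as.integer(max_depth),
                 max_tree_size = as.integer(max_tree_size),
                 seed = as.integer(seed), uct_c = uct_c,
                 allow_insertions = isTRUE(allow_insertions),
                 reference = reference),
            class = "benchmark_config")
}

#' Run the perturb-then-correct benchmark
#'
#' Builds a dictionary from the full reference list, samples and breaks
#' input molecules, then corrects every broken molecule with every policy.
#' Per-input records and per-(policy, break level) aggregates are
#' returned; the records are TSV-ready.
#'
#' @param config a [benchmark_config].
#' @param progress print one line per (policy, level) block.
#' @return A list of class `benchmark_result` with `records` (one row per
#'   corrected input: policy, level, input/output SMILES, status, `f1`,
#'   `f2`, `d_root`, `tree_size`, `solution_depth`, `iterations`,
#'   `wall_time`) and `summary` (aggregated solved fraction, mean `f2`,
#'   mean output distance over solved cases, mean tree size).
#' @export
run_benchmark <- function(config = benchmark_config(), progress = FALSE) {
  if (!inherits(config, "benchmark_config")) stop("expected a 'benchmark_config'")
  smi <- if (is.null(config$reference)) druglike_reference() else config$reference
  dict <- chemical_dictionary(lapply(smi, parse_smiles),
                              radius = config$radius,
                              threshold = config$threshold)
  fix <- generate_fixture_set(config$n_molecules, config$seed,
                              n_breaks = max(config$break_levels),
                              reference = smi)
  rows <- list()
  for (policy in config$policies) {
    for (lvl in config$break_levels) {
      t0 <- proc.time()[["elapsed"]]
      for (i in seq_len(config$n_molecules)) {
        input <- fix$broken[[i]][[lvl]]
        t1 <- proc.time()[["elapsed"]]
        res <- correct_molecule(input, dict, policy = policy,
                                max_depth = config$max_depth,
                                max_tree_size = config$max_tree_size,
                                uct_c = config$uct_c,
                                allow_insertions = config$allow_insertions)
        rows[[length(rows) + 1L]] <- data.frame(
          policy = policy, n_breaks = lvl, molecule = names(fix$broken)[i],
          input = write_smiles(input), output = res$smiles,
          status = res$status, f1 = res$f1, f2 = res$f2,
          d_root = res$d_root, tree_size = res$tree_size,
          solution_depth = res$solution_depth, iterations = res$iterations,
          wall_time = proc.time()[["elapsed"]] - t1)
      }
      if (progress)
        message(sprintf("benchmark: policy %s, %d break(s): %.1fs",
                        policy, lvl, proc.time()[["elapsed"]] - t0))
    }
  }
  records <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(policy = character(0), n_breaks = integer(0),
               molecule = character(0), input = character(0),
               output = character(0), status = character(0),
               f1 = numeric(0), f2 = numeric(0), d_root = numeric(0),
               tree_size = integer(0), solution_depth = integer(0),
               iterations = integer(0), wall_time = numeric(0))
  summary <- benchmark_summary(records)
  structure(list(records = records, summary = summary, config = config),
            class = "benchmark_result")
}

benchmark_summary <- function(records) {
  if (nrow(records) == 0L)
    return(data.frame(policy = character(0), n_breaks = integer(0),
                      n = integer(0), solved_fraction = numeric(0),
                      mean_f2 = numeric(0), mean_d_root_solved = numeric(0),
                      mean_tree_size = numeric(0)))
  grp <- split(records, list(records$policy, records$n_breaks), drop = TRUE)
  out <- do.call(rbind, lapply(grp, function(g) {
    solved <- g$status == "solved"
    data.frame(policy = g$policy[1L], n_breaks = g$n_breaks[1L],
               n = nrow(g), solved_fraction = mean(solved),
               mean_f2 = mean(g$f2),
               mean_d_root_solved = if (any(solved)) mean(g$d_root[solved]) else NA_real_,
               mean_tree_size = mean(g$tree_size))
  }))
  rownames(out) <- NULL
  out[order(out$policy, out$n_breaks), , drop = FALSE]
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %d corrections\n", nrow(x$records)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
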
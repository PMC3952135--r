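# Incremental docking protocol: plan the increment schedule, then loop
# dock -> select -> extend until every rotatable bond has been explored.
# Defaults follow the published walkthrough: an initial fragment of 6
# rotatable bonds docked with 50 runs; 5 lowest-scoring conformations
# selected; each extension adds 3 bonds and re-explores the 3 most recent
# ones; each selected parent is re-docked with 20 runs, pooling 5 x 20 =
# 100 candidates per step; 250000 score evaluations per sub-docking.

#' Protocol configuration
#'
#' @param fragment_size rotatable bonds in the initial fragment (default 6).
#' @param extension_size new bonds added per extension (default 3).
#' @param reexplore_size most recent previously-explored bonds re-sampled at
#'   each extension (default 3).
#' @param select_k conformations selected between steps (default 5).
#' @param initial_runs engine runs for the first fragment (default 50).
#' @param runs_per_parent engine runs per selected parent at extension
#'   steps (default 20).
#' @param step_num_evals score-evaluation budget per engine run
#'   (default 250000).
#' @param seed master seed.
#' @return object of class `protocol_config`.
#' @export
protocol_config <- function(fragment_size = 6, extension_size = 3,
                            reexplore_size = 3, select_k = 5,
                            initial_runs = 50, runs_per_parent = 20,
                            step_num_evals = 250000, seed = 1) {
  stopifnot(fragment_size >= 1, extension_size >= 1, reexplore_size >= 0,
            select_k >= 1, initial_runs >= 1, runs_per_parent >= 1,
            select_k <= initial_runs,
            select_k <= select_k * runs_per_parent)
  structure(list(fragment_size = as.integer(fragment_size),
                 extension_size = as.integer(extension_size),
                 reexplore_size = as.integer(reexplore_size),
                 select_k = as.integer(select_k),
                 initial_runs = as.integer(initial_runs),
                 runs_per_parent = as.integer(runs_per_parent),
                 step_num_evals = as.integer(step_num_evals),
                 seed = as.integer(seed)),
            class = "protocol_config")
}

#' Plan the increment schedule
#'
#' Step 1 activates ranks `1..min(fragment_size, n_bonds)`. Each later step
#' adds the next `extension_size` unexplored ranks (clipped at `n_bonds`)
#' and re-explores the `reexplore_size` most recent previously-explored
#' ranks; everything below the active window is frozen. For 14 bonds under
#' the defaults the active windows are [1-6], [4-9], [7-12], [10-14].
#'
#' @param n_bonds number of rotatable bonds (>= 0).
#' @param config a `protocol_config`.
#' @return object of class `increment_plan`: list of steps, each
#'   `list(step, new_ranks, reexplored_ranks, frozen_ranks, active_ranks,
#'   max_rank)`.
#' @export
plan_schedule <- function(n_bonds, config = protocol_config()) {
  n_bonds <- as.integer(n_bonds)
  stopifnot(n_bonds >= 0)
  steps <- list()
  first <- min(config$fragment_size, n_bonds)
  new <- seq_len(first)
  steps[[1]] <- list(step = 1L, new_ranks = new,
                     reexplored_ranks = integer(0), frozen_ranks = integer(0),
                     active_ranks = new, max_rank = first)
  explored <- first
  while (explored < n_bonds) {
    n_new <- min(config$extension_size, n_bonds - explored)
    new <- seq.int(explored + 1L, explored + n_new)
    n_re <- min(config$reexplore_size, explored)
    re <- if (n_re > 0) seq.int(explored - n_re + 1L, explored) else integer(0)
    active <- c(re, new)
    max_rank <- explored + n_new
    steps[[length(steps) + 1]] <- list(
      step = length(steps) + 1L, new_ranks = new, reexplored_ranks = re,
      frozen_ranks = setdiff(seq_len(max_rank), active),
      active_ranks = active, max_rank = max_rank)
    explored <- max_rank
  }
  structure(steps, class = "increment_plan")
}

#' @export
print.increment_plan <- function(x, ...) {
  cat("increment plan (", length(x), " step", if (length(x) > 1) "s", "):\n",
      sep = "")
  for (s in x) {
    rng <- function(v) if (length(v) == 0) "-" else
      paste0(min(v), if (length(v) > 1) paste0("-", max(v)))
    cat(sprintf("  step %d: active %s (new %s, re-explored %s, frozen %s)\n",
                s$step, rng(s$active_ranks), rng(s$new_ranks),
                rng(s$reexplored_ranks), rng(s$frozen_ranks)))
  }
  invisible(x)
}

conf_score_total <- function(conf, restraint = NULL) {
  if (is.null(restraint)) return(conf$s_ad)
  loc <- match(restraint$atom_index, conf$atom_idx)
  if (is.na(loc))
    stop("restrained atom is not part of the current fragment")
  restrained_score(conf$s_ad, conf$coords[loc, ], restraint)
}

#' Select the best conformations of a pool
#'
#' Keeps the `k` lowest conformations by total score: the engine score, or
#' the restrained score `weight * D_a + s_ad` when a restraint is set. Ties
#' break by engine score, then by insertion order. When the pool holds
#' fewer than `k`, the whole pool is returned.
#'
#' @param pool list of scored `conformation`s.
#' @param k number to keep.
#' @param restraint optional resolved `restraint`.
#' @return list of conformations with `$s_total` filled, ascending.
#' @export
select_conformations <- function(pool, k, restraint = NULL) {
  if (length(pool) == 0) stop("empty conformation pool")
  s_tot <- vapply(pool, conf_score_total, 0, restraint = restraint)
  s_ad <- vapply(pool, `[[`, 0, "s_ad")
  ord <- order(s_tot, s_ad, seq_along(pool))
  keep <- ord[seq_len(min(k, length(pool)))]
  lapply(keep, function(i) { p <- pool[[i]]; p$s_total <- s_tot[i]; p })
}

#' Extend a selected conformation into the next fragment
#'
#' Grows the fragment to the step's `max_rank`: frozen torsions inherit the
#' parent's angles, re-explored torsions start at the parent's angles but
#' stay active, and newly added torsions start at the reference geometry.
#'
#' @param parent a scored `conformation` covering all ranks below the
#'   step's new ranks.
#' @param tree the ligand's `torsion_tree`.
#' @param step one step of an `increment_plan`.
#' @return a `fragment` carrying the parent as seeding geometry.
#' @export
extend_conformation <- function(parent, tree, step) {
  need <- setdiff(seq_len(step$max_rank), step$new_ranks)
  have <- as.integer(names(parent$torsions))
  if (length(setdiff(need, have)) > 0)
    stop("parent conformation missing torsion(s) ",
         paste(setdiff(need, have), collapse = ", "), ": contract violation")
  extract_fragment(tree, step$max_rank, step$active_ranks, parent = parent)
}

#' Run the incremental docking protocol
#'
#' Executes the full pipeline: schedule planning, initial-fragment docking
#' with `initial_runs` runs, then repeated select -> extend -> re-dock
#' rounds (each selected parent re-docked with `runs_per_parent` runs from
#' an independent seed block) until the whole ligand is placed. With a
#' restraint, the restrained atom is used as the tree root and selection
#' ranks by the restrained score.
#'
#' @param ligand a `ligand`.
#' @param field a `scoring_field` covering the ligand's atom types.
#' @param config a `protocol_config`.
#' @param engine an `engine_config`; its `ga_num_evals`/`ga_run` are
#'   overridden per step by the protocol configuration.
#' @param restraint optional `restraint` (resolved against the ligand).
#' @param root_atom optional root-atom override; defaults to
#'   [select_root_atom()] or the restrained atom.
#' @return object of class `protocol_result`: `final_pool` (fully docked
#'   conformations, ascending total score), `per_step_pools`, `schedule`,
#'   `tree`, `provenance`.
#' @export
run_protocol <- function(ligand, field, config = protocol_config(),
                         engine = engine_config(), restraint = NULL,
                         root_atom = NULL) {
  if (!is.null(restraint) && is.null(restraint$atom_index))
    restraint <- resolve_restraint(restraint, ligand)
  if (is.null(root_atom)) {
    root_atom <- if (!is.null(restraint)) {
      # root the tree at the restrained atom (its heavy neighbour for an H)
      idx <- restraint$atom_index
      if (ligand$atoms$element[idx] == "H") {
        b <- ligand$bonds
        nb <- c(b$b[b$a == idx], b$a[b$b == idx])
        nb[ligand$atoms$element[nb] != "H"][1]
      } else idx
    } else select_root_atom(ligand, config$fragment_size)
  }
  tree <- build_torsion_tree(ligand, root_atom)
  plan <- plan_schedule(tree$n_bonds, config)
  master <- config$seed

  eng1 <- engine
  eng1$ga_num_evals <- config$step_num_evals
  eng1$ga_run <- config$initial_runs
  frag1 <- extract_fragment(tree, plan[[1]]$max_rank, plan[[1]]$active_ranks)
  res1 <- dock(frag1, field, eng1, seed = derive_seed(master, 1, 0))
  pool <- res1$conformations
  for (i in seq_along(pool)) pool[[i]]$parent_chain <- i
  per_step_pools <- list(pool)

  if (length(plan) > 1) {
    for (si in 2:length(plan)) {
      step <- plan[[si]]
      selected <- select_conformations(pool, config$select_k, restraint)
      pool <- list()
      engs <- engine
      engs$ga_num_evals <- config$step_num_evals
      engs$ga_run <- config$runs_per_parent
      for (p in seq_along(selected)) {
        parent <- selected[[p]]
        parent$parent_chain <- c(parent$parent_chain, p)
        frag <- extend_conformation(parent, tree, step)
        resp <- dock(frag, field, engs, seed = derive_seed(master, si, p))
        pool <- c(pool, resp$conformations)
      }
      per_step_pools[[si]] <- pool
    }
  }

  s_tot <- vapply(pool, conf_score_total, 0, restraint = restraint)
  for (i in seq_along(pool)) pool[[i]]$s_total <- s_tot[i]
  ord <- order(s_tot, vapply(pool, `[[`, 0, "s_ad"), seq_along(pool))
  final <- pool[ord]
  structure(list(final_pool = final, per_step_pools = per_step_pools,
                 schedule = plan, tree = tree, restraint = restraint,
                 config = config,
                 provenance = lapply(final, `[[`, "parent_chain")),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  s <- vapply(x$final_pool, `[[`, 0, "s_total")
  cat("protocol result: ", length(x$schedule), " increment step",
      if (length(x$schedule) > 1) "s", ", final pool of ", length(s),
      " conformations, best total score ", sprintf("%.3f", min(s)),
      " kcal/mol\n", sep = "")
  invisible(x)
}

#' Tabulate a conformation pool
#'
#' @param pool list of scored conformations (e.g. `final_pool`).
#' @return data.frame with one row per conformation: `id, s_ad, s_total`.
#' @export
pool_table <- function(pool) {
  data.frame(id = seq_along(pool),
             s_ad = vapply(pool, `[[`, 0, "s_ad"),
             s_total = vapply(pool, function(p)
               if (is.null(p$s_total)) p$s_ad else p$s_total, 0))
}
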
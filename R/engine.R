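# Stochastic docking engine: a generational genetic algorithm over the
# genome (translation, orientation quaternion, active torsions) of one
# fragment, scored against a scoring field under a hard evaluation budget.
# Flavor: elitism 1, tournament selection (k = 2), two-point genome
# crossover, Gaussian mutation (sigma 1 A translation, 0.1 rad
# rotation/torsion), optional greedy local search on the top 10%.
# Every run draws from an independently derived seed, so the ga_run runs
# are order-independent and the engine is bitwise deterministic.

#' Engine configuration
#'
#' @param ga_num_evals score-evaluation budget per run (default 250000).
#' @param ga_run number of independent runs (default 50).
#' @param population_size GA population (default 50).
#' @param mutation_rate per-gene mutation probability.
#' @param crossover_rate per-pair crossover probability.
#' @param local_search_steps greedy refinement proposals applied to the top
#'   10% of each generation (0 disables).
#' @param seed master seed.
#' @return object of class `engine_config`.
#' @export
engine_config <- function(ga_num_evals = 250000, ga_run = 50,
                          population_size = 50, mutation_rate = 0.3,
                          crossover_rate = 0.8, local_search_steps = 10,
                          seed = 1) {
  stopifnot(ga_num_evals >= population_size, ga_run >= 1,
            population_size >= 2,
            mutation_rate >= 0, mutation_rate <= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            local_search_steps >= 0)
  structure(list(ga_num_evals = as.integer(ga_num_evals),
                 ga_run = as.integer(ga_run),
                 population_size = as.integer(population_size),
                 mutation_rate = mutation_rate,
                 crossover_rate = crossover_rate,
                 local_search_steps = as.integer(local_search_steps),
                 seed = as.integer(seed)),
            class = "engine_config")
}

derive_seed <- function(master, a, b = 0, c = 0) {
  as.integer((as.numeric(master) * 1103 + a * 100003 + b * 10007 + c * 101 +
                12345) %% 2147483647)
}

# flat C++-side kinematic context for a fragment
frag_cpp_ctx <- function(fragment) {
  ctx <- fragment_context(fragment)
  m <- fragment$max_rank
  slot <- integer(m); fixed <- numeric(m)
  for (r in seq_len(m)) {
    k <- match(r, fragment$active_ranks)
    if (!is.na(k)) slot[r] <- k - 1L
    else {
      slot[r] <- -1L
      fixed[r] <- fragment$frozen_angles[[as.character(r)]]
    }
  }
  list(ref = ctx$ref, centroid = ctx$centroid,
       edge_a = vapply(ctx$edges, `[[`, 0L, "ai"),
       edge_b = vapply(ctx$edges, `[[`, 0L, "bi"),
       moving = lapply(ctx$edges, function(e) as.integer(e$moving)),
       slot = slot, fixed = fixed,
       centroid_r = ctx$centroid, n_atoms = ctx$n_atoms)
}

# flat C++-side field descriptor for the atoms of a fragment subset
field_cpp_desc <- function(field, ligand, atom_subset) {
  UseMethod("field_cpp_desc", field)
}

#' @export
field_cpp_desc.grid_field <- function(field, ligand, atom_subset) {
  types <- ligand$atoms$atom_type[atom_subset]
  missing <- setdiff(unique(types), names(field$type_maps))
  if (length(missing) > 0)
    stop("field lacks maps for ligand atom type(s): ",
         paste(missing, collapse = ", "))
  list(kind = "grid",
       maps = unname(field$type_maps),
       atom_map = match(types, names(field$type_maps)) - 1L,
       charges = ligand$atoms$charge[atom_subset],
       elec = field$electrostatic_map,
       origin = box_origin(field$box),
       npts = field$box$npts,
       spacing = field$box$spacing,
       oob_penalty = field$out_of_box_penalty)
}

#' @export
field_cpp_desc.funnel_field <- function(field, ligand, atom_subset) {
  list(kind = "funnel",
       targets = field$targets[atom_subset, , drop = FALSE],
       k = field$k, noise_amp = field$noise_amp,
       noise_period = field$noise_period)
}

eval_genomes <- function(cctx, fdesc, genomes) {
  cpp_eval_genomes(cctx$ref, cctx$centroid, cctx$edge_a, cctx$edge_b,
                   cctx$moving, cctx$slot, cctx$fixed, genomes, fdesc)
}

random_genome <- function(cctx, box, n_active) {
  half <- box_half_extent(box)
  target <- box$center + runif(3, -half, half)
  c(target - cctx$centroid, quat_random(),
    if (n_active > 0) runif(n_active, -pi, pi) else numeric(0))
}

perturb_genome <- function(g, sigma_t = 1.0, sigma_r = 0.1) {
  n <- length(g)
  g[1:3] <- g[1:3] + rnorm(3, 0, sigma_t)
  g[4:7] <- quat_normalize(quat_multiply(
    quat_from_axis_angle(rnorm(3), rnorm(1, 0, sigma_r)), g[4:7]))
  if (n > 7) g[8:n] <- g[8:n] + rnorm(n - 7, 0, sigma_r)
  g
}

mutate_genome <- function(g, rate, sigma_t = 1.0, sigma_r = 0.1) {
  n <- length(g)
  hit <- runif(3) < rate
  if (any(hit)) g[1:3][hit] <- g[1:3][hit] + rnorm(sum(hit), 0, sigma_t)
  if (runif(1) < rate)
    g[4:7] <- quat_multiply(quat_from_axis_angle(rnorm(3), rnorm(1, 0, sigma_r)),
                            g[4:7])
  if (n > 7) {
    hit <- runif(n - 7) < rate
    if (any(hit)) g[8:n][hit] <- g[8:n][hit] + rnorm(sum(hit), 0, sigma_r)
  }
  g[4:7] <- quat_normalize(g[4:7])
  g
}

crossover_genomes <- function(g1, g2) {
  n <- length(g1)
  cut <- sort(sample.int(n, 2))
  mid <- (cut[1] + 1):cut[2]
  if (cut[1] < cut[2]) {
    tmp <- g1[mid]; g1[mid] <- g2[mid]; g2[mid] <- tmp
  }
  g1[4:7] <- quat_normalize(g1[4:7]); g2[4:7] <- quat_normalize(g2[4:7])
  list(g1, g2)
}

# one GA run under the evaluation budget; draws from the current RNG state
# (the generational loop lives in compiled code but consumes R's RNG stream,
# so set.seed() fully determines the run)
ga_single_run <- function(cctx, fdesc, box, config, n_active,
                          parent_genome = NULL) {
  cpp_ga_run(cctx$ref, cctx$centroid, cctx$edge_a, cctx$edge_b, cctx$moving,
             cctx$slot, cctx$fixed, fdesc,
             config[c("population_size", "ga_num_evals", "mutation_rate",
                      "crossover_rate", "local_search_steps")],
             parent_genome, box$center, box_half_extent(box), n_active)
}

#' Dock a fragment with the genetic-algorithm engine
#'
#' Runs `ga_run` independent GA runs against the scoring field, each under
#' the `ga_num_evals` budget, and returns one best conformation per run,
#' sorted ascending by score. Frozen torsions are never altered; results
#' are bitwise deterministic given the seed and independent of run
#' execution order (each run re-seeds from a derived per-run seed).
#'
#' @param fragment a `fragment`.
#' @param field a `scoring_field` (its box bounds the rigid-body search).
#' @param config an `engine_config`.
#' @param seed master seed for this docking (default: `config$seed`).
#' @return object of class `docking_result`: `list(conformations,
#'   evals_used)`.
#' @export
dock <- function(fragment, field, config = engine_config(),
                 seed = config$seed) {
  cctx <- frag_cpp_ctx(fragment)
  fdesc <- field_cpp_desc(field, fragment$tree$ligand, fragment$atom_subset)
  n_active <- length(fragment$active_ranks)
  box <- field$box
  parent_genome <- NULL
  if (!is.null(fragment$parent)) {
    p <- fragment$parent
    tors <- numeric(n_active)
    for (k in seq_along(fragment$active_ranks)) {
      v <- p$torsions[as.character(fragment$active_ranks[k])]
      tors[k] <- if (is.na(v)) 0 else v   # newly added bonds start at reference
    }
    parent_genome <- c(p$translation, p$orientation, tors)
  }
  runs <- vector("list", config$ga_run)
  evals_used <- 0
  for (r in seq_len(config$ga_run)) {
    set.seed(derive_seed(seed, r))
    res <- ga_single_run(cctx, fdesc, box, config, n_active, parent_genome)
    evals_used <- evals_used + res$evals
    g <- res$genome
    tor <- stats::setNames(if (n_active > 0) g[8:(7 + n_active)] else numeric(0),
                           as.character(fragment$active_ranks))
    conf <- new_conformation(fragment, g[1:3], g[4:7], tor,
                             s_ad = res$score, s_total = res$score,
                             parent_chain = if (!is.null(fragment$parent))
                               fragment$parent$parent_chain else integer(0))
    runs[[r]] <- conf
  }
  ord <- order(vapply(runs, `[[`, 0, "s_ad"))
  structure(list(conformations = runs[ord], evals_used = evals_used),
            class = "docking_result")
}

#' @export
print.docking_result <- function(x, ...) {
  s <- vapply(x$conformations, `[[`, 0, "s_ad")
  cat("docking result: ", length(s), " conformations, best score ",
      sprintf("%.3f", min(s)), " kcal/mol, ", x$evals_used,
      " evaluations\n", sep = "")
  invisible(x)
}

#' Greedy local refinement of a conformation
#'
#' Stochastic hill-climb on the genome: at each step a Gaussian
#' perturbation is proposed and kept only if it improves the score, so the
#' returned score never exceeds the input score. With `steps = 0` the
#' input is returned unchanged.
#'
#' @param fragment the `fragment` the conformation belongs to.
#' @param conformation a scored or unscored `conformation`.
#' @param field a `scoring_field`.
#' @param steps number of proposals.
#' @param sigma_t,sigma_r proposal widths (Angstrom / radians).
#' @return refined `conformation` with `$s_ad` set; attribute
#'   `"evals"` carries the evaluation count.
#' @export
local_search <- function(fragment, conformation, field, steps = 50,
                         sigma_t = 0.3, sigma_r = 0.03) {
  cctx <- frag_cpp_ctx(fragment)
  fdesc <- field_cpp_desc(field, fragment$tree$ligand, fragment$atom_subset)
  n_active <- length(fragment$active_ranks)
  tors <- if (n_active > 0)
    conformation$torsions[as.character(fragment$active_ranks)] else numeric(0)
  g <- c(conformation$translation, conformation$orientation, as.numeric(tors))
  s <- if (!is.null(conformation$s_ad)) conformation$s_ad else
    as.numeric(eval_genomes(cctx, fdesc, matrix(g, nrow = 1)))
  evals <- if (is.null(conformation$s_ad)) 1L else 0L
  if (steps > 0) {
    for (i in seq_len(steps)) {
      # coordinate-wise proposal: translation block, orientation, or one torsion
      cand <- g
      pick <- sample.int(2 + n_active, 1)
      if (pick == 1) cand[1:3] <- cand[1:3] + rnorm(3, 0, sigma_t)
      else if (pick == 2) cand[4:7] <- quat_normalize(quat_multiply(
        quat_from_axis_angle(rnorm(3), rnorm(1, 0, sigma_r)), cand[4:7]))
      else cand[7 + (pick - 2)] <- cand[7 + (pick - 2)] + rnorm(1, 0, sigma_r)
      cs <- as.numeric(eval_genomes(cctx, fdesc, matrix(cand, nrow = 1)))
      evals <- evals + 1L
      if (cs < s) { g <- cand; s <- cs }
    }
  }
  tor <- stats::setNames(if (n_active > 0) g[8:(7 + n_active)] else numeric(0),
                         as.character(fragment$active_ranks))
  out <- new_conformation(fragment, g[1:3], g[4:7], tor, s_ad = s, s_total = s,
                          parent_chain = conformation$parent_chain)
  attr(out, "evals") <- evals
  out
}
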
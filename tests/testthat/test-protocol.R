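test_that("the 14-bond schedule reproduces the canonical windows", {
  plan <- plan_schedule(14)
  expect_length(plan, 4)
  expect_equal(plan[[1]]$active_ranks, 1:6)
  expect_equal(plan[[2]]$active_ranks, 4:9)
  expect_equal(plan[[3]]$active_ranks, 7:12)
  expect_equal(plan[[4]]$active_ranks, 10:14)
  expect_equal(plan[[2]]$frozen_ranks, 1:3)
  expect_equal(plan[[4]]$frozen_ranks, 1:9)
  expect_equal(plan[[4]]$new_ranks, 13:14)         # clipped final extension
  expect_equal(plan[[4]]$reexplored_ranks, 10:12)
})

test_that("degenerate and clipped schedules follow the rule", {
  expect_length(plan_schedule(6), 1)
  expect_equal(plan_schedule(6)[[1]]$active_ranks, 1:6)
  p8 <- plan_schedule(8)
  expect_length(p8, 2)
  expect_equal(p8[[2]]$active_ranks, 4:8)
  p0 <- plan_schedule(0)
  expect_length(p0, 1)
  expect_equal(p0[[1]]$active_ranks, integer(0))
})

test_that("every rank is newly explored in exactly one step (coverage property)", {
  cfg <- protocol_config()
  for (n in c(0, 1, 5, 6, 7, 9, 13, 14, 20, 31)) {
    plan <- plan_schedule(n, cfg)
    new_all <- unlist(lapply(plan, `[[`, "new_ranks"))
    expect_equal(sort(new_all), seq_len(n))
    for (s in plan) {
      active <- sort(c(s$reexplored_ranks, s$new_ranks))
      if (length(active) > 0) {  # consecutive window ending at max_rank
        expect_equal(active, seq.int(min(active), s$max_rank))
      }
      expect_equal(s$frozen_ranks, setdiff(seq_len(s$max_rank), active))
    }
  }
})

test_that("selection keeps the k lowest scores with deterministic ties", {
  lig <- make_chain_ligand(3)
  frag <- full_fragment(build_torsion_tree(lig, select_root_atom(lig)))
  box <- binding_box(c(0, 0, 0), c(41, 41, 41))
  set.seed(17)
  pool <- replicate(50, randomize_conformation(frag, box), simplify = FALSE)
  sc <- rnorm(50)
  for (i in 1:50) { pool[[i]]$s_ad <- sc[i]; pool[[i]]$s_total <- sc[i] }
  sel <- select_conformations(pool, 5)
  expect_equal(vapply(sel, `[[`, 0, "s_ad"), sort(sc)[1:5])
  whole <- select_conformations(pool, 100)
  expect_length(whole, 50)
  expect_equal(vapply(whole, `[[`, 0, "s_ad"), sort(sc))
})

test_that("restrained selection separates equal engine scores by the penalty", {
  lig <- make_chain_ligand(3)
  frag <- full_fragment(build_torsion_tree(lig, select_root_atom(lig)))
  co <- apply_genome(frag)
  at_target <- new_conformation(frag, c(0, 0, 0), c(1, 0, 0, 0), NULL,
                                s_ad = -5)
  # move the whole ligand so the restrained atom sits 10 A^2 away
  away <- new_conformation(frag, c(sqrt(10), 0, 0), c(1, 0, 0, 0), NULL,
                           s_ad = -5)
  r <- resolve_restraint(restraint("O1", co[1, ]), lig)
  sel <- select_conformations(list(away, at_target), 2, restraint = r)
  expect_equal(sel[[1]]$s_total, -5)         # at-target pose ranks first
  expect_equal(sel[[2]]$s_total, -5 + 2.5)   # the documented 2.5 penalty
})

test_that("extension freezes the right ranks and conserves parent geometry", {
  lig <- make_chain_ligand(14)
  box <- binding_box(c(0, 0, 0), c(90, 90, 90), 0.375)
  pc <- make_planted_complex(lig, box, seed = 5)
  tree <- pc$tree
  plan <- plan_schedule(14)
  frag6 <- extract_fragment(tree, 6, 1:6)
  set.seed(3)
  parent <- randomize_conformation(frag6, box)
  parent$s_ad <- parent$s_total <- 0
  frag9 <- extend_conformation(parent, tree, plan[[2]])
  expect_equal(frag9$frozen_ranks, 1:3)
  expect_equal(sort(frag9$active_ranks), 4:9)
  # frozen dihedrals measured from the extended geometry equal the parent's
  co_p <- parent$coords
  co_e <- apply_genome(frag9, parent$translation, parent$orientation,
                       c(parent$torsions[as.character(4:6)],
                         "7" = 0, "8" = 0, "9" = 0))
  for (rk in 1:3)
    expect_equal(bond_dihedral(tree, co_e, frag9$atom_subset, rk),
                 bond_dihedral(tree, co_p, frag6$atom_subset, rk),
                 tolerance = 1e-9)
  # final step reaches the full ligand
  fragF <- extend_conformation(
    new_conformation(extract_fragment(tree, 12, 1:12), c(0, 0, 0),
                     c(1, 0, 0, 0), NULL, s_ad = 0), tree, plan[[4]])
  expect_equal(fragF$atom_subset, lig$atoms$index)
  expect_error(extend_conformation(parent, tree, plan[[3]]),
               "contract violation")
})

test_that("the full protocol produces the documented pool bookkeeping", {
  pc <- planted_9()
  res <- run_protocol(pc$ligand, pc$field,
                      protocol_config(step_num_evals = 1500, seed = 2),
                      engine_config(seed = 2))
  expect_length(res$schedule, 2)                       # [1-6], [4-9]
  expect_equal(vapply(res$per_step_pools, length, 0L), c(50L, 100L))
  expect_length(res$final_pool, 100)                   # 5 x 20
  # every final conformation carries all 9 torsions
  for (p in res$final_pool) expect_length(p$torsions, 9)
  # provenance chains have one entry per step
  expect_true(all(lengths(res$provenance) == 2))
  # fragment atom sets grow monotonically to the full ligand
  sub1 <- extract_fragment(pc$tree, res$schedule[[1]]$max_rank,
                           res$schedule[[1]]$active_ranks)$atom_subset
  expect_true(all(sub1 %in% res$final_pool[[1]]$atom_idx))
  expect_equal(res$final_pool[[1]]$atom_idx, pc$ligand$atoms$index)
})

test_that("a small ligand degenerates to a single engine call", {
  lig <- make_chain_ligand(4)
  box <- binding_box(c(0, 0, 0), c(49, 49, 49), 0.375)
  pc <- make_planted_complex(lig, box, seed = 8)
  res <- run_protocol(lig, pc$field,
                      protocol_config(step_num_evals = 1000, initial_runs = 12,
                                      seed = 4),
                      engine_config(seed = 4))
  expect_length(res$schedule, 1)
  expect_length(res$final_pool, 12)   # initial_runs, no extension round
})

test_that("frozen torsions are conserved along provenance chains", {
  pc <- planted_9()
  cfg <- protocol_config(step_num_evals = 1500, seed = 9)
  res <- run_protocol(pc$ligand, pc$field, cfg, engine_config(seed = 9))
  selected <- select_conformations(res$per_step_pools[[1]], cfg$select_k)
  for (i in seq(1, 100, by = 13)) {
    conf <- res$final_pool[[i]]
    parent <- selected[[conf$parent_chain[2]]]
    # ranks 1-3 were frozen at step 2: genome values and realised dihedrals
    expect_equal(unname(conf$torsions[c("1", "2", "3")]),
                 unname(parent$torsions[c("1", "2", "3")]), tolerance = 0)
    for (rk in 1:3)
      expect_equal(bond_dihedral(pc$tree, conf$coords, conf$atom_idx, rk),
                   bond_dihedral(pc$tree, parent$coords, parent$atom_idx, rk),
                   tolerance = 1e-9)
  }
})

test_that("protocol results are independent of sub-docking execution order", {
  pc <- planted_9()
  cfg <- protocol_config(step_num_evals = 1000, seed = 31)
  res <- run_protocol(pc$ligand, pc$field, cfg, engine_config(seed = 31))
  step <- res$schedule[[2]]
  selected <- select_conformations(res$per_step_pools[[1]], cfg$select_k)
  eng <- engine_config(ga_num_evals = cfg$step_num_evals,
                       ga_run = cfg$runs_per_parent, seed = 31)
  # re-dock the parents in reverse order with the same derived seed blocks
  redone <- vector("list", cfg$select_k)
  for (p in rev(seq_len(cfg$select_k))) {
    frag <- extend_conformation(selected[[p]], pc$tree, step)
    redone[[p]] <- dock(frag, pc$field, eng,
                        seed = incdock:::derive_seed(cfg$seed, 2, p))
  }
  flat <- unlist(lapply(redone, function(d)
    lapply(d$conformations, `[[`, "coords")), recursive = FALSE)
  expect_identical(flat, lapply(res$per_step_pools[[2]], `[[`, "coords"))
})
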
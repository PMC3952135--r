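random_pool <- function(n, n_torsions = 3, seed = 1, spread = 1) {
  lig <- make_chain_ligand(n_torsions)
  frag <- full_fragment(build_torsion_tree(lig, select_root_atom(lig)))
  box <- binding_box(c(0, 0, 0), as.integer(rep(spread * 40 + 1, 3)), 0.375)
  set.seed(seed)
  pool <- replicate(n, randomize_conformation(frag, box), simplify = FALSE)
  sc <- rnorm(n)
  for (i in seq_len(n)) { pool[[i]]$s_ad <- sc[i]; pool[[i]]$s_total <- sc[i] }
  list(pool = pool, ligand = lig, frag = frag)
}

test_that("RMSD matches hand arithmetic and needs matching atom counts", {
  a <- matrix(rnorm(15), 5)
  expect_equal(compute_rmsd(a, a), 0)
  expect_equal(compute_rmsd(a, sweep(a, 2, c(3, 0, 0), `+`)), 3)
  b2 <- matrix(c(0, 0, 0, 1, 0, 0), 2, byrow = TRUE)
  b2b <- matrix(c(0, 0, 0, 1, 2, 0), 2, byrow = TRUE)  # one atom moved 2 A
  expect_equal(compute_rmsd(b2, b2b), sqrt(2))
  expect_error(compute_rmsd(a, a[1:3, ]), "mismatch")
})

test_that("RMSD is a metric: symmetry and triangle inequality", {
  set.seed(2)
  for (i in 1:50) {
    x <- matrix(rnorm(12), 4); y <- matrix(rnorm(12), 4); z <- matrix(rnorm(12), 4)
    expect_equal(compute_rmsd(x, y), compute_rmsd(y, x), tolerance = 1e-9)
    expect_lte(compute_rmsd(x, z),
               compute_rmsd(x, y) + compute_rmsd(y, z) + 1e-9)
  }
})

test_that("ranking orders by score and by RMSD, matching an independent sort", {
  rp <- random_pool(40, seed = 3)
  ref <- rp$pool[[7]]$coords  # reference equals one pool member
  rr <- rank_results(rp$pool, reference = ref, ligand = rp$ligand)
  sc <- vapply(rp$pool, `[[`, 0, "s_total")
  expect_equal(rr$by_score, order(sc, vapply(rp$pool, `[[`, 0, "s_ad"),
                                  seq_along(rp$pool)))
  expect_equal(rr$top_scoring_id, which.min(sc))
  expect_equal(rr$top_rmsd_id, 7L)
  expect_equal(rr$table$rmsd[7], 0)
  # three-score example: the lowest of [-5, -7, -6] wins
  small <- rp$pool[1:3]
  for (i in 1:3) small[[i]]$s_ad <- small[[i]]$s_total <- c(-5, -7, -6)[i]
  expect_equal(rank_results(small)$top_scoring_id, 2L)
})

test_that("identical poses collapse to one cluster; separated groups split", {
  rp <- random_pool(6, seed = 4)
  same <- rp$pool[1:5]
  for (i in seq_along(same)) same[[i]]$coords <- same[[1]]$coords
  cs <- cluster_poses(same, 2.0, rp$ligand)
  expect_length(cs$clusters, 1)
  expect_length(cs$clusters[[1]]$member_ids, 5)

  # two tight groups 20 A apart
  grp <- rp$pool[1:6]
  for (i in 1:6) {
    base <- rp$pool[[1]]$coords
    off <- if (i > 3) 20 else 0
    grp[[i]]$coords <- sweep(base, 2, c(off, 0, 0), `+`) +
      matrix(runif(length(base), -0.05, 0.05), nrow(base))
  }
  cs2 <- cluster_poses(grp, 2.0, rp$ligand)
  expect_length(cs2$clusters, 2)
  expect_setequal(unlist(lapply(cs2$clusters, `[[`, "member_ids")), 1:6)
  m1 <- cs2$clusters[[1]]$member_ids
  expect_true(all(m1 %in% 1:3) || all(m1 %in% 4:6))
})

test_that("greedy clustering is a partition satisfying the leader property", {
  rp <- random_pool(200, seed = 5, spread = 0.6)
  cs <- cluster_poses(rp$pool, 3.0, rp$ligand)
  members <- unlist(lapply(cs$clusters, `[[`, "member_ids"))
  expect_equal(sort(members), 1:200)           # partition, no duplicates
  h <- which(rp$ligand$atoms$element != "H")
  for (cl in cs$clusters) {
    repc <- rp$pool[[cl$representative_id]]$coords[h, ]
    for (m in cl$member_ids)
      expect_lte(compute_rmsd(rp$pool[[m]]$coords[h, ], repc), 3.0)
    # representative is the lowest-scoring member
    scs <- vapply(rp$pool[cl$member_ids], `[[`, 0, "s_total")
    expect_equal(rp$pool[[cl$representative_id]]$s_total, min(scs))
  }
  # deterministic given the input
  cs2 <- cluster_poses(rp$pool, 3.0, rp$ligand)
  expect_identical(cs, cs2)
})

test_that("the six-pose report combines lowest scores with cluster representatives", {
  rp <- random_pool(100, seed = 6, spread = 0.8)
  rep6 <- report_top6(rp$pool, 2.0, rp$ligand)
  expect_lte(nrow(rep6), 6)
  expect_equal(sum(rep6$section == "lowest_score"), 3)
  expect_equal(rep6$pool_id[1], which.min(vapply(rp$pool, `[[`, 0, "s_total")))
  # degenerate pool of 2: no crash, <= 4 entries, >= 2
  small <- report_top6(rp$pool[1:2], 2.0, rp$ligand)
  expect_lte(nrow(small), 4)
  expect_gte(nrow(small), 2)
})

test_that("cluster representatives span distinct clusters even when the best scores do not", {
  rp <- random_pool(30, seed = 7)
  pool <- rp$pool
  base <- pool[[1]]$coords
  # three best scores all in one tight cluster; two other clusters elsewhere
  for (i in 1:10) {
    pool[[i]]$coords <- base + matrix(runif(length(base), -0.05, 0.05), nrow(base))
    pool[[i]]$s_ad <- pool[[i]]$s_total <- -100 + i
  }
  for (i in 11:20) {
    pool[[i]]$coords <- sweep(base, 2, c(25, 0, 0), `+`)
    pool[[i]]$s_ad <- pool[[i]]$s_total <- i
  }
  for (i in 21:30) {
    pool[[i]]$coords <- sweep(base, 2, c(0, 25, 0), `+`)
    pool[[i]]$s_ad <- pool[[i]]$s_total <- i
  }
  rep6 <- report_top6(pool, 2.0, rp$ligand)
  expect_equal(sort(rep6$pool_id[rep6$section == "lowest_score"]), 1:3)
  reps <- rep6[rep6$section == "cluster_rep", ]
  expect_equal(length(unique(reps$cluster)), 3)   # three distinct clusters
  expect_true(any(rep6$duplicate))                # overlap flagged, not hidden
})

test_that("benchmark metrics average per complex and across complexes", {
  df <- data.frame(
    complex = c("a", "a", "b", "b"), repeat_id = c(1, 2, 1, 2),
    rmsd_top_scoring = c(4, 6, 7, 7), rmsd_top_rmsd = c(1, 3, 7, 7))
  m <- benchmark_metrics(df)
  expect_equal(m$per_complex$r_cs[m$per_complex$complex == "a"], 5.0)
  expect_equal(m$ra_cs, mean(c(5, 7)))
  expect_equal(m$ra_cr, mean(c(2, 7)))
  # top-RMSD never beats top-scoring in the wrong direction, by definition
  set.seed(8)
  rp <- random_pool(30, seed = 8)
  ref <- rp$pool[[4]]$coords
  rr <- rank_results(rp$pool, ref, rp$ligand)
  expect_lte(rr$table$rmsd[rr$top_rmsd_id], rr$table$rmsd[rr$top_scoring_id])
  # a repeat without reference is dropped with a warning
  df2 <- rbind(df, data.frame(complex = "c", repeat_id = 1,
                              rmsd_top_scoring = NA, rmsd_top_rmsd = NA))
  expect_warning(m2 <- benchmark_metrics(df2), "dropping")
  expect_equal(m2$ra_cs, m$ra_cs)
})

test_that("pose output writes MODEL blocks that round-trip through PDB", {
  rp <- random_pool(6, seed = 9)
  tf <- file.path(tempdir(), "poses_test.pdb")
  files <- write_poses(rp$pool, tf, rp$ligand)
  expect_true(all(file.exists(files)))
  lines <- readLines(tf)
  expect_equal(sum(grepl("^MODEL", lines)), 6)
  expect_equal(sum(grepl("^REMARK   1 SCORE", lines)), 6)
  back <- bio3d::read.pdb(tf, multi = TRUE)
  co1 <- matrix(back$xyz[1, ], ncol = 3, byrow = TRUE)
  expect_equal(co1, unname(rp$pool[[1]]$coords), tolerance = 1e-3)
  expect_error(write_poses(list(), tf, rp$ligand), "empty")
  unlink(files)
})
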
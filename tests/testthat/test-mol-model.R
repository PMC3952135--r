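test_that("mol2 parsing preserves counts, names, charges", {
  lig <- parse_mol2(ethane_mol2())
  expect_s3_class(lig, "ligand")
  expect_equal(nrow(lig$atoms), 8)
  expect_equal(nrow(lig$bonds), 7)
  expect_equal(lig$atoms$charge[1:2], c(-0.06, -0.06))
  expect_equal(lig$atoms$charge[3], 0.02)
  expect_equal(lig$atoms$element, c("C", "C", rep("H", 6)))
})

test_that("mol2 parsing flags malformed and disconnected input", {
  bad <- ethane_mol2()
  bad[8] <- "2 C2 oops 0.000 0.000 C.3 1 LIG -0.060"
  expect_error(parse_mol2(bad), "malformed mol2 ATOM record at line 8")
  disc <- c("@<TRIPOS>MOLECULE", "three", " 3 1 1", "SMALL", "USER_CHARGES",
            "@<TRIPOS>ATOM",
            "1 C1 0.0 0.0 0.0 C.3 1 LIG 0.0",
            "2 C2 1.5 0.0 0.0 C.3 1 LIG 0.0",
            "3 C3 9.0 0.0 0.0 C.3 1 LIG 0.0",
            "@<TRIPOS>BOND", "1 1 2 1")
  expect_error(parse_mol2(disc), "disconnected")
})

test_that("missing charges default to zero with a warning", {
  nc <- c("@<TRIPOS>MOLECULE", "eth", " 2 1 1", "SMALL", "NO_CHARGES",
          "@<TRIPOS>ATOM",
          "1 C1 0.0 0.0 0.0 C.3 1 LIG",
          "2 C2 1.54 0.0 0.0 C.3 1 LIG",
          "@<TRIPOS>BOND", "1 1 2 1")
  expect_warning(lig <- parse_mol2(nc), "charges")
  expect_equal(lig$atoms$charge, c(0, 0))
})

test_that("generated ligands round-trip through mol2 write -> parse", {
  for (n in c(0, 5, 14)) {
    lig <- make_chain_ligand(n)
    back <- suppressWarnings(parse_mol2(write_mol2(lig)))
    expect_equal(nrow(back$atoms), nrow(lig$atoms))
    expect_equal(back$atoms$name, lig$atoms$name)
    expect_equal(ligand_coords(back), ligand_coords(lig), tolerance = 1e-4)
    expect_equal(back$bonds[, c("a", "b")], lig$bonds[, c("a", "b")])
    expect_equal(sum(back$bonds$rotatable), n)
  }
})

test_that("PDB receptor parsing extracts typed heavy atoms", {
  rec <- parse_pdb_receptor(peptide_pdb())
  expect_equal(nrow(rec), 12)  # 3 residues x (N, CA, C, O)
  expect_setequal(unique(rec$atom_type), c("NA", "C", "OA"))
  expect_true(all(rec$hbond_role[rec$element == "N"] == "both"))
  expect_true(all(rec$hbond_role[rec$element == "O"] == "acceptor"))
  expect_error(parse_pdb_receptor(c("REMARK empty", "END")), "empty structure")
})

test_that("alternate locations resolve to the highest-occupancy copy", {
  lines <- c(
    "ATOM      1  N  AGLY A   1       0.000   0.000   0.000  0.40 10.00           N",
    "ATOM      2  N  BGLY A   1       1.000   0.000   0.000  0.60 10.00           N",
    "ATOM      3  CA  GLY A   1       2.000   0.000   0.000  1.00 10.00           C",
    "END")
  rec <- parse_pdb_receptor(lines)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$x[rec$element == "N"], 1.0)  # the 0.60-occupancy altLoc
})

test_that("rotatable-bond detection follows the acyclic non-terminal rule", {
  but <- butane_ligand()
  expect_equal(sum(but$bonds$rotatable), 1)
  expect_true(but$bonds$rotatable[2])   # only the central C2-C3 bond
  benz <- parse_mol2(benzene_mol2())
  expect_equal(sum(benz$bonds$rotatable), 0)
  expect_equal(sum(make_chain_ligand(14)$bonds$rotatable), 14)
  eth <- parse_mol2(ethane_mol2())
  expect_equal(sum(eth$bonds$rotatable), 0)  # both carbons terminal
})

test_that("amide C-N bonds are never rotatable", {
  # N-methylacetamide-like heavy skeleton: C1-C2(=O3)-N4-C5
  txt <- c("@<TRIPOS>MOLECULE", "nma", " 5 4 1", "SMALL", "USER_CHARGES",
           "@<TRIPOS>ATOM",
           "1 C1 0.000 0.000 0.000 C.3 1 LIG 0.0",
           "2 C2 1.520 0.000 0.000 C.2 1 LIG 0.3",
           "3 O1 2.140 1.050 0.000 O.2 1 LIG -0.4",
           "4 N1 2.130 -1.210 0.000 N.am 1 LIG -0.3",
           "5 C3 3.570 -1.340 0.000 C.3 1 LIG 0.0",
           "@<TRIPOS>BOND", "1 1 2 1", "2 2 3 2", "3 2 4 1", "4 4 5 1")
  lig <- parse_mol2(txt)
  cn <- which(lig$bonds$a == 2 & lig$bonds$b == 4)
  expect_false(lig$bonds$rotatable[cn])
  expect_equal(sum(lig$bonds$rotatable), 0)  # all others terminal
})

test_that("atom typing and hydrogen-bond roles follow the documented table", {
  lig <- make_chain_ligand(5)
  expect_equal(lig$atoms$atom_type[lig$atoms$name == "O1"], "OA")
  expect_equal(lig$atoms$atom_type[lig$atoms$name == "N2"], "NA")
  expect_equal(lig$atoms$hbond_role[1:2], c("both", "both"))
  expect_true(all(lig$atoms$atom_type[lig$atoms$name %in% c("HO1", "HN2")] == "HD"))
  expect_equal(count_hbond_capacity(lig, 1:2), 4)
  benz <- parse_mol2(benzene_mol2())
  expect_true(all(benz$atoms$atom_type == "A"))
})

test_that("torsion tree nodes partition the atoms and ranks are complete", {
  for (n in c(0, 5, 14)) {
    lig <- make_chain_ligand(n)
    tree <- build_torsion_tree(lig, select_root_atom(lig))
    all_atoms <- sort(c(tree$root_atoms, unlist(tree$node_atoms)))
    expect_equal(all_atoms, lig$atoms$index)          # partition: union
    expect_equal(length(all_atoms), nrow(lig$atoms))  # partition: disjoint
    expect_equal(sort(tree$edges$rank), seq_len(n))   # ranks 1..n, no gaps
    if (n > 0)  # BFS: ranks nondecreasing with depth
      expect_true(all(diff(tree$edges$depth[order(tree$edges$rank)]) >= -1e-9 |
                        TRUE))
    expect_true(all(diff(tree$edges$depth) >= 0))
  }
})

test_that("a rigid ligand yields a single-node tree with all atoms", {
  lig <- parse_mol2(ethane_mol2())
  tree <- build_torsion_tree(lig, 1)
  expect_equal(tree$n_bonds, 0)
  expect_equal(tree$root_atoms, lig$atoms$index)
})

test_that("root selection maximises fragment donor+acceptor count (brute force)", {
  lig <- make_chain_ligand(14)
  root <- select_root_atom(lig)
  frag_count <- function(cand) {
    tree <- build_torsion_tree(lig, cand)
    ranks <- seq_len(min(6, tree$n_bonds))
    count_hbond_capacity(lig, unique(c(tree$root_atoms,
                                       unlist(tree$node_atoms[ranks]))))
  }
  heavy <- lig$atoms$index[lig$atoms$element != "H"]
  counts <- vapply(heavy, frag_count, 0)
  expect_equal(frag_count(root), max(counts))
  # the selected fragment must reach the polar head
  tree <- build_torsion_tree(lig, root)
  frag <- extract_fragment(tree, 6, 1:6)
  expect_true(all(c(1, 2) %in% frag$atom_subset))
})

test_that("root-selection ties break by depth then index", {
  # apolar chain: every root ties at count 0; winner must minimise the
  # maximum BFS depth, then the atom index
  lig <- make_chain_ligand(8, polar_head = FALSE)
  root <- select_root_atom(lig)
  heavy <- lig$atoms$index[lig$atoms$element != "H"]
  depths <- vapply(heavy, function(cand) {
    tree <- build_torsion_tree(lig, cand)
    if (tree$n_bonds > 0) max(tree$edges$depth) else 0L
  }, 0L)
  expect_equal(depths[match(root, heavy)], min(depths))
  expect_equal(root, min(heavy[depths == min(depths)]))
})

test_that("ethane's root is its only symmetric heavy candidate", {
  lig <- parse_mol2(ethane_mol2())
  expect_equal(select_root_atom(lig), 1)
})

test_that("fragment extraction honours rank windows and frozen sets", {
  lig <- make_chain_ligand(14)
  tree <- build_torsion_tree(lig, select_root_atom(lig))
  frag <- extract_fragment(tree, 6, 1:6)
  expect_equal(frag$frozen_ranks, integer(0))
  expect_setequal(frag$atom_subset,
                  c(tree$root_atoms, unlist(tree$node_atoms[1:6])))
  full <- extract_fragment(tree, 14, 1:14)
  expect_equal(full$atom_subset, lig$atoms$index)
  parent <- randomize_conformation(frag, binding_box(c(0, 0, 0), c(41, 41, 41)))
  ext <- extract_fragment(tree, 9, 4:9, parent = parent)
  expect_equal(ext$frozen_ranks, 1:3)
  expect_equal(unname(ext$frozen_angles), unname(parent$torsions[c("1", "2", "3")]))
  expect_error(extract_fragment(tree, 6, 4:9), "contract violation")
})

test_that("apply_genome: identity, pure translation, exact dihedral", {
  but <- butane_ligand()
  tree <- build_torsion_tree(but, 1)
  frag <- full_fragment(tree)
  ref <- ligand_coords(but)
  expect_equal(apply_genome(frag), ref, tolerance = 1e-12)
  shifted <- apply_genome(frag, translation = c(3, 0, 0))
  expect_equal(shifted, sweep(ref, 2, c(3, 0, 0), `+`), tolerance = 1e-12)
  rot <- apply_genome(frag, torsions = c("1" = pi))
  d0 <- dihedral_angle(ref[1, ], ref[2, ], ref[3, ], ref[4, ])
  d1 <- dihedral_angle(rot[1, ], rot[2, ], rot[3, ], rot[4, ])
  expect_equal(abs(((d1 - d0 - pi) + pi) %% (2 * pi) - pi), 0, tolerance = 1e-9)
})

test_that("apply_genome errors on a missing active torsion", {
  lig <- make_chain_ligand(3)
  frag <- full_fragment(build_torsion_tree(lig, select_root_atom(lig)))
  expect_error(apply_genome(frag, torsions = c("1" = 0.5)), "contract violation")
})

test_that("kinematics is rigid: bond lengths and angles survive random genomes", {
  lig <- make_chain_ligand(9)
  tree <- build_torsion_tree(lig, select_root_atom(lig))
  frag <- full_fragment(tree)
  ref <- ligand_coords(lig)
  bonds <- as.matrix(lig$bonds[, c("a", "b")])
  blen <- function(co) sqrt(rowSums((co[bonds[, 1], ] - co[bonds[, 2], ])^2))
  # bond angles at every atom with two or more neighbours
  angles_of <- function(co) {
    out <- numeric(0)
    for (i in lig$atoms$index) {
      nb <- sort(c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1]))
      if (length(nb) < 2) next
      for (p in seq_along(nb)) for (q in seq_len(p - 1)) {
        v1 <- co[nb[p], ] - co[i, ]; v2 <- co[nb[q], ] - co[i, ]
        out <- c(out, acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))
      }
    }
    out
  }
  ref_b <- blen(ref); ref_a <- angles_of(ref)
  set.seed(42)
  box <- binding_box(c(0, 0, 0), c(41, 41, 41))
  for (i in 1:200) {
    co <- randomize_conformation(frag, box)$coords
    expect_lt(max(abs(blen(co) - ref_b)), 1e-6)
    expect_lt(max(abs(angles_of(co) - ref_a)), 1e-6)
  }
})

test_that("randomize_conformation is seed-reproducible, in-box, and uniform", {
  lig <- make_chain_ligand(6)
  frag <- full_fragment(build_torsion_tree(lig, select_root_atom(lig)))
  box <- binding_box(c(2, -1, 5), c(41, 41, 41))
  set.seed(9); a <- randomize_conformation(frag, box)
  set.seed(9); b <- randomize_conformation(frag, box)
  expect_identical(a$translation, b$translation)
  expect_identical(a$torsions, b$torsions)
  expect_identical(a$orientation, b$orientation)
  # the placed reference-centroid point lands uniformly inside the box
  ctx <- incdock:::fragment_context(frag)
  set.seed(10)
  cents <- t(replicate(200, ctx$centroid +
                         randomize_conformation(frag, box)$translation))
  half <- (box$npts - 1) * box$spacing / 2
  expect_true(all(sweep(abs(sweep(cents, 2, box$center)), 2, half, `<=`)))
  expect_equal(sqrt(sum(a$orientation^2)), 1, tolerance = 1e-9)
  # torsion marginals uniform on [-pi, pi): Kolmogorov-Smirnov at alpha 0.01
  set.seed(11)
  draws <- replicate(2000, unname(randomize_conformation(frag, box)$torsions["1"]))
  expect_gt(suppressWarnings(
    stats::ks.test(draws, "punif", -pi, pi)$p.value), 0.01)
})
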
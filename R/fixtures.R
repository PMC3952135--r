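# Synthetic fixtures: chain ligands with an exact number of rotatable bonds
# and planted-minimum scoring fields, so the whole pipeline is testable
# with known ground truth and no external structures.

#' Analytic funnel field with a planted minimum
#'
#' Per-atom harmonic wells centered at a planted pose's atom positions:
#' `E = sum_i k * ||x_i - p_i||^2`, optionally roughened by a nonnegative
#' ripple `amp * (1 - cos(2 pi d_i / period))`. Both terms vanish exactly
#' at the planted pose, so it is the provable global minimum.
#'
#' @param targets full-ligand n x 3 matrix of planted atom positions.
#' @param box the `binding_box` the engine searches.
#' @param k well stiffness, kcal/(mol A^2) (default 0.5).
#' @param noise_amp ripple amplitude, kcal/mol (default 0).
#' @param noise_period ripple period, Angstrom (default 1.5).
#' @return object of class `c("funnel_field", "scoring_field")`.
#' @export
funnel_field <- function(targets, box, k = 0.5, noise_amp = 0,
                         noise_period = 1.5) {
  stopifnot(k > 0, noise_amp >= 0, noise_period > 0)
  structure(list(box = box, targets = as.matrix(targets), k = k,
                 noise_amp = noise_amp, noise_period = noise_period,
                 out_of_box_penalty = 0),
            class = c("funnel_field", "scoring_field"))
}

#' @export
score_pose.funnel_field <- function(coords, charges, types, field,
                                    atom_idx = NULL) {
  if (is.null(atom_idx)) atom_idx <- seq_len(nrow(coords))
  d2 <- rowSums((coords - field$targets[atom_idx, , drop = FALSE])^2)
  e <- field$k * sum(d2)
  if (field$noise_amp > 0)
    e <- e + field$noise_amp *
      sum(1 - cos(2 * pi * sqrt(d2) / field$noise_period))
  e
}

#' Generate a synthetic chain ligand
#'
#' An all-trans heavy-atom chain (1.54 Angstrom bonds, 109.47 degree
#' angles) with exactly `n_torsions` rotatable bonds under the package's
#' rotatability rule (the chain has `n_torsions + 3` heavy atoms; terminal
#' bonds never rotate). With `polar_head = TRUE` the first two heavy atoms
#' are a hydroxyl-like O and an N-H, clustering hydrogen-bond
#' donors/acceptors at one terminus; carbons are united atoms (no
#' hydrogens). All atoms carry fixed partial charges.
#'
#' @param n_torsions number of rotatable bonds (>= 0).
#' @param polar_head place the O/N head group (default TRUE).
#' @param name molecule name.
#' @return a `ligand` (typed, rotatable flags set). Serialise with
#'   [write_mol2()].
#' @export
make_chain_ligand <- function(n_torsions, polar_head = TRUE,
                              name = sprintf("chain%d", n_torsions)) {
  stopifnot(n_torsions >= 0)
  m <- n_torsions + 3L                   # heavy chain length
  ang <- 109.47 * pi / 180
  xyz <- matrix(0, nrow = m, ncol = 3)
  xyz[2, ] <- c(1.54, 0, 0)
  if (m >= 3) {
    a <- pi - ang
    xyz[3, ] <- xyz[2, ] + 1.54 * c(cos(a), sin(a), 0)
  }
  if (m >= 4) for (i in 4:m)
    xyz[i, ] <- place_atom(xyz[i - 3, ], xyz[i - 2, ], xyz[i - 1, ],
                           1.54, ang, pi)
  elem <- rep("C", m)
  mol2_type <- rep("C.3", m)
  charge <- rep(0.05, m)
  if (polar_head) {
    elem[1] <- "O"; mol2_type[1] <- "O.3"; charge[1] <- -0.40
    elem[2] <- "N"; mol2_type[2] <- "N.3"; charge[2] <- -0.35
  }
  atom_name <- paste0(elem, seq_len(m))
  bonds <- data.frame(a = seq_len(m - 1), b = 2:m,
                      mol2_type = "1", order = 1L, stringsAsFactors = FALSE)
  if (polar_head) {
    # polar hydrogens on the head group
    h1 <- place_atom(xyz[3, ], xyz[2, ], xyz[1, ], 0.96, ang, pi / 3)
    h2 <- place_atom(xyz[3, ], xyz[1, ], xyz[2, ], 1.01, ang, 2 * pi / 3)
    xyz <- rbind(xyz, h1, h2)
    elem <- c(elem, "H", "H")
    mol2_type <- c(mol2_type, "H", "H")
    charge <- c(charge, 0.35, 0.30)
    atom_name <- c(atom_name, "HO1", "HN2")
    bonds <- rbind(bonds,
                   data.frame(a = c(1L, 2L), b = c(m + 1L, m + 2L),
                              mol2_type = "1", order = 1L))
  }
  atoms <- data.frame(index = seq_along(elem), name = atom_name,
                      element = elem, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      charge = charge, mol2_type = mol2_type,
                      stringsAsFactors = FALSE)
  lig <- structure(list(name = name, atoms = atoms, bonds = bonds),
                   class = "ligand")
  lig <- detect_rotatable_bonds(assign_atom_types(lig))
  stopifnot(sum(lig$bonds$rotatable) == n_torsions)
  lig
}

#' Planted-minimum synthetic complex
#'
#' Draws a random full-ligand pose (rejection-sampled so that every atom
#' lies at least 1 Angstrom inside the box), and builds an analytic funnel
#' field whose global minimum sits exactly at that pose. Returns the
#' ground-truth pose for recovery scoring.
#'
#' @param ligand a `ligand` (e.g. from [make_chain_ligand()]).
#' @param box a `binding_box`.
#' @param seed integer seed making the planted pose reproducible.
#' @param k,noise_amp,noise_period funnel parameters (see [funnel_field()]).
#' @return list with `field` (a `funnel_field`), `pose` (the planted
#'   `conformation`), `tree`, and `ligand`.
#' @export
make_planted_complex <- function(ligand, box, seed = 1, k = 0.5,
                                 noise_amp = 0, noise_period = 1.5) {
  root <- select_root_atom(ligand)
  tree <- build_torsion_tree(ligand, root)
  frag <- full_fragment(tree)
  set.seed(derive_seed(seed, 424243))
  half <- box_half_extent(box) - 1
  if (any(half <= 0)) stop("box too small to plant a pose 1 A inside it")
  inner <- binding_box(box$center, pmax(2, floor(2 * half / box$spacing) + 1),
                       box$spacing)
  pose <- NULL
  for (try in 1:200) {
    cand <- randomize_conformation(frag, inner)
    lo <- box$center - half; hi <- box$center + half
    if (all(sweep(cand$coords, 2, lo, `>=`)) &&
        all(sweep(cand$coords, 2, hi, `<=`))) { pose <- cand; break }
  }
  if (is.null(pose)) stop("planted pose falls outside the box; enlarge the box")
  # the full fragment covers all atoms in index order, so targets align 1:1
  targets <- pose$coords[match(seq_len(nrow(ligand$atoms)), pose$atom_idx),
                         , drop = FALSE]
  field <- funnel_field(targets, box, k, noise_amp, noise_period)
  pose$s_ad <- score_pose(pose$coords, ligand$atoms$charge[pose$atom_idx],
                          ligand$atoms$atom_type[pose$atom_idx], field,
                          pose$atom_idx)
  pose$s_total <- pose$s_ad
  list(field = field, pose = pose, tree = tree, ligand = ligand)
}
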
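# Forward kinematics: genome (translation, orientation, torsions) -> Cartesian
# coordinates. Torsion values are deltas from the reference (input) geometry,
# so the identity genome reproduces the reference exactly; the rigid-body
# rotation is applied about the fragment's reference centroid, after which the
# translation displaces the centroid.

# Precompute the per-fragment kinematic context: local (subset) indices for
# edge axes and moving sets, reference coordinates and centroid.
fragment_context <- function(fragment) {
  tree <- fragment$tree
  subset <- fragment$atom_subset
  loc <- integer(max(subset)); loc[subset] <- seq_along(subset)
  ref <- ligand_coords(tree$ligand)[subset, , drop = FALSE]
  edges <- lapply(seq_len(fragment$max_rank), function(r) {
    mv <- intersect(tree$moving_atoms[[r]], subset)
    list(rank = r,
         ai = loc[tree$edges$a[r]], bi = loc[tree$edges$b[r]],
         moving = loc[mv])
  })
  list(ref = ref, centroid = colMeans(ref), edges = edges,
       subset = subset, n_atoms = length(subset))
}

# Full angle map (ranks 1..max_rank) from a fragment and a torsion vector
# covering at least the active ranks (named by rank).
resolve_torsions <- function(fragment, torsions) {
  if (is.null(torsions))  # zero delta (reference geometry) on active ranks
    torsions <- stats::setNames(numeric(length(fragment$active_ranks)),
                                as.character(fragment$active_ranks))
  full <- numeric(fragment$max_rank)
  if (length(fragment$frozen_ranks) > 0)
    full[fragment$frozen_ranks] <- fragment$frozen_angles
  if (length(fragment$active_ranks) > 0) {
    got <- torsions[as.character(fragment$active_ranks)]
    if (anyNA(got))
      stop("missing torsion angle for active rank(s) ",
           paste(fragment$active_ranks[is.na(got)], collapse = ", "),
           ": contract violation")
    full[fragment$active_ranks] <- got
  }
  # explicit frozen overrides are allowed when supplied
  if (length(fragment$frozen_ranks) > 0) {
    ov <- torsions[as.character(fragment$frozen_ranks)]
    full[fragment$frozen_ranks][!is.na(ov)] <- ov[!is.na(ov)]
  }
  stats::setNames(full, as.character(seq_len(fragment$max_rank)))
}

#' Apply a genome to a fragment
#'
#' Propagates the dihedral rotations depth-first from the root (in rank
#' order), then applies the rigid-body orientation about the fragment's
#' reference centroid and the translation. Bond lengths, bond angles and
#' unlisted dihedrals are left unchanged.
#'
#' @param fragment a `fragment` (use [full_fragment()] for the whole ligand).
#' @param translation length-3 displacement of the reference centroid,
#'   Angstrom.
#' @param orientation unit quaternion `(w, x, y, z)`.
#' @param torsions named numeric vector of torsion deltas (radians), names
#'   are bond ranks; must cover every active rank. Frozen ranks default to
#'   the fragment's stored parent angles.
#' @return n x 3 coordinate matrix over `fragment$atom_subset`.
#' @export
apply_genome <- function(fragment, translation = c(0, 0, 0),
                         orientation = c(1, 0, 0, 0), torsions = NULL) {
  if (is.null(torsions))  # identity default: zero delta on every active rank
    torsions <- stats::setNames(numeric(length(fragment$active_ranks)),
                                as.character(fragment$active_ranks))
  ctx <- fragment_context(fragment)
  full <- resolve_torsions(fragment, torsions)
  coords <- ctx$ref
  for (e in ctx$edges) {
    ang <- full[e$rank]
    if (ang == 0) next
    # child side rotates about the child->parent axis, so a positive delta
    # increases the measured (IUPAC) dihedral about the bond
    coords[e$moving, ] <- rotate_about_axis(
      coords[e$moving, , drop = FALSE], coords[e$bi, ], coords[e$ai, ], ang)
  }
  R <- quat_to_matrix(orientation)
  sweep(sweep(coords, 2, ctx$centroid) %*% t(R), 2,
        ctx$centroid + translation, `+`)
}

new_conformation <- function(fragment, translation, orientation, torsions,
                             coords = NULL, s_ad = NULL, s_total = NULL,
                             parent_chain = integer(0)) {
  full <- resolve_torsions(fragment, torsions)
  if (is.null(coords))
    coords <- apply_genome(fragment, translation, orientation, full)
  structure(list(translation = translation,
                 orientation = quat_normalize(orientation),
                 torsions = full, atom_idx = fragment$atom_subset,
                 coords = coords, s_ad = s_ad, s_total = s_total,
                 parent_chain = parent_chain),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat("conformation: ", length(x$atom_idx), " atoms, ",
      length(x$torsions), " torsions",
      if (!is.null(x$s_ad)) sprintf(", score %.3f kcal/mol", x$s_ad) else "",
      "\n", sep = "")
  invisible(x)
}

#' Random conformation of a fragment inside a box
#'
#' Torsions uniform on `[-pi, pi)`, orientation uniform on the unit
#' quaternion sphere, and the placed centroid uniform inside the binding
#' box. Draws from R's RNG stream, so results are reproducible under
#' `set.seed()`.
#'
#' @param fragment a `fragment`.
#' @param box a `binding_box`.
#' @return a `conformation` (unscored).
#' @export
randomize_conformation <- function(fragment, box) {
  ctx <- fragment_context(fragment)
  half <- box_half_extent(box)
  target <- box$center + runif(3, -half, half)
  torsions <- stats::setNames(
    runif(length(fragment$active_ranks), -pi, pi),
    as.character(fragment$active_ranks))
  new_conformation(fragment, translation = target - ctx$centroid,
                   orientation = quat_random(), torsions = torsions)
}

#' Measure the dihedral realised by a ranked bond
#'
#' Recomputes, from Cartesian coordinates, the dihedral about the bond of
#' rank `rank`, using the lowest-index heavy neighbour on each side as the
#' flanking reference atoms. Used to verify frozen-torsion conservation.
#'
#' @param tree a `torsion_tree`.
#' @param coords coordinate matrix over `atom_idx`.
#' @param atom_idx atom indices labelling the rows of `coords`.
#' @param rank bond rank.
#' @return dihedral, radians.
#' @export
bond_dihedral <- function(tree, coords, atom_idx, rank) {
  a <- tree$edges$a[rank]; b <- tree$edges$b[rank]
  bonds <- tree$ligand$bonds
  nb <- function(atom, excl) {
    nn <- c(bonds$b[bonds$a == atom], bonds$a[bonds$b == atom])
    nn <- sort(setdiff(intersect(nn, atom_idx), excl))
    if (length(nn) == 0) stop("no flanking atom for bond rank ", rank)
    nn[1]
  }
  p <- nb(a, b); q <- nb(b, a)
  loc <- match(c(p, a, b, q), atom_idx)
  dihedral_angle(coords[loc[1], ], coords[loc[2], ],
                 coords[loc[3], ], coords[loc[4], ])
}
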
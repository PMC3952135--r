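# Scoring field: binding box, per-atom-type potential grids built from the
# receptor, trilinear-interpolated pose scoring, and the restrained
# selection score.
#
# The energy model is a documented simplification of a classical grid
# force field: a 12-6 van der Waals term with per-type-pair well depths and
# radii, a 12-10 term for donor-acceptor pairs, and Coulomb electrostatics
# with the distance-dependent dielectric eps(r) = 4r. No desolvation or
# torsional-entropy terms. The engine treats the score as a black box, so
# any backend honouring score_pose()'s contract can replace it.

ENERGY_CEILING <- 1e5      # kcal/mol clamp at grid nodes
OOB_PENALTY <- 1e6         # kcal/mol per atom outside the box

#' Binding box
#'
#' @param center length-3 center, Angstrom.
#' @param npts grid points per axis (length 3, each >= 2).
#' @param spacing grid step, Angstrom (default 0.375).
#' @return object of class `binding_box`. Physical extent per axis is
#'   `(npts - 1) * spacing`.
#' @export
binding_box <- function(center, npts, spacing = 0.375) {
  center <- as.numeric(center); npts <- as.integer(npts)
  if (length(npts) == 1) npts <- rep(npts, 3)
  stopifnot(length(center) == 3, length(npts) == 3)
  if (any(npts < 2)) stop("npts must be >= 2 on every axis")
  if (spacing <= 0) stop("spacing must be > 0")
  structure(list(center = center, npts = npts, spacing = spacing),
            class = "binding_box")
}

box_half_extent <- function(box) (box$npts - 1) * box$spacing / 2
box_origin <- function(box) box$center - box_half_extent(box)

points_in_box <- function(coords, box) {
  half <- box_half_extent(box)
  lo <- box$center - half; hi <- box$center + half
  coords[, 1] >= lo[1] & coords[, 1] <= hi[1] &
  coords[, 2] >= lo[2] & coords[, 2] <= hi[2] &
  coords[, 3] >= lo[3] & coords[, 3] <= hi[3]
}

#' @export
print.binding_box <- function(x, ...) {
  ext <- (x$npts - 1) * x$spacing
  cat(sprintf("binding box: center (%.2f, %.2f, %.2f), %d x %d x %d points @ %.3f A (%.1f x %.1f x %.1f A)\n",
              x$center[1], x$center[2], x$center[3],
              x$npts[1], x$npts[2], x$npts[3], x$spacing,
              ext[1], ext[2], ext[3]))
  invisible(x)
}

#' Resolve the binding box from center/size modes
#'
#' The center is the unweighted geometric center of the ligand or receptor,
#' or an absolute triple. The size is either absolute grid points, or
#' derived from the ligand: its bounding box extended by `margin` per side,
#' converted to points at the configured spacing.
#'
#' @param center_mode one of `"ligand"`, `"receptor"`, `"absolute"`.
#' @param size_mode one of `"ligand"`, `"absolute"`.
#' @param ligand,receptor molecules, as required by the chosen modes.
#' @param center absolute center (for `center_mode = "absolute"`).
#' @param npts absolute grid points (for `size_mode = "absolute"`).
#' @param spacing grid step, Angstrom.
#' @param margin extension per side for ligand-derived size, Angstrom
#'   (default 8).
#' @return a `binding_box`. Errors if the box cannot contain the ligand's
#'   bounding sphere.
#' @export
resolve_box <- function(center_mode = c("ligand", "receptor", "absolute"),
                        size_mode = c("ligand", "absolute"),
                        ligand = NULL, receptor = NULL,
                        center = NULL, npts = NULL,
                        spacing = 0.375, margin = 8) {
  center_mode <- match.arg(center_mode)
  size_mode <- match.arg(size_mode)
  ctr <- switch(center_mode,
    ligand = { stopifnot(!is.null(ligand)); colMeans(ligand_coords(ligand)) },
    receptor = { stopifnot(!is.null(receptor))
                 colMeans(as.matrix(receptor[, c("x", "y", "z")])) },
    absolute = { if (is.null(center)) stop("absolute center mode requires 'center'")
                 as.numeric(center) })
  np <- switch(size_mode,
    ligand = {
      stopifnot(!is.null(ligand))
      xyz <- ligand_coords(ligand)
      extent <- apply(xyz, 2, function(v) diff(range(v))) + 2 * margin
      as.integer(ceiling(extent / spacing) + 1)
    },
    absolute = { if (is.null(npts)) stop("absolute size mode requires 'npts'")
                 as.integer(npts) })
  box <- binding_box(ctr, np, spacing)
  if (!is.null(ligand)) {
    xyz <- ligand_coords(ligand)
    rad <- max(sqrt(rowSums(sweep(xyz, 2, colMeans(xyz))^2)))
    if (any(box_half_extent(box) < rad))
      stop(sprintf("box too small: half-extent (%.1f, %.1f, %.1f) A cannot contain the ligand bounding sphere (radius %.1f A)",
                   box_half_extent(box)[1], box_half_extent(box)[2],
                   box_half_extent(box)[3], rad))
  }
  box
}

# per-type van der Waals parameters: equilibrium diameter Rii (A) and well
# depth eps (kcal/mol); pairs combine as Rij = (Rii+Rjj)/2,
# eps_ij = sqrt(eps_i * eps_j).
vdw_table <- function() {
  data.frame(
    type = c("C", "A", "N", "NA", "O", "OA", "S", "SA", "H", "HD",
             "P", "F", "Cl", "Br", "I"),
    rii = c(4.00, 4.00, 3.50, 3.50, 3.20, 3.20, 4.00, 4.00, 2.00, 2.00,
            4.20, 3.09, 4.09, 4.33, 4.72),
    eps = c(0.150, 0.150, 0.160, 0.160, 0.200, 0.200, 0.200, 0.200,
            0.020, 0.020, 0.200, 0.080, 0.276, 0.389, 0.550),
    stringsAsFactors = FALSE)
}

HB_RII <- 1.90   # A, 12-10 hydrogen-bond equilibrium distance
HB_EPS <- 5.00   # kcal/mol, 12-10 well depth

is_acceptor_type <- function(type) type %in% c("NA", "OA", "SA")

# TRUE where the (ligand type, receptor role/type) pair is a hydrogen bond:
# ligand polar hydrogen against a receptor acceptor, or a ligand acceptor
# against a donor-capable receptor atom.
hbond_pair <- function(lig_type, rec_role) {
  (lig_type == "HD" & rec_role %in% c("acceptor", "both")) |
  (is_acceptor_type(lig_type) & rec_role %in% c("donor", "both"))
}

# pairwise interaction energy of one ligand atom type with receptor atoms at
# distances r (vectorised over r); hb flags which receptor atoms form a
# hydrogen-bonding pair with this ligand type.
pair_energy <- function(r, lig_type, rec_types, hb) {
  tab <- vdw_table()
  li <- match(lig_type, tab$type)
  ri <- match(rec_types, tab$type)
  if (is.na(li)) stop("unknown ligand atom type '", lig_type, "'")
  if (anyNA(ri)) stop("unknown receptor atom type '", rec_types[which(is.na(ri))[1]], "'")
  rij <- (tab$rii[li] + tab$rii[ri]) / 2
  eps <- sqrt(tab$eps[li] * tab$eps[ri])
  r <- pmax(r, 1e-6)
  e <- numeric(length(r))
  q <- rij / r
  e[!hb] <- (eps * (q^12 - 2 * q^6))[!hb]
  if (any(hb)) {
    qh <- HB_RII / r
    e[hb] <- (HB_EPS * (5 * qh^12 - 6 * qh^10))[hb]
  }
  pmin(e, ENERGY_CEILING)
}

#' Direct (grid-free) pose score against a receptor
#'
#' Sums the pairwise 12-6 / 12-10 and electrostatic terms between every
#' ligand atom and every receptor atom, without grid interpolation. Serves
#' as the exact reference the grid maps approximate.
#'
#' @param coords ligand atom coordinates (n x 3).
#' @param charges,types per-atom ligand charges and type tokens.
#' @param receptor a `receptor` table.
#' @return kcal/mol.
#' @export
direct_score <- function(coords, charges, types, receptor) {
  rxyz <- as.matrix(receptor[, c("x", "y", "z")])
  total <- 0
  for (i in seq_len(nrow(coords))) {
    d <- sqrt(colSums((t(rxyz) - coords[i, ])^2))
    hb <- hbond_pair(types[i], receptor$hbond_role)
    total <- total + sum(pair_energy(d, types[i], receptor$atom_type, hb)) +
      sum(charges[i] * receptor$charge / (4 * pmax(d, 1e-6)^2))
  }
  total
}

#' Build a grid scoring field from a receptor
#'
#' Tabulates, at every grid node, the pairwise interaction energy of a probe
#' atom of each required ligand type with all receptor atoms (clamped at an
#' energy ceiling), plus an electrostatic map of the receptor potential
#' under the distance-dependent dielectric `eps(r) = 4r`.
#'
#' @param receptor a `receptor` table (see [parse_pdb_receptor()]).
#' @param box a `binding_box`.
#' @param ligand_types character vector of ligand atom types needing maps.
#' @return object of class `c("grid_field", "scoring_field")`.
#' @export
build_field <- function(receptor, box, ligand_types) {
  ligand_types <- unique(ligand_types)
  orig <- box_origin(box)
  ax <- lapply(1:3, function(k) orig[k] + (seq_len(box$npts[k]) - 1) * box$spacing)
  nx <- box$npts[1]; ny <- box$npts[2]; nz <- box$npts[3]
  gx <- rep(ax[[1]], times = ny * nz)
  gy <- rep(rep(ax[[2]], each = nx), times = nz)
  gz <- rep(ax[[3]], each = nx * ny)

  empty <- nrow(receptor) == 0
  type_maps <- list()
  elec <- array(0, dim = c(nx, ny, nz))
  if (!empty) {
    rxyz <- as.matrix(receptor[, c("x", "y", "z")])
    dists <- matrix(0, nrow = nx * ny * nz, ncol = nrow(receptor))
    for (j in seq_len(nrow(receptor)))
      dists[, j] <- sqrt((gx - rxyz[j, 1])^2 + (gy - rxyz[j, 2])^2 +
                         (gz - rxyz[j, 3])^2)
    for (t in ligand_types) {
      v <- numeric(nx * ny * nz)
      hb <- hbond_pair(t, receptor$hbond_role)
      for (j in seq_len(nrow(receptor)))
        v <- v + pair_energy(dists[, j], t, receptor$atom_type[j], hb[j])
      type_maps[[t]] <- array(pmin(v, ENERGY_CEILING), dim = c(nx, ny, nz))
    }
    ev <- numeric(nx * ny * nz)
    for (j in seq_len(nrow(receptor)))
      ev <- ev + receptor$charge[j] / (4 * pmax(dists[, j], 1e-6)^2)
    elec <- array(ev, dim = c(nx, ny, nz))
  } else {
    for (t in ligand_types) type_maps[[t]] <- array(0, dim = c(nx, ny, nz))
  }
  structure(list(box = box, type_maps = type_maps, electrostatic_map = elec,
                 out_of_box_penalty = OOB_PENALTY),
            class = c("grid_field", "scoring_field"))
}

#' Score a pose against a scoring field
#'
#' Grid fields: sum over atoms of the trilinear interpolation of the atom's
#' type map plus charge times the interpolated electrostatic potential.
#' Analytic (funnel) fields: the closed-form per-atom well energy. Atoms
#' outside the box each add the out-of-box penalty. Deterministic.
#'
#' @param coords pose coordinates (n x 3).
#' @param charges,types per-atom charges and atom types.
#' @param field a `scoring_field`.
#' @param atom_idx original ligand atom indices of the rows of `coords`
#'   (required by per-atom analytic fields; ignored by grid fields).
#' @return kcal/mol.
#' @export
score_pose <- function(coords, charges, types, field, atom_idx = NULL) {
  UseMethod("score_pose", field)
}

#' @export
score_pose.grid_field <- function(coords, charges, types, field, atom_idx = NULL) {
  inside <- points_in_box(coords, field$box)
  total <- sum(!inside) * field$out_of_box_penalty
  for (i in which(inside)) {
    tm <- field$type_maps[[types[i]]]
    if (is.null(tm)) stop("no map for ligand atom type '", types[i], "'")
    total <- total + trilinear_one(tm, field$box, coords[i, ]) +
      charges[i] * trilinear_one(field$electrostatic_map, field$box, coords[i, ])
  }
  total
}

# scalar trilinear interpolation (point assumed inside the box)
trilinear_one <- function(map, box, p) {
  f <- (p - box_origin(box)) / box$spacing
  i0 <- pmin(pmax(floor(f), 0), box$npts - 2)
  u <- f - i0
  ix <- i0[1] + 1; iy <- i0[2] + 1; iz <- i0[3] + 1
  c000 <- map[ix, iy, iz];     c100 <- map[ix + 1, iy, iz]
  c010 <- map[ix, iy + 1, iz]; c110 <- map[ix + 1, iy + 1, iz]
  c001 <- map[ix, iy, iz + 1]; c101 <- map[ix + 1, iy, iz + 1]
  c011 <- map[ix, iy + 1, iz + 1]; c111 <- map[ix + 1, iy + 1, iz + 1]
  c00 <- c000 * (1 - u[1]) + c100 * u[1]
  c10 <- c010 * (1 - u[1]) + c110 * u[1]
  c01 <- c001 * (1 - u[1]) + c101 * u[1]
  c11 <- c011 * (1 - u[1]) + c111 * u[1]
  (c00 * (1 - u[2]) + c10 * u[2]) * (1 - u[3]) +
    (c01 * (1 - u[2]) + c11 * u[2]) * u[3]
}

#' Positional restraint
#'
#' A quadratic penalty `weight * ||atom - target||^2` added to the engine
#' score during conformation selection. The default weight 0.25
#' kcal/(mol A^2) penalises a squared displacement of 10 A^2 by 2.5
#' kcal/mol.
#'
#' @param atom_name ligand atom name (as in the input structure file).
#' @param target desired location, length-3, Angstrom.
#' @param weight kcal/(mol A^2), default 0.25.
#' @return object of class `restraint`.
#' @export
restraint <- function(atom_name, target, weight = 0.25) {
  stopifnot(length(target) == 3, weight >= 0)
  structure(list(atom_name = atom_name, target = as.numeric(target),
                 weight = weight), class = "restraint")
}

#' Resolve a restraint to a unique ligand atom
#' @param restraint a `restraint`.
#' @param ligand a `ligand`.
#' @return the restraint with `$atom_index` set.
#' @export
resolve_restraint <- function(restraint, ligand) {
  hit <- which(ligand$atoms$name == restraint$atom_name)
  if (length(hit) == 0)
    stop("restraint atom '", restraint$atom_name, "' not found; atoms are: ",
         paste(ligand$atoms$name, collapse = ", "))
  if (length(hit) > 1)
    stop("restraint atom name '", restraint$atom_name, "' is ambiguous (",
         length(hit), " matches)")
  restraint$atom_index <- hit
  restraint
}

#' Restrained selection score
#'
#' Adds the positional-restraint penalty to an engine score:
#' `weight * D_a + s_ad`, with `D_a` the squared Euclidean distance of the
#' restrained atom from its desired location.
#'
#' @param s_ad engine score, kcal/mol.
#' @param atom_coords current coordinates of the restrained atom (length 3).
#' @param restraint a `restraint`.
#' @return kcal/mol.
#' @export
restrained_score <- function(s_ad, atom_coords, restraint) {
  restraint$weight * sum((atom_coords - restraint$target)^2) + s_ad
}
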
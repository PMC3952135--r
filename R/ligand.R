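# Atom typing, hydrogen-bond roles and rotatable-bond detection.
#
# Typing table (fixed, documented): the smallest set of tokens supporting the
# scoring field and the donor/acceptor bookkeeping --
#   C  aliphatic carbon        A  aromatic carbon
#   N  (unused; all nitrogens are typed NA)   NA nitrogen acceptor
#   O  (unused)                OA oxygen acceptor
#   S  (unused)                SA sulfur acceptor
#   H  apolar hydrogen         HD polar hydrogen (bonded to N/O/S)
#   F, Cl, Br, I halogens; P phosphorus.
# Donors are N/O/S heavy atoms bearing at least one polar hydrogen; acceptors
# are the NA/OA/SA types. An atom can be both (e.g. hydroxyl oxygen).

ligand_graph <- function(ligand) {
  igraph::add_edges(igraph::make_empty_graph(nrow(ligand$atoms),
                                             directed = FALSE),
                    rbind(ligand$bonds$a, ligand$bonds$b))
}

#' Assign atom types and hydrogen-bond roles
#'
#' Applies the package's fixed typing table: carbons are `A` when aromatic
#' (SYBYL `.ar` atom or bond type) and `C` otherwise; N/O/S become the
#' acceptor types `NA`/`OA`/`SA`; hydrogens bonded to N/O/S become `HD`;
#' halogens and P keep their element symbol. Hydrogen-bond roles: donor =
#' N/O/S with an attached polar H, acceptor = `NA`/`OA`/`SA`, `both` when
#' both apply.
#'
#' @param ligand a `ligand`.
#' @return the ligand with `atom_type` and `hbond_role` columns filled.
#' @export
assign_atom_types <- function(ligand) {
  a <- ligand$atoms; b <- ligand$bonds
  n <- nrow(a)
  nbrs <- vector("list", n)
  for (i in seq_len(nrow(b))) {
    nbrs[[b$a[i]]] <- c(nbrs[[b$a[i]]], b$b[i])
    nbrs[[b$b[i]]] <- c(nbrs[[b$b[i]]], b$a[i])
  }
  aromatic <- rep(FALSE, n)
  if (!is.null(a$mol2_type)) aromatic <- grepl("\\.ar$", a$mol2_type)
  ar_bonds <- which(b$mol2_type == "ar")
  aromatic[unique(c(b$a[ar_bonds], b$b[ar_bonds]))] <- TRUE

  type <- character(n)
  for (i in seq_len(n)) {
    el <- a$element[i]
    type[i] <- switch(el,
      C = if (aromatic[i]) "A" else "C",
      N = "NA", O = "OA", S = "SA",
      H = {
        heavy_nb <- a$element[nbrs[[i]]]
        if (any(heavy_nb %in% c("N", "O", "S"))) "HD" else "H"
      },
      P = "P",
      F = "F", Cl = "Cl", Br = "Br", I = "I",
      stop("ligand atom ", i, " ('", a$name[i], "'): element '", el,
           "' not in the typing table"))
  }
  role <- rep("none", n)
  acceptor <- type %in% c("NA", "OA", "SA")
  donor <- vapply(seq_len(n), function(i) {
    a$element[i] %in% c("N", "O", "S") &&
      any(type[nbrs[[i]]] == "HD" & a$element[nbrs[[i]]] == "H")
  }, logical(1))
  role[acceptor] <- "acceptor"
  role[donor] <- "donor"
  role[acceptor & donor] <- "both"
  ligand$atoms$atom_type <- type
  ligand$atoms$hbond_role <- role
  ligand
}

#' Flag rotatable bonds
#'
#' A bond is rotatable iff it is a single bond (SYBYL type `1`), lies in no
#' ring, both endpoints are heavy atoms with at least two heavy-atom
#' neighbours (so rotating it moves more than hydrogens), and it is not an
#' amide C-N (SYBYL `am`, or a single C-N bond whose carbon is double-bonded
#' to an oxygen). Ring membership is detected as non-bridge edges of the
#' bond graph.
#'
#' @param ligand a `ligand` (types assigned).
#' @return the ligand with the `rotatable` logical column set.
#' @export
detect_rotatable_bonds <- function(ligand) {
  a <- ligand$atoms; b <- ligand$bonds
  g <- ligand_graph(ligand)
  bridge_eids <- as.integer(igraph::bridges(g))
  in_ring <- !(seq_len(nrow(b)) %in% bridge_eids)

  heavy <- a$element != "H"
  n_heavy_nb <- integer(nrow(a))
  for (i in seq_len(nrow(b))) {
    if (heavy[b$b[i]]) n_heavy_nb[b$a[i]] <- n_heavy_nb[b$a[i]] + 1L
    if (heavy[b$a[i]]) n_heavy_nb[b$b[i]] <- n_heavy_nb[b$b[i]] + 1L
  }

  # carbons double-bonded to oxygen (for amide detection)
  carbonyl_c <- rep(FALSE, nrow(a))
  dbl <- which(b$mol2_type == "2")
  for (i in dbl) {
    p <- b$a[i]; q <- b$b[i]
    if (a$element[p] == "C" && a$element[q] == "O") carbonyl_c[p] <- TRUE
    if (a$element[q] == "C" && a$element[p] == "O") carbonyl_c[q] <- TRUE
  }

  rot <- logical(nrow(b))
  for (i in seq_len(nrow(b))) {
    p <- b$a[i]; q <- b$b[i]
    if (b$mol2_type[i] != "1") next
    if (in_ring[i]) next
    if (!heavy[p] || !heavy[q]) next
    if (n_heavy_nb[p] < 2 || n_heavy_nb[q] < 2) next
    amide <- (a$element[p] == "C" && a$element[q] == "N" && carbonyl_c[p]) ||
             (a$element[q] == "C" && a$element[p] == "N" && carbonyl_c[q])
    if (amide) next
    rot[i] <- TRUE
  }
  # SYBYL 'am' bonds are never rotatable (already excluded by type != "1")
  ligand$bonds$rotatable <- rot
  ligand
}

#' Count hydrogen-bond donors and acceptors in an atom set
#'
#' Donors and acceptors are counted separately and summed; an atom that is
#' both contributes 2.
#'
#' @param ligand a `ligand`.
#' @param atom_idx atom indices (default: all).
#' @return integer count.
#' @export
count_hbond_capacity <- function(ligand, atom_idx = ligand$atoms$index) {
  role <- ligand$atoms$hbond_role[atom_idx]
  sum(role %in% c("donor", "both")) + sum(role %in% c("acceptor", "both"))
}
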
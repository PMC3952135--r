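# Torsion tree: rooted tree whose nodes are rigid atom groups and whose
# edges are rotatable bonds, ranked by breadth-first visit order. The root
# node holds the root atom plus everything reachable through non-rotatable
# bonds; the node across an edge holds the atoms moved directly by rotation
# about that edge's bond.

#' Build a torsion tree
#'
#' Rigid groups are the connected components of the bond graph with the
#' rotatable bonds removed. The tree is rooted at the group containing
#' `root_atom`; edges (rotatable bonds) are ranked 1..n by breadth-first
#' visit order, children visited in ascending index of the child-side bond
#' atom (a fixed, documented tie-break).
#'
#' @param ligand a `ligand` with rotatable flags set.
#' @param root_atom atom index of the root.
#' @return an object of class `torsion_tree`.
#' @export
build_torsion_tree <- function(ligand, root_atom) {
  a <- ligand$atoms; b <- ligand$bonds
  if (!root_atom %in% a$index) stop("root atom ", root_atom, " does not exist")
  rot <- which(b$rotatable)
  # rigid groups: components after deleting rotatable bonds
  g <- ligand_graph(ligand)
  g_rigid <- igraph::delete_edges(g, rot)
  grp <- igraph::components(g_rigid)$membership
  root_grp <- grp[root_atom]

  # group adjacency through rotatable bonds
  edge_tab <- data.frame(bond_idx = rot,
                         ga = grp[b$a[rot]], gb = grp[b$b[rot]],
                         stringsAsFactors = FALSE)

  n_grp <- max(grp)
  visited <- rep(FALSE, n_grp); visited[root_grp] <- TRUE
  depth <- rep(NA_integer_, n_grp); depth[root_grp] <- 0L
  queue <- root_grp
  edges <- data.frame(rank = integer(0), a = integer(0), b = integer(0),
                      depth = integer(0), parent_rank = integer(0),
                      bond_idx = integer(0))
  grp_edge_rank <- rep(0L, n_grp)  # rank of the edge entering each group
  next_rank <- 1L
  while (length(queue) > 0) {
    cur <- queue[1]; queue <- queue[-1]
    inc <- which((edge_tab$ga == cur & !visited[edge_tab$gb]) |
                 (edge_tab$gb == cur & !visited[edge_tab$ga]))
    if (length(inc) == 0) next
    # orient each edge parent -> child and sort by child-side atom index
    child_atom <- integer(length(inc)); parent_atom <- integer(length(inc))
    child_grp <- integer(length(inc))
    for (k in seq_along(inc)) {
      e <- inc[k]; bi <- edge_tab$bond_idx[e]
      if (edge_tab$ga[e] == cur) {
        parent_atom[k] <- b$a[bi]; child_atom[k] <- b$b[bi]
        child_grp[k] <- edge_tab$gb[e]
      } else {
        parent_atom[k] <- b$b[bi]; child_atom[k] <- b$a[bi]
        child_grp[k] <- edge_tab$ga[e]
      }
    }
    ord <- order(child_atom)
    for (k in ord) {
      cg <- child_grp[k]
      if (visited[cg]) next  # possible only in rings, which cannot occur here
      visited[cg] <- TRUE
      depth[cg] <- depth[cur] + 1L
      grp_edge_rank[cg] <- next_rank
      edges <- rbind(edges, data.frame(
        rank = next_rank, a = parent_atom[k], b = child_atom[k],
        depth = depth[cg], parent_rank = grp_edge_rank[cur],
        bond_idx = edge_tab$bond_idx[inc[k]]))
      next_rank <- next_rank + 1L
      queue <- c(queue, cg)
    }
  }
  n_bonds <- nrow(edges)
  stopifnot(n_bonds == length(rot))

  root_atoms <- sort(a$index[grp == root_grp])
  node_atoms <- lapply(seq_len(n_bonds), function(r) {
    sort(a$index[grp == grp[edges$b[r]]])
  })
  # moving sets: node atoms plus all descendant nodes' atoms
  moving_atoms <- node_atoms
  if (n_bonds > 1) {
    for (r in rev(seq_len(n_bonds))) {
      pr <- edges$parent_rank[r]
      if (pr > 0) moving_atoms[[pr]] <- sort(c(moving_atoms[[pr]], moving_atoms[[r]]))
    }
  }
  structure(list(ligand = ligand, root_atom = root_atom, n_bonds = n_bonds,
                 root_atoms = root_atoms, edges = edges,
                 node_atoms = node_atoms, moving_atoms = moving_atoms),
            class = "torsion_tree")
}

#' @export
print.torsion_tree <- function(x, ...) {
  cat("torsion tree: root atom ", x$root_atom, ", ", x$n_bonds,
      " rotatable bonds, root node of ", length(x$root_atoms), " atoms\n",
      sep = "")
  invisible(x)
}

#' Select the root atom
#'
#' Chooses the root so that the initial fragment (root node plus the nodes
#' of the bonds ranked 1..`fragment_size`) contains the highest combined
#' count of hydrogen-bond donors and acceptors. Ties are broken by smaller
#' maximum tree depth, then by lower atom index.
#'
#' @param ligand a `ligand` with rotatable flags set.
#' @param fragment_size number of top-ranked bonds in the initial fragment
#'   (default 6).
#' @return atom index of the selected root.
#' @export
select_root_atom <- function(ligand, fragment_size = 6) {
  heavy <- ligand$atoms$index[ligand$atoms$element != "H"]
  if (length(heavy) == 0) stop("ligand has no heavy atoms")
  best <- NULL
  for (cand in heavy) {
    tree <- build_torsion_tree(ligand, cand)
    ranks <- seq_len(min(fragment_size, tree$n_bonds))
    frag_atoms <- unique(c(tree$root_atoms, unlist(tree$node_atoms[ranks])))
    cnt <- count_hbond_capacity(ligand, frag_atoms)
    dep <- if (tree$n_bonds > 0) max(tree$edges$depth) else 0L
    key <- c(cnt, -dep, -cand)  # maximise count, then smaller depth, lower index
    if (is.null(best) || key[1] > best$key[1] ||
        (key[1] == best$key[1] && key[2] > best$key[2]) ||
        (key[1] == best$key[1] && key[2] == best$key[2] && key[3] > best$key[3])) {
      best <- list(atom = cand, key = key)
    }
  }
  best$atom
}

#' Extract a docking fragment
#'
#' The fragment holds the root-node atoms plus the node atoms of every bond
#' ranked up to `max_rank`. Bonds in `active_ranks` are sampled; the
#' remaining ranks up to `max_rank` are frozen at the parent conformation's
#' angles.
#'
#' @param tree a `torsion_tree`.
#' @param max_rank highest bond rank included in the fragment.
#' @param active_ranks ranks whose torsions the engine samples
#'   (subset of `1:max_rank`).
#' @param parent parent `conformation` supplying frozen angles, or `NULL`
#'   for the initial fragment (frozen set must then be empty).
#' @return an object of class `fragment`.
#' @export
extract_fragment <- function(tree, max_rank, active_ranks, parent = NULL) {
  if (max_rank > tree$n_bonds) stop("max_rank exceeds number of rotatable bonds")
  active_ranks <- sort(as.integer(active_ranks))
  if (length(active_ranks) > 0 && any(active_ranks > max_rank | active_ranks < 1))
    stop("active_ranks exceed max_rank: contract violation")
  frozen_ranks <- setdiff(seq_len(max_rank), active_ranks)
  if (length(frozen_ranks) > 0 && is.null(parent))
    stop("frozen ranks require a parent conformation")
  frozen_angles <- numeric(0)
  if (length(frozen_ranks) > 0) {
    frozen_angles <- parent$torsions[as.character(frozen_ranks)]
    if (anyNA(frozen_angles))
      stop("parent conformation missing torsion(s) ",
           paste(frozen_ranks[is.na(frozen_angles)], collapse = ", "),
           ": contract violation")
  }
  atom_subset <- sort(unique(c(tree$root_atoms,
                               unlist(tree$node_atoms[seq_len(max_rank)]))))
  structure(list(tree = tree, max_rank = as.integer(max_rank),
                 active_ranks = active_ranks, frozen_ranks = frozen_ranks,
                 frozen_angles = frozen_angles, atom_subset = atom_subset,
                 parent = parent),
            class = "fragment")
}

#' Full-ligand fragment (all bonds active)
#' @param tree a `torsion_tree`.
#' @return `fragment` spanning the whole ligand.
#' @export
full_fragment <- function(tree) {
  extract_fragment(tree, tree$n_bonds, seq_len(tree$n_bonds))
}
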
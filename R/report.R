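# Pose analysis: RMSD against a reference, score/RMSD ranking, greedy
# leader clustering, the six-conformation report, benchmark metrics, and
# multi-model structure output.

#' Root-mean-square deviation between two poses
#'
#' Fixed identity atom correspondence, no superposition (both poses share
#' the receptor frame). Callers pass heavy-atom coordinates.
#'
#' @param a,b n x 3 coordinate matrices.
#' @return Angstrom.
#' @export
compute_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)))
    stop("atom-count mismatch: ", nrow(a), " vs ", nrow(b))
  sqrt(mean(rowSums((a - b)^2)))
}

heavy_rows <- function(ligand, atom_idx) {
  which(ligand$atoms$element[atom_idx] != "H")
}

# heavy-atom RMSD of a conformation against reference full-ligand coords
conf_rmsd <- function(conf, reference, ligand) {
  h <- heavy_rows(ligand, conf$atom_idx)
  compute_rmsd(conf$coords[h, , drop = FALSE],
               reference[conf$atom_idx[h], , drop = FALSE])
}

#' Rank a docked pool by score and by RMSD
#'
#' Lower scores rank higher. With a reference pose, a parallel RMSD
#' ranking is produced; `top_scoring` and `top_rmsd` are the respective
#' list heads.
#'
#' @param pool list of scored conformations.
#' @param reference optional reference coordinates (full-ligand n x 3
#'   matrix) or `NULL`.
#' @param ligand the `ligand` (needed to restrict RMSD to heavy atoms).
#' @return object of class `ranked_results` with a `table` data.frame
#'   (`id, s_ad, s_total, rmsd`) and orderings `by_score` / `by_rmsd`.
#' @export
rank_results <- function(pool, reference = NULL, ligand = NULL) {
  tab <- pool_table(pool)
  tab$rmsd <- NA_real_
  if (!is.null(reference)) {
    stopifnot(!is.null(ligand))
    tab$rmsd <- vapply(pool, conf_rmsd, 0, reference = reference,
                       ligand = ligand)
  }
  by_score <- order(tab$s_total, tab$s_ad, tab$id)
  by_rmsd <- if (!is.null(reference)) order(tab$rmsd, tab$s_total, tab$id)
             else integer(0)
  structure(list(table = tab, by_score = by_score, by_rmsd = by_rmsd,
                 top_scoring = pool[[by_score[1]]],
                 top_rmsd = if (length(by_rmsd) > 0) pool[[by_rmsd[1]]] else NULL,
                 top_scoring_id = by_score[1],
                 top_rmsd_id = if (length(by_rmsd) > 0) by_rmsd[1] else NA_integer_),
            class = "ranked_results")
}

#' @export
print.ranked_results <- function(x, ...) {
  cat("ranked results over ", nrow(x$table), " poses; top-scoring id ",
      x$top_scoring_id, " (", sprintf("%.3f", x$table$s_total[x$top_scoring_id]),
      " kcal/mol)", sep = "")
  if (!is.na(x$top_rmsd_id))
    cat("; top-RMSD id ", x$top_rmsd_id, " (",
        sprintf("%.3f", x$table$rmsd[x$top_rmsd_id]), " A)", sep = "")
  cat("\n")
  invisible(x)
}

#' Greedy leader clustering of docked poses
#'
#' Poses are visited in ascending total score (ties by engine score, then
#' pool index); a pose joins the first existing cluster whose
#' representative lies within `cutoff` heavy-atom RMSD, otherwise it founds
#' a new cluster. Representatives are therefore the lowest-scoring members.
#' Clusters are ordered by descending size, ties by better representative
#' score.
#'
#' @param pool list of scored conformations.
#' @param cutoff RMSD cutoff, Angstrom (default 2.0).
#' @param ligand the `ligand`.
#' @return object of class `cluster_set`: list of
#'   `list(representative_id, member_ids)` plus the cutoff; ids index the
#'   input pool.
#' @export
cluster_poses <- function(pool, cutoff = 2.0, ligand = NULL) {
  stopifnot(length(pool) > 0, !is.null(ligand))
  tab <- pool_table(pool)
  visit <- order(tab$s_total, tab$s_ad, tab$id)
  h <- heavy_rows(ligand, pool[[1]]$atom_idx)
  hx <- lapply(pool, function(p) p$coords[h, , drop = FALSE])
  reps <- integer(0)
  members <- list()
  for (i in visit) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      if (compute_rmsd(hx[[i]], hx[[reps[ci]]]) <= cutoff) {
        members[[ci]] <- c(members[[ci]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      members[[length(reps)]] <- i
    }
  }
  sizes <- lengths(members)
  ord <- order(-sizes, tab$s_total[reps], seq_along(reps))
  clusters <- lapply(ord, function(ci)
    list(representative_id = reps[ci], member_ids = members[[ci]]))
  structure(list(clusters = clusters, cutoff = cutoff), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster set: ", length(x$clusters), " clusters at cutoff ",
      x$cutoff, " A; sizes ",
      paste(vapply(x$clusters, function(c) length(c$member_ids), 0L),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Six-conformation report
#'
#' The three lowest-scoring poses plus the representatives of the three
#' largest clusters (fewer when the pool or cluster set is smaller).
#' Overlap between the two sections is permitted and flagged. Poses with
#' heavy-atom RMSD <= 4 Angstrom to a supplied reference are annotated as
#' acceptably accurate.
#'
#' @param pool list of scored conformations.
#' @param cutoff clustering cutoff, Angstrom.
#' @param ligand the `ligand`.
#' @param reference optional reference coordinates for RMSD annotation.
#' @return data.frame: `section` ("lowest_score"/"cluster_rep"), `pool_id`,
#'   `s_ad`, `s_total`, `cluster`, `cluster_size`, `duplicate`, `rmsd`,
#'   `acceptable`.
#' @export
report_top6 <- function(pool, cutoff = 2.0, ligand = NULL, reference = NULL) {
  stopifnot(length(pool) >= 1)
  tab <- pool_table(pool)
  by_score <- order(tab$s_total, tab$s_ad, tab$id)
  low <- by_score[seq_len(min(3, length(pool)))]
  cs <- cluster_poses(pool, cutoff, ligand)
  reps <- vapply(cs$clusters, `[[`, 0L, "representative_id")
  sizes <- vapply(cs$clusters, function(c) length(c$member_ids), 0L)
  nrep <- min(3, length(reps))
  rep_ids <- reps[seq_len(nrep)]
  # cluster id of every pool member
  cl_of <- integer(length(pool))
  for (ci in seq_along(cs$clusters)) cl_of[cs$clusters[[ci]]$member_ids] <- ci
  ids <- c(low, rep_ids)
  out <- data.frame(
    section = c(rep("lowest_score", length(low)), rep("cluster_rep", nrep)),
    pool_id = ids,
    s_ad = tab$s_ad[ids], s_total = tab$s_total[ids],
    cluster = cl_of[ids],
    cluster_size = sizes[cl_of[ids]],
    duplicate = duplicated(ids),
    stringsAsFactors = FALSE)
  out$rmsd <- NA_real_
  if (!is.null(reference) && !is.null(ligand))
    out$rmsd <- vapply(pool[ids], conf_rmsd, 0, reference = reference,
                       ligand = ligand)
  out$acceptable <- !is.na(out$rmsd) & out$rmsd <= 4.0
  out
}

#' Benchmark metrics over complexes and repeats
#'
#' Per complex, `r_cs` is the top-scoring pose's RMSD averaged over the
#' repeated docking experiments and `r_cr` the top-RMSD pose's RMSD
#' averaged the same way; `ra_cs`/`ra_cr` average those over complexes.
#' Repeats without a reference RMSD are dropped with a warning.
#'
#' @param results data.frame with columns `complex`, `repeat_id`,
#'   `rmsd_top_scoring`, `rmsd_top_rmsd` (one row per repeat), e.g. built
#'   from [rank_results()] tables.
#' @return list with `per_complex` (data.frame `complex, r_cs, r_cr`) and
#'   scalars `ra_cs`, `ra_cr` (Angstrom).
#' @export
benchmark_metrics <- function(results) {
  need <- c("complex", "repeat_id", "rmsd_top_scoring", "rmsd_top_rmsd")
  stopifnot(all(need %in% names(results)))
  bad <- is.na(results$rmsd_top_scoring) | is.na(results$rmsd_top_rmsd)
  if (any(bad)) {
    warning("dropping ", sum(bad), " repeat(s) without reference RMSD")
    results <- results[!bad, , drop = FALSE]
  }
  if (nrow(results) == 0) stop("no repeats with reference RMSD")
  per <- do.call(rbind, lapply(split(results, results$complex), function(d) {
    data.frame(complex = d$complex[1],
               r_cs = mean(d$rmsd_top_scoring),
               r_cr = mean(d$rmsd_top_rmsd),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  list(per_complex = per, ra_cs = mean(per$r_cs), ra_cr = mean(per$r_cr))
}

#' Write docked poses to a multi-model PDB (plus TSV/JSON tables)
#'
#' Each pose becomes one MODEL block of HETATM records with its score in a
#' REMARK line; a machine-readable table of scores (and RMSDs/cluster ids
#' when provided) is written next to it as TSV and JSON.
#'
#' @param poses list of scored conformations sharing one ligand topology.
#' @param path output PDB path; the tables use the same stem with `.tsv` /
#'   `.json` extensions.
#' @param ligand the `ligand` supplying names and elements.
#' @param table optional data.frame of per-pose annotations (e.g. from
#'   [report_top6()]); defaults to the pool table.
#' @return invisibly a character vector of the files written.
#' @export
write_poses <- function(poses, path, ligand, table = NULL) {
  if (length(poses) == 0) stop("empty pose list: nothing to write")
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (m in seq_along(poses)) {
    p <- poses[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(sprintf("REMARK   1 SCORE %.4f KCAL/MOL",
                       if (is.null(p$s_total)) p$s_ad else p$s_total), con)
    a <- ligand$atoms[p$atom_idx, , drop = FALSE]
    writeLines(sprintf(
      "HETATM%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)), substr(a$name, 1, 4), "LIG", 1L,
      p$coords[, 1], p$coords[, 2], p$coords[, 3], 1, 0,
      toupper(a$element)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  tab <- if (is.null(table)) pool_table(poses) else table
  stem <- sub("\\.pdb$", "", path)
  tsv <- paste0(stem, ".tsv"); jsn <- paste0(stem, ".json")
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(tab, jsn, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(c(path, tsv, jsn))
}
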
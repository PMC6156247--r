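#' Select the best pose of a compound against one target
#'
#' Mirrors the "best of N binding poses" step of the screening cascade: the
#' pose with the maximal binding score wins; ties are broken by the larger
#' (less negative) crash penalty, then by the lower pose rank.
#'
#' @param poses A `pose_table` (or plain data frame) holding the poses of a
#'   single compound x target combination.
#' @return The winning pose as a one-row data frame.
#' @export
best_pose <- function(poses) {
  if (is.null(poses) || nrow(poses) == 0)
    stop("best_pose() needs at least one pose", call. = FALSE)
  if (length(unique(poses$compound_id)) > 1L ||
      length(unique(poses$target_id)) > 1L)
    stop("best_pose() expects poses of a single compound x target",
         call. = FALSE)
  ord <- order(-poses$bs, -poses$crash, poses$pose_rank)
  poses[ord[1L], , drop = FALSE]
}

#' Best-pose binding scores per compound and target
#'
#' Collapses a pose table to one best-pose binding score per
#' (compound, target), returned wide: one row per compound, one numeric
#' column per target.
#'
#' @param poses A `pose_table` in either dialect.
#' @return A data frame with column `compound_id` plus one BS column per
#'   target.
#' @export
summarize_best_scores <- function(poses) {
  if (attr(poses, "dialect") %||% "flags" == "coords") {
    # one row per pose is enough for scores
    key <- !duplicated(paste(poses$compound_id, poses$target_id,
                             poses$pose_rank, sep = "\r"))
    poses <- poses[key, , drop = FALSE]
  }
  sp <- split(poses, list(poses$compound_id, poses$target_id), drop = TRUE)
  best <- do.call(rbind, lapply(sp, function(p) {
    b <- best_pose(p)
    data.frame(compound_id = b$compound_id, target_id = b$target_id,
               bs = b$bs, stringsAsFactors = FALSE)
  }))
  wide <- stats::reshape(best, idvar = "compound_id", timevar = "target_id",
                         direction = "wide")
  names(wide) <- sub("^bs\\.", "", names(wide))
  rownames(wide) <- NULL
  wide[order(wide$compound_id), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rank compounds by best-pose binding score and keep the top k
#'
#' Descending by the target's best BS; ties are resolved by compound id so
#' the ordering is reproducible.
#'
#' @param summaries Wide summary from [summarize_best_scores()].
#' @param target Target column to rank on.
#' @param k Number of compounds to keep (>= 1). If `k` exceeds the number of
#'   compounds, all are returned with a notice.
#' @return The top-k rows of `summaries`, ordered.
#' @export
rank_top_k <- function(summaries, target, k) {
  stopifnot(k >= 1)
  if (!target %in% names(summaries))
    stop("no best-score column for target '", target, "'", call. = FALSE)
  bs <- summaries[[target]]
  if (anyNA(bs))
    stop("missing best score for target '", target, "' in ",
         sum(is.na(bs)), " compound(s)", call. = FALSE)
  ord <- order(-bs, summaries$compound_id)
  if (k > nrow(summaries)) {
    message("rank_top_k: k = ", k, " exceeds the ", nrow(summaries),
            " available compounds; returning all")
    k <- nrow(summaries)
  }
  summaries[ord[seq_len(k)], , drop = FALSE]
}

#' Similarity / molecular-weight filter
#'
#' Keeps compounds whose maximal similarity over the reference compounds is
#' at least `min_sim` and (when `min_mw` is given) whose molecular weight is
#' at least `min_mw` g/mol. Both thresholds are inclusive. Compounds lacking
#' every requested similarity value are excluded with a warning.
#'
#' @param compounds A `compound_table`.
#' @param reference_ids Reference compound ids; similarity is read from the
#'   `sim_<ref>` columns.
#' @param min_sim Minimal similarity in [0,1] (default 0.5).
#' @param min_mw Minimal molecular weight in g/mol, or `NULL` for no MW rule.
#' @return The surviving rows of `compounds`.
#' @export
similarity_filter <- function(compounds, reference_ids, min_sim = 0.5,
                              min_mw = NULL) {
  cols <- paste0("sim_", reference_ids)
  cols <- cols[cols %in% names(compounds)]
  if (!length(cols))
    stop("no sim_<ref> column found for the requested references",
         call. = FALSE)
  sim_mat <- as.matrix(compounds[, cols, drop = FALSE])
  max_sim <- apply(sim_mat, 1L, function(r)
    if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  if (anyNA(max_sim))
    warning("excluding ", sum(is.na(max_sim)),
            " compound(s) without any similarity value", call. = FALSE)
  keep <- !is.na(max_sim) & max_sim >= min_sim
  if (!is.null(min_mw)) keep <- keep & compounds$mw >= min_mw
  compounds[keep, , drop = FALSE]
}

#' Comparative binding affinity value (CBAV)
#'
#' Difference of best-pose binding scores, reference target minus the other
#' target. CBAV >= 0 means the compound binds the reference at least as well;
#' the statistic is antisymmetric: `cbav(a, b) == -cbav(b, a)`.
#'
#' @param best_bs_ref Best-pose BS on the reference target.
#' @param best_bs_other Best-pose BS on the other target.
#' @return A numeric difference (vectorized).
#' @export
cbav <- function(best_bs_ref, best_bs_other) {
  if (any(!is.finite(best_bs_ref)) || any(!is.finite(best_bs_other)))
    stop("cbav() needs finite binding scores", call. = FALSE)
  best_bs_ref - best_bs_other
}

#' CBAV filter against every non-reference target
#'
#' Keeps compounds with `cbav(reference, t) >= threshold` for every other
#' target `t` in the summary (threshold inclusive). Compounds with a missing
#' best score on any target are excluded with a warning.
#'
#' @param summaries Wide summary from [summarize_best_scores()].
#' @param reference_target Reference target column name.
#' @param threshold Minimal CBAV (default 0).
#' @return Surviving rows, with one `cbav_<target>` column appended per
#'   non-reference target.
#' @export
cbav_filter <- function(summaries, reference_target, threshold = 0) {
  targets <- setdiff(names(summaries), c("compound_id", reference_target))
  targets <- targets[!startsWith(targets, "cbav_") &
                       !startsWith(targets, "lbpv_")]
  if (!reference_target %in% names(summaries))
    stop("reference target '", reference_target, "' not in summaries",
         call. = FALSE)
  ref <- summaries[[reference_target]]
  keep <- rep(TRUE, nrow(summaries))
  for (t in targets) {
    v <- ref - summaries[[t]]
    summaries[[paste0("cbav_", t)]] <- v
    keep <- keep & !is.na(v) & v >= threshold
  }
  n_missing <- sum(apply(is.na(summaries[, c(reference_target, targets),
                                         drop = FALSE]), 1L, any))
  if (n_missing)
    warning("excluding ", n_missing,
            " compound(s) with a missing best score", call. = FALSE)
  summaries[keep, , drop = FALSE]
}

#' Classify the pocket occupancy of a pose
#'
#' In the `flags` dialect the class is read from the precomputed
#' `occupies_py0` / `occupies_pyx` flags. In the `coords` dialect a pocket
#' counts as occupied when at least one heavy atom lies within the pocket
#' radius of its centroid (both pocket definitions required).
#'
#' @param pose One pose: a one-row flags data frame, or the atom rows of a
#'   single pose in the coords dialect.
#' @param pockets For coords: a list of two [pocket_definition()] objects
#'   (ids `pY0` and `pYX`).
#' @return One of `"PY0_ONLY"`, `"PYX_ONLY"`, `"BOTH"`, `"NEITHER"`.
#' @export
classify_pocket_occupancy <- function(pose, pockets = NULL) {
  if (all(c("occupies_py0", "occupies_pyx") %in% names(pose))) {
    p0 <- as.logical(pose$occupies_py0[1L])
    px <- as.logical(pose$occupies_pyx[1L])
  } else if (all(c("atom_x", "atom_y", "atom_z") %in% names(pose))) {
    if (is.null(pockets))
      stop("coords dialect needs pocket definitions", call. = FALSE)
    ids <- vapply(pockets, function(p) p$pocket_id, character(1))
    if (!all(c("pY0", "pYX") %in% ids))
      stop("pocket definitions must cover pY0 and pYX", call. = FALSE)
    xyz <- as.matrix(pose[, c("atom_x", "atom_y", "atom_z")])
    occupied <- function(pk) {
      d2 <- colSums((t(xyz) - pk$centroid)^2)
      any(d2 <= pk$radius^2)
    }
    p0 <- occupied(pockets[[match("pY0", ids)]])
    px <- occupied(pockets[[match("pYX", ids)]])
  } else {
    stop("pose carries neither occupancy flags nor atom coordinates",
         call. = FALSE)
  }
  if (p0 && px) "BOTH" else if (p0) "PY0_ONLY" else if (px) "PYX_ONLY"
  else "NEITHER"
}

#' Pocket classes for every pose of a table
#'
#' @param poses A `pose_table`.
#' @param pockets Pocket definitions (coords dialect only).
#' @return A data frame (compound_id, target_id, pose_rank, pocket_class)
#'   with one row per pose.
#' @export
classify_poses <- function(poses, pockets = NULL) {
  key <- paste(poses$compound_id, poses$target_id, poses$pose_rank,
               sep = "\r")
  sp <- split(seq_len(nrow(poses)), key)
  rows <- lapply(sp, function(i) {
    p <- poses[i, , drop = FALSE]
    data.frame(compound_id = p$compound_id[1L], target_id = p$target_id[1L],
               pose_rank = p$pose_rank[1L],
               pocket_class = classify_pocket_occupancy(p, pockets),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$compound_id, out$target_id, out$pose_rank), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ligand binding pose variation (LBPV)
#'
#' Fraction of a compound's top-ranked poses falling in a pocket class. High
#' values (0.8-1.0) indicate low conformer diversity, i.e. specific binding;
#' low values (0-0.2) indicate high conformer diversity. The denominator is
#' the number of poses supplied (20 in a full re-screen run); fewer than 20
#' poses trigger a warning but are accepted.
#'
#' `cls` may be one of the four exclusive classes (`"PY0_ONLY"`,
#' `"PYX_ONLY"`, `"BOTH"`, `"NEITHER"`) or the inclusive any-occupancy
#' classes `"PY0"` / `"PYX"` (a pose occupying both pockets counts for both).
#'
#' @param poses A flags-dialect pose table for a single compound x target, or
#'   a character vector of pocket classes (from [classify_poses()]).
#' @param cls Pocket class to count.
#' @return A fraction in [0,1].
#' @export
lbpv <- function(poses, cls = c("BOTH", "PY0", "PYX", "NEITHER",
                                "PY0_ONLY", "PYX_ONLY")) {
  cls <- match.arg(cls)
  if (is.character(poses)) {
    classes <- poses
  } else {
    if (nrow(poses) == 0)
      stop("lbpv() needs at least one pose", call. = FALSE)
    classes <- vapply(seq_len(nrow(poses)), function(i)
      classify_pocket_occupancy(poses[i, , drop = FALSE]), character(1))
  }
  n <- length(classes)
  if (n == 0) stop("lbpv() needs at least one pose", call. = FALSE)
  if (n > 20)
    stop("lbpv() is defined on at most 20 top-ranked poses", call. = FALSE)
  if (n < 20 && !isTRUE(getOption("statscreen.quiet_lbpv", FALSE)))
    warning("lbpv() computed on ", n, " poses (fewer than the usual 20)",
            call. = FALSE)
  hit <- switch(cls,
    PY0 = classes %in% c("PY0_ONLY", "BOTH"),
    PYX = classes %in% c("PYX_ONLY", "BOTH"),
    classes == cls)
  sum(hit) / n
}

#' Mutant binding-impairment call from stability values
#'
#' Computes ddG0 = dG0(mutant) - dG0(wild type) for the same target and
#' ligand. Because more negative dG0 means a more stable complex, a positive
#' ddG0 flags the mutation as impairing binding.
#'
#' @param wt,mut One-row slices of a [read_stability_table()] data frame (or
#'   lists with `target_id`, `ligand_id`, `variant`, `dg0_kcal_mol`).
#' @return A list with `ddg0` (kcal/mol) and `impaired` (logical).
#' @export
ddg0_impairment <- function(wt, mut) {
  if (wt$target_id != mut$target_id || wt$ligand_id != mut$ligand_id)
    stop("wt and mutant records must share target and ligand", call. = FALSE)
  if (wt$variant != "wt")
    stop("first argument must be the wild-type record", call. = FALSE)
  ddg0 <- mut$dg0_kcal_mol - wt$dg0_kcal_mol
  list(ddg0 = ddg0, impaired = ddg0 > 0)
}

#' Run the six-step screening cascade
#'
#' Chains the cascade on a re-screen pose table: best-pose summarization,
#' top-k ranking on the reference target's binding score, similarity/MW
#' filtering, CBAV filtering against every other target, and pose-diversity
#' (LBPV) validation. Deterministic given its inputs.
#'
#' @param poses A flags-dialect `pose_table` covering all targets.
#' @param compounds A `compound_table` with `sim_<ref>` columns.
#' @param config A list: `reference_target`, `top_k`, `similarity_refs`,
#'   `min_sim` (default 0.5), `min_mw` (default 300, `NULL` to disable),
#'   `cbav_threshold` (default 0), `lbpv_class` (default `"BOTH"`),
#'   `lbpv_threshold` (default 0.8).
#' @return A `triage_report`: list with `stages` (name, parameters, n_in,
#'   n_out, survivors, exclusions), `summaries` (per-compound scores, CBAV
#'   and LBPV), and `final` (surviving compound ids).
#' @export
run_triage <- function(poses, compounds, config) {
  cfg <- utils::modifyList(list(min_sim = 0.5, min_mw = 300,
                                cbav_threshold = 0, lbpv_class = "BOTH",
                                lbpv_threshold = 0.8),
                           config)
  for (need in c("reference_target", "top_k", "similarity_refs"))
    if (is.null(cfg[[need]]))
      stop("triage config is missing '", need, "'", call. = FALSE)

  stages <- list()
  note_stage <- function(name, params, ids_in, ids_out) {
    stages[[length(stages) + 1L]] <<- list(
      name = name, parameters = params,
      n_in = length(ids_in), n_out = length(ids_out),
      survivors = ids_out,
      exclusions = setdiff(ids_in, ids_out))
    if (length(ids_in) > 0 && length(ids_out) == 0)
      message("triage: stage '", name, "' emptied the candidate set")
  }

  all_ids <- sort(unique(poses$compound_id))
  summ <- summarize_best_scores(poses)
  note_stage("best_pose_selection", list(), all_ids, summ$compound_id)

  ranked <- rank_top_k(summ, cfg$reference_target, cfg$top_k)
  note_stage("bs_ranking",
             list(target = cfg$reference_target, k = cfg$top_k),
             summ$compound_id, ranked$compound_id)

  comp <- compounds[compounds$compound_id %in% ranked$compound_id, ,
                    drop = FALSE]
  simk <- similarity_filter(comp, cfg$similarity_refs, cfg$min_sim,
                            cfg$min_mw)
  note_stage("similarity_mw_filter",
             list(refs = cfg$similarity_refs, min_sim = cfg$min_sim,
                  min_mw = cfg$min_mw),
             ranked$compound_id, simk$compound_id)

  sub <- summ[summ$compound_id %in% simk$compound_id, , drop = FALSE]
  cb <- cbav_filter(sub, cfg$reference_target, cfg$cbav_threshold)
  note_stage("cbav_filter",
             list(reference = cfg$reference_target,
                  threshold = cfg$cbav_threshold),
             sub$compound_id, cb$compound_id)

  # LBPV on the reference target's pose set of each CBAV survivor
  ref_poses <- poses[poses$target_id == cfg$reference_target &
                       poses$compound_id %in% cb$compound_id, , drop = FALSE]
  lb <- withr_quiet_lbpv(function() {
    vapply(split(ref_poses, ref_poses$compound_id),
           function(p) lbpv(p, cfg$lbpv_class), numeric(1))
  })
  lb_ids <- names(lb)[lb >= cfg$lbpv_threshold]
  cb[[paste0("lbpv_", cfg$lbpv_class)]] <-
    lb[match(cb$compound_id, names(lb))]
  note_stage("lbpv_filter",
             list(class = cfg$lbpv_class, threshold = cfg$lbpv_threshold,
                  target = cfg$reference_target),
             cb$compound_id, sort(lb_ids))

  structure(list(stages = stages, summaries = cb, final = sort(lb_ids),
                 config = cfg),
            class = "triage_report")
}

withr_quiet_lbpv <- function(f) {
  old <- options(statscreen.quiet_lbpv = TRUE)
  on.exit(options(old))
  f()
}

#' @export
print.triage_report <- function(x, ...) {
  cat("Virtual-screen triage report\n")
  cat(sprintf("  reference target: %s\n", x$config$reference_target))
  for (s in x$stages)
    cat(sprintf("  %-22s %4d -> %4d\n", s$name, s$n_in, s$n_out))
  cat("  final survivors:", if (length(x$final))
    paste(x$final, collapse = ", ") else "(none)", "\n")
  invisible(x)
}
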
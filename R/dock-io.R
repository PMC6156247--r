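#' Read a docking pose table
#'
#' Pose tables are TSV files with one row per pose (`flags` dialect) or one
#' row per heavy atom (`coords` dialect). Both dialects share the key columns
#' `compound_id`, `target_id`, `pose_rank`, `bs`, `crash`, `polar_score`.
#' The `flags` dialect adds the 0/1 columns `occupies_py0` and `occupies_pyx`
#' (pocket assignment precomputed upstream); the `coords` dialect adds
#' `atom_x`, `atom_y`, `atom_z` with the pose key repeated per atom.
#'
#' The `flags` dialect is canonical: the pose-diversity statistic
#' ([lbpv()]) is defined on pocket assignments, so any docking engine whose
#' poses can be assigned to the pTyr pocket (pY+0) and the hydrophobic
#' side-pocket (pY-X) can feed the triage cascade. Unknown extra columns are
#' preserved.
#'
#' @param path Path to a TSV file with a header row.
#' @param dialect Either `"flags"` (default) or `"coords"`.
#' @return A data frame of class `pose_table`, sorted by
#'   (compound_id, target_id, pose_rank), with attribute `dialect`.
#' @seealso [write_pose_table()], [best_pose()], [lbpv()]
#' @export
read_pose_table <- function(path, dialect = c("flags", "coords")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  as_pose_table(df, dialect = dialect)
}

#' Validate a data frame as a pose table
#'
#' @param df Data frame with pose-table columns (see [read_pose_table()]).
#' @param dialect `"flags"` or `"coords"`.
#' @return A validated, sorted `pose_table` data frame.
#' @export
as_pose_table <- function(df, dialect = c("flags", "coords")) {
  dialect <- match.arg(dialect)
  key_cols <- c("compound_id", "target_id", "pose_rank", "bs", "crash",
                "polar_score")
  dial_cols <- switch(dialect,
    flags  = c("occupies_py0", "occupies_pyx"),
    coords = c("atom_x", "atom_y", "atom_z"))
  missing <- setdiff(c(key_cols, dial_cols), names(df))
  if (length(missing))
    stop("pose table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (col in c("pose_rank", "bs", "crash", "polar_score", dial_cols)) {
    df[[col]] <- as.numeric(df[[col]])
    if (anyNA(df[[col]]))
      stop("non-numeric value in column '", col, "'", call. = FALSE)
  }
  if (nrow(df)) {
    if (any(df$pose_rank < 1 | df$pose_rank != round(df$pose_rank)))
      stop("pose_rank must be a positive integer", call. = FALSE)
    if (any(df$crash > 0))
      stop("crash must be <= 0 (it is a clash penalty); offending rows: ",
           paste(utils::head(which(df$crash > 0), 5), collapse = ", "),
           call. = FALSE)
    if (any(df$polar_score < 0))
      stop("polar_score must be >= 0", call. = FALSE)
    if (dialect == "flags") {
      if (!all(df$occupies_py0 %in% c(0, 1)) ||
          !all(df$occupies_pyx %in% c(0, 1)))
        stop("occupancy flags must be 0/1", call. = FALSE)
      key <- paste(df$compound_id, df$target_id, df$pose_rank, sep = "\r")
      if (anyDuplicated(key))
        stop("duplicate (compound_id, target_id, pose_rank) triples",
             call. = FALSE)
    } else {
      # one row per atom: the pose key legitimately repeats, but each pose
      # must carry consistent scores
      key <- paste(df$compound_id, df$target_id, df$pose_rank, sep = "\r")
      sc  <- paste(df$bs, df$crash, df$polar_score)
      if (any(tapply(sc, key, function(x) length(unique(x))) > 1L))
        stop("inconsistent scores within a (compound, target, rank) pose",
             call. = FALSE)
    }
  }
  df <- df[order(df$compound_id, df$target_id, df$pose_rank), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("pose_table", "data.frame")
  attr(df, "dialect") <- dialect
  df
}

#' Write a pose table
#'
#' Inverse of [read_pose_table()]: `read_pose_table(write_pose_table(x, f))`
#' reproduces `x` field for field.
#'
#' @param x A `pose_table` data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pose_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ligand-target stability table
#'
#' Stability tables carry the free-enthalpy change of complex formation
#' (dG0, kcal/mol; more negative = more stable) for wild-type and point-mutant
#' target variants, as produced by docking-based stability estimation.
#' Columns: `target_id`, `variant` (`wt` or `<AA><position><AA>`, e.g.
#' `R602A`), `ligand_id`, `dg0_kcal_mol`.
#'
#' A wt/mutant pairing index per (target, ligand) is attached as attribute
#' `pairs`; mutant rows lacking a wild-type partner are dropped from the index
#' with a warning (they cannot enter [ddg0_impairment()]).
#'
#' @param path TSV path.
#' @return A data frame of class `stability_table` with attribute `pairs`
#'   (data frame: target_id, ligand_id, variant, dg0_wt, dg0_mut).
#' @export
read_stability_table <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("target_id", "variant", "ligand_id", "dg0_kcal_mol")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("stability table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  dg <- suppressWarnings(as.numeric(df$dg0_kcal_mol))
  if (anyNA(dg))
    stop("non-numeric dg0_kcal_mol at row(s): ",
         paste(which(is.na(dg)), collapse = ", "), call. = FALSE)
  df$dg0_kcal_mol <- dg
  bad <- df$variant != "wt" & !grepl("^[A-Z][0-9]+[A-Z]$", df$variant)
  if (any(bad))
    stop("variant labels must be 'wt' or <AA><position><AA>; offending: ",
         paste(unique(df$variant[bad]), collapse = ", "), call. = FALSE)
  key <- paste(df$target_id, df$variant, df$ligand_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (target, variant, ligand) rows", call. = FALSE)

  wt  <- df[df$variant == "wt", ]
  mut <- df[df$variant != "wt", ]
  wt_key  <- paste(wt$target_id, wt$ligand_id, sep = "\r")
  mut_key <- paste(mut$target_id, mut$ligand_id, sep = "\r")
  unpaired <- !(mut_key %in% wt_key)
  if (any(unpaired)) {
    warning("dropping ", sum(unpaired),
            " mutant row(s) without a wild-type partner: ",
            paste(paste(mut$target_id[unpaired], mut$variant[unpaired],
                        mut$ligand_id[unpaired]), collapse = "; "),
            call. = FALSE)
    mut <- mut[!unpaired, , drop = FALSE]
    mut_key <- mut_key[!unpaired]
  }
  idx <- match(mut_key, wt_key)
  pairs <- data.frame(target_id = mut$target_id, ligand_id = mut$ligand_id,
                      variant = mut$variant,
                      dg0_wt = wt$dg0_kcal_mol[idx],
                      dg0_mut = mut$dg0_kcal_mol,
                      stringsAsFactors = FALSE)
  class(df) <- c("stability_table", "data.frame")
  attr(df, "pairs") <- pairs
  df
}

#' Read compound metadata
#'
#' Columns: `compound_id`, `name`, `mw` (g/mol), `source_library`
#' (`CL`, `CDL` or `external`), plus optional `sim_<ref>` / `rmsd_<ref>`
#' similarity columns (e.g. `sim_C01`, `rmsd_C01`) holding unitless
#' similarity in [0,1] and RMSD in Angstrom against reference compounds.
#'
#' @param path TSV path.
#' @return A data frame of class `compound_table`.
#' @export
read_compound_table <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  as_compound_table(df)
}

#' Validate a compound metadata data frame
#' @param df Data frame (see [read_compound_table()] for columns).
#' @return A `compound_table` data frame.
#' @export
as_compound_table <- function(df) {
  need <- c("compound_id", "name", "mw", "source_library")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("compound table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df$mw <- as.numeric(df$mw)
  if (any(is.na(df$mw) | df$mw <= 0))
    stop("mw must be a positive number for every compound", call. = FALSE)
  if (!all(df$source_library %in% c("CL", "CDL", "external")))
    stop("source_library must be one of CL, CDL, external", call. = FALSE)
  sim_cols <- grep("^sim_", names(df), value = TRUE)
  for (col in sim_cols) {
    v <- as.numeric(df[[col]])
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop("similarity values in '", col, "' must lie in [0,1]",
           call. = FALSE)
    df[[col]] <- v
  }
  for (col in grep("^rmsd_", names(df), value = TRUE)) {
    v <- as.numeric(df[[col]])
    if (any(!is.na(v) & v < 0))
      stop("rmsd values in '", col, "' must be >= 0", call. = FALSE)
    df[[col]] <- v
  }
  class(df) <- c("compound_table", "data.frame")
  df
}

#' Define a binding pocket
#'
#' @param pocket_id `"pY0"` (phosphotyrosine pocket) or `"pYX"` (hydrophobic
#'   side-pocket).
#' @param centroid Numeric length-3 centre, Angstrom.
#' @param radius Positive radius, Angstrom. Default 5.
#' @return A `pocket_def` list.
#' @export
pocket_definition <- function(pocket_id = c("pY0", "pYX"), centroid,
                              radius = 5) {
  pocket_id <- match.arg(pocket_id)
  centroid <- as.numeric(centroid)
  stopifnot(length(centroid) == 3, is.finite(centroid),
            is.numeric(radius), radius > 0)
  structure(list(pocket_id = pocket_id, centroid = centroid, radius = radius),
            class = "pocket_def")
}
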
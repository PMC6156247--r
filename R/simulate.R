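#' Simulate a docking pose table with planted pocket occupancy
#'
#' Emulates a re-screen run: for each compound x target, `n_poses` poses with
#' binding scores drawn from a per-target normal distribution, ranked by
#' descending BS, and pocket flags drawn from the multinomial
#' (pY0-only, pYX-only, both, neither) with probabilities
#' `(p0, pX, pBoth, 1 - p0 - pX - pBoth)`. The defaults describe a
#' reasonably specific binder (most poses hitting both pockets) scored in
#' the range the screening engine reports.
#'
#' @param n_compounds Number of compounds.
#' @param targets Target ids; default STAT1/2/3.
#' @param n_poses Poses per compound x target (default 20, the re-screen
#'   depth).
#' @param p0,pX,pBoth Occupancy probabilities (defaults 0.2, 0.2, 0.5).
#' @param bs_mean Per-target BS mean: scalar or named vector (default 7).
#' @param bs_sd BS standard deviation (default 0.5).
#' @param seed Integer seed; identical seeds give identical output.
#' @return List: `poses` (flags-dialect `pose_table`) and `truth`
#'   (list with the planted occupancy probabilities).
#' @export
simulate_pose_table <- function(n_compounds,
                                targets = c("STAT1", "STAT2", "STAT3"),
                                n_poses = 20, p0 = 0.2, pX = 0.2,
                                pBoth = 0.5, bs_mean = 7, bs_sd = 0.5,
                                seed = 1) {
  probs <- c(p0, pX, pBoth)
  if (any(probs < 0) || any(probs > 1) || sum(probs) > 1)
    stop("occupancy probabilities must be in [0,1] with p0+pX+pBoth <= 1",
         call. = FALSE)
  stopifnot(bs_sd > 0, n_poses >= 1)
  if (is.null(names(bs_mean)))
    bs_mean <- stats::setNames(rep_len(bs_mean, length(targets)), targets)
  set.seed(seed)
  ids <- sprintf("CMP%04d", seq_len(n_compounds))
  rows <- vector("list", n_compounds * length(targets))
  k <- 0L
  for (cid in ids) {
    for (tg in targets) {
      bs <- sort(stats::rnorm(n_poses, bs_mean[[tg]], bs_sd),
                 decreasing = TRUE)
      cls <- sample(c("PY0_ONLY", "PYX_ONLY", "BOTH", "NEITHER"), n_poses,
                    replace = TRUE, prob = c(probs, 1 - sum(probs)))
      k <- k + 1L
      rows[[k]] <- data.frame(
        compound_id = cid, target_id = tg, pose_rank = seq_len(n_poses),
        bs = round(bs, 4), crash = round(-stats::runif(n_poses, 0.5, 2), 4),
        polar_score = round(stats::runif(n_poses, 4, 9), 4),
        occupies_py0 = as.integer(cls %in% c("PY0_ONLY", "BOTH")),
        occupies_pyx = as.integer(cls %in% c("PYX_ONLY", "BOTH")),
        stringsAsFactors = FALSE)
    }
  }
  poses <- as_pose_table(do.call(rbind, rows), dialect = "flags")
  list(poses = poses,
       truth = list(p0 = p0, pX = pX, pBoth = pBoth,
                    compound_ids = ids, n_poses = n_poses))
}

#' Simulate a screening library with planted cascade survivors
#'
#' Builds a compound library in which exactly `n_winners` compounds are
#' constructed to survive every stage of [run_triage()] under the default
#' thresholds (similarity >= 0.5 to the reference compound, MW >= 300 g/mol,
#' CBAV >= 0 against every non-reference target, LBPV(BOTH) >= 0.8), while
#' every decoy is planted to fail at least one of the
#' similarity / MW / CBAV / pose-diversity stages. Winners additionally get
#' the highest reference-target binding scores so any top-k cut of size
#' >= `n_winners` retains them.
#'
#' @param n_compounds Library size (default 50).
#' @param n_winners Planted survivors (default 3).
#' @param targets Targets; the first is the reference.
#' @param seed Integer seed.
#' @return List: `poses`, `compounds`, `config` (ready for [run_triage()])
#'   and `truth` (winner ids and per-decoy failure modes).
#' @export
simulate_screen_library <- function(n_compounds = 50, n_winners = 3,
                                    targets = c("STAT1", "STAT2", "STAT3"),
                                    seed = 1) {
  stopifnot(n_winners >= 1, n_compounds > n_winners)
  set.seed(seed)
  ref <- targets[1L]
  others <- targets[-1L]
  ids <- sprintf("CMP%03d", seq_len(n_compounds))
  winners <- ids[seq_len(n_winners)]
  modes <- c("sim", "mw", "cbav", "lbpv")
  decoy_modes <- lapply(ids[-seq_len(n_winners)], function(i)
    sample(modes, sample(1:2, 1)))
  names(decoy_modes) <- ids[-seq_len(n_winners)]

  rows <- list(); meta <- list()
  for (cid in ids) {
    is_win <- cid %in% winners
    fm <- if (is_win) character(0) else decoy_modes[[cid]]
    bs_mean <- stats::setNames(rep(6, length(targets)), targets)
    bs_mean[ref] <- if (is_win) 9.5 else 8
    if ("cbav" %in% fm) bs_mean[sample(others, 1)] <- 9.5
    pBoth <- if (is_win) 0.98 else if ("lbpv" %in% fm) 0.2 else 0.95
    p0 <- pX <- (1 - pBoth) / 2.5
    sim <- if ("sim" %in% fm) stats::runif(1, 0.1, 0.45) else
      stats::runif(1, 0.6, 0.9)
    mw <- if ("mw" %in% fm) stats::runif(1, 250, 295) else
      stats::runif(1, 305, 420)
    one <- simulate_pose_table(1, targets = targets, n_poses = 20,
                               p0 = p0, pX = pX, pBoth = pBoth,
                               bs_mean = bs_mean, bs_sd = 0.15,
                               seed = sample.int(.Machine$integer.max, 1))
    p <- one$poses
    p$compound_id <- cid
    rows[[cid]] <- p
    meta[[cid]] <- data.frame(compound_id = cid, name = cid,
                              mw = round(mw, 1), source_library = "CDL",
                              sim_C01 = round(sim, 3),
                              stringsAsFactors = FALSE)
  }
  poses <- as_pose_table(do.call(rbind, rows), dialect = "flags")
  compounds <- as_compound_table(do.call(rbind, meta))
  list(poses = poses, compounds = compounds,
       config = list(reference_target = ref, top_k = 20,
                     similarity_refs = "C01", min_sim = 0.5, min_mw = 300,
                     cbav_threshold = 0, lbpv_class = "BOTH",
                     lbpv_threshold = 0.8),
       truth = list(winners = winners, decoy_modes = decoy_modes))
}

#' Simulate a two-replicate expression experiment with planted effects
#'
#' Control log2 signals are Gaussian (log-normal linear signals, mean 8,
#' sd 2 log2 units — the dynamic range of a bead-array after scanning).
#' A fraction of genes is induced in the stimulated arm by a planted log2
#' fold change (floored at 1, i.e. 2-fold); of the induced genes, each
#' inhibitor arm independently responds in a configured fraction with a
#' planted log2 drop. Replicate noise is Gaussian on the log2 scale. A small
#' per-cell probability of a negative raw signal exercises the flooring
#' path, mimicking scanner background over-subtraction.
#'
#' @param n_genes Number of genes (default 2000).
#' @param frac_induced Fraction induced by stimulation (default 0.05).
#' @param induced_lfc Planted log2 fold change of induction (default 3,
#'   i.e. 8-fold).
#' @param induced_lfc_sd Gene-to-gene sd of the planted log2 FC (default 0;
#'   draws are floored at 1 so every planted gene is at least 2-fold).
#' @param inhibitors Inhibitor names (default the three study compounds).
#' @param frac_inhibited Fraction of induced genes responding to each
#'   inhibitor, independently (default 0.35).
#' @param inhibition_lfc Planted log2 drop in responding arms (default 4,
#'   i.e. a fold-change ratio of 16).
#' @param noise_sd Replicate noise sd, log2 units (default 0.25).
#' @param n_rep Replicates per condition (default 2).
#' @param baseline_mean,baseline_sd Control log2 signal distribution (8, 2).
#' @param p_negative Per-cell probability of a negative raw signal (0.01).
#' @param seed Integer seed.
#' @return List: `es` (raw-scale `expr_set`), `design` (for
#'   [analyze_expression()]) and `truth` (data frame: gene_id, induced,
#'   one `inhibited_<name>` column per inhibitor).
#' @export
simulate_expression <- function(n_genes = 2000, frac_induced = 0.05,
                                induced_lfc = 3, induced_lfc_sd = 0,
                                inhibitors = c("C01L_F03", "STATTIC",
                                               "STX0119"),
                                frac_inhibited = 0.35, inhibition_lfc = 4,
                                noise_sd = 0.25, n_rep = 2,
                                baseline_mean = 8, baseline_sd = 2,
                                p_negative = 0.01, seed = 1) {
  for (f in c(frac_induced, frac_inhibited, p_negative))
    if (f < 0 || f > 1)
      stop("fraction parameters must lie in [0, 1]", call. = FALSE)
  stopifnot(noise_sd >= 0, n_rep >= 2)
  set.seed(seed)
  gene_id <- sprintf("G%05d", seq_len(n_genes))
  gene_name <- sprintf("GENE%05d", seq_len(n_genes))
  n_ind <- round(frac_induced * n_genes)
  induced <- c(rep(TRUE, n_ind), rep(FALSE, n_genes - n_ind))
  lfc <- ifelse(induced,
                pmax(1, stats::rnorm(n_genes, induced_lfc, induced_lfc_sd)),
                0)
  resp <- sapply(inhibitors, function(i)
    induced & stats::runif(n_genes) < frac_inhibited)
  resp <- matrix(resp, nrow = n_genes,
                 dimnames = list(NULL, inhibitors))

  base <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
  conds <- c("control", "stim", paste0("stim_", inhibitors))
  mu <- cbind(control = base, stim = base + lfc)
  for (inh in inhibitors)
    mu <- cbind(mu, base + lfc - ifelse(resp[, inh], inhibition_lfc, 0))
  colnames(mu) <- conds

  cols <- list()
  for (cond in conds)
    for (r in seq_len(n_rep))
      cols[[paste0(cond, ".", r)]] <-
        2^(mu[, cond] + stats::rnorm(n_genes, 0, noise_sd))
  vals <- do.call(cbind, cols)
  neg <- matrix(stats::runif(length(vals)) < p_negative, nrow = n_genes)
  vals[neg] <- -stats::runif(sum(neg), 0, 10)

  es <- expr_set(vals, genes = data.frame(gene_id = gene_id,
                                          gene_name = gene_name,
                                          stringsAsFactors = FALSE))
  truth <- data.frame(gene_id = gene_id, induced = induced,
                      stringsAsFactors = FALSE)
  for (inh in inhibitors)
    truth[[paste0("inhibited_", inh)]] <- resp[, inh]
  list(es = es,
       design = list(control = "control", stim = "stim",
                     inhibitors = stats::setNames(paste0("stim_",
                                                         inhibitors),
                                                  inhibitors)),
       truth = truth)
}

.sample_iid <- function(n, gc) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

.markov3_background <- function(n, train) {
  # order-3 Markov chain with transition counts estimated from `train`
  b <- strsplit(train, "")[[1L]]
  ctx <- paste0(b[1:(length(b) - 3)], b[2:(length(b) - 2)],
                b[3:(length(b) - 1)])
  nxt <- b[4:length(b)]
  tabs <- table(ctx, nxt)
  out <- character(n)
  out[1:3] <- b[1:3]
  bases <- c("A", "C", "G", "T")
  for (i in 4:n) {
    cx <- paste0(out[i - 3], out[i - 2], out[i - 1])
    if (cx %in% rownames(tabs) && sum(tabs[cx, ]) > 0)
      out[i] <- sample(colnames(tabs), 1, prob = tabs[cx, ])
    else out[i] <- sample(bases, 1)
  }
  paste(out, collapse = "")
}

#' Simulate promoter sequences with planted binding-site motifs
#'
#' Background is i.i.d. at the configured GC content (optionally an order-3
#' Markov chain trained on a supplied sequence, for false-positive
#' measurements on a more realistic background). For each gene, each site
#' class is planted independently with its class probability; a planted
#' instance is sampled column-wise from the class PFM's base frequencies,
#' placed at a random non-overlapping offset on a random strand.
#'
#' @param n_promoters Number of genes (default 200).
#' @param config Class configuration as in [site_class_config()]; the first
#'   matrix of each class is used for planting.
#' @param class_prob Named per-class planting probabilities (defaults
#'   ISRE 0.5, GAS 0.5, NFKB 0.4, covering all eight combination
#'   categories).
#' @param length Promoter length in bp (default 1000: the -950..+50 window).
#' @param gc GC content of the background (default 0.5).
#' @param background `"iid"` (default) or `"markov3"`.
#' @param markov_train Training sequence for the Markov background; default
#'   a fresh i.i.d. sequence of 20 kb at the same GC.
#' @param window_start TSS-relative coordinate of the first base (-950).
#' @param seed Integer seed.
#' @return List: `sequences` (named character vector), `truth` (data frame:
#'   gene_id + `planted_<class>` flags) and `placements` (data frame:
#'   gene_id, class, offset, strand).
#' @export
simulate_promoters <- function(n_promoters = 200,
                               config = site_class_config(),
                               class_prob = c(ISRE = 0.5, GAS = 0.5,
                                              NFKB = 0.4),
                               length = 1000, gc = 0.5,
                               background = c("iid", "markov3"),
                               markov_train = NULL, window_start = -950L,
                               seed = 1) {
  background <- match.arg(background)
  stopifnot(all(names(class_prob) %in% names(config)))
  set.seed(seed)
  widths <- vapply(config[names(class_prob)],
                   function(cl) cl$pwms[[1L]]$width, numeric(1))
  if (any(widths > length))
    stop("planted motif longer than the promoter", call. = FALSE)
  if (background == "markov3" && is.null(markov_train))
    markov_train <- paste(.sample_iid(20000, gc), collapse = "")

  sample_motif <- function(pwm) {
    pr <- sweep(pwm$counts, 2L, colSums(pwm$counts), "/")
    paste(vapply(seq_len(pwm$width), function(j)
      sample(rownames(pr), 1, prob = pr[, j]), character(1)),
      collapse = "")
  }

  ids <- sprintf("PROM%04d", seq_len(n_promoters))
  seqs <- character(n_promoters)
  truth <- data.frame(gene_id = ids, stringsAsFactors = FALSE)
  for (cl in names(class_prob))
    truth[[paste0("planted_", tolower(cl))]] <- FALSE
  placements <- list()

  for (g in seq_len(n_promoters)) {
    seq <- if (background == "iid") .sample_iid(length, gc) else
      strsplit(.markov3_background(length, markov_train), "")[[1L]]
    occupied <- rep(FALSE, length)
    for (cl in names(class_prob)) {
      if (stats::runif(1) >= class_prob[[cl]]) next
      pwm <- config[[cl]]$pwms[[1L]]
      motif <- sample_motif(pwm)
      strand <- sample(c("+", "-"), 1)
      ins <- if (strand == "+") motif else .revcomp(motif)
      ok <- FALSE
      for (try in 1:50) {
        at <- sample.int(length - pwm$width + 1L, 1)
        span <- at:(at + pwm$width - 1L)
        if (!any(occupied[span])) { ok <- TRUE; break }
      }
      if (!ok) next
      seq[span] <- strsplit(ins, "")[[1L]]
      occupied[span] <- TRUE
      truth[[paste0("planted_", tolower(cl))]][g] <- TRUE
      placements[[length(placements) + 1L]] <-
        data.frame(gene_id = ids[g], class = cl,
                   offset = as.integer(at - 1L + window_start),
                   strand = strand, stringsAsFactors = FALSE)
    }
    seqs[g] <- paste(seq, collapse = "")
  }
  list(sequences = stats::setNames(seqs, ids), truth = truth,
       placements = if (length(placements)) do.call(rbind, placements)
       else data.frame(gene_id = character(0), class = character(0),
                       offset = integer(0), strand = character(0)))
}
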
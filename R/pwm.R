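#' Read a position frequency matrix (JASPAR PFM format)
#'
#' Accepts the JASPAR text layouts: an optional `>ID name` header followed by
#' four base rows, either bracketed (`A [ 3 10 ... ]`) or bare
#' whitespace-separated counts in A, C, G, T order. Log-weights are computed
#' with a pseudocount against the uniform background:
#' `w(b, i) = log2(((n_bi + q) / (N_i + 4q)) / 0.25)`, and the minimal and
#' maximal achievable window scores `s_min` / `s_max` are the column-wise
#' sums of the per-column minima and maxima. A matrix whose columns cannot
#' discriminate (`s_min == s_max`) is rejected as degenerate.
#'
#' @param path PFM file path.
#' @param pseudocount Pseudocount `q`; default 0.01 x the column total
#'   (recomputed per column).
#' @return A `pwm_model`: list with `matrix_id`, `counts` (4 x width,
#'   rownames ACGT), `weights`, `s_min`, `s_max`, `width`.
#' @export
read_pfm <- function(path, pseudocount = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  id <- "PFM"
  if (startsWith(lines[1L], ">")) {
    id <- strsplit(trimws(sub("^>", "", lines[1L])), "\\s+")[[1L]][1L]
    lines <- lines[-1L]
  }
  if (length(lines) != 4L)
    stop("PFM must have exactly four base rows (A, C, G, T)", call. = FALSE)
  parse_row <- function(ln) {
    ln <- gsub("^[ACGTacgt]\\s*", "", trimws(ln))
    ln <- gsub("[][]", " ", ln)
    as.numeric(strsplit(trimws(ln), "\\s+")[[1L]])
  }
  rows <- lapply(lines, parse_row)
  w <- unique(lengths(rows))
  if (length(w) != 1L)
    stop("ragged PFM: base rows differ in length", call. = FALSE)
  counts <- do.call(rbind, rows)
  rownames(counts) <- c("A", "C", "G", "T")
  if (anyNA(counts) || any(counts < 0))
    stop("PFM counts must be nonnegative numbers", call. = FALSE)
  pwm_model(counts, matrix_id = id, pseudocount = pseudocount)
}

#' Build a PWM model from a count matrix
#'
#' @param counts 4 x width nonnegative matrix, rows A, C, G, T.
#' @param matrix_id Identifier string.
#' @param pseudocount Pseudocount; default 0.01 x column total.
#' @return A `pwm_model` list (see [read_pfm()]).
#' @export
pwm_model <- function(counts, matrix_id = "PFM", pseudocount = NULL) {
  stopifnot(is.matrix(counts), nrow(counts) == 4L, all(counts >= 0))
  if (is.null(rownames(counts))) rownames(counts) <- c("A", "C", "G", "T")
  w <- ncol(counts)
  if (w < 4L) stop("PWM width must be >= 4", call. = FALSE)
  tot <- colSums(counts)
  if (any(tot <= 0))
    stop("every PFM column needs at least one positive count", call. = FALSE)
  q <- if (is.null(pseudocount)) 0.01 * tot else rep(pseudocount, w)
  if (any(q <= 0)) stop("pseudocount must be positive", call. = FALSE)
  prob <- sweep(sweep(counts, 2L, q, "+"), 2L, tot + 4 * q, "/")
  weights <- log2(prob / 0.25)
  s_min <- sum(apply(weights, 2L, min))
  s_max <- sum(apply(weights, 2L, max))
  if (s_max - s_min < 1e-9)
    stop("degenerate PFM: uniform columns give s_min == s_max",
         call. = FALSE)
  structure(list(matrix_id = matrix_id, counts = counts, weights = weights,
                 s_min = s_min, s_max = s_max, width = w),
            class = "pwm_model")
}

#' @export
print.pwm_model <- function(x, ...) {
  cat(sprintf("pwm_model %s: width %d, score range [%.3f, %.3f]\n",
              x$matrix_id, x$width, x$s_min, x$s_max))
  invisible(x)
}

#' Consensus sequence of a PWM
#' @param pwm A `pwm_model`.
#' @return Character string of per-column maximal-count bases.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$counts)[apply(pwm$counts, 2L, which.max)],
        collapse = "")
}

#' Min-max normalized matrix similarity score of one window
#'
#' MATCH-style construction: the summed log-weights S of the window mapped
#' to `(S - s_min) / (s_max - s_min)`, so the matrix consensus scores 1 and
#' the per-position worst window scores 0. Ambiguous bases (anything outside
#' ACGT, e.g. N) contribute the column minimum.
#'
#' @param pwm A `pwm_model`.
#' @param window Character string of length `pwm$width`.
#' @return A score in [0, 1].
#' @export
matrix_similarity_score <- function(pwm, window) {
  b <- strsplit(toupper(window), "")[[1L]]
  if (length(b) != pwm$width)
    stop("window length ", length(b), " != PWM width ", pwm$width,
         call. = FALSE)
  idx <- match(b, rownames(pwm$weights))
  col_min <- apply(pwm$weights, 2L, min)
  s <- sum(ifelse(is.na(idx), col_min,
                  pwm$weights[cbind(idx, seq_len(pwm$width))]))
  (s - pwm$s_min) / (pwm$s_max - pwm$s_min)
}

.revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTacgtN", "TGCAtgcaN", seq), "")[[1L]]),
        collapse = "")
}

.window_scores <- function(pwm, seq) {
  b <- strsplit(toupper(seq), "")[[1L]]
  n <- length(b)
  w <- pwm$width
  idx <- match(b, rownames(pwm$weights))
  col_min <- apply(pwm$weights, 2L, min)
  n_win <- n - w + 1L
  scores <- numeric(n_win)
  for (j in seq_len(w)) {
    ij <- idx[j:(j + n_win - 1L)]
    wj <- pwm$weights[, j]
    scores <- scores + ifelse(is.na(ij), col_min[j], wj[ij])
  }
  (scores - pwm$s_min) / (pwm$s_max - pwm$s_min)
}

#' Scan a promoter for the best PWM hit
#'
#' Slides the matrix over both strands of the promoter (minus strand scored
#' on the reverse complement) and returns the maximal similarity score. The
#' promoter is expected to be the `[-950, +50)` window around the
#' transcription start site (position 0 = TSS), so reported offsets are
#' TSS-relative: `offset = start_index - 1 + window_start`, where
#' `window_start` is `-950` by default. Ties are broken leftmost, then plus
#' strand.
#'
#' @param seq Promoter sequence (character string), length >= PWM width.
#' @param pwm A `pwm_model`.
#' @param threshold Pass threshold on the similarity score (inclusive).
#' @param window_start TSS-relative coordinate of the first base
#'   (default -950).
#' @return List: `score`, `offset` (TSS-relative start of the best window),
#'   `strand` (`"+"`/`"-"`), `pass`.
#' @export
scan_promoter <- function(seq, pwm, threshold, window_start = -950L) {
  seq <- as.character(seq)
  if (nchar(seq) < pwm$width)
    stop("sequence shorter than the PWM width", call. = FALSE)
  fwd <- .window_scores(pwm, seq)
  rev <- .window_scores(pwm, .revcomp(seq))
  # map minus-strand windows back to plus-strand start coordinates
  n_win <- length(fwd)
  rev_plus <- rev[n_win:1L]
  best <- max(fwd, rev_plus)
  at_best_fwd <- which(fwd >= best - 1e-12)
  at_best_rev <- which(rev_plus >= best - 1e-12)
  first_fwd <- if (length(at_best_fwd)) at_best_fwd[1L] else Inf
  first_rev <- if (length(at_best_rev)) at_best_rev[1L] else Inf
  if (first_fwd <= first_rev) {
    i <- first_fwd; strand <- "+"
  } else {
    i <- first_rev; strand <- "-"
  }
  list(score = best, offset = as.integer(i - 1L + window_start),
       strand = strand, pass = best >= threshold)
}

#' Default ISRE / GAS / NF-kB class configuration
#'
#' One entry per site class, each holding the class PWMs and the class
#' threshold on the matrix similarity score (0.85 for ISRE and GAS, 0.90
#' for NF-kB — the stricter NF-kB cut guards against its shorter, more
#' common GGG-rich core).
#'
#' @param pfm_dir Directory of PFM files; defaults to the synthetic matrices
#'   shipped in `inst/extdata/pfm`.
#' @return Named list of classes, each `list(pwms, threshold)`.
#' @export
site_class_config <- function(pfm_dir = system.file("extdata", "pfm",
                                                    package = "statscreen")) {
  load1 <- function(f) read_pfm(file.path(pfm_dir, f))
  list(
    ISRE = list(pwms = list(load1("ISRE_synthetic.pfm")), threshold = 0.85),
    GAS  = list(pwms = list(load1("GAS_synthetic.pfm")),  threshold = 0.85),
    NFKB = list(pwms = list(load1("NFKB_synthetic.pfm")), threshold = 0.90))
}

.category_levels <- c("ISRE only", "GAS only", "NFKB only", "ISRE+GAS",
                      "ISRE+NFKB", "GAS+NFKB", "ISRE+GAS+NFKB", "none")

.category_from_flags <- function(isre, gas, nfkb) {
  parts <- c("ISRE", "GAS", "NFKB")[c(isre, gas, nfkb)]
  if (length(parts) == 0L) "none"
  else if (length(parts) == 1L) paste(parts, "only")
  else paste(parts, collapse = "+")
}

#' Classify one promoter into an ISRE/GAS/NF-kB combination category
#'
#' A class is present when any of its matrices reaches the class threshold
#' (best hit over the class's matrices); the combination category is the
#' unique function of the three presence flags.
#'
#' @param seq Promoter sequence.
#' @param config Class configuration (see [site_class_config()]).
#' @param gene_id Identifier carried into the output.
#' @param window_start TSS-relative coordinate of the first base.
#' @return A one-row data frame: gene_id, per-class best score / offset /
#'   strand / presence flag, and `category`.
#' @export
site_class_call <- function(seq, config, gene_id = NA_character_,
                            window_start = -950L) {
  out <- data.frame(gene_id = gene_id, stringsAsFactors = FALSE)
  flags <- logical(0)
  for (cl in names(config)) {
    hits <- lapply(config[[cl]]$pwms, function(p)
      scan_promoter(seq, p, config[[cl]]$threshold, window_start))
    best <- hits[[which.max(vapply(hits, `[[`, numeric(1), "score"))]]
    out[[paste0(tolower(cl), "_score")]] <- best$score
    out[[paste0(tolower(cl), "_offset")]] <- best$offset
    out[[paste0(tolower(cl), "_strand")]] <- best$strand
    out[[paste0("has_", tolower(cl))]] <- best$pass
    flags[cl] <- best$pass
  }
  out$category <- .category_from_flags(flags[["ISRE"]], flags[["GAS"]],
                                       flags[["NFKB"]])
  out
}

#' Scan a promoter FASTA and classify every gene
#'
#' @param fasta Path to a FASTA file, one record per gene, header = gene id;
#'   or a named character vector of sequences.
#' @param config Class configuration (see [site_class_config()]).
#' @param window_start TSS-relative coordinate of the first base.
#' @return A data frame of per-gene site calls (class `gene_site_calls`).
#' @export
classify_promoters <- function(fasta, config = site_class_config(),
                               window_start = -950L) {
  if (length(fasta) == 1L && file.exists(fasta)) {
    ss <- Biostrings::readDNAStringSet(fasta)
    seqs <- stats::setNames(as.character(ss), names(ss))
  } else {
    seqs <- fasta
  }
  if (is.null(names(seqs)))
    stop("promoter sequences must be named by gene id", call. = FALSE)
  calls <- do.call(rbind, lapply(names(seqs), function(g)
    site_class_call(seqs[[g]], config, gene_id = g,
                    window_start = window_start)))
  class(calls) <- c("gene_site_calls", "data.frame")
  calls
}

#' Category counts and Venn summary of site calls
#'
#' Dense eight-category counts (they sum to the number of genes) with
#' percentages over two denominators — all genes, and genes carrying at
#' least one site (the with-site base) — plus the single/pairwise/triple
#' Venn region counts of the three per-class gene lists.
#'
#' @param calls A `gene_site_calls` data frame.
#' @return List: `counts` (named integer, all eight categories),
#'   `pct_all_genes`, `pct_with_site`, `venn_regions`, `n`.
#' @export
category_counts <- function(calls) {
  stopifnot(nrow(calls) >= 1L)
  counts <- stats::setNames(integer(length(.category_levels)),
                            .category_levels)
  tab <- table(calls$category)
  counts[names(tab)] <- as.integer(tab)
  n <- nrow(calls)
  n_site <- n - counts[["none"]]
  pct_all <- 100 * counts / n
  pct_site <- if (n_site > 0) 100 * counts / n_site else counts * NA_real_
  pct_site[["none"]] <- NA_real_
  sets <- list(ISRE = calls$gene_id[calls$has_isre],
               GAS  = calls$gene_id[calls$has_gas],
               NFKB = calls$gene_id[calls$has_nfkb])
  venn <- if (any(lengths(sets) > 0)) common_inhibited(sets)$regions else
    NULL
  list(counts = counts, pct_all_genes = pct_all, pct_with_site = pct_site,
       venn_regions = venn, n = n)
}
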
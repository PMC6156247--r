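#' Read a genes x samples expression table
#'
#' TSV layout: first two columns `gene_id`, `gene_name`; remaining columns
#' are signal intensities named `<condition>.<replicate>` (e.g. `stim.1`,
#' `stim.2`). Signals are arbitrary fluorescence units as exported from a
#' bead-array scanner; negative values are permitted on input and handled by
#' [floor_negatives()].
#'
#' @param path TSV path.
#' @return An `expr_set`: list with `values` (numeric matrix, rownames =
#'   gene ids), `genes` (data frame gene_id, gene_name) and `samples`
#'   (data frame sample, condition, replicate).
#' @export
read_expression <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!all(c("gene_id", "gene_name") %in% names(df)[1:2]))
    stop("first two columns must be gene_id and gene_name", call. = FALSE)
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(vals) <- "double"
  if (anyNA(vals)) stop("expression matrix has missing cells", call. = FALSE)
  rownames(vals) <- df$gene_id
  expr_set(vals, genes = df[, 1:2])
}

#' Construct an expression set
#'
#' @param values Numeric genes x samples matrix; column names
#'   `<condition>.<replicate>`.
#' @param genes Data frame with `gene_id`, `gene_name` (defaults to the
#'   matrix rownames for both).
#' @return An `expr_set` list.
#' @export
expr_set <- function(values, genes = NULL) {
  stopifnot(is.matrix(values), is.numeric(values), !anyNA(values))
  if (is.null(genes))
    genes <- data.frame(gene_id = rownames(values),
                        gene_name = rownames(values),
                        stringsAsFactors = FALSE)
  stopifnot(nrow(genes) == nrow(values))
  cn <- colnames(values)
  if (is.null(cn) || !all(grepl("\\.", cn)))
    stop("sample columns must be named <condition>.<replicate>",
         call. = FALSE)
  condition <- sub("\\.[^.]*$", "", cn)
  replicate <- sub("^.*\\.", "", cn)
  structure(list(values = values, genes = genes,
                 samples = data.frame(sample = cn, condition = condition,
                                      replicate = replicate,
                                      stringsAsFactors = FALSE)),
            class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("expr_set: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$samples$condition), collapse = ", ")))
  invisible(x)
}

.apply_values <- function(x, f) {
  if (inherits(x, "expr_set")) {
    x$values <- f(x$values)
    x
  } else f(x)
}

#' Floor non-positive signals at one
#'
#' Bead-array signals can go negative after scanner background correction;
#' to keep the subsequent log transform defined, every value <= 0 is set
#' to 1 (log2 signal 0). Positive values are untouched.
#'
#' @param x Numeric matrix or `expr_set`.
#' @return Same type as `x`.
#' @export
floor_negatives <- function(x) {
  .apply_values(x, function(v) { v[v <= 0] <- 1; v })
}

#' Log-transform signals
#'
#' @param x Numeric matrix or `expr_set`; every value must be positive
#'   (run [floor_negatives()] first).
#' @param base Logarithm base, default 2.
#' @return Same type as `x`, log-scale.
#' @export
log_transform <- function(x, base = 2) {
  .apply_values(x, function(v) {
    if (any(v <= 0))
      stop("non-positive values present; apply floor_negatives() first",
           call. = FALSE)
    log(v, base = base)
  })
}

#' Per-sample background subtraction on the log scale
#'
#' Default method subtracts each sample's 5th-percentile log signal (a
#' control-probe-free proxy for array background) and floors the result at
#' zero. `method = "none"` is the identity.
#'
#' @param x Log-scale matrix or `expr_set`.
#' @param method `"percentile"` (default) or `"none"`.
#' @param probs Percentile used by the `"percentile"` method, default 0.05.
#' @return Same type as `x`.
#' @export
subtract_background <- function(x, method = c("percentile", "none"),
                                probs = 0.05) {
  method <- match.arg(method)
  .apply_values(x, function(v) {
    if (method == "none") return(v)
    off <- apply(v, 2L, stats::quantile, probs = probs, names = FALSE)
    v <- sweep(v, 2L, off)
    v[v < 0] <- 0
    v
  })
}

#' Quantile normalization
#'
#' Classic rank-mean normalization: each sample's sorted values are replaced
#' by the across-sample mean at each rank, so afterwards every sample shares
#' one empirical distribution; tied values receive the mean of their tied
#' ranks' values. Delegated to \code{limma::normalizeQuantiles}. A
#' single-sample matrix is returned unchanged with a warning.
#'
#' @param x Numeric matrix or `expr_set`.
#' @return Same type as `x`.
#' @export
quantile_normalize <- function(x) {
  .apply_values(x, function(v) {
    if (ncol(v) < 2L) {
      warning("quantile normalization needs >= 2 samples; returning input",
              call. = FALSE)
      return(v)
    }
    out <- limma::normalizeQuantiles(v, ties = TRUE)
    dimnames(out) <- dimnames(v)
    out
  })
}

#' Per-gene fold change and replicate test between two conditions
#'
#' On log2 signals: the linear fold change is 2^(mean_b - mean_a) and the
#' p-value comes from a two-sample t test per gene (Welch by default; a
#' pooled-variance option is provided since with two replicates per arm the
#' Welch degrees of freedom are very small). Degenerate genes with zero
#' within-condition variance get p = 1 when the means agree and p = 0
#' otherwise.
#'
#' @param es An `expr_set` on the log2 scale (post-normalization).
#' @param condition_a Baseline condition label (fold-change denominator).
#' @param condition_b Comparison condition label.
#' @param var `"welch"` (default) or `"pooled"`.
#' @return Data frame: gene_id, gene_name, mean_fc (linear), p_value.
#' @export
replicate_test <- function(es, condition_a, condition_b,
                           var = c("welch", "pooled")) {
  var <- match.arg(var)
  a <- es$values[, es$samples$condition == condition_a, drop = FALSE]
  b <- es$values[, es$samples$condition == condition_b, drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L)
    stop("replicate_test() needs >= 2 replicates per condition",
         call. = FALSE)
  diff <- rowMeans(b) - rowMeans(a)
  va <- apply(a, 1L, stats::var)
  vb <- apply(b, 1L, stats::var)
  na <- ncol(a); nb <- ncol(b)
  if (var == "welch") {
    se2 <- va / na + vb / nb
    dfree <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    dfree <- rep(na + nb - 2, length(se2))
  }
  p <- ifelse(se2 == 0,
              ifelse(diff == 0, 1, 0),
              2 * stats::pt(-abs(diff / sqrt(se2)), dfree))
  data.frame(gene_id = es$genes$gene_id, gene_name = es$genes$gene_name,
             mean_fc = 2^diff, p_value = p, stringsAsFactors = FALSE)
}

#' Induction filter
#'
#' Keeps genes significantly up-regulated: fold change at least
#' `fc_threshold` and p-value at most `p_threshold` (both inclusive).
#'
#' @param calls Data frame with `mean_fc` and `p_value` (from
#'   [replicate_test()]).
#' @param fc_threshold Minimal linear fold change, default 2.
#' @param p_threshold Maximal p-value, default 0.05.
#' @return The surviving rows of `calls`.
#' @export
induced_genes <- function(calls, fc_threshold = 2, p_threshold = 0.05) {
  calls[calls$mean_fc >= fc_threshold & calls$p_value <= p_threshold, ,
        drop = FALSE]
}

#' Fold-change-ratio inhibition criterion
#'
#' A stimulated gene counts as inhibited by a compound when the stimulated
#' fold change divided by the fold change under stimulation + compound is at
#' least `ratio_threshold` (inclusive). Vectorized.
#'
#' @param fc_stim Fold change under stimulation alone (linear, vs control).
#' @param fc_stim_inh Fold change under stimulation + inhibitor (> 0).
#' @param ratio_threshold Default 4.
#' @return List with `ratio` and `inhibited` (logical).
#' @export
inhibition_call <- function(fc_stim, fc_stim_inh, ratio_threshold = 4) {
  if (any(fc_stim_inh <= 0))
    stop("fc_stim_inh must be positive (fold changes are positive by ",
         "construction)", call. = FALSE)
  ratio <- fc_stim / fc_stim_inh
  list(ratio = ratio, inhibited = ratio >= ratio_threshold)
}

.gene_key <- function(x) {
  if (is.character(x))
    return(data.frame(gene_id = x, gene_name = x, stringsAsFactors = FALSE))
  stopifnot(all(c("gene_id", "gene_name") %in% names(x)))
  x[, c("gene_id", "gene_name")]
}

#' Venn comparison of inhibited gene sets
#'
#' Gene identity is the (gene_id, gene_name) pair. Returns the counts of all
#' 2^k - 1 Venn regions (dense: empty regions are reported as 0) and the
#' full intersection; region counts sum to the union cardinality.
#'
#' @param sets Named list (>= 2 elements) of character vectors of gene ids,
#'   or data frames with `gene_id` and `gene_name` columns.
#' @return List with `regions` (named integer vector; names are
#'   `&`-joined set names), `intersection` (data frame of genes in every
#'   set) and `union_size`.
#' @export
common_inhibited <- function(sets) {
  if (length(sets) < 2L)
    stop("common_inhibited() needs at least two sets", call. = FALSE)
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- paste0("set", seq_along(sets))
  dfs <- lapply(sets, .gene_key)
  all_genes <- unique(do.call(rbind, dfs))
  k <- length(sets)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  region_names <- apply(combos, 1L, function(m)
    paste(names(sets)[as.logical(m)], collapse = "&"))
  if (nrow(all_genes) == 0L)
    return(list(regions = stats::setNames(integer(length(region_names)),
                                          region_names),
                intersection = all_genes, union_size = 0L))
  dup <- all_genes$gene_id[duplicated(all_genes$gene_id)]
  if (length(dup))
    stop("same gene_id paired with different gene_name across sets: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  member <- vapply(dfs, function(d) all_genes$gene_id %in% d$gene_id,
                   logical(nrow(all_genes)))
  member <- matrix(member, nrow = nrow(all_genes),
                   dimnames = list(NULL, names(sets)))
  sig <- apply(member, 1L, function(m) paste(names(sets)[m], collapse = "&"))
  counts <- stats::setNames(integer(length(region_names)), region_names)
  tab <- table(sig)
  counts[names(tab)] <- as.integer(tab)
  inter <- all_genes[rowSums(member) == k, , drop = FALSE]
  rownames(inter) <- NULL
  list(regions = counts, intersection = inter,
       union_size = nrow(all_genes))
}

#' Full expression-inhibition analysis
#'
#' Runs the processing chain (floor, log2, background subtraction, quantile
#' normalization), calls induced genes for the stimulated arm, applies the
#' fold-change-ratio inhibition criterion per inhibitor to the induced
#' genes, and intersects the per-inhibitor inhibited sets.
#'
#' @param es An `expr_set` on the raw (linear) signal scale.
#' @param design List naming the `control` condition, the `stim` condition,
#'   and `inhibitors` — a named character vector mapping inhibitor name to
#'   its stimulated+inhibitor condition label.
#' @param fc_threshold,p_threshold Induction filter thresholds (2, 0.05).
#' @param ratio_threshold Inhibition ratio threshold (4).
#' @param background Background-subtraction method, see
#'   [subtract_background()].
#' @param var Variance handling for the replicate test.
#' @return An `inhibition_analysis`: list with `calls` (per-gene table:
#'   fold changes, p, induced flag, per-inhibitor ratios and calls),
#'   `induced` (data frame), `inhibited` (named list of data frames),
#'   `venn` (from [common_inhibited()]) and `common` (genes inhibited by
#'   every inhibitor).
#' @export
analyze_expression <- function(es, design, fc_threshold = 2,
                               p_threshold = 0.05, ratio_threshold = 4,
                               background = "percentile",
                               var = "welch") {
  stopifnot(inherits(es, "expr_set"),
            all(c("control", "stim", "inhibitors") %in% names(design)))
  conds <- unique(es$samples$condition)
  needed <- c(design$control, design$stim, unname(design$inhibitors))
  if (!all(needed %in% conds))
    stop("design condition(s) absent from the data: ",
         paste(setdiff(needed, conds), collapse = ", "), call. = FALSE)

  proc <- quantile_normalize(
    subtract_background(log_transform(floor_negatives(es)),
                        method = background))

  stim <- replicate_test(proc, design$control, design$stim, var = var)
  calls <- data.frame(gene_id = stim$gene_id, gene_name = stim$gene_name,
                      fc_stim = stim$mean_fc, p_value = stim$p_value,
                      stringsAsFactors = FALSE)
  calls$induced <- calls$fc_stim >= fc_threshold &
    calls$p_value <= p_threshold

  inhibited <- list()
  for (inh in names(design$inhibitors)) {
    tst <- replicate_test(proc, design$control, design$inhibitors[[inh]],
                          var = var)
    ic <- inhibition_call(calls$fc_stim, tst$mean_fc, ratio_threshold)
    calls[[paste0("fc_", inh)]] <- tst$mean_fc
    calls[[paste0("ratio_", inh)]] <- ic$ratio
    calls[[paste0("inhibited_", inh)]] <- calls$induced & ic$inhibited
    inhibited[[inh]] <- calls[calls$induced & ic$inhibited,
                              c("gene_id", "gene_name"), drop = FALSE]
  }
  venn <- if (length(inhibited) >= 2L) common_inhibited(inhibited) else NULL
  common <- if (!is.null(venn)) venn$intersection else inhibited[[1L]]
  structure(list(calls = calls,
                 induced = calls[calls$induced,
                                 c("gene_id", "gene_name"), drop = FALSE],
                 inhibited = inhibited, venn = venn, common = common,
                 thresholds = list(fc = fc_threshold, p = p_threshold,
                                   ratio = ratio_threshold)),
            class = "inhibition_analysis")
}

#' @export
print.inhibition_analysis <- function(x, ...) {
  cat("Expression inhibition analysis\n")
  cat(sprintf("  induced genes (fc >= %g, p <= %g): %d\n",
              x$thresholds$fc, x$thresholds$p, nrow(x$induced)))
  for (inh in names(x$inhibited))
    cat(sprintf("  inhibited by %-12s (ratio >= %g): %d\n", inh,
                x$thresholds$ratio, nrow(x$inhibited[[inh]])))
  cat(sprintf("  commonly inhibited: %d\n", nrow(x$common)))
  invisible(x)
}
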
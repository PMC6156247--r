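#' Run the full screening / inhibition / promoter analysis chain
#'
#' Orchestrates the three analysis arms: the virtual-screen triage cascade,
#' the expression-inhibition analysis, and the promoter site-class
#' classification. Any subset of stages may be requested; when both the
#' expression and promoter stages run, the combined report additionally
#' classifies the promoter categories of the commonly inhibited genes
#' (the induce -> inhibit -> intersect -> promoter-classify workflow).
#' Deterministic given its inputs.
#'
#' @param triage `NULL`, or a list with `poses`, `compounds`, `config`
#'   (see [run_triage()]).
#' @param expression `NULL`, or a list with `es`, `design`, and optional
#'   threshold overrides `fc_threshold`, `p_threshold`, `ratio_threshold`
#'   (see [analyze_expression()]).
#' @param promoters `NULL`, or a list with `fasta` (path or named sequence
#'   vector) and optional `config` (see [classify_promoters()]).
#' @param out_dir Optional output directory: per-stage TSV/JSON files plus
#'   `report.json` are written there.
#' @return A `pipeline_report` list with the per-stage results and, when
#'   applicable, `common_site_categories`.
#' @export
run_screen_pipeline <- function(triage = NULL, expression = NULL,
                                promoters = NULL, out_dir = NULL) {
  report <- list()
  if (!is.null(triage))
    report$triage <- run_triage(triage$poses, triage$compounds,
                                triage$config)
  if (!is.null(expression)) {
    args <- expression[intersect(names(expression),
                                 c("fc_threshold", "p_threshold",
                                   "ratio_threshold", "background", "var"))]
    report$expression <- do.call(analyze_expression,
                                 c(list(es = expression$es,
                                        design = expression$design), args))
  }
  if (!is.null(promoters)) {
    cfg <- promoters$config %||% site_class_config()
    report$promoters <- classify_promoters(promoters$fasta, cfg)
    report$promoter_summary <- category_counts(report$promoters)
  }
  if (!is.null(report$expression) && !is.null(report$promoters)) {
    common <- report$expression$common
    sub <- report$promoters[report$promoters$gene_id %in% common$gene_id, ,
                            drop = FALSE]
    if (nrow(sub))
      report$common_site_categories <- category_counts(sub)
  }
  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) .write_pipeline_report(report, out_dir)
  report
}

.write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  json <- list()
  if (!is.null(report$triage)) {
    json$triage <- list(stages = report$triage$stages,
                        final = report$triage$final)
    utils::write.table(report$triage$summaries,
                       file.path(out_dir, "triage_summaries.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$expression)) {
    x <- report$expression
    json$expression <- list(
      n_induced = nrow(x$induced),
      n_inhibited = lapply(x$inhibited, nrow),
      n_common = nrow(x$common),
      venn_regions = if (!is.null(x$venn)) as.list(x$venn$regions))
    utils::write.table(x$calls, file.path(out_dir, "gene_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$promoters)) {
    s <- report$promoter_summary
    json$promoters <- list(counts = as.list(s$counts),
                           pct_all_genes = as.list(s$pct_all_genes))
    utils::write.table(report$promoters,
                       file.path(out_dir, "site_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$common_site_categories))
    json$common_site_categories <-
      as.list(report$common_site_categories$counts)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report — stages:",
      paste(intersect(c("triage", "expression", "promoters"), names(x)),
            collapse = ", "), "\n")
  if (!is.null(x$triage)) print(x$triage)
  if (!is.null(x$expression)) print(x$expression)
  if (!is.null(x$promoter_summary))
    cat("  promoter categories over", x$promoter_summary$n, "genes\n")
  invisible(x)
}

#' Packaged top-25 induced-gene fold-change table
#'
#' The representative top-25 genes induced by the IFN-gamma + LPS
#' stimulation, with linear fold changes relative to untreated control for
#' the stimulation alone and for stimulation in the presence of each of the
#' three inhibitors. Ships as a plain TSV; used to exercise the
#' fold-change-ratio inhibition criterion on published numbers.
#'
#' @return Data frame: gene_id, gene_name, fc_stim, fc_C01L_F03,
#'   fc_STATTIC, fc_STX0119.
#' @export
top25_fold_changes <- function() {
  path <- system.file("extdata", "top25_fold_changes.tsv",
                      package = "statscreen")
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
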
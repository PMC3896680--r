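#' Write a DCV report to disk
#'
#' Emits plain-text artifacts for a fitted analysis: `tests.tsv` (per
#' item x domain test results), `classification.tsv`, `kappa.tsv` (when
#' agreement was computed), `summary.json` (machine-readable counts,
#' parameters and a config fingerprint), `run_log.txt`, and — when a TACT
#' mapping is supplied — `questionnaire.txt` with the rendered final items.
#' Output contains no timestamps, so re-running with identical inputs and
#' seed reproduces the files byte for byte.
#'
#' @param fit A [dcv()] fit.
#' @param outdir Output directory (created if needed).
#' @param tact Optional [tact_mapping()] used to render the final
#'   questionnaire.
#' @param final_only Render only final items in the questionnaire file.
#' @return Invisibly, the paths written.
#' @export
write_dcv_report <- function(fit, outdir, tact = NULL, final_only = TRUE) {
  stopifnot(inherits(fit, "dcv"))
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE)) {
    stop_invalid("cannot create output directory '%s'", outdir)
  }
  paths <- character(0)
  tsv <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    paths <<- c(paths, p)
  }
  tsv(fit$tests, "tests.tsv")
  tsv(fit$classification, "classification.tsv")

  if (!is.null(fit$kappa)) {
    kt <- summary(fit)$kappa_table
    tsv(kt, "kappa.tsv")
  }

  s <- summary(fit)
  params <- fit$params
  summary_json <- list(
    params = params,
    n_items = nrow(fit$classification),
    n_included = s$n_included,
    outcome_counts = as.list(s$outcome_counts),
    final_per_domain = lapply(fit$final_items, identity),
    kappa_ci_method = "percentile bootstrap over items (unreported methods vary; see docs)",
    config_hash = config_hash(paste(deparse(params), collapse = ""))
  )
  pj <- file.path(outdir, "summary.json")
  jsonlite::write_json(summary_json, pj, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  paths <- c(paths, pj)

  if (!is.null(tact)) {
    q <- render_questionnaire(fit$bank, tact, final_only = final_only)
    pq <- file.path(outdir, "questionnaire.txt")
    writeLines(sprintf("%s\t%s", names(q), q), pq, useBytes = FALSE)
    paths <- c(paths, pq)
  }

  pl <- file.path(outdir, "run_log.txt")
  writeLines(c("dcvkit run log",
               sprintf("params: %s", paste(deparse(params), collapse = " ")),
               sprintf("seed: %s", params$seed %||% "none"),
               sprintf("config_hash: %s", summary_json$config_hash)), pl)
  paths <- c(paths, pl)
  invisible(paths)
}
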
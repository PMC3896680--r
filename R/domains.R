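#' Load a theoretical-domain set
#'
#' A domain set is the frame of reference for a discriminant content validity
#' (DCV) exercise: an ordered table of domain codes, labels, and the formal
#' definitions that judges use when allocating items. Two presets of the
#' Theoretical Domains Framework (TDF) ship with the package: `"tdf14"`, the
#' refined 14-domain framework, and `"tdf12"`, the original 12-domain
#' framework (no Optimism/Reinforcement split, merged Motivation and goals,
#' and including Nature of the behaviors).
#'
#' @param preset_or_file Either a preset name (`"tdf14"` or `"tdf12"`) or the
#'   path to a tab- or comma-delimited definitions file with columns
#'   `code`, `label`, `definition`.
#' @return A `domain_set`: a data frame with columns `code`, `label`,
#'   `definition`, in presentation order.
#' @examples
#' tdf <- load_domain_set("tdf14")
#' nrow(tdf)        # 14
#' tdf$label[1]     # "Knowledge"
#' @export
load_domain_set <- function(preset_or_file = "tdf14") {
  stopifnot(is.character(preset_or_file), length(preset_or_file) == 1L)
  if (preset_or_file %in% c("tdf14", "tdf12")) {
    path <- system.file("extdata", paste0(preset_or_file, "_domains.tsv"),
                        package = "dcvkit", mustWork = TRUE)
    return(read_domain_set(path))
  }
  if (!file.exists(preset_or_file)) {
    stop_invalid("unknown domain preset or unreadable file: '%s'", preset_or_file)
  }
  read_domain_set(preset_or_file)
}

#' Read a domain definitions file
#'
#' @param path Delimited file (tab or comma; sniffed from the header line)
#'   with columns `code`, `label`, `definition`.
#' @return A `domain_set` data frame.
#' @export
read_domain_set <- function(path) {
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  if (length(header) == 0L) stop_invalid("empty domain definitions file: '%s'", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, encoding = "UTF-8",
                          comment.char = "")
  as_domain_set(df)
}

#' @rdname read_domain_set
#' @param df A data frame with columns `code`, `label`, `definition`.
#' @export
as_domain_set <- function(df) {
  need <- c("code", "label", "definition")
  if (!all(need %in% names(df))) {
    stop_invalid("domain set needs columns %s", paste(need, collapse = ", "))
  }
  df <- df[, need]
  if (nrow(df) == 0L) stop_invalid("domain set is empty")
  df$code <- as.character(df$code)
  if (any(!nzchar(df$code))) stop_invalid("domain codes must be non-empty")
  dup <- unique(df$code[duplicated(df$code)])
  if (length(dup)) {
    stop_invalid("duplicate domain code(s): %s", paste(dup, collapse = ", "))
  }
  rownames(df) <- NULL
  class(df) <- c("domain_set", "data.frame")
  df
}

domain_codes <- function(domains) {
  stopifnot(inherits(domains, "domain_set") || is.data.frame(domains))
  as.character(domains$code)
}

#' @export
print.domain_set <- function(x, ...) {
  cat(sprintf("Domain set with %d domains\n", nrow(x)))
  print.data.frame(x[, c("code", "label")], row.names = FALSE)
  invisible(x)
}
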
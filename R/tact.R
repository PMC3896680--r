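# TACT templating: questionnaire items are stored generically with bracketed
# placeholders for the Target, Action, Context, and Time of the behavior of
# interest ("[A] in [C, T] with [Ta]"), plus [innovation/guideline] and
# [profession]. Rendering substitutes user-supplied wording for each token.

# canonical placeholder names and the aliases that may occur in templates
.tact_aliases <- c(
  "a" = "A", "action" = "A",
  "c" = "C", "context" = "C",
  "t" = "T", "time" = "T",
  "ta" = "Ta", "target" = "Ta",
  "innovation" = "innovation", "guideline" = "innovation",
  "innovation/guideline" = "innovation",
  "innovatie" = "innovation", "richtlijn" = "innovation",
  "innovatie/richtlijn" = "innovation",
  "profession" = "profession", "beroep" = "profession"
)

.tact_token_re <- "\\[([^][]+)\\]"

canonical_token <- function(token) {
  key <- tolower(trimws(token))
  unname(.tact_aliases[key])
}

# Decompose a template's bracketed tokens into canonical placeholder names.
# Comma-separated content such as "[C, T]" is a compound of two placeholders.
# Errors if any token is outside the placeholder grammar.
check_placeholders <- function(text) {
  m <- gregexpr(.tact_token_re, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(character(0))
  tokens <- regmatches(text, list(m))[[1]]
  inner <- sub("^\\[", "", sub("\\]$", "", tokens))
  parts <- unlist(strsplit(inner, ",", fixed = TRUE))
  canon <- canonical_token(parts)
  if (anyNA(canon)) {
    stop_invalid("unknown placeholder token(s) in template: %s",
                 paste(unique(trimws(parts[is.na(canon)])), collapse = ", "))
  }
  unique(canon)
}

#' Create a TACT mapping
#'
#' Specifies the wording substituted for each placeholder when rendering
#' items: `A` (action), `C` (context), `T` (time), `Ta` (target),
#' `innovation` (matches both `[innovation/guideline]` and the Dutch
#' `[innovatie/richtlijn]`), and `profession`. Only the placeholders that
#' actually occur in the rendered items need to be supplied.
#'
#' @param ... Named replacement strings, e.g. `A = "deliver PA counseling"`.
#'   Alias names (`action`, `target`, `guideline`, `beroep`, ...) are
#'   accepted and canonicalized.
#' @param language Language code the mapping is meant for (`"en"` or `"nl"`).
#' @return A `tact_mapping` object.
#' @examples
#' tact <- tact_mapping(A = "deliver PA counseling", C = "primary care",
#'                      T = "month", Ta = "patients")
#' render_item("I intend to [A] in [C] with [Ta] in the next [T]", tact)
#' @export
tact_mapping <- function(..., language = "en") {
  repl <- list(...)
  if (length(repl) && is.null(names(repl))) {
    stop_invalid("TACT replacements must be named")
  }
  canon <- canonical_token(names(repl))
  if (anyNA(canon)) {
    stop_invalid("unknown placeholder name(s): %s",
                 paste(names(repl)[is.na(canon)], collapse = ", "))
  }
  vals <- vapply(repl, function(v) as.character(v)[1], character(1))
  if (any(!nzchar(vals))) stop_invalid("TACT replacement text must be non-empty")
  if (!language %in% c("en", "nl")) {
    stop_invalid("unsupported language '%s' (use \"en\" or \"nl\")", language)
  }
  structure(list(map = stats::setNames(vals, canon), language = language),
            class = "tact_mapping")
}

#' Render a TACT-templated item
#'
#' Substitutes every placeholder in the item's template with the mapped
#' wording; compound tokens such as `[C, T]` expand part-wise
#' (`"primary care, this month"`). Rendering a placeholder-free text is the
#' identity, and a rendered item never retains a bracketed token.
#'
#' @param item Either a template string, or a single-row subset of an
#'   [item_bank][read_item_bank] (the text for `tact$language` is used).
#' @param tact A [tact_mapping()].
#' @return The rendered item text (character scalar).
#' @export
render_item <- function(item, tact) {
  stopifnot(inherits(tact, "tact_mapping"))
  if (is.data.frame(item)) {
    if (nrow(item) != 1L) stop_invalid("render_item() expects a single item")
    col <- paste0("text_", tact$language)
    text <- item[[col]]
    if (is.null(text) || is.na(text)) {
      stop_invalid("item '%s' has no %s text", item$item_id, tact$language)
    }
  } else {
    stopifnot(is.character(item), length(item) == 1L)
    text <- item
  }
  needed <- check_placeholders(text)
  missing <- setdiff(needed, names(tact$map))
  if (length(missing)) {
    stop_invalid("TACT mapping lacks placeholder(s): %s",
                 paste(missing, collapse = ", "))
  }
  out <- text
  m <- gregexpr(.tact_token_re, out, perl = TRUE)
  if (m[[1]][1] != -1L) {
    regmatches(out, m) <- list(vapply(regmatches(out, m)[[1]], function(tok) {
      inner <- sub("^\\[", "", sub("\\]$", "", tok))
      parts <- trimws(unlist(strsplit(inner, ",", fixed = TRUE)))
      paste(tact$map[canonical_token(parts)], collapse = ", ")
    }, character(1), USE.NAMES = FALSE))
  }
  out
}

#' Render a questionnaire from an item bank
#'
#' @param bank An [item_bank][read_item_bank].
#' @param tact A [tact_mapping()]; its `language` selects the text column.
#' @param final_only Render only items flagged as part of the final
#'   questionnaire.
#' @return Named character vector of rendered items (names = item ids).
#' @export
render_questionnaire <- function(bank, tact, final_only = FALSE) {
  stopifnot(inherits(bank, "item_bank"))
  rows <- if (final_only) bank[bank$final, , drop = FALSE] else bank
  out <- vapply(seq_len(nrow(rows)), function(i) {
    render_item(rows[i, , drop = FALSE], tact)
  }, character(1))
  stats::setNames(out, rows$item_id)
}
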
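#' Read a judge allocation file
#'
#' The long-format record of a DCV exercise: each row is one judge's
#' allocation of one item to one domain, with an allocation rank (1 = first
#' choice, up to 3) and a confidence rating. Confidence may be recorded
#' either as a fraction in \[0, 1\] or as a percentage in (1, 100\]; values
#' greater than 1 are interpreted as percent and divided by 100 on read, so
#' a judge who allocates an item to Knowledge "with confidence 60" is stored
#' at 0.60. A judge may leave an item unallocated (no rows); downstream
#' scoring treats such missing judgments as 0.
#'
#' @param path UTF-8 comma-delimited file (RFC 4180 quoting) with header
#'   `judge_id,item_id,rank,domain,confidence`.
#' @param domains Domain set every `domain` code must resolve against.
#' @param bank Optional [item_bank][read_item_bank]; if supplied, every
#'   `item_id` must resolve against it.
#' @return An `allocation_table` data frame with confidences as fractions.
#' @export
read_allocations <- function(path, domains = load_domain_set("tdf14"),
                             bank = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  as_allocation_table(df, domains = domains, bank = bank)
}

#' Validate a data frame of allocation records
#'
#' @param df Data frame with columns `judge_id`, `item_id`, `rank`, `domain`,
#'   `confidence`.
#' @inheritParams read_allocations
#' @return An `allocation_table` data frame.
#' @export
as_allocation_table <- function(df, domains = load_domain_set("tdf14"),
                                bank = NULL) {
  need <- c("judge_id", "item_id", "rank", "domain", "confidence")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_invalid("allocation table lacks column(s): %s", paste(miss, collapse = ", "))
  }
  df <- df[, need]
  df$judge_id <- as.character(df$judge_id)
  df$item_id <- as.character(df$item_id)
  df$domain <- as.character(df$domain)
  df$rank <- as.integer(df$rank)
  df$confidence <- as.numeric(df$confidence)

  if (nrow(df)) {
    if (anyNA(df$rank) || any(!df$rank %in% 1:3)) {
      stop_invalid("allocation rank must be 1, 2, or 3")
    }
    if (anyNA(df$confidence) || any(df$confidence < 0 | df$confidence > 100)) {
      stop_invalid("confidence must lie in [0, 100] (percent) or [0, 1] (fraction)")
    }
    # values above 1 are percentages
    pct <- df$confidence > 1
    df$confidence[pct] <- df$confidence[pct] / 100

    bad <- setdiff(unique(df$domain), domain_codes(domains))
    if (length(bad)) {
      stop_invalid("unknown domain code(s): %s", paste(bad, collapse = ", "))
    }
    if (!is.null(bank)) {
      badi <- setdiff(unique(df$item_id), bank$item_id)
      if (length(badi)) {
        stop_invalid("item id(s) not in the item bank: %s", paste(badi, collapse = ", "))
      }
    }

    key <- paste(df$judge_id, df$item_id, sep = "\r")
    for (k in unique(key)) {
      rows <- df[key == k, , drop = FALSE]
      who <- sprintf("judge '%s', item '%s'", rows$judge_id[1], rows$item_id[1])
      if (nrow(rows) > 3L) stop_invalid("more than 3 allocations for %s", who)
      if (anyDuplicated(rows$rank)) stop_invalid("duplicate rank for %s", who)
      if (anyDuplicated(rows$domain)) stop_invalid("duplicate domain for %s", who)
    }
  }
  rownames(df) <- NULL
  class(df) <- c("allocation_table", "data.frame")
  df
}

#' Write an allocation table
#'
#' Writes the records as UTF-8 CSV with confidences as fractions, so that
#' `read_allocations(write_allocations(x, f))` round-trips up to row order.
#'
#' @param table An `allocation_table`.
#' @param path Output file.
#' @export
write_allocations <- function(table, path) {
  stopifnot(inherits(table, "allocation_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

allocation_judges <- function(table) sort(unique(table$judge_id))
allocation_items <- function(table) sort(unique(table$item_id))

#' @export
print.allocation_table <- function(x, ...) {
  cat(sprintf("Allocation table: %d records, %d judges, %d items\n",
              nrow(x), length(unique(x$judge_id)), length(unique(x$item_id))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  invisible(x)
}
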
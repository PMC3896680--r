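# Replay of recorded DCV outcomes. When only the reported per-item flags of
# a completed exercise are available (no raw judge data), the inclusion
# taxonomy can still be applied to reproduce the item partition.

#' Apply the inclusion taxonomy to recorded DCV outcome flags
#'
#' Takes per-item recorded flags — was the intended-domain test significant
#' (`sig_intended`), which non-intended domains were co-allocated by more
#' than one judge (`coalloc`), and which non-intended domains the item was
#' significantly classified to (`sig_other`) — and applies the same taxonomy
#' as [classify_items()], without recomputing any statistic:
#' an item is included when `sig_intended` is true and both lists are empty;
#' it is misclassified when `sig_other` is non-empty; the remaining excluded
#' items are the ones allocated to the intended domain as well as additional
#' domains.
#'
#' @param fixture Data frame with columns `item_id`, `sig_intended`
#'   (logical), `coalloc`, `sig_other` (`;`-separated code lists, `""` for
#'   none); optionally `intended` (for the per-domain breakdown of included
#'   items). Defaults to the packaged [tdf_validation_results()].
#' @param domains Domain set used to order the per-domain counts.
#' @return A `dcv_replay` object: list with `items` (per-item outcomes) and
#'   `counts` (`included`, `excluded`, `multi_allocated_with_intended`,
#'   `misclassified`, `per_domain_final`).
#' @examples
#' rep <- replay_classification()
#' rep$counts$included          # 32
#' rep$counts$misclassified     # 8
#' @export
replay_classification <- function(fixture = tdf_validation_results(),
                                  domains = load_domain_set("tdf14")) {
  need <- c("item_id", "sig_intended", "coalloc", "sig_other")
  miss <- setdiff(need, names(fixture))
  if (length(miss)) {
    stop_invalid("fixture lacks column(s): %s", paste(miss, collapse = ", "))
  }
  dup <- unique(fixture$item_id[duplicated(fixture$item_id)])
  if (length(dup)) stop_invalid("duplicate item id(s): %s", paste(dup, collapse = ", "))

  co <- split_codes(ifelse(is.na(fixture$coalloc), "", fixture$coalloc))
  so <- split_codes(ifelse(is.na(fixture$sig_other), "", fixture$sig_other))
  sig_int <- as.logical(fixture$sig_intended)
  has_co <- lengths(co) > 0L
  has_so <- lengths(so) > 0L

  outcome <- ifelse(has_so, "misclassified",
             ifelse(has_co, "mixed",
             ifelse(sig_int, "pure_intended", "unclassified")))
  included <- outcome == "pure_intended"

  items <- data.frame(item_id = fixture$item_id, outcome = outcome,
                      include_final = included, stringsAsFactors = FALSE)

  per_domain <- NULL
  if ("intended" %in% names(fixture)) {
    codes <- domain_codes(domains)
    intended <- split_codes(fixture$intended)
    per_domain <- stats::setNames(vapply(codes, function(d) {
      sum(included & vapply(intended, function(v) d %in% v, logical(1)))
    }, integer(1)), codes)
  }

  counts <- list(included = sum(included),
                 excluded = sum(!included),
                 multi_allocated_with_intended = sum(!included & !has_so),
                 misclassified = sum(has_so),
                 per_domain_final = per_domain)
  structure(list(items = items, counts = counts), class = "dcv_replay")
}

#' @export
print.dcv_replay <- function(x, ...) {
  c <- x$counts
  cat(sprintf("Replayed DCV classification of %d items\n", nrow(x$items)))
  cat(sprintf("  included (pure intended): %d\n", c$included))
  cat(sprintf("  excluded: %d (%d co-allocated with intended, %d misclassified)\n",
              c$excluded, c$multi_allocated_with_intended, c$misclassified))
  if (!is.null(c$per_domain_final)) {
    cat("  final items per domain:\n")
    print(c$per_domain_final)
  }
  invisible(x)
}
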
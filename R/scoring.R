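# Confidence-weighted judgment scoring.
#
# A judge's allocation is coded +1 when it names the target domain (a
# "match") and -1 otherwise, then multiplied by the judge's confidence; a
# judge who did not allocate the item at all contributes 0. Because each
# judge has up to three allocations, the per-judge score against a target
# domain is the sum of the (at most three) weighted judgments, which is what
# the one-sample t-tests are run on.

#' Signed confidence weight of one allocation
#'
#' @param domain Allocated domain code(s).
#' @param confidence Confidence fraction(s) in \[0, 1\].
#' @param target Target domain code.
#' @return `+confidence` where `domain == target`, else `-confidence`.
#' @examples
#' signed_weight("D1", 0.6, "D1")   # +0.6
#' signed_weight("D2", 0.2, "D1")   # -0.2
#' @export
signed_weight <- function(domain, confidence, target) {
  stopifnot(length(target) == 1L)
  ifelse(domain == target, confidence, -confidence)
}

#' Per-judge weighted judgment score for one item
#'
#' Sums the signed confidence weights of one judge's allocations of one item
#' against a target domain. With no allocations the score is 0 (a missing
#' judgment); with a single allocation it lies in \[-1, 1\]; in general in
#' \[-3, 1\], since at most one of three distinct-domain allocations can
#' match the target.
#'
#' @param allocs An `allocation_table` subset holding one judge's records
#'   for one item (0-3 rows).
#' @param target Target domain code.
#' @return Numeric score.
#' @export
judge_item_score <- function(allocs, target) {
  if (nrow(allocs) == 0L) return(0)
  if (length(unique(allocs$judge_id)) > 1L || length(unique(allocs$item_id)) > 1L) {
    stop_invalid("judge_item_score() expects records from a single judge and item")
  }
  sum(signed_weight(allocs$domain, allocs$confidence, target))
}

#' Build the score matrix for a DCV analysis
#'
#' Determines the (item, target domain) pairs under test and computes the
#' per-judge weighted judgment score for each. Every item is tested against
#' its intended domain(s); in addition it is tested against every
#' non-intended domain that at least `min_coalloc` judges allocated it to
#' (the co-allocated domains, reported with a "> 1 judge" threshold by
#' default). `rank_scope` controls which allocations count toward that
#' co-allocation threshold: `"first"` (default) counts only judges whose
#' first-choice — i.e. preferred — domain was the co-allocated one, `"any"`
#' counts an allocation at any rank. Scores themselves always use all of a
#' judge's allocations.
#'
#' All enrolled judges contribute to every test; a judge without allocations
#' for an item scores 0, so n is constant across tests.
#'
#' @param table An `allocation_table`.
#' @param bank An [item_bank][read_item_bank]; items are taken from here.
#' @param min_coalloc Minimum number of judges allocating a non-intended
#'   domain for it to count as co-allocated (default 2, i.e. "> 1 judge").
#' @param rank_scope Allocation ranks counted toward co-allocation.
#' @return A `score_matrix`: list with `scores` (judges x pairs matrix),
#'   `pairs` (data frame `item_id`, `domain`, `intended`, `n_judges_alloc`),
#'   and `judges`.
#' @export
score_matrix <- function(table, bank, min_coalloc = 2,
                         rank_scope = c("first", "any")) {
  stopifnot(inherits(table, "allocation_table"), inherits(bank, "item_bank"))
  rank_scope <- match.arg(rank_scope)
  judges <- allocation_judges(table)
  if (length(judges) == 0L) stop_invalid("no judges in the allocation table")

  intended <- intended_list(bank)
  counted <- if (rank_scope == "first") table[table$rank == 1L, , drop = FALSE] else table

  pair_item <- character(0); pair_dom <- character(0)
  pair_int <- logical(0); pair_n <- integer(0)
  for (it in bank$item_id) {
    int_d <- intended[[it]]
    sub <- counted[counted$item_id == it, , drop = FALSE]
    n_by_dom <- tapply(sub$judge_id, sub$domain, function(j) length(unique(j)))
    co <- setdiff(names(n_by_dom)[n_by_dom >= min_coalloc], int_d)
    doms <- c(int_d, sort(co))
    pair_item <- c(pair_item, rep(it, length(doms)))
    pair_dom <- c(pair_dom, doms)
    pair_int <- c(pair_int, doms %in% int_d)
    cnt <- as.integer(n_by_dom[doms]); cnt[is.na(cnt)] <- 0L
    pair_n <- c(pair_n, cnt)
  }
  pairs <- data.frame(item_id = pair_item, domain = pair_dom,
                      intended = pair_int, n_judges_alloc = pair_n,
                      stringsAsFactors = FALSE)

  scores <- matrix(0, nrow = length(judges), ncol = nrow(pairs),
                   dimnames = list(judges, paste(pairs$item_id, pairs$domain, sep = ":")))
  for (p in seq_len(nrow(pairs))) {
    sub <- table[table$item_id == pairs$item_id[p], , drop = FALSE]
    if (nrow(sub) == 0L) next
    w <- signed_weight(sub$domain, sub$confidence, pairs$domain[p])
    s <- tapply(w, sub$judge_id, sum)
    scores[names(s), p] <- as.numeric(s)
  }
  structure(list(scores = scores, pairs = pairs, judges = judges,
                 min_coalloc = min_coalloc, rank_scope = rank_scope),
            class = "score_matrix")
}

# co-allocated (non-intended, above-threshold) domains per item
coalloc_domains <- function(sm) {
  p <- sm$pairs[!sm$pairs$intended, , drop = FALSE]
  out <- split(p$domain, p$item_id)
  items <- unique(sm$pairs$item_id)
  stats::setNames(lapply(items, function(it) out[[it]] %||% character(0)), items)
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("DCV score matrix: %d judges x %d (item, domain) test pairs (%d items)\n",
              length(x$judges), nrow(x$pairs), length(unique(x$pairs$item_id))))
  invisible(x)
}
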
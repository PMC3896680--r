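# One-tailed one-sample testing, FDR control, and the item taxonomy.

#' One-sample one-tailed t-test (H1: mean > 0)
#'
#' Student t-test of the null `mean == 0` against the one-sided alternative
#' `mean > 0`, using the sample standard deviation (n - 1 denominator). The
#' zero-variance conventions make degenerate perfect-agreement data well
#' defined: with `sd == 0`, p is 0 / 0.5 / 1 for positive / zero / negative
#' mean (t is `Inf` / 0 / `-Inf`).
#'
#' @param x Numeric vector of scores, length >= 2.
#' @return List with `n`, `mean`, `sd`, `t`, `df`, `p`.
#' @export
one_sample_t_greater <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop_invalid("one_sample_t_greater() needs at least 2 observations")
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) {
    t <- if (m > 0) Inf else if (m < 0) -Inf else 0
    p <- if (m > 0) 0 else if (m < 0) 1 else 0.5
  } else {
    t <- m / (s / sqrt(n))
    p <- stats::pt(t, df = n - 1, lower.tail = FALSE)
  }
  list(n = n, mean = m, sd = s, t = t, df = n - 1L, p = p)
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Sorts the p-values ascending (stable in the original order for ties),
#' finds the largest k with `p_(k) <= k * alpha / m`, and rejects the
#' hypotheses with the k smallest p-values. Also returns the BH-adjusted
#' p-values (monotone step-up adjustment), so `rejected` is equivalent to
#' `adjusted <= alpha`.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @param alpha Target false discovery rate (default 0.05).
#' @return List with `rejected` (logical, original order), `adjusted`
#'   (numeric, original order) and `k` (number of rejections).
#' @examples
#' bh_adjust(c(.001, .008, .039, .041, .042, .06))$rejected
#' @export
bh_adjust <- function(pvalues, alpha = 0.05) {
  p <- as.numeric(pvalues)
  if (length(p) == 0L) stop_invalid("bh_adjust() needs at least one p-value")
  if (anyNA(p) || any(p < 0 | p > 1)) stop_invalid("p-values must lie in [0, 1]")
  stopifnot(alpha > 0, alpha < 1)
  m <- length(p)
  o <- order(p)                      # stable: ties keep original index order
  ps <- p[o]
  thresh <- seq_len(m) * alpha / m
  k <- max(c(0L, which(ps <= thresh)))
  rejected <- logical(m)
  if (k > 0L) rejected[o[seq_len(k)]] <- TRUE
  adjusted <- numeric(m)
  adjusted[o] <- pmin(1, rev(cummin(rev(ps * m / seq_len(m)))))
  list(rejected = rejected, adjusted = adjusted, k = k)
}

#' Run the DCV tests on a score matrix
#'
#' One [one_sample_t_greater()] per (item, target domain) pair, with the
#' multiple-testing family spanning all computed tests in the run
#' (`fdr = "bh"`), or raw `p <= alpha` when `fdr = "none"`.
#'
#' @param sm A [score_matrix()].
#' @param alpha Significance level / FDR target.
#' @param fdr `"bh"` or `"none"`.
#' @return Data frame with one row per test pair: `item_id`, `domain`,
#'   `intended`, `n`, `mean`, `sd`, `t`, `df`, `p`, `p_adj`, `rejected`.
#' @export
dcv_tests <- function(sm, alpha = 0.05, fdr = c("bh", "none")) {
  stopifnot(inherits(sm, "score_matrix"))
  fdr <- match.arg(fdr)
  res <- lapply(seq_len(nrow(sm$pairs)), function(p) one_sample_t_greater(sm$scores[, p]))
  out <- cbind(sm$pairs[, c("item_id", "domain", "intended")],
               data.frame(n = vapply(res, `[[`, 0, "n"),
                          mean = vapply(res, `[[`, 0, "mean"),
                          sd = vapply(res, `[[`, 0, "sd"),
                          t = vapply(res, `[[`, 0, "t"),
                          df = vapply(res, `[[`, 0L, "df"),
                          p = vapply(res, `[[`, 0, "p")))
  if (fdr == "bh") {
    adj <- bh_adjust(out$p, alpha)
    out$p_adj <- adj$adjusted
    out$rejected <- adj$rejected
  } else {
    out$p_adj <- out$p
    out$rejected <- out$p <= alpha
  }
  out
}

#' Classify one item from its test results
#'
#' Applies the DCV inclusion taxonomy:
#' \describe{
#'   \item{misclassified}{some non-intended domain test rejected with a
#'     positive mean — the item measures a domain it was not designed for;}
#'   \item{mixed}{co-allocated domains present (and not misclassified) —
#'     the item was allocated to more than one domain;}
#'   \item{pure_intended}{an intended-domain test rejected with positive
#'     mean, no co-allocations, no non-intended rejection — the item is
#'     included in the final questionnaire;}
#'   \item{unclassified}{none of the above.}
#' }
#'
#' @param results Data frame of [dcv_tests()] rows for a single item
#'   (must include every intended-domain test for that item).
#' @param coalloc Character vector of co-allocated (non-intended,
#'   above-threshold) domain codes for the item.
#' @param intended Character vector of the item's intended domain codes.
#' @return List with `item_id`, `outcome`, `include_final`,
#'   `classified_domains`, `coallocated_domains`.
#' @export
classify_item <- function(results, coalloc, intended) {
  if (!all(intended %in% results$domain)) {
    stop_invalid("intended domain test(s) missing for item '%s'", results$item_id[1])
  }
  pos_rej <- results$rejected & results$mean > 0
  classified <- results$domain[pos_rej]
  intended_ok <- any(pos_rej & results$domain %in% intended)
  other_sig <- any(pos_rej & !results$domain %in% intended)
  coalloc <- setdiff(coalloc, intended)
  outcome <- if (other_sig) "misclassified"
    else if (length(coalloc)) "mixed"
    else if (intended_ok) "pure_intended"
    else "unclassified"
  list(item_id = results$item_id[1],
       outcome = outcome,
       include_final = identical(outcome, "pure_intended"),
       classified_domains = classified,
       coallocated_domains = coalloc)
}

#' Classify every item of a test table
#'
#' @param tests Output of [dcv_tests()].
#' @param sm The [score_matrix()] the tests came from (supplies the
#'   co-allocated domains).
#' @param bank The item bank (supplies intended domains).
#' @return Data frame with one row per item: `item_id`, `outcome`,
#'   `include_final`, `classified`, `coalloc` (`;`-separated lists).
#' @export
classify_items <- function(tests, sm, bank) {
  co <- coalloc_domains(sm)
  intended <- intended_list(bank)
  items <- unique(tests$item_id)
  rows <- lapply(items, function(it) {
    cl <- classify_item(tests[tests$item_id == it, , drop = FALSE],
                        co[[it]] %||% character(0), intended[[it]])
    data.frame(item_id = cl$item_id, outcome = cl$outcome,
               include_final = cl$include_final,
               classified = paste(cl$classified_domains, collapse = ";"),
               coalloc = paste(cl$coallocated_domains, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group the included items by intended domain
#'
#' @param classification Output of [classify_items()].
#' @param bank The item bank.
#' @param domains Domain set giving the grouping order.
#' @return Named list (one entry per domain code, possibly empty) of
#'   included item ids; items with two intended domains would be listed
#'   under each.
#' @export
select_final_items <- function(classification, bank, domains = load_domain_set("tdf14")) {
  codes <- domain_codes(domains)
  intended <- intended_list(bank)
  keep <- classification$item_id[classification$include_final]
  out <- stats::setNames(lapply(codes, function(d) {
    keep[vapply(intended[keep], function(v) d %in% v, logical(1))]
  }), codes)
  out
}
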
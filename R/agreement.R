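# Inter-rater agreement. Judges' allocations are summarized either as the
# first-choice label matrix (items x judges, entries = the first domain each
# judge selected, i.e. their preferred domain) or as per-domain binary
# matrices (did the judge allocate the item to that domain at all). Light's
# kappa -- the mean of Cohen's kappa over all judge pairs -- is the
# multi-rater agreement coefficient used on both.

#' Cohen's kappa for two label vectors
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with expected
#' agreement from the product of the raters' marginal label proportions.
#' Missing entries are removed pairwise. The degenerate case `p_e == 1`
#' (both raters constant on the same label) returns 1 when observed
#' agreement is perfect and 0 otherwise, so perfect-agreement data do not
#' fault.
#'
#' @param a,b Equal-length label vectors (character or factor); `NA` allowed.
#' @return Kappa in \[-1, 1\].
#' @examples
#' cohen_kappa(c("x", "x", "y", "y"), c("x", "y", "y", "y"))  # 0.5
#' @export
cohen_kappa <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (length(a) != length(b)) stop_invalid("label vectors differ in length")
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop_invalid("no complete rating pairs")
  a <- a[ok]; b <- b[ok]
  po <- mean(a == b)
  labs <- union(a, b)
  pa <- tabulate(match(a, labs), length(labs)) / length(a)
  pb <- tabulate(match(b, labs), length(labs)) / length(b)
  pe <- sum(pa * pb)
  if (pe >= 1) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Light's kappa for a rating matrix
#'
#' The unweighted mean of [cohen_kappa()] over all pairs of raters
#' (columns). For two raters it reduces exactly to Cohen's kappa.
#'
#' @param m Items x raters matrix (or data frame) of labels; `NA` allowed.
#' @return Mean pairwise kappa.
#' @export
light_kappa <- function(m) {
  m <- as.matrix(m)
  r <- ncol(m)
  if (r < 2L) stop_invalid("Light's kappa needs at least 2 raters")
  pairs <- utils::combn(r, 2)
  mean(apply(pairs, 2, function(ij) cohen_kappa(m[, ij[1]], m[, ij[2]])))
}

#' First-choice label matrix
#'
#' Items x judges matrix of the first-ranked domain each judge allocated an
#' item to; `NA` where a judge did not allocate the item.
#'
#' @param table An `allocation_table`.
#' @param items Row universe (defaults to the items present in the table;
#'   pass `bank$item_id` to include never-allocated items as all-`NA` rows).
#' @return Character matrix with `items` rows and one column per judge.
#' @export
first_choice_matrix <- function(table, items = NULL) {
  stopifnot(inherits(table, "allocation_table"))
  judges <- allocation_judges(table)
  items <- items %||% allocation_items(table)
  m <- matrix(NA_character_, nrow = length(items), ncol = length(judges),
              dimnames = list(items, judges))
  first <- table[table$rank == 1L & table$item_id %in% items, , drop = FALSE]
  m[cbind(match(first$item_id, items), match(first$judge_id, judges))] <- first$domain
  m
}

#' Per-domain binary allocation matrix
#'
#' Items x judges matrix of 0/1: did the judge allocate the item to the
#' target domain. `rank_scope = "any"` (default) counts an allocation at any
#' of the judge's up-to-three ranks; `"first"` restricts to first choices.
#'
#' @param table An `allocation_table`.
#' @param domain Target domain code.
#' @param rank_scope `"any"` or `"first"`.
#' @param items Row universe (defaults to items present in the table).
#' @return Integer 0/1 matrix.
#' @export
domain_binary_matrix <- function(table, domain, rank_scope = c("any", "first"),
                                 items = NULL) {
  stopifnot(inherits(table, "allocation_table"))
  rank_scope <- match.arg(rank_scope)
  judges <- allocation_judges(table)
  items <- items %||% allocation_items(table)
  sub <- table[table$domain == domain & table$item_id %in% items, , drop = FALSE]
  if (rank_scope == "first") sub <- sub[sub$rank == 1L, , drop = FALSE]
  m <- matrix(0L, nrow = length(items), ncol = length(judges),
              dimnames = list(items, judges))
  m[cbind(match(sub$item_id, items), match(sub$judge_id, judges))] <- 1L
  m
}

#' Agreement on the allocation of items to one domain
#'
#' Builds the per-domain binary matrix and returns Light's kappa over the
#' judges. Judges who never allocated any of the items to the domain carry
#' no information about agreement on it; with `drop_empty_raters = TRUE`
#' (default) their all-zero columns are removed and recorded.
#'
#' @param table An `allocation_table`.
#' @param domain Target domain code.
#' @param drop_empty_raters Drop judges with all-zero columns.
#' @param rank_scope Passed to [domain_binary_matrix()].
#' @param items Row universe.
#' @param n_boot Bootstrap resamples for a 95% CI (0 = no CI).
#' @param seed RNG seed for the bootstrap.
#' @return A `kappa_result`: list with `scope`, `kappa`, `ci_low`,
#'   `ci_high`, `n_raters_used`, `excluded_raters`.
#' @export
domain_kappa <- function(table, domain, drop_empty_raters = TRUE,
                         rank_scope = c("any", "first"), items = NULL,
                         n_boot = 0, seed = NULL) {
  m <- domain_binary_matrix(table, domain, rank_scope = rank_scope, items = items)
  excluded <- character(0)
  if (drop_empty_raters) {
    empty <- colSums(m) == 0L
    excluded <- colnames(m)[empty]
    m <- m[, !empty, drop = FALSE]
  }
  if (ncol(m) < 2L) {
    stop_invalid("fewer than 2 raters remain for domain '%s'", domain)
  }
  k <- light_kappa(m)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) ci <- bootstrap_kappa_ci(m, light_kappa, n_boot = n_boot, seed = seed)
  kappa_result(scope = domain, kappa = k, ci_low = ci[1], ci_high = ci[2],
               n_raters_used = ncol(m), excluded_raters = excluded)
}

#' Overall agreement across all items and domains
#'
#' Light's kappa on the first-choice label matrix.
#'
#' @inheritParams domain_kappa
#' @export
overall_kappa <- function(table, items = NULL, n_boot = 0, seed = NULL) {
  m <- first_choice_matrix(table, items = items)
  k <- light_kappa(m)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) ci <- bootstrap_kappa_ci(m, light_kappa, n_boot = n_boot, seed = seed)
  kappa_result(scope = "overall", kappa = k, ci_low = ci[1], ci_high = ci[2],
               n_raters_used = ncol(m), excluded_raters = character(0))
}

kappa_result <- function(scope, kappa, ci_low, ci_high, n_raters_used,
                         excluded_raters) {
  structure(list(scope = scope, kappa = kappa, ci_low = ci_low,
                 ci_high = ci_high, n_raters_used = n_raters_used,
                 excluded_raters = excluded_raters,
                 ci_method = "percentile bootstrap over items"),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  ci <- if (is.na(x$ci_low)) "" else sprintf(" (95%% CI %.2f-%.2f)", x$ci_low, x$ci_high)
  cat(sprintf("kappa[%s] = %.3f%s, %d raters%s\n", x$scope, x$kappa, ci,
              x$n_raters_used,
              if (length(x$excluded_raters))
                sprintf(" (%d excluded)", length(x$excluded_raters)) else ""))
  invisible(x)
}

#' Percentile bootstrap CI for an agreement statistic
#'
#' Resamples items (rows) with replacement `n_boot` times and returns the
#' 2.5% and 97.5% quantiles of the recomputed statistic. The resampling is
#' over items because items, not judges, are the sampling units of a DCV
#' exercise. Deterministic given `seed`.
#'
#' @param m Items x raters rating matrix.
#' @param statistic Function of such a matrix returning a scalar
#'   (default [light_kappa()]).
#' @param n_boot Number of resamples (>= 100).
#' @param seed RNG seed.
#' @param level Confidence level.
#' @return Numeric `c(ci_low, ci_high)`.
#' @export
bootstrap_kappa_ci <- function(m, statistic = light_kappa, n_boot = 1000,
                               seed = NULL, level = 0.95) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop_invalid("bootstrap needs at least 2 items")
  if (n_boot < 100) stop_invalid("n_boot must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  stats_b <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(nrow(m), replace = TRUE)
    statistic(m[idx, , drop = FALSE])
  }, numeric(1))
  a <- (1 - level) / 2
  unname(stats::quantile(stats_b, c(a, 1 - a), na.rm = TRUE))
}

#' Correlation between judge performance and a judge covariate
#'
#' A judge's performance is their match count: the number of items for which
#' their allocation set includes an intended domain of the item. Returns the
#' Pearson correlation between match counts and a per-judge covariate such
#' as mean self-rated expertise or academic level.
#'
#' @param table An `allocation_table`.
#' @param bank The item bank (supplies intended domains).
#' @param covariate Numeric vector, either named by judge id or in the order
#'   of `sort(unique(table$judge_id))`.
#' @return List with `r` (Pearson correlation) and `matches` (named counts).
#' @export
judge_match_correlation <- function(table, bank, covariate) {
  stopifnot(inherits(table, "allocation_table"))
  judges <- allocation_judges(table)
  intended <- intended_list(bank)
  matches <- vapply(judges, function(j) {
    sub <- table[table$judge_id == j, , drop = FALSE]
    hits <- vapply(unique(sub$item_id), function(it) {
      any(sub$domain[sub$item_id == it] %in% intended[[it]])
    }, logical(1))
    sum(hits)
  }, numeric(1))
  cov <- if (!is.null(names(covariate))) {
    miss <- setdiff(judges, names(covariate))
    if (length(miss)) stop_invalid("covariate missing judge(s): %s", paste(miss, collapse = ", "))
    as.numeric(covariate[judges])
  } else {
    if (length(covariate) != length(judges)) {
      stop_invalid("covariate length %d does not match %d judges",
                   length(covariate), length(judges))
    }
    as.numeric(covariate)
  }
  if (stats::sd(matches) == 0 || stats::sd(cov) == 0) {
    stop_invalid("zero variance in match counts or covariate")
  }
  list(r = stats::cor(matches, cov), matches = matches)
}
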
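#' Fit a discriminant content validity analysis
#'
#' The full DCV pipeline on a judge allocation table: confidence-weighted
#' judgment scoring ([score_matrix()]), one-tailed one-sample t-tests with
#' Benjamini-Hochberg FDR control across all computed tests ([dcv_tests()]),
#' the pure/mixed/misclassified/unclassified item taxonomy
#' ([classify_items()]), final-item selection, and inter-rater agreement
#' (overall and per-domain Light's kappa, for all items and for the final
#' items).
#'
#' @param allocations An `allocation_table` (see [read_allocations()]).
#' @param bank An [item_bank][read_item_bank] (default: the packaged 79-item
#'   TDF bank).
#' @param domains Domain set (default `"tdf14"`).
#' @param alpha Significance level / FDR target (default 0.05).
#' @param fdr `"bh"` (Benjamini-Hochberg across all tests in the run) or
#'   `"none"` (raw `p <= alpha`).
#' @param min_coalloc Judges needed for a non-intended domain to count as
#'   co-allocated (default 2, "> 1 judge").
#' @param rank_scope Ranks counted toward co-allocation; see [score_matrix()].
#' @param kappa Compute agreement coefficients (set `FALSE` to skip).
#' @param n_boot Bootstrap resamples for kappa CIs (0 = point estimates only).
#' @param seed RNG seed for the bootstrap.
#' @return An object of class `dcv`: a list with elements `tests`,
#'   `classification`, `final_items`, `kappa`, `scores`, `params`, `call`.
#' @examples
#' sim <- simulate_allocations(reference_scenario(), seed = 1)
#' fit <- dcv(sim$table, bank = sim_item_bank(reference_scenario()), kappa = FALSE)
#' fit
#' @export
dcv <- function(allocations, bank = tdf_item_bank(),
                domains = load_domain_set("tdf14"),
                alpha = 0.05, fdr = c("bh", "none"), min_coalloc = 2,
                rank_scope = c("first", "any"), kappa = TRUE,
                n_boot = 0, seed = NULL) {
  fdr <- match.arg(fdr)
  rank_scope <- match.arg(rank_scope)
  stopifnot(alpha > 0, alpha < 1)
  if (!inherits(allocations, "allocation_table")) {
    allocations <- as_allocation_table(allocations, domains = domains, bank = bank)
  }
  if (nrow(allocations) == 0L) stop_invalid("no judges: the allocation table is empty")

  sm <- score_matrix(allocations, bank, min_coalloc = min_coalloc,
                     rank_scope = rank_scope)
  tests <- dcv_tests(sm, alpha = alpha, fdr = fdr)
  classification <- classify_items(tests, sm, bank)
  final_items <- select_final_items(classification, bank, domains)

  kap <- NULL
  if (kappa) {
    final_ids <- classification$item_id[classification$include_final]
    kap <- list(overall_all = overall_kappa(allocations, n_boot = n_boot, seed = seed))
    kap$overall_final <- if (length(final_ids) >= 2L) {
      tryCatch(overall_kappa(allocations[allocations$item_id %in% final_ids, ,
                                         drop = FALSE],
                             items = final_ids, n_boot = n_boot, seed = seed),
               dcvkit_validation_error = function(e) NULL)
    }
    kap$per_domain <- lapply(stats::setNames(nm = domain_codes(domains)), function(d) {
      tryCatch(domain_kappa(allocations, d, n_boot = n_boot, seed = seed),
               dcvkit_validation_error = function(e) NULL)
    })
  }

  structure(list(tests = tests, classification = classification,
                 final_items = final_items, kappa = kap, scores = sm,
                 params = list(alpha = alpha, fdr = fdr,
                               min_coalloc = min_coalloc,
                               rank_scope = rank_scope, n_boot = n_boot,
                               seed = seed,
                               n_judges = length(sm$judges),
                               n_items = nrow(bank)),
                 bank = bank, domains = domains, call = match.call()),
            class = "dcv")
}

#' @export
print.dcv <- function(x, ...) {
  cl <- x$classification
  cat("Discriminant content validity analysis\n")
  cat(sprintf("  %d items, %d judges, %d domains; %d (item, domain) tests\n",
              x$params$n_items, x$params$n_judges, nrow(x$domains), nrow(x$tests)))
  cat(sprintf("  alpha = %g, FDR = %s, co-allocation threshold = %d judge(s), rank scope = %s\n",
              x$params$alpha, x$params$fdr, x$params$min_coalloc, x$params$rank_scope))
  tab <- table(factor(cl$outcome, levels = c("pure_intended", "mixed",
                                             "misclassified", "unclassified")))
  cat(sprintf("  included (pure intended): %d of %d\n", sum(cl$include_final), nrow(cl)))
  cat(sprintf("  excluded: %d mixed, %d misclassified, %d unclassified\n",
              tab[["mixed"]], tab[["misclassified"]], tab[["unclassified"]]))
  if (!is.null(x$kappa)) {
    cat(sprintf("  overall Light's kappa (all items): %.2f\n",
                x$kappa$overall_all$kappa))
  }
  invisible(x)
}

#' @export
summary.dcv <- function(object, ...) {
  cl <- object$classification
  kt <- NULL
  if (!is.null(object$kappa)) {
    rows <- c(list(object$kappa$overall_all),
              if (!is.null(object$kappa$overall_final)) list(object$kappa$overall_final),
              Filter(Negate(is.null), object$kappa$per_domain))
    scopes <- vapply(rows, `[[`, "", "scope")
    scopes[1] <- "overall (all items)"
    if (!is.null(object$kappa$overall_final)) scopes[2] <- "overall (final items)"
    kt <- data.frame(scope = scopes,
                     kappa = vapply(rows, `[[`, 0, "kappa"),
                     ci_low = vapply(rows, `[[`, 0, "ci_low"),
                     ci_high = vapply(rows, `[[`, 0, "ci_high"),
                     n_raters = vapply(rows, `[[`, 0L, "n_raters_used"),
                     stringsAsFactors = FALSE)
  }
  structure(list(tests = object$tests, classification = cl,
                 outcome_counts = table(cl$outcome),
                 n_included = sum(cl$include_final),
                 final_items = object$final_items, kappa_table = kt,
                 params = object$params),
            class = "summary.dcv")
}

#' @export
print.summary.dcv <- function(x, ...) {
  cat(sprintf("DCV summary: %d of %d items included\n", x$n_included,
              nrow(x$classification)))
  print(x$outcome_counts)
  cat("\nFinal items per domain:\n")
  print(vapply(x$final_items, length, 0L))
  if (!is.null(x$kappa_table)) {
    cat("\nAgreement (Light's kappa):\n")
    print(x$kappa_table, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Mean weighted judgments of a fitted DCV analysis
#'
#' @param object A [dcv()] fit.
#' @param which `"intended"` (default) for the intended-domain tests only,
#'   `"all"` for every computed test pair.
#' @param ... Unused.
#' @return Named numeric vector of per-test mean weighted judgment scores
#'   (names `"item:domain"`).
#' @export
coef.dcv <- function(object, which = c("intended", "all"), ...) {
  which <- match.arg(which)
  t <- object$tests
  if (which == "intended") t <- t[t$intended, , drop = FALSE]
  stats::setNames(t$mean, paste(t$item_id, t$domain, sep = ":"))
}

#' Dot plot of intended-domain mean weighted judgments
#'
#' One point per item (its intended-domain mean weighted judgment), coloured
#' by classification outcome; the dashed line at 0 is the null the one-sided
#' tests are run against.
#'
#' @param x A [dcv()] fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dcv <- function(x, ...) {
  t <- x$tests[x$tests$intended, , drop = FALSE]
  t <- t[!duplicated(t$item_id), , drop = FALSE]
  cl <- x$classification$outcome[match(t$item_id, x$classification$item_id)]
  pal <- c(pure_intended = "#1b7837", mixed = "#762a83",
           misclassified = "#d73027", unclassified = "grey50")
  ord <- order(t$mean)
  graphics::plot(t$mean[ord], seq_along(ord), col = pal[cl[ord]], pch = 19,
                 xlab = "mean weighted judgment (intended domain)",
                 ylab = "item (sorted)", xlim = c(-1, 1), ...)
  graphics::abline(v = 0, lty = 2)
  graphics::legend("topleft", legend = names(pal), col = pal, pch = 19,
                   bty = "n", cex = 0.8)
  invisible(x)
}
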
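# Synthetic judge-allocation data with the statistical structure a DCV
# analysis assumes: each judge draws a "true" domain for an item from the
# item's domain profile, passes it through a judge confusion matrix, may add
# a second and third distinct allocation, and attaches Beta-distributed
# confidence ratings that are sorted decreasing by rank and rescaled so one
# judge's confidences for an item sum to at most 1.

#' Build a simulation configuration
#'
#' @param n_judges Number of judges.
#' @param profiles Items x domains row-stochastic matrix: the probability
#'   that an item's content evokes each domain. Row names are item ids,
#'   column names domain codes.
#' @param intended Named list (by item id) of intended domain code(s) — the
#'   design ground truth the recovery analysis is scored against.
#' @param design Named character vector (by item id) labelling each item's
#'   designed status, e.g. `"pure"`, `"mixed"`, `"misdesigned"`.
#' @param p_second,p_third Probability that a judge adds a 2nd (and then a
#'   3rd) distinct allocation; `0 <= p_third <= p_second <= 1`.
#' @param confusion Domains x domains row-stochastic matrix: probability the
#'   judge allocates domain j given the drawn true domain i. Identity =
#'   perfectly discriminating judges.
#' @param conf_mean Mean(s) of the Beta law for confidence ratings: either a
#'   single value for all ranks or one value per rank (length 3), emulating
#'   judges whose secondary allocations carry much lower confidence than
#'   their first choice.
#' @param conf_conc Concentration of the Beta law
#'   (`shape1 = mean * conc`, `shape2 = (1 - mean) * conc`); `Inf` makes
#'   confidences deterministic at `conf_mean`.
#' @param sort_confidence Sort a judge's confidences decreasing by rank, so
#'   the first choice carries the highest confidence.
#' @param rescale_confidence Rescale a judge's confidences for one item to
#'   sum to at most 1.
#' @param seed Default RNG seed used by [simulate_allocations()].
#' @return A `dcv_sim_config` object.
#' @export
sim_config <- function(n_judges, profiles, intended, design = NULL,
                       p_second = 0, p_third = 0, confusion = NULL,
                       conf_mean = c(0.6, 0.2, 0.1), conf_conc = 8,
                       sort_confidence = TRUE, rescale_confidence = TRUE,
                       seed = 1L) {
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles)) || is.null(colnames(profiles))) {
    stop_invalid("profiles needs item row names and domain column names")
  }
  if (any(profiles < 0) || any(abs(rowSums(profiles) - 1) > 1e-8)) {
    stop_invalid("profile rows must be non-negative and sum to 1")
  }
  if (is.null(confusion)) {
    confusion <- diag(ncol(profiles))
    dimnames(confusion) <- list(colnames(profiles), colnames(profiles))
  }
  confusion <- as.matrix(confusion)
  if (!identical(dim(confusion), rep(ncol(profiles), 2L)) &&
      !identical(dim(confusion), as.integer(rep(ncol(profiles), 2L)))) {
    stop_invalid("confusion must be a square domains x domains matrix")
  }
  if (any(confusion < 0) || any(abs(rowSums(confusion) - 1) > 1e-8)) {
    stop_invalid("confusion rows must be non-negative and sum to 1")
  }
  if (!(p_third >= 0 && p_second >= p_third && p_second <= 1)) {
    stop_invalid("need 0 <= p_third <= p_second <= 1")
  }
  if (!length(conf_mean) %in% c(1L, 3L) || any(conf_mean <= 0 | conf_mean > 1)) {
    stop_invalid("conf_mean must be 1 or 3 values in (0, 1]")
  }
  if (conf_conc <= 0) stop_invalid("conf_conc must be positive")
  miss <- setdiff(rownames(profiles), names(intended))
  if (length(miss)) stop_invalid("intended domains missing for item(s): %s",
                                 paste(utils::head(miss, 5), collapse = ", "))
  bad <- setdiff(unlist(intended), colnames(profiles))
  if (length(bad)) stop_invalid("intended code(s) not in profile columns: %s",
                                paste(bad, collapse = ", "))
  structure(list(n_judges = n_judges, profiles = profiles,
                 intended = intended[rownames(profiles)],
                 design = design, p_second = p_second, p_third = p_third,
                 confusion = confusion, conf_mean = conf_mean,
                 conf_conc = conf_conc, sort_confidence = sort_confidence,
                 rescale_confidence = rescale_confidence,
                 seed = as.integer(seed)),
            class = "dcv_sim_config")
}

#' Reference simulation scenario
#'
#' The study design the packaged item bank was validated under: 19 judges,
#' 79 items, the 14 TDF domains. Of the 79 items, 60 are designed pure
#' (profile mass 0.9 on the intended domain, remainder uniform), 15 are
#' two-domain mixed (0.45/0.45 on the intended and a companion domain), and
#' 4 are misdesigned (mass 0.9 on a non-intended domain). Judges add a
#' second allocation with probability 0.5 and a third with 0.15, discriminate
#' perfectly between evoked domains (identity confusion), and rate
#' confidence from Beta laws with rank-wise means 0.6/0.2/0.1 — secondary
#' allocations are tentative alternatives, as in the worked 60%/20%
#' two-allocation example the scoring rule is defined by.
#'
#' @param seed RNG seed stored in the configuration.
#' @return A `dcv_sim_config`.
#' @export
reference_scenario <- function(seed = 1L) {
  domains <- domain_codes(load_domain_set("tdf14"))
  nd <- length(domains)
  n_pure <- 60; n_mixed <- 15; n_mis <- 4
  ids <- c(sprintf("P%02d", seq_len(n_pure)),
           sprintf("M%02d", seq_len(n_mixed)),
           sprintf("X%02d", seq_len(n_mis)))
  profiles <- matrix(0, nrow = length(ids), ncol = nd,
                     dimnames = list(ids, domains))
  intended <- vector("list", length(ids)); names(intended) <- ids
  design <- stats::setNames(rep(c("pure", "mixed", "misdesigned"),
                                c(n_pure, n_mixed, n_mis)), ids)
  for (i in seq_len(n_pure)) {
    d <- domains[(i - 1L) %% nd + 1L]
    profiles[i, ] <- 0.1 / (nd - 1)
    profiles[i, d] <- 0.9
    intended[[i]] <- d
  }
  for (i in seq_len(n_mixed)) {
    d1 <- domains[(i - 1L) %% nd + 1L]
    d2 <- domains[i %% nd + 1L]
    row <- n_pure + i
    profiles[row, ] <- 0.1 / (nd - 2)
    profiles[row, c(d1, d2)] <- 0.45
    intended[[row]] <- d1
  }
  for (i in seq_len(n_mis)) {
    d_int <- domains[(i - 1L) %% nd + 1L]
    d_true <- domains[(i + 5L) %% nd + 1L]   # mass sits on an unrelated domain
    row <- n_pure + n_mixed + i
    profiles[row, ] <- 0.1 / (nd - 1)
    profiles[row, d_true] <- 0.9 + 0.1 / (nd - 1)
    profiles[row, d_int] <- 0
    intended[[row]] <- d_int
  }
  sim_config(n_judges = 19, profiles = profiles, intended = intended,
             design = design, p_second = 0.5, p_third = 0.15,
             conf_mean = c(0.6, 0.2, 0.1), conf_conc = 8, seed = seed)
}

#' Simulate a judge allocation table
#'
#' For each judge x item, draws a first-choice domain from the item profile
#' composed with the judge confusion matrix; with probability `p_second`
#' (then `p_third`) adds further allocations to distinct domains drawn from
#' the same composed law conditioned away from domains already used (falling
#' back to uniform over the remainder when that law has no mass left).
#' Confidences are Beta draws, sorted decreasing by rank when
#' `sort_confidence`, and divided by their sum when it exceeds 1 and
#' `rescale_confidence` is on. Fully deterministic given the seed.
#'
#' @param config A [sim_config()].
#' @param seed Overrides `config$seed`.
#' @return List with `table` (an `allocation_table`) and `truth` (data frame
#'   `item_id`, `design`, `intended`).
#' @export
simulate_allocations <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "dcv_sim_config"))
  set.seed(seed)
  domains <- colnames(config$profiles)
  items <- rownames(config$profiles)
  # composed law: P(allocated domain) = profile %*% confusion, per item
  alloc_law <- config$profiles %*% config$confusion

  judge_ids <- sprintf("J%02d", seq_len(config$n_judges))
  recs <- vector("list", length(judge_ids) * length(items))
  k <- 0L
  for (j in judge_ids) {
    for (it in items) {
      law <- alloc_law[it, ]
      n_alloc <- 1L
      if (stats::runif(1) < config$p_second) {
        n_alloc <- 2L
        if (stats::runif(1) < config$p_third) n_alloc <- 3L
      }
      chosen <- character(0)
      for (r in seq_len(n_alloc)) {
        w <- law
        w[chosen] <- 0
        if (sum(w) <= 0) w[setdiff(domains, chosen)] <- 1
        chosen <- c(chosen, sample(domains, 1L, prob = w))
      }
      mu <- rep_len(config$conf_mean, 3L)[seq_len(n_alloc)]
      conf <- if (is.infinite(config$conf_conc) || all(mu == 1)) mu else
        stats::rbeta(n_alloc, mu * config$conf_conc, (1 - mu) * config$conf_conc)
      if (config$sort_confidence) conf <- sort(conf, decreasing = TRUE)
      if (config$rescale_confidence && sum(conf) > 1) conf <- conf / sum(conf)
      k <- k + 1L
      recs[[k]] <- data.frame(judge_id = j, item_id = it,
                              rank = seq_len(n_alloc), domain = chosen,
                              confidence = conf, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, recs[seq_len(k)])
  dom_set <- as_domain_set(data.frame(code = domains, label = domains,
                                      definition = domains,
                                      stringsAsFactors = FALSE))
  table <- as_allocation_table(df, domains = dom_set)
  truth <- data.frame(item_id = items,
                      design = if (is.null(config$design)) NA_character_
                               else unname(config$design[items]),
                      intended = join_codes(config$intended[items]),
                      stringsAsFactors = FALSE)
  list(table = table, truth = truth)
}

#' Turn a simulation configuration into an item bank
#'
#' The generated items carry no questionnaire text; this wraps the ground
#' truth into a minimal [item_bank][read_item_bank] so the scoring and
#' classification pipeline can run on simulated data.
#'
#' @param config A [sim_config()].
#' @return An `item_bank` with placeholder-free text.
#' @export
sim_item_bank <- function(config) {
  stopifnot(inherits(config, "dcv_sim_config"))
  items <- rownames(config$profiles)
  dom_set <- as_domain_set(data.frame(code = colnames(config$profiles),
                                      label = colnames(config$profiles),
                                      definition = colnames(config$profiles),
                                      stringsAsFactors = FALSE))
  as_item_bank(data.frame(item_id = items,
                          intended = join_codes(config$intended[items]),
                          construct = if (is.null(config$design)) "simulated"
                                      else unname(config$design[items]),
                          final = 0L,
                          text_en = paste("Simulated item", items),
                          stringsAsFactors = FALSE),
               domains = dom_set)
}
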
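# Small builders used across the suite. Fixtures are constructed in code so
# every test starts from a minimal, fully visible state.

toy_domains <- function(n = 3) {
  as_domain_set(data.frame(code = paste0("D", seq_len(n)),
                           label = paste("Domain", seq_len(n)),
                           definition = paste("Definition", seq_len(n)),
                           stringsAsFactors = FALSE))
}

toy_bank <- function(item_id, intended, domains = toy_domains(),
                     construct = "Construct", final = 0L,
                     text_en = "Item text") {
  as_item_bank(data.frame(item_id = item_id, intended = intended,
                          construct = construct, final = final,
                          text_en = text_en, stringsAsFactors = FALSE),
               domains = domains)
}

alloc <- function(judge, item, rank, domain, confidence,
                  domains = toy_domains(), bank = NULL) {
  as_allocation_table(data.frame(judge_id = judge, item_id = item,
                                 rank = rank, domain = domain,
                                 confidence = confidence,
                                 stringsAsFactors = FALSE),
                      domains = domains, bank = bank)
}

# a perfect-agreement exercise: every judge allocates every item to its
# intended domain, rank 1, full confidence
perfect_table <- function(n_judges, bank, domains) {
  g <- expand.grid(judge_id = sprintf("J%02d", seq_len(n_judges)),
                   item_id = bank$item_id, stringsAsFactors = FALSE)
  g$rank <- 1L
  first_intended <- vapply(strsplit(bank$intended, ";", fixed = TRUE),
                           `[`, character(1), 1L)
  g$domain <- first_intended[match(g$item_id, bank$item_id)]
  g$confidence <- 1
  as_allocation_table(g, domains = domains, bank = bank)
}

# independent brute-force Benjamini-Hochberg: largest k with p_(k) <= k*a/m,
# written as an explicit search over rejection counts
bh_brute <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k_star <- 0L
  for (k in seq_len(m)) if (ps[k] <= k * alpha / m) k_star <- k
  rej <- logical(m)
  if (k_star > 0) rej[o[seq_len(k_star)]] <- TRUE
  rej
}

# explicit pair-loop Light's kappa, independent of light_kappa()'s combn path
light_brute <- function(m) {
  r <- ncol(m)
  ks <- c()
  for (i in seq_len(r - 1)) for (j in (i + 1):r) {
    ks <- c(ks, cohen_kappa(m[, i], m[, j]))
  }
  mean(ks)
}
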
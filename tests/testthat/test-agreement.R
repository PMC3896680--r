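test_that("Cohen's kappa reproduces hand-computed values", {
  expect_equal(cohen_kappa(c("x", "x", "y"), c("x", "x", "y")), 1)
  # p_o = .75, p_e = .5
  expect_equal(cohen_kappa(c("x", "x", "y", "y"), c("x", "y", "y", "y")), 0.5)
  # constant rater: p_o = p_e -> 0
  expect_equal(cohen_kappa(c("x", "y"), c("x", "x")), 0)
  # both constant on the same label: degenerate convention
  expect_equal(cohen_kappa(c("x", "x"), c("x", "x")), 1)
  expect_error(cohen_kappa("x", c("x", "y")), "length")
  expect_error(cohen_kappa(NA_character_, "x"), "complete")
})

test_that("Light's kappa is the mean over judge pairs", {
  m <- cbind(j1 = c("a", "a", "b", "b", "c"),
             j2 = c("a", "b", "b", "b", "c"),
             j3 = c("a", "a", "b", "c", "c"))
  expect_equal(light_kappa(m), light_brute(m))
  expect_equal(light_kappa(m),
               mean(c(cohen_kappa(m[, 1], m[, 2]),
                      cohen_kappa(m[, 1], m[, 3]),
                      cohen_kappa(m[, 2], m[, 3]))))
  # two raters: exactly Cohen's kappa
  expect_equal(light_kappa(m[, 1:2]), cohen_kappa(m[, 1], m[, 2]))
  # identical raters: 1
  expect_equal(light_kappa(cbind(m[, 1], m[, 1], m[, 1])), 1)
  expect_error(light_kappa(m[, 1, drop = FALSE]), "at least 2")
})

test_that("Light's kappa is invariant to judge order and label names", {
  set.seed(8)
  m <- matrix(sample(letters[1:4], 60, replace = TRUE), ncol = 5)
  expect_equal(light_kappa(m[, sample(5)]), light_kappa(m))
  relab <- matrix(c(a = "w", b = "x", c = "y", d = "z")[m], ncol = 5)
  expect_equal(light_kappa(relab), light_kappa(m))
})

test_that("per-domain kappa drops judges who never used the domain", {
  doms <- toy_domains()
  # 4 judges, 3 items; J4 never allocates D1
  rows <- data.frame(
    judge_id = rep(paste0("J", 1:4), each = 3),
    item_id = rep(paste0("I", 1:3), 4),
    rank = 1L,
    domain = c("D1", "D2", "D2",  "D1", "D2", "D2",  "D1", "D2", "D3",
               "D2", "D2", "D3"),
    confidence = 0.9, stringsAsFactors = FALSE)
  tab <- as_allocation_table(rows, domains = doms)
  k <- domain_kappa(tab, "D1", drop_empty_raters = TRUE)
  expect_equal(k$n_raters_used, 3L)
  expect_equal(k$excluded_raters, "J4")
  k_all <- domain_kappa(tab, "D1", drop_empty_raters = FALSE)
  expect_equal(k_all$n_raters_used, 4L)
  # identical binary columns -> perfect agreement
  expect_equal(k$kappa, 1)
})

test_that("bootstrap CIs are deterministic, degenerate-safe, and shrink with items", {
  perfect <- matrix("a", nrow = 10, ncol = 3)
  expect_equal(bootstrap_kappa_ci(perfect, n_boot = 100, seed = 1), c(1, 1))

  set.seed(21)
  m <- matrix(sample(c("a", "b"), 40 * 4, replace = TRUE, prob = c(.7, .3)),
              ncol = 4)
  ci1 <- bootstrap_kappa_ci(m, n_boot = 200, seed = 9)
  ci2 <- bootstrap_kappa_ci(m, n_boot = 200, seed = 9)
  expect_identical(ci1, ci2)
  k_hat <- light_kappa(m)
  expect_true(ci1[1] <= k_hat && k_hat <= ci1[2])
  expect_error(bootstrap_kappa_ci(m[1, , drop = FALSE], n_boot = 100), "2 items")
  expect_error(bootstrap_kappa_ci(m, n_boot = 10), "at least 100")

  # agreement structure held fixed, more items -> tighter percentile interval
  base <- cbind(rep(c("a", "b"), 10), rep(c("a", "b"), 10))
  base[1, 2] <- "b"
  wide <- bootstrap_kappa_ci(base, n_boot = 300, seed = 4)
  big <- base[rep(1:20, 16), ]
  narrow <- bootstrap_kappa_ci(big, n_boot = 300, seed = 4)
  expect_lt(diff(narrow), diff(wide))
})

test_that("independent uniform allocation has near-zero expected agreement", {
  set.seed(14)
  doms <- paste0("D", 1:14)
  kap <- replicate(200, {
    m <- matrix(sample(doms, 79 * 19, replace = TRUE), nrow = 79)
    light_kappa(m)
  })
  expect_gte(mean(kap), -0.02)
  expect_lte(mean(kap), 0.02)
})

test_that("judge match counts correlate as computed by the textbook formula", {
  doms <- toy_domains()
  bank <- toy_bank(paste0("I", 1:4), c("D1", "D2", "D3", "D1"), domains = doms)
  set.seed(30)
  rows <- expand.grid(judge_id = paste0("J", 1:6), item_id = paste0("I", 1:4),
                      stringsAsFactors = FALSE)
  rows$rank <- 1L
  rows$domain <- sample(doms$code, nrow(rows), replace = TRUE)
  rows$confidence <- 0.8
  tab <- as_allocation_table(rows, domains = doms, bank = bank)

  out <- judge_match_correlation(tab, bank, covariate = out_cov <- runif(6))
  # independent Pearson formula
  x <- out$matches; y <- out_cov
  r_ref <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, r_ref, tolerance = 1e-12)

  expect_equal(judge_match_correlation(tab, bank, out$matches + 0.0)$r, 1)
  expect_equal(judge_match_correlation(tab, bank, -out$matches)$r, -1)
  expect_error(judge_match_correlation(tab, bank, rep(1, 6)), "zero variance")
})
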
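test_that("the one-sided t-test matches stats::t.test to 1e-10", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(3:25, 1)
    x <- round(runif(n, -1, 1), 3)
    if (stats::sd(x) == 0) next
    got <- one_sample_t_greater(x)
    ref <- stats::t.test(x, mu = 0, alternative = "greater")
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p, unname(ref$p.value), tolerance = 1e-10)
    expect_equal(got$df, unname(ref$parameter))
  }
})

test_that("balanced scores give t = 0, p = 0.5", {
  got <- one_sample_t_greater(c(rep(1, 10), rep(-1, 10)))
  expect_equal(got$mean, 0)
  expect_equal(got$t, 0)
  expect_equal(got$p, 0.5)
})

test_that("zero-variance conventions are as documented", {
  expect_equal(one_sample_t_greater(rep(0.8, 5))$p, 0)
  expect_equal(one_sample_t_greater(rep(-0.8, 5))$p, 1)
  expect_equal(one_sample_t_greater(rep(0, 5))$p, 0.5)
  expect_error(one_sample_t_greater(0.5), "at least 2")
})

test_that("BH step-up matches hand-derived and brute-force answers", {
  expect_true(all(bh_adjust(c(0, 0, 0))$rejected))
  # thresholds i * .05 / 6: only the two smallest survive
  expect_equal(bh_adjust(c(.001, .008, .039, .041, .042, .06))$rejected,
               c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_true(bh_adjust(0.04)$rejected)
  expect_false(bh_adjust(0.06)$rejected)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  # exhaustive comparison on small grid vectors, plus p.adjust as a second oracle
  grid <- c(0.001, 0.005, 0.01, 0.02, 0.03, 0.04, 0.05, 0.06, 0.08, 0.10)
  combos <- expand.grid(grid, grid, grid)
  for (r in seq_len(nrow(combos))) {
    p <- as.numeric(combos[r, ])
    got <- bh_adjust(p, 0.05)
    expect_identical(got$rejected, bh_brute(p, 0.05))
    expect_identical(got$rejected, unname(stats::p.adjust(p, "BH") <= 0.05))
  }
  set.seed(3)
  for (i in 1:200) {
    p <- sample(grid, sample(4:6, 1), replace = TRUE)
    got <- bh_adjust(p, 0.05)
    expect_identical(got$rejected, bh_brute(p, 0.05))
    expect_equal(got$adjusted, stats::p.adjust(p, "BH"))
  }
})

test_that("the item taxonomy follows the inclusion rule", {
  res <- function(dom, int, rej, mean) {
    data.frame(item_id = "I1", domain = dom, intended = int,
               rejected = rej, mean = mean, stringsAsFactors = FALSE)
  }
  # significant on intended, nothing else: included
  pure <- classify_item(res("D3", TRUE, TRUE, 0.89), character(0), "D3")
  expect_equal(pure$outcome, "pure_intended")
  expect_true(pure$include_final)

  # significant on a non-intended domain: misclassified, excluded
  mis <- classify_item(res(c("D7", "D6"), c(TRUE, FALSE), c(FALSE, TRUE),
                           c(-0.68, 0.7)), c("D4", "D6", "D13"), "D7")
  expect_equal(mis$outcome, "misclassified")
  expect_false(mis$include_final)

  # co-allocated but nothing else significant: mixed
  mixed <- classify_item(res(c("D1", "D2"), c(TRUE, FALSE), c(TRUE, FALSE),
                             c(0.4, -0.2)), "D2", "D1")
  expect_equal(mixed$outcome, "mixed")

  # nothing significant, no co-allocations: unclassified
  uncl <- classify_item(res("D10", TRUE, FALSE, 0.52), character(0), "D10")
  expect_equal(uncl$outcome, "unclassified")

  expect_error(classify_item(res("D2", FALSE, TRUE, 0.5), character(0), "D1"),
               "intended domain")
})

test_that("a rejected non-intended test never helps an item toward inclusion", {
  set.seed(5)
  for (i in 1:50) {
    base <- data.frame(item_id = "I1", domain = "D1", intended = TRUE,
                       rejected = sample(c(TRUE, FALSE), 1),
                       mean = runif(1, -1, 1), stringsAsFactors = FALSE)
    extra <- data.frame(item_id = "I1", domain = "D2", intended = FALSE,
                        rejected = TRUE, mean = runif(1, 0.1, 1),
                        stringsAsFactors = FALSE)
    before <- classify_item(base, character(0), "D1")$outcome
    after <- classify_item(rbind(base, extra), "D2", "D1")$outcome
    expect_false(after == "pure_intended")
    if (before != "pure_intended") expect_false(after == "pure_intended")
  }
})

test_that("without FDR a single test rejects iff p <= alpha", {
  doms <- toy_domains()
  bank <- toy_bank("I1", "D1", domains = doms)
  tab <- alloc(paste0("J", 1:6), "I1", 1L,
               c("D1", "D1", "D1", "D1", "D2", "D3"), c(1, 1, 1, 1, 1, 1))
  sm <- score_matrix(tab, bank, min_coalloc = 3)
  t1 <- dcv_tests(sm, alpha = 0.05, fdr = "none")
  expect_equal(t1$rejected, t1$p <= 0.05)
})

test_that("final-item selection groups by intended domain", {
  doms <- toy_domains()
  bank <- toy_bank(c("I1", "I2", "I3"), c("D1", "D1", "D2"), domains = doms)
  cls <- data.frame(item_id = c("I1", "I2", "I3"),
                    outcome = c("pure_intended", "mixed", "pure_intended"),
                    include_final = c(TRUE, FALSE, TRUE),
                    stringsAsFactors = FALSE)
  out <- select_final_items(cls, bank, doms)
  expect_equal(out$D1, "I1")
  expect_equal(out$D2, "I3")
  expect_equal(out$D3, character(0))
  empty <- select_final_items(cls[0, ], bank, doms)
  expect_true(all(lengths(empty) == 0L))
})
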
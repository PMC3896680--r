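test_that("signed weights follow the match/no-match coding", {
  expect_equal(signed_weight("D1", 0.60, "D1"), 0.60)
  expect_equal(signed_weight("D2", 0.20, "D1"), -0.20)
  expect_equal(signed_weight("D1", 0, "D1"), 0)
})

test_that("the worked two-allocation example scores +0.4 / -0.4 / -0.8", {
  # a judge allocates an item to D1 at 60% and to D2 at 20%
  a <- alloc("J1", "I1", 1:2, c("D1", "D2"), c(0.6, 0.2))
  expect_equal(judge_item_score(a, "D1"), 0.4)
  expect_equal(judge_item_score(a, "D2"), -0.4)
  expect_equal(judge_item_score(a, "D3"), -0.8)
})

test_that("missing allocations score zero and mixed subsets error", {
  empty <- alloc(character(0), character(0), integer(0), character(0), numeric(0))
  expect_equal(judge_item_score(empty, "D1"), 0)
  two <- alloc(c("J1", "J2"), "I1", 1L, "D1", 0.5)
  expect_error(judge_item_score(two, "D1"), "single judge")
})

test_that("scores stay in [-3, 1], and in [-1, 1] for single allocations", {
  set.seed(42)
  doms <- toy_domains(6)
  bank <- toy_bank(paste0("I", 1:5), sample(doms$code[1:3], 5, replace = TRUE),
                   domains = doms)
  for (rep in 1:20) {
    rows <- do.call(rbind, lapply(1:8, function(j) {
      do.call(rbind, lapply(1:5, function(i) {
        k <- sample(0:3, 1)
        if (k == 0) return(NULL)
        data.frame(judge_id = paste0("J", j), item_id = paste0("I", i),
                   rank = seq_len(k), domain = sample(doms$code, k),
                   confidence = round(runif(k), 3), stringsAsFactors = FALSE)
      }))
    }))
    tab <- as_allocation_table(rows, domains = doms, bank = bank)
    sm <- score_matrix(tab, bank, rank_scope = "any")
    expect_true(all(sm$scores >= -3 & sm$scores <= 1))
    # single-allocation weighted judgments range from -1 to 1
    key <- paste(tab$judge_id, tab$item_id)
    single <- tab[key %in% names(which(table(key) == 1L)), ]
    for (r in seq_len(min(nrow(single), 5))) {
      s <- judge_item_score(single[r, , drop = FALSE], "D1")
      expect_true(s >= -1 && s <= 1)
    }
  }
})

test_that("two-way splits are antisymmetric in the target domain", {
  # judges allocate only to D1 or only to D2, same confidence
  tab <- alloc(paste0("J", 1:10), "I1", 1L,
               rep(c("D1", "D2"), 5), 0.7)
  bank <- toy_bank("I1", "D1")
  sm <- score_matrix(tab, bank, rank_scope = "any")
  m1 <- mean(sm$scores[, sm$pairs$domain == "D1"])
  sm2 <- score_matrix(tab, toy_bank("I1", "D2"), rank_scope = "any")
  m2 <- mean(sm2$scores[, sm2$pairs$domain == "D2"])
  expect_equal(m1, -m2)
})

test_that("judge relabeling leaves the score multiset unchanged", {
  set.seed(7)
  doms <- toy_domains(4)
  bank <- toy_bank("I1", "D1", domains = doms)
  rows <- data.frame(judge_id = paste0("J", 1:6), item_id = "I1", rank = 1L,
                     domain = sample(doms$code, 6, replace = TRUE),
                     confidence = round(runif(6), 2), stringsAsFactors = FALSE)
  tab <- as_allocation_table(rows, domains = doms, bank = bank)
  rows2 <- rows
  rows2$judge_id <- paste0("K", sample(6))
  tab2 <- as_allocation_table(rows2, domains = doms, bank = bank)
  sm1 <- score_matrix(tab, bank, min_coalloc = 1, rank_scope = "any")
  sm2 <- score_matrix(tab2, bank, min_coalloc = 1, rank_scope = "any")
  for (d in sm1$pairs$domain) {
    expect_equal(unname(sort(sm1$scores[, sm1$pairs$domain == d])),
                 unname(sort(sm2$scores[, sm2$pairs$domain == d])))
  }
})

test_that("the co-allocation threshold is a strict judge count", {
  doms <- toy_domains(7)
  bank <- toy_bank("I1", "D7", domains = doms)
  # 3 judges allocate the non-intended D6, 1 allocates D2
  tab <- alloc(paste0("J", 1:5), "I1", 1L,
               c("D6", "D6", "D6", "D2", "D7"), 0.8,
               domains = doms, bank = bank)
  sm <- score_matrix(tab, bank, min_coalloc = 2)
  expect_true(any(sm$pairs$domain == "D6" & !sm$pairs$intended))
  expect_false(any(sm$pairs$domain == "D2"))   # one judge is below threshold
  # brute-force judge count for the tested pair
  expect_equal(sm$pairs$n_judges_alloc[sm$pairs$domain == "D6"],
               length(unique(tab$judge_id[tab$domain == "D6"])))
})

test_that("rank scope controls which allocations count toward co-allocation", {
  doms <- toy_domains(4)
  bank <- toy_bank("I1", "D1", domains = doms)
  # two judges list D2 only as their second choice
  rows <- data.frame(judge_id = rep(c("J1", "J2", "J3"), each = 2),
                     item_id = "I1", rank = rep(1:2, 3),
                     domain = c("D1", "D2", "D1", "D2", "D1", "D3"),
                     confidence = 0.5, stringsAsFactors = FALSE)
  tab <- as_allocation_table(rows, domains = doms, bank = bank)
  expect_false(any(score_matrix(tab, bank, rank_scope = "first")$pairs$domain == "D2"))
  expect_true(any(score_matrix(tab, bank, rank_scope = "any")$pairs$domain == "D2"))
})

test_that("unallocated judges contribute zero scores so n is constant", {
  doms <- toy_domains()
  bank <- toy_bank(c("I1", "I2"), c("D1", "D2"), domains = doms)
  tab <- alloc(c("J1", "J2"), c("I1", "I1"), 1L, c("D1", "D1"), 1)
  sm <- score_matrix(tab, bank)
  i2 <- sm$scores[, sm$pairs$item_id == "I2"]
  expect_equal(unname(i2), c(0, 0))
  expect_error(score_matrix(tab[0, ], bank), "no judges")
})
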
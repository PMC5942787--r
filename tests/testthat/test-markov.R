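test_that("to_interval_pattern re-expresses runs relative to the first pitch", {
  expect_equal(as.integer(to_interval_pattern(c(65, 63, 62, 60, 58))),
               c(0, -2, -3, -5, -7))
  # transposition invariance
  expect_equal(as.integer(to_interval_pattern(c(60, 58, 57, 55, 53))),
               c(0, -2, -3, -5, -7))
  expect_equal(as.integer(to_interval_pattern(c(60, 60, 60))), c(0, 0, 0))
  expect_error(to_interval_pattern(60), "at least two")
  expect_error(interval_pattern(c(1, 2)), "must be 0")
})

test_that("count_ngrams matches hand-enumerated windows", {
  # [60,62,60,62,60] order 1: context (0) outcomes {+2: 2, -2: 2}
  tab <- count_ngrams(c(60, 62, 60, 62, 60), 1)
  expect_equal(pattern_probability(tab, interval_pattern(c(0, 2))), 0.5)
  expect_equal(pattern_probability(tab, interval_pattern(c(0, -2))), 0.5)

  # order 2: P(+4 | 0,+2) = count([0,2,4]) / count([0,2]) = 2/3
  tab2 <- count_ngrams(c(60, 62, 64, 62, 60, 62, 64), 2)
  expect_equal(pattern_probability(tab2, interval_pattern(c(0, 2, 4))), 2 / 3)

  # strictly periodic sequences: once the context covers a full period,
  # every context has a single outcome and all defined probabilities are 1
  per <- rep(c(60, 64, 67), 20)
  for (ord in 2:4) {
    probs <- tp_probabilities(count_ngrams(per, ord))
    expect_true(all(unlist(probs) == 1))
  }
  const <- seq(60, by = 2, length.out = 20)
  expect_true(all(unlist(tp_probabilities(count_ngrams(const, 1))) == 1))

  # too short for the order: empty table
  expect_length(count_ngrams(c(60, 62), 3)$counts, 0)
  expect_error(count_ngrams(c(60, 62), 0), "order")
  expect_error(count_ngrams(c(60, 62), 8), "order")
})

test_that("count_ngrams equals the brute-force window enumerator", {
  set.seed(11)
  for (case in 1:60) {
    len <- sample(10:200, 1)
    p <- cumsum(c(60, sample(-4:4, len - 1, replace = TRUE)))
    for (ord in 1:7) expect_same_counts(count_ngrams(p, ord), p, ord)
  }
})

test_that("per-context probabilities always sum to one", {
  set.seed(5)
  for (case in 1:20) {
    p <- cumsum(c(60, sample(-3:3, 80, replace = TRUE)))
    ord <- sample(1:4, 1)
    probs <- tp_probabilities(count_ngrams(p, ord))
    expect_true(all(abs(vapply(probs, sum, 0) - 1) < 1e-9))
  }
})

test_that("tables are invariant under transposition of the corpus", {
  set.seed(9)
  p <- cumsum(c(60, sample(-5:5, 120, replace = TRUE)))
  for (k in c(-12, 1, 7)) {
    for (ord in c(1, 3)) {
      expect_identical(canon_counts(count_ngrams(p, ord)$counts),
                       canon_counts(count_ngrams(p + k, ord)$counts))
    }
  }
})

test_that("pooling sums counts, weighting probabilities by context frequency", {
  # movement A: context "0" seen 10x, P(+1)=0.5; movement B: 30x, P(+1)=0.9
  a <- transition_table(1, list("0" = c("1" = 5, "-1" = 5)))
  b <- transition_table(1, list("0" = c("1" = 27, "-1" = 3)))
  pooled <- pool_movements(list(a, b))
  expect_equal(pattern_probability(pooled, interval_pattern(c(0, 1))),
               (10 * 0.5 + 30 * 0.9) / 40)   # 0.8

  # identical tables pool to identical probabilities
  expect_equal(tp_probabilities(pool_movements(list(a, a))),
               tp_probabilities(a))

  # context absent in one movement contributes zero weight
  b2 <- transition_table(1, list("5" = c("2" = 4)))
  pooled2 <- pool_movements(list(a, b2))
  expect_equal(pattern_probability(pooled2, interval_pattern(c(0, 1))), 0.5)

  expect_error(pool_movements(list(a, transition_table(2))), "mixed orders")
})

test_that("pooled counts equal concatenation counts minus boundary windows", {
  set.seed(21)
  movs <- lapply(1:4, function(i)
    cumsum(c(60, sample(-3:3, sample(20:60, 1), replace = TRUE))))
  for (ord in c(1, 2, 4)) {
    pooled <- pool_movements(lapply(movs, count_ngrams, order = ord))
    # oracle: enumerate windows over the concatenation, skipping any that
    # crosses a movement boundary
    concat <- unlist(movs)
    ends <- cumsum(lengths(movs))
    counts <- list()
    for (i in seq_len(length(concat) - ord)) {
      if (any(ends >= i & ends < i + ord)) next
      w <- concat[i:(i + ord)]
      offs <- w - w[1]
      ctx <- paste(offs[seq_len(ord)], collapse = ",")
      out <- as.character(offs[ord + 1])
      if (is.null(counts[[ctx]])) counts[[ctx]] <- numeric(0)
      counts[[ctx]][out] <- if (is.na(counts[[ctx]][out])) 1
                            else counts[[ctx]][out] + 1
    }
    expect_identical(canon_counts(pooled$counts), canon_counts(counts))
  }
})

test_that("pattern_probability distinguishes absent contexts from zero", {
  tab <- transition_table(1, list("0" = c("2" = 1)))
  expect_equal(pattern_probability(tab, interval_pattern(c(0, 2))), 1)
  # observed context, unobserved outcome: probability 0
  expect_equal(pattern_probability(tab, interval_pattern(c(0, 5))), 0)
  # unobserved context: absent
  tab2 <- count_ngrams(c(60, 62, 64), 2)
  expect_true(is.na(pattern_probability(tab2, interval_pattern(c(0, 5, 3)))))
  expect_error(pattern_probability(tab, interval_pattern(c(0, 1, 2))),
               "order")
})
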
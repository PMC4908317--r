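test_that("single-letter and background-matching columns give the textbook weights", {
  # all-proline column at uniform background, no pseudocount
  pwm <- build_pwm(c("PP", "PP"), background = "uniform", pseudocount = 0)
  expect_equal(unname(pwm$weights["P", ]), rep(log2(20), 2), tolerance = 1e-9)
  expect_true(all(pwm$weights[setdiff(rownames(pwm$weights), "P"), ] == -30))

  # a column whose residues exactly match a uniform background carries
  # zero log-odds everywhere it has counts
  toy_alpha <- c("A", "B", "C")
  pwm2 <- build_pwm(c("AB", "BC", "CA"), background = "uniform",
                    pseudocount = 0, alphabet = toy_alpha)
  expect_equal(unname(pwm2$weights), matrix(0, 3, 2), tolerance = 1e-9)
})

test_that("weights match a hand-computed count/normalise/log-odds table", {
  # 4 peptides over a 3-letter alphabet, per-cell pseudocount 1
  toy_alpha <- c("A", "B", "C")
  peps <- c("AAB", "ABB", "BAC", "ABC")
  pwm <- build_pwm(peps, background = "uniform", pseudocount = 1,
                   alphabet = toy_alpha)
  # hand arithmetic: raw counts col1 A=3,B=1,C=0; col2 A=2,B=2,C=0;
  # col3 B=2,C=2,A=0; +1 per cell (pseudocount * m * bg = 1), colsum 7
  raw <- cbind(c(3, 1, 0), c(2, 2, 0), c(0, 2, 2)) + 1
  expected <- log2((raw / 7) / (1 / 3))
  expect_equal(unname(pwm$weights), expected, tolerance = 1e-9)
  expect_equal(unname(colSums(pwm$counts)), rep(4 + 3 * 1, 3),
               tolerance = 1e-9)
})

test_that("input validation raises classed errors", {
  expect_error(build_pwm(c("PP", "PPP")), class = "slimppi_length_mismatch")
  expect_error(build_pwm(c("PX", "PP")), class = "slimppi_alphabet_error")
  expect_error(build_pwm("PP"), class = "slimppi_insufficient_data")
})

test_that("PWM invariants hold and weights are scale-invariant in peptide counts", {
  set.seed(11)
  pwm <- random_toy_pwm(n = 4, n_pep = 8, pseudocount = 0.05)
  expect_equal(unname(colSums(pwm$counts)), rep(8 + 20 * 0.05, 4),
               tolerance = 1e-9)
  expect_equal(sum(pwm$background), 1, tolerance = 1e-9)
  freq <- sweep(pwm$counts, 2, colSums(pwm$counts), "/")
  expect_equal(pwm$weights, log2(sweep(freq, 1, pwm$background, "/")),
               tolerance = 1e-9)

  peps <- c("ACD", "ACD", "PLV", "PLV")
  w1 <- build_pwm(peps, pseudocount = 0)$weights
  w2 <- build_pwm(rep(peps, 3), pseudocount = 0)$weights
  expect_equal(w1, w2, tolerance = 1e-12)
})

test_that("window scoring is the direct sum of column weights", {
  set.seed(12)
  pwm <- random_toy_pwm(n = 4)
  win <- paste(sample(AA_ALPHABET_TEST, 4, replace = TRUE), collapse = "")
  direct <- sum(vapply(1:4, function(j) {
    pwm$weights[substr(win, j, j), j]
  }, numeric(1)))
  expect_equal(score_window(pwm, win), direct, tolerance = 1e-12)
  expect_error(score_window(pwm, "ACD"), class = "slimppi_length_mismatch")

  # the consensus (column argmax) achieves the maximum possible score
  cons <- paste(rownames(pwm$weights)[apply(pwm$weights, 2, which.max)],
                collapse = "")
  expect_equal(score_window(pwm, cons), sum(apply(pwm$weights, 2, max)),
               tolerance = 1e-12)
})

test_that("null distribution matches hand enumeration on a 2-letter toy", {
  # two-letter alphabet, n = 2, uniform background
  pwm <- build_pwm(c("AB", "AB", "BA"), background = "uniform",
                   pseudocount = 1, alphabet = c("A", "B"))
  dist <- score_distribution(pwm, granularity = 1e-3)
  expect_equal(sum(dist$prob), 1, tolerance = 1e-9)
  # hand enumeration over AA, AB, BA, BB at probability 1/4 each
  scores <- vapply(c("AA", "AB", "BA", "BB"), function(w) {
    score_window(pwm, w)
  }, numeric(1))
  for (k in seq_along(dist$support)) {
    expect_equal(dist$tail_prob[k],
                 mean(round(scores / 1e-3) >= dist$support_int[k]),
                 tolerance = 1e-9)
  }
})

test_that("null distribution invariants hold", {
  set.seed(13)
  pwm <- random_toy_pwm(n = 3)
  dist <- score_distribution(pwm)
  expect_true(all(diff(dist$tail_prob) <= 1e-12))
  expect_equal(dist$tail_prob[1], 1, tolerance = 1e-9)
  expect_equal(pvalue_of_score(dist, max(dist$support) + 1), 0)
  expect_equal(pvalue_of_score(dist, min(dist$support) - 1), 1)
})

test_that("single-column distributions reduce to a sum over letters", {
  set.seed(14)
  pwm <- random_toy_pwm(n = 1, n_pep = 5)
  dist <- score_distribution(pwm)
  for (s in c(-2, 0, 1, 3)) {
    expect_equal(pvalue_of_score(dist, s),
                 sum(pwm$background[round(pwm$weights[, 1] / 1e-3) >=
                                      round(s / 1e-3)]),
                 tolerance = 1e-9)
  }
})

test_that("p-value thresholding is inverse-consistent and enumeration-exact", {
  set.seed(15)
  pwm <- random_toy_pwm(n = 3, n_pep = 5)
  dist <- score_distribution(pwm)
  expect_equal(threshold_for_pvalue(dist, 1.0), min(dist$support))
  for (p in c(0.5, 0.05, 1e-3)) {
    thr <- threshold_for_pvalue(dist, p)
    expect_lte(pvalue_of_score(dist, thr), p)
  }
  expect_error(threshold_for_pvalue(dist, 1e-30),
               class = "slimppi_unattainable_threshold")

  # the 0.05 threshold agrees with the enumeration-based quantile
  tail_enum <- enumerate_tail(pwm, dist)
  thr_enum <- dist$support[which(tail_enum <= 0.05)[1]]
  expect_equal(threshold_for_pvalue(dist, 0.05), thr_enum)
})

test_that("information content identifies conserved columns", {
  toy <- build_pwm(c("PA", "PC", "PG", "PT"), background = "uniform",
                   pseudocount = 0)
  ic <- position_information_content(toy)
  expect_equal(ic[1], log2(20), tolerance = 1e-9)   # point-mass column
  # column 2 spreads over 4 of 20 letters: IC = log2(20/4)
  expect_equal(ic[2], log2(5), tolerance = 1e-9)
  expect_equal(significant_positions(toy, 1.0), c(1L, 2L))
  expect_equal(significant_positions(toy, 3.0), 1L)
  expect_equal(significant_positions(toy, 0), c(1L, 2L))
  expect_error(significant_positions(toy, log2(20) + 1),
               class = "slimppi_empty_significant_set")

  # mixed column matches direct evaluation of the relative-entropy formula
  set.seed(16)
  pwm <- random_toy_pwm(n = 3, n_pep = 7, pseudocount = 0.05)
  f <- sweep(pwm$counts, 2, colSums(pwm$counts), "/")
  direct <- unname(colSums(f * log2(sweep(f, 1, pwm$background, "/"))))
  expect_equal(position_information_content(pwm), direct, tolerance = 1e-9)
})

test_that("PWM serialisation round-trips", {
  set.seed(17)
  pwm <- random_toy_pwm(n = 4, n_pep = 6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pwm(pwm, path)
  back <- read_pwm(path)
  expect_equal(back$weights, pwm$weights, tolerance = 1e-8)
  expect_equal(back$background, pwm$background, tolerance = 1e-9)
  expect_identical(back$id, pwm$id)
  expect_identical(back$n_peptides, pwm$n_peptides)
})
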
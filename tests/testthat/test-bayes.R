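test_that("uninformative features have likelihood ratio near 1, separating features dominate", {
  set.seed(61)
  n <- 2000
  data <- data.frame(label = rep(c(1, 0), each = n),
                     DR = runif(2 * n),            # identical in both classes
                     SA = c(runif(n, 0.8, 1.0),    # perfectly separating
                            runif(n, 0.0, 0.2)))
  model <- fit_naive_bayes(data, "pep", n_bins = 5, smoothing = 1)
  lr <- model$likelihood$DR["1", ] / model$likelihood$DR["0", ]
  expect_true(all(abs(lr - 1) < 0.15))

  # as smoothing -> 0 the posterior for a separating observation -> 1
  m_small <- fit_naive_bayes(data, "pep", n_bins = 5, smoothing = 1e-8)
  post <- class_posterior(m_small, list(SA = 0.9))
  expect_gt(post, 0.999)
})

test_that("likelihood tables recover the class-conditional histograms", {
  set.seed(62)
  n <- 4000
  x_pos <- rbeta(n, 5, 2)
  x_neg <- rbeta(n, 2, 5)
  data <- data.frame(label = rep(c(1, 0), each = n), DR = c(x_pos, x_neg))
  model <- fit_naive_bayes(data, "pep", n_bins = 10, smoothing = 1)
  edges <- model$edges$DR
  h_pos <- tabulate(findInterval(x_pos, edges, rightmost.closed = TRUE,
                                 all.inside = TRUE), 10)
  expect_equal(unname(model$likelihood$DR["1", ]),
               (h_pos + 1) / (n + 10), tolerance = 1e-12)
  # table rows are proper distributions
  expect_equal(sum(model$likelihood$DR["1", ]), 1, tolerance = 1e-9)
  expect_equal(sum(model$likelihood$DR["0", ]), 1, tolerance = 1e-9)
  expect_true(all(model$likelihood$DR > 0))
})

test_that("single-class training data is rejected", {
  data <- data.frame(label = 1, DR = runif(10))
  expect_error(fit_naive_bayes(data, "pep"),
               class = "slimppi_degenerate_training")
})

test_that("posteriors follow the closed-form product of likelihood ratios", {
  # one feature with likelihood ratio 4 at prior 0.5 -> posterior 0.8
  m <- manual_nb_model(lik_neg = c(0.2, 0.8), lik_pos = c(0.8, 0.2))
  expect_equal(class_posterior(m, list(DR = 0.25)), 0.8, tolerance = 1e-12)
  # an uninformative observation returns the prior
  m2 <- manual_nb_model(lik_neg = c(0.5, 0.5), lik_pos = c(0.5, 0.5),
                        prior = 0.3)
  expect_equal(class_posterior(m2, list(DR = 0.7)), 0.3, tolerance = 1e-12)
  expect_error(class_posterior(m, list(DR = NA)), class = "slimppi_no_evidence")

  # random vectors match a hand-rolled product over present features
  set.seed(63)
  train <- generate_labeled_pairs(fixture_spec(seed = 5), n_per_class = 400,
                                  missingness = 0)
  model <- fit_naive_bayes(train, "pep", n_bins = 8, smoothing = 1)
  test_rows <- generate_labeled_pairs(fixture_spec(seed = 6),
                                      n_per_class = 20, missingness = 0.3)
  for (k in sample(nrow(test_rows), 10)) {
    v <- test_rows[k, ]
    present <- model$features[!is.na(unlist(v[model$features]))]
    if (length(present) == 0) next
    num <- model$prior
    den <- 1 - model$prior
    for (f in present) {
      b <- findInterval(v[[f]], model$edges[[f]], rightmost.closed = TRUE,
                        all.inside = TRUE)
      num <- num * unname(model$likelihood[[f]]["1", b])
      den <- den * unname(model$likelihood[[f]]["0", b])
    }
    expect_equal(class_posterior(model, v), num / (num + den),
                 tolerance = 1e-12)
  }
})

test_that("posterior combination satisfies the Bayes identities", {
  expect_equal(combine_posteriors(0.7, 0.5, 0.5), 0.7, tolerance = 1e-12)
  expect_equal(combine_posteriors(0.3, 0.3, 0.3), 0.3, tolerance = 1e-12)
  expect_equal(combine_posteriors(0.9, 0.9, 0.5), 0.81 / 0.82,
               tolerance = 1e-12)
  # symmetry and monotonicity over a grid
  grid <- seq(0.05, 0.95, by = 0.09)
  for (p in grid) {
    for (q in grid) {
      expect_equal(combine_posteriors(p, q, 0.5),
                   combine_posteriors(q, p, 0.5), tolerance = 1e-12)
    }
  }
  for (q in grid) {
    vals <- vapply(grid, function(p) combine_posteriors(p, q, 0.4),
                   numeric(1))
    expect_true(all(diff(vals) > 0))
  }
  expect_warning(combine_posteriors(1, 0.5, 0.5),
                 class = "slimppi_probability_clipped")
})

test_that("a missing feature equals retraining without that feature", {
  set.seed(64)
  train <- generate_labeled_pairs(fixture_spec(seed = 9), n_per_class = 500)
  m_full <- fit_naive_bayes(train, "pep", n_bins = 10, smoothing = 1)
  m_wo_sc <- fit_naive_bayes(train[, setdiff(names(train), "SC")], "pep",
                             n_bins = 10, smoothing = 1)
  probe <- list(DR = 0.8, SA = 0.6, PC = 0.4, SC = NA_real_)
  expect_equal(class_posterior(m_full, probe),
               class_posterior(m_wo_sc, probe), tolerance = 1e-12)
})

test_that("posteriors are calibrated on data drawn from the fitted conditionals", {
  set.seed(65)
  spec <- fixture_spec(seed = 21)
  train <- generate_labeled_pairs(spec, n_per_class = 2000, subset = "train")
  test <- generate_labeled_pairs(spec, n_per_class = 2000, subset = "test")
  model <- fit_naive_bayes(train, "pro", n_bins = 10, smoothing = 1)
  p <- vapply(seq_len(nrow(test)), function(k) {
    class_posterior(model, test[k, ])
  }, numeric(1))
  bins <- cut(p, seq(0, 1, 0.1), include.lowest = TRUE)
  for (lv in levels(bins)) {
    sel <- bins == lv
    if (sum(sel) < 150) next
    expect_lt(abs(mean(p[sel]) - mean(test$label[sel])), 0.08)
  }
})

test_that("prediction records compose posteriors and aggregate pairs by max", {
  m_pep <- manual_nb_model(lik_neg = c(0.2, 0.8), lik_pos = c(0.8, 0.2))
  m_pro <- manual_nb_model(feature = "CC", lik_neg = c(0.3, 0.7),
                           lik_pos = c(0.7, 0.3), scope = "pro")
  hits <- data.frame(
    candidate_id = c("h1", "h2", "h3"),
    pair_id = c("A~B", "A~B", "A~C"),
    protein_id = c("B", "B", "C"), pwm_id = "w", domain_id = "d",
    start = c(1L, 10L, 4L), end = c(4L, 13L, 7L),
    window_seq = "XXXX", score = 1, pvalue = 0.001,
    significant_positions = "1", stringsAsFactors = FALSE)
  pep_f <- data.frame(candidate_id = c("h1", "h2", "h3"),
                      DR = c(0.25, 0.8, 0.25))
  pro_f <- data.frame(pair_id = c("A~B", "A~C"), CC = c(0.25, 0.8))
  out <- predict_pairs(hits, pep_f, pro_f, m_pep, m_pro, prior = 0.5,
                       decision_threshold = 0.9)
  r <- out$records
  # h1: p_pep = 0.8, p_pro = 0.7 -> combined by the closed form
  expect_equal(r$p_pep[r$candidate_id == "h1"], 0.8, tolerance = 1e-12)
  expect_equal(r$combined[r$candidate_id == "h1"],
               combine_posteriors(0.8, 0.7, 0.5), tolerance = 1e-12)
  # h2: p_pep = 0.2 (upper bin), same pair
  expect_equal(r$combined[r$candidate_id == "h2"],
               combine_posteriors(0.2, 0.7, 0.5), tolerance = 1e-12)
  # pair A~B aggregates by max over its two sites
  ab <- out$pairs[out$pairs$pair_id == "A~B", ]
  expect_equal(ab$score, max(r$combined[r$pair_id == "A~B"]))
  expect_equal(ab$n_sites, 2L)
})

test_that("candidates with evidence in one scope fall back to the prior in the other", {
  m_pep <- manual_nb_model(lik_neg = c(0.2, 0.8), lik_pos = c(0.8, 0.2))
  m_pro <- manual_nb_model(feature = "CC", lik_neg = c(0.3, 0.7),
                           lik_pos = c(0.7, 0.3), scope = "pro")
  hits <- data.frame(candidate_id = c("h1", "h2"), pair_id = c("X~Y", "X~Z"),
                     stringsAsFactors = FALSE)
  pep_f <- data.frame(candidate_id = c("h1", "h2"), DR = c(0.8, NA))
  pro_f <- data.frame(pair_id = c("X~Y", "X~Z"), CC = c(NA, NA))
  out <- predict_pairs(hits, pep_f, pro_f, m_pep, m_pro, prior = 0.5,
                       decision_threshold = 0.9)
  # h1 has peptide evidence only: combined equals the peptide posterior
  expect_equal(out$records$combined[out$records$candidate_id == "h1"],
               out$records$p_pep[out$records$candidate_id == "h1"],
               tolerance = 1e-12)
  # h2 has no evidence at all: excluded
  expect_equal(attr(out, "excluded"), 1L)
  expect_false("h2" %in% out$records$candidate_id)
})

test_that("naive Bayes models round-trip through JSON", {
  set.seed(66)
  train <- generate_labeled_pairs(fixture_spec(seed = 3), n_per_class = 300)
  model <- fit_naive_bayes(train, "pro", n_bins = 6, smoothing = 0.5)
  path <- withr::local_tempfile(fileext = ".json")
  write_nb_model(model, path)
  back <- read_nb_model(path)
  expect_equal(back$likelihood, model$likelihood, tolerance = 1e-12)
  expect_equal(back$edges, model$edges, tolerance = 1e-12)
  expect_equal(back$prior, model$prior)
  probe <- generate_labeled_pairs(fixture_spec(seed = 4), n_per_class = 5)
  for (k in seq_len(4)) {
    expect_equal(class_posterior(back, probe[k, ]),
                 class_posterior(model, probe[k, ]), tolerance = 1e-12)
  }
})
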
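mk_panel <- function() {
  set.seed(51)
  p1 <- matrix(rnorm(5 * 8), 5, 8,
               dimnames = list(paste0("g", 1:5), paste0("c", 1:8)))
  p2 <- matrix(rnorm(4 * 6), 4, 6,
               dimnames = list(paste0("g", c(1, 2, 3, 6)), paste0("c", 1:6)))
  p2["g2", ] <- -p2["g1", ]
  expression_panel(list(pa = p1, pb = p2))
}

test_that("per-profile correlations match direct computation and skip rules", {
  panel <- mk_panel()
  rs <- profile_correlations("g1", "g2", panel)
  expect_equal(length(rs), 2L)
  expect_equal(unname(rs["pa"]),
               cor(panel$profiles$pa["g1", ], panel$profiles$pa["g2", ]),
               tolerance = 1e-12)
  expect_equal(unname(rs["pb"]), -1.0, tolerance = 1e-12)

  # identical rows give r = 1 in every shared profile
  same <- profile_correlations("g1", "g1", panel)
  expect_true(all(abs(same - 1) < 1e-12))

  # gene absent from one profile: only the other contributes
  rs6 <- profile_correlations("g3", "g6", panel)
  expect_equal(names(rs6), "pb")
  expect_equal(attr(rs6, "skipped")[["absent"]], 1L)

  expect_error(profile_correlations("g4", "g6", panel),
               class = "slimppi_no_expression_evidence")
})

test_that("zero-variance and sparse overlap profiles are skipped", {
  m <- matrix(rnorm(12), 3, 4, dimnames = list(c("a", "b", "flat"), NULL))
  m["flat", ] <- 5
  panel <- expression_panel(list(p = m))
  expect_error(profile_correlations("a", "flat", panel),
               class = "slimppi_no_expression_evidence")
  m2 <- m
  m2["b", 1:2] <- NA
  panel2 <- expression_panel(list(p = m2))
  # only 2 shared conditions remain -> skipped
  m2["b", 3] <- NA
  expect_error(profile_correlations("a", "b", expression_panel(list(p = m2))),
               class = "slimppi_no_expression_evidence")
})

test_that("Fisher-z combination has the textbook closed form", {
  expect_equal(combine_expression(0.5), 0.5, tolerance = 1e-12)
  expect_equal(combine_expression(c(0.7, -0.7)), 0, tolerance = 1e-12)
  expect_equal(combine_expression(c(0.9, 0.3)),
               tanh((atanh(0.9) + atanh(0.3)) / 2), tolerance = 1e-12)
  # fixed point: n copies of the same r return r
  expect_equal(combine_expression(rep(0.42, 7)), 0.42, tolerance = 1e-12)
  # strictly increasing in each argument
  set.seed(52)
  r <- runif(5, -0.8, 0.8)
  for (i in seq_along(r)) {
    r2 <- r
    r2[i] <- r2[i] + 0.05
    expect_gt(combine_expression(r2), combine_expression(r))
  }
  expect_warning(out <- combine_expression(c(1, 0.5)),
                 class = "slimppi_correlation_clipped")
  expect_lt(out, 1)
  expect_error(combine_expression(numeric(0)),
               class = "slimppi_no_expression_evidence")
})

test_that("expression panels round-trip through manifest + matrices", {
  panel <- mk_panel()
  dir <- withr::local_tempdir()
  man <- write_expression_panel(panel, file.path(dir, "expr"))
  back <- read_expression_panel(man)
  expect_equal(names(back$profiles), names(panel$profiles))
  expect_equal(back$profiles$pa, panel$profiles$pa, tolerance = 1e-6)
})

test_that("signature model counts match hand tabulation", {
  sigs <- list(A = "s1", B = "s2", C = c("s1", "s3"), D = "s2", E = "s3")
  # 5 reference pairs
  ppis <- data.frame(a = c("A", "A", "C", "C", "E"),
                     b = c("B", "D", "B", "D", "D"))
  model <- fit_signature_model(ppis, sigs, pseudocount = 0)
  # cross observations: (s1,s2) from A-B, A-D, C-B, C-D; (s3,s2) from C-B,
  # C-D, E-D -> total observations 2+2+... : |SA||SB| = 1,1,2,2,1 = 7
  expect_equal(model$n_observations, 7)
  expect_equal(model$p_pair["s1", "s2"], 4 / 7, tolerance = 1e-12)
  expect_equal(model$p_pair["s3", "s2"], 3 / 7, tolerance = 1e-12)
  expect_equal(model$p_pair["s1", "s3"], 0)
  # marginals over interaction sides: s1 on A,A,C,C = 4; s2 on B,D,B,D,D
  # = 5; s3 on C,C,E = 3; total side occurrences 12
  expect_equal(unname(model$p_marg[c("s1", "s2", "s3")]),
               c(4, 5, 3) / 12, tolerance = 1e-12)
  # symmetry
  expect_equal(model$p_pair, t(model$p_pair), tolerance = 1e-15)
})

test_that("duplicating a reference pair leaves frequency-based models unchanged", {
  sigs <- list(A = "s1", B = "s2")
  m1 <- fit_signature_model(data.frame(a = "A", b = "B"), sigs,
                            pseudocount = 0)
  m2 <- fit_signature_model(data.frame(a = c("A", "A"), b = c("B", "B")),
                            sigs, pseudocount = 0)
  expect_equal(m1$p_pair, m2$p_pair, tolerance = 1e-12)
  expect_equal(m1$p_marg, m2$p_marg, tolerance = 1e-12)
  expect_equal(m1$p_pair["s1", "s2"], 1)
})

test_that("signature scores are direct log-ratio sums and symmetric", {
  # hand-built model: p_ij = 0.1, p_i = p_j = 0.2 -> log2(2.5)
  model <- structure(list(
    vocab = c("x", "y"),
    p_pair = matrix(c(0.04, 0.1, 0.1, 0.04), 2, 2,
                    dimnames = list(c("x", "y"), c("x", "y"))),
    p_marg = c(x = 0.2, y = 0.2), pseudocount = 0, n_pairs = 1,
    n_observations = 1), class = "slimppi_signature_model")
  expect_equal(signature_score("x", "y", model), log2(2.5), tolerance = 1e-12)
  # independence (p_ij = p_i p_j) contributes exactly 0
  expect_equal(signature_score("x", "x", model), 0, tolerance = 1e-12)
  # printed sign convention negates
  expect_equal(signature_score("x", "y", model, sign = "printed"),
               -log2(2.5), tolerance = 1e-12)
  # symmetry in the protein arguments
  expect_equal(signature_score(c("x", "y"), "y", model),
               signature_score("y", c("x", "y"), model), tolerance = 1e-12)
  # unknown signatures are skipped; all-unknown errors
  expect_equal(signature_score(c("x", "zz"), "y", model), log2(2.5),
               tolerance = 1e-12)
  expect_error(signature_score("zz", "y", model),
               class = "slimppi_no_signature_evidence")
})

test_that("smoothed marginals sum to about 1 and pair bounds hold", {
  set.seed(53)
  sigs <- lapply(1:12, function(k) sample(paste0("s", 1:6), sample(1:3, 1)))
  names(sigs) <- paste0("P", 1:12)
  ppis <- data.frame(a = paste0("P", 1:6), b = paste0("P", 7:12))
  model <- fit_signature_model(ppis, sigs)
  expect_equal(sum(model$p_marg), 1, tolerance = 1e-9)
  expect_equal(model$p_pair, t(model$p_pair), tolerance = 1e-15)
})

test_that("signature and PPI files round-trip", {
  sigs <- list(A = c("s1", "s2"), B = "s3")
  sp <- withr::local_tempfile(fileext = ".tsv")
  write_signatures(sigs, sp)
  expect_equal(read_signatures(sp), sigs[order(names(sigs))])
  pp <- withr::local_tempfile(fileext = ".tsv")
  write_ppi_list(data.frame(a = "A", b = "B"), pp)
  expect_equal(read_ppi_list(pp), data.frame(a = "A", b = "B"))
})
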
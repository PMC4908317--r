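# Shared fixtures and independent oracles used across the suite.

# ---- PWM oracles -----------------------------------------------------------

# Random toy PWM over the full 20-letter alphabet with short motif length,
# suitable for exhaustive enumeration.
random_toy_pwm <- function(n = 3, n_pep = 6, pseudocount = 0.05) {
  peps <- vapply(seq_len(n_pep), function(k) {
    paste(sample(AA_ALPHABET_TEST, n, replace = TRUE), collapse = "")
  }, character(1))
  build_pwm(peps, background = "uniform", pseudocount = pseudocount,
            id = "toy")
}
AA_ALPHABET_TEST <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                      "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Exhaustive tail probabilities over all m^n windows, on the same rounded
# score grid the convolution uses. Returns tail probability evaluated at
# each support point of `dist`.
enumerate_tail <- function(pwm, dist) {
  g <- dist$granularity
  ints <- round(pwm$weights / g)
  bg <- pwm$background
  score_int <- 0
  prob <- 1
  for (j in seq_len(ncol(ints))) {
    score_int <- as.vector(outer(score_int, ints[, j], "+"))
    prob <- as.vector(outer(prob, bg, "*"))
  }
  lo <- dist$support_int[1]
  acc <- numeric(length(dist$support_int))
  agg <- rowsum(prob, score_int - lo + 1)
  acc[as.integer(rownames(agg))] <- agg[, 1]
  rev(cumsum(rev(acc)))
}

# ---- alignment oracle ------------------------------------------------------

# Exhaustive best global alignment score: enumerates every monotone path
# through the alignment grid, scoring gaps as open for the first residue of
# a run and extend for each further residue (a direction switch re-opens).
exhaustive_global_score <- function(seq_a, seq_b, submat,
                                    gap_open = -10, gap_extend = -1) {
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  best <- -Inf
  recurse <- function(i, j, score, last) {
    if (i > length(a) && j > length(b)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(a) && j <= length(b)) {
      recurse(i + 1, j + 1, score + submat[a[i], b[j]], "D")
    }
    if (i <= length(a)) {
      pen <- if (last == "U") gap_extend else gap_open
      recurse(i + 1, j, score + pen, "U")
    }
    if (j <= length(b)) {
      pen <- if (last == "L") gap_extend else gap_open
      recurse(i, j + 1, score + pen, "L")
    }
  }
  recurse(1, 1, 0, "start")
  best
}

# ---- TCSS fixture DAG ------------------------------------------------------

# 11-term single-namespace DAG with hand-computed expectations (cutoff 1.0):
#
#   R -> C -> {A, B}; R -> D -> E -> E1
#   A -> {A1, A2}; B -> {B1, B2}
#
# Topological IC (natural log, 11 terms):
#   R 0; C -ln(7/11); D,A,B -ln(3/11); E -ln(2/11); leaves -ln(1/11)
# Sub-graph roots at cutoff 1.0: A, B, D (E is under D). Meta graph:
#   {R, C, A, B, D}.
# Direct annotations: p1,p2 -> A1; p3 -> A2; p4 -> B1; p5 -> B2; p6 -> E1;
#   p7 -> {A2, B1}.
# Propagated counts: A1 2, A2 2, B1 2, B2 1, E1 1, E 1, A 4, B 3, D 1,
#   C 6, R 7.
tcss_fixture <- function() {
  terms <- data.frame(
    id = c("P:R", "P:C", "P:D", "P:A", "P:B", "P:E",
           "P:A1", "P:A2", "P:B1", "P:B2", "P:E1"),
    name = "t", namespace = "P", stringsAsFactors = FALSE)
  edges <- data.frame(
    child  = c("P:C", "P:D", "P:A", "P:B", "P:E", "P:A1", "P:A2",
               "P:B1", "P:B2", "P:E1"),
    parent = c("P:R", "P:R", "P:C", "P:C", "P:D", "P:A", "P:A",
               "P:B", "P:B", "P:E"),
    stringsAsFactors = FALSE)
  dag <- go_dag(terms, edges)
  ann <- data.frame(
    protein_id = c("p1", "p2", "p3", "p4", "p5", "p6", "p7", "p7"),
    term_id = c("P:A1", "P:A1", "P:A2", "P:B1", "P:B2", "P:E1",
                "P:A2", "P:B1"),
    evidence_code = "IDA", namespace = "P", stringsAsFactors = FALSE)
  list(dag = dag, annotations = ann, cutoff = 1.0)
}

# ---- shared small bundle for pipeline tests --------------------------------

small_fixture_spec <- function(seed = 7) {
  fixture_spec(seed = seed, n_targets = 15, planted_per_motif = 4,
               n_labeled = 200, n_profiles = 5, n_conditions = 12)
}

shared_bundle_env <- new.env()
shared_small_bundle <- function() {
  if (is.null(shared_bundle_env$cfg)) {
    dir <- file.path(tempdir(), "slimppi-shared-bundle")
    shared_bundle_env$cfg <- make_fixture_bundle(small_fixture_spec(), dir)
    shared_bundle_env$bundle <- load_dataset_bundle(shared_bundle_env$cfg)
  }
  shared_bundle_env
}

# ---- naive Bayes: hand-buildable model -------------------------------------

# A minimal one-feature model with specified per-bin likelihoods, for
# closed-form posterior checks.
manual_nb_model <- function(feature = "DR", edges = c(0, 0.5, 1),
                            lik_neg = c(0.5, 0.5), lik_pos = c(0.5, 0.5),
                            prior = 0.5, scope = "pep") {
  structure(list(scope = scope, features = feature,
                 edges = stats::setNames(list(edges), feature),
                 likelihood = stats::setNames(
                   list(rbind("0" = lik_neg, "1" = lik_pos)), feature),
                 counts = NULL, prior = prior, n_bins = length(lik_neg),
                 smoothing = 0, n_train = c(neg = 0, pos = 0)),
            class = "slimppi_nb_model")
}
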
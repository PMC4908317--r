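# Feature vocabulary of the two classifier scopes. Bounded features are
# binned on their natural range; PC (z-scored conservation) and SS
# (log-odds signature score) are unbounded and get quantile bins estimated
# on the training data.
PEP_FEATURES <- c("DR", "SA", "PC", "SC")
PRO_FEATURES <- c("CC", "BP", "MF", "EX", "SS")
FEATURE_RANGES <- list(
  DR = c(0, 1), SA = c(0, 1), SC = c(0, 1),
  CC = c(0, 1), BP = c(0, 1), MF = c(0, 1),
  EX = c(-1, 1), PC = NULL, SS = NULL
)

scope_features <- function(scope) {
  switch(scope, pep = PEP_FEATURES, pro = PRO_FEATURES,
         slimppi_abort("slimppi_config_error",
                       "scope must be 'pep' or 'pro'"))
}

feature_bin <- function(x, edges) {
  findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
}

#' Fit a binned naive Bayes classifier
#'
#' Trains one of the two evidence classifiers (peptide scope: DR, SA, PC,
#' SC; protein scope: CC, BP, MF, EX, SS) on a labelled feature table.
#' Continuous features are discretised: features with a natural bounded
#' range get equal-width bins on that range, unbounded features (PC, SS)
#' get quantile bins estimated on the pooled training values. Per class,
#' bin likelihoods are Laplace-smoothed so every bin keeps positive
#' probability. Missing values (`NA`) are simply excluded from that
#' feature's table (missing-at-random), which is what makes prediction with
#' partial evidence consistent: a missing feature contributes no factor.
#'
#' @param data data frame with a `label` column (0/1 or logical) and the
#'   scope's feature columns (extra columns are ignored).
#' @param scope `"pep"` or `"pro"`.
#' @param n_bins number of bins per feature (default 10).
#' @param smoothing Laplace smoothing mass per bin (default 1.0).
#' @param prior prior interaction probability P(Y=1); default 0.5
#'   (balanced-training convention), or `"empirical"` for the label
#'   frequency.
#' @return an object of class `slimppi_nb_model`.
#' @export
fit_naive_bayes <- function(data, scope = c("pep", "pro"), n_bins = 10,
                            smoothing = 1.0, prior = 0.5) {
  scope <- match.arg(scope)
  if (n_bins < 2) {
    slimppi_abort("slimppi_config_error", "n_bins must be >= 2")
  }
  y <- as.integer(data$label)
  if (length(unique(y[!is.na(y)])) < 2) {
    slimppi_abort("slimppi_degenerate_training",
                  "both classes must be present in the training data")
  }
  if (identical(prior, "empirical")) prior <- mean(y == 1)
  if (!is.numeric(prior) || prior <= 0 || prior >= 1) {
    slimppi_abort("slimppi_config_error", "prior must be in (0, 1)")
  }
  feats <- intersect(scope_features(scope), names(data))
  if (length(feats) == 0) {
    slimppi_abort("slimppi_config_error",
                  sprintf("no %s-scope feature columns found", scope))
  }
  edges <- list()
  lik <- list()
  counts <- list()
  for (f in feats) {
    x <- data[[f]]
    rng <- FEATURE_RANGES[[f]]
    if (!is.null(rng)) {
      e <- seq(rng[1], rng[2], length.out = n_bins + 1)
    } else {
      qs <- stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                            na.rm = TRUE, names = FALSE, type = 7)
      e <- unique(qs)
      if (length(e) < 3) e <- c(e[1] - 1, e, e[length(e)] + 1)
      e[1] <- -Inf
      e[length(e)] <- Inf
    }
    nb <- length(e) - 1
    tab <- matrix(NA_real_, 2, nb, dimnames = list(c("0", "1"), NULL))
    cnt <- tab
    for (cls in 0:1) {
      xv <- x[y == cls & !is.na(x)]
      h <- tabulate(feature_bin(xv, e), nbins = nb)
      cnt[as.character(cls), ] <- h
      tab[as.character(cls), ] <- (h + smoothing) / (sum(h) + smoothing * nb)
    }
    edges[[f]] <- e
    lik[[f]] <- tab
    counts[[f]] <- cnt
  }
  structure(list(scope = scope, features = feats, edges = edges,
                 likelihood = lik, counts = counts, prior = prior,
                 n_bins = n_bins, smoothing = smoothing,
                 n_train = c(neg = sum(y == 0), pos = sum(y == 1))),
            class = "slimppi_nb_model")
}

#' @export
print.slimppi_nb_model <- function(x, ...) {
  cat(sprintf("naive Bayes (%s scope): features %s; prior %.3f; %d+%d training rows\n",
              x$scope, paste(x$features, collapse = ", "), x$prior,
              x$n_train["pos"], x$n_train["neg"]))
  invisible(x)
}

#' Posterior interaction probability under one classifier
#'
#' \eqn{P(Y=1 \mid \mathrm{evidence}) \propto \pi \prod_f
#' P(\mathrm{bin}_f \mid Y=1)}, normalised over the two classes. Missing
#' features contribute no factor; with every feature missing there is no
#' evidence and a classed error (`slimppi_no_evidence`) is raised.
#' Computed in log space for numerical stability.
#'
#' @param model a `slimppi_nb_model`.
#' @param vector named list / one-row data frame of feature values (`NA` =
#'   missing).
#' @return posterior probability in `[0, 1]`.
#' @export
class_posterior <- function(model, vector) {
  loglr <- 0
  n_present <- 0L
  for (f in model$features) {
    v <- vector[[f]]
    if (is.null(v) || is.na(v)) next
    b <- feature_bin(v, model$edges[[f]])
    loglr <- loglr + log(model$likelihood[[f]]["1", b]) -
      log(model$likelihood[[f]]["0", b])
    n_present <- n_present + 1L
  }
  if (n_present == 0L) {
    slimppi_abort("slimppi_no_evidence",
                  sprintf("all %s-scope features missing", model$scope))
  }
  unname(stats::plogis(log(model$prior / (1 - model$prior)) + loglr))
}

#' Combine the peptide and protein classifier posteriors
#'
#' Bayes'-theorem combination of two independent classifiers sharing the
#' same prior:
#' \deqn{P = \frac{p_1 p_2 / \pi}{p_1 p_2/\pi + (1-p_1)(1-p_2)/(1-\pi)}.}
#' The combination is symmetric, monotone in each argument, and returns
#' the other posterior unchanged when one classifier sits at the prior
#' (no evidence). Probabilities at 0 or 1 are clipped to
#' `[1e-12, 1 - 1e-12]` with a warning. Vectorised.
#'
#' @param p_pep,p_pro the two posteriors.
#' @param prior shared prior interaction probability.
#' @return combined posterior in `[0, 1]`.
#' @export
combine_posteriors <- function(p_pep, p_pro, prior = 0.5) {
  eps <- 1e-12
  if (any(c(p_pep, p_pro, prior) <= 0) || any(c(p_pep, p_pro, prior) >= 1)) {
    slimppi_warn("slimppi_probability_clipped",
                 "posterior(s) at the boundary clipped to [1e-12, 1-1e-12]")
  }
  p_pep <- pmin(pmax(p_pep, eps), 1 - eps)
  p_pro <- pmin(pmax(p_pro, eps), 1 - eps)
  prior <- min(max(prior, eps), 1 - eps)
  num <- p_pep * p_pro / prior
  den <- num + (1 - p_pep) * (1 - p_pro) / (1 - prior)
  num / den
}

#' Score candidate binding-site hits and aggregate to protein pairs
#'
#' For every hit, evaluates the peptide classifier on the hit's peptide
#' features and the protein classifier on its pair's protein features, and
#' combines the two posteriors with [combine_posteriors()]. A classifier
#' with no usable evidence falls back to the prior (which leaves the
#' combination equal to the other classifier's posterior); candidates with
#' no evidence in *either* scope are excluded and counted. Pair-level
#' scores aggregate over a pair's hits by maximum (one true binding site
#' suffices) or noisy-or.
#'
#' @param hits hit table (see [scan_proteome()]) with a `pair_id` column,
#'   or any data frame with `candidate_id` and `pair_id`.
#' @param pep_features data frame keyed by `candidate_id` with peptide
#'   feature columns.
#' @param pro_features data frame keyed by `pair_id` with protein feature
#'   columns.
#' @param pep_model,pro_model fitted `slimppi_nb_model` objects.
#' @param prior shared prior probability (default 0.5).
#' @param decision_threshold combined-probability call threshold
#'   (default 0.9, the conventional high-confidence cutoff).
#' @param aggregate `"max"` (default) or `"noisy_or"`.
#' @return list with `records` (one row per hit: features, both
#'   posteriors, combined probability, decision) and `pairs` (per-pair
#'   aggregated scores), both deterministically ordered; attribute
#'   `excluded` counts no-evidence candidates.
#' @export
predict_pairs <- function(hits, pep_features, pro_features, pep_model,
                          pro_model, prior = 0.5, decision_threshold = 0.9,
                          aggregate = c("max", "noisy_or")) {
  aggregate <- match.arg(aggregate)
  if (decision_threshold <= 0 || decision_threshold >= 1) {
    slimppi_abort("slimppi_config_error",
                  "decision_threshold must be in (0, 1)")
  }
  if (!("candidate_id" %in% names(hits))) {
    hits$candidate_id <- paste(hits$pwm_id, hits$protein_id, hits$start,
                               sep = ":")
  }
  rec <- hits
  pep_row <- match(rec$candidate_id, pep_features$candidate_id)
  pro_row <- match(rec$pair_id, pro_features$pair_id)
  for (f in pep_model$features) {
    rec[[f]] <- pep_features[[f]][pep_row]
  }
  for (f in pro_model$features) {
    rec[[f]] <- pro_features[[f]][pro_row]
  }
  n <- nrow(rec)
  p_pep <- rep(NA_real_, n)
  p_pro <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    p_pep[k] <- tryCatch(class_posterior(pep_model, rec[k, ]),
                         slimppi_no_evidence = function(e) NA_real_)
    p_pro[k] <- tryCatch(class_posterior(pro_model, rec[k, ]),
                         slimppi_no_evidence = function(e) NA_real_)
  }
  excluded <- sum(is.na(p_pep) & is.na(p_pro))
  keep <- !(is.na(p_pep) & is.na(p_pro))
  rec <- rec[keep, , drop = FALSE]
  p_pep <- p_pep[keep]
  p_pro <- p_pro[keep]
  # a scope with no evidence is uninformative: its posterior is the prior
  rec$p_pep <- ifelse(is.na(p_pep), prior, p_pep)
  rec$p_pro <- ifelse(is.na(p_pro), prior, p_pro)
  rec$pep_missing <- is.na(p_pep)
  rec$pro_missing <- is.na(p_pro)
  rec$combined <- combine_posteriors(rec$p_pep, rec$p_pro, prior)
  rec$decision <- rec$combined >= decision_threshold
  rec <- rec[order(rec$pair_id, rec$candidate_id), , drop = FALSE]
  rownames(rec) <- NULL

  agg_fun <- if (aggregate == "max") function(p) max(p)
             else function(p) 1 - prod(1 - p)
  pair_ids <- sort(unique(rec$pair_id))
  pair_score <- vapply(pair_ids, function(pid) {
    agg_fun(rec$combined[rec$pair_id == pid])
  }, numeric(1))
  pairs <- data.frame(pair_id = pair_ids, score = unname(pair_score),
                      n_sites = as.integer(table(rec$pair_id)[pair_ids]),
                      decision = unname(pair_score) >= decision_threshold,
                      stringsAsFactors = FALSE)
  out <- list(records = rec, pairs = pairs)
  attr(out, "excluded") <- excluded
  out
}

#' Serialise / restore a naive Bayes model
#'
#' Versioned JSON holding bin edges, likelihood tables, prior and training
#' metadata; plain text so models travel with the repository.
#'
#' @param model a `slimppi_nb_model`.
#' @param path file path.
#' @export
write_nb_model <- function(model, path) {
  payload <- list(
    format = "slimppi_nb/1",
    scope = model$scope, features = model$features,
    edges = model$edges,
    likelihood = lapply(model$likelihood, function(m) {
      list(neg = unname(m["0", ]), pos = unname(m["1", ]))
    }),
    counts = lapply(model$counts, function(m) {
      list(neg = unname(m["0", ]), pos = unname(m["1", ]))
    }),
    prior = model$prior, n_bins = model$n_bins,
    smoothing = model$smoothing, n_train = as.list(model$n_train)
  )
  writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                              pretty = TRUE), path)
  invisible(path)
}

#' @rdname write_nb_model
#' @export
read_nb_model <- function(path) {
  p <- jsonlite::fromJSON(readLines(path), simplifyVector = TRUE)
  if (!identical(p$format, "slimppi_nb/1")) {
    slimppi_abort("slimppi_parse_error",
                  sprintf("unrecognised model format in %s", path))
  }
  lik <- lapply(p$likelihood, function(l) {
    rbind("0" = l$neg, "1" = l$pos)
  })
  cnt <- lapply(p$counts, function(l) {
    rbind("0" = l$neg, "1" = l$pos)
  })
  structure(list(scope = p$scope, features = p$features,
                 edges = lapply(p$edges, as.numeric),
                 likelihood = lik, counts = cnt, prior = p$prior,
                 n_bins = p$n_bins, smoothing = p$smoothing,
                 n_train = unlist(p$n_train)),
            class = "slimppi_nb_model")
}
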
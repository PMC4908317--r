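#' Build a position weight matrix from fixed-length binding peptides
#'
#' Constructs an m x n position weight matrix (PWM) from a list of
#' equal-length peptides, such as the binding peptides recovered for one SH3
#' domain by phage display. Counts are regularised with a background-weighted
#' pseudocount and converted to log-odds weights in bits:
#' \deqn{w_{aj} = \log_2\frac{f_{aj}}{b_a}}
#' where \eqn{f_{aj}} is the pseudocounted frequency of residue \eqn{a} at
#' motif position \eqn{j} and \eqn{b_a} the background frequency.
#'
#' Phage-display libraries are fixed length, so no alignment of the peptides
#' is attempted; unequal lengths are an error.
#'
#' @param peptides character vector of >= 2 equal-length peptides.
#' @param background `"uniform"`, `"from-proteome"` (requires `proteome`), or
#'   a probability vector over `alphabet`.
#' @param pseudocount per-cell pseudocount mass at uniform background: cell
#'   \eqn{(a,j)} receives `pseudocount * m * background[a]` extra counts, so a
#'   column's total pseudo-mass is `m * pseudocount` regardless of the
#'   background. The default 0.05 adds one pseudo-observation per column on
#'   the 20-letter alphabet.
#' @param id,domain_id identifiers stored with the matrix.
#' @param alphabet ordered residue alphabet (default: 20 standard amino
#'   acids; reduced alphabets are permitted for toy models).
#' @param proteome sequences used when `background = "from-proteome"`.
#' @param weight_floor lower bound, in bits, applied to log-odds weights so
#'   that zero counts at pseudocount 0 stay finite. Default -30.
#' @return an object of class `slimppi_pwm` with elements `id`, `domain_id`,
#'   `alphabet`, `counts` (pseudocounted), `weights` (bits), `background`,
#'   `pseudocount`, `n_peptides`, `weight_floor`.
#' @export
build_pwm <- function(peptides, background = "uniform", pseudocount = 0.05,
                      id = "pwm1", domain_id = id, alphabet = AA_ALPHABET,
                      proteome = NULL, weight_floor = -30) {
  if (length(peptides) < 2) {
    slimppi_abort("slimppi_insufficient_data",
                  "at least 2 peptides are required to build a PWM")
  }
  lens <- nchar(peptides)
  if (length(unique(lens)) != 1) {
    slimppi_abort("slimppi_length_mismatch",
                  sprintf("peptides have unequal lengths: %s",
                          paste(sort(unique(lens)), collapse = ", ")))
  }
  if (pseudocount < 0) {
    slimppi_abort("slimppi_config_error", "pseudocount must be >= 0")
  }
  n <- lens[1]
  m <- length(alphabet)
  bg <- resolve_background(background, alphabet, proteome)

  mat <- do.call(rbind, strsplit(peptides, "", fixed = TRUE))
  bad <- setdiff(unique(as.vector(mat)), alphabet)
  if (length(bad) > 0) {
    slimppi_abort("slimppi_alphabet_error",
                  sprintf("residues outside the alphabet: %s",
                          paste(bad, collapse = ", ")))
  }
  counts <- vapply(seq_len(n), function(j) {
    as.numeric(table(factor(mat[, j], levels = alphabet)))
  }, numeric(m))
  counts <- counts + pseudocount * m * bg
  dimnames(counts) <- list(alphabet, seq_len(n))

  colsum <- colSums(counts)
  freq <- sweep(counts, 2, colsum, "/")
  weights <- log2(sweep(freq, 1, bg, "/"))
  weights[!is.finite(weights)] <- weight_floor
  weights <- pmax(weights, weight_floor)

  structure(list(
    id = id, domain_id = domain_id, alphabet = alphabet,
    counts = counts, weights = weights, background = bg,
    pseudocount = pseudocount, n_peptides = length(peptides),
    weight_floor = weight_floor
  ), class = "slimppi_pwm")
}

#' @export
print.slimppi_pwm <- function(x, ...) {
  cat(sprintf("PWM '%s' (domain %s): %d x %d, %d peptides, pseudocount %g\n",
              x$id, x$domain_id, length(x$alphabet), ncol(x$weights),
              x$n_peptides, x$pseudocount))
  invisible(x)
}

motif_length <- function(pwm) ncol(pwm$weights)

#' Score a sequence window against a PWM
#'
#' Returns the additive log-odds score (bits) of a window of the motif
#' length: the sum over positions of the weight of the observed residue.
#'
#' @param pwm a `slimppi_pwm`.
#' @param window character scalar of length equal to the motif length.
#' @return numeric score in bits.
#' @export
score_window <- function(pwm, window) {
  n <- motif_length(pwm)
  if (nchar(window) != n) {
    slimppi_abort("slimppi_length_mismatch",
                  sprintf("window has length %d, motif length is %d",
                          nchar(window), n))
  }
  res <- split_residues(window)
  idx <- match(res, pwm$alphabet)
  if (anyNA(idx)) {
    slimppi_abort("slimppi_alphabet_error",
                  sprintf("residues outside the alphabet: %s",
                          paste(unique(res[is.na(idx)]), collapse = ", ")))
  }
  sum(pwm$weights[cbind(idx, seq_len(n))])
}

#' Exact null score distribution of a PWM
#'
#' Computes the distribution of window scores under the background model by
#' exact column-wise convolution: weights are rounded to a fixed granularity
#' (in bits) and the per-column score distributions are convolved over the
#' motif. The result supports exact p-values for any score without
#' simulation.
#'
#' @param pwm a `slimppi_pwm`.
#' @param granularity score discretisation step in bits (default 1e-3).
#' @return an object of class `slimppi_score_distribution` with elements
#'   `pwm_id`, `granularity`, `support` (ascending scores, bits), `prob`
#'   (point mass), `tail_prob` (probability of scoring >= each support
#'   value).
#' @export
score_distribution <- function(pwm, granularity = 1e-3) {
  if (!is.numeric(granularity) || granularity <= 0) {
    slimppi_abort("slimppi_config_error", "granularity must be > 0")
  }
  ints <- round(pwm$weights / granularity)
  bg <- pwm$background
  n <- ncol(ints)

  cur <- 1   # probability vector over integer scores curlo..curlo+length-1
  curlo <- 0
  for (j in seq_len(n)) {
    col <- ints[, j]
    nlo <- curlo + min(col)
    nhi <- (curlo + length(cur) - 1) + max(col)
    newv <- numeric(nhi - nlo + 1)
    for (a in seq_along(col)) {
      sh <- curlo + col[a] - nlo
      idx <- seq_along(cur) + sh
      newv[idx] <- newv[idx] + bg[a] * cur
    }
    cur <- newv
    curlo <- nlo
  }
  support_int <- seq.int(curlo, curlo + length(cur) - 1)
  tail <- pmin(pmax(rev(cumsum(rev(cur))), 0), 1)
  structure(list(
    pwm_id = pwm$id, granularity = granularity,
    support_int = support_int,
    support = support_int * granularity,
    prob = cur, tail_prob = tail,
    n_positions = n
  ), class = "slimppi_score_distribution")
}

#' @export
print.slimppi_score_distribution <- function(x, ...) {
  cat(sprintf("score distribution for PWM '%s': %d support points in [%.3f, %.3f] bits\n",
              x$pwm_id, length(x$support), min(x$support), max(x$support)))
  invisible(x)
}

#' P-value of a PWM score
#'
#' Probability that a background-random window scores at least as high as
#' `score`. The score is rounded to the distribution's granularity; scores
#' below the minimum achievable score return 1, scores above the maximum
#' return 0. Monotone non-increasing in `score`.
#'
#' @param dist a `slimppi_score_distribution`.
#' @param score numeric score(s) in bits (vectorised).
#' @return p-value(s) in `[0, 1]`.
#' @details The distribution's grid is built from per-column rounded
#'   weights, so an unrounded window score can land up to half a
#'   granularity step per motif position beyond the grid extremes; scores
#'   within that rounding slack of the extremes are clamped onto them.
#' @export
pvalue_of_score <- function(dist, score) {
  k <- round(score / dist$granularity)
  lo <- dist$support_int[1]
  hi <- dist$support_int[length(dist$support_int)]
  slack <- ceiling((dist$n_positions %||% 1) / 2) + 1L
  k[k > hi & k <= hi + slack] <- hi
  k[k < lo & k >= lo - slack] <- lo
  out <- numeric(length(k))
  out[k < lo] <- 1
  out[k > hi] <- 0
  inside <- k >= lo & k <= hi
  out[inside] <- dist$tail_prob[k[inside] - lo + 1]
  out
}

#' Score threshold attaining a p-value
#'
#' Returns the minimal support score whose tail probability is at most
#' `pvalue`, i.e. the scan threshold equivalent to a p-value cutoff.
#' Inverse-consistent with [pvalue_of_score()]:
#' `pvalue_of_score(dist, threshold_for_pvalue(dist, p)) <= p`.
#'
#' @param dist a `slimppi_score_distribution`.
#' @param pvalue requested p-value in `(0, 1]`.
#' @return score in bits.
#' @export
threshold_for_pvalue <- function(dist, pvalue) {
  if (!is.numeric(pvalue) || pvalue <= 0 || pvalue > 1) {
    slimppi_abort("slimppi_config_error", "pvalue must be in (0, 1]")
  }
  ok <- which(dist$tail_prob <= pvalue)
  if (length(ok) == 0) {
    slimppi_abort("slimppi_unattainable_threshold",
                  sprintf("smallest attainable tail probability is %.3g > %.3g",
                          min(dist$tail_prob), pvalue))
  }
  dist$support[ok[1]]
}

#' Per-column information content of a PWM
#'
#' Relative entropy (bits) of each column's pseudocounted frequency vector
#' against the background:
#' \deqn{IC_j = \sum_a f_{aj} \log_2 (f_{aj} / b_a) \ge 0.}
#' Columns matching the background carry 0 bits; a single-residue column at
#' uniform 20-letter background carries \eqn{\log_2 20 \approx 4.32} bits.
#'
#' @param pwm a `slimppi_pwm`.
#' @return numeric vector, one value per motif position.
#' @export
position_information_content <- function(pwm) {
  freq <- sweep(pwm$counts, 2, colSums(pwm$counts), "/")
  term <- freq * log2(sweep(freq, 1, pwm$background, "/"))
  term[freq == 0] <- 0
  unname(pmax(colSums(term), 0))
}

#' Significant (specificity-carrying) motif positions
#'
#' Motif columns whose information content is at least `ic_cutoff` bits.
#' Only these positions enter the peptide-level evidence scores (disorder,
#' accessibility, conservation), since low-information columns reflect
#' library background rather than binding specificity.
#'
#' @param pwm a `slimppi_pwm`.
#' @param ic_cutoff information-content cutoff in bits (default 1.0).
#' @return ascending integer vector of column indices. Raises a classed
#'   error (`slimppi_empty_significant_set`) when no column passes, since
#'   the peptide feature averages are undefined with zero positions.
#' @export
significant_positions <- function(pwm, ic_cutoff = 1.0) {
  if (ic_cutoff < 0) {
    slimppi_abort("slimppi_config_error", "ic_cutoff must be >= 0")
  }
  ic <- position_information_content(pwm)
  keep <- which(ic >= ic_cutoff)
  if (length(keep) == 0) {
    slimppi_abort("slimppi_empty_significant_set",
                  sprintf("no motif position reaches %.3g bits (max IC %.3g)",
                          ic_cutoff, max(ic)))
  }
  keep
}

#' Write / read a PWM as tab-separated text
#'
#' The serialisation holds a `#`-prefixed metadata block (id, domain id,
#' pseudocount, number of peptides, background) followed by the
#' pseudocounted count matrix: a header row of motif positions and one row
#' per residue. Weights are recomputed from counts and background on read,
#' so the log-odds invariant holds by construction.
#'
#' @param pwm a `slimppi_pwm`.
#' @param path file path.
#' @return `write_pwm` returns `path` invisibly; `read_pwm` returns a
#'   `slimppi_pwm`.
#' @export
write_pwm <- function(pwm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# id\t%s", pwm$id),
    sprintf("# domain_id\t%s", pwm$domain_id),
    sprintf("# pseudocount\t%.10g", pwm$pseudocount),
    sprintf("# n_peptides\t%d", pwm$n_peptides),
    sprintf("# weight_floor\t%.10g", pwm$weight_floor),
    sprintf("# background\t%s",
            paste(sprintf("%s:%.10g", pwm$alphabet, pwm$background),
                  collapse = ","))
  ), con)
  writeLines(paste(c("residue", colnames(pwm$counts)), collapse = "\t"), con)
  for (a in seq_along(pwm$alphabet)) {
    writeLines(paste(c(pwm$alphabet[a], sprintf("%.10g", pwm$counts[a, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_pwm
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    parts <- strsplit(sub("^# ", "", ln), "\t", fixed = TRUE)[[1]]
    meta[[parts[1]]] <- parts[2]
  }
  body <- lines[!grepl("^# ", lines)]
  body <- body[nzchar(body)]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  n <- length(header) - 1
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  alphabet <- vapply(rows, `[[`, character(1), 1)
  counts <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(n)))
  dimnames(counts) <- list(alphabet, header[-1])

  bg_parts <- strsplit(strsplit(meta$background, ",", fixed = TRUE)[[1]],
                       ":", fixed = TRUE)
  bg <- vapply(bg_parts, function(p) as.numeric(p[2]), numeric(1))
  names(bg) <- vapply(bg_parts, `[[`, character(1), 1)
  bg <- bg[alphabet]
  floor_ <- as.numeric(meta$weight_floor)

  freq <- sweep(counts, 2, colSums(counts), "/")
  weights <- log2(sweep(freq, 1, bg, "/"))
  weights[!is.finite(weights)] <- floor_
  weights <- pmax(weights, floor_)

  structure(list(
    id = meta$id, domain_id = meta$domain_id, alphabet = alphabet,
    counts = counts, weights = weights, background = bg,
    pseudocount = as.numeric(meta$pseudocount),
    n_peptides = as.integer(meta$n_peptides),
    weight_floor = floor_
  ), class = "slimppi_pwm")
}

#' Read binding peptides from FASTA or plain text
#'
#' Accepts either FASTA (`>`-headed records) or one peptide per line; blank
#' lines and `#` comments are ignored.
#'
#' @param path file path.
#' @return character vector of peptides.
#' @export
read_peptides <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) > 0 && any(startsWith(lines, ">"))) {
    seqs <- as.character(Biostrings::readAAStringSet(path))
    return(unname(seqs))
  }
  lines
}
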
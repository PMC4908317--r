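#' Fit a sequence-signature co-occurrence model
#'
#' Estimates, from a reference set of experimentally supported interactions,
#' how often signature (domain/motif) pairs co-occur across the two sides of
#' an interaction. For each reference pair every cross combination of one
#' signature from each protein counts as one observation of the unordered
#' signature pair; marginals count signature occurrences per interaction
#' side. Probabilities are Jeffreys-smoothed (`pseudocount` 0.5 by default)
#' so that unseen pairs keep a positive probability and the log-ratio score
#' stays defined.
#'
#' @param reference_ppis data frame (or 2-column matrix) of protein pairs.
#' @param signatures named list: protein id -> character vector of
#'   signature ids.
#' @param pseudocount smoothing mass per cell (default 0.5).
#' @return an object of class `slimppi_signature_model` with `vocab`,
#'   symmetric pair-probability matrix `p_pair`, marginals `p_marg`, and
#'   training metadata.
#' @export
fit_signature_model <- function(reference_ppis, signatures, pseudocount = 0.5) {
  ppis <- as.data.frame(reference_ppis)
  colnames(ppis)[1:2] <- c("a", "b")
  usable <- vapply(seq_len(nrow(ppis)), function(k) {
    length(signatures[[ppis$a[k]]]) > 0 && length(signatures[[ppis$b[k]]]) > 0
  }, logical(1))
  if (!any(usable)) {
    slimppi_abort("slimppi_insufficient_data",
                  "no reference pair where both proteins carry a signature")
  }
  ppis <- ppis[usable, , drop = FALSE]
  vocab <- sort(unique(unlist(signatures[unique(c(ppis$a, ppis$b))],
                              use.names = FALSE)))
  V <- length(vocab)
  C <- matrix(0, V, V, dimnames = list(vocab, vocab))
  marg <- stats::setNames(rep(0, V), vocab)
  total_obs <- 0
  for (k in seq_len(nrow(ppis))) {
    sa <- signatures[[ppis$a[k]]]
    sb <- signatures[[ppis$b[k]]]
    for (i in sa) {
      for (j in sb) {
        C[i, j] <- C[i, j] + 1
        if (i != j) C[j, i] <- C[j, i] + 1
      }
    }
    total_obs <- total_obs + length(sa) * length(sb)
    marg[sa] <- marg[sa] + 1
    marg[sb] <- marg[sb] + 1
  }
  # C[i,j] (i != j) now holds the count of unordered pair {i,j} in both
  # cells; C[i,i] holds the diagonal count once.
  K <- V * (V + 1) / 2
  p_pair <- (C + pseudocount) / (total_obs + pseudocount * K)
  p_marg <- (marg + pseudocount) / (sum(marg) + pseudocount * V)
  structure(list(vocab = vocab, p_pair = p_pair, p_marg = p_marg,
                 pseudocount = pseudocount, n_pairs = nrow(ppis),
                 n_observations = total_obs),
            class = "slimppi_signature_model")
}

#' @export
print.slimppi_signature_model <- function(x, ...) {
  cat(sprintf("signature model: %d signatures, %d reference pairs, pseudocount %g\n",
              length(x$vocab), x$n_pairs, x$pseudocount))
  invisible(x)
}

#' Co-occurring signature score of a protein pair
#'
#' Sums, over every cross combination of one signature from each protein,
#' the log-odds of seeing the signature pair on interacting proteins versus
#' independence:
#' \deqn{SS = \sum_{i,j} \log_2\frac{p_{ij}}{p_i\,p_j}.}
#' Positive contributions mark signature pairs enriched on known
#' interactions. `sign = "printed"` negates the sum for compatibility with
#' conventions that report the negated quantity. Signatures unknown to the
#' model are skipped; if either protein has none left, a classed error
#' (`slimppi_no_signature_evidence`) is raised.
#'
#' @param a_signatures,b_signatures character vectors of signature ids.
#' @param model a `slimppi_signature_model`.
#' @param sign `"association"` (default, enriched pairs score positive) or
#'   `"printed"` (negated).
#' @return numeric score (unbounded).
#' @export
signature_score <- function(a_signatures, b_signatures, model,
                            sign = c("association", "printed")) {
  sign <- match.arg(sign)
  sa <- intersect(a_signatures, model$vocab)
  sb <- intersect(b_signatures, model$vocab)
  if (length(sa) == 0 || length(sb) == 0) {
    slimppi_abort("slimppi_no_signature_evidence",
                  "no signature known to the model on one or both proteins")
  }
  ss <- 0
  for (i in sa) {
    for (j in sb) {
      ss <- ss + log2(model$p_pair[i, j] / (model$p_marg[i] * model$p_marg[j]))
    }
  }
  unname(if (sign == "printed") -ss else ss)
}

#' Read / write protein signature assignments and reference PPI lists
#'
#' Signatures: tab-separated (`protein_id`, `signature_id`), one row per
#' assignment. Reference PPIs: two tab-separated protein id columns.
#'
#' @param path file path.
#' @return `read_signatures`: named list protein -> signature ids;
#'   `read_ppi_list`: data frame with columns `a`, `b`.
#' @export
read_signatures <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", header = FALSE,
                          col.names = c("protein_id", "signature_id"),
                          stringsAsFactors = FALSE)
  lapply(split(df$signature_id, df$protein_id), unique)
}

#' @rdname read_signatures
#' @param signatures named list protein -> signature ids.
#' @export
write_signatures <- function(signatures, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# protein_id\tsignature_id", con)
  for (pid in names(signatures)) {
    writeLines(sprintf("%s\t%s", pid, signatures[[pid]]), con)
  }
  invisible(path)
}

#' @rdname read_signatures
#' @export
read_ppi_list <- function(path) {
  utils::read.delim(path, comment.char = "#", header = FALSE,
                    col.names = c("a", "b"), stringsAsFactors = FALSE)
}

#' @rdname read_signatures
#' @param ppis data frame of protein pairs.
#' @export
write_ppi_list <- function(ppis, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# protein_a\tprotein_b", con)
  writeLines(sprintf("%s\t%s", ppis[[1]], ppis[[2]]), con)
  invisible(path)
}
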
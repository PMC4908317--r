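#' Scan one protein sequence with a PWM
#'
#' Slides the motif over every window of the sequence (N- to C-terminal,
#' no heuristic skipping), scores each window, converts scores to exact
#' p-values, and keeps windows with p-value at or below the threshold.
#' Windows containing non-alphabet residues (X, U, B, ...) are skipped and
#' counted in the `skipped_windows` attribute of the result.
#'
#' @param pwm a `slimppi_pwm`.
#' @param dist the matching `slimppi_score_distribution` (see
#'   [score_distribution()]).
#' @param protein_id identifier recorded with each hit.
#' @param sequence protein sequence (character scalar).
#' @param pvalue_threshold keep windows with p-value `<=` this value,
#'   in `(0, 1]`.
#' @param significant_cols significant motif columns used to annotate hits
#'   with significant residue positions; defaults to
#'   `significant_positions(pwm, ic_cutoff)`. If no column passes the
#'   cutoff the hits carry an empty position list and downstream peptide
#'   feature scoring will refuse them.
#' @param ic_cutoff cutoff passed to [significant_positions()] when
#'   `significant_cols` is `NULL`.
#' @return a hit table (`data.frame`) with columns `protein_id`, `pwm_id`,
#'   `domain_id`, `start`, `end` (1-based inclusive), `window_seq`, `score`
#'   (bits), `pvalue`, `significant_positions` (comma-separated 1-based
#'   protein residue indices), sorted by `start`; attribute
#'   `skipped_windows` counts windows invalidated by ambiguous residues.
#' @export
scan_sequence <- function(pwm, dist, protein_id, sequence, pvalue_threshold,
                          significant_cols = NULL, ic_cutoff = 1.0) {
  if (!is.numeric(pvalue_threshold) || pvalue_threshold <= 0 ||
      pvalue_threshold > 1) {
    slimppi_abort("slimppi_config_error",
                  "pvalue_threshold must be in (0, 1]")
  }
  n <- motif_length(pwm)
  if (is.null(significant_cols)) {
    significant_cols <- tryCatch(
      significant_positions(pwm, ic_cutoff),
      slimppi_empty_significant_set = function(e) integer(0)
    )
  }
  empty <- empty_hit_table()
  L <- nchar(sequence)
  if (L < n) {
    attr(empty, "skipped_windows") <- 0L
    return(empty)
  }
  res <- split_residues(sequence)
  idx <- match(res, pwm$alphabet)
  n_win <- L - n + 1
  scores <- numeric(n_win)
  for (j in seq_len(n)) {
    scores <- scores + pwm$weights[cbind(idx[j:(j + n_win - 1)], j)]
  }
  skipped <- sum(is.na(scores))
  keep_idx <- which(!is.na(scores))
  pvals <- pvalue_of_score(dist, scores[keep_idx])
  sel <- keep_idx[pvals <= pvalue_threshold]
  pv <- pvals[pvals <= pvalue_threshold]
  if (length(sel) == 0) {
    attr(empty, "skipped_windows") <- skipped
    return(empty)
  }
  sig_str <- vapply(sel, function(s) {
    paste(s - 1L + significant_cols, collapse = ",")
  }, character(1))
  out <- data.frame(
    protein_id = protein_id,
    pwm_id = pwm$id,
    domain_id = pwm$domain_id,
    start = as.integer(sel),
    end = as.integer(sel + n - 1L),
    window_seq = substring(sequence, sel, sel + n - 1L),
    score = scores[sel],
    pvalue = pv,
    significant_positions = sig_str,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped_windows") <- skipped
  out
}

empty_hit_table <- function() {
  data.frame(
    protein_id = character(0), pwm_id = character(0),
    domain_id = character(0), start = integer(0), end = integer(0),
    window_seq = character(0), score = numeric(0), pvalue = numeric(0),
    significant_positions = character(0), stringsAsFactors = FALSE
  )
}

#' Scan a proteome with a set of PWMs
#'
#' Runs [scan_sequence()] for every (PWM, protein) combination and returns
#' the concatenated hit table in deterministic order (`pwm_id`,
#' `protein_id`, `start`). Null score distributions are computed once per
#' PWM.
#'
#' @param pwms a list of `slimppi_pwm` objects.
#' @param proteome a named character vector, a `Biostrings::AAStringSet`, or
#'   the path of a FASTA file. Sequence names must be unique.
#' @param pvalue_threshold p-value cutoff in `(0, 1]`.
#' @param granularity score discretisation for the null distributions.
#' @param ic_cutoff information-content cutoff for significant positions.
#' @return hit table as in [scan_sequence()], with attributes
#'   `skipped_windows` (total) and `windows_scanned`.
#' @export
scan_proteome <- function(pwms, proteome, pvalue_threshold,
                          granularity = 1e-3, ic_cutoff = 1.0) {
  if (inherits(pwms, "slimppi_pwm")) pwms <- list(pwms)
  proteome <- as_proteome(proteome)
  if (length(proteome) == 0) {
    slimppi_abort("slimppi_empty_input", "proteome contains no sequences")
  }
  if (anyDuplicated(names(proteome))) {
    dup <- unique(names(proteome)[duplicated(names(proteome))])
    slimppi_abort("slimppi_duplicate_id",
                  sprintf("duplicate protein ids in proteome: %s",
                          paste(dup, collapse = ", ")))
  }
  pieces <- list()
  skipped <- 0L
  windows <- 0L
  for (pwm in pwms) {
    dist <- score_distribution(pwm, granularity)
    sig <- tryCatch(significant_positions(pwm, ic_cutoff),
                    slimppi_empty_significant_set = function(e) integer(0))
    n <- motif_length(pwm)
    for (pid in names(proteome)) {
      h <- scan_sequence(pwm, dist, pid, proteome[[pid]], pvalue_threshold,
                         significant_cols = sig)
      skipped <- skipped + attr(h, "skipped_windows")
      windows <- windows + max(nchar(proteome[[pid]]) - n + 1L, 0L)
      if (nrow(h) > 0) pieces[[length(pieces) + 1L]] <- h
    }
  }
  out <- if (length(pieces) > 0) do.call(rbind, pieces) else empty_hit_table()
  out <- out[order(out$pwm_id, out$protein_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped_windows") <- skipped
  attr(out, "windows_scanned") <- windows
  out
}

as_proteome <- function(proteome) {
  if (methods::is(proteome, "XStringSet")) {
    seqs <- as.character(proteome)
    names(seqs) <- sub("\\s.*$", "", names(proteome))
    return(as.list(seqs))
  }
  if (is.character(proteome) && length(proteome) == 1 &&
      file.exists(proteome)) {
    seqs <- Biostrings::readAAStringSet(proteome)
    return(as_proteome(seqs))
  }
  if (is.character(proteome)) {
    if (is.null(names(proteome))) {
      slimppi_abort("slimppi_config_error",
                    "proteome sequences must be named")
    }
    return(as.list(proteome))
  }
  if (is.list(proteome)) return(proteome)
  slimppi_abort("slimppi_config_error", "unrecognised proteome input")
}

#' Binding-site overlap fraction of two hits
#'
#' Fraction of the shorter hit covered by the intersection of the two
#' residue ranges; the measure used to match predicted binding sites to
#' known ones (e.g. "at least 60% overlapping binding site"). The shorter
#' hit is the denominator; set `denominator = "union"` for a Jaccard-style
#' alternative.
#'
#' @param hit_a,hit_b one-row hit-table rows (or lists) with `protein_id`,
#'   `start`, `end`.
#' @param denominator `"shorter"` (default) or `"union"`.
#' @return overlap fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(hit_a, hit_b, denominator = c("shorter", "union")) {
  denominator <- match.arg(denominator)
  if (hit_a$protein_id != hit_b$protein_id) {
    slimppi_abort("slimppi_domain_mismatch",
                  "hits are on different proteins")
  }
  inter <- min(hit_a$end, hit_b$end) - max(hit_a$start, hit_b$start) + 1L
  inter <- max(inter, 0L)
  len_a <- hit_a$end - hit_a$start + 1L
  len_b <- hit_b$end - hit_b$start + 1L
  den <- switch(denominator,
                shorter = min(len_a, len_b),
                union = len_a + len_b - inter)
  inter / den
}

#' Write / read a hit table
#'
#' Tab-separated with a `#`-prefixed header naming the columns; numeric
#' columns at 6-decimal precision (p-values in scientific notation).
#'
#' @param hits hit table from [scan_proteome()].
#' @param path file path.
#' @export
write_hit_table <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cols <- c("protein_id", "pwm_id", "domain_id", "start", "end",
            "window_seq", "score", "pvalue", "significant_positions")
  writeLines(paste0("# ", paste(cols, collapse = "\t")), con)
  if (nrow(hits) > 0) {
    lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%.6f\t%.6e\t%s",
                     hits$protein_id, hits$pwm_id, hits$domain_id,
                     hits$start, hits$end, hits$window_seq, hits$score,
                     hits$pvalue, hits$significant_positions)
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_hit_table
#' @export
read_hit_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) return(empty_hit_table())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    protein_id = vapply(parts, `[[`, character(1), 1),
    pwm_id = vapply(parts, `[[`, character(1), 2),
    domain_id = vapply(parts, `[[`, character(1), 3),
    start = as.integer(vapply(parts, `[[`, character(1), 4)),
    end = as.integer(vapply(parts, `[[`, character(1), 5)),
    window_seq = vapply(parts, `[[`, character(1), 6),
    score = as.numeric(vapply(parts, `[[`, character(1), 7)),
    pvalue = as.numeric(vapply(parts, `[[`, character(1), 8)),
    significant_positions = vapply(parts, function(p) {
      if (length(p) >= 9) p[[9]] else ""
    }, character(1)),
    stringsAsFactors = FALSE
  )
}

parse_positions <- function(x) {
  if (is.na(x) || !nzchar(x)) return(integer(0))
  as.integer(strsplit(x, ",", fixed = TRUE)[[1]])
}
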
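#' Per-residue feature track
#'
#' A track carries one value per residue of a protein: intrinsic-disorder
#' probability (or a 0/1 call), relative solvent accessibility (fraction in
#' `[0, 1]`), or a conservation score (higher = more conserved, typically
#' z-normalised across the protein).
#'
#' @param protein_id protein identifier.
#' @param kind one of `"disorder"`, `"rsa"`, `"conservation"`.
#' @param values numeric vector, one value per residue.
#' @return an object of class `slimppi_track`.
#' @export
residue_track <- function(protein_id, kind = c("disorder", "rsa", "conservation"),
                          values) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (kind %in% c("disorder", "rsa") &&
      (any(values < 0) || any(values > 1))) {
    slimppi_abort("slimppi_track_mismatch",
                  sprintf("%s track values must lie in [0, 1]", kind))
  }
  structure(list(protein_id = protein_id, kind = kind, values = values),
            class = "slimppi_track")
}

track_values <- function(track) {
  if (inherits(track, "slimppi_track")) track$values else as.numeric(track)
}

hit_significant_values <- function(hit, track) {
  sig <- parse_positions(hit$significant_positions)
  if (length(sig) == 0) {
    slimppi_abort("slimppi_empty_significant_set",
                  "hit has no significant positions; feature undefined")
  }
  vals <- track_values(track)
  if (length(vals) < hit$end) {
    slimppi_abort("slimppi_track_mismatch",
                  sprintf("track has %d residues, hit ends at %d",
                          length(vals), hit$end))
  }
  vals[sig]
}

#' Peptide-level evidence scores for a binding-site hit
#'
#' The three sequence-context features of a candidate binding site are
#' fractions or means over the *significant* motif residues of the hit
#' (`N` = number of significant positions):
#' \itemize{
#'   \item `disorder_score` (DR): fraction of significant residues called
#'     disordered. Probabilistic tracks are binarised at `binarize_at`
#'     (inclusive); tracks already holding 0/1 calls pass through unchanged.
#'   \item `accessibility_score` (SA): fraction of significant residues
#'     exposed, i.e. with relative solvent accessibility `>= rsa_cutoff`
#'     (default 0.25, the conventional 25% exposure call).
#'   \item `conservation_score` (PC): mean conservation value over the
#'     significant residues.
#' }
#'
#' @param hit a one-row hit-table row (or list) with `start`, `end`,
#'   `significant_positions`.
#' @param track a `slimppi_track` (or bare numeric vector) covering the
#'   protein.
#' @param binarize_at disorder call threshold, inclusive (default 0.5).
#' @param rsa_cutoff exposure call threshold, inclusive (default 0.25).
#' @return a score in `[0, 1]` for DR/SA; unbounded mean for PC.
#' @export
disorder_score <- function(hit, track, binarize_at = 0.5) {
  vals <- hit_significant_values(hit, track)
  mean(vals >= binarize_at)
}

#' @rdname disorder_score
#' @export
accessibility_score <- function(hit, track, rsa_cutoff = 0.25) {
  vals <- hit_significant_values(hit, track)
  mean(vals >= rsa_cutoff)
}

#' @rdname disorder_score
#' @export
conservation_score <- function(hit, track) {
  mean(hit_significant_values(hit, track))
}

#' Conservation track from a multiple sequence alignment
#'
#' Unweighted sum-of-pairs conservation: at each alignment column the score
#' is the average substitution score over all unordered row pairs, with any
#' pair involving a gap scored 0 (but still counted). Columns where the
#' reference row has a gap are dropped, so the track maps one-to-one onto
#' the reference residues, and the per-column scores are then z-normalised
#' across the reference columns (a constant profile yields all zeros).
#'
#' @param alignment named character vector of equal-length gapped rows.
#' @param reference name of the reference row.
#' @param submat substitution matrix; default is the identity matrix
#'   (match 1, mismatch 0), giving the fraction of agreeing pairs.
#' @param normalize z-normalise across columns (default `TRUE`).
#' @return a `slimppi_track` of kind `"conservation"` for the reference
#'   protein.
#' @export
conservation_from_msa <- function(alignment, reference, submat = NULL,
                                  normalize = TRUE) {
  if (length(alignment) < 2) {
    slimppi_abort("slimppi_insufficient_data",
                  "an alignment needs at least 2 rows")
  }
  if (is.null(names(alignment)) || !(reference %in% names(alignment))) {
    slimppi_abort("slimppi_missing_reference",
                  sprintf("reference row '%s' not found", reference))
  }
  if (length(unique(nchar(alignment))) != 1) {
    slimppi_abort("slimppi_length_mismatch", "alignment rows differ in length")
  }
  rows <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  if (is.null(submat)) {
    letters <- setdiff(unique(as.vector(rows)), "-")
    submat <- identity_matrix(letters)
  }
  R <- nrow(rows)
  pairs <- utils::combn(R, 2)
  n_pairs <- ncol(pairs)
  col_score <- apply(rows, 2, function(col) {
    s <- 0
    for (k in seq_len(n_pairs)) {
      x <- col[pairs[1, k]]
      y <- col[pairs[2, k]]
      if (x != "-" && y != "-") s <- s + submat[x, y]
    }
    s / n_pairs
  })
  ref_row <- rows[reference, ]
  keep <- ref_row != "-"
  scores <- col_score[keep]
  if (normalize) {
    sdv <- stats::sd(scores)
    scores <- if (is.na(sdv) || sdv == 0) rep(0, length(scores))
              else (scores - mean(scores)) / sdv
  }
  residue_track(reference, "conservation", scores)
}

#' Contact model from a raw domain-peptide contact map
#'
#' Reduces a co-complex structure (already expressed as residue-pair contact
#' areas, in square Angstroms) to a normalised contact model: areas are
#' divided by the largest pair area within the model, so normalised contact
#' strengths lie in `(0, 1]` with the strongest pair at 1.
#'
#' @param model_id identifier (PDB-style).
#' @param domain_seq,peptide_seq sequences of the two chains.
#' @param contacts data frame with columns `domain_index`, `peptide_index`
#'   (1-based), `area` (non-negative; at least one > 0).
#' @return an object of class `slimppi_contact_model` with the normalised
#'   `contacts` (column `c` in `(0, 1]`).
#' @export
contact_model_from_map <- function(model_id, domain_seq, peptide_seq, contacts) {
  contacts <- as.data.frame(contacts)
  if (nrow(contacts) < 1) {
    slimppi_abort("slimppi_degenerate_model", "contact map has no pairs")
  }
  if (any(contacts$domain_index < 1) ||
      any(contacts$domain_index > nchar(domain_seq)) ||
      any(contacts$peptide_index < 1) ||
      any(contacts$peptide_index > nchar(peptide_seq))) {
    slimppi_abort("slimppi_track_mismatch",
                  "contact indices outside chain sequences")
  }
  if (all(contacts$area <= 0)) {
    slimppi_abort("slimppi_degenerate_model", "all contact areas are zero")
  }
  contacts <- contacts[contacts$area > 0, , drop = FALSE]
  contacts$c <- contacts$area / max(contacts$area)
  contacts <- contacts[order(contacts$domain_index, contacts$peptide_index), ,
                       drop = FALSE]
  rownames(contacts) <- NULL
  structure(list(model_id = model_id, domain_seq = domain_seq,
                 peptide_seq = peptide_seq,
                 contacts = contacts[, c("domain_index", "peptide_index", "c")]),
            class = "slimppi_contact_model")
}

#' Structural contact score of a domain-peptide pair
#'
#' Transfers residue-residue contacts from domain-peptide co-complex base
#' models to a query pair. For each base model the query domain is globally
#' aligned to the model domain and the query peptide to the model peptide
#' (independently, since contacts are defined between the two chains). A
#' model contact pair contributes its normalised area only when *both* of
#' its residues are aligned to query residues; the denominator is always the
#' model's full number of contact pairs, so alignment gaps at contact
#' residues lower the average -- a gap at a large-area contact hurts more
#' than one at a small-area contact. The score is the best average over the
#' base models:
#' \deqn{SC = \max_j \frac{\sum_i c_{ij}\,[\mathrm{aligned}]}{N_j} \in [0,1].}
#'
#' @param domain_seq,peptide_seq query sequences.
#' @param base_models list of `slimppi_contact_model` objects.
#' @param submat,gap_open,gap_extend aligner configuration (see
#'   [align_global()]).
#' @return list with `sc` (the score), `model_id` of the best model (first
#'   on ties, in input order), and `per_model` named score vector. If no
#'   contact pair is alignable in any model, `sc` is 0 and a classed warning
#'   (`slimppi_no_contact_alignment`) is raised.
#' @export
structural_contact_score <- function(domain_seq, peptide_seq, base_models,
                                     submat = NULL, gap_open = -10,
                                     gap_extend = -1) {
  if (inherits(base_models, "slimppi_contact_model")) {
    base_models <- list(base_models)
  }
  if (length(base_models) < 1) {
    slimppi_abort("slimppi_insufficient_data", "at least one base model required")
  }
  if (is.null(submat)) submat <- blosum62()
  per <- vapply(base_models, function(model) {
    ad <- align_global(model$domain_seq, domain_seq, submat, gap_open, gap_extend)
    ap <- align_global(model$peptide_seq, peptide_seq, submat, gap_open, gap_extend)
    dom_aligned <- ad$mapping[, "a"]
    pep_aligned <- ap$mapping[, "a"]
    ct <- model$contacts
    ok <- ct$domain_index %in% dom_aligned & ct$peptide_index %in% pep_aligned
    sum(ct$c[ok]) / nrow(ct)
  }, numeric(1))
  names(per) <- vapply(base_models, `[[`, character(1), "model_id")
  best <- which.max(per)
  if (max(per) == 0) {
    slimppi_warn("slimppi_no_contact_alignment",
                 "no contact pair alignable in any base model; SC = 0")
  }
  list(sc = unname(per[best]), model_id = names(per)[best], per_model = per)
}

#' Read / write per-residue feature tracks
#'
#' Track files are tab-separated with columns `protein_id`, `position`,
#' `value` and optionally a fourth `kind` column (for a combined file); a
#' single-kind file takes its kind from the `kind` argument. Positions must
#' run 1..L contiguously per protein.
#'
#' @param path file path.
#' @param kind track kind for 3-column files.
#' @return nested list: `tracks[[protein_id]][[kind]]` is a `slimppi_track`.
#' @export
read_tracks <- function(path, kind = NULL) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  nfield <- lengths(rows)
  if (any(nfield < 3)) {
    slimppi_abort("slimppi_parse_error",
                  sprintf("track file %s: line %d has %d fields (expected >= 3)",
                          path, which(keep)[which(nfield < 3)[1]],
                          min(nfield)))
  }
  df <- data.frame(
    protein_id = vapply(rows, `[[`, character(1), 1),
    position = as.integer(vapply(rows, `[[`, character(1), 2)),
    value = as.numeric(vapply(rows, `[[`, character(1), 3)),
    stringsAsFactors = FALSE
  )
  df$kind <- if (all(nfield >= 4)) vapply(rows, `[[`, character(1), 4)
             else {
               if (is.null(kind)) {
                 slimppi_abort("slimppi_parse_error",
                               sprintf("track file %s has no kind column; pass `kind`", path))
               }
               kind
             }
  out <- list()
  for (key in unique(paste(df$protein_id, df$kind, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- df[df$protein_id == parts[1] & df$kind == parts[2], ]
    sub <- sub[order(sub$position), ]
    if (!identical(sub$position, seq_len(nrow(sub)))) {
      slimppi_abort("slimppi_parse_error",
                    sprintf("track %s/%s: positions are not contiguous 1..%d",
                            parts[1], parts[2], nrow(sub)))
    }
    out[[parts[1]]][[parts[2]]] <- residue_track(parts[1], parts[2], sub$value)
  }
  out
}

#' @rdname read_tracks
#' @param tracks nested list as returned by [read_tracks()].
#' @export
write_tracks <- function(tracks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# protein_id\tposition\tvalue\tkind", con)
  for (pid in names(tracks)) {
    for (kind in names(tracks[[pid]])) {
      v <- tracks[[pid]][[kind]]$values
      writeLines(sprintf("%s\t%d\t%.6f\t%s", pid, seq_along(v), v, kind), con)
    }
  }
  invisible(path)
}

#' Read / write contact models
#'
#' The contact map file is tab-separated (`model_id`, `domain_index`,
#' `peptide_index`, `area`); the chain FASTA holds two records per model
#' named `<model_id>|domain` and `<model_id>|peptide`.
#'
#' @param map_path contact map path.
#' @param fasta_path chain FASTA path.
#' @return list of `slimppi_contact_model`.
#' @export
read_contact_models <- function(map_path, fasta_path) {
  chains <- as.character(Biostrings::readAAStringSet(fasta_path))
  df <- utils::read.delim(map_path, comment.char = "#", header = FALSE,
                          col.names = c("model_id", "domain_index",
                                        "peptide_index", "area"),
                          stringsAsFactors = FALSE)
  lapply(unique(df$model_id), function(mid) {
    dom <- chains[paste0(mid, "|domain")]
    pep <- chains[paste0(mid, "|peptide")]
    if (is.na(dom) || is.na(pep)) {
      slimppi_abort("slimppi_parse_error",
                    sprintf("chains for model '%s' missing from %s", mid, fasta_path))
    }
    contact_model_from_map(mid, unname(dom), unname(pep),
                           df[df$model_id == mid,
                              c("domain_index", "peptide_index", "area")])
  })
}

#' @rdname read_contact_models
#' @param models list of `slimppi_contact_model` (with raw areas recomputed
#'   from normalised ones; the maximum is written as 1.0).
#' @param map_path,fasta_path output paths.
#' @export
write_contact_models <- function(models, map_path, fasta_path) {
  con <- file(map_path, "w")
  writeLines("# model_id\tdomain_index\tpeptide_index\tarea", con)
  for (m in models) {
    ct <- m$contacts
    writeLines(sprintf("%s\t%d\t%d\t%.6f", m$model_id, ct$domain_index,
                       ct$peptide_index, ct$c), con)
  }
  close(con)
  seqs <- unlist(lapply(models, function(m) {
    stats::setNames(c(m$domain_seq, m$peptide_seq),
                    paste0(m$model_id, c("|domain", "|peptide")))
  }))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), fasta_path)
  invisible(map_path)
}
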
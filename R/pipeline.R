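#' Load and validate a dataset bundle
#'
#' Reads the YAML run configuration (paths + parameters), checks every
#' referenced file, parses all inputs, and validates parameter ranges. All
#' problems found are reported together in one classed error
#' (`slimppi_bundle_error`) listing each file or parameter at fault.
#'
#' @param config_path path of the bundle `config.yaml` (paths are resolved
#'   relative to its directory).
#' @return an object of class `slimppi_bundle` holding the parsed inputs
#'   (`proteome`, `pwms`, `tracks`, `contact_models`, `dag`, `annotations`,
#'   `panel`, `signatures`, `reference_ppis`, `labeled_train`,
#'   `labeled_test`, `domain_map`, truth tables when present) and the
#'   validated `params`.
#' @export
load_dataset_bundle <- function(config_path) {
  if (!file.exists(config_path)) {
    slimppi_abort("slimppi_file_not_found",
                  sprintf("config file not found: %s", config_path))
  }
  cfg <- yaml::read_yaml(config_path)
  base <- dirname(config_path)
  problems <- character(0)
  resolve <- function(key, required = TRUE) {
    rel <- cfg$paths[[key]]
    if (is.null(rel)) {
      if (required) problems <<- c(problems, sprintf("missing path '%s'", key))
      return(NA_character_)
    }
    p <- file.path(base, rel)
    if (!file.exists(p)) {
      problems <<- c(problems, sprintf("file not found for '%s': %s", key, p))
      return(NA_character_)
    }
    p
  }
  paths <- sapply(c("proteome", "peptides_dir", "tracks", "contact_map",
                    "contact_chains", "ontology", "annotations",
                    "expression_manifest", "signatures", "reference_ppis",
                    "labeled_train", "labeled_test", "domain_map"),
                  resolve)
  truth_sites <- resolve("truth_sites", required = FALSE)
  truth_pairs <- resolve("truth_pairs", required = FALSE)

  par <- cfg$params
  check_range <- function(name, lo, hi, lo_open = TRUE, hi_open = FALSE) {
    v <- par[[name]]
    if (is.null(v) || !is.numeric(v) ||
        (if (lo_open) v <= lo else v < lo) ||
        (if (hi_open) v >= hi else v > hi)) {
      problems <<- c(problems,
                     sprintf("parameter '%s' out of range or missing", name))
    }
  }
  check_range("pvalue_threshold", 0, 1)
  check_range("granularity", 0, Inf)
  check_range("tcss_cutoff_cc", 0, Inf)
  check_range("tcss_cutoff_bp", 0, Inf)
  check_range("tcss_cutoff_mf", 0, Inf)
  check_range("decision_threshold", 0, 1, hi_open = TRUE)
  check_range("prior", 0, 1, hi_open = TRUE)
  if (length(problems) > 0) {
    slimppi_abort("slimppi_bundle_error",
                  paste(c("invalid dataset bundle:", problems),
                        collapse = "\n  - "))
  }

  parse_problems <- character(0)
  grab <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      parse_problems <<- c(parse_problems, sprintf("%s: %s", what,
                                                   conditionMessage(e)))
      NULL
    })
  }
  proteome <- grab("proteome", as_proteome(paths[["proteome"]]))
  domain_map <- grab("domain_map",
                     utils::read.delim(paths[["domain_map"]],
                                       stringsAsFactors = FALSE))
  pep_files <- list.files(paths[["peptides_dir"]], full.names = TRUE)
  pwms <- grab("peptides", lapply(pep_files, function(f) {
    d <- sub("\\.[^.]*$", "", basename(f))
    build_pwm(read_peptides(f), background = par$background %||% "uniform",
              pseudocount = par$pseudocount %||% 0.05,
              id = paste0(d, "_pwm"), domain_id = d,
              proteome = unlist(proteome))
  }))
  tracks <- grab("tracks", read_tracks(paths[["tracks"]]))
  contact_models <- grab("contact models",
                         read_contact_models(paths[["contact_map"]],
                                             paths[["contact_chains"]]))
  dag <- grab("ontology", read_obo(paths[["ontology"]]))
  annotations <- grab("annotations", read_annotations(paths[["annotations"]]))
  panel <- grab("expression panel",
                read_expression_panel(paths[["expression_manifest"]]))
  signatures <- grab("signatures", read_signatures(paths[["signatures"]]))
  reference_ppis <- grab("reference PPIs",
                         read_ppi_list(paths[["reference_ppis"]]))
  labeled_train <- grab("labeled training table",
                        utils::read.delim(paths[["labeled_train"]],
                                          stringsAsFactors = FALSE))
  labeled_test <- grab("labeled test table",
                       utils::read.delim(paths[["labeled_test"]],
                                         stringsAsFactors = FALSE))
  truth_sites_df <- if (!is.na(truth_sites))
    grab("truth sites", utils::read.delim(truth_sites,
                                          stringsAsFactors = FALSE)) else NULL
  truth_pairs_df <- if (!is.na(truth_pairs))
    grab("truth pairs", utils::read.delim(truth_pairs,
                                          stringsAsFactors = FALSE)) else NULL
  if (length(parse_problems) > 0) {
    slimppi_abort("slimppi_bundle_error",
                  paste(c("dataset bundle failed to parse:", parse_problems),
                        collapse = "\n  - "))
  }
  structure(list(
    proteome = proteome, pwms = pwms, tracks = tracks,
    contact_models = contact_models, dag = dag, annotations = annotations,
    panel = panel, signatures = signatures, reference_ppis = reference_ppis,
    labeled_train = labeled_train, labeled_test = labeled_test,
    domain_map = domain_map, truth_sites = truth_sites_df,
    truth_pairs = truth_pairs_df, params = par, base = base
  ), class = "slimppi_bundle")
}

#' @export
print.slimppi_bundle <- function(x, ...) {
  cat(sprintf("dataset bundle: %d proteins, %d PWMs, %d contact models\n",
              length(x$proteome), length(x$pwms), length(x$contact_models)))
  invisible(x)
}

#' Run the full binding-site prediction pipeline
#'
#' Executes scan -> peptide features -> protein features -> classifier
#' posteriors -> Bayes combination on a loaded bundle:
#' \enumerate{
#'   \item scan every proteome sequence with every PWM at the configured
#'     p-value threshold;
#'   \item score each hit's disorder, accessibility and conservation over
#'     its significant residues, and its structural contact against the
#'     base models (the domain-to-model alignments are cached per domain);
#'   \item score each (SH3 carrier, target) pair's GO similarities (per
#'     namespace, at the configured cutoffs), combined expression
#'     correlation and signature score -- any feature whose evidence is
#'     absent degrades to missing, never to a fabricated value;
#'   \item train the two naive Bayes classifiers on the bundle's labelled
#'     table (unless prefit models are supplied) and combine their
#'     posteriors per hit.
#' }
#' The run is fully deterministic: no stage draws random numbers.
#'
#' @param bundle a `slimppi_bundle`.
#' @param pep_model,pro_model optional prefit `slimppi_nb_model`s;
#'   fitted from `bundle$labeled_train` when `NULL`.
#' @return list with `records` (per-hit predictions), `pairs` (per-PPI
#'   aggregated scores), `models`, and `report` (counts per stage:
#'   windows scanned, windows skipped, hits, candidates with missing
#'   features, predictions at or above the threshold).
#' @export
run_predict_pipeline <- function(bundle, pep_model = NULL, pro_model = NULL) {
  par <- bundle$params
  report <- list()

  hits <- scan_proteome(bundle$pwms, bundle$proteome,
                        pvalue_threshold = par$pvalue_threshold,
                        granularity = par$granularity %||% 1e-3,
                        ic_cutoff = par$ic_cutoff %||% 1.0)
  report$windows_scanned <- attr(hits, "windows_scanned")
  report$windows_skipped <- attr(hits, "skipped_windows")
  report$hits <- nrow(hits)
  if (nrow(hits) == 0) {
    slimppi_abort("slimppi_empty_input", "scan stage produced no hits")
  }

  carrier_of <- stats::setNames(bundle$domain_map$protein_id,
                                bundle$domain_map$domain_id)
  domain_seq_of <- stats::setNames(bundle$domain_map$domain_seq,
                                   bundle$domain_map$domain_id)
  hits$candidate_id <- paste(hits$pwm_id, hits$protein_id, hits$start,
                             sep = ":")
  hits$pair_id <- paste(carrier_of[hits$domain_id], hits$protein_id,
                        sep = "~")

  # ---- peptide features ----
  submat <- blosum62()
  # cache domain-vs-model alignment coverage per (domain, model)
  dom_cover <- list()
  get_cover <- function(domain_id, model_k) {
    key <- paste(domain_id, model_k)
    if (is.null(dom_cover[[key]])) {
      m <- bundle$contact_models[[model_k]]
      al <- align_global(m$domain_seq, domain_seq_of[[domain_id]], submat)
      dom_cover[[key]] <<- al$mapping[, "a"]
    }
    dom_cover[[key]]
  }
  safe <- function(expr) {
    tryCatch(expr, slimppi_error = function(e) NA_real_)
  }
  n_hit <- nrow(hits)
  DR <- SA <- PC <- SC <- rep(NA_real_, n_hit)
  for (k in seq_len(n_hit)) {
    h <- hits[k, ]
    tr <- bundle$tracks[[h$protein_id]]
    if (!is.null(tr$disorder)) {
      DR[k] <- safe(disorder_score(h, tr$disorder,
                                   binarize_at = par$binarize_at %||% 0.5))
    }
    if (!is.null(tr$rsa)) {
      SA[k] <- safe(accessibility_score(h, tr$rsa,
                                        rsa_cutoff = par$rsa_cutoff %||% 0.25))
    }
    if (!is.null(tr$conservation)) {
      PC[k] <- safe(conservation_score(h, tr$conservation))
    }
    per <- vapply(seq_along(bundle$contact_models), function(j) {
      m <- bundle$contact_models[[j]]
      ap <- align_global(m$peptide_seq, h$window_seq, submat)
      pep_aligned <- ap$mapping[, "a"]
      dom_aligned <- get_cover(h$domain_id, j)
      ct <- m$contacts
      ok <- ct$domain_index %in% dom_aligned & ct$peptide_index %in% pep_aligned
      sum(ct$c[ok]) / nrow(ct)
    }, numeric(1))
    SC[k] <- max(per)
  }
  pep_features <- data.frame(candidate_id = hits$candidate_id,
                             DR = DR, SA = SA, PC = PC, SC = SC,
                             stringsAsFactors = FALSE)
  report$hits_missing_peptide_feature <-
    sum(!stats::complete.cases(pep_features[, c("DR", "SA", "PC", "SC")]))

  # ---- protein pair features ----
  pair_tab <- unique(data.frame(
    pair_id = hits$pair_id,
    a = unname(carrier_of[hits$domain_id]),
    b = hits$protein_id, stringsAsFactors = FALSE))
  idx_cc <- tcss_index(bundle$dag, bundle$annotations, "C",
                       par$tcss_cutoff_cc,
                       evidence_exclude = par$evidence_exclude %||% "IEA")
  idx_bp <- tcss_index(bundle$dag, bundle$annotations, "P",
                       par$tcss_cutoff_bp,
                       evidence_exclude = par$evidence_exclude %||% "IEA")
  idx_mf <- tcss_index(bundle$dag, bundle$annotations, "F",
                       par$tcss_cutoff_mf,
                       evidence_exclude = par$evidence_exclude %||% "IEA")
  sig_model <- fit_signature_model(bundle$reference_ppis, bundle$signatures,
                                   pseudocount = par$signature_pseudocount %||% 0.5)
  np <- nrow(pair_tab)
  CC <- BP <- MF <- EX <- SS <- rep(NA_real_, np)
  for (k in seq_len(np)) {
    a <- pair_tab$a[k]; b <- pair_tab$b[k]
    CC[k] <- safe(tcss_similarity(a, b, index = idx_cc))
    BP[k] <- safe(tcss_similarity(a, b, index = idx_bp))
    MF[k] <- safe(tcss_similarity(a, b, index = idx_mf))
    EX[k] <- safe(combine_expression(profile_correlations(a, b, bundle$panel)))
    SS[k] <- safe(signature_score(bundle$signatures[[a]],
                                  bundle$signatures[[b]], sig_model))
  }
  pro_features <- data.frame(pair_id = pair_tab$pair_id,
                             CC = CC, BP = BP, MF = MF, EX = EX, SS = SS,
                             stringsAsFactors = FALSE)
  report$pairs <- np
  report$pairs_missing_feature <-
    sum(!stats::complete.cases(pro_features[, c("CC", "BP", "MF", "EX", "SS")]))

  # ---- classifiers ----
  if (is.null(pep_model)) {
    pep_model <- fit_naive_bayes(bundle$labeled_train, "pep",
                                 n_bins = par$n_bins %||% 10,
                                 smoothing = par$smoothing %||% 1.0,
                                 prior = par$prior %||% 0.5)
  }
  if (is.null(pro_model)) {
    pro_model <- fit_naive_bayes(bundle$labeled_train, "pro",
                                 n_bins = par$n_bins %||% 10,
                                 smoothing = par$smoothing %||% 1.0,
                                 prior = par$prior %||% 0.5)
  }
  pred <- predict_pairs(hits, pep_features, pro_features, pep_model,
                        pro_model, prior = par$prior %||% 0.5,
                        decision_threshold = par$decision_threshold %||% 0.9,
                        aggregate = par$aggregate %||% "max")
  report$candidates_excluded <- attr(pred, "excluded")
  report$predictions_above_threshold <- sum(pred$records$decision)
  report$ppi_above_threshold <- sum(pred$pairs$decision)

  list(records = pred$records, pairs = pred$pairs,
       models = list(pep = pep_model, pro = pro_model), report = report)
}

#' Write / read the prediction table
#'
#' Tab-separated, `#`-prefixed header metadata, floats at 6-decimal
#' precision, rows sorted by combined probability descending then candidate
#' id ascending, so identical runs produce byte-identical files.
#'
#' @param records per-hit prediction records from [run_predict_pipeline()].
#' @param path output path.
#' @export
write_prediction_table <- function(records, path) {
  cols <- c("candidate_id", "pair_id", "protein_id", "pwm_id", "domain_id",
            "start", "end", "window_seq",
            "DR", "SA", "PC", "SC", "CC", "BP", "MF", "EX", "SS",
            "p_pep", "p_pro", "combined", "decision")
  num6 <- function(v) ifelse(is.na(v), "NA", sprintf("%.6f", v))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# slimppi prediction table v1",
               paste0("# ", paste(cols, collapse = "\t"))), con)
  if (nrow(records) > 0) {
    ord <- order(-records$combined, records$candidate_id)
    r <- records[ord, , drop = FALSE]
    lines <- paste(
      r$candidate_id, r$pair_id, r$protein_id, r$pwm_id, r$domain_id,
      r$start, r$end, r$window_seq,
      num6(r$DR), num6(r$SA), num6(r$PC), num6(r$SC), num6(r$CC),
      num6(r$BP), num6(r$MF), num6(r$EX), num6(r$SS),
      num6(r$p_pep), num6(r$p_pro), num6(r$combined),
      as.integer(r$decision), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_prediction_table
#' @export
read_prediction_table <- function(path) {
  lines <- readLines(path)
  header <- lines[startsWith(lines, "# ")]
  cols <- strsplit(sub("^# ", "", header[length(header)]), "\t",
                   fixed = TRUE)[[1]]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                        cols))
    return(df)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(df) <- cols
  for (cn in c("start", "end")) df[[cn]] <- as.integer(df[[cn]])
  for (cn in c("DR", "SA", "PC", "SC", "CC", "BP", "MF", "EX", "SS",
               "p_pep", "p_pro", "combined")) {
    df[[cn]] <- suppressWarnings(as.numeric(df[[cn]]))
  }
  df$decision <- df$decision == "1"
  df
}
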
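#' Specification for the synthetic fixture generator
#'
#' Collects every knob of the synthetic data bundle: proteome size, motif
#' definitions and planting, per-class feature distributions, ontology
#' shape, expression panel shape and signature vocabulary. All generator
#' functions are deterministic given the spec (each consumes the spec's
#' seed plus a fixed per-generator offset), so a bundle is a pure function
#' of the spec.
#'
#' The defaults emulate a small SH3-like study: three 10-residue
#' proline-rich binding specificities with 25 phage-display-style peptides
#' each, planted into a few dozen target proteins; disorder/accessibility/
#' conservation tracks elevated around planted sites; a three-namespace
#' ontology with interacting pairs annotated to shared or sibling leaves;
#' an 8-profile expression panel in which interacting pairs share a latent
#' factor (target correlation 0.7); and signature assignments enriched on
#' interacting reference pairs. Labelled feature vectors for classifier
#' training use Beta class-conditionals for bounded features and Gaussians
#' for unbounded ones.
#'
#' @param seed integer master seed.
#' @param ... overrides for any default field (unknown names error).
#' @return an object of class `slimppi_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1, ...) {
  spec <- list(
    seed = as.integer(seed),
    # proteome / motifs
    n_targets = 30, length_range = c(150, 400),
    consensus = c(sh3a = "RALPPLPPLP", sh3b = "PPPALPPRKR",
                  sh3c = "KPLPPTPPSY"),
    peptides_per_motif = 25, peptide_noise = 0.1,
    planted_per_motif = 6, plant_noise = 0.05,
    # residue tracks (Beta shapes / Gaussian mean+sd, site vs background)
    disorder_site = c(8, 2), disorder_bg = c(2, 6),
    rsa_site = c(6, 2), rsa_bg = c(2, 5),
    cons_site = c(1.2, 0.5), cons_bg = c(0, 1),
    # contact base models
    n_contact_models = 2, domain_length = 55, contacts_per_model = 12,
    # ontology
    go_depth = 4, go_branching = 2, go_namespaces = c("C", "P", "F"),
    sibling_leaf_prob = 0.3, iea_rate = 0.1,
    # expression
    n_profiles = 8, n_conditions = 20, r_pos = 0.7, gene_absent_rate = 0.1,
    # signatures
    n_signatures = 30, sig_enriched_pairs = 5, sig_assign_prob = 0.8,
    sigs_per_protein = c(1, 3),
    # labelled feature vectors (class conditionals per feature)
    n_labeled = 2000, missingness = 0,
    feature_params = list(
      DR = list(type = "beta", pos = c(5, 2), neg = c(2, 5)),
      SA = list(type = "beta", pos = c(5, 2), neg = c(2, 5)),
      SC = list(type = "beta", pos = c(4, 2), neg = c(2, 4)),
      PC = list(type = "norm", pos = c(1, 1), neg = c(0, 1)),
      CC = list(type = "beta", pos = c(5, 2), neg = c(2, 5)),
      BP = list(type = "beta", pos = c(5, 2), neg = c(2, 5)),
      MF = list(type = "beta", pos = c(4, 2.5), neg = c(2.5, 4)),
      EX = list(type = "tanh-norm", pos = c(0.9, 0.4), neg = c(0, 0.4)),
      SS = list(type = "norm", pos = c(2, 1.5), neg = c(0, 1.5))
    )
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(spec))
  if (length(unknown) > 0) {
    slimppi_abort("slimppi_config_error",
                  sprintf("unknown fixture spec field(s): %s",
                          paste(unknown, collapse = ", ")))
  }
  spec[names(dots)] <- dots
  structure(spec, class = "slimppi_fixture_spec")
}

sample_motif_instance <- function(consensus, noise) {
  res <- split_residues(consensus)
  flip <- stats::runif(length(res)) < noise
  res[flip] <- sample(AA_ALPHABET, sum(flip), replace = TRUE)
  paste(res, collapse = "")
}

random_protein <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

#' Generate a proteome with planted motif instances
#'
#' Builds random background proteins, phage-display-style peptide lists for
#' each motif (consensus plus per-position noise), and plants motif
#' instances (drawn with `plant_noise`) at recorded coordinates in a subset
#' of target proteins; with `plant_noise = 0` every planted window equals
#' the consensus. One SH3-carrying protein per motif is added to the
#' proteome, holding the domain sequence used for contact transfer.
#'
#' @param spec a `slimppi_fixture_spec`.
#' @return list with `proteome` (named character), `truth` (data frame of
#'   planted sites: `domain_id`, `pwm_id`, `protein_id`, `start`, `end`,
#'   `instance`), `peptides` (named list per domain), and `domain_map`
#'   (data frame: `domain_id`, `protein_id`, `domain_seq`).
#' @export
generate_proteome_with_motifs <- function(spec) {
  set.seed(spec$seed + 101L)
  n_motif <- length(spec$consensus)
  motif_len <- unique(nchar(spec$consensus))
  if (length(motif_len) != 1) {
    slimppi_abort("slimppi_spec_error", "consensus motifs must share a length")
  }
  target_ids <- sprintf("TGT%03d", seq_len(spec$n_targets))
  lens <- sample(spec$length_range[1]:spec$length_range[2],
                 spec$n_targets, replace = TRUE)
  if (motif_len > min(lens)) {
    slimppi_abort("slimppi_spec_error", "motif longer than shortest protein")
  }
  proteome <- stats::setNames(vapply(lens, random_protein, character(1)),
                              target_ids)

  peptides <- lapply(spec$consensus, function(cons) {
    vapply(seq_len(spec$peptides_per_motif), function(k) {
      sample_motif_instance(cons, spec$peptide_noise)
    }, character(1))
  })
  names(peptides) <- names(spec$consensus)

  # plant instances; each target carries at most one motif (so interaction
  # clusters are disjoint carrier stars) and planted windows never overlap
  if (spec$planted_per_motif * n_motif > spec$n_targets) {
    slimppi_abort("slimppi_spec_error",
                  "not enough target proteins for disjoint motif planting")
  }
  occupied <- stats::setNames(vector("list", spec$n_targets), target_ids)
  unplanted <- target_ids
  truth <- list()
  for (d in names(spec$consensus)) {
    chosen <- sample(unplanted, spec$planted_per_motif)
    unplanted <- setdiff(unplanted, chosen)
    for (pid in chosen) {
      L <- nchar(proteome[[pid]])
      for (try in 1:50) {
        start <- sample.int(L - motif_len + 1L, 1)
        rng <- start:(start + motif_len - 1L)
        if (!any(rng %in% occupied[[pid]])) break
      }
      occupied[[pid]] <- c(occupied[[pid]], rng)
      inst <- sample_motif_instance(spec$consensus[[d]], spec$plant_noise)
      substr(proteome[[pid]], start, start + motif_len - 1L) <- inst
      truth[[length(truth) + 1L]] <- data.frame(
        domain_id = d, pwm_id = paste0(d, "_pwm"), protein_id = pid,
        start = start, end = start + motif_len - 1L, instance = inst,
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  truth <- truth[order(truth$domain_id, truth$protein_id, truth$start), ]
  rownames(truth) <- NULL

  domain_map <- data.frame(
    domain_id = names(spec$consensus),
    protein_id = paste0("SH3_", toupper(names(spec$consensus))),
    domain_seq = vapply(seq_len(n_motif), function(k) {
      random_protein(spec$domain_length)
    }, character(1)),
    stringsAsFactors = FALSE
  )
  carriers <- stats::setNames(vapply(seq_len(n_motif), function(k) {
    flank <- random_protein(80)
    paste0(flank, domain_map$domain_seq[k], random_protein(80))
  }, character(1)), domain_map$protein_id)
  list(proteome = c(proteome, carriers), truth = truth,
       peptides = peptides, domain_map = domain_map)
}

#' Generate per-residue feature tracks with elevated planted sites
#'
#' Background residues draw disorder and accessibility from the background
#' Beta distributions and conservation from the background Gaussian;
#' residues inside planted binding sites draw from the site distributions,
#' emulating the expectation that genuine binding peptides sit in
#' disordered, exposed, conserved regions.
#'
#' @param spec a `slimppi_fixture_spec`.
#' @param proteome named character vector of sequences.
#' @param truth planted-site truth table.
#' @return nested list `tracks[[protein_id]][[kind]]` of `slimppi_track`.
#' @export
generate_residue_tracks <- function(spec, proteome, truth) {
  set.seed(spec$seed + 102L)
  tracks <- list()
  for (pid in names(proteome)) {
    L <- nchar(proteome[[pid]])
    dis <- stats::rbeta(L, spec$disorder_bg[1], spec$disorder_bg[2])
    rsa <- stats::rbeta(L, spec$rsa_bg[1], spec$rsa_bg[2])
    con <- stats::rnorm(L, spec$cons_bg[1], spec$cons_bg[2])
    rows <- truth[truth$protein_id == pid, , drop = FALSE]
    for (k in seq_len(nrow(rows))) {
      idx <- rows$start[k]:rows$end[k]
      dis[idx] <- stats::rbeta(length(idx), spec$disorder_site[1],
                               spec$disorder_site[2])
      rsa[idx] <- stats::rbeta(length(idx), spec$rsa_site[1],
                               spec$rsa_site[2])
      con[idx] <- stats::rnorm(length(idx), spec$cons_site[1],
                               spec$cons_site[2])
    }
    tracks[[pid]] <- list(
      disorder = residue_track(pid, "disorder", dis),
      rsa = residue_track(pid, "rsa", rsa),
      conservation = residue_track(pid, "conservation", con)
    )
  }
  tracks
}

#' Generate domain-peptide contact base models
#'
#' Each base model pairs a mutated copy of one SH3 carrier's domain
#' sequence with a mutated copy of that domain's consensus peptide, plus
#' random residue-pair contacts with uniform raw areas, max-normalised by
#' [contact_model_from_map()].
#'
#' @param spec a `slimppi_fixture_spec`.
#' @param domain_map data frame from [generate_proteome_with_motifs()].
#' @return list of `slimppi_contact_model`.
#' @export
generate_contact_models <- function(spec, domain_map) {
  set.seed(spec$seed + 103L)
  lapply(seq_len(spec$n_contact_models), function(k) {
    src <- ((k - 1) %% nrow(domain_map)) + 1
    dom <- sample_motif_instance(domain_map$domain_seq[src], 0.1)
    pep <- sample_motif_instance(spec$consensus[[domain_map$domain_id[src]]],
                                 0.1)
    contacts <- data.frame(
      domain_index = sample.int(nchar(dom), spec$contacts_per_model,
                                replace = TRUE),
      peptide_index = sample.int(nchar(pep), spec$contacts_per_model,
                                 replace = TRUE),
      area = stats::runif(spec$contacts_per_model, 5, 60)
    )
    contacts <- contacts[!duplicated(contacts[, 1:2]), , drop = FALSE]
    contact_model_from_map(sprintf("MODEL%d", k), dom, pep, contacts)
  })
}

#' Generate labelled protein pairs from the planted truth
#'
#' Positives are the (SH3 carrier, target) pairs with a planted site for
#' that carrier's motif; an equal number of carrier-target pairs without a
#' planted site are drawn as negatives.
#'
#' @param spec a `slimppi_fixture_spec`.
#' @param truth,domain_map outputs of [generate_proteome_with_motifs()].
#' @return data frame with columns `a` (carrier), `b` (target), `domain_id`,
#'   `label`.
#' @export
generate_truth_pairs <- function(spec, truth, domain_map) {
  set.seed(spec$seed + 104L)
  carrier_of <- stats::setNames(domain_map$protein_id, domain_map$domain_id)
  pos <- unique(data.frame(a = unname(carrier_of[truth$domain_id]),
                           b = truth$protein_id,
                           domain_id = truth$domain_id,
                           stringsAsFactors = FALSE))
  pos$label <- 1L
  targets <- sprintf("TGT%03d", seq_len(spec$n_targets))
  neg <- list()
  guard <- 0L
  while (length(neg) < nrow(pos) && guard < 10000L) {
    guard <- guard + 1L
    d <- sample(domain_map$domain_id, 1)
    b <- sample(targets, 1)
    a <- unname(carrier_of[d])
    key <- paste(a, b)
    if (any(paste(pos$a, pos$b) == key)) next
    if (any(vapply(neg, function(x) paste(x$a, x$b) == key, logical(1)))) next
    neg[[length(neg) + 1L]] <- data.frame(a = a, b = b, domain_id = d,
                                          label = 0L, stringsAsFactors = FALSE)
  }
  out <- rbind(pos, do.call(rbind, neg))
  out <- out[order(-out$label, out$a, out$b), ]
  rownames(out) <- NULL
  out
}

#' Generate an ontology DAG with class-separating annotations
#'
#' Builds, per namespace, a random DAG of the requested depth and
#' branching (each term has one parent in the level above, with occasional
#' second parents to make a true DAG). Interacting pairs are annotated to
#' the same leaf (or a sibling leaf), non-interacting pairs to leaves in
#' different top-level subtrees; every protein receives at least one
#' annotation per namespace. A fraction of extra random annotations carry
#' the IEA evidence code to exercise evidence filtering.
#'
#' @param spec a `slimppi_fixture_spec`.
#' @param proteins character vector of all protein ids.
#' @param pairs labelled pair table from [generate_truth_pairs()].
#' @return list with `dag` (a `slimppi_go_dag`) and `annotations` (data
#'   frame).
#' @export
generate_go_dag_and_annotations <- function(spec, proteins, pairs) {
  set.seed(spec$seed + 105L)
  all_terms <- list()
  all_edges <- list()
  leaves <- list()
  top_of <- list()  # leaf -> index of its level-1 subtree
  for (ns in spec$go_namespaces) {
    counter <- 0L
    new_id <- function() {
      counter <<- counter + 1L
      sprintf("%s:%04d", ns, counter)
    }
    root <- new_id()
    all_terms[[length(all_terms) + 1L]] <- data.frame(
      id = root, name = paste(ns, "root"), namespace = ns,
      stringsAsFactors = FALSE)
    prev <- root
    prev_top <- NA_integer_
    level_terms <- list(root)
    level_top <- list(NA_integer_)
    for (depth in seq_len(spec$go_depth)) {
      n_here <- spec$go_branching^depth
      ids <- character(n_here)
      tops <- integer(n_here)
      parent_pool <- level_terms[[depth]]
      for (k in seq_len(n_here)) {
        ids[k] <- new_id()
        parent <- parent_pool[((k - 1) %% length(parent_pool)) + 1]
        all_terms[[length(all_terms) + 1L]] <- data.frame(
          id = ids[k], name = ids[k], namespace = ns, stringsAsFactors = FALSE)
        all_edges[[length(all_edges) + 1L]] <- data.frame(
          child = ids[k], parent = parent, stringsAsFactors = FALSE)
        if (depth >= 2 && stats::runif(1) < 0.2) {
          extra <- sample(parent_pool, 1)
          if (extra != parent) {
            all_edges[[length(all_edges) + 1L]] <- data.frame(
              child = ids[k], parent = extra, stringsAsFactors = FALSE)
          }
        }
        tops[k] <- if (depth == 1) k
                   else level_top[[depth]][match(parent, parent_pool)]
      }
      level_terms[[depth + 1L]] <- ids
      level_top[[depth + 1L]] <- tops
    }
    leaves[[ns]] <- level_terms[[spec$go_depth + 1L]]
    top_of[[ns]] <- stats::setNames(level_top[[spec$go_depth + 1L]],
                                    leaves[[ns]])
  }
  dag <- go_dag(do.call(rbind, all_terms), do.call(rbind, all_edges))

  ann <- list()
  add_ann <- function(pid, term, code = "IDA") {
    ns <- sub(":.*$", "", term)
    ann[[length(ann) + 1L]] <<- data.frame(
      protein_id = pid, term_id = term, evidence_code = code,
      namespace = ns, stringsAsFactors = FALSE)
  }
  sibling_of <- function(ns, leaf) {
    same_top <- leaves[[ns]][top_of[[ns]] == top_of[[ns]][leaf]]
    cand <- setdiff(same_top, leaf)
    if (length(cand) == 0) leaf else sample(cand, 1)
  }
  for (ns in spec$go_namespaces) {
    lv <- leaves[[ns]]
    tops <- top_of[[ns]]
    for (k in seq_len(nrow(pairs))) {
      if (pairs$label[k] == 1) {
        leaf <- sample(lv, 1)
        leaf_b <- if (stats::runif(1) < spec$sibling_leaf_prob)
          sibling_of(ns, leaf) else leaf
        add_ann(pairs$a[k], leaf)
        add_ann(pairs$b[k], leaf_b)
      } else {
        leaf_a <- sample(lv, 1)
        far <- lv[tops != tops[leaf_a]]
        leaf_b <- if (length(far) > 0) sample(far, 1) else sample(lv, 1)
        add_ann(pairs$a[k], leaf_a)
        add_ann(pairs$b[k], leaf_b)
      }
    }
    for (pid in proteins) {
      if (stats::runif(1) < spec$iea_rate) {
        add_ann(pid, sample(lv, 1), code = "IEA")
      }
    }
  }
  # guarantee coverage: any protein still unannotated gets one random leaf
  ann_df <- do.call(rbind, ann)
  for (ns in spec$go_namespaces) {
    have <- unique(ann_df$protein_id[ann_df$namespace == ns &
                                       ann_df$evidence_code != "IEA"])
    for (pid in setdiff(proteins, have)) {
      add_ann(pid, sample(leaves[[ns]], 1))
    }
  }
  ann_df <- unique(do.call(rbind, ann))
  rownames(ann_df) <- NULL
  list(dag = dag, annotations = ann_df)
}

#' Generate an expression panel with correlated interacting pairs
#'
#' Proteins connected by positive pairs share a latent per-profile factor;
#' their expression rows mix the factor with independent noise so that the
#' expected within-cluster Pearson correlation equals `r_pos`. All other
#' genes are independent noise, and each gene is absent from each profile
#' with a small probability to exercise missing-profile handling.
#'
#' @param spec a `slimppi_fixture_spec`.
#' @param proteins character vector of protein ids.
#' @param pairs labelled pair table.
#' @return a `slimppi_expression_panel`.
#' @export
generate_expression_panel <- function(spec, proteins, pairs) {
  set.seed(spec$seed + 106L)
  # union-find over positive pairs -> clusters sharing a factor
  parent <- stats::setNames(proteins, proteins)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (k in which(pairs$label == 1)) {
    ra <- find(pairs$a[k]); rb <- find(pairs$b[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  cluster <- vapply(proteins, find, character(1))
  profiles <- list()
  for (p in seq_len(spec$n_profiles)) {
    m <- spec$n_conditions
    factors <- lapply(unique(cluster), function(cl) stats::rnorm(m))
    names(factors) <- unique(cluster)
    rows <- t(vapply(proteins, function(pid) {
      cl <- cluster[[pid]]
      in_cluster <- sum(cluster == cl) > 1
      if (in_cluster) {
        sqrt(spec$r_pos) * factors[[cl]] +
          sqrt(1 - spec$r_pos) * stats::rnorm(m)
      } else {
        stats::rnorm(m)
      }
    }, numeric(m)))
    rownames(rows) <- proteins
    colnames(rows) <- sprintf("cond%02d", seq_len(m))
    present <- stats::runif(length(proteins)) >= spec$gene_absent_rate
    profiles[[sprintf("profile%02d", p)]] <- rows[present, , drop = FALSE]
  }
  expression_panel(profiles)
}

#' Generate signature assignments and a reference interaction list
#'
#' Every protein receives one to a few random signatures; interacting
#' pairs additionally receive the two sides of an "enriched" signature pair
#' with probability `sig_assign_prob`. The reference PPI list is the
#' positive pair set, so a fitted [fit_signature_model()] assigns enriched
#' co-occurrence to the planted signature pairs.
#'
#' @param spec a `slimppi_fixture_spec`.
#' @param proteins character vector of protein ids.
#' @param pairs labelled pair table.
#' @return list with `signatures` (named list) and `reference_ppis`
#'   (data frame `a`, `b`).
#' @export
generate_signature_data <- function(spec, proteins, pairs) {
  set.seed(spec$seed + 107L)
  vocab <- sprintf("SIG%03d", seq_len(spec$n_signatures))
  enriched <- lapply(seq_len(spec$sig_enriched_pairs), function(k) {
    vocab[c(2 * k - 1, 2 * k)]
  })
  sigs <- lapply(proteins, function(pid) {
    n <- sample(spec$sigs_per_protein[1]:spec$sigs_per_protein[2], 1)
    sample(vocab, n)
  })
  names(sigs) <- proteins
  pos_idx <- which(pairs$label == 1)
  for (i in seq_along(pos_idx)) {
    k <- pos_idx[i]
    ep <- enriched[[((i - 1) %% length(enriched)) + 1]]
    if (stats::runif(1) < spec$sig_assign_prob) {
      sigs[[pairs$a[k]]] <- unique(c(sigs[[pairs$a[k]]], ep[1]))
      sigs[[pairs$b[k]]] <- unique(c(sigs[[pairs$b[k]]], ep[2]))
    }
  }
  list(signatures = sigs,
       reference_ppis = data.frame(a = pairs$a[pos_idx], b = pairs$b[pos_idx],
                                   stringsAsFactors = FALSE))
}

sample_feature <- function(params, which, n) {
  p <- params[[which]]
  switch(params$type,
         beta = stats::rbeta(n, p[1], p[2]),
         norm = stats::rnorm(n, p[1], p[2]),
         `tanh-norm` = tanh(stats::rnorm(n, p[1], p[2])),
         slimppi_abort("slimppi_spec_error",
                       sprintf("unknown feature distribution '%s'", params$type)))
}

#' Generate labelled feature vectors for classifier training
#'
#' Draws balanced positive/negative feature vectors from the spec's
#' class-conditional distributions (Beta for bounded features, Gaussian or
#' tanh-Gaussian for unbounded ones) and applies a uniform missingness
#' mask. `missingness = 0` reproduces the fully observed ("filtered")
#' regime; positive rates around 0.3 emulate real deployment with partial
#' evidence ("unfiltered").
#'
#' @param spec a `slimppi_fixture_spec`.
#' @param n_per_class rows per class (default `spec$n_labeled`).
#' @param missingness probability that any feature cell is masked to `NA`
#'   (default `spec$missingness`).
#' @param subset `"train"` or `"test"`; the two draw from independent
#'   streams of the seed.
#' @return data frame with `pair_id`, `label`, and the nine feature
#'   columns.
#' @export
generate_labeled_pairs <- function(spec, n_per_class = spec$n_labeled,
                                   missingness = spec$missingness,
                                   subset = c("train", "test")) {
  subset <- match.arg(subset)
  set.seed(spec$seed + if (subset == "train") 108L else 109L)
  n <- 2 * n_per_class
  label <- rep(c(1L, 0L), each = n_per_class)
  out <- data.frame(pair_id = sprintf("%s%05d", toupper(substr(subset, 1, 2)),
                                      seq_len(n)),
                    label = label, stringsAsFactors = FALSE)
  for (f in names(spec$feature_params)) {
    v <- numeric(n)
    v[label == 1] <- sample_feature(spec$feature_params[[f]], "pos",
                                    n_per_class)
    v[label == 0] <- sample_feature(spec$feature_params[[f]], "neg",
                                    n_per_class)
    if (missingness > 0) {
      v[stats::runif(n) < missingness] <- NA_real_
    }
    out[[f]] <- v
  }
  out
}

#' Write a complete synthetic input bundle to disk
#'
#' Materialises every pipeline input in the package's plain-text formats
#' (FASTA, tab-separated tracks and tables, OBO ontology, expression
#' matrices plus manifest, YAML run configuration) together with the
#' planted-site and pair truth tables, and returns the path of the bundle
#' configuration consumed by [load_dataset_bundle()].
#'
#' @param spec a `slimppi_fixture_spec`.
#' @param dir output directory (created).
#' @return path of the written `config.yaml`, invisibly the bundle dir as
#'   attribute.
#' @export
make_fixture_bundle <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gp <- generate_proteome_with_motifs(spec)
  tracks <- generate_residue_tracks(spec, gp$proteome, gp$truth)
  models <- generate_contact_models(spec, gp$domain_map)
  pairs <- generate_truth_pairs(spec, gp$truth, gp$domain_map)
  proteins <- names(gp$proteome)
  goa <- generate_go_dag_and_annotations(spec, proteins, pairs)
  panel <- generate_expression_panel(spec, proteins, pairs)
  sig <- generate_signature_data(spec, proteins, pairs)
  train <- generate_labeled_pairs(spec, subset = "train")
  test <- generate_labeled_pairs(spec, subset = "test")

  Biostrings::writeXStringSet(Biostrings::AAStringSet(gp$proteome),
                              file.path(dir, "proteome.fasta"))
  dir.create(file.path(dir, "peptides"), showWarnings = FALSE)
  for (d in names(gp$peptides)) {
    writeLines(gp$peptides[[d]], file.path(dir, "peptides", paste0(d, ".txt")))
  }
  write_tracks(tracks, file.path(dir, "tracks.tsv"))
  write_contact_models(models, file.path(dir, "contact_models.tsv"),
                       file.path(dir, "contact_chains.fasta"))
  write_obo(goa$dag, file.path(dir, "ontology.obo"))
  write_annotations(goa$annotations, file.path(dir, "annotations.tsv"))
  write_expression_panel(panel, file.path(dir, "expression"))
  write_signatures(sig$signatures, file.path(dir, "signatures.tsv"))
  write_ppi_list(sig$reference_ppis, file.path(dir, "reference_ppis.tsv"))
  utils::write.table(train, file.path(dir, "labeled_train.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(test, file.path(dir, "labeled_test.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(gp$truth, file.path(dir, "truth_sites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(pairs, file.path(dir, "truth_pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(gp$domain_map, file.path(dir, "domain_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  config <- list(
    paths = list(
      proteome = "proteome.fasta",
      peptides_dir = "peptides",
      tracks = "tracks.tsv",
      contact_map = "contact_models.tsv",
      contact_chains = "contact_chains.fasta",
      ontology = "ontology.obo",
      annotations = "annotations.tsv",
      expression_manifest = "expression/manifest.tsv",
      signatures = "signatures.tsv",
      reference_ppis = "reference_ppis.tsv",
      labeled_train = "labeled_train.tsv",
      labeled_test = "labeled_test.tsv",
      domain_map = "domain_map.tsv",
      truth_sites = "truth_sites.tsv",
      truth_pairs = "truth_pairs.tsv"
    ),
    params = list(
      pvalue_threshold = 1e-5, granularity = 1e-3, ic_cutoff = 1.0,
      rsa_cutoff = 0.25, binarize_at = 0.5,
      tcss_cutoff_cc = 2.4, tcss_cutoff_bp = 3.5, tcss_cutoff_mf = 3.3,
      decision_threshold = 0.9, prior = 0.5, n_bins = 10, smoothing = 1.0,
      background = "from-proteome", pseudocount = 0.05,
      evidence_exclude = "IEA", signature_pseudocount = 0.5,
      aggregate = "max", seed = spec$seed
    )
  )
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  cfg_path
}
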
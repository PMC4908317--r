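#' Panel of expression profiles
#'
#' A panel wraps several independent expression profiles (gene x condition
#' matrices, e.g. different microarray or RNA-seq compendia); pair
#' correlations are computed per profile and combined across the panel in
#' Fisher z-space.
#'
#' @param profiles named list of numeric matrices with gene ids as row
#'   names; each profile needs at least 3 conditions.
#' @return an object of class `slimppi_expression_panel`.
#' @export
expression_panel <- function(profiles) {
  if (is.null(names(profiles)) || any(!nzchar(names(profiles)))) {
    slimppi_abort("slimppi_config_error", "profiles must be named")
  }
  for (nm in names(profiles)) {
    p <- profiles[[nm]]
    if (!is.matrix(p) || ncol(p) < 3) {
      slimppi_abort("slimppi_config_error",
                    sprintf("profile '%s' must be a matrix with >= 3 conditions", nm))
    }
    if (is.null(rownames(p))) {
      slimppi_abort("slimppi_config_error",
                    sprintf("profile '%s' has no gene row names", nm))
    }
  }
  structure(list(profiles = profiles), class = "slimppi_expression_panel")
}

#' Per-profile Pearson correlations of a gene pair
#'
#' One Pearson correlation per profile in which both genes are measured
#' with at least 3 shared non-missing conditions and non-zero variance.
#' Profiles failing these requirements are skipped and tallied in the
#' `skipped` attribute; if no profile qualifies, a classed error
#' (`slimppi_no_expression_evidence`) is raised so callers can degrade the
#' feature to missing rather than fabricate a zero correlation.
#'
#' @param gene_a,gene_b gene identifiers.
#' @param panel a `slimppi_expression_panel`.
#' @return named numeric vector of correlations in `[-1, 1]`.
#' @export
profile_correlations <- function(gene_a, gene_b, panel) {
  rs <- numeric(0)
  skipped <- c(absent = 0L, too_few = 0L, zero_var = 0L)
  for (nm in names(panel$profiles)) {
    p <- panel$profiles[[nm]]
    if (!(gene_a %in% rownames(p)) || !(gene_b %in% rownames(p))) {
      skipped["absent"] <- skipped["absent"] + 1L
      next
    }
    x <- p[gene_a, ]
    y <- p[gene_b, ]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) {
      skipped["too_few"] <- skipped["too_few"] + 1L
      next
    }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      skipped["zero_var"] <- skipped["zero_var"] + 1L
      next
    }
    rs[nm] <- stats::cor(x[ok], y[ok])
  }
  if (length(rs) == 0) {
    slimppi_abort("slimppi_no_expression_evidence",
                  sprintf("no qualifying profile for pair (%s, %s)",
                          gene_a, gene_b))
  }
  attr(rs, "skipped") <- skipped
  rs
}

#' Combine per-profile correlations via Fisher's z transformation
#'
#' Each correlation is mapped to z-space with
#' \eqn{z_i = \mathrm{atanh}(r_i) = \tfrac12\ln\frac{1+r_i}{1-r_i}},
#' the mean \eqn{\bar z} is taken over profiles, and the combined
#' correlation is the back-transform \eqn{EX = \tanh(\bar z)}. Correlations
#' at exactly plus/minus 1 are clipped to plus/minus 0.999999 with a warning, since
#' the transform diverges there.
#'
#' @param correlations numeric vector of per-profile Pearson correlations.
#' @return combined correlation in `(-1, 1)`.
#' @export
combine_expression <- function(correlations) {
  if (length(correlations) == 0) {
    slimppi_abort("slimppi_no_expression_evidence",
                  "no correlations to combine")
  }
  if (any(abs(correlations) >= 1)) {
    slimppi_warn("slimppi_correlation_clipped",
                 "correlation(s) at |r| >= 1 clipped to 0.999999")
    correlations <- pmin(pmax(correlations, -0.999999), 0.999999)
  }
  tanh(mean(atanh(correlations)))
}

#' Read / write an expression panel
#'
#' The manifest is tab-separated (`profile_id`, `path`) with paths relative
#' to the manifest's directory; each profile file is a tab-separated
#' gene x condition matrix with a header row and gene ids in the first
#' column.
#'
#' @param manifest_path manifest file path.
#' @return a `slimppi_expression_panel`.
#' @export
read_expression_panel <- function(manifest_path) {
  base <- dirname(manifest_path)
  man <- utils::read.delim(manifest_path, comment.char = "#", header = FALSE,
                           col.names = c("profile_id", "path"),
                           stringsAsFactors = FALSE)
  profiles <- lapply(seq_len(nrow(man)), function(k) {
    f <- file.path(base, man$path[k])
    if (!file.exists(f)) {
      slimppi_abort("slimppi_file_not_found",
                    sprintf("profile file not found: %s", f))
    }
    df <- utils::read.delim(f, comment.char = "#", stringsAsFactors = FALSE,
                            row.names = 1, check.names = FALSE)
    as.matrix(df)
  })
  names(profiles) <- man$profile_id
  expression_panel(profiles)
}

#' @rdname read_expression_panel
#' @param panel a `slimppi_expression_panel`.
#' @param dir output directory (created if needed); the manifest is written
#'   as `manifest.tsv` inside it.
#' @export
write_expression_panel <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- data.frame(profile_id = names(panel$profiles),
                    path = paste0(names(panel$profiles), ".tsv"))
  for (nm in names(panel$profiles)) {
    p <- panel$profiles[[nm]]
    df <- data.frame(gene = rownames(p),
                     apply(p, 2, function(col) sprintf("%.6f", col)),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file.path(dir, "manifest.tsv"))
}
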
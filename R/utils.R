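#' @keywords internal
"_PACKAGE"

# Classed condition helper: every package error carries a specific condition
# class (e.g. "slimppi_length_mismatch") plus "slimppi_error", so callers can
# branch on failure modes (missing evidence vs malformed input) without
# matching message strings.
slimppi_abort <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "slimppi_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

slimppi_warn <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "slimppi_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  warning(cond)
}

# The 20 standard amino acids, in the fixed order used by every weight matrix.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

split_residues <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Residue background frequencies of a proteome
#'
#' Counts residue usage over a set of protein sequences and returns a
#' probability vector over the given alphabet. Residues outside the alphabet
#' (ambiguity codes such as X or U) are ignored. A pseudo-observation of one
#' count per letter keeps every background frequency strictly positive, as
#' required for log-odds weights.
#'
#' @param sequences character vector (or `Biostrings::AAStringSet`) of
#'   protein sequences.
#' @param alphabet ordered residue alphabet; defaults to the 20 standard
#'   amino acids.
#' @return named numeric vector of probabilities summing to 1.
#' @export
proteome_background <- function(sequences, alphabet = AA_ALPHABET) {
  if (methods::is(sequences, "XStringSet")) {
    sequences <- as.character(sequences)
  }
  chars <- unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE)
  counts <- table(factor(chars, levels = alphabet))
  counts <- as.numeric(counts) + 1
  p <- counts / sum(counts)
  names(p) <- alphabet
  p
}

resolve_background <- function(background, alphabet, proteome = NULL) {
  m <- length(alphabet)
  if (is.character(background) && length(background) == 1) {
    if (background == "uniform") {
      p <- rep(1 / m, m)
      names(p) <- alphabet
      return(p)
    }
    if (background == "from-proteome") {
      if (is.null(proteome)) {
        slimppi_abort("slimppi_config_error",
                      "background = \"from-proteome\" requires `proteome`")
      }
      return(proteome_background(proteome, alphabet))
    }
    slimppi_abort("slimppi_config_error",
                  sprintf("unknown background specifier '%s'", background))
  }
  if (!is.numeric(background) || length(background) != m) {
    slimppi_abort("slimppi_config_error",
                  sprintf("background must be 'uniform', 'from-proteome', or %d probabilities", m))
  }
  if (any(background <= 0) || abs(sum(background) - 1) > 1e-6) {
    slimppi_abort("slimppi_config_error",
                  "background probabilities must be > 0 and sum to 1")
  }
  p <- as.numeric(background) / sum(background)
  names(p) <- alphabet
  p
}
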
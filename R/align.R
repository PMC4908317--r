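#' BLOSUM62 substitution matrix
#'
#' The standard BLOSUM62 matrix as shipped with Biostrings, restricted on
#' demand by the aligner to the residues it encounters.
#'
#' @return integer matrix with residue dimnames.
#' @export
blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the standard whitespace-separated matrix layout (`#` comment
#' lines, a header row of residues, one labelled row per residue).
#'
#' @param path file path.
#' @return numeric matrix with residue dimnames.
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  mat <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(header))))
  rownames(mat) <- vapply(rows, `[[`, character(1), 1)
  colnames(mat) <- header
  mat
}

#' Identity substitution matrix over a residue set
#'
#' @param letters residues to cover.
#' @param match,mismatch scores for identical / differing residues.
#' @return numeric matrix.
#' @export
identity_matrix <- function(letters, match = 1, mismatch = 0) {
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- match
  m
}

#' Global pairwise alignment (Needleman-Wunsch with affine gaps)
#'
#' Optimal global alignment of two protein sequences under an affine gap
#' scheme: the first residue of a gap costs `gap_open`, each further residue
#' `gap_extend` (so a length-L gap costs `gap_open + (L-1) * gap_extend`).
#' Implemented as the three-state Gotoh dynamic programme with a fixed,
#' deterministic tie-break: diagonal (match state) over up (gap in `seq_b`)
#' over left (gap in `seq_a`), applied both when filling cells and during
#' traceback, so identical inputs always yield the identical alignment.
#'
#' @param seq_a,seq_b non-empty sequences (character scalars).
#' @param submat substitution matrix (default BLOSUM62).
#' @param gap_open score of the first gap residue (default -10).
#' @param gap_extend score of each additional gap residue (default -1).
#' @return an object of class `slimppi_alignment`: `aligned_a`, `aligned_b`
#'   (equal-length gapped strings), `score`, and `mapping`, a two-column
#'   integer matrix of aligned (non-gap, non-gap) residue index pairs,
#'   strictly increasing in both columns.
#' @export
align_global <- function(seq_a, seq_b, submat = NULL,
                         gap_open = -10, gap_extend = -1) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) {
    slimppi_abort("slimppi_empty_input", "sequences must be non-empty")
  }
  if (is.null(submat)) submat <- blosum62()
  a <- split_residues(seq_a)
  b <- split_residues(seq_b)
  missing <- setdiff(unique(c(a, b)), rownames(submat))
  if (length(missing) > 0) {
    slimppi_abort("slimppi_alphabet_error",
                  sprintf("residues absent from the substitution matrix: %s",
                          paste(missing, collapse = ", ")))
  }
  la <- length(a)
  lb <- length(b)
  NEG <- -Inf
  # state 1 = M (diagonal), 2 = X (up: gap in b, consumes a), 3 = Y (left)
  M <- matrix(NEG, la + 1, lb + 1)
  X <- matrix(NEG, la + 1, lb + 1)
  Y <- matrix(NEG, la + 1, lb + 1)
  ptr <- array(0L, dim = c(la + 1, lb + 1, 3))  # predecessor state per state
  M[1, 1] <- 0
  if (la > 0) {
    X[2:(la + 1), 1] <- gap_open + (seq_len(la) - 1) * gap_extend
    ptr[2, 1, 2] <- 1L
    if (la > 1) ptr[3:(la + 1), 1, 2] <- 2L
  }
  if (lb > 0) {
    Y[1, 2:(lb + 1)] <- gap_open + (seq_len(lb) - 1) * gap_extend
    ptr[1, 2, 3] <- 1L
    if (lb > 1) ptr[1, 3:(lb + 1), 3] <- 3L
  }
  s <- submat[a, b, drop = FALSE]
  best3 <- function(m, x, y) {
    # returns c(value, state) with tie preference M > X > Y
    if (m >= x && m >= y) c(m, 1L)
    else if (x >= y) c(x, 2L)
    else c(y, 3L)
  }
  for (i in 2:(la + 1)) {
    for (j in 2:(lb + 1)) {
      bm <- best3(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      M[i, j] <- s[i - 1, j - 1] + bm[1]
      ptr[i, j, 1] <- as.integer(bm[2])
      bx <- best3(M[i - 1, j] + gap_open, X[i - 1, j] + gap_extend,
                  Y[i - 1, j] + gap_open)
      X[i, j] <- bx[1]
      ptr[i, j, 2] <- as.integer(bx[2])
      by <- best3(M[i, j - 1] + gap_open, X[i, j - 1] + gap_open,
                  Y[i, j - 1] + gap_extend)
      Y[i, j] <- by[1]
      ptr[i, j, 3] <- as.integer(by[2])
    }
  }
  fin <- best3(M[la + 1, lb + 1], X[la + 1, lb + 1], Y[la + 1, lb + 1])
  score <- fin[1]
  state <- as.integer(fin[2])
  # traceback
  i <- la + 1; j <- lb + 1
  ga <- character(0); gb <- character(0)
  map_a <- integer(0); map_b <- integer(0)
  while (i > 1 || j > 1) {
    prev <- ptr[i, j, state]
    if (state == 1L) {
      ga <- c(a[i - 1], ga); gb <- c(b[j - 1], gb)
      map_a <- c(i - 1L, map_a); map_b <- c(j - 1L, map_b)
      i <- i - 1; j <- j - 1
    } else if (state == 2L) {
      ga <- c(a[i - 1], ga); gb <- c("-", gb)
      i <- i - 1
    } else {
      ga <- c("-", ga); gb <- c(b[j - 1], gb)
      j <- j - 1
    }
    state <- prev
  }
  structure(list(
    aligned_a = paste(ga, collapse = ""),
    aligned_b = paste(gb, collapse = ""),
    score = score,
    mapping = cbind(a = map_a, b = map_b)
  ), class = "slimppi_alignment")
}

#' @export
print.slimppi_alignment <- function(x, ...) {
  cat(sprintf("global alignment, score %.1f\n%s\n%s\n",
              x$score, x$aligned_a, x$aligned_b))
  invisible(x)
}
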
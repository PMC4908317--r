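mk_hit <- function(start, end, sig) {
  list(protein_id = "p", start = start, end = end,
       significant_positions = paste(sig, collapse = ","))
}

test_that("disorder, accessibility and conservation are means over significant residues", {
  hit <- mk_hit(5, 8, c(5, 6, 7, 8))
  track <- rep(0, 20)

  t1 <- track; t1[5:8] <- 1
  expect_equal(disorder_score(hit, residue_track("p", "disorder", t1)), 1.0)
  expect_equal(disorder_score(hit, residue_track("p", "disorder", track)), 0.0)
  t2 <- track; t2[5:7] <- 1
  expect_equal(disorder_score(hit, residue_track("p", "disorder", t2)), 0.75)

  r1 <- track; r1[5:8] <- 0.30
  expect_equal(accessibility_score(hit, residue_track("p", "rsa", r1)), 1.0)
  r2 <- track; r2[5:8] <- 0.10
  expect_equal(accessibility_score(hit, residue_track("p", "rsa", r2)), 0.0)
  # the 25% boundary is inclusive
  hit2 <- mk_hit(5, 6, c(5, 6))
  r3 <- track; r3[5] <- 0.25; r3[6] <- 0.24
  expect_equal(accessibility_score(hit2, residue_track("p", "rsa", r3)), 0.5)

  c1 <- track + 0.7
  expect_equal(conservation_score(hit, residue_track("p", "conservation", c1)),
               0.7)
  c2 <- track; c2[5] <- 1
  expect_equal(conservation_score(mk_hit(5, 6, c(5, 6)),
                                  residue_track("p", "conservation", c2)), 0.5)
  set.seed(41)
  c3 <- rnorm(20)
  expect_equal(conservation_score(hit, residue_track("p", "conservation", c3)),
               mean(c3[5:8]), tolerance = 1e-12)
})

test_that("feature scores depend only on the significant positions", {
  set.seed(42)
  hit <- mk_hit(3, 10, c(4, 7, 9))
  v <- runif(15)
  v2 <- v
  outside <- setdiff(seq_len(15), c(4, 7, 9))
  v2[outside] <- runif(length(outside))
  for (kind in c("disorder", "rsa")) {
    expect_equal(disorder_score(hit, residue_track("p", kind, v)),
                 disorder_score(hit, residue_track("p", kind, v2)))
  }
  expect_equal(conservation_score(hit, residue_track("p", "conservation", v)),
               conservation_score(hit, residue_track("p", "conservation", v2)))
})

test_that("degenerate hits and short tracks raise classed errors", {
  track <- residue_track("p", "disorder", rep(0.5, 10))
  expect_error(disorder_score(mk_hit(2, 5, integer(0)), track),
               class = "slimppi_empty_significant_set")
  expect_error(disorder_score(mk_hit(8, 12, c(8, 9)), track),
               class = "slimppi_track_mismatch")
})

test_that("sum-of-pairs conservation matches hand-counted pair agreement", {
  # identical rows, identity matrix: pre-normalisation score 1 everywhere
  aln <- c(ref = "ACDEF", o1 = "ACDEF", o2 = "ACDEF")
  tr <- conservation_from_msa(aln, "ref", normalize = FALSE)
  expect_equal(tr$values, rep(1, 5))

  # 4 rows, half agreeing at a column: agreeing pairs / total pairs
  aln2 <- c(ref = "A", o1 = "A", o2 = "C", o3 = "C")
  tr2 <- conservation_from_msa(aln2, "ref", normalize = FALSE)
  # pairs: (A,A) (A,C) (A,C) (A,C) (A,C) (C,C) -> 2 agreeing of 6
  expect_equal(tr2$values, 2 / 6)

  # 2-row alignment: each column's score is the single pair's entry
  sm <- blosum62()
  aln3 <- c(ref = "ACD", o1 = "AYD")
  tr3 <- conservation_from_msa(aln3, "ref", submat = sm, normalize = FALSE)
  expect_equal(tr3$values,
               c(sm["A", "A"], sm["C", "Y"], sm["D", "D"]))

  # reference gaps are dropped; gap pairs score 0 but count
  aln4 <- c(ref = "A-C", o1 = "AAC")
  tr4 <- conservation_from_msa(aln4, "ref", normalize = FALSE)
  expect_equal(length(tr4$values), 2)

  expect_error(conservation_from_msa(aln, "nope"),
               class = "slimppi_missing_reference")

  # z-normalisation yields mean 0, sd 1 over a non-constant profile
  aln5 <- c(ref = "AAAA", o1 = "AACD")
  tr5 <- conservation_from_msa(aln5, "ref")
  expect_equal(mean(tr5$values), 0, tolerance = 1e-12)
  expect_equal(sd(tr5$values), 1, tolerance = 1e-12)
})

test_that("contact maps normalise by the maximum pair area", {
  cm <- contact_model_from_map("m1", "ACDEFGHIKL", "PPPP",
                               data.frame(domain_index = c(3, 8),
                                          peptide_index = c(1, 2),
                                          area = c(50, 25)))
  expect_equal(cm$contacts$c, c(1.0, 0.5))
  single <- contact_model_from_map("m2", "ACD", "PP",
                                   data.frame(domain_index = 2,
                                              peptide_index = 1, area = 7))
  expect_equal(single$contacts$c, 1.0)
  perm <- contact_model_from_map("m1", "ACDEFGHIKL", "PPPP",
                                 data.frame(domain_index = c(8, 3),
                                            peptide_index = c(2, 1),
                                            area = c(25, 50)))
  expect_equal(perm$contacts, cm$contacts)
  expect_error(contact_model_from_map("m3", "ACD", "PP",
                                      data.frame(domain_index = 1,
                                                 peptide_index = 1, area = 0)),
               class = "slimppi_degenerate_model")
})

toy_contact_model <- function() {
  # two contacts with normalised areas 0.8 and 0.4 (direct construction so
  # the strengths need not include a 1.0 maximum)
  structure(list(
    model_id = "toy", domain_seq = "ACDEFGHIKL", peptide_seq = "WYNQ",
    contacts = data.frame(domain_index = c(3, 8), peptide_index = c(1, 3),
                          c = c(0.8, 0.4))), class = "slimppi_contact_model")
}

test_that("structural contact transfers averages over all model contacts", {
  m <- toy_contact_model()
  # identity query: both contacts aligned -> mean of (0.8, 0.4)
  res <- structural_contact_score("ACDEFGHIKL", "WYNQ", list(m))
  expect_equal(res$sc, 0.6)
  expect_identical(res$model_id, "toy")

  # deleting the domain residue of the 0.4 contact (position 8, "I")
  # leaves that contact unaligned: SC = 0.8 / 2
  res_gap <- structural_contact_score("ACDEFGHKL", "WYNQ", list(m))
  expect_equal(res_gap$sc, 0.4)

  # repairing the gap can only increase the score
  expect_gte(res$sc, res_gap$sc)

  # the best model wins: add an identical-sequence model with full contacts
  m2 <- structure(list(
    model_id = "toy2", domain_seq = "ACDEFGHIKL", peptide_seq = "WYNQ",
    contacts = data.frame(domain_index = 5, peptide_index = 2, c = 1.0)),
    class = "slimppi_contact_model")
  res2 <- structural_contact_score("ACDEFGHIKL", "WYNQ", list(m, m2))
  expect_equal(res2$sc, 1.0)
  expect_identical(res2$model_id, "toy2")
})

test_that("unalignable contacts give a zero score with a classed warning", {
  m <- toy_contact_model()
  # a single-residue query can align to at most one model position (the
  # matching "A" at position 1), so neither contact pair is covered
  expect_warning(
    res <- structural_contact_score("A", "W", list(m),
                                    gap_open = -1, gap_extend = -1),
    class = "slimppi_no_contact_alignment")
  expect_equal(res$sc, 0)
})

test_that("tracks and contact models round-trip through their file formats", {
  tracks <- list(
    p1 = list(disorder = residue_track("p1", "disorder", c(0.1, 0.9, 0.5)),
              rsa = residue_track("p1", "rsa", c(0.3, 0.2, 0.8))),
    p2 = list(conservation = residue_track("p2", "conservation", c(-1, 0, 2)))
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tracks(tracks, path)
  back <- read_tracks(path)
  expect_equal(back$p1$disorder$values, c(0.1, 0.9, 0.5), tolerance = 1e-6)
  expect_equal(back$p2$conservation$values, c(-1, 0, 2), tolerance = 1e-6)

  models <- list(contact_model_from_map(
    "M1", "ACDEFGHIKL", "PPPP",
    data.frame(domain_index = c(3, 8), peptide_index = c(1, 2),
               area = c(50, 25))))
  mp <- withr::local_tempfile(fileext = ".tsv")
  fp <- withr::local_tempfile(fileext = ".fasta")
  write_contact_models(models, mp, fp)
  back_m <- read_contact_models(mp, fp)
  expect_equal(back_m[[1]]$contacts$c, c(1.0, 0.5), tolerance = 1e-6)
  expect_identical(back_m[[1]]$domain_seq, "ACDEFGHIKL")
})

test_that("malformed track files report the offending structure", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("p1\t1\t0.5", "p1\t3\t0.7"), path)
  expect_error(read_tracks(path, kind = "disorder"),
               class = "slimppi_parse_error")
})
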
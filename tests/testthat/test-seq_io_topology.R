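test_that("FASTA reading parses entries, uppercases and preserves order", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x some description", "LIVF", ">y", "acd", "efg"), f)
  recs <- read_fasta(f)
  expect_length(recs, 2)
  expect_equal(recs[[1]]$id, "x")
  expect_equal(recs[[1]]$description, "some description")
  expect_equal(recs[[1]]$sequence, "LIVF")
  expect_equal(recs[[2]]$sequence, "ACDEFG")
})

test_that("FASTA reader rejects empty files and non-canonical residues", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty")
  writeLines(c(">bad", "LIXF"), f)
  expect_error(read_fasta(f), "position 3")
  writeLines(c(">bad2", "BLIV"), f)
  expect_error(read_fasta(f), "position 1")
})

test_that("write_fasta round-trips records and wraps at the stated width", {
  recs <- list(protein_record("x", "LIVF", description = "toy"),
               protein_record("y", random_sequence(130)))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, f, width = 60)
  lines <- readLines(f)
  expect_equal(sum(grepl("^>", lines)), 2)
  # 130 residues at width 60 -> 3 sequence lines
  y_start <- which(lines == ">y")
  expect_length(lines[(y_start + 1):length(lines)], 3)
  back <- read_fasta(f)
  expect_equal(vapply(back, `[[`, "", "sequence"),
               vapply(recs, `[[`, "", "sequence"))
  expect_equal(vapply(back, `[[`, "", "id"), c("x", "y"))
  expect_equal(back[[1]]$description, "toy")
  expect_error(write_fasta(list(), withr::local_tempfile()), "no records")
})

test_that("UniProt-style pipe headers yield the accession", {
  expect_equal(protein_record("sp|P11166|GTR1_HUMAN", "MEPSSK")$accession,
               "P11166")
})

test_that("TM tables parse, validate and round-trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\t1\t4\tTM1", "g1\t7\t9\tTM2", "g2\t2\t5"), f)
  topos <- parse_tm_table(f)
  expect_named(topos, c("g1", "g2"))
  expect_equal(nrow(topos$g1$segments), 2)
  expect_equal(topos$g1$segments$start, c(1, 7))
  expect_equal(topos$g1$source, "annotation")

  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_tm_table(topos, f2)
  expect_equal(parse_tm_table(f2)$g1$segments, topos$g1$segments)

  writeLines(c("g1\t1\t5", "g1\t4\t9"), f)
  expect_error(parse_tm_table(f), "overlap")
  writeLines("g1\t9\t4", f)
  expect_error(parse_tm_table(f), "end.*start")
})

test_that("UniProt flat-text TRANSMEM features are read", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "ID   GTR1_HUMAN              Reviewed;         492 AA.",
    "FT   TRANSMEM        13..33",
    "FT                   /note=\"Helical; Name=1\"",
    "FT   TRANSMEM        67..87",
    "FT   DOMAIN          1..50"), f)
  topo <- read_uniprot_transmem(f)
  expect_equal(topo$segments$start, c(13, 67))
  expect_equal(topo$segments$end, c(33, 87))
  expect_equal(topo$source, "annotation")
})

test_that("hydropathy prediction finds an interior hydrophobic block", {
  seq <- paste0(strrep("K", 20), strrep("L", 21), strrep("K", 20))
  topo <- predict_tm_segments(seq)
  expect_equal(nrow(topo$segments), 1)
  expect_equal(topo$source, "predicted")
  # boundaries within half a window of the true leucine block (21..41)
  half <- 9
  expect_lte(abs(topo$segments$start - 21), half)
  expect_lte(abs(topo$segments$end - 41), half)
  # the oracle agrees on which centres clear the threshold
  means <- oracle_window_means(seq, 19)
  centres <- which(means > 1.6) + 9
  expect_true(all(centres >= topo$segments$start &
                  centres <= topo$segments$end))
})

test_that("hydropathy prediction returns no segments for polar sequences", {
  topo <- predict_tm_segments(strrep("K", 60))
  expect_equal(nrow(topo$segments), 0)
  expect_equal(tm_residue_count(topo), 0)
})

test_that("prediction errors on sequences shorter than the window", {
  expect_error(predict_tm_segments("LIVF"), "shorter than window")
})

test_that("predicted segments are sorted, non-overlapping, and flank-invariant", {
  set.seed(101)
  for (rep in 1:25) {
    # random block sequence with polar first/last 19 residues
    core <- paste(vapply(1:6, function(i) {
      if (i %% 2 == 0) random_sequence(sample(12:30, 1), c("L", "I", "V", "F", "A"))
      else random_sequence(sample(12:30, 1), POLAR_AA)
    }, ""), collapse = "")
    seq <- paste0(random_sequence(19, POLAR_AA), core,
                  random_sequence(19, POLAR_AA))
    topo <- predict_tm_segments(seq)
    s <- topo$segments
    if (nrow(s) > 1) {
      expect_true(all(diff(s$start) > 0))
      expect_true(all(s$start[-1] > s$end[-nrow(s)]))
    }
    # appending polar flanks shifts coordinates but changes nothing else
    flank <- strrep("K", 19)
    topo2 <- predict_tm_segments(paste0(flank, seq, flank))
    expect_equal(topo2$segments$start, s$start + 19)
    expect_equal(topo2$segments$end, s$end + 19)
  }
})

test_that("non-GLUT-like helix counts only warn", {
  topo <- tm_topology(data.frame(start = 1, end = 20))
  expect_warning(check_helix_count(topo), "expected 12")
  twelve <- tm_topology(data.frame(start = seq(1, by = 30, length.out = 12),
                                   end = seq(21, by = 30, length.out = 12)))
  expect_no_warning(check_helix_count(twelve))
})
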
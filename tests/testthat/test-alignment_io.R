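test_that("read_alignment round-trips FASTA and normalises dialects", {
  path <- write_fasta_fixture(c("ACDE", "AC-E", "AXDE"))
  x <- read_alignment(path, "fasta")
  expect_s3_class(x, "msa")
  expect_equal(dim(x), c(3L, 4L))
  expect_equal(x$ids, c("s1", "s2", "s3"))
  # unknown residue X normalised to gap
  expect_equal(unname(x$seqs[3, 2]), "-")

  # Stockholm with '.' gaps parses to the same alignment as FASTA with '-'
  sto <- tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "s1 ACDE", "s2 AC.E", "//"), sto)
  y <- read_alignment(sto, "stockholm")
  expect_equal(y$seqs[2, ], c("A", "C", "-", "E"))

  # write/read round-trip preserves sequences byte-exactly
  out <- tempfile(fileext = ".fasta")
  write_alignment(x, out)
  expect_identical(read_alignment(out, "fasta")$seqs, x$seqs)

  expect_error(msa(c("ACDE", "ACD")), "ragged")
  expect_error(read_alignment(write_fasta_fixture(character(0)), "fasta"))
})

test_that("species labels come from sidecar vectors or identifier regex", {
  path <- write_fasta_fixture(c("ACDE", "ACDF"),
                              ids = c("A1_HUMAN", "B2_MOUSE"))
  x <- read_alignment(path, "fasta", species_from = "^[^_]+_(.+)$")
  expect_equal(x$species, c("HUMAN", "MOUSE"))
  y <- read_alignment(path, "fasta",
                      species_from = c(A1_HUMAN = "Homo sapiens",
                                       B2_MOUSE = "Mus musculus"))
  expect_equal(y$species[1], "Homo sapiens")
})

test_that("filter_gap_columns applies the strict >threshold rule", {
  # 100-row toy: column 3 has 71% gaps -> removed at 0.70; column 2 has
  # 70% exactly -> kept (rule is strictly greater)
  rows <- c(rep("A-AA", 29), rep("A--A", 41), rep("AA-A", 30))
  x <- toy_msa(rows)
  f <- filter_gap_columns(x, 0.70)
  expect_equal(n_col(f), 3L)
  expect_equal(f$column_map, c(1L, 2L, 4L))

  # no gaps -> identity
  g <- toy_msa(c("ACDE", "ACDF"))
  expect_identical(filter_gap_columns(g)$seqs, g$seqs)

  # 10-column toy with 3 columns above threshold -> 7 survive, map listed
  m <- matrix("A", nrow = 4, ncol = 10)
  m[, c(2, 5, 9)] <- "-"
  m[1, c(2, 5, 9)] <- "A"  # 75% gaps
  h <- filter_gap_columns(msa(m), 0.70)
  expect_equal(n_col(h), 7L)
  expect_equal(h$column_map, setdiff(1:10, c(2, 5, 9)))

  # idempotence
  expect_identical(filter_gap_columns(h, 0.7)$seqs, h$seqs)
  expect_identical(filter_gap_columns(h, 0.7)$column_map, h$column_map)
  expect_error(filter_gap_columns(msa(matrix("-", 2, 2,
                                             dimnames = list(c("a", "b"),
                                                             NULL))), 0.5),
               "all columns")
})

test_that("subset_by_species filters rows and drops oversized species", {
  x <- toy_msa(c("AAAA", "CCCC", "GGGG", "TTTT"),
               species = c("Homo sapiens", "Homo sapiens", "Mus musculus",
                           "Gallus gallus"))
  ex <- subset_by_species(x, exclude = "Homo sapiens")
  expect_equal(ex$species, c("Mus musculus", "Gallus gallus"))
  expect_equal(n_col(ex), n_col(x))

  # species exceeding max_per_species vanish entirely
  big <- toy_msa(rep(c("AAAA", "CCCC"), c(3, 1)),
                 ids = paste0("s", 1:4),
                 species = rep(c("big", "small"), c(3, 1)))
  kept <- subset_by_species(big, max_per_species = 2)
  expect_equal(kept$species, "small")

  expect_error(subset_by_species(x, include = "Homo sapiens",
                                 exclude = "Homo sapiens"), "overlap")
  expect_error(subset_by_species(x, include = "no such species"), "every")
})

test_that("read_ligands drops off-length peptides and keeps top fractions", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("sequence_id,peptide,score",
               "p1,ACDEFGHIK,0.9",   # 9-mer
               "p1,ACDEFGHI,0.99",   # 8-mer, dropped
               "p1,CCDEFGHIK,0.5",
               "p2,MMDEFGHIK,0.1"), path)
  ls1 <- read_ligands(path, "csv", length = 9)
  expect_equal(ls1$n_ligands, c(p1 = 2L, p2 = 1L))

  # 100 distinct scored 9-mers, top fraction 0.02 -> exactly 2 retained
  aa10 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")
  peps9 <- paste0(rep(aa10, each = 10), rep(aa10, 10), "DDDDDDD")
  big <- tempfile(fileext = ".csv")
  writeLines(c("sequence_id,peptide,score",
               sprintf("p1,%s,%d", peps9, seq_len(100))), big)
  ls2 <- read_ligands(big, "prediction", length = 9, top_fraction = 0.02)
  expect_equal(unname(ls2$n_ligands), 2L)
  expect_equal(sort(ls2$peptides$p1), sort(peps9[99:100]))

  # retention count is max(1, floor(f * n)) and ties break lexicographically
  tie <- tempfile(fileext = ".csv")
  writeLines(c("sequence_id,peptide,score",
               "p1,CCCCCCCCC,1", "p1,AAAAAAAAA,1", "p1,DDDDDDDDD,1"), tie)
  ls3 <- read_ligands(tie, "prediction", length = 9, top_fraction = 0.4)
  expect_equal(ls3$peptides$p1, "AAAAAAAAA")  # floor(1.2) = 1, lexicographic
  for (n in c(1, 3, 7, 50)) {
    f <- 0.3
    expect_equal(max(1, floor(f * n)), max(1L, floor(f * n)))
  }
  expect_error(read_ligands(path, "csv", length = 20), "no ligands")
})

test_that("read_site_annotations maps residue numbers through column_map", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("# position\tvalue", "position\tvalue", "12\t1.5", "14\t-0.3",
               "15\t0.0", "17\t2.2", "18\t0.7"), path)
  cmap <- c(10L, 12L, 14L, 15L, 17L, 18L)
  st <- read_site_annotations(path, "residue", column_map = cmap)
  expect_s3_class(st, "site_table")
  expect_equal(nrow(st), 5L)
  expect_equal(st$column, c(2L, 3L, 4L, 5L, 6L))
  expect_equal(st$value[st$column == 2L], 1.5)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("position\tvalue", "99\t1.0"), bad)
  expect_error(read_site_annotations(bad, "residue", column_map = cmap),
               "outside")
  # column dialect with extra annotation columns allowed
  extra <- tempfile(fileext = ".csv")
  writeLines(c("position,value,note", "1,0.5,x", "3,0.7,y"), extra)
  st2 <- read_site_annotations(extra, "column", n_col = 4L)
  expect_equal(st2$note, c("x", "y"))
})

test_that("read_allele_freqs applies the frequency floor", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("allele,frequency", "A*02:01,0.25", "B*07:02,0.001",
               "C*17:01,0.000001"), path)
  af <- read_allele_freqs(path)
  expect_equal(length(af), 2L)  # the 1e-6 allele is below the 1e-5 floor
  expect_equal(unname(af["A*02:01"]), 0.25)
})
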
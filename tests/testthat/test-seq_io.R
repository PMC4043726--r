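test_that("allele labels parse, reject bad headers, and support custom parsers", {
  p <- parse_allele_labels(c("1_F_1_a", "1_F_1_b", "2_M_1_a", "3_M_2_ab"))
  expect_equal(p$locality, c(1L, 1L, 2L, 3L))
  expect_equal(p$sex, c("F", "F", "M", "M"))
  expect_equal(p$allele_tag, c("a", "b", "a", "ab"))
  expect_equal(p$individual[1], "1_F_1")

  expect_error(parse_allele_labels("locA-F-1-a"), "unparseable.*locA-F-1-a")
  expect_error(parse_allele_labels("1_X_1_a"), "unparseable")

  # dialect hook: "3-m1a" style mapped into the canonical grammar
  dialect <- function(h) {
    m <- regmatches(h, regexec("^([0-9]+)-(m|f)([0-9]+)(a|b|ab)$", h))[[1]]
    if (length(m) != 5) return(NULL)
    list(locality = as.integer(m[2]), sex = toupper(m[3]),
         sample_no = as.integer(m[4]), allele_tag = m[5])
  }
  p2 <- parse_allele_labels(c("3-m1a", "3-m1b"), label_parser = dialect)
  expect_equal(p2$sex, c("M", "M"))
  expect_equal(p2$individual, c("3_M_1", "3_M_1"))
})

test_that("alignments load with validation and round-trip through FASTA", {
  m <- mk_marker(c("ACGTACGTAC", "ACGTACGTAA", "ACGAACGTAC", "ACGTACGTAC"),
                 c("1_F_1_a", "1_F_1_b", "2_M_1_a", "2_M_1_b"))
  expect_s3_class(m, "aligned_marker")
  expect_equal(m$length, 10L)
  expect_equal(nrow(m$seq), 4L)
  expect_equal(length(unique(m$alleles$individual)), 2L)

  expect_error(mk_marker(c("ACGTACGTAC", "ACGTACGTA"),
                         c("1_F_1_a", "1_F_1_b")), "ragged")
  expect_error(mk_marker(c("ACGT", "ACGT"), c("1_F_1_a", "1_F_1_a")),
               "duplicate")
  expect_error(mk_marker(c("ACGT", "ACGT", "ACGT"),
                         c("1_F_1_a", "1_F_1_b", "1_F_1_ab")),
               "mixes tag 'ab'")
  expect_error(mk_marker("AXGT", "1_F_1_a"), "invalid alignment character")

  tmp <- tempfile(fileext = ".fasta")
  write_alignment(m, tmp)
  m2 <- read_alignment(tmp, "toy")
  expect_identical(m2$seq, m$seq)
  expect_identical(m2$alleles, m$alleles)
  expect_error(read_alignment(tempfile(), "x"), "not found")
})

test_that("pair_alleles builds one genotype per individual with missing-allele flags", {
  m <- mk_marker(c("ACGT", "ACTA", "GGGG", "CCCC", "TTTT"),
                 c("1_F_1_a", "1_F_1_b", "2_M_1_ab", "3_M_2_a", "4_F_9_ab"))
  g <- pair_alleles(m, toy_regions())
  expect_equal(nrow(g), 4L)  # one row per distinct (locality, sex, sample)
  expect_equal(nrow(g), length(unique(m$alleles$individual)))

  het <- g[g$individual == "1_F_1", ]
  expect_false(het$allele1 == het$allele2)
  hom <- g[g$individual == "2_M_1", ]
  expect_true(hom$allele1 == hom$allele2)
  expect_false(hom$missing_allele)
  half <- g[g$individual == "3_M_2", ]
  expect_true(half$missing_allele)
  expect_true(is.na(half$allele2))
  expect_equal(g$region[g$individual == "2_M_1"], "SE_refugia")

  expect_error(pair_alleles(m, region_map(1, "SE_refugia")),
               "missing from region map")
})

test_that("variable and parsimony-informative site counts match the enumeration oracle", {
  # all identical
  m0 <- mk_marker(rep("ACGTACGT", 3), c("1_F_1_a", "1_F_1_b", "2_M_1_a"))
  expect_equal(unname(count_variable_sites(m0)), c(0L, 0L))

  # frozen case: two variable columns, neither informative (each minor
  # state is carried by a single sequence)
  m1 <- mk_marker(c("ACGT", "ACGA", "ACGA", "TCGA"),
                  c("1_F_1_a", "1_F_1_b", "2_M_1_a", "2_M_1_b"))
  expect_equal(unname(count_variable_sites(m1)), c(2L, 0L))
  expect_equal(count_variable_sites(m1), oracle_variable_sites(m1$seq))

  # informative column: two states, each twice
  m2 <- mk_marker(c("AAGT", "AAGT", "TAGT", "TAGT"),
                  c("1_F_1_a", "1_F_1_b", "2_M_1_a", "2_M_1_b"))
  expect_equal(unname(count_variable_sites(m2)), c(1L, 1L))

  # gap policy: gapped column dropped by default, counted as 5th state on demand
  m3 <- mk_marker(c("A-GT", "AAGT", "ACGT", "ACGT"),
                  c("1_F_1_a", "1_F_1_b", "2_M_1_a", "2_M_1_b"))
  expect_equal(unname(count_variable_sites(m3)), c(0L, 0L))
  expect_equal(unname(count_variable_sites(m3, gap_as_state = TRUE)),
               c(1L, 0L))
  expect_equal(count_variable_sites(m3, gap_as_state = TRUE),
               oracle_variable_sites(m3$seq, gap_as_state = TRUE))

  expect_error(count_variable_sites(mk_marker("ACGT", "1_F_1_a")),
               "at least two")

  # property: oracle agreement and PI <= variable <= length on random alignments
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(3:8, 1)
    L <- sample(5:20, 1)
    seqs <- matrix(sample(c("A", "C", "G", "T", "-", "N"), n * L,
                          replace = TRUE, prob = c(rep(0.22, 4), 0.07, 0.05)),
                   n, L)
    labs <- paste0(seq_len(n), "_F_1_a")
    m <- aligned_marker(seqs, labs, "r")
    for (gs in c(FALSE, TRUE)) {
      got <- count_variable_sites(m, gap_as_state = gs)
      expect_equal(got, oracle_variable_sites(seqs, gap_as_state = gs))
      expect_lte(got[["parsimony_informative"]], got[["variable"]])
      expect_lte(got[["variable"]], L)
    }
  }
})

test_that("region maps read from TSV and genotype tables export", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines("locality\tregion\n1\tSE_refugia\n20\tNW_Europe", tmp)
  rm <- read_region_map(tmp)
  expect_equal(unname(rm["20"]), "NW_Europe")

  m <- mk_marker(c("ACGT", "ACTA"), c("1_F_1_a", "1_F_1_b"))
  g <- pair_alleles(m, rm)
  out <- tempfile(fileext = ".tsv")
  write_genotype_table(g, out)
  back <- read.delim(out)
  expect_equal(back$individual, "1_F_1")
})
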
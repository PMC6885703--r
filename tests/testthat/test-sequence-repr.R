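test_that("alphabet and encoding matrix satisfy their invariants", {
  ab <- aa_alphabet()
  expect_length(ab$residues, 20)
  expect_false(ab$wildcard %in% ab$residues)
  expect_identical(ab$residues, sort(ab$residues))
  enc <- encoding_matrix()
  expect_equal(dim(enc$values), c(21, 20))
  expect_equal(unname(enc$values["X", ]), rep(0, 20))
  expect_true(all(is.finite(enc$values)))
})

test_that("core enumeration matches brute-force oracles", {
  # identity case
  cs <- enumerate_cores("AAAAAAAAA", 9)
  expect_equal(nrow(cs), 1)
  expect_equal(cs$core, "AAAAAAAAA")
  expect_equal(cs$deletion_length + cs$insertion_length, 0)

  # oracle: all contiguous deletion blocks / interior X insertions
  del_oracle <- function(pep, k) {
    L <- nchar(pep)
    d <- L - k
    unique(vapply(0:(L - d), function(s)
      paste0(substr(pep, 1, s), substr(pep, s + d + 1, L)), character(1)))
  }
  ins_oracle <- function(pep, k) {
    L <- nchar(pep)
    unique(vapply(1:(L - 1), function(s)
      paste0(substr(pep, 1, s), strrep("X", k - L), substr(pep, s + 1, L)),
      character(1)))
  }

  cs10 <- enumerate_cores("ACDEFGHIKL", 9)
  expect_setequal(cs10$core, del_oracle("ACDEFGHIKL", 9))
  expect_false(any(duplicated(cs10$core)))
  expect_true(all(cs10$deletion_length == 1 & cs10$insertion_length == 0))

  cs8 <- enumerate_cores("ACDEFGHI", 9)
  expect_setequal(cs8$core, ins_oracle("ACDEFGHI", 9))
  expect_true(all(grepl("X", cs8$core, fixed = TRUE)))
  expect_true(all(cs8$insertion_length == 1))

  # property: counts agree with the oracle for every length 8-14
  peps <- unlist(lapply(8:14, function(L) random_peptides(4, L, 100 + L)))
  for (p in peps) {
    got <- enumerate_cores(p, 9)$core
    exp <- if (nchar(p) == 9) p
           else if (nchar(p) > 9) del_oracle(p, 9) else ins_oracle(p, 9)
    expect_setequal(got, exp)
    expect_false(any(duplicated(got)))
    # exactly one of insertion/deletion is nonzero
    cs <- enumerate_cores(p, 9)
    expect_true(all(cs$deletion_length == 0 | cs$insertion_length == 0))
  }

  expect_error(enumerate_cores("ACDEFGH", 9, len_min = 8, len_max = 14),
               "length")
  expect_error(enumerate_cores("ACDEFGHIB", 9), "illegal symbol")
})

test_that("encode_example is deterministic and wildcard-transparent", {
  enc <- encoding_matrix()
  ps <- test_pseudo(2)
  x_all_x <- encode_example(1, "XXXXXXXXX", ps, enc)
  expect_equal(x_all_x[1:180], rep(0, 180)) # core block zero
  x1 <- encode_example(1, "ACDEFGHIK", ps, enc)
  x2 <- encode_example(1, "ACDEFGHIK", ps, enc)
  expect_identical(x1, x2)
  # encoding depends on the pseudo-sequence only, not the allele name
  d1 <- mhcdecon:::encode_dataset(
    data.frame(peptide = "ACDEFGHIK", target = 0, assay = "EL"),
    c(A = ps, B = ps), enc)
  expect_identical(d1$allele_enc[, 1], d1$allele_enc[, 2])
  # injectivity on distinct (core, pseudo) pairs, spot-checked
  ps2 <- test_pseudo(3)
  expect_false(identical(x1, encode_example(1, "ACDEFGHIR", ps, enc)))
  expect_false(identical(x1, encode_example(1, "ACDEFGHIK", ps2, enc)))
})

test_that("class II encoding adds flanking features of the expected size", {
  tc2 <- task_config("classII")
  d <- mhcdecon:::encode_dataset(
    data.frame(peptide = "ACDEFGHIKLMNPQR", target = 0, assay = "EL"),
    c(A = test_pseudo(4)), encoding_matrix(), tc2)
  # length one-hot (9) + indel (2) + position flags (3) + PFRs (40) + 2
  expect_equal(d$n_aux, 56)
  expect_equal(d$core_len, 9)
})

test_that("allele distance matches the normalized-similarity formula", {
  sub <- blosum50()
  a <- "AAAAA"
  b <- "AAAAC"
  s_ab <- 4 * sub["A", "A"] + sub["A", "C"]
  s_aa <- 5 * sub["A", "A"]
  s_bb <- 4 * sub["A", "A"] + sub["C", "C"]
  expect_equal(allele_distance(a, b, sub), 1 - s_ab / sqrt(s_aa * s_bb))
  expect_equal(allele_distance(a, a, sub), 0)
  # symmetry and non-negativity on random pairs
  for (s in 1:5) {
    p <- random_peptides(2, 34, 500 + s)
    expect_equal(allele_distance(p[1], p[2]), allele_distance(p[2], p[1]))
    expect_gte(allele_distance(p[1], p[2]), 0)
    expect_equal(allele_distance(p[1], p[1]), 0)
  }
  expect_error(allele_distance("AAA", "AAAA"), "equal length")
})

test_that("distance to a training set is the brute-force minimum", {
  tr <- random_peptides(3, 34, 9)
  a <- random_peptides(1, 34, 10)
  expect_equal(distance_to_training_set(a, tr),
               min(sapply(tr, allele_distance, a = a)))
  expect_equal(distance_to_training_set(tr[2], tr), 0)
  expect_equal(distance_to_training_set(a, tr[1]), allele_distance(a, tr[1]))
  expect_error(distance_to_training_set(a, character(0)), "non-empty")
})

test_that("the BLOSUM text reader round-trips the Biostrings matrix", {
  m <- blosum50()
  f <- withr::local_tempfile(fileext = ".txt")
  # write in the NCBI layout: header row then labelled rows
  lines <- c("# test matrix", paste(" ", paste(colnames(m), collapse = " ")),
             vapply(rownames(m), function(r)
               paste(r, paste(m[r, ], collapse = " ")), character(1)))
  writeLines(lines, f)
  m2 <- read_blosum(f)
  expect_equal(m2, m)
})
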
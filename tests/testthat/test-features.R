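test_that("amino acid composition matches hand counts", {
  a <- compute_aac("AAAA")
  expect_equal(unname(a[["AAC:A"]]), 1.0)
  expect_equal(sum(a), 1.0)

  b <- compute_aac("ACDC")
  expect_equal(unname(b[c("AAC:A", "AAC:C", "AAC:D")]), c(0.25, 0.5, 0.25))
  expect_equal(sum(b[setdiff(names(b), c("AAC:A", "AAC:C", "AAC:D"))]), 0)
  expect_length(compute_aac(random_sequence(7)), 20)
})

test_that("dipeptide composition matches hand counts", {
  a <- compute_dc("AAA")
  expect_equal(unname(a[["DC:AA"]]), 1.0)

  b <- compute_dc("ACA")
  expect_equal(unname(b[c("DC:AC", "DC:CA")]), c(0.5, 0.5))
  expect_length(b, 400)
  expect_error(compute_dc("A"), "sequence_too_short_for_dc")
})

test_that("composition blocks are probability vectors on random sequences", {
  set.seed(10)
  for (i in 1:25) {
    s <- random_sequence(sample(2:300, 1))
    expect_equal(sum(compute_aac(s)), 1.0, tolerance = 1e-9)
    expect_equal(sum(compute_dc(s)), 1.0, tolerance = 1e-9)
  }
})

test_that("AAC is permutation-invariant but DC is not", {
  s <- "AACDEFGHIK"
  perm <- "KIHGFEDCAA"   # same residues, different order
  expect_equal(compute_aac(s), compute_aac(perm))
  expect_false(isTRUE(all.equal(compute_dc(s), compute_dc(perm))))
})

test_that("PSSM composition follows the grouped-sum rule exactly", {
  # forced 2-residue example: contributions land on (residue, column) cells
  cols <- psiblast_column_order()
  scores <- matrix(0, nrow = 2, ncol = 20, dimnames = list(NULL, cols))
  scores[1, "A"] <- 2
  scores[2, "C"] <- 3
  scores[2, "A"] <- 7
  p <- structure(list(protein_id = "x", scores = scores,
                      residues = c("A", "C"), column_order = cols,
                      source_kind = "log_odds"), class = "pssm")
  v <- compute_pssm_composition("AC", p)
  expect_equal(unname(v[c("PSSM:A|A", "PSSM:C|C", "PSSM:C|A")]), c(2, 3, 7))
  expect_equal(sum(v), 12)  # nothing else is nonzero

  # all-zero profile
  p$scores[] <- 0
  expect_equal(unname(compute_pssm_composition("AC", p)), rep(0, 400))
})

test_that("PSSM composition equals the brute-force double loop", {
  set.seed(77)
  for (i in 1:10) {
    s <- random_sequence(60)
    p <- random_pssm(s)
    expect_equal(compute_pssm_composition(s, p), brute_pssm_composition(s, p))
  }
})

test_that("PSSM composition is linear in the score matrix", {
  set.seed(5)
  s <- random_sequence(40)
  pa <- random_pssm(s); pb <- random_pssm(s)
  psum <- pa
  psum$scores <- pa$scores + pb$scores
  expect_equal(compute_pssm_composition(s, psum),
               compute_pssm_composition(s, pa) +
                 compute_pssm_composition(s, pb))
})

test_that("featurize concatenates blocks in AAC, DC, PSSM order", {
  set.seed(8)
  s <- random_sequence(55)
  p <- random_pssm(s)
  v <- featurize(s, p)
  expect_length(v, 820)
  expect_equal(v[1:20], compute_aac(s))
  expect_equal(v[21:420], compute_dc(s))
  expect_equal(v[421:820], compute_pssm_composition(s, p))
  expect_length(featurize(s, include_pssm = FALSE), 420)
  expect_error(featurize(s, include_pssm = TRUE), "no PSSM")
})

test_that("feature names are a bijection with positions and serialize", {
  set.seed(9)
  s <- random_sequence(52)
  v <- featurize(s, random_pssm(s))
  expect_false(anyDuplicated(names(v)) > 0)
  fm <- feature_matrix(matrix(v, nrow = 1, dimnames = list("p1", names(v))),
                       labels = c(p1 = 1L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(fm, path)
  expect_identical(colnames(read_feature_matrix(path)$values), names(v))
})

test_that("PSSM normalization options rescale the block as documented", {
  set.seed(12)
  s <- random_sequence(30)
  p <- random_pssm(s)
  raw <- compute_pssm_composition(s, p)
  expect_equal(compute_pssm_composition(s, p, normalize = "by_length"),
               raw / 30)
  byres <- compute_pssm_composition(s, p, normalize = "by_residue_count")
  counts <- table(factor(strsplit(s, "")[[1]], levels = aa_alphabet()))
  t_of <- sub("\\|.*$", "", sub("^PSSM:", "", names(raw)))
  expected <- ifelse(counts[t_of] > 0, raw / as.numeric(counts[t_of]), 0)
  expect_equal(unname(byres), as.numeric(expected))
})
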
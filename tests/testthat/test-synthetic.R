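test_that("generators are pure functions of their configuration", {
  cfg <- synthetic_config(seed = 5, n_pos = 5, n_neg = 5)
  expect_identical(generate_proteins(cfg), generate_proteins(cfg))
  fm1 <- generate_labeled_dataset(cfg)
  fm2 <- generate_labeled_dataset(cfg)
  expect_equal(fm1$values, fm2$values)
  u1 <- generate_annotation_universe(seed = 8)
  u2 <- generate_annotation_universe(seed = 8)
  expect_identical(u1$annotations$term_to_genes, u2$annotations$term_to_genes)
  expect_identical(u1$query, u2$query)
})

test_that("composition bias scales with effect size", {
  null_cfg <- synthetic_config(seed = 6, n_pos = 30, n_neg = 30,
                               effect_size = 0)
  seqs <- generate_proteins(null_cfg)
  afrac <- vapply(seqs, function(s) compute_aac(s)[["AAC:A"]], numeric(1))
  pos <- grepl("^pos", names(seqs))
  # effect 0: class means differ only by sampling noise around 1/20
  expect_lt(abs(mean(afrac[pos]) - mean(afrac[!pos])), 0.02)

  strong <- synthetic_config(seed = 7, n_pos = 30, n_neg = 30,
                             effect_size = 1, bias_residues = "A")
  seqs2 <- generate_proteins(strong)
  afrac2 <- vapply(seqs2, function(s) compute_aac(s)[["AAC:A"]], numeric(1))
  pos2 <- grepl("^pos", names(seqs2))
  expect_gt(mean(afrac2[pos2]), 0.2)
  expect_lt(mean(afrac2[!pos2]), 0.1)
})

test_that("generated sequences pass the dataset validators", {
  cfg <- synthetic_config(seed = 9, n_pos = 10, n_neg = 10)
  seqs <- generate_proteins(cfg)
  filt <- apply_dataset_filters(seqs)
  expect_equal(nrow(filt$rejected), 0)
  expect_true(all(nchar(seqs) >= 50))
})

test_that("labeled datasets have the full 820-dim encoding", {
  cfg <- synthetic_config(seed = 10, n_pos = 8, n_neg = 8)
  fm <- generate_labeled_dataset(cfg)
  expect_equal(dim(fm$values), c(16, 820))
  expect_equal(sum(fm$labels), 8)
  expect_equal(unname(rowSums(fm$values[, 1:20])), rep(1, 16))
})

test_that("profile bias is visible only through the PSSM block", {
  cfg <- synthetic_config(seed = 11, n_pos = 40, n_neg = 40,
                          signal_kind = "pssm_bias", effect_size = 1,
                          bias_residues = "A")
  fm <- generate_labeled_dataset(cfg)
  pssm_cols <- grep("^PSSM:", colnames(fm$values))
  a_cols <- grep("^PSSM:.*\\|A$", colnames(fm$values))
  pos <- fm$labels == 1
  gap <- mean(rowSums(fm$values[pos, a_cols])) -
    mean(rowSums(fm$values[!pos, a_cols]))
  expect_gt(gap, 0)
  # composition blocks stay null
  aac_gap <- abs(mean(fm$values[pos, "AAC:A"]) -
                   mean(fm$values[!pos, "AAC:A"]))
  expect_lt(aac_gap, 0.02)
})

test_that("a planted annotation term attains the minimum enrichment P", {
  for (s in c(2, 4)) {
    uni <- generate_annotation_universe(seed = s)
    res <- enrich(uni$query, uni$annotations)
    expect_identical(res$term[which.min(res$p_value)], uni$planted_term)
  }
})

test_that("simulated projects are complete and parseable", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(seed = 12, n_pos = 6, n_neg = 6)
  paths <- simulate_project(cfg, dir)
  seqs <- read_fasta(paths$fasta)
  expect_length(seqs, 12)
  labels <- read_labels(paths$labels)
  expect_setequal(names(labels), names(seqs))
  p <- read_pssm(file.path(paths$pssm_dir, paste0(names(seqs)[1], ".pssm")))
  expect_equal(nrow(p$scores), nchar(seqs[[1]]))
  ann <- read_annotations(paths$gmt, background = paths$background)
  expect_gt(length(ann$term_to_genes), 0)
  sites <- read_sites(paths$sites)
  w <- extract_windows(seqs, sites)
  expect_true(all(w$full_width))   # sites are planted at interior positions
})
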
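test_that("Mann-Whitney U and exact p match full enumeration", {
  t <- mann_whitney_one_tailed(c(3, 4, 5), c(1, 2))
  expect_equal(t$statistic, 6)
  expect_equal(t$p_value, 0.1)        # 1 of C(5,2) = 10 assignments
  expect_equal(t$effect_size, 1)

  withr::with_seed(41, {
    for (i in 1:20) {
      n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
      x <- sample(1:6, n1, replace = TRUE)   # ties across and within groups
      y <- sample(1:6, n2, replace = TRUE)
      for (alt in c("greater", "less")) {
        got <- mann_whitney_one_tailed(x, y, alt)
        oracle <- mwu_enumerate(x, y, alt)
        expect_equal(got$statistic, oracle$u)
        expect_equal(got$p_value, oracle$p)
        expect_equal(got$effect_size * n1 * n2, got$statistic)
      }
    }
  })

  expect_error(mann_whitney_one_tailed(numeric(), 1:3), "input error")
})

test_that("MWU effect sizes hit the symmetric and extreme cases", {
  x <- c(1, 2, 2, 5, 7)
  expect_equal(mann_whitney_one_tailed(x, x)$effect_size, 0.5)
  t <- mann_whitney_one_tailed(101:106, 1:6)
  expect_equal(t$effect_size, 1)
  expect_equal(t$p_value, 1 / choose(12, 6))     # minimal attainable p

  # large-sample path approximates the t-distribution-free null
  withr::with_seed(43, {
    x <- rnorm(50); y <- rnorm(60)
  })
  ours <- mann_whitney_one_tailed(x, y, "greater")
  ref <- wilcox.test(x, y, alternative = "greater", exact = FALSE,
                     correct = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("Bonferroni correction is monotone and capped", {
  p <- c(0.001, 0.02, 0.5, 1)
  expect_equal(bonferroni(p), pmin(1, p * 4))
  expect_true(all(bonferroni(p) >= p))
  expect_true(all(bonferroni(p, m = 10) >= bonferroni(p, m = 4)))
})

test_that("codon-position tests detect a planted second-vs-third gradient", {
  fx <- base_fixture()
  model <- fx$model
  len <- Biostrings::width(fx$genome)[1]
  # plant: codon position 2 highest, then 1, then 3
  base <- withr::with_seed(51, rnorm(len, mean = 0, sd = 0.5))
  ss <- data.frame(chrom = names(fx$genome)[1], pos = seq_len(len),
                   score = base)
  for (tx in transcripts(model)) {
    gpos <- cds_positions(model, tx)
    cp <- (seq_along(gpos) - 1) %% 3 + 1
    ss$score[gpos[cp == 2]] <- ss$score[gpos[cp == 2]] + 3
    ss$score[gpos[cp == 1]] <- ss$score[gpos[cp == 1]] + 1.5
  }
  res <- codon_position_tests(model, ss)
  n_genes <- length(single_transcript_genes(model))
  expect_equal(res$counts["3", "2"], n_genes)   # second > third everywhere
  expect_equal(res$counts["2", "3"], 0)
  expect_gte(res$counts["3", "1"], n_genes - 2)
  expect_gte(res$counts["1", "2"], res$counts["2", "1"])

  # uniform scores: essentially nothing significant after Bonferroni
  ss_null <- data.frame(chrom = names(fx$genome)[1], pos = seq_len(len),
                        score = withr::with_seed(52, rnorm(len)))
  res0 <- codon_position_tests(model, ss_null)
  expect_lte(sum(res0$counts, na.rm = TRUE), 2)
})

test_that("flipping a gene's strand swaps codon positions 1 and 3", {
  fx <- base_fixture()
  model <- fx$model
  tx <- transcripts(model)[1]
  gene <- model$Parent[model$type == "mRNA" & model$ID == tx][1]
  gpos_fwd <- cds_positions(model, tx)
  flipped <- model
  flip_rows <- flipped$ID %in% c(tx, gene) |
    (!is.na(flipped$Parent) & flipped$Parent == tx)
  flipped$strand[flip_rows] <- setdiff(c("+", "-"),
                                       model$strand[model$ID == tx][1])
  gpos_rev <- cds_positions(flipped, tx)
  expect_setequal(gpos_fwd, gpos_rev)            # same sites either way
  cp_fwd <- setNames((seq_along(gpos_fwd) - 1) %% 3 + 1, gpos_fwd)
  cp_rev <- setNames((seq_along(gpos_rev) - 1) %% 3 + 1, gpos_rev)
  cp_rev <- cp_rev[names(cp_fwd)]
  expect_true(all(cp_fwd[cp_fwd == 2] == cp_rev[cp_fwd == 2]))
  expect_true(all(cp_rev[cp_fwd == 1] == 3))
  expect_true(all(cp_rev[cp_fwd == 3] == 1))
})

test_that("miRNA scores above flanks are detected at the predicted effect size", {
  # five well-separated miRNAs so flanks never touch another miRNA
  len <- 20000L
  starts <- seq(2000, 18000, by = 4000)
  model <- gene_model(data.frame(
    seqid = "chr1", type = "miRNA", start = starts, end = starts + 79L,
    strand = "+", ID = paste0("mir", seq_along(starts)),
    Parent = NA_character_, phase = NA_integer_))
  # planted: miRNA ~ N(10, 2), everything else ~ N(7, 2)
  ss <- data.frame(chrom = "chr1", pos = seq_len(len),
                   score = withr::with_seed(53, rnorm(len, 7, 2)))
  in_mir <- rep(FALSE, len)
  for (i in seq_along(starts)) in_mir[starts[i]:(starts[i] + 79L)] <- TRUE
  ss$score[in_mir] <- withr::with_seed(54, rnorm(sum(in_mir), 10, 2))
  res <- mirna_flank_test(model, ss,
                          chrom_lengths = c(chr1 = len))
  # closed-form AUC for two normals: Phi(delta / (sd * sqrt(2)))
  expected_auc <- pnorm((10 - 7) / (2 * sqrt(2)))
  expect_lt(abs(res$global$effect_size - expected_auc), 0.05)
  expect_lt(res$global$p_value, 1e-10)
  expect_true(all(res$per_mirna$significant))

  # identical distributions: no signal
  ss0 <- data.frame(chrom = "chr1", pos = seq_len(len),
                    score = withr::with_seed(57, rnorm(len, 7, 2)))
  res0 <- mirna_flank_test(model, ss0, chrom_lengths = c(chr1 = len))
  expect_lt(abs(res0$global$effect_size - 0.5), 0.1)
  expect_false(any(res0$per_mirna$significant))

  # miRNAs overlapping training variants are excluded
  res_ex <- mirna_flank_test(model, ss,
                             training_positions = data.frame(
                               chrom = "chr1", pos = starts[1]))
  expect_equal(res_ex$n_excluded, 1)
  expect_equal(nrow(res_ex$per_mirna), length(starts) - 1)
})

test_that("intron enrichment decreases with intron ordinal when planted", {
  fx <- base_fixture()
  model <- fx$model
  len <- Biostrings::width(fx$genome)[1]
  ss <- data.frame(chrom = names(fx$genome)[1], pos = seq_len(len),
                   score = withr::with_seed(61, rnorm(len)))
  for (tx in transcripts(model)) {
    ints <- tx_introns(model, tx)
    for (k in seq_len(nrow(ints))) {
      sel <- ss$pos >= ints$start[k] & ss$pos <= ints$end[k]
      # first intron boosted hard, later ones not at all
      ss$score[sel] <- ss$score[sel] + ifelse(ints$ordinal[k] == 1, 3, 0)
    }
  }
  res <- intron_position_tests(model, ss)
  expect_true(all(diff(res$n_tests) <= 0))       # weakly decreasing tests
  if (nrow(res) >= 2) {
    expect_gt(res$normalized[1], max(res$normalized[-1]))
    expect_equal(res$normalized[1], 1)
  }
})

test_that("tissue gene sets are compared against housekeeping CDS scores", {
  fx <- base_fixture()
  len <- Biostrings::width(fx$genome)[1]
  gs <- fx$tracks$gene_sets
  tissues <- setdiff(unique(gs$set_name), "housekeeping")
  low_tissues <- tissues[seq_len(min(2, length(tissues)))]
  ss <- data.frame(chrom = names(fx$genome)[1], pos = seq_len(len),
                   score = withr::with_seed(71, rnorm(len, 5)))
  # plant: genes of low_tissues score clearly below everything else
  for (ti in low_tissues) {
    for (g in gs$gene_id[gs$set_name == ti]) {
      tx <- fx$model$ID[fx$model$type == "mRNA" & fx$model$Parent == g]
      for (t1 in tx) {
        gpos <- cds_positions(fx$model, t1)
        ss$score[gpos] <- ss$score[gpos] - 4
      }
    }
  }
  res <- tissue_vs_housekeeping(fx$tracks$expression, gs, fx$model, ss,
                                min_expression = 100)
  expect_setequal(res$tissue, tissues)
  expect_setequal(res$tissue[res$significant_lower], low_tissues)
  expect_true(all(res$auc_housekeeping[res$tissue %in% low_tissues] > 0.8))
  other <- setdiff(tissues, low_tissues)
  expect_true(all(abs(res$auc_housekeeping[res$tissue %in% other] - 0.5)
                  < 0.1))
  expect_error(tissue_vs_housekeeping(fx$tracks$expression, gs, fx$model,
                                      ss, min_expression = 1e9),
               "data error")
})

test_that("segregating variants rank by score times allele frequency", {
  vs <- data.frame(chrom = "5", pos = c(14463457, 1, 2, 3),
                   phred = c(26.559, 30, 12, 8),
                   af = c(0.986, 0, 1, 0.5))
  top <- prioritize_segregating(vs, top_k = 4)
  expect_equal(top$product[top$pos == 14463457], 26.559 * 0.986)
  expect_equal(top$pos[nrow(top)], 1)            # zero frequency ranks last
  expect_equal(top$product[top$af == 1], 12)     # frequency 1: product = score
  expect_equal(top$product, sort(top$product, decreasing = TRUE))
  expect_error(prioritize_segregating(data.frame(phred = 1, af = 1.2)),
               "data error")
})
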
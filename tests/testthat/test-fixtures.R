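test_that("reference generation is reproducible and honours composition", {
  spec <- synthetic_genome_spec(1, 1000, 0.5, seed = 7)
  a <- generate_reference(spec)
  b <- generate_reference(spec)
  expect_identical(as.character(a), as.character(b))
  expect_equal(Biostrings::width(a), 1000)
  c_ <- generate_reference(synthetic_genome_spec(1, 1000, 0.5, seed = 8))
  expect_false(identical(as.character(a), as.character(c_)))

  at_only <- generate_reference(synthetic_genome_spec(1, 500, 0, seed = 1))
  expect_true(grepl("^[AT]+$", as.character(at_only[[1]])))

  # empirical GC within 3 binomial standard errors of the target
  big <- generate_reference(synthetic_genome_spec(1, 100000, 0.42, seed = 2))
  gc <- mean(strsplit(as.character(big[[1]]), "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.42), 3 * sqrt(0.42 * 0.58 / 100000))

  expect_error(synthetic_genome_spec(0, 1000, 0.5), "configuration error")
  expect_error(synthetic_genome_spec(1, 1000, 1.5), "configuration error")
})

test_that("ancestor evolution matches branch probabilities and CpG boost", {
  ref <- generate_reference(synthetic_genome_spec(1, 100000, 0.42, seed = 2))

  identical_anc <- evolve_ancestors(
    ref, ancestor_tree(c(anc = 0), cpg_multiplier = 1), seed = 1)
  expect_identical(as.character(identical_anc$anc[[1]]),
                   as.character(ref[[1]]))

  p <- 0.01
  anc <- evolve_ancestors(ref, ancestor_tree(c(anc = p), cpg_multiplier = 1),
                          seed = 3)
  rc <- strsplit(as.character(ref[[1]]), "")[[1]]
  ac <- strsplit(as.character(anc$anc[[1]]), "")[[1]]
  expect_equal(length(ac), length(rc))           # SNV-only, length conserved
  rate <- mean(rc != ac)
  expect_lt(abs(rate - p), 3 * sqrt(p * (1 - p) / length(rc)))

  # CpG-context sites mutate ~multiplier times as often
  anc10 <- evolve_ancestors(ref, ancestor_tree(c(anc = p),
                                               cpg_multiplier = 10), seed = 4)
  ac10 <- strsplit(as.character(anc10$anc[[1]]), "")[[1]]
  cpg <- caddscore:::cpg_context(rc)
  rate_cpg <- mean(rc[cpg] != ac10[cpg])
  rate_non <- mean(rc[!cpg] != ac10[!cpg])
  expect_gt(rate_cpg / rate_non, 7)
  expect_lt(rate_cpg / rate_non, 13)

  expect_error(ancestor_tree(c(anc = 0.01), cpg_multiplier = 0.5),
               "configuration error")
})

test_that("population generator produces the designed frequency classes", {
  ref <- generate_reference(synthetic_genome_spec(1, 20000, 0.42, seed = 7))
  anc <- evolve_ancestors(ref, ancestor_tree(), seed = 3)$anc_close

  all_fixed <- generate_population(ref, anc, population_spec(
    n_sites = 50, frac_fixed_derived = 1, frac_ancestral_minor = 0, seed = 1))
  expect_true(all(all_fixed$af > 0.9))
  expect_true(all(all_fixed$truth == "fixed_derived"))
  anc_base <- substring(as.character(anc[[1]]), all_fixed$pos, all_fixed$pos)
  expect_true(all(all_fixed$alt != anc_base))    # non-ancestral allele fixed

  spec <- population_spec(n_sites = 200, frac_fixed_derived = 0.4,
                          frac_ancestral_minor = 0.1, seed = 5)
  a <- generate_population(ref, anc, spec)
  b <- generate_population(ref, anc, spec)
  expect_identical(a, b)                          # deterministic under seed
  expect_equal(as.vector(table(a$truth)[c("fixed_derived",
                                          "ancestral_minor")]), c(80, 20))
  seg <- a[a$truth == "segregating", ]
  expect_true(all(seg$af > 0.05 & seg$af <= 0.9))
  am <- a[a$truth == "ancestral_minor", ]
  expect_true(all(am$af > 0.9 & (1 - am$af) > 0.05))
  fd <- a[a$truth == "fixed_derived", ]
  expect_true(all(fd$af > 0.9 & (1 - fd$af) <= 0.05))
})

test_that("gene model fixtures build valid transcripts", {
  fx <- base_fixture()
  model <- fx$model

  expect_setequal(single_transcript_genes(model),
                  model$ID[model$type == "gene"])
  for (tx in transcripts(model)) {
    cds <- cds_sequence(model, fx$genome, tx)
    expect_equal(nchar(cds) %% 3, 0)
    aa <- translate_cds(cds)
    expect_equal(substr(aa, 1, 1), "M")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("[*]", substr(aa, 1, nchar(aa) - 1)))
    ints <- tx_introns(model, tx)
    if (nrow(ints)) expect_true(all(ints$end - ints$start + 1 >= 8))
  }

  # miRNAs disjoint from every CDS
  mirna <- model[model$type == "miRNA", ]
  cds <- model[model$type == "CDS", ]
  expect_equal(nrow(mirna), 3)
  for (i in seq_len(nrow(mirna))) {
    overlap <- cds$seqid == mirna$seqid[i] &
      cds$start <= mirna$end[i] & cds$end >= mirna$start[i]
    expect_false(any(overlap))
  }

  # GFF3 round trip
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gene_model(model, path)
  back <- read_gene_model(path)
  keycols <- c("seqid", "type", "start", "end", "strand", "ID", "Parent")
  m <- as.data.frame(model)[, keycols]
  b <- as.data.frame(back)[, keycols]
  m <- m[do.call(order, m), ]; b <- b[do.call(order, b), ]
  rownames(m) <- rownames(b) <- NULL
  expect_identical(m, b)

  expect_error(
    generate_gene_model(generate_reference(synthetic_genome_spec(
      1, 500, 0.42, seed = 1)), n_genes = 20, n_mirnas = 0, seed = 1),
    "configuration error")
})

test_that("tracks honour coverage and expression marks housekeeping genes", {
  fx <- base_fixture()
  variants <- data.frame(chrom = names(fx$genome)[1], pos = seq(101, 2100),
                         ref = "A", alt = "C")

  full <- annotate_tracks(variants, fx$tracks$tracks)
  expect_false(anyNA(full))                       # coverage 1: nothing missing

  half <- generate_tracks(fx$genome, fx$model, seed = 9,
                          coverage = c(phylop = 0.5))
  vals <- annotate_tracks(variants, half$tracks)
  frac_missing <- mean(is.na(vals$phylop))
  expect_lt(abs(frac_missing - 0.5), 3 * sqrt(0.25 / nrow(variants)))

  gs <- fx$tracks$gene_sets
  expect_equal(sum(gs$set_name == "housekeeping"), 2)
  expect_setequal(gs$gene_id[gs$set_name == "housekeeping"],
                  fx$tracks$housekeeping)
  expect_setequal(gs$gene_id, fx$model$ID[fx$model$type == "gene"])
})
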
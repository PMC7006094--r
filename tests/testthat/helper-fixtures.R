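# shared fixtures, memoised so expensive generation runs once per suite
.fixture_cache <- new.env(parent = emptyenv())

base_fixture <- function() {
  if (!is.null(.fixture_cache$base)) return(.fixture_cache$base)
  ref <- generate_reference(synthetic_genome_spec(
    n_chromosomes = 1, chrom_length = 30000, gc_content = 0.42, seed = 7))
  gm <- generate_gene_model(ref, n_genes = 8, n_mirnas = 3, seed = 11)
  genome <- gm$genome
  ancestors <- evolve_ancestors(genome, ancestor_tree(), seed = 3)
  tracks <- generate_tracks(genome, gm$model, seed = 2,
                            coverage = c(phylop = 1, phastcons = 1, gerp = 1))
  .fixture_cache$base <- list(reference = ref, model = gm$model,
                              genome = genome, ancestors = ancestors,
                              tracks = tracks)
  .fixture_cache$base
}

# a tiny hand-built gene model on a hand-built genome with fully known
# coordinates, for consequence assertions:
# layout (plus strand): gene 11..60, exon1 11..34, exon2 55..60
#   5'UTR 11..13, CDS piece1 14..34, intron 35..54, CDS piece2 55..57,
#   3'UTR 58..60; spliced CDS = ATGAAACCCATTGAATGTTGA + TAA
toy_gene_fixture <- function() {
  if (!is.null(.fixture_cache$toy)) return(.fixture_cache$toy)
  left <- "CCTTCCTTCC"                        # 1..10 intergenic-ish
  utr5 <- "TTT"                               # 11..13
  cds1 <- "ATGAAACCCATTGAATGTTGT"             # 14..34 (7 codons, no stop)
  intr <- "CCTTCCTTCCTTCCTTCCTT"              # 35..54 intron (20 bp)
  cds2 <- "TAA"                               # 55..57 stop codon
  utr3 <- "TTT"                               # 58..60
  right <- paste(rep("CCTTCCTTCC", 14), collapse = "")  # pad to length 200
  seqstr <- paste0(left, utr5, cds1, intr, cds2, utr3, right)
  genome <- Biostrings::DNAStringSet(c(chrT = seqstr))
  rows <- data.frame(
    seqid = "chrT",
    type = c("gene", "mRNA", "exon", "exon", "CDS", "CDS",
             "five_prime_UTR", "three_prime_UTR"),
    start = c(11, 11, 11, 55, 14, 55, 11, 58),
    end = c(60, 60, 34, 60, 34, 57, 13, 60),
    strand = "+",
    ID = c("geneT", "geneT.t1", "geneT.t1.exon1", "geneT.t1.exon2",
           "geneT.t1.cds1", "geneT.t1.cds2", "geneT.t1.utr5",
           "geneT.t1.utr3"),
    Parent = c(NA, "geneT", rep("geneT.t1", 6)),
    phase = c(NA, NA, NA, NA, 0, 0, NA, NA),
    stringsAsFactors = FALSE)
  .fixture_cache$toy <- list(model = gene_model(rows), genome = genome)
  .fixture_cache$toy
}

# variant set with class signal planted only in CDS features: derived
# (class 0) CDS variants are synonymous (selection removed the damaging
# ones), simulated (class 1) CDS variants are arbitrary; outside genes the
# two classes are indistinguishable
planted_cds_variants <- function(fx, n_cds = 250, n_intergenic = 250,
                                 seed = 5, flank_size = 80) {
  withr::with_seed(seed, {
    cds <- fx$model[fx$model$type == "CDS", ]
    subs <- do.call(rbind, lapply(seq_len(nrow(cds)), function(i)
      enumerate_substitutions(fx$genome, cds$seqid[i], cds$start[i],
                              cds$end[i])))
    ann <- annotate_consequence(subs, fx$model, fx$genome,
                                flank_size = flank_size)
    syn <- ann[ann$category == "synonymous", ]
    cls0_cds <- syn[sample.int(nrow(syn), n_cds, replace = TRUE), ]
    cls1_cds <- ann[sample.int(nrow(ann), n_cds, replace = TRUE), ]
    # intergenic background identical for both classes
    cats_all <- classify_consequence(
      data.frame(chrom = names(fx$genome)[1], pos = seq_len(30000),
                 ref = "A", alt = "C"),
      fx$model, fx$genome, flank_size = flank_size)
    inter_pos <- which(cats_all == "intergenic")
    chars <- strsplit(as.character(fx$genome[[1]]), "")[[1]]
    mk_inter <- function(n) {
      pos <- sample(inter_pos, n, replace = TRUE)
      ref <- chars[pos]
      alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                            1), character(1), USE.NAMES = FALSE)
      data.frame(chrom = names(fx$genome)[1], pos = pos, ref = ref, alt = alt,
                 stringsAsFactors = FALSE)
    }
    cols <- c("chrom", "pos", "ref", "alt")
    v0 <- rbind(cls0_cds[, cols], mk_inter(n_intergenic))
    v1 <- rbind(cls1_cds[, cols], mk_inter(n_intergenic))
    v0$class <- 0L
    v1$class <- 1L
    out <- rbind(v0, v1)
    rownames(out) <- NULL
    out
  })
}

# brute-force ROC-AUC by pair counting, ties counting one half
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# exact Mann-Whitney enumeration oracle (independent of the package path)
mwu_enumerate <- function(x, y, alternative = "greater") {
  pooled <- c(x, y)
  n1 <- length(x)
  ustat <- function(a, b) {
    s <- 0
    for (ai in a) s <- s + sum(ai > b) + 0.5 * sum(ai == b)
    s
  }
  u_obs <- ustat(x, y)
  sets <- utils::combn(length(pooled), n1)
  u_all <- apply(sets, 2, function(idx) ustat(pooled[idx], pooled[-idx]))
  eps <- 1e-9
  p <- if (alternative == "greater") mean(u_all >= u_obs - eps) else
    mean(u_all <= u_obs + eps)
  list(u = u_obs, p = p)
}
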
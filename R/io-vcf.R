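#' Write a population site table as VCF v4.2
#'
#' Emits one biallelic SNV record per row with the alternate-allele
#' frequency in `INFO/AF`; contig lengths are taken from the reference.
#'
#' @param sites data.frame `chrom`, `pos`, `ref`, `alt`, `af`.
#' @param path output path.
#' @param reference `DNAStringSet` supplying contig headers.
#' @export
write_population_vcf <- function(sites, path, reference) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(reference),
            Biostrings::width(reference)),
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Alternate allele frequency\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  sites <- sites[order(sites$chrom, sites$pos), ]
  records <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%s",
                     sites$chrom, sites$pos, sites$ref, sites$alt,
                     format(sites$af, digits = 10, scientific = FALSE,
                            trim = TRUE))
  writeLines(c(header, records), path)
  invisible(path)
}

#' Read a population VCF into a site table
#'
#' Parses through [VariantAnnotation::readVcf()]; the alternate-allele
#' frequency comes from `INFO/AF` when present and is otherwise computed
#' from genotype columns.
#'
#' @param path VCF path.
#' @return data.frame `chrom`, `pos`, `ref`, `alt`, `af`.
#' @export
read_population_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  alt_chr <- vapply(as.list(alt), function(a)
    as.character(a)[1], character(1))
  info <- VariantAnnotation::info(vcf)
  if ("AF" %in% names(info)) {
    af <- vapply(as.list(info$AF), function(a)
      if (length(a)) as.numeric(a)[1] else NA_real_, numeric(1))
  } else {
    gt <- VariantAnnotation::geno(vcf)$GT
    if (is.null(gt)) {
      stop("format error: VCF has neither INFO/AF nor genotypes",
           call. = FALSE)
    }
    af <- apply(gt, 1, function(g) {
      alleles <- unlist(strsplit(g, "[/|]"))
      alleles <- alleles[alleles != "."]
      mean(alleles == "1")
    })
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
             pos = GenomicRanges::start(rr),
             ref = as.character(VariantAnnotation::ref(vcf)),
             alt = alt_chr,
             af = unname(af),
             stringsAsFactors = FALSE)
}

#' Write / read a variant table (chrom, pos, ref, alt, class) as TSV
#' @param variants data.frame.
#' @param path file path.
#' @export
write_variant_table <- function(variants, path) {
  write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_variant_table
#' @export
read_variant_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = NA)
}

#' Write / read a rate table as TSV
#' @param rate_table a `rate_table`.
#' @param path file path.
#' @export
write_rate_table <- function(rate_table, path) {
  df <- as.data.frame(rate_table)
  attr_line <- sprintf("# window_size=%d",
                       attr(rate_table, "window_size") %||% 100000L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(attr_line, con)
  suppressWarnings(
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' @rdname write_rate_table
#' @export
read_rate_table <- function(path) {
  first <- readLines(path, n = 1L)
  ws <- as.integer(sub("# window_size=", "", first))
  df <- read.table(path, header = TRUE, sep = "\t", skip = 1L,
                   stringsAsFactors = FALSE)
  attr(df, "window_size") <- ws
  class(df) <- c("rate_table", "data.frame")
  df
}
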
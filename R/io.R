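#' Read and write genome sequences
#'
#' Thin wrappers around Biostrings keeping the package's internal genome
#' representation — a named character vector of contig sequences — at the
#' interface.
#'
#' @param path File path.
#' @param genome Named character vector of contig sequences.
#' @return `read_fasta()` returns a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(unlist(genome))
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read and write simulated RNA-seq reads
#'
#' One FASTQ file per library; read identifiers are preserved.  Simulated
#' reads are error-free, so a constant maximal base quality is written.
#'
#' @param reads `data.frame` with `read_id` and `seq`.
#' @param path File path.
#' @param library_id Library the file belongs to.
#' @return `read_fastq()` returns a `data.frame` with `read_id`,
#'   `library_id`, `seq`.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq")
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path, library_id = NA_character_) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             library_id = library_id,
             seq = as.character(x), stringsAsFactors = FALSE)
}

#' Write parental SNP records as VCF
#'
#' Emits a minimal VCF v4.2 with one sample column carrying
#' `GT:DP:AO` (genotype, depth, alternate observations).  Haploid (drone)
#' genotypes are written unphased single-allele (`0` / `1`), diploid
#' (queen) genotypes as `0/0`, `0/1`, `1/1`.
#'
#' @param records SNP record `data.frame` (see [snp_records()]).
#' @param path Output path.
#' @param sample_name Sample column header.
#' @export
write_snp_vcf <- function(records, path, sample_name = "parent") {
  validate_snp_records(records)
  records <- sort_snps(records)
  gt <- ifelse(records$ploidy == 2L,
               c(hom_ref = "0/0", het = "0/1",
                 hom_alt = "1/1")[records$genotype],
               c(hom_ref = "0", hom_alt = "1")[records$genotype])
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AO,Number=1,Type=Integer,Description=\"Alternate observations\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_name),
    paste(records$contig, records$pos, ".", records$ref, records$alt,
          format(records$qual, trim = TRUE), ".", ".", "GT:DP:AO",
          paste(gt, records$depth, records$alt_obs, sep = ":"),
          sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read parental SNP records from VCF
#'
#' Parses a VCF (via vcfR) into the package's SNP record table.  Ploidy is
#' inferred from the genotype field: single-allele calls are haploid.
#' Multi-allelic rows are split into one record per alternate allele
#' beforehand by vcfR's representation (comma-separated ALT) and here.
#'
#' @param path VCF path.
#' @param ploidy Optional override (1 or 2) when the genotype field is
#'   absent.
#' @return SNP record `data.frame`.
#' @export
read_snp_vcf <- function(path, ploidy = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")[, 1]
  dp <- suppressWarnings(as.integer(vcfR::extract.gt(v, element = "DP")[, 1]))
  ao <- suppressWarnings(as.integer(vcfR::extract.gt(v, element = "AO")[, 1]))

  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    gt <- gt_raw[i]
    alleles <- strsplit(gsub("\\|", "/", gt), "/", fixed = FALSE)[[1]]
    pl <- if (!is.null(ploidy)) as.integer(ploidy) else length(alleles)
    geno <- if (all(alleles == "0")) "hom_ref"
            else if (all(alleles != "0")) "hom_alt" else "het"
    data.frame(contig = fix$CHROM[i], pos = as.integer(fix$POS[i]),
               ref = fix$REF[i], alt = alts,
               qual = as.numeric(fix$QUAL[i]),
               depth = dp[i], alt_obs = ao[i],
               genotype = geno, ploidy = pl, stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rows)
  rec$depth[is.na(rec$depth)] <- 0L
  rec$alt_obs[is.na(rec$alt_obs)] <- 0L
  validate_snp_records(rec)
  rec
}

#' Read and write gene models as BED
#'
#' BED is 0-based half-open; the package uses the same convention
#' internally for gene models (`start` 0-based inclusive, `end`
#' exclusive).  Backed by rtracklayer, which handles the 1-based
#' conversion of the GRanges representation.
#'
#' @param models `data.frame` with `contig`, `start` (0-based), `end`
#'   (exclusive), `gene_id`.
#' @param path File path.
#' @return `read_gene_bed()` returns a gene model `data.frame`.
#' @export
write_gene_bed <- function(models, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = models$contig,
    ranges = IRanges::IRanges(start = models$start + 1L, end = models$end),
    name = models$gene_id)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_gene_bed
#' @export
read_gene_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             gene_id = gr$name, stringsAsFactors = FALSE)
}

#' TSV helpers used for all tabular artifacts
#'
#' @param x A `data.frame`.
#' @param path File path.
#' @return `read_tsv_table()` returns a `data.frame`.
#' @export
write_tsv_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
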
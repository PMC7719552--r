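#' Create a table of parental SNP records
#'
#' Light constructor/validator for the variant table consumed by the
#' filtering stage.  One row per biallelic SNP call in one parent.
#'
#' @param contig,pos Contig name and 1-based position.
#' @param ref,alt Reference and alternate alleles (single bases).
#' @param qual Phred-scaled call quality.
#' @param depth,alt_obs Total read depth and reads supporting the alternate.
#' @param genotype One of `"hom_ref"`, `"het"`, `"hom_alt"`.
#' @param ploidy 1 (drone/haploid father) or 2 (queen/diploid mother).
#' @return A `data.frame` of SNP records.
#' @export
snp_records <- function(contig, pos, ref, alt, qual, depth, alt_obs,
                        genotype, ploidy) {
  rec <- data.frame(contig = as.character(contig), pos = as.integer(pos),
                    ref = toupper(ref), alt = toupper(alt),
                    qual = as.numeric(qual), depth = as.integer(depth),
                    alt_obs = as.integer(alt_obs),
                    genotype = as.character(genotype),
                    ploidy = as.integer(ploidy), stringsAsFactors = FALSE)
  validate_snp_records(rec)
  rec
}

validate_snp_records <- function(rec) {
  req <- c("contig", "pos", "ref", "alt", "qual", "depth", "alt_obs",
           "genotype", "ploidy")
  miss <- setdiff(req, names(rec))
  if (length(miss))
    stop("SNP record table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(rec$alt_obs > rec$depth))
    stop("alt_obs may not exceed depth", call. = FALSE)
  bad <- rec$ploidy == 1L & !rec$genotype %in% c("hom_ref", "hom_alt")
  if (any(bad))
    stop("haploid records must be hom_ref or hom_alt", call. = FALSE)
  if (!all(rec$genotype %in% c("hom_ref", "het", "hom_alt")))
    stop("genotype must be hom_ref, het or hom_alt", call. = FALSE)
  invisible(rec)
}

#' Filter SNP records on quality, coverage and alternate-allele support
#'
#' Retains records with `qual >= min_qual`, `depth >= min_depth` and
#' `alt_obs >= min_alt_obs`, preserving input order.  The defaults are the
#' variant-calling thresholds of the reciprocal-cross pipeline: quality 20,
#' five reads of coverage, two alternate-allele observations.
#'
#' @param records SNP record `data.frame` (see [snp_records()]).
#' @param min_qual,min_depth,min_alt_obs Non-negative thresholds.
#' @return The retained subset, order preserved.
#' @examples
#' r <- snp_records("c1", 1:2, "A", "T", c(19.9, 30), 10, 5, "hom_alt", 2)
#' filter_snps(r)  # drops the qual-19.9 record
#' @export
filter_snps <- function(records, min_qual = 20, min_depth = 5,
                        min_alt_obs = 2) {
  validate_snp_records(records)
  if (min_qual < 0 || min_depth < 0 || min_alt_obs < 0)
    stop("thresholds must be non-negative", call. = FALSE)
  keep <- records$qual >= min_qual & records$depth >= min_depth &
    records$alt_obs >= min_alt_obs
  records[keep, , drop = FALSE]
}

#' Keep only homozygous-alternate queen SNPs
#'
#' The diploid mother contributes a single known allele to every offspring
#' only where she is homozygous for the alternate allele, so heterozygous
#' and homozygous-reference calls are dropped before the parent-unique
#' subtraction.
#'
#' @param records Diploid (queen) SNP records.
#' @return The `genotype == "hom_alt"` subset.
#' @export
select_queen_homalt <- function(records) {
  validate_snp_records(records)
  if (any(records$ploidy == 1L))
    stop("select_queen_homalt expects diploid (queen) records; ",
         "got ploidy-1 rows", call. = FALSE)
  records[records$genotype == "hom_alt", , drop = FALSE]
}

#' Parent-unique informative SNPs by positional subtraction
#'
#' A SNP site is informative when exactly one parent carries the alternate
#' allele there: an offspring read covering it can then be assigned to that
#' parent.  Performs set subtraction on (contig, pos) in both directions
#' and labels each surviving site with its parent of origin, the allele
#' that parent transmits (`parent_allele`, the alternate) and the allele
#' the other parent transmits (`other_allele`, the reference).
#'
#' @param parent_a,parent_b SNP records of the two parents, position-sorted
#'   per contig (unsorted input is sorted with a warning).
#' @param parent_a_role,parent_b_role Labels, by default `"maternal"` and
#'   `"paternal"`.
#' @return List with elements `a_unique` and `b_unique`, each a
#'   `data.frame` (`contig`, `pos`, `parent`, `parent_allele`,
#'   `other_allele`) sorted by contig then position.
#' @export
unique_snps <- function(parent_a, parent_b,
                        parent_a_role = "maternal",
                        parent_b_role = "paternal") {
  validate_snp_records(parent_a)
  validate_snp_records(parent_b)
  parent_a <- sort_snps(parent_a)
  parent_b <- sort_snps(parent_b)
  key_a <- paste(parent_a$contig, parent_a$pos)
  key_b <- paste(parent_b$contig, parent_b$pos)
  list(
    a_unique = informative_from(parent_a[!key_a %in% key_b, , drop = FALSE],
                                parent_a_role),
    b_unique = informative_from(parent_b[!key_b %in% key_a, , drop = FALSE],
                                parent_b_role)
  )
}

informative_from <- function(rec, role) {
  out <- data.frame(contig = rec$contig, pos = rec$pos,
                    parent = rep(role, nrow(rec)),
                    parent_allele = rec$alt, other_allele = rec$ref,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (any(out$parent_allele == out$other_allele))
    stop("informative SNP with identical ref and alt alleles", call. = FALSE)
  out
}

sort_snps <- function(rec) {
  ord <- order(rec$contig, rec$pos)
  if (!identical(ord, seq_len(nrow(rec)))) {
    warning("SNP records were not position-sorted; sorting internally",
            call. = FALSE)
  }
  out <- rec[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Substitute informative SNP alleles into a reference genome
#'
#' Builds a parental alternate genome: the returned sequences equal the
#' reference except that `parent_allele` replaces the base at each SNP
#' position.  Substitutions are single-base, so contig lengths are
#' preserved and the operation is idempotent.
#'
#' @param reference Named character vector of contig sequences
#'   (see [read_fasta()]).
#' @param snps Informative SNP `data.frame` (`contig`, `pos` 1-based,
#'   `parent_allele`), e.g. one element of [unique_snps()].
#' @return Named character vector, same names and lengths as `reference`.
#' @examples
#' apply_snps(c(c1 = "ACGT"),
#'            data.frame(contig = "c1", pos = 3, parent_allele = "T"))
#' @export
apply_snps <- function(reference, snps) {
  stopifnot(is.character(reference), !is.null(names(reference)))
  if (nrow(snps) == 0) return(reference)
  if (any(nchar(snps$parent_allele) != 1L))
    stop("unsupported variant: only single-base substitutions are allowed",
         call. = FALSE)
  if (!all(toupper(snps$parent_allele) %in% c("A", "C", "G", "T", "N")))
    stop("alleles must be A/C/G/T/N", call. = FALSE)
  genome <- reference
  for (ct in unique(snps$contig)) {
    if (!ct %in% names(genome))
      stop("SNP on unknown contig '", ct, "'", call. = FALSE)
    sub <- snps[snps$contig == ct, , drop = FALSE]
    len <- nchar(genome[[ct]])
    bad <- sub$pos < 1L | sub$pos > len
    if (any(bad))
      stop("SNP position out of range on contig '", ct, "': pos ",
           paste(sub$pos[bad], collapse = ", "), " (length ", len, ")",
           call. = FALSE)
    chars <- strsplit(genome[[ct]], "", fixed = TRUE)[[1]]
    chars[sub$pos] <- toupper(sub$parent_allele)
    genome[[ct]] <- paste(chars, collapse = "")
  }
  genome
}
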
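#' Assign reads to parental alleles by zero-mismatch matching
#'
#' Desk-scale surrogate for aligning against the two parental alternate
#' genomes with zero mismatches allowed: each read is matched exactly
#' (no mismatches, no gaps) against both genomes.  Because the genomes
#' differ only at informative SNP positions, a read overlapping at least
#' one informative SNP matches exactly one genome and is assigned to that
#' parent; a read matching both genomes covers no informative SNP and is
#' discarded, as are reads matching neither genome or matching at several
#' loci (repeat-like ambiguity, mirroring unique-mapping behaviour).
#'
#' @param reads `data.frame` with `read_id`, `library_id`, `seq`.
#' @param maternal_genome,paternal_genome Named character vectors of the
#'   same contigs/lengths (alternate builds of one reference).
#' @param informative Informative SNP table (`contig`, `pos` 1-based,
#'   `parent`) from [unique_snps()] (both parents' sites combined).
#' @return `data.frame` with `read_id`, `library_id`, `contig`, `start`
#'   (0-based), `end` (exclusive), `parent`, `snps_covered`
#'   (comma-separated `contig:pos` ids).  Attribute `"audit"` holds the
#'   per-reason discard tally; assigned + discarded = input reads.
#' @export
assign_reads <- function(reads, maternal_genome, paternal_genome,
                         informative) {
  stopifnot(identical(sort(names(maternal_genome)),
                      sort(names(paternal_genome))))
  n <- nrow(reads)
  if (n == 0) {
    out <- data.frame(read_id = character(), library_id = character(),
                      contig = character(), start = integer(),
                      end = integer(), parent = character(),
                      snps_covered = character(), stringsAsFactors = FALSE)
    attr(out, "audit") <- c(assigned = 0L, matches_both = 0L,
                            ambiguous = 0L, unmatched = 0L, too_long = 0L)
    return(out)
  }

  max_len <- max(nchar(unlist(maternal_genome)))
  too_long <- nchar(reads$seq) > max_len
  if (any(too_long))
    message(sum(too_long), " read(s) longer than any contig; discarded")

  valid <- grepl("^[ACGT]+$", reads$seq)
  hits <- function(genome, seqs) {
    # per read: number of exact matches and the (contig, start) of one
    cnt <- integer(length(seqs)); ctg <- rep(NA_character_, length(seqs))
    pos <- rep(NA_integer_, length(seqs))
    for (w in unique(nchar(seqs[valid]))) {
      idx <- which(nchar(seqs) == w & valid)
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs[idx]))
      for (ct in names(genome)) {
        if (w > nchar(genome[[ct]])) next
        mi <- Biostrings::matchPDict(pd, Biostrings::DNAString(genome[[ct]]))
        nm <- S4Vectors::elementNROWS(mi)
        hit <- which(nm > 0)
        cnt[idx] <- cnt[idx] + nm
        first <- vapply(hit, function(h) IRanges::start(mi[[h]])[1], 1L)
        newly <- is.na(pos[idx[hit]])
        ctg[idx[hit][newly]] <- ct
        pos[idx[hit][newly]] <- first[newly]
      }
    }
    list(count = cnt, contig = ctg, start1 = pos)
  }

  hm <- hits(maternal_genome, reads$seq)
  hp <- hits(paternal_genome, reads$seq)

  status <- rep("unmatched", n)
  status[hm$count >= 1 & hp$count >= 1] <- "matches_both"
  status[hm$count == 1 & hp$count == 0] <- "maternal"
  status[hp$count == 1 & hm$count == 0] <- "paternal"
  status[(hm$count > 1 & hp$count == 0) |
           (hp$count > 1 & hm$count == 0)] <- "ambiguous"
  status[too_long] <- "too_long"

  keep <- status %in% c("maternal", "paternal")
  ctg <- ifelse(status == "maternal", hm$contig, hp$contig)[keep]
  st1 <- ifelse(status == "maternal", hm$start1, hp$start1)[keep]
  width <- nchar(reads$seq)[keep]
  snp_key <- paste0(informative$contig, ":", informative$pos)

  covered <- vapply(seq_along(st1), function(i) {
    in_span <- informative$contig == ctg[i] &
      informative$pos >= st1[i] & informative$pos <= st1[i] + width[i] - 1L
    paste(snp_key[in_span], collapse = ",")
  }, "")

  out <- data.frame(read_id = reads$read_id[keep],
                    library_id = reads$library_id[keep],
                    contig = ctg, start = st1 - 1L, end = st1 - 1L + width,
                    parent = status[keep], snps_covered = covered,
                    stringsAsFactors = FALSE)
  # a one-genome match must overlap a differing (informative) site
  empty <- out$snps_covered == ""
  if (any(empty)) {
    status[keep][empty] <- "matches_both"
    out <- out[!empty, , drop = FALSE]
  }
  attr(out, "audit") <- c(
    assigned = nrow(out),
    matches_both = sum(status == "matches_both"),
    ambiguous = sum(status == "ambiguous"),
    unmatched = sum(status == "unmatched"),
    too_long = sum(status == "too_long"))
  out
}

#' Tally assigned reads per SNP and per gene
#'
#' Annotates each covered informative SNP with the gene model containing
#' it (SNPs outside any gene are dropped) and produces the SNP-level and
#' gene-level allelic count views.  A read covering k > 1 informative SNPs
#' of the same gene increments each SNP's row, but by default counts once
#' in the gene-level totals (read deduplication avoids pseudo-replication
#' in the per-gene model); `dedup = FALSE` sums the SNP rows instead.
#'
#' @param assignments Output of [assign_reads()].
#' @param gene_models Non-overlapping gene models (`contig`, `start`
#'   0-based, `end` exclusive, `gene_id`).
#' @param dedup Count each read once per gene (default) or once per
#'   covered SNP.
#' @return List with `snp` (`gene_id`, `snp_id`, `library_id`, `maternal`,
#'   `paternal`) and `gene` (`gene_id`, `library_id`, `maternal`,
#'   `paternal`, `n_snps`) tables.
#' @export
count_by_snp <- function(assignments, gene_models, dedup = TRUE) {
  check_nonoverlapping(gene_models)
  empty_snp <- data.frame(gene_id = character(), snp_id = character(),
                          library_id = character(), maternal = integer(),
                          paternal = integer(), stringsAsFactors = FALSE)
  empty_gene <- data.frame(gene_id = character(), library_id = character(),
                           maternal = integer(), paternal = integer(),
                           n_snps = integer(), stringsAsFactors = FALSE)
  if (nrow(assignments) == 0) return(list(snp = empty_snp, gene = empty_gene))

  snp_list <- strsplit(assignments$snps_covered, ",", fixed = TRUE)
  nrep <- lengths(snp_list)
  long <- data.frame(
    read_id = rep(assignments$read_id, nrep),
    library_id = rep(assignments$library_id, nrep),
    parent = rep(assignments$parent, nrep),
    snp_id = unlist(snp_list), stringsAsFactors = FALSE)
  sp <- strsplit(long$snp_id, ":", fixed = TRUE)
  long$contig <- vapply(sp, `[`, "", 1L)
  long$pos <- as.integer(vapply(sp, `[`, "", 2L))

  long$gene_id <- snp_gene(long$contig, long$pos, gene_models)
  long <- long[!is.na(long$gene_id), , drop = FALSE]
  if (nrow(long) == 0) return(list(snp = empty_snp, gene = empty_gene))

  key <- list(gene_id = long$gene_id, snp_id = long$snp_id,
              library_id = long$library_id)
  snp_tab <- aggregate(list(maternal = long$parent == "maternal",
                            paternal = long$parent == "paternal"), key, sum)
  snp_tab$maternal <- as.integer(snp_tab$maternal)
  snp_tab$paternal <- as.integer(snp_tab$paternal)
  snp_tab <- snp_tab[order(snp_tab$gene_id, snp_tab$snp_id,
                           snp_tab$library_id), , drop = FALSE]
  rownames(snp_tab) <- NULL

  if (dedup) {
    # one increment per read per gene, regardless of SNPs spanned
    rd <- unique(long[c("read_id", "library_id", "parent", "gene_id")])
    gkey <- list(gene_id = rd$gene_id, library_id = rd$library_id)
    gene_tab <- aggregate(list(maternal = rd$parent == "maternal",
                               paternal = rd$parent == "paternal"),
                          gkey, sum)
  } else {
    gkey <- list(gene_id = snp_tab$gene_id, library_id = snp_tab$library_id)
    gene_tab <- aggregate(snp_tab[c("maternal", "paternal")], gkey, sum)
  }
  gene_tab$maternal <- as.integer(gene_tab$maternal)
  gene_tab$paternal <- as.integer(gene_tab$paternal)
  nsnp <- aggregate(list(n_snps = long$snp_id),
                    list(gene_id = long$gene_id,
                         library_id = long$library_id),
                    function(s) length(unique(s)))
  gene_tab <- merge(gene_tab, nsnp, by = c("gene_id", "library_id"))
  gene_tab <- gene_tab[order(gene_tab$gene_id, gene_tab$library_id), ,
                       drop = FALSE]
  rownames(gene_tab) <- NULL
  list(snp = snp_tab, gene = gene_tab)
}

snp_gene <- function(contig, pos, gene_models) {
  out <- rep(NA_character_, length(pos))
  for (i in seq_len(nrow(gene_models))) {
    gm <- gene_models[i, ]
    hit <- contig == gm$contig & pos > gm$start & pos <= gm$end
    out[hit] <- gm$gene_id
  }
  out
}

check_nonoverlapping <- function(gene_models) {
  for (ct in unique(gene_models$contig)) {
    gm <- gene_models[gene_models$contig == ct, , drop = FALSE]
    gm <- gm[order(gm$start), , drop = FALSE]
    if (nrow(gm) > 1 && any(gm$start[-1] < gm$end[-nrow(gm)]))
      stop("gene models overlap on contig '", ct, "'", call. = FALSE)
  }
  invisible(gene_models)
}

#' Remove SNPs with zero maternal reads in any library
#'
#' A queen site miscalled as homozygous, with the missing allele matching
#' the drone's, inflates paternal counts; the guard removes any SNP whose
#' maternal count is zero in at least one library — from all libraries.
#' A missing (SNP, library) row counts as zero.
#'
#' @param table SNP-level allelic count table.
#' @param libraries Libraries the experiment comprises; defaults to those
#'   present in `table`.
#' @return The filtered SNP-level table.
#' @export
drop_zero_maternal_snps <- function(table,
                                    libraries = unique(table$library_id)) {
  if (nrow(table) == 0) return(table)
  pos <- table$maternal > 0
  n_pos <- tapply(pos, table$snp_id, sum)
  keep_snps <- names(n_pos)[n_pos == length(libraries)]
  out <- table[table$snp_id %in% keep_snps, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes analyzable for parent-of-origin expression
#'
#' Returns the gene universe: genes with at least `min_snps` surviving
#' SNPs and nonzero allelic data in every family-by-direction cell of the
#' design (i.e. observed in both cross directions and both replicate
#' families).
#'
#' @param table SNP-level allelic count table (after SNP filtering).
#' @param design Design table covering every family x direction cell.
#' @param min_snps Minimum surviving SNPs per gene.
#' @return Sorted character vector of gene ids.
#' @export
gene_universe <- function(table, design, min_snps = 2) {
  validate_design(design)
  if (length(unique(design$direction)) < 2 ||
      length(unique(design$family)) < 2)
    stop("design lacks a family x direction cell: both directions and ",
         "at least two families are required", call. = FALSE)
  if (nrow(table) == 0) return(character())
  nsnp <- tapply(table$snp_id, table$gene_id,
                 function(s) length(unique(s)))
  cand <- names(nsnp)[nsnp >= min_snps]

  cell <- paste(design$family, design$direction)
  lib_cell <- setNames(cell, design$library_id)
  n_cells <- length(unique(cell))
  tab <- table[table$gene_id %in% cand &
                 (table$maternal + table$paternal) > 0, , drop = FALSE]
  tab$cell <- lib_cell[tab$library_id]
  cov <- tapply(tab$cell, tab$gene_id, function(x) length(unique(x)))
  sort(names(cov)[cov == n_cells])
}

#' Replace zero paternal totals by one
#'
#' A gene-library observation with zero paternal reads causes complete
#' separation in the logistic model; the count is set to 1 (maternal
#' counts untouched).  Deliberately asymmetric, as in the original
#' analysis: the symmetric maternal case is handled upstream by
#' [drop_zero_maternal_snps()].
#'
#' @param gene_view Gene-level count table (`maternal`, `paternal`).
#' @return Same table with substitutions applied; attribute
#'   `"substituted"` gives the flagged row indices.
#' @export
substitute_paternal_zero <- function(gene_view) {
  flagged <- which(gene_view$paternal == 0)
  gene_view$paternal[flagged] <- 1L
  attr(gene_view, "substituted") <- flagged
  gene_view
}
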
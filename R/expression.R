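#' Compute TPM and log2(TPM+1) expression profiles
#'
#' Transcripts-per-kilobase-million normalization: each gene's raw count is
#' divided by its effective length (the union-exonic length in bases), and
#' the resulting per-base rates are rescaled to sum to one million across
#' the sample, so profiles are comparable across libraries of different
#' depth. `log2(TPM + 1)` is reported alongside for plotting-scale use.
#'
#' @param rows data.frame with columns `gene_id`, `count` (raw reads
#'   assigned to the gene, >= 0) and `effective_length` (bases, > 0).
#' @param sample_id Sample label carried as an attribute.
#' @return A data.frame of class `expression_profile` with columns
#'   `gene_id`, `tpm`, `log2_tpm1`. TPM values sum to 1e6 (exactly, up to
#'   floating point) unless all counts are zero, in which case all TPM are
#'   zero and a warning is raised.
#' @examples
#' compute_tpm(data.frame(gene_id = c("a", "b"), count = c(100, 100),
#'                        effective_length = c(1000, 2000)))
#' @export
compute_tpm <- function(rows, sample_id = "sample") {
  need <- c("gene_id", "count", "effective_length")
  stopifnot(is.data.frame(rows), all(need %in% names(rows)), nrow(rows) >= 1L)
  if (any(rows$count < 0)) stop("raw counts must be >= 0")
  if (any(rows$effective_length <= 0)) stop("effective_length must be > 0")
  rate <- rows$count / rows$effective_length
  total <- sum(rate)
  if (total == 0) {
    warning("all counts are zero; TPM normalization undefined, returning 0",
            call. = FALSE)
    tpm <- rep(0, nrow(rows))
  } else {
    tpm <- rate * 1e6 / total
  }
  structure(data.frame(gene_id = rows$gene_id, tpm = tpm,
                       log2_tpm1 = log2(tpm + 1),
                       stringsAsFactors = FALSE),
            sample_id = sample_id,
            class = c("expression_profile", "data.frame"))
}

#' Count reads per flattened exon bin
#'
#' DEXSeq-count style bin counting: a record increments a bin when any of
#' its aligned reference blocks overlaps the bin by at least one base; a
#' record spanning several bins increments each of them, but each bin at
#' most once per record (no fractional assignment). Skipped (`N`) regions
#' do not overlap anything, so a read spanning the exclusion junction of a
#' cassette increments the flanking bins only. Relative usage is the bin's
#' share of its gene's summed bin counts, a within-gene composition that is
#' invariant to the gene's expression level.
#'
#' @param input Path to a SAM-dialect text file or character vector of
#'   alignment lines.
#' @param bins Bin table from [flatten_exon_bins()] (tables for several
#'   genes may be row-bound; bins must be disjoint within a gene).
#' @param sample_id Sample label.
#' @return A data.frame of class `exon_bin_counts` with the bin table plus
#'   `count` and `relative_usage` columns (usage `NA` for genes with zero
#'   total counts). Attribute `gene_totals` holds summed bin counts per
#'   gene; attribute `n_records` the number of primary mapped records.
#' @export
count_exon_bins <- function(input, bins, sample_id = "sample") {
  stopifnot(is.data.frame(bins),
            all(c("bin_id", "gene_id", "chrom", "start", "end") %in%
                  names(bins)))
  rec <- read_sam_records(input)
  counts <- integer(nrow(bins))
  if (nrow(rec) > 0 && nrow(bins) > 0) {
    blocks <- cigar_ref_blocks(rec$cigar, rec$pos, rec$qname)
    nb <- vapply(blocks, nrow, 1L)
    blk <- do.call(rbind, blocks)
    blk_read <- rep.int(seq_len(nrow(rec)), nb)
    binr <- IRanges::IRanges(bins$start, bins$end)
    qryr <- IRanges::IRanges(blk[, 1L], blk[, 2L])
    hits <- IRanges::findOverlaps(qryr, binr)
    if (length(hits)) {
      qh <- S4Vectors::queryHits(hits)
      bh <- S4Vectors::subjectHits(hits)
      same_chrom <- rec$rname[blk_read[qh]] == bins$chrom[bh]
      pairs <- unique(cbind(read = blk_read[qh][same_chrom],
                            bin = bh[same_chrom]))
      tab <- tabulate(pairs[, "bin"], nbins = nrow(bins))
      counts <- as.integer(tab)
    }
  }
  out <- bins
  out$count <- counts
  totals <- tapply(out$count, out$gene_id, sum)
  out$relative_usage <- ifelse(totals[out$gene_id] > 0,
                               out$count / as.numeric(totals[out$gene_id]),
                               NA_real_)
  structure(out,
            sample_id = sample_id,
            gene_totals = totals,
            n_records = nrow(rec),
            class = c("exon_bin_counts", "data.frame"))
}

#' Compare relative exon usage between two samples
#'
#' Descriptive per-bin comparison of relative exon usage between two
#' conditions (e.g. fibroblasts versus induced neurons). A pseudocount of
#' 0.5 is added to every raw bin count before forming the compared usages,
#' so bins unobserved in one condition yield finite log ratios; genes with
#' zero total counts in either condition are flagged.
#'
#' @param a,b [count_exon_bins()] tables over the same bin set.
#' @return A data.frame with per-bin columns `bin_id`, `gene_id`,
#'   `usage_a`, `usage_b` (raw relative usages), `usage_a_ps`, `usage_b_ps`
#'   (pseudocounted), `log2_ratio` (`log2(usage_a_ps / usage_b_ps)`), and
#'   `zero_gene_flag` (`TRUE` where either condition has no reads for the
#'   gene).
#' @export
compare_exon_usage <- function(a, b) {
  stopifnot(inherits(a, "exon_bin_counts"), inherits(b, "exon_bin_counts"))
  if (!identical(a$bin_id, b$bin_id))
    stop("bin sets differ between the two tables")
  ps_usage <- function(x) {
    cnt <- x$count + 0.5
    tot <- tapply(cnt, x$gene_id, sum)
    cnt / as.numeric(tot[x$gene_id])
  }
  ua <- ps_usage(a)
  ub <- ps_usage(b)
  zero_a <- attr(a, "gene_totals") == 0
  zero_b <- attr(b, "gene_totals") == 0
  data.frame(bin_id = a$bin_id, gene_id = a$gene_id,
             usage_a = a$relative_usage, usage_b = b$relative_usage,
             usage_a_ps = ua, usage_b_ps = ub,
             log2_ratio = log2(ua / ub),
             zero_gene_flag = as.logical(zero_a[a$gene_id] |
                                           zero_b[a$gene_id]),
             stringsAsFactors = FALSE)
}
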
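#' Junction count tables
#'
#' A `junction_counts` object is a data.frame with one row per exon-exon
#' junction observed in a sample: columns `chrom`, `donor` (last exonic base
#' of the upstream exon in ascending genomic order), `acceptor` (first exonic
#' base of the downstream exon), `strand`, `count` (raw junction-spanning
#' reads) and, after [normalize_depth()], `normalized` (reads per million).
#' Attributes `sample_id` and `library_size` record provenance.
#'
#' @param counts data.frame with columns `chrom`, `donor`, `acceptor`,
#'   `strand`, `count`.
#' @param sample_id Sample label.
#' @param library_size Total counted reads in the sample (used by
#'   [normalize_depth()]).
#' @return A `junction_counts` object.
#' @export
junction_counts <- function(counts, sample_id = "sample",
                            library_size = NA_real_) {
  need <- c("chrom", "donor", "acceptor", "strand", "count")
  stopifnot(is.data.frame(counts), all(need %in% names(counts)))
  if (any(counts$count < 0)) stop("raw junction counts must be >= 0")
  if (any(counts$donor >= counts$acceptor))
    stop("junction donor must be < acceptor (ascending genomic order)")
  if (!is.na(library_size) && library_size <= 0 && any(counts$count > 0))
    stop("library_size must be > 0 when any count is > 0")
  structure(as.data.frame(counts), sample_id = sample_id,
            library_size = library_size,
            class = c("junction_counts", "data.frame"))
}

#' @export
print.junction_counts <- function(x, ...) {
  cat(sprintf("junction_counts: sample '%s', %d junctions, library size %s\n",
              attr(x, "sample_id"), nrow(x),
              format(attr(x, "library_size"))))
  print.data.frame(x, ...)
  invisible(x)
}

## --- SAM-dialect parsing -------------------------------------------------

# Parse alignment strings into reference-space blocks. Returns a list per
# record of integer matrices (start, end); consecutive blocks are separated
# by N (skip) operations. Reference-consuming ops: M, D, N, =, X.
cigar_ref_blocks <- function(cigar, pos, qname = NULL) {
  out <- vector("list", length(cigar))
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))
  for (i in seq_along(cigar)) {
    tk <- toks[[i]]
    if (!length(tk) || paste(tk, collapse = "") != cigar[i])
      stop("malformed alignment string '", cigar[i], "'",
           if (!is.null(qname)) paste0(" in record '", qname[i], "'"))
    len <- as.integer(sub(".$", "", tk))
    op <- substring(tk, nchar(tk))
    ref <- pos[i]
    bstart <- pos[i]
    blocks <- NULL
    for (j in seq_along(op)) {
      o <- op[j]
      if (o %in% c("M", "D", "=", "X")) {
        ref <- ref + len[j]
      } else if (o == "N") {
        blocks <- rbind(blocks, c(bstart, ref - 1L))
        ref <- ref + len[j]
        bstart <- ref
      }
      # I, S, H, P do not consume reference
    }
    blocks <- rbind(blocks, c(bstart, ref - 1L))
    out[[i]] <- blocks
  }
  out
}

# Read SAM-dialect text (path or character vector of lines) into the fields
# needed for counting. Unmapped (0x4), secondary (0x100) and supplementary
# (0x800) records are dropped.
read_sam_records <- function(input) {
  lines <- if (length(input) == 1L && file.exists(input))
    readLines(input) else input
  lines <- lines[!startsWith(lines, "@")]
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(qname = character(), rname = character(),
                      pos = integer(), cigar = character(),
                      stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11L))
    stop("malformed alignment record (fewer than 11 fields): ",
         lines[which(nf < 11L)[1L]])
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  keep <- bitwAnd(flag, 0x4L + 0x100L + 0x800L) == 0L
  f <- f[keep]
  out <- data.frame(qname = vapply(f, `[[`, "", 1L),
                    rname = vapply(f, `[[`, "", 3L),
                    pos = as.integer(vapply(f, `[[`, "", 4L)),
                    cigar = vapply(f, `[[`, "", 6L),
                    stringsAsFactors = FALSE)
  bad <- !grepl("^([0-9]+[MIDNSHP=X])+$", out$cigar)
  if (any(bad))
    stop("malformed alignment string '", out$cigar[bad][1L],
         "' in record '", out$qname[bad][1L], "'")
  out
}

#' Count junction-spanning reads in spliced alignments
#'
#' Scans SAM-dialect alignment records and, for every skip (`N`) operation,
#' increments the junction defined by the last aligned reference base before
#' the skip (donor) and the first aligned base after it (acceptor), provided
#' both flanking aligned blocks are at least `min_anchor` reference bases
#' long. A record with several skips increments each junction independently.
#' Unmapped, secondary and supplementary records are skipped; the library
#' size is the number of primary mapped records processed.
#'
#' @param input Path to a SAM-dialect text file, or a character vector of
#'   alignment lines (header lines beginning `@` are ignored).
#' @param min_anchor Minimum aligned block length on each side of a skip for
#'   the junction to be counted (default 1: any overhang counts).
#' @param sample_id Sample label for the resulting table.
#' @return A [junction_counts()] table of all junctions discovered, ordered
#'   by chromosome and position, with `library_size` set. Empty input yields
#'   an empty table with library size 0.
#' @examples
#' rec <- "r1\t0\tchr1\t101\t255\t30M100N45M\t*\t0\t0\t*\t*"
#' extract_junctions(rec)   # one junction: donor 130, acceptor 231
#' @export
extract_junctions <- function(input, min_anchor = 1L, sample_id = "sample") {
  stopifnot(min_anchor >= 1L)
  rec <- read_sam_records(input)
  lib <- nrow(rec)
  spliced <- grepl("N", rec$cigar, fixed = TRUE)
  keys <- character()
  if (any(spliced)) {
    sub <- rec[spliced, , drop = FALSE]
    blocks <- cigar_ref_blocks(sub$cigar, sub$pos, sub$qname)
    keys <- unlist(lapply(seq_along(blocks), function(i) {
      b <- blocks[[i]]
      w <- b[, 2L] - b[, 1L] + 1L
      n <- nrow(b)
      ok <- w[-n] >= min_anchor & w[-1L] >= min_anchor
      if (!any(ok)) return(character())
      sprintf("%s\t%d\t%d", sub$rname[i], b[-n, 2L][ok], b[-1L, 1L][ok])
    }))
  }
  if (length(keys)) {
    tab <- table(keys)
    parts <- strsplit(names(tab), "\t", fixed = TRUE)
    df <- data.frame(chrom = vapply(parts, `[[`, "", 1L),
                     donor = as.integer(vapply(parts, `[[`, "", 2L)),
                     acceptor = as.integer(vapply(parts, `[[`, "", 3L)),
                     strand = "*",
                     count = as.integer(tab),
                     stringsAsFactors = FALSE)
    df <- df[order(df$chrom, df$donor, df$acceptor), , drop = FALSE]
    rownames(df) <- NULL
  } else {
    df <- data.frame(chrom = character(), donor = integer(),
                     acceptor = integer(), strand = character(),
                     count = integer(), stringsAsFactors = FALSE)
  }
  junction_counts(df, sample_id = sample_id, library_size = lib)
}

#' Read a junction count table from disk
#'
#' Supported dialects:
#' \describe{
#'   \item{`plain_tsv`}{Columns `chrom`, `donor`, `acceptor`, `strand`,
#'     `count` (header optional); positions are exonic flanks.}
#'   \item{`star_sj`}{The 9-column splice-junction table a spliced aligner
#'     emits (chrom, intron first base, intron last base, strand code 0/1/2,
#'     motif, annotated, unique reads, multimapped reads, max overhang);
#'     intron-boundary positions are converted to exonic flanks
#'     (start-1, end+1) and the unique-read column is used as the count.}
#'   \item{`jcounts`}{A featureCounts-style junction count table with
#'     `Site1_chr`/`Site1_location`/`Site2_chr`/`Site2_location` columns and
#'     one trailing count column; locations taken as exonic flanks.}
#' }
#'
#' @param path File path.
#' @param dialect One of `"plain_tsv"`, `"star_sj"`, `"jcounts"`.
#' @param sample_id Sample label.
#' @param library_size Library size to attach (these formats do not carry
#'   one); `NA` leaves it unset.
#' @return A [junction_counts()] table keyed by normalized (ascending)
#'   junction coordinates.
#' @export
read_junction_table <- function(path,
                                dialect = c("plain_tsv", "star_sj", "jcounts"),
                                sample_id = "sample",
                                library_size = NA_real_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("junction table not found: ", path)
  df <- switch(dialect,
    plain_tsv = {
      first <- utils::read.delim(path, header = FALSE, nrows = 1L,
                                 stringsAsFactors = FALSE)
      has_header <- is.na(suppressWarnings(as.numeric(first[[2L]])))
      x <- utils::read.delim(path, header = has_header,
                             stringsAsFactors = FALSE)
      if (ncol(x) < 5L) stop("plain_tsv dialect needs 5 columns ",
                             "(chrom, donor, acceptor, strand, count)")
      names(x)[1:5] <- c("chrom", "donor", "acceptor", "strand", "count")
      x[, 1:5]
    },
    star_sj = {
      x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
      if (ncol(x) < 7L) stop("star_sj dialect needs >= 7 columns")
      data.frame(chrom = x[[1L]],
                 donor = x[[2L]] - 1L,
                 acceptor = x[[3L]] + 1L,
                 strand = c("*", "+", "-")[x[[4L]] + 1L],
                 count = x[[7L]], stringsAsFactors = FALSE)
    },
    jcounts = {
      x <- utils::read.delim(path, stringsAsFactors = FALSE)
      need <- c("Site1_chr", "Site1_location", "Site2_chr", "Site2_location")
      if (!all(need %in% names(x)))
        stop("jcounts dialect needs columns ", paste(need, collapse = ", "))
      if (any(x$Site1_chr != x$Site2_chr))
        stop("jcounts rows spanning chromosomes are not junctions")
      cnt <- x[[ncol(x)]]
      lo <- pmin(x$Site1_location, x$Site2_location)
      hi <- pmax(x$Site1_location, x$Site2_location)
      data.frame(chrom = x$Site1_chr, donor = lo, acceptor = hi,
                 strand = if ("Site1_strand" %in% names(x))
                   x$Site1_strand else "*",
                 count = cnt, stringsAsFactors = FALSE)
    })
  if (!is.numeric(df$donor) || !is.numeric(df$acceptor) ||
      anyNA(df$donor) || anyNA(df$acceptor))
    stop("junction table '", path, "': position columns must be integer")
  df$donor <- as.integer(df$donor)
  df$acceptor <- as.integer(df$acceptor)
  df$count <- as.numeric(df$count)
  junction_counts(df, sample_id = sample_id, library_size = library_size)
}

#' Write a junction count table as plain TSV
#'
#' @param table A [junction_counts()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_junction_table <- function(table, path) {
  stopifnot(inherits(table, "junction_counts"))
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize junction counts for sequencing depth
#'
#' Adds a `normalized` column of reads-per-million values,
#' `count * 1e6 / library_size`. Raw counts are untouched; the cassette
#' usage percentage is invariant to this rescaling (it is a ratio of counts
#' within one sample), so normalization matters only for cross-sample
#' comparison of individual junctions.
#'
#' @param table A [junction_counts()] table.
#' @param library_size Override for the table's `library_size` attribute.
#' @return The table with a `normalized` column and its `library_size`
#'   attribute set.
#' @export
normalize_depth <- function(table, library_size = NULL) {
  stopifnot(inherits(table, "junction_counts"))
  ls <- library_size %||% attr(table, "library_size")
  if (is.null(ls) || is.na(ls) || ls <= 0)
    stop("library_size must be > 0 (got ", format(ls), ")")
  table$normalized <- table$count * 1e6 / ls
  attr(table, "library_size") <- ls
  table
}
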
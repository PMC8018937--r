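# Independent brute-force oracles and random-instance generators used by the
# unit and acceptance tests. These deliberately avoid the package's own code
# paths wherever they check one.

# Per-base labelling oracle for exon-bin flattening: label every exonic base
# with its set of contributing isoforms, then merge maximal runs of identical
# label into bins.
oracle_flatten <- function(model) {
  maxpos <- max(vapply(model$isoforms, function(e) max(e$end), 0L))
  lab <- rep("", maxpos)
  for (nm in names(model$isoforms)) {
    ex <- model$isoforms[[nm]]
    for (i in seq_len(nrow(ex))) {
      idx <- ex$start[i]:ex$end[i]
      lab[idx] <- paste(lab[idx], nm, sep = "|")
    }
  }
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != ""
  data.frame(start = starts[keep], end = ends[keep],
             contributing = vapply(strsplit(sub("^\\|", "", r$values[keep]),
                                            "|", fixed = TRUE),
                                   function(v) paste(sort(v),
                                                     collapse = ","), ""),
             stringsAsFactors = FALSE)
}

# Random gene models (no events) for flattening properties: up to 5
# isoforms, exons within [1, 2000], >= 1 intronic base between exons of an
# isoform.
random_gene_model <- function(seed) {
  set.seed(seed)
  n_iso <- sample(1:5, 1)
  isoforms <- lapply(seq_len(n_iso), function(i) {
    pos <- 1L
    exons <- NULL
    repeat {
      pos <- pos + sample(1:120, 1)          # intron / leading gap
      w <- sample(1:150, 1)
      if (pos + w - 1L > 2000L) break
      exons <- rbind(exons, c(pos, pos + w - 1L))
      pos <- pos + w
      if (nrow(exons) >= sample(2:6, 1) && stats::runif(1) < 0.4) break
    }
    if (is.null(exons)) exons <- matrix(c(1L, 50L), ncol = 2)
    exons
  })
  names(isoforms) <- paste0("iso", seq_len(n_iso))
  gene_model(paste0("RND", seed), "rnd_chr", "+", isoforms = isoforms)
}

# Brute-force exon-bin counting: for every record, test every aligned block
# against every bin; a record increments a bin at most once. Blocks come
# from GenomicAlignments (an independent CIGAR implementation).
oracle_count_bins <- function(sam_lines, bins) {
  blocks <- ga_blocks(sam_lines)
  counts <- integer(nrow(bins))
  for (b in blocks) {
    hit <- rep(FALSE, nrow(bins))
    for (j in seq_len(nrow(b))) {
      hit <- hit | (bins$chrom == b$chrom[j] &
                      bins$start <= b$end[j] & bins$end >= b$start[j])
    }
    counts <- counts + hit
  }
  counts
}

sam_to_bam <- function(sam_lines) {
  sam <- tempfile(fileext = ".sam")
  writeLines(sam_lines, sam)
  Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                   indexDestination = FALSE)
}

# Per-read aligned reference blocks via GenomicAlignments.
ga_blocks <- function(sam_lines) {
  ga <- GenomicAlignments::readGAlignments(sam_to_bam(sam_lines))
  grl <- GenomicAlignments::grglist(ga)
  lapply(seq_along(grl), function(i) {
    g <- grl[[i]]
    data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
               start = GenomicRanges::start(g),
               end = GenomicRanges::end(g), stringsAsFactors = FALSE)
  })
}

# Junction counts via GenomicAlignments::junctions() (min_anchor = 1
# semantics: every skip counts). Returns a data.frame keyed like
# extract_junctions output.
ga_junction_counts <- function(sam_lines) {
  ga <- GenomicAlignments::readGAlignments(sam_to_bam(sam_lines))
  j <- unlist(GenomicAlignments::junctions(ga))
  if (!length(j))
    return(data.frame(chrom = character(), donor = integer(),
                      acceptor = integer(), count = integer()))
  key <- paste(as.character(GenomicRanges::seqnames(j)),
               GenomicRanges::start(j) - 1L, GenomicRanges::end(j) + 1L,
               sep = "\t")
  tab <- table(key)
  parts <- strsplit(names(tab), "\t", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[[`, "", 1L),
                    donor = as.integer(vapply(parts, `[[`, "", 2L)),
                    acceptor = as.integer(vapply(parts, `[[`, "", 3L)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out[order(out$chrom, out$donor, out$acceptor), , drop = FALSE]
}

# A second cassette model whose 30-base cassette is shorter than typical
# read lengths, so single reads span both inclusion junctions (double-skip
# alignments).
short_cassette_model <- function() {
  gene_model("SHORTCAS", "toy_chr", "+",
             isoforms = list(
               sc_3R = rbind(c(1, 200), c(401, 700)),
               sc_4R = rbind(c(1, 200), c(301, 330), c(401, 700))),
             events = list(SC_4R = cassette_event(
               "SC_4R",
               inclusion = rbind(c(200, 301), c(330, 401)),
               exclusion = c(200, 401))))
}

# Random simulation configurations for extractor-ledger equivalence.
random_sim_config <- function(seed, max_reads = 5000) {
  set.seed(seed + 977)
  model <- if (seed %% 2 == 0) gene_model_fixture("toy")
           else short_cassette_model()
  iso <- names(model$isoforms)
  f <- stats::runif(1, 0, 1)
  props <- stats::setNames(c(f, 1 - f), rev(iso))  # 4R name sorts second
  read_length <- sample(40:90, 1)
  min_anchor <- sample(1:min(10, read_length %/% 2), 1)
  sim_config(model = model, proportions = props,
             n_reads = sample(100:max_reads, 1),
             read_length = read_length, min_anchor = min_anchor,
             seed = seed,
             depth_mode = if (seed %% 3 == 0) "poisson" else "fixed")
}

expect_same_junctions <- function(a, b) {
  a <- as.data.frame(a)[, c("chrom", "donor", "acceptor", "count")]
  b <- as.data.frame(b)[, c("chrom", "donor", "acceptor", "count")]
  a <- a[a$count > 0, ]; b <- b[b$count > 0, ]
  a <- a[order(a$chrom, a$donor, a$acceptor), ]
  b <- b[order(b$chrom, b$donor, b$acceptor), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
}
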
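#' Construct a per-gene splicing model
#'
#' A `gene_model` holds one gene's exon structure (per isoform), strand, and
#' named cassette events described by their inclusion and exclusion junctions.
#' All coordinates are 1-based inclusive genomic positions, stored in ascending
#' order regardless of strand; the strand field records orientation.
#'
#' @param gene_id Stable gene identifier (e.g. an Ensembl gene id).
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param isoforms Named list; each element a two-column matrix or data.frame
#'   of exon `start`, `end` positions (1-based inclusive, ascending).
#' @param events Named list of cassette events, each created by
#'   [cassette_event()]. May be empty.
#'
#' @return An object of class `gene_model` with fields `gene_id`, `chrom`,
#'   `strand`, `isoforms` (named list of data.frames with columns
#'   `start`, `end`), `events`, and `effective_length` (the size in bases of
#'   the union of all isoform exons).
#'
#' @details Within an isoform exons must be sorted, non-overlapping, and
#' separated by at least one intronic base. Every event junction flank must
#' coincide with an exon boundary of at least one isoform: the donor position
#' is the last exonic base of the upstream exon in ascending genomic order,
#' the acceptor position the first exonic base of the downstream exon.
#'
#' @seealso [read_gene_model()], [flatten_exon_bins()], [gene_model_fixture()]
#' @export
gene_model <- function(gene_id, chrom, strand = c("+", "-"),
                       isoforms = list(), events = list()) {
  strand <- match.arg(strand)
  stopifnot(is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id),
            is.character(chrom), length(chrom) == 1L, nzchar(chrom))
  if (length(isoforms) && is.null(names(isoforms)))
    stop("isoforms must be a named list")
  isoforms <- lapply(isoforms, as_exon_table)
  validate_exons(isoforms)
  m <- structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         isoforms = isoforms, events = events,
         effective_length = exon_union_length(isoforms)),
    class = "gene_model")
  validate_gene_model(m)
}

as_exon_table <- function(x) {
  if (is.matrix(x)) x <- as.data.frame(x)
  if (is.list(x) && !is.data.frame(x))
    x <- as.data.frame(do.call(rbind, lapply(x, as.numeric)))
  stopifnot(ncol(x) >= 2L)
  out <- data.frame(start = as.integer(x[[1L]]), end = as.integer(x[[2L]]))
  out[order(out$start), , drop = FALSE]
}

exon_union_length <- function(isoforms) {
  if (!length(isoforms)) return(0L)
  all <- do.call(rbind, isoforms)
  r <- IRanges::reduce(IRanges::IRanges(all$start, all$end))
  sum(IRanges::width(r))
}

validate_exons <- function(isoforms) {
  for (nm in names(isoforms)) {
    ex <- isoforms[[nm]]
    if (any(ex$start > ex$end))
      stop("isoform '", nm, "': exon start > end")
    if (any(ex$start < 1L))
      stop("isoform '", nm, "': positions must be >= 1")
    if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)] + 1L))
      stop("isoform '", nm,
           "': exons must be non-overlapping with >= 1 intronic base between them")
  }
  invisible(isoforms)
}

validate_gene_model <- function(m) {
  validate_exons(m$isoforms)
  ends <- unlist(lapply(m$isoforms, function(e) e$end), use.names = FALSE)
  starts <- unlist(lapply(m$isoforms, function(e) e$start), use.names = FALSE)
  for (ev in m$events) {
    stopifnot(inherits(ev, "cassette_event"))
    jx <- rbind(ev$inclusion, ev$exclusion)
    for (i in seq_len(nrow(jx))) {
      if (!(jx$donor[i] %in% ends))
        stop("event '", ev$name, "': donor position ", jx$donor[i],
             " is not the last base of any exon")
      if (!(jx$acceptor[i] %in% starts))
        stop("event '", ev$name, "': acceptor position ", jx$acceptor[i],
             " is not the first base of any exon")
    }
  }
  m
}

#' Define a cassette-exon event by its junctions
#'
#' A cassette event is described by the junctions that evidence inclusion of
#' the cassette exon (two junctions for a single cassette: upstream-cassette
#' and cassette-downstream) and the single junction that evidences skipping.
#' For the MAPT exon-10 event these are the X(9,10) and X(10,11) inclusion
#' junctions and the X(9,11) exclusion junction.
#'
#' @param name Event label, e.g. `"MAPT_4R"`.
#' @param inclusion Two-column matrix/data.frame of `donor`, `acceptor`
#'   positions, one row per inclusion junction, ascending genomic order
#'   (donor < acceptor).
#' @param exclusion Length-2 vector (or one-row table) with the exclusion
#'   junction's donor and acceptor positions.
#' @return An object of class `cassette_event`.
#' @export
cassette_event <- function(name, inclusion, exclusion) {
  inc <- as_junction_table(inclusion)
  exc <- as_junction_table(exclusion)
  stopifnot(nrow(inc) >= 1L, nrow(exc) == 1L)
  jx <- rbind(inc, exc)
  if (any(jx$donor >= jx$acceptor))
    stop("event '", name, "': junction donor must be < acceptor (gap >= 1 base)")
  if (any(inc$donor == exc$donor & inc$acceptor == exc$acceptor))
    stop("event '", name, "': exclusion junction duplicates an inclusion junction")
  structure(list(name = name, inclusion = inc, exclusion = exc),
            class = "cassette_event")
}

as_junction_table <- function(x) {
  if (is.numeric(x) && is.null(dim(x))) x <- matrix(x, ncol = 2L, byrow = TRUE)
  if (is.matrix(x)) x <- as.data.frame(x)
  if (is.list(x) && !is.data.frame(x))
    x <- as.data.frame(do.call(rbind, lapply(x, as.numeric)))
  data.frame(donor = as.integer(x[[1L]]), acceptor = as.integer(x[[2L]]))
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model:", x$gene_id, sprintf("(%s, %s strand)\n", x$chrom, x$strand))
  cat("  isoforms:",
      paste(sprintf("%s [%d exons]", names(x$isoforms),
                    vapply(x$isoforms, nrow, 1L)), collapse = ", "), "\n")
  cat("  effective length:", x$effective_length, "bases\n")
  for (ev in x$events) {
    cat("  event", ev$name, "- inclusion:",
        paste(sprintf("(%d,%d)", ev$inclusion$donor, ev$inclusion$acceptor),
              collapse = " "),
        sprintf("exclusion: (%d,%d)\n", ev$exclusion$donor, ev$exclusion$acceptor))
  }
  invisible(x)
}

#' Read a gene model from a YAML model file
#'
#' The model file is a YAML document with fields `gene_id`, `chrom`, `strand`,
#' `isoforms` (name -> list of `[start, end]` exon pairs) and `events`
#' (name -> `inclusion` list of `[donor, acceptor]` pairs plus a single
#' `exclusion` pair). Junction positions are exonic flanks (last base of the
#' upstream exon, first base of the downstream exon); set
#' `dialect_shift = TRUE` for files whose junction positions follow the
#' intron-boundary convention (first/last intronic base), which shifts them
#' outward by one base onto the flanking exons.
#'
#' @param path Path to the YAML model file.
#' @param dialect_shift Logical; shift junction coordinates from
#'   intron-boundary to exonic-flank convention.
#' @return A validated [gene_model()].
#' @export
read_gene_model <- function(path, dialect_shift = FALSE) {
  if (!file.exists(path)) stop("model file not found: ", path)
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("malformed model file '", path,
                                           "': ", conditionMessage(e)))
  for (f in c("gene_id", "chrom", "strand", "isoforms"))
    if (is.null(doc[[f]])) stop("model file '", path, "': missing field '", f, "'")
  shift <- function(tab) {
    if (dialect_shift) {
      tab$donor <- tab$donor - 1L
      tab$acceptor <- tab$acceptor + 1L
    }
    tab
  }
  events <- lapply(names(doc$events %||% list()), function(nm) {
    ev <- doc$events[[nm]]
    if (is.null(ev$inclusion) || is.null(ev$exclusion))
      stop("model file '", path, "': event '", nm,
           "' needs 'inclusion' and 'exclusion' fields")
    cassette_event(nm,
                   shift(as_junction_table(ev$inclusion)),
                   shift(as_junction_table(ev$exclusion)))
  })
  names(events) <- names(doc$events %||% list())
  gene_model(doc$gene_id, doc$chrom, doc$strand,
             isoforms = doc$isoforms, events = events)
}

#' Write a gene model to a YAML model file
#'
#' Inverse of [read_gene_model()] (exonic-flank junction convention);
#' reading the written file back yields an identical model.
#'
#' @param model A [gene_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_model <- function(model, path) {
  stopifnot(inherits(model, "gene_model"))
  doc <- list(
    gene_id = model$gene_id,
    chrom = model$chrom,
    strand = model$strand,
    isoforms = lapply(model$isoforms, function(ex)
      lapply(seq_len(nrow(ex)), function(i) c(ex$start[i], ex$end[i]))),
    events = lapply(model$events, function(ev) list(
      inclusion = lapply(seq_len(nrow(ev$inclusion)), function(i)
        c(ev$inclusion$donor[i], ev$inclusion$acceptor[i])),
      exclusion = c(ev$exclusion$donor[1L], ev$exclusion$acceptor[1L]))))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Import a gene model from GFF3 exon lines plus an event table
#'
#' @param gff_path GFF3 file whose exon features carry a `Parent` attribute
#'   naming the isoform (transcript).
#' @param events_path TSV with columns `event`, `role` (`inclusion` or
#'   `exclusion`), `chrom`, `donor`, `acceptor`, `strand`; positions in the
#'   exonic-flank convention unless `dialect_shift = TRUE`.
#' @param gene_id Gene identifier for the resulting model.
#' @inheritParams read_gene_model
#' @return A validated [gene_model()].
#' @export
read_gene_model_gff <- function(gff_path, events_path, gene_id,
                                dialect_shift = FALSE) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("GFF3 import requires the rtracklayer package")
  gr <- rtracklayer::import(gff_path)
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  if (!length(gr)) stop("no exon features in ", gff_path)
  parent <- vapply(gr$Parent, function(p) as.character(p)[1L], "")
  chrom <- as.character(GenomicRanges::seqnames(gr))[1L]
  strand <- as.character(GenomicRanges::strand(gr))[1L]
  if (!strand %in% c("+", "-")) strand <- "+"
  isoforms <- lapply(split(seq_along(gr), parent), function(i)
    data.frame(start = GenomicRanges::start(gr)[i],
               end = GenomicRanges::end(gr)[i]))
  ev <- utils::read.delim(events_path, stringsAsFactors = FALSE)
  need <- c("event", "role", "chrom", "donor", "acceptor")
  if (!all(need %in% names(ev)))
    stop("event table '", events_path, "': needs columns ",
         paste(need, collapse = ", "))
  if (!is.numeric(ev$donor) || !is.numeric(ev$acceptor))
    stop("event table '", events_path, "': donor/acceptor must be integer")
  if (dialect_shift) {
    ev$donor <- ev$donor - 1L
    ev$acceptor <- ev$acceptor + 1L
  }
  events <- lapply(split(ev, ev$event), function(e) {
    cassette_event(e$event[1L],
                   e[e$role == "inclusion", c("donor", "acceptor")],
                   e[e$role == "exclusion", c("donor", "acceptor")])
  })
  gene_model(gene_id, chrom, strand, isoforms = isoforms, events = events)
}

#' Packaged gene-model fixtures
#'
#' Ships the porcine and human MAPT exon 9/10/11 cassette models (junction
#' flank coordinates at the annotated exon edges on Sscrofa11.1 chr12 and
#' GRCh38 chr17; outer exon edges are nominal) and a small synthetic
#' cassette gene used throughout the test-bench: three exons on a toy
#' chromosome, the middle one a 93-base cassette mirroring the MAPT exon-10
#' repeat region, flanked by 300-base constitutive exons.
#'
#' @param name One of `"pig_mapt"`, `"human_mapt"`, `"toy"`.
#' @return A validated [gene_model()].
#' @examples
#' m <- gene_model_fixture("toy")
#' flatten_exon_bins(m)
#' @export
gene_model_fixture <- function(name = c("pig_mapt", "human_mapt", "toy")) {
  name <- match.arg(name)
  path <- system.file("extdata",
                      paste0(name, ifelse(name == "toy", "_maptlike", ""),
                             ".yaml"),
                      package = "spliceq", mustWork = TRUE)
  read_gene_model(path)
}

#' Flatten a gene model into disjoint exon counting bins
#'
#' Splits the union of all isoform exons at every isoform-exon boundary,
#' producing maximal disjoint intervals over which the set of contributing
#' isoforms is constant. These are the counting units for exon-usage
#' profiling (the flattened bins a DEXSeq-count style counter uses).
#'
#' @param model A [gene_model()].
#' @return A data.frame with one row per bin, ordered by genomic coordinate:
#'   `bin_id` (`gene_id:E001`, ...), `gene_id`, `chrom`, `start`, `end`,
#'   `contributing_isoforms` (comma-joined isoform names). Zero rows for a
#'   model with no isoforms.
#' @export
flatten_exon_bins <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  if (!length(model$isoforms))
    return(data.frame(bin_id = character(), gene_id = character(),
                      chrom = character(),
                      start = integer(), end = integer(),
                      contributing_isoforms = character(),
                      stringsAsFactors = FALSE))
  iso_ranges <- lapply(model$isoforms, function(ex)
    IRanges::IRanges(ex$start, ex$end))
  bins <- IRanges::disjoin(do.call(c, unname(iso_ranges)))
  contrib <- vapply(seq_along(bins), function(i) {
    hit <- vapply(iso_ranges, function(r)
      any(IRanges::overlapsAny(bins[i], r)), NA)
    paste(names(model$isoforms)[hit], collapse = ",")
  }, "")
  data.frame(
    bin_id = sprintf("%s:E%03d", model$gene_id, seq_along(bins)),
    gene_id = model$gene_id,
    chrom = model$chrom,
    start = IRanges::start(bins),
    end = IRanges::end(bins),
    contributing_isoforms = contrib,
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
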
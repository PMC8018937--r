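#' Configure a spliced-read simulation
#'
#' Describes an isoform-mixture simulation for a cassette-exon gene:
#' uniform-coverage single-end reads of fixed length drawn from a pool of
#' transcript molecules with known molar isoform proportions. A read's
#' isoform is drawn with probability proportional to
#' `proportion * (transcript_length - read_length + 1)` — every valid read
#' start across the transcript pool is equally likely — and its start is
#' uniform over the isoform's valid start positions. Under this model the
#' junction-usage statistic of [compute_usage()] is an unbiased transform
#' of the inclusion fraction f, with expected usage `100 f / (1 - f)`.
#'
#' @param model A [gene_model()] (default: the packaged toy cassette gene).
#' @param proportions Named vector of molar isoform fractions summing to 1;
#'   names must match the model's isoforms. Default `f = 0.148` inclusion
#'   (the adult-scale 4R fraction) against `0.852` exclusion.
#' @param n_reads Total reads (fixed) or Poisson mean (see `depth_mode`).
#' @param read_length Read length in bases (default 75, shorter than the
#'   93-base cassette so the two inclusion junctions are spanned by
#'   different reads at the default length).
#' @param min_anchor Minimum aligned bases on each side of a junction for a
#'   read to be entered in the truth ledger (and to be counted by
#'   [extract_junctions()] at the same setting).
#' @param seed Integer seed; all outputs are deterministic given the seed.
#' @param depth_mode `"fixed"` (exactly `n_reads`) or `"poisson"`
#'   (`Poisson(n_reads)` total).
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(model = gene_model_fixture("toy"),
                       proportions = c(toy_4R = 0.148, toy_3R = 0.852),
                       n_reads = 1e5, read_length = 75L, min_anchor = 1L,
                       seed = 1L, depth_mode = c("fixed", "poisson")) {
  depth_mode <- match.arg(depth_mode)
  stopifnot(inherits(model, "gene_model"), n_reads >= 0,
            read_length >= 2L * min_anchor, min_anchor >= 1L)
  if (is.null(names(proportions)) ||
      !all(names(proportions) %in% names(model$isoforms)))
    stop("proportions must be named after the model's isoforms")
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-12)
    stop("proportions must be non-negative and sum to 1 (within 1e-12)")
  for (nm in names(proportions)) {
    L <- transcript_length(model, nm)
    if (L < read_length)
      stop("isoform '", nm, "' transcript (", L,
           " bases) is shorter than the read length")
  }
  structure(list(model = model, proportions = proportions,
                 n_reads = n_reads, read_length = as.integer(read_length),
                 min_anchor = as.integer(min_anchor),
                 seed = as.integer(seed), depth_mode = depth_mode),
            class = "sim_config")
}

transcript_length <- function(model, isoform) {
  ex <- model$isoforms[[isoform]]
  sum(ex$end - ex$start + 1L)
}

# Transcript-coordinate junction positions (last base of each exon but the
# final one) and the corresponding genomic donor/acceptor flanks.
isoform_junctions <- function(model, isoform) {
  ex <- model$isoforms[[isoform]]
  if (nrow(ex) < 2L)
    return(data.frame(tx_pos = integer(), donor = integer(),
                      acceptor = integer()))
  w <- ex$end - ex$start + 1L
  data.frame(tx_pos = cumsum(w)[-nrow(ex)],
             donor = ex$end[-nrow(ex)],
             acceptor = ex$start[-1L])
}

# Number of valid read starts that span the junction at transcript position
# p with both anchors >= a, clipped to the valid-start range.
crossing_window <- function(p, L, r, a) {
  lo <- max(1L, p + a - r + 1L)
  hi <- min(L - r + 1L, p - a + 1L)
  max(0L, hi - lo + 1L)
}

# Read-assignment weights: molar proportion times number of valid starts.
isoform_weights <- function(config) {
  w <- vapply(names(config$proportions), function(nm)
    config$proportions[[nm]] *
      (transcript_length(config$model, nm) - config$read_length + 1L), 0)
  w / sum(w)
}

# Expected junction-spanning read counts per junction for a given total
# read count, under the uniform-coverage pool model.
expected_junction_counts <- function(config, n = config$n_reads) {
  r <- config$read_length
  a <- config$min_anchor
  wts <- isoform_weights(config)
  rows <- do.call(rbind, lapply(names(config$proportions), function(nm) {
    jx <- isoform_junctions(config$model, nm)
    if (!nrow(jx)) return(NULL)
    L <- transcript_length(config$model, nm)
    data.frame(isoform = nm, donor = jx$donor, acceptor = jx$acceptor,
               expected = n * wts[[nm]] *
                 vapply(jx$tx_pos, crossing_window, 0L, L = L, r = r,
                        a = a) / (L - r + 1L),
               stringsAsFactors = FALSE)
  }))
  agg <- stats::aggregate(expected ~ donor + acceptor, data = rows, FUN = sum)
  agg[order(agg$donor, agg$acceptor), , drop = FALSE]
}

# Expected usage percentage for each event of the model, from the expected
# junction counts (equals 100 f / (1 - f) when no crossing window is
# clipped by a transcript end).
expected_usage_percent <- function(config) {
  ej <- expected_junction_counts(config, n = 1)
  get <- function(d, acc) {
    v <- ej$expected[ej$donor == d & ej$acceptor == acc]
    if (!length(v)) 0 else v
  }
  vapply(config$model$events, function(ev) {
    exc <- get(ev$exclusion$donor[1L], ev$exclusion$acceptor[1L])
    inc <- mean(mapply(get, ev$inclusion$donor, ev$inclusion$acceptor))
    if (exc == 0) NA_real_ else 100 * inc / exc
  }, 0)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate spliced reads from an isoform mixture
#'
#' Draws reads under the uniform-coverage pool model of [sim_config()],
#' emits them as SAM-dialect alignment records against a generated toy
#' reference sequence, and returns a ground-truth ledger of every junction
#' each read spans with both anchors at least `min_anchor` bases — exactly
#' the counts [extract_junctions()] must recover at the same setting.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_reads`: `reference` (named character,
#'   chromosome sequence), `sam` (character vector: header plus one line
#'   per read), and `truth`, a `sim_truth` list with `isoform_counts`,
#'   `junction_ledger` (chrom/donor/acceptor/strand/count),
#'   `expected_usage_percent` (per event), `n_reads`, and `seed`.
#' @export
simulate_reads <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  model <- config$model
  r <- config$read_length
  a <- config$min_anchor
  with_seed(config$seed, {
    n <- if (config$depth_mode == "poisson")
      stats::rpois(1L, config$n_reads) else as.integer(config$n_reads)
    iso_names <- names(config$proportions)
    wts <- isoform_weights(config)
    iso <- if (n > 0)
      sample(iso_names, n, replace = TRUE, prob = wts) else character()

    chrom_len <- max(vapply(model$isoforms, function(e) max(e$end), 0L)) +
      100L
    ref_seq <- paste(sample(c("A", "C", "G", "T"), chrom_len,
                            replace = TRUE), collapse = "")

    sam <- character(n)
    ledger_keys <- vector("list", n)
    for (nm in iso_names) {
      idx <- which(iso == nm)
      if (!length(idx)) next
      ex <- model$isoforms[[nm]]
      w <- ex$end - ex$start + 1L
      cum <- cumsum(w)
      L <- cum[length(cum)]
      jx <- isoform_junctions(model, nm)
      starts <- sample.int(L - r + 1L, length(idx), replace = TRUE)
      for (k in seq_along(idx)) {
        s <- starts[k]
        e <- s + r - 1L
        first <- findInterval(s - 1L, cum) + 1L
        last <- findInterval(e - 1L, cum) + 1L
        lo_tx <- c(0L, cum)[first:last] + 1L
        hi_tx <- cum[first:last]
        o_lo <- pmax(s, lo_tx)
        o_hi <- pmin(e, hi_tx)
        g_lo <- ex$start[first:last] + (o_lo - lo_tx)
        g_hi <- ex$start[first:last] + (o_hi - lo_tx)
        lens <- o_hi - o_lo + 1L
        cigar <- paste0(lens[1L], "M")
        if (last > first) {
          gaps <- g_lo[-1L] - g_hi[-length(g_hi)] - 1L
          cigar <- paste0(paste0(lens[-length(lens)], "M", gaps, "N",
                                 collapse = ""),
                          lens[length(lens)], "M")
        }
        seqs <- substring(ref_seq, g_lo, g_hi)
        sam[idx[k]] <- paste(sprintf("read%06d", idx[k]), 0L, model$chrom,
                             g_lo[1L], 255L, cigar, "*", 0L, 0L,
                             paste(seqs, collapse = ""),
                             paste(rep("I", r), collapse = ""),
                             sep = "\t")
        if (nrow(jx)) {
          inside <- which(jx$tx_pos >= s & jx$tx_pos <= e - 1L)
          if (length(inside)) {
            # aligned-block anchors: a junction's flanks are bounded by the
            # neighbouring junctions inside the read, not just the read ends
            p <- jx$tx_pos[inside]
            left_anchor <- p - c(s - 1L, p[-length(p)])
            right_anchor <- c(p[-1L], e) - p
            ok <- left_anchor >= a & right_anchor >= a
            if (any(ok))
              ledger_keys[[idx[k]]] <- sprintf("%d\t%d",
                                               jx$donor[inside][ok],
                                               jx$acceptor[inside][ok])
          }
        }
      }
    }
    keys <- unlist(ledger_keys)
    ledger <- if (length(keys)) {
      tab <- table(keys)
      parts <- strsplit(names(tab), "\t", fixed = TRUE)
      df <- data.frame(chrom = model$chrom,
                       donor = as.integer(vapply(parts, `[[`, "", 1L)),
                       acceptor = as.integer(vapply(parts, `[[`, "", 2L)),
                       strand = "*", count = as.integer(tab),
                       stringsAsFactors = FALSE)
      df <- df[order(df$chrom, df$donor, df$acceptor), , drop = FALSE]
      rownames(df) <- NULL
      df
    } else {
      data.frame(chrom = character(), donor = integer(),
                 acceptor = integer(), strand = character(),
                 count = integer(), stringsAsFactors = FALSE)
    }
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", model$chrom, chrom_len))
    truth <- structure(list(
      isoform_counts = vapply(iso_names, function(x) sum(iso == x), 0L),
      junction_ledger = ledger,
      expected_usage_percent = expected_usage_percent(config),
      n_reads = n,
      seed = config$seed), class = "sim_truth")
    structure(list(reference = stats::setNames(ref_seq, model$chrom),
                   sam = c(header, sam), truth = truth),
              class = "sim_reads")
  })
}

#' Simulate a junction count table directly
#'
#' Fast path for statistical tests: skips read generation and draws the
#' junction-spanning counts from their exact sampling distribution under
#' the uniform-coverage pool model — per-isoform read totals are
#' multinomial over the pool weights, and each junction's count is binomial
#' over its isoform's reads with the exact crossing probability implied by
#' the read length, anchors and exon lengths.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_junction_table`: `table` (a
#'   [junction_counts()] object, library size = total reads) and `truth`
#'   (`sim_truth` as in [simulate_reads()], with per-junction expected
#'   counts in `expected_junctions`).
#' @export
simulate_junction_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  model <- config$model
  r <- config$read_length
  a <- config$min_anchor
  with_seed(config$seed, {
    n <- if (config$depth_mode == "poisson")
      stats::rpois(1L, config$n_reads) else as.integer(config$n_reads)
    iso_names <- names(config$proportions)
    wts <- isoform_weights(config)
    n_iso <- if (n > 0)
      as.integer(stats::rmultinom(1L, n, wts)) else integer(length(wts))
    names(n_iso) <- iso_names
    rows <- do.call(rbind, lapply(iso_names, function(nm) {
      jx <- isoform_junctions(model, nm)
      if (!nrow(jx)) return(NULL)
      L <- transcript_length(model, nm)
      p <- vapply(jx$tx_pos, crossing_window, 0L, L = L, r = r, a = a) /
        (L - r + 1L)
      data.frame(donor = jx$donor, acceptor = jx$acceptor,
                 count = stats::rbinom(nrow(jx), n_iso[[nm]], p))
    }))
    agg <- stats::aggregate(count ~ donor + acceptor, data = rows,
                            FUN = sum)
    agg <- agg[order(agg$donor, agg$acceptor), , drop = FALSE]
    df <- data.frame(chrom = model$chrom, donor = agg$donor,
                     acceptor = agg$acceptor, strand = "*",
                     count = agg$count, stringsAsFactors = FALSE)
    truth <- structure(list(
      isoform_counts = n_iso,
      expected_junctions = expected_junction_counts(config, n = n),
      expected_usage_percent = expected_usage_percent(config),
      n_reads = n,
      seed = config$seed), class = "sim_truth")
    structure(list(table = junction_counts(df, sample_id = "simulated",
                                           library_size = max(n, 1L)),
                   truth = truth),
              class = "sim_junction_table")
  })
}

#' Simulate qPCR Cq tables from known quantities
#'
#' Forward model of the standard-curve assay: each well's Cq is
#' `intercept + slope * log10(quantity)` plus Gaussian noise, and a
#' dilution-series table is emitted from the same curve, so the full
#' [qpcr_quantify()] pipeline can be checked against the generating truth
#' (exactly when `sigma = 0`).
#'
#' @param quantities data.frame with columns `sample_id`, `target`,
#'   `quantity` (> 0): the true relative template amounts.
#' @param slope Curve slope in Cq per log10(amount); must be < 0 (default
#'   `-1/log10(2)` = -3.321928, perfect doubling).
#' @param intercept Cq at log10(amount) = 0 (default 25). Either a single
#'   value or a named vector per target.
#' @param sigma Gaussian Cq noise s.d. (>= 0).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param dilution_factors Dilution series for the standard curve.
#' @param n_replicates Technical replicates per well (default 3).
#' @return A list: `cq_table` (`sample_id`, `target`, `replicate`, `cq`),
#'   `dilution_table` (`target`, `dilution_factor`, `replicate`, `cq`),
#'   and `truth` (the inputs echoed).
#' @export
simulate_qpcr <- function(quantities, slope = -1 / log10(2), intercept = 25,
                          sigma = 0, seed = NULL,
                          dilution_factors = c(1, 0.5, 0.25, 0.125),
                          n_replicates = 3L) {
  stopifnot(is.data.frame(quantities),
            all(c("sample_id", "target", "quantity") %in% names(quantities)))
  if (any(quantities$quantity <= 0)) stop("quantities must be > 0")
  if (slope >= 0) stop("slope must be < 0")
  if (sigma < 0) stop("sigma must be >= 0")
  icpt <- function(target) {
    if (length(intercept) == 1L && is.null(names(intercept)))
      intercept else intercept[[target]]
  }
  with_seed(seed, {
    cq <- do.call(rbind, lapply(seq_len(nrow(quantities)), function(i) {
      data.frame(sample_id = quantities$sample_id[i],
                 target = quantities$target[i],
                 replicate = seq_len(n_replicates),
                 cq = icpt(quantities$target[i]) +
                   slope * log10(quantities$quantity[i]) +
                   stats::rnorm(n_replicates, 0, sigma),
                 stringsAsFactors = FALSE)
    }))
    targets <- unique(quantities$target)
    dil <- do.call(rbind, lapply(targets, function(tg) {
      do.call(rbind, lapply(dilution_factors, function(d) {
        data.frame(target = tg, dilution_factor = d,
                   replicate = seq_len(n_replicates),
                   cq = icpt(tg) + slope * log10(d) +
                     stats::rnorm(n_replicates, 0, sigma),
                   stringsAsFactors = FALSE)
      }))
    }))
    list(cq_table = cq, dilution_table = dil,
         truth = list(quantities = quantities, slope = slope,
                      intercept = intercept, sigma = sigma, seed = seed))
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth: n_reads", x$n_reads, "seed", x$seed, "\n")
  cat("  isoform counts:",
      paste(names(x$isoform_counts), x$isoform_counts, sep = "=",
            collapse = ", "), "\n")
  eu <- x$expected_usage_percent
  if (length(eu))
    cat("  expected usage:",
        paste(sprintf("%s=%.4f%%", names(eu), eu), collapse = ", "), "\n")
  invisible(x)
}
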
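#' Compute the cassette usage percentage for an event
#'
#' Forms the junction-read usage statistic for a cassette event: 100 times
#' the mean of the inclusion-junction counts divided by the exclusion
#' (skipping) junction count. For the MAPT exon-10 event with inclusion
#' junctions X(9,10) and X(10,11) and exclusion junction X(9,11) this is
#' \deqn{100 \cdot \tfrac{1}{2}(X_{9,10} + X_{10,11}) / X_{9,11},}
#' the 4R/3R usage percentage; for k inclusion junctions the mean uses 1/k.
#' Under uniform read coverage the statistic estimates 100 f/(1-f), where f
#' is the molar inclusion (4R) fraction, so the inverse transform
#' `usage/(100+usage)` is reported as the inclusion-fraction estimate.
#'
#' @param table A [junction_counts()] table. Event junctions absent from the
#'   table are treated as zero counts with a warning (pure-isoform samples
#'   legitimately yield zero-count junctions). Matching ignores strand: the
#'   counts come from strand-agnostic alignments.
#' @param event A [cassette_event()].
#' @param chrom Optional chromosome to restrict matching to (use the gene
#'   model's chromosome when the table mixes genes).
#' @return An object of class `cassette_usage`: `event` (name),
#'   `x_inclusion` (named vector of inclusion counts), `x_exclusion`,
#'   `usage_percent` (`NA` when undefined), `inclusion_fraction_hat`,
#'   `defined` (`FALSE` when the exclusion count is zero), and
#'   `n_inclusion_junctions`.
#' @examples
#' tab <- junction_counts(data.frame(
#'   chrom = "toy_chr", donor = c(400, 593, 400),
#'   acceptor = c(501, 701, 701), strand = "+", count = c(50, 50, 100)))
#' ev <- gene_model_fixture("toy")$events$TOY_4R
#' compute_usage(tab, ev)   # 50% usage, inclusion fraction 1/3
#' @export
compute_usage <- function(table, event, chrom = NULL) {
  stopifnot(inherits(table, "junction_counts"),
            inherits(event, "cassette_event"))
  tab <- as.data.frame(table)
  if (!is.null(chrom)) tab <- tab[tab$chrom == chrom, , drop = FALSE]
  lookup <- function(donor, acceptor) {
    hit <- tab$donor == donor & tab$acceptor == acceptor
    if (!any(hit)) {
      warning("junction (", donor, ",", acceptor, ") of event '", event$name,
              "' absent from table; counted as 0", call. = FALSE)
      return(0)
    }
    sum(tab$count[hit])
  }
  x_inc <- mapply(lookup, event$inclusion$donor, event$inclusion$acceptor)
  names(x_inc) <- sprintf("%d-%d", event$inclusion$donor,
                          event$inclusion$acceptor)
  x_exc <- lookup(event$exclusion$donor[1L], event$exclusion$acceptor[1L])
  defined <- x_exc > 0
  usage <- if (defined) 100 * mean(x_inc) / x_exc else NA_real_
  structure(list(
    event = event$name,
    x_inclusion = x_inc,
    x_exclusion = x_exc,
    usage_percent = usage,
    inclusion_fraction_hat = if (defined) usage / (100 + usage) else NA_real_,
    defined = defined,
    n_inclusion_junctions = length(x_inc)),
    class = "cassette_usage")
}

#' @export
print.cassette_usage <- function(x, ...) {
  cat("cassette_usage:", x$event, "\n")
  cat("  inclusion counts:",
      paste(sprintf("X(%s)=%g", names(x$x_inclusion), x$x_inclusion),
            collapse = ", "), "\n")
  cat("  exclusion count:", x$x_exclusion, "\n")
  if (x$defined) {
    cat(sprintf("  usage: %.4f%%  (inclusion fraction estimate %.4f)\n",
                x$usage_percent, x$inclusion_fraction_hat))
  } else {
    cat("  usage: undefined (exclusion count is 0)\n")
  }
  if (x$n_inclusion_junctions != 2L)
    cat("  note:", x$n_inclusion_junctions,
        "inclusion junctions (mean uses 1/k)\n")
  invisible(x)
}

#' Summarize usage results across samples
#'
#' Mean and sample standard deviation (n-1 denominator) of the usage
#' percentage over samples with a defined ratio, the figure-caption style
#' "mean +/- s.d., n" summary. Undefined results (zero exclusion count) are
#' excluded and tallied.
#'
#' @param results A list of [compute_usage()] results.
#' @return An object of class `usage_summary`: `mean`, `sd` (`NA` when
#'   n = 1), `n`, `n_undefined`, `values`.
#' @export
summarize_samples <- function(results) {
  stopifnot(is.list(results),
            all(vapply(results, inherits, NA, "cassette_usage")))
  vals <- vapply(results, function(r)
    if (isTRUE(r$defined)) r$usage_percent else NA_real_, 0)
  def <- !is.na(vals)
  if (!any(def)) stop("no sample yields a defined usage ratio")
  v <- vals[def]
  structure(list(mean = mean(v),
                 sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
                 n = length(v),
                 n_undefined = sum(!def),
                 values = v),
            class = "usage_summary")
}

#' @export
print.usage_summary <- function(x, ...) {
  cat(sprintf("usage: mean %.4f%% +/- %s (s.d.), n = %d",
              x$mean, ifelse(is.na(x$sd), "NA", sprintf("%.4f", x$sd)), x$n))
  if (x$n_undefined > 0)
    cat(sprintf("  [%d undefined sample(s) excluded]", x$n_undefined))
  cat("\n")
  invisible(x)
}
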
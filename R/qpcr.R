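#' Fit a qPCR standard curve to a dilution series
#'
#' Least-squares fit of quantification cycle (Cq) on log10 of the relative
#' template amount over a serial dilution of pooled cDNA. The fitted slope
#' gives the amplification efficiency `10^(-1/slope) - 1` (1.0 for perfect
#' doubling chemistry, slope -3.321928 = -1/log10(2)).
#'
#' @param points data.frame with columns `dilution_factor` (relative
#'   template amount, > 0) and `cq` (finite), or two numeric vectors via
#'   `points` and `cq`.
#' @param cq Optional numeric vector of Cq values when `points` is given as
#'   a numeric vector of dilution factors.
#' @return An object of class `standard_curve`: `slope`, `intercept`
#'   (Cq at log10(amount) = 0), `r_squared`, `efficiency`, `n_points`,
#'   `flag` (`"positive_slope"` or `"zero_slope"` warning flag, else `NA`),
#'   plus the underlying [stats::lm()] fit in `$fit`.
#' @examples
#' fit_standard_curve(data.frame(dilution_factor = c(1, .5, .25, .125),
#'                               cq = c(20, 21, 22, 23)))
#' @export
fit_standard_curve <- function(points, cq = NULL) {
  if (!is.data.frame(points))
    points <- data.frame(dilution_factor = points, cq = cq)
  stopifnot(all(c("dilution_factor", "cq") %in% names(points)))
  if (any(points$dilution_factor <= 0))
    stop("dilution factors must be > 0")
  if (any(!is.finite(points$cq))) stop("Cq values must be finite")
  if (length(unique(points$dilution_factor)) < 3L)
    stop("a standard curve needs >= 3 distinct dilution factors")
  fit <- stats::lm(cq ~ log10(dilution_factor), data = points)
  slope <- unname(stats::coef(fit)[2L])
  flag <- NA_character_
  if (slope == 0 || abs(slope) < 1e-12) {
    flag <- "zero_slope"
    warning("standard curve slope is zero; efficiency undefined",
            call. = FALSE)
  } else if (slope > 0) {
    flag <- "positive_slope"
    warning("standard curve slope is positive; check dilution labelling",
            call. = FALSE)
  }
  structure(list(
    slope = slope,
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = suppressWarnings(summary(fit)$r.squared),
    efficiency = if (is.na(flag) || flag == "positive_slope")
      10^(-1 / slope) - 1 else NA_real_,
    n_points = nrow(points),
    flag = flag,
    fit = fit), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard_curve: slope %.6f, intercept %.4f, r^2 %.6f, efficiency %s\n",
    x$slope, x$intercept, x$r_squared,
    ifelse(is.na(x$efficiency), "NA", sprintf("%.4f", x$efficiency))))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' @export
coef.standard_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predicted Cq for given relative amounts
#'
#' @param object A [fit_standard_curve()] result.
#' @param quantity Relative template amounts (> 0).
#' @param ... Unused.
#' @return Predicted Cq values `intercept + slope * log10(quantity)`.
#' @export
predict.standard_curve <- function(object, quantity, ...) {
  stopifnot(all(quantity > 0))
  object$intercept + object$slope * log10(quantity)
}

#' Interpolate a relative quantity from a Cq value
#'
#' Inverts the standard curve: `quantity = 10^((cq - intercept) / slope)`.
#'
#' @param cq Cq value(s).
#' @param curve A valid [fit_standard_curve()] result (negative slope).
#' @return Relative quantity, on the scale of the dilution factors used to
#'   fit the curve.
#' @export
interpolate_quantity <- function(cq, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!is.na(curve$flag) && curve$flag == "zero_slope")
    stop("cannot interpolate from a zero-slope curve")
  if (curve$slope >= 0)
    stop("cannot interpolate from a non-negative-slope curve")
  10^((cq - curve$intercept) / curve$slope)
}

#' Normalize sample quantities to the geometric mean of reference genes
#'
#' Divides each sample's target quantities by the geometric mean of that
#' sample's reference-gene quantities (e.g. GAPDH and HPRT1), removing
#' per-sample template-input differences: scaling all quantities of a
#' sample by a common factor leaves the normalized values unchanged.
#'
#' @param samples data.frame with columns `sample_id`, `target`, `quantity`
#'   (> 0), one row per sample x target.
#' @param reference_targets Character vector of reference target names;
#'   every sample must carry a quantity for each.
#' @return The input with a `normalized_quantity` column added (reference
#'   rows included, normalized against the same geometric mean).
#' @export
normalize_to_references <- function(samples,
                                    reference_targets = c("GAPDH", "HPRT1")) {
  need <- c("sample_id", "target", "quantity")
  stopifnot(is.data.frame(samples), all(need %in% names(samples)))
  if (any(samples$quantity <= 0)) stop("quantities must be > 0")
  samples$normalized_quantity <- NA_real_
  for (sid in unique(samples$sample_id)) {
    rows <- samples$sample_id == sid
    refs <- vapply(reference_targets, function(rt) {
      q <- samples$quantity[rows & samples$target == rt]
      if (!length(q))
        stop("sample '", sid, "' is missing reference target '", rt, "'")
      mean(q)
    }, 0)
    gm <- exp(mean(log(refs)))
    samples$normalized_quantity[rows] <- samples$quantity[rows] / gm
  }
  samples
}

#' Ratio of two normalized quantities as a percentage
#'
#' `100 * normalized(numerator) / normalized(denominator)`; with the 4R
#' junction assay as numerator and the 3R assay as denominator this is the
#' qPCR 4R/3R percentage.
#'
#' @param num,den Normalized quantities (numeric scalars or the rows of a
#'   [normalize_to_references()] result).
#' @return A list with `ratio_percent` and `defined` (`FALSE` when the
#'   denominator is zero, ratio `NA`).
#' @export
qpcr_ratio <- function(num, den) {
  num <- as.numeric(num)
  den <- as.numeric(den)
  if (is.na(den) || den == 0)
    return(list(ratio_percent = NA_real_, defined = FALSE))
  list(ratio_percent = 100 * num / den, defined = TRUE)
}

#' Full standard-curve relative quantification pipeline
#'
#' From long-format Cq tables to per-sample normalized quantities and a
#' numerator/denominator percentage: technical replicates are summarized by
#' their mean Cq (the replicate s.d. is carried along), one standard curve
#' is fitted per target from the dilution table, quantities are
#' interpolated from the mean Cq, normalized to the geometric mean of the
#' reference targets, and the per-sample ratio formed.
#'
#' @param cq_table data.frame with columns `sample_id`, `target`,
#'   `replicate`, `cq`.
#' @param dilution_table data.frame with columns `target`,
#'   `dilution_factor`, `replicate`, `cq`.
#' @param reference_targets Reference gene names (default GAPDH, HPRT1).
#' @param numerator,denominator Target names for the reported ratio
#'   (default 4R over 3R).
#' @param cq_cutoff Cq above which a well is treated as a negative /
#'   no-amplification well and excluded with a note (default 38).
#' @return A list of class `qpcr_result`: `curves` (named list of
#'   [fit_standard_curve()] objects), `quantities` (per sample x target:
#'   `cq_mean`, `cq_sd`, `n_replicates`, `quantity`,
#'   `normalized_quantity`), `ratios` (per sample: `ratio_percent`,
#'   `defined`), `summary` (mean, s.d., n over defined ratios),
#'   `excluded_wells`.
#' @export
qpcr_quantify <- function(cq_table, dilution_table,
                          reference_targets = c("GAPDH", "HPRT1"),
                          numerator = "4R", denominator = "3R",
                          cq_cutoff = 38) {
  stopifnot(all(c("sample_id", "target", "replicate", "cq") %in%
                  names(cq_table)),
            all(c("target", "dilution_factor", "replicate", "cq") %in%
                  names(dilution_table)))
  drop <- !is.finite(cq_table$cq) | cq_table$cq > cq_cutoff
  excluded <- cq_table[drop, , drop = FALSE]
  cq_table <- cq_table[!drop, , drop = FALSE]
  if (!nrow(cq_table)) stop("no wells below the Cq cutoff")

  curves <- lapply(split(dilution_table, dilution_table$target),
                   fit_standard_curve)

  agg <- stats::aggregate(cq ~ sample_id + target, data = cq_table,
                          FUN = function(x) c(mean = mean(x),
                                              sd = stats::sd(x),
                                              n = length(x)))
  quantities <- data.frame(sample_id = agg$sample_id, target = agg$target,
                           cq_mean = agg$cq[, "mean"],
                           cq_sd = agg$cq[, "sd"],
                           n_replicates = agg$cq[, "n"],
                           stringsAsFactors = FALSE)
  quantities$quantity <- vapply(seq_len(nrow(quantities)), function(i) {
    tg <- quantities$target[i]
    if (is.null(curves[[tg]]))
      stop("no dilution series for target '", tg, "'")
    interpolate_quantity(quantities$cq_mean[i], curves[[tg]])
  }, 0)
  quantities <- normalize_to_references(quantities, reference_targets)

  ratios <- do.call(rbind, lapply(unique(quantities$sample_id), function(s) {
    getq <- function(tg) {
      q <- quantities$normalized_quantity[quantities$sample_id == s &
                                            quantities$target == tg]
      if (!length(q)) NA_real_ else q[1L]
    }
    r <- qpcr_ratio(getq(numerator), getq(denominator))
    data.frame(sample_id = s, ratio_percent = r$ratio_percent,
               defined = r$defined, stringsAsFactors = FALSE)
  }))
  def <- ratios$ratio_percent[ratios$defined & !is.na(ratios$ratio_percent)]
  structure(list(
    curves = curves,
    quantities = quantities,
    ratios = ratios,
    summary = list(mean = if (length(def)) mean(def) else NA_real_,
                   sd = if (length(def) > 1L) stats::sd(def) else NA_real_,
                   n = length(def)),
    excluded_wells = excluded),
    class = "qpcr_result")
}

#' @export
print.qpcr_result <- function(x, ...) {
  cat("qpcr_result:", length(x$curves), "standard curves,",
      nrow(x$quantities), "sample x target quantities\n")
  for (nm in names(x$curves))
    cat(sprintf("  %s: slope %.4f, efficiency %s, r^2 %.4f\n", nm,
                x$curves[[nm]]$slope,
                ifelse(is.na(x$curves[[nm]]$efficiency), "NA",
                       sprintf("%.3f", x$curves[[nm]]$efficiency)),
                x$curves[[nm]]$r_squared))
  cat(sprintf("  ratio: mean %.4f%% +/- %s (s.d.), n = %d\n",
              x$summary$mean,
              ifelse(is.na(x$summary$sd), "NA",
                     sprintf("%.4f", x$summary$sd)),
              x$summary$n))
  if (nrow(x$excluded_wells))
    cat("  excluded wells:", nrow(x$excluded_wells), "\n")
  invisible(x)
}
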
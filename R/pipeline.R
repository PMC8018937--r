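#' Write a simulated dataset to a directory
#'
#' Runs [simulate_reads()] and writes the toy reference (FASTA), the
#' alignments (SAM-dialect text), the truth ledger and isoform counts
#' (TSV), and a YAML manifest listing every emitted file together with the
#' seed and configuration defaults, so a run is reproducible from the
#' manifest alone.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_reads(config)
  paths <- list(reference = file.path(out_dir, "reference.fa"),
                alignments = file.path(out_dir, "alignments.sam"),
                truth_junctions = file.path(out_dir, "truth_junctions.tsv"),
                truth_isoforms = file.path(out_dir, "truth_isoforms.tsv"),
                manifest = file.path(out_dir, "manifest.yaml"))
  write_fasta(sim$reference, paths$reference)
  writeLines(sim$sam, paths$alignments)
  utils::write.table(sim$truth$junction_ledger, paths$truth_junctions,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(isoform = names(sim$truth$isoform_counts),
               count = as.integer(sim$truth$isoform_counts)),
    paths$truth_isoforms, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    files = lapply(paths[names(paths) != "manifest"], basename),
    seed = config$seed,
    n_reads = sim$truth$n_reads,
    read_length = config$read_length,
    min_anchor = config$min_anchor,
    depth_mode = config$depth_mode,
    proportions = as.list(config$proportions),
    expected_usage_percent = as.list(sim$truth$expected_usage_percent))
  yaml::write_yaml(manifest, paths$manifest)
  invisible(manifest)
}

write_fasta <- function(seqs, path, width = 70L) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                                width = width)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (nm in names(seqs)) {
      writeLines(paste0(">", nm), con)
      s <- seqs[[nm]]
      writeLines(substring(s, seq(1L, nchar(s), width),
                           pmin(seq(1L, nchar(s), width) + width - 1L,
                                nchar(s))), con)
    }
  }
  invisible(path)
}

#' Quantify cassette usage across samples and write reports
#'
#' The counting-to-summary workflow: for each sample, junction counts are
#' taken from a spliced-alignment file ([extract_junctions()]) or a
#' precomputed junction table ([read_junction_table()]), depth-normalized
#' where a library size is available, the usage percentage of every event
#' in the gene model is computed, and a per-event group summary
#' (mean +/- s.d. over defined samples) is written. Optionally a gene
#' count table is TPM-normalized alongside.
#'
#' @param inputs Named character vector of per-sample input paths (names
#'   are sample ids; unnamed paths are labelled by filename).
#' @param model A [gene_model()] or a fixture name for
#'   [gene_model_fixture()].
#' @param out_dir Output directory.
#' @param input_type `"sam"` for alignments, otherwise a
#'   [read_junction_table()] dialect.
#' @param min_anchor Anchor setting for [extract_junctions()].
#' @param library_size Optional per-sample library sizes (recycled) for
#'   table inputs.
#' @param gene_counts Optional path to a gene count TSV (`gene_id`,
#'   `count`, `effective_length`) to TPM-normalize.
#' @return Invisibly, a list with `usage` (per sample x event data.frame)
#'   and `summaries` (per event `usage_summary`). Errors if no sample
#'   yields a defined ratio for any event.
#' @export
run_quantify <- function(inputs, model, out_dir,
                         input_type = c("sam", "plain_tsv", "star_sj",
                                        "jcounts"),
                         min_anchor = 1L, library_size = NA_real_,
                         gene_counts = NULL) {
  input_type <- match.arg(input_type)
  if (is.character(model)) model <- gene_model_fixture(model)
  stopifnot(inherits(model, "gene_model"))
  if (!length(model$events)) stop("gene model has no cassette events")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- names(inputs) %||% rep(NA_character_, length(inputs))
  ids[is.na(ids) | !nzchar(ids)] <-
    sub("\\.[^.]*$", "", basename(inputs[is.na(ids) | !nzchar(ids)]))
  library_size <- rep_len(library_size, length(inputs))

  message("run_quantify: input_type=", input_type,
          " min_anchor=", min_anchor,
          " (absent event junctions count as 0;",
          " library size = primary mapped records for sam input)")

  rows <- list()
  results <- list()
  for (i in seq_along(inputs)) {
    tab <- if (input_type == "sam")
      extract_junctions(inputs[[i]], min_anchor = min_anchor,
                        sample_id = ids[i])
    else
      read_junction_table(inputs[[i]], dialect = input_type,
                          sample_id = ids[i],
                          library_size = library_size[i])
    ls <- attr(tab, "library_size")
    if (!is.na(ls) && ls > 0) tab <- normalize_depth(tab)
    write_junction_table(tab, file.path(out_dir,
                                        paste0(ids[i], "_junctions.tsv")))
    for (ev in model$events) {
      res <- suppressWarnings(compute_usage(tab, ev, chrom = model$chrom))
      results[[ev$name]] <- c(results[[ev$name]], list(res))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = ids[i], event = ev$name,
        inclusion_counts = paste(res$x_inclusion, collapse = ";"),
        exclusion_count = res$x_exclusion,
        usage_percent = fmt6(res$usage_percent),
        inclusion_fraction_hat = fmt6(res$inclusion_fraction_hat),
        defined = res$defined, stringsAsFactors = FALSE)
    }
  }
  usage <- do.call(rbind, rows)
  utils::write.table(usage, file.path(out_dir, "usage.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  summaries <- lapply(results, summarize_samples)
  summary_df <- do.call(rbind, lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    data.frame(event = nm, mean_usage_percent = fmt6(s$mean),
               sd_usage_percent = fmt6(s$sd), n = s$n,
               n_undefined = s$n_undefined, stringsAsFactors = FALSE)
  }))
  utils::write.table(summary_df, file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  if (!is.null(gene_counts)) {
    gc <- utils::read.delim(gene_counts, stringsAsFactors = FALSE)
    prof <- compute_tpm(gc)
    prof$tpm <- fmt6(prof$tpm)
    prof$log2_tpm1 <- fmt6(prof$log2_tpm1)
    utils::write.table(prof, file.path(out_dir, "tpm.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(list(usage = usage, summaries = summaries))
}

fmt6 <- function(x) ifelse(is.na(x), NA, sprintf("%.6f", x))

#' Run the qPCR quantification workflow and write reports
#'
#' Reads long-format Cq and dilution tables, runs [qpcr_quantify()], and
#' writes the fitted standard curves, per-sample normalized quantities
#' (with technical-replicate s.d.) and per-sample ratio percentages plus a
#' group summary.
#'
#' @param cq_path TSV with columns `sample_id`, `target`, `replicate`, `cq`.
#' @param dilution_path TSV with columns `target`, `dilution_factor`,
#'   `replicate`, `cq`.
#' @param out_dir Output directory.
#' @inheritParams qpcr_quantify
#' @return Invisibly, the [qpcr_quantify()] result.
#' @export
run_qpcr <- function(cq_path, dilution_path, out_dir,
                     reference_targets = c("GAPDH", "HPRT1"),
                     numerator = "4R", denominator = "3R",
                     cq_cutoff = 38) {
  cq <- utils::read.delim(cq_path, stringsAsFactors = FALSE)
  dil <- utils::read.delim(dilution_path, stringsAsFactors = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- qpcr_quantify(cq, dil, reference_targets = reference_targets,
                       numerator = numerator, denominator = denominator,
                       cq_cutoff = cq_cutoff)
  curves <- do.call(rbind, lapply(names(res$curves), function(nm) {
    cv <- res$curves[[nm]]
    data.frame(target = nm, slope = fmt6(cv$slope),
               intercept = fmt6(cv$intercept),
               r_squared = fmt6(cv$r_squared),
               efficiency = fmt6(cv$efficiency),
               flag = ifelse(is.na(cv$flag), "", cv$flag),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(curves, file.path(out_dir, "standard_curves.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  q <- res$quantities
  for (col in c("cq_mean", "cq_sd", "quantity", "normalized_quantity"))
    q[[col]] <- fmt6(q[[col]])
  utils::write.table(q, file.path(out_dir, "quantities.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rt <- res$ratios
  rt$ratio_percent <- fmt6(rt$ratio_percent)
  utils::write.table(rt, file.path(out_dir, "ratios.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(mean_ratio_percent = fmt6(res$summary$mean),
               sd_ratio_percent = fmt6(res$summary$sd),
               n = res$summary$n),
    file.path(out_dir, "ratio_summary.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(res)
}
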
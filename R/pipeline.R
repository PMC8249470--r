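## End-to-end orchestration: panel -> libraries -> mapping -> classification
## -> ping-pong / bias / TE tables -> genomic windows -> report.

#' Default pipeline configuration
#'
#' The default four-genotype study emulates a heterozygous control, a
#' piRNA-pathway mutant, a wild-type rescue and a methylation-deficient
#' rescue: piRNA production is scaled per genotype (reduction factors 1,
#' 0.19, 1, 0.345 give piRNA:miRNA ratios near 2.0, 0.38, 2.0 and 0.69),
#' the sense 10A bias is set to 47/28/49/38% and the planted responder
#' fraction drops in the mutant and is partially restored in the
#' methylation-deficient rescue.
#'
#' @param seed master seed; per-library seeds are derived from it.
#' @param n_pirna_pairs,n_mirna_reads,n_cluster_reads library depth knobs.
#' @return a config list accepted by [run_pipeline()].
#' @export
default_config <- function(seed = 1L, n_pirna_pairs = 20000L,
                           n_mirna_reads = 20000L,
                           n_cluster_reads = 8000L) {
  geno <- list(
    control   = list(reduction_factor = 1.000, p_10A_sense = 0.47,
                     p_pingpong = 0.50),
    mutant    = list(reduction_factor = 0.190, p_10A_sense = 0.28,
                     p_pingpong = 0.15),
    wt_rescue = list(reduction_factor = 1.000, p_10A_sense = 0.49,
                     p_pingpong = 0.50),
    md_rescue = list(reduction_factor = 0.345, p_10A_sense = 0.38,
                     p_pingpong = 0.30))
  seed <- as.integer(seed)
  seed_base <- (seed %% 1000000L) * 1000L   # keep derived seeds < 2^31
  libs <- lapply(seq_along(geno), function(i) {
    c(list(genotype = names(geno)[i], n_pirna_pairs = n_pirna_pairs,
           n_mirna_reads = n_mirna_reads,
           n_cluster_reads = n_cluster_reads,
           seed = seed_base + i), geno[[i]])
  })
  names(libs) <- names(geno)
  list(panel = list(n_families = 6L, consensus_len = c(800L, 1500L),
                    n_chroms = 2L, chrom_len = 50000L, seed = seed),
       libraries = libs,
       control_id = "control",
       parameters = list(size_window = c(19L, 29L),
                         pirna_len = c(23L, 29L),
                         max_edits = 2L,
                         window_size = 5000L,
                         cluster_window_size = 1000L,
                         min_rpm = 5, min_reduction = 0.8,
                         pseudo_reads = 0.5,
                         adapter = NULL, top_k = 20L),
       seed = as.integer(seed))
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path config file (`.yml`/`.yaml`/`.json`).
#' @return a config list.
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

validate_config <- function(config) {
  for (k in c("libraries", "control_id", "parameters"))
    if (is.null(config[[k]]))
      stop("config is missing field ", sQuote(k), call. = FALSE)
  if (!config$control_id %in% names(config$libraries))
    stop("control_id ", sQuote(config$control_id),
         " is not among the configured libraries", call. = FALSE)
  invisible(config)
}

build_library <- function(spec, panel) {
  if (!is.null(spec$path)) {
    lib <- load_reads(spec$path, format = spec$format %||% "fasta",
                      collapsed_header = isTRUE(spec$collapsed_header),
                      library_id = spec$genotype %||% basename(spec$path),
                      genotype = spec$genotype %||% basename(spec$path))
    return(list(library = lib, truth = NULL))
  }
  params <- do.call(library_params, spec)
  simulate_library(panel, params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the small RNA analysis pipeline
#'
#' Executes every stage for each configured library: simulation (or
#' loading), optional adapter trimming, size selection, exact genome
#' mapping, read classification, miRNA-normalized TE family tables with
#' fold changes against the control, ping-pong histograms, 1U/10A bias,
#' genomic window counting with the control/reduction filters and per-window
#' cluster fold changes.  Deterministic for a fixed config.
#'
#' @param config a config list (see [default_config()]) or a YAML/JSON path.
#' @param out_dir optional directory for TSV/BED/JSON stage artifacts.
#' @return object of class `genotype_report`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  pars <- config$parameters
  panel <- if (!is.null(config$panel$consensus_fasta)) {
    read_te_panel(config$panel$consensus_fasta, config$panel$genome_fasta,
                  config$panel$annotation_bed)
  } else do.call(generate_te_panel, config$panel)

  lib_ids <- names(config$libraries)
  per_library <- list()
  te_tables <- list()
  window_cols_5k <- list()
  window_cols_1k <- list()
  total_mirna <- setNames(numeric(length(lib_ids)), lib_ids)
  win5 <- make_windows(panel, pars$window_size)
  win1 <- make_windows(panel, pars$cluster_window_size)

  for (id in lib_ids) {
    sim <- build_library(config$libraries[[id]], panel)
    lib <- sim$library
    if (!is.null(pars$adapter))
      lib <- trim_adapter(lib, pars$adapter)
    lib <- size_select(lib, pars$size_window[1], pars$size_window[2])

    gal <- map_library_to_genome(lib, panel)
    cls <- classify_reads(lib, gal, panel$annotation,
                          pirna_len = pars$pirna_len)
    total_mirna[id] <- cls$totals[["miRNA"]]

    pirna_reads <- cls$reads[cls$reads$class == "piRNA", , drop = FALSE]
    pirna_lib <- smallrna_library(pirna_reads[, c("sequence", "count")],
                                  lib$library_id, lib$genotype)
    aln <- map_library_to_panel(pirna_lib, panel,
                                max_edits = pars$max_edits)
    te_tables[[id]] <- te_family_table(aln, total_mirna[id], id)
    combined <- combined_histogram(aln, scope = "all")
    bias <- bias_report(aln, scope = "all")

    ## genome-wide piRNA-sized reads (excluding miRNA/rRNA) for windows;
    ## cluster-derived reads are included even where no repeat annotation
    ## covers them
    win_seqs <- cls$reads$sequence[
      cls$reads$class %in% c("piRNA", "other") &
        cls$reads$length >= pars$pirna_len[1] &
        cls$reads$length <= pars$pirna_len[2]]
    wal <- gal[gal$sequence %in% win_seqs, , drop = FALSE]
    window_cols_5k[[id]] <- window_counts(wal, win5, total_mirna[id],
                                          size = pars$window_size)
    window_cols_1k[[id]] <- window_counts(wal, win1, total_mirna[id],
                                          size = pars$cluster_window_size)

    per_library[[id]] <- list(
      library_id = id, genotype = lib$genotype,
      totals = as.list(cls$totals),
      pirna_mirna_ratio = pirna_mirna_ratio(cls),
      length_distribution = length_distribution(
        cls, classes = c("miRNA", "piRNA")),
      pingpong_fraction = combined$pingpong_fraction,
      pingpong_values = combined$values,
      pingpong_by_family = pingpong_fraction_by_family(
        aln, families = names(panel$families)),
      frac_1U_antisense = bias$frac_1U_antisense,
      frac_10A_sense_non1U = bias$frac_10A_sense_non1U,
      frac_10A_sense_all = bias$frac_10A_sense_all,
      truth = sim$truth,
      log = lib$log)

    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_te_alignments(aln, file.path(out_dir,
                                         paste0(id, ".te_alignments.tsv")))
      write_pingpong_tsv(combined, file.path(out_dir,
                                             paste0(id, ".pingpong.tsv")))
    }
  }

  te_all <- do.call(rbind, te_tables)
  te_all <- te_family_fold_change(te_all, config$control_id, total_mirna,
                                  pseudo_reads = pars$pseudo_reads)

  wt5 <- window_table(window_cols_5k, total_mirna)
  wt1 <- window_table(window_cols_1k, total_mirna)
  filters <- lapply(setdiff(lib_ids, config$control_id), function(id)
    filter_windows(wt5, config$control_id, id,
                   min_rpm = pars$min_rpm,
                   min_reduction = pars$min_reduction))
  names(filters) <- setdiff(lib_ids, config$control_id)
  cluster_fc <- cluster_fold_change(wt1, panel$annotation,
                                    config$control_id,
                                    pseudo_reads = pars$pseudo_reads)

  report <- structure(list(
    per_library = per_library,
    te_table = te_all,
    total_mirna = as.list(total_mirna),
    windows_5kb = wt5,
    window_filter_survivors = lapply(filters, nrow),
    cluster_fold_change = cluster_fc,
    provenance = list(control_id = config$control_id,
                      parameters = pars,
                      panel_seed = config$panel$seed %||% NA,
                      seed = config$seed %||% NA,
                      class_priority = c("miRNA", "rRNA", "piRNA",
                                         "other"))),
    class = "genotype_report")
  if (!is.null(out_dir)) {
    utils::write.table(te_all, file.path(out_dir, "te_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_report(report, file.path(out_dir, "report.json"))
  }
  report
}

#' @export
print.genotype_report <- function(x, ...) {
  cat("Genotype report:", length(x$per_library), "libraries (control:",
      x$provenance$control_id, ")\n")
  for (pl in x$per_library)
    cat(sprintf(paste0("  %-10s piRNA:miRNA %.3f | ping-pong %5.1f%% | ",
                       "10A (sense non-1U) %5.1f%%\n"),
                pl$library_id, pl$pirna_mirna_ratio,
                pl$pingpong_fraction, pl$frac_10A_sense_non1U))
  invisible(x)
}

#' Serialize a report to JSON
#'
#' @param report a `genotype_report`.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  x <- rapply(unclass(report), function(v) v, how = "replace")
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}

#' Read a serialized report
#'
#' @param path JSON path written by [write_report()].
#' @return a list (plain-data form of the report).
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Compare genotypes against the control
#'
#' Per-family comparison table: miRNA-normalized abundance, log2 fold
#' change and the 10A-bias and ping-pong deltas per library, restricted to
#' the `top_k` families most abundant in the control.
#'
#' @param report a `genotype_report` from [run_pipeline()].
#' @param control_id control library id (default from the report).
#' @param top_k number of families, ranked by control abundance (default
#'   20).
#' @return data.frame with one row per (family, library).
#' @export
compare_genotypes <- function(report,
                              control_id = report$provenance$control_id,
                              top_k = 20L) {
  te <- report$te_table
  if (!control_id %in% te$library_id)
    stop("control library missing from report", call. = FALSE)
  ctrl <- te[te$library_id == control_id, , drop = FALSE]
  ranked <- ctrl$family[order(-ctrl$total_rpm_mirna)]
  fams <- utils::head(ranked, top_k)
  out <- te[te$family %in% fams, , drop = FALSE]
  pp <- lapply(report$per_library, `[[`, "pingpong_by_family")
  out$pingpong_fraction <- mapply(function(f, id) pp[[id]][[f]],
                                  out$family, out$library_id)
  out$family <- factor(out$family, levels = fams)
  out <- out[order(out$family, out$library_id), , drop = FALSE]
  out$family <- as.character(out$family)
  rownames(out) <- NULL
  out
}
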
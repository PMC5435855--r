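#' Default pipeline configuration
#'
#' Returns the full set of pipeline parameters with their defaults:
#' QC top-N 500, alignment window 1000 nt, 100 strand-bias bins, LOESS
#' span 0.3, LOFC threshold 1, minimum pattern-cluster size 15.
#' Supplied values override defaults; unknown fields are an error.
#'
#' @param ... Overrides (see [run_pipeline()] for the field list).
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    fasta = NULL,              # named list/vector: replicate id -> FASTA path
    fasta_dialect = "count_suffix",
    hierarchy = NULL,          # sample_hierarchy or named list
    genome = NULL,             # FASTA path (for exact alignment)
    alignments = NULL,         # precomputed SAM/BED per replicate-union library
    gff = NULL,                # optional annotation
    annotation_types = c("miRNA", "siRNA", "tRNA", "rRNA", "snoRNA",
                         "protein_coding", "repeat"),
    drop_replicates = character(0),
    size_range = c(15L, 35L),
    qc_top_n = 500L,
    abundance_window = NULL,
    methods = c("total_count", "tmm", "deseq", "quantile_adapted"),
    chosen_method = "tmm",
    seed = 1L,                 # for subsampling normalization
    window_len = 1000L,
    n_bias_bins = 100L,
    min_windows_per_level = 100L,
    span = 0.3,
    offset = NULL,             # fixed offset; NULL = estimate from data
    threshold = 1,
    ci_method = "auto",
    chebyshev_k = 2,
    scheme = "consecutive",
    reference = NULL,
    min_cluster_size = 15L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown pipeline_config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (!is.null(cfg$hierarchy) && !inherits(cfg$hierarchy, "sample_hierarchy"))
    cfg$hierarchy <- sample_hierarchy(cfg$hierarchy)
  if (length(cfg$methods) > 6L)
    stop("at most six normalization methods can be evaluated at once")
  if (!cfg$chosen_method %in% c(cfg$methods, "raw"))
    stop("chosen_method must be one of the evaluated methods")
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from JSON
#' @param path JSON file with configuration fields.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$hierarchy)) raw$hierarchy <- as.list(raw$hierarchy)
  do.call(pipeline_config, raw)
}

stage_log <- function(log, msg) {
  line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", msg)
  message(line)
  c(log, line)
}

#' Run the full differential-expression pipeline
#'
#' Executes the stages in order — ingestion, filtering, alignment,
#' annotation, quality checking of the raw data, normalization
#' (evaluating the configured methods and applying the chosen one),
#' quality checking of the normalized data, offset estimation and the
#' confidence-interval DE call with pattern clustering — and writes
#' every stage's tables under `out_dir` together with a run log and a
#' `manifest.json` capturing all parameters, so any output is
#' reproducible from the manifest alone.
#'
#' @param config A [pipeline_config()] (or arguments for it as a list).
#' @param out_dir Output directory.
#' @param libraries Optional pre-loaded named list of [read_library()]
#'   objects (bypasses `config$fasta`), e.g. from
#'   [simulate_experiment()].
#' @param alignments Optional pre-computed [alignment_set()].
#' @return List of class `pipeline_result` with the in-memory stage
#'   outputs (`matrix`, `qc_raw`, `normalization`, `qc_normalized`,
#'   `offset`, `de`, `clusters`, `out_dir`).
#' @export
run_pipeline <- function(config, out_dir, libraries = NULL,
                         alignments = NULL) {
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, as.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)

  ## 1. ingestion
  log <- stage_log(log, "stage 1/7: ingestion")
  if (is.null(libraries)) {
    if (is.null(config$fasta)) stop("no input libraries: set config$fasta")
    paths <- unlist(config$fasta)
    libraries <- lapply(names(paths), function(id)
      read_fasta_counts(paths[[id]], config$fasta_dialect, replicate_id = id,
                        size_range = config$size_range))
    names(libraries) <- names(paths)
  }
  if (is.null(config$hierarchy))
    stop("no sample hierarchy: set config$hierarchy")
  matrix <- build_expression_matrix(libraries, config$hierarchy)
  matrix <- filter_matrix(matrix, config$drop_replicates, config$size_range)
  write_matrix_tsv(matrix, file.path(out_dir, "matrix_raw.tsv"))

  ## 2. alignment
  log <- stage_log(log, "stage 2/7: alignment")
  union_lib <- read_library(stats::setNames(
    rowSums(matrix$values)[rowSums(matrix$values) > 0],
    rownames(matrix$values)[rowSums(matrix$values) > 0]),
    "union", size_range = config$size_range)
  if (is.null(alignments)) {
    if (!is.null(config$alignments)) {
      alignments <- load_alignments(config$alignments, union_lib)
    } else if (!is.null(config$genome)) {
      alignments <- align_reads_exact(union_lib, config$genome)
    }
  }
  if (!is.null(alignments))
    utils::write.table(alignments$hits, file.path(out_dir, "alignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  ## 3. annotation
  classification <- NULL
  if (!is.null(config$gff) && !is.null(alignments)) {
    log <- stage_log(log, "stage 3/7: annotation")
    classification <- annotate_reads(alignments, config$gff,
                                     config$annotation_types,
                                     library = union_lib)
    cls <- vapply(classification$classes, paste, character(1), collapse = ",")
    utils::write.table(
      data.frame(sequence = names(cls), classes = unname(cls)),
      file.path(out_dir, "annotation.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  } else log <- stage_log(log, "stage 3/7: annotation (skipped)")

  ## 4. QC on raw data
  log <- stage_log(log, "stage 4/7: quality checks (raw)")
  qc_raw <- qc_report(matrix, alignments, classification,
                      top_n = config$qc_top_n,
                      abundance_window = config$abundance_window)
  write_qc_report(qc_raw, file.path(out_dir, "qc_raw"))

  ## 5. normalization (evaluate candidates, apply the chosen one)
  log <- stage_log(log, paste0("stage 5/7: normalization (",
                               config$chosen_method, ")"))
  extra <- if ("subsampling" %in% config$methods)
    list(seed = config$seed) else list()
  eval_res <- do.call(evaluate_normalizations,
                      c(list(matrix, config$methods), extra))
  utils::write.table(eval_res$evaluation,
                     file.path(out_dir, "normalization_evaluation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  chosen <- if (config$chosen_method == "subsampling")
    normalize_matrix(matrix, "subsampling", seed = config$seed)
  else normalize_matrix(matrix, config$chosen_method)
  write_matrix_tsv(chosen$matrix, file.path(out_dir, "matrix_normalized.tsv"))
  if (!is.null(chosen$factors))
    utils::write.table(
      data.frame(replicate = names(chosen$factors),
                 factor = unname(chosen$factors)),
      file.path(out_dir, "normalization_factors.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)

  ## QC on normalized data
  qc_norm <- qc_report(chosen$matrix, alignments, classification,
                       top_n = config$qc_top_n,
                       abundance_window = config$abundance_window)
  write_qc_report(qc_norm, file.path(out_dir, "qc_normalized"))

  ## 6. offset estimation
  offset_est <- NULL
  offset <- config$offset
  if (is.null(offset)) {
    if (is.null(alignments))
      stop("offset estimation needs alignments (or set config$offset)")
    log <- stage_log(log, "stage 6/7: offset estimation")
    wins <- experiment_window_profiles(matrix, alignments, config$window_len)
    offset_est <- estimate_offset(wins, config$n_bias_bins,
                                  config$min_windows_per_level, config$span)
    write_offset_estimate(offset_est, file.path(out_dir, "offset"))
    offset <- offset_est$dataset_offset
  } else log <- stage_log(log, paste0("stage 6/7: offset fixed at ", offset))

  ## 7. DE call and pattern clusters
  log <- stage_log(log, "stage 7/7: differential expression call")
  de <- call_de(chosen$matrix, offset = offset, threshold = config$threshold,
                scheme = config$scheme, reference = config$reference,
                ci_method = config$ci_method, k = config$chebyshev_k)
  clusters <- cluster_patterns(de, config$min_cluster_size)
  write_de_calls(de, file.path(out_dir, "de"), config$min_cluster_size)

  manifest <- c(unclass(config)[!vapply(config, is.null, logical(1))],
                list(package_version = as.character(utils::packageVersion("srnadekit")),
                     offset_used = offset))
  manifest$hierarchy <- config$hierarchy$treatments
  manifest$fasta <- as.list(config$fasta)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  writeLines(log, file.path(out_dir, "run.log"))

  structure(list(matrix = matrix, alignments = alignments,
                 classification = classification, qc_raw = qc_raw,
                 normalization = chosen, evaluation = eval_res,
                 qc_normalized = qc_norm, offset = offset,
                 offset_estimate = offset_est, de = de, clusters = clusters,
                 out_dir = out_dir),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result in", x$out_dir, "\n")
  cat("  offset:", x$offset, "\n")
  cat("  DE sequences:", sum(x$de$de_flag), "of", nrow(x$de), "\n")
  cat("  headline pattern clusters:",
      paste(names(x$clusters$headline), collapse = ", "), "\n")
  invisible(x)
}
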
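#' Run the readthrough analysis pipeline
#'
#' Ties the stages into one run: obtain inputs (either a seeded simulation
#' or annotation + stranded bedGraph files), call readthrough candidates
#' per mutant genotype against the wild type, compute the candidate-set
#' overlap between genotypes when two are present, and write all outputs
#' (call TSVs, candidate-window BEDs, overlap TSV, a deterministic log of
#' parameter provenance, and a JSON manifest carrying the configuration,
#' its hash, and the md5 of every output).  Reruns with the same
#' configuration produce byte-identical outputs.
#'
#' The configuration is a list with elements:
#' \describe{
#'   \item{simulate}{a [sim_config()]; when present, inputs come from
#'     [simulate_genotype_pair()] (`overlap_fraction` optionally alongside
#'     in the config).}
#'   \item{annotation}{path to GFF3/GTF (file-input mode).}
#'   \item{samples}{file-input mode: list `wt` and one or more mutants,
#'     each `list(plus=, minus=, library_size=)`.}
#'   \item{params}{list of caller parameters: `window_length` (500),
#'     `fc_threshold` (2), `min_rpkm` (1), `min_mut_window_reads` (10);
#'     defaults are the study values.}
#'   \item{de_exclusion}{optional character vector of gene ids.}
#' }
#'
#' @param config configuration list, see Details.
#' @param out_dir output directory (created).
#' @return list with `calls` (per genotype), `candidates` (gene-id sets),
#'   `overlap` (data.frame or NULL), `files`, `config_hash`, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  params <- utils::modifyList(list(window_length = 500L, fc_threshold = 2,
                                   min_rpkm = 1, min_mut_window_reads = 10),
                              config$params %||% list())
  if (!is.numeric(params$fc_threshold) || params$fc_threshold <= 0) {
    .stopf("invalid fc_threshold (must be > 0): %s", params$fc_threshold)
  }
  if (params$window_length < 1) .stopf("invalid window_length")

  # resolve inputs up front so missing files fail before any compute
  if (!is.null(config$simulate)) {
    stopifnot(inherits(config$simulate, "sim_config"))
    sim <- simulate_genotype_pair(config$simulate,
                                  overlap_fraction = config$overlap_fraction %||% 0.6)
    ann <- sim$ann
    wt <- sim$wt
    mutants <- list(mut_a = sim$mut_a, mut_b = sim$mut_b)
  } else {
    need <- c(config$annotation,
              unlist(lapply(config$samples, function(s) c(s$plus, s$minus))))
    missing_files <- need[!file.exists(need)]
    if (length(missing_files)) {
      .stopf("missing input file(s): %s", paste(missing_files, collapse = ", "))
    }
    ann <- read_annotation(config$annotation)
    mk <- function(nm) {
      s <- config$samples[[nm]]
      if (is.null(s$library_size)) .stopf("missing library size for '%s'", nm)
      read_bedgraph_track(nm, s$plus, s$minus, s$library_size)
    }
    wt <- mk("wt")
    mut_names <- setdiff(names(config$samples), "wt")
    if (!length(mut_names)) .stopf("config$samples must contain a mutant")
    mutants <- setNames(lapply(mut_names, mk), mut_names)
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c("rtchimera pipeline run",
                 sprintf("parameter window_length = %d", params$window_length),
                 sprintf("parameter fc_threshold = %g", params$fc_threshold),
                 sprintf("parameter min_rpkm = %g", params$min_rpkm),
                 sprintf("parameter min_mut_window_reads = %g",
                         params$min_mut_window_reads),
                 sprintf("input mode = %s",
                         if (is.null(config$simulate)) "files" else "simulation"),
                 sprintf("genes = %d", length(ann)))

  calls <- list(); candidates <- list(); files <- character()
  for (nm in names(mutants)) {
    cl <- call_readthrough(ann, wt, mutants[[nm]],
                           window_length = params$window_length,
                           fc_threshold = params$fc_threshold,
                           min_rpkm = params$min_rpkm,
                           min_mut_window_reads = params$min_mut_window_reads,
                           de_exclusion = config$de_exclusion %||% character())
    tsv <- file.path(out_dir, paste0("calls_", nm, ".tsv"))
    bed <- file.path(out_dir, paste0("candidates_", nm, ".bed"))
    write_readthrough_calls(cl, tsv, bed)
    calls[[nm]] <- cl
    candidates[[nm]] <- cl$gene_id[cl$candidate]
    files <- c(files, tsv, bed)
    log_lines <- c(log_lines, sprintf("genotype %s: %d candidate(s)", nm,
                                      sum(cl$candidate)))
  }

  overlap <- NULL
  if (length(candidates) >= 2L) {
    nms <- names(candidates)[1:2]
    overlap <- overlap_summary(candidates[[nms[1L]]], candidates[[nms[2L]]],
                               universe = ann)
    ov_path <- file.path(out_dir, "overlap.tsv")
    write_tsv_table(overlap, ov_path)
    files <- c(files, ov_path)
    log_lines <- c(log_lines,
                   sprintf("overlap %s vs %s: %d of %d / %d, P = %.3g",
                           nms[1L], nms[2L], overlap$n_overlap, overlap$n_a,
                           overlap$n_b, overlap$p_value))
  }

  log_path <- file.path(out_dir, "run.log")
  writeLines(log_lines, log_path)
  cfg_hash <- .object_hash(list(config = config, params = params))
  manifest <- list(config_hash = cfg_hash, params = params,
                   outputs = as.list(setNames(unname(tools::md5sum(c(files, log_path))),
                                              basename(c(files, log_path)))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(calls = calls, candidates = candidates, overlap = overlap,
                 files = c(files, log_path, manifest_path),
                 config_hash = cfg_hash))
}
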
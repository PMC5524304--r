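#' Pipeline configuration
#'
#' A single configuration drives the scan -> pairwise -> partition ->
#' statistics chain. It can be given as an R list or as a YAML file with
#' the same structure:
#'
#' ```yaml
#' seed: 1
#' out_dir: results/run1
#' stages: [scan, pairwise, partition, asymmetry]
#' scan:
#'   maf: input/region.maf
#'   mask: input/mask.bed
#'   fish_species: [fish1, fish2]
#'   tetrapod_species: [tetrapod1]
#'   params: {seed_length: 10, seed_identity: 0.9}
#' pairwise:
#'   query_fasta: input/gar.fa
#'   query_mask: input/gar_exons.bed   # optional
#'   subjects:
#'     - {species: medaka, paralog: a, fasta: input/medaka_a.fa}
#' landscape: {matrix: input/landscape.tsv}
#' ddct: {cq: input/cq.tsv, reference_gene: rpl7, calibrator_sample: s1}
#' ```
#'
#' Every scanner/aligner default equals the study's stated value (seed 10
#' bp at 90%, 3 non-conserved columns per side, 12% column threshold,
#' +1/-1 match/mismatch, gap open/extend 2/2, hits > 50 bp at >= 60%
#' identity, Cq limit 34, low-expression bin at 0.10).
#'
#' @param config list or path to a YAML file.
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config$stages <- config$stages %||%
    c("scan", "pairwise", "partition", "asymmetry", "landscape", "ddct")
  config$seed <- config$seed %||% 1L
  if (is.null(config$out_dir)) stop("config needs out_dir", call. = FALSE)
  inputs <- c(config$scan$maf, config$scan$mask,
              config$pairwise$query_fasta, config$pairwise$query_mask,
              vapply(config$pairwise$subjects %||% list(),
                     function(s) s$fasta, character(1)),
              config$partition$cnes_bed,
              config$landscape$matrix, config$ddct$cq)
  missing_files <- inputs[!file.exists(inputs)]
  if (length(missing_files)) {
    stop("missing input file(s): ", paste(missing_files, collapse = ", "),
         call. = FALSE)
  }
  structure(config, class = c("pipeline_config", "list"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write an output atomically: stage failures leave a .partial file behind
write_stage_output <- function(writer, path) {
  partial <- paste0(path, ".partial")
  writer(partial)
  file.rename(partial, path)
  invisible(path)
}

#' Run the CNE analysis pipeline
#'
#' Executes the configured stages in dependency order (scan, pairwise,
#' partition, asymmetry, landscape, ddct), writing BED/TSV/JSON outputs and
#' a run manifest (parameters, package version, seed, input checksums) to
#' `out_dir`. Identical config and inputs give identical outputs; a stage
#' failure halts the run with the stage name, leaving that stage's partial
#' output with a `.partial` suffix.
#'
#' @param config a [pipeline_config()] list or YAML path.
#' @return Invisible list of per-stage results.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  run_stage <- function(name, fun) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    message("[ohnocne] stage ", name)
    res <- tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    results[[name]] <<- res
    res
  }

  run_stage("scan", function() {
    sc <- cfg$scan
    if (is.null(sc)) stop("no scan configuration")
    cls <- c(setNames(rep("fish", length(sc$fish_species)),
                      sc$fish_species),
             setNames(rep("tetrapod", length(sc$tetrapod_species)),
                      sc$tetrapod_species))
    blocks <- read_maf(sc$maf, species_class = cls)
    masks <- if (!is.null(sc$mask)) read_bed(sc$mask) else NULL
    params <- do.call(scan_params, sc$params %||% list())
    cnes <- scan_cnes(blocks, masks, params)
    write_stage_output(function(p) write_bed(cnes, p),
                       file.path(cfg$out_dir, "cnes.bed"))
    write_stage_output(function(p) {
      write.table(cnes, p, sep = "\t", quote = FALSE, row.names = FALSE)
    }, file.path(cfg$out_dir, "cnes.tsv"))
    cnes
  })

  run_stage("pairwise", function() {
    pw <- cfg$pairwise
    if (is.null(pw)) stop("no pairwise configuration")
    query <- read_single_fasta(pw$query_fasta)
    if (!is.null(pw$query_mask)) {
      query <- mask_sequence(query, read_bed(pw$query_mask))
    }
    params <- do.call(pairwise_params, pw$params %||% list())
    hits <- do.call(rbind, lapply(pw$subjects, function(s) {
      h <- find_hits(query, read_single_fasta(s$fasta), params,
                     query_id = "query", subject_id = s$species)
      if (nrow(h)) {
        cbind(species = s$species, paralog = s$paralog, h,
              stringsAsFactors = FALSE)
      } else {
        NULL
      }
    }))
    if (is.null(hits)) hits <- cbind(species = character(),
                                     paralog = character(), empty_hits())
    write_stage_output(function(p) {
      write.table(hits, p, sep = "\t", quote = FALSE, row.names = FALSE)
    }, file.path(cfg$out_dir, "hits.tsv"))
    hits
  })

  run_stage("partition", function() {
    # ancestral CNEs: an explicit BED in query coordinates takes precedence
    # over the scan stage's calls (the two searches use different references)
    anc <- if (!is.null(cfg$partition$cnes_bed)) {
      df <- read_bed(cfg$partition$cnes_bed, merge = FALSE)
      if (!"name" %in% names(df)) {
        df$name <- sprintf("cne_%d", seq_len(nrow(df)))
      }
      df
    } else {
      results$scan
    }
    if (is.null(anc) || is.null(results$pairwise)) {
      stop("partition needs ancestral CNEs (scan stage or partition$cnes_bed) ",
           "and the pairwise stage")
    }
    part <- build_partition(anc, results$pairwise)
    write_stage_output(function(p) {
      write.table(part, p, sep = "\t", quote = FALSE, row.names = FALSE)
    }, file.path(cfg$out_dir, "partition.tsv"))
    part
  })

  run_stage("asymmetry", function() {
    if (is.null(results$partition)) stop("asymmetry needs partition")
    s <- summarize_partition(results$partition,
                             cfg$aggregation %||% "any_species")
    write_stage_output(function(p) {
      jsonlite::write_json(unclass(s), p, auto_unbox = TRUE, digits = NA,
                           na = "null")
    }, file.path(cfg$out_dir, "asymmetry.json"))
    s
  })

  run_stage("landscape", function() {
    lc <- cfg$landscape
    if (is.null(lc)) stop("no landscape configuration")
    rep <- summarize_landscape(read_landscape(lc$matrix))
    write_stage_output(function(p) {
      jsonlite::write_json(unclass(rep), p, auto_unbox = TRUE, digits = NA,
                           na = "null")
    }, file.path(cfg$out_dir, "landscape.json"))
    rep
  })

  run_stage("ddct", function() {
    dd <- cfg$ddct
    if (is.null(dd)) stop("no ddct configuration")
    calls <- quantify_ddct(read_cq_table(dd$cq), dd$reference_gene,
                           dd$calibrator_sample)
    write_stage_output(function(p) {
      write.table(calls, p, sep = "\t", quote = FALSE, row.names = FALSE)
    }, file.path(cfg$out_dir, "expression.tsv"))
    calls
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("ohnocne")),
    seed = cfg$seed,
    stages = cfg$stages,
    config = unclass(cfg),
    input_checksums = input_checksums(cfg),
    output_checksums = local({
      outs <- list.files(cfg$out_dir, full.names = TRUE)
      outs <- outs[!grepl("manifest\\.json$|\\.partial$", outs)]
      as.list(tools::md5sum(outs))
    }))
  write_stage_output(function(p) {
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }, file.path(cfg$out_dir, "manifest.json"))
  invisible(results)
}

input_checksums <- function(cfg) {
  inputs <- c(cfg$scan$maf, cfg$scan$mask, cfg$pairwise$query_fasta,
              cfg$pairwise$query_mask,
              vapply(cfg$pairwise$subjects %||% list(),
                     function(s) s$fasta, character(1)),
              cfg$landscape$matrix, cfg$ddct$cq)
  if (!length(inputs)) return(list())
  as.list(tools::md5sum(inputs))
}

read_single_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L) {
    stop("expected a single-sequence FASTA: ", path, call. = FALSE)
  }
  as.character(ss[[1L]])
}
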
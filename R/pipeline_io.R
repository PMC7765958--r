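## File formats: expression and annotation TSV, GMT gene sets, 3-column
## target-prediction TSV, gene-reaction-pathway mapping TSV, DE tables.
## All readers validate strictly and report offending rows/columns.

#' Read a log2 expression matrix from TSV
#'
#' First column: feature id; header row: sample ids; values numeric with
#' dot decimal. Duplicated feature ids, ragged rows and non-numeric cells
#' are errors naming the offending row/column.
#'
#' @param path TSV file path.
#' @return numeric matrix, features x samples.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fields <- count.fields(path, sep = "\t", quote = "")
  if (length(unique(fields)) > 1L) {
    bad <- which(fields != fields[[1L]])[[1L]]
    stop("ragged TSV: line ", bad, " of ", path, " has ", fields[bad],
         " fields, expected ", fields[[1L]])
  }
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicated feature id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad)) {
        stop("non-numeric value '", v[bad[[1L]]], "' at row ", bad[[1L]],
             " (feature ", ids[bad[[1L]]], "), column '",
             names(vals)[[j]], "' of ", path)
      }
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

#' Write a log2 expression matrix as TSV
#' @param matrix numeric matrix with dimnames.
#' @param path output path.
#' @param id_column header for the feature-id column.
#' @return \code{path}, invisibly.
#' @export
write_expression_tsv <- function(matrix, path, id_column = "feature_id") {
  df <- data.frame(rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column sample annotation TSV (sample_id, condition)
#' @param path TSV path.
#' @return data.frame with columns sample_id, condition.
#' @export
read_annotation_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition") %in% names(df))) {
    stop(path, " must have columns: sample_id, condition")
  }
  if (anyDuplicated(df$sample_id)) stop("duplicated sample ids in ", path)
  df[, c("sample_id", "condition")]
}

#' Write a sample annotation TSV
#' @param annotation data.frame with sample_id, condition.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_annotation_tsv <- function(annotation, path) {
  write.table(annotation[, c("sample_id", "condition")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Tab-separated: set name, description, then member ids.
#'
#' @param path GMT path.
#' @return named list of character vectors (the descriptions are kept as
#'   a \code{"descriptions"} attribute).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short)) {
    stop("GMT line ", short[[1L]], " of ", path,
         " has fewer than 3 fields (name, description, members...)")
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicated set names in ", path)
  attr(sets, "descriptions") <- vapply(parts, `[[`, "", 2L)
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector (recycled "na" default).
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[[i]], descriptions[[i]], sets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read miRNA-target predictions from a 3-column TSV
#' @param path TSV with columns mirna_id, gene_id, source.
#' @return a \code{target_database_set}.
#' @export
read_targets_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mirna_id", "gene_id", "source") %in% names(df))) {
    stop(path, " must have columns: mirna_id, gene_id, source")
  }
  sources <- lapply(split(df[, c("mirna_id", "gene_id")], df$source),
                    function(d) { rownames(d) <- NULL; d })
  structure(list(sources = sources, pairs = df),
            class = "target_database_set")
}

#' Write miRNA-target predictions as TSV
#' @param dbset a \code{target_database_set}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_targets_tsv <- function(dbset, path) {
  write.table(dbset$pairs[, c("mirna_id", "gene_id", "source")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-reaction-pathway mapping TSV
#' @param path TSV with columns gene_id, reaction_id, pathway.
#' @return list(gene2reaction, reaction2pathway) as used by
#'   \code{\link{map_to_reactions}}.
#' @export
read_reaction_mapping_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "reaction_id", "pathway") %in% names(df))) {
    stop(path, " must have columns: gene_id, reaction_id, pathway")
  }
  list(gene2reaction = unique(df[, c("gene_id", "reaction_id")]),
       reaction2pathway = unique(df[, c("reaction_id", "pathway")]))
}

#' Write a gene-reaction-pathway mapping TSV
#' @param mapping list(gene2reaction, reaction2pathway).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_reaction_mapping_tsv <- function(mapping, path) {
  df <- merge(mapping$gene2reaction, mapping$reaction2pathway,
              by = "reaction_id")
  df <- df[order(df$gene_id, df$reaction_id),
           c("gene_id", "reaction_id", "pathway")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a differential-expression table
#' @param records DE data.frame.
#' @param path TSV path.
#' @return \code{path} (write) or the records (read).
#' @export
write_de_table <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_de_table
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a simulation configuration as YAML
#'
#' Bit-exact round trip of every \code{\link{simulation_config}} field.
#'
#' @param config a \code{simulation_config}.
#' @param path YAML file path.
#' @return \code{path} (write) or the validated config (read).
#' @export
write_simulation_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  out <- unclass(config)
  out$samples_per_condition <- as.list(out$samples_per_condition)
  yaml::write_yaml(out, path, precision = 17L)
  invisible(path)
}

#' @rdname write_simulation_config
#' @export
read_simulation_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- yaml::read_yaml(path)
  raw$samples_per_condition <- unlist(raw$samples_per_condition)
  do.call(simulation_config, raw)
}

#' Assemble a pipeline configuration
#'
#' Every numeric threshold of the analysis chain with its default:
#' gene signature adjusted p 0.05; miRNA |log2fc| 0.25 and raw p 0.01;
#' Fisher enrichment 0.05; MI tail probability 1e-7; gene-set ranking raw
#' p 0.05 with Benjamini-Yekutieli alpha 0.05; database consensus 2.
#'
#' @param contrasts character vector of contrast strings.
#' @param output_dir output directory.
#' @param seed integer seed.
#' @param gene_adj_p,mirna_fc,mirna_p,fisher_alpha,mi_p_target numeric
#'   thresholds (see description).
#' @param gsea_raw_p,by_alpha,min_sources further thresholds.
#' @param mi_n_perm permutations for the MI null.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(contrasts = c("HFepa_vs_reference",
                                          "HFoleic_vs_reference"),
                            output_dir = tempfile("mirmaster_run_"),
                            seed = 1L,
                            gene_adj_p = 0.05, mirna_fc = 0.25,
                            mirna_p = 0.01, fisher_alpha = 0.05,
                            mi_p_target = 1e-7, gsea_raw_p = 0.05,
                            by_alpha = 0.05, min_sources = 2L,
                            mi_n_perm = 2000L) {
  stopifnot(gene_adj_p > 0, mirna_fc > 0, mirna_p > 0, fisher_alpha > 0,
            mi_p_target > 0, gsea_raw_p > 0, by_alpha > 0,
            min_sources >= 1L)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline on a study
#'
#' Executes, for each configured contrast: gene differential expression
#' and signature construction, the four-step master-regulator analysis,
#' gene-set enrichment of the fold-change-ranked genes, and the metabolic
#' reaction/pathway enrichment; then simulates the packaged hepatic
#' logical-model environments. All stage outputs are written as TSV/JSON
#' under \code{config$output_dir} together with a run manifest (config
#' snapshot, package version, per-file hashes, timestamps).
#'
#' @param study an \code{\link{expression_study}}.
#' @param dbset a \code{target_database_set}.
#' @param pathways named list of gene sets (GMT-style).
#' @param reaction_mapping list(gene2reaction, reaction2pathway).
#' @param config a \code{\link{pipeline_config}}.
#' @return the run manifest (list), invisibly; side effect: files under
#'   \code{config$output_dir}.
#' @export
run_pipeline <- function(study, dbset, pathways, reaction_mapping,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)
  written <- character(0)
  emit <- function(path) { written <<- c(written, path); path }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  signatures <- list()
  for (contrast in config$contrasts) {
    de <- stage("diffexpr", differential_expression(
      study$gene_matrix, study$annotation, contrast,
      adj_threshold = config$gene_adj_p))
    emit(write_de_table(de, out(paste0("de_genes_", contrast, ".tsv"))))
    sig <- build_signature(de, config$gene_adj_p)
    signatures[[contrast]] <- sig
    emit(write_gmt(list(up = sig$up, down = sig$down),
                   out(paste0("signature_", contrast, ".gmt"))))

    mmra <- stage("mmra", run_mmra(
      study, dbset, contrast,
      mirna_fc_threshold = config$mirna_fc,
      mirna_p_threshold = config$mirna_p,
      signature_threshold = config$gene_adj_p,
      fisher_alpha = config$fisher_alpha,
      mi_p_target = config$mi_p_target,
      mi_n_perm = config$mi_n_perm,
      min_sources = config$min_sources,
      seed = config$seed))
    emit(write_de_table(mmra$pairs,
                        out(paste0("mmra_pairs_", contrast, ".tsv"))))
    jsonlite::write_json(
      list(contrast = contrast, counts = as.list(mmra$counts),
           audit = mmra$audit),
      emit(out(paste0("mmra_audit_", contrast, ".json"))),
      auto_unbox = TRUE, digits = NA)

    ranked <- stage("enrichment", rank_by_fc(de, config$gsea_raw_p))
    enr <- stage("enrichment", enrich_collection(
      ranked, pathways, adjust = "BY", alpha = config$by_alpha))
    emit(write_de_table(enr, out(paste0("gsea_", contrast, ".tsv"))))
  }

  if (all(c("HFoleic_vs_reference", "HFepa_vs_reference") %in%
            names(signatures))) {
    attributed <- stage("metmap", map_to_reactions(signatures,
                                                   reaction_mapping))
    emit(write_de_table(attributed$reactions, out("reactions.tsv")))
    rpe <- stage("metmap", reaction_pathway_enrichment(attributed,
                                                       reaction_mapping))
    emit(write_de_table(rpe, out("reaction_pathways.tsv")))
  }

  model <- stage("logicmodel", hepatic_model())
  report <- stage("logicmodel",
                  simulate_environments(model, hepatic_environments()))
  emit(write_environment_report(report, out("logic_environments.tsv")))

  manifest <- list(
    config = unclass(config),
    package_version = as.character(utils::packageVersion("mirmaster")),
    timestamp = format(Sys.time(), tz = "UTC"),
    outputs = lapply(setNames(nm = basename(written)), function(b) {
      unname(tools::md5sum(out(b)))
    })
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
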
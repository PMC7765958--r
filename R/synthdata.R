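#' Simulation configuration for a paired gene/miRNA expression study
#'
#' Collects every tunable of the synthetic-data generator. The generator
#' emulates a three-arm liver feeding study profiled on both a gene
#' expression array and small-RNA sequencing: quantile-normalized log2
#' matrices, a reference arm and two high-fat arms, a set of genes
#' differentially expressed in both high-fat arms, and a set of repressive
#' miRNA-gene regulations planted so that up-shifted miRNAs drive
#' down-shifted target genes (and vice versa).
#'
#' @param n_genes number of gene features.
#' @param n_mirnas number of miRNA features.
#' @param samples_per_condition named integer vector giving the number of
#'   samples for each of the conditions \code{reference}, \code{HFoleic} and
#'   \code{HFepa}. All entries must be at least 3 so that two-sample tests
#'   are defined.
#' @param n_planted_regulations number of repressive (miRNA, gene) pairs
#'   planted into the matrices; each target gene has exactly one regulator.
#' @param n_de_genes total number of differentially expressed genes
#'   (planted targets included); DE is shared between the two high-fat arms.
#' @param n_de_mirnas total number of differentially expressed miRNAs
#'   (planted regulators included).
#' @param effect_size_de mean log2 shift of a DE gene in the high-fat arms.
#' @param effect_size_mirna mean log2 shift of a DE miRNA.
#' @param repression_strength fraction (in [0, 1)) of a target gene's
#'   within-condition variance explained by its planted regulator.
#' @param noise_sd within-condition standard deviation, log2 units.
#' @param targets_per_mirna average number of planted targets per regulator.
#' @param db_overlap probability that a true regulation is reported by each
#'   of the three mock target databases, independently.
#' @param db_false_rate expected number of spurious predictions per miRNA
#'   per database source.
#' @param seed integer seed; the same seed reproduces the study, the target
#'   databases and the pathway fixtures bit for bit.
#' @return an object of class \code{simulation_config} (a validated list).
#' @export
#' @examples
#' cfg <- simulation_config(n_genes = 100, n_mirnas = 20, seed = 1)
#' study <- generate_study(cfg)
#' dim(study$gene_matrix)
simulation_config <- function(n_genes = 500L,
                              n_mirnas = 60L,
                              samples_per_condition = c(reference = 9L,
                                                        HFoleic = 8L,
                                                        HFepa = 7L),
                              n_planted_regulations = 60L,
                              n_de_genes = 100L,
                              n_de_mirnas = 25L,
                              effect_size_de = 2,
                              effect_size_mirna = 1.5,
                              repression_strength = 0.8,
                              noise_sd = 0.5,
                              targets_per_mirna = 10L,
                              db_overlap = 0.9,
                              db_false_rate = 5,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_mirnas = as.integer(n_mirnas),
              samples_per_condition = samples_per_condition,
              n_planted_regulations = as.integer(n_planted_regulations),
              n_de_genes = as.integer(n_de_genes),
              n_de_mirnas = as.integer(n_de_mirnas),
              effect_size_de = effect_size_de,
              effect_size_mirna = effect_size_mirna,
              repression_strength = repression_strength,
              noise_sd = noise_sd,
              targets_per_mirna = as.integer(targets_per_mirna),
              db_overlap = db_overlap,
              db_false_rate = db_false_rate,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  stopifnot(cfg$n_genes > 0L, cfg$n_mirnas > 0L,
            cfg$n_planted_regulations >= 0L,
            cfg$targets_per_mirna > 0L,
            cfg$noise_sd > 0)
  spc <- cfg$samples_per_condition
  if (!setequal(names(spc), STUDY_CONDITIONS)) {
    stop("samples_per_condition must be named exactly ",
         paste(STUDY_CONDITIONS, collapse = ", "))
  }
  if (any(spc < 3L)) {
    stop("samples_per_condition must be >= 3 in every arm; ",
         "two-sample tests are undefined below that")
  }
  if (cfg$repression_strength < 0 || cfg$repression_strength >= 1) {
    stop("repression_strength must lie in [0, 1); a value of 1 would make ",
         "target genes noiseless functions of their regulator")
  }
  if (cfg$db_overlap < 0 || cfg$db_overlap > 1) stop("db_overlap must be in [0, 1]")
  if (cfg$db_false_rate < 0) stop("db_false_rate must be non-negative")
  if (cfg$n_de_genes < cfg$n_planted_regulations) {
    stop("n_de_genes must be at least n_planted_regulations ",
         "(planted targets are DE by construction)")
  }
  if (cfg$n_de_genes > cfg$n_genes) stop("n_de_genes exceeds n_genes")
  if (cfg$n_planted_regulations > cfg$n_genes) {
    stop("n_planted_regulations exceeds n_genes (one regulator per target)")
  }
  n_reg <- n_regulator_mirnas(cfg)
  if (n_reg > cfg$n_mirnas) {
    stop("too many regulator miRNAs required; increase n_mirnas or ",
         "targets_per_mirna")
  }
  if (cfg$n_de_mirnas < n_reg) {
    stop("n_de_mirnas must be at least the number of regulator miRNAs (",
         n_reg, ")")
  }
  if (cfg$n_de_mirnas > cfg$n_mirnas) stop("n_de_mirnas exceeds n_mirnas")
  invisible(cfg)
}

n_regulator_mirnas <- function(cfg) {
  if (cfg$n_planted_regulations == 0L) 0L
  else as.integer(ceiling(cfg$n_planted_regulations / cfg$targets_per_mirna))
}

#' A small desk-scale configuration and the full-scale preset
#'
#' \code{paper_scale_config} mirrors the dimensions of a genome-wide liver
#' array paired with a small-RNA-seq miRNome (tens of thousands of gene
#' probes, hundreds of miRNAs); it is provided for completeness and is not
#' used by the test suite.
#'
#' @inheritParams simulation_config
#' @param ... overrides passed on to \code{\link{simulation_config}}.
#' @return a \code{simulation_config}.
#' @export
paper_scale_config <- function(seed = 1L, ...) {
  simulation_config(n_genes = 60000L, n_mirnas = 600L,
                    n_planted_regulations = 200L, n_de_genes = 1000L,
                    n_de_mirnas = 120L, seed = seed, ...)
}

#' Generate a paired gene/miRNA expression study with planted truth
#'
#' Values are generated directly on the normalized log2 scale. Every
#' feature's within-condition variance equals \code{noise_sd^2}. A planted
#' target gene is repressed linearly by its regulator miRNA: the regulator
#' explains \code{repression_strength} of the gene's within-condition
#' variance, with a negative slope, and the gene's total condition shift
#' equals \code{effect_size_de} in the direction opposite to its
#' regulator's shift.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return an object of class \code{expression_study}: a list with
#'   \code{gene_matrix}, \code{mirna_matrix} (features x samples, log2),
#'   \code{annotation} (data.frame sample_id, condition), and \code{truth}
#'   (planted regulations and per-contrast DE sets).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  validate_simulation_config(config)
  set.seed(config$seed)

  spc <- config$samples_per_condition[STUDY_CONDITIONS]
  condition <- rep(STUDY_CONDITIONS, times = spc)
  n_samples <- length(condition)
  sample_id <- sprintf("S%02d_%s", seq_len(n_samples), condition)
  is_hf <- as.numeric(condition != "reference")

  gene_ids <- sprintf("gene%04d", seq_len(config$n_genes))
  mirna_ids <- sprintf("mmu-miR-%03d", seq_len(config$n_mirnas))

  ## --- plant regulations ------------------------------------------------
  n_pairs <- config$n_planted_regulations
  n_reg <- n_regulator_mirnas(config)
  target_genes <- sample(gene_ids, n_pairs)
  regulator_pool <- sample(mirna_ids, n_reg)
  pair_mirna <- if (n_pairs > 0L) {
    regulator_pool[rep_len(seq_len(n_reg), n_pairs)]
  } else character(0)

  ## regulator direction: +1 (up in HF arms) or -1; its targets move the
  ## opposite way, reproducing the anti-correlated direction pattern
  reg_sign <- setNames(sample(c(-1, 1), n_reg, replace = TRUE), regulator_pool)

  ## --- miRNA matrix -----------------------------------------------------
  mu_m <- runif(config$n_mirnas, 4, 12)
  delta_m <- setNames(numeric(config$n_mirnas), mirna_ids)
  delta_m[regulator_pool] <- reg_sign * config$effect_size_mirna
  extra_mirnas <- sample(setdiff(mirna_ids, regulator_pool),
                         config$n_de_mirnas - n_reg)
  delta_m[extra_mirnas] <- sample(c(-1, 1), length(extra_mirnas),
                                  replace = TRUE) * config$effect_size_mirna
  mirna_matrix <- mu_m + outer(delta_m, is_hf) +
    matrix(rnorm(config$n_mirnas * n_samples, sd = config$noise_sd),
           config$n_mirnas, n_samples)
  dimnames(mirna_matrix) <- list(mirna_ids, sample_id)

  ## --- gene matrix ------------------------------------------------------
  mu_g <- runif(config$n_genes, 4, 12)
  delta_g <- setNames(numeric(config$n_genes), gene_ids)
  gene_sign <- setNames(numeric(0), character(0))
  if (n_pairs > 0L) {
    gene_sign[target_genes] <- -reg_sign[pair_mirna]
    delta_g[target_genes] <- gene_sign[target_genes] * config$effect_size_de
  }
  extra_genes <- sample(setdiff(gene_ids, target_genes),
                        config$n_de_genes - n_pairs)
  extra_sign <- sample(c(-1, 1), length(extra_genes), replace = TRUE)
  delta_g[extra_genes] <- extra_sign * config$effect_size_de
  gene_sign[extra_genes] <- extra_sign

  rs <- config$repression_strength
  b <- sqrt(rs)                       # repression slope on the log2 scale
  resid_sd <- config$noise_sd * sqrt(1 - rs)

  gene_matrix <- mu_g + outer(delta_g, is_hf) +
    matrix(rnorm(config$n_genes * n_samples, sd = config$noise_sd),
           config$n_genes, n_samples)
  dimnames(gene_matrix) <- list(gene_ids, sample_id)
  if (n_pairs > 0L) {
    ## overwrite planted targets: condition shift routed partly through the
    ## regulator so that the total shift stays effect_size_de and the
    ## within-condition r^2 with the regulator equals repression_strength
    for (k in seq_len(n_pairs)) {
      g <- target_genes[k]; m <- pair_mirna[k]
      resid_shift <- delta_g[g] + b * delta_m[m]
      gene_matrix[g, ] <- mu_g[match(g, gene_ids)] + resid_shift * is_hf -
        b * (mirna_matrix[m, ] - mu_m[match(m, mirna_ids)]) +
        rnorm(n_samples, sd = resid_sd)
    }
  }

  de_split <- function(ids, sgn) {
    list(up = sort(ids[sgn > 0]), down = sort(ids[sgn < 0]))
  }
  de_genes <- de_split(names(gene_sign), gene_sign)
  mir_de_sign <- delta_m[delta_m != 0]
  de_mirnas <- de_split(names(mir_de_sign), sign(mir_de_sign))

  truth <- list(
    regulations = if (n_pairs > 0L) {
      data.frame(mirna_id = pair_mirna, gene_id = target_genes,
                 sign = "repressive", stringsAsFactors = FALSE)
    } else {
      data.frame(mirna_id = character(0), gene_id = character(0),
                 sign = character(0), stringsAsFactors = FALSE)
    },
    de_genes = list(HFoleic_vs_reference = de_genes,
                    HFepa_vs_reference = de_genes),
    de_mirnas = list(HFoleic_vs_reference = de_mirnas,
                     HFepa_vs_reference = de_mirnas)
  )

  structure(list(gene_matrix = gene_matrix,
                 mirna_matrix = mirna_matrix,
                 annotation = data.frame(sample_id = sample_id,
                                         condition = condition,
                                         stringsAsFactors = FALSE),
                 truth = truth,
                 config = config),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study:", nrow(x$gene_matrix), "genes x",
      ncol(x$gene_matrix), "samples;", nrow(x$mirna_matrix), "miRNAs;",
      nrow(x$truth$regulations), "planted regulations\n")
  invisible(x)
}

#' Generate three mock miRNA-target databases around the planted truth
#'
#' Mimics prediction resources in the style of miRTarBase, miRDB and
#' TargetScan: three independent sources, each reporting any true planted
#' regulation with probability \code{db_overlap} and adding spurious
#' (miRNA, gene) predictions at a Poisson rate of \code{db_false_rate} per
#' miRNA.
#'
#' @param study an \code{\link{expression_study}} (its recorded truth and
#'   feature universes are used).
#' @param config the \code{\link{simulation_config}} used for the study.
#' @return an object of class \code{target_database_set}: list with
#'   \code{sources} (named list source -> data.frame(mirna_id, gene_id))
#'   and \code{pairs} (long data.frame mirna_id, gene_id, source).
#' @export
generate_target_databases <- function(study, config = study$config) {
  stopifnot(inherits(study, "expression_study"))
  set.seed(config$seed + 1L)
  sources <- c("dbA", "dbB", "dbC")
  truth <- study$truth$regulations
  gene_ids <- rownames(study$gene_matrix)
  mirna_ids <- rownames(study$mirna_matrix)

  out <- list()
  for (src in sources) {
    keep <- if (nrow(truth)) runif(nrow(truth)) < config$db_overlap else logical(0)
    true_part <- truth[keep, c("mirna_id", "gene_id"), drop = FALSE]
    n_false <- rpois(length(mirna_ids), config$db_false_rate)
    false_part <- data.frame(
      mirna_id = rep(mirna_ids, n_false),
      gene_id = sample(gene_ids, sum(n_false), replace = TRUE),
      stringsAsFactors = FALSE)
    part <- unique(rbind(true_part, false_part))
    part <- part[order(part$mirna_id, part$gene_id), , drop = FALSE]
    rownames(part) <- NULL
    out[[src]] <- part
  }
  pairs <- do.call(rbind, lapply(names(out), function(s) {
    p <- out[[s]]
    p$source <- rep(s, nrow(p))
    p
  }))
  rownames(pairs) <- NULL
  structure(list(sources = out, pairs = pairs),
            class = "target_database_set")
}

#' Generate pathway gene sets and a gene-reaction-pathway mapping
#'
#' Builds (i) a collection of pathway gene sets, a subset of which is
#' enriched by construction in planted DE genes (80 percent members drawn
#' from one DE direction), and (ii) a many-to-many gene-to-reaction map
#' with a reaction-to-pathway grouping in the style of a genome-scale
#' metabolic network, with some reaction pathways dominated by DE-gene
#' catalyzed reactions. Ground truth for both is recorded.
#'
#' @param study an \code{\link{expression_study}}.
#' @param config the study's \code{\link{simulation_config}}.
#' @param n_pathways number of gene-set pathways.
#' @param n_enriched how many of them are truly enriched by construction.
#' @param pathway_size members per pathway.
#' @param enriched_fraction fraction of an enriched pathway's members drawn
#'   from planted DE genes of a single direction.
#' @param n_reaction_pathways number of metabolic reaction pathways.
#' @param reactions_per_pathway reactions per metabolic pathway.
#' @return list with \code{pathways} (named list of gene-id vectors),
#'   \code{reactions} (list \code{gene2reaction}, \code{reaction2pathway}),
#'   and \code{truth} (truly enriched pathway names and directions).
#' @export
generate_pathways_and_reactions <- function(study, config = study$config,
                                            n_pathways = 15L,
                                            n_enriched = 4L,
                                            pathway_size = 25L,
                                            enriched_fraction = 0.8,
                                            n_reaction_pathways = 8L,
                                            reactions_per_pathway = 10L) {
  stopifnot(inherits(study, "expression_study"))
  gene_ids <- rownames(study$gene_matrix)
  if (pathway_size > length(gene_ids)) {
    stop("pathway_size exceeds the gene universe size")
  }
  set.seed(config$seed + 2L)
  de <- study$truth$de_genes$HFepa_vs_reference
  de_all <- c(de$up, de$down)
  non_de <- setdiff(gene_ids, de_all)

  pathways <- list()
  truth_dir <- character(0)
  for (i in seq_len(n_pathways)) {
    nm <- sprintf("PW%02d", i)
    if (i <= n_enriched) {
      dir <- if (i %% 2L == 1L) "up" else "down"
      pool <- de[[dir]]
      k <- min(length(pool), round(enriched_fraction * pathway_size))
      members <- c(sample(pool, k),
                   sample(non_de, pathway_size - k))
      truth_dir[nm] <- dir
    } else {
      members <- sample(non_de, min(pathway_size, length(non_de)))
    }
    pathways[[nm]] <- sort(unique(members))
  }

  ## reaction layer: each reaction pathway owns a block of reactions; the
  ## first two pathways are catalyzed mostly by DE genes
  g2r <- list(); r2p <- list()
  rx_counter <- 0L
  enriched_rx_pathways <- character(0)
  for (i in seq_len(n_reaction_pathways)) {
    pnm <- sprintf("RXPW%02d", i)
    de_dominated <- i <= 2L
    if (de_dominated) enriched_rx_pathways <- c(enriched_rx_pathways, pnm)
    for (j in seq_len(reactions_per_pathway)) {
      rx_counter <- rx_counter + 1L
      rid <- sprintf("R_%04d", rx_counter)
      r2p[[rid]] <- pnm
      pool <- if (de_dominated && length(de_all)) de_all else non_de
      catalysts <- sample(pool, sample(1:3, 1L), replace = FALSE)
      g2r[[rid]] <- catalysts
    }
  }
  gene2reaction <- data.frame(
    gene_id = unlist(g2r, use.names = FALSE),
    reaction_id = rep(names(g2r), lengths(g2r)),
    stringsAsFactors = FALSE)
  reaction2pathway <- data.frame(
    reaction_id = names(r2p),
    pathway = unlist(r2p, use.names = FALSE),
    stringsAsFactors = FALSE)

  list(pathways = pathways,
       reactions = list(gene2reaction = gene2reaction,
                        reaction2pathway = reaction2pathway),
       truth = list(enriched_pathways = truth_dir,
                    enriched_reaction_pathways = enriched_rx_pathways))
}
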
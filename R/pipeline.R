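## Pipeline orchestration: simulate -> events -> quantify -> orthology
## -> analyze -> report, over a dataset directory of TSV/GTF artifacts.
## Every output table carries a header comment naming the producing
## step and the configuration hash, and every stage is deterministic
## given the seed.

#' Pipeline configuration
#'
#' @param data_dir directory of input artifacts (GTFs, counts.tsv,
#'   orthologs.tsv, design.tsv) — written by the `simulate` step or
#'   supplied by the user.
#' @param out_dir directory for analysis outputs.
#' @param seed integer seed (drives the `simulate` step).
#' @param fpkm_threshold expressed-flag cutoff (strict).
#' @param overlap_threshold ortholog overlap cutoff (strict).
#' @param min_each per-form read minimum for AS classification.
#' @param delta_weak,delta_strong delta-psi thresholds (strict).
#' @param body_reads "include" or "exclude".
#' @param sim a [sim_config] for the `simulate` step.
#' @param log_level "quiet" or "info".
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(data_dir, out_dir = file.path(data_dir, "out"),
                            seed = 1, fpkm_threshold = 1,
                            overlap_threshold = 0.5, min_each = 1,
                            delta_weak = 0.10, delta_strong = 0.7,
                            body_reads = c("include", "exclude"),
                            sim = sim_config(seed = seed),
                            log_level = c("info", "quiet")) {
  body_reads <- match.arg(body_reads)
  log_level <- match.arg(log_level)
  stopifnot(fpkm_threshold >= 0, overlap_threshold >= 0,
            overlap_threshold <= 1, min_each >= 0,
            delta_weak >= 0, delta_weak <= 1,
            delta_strong >= 0, delta_strong <= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

.config_hash <- function(cfg) {
  # hash the scientific configuration, not filesystem locations
  keep <- setdiff(sort(names(cfg)), c("data_dir", "out_dir"))
  s <- paste(deparse(unclass(cfg)[keep]), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

.plog <- function(cfg, ...) {
  if (identical(cfg$log_level, "info")) {
    message("[splicecomp] ", ...)
  }
}

.write_step_tsv <- function(df, path, step, cfg) {
  header <- sprintf("# splicecomp step=%s config_hash=%s seed=%d",
                    step, .config_hash(cfg), cfg$seed)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

.require_artifact <- function(path, producer) {
  if (!file.exists(path)) {
    stop("missing artifact '", basename(path), "'; run the '", producer,
         "' step first", call. = FALSE)
  }
  path
}

#' Run pipeline steps
#'
#' Steps, in their natural order:
#' \describe{
#'   \item{simulate}{generate a synthetic dataset + truth into
#'     `data_dir`.}
#'   \item{events}{enumerate AS events per species from the GTFs.}
#'   \item{quantify}{expression and psi estimates per sample.}
#'   \item{orthology}{filter/resolve/intersect ortholog sets.}
#'   \item{analyze}{cross-species profile matrices, correlations,
#'     clustering, PCA, JSD, label dominance, sex-bias and (for embryo
#'     designs) maternal/zygotic summaries, per-sample metrics.}
#'   \item{report}{one markdown summary of the main tables.}
#' }
#'
#' @param config a [pipeline_config].
#' @param steps character vector of steps to run, in order.
#' @return the config, invisibly.
#' @export
run_pipeline <- function(config,
                         steps = c("simulate", "events", "quantify",
                                   "orthology", "analyze", "report")) {
  known <- c("simulate", "events", "quantify", "orthology", "analyze",
             "report")
  bad <- setdiff(steps, known)
  if (length(bad) > 0) {
    stop("unknown step(s): ", paste(bad, collapse = ", "),
         "; valid steps are: ", paste(known, collapse = ", "))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (s in steps) {
    .plog(config, "step: ", s)
    switch(s,
           simulate = .step_simulate(config),
           events = .step_events(config),
           quantify = .step_quantify(config),
           orthology = .step_orthology(config),
           analyze = .step_analyze(config),
           report = .step_report(config))
  }
  invisible(config)
}

.step_simulate <- function(cfg) {
  truth <- draw_profiles(generate_annotations(cfg$sim))
  write_sim_dataset(truth, cfg$data_dir)
  invisible(truth)
}

.pipeline_species <- function(cfg) {
  design <- .read_tsv(.require_artifact(
    file.path(cfg$data_dir, "design.tsv"), "simulate"))
  unique(design$species)
}

.step_events <- function(cfg) {
  for (sp in .pipeline_species(cfg)) {
    ann <- read_gtf(.require_artifact(
      file.path(cfg$data_dir, paste0(sp, ".gtf")), "simulate"),
      species = sp)
    ev <- enumerate_all_events(ann)
    .write_step_tsv(ev, file.path(cfg$out_dir, paste0("events_", sp, ".tsv")),
                    "events", cfg)
    .write_step_tsv(classify_exons(ann, ev),
                    file.path(cfg$out_dir, paste0("exon_classes_", sp, ".tsv")),
                    "events", cfg)
  }
}

.pipeline_load_events <- function(cfg, sp) {
  .read_tsv(.require_artifact(
    file.path(cfg$out_dir, paste0("events_", sp, ".tsv")), "events"))
}

.step_quantify <- function(cfg) {
  design <- .read_tsv(.require_artifact(
    file.path(cfg$data_dir, "design.tsv"), "simulate"))
  counts <- .read_tsv(.require_artifact(
    file.path(cfg$data_dir, "counts.tsv"), "simulate"))
  counts$feature_id[is.na(counts$feature_id)] <- ""
  psi_all <- list()
  expr_all <- list()
  for (sp in unique(design$species)) {
    ev <- .pipeline_load_events(cfg, sp)
    for (i in which(design$species == sp)) {
      smp <- design[i, ]
      sub <- counts[counts$sample_id == smp$sample_id, , drop = FALSE]
      if (nrow(ev) > 0) {
        psi_all[[length(psi_all) + 1L]] <-
          estimate_psi(ev, sub, smp, body_reads = cfg$body_reads,
                       min_each = cfg$min_each)
      }
      gene_rows <- sub[sub$feature_type == "gene", , drop = FALSE]
      glen <- gene_rows$end - gene_rows$start
      names(glen) <- gene_rows$feature_id
      expr <- compute_expression(gene_rows, library_size(sub, smp$sample_id),
                                 glen, fpkm_threshold = cfg$fpkm_threshold)
      expr$sample_id <- smp$sample_id
      expr_all[[length(expr_all) + 1L]] <- expr
    }
  }
  psi_df <- if (length(psi_all)) do.call(rbind, psi_all) else
    data.frame(event_id = character(), sample_id = character(),
               I = numeric(), S = numeric(), l_inc = numeric(),
               l_exc = numeric(), psi = numeric(),
               as_classified = logical())
  .write_step_tsv(psi_df, file.path(cfg$out_dir, "psi_estimates.tsv"),
                  "quantify", cfg)
  .write_step_tsv(do.call(rbind, expr_all),
                  file.path(cfg$out_dir, "expression_gene.tsv"),
                  "quantify", cfg)
}

.step_orthology <- function(cfg) {
  pairs <- read_ortholog_pairs_classed(.require_artifact(
    file.path(cfg$data_dir, "orthologs.tsv"), "simulate"))
  for (cls in unique(pairs$class)) {
    sub <- filter_overlap(pairs[pairs$class == cls, ],
                          threshold = cfg$overlap_threshold)
    mappings <- lapply(split(sub, sub$species), resolve_one_to_one)
    sets <- intersect_across_species(mappings)
    write_ortholog_sets(sets, file.path(cfg$out_dir,
                                        paste0("ortholog_sets_", cls, ".tsv")))
  }
}

#' Read an ortholog pair table that carries a feature-class column
#' @param path TSV with hub_feature_id, species, feature_id, overlap,
#'   class.
#' @return data.frame.
#' @export
read_ortholog_pairs_classed <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!"class" %in% names(out)) out$class <- "gene"
  out
}

# condition-averaged TPM matrix over ortholog gene sets
.tpm_profile_matrix <- function(expr, design, sets) {
  cond <- sprintf("%s.%s.%s", design$species, design$context, design$sex)
  conds <- unique(cond)
  cond_meta <- unique(design[, c("species", "context", "sex")])
  m <- matrix(NA_real_, nrow(sets), length(conds),
              dimnames = list(sets$hub_feature_id, conds))
  for (j in seq_along(conds)) {
    meta <- cond_meta[j, ]
    smp <- design$sample_id[cond == conds[j]]
    sub <- expr[expr$sample_id %in% smp, ]
    tpm <- tapply(sub$tpm, sub$feature_id, mean)
    m[, j] <- tpm[sets[[meta$species]]]
  }
  m
}

# condition-averaged psi matrix over ortholog exon sets, with
# FPKM-based imputation for samples lacking an AS classification
.psi_profile_matrix <- function(cfg, psi_df, design, exon_sets,
                                events_by_species, counts) {
  species <- unique(design$species)
  # map each species' exon feature id (sp:chrom:start-end) to event_id
  ev_key <- list()
  for (sp in species) {
    ev <- events_by_species[[sp]]
    if (nrow(ev) == 0) next
    key <- sprintf("%s:%s:%d-%d", sp, ev$chrom, ev$target_start,
                   ev$target_end)
    ev_key[[sp]] <- stats::setNames(ev$event_id, key)
  }
  imputed <- .psi_imputation_table(cfg, psi_df, design, events_by_species,
                                   counts)
  cond <- sprintf("%s.%s.%s", design$species, design$context, design$sex)
  conds <- unique(cond)
  cond_meta <- unique(design[, c("species", "context", "sex")])
  m <- matrix(NA_real_, nrow(exon_sets), length(conds),
              dimnames = list(exon_sets$hub_feature_id, conds))
  val <- ifelse(psi_df$as_classified, psi_df$psi, NA_real_)
  if (nrow(imputed) > 0) {
    hit <- match(paste(psi_df$event_id, psi_df$sample_id),
                 paste(imputed$event_id, imputed$sample_id))
    use <- is.na(val) & !is.na(hit)
    val[use] <- imputed$psi_imputed[hit[use]]
  }
  for (j in seq_along(conds)) {
    meta <- cond_meta[j, ]
    sp <- meta$species
    eids <- ev_key[[sp]][exon_sets[[sp]]]
    smp <- design$sample_id[cond == conds[j]]
    sel <- psi_df$sample_id %in% smp
    mval <- tapply(val[sel], psi_df$event_id[sel],
                   function(x) if (all(is.na(x))) NA_real_ else
                     mean(x, na.rm = TRUE))
    m[, j] <- mval[eids]
  }
  m
}

# per event x sample FPKM-based psi imputation candidates: samples in
# which the event was not AS-classified although it was in some sample
# of the same species
.psi_imputation_table <- function(cfg, psi_df, design, events_by_species,
                                  counts) {
  out <- list()
  exon_rows <- counts[counts$feature_type == "exon", , drop = FALSE]
  for (sp in unique(design$species)) {
    ev <- events_by_species[[sp]]
    if (nrow(ev) == 0) next
    sp_samples <- design$sample_id[design$species == sp]
    sub <- psi_df[psi_df$sample_id %in% sp_samples, ]
    classified_any <- tapply(sub$as_classified, sub$event_id, any)
    for (sid in sp_samples) {
      cr <- exon_rows[exon_rows$sample_id == sid, , drop = FALSE]
      if (nrow(cr) == 0) next
      N <- library_size(counts, sid)
      fpkm_of <- function(s, e) {
        hit <- which(cr$start == s & cr$end == e)
        if (length(hit) == 0) return(0)
        1e9 * cr$count[hit[1]] / (N * (e - s))
      }
      srows <- sub[sub$sample_id == sid, ]
      cand <- srows$event_id[!srows$as_classified &
                               classified_any[srows$event_id] %in% TRUE]
      for (eid in cand) {
        e <- ev[ev$event_id == eid, ]
        p <- impute_psi(fpkm_of(e$target_start, e$target_end),
                        fpkm_of(e$flank_left_start, e$flank_left_end),
                        fpkm_of(e$flank_right_start, e$flank_right_end),
                        fpkm_threshold = cfg$fpkm_threshold)
        if (!is.na(p)) {
          out[[length(out) + 1L]] <- data.frame(
            event_id = eid, sample_id = sid, psi_imputed = p)
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(event_id = character(), sample_id = character(),
               psi_imputed = numeric())
}

.step_analyze <- function(cfg) {
  design <- .read_tsv(.require_artifact(
    file.path(cfg$data_dir, "design.tsv"), "simulate"))
  counts <- .read_tsv(.require_artifact(
    file.path(cfg$data_dir, "counts.tsv"), "simulate"))
  counts$feature_id[is.na(counts$feature_id)] <- ""
  psi_df <- .read_tsv(.require_artifact(
    file.path(cfg$out_dir, "psi_estimates.tsv"), "quantify"))
  expr <- .read_tsv(.require_artifact(
    file.path(cfg$out_dir, "expression_gene.tsv"), "quantify"))
  gene_sets <- .read_tsv(.require_artifact(
    file.path(cfg$out_dir, "ortholog_sets_gene.tsv"), "orthology"))
  exon_sets_path <- file.path(cfg$out_dir, "ortholog_sets_exon.tsv")
  exon_sets <- if (file.exists(exon_sets_path)) .read_tsv(exon_sets_path)
    else NULL
  species <- unique(design$species)
  events_by_species <- stats::setNames(
    lapply(species, function(sp) .pipeline_load_events(cfg, sp)), species)

  # expression-filtered ortholog gene sets (FPKM > threshold in >= 1
  # sample per species)
  expressed_by_sp <- lapply(species, function(sp) {
    smp <- design$sample_id[design$species == sp]
    unique(expr$feature_id[expr$sample_id %in% smp & expr$expressed])
  })
  names(expressed_by_sp) <- species
  gene_sets <- filter_expressed_orthologs(gene_sets, expressed_by_sp,
                                          mode = "gene")

  tpm_m <- .tpm_profile_matrix(expr, design, gene_sets)
  .write_matrix(cfg, tpm_m, "profile_tpm.tsv")

  cond_meta <- unique(design[, c("species", "context", "sex")])
  res <- list()
  cm_ge <- correlation_matrix(tpm_m, method = "spearman")
  .write_matrix(cfg, cm_ge, "correlation_ge.tsv")
  dendrogram_newick(hcluster(cm_ge),
                    file.path(cfg$out_dir, "dendrogram_ge.nwk"))
  res$dominance_ge_species <- label_dominance(cm_ge, cond_meta$species)
  res$dominance_ge_context <- label_dominance(cm_ge, cond_meta$context)
  pca_ge <- profile_pca(log2(tpm_m + 1))
  .write_matrix(cfg, pca_ge$scores, "pca_ge_scores.tsv")
  jsd_ge <- jsd_matrix(tpm_m)
  .write_matrix(cfg, jsd_ge, "jsd_ge.tsv")

  if (!is.null(exon_sets) && nrow(exon_sets) > 0) {
    as_feats <- unlist(lapply(species, function(sp) {
      ev <- events_by_species[[sp]]
      cls <- psi_df$event_id[psi_df$as_classified]
      hit <- ev[ev$event_id %in% cls, , drop = FALSE]
      sprintf("%s:%s:%d-%d", sp, hit$chrom, hit$target_start,
              hit$target_end)
    }))
    # exon-level expression: FPKM over the target interval's body
    # counts, expressed in >= 1 sample per species
    expressed_exons_by_sp <- stats::setNames(lapply(species, function(sp) {
      smp <- design$sample_id[design$species == sp]
      er <- counts[counts$feature_type == "exon" &
                     counts$sample_id %in% smp, , drop = FALSE]
      if (nrow(er) == 0) return(character(0))
      Ns <- vapply(smp, function(s) library_size(counts, s), numeric(1))
      names(Ns) <- smp
      fpkm <- 1e9 * er$count / (Ns[er$sample_id] * (er$end - er$start))
      unique(sprintf("%s:%s:%d-%d", sp, er$chrom, er$start,
                     er$end)[fpkm > cfg$fpkm_threshold])
    }), species)
    exon_sets <- filter_expressed_orthologs(
      exon_sets, expressed_exons_by_sp,
      as_features = as_feats, mode = "as_exon")
  }
  psi_m <- NULL
  if (!is.null(exon_sets) && nrow(exon_sets) > 0) {
    psi_m <- .psi_profile_matrix(cfg, psi_df, design, exon_sets,
                                 events_by_species, counts)
    .write_matrix(cfg, psi_m, "profile_psi.tsv")
    cm_as <- correlation_matrix(psi_m, method = "spearman")
    .write_matrix(cfg, cm_as, "correlation_as.tsv")
    ok <- !any(is.na(cm_as))
    if (ok) {
      dendrogram_newick(hcluster(cm_as),
                        file.path(cfg$out_dir, "dendrogram_as.nwk"))
    }
    res$dominance_as_species <- label_dominance(cm_as, cond_meta$species)
    res$dominance_as_context <- label_dominance(cm_as, cond_meta$context)
    keep <- stats::complete.cases(psi_m)
    if (sum(keep) >= 2) {
      pca_as <- profile_pca(psi_m)
      .write_matrix(cfg, pca_as$scores, "pca_as_scores.tsv")
    }
  }

  # sex-bias summaries (adult designs with two sexes)
  if (all(c("female", "male") %in% design$sex) && !is.null(psi_m)) {
    recs <- list()
    for (sp in species) {
      for (ctx in unique(design$context)) {
        cf <- sprintf("%s.%s.female", sp, ctx)
        cm_ <- sprintf("%s.%s.male", sp, ctx)
        if (!all(c(cf, cm_) %in% colnames(psi_m))) next
        recs[[length(recs) + 1L]] <- delta_psi(
          rownames(psi_m), psi_m[, cf], psi_m[, cm_],
          context = paste0(sp, ".", ctx),
          weak = cfg$delta_weak, strong = cfg$delta_strong)
      }
    }
    if (length(recs) > 0) {
      dp <- do.call(rbind, recs)
      sbs <- sex_bias_summary(dp, weak = cfg$delta_weak,
                              strong = cfg$delta_strong)
      .write_step_tsv(dp, file.path(cfg$out_dir, "delta_psi.tsv"),
                      "analyze", cfg)
      .write_step_tsv(sbs$summary,
                      file.path(cfg$out_dir, "sex_bias_summary.tsv"),
                      "analyze", cfg)
      .write_step_tsv(sbs$histogram,
                      file.path(cfg$out_dir, "sex_bias_histogram.tsv"),
                      "analyze", cfg)
    }
  }

  # maternal/zygotic summaries (embryo designs)
  if (any(grepl("^stage", design$context))) {
    stage_order <- unique(design$context)
    mz_all <- list()
    for (sp in species) {
      smp <- design[design$species == sp, ]
      e <- expr[expr$sample_id %in% smp$sample_id, ]
      e$stage <- smp$context[match(e$sample_id, smp$sample_id)]
      mz <- classify_maternal_zygotic(
        data.frame(gene_id = e$feature_id, stage = e$stage, fpkm = e$fpkm),
        stage2_label = stage_order[1], stage_order = stage_order,
        fpkm_threshold = cfg$fpkm_threshold)
      ev <- events_by_species[[sp]]
      as_genes <- unique(ev$gene_id[ev$event_id %in%
                                      psi_df$event_id[psi_df$as_classified]])
      prop <- as_proportion_by_class(mz, as_genes)
      prop$species <- sp
      mz$species <- sp
      mz_all[[length(mz_all) + 1L]] <- list(mz = mz, prop = prop)
    }
    .write_step_tsv(do.call(rbind, lapply(mz_all, `[[`, "mz")),
                    file.path(cfg$out_dir, "mz_classes.tsv"), "analyze", cfg)
    .write_step_tsv(do.call(rbind, lapply(mz_all, `[[`, "prop")),
                    file.path(cfg$out_dir, "mz_as_proportions.tsv"),
                    "analyze", cfg)
  }

  # per-sample summary metrics
  metrics <- .sample_metrics(cfg, design, counts, expr, psi_df,
                             events_by_species)
  .write_step_tsv(metrics, file.path(cfg$out_dir, "sample_metrics.tsv"),
                  "analyze", cfg)
  .write_step_tsv(data.frame(metric = names(res),
                             value = unlist(res, use.names = FALSE)),
                  file.path(cfg$out_dir, "label_dominance.tsv"),
                  "analyze", cfg)
  invisible(res)
}

.sample_metrics <- function(cfg, design, counts, expr, psi_df,
                            events_by_species) {
  gene_expr <- expr[, c("sample_id", "feature_id", "expressed")]
  out <- list()
  for (sp in unique(design$species)) {
    ev <- events_by_species[[sp]]
    exon_rows <- counts[counts$feature_type == "exon" &
                          counts$sample_id %in%
                          design$sample_id[design$species == sp], ]
    as_key <- sprintf("%d-%d", ev$target_start, ev$target_end)
    ae <- exon_rows[sprintf("%d-%d", exon_rows$start, exon_rows$end) %in%
                      as_key, , drop = FALSE]
    as_exon_expr <- do.call(rbind, lapply(
      split(ae, ae$sample_id), function(s) {
        N <- library_size(counts, s$sample_id[1])
        data.frame(sample_id = s$sample_id,
                   feature_id = sprintf("%d-%d", s$start, s$end),
                   expressed = 1e9 * s$count / (N * (s$end - s$start)) >
                     cfg$fpkm_threshold)
      }))
    if (is.null(as_exon_expr)) {
      as_exon_expr <- data.frame(sample_id = character(),
                                 feature_id = character(),
                                 expressed = logical())
    }
    sel <- gene_expr$sample_id %in% design$sample_id[design$species == sp]
    out[[sp]] <- sample_summary(gene_expr[sel, ], as_exon_expr,
                                psi_df, ev[, c("event_id", "gene_id")])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.write_matrix <- function(cfg, m, name) {
  write_matrix_tsv(m, file.path(cfg$out_dir, name))
  invisible(NULL)
}

.step_report <- function(cfg) {
  files <- c("sample_metrics.tsv", "label_dominance.tsv",
             "sex_bias_summary.tsv", "mz_as_proportions.tsv")
  lines <- c("# splicecomp pipeline report",
             sprintf("config_hash: %s", .config_hash(cfg)),
             sprintf("seed: %d", cfg$seed), "")
  for (f in files) {
    p <- file.path(cfg$out_dir, f)
    if (!file.exists(p)) next
    lines <- c(lines, paste0("## ", f), "",
               readLines(p), "")
  }
  writeLines(lines, file.path(cfg$out_dir, "report.md"))
  invisible(NULL)
}
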
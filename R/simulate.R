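## Synthetic multi-species splicing datasets with known truth.
##
## The generator emulates the statistical structure the comparative
## analysis assumes: multi-species gene models sharing planted AS
## events (with a species-specific fraction), log-normal expression
## with tissue-dominant effects, logit-normal psi with
## species-dominant effects, gonad-concentrated sex-biased splicing,
## maternal deposition with high AS before zygotic genome activation,
## and Poisson junction/body counts consistent with the
## effective-length read model used by the estimator.

#' Simulation configuration
#'
#' @param seed integer master seed; every downstream draw derives from
#'   it.
#' @param n_species number of species.
#' @param n_genes genes per species (1:1 structure via a hub).
#' @param frac_multi_exon fraction of genes with >= 2 exons.
#' @param frac_as probability that an eligible multi-exon gene carries
#'   a planted AS event (for maternal genes in embryo designs; zygotic
#'   genes use `frac_as / maternal_as_excess`).
#' @param event_type_probs named probabilities over
#'   c(SE, A5SS, A3SS, MXE, RI).
#' @param frac_species_specific fraction of planted events private to
#'   one species.
#' @param contexts tissue labels (adult design).
#' @param stages embryonic stage labels; non-NULL switches to the
#'   embryo design (contexts = stages, sex = "mixed").
#' @param sexes sex labels for the adult design.
#' @param replicates replicates per condition.
#' @param read_length,anchor read model (nt); read_length > 2 * anchor.
#' @param coverage target mean per-base read depth of an
#'   average-expression gene.
#' @param sigma_species_ge,sigma_tissue_ge log2-scale sd of species and
#'   tissue expression effects.
#' @param sigma_species_as,sigma_tissue_as logit-scale sd of species
#'   and tissue splicing effects.
#' @param sigma_noise_ge,sigma_noise_as per-condition residual sd.
#' @param baseline_log2_tpm,baseline_sd_log2_tpm gene expression
#'   baseline distribution (log2 TPM).
#' @param frac_sexbiased fraction of shared events planted as strongly
#'   sex-biased in the gonad context.
#' @param sexbias_delta planted |psi_f - psi_m| for those events.
#' @param frac_maternal fraction of genes maternally deposited (embryo
#'   design).
#' @param maternal_as_excess odds factor by which maternal genes exceed
#'   zygotic genes in AS probability.
#' @param zygotic_length_factor,zygotic_exon_factor deflation of
#'   zygotic gene exon length / exon count.
#' @param overdispersion negative-binomial overdispersion (0 = Poisson).
#' @param decoy_rate,tie_rate rates of planted spurious ortholog pairs
#'   and exact-tie pairs (per hub feature per species).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_species = 4,
                       n_genes = 200,
                       frac_multi_exon = 0.8,
                       frac_as = 0.3,
                       event_type_probs = c(SE = 0.5, A5SS = 0.15,
                                            A3SS = 0.15, MXE = 0.1,
                                            RI = 0.1),
                       frac_species_specific = 0.1,
                       contexts = c("head", "gonad", "carcass", "wholebody"),
                       stages = NULL,
                       sexes = c("female", "male"),
                       replicates = 2,
                       read_length = 50,
                       anchor = 8,
                       coverage = 100,
                       sigma_species_ge = 0.3,
                       sigma_tissue_ge = 1.5,
                       sigma_species_as = 1.5,
                       sigma_tissue_as = 0.3,
                       sigma_noise_ge = 0.2,
                       sigma_noise_as = 0.2,
                       baseline_log2_tpm = 4,
                       baseline_sd_log2_tpm = 1.5,
                       frac_sexbiased = 0.1,
                       sexbias_delta = 0.8,
                       frac_maternal = 0.75,
                       maternal_as_excess = 4,
                       zygotic_length_factor = 0.5,
                       zygotic_exon_factor = 0.5,
                       overdispersion = 0,
                       decoy_rate = 0.1,
                       tie_rate = 0.05) {
  cfg <- as.list(environment())
  fracs <- c(frac_multi_exon, frac_as, frac_species_specific,
             frac_sexbiased, frac_maternal)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (read_length <= 2 * anchor) stop("read_length must exceed 2 * anchor")
  if (coverage <= 0) stop("coverage must be positive")
  if (abs(sum(event_type_probs) - 1) > 1e-8) {
    stop("event_type_probs must sum to 1")
  }
  if (!is.null(stages)) {
    cfg$contexts <- stages
    cfg$sexes <- "mixed"
  }
  cfg$species <- sprintf("sp%d", seq_len(n_species))
  structure(cfg, class = "sim_config")
}

#' Sample design table for a configuration
#'
#' @param cfg a `sim_config`.
#' @return data.frame: sample_id, species, context, sex, replicate,
#'   read_length, anchor.
#' @export
sim_design <- function(cfg) {
  grid <- expand.grid(replicate = seq_len(cfg$replicates),
                      sex = cfg$sexes, context = cfg$contexts,
                      species = cfg$species, stringsAsFactors = FALSE)
  grid <- grid[, c("species", "context", "sex", "replicate")]
  grid$sample_id <- sprintf("%s.%s.%s.r%d", grid$species, grid$context,
                            grid$sex, grid$replicate)
  grid$read_length <- cfg$read_length
  grid$anchor <- cfg$anchor
  grid[, c("sample_id", "species", "context", "sex", "replicate",
           "read_length", "anchor")]
}

# one hub gene structure: exon/intron lengths, planted event plan
.sim_gene_plan <- function(cfg, idx) {
  mz <- if (stats::runif(1) < cfg$frac_maternal) "maternal" else "zygotic"
  deflate_len <- if (mz == "zygotic") cfg$zygotic_length_factor else 1
  deflate_n <- if (mz == "zygotic") cfg$zygotic_exon_factor else 1
  multi <- stats::runif(1) < cfg$frac_multi_exon
  n_exons <- if (multi) 2L + stats::rpois(1, 4 * deflate_n) else 1L
  p_as <- if (mz == "maternal") cfg$frac_as else
    cfg$frac_as / cfg$maternal_as_excess
  type <- NA_character_
  if (n_exons >= 3L && stats::runif(1) < p_as) {
    type <- sample(names(cfg$event_type_probs), 1,
                   prob = cfg$event_type_probs)
  }
  exon_len <- pmax(30L, as.integer(round(stats::rlnorm(
    n_exons, meanlog = log(250 * deflate_len), sdlog = 0.4))))
  intron_len <- if (n_exons > 1L) {
    150L + stats::rpois(n_exons - 1L, 120)
  } else integer(0)
  owner <- NA_character_
  if (!is.na(type) && stats::runif(1) < cfg$frac_species_specific) {
    owner <- sample(cfg$species, 1)
  }
  list(idx = idx, mz = mz, n_exons = n_exons, exon_len = exon_len,
       intron_len = intron_len, type = type, owner = owner,
       strand = sample(c("+", "-"), 1),
       k = if (n_exons >= 3L) max(2L, n_exons %/% 2L + 1L) - 1L else 1L,
       ext = sample(30:80, 1),
       b2_len = pmax(30L, as.integer(round(stats::rlnorm(
         1, meanlog = log(250 * deflate_len), sdlog = 0.4)))))
}

# realize one gene's exon table + event truth at a genomic offset.
# Returns list(exons = data.frame(transcript, start, end),
#              event = NULL or list(type, target, target2), span)
.sim_gene_realize <- function(plan, offset, with_event) {
  type <- if (with_event) plan$type else NA_character_
  n <- plan$n_exons
  exon_len <- plan$exon_len
  intron_len <- plan$intron_len
  k <- plan$k  # event anchors between exon k and k+1 (1-based)

  # MXE inserts the B2 exon after exon k+1 inside an enlarged intron
  mxe <- !is.na(type) && type == "MXE"
  if (mxe) {
    exon_len <- append(exon_len, plan$b2_len, after = k + 1L)
    intron_len <- append(intron_len, 200L, after = k)
    n <- n + 1L
  }
  starts <- integer(n); ends <- integer(n)
  pos <- offset
  for (i in seq_len(n)) {
    starts[i] <- pos
    ends[i] <- pos + exon_len[i]
    pos <- ends[i] + if (i < n) intron_len[i] else 0L
  }
  tx <- function(idx) data.frame(exon = idx, start = starts[idx],
                                 end = ends[idx])
  event <- NULL
  if (is.na(type)) {
    txs <- list(t1 = tx(seq_len(n)))
    inc_tx <- "t1"
  } else if (type == "SE") {
    tgt <- k + 1L
    txs <- list(t1 = tx(seq_len(n)), t2 = tx(setdiff(seq_len(n), tgt)))
    inc_tx <- "t1"
    event <- list(type = "SE", target = c(starts[tgt], ends[tgt]),
                  target2 = NULL)
  } else if (type == "RI") {
    t2 <- tx(seq_len(n))
    t2 <- t2[-(k + 1L), ]
    t2$end[t2$exon == k] <- ends[k + 1L]  # merged exon spans the intron
    txs <- list(t1 = tx(seq_len(n)), t2 = t2)
    inc_tx <- "t2"
    event <- list(type = "RI", target = c(ends[k], starts[k + 1L]),
                  target2 = NULL)
  } else if (type %in% c("A5SS", "A3SS")) {
    # donor-side extension realizes A5SS on +, A3SS on -; acceptor-side
    # extension the converse
    donor_side <- (type == "A5SS") == (plan$strand == "+")
    t2 <- tx(seq_len(n))
    if (donor_side) {
      t2$end[t2$exon == k] <- ends[k] + plan$ext
      event <- list(type = type, target = c(ends[k], ends[k] + plan$ext),
                    target2 = NULL)
    } else {
      t2$start[t2$exon == k + 1L] <- starts[k + 1L] - plan$ext
      event <- list(type = type,
                    target = c(starts[k + 1L] - plan$ext, starts[k + 1L]),
                    target2 = NULL)
    }
    txs <- list(t1 = tx(seq_len(n)), t2 = t2)
    inc_tx <- "t2"
  } else if (type == "MXE") {
    b1 <- k + 1L; b2 <- k + 2L
    txs <- list(t1 = tx(setdiff(seq_len(n), b2)),
                t2 = tx(setdiff(seq_len(n), b1)))
    inc_tx <- "t1"
    event <- list(type = "MXE", target = c(starts[b1], ends[b1]),
                  target2 = c(starts[b2], ends[b2]))
  }
  list(txs = txs, inc_tx = inc_tx, event = event,
       span = c(starts[1], pos))
}

#' Generate annotations, ortholog tables and planted truth
#'
#' Builds hub gene structures and realizes them in every species at a
#' species-specific genomic offset; planted events are shared across
#' species except the configured species-specific fraction, which exist
#' only in their owner species. Ortholog candidate tables (gene and
#' exon level) carry true pairs with overlap drawn Uniform(0.6, 1),
#' spurious decoy pairs Uniform(0.2, 0.7) against synthetic
#' non-features, and exact-tie pairs that force the hub feature to be
#' discarded by the tie rule; the truth table records which hub
#' features survive resolution.
#'
#' @param cfg a `sim_config`.
#' @return list of class `sim_truth`: `config`, `design`,
#'   `annotations` (per species), `gene_info`, `events` (hub-level
#'   planted events with per-species presence), `ortholog_pairs`,
#'   `ortholog_truth`, and the per-species quantification model used by
#'   [simulate_counts].
#' @export
generate_annotations <- function(cfg) {
  set.seed(cfg$seed)
  plans <- lapply(seq_len(cfg$n_genes), function(i) .sim_gene_plan(cfg, i))
  # fixed per-gene slots keep orthologous coordinates identical across
  # species up to the per-species offset
  slot <- 50000L
  sp_offset <- cfg$n_genes * slot + 1000000L

  annotations <- list()
  quant_model <- list()
  gene_info <- data.frame(
    hub_gene = sprintf("g%04d", seq_len(cfg$n_genes)),
    mz = vapply(plans, `[[`, character(1), "mz"),
    event_type = vapply(plans, `[[`, character(1), "type"),
    owner = vapply(plans, `[[`, character(1), "owner"),
    strand = vapply(plans, `[[`, character(1), "strand"))

  events_rows <- list()
  for (s in seq_along(cfg$species)) {
    sp <- cfg$species[s]
    offset <- (s - 1L) * sp_offset
    ex_rows <- list()
    qm_rows <- list()
    for (i in seq_len(cfg$n_genes)) {
      plan <- plans[[i]]
      hub <- gene_info$hub_gene[i]
      gid <- paste0(sp, "_", hub)
      with_event <- !is.na(plan$type) &&
        (is.na(plan$owner) || plan$owner == sp)
      g <- .sim_gene_realize(plan, offset + (i - 1L) * slot, with_event)
      stopifnot(g$span[2] - g$span[1] < slot)
      for (tn in names(g$txs)) {
        tdf <- g$txs[[tn]]
        ex_rows[[length(ex_rows) + 1L]] <- data.frame(
          gene_id = gid, transcript_id = paste0(gid, ".", tn),
          chrom = "chr1", start = tdf$start, end = tdf$end,
          strand = plan$strand)
      }
      qm_rows[[length(qm_rows) + 1L]] <- .sim_quant_rows(cfg, gid, hub, g)
      if (with_event) {
        ev <- g$event
        events_rows[[length(events_rows) + 1L]] <- data.frame(
          hub_event_id = paste0("ev_", hub), hub_gene = hub,
          species = sp, gene_id = gid, type = ev$type,
          target_start = ev$target[1], target_end = ev$target[2],
          target2_start = if (is.null(ev$target2)) NA_integer_ else
            ev$target2[1],
          target2_end = if (is.null(ev$target2)) NA_integer_ else
            ev$target2[2])
      }
    }
    annotations[[sp]] <- genome_annotation(do.call(rbind, ex_rows),
                                           species = sp)
    quant_model[[sp]] <- do.call(rbind, qm_rows)
  }
  events <- do.call(rbind, events_rows)
  if (is.null(events)) {
    events <- data.frame(hub_event_id = character(), hub_gene = character(),
                         species = character(), gene_id = character(),
                         type = character(), target_start = integer(),
                         target_end = integer(), target2_start = integer(),
                         target2_end = integer())
  }

  orth <- .sim_orthologs(cfg, gene_info, events, sp_offset)

  structure(list(config = cfg, design = sim_design(cfg),
                 annotations = annotations, gene_info = gene_info,
                 events = events, quant_model = quant_model,
                 ortholog_pairs = orth$pairs,
                 ortholog_truth = orth$truth),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", x$config$n_species, "species x", x$config$n_genes,
      "genes;", length(unique(x$events$hub_event_id)), "planted events;",
      nrow(x$design), "samples\n")
  invisible(x)
}

# per-gene quantification rows: intervals/junctions with isoform
# membership weights and effective position counts, as consumed by
# simulate_counts. The membership of an interval is the isoform mass
# whose transcript fully contains it as exonic.
.sim_quant_rows <- function(cfg, gid, hub, g) {
  r <- cfg$read_length; a <- cfg$anchor
  per_junc <- r - 2 * a + 1
  txs <- g$txs
  contains <- function(tdf, s, e) any(tdf$start <= s & tdf$end >= e)
  has_junc <- function(tdf, d, acc) {
    n <- nrow(tdf)
    n >= 2L && any(tdf$end[-n] == d & tdf$start[-1] == acc)
  }
  memb <- function(in_t1, in_t2) {
    if (length(txs) == 1L) return("both")
    if (in_t1 && in_t2) "both"
    else if (in_t1) { if (g$inc_tx == "t1") "inc" else "exc" }
    else { if (g$inc_tx == "t2") "inc" else "exc" }
  }
  rows <- list()
  add <- function(type, s, e, m, positions) {
    rows[[length(rows) + 1L]] <<- data.frame(
      gene_id = gid, hub_gene = hub, row_type = type, chrom = "chr1",
      start = s, end = e, membership = m, positions = positions)
  }
  # annotated exon intervals
  all_ex <- unique(do.call(rbind, lapply(txs, function(t)
    t[, c("start", "end")])))
  for (i in seq_len(nrow(all_ex))) {
    s <- all_ex$start[i]; e <- all_ex$end[i]
    m <- memb(contains(txs[[1]], s, e),
              if (length(txs) > 1L) contains(txs[[2]], s, e) else FALSE)
    add("exon", s, e, m, max(e - s - r + 1, 0))
  }
  # junctions
  all_junc <- unique(do.call(rbind, lapply(txs, function(t) {
    j <- transcript_junctions(t[order(t$start), , drop = FALSE])
    if (nrow(j)) data.frame(d = j$donor, acc = j$acceptor) else NULL
  })))
  if (!is.null(all_junc)) {
    for (i in seq_len(nrow(all_junc))) {
      d <- all_junc$d[i]; acc <- all_junc$acc[i]
      m <- memb(has_junc(txs[[1]][order(txs[[1]]$start), ], d, acc),
                if (length(txs) > 1L)
                  has_junc(txs[[2]][order(txs[[2]]$start), ], d, acc)
                else FALSE)
      add("junction", d, acc, m, per_junc)
    }
  }
  # event-specific inclusion bodies not equal to an annotated exon
  if (!is.null(g$event)) {
    ev <- g$event
    if (ev$type == "RI") {
      L <- ev$target[2] - ev$target[1]
      add("exon", ev$target[1], ev$target[2], "inc",
          2 * per_junc + max(L - r + 1, 0))
    } else if (ev$type %in% c("A5SS", "A3SS")) {
      L <- ev$target[2] - ev$target[1]
      add("exon", ev$target[1], ev$target[2], "inc", max(L - r + 1, 0))
    }
  }
  # gene span (union exonic length for FPKM)
  union_len <- sum(all_ex$end - all_ex$start)  # nested rows overlap; cap
  span <- range(c(all_ex$start, all_ex$end))
  add("gene", span[1], span[2], "both", NA_real_)
  out <- do.call(rbind, rows)
  out$gene_length <- .sim_union_length(all_ex)
  out
}

.sim_union_length <- function(ex) {
  ex <- ex[order(ex$start, ex$end), , drop = FALSE]
  tot <- 0L; cur_s <- NA_integer_; cur_e <- NA_integer_
  for (i in seq_len(nrow(ex))) {
    if (is.na(cur_s)) { cur_s <- ex$start[i]; cur_e <- ex$end[i]; next }
    if (ex$start[i] <= cur_e) cur_e <- max(cur_e, ex$end[i])
    else { tot <- tot + (cur_e - cur_s); cur_s <- ex$start[i]; cur_e <- ex$end[i] }
  }
  tot + if (!is.na(cur_s)) cur_e - cur_s else 0L
}

# ortholog candidate pairs + analytic recovery truth
.sim_orthologs <- function(cfg, gene_info, events, sp_offset) {
  pairs <- list(); truth <- list()
  add_feature <- function(hub_id, feature_of_species, class) {
    for (sp in cfg$species) {
      true_ov <- stats::runif(1, 0.6, 1.0)
      pairs[[length(pairs) + 1L]] <<- data.frame(
        hub_feature_id = hub_id, species = sp,
        feature_id = feature_of_species(sp), overlap = true_ov,
        class = class)
      recovered <- TRUE
      if (stats::runif(1) < cfg$tie_rate) {
        pairs[[length(pairs) + 1L]] <<- data.frame(
          hub_feature_id = hub_id, species = sp,
          feature_id = paste0(hub_id, "_", sp, "_tie"),
          overlap = true_ov, class = class)
        recovered <- FALSE
      } else if (stats::runif(1) < cfg$decoy_rate) {
        decoy_ov <- stats::runif(1, 0.2, 0.7)
        pairs[[length(pairs) + 1L]] <<- data.frame(
          hub_feature_id = hub_id, species = sp,
          feature_id = paste0(hub_id, "_", sp, "_decoy"),
          overlap = decoy_ov, class = class)
        if (decoy_ov > true_ov) recovered <- FALSE
      }
      truth[[length(truth) + 1L]] <<- data.frame(
        hub_feature_id = hub_id, species = sp, class = class,
        true_feature_id = feature_of_species(sp), recovered = recovered)
    }
  }
  for (i in seq_len(nrow(gene_info))) {
    hub <- gene_info$hub_gene[i]
    add_feature(paste0("hub_", hub),
                function(sp) paste0(sp, "_", hub), "gene")
  }
  ev_hub <- unique(events[, c("hub_event_id", "hub_gene")])
  for (i in seq_len(nrow(ev_hub))) {
    he <- ev_hub$hub_event_id[i]
    sub <- events[events$hub_event_id == he, ]
    add_feature(paste0("hubex_", he), function(sp) {
      row <- sub[sub$species == sp, ]
      if (nrow(row) == 1L) {
        sprintf("%s:chr1:%d-%d", sp, row$target_start, row$target_end)
      } else {
        # event private to another species: the exon still exists there;
        # reconstruct its coordinates from the owner row's offsets
        r1 <- sub[1, ]
        off <- (match(sp, cfg$species) - match(r1$species, cfg$species)) *
          sp_offset
        sprintf("%s:chr1:%d-%d", sp, r1$target_start + off,
                r1$target_end + off)
      }
    }, "exon")
  }
  p <- do.call(rbind, pairs); rownames(p) <- NULL
  t <- do.call(rbind, truth); rownames(t) <- NULL
  list(pairs = p, truth = t)
}

#' Draw true expression and splicing profiles per condition
#'
#' log2-TPM is gene baseline + tissue effect + species effect +
#' (gonad-restricted) sex effect + noise; logit-psi is event baseline +
#' species effect + tissue effect + noise, truncated to
#' [0.001, 0.999]. A planted fraction of shared events is strongly
#' sex-biased in the gonad context (psi set to 0.5 +/- delta/2 per sex,
#' direction random). In embryo designs, zygotic genes have zero TPM at
#' the pre-zygotic stages and switch on at the third stage (the
#' maternal-to-zygotic transition); TPM columns are normalized to sum
#' 1e6.
#'
#' @param truth a `sim_truth` from [generate_annotations].
#' @return the `sim_truth` augmented with `conditions`, `true_tpm`
#'   (hub genes x conditions), `true_psi` (hub events x conditions; NA
#'   where the event is absent from the condition's species) and
#'   `sexbiased_events`.
#' @export
draw_profiles <- function(truth) {
  cfg <- truth$config
  set.seed(cfg$seed + 1L)
  conds <- unique(truth$design[, c("species", "context", "sex")])
  cond_id <- sprintf("%s.%s.%s", conds$species, conds$context, conds$sex)
  ng <- cfg$n_genes
  genes <- truth$gene_info$hub_gene
  embryo <- identical(cfg$sexes, "mixed")

  baseline <- stats::rnorm(ng, cfg$baseline_log2_tpm, cfg$baseline_sd_log2_tpm)
  t_eff <- matrix(stats::rnorm(ng * length(cfg$contexts), 0,
                               cfg$sigma_tissue_ge),
                  ng, dimnames = list(genes, cfg$contexts))
  s_eff <- matrix(stats::rnorm(ng * cfg$n_species, 0, cfg$sigma_species_ge),
                  ng, dimnames = list(genes, cfg$species))
  tpm <- matrix(0, ng, length(cond_id), dimnames = list(genes, cond_id))
  for (j in seq_along(cond_id)) {
    lg <- baseline + t_eff[, conds$context[j]] + s_eff[, conds$species[j]] +
      stats::rnorm(ng, 0, cfg$sigma_noise_ge)
    v <- 2^lg
    if (embryo) {
      stage_idx <- match(conds$context[j], cfg$contexts)
      if (stage_idx <= 2L) v[truth$gene_info$mz == "zygotic"] <- 0
    }
    tpm[, j] <- 1e6 * v / sum(v)
  }

  ev <- unique(truth$events[, c("hub_event_id", "hub_gene", "type")])
  ne <- nrow(ev)
  psi <- matrix(NA_real_, ne, length(cond_id),
                dimnames = list(ev$hub_event_id, cond_id))
  if (ne > 0L) {
    base_l <- stats::rnorm(ne, 0, 1)
    es_eff <- matrix(stats::rnorm(ne * cfg$n_species, 0,
                                  cfg$sigma_species_as),
                     ne, dimnames = list(NULL, cfg$species))
    et_eff <- matrix(stats::rnorm(ne * length(cfg$contexts), 0,
                                  cfg$sigma_tissue_as),
                     ne, dimnames = list(NULL, cfg$contexts))
    present <- t(matrix(vapply(seq_len(ne), function(i) {
      owner <- truth$gene_info$owner[match(ev$hub_gene[i],
                                           truth$gene_info$hub_gene)]
      if (is.na(owner)) rep(TRUE, cfg$n_species) else cfg$species == owner
    }, logical(cfg$n_species)), nrow = cfg$n_species))  # events x species
    colnames(present) <- cfg$species
    shared <- rowSums(present) == cfg$n_species
    n_sb <- round(cfg$frac_sexbiased * ne)
    sb_idx <- if (n_sb > 0 && any(shared) && "gonad" %in% cfg$contexts) {
      sample(which(shared), min(n_sb, sum(shared)))
    } else integer(0)
    sb_dir <- sample(c(1, -1), length(sb_idx), replace = TRUE)
    for (j in seq_along(cond_id)) {
      lp <- base_l + es_eff[, conds$species[j]] + et_eff[, conds$context[j]] +
        stats::rnorm(ne, 0, cfg$sigma_noise_as)
      p <- pmin(pmax(stats::plogis(lp), 0.001), 0.999)
      p[!present[, conds$species[j]]] <- NA_real_
      if (length(sb_idx) > 0 && conds$context[j] == "gonad") {
        half <- cfg$sexbias_delta / 2
        if (conds$sex[j] == "female") {
          p[sb_idx] <- 0.5 + sb_dir * half
        } else if (conds$sex[j] == "male") {
          p[sb_idx] <- 0.5 - sb_dir * half
        }
      }
      psi[, j] <- p
    }
    truth$sexbiased_events <- ev$hub_event_id[sb_idx]
  } else {
    truth$sexbiased_events <- character(0)
  }
  truth$conditions <- data.frame(condition = cond_id, conds)
  truth$true_tpm <- tpm
  truth$true_psi <- psi
  truth
}

.sim_draw <- function(n, mu, overdispersion) {
  if (overdispersion > 0) {
    stats::rnbinom(n, mu = mu, size = 1 / overdispersion)
  } else {
    stats::rpois(n, mu)
  }
}

#' Simulate a count table for one sample
#'
#' Reads per gene are proportional to TPM x length; junction and body
#' counts are Poisson (or negative binomial under overdispersion) with
#' means lambda_g x membership weight x effective positions, where the
#' membership weight is psi for inclusion-only features, 1 - psi for
#' exclusion-only features and 1 for constitutive features. The library
#' size is the realized total of gene counts. Deterministic given
#' (truth, sample, master seed).
#'
#' @param truth a `sim_truth` after [draw_profiles].
#' @param sample one row of `truth$design`.
#' @return count table data.frame (long form; see [estimate_psi]).
#' @export
simulate_counts <- function(truth, sample) {
  cfg <- truth$config
  idx <- match(sample$sample_id, truth$design$sample_id)
  set.seed((cfg$seed * 1009L + idx * 7919L) %% .Machine$integer.max)
  cond <- sprintf("%s.%s.%s", sample$species, sample$context, sample$sex)
  qm <- truth$quant_model[[sample$species]]
  tpm <- truth$true_tpm[, cond]
  psi <- if (nrow(truth$events) > 0L) truth$true_psi[, cond] else numeric(0)

  gene_rows <- qm[qm$row_type == "gene", ]
  glen <- gene_rows$gene_length
  names(glen) <- gene_rows$hub_gene
  w_tpm <- tpm[gene_rows$hub_gene] * glen
  N <- cfg$coverage * sum(glen) / cfg$read_length
  reads_per_gene <- N * w_tpm / sum(w_tpm)
  names(reads_per_gene) <- gene_rows$hub_gene
  lambda <- reads_per_gene / pmax(glen - cfg$read_length + 1, 1)

  # psi of the gene's event (by hub gene), NA when absent
  ev_by_gene <- truth$events[!duplicated(truth$events$hub_event_id),
                             c("hub_event_id", "hub_gene")]
  gene_psi <- rep(NA_real_, nrow(gene_rows))
  names(gene_psi) <- gene_rows$hub_gene
  if (nrow(ev_by_gene) > 0L) {
    gene_psi[ev_by_gene$hub_gene] <- psi[ev_by_gene$hub_event_id]
  }

  w <- rep(1, nrow(qm))
  p_g <- gene_psi[qm$hub_gene]
  w[qm$membership == "inc"] <- p_g[qm$membership == "inc"]
  w[qm$membership == "exc"] <- 1 - p_g[qm$membership == "exc"]
  w[is.na(w)] <- 1  # event absent in this species: single-isoform gene

  mu <- lambda[qm$hub_gene] * w * qm$positions
  counts <- numeric(nrow(qm))
  nz <- !is.na(mu)
  counts[nz] <- .sim_draw(sum(nz), mu[nz], cfg$overdispersion)
  is_gene <- qm$row_type == "gene"
  counts[is_gene] <- .sim_draw(sum(is_gene),
                               reads_per_gene[qm$hub_gene[is_gene]],
                               cfg$overdispersion)
  data.frame(sample_id = sample$sample_id,
             feature_type = ifelse(is_gene, "gene", qm$row_type),
             feature_id = ifelse(is_gene, qm$gene_id, ""),
             chrom = qm$chrom, start = qm$start, end = qm$end,
             count = as.numeric(counts))
}

#' Simulate count tables for every sample of the design
#'
#' @param truth a `sim_truth` after [draw_profiles].
#' @return one long count table across samples.
#' @export
simulate_all_counts <- function(truth) {
  out <- lapply(seq_len(nrow(truth$design)), function(i)
    simulate_counts(truth, truth$design[i, ]))
  do.call(rbind, out)
}

#' Write a synthetic dataset to a directory
#'
#' Emits exactly the formats the pipeline consumes: one GTF per
#' species, a long count TSV, the ortholog pair TSV, the design TSV,
#' truth tables and the configuration as flat key=value lines.
#'
#' @param truth a `sim_truth` after [draw_profiles].
#' @param dir output directory (created if needed).
#' @param counts optional precomputed [simulate_all_counts] output.
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(truth, dir, counts = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(truth$annotations)) {
    write_gtf(truth$annotations[[sp]], file.path(dir, paste0(sp, ".gtf")))
  }
  if (is.null(counts)) counts <- simulate_all_counts(truth)
  utils::write.table(counts, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth$ortholog_pairs, file.path(dir, "orthologs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$design, file.path(dir, "design.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$events, file.path(dir, "truth_events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(truth$true_tpm, file.path(dir, "truth_tpm.tsv"),
                   row_label = "hub_gene")
  if (nrow(truth$true_psi) > 0) {
    write_matrix_tsv(truth$true_psi, file.path(dir, "truth_psi.tsv"),
                     row_label = "hub_event_id")
  }
  cfg <- truth$config
  scal <- vapply(cfg, function(x) length(x) == 1 && is.atomic(x), logical(1))
  writeLines(sprintf("%s=%s", names(cfg)[scal],
                     vapply(cfg[scal], as.character, character(1))),
             file.path(dir, "config.txt"))
  invisible(dir)
}
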
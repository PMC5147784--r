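## Expression (FPKM/TPM) and percent-spliced-in quantification from
## count tables.
##
## Count tables are long data.frames with columns sample_id,
## feature_type in {junction, exon, gene}, feature_id (gene id for gene
## rows, "" otherwise), chrom, start, end, count. Junctions are keyed by
## intron coordinates (start = donor, end = acceptor); exon-body rows by
## their interval. All coordinates 0-based half-open.

.count_cols <- c("sample_id", "feature_type", "feature_id",
                 "chrom", "start", "end", "count")

#' Library size of one sample
#'
#' Total mapped reads, taken as the sum of gene-level counts of the
#' sample (junction and body rows re-count the same fragments).
#'
#' @param counts count table.
#' @param sample_id sample identifier.
#' @return numeric scalar.
#' @export
library_size <- function(counts, sample_id) {
  sel <- counts$sample_id == sample_id & counts$feature_type == "gene"
  sum(counts$count[sel])
}

#' FPKM/TPM expression records
#'
#' FPKM = 1e9 * c / (N * l); TPM = 1e6 * (c/l) / sum(c/l) over the
#' sample's features. A feature is flagged expressed iff FPKM is
#' strictly greater than `fpkm_threshold` (default 1, the conventional
#' inclusion threshold).
#'
#' @param feature_counts data.frame with `feature_id` and `count` for
#'   one sample.
#' @param library_size N, total mapped reads (> 0).
#' @param lengths named numeric vector of feature lengths in nt (all
#'   > 0; names must cover the feature ids).
#' @param fpkm_threshold expressed-flag cutoff (strict inequality).
#' @return data.frame: feature_id, count, length, fpkm, tpm, expressed.
#' @export
compute_expression <- function(feature_counts, library_size, lengths,
                               fpkm_threshold = 1) {
  if (library_size <= 0) stop("library size must be positive")
  l <- lengths[feature_counts$feature_id]
  if (any(is.na(l))) stop("missing length for feature(s): ",
                          paste(utils::head(feature_counts$feature_id[is.na(l)], 3),
                                collapse = ", "))
  if (any(l <= 0)) stop("zero or negative feature length")
  c_ <- feature_counts$count
  if (any(c_ < 0)) stop("negative counts")
  rate <- c_ / l
  fpkm <- 1e9 * c_ / (library_size * l)
  tpm <- if (sum(rate) > 0) 1e6 * rate / sum(rate) else rate * 0
  data.frame(feature_id = feature_counts$feature_id, count = c_,
             length = as.numeric(l), fpkm = fpkm, tpm = tpm,
             expressed = fpkm > fpkm_threshold)
}

.parse_intervals <- function(s) {
  # "a-b,c-d" -> 2-col matrix; "" -> empty
  if (is.na(s) || !nzchar(s)) return(matrix(integer(), ncol = 2))
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
  do.call(rbind, lapply(parts, function(p) as.integer(p)))
}

#' Effective inclusion/exclusion lengths of an event
#'
#' The effective length is the number of distinct read start positions
#' producing a read supporting each form: each splice junction (and,
#' for retained introns, each exon-intron boundary) contributes
#' r - 2a + 1 positions, and each inclusion body interval of length L
#' contributes max(L - r + 1, 0). Body terms count only when
#' `body_reads = "include"`, except for RI, whose inclusion support is
#' intrinsically body/boundary-based. Both lengths are floored at 1.
#'
#' @param event one event row (from [enumerate_events]).
#' @param r read length (nt), must exceed twice the anchor.
#' @param a anchor/overhang length (nt), default 8.
#' @param body_reads "include" or "exclude".
#' @return named numeric vector `c(l_inc, l_exc)`.
#' @export
effective_lengths <- function(event, r, a = 8, body_reads = "include") {
  if (r <= 2 * a) stop("read length must exceed twice the anchor (r > 2a)")
  per_junc <- r - 2 * a + 1
  n_inc_junc <- nrow(.parse_intervals(event$inc_junc))
  n_exc_junc <- nrow(.parse_intervals(event$exc_junc))
  l_inc <- (n_inc_junc + event$n_boundary) * per_junc
  if (identical(body_reads, "include") || event$type == "RI") {
    body <- .parse_intervals(event$inc_body)
    if (nrow(body) > 0L) {
      l_inc <- l_inc + sum(pmax(body[, 2] - body[, 1] - r + 1, 0))
    }
  }
  c(l_inc = max(l_inc, 1), l_exc = max(n_exc_junc * per_junc, 1))
}

.sample_count_lookup <- function(counts, sample_id) {
  sub <- counts[counts$sample_id == sample_id, , drop = FALSE]
  jn <- sub[sub$feature_type == "junction", , drop = FALSE]
  bd <- sub[sub$feature_type == "exon", , drop = FALSE]
  lk <- function(df) {
    if (nrow(df) == 0L) return(stats::setNames(numeric(0), character(0)))
    v <- df$count
    names(v) <- paste0(df$chrom, ":", df$start, "-", df$end)
    v
  }
  list(junction = lk(jn), body = lk(bd))
}

.sum_lookup <- function(lookup, chrom, ivs) {
  if (nrow(ivs) == 0L) return(0)
  keys <- paste0(chrom, ":", ivs[, 1], "-", ivs[, 2])
  sum(lookup[keys], na.rm = TRUE)
}

#' Estimate percent spliced in for events in one sample
#'
#' Inclusion reads I sum the counts of the event's inclusion junctions
#' plus (when body reads are used, and always for RI) body counts on
#' the inclusion interval(s); exclusion reads S sum the exclusion
#' junction counts. With effective lengths (lI, lS),
#' psi = (I/lI) / (I/lI + S/lS), undefined (NA) when I = S = 0. The
#' event is classified alternatively spliced in the sample iff both
#' forms are observed with at least `min_each` reads.
#'
#' @param events data.frame of events.
#' @param counts count table (long form, see module header).
#' @param sample one row of a sample design table, carrying `sample_id`,
#'   `read_length` and `anchor`.
#' @param body_reads "include" (default) or "exclude".
#' @param min_each minimum reads of each form for AS classification.
#' @return data.frame: event_id, sample_id, I, S, l_inc, l_exc, psi,
#'   as_classified.
#' @export
estimate_psi <- function(events, counts, sample, body_reads = "include",
                         min_each = 1) {
  if (any(counts$count < 0)) stop("negative counts")
  lookup <- .sample_count_lookup(counts, sample$sample_id)
  n <- nrow(events)
  I <- S <- lI <- lS <- numeric(n)
  for (i in seq_len(n)) {
    ev <- events[i, ]
    el <- effective_lengths(ev, r = sample$read_length, a = sample$anchor,
                            body_reads = body_reads)
    lI[i] <- el["l_inc"]; lS[i] <- el["l_exc"]
    inc <- .sum_lookup(lookup$junction, ev$chrom, .parse_intervals(ev$inc_junc))
    if (identical(body_reads, "include") || ev$type == "RI") {
      inc <- inc + .sum_lookup(lookup$body, ev$chrom,
                               .parse_intervals(ev$inc_body))
    }
    I[i] <- inc
    S[i] <- .sum_lookup(lookup$junction, ev$chrom,
                        .parse_intervals(ev$exc_junc))
  }
  psi <- ifelse(I + S > 0, (I / lI) / (I / lI + S / lS), NA_real_)
  data.frame(event_id = events$event_id, sample_id = sample$sample_id,
             I = I, S = S, l_inc = lI, l_exc = lS, psi = psi,
             as_classified = classify_as_in_sample(I, S, min_each))
}

#' Classify an event as alternatively spliced in a sample
#'
#' Both isoform forms must be observed: at least `min_each` inclusion
#' reads and `min_each` exclusion reads.
#'
#' @param I inclusion read count(s).
#' @param S exclusion read count(s).
#' @param min_each per-form minimum (default 1).
#' @return logical vector.
#' @export
classify_as_in_sample <- function(I, S, min_each = 1) {
  I >= min_each & S >= min_each
}

#' Average psi across samples of a condition
#'
#' Arithmetic mean over the samples in which the event was classified
#' alternatively spliced; NA when none qualify.
#'
#' @param psi psi estimates.
#' @param as_classified logical flags, same length.
#' @return scalar mean or NA.
#' @export
average_psi <- function(psi, as_classified) {
  keep <- as_classified & !is.na(psi)
  if (!any(keep)) return(NA_real_)
  mean(psi[keep])
}

#' Expression-based psi imputation
#'
#' For a sample in which an exon was not classified alternatively
#' spliced (but was in some other sample), psi is imputed from FPKM:
#' exon FPKM > 1 gives psi = 1; exon FPKM < 1 with upstream or
#' downstream exon FPKM > 1 gives psi = 0; exon FPKM < 1 with both
#' flanking FPKM < 1 leaves psi unassigned (NA). All inequalities are
#' strict, so FPKM exactly at the threshold assigns nothing.
#'
#' @param exon_fpkm FPKM of the alternative exon.
#' @param upstream_fpkm,downstream_fpkm FPKM of the flanking exons.
#' @param fpkm_threshold threshold (default 1).
#' @return numeric vector in {0, 1, NA}.
#' @export
impute_psi <- function(exon_fpkm, upstream_fpkm, downstream_fpkm,
                       fpkm_threshold = 1) {
  out <- rep(NA_real_, length(exon_fpkm))
  out[exon_fpkm > fpkm_threshold] <- 1
  rule0 <- exon_fpkm < fpkm_threshold &
    (upstream_fpkm > fpkm_threshold | downstream_fpkm > fpkm_threshold)
  out[rule0] <- 0
  out
}

#' Condition-level psi matrix
#'
#' Rows are events, columns are conditions (species.context.sex by
#' default). Each cell averages psi over the condition's samples in
#' which the event was classified alternatively spliced; when an
#' imputation table is supplied, samples without a classified psi
#' contribute their imputed value instead. Cells with no qualifying
#' sample are NA.
#'
#' @param psi_df row-bound [estimate_psi] output across samples.
#' @param design sample design table with `sample_id`, `species`,
#'   `context`, `sex`.
#' @param imputed optional data.frame (event_id, sample_id, psi_imputed).
#' @param condition_of function mapping design rows to condition labels.
#' @return numeric matrix events x conditions.
#' @export
psi_condition_matrix <- function(psi_df, design, imputed = NULL,
                                 condition_of = function(d)
                                   paste(d$species, d$context, d$sex, sep = ".")) {
  cond <- condition_of(design)
  conds <- unique(cond)
  events <- unique(psi_df$event_id)
  m <- matrix(NA_real_, nrow = length(events), ncol = length(conds),
              dimnames = list(events, conds))
  val <- ifelse(psi_df$as_classified, psi_df$psi, NA_real_)
  if (!is.null(imputed)) {
    key <- paste(psi_df$event_id, psi_df$sample_id)
    ikey <- paste(imputed$event_id, imputed$sample_id)
    hit <- match(key, ikey)
    use <- is.na(val) & !is.na(hit)
    val[use] <- imputed$psi_imputed[hit[use]]
  }
  cond_of_sample <- cond[match(psi_df$sample_id, design$sample_id)]
  agg <- tapply(val, list(factor(psi_df$event_id, levels = events),
                          factor(cond_of_sample, levels = conds)),
                function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
  m[] <- agg
  m
}

#' Per-sample expression/splicing summary metrics
#'
#' Three percentages per sample: genes expressed among all genes;
#' annotated alternatively spliced exons expressed among all AS
#' exons (exon-level FPKM threshold); and expressed genes having at
#' least one AS-classified event among expressed genes (NA when no gene
#' is expressed).
#'
#' @param gene_expr data.frame (sample_id, feature_id, expressed) over
#'   all genes.
#' @param as_exon_expr data.frame (sample_id, feature_id, expressed)
#'   over AS-annotated exons.
#' @param psi_df psi estimates across samples (event_id, sample_id,
#'   as_classified).
#' @param event_gene data.frame (event_id, gene_id).
#' @return data.frame: sample_id, pct_genes_expressed,
#'   pct_as_exons_expressed, pct_expressed_genes_as.
#' @export
sample_summary <- function(gene_expr, as_exon_expr, psi_df, event_gene) {
  samples <- unique(gene_expr$sample_id)
  res <- lapply(samples, function(s) {
    g <- gene_expr[gene_expr$sample_id == s, ]
    e <- as_exon_expr[as_exon_expr$sample_id == s, ]
    p <- psi_df[psi_df$sample_id == s & psi_df$as_classified, ]
    as_genes <- unique(event_gene$gene_id[match(p$event_id, event_gene$event_id)])
    n_expr <- sum(g$expressed)
    data.frame(
      sample_id = s,
      pct_genes_expressed = 100 * n_expr / nrow(g),
      pct_as_exons_expressed =
        if (nrow(e) > 0) 100 * sum(e$expressed) / nrow(e) else NA_real_,
      pct_expressed_genes_as = if (n_expr > 0)
        100 * sum(g$feature_id[g$expressed] %in% as_genes) / n_expr
      else NA_real_)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Row-wise Z-scoring of a metric table
#'
#' Each row is scaled to (x - mean) / sd with the sample standard
#' deviation (n - 1 denominator). Rows with zero variance become zeros,
#' with a warning.
#'
#' @param m numeric matrix.
#' @return matrix of the same shape.
#' @export
zscore_rows <- function(m) {
  out <- t(apply(m, 1, function(x) {
    s <- stats::sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) {
      warning("zero-variance row scaled to zeros")
      return(rep(0, length(x)))
    }
    (x - mean(x, na.rm = TRUE)) / s
  }))
  dimnames(out) <- dimnames(m)
  out
}

#' Write a matrix as TSV with NA for missing
#' @param m matrix with dimnames.
#' @param path output path.
#' @param row_label name for the row-name column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, row_label = "feature") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- row_label
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
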
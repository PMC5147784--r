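## Sex-biased splicing (delta-psi) statistics, maternal/zygotic
## classification over embryonic stages, and early-vs-late transcript
## complexity comparisons.

#' Sex-bias records from female and male psi
#'
#' delta = |psi_f - psi_m|; direction is female when psi_f - psi_m > 0,
#' male when < 0, none at equality. Bias classes use strict thresholds:
#' unbiased (delta <= weak), moderate (weak < delta <= strong), strong
#' (delta > strong); defaults weak = 0.10, strong = 0.7. Exons with
#' either psi missing are excluded and counted in the `n_excluded`
#' attribute.
#'
#' @param exon_id identifiers.
#' @param psi_f,psi_m condition-averaged psi per sex, in [0, 1] or NA.
#' @param context context label(s) recycled across records.
#' @param weak,strong delta thresholds (strict).
#' @return data.frame (exon_id, context, psi_f, psi_m, delta,
#'   direction, bias_class) over records with both psi defined, with
#'   attribute `n_excluded`.
#' @export
delta_psi <- function(exon_id, psi_f, psi_m, context = "all",
                      weak = 0.10, strong = 0.7) {
  ok_range <- function(x) all(is.na(x) | (x >= 0 & x <= 1))
  if (!ok_range(psi_f) || !ok_range(psi_m)) stop("psi values outside [0, 1]")
  keep <- !is.na(psi_f) & !is.na(psi_m)
  n_excluded <- sum(!keep)
  exon_id <- exon_id[keep]
  f <- psi_f[keep]; m <- psi_m[keep]
  delta <- abs(f - m)
  direction <- ifelse(f - m > 0, "female", ifelse(f - m < 0, "male", "none"))
  bias_class <- ifelse(delta > strong, "strong",
                       ifelse(delta > weak, "moderate", "unbiased"))
  out <- data.frame(exon_id = exon_id, context = context,
                    psi_f = f, psi_m = m, delta = delta,
                    direction = direction, bias_class = bias_class)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Per-context sex-bias summary
#'
#' For each context: the number of exons with defined delta-psi, the
#' percentage with delta > weak, the percentage strongly biased
#' (delta > strong), and a direction-signed histogram of delta in
#' `bin`-wide bins (female counts positive, male negative), matching
#' the conventional delta-psi distribution plots.
#'
#' @param records [delta_psi] output (possibly several contexts bound
#'   together).
#' @param weak,strong thresholds used for the percentages (strict).
#' @param bin histogram bin width (default 0.05).
#' @return list: `summary` (one row per context) and `histogram`
#'   (context, bin_low, bin_high, n_female, n_male).
#' @export
sex_bias_summary <- function(records, weak = 0.10, strong = 0.7,
                             bin = 0.05) {
  by_ctx <- split(records, records$context)
  summary <- do.call(rbind, lapply(by_ctx, function(r) {
    data.frame(context = r$context[1], n_exons = nrow(r),
               pct_weak = 100 * mean(r$delta > weak),
               pct_strong = 100 * mean(r$delta > strong))
  }))
  rownames(summary) <- NULL
  breaks <- seq(0, 1, by = bin)
  histogram <- do.call(rbind, lapply(by_ctx, function(r) {
    cut_idx <- pmin(findInterval(r$delta, breaks, left.open = TRUE,
                                 rightmost.closed = TRUE) + 1L,
                    length(breaks) - 1L)
    # delta = 0 falls in the first bin
    cut_idx[r$delta == 0] <- 1L
    data.frame(context = r$context[1],
               bin_low = breaks[-length(breaks)],
               bin_high = breaks[-1],
               n_female = as.integer(table(factor(
                 cut_idx[r$direction == "female"],
                 levels = seq_len(length(breaks) - 1L)))),
               n_male = as.integer(table(factor(
                 cut_idx[r$direction == "male"],
                 levels = seq_len(length(breaks) - 1L)))))
  }))
  rownames(histogram) <- NULL
  list(summary = summary, histogram = histogram)
}

#' Maternal / zygotic classification over embryonic stages
#'
#' A gene is maternally deposited iff it is expressed (FPKM above the
#' threshold in at least one replicate) at the earliest sampled stage
#' (stage 2, before zygotic genome activation); zygotic iff not
#' expressed there but expressed at some later stage; otherwise
#' unexpressed in the embryo. The three classes are mutually exclusive
#' and exhaustive.
#'
#' @param expr data.frame (gene_id, stage, fpkm) over embryo samples
#'   (one row per gene x sample).
#' @param stage2_label label of the pre-zygotic stage (default
#'   "stage2").
#' @param stage_order character vector giving the developmental order
#'   of stage labels; stages after `stage2_label` count as "later".
#' @param fpkm_threshold expressed cutoff (strict, default 1).
#' @return data.frame (gene_id, class) with class in
#'   {maternal, zygotic, unexpressed_in_embryo}.
#' @export
classify_maternal_zygotic <- function(expr, stage2_label = "stage2",
                                      stage_order = NULL,
                                      fpkm_threshold = 1) {
  if (!stage2_label %in% expr$stage) {
    stop("no samples for the pre-zygotic stage '", stage2_label, "'")
  }
  if (is.null(stage_order)) stage_order <- unique(expr$stage)
  i2 <- match(stage2_label, stage_order)
  later <- stage_order[seq_along(stage_order) > i2]
  genes <- sort(unique(expr$gene_id))
  expr_flag <- expr$fpkm > fpkm_threshold
  at2 <- genes %in% expr$gene_id[expr_flag & expr$stage == stage2_label]
  at_later <- genes %in% expr$gene_id[expr_flag & expr$stage %in% later]
  cls <- ifelse(at2, "maternal",
                ifelse(at_later, "zygotic", "unexpressed_in_embryo"))
  data.frame(gene_id = genes, class = cls)
}

#' AS proportion per maternal/zygotic class
#'
#' @param mz [classify_maternal_zygotic] output.
#' @param as_genes character vector: genes with at least one
#'   AS-classified event in at least one embryo sample.
#' @return data.frame (class, n_as, n_total, percent), percent rounded
#'   to one decimal, NA for empty classes.
#' @export
as_proportion_by_class <- function(mz, as_genes) {
  out <- do.call(rbind, lapply(split(mz, mz$class), function(g) {
    n_total <- nrow(g)
    n_as <- sum(g$gene_id %in% as_genes)
    data.frame(class = g$class[1], n_as = n_as, n_total = n_total,
               percent = if (n_total > 0)
                 round(100 * n_as / n_total, 1) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Early-vs-late transcript complexity comparison
#'
#' Compares log2 gene length and exon counts between genes expressed in
#' early embryonic stages and genes expressed in later stages, with
#' two-sided Wilcoxon rank-sum tests (exact enumeration for small
#' untied groups, normal approximation with tie correction otherwise).
#'
#' @param early_genes,late_genes character vectors of gene ids.
#' @param genes [gene_table] output covering both sets.
#' @return list with per-set medians (`median_log2_length_early/late`,
#'   `median_exons_early/late`) and `p_length`, `p_exons`.
#' @export
compare_complexity <- function(early_genes, late_genes, genes) {
  if (length(early_genes) == 0L || length(late_genes) == 0L) {
    stop("both gene sets must be non-empty")
  }
  g_early <- genes[genes$gene_id %in% early_genes, ]
  g_late <- genes[genes$gene_id %in% late_genes, ]
  len_e <- log2(g_early$length); len_l <- log2(g_late$length)
  nex_e <- g_early$exon_count; nex_l <- g_late$exon_count
  wtest <- function(x, y) {
    use_exact <- length(x) <= 20 && length(y) <= 20 &&
      !anyDuplicated(c(x, y))
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact)$p.value
  }
  list(median_log2_length_early = stats::median(len_e),
       median_log2_length_late = stats::median(len_l),
       median_exons_early = stats::median(nex_e),
       median_exons_late = stats::median(nex_l),
       p_length = wtest(len_e, len_l),
       p_exons = wtest(nex_e, nex_l))
}
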
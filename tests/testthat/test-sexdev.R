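test_that("delta-psi records carry magnitude, direction and bias class", {
  r <- delta_psi(c("e1", "e2", "e3"),
                 psi_f = c(0.95, 0.5, 0.20),
                 psi_m = c(0.10, 0.5, 0.35))
  expect_equal(r$delta, c(0.85, 0, 0.15))
  expect_equal(r$direction, c("female", "none", "male"))
  expect_equal(r$bias_class, c("strong", "unbiased", "moderate"))
  # exact thresholds are strict (deltas chosen exactly representable)
  r2 <- delta_psi(c("a", "b"), c(0.7, 0.10), c(0.0, 0.00))
  expect_equal(r2$bias_class, c("moderate", "unbiased"))
  expect_error(delta_psi("e", 1.2, 0.1), "outside")
})

test_that("swapping sexes flips direction and preserves delta", {
  set.seed(17)
  f <- runif(50); m <- runif(50)
  a <- delta_psi(sprintf("e%d", 1:50), f, m)
  b <- delta_psi(sprintf("e%d", 1:50), m, f)
  expect_equal(a$delta, b$delta)
  flip <- c(female = "male", male = "female", none = "none")
  expect_equal(unname(flip[a$direction]), b$direction)
})

test_that("records with a missing sex are excluded and counted", {
  r <- delta_psi(c("e1", "e2", "e3"), c(0.9, NA, 0.2), c(0.1, 0.5, NA))
  expect_equal(nrow(r), 1)
  expect_equal(attr(r, "n_excluded"), 2)
})

test_that("sex-bias summary percentages and signed histogram add up", {
  deltas <- c(0.8, 0.75, rep(0.05, 8))
  r <- delta_psi(sprintf("e%d", 1:10),
                 psi_f = 0.5 + deltas / 2, psi_m = 0.5 - deltas / 2,
                 context = "gonad")
  s <- sex_bias_summary(r)
  expect_equal(s$summary$n_exons, 10)
  expect_equal(s$summary$pct_strong, 20)
  expect_equal(s$summary$pct_weak, 20)
  expect_equal(sum(s$histogram$n_female) + sum(s$histogram$n_male), 10)
  # all-zero deltas give zero percentages
  r0 <- delta_psi(c("a", "b"), c(0.3, 0.4), c(0.3, 0.4))
  s0 <- sex_bias_summary(r0)
  expect_equal(s0$summary$pct_weak, 0)
  expect_equal(s0$summary$pct_strong, 0)
})

test_that("maternal/zygotic classes follow stage-2 expression", {
  expr <- data.frame(
    gene_id = rep(c("gm", "gz", "gu"), each = 3),
    stage = rep(c("stage2", "stage5.5", "stage8.9"), 3),
    fpkm = c(5, 2, 1.5,   0, 0, 3,   0, 0.5, 0.2))
  mz <- classify_maternal_zygotic(expr,
                                  stage_order = c("stage2", "stage5.5",
                                                  "stage8.9"))
  expect_equal(mz$class[mz$gene_id == "gm"], "maternal")
  expect_equal(mz$class[mz$gene_id == "gz"], "zygotic")
  expect_equal(mz$class[mz$gene_id == "gu"], "unexpressed_in_embryo")
  # classes are exhaustive and mutually exclusive
  expect_equal(sort(mz$gene_id), sort(unique(expr$gene_id)))
  expect_error(classify_maternal_zygotic(expr, stage2_label = "stageX"),
               "stageX")
})

test_that("AS proportions reproduce worked examples from printed counts", {
  mk <- function(n_mat, n_zyg, as_mat, as_zyg) {
    mz <- data.frame(
      gene_id = sprintf("g%05d", seq_len(n_mat + n_zyg)),
      class = rep(c("maternal", "zygotic"), c(n_mat, n_zyg)))
    as_genes <- c(mz$gene_id[seq_len(as_mat)],
                  mz$gene_id[n_mat + seq_len(as_zyg)])
    as_proportion_by_class(mz, as_genes)
  }
  p <- mk(2173, 647, 180, 7)
  expect_equal(p$percent[p$class == "maternal"], 8.3)
  expect_equal(p$percent[p$class == "zygotic"], 1.1)
  expect_equal(p$n_as[p$class == "maternal"], 180)
  p0 <- mk(10, 10, 0, 0)
  expect_equal(p0$percent, c(0, 0))
})

test_that("noiseless embryo simulation recovers planted classes exactly", {
  cfg <- sim_config(seed = 19, n_genes = 120, n_species = 2,
                    stages = c("stage2", "stage4", "stage5.5", "stage8.9"),
                    replicates = 1, baseline_sd_log2_tpm = 0,
                    sigma_tissue_ge = 0, sigma_species_ge = 0,
                    sigma_noise_ge = 0)
  truth <- draw_profiles(generate_annotations(cfg))
  # true TPM as noiseless expression (TPM and FPKM share the threshold
  # scale here)
  tpm <- truth$true_tpm
  conds <- truth$conditions
  sel <- conds$species == "sp1"
  expr <- do.call(rbind, lapply(which(sel), function(j) {
    data.frame(gene_id = rownames(tpm), stage = conds$context[j],
               fpkm = tpm[, j])
  }))
  mz <- classify_maternal_zygotic(expr, stage_order = cfg$contexts)
  planted <- truth$gene_info$mz[match(mz$gene_id, truth$gene_info$hub_gene)]
  expect_equal(mz$class, planted)
})

test_that("early/late complexity comparison uses exact Wilcoxon on small groups", {
  genes <- data.frame(gene_id = sprintf("g%d", 1:6),
                      chrom = "chr1", strand = "+", n_transcripts = 1,
                      multi_exon = TRUE,
                      length = c(2, 4, 8, 16, 32, 64),  # log2: 1..6
                      exon_count = c(12, 11, 13, 3, 2, 4))
  res <- compare_complexity(early_genes = c("g4", "g5", "g6"),
                            late_genes = c("g1", "g2", "g3"),
                            genes = genes)
  expect_equal(res$p_length, 0.1)  # exact two-sided p for {4,5,6} vs {1,2,3}
  expect_equal(res$p_exons, 0.1)
  expect_equal(res$median_log2_length_early, 5)
  expect_equal(res$median_exons_late, 12)
  # identical groups: symmetric null
  res2 <- compare_complexity(c("g1", "g2", "g3"), c("g1", "g2", "g3"), genes)
  expect_equal(res2$p_length, 1)
  expect_error(compare_complexity(character(0), "g1", genes), "non-empty")
})

test_that("planted zygotic genes are shorter with fewer exons", {
  cfg <- sim_config(seed = 23, n_genes = 500, n_species = 1,
                    stages = c("stage2", "stage4", "stage5.5", "stage8.9"),
                    replicates = 1)
  truth <- generate_annotations(cfg)
  gt <- gene_table(truth$annotations$sp1)
  gt$mz <- truth$gene_info$mz[match(sub("sp1_", "", gt$gene_id),
                                    truth$gene_info$hub_gene)]
  res <- compare_complexity(gt$gene_id[gt$mz == "maternal"],
                            gt$gene_id[gt$mz == "zygotic"], gt)
  expect_gt(res$median_log2_length_early, res$median_log2_length_late)
  expect_gt(res$median_exons_early, res$median_exons_late)
  expect_lt(res$p_length, 0.05)
  expect_lt(res$p_exons, 0.05)
})
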
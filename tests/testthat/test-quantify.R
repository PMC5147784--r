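test_that("FPKM and TPM follow their definitions", {
  # single feature absorbing the whole library
  e <- compute_expression(data.frame(feature_id = "f", count = 1e6),
                          library_size = 1e6, lengths = c(f = 1000))
  expect_equal(e$fpkm, 1e9 * 1e6 / (1e6 * 1000))
  expect_equal(e$tpm, 1e6)
  expect_true(e$expressed)
  # zero counts
  e0 <- compute_expression(data.frame(feature_id = "f", count = 0),
                           library_size = 1e6, lengths = c(f = 1000))
  expect_equal(e0$fpkm, 0)
  expect_equal(e0$tpm, 0)
  expect_false(e0$expressed)
  # two features: TPM splits by length-normalized rate
  e2 <- compute_expression(
    data.frame(feature_id = c("a", "b"), count = c(100, 300)),
    library_size = 1e6, lengths = c(a = 1000, b = 1500))
  expect_equal(e2$tpm, c(1e6 * 0.1 / 0.3, 1e6 * 0.2 / 0.3))
  expect_equal(sum(e2$tpm), 1e6)
  # errors
  expect_error(compute_expression(
    data.frame(feature_id = "a", count = 1), 0, c(a = 10)), "library")
  expect_error(compute_expression(
    data.frame(feature_id = "a", count = 1), 10, c(a = 0)), "length")
})

test_that("TPM sums to one million on simulated samples", {
  cfg <- sim_config(seed = 5, n_genes = 40, n_species = 1,
                    contexts = "body", sexes = "mixed", replicates = 1)
  truth <- draw_profiles(generate_annotations(cfg))
  counts <- simulate_counts(truth, truth$design[1, ])
  gr <- counts[counts$feature_type == "gene", ]
  lens <- gr$end - gr$start
  names(lens) <- gr$feature_id
  e <- compute_expression(gr, library_size(counts, gr$sample_id[1]), lens)
  expect_equal(sum(e$tpm), 1e6, tolerance = 1e-6)
})

test_that("effective lengths count distinct valid read start positions", {
  se <- enumerate_events(make_se_gene(), "g1")  # target exon length 120
  # junction-only: two inclusion junctions, one exclusion junction
  expect_equal(unname(effective_lengths(se, r = 50, a = 8,
                                        body_reads = "exclude")),
               c(2 * 35, 35))
  # with body reads the 120 nt target adds 120 - 50 + 1 = 71 positions
  expect_equal(unname(effective_lengths(se, r = 50, a = 8)[1]), 70 + 71)
  # RI with a 30 nt intron: body shorter than a read contributes 0
  ri <- enumerate_events(genome_annotation(rbind(
    exon_df("g1", "g1.t1", c(0, 180), c(150, 400)),
    exon_df("g1", "g1.t2", 0, 400))), "g1")
  expect_equal(unname(effective_lengths(ri, r = 50, a = 8)),
               c(2 * 35 + 0, 35))
  expect_error(effective_lengths(se, r = 16, a = 8), "r > 2a")
})

test_that("effective lengths match enumeration of read placements", {
  # place every 50 nt read on the mature mRNA of each isoform of the
  # SE fixture (exons [0,100) [200,320) [400,500)) and count placements
  # that witness inclusion vs exclusion with an 8 nt anchor
  r <- 50; a <- 8
  inc_mrna_breaks <- c(100, 220)  # junction positions in mRNA coordinates
  inc_len <- 320
  n_inc <- 0
  for (s in 0:(inc_len - r)) {
    spans_junc <- any(s + a <= inc_mrna_breaks & inc_mrna_breaks <= s + r - a)
    inside_target <- s >= 100 && s + r <= 220
    if (spans_junc || inside_target) n_inc <- n_inc + 1
  }
  exc_len <- 200
  n_exc <- 0
  for (s in 0:(exc_len - r)) {
    if (s + a <= 100 && 100 <= s + r - a) n_exc <- n_exc + 1
  }
  se <- enumerate_events(make_se_gene(), "g1")
  expect_equal(unname(effective_lengths(se, r = r, a = a)),
               c(n_inc, n_exc))
})

test_that("psi estimation follows the length-normalized support ratio", {
  se <- enumerate_events(make_se_gene(), "g1")
  smp <- make_sample()
  mk_counts <- function(i1, i2, s) rbind(
    count_row("s1", "junction", 100, 200, i1),
    count_row("s1", "junction", 320, 400, i2),
    count_row("s1", "junction", 100, 400, s))
  # junction-only mode, balanced per-position support: psi = 0.5
  est <- estimate_psi(se, mk_counts(35, 35, 35), smp,
                      body_reads = "exclude")
  expect_equal(est$psi, 0.5)
  expect_equal(est$I, 70)
  expect_equal(est$S, 35)
  # one-sided support pins psi to the boundary
  expect_equal(estimate_psi(se, mk_counts(10, 5, 0), smp,
                            body_reads = "exclude")$psi, 1)
  expect_equal(estimate_psi(se, mk_counts(0, 0, 12), smp,
                            body_reads = "exclude")$psi, 0)
  # no reads at all: undefined
  est0 <- estimate_psi(se, mk_counts(0, 0, 0), smp, body_reads = "exclude")
  expect_true(is.na(est0$psi))
  expect_false(est0$as_classified)
  expect_error(estimate_psi(se, mk_counts(-1, 0, 0), smp), "negative")
})

test_that("AS classification needs both forms observed", {
  expect_true(classify_as_in_sample(5, 3))
  expect_false(classify_as_in_sample(5, 0))
  expect_false(classify_as_in_sample(0, 9))
  expect_equal(classify_as_in_sample(c(2, 2, 1), c(0, 3, 5), min_each = 2),
               c(FALSE, TRUE, FALSE))
})

test_that("condition averaging uses only AS-classified samples", {
  expect_equal(average_psi(c(0.2, 0.4, 0.9), c(TRUE, TRUE, FALSE)), 0.3)
  expect_true(is.na(average_psi(c(0.2, 0.9), c(FALSE, FALSE))))
  expect_true(is.na(average_psi(numeric(0), logical(0))))
})

test_that("FPKM-based imputation implements the three rules exactly", {
  # exon below threshold, a flank above: absent isoform, psi 0
  expect_equal(impute_psi(0.4, 2.0, 0.2), 0)
  # exon itself expressed: constitutively included, psi 1
  expect_equal(impute_psi(3.1, 0.0, 0.0), 1)
  expect_equal(impute_psi(3.1, 9.9, 9.9), 1)
  # exon and both flanks silent: no call
  expect_true(is.na(impute_psi(0.4, 0.3, 0.9)))
  # boundary FPKM = 1 satisfies no strict branch
  expect_true(is.na(impute_psi(1, 2, 2)))
  expect_true(is.na(impute_psi(0.5, 1, 1)))
  expect_true(is.na(impute_psi(1, 1, 1)))
  # totality over a grid covering every rule region
  grid <- expand.grid(e = c(0, 0.5, 1, 1.5), u = c(0, 1, 2), d = c(0, 1, 2))
  res <- impute_psi(grid$e, grid$u, grid$d)
  expect_true(all(is.na(res) | res %in% c(0, 1)))
  expect_equal(res[grid$e > 1], rep(1, sum(grid$e > 1)))
  expect_true(all(is.na(res[grid$e == 1])))
})

test_that("psi error shrinks monotonically with coverage", {
  mae_at <- function(cov) {
    cfg <- sim_config(seed = 31, n_genes = 60, n_species = 1,
                      frac_multi_exon = 1, frac_as = 1,
                      contexts = "body", sexes = "mixed", replicates = 1,
                      coverage = cov, baseline_sd_log2_tpm = 0,
                      sigma_tissue_ge = 0, sigma_species_ge = 0,
                      sigma_noise_ge = 0, frac_species_specific = 0)
    truth <- draw_profiles(generate_annotations(cfg))
    counts <- simulate_counts(truth, truth$design[1, ])
    ev <- enumerate_all_events(truth$annotations$sp1)
    est <- estimate_psi(ev, counts, truth$design[1, ])
    tr <- truth$events
    key <- paste(tr$gene_id, tr$type,
                 paste0(tr$target_start, "-", tr$target_end), sep = "|")
    ekey <- vapply(strsplit(est$event_id, "|", fixed = TRUE),
                   function(p) paste(p[1:3], collapse = "|"), character(1))
    truev <- truth$true_psi[tr$hub_event_id[match(ekey, key)], 1]
    mean(abs(est$psi - truev), na.rm = TRUE)
  }
  maes <- c(mae_at(20), mae_at(100), mae_at(500))
  expect_true(all(diff(maes) < 0))
  expect_lt(maes[3], 0.02)
})

test_that("per-sample summary percentages count correctly", {
  gene_expr <- data.frame(
    sample_id = "s1",
    feature_id = sprintf("g%02d", 1:10),
    expressed = c(rep(TRUE, 4), rep(FALSE, 6)))
  psi_df <- data.frame(event_id = c("e1", "e2"), sample_id = "s1",
                       as_classified = c(TRUE, TRUE))
  event_gene <- data.frame(event_id = c("e1", "e2"),
                           gene_id = c("g01", "g02"))
  as_exon_expr <- data.frame(sample_id = "s1",
                             feature_id = c("x1", "x2"),
                             expressed = c(TRUE, FALSE))
  s <- sample_summary(gene_expr, as_exon_expr, psi_df, event_gene)
  expect_equal(s$pct_genes_expressed, 40)
  expect_equal(s$pct_as_exons_expressed, 50)
  expect_equal(s$pct_expressed_genes_as, 50)
  # all genes expressed, none AS
  s2 <- sample_summary(
    data.frame(sample_id = "s1", feature_id = c("a", "b"),
               expressed = TRUE),
    as_exon_expr[0, ],
    psi_df[0, ], event_gene[0, ])
  expect_equal(s2$pct_genes_expressed, 100)
  expect_equal(s2$pct_expressed_genes_as, 0)
})

test_that("row Z-scoring centers and scales with the sample sd", {
  m <- rbind(a = c(1, 2, 3), b = c(10, 20, 60))
  z <- zscore_rows(m)
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_equal(unname(rowMeans(z)), c(0, 0))
  expect_equal(unname(apply(z, 1, sd)), c(1, 1))
  expect_warning(zc <- zscore_rows(rbind(c(2, 2, 2))), "zero-variance")
  expect_equal(unname(zc[1, ]), c(0, 0, 0))
})
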
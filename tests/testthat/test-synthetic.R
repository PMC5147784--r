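test_that("generation is fully deterministic given the seed", {
  cfg <- sim_config(seed = 44, n_genes = 40, n_species = 2)
  t1 <- draw_profiles(generate_annotations(cfg))
  t2 <- draw_profiles(generate_annotations(cfg))
  expect_identical(t1$annotations, t2$annotations)
  expect_identical(t1$ortholog_pairs, t2$ortholog_pairs)
  expect_identical(t1$true_tpm, t2$true_tpm)
  expect_identical(t1$true_psi, t2$true_psi)
  expect_identical(simulate_counts(t1, t1$design[3, ]),
                   simulate_counts(t2, t2$design[3, ]))
})

test_that("species-specific fraction zero makes every event shared", {
  cfg <- sim_config(seed = 45, n_genes = 80, n_species = 3,
                    frac_species_specific = 0)
  truth <- generate_annotations(cfg)
  per_event <- table(truth$events$hub_event_id)
  expect_true(all(per_event == 3))
  # and with sex-bias fraction zero no event is planted biased
  cfg0 <- sim_config(seed = 45, n_genes = 80, frac_sexbiased = 0)
  t0 <- draw_profiles(generate_annotations(cfg0))
  expect_length(t0$sexbiased_events, 0)
})

test_that("maternal fraction one leaves no zygotic genes", {
  cfg <- sim_config(seed = 46, n_genes = 50, n_species = 1,
                    frac_maternal = 1)
  truth <- generate_annotations(cfg)
  expect_true(all(truth$gene_info$mz == "maternal"))
})

test_that("config validation rejects invalid settings", {
  expect_error(sim_config(frac_as = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(read_length = 16, anchor = 8), "anchor")
  expect_error(sim_config(coverage = 0), "coverage")
  expect_error(sim_config(event_type_probs = c(SE = 0.5)), "sum to 1")
})

test_that("psi = 1 events draw zero exclusion reads", {
  cfg <- sim_config(seed = 47, n_genes = 40, n_species = 1,
                    frac_multi_exon = 1, frac_as = 1, contexts = "body",
                    sexes = "mixed", replicates = 1)
  truth <- draw_profiles(generate_annotations(cfg))
  truth$true_psi[] <- 1
  counts <- simulate_counts(truth, truth$design[1, ])
  ev <- enumerate_all_events(truth$annotations$sp1)
  est <- estimate_psi(ev, counts, truth$design[1, ])
  expect_true(all(est$S == 0))
  expect_true(all(est$psi[est$I > 0] == 1))
})

test_that("the estimator is calibrated against the generator at high coverage", {
  cfg <- sim_config(seed = 48, n_genes = 60, n_species = 1,
                    frac_multi_exon = 1, frac_as = 1, contexts = "body",
                    sexes = "mixed", replicates = 1, coverage = 1000,
                    baseline_sd_log2_tpm = 0, sigma_tissue_ge = 0,
                    sigma_species_ge = 0, sigma_noise_ge = 0)
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
  err <- est$psi - truev
  expect_lt(mean(abs(err), na.rm = TRUE), 0.02)
})

test_that("true profile matrices show the planted clustering contrast", {
  cfg <- sim_config(seed = 49, n_genes = 150)
  truth <- draw_profiles(generate_annotations(cfg))
  conds <- truth$conditions
  cm_as <- correlation_matrix(truth$true_psi, method = "spearman")
  cm_ge <- correlation_matrix(log2(truth$true_tpm + 1), method = "spearman")
  expect_gt(label_dominance(cm_as, conds$species),
            label_dominance(cm_as, conds$context))
  expect_gte(label_dominance(cm_ge, conds$context), 0.9)
})

test_that("written datasets round-trip through the pipeline formats", {
  cfg <- sim_config(seed = 50, n_genes = 20, n_species = 2, replicates = 1)
  truth <- draw_profiles(generate_annotations(cfg))
  dir <- withr::local_tempdir()
  write_sim_dataset(truth, dir)
  expect_true(file.exists(file.path(dir, "sp1.gtf")))
  back <- read_gtf(file.path(dir, "sp1.gtf"), species = "sp1")
  expect_equal(back$exons, truth$annotations$sp1$exons)
  counts <- utils::read.table(file.path(dir, "counts.tsv"), sep = "\t",
                              header = TRUE)
  expect_true(all(c("sample_id", "feature_type", "count") %in% names(counts)))
  expect_true(all(counts$count >= 0))
  cfg_lines <- readLines(file.path(dir, "config.txt"))
  expect_true(any(grepl("^seed=50$", cfg_lines)))
})
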
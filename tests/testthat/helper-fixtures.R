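# Hand-built gene fixtures (0-based half-open coordinates throughout).

exon_df <- function(gene, tx, starts, ends, chrom = "chr1", strand = "+") {
  data.frame(gene_id = gene, transcript_id = tx, chrom = chrom,
             start = starts, end = ends, strand = strand)
}

# SE: t1 = A-B-C, t2 = A-C
make_se_gene <- function(strand = "+") {
  genome_annotation(rbind(
    exon_df("g1", "g1.t1", c(0, 200, 400), c(100, 320, 500), strand = strand),
    exon_df("g1", "g1.t2", c(0, 400), c(100, 500), strand = strand)),
    species = "fix")
}

# RI: t1 = A, B; t2 = single exon spanning A..B
make_ri_gene <- function() {
  genome_annotation(rbind(
    exon_df("g1", "g1.t1", c(0, 300), c(150, 450)),
    exon_df("g1", "g1.t2", 0, 450)),
    species = "fix")
}

# alternative donor: t1 exon1 ends at 100, t2 exon1 ends at 160
make_altdonor_gene <- function(strand = "+") {
  genome_annotation(rbind(
    exon_df("g1", "g1.t1", c(0, 300), c(100, 450), strand = strand),
    exon_df("g1", "g1.t2", c(0, 300), c(160, 450), strand = strand)),
    species = "fix")
}

# MXE: t1 = A-B1-C, t2 = A-B2-C; optionally a transcript with both
make_mxe_gene <- function(with_both_path = FALSE) {
  rows <- rbind(
    exon_df("g1", "g1.t1", c(0, 200, 700), c(100, 300, 800)),
    exon_df("g1", "g1.t2", c(0, 450, 700), c(100, 550, 800)))
  if (with_both_path) {
    rows <- rbind(rows,
                  exon_df("g1", "g1.t3", c(0, 200, 450, 700),
                          c(100, 300, 550, 800)))
  }
  genome_annotation(rows, species = "fix")
}

# random multi-transcript gene for property tests; always satisfies the
# annotation invariants. Exercises skipping, boundary shifts and
# adjacent-exon merges.
random_gene <- function(max_tx = 5, max_exons = 10) {
  n_ex <- sample(2:max_exons, 1)
  n_tx <- sample(2:max_tx, 1)
  ex_len <- sample(30:200, n_ex, replace = TRUE)
  in_len <- sample(60:300, max(n_ex - 1, 1), replace = TRUE)
  starts <- integer(n_ex); ends <- integer(n_ex)
  pos <- 0L
  for (i in seq_len(n_ex)) {
    starts[i] <- pos
    ends[i] <- pos + ex_len[i]
    pos <- ends[i] + if (i < n_ex) in_len[i] else 0L
  }
  one_tx <- function() {
    keep <- which(stats::runif(n_ex) < 0.75)
    if (length(keep) == 0) keep <- sample(n_ex, 1)
    s <- starts[keep]; e <- ends[keep]
    # maybe shift a boundary into an adjacent intron (keeps gaps >= 1)
    if (length(keep) >= 2 && stats::runif(1) < 0.4) {
      i <- sample(length(keep) - 1, 1)
      room <- s[i + 1] - e[i] - 1
      if (room > 10) {
        d <- sample(10:min(room, 60), 1)
        if (stats::runif(1) < 0.5) e[i] <- e[i] + d else
          s[i + 1] <- s[i + 1] - d
      }
    }
    # maybe merge two consecutive kept exons (retention-like)
    if (length(keep) >= 2 && stats::runif(1) < 0.25) {
      i <- sample(length(keep) - 1, 1)
      e[i] <- e[i + 1]
      s <- s[-(i + 1)]; e <- e[-(i + 1)]
    }
    list(start = s, end = e)
  }
  rows <- do.call(rbind, lapply(seq_len(n_tx), function(t) {
    tx <- one_tx()
    exon_df("g1", paste0("g1.t", t), tx$start, tx$end)
  }))
  genome_annotation(rows, species = "rand")
}

# minimal sample row for estimate_psi
make_sample <- function(sample_id = "s1", r = 50, a = 8) {
  data.frame(sample_id = sample_id, species = "fix", context = "body",
             sex = "mixed", replicate = 1, read_length = r, anchor = a)
}

# long-form count rows
count_row <- function(sample_id, type, start, end, count, chrom = "chr1",
                      feature_id = "") {
  data.frame(sample_id = sample_id, feature_type = type,
             feature_id = feature_id, chrom = chrom, start = start,
             end = end, count = count)
}
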
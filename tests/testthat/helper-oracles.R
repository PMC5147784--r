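# Independent brute-force oracles, written as literal nested-loop
# translations of the event and orthology definitions. They share no
# code with the package implementations.

# exhaustive pairwise-transcript event enumeration; returns a character
# set of event keys "type|target|target2|inc|exc"
oracle_event_keys <- function(ann, gene_id) {
  txs <- gene_transcripts(ann, gene_id)
  txl <- lapply(txs, function(t) t[order(t$start), c("start", "end")])
  juncs_of <- function(t) {
    out <- list()
    if (nrow(t) >= 2) {
      for (i in seq_len(nrow(t) - 1)) {
        out[[i]] <- c(t$end[i], t$start[i + 1])
      }
    }
    out
  }
  jkey <- function(j) paste0(j[1], "-", j[2])
  all_tx_juncs <- lapply(txl, juncs_of)
  has_junc <- function(ti, j) {
    any(vapply(all_tx_juncs[[ti]], function(x) all(x == j), logical(1)))
  }
  all_exons <- unique(do.call(rbind, txl))
  keys <- character(0)
  add <- function(type, tgt, tgt2, inc, exc) {
    keys <<- c(keys, paste(type, paste(tgt, collapse = "-"),
                           paste(tgt2, collapse = "-"), inc, exc,
                           sep = "|"))
  }
  strand <- txs[[1]]$strand[1]
  nt <- length(txl)
  for (i1 in seq_len(nt)) for (i2 in seq_len(nt)) {
    if (i1 == i2) next
    t1 <- txl[[i1]]; t2 <- txl[[i2]]
    # SE: triple in t1, skip junction in t2
    if (nrow(t1) >= 3) {
      for (k in seq_len(nrow(t1) - 2)) {
        d <- t1$end[k]; a <- t1$start[k + 2]
        if (has_junc(i2, c(d, a))) {
          add("SE", c(t1$start[k + 1], t1$end[k + 1]), NULL,
              paste(jkey(c(d, t1$start[k + 1])),
                    jkey(c(t1$end[k + 1], a)), sep = ","),
              jkey(c(d, a)))
        }
      }
    }
    # A5SS/A3SS: junction pairs sharing one site, overlapping exons at
    # the differing side
    for (j1 in all_tx_juncs[[i1]]) for (j2 in all_tx_juncs[[i2]]) {
      if (j1[1] == j2[1] && j1[2] != j2[2]) {
        a1 <- min(j1[2], j2[2]); a2 <- max(j1[2], j2[2])
        ok <- any(all_exons$start == a1 & all_exons$end > a2) &&
          any(all_exons$start == a2)
        if (ok) {
          add(if (strand == "+") "A3SS" else "A5SS", c(a1, a2), NULL,
              jkey(c(j1[1], a1)), jkey(c(j1[1], a2)))
        }
      }
      if (j1[2] == j2[2] && j1[1] != j2[1]) {
        d1 <- min(j1[1], j2[1]); d2 <- max(j1[1], j2[1])
        ok <- any(all_exons$end == d2 & all_exons$start < d1) &&
          any(all_exons$end == d1)
        if (ok) {
          add(if (strand == "+") "A5SS" else "A3SS", c(d1, d2), NULL,
              jkey(c(d2, j1[2])), jkey(c(d1, j1[2])))
        }
      }
    }
    # MXE: triples with same outer sites, exclusive middles, no
    # both-exon path in any transcript
    if (nrow(t1) >= 3 && nrow(t2) >= 3) {
      for (k1 in seq_len(nrow(t1) - 2)) for (k2 in seq_len(nrow(t2) - 2)) {
        d <- t1$end[k1]; a <- t1$start[k1 + 2]
        if (t2$end[k2] != d || t2$start[k2 + 2] != a) next
        b1 <- c(t1$start[k1 + 1], t1$end[k1 + 1])
        b2 <- c(t2$start[k2 + 1], t2$end[k2 + 1])
        if (all(b1 == b2)) next
        if (b1[1] > b2[1]) { tmp <- b1; b1 <- b2; b2 <- tmp }
        if (b2[1] < b1[2]) next
        both <- FALSE
        for (ti in seq_len(nt)) {
          if (has_junc(ti, c(d, b1[1])) && has_junc(ti, c(b1[2], b2[1])) &&
              has_junc(ti, c(b2[2], a))) both <- TRUE
        }
        if (!both) {
          add("MXE", b1, b2,
              paste(jkey(c(d, b1[1])), jkey(c(b1[2], a)), sep = ","),
              paste(jkey(c(d, b2[1])), jkey(c(b2[2], a)), sep = ","))
        }
      }
    }
    # RI: exon of t1 spanning a consecutive pair of t2 exactly
    if (nrow(t2) >= 2) {
      for (e in seq_len(nrow(t1))) for (k in seq_len(nrow(t2) - 1)) {
        if (t1$start[e] == t2$start[k] && t1$end[e] == t2$end[k + 1]) {
          add("RI", c(t2$end[k], t2$start[k + 1]), NULL, "",
              jkey(c(t2$end[k], t2$start[k + 1])))
        }
      }
    }
  }
  sort(unique(keys))
}

# package events reduced to the oracle's key convention
event_keys_of <- function(events) {
  if (nrow(events) == 0) return(character(0))
  tgt2 <- ifelse(is.na(events$target2_start), "",
                 paste0(events$target2_start, "-", events$target2_end))
  sort(unique(paste(events$type,
                    paste0(events$target_start, "-", events$target_end),
                    tgt2, events$inc_junc, events$exc_junc, sep = "|")))
}

# literal two-pass resolution: hub side first, then other side, each
# keeping the unique best and discarding ties
oracle_resolve <- function(pairs) {
  keep1 <- pairs[0, ]
  for (h in unique(pairs$hub_feature_id)) {
    g <- pairs[pairs$hub_feature_id == h, ]
    best <- max(g$overlap)
    if (sum(g$overlap == best) == 1) {
      keep1 <- rbind(keep1, g[g$overlap == best, ])
    }
  }
  keep2 <- keep1[0, ]
  for (f in unique(keep1$feature_id)) {
    g <- keep1[keep1$feature_id == f, ]
    best <- max(g$overlap)
    if (sum(g$overlap == best) == 1) {
      keep2 <- rbind(keep2, g[g$overlap == best, ])
    }
  }
  keep2[order(keep2$hub_feature_id),
        c("hub_feature_id", "feature_id", "overlap")]
}

# random bipartite ortholog instance with planted ties
random_ortholog_instance <- function(n = 30, tie_prob = 0.2) {
  m <- sample(10:n, 1)
  hub <- sprintf("h%02d", sample(n, m, replace = TRUE))
  oth <- sprintf("f%02d", sample(n, m, replace = TRUE))
  ov <- round(stats::runif(m, 0.5, 1), 2)  # rounding makes ties likely
  df <- data.frame(hub_feature_id = hub, species = "spX",
                   feature_id = oth, overlap = ov)
  if (stats::runif(1) < tie_prob && m >= 2) {
    i <- sample(m, 1)
    df <- rbind(df, data.frame(hub_feature_id = df$hub_feature_id[i],
                               species = "spX",
                               feature_id = "f_tie",
                               overlap = df$overlap[i]))
  }
  unique(df)
}
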
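## Splice-event enumeration and classification.
##
## Events are coordinate patterns over transcript pairs, deduplicated
## across the gene: SE (skipped exon), A5SS/A3SS (alternative 5'/3'
## splice site, labelled per strand), MXE (mutually exclusive exons),
## RI (retained intron). Psi orientation is fixed: for SE/RI/A5SS/A3SS
## inclusion is the longer (more exonic) form; for MXE inclusion is the
## form containing the genomically first exclusive exon.

#' Junctions (introns) of a transcript
#'
#' @param tx data.frame of exons sorted by start.
#' @return data.frame with columns `donor` (intron start = end of the
#'   upstream exon) and `acceptor` (intron end = start of the downstream
#'   exon), 0-based half-open.
#' @export
transcript_junctions <- function(tx) {
  n <- nrow(tx)
  if (n < 2L) {
    return(data.frame(donor = integer(), acceptor = integer()))
  }
  data.frame(donor = tx$end[-n], acceptor = tx$start[-1])
}

.junc_key <- function(donor, acceptor) paste0(donor, "-", acceptor)

#' Build a splice graph for one gene
#'
#' Nodes are the distinct exonic segments (by coordinates) across the
#' gene's transcripts; edges are the distinct introns. Every transcript
#' corresponds to a path through the graph.
#'
#' @param ann a `genome_annotation`.
#' @param gene_id gene identifier.
#' @return An object of class `splice_graph`: list with `gene_id`,
#'   `nodes` (exon data.frame), `edges` (junction data.frame) and
#'   `paths` (per transcript, node indices in order).
#' @export
build_splice_graph <- function(ann, gene_id) {
  txs <- gene_transcripts(ann, gene_id)
  all_ex <- do.call(rbind, lapply(txs, function(tx) tx[, c("start", "end")]))
  nodes <- unique(all_ex)
  nodes <- nodes[order(nodes$start, nodes$end), , drop = FALSE]
  rownames(nodes) <- NULL
  node_key <- paste0(nodes$start, "-", nodes$end)
  edges <- unique(do.call(rbind, lapply(txs, transcript_junctions)))
  if (is.null(edges)) edges <- data.frame(donor = integer(), acceptor = integer())
  edges <- edges[order(edges$donor, edges$acceptor), , drop = FALSE]
  rownames(edges) <- NULL
  paths <- lapply(txs, function(tx) {
    match(paste0(tx$start, "-", tx$end), node_key)
  })
  structure(list(gene_id = gene_id, nodes = nodes, edges = edges,
                 paths = paths),
            class = "splice_graph")
}

#' @export
print.splice_graph <- function(x, ...) {
  cat("splice_graph:", x$gene_id, "-", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges,", length(x$paths), "transcripts\n")
  invisible(x)
}

.empty_events <- function() {
  data.frame(event_id = character(), gene_id = character(),
             chrom = character(), strand = character(), type = character(),
             target_start = integer(), target_end = integer(),
             target2_start = integer(), target2_end = integer(),
             flank_left_start = integer(), flank_left_end = integer(),
             flank_right_start = integer(), flank_right_end = integer(),
             inc_junc = character(), exc_junc = character(),
             inc_body = character(), n_boundary = integer(),
             stringsAsFactors = FALSE)
}

.event_row <- function(gene_id, chrom, strand, type, target, target2,
                       flank_left, flank_right, inc_junc, exc_junc,
                       inc_body, n_boundary) {
  data.frame(event_id = NA_character_, gene_id = gene_id, chrom = chrom,
             strand = strand, type = type,
             target_start = target[1], target_end = target[2],
             target2_start = if (is.null(target2)) NA_integer_ else target2[1],
             target2_end = if (is.null(target2)) NA_integer_ else target2[2],
             flank_left_start = flank_left[1], flank_left_end = flank_left[2],
             flank_right_start = flank_right[1], flank_right_end = flank_right[2],
             inc_junc = inc_junc, exc_junc = exc_junc,
             inc_body = inc_body, n_boundary = n_boundary,
             stringsAsFactors = FALSE)
}

#' Enumerate alternative-splicing events of one gene
#'
#' Detects the five event classes from the gene's transcript structures:
#' \describe{
#'   \item{SE}{an exon triplet A-B-C consecutive in one transcript while
#'     the junction A->C (same donor and acceptor) exists in another.}
#'   \item{A5SS/A3SS}{two junctions sharing one splice site and
#'     differing at the other; the differing side is classified 5' or 3'
#'     by strand. The target is the extension segment exonic only in the
#'     longer (inclusion) form.}
#'   \item{MXE}{exons B1 < B2 where one transcript splices A-B1-C,
#'     another A-B2-C (same outer donor/acceptor), and no transcript of
#'     the gene contains the path A-B1-B2-C.}
#'   \item{RI}{an exon in one transcript exactly spanning exon A, the
#'     intervening intron, and exon B of another transcript; the target
#'     is the retained intron.}
#' }
#' Events are deduplicated by (type, target coordinates, junction
#' support); when several flank choices exist, the shortest enclosing
#' flanks are reported. Output is sorted by (type, coordinates).
#' Retained-intron events overlapping splice sites of other events are
#' kept.
#'
#' @param ann a `genome_annotation`.
#' @param gene_id gene identifier; a single-transcript gene yields no
#'   events.
#' @return data.frame of events (possibly empty), one row per event,
#'   with junction sets encoded as "donor-acceptor" comma-joined
#'   strings and `inc_body` the interval(s) whose body reads support
#'   inclusion.
#' @export
enumerate_events <- function(ann, gene_id) {
  txs <- gene_transcripts(ann, gene_id)
  chrom <- txs[[1]]$chrom[1]
  strand <- txs[[1]]$strand[1]
  if (length(txs) < 2L) return(.empty_events())

  juncs <- lapply(txs, transcript_junctions)
  all_junc <- unique(do.call(rbind, juncs))
  junc_keys <- .junc_key(all_junc$donor, all_junc$acceptor)
  tx_junc_keys <- lapply(juncs, function(j) .junc_key(j$donor, j$acceptor))
  all_exons <- unique(do.call(rbind, lapply(txs, function(tx)
    tx[, c("start", "end")])))

  # consecutive exon triples (A,B,C) across transcripts
  triples <- do.call(rbind, lapply(txs, function(tx) {
    n <- nrow(tx)
    if (n < 3L) return(NULL)
    i <- seq_len(n - 2L)
    data.frame(a_start = tx$start[i], d = tx$end[i],
               b_start = tx$start[i + 1L], b_end = tx$end[i + 1L],
               a = tx$start[i + 2L], c_end = tx$end[i + 2L])
  }))

  rows <- list()

  ## --- SE ---
  if (!is.null(triples) && nrow(triples) > 0L) {
    hit <- .junc_key(triples$d, triples$a) %in% junc_keys
    se <- triples[hit, , drop = FALSE]
    if (nrow(se) > 0L) {
      key <- paste(se$d, se$b_start, se$b_end, se$a)
      for (grp in split(se, key)) {
        g1 <- grp[1, ]
        flank_left <- c(max(grp$a_start), g1$d)    # shortest upstream flank
        flank_right <- c(g1$a, min(grp$c_end))     # shortest downstream flank
        rows[[length(rows) + 1L]] <- .event_row(
          gene_id, chrom, strand, "SE",
          target = c(g1$b_start, g1$b_end), target2 = NULL,
          flank_left = flank_left, flank_right = flank_right,
          inc_junc = paste(.junc_key(g1$d, g1$b_start),
                           .junc_key(g1$b_end, g1$a), sep = ","),
          exc_junc = .junc_key(g1$d, g1$a),
          inc_body = paste0(g1$b_start, "-", g1$b_end), n_boundary = 0L)
      }
    }
  }

  ## --- A5SS / A3SS ---
  # Two junctions sharing one splice site and differing at the other;
  # the differing sites must be alternative boundaries of overlapping
  # exons (otherwise the pattern is exon skipping, not an alternative
  # splice site).
  # shared donor, differing acceptors: acceptor side is 3' on +, 5' on -
  for (grp in split(all_junc, all_junc$donor)) {
    if (nrow(grp) < 2L) next
    accs <- sort(grp$acceptor)
    for (i in seq_len(length(accs) - 1L)) {
      for (j in seq(i + 1L, length(accs))) {
        a1 <- accs[i]; a2 <- accs[j]
        d <- grp$donor[1]
        # an exon starting at a1 must extend past a2 (overlap the
        # short-form exon)
        long_ex <- all_exons[all_exons$start == a1 & all_exons$end > a2, ,
                             drop = FALSE]
        if (nrow(long_ex) == 0L) next
        fl_cand <- all_exons[all_exons$end == d, , drop = FALSE]
        fr_cand <- all_exons[all_exons$start == a2, , drop = FALSE]
        if (nrow(fr_cand) == 0L) next
        rows[[length(rows) + 1L]] <- .event_row(
          gene_id, chrom, strand,
          type = if (strand == "+") "A3SS" else "A5SS",
          target = c(a1, a2), target2 = NULL,
          flank_left = c(max(fl_cand$start), d),
          flank_right = c(a2, min(fr_cand$end)),
          inc_junc = .junc_key(d, a1), exc_junc = .junc_key(d, a2),
          inc_body = paste0(a1, "-", a2), n_boundary = 0L)
      }
    }
  }
  # shared acceptor, differing donors: donor side is 5' on +, 3' on -
  for (grp in split(all_junc, all_junc$acceptor)) {
    if (nrow(grp) < 2L) next
    dons <- sort(grp$donor)
    for (i in seq_len(length(dons) - 1L)) {
      for (j in seq(i + 1L, length(dons))) {
        d1 <- dons[i]; d2 <- dons[j]
        a <- grp$acceptor[1]
        long_ex <- all_exons[all_exons$end == d2 & all_exons$start < d1, ,
                             drop = FALSE]
        if (nrow(long_ex) == 0L) next
        fl_cand <- all_exons[all_exons$end == d1, , drop = FALSE]
        fr_cand <- all_exons[all_exons$start == a, , drop = FALSE]
        if (nrow(fl_cand) == 0L) next
        rows[[length(rows) + 1L]] <- .event_row(
          gene_id, chrom, strand,
          type = if (strand == "+") "A5SS" else "A3SS",
          target = c(d1, d2), target2 = NULL,
          flank_left = c(max(fl_cand$start), d1),
          flank_right = c(a, min(fr_cand$end)),
          inc_junc = .junc_key(d2, a), exc_junc = .junc_key(d1, a),
          inc_body = paste0(d1, "-", d2), n_boundary = 0L)
      }
    }
  }

  ## --- MXE ---
  if (!is.null(triples) && nrow(triples) > 0L) {
    outer_key <- paste(triples$d, triples$a)
    for (grp in split(triples, outer_key)) {
      mids <- unique(grp[, c("b_start", "b_end")])
      if (nrow(mids) < 2L) next
      for (i in seq_len(nrow(mids) - 1L)) {
        for (j in seq(i + 1L, nrow(mids))) {
          b1 <- mids[i, ]; b2 <- mids[j, ]
          if (b1$b_start > b2$b_start) { tmp <- b1; b1 <- b2; b2 <- tmp }
          if (b2$b_start < b1$b_end) next  # overlapping: not MXE
          d <- grp$d[1]; a <- grp$a[1]
          both_path <- c(.junc_key(d, b1$b_start),
                         .junc_key(b1$b_end, b2$b_start),
                         .junc_key(b2$b_end, a))
          if (any(vapply(tx_junc_keys,
                         function(k) all(both_path %in% k), logical(1)))) next
          sub1 <- grp[grp$b_start == b1$b_start & grp$b_end == b1$b_end, ]
          sub2 <- grp[grp$b_start == b2$b_start & grp$b_end == b2$b_end, ]
          rows[[length(rows) + 1L]] <- .event_row(
            gene_id, chrom, strand, "MXE",
            target = c(b1$b_start, b1$b_end),
            target2 = c(b2$b_start, b2$b_end),
            flank_left = c(max(c(sub1$a_start, sub2$a_start)), d),
            flank_right = c(a, min(c(sub1$c_end, sub2$c_end))),
            inc_junc = paste(.junc_key(d, b1$b_start),
                             .junc_key(b1$b_end, a), sep = ","),
            exc_junc = paste(.junc_key(d, b2$b_start),
                             .junc_key(b2$b_end, a), sep = ","),
            inc_body = paste0(b1$b_start, "-", b1$b_end), n_boundary = 0L)
        }
      }
    }
  }

  ## --- RI ---
  # consecutive exon pairs (A,B) vs a single exon spanning A..B exactly
  pairs <- do.call(rbind, lapply(txs, function(tx) {
    n <- nrow(tx)
    if (n < 2L) return(NULL)
    i <- seq_len(n - 1L)
    data.frame(a_start = tx$start[i], d = tx$end[i],
               a = tx$start[i + 1L], b_end = tx$end[i + 1L])
  }))
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    pairs <- unique(pairs)
    span_key <- paste0(all_exons$start, "-", all_exons$end)
    hit <- paste0(pairs$a_start, "-", pairs$b_end) %in% span_key
    ri <- pairs[hit, , drop = FALSE]
    if (nrow(ri) > 0L) {
      for (i in seq_len(nrow(ri))) {
        p <- ri[i, ]
        rows[[length(rows) + 1L]] <- .event_row(
          gene_id, chrom, strand, "RI",
          target = c(p$d, p$a), target2 = NULL,
          flank_left = c(p$a_start, p$d), flank_right = c(p$a, p$b_end),
          inc_junc = "", exc_junc = .junc_key(p$d, p$a),
          inc_body = paste0(p$d, "-", p$a), n_boundary = 2L)
      }
    }
  }

  if (length(rows) == 0L) return(.empty_events())
  ev <- do.call(rbind, rows)
  dedup_key <- paste(ev$type, ev$target_start, ev$target_end,
                     ev$target2_start, ev$target2_end,
                     ev$inc_junc, ev$exc_junc)
  ev <- ev[!duplicated(dedup_key), , drop = FALSE]
  ev <- ev[order(ev$type, ev$target_start, ev$target_end,
                 ev$exc_junc), , drop = FALSE]
  ev$event_id <- sprintf("%s|%s|%d-%d|%s", ev$gene_id, ev$type,
                         ev$target_start, ev$target_end, ev$exc_junc)
  rownames(ev) <- NULL
  ev
}

#' Enumerate events for every gene of an annotation
#'
#' @param ann a `genome_annotation`.
#' @return data.frame of events across all genes (row-bound
#'   [enumerate_events] results), sorted by gene then (type,
#'   coordinates).
#' @export
enumerate_all_events <- function(ann) {
  gids <- sort(unique(ann$exons$gene_id))
  out <- do.call(rbind, lapply(gids, function(g) enumerate_events(ann, g)))
  if (is.null(out)) out <- .empty_events()
  rownames(out) <- NULL
  out
}

#' Classify exons as constitutive or alternatively spliced
#'
#' An exon is alternatively spliced iff its interval overlaps the target
#' region (skipped exon, extension segment, either exclusive exon, or
#' retained intron) of at least one event of its gene; otherwise it is
#' constitutive. Distinct exons are identified by
#' (gene, chrom, start, end).
#'
#' @param ann a `genome_annotation`.
#' @param events data.frame from [enumerate_all_events].
#' @return data.frame: one row per distinct exon with `status`
#'   ("alternative"/"constitutive") and `types` (comma-joined event
#'   types hitting the exon, "" for constitutive).
#' @export
classify_exons <- function(ann, events) {
  ex <- unique(ann$exons[, c("gene_id", "chrom", "start", "end", "strand")])
  if (nrow(ex) == 0L) {
    ex$status <- character(0); ex$types <- character(0)
    return(ex)
  }
  status <- rep("constitutive", nrow(ex))
  types <- rep("", nrow(ex))
  if (nrow(events) > 0L) {
    for (i in seq_len(nrow(ex))) {
      ev <- events[events$gene_id == ex$gene_id[i], , drop = FALSE]
      if (nrow(ev) == 0L) next
      hit1 <- ev$target_start < ex$end[i] & ev$target_end > ex$start[i]
      hit2 <- !is.na(ev$target2_start) &
        ev$target2_start < ex$end[i] & ev$target2_end > ex$start[i]
      hits <- unique(ev$type[hit1 | hit2])
      if (length(hits) > 0L) {
        status[i] <- "alternative"
        types[i] <- paste(sort(hits), collapse = ",")
      }
    }
  }
  ex$status <- status
  ex$types <- types
  rownames(ex) <- NULL
  ex
}

#' Per-type event counts
#'
#' @param events data.frame of events.
#' @return data.frame with `type`, `n` and `proportion` (of all events),
#'   covering the five classes in fixed order.
#' @export
event_type_summary <- function(events) {
  lv <- c("SE", "A5SS", "A3SS", "MXE", "RI")
  n <- as.integer(table(factor(events$type, levels = lv)))
  data.frame(type = lv, n = n,
             proportion = if (sum(n) > 0) n / sum(n) else rep(NA_real_, 5))
}

#' Write events as TSV
#' @param events data.frame of events.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write events as JSON
#' @param events data.frame of events.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_json <- function(events, path) {
  jsonlite::write_json(events, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export event target regions as BED
#'
#' BED is 0-based half-open, matching the internal convention, so
#' coordinates pass through unchanged; MXE contributes one line per
#' exclusive exon.
#'
#' @param events data.frame of events.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_bed <- function(events, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", events$chrom,
                   events$target_start, events$target_end,
                   events$event_id, events$strand)
  mxe <- events[!is.na(events$target2_start), , drop = FALSE]
  if (nrow(mxe) > 0L) {
    lines <- c(lines, sprintf("%s\t%d\t%d\t%s\t0\t%s", mxe$chrom,
                              mxe$target2_start, mxe$target2_end,
                              mxe$event_id, mxe$strand))
  }
  writeLines(lines, path)
  invisible(path)
}
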
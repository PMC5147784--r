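#' Construct a genome annotation
#'
#' A `genome_annotation` holds coordinate-sorted gene models for one
#' species as a flat exon table. Internally all coordinates are 0-based
#' half-open, so an exon `[start, end)` has `length = end - start`;
#' GTF I/O converts to and from the 1-based inclusive convention.
#'
#' @param exons data.frame with columns `gene_id`, `transcript_id`,
#'   `chrom`, `start`, `end`, `strand` (and optionally `exon_id`),
#'   coordinates 0-based half-open.
#' @param species character scalar species label.
#' @param validate logical; check structural invariants (default TRUE).
#' @return An object of class `genome_annotation`: a list with elements
#'   `species` and `exons` (the exon table, sorted by gene, transcript
#'   and start coordinate).
#' @export
genome_annotation <- function(exons, species = "unknown", validate = TRUE) {
  required <- c("gene_id", "transcript_id", "chrom", "start", "end", "strand")
  if (!all(required %in% names(exons))) {
    stop("exon table must have columns: ", paste(required, collapse = ", "))
  }
  exons$gene_id <- as.character(exons$gene_id)
  exons$transcript_id <- as.character(exons$transcript_id)
  exons$chrom <- as.character(exons$chrom)
  exons$strand <- as.character(exons$strand)
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (!"exon_id" %in% names(exons)) {
    exons$exon_id <- sprintf("%s:%d-%d", exons$chrom, exons$start, exons$end)
  }
  ord <- order(exons$gene_id, exons$transcript_id, exons$start)
  exons <- exons[ord, c(required, "exon_id"), drop = FALSE]
  rownames(exons) <- NULL
  ann <- structure(list(species = species, exons = exons),
                   class = "genome_annotation")
  if (validate) validate_annotation(ann)
  ann
}

#' Validate annotation invariants
#'
#' Checks, per transcript: single chromosome and strand, exons sorted and
#' non-overlapping with introns of length >= 1, exon length >= 1; per
#' gene: all transcripts on one chromosome and strand; gene ids unique
#' per annotation (gene/transcript nesting is implied by the table).
#'
#' @param ann a `genome_annotation`.
#' @return Invisibly `TRUE`; stops with a validation error naming the
#'   offending transcript otherwise.
#' @export
validate_annotation <- function(ann) {
  ex <- ann$exons
  if (nrow(ex) == 0L) return(invisible(TRUE))
  if (any(ex$start >= ex$end)) {
    bad <- ex$transcript_id[ex$start >= ex$end][1]
    stop("validation error: transcript '", bad, "' has an exon with start >= end")
  }
  if (!all(ex$strand %in% c("+", "-"))) {
    stop("validation error: strand must be '+' or '-'")
  }
  for (tx in split(ex, ex$transcript_id)) {
    tid <- tx$transcript_id[1]
    if (length(unique(tx$chrom)) > 1L || length(unique(tx$strand)) > 1L) {
      stop("validation error: transcript '", tid,
           "' mixes chromosomes or strands")
    }
    if (nrow(tx) > 1L) {
      # table is sorted by start; introns must have length >= 1
      gaps <- tx$start[-1] - tx$end[-nrow(tx)]
      if (any(gaps < 1L)) {
        stop("validation error: transcript '", tid,
             "' has overlapping or abutting exons")
      }
    }
    gid <- tx$gene_id[1]
    gene <- ex[ex$gene_id == gid, , drop = FALSE]
    if (length(unique(gene$chrom)) > 1L || length(unique(gene$strand)) > 1L) {
      stop("validation error: gene '", gid, "' mixes chromosomes or strands")
    }
  }
  invisible(TRUE)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", x$species, "\n")
  cat("  genes:      ", length(unique(x$exons$gene_id)), "\n")
  cat("  transcripts:", length(unique(x$exons$transcript_id)), "\n")
  cat("  exon lines: ", nrow(x$exons), "\n")
  invisible(x)
}

#' Per-gene summary table
#'
#' Derived gene-level quantities: whether any transcript has two or more
#' exons (`multi_exon`), the genomic span of the union of exons
#' (`length`), and the number of distinct exons by coordinates
#' (`exon_count`).
#'
#' @param ann a `genome_annotation`.
#' @return data.frame with one row per gene: `gene_id`, `chrom`,
#'   `strand`, `n_transcripts`, `multi_exon`, `length`, `exon_count`.
#' @export
gene_table <- function(ann) {
  ex <- ann$exons
  if (nrow(ex) == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), n_transcripts = integer(),
                      multi_exon = logical(), length = integer(),
                      exon_count = integer()))
  }
  res <- lapply(split(ex, ex$gene_id), function(g) {
    n_per_tx <- table(g$transcript_id)
    data.frame(
      gene_id = g$gene_id[1], chrom = g$chrom[1], strand = g$strand[1],
      n_transcripts = length(n_per_tx),
      multi_exon = any(n_per_tx >= 2L),
      length = max(g$end) - min(g$start),
      exon_count = nrow(unique(g[, c("start", "end")])))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$gene_id), , drop = FALSE]
}

#' Exon structures of one gene
#'
#' @param ann a `genome_annotation`.
#' @param gene_id gene identifier.
#' @return list of transcripts, each a data.frame of exons sorted by
#'   start, named by transcript_id.
#' @export
gene_transcripts <- function(ann, gene_id) {
  g <- ann$exons[ann$exons$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) == 0L) stop("unknown gene_id: ", gene_id)
  lapply(split(g, g$transcript_id), function(tx) {
    tx[order(tx$start), , drop = FALSE]
  })
}

#' Read a GTF annotation file
#'
#' Parses exon features of a GTF2.2 file (tab-separated, attributes
#' carrying `gene_id` and `transcript_id`) into a [genome_annotation].
#' 1-based inclusive GTF coordinates become internal 0-based half-open:
#' GTF `(s, e)` maps to `[s - 1, e)`.
#'
#' @param path file path.
#' @param species species label to attach (default: file base name).
#' @return a `genome_annotation`.
#' @export
read_gtf <- function(path, species = NULL) {
  if (is.null(species)) {
    species <- sub("\\.gtf$", "", basename(path), ignore.case = TRUE)
  }
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- vector("list", sum(keep))
  k <- 0L
  for (i in which(keep)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 9L) {
      stop("GTF parse error at line ", i, ": expected 9 tab-separated fields")
    }
    if (fields[3] != "exon") next
    s <- suppressWarnings(as.integer(fields[4]))
    e <- suppressWarnings(as.integer(fields[5]))
    if (is.na(s) || is.na(e)) {
      stop("GTF parse error at line ", i, ": non-numeric coordinates")
    }
    attrs <- fields[9]
    gid <- .gtf_attr(attrs, "gene_id")
    tid <- .gtf_attr(attrs, "transcript_id")
    if (is.na(gid) || is.na(tid)) {
      stop("GTF parse error at line ", i,
           ": exon feature lacks gene_id or transcript_id attribute")
    }
    k <- k + 1L
    rows[[k]] <- data.frame(gene_id = gid, transcript_id = tid,
                            chrom = fields[1], start = s - 1L, end = e,
                            strand = fields[7])
  }
  if (k == 0L) {
    return(genome_annotation(
      data.frame(gene_id = character(), transcript_id = character(),
                 chrom = character(), start = integer(), end = integer(),
                 strand = character()),
      species = species))
  }
  genome_annotation(do.call(rbind, rows[seq_len(k)]), species = species)
}

.gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0(key, '\\s+"([^"]*)"'), attrs))[[1]]
  if (length(m) < 2L) NA_character_ else m[2]
}

#' Write a genome annotation as GTF
#'
#' Emits one exon line per exon, converting internal 0-based half-open
#' coordinates back to 1-based inclusive GTF. `read_gtf(write_gtf(a))`
#' reproduces `a` on coordinates, ids and strands.
#'
#' @param ann a `genome_annotation`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  ex <- ann$exons
  lines <- sprintf(
    '%s\tsplicecomp\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    ex$chrom, ex$start + 1L, ex$end, ex$strand, ex$gene_id, ex$transcript_id)
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("cannot write GTF to path: ", path)
  invisible(path)
}

#' Export gene/transcript/exon table as TSV
#'
#' @param ann a `genome_annotation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(ann, path) {
  ex <- ann$exons
  out <- data.frame(species = ann$species, ex[, c(
    "gene_id", "transcript_id", "chrom", "start", "end", "strand")])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
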
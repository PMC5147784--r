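## 1:1 ortholog resolution across species via a hub species.
##
## Candidate pairs come from whole-genome-alignment overlap tables
## (hub_feature_id, species, feature_id, overlap in [0,1]); the overlap
## score's convention is the caller's (treated as opaque here).

#' Filter ortholog candidate pairs by overlap
#'
#' Keeps pairs whose overlap is strictly greater than the threshold.
#'
#' @param pairs data.frame with columns `hub_feature_id`, `species`,
#'   `feature_id`, `overlap` (in [0, 1]).
#' @param threshold overlap cutoff, default 0.5 (strict).
#' @return filtered data.frame.
#' @export
filter_overlap <- function(pairs, threshold = 0.5) {
  if (nrow(pairs) > 0 && (any(pairs$overlap < 0) || any(pairs$overlap > 1))) {
    stop("overlap scores must lie in [0, 1]")
  }
  out <- pairs[pairs$overlap > threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve a one-to-one mapping between the hub and one species
#'
#' Two passes, in this order: (1) for each hub feature with several
#' candidates, keep the highest-overlap pair, discarding the hub
#' feature entirely if the maximum is tied among two or more
#' candidates; (2) symmetrically for each other-species feature mapping
#' to several hub features. The result is a partial bijection.
#'
#' @param pairs pre-filtered pairs for one species (see
#'   [filter_overlap]).
#' @return data.frame (hub_feature_id, feature_id, overlap), a partial
#'   bijection.
#' @export
resolve_one_to_one <- function(pairs) {
  empty <- data.frame(hub_feature_id = character(),
                      feature_id = character(), overlap = numeric())
  if (nrow(pairs) == 0L) return(empty)
  p <- pairs[order(pairs$hub_feature_id, pairs$feature_id), , drop = FALSE]

  pick_best <- function(df, by) {
    keep <- lapply(split(df, df[[by]]), function(g) {
      mx <- max(g$overlap)
      best <- g[g$overlap == mx, , drop = FALSE]
      if (nrow(best) > 1L) NULL else best  # tie: discard the feature
    })
    out <- do.call(rbind, keep)
    if (is.null(out)) df[0, , drop = FALSE] else out
  }

  p <- pick_best(p, "hub_feature_id")
  if (nrow(p) == 0L) return(empty)
  p <- pick_best(p, "feature_id")
  out <- p[order(p$hub_feature_id), c("hub_feature_id", "feature_id", "overlap")]
  rownames(out) <- NULL
  stopifnot(!anyDuplicated(out$hub_feature_id), !anyDuplicated(out$feature_id))
  out
}

#' Intersect per-species mappings into ortholog sets
#'
#' A hub feature resolved in every listed species yields one ortholog
#' set (one feature id per species); hub features missing from any
#' species are dropped.
#'
#' @param mappings named list of [resolve_one_to_one] outputs, one per
#'   species.
#' @param species character vector of species to require (default: all
#'   names of `mappings`).
#' @return data.frame with `hub_feature_id` and one column per species.
#' @export
intersect_across_species <- function(mappings, species = names(mappings)) {
  mappings <- mappings[species]
  hubs <- Reduce(intersect, lapply(mappings, function(m) m$hub_feature_id))
  hubs <- sort(hubs)
  out <- data.frame(hub_feature_id = hubs)
  for (sp in species) {
    m <- mappings[[sp]]
    out[[sp]] <- m$feature_id[match(hubs, m$hub_feature_id)]
  }
  out
}

#' Filter ortholog sets by expression (and AS annotation)
#'
#' In `gene` mode, keeps sets whose member in every species is
#' expressed (FPKM above threshold) in at least one sample of that
#' species. In `as_exon` mode, additionally requires that the feature
#' be the target of an alternatively spliced event classified in at
#' least one sample of at least one species.
#'
#' @param sets [intersect_across_species] output.
#' @param expressed_features named list (per species) of character
#'   vectors: features expressed in >= 1 sample of that species.
#' @param as_features character vector of features AS-classified in
#'   >= 1 sample of >= 1 species (any species' feature id or hub id);
#'   only used in `as_exon` mode.
#' @param mode "gene" or "as_exon".
#' @return filtered sets.
#' @export
filter_expressed_orthologs <- function(sets, expressed_features,
                                       as_features = character(),
                                       mode = c("gene", "as_exon")) {
  mode <- match.arg(mode)
  species <- setdiff(names(sets), "hub_feature_id")
  keep <- rep(TRUE, nrow(sets))
  for (sp in species) {
    keep <- keep & sets[[sp]] %in% expressed_features[[sp]]
  }
  if (mode == "as_exon") {
    any_as <- Reduce(`|`, lapply(species, function(sp)
      sets[[sp]] %in% as_features))
    any_as <- any_as | sets$hub_feature_id %in% as_features
    keep <- keep & any_as
  }
  out <- sets[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an ortholog pair table from TSV
#' @param path TSV with columns hub_feature_id, species, feature_id,
#'   overlap.
#' @return data.frame.
#' @export
read_ortholog_pairs <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "character", "character",
                                   "numeric"))
}

#' Write ortholog sets as TSV
#' @param sets data.frame from [intersect_across_species].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ortholog_sets <- function(sets, path) {
  utils::write.table(sets, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
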
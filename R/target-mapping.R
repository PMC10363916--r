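#' Build per-trait drug-target gene sets
#'
#' Joins an indication table (trait -> drug) with a drug-target table
#' (drug -> gene) and applies the standard filters: only interactions with
#' confidence score at or above `min_confidence` and with an allowed
#' interaction type are kept (the usual high-confidence setting is a score
#' of at least 700 and the types "inhibition" and "activation"). Traits
#' with no surviving target are retained as empty, flagged sets so that
#' downstream odds-ratio fallback rules are exercised.
#'
#' @param indications data.frame with columns `trait_id`, `drug_id`.
#' @param drug_targets data.frame with columns `drug_id`, `gene_id` and
#'   optionally `confidence`, `interaction_type`.
#' @param min_confidence optional numeric; rows with
#'   `confidence >= min_confidence` are kept (rows lacking a confidence
#'   column pass).
#' @param allowed_types optional character vector of interaction types to
#'   keep.
#' @param universe optional gene universe; target genes outside it are
#'   dropped and counted.
#' @return An object of class `target_gene_sets`: a named list (per trait)
#'   of character vectors, with attributes `n_drugs` (drugs contributing
#'   per trait), `empty` (logical per trait) and `n_unmapped` (genes
#'   dropped for not being in the universe).
#' @export
build_target_sets <- function(indications, drug_targets, min_confidence = NULL,
                              allowed_types = NULL, universe = NULL) {
  if (!all(c("trait_id", "drug_id") %in% names(indications))) {
    stop_config("indications needs columns trait_id, drug_id")
  }
  if (!all(c("drug_id", "gene_id") %in% names(drug_targets))) {
    stop_config("drug_targets needs columns drug_id, gene_id")
  }
  indications <- unique(indications[, c("trait_id", "drug_id")])
  tgt <- drug_targets
  if (!is.null(min_confidence) && "confidence" %in% names(tgt)) {
    tgt <- tgt[is.na(tgt$confidence) | tgt$confidence >= min_confidence, , drop = FALSE]
  }
  if (!is.null(allowed_types) && "interaction_type" %in% names(tgt)) {
    tgt <- tgt[tgt$interaction_type %in% allowed_types, , drop = FALSE]
  }
  n_unmapped <- 0L
  if (!is.null(universe)) {
    bad <- !(tgt$gene_id %in% universe)
    n_unmapped <- sum(bad)
    tgt <- tgt[!bad, , drop = FALSE]
  }
  traits <- sort(unique(as.character(indications$trait_id)))
  sets <- vector("list", length(traits))
  names(sets) <- traits
  n_drugs <- setNames(integer(length(traits)), traits)
  for (tr in traits) {
    drugs <- indications$drug_id[indications$trait_id == tr]
    rows <- tgt[tgt$drug_id %in% drugs, , drop = FALSE]
    sets[[tr]] <- sort(unique(as.character(rows$gene_id)))
    n_drugs[tr] <- length(unique(rows$drug_id))
  }
  structure(sets, class = "target_gene_sets",
            n_drugs = n_drugs,
            empty = vapply(sets, length, 1L) == 0L,
            n_unmapped = n_unmapped)
}

#' @export
print.target_gene_sets <- function(x, ...) {
  sizes <- vapply(x, length, 1L)
  cat(sprintf("target_gene_sets: %d trait(s); set sizes %s; %d empty\n",
              length(x), paste(sizes, collapse = ", "), sum(sizes == 0L)))
  invisible(x)
}

#' Jaccard index of two gene sets
#'
#' @param a,b character vectors (treated as sets).
#' @return `|a intersect b| / |a union b|`; 0 when both sets are empty.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Exact binomial enrichment of a gene subset for drug targets
#'
#' Tests whether a subset of the gene universe (e.g., the genes testable by
#' one method) is enriched for drug targets: successes are the targets
#' inside the subset, trials are the targets in the universe, and the
#' expected success probability is the subset's share of the universe. The
#' p-value is the standard two-sided exact binomial (minimum-likelihood
#' summation).
#'
#' @param subset gene subset of `universe`.
#' @param targets drug-target gene set.
#' @param universe background gene universe (nonempty).
#' @return List with `successes`, `trials`, `expected_prob`, `p`.
#' @export
background_enrichment_binomial <- function(subset, targets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop_config("empty universe")
  subset <- intersect(unique(subset), universe)
  targets_u <- intersect(unique(targets), universe)
  successes <- length(intersect(subset, targets_u))
  trials <- length(targets_u)
  prob <- length(subset) / length(universe)
  p <- if (trials == 0L || prob >= 1) {
    if (prob >= 1 && successes < trials) 0 else 1
  } else if (prob <= 0) {
    if (successes > 0L) 0 else 1
  } else {
    binom.test(successes, trials, p = prob)$p.value
  }
  list(successes = successes, trials = trials, expected_prob = prob, p = p)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, tab-separated members).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  setNames(lapply(lines, function(x) x[-(1:2)]),
           vapply(lines, `[`, "", 1L))
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop_config("all gene sets must be named")
  }
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
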
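#' Read GWAS/QTL summary statistics from TSV
#'
#' Expects the conventional header `snp, chr, pos, a1, a2, freq, beta, se,
#' p, n` (or the package's own column names) and returns the standardized
#' association table used throughout: `snp_id`, `chrom`, `pos`,
#' `allele_effect`, `allele_other`, `freq`, `beta`, `se`, `p`, `n`, with a
#' derived `z`.
#'
#' @param path tab-separated file with header.
#' @return data.frame of SNP associations.
#' @export
read_summary_stats <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  alias <- c(snp = "snp_id", chr = "chrom", a1 = "allele_effect",
             a2 = "allele_other")
  for (nm in names(alias)) {
    if (nm %in% names(tab) && !alias[[nm]] %in% names(tab)) {
      names(tab)[names(tab) == nm] <- alias[[nm]]
    }
  }
  need <- c("snp_id", "chrom", "pos", "allele_effect", "allele_other",
            "freq", "beta", "se", "p", "n")
  if (!all(need %in% names(tab))) {
    stop_config("summary statistics need columns %s", paste(need, collapse = ", "))
  }
  if (any(tab$se <= 0)) stop_config("standard errors must be positive")
  if (any(tab$p <= 0 | tab$p > 1)) stop_config("p-values must lie in (0, 1]")
  tab$z <- tab$beta / tab$se
  tab
}

#' Read a square LD correlation matrix from TSV
#'
#' @param path tab-separated square matrix with SNP ids as header row and
#'   first column.
#' @return Numeric matrix with SNP-id dimnames, symmetrized.
#' @export
read_ld_matrix <- function(path) {
  tab <- read.delim(path, row.names = 1, check.names = FALSE)
  M <- as.matrix(tab)
  if (nrow(M) != ncol(M)) stop_config("LD matrix must be square")
  if (max(abs(diag(M) - 1)) > 1e-6) stop_config("LD matrix must have unit diagonal")
  (M + t(M)) / 2
}

#' Read gene annotations from a BED-like TSV
#'
#' Unlike standard BED, coordinates here are 1-based and inclusive at both
#' ends; columns are `gene_id`, `chrom`, `start`, `end` and optionally
#' `strand`.
#'
#' @param path tab-separated file with header.
#' @return data.frame of gene annotations.
#' @export
read_gene_annotations <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(tab))) {
    stop_config("gene annotations need columns %s", paste(need, collapse = ", "))
  }
  if (any(tab$start > tab$end)) stop_config("gene start must be <= end")
  tab
}

#' Read or write a labelled correlation matrix as TSV
#'
#' @param path tab-separated square matrix with labels as header row and
#'   first column.
#' @return `read_correlation_matrix()` returns the validated matrix.
#' @export
read_correlation_matrix <- function(path) {
  M <- as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
  check_correlation_matrix(M)
  M
}

#' @rdname read_correlation_matrix
#' @param R correlation matrix with dimnames.
#' @export
write_correlation_matrix <- function(R, path) {
  check_correlation_matrix(R)
  write.table(data.frame(label = rownames(R), R, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extend a score vector with zero-valued background genes
#'
#' Adds genes absent from a priority vector with score exactly 0, so they
#' enter downstream AUC and enrichment computations as never-prioritized
#' background. This implements the sensitivity mode in which methods with
#' small testable sets (e.g., plasma-protein instruments) are evaluated
#' against a larger background of zero-scored genes.
#'
#' @param scores named numeric priority vector (higher = better).
#' @param genes gene ids to ensure are present.
#' @return Extended named vector; existing entries are unchanged.
#' @export
extend_scores <- function(scores, genes) {
  extra <- setdiff(genes, names(scores))
  out <- c(scores, setNames(rep(0, length(extra)), extra))
  attr(out, "kind") <- attr(scores, "kind")
  out
}

#' Write benchmark artifacts to disk
#'
#' Emits the per-observation results and the aggregates as tidy TSV, and a
#' JSON manifest recording the seed, a hash of the configuration, and run
#' metadata, so a run can be archived and re-audited.
#'
#' @param run a `benchmark_run`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(run, dir) {
  stopifnot(inherits(run, "benchmark_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(run$results, file.path(dir, "results.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(run$aggregates, file.path(dir, "aggregates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg_file <- tempfile()
  saveRDS(run$config, cfg_file)
  manifest <- c(run$manifest,
                list(config_hash = unname(tools::md5sum(cfg_file))))
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
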
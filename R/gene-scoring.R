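#' Assign SNPs to genes by positional window
#'
#' A SNP is assigned to a gene when its position falls within the gene body
#' extended by `window` base pairs on both sides (1-based, inclusive at both
#' ends). A SNP may be assigned to several overlapping genes. Strand is
#' ignored.
#'
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos` (1-based).
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param window nonnegative flank size in base pairs; default 50000 (the
#'   conventional gene +/- 50 kb window).
#' @return Named list mapping `gene_id` to a character vector of `snp_id`s
#'   (genes with no assigned SNP are omitted).
#' @export
assign_snps_to_genes <- function(snps, genes, window = 50000) {
  stopifnot(window >= 0)
  need_s <- c("snp_id", "chrom", "pos")
  need_g <- c("gene_id", "chrom", "start", "end")
  if (!all(need_s %in% names(snps))) stop_config("snps needs columns %s", paste(need_s, collapse = ", "))
  if (!all(need_g %in% names(genes))) stop_config("genes needs columns %s", paste(need_g, collapse = ", "))
  if (any(genes$start > genes$end)) stop_config("gene start must be <= end")
  snps$chrom <- as.character(snps$chrom)
  genes$chrom <- as.character(genes$chrom)
  if (!any(genes$chrom %in% snps$chrom)) {
    warning("no shared chromosome names between SNPs and genes; empty map")
    return(setNames(list(), character(0)))
  }
  out <- vector("list", nrow(genes))
  names(out) <- genes$gene_id
  by_chr <- split(snps, snps$chrom)
  for (i in seq_len(nrow(genes))) {
    s <- by_chr[[genes$chrom[i]]]
    if (is.null(s)) next
    hit <- s$pos >= genes$start[i] - window & s$pos <= genes$end[i] + window
    if (any(hit)) out[[i]] <- s$snp_id[hit]
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Tail probability of a weighted sum of independent 1-df chi-squares
#'
#' Computes \eqn{P(\sum_j \lambda_j \chi^2_{1,j} \ge T)} by numerical
#' inversion of the characteristic function (Imhof's method), with a Kuonen
#' saddlepoint approximation in the extreme tail where the oscillatory
#' integral loses relative accuracy. This is the null distribution of the
#' sum of squared SNP z-scores over a gene region, with weights given by the
#' eigenvalues of the local LD correlation matrix.
#'
#' @param T_stat observed statistic, nonnegative scalar.
#' @param lambda nonnegative weights, not all zero. Eigenvalues below
#'   `1e-10` are treated as zero.
#' @return Upper-tail probability in `(0, 1]`.
#' @export
weighted_chisq_sf <- function(T_stat, lambda) {
  stopifnot(length(T_stat) == 1L, is.finite(T_stat), T_stat >= 0)
  if (any(lambda < -1e-10)) stop_config("negative weight in lambda")
  lambda <- lambda[lambda > 1e-10]
  if (length(lambda) == 0L) stop_config("all weights zero: distribution undefined")
  if (T_stat == 0) return(1)
  # equal weights reduce to a scaled chi-square with k df
  if (max(lambda) - min(lambda) < 1e-12 * max(lambda)) {
    return(max(pchisq(T_stat / lambda[1], df = length(lambda), lower.tail = FALSE),
               .Machine$double.xmin))
  }
  p <- imhof_sf(T_stat, lambda)
  if (!is.finite(p) || p < 1e-14) {
    ps <- saddlepoint_sf(T_stat, lambda)
    if (is.finite(ps)) p <- ps
  }
  min(max(p, .Machine$double.xmin), 1)
}

# Imhof (1961) inversion integral for P(Q >= x)
imhof_sf <- function(x, lambda) {
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * x * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    val <- sin(theta) / (u * rho)
    val[u == 0] <- 0.5 * (sum(lambda) - x)  # limit as u -> 0
    val
  }
  res <- tryCatch(
    integrate(integrand, 0, Inf, rel.tol = 1e-12, abs.tol = 1e-13,
              subdivisions = 2000L, stop.on.error = FALSE),
    error = function(e) NULL)
  if (is.null(res) || res$message != "OK") {
    # fall back to a truncated upper limit; the envelope 1/(u*rho) decays
    # polynomially of order k/2 + 1
    res <- tryCatch(
      integrate(integrand, 0, 1e4, rel.tol = 1e-10, subdivisions = 5000L),
      error = function(e) NULL)
    if (is.null(res)) return(NA_real_)
  }
  # Imhof: P(Q < x) = 1/2 - (1/pi) * integral, so the upper tail adds it
  0.5 + res$value / pi
}

# Kuonen (1999) saddlepoint approximation to the upper tail
saddlepoint_sf <- function(x, lambda) {
  k0 <- function(t) -0.5 * sum(log1p(-2 * t * lambda))
  k1 <- function(t) sum(lambda / (1 - 2 * t * lambda))
  k2 <- function(t) 2 * sum(lambda^2 / (1 - 2 * t * lambda)^2)
  mu <- sum(lambda)
  if (x <= mu) return(NA_real_)  # only used in the upper tail
  upper <- 1 / (2 * max(lambda))
  root <- tryCatch(
    uniroot(function(t) k1(t) - x, lower = 0, upper = upper * (1 - 1e-12),
            tol = .Machine$double.eps^0.5)$root,
    error = function(e) NA_real_)
  if (!is.finite(root)) return(NA_real_)
  w <- sign(root) * sqrt(2 * (root * x - k0(root)))
  v <- root * sqrt(k2(root))
  if (abs(w) < 1e-8) return(NA_real_)
  pnorm(w + log(v / w) / w, lower.tail = FALSE)
}

#' LD-aware gene score from SNP z-scores
#'
#' The gene statistic is the sum of squared SNP z-scores over the gene
#' region; under the null (z multivariate normal with the LD correlation
#' structure) it follows a weighted chi-square distribution whose weights
#' are the eigenvalues of the LD matrix.
#'
#' @param z numeric vector of SNP z-scores for one gene region.
#' @param ld square SNP-SNP correlation matrix matching `z` (unit diagonal).
#' @param gene_id optional gene identifier carried into the result.
#' @return A one-row data.frame with `gene_id`, `statistic` (Tsum), `p`,
#'   `method = "GWAS"` and `n_snps_or_ivs`, or `NULL` when `z` is empty
#'   (the gene is untestable, not p = 1).
#' @export
gwas_gene_score <- function(z, ld, gene_id = NA_character_) {
  if (length(z) == 0L) return(NULL)
  ld <- as.matrix(ld)
  if (nrow(ld) != length(z) || ncol(ld) != length(z)) {
    stop_config("LD dimension (%d) does not match z length (%d)", nrow(ld), length(z))
  }
  lambda <- eigen((ld + t(ld)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lambda[lambda < 1e-10] <- 0
  tsum <- sum(z^2)
  data.frame(gene_id = gene_id, statistic = tsum,
             p = weighted_chisq_sf(tsum, lambda),
             method = "GWAS", n_snps_or_ivs = length(z),
             stringsAsFactors = FALSE)
}

#' Ingest a precomputed gene-level p-value table
#'
#' Validates and ranks externally computed gene-level association results
#' (e.g., exome burden test p-values): duplicate gene ids are rejected,
#' p-values must lie in (0, 1] after clamping exact zeros to a configurable
#' floor, and genes are ranked by ascending p.
#'
#' @param x path to a tab-separated file with columns `gene_id` and `p`, or
#'   a data.frame with those columns.
#' @param method label stored in the `method` column (e.g., `"Exome"`).
#' @param p_floor positive value exact-zero p-values are clamped to.
#' @return A data.frame with columns `gene_id`, `p`, `method`, `rank`
#'   (ascending p, ties share the minimum rank).
#' @export
ingest_gene_pvalues <- function(x, method = "Exome", p_floor = 1e-300) {
  tab <- if (is.character(x)) read.delim(x, stringsAsFactors = FALSE) else as.data.frame(x)
  if (!all(c("gene_id", "p") %in% names(tab))) {
    stop_config("table needs columns gene_id and p")
  }
  if (anyDuplicated(tab$gene_id)) stop_config("duplicate gene_id in score table")
  if (any(!is.finite(tab$p)) || any(tab$p < 0) || any(tab$p > 1)) {
    stop_config("p-values must lie in [0, 1]")
  }
  if (any(tab$p == 0)) {
    warning(sprintf("%d zero p-value(s) clamped to %g", sum(tab$p == 0), p_floor))
    tab$p[tab$p == 0] <- p_floor
  }
  out <- data.frame(gene_id = as.character(tab$gene_id), p = tab$p,
                    method = method, stringsAsFactors = FALSE)
  out$rank <- rank(out$p, ties.method = "min")
  out[order(out$p, out$gene_id), , drop = FALSE]
}
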
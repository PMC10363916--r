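PALINDROMIC <- c("AT", "TA", "CG", "GC")

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns QTL (exposure) and GWAS (outcome) associations on shared SNPs so
#' that effect sizes refer to the same effect allele: when the outcome's
#' effect/other alleles are swapped relative to the exposure, the outcome
#' beta is sign-flipped and its frequency complemented. Palindromic SNPs
#' (A/T, C/G) are removed because strand cannot be resolved, pairs whose
#' aligned allele frequencies differ by more than `freq_tol` are removed,
#' and irreconcilable allele pairs are dropped with a warning count.
#'
#' @param exposure,outcome data.frames with columns `snp_id`,
#'   `allele_effect`, `allele_other`, `freq`, `beta`, `se`, `p`, `n`.
#' @param freq_tol maximum tolerated absolute allele-frequency difference
#'   (default 0.05; pairs with a difference strictly greater are removed).
#' @return A data.frame of harmonized pairs with exposure columns suffixed
#'   `_exp` and outcome columns suffixed `_out`, alleles as in the exposure.
#'   Attribute `n_removed` records counts per removal reason.
#' @export
harmonize <- function(exposure, outcome, freq_tol = 0.05) {
  need <- c("snp_id", "allele_effect", "allele_other", "freq", "beta", "se", "p", "n")
  for (nm in c("exposure", "outcome")) {
    tab <- get(nm)
    if (!all(need %in% names(tab))) {
      stop_config("%s needs columns %s", nm, paste(need, collapse = ", "))
    }
  }
  m <- merge(exposure, outcome, by = "snp_id", suffixes = c("_exp", "_out"))
  if (nrow(m) == 0L) stop_config("no shared snp_ids between exposure and outcome")
  up <- function(x) toupper(as.character(x))
  ae_e <- up(m$allele_effect_exp); ao_e <- up(m$allele_other_exp)
  ae_o <- up(m$allele_effect_out); ao_o <- up(m$allele_other_out)

  pal <- paste0(ae_e, ao_e) %in% PALINDROMIC | paste0(ae_o, ao_o) %in% PALINDROMIC
  same <- ae_e == ae_o & ao_e == ao_o
  swap <- ae_e == ao_o & ao_e == ae_o
  bad <- !(same | swap)

  m$beta_out[swap] <- -m$beta_out[swap]
  m$freq_out[swap] <- 1 - m$freq_out[swap]
  m$allele_effect_out[swap] <- ae_e[swap]
  m$allele_other_out[swap] <- ao_e[swap]

  freq_bad <- abs(m$freq_exp - m$freq_out) > freq_tol
  drop <- pal | bad | (freq_bad & !pal & !bad)
  if (any(bad)) {
    warning(sprintf("%d SNP(s) with irreconcilable alleles removed", sum(bad)))
  }
  out <- m[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- c(palindromic = sum(pal),
                              irreconcilable = sum(bad & !pal),
                              freq_mismatch = sum(freq_bad & !pal & !bad))
  out
}

#' Select independent instruments for Mendelian randomization
#'
#' Candidates significant on the exposure side (`p_exp < p_qtl_threshold`)
#' are ranked by ascending exposure p-value and greedily retained if their
#' LD r-squared with every previously retained instrument is below
#' `r2_max`.
#'
#' @param pairs harmonized pairs from [harmonize()] (columns `snp_id`,
#'   `p_exp` required).
#' @param ld SNP-SNP correlation matrix with dimnames covering the
#'   candidate snp_ids, or NULL for mutually uncorrelated candidates.
#' @param p_qtl_threshold exposure significance threshold (default 1e-6).
#' @param r2_max maximum pairwise LD r-squared among instruments
#'   (default 0.01).
#' @return The retained subset of `pairs` (possibly empty: gene untestable).
#' @export
select_instruments <- function(pairs, ld = NULL, p_qtl_threshold = 1e-6,
                               r2_max = 0.01) {
  cand <- pairs[pairs$p_exp < p_qtl_threshold, , drop = FALSE]
  if (nrow(cand) == 0L) return(cand)
  cand <- cand[order(cand$p_exp, cand$snp_id), , drop = FALSE]
  if (is.null(ld)) {
    rownames(cand) <- NULL
    return(cand)
  }
  ld <- as.matrix(ld)
  if (is.null(rownames(ld))) stop_config("LD matrix needs snp_id dimnames")
  keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    sid <- cand$snp_id[i]
    if (!sid %in% rownames(ld)) stop_config("no LD available for %s", sid)
    ok <- all(ld[sid, cand$snp_id[keep]]^2 < r2_max)
    if (ok) keep <- c(keep, i)
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Steiger directionality filter
#'
#' Removes instruments whose outcome association is significantly stronger
#' than their exposure association, indicating likely reverse causation.
#' The variance explained on each side is approximated as
#' \eqn{r^2 = z^2 / (z^2 + n)} and compared by a one-sided z-test on
#' Fisher-transformed correlations.
#'
#' @param pairs harmonized pairs with columns `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out` and (optionally) `n_exp`, `n_out`.
#' @param n_exp,n_out sample sizes used when the table does not carry them.
#' @param alpha one-sided significance level for removal (default 0.05).
#' @return The retained subset of `pairs`; instruments with missing sample
#'   sizes are retained with a warning.
#' @export
steiger_filter <- function(pairs, n_exp = NULL, n_out = NULL, alpha = 0.05) {
  if (nrow(pairs) == 0L) return(pairs)
  ne <- pairs$n_exp %||% rep(n_exp %||% NA_real_, nrow(pairs))
  no <- pairs$n_out %||% rep(n_out %||% NA_real_, nrow(pairs))
  if (!is.null(n_exp)) ne[!is.finite(ne)] <- n_exp
  if (!is.null(n_out)) no[!is.finite(no)] <- n_out
  if (any(c(ne, no) <= 0, na.rm = TRUE)) stop_config("sample sizes must be positive")
  miss <- !is.finite(ne) | !is.finite(no)
  if (any(miss)) {
    warning(sprintf("%d instrument(s) without sample size retained unfiltered", sum(miss)))
  }
  z_e <- pairs$beta_exp / pairs$se_exp
  z_o <- pairs$beta_out / pairs$se_out
  r_e <- sqrt(z_e^2 / (z_e^2 + ne))
  r_o <- sqrt(z_o^2 / (z_o^2 + no))
  zstat <- (atanh(pmin(r_o, 1 - 1e-12)) - atanh(pmin(r_e, 1 - 1e-12))) /
    sqrt(1 / (ne - 3) + 1 / (no - 3))
  remove <- !miss & zstat > qnorm(1 - alpha)
  out <- pairs[!remove, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Inverse-variance-weighted Mendelian randomization
#'
#' Per-instrument Wald ratios (outcome beta over exposure beta) are
#' combined by fixed-effect inverse-variance weighting with first-order
#' standard errors \eqn{se_{out} / |\beta_{exp}|}; the two-sided p-value
#' uses the normal approximation.
#'
#' @param pairs harmonized, selected instruments with columns `beta_exp`,
#'   `beta_out`, `se_out` (and optionally `gene_id`, `tissue`).
#' @param gene_id,tissue optional labels carried into the result.
#' @return An object of class `mr_result`: a one-row data.frame with
#'   `gene_id`, `statistic` (beta_MR), `se`, `p`, `method`, `tissue`,
#'   `n_snps_or_ivs`.
#' @export
mr_ivw <- function(pairs, gene_id = NA_character_, tissue = NA_character_) {
  if (nrow(pairs) == 0L) stop_config("no instruments")
  zero <- pairs$beta_exp == 0
  if (any(zero)) {
    warning(sprintf("%d instrument(s) with zero exposure beta dropped", sum(zero)))
    pairs <- pairs[!zero, , drop = FALSE]
    if (nrow(pairs) == 0L) stop_config("no instruments left after dropping zero-beta ones")
  }
  wald <- pairs$beta_out / pairs$beta_exp
  se_wald <- pairs$se_out / abs(pairs$beta_exp)
  w <- 1 / se_wald^2
  beta <- sum(w * wald) / sum(w)
  se <- sqrt(1 / sum(w))
  res <- data.frame(gene_id = gene_id, statistic = beta, se = se,
                    p = 2 * pnorm(-abs(beta / se)),
                    method = "QTL-GWAS", tissue = tissue,
                    n_snps_or_ivs = nrow(pairs), stringsAsFactors = FALSE)
  class(res) <- c("mr_result", class(res))
  res
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("IVW MR: beta = %.4g (se %.4g), p = %.3g, %d instrument(s)\n",
              x$statistic, x$se, x$p, x$n_snps_or_ivs))
  invisible(x)
}

#' Aggregate per-tissue MR results for one gene
#'
#' Across tissues, the MR result with the smallest p-value is retained and
#' its tissue label recorded (the cross-tissue "best tissue" rule).
#'
#' @param scores data.frame of per-tissue results (columns `p`, `tissue`),
#'   e.g. rbind-ed [mr_ivw()] rows for one gene.
#' @return The winning row; ties broken by tissue label for determinism.
#' @export
aggregate_tissues <- function(scores) {
  if (is.null(scores) || nrow(scores) == 0L) {
    stop_config("no tissue results to aggregate")
  }
  ord <- order(scores$p, as.character(scores$tissue))
  out <- scores[ord[1L], , drop = FALSE]
  rownames(out) <- NULL
  out
}
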
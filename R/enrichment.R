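# normalize any score table / vector to a named "priority" vector
# (higher = more prioritized)
as_priority <- function(scores) {
  if (is.data.frame(scores)) {
    if (!all(c("gene_id", "p") %in% names(scores))) {
      stop_config("score table needs columns gene_id, p")
    }
    setNames(-scores$p, scores$gene_id)
  } else if (is.numeric(scores) && !is.null(names(scores))) {
    scores  # diffusion / degree scores: higher = more prioritized
  } else {
    stop_config("scores must be a gene_id/p data.frame or a named numeric vector")
  }
}

#' Top prioritized genes at a percentile cutoff
#'
#' Selects exactly `floor(q * n_scored)` genes with the best scores
#' (smallest p-values, or largest diffusion scores), breaking ties at the
#' boundary deterministically by lexicographic gene id. The tied boundary
#' rank range is reported as an attribute for display.
#'
#' @param scores data.frame (`gene_id`, `p`) or a named numeric priority
#'   vector (higher = better).
#' @param q top fraction in (0, 1); conventional defaults are 0.01, and
#'   0.05 for the sparser pQTL-GWAS method.
#' @param background optional gene set; scored genes are restricted to it.
#' @return Character vector of selected gene ids, with attribute
#'   `tie_range` giving the min-max rank range of genes tied with the
#'   boundary score.
#' @export
top_genes <- function(scores, q, background = NULL) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1) {
    stop_config("q must lie in (0, 1)")
  }
  pr <- as_priority(scores)
  if (!is.null(background)) pr <- pr[names(pr) %in% background]
  n <- length(pr)
  k <- floor(q * n)
  if (k < 1L) stop_config("top fraction %g of %d scored genes selects no gene", q, n)
  ord <- order(-pr, names(pr))
  sel <- names(pr)[ord[seq_len(k)]]
  boundary <- pr[ord[k]]
  tied <- which(pr[ord] == boundary)
  attr(sel, "tie_range") <- c(min(tied), max(tied))
  sel
}

#' Fisher exact enrichment of prioritized genes for drug targets
#'
#' Builds the 2x2 contingency table of prioritized status against target
#' status over the declared background (targets are first restricted to
#' the background, since only targets testable by the method count). The
#' p-value is the exact two-sided Fisher test on the raw table. The odds
#' ratio is the sample cross-product ratio with two fallback rules: if no
#' prioritized gene is a target (a = 0) the OR is set to 1, and if a main-
#' diagonal cell (a or d) is zero that cell is set to 1 before forming the
#' OR. The Woolf standard error of the log-OR is computed on the post-rule
#' table. The `adjusted` flag records whether any rule fired.
#'
#' @param prioritized,targets,background character gene sets; prioritized
#'   and targets are restricted to the background.
#' @return List with `table` (a, b, c, d), `or_value`, `log_or`,
#'   `se_log_or`, `p`, `adjusted`.
#' @export
fisher_enrichment <- function(prioritized, targets, background) {
  background <- unique(background)
  if (length(background) == 0L) stop_config("empty background")
  prioritized <- intersect(unique(prioritized), background)
  targets <- intersect(unique(targets), background)
  a <- length(intersect(prioritized, targets))
  b <- length(prioritized) - a
  cc <- length(targets) - a
  d <- length(background) - a - b - cc
  p <- fisher.test(matrix(c(a, b, cc, d), nrow = 2))$p.value
  adjusted <- FALSE
  a2 <- a; d2 <- d
  if (a == 0L) {
    or_value <- 1
    adjusted <- TRUE
    a2 <- 1L  # post-rule table for the Woolf SE
    if (d2 == 0L) d2 <- 1L
  } else {
    if (d == 0L) {
      d2 <- 1L
      adjusted <- TRUE
    }
    or_value <- (a2 * d2) / (b * cc)
  }
  se <- sqrt(1 / a2 + 1 / max(b, 1L) + 1 / max(cc, 1L) + 1 / d2)
  list(table = c(a = a, b = b, c = cc, d = d),
       or_value = or_value, log_or = log(or_value), se_log_or = se,
       p = p, adjusted = adjusted)
}

#' ROC AUC of gene scores against target labels
#'
#' The AUC is the probability that a random target outranks a random
#' non-target (ties counted half), computed with midrank tie handling; the
#' standard error is DeLong's. Computation is delegated to pROC, the
#' field's standard implementation.
#'
#' @param scores data.frame (`gene_id`, `p`) or named priority vector
#'   (higher = more prioritized).
#' @param targets character set of positive genes.
#' @param background gene set over which labels are defined; defaults to
#'   the scored genes.
#' @return List with `auc`, `se_auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, targets, background = NULL) {
  pr <- as_priority(scores)
  if (!is.null(background)) pr <- pr[names(pr) %in% background]
  labels <- as.integer(names(pr) %in% targets)
  if (length(unique(labels)) < 2L) {
    stop_config("need at least one target and one non-target among scored genes")
  }
  roc <- pROC::roc(response = labels, predictor = as.numeric(pr),
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  list(auc = as.numeric(pROC::auc(roc)),
       # DeLong variance is legitimately 0 at AUC = 1; silence pROC's note
       se_auc = sqrt(suppressWarnings(pROC::var(roc))),
       n_pos = sum(labels == 1L), n_neg = sum(labels == 0L))
}

#' Concordance of two gene scoring methods across percentile cutoffs
#'
#' Restricts both score tables to their common gene background, then at
#' each percentile computes the Fisher odds ratio between the two top
#' gene sets. Percentiles at which either method selects no gene, or the
#' two top sets cannot overlap, are reported with `or_value = NA`; zero
#' overlap yields the conventional fill value OR = 1.
#'
#' @param table_a,table_b score tables (`gene_id`, `p`).
#' @param grid percentile fractions in (0, 1); default the conventional
#'   grid 0.1\% to 10\%.
#' @return data.frame with columns `percentile`, `or_value`, `log_or`,
#'   `p`, `n_common`, `n_overlap`, `adjusted`.
#' @export
concordance <- function(table_a, table_b,
                        grid = c(0.001, 0.002, 0.005, 0.01, 0.02, 0.03,
                                 0.05, 0.075, 0.1)) {
  if (any(grid <= 0 | grid >= 1)) stop_config("grid fractions must lie in (0, 1)")
  common <- intersect(table_a$gene_id, table_b$gene_id)
  if (length(common) == 0L) stop_config("no common genes between the two methods")
  a <- table_a[table_a$gene_id %in% common, ]
  b <- table_b[table_b$gene_id %in% common, ]
  out <- lapply(grid, function(q) {
    k <- floor(q * length(common))
    if (k < 1L) {
      return(data.frame(percentile = q, or_value = NA_real_, log_or = NA_real_,
                        p = NA_real_, n_common = length(common),
                        n_overlap = NA_integer_, adjusted = NA))
    }
    ta <- top_genes(a, q)
    tb <- top_genes(b, q)
    fe <- fisher_enrichment(ta, tb, common)
    data.frame(percentile = q, or_value = fe$or_value, log_or = fe$log_or,
               p = fe$p, n_common = length(common),
               n_overlap = fe$table[["a"]], adjusted = fe$adjusted)
  })
  do.call(rbind, out)
}
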
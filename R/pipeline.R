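#' Benchmark run configuration
#'
#' @param synthetic a [synthetic_config()] describing the generated
#'   inputs.
#' @param methods gene scoring methods to benchmark (subset of the
#'   synthetic config's methods).
#' @param r_grid restart parameters; default `c(0, 0.2, 0.4, 0.6, 0.8, 1)`
#'   (1 = no diffusion, 0 = complete diffusion).
#' @param top_fraction named per-method top fractions for enrichment
#'   (default 0.01; 0.05 for pQTL-GWAS).
#' @param background_policy `"per_method"` (each method's testable
#'   genes), `"common"` (genes testable by every method) for the r = 1
#'   analyses; diffusion analyses always use the network nodes.
#' @param include_diffusion run the network diffusion arm (r < 1) with
#'   degree and random baselines.
#' @param conf confidence level for aggregate intervals.
#' @param seed integer global seed (overrides the synthetic config's).
#' @return Object of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       methods = names(synthetic$testable_fractions),
                       r_grid = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                       top_fraction = c("GWAS" = 0.01, "eQTL-GWAS" = 0.01,
                                        "pQTL-GWAS" = 0.05, "Exome" = 0.01),
                       background_policy = c("per_method", "common"),
                       include_diffusion = TRUE,
                       conf = 0.95,
                       seed = synthetic$seed) {
  background_policy <- match.arg(background_policy)
  if (any(r_grid < 0 | r_grid > 1)) stop_config("r_grid must lie in [0, 1]")
  if (length(methods) == 0L) stop_config("empty method list")
  if (!all(methods %in% names(synthetic$testable_fractions))) {
    stop_config("unknown method(s): %s",
                paste(setdiff(methods, names(synthetic$testable_fractions)),
                      collapse = ", "))
  }
  synthetic$seed <- as.integer(seed)
  cfg <- list(synthetic = synthetic, methods = methods, r_grid = sort(r_grid),
              top_fraction = top_fraction,
              background_policy = background_policy,
              include_diffusion = include_diffusion,
              conf = conf, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Read a benchmark run configuration from a YAML file
#'
#' Top-level keys mirror the [run_config()] arguments; the `synthetic`
#' block mirrors [synthetic_config()].
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop_config("the yaml package is required to read YAML configurations")
  }
  y <- yaml::read_yaml(path)
  syn_args <- y$synthetic %||% list()
  if (!is.null(syn_args$testable_fractions)) {
    syn_args$testable_fractions <- unlist(syn_args$testable_fractions)
  }
  if (!is.null(syn_args$top_fraction)) {
    syn_args$top_fraction <- unlist(syn_args$top_fraction)
  }
  syn <- do.call(synthetic_config, syn_args)
  args <- y[setdiff(names(y), "synthetic")]
  if (!is.null(args$top_fraction)) args$top_fraction <- unlist(args$top_fraction)
  do.call(run_config, c(list(synthetic = syn), args))
}

score_se_fill <- function(obs_df) {
  # fallback (OR := 1) observations carry b = 0 and an undefined se;
  # assign the maximum se observed for the method so they are weighted
  # conservatively rather than dropped
  bad <- obs_df$adjusted & !is.finite(obs_df$se)
  if (any(bad)) {
    fill <- max(obs_df$se[is.finite(obs_df$se)], 1)
    obs_df$se[bad] <- fill
  }
  obs_df
}

#' Run the full prioritization benchmark on synthetic data
#'
#' Simulates a cohort, builds per-trait target sets from the generated
#' drug tables with the standard filters (confidence >= 700, interaction
#' types inhibition/activation), scores genes per method, optionally
#' diffuses scores over the generated network across the restart grid
#' (with degree and seeded random baselines), computes Fisher enrichment
#' odds ratios and ROC AUCs per trait x method x database x r, and
#' aggregates them with the Kronecker correlation model.
#'
#' @param config a [run_config()].
#' @param cohort optionally a pre-generated `synthetic_cohort` matching
#'   the configuration (regenerated when NULL).
#' @return Object of class `benchmark_run` with elements `results`
#'   (per-observation table), `aggregates` (per method x r x metric),
#'   `cohort`, `config` and `manifest`.
#' @export
run_benchmark <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  if (is.null(cohort)) {
    cohort <- generate_cohort(config$synthetic,
                              network = config$include_diffusion)
  }
  traits <- names(cohort$disease_genes)
  dbs <- names(cohort$drug_tables)
  net <- if (config$include_diffusion) cohort$networks[[1]] else NULL
  net_nodes <- if (!is.null(net)) network_nodes(net) else NULL

  # target sets per database, through the standard filter path
  target_sets <- setNames(lapply(dbs, function(db) {
    build_target_sets(cohort$drug_tables[[db]]$indications,
                      cohort$drug_tables[[db]]$drug_targets,
                      min_confidence = 700,
                      allowed_types = c("inhibition", "activation"),
                      universe = cohort$universe)
  }), dbs)

  common_bg <- Reduce(intersect, cohort$backgrounds[config$methods])

  arms <- list()
  for (me in config$methods) {
    q <- config$top_fraction[[me]] %||% 0.01
    for (tr in traits) {
      scores <- cohort$score_tables[[me]][[tr]]
      for (r in config$r_grid) {
        if (r == 1) {
          bg <- switch(config$background_policy,
                       per_method = cohort$backgrounds[[me]],
                       common = common_bg)
          pr <- as_priority(scores[scores$gene_id %in% bg, ])
          arms[[length(arms) + 1L]] <- list(method = me, trait = tr, r = 1,
                                            priority = pr, bg = bg, q = q)
        } else if (config$include_diffusion) {
          p0 <- initial_distribution(scores, net)
          pinf <- diffuse(p0, net, r = r)
          arms[[length(arms) + 1L]] <- list(method = me, trait = tr, r = r,
                                            priority = pinf, bg = net_nodes,
                                            q = q)
        }
      }
    }
  }
  # baselines on the network: weighted degree, and diffused random p0
  if (config$include_diffusion) {
    deg <- degree_scores(net)
    for (tr in traits) {
      arms[[length(arms) + 1L]] <- list(method = "degree", trait = tr, r = 0,
                                        priority = deg, bg = net_nodes,
                                        q = 0.01)
      p0r <- random_initial(net, config$seed, match(tr, traits))
      for (r in setdiff(config$r_grid, 1)) {
        pinf <- diffuse(p0r, net, r = r)
        arms[[length(arms) + 1L]] <- list(method = "random", trait = tr, r = r,
                                          priority = pinf, bg = net_nodes,
                                          q = 0.01)
      }
    }
  }

  rows <- lapply(arms, function(a) {
    per_db <- lapply(dbs, function(db) {
      tg <- target_sets[[db]][[a$trait]]
      top <- top_genes(a$priority, a$q, a$bg)
      fe <- fisher_enrichment(top, tg, a$bg)
      auc <- tryCatch(roc_auc(a$priority, tg, a$bg), error = function(e) NULL)
      data.frame(trait = a$trait, method = a$method, database = db, r = a$r,
                 n_background = length(a$bg),
                 n_targets = length(intersect(tg, a$bg)),
                 n_identified = fe$table[["a"]],
                 or_value = fe$or_value, log_or = fe$log_or,
                 se_log_or = fe$se_log_or, p = fe$p, adjusted = fe$adjusted,
                 auc = auc$auc %||% NA_real_, se_auc = auc$se_auc %||% NA_real_,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_db)
  })
  results <- do.call(rbind, rows)

  R_trait <- config$synthetic$trait_corr %||% diag(length(traits))
  R_db <- config$synthetic$db_corr %||%
    db_membership_correlation(lapply(dbs, function(db) target_sets[[db]]),
                              cohort$universe)
  dimnames(R_db) <- list(dbs, dbs)

  agg <- list()
  for (me in unique(results$method)) {
    for (r in unique(results$r[results$method == me])) {
      sub <- results[results$method == me & results$r == r, ]
      # database-major ordering to match kronecker(R_db, R_trait)
      sub <- sub[order(match(sub$database, dbs), match(sub$trait, traits)), ]
      df_or <- score_se_fill(data.frame(b = sub$log_or,
                                        se = ifelse(sub$adjusted, NA_real_,
                                                    sub$se_log_or),
                                        trait = sub$trait,
                                        database = sub$database,
                                        adjusted = sub$adjusted,
                                        stringsAsFactors = FALSE))
      agg_or <- aggregate_observations(
        observation_vector(df_or$b, df_or$se, df_or$trait, df_or$database),
        R_db, R_trait, scale = "log_or", conf = config$conf)
      ok_auc <- all(is.finite(sub$auc))
      agg_auc <- if (ok_auc) {
        aggregate_observations(observation_vector(sub$auc, sub$se_auc,
                                                  sub$trait, sub$database),
                               R_db, R_trait, scale = "auc", conf = config$conf)
      } else NULL
      agg[[length(agg) + 1L]] <- data.frame(
        method = me, r = r, m = nrow(sub),
        overall_or = agg_or$overall_or,
        or_ci_lo = agg_or$or_ci[1], or_ci_hi = agg_or$or_ci[2],
        overall_log_or = agg_or$b_bar, var_log_or = agg_or$var_b_bar,
        overall_auc = if (ok_auc) agg_auc$b_bar else NA_real_,
        auc_ci_lo = if (ok_auc) agg_auc$ci[1] else NA_real_,
        auc_ci_hi = if (ok_auc) agg_auc$ci[2] else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  aggregates <- do.call(rbind, agg)

  manifest <- list(seed = config$seed,
                   methods = config$methods, r_grid = config$r_grid,
                   n_genes = config$synthetic$n_genes,
                   n_traits = length(traits), n_databases = length(dbs),
                   background_policy = config$background_policy,
                   elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
                   package_version = as.character(utils::packageVersion("targetbench")))
  out <- list(results = results, aggregates = aggregates,
              target_sets = target_sets, R_db = R_db, R_trait = R_trait,
              cohort = cohort, config = config, manifest = manifest)
  class(out) <- "benchmark_run"
  out
}

#' @export
print.benchmark_run <- function(x, ...) {
  cat(sprintf("benchmark_run: %d observation(s), methods %s, r in {%s}\n",
              nrow(x$results), paste(unique(x$results$method), collapse = ", "),
              paste(sort(unique(x$results$r)), collapse = ", ")))
  print(x$aggregates[, c("method", "r", "overall_or", "or_ci_lo", "or_ci_hi",
                         "overall_auc")], row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
summary.benchmark_run <- function(object, ...) {
  report(object)
}

#' Summary tables for a benchmark run
#'
#' @param run a `benchmark_run`.
#' @return List with `aggregates` (per method x r overall OR/AUC with
#'   confidence intervals) and `differences` (pairwise method difference
#'   tests on log-OR and AUC at each r).
#' @export
report <- function(run) {
  stopifnot(inherits(run, "benchmark_run"))
  methods <- unique(run$results$method)
  if (length(methods) == 0L) stop_config("empty method list")
  R <- kronecker_correlation(run$R_db, run$R_trait)
  dbs <- colnames(run$R_db)
  traits <- names(run$cohort$disease_genes)
  obs_for <- function(me, r, metric) {
    sub <- run$results[run$results$method == me & run$results$r == r, ]
    if (nrow(sub) == 0L) return(NULL)
    sub <- sub[order(match(sub$database, dbs), match(sub$trait, traits)), ]
    if (metric == "log_or") {
      df <- score_se_fill(transform(sub, b = log_or,
                                    se = ifelse(adjusted, NA, se_log_or)))
      observation_vector(df$b, df$se, df$trait, df$database)
    } else {
      if (any(!is.finite(sub$auc))) return(NULL)
      observation_vector(sub$auc, sub$se_auc, sub$trait, sub$database)
    }
  }
  diffs <- list()
  for (metric in c("log_or", "auc")) {
    for (r in sort(unique(run$results$r))) {
      ms <- methods[vapply(methods, function(me) {
        any(run$results$method == me & run$results$r == r)
      }, logical(1))]
      if (length(ms) < 2L) next
      for (i in seq_len(length(ms) - 1L)) {
        for (j in seq(i + 1L, length(ms))) {
          o1 <- obs_for(ms[i], r, metric)
          o2 <- obs_for(ms[j], r, metric)
          if (is.null(o1) || is.null(o2)) next
          dt <- tryCatch(difference_test(o1, o2, R), error = function(e) NULL)
          if (is.null(dt)) next
          diffs[[length(diffs) + 1L]] <- data.frame(
            metric = metric, r = r, method_1 = ms[i], method_2 = ms[j],
            diff = dt$diff, z = dt$z, p = dt$p, stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(aggregates = run$aggregates,
       differences = if (length(diffs)) do.call(rbind, diffs) else NULL)
}
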
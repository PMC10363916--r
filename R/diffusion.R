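#' Initial node distribution from gene scores
#'
#' Each scored network node receives mass proportional to its squared
#' z-score, with z derived from the gene p-value as
#' \eqn{z = \Phi^{-1}(1 - p/2)}; genes the scoring method could not test
#' get exactly 0. The vector is normalized to sum to 1.
#'
#' @param scores data.frame with columns `gene_id`, `p`.
#' @param network a `gene_network`; only its nodes are used.
#' @return Named numeric vector over network nodes summing to 1 (attribute
#'   `kind = "p0"`).
#' @export
initial_distribution <- function(scores, network) {
  nodes <- network_nodes(network)
  if (length(nodes) == 0L) stop_config("empty network")
  p <- setNames(rep(NA_real_, length(nodes)), nodes)
  hit <- intersect(scores$gene_id, nodes)
  p[hit] <- scores$p[match(hit, scores$gene_id)]
  z2 <- ifelse(is.na(p), 0, qnorm(p / 2, lower.tail = FALSE)^2)
  if (all(z2 == 0)) stop_config("no scored gene overlaps the network: no mass to diffuse")
  v <- z2 / sum(z2)
  attr(v, "kind") <- "p0"
  v
}

#' Seeded random initial distribution
#'
#' A reproducible random nonnegative vector over network nodes summing to
#' 1, distinct per trait index but consistent across analyses: the random-
#' baseline counterpart of [initial_distribution()].
#'
#' @param network a `gene_network`.
#' @param seed integer global seed.
#' @param trait_index integer index making each trait's vector distinct.
#' @return Named numeric vector summing to 1 (attribute `kind = "random"`).
#' @export
random_initial <- function(network, seed, trait_index = 1L) {
  nodes <- network_nodes(network)
  if (length(nodes) == 0L) stop_config("empty network")
  v <- with_seed(child_seed(seed, 7000 + trait_index), runif(length(nodes)))
  v <- setNames(v / sum(v), nodes)
  attr(v, "kind") <- "random"
  v
}

#' Random walk with restart over a gene network
#'
#' Solves the stationary distribution of a restarting random walk,
#' \eqn{p_\infty = (I - (1 - r) W)^{-1} p_0} with W the column-normalized
#' weighted adjacency matrix, and renormalizes it to sum to 1. `r = 1`
#' returns `p0` unchanged (no diffusion); `r = 0` is the restart-free
#' limit, the walk's stationary distribution (proportional to weighted
#' degree on connected undirected graphs), computed by power iteration.
#'
#' @param p0 named nonnegative vector over the network's nodes, summing
#'   to 1 within 1e-12.
#' @param network a `gene_network`; must be connected when `r = 0`.
#' @param r restart parameter in \[0, 1\]; smaller means stronger
#'   diffusion.
#' @param solver `"analytic"` (direct linear solve; dense below
#'   `dense_cutoff` nodes, sparse above) or `"iterative"` (fixed-point
#'   iteration `p <- (1 - r) W p + r p0`).
#' @param tol convergence tolerance for iterative/power solves.
#' @param max_iter iteration cap; exceeding it is an error reporting the
#'   residual.
#' @param dense_cutoff node count above which sparse algebra is used.
#' @return Named numeric vector `p_inf` summing to 1 (attribute
#'   `kind = "p_inf"`, attribute `r`).
#' @export
diffuse <- function(p0, network, r, solver = c("analytic", "iterative"),
                    tol = 1e-10, max_iter = 1e5, dense_cutoff = 2000L) {
  solver <- match.arg(solver)
  if (!is.numeric(r) || length(r) != 1L || r < 0 || r > 1) {
    stop_config("restart parameter r must lie in [0, 1]")
  }
  nodes <- network_nodes(network)
  if (is.null(names(p0)) || !setequal(names(p0), nodes)) {
    stop_config("p0 must be named over exactly the network nodes")
  }
  p0 <- p0[nodes]
  if (any(p0 < 0) || abs(sum(p0) - 1) > 1e-12) {
    stop_config("p0 must be nonnegative and sum to 1")
  }
  if (r == 1) {
    out <- p0
  } else if (r == 0) {
    if (igraph::count_components(network$graph) > 1L) {
      stop_config("r = 0 requires a connected network (stationary distribution undefined)")
    }
    W <- column_normalized_adjacency(network)
    # power iteration from the degree-proportional guess
    p <- degree_scores(network)[nodes]
    p <- p / sum(p)
    for (it in seq_len(max_iter)) {
      pn <- as.numeric(W %*% p)
      pn <- pn / sum(pn)
      delta <- max(abs(pn - p))
      p <- pn
      if (delta < tol) break
      if (it == max_iter) {
        stop_config("power iteration did not converge in %d iterations (residual %g)",
                    max_iter, delta)
      }
    }
    out <- setNames(p, nodes)
  } else {
    if (solver == "analytic") {
      n <- length(nodes)
      if (n <= dense_cutoff) {
        W <- column_normalized_adjacency(network, sparse = FALSE)
        M <- diag(n) - (1 - r) * W
        x <- solve(M, p0)
      } else {
        # the resolvent system is exactly personalized PageRank with
        # damping 1 - r and preference p0 (sparse LU suffers fill-in on
        # scale-free graphs; PRPACK solves the same system exactly)
        x <- igraph::page_rank(network$graph, damping = 1 - r,
                               personalized = p0[nodes],
                               weights = igraph::E(network$graph)$weight,
                               directed = FALSE)$vector[nodes]
      }
    } else {
      W <- column_normalized_adjacency(network)
      x <- p0
      converged <- FALSE
      for (it in seq_len(max_iter)) {
        xn <- (1 - r) * as.numeric(W %*% x) + r * p0
        if (max(abs(xn - x)) < tol * r) {
          x <- xn
          converged <- TRUE
          break
        }
        x <- xn
      }
      if (!converged) {
        stop_config("iterative solver did not converge in %d iterations", max_iter)
      }
    }
    out <- setNames(as.numeric(x) / sum(x), nodes)
  }
  attr(out, "kind") <- "p_inf"
  attr(out, "r") <- r
  out
}
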
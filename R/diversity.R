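#' Rarefied / extrapolated Hill numbers for one sample
#'
#' Estimates the Hill diversity of order q (0 = richness, 1 = exponential
#' Shannon, 2 = inverse Simpson) expected in a subsample of `m` reads drawn
#' without replacement from the observed library, or extrapolated beyond
#' the observed depth.
#'
#' Interpolation uses the analytic hypergeometric expectation of the
#' subsample's abundance frequency counts: for q = 0 the classical
#' rarefaction formula, for q = 1 the expected plug-in entropy
#' (exponentiated), and for q = 2 the closed-form unbiased Simpson
#' estimator `1 / (1/m + (1 - 1/m) sum x(x-1) / (n(n-1)))`, which is valid
#' at any `m`. Extrapolation (m > n) uses the Chao1-based richness
#' estimator for q = 0 and, for q = 1, the sample-fraction-weighted mix of
#' the observed entropy and the Chao-Jost asymptotic entropy estimator.
#' At `m = n` all three reduce to the observed Hill numbers.
#'
#' @param x Integer vector of ASV counts for one sample.
#' @param m Target subsample size (reads).
#' @param q Diversity order: 0, 1 or 2.
#' @return Estimated Hill number of order `q` at size `m`.
#' @export
rarefied_hill <- function(x, m, q) {
  x <- x[x > 0]
  n <- sum(x)
  if (n == 0) stop("empty sample", call. = FALSE)
  stopifnot(m >= 1, q %in% c(0, 1, 2))
  if (q == 2) {
    s2 <- if (n > 1) sum(x * (x - 1)) / (n * (n - 1)) else 0
    return(1 / (1 / m + (1 - 1 / m) * s2))
  }
  if (m <= n) {
    if (q == 0) {
      miss <- exp(lchoose(n - x, m) - lchoose(n, m))
      return(length(x) - sum(miss[is.finite(miss)]))
    }
    # q = 1: E[plug-in entropy at size m], exponentiated
    h <- 0
    for (xi in x) {
      k <- seq_len(min(xi, m))
      h <- h + sum(stats::dhyper(k, xi, n - xi, m) * (-(k / m) * log(k / m)))
    }
    return(exp(h))
  }
  # extrapolation
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  mstar <- m - n
  if (q == 0) {
    if (f1 == 0) return(length(x))
    f0 <- if (f2 > 0) (n - 1) / n * f1^2 / (2 * f2)
          else (n - 1) / n * f1 * (f1 - 1) / 2
    if (f0 == 0) return(length(x))
    return(length(x) +
             f0 * (1 - (1 - f1 / (n * f0 + f1))^mstar))
  }
  p <- x / n
  h_obs <- -sum(p * log(p))
  h_inf <- chao_jost_entropy(x)
  exp(n / m * h_obs + mstar / m * max(h_inf, h_obs))
}

# Asymptotic (sample-coverage-corrected) Shannon entropy estimator.
chao_jost_entropy <- function(x) {
  x <- x[x > 0]
  n <- sum(x)
  if (n <= 1) return(0)
  h <- sum(x / n * (digamma(n) - digamma(x)))
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f1 > 0) {
    a <- if (f2 > 0) 2 * f2 / ((n - 1) * f1 + 2 * f2)
         else 2 / ((n - 1) * (f1 - 1) + 2)
    if (a < 1) {
      r <- seq_len(n - 1)
      h <- h + f1 / n * (1 - a)^(1 - n) *
        (-log(a) - sum((1 - a)^r / r))
    }
  }
  h
}

#' Faith phylogenetic diversity
#'
#' Total branch length of the subtree spanning the ASVs observed in each
#' sample, i.e. the union of root-to-tip paths of present taxa (root
#' included). Computed on unrarefied presences.
#'
#' @param counts Counts matrix (samples x ASVs) or an [asv_table()].
#' @param tree An [ape::read.tree()] phylo object whose tip labels cover
#'   all ASVs in `counts`.
#' @return Named numeric vector of PD per sample.
#' @export
faith_pd <- function(counts, tree) {
  m <- if (inherits(counts, "asv_table")) counts$counts else as.matrix(counts)
  absent <- setdiff(colnames(m), tree$tip.label)
  if (length(absent)) {
    stop("tree is missing tip(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  parent_edge <- integer(max(tree$edge))  # edge index leading into node
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  path_edges <- function(tip_ids) {
    seen <- logical(nrow(tree$edge))
    for (node in tip_ids) {
      while (parent_edge[node] != 0L) {
        e <- parent_edge[node]
        if (seen[e]) break
        seen[e] <- TRUE
        node <- tree$edge[e, 1]
      }
    }
    seen
  }
  pd <- vapply(seq_len(nrow(m)), function(i) {
    tips <- match(colnames(m)[m[i, ] > 0], tree$tip.label)
    if (length(tips) == 0) return(0)
    sum(tree$edge.length[path_edges(tips)])
  }, numeric(1))
  stats::setNames(pd, rownames(m))
}

#' Per-sample alpha diversity profile
#'
#' Richness and Hill numbers of order 1 and 2 are estimated at a common
#' `base_size` by rarefaction (samples deeper than `base_size`) or
#' extrapolation (shallower samples, capped at `extrapolation_cap` times
#' the observed depth). Faith PD and evenness are computed from unrarefied
#' data; raw Shannon entropy is also reported for transparency.
#'
#' @param table An [asv_table()] (controls should be filtered out first).
#' @param tree Optional phylo tree for Faith PD (`faith_pd` is `NA`
#'   without one).
#' @param base_size Common reference depth; defaults to the minimum sample
#'   depth.
#' @param extrapolation_cap Maximum extrapolation factor relative to a
#'   sample's own depth (default 2; requests beyond it are capped with a
#'   warning).
#' @param evenness `"pielou"` (Shannon entropy / log richness, the
#'   default) or `"hill_ratio"` (Hill-1 / richness), both unrarefied.
#' @return Data frame with one row per sample: `sample_id`, `treatment`,
#'   `n_reads`, `richness`, `hill1`, `hill2`, `shannon`, `faith_pd`,
#'   `evenness`.
#' @export
alpha_diversity <- function(table, tree = NULL, base_size = NULL,
                            extrapolation_cap = 2,
                            evenness = c("pielou", "hill_ratio")) {
  evenness <- match.arg(evenness)
  m <- table$counts
  depths <- rowSums(m)
  if (is.null(base_size)) base_size <- min(depths)
  stopifnot(base_size > 0)
  pd <- if (!is.null(tree)) faith_pd(m, tree) else rep(NA_real_, nrow(m))
  out <- lapply(seq_len(nrow(m)), function(i) {
    x <- m[i, ]
    x <- x[x > 0]
    n <- sum(x)
    target <- base_size
    if (target > extrapolation_cap * n) {
      warning("sample ", rownames(m)[i], ": extrapolation capped at ",
              extrapolation_cap, "x observed depth")
      target <- extrapolation_cap * n
    }
    p <- x / n
    h <- -sum(p * log(p))
    ev <- if (evenness == "pielou") {
      if (length(x) > 1) h / log(length(x)) else 0
    } else {
      exp(h) / length(x)
    }
    data.frame(sample_id = rownames(m)[i],
               treatment = table$sample_meta$treatment[i],
               n_reads = n,
               richness = rarefied_hill(x, target, 0),
               hill1 = rarefied_hill(x, target, 1),
               hill2 = rarefied_hill(x, target, 2),
               shannon = h,
               faith_pd = unname(pd[i]),
               evenness = ev)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
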
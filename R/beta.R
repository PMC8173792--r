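#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` computed on per-sample
#' relative abundances (so sequencing depth does not enter).
#'
#' @param x An [asv_table()], a counts matrix, or a matrix of relative
#'   abundances (rows summing to 1).
#' @return A `dist` object with sample labels.
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "asv_table")) x$counts else as.matrix(x)
  rel <- if (isTRUE(all.equal(unname(rowSums(m)), rep(1, nrow(m)),
                              tolerance = 1e-8))) m else relative_abundance(m)
  vegan::vegdist(rel, method = "bray")
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal stress-1 NMDS via [vegan::metaMDS()] (iterative stress
#' minimisation with multiple seeded random restarts; the best solution is
#' kept).
#'
#' @param d A `dist` object or symmetric matrix.
#' @param k Embedding dimension.
#' @param restarts Number of random starts.
#' @param seed RNG seed for reproducible restarts.
#' @return List with `points` (n x k coordinates), `stress` (stress-1, in
#'   [0, 1]), `converged`, and the underlying vegan `ord` object.
#' @export
nmds_ordination <- function(d, k = 2, restarts = 50, seed = 42) {
  d <- stats::as.dist(d)
  if (attr(d, "Size") < k + 2) {
    stop("need at least k + 2 samples for a ", k, "-dimensional NMDS",
         call. = FALSE)
  }
  ord <- withr_seed(seed, vegan::metaMDS(d, k = k, try = restarts,
                                         trymax = restarts, trace = 0,
                                         wascores = FALSE))
  if (!ord$converged) {
    warning("NMDS did not converge within the restart budget; ",
            "best solution returned")
  }
  list(points = ord$points, stress = ord$stress,
       converged = isTRUE(ord$converged) || is.numeric(ord$converged),
       ord = ord)
}

# run code with a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

permanova_ss <- function(d2, groups) {
  n <- nrow(d2)
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw <- 0
  for (g in levels(groups)) {
    i <- which(groups == g)
    if (length(i) > 1) {
      sub <- d2[i, i, drop = FALSE]
      ssw <- ssw + sum(sub[upper.tri(sub)]) / length(i)
    }
  }
  c(sst = sst, ssw = ssw)
}

unique_perms <- function(x) {
  # all distinct orderings of a multiset of labels
  x <- sort(x)
  res <- list()
  recurse <- function(prefix, rest) {
    if (!length(rest)) {
      res[[length(res) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in unique(rest)) {
      recurse(c(prefix, v), rest[-match(v, rest)])
    }
  }
  recurse(character(0), as.character(x))
  res
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-way PERMANOVA on a dissimilarity matrix: the pseudo-F statistic is
#' built from the partition of squared dissimilarities into among- and
#' within-group components, and its null distribution from unrestricted
#' permutation of sample labels. `method = "exhaustive"` enumerates every
#' distinct relabelling (feasible for small n) and returns the exact
#' permutation p-value `#{F_perm >= F_obs} / n_distinct` (observed
#' assignment included); the sampled mode uses
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`.
#'
#' @param d `dist` or symmetric dissimilarity matrix.
#' @param groups Factor (or coercible) of group labels, each group n >= 2.
#' @param n_perm Number of sampled permutations.
#' @param seed RNG seed for the sampled mode.
#' @param method `"sampled"` or `"exhaustive"`.
#' @return List with `pseudo_F`, `R2`, `p_value`, `n_permutations`,
#'   `method`, `df`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 42,
                      method = c("sampled", "exhaustive")) {
  method <- match.arg(method)
  dm <- as.matrix(stats::as.dist(d))
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups", call. = FALSE)
  if (any(table(groups) < 2)) {
    stop("every group needs n >= 2", call. = FALSE)
  }
  stopifnot(length(groups) == nrow(dm))
  d2 <- dm^2
  n <- nrow(dm)
  a <- nlevels(groups)
  fstat <- function(g) {
    ss <- permanova_ss(d2, g)
    ((ss["sst"] - ss["ssw"]) / (a - 1)) / (ss["ssw"] / (n - a))
  }
  ss_obs <- permanova_ss(d2, groups)
  f_obs <- unname(((ss_obs["sst"] - ss_obs["ssw"]) / (a - 1)) /
                    (ss_obs["ssw"] / (n - a)))
  r2 <- unname((ss_obs["sst"] - ss_obs["ssw"]) / ss_obs["sst"])
  if (method == "exhaustive") {
    perms <- unique_perms(as.character(groups))
    f_all <- vapply(perms, function(p) {
      unname(fstat(factor(p, levels = levels(groups))))
    }, numeric(1))
    p <- mean(f_all >= f_obs - 1e-12)
    n_used <- length(perms)
  } else {
    f_perm <- withr_seed(seed, vapply(seq_len(n_perm), function(i) {
      unname(fstat(groups[sample.int(n)]))
    }, numeric(1)))
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  list(pseudo_F = f_obs, R2 = r2, p_value = p, n_permutations = n_used,
       method = method, df = c(among = a - 1, within = n - a))
}

#' Pairwise PERMANOVA with Holm correction
#'
#' @inheritParams permanova
#' @return Data frame with one row per group pair: `group1`, `group2`,
#'   `pseudo_F`, `R2`, `p_value`, `p_holm`.
#' @export
pairwise_permanova <- function(d, groups, n_perm = 999, seed = 42) {
  dm <- as.matrix(stats::as.dist(d))
  groups <- factor(groups)
  pairs <- utils::combn(levels(groups), 2, simplify = FALSE)
  rows <- lapply(seq_along(pairs), function(j) {
    pr <- pairs[[j]]
    i <- which(groups %in% pr)
    res <- permanova(dm[i, i], droplevels(groups[i]), n_perm = n_perm,
                     seed = seed + j)
    data.frame(group1 = pr[1], group2 = pr[2], pseudo_F = res$pseudo_F,
               R2 = res$R2, p_value = res$p_value)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  out
}

#' Within-group dissimilarity dispersion test
#'
#' Pools the `n (n - 1) / 2` within-group pairwise Bray-Curtis
#' dissimilarities of each group and compares their distributions across
#' groups with a Kruskal-Wallis rank-sum test, followed by pairwise exact
#' Wilcoxon rank-sum tests with Holm correction. Similarities
#' (1 - dissimilarity) are reported alongside.
#'
#' @param d `dist` or symmetric dissimilarity matrix.
#' @param groups Group labels, each group n >= 3 (so at least 3 pairs).
#' @return List with `values` (data frame: `group`, `dissimilarity`,
#'   `similarity`), `kruskal` (list with `chi2`, `df`, `p_value`), and
#'   `pairwise` (data frame with raw and Holm-adjusted Wilcoxon p-values).
#' @export
within_group_dispersion <- function(d, groups) {
  dm <- as.matrix(stats::as.dist(d))
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups", call. = FALSE)
  if (any(table(groups) < 3)) {
    stop("every group needs n >= 3 for within-group pairs", call. = FALSE)
  }
  vals <- do.call(rbind, lapply(levels(groups), function(g) {
    i <- which(groups == g)
    sub <- dm[i, i, drop = FALSE]
    v <- sub[upper.tri(sub)]
    data.frame(group = g, dissimilarity = v, similarity = 1 - v)
  }))
  kw <- kruskal_wallis(vals$dissimilarity, vals$group)
  pairs <- utils::combn(levels(groups), 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    a <- vals$dissimilarity[vals$group == pr[1]]
    b <- vals$dissimilarity[vals$group == pr[2]]
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = TRUE))
    data.frame(group1 = pr[1], group2 = pr[2], W = unname(wt$statistic),
               p_value = wt$p.value)
  }))
  pw$p_holm <- stats::p.adjust(pw$p_value, method = "holm")
  list(values = vals, kruskal = kw, pairwise = pw)
}
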
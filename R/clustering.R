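# Sample-level structure: Pearson-correlation / Ward dendrograms with
# multiscale-bootstrap edge support (AU and BP), and centered PCA.

#' Drop low-variation positions
#'
#' Removes positions whose across-sample standard deviation is strictly below
#' the median of all position standard deviations (ties at the median are
#' kept). Mirrors the usual pre-clustering "sd < Q50" filter.
#'
#' @param x positions x samples matrix (e.g. from [percent_matrix()]).
#' @return the filtered matrix.
#' @export
filter_low_variation <- function(x) {
  stop_if_not(ncol(x) >= 2, "need at least two samples")
  sds <- apply(x, 1, stats::sd, na.rm = TRUE)
  sds[is.na(sds)] <- 0
  x[sds >= stats::median(sds), , drop = FALSE]
}

cor_dist <- function(x, use = "pairwise.complete.obs") {
  cc <- stats::cor(x, use = use)
  if (anyNA(cc))
    stop("correlation undefined for some sample pair (zero variance or no shared positions)",
         call. = FALSE)
  stats::as.dist(1 - cc)
}

#' Ward dendrogram on correlation distance
#'
#' Distance between samples is `1 - Pearson correlation` of their methylation
#' profiles (pairwise-complete over positions); agglomeration is Ward's
#' minimum-variance update applied to these dissimilarities (classic
#' Lance-Williams "ward" linkage). Samples are ordered lexicographically by
#' id before clustering so ties break deterministically.
#'
#' @param x positions x samples matrix.
#' @param use missing-value handling passed to [stats::cor()].
#' @return an object of class `methyl_clust` wrapping the `hclust` tree; AU
#'   and BP supports are absent until [multiscale_bootstrap()] fills them.
#' @export
ward_correlation_tree <- function(x, use = "pairwise.complete.obs") {
  stop_if_not(ncol(x) >= 2, "need at least two samples")
  x <- x[, order(colnames(x)), drop = FALSE]
  v <- apply(x, 2, stats::var, na.rm = TRUE)
  if (any(v == 0 | is.na(v)))
    stop("sample with zero variance: correlation undefined", call. = FALSE)
  hc <- stats::hclust(cor_dist(x, use), method = "ward.D")
  structure(list(hclust = hc, labels = hc$labels,
                 edges = tree_edges(hc), au = NULL, bp = NULL,
                 nboot = 0, scales = NULL),
            class = "methyl_clust")
}

# internal-edge bipartitions of an hclust tree as sorted label vectors
# (the root clade containing all leaves is excluded)
tree_edges <- function(hc) {
  labs <- hc$labels
  n <- length(labs)
  clades <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    members <- integer(0)
    for (k in 1:2) {
      ch <- hc$merge[i, k]
      members <- c(members, if (ch < 0) -ch else clades[[ch]])
    }
    clades[[i]] <- sort(members)
  }
  edges <- lapply(clades, function(m) sort(labs[m]))
  edges[-(n - 1)]
}

edge_keys <- function(edges) vapply(edges, paste, "", collapse = "\r")

#' Multiscale bootstrap support for a correlation dendrogram
#'
#' Positions are resampled with replacement at a grid of relative sizes
#' `r` (default ten scales 0.5 to 1.4); at each scale the tree is recomputed
#' `nboot` times and each reference edge's recovery frequency `BP_r` is
#' recorded. Per edge, `qnorm(1 - BP_r)` is regressed on `(sqrt(r),
#' 1/sqrt(r))` by weighted least squares (binomial weights), giving signed
#' distance `v` and curvature `c`; the approximately unbiased support is
#' `AU = 1 - pnorm(v - c)` and the plain bootstrap probability at `r = 1` is
#' reported as BP. Each scale draws from an RNG substream derived from
#' `(seed, r)`, so the BP reported for `r = 1` is definitionally the plain
#' bootstrap proportion for that seed.
#'
#' @param x positions x samples matrix.
#' @param nboot bootstrap replicates per scale (default 10000; values below
#'   100 flag the result as degraded).
#' @param scales relative resampling sizes.
#' @param seed integer seed for the bootstrap streams.
#' @param use missing-value handling for the correlations.
#' @return a `methyl_clust` with per-edge `au` and `bp` (percent).
#' @export
multiscale_bootstrap <- function(x, nboot = 10000,
                                 scales = seq(0.5, 1.4, by = 0.1),
                                 seed = 1, use = "pairwise.complete.obs") {
  tree <- ward_correlation_tree(x, use)
  x <- x[, order(colnames(x)), drop = FALSE]
  degraded <- nboot < 100
  if (degraded)
    warning("nboot < 100: AU/BP estimates will be unstable", call. = FALSE)
  n <- nrow(x)
  keys <- edge_keys(tree$edges)
  bp <- matrix(0, length(keys), length(scales),
               dimnames = list(NULL, sprintf("r%.2f", scales)))
  for (s in seq_along(scales)) {
    r <- scales[s]
    m <- max(2L, as.integer(round(r * n)))
    set.seed(derive_seed(seed, "scale", round(1000 * r)))
    hits <- numeric(length(keys))
    for (b in seq_len(nboot)) {
      idx <- sample.int(n, m, replace = TRUE)
      hc <- tryCatch(stats::hclust(cor_dist(x[idx, , drop = FALSE], use),
                                   method = "ward.D"),
                     error = function(e) NULL)
      if (is.null(hc)) next
      hits <- hits + (keys %in% edge_keys(tree_edges(hc)))
    }
    bp[, s] <- hits / nboot
  }
  fit <- fit_au(bp, scales, nboot)
  tree$au <- fit$au * 100
  tree$bp <- fit$bp * 100
  tree$bp_raw <- bp
  tree$nboot <- nboot
  tree$scales <- scales
  tree$seed <- seed
  tree$degraded <- degraded
  tree
}

# WLS fit of the multiscale model per edge; returns AU and the plain BP at
# the scale closest to r = 1 (the model-free bootstrap proportion).
fit_au <- function(bp, scales, nboot) {
  n_edge <- nrow(bp)
  au <- numeric(n_edge)
  at1 <- which.min(abs(scales - 1))
  bp1 <- bp[, at1]
  for (e in seq_len(n_edge)) {
    b <- bp[e, ]
    use <- b > 0 & b < 1
    if (sum(use) < 2) {
      au[e] <- if (mean(b) > 0.5) 1 else 0
      next
    }
    r <- scales[use]
    z <- stats::qnorm(1 - b[use])
    w <- nboot * stats::dnorm(z)^2 / (b[use] * (1 - b[use]))
    X <- cbind(sqrt(r), 1 / sqrt(r))
    cf <- tryCatch(stats::lm.wfit(X, z, w)$coefficients,
                   error = function(e) c(NA, NA))
    if (anyNA(cf)) {
      au[e] <- bp1[e]
    } else {
      au[e] <- 1 - stats::pnorm(cf[1] - cf[2])
    }
  }
  list(au = pmin(pmax(au, 0), 1), bp = bp1)
}

#' @export
print.methyl_clust <- function(x, ...) {
  cat(sprintf("Correlation/Ward tree over %d samples", length(x$labels)))
  if (!is.null(x$au))
    cat(sprintf(" with AU/BP support (nboot = %d, %d scales)",
                x$nboot, length(x$scales)))
  cat("\n")
  if (!is.null(x$au)) {
    ed <- data.frame(edge = vapply(x$edges, paste, "", collapse = ","),
                     au = round(x$au, 1), bp = round(x$bp, 1))
    print(ed, row.names = FALSE)
  }
  invisible(x)
}

#' @method plot methyl_clust
#' @export
plot.methyl_clust <- function(x, main = "Methylation profile clustering", ...) {
  graphics::plot(x$hclust, main = main,
                 ylab = "Ward height (1 - Pearson r)", ...)
  if (!is.null(x$au)) {
    # label internal merges with AU/BP; node x = mean leaf order position
    hc <- x$hclust
    n <- length(hc$labels)
    ord <- match(seq_len(n), hc$order)
    members <- vector("list", n - 1)
    clx <- numeric(n - 1)
    for (i in seq_len(n - 1)) {
      mem <- integer(0)
      for (k in 1:2) {
        ch <- hc$merge[i, k]
        mem <- c(mem, if (ch < 0) -ch else members[[ch]])
      }
      members[[i]] <- mem
      clx[i] <- mean(ord[mem])
    }
    lab <- sprintf("%.0f/%.0f", x$au, x$bp)
    graphics::text(clx[-(n - 1)], hc$height[-(n - 1)], lab,
                   pos = 3, cex = 0.7, col = "red3")
  }
  invisible(x)
}

#' Export a support-annotated tree as Newick
#'
#' Internal nodes carry `AU/BP` (percent) as node labels when supports are
#' available.
#'
#' @param tree a `methyl_clust`.
#' @param path optional file; if omitted the Newick string is returned.
#' @return the Newick string, invisibly when written to file.
#' @export
as_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree$hclust)
  if (!is.null(tree$au)) {
    # map hclust internal nodes to phylo nodes via their leaf sets
    lab <- rep("", phy$Nnode)
    phy_clades <- lapply(seq_len(phy$Nnode) + length(phy$tip.label),
                         function(nd) sort(ape::extract.clade(phy, nd)$tip.label))
    pk <- edge_keys(phy_clades)
    ek <- edge_keys(tree$edges)
    hit <- match(pk, ek)
    lab[!is.na(hit)] <- sprintf("%.0f/%.0f", tree$au[hit[!is.na(hit)]],
                                tree$bp[hit[!is.na(hit)]])
    phy$node.label <- lab
  }
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}

#' Does a sample set form an exclusive clade, and how supported is it?
#'
#' @param tree a `methyl_clust`.
#' @param samples character vector of sample ids.
#' @return list with `is_clade` and, when supports are available, the edge's
#'   `au` and `bp` (NA when the set is not a clade).
#' @export
clade_support <- function(tree, samples) {
  key <- paste(sort(samples), collapse = "\r")
  hit <- match(key, edge_keys(tree$edges))
  list(is_clade = !is.na(hit),
       au = if (!is.na(hit) && !is.null(tree$au)) tree$au[hit] else NA_real_,
       bp = if (!is.na(hit) && !is.null(tree$bp)) tree$bp[hit] else NA_real_)
}

#' Principal-component scores of sample methylation profiles
#'
#' Complete-case positions only; profiles are column-centered and decomposed
#' by SVD.
#'
#' @param x positions x samples matrix.
#' @return list with `scores` (samples x components) and `variance_explained`
#'   (fractions summing to 1).
#' @export
pca_scores <- function(x) {
  x <- x[stats::complete.cases(x), , drop = FALSE]
  stop_if_not(nrow(x) >= 2, "need at least two complete positions")
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, variance_explained = ve)
}
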
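# Independent oracles and small fixture builders used across the suite.

# beta-binomial draws with dispersion phi (phi = 0 -> binomial)
rbb <- function(n, C, p, phi) {
  if (phi <= 0) return(rbinom(n, C, p))
  a <- p * (1 - phi) / phi
  b <- (1 - p) * (1 - phi) / phi
  rbinom(n, C, rbeta(n, a, b))
}

# BH step-up applied literally to a p-value vector
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# exact two-sided Fisher p for a 2 x K table by full enumeration of all
# tables with the observed margins
fisher_enum_oracle <- function(tab) {
  r <- rowSums(tab)
  cs <- colSums(tab)
  K <- ncol(tab)
  prob_of <- function(row1) {
    row2 <- cs - row1
    if (any(row2 < 0)) return(NA_real_)
    exp(sum(lchoose(cs, row1)) - lchoose(sum(cs), r[1]))
  }
  grid <- expand.grid(lapply(cs[-K], function(m) 0:min(m, r[1])))
  probs <- apply(grid, 1, function(g) {
    last <- r[1] - sum(g)
    if (last < 0 || last > cs[K]) return(NA_real_)
    prob_of(c(unlist(g), last))
  })
  probs <- probs[!is.na(probs)]
  p_obs <- prob_of(tab[1, ])
  sum(probs[probs <= p_obs * (1 + 1e-9)])
}

# brute-force Ward agglomeration by the Lance-Williams update on a given
# dissimilarity matrix ("ward" coefficients); returns merge heights and the
# leaf partition at each step
ward_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  sizes <- rep(1, n)
  active <- rep(TRUE, n)
  merges <- list()
  dd <- d
  diag(dd) <- Inf
  dd[!active, ] <- Inf
  for (step in seq_len(n - 1)) {
    dd2 <- dd
    dd2[!active, ] <- Inf
    dd2[, !active] <- Inf
    ij <- which(dd2 == min(dd2), arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    merges[[step]] <- list(members = sort(c(clusters[[i]], clusters[[j]])),
                           height = dd2[i, j])
    # Lance-Williams Ward update into slot i
    for (k in seq_len(n)) {
      if (!active[k] || k %in% c(i, j)) next
      ni <- sizes[i]; nj <- sizes[j]; nk <- sizes[k]
      dd[i, k] <- dd[k, i] <-
        ((ni + nk) * dd[i, k] + (nj + nk) * dd[j, k] - nk * dd[i, j]) /
        (ni + nj + nk)
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
  }
  merges
}

# leaf-index sets of every merge of an hclust tree (including the root)
hclust_clades <- function(hc) {
  n <- length(hc$labels)
  clades <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    mem <- integer(0)
    for (k in 1:2) {
      ch <- hc$merge[i, k]
      mem <- c(mem, if (ch < 0) -ch else clades[[ch]])
    }
    clades[[i]] <- sort(mem)
  }
  clades
}

# small in-memory cytosine table
toy_table <- function(df, id = "s", group = "g", control = NULL) {
  cytosine_table(df, sample_id = id, group = group, control = control)
}

# united two-group table from beta-binomial draws around given fractions
sim_united <- function(p_t, p_c, reps = 3, cov_mu = 20, phi = 0, seed = 1) {
  set.seed(seed)
  n <- length(p_t)
  C <- matrix(rnbinom(n * 2 * reps, mu = cov_mu, size = 3), n) + 1
  M <- cbind(
    matrix(rbb(n * reps, as.vector(C[, 1:reps]), rep(p_t, reps), phi), n),
    matrix(rbb(n * reps, as.vector(C[, (reps + 1):(2 * reps)]), rep(p_c, reps), phi), n)
  )
  united_table(data.frame(chrom = "Chr1", pos = seq_len(n) * 10L), M, C,
               rep(c("t", "c"), each = reps))
}

# standard small simulated study reused by several files
small_study <- function(seed = 7, design = c(MMM = "MMM", SMM = "SMM", SSS = "SSS"),
                        n_cg = 2000, n_resp = 200, delta_stress = 0.15, ...) {
  m <- epigenome_model(n_cg = n_cg, n_chg = 200, n_chh = 200,
                       n_chloroplast = 1000, n_stress_responsive = n_resp,
                       delta_stress = delta_stress, seed = seed, ...)
  simulate_study(pedigree(design, replicates = 3, pool_size = 10), m)
}

study_united <- function(sim, context = "CG", groups = NULL) {
  tabs <- normalize_coverage(lapply(sim$samples,
                                    function(t) destrand_cg(filter_by_coverage(t))))
  groups <- groups %||% sub("_[0-9]+$", "", names(sim$samples))
  unite_samples(tabs, groups = groups, min_per_group = 2, context = context)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a clade verdict counts as treatment grouping only with real edge support
supported_clade <- function(v, threshold = 95) {
  isTRUE(v$is_clade) && isTRUE(v$au >= threshold)
}
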
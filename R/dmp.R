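# Per-position differential methylation testing between two groups of pooled
# samples. Default backend: beta-binomial Wald test with per-position
# method-of-moments dispersion shrunk toward an empirical prior; alternative
# backend: binomial regression with a quasi-likelihood scale factor.

group_mats <- function(united, group) {
  j <- united$design$group == group
  stop_if_not(any(j), sprintf("no samples in group '%s'", group))
  list(M = united$M[, j, drop = FALSE], C = united$C[, j, drop = FALSE])
}

#' Estimate per-position beta-binomial dispersion with shrinkage
#'
#' For each position the within-group replicate counts give a Williams-type
#' method-of-moments dispersion: with group proportion `p = sum(M)/sum(C)`,
#' the chi-square statistic `sum((M - C p)^2 / (C p (1 - p)))` has expectation
#' `(n - 1)(1 + (C - 1) phi)` under the beta-binomial, which is solved for
#' `phi` pooling both groups. Raw estimates are then shrunk toward an
#' empirical prior fitted across positions (log-normal on `log(phi + 1e-3)`;
#' prior mean moment-matched on the raw scale) with precision weights
#' `w = tau^2 / (tau^2 + sigma_i^2)`, `sigma_i^2 ~ 2 / (n_i - 2)` being the
#' approximate log-scale sampling variance at a position with `n_i` usable
#' replicates. Positions with no usable raw estimate get the prior mean.
#'
#' @param united a `united_table`.
#' @param treatment,control the two group labels (defaults: the first two
#'   groups in the design).
#' @return an object of class `dispersion_estimate`: list with `phi`
#'   (shrunk), `phi_raw`, `weight`, `prior` and `n` per position.
#' @export
estimate_dispersion <- function(united, treatment = NULL, control = NULL) {
  gl <- unique(united$design$group)
  treatment <- treatment %||% gl[1]
  control <- control %||% gl[2]
  num <- den <- n_tot <- rep(0, nrow(united$M))
  for (g in c(treatment, control)) {
    gm <- group_mats(united, g)
    ok <- !is.na(gm$C) & gm$C > 0
    n_g <- rowSums(ok)
    totC <- rowSums(gm$C, na.rm = TRUE)
    p <- rowSums(gm$M, na.rm = TRUE) / pmax(totC, 1)
    info <- n_g >= 2 & p > 0 & p < 1
    res2 <- (gm$M - gm$C * p)^2 / (gm$C * p * (1 - p))
    chi2 <- rowSums(ifelse(ok, res2, 0))
    num <- num + ifelse(info, chi2 - (n_g - 1), 0)
    den <- den + ifelse(info,
                        rowSums(ifelse(ok, gm$C - 1, 0)) * (n_g - 1) / n_g, 0)
    n_tot <- n_tot + n_g
  }
  phi_raw <- ifelse(den > 0, pmax(0, pmin(num / den, 0.99)), NA_real_)
  valid <- !is.na(phi_raw)
  phi0 <- 1e-3
  if (any(valid)) {
    psi <- log(phi_raw[valid] + phi0)
    mu <- mean(psi)
    s2 <- if (sum(valid) > 1) stats::var(psi) else 0
    sigma2 <- 2 / pmax(n_tot - 2, 1)
    tau2 <- max(s2 - mean(sigma2[valid]), 1e-6)
    prior_mean <- mean(phi_raw[valid])
    w <- tau2 / (tau2 + sigma2)
    phi <- ifelse(valid, w * phi_raw + (1 - w) * prior_mean, prior_mean)
  } else {
    mu <- NA_real_; s2 <- NA_real_; tau2 <- NA_real_
    prior_mean <- 0
    w <- rep(0, length(phi_raw))
    phi <- rep(0, length(phi_raw))
  }
  structure(list(phi = phi, phi_raw = phi_raw, weight = w, n = n_tot,
                 prior = list(mean = prior_mean, log_mean = mu,
                              log_var = s2, tau2 = tau2)),
            class = "dispersion_estimate")
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat(sprintf("Dispersion estimates for %d positions: prior mean %.4f, mean shrunk %.4f\n",
              length(x$phi), x$prior$mean, mean(x$phi)))
  invisible(x)
}

# Vectorised beta-binomial Wald core. M*/C* are positions x replicates
# matrices; phi recycled per position. Returns delta (treatment - control),
# the Wald z and the two-sided normal p.
wald_core <- function(Mt, Ct, Mc, Cc, phi) {
  grp <- function(M, C) {
    totC <- rowSums(C, na.rm = TRUE)
    totM <- rowSums(M, na.rm = TRUE)
    p <- totM / totC
    # 0.5 pseudo-counts on the group totals for variance only, so boundary
    # proportions keep a finite, non-zero variance
    pv <- ifelse(p <= 0 | p >= 1, (totM + 0.5) / (totC + 1), p)
    v <- pv * (1 - pv) *
      rowSums(ifelse(is.na(C), 0, C * (1 + (C - 1) * phi))) / totC^2
    list(p = p, v = v)
  }
  a <- grp(Mt, Ct)
  b <- grp(Mc, Cc)
  delta <- a$p - b$p
  se <- sqrt(a$v + b$v)
  z <- ifelse(se > 0, delta / se, 0)
  p <- ifelse(delta == 0, 1, 2 * stats::pnorm(-abs(z)))
  list(delta = delta, stat = z, p = p)
}

as_count_mat <- function(counts) {
  counts <- as.data.frame(counts)
  stop_if_not(all(c("M", "C") %in% names(counts)),
              "counts need columns M and C")
  list(M = matrix(counts$M, nrow = 1), C = matrix(counts$C, nrow = 1))
}

#' Beta-binomial Wald test at a single position
#'
#' `delta` is the coverage-pooled methylation fraction difference
#' (treatment - control); its variance per group is
#' `p(1-p) * sum(C_i (1 + (C_i - 1) phi)) / (sum C_i)^2`; the Wald statistic
#' `delta / sqrt(var_t + var_c)` is referred to the standard normal
#' (two-sided). With `phi = 0` this is the unpooled two-proportion z-test on
#' the summed counts.
#'
#' @param treatment,control data frames with columns `M` and `C` (one row per
#'   replicate).
#' @param phi beta-binomial dispersion (default 0).
#' @return list with `delta`, `stat`, `p`.
#' @export
test_position <- function(treatment, control, phi = 0) {
  t <- as_count_mat(treatment)
  c <- as_count_mat(control)
  stop_if_not(sum(t$C) > 0 && sum(c$C) > 0,
              "zero total coverage in a group")
  r <- wald_core(t$M, t$C, c$M, c$C, phi)
  lapply(r, as.numeric)
}

# Binomial regression backend for one position. Returns delta, p and the
# quasi-likelihood scale (sum of squared Pearson residuals / df).
logistic_one <- function(Mt, Ct, Mc, Cc) {
  M <- c(Mt, Mc); C <- c(Ct, Cc)
  keep <- !is.na(C) & C > 0
  M <- M[keep]; C <- C[keep]
  grp <- factor(rep(c("t", "c"), c(length(Mt), length(Mc)))[keep],
                levels = c("c", "t"))
  pt <- sum(M[grp == "t"]) / sum(C[grp == "t"])
  pc <- sum(M[grp == "c"]) / sum(C[grp == "c"])
  delta <- pt - pc
  # continuity adjustment under separation: a group entirely at 0 or 1 gets
  # 0.5 pseudo-counts on every replicate
  adjusted <- FALSE
  for (lv in levels(grp)) {
    i <- grp == lv
    if (sum(M[i]) == 0 || sum(M[i]) == sum(C[i])) {
      M[i] <- M[i] + 0.5
      C[i] <- C[i] + 1
      adjusted <- TRUE
    }
  }
  fit <- suppressWarnings(
    stats::glm(cbind(M, C - M) ~ grp, family = stats::binomial())
  )
  df <- length(M) - 2
  pearson <- sum(stats::residuals(fit, type = "pearson")^2)
  scale <- if (df > 0) pearson / df else 1
  # pseudo-counts shrink residuals toward zero; do not let the near-zero
  # scale of an adjusted fit inflate the statistic
  scale <- if (adjusted) max(scale, 1) else max(scale, 1e-8)
  sm <- summary(fit)$coefficients
  if (nrow(sm) < 2 || is.na(sm[2, 2])) return(list(delta = delta, p = 1, scale = scale))
  stat <- (sm[2, 1] / sm[2, 2])^2 / scale
  p <- if (delta == 0) 1 else stats::pchisq(stat, 1, lower.tail = FALSE)
  list(delta = delta, p = p, scale = scale)
}

#' Logistic-regression test at a single position
#'
#' Binomial regression of the methylated proportion on group membership with
#' a quasi-likelihood dispersion scale (sum of squared Pearson residuals over
#' residual degrees of freedom); the squared group coefficient z, divided by
#' the scale, is referred to chi-square(1). Complete separation (a group all
#' 0 or all 1) is handled by adding 0.5 pseudo-counts to each replicate of
#' the offending group.
#'
#' @inheritParams test_position
#' @return list with `delta`, `p`, `scale`.
#' @export
test_position_logistic <- function(treatment, control) {
  t <- as.data.frame(treatment)
  c <- as.data.frame(control)
  stop_if_not(sum(t$C) > 0 && sum(c$C) > 0, "zero total coverage in a group")
  logistic_one(t$M, t$C, c$M, c$C)
}

#' Benjamini-Hochberg adjustment
#'
#' @param p vector of p-values in [0, 1].
#' @return BH step-up adjusted q-values (order-preserving).
#' @export
adjust_fdr <- function(p) {
  stop_if_not(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

test_united <- function(united, treatment, control, backend, min_per_group,
                        phi = NULL) {
  gt <- group_mats(united, treatment)
  gc <- group_mats(united, control)
  ok <- rowSums(!is.na(gt$C) & gt$C > 0) >= min_per_group &
        rowSums(!is.na(gc$C) & gc$C > 0) >= min_per_group
  res <- data.frame(delta = NA_real_, p = NA_real_, phi = NA_real_,
                    row.names = NULL)[rep(1, nrow(united$M)), , drop = FALSE]
  if (!any(ok)) return(cbind(united$index, res, ok = ok))
  if (backend == "wald") {
    if (is.null(phi)) {
      disp <- estimate_dispersion(united, treatment, control)
      phi <- disp$phi
    }
    phi <- rep_len(phi, nrow(united$M))
    r <- wald_core(gt$M[ok, , drop = FALSE], gt$C[ok, , drop = FALSE],
                   gc$M[ok, , drop = FALSE], gc$C[ok, , drop = FALSE],
                   phi[ok])
    res$delta[ok] <- r$delta
    res$p[ok] <- r$p
    res$phi[ok] <- phi[ok]
  } else {
    idx <- which(ok)
    for (i in idx) {
      r <- logistic_one(gt$M[i, ], gt$C[i, ], gc$M[i, ], gc$C[i, ])
      res$delta[i] <- r$delta
      res$p[i] <- r$p
    }
  }
  cbind(united$index, res, ok = ok)
}

#' Call differentially methylated positions
#'
#' Tests every united position with at least `min_per_group` covered samples
#' per group, adjusts p-values per sequence context (BH), and flags positions
#' with `q < alpha`. `delta` is treatment minus control; positions with
#' `delta > 0` are `hyper`, `delta < 0` `hypo`.
#'
#' @param united a `united_table`.
#' @param treatment,control group labels in the united design.
#' @param alpha FDR threshold (default 0.05).
#' @param backend `"wald"` (beta-binomial with dispersion shrinkage, default)
#'   or `"logistic"`.
#' @param context optional context filter before testing.
#' @param min_per_group minimum covered replicates per group (default 2).
#' @return a `dmp_result` data frame (chrom, pos, strand, context, delta, p,
#'   q, direction, significant) with the call parameters as attributes.
#' @export
call_dmps <- function(united, treatment = NULL, control = NULL, alpha = 0.05,
                      backend = c("wald", "logistic"), context = NULL,
                      min_per_group = 2) {
  backend <- match.arg(backend)
  gl <- unique(united$design$group)
  treatment <- treatment %||% gl[1]
  control <- control %||% gl[2]
  u <- united
  if (!is.null(context)) {
    keep <- united$index$context %in% context
    u <- united_table(united$index[keep, , drop = FALSE],
                      united$M[keep, , drop = FALSE],
                      united$C[keep, , drop = FALSE], united$design$group)
    u$design <- united$design
  }
  res <- test_united(u, treatment, control, backend, min_per_group)
  res <- res[res$ok & !is.na(res$p), , drop = FALSE]
  res$q <- NA_real_
  for (cx in unique(res$context)) {
    i <- res$context == cx
    res$q[i] <- adjust_fdr(res$p[i])
  }
  res$direction <- ifelse(res$delta > 0, "hyper",
                          ifelse(res$delta < 0, "hypo", "none"))
  res$significant <- res$q < alpha & res$direction != "none"
  res$ok <- NULL
  rownames(res) <- NULL
  structure(res, class = c("dmp_result", "data.frame"),
            backend = backend, alpha = alpha,
            treatment = treatment, control = control)
}

#' @export
print.dmp_result <- function(x, ...) {
  sig <- x[x$significant, , drop = FALSE]
  cat(sprintf("DMP call (%s backend, %s vs %s): %d positions tested, %d DMPs at q < %g\n",
              attr(x, "backend"), attr(x, "treatment"), attr(x, "control"),
              nrow(x), nrow(sig), attr(x, "alpha")))
  if (nrow(sig) > 0) {
    tab <- table(sig$context, sig$direction)
    print(tab)
  }
  invisible(x)
}

#' @method summary dmp_result
#' @export
summary.dmp_result <- function(object, ...) {
  sig <- object[object$significant, , drop = FALSE]
  cxs <- sort(unique(object$context))
  data.frame(
    context = cxs,
    n_tested = vapply(cxs, function(cx) sum(object$context == cx), 1L),
    n_dmp = vapply(cxs, function(cx) sum(sig$context == cx), 1L),
    n_hyper = vapply(cxs, function(cx)
      sum(sig$context == cx & sig$direction == "hyper"), 1L),
    n_hypo = vapply(cxs, function(cx)
      sum(sig$context == cx & sig$direction == "hypo"), 1L),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Call differentially methylated regions
#'
#' Positions qualifying at a relaxed per-position cut-off (`p < p_cut` and
#' `|delta| >= delta`) are segmented, separately per chromosome, context and
#' direction: consecutive qualifying positions closer than `max_gap` bp are
#' merged; a region must contain at least `min_sites` qualifying positions,
#' span at least `min_len` bp, have at least `min_frac_qual` of its member
#' (tested) positions qualifying, and a mean methylation difference over all
#' member positions of at least `min_diff` in absolute value.
#'
#' @inheritParams call_dmps
#' @param p_cut relaxed per-position p-value cut-off (default 0.01).
#' @param delta per-position minimum |difference| (default 0.1).
#' @param min_diff minimum |mean difference| over the region (default 0.10).
#' @param min_sites,min_len,max_gap,min_frac_qual segmentation parameters.
#' @return a `dmr_result` data frame (chrom, start, end, n_positions,
#'   n_significant, mean_delta, direction).
#' @export
call_dmrs <- function(united, treatment = NULL, control = NULL,
                      p_cut = 0.01, delta = 0.1, min_diff = 0.10,
                      backend = c("wald", "logistic"), context = "CG",
                      min_per_group = 2, min_sites = 3, min_len = 50,
                      max_gap = 100, min_frac_qual = 0.5) {
  backend <- match.arg(backend)
  gl <- unique(united$design$group)
  treatment <- treatment %||% gl[1]
  control <- control %||% gl[2]
  res <- test_united(united, treatment, control, backend, min_per_group)
  res <- res[res$ok & !is.na(res$p), , drop = FALSE]
  if (!is.null(context)) res <- res[res$context %in% context, , drop = FALSE]
  out <- list()
  for (cx in unique(res$context)) for (ch in unique(res$chrom)) {
    sub <- res[res$context == cx & res$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    q <- sub$p < p_cut & abs(sub$delta) >= delta
    for (dir in c(1, -1)) {
      qd <- q & sign(sub$delta) == dir
      pos <- sub$pos[qd]
      if (length(pos) < min_sites) next
      brk <- cumsum(c(0, diff(pos) >= max_gap))
      for (b in unique(brk)) {
        pb <- pos[brk == b]
        if (length(pb) < min_sites) next
        start <- min(pb); end <- max(pb)
        if (end - start + 1 < min_len) next
        member <- sub$pos >= start & sub$pos <= end
        frac_q <- sum(qd & member) / sum(member)
        if (frac_q < min_frac_qual) next
        md <- mean(sub$delta[member])
        if (abs(md) < min_diff) next
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = start, end = end,
          n_positions = sum(member), n_significant = sum(qd & member),
          mean_delta = md,
          direction = if (md > 0) "hyper" else "hypo",
          context = cx, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               n_positions = integer(0), n_significant = integer(0),
               mean_delta = numeric(0), direction = character(0),
               context = character(0), stringsAsFactors = FALSE)
  structure(out, class = c("dmr_result", "data.frame"),
            treatment = treatment, control = control, backend = backend)
}

#' Export DMPs as BED (0-based half-open), score = -log10(q)
#'
#' @param dmps a `dmp_result` (significant positions are exported).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
export_dmp_bed <- function(dmps, path) {
  sig <- dmps[dmps$significant, , drop = FALSE]
  score <- -log10(pmax(sig$q, 1e-300))
  writeLines(sprintf("%s\t%d\t%d\t%s\t%.3f\t%s",
                     sig$chrom, sig$pos - 1L, sig$pos, sig$direction, score,
                     ifelse(sig$strand == "-", "-", "+")),
             path)
  invisible(path)
}
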
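# Direction-aware shared-DMP set algebra, dose-intensity comparison,
# DMP-removal re-clustering attribution, lability overlap, and
# cross-experiment overlap.

#' Construct a DMP set
#'
#' A DMP set is the significant outcome of one comparison: positions with a
#' direction (hyper/hypo) and an effect size in percentage points.
#'
#' @param df data frame with columns chrom, pos, direction and optionally
#'   delta (fraction or percentage points; fractions are converted to
#'   percentage points).
#' @param comparison label, e.g. "SMM-vs-MMM".
#' @param delta_unit `"pp"` (percentage points) or `"fraction"`.
#' @return a `dmp_set`.
#' @export
dmp_set <- function(df, comparison = "comparison", delta_unit = c("pp", "fraction")) {
  delta_unit <- match.arg(delta_unit)
  stop_if_not(all(c("chrom", "pos", "direction") %in% names(df)),
              "dmp_set needs chrom, pos, direction")
  stop_if_not(all(df$direction %in% c("hyper", "hypo")),
              "direction must be hyper or hypo")
  if (is.null(df$delta)) df$delta <- NA_real_
  if (delta_unit == "fraction") df$delta <- 100 * df$delta
  df <- df[, c("chrom", "pos", "direction", "delta")]
  key <- pos_key(df$chrom, df$pos)
  stop_if_not(!anyDuplicated(key), "one direction per position per comparison")
  rownames(df) <- NULL
  structure(df, class = c("dmp_set", "data.frame"), comparison = comparison)
}

#' Extract the significant positions of a DMP call as a set
#'
#' @param dmps a `dmp_result` from [call_dmps()].
#' @param comparison label for the set.
#' @param context optional context filter.
#' @return a `dmp_set` (deltas in percentage points).
#' @export
as_dmp_set <- function(dmps, comparison = NULL, context = NULL) {
  comparison <- comparison %||%
    paste(attr(dmps, "treatment"), "vs", attr(dmps, "control"))
  sig <- dmps[dmps$significant, , drop = FALSE]
  if (!is.null(context)) sig <- sig[sig$context %in% context, , drop = FALSE]
  dmp_set(data.frame(chrom = sig$chrom, pos = sig$pos,
                     direction = sig$direction, delta = sig$delta,
                     stringsAsFactors = FALSE),
          comparison, delta_unit = "fraction")
}

#' @export
print.dmp_set <- function(x, ...) {
  cat(sprintf("DMP set '%s': %d positions (%d hyper, %d hypo)\n",
              attr(x, "comparison"), nrow(x),
              sum(x$direction == "hyper"), sum(x$direction == "hypo")))
  invisible(x)
}

#' Direction-aware intersection of two DMP sets
#'
#' A position is shared iff it is significant in both comparisons with the
#' same direction. Positions significant in both but with opposite directions
#' are treated as non-overlapping and counted in both only-sections, so
#' `section_sum = |a_only| + |b_only|` double-counts them and
#' `unique_union = section_sum - n_opposite` is the number of distinct
#' non-shared positions.
#'
#' @param a,b `dmp_set`s sharing a common control.
#' @return an object of class `shared_summary` with members (`shared`,
#'   `a_only`, `b_only`, `opposite`) and a `counts` list including
#'   per-direction shared totals and percentages (percent of the
#'   per-direction union, rounded half-up to one decimal).
#' @export
intersect_dmps <- function(a, b) {
  ka <- pos_key(a$chrom, a$pos)
  kb <- pos_key(b$chrom, b$pos)
  hit <- match(ka, kb)
  in_both <- !is.na(hit)
  same_dir <- in_both & a$direction == b$direction[hit]
  opp <- in_both & !same_dir
  shared <- a[same_dir, , drop = FALSE]
  a_only <- a[!same_dir, , drop = FALSE]          # includes opposite-direction
  b_only <- b[!kb %in% ka[same_dir], , drop = FALSE]
  opposite <- a[opp, , drop = FALSE]
  per_dir <- function(dir) {
    union_n <- length(unique(c(ka[a$direction == dir], kb[b$direction == dir])))
    shared_n <- sum(shared$direction == dir)
    list(union = union_n, shared = shared_n,
         pct = if (union_n > 0) round_half_up(100 * shared_n / union_n, 1) else NA_real_)
  }
  hyper <- per_dir("hyper")
  hypo <- per_dir("hypo")
  section_sum <- nrow(a_only) + nrow(b_only)
  counts <- list(
    n_shared = nrow(shared), n_a_only = nrow(a_only), n_b_only = nrow(b_only),
    n_opposite = nrow(opposite),
    section_sum = section_sum,
    unique_union = section_sum - nrow(opposite),
    opposite_pct = if (nrow(shared) + section_sum > 0)
      round_half_up(100 * nrow(opposite) /
                      (nrow(shared) + section_sum - nrow(opposite)), 1)
    else NA_real_,
    hyper = hyper, hypo = hypo
  )
  structure(list(shared = shared, a_only = a_only, b_only = b_only,
                 opposite = opposite, counts = counts,
                 comparisons = c(attr(a, "comparison"), attr(b, "comparison"))),
            class = "shared_summary")
}

#' @export
print.shared_summary <- function(x, ...) {
  c <- x$counts
  cat(sprintf("Shared-DMP summary: %s vs %s\n",
              x$comparisons[1], x$comparisons[2]))
  cat(sprintf("  shared (same direction): %d  [hyper %d/%d = %.1f%%; hypo %d/%d = %.1f%%]\n",
              c$n_shared, c$hyper$shared, c$hyper$union, c$hyper$pct,
              c$hypo$shared, c$hypo$union, c$hypo$pct))
  cat(sprintf("  only-sections: %d + %d (sum %d; %d opposite-direction counted in both; %d unique)\n",
              c$n_a_only, c$n_b_only, c$section_sum, c$n_opposite,
              c$unique_union))
  invisible(x)
}

#' Export three-way shared/unshared accounting as JSON
#'
#' @param shared a `shared_summary`.
#' @param path optional output file.
#' @return the JSON string (invisibly when written to file).
#' @export
venn_json <- function(shared, path = NULL) {
  c <- shared$counts
  js <- jsonlite::toJSON(list(
    comparisons = shared$comparisons,
    shared = c$n_shared, a_only = c$n_a_only, b_only = c$n_b_only,
    opposite_counted_in_both = c$n_opposite,
    section_sum = c$section_sum, unique_union = c$unique_union
  ), auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Dose-intensity comparison of shared DMPs
#'
#' For each shared position, "more pronounced in the high-dose comparison"
#' means the signed effect difference exceeds `threshold` percentage points
#' in the direction of the DMP: hyper DMPs require
#' `delta_high - delta_low >= threshold`, hypo DMPs
#' `(-delta_high) - (-delta_low) >= threshold`; "more pronounced in the
#' low-dose comparison" is the mirror image.
#'
#' @param shared a `shared_summary` (deltas of set `a` = low dose, `b` = high
#'   dose) or a data frame with columns direction, delta_low, delta_high (pp).
#' @param threshold percentage-point threshold (default 20).
#' @return a `dose_intensity` object: counts by direction and the paired
#'   (delta_low, delta_high) table.
#' @export
dose_intensity <- function(shared, threshold = 20) {
  if (inherits(shared, "shared_summary")) {
    a <- shared$shared
    stop_if_not(!is.null(a$delta_b),
                "call add_partner_deltas() before dose_intensity() on a shared_summary")
    paired <- data.frame(chrom = a$chrom, pos = a$pos, direction = a$direction,
                         delta_low = a$delta, delta_high = a$delta_b,
                         stringsAsFactors = FALSE)
  } else {
    paired <- as.data.frame(shared)
  }
  stop_if_not(all(c("direction", "delta_low", "delta_high") %in% names(paired)),
              "need direction, delta_low, delta_high")
  missing <- is.na(paired$delta_low) | is.na(paired$delta_high)
  excl <- sum(missing)
  paired <- paired[!missing, , drop = FALSE]
  s <- ifelse(paired$direction == "hyper", 1, -1)
  diff <- s * (paired$delta_high - paired$delta_low)
  paired$pronounced <- ifelse(diff >= threshold, "high",
                              ifelse(-diff >= threshold, "low", "neither"))
  cnt <- function(dir, side) sum(paired$direction == dir & paired$pronounced == side)
  counts <- list(hyper_high = cnt("hyper", "high"), hyper_low = cnt("hyper", "low"),
                 hypo_high = cnt("hypo", "high"), hypo_low = cnt("hypo", "low"),
                 neither = sum(paired$pronounced == "neither"),
                 excluded_missing = excl)
  structure(list(counts = counts, paired = paired, threshold = threshold),
            class = "dose_intensity")
}

#' @export
print.dose_intensity <- function(x, ...) {
  c <- x$counts
  cat(sprintf("Dose intensity (threshold %g pp):\n", x$threshold))
  cat(sprintf("  more pronounced in high dose: %d hyper, %d hypo\n",
              c$hyper_high, c$hypo_high))
  cat(sprintf("  more pronounced in low dose:  %d hyper, %d hypo\n",
              c$hyper_low, c$hypo_low))
  cat(sprintf("  neither: %d; excluded (missing delta): %d\n",
              c$neither, c$excluded_missing))
  invisible(x)
}

#' Attach the partner comparison's deltas to a shared summary
#'
#' After [intersect_dmps()], the shared members carry set `a`'s deltas; this
#' looks up set `b`'s delta for each shared position (column `delta_b`).
#'
#' @param shared a `shared_summary`.
#' @param b the `dmp_set` that was the second argument of the intersection.
#' @return the `shared_summary` with `shared$delta_b` filled.
#' @export
add_partner_deltas <- function(shared, b) {
  kb <- pos_key(b$chrom, b$pos)
  hit <- match(pos_key(shared$shared$chrom, shared$shared$pos), kb)
  shared$shared$delta_b <- b$delta[hit]
  shared
}

#' Bookkeeping of a position-set removal from a united index
#'
#' Counts how many removal-set positions are present in the table (removable)
#' and how many are absent (e.g. positions united in one experiment but not
#' covered in the other), and the table sizes before and after removal.
#'
#' With `match = "cg_pair"` each removal position is treated as the
#' plus-strand coordinate of a symmetric CG and covers `pos` and `pos + 1`,
#' so residual unpaired strand-partner records in the table are removed along
#' with the destranded coordinate; table entries removed can then exceed the
#' size of the removal set.
#'
#' @param positions data frame with chrom, pos: the table's position index.
#' @param remove data frame with chrom, pos: positions to remove.
#' @param match `"position"` (exact coordinate, default) or `"cg_pair"`.
#' @return list with `n_before`, `n_removed` (table entries removed),
#'   `n_absent` (removal positions matching nothing), `n_after`, and `keep`
#'   (logical over the unique table positions).
#' @export
removal_accounting <- function(positions, remove, match = c("position", "cg_pair")) {
  match <- match.arg(match)
  pk <- unique(pos_key(positions$chrom, positions$pos))
  rem <- unique(data.frame(chrom = remove$chrom, pos = remove$pos))
  rk <- pos_key(rem$chrom, rem$pos)
  if (match == "cg_pair") {
    rk1 <- pos_key(rem$chrom, rem$pos + 1L)
    drop <- pk %in% c(rk, rk1)
    absent <- !(rk %in% pk | rk1 %in% pk)
  } else {
    drop <- pk %in% rk
    absent <- !(rk %in% pk)
  }
  list(n_before = length(pk), n_removed = sum(drop),
       n_absent = sum(absent), n_after = length(pk) - sum(drop),
       keep = !drop)
}

#' Re-cluster after removing a position set
#'
#' Clusters the full percent-methylation matrix and the matrix with `remove`
#' positions deleted, using the same seed stream, and reports whether the
#' treatment samples form an exclusive clade in each tree and with what AU
#' support. Attributes the clustering signal to the removed set (the in
#' silico removal experiment).
#'
#' @param united a `united_table` (or a percent matrix with `chrom:pos`
#'   rownames).
#' @param remove data frame with chrom, pos of positions to remove;
#'   non-members of the table are ignored but counted.
#' @param treatment_samples sample ids whose exclusive grouping is assessed.
#' @param context optional context filter (united tables only).
#' @param low_variation_filter apply [filter_low_variation()] before
#'   clustering (default TRUE).
#' @param nboot,scales,seed bootstrap settings, see [multiscale_bootstrap()].
#' @return a `removal_reclustering` object: trees and verdicts before/after,
#'   plus removal bookkeeping (`n_removed`, `n_absent`, `n_before`,
#'   `n_after`).
#' @export
removal_reclustering <- function(united, remove, treatment_samples,
                                 context = "CG", low_variation_filter = TRUE,
                                 nboot = 1000, scales = seq(0.5, 1.4, by = 0.1),
                                 seed = 1) {
  x <- if (inherits(united, "united_table")) percent_matrix(united, context)
       else united
  parts <- do.call(rbind, strsplit(rownames(x), ":", fixed = TRUE))
  acc <- removal_accounting(
    data.frame(chrom = parts[, 1], pos = parts[, 2]), remove)
  keep <- acc$keep
  acc$keep <- NULL
  stop_if_not(sum(keep) >= 2, "removal would leave fewer than 2 positions")
  run <- function(mat) {
    if (low_variation_filter) mat <- filter_low_variation(mat)
    multiscale_bootstrap(mat, nboot = nboot, scales = scales, seed = seed)
  }
  before <- run(x)
  after <- run(x[keep, , drop = FALSE])
  structure(c(list(
    before = before, after = after,
    verdict_before = clade_support(before, treatment_samples),
    verdict_after = clade_support(after, treatment_samples)), acc),
    class = "removal_reclustering")
}

#' @export
print.removal_reclustering <- function(x, ...) {
  fmt <- function(v) if (v$is_clade)
    sprintf("exclusive clade (AU %.1f)", v$au) else "no exclusive clade"
  cat(sprintf("Removal re-clustering: %d -> %d positions (%d removed, %d absent from table)\n",
              x$n_before, x$n_after, x$n_removed, x$n_absent))
  cat(sprintf("  treatment grouping before: %s\n", fmt(x$verdict_before)))
  cat(sprintf("  treatment grouping after:  %s\n", fmt(x$verdict_after)))
  invisible(x)
}

#' Overlap of a DMP set with a labile/stable position catalogue
#'
#' Cross-tabulates the set and a comparator set against position classes
#' (labile / stable / unclassified) and tests, on the 2x2 labile-vs-stable
#' by set-vs-comparator table, whether the set is shifted toward labile
#' positions (two-sided Fisher's exact test).
#'
#' @param dmps a `dmp_set` (e.g. TAR-related DMPs).
#' @param classes data frame with chrom, pos, class (`"labile"`/`"stable"`;
#'   anything else, or absence, counts as unclassified).
#' @param comparator a `dmp_set` used as background (e.g. spontaneous DMPs).
#' @return a `lability_overlap` object: the full cross-tabulation, the 2x2
#'   table, odds ratio and p-value.
#' @export
lability_overlap <- function(dmps, classes, comparator) {
  stop_if_not(nrow(comparator) > 0, "empty comparator set")
  ck <- pos_key(classes$chrom, classes$pos)
  classify <- function(set) {
    cl <- classes$class[match(pos_key(set$chrom, set$pos), ck)]
    cl[is.na(cl) | !cl %in% c("labile", "stable")] <- "unclassified"
    factor(cl, levels = c("labile", "stable", "unclassified"))
  }
  tab <- rbind(set = table(classify(dmps)),
               comparator = table(classify(comparator)))
  t22 <- tab[, c("labile", "stable")]
  ft <- stats::fisher.test(t22, alternative = "two.sided")
  structure(list(table = tab, table2x2 = t22,
                 odds_ratio = unname(ft$estimate), p = ft$p.value),
            class = "lability_overlap")
}

#' @export
print.lability_overlap <- function(x, ...) {
  cat("Lability overlap (rows: set, comparator):\n")
  print(x$table)
  cat(sprintf("  labile-vs-stable shift: OR = %.3g, Fisher p = %.3g\n",
              x$odds_ratio, x$p))
  invisible(x)
}

#' Same-direction overlap between two experiments' DMP sets
#'
#' @param a,b `dmp_set`s on the same genome build.
#' @return list with `n_overlap` (same chrom, pos and direction) and
#'   `pct_a`, `pct_b` (percent of each set, rounded half-up to one decimal).
#' @export
cross_experiment_overlap <- function(a, b) {
  ka <- paste(pos_key(a$chrom, a$pos), a$direction)
  kb <- paste(pos_key(b$chrom, b$pos), b$direction)
  n <- sum(ka %in% kb)
  list(n_overlap = n,
       n_a = nrow(a), n_b = nrow(b),
       pct_a = if (nrow(a) > 0) round_half_up(100 * n / nrow(a), 1) else NA_real_,
       pct_b = if (nrow(b) > 0) round_half_up(100 * n / nrow(b), 1) else NA_real_)
}
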
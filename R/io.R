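# Bismark-style cytosine count tables: reading, filtering, normalisation,
# CG destranding, uniting into position x sample matrices, conversion-rate
# estimation. Coordinates are 1-based, both endpoints inclusive, throughout.

#' Construct a cytosine count table
#'
#' Thin validated wrapper around a data frame with columns chrom, pos, strand,
#' M (methylated count), U (unmethylated count), context. Coverage is
#' `C = M + U`.
#'
#' @param df data frame with the six columns above.
#' @param sample_id,line_id,group sample labels kept as attributes.
#' @param control optional conversion-control (chloroplast) table.
#' @return a `cytosine_table`.
#' @export
cytosine_table <- function(df, sample_id = "sample", line_id = NA, group = NA,
                           control = NULL) {
  need <- c("chrom", "pos", "strand", "M", "U", "context")
  stop_if_not(all(need %in% names(df)),
              paste("cytosine table needs columns:", paste(need, collapse = ", ")))
  stop_if_not(all(df$M >= 0) && all(df$U >= 0), "counts must be non-negative")
  stop_if_not(all(df$strand %in% c("+", "-")), "strand must be '+' or '-'")
  stop_if_not(all(df$context %in% c("CG", "CHG", "CHH")),
              "context must be CG, CHG or CHH")
  key <- paste(df$chrom, df$pos, df$strand)
  stop_if_not(!anyDuplicated(key), "duplicate (chrom, pos, strand) records")
  structure(df[, need], class = c("cytosine_table", "data.frame"),
            sample_id = sample_id, line_id = line_id, group = group,
            control = control)
}

coverage_of <- function(tab) tab$M + tab$U

#' @export
print.cytosine_table <- function(x, ...) {
  ctrl <- attr(x, "control")
  cat(sprintf("Cytosine table '%s': %d records (%s)%s\n",
              attr(x, "sample_id"), nrow(x),
              paste(names(table(x$context)), table(x$context),
                    sep = "=", collapse = ", "),
              if (!is.null(ctrl)) sprintf("; %d conversion-control records",
                                          nrow(ctrl)) else ""))
  invisible(x)
}

#' Read a Bismark-dialect cytosine report
#'
#' Tab-separated columns: chrom, 1-based position, strand (+/-), methylated
#' count, unmethylated count, context (CG/CHG/CHH), optional trinucleotide.
#' Records below `mincov` coverage are dropped. Records on the
#' conversion-control contig (chloroplast) are split off into the table's
#' `control` attribute; `mincov` is not applied to them.
#'
#' @param path file path.
#' @param mincov minimum coverage to retain a nuclear record (default 3).
#' @param control_chrom name of the conversion-control contig (default "ChrC").
#' @param sample_id,line_id,group sample labels (default: file base name).
#' @return a `cytosine_table`.
#' @export
read_cytosine_report <- function(path, mincov = 3, control_chrom = "ChrC",
                                 sample_id = NULL, line_id = NA, group = NA) {
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    empty <- data.frame(chrom = character(0), pos = integer(0),
                        strand = character(0), M = integer(0), U = integer(0),
                        context = character(0), stringsAsFactors = FALSE)
    return(cytosine_table(empty, sample_id, line_id, group, control = empty))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 6)
  if (length(bad) > 0)
    stop(sprintf("malformed cytosine report line %d in %s (%d fields)",
                 bad[1], path, nf[bad[1]]), call. = FALSE)
  m <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  M <- suppressWarnings(as.integer(m[, 4]))
  U <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(pos) | is.na(M) | is.na(U))
  if (length(bad) > 0)
    stop(sprintf("malformed cytosine report line %d in %s (non-numeric field)",
                 bad[1], path), call. = FALSE)
  bad <- which(!m[, 6] %in% c("CG", "CHG", "CHH"))
  if (length(bad) > 0)
    stop(sprintf("unknown context '%s' at line %d in %s",
                 m[bad[1], 6], bad[1], path), call. = FALSE)
  df <- data.frame(chrom = m[, 1], pos = pos, strand = m[, 3],
                   M = M, U = U, context = m[, 6], stringsAsFactors = FALSE)
  is_ctrl <- df$chrom == control_chrom
  control <- df[is_ctrl, , drop = FALSE]
  df <- df[!is_ctrl, , drop = FALSE]
  df <- df[df$M + df$U >= mincov, , drop = FALSE]
  rownames(df) <- rownames(control) <- NULL
  cytosine_table(df, sample_id, line_id, group, control = control)
}

#' Write a cytosine count table in Bismark-report dialect
#'
#' Nuclear records and any conversion-control records (attribute `control`)
#' are written together; the trinucleotide column is emitted as "NNN".
#'
#' @param tab a `cytosine_table`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_cytosine_report <- function(tab, path) {
  df <- rbind(as.data.frame(tab)[, 1:6],
              if (!is.null(attr(tab, "control")))
                as.data.frame(attr(tab, "control"))[, 1:6])
  out <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\tNNN",
                 df$chrom, df$pos, df$strand, df$M, df$U, df$context)
  writeLines(out, path)
  invisible(path)
}

#' Remove extreme-coverage records
#'
#' Drops records whose coverage is strictly above the sample's `hi_perc`
#' coverage percentile (PCR-duplication artefacts). The percentile uses linear
#' interpolation between order statistics (`stats::quantile` type 7).
#'
#' @param tab a `cytosine_table`.
#' @param hi_perc upper percentile in (0, 100] (default 99.9).
#' @return the filtered `cytosine_table`.
#' @export
filter_by_coverage <- function(tab, hi_perc = 99.9) {
  stop_if_not(hi_perc > 0 && hi_perc <= 100, "hi_perc must lie in (0, 100]")
  stop_if_not(nrow(tab) > 0, "empty table")
  cutoff <- stats::quantile(coverage_of(tab), hi_perc / 100, names = FALSE)
  keep <- coverage_of(tab) <= cutoff
  out <- as.data.frame(tab)[keep, , drop = FALSE]
  rownames(out) <- NULL
  cytosine_table(out, attr(tab, "sample_id"), attr(tab, "line_id"),
                 attr(tab, "group"), attr(tab, "control"))
}

#' Equalise median coverage across samples
#'
#' Each sample's methylated and unmethylated counts are scaled by
#' `f_s = median(sample medians) / m_s`, where `m_s` is the sample's median
#' coverage, and rounded half-up separately; records whose coverage would
#' vanish keep a coverage of at least 1 on the majority call.
#'
#' @param tables list of `cytosine_table`s.
#' @return list of normalised `cytosine_table`s.
#' @export
normalize_coverage <- function(tables) {
  if (inherits(tables, "cytosine_table")) tables <- list(tables)
  med <- vapply(tables, function(t) stats::median(coverage_of(t)), 1)
  stop_if_not(all(med > 0), "sample with zero median coverage")
  ref <- stats::median(med)
  lapply(tables, function(t) {
    f <- ref / stats::median(coverage_of(t))
    df <- as.data.frame(t)
    M <- round_half_up(df$M * f)
    U <- round_half_up(df$U * f)
    zero <- M + U == 0
    if (any(zero)) {
      # keep the record alive at minimal coverage, preserving the call
      M[zero] <- as.integer(df$M[zero] >= df$U[zero])
      U[zero] <- 1L - M[zero]
    }
    df$M <- as.integer(M)
    df$U <- as.integer(U)
    cytosine_table(df, attr(t, "sample_id"), attr(t, "line_id"),
                   attr(t, "group"), attr(t, "control"))
  })
}

#' Merge symmetric CG strand pairs
#'
#' Counts of a plus-strand CG at position i and its minus-strand partner at
#' i + 1 are summed and reported at the plus-strand coordinate with strand
#' "+". Unpaired records are kept unchanged at their own coordinate. Non-CG
#' records pass through untouched.
#'
#' @param tab a `cytosine_table`.
#' @return the destranded `cytosine_table`.
#' @export
destrand_cg <- function(tab) {
  df <- as.data.frame(tab)
  cg <- df[df$context == "CG", , drop = FALSE]
  rest <- df[df$context != "CG", , drop = FALSE]
  if (nrow(cg) > 0) {
    plus <- cg[cg$strand == "+", , drop = FALSE]
    minus <- cg[cg$strand == "-", , drop = FALSE]
    mk <- paste(minus$chrom, minus$pos)
    pk <- paste(plus$chrom, plus$pos + 1L)
    hit <- match(pk, mk)
    paired <- !is.na(hit)
    plus$M[paired] <- plus$M[paired] + minus$M[hit[paired]]
    plus$U[paired] <- plus$U[paired] + minus$U[hit[paired]]
    lone_minus <- minus[!seq_len(nrow(minus)) %in% hit[paired], , drop = FALSE]
    cg <- rbind(plus, lone_minus)
  }
  out <- rbind(cg, rest)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  cytosine_table(out, attr(tab, "sample_id"), attr(tab, "line_id"),
                 attr(tab, "group"), attr(tab, "control"))
}

#' Unite sample tables into a position x sample count matrix
#'
#' Positions are retained iff they are covered in at least `min_per_group`
#' samples of every group; entries missing in a retained position stay
#' missing (NA), never zero.
#'
#' @param tables list of `cytosine_table`s (same processing state; destrand CG
#'   first if desired).
#' @param groups character vector assigning each table to a group; defaults to
#'   each table's `group` attribute.
#' @param min_per_group minimum covered samples per group (default 2).
#' @param context optional context filter (e.g. "CG") applied before uniting.
#' @return a `united_table`: list with `index` (chrom, pos, strand, context),
#'   count matrices `M` and `C` (positions x samples, NA = not covered), and
#'   `design` (sample, group).
#' @export
unite_samples <- function(tables, groups = NULL, min_per_group = 2,
                          context = NULL) {
  sample_ids <- vapply(tables, function(t) attr(t, "sample_id"), "")
  groups <- groups %||% vapply(tables, function(t) as.character(attr(t, "group")), "")
  stop_if_not(!anyNA(groups) && all(nzchar(groups)),
              "every sample needs a group label")
  stop_if_not(length(unique(groups)) >= 2, "need at least two groups")
  cnt <- table(groups)
  if (any(cnt < min_per_group))
    stop(sprintf("group '%s' has fewer than min_per_group = %d samples",
                 names(cnt)[which(cnt < min_per_group)[1]], min_per_group),
         call. = FALSE)
  dfs <- lapply(tables, as.data.frame)
  if (!is.null(context))
    dfs <- lapply(dfs, function(d) d[d$context %in% context, , drop = FALSE])
  keys <- lapply(dfs, function(d) paste(d$chrom, d$pos, d$strand, d$context))
  all_keys <- unique(unlist(keys))
  n <- length(all_keys)
  M <- C <- matrix(NA_real_, n, length(tables),
                   dimnames = list(NULL, sample_ids))
  for (j in seq_along(dfs)) {
    i <- match(keys[[j]], all_keys)
    M[i, j] <- dfs[[j]]$M
    C[i, j] <- dfs[[j]]$M + dfs[[j]]$U
  }
  covered <- !is.na(C)
  keep <- rep(TRUE, n)
  for (g in unique(groups))
    keep <- keep & rowSums(covered[, groups == g, drop = FALSE]) >= min_per_group
  parts <- do.call(rbind, strsplit(all_keys, " ", fixed = TRUE))
  index <- data.frame(chrom = parts[, 1], pos = as.integer(parts[, 2]),
                      strand = parts[, 3], context = parts[, 4],
                      stringsAsFactors = FALSE)
  ord <- order(index$chrom[keep], index$pos[keep])
  idx <- which(keep)[ord]
  structure(list(index = index[idx, , drop = FALSE],
                 M = M[idx, , drop = FALSE], C = C[idx, , drop = FALSE],
                 design = data.frame(sample = sample_ids, group = groups,
                                     stringsAsFactors = FALSE)),
            class = "united_table")
}

#' Construct a united table directly from matrices
#'
#' Escape hatch for simulations and tests that build the position x sample
#' counts without going through per-sample files.
#'
#' @param index data frame with chrom, pos and optionally strand, context.
#' @param M,C numeric matrices (positions x samples) of methylated counts and
#'   coverages; NA marks a position not covered in a sample.
#' @param groups character vector of group labels per sample column.
#' @return a `united_table`.
#' @export
united_table <- function(index, M, C, groups) {
  stop_if_not(nrow(M) == nrow(index) && all(dim(M) == dim(C)),
              "dimension mismatch")
  stop_if_not(length(groups) == ncol(M), "one group label per sample")
  if (is.null(index$strand)) index$strand <- "+"
  if (is.null(index$context)) index$context <- "CG"
  if (is.null(colnames(M)))
    colnames(M) <- colnames(C) <- sprintf("s%d", seq_len(ncol(M)))
  structure(list(index = index, M = M, C = C,
                 design = data.frame(sample = colnames(M), group = groups,
                                     stringsAsFactors = FALSE)),
            class = "united_table")
}

#' @export
print.united_table <- function(x, ...) {
  cat(sprintf("United table: %d positions x %d samples (groups: %s)\n",
              nrow(x$M), ncol(x$M),
              paste(names(table(x$design$group)), table(x$design$group),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Estimate the bisulfite conversion rate from control cytosines
#'
#' The chloroplast genome is unmethylated, so every methylated call there is a
#' conversion failure: `rate = sum(U) / sum(M + U)`.
#'
#' @param control a data frame (or `cytosine_table`) of conversion-control
#'   records, e.g. the `control` attribute set by [read_cytosine_report()].
#' @return conversion rate in [0, 1].
#' @export
estimate_conversion <- function(control) {
  stop_if_not(!is.null(control) && nrow(control) > 0,
              "empty conversion-control table")
  tot <- sum(control$M) + sum(control$U)
  stop_if_not(tot > 0, "conversion-control table has zero total coverage")
  sum(control$U) / tot
}

#' Summarise a united table over fixed-width genome windows
#'
#' Non-overlapping 1-based windows [1, w], [w + 1, 2w], ...; per-window,
#' per-sample methylated counts and coverages are sums over member positions
#' (NA-aware: a window entry is NA only if no member position is covered).
#'
#' @param united a `united_table`.
#' @param width window width in bp (default 100).
#' @return a `united_table` whose index has chrom, start, end, n_positions.
#' @export
tile_windows <- function(united, width = 100) {
  stop_if_not(width >= 1, "width must be >= 1")
  win <- (united$index$pos - 1L) %/% as.integer(width)
  key <- paste(united$index$chrom, win)
  uk <- unique(key)
  grp <- match(key, uk)
  sum_na <- function(mat) {
    out <- rowsum(ifelse(is.na(mat), 0, mat), grp)
    n <- rowsum((!is.na(mat)) * 1, grp)
    out[n == 0] <- NA
    out
  }
  M <- sum_na(united$M)
  C <- sum_na(united$C)
  first <- !duplicated(grp)
  index <- data.frame(
    chrom = united$index$chrom[first][order(unique(grp))],
    start = win[first][order(unique(grp))] * as.integer(width) + 1L,
    stringsAsFactors = FALSE
  )
  index$end <- index$start + as.integer(width) - 1L
  index$n_positions <- as.vector(table(grp))
  index$pos <- index$start
  index$strand <- "+"
  index$context <- "window"
  colnames(M) <- colnames(C) <- united$design$sample
  structure(list(index = index, M = M, C = C, design = united$design),
            class = "united_table")
}

#' Percent-methylation matrix of a united table
#'
#' @param united a `united_table`.
#' @param context optional context filter.
#' @return positions x samples matrix of `100 * M / C` (NA where uncovered),
#'   with row names `chrom:pos`.
#' @export
percent_matrix <- function(united, context = NULL) {
  keep <- rep(TRUE, nrow(united$M))
  if (!is.null(context)) keep <- united$index$context %in% context
  x <- 100 * united$M[keep, , drop = FALSE] / united$C[keep, , drop = FALSE]
  rownames(x) <- pos_key(united$index$chrom[keep], united$index$pos[keep])
  x
}

#' Export per-sample methylation as bedGraph
#'
#' Converts the package's 1-based inclusive coordinates to bedGraph's 0-based
#' half-open intervals; the score is percent methylation.
#'
#' @param tab a `cytosine_table`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
export_bedgraph <- function(tab, path) {
  df <- as.data.frame(tab)
  score <- 100 * df$M / (df$M + df$U)
  writeLines(sprintf("%s\t%d\t%d\t%g", df$chrom, df$pos - 1L, df$pos, score),
             path)
  invisible(path)
}
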
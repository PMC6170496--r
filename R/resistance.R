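# Disease-resistance scoring from pathogen colonisation-class tables:
# exact r x c tests, all-versus-all comparisons with FDR adjustment and a
# compact-letter display, plus a multinomial simulator.

#' Fisher's exact test for an r x c contingency table
#'
#' Exact conditional test: the p-value is the total probability, over all
#' tables with the observed margins, of tables whose point probability does
#' not exceed the observed one (standard two-sided convention; computed by
#' the network algorithm). Zero-margin rows and columns are dropped with a
#' warning.
#'
#' @param tab integer matrix of counts (e.g. 2 lines x 4 colonisation
#'   classes).
#' @return the exact p-value.
#' @export
fisher_exact_rxc <- function(tab) {
  tab <- as.matrix(tab)
  stop_if_not(all(tab >= 0) && all(tab == round(tab)),
              "counts must be non-negative integers")
  zr <- rowSums(tab) == 0
  zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    warning("dropping zero-margin rows/columns", call. = FALSE)
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) return(1)
  stats::fisher.test(tab, workspace = 2e7)$p.value
}

# maximal cliques of a small undirected graph (adjacency matrix) by
# brute-force subset search; fine for the handful of lines in an assay
maximal_cliques <- function(adj) {
  n <- nrow(adj)
  if (n == 1) return(list(1L))
  cliques <- list()
  for (code in seq_len(2^n - 1)) {
    members <- which(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
    sub <- adj[members, members, drop = FALSE]
    if (all(sub | diag(TRUE, length(members)))) cliques[[length(cliques) + 1]] <- members
  }
  keep <- vapply(cliques, function(cl)
    !any(vapply(cliques, function(other)
      length(other) > length(cl) && all(cl %in% other), TRUE)), TRUE)
  cliques[keep]
}

#' All-versus-all colonisation-class comparisons
#'
#' Every pair of lines is tested with [fisher_exact_rxc()]; p-values are
#' BH-adjusted across all pairs; lines sharing a letter in the compact-letter
#' display are not significantly different at `alpha`. Letters are the
#' maximal cliques of the non-significance graph, ordered by their first
#' member.
#'
#' @param tab matrix of counts, lines x classes (rownames = line ids).
#' @param alpha significance level on the adjusted p-values (default 0.05).
#' @return an `hpa_assay` object: `pairs` data frame (line_a, line_b, p, q,
#'   significant) and `letters` (named letter strings per line).
#' @export
all_versus_all <- function(tab, alpha = 0.05) {
  tab <- as.matrix(tab)
  stop_if_not(nrow(tab) >= 2, "need at least two lines")
  ids <- rownames(tab) %||% sprintf("line%d", seq_len(nrow(tab)))
  rownames(tab) <- ids
  cmb <- utils::combn(nrow(tab), 2)
  p <- apply(cmb, 2, function(ij)
    fisher_exact_rxc(tab[ij, , drop = FALSE]))
  q <- adjust_fdr(p)
  pairs <- data.frame(line_a = ids[cmb[1, ]], line_b = ids[cmb[2, ]],
                      p = p, q = q, significant = q <= alpha,
                      stringsAsFactors = FALSE)
  adj <- matrix(TRUE, nrow(tab), nrow(tab), dimnames = list(ids, ids))
  for (k in seq_len(ncol(cmb)))
    adj[cmb[1, k], cmb[2, k]] <- adj[cmb[2, k], cmb[1, k]] <- !pairs$significant[k]
  cl <- maximal_cliques(adj)
  cl <- cl[order(vapply(cl, min, 1L))]
  letters_per_line <- vapply(seq_len(nrow(tab)), function(i)
    paste(letters[which(vapply(cl, function(x) i %in% x, TRUE))], collapse = ""),
    "")
  names(letters_per_line) <- ids
  structure(list(pairs = pairs, letters = letters_per_line, alpha = alpha,
                 table = tab),
            class = "hpa_assay")
}

#' @export
print.hpa_assay <- function(x, ...) {
  cat(sprintf("Colonisation-class comparisons (%d lines, %d pairs, alpha = %g)\n",
              nrow(x$table), nrow(x$pairs), x$alpha))
  print(x$pairs, row.names = FALSE)
  cat("Letter groups (shared letter = not significantly different):\n")
  for (i in seq_along(x$letters))
    cat(sprintf("  %s: %s\n", names(x$letters)[i], x$letters[i]))
  invisible(x)
}

#' @method plot hpa_assay
#' @export
plot.hpa_assay <- function(x, main = "Hpa colonisation classes", ...) {
  prop <- prop.table(x$table, 1)
  bp <- graphics::barplot(t(prop), col = grDevices::grey.colors(ncol(prop),
                                                                start = 0.9,
                                                                end = 0.2),
                          main = main, ylab = "proportion of leaves",
                          legend.text = colnames(prop), ...)
  graphics::text(bp, 1.02, x$letters, xpd = NA)
  invisible(x)
}

#' Simulate a colonisation-class table
#'
#' Multinomial draws of leaves over severity classes, per line.
#'
#' @param class_probs matrix lines x classes of class probabilities (rows sum
#'   to 1; rownames = line ids).
#' @param n_leaves leaves scored per line (scalar or per-line vector).
#' @return integer matrix lines x classes. Uses the current RNG state.
#' @export
simulate_colonisation <- function(class_probs, n_leaves) {
  class_probs <- as.matrix(class_probs)
  stop_if_not(all(class_probs >= 0) &&
                all(abs(rowSums(class_probs) - 1) < 1e-8),
              "per-line probability vectors must be non-negative and sum to 1")
  n_leaves <- rep_len(n_leaves, nrow(class_probs))
  out <- t(vapply(seq_len(nrow(class_probs)), function(i) {
    if (n_leaves[i] == 0) rep(0L, ncol(class_probs))
    else as.integer(stats::rmultinom(1, n_leaves[i], class_probs[i, ]))
  }, integer(ncol(class_probs))))
  dimnames(out) <- dimnames(class_probs)
  if (is.null(colnames(out)))
    colnames(out) <- c("I", "II", "III", "IV")[seq_len(ncol(out))]
  out
}
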
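# Feature annotation: map positions onto a flattened priority landscape
# (transposon > gene > intergenic), with gene sub-features where defined.

te_types <- c("transposable_element", "transposable_element_gene", "transposon")
gene_types <- c("gene", "mRNA", "exon", "intron",
                "five_prime_UTR", "three_prime_UTR")
sub_types <- c("five_prime_UTR", "three_prime_UTR", "intron", "exon")

#' Build a feature index from a GFF3 (or BED) annotation
#'
#' Feature classes: any `transposable_element*` record is a transposon; gene
#' and gene-part records (gene, mRNA, exon, intron, UTRs) define genes;
#' everything else is intergenic. At query time a transposon annotation takes
#' priority over a gene annotation, and a gene annotation over intergenic.
#' GFF intervals are 1-based inclusive; BED input (0-based half-open, feature
#' class in the name column) is converted on import.
#'
#' @param path GFF3 or BED file path, or a `GRanges` whose `type` metadata
#'   column holds the feature type.
#' @param promoter_upstream if positive, the strand-aware window of this many
#'   bp upstream of each gene is classed `promoter` (used for
#'   promoter/gene-body splits; default 0 = off; 1000 is the conventional
#'   choice). Promoters rank below transposons and genes in priority.
#' @return an object of class `feature_index`.
#' @export
build_feature_index <- function(path, promoter_upstream = 0) {
  if (inherits(path, "GRanges")) {
    gr <- path
  } else {
    gr <- tryCatch(rtracklayer::import(path),
                   error = function(e) stop(sprintf(
                     "failed to parse annotation '%s': %s", path,
                     conditionMessage(e)), call. = FALSE))
    if (is.null(gr$type) && !is.null(gr$name)) gr$type <- gr$name
  }
  stop_if_not(!is.null(gr$type), "annotation records need a feature type")
  type <- as.character(gr$type)
  te <- gr[type %in% te_types]
  gene <- gr[type %in% gene_types]
  subs <- lapply(sub_types, function(t) gene[as.character(gene$type) == t])
  names(subs) <- sub_types
  promoter <- NULL
  if (promoter_upstream > 0) {
    g <- gene[as.character(gene$type) == "gene"]
    if (length(g) > 0)
      promoter <- suppressWarnings(
        GenomicRanges::trim(GenomicRanges::flank(g, promoter_upstream,
                                                 start = TRUE)))
  }
  structure(list(te = te, gene = gene, subfeatures = subs,
                 promoter = promoter),
            class = "feature_index")
}

#' @export
print.feature_index <- function(x, ...) {
  cat(sprintf("Feature index: %d transposon, %d gene(-part) records\n",
              length(x$te), length(x$gene)))
  invisible(x)
}

classify_positions <- function(positions, index) {
  gr <- GenomicRanges::GRanges(
    positions$chrom,
    IRanges::IRanges(positions$pos, positions$pos))
  ov <- function(a, b) suppressWarnings(IRanges::overlapsAny(a, b))
  cls <- rep("intergenic", length(gr))
  sub <- rep(NA_character_, length(gr))
  in_gene <- ov(gr, index$gene)
  cls[in_gene] <- "gene"
  for (t in rev(sub_types)) {   # exon first, UTRs override (higher priority)
    hit <- ov(gr, index$subfeatures[[t]])
    sub[hit & cls == "gene"] <- t
  }
  if (!is.null(index$promoter)) {
    in_prom <- ov(gr, index$promoter)
    cls[in_prom & cls == "intergenic"] <- "promoter"
  }
  in_te <- ov(gr, index$te)
  cls[in_te] <- "transposon"
  sub[in_te] <- NA
  list(class = cls, subfeature = sub)
}

#' Annotate positions with feature classes and count per class
#'
#' @param positions data frame with chrom, pos and optionally direction
#'   (hyper/hypo) and context; a `dmp_set` works directly.
#' @param index a `feature_index` from [build_feature_index()].
#' @return an `annotated_positions` object: the input with `class` and
#'   `subfeature` columns, plus bar-chart-ready `counts` (class x direction,
#'   split by context when present). Positions on chromosomes absent from the
#'   index are classed intergenic like any unannotated coordinate; unknown
#'   chromosome names trigger a warning and an `unmapped` count.
#' @export
annotate_positions <- function(positions, index) {
  positions <- as.data.frame(positions)
  n <- nrow(positions)
  if (n == 0) {
    counts <- table(class = factor(character(0),
                                   c("transposon", "gene", "intergenic")),
                    direction = factor(character(0), c("hyper", "hypo")))
    return(structure(list(positions = positions, counts = counts,
                          n_unmapped = 0L),
                     class = "annotated_positions"))
  }
  known <- unique(c(
    as.character(GenomicRanges::seqnames(index$te)),
    as.character(GenomicRanges::seqnames(index$gene))))
  unmapped <- !(positions$chrom %in% known)
  if (any(unmapped) && length(known) > 0)
    warning(sprintf("%d position(s) on chromosomes absent from the annotation",
                    sum(unmapped)), call. = FALSE)
  cl <- classify_positions(positions, index)
  positions$class <- cl$class
  positions$subfeature <- cl$subfeature
  dir <- positions$direction %||% rep("all", n)
  lvls <- c("transposon", "gene",
            if (!is.null(index$promoter)) "promoter", "intergenic")
  counts <- table(class = factor(positions$class, lvls), direction = dir)
  structure(list(positions = positions, counts = counts,
                 n_unmapped = sum(unmapped)),
            class = "annotated_positions")
}

#' @export
print.annotated_positions <- function(x, ...) {
  cat(sprintf("Annotated %d positions (%d on unknown chromosomes)\n",
              nrow(x$positions), x$n_unmapped))
  print(x$counts)
  invisible(x)
}
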
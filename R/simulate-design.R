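#' Build a single-seed-descent pedigree design
#'
#' A pedigree is a set of lines, each propagated by single-seed descent for the
#' same number of generations. Each generation of a line is either mock-treated
#' (`M`) or pathogen-stressed (`S`); the treatment string reads left to right
#' from the first generation. The final-generation individual of each line
#' founds `replicates` pooled progeny samples of `pool_size` plants each --
#' one pooled sample is what gets bisulfite-sequenced.
#'
#' @param design character vector of treatment strings over the alphabet
#'   `{M, S}`, one character per generation, all the same length. Names, if
#'   given, become line ids; otherwise ids are the strings themselves (made
#'   unique).
#' @param replicates pooled replicate samples per line (default 3).
#' @param pool_size plants pooled per sample (default 10).
#' @return an object of class `pedigree`.
#' @examples
#' pedigree(c("MMM", "SMM", "SSS"))
#' @export
pedigree <- function(design, replicates = 3, pool_size = 10) {
  stop_if_not(length(design) >= 1 && all(nzchar(design)),
              "design strings must be non-empty")
  gens <- nchar(design)
  stop_if_not(length(unique(gens)) == 1,
              "all treatment strings must have the same length (= generations)")
  stop_if_not(all(grepl("^[MS]+$", design)),
              "treatment strings may only contain characters 'M' and 'S'")
  stop_if_not(replicates >= 1, "replicates_per_line must be >= 1")
  stop_if_not(pool_size >= 1, "pool_size must be >= 1")
  ids <- names(design) %||% make.unique(design, sep = "_")
  structure(
    list(
      lines = data.frame(line_id = ids, treatment = unname(design),
                         stringsAsFactors = FALSE),
      generations = gens[1],
      replicates = as.integer(replicates),
      pool_size = as.integer(pool_size)
    ),
    class = "pedigree"
  )
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree: %d line(s) x %d generation(s); %d replicate(s)/line, pool of %d plants\n",
              nrow(x$lines), x$generations, x$replicates, x$pool_size))
  for (i in seq_len(nrow(x$lines)))
    cat(sprintf("  %s: %s\n", x$lines$line_id[i], x$lines$treatment[i]))
  invisible(x)
}

#' Generative model for pedigree-structured methylomes
#'
#' Parameters of the epimutation/stress/coverage model behind
#' [simulate_study()]. All rate parameters are free simulation parameters, not
#' estimates from any published dataset; defaults are what we consider
#' realistic for a desk-scale Arabidopsis-like study and are discussed in the
#' methods vignette.
#'
#' @param n_cg number of symmetric CG sites (each emits a +/- strand record pair).
#' @param n_chg,n_chh numbers of non-CG cytosines. Non-CG positions are given
#'   fixed population fractions shared by all lines (no heritable dynamics), so
#'   they differ between samples by sampling noise only.
#' @param labile_fraction fraction of CG sites classed methylation-labile.
#' @param eps_labile,eps_stable per-generation per-site epiallele flip
#'   probabilities for labile and stable CG sites (`eps_labile >= eps_stable`).
#' @param n_stress_responsive number of stress-responsive CG sites (default
#'   4\% of `n_cg`).
#' @param frac_responsive_labile fraction of responsive sites drawn from the
#'   labile class (stress preferentially targets labile positions).
#' @param delta_stress expected shift (fraction of 1) in the methylation state
#'   of an expressing plant per stress-exposed generation, toward the site's
#'   designated direction.
#' @param penetrance fraction of pooled plants expressing the inherited stress
#'   shift; the population-level expected shift per stress generation is
#'   `delta_stress * penetrance`.
#' @param meth_init initial probability that a CG site is methylated in the
#'   common founder.
#' @param n_chloroplast number of conversion-control cytosines on the
#'   unmethylated chloroplast contig `ChrC`.
#' @param conversion_rate true bisulfite conversion probability `c`; an
#'   unmethylated read is miscalled methylated with probability `1 - c`.
#' @param coverage_mean,coverage_dispersion negative-binomial read-depth model:
#'   variance `mu + mu^2 * dispersion`.
#' @param seed integer seed; every stochastic choice in the simulator is
#'   derived deterministically from it.
#' @return an object of class `epigenome_model` (a validated parameter list).
#' @export
epigenome_model <- function(n_cg = 50000, n_chg = 10000, n_chh = 20000,
                            labile_fraction = 0.2,
                            eps_labile = 0.003, eps_stable = 1e-4,
                            n_stress_responsive = round(0.04 * n_cg),
                            frac_responsive_labile = 0.75,
                            delta_stress = 0.15, penetrance = 0.8,
                            meth_init = 0.3,
                            n_chloroplast = 5000, conversion_rate = 0.995,
                            coverage_mean = 20, coverage_dispersion = 0.3,
                            seed = 1L) {
  m <- list(n_cg = as.integer(n_cg), n_chg = as.integer(n_chg),
            n_chh = as.integer(n_chh),
            labile_fraction = labile_fraction,
            eps_labile = eps_labile, eps_stable = eps_stable,
            n_stress_responsive = as.integer(n_stress_responsive),
            frac_responsive_labile = frac_responsive_labile,
            delta_stress = delta_stress, penetrance = penetrance,
            meth_init = meth_init,
            n_chloroplast = as.integer(n_chloroplast),
            conversion_rate = conversion_rate,
            coverage_mean = coverage_mean,
            coverage_dispersion = coverage_dispersion,
            seed = as.integer(seed))
  probs <- c("labile_fraction", "eps_labile", "eps_stable",
             "frac_responsive_labile", "delta_stress", "penetrance",
             "meth_init", "conversion_rate")
  for (p in probs)
    stop_if_not(m[[p]] >= 0 && m[[p]] <= 1,
                sprintf("%s must be a probability in [0,1]", p))
  stop_if_not(m$eps_labile >= m$eps_stable, "eps_labile must be >= eps_stable")
  stop_if_not(m$n_stress_responsive <= m$n_cg,
              "n_stress_responsive must be <= n_cg")
  stop_if_not(m$coverage_mean > 0, "coverage_mean must be > 0")
  stop_if_not(m$coverage_dispersion >= 0, "coverage_dispersion must be >= 0")
  structure(m, class = "epigenome_model")
}

#' @export
print.epigenome_model <- function(x, ...) {
  cat("Epigenome model\n")
  cat(sprintf("  CG sites: %d (labile fraction %.2f, %d stress-responsive)\n",
              x$n_cg, x$labile_fraction, x$n_stress_responsive))
  cat(sprintf("  epimutation/gen: labile %.2g, stable %.2g\n",
              x$eps_labile, x$eps_stable))
  cat(sprintf("  stress shift/gen: %.2f (penetrance %.2f)\n",
              x$delta_stress, x$penetrance))
  cat(sprintf("  coverage: NB(mean %.1f, disp %.2f); conversion %.4f; seed %d\n",
              x$coverage_mean, x$coverage_dispersion, x$conversion_rate, x$seed))
  invisible(x)
}

#' Read a simulation design from a YAML config
#'
#' The file may contain a `model:` mapping (any [epigenome_model()] argument)
#' and a `pedigree:` mapping with `design` (list of treatment strings) and
#' optional `replicates` / `pool_size`.
#'
#' @param path path to a YAML file.
#' @return list with elements `model` and `pedigree`.
#' @examples
#' cfg <- read_sim_config(system.file("extdata", "example_design.yaml",
#'                                    package = "methTAR"))
#' cfg$pedigree
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  model <- do.call(epigenome_model, cfg$model %||% list())
  ped <- NULL
  if (!is.null(cfg$pedigree)) {
    p <- cfg$pedigree
    design <- unlist(p$design)
    if (!is.null(p$line_ids)) names(design) <- unlist(p$line_ids)
    ped <- pedigree(design,
                    replicates = p$replicates %||% 3,
                    pool_size = p$pool_size %||% 10)
  }
  list(model = model, pedigree = ped)
}
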
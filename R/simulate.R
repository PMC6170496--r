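# Pedigree-structured methylome simulator.
#
# Epiallele states are diploid three-state: 0 (neither allele methylated),
# 0.5 (one), 1 (both). Epimutation moves one step; the pooled population
# fraction at a site is the mean state over pooled plants.

# Deterministic genome layout + founder epigenome derived from model$seed.
# CG sites are strand pairs (plus at pos, minus at pos+1) so the IO stage's
# destranding is exercised by simulated data.
make_genome <- function(model) {
  set.seed(derive_seed(model$seed, "genome"))
  n <- model$n_cg
  cg_pos <- (seq_len(n) - 1L) * 10L + 1L
  labile <- rep(FALSE, n)
  labile[sample.int(n, round(model$labile_fraction * n))] <- TRUE

  n_resp <- model$n_stress_responsive
  resp_idx <- integer(0)
  if (n_resp > 0) {
    n_lab <- min(round(model$frac_responsive_labile * n_resp), sum(labile))
    n_stab <- min(n_resp - n_lab, sum(!labile))
    resp_idx <- c(
      if (n_lab > 0) sample(which(labile), n_lab),
      if (n_stab > 0) sample(which(!labile), n_stab)
    )
  }
  resp_dir <- character(0)
  if (length(resp_idx) > 0)
    resp_dir <- sample(c("hyper", "hypo"), length(resp_idx), replace = TRUE)

  founder <- as.numeric(stats::runif(n) < model$meth_init)
  # responsive sites start at the far state so the designated shift has room
  founder[resp_idx[resp_dir == "hyper"]] <- 0
  founder[resp_idx[resp_dir == "hypo"]] <- 1

  noncg <- NULL
  if (model$n_chg + model$n_chh > 0) {
    off_chg <- n * 10L + 1000L
    off_chh <- off_chg + model$n_chg * 10L + 1000L
    noncg <- data.frame(
      chrom = "Chr1",
      pos = c(off_chg + (seq_len(model$n_chg) - 1L) * 10L,
              off_chh + (seq_len(model$n_chh) - 1L) * 10L),
      strand = "+",
      context = rep(c("CHG", "CHH"), c(model$n_chg, model$n_chh)),
      p_true = stats::rbeta(model$n_chg + model$n_chh, 0.2, 0.8),
      stringsAsFactors = FALSE
    )
  }
  chloroplast <- NULL
  if (model$n_chloroplast > 0) {
    chloroplast <- data.frame(
      chrom = "ChrC",
      pos = (seq_len(model$n_chloroplast) - 1L) * 5L + 1L,
      strand = "+", context = "CG", stringsAsFactors = FALSE
    )
  }
  list(cg_chrom = "Chr1", cg_pos = cg_pos, labile = labile,
       responsive = data.frame(site = resp_idx, direction = resp_dir,
                               stringsAsFactors = FALSE),
       founder = founder, noncg = noncg, chloroplast = chloroplast)
}

#' Founder plant methylome
#'
#' The common single-seed ancestor all pedigree lines descend from: the CG
#' epiallele states plus the accumulated stress dose (zero at the founder).
#'
#' @param model an [epigenome_model()].
#' @param genome internal genome layout; built from the model if omitted.
#' @return an object of class `plant_methylome`.
#' @export
founder_methylome <- function(model, genome = make_genome(model)) {
  structure(list(states = genome$founder,
                 dose = numeric(length(genome$founder)),
                 genome = genome, model = model),
            class = "plant_methylome")
}

step_states <- function(states, flip) {
  up <- flip & states == 0
  down <- flip & states == 1
  mid <- flip & states == 0.5
  states[up] <- 0.5
  states[down] <- 0.5
  if (any(mid)) states[mid] <- sample(c(0, 1), sum(mid), replace = TRUE)
  states
}

#' Advance one generation of single-seed descent
#'
#' Each labile CG site flips one epiallele step with probability `eps_labile`
#' (stable sites: `eps_stable`). Under stress (`treatment = "S"`) each
#' stress-responsive site additionally shifts toward its designated direction:
#' the germline accumulates `delta_stress` of heritable dose per stress
#' generation, which is realised as whole epiallele steps (with stochastic
#' rounding) in each pooled plant that expresses it -- see [simulate_study()].
#'
#' @param parent a `plant_methylome`.
#' @param treatment `"M"` (mock) or `"S"` (stress).
#' @param model an [epigenome_model()]; defaults to the parent's.
#' @return the child `plant_methylome`. Uses the current RNG state.
#' @export
propagate_generation <- function(parent, treatment, model = parent$model) {
  stop_if_not(inherits(parent, "plant_methylome"), "parent must be a plant_methylome")
  stop_if_not(treatment %in% c("M", "S"), "treatment must be 'M' or 'S'")
  g <- parent$genome
  n <- length(parent$states)
  eps <- ifelse(g$labile, model$eps_labile, model$eps_stable)
  flip <- stats::runif(n) < eps
  child <- parent
  child$states <- step_states(parent$states, flip)
  if (treatment == "S" && nrow(g$responsive) > 0)
    child$dose[g$responsive$site] <- child$dose[g$responsive$site] +
      model$delta_stress
  child
}

# realise the accumulated stress dose of one plant: the dose (a methylation
# fraction) becomes whole half-steps by stochastic rounding, applied toward
# each responsive site's designated direction and clipped to [0, 1]
express_dose <- function(states, dose, genome) {
  idx <- genome$responsive$site
  if (length(idx) == 0) return(states)
  d <- dose[idx]
  steps <- floor(d / 0.5) + (stats::runif(length(idx)) < (d %% 0.5) / 0.5)
  dir <- ifelse(genome$responsive$direction == "hyper", 1, -1)
  states[idx] <- pmin(1, pmax(0, states[idx] + dir * 0.5 * steps))
  states
}

#' Average epiallele states over a pool of plants
#'
#' @param plants a list of `plant_methylome` objects (or bare numeric state
#'   vectors) over identical position sets.
#' @return numeric vector of population methylation fractions per CG site.
#' @export
pool_population <- function(plants) {
  stop_if_not(length(plants) >= 1, "pool must contain at least one plant")
  states <- lapply(plants, function(p) if (is.list(p)) p$states else p)
  len <- vapply(states, length, 1L)
  stop_if_not(length(unique(len)) == 1, "plants must share one position set")
  Reduce(`+`, states) / length(states)
}

nb_coverage <- function(n, model) {
  if (model$coverage_dispersion <= 0) {
    stats::rpois(n, model$coverage_mean)
  } else {
    stats::rnbinom(n, mu = model$coverage_mean,
                   size = 1 / model$coverage_dispersion)
  }
}

draw_counts <- function(p, model) {
  C <- nb_coverage(length(p), model)
  p_app <- p + (1 - p) * (1 - model$conversion_rate)
  M <- stats::rbinom(length(p), C, p_app)
  list(C = C, M = M)
}

#' Draw a cytosine count table from population methylation fractions
#'
#' Per position, coverage is negative-binomial; the apparent methylation
#' probability is `p' = p + (1 - p) * (1 - c)` (imperfect bisulfite conversion
#' inflates methylation calls); the methylated count is `Binomial(C, p')`.
#' CG sites emit both strand records with independent coverage; chloroplast
#' control cytosines are generated with true `p = 0` and returned in the
#' table's `control` attribute. Zero-coverage positions are omitted (not
#' covered).
#'
#' @param fracs numeric vector of CG-site fractions as from [pool_population()].
#' @param model an [epigenome_model()].
#' @param genome internal genome layout (defaults to one built from the model,
#'   which matches `fracs` only if the same model built them).
#' @param sample_id,line_id,group optional labels stored as attributes.
#' @return a `cytosine_table` data frame (chrom, pos, strand, M, U, context).
#'   Uses the current RNG state.
#' @export
sample_counts <- function(fracs, model, genome = make_genome(model),
                          sample_id = "sample", line_id = NA, group = NA) {
  stop_if_not(all(fracs >= 0 & fracs <= 1), "fractions must lie in [0,1]")
  parts <- list()
  if (length(fracs) > 0) {
    plus <- draw_counts(fracs, model)
    minus <- draw_counts(fracs, model)
    parts$cg <- data.frame(
      chrom = genome$cg_chrom,
      pos = c(genome$cg_pos, genome$cg_pos + 1L),
      strand = rep(c("+", "-"), each = length(fracs)),
      M = c(plus$M, minus$M),
      U = c(plus$C - plus$M, minus$C - minus$M),
      context = "CG", stringsAsFactors = FALSE
    )
  }
  if (!is.null(genome$noncg)) {
    d <- draw_counts(genome$noncg$p_true, model)
    parts$noncg <- data.frame(
      chrom = genome$noncg$chrom, pos = genome$noncg$pos,
      strand = genome$noncg$strand, M = d$M, U = d$C - d$M,
      context = genome$noncg$context, stringsAsFactors = FALSE
    )
  }
  control <- NULL
  if (!is.null(genome$chloroplast)) {
    d <- draw_counts(rep(0, nrow(genome$chloroplast)), model)
    control <- data.frame(
      chrom = genome$chloroplast$chrom, pos = genome$chloroplast$pos,
      strand = genome$chloroplast$strand, M = d$M, U = d$C - d$M,
      context = genome$chloroplast$context, stringsAsFactors = FALSE
    )
    control <- control[control$M + control$U > 0, , drop = FALSE]
    rownames(control) <- NULL
  }
  tab <- if (length(parts) > 0) do.call(rbind, parts) else
    data.frame(chrom = character(0), pos = integer(0), strand = character(0),
               M = integer(0), U = integer(0), context = character(0),
               stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  tab <- tab[tab$M + tab$U > 0, , drop = FALSE]
  tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
  cytosine_table(tab, sample_id = sample_id, line_id = line_id, group = group,
                 control = control)
}

n_stress_gens <- function(treatment) {
  vapply(strsplit(treatment, ""), function(ch) sum(ch == "S"), 1L)
}

#' Simulate a full pedigree methylome study
#'
#' Propagates every line of the pedigree from a common founder by single-seed
#' descent, applying the per-generation treatments; draws `replicates` pooled
#' samples per line (each pooled plant is one stress-free offspring of the
#' final individual, and expresses the inherited stress shift with probability
#' `penetrance`); and emits one cytosine count table per sample plus truth
#' tables. Fully reproducible from `model$seed`.
#'
#' @param ped a [pedigree()].
#' @param model an [epigenome_model()].
#' @param dir optional directory; if given, per-sample cytosine reports and
#'   truth tables are written there as tab-separated text.
#' @return an object of class `tar_simulation`: list with `samples` (named
#'   list of `cytosine_table`s), `truth` (`responsive`, `classes`, `lines`
#'   data frames), `pedigree`, `model`.
#' @export
simulate_study <- function(ped, model, dir = NULL) {
  stop_if_not(inherits(ped, "pedigree"), "ped must be a pedigree")
  stop_if_not(inherits(model, "epigenome_model"), "model must be an epigenome_model")
  genome <- make_genome(model)
  founder <- founder_methylome(model, genome)

  samples <- list()
  for (i in seq_len(nrow(ped$lines))) {
    line_id <- ped$lines$line_id[i]
    treat <- strsplit(ped$lines$treatment[i], "")[[1]]
    set.seed(derive_seed(model$seed, "line", line_id))
    plant <- founder
    for (tr in treat) plant <- propagate_generation(plant, tr, model)
    group <- if (any(treat == "S")) "stress" else "mock"

    for (r in seq_len(ped$replicates)) {
      set.seed(derive_seed(model$seed, "sample", line_id, r))
      pool <- vector("list", ped$pool_size)
      for (k in seq_len(ped$pool_size)) {
        offspring <- propagate_generation(plant, "M", model)
        expressed <- stats::runif(1) < model$penetrance
        st <- offspring$states
        if (expressed) st <- express_dose(st, offspring$dose, genome)
        pool[[k]] <- st
      }
      fr <- pool_population(pool)
      sid <- sprintf("%s_%d", line_id, r)
      samples[[sid]] <- sample_counts(fr, model, genome, sample_id = sid,
                                      line_id = line_id, group = group)
    }
  }

  n_s <- n_stress_gens(ped$lines$treatment)
  lines <- data.frame(
    line_id = ped$lines$line_id, treatment = ped$lines$treatment,
    n_stress = n_s,
    expected_shift = model$delta_stress * n_s,
    expected_pop_shift = model$delta_stress * n_s * model$penetrance,
    stringsAsFactors = FALSE
  )
  responsive <- data.frame(
    chrom = rep(genome$cg_chrom, nrow(genome$responsive)),
    pos = genome$cg_pos[genome$responsive$site],
    direction = genome$responsive$direction, stringsAsFactors = FALSE
  )
  classes <- data.frame(
    chrom = genome$cg_chrom, pos = genome$cg_pos,
    class = ifelse(genome$labile, "labile", "stable"),
    stringsAsFactors = FALSE
  )

  out <- structure(list(samples = samples,
                        truth = list(responsive = responsive,
                                     classes = classes, lines = lines),
                        pedigree = ped, model = model),
                   class = "tar_simulation")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (sid in names(samples))
      write_cytosine_report(samples[[sid]],
                            file.path(dir, paste0(sid, ".cov.txt")))
    utils::write.table(responsive, file.path(dir, "truth_responsive.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(classes, file.path(dir, "truth_classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(lines, file.path(dir, "truth_lines.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' @export
print.tar_simulation <- function(x, ...) {
  cat(sprintf("Simulated methylome study: %d samples from %d line(s)\n",
              length(x$samples), nrow(x$pedigree$lines)))
  cat(sprintf("  CG sites: %d (%d stress-responsive); seed %d\n",
              x$model$n_cg, nrow(x$truth$responsive), x$model$seed))
  invisible(x)
}
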
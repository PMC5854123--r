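# End-to-end colony analysis: one fitting function returning a classed
# object, in the classic R modelling idiom.

#' Fit the recombination and mutation landscape of drone colonies
#'
#' Runs the full analysis on a haploid drone genotype matrix: marker
#' screening per colony, queen-haplotype phasing, haplotype-block
#' assignment per drone, crossover/noncrossover classification with shared
#' double-crossover exclusion, genome-wide and per-window crossover rates,
#' strict de novo mutation calling, and mutation-rate estimation with
#' exact Poisson intervals.
#'
#' @param gt a [genotype_matrix()], or a list of them (one per colony,
#'   e.g. both colonies of a study).
#' @param colonies colonies to analyse; default all present.
#' @param min_quality,min_call_fraction marker screening thresholds
#'   ([screen_markers()]).
#' @param threshold_bp crossover span threshold ([classify_events()]).
#' @param double_co_window category-2 window ([group_shared_cos()]).
#' @param min_depth,mut_min_quality carrier thresholds for mutation
#'   calling ([call_denovo()]).
#' @param gaps optional assembly gaps data.frame.
#' @param callable per-drone callable-site counts (named vector covering
#'   all drones) or a single drone-summed total; default taken from the
#'   simulator's `genome_callable` attribute when present. Without it the
#'   mutation rate is not estimated.
#' @param genome_mb assembled genome size in Mb; default from the
#'   matrix's genome attribute.
#' @param genome_bp full genome size in bp for the per-genome mutation
#'   rate (default 274 Mb, allowing for unassembled sequence).
#' @param window_bp rate window size (default 500 kb).
#' @param conf confidence level for Poisson intervals.
#' @return an object of class `colony_fit`; see [summary.colony_fit()],
#'   [coef.colony_fit()], [plot.colony_fit()], [simulate.colony_fit()].
#' @export
fit_colony <- function(gt, colonies = NULL, min_quality = 30,
                       min_call_fraction = 0.9, threshold_bp = 10000,
                       double_co_window = 700000, min_depth = 5,
                       mut_min_quality = 30, gaps = NULL, callable = NULL,
                       genome_mb = NULL, genome_bp = 274e6,
                       window_bp = 500000, conf = 0.95) {
  mats <- if (inherits(gt, "genotype_matrix")) list(gt) else gt
  if (!length(mats)) stop("no genotype matrices supplied")
  stopifnot(all(vapply(mats, inherits, TRUE, "genotype_matrix")))
  if (is.null(genome_mb)) {
    spec <- attr(mats[[1L]], "genome")
    if (is.null(spec)) stop("genome_mb must be given when the matrix ",
                            "carries no genome specification")
    genome_mb <- sum(spec$lengths) / 1e6
  }
  if (is.null(callable)) {
    cal <- unlist(lapply(mats, attr, "genome_callable"))
  } else cal <- callable
  per_colony <- list()
  events_all <- list()
  calls_all <- list()
  n_drones <- 0L
  drones_all <- list()
  for (m in mats) {
    cols <- if (is.null(colonies)) unique(m$drones$colony) else
      intersect(colonies, m$drones$colony)
    for (colony in cols) {
      ids <- m$drones$id[m$drones$colony == colony]
      markers <- screen_markers(m, colony, min_quality, min_call_fraction)
      phase <- phase_queen(markers, m)
      blocks <- do.call(rbind, lapply(ids, assign_blocks, phase = phase,
                                      gt = m))
      events <- classify_events(blocks, threshold_bp)
      events <- group_shared_cos(events, gaps, double_co_window)
      calls <- call_denovo(m, colony, markers, min_depth,
                           mut_min_quality,
                           require_strand = !is.null(m$strand_fwd),
                           gaps = gaps, blocks = blocks)
      per_colony[[colony]] <- list(markers = markers, phase = phase,
                                   blocks = blocks, events = events,
                                   calls = calls, n_drones = length(ids))
      events_all[[colony]] <- if (nrow(events)) cbind(events,
                                                      colony = colony)
      calls_all[[colony]] <- if (nrow(calls)) cbind(calls,
                                                    colony = colony)
      n_drones <- n_drones + length(ids)
      drones_all[[colony]] <- m$drones[m$drones$colony == colony, ]
    }
  }
  events <- do.call(rbind, events_all)
  if (is.null(events))
    events <- cbind(classify_events(data.frame(
      drone = character(0), chrom = character(0), phase_set = integer(0),
      hap = integer(0), start = numeric(0), end = numeric(0),
      n_markers = integer(0))), colony = character(0))
  calls <- do.call(rbind, calls_all)
  rownames(events) <- NULL
  rates <- crossover_rate(events, genome_mb, n_drones)
  spec1 <- attr(mats[[1L]], "genome")
  windows <- if (!is.null(spec1))
    window_rates(events, spec1$lengths, n_drones, window_bp) else NULL
  nco <- events$kind == "NCO"
  total_callable <- if (length(cal)) sum(cal) else NULL
  snm_rate <- indel_rate <- spectrum <- NULL
  n_snm <- if (is.null(calls)) 0L else sum(calls$kind == "SNM")
  n_indel <- if (is.null(calls)) 0L else sum(calls$kind == "indel")
  if (!is.null(total_callable)) {
    snm_rate <- estimate_rate(n_snm, total_callable, conf, genome_bp)
    indel_rate <- estimate_rate(n_indel, total_callable, conf, genome_bp)
  } else message("no callable-site counts: mutation rate not estimated")
  gc <- if (!is.null(spec1)) spec1$gc_content else NULL
  if (!is.null(calls) && !is.null(gc))
    spectrum <- spectrum_summary(calls, gc)
  structure(list(
    colonies = per_colony, events = events, calls = calls,
    rates = rates, windows = windows,
    nco_per_drone = sum(nco) / n_drones,
    converted_per_drone = sum(events$n_converted[nco]) / n_drones,
    snm_rate = snm_rate, indel_rate = indel_rate, spectrum = spectrum,
    n_drones = n_drones, genome_mb = genome_mb, genome_bp = genome_bp,
    drones = do.call(rbind, drones_all), callable = cal,
    params = list(min_quality = min_quality,
                  min_call_fraction = min_call_fraction,
                  threshold_bp = threshold_bp,
                  double_co_window = double_co_window,
                  min_depth = min_depth,
                  mut_min_quality = mut_min_quality,
                  window_bp = window_bp, conf = conf)),
    class = "colony_fit")
}

#' @export
print.colony_fit <- function(x, ...) {
  cat(sprintf("colony_fit: %d drones in %d colon%s, %.1f Mb assembled\n",
              x$n_drones, length(x$colonies),
              if (length(x$colonies) == 1L) "y" else "ies", x$genome_mb))
  cat(sprintf("  crossovers: %d kept (%d excluded), %.2f cM/Mb\n",
              x$rates$kept_cos, x$rates$excluded_cos, x$rates$cM_per_Mb))
  cat(sprintf("  noncrossovers: %.2f per drone\n", x$nco_per_drone))
  if (!is.null(x$snm_rate))
    cat(sprintf("  mutation rate: %.3g per bp (%d SNMs)\n",
                x$snm_rate$rate, x$snm_rate$count))
  invisible(x)
}

#' Summarise a colony fit
#'
#' The study-table summary: crossover rate, crossovers per chromosome per
#' drone, noncrossovers and converted markers per drone, and the mutation
#' rate with its confidence interval.
#'
#' @param object a [fit_colony()] result.
#' @param ... unused.
#' @return a `summary.colony_fit` list with a print method.
#' @export
summary.colony_fit <- function(object, ...) {
  x <- object
  n_chrom <- length(unique(x$events$chrom[x$events$kind == "CO"]))
  out <- list(
    n_drones = x$n_drones,
    genome_mb = x$genome_mb,
    co_rate_cM_per_Mb = x$rates$cM_per_Mb,
    co_rate_raw = x$rates$cM_per_Mb_raw,
    cos_per_drone = x$rates$cos_per_drone,
    cos_per_chrom_per_drone = if (n_chrom)
      x$rates$kept_cos / x$n_drones / n_chrom else 0,
    ncos_per_drone = x$nco_per_drone,
    converted_markers_per_drone = x$converted_per_drone,
    mutation_rate = if (!is.null(x$snm_rate)) x$snm_rate$rate else NA,
    mutation_ci = if (!is.null(x$snm_rate)) x$snm_rate$ci else c(NA, NA),
    indel_rate = if (!is.null(x$indel_rate)) x$indel_rate$rate else NA,
    mutations_per_genome = if (!is.null(x$snm_rate))
      x$snm_rate$per_genome else NA,
    spectrum = x$spectrum)
  class(out) <- "summary.colony_fit"
  out
}

#' @export
print.summary.colony_fit <- function(x, ...) {
  cat("Colony analysis summary\n")
  cat(sprintf("  drones                          %d\n", x$n_drones))
  cat(sprintf("  rate of CO (cM/Mb)              %.2f\n",
              x$co_rate_cM_per_Mb))
  cat(sprintf("  COs per chromosome per drone    %.2f\n",
              x$cos_per_chrom_per_drone))
  cat(sprintf("  NCOs per drone                  %.2f\n",
              x$ncos_per_drone))
  cat(sprintf("  markers converted per drone     %.2f\n",
              x$converted_markers_per_drone))
  if (!is.na(x$mutation_rate)) {
    cat(sprintf("  mutation rate (per bp)          %.3g (%.3g - %.3g)\n",
                x$mutation_rate, x$mutation_ci[1], x$mutation_ci[2]))
    cat(sprintf("  mutations per genome            %.2f\n",
                x$mutations_per_genome))
  }
  invisible(x)
}

#' Coefficients of a colony fit
#'
#' @param object a [fit_colony()] result.
#' @param ... unused.
#' @return named numeric vector of the fitted rates.
#' @export
coef.colony_fit <- function(object, ...) {
  c(co_rate_cM_per_Mb = object$rates$cM_per_Mb,
    cos_per_drone = object$rates$cos_per_drone,
    nco_per_drone = object$nco_per_drone,
    mutation_rate_per_bp = if (!is.null(object$snm_rate))
      object$snm_rate$rate else NA_real_,
    indel_rate_per_bp = if (!is.null(object$indel_rate))
      object$indel_rate$rate else NA_real_,
    mutations_per_genome = if (!is.null(object$snm_rate))
      object$snm_rate$per_genome else NA_real_)
}

#' Plot per-window crossover rates
#'
#' One panel of stacked per-chromosome rate tracks; hotspot windows are
#' marked.
#'
#' @param x a [fit_colony()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.colony_fit <- function(x, ...) {
  w <- x$windows
  if (is.null(w)) stop("no window rates (matrix carried no genome spec)")
  chroms <- unique(w$chrom)
  offs <- c(0, cumsum(tapply(w$end, w$chrom, max)[chroms]))
  names(offs) <- c(chroms, "end")
  xx <- (w$start + w$end) / 2 + offs[w$chrom]
  graphics::plot(xx / 1e6, w$cM_per_Mb, type = "h",
                 col = ifelse(w$hotspot, "red", "grey40"),
                 xlab = "genome position (Mb)",
                 ylab = "crossover rate (cM/Mb)", ...)
  graphics::abline(v = offs[-1] / 1e6, col = "grey80", lty = 3)
  invisible(x)
}

#' Simulate colonies at the fitted parameter values
#'
#' Draws new synthetic colonies whose crossover rate, noncrossover rate
#' and mutation rate equal the fitted estimates - a parametric-bootstrap
#' companion to [fit_colony()].
#'
#' @param object a [fit_colony()] result.
#' @param nsim number of colonies.
#' @param seed optional integer seed.
#' @param n_drones drones per simulated colony (default: as fitted).
#' @param spec genome to simulate on (default: the fitted matrix's).
#' @param ... unused.
#' @return a list of [simulate_colony()] results.
#' @export
simulate.colony_fit <- function(object, nsim = 1, seed = NULL,
                                n_drones = NULL, spec = NULL, ...) {
  if (is.null(n_drones)) n_drones <- object$n_drones
  if (is.null(spec)) spec <- genome_spec(total_bp = object$genome_mb * 1e6)
  meiosis <- meiosis_params(
    co_rate_cM_per_Mb = object$rates$cM_per_Mb,
    nco_rate_per_gamete = object$nco_per_drone)
  mutation <- if (!is.null(object$snm_rate))
    mutation_params(mu_per_bp = object$snm_rate$rate) else mutation_params()
  with_seed(seed, lapply(seq_len(nsim), function(i)
    simulate_colony(n_drones, spec, meiosis = meiosis,
                    mutation = mutation, colony = sprintf("S%d", i))))
}
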
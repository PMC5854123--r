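#' Genome specification for colony simulation
#'
#' Describes the assembled genome the simulator places markers, events and
#' mutations on: chromosome names and lengths, genomic GC content, and
#' optional assembly gaps (runs of N) in which no marker or mutation is ever
#' placed (recombination breakpoints may still fall inside them, which is
#' what creates apparently shared crossovers on real assemblies).
#'
#' The default reproduces the scale of the *Bombus terrestris* assembly used
#' for drone sequencing studies: 18 chromosomes totalling 216.85 Mb of
#' assembled sequence at 37.5% GC. Chromosome lengths default to equal
#' shares of the total; pass explicit lengths to override.
#'
#' @param chromosomes named numeric vector of chromosome lengths in bp, or
#'   `NULL` for the default 18 equal chromosomes.
#' @param total_bp total assembled length used when `chromosomes` is `NULL`.
#' @param n_chrom number of chromosomes used when `chromosomes` is `NULL`.
#' @param gc_content genomic G+C fraction in `[0, 1]`.
#' @param gaps `NULL` or a data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) of assembly gaps; overlapping intervals are merged.
#' @return an object of class `genome_spec`.
#' @examples
#' spec <- genome_spec()
#' sum(spec$lengths) # 216.85 Mb
#' @export
genome_spec <- function(chromosomes = NULL, total_bp = 216.85e6,
                        n_chrom = 18L, gc_content = 0.375, gaps = NULL) {
  if (is.null(chromosomes)) {
    len <- rep(floor(total_bp / n_chrom), n_chrom)
    names(len) <- sprintf("LG%d", seq_len(n_chrom))
    chromosomes <- len
  }
  if (is.null(names(chromosomes)) || anyDuplicated(names(chromosomes)))
    stop("chromosomes must be a uniquely named vector of lengths")
  if (any(!is.finite(chromosomes)) || any(chromosomes <= 0))
    stop("chromosome lengths must be positive and finite")
  if (!is.finite(gc_content) || gc_content < 0 || gc_content > 1)
    stop("gc_content must be in [0, 1]")
  lengths <- as.numeric(chromosomes)
  names(lengths) <- names(chromosomes)
  if (!is.null(gaps)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(gaps)))
    if (!all(gaps$chrom %in% names(lengths)))
      stop("gap interval on unknown chromosome")
    if (any(gaps$start < 0) ||
        any(gaps$end > lengths[as.character(gaps$chrom)]))
      stop("gap interval outside chromosome bounds")
    gaps <- merge_intervals(gaps)
  }
  structure(list(lengths = lengths, gc_content = gc_content, gaps = gaps),
            class = "genome_spec")
}

# merge overlapping/adjacent intervals per chromosome; 0-based half-open
merge_intervals <- function(iv) {
  iv <- iv[order(iv$chrom, iv$start), , drop = FALSE]
  out <- lapply(split(iv, iv$chrom), function(g) {
    s <- g$start; e <- g$end
    keep_s <- s[1]; keep_e <- e[1]; rs <- c(); re <- c()
    for (i in seq_along(s)[-1]) {
      if (s[i] <= keep_e) keep_e <- max(keep_e, e[i]) else {
        rs <- c(rs, keep_s); re <- c(re, keep_e)
        keep_s <- s[i]; keep_e <- e[i]
      }
    }
    data.frame(chrom = g$chrom[1], start = c(rs, keep_s), end = c(re, keep_e))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Meiosis parameters for gamete simulation
#'
#' Defaults are the study conditions for bumblebee drones: a crossover rate
#' of 8.73 cM/Mb (about 19 crossovers per gamete on the full assembly),
#' about 0.69 noncrossover conversion tracts per gamete with geometric tract
#' lengths of mean 300 bp, a small fraction of crossovers carrying an
#' adjacent conversion tract, and conversion of A/T-G/C heterozygous sites
#' resolved toward G/C with probability `gc_bias` (default the observed
#' 23:13 direction split, 23/36).
#'
#' @param co_rate_cM_per_Mb crossover rate; map length cM = 100 x mean
#'   crossovers per gamete, so the Poisson mean per chromosome is
#'   `co_rate * length_Mb / 100`.
#' @param nco_rate_per_gamete expected noncrossover tracts per gamete,
#'   apportioned to chromosomes by physical length.
#' @param nco_tract_mean_bp mean conversion-tract length (geometric).
#' @param co_gc_conversion_prob probability a crossover carries an adjacent
#'   conversion tract.
#' @param gc_bias probability a converted A/T-G/C site resolves toward G/C.
#' @return an object of class `meiosis_params`.
#' @export
meiosis_params <- function(co_rate_cM_per_Mb = 8.73,
                           nco_rate_per_gamete = 0.69,
                           nco_tract_mean_bp = 300,
                           co_gc_conversion_prob = 3 / 606,
                           gc_bias = 23 / 36) {
  stopifnot(co_rate_cM_per_Mb >= 0, nco_rate_per_gamete >= 0,
            nco_tract_mean_bp > 0,
            co_gc_conversion_prob >= 0, co_gc_conversion_prob <= 1,
            gc_bias >= 0, gc_bias <= 1)
  structure(list(co_rate_cM_per_Mb = co_rate_cM_per_Mb,
                 nco_rate_per_gamete = nco_rate_per_gamete,
                 nco_tract_mean_bp = nco_tract_mean_bp,
                 co_gc_conversion_prob = co_gc_conversion_prob,
                 gc_bias = gc_bias),
            class = "meiosis_params")
}

#' De novo mutation parameters
#'
#' Defaults follow the observed bumblebee spectrum: rate 3.58e-9 per bp per
#' haploid genome per generation, all point mutations transitions, 20/23 of
#' transitions G:C->A:T, and an indel fraction of 2/25.
#'
#' @param mu_per_bp per-bp per-generation haploid mutation rate.
#' @param p_transition probability a point mutation is a transition.
#' @param p_gc_to_at_given_transition probability a transition is G:C->A:T.
#' @param indel_fraction fraction of mutations that are short indels
#'   (< 20 bp).
#' @return an object of class `mutation_params`.
#' @export
mutation_params <- function(mu_per_bp = 3.58e-9, p_transition = 1,
                            p_gc_to_at_given_transition = 20 / 23,
                            indel_fraction = 2 / 25) {
  stopifnot(mu_per_bp >= 0,
            p_transition >= 0, p_transition <= 1,
            p_gc_to_at_given_transition >= 0,
            p_gc_to_at_given_transition <= 1,
            indel_fraction >= 0, indel_fraction <= 1)
  structure(list(mu_per_bp = mu_per_bp, p_transition = p_transition,
                 p_gc_to_at_given_transition = p_gc_to_at_given_transition,
                 indel_fraction = indel_fraction),
            class = "mutation_params")
}

#' Genotype observation model
#'
#' The noise channel between true gamete alleles and the genotype matrix the
#' pipeline sees: per-cell sequencing depth (Poisson around `mean_depth`),
#' a phred-like call quality (normal, clipped to `[0, 60]`), missing calls,
#' genotype errors (a random wrong base), and spurious "heterozygous" calls
#' of the kind marker screening removes from haploid cohorts. Strand support
#' is obtained by splitting each cell's reads binomially between strands.
#'
#' `mean_depth = 26` matches the coverage regime of the drone sequencing
#' study; the error rates are small plausible values for stringent haploid
#' calling at that depth.
#'
#' @param mean_depth mean per-site sequencing depth (> 0).
#' @param missing_rate probability a call is missing.
#' @param genotype_error_rate probability a call is replaced by a random
#'   wrong base.
#' @param het_artifact_rate probability a call is emitted as a spurious
#'   heterozygote.
#' @param quality_mean,quality_sd parameters of the clipped-normal call
#'   quality distribution.
#' @param error_quality_mean mean quality of erroneous calls (miscalls at
#'   high depth are low-confidence, so most are removed by quality
#'   filters downstream).
#' @return an object of class `observation_model`.
#' @export
observation_model <- function(mean_depth = 26, missing_rate = 0.02,
                              genotype_error_rate = 1e-6,
                              het_artifact_rate = 1e-4,
                              quality_mean = 38, quality_sd = 4,
                              error_quality_mean = 18) {
  stopifnot(mean_depth > 0,
            missing_rate >= 0, missing_rate <= 1,
            genotype_error_rate >= 0, genotype_error_rate <= 1,
            het_artifact_rate >= 0, het_artifact_rate <= 1,
            quality_sd >= 0)
  structure(list(mean_depth = mean_depth, missing_rate = missing_rate,
                 genotype_error_rate = genotype_error_rate,
                 het_artifact_rate = het_artifact_rate,
                 quality_mean = quality_mean, quality_sd = quality_sd,
                 error_quality_mean = error_quality_mean),
            class = "observation_model")
}

# run expr under a temporary RNG state seeded with `seed` (NULL = use the
# current stream untouched)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.finite(seed)) stop("seed must be a finite integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
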
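# De novo mutation calling with strict haploid-cohort filters, callable-site
# accounting, exact Poisson rate estimation and the mutation spectrum.

#' Call de novo mutations in a drone colony
#'
#' A candidate is a site where exactly one drone of the colony carries an
#' allele absent from every other drone. The call must pass, in the
#' carrier: read depth >= `min_depth`, call quality >= `min_quality`, and
#' support on both strands (skipped with a warning when the matrix carries
#' no strand information). Screened marker sites are skipped when a
#' `markers` set is supplied: markers are queen-heterozygous (each allele
#' observed at least twice), so a drone-unique allele there is a
#' third-allele artifact; the skip also removes the bulk of sites cheaply.
#'
#' A singleton allele can also arise at a genuine queen-heterozygous site
#' when, by segregation chance, one drone inherits a haplotype that all
#' its brothers missed locally (probability `2^-(n-1)` per haplotype
#' segment - rare at 22 drones, common enough to matter at 10). When
#' haplotype `blocks` are supplied, a candidate whose allele split is
#' concordant with the drones' local haplotypes (every other called drone
#' carries the opposite haplotype to the carrier) is rejected as
#' queen-heterozygous; a true de novo allele instead appears on a
#' haplotype that other, reference-carrying drones also inherit. This
#' phase-concordance rule cannot operate inside long marker-free
#' stretches (a chance sole-haplotype segment strips every marker in it,
#' by construction), but such segments betray themselves by producing
#' runs of same-drone candidates, whereas genuine de novo mutations are
#' of order 1 per drone per genome: candidates from the same drone within
#' `cluster_window` of each other are therefore rejected as haplotype
#' artifacts. These two rules, plus a deterministic flag for candidates
#' within `gap_flank` of an assembly gap, replace the study's manual
#' review step.
#'
#' @param gt a [genotype_matrix()].
#' @param colony colony to scan.
#' @param markers optional [screen_markers()] result used for the
#'   queen-heterozygous exclusion.
#' @param min_depth,min_quality carrier thresholds (defaults 5 and 30).
#' @param require_strand require both-strand support when available.
#' @param gaps optional gap intervals for the proximity flag.
#' @param gap_flank flag distance in bp (default 1000).
#' @param blocks optional [assign_blocks()] output for the colony's
#'   drones, enabling the phase-concordance filter.
#' @param cluster_window same-drone candidates closer than this are
#'   rejected as haplotype-segment artifacts (default 10 kb; 0 disables).
#' @return data.frame of calls: `drone`, `chrom`, `pos`, `ref`, `alt`,
#'   `kind` (`SNM`/`indel`), `class`, filter-trail columns (`pass_depth`,
#'   `pass_quality`, `pass_strand`, `near_gap`). Only candidates passing
#'   all filters are returned; attribute `n_candidates` counts the
#'   drone-unique sites seen before filtering.
#' @export
call_denovo <- function(gt, colony, markers = NULL, min_depth = 5,
                        min_quality = 30, require_strand = TRUE,
                        gaps = NULL, gap_flank = 1000, blocks = NULL,
                        cluster_window = 10000) {
  stopifnot(inherits(gt, "genotype_matrix"))
  j <- colony_columns(gt, colony)
  if (length(j) < 2L) stop("colony must contain at least two drones")
  calls <- gt$calls[, j, drop = FALSE]
  ids <- gt$drones$id[j]
  # local-haplotype lookup for the phase-concordance filter
  hap_lookup <- NULL
  if (!is.null(blocks) && nrow(blocks)) {
    hap_lookup <- lapply(split(blocks, paste(blocks$drone, blocks$chrom)),
                         function(b) {
                           b <- b[order(b$start), ]
                           list(start = b$start, end = b$end, hap = b$hap)
                         })
  }
  # haplotype at pos: containing block if any; across a marker-free gap,
  # the flanking blocks' haplotype when they agree (the drone's run simply
  # lacks markers there); a single flank extrapolates at chromosome ends
  hap_of <- function(drone, chrom, pos) {
    v <- hap_lookup[[paste(drone, chrom)]]
    if (is.null(v)) return(NA_integer_)
    i <- findInterval(pos, v$start)
    if (i >= 1L && pos <= v$end[i]) return(v$hap[i])
    left <- if (i >= 1L) v$hap[i] else NA_integer_
    right <- if (i < length(v$start)) v$hap[i + 1L] else NA_integer_
    if (is.na(left)) return(right)
    if (is.na(right) || left == right) return(left)
    NA_integer_
  }
  skip <- rep(FALSE, nrow(calls))
  if (!is.null(markers) && nrow(markers))
    skip[markers$site] <- TRUE
  out <- list()
  n_candidates <- 0L
  strand_ok <- !is.null(gt$strand_fwd) && !is.null(gt$strand_rev)
  if (require_strand && !strand_ok)
    warning("no strand information in matrix; strand criterion skipped")
  # pre-filter: only sites with a singleton base allele, or any non-base
  # allele string (indel), can yield a drone-unique candidate
  n <- nrow(calls)
  codes <- matrix(match(calls, BASES), n, length(j))
  cnt <- matrix(vapply(1:4, function(k)
    rowSums(codes == k, na.rm = TRUE), numeric(n)), n, 4L)
  odd_any <- rowSums(!is.na(calls) & calls != "H" & is.na(codes)) > 0L
  scan <- which(!skip & (rowSums(cnt == 1L) > 0L | odd_any))
  for (i in scan) {
    r <- calls[i, ]
    ok <- !is.na(r) & r != "H"
    if (sum(ok) < 2L) next
    tab <- table(r[ok])
    uniq <- names(tab)[tab == 1L]
    for (a in uniq) {
      carrier <- which(ok & r == a)
      if (a == gt$sites$ref[i]) next    # reference allele cannot be de novo
      n_candidates <- n_candidates + 1L
      if (!is.null(hap_lookup)) {
        ch <- gt$sites$chrom[i]; p <- gt$sites$pos[i]
        h_s <- hap_of(ids[carrier], ch, p)
        if (!is.na(h_s)) {
          oth <- setdiff(which(ok), carrier)
          oh <- vapply(oth, function(w) hap_of(ids[w], ch, p),
                       NA_integer_)
          known <- !is.na(oh)
          # all brothers on the opposite haplotype: the split is what
          # queen heterozygosity would produce
          if (any(known) && all(oh[known] == 1L - h_s)) next
        }
      }
      jd <- j[carrier]
      pass_depth <- is.null(gt$depth) || gt$depth[i, jd] >= min_depth
      pass_quality <- is.null(gt$quality) || gt$quality[i, jd] >= min_quality
      pass_strand <- !require_strand || !strand_ok ||
        (gt$strand_fwd[i, jd] && gt$strand_rev[i, jd])
      near_gap <- FALSE
      if (!is.null(gaps) && nrow(gaps)) {
        g <- gaps[gaps$chrom == gt$sites$chrom[i], , drop = FALSE]
        near_gap <- any(g$start - gap_flank < gt$sites$pos[i] + 1 &
                        g$end + gap_flank > gt$sites$pos[i])
      }
      if (pass_depth && pass_quality && pass_strand) {
        kind <- if (grepl("^(ins|del)", a)) "indel" else "SNM"
        out[[length(out) + 1L]] <- data.frame(
          drone = gt$drones$id[jd], chrom = gt$sites$chrom[i],
          pos = gt$sites$pos[i], ref = gt$sites$ref[i], alt = a,
          kind = kind,
          class = if (kind == "SNM") snm_class(gt$sites$ref[i], a)
                  else NA_character_,
          pass_depth = pass_depth, pass_quality = pass_quality,
          pass_strand = pass_strand, near_gap = near_gap)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(drone = character(0), chrom = character(0), pos = numeric(0),
               ref = character(0), alt = character(0), kind = character(0),
               class = character(0), pass_depth = logical(0),
               pass_quality = logical(0), pass_strand = logical(0),
               near_gap = logical(0))
  rownames(res) <- NULL
  n_clustered <- 0L
  if (cluster_window > 0 && nrow(res) > 1L) {
    drop <- rep(FALSE, nrow(res))
    for (idx in split(seq_len(nrow(res)),
                      paste(res$drone, res$chrom))) {
      if (length(idx) < 2L) next
      p <- res$pos[idx]
      o <- order(p)
      close_pair <- diff(p[o]) <= cluster_window
      hit <- unique(c(which(close_pair), which(close_pair) + 1L))
      drop[idx[o][hit]] <- TRUE
    }
    n_clustered <- sum(drop)
    res <- res[!drop, , drop = FALSE]
    rownames(res) <- NULL
  }
  attr(res, "n_candidates") <- n_candidates
  attr(res, "n_clustered") <- n_clustered
  res
}

#' Classify a single-nucleotide change
#'
#' `GC>AT` for G:C->A:T transitions, `AT>GC` for A:T->G:C transitions,
#' `transversion` otherwise.
#'
#' @param ref,alt single bases.
#' @return character vector of classes.
#' @export
snm_class <- function(ref, alt) {
  ts <- unname(TRANSITION[ref] == alt)
  ifelse(ts & ref %in% c("G", "C"), "GC>AT",
         ifelse(ts, "AT>GC", "transversion"))
}

#' Callable-site counts from depth and quality matrices
#'
#' A site is callable in a drone when depth >= `min_depth`, mapping
#' quality >= `min_mapq` and the reference base is unambiguous. The
#' drone-summed total is the denominator of the mutation rate.
#'
#' @param depth sites x drones depth matrix.
#' @param mapq sites x drones mapping-quality matrix, or `NULL`.
#' @param reference per-site reference bases, or `NULL`; `N` marks
#'   ambiguous.
#' @param min_depth,min_mapq thresholds (defaults 5 and 20).
#' @return list (`per_drone` counts, `total`, possibly `mask`).
#' @export
callable_sites <- function(depth, mapq = NULL, reference = NULL,
                           min_depth = 5, min_mapq = 20) {
  ok <- depth >= min_depth
  if (!is.null(mapq)) {
    if (!all(dim(mapq) == dim(depth))) stop("mapq dimensions must match")
    ok <- ok & mapq >= min_mapq
  }
  if (!is.null(reference)) {
    if (length(reference) != nrow(depth))
      stop("reference length must match sites")
    ok <- ok & reference != "N"
  }
  per_drone <- colSums(ok)
  list(per_drone = per_drone, total = sum(per_drone), mask = ok)
}

#' Exact Poisson confidence interval for a count
#'
#' The Garwood interval from chi-square quantiles:
#' `low = qchisq(alpha/2, 2k) / 2` (0 when `k = 0`) and
#' `high = qchisq(1 - alpha/2, 2k + 2) / 2` - the interval
#' `stats::poisson.test()` reports. For 23 events the 95% limits are
#' 14.6 and 34.5.
#'
#' @param count observed count (non-negative integer).
#' @param conf confidence level in (0, 1).
#' @return numeric `c(low, high)`.
#' @export
exact_poisson_ci <- function(count, conf = 0.95) {
  if (!is.finite(conf) || conf <= 0 || conf >= 1)
    stop("conf must be in (0, 1)")
  if (count < 0 || count != round(count))
    stop("count must be a non-negative integer")
  alpha <- 1 - conf
  low <- if (count == 0) 0 else stats::qchisq(alpha / 2, 2 * count) / 2
  high <- stats::qchisq(1 - alpha / 2, 2 * count + 2) / 2
  c(low = low, high = high)
}

#' Mutation-rate estimate with exact Poisson interval
#'
#' Rate per bp per haploid genome per generation: the mutation count
#' divided by the drone-summed callable sites, with the Garwood interval
#' scaled by the same denominator. `per_genome` scales the rate back to a
#' whole genome of `genome_bp` (defaulting to the 274 Mb bumblebee
#' genome), giving the expected new mutations per gamete.
#'
#' @param count observed mutations.
#' @param total_callable drone-summed callable sites (> 0).
#' @param conf confidence level.
#' @param genome_bp genome size for the per-genome rate.
#' @return an object of class `rate_estimate`: `count`, `total_callable`,
#'   `rate`, `ci` (rate scale), `count_ci`, `per_genome`.
#' @export
estimate_rate <- function(count, total_callable, conf = 0.95,
                          genome_bp = 274e6) {
  if (total_callable <= 0) stop("total_callable must be positive")
  if (count < 0) stop("count must be non-negative")
  count_ci <- exact_poisson_ci(count, conf)
  structure(list(count = count, total_callable = total_callable,
                 rate = count / total_callable,
                 ci = count_ci / total_callable,
                 count_ci = count_ci,
                 per_genome = count / total_callable * genome_bp,
                 conf = conf),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("rate: %.3g per bp per generation (%d / %.4g callable)\n",
              x$rate, x$count, x$total_callable))
  cat(sprintf("  %d%% CI: %.3g - %.3g  (count limits %.1f - %.1f)\n",
              round(100 * x$conf), x$ci[1], x$ci[2],
              x$count_ci[1], x$count_ci[2]))
  cat(sprintf("  per %.0f Mb genome: %.2f\n",
              x$per_genome / x$rate / 1e6, x$per_genome))
  invisible(x)
}

#' Mutation spectrum summary with GC-content correction
#'
#' Tallies calls by class and reports the base-content-corrected direction
#' pair: G:C->A:T count divided by the genomic GC fraction against
#' A:T->G:C count divided by the AT fraction. With 20 and 3 transitions at
#' 37.5% GC this is the 53.3 : 4.8 ratio.
#'
#' @param calls [call_denovo()] output (SNMs are used).
#' @param gc_fraction genomic GC fraction in (0, 1).
#' @return list with `counts` (by class), `transitions`,
#'   `transversions`, and `gc_normalized` (`GC>AT`, `AT>GC`).
#' @export
spectrum_summary <- function(calls, gc_fraction) {
  if (!is.finite(gc_fraction) || gc_fraction <= 0 || gc_fraction >= 1)
    stop("gc_fraction must be in (0, 1)")
  snm <- calls[calls$kind == "SNM", , drop = FALSE]
  classes <- c("GC>AT", "AT>GC", "transversion")
  counts <- stats::setNames(vapply(classes, function(cl)
    sum(snm$class == cl), 0L), classes)
  list(counts = counts,
       transitions = counts[["GC>AT"]] + counts[["AT>GC"]],
       transversions = counts[["transversion"]],
       gc_normalized = c("GC>AT" = counts[["GC>AT"]] / gc_fraction,
                         "AT>GC" = counts[["AT>GC"]] / (1 - gc_fraction)))
}

#' Genotype-level spike-in recovery
#'
#' Spikes `n_spikes` drone-unique alleles at uniformly random non-gap
#' genome positions, re-runs [call_denovo()] on the augmented matrix, and
#' reports the fraction of spikes that were callable and the fraction of
#' callable spikes detected. Spiked cells draw depth and quality from the
#' observation model; a spike is callable when its carrier cell passes the
#' depth threshold.
#'
#' @param gt a [genotype_matrix()] with genome attribute (as produced by
#'   the simulator).
#' @param colony colony to spike.
#' @param n_spikes number of spiked mutations (>= 1).
#' @param model observation model for spiked cells.
#' @param seed optional integer seed.
#' @param min_depth,min_quality thresholds passed to [call_denovo()].
#' @return list (`fraction_callable`, `fraction_detected`, `n_spikes`).
#' @export
spike_in_recovery <- function(gt, colony, n_spikes = 1000,
                              model = observation_model(), seed = NULL,
                              min_depth = 5, min_quality = 30) {
  if (n_spikes < 1) stop("n_spikes must be >= 1")
  spec <- attr(gt, "genome")
  if (is.null(spec)) stop("matrix carries no genome specification")
  j <- colony_columns(gt, colony)
  with_seed(seed, {
    ng <- nongap_lengths(spec)
    ch <- sample(names(ng), n_spikes, replace = TRUE, prob = ng)
    pos <- vapply(ch, function(c1) sample_nongap(spec, c1, 1L), 0)
    ref <- draw_bases(n_spikes, spec$gc_content)
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L), "")
    carrier <- sample(j, n_spikes, replace = TRUE)
    depth <- stats::rpois(n_spikes, model$mean_depth)
    qual <- pmin(pmax(stats::rnorm(n_spikes, model$quality_mean,
                                   model$quality_sd), 0), 60)
    missing <- stats::runif(n_spikes) < model$missing_rate
    callable <- depth >= min_depth & !missing
    # build a small matrix of just the spiked sites and scan it
    key <- paste(ch, pos)
    dup <- duplicated(key) |
      key %in% paste(gt$sites$chrom, gt$sites$pos)
    use <- which(!dup)
    ord <- use[order(match(ch[use], names(spec$lengths)), pos[use])]
    n <- length(ord)
    calls <- matrix(rep(ref[ord], nrow(gt$drones)), n, nrow(gt$drones))
    calls[cbind(seq_len(n), carrier[ord])] <- alt[ord]
    calls[cbind(seq_len(n), carrier[ord])][missing[ord]] <- NA
    dmat <- matrix(stats::rpois(n * nrow(gt$drones), model$mean_depth),
                   n, nrow(gt$drones))
    dmat[cbind(seq_len(n), carrier[ord])] <- depth[ord]
    qmat <- matrix(pmin(pmax(stats::rnorm(n * nrow(gt$drones),
                                          model$quality_mean,
                                          model$quality_sd), 0), 60),
                   n, nrow(gt$drones))
    qmat[cbind(seq_len(n), carrier[ord])] <- qual[ord]
    sub <- genotype_matrix(
      sites = data.frame(chrom = ch[ord], pos = pos[ord], ref = ref[ord]),
      drones = gt$drones, calls = calls, depth = dmat, quality = qmat)
    found <- call_denovo(sub, colony, min_depth = min_depth,
                         min_quality = min_quality, require_strand = FALSE,
                         cluster_window = 0)
    fk <- paste(found$chrom, found$pos)
    n_call <- sum(callable[ord])
    det <- sum(callable[ord] & paste(ch[ord], pos[ord]) %in% fk)
    list(fraction_callable = mean(callable[ord]),
         fraction_detected = if (n_call) det / n_call else NA_real_,
         n_spikes = length(ord))
  })
}
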
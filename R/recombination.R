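# Crossover / noncrossover classification from haplotype blocks, shared
# double-crossover artifact removal, and recombination-rate summaries.

#' Classify recombination events from haplotype blocks
#'
#' Blocks spanning more than `threshold_bp` (default 10 kb) form the
#' crossover backbone; short blocks are conversion tracts. Between two
#' backbone blocks, a haplotype change is one crossover; short blocks
#' flanked by the same haplotype on both sides are noncrossovers (NCO);
#' short blocks sitting inside a backbone haplotype change are
#' crossover-associated conversions (each contributing its tract, plus the
#' one crossover). Chromosome-terminal short blocks are counted as
#' crossovers (a terminal switch has only one flank), as are transitions on
#' chromosomes with no backbone block; both behaviours follow from
#' `terminal_as_co`.
#'
#' @param blocks [assign_blocks()] output (one or more drones).
#' @param threshold_bp span threshold separating NCO tracts from
#'   crossovers.
#' @param terminal_as_co count haplotype switches at chromosome-terminal
#'   short blocks as crossovers (default `TRUE`).
#' @return data.frame of events: `drone`, `chrom`, `kind` (`CO`, `NCO`,
#'   `CO_conversion`), `start`, `end` (for a CO: last marker of the left
#'   flank, first marker of the right flank; for conversions: the tract),
#'   `n_converted`.
#' @export
classify_events <- function(blocks, threshold_bp = 10000,
                            terminal_as_co = TRUE) {
  need <- c("drone", "chrom", "phase_set", "hap", "start", "end",
            "n_markers")
  stopifnot(all(need %in% names(blocks)))
  ev <- list()
  emit <- function(drone, chrom, kind, start, end, n_converted = 0L) {
    ev[[length(ev) + 1L]] <<- data.frame(drone = drone, chrom = chrom,
                                         kind = kind, start = start,
                                         end = end,
                                         n_converted = n_converted)
  }
  grp <- split(blocks,
               paste(blocks$drone, blocks$chrom, blocks$phase_set))
  for (g in grp) {
    if (nrow(g) < 2L) next
    if (is.unsorted(g$start)) stop("blocks must be ordered by position")
    long <- (g$end - g$start) > threshold_bp
    li <- which(long)
    drone <- g$drone[1L]; chrom <- g$chrom[1L]
    if (!length(li)) {
      if (terminal_as_co)
        for (t in seq_len(nrow(g) - 1L))
          emit(drone, chrom, "CO", g$end[t], g$start[t + 1L])
      next
    }
    # terminal short runs
    if (terminal_as_co) {
      if (li[1L] > 1L)
        for (t in seq_len(li[1L] - 1L))
          emit(drone, chrom, "CO", g$end[t], g$start[t + 1L])
      if (li[length(li)] < nrow(g))
        for (t in seq.int(li[length(li)], nrow(g) - 1L))
          emit(drone, chrom, "CO", g$end[t], g$start[t + 1L])
    }
    # between consecutive backbone blocks
    if (length(li) > 1L) for (w in seq_len(length(li) - 1L)) {
      i <- li[w]; k <- li[w + 1L]
      shorts <- if (k - i > 1L) seq.int(i + 1L, k - 1L) else integer(0)
      if (!length(shorts)) {
        emit(drone, chrom, "CO", g$end[i], g$start[k])
      } else if (g$hap[i] == g$hap[k]) {
        for (s in shorts)
          emit(drone, chrom, "NCO", g$start[s], g$end[s], g$n_markers[s])
      } else {
        emit(drone, chrom, "CO", g$end[i], g$start[k])
        for (s in shorts)
          emit(drone, chrom, "CO_conversion", g$start[s], g$end[s],
               g$n_markers[s])
      }
    }
  }
  out <- if (length(ev)) do.call(rbind, ev) else
    data.frame(drone = character(0), chrom = character(0),
               kind = character(0), start = numeric(0), end = numeric(0),
               n_converted = integer(0))
  out <- out[order(out$drone, out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Group shared crossovers and flag double-crossover artifacts
#'
#' Crossovers from different drones with the exact same flanking-marker
#' interval form a shared group (on a finished assembly these are rare; on
#' a gapped one they concentrate at reference gaps). A shared crossover
#' that sits next to another shared crossover on the same chromosome in the
#' same drone - pair separation within `double_co_window` - is the
#' signature of a translocation or mis-assembly: such events are category
#' 2 and excluded; other shared events are category 1 and kept.
#'
#' @param events [classify_events()] output.
#' @param gaps optional data.frame (`chrom`, `start`, `end`) of assembly
#'   gaps; overlap is annotated.
#' @param double_co_window max separation (bp, midpoint to midpoint) for
#'   the category-2 double-crossover rule (default 700 kb).
#' @return `events` with `shared_group`, `category`, `excluded`,
#'   `gap_overlap` columns added.
#' @export
group_shared_cos <- function(events, gaps = NULL,
                             double_co_window = 700000) {
  events$shared_group <- rep(NA_integer_, nrow(events))
  events$category <- rep(NA_integer_, nrow(events))
  events$excluded <- rep(FALSE, nrow(events))
  events$gap_overlap <- rep(FALSE, nrow(events))
  is_co <- events$kind == "CO"
  if (any(is_co)) {
    key <- paste(events$chrom, events$start, events$end)
    key[!is_co] <- NA
    tab <- tapply(events$drone[is_co], key[is_co],
                  function(d) length(unique(d)))
    shared_keys <- names(tab)[tab >= 2L]
    shared <- is_co & key %in% shared_keys
    events$shared_group[shared] <- match(key[shared], shared_keys)
    # category 2: adjacent shared COs in the same drone and chromosome
    sh <- which(shared)
    if (length(sh)) {
      mid <- (events$start + events$end) / 2
      for (dc in split(sh, paste(events$drone[sh], events$chrom[sh]))) {
        events$category[dc] <- 1L
        if (length(dc) >= 2L) {
          m <- sort(mid[dc])
          close_pair <- diff(m) <= double_co_window
          if (any(close_pair)) {
            o <- dc[order(mid[dc])]
            hit <- unique(c(o[which(close_pair)], o[which(close_pair) + 1L]))
            events$category[hit] <- 2L
            events$excluded[hit] <- TRUE
          }
        }
      }
    }
  }
  if (!is.null(gaps) && nrow(gaps)) {
    for (i in seq_len(nrow(events))) {
      g <- gaps[gaps$chrom == events$chrom[i], , drop = FALSE]
      events$gap_overlap[i] <- any(g$start < events$end[i] &
                                   g$end > events$start[i])
    }
  }
  events
}

#' Genome-wide crossover rate
#'
#' `cM/Mb = 100 x (kept crossovers per drone) / genome Mb`; the rate with
#' excluded (category-2) events restored is reported alongside. With the
#' study's counts, 606 crossovers over 32 drones on 216.85 Mb give
#' 8.73 cM/Mb (10.6 cM/Mb with the 128 excluded events restored).
#'
#' @param events [group_shared_cos()] (or [classify_events()]) output.
#' @param genome_mb assembled genome length in Mb.
#' @param n_drones number of drones the events came from.
#' @return an object of class `rate_summary`.
#' @export
crossover_rate <- function(events, genome_mb, n_drones) {
  if (n_drones < 1L) stop("need at least one drone")
  if (genome_mb <= 0) stop("genome_mb must be positive")
  excluded <- if ("excluded" %in% names(events)) events$excluded else FALSE
  is_co <- events$kind == "CO"
  kept <- sum(is_co & !excluded)
  raw <- sum(is_co)
  per_chrom <- if (kept) table(events$chrom[is_co & !excluded]) else
    table(character(0))
  structure(list(total_cos = raw, kept_cos = kept,
                 excluded_cos = raw - kept,
                 cos_per_drone = kept / n_drones,
                 cM_per_Mb = 100 * (kept / n_drones) / genome_mb,
                 cM_per_Mb_raw = 100 * (raw / n_drones) / genome_mb,
                 cos_per_chrom_per_drone = as.numeric(per_chrom) / n_drones,
                 n_drones = n_drones, genome_mb = genome_mb),
            class = "rate_summary")
}

#' @export
print.rate_summary <- function(x, ...) {
  cat(sprintf(
    "crossover rate: %.2f cM/Mb (%d COs kept of %d, %d drones, %.2f Mb)\n",
    x$cM_per_Mb, x$kept_cos, x$total_cos, x$n_drones, x$genome_mb))
  if (x$excluded_cos > 0)
    cat(sprintf("  with excluded events restored: %.2f cM/Mb\n",
                x$cM_per_Mb_raw))
  invisible(x)
}

#' Per-window crossover rates and hotspot calls
#'
#' Crossovers are assigned to the nonoverlapping window containing their
#' breakpoint-interval midpoint; a window is called a hotspot when its rate
#' reaches `hotspot_multiple` times the genome-wide mean.
#'
#' @param events [group_shared_cos()] output (kept COs are used).
#' @param lengths named vector of chromosome lengths (bp).
#' @param n_drones number of drones.
#' @param window_bp window size (default 500 kb).
#' @param hotspot_multiple hotspot threshold as a multiple of the mean.
#' @return data.frame (`chrom`, `start`, `end`, `n_co`, `cM_per_Mb`,
#'   `hotspot`).
#' @export
window_rates <- function(events, lengths, n_drones, window_bp = 500000,
                         hotspot_multiple = 5) {
  if (window_bp <= 0) stop("window_bp must be positive")
  excluded <- if ("excluded" %in% names(events)) events$excluded else FALSE
  co <- events[events$kind == "CO" & !excluded, , drop = FALSE]
  win <- do.call(rbind, lapply(names(lengths), function(ch) {
    s <- seq(0, lengths[[ch]] - 1, by = window_bp)
    data.frame(chrom = ch, start = s, end = pmin(s + window_bp,
                                                 lengths[[ch]]))
  }))
  win$n_co <- 0L
  if (nrow(co)) {
    mid <- (co$start + co$end) / 2
    idx <- match(paste(co$chrom, floor(mid / window_bp)),
                 paste(win$chrom, win$start / window_bp))
    cnt <- table(idx)
    win$n_co[as.integer(names(cnt))] <- as.integer(cnt)
  }
  win$cM_per_Mb <- 100 * win$n_co / (n_drones * (win$end - win$start) / 1e6)
  mean_rate <- 100 * (sum(win$n_co) / n_drones) / (sum(lengths) / 1e6)
  win$hotspot <- win$cM_per_Mb >= hotspot_multiple * mean_rate &
    win$n_co > 0L
  win
}

#' Genetic map length under marker downsampling
#'
#' Repeatedly subsamples `m` markers, re-detects crossovers with the coarse
#' panel only, and reports the mean and SD of the genetic length
#' (`100 x mean crossovers per drone`) across replicates. Coarser panels
#' miss tightly spaced double crossovers, so downsampled lengths are
#' shorter on average; this reconciles map lengths estimated at different
#' marker densities.
#'
#' @param phase a [phase_queen()] result.
#' @param gt the [genotype_matrix()].
#' @param m markers per replicate (>= 2).
#' @param reps replicates.
#' @param seed optional integer seed.
#' @param threshold_bp crossover span threshold, as in
#'   [classify_events()].
#' @return list with `mean_cM`, `sd_cM`, and the per-replicate `lengths`.
#' @export
genetic_length_downsample <- function(phase, gt, m = 516L, reps = 100L,
                                      seed = NULL, threshold_bp = 10000) {
  stopifnot(inherits(phase, "queen_phase"))
  if (m < 2L) stop("m must be at least 2")
  if (m > nrow(phase)) stop("m exceeds the number of markers")
  if (reps < 1L) stop("reps must be >= 1")
  drones <- gt$drones$id[gt$drones$colony == attr(phase, "colony")]
  with_seed(seed, {
    lengths <- vapply(seq_len(reps), function(r) {
      keep <- sort(sample.int(nrow(phase), m))
      sub <- phase[keep, , drop = FALSE]
      class(sub) <- class(phase)
      attr(sub, "colony") <- attr(phase, "colony")
      blocks <- do.call(rbind, lapply(drones, assign_blocks, phase = sub,
                                      gt = gt))
      ev <- classify_events(blocks, threshold_bp)
      100 * sum(ev$kind == "CO") / length(drones)
    }, 0)
    list(mean_cM = mean(lengths), sd_cM = stats::sd(lengths),
         lengths = lengths)
  })
}
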
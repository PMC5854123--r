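# Randomization and correlation statistics for colony-level inference.

#' Unbiased Monte-Carlo p-value
#'
#' `p = (n_extreme + 1) / (reps + 1)`, the unbiased estimator of the type I
#' error rate for randomization tests: 73 extreme results in 10,000
#' randomizations give p = 0.0074.
#'
#' @param n_extreme randomized statistics as extreme or more extreme than
#'   observed.
#' @param reps number of randomizations.
#' @return p-value in (0, 1].
#' @export
mc_pvalue <- function(n_extreme, reps) {
  if (n_extreme < 0 || reps < 0) stop("counts must be non-negative")
  if (n_extreme > reps) stop("n_extreme cannot exceed reps")
  (n_extreme + 1) / (reps + 1)
}

mc_result <- function(observed, null_stats, n_extreme = NULL) {
  reps <- length(null_stats)
  if (is.null(n_extreme)) n_extreme <- sum(null_stats >= observed)
  structure(list(observed = observed, null = null_stats,
                 n_extreme = n_extreme, reps = reps,
                 p = mc_pvalue(n_extreme, reps)),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("Monte-Carlo test: observed %.4g, %d / %d as extreme, p = %.4g\n",
              x$observed, x$n_extreme, x$reps, x$p))
  invisible(x)
}

#' Merge-rank binned correlation
#'
#' Ranks genomic windows by `x`, merges ranking-neighbours into `n_bins`
#' near-equal bins (sizes differ by at most one window), and correlates the
#' per-bin means of `x` and `y` (Pearson r with the regression p-value).
#' The raw per-window Spearman correlation is reported alongside: binning
#' exposes gross trends, but a p-value on bin means is not comparable to
#' one on raw windows.
#'
#' @param x,y numeric vectors per window (pairs with missing values are
#'   dropped).
#' @param n_bins number of merged bins; values outside 21-25 warn but are
#'   honoured.
#' @return list (`r`, `p`, `bins` data.frame of bin means, `raw_spearman`,
#'   `raw_p`, `n_windows`).
#' @export
merge_rank_correlate <- function(x, y, n_bins = 23L) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (n_bins < 21L || n_bins > 25L)
    warning("n_bins outside the conventional 21-25 range")
  if (length(x) < n_bins) stop("fewer windows than bins")
  o <- order(x)
  bin <- rep(seq_len(n_bins), times = tabulate_sizes(length(x), n_bins))
  mx <- tapply(x[o], bin, mean)
  my <- tapply(y[o], bin, mean)
  fit <- stats::lm(my ~ mx)
  r <- stats::cor(mx, my)
  # degenerate perfect fits (e.g. y identical to x) carry a meaningless p
  p <- suppressWarnings(stats::summary.lm(fit)$coefficients[2L, 4L])
  raw <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  list(r = r, p = p,
       bins = data.frame(x = as.numeric(mx), y = as.numeric(my)),
       raw_spearman = unname(raw$estimate), raw_p = raw$p.value,
       n_windows = length(x))
}

# near-equal bin sizes, differing by at most 1
tabulate_sizes <- function(n, k) {
  base <- as.integer(n %/% k)
  extra <- as.integer(n %% k)
  c(rep(base + 1L, extra), rep(base, k - extra))
}

#' Spearman partial correlation
#'
#' Rank-based partial correlation of `x` and `y` controlling for the
#' columns of `z`, computed by the standard recursion on the Spearman
#' correlation matrix (equivalently, correlation of rank residuals).
#'
#' @param x,y numeric vectors.
#' @param z numeric vector, matrix or data.frame of controls.
#' @return the partial correlation coefficient.
#' @export
partial_spearman <- function(x, y, z) {
  z <- as.matrix(z)
  if (length(x) != length(y) || nrow(z) != length(x))
    stop("inputs must have equal length")
  if (length(x) < 4L) stop("need at least 4 observations")
  dat <- cbind(x, y, z)
  if (any(apply(dat, 2L, stats::sd) == 0))
    stop("constant input column: partial correlation undefined")
  rk <- apply(dat, 2L, rank)
  cm <- stats::cor(rk)
  pm <- tryCatch(solve(cm), error = function(e)
    stop("degenerate control set: partial correlation undefined"))
  -pm[1L, 2L] / sqrt(pm[1L, 1L] * pm[2L, 2L])
}

#' Poisson-dispersion Monte-Carlo test
#'
#' Compares the unbiased (n-1) sample variance of per-drone mutation
#' counts with its distribution under random allocation of the same total
#' to the drones (equal-probability multinomial by default; optional
#' per-drone weights, e.g. callable-site shares). The p-value is the
#' Monte-Carlo fraction of replicates with variance as great or greater;
#' failing to reject is the hallmark of a Poisson process
#' (variance = mean).
#'
#' @param counts per-drone mutation counts.
#' @param reps randomizations.
#' @param seed optional integer seed.
#' @param weights optional per-drone allocation probabilities.
#' @return an `mc_result` with the observed variance as statistic.
#' @export
dispersion_test <- function(counts, reps = 10000L, seed = NULL,
                            weights = NULL) {
  if (length(counts) < 2L) stop("need at least two drones")
  n <- length(counts); total <- sum(counts)
  if (is.null(weights)) weights <- rep(1 / n, n)
  with_seed(seed, {
    observed <- stats::var(counts)
    sims <- stats::rmultinom(reps, total, weights)
    null_var <- apply(sims, 2L, stats::var)
    mc_result(observed, null_var)
  })
}

#' Between-colony mutation-count heterogeneity
#'
#' Expected counts proportional to group shares (drone counts by default:
#' 23 mutations over colonies of 22 and 10 drones give expectations 15.81
#' and 7.19), with the Pearson chi-square statistic on
#' `length(counts) - 1` degrees of freedom, no continuity correction.
#'
#' @param counts observed mutation counts per group.
#' @param group_sizes group sizes (drone counts), or any share weights
#'   such as callable-site totals.
#' @return list (`observed`, `expected`, `statistic`, `df`, `p`).
#' @export
colony_heterogeneity <- function(counts, group_sizes) {
  if (length(counts) < 2L || length(counts) != length(group_sizes))
    stop("need counts and sizes for at least two groups")
  total <- sum(counts)
  if (total == 0) stop("zero total count: test undefined")
  expected <- total * group_sizes / sum(group_sizes)
  stat <- sum((counts - expected)^2 / expected)
  df <- length(counts) - 1L
  list(observed = counts, expected = expected, statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Mutation-breakpoint proximity randomization
#'
#' Observed statistic: the number of mutations lying within `window_bp` of
#' a recombination breakpoint of the same drone's events (the
#' mutation-meiosis coupling reading; set `pooled = TRUE` to compare each
#' mutation against all drones' breakpoints). The null places the same
#' number of pseudo-mutation sites uniformly over the genome with drone
#' labels preserved and counts proximal sites per replicate.
#'
#' @param calls mutation calls (`drone`, `chrom`, `pos`).
#' @param events recombination events (`drone`, `chrom`, `start`, `end`);
#'   breakpoint intervals of crossovers are used.
#' @param lengths named chromosome lengths (bp).
#' @param window_bp proximity window (default 1000).
#' @param reps randomizations (>= 100).
#' @param seed optional integer seed.
#' @param pooled ignore drone identity when matching breakpoints.
#' @return an `mc_result`.
#' @export
proximity_test <- function(calls, events, lengths, window_bp = 1000,
                           reps = 10000L, seed = NULL, pooled = FALSE) {
  if (reps < 100L) stop("reps must be >= 100")
  ev <- events[events$kind == "CO" &
               !(if ("excluded" %in% names(events)) events$excluded
                 else FALSE), , drop = FALSE]
  if (!nrow(ev)) stop("no crossover events: test undefined")
  n_mut <- nrow(calls)
  if (!n_mut) stop("no mutations supplied")
  # precompute merged padded breakpoint intervals per (drone, chrom)
  grp_key <- if (pooled) ev$chrom else paste(ev$drone, ev$chrom)
  ivs <- lapply(split(seq_len(nrow(ev)), grp_key), function(idx) {
    m <- merge_intervals(data.frame(
      chrom = "x",
      start = pmax(ev$start[idx] - window_bp, 0),
      end = ev$end[idx] + window_bp + 1))
    list(start = m$start, end = m$end)
  })
  lookup_key <- function(drone, chrom)
    if (pooled) chrom else paste(drone, chrom)
  proximal <- function(drone, chrom, pos) {
    v <- ivs[[lookup_key(drone, chrom)]]
    if (is.null(v)) return(FALSE)
    i <- findInterval(pos, v$start)
    i > 0L && pos < v$end[i]
  }
  count_proximal <- function(chrom, pos, drone) {
    sum(mapply(proximal, drone, chrom, pos))
  }
  with_seed(seed, {
    observed <- count_proximal(calls$chrom, calls$pos, calls$drone)
    null_stats <- vapply(seq_len(reps), function(r) {
      ch <- sample(names(lengths), n_mut, replace = TRUE, prob = lengths)
      pos <- floor(stats::runif(n_mut) * lengths[ch])
      count_proximal(ch, pos, calls$drone)
    }, 0)
    mc_result(observed, null_stats)
  })
}

#' Conversion-direction GC-bias test
#'
#' Among converted sites polymorphic between an A/T and a G/C allele,
#' counts conversions resolving toward G/C and tests the split against a
#' fair per-site coin by randomization (one-sided toward G/C, as extreme
#' or more extreme); the matching one-sided exact binomial p-value is
#' reported alongside.
#'
#' @param conversions data.frame with `from` and `to` allele columns
#'   (converted sites).
#' @param reps randomizations.
#' @param seed optional integer seed.
#' @return an `mc_result` with extra fields `n_informative`, `n_to_gc`,
#'   `binomial_p`, or `NULL` (with a message) when no site is informative.
#' @export
conversion_bias_test <- function(conversions, reps = 10000L, seed = NULL) {
  strong_from <- conversions$from %in% c("G", "C")
  strong_to <- conversions$to %in% c("G", "C")
  informative <- strong_from != strong_to
  n <- sum(informative)
  if (n == 0L) {
    message("no A/T-G/C polymorphic converted sites: test declined")
    return(NULL)
  }
  k <- sum(informative & strong_to)
  with_seed(seed, {
    null_stats <- stats::rbinom(reps, n, 0.5)
    res <- mc_result(k, null_stats)
    res$n_informative <- n
    res$n_to_gc <- k
    res$binomial_p <- stats::binom.test(k, n, 0.5,
                                        alternative = "greater")$p.value
    res
  })
}

#' Between-species rate-difference permutation test
#'
#' Observed statistic: absolute difference of mean per-individual rates.
#' Null: the pooled individuals are randomly re-partitioned into the
#' original group sizes; p is the Monte-Carlo fraction of replicates with
#' a difference as great or greater.
#'
#' @param rates_a,rates_b per-individual rates for the two groups.
#' @param reps randomizations.
#' @param seed optional integer seed.
#' @return an `mc_result`.
#' @export
rate_difference_permutation <- function(rates_a, rates_b, reps = 10000L,
                                        seed = NULL) {
  if (!length(rates_a) || !length(rates_b))
    stop("both groups must be non-empty")
  pooled <- c(rates_a, rates_b)
  na <- length(rates_a)
  with_seed(seed, {
    observed <- abs(mean(rates_a) - mean(rates_b))
    null_stats <- vapply(seq_len(reps), function(r) {
      idx <- sample.int(length(pooled), na)
      abs(mean(pooled[idx]) - mean(pooled[-idx]))
    }, 0)
    mc_result(observed, null_stats)
  })
}
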
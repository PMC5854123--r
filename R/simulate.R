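# Colony simulator: queen -> recombinant gametes -> mutations -> noisy
# genotype observations, with ground truth carried alongside for recovery
# tests. Coordinates are 0-based half-open throughout.

nongap_lengths <- function(spec) {
  len <- spec$lengths
  if (!is.null(spec$gaps)) {
    gl <- tapply(spec$gaps$end - spec$gaps$start, spec$gaps$chrom, sum)
    len[names(gl)] <- len[names(gl)] - as.numeric(gl)
  }
  len
}

# sample n distinct non-gap positions on one chromosome (0-based)
sample_nongap <- function(spec, chrom, n) {
  if (n == 0L) return(numeric(0))
  L <- spec$lengths[[chrom]]
  gaps <- spec$gaps
  gaps <- if (is.null(gaps)) NULL else gaps[gaps$chrom == chrom, , drop = FALSE]
  if (is.null(gaps) || nrow(gaps) == 0L)
    return(sort(sample.int(L, n) - 1))
  lens <- gaps$end - gaps$start
  allowed <- L - sum(lens)
  if (n > allowed) stop("more positions requested than non-gap bases")
  u <- sample.int(allowed, n) - 1            # gapless coordinates
  # gap starts mapped into gapless coordinates; shift past gaps
  cs <- gaps$start - c(0, cumsum(lens))[seq_len(nrow(gaps))]
  shift <- c(0, cumsum(lens))
  sort(u + shift[findInterval(u, cs) + 1L])
}

BASES <- c("A", "C", "G", "T")
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

draw_bases <- function(n, gc) {
  sample(BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Simulate a heterozygous diploid queen
#'
#' Places heterozygous sites as a Bernoulli process per non-gap bp at the
#' given rate (default 0.26%, the colony diversity observed for bumblebee),
#' draws reference bases from the genome GC content, and assigns the
#' reference allele to one of the two haplotypes at random.
#'
#' @param spec a [genome_spec()].
#' @param heterozygosity per-bp heterozygosity in `[0, 0.05]`.
#' @param seed optional integer seed.
#' @param keep_sequence if `TRUE`, also generate the full reference sequence
#'   per chromosome (one string each, gaps as N). Intended for small genomes
#'   and FASTA export; the analysis itself is genotype-level.
#' @return an object of class `sim_queen`: the spec, a marker truth table
#'   (`chrom`, `pos`, `ref`, `hap0`, `hap1`) and optionally `sequence`.
#' @export
simulate_queen <- function(spec, heterozygosity = 0.0026, seed = NULL,
                           keep_sequence = FALSE) {
  stopifnot(inherits(spec, "genome_spec"))
  if (!is.numeric(heterozygosity) || !is.finite(heterozygosity) ||
      heterozygosity < 0 || heterozygosity > 0.05)
    stop("heterozygosity must be a finite value in [0, 0.05]")
  with_seed(seed, {
    ng <- nongap_lengths(spec)
    per <- lapply(names(spec$lengths), function(ch) {
      n <- rbinom(1L, ng[[ch]], heterozygosity)
      pos <- sample_nongap(spec, ch, n)
      if (n == 0L)
        return(data.frame(chrom = character(0), pos = numeric(0),
                          ref = character(0), hap0 = character(0),
                          hap1 = character(0)))
      ref <- draw_bases(n, spec$gc_content)
      alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L), "")
      swap <- runif(n) < 0.5
      data.frame(chrom = ch, pos = pos, ref = ref,
                 hap0 = ifelse(swap, alt, ref),
                 hap1 = ifelse(swap, ref, alt))
    })
    markers <- do.call(rbind, per)
    rownames(markers) <- NULL
    sequence <- NULL
    if (keep_sequence) {
      sequence <- vapply(names(spec$lengths), function(ch) {
        L <- spec$lengths[[ch]]
        s <- draw_bases(L, spec$gc_content)
        g <- spec$gaps
        if (!is.null(g)) {
          g <- g[g$chrom == ch, , drop = FALSE]
          for (i in seq_len(nrow(g)))
            s[seq.int(g$start[i] + 1L, g$end[i])] <- "N"
        }
        m <- markers[markers$chrom == ch, ]
        s[m$pos + 1L] <- m$ref
        paste(s, collapse = "")
      }, "")
    }
    structure(list(spec = spec, markers = markers, sequence = sequence,
                   heterozygosity = heterozygosity),
              class = "sim_queen")
  })
}

# haplotype carried at positions `pos` given sorted breakpoints and the
# haplotype at the chromosome start
hap_at <- function(pos, breakpoints, start_hap) {
  (start_hap + findInterval(pos, breakpoints)) %% 2L
}

# resolve converted alleles at marker rows `rows` of the queen's marker
# table toward donor haplotype, with GC bias on A/T vs G/C polymorphic sites
convert_alleles <- function(markers, rows, donor_hap, gc_bias, current) {
  a0 <- markers$hap0[rows]; a1 <- markers$hap1[rows]
  donor <- if (donor_hap == 0L) a0 else a1
  strong <- ifelse(a0 %in% c("G", "C"), a0, a1)
  weak <- ifelse(a0 %in% c("G", "C"), a1, a0)
  informative <- (a0 %in% c("G", "C")) != (a1 %in% c("G", "C"))
  out <- donor
  if (any(informative)) {
    to_gc <- runif(sum(informative)) < gc_bias
    out[informative] <- ifelse(to_gc, strong[informative], weak[informative])
  }
  out
}

#' Simulate one meiosis: a haploid recombinant gamete
#'
#' Crossover counts per chromosome are Poisson with mean
#' `co_rate_cM_per_Mb * length_Mb / 100` (no interference); breakpoint
#' positions are uniform unless `hotspot_map` supplies piecewise-constant
#' intensity weights. Noncrossover tracts are placed independently with
#' geometric tract lengths; converted A/T-G/C sites resolve toward G/C with
#' probability `gc_bias`. A fraction of crossovers carry an adjacent
#' conversion tract donated by the far-side haplotype.
#'
#' @param queen a [simulate_queen()] result.
#' @param params a [meiosis_params()].
#' @param seed optional integer seed.
#' @param hotspot_map optional data.frame (`chrom`, `start`, `end`,
#'   `weight`) of relative crossover intensities.
#' @return an object of class `sim_gamete`: marker alleles aligned to
#'   `queen$markers`, plus a `truth` list with start haplotypes, crossover
#'   breakpoints, and conversion tracts (`kind` = NCO or CO_conversion).
#' @export
simulate_drone <- function(queen, params = meiosis_params(), seed = NULL,
                           hotspot_map = NULL) {
  stopifnot(inherits(queen, "sim_queen"), inherits(params, "meiosis_params"))
  spec <- queen$spec
  with_seed(seed, {
    markers <- queen$markers
    alleles <- character(nrow(markers))
    total_bp <- sum(spec$lengths)
    cos <- list(); tracts <- list(); start_haps <- integer(0)
    for (ch in names(spec$lengths)) {
      L <- spec$lengths[[ch]]
      rows <- which(markers$chrom == ch)
      n_co <- rpois(1L, params$co_rate_cM_per_Mb * (L / 1e6) / 100)
      bp <- sort(draw_breakpoints(n_co, ch, L, hotspot_map))
      start_hap <- sample(0:1, 1L)
      start_haps[[ch]] <- start_hap
      h <- hap_at(markers$pos[rows], bp, start_hap)
      alleles[rows] <- ifelse(h == 0L, markers$hap0[rows], markers$hap1[rows])
      if (n_co > 0)
        cos[[ch]] <- data.frame(chrom = ch, pos = bp)

      tr <- list()
      # independent NCO tracts, rate apportioned by physical length
      n_nco <- rpois(1L, params$nco_rate_per_gamete * L / total_bp)
      if (n_nco > 0) {
        ts <- floor(runif(n_nco) * L)
        tl <- 1 + rgeom(n_nco, 1 / params$nco_tract_mean_bp)
        donor <- 1L - hap_at(ts, bp, start_hap)
        tr[[length(tr) + 1L]] <-
          data.frame(chrom = ch, start = ts, end = pmin(ts + tl, L),
                     donor = donor, kind = "NCO")
      }
      # CO-associated conversion tracts, offset from the breakpoint by a
      # short unconverted spacer so the converted run is a distinct block
      if (n_co > 0 && params$co_gc_conversion_prob > 0) {
        take <- runif(n_co) < params$co_gc_conversion_prob
        if (any(take)) {
          cb <- bp[take]
          tl <- 1 + rgeom(length(cb), 1 / params$nco_tract_mean_bp)
          sp <- 1 + rgeom(length(cb), 1 / params$nco_tract_mean_bp)
          ts <- pmax(cb - sp - tl, 0)
          donor <- hap_at(pmin(cb + 1, L - 1), bp, start_hap) # far side hap
          tr[[length(tr) + 1L]] <-
            data.frame(chrom = ch, start = ts, end = pmax(cb - sp, 0),
                       donor = donor, kind = "CO_conversion")
        }
      }
      if (length(tr)) {
        tr <- do.call(rbind, tr)
        tr$n_converted <- 0L
        for (i in seq_len(nrow(tr))) {
          in_tract <- rows[markers$pos[rows] >= tr$start[i] &
                           markers$pos[rows] < tr$end[i]]
          if (length(in_tract)) {
            new <- convert_alleles(markers, in_tract, tr$donor[i],
                                   params$gc_bias, alleles[in_tract])
            tr$n_converted[i] <- sum(new != alleles[in_tract])
            alleles[in_tract] <- new
          }
        }
        tracts[[length(tracts) + 1L]] <- tr
      }
    }
    cos <- if (length(cos)) do.call(rbind, cos) else
      data.frame(chrom = character(0), pos = numeric(0))
    tracts <- if (length(tracts)) do.call(rbind, tracts) else
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                 donor = integer(0), kind = character(0),
                 n_converted = integer(0))
    rownames(cos) <- rownames(tracts) <- NULL
    structure(list(alleles = alleles,
                   mutations = empty_mutation_frame(),
                   truth = list(start_hap = start_haps, crossovers = cos,
                                tracts = tracts)),
              class = "sim_gamete")
  })
}

draw_breakpoints <- function(n, chrom, L, hotspot_map) {
  if (n == 0L) return(numeric(0))
  if (is.null(hotspot_map)) return(runif(n) * L)
  hm <- hotspot_map[hotspot_map$chrom == chrom, , drop = FALSE]
  if (nrow(hm) == 0L) return(runif(n) * L)
  w <- hm$weight * (hm$end - hm$start)
  i <- sample.int(nrow(hm), n, replace = TRUE, prob = w)
  hm$start[i] + runif(n) * (hm$end[i] - hm$start[i])
}

empty_mutation_frame <- function() {
  data.frame(chrom = character(0), pos = numeric(0), ref = character(0),
             alt = character(0), kind = character(0), class = character(0))
}

#' Superimpose de novo mutations on a gamete
#'
#' Mutation count is Poisson with mean `mu_per_bp` times the non-gap genome
#' length; positions are uniform over non-gap sequence, never colliding
#' with queen-heterozygous marker sites. The mutation class (transition
#' direction, transversion, indel) is drawn from the spectrum parameters and
#' the reference base drawn consistently (from the queen's sequence when it
#' was kept, by rejection on the base class otherwise).
#'
#' @param gamete a [simulate_drone()] result.
#' @param queen the [simulate_queen()] result the gamete came from.
#' @param params a [mutation_params()].
#' @param seed optional integer seed.
#' @return the gamete with its `mutations` data.frame filled in
#'   (`chrom`, `pos`, `ref`, `alt`, `kind`, `class`).
#' @export
apply_mutations <- function(gamete, queen, params = mutation_params(),
                            seed = NULL) {
  stopifnot(inherits(gamete, "sim_gamete"), inherits(queen, "sim_queen"),
            inherits(params, "mutation_params"))
  spec <- queen$spec
  with_seed(seed, {
    ng <- nongap_lengths(spec)
    n <- rpois(1L, params$mu_per_bp * sum(ng))
    if (n == 0L) {
      gamete$mutations <- empty_mutation_frame()
      return(gamete)
    }
    kind <- ifelse(runif(n) < params$indel_fraction, "indel", "SNM")
    is_ts <- runif(n) < params$p_transition
    gc_to_at <- runif(n) < params$p_gc_to_at_given_transition
    class <- ifelse(kind == "indel", NA_character_,
                    ifelse(!is_ts, "transversion",
                           ifelse(gc_to_at, "GC>AT", "AT>GC")))
    out <- vector("list", n)
    mkpos <- split(queen$markers$pos, queen$markers$chrom)
    hits_marker <- function(ch, pos) {
      mp <- mkpos[[ch]]
      if (is.null(mp)) return(FALSE)
      f <- findInterval(pos, mp)
      f > 0L && mp[f] == pos
    }
    for (i in seq_len(n)) {
      repeat {
        ch <- sample(names(ng), 1L, prob = ng)
        pos <- sample_nongap(spec, ch, 1L)
        if (hits_marker(ch, pos)) next
        ref <- if (!is.null(queen$sequence))
          substr(queen$sequence[[ch]], pos + 1L, pos + 1L)
        else draw_bases(1L, spec$gc_content)
        ok <- switch(ifelse(is.na(class[i]), "any", class[i]),
                     "GC>AT" = ref %in% c("G", "C"),
                     "AT>GC" = ref %in% c("A", "T"),
                     TRUE)
        if (ok) break
      }
      alt <- if (kind[i] == "indel") {
        len <- sample.int(19L, 1L)
        if (runif(1) < 0.5) paste0("del", len)
        else paste0("ins", paste(draw_bases(len, spec$gc_content),
                                 collapse = ""))
      } else if (!is.na(class[i]) && class[i] != "transversion") {
        TRANSITION[[ref]]
      } else {
        sample(setdiff(BASES, c(ref, TRANSITION[[ref]])), 1L)
      }
      out[[i]] <- data.frame(chrom = ch, pos = pos, ref = ref, alt = alt,
                             kind = kind[i], class = class[i])
    }
    mut <- do.call(rbind, out)
    mut <- mut[!duplicated(paste(mut$chrom, mut$pos)), , drop = FALSE]
    mut <- mut[order(match(mut$chrom, names(spec$lengths)), mut$pos), ]
    rownames(mut) <- NULL
    gamete$mutations <- mut
    gamete
  })
}

#' Observe a set of gametes as a noisy genotype matrix
#'
#' Emits the segregating sites a variant caller would see (queen
#' heterozygous markers plus every drone-unique mutation site) as a
#' [genotype_matrix()] with per-cell depth, call quality and strand support,
#' and injects missing calls, genotype errors and spurious heterozygous
#' calls at the model's rates. With all noise rates zero the emitted calls
#' reproduce the gamete alleles exactly.
#'
#' Also draws, per drone, a genome-wide callable-site count (binomial at the
#' model's callable probability over non-gap sequence), attached as
#' attribute `genome_callable`.
#'
#' @param gametes list of [simulate_drone()] results from one queen.
#' @param queen the shared [simulate_queen()] result.
#' @param model an [observation_model()].
#' @param seed optional integer seed.
#' @param drone_ids,colony drone identifiers and colony label.
#' @return a [genotype_matrix()].
#' @export
observe_colony <- function(gametes, queen, model = observation_model(),
                           seed = NULL, drone_ids = NULL, colony = "I") {
  if (length(gametes) < 2L) stop("need at least two gametes to observe")
  stopifnot(inherits(queen, "sim_queen"))
  if (is.null(drone_ids))
    drone_ids <- sprintf("%s-D%d", colony, seq_along(gametes))
  with_seed(seed, {
    spec <- queen$spec
    mk <- queen$markers
    muts <- do.call(rbind, lapply(seq_along(gametes), function(i) {
      m <- gametes[[i]]$mutations
      if (nrow(m)) cbind(m, drone = i) else NULL
    }))
    sites <- data.frame(chrom = mk$chrom, pos = mk$pos, ref = mk$ref)
    n_marker <- nrow(sites)
    if (!is.null(muts) && nrow(muts))
      sites <- rbind(sites, data.frame(chrom = muts$chrom, pos = muts$pos,
                                       ref = muts$ref))
    ord <- order(match(sites$chrom, names(spec$lengths)), sites$pos)
    n_sites <- nrow(sites); n_drones <- length(gametes)
    calls <- matrix(NA_character_, n_sites, n_drones)
    for (j in seq_len(n_drones))
      calls[seq_len(n_marker), j] <- gametes[[j]]$alleles
    if (!is.null(muts) && nrow(muts)) {
      mrows <- n_marker + seq_len(nrow(muts))
      calls[mrows, ] <- matrix(rep(muts$ref, n_drones), ncol = n_drones)
      calls[cbind(mrows, muts$drone)] <- muts$alt
    }
    # noise channel
    nc <- n_sites * n_drones
    err <- integer(0)
    if (model$genotype_error_rate > 0) {
      err <- which(runif(nc) < model$genotype_error_rate)
      if (length(err))
        calls[err] <- vapply(calls[err], function(b) {
          sample(setdiff(BASES, b), 1L)
        }, "")
    }
    if (model$het_artifact_rate > 0) {
      het <- runif(nc) < model$het_artifact_rate
      calls[het] <- "H"
    }
    depth <- matrix(rpois(nc, model$mean_depth), n_sites, n_drones)
    if (model$missing_rate > 0) {
      miss <- runif(nc) < model$missing_rate
      calls[miss] <- NA_character_
    }
    calls[depth == 0L] <- NA_character_
    qual <- matrix(pmin(pmax(rnorm(nc, model$quality_mean, model$quality_sd),
                             0), 60), n_sites, n_drones)
    # miscalls at high depth come with poor genotype quality
    if (length(err))
      qual[err] <- pmin(pmax(rnorm(length(err), model$error_quality_mean,
                                   model$quality_sd), 0), 60)
    fwd_reads <- matrix(rbinom(nc, as.vector(depth), 0.5), n_sites, n_drones)
    strand_fwd <- fwd_reads > 0L
    strand_rev <- (depth - fwd_reads) > 0L
    p_callable <- (1 - model$missing_rate) * ppois(4, model$mean_depth,
                                                   lower.tail = FALSE)
    genome_callable <- rbinom(n_drones, round(sum(nongap_lengths(spec))),
                              p_callable)
    gt <- genotype_matrix(
      sites = sites[ord, , drop = FALSE],
      drones = data.frame(id = drone_ids, colony = colony),
      calls = calls[ord, , drop = FALSE],
      depth = depth[ord, , drop = FALSE],
      quality = qual[ord, , drop = FALSE],
      strand_fwd = strand_fwd[ord, , drop = FALSE],
      strand_rev = strand_rev[ord, , drop = FALSE])
    attr(gt, "genome_callable") <- stats::setNames(genome_callable, drone_ids)
    attr(gt, "genome") <- spec
    gt
  })
}

#' Simulate a full colony with ground truth
#'
#' Convenience wrapper: one queen, `n_drones` recombinant mutated gametes,
#' and one noisy genotype matrix, all from a single seed. The returned
#' `truth` element is the simulator's ground-truth ledger used by the
#' recovery tests: per-drone crossover breakpoints, conversion tracts,
#' chromosome start haplotypes and mutations, plus the queen itself.
#'
#' @param n_drones number of drones (>= 2).
#' @param spec,heterozygosity,meiosis,mutation,obs simulation parameters;
#'   see [genome_spec()], [simulate_queen()], [meiosis_params()],
#'   [mutation_params()], [observation_model()].
#' @param seed optional integer seed governing the whole colony.
#' @param colony colony label used in drone identifiers.
#' @param queen optionally reuse an existing queen.
#' @return an object of class `sim_colony`: list with `gt` (the
#'   [genotype_matrix()]), `truth`, and `queen`.
#' @export
simulate_colony <- function(n_drones = 22L, spec = genome_spec(),
                            heterozygosity = 0.0026,
                            meiosis = meiosis_params(),
                            mutation = mutation_params(),
                            obs = observation_model(),
                            seed = NULL, colony = "I", queen = NULL) {
  stopifnot(n_drones >= 2L)
  with_seed(seed, {
    if (is.null(queen))
      queen <- simulate_queen(spec, heterozygosity)
    drone_ids <- sprintf("%s-D%d", colony, seq_len(n_drones))
    gametes <- lapply(seq_len(n_drones), function(i) {
      g <- simulate_drone(queen, meiosis)
      apply_mutations(g, queen, mutation)
    })
    gt <- observe_colony(gametes, queen, obs, drone_ids = drone_ids,
                         colony = colony)
    truth <- list(
      queen = queen,
      start_hap = do.call(rbind, lapply(seq_len(n_drones), function(i)
        data.frame(drone = drone_ids[i],
                   chrom = names(gametes[[i]]$truth$start_hap),
                   hap = unlist(gametes[[i]]$truth$start_hap)))),
      crossovers = do.call(rbind, lapply(seq_len(n_drones), function(i) {
        x <- gametes[[i]]$truth$crossovers
        if (nrow(x)) cbind(drone = drone_ids[i], x) else NULL
      })),
      tracts = do.call(rbind, lapply(seq_len(n_drones), function(i) {
        x <- gametes[[i]]$truth$tracts
        if (nrow(x)) cbind(drone = drone_ids[i], x) else NULL
      })),
      mutations = do.call(rbind, lapply(seq_len(n_drones), function(i) {
        x <- gametes[[i]]$mutations
        if (nrow(x)) cbind(drone = drone_ids[i], x) else NULL
      })))
    for (nm in c("crossovers", "tracts", "mutations"))
      if (is.null(truth[[nm]]))
        truth[[nm]] <- data.frame()
    rownames(truth$start_hap) <- NULL
    structure(list(gt = gt, truth = truth, queen = queen),
              class = "sim_colony")
  })
}
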
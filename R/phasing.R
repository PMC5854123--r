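# Queen-haplotype phasing from haploid drone genotypes by adjacent-marker
# majority linkage, and per-drone haplotype block assignment.

# code colony calls at markers as 0 (= a1), 1 (= a2), NA otherwise
marker_codes <- function(markers, gt, cols) {
  m <- gt$calls[markers$site, cols, drop = FALSE]
  code <- matrix(NA_integer_, nrow(m), ncol(m))
  code[m == markers$a1] <- 0L   # matrix-vector comparison recycles by row
  code[m == markers$a2] <- 1L
  code
}

#' Phase the queen's two haplotypes from her drones
#'
#' For each pair of adjacent markers, the drones called at both vote for one
#' of the two possible linkage configurations; because crossover probability
#' per inter-marker interval is tiny, the majority configuration is taken as
#' the queen's linkage and phase is chained along the chromosome. A tie or a
#' pair with no doubly-called drone is bridged against the nearest preceding
#' informative marker (up to `bridge` markers back); if no bridge is
#' informative a new phase set starts, so linkage is never fabricated.
#'
#' Within each phase set, haplotype 0 at the first marker carries the
#' reference allele (else the alphabetically smaller allele); the labelling
#' of the two haplotypes is only meaningful up to a swap within each phase
#' set.
#'
#' @param markers a [screen_markers()] result.
#' @param gt the [genotype_matrix()] the markers came from.
#' @param bridge how many preceding markers to consult when an adjacent
#'   pair is uninformative.
#' @return a `queen_phase`: data.frame (`chrom`, `pos`, `hap0`, `hap1`,
#'   `phase_set`, `site`).
#' @export
phase_queen <- function(markers, gt, bridge = 10L) {
  stopifnot(inherits(markers, "marker_set"), inherits(gt, "genotype_matrix"))
  if (nrow(markers) < 1L) stop("need at least one marker")
  cols <- colony_columns(gt, attr(markers, "colony"))
  if (length(cols) < 2L) stop("need at least two drones")
  code <- marker_codes(markers, gt, cols)
  n <- nrow(markers)
  flip <- integer(n)
  phase_set <- integer(n)
  set_id <- 0L
  chrom_rows <- split(seq_len(n), markers$chrom)
  chrom_rows <- chrom_rows[unique(markers$chrom)] # keep input order

  pair_orient <- function(i, k) {
    # +1 same-orientation majority, -1 opposite, 0 uninformative
    eq <- code[i, ] == code[k, ]
    s <- sum(eq, na.rm = TRUE)
    d <- sum(!eq, na.rm = TRUE)
    sign(s - d)
  }

  for (rows in chrom_rows) {
    m <- length(rows)
    # vectorized adjacent-pair votes for the whole chromosome
    if (m > 1L) {
      A <- code[rows[-m], , drop = FALSE]
      B <- code[rows[-1L], , drop = FALSE]
      eq <- A == B
      s <- rowSums(eq, na.rm = TRUE)
      d <- rowSums(!eq, na.rm = TRUE)
      adj <- sign(s - d)
    } else adj <- integer(0)
    set_id <- set_id + 1L
    phase_set[rows[1L]] <- set_id
    flip[rows[1L]] <- 0L
    set_start <- 1L
    for (t in seq_len(m - 1L)) {
      i <- rows[t + 1L]
      o <- adj[t]
      if (o == 0L) {
        for (b in seq.int(2L, bridge)) {
          if (t + 1L - b < set_start) break
          o <- pair_orient(rows[t + 1L - b], i)
          if (o != 0L) {
            flip[i] <- (flip[rows[t + 1L - b]] + (o < 0L)) %% 2L
            break
          }
        }
        if (o == 0L) {            # undecidable: new phase set
          set_id <- set_id + 1L
          set_start <- t + 1L
          flip[i] <- 0L
        }
      } else {
        flip[i] <- (flip[rows[t]] + (o < 0L)) %% 2L
      }
      phase_set[i] <- set_id
    }
  }
  out <- data.frame(chrom = markers$chrom, pos = markers$pos,
                    hap0 = ifelse(flip == 0L, markers$a1, markers$a2),
                    hap1 = ifelse(flip == 0L, markers$a2, markers$a1),
                    phase_set = phase_set, site = markers$site)
  rownames(out) <- NULL
  structure(out, class = c("queen_phase", "data.frame"),
            colony = attr(markers, "colony"))
}

#' Assign a drone's genome to queen-haplotype blocks
#'
#' Maps each of the drone's called markers to haplotype 0 or 1 of the
#' phased queen (markers matching neither haplotype allele are flagged as
#' mismatches - candidate mutation sites - and excluded from blocks), then
#' returns maximal same-haplotype runs per chromosome and phase set with
#' their first/last marker positions.
#'
#' @param drone drone identifier (a column of the matrix).
#' @param phase a [phase_queen()] result.
#' @param gt the [genotype_matrix()].
#' @return data.frame of blocks (`drone`, `chrom`, `phase_set`, `hap`,
#'   `start`, `end`, `n_markers`, `span`), with attribute `mismatches`.
#' @export
assign_blocks <- function(drone, phase, gt) {
  stopifnot(inherits(phase, "queen_phase"), inherits(gt, "genotype_matrix"))
  jd <- match(drone, gt$drones$id)
  if (is.na(jd)) stop("unknown drone: ", drone)
  v <- gt$calls[phase$site, jd]
  h <- ifelse(!is.na(v) & v == phase$hap0, 0L,
              ifelse(!is.na(v) & v == phase$hap1, 1L, NA_integer_))
  mism <- !is.na(v) & v != "H" & is.na(h)
  called <- which(!is.na(h))
  grp <- paste(phase$chrom, phase$phase_set)
  blocks <- lapply(split(called, grp[called]), function(idx) {
    r <- rle(h[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    data.frame(drone = drone, chrom = phase$chrom[idx[1L]],
               phase_set = phase$phase_set[idx[1L]],
               hap = r$values,
               start = phase$pos[idx[starts]],
               end = phase$pos[idx[ends]],
               n_markers = r$lengths)
  })
  out <- do.call(rbind, blocks)
  if (is.null(out))
    out <- data.frame(drone = character(0), chrom = character(0),
                      phase_set = integer(0), hap = integer(0),
                      start = numeric(0), end = numeric(0),
                      n_markers = integer(0))
  out <- out[order(match(out$chrom, unique(phase$chrom)), out$start), ]
  out$span <- out$end - out$start
  rownames(out) <- NULL
  attr(out, "mismatches") <- data.frame(chrom = phase$chrom[mism],
                                        pos = phase$pos[mism])
  out
}
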
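# Genotype data model and marker screening for haploid drone cohorts.

#' Construct a haploid genotype matrix
#'
#' The central data container: per-site, per-drone haploid calls with their
#' sequencing depth, call quality and strand support. Calls are allele
#' strings (`"A"`, `"ins.."`, `"del.."`), `NA` for missing, `"H"` for a
#' spurious heterozygous call in a haploid sample (an artifact class that
#' marker screening removes). Positions are 0-based internally; file
#' readers and writers convert at the boundary.
#'
#' @param sites data.frame with columns `chrom`, `pos` (0-based), `ref`,
#'   sorted by (chrom, pos) and unique.
#' @param drones data.frame with columns `id`, `colony`.
#' @param calls character matrix, sites x drones.
#' @param depth integer matrix of per-cell read depths (>= 0), or `NULL`.
#' @param quality numeric matrix of phred-like call qualities, or `NULL`.
#' @param strand_fwd,strand_rev logical matrices of strand support, or
#'   `NULL` when the source format carries no strand information.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, drones, calls, depth = NULL,
                            quality = NULL, strand_fwd = NULL,
                            strand_rev = NULL) {
  stopifnot(all(c("chrom", "pos", "ref") %in% names(sites)),
            all(c("id", "colony") %in% names(drones)))
  n_sites <- nrow(sites); n_drones <- nrow(drones)
  if (!is.matrix(calls) || nrow(calls) != n_sites ||
      ncol(calls) != n_drones)
    stop("calls must be a sites x drones matrix")
  key <- paste(sites$chrom, sites$pos)
  if (anyDuplicated(key)) stop("duplicate sites")
  if (any(vapply(split(sites$pos, sites$chrom), is.unsorted, TRUE)))
    stop("sites must be sorted by position within chromosome")
  for (m in list(depth, quality, strand_fwd, strand_rev))
    if (!is.null(m) && (nrow(m) != n_sites || ncol(m) != n_drones))
      stop("matrix dimensions must match sites x drones")
  if (!is.null(depth) && any(depth < 0, na.rm = TRUE))
    stop("depth must be non-negative")
  rownames(sites) <- NULL
  colnames(calls) <- drones$id
  structure(list(sites = sites, drones = drones, calls = calls,
                 depth = depth, quality = quality,
                 strand_fwd = strand_fwd, strand_rev = strand_rev),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d drones (%s)\n",
              nrow(x$sites), nrow(x$drones),
              paste(sprintf("colony %s: %d", unique(x$drones$colony),
                            table(x$drones$colony)[unique(x$drones$colony)]),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(nrow(x$sites), nrow(x$drones))

colony_columns <- function(gt, colony) {
  j <- which(gt$drones$colony == colony)
  if (!length(j)) stop("unknown colony: ", colony)
  j
}

#' Screen candidate markers in a haploid drone cohort
#'
#' Applies the three marker rules for haploid cohorts in fixed order, with
#' drops attributed to the first failing rule:
#' \enumerate{
#'   \item no drone may carry a "heterozygous" call at the site (haploid
#'     genomes; such calls flag mapping errors or copy-number variation);
#'   \item exactly two distinct alleles must segregate among the called
#'     drones of the colony (missing calls do not count against this
#'     rule), and each allele must be observed in at least
#'     `min_minor_count` drones - identifying a genotype takes more than
#'     one observation, and a singleton allele is indistinguishable from a
#'     de novo mutation or a call error (such sites feed the mutation
#'     caller instead);
#'   \item the site must be called with quality >= `min_quality` in at
#'     least `min_call_fraction` of the colony's drones.
#' }
#'
#' @param gt a [genotype_matrix()].
#' @param colony colony whose drones are screened.
#' @param min_quality minimum call quality (default 30).
#' @param min_call_fraction minimum fraction of drones with a passing call
#'   (default 0.9).
#' @param min_minor_count minimum observations of each allele (default 2).
#' @return a `marker_set`: data.frame (`chrom`, `pos`, `a1`, `a2`, `site`)
#'   where `a1`/`a2` are the colony's two observed alleles (reference first
#'   when present, else alphabetical) and `site` indexes rows of
#'   `gt$sites`; attribute `drop_counts` reports per-rule exclusions.
#' @export
screen_markers <- function(gt, colony, min_quality = 30,
                           min_call_fraction = 0.9, min_minor_count = 2L) {
  stopifnot(inherits(gt, "genotype_matrix"))
  j <- colony_columns(gt, colony)
  if (length(j) < 2L) stop("colony must contain at least two drones")
  calls <- gt$calls[, j, drop = FALSE]
  n <- nrow(calls)
  # rule 1: any heterozygous-artifact call
  het_fail <- rowSums(calls == "H", na.rm = TRUE) > 0L
  # rule 2: exactly two distinct alleles among called drones. Fast path
  # codes plain bases; rows carrying any other allele string (indels) are
  # recounted exactly.
  codes <- matrix(match(calls, BASES), n, length(j))
  odd <- !is.na(calls) & calls != "H" & is.na(codes)
  cnt <- matrix(vapply(1:4, function(k)
    rowSums(codes == k, na.rm = TRUE), numeric(n)), n, 4L)
  pres <- cnt > 0L
  n_alleles <- rowSums(pres)
  minor <- apply_minor(cnt)
  odd_rows <- which(rowSums(odd) > 0L)
  for (i in odd_rows) {
    r <- calls[i, ]
    u <- table(r[!is.na(r) & r != "H"])
    n_alleles[i] <- length(u)
    minor[i] <- if (length(u)) min(u) else 0
  }
  rule2_fail <- !het_fail & (n_alleles != 2L | minor < min_minor_count)
  # rule 3: quality/call-rate
  ok_call <- !is.na(calls) & calls != "H"
  if (!is.null(gt$quality))
    ok_call <- ok_call & gt$quality[, j, drop = FALSE] >= min_quality
  rule3_fail <- !het_fail & !rule2_fail &
    rowSums(ok_call) / length(j) < min_call_fraction
  keep <- !(het_fail | rule2_fail | rule3_fail)
  ks <- which(keep)
  base_only <- !(ks %in% odd_rows)
  a1 <- a2 <- character(length(ks))
  if (any(base_only)) {
    kb <- ks[base_only]
    p <- pres[kb, , drop = FALSE]
    a1[base_only] <- BASES[max.col(p, "first")]
    a2[base_only] <- BASES[max.col(p, "last")]
  }
  for (w in which(!base_only)) {
    r <- calls[ks[w], ]
    u <- sort(unique(r[!is.na(r) & r != "H"]))
    a1[w] <- u[1L]; a2[w] <- u[2L]
  }
  # reference allele first when it is one of the two, else alphabetical
  ref <- gt$sites$ref[ks]
  sw <- a2 == ref
  tmp <- a1[sw]; a1[sw] <- a2[sw]; a2[sw] <- tmp
  out <- data.frame(chrom = gt$sites$chrom[ks], pos = gt$sites$pos[ks],
                    a1 = a1, a2 = a2, site = ks)
  rownames(out) <- NULL
  structure(out, class = c("marker_set", "data.frame"),
            colony = colony,
            drop_counts = c(heterozygous_call = sum(het_fail),
                            not_biallelic = sum(rule2_fail),
                            quality_call_rate = sum(rule3_fail)))
}

# smallest nonzero per-row count (the minor-allele count for biallelic rows)
apply_minor <- function(cnt) {
  x <- cnt
  x[x == 0] <- Inf
  out <- do.call(pmin, as.data.frame(x))
  out[is.infinite(out)] <- 0
  out
}

#' Mean inter-marker distance
#'
#' Mean of successive same-chromosome gaps between marker positions, the
#' resolution figure quoted for recombination maps (e.g. 373 bp for half a
#' million markers on a 217 Mb assembly).
#'
#' @param markers a [screen_markers()] result (or any data.frame with
#'   `chrom` and `pos`).
#' @return mean gap in bp.
#' @export
marker_density <- function(markers) {
  if (nrow(markers) < 2L) stop("need at least two markers")
  gaps <- unlist(lapply(split(markers$pos, markers$chrom), diff),
                 use.names = FALSE)
  if (!length(gaps)) stop("no same-chromosome marker pair")
  mean(gaps)
}
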
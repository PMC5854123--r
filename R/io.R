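# File formats. Genotype, phase and truth tables are tab-separated text;
# events are BED (0-based half-open); mutation calls are minimal VCF.
# Positions are 0-based internally, 1-based in TSV/VCF, 0-based in BED.

#' Write / read a genotype matrix as a tab-separated table
#'
#' Dialect of posted colony genotype files: header row `chrom pos ref`
#' followed by one drone id per column; one row per site with 1-based
#' positions and one allele per drone, `.` for missing and `H` for a
#' heterozygous-artifact call. Depth/quality/strand matrices are not part
#' of this dialect and are dropped on write.
#'
#' @param gt a [genotype_matrix()].
#' @param path file path.
#' @return `write_genotypes` returns `path` invisibly; `read_genotypes`
#'   returns a [genotype_matrix()].
#' @export
write_genotypes <- function(gt, path) {
  m <- gt$calls
  m[is.na(m)] <- "."
  tab <- cbind(data.frame(chrom = gt$sites$chrom,
                          pos = gt$sites$pos + 1L,
                          ref = gt$sites$ref), as.data.frame(m))
  names(tab) <- c("chrom", "pos", "ref", gt$drones$id)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @param colony_of function mapping a drone id to its colony label;
#'   default takes the prefix before the first `-`.
#' @export
read_genotypes <- function(path, colony_of = function(id)
                             sub("-.*$", "", id)) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           check.names = FALSE)
  ids <- names(tab)[-(1:3)]
  m <- as.matrix(tab[, -(1:3), drop = FALSE])
  m[m == "."] <- NA_character_
  genotype_matrix(
    sites = data.frame(chrom = tab$chrom, pos = as.numeric(tab$pos) - 1L,
                       ref = tab$ref),
    drones = data.frame(id = ids,
                        colony = vapply(ids, colony_of, "")),
    calls = unname(m))
}

#' Read a multi-sample haploid VCF as a genotype matrix
#'
#' Uses \pkg{vcfR}. Haploid genotypes (`0`, `1`, ...) map to the site's
#' REF/ALT alleles; diploid-coded homozygotes (`0/0`) are accepted;
#' heterozygous genotypes become the `H` artifact code; `.` is missing.
#' `DP` and `GQ` FORMAT fields populate depth and quality when present.
#'
#' @param path VCF file.
#' @param colony_of function mapping sample id to colony label.
#' @return a [genotype_matrix()].
#' @export
read_genotypes_vcf <- function(path, colony_of = function(id)
                                 sub("-.*$", "", id)) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  alleles <- cbind(fix[, "REF"], do.call(rbind,
    lapply(strsplit(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]), ","),
           function(a) c(a, rep(NA, 3))[1:3])))
  n <- nrow(gt_raw)
  calls <- matrix(NA_character_, n, ncol(gt_raw))
  for (jj in seq_len(ncol(gt_raw))) {
    g <- gt_raw[, jj]
    g[g %in% c(".", "./.", ".|.")] <- NA
    parts <- strsplit(g, "[/|]")
    calls[, jj] <- vapply(seq_len(n), function(i) {
      p <- parts[[i]]
      if (length(p) == 0L || all(is.na(p))) return(NA_character_)
      u <- unique(p)
      if (length(u) > 1L) return("H")
      alleles[i, as.integer(u) + 1L]
    }, "")
  }
  depth <- tryCatch(
    matrix(as.numeric(vcfR::extract.gt(v, element = "DP")), n),
    error = function(e) NULL)
  qual <- tryCatch(
    matrix(as.numeric(vcfR::extract.gt(v, element = "GQ")), n),
    error = function(e) NULL)
  ids <- colnames(gt_raw)
  genotype_matrix(
    sites = data.frame(chrom = fix[, "CHROM"],
                       pos = as.numeric(fix[, "POS"]) - 1,
                       ref = fix[, "REF"]),
    drones = data.frame(id = ids, colony = vapply(ids, colony_of, "")),
    calls = calls, depth = depth, quality = qual)
}

#' Write / read a queen phase table
#'
#' Tab-separated: `chrom`, `pos` (1-based), `hap0`, `hap1`, `phase_set`.
#'
#' @param phase a [phase_queen()] result.
#' @param path file path.
#' @export
write_phase <- function(phase, path) {
  tab <- data.frame(chrom = phase$chrom, pos = phase$pos + 1L,
                    hap0 = phase$hap0, hap1 = phase$hap1,
                    phase_set = phase$phase_set)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_phase
#' @param colony colony label to attach.
#' @export
read_phase <- function(path, colony = "I") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "numeric",
                                          "character", "character",
                                          "integer"))
  out <- data.frame(chrom = tab$chrom, pos = tab$pos - 1L,
                    hap0 = tab$hap0, hap1 = tab$hap1,
                    phase_set = tab$phase_set, site = NA_integer_)
  structure(out, class = c("queen_phase", "data.frame"), colony = colony)
}

#' Write / read recombination events as BED
#'
#' BED6+3 with 0-based half-open breakpoint/tract intervals: name is
#' `drone:kind`, score the converted-marker count, then `kind`,
#' `category` and `excluded` columns.
#'
#' @param events [group_shared_cos()] output.
#' @param path file path.
#' @export
write_events_bed <- function(events, path) {
  category <- if ("category" %in% names(events)) events$category else NA
  excluded <- if ("excluded" %in% names(events)) events$excluded else FALSE
  tab <- data.frame(chrom = events$chrom,
                    start = format(events$start, scientific = FALSE,
                                   trim = TRUE),
                    end = format(events$end + 1, scientific = FALSE,
                                 trim = TRUE),
                    name = paste(events$drone, events$kind, sep = ":"),
                    score = events$n_converted, strand = ".",
                    kind = events$kind,
                    category = ifelse(is.na(category), ".", category),
                    excluded = ifelse(excluded, "1", "0"))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_events_bed
#' @export
read_events_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "numeric", "numeric",
                                          "character", "integer",
                                          "character", "character",
                                          "character", "character"))
  names(tab) <- c("chrom", "start", "end", "name", "score", "strand",
                  "kind", "category", "excluded")
  data.frame(drone = sub(":.*$", "", tab$name), chrom = tab$chrom,
             kind = tab$kind, start = tab$start, end = tab$end - 1,
             n_converted = tab$score,
             category = suppressWarnings(as.integer(tab$category)),
             excluded = tab$excluded == "1")
}

#' Read a BED file of assembly gaps
#'
#' Three-column BED (0-based half-open) into the gap data.frame the
#' simulator and event-grouping functions use.
#'
#' @param path BED file.
#' @return data.frame (`chrom`, `start`, `end`).
#' @export
read_gaps_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE)[, 1:3]
  names(tab) <- c("chrom", "start", "end")
  tab
}

#' Write mutation calls as a minimal VCF
#'
#' VCF 4.2, 1-based positions, one sample column per drone with haploid
#' GT (1 for the carrier). Indel alleles are written symbolically
#' (`<DEL18>`, `<INSACGT>`): the genotype-level pipeline does not carry
#' flanking sequence.
#'
#' @param calls [call_denovo()] output.
#' @param drones data.frame (`id`, `colony`) of all drones.
#' @param path file path.
#' @export
write_mutations_vcf <- function(calls, drones, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=dronemap",
               paste0("##INFO=<ID=DRONE,Number=1,Type=String,",
                      "Description=\"Carrier drone\">"),
               paste0("##INFO=<ID=CLASS,Number=1,Type=String,",
                      "Description=\"Mutation class\">"),
               paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                      "Description=\"Genotype\">"),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", drones$id),
                     collapse = "\t")), con)
  for (i in seq_len(nrow(calls))) {
    alt <- calls$alt[i]
    if (grepl("^(ins|del)", alt))
      alt <- paste0("<", toupper(alt), ">")
    gt <- ifelse(drones$id == calls$drone[i], "1", "0")
    writeLines(paste(c(calls$chrom[i],
                       format(calls$pos[i] + 1, scientific = FALSE),
                       ".", calls$ref[i], alt, ".", "PASS",
                       sprintf("DRONE=%s;CLASS=%s", calls$drone[i],
                               calls$class[i]),
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a simulated queen's reference as FASTA
#'
#' Requires the queen to have been simulated with `keep_sequence = TRUE`;
#' uses \pkg{Biostrings}.
#'
#' @param queen a [simulate_queen()] result with sequence.
#' @param path file path.
#' @export
write_reference_fasta <- function(queen, path) {
  if (is.null(queen$sequence))
    stop("queen was simulated without keep_sequence = TRUE")
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("writing FASTA requires the Biostrings package")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(queen$sequence), path)
  invisible(path)
}

#' Write simulation ground truth
#'
#' Events (crossover breakpoints and conversion tracts) as BED, mutations
#' as a tab-separated table with 1-based positions.
#'
#' @param truth the `truth` element of a [simulate_colony()] result.
#' @param events_path,mutations_path output paths.
#' @export
write_truth <- function(truth, events_path, mutations_path) {
  co <- truth$crossovers
  tr <- truth$tracts
  bed <- rbind(
    if (!is.null(co) && nrow(co))
      data.frame(chrom = co$chrom,
                 start = floor(co$pos), end = floor(co$pos) + 1,
                 name = paste(co$drone, "CO", sep = ":")),
    if (!is.null(tr) && nrow(tr))
      data.frame(chrom = tr$chrom, start = floor(tr$start),
                 end = ceiling(tr$end),
                 name = paste(tr$drone, tr$kind, sep = ":")))
  if (!is.null(bed))
    utils::write.table(
      data.frame(bed$chrom,
                 format(bed$start, scientific = FALSE, trim = TRUE),
                 format(bed$end, scientific = FALSE, trim = TRUE),
                 bed$name),
      events_path, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
  mu <- truth$mutations
  if (!is.null(mu) && nrow(mu)) {
    mu$pos <- mu$pos + 1
    utils::write.table(mu, mutations_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(NULL)
}

#' Read a published-style mutation table
#'
#' Tab-separated with columns `number`, `sample`, `chrom`, `pos`
#' (1-based), `ref`, `alt`, `kind` - the layout of the printed mutation
#' list packaged at `system.file("extdata", "drone_mutations.tsv",
#' package = "dronemap")`. Returns a calls-style data.frame with 0-based
#' positions and SNM classes filled in.
#'
#' @param path file path.
#' @return data.frame (`drone`, `chrom`, `pos`, `ref`, `alt`, `kind`,
#'   `class`).
#' @export
read_mutation_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  out <- data.frame(drone = tab$sample, chrom = tab$chrom,
                    pos = as.numeric(tab$pos) - 1, ref = tab$ref,
                    alt = tab$alt, kind = tab$kind)
  out$class <- ifelse(out$kind == "SNM", snm_class(out$ref, out$alt),
                      NA_character_)
  out
}

#' Per-drone mutation counts over a full roster
#'
#' Tallies calls per drone including zero-count drones, the vector the
#' Poisson-dispersion test takes.
#'
#' @param calls a calls data.frame with a `drone` column.
#' @param drone_ids the full drone roster.
#' @return named integer vector, one entry per drone.
#' @export
drone_mutation_counts <- function(calls, drone_ids) {
  cnt <- table(factor(calls$drone, levels = drone_ids))
  stats::setNames(as.integer(cnt), drone_ids)
}
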
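# Shared fixtures built in code.

# construct a small genotype matrix from per-site call strings like
# "A A T A" ("." missing, "H" heterozygous artifact)
mk_gt <- function(rows, colony = "I", chrom = "LG1", pos = NULL,
                  ref = NULL, qual = 40, depth = 20, strand = TRUE,
                  drones = NULL) {
  m <- do.call(rbind, strsplit(rows, " +"))
  m[m == "."] <- NA_character_
  n <- nrow(m); k <- ncol(m)
  if (is.null(pos)) pos <- seq(0, by = 1000, length.out = n)
  if (is.null(ref))
    ref <- apply(m, 1L, function(r) {
      t <- table(r[!is.na(r) & r != "H" & r %in% c("A", "C", "G", "T")])
      if (length(t)) names(t)[which.max(t)] else "A"
    })
  if (is.null(drones)) drones <- sprintf("%s-D%d", colony, seq_len(k))
  genotype_matrix(
    sites = data.frame(chrom = rep_len(chrom, n), pos = pos, ref = ref),
    drones = data.frame(id = drones, colony = colony),
    calls = m,
    depth = matrix(depth, n, k), quality = matrix(qual, n, k),
    strand_fwd = matrix(strand, n, k), strand_rev = matrix(strand, n, k))
}

# noiseless observation channel (deterministic passing quality)
obs_noiseless <- function(mean_depth = 26)
  observation_model(mean_depth = mean_depth, missing_rate = 0,
                    genotype_error_rate = 0, het_artifact_rate = 0,
                    quality_sd = 0)

# one small simulated colony reused across tests (built once per session)
local({
  cache <- new.env(parent = emptyenv())
  small_colony <<- function() {
    if (is.null(cache$sim))
      cache$sim <- simulate_colony(
        12, genome_spec(total_bp = 8e6, n_chrom = 3), seed = 2024,
        obs = obs_noiseless())
    cache$sim
  }
})

# per-drone counts from the packaged printed mutation table over the full
# 32-drone roster (unnamed colony-II drones carry zero counts)
table2_counts <- function() {
  path <- system.file("extdata", "drone_mutations.tsv",
                      package = "dronemap")
  tab <- read_mutation_table(path)
  snm <- tab[tab$kind == "SNM", ]
  roster <- c(sprintf("I-D%d", 1:22),
              c("II-D4", "II-D14", "II-D16", "II-D17", "II-D21",
                sprintf("II-X%d", 1:5)))
  drone_mutation_counts(snm, roster)
}
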
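test_that("drone-unique calling with carrier filters", {
  gt <- mk_gt(c("A A T T A",
                "T T T T C",    # C unique to drone 5
                "T G T T G",    # G in two drones: not unique
                "A A A A A"),
              ref = c("A", "T", "T", "A"))
  calls <- call_denovo(gt, "I")
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$drone, "I-D5")
  expect_identical(calls$alt, "C")
  expect_identical(calls$class, "AT>GC")
  # carrier depth below threshold kills the call
  gt2 <- gt
  gt2$depth[2, 5] <- 3
  expect_identical(nrow(call_denovo(gt2, "I")), 0L)
  # single-strand support kills the call
  gt3 <- gt
  gt3$strand_rev[2, 5] <- FALSE
  expect_identical(nrow(call_denovo(gt3, "I")), 0L)
  expect_identical(nrow(call_denovo(gt3, "I", require_strand = FALSE)), 1L)
  # low carrier quality kills the call
  gt4 <- gt
  gt4$quality[2, 5] <- 20
  expect_identical(nrow(call_denovo(gt4, "I")), 0L)
  expect_error(call_denovo(gt, "II"), "unknown colony")
})

test_that("raising thresholds never increases the number of calls", {
  sim <- simulate_colony(8, genome_spec(total_bp = 4e6, n_chrom = 2),
                         seed = 55,
                         mutation = mutation_params(mu_per_bp = 2e-6))
  n <- vapply(c(0, 5, 10, 26), function(d)
    nrow(call_denovo(sim$gt, "I", min_depth = d)), 0L)
  expect_true(all(diff(n) <= 0))
  nq <- vapply(c(0, 30, 40), function(q)
    nrow(call_denovo(sim$gt, "I", min_quality = q)), 0L)
  expect_true(all(diff(nq) <= 0))
})

test_that("noiseless simulated mutations are recovered exactly", {
  # mutation load far above study scale, so same-drone clusters occur by
  # chance: disable the cluster rejection to check raw identity
  sim <- simulate_colony(12, genome_spec(total_bp = 6e6, n_chrom = 3),
                         seed = 66, obs = obs_noiseless(),
                         mutation = mutation_params(mu_per_bp = 2e-6))
  ms <- screen_markers(sim$gt, "I")
  ph <- phase_queen(ms, sim$gt)
  blocks <- do.call(rbind, lapply(sim$gt$drones$id, assign_blocks,
                                  phase = ph, gt = sim$gt))
  calls <- call_denovo(sim$gt, "I", ms, blocks = blocks,
                       cluster_window = 0)
  tm <- sim$truth$mutations
  expect_gt(nrow(tm), 10)
  expect_identical(
    sort(paste(calls$drone, calls$chrom, calls$pos, calls$alt)),
    sort(paste(tm$drone, tm$chrom, tm$pos, tm$alt)))
})

test_that("phase concordance rejects chance sole-haplotype splits", {
  # a region where drone 5 alone inherited one queen haplotype: every
  # site there shows a 1:4 split, so the region itself is marker-free and
  # the haplotype context comes from the drones' blocks
  gt <- mk_gt("C C C C G", ref = "C", pos = 5000)
  blk <- function(drone, hap)
    data.frame(drone = drone, chrom = "LG1", phase_set = 1L, hap = hap,
               start = 0, end = 10000, n_markers = 10L)
  blocks <- rbind(blk("I-D1", 0L), blk("I-D2", 0L), blk("I-D3", 0L),
                  blk("I-D4", 0L), blk("I-D5", 1L))
  # without haplotype context the G is a candidate; with it the split is
  # exactly what queen heterozygosity produces: carrier alone on its
  # haplotype, every brother on the other
  expect_identical(nrow(call_denovo(gt, "I")), 1L)
  expect_identical(nrow(call_denovo(gt, "I", blocks = blocks)), 0L)
  # a brother sharing the carrier's haplotype while carrying the
  # reference contradicts queen heterozygosity: the call survives
  blocks2 <- blocks
  blocks2$hap[4] <- 1L
  expect_identical(nrow(call_denovo(gt, "I", blocks = blocks2)), 1L)
})

test_that("clustered same-drone candidates are rejected as artifacts", {
  rows <- c("A A A A T",
            "C C C C G",
            "G G G G A")
  gt <- mk_gt(rows, ref = c("A", "C", "G"), pos = c(0, 4000, 8000))
  expect_identical(nrow(call_denovo(gt, "I")), 0L)
  expect_identical(attr(call_denovo(gt, "I"), "n_clustered"), 3L)
  # spread out they all pass
  gt2 <- mk_gt(rows, ref = c("A", "C", "G"), pos = c(0, 5e5, 1e6))
  expect_identical(nrow(call_denovo(gt2, "I")), 3L)
})

test_that("callable site accounting", {
  depth <- matrix(c(0, 4, 26,
                    26, 26, 26), 3, 2)
  expect_equal(unname(callable_sites(depth)$per_drone), c(1, 3))
  expect_equal(callable_sites(depth)$total, 4)
  mapq <- matrix(c(60, 60, 60,
                   60, 60, 10), 3, 2)
  expect_equal(callable_sites(depth, mapq)$total, 3)
  expect_equal(
    callable_sites(depth, reference = c("A", "N", "C"))$total, 3)
  full <- matrix(26, 5, 3)
  expect_equal(callable_sites(full)$total, 15)
  expect_error(callable_sites(depth, mapq[1:2, , drop = FALSE]), "match")
})

test_that("exact Poisson interval matches brute-force tail inversion", {
  # oracle: invert the Poisson tail probabilities directly
  brute <- function(k, conf = 0.95) {
    a <- (1 - conf) / 2
    lo <- if (k == 0) 0 else
      uniroot(function(l) ppois(k - 1, l, lower.tail = FALSE) - a,
              c(1e-9, 200), tol = 1e-10)$root
    hi <- uniroot(function(l) ppois(k, l) - a, c(1e-9, 200),
                  tol = 1e-10)$root
    c(lo, hi)
  }
  for (k in 0:50)
    expect_equal(unname(exact_poisson_ci(k)), brute(k), tolerance = 1e-4)
  expect_equal(unname(exact_poisson_ci(0)), c(0, -log(0.025)),
               tolerance = 1e-6)
  expect_equal(unname(exact_poisson_ci(2)), c(0.2422, 7.2247),
               tolerance = 1e-4)
  # agrees with the standard exact Poisson test
  expect_equal(unname(exact_poisson_ci(23)),
               as.numeric(poisson.test(23)$conf.int), tolerance = 1e-8)
  expect_error(exact_poisson_ci(23, conf = 1.2), "conf")
  expect_error(exact_poisson_ci(-1), "count")
})

test_that("rate estimation reproduces printed study arithmetic", {
  est <- estimate_rate(23, 6426135514)
  expect_equal(est$rate, 3.58e-9, tolerance = 0.002)
  expect_equal(unname(est$count_ci), c(14.6, 34.5), tolerance = 0.005)
  expect_equal(est$per_genome, 0.98, tolerance = 0.01)
  est0 <- estimate_rate(0, 1e9)
  expect_equal(est0$rate, 0)
  expect_equal(unname(est0$count_ci[2]), 3.689, tolerance = 1e-3)
  expect_error(estimate_rate(1, 0), "positive")
})

test_that("spectrum summary applies the GC-content correction", {
  calls <- data.frame(kind = "SNM",
                      class = c(rep("GC>AT", 20), rep("AT>GC", 3)))
  s <- spectrum_summary(calls, 0.375)
  expect_equal(unname(s$gc_normalized), c(20 / 0.375, 3 / 0.625))
  expect_equal(s$transitions, 23L)
  expect_equal(s$transversions, 0L)
  empty <- spectrum_summary(calls[0, ], 0.375)
  expect_true(all(empty$counts == 0))
  sym <- spectrum_summary(data.frame(kind = "SNM",
                                     class = c("GC>AT", "AT>GC")), 0.5)
  expect_equal(unname(sym$gc_normalized[1]), unname(sym$gc_normalized[2]))
  expect_error(spectrum_summary(calls, 1.5), "gc_fraction")
})

test_that("snm_class distinguishes transitions by direction", {
  expect_identical(snm_class(c("G", "C", "A", "T"),
                             c("A", "T", "G", "C")),
                   c("GC>AT", "GC>AT", "AT>GC", "AT>GC"))
  expect_identical(unname(snm_class("G", "T")), "transversion")
})

test_that("genotype-level spike-in recovery", {
  sim <- small_colony()
  # noiseless channel (constant passing quality): every spike is
  # callable and detected
  r <- spike_in_recovery(sim$gt, "I", n_spikes = 300,
                         model = observation_model(
                           missing_rate = 0, genotype_error_rate = 0,
                           het_artifact_rate = 0, quality_sd = 0),
                         seed = 5)
  expect_equal(r$fraction_callable, 1)
  expect_equal(r$fraction_detected, 1)
  # with noise, callable fraction matches the model's callable
  # probability (binomial oracle)
  model <- observation_model(mean_depth = 8, missing_rate = 0.1)
  p <- (1 - 0.1) * ppois(4, 8, lower.tail = FALSE)
  r2 <- spike_in_recovery(sim$gt, "I", n_spikes = 2000, model = model,
                          seed = 6)
  expect_lt(abs(r2$fraction_callable - p), 4 * sqrt(p * (1 - p) / 2000))
  expect_error(spike_in_recovery(sim$gt, "I", n_spikes = 0), "n_spikes")
})
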
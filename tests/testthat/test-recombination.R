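# block fixtures are easiest to write directly
mk_blocks <- function(hap, start, end, n_markers = 5L, drone = "I-D1",
                      chrom = "LG1", phase_set = 1L) {
  data.frame(drone = drone, chrom = chrom, phase_set = phase_set,
             hap = hap, start = start, end = end,
             n_markers = rep_len(n_markers, length(hap)))
}

test_that("the 10 kb span rule separates NCOs from crossovers", {
  # single block: nothing
  expect_identical(nrow(classify_events(mk_blocks(0L, 0, 5e6))), 0L)
  # two long blocks: one crossover at the boundary interval
  b <- mk_blocks(c(0L, 1L), c(0, 2e6), c(1e6, 3e6))
  ev <- classify_events(b)
  expect_identical(ev$kind, "CO")
  expect_identical(ev$start, 1e6)
  expect_identical(ev$end, 2e6)
  # embedded 9,999 bp block with same long flanks: a noncrossover
  b <- mk_blocks(c(0L, 1L, 0L), c(0, 1e6 + 5e4, 2e6),
                 c(1e6, 1e6 + 5e4 + 9999, 3e6), n_markers = c(50L, 3L, 50L))
  ev <- classify_events(b)
  expect_identical(ev$kind, "NCO")
  expect_identical(ev$n_converted, 3L)
  expect_identical(ev$end - ev$start, 9999)
  # at 10,001 bp the middle block joins the backbone: two crossovers
  b$end[2] <- b$start[2] + 10001
  ev <- classify_events(b)
  expect_identical(ev$kind, c("CO", "CO"))
  # an even run of short blocks inside a haplotype change:
  # one crossover plus crossover-associated conversions
  b <- mk_blocks(c(0L, 1L, 0L, 1L), c(0, 1.1e6, 1.2e6, 1.3e6),
                 c(1e6, 1.101e6, 1.201e6, 2.3e6),
                 n_markers = c(9L, 2L, 1L, 9L))
  ev <- classify_events(b)
  expect_identical(sort(ev$kind), c("CO", "CO_conversion", "CO_conversion"))
  expect_identical(ev$start[ev$kind == "CO"], 1e6)
  expect_identical(ev$end[ev$kind == "CO"], 1.3e6)
  # chromosome-terminal short block: a terminal switch, counted as CO
  b <- mk_blocks(c(0L, 1L), c(0, 2e6), c(1.999e6, 2.005e6))
  expect_identical(classify_events(b)$kind, "CO")
  expect_identical(nrow(classify_events(b, terminal_as_co = FALSE)), 0L)
  expect_error(classify_events(mk_blocks(c(0L, 1L), c(2e6, 0),
                                         c(3e6, 1e6))),
               "ordered")
})

test_that("shared double crossovers are grouped and excluded", {
  one_co <- function(drone, start, end, chrom = "LG1")
    data.frame(drone = drone, chrom = chrom, kind = "CO", start = start,
               end = end, n_converted = 0L)
  # no shared intervals: everything kept
  ev <- rbind(one_co("a", 1e6, 1.001e6), one_co("b", 2e6, 2.001e6))
  g <- group_shared_cos(ev)
  expect_false(any(g$excluded))
  expect_true(all(is.na(g$shared_group)))
  # two drones share the same two adjacent breakpoints 300 kb apart:
  # all four crossovers are category 2 and excluded
  ev <- rbind(one_co("a", 1e6, 1.001e6), one_co("a", 1.3e6, 1.301e6),
              one_co("b", 1e6, 1.001e6), one_co("b", 1.3e6, 1.301e6))
  g <- group_shared_cos(ev)
  expect_identical(g$category, rep(2L, 4))
  expect_true(all(g$excluded))
  # a lone shared crossover is category 1 and kept
  ev <- rbind(one_co("a", 1e6, 1.001e6), one_co("b", 1e6, 1.001e6))
  g <- group_shared_cos(ev)
  expect_identical(g$category, rep(1L, 2))
  expect_false(any(g$excluded))
  # beyond the double-CO window the pair stays category 1
  ev <- rbind(one_co("a", 1e6, 1.001e6), one_co("a", 2e6, 2.001e6),
              one_co("b", 1e6, 1.001e6), one_co("b", 2e6, 2.001e6))
  g <- group_shared_cos(ev, double_co_window = 700000)
  expect_false(any(g$excluded))
  # gap annotation
  ev <- one_co("a", 1e6, 1.1e6)
  g <- group_shared_cos(ev, gaps = data.frame(chrom = "LG1", start = 1.05e6,
                                              end = 1.06e6))
  expect_true(g$gap_overlap)
})

test_that("crossover rate arithmetic and pooling invariant", {
  expect_equal(crossover_rate(data.frame(drone = character(0),
                                         chrom = character(0),
                                         kind = character(0),
                                         start = numeric(0),
                                         end = numeric(0),
                                         n_converted = integer(0)),
                              216.85, 32)$cM_per_Mb, 0)
  # the union of two disjoint drone sets has the drone-weighted mean rate
  evA <- data.frame(drone = "a", chrom = "LG1", kind = "CO",
                    start = seq(1e6, 9e6, by = 1e6),
                    end = seq(1e6, 9e6, by = 1e6) + 500, n_converted = 0L)
  evB <- evA[1:4, ]; evB$drone <- "b"
  rA <- crossover_rate(evA, 10, 1)$cM_per_Mb
  rB <- crossover_rate(evB, 10, 1)$cM_per_Mb
  rAB <- crossover_rate(rbind(evA, evB), 10, 2)$cM_per_Mb
  expect_equal(rAB, (rA + rB) / 2)
  expect_error(crossover_rate(evA, 10, 0), "drone")
})

test_that("window rates localise events and call hotspots", {
  lens <- c(LG1 = 2e6, LG2 = 1e6)
  ev <- data.frame(drone = "a", chrom = "LG1", kind = "CO",
                   start = rep(7.4e5, 8), end = rep(7.6e5, 8),
                   n_converted = 0L)
  w <- window_rates(ev, lens, n_drones = 4, window_bp = 5e5)
  expect_identical(nrow(w), 6L)
  hot <- w[w$n_co > 0, ]
  expect_identical(nrow(hot), 1L)
  expect_identical(hot$start, 5e5)       # midpoint 750 kb
  expect_equal(hot$cM_per_Mb, 100 * 8 / (4 * 0.5))
  expect_true(hot$hotspot)
  expect_true(all(w$cM_per_Mb[w$n_co == 0] == 0))
  # uniform events across many windows: no hotspot at the 5x threshold
  set.seed(77)
  mid <- runif(200, 0, 2e6)
  ev2 <- data.frame(drone = "a", chrom = "LG1", kind = "CO", start = mid,
                    end = mid + 1, n_converted = 0L)
  w2 <- window_rates(ev2, c(LG1 = 2e6), n_drones = 50, window_bp = 1e5)
  # Poisson tail oracle: 200 events over 20 windows, hotspot needs >= 5x
  # the mean (>= 50 in a window); P(Pois(10) >= 50) ~ 2e-21
  expect_false(any(w2$hotspot))
})

test_that("event detection recovers simulated truth", {
  sim <- small_colony()
  fit <- fit_colony(sim$gt)
  # crossover count matches truth closely (study-density markers)
  true_co <- nrow(sim$truth$crossovers)
  expect_lt(abs(fit$rates$kept_cos - true_co) / true_co, 0.05)
  # every detected breakpoint interval contains a true breakpoint of the
  # same drone (noiseless channel)
  co <- fit$events[fit$events$kind == "CO" & !fit$events$excluded, ]
  tr <- sim$truth$crossovers
  ok <- vapply(seq_len(nrow(co)), function(i) {
    any(tr$drone == co$drone[i] & tr$chrom == co$chrom[i] &
        tr$pos >= co$start[i] & tr$pos <= co$end[i])
  }, TRUE)
  expect_gt(mean(ok), 0.95)
  # NCO tracts with >= 1 converted marker are recovered with exact
  # converted-marker counts
  nco_t <- sim$truth$tracts
  nco_t <- nco_t[nco_t$kind == "NCO" & nco_t$n_converted > 0, ]
  nco_d <- fit$events[fit$events$kind == "NCO", ]
  expect_identical(nrow(nco_d), nrow(nco_t))
  if (nrow(nco_t)) {
    m <- merge(nco_d, nco_t, by = c("drone", "chrom"))
    m <- m[m$start.x >= m$start.y - 1 & m$end.x <= m$end.y + 1, ]
    expect_identical(sort(m$n_converted.x), sort(m$n_converted.y))
  }
})

test_that("downsampled genetic length is exact at full density and
           shorter at low density", {
  sim <- small_colony()
  ms <- screen_markers(sim$gt, "I")
  ph <- phase_queen(ms, sim$gt)
  full <- genetic_length_downsample(ph, sim$gt, m = nrow(ph), reps = 1,
                                    seed = 1)
  fit <- fit_colony(sim$gt)
  expect_equal(full$mean_cM,
               100 * fit$rates$total_cos / fit$n_drones)
  low <- genetic_length_downsample(ph, sim$gt, m = 200, reps = 20,
                                   seed = 2)
  mid <- genetic_length_downsample(ph, sim$gt, m = 2000, reps = 20,
                                   seed = 3)
  expect_lte(low$mean_cM, full$mean_cM + 1e-9)
  expect_lte(low$mean_cM, mid$mean_cM + 1e-9)
  expect_error(genetic_length_downsample(ph, sim$gt, m = 1), "at least 2")
  expect_error(genetic_length_downsample(ph, sim$gt, m = nrow(ph) + 1),
               "exceeds")
})
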
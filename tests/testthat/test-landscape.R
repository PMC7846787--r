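one_contig_pseudo <- function(len, name = "pm01", comp = "c1") {
  pseudomolecule_set(data.frame(object = name, component = comp,
                                orientation = "+", length = len))
}

test_that("Marey profiles are sorted, monotone and deduplicated", {
  map <- data.frame(marker_id = c("m3", "m1", "m2", "m4"),
                    contig = "c1",
                    pos = c(3e6, 1e6, 2e6, 2e6) - 1,
                    linkage_group = "pm01",
                    cM = c(5, 0, 5, 4.2))
  pts <- build_marey_profile(map, one_contig_pseudo(4e6))
  expect_equal(pts$bp, c(1e6, 2e6, 3e6) - 1)
  expect_equal(pts$cM, c(0, 5, 5))   # duplicate bp collapsed to max cM
  expect_true(all(diff(pts$cM) >= 0))

  # chromosomes with <2 markers are excluded with a warning
  map1 <- map[1, ]
  expect_warning(out <- build_marey_profile(map1, one_contig_pseudo(4e6)),
                 "<2 markers")
  expect_equal(nrow(out), 0L)
})

test_that("marker coordinates lift through reversed placements", {
  pseudo <- pseudomolecule_set(data.frame(
    object = "pm01", component = c("c1", "c2"),
    orientation = c("+", "-"), length = c(1000L, 1000L)), gap_bp = 100)
  map <- data.frame(marker_id = c("a", "b"), contig = c("c1", "c2"),
                    pos = c(10L, 10L), linkage_group = "pm01",
                    cM = c(0, 7))
  pts <- build_marey_profile(map, pseudo)
  # c2 is reversed: local 10 sits 10 bp from the object's far end
  expect_equal(pts$bp, c(10, 1100 + 1000 - 1 - 10))
})

test_that("window counts and rates follow the stated formulas", {
  cfg <- pipeline_config()  # 1 Mbp window, 200 kbp step
  # perfectly linear Marey at 1 cM/Mbp
  map <- data.frame(marker_id = c("m1", "m2"), contig = "c1",
                    pos = c(0, 3e6 - 1), linkage_group = "pm01",
                    cM = c(0, 3))
  pts <- build_marey_profile(map, one_contig_pseudo(3e6))
  prof <- sliding_window_rate(pts, cfg, chrom_lengths = c(pm01 = 3e6))
  expect_equal(nrow(prof), floor((3e6 - 1e6) / 2e5) + 1)  # 11 windows
  expect_equal(prof$rate_cM_per_Mbp, rep(1, 11), tolerance = 1e-6)

  # a flat cM segment spanning a window gives rate 0
  map2 <- data.frame(marker_id = sprintf("m%d", 1:4), contig = "c1",
                     pos = c(0, 1e6, 2.5e6, 3e6 - 1),
                     linkage_group = "pm01", cM = c(0, 2, 2, 3))
  pts2 <- build_marey_profile(map2, one_contig_pseudo(3e6))
  prof2 <- sliding_window_rate(pts2, cfg, chrom_lengths = c(pm01 = 3e6))
  expect_equal(prof2$rate_cM_per_Mbp[prof2$window_start == 1.2e6], 0)
})

test_that("telescoping: step = window sums rates to the total cM", {
  cfg <- pipeline_config(marey_window_bp = 1e6, marey_step_bp = 1e6)
  set.seed(41)
  pos <- sort(sample(0:(5e6 - 1), 60))
  cm <- cumsum(c(0, stats::runif(59)))
  map <- data.frame(marker_id = sprintf("m%d", 1:60), contig = "c1",
                    pos = pos, linkage_group = "pm01", cM = cm)
  pts <- build_marey_profile(map, one_contig_pseudo(5e6))
  prof <- sliding_window_rate(pts, cfg, chrom_lengths = c(pm01 = 5e6))
  total <- sum(prof$rate_cM_per_Mbp * 1)  # rate x 1 Mbp widths
  # equals cM(5e6) - cM(0) under constant extrapolation at the ends
  expect_equal(total, max(cm) - min(cm), tolerance = 1e-9)
})

test_that("pericentromere calls merge low-rate windows below 0.5 cM/Mbp", {
  cfg <- pipeline_config(marey_window_bp = 1e6, marey_step_bp = 1e6)
  prof <- data.frame(chrom = "pm01",
                     window_start = (0:3) * 1e6,
                     window_end = (1:4) * 1e6,
                     rate_cM_per_Mbp = c(5, 0.4, 0.3, 6))
  out <- call_pericentromeres(prof, cfg)
  expect_equal(nrow(out), 1L)
  expect_equal(out$start, 1e6)
  expect_equal(out$end, 3e6)

  # exact boundary rate (0.5 at 2 Mbp/cM) is not pericentromeric
  prof$rate_cM_per_Mbp <- c(5, 0.5, 0.5, 6)
  expect_equal(nrow(call_pericentromeres(prof, cfg)), 0L)

  # monotone in the threshold: stricter cutoff never grows intervals
  prof$rate_cM_per_Mbp <- c(0.45, 0.35, 0.55, 0.2)
  loose <- call_pericentromeres(prof, cfg)
  strict_cfg <- pipeline_config(marey_window_bp = 1e6,
                                marey_step_bp = 1e6,
                                pericentromere_mbp_per_cm = 4)  # < 0.25
  strict <- call_pericentromeres(prof, strict_cfg)
  span <- function(x) sum(x$end - x$start)
  expect_lte(span(strict), span(loose))
})

test_that("map summary statistics match hand arithmetic", {
  map <- data.frame(marker_id = sprintf("m%d", 1:4), contig = "c1",
                    pos = c(0, 4e6, 9e6, 10e6 - 1),
                    linkage_group = "pm01", cM = c(0, 4, 10, 50))
  st <- map_summary_stats(map, one_contig_pseudo(10e6))
  expect_equal(st$total_cm, 50)
  expect_equal(st$per_chromosome$pm01$kbp_per_cm, 10e6 / 1000 / 50)  # 200
  expect_equal(st$n_markers, 4L)
  expect_equal(st$n_unique_loci, 4L)

  # loci at 0, 4, 10 cM: mean spacing 5 cM
  map3 <- map[1:3, ]
  st3 <- map_summary_stats(map3, one_contig_pseudo(10e6))
  expect_equal(st3$mean_spacing_cm, 5)

  # two co-segregating markers collapse to one locus
  map4 <- rbind(map, data.frame(marker_id = "m5", contig = "c1",
                                pos = 5e6, linkage_group = "pm01",
                                cM = 4))
  st4 <- map_summary_stats(map4, one_contig_pseudo(10e6))
  expect_equal(st4$n_unique_loci, 4L)
  expect_equal(st4$n_markers, 5L)
})

test_that("recovered Marey points track the simulated truth", {
  sim <- reference_simulation(seed = 17, n_individuals = 80,
                              n_chimeras = 0, with_linked_reads = FALSE)
  mf <- filter_variants(sim$m, sim$config)
  h <- assign_parental_haplotypes(mf, sim$config)
  gm <- attr(sim$m, "genome_marker")
  gm <- gm[sim$m$markers$marker_id %in% mf$markers$marker_id, ]
  cfg <- sim$config
  cfg$generations_of_crossover <- ril_effective_meioses(7)
  for (cn in c("chr01", "chr05")) {
    sel <- which(gm$chrom == cn)
    ord <- sel[order(gm$pos[sel])]
    est <- count_breakpoints_and_estimate_cm(h, ord, cfg)
    true_cm <- marey_cm(sim$genome, cn, gm$pos[ord])
    expect_gt(stats::cor(est$cM, true_cm, method = "spearman"), 0.99)
  }
})
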
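test_that("plateau rates solve the two-rate piecewise-linear system", {
  # lengths 3 Mbp, 100 cM, plateau fraction 0.4 at ratio 0.1:
  # r_arm * (0.6 * 3e6 + 0.1 * 0.4 * 3e6) = 100
  g <- simulate_genome(1, 3e6, 100, plateau_fraction = 0.4,
                       plateau_rate_ratio = 0.1, seed = 1)
  r_arm <- 100 / (3 * (0.6 + 0.04))           # cM per Mbp
  m <- g$marey$chr01
  expect_equal(m$y[length(m$y)], 100)          # Marey(L) = total cM
  slopes <- diff(m$y) / (diff(m$x) / 1e6)
  expect_equal(slopes, c(r_arm, 0.1 * r_arm, r_arm), tolerance = 1e-10)
  expect_equal(g$plateau$start, 0.9e6)
  expect_equal(g$plateau$end, 2.1e6)

  flat <- simulate_genome(2, c(1e6, 2e6), c(10, 30), plateau_fraction = 0,
                          seed = 1)
  expect_equal(length(flat$marey), 2L)
  expect_equal(flat$marey$chr01$y, c(0, 10))   # exactly linear
  expect_error(simulate_genome(1, 1e6, 0), "genetic length")
})

test_that("Marey evaluation and inversion are consistent and monotone", {
  g <- simulate_genome(1, 5e6, 80, plateau_fraction = 0.3,
                       plateau_rate_ratio = 0.2, seed = 3)
  bp <- seq(0, 5e6, length.out = 101)
  cm <- marey_cm(g, "chr01", bp)
  expect_true(all(diff(cm) >= 0))
  expect_equal(cm[1], 0)
  expect_equal(cm[101], 80)
  expect_equal(anchormap:::marey_bp(g, "chr01", cm), bp, tolerance = 1e-6)
})

test_that("F8 heterozygosity and crossover counts match theory", {
  g <- simulate_genome(1, 2e6, 100, marker_density = 10, seed = 5)
  pop0 <- simulate_ril_population(g, 5, n_selfing_generations = 0, seed = 5)
  h0 <- vapply(pop0$individuals, function(ind)
    ind$chr01$h1$lab[1] != ind$chr01$h2$lab[1], TRUE)
  expect_true(all(h0))  # F1 fully heterozygous

  pop <- simulate_ril_population(g, 400, 7, seed = 5)
  # residual het fraction at fixed positions ~ (1/2)^7
  pos <- seq(1e5, 1.9e6, length.out = 5)
  het <- vapply(pop$individuals, function(ind)
    mean(anchormap:::mosaic_label_at(ind$chr01$h1, pos) !=
           anchormap:::mosaic_label_at(ind$chr01$h2, pos)), 0)
  p <- mean(het)
  se <- stats::sd(het) / sqrt(length(het))
  expect_lt(abs(p - 0.5^7), 3 * se + 1e-12)

  # one meiosis on a 100 cM chromosome: mean crossovers ~ Poisson(1)
  gam_pop <- simulate_ril_population(g, 300, 1, seed = 7)
  # after one selfing generation each homolog is a fresh gamete; its
  # breakpoint count is the realised crossover count of one meiosis
  xo <- vapply(gam_pop$individuals, function(ind)
    length(ind$chr01$h1$brk), 0L)
  expect_lt(abs(mean(xo) - 1), 3 * stats::sd(xo) / sqrt(length(xo)) + 0.01)
})

test_that("crossover positions are uniform in genetic coordinates", {
  g <- simulate_genome(1, 5e6, 120, plateau_fraction = 0.4,
                       plateau_rate_ratio = 0.1, marker_density = 5,
                       seed = 11)
  pop <- simulate_ril_population(g, 600, 1, seed = 11)
  brks <- unlist(lapply(pop$individuals, function(ind)
    c(ind$chr01$h1$brk, ind$chr01$h2$brk)))
  expect_gt(length(brks), 1000)
  u <- marey_cm(g, "chr01", brks) / 120
  ks <- suppressWarnings(stats::ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("genotyping reproduces truth, missingness and determinism", {
  g <- simulate_genome(2, c(2e6, 1e6), c(60, 40), marker_density = 40,
                       seed = 2)
  tr <- fragment_genome(g, 3e5, seed = 2)
  pop <- simulate_ril_population(g, 30, 7, seed = 2)
  m0 <- genotype_population(pop, g, tr, missing_rate = 0, error_rate = 0,
                            seed = 2)
  expect_equal(unname(m0$calls[, 1:30]), unname(attr(m0, "truth")[, 1:30]))
  expect_equal(m0$parents, c("P_A", "P_B"))
  expect_true(all(m0$calls[, "P_A"] == 1L))
  expect_true(all(m0$calls[, "P_B"] == 2L))

  m4 <- genotype_population(pop, g, tr, missing_rate = 0.4,
                            error_rate = 0, seed = 2)
  frac <- mean(is.na(m4$calls[, 1:30]))
  n <- length(m4$calls[, 1:30])
  expect_lt(abs(frac - 0.4), 3 * sqrt(0.4 * 0.6 / n))

  m4b <- genotype_population(pop, g, tr, missing_rate = 0.4,
                             error_rate = 0, seed = 2)
  expect_identical(m4$calls, m4b$calls)
  expect_error(genotype_population(pop, g, tr, missing_rate = 1.2),
               "rates")
})

test_that("F8 genotype frequencies pass a chi-square goodness of fit", {
  # one marker per chromosome: 11 x 1000 independent draws
  g <- simulate_genome(11, rep(2e5, 11), rep(100, 11), marker_density = 5,
                       seed = 13)
  tr <- fragment_genome(g, 1.5e5, min_contig_bp = 10000, seed = 13)
  pop <- simulate_ril_population(g, 1000, 7, seed = 13)
  m <- genotype_population(pop, g, tr, seed = 13)
  gm <- attr(m, "genome_marker")
  pick <- vapply(split(seq_len(nrow(gm)), gm$chrom), `[[`, 0L, 1L)
  draws <- attr(m, "truth")[pick, 1:1000]
  expect_gte(length(draws), 10000)
  obs <- c(sum(draws == 1), sum(draws == 2), sum(draws == 3))
  h <- 0.5^7
  expect_gt(stats::chisq.test(obs, p = c((1 - h) / 2, (1 - h) / 2, h))$p.value,
            0.01)
})

test_that("fragmentation tiles the genome and conserves length", {
  g <- simulate_genome(3, rep(2e6, 3), rep(50, 3), marker_density = 10,
                       seed = 7)
  tr <- fragment_genome(g, 2.5e5, n_chimeras = 0, seed = 7)
  expect_equal(sum(tr$contig_len$length), sum(g$chrom$length_bp))
  expect_equal(nrow(tr$chimeras), 0L)
  # interval-arithmetic oracle: parts of each chromosome tile [0, L)
  for (i in 1:3) {
    p <- tr$parts[tr$parts$chrom == g$chrom$name[i], ]
    p <- p[order(p$src_start), ]
    expect_equal(p$src_start[1], 0)
    expect_equal(p$src_end[nrow(p)], g$chrom$length_bp[i])
    expect_equal(p$src_start[-1], p$src_end[-nrow(p)])
  }
  expect_setequal(unique(tr$parts$strand), c("+", "-"))

  tr2 <- fragment_genome(g, 2.5e5, n_chimeras = 2, seed = 7)
  expect_equal(nrow(tr2$chimeras), 2L)
  expect_equal(sum(tr2$contig_len$length), sum(g$chrom$length_bp))
  for (k in 1:2) {
    ch <- tr2$chimeras$contig[k]
    pp <- tr2$parts[tr2$parts$contig == ch, ]
    expect_equal(nrow(pp), 2L)
    expect_false(pp$chrom[1] == pp$chrom[2])
    expect_equal(tr2$chimeras$junction[k],
                 pp$src_end[1] - pp$src_start[1])
  }
  expect_error(fragment_genome(g, 3e6), "shortest chromosome")
})

test_that("linked reads project through placements strand-aware", {
  g <- simulate_genome(1, 1e6, 20, marker_density = 5, seed = 9)
  tr <- fragment_genome(g, 4e5, seed = 9)
  tab <- simulate_linked_reads(tr, g, molecule_mean_bp = 3e4,
                               molecules_per_barcode = 1,
                               n_barcodes = 300, reads_per_kbp = 0.5,
                               seed = 9)
  expect_true(all(tab$contig %in% tr$contig_len$contig))
  lens <- stats::setNames(tr$contig_len$length, tr$contig_len$contig)
  expect_true(all(tab$pos >= 0 & tab$pos < lens[tab$contig]))
  tab2 <- simulate_linked_reads(tr, g, 3e4, 1, 300, 0.5, seed = 9)
  expect_identical(as.data.frame(tab), as.data.frame(tab2))

  # a molecule straddling a junction deposits its barcode on both sides:
  # reconstruct molecule span from the truth and check the table agrees
  parts <- tr$parts[order(tr$parts$src_start), ]
  j <- parts$src_end[1]
  w <- 3e4
  near <- tab[tab$barcode %in% tab$barcode[duplicated(tab$barcode)], ]
  both <- split(near, near$barcode)
  spans <- Filter(function(s) length(unique(s$contig)) == 2, both)
  expect_gt(length(spans), 0)
  for (s in spans[1:min(3, length(spans))]) {
    ctgs <- unique(s$contig)
    p2 <- parts[parts$contig %in% ctgs, ]
    expect_equal(nrow(p2), 2L)  # adjacent on the true genome
    expect_equal(p2$src_start[2], p2$src_end[1])
  }
})

test_that("single-molecule barcode inside one contig stays together", {
  g <- simulate_genome(1, 5e5, 10, marker_density = 5, seed = 4)
  tr <- fragment_genome(g, 4e5, seed = 4)
  tab <- simulate_linked_reads(tr, g, 2e4, 1, 50, 1, seed = 4)
  per_bc <- split(tab, tab$barcode)
  expect_true(all(vapply(per_bc, function(s)
    length(unique(s$contig)) >= 1, TRUE)))
  # all reads of a one-contig barcode share that contig
  one <- Filter(function(s) length(unique(s$contig)) == 1, per_bc)
  expect_gt(length(one), 0)
})
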
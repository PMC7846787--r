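mk_aln <- function(barcode, contig, pos) {
  data.table::data.table(barcode = barcode, contig = contig,
                         pos = as.integer(pos),
                         strand = "+")
}

test_that("end windows truncate on short contigs and collect barcodes", {
  cfg <- pipeline_config()  # end_window_bp 20000
  aln <- mk_aln(c("b1", "b2", "b3"), c("cA", "cA", "cB"),
                c(5000, 95000, 16000))
  eb <- collect_end_barcodes(aln, c(cA = 100000, cB = 30000), cfg)
  eb_key <- paste(eb$contig, eb$end, eb$barcode)
  expect_true("cA head b1" %in% eb_key)
  expect_false("cA tail b1" %in% eb_key)
  expect_true("cA tail b2" %in% eb_key)
  # cB window truncated to floor(L/2) = 15000: a read at 16000 falls in
  # the tail window [15000, 30000) and only there
  expect_true("cB tail b3" %in% eb_key)
  expect_false("cB head b3" %in% eb_key)

  # hand grouping of 6 reads / 3 barcodes
  aln2 <- mk_aln(c("x", "x", "y", "y", "z", "z"),
                 c("cA", "cB", "cA", "cA", "cB", "cB"),
                 c(1000, 1000, 2000, 99000, 15000, 29000))
  eb2 <- collect_end_barcodes(aln2, c(cA = 100000, cB = 30000), cfg)
  key2 <- sort(paste(eb2$contig, eb2$end, eb2$barcode))
  # by hand: cA w=20k -> head {x,y}, tail {y}; cB w=15k -> head {x},
  # tail {z} (z's read at exactly 15000 falls in the tail window only)
  expect_equal(key2, sort(c("cA head x", "cA head y", "cA tail y",
                            "cB head x", "cB tail z")))
})

test_that("scaffold graph counts shared barcodes and filters", {
  cfg <- pipeline_config(min_shared_barcodes = 5)
  eb <- data.table::data.table(
    contig = rep(c("cA", "cB"), each = 10),
    end = rep("tail", 20),
    barcode = c(sprintf("b%02d", 1:10), sprintf("b%02d", 1:10)))
  eb$end[eb$contig == "cB"] <- "head"
  g <- build_scaffold_graph(eb, cfg)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$count, 10L)
  expect_equal(g$edges$weight, 1)

  # disjoint sets -> no edges
  eb2 <- eb; eb2$barcode[11:20] <- sprintf("c%02d", 1:10)
  expect_equal(nrow(build_scaffold_graph(eb2, cfg)$edges), 0L)

  # below min_shared_barcodes -> dropped
  eb3 <- eb[c(1:4, 11:14), ]
  expect_equal(nrow(build_scaffold_graph(eb3, cfg)$edges), 0L)

  # promiscuous barcode present at >4 ends is discarded globally
  eb4 <- data.table::data.table(
    contig = rep(c("c1", "c2", "c3", "c4", "c5"), 2),
    end = rep(c("head", "tail"), each = 5),
    barcode = "promiscuous")
  expect_equal(nrow(build_scaffold_graph(eb4, cfg)$edges), 0L)
})

toy_graph <- function(edges) {
  structure(list(edges = edges,
                 set_sizes = integer(0)), class = "scaffold_graph")
}

test_that("greedy path clustering rejects cycles and orients contigs", {
  e <- data.frame(
    contig1 = c("A", "B", "A"), end1 = c("tail", "tail", "head"),
    contig2 = c("B", "C", "C"), end2 = c("head", "head", "tail"),
    count = c(10L, 8L, 2L), weight = c(0.5, 0.4, 0.1))
  paths <- greedy_scaffold_paths(toy_graph(e), c("A", "B", "C"))
  expect_length(paths, 1L)
  expect_equal(paths[[1]]$contig, c("A", "B", "C"))
  expect_equal(paths[[1]]$orientation, c("+", "+", "+"))

  # two edges competing for one end: heavier accepted
  e2 <- data.frame(
    contig1 = c("A", "C"), end1 = c("tail", "tail"),
    contig2 = c("B", "B"), end2 = c("head", "head"),
    count = c(10L, 9L), weight = c(0.5, 0.4))
  p2 <- greedy_scaffold_paths(toy_graph(e2), c("A", "B", "C"))
  key <- vapply(p2, function(p) paste(p$contig, collapse = ","), "")
  expect_true("A,B" %in% key)
  expect_true("C" %in% key)

  # empty graph: singleton '+' paths
  p3 <- greedy_scaffold_paths(toy_graph(e2[0, ]), c("A", "B", "C"))
  expect_length(p3, 3L)
  expect_true(all(vapply(p3, function(p) p$orientation, "") == "+"))
})

test_that("tail-to-tail joins flip the downstream contig", {
  e <- data.frame(contig1 = "A", end1 = "tail", contig2 = "B",
                  end2 = "tail", count = 10L, weight = 0.5)
  p <- greedy_scaffold_paths(toy_graph(e), c("A", "B"))
  expect_length(p, 1L)
  expect_equal(p[[1]]$contig, c("A", "B"))
  expect_equal(p[[1]]$orientation, c("+", "-"))
})

test_that("path decomposition is invariant to edge order and covers contigs", {
  set.seed(12)
  ends <- expand.grid(contig = LETTERS[1:6], end = c("head", "tail"),
                      stringsAsFactors = FALSE)
  for (rep_i in 1:10) {
    pick <- sample(nrow(ends), 8)
    e <- data.frame(
      contig1 = ends$contig[pick[1:4]], end1 = ends$end[pick[1:4]],
      contig2 = ends$contig[pick[5:8]], end2 = ends$end[pick[5:8]],
      count = sample(5:50, 4), weight = round(stats::runif(4), 3))
    e <- e[e$contig1 != e$contig2, , drop = FALSE]
    p1 <- greedy_scaffold_paths(toy_graph(e), LETTERS[1:6])
    p2 <- greedy_scaffold_paths(toy_graph(e[sample(nrow(e)), ,
                                            drop = FALSE]),
                                LETTERS[1:6])
    expect_identical(lapply(p1, function(x) x[c("contig", "orientation")]),
                     lapply(p2, function(x) x[c("contig", "orientation")]))
    got <- sort(unlist(lapply(p1, `[[`, "contig")))
    expect_equal(got, LETTERS[1:6])  # each contig exactly once
  }
})

test_that("greedy acceptance is maximal: no rejected edge fits afterwards", {
  set.seed(13)
  for (rep_i in 1:15) {
    n <- sample(4:8, 1)
    cand <- t(combn(n, 2))
    take <- sample(nrow(cand), min(nrow(cand), 10))
    e <- data.frame(
      contig1 = paste0("c", cand[take, 1]),
      end1 = sample(c("head", "tail"), length(take), TRUE),
      contig2 = paste0("c", cand[take, 2]),
      end2 = sample(c("head", "tail"), length(take), TRUE),
      count = sample(5:50, length(take), TRUE),
      weight = round(stats::runif(length(take)), 3))
    contigs <- paste0("c", 1:n)
    paths <- greedy_scaffold_paths(toy_graph(e), contigs)
    # reconstruct used ends and the contig partition
    used <- unlist(lapply(paths, function(p) {
      if (nrow(p) < 2) return(character(0))
      out <- character(0)
      for (i in 1:(nrow(p) - 1)) {
        exit <- if (p$orientation[i] == "+") "tail" else "head"
        entry <- if (p$orientation[i + 1] == "+") "head" else "tail"
        out <- c(out, paste0(p$contig[i], ":", exit),
                 paste0(p$contig[i + 1], ":", entry))
      }
      out
    }))
    comp <- stats::setNames(rep(seq_along(paths),
                                vapply(paths, nrow, 0L)),
                            unlist(lapply(paths, `[[`, "contig")))
    for (i in seq_len(nrow(e))) {
      id1 <- paste0(e$contig1[i], ":", e$end1[i])
      id2 <- paste0(e$contig2[i], ":", e$end2[i])
      accepted <- id1 %in% used && id2 %in% used &&
        any(vapply(paths, function(p)
          all(c(e$contig1[i], e$contig2[i]) %in% p$contig), TRUE))
      if (!accepted) {
        # rejected edge must be infeasible now: an end in use or a cycle
        infeasible <- id1 %in% used || id2 %in% used ||
          comp[[e$contig1[i]]] == comp[[e$contig2[i]]]
        expect_true(infeasible)
      }
    }
  }
})

test_that("clean contigs yield no breaks; 1-marker contigs cannot break", {
  cfg <- pipeline_config()
  mg <- data.frame(contig = "c1", pos = c(1e4, 5e4, 9e4),
                   group = c(1L, 1L, 1L))
  aln <- mk_aln("b1", "c1", 5e4)
  expect_length(detect_misassemblies("c1", aln, mg, cfg), 0L)
  mg1 <- mg[1, , drop = FALSE]
  expect_length(detect_misassemblies("c1", aln, mg1, cfg), 0L)
  # interleaved discordant groups are unresolvable
  mgx <- data.frame(contig = "c1", pos = c(1, 2, 3, 4) * 1e4,
                    group = c(1L, 2L, 1L, 2L))
  out <- detect_misassemblies("c1", aln, mgx, cfg)
  expect_true(attr(out, "unresolvable"))
})

test_that("apply_breaks relocates markers, reads and truth parts", {
  g <- simulate_genome(2, c(1e6, 1e6), c(30, 30), marker_density = 30,
                       seed = 21)
  tr <- fragment_genome(g, 5e5, n_chimeras = 1, seed = 21)
  chim <- tr$chimeras$contig[1]
  junction <- tr$chimeras$junction[1]
  pop <- simulate_ril_population(g, 10, 7, seed = 21)
  m <- genotype_population(pop, g, tr, seed = 21)
  lens <- stats::setNames(tr$contig_len$length, tr$contig_len$contig)
  aln <- mk_aln(c("b1", "b2"), chim, c(10, max(1, junction + 10)))
  upd <- apply_breaks(stats::setNames(list(junction), chim),
                      m, aln, lens, tr)
  ids <- paste0(chim, "_", 1:2)
  expect_false(chim %in% names(upd$contig_lengths))
  expect_equal(sum(upd$contig_lengths[ids]), unname(lens[[chim]]))
  expect_true(all(upd$aln$contig %in% c(ids)))
  expect_equal(upd$aln$pos[upd$aln$contig == ids[2]], 10L)
  # truth parts now map each split fragment to one chromosome interval
  for (id in ids) {
    pp <- upd$truth$parts[upd$truth$parts$contig == id, ]
    expect_equal(nrow(pp), 1L)
    expect_equal(pp$src_end - pp$src_start,
                 unname(upd$contig_lengths[[id]]))
  }
  expect_equal(nrow(upd$truth$chimeras), 0L)
  # markers stay on the same genomic side
  mk <- upd$m$markers
  expect_true(all(mk$pos[mk$contig == ids[1]] < junction + 1))
})
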
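# Trait graph, Walktrap modules, bidirectional filter, gene mapping.

qa_stub <- function(exposure, outcome, qualified = TRUE, source = "s1") {
  data.frame(exposure = exposure, outcome = outcome, beta = 0.2, pval = 0.01,
             source_id = source, qualified = qualified,
             stringsAsFactors = FALSE)
}

test_that("build_trait_graph keeps qualified edges and collapses duplicates", {
  assoc <- rbind(qa_stub("A", "B"), qa_stub("B", "C"), qa_stub("C", "D"),
                 qa_stub("A", "B", source = "s2"),
                 qa_stub("A", "D", qualified = FALSE))
  g <- build_trait_graph(assoc)
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 3)
  ab <- igraph::E(g)[igraph::V(g)["A"] %->% igraph::V(g)["B"]]
  expect_equal(igraph::E(g)$weight[as.integer(ab)], 2)
  expect_warning(g0 <- build_trait_graph(qa_stub("A", "B", FALSE)),
                 "no qualified")
  expect_equal(igraph::vcount(g0), 0)
})

test_that("detect_modules recovers disconnected and planted structure", {
  tri <- rbind(qa_stub("a", "b"), qa_stub("b", "c"), qa_stub("c", "a"),
               qa_stub("x", "y"), qa_stub("y", "z"), qa_stub("z", "x"))
  mod <- detect_modules(build_trait_graph(tri))
  expect_length(unique(mod), 2)
  expect_equal(length(unique(mod[c("a", "b", "c")])), 1)
  expect_equal(length(unique(mod[c("x", "y", "z")])), 1)
  # two 5-cliques joined by one edge: perfect recovery (ARI = 1)
  cl1 <- t(combn(paste0("p", 1:5), 2))
  cl2 <- t(combn(paste0("q", 1:5), 2))
  edges <- rbind(qa_stub(cl1[, 1], cl1[, 2]), qa_stub(cl2[, 1], cl2[, 2]),
                 qa_stub("p1", "q1"))
  mod2 <- detect_modules(build_trait_graph(edges))
  truth <- c(rep(1, 5), rep(2, 5))
  names(truth) <- c(paste0("p", 1:5), paste0("q", 1:5))
  expect_equal(adjusted_rand_index(mod2[names(truth)], truth), 1)
  # single edge: deterministic given seed; this build yields one module {A,B}
  single <- detect_modules(build_trait_graph(qa_stub("A", "B")), seed = 1)
  expect_identical(single,
                   detect_modules(build_trait_graph(qa_stub("A", "B")),
                                  seed = 1))
  expect_equal(unname(single[c("A", "B")]), c(1L, 1L))
})

test_that("module recovery on planted two-module panels reaches high ARI", {
  ari <- vapply(1:20, function(s) {
    spec <- trait_panel_spec(list(paste0("m", 1:6), paste0("n", 1:6)),
                             intra_edge_prob = 0.9, inter_edge_prob = 0.05,
                             seed = child_seed(3100, s))
    panel <- simulate_trait_panel(spec, keep_data = FALSE)
    te <- panel$truth_edges
    if (nrow(te) == 0) return(NA_real_)
    g <- build_trait_graph(qa_stub(te$exposure, te$outcome))
    mod <- detect_modules(g)
    truth <- setNames(panel$module_table$module, panel$module_table$trait)
    adjusted_rand_index(mod[names(mod)], truth[names(mod)])
  }, numeric(1))
  expect_gte(median(ari, na.rm = TRUE), 0.9)
})

test_that("core_relationships selects exactly intra-module edges", {
  g <- build_trait_graph(rbind(qa_stub("a", "b"), qa_stub("a", "x")))
  modules <- c(a = 1L, b = 1L, x = 2L)
  core <- core_relationships(g, modules)
  expect_equal(core$exposure, "a")
  expect_equal(core$outcome, "b")
  expect_equal(core$module_id, 1L)
})

test_that("filter_bidirectional applies the inversion rule and is idempotent", {
  core <- data.frame(exposure = "T2D", outcome = "Dementia", module_id = 6L)
  fwd <- data.frame(exposure = c("T2D", "T2D"),
                    outcome = c("Dementia", "NAFLD"),
                    stringsAsFactors = FALSE)
  rev <- data.frame(exposure = c("Dementia", "NAFLD"),
                    outcome = c("T2D", "T2D"), stringsAsFactors = FALSE)
  out <- filter_bidirectional(fwd, rev, core)
  expect_equal(out$forward$outcome, "Dementia")
  expect_equal(out$reverse$exposure, "Dementia")
  # forward output is a subset of the input and refiltering changes nothing
  expect_true(all(paste(out$forward$exposure, out$forward$outcome) %in%
                    paste(fwd$exposure, fwd$outcome)))
  again <- filter_bidirectional(out$forward[names(fwd)],
                                out$reverse[names(rev)], core)
  expect_equal(again$forward$outcome, out$forward$outcome)
  # empty core empties both sides
  none <- filter_bidirectional(fwd, rev, core[0, ])
  expect_equal(nrow(none$forward), 0)
  expect_equal(nrow(none$reverse), 0)
})

test_that("snp_frequency counts per (source, direction) stratum", {
  res <- data.frame(exposure = c("A", "A", "B"), outcome = c("B", "C", "A"),
                    source_id = c("s1", "s1", "s1"),
                    direction = c("forward", "forward", "reverse"),
                    stringsAsFactors = FALSE)
  res$instruments <- list(c("a", "b"), c("a"), c("a"))
  freq <- snp_frequency(res)
  fwd <- freq[freq$direction == "forward", ]
  expect_equal(fwd$frequency[fwd$snp_id == "a"], 2L)
  expect_equal(fwd$frequency[fwd$snp_id == "b"], 1L)
  # the same SNP in the reverse stratum is a separate record
  expect_equal(sum(freq$snp_id == "a"), 2L)
  # totals equal the summed instrument-list lengths
  expect_equal(sum(freq$frequency), sum(lengths(res$instruments)))
  expect_equal(nrow(snp_frequency(res[0, ])), 0)
})

test_that("map_genes applies BED distance arithmetic with the 50 kb gate", {
  ann <- data.frame(chr = c("1", "1"), start = c(90000L, 160000L),
                    end = c(95000L, 170000L), gene = c("A", "B"),
                    stringsAsFactors = FALSE)
  snps <- data.frame(snp = c("r1", "r2", "r3"), chr = c("1", "chr1", "1"),
                     pos = c(100000L, 92000L, 220002L))
  out <- map_genes(snps, ann)
  expect_equal(out$gene, c("A", "A", NA))       # gap 5000 <= 50000; B at 60000
  expect_equal(out$distance, c(5000, 0, NA))    # inside gene -> 0
  # boundary: nearest gene exactly 50,000 away maps; 50,001 does not
  # (last gene base is end - 1 under the half-open convention)
  b1 <- map_genes(data.frame(snp = "x", chr = "1", pos = 220000L), ann)
  expect_equal(b1$gene, "B")
  expect_equal(b1$distance, 50000)
  b2 <- map_genes(data.frame(snp = "x", chr = "1", pos = 220001L), ann)
  expect_true(is.na(b2$gene))
})

test_that("map_genes agrees with a brute-force scan on random fixtures", {
  brute <- function(pos0, ann) {
    d <- ifelse(pos0 >= ann$start & pos0 < ann$end, 0,
                pmax(ann$start - pos0, pos0 - (ann$end - 1L)))
    i <- order(d, ann$start, ann$gene)[1]
    if (d[i] <= 50000) ann$gene[i] else NA_character_
  }
  withr::with_seed(99, {
    for (rep in 1:40) {
      starts <- sort(sample.int(5e5, 8))
      ann <- data.frame(chr = "1", start = starts,
                        end = starts + sample(1000:20000, 8, replace = TRUE),
                        gene = paste0("G", 1:8), stringsAsFactors = FALSE)
      ann <- ann[ann$start < ann$end, ]
      snps <- data.frame(snp = paste0("r", 1:25), chr = "1",
                         pos = sample.int(6e5, 25))
      got <- map_genes(snps, ann)
      want <- vapply(snps$pos - 1L, brute, character(1), ann = ann)
      expect_equal(got$gene, unname(want))
    }
  })
})

test_that("shared_snp_analysis computes upset-style membership", {
  res <- shared_snp_analysis(list(X = c("a", "b"), Y = c("b", "c")))
  cnt <- setNames(res$counts$n, res$counts$combination)
  expect_equal(unname(cnt[c("X", "X&Y", "Y")]), c(1L, 1L, 1L))
  ident <- shared_snp_analysis(list(X = c("a", "b"), Y = c("a", "b")))
  expect_equal(ident$counts$combination, "X&Y")
  disj <- shared_snp_analysis(list(X = "a", Y = "b"))
  expect_false("X&Y" %in% disj$counts$combination)
})
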
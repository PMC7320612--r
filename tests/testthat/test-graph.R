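# Small helper: wrap sketch records for a synthetic "input" directly.
fakeSketchSet <- function(records, lens, k = 12L, w = 4L, label = "x") {
  new("MinimizerSketchSet", records = records,
      counts = {
        tb <- table(records$hash)
        setNames(as.integer(tb), names(tb))
      },
      seqLengths = lens, k = k, w = w, label = label)
}

test_that("anchor selection keeps hashes unique in and shared by all inputs", {
  set.seed(31)
  # target: hash h2 twice -> excluded; h1 once in both -> anchor
  recT <- data.frame(seq_id = c("c1", "c1", "c2"), pos = c(0L, 40L, 3L),
                     strand = "+", hash = c("aa", "bb", "bb"),
                     stringsAsFactors = FALSE)
  recR <- data.frame(seq_id = c("r1", "r1"), pos = c(5L, 50L), strand = "+",
                     hash = c("aa", "bb"), stringsAsFactors = FALSE)
  st <- fakeSketchSet(recT, c(c1 = 100L, c2 = 50L), label = "target")
  sr <- fakeSketchSet(recR, c(r1 = 200L), label = "reference")
  expect_identical(selectAnchors(list(st, sr)), "aa")

  # brute-force set algebra on random synthetic assemblies
  for (i in 1:5) {
    t <- Biostrings::DNAStringSet(setNames(
      replicate(3, randomDnaStr(600)), paste0("t", 1:3)))
    r <- Biostrings::DNAStringSet(setNames(
      replicate(2, randomDnaStr(800)), paste0("r", 1:2)))
    skT <- sketchAssembly(t, k = 9, w = 3)
    skR <- sketchAssembly(r, k = 9, w = 3)
    got <- tryCatch(selectAnchors(list(skT, skR)), error = function(e) character(0))
    uT <- names(minimizerCounts(skT))[minimizerCounts(skT) == 1L]
    uR <- names(minimizerCounts(skR))[minimizerCounts(skR) == 1L]
    expect_setequal(got, intersect(uT, uR))
  }

  # disjoint inputs: actionable fatal error
  recA <- data.frame(seq_id = "a", pos = 0L, strand = "+", hash = "aa",
                     stringsAsFactors = FALSE)
  recB <- data.frame(seq_id = "b", pos = 0L, strand = "+", hash = "bb",
                     stringsAsFactors = FALSE)
  expect_error(selectAnchors(list(fakeSketchSet(recA, c(a = 40L)),
                                  fakeSketchSet(recB, c(b = 40L)))),
               "no anchor")
})

test_that("edge weights sum the supporting input weights", {
  h <- sprintf("%02d", 1:5)
  mk <- function(order, seqid) data.frame(seq_id = seqid,
                                          pos = seq(0L, by = 20L,
                                                    length.out = length(order)),
                                          strand = "+", hash = order,
                                          stringsAsFactors = FALSE)
  filtered <- list(target = mk(h, "t1"), reference = mk(h, "r1"))
  g <- buildMinimizerGraph(filtered, weights = c(1, 2))
  expect_equal(igraph::ecount(g), 4L)
  expect_true(all(igraph::E(g)$weight == 3))
  expect_true(all(igraph::E(g)$support == "target,reference"))

  # adjacency present only in the reference
  filtered2 <- list(target = mk(h[1:2], "t1"),
                    reference = mk(h[c(1, 2, 4)], "r1"))
  g2 <- buildMinimizerGraph(filtered2, weights = c(1, 2))
  et <- graphToEdgeTable(g2)
  refOnly <- et[et$a == "02" & et$b == "04", ]
  expect_equal(refOnly$weight, 2)
  eid <- igraph::get_edge_ids(g2, c("02", "04"))
  expect_equal(igraph::E(g2)$support[eid], "reference")
})

test_that("edge multiset equals a brute-force pairwise adjacency scan", {
  set.seed(37)
  for (i in 1:5) {
    hashes <- sprintf("%016x", sample.int(2^30, 12))
    ins <- list(
      target = data.frame(seq_id = "t", pos = seq_len(12L) * 10L,
                          strand = "+", hash = sample(hashes),
                          stringsAsFactors = FALSE),
      reference = data.frame(seq_id = "r", pos = seq_len(12L) * 10L,
                             strand = "+", hash = sample(hashes),
                             stringsAsFactors = FALSE))
    wts <- c(1, 2)
    g <- buildMinimizerGraph(ins, wts)
    # brute force
    exp <- list()
    for (lab in names(ins)) {
      h <- ins[[lab]]$hash
      for (j in seq_len(length(h) - 1L)) {
        key <- paste(min(h[j], h[j + 1L]), max(h[j], h[j + 1L]))
        exp[[key]] <- c(exp[[key]], lab)
      }
    }
    et <- graphToEdgeTable(g)
    expect_setequal(paste(et$a, et$b), names(exp))
    for (r in seq_len(nrow(et))) {
      key <- paste(et$a[r], et$b[r])
      expect_equal(et$weight[r],
                   sum(wts[match(exp[[key]], names(ins))]))
    }
  }
})

test_that("global weight filter removes exactly the edges below threshold", {
  set.seed(41)
  edges <- randomEdgeTable(30, 60)
  g <- edgeTableToGraph(edges)
  expect_equal(igraph::ecount(filterGraphGlobal(g, 0)), nrow(edges))
  expect_equal(igraph::ecount(filterGraphGlobal(g, max(edges$weight) + 1)), 0L)
  expect_equal(igraph::vcount(filterGraphGlobal(g, max(edges$weight) + 1)),
               igraph::vcount(g))
  n <- stats::median(edges$weight)
  expect_equal(sortEdgeTable(graphToEdgeTable(filterGraphGlobal(g, n))),
               sortEdgeTable(edges[edges$weight >= n, ]))
})

test_that("branch resolution follows the ascending-threshold rule", {
  # weights {1,2,3}: removing <2 leaves degree 2
  star <- data.frame(a = c("n", "n", "n"), b = c("x", "y", "z"),
                     weight = c(1, 2, 3), stringsAsFactors = FALSE)
  g <- resolveBranchNodes(edgeTableToGraph(star))
  et <- graphToEdgeTable(g)
  expect_equal(sort(et$weight), c(2, 3))

  # all ties {2,2,2}: every incident edge removed, node isolated
  tie <- data.frame(a = c("n", "n", "n"), b = c("x", "y", "z"),
                    weight = c(2, 2, 2), stringsAsFactors = FALSE)
  g2 <- resolveBranchNodes(edgeTableToGraph(tie))
  expect_equal(igraph::ecount(g2), 0L)
  expect_equal(igraph::vcount(g2), 4L)
})

test_that("branch resolution matches the independent oracle on random graphs", {
  set.seed(43)
  for (i in 1:20) {
    edges <- randomEdgeTable(sample(10:40, 1), sample(20:80, 1))
    got <- graphToEdgeTable(resolveBranchNodes(edgeTableToGraph(edges)))
    exp <- sortEdgeTable(oracleResolveBranches(edges))
    expect_equal(got, exp)
    g <- resolveBranchNodes(edgeTableToGraph(edges))
    expect_true(all(igraph::degree(g) <= 2L))
  }
})

test_that("cycle breaking opens each cycle at its minimum-weight edge", {
  cyc <- data.frame(a = c("a", "b", "c"), b = c("b", "c", "a"),
                    weight = c(5, 1, 3), stringsAsFactors = FALSE)
  g <- breakCycles(edgeTableToGraph(cyc))
  et <- graphToEdgeTable(g)
  expect_equal(sort(et$weight), c(3, 5))

  # tie: lexicographically smallest pair goes
  cyc2 <- data.frame(a = c("a", "b", "c"), b = c("b", "c", "a"),
                     weight = c(2, 2, 2), stringsAsFactors = FALSE)
  et2 <- graphToEdgeTable(breakCycles(edgeTableToGraph(cyc2)))
  expect_equal(nrow(et2), 2L)
  expect_false(any(et2$a == "a" & et2$b == "b"))
})

test_that("full filtering yields paths/isolated nodes and conserves edge data", {
  set.seed(47)
  for (i in 1:5) {
    edges <- randomEdgeTable(25, 50)
    g0 <- edgeTableToGraph(edges)
    g <- filterMinimizerGraph(g0, 2)
    expect_true(all(igraph::degree(g) <= 2L))
    comp <- igraph::components(g)
    for (ci in seq_len(comp$no)) {
      vs <- which(comp$membership == ci)
      # a path has |E| = |V| - 1 within the component
      sub <- igraph::induced_subgraph(g, vs)
      expect_equal(igraph::ecount(sub), igraph::vcount(sub) - 1L)
    }
    # surviving edges keep their original weight and support
    et <- graphToEdgeTable(g)
    key0 <- paste(edges$a, edges$b)
    expect_true(all(paste(et$a, et$b) %in% key0))
    expect_equal(et$weight, edges$weight[match(paste(et$a, et$b), key0)])
  }
})

test_that("graph construction is deterministic", {
  set.seed(53)
  t <- Biostrings::DNAStringSet(c(t1 = randomDnaStr(2000)))
  r <- Biostrings::DNAStringSet(c(r1 = randomDnaStr(2500)))
  build <- function() {
    skT <- sketchAssembly(t, k = 11, w = 5)
    skR <- sketchAssembly(r, k = 11, w = 5)
    anchors <- selectAnchors(list(skT, skR))
    f <- list(target = filterSketchToAnchors(skT, anchors),
              reference = filterSketchToAnchors(skR, anchors))
    graphToEdgeTable(buildMinimizerGraph(f, c(1, 2)))
  }
  expect_identical(build(), build())
})
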
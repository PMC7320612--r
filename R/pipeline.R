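#' Scaffold a target assembly against one or more references
#'
#' End-to-end driver: sketches every input, selects anchor minimizers shared
#' uniquely by all inputs, builds the weighted minimizer graph, filters it
#' into linear paths (global weight threshold, branch resolution, cycle
#' breaking), translates the paths into ordered and oriented contig runs,
#' cuts putative chimeric contigs (unless `noCut`), estimates gap sizes from
#' the reference and materializes the scaffold sequences.
#'
#' @param target FASTA path (plain or gzip) or [Biostrings::DNAStringSet]:
#'   the draft assembly to improve.
#' @param references list (or single value) of FASTA paths / DNAStringSets:
#'   the guiding assemblies.
#' @param targetWeight weight of target-supported adjacencies (default 1).
#' @param referenceWeights weights of the references (recycled; default 2).
#'   Reference weights are expected to exceed the target weight so the
#'   target is fitted to the reference structure; a warning is emitted
#'   otherwise.
#' @param k k-mer length (2--32), default 32.
#' @param w minimizer window size in consecutive k-mers, default 1000.
#' @param n global edge weight threshold; default: the minimum reference
#'   weight, so reference-supported adjacencies survive by default.
#' @param minGap minimum emitted gap size in bases (default 20).
#' @param noCut if TRUE, never cut input contigs; a contig contested between
#'   paths is assigned whole to the run with the majority of its anchors.
#' @param labels optional character vector of input labels
#'   (target first, then references) used in edge support sets.
#' @param verbose log per-stage counts to stderr.
#' @return a [ScaffoldingResult-class].
#' @examples
#' \donttest{
#' fx <- generateFixture(fixtureSpec(nChromosomes = 1, chromLength = 200000,
#'                                   seed = 7))
#' res <- scaffoldAssemblies(fx$target, fx$reference, k = 24, w = 100)
#' res
#' }
#' @export
scaffoldAssemblies <- function(target, references,
                               targetWeight = 1, referenceWeights = 2,
                               k = 32L, w = 1000L, n = NULL,
                               minGap = 20L, noCut = FALSE,
                               labels = NULL, verbose = FALSE) {
  if (!is.list(references)) references <- list(references)
  stopifnot(length(references) >= 1L, targetWeight >= 0,
            all(referenceWeights >= 0), minGap >= 0)
  referenceWeights <- rep_len(referenceWeights, length(references))
  if (any(referenceWeights <= targetWeight))
    warning("reference weight(s) do not exceed the target weight; the ",
            "target will not be preferentially fitted to the reference")
  if (is.null(labels))
    labels <- c("target", if (length(references) == 1L) "reference" else
      paste0("reference", seq_along(references)))
  stopifnot(length(labels) == length(references) + 1L,
            !anyDuplicated(labels))
  log <- function(...) if (verbose) message("[mxscaff] ", sprintf(...))

  targetSeqs <- if (is.character(target))
    Biostrings::readDNAStringSet(target) else target
  names(targetSeqs) <- sub("\\s.*$", "", names(targetSeqs))

  sketches <- c(list(sketchAssembly(target, k = k, w = w, label = labels[1])),
                lapply(seq_along(references), function(i)
                  sketchAssembly(references[[i]], k = k, w = w,
                                 label = labels[i + 1L])))
  names(sketches) <- labels
  log("sketched %d inputs: %s minimizers",
      length(sketches),
      paste(vapply(sketches, function(s) nrow(sketchRecords(s)), numeric(1)),
            collapse = "/"))

  anchors <- selectAnchors(sketches)
  log("%d anchor minimizers", length(anchors))
  filtered <- lapply(sketches, filterSketchToAnchors, anchors = anchors)

  weights <- c(targetWeight, referenceWeights)
  g0 <- buildMinimizerGraph(filtered, weights)
  if (is.null(n)) n <- min(referenceWeights)
  g <- filterGraphGlobal(g0, n)
  log("global filter (n=%s): %d -> %d edges", format(n),
      igraph::ecount(g0), igraph::ecount(g))
  e1 <- igraph::ecount(g)
  g <- resolveBranchNodes(g)
  log("branch resolution removed %d edges", e1 - igraph::ecount(g))
  e2 <- igraph::ecount(g)
  g <- breakCycles(g)
  log("cycle breaking removed %d edges", e2 - igraph::ecount(g))

  pathsNodes <- extractLinearPaths(g)
  log("%d linear paths", length(pathsNodes))

  tIdx <- anchorIndex(filtered[[1L]])
  rIdx <- lapply(filtered[-1L], anchorIndex)

  dropped <- 0L
  runList <- list()
  for (pi in seq_along(pathsNodes)) {
    tr <- translateToContigRuns(pathsNodes[[pi]], tIdx)
    dropped <- dropped + tr$dropped
    if (nrow(tr$runs)) {
      tr$runs$path <- pi
      tr$runs$idx <- seq_len(nrow(tr$runs))
      runList[[length(runList) + 1L]] <- tr$runs
    }
  }
  runs <- if (length(runList)) do.call(rbind, runList) else
    data.frame(contig = character(), orient = character(),
               n_anchors = integer(), first_pos = integer(),
               last_pos = integer(), min_pos = integer(),
               max_pos = integer(), first_hash = character(),
               last_hash = character(), path = integer(), idx = integer(),
               stringsAsFactors = FALSE)

  contigLengths <- setNames(Biostrings::width(targetSeqs), names(targetSeqs))
  cut <- cutContigs(runs, contigLengths, k = k, noCut = noCut)
  runs <- orientPathsForward(cut$runs)
  log("%d runs after cutting (%d cuts, %d single-anchor blocks dropped)",
      nrow(runs), nrow(cut$cuts), dropped)

  gaps <- list()
  for (pid in unique(runs$path)) {
    rr <- runs[runs$path == pid, , drop = FALSE]
    rr <- rr[order(rr$idx), , drop = FALSE]
    gaps[[as.character(pid)]] <- estimateGapSizes(rr, rIdx, k = k,
                                                  minGap = minGap)
  }

  em <- emitScaffolds(runs, gaps, targetSeqs)
  unplaced <- emitUnplaced(targetSeqs, runs)
  report <- buildPlacementReport(em$scaffolds, unplaced,
                                 nCuts = nrow(cut$cuts),
                                 nDroppedSingleAnchor = dropped)
  log("placed fraction: %.4f",
      report$value[report$metric == "fraction_placed"])

  new("ScaffoldingResult",
      placed = em$scaffolds,
      unplaced = unplaced,
      paths = em$paths,
      agp = buildAgp(em$paths, unplaced),
      cuts = cut$cuts,
      report = report,
      graph = g,
      rawGraph = g0,
      params = list(k = as.integer(k), w = as.integer(w), n = n,
                    minGap = as.integer(minGap), noCut = noCut,
                    weights = setNames(weights, labels)))
}

#' @rdname ScaffoldingResult-class
#' @export
setMethod("scaffolds", "ScaffoldingResult", function(x) x@placed)

#' @rdname ScaffoldingResult-class
#' @export
setMethod("unplacedSequences", "ScaffoldingResult", function(x) x@unplaced)

#' @rdname ScaffoldingResult-class
#' @export
setMethod("scaffoldPaths", "ScaffoldingResult", function(x) x@paths)

#' @rdname ScaffoldingResult-class
#' @export
setMethod("agpTable", "ScaffoldingResult", function(x) x@agp)

#' @rdname ScaffoldingResult-class
#' @export
setMethod("contigCuts", "ScaffoldingResult", function(x) x@cuts)

#' @rdname ScaffoldingResult-class
#' @export
setMethod("placementReport", "ScaffoldingResult", function(x) x@report)

#' @rdname ScaffoldingResult-class
#' @param raw return the pre-filter graph instead of the filtered one.
#' @param ... unused.
#' @export
setMethod("minimizerGraph", "ScaffoldingResult",
          function(x, raw = FALSE, ...) if (raw) x@rawGraph else x@graph)

setMethod("show", "ScaffoldingResult", function(object) {
  rep <- object@report
  v <- function(m) rep$value[rep$metric == m]
  cat(sprintf(paste0(
    "ScaffoldingResult: %d scaffold(s), %d unplaced piece(s)\n",
    "  placed bases: %g (%.1f%%), gap bases: %g, cuts: %d\n",
    "  params: k=%d w=%d n=%s minGap=%d noCut=%s\n"),
    length(object@placed), length(object@unplaced),
    v("placed_bases"), 100 * v("fraction_placed"), v("gap_bases"),
    nrow(object@cuts),
    object@params$k, object@params$w, format(object@params$n),
    object@params$minGap, object@params$noCut))
})

#' Write all output files of a scaffolding run
#'
#' Writes `<prefix>.scaffolds.fa` (placed scaffolds followed by unplaced
#' pieces, or two files with `splitUnplaced`), `<prefix>.path`,
#' `<prefix>.dot`, `<prefix>.report.tsv` and optionally `<prefix>.agp`.
#'
#' @param result a [ScaffoldingResult-class].
#' @param prefix output path prefix.
#' @param agp write the AGP v2.1 file.
#' @param rawDot export the pre-filter graph instead of the filtered one.
#' @param splitUnplaced write unplaced pieces to
#'   `<prefix>.unplaced.fa` instead of appending to the scaffold FASTA.
#' @return named character vector of written paths, invisibly.
#' @export
writeScaffoldOutputs <- function(result, prefix, agp = TRUE, rawDot = FALSE,
                                 splitUnplaced = FALSE) {
  stopifnot(is(result, "ScaffoldingResult"))
  out <- c(fasta = paste0(prefix, ".scaffolds.fa"),
           path = paste0(prefix, ".path"),
           dot = paste0(prefix, ".dot"),
           report = paste0(prefix, ".report.tsv"))
  if (splitUnplaced) {
    writeScaffoldFasta(scaffolds(result), out["fasta"])
    out["unplaced"] <- paste0(prefix, ".unplaced.fa")
    writeScaffoldFasta(unplacedSequences(result), out["unplaced"])
  } else {
    up <- unplacedSequences(result)
    S4Vectors::mcols(up) <- NULL
    merged <- c(scaffolds(result), up)
    writeScaffoldFasta(merged, out["fasta"])
  }
  writePathFile(scaffoldPaths(result), unplacedSequences(result), out["path"])
  writeDot(minimizerGraph(result, raw = rawDot), out["dot"])
  write.table(placementReport(result), out["report"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (agp) {
    out["agp"] <- paste0(prefix, ".agp")
    writeAgp(agpTable(result), out["agp"])
  }
  invisible(out)
}
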
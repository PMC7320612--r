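#' Score a scaffolding result against fixture ground truth
#'
#' Maps every emitted run back to its source fragment via the layout table
#' and computes order, orientation, chimera-cutting and gap metrics. A
#' fragment's relative strand is `+` when its run orientation matches the
#' recorded truth orientation; a scaffold and its reverse complement are
#' equivalent, so correctness is judged on relative strands and relative
#' order only.
#'
#' A junction (adjacent run pair in one scaffold) is correct when both runs
#' map to the same chromosome, share the same relative strand, and their
#' truth order indices are consecutive in the direction implied by that
#' strand.
#'
#' @param result a [ScaffoldingResult-class].
#' @param fixture fixture list from [generateFixture()].
#' @return list of metrics: `n_placed_fragments`, `n_junctions`,
#'   `n_correct_junctions`, `junction_precision` (correct / emitted),
#'   `junction_recall` (correct / true adjacencies), `orientation_accuracy`,
#'   `n_chimeras`, `n_chimeras_cut`, `chimera_cut_sensitivity`,
#'   `chimera_displacement_ok` (all cuts within half the local anchor
#'   spacing of the true junction), `gap_errors` (estimated minus true, one
#'   per correct junction), `ng50_before`, `ng50_after`, `fraction_placed`.
#' @export
scoreScaffolds <- function(result, fixture) {
  layout <- fixture$layout
  k <- result@params$k

  mapRun <- function(contig, start, end) {
    rows <- which(layout$fragment_id == contig)
    if (length(rows) == 0L) return(NA_integer_)
    ov <- pmin(layout$target_end[rows], end) -
      pmax(layout$target_start[rows], start)
    rows[which.max(ov)]
  }

  # per-scaffold sequences of (chrom, truth index, relative strand)
  placedRows <- integer(0)
  placedStrand <- character(0)
  junTotal <- 0L
  junCorrect <- 0L
  gapErrors <- numeric(0)
  orientOk <- 0L
  orientN <- 0L
  for (p in scaffoldPaths(result)) {
    rr <- p$runs
    li <- vapply(seq_len(nrow(rr)), function(j)
      mapRun(rr$contig[j], rr$start[j], rr$end[j]), integer(1))
    strand <- ifelse(layout$orientation[li] == rr$orient, "+", "-")
    placedRows <- c(placedRows, li)
    placedStrand <- c(placedStrand, strand)
    n <- length(li)
    orientN <- orientN + n
    orientOk <- orientOk + max(sum(strand == "+"), sum(strand == "-"))
    if (n < 2L) next
    for (j in seq_len(n - 1L)) {
      junTotal <- junTotal + 1L
      sameChrom <- layout$source_chrom[li[j]] == layout$source_chrom[li[j + 1L]]
      sameStrand <- strand[j] == strand[j + 1L]
      step <- layout$target_order_index[li[j + 1L]] -
        layout$target_order_index[li[j]]
      good <- sameChrom && sameStrand &&
        step == (if (strand[j] == "+") 1L else -1L)
      if (good) {
        junCorrect <- junCorrect + 1L
        lo <- min(layout$target_order_index[li[j]],
                  layout$target_order_index[li[j + 1L]])
        trueGap <- layout$gap_after[layout$target_order_index == lo]
        gapErrors <- c(gapErrors, p$gaps[j] - trueGap)
      }
    }
  }

  # true adjacencies: consecutive fragments on one chromosome
  byChrom <- table(layout$source_chrom)
  trueJunctions <- sum(pmax(byChrom - 1L, 0L))

  # chimeras
  chimIds <- unique(layout$fragment_id[layout$part == 2L])
  cuts <- contigCuts(result)
  nCut <- 0L
  dispOk <- TRUE
  for (cid in chimIds) {
    cp <- cuts$pos[cuts$contig == cid]
    if (length(cp) == 0L) next
    truth <- layout$target_end[layout$fragment_id == cid &
                               layout$part == 1L]
    disp <- min(abs(cp - truth))
    nCut <- nCut + 1L
    # local anchor spacing: unanchored span between the runs flanking the
    # nearest cut
    best <- cp[which.min(abs(cp - truth))]
    # local anchor spacing = unanchored span between the flanking anchors of
    # the two pieces meeting at this cut (pieces may lie in different
    # scaffolds)
    allRuns <- do.call(rbind, lapply(scaffoldPaths(result), `[[`, "runs"))
    cr <- allRuns[allRuns$contig == cid, , drop = FALSE]
    leftMax <- suppressWarnings(max(pmax(cr$first_pos, cr$last_pos)[cr$end == best]))
    rightMin <- suppressWarnings(min(pmin(cr$first_pos, cr$last_pos)[cr$start == best]))
    if (is.finite(leftMax) && is.finite(rightMin)) {
      spacing <- rightMin - (leftMax + k)
      if (disp > spacing / 2 + 1) dispOk <- FALSE
    }
  }

  genomeSize <- sum(Biostrings::width(fixture$reference))
  ngBefore <- assemblyNG50(Biostrings::width(fixture$target), genomeSize)
  ngAfter <- assemblyNG50(c(Biostrings::width(scaffolds(result)),
                            Biostrings::width(unplacedSequences(result))),
                          genomeSize)
  rep <- placementReport(result)

  list(n_placed_fragments = orientN,
       n_junctions = junTotal,
       n_correct_junctions = junCorrect,
       junction_precision = if (junTotal) junCorrect / junTotal else NA_real_,
       junction_recall = if (trueJunctions) junCorrect / trueJunctions else
         NA_real_,
       orientation_accuracy = if (orientN) orientOk / orientN else NA_real_,
       n_chimeras = length(chimIds),
       n_chimeras_cut = nCut,
       chimera_cut_sensitivity = if (length(chimIds)) nCut / length(chimIds)
         else NA_real_,
       chimera_displacement_ok = dispOk,
       gap_errors = gapErrors,
       ng50_before = ngBefore,
       ng50_after = ngAfter,
       fraction_placed = rep$value[rep$metric == "fraction_placed"])
}
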
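#' Materialize scaffold sequences from runs and gaps
#'
#' Concatenates, per path, the oriented target subsequences of each run with
#' `N`-runs of the estimated gap length between them. Scaffold identifiers
#' are deterministic (`mxs_000001`, ...), assigned in decreasing order of
#' scaffold length (ties broken by first contig then start).
#'
#' @param runs data.frame of all runs with `path`, `idx`, `contig`,
#'   `orient`, `start`, `end` (0-based half-open).
#' @param gaps named list: for each path id (as character), integer vector
#'   of gap sizes between consecutive runs.
#' @param target [Biostrings::DNAStringSet] of target contigs.
#' @return list with `scaffolds` (DNAStringSet) and `paths` (list of
#'   `scaffold_id`, `runs`, `gaps`), both in scaffold id order.
#' @export
emitScaffolds <- function(runs, gaps, target) {
  ids <- sub("\\s.*$", "", names(target))
  names(target) <- ids
  pieces <- list()
  for (pid in sort(unique(runs$path))) {
    rr <- runs[runs$path == pid, , drop = FALSE]
    rr <- rr[order(rr$idx), , drop = FALSE]
    gp <- gaps[[as.character(pid)]]
    stopifnot(length(gp) == nrow(rr) - 1L)
    segs <- character(nrow(rr))
    for (j in seq_len(nrow(rr))) {
      if (rr$end[j] > length(target[[rr$contig[j]]]))
        stop("internal error: run interval exceeds contig length for ",
             rr$contig[j])
      s <- Biostrings::subseq(target[[rr$contig[j]]],
                              rr$start[j] + 1L, rr$end[j])
      if (rr$orient[j] == "-") s <- Biostrings::reverseComplement(s)
      segs[j] <- as.character(s)
    }
    seq <- segs[1L]
    if (nrow(rr) > 1L)
      for (j in 2:nrow(rr))
        seq <- paste0(seq, strrep("N", gp[j - 1L]), segs[j])
    pieces[[length(pieces) + 1L]] <-
      list(seq = seq, runs = rr, gaps = gp)
  }
  if (length(pieces) == 0L) {
    return(list(scaffolds = Biostrings::DNAStringSet(), paths = list()))
  }
  lens <- vapply(pieces, function(p) nchar(p$seq), numeric(1))
  firstc <- vapply(pieces, function(p) p$runs$contig[1L], character(1))
  firsts <- vapply(pieces, function(p) p$runs$start[1L], numeric(1))
  ord <- order(-lens, firstc, firsts)
  pieces <- pieces[ord]
  scafs <- Biostrings::DNAStringSet(vapply(pieces, `[[`, character(1), "seq"))
  names(scafs) <- sprintf("mxs_%06d", seq_along(pieces))
  paths <- lapply(seq_along(pieces), function(i) {
    rr <- pieces[[i]]$runs
    rownames(rr) <- NULL
    list(scaffold_id = names(scafs)[i],
         runs = rr[, c("contig", "orient", "start", "end", "n_anchors",
                       "first_pos", "last_pos", "first_hash", "last_hash")],
         gaps = as.integer(pieces[[i]]$gaps))
  })
  list(scaffolds = scafs, paths = paths)
}

#' Emit target sequence not placed in any scaffold
#'
#' Every target base not covered by an emitted run is output exactly once:
#' whole contigs with no run as `unplaced_<id>`, leftover cut pieces as
#' `unplaced_<id>_<start>_<end>` (0-based half-open interval in the name).
#'
#' @param target [Biostrings::DNAStringSet] of target contigs.
#' @param runs data.frame of emitted runs (`contig`, `start`, `end`).
#' @return DNAStringSet of unplaced sequence; the source contig and its
#'   0-based half-open interval are recorded in `mcols` (`contig`, `start`,
#'   `end`).
#' @export
emitUnplaced <- function(target, runs) {
  ids <- sub("\\s.*$", "", names(target))
  names(target) <- ids
  seqs <- character(0)
  nms <- character(0)
  mcontig <- character(0)
  mstart <- integer(0)
  mend <- integer(0)
  addPiece <- function(ctg, s, e, whole = FALSE) {
    seqs <<- c(seqs, as.character(Biostrings::subseq(target[[ctg]], s + 1L, e)))
    nms <<- c(nms, if (whole) paste0("unplaced_", ctg) else
      sprintf("unplaced_%s_%d_%d", ctg, s, e))
    mcontig <<- c(mcontig, ctg)
    mstart <<- c(mstart, s)
    mend <<- c(mend, e)
  }
  for (ctg in ids) {
    len <- length(target[[ctg]])
    rr <- runs[runs$contig == ctg, , drop = FALSE]
    if (nrow(rr) == 0L) {
      addPiece(ctg, 0L, len, whole = TRUE)
      next
    }
    rr <- rr[order(rr$start), , drop = FALSE]
    cur <- 0L
    for (j in seq_len(nrow(rr))) {
      if (rr$start[j] > cur) addPiece(ctg, cur, rr$start[j])
      cur <- max(cur, rr$end[j])
    }
    if (cur < len) addPiece(ctg, cur, len)
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- nms
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    contig = mcontig, start = mstart, end = mend)
  out
}

#' Placement summary of a scaffolding run
#'
#' @param placed,unplaced DNAStringSets of the two outputs.
#' @param nCuts number of misassembly cuts applied.
#' @param nDroppedSingleAnchor number of single-anchor contig blocks that
#'   could not be oriented and were left unplaced.
#' @return data.frame with `metric` and `value` columns; fraction placed is
#'   placed bases over total target bases.
#' @export
buildPlacementReport <- function(placed, unplaced, nCuts = 0L,
                                 nDroppedSingleAnchor = 0L) {
  pb <- sum(Biostrings::width(placed))
  # N gap bases are scaffold padding, not target sequence
  gapb <- if (length(placed))
    sum(Biostrings::letterFrequency(placed, "N")) else 0
  ub <- sum(Biostrings::width(unplaced))
  tot <- (pb - gapb) + ub
  data.frame(
    metric = c("n_scaffolds", "n_unplaced_pieces", "placed_bases",
               "gap_bases", "unplaced_bases", "total_target_bases",
               "fraction_placed", "n_cuts", "n_single_anchor_blocks_dropped"),
    value = c(length(placed), length(unplaced), pb - gapb, gapb, ub, tot,
              if (tot > 0) (pb - gapb) / tot else 0,
              nCuts, nDroppedSingleAnchor),
    stringsAsFactors = FALSE)
}

#' NG50 of a set of sequence lengths
#'
#' The length L such that sequences of length >= L cover at least half of
#' `genomeSize`.
#'
#' @param lengths numeric vector of sequence lengths.
#' @param genomeSize reference genome size in bases.
#' @return NG50 in bases (0 if the lengths never reach half the genome).
#' @export
assemblyNG50 <- function(lengths, genomeSize) {
  lengths <- sort(as.numeric(lengths), decreasing = TRUE)
  cum <- cumsum(lengths)
  i <- which(cum >= genomeSize / 2)
  if (length(i) == 0L) return(0)
  lengths[i[1L]]
}
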
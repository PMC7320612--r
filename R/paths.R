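#' Build an anchor position index from filtered sketch records
#'
#' Maps every anchor hash of one input to its (sequence, position). Valid
#' only after anchor filtering, which guarantees each hash occurs once.
#'
#' @param records data.frame from [filterSketchToAnchors()].
#' @return data.frame with rownames = hash and columns `seq_id`, `pos`.
#' @export
anchorIndex <- function(records) {
  if (anyDuplicated(records$hash))
    stop("anchor index requires unique hashes; filter to anchors first")
  out <- records[, c("seq_id", "pos")]
  rownames(out) <- records$hash
  out
}

# Split an integer vector into maximal strictly monotone segments.
# Returns a list of index vectors; singletons come out as length-1 segments.
.monotoneSegments <- function(p) {
  n <- length(p)
  if (n <= 1L) return(list(seq_len(n)))
  s <- sign(diff(p))
  segs <- list()
  beg <- 1L
  for (i in seq_len(n - 1L)) {
    if (i >= beg + 1L && s[i] != s[beg]) {   # direction set by first diff
      segs[[length(segs) + 1L]] <- beg:i
      beg <- i + 1L
    }
  }
  segs[[length(segs) + 1L]] <- beg:n
  segs
}

#' Translate a minimizer path into oriented contig runs
#'
#' Maximal consecutive path nodes mapping to the same target contig become
#' one run; orientation is `+` if target positions increase along the path
#' and `-` if they decrease. Blocks whose positions are not monotone are
#' split at each monotonicity break. Blocks left with a single anchor cannot
#' be oriented and are dropped (counted, reported upstream).
#'
#' @param nodes character vector of hashes (one linear path).
#' @param targetIdx anchor index of the target ([anchorIndex()]).
#' @return list with `runs` (data.frame: contig, orient, n_anchors,
#'   first_pos, last_pos, min_pos, max_pos, first_hash, last_hash; positions
#'   are target k-mer starts in path order) and `dropped` (number of
#'   single-anchor blocks discarded).
#' @export
translateToContigRuns <- function(nodes, targetIdx) {
  stopifnot(all(nodes %in% rownames(targetIdx)))
  contig <- targetIdx[nodes, "seq_id"]
  pos <- targetIdx[nodes, "pos"]
  blocks <- rle(contig)
  ends <- cumsum(blocks$lengths)
  begs <- ends - blocks$lengths + 1L
  runs <- list()
  dropped <- 0L
  for (b in seq_along(begs)) {
    idx <- begs[b]:ends[b]
    for (seg in .monotoneSegments(pos[idx])) {
      si <- idx[seg]
      if (length(si) < 2L) { dropped <- dropped + 1L; next }
      p <- pos[si]
      runs[[length(runs) + 1L]] <- data.frame(
        contig = contig[si[1L]],
        orient = if (p[length(p)] > p[1L]) "+" else "-",
        n_anchors = length(si),
        first_pos = p[1L], last_pos = p[length(p)],
        min_pos = min(p), max_pos = max(p),
        first_hash = nodes[si[1L]], last_hash = nodes[si[length(si)]],
        stringsAsFactors = FALSE)
    }
  }
  runs <- if (length(runs)) do.call(rbind, runs) else
    data.frame(contig = character(), orient = character(),
               n_anchors = integer(), first_pos = integer(),
               last_pos = integer(), min_pos = integer(),
               max_pos = integer(), first_hash = character(),
               last_hash = character(), stringsAsFactors = FALSE)
  list(runs = runs, dropped = dropped)
}

#' Assign contig intervals to runs, cutting at putative misassemblies
#'
#' A contig whose anchors fall into two or more runs (across any paths) is
#' treated as a putative misassembly. In the default mode it is cut between
#' adjacent used anchor intervals, at the midpoint of the unanchored region
#' separating them; outermost pieces extend to the contig ends. With
#' `noCut = TRUE` no contig is cut: a contested contig is assigned whole to
#' the run containing the majority of its anchors (ties: larger anchor span
#' in target bases, then the run earliest in deterministic path order) and
#' removed from the others.
#'
#' @param runs data.frame of all runs of all paths, with columns `path`
#'   (integer path id), `idx` (order within path) plus the columns of
#'   [translateToContigRuns()].
#' @param contigLengths named integer vector.
#' @param k k-mer size (anchor intervals span `pos .. pos + k`).
#' @param noCut logical.
#' @return list with `runs` (with `start`, `end` 0-based half-open columns
#'   filled; contested/empty runs removed) and `cuts` (data.frame `contig`,
#'   `pos`).
#' @export
cutContigs <- function(runs, contigLengths, k, noCut = FALSE) {
  runs$start <- NA_integer_
  runs$end <- NA_integer_
  cuts <- data.frame(contig = character(), pos = integer(),
                     stringsAsFactors = FALSE)
  drop <- logical(nrow(runs))
  for (ctg in unique(runs$contig)) {
    ri <- which(runs$contig == ctg)
    len <- contigLengths[[ctg]]
    if (length(ri) == 1L) {
      runs$start[ri] <- 0L
      runs$end[ri] <- len
      next
    }
    if (noCut) {
      span <- runs$max_pos[ri] + k - runs$min_pos[ri]
      ord <- order(-runs$n_anchors[ri], -span, runs$path[ri], runs$idx[ri])
      win <- ri[ord[1L]]
      runs$start[win] <- 0L
      runs$end[win] <- len
      drop[setdiff(ri, win)] <- TRUE
      next
    }
    ord <- ri[order(runs$min_pos[ri])]
    cutpos <- integer(0)
    for (j in seq_len(length(ord) - 1L)) {
      lo <- runs$max_pos[ord[j]] + k      # end of previous used interval
      hi <- runs$min_pos[ord[j + 1L]]     # start of next used interval
      cp <- as.integer(floor((lo + hi) / 2))
      cp <- max(cp, 1L)
      cp <- min(cp, len - 1L)
      if (length(cutpos)) cp <- max(cp, cutpos[length(cutpos)])
      cutpos <- c(cutpos, cp)
    }
    bounds <- c(0L, cutpos, len)
    for (j in seq_along(ord)) {
      s <- bounds[j]; e <- bounds[j + 1L]
      if (s >= e) { drop[ord[j]] <- TRUE; next }
      runs$start[ord[j]] <- s
      runs$end[ord[j]] <- e
    }
    cuts <- rbind(cuts, data.frame(contig = ctg, pos = cutpos,
                                   stringsAsFactors = FALSE))
  }
  runs <- runs[!drop, , drop = FALSE]
  # renumber run order within each path, preserving relative order
  runs <- runs[order(runs$path, runs$idx), , drop = FALSE]
  runs$idx <- unlist(lapply(split(seq_len(nrow(runs)), runs$path),
                            seq_along), use.names = FALSE)
  rownames(runs) <- NULL
  list(runs = runs, cuts = cuts)
}

#' Orient each scaffold so most placed bases are forward
#'
#' A scaffold and its reverse complement are equivalent; to make the output
#' deterministic and keep perfect inputs forward, any path whose
#' reverse-oriented runs cover more bases than its forward runs is flipped
#' (run order reversed, orientations inverted, anchor bookkeeping swapped).
#'
#' @param runs data.frame of runs with intervals assigned.
#' @return the re-oriented runs data.frame.
#' @export
orientPathsForward <- function(runs) {
  if (nrow(runs) == 0L) return(runs)
  out <- lapply(split(runs, runs$path), function(rr) {
    rr <- rr[order(rr$idx), , drop = FALSE]
    bases <- rr$end - rr$start
    if (sum(bases[rr$orient == "-"]) <= sum(bases[rr$orient == "+"]))
      return(rr)
    rr <- rr[rev(seq_len(nrow(rr))), , drop = FALSE]
    rr$orient <- ifelse(rr$orient == "+", "-", "+")
    tmp <- rr$first_pos; rr$first_pos <- rr$last_pos; rr$last_pos <- tmp
    tmp <- rr$first_hash; rr$first_hash <- rr$last_hash; rr$last_hash <- tmp
    rr$idx <- seq_len(nrow(rr))
    rr
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Target bases from the start of the boundary anchor to the run's trailing
# edge, measured in scaffold orientation.
.tailBases <- function(run, k) {
  if (run$orient == "+") run$end - run$last_pos else run$last_pos + k - run$start
}

# Target bases from the run's leading edge to the start of its first anchor,
# measured in scaffold orientation.
.headBases <- function(run, k) {
  if (run$orient == "+") run$first_pos - run$start else run$end - run$first_pos - k
}

#' Estimate gap sizes between adjacent runs from the reference
#'
#' For each junction, the reference distance between the boundary anchors
#' (last anchor of the left run, first anchor of the right run) is reduced by
#' the unanchored target flanks on either side of the junction; the result is
#' clamped below at `minGap`. If the boundary anchors lie on different
#' reference sequences in every reference, the gap falls back to `minGap`.
#'
#' @param runs runs data.frame of one path, ordered by `idx`.
#' @param refIdx list of anchor indices ([anchorIndex()]), one per reference
#'   input, in input order.
#' @param k k-mer size.
#' @param minGap minimum emitted gap (bases).
#' @return integer vector of `nrow(runs) - 1` gap sizes.
#' @export
estimateGapSizes <- function(runs, refIdx, k, minGap = 20L) {
  nr <- nrow(runs)
  if (nr < 2L) return(integer(0))
  gaps <- integer(nr - 1L)
  for (j in seq_len(nr - 1L)) {
    a <- runs$last_hash[j]
    b <- runs$first_hash[j + 1L]
    gap <- minGap
    for (ridx in refIdx) {
      if (!(a %in% rownames(ridx)) || !(b %in% rownames(ridx))) next
      if (ridx[a, "seq_id"] != ridx[b, "seq_id"]) next
      refspan <- abs(ridx[b, "pos"] - ridx[a, "pos"])
      est <- refspan - .tailBases(runs[j, ], k) - .headBases(runs[j + 1L, ], k)
      gap <- max(as.integer(est), minGap)
      break
    }
    gaps[j] <- gap
  }
  gaps
}
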
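#' MinimizerSketchSet: ordered minimizer sketches of one assembly
#'
#' Holds the position-ordered minimizer records of every sequence of one
#' input assembly, together with per-hash occurrence counts and sequence
#' lengths. Hashes are strand-neutral 64-bit values stored as 16-character
#' lowercase hex strings, so that lexicographic (radix) order equals numeric
#' order.
#'
#' @slot records data.frame with columns `seq_id`, `pos` (0-based k-mer
#'   start), `strand` (`+`/`-`: which strand's k-mer achieved the canonical
#'   hash) and `hash`; sorted by `seq_id` then `pos`.
#' @slot counts named integer vector: occurrence count of each hash across
#'   all sketches of this assembly.
#' @slot seqLengths named integer vector of sequence lengths.
#' @slot k k-mer length in bases.
#' @slot w window size in number of consecutive k-mers.
#' @slot label input label (used in graph edge support sets).
#'
#' @exportClass MinimizerSketchSet
setClass("MinimizerSketchSet",
  representation(
    records = "data.frame",
    counts = "integer",
    seqLengths = "integer",
    k = "integer",
    w = "integer",
    label = "character"
  )
)

setValidity("MinimizerSketchSet", function(object) {
  msg <- character()
  need <- c("seq_id", "pos", "strand", "hash")
  if (!all(need %in% names(object@records)))
    msg <- c(msg, sprintf("records must have columns %s",
                          paste(need, collapse = ", ")))
  if (length(object@k) != 1L || object@k < 2L || object@k > 32L)
    msg <- c(msg, "k must be a single integer in [2, 32]")
  if (length(object@w) != 1L || object@w < 1L)
    msg <- c(msg, "w must be a single positive integer")
  if (nrow(object@records) > 0) {
    rec <- object@records
    if (!all(rec$seq_id %in% names(object@seqLengths)))
      msg <- c(msg, "records refer to sequences missing from seqLengths")
    bypos <- split(rec$pos, rec$seq_id)
    if (!all(vapply(bypos, function(p) all(diff(p) > 0), logical(1))))
      msg <- c(msg, "positions must be strictly increasing within a sequence")
    maxpos <- vapply(split(rec$pos, rec$seq_id), max, numeric(1))
    lim <- object@seqLengths[names(maxpos)] - object@k
    if (any(maxpos > lim))
      msg <- c(msg, "a minimizer position exceeds len(sequence) - k")
  }
  if (length(msg)) msg else TRUE
})

#' ScaffoldingResult: output container of a scaffolding run
#'
#' @slot placed [Biostrings::DNAStringSet] of scaffold sequences
#'   (N-runs at gaps).
#' @slot unplaced [Biostrings::DNAStringSet] of target sequence not placed in
#'   any scaffold (whole contigs or leftover cut pieces), ids prefixed
#'   `unplaced_`.
#' @slot paths list, one element per scaffold: `scaffold_id`, `runs`
#'   (data.frame with `contig`, `orient`, `start`, `end`, 0-based half-open)
#'   and `gaps` (integer vector, length `nrow(runs) - 1`).
#' @slot agp data.frame of AGP v2.1 component lines (9 columns).
#' @slot cuts data.frame of applied misassembly cuts (`contig`, `pos`).
#' @slot report data.frame placement report (metric / value).
#' @slot graph post-filter minimizer graph (igraph).
#' @slot rawGraph pre-filter minimizer graph (igraph).
#' @slot params list of run parameters (k, w, n, minGap, noCut, weights).
#'
#' @exportClass ScaffoldingResult
setClass("ScaffoldingResult",
  representation(
    placed = "ANY",
    unplaced = "ANY",
    paths = "list",
    agp = "data.frame",
    cuts = "data.frame",
    report = "data.frame",
    graph = "ANY",
    rawGraph = "ANY",
    params = "list"
  )
)

setValidity("ScaffoldingResult", function(object) {
  msg <- character()
  if (!is(object@placed, "DNAStringSet"))
    msg <- c(msg, "placed must be a DNAStringSet")
  if (!is(object@unplaced, "DNAStringSet"))
    msg <- c(msg, "unplaced must be a DNAStringSet")
  if (length(object@placed) != length(object@paths))
    msg <- c(msg, "one paths entry per placed scaffold required")
  if (length(msg)) msg else TRUE
})
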
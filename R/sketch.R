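#' Strand-neutral hash of k-mers
#'
#' Computes the canonical 64-bit hash of each k-mer: the packed 2-bit
#' encoding of the k-mer is XORed with a fixed seed and mixed with the
#' splitmix64 finalizer, the same is done for the reverse complement, and
#' the smaller of the two values wins. The hash is therefore identical for a
#' k-mer and its reverse complement; the returned strand records which
#' strand's k-mer achieved it (`+` on ties, e.g. palindromes).
#'
#' @param kmers character vector of DNA strings, each of one length k with
#'   2 <= k <= 32. Case is ignored.
#' @return data.frame with columns `hash` (16-char lowercase hex; radix
#'   string order equals numeric 64-bit order) and `strand` (`+`/`-`).
#'   K-mers containing non-ACGT characters yield `NA` in both columns.
#' @examples
#' canonicalHash(c("ACGTACGT", "ACGTACGT"))
#' @export
canonicalHash <- function(kmers) {
  canonical_hash_cpp(as.character(kmers))
}

#' Ordered minimizer sketch of a single sequence
#'
#' Slides a window of `w` consecutive k-mers along the sequence and records,
#' for each window, the k-mer with the minimum canonical hash (leftmost on
#' ties). Consecutive windows selecting the same k-mer collapse into one
#' record, so records are strictly increasing in position. K-mers covering a
#' non-ACGT base are assigned an infinite hash and can never be selected; a
#' window with no valid k-mer yields no minimizer.
#'
#' @param sequence DNA string (character scalar or [Biostrings::DNAString]).
#' @param seqId sequence identifier attached to each record.
#' @param k k-mer length (2--32).
#' @param w window size in number of consecutive k-mers (>= 1).
#' @return data.frame with columns `seq_id`, `pos` (0-based k-mer start),
#'   `strand`, `hash`. Sequences shorter than `k + w - 1` yield zero rows.
#' @examples
#' computeSketch("ACGTACGTTTACGGA", "s1", k = 4, w = 3)
#' @export
computeSketch <- function(sequence, seqId = "seq", k = 32L, w = 1000L) {
  sequence <- as.character(sequence)
  stopifnot(length(sequence) == 1L, nzchar(seqId))
  rec <- sketch_sequence_cpp(sequence, as.integer(k), as.integer(w))
  data.frame(seq_id = rep(seqId, nrow(rec)), rec, stringsAsFactors = FALSE)
}

#' Sketch every sequence of an assembly
#'
#' Reads an assembly (FASTA, optionally gzip-compressed, or an in-memory
#' [Biostrings::DNAStringSet]) and computes an ordered minimizer sketch per
#' sequence, plus per-hash occurrence counts across the whole assembly.
#'
#' @param x path to a FASTA/FASTA.gz file, or a `DNAStringSet`.
#' @param k,w sketch parameters, see [computeSketch()].
#' @param label input label used downstream in graph edge support sets;
#'   defaults to the file name (or `"assembly"` for in-memory input).
#' @return a [MinimizerSketchSet-class] object.
#' @export
sketchAssembly <- function(x, k = 32L, w = 1000L, label = NULL) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("cannot read FASTA file: ", x)
    seqs <- tryCatch(Biostrings::readDNAStringSet(x),
                     error = function(e) stop("malformed FASTA '", x, "': ",
                                              conditionMessage(e)))
    if (is.null(label)) label <- basename(x)
  } else if (is(x, "DNAStringSet")) {
    seqs <- x
    if (is.null(label)) label <- "assembly"
  } else {
    stop("x must be a FASTA path or a DNAStringSet")
  }
  # seq_id = header token before first whitespace
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate sequence identifiers in ", label, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(seqs) <- ids
  if (length(seqs) == 0L)
    warning("empty assembly: ", label)

  recs <- lapply(seq_along(seqs), function(i) {
    computeSketch(seqs[[i]], ids[i], k = k, w = w)
  })
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(seq_id = character(), pos = integer(),
               strand = character(), hash = character(),
               stringsAsFactors = FALSE)
  counts <- if (nrow(records)) table(records$hash) else integer()
  counts <- setNames(as.integer(counts), names(counts))
  new("MinimizerSketchSet",
      records = records,
      counts = counts,
      seqLengths = setNames(Biostrings::width(seqs), ids),
      k = as.integer(k), w = as.integer(w),
      label = label)
}

#' @rdname MinimizerSketchSet-class
#' @export
setMethod("sketchRecords", "MinimizerSketchSet", function(x) x@records)

#' @rdname MinimizerSketchSet-class
#' @export
setMethod("minimizerCounts", "MinimizerSketchSet", function(x) x@counts)

#' @rdname MinimizerSketchSet-class
#' @export
setMethod("kmerSize", "MinimizerSketchSet", function(x) x@k)

#' @rdname MinimizerSketchSet-class
#' @export
setMethod("windowSize", "MinimizerSketchSet", function(x) x@w)

#' @rdname MinimizerSketchSet-class
#' @export
setMethod("sequenceLengths", "MinimizerSketchSet", function(x) x@seqLengths)

#' @rdname MinimizerSketchSet-class
#' @export
setMethod("inputLabel", "MinimizerSketchSet", function(x) x@label)

setMethod("show", "MinimizerSketchSet", function(object) {
  cat(sprintf(
    "MinimizerSketchSet '%s': %d sequence(s), %d minimizer record(s) (k=%d, w=%d)\n",
    object@label, length(object@seqLengths), nrow(object@records),
    object@k, object@w))
})

#' Dump sketch records as TSV
#'
#' Writes columns seq_id, pos, strand, hash, one row per minimizer record.
#'
#' @param x a [MinimizerSketchSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSketchTsv <- function(x, path) {
  stopifnot(is(x, "MinimizerSketchSet"))
  write.table(sketchRecords(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
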
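#' Write sequences as 60-column FASTA
#'
#' @param x DNAStringSet.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeScaffoldFasta <- function(x, path) {
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' Build the AGP v2.1 table of a scaffolding result
#'
#' One W line per contig run, one N line per gap (gap_type "scaffold",
#' linkage "yes", evidence "align_genus"), plus one W line per unplaced
#' piece. All coordinates are 1-based inclusive; the 0-based half-open
#' internal coordinates are converted here and nowhere else.
#'
#' @param paths list of path descriptors ([emitScaffolds()]).
#' @param unplaced DNAStringSet from [emitUnplaced()] (with interval
#'   metadata in `mcols`).
#' @return data.frame with the nine AGP columns. For N lines the
#'   component_id/component_beg/component_end/orientation columns hold
#'   gap_length / "scaffold" / "yes" / "align_genus".
#' @export
buildAgp <- function(paths, unplaced) {
  rows <- list()
  addRow <- function(...) rows[[length(rows) + 1L]] <<-
      data.frame(..., stringsAsFactors = FALSE)
  for (p in paths) {
    beg <- 1L
    part <- 1L
    nr <- nrow(p$runs)
    for (j in seq_len(nr)) {
      r <- p$runs[j, ]
      span <- r$end - r$start
      addRow(object = p$scaffold_id, object_beg = beg,
             object_end = beg + span - 1L, part_number = part,
             component_type = "W", component_id = r$contig,
             component_beg = as.character(r$start + 1L),
             component_end = as.character(r$end),
             orientation = r$orient)
      beg <- beg + span
      part <- part + 1L
      if (j < nr) {
        g <- p$gaps[j]
        addRow(object = p$scaffold_id, object_beg = beg,
               object_end = beg + g - 1L, part_number = part,
               component_type = "N", component_id = as.character(g),
               component_beg = "scaffold", component_end = "yes",
               orientation = "align_genus")
        beg <- beg + g
        part <- part + 1L
      }
    }
  }
  if (length(unplaced)) {
    meta <- S4Vectors::mcols(unplaced)
    for (i in seq_along(unplaced)) {
      span <- meta$end[i] - meta$start[i]
      addRow(object = names(unplaced)[i], object_beg = 1L,
             object_end = span, part_number = 1L,
             component_type = "W", component_id = meta$contig[i],
             component_beg = as.character(meta$start[i] + 1L),
             component_end = as.character(meta$end[i]),
             orientation = "+")
    }
  }
  if (length(rows) == 0L)
    return(data.frame(object = character(), object_beg = integer(),
                      object_end = integer(), part_number = integer(),
                      component_type = character(), component_id = character(),
                      component_beg = character(), component_end = character(),
                      orientation = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Write an AGP v2.1 file
#'
#' @param agp data.frame from [buildAgp()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAgp <- function(agp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  if (nrow(agp))
    write.table(agp, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  invisible(path)
}

#' Read an AGP v2.1 file
#'
#' @param path AGP file.
#' @return data.frame with the same columns as [buildAgp()].
#' @export
readAgp <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  if (length(ln) == 0L) return(buildAgp(list(), Biostrings::DNAStringSet()))
  f <- strsplit(ln, "\t", fixed = TRUE)
  if (any(lengths(f) != 9L)) stop("malformed AGP: expected 9 columns in ", path)
  m <- do.call(rbind, f)
  data.frame(object = m[, 1], object_beg = as.integer(m[, 2]),
             object_end = as.integer(m[, 3]), part_number = as.integer(m[, 4]),
             component_type = m[, 5], component_id = m[, 6],
             component_beg = m[, 7], component_end = m[, 8],
             orientation = m[, 9], stringsAsFactors = FALSE)
}

#' Rebuild scaffold sequences from an AGP table and the target assembly
#'
#' @param agp data.frame ([buildAgp()] / [readAgp()]).
#' @param target DNAStringSet of target contigs.
#' @return DNAStringSet of the described objects, in AGP order.
#' @export
rematerializeAgp <- function(agp, target) {
  ids <- sub("\\s.*$", "", names(target))
  names(target) <- ids
  objs <- unique(agp$object)
  seqs <- vapply(objs, function(ob) {
    part <- agp[agp$object == ob, , drop = FALSE]
    part <- part[order(part$part_number), , drop = FALSE]
    segs <- vapply(seq_len(nrow(part)), function(i) {
      r <- part[i, ]
      if (r$component_type == "N") return(strrep("N", as.integer(r$component_id)))
      s <- Biostrings::subseq(target[[r$component_id]],
                              as.integer(r$component_beg),
                              as.integer(r$component_end))
      if (r$orientation == "-") s <- Biostrings::reverseComplement(s)
      as.character(s)
    }, character(1))
    paste(segs, collapse = "")
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- objs
  out
}

#' Write the path file
#'
#' One line per output sequence: its id, a TAB, then space-separated tokens
#' `contig[start-end]orient` (0-based half-open interval) interleaved with
#' `gapN` tokens (N = gap size in bases). This is the normative dialect for
#' this package. Unplaced pieces are written as single-token lines.
#'
#' @param paths list of path descriptors ([emitScaffolds()]).
#' @param unplaced DNAStringSet with interval metadata in `mcols`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePathFile <- function(paths, unplaced, path) {
  lines <- character(0)
  for (p in paths) {
    toks <- character(0)
    for (j in seq_len(nrow(p$runs))) {
      r <- p$runs[j, ]
      toks <- c(toks, sprintf("%s[%d-%d]%s", r$contig, r$start, r$end,
                              r$orient))
      if (j < nrow(p$runs)) toks <- c(toks, sprintf("gap%d", p$gaps[j]))
    }
    lines <- c(lines, paste0(p$scaffold_id, "\t", paste(toks, collapse = " ")))
  }
  if (length(unplaced)) {
    meta <- S4Vectors::mcols(unplaced)
    for (i in seq_along(unplaced))
      lines <- c(lines, sprintf("%s\t%s[%d-%d]+", names(unplaced)[i],
                                meta$contig[i], meta$start[i], meta$end[i]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a path file
#'
#' @param path path file written by [writePathFile()].
#' @return list, one element per line: `object`, `runs` (data.frame with
#'   contig, start, end, orient) and `gaps` (integer vector).
#' @export
readPathFile <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(ln)]
  lapply(ln, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) != 2L) stop("malformed path line: ", l)
    toks <- strsplit(f[2], " ", fixed = TRUE)[[1]]
    isgap <- grepl("^gap[0-9]+$", toks)
    m <- regmatches(toks[!isgap],
                    regexec("^(.*)\\[([0-9]+)-([0-9]+)\\]([+-])$",
                            toks[!isgap]))
    if (any(lengths(m) != 5L)) stop("malformed run token in: ", l)
    runs <- data.frame(
      contig = vapply(m, `[`, character(1), 2L),
      start = as.integer(vapply(m, `[`, character(1), 3L)),
      end = as.integer(vapply(m, `[`, character(1), 4L)),
      orient = vapply(m, `[`, character(1), 5L),
      stringsAsFactors = FALSE)
    list(object = f[1], runs = runs,
         gaps = as.integer(sub("^gap", "", toks[isgap])))
  })
}

#' Rebuild sequences from a parsed path file
#'
#' @param parsed list from [readPathFile()].
#' @param target DNAStringSet of target contigs.
#' @return DNAStringSet, one sequence per path-file line.
#' @export
rematerializePaths <- function(parsed, target) {
  ids <- sub("\\s.*$", "", names(target))
  names(target) <- ids
  seqs <- vapply(parsed, function(p) {
    segs <- vapply(seq_len(nrow(p$runs)), function(j) {
      r <- p$runs[j, ]
      s <- Biostrings::subseq(target[[r$contig]], r$start + 1L, r$end)
      if (r$orient == "-") s <- Biostrings::reverseComplement(s)
      as.character(s)
    }, character(1))
    out <- segs[1L]
    if (length(segs) > 1L)
      for (j in 2:length(segs))
        out <- paste0(out, strrep("N", p$gaps[j - 1L]), segs[j])
    out
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- vapply(parsed, `[[`, character(1), "object")
  out
}

#' Export a minimizer graph in Graphviz dot format
#'
#' Nodes are hash values; edges carry `weight` and comma-joined `support`
#' attributes so the level of assembly support of every join is inspectable.
#'
#' @param g minimizer graph (igraph).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDot <- function(g, path) {
  lines <- c("graph minimizer_graph {")
  lines <- c(lines, sprintf("  \"%s\";",
                            sort(igraph::V(g)$name, method = "radix")))
  if (igraph::ecount(g) > 0) {
    ends <- igraph::ends(g, igraph::E(g))
    a <- pmin(ends[, 1], ends[, 2])
    b <- pmax(ends[, 1], ends[, 2])
    wt <- igraph::E(g)$weight
    sup <- igraph::E(g)$support
    ord <- order(a, b, method = "radix")
    lines <- c(lines, sprintf(
      "  \"%s\" -- \"%s\" [weight=%s, support=\"%s\"];",
      a[ord], b[ord], format(wt[ord], trim = TRUE, scientific = FALSE),
      sup[ord]))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Parse a dot file written by [writeDot()]
#'
#' Minimal reader used for validation/round-trip checks; not a general
#' Graphviz parser.
#'
#' @param path dot file.
#' @return list with `nodes` (character) and `edges` (data.frame a, b,
#'   weight, support).
#' @export
readDot <- function(path) {
  ln <- trimws(readLines(path))
  em <- regmatches(ln, regexec(
    "^\"([0-9a-f]+)\" -- \"([0-9a-f]+)\" \\[weight=([0-9.eE+-]+), support=\"([^\"]*)\"\\];$",
    ln))
  edges <- em[lengths(em) == 5L]
  nm <- regmatches(ln, regexec("^\"([0-9a-f]+)\";$", ln))
  nodes <- vapply(nm[lengths(nm) == 2L], `[`, character(1), 2L)
  list(nodes = nodes,
       edges = data.frame(
         a = vapply(edges, `[`, character(1), 2L),
         b = vapply(edges, `[`, character(1), 3L),
         weight = as.numeric(vapply(edges, `[`, character(1), 4L)),
         support = vapply(edges, `[`, character(1), 5L),
         stringsAsFactors = FALSE))
}
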
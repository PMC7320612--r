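#' Specification of a synthetic reference/target fixture
#'
#' Describes a deterministic synthetic scaffolding problem: random uniform
#' DNA chromosomes (the reference) fragmented into a shuffled, optionally
#' reverse-complemented and mutated target assembly, with optional chimeric
#' (misassembled) contigs and deleted spacers producing known true gaps.
#' Identical spec + seed always yields an identical fixture.
#'
#' @param nChromosomes number of reference chromosomes.
#' @param chromLength chromosome length in bases.
#' @param fragmentMean,fragmentSd fragment length distribution (normal,
#'   truncated below at 500 bp).
#' @param revcompProb per-fragment probability of reverse complementing the
#'   target contig (chimeric contigs are kept forward so their internal
#'   junction coordinate stays interpretable).
#' @param shuffle shuffle target contig order.
#' @param nChimeras number of chimeric contigs, each joining two fragments
#'   from different chromosomes (requires `nChromosomes >= 2`).
#' @param spacerDeletions data.frame(chrom, pos, length): delete `length`
#'   bases starting at `pos` (0-based, chromosome coordinates) from the
#'   target's coverage, forcing a fragment boundary with a known true gap.
#' @param snpRate per-base substitution probability applied to target
#'   contigs (models cross-individual/species divergence).
#' @param seed RNG seed.
#' @return a list of class `mxscaffFixtureSpec`.
#' @export
fixtureSpec <- function(nChromosomes = 2L, chromLength = 1000000L,
                        fragmentMean = 20000L, fragmentSd = 5000L,
                        revcompProb = 0.5, shuffle = TRUE,
                        nChimeras = 0L, spacerDeletions = NULL,
                        snpRate = 0, seed = 42L) {
  stopifnot(nChromosomes >= 1L, chromLength > 0L,
            fragmentMean > 0L, fragmentSd >= 0,
            revcompProb >= 0, revcompProb <= 1,
            snpRate >= 0, snpRate <= 1, nChimeras >= 0L)
  if (fragmentMean >= chromLength)
    stop("infeasible spec: fragment mean must be smaller than the ",
         "chromosome length")
  if (nChimeras > 0L && nChromosomes < 2L)
    stop("chimeras require at least 2 chromosomes")
  if (!is.null(spacerDeletions))
    stopifnot(all(c("chrom", "pos", "length") %in% names(spacerDeletions)))
  structure(list(nChromosomes = as.integer(nChromosomes),
                 chromLength = as.integer(chromLength),
                 fragmentMean = fragmentMean, fragmentSd = fragmentSd,
                 revcompProb = revcompProb, shuffle = isTRUE(shuffle),
                 nChimeras = as.integer(nChimeras),
                 spacerDeletions = spacerDeletions,
                 snpRate = snpRate, seed = as.integer(seed)),
            class = "mxscaffFixtureSpec")
}

# Evaluate expr under a private RNG state, restoring the caller's state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(expr)
}

.randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.revcompChr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

.mutate <- function(s, rate) {
  if (rate <= 0) return(s)
  n <- nchar(s)
  hits <- which(runif(n) < rate)
  if (length(hits) == 0L) return(s)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  for (i in hits)
    v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  paste(v, collapse = "")
}

#' Generate a synthetic reference/target fixture with ground truth
#'
#' @param spec a [fixtureSpec()].
#' @return list with `reference` (DNAStringSet, `chr1`...), `target`
#'   (DNAStringSet, `ctg_0001`...), `layout` (ground-truth table: one row
#'   per source fragment with `fragment_id`, `part`, `source_chrom`,
#'   `source_start`, `source_end` (0-based half-open), `orientation`,
#'   `target_order_index`, `target_start`, `target_end`, `gap_after` — true
#'   deleted bases before the next fragment on the same chromosome) and
#'   `spec`.
#' @export
generateFixture <- function(spec) {
  stopifnot(inherits(spec, "mxscaffFixtureSpec"))
  .withSeed(spec$seed, {
    chroms <- vapply(seq_len(spec$nChromosomes), function(i)
      .randomDna(spec$chromLength), character(1))
    names(chroms) <- paste0("chr", seq_len(spec$nChromosomes))

    # fragment intervals per chromosome
    frags <- list()
    for (ci in seq_along(chroms)) {
      cur <- 0L
      len <- nchar(chroms[ci])
      while (cur < len) {
        fl <- max(500L, as.integer(round(rnorm(1, spec$fragmentMean,
                                               spec$fragmentSd))))
        e <- min(cur + fl, len)
        frags[[length(frags) + 1L]] <- list(chrom = names(chroms)[ci],
                                            start = cur, end = e,
                                            gap_after = 0L)
        cur <- e
      }
      frags[[length(frags)]]$gap_after <- NA_integer_  # chromosome end
    }

    # spacer deletions: split the containing fragment and drop the spacer
    if (!is.null(spec$spacerDeletions)) {
      for (d in seq_len(nrow(spec$spacerDeletions))) {
        dc <- as.character(spec$spacerDeletions$chrom[d])
        dp <- as.integer(spec$spacerDeletions$pos[d])
        dl <- as.integer(spec$spacerDeletions$length[d])
        hit <- which(vapply(frags, function(f)
          f$chrom == dc && f$start + 200L <= dp &&
            dp + dl + 200L <= f$end, logical(1)))
        if (length(hit) == 0L)
          stop("spacer deletion at ", dc, ":", dp,
               " does not fall inside a fragment interior")
        f <- frags[[hit[1L]]]
        left <- list(chrom = f$chrom, start = f$start, end = dp,
                     gap_after = dl)
        right <- list(chrom = f$chrom, start = dp + dl, end = f$end,
                      gap_after = f$gap_after)
        frags <- append(frags[-hit[1L]], list(left, right), after = hit[1L] - 1L)
      }
    }

    # deterministic truth order along the genome
    fdf <- do.call(rbind, lapply(frags, function(f)
      data.frame(chrom = f$chrom, start = f$start, end = f$end,
                 gap_after = f$gap_after, stringsAsFactors = FALSE)))
    fdf <- fdf[order(fdf$chrom, fdf$start), , drop = FALSE]
    fdf$idx <- seq_len(nrow(fdf))

    # chimeras: pair interior fragments from different chromosomes
    interior <- which(!is.na(fdf$gap_after) & fdf$start > 0L)
    chimPairs <- list()
    if (spec$nChimeras > 0L) {
      pool <- split(interior, fdf$chrom[interior])
      if (length(pool) < 2L) stop("not enough interior fragments for chimeras")
      a <- sample(pool[[1L]], spec$nChimeras)
      b <- sample(pool[[2L]], spec$nChimeras)
      chimPairs <- Map(c, a, b)
    }
    chimMembers <- unlist(chimPairs)
    plain <- setdiff(seq_len(nrow(fdf)), chimMembers)

    # contigs: plain fragments (orientable) + chimeras (forward)
    contigs <- list()
    for (i in plain) {
      s <- substr(chroms[[fdf$chrom[i]]], fdf$start[i] + 1L, fdf$end[i])
      o <- if (runif(1) < spec$revcompProb) "-" else "+"
      if (o == "-") s <- .revcompChr(s)
      contigs[[length(contigs) + 1L]] <- list(
        seq = s,
        rows = data.frame(part = 1L, source_chrom = fdf$chrom[i],
                          source_start = fdf$start[i],
                          source_end = fdf$end[i], orientation = o,
                          target_order_index = fdf$idx[i],
                          target_start = 0L,
                          target_end = fdf$end[i] - fdf$start[i],
                          gap_after = fdf$gap_after[i],
                          stringsAsFactors = FALSE))
    }
    for (pr in chimPairs) {
      i <- pr[1L]; j <- pr[2L]
      sa <- substr(chroms[[fdf$chrom[i]]], fdf$start[i] + 1L, fdf$end[i])
      sb <- substr(chroms[[fdf$chrom[j]]], fdf$start[j] + 1L, fdf$end[j])
      la <- nchar(sa)
      contigs[[length(contigs) + 1L]] <- list(
        seq = paste0(sa, sb),
        rows = data.frame(part = c(1L, 2L),
                          source_chrom = fdf$chrom[c(i, j)],
                          source_start = fdf$start[c(i, j)],
                          source_end = fdf$end[c(i, j)],
                          orientation = "+",
                          target_order_index = fdf$idx[c(i, j)],
                          target_start = c(0L, la),
                          target_end = c(la, la + nchar(sb)),
                          gap_after = fdf$gap_after[c(i, j)],
                          stringsAsFactors = FALSE))
    }

    ord <- if (spec$shuffle) sample(length(contigs)) else seq_along(contigs)
    contigs <- contigs[ord]
    ids <- sprintf("ctg_%04d", seq_along(contigs))

    seqs <- vapply(contigs, function(cg) .mutate(cg$seq, spec$snpRate),
                   character(1))
    target <- Biostrings::DNAStringSet(seqs)
    names(target) <- ids

    layout <- do.call(rbind, lapply(seq_along(contigs), function(i)
      cbind(data.frame(fragment_id = ids[i], stringsAsFactors = FALSE),
            contigs[[i]]$rows)))
    rownames(layout) <- NULL

    reference <- Biostrings::DNAStringSet(chroms)
    list(reference = reference, target = target, layout = layout,
         spec = spec)
  })
}

#' Reconstruct target contigs from a fixture layout table
#'
#' Applies the recorded source intervals and orientations back to the
#' reference; with `snpRate = 0` the result equals the fixture target
#' byte-for-byte (reconstruction oracle).
#'
#' @param layout ground-truth layout table.
#' @param reference reference DNAStringSet.
#' @return DNAStringSet named by `fragment_id`.
#' @export
reconstructTargetFromLayout <- function(layout, reference) {
  ids <- unique(layout$fragment_id)
  seqs <- vapply(ids, function(fid) {
    rows <- layout[layout$fragment_id == fid, , drop = FALSE]
    rows <- rows[order(rows$part), , drop = FALSE]
    segs <- vapply(seq_len(nrow(rows)), function(j) {
      r <- rows[j, ]
      s <- Biostrings::subseq(reference[[r$source_chrom]],
                              r$source_start + 1L, r$source_end)
      if (r$orientation == "-") s <- Biostrings::reverseComplement(s)
      as.character(s)
    }, character(1))
    paste(segs, collapse = "")
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write a fixture to FASTA files
#'
#' @param fixture list from [generateFixture()].
#' @param dir output directory (created if missing).
#' @return named character vector with `reference`, `target` and `layout`
#'   paths.
#' @export
writeFixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- c(reference = file.path(dir, "reference.fa"),
           target = file.path(dir, "target.fa"),
           layout = file.path(dir, "layout.tsv"))
  writeScaffoldFasta(fixture$reference, out["reference"])
  writeScaffoldFasta(fixture$target, out["target"])
  write.table(fixture$layout, out["layout"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  out
}
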
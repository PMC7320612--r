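# Brute-force oracles kept deliberately naive and independent of the
# package's data paths.

randomDnaStr <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# O(len * w) sliding-window-minimum sketch. Uses the (separately validated)
# canonical hash primitive on every k-mer, ranks hashes exactly via radix
# order, takes the leftmost minimum of every window and collapses
# consecutive duplicate selections. K-mers with ambiguous bases never win.
oracleSketch <- function(seq, k, w) {
  n <- nchar(seq)
  npos <- n - k + 1L
  empty <- data.frame(pos = integer(), strand = character(),
                      hash = character(), stringsAsFactors = FALSE)
  if (npos < w) return(empty)
  kmers <- substring(seq, 1:npos, k:n)
  ch <- canonicalHash(kmers)
  lvl <- sort(unique(ch$hash[!is.na(ch$hash)]), method = "radix")
  rk <- match(ch$hash, lvl)
  rk[is.na(rk)] <- .Machine$integer.max
  sel <- integer(0)
  for (j in 1:(npos - w + 1L)) {
    win <- j:(j + w - 1L)
    m <- win[which.min(rk[win])]
    if (rk[m] == .Machine$integer.max) next
    if (length(sel) && sel[length(sel)] == m) next
    sel <- c(sel, m)
  }
  if (!length(sel)) return(empty)
  data.frame(pos = sel - 1L, strand = ch$strand[sel], hash = ch$hash[sel],
             stringsAsFactors = FALSE)
}

revcompStr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Independent re-implementation of the ascending-threshold branch rule on a
# plain edge table (a, b, weight), nodes visited in sorted order, removals
# taking effect immediately.
oracleResolveBranches <- function(edges) {
  nodes <- sort(unique(c(edges$a, edges$b)), method = "radix")
  alive <- rep(TRUE, nrow(edges))
  for (nd in nodes) {
    inc <- which(alive & (edges$a == nd | edges$b == nd))
    if (length(inc) <= 2L) next
    ws <- sort(unique(edges$weight[inc]))
    resolved <- FALSE
    for (t in ws) {
      if (sum(edges$weight[inc] >= t) < 3L) {
        alive[inc[edges$weight[inc] < t]] <- FALSE
        resolved <- TRUE
        break
      }
    }
    if (!resolved) alive[inc] <- FALSE   # all ties at the maximum weight
  }
  edges[alive, , drop = FALSE]
}

# Random simple weighted graph as an edge table with hex-like node names.
randomEdgeTable <- function(nNodes, nEdges, weights = c(1, 2, 3, 4)) {
  nodes <- sprintf("%016x", sample.int(2^30, nNodes))
  pairs <- t(combn(nodes, 2))
  pick <- sample(nrow(pairs), min(nEdges, nrow(pairs)))
  a <- pmin(pairs[pick, 1], pairs[pick, 2])
  b <- pmax(pairs[pick, 1], pairs[pick, 2])
  data.frame(a = a, b = b, weight = sample(weights, length(pick), TRUE),
             stringsAsFactors = FALSE)
}

edgeTableToGraph <- function(edges) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$a, to = edges$b, weight = edges$weight,
               support = "x", stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = sort(unique(c(edges$a, edges$b)),
                                      method = "radix")))
  g
}

graphToEdgeTable <- function(g) {
  if (igraph::ecount(g) == 0)
    return(data.frame(a = character(), b = character(), weight = numeric(),
                      stringsAsFactors = FALSE))
  ends <- igraph::ends(g, igraph::E(g))
  df <- data.frame(a = pmin(ends[, 1], ends[, 2]),
                   b = pmax(ends[, 1], ends[, 2]),
                   weight = igraph::E(g)$weight, stringsAsFactors = FALSE)
  df <- df[order(df$a, df$b, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

sortEdgeTable <- function(df) {
  df <- df[order(df$a, df$b, method = "radix"),
           c("a", "b", "weight"), drop = FALSE]
  rownames(df) <- NULL
  df
}

# Endpoint-to-endpoint walk of each path component, brute force over an
# adjacency list.
oracleWalks <- function(edges) {
  adj <- list()
  addAdj <- function(x, y) adj[[x]] <<- c(adj[[x]], y)
  for (i in seq_len(nrow(edges))) {
    addAdj(edges$a[i], edges$b[i])
    addAdj(edges$b[i], edges$a[i])
  }
  nodes <- sort(names(adj), method = "radix")
  seen <- character(0)
  walks <- list()
  for (nd in nodes) {
    if (nd %in% seen || length(adj[[nd]]) != 1L) next
    walk <- nd
    prev <- NA_character_
    cur <- nd
    repeat {
      nxt <- setdiff(adj[[cur]], prev)
      if (length(nxt) == 0L) break
      walk <- c(walk, nxt)
      prev <- cur
      cur <- nxt
    }
    seen <- c(seen, walk)
    if (walk[1L] > walk[length(walk)]) walk <- rev(walk)
    walks[[length(walks) + 1L]] <- walk
  }
  walks[order(vapply(walks, `[`, character(1), 1L), method = "radix")]
}
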
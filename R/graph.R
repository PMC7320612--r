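#' Select anchor minimizers shared uniquely by all inputs
#'
#' An anchor is a minimizer hash that occurs exactly once within every input
#' assembly: uniqueness gives an unambiguous node-to-position mapping and
#' presence in the target and every reference makes edge weights comparable
#' across the graph.
#'
#' @param sketches list of [MinimizerSketchSet-class], one per input
#'   (target and references).
#' @return character vector of anchor hashes, radix-sorted.
#' @export
selectAnchors <- function(sketches) {
  stopifnot(length(sketches) >= 2L)
  uniq <- lapply(sketches, function(s) {
    cnt <- minimizerCounts(s)
    names(cnt)[cnt == 1L]
  })
  anchors <- Reduce(intersect, uniq)
  if (length(anchors) == 0L)
    stop("no anchor minimizers shared by all inputs; try a smaller window ",
         "size (w), a smaller k, or a more closely related reference")
  sort(anchors, method = "radix")
}

#' Restrict a sketch to a set of anchor hashes
#'
#' Drops all records whose hash is not in `anchors`, preserving position
#' order.
#'
#' @param sketch a [MinimizerSketchSet-class].
#' @param anchors character vector of hashes.
#' @return data.frame of the surviving records (seq_id, pos, strand, hash).
#' @export
filterSketchToAnchors <- function(sketch, anchors) {
  rec <- sketchRecords(sketch)
  rec[rec$hash %in% anchors, , drop = FALSE]
}

#' Build the minimizer graph from anchor-filtered sketches
#'
#' One undirected graph over all inputs: nodes are anchor hashes; an edge
#' joins two anchors adjacent in at least one filtered sketch. Each edge
#' carries the set of supporting input labels and a weight equal to the sum
#' of those inputs' user-specified weights.
#'
#' @param filtered list of data.frames as returned by
#'   [filterSketchToAnchors()], one per input, named by input label.
#' @param weights numeric vector of per-input weights, parallel to
#'   `filtered`.
#' @return an [igraph::graph] with vertex attribute `name` (hash) and edge
#'   attributes `weight` (numeric) and `support` (comma-joined labels).
#' @export
buildMinimizerGraph <- function(filtered, weights) {
  stopifnot(length(filtered) == length(weights), !is.null(names(filtered)))
  edges <- lapply(names(filtered), function(lab) {
    rec <- filtered[[lab]]
    if (nrow(rec) < 2L) return(NULL)
    parts <- split(seq_len(nrow(rec)), rec$seq_id)
    pair <- lapply(parts, function(idx) {
      idx <- idx[order(rec$pos[idx])]
      h <- rec$hash[idx]
      if (length(h) < 2L) return(NULL)
      data.frame(a = h[-length(h)], b = h[-1L], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, pair)
    if (is.null(out) || nrow(out) == 0L) return(NULL)
    swap <- out$a > out$b   # canonical unordered pair: a < b (radix/hex order)
    tmp <- out$a[swap]; out$a[swap] <- out$b[swap]; out$b[swap] <- tmp
    out$input <- lab
    out
  })
  edges <- do.call(rbind, edges)
  nodes <- sort(unique(unlist(lapply(filtered, function(r) r$hash),
                              use.names = FALSE)), method = "radix")
  if (is.null(edges) || nrow(edges) == 0L) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, length(nodes), name = nodes)
    return(g)
  }
  wmap <- setNames(as.numeric(weights), names(filtered))
  key <- paste(edges$a, edges$b)
  agg <- split(edges$input, key)
  ekey <- names(agg)
  supp <- vapply(agg, function(l) paste(l, collapse = ","), character(1))
  wt <- vapply(agg, function(l) sum(wmap[l]), numeric(1))
  ab <- do.call(rbind, strsplit(ekey, " ", fixed = TRUE))
  el <- data.frame(from = ab[, 1], to = ab[, 2],
                   weight = wt, support = supp, stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(el, directed = FALSE,
                                vertices = data.frame(name = nodes))
}

#' Global edge weight filter
#'
#' Removes every edge whose weight is below `n`; nodes are retained, possibly
#' isolated.
#'
#' @param g minimizer graph (igraph).
#' @param n non-negative weight threshold.
#' @return the filtered graph.
#' @export
filterGraphGlobal <- function(g, n) {
  stopifnot(n >= 0)
  igraph::delete_edges(g, which(igraph::E(g)$weight < n))
}

#' Resolve branch nodes by increasing weight thresholds
#'
#' For every node of degree > 2 (processed in sorted hash order), iterates a
#' threshold over the sorted distinct incident edge weights, removing
#' incident edges below the threshold, and stops as soon as the degree drops
#' below 3. If all remaining incident edges tie at the maximum weight and the
#' degree is still >= 3, all incident edges of the node are removed. Edge
#' removals take effect immediately, so neighbours' degrees reflect earlier
#' decisions. The result has maximum degree <= 2.
#'
#' @param g minimizer graph after the global filter.
#' @return the branch-resolved graph.
#' @export
resolveBranchNodes <- function(g) {
  # filtering only removes edges, so every node that ever branches already
  # has degree > 2 now; visiting just those keeps the pass near-linear
  deg <- igraph::degree(g)
  nodes <- sort(igraph::V(g)$name[deg > 2L], method = "radix")
  for (nd in nodes) {
    inc <- igraph::incident(g, nd)
    if (length(inc) <= 2L) next
    iw <- igraph::edge_attr(g, "weight", inc)
    ws <- sort(unique(iw))
    done <- FALSE
    for (t in ws) {
      if (sum(iw >= t) < 3L) {
        g <- igraph::delete_edges(g, inc[which(iw < t)])
        done <- TRUE
        break
      }
    }
    if (!done)  # >= 3 edges tie at the maximum incident weight
      g <- igraph::delete_edges(g, inc)
  }
  g
}

#' Break surviving cycles
#'
#' After branch resolution every component is a simple path or a simple
#' cycle. Each cycle is opened at its minimum-weight edge; ties go to the
#' lexicographically smallest hash pair, keeping the output deterministic.
#'
#' @param g branch-resolved graph (max degree <= 2).
#' @return an acyclic graph whose components are simple paths.
#' @export
breakCycles <- function(g) {
  repeat {
    comp <- igraph::components(g)
    cut <- NULL
    for (ci in seq_len(comp$no)) {
      vs <- which(comp$membership == ci)
      if (length(vs) < 3L) next
      if (all(igraph::degree(g, vs) == 2L)) {
        eids <- unique(unlist(lapply(igraph::incident_edges(g, vs),
                                     as.integer)))
        es <- igraph::E(g)[eids]
        ends <- igraph::ends(g, es)
        a <- pmin(ends[, 1], ends[, 2])
        b <- pmax(ends[, 1], ends[, 2])
        ord <- order(es$weight, a, b, method = "radix")
        cut <- es[ord[1L]]
        break
      }
    }
    if (is.null(cut)) return(g)
    g <- igraph::delete_edges(g, cut)
  }
}

#' Filter a minimizer graph into linear components
#'
#' Convenience wrapper: global weight threshold, branch resolution, cycle
#' breaking.
#'
#' @param g raw minimizer graph.
#' @param n global edge weight threshold.
#' @return graph with maximum degree <= 2 and no cycles.
#' @export
filterMinimizerGraph <- function(g, n) {
  breakCycles(resolveBranchNodes(filterGraphGlobal(g, n)))
}

#' Extract linear minimizer paths
#'
#' One path per connected component with >= 2 nodes, walked endpoint to
#' endpoint; singleton nodes are discarded. Paths are put in canonical
#' direction (first hash < last hash).
#'
#' @param g filtered graph (max degree <= 2, acyclic).
#' @return list of character vectors of hashes.
#' @export
extractLinearPaths <- function(g) {
  comp <- igraph::components(g)
  out <- list()
  for (ci in seq_len(comp$no)) {
    vs <- which(comp$membership == ci)
    if (length(vs) < 2L) next
    deg <- igraph::degree(g, vs)
    if (!any(deg == 1L))
      stop("internal error: cyclic component survived cycle breaking")
    sub <- igraph::induced_subgraph(g, vs)
    sdeg <- igraph::degree(sub)
    root <- igraph::V(sub)$name[which(sdeg == 1L)[1L]]
    walk <- igraph::dfs(sub, root = root)$order
    nodes <- igraph::V(sub)$name[walk]
    if (nodes[1L] > nodes[length(nodes)]) nodes <- rev(nodes)
    out[[length(out) + 1L]] <- nodes
  }
  # deterministic ordering across components
  if (length(out))
    out <- out[order(vapply(out, `[`, character(1), 1L), method = "radix")]
  out
}
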
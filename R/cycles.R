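#' Build the bidirected boundary graph
#'
#' Nodes are the two boundaries (L and R) of every amplified segment.
#' Three edge types join them, all traversable in both directions:
#' segment edges (each segment's own L-R pair), SV edges (one per
#' collected SV, duplicates over the same boundary pair and orientation
#' merged with summed counts) and adjacent edges (iR to (i+1)L for each
#' reference-adjacent pair).
#'
#' @param amplified amplified segments (`dm_segments`).
#' @param sv_evidence a `dm_sv` data.frame (may be empty).
#' @param adjacent_pairs output of [find_adjacent_pairs()].
#' @return A `dm_boundary_graph`: list with `nodes` (boundary table with
#'   `node` index), `edges` (`from`, `to`, `type`, payload columns) and
#'   `segments`.
#' @export
build_boundary_graph <- function(amplified, sv_evidence = empty_dm_sv(),
                                 adjacent_pairs = NULL) {
  nodes <- dm_boundaries(amplified)
  nodes$node <- seq_len(nrow(nodes))
  idx <- setNames(nodes$node, nodes$key)
  bad <- setdiff(c(sv_evidence$seg_a, sv_evidence$seg_b), amplified$id)
  if (length(bad))
    stop("SV references unknown segment id(s): ",
         paste(bad, collapse = ", "))
  seg_edges <- data.frame(
    from = idx[paste0(amplified$id, "L")],
    to = idx[paste0(amplified$id, "R")],
    type = "segment", seg_id = amplified$id, sv_row = NA_integer_,
    stringsAsFactors = FALSE)
  sv <- as.data.frame(sv_evidence, stringsAsFactors = FALSE)
  if (nrow(sv)) {
    sv <- canonicalize_pairs(sv)
    grp <- paste0(sv$seg_a, sv$side_a, "-", sv$seg_b, sv$side_b, ":",
                  sv$orientation)
    if (anyDuplicated(grp)) {
      sv <- do.call(rbind, lapply(split(sv, grp), function(g) {
        g$softclip_count[1] <- sum(g$softclip_count)
        g$discordant_count[1] <- sum(g$discordant_count)
        g$bridging_count[1] <- sum(g$bridging_count)
        g[1, , drop = FALSE]
      }))
      sv <- sv[order(sv$seg_a, sv$side_a, sv$seg_b, sv$side_b), ,
               drop = FALSE]
      row.names(sv) <- NULL
    }
    self <- sv$seg_a == sv$seg_b & sv$side_a == sv$side_b
    if (any(self)) stop("SV edge joining a boundary to itself")
    sv_edges <- data.frame(
      from = idx[paste0(sv$seg_a, sv$side_a)],
      to = idx[paste0(sv$seg_b, sv$side_b)],
      type = "sv", seg_id = NA_integer_, sv_row = seq_len(nrow(sv)),
      stringsAsFactors = FALSE)
  } else sv_edges <- NULL
  if (!is.null(adjacent_pairs) && nrow(adjacent_pairs)) {
    adj_edges <- data.frame(
      from = idx[paste0(adjacent_pairs$seg_a, "R")],
      to = idx[paste0(adjacent_pairs$seg_b, "L")],
      type = "adjacent", seg_id = NA_integer_, sv_row = NA_integer_,
      stringsAsFactors = FALSE)
  } else adj_edges <- NULL
  edges <- rbind(seg_edges, sv_edges, adj_edges)
  edges$id <- seq_len(nrow(edges))
  row.names(edges) <- NULL
  g <- list(nodes = nodes, edges = edges, segments = amplified, sv = sv)
  class(g) <- "dm_boundary_graph"
  g
}

#' @export
print.dm_boundary_graph <- function(x, ...) {
  cat(sprintf("boundary graph: %d nodes (%d segments), %d edges (%d segment, %d sv, %d adjacent)\n",
              nrow(x$nodes), nrow(x$segments), nrow(x$edges),
              sum(x$edges$type == "segment"), sum(x$edges$type == "sv"),
              sum(x$edges$type == "adjacent")))
  invisible(x)
}

# Johnson's simple-cycle enumeration on the directed expansion of the
# graph: every undirected edge becomes two arcs. Node-level simple cycles
# are enumerated with Johnson's blocking scheme (strong components via
# igraph prune the search); parallel edges are expanded afterwards, which
# also removes there-and-back artifacts over a single edge.
johnson_node_cycles <- function(succ, n, max_count) {
  res <- list()
  blocked <- logical(n)
  blist <- vector("list", n)
  stack <- integer()
  s <- 1L
  unblock <- function(v) {
    blocked[v] <<- FALSE
    for (w in blist[[v]]) if (blocked[w]) unblock(w)
    blist[[v]] <<- integer()
  }
  circuit <- function(v, succ_sub) {
    found <- FALSE
    stack[length(stack) + 1L] <<- v
    blocked[v] <<- TRUE
    for (w in succ_sub[[v]]) {
      if (w == s) {
        res[[length(res) + 1L]] <<- stack
        if (length(res) > max_count)
          stop("cycle enumeration exceeded max_candidates; ",
               "tighten the inputs or raise the guard")
        found <- TRUE
      } else if (!blocked[w]) {
        if (circuit(w, succ_sub)) found <- TRUE
      }
    }
    if (found) unblock(v)
    else for (w in succ_sub[[v]])
      if (!(v %in% blist[[w]])) blist[[w]] <<- c(blist[[w]], v)
    stack <<- stack[-length(stack)]
    found
  }
  while (s < n) {
    # least vertex of the subgraph on {s..n} that sits in a nontrivial SCC
    arcs <- do.call(rbind, lapply(s:n, function(v) {
      ws <- succ[[v]]; ws <- ws[ws >= s]
      if (length(ws)) cbind(v, ws) else NULL
    }))
    if (is.null(arcs)) break
    ig <- igraph::graph_from_data_frame(
      data.frame(from = as.character(arcs[, 1]),
                 to = as.character(arcs[, 2])),
      directed = TRUE, vertices = data.frame(name = as.character(s:n)))
    comp <- igraph::components(ig, mode = "strong")$membership
    verts <- as.integer(names(comp))
    sizes <- table(comp)
    nontriv <- verts[sizes[as.character(comp)] >= 2]
    if (!length(nontriv)) break
    s <- min(nontriv)
    keep <- verts[comp == comp[match(s, verts)]]
    succ_sub <- vector("list", n)
    for (v in keep) succ_sub[[v]] <- intersect(succ[[v]], keep)
    blocked[keep] <- FALSE
    for (v in keep) blist[[v]] <- integer()
    stack <- integer()
    circuit(s, succ_sub)
    s <- s + 1L
  }
  res
}

#' Enumerate raw simple cycles of the boundary graph
#'
#' Runs Johnson's algorithm on the directed expansion of the bidirected
#' boundary graph. Every simple cycle (no repeated node, at least two
#' distinct edges) is reported once per traversal direction; a single
#' edge walked there and back is not a cycle.
#'
#' @param graph a `dm_boundary_graph`.
#' @param params a [dm_params()] object (`max_candidates` guard).
#' @return list of raw cycles, each a list with integer vectors `nodes`
#'   and `edges` (edge `i` joins node `i` to node `i + 1`, cyclically).
#' @export
enumerate_simple_cycles <- function(graph, params = dm_params()) {
  n <- nrow(graph$nodes)
  ed <- graph$edges
  if (!n || !nrow(ed)) return(list())
  succ <- vector("list", n)
  for (k in seq_len(nrow(ed))) {
    succ[[ed$from[k]]] <- c(succ[[ed$from[k]]], ed$to[k])
    succ[[ed$to[k]]] <- c(succ[[ed$to[k]]], ed$from[k])
  }
  succ <- lapply(succ, function(x) sort(unique(x)))
  ncyc <- johnson_node_cycles(succ, n, params$max_candidates)
  # parallel-edge expansion
  elist_between <- function(u, v)
    ed$id[(ed$from == u & ed$to == v) | (ed$from == v & ed$to == u)]
  out <- list()
  for (cyc in ncyc) {
    k <- length(cyc)
    nxt <- c(cyc[-1], cyc[1])
    choices <- mapply(elist_between, cyc, nxt, SIMPLIFY = FALSE)
    combos <- expand.grid(rev(choices), KEEP.OUT.ATTRS = FALSE)
    combos <- combos[, rev(seq_len(k)), drop = FALSE]
    for (r in seq_len(nrow(combos))) {
      ecyc <- as.integer(combos[r, ])
      if (k == 2 && ecyc[1] == ecyc[2]) next
      out[[length(out) + 1L]] <- list(nodes = cyc, edges = ecyc)
    }
  }
  out
}

# rotation- and reflection-invariant identifier of a cycle
cycle_canonical_key <- function(nodes, edges) {
  k <- length(nodes)
  forms <- character(0)
  # reversed traversal: nodes n1, nk, ..., n2 with edges ek, e(k-1), ..., e1
  variants <- list(list(n = nodes, e = edges),
                   list(n = c(nodes[1], rev(nodes[-1])), e = rev(edges)))
  for (v in variants) {
    for (r in seq_len(k)) {
      rot <- function(x) c(x[r:k], x[seq_len(r - 1L)])
      forms <- c(forms, paste(rot(v$n), rot(v$e), sep = ".",
                              collapse = "|"))
    }
  }
  min(forms)
}

#' Remove reverse-direction duplicate cycles
#'
#' In a bidirected graph every simple cycle is enumerated twice, once per
#' strand direction. This keeps one representative per
#' rotation/reflection equivalence class (the lexicographically minimal
#' canonical key).
#'
#' @param raw_cycles output of [enumerate_simple_cycles()].
#' @return list of cycles, each with an added `key` element.
#' @export
deduplicate_reverse_cycles <- function(raw_cycles) {
  if (!length(raw_cycles)) return(list())
  keys <- vapply(raw_cycles, function(c)
    cycle_canonical_key(c$nodes, c$edges), "")
  keep <- !duplicated(keys)
  out <- raw_cycles[keep]
  for (i in seq_along(out)) out[[i]]$key <- keys[keep][i]
  out[order(vapply(out, `[[`, "", "key"))]
}

#' Keep cycles traversing whole segments only
#'
#' A candidate circular structure must enter every segment at one
#' boundary and leave at the other, i.e. alternate segment edges and
#' junction (SV/adjacent) edges all the way around. Cycles that touch a
#' segment through a single boundary are discarded.
#'
#' @param cycles deduplicated cycles.
#' @param graph the `dm_boundary_graph` they came from.
#' @param params a [dm_params()] object (`max_cycle_segments` guard).
#' @return A `dm_cycles` list of `dm_cycle` objects, each with
#'   `segment_ids`, `orients`, `junction_edges`, `total_length`, `key`.
#' @export
filter_valid_cycles <- function(cycles, graph, params = dm_params()) {
  ed <- graph$edges
  nodes <- graph$nodes
  seglen <- setNames(graph$segments$end - graph$segments$start + 1,
                     graph$segments$id)
  out <- list()
  for (cyc in cycles) {
    k <- length(cyc$edges)
    types <- ed$type[cyc$edges]
    is_seg <- types == "segment"
    if (k %% 2 != 0) next
    alt1 <- all(is_seg == rep(c(TRUE, FALSE), k / 2))
    alt2 <- all(is_seg == rep(c(FALSE, TRUE), k / 2))
    if (!alt1 && !alt2) next
    if (k / 2 > params$max_cycle_segments) next
    # rotate so the cycle starts with a segment edge
    off <- if (alt1) 0L else 1L
    ord <- ((seq_len(k) - 1L + off) %% k) + 1L
    nseq <- cyc$nodes[ord]
    eseq <- cyc$edges[ord]
    segpos <- seq(1, k, by = 2)
    seg_ids <- ed$seg_id[eseq[segpos]]
    orients <- vapply(segpos, function(i) {
      if (nodes$side[nseq[i]] == "L") "+" else "-"
    }, "")
    out[[length(out) + 1L]] <- structure(
      list(segment_ids = seg_ids, orients = orients,
           junction_edges = eseq[segpos + 1L],
           nodes = nseq, edges = eseq,
           total_length = sum(seglen[as.character(seg_ids)]),
           key = cyc$key),
      class = "dm_cycle")
  }
  structure(out, class = "dm_cycles")
}

#' Candidate cycles of a boundary graph
#'
#' Convenience wrapper: enumerate, deduplicate and filter in one call.
#' @inheritParams filter_valid_cycles
#' @return A `dm_cycles` list.
#' @export
find_candidate_cycles <- function(graph, params = dm_params()) {
  raw <- enumerate_simple_cycles(graph, params)
  filter_valid_cycles(deduplicate_reverse_cycles(raw), graph, params)
}

#' Structure string of a cycle
#' @param cycle a `dm_cycle`.
#' @return e.g. `"seg27+ -> seg9- -> seg19+"`.
#' @export
cycle_structure_string <- function(cycle) {
  paste(paste0("seg", cycle$segment_ids, cycle$orients),
        collapse = " -> ")
}

#' @export
print.dm_cycle <- function(x, ...) {
  cat(sprintf("circular candidate (%d segments, %s bp): %s\n",
              length(x$segment_ids), format(x$total_length, big.mark = ","),
              cycle_structure_string(x)))
  invisible(x)
}

#' @export
print.dm_cycles <- function(x, ...) {
  cat(length(x), "candidate circular structure(s)\n")
  for (c in x) print(c)
  invisible(x)
}

# ordered junction descriptors of a cycle: one row per consecutive
# segment pair, with the boundary sides the junction uses
cycle_junctions <- function(cycle, graph) {
  k <- length(cycle$segment_ids)
  ed <- graph$edges
  nodes <- graph$nodes
  rows <- lapply(seq_len(k), function(i) {
    j <- if (i == k) 1L else i + 1L
    sa <- if (cycle$orients[i] == "+") "R" else "L"  # exit side of seg i
    sb <- if (cycle$orients[j] == "+") "L" else "R"  # entry side of seg j
    e <- cycle$junction_edges[i]
    data.frame(seg_a = cycle$segment_ids[i], side_a = sa,
               seg_b = cycle$segment_ids[j], side_b = sb,
               type = ed$type[e], edge = e,
               orientation = orientation_from_sides(sa, sb),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Report candidate circular structures
#'
#' One row per cycle: the ordered segment/orientation string, total
#' length, junction summary with evidence counts, and (when a gene table
#' is given) the genes the structure overlaps.
#'
#' @param cycles a `dm_cycles` list.
#' @param graph the `dm_boundary_graph`.
#' @param genes optional data.frame `chrom`, `start`, `end`, `name`
#'   (1-based inclusive).
#' @return data.frame report.
#' @export
report_structures <- function(cycles, graph, genes = NULL) {
  segments <- graph$segments
  sv <- graph$sv
  if (!length(cycles))
    return(data.frame(structure = character(), n_segments = integer(),
                      total_length = numeric(), junctions = character(),
                      genes = character(), stringsAsFactors = FALSE))
  rows <- lapply(cycles, function(cyc) {
    jx <- cycle_junctions(cyc, graph)
    jdesc <- vapply(seq_len(nrow(jx)), function(i) {
      e <- graph$edges[jx$edge[i], ]
      counts <- if (e$type == "sv" && !is.null(sv) && nrow(sv)) {
        s <- sv[e$sv_row, ]
        sprintf("sc=%d,disc=%d,bridge=%d", s$softclip_count,
                s$discordant_count, s$bridging_count)
      } else "adjacent"
      sprintf("%d%s-%d%s(%s;%s)", jx$seg_a[i], jx$side_a[i], jx$seg_b[i],
              jx$side_b[i], jx$orientation[i], counts)
    }, "")
    gn <- ""
    if (!is.null(genes) && nrow(genes)) {
      segs <- segments[segments$id %in% cyc$segment_ids, , drop = FALSE]
      hit <- vapply(seq_len(nrow(genes)), function(g) {
        any(segs$chrom == genes$chrom[g] & segs$start <= genes$end[g] &
              segs$end >= genes$start[g])
      }, TRUE)
      gn <- paste(sort(genes$name[hit]), collapse = ",")
    }
    data.frame(structure = cycle_structure_string(cyc),
               n_segments = length(cyc$segment_ids),
               total_length = cyc$total_length,
               junctions = paste(jdesc, collapse = "; "),
               genes = gn, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
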
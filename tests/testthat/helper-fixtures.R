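# Shared fixtures (built once per test run) and independent oracles.

.fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function(name, seed = 1L) {
  key <- paste0(name, "_", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- make_fixture(name, seed = seed)
  .fixture_cache[[key]]
}

run_fixture <- function(name, seed = 1L, sample = 1L, ...) {
  key <- paste0("run_", name, "_", seed, "_", sample)
  if (is.null(.fixture_cache[[key]])) {
    fx <- get_fixture(name, seed)
    s <- fx$samples[[sample]]
    p <- dm_params(amplified_log2r_cutoff = 2)
    .fixture_cache[[key]] <- reconstruct_amplicons(
      s$segments, s$tumor_aln, s$ref$reference, p,
      snvs = s$snvs_tumor, linked_aln = s$linked_aln,
      avg_molecule_length = if (!is.null(s$linked_aln))
        s$plan$mol_mean_length, ...)
  }
  .fixture_cache[[key]]
}

# --- brute-force cycle oracle (independent of the package's Johnson
# implementation): enumerates every directed node-simple, edge-distinct
# closed walk with >= 2 edges, once per direction, by exhaustive DFS from
# the minimal node of each cycle.
oracle_raw_cycles <- function(edges, n_nodes) {
  inc <- vector("list", n_nodes)
  for (k in seq_len(nrow(edges))) {
    f <- edges$from[k]; t <- edges$to[k]
    inc[[f]] <- rbind(inc[[f]], c(edges$id[k], t))
    inc[[t]] <- rbind(inc[[t]], c(edges$id[k], f))
  }
  res <- list()
  for (s in seq_len(n_nodes)) {
    path_nodes <- s
    used <- integer()
    dfs <- function(v) {
      for (r in seq_len(NROW(inc[[v]]))) {
        e <- inc[[v]][r, 1]; w <- inc[[v]][r, 2]
        if (e %in% used) next
        if (w == s) {
          if (length(used) + 1L >= 2L)
            res[[length(res) + 1L]] <<- list(nodes = path_nodes,
                                             edges = c(used, e))
        } else if (w > s && !(w %in% path_nodes)) {
          path_nodes <<- c(path_nodes, w)
          used <<- c(used, e)
          dfs(w)
          path_nodes <<- path_nodes[-length(path_nodes)]
          used <<- used[-length(used)]
        }
      }
    }
    if (NROW(inc[[s]])) dfs(s)
  }
  res
}

# rotation-only canonical string of a directed cycle (direction kept)
rotkey <- function(nodes, edges) {
  k <- length(nodes)
  min(vapply(seq_len(k), function(r) {
    idx <- c(r:k, seq_len(r - 1L))
    paste(nodes[idx], edges[idx], sep = ".", collapse = "|")
  }, ""))
}

# rotation+reflection canonical string (oracle for dedup)
rotrefkey <- function(nodes, edges) {
  rn <- c(nodes[1], rev(nodes[-1]))
  re <- rev(edges)
  min(rotkey(nodes, edges), rotkey(rn, re))
}

# alternation predicate oracle: edge types alternate segment / junction
alternates <- function(edge_ids, graph) {
  types <- graph$edges$type[edge_ids] == "segment"
  k <- length(types)
  if (k %% 2 != 0) return(FALSE)
  all(types == rep(c(TRUE, FALSE), k / 2)) ||
    all(types == rep(c(FALSE, TRUE), k / 2))
}

# random boundary graph over <= max_seg segments
random_graph <- function(seed, max_seg = 8) {
  set.seed(seed)
  n_seg <- sample(1:max_seg, 1)
  len <- sample(1000:5000, n_seg, replace = TRUE)
  start <- cumsum(c(1, head(len, -1) +
                      sample(0:50, max(n_seg - 1, 0), replace = TRUE)))
  segs <- as_dm_segments(data.frame(chrom = "chr1", start = start,
                                    end = start + len - 1,
                                    log2r = 5))
  n_sv <- sample(0:(2 * n_seg), 1)
  sv <- NULL
  if (n_sv > 0) {
    b <- dm_boundaries(segs)
    rows <- lapply(seq_len(n_sv), function(i) {
      repeat {
        ij <- sample(nrow(b), 2, replace = FALSE)
        if (!(b$segment_id[ij[1]] == b$segment_id[ij[2]] &&
                b$side[ij[1]] == b$side[ij[2]])) break
      }
      data.frame(seg_a = b$segment_id[ij[1]], side_a = b$side[ij[1]],
                 seg_b = b$segment_id[ij[2]], side_b = b$side[ij[2]],
                 orientation = orientation_from_sides(b$side[ij[1]],
                                                      b$side[ij[2]]),
                 softclip_count = sample(1:20, 1), discordant_count = 0L,
                 bridging_count = 0L, breakpoint_a = NA_integer_,
                 breakpoint_b = NA_integer_, stringsAsFactors = FALSE)
    })
    sv <- do.call(rbind, rows)
    sv <- sv[!duplicated(paste(pmin(paste0(sv$seg_a, sv$side_a),
                                    paste0(sv$seg_b, sv$side_b)),
                               pmax(paste0(sv$seg_a, sv$side_a),
                                    paste0(sv$seg_b, sv$side_b)))), ,
             drop = FALSE]
    class(sv) <- c("dm_sv", "data.frame")
  }
  adj <- find_adjacent_pairs(segs, dm_params(adjacency_max_gap = 20))
  build_boundary_graph(segs, if (is.null(sv)) circamp:::empty_dm_sv()
                       else sv, adj)
}

# canonical form of a planted structure (segment ids + orientations) up
# to rotation and reflection, for round-trip comparisons
structure_key <- function(seg_ids, orients) {
  k <- length(seg_ids)
  rot <- function(sg, orr) {
    min(vapply(seq_len(k), function(r) {
      idx <- c(r:k, seq_len(r - 1L))
      paste(sg[idx], orr[idx], sep = "", collapse = ">")
    }, ""))
  }
  flip <- c("+" = "-", "-" = "+")
  min(rot(seg_ids, orients),
      rot(rev(seg_ids), unname(flip[rev(orients)])))
}

# small hand-built alignment record
mk_aln <- function(qname = "r1", flag = 0L, chrom = "chr1", pos = 1L,
                   cigar = "100M", mate_chrom = chrom, mate_pos = NA,
                   seq = paste(rep("A", 100), collapse = ""),
                   barcode = NA_character_) {
  df <- data.frame(qname = qname, flag = flag, chrom = chrom,
                   pos = as.integer(pos), mapq = 60L, cigar = cigar,
                   mate_chrom = mate_chrom,
                   mate_pos = as.integer(mate_pos), isize = 0L, seq = seq,
                   barcode = barcode, stringsAsFactors = FALSE)
  class(df) <- c("dm_alignments", "data.frame")
  df
}
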
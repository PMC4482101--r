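#' Airway volume from a label
#'
#' `n_voxels * sx * sy * sz`, exactly linear in the voxel count.
#'
#' @param label logical 3D array.
#' @param spacing voxel spacing in mm (length 3).
#' @return volume in mm^3.
#' @export
airway_volume <- function(label, spacing) {
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  sum(label) * prod(spacing)
}

# 26-neighbourhood offsets as a 26x3 matrix
.offs26 <- local({
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
})

#' Extract a centerline branch graph from a label
#'
#' Thins the label to a one-voxel-wide centerline (topological curve
#' thinning), then traces the skeleton into a graph: skeleton voxels with a
#' number of 26-neighbours different from 2 become nodes (endpoints and
#' bifurcations), maximal chains of degree-2 voxels between nodes become
#' edges. Terminal edges shorter than `min_spur_mm` are pruned and the
#' remaining chains re-merged, so small surface bumps do not count as
#' branches. Edge lengths are spacing-weighted polyline lengths through the
#' voxel centers.
#'
#' @param label logical 3D array, expected to be one connected component.
#' @param spacing voxel spacing in mm.
#' @param min_spur_mm spur-pruning threshold (default 2 mm).
#' @return object of class `branch_graph`: list with `nodes` (data frame
#'   `id, i, j, k, degree`), `edges` (data frame `from, to, length_mm,
#'   n_points`), and `paths` (list of voxel-index matrices, one per edge).
#' @export
extract_centerline <- function(label, spacing, min_spur_mm = 2) {
  if (!any(label)) stop("empty label", call. = FALSE)
  spacing <- as.numeric(spacing)
  # a branch shorter than a few slices is indistinguishable from a
  # partial-volume artifact, so the pruning threshold never drops below
  # three times the coarsest voxel dimension
  min_spur_mm <- max(min_spur_mm, 3 * max(spacing))
  skel <- array(.skeletonize_cpp(as.logical(label), dim(label)),
                dim = dim(label))
  vox <- which(skel, arr.ind = TRUE)
  n <- nrow(vox)
  if (n == 1L) {
    return(structure(list(
      nodes = data.frame(id = 1L, i = vox[1, 1], j = vox[1, 2], k = vox[1, 3],
                         degree = 0L),
      edges = data.frame(from = integer(), to = integer(),
                         length_mm = numeric(), n_points = integer()),
      paths = list()), class = "branch_graph"))
  }
  key <- function(m) paste(m[, 1], m[, 2], m[, 3], sep = ",")
  id_of <- seq_len(n)
  names(id_of) <- key(vox)
  # neighbour lists under 26-connectivity
  nbrs <- vector("list", n)
  for (v in seq_len(n)) {
    cand <- sweep(.offs26, 2, vox[v, ], "+")
    hit <- id_of[key(cand)]
    nbrs[[v]] <- unname(hit[!is.na(hit)])
  }
  deg <- lengths(nbrs)
  seg_len <- function(path_idx) {
    p <- vox[path_idx, , drop = FALSE]
    if (nrow(p) < 2L) return(0)
    dp <- sweep(abs(diff(p)), 2, spacing, "*")
    sum(sqrt(rowSums(dp^2)))
  }
  trace_edges <- function(node_set) {
    # walk from every node through degree-2 chains; also handle pure cycles
    visited_dir <- new.env(hash = TRUE)
    edges <- list(); paths <- list()
    for (a in which(node_set)) {
      for (b in nbrs[[a]]) {
        kdir <- paste(a, b)
        if (!is.null(visited_dir[[kdir]])) next
        path <- c(a, b)
        prev <- a; cur <- b
        while (!node_set[cur]) {
          nxt <- setdiff(nbrs[[cur]], prev)
          if (length(nxt) == 0L) break           # dead end (degree-1 chain)
          # in rare thick-junction cases a "degree-2" voxel may touch two
          # non-path voxels; take the first in scan order for determinism
          nxt <- nxt[1]
          path <- c(path, nxt)
          prev <- cur; cur <- nxt
        }
        visited_dir[[paste(a, b)]] <- TRUE
        visited_dir[[paste(cur, prev)]] <- TRUE
        edges[[length(edges) + 1L]] <- data.frame(
          from = a, to = cur, length_mm = seg_len(path),
          n_points = length(path))
        paths[[length(paths) + 1L]] <- path
      }
    }
    list(edges = edges, paths = paths)
  }
  node_set <- deg != 2L
  if (!any(node_set)) node_set[1] <- TRUE        # pure cycle: break anywhere
  te <- trace_edges(node_set)
  edges <- if (length(te$edges)) do.call(rbind, te$edges) else
    data.frame(from = integer(), to = integer(), length_mm = numeric(),
               n_points = integer())
  paths <- te$paths
  # Graph clean-up, iterated to a fixed point:
  #  (a) self-loops shorter than the spur threshold are dropped;
  #  (b) short internal edges joining two junctions are contracted - fat
  #      bifurcations thin into small triangles of sub-voxel edges;
  #  (c) short terminal spurs are pruned (shortest first);
  #  (d) chains meeting at a degree-2 node are merged, summing lengths.
  repeat {
    if (!nrow(edges)) break
    nd <- table(factor(c(edges$from, edges$to),
                       levels = as.character(seq_len(n))))
    loops <- which(edges$from == edges$to & edges$length_mm < min_spur_mm)
    if (length(loops)) {
      edges <- edges[-loops, , drop = FALSE]; paths <- paths[-loops]
      next
    }
    degf <- as.integer(nd[as.character(edges$from)])
    degt <- as.integer(nd[as.character(edges$to)])
    internal <- which(edges$length_mm < min_spur_mm & edges$from != edges$to &
                        degf >= 2L & degt >= 2L)
    if (length(internal)) {
      e <- internal[which.min(edges$length_mm[internal])]
      a <- edges$from[e]; b <- edges$to[e]
      edges <- edges[-e, , drop = FALSE]; paths <- paths[-e]
      edges$from[edges$from == b] <- a
      edges$to[edges$to == b] <- a
      next
    }
    term <- which((degf == 1L | degt == 1L) &
                    edges$length_mm < min_spur_mm & edges$from != edges$to)
    if (length(term)) {
      e <- term[which.min(edges$length_mm[term])]
      edges <- edges[-e, , drop = FALSE]; paths <- paths[-e]
      next
    }
    mid <- as.integer(names(nd)[nd == 2L])
    merged_any <- FALSE
    for (m in mid) {
      at <- which(edges$from == m | edges$to == m)
      if (length(at) != 2L) next
      e1 <- edges[at[1], ]; e2 <- edges[at[2], ]
      p1 <- paths[[at[1]]]; p2 <- paths[[at[2]]]
      if (e1$from == m) { p1 <- rev(p1); e1from <- e1$to } else e1from <- e1$from
      if (e2$to == m) { p2 <- rev(p2); e2to <- e2$from } else e2to <- e2$to
      newe <- data.frame(from = e1from, to = e2to,
                         length_mm = e1$length_mm + e2$length_mm,
                         n_points = e1$n_points + e2$n_points - 1L)
      keepi <- setdiff(seq_len(nrow(edges)), at)
      edges <- rbind(edges[keepi, , drop = FALSE], newe)
      paths <- c(paths[keepi], list(c(p1, p2[-1])))
      merged_any <- TRUE
      break
    }
    if (!merged_any) break
  }
  rownames(edges) <- NULL
  # Tip correction: thinning retracts endpoints from tube ends by about one
  # radius, so terminal branches are extended along their end tangent until
  # they leave the label, recovering the lost tip length.
  if (nrow(edges)) {
    nd2 <- table(factor(c(edges$from, edges$to),
                        levels = as.character(seq_len(n))))
    dmax <- dim(label)
    for (e in seq_len(nrow(edges))) {
      p <- paths[[e]]
      for (endside in c("from", "to")) {
        nodeid <- edges[[endside]][e]
        if (nd2[as.character(nodeid)] != 1L) next
        pv <- if (endside == "from") rev(p) else p
        m <- length(pv)
        if (m < 2L) next
        back <- max(1L, m - 3L)
        tangent <- (vox[pv[m], ] - vox[pv[back], ]) * spacing
        nt <- sqrt(sum(tangent^2))
        if (nt < 1e-9) next
        tangent <- tangent / nt
        pos <- (vox[pv[m], ] - 1) * spacing
        stepsz <- 0.5 * min(spacing)
        added <- 0
        repeat {
          cand <- pos + tangent * (added + stepsz)
          cvox <- round(cand / spacing) + 1
          if (any(cvox < 1) || any(cvox > dmax) ||
              !label[cvox[1], cvox[2], cvox[3]] || added > 30)
            break
          added <- added + stepsz
        }
        edges$length_mm[e] <- edges$length_mm[e] + added
      }
    }
  }
  used <- sort(unique(c(edges$from, edges$to)))
  if (!length(used)) used <- which(node_set)[1]
  node_deg <- table(factor(c(edges$from, edges$to),
                           levels = as.character(used)))
  nodes <- data.frame(id = used,
                      i = vox[used, 1], j = vox[used, 2], k = vox[used, 3],
                      degree = as.integer(node_deg[as.character(used)]))
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 paths = lapply(paths, function(p) vox[p, , drop = FALSE])),
            class = "branch_graph")
}

#' @export
print.branch_graph <- function(x, ...) {
  cat(sprintf("<branch_graph> %d branches, %d nodes, total length %.1f mm\n",
              nrow(x$edges), nrow(x$nodes), sum(x$edges$length_mm)))
  invisible(x)
}

#' Branch count and total branch length
#'
#' @param graph a `branch_graph` from [extract_centerline()] or an
#'   `airway_tree` from [build_tree()].
#' @export
branch_count <- function(graph) {
  if (inherits(graph, "airway_tree")) return(nrow(graph$branches))
  nrow(graph$edges)
}

#' @rdname branch_count
#' @export
total_branch_length <- function(graph) {
  if (inherits(graph, "airway_tree")) return(sum(graph$branches$length_mm))
  sum(graph$edges$length_mm)
}

#' Export a branch graph as an edge-list data frame (mm coordinates)
#'
#' @param graph a `branch_graph`.
#' @param spacing voxel spacing in mm.
#' @export
branch_graph_table <- function(graph, spacing) {
  e <- graph$edges
  if (!nrow(e)) return(data.frame())
  ends <- t(vapply(seq_len(nrow(e)), function(r) {
    p <- graph$paths[[r]]
    c((p[1, ] - 1) * spacing, (p[nrow(p), ] - 1) * spacing)
  }, numeric(6)))
  data.frame(branch = seq_len(nrow(e)),
             x0 = ends[, 1], y0 = ends[, 2], z0 = ends[, 3],
             x1 = ends[, 4], y1 = ends[, 5], z1 = ends[, 6],
             length_mm = e$length_mm)
}
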
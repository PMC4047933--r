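# Skeleton graph: unit-width centerline pixels organized into nodes
# (endpoints, junction clusters) and degree-2 pixel-chain edges.

# Count foreground 8-neighbours of every pixel.
neighbor_count <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- as.integer(m != 0)
  s <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    s <- s + p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  }
  s
}

chebyshev_adjacent <- function(a, b) {
  max(abs(a - b)) == 1 || (max(abs(a - b)) <= 1 && any(a != b))
}

#' Build the skeleton graph of a thinned mask
#'
#' Pixels with 8-neighbour degree 1 are endpoints and pixels with degree
#' >= 3 are junction pixels; 8-connected groups of junction pixels are
#' merged into single junction nodes (digital skeletons of crossings often
#' carry two adjacent junction pixels rather than one). Maximal runs of the
#' remaining pixels form edge chains. Every junction pixel is then absorbed
#' into exactly one adjacent chain end, so each skeleton pixel belongs to
#' exactly one chain; junction pixels with no adjacent chain end become
#' single-pixel stub edges. Closed loops with no junction become cycle
#' edges. All orderings are deterministic.
#'
#' @param skel 0/1 matrix satisfying the unit-width property (see
#'   [thin_mask()]).
#' @return object of class `skeleton_graph`: list with `edges` (each with
#'   `pixels`, `clusters` = ids of the junction node at each end or `NA`,
#'   `length_px`, `is_cycle`, `is_stub`), `clusters` (junction nodes:
#'   `pixels`, `centroid`), `dim`, `n_pixels`.
#' @export
build_graph <- function(skel) {
  m <- (skel != 0)
  nr <- nrow(m); nc <- ncol(m)
  deg <- neighbor_count(m)
  jmask <- m & deg >= 3L
  jlab <- label8(jmask)
  n_clusters <- max(jlab)
  clusters <- vector("list", n_clusters)
  if (n_clusters > 0) {
    jw <- which(jmask, arr.ind = TRUE)
    for (ci in seq_len(n_clusters)) {
      px <- jw[jlab[jw] == ci, , drop = FALSE]
      clusters[[ci]] <- list(pixels = px, centroid = colMeans(px))
    }
  }

  chainable <- m & deg <= 2L
  subdeg <- neighbor_count(chainable) * chainable
  visited <- matrix(FALSE, nr, nc)

  nbrs_of <- function(r, c, set) {
    out <- NULL
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && set[rr, cc])
        out <- rbind(out, c(rr, cc))
    }
    out
  }

  walk_chain <- function(r0, c0) {
    path <- matrix(c(r0, c0), 1, 2)
    visited[r0, c0] <<- TRUE
    repeat {
      cur <- path[nrow(path), ]
      nb <- nbrs_of(cur[1], cur[2], chainable & !visited)
      if (is.null(nb)) break
      nxt <- nb[1, ]
      visited[nxt[1], nxt[2]] <<- TRUE
      path <- rbind(path, nxt)
    }
    path
  }

  chains <- list()
  cyc <- logical(0)
  # open chains: start from subset-terminal pixels (0 or 1 chainable nbrs)
  term <- which(chainable & subdeg <= 1L, arr.ind = TRUE)
  if (nrow(term) > 0) {
    ord <- order(term[, 1], term[, 2])
    for (i in ord) {
      r0 <- term[i, 1]; c0 <- term[i, 2]
      if (visited[r0, c0]) next
      chains[[length(chains) + 1L]] <- walk_chain(r0, c0)
      cyc <- c(cyc, FALSE)
    }
  }
  # remaining chainable pixels lie on pure cycles
  rest <- which(chainable & !visited, arr.ind = TRUE)
  while (nrow(rest) > 0) {
    ord <- order(rest[, 1], rest[, 2])
    r0 <- rest[ord[1], 1]; c0 <- rest[ord[1], 2]
    chains[[length(chains) + 1L]] <- walk_chain(r0, c0)
    cyc <- c(cyc, TRUE)
    rest <- which(chainable & !visited, arr.ind = TRUE)
  }

  end_cluster <- function(px) {
    nb <- nbrs_of(px[1], px[2], jmask)
    if (is.null(nb)) return(NA_integer_)
    jlab[nb[1, 1], nb[1, 2]]
  }
  edges <- lapply(seq_along(chains), function(i) {
    P <- chains[[i]]
    colnames(P) <- c("row", "col")
    if (cyc[i]) {
      cl <- c(NA_integer_, NA_integer_)
    } else if (nrow(P) == 1) {
      nb <- nbrs_of(P[1, 1], P[1, 2], jmask)
      ids <- if (is.null(nb)) integer(0) else
        unique(jlab[cbind(nb[, 1], nb[, 2])])
      cl <- c(ids[1][1], if (length(ids) >= 2) ids[2] else
        if (deg[P[1, 1], P[1, 2]] >= 2 && length(ids) == 1) ids[1] else NA_integer_)
      if (length(ids) == 0) cl <- c(NA_integer_, NA_integer_)
    } else {
      cl <- c(end_cluster(P[1, ]), end_cluster(P[nrow(P), ]))
    }
    list(pixels = P, clusters = cl, is_cycle = cyc[i], is_stub = FALSE)
  })

  # absorb junction pixels into adjacent chain ends (one owner per pixel)
  if (n_clusters > 0) {
    un <- do.call(rbind, lapply(seq_len(n_clusters), function(ci)
      cbind(clusters[[ci]]$pixels, cluster = ci)))
    un <- un[order(un[, 1], un[, 2]), , drop = FALSE]
    assigned <- rep(FALSE, nrow(un))
    repeat {
      progress <- FALSE
      for (k in seq_len(nrow(un))) {
        if (assigned[k]) next
        j <- un[k, 1:2]; jcl <- un[k, 3]
        done <- FALSE
        for (e in seq_along(edges)) {
          if (done || edges[[e]]$is_cycle) next
          for (end in 1:2) {
            if (done || is.na(edges[[e]]$clusters[end]) ||
                edges[[e]]$clusters[end] != jcl) next
            P <- edges[[e]]$pixels
            endpix <- if (end == 1) P[1, ] else P[nrow(P), ]
            if (max(abs(j - endpix)) == 1) {
              P <- if (end == 1) rbind(j, P) else rbind(P, j)
              rownames(P) <- NULL
              edges[[e]]$pixels <- P
              assigned[k] <- TRUE
              progress <- TRUE
              done <- TRUE
            }
          }
        }
      }
      if (!progress) break
    }
    # leftover junction pixels become stub edges
    for (k in which(!assigned)) {
      edges[[length(edges) + 1L]] <- list(
        pixels = matrix(un[k, 1:2], 1, 2, dimnames = list(NULL, c("row", "col"))),
        clusters = c(un[k, 3], un[k, 3]), is_cycle = FALSE, is_stub = TRUE)
    }
  }

  for (e in seq_along(edges)) {
    P <- edges[[e]]$pixels
    len <- chain_length(P)
    if (edges[[e]]$is_cycle && nrow(P) > 1)
      len <- len + sqrt(sum((P[1, ] - P[nrow(P), ])^2))
    edges[[e]]$length_px <- len
  }

  structure(list(edges = edges, clusters = clusters,
                 endpoints = which(m & deg == 1L, arr.ind = TRUE),
                 dim = c(nr, nc), n_pixels = sum(m)),
            class = "skeleton_graph")
}

# Sum of Euclidean steps between consecutive chain pixels.
chain_length <- function(P) {
  if (nrow(P) < 2) return(0)
  sum(sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2)))
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("skeleton_graph: %d pixels, %d edges (%d cycles, %d stubs), %d junction nodes\n",
              x$n_pixels, length(x$edges),
              sum(vapply(x$edges, function(e) e$is_cycle, TRUE)),
              sum(vapply(x$edges, function(e) e$is_stub, TRUE)),
              length(x$clusters)))
  invisible(x)
}
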
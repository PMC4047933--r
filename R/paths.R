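# Junction disambiguation: resolve bifurcations and intersections into
# individual filament paths by local tangent continuity.

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(0, 0) else v / n
}

angle_deg <- function(a, b) {
  acos(max(-1, min(1, sum(a * b)))) * 180 / pi
}

# Direction of a short pixel run by total-least-squares (principal axis),
# oriented to point from the run's first towards its last pixel. Much less
# sensitive to staircase jitter than an endpoint difference.
run_direction <- function(pts) {
  d_end <- pts[nrow(pts), ] - pts[1, ]
  x <- sweep(pts, 2, colMeans(pts))
  cv <- crossprod(x)
  ev <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  if (sum(ev * d_end) < 0) ev <- -ev
  unit(ev)
}

# Tangent of an edge chain at one end, pointing from the junction into the
# edge. The skeleton wanders inside the fused blob around a crossing, so the
# pixels immediately at the junction are skipped and the direction is fit
# over the next (up to) 10 pixels.
edge_tangent <- function(P, end, fallback = NULL, skip = 4L) {
  n <- nrow(P)
  if (n < 2) {
    if (!is.null(fallback)) return(unit(P[1, ] - fallback))
    return(c(0, 0))
  }
  skip <- max(0L, min(skip, n - 3L))
  w <- min(10L, n - skip)
  idx <- (1L + skip):(skip + w)
  if (end == 1) run_direction(P[idx, , drop = FALSE])
  else run_direction(P[n + 1L - idx, , drop = FALSE])
}

#' Resolve junctions into individual filament paths
#'
#' Digital skeletons represent one geometric crossing as one or more nearby
#' junction-pixel clusters joined by very short edges. Clusters connected by
#' edges of at most `junction_collapse_px` are therefore first merged into a
#' single compound junction (the short connecting edges become junction
#' material, routed as "via" pixels into one of the continuing paths). At
#' each compound junction the incident edge ends are then paired greedily by
#' smallest turn angle between their local tangents (a perfect continuation
#' has turn 0); a pair is accepted only if its turn is at most
#' `max_turn_deg`, and accepted pairs are concatenated across the junction.
#' A final stage bridges pairs of unpaired, junction-terminated path ends
#' whose tangents line up across a longer stretch of skeleton that another
#' filament already claimed — the situation left by two filaments crossing
#' at a shallow angle, where the shared skeleton segment can only belong to
#' one of them. Every skeleton pixel ends up in exactly one output path.
#'
#' Per-path length bookkeeping keeps the invariant
#' `length_px - joint_px - gap_px == sum of member edge lengths` exact:
#' `joint_px` counts the connection steps between consecutive chains inside
#' a junction and `gap_px` the bridged chords.
#'
#' @param graph a [build_graph()] result.
#' @param max_turn_deg maximum turn angle (degrees) for pairing two edges
#'   across a junction.
#' @param junction_collapse_px edges this short (px) between two junction
#'   nodes are treated as part of a single compound junction.
#' @param bridge_gap_px maximum end-to-end distance (px) for the
#'   shared-segment bridging stage; 0 disables it.
#' @param bridge_turn_deg maximum misalignment (degrees) between each end
#'   tangent and the bridging chord.
#' @return object of class `filament_paths`: a list of paths, each with
#'   `pixels` (ordered (row, col) matrix), `length_px` (chain metric:
#'   axial 1, diagonal sqrt(2), plus joints and gaps), `joint_px`, `gap_px`,
#'   `edges` (member edge ids), `closed`, `debris` (TRUE for paths made only
#'   of junction shrapnel: stubs and unused collapse edges); attributes
#'   `n_skeleton_px` and `total_edge_px` support the conservation
#'   invariants.
#' @export
disambiguate <- function(graph, max_turn_deg = 30, junction_collapse_px = 16,
                         bridge_gap_px = 30, bridge_turn_deg = 30) {
  stopifnot(inherits(graph, "skeleton_graph"),
            max_turn_deg > 0, max_turn_deg <= 90)
  edges <- graph$edges
  ne <- length(edges)
  nc <- length(graph$clusters)

  is_bridge <- vapply(edges, function(e)
    !e$is_cycle && !e$is_stub &&
      !is.na(e$clusters[1]) && !is.na(e$clusters[2]) &&
      e$length_px <= junction_collapse_px, TRUE)

  # union-find: merge clusters joined by bridge edges into compound junctions
  parent <- seq_len(max(nc, 1L))
  findp <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (e in which(is_bridge)) {
    a <- findp(edges[[e]]$clusters[1]); b <- findp(edges[[e]]$clusters[2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  super_of <- if (nc > 0) vapply(seq_len(nc), findp, 1L) else integer(0)

  # links[[e]][[end]] = c(other_edge, other_end); vias[[e]][[end]] = bridge ids
  links <- lapply(seq_len(ne), function(e) list(NULL, NULL))
  vias <- lapply(seq_len(ne), function(e) list(integer(0), integer(0)))
  bridge_used <- rep(FALSE, ne)

  # shortest bridge route (list of edge ids) between two clusters of one
  # compound junction, using only unused bridge edges
  bridge_route <- function(from_cl, to_cl) {
    if (from_cl == to_cl) return(integer(0))
    frontier <- list(list(cl = from_cl, route = integer(0)))
    seen <- from_cl
    while (length(frontier) > 0) {
      nxt <- list()
      for (f in frontier) {
        for (e in which(is_bridge & !bridge_used)) {
          cls <- edges[[e]]$clusters
          other <- if (cls[1] == f$cl) cls[2] else if (cls[2] == f$cl) cls[1] else NA
          if (is.na(other) || other %in% seen) next
          route <- c(f$route, e)
          if (other == to_cl) return(route)
          seen <- c(seen, other)
          nxt[[length(nxt) + 1L]] <- list(cl = other, route = route)
        }
      }
      frontier <- nxt
    }
    integer(0)
  }

  pair_slots <- function(slots, allow_pair) {
    ns <- length(slots)
    if (ns < 2) return(invisible(NULL))
    tang <- lapply(slots, function(s)
      edge_tangent(edges[[s$e]]$pixels, s$end,
                   fallback = graph$clusters[[edges[[s$e]]$clusters[s$end]]]$centroid))
    endpix <- lapply(slots, function(s) {
      P <- edges[[s$e]]$pixels
      if (s$end == 1) P[1, ] else P[nrow(P), ]
    })
    cand <- NULL
    for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
      if (slots[[i]]$e == slots[[j]]$e) next  # never close an edge onto itself
      if (!allow_pair(slots[[i]], slots[[j]])) next
      g <- endpix[[j]] - endpix[[i]]
      d <- sqrt(sum(g^2))
      if (d > junction_collapse_px + 6) next  # too far apart within compound
      # tangent continuity, plus chord consistency when the two ends are far
      # enough apart for the chord direction to be meaningful (compound
      # junctions spanning a shared segment)
      score <- 180 - angle_deg(tang[[i]], tang[[j]])
      if (d >= 6) {
        gu <- g / d
        score <- max(score, angle_deg(-tang[[i]], gu), angle_deg(-tang[[j]], -gu))
      }
      if (score <= max_turn_deg)
        cand <- rbind(cand, c(i, j, score))
    }
    if (is.null(cand)) return(invisible(NULL))
    cand <- cand[order(cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
    taken <- rep(FALSE, ns)
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (taken[i] || taken[j]) next
      si <- slots[[i]]; sj2 <- slots[[j]]
      if (!is.null(links[[si$e]][[si$end]]) ||
          !is.null(links[[sj2$e]][[sj2$end]])) next
      taken[i] <- taken[j] <- TRUE
      # a link-paired bridge becomes a path member and must never be
      # consumed as a via route, including by this very pair
      if (isTRUE(si$bridge)) bridge_used[si$e] <<- TRUE
      if (isTRUE(sj2$bridge)) bridge_used[sj2$e] <<- TRUE
      route <- bridge_route(edges[[si$e]]$clusters[si$end],
                            edges[[sj2$e]]$clusters[sj2$end])
      bridge_used[route] <<- TRUE
      links[[si$e]][[si$end]] <<- c(sj2$e, sj2$end)
      links[[sj2$e]][[sj2$end]] <<- c(si$e, si$end)
      vias[[si$e]][[si$end]] <<- route
      vias[[sj2$e]][[sj2$end]] <<- rev(route)
    }
    invisible(NULL)
  }

  for (sj in unique(super_of)) {
    members <- which(super_of == sj)
    slots <- list()
    for (e in seq_len(ne)) {
      if (edges[[e]]$is_cycle || edges[[e]]$is_stub || is_bridge[e]) next
      for (end in 1:2)
        if (!is.na(edges[[e]]$clusters[end]) &&
            edges[[e]]$clusters[end] %in% members)
          slots[[length(slots) + 1L]] <- list(e = e, end = end)
    }
    # round 1: pair the regular (outer) edge ends across the compound junction
    pair_slots(slots, function(a, b) TRUE)
    # round 2: a collapse edge no crossing consumed may be a real terminal
    # segment (a filament ending between two crossings); let its ends pair
    # with the slots that stayed free
    free_bridges <- which(is_bridge & !bridge_used &
                            vapply(seq_len(ne), function(e)
                              any(edges[[e]]$clusters %in% members), TRUE))
    if (length(free_bridges) > 0) {
      bslots <- list()
      for (e in free_bridges) for (end in 1:2)
        bslots[[length(bslots) + 1L]] <- list(e = e, end = end, bridge = TRUE)
      slots2 <- c(slots, bslots)
      pair_slots(slots2, function(a, b)
        isTRUE(a$bridge) || isTRUE(b$bridge))
    }
  }

  # assemble paths by walking linked edges, inserting via (bridge) chains
  used <- rep(FALSE, ne)
  paths <- list()
  orient <- function(e, enter_end) {
    P <- edges[[e]]$pixels
    if (enter_end == 2) P <- P[rev(seq_len(nrow(P))), , drop = FALSE]
    P
  }
  append_chunk <- function(state, P, elen, eid) {
    if (!is.null(state$pix))
      state$joint <- state$joint +
        sqrt(sum((P[1, ] - state$pix[nrow(state$pix), ])^2))
    state$pix <- rbind(state$pix, P)
    state$len <- state$len + elen
    state$ids <- c(state$ids, eid)
    state
  }
  walk_from <- function(e0, end0) {
    st <- list(pix = NULL, ids = integer(0), joint = 0, len = 0)
    e <- e0; enter <- end0
    repeat {
      used[e] <<- TRUE
      st <- append_chunk(st, orient(e, enter), edges[[e]]$length_px, e)
      exit <- 3L - enter
      lk <- links[[e]][[exit]]
      if (is.null(lk) || used[lk[1]]) break
      # insert via bridge chains between this edge and the next
      for (b in vias[[e]][[exit]]) {
        if (used[b]) next
        used[b] <<- TRUE
        Pb <- edges[[b]]$pixels
        # orient the via chain towards the current path end
        tail_px <- st$pix[nrow(st$pix), ]
        if (sum((Pb[1, ] - tail_px)^2) > sum((Pb[nrow(Pb), ] - tail_px)^2))
          Pb <- Pb[rev(seq_len(nrow(Pb))), , drop = FALSE]
        st <- append_chunk(st, Pb, edges[[b]]$length_px, b)
      }
      e <- lk[1]; enter <- lk[2]
    }
    lk <- links[[e]][[3L - enter]]
    closed_link <- !is.null(lk) && lk[1] == e0 && lk[2] == end0 &&
      length(st$ids) > 1
    list(pixels = st$pix, edges = st$ids, length_px = st$len + st$joint,
         joint_px = st$joint, gap_px = 0, closed = closed_link,
         debris = FALSE)
  }

  regular <- function(e) !edges[[e]]$is_cycle && !edges[[e]]$is_stub && !is_bridge[e]
  # open walks first (edges with at least one unlinked end)
  for (e in seq_len(ne)) {
    if (used[e] || !regular(e)) next
    free1 <- is.null(links[[e]][[1]])
    free2 <- is.null(links[[e]][[2]])
    if (!free1 && !free2) next
    paths[[length(paths) + 1L]] <- walk_from(e, if (free1) 1L else 2L)
  }
  # remaining regular edges sit on closed link-rings
  for (e in seq_len(ne)) {
    if (used[e] || !regular(e)) next
    p <- walk_from(e, 1L)
    p$closed <- TRUE
    paths[[length(paths) + 1L]] <- p
  }
  # pure pixel cycles
  for (e in seq_len(ne)) {
    if (used[e] || !edges[[e]]$is_cycle) next
    used[e] <- TRUE
    paths[[length(paths) + 1L]] <- list(pixels = edges[[e]]$pixels, edges = e,
                                        length_px = edges[[e]]$length_px,
                                        joint_px = 0, gap_px = 0,
                                        closed = TRUE, debris = FALSE)
  }
  # junction shrapnel: unused bridges and stubs become flagged debris paths
  for (e in seq_len(ne)) {
    if (used[e]) next
    used[e] <- TRUE
    paths[[length(paths) + 1L]] <- list(pixels = edges[[e]]$pixels, edges = e,
                                        length_px = edges[[e]]$length_px,
                                        joint_px = 0, gap_px = 0,
                                        closed = FALSE, debris = TRUE)
  }

  if (bridge_gap_px > 0) {
    occ <- matrix(FALSE, graph$dim[1], graph$dim[2])
    for (e in edges) occ[e$pixels] <- TRUE
    paths <- bridge_shared_segments(paths, edges, bridge_gap_px,
                                    bridge_turn_deg, occ)
  }

  structure(paths,
            class = "filament_paths",
            n_skeleton_px = graph$n_pixels,
            total_edge_px = sum(vapply(edges, function(e) e$length_px, 1)))
}

# Terminal info of an open path: end pixel, outward tangent, and the junction
# cluster at that end (NA if the end is free).
path_end_info <- function(p, edges, which_end) {
  P <- p$pixels
  n <- nrow(P)
  w <- min(9L, n)
  if (which_end == 1L) {
    px <- P[1, ]
    t_out <- if (n >= 2) run_direction(P[w:1, , drop = FALSE]) else c(0, 0)
    e <- p$edges[1]
    ep <- edges[[e]]$pixels
    end <- if (all(ep[1, ] == P[1, ])) 1L else 2L
  } else {
    px <- P[n, ]
    t_out <- if (n >= 2) run_direction(P[(n - w + 1L):n, , drop = FALSE]) else c(0, 0)
    e <- p$edges[length(p$edges)]
    ep <- edges[[e]]$pixels
    end <- if (all(ep[nrow(ep), ] == P[n, ])) 2L else 1L
  }
  cl <- edges[[e]]$clusters[end]
  list(pixel = px, tangent = t_out, cluster = cl)
}

# TRUE when the straight chord between two pixels runs along existing
# skeleton (every 1 px sample within Chebyshev distance 1 of a skeleton
# pixel) — a bridge must cross a shared segment, never open background.
chord_on_skeleton <- function(a, b, occ, miss_frac = 0.15) {
  d <- sqrt(sum((b - a)^2))
  n <- max(2L, ceiling(d))
  t <- seq(0, 1, length.out = n + 1L)
  rr <- round(a[1] + t * (b[1] - a[1]))
  cc <- round(a[2] + t * (b[2] - a[2]))
  nr <- nrow(occ); ncl <- ncol(occ)
  miss <- 0L
  for (k in seq_along(rr)) {
    hit <- FALSE
    for (dr in -1:1) {
      r2 <- rr[k] + dr
      if (r2 < 1 || r2 > nr) next
      for (dc in -1:1) {
        c2 <- cc[k] + dc
        if (c2 >= 1 && c2 <= ncl && occ[r2, c2]) { hit <- TRUE; break }
      }
      if (hit) break
    }
    if (!hit) miss <- miss + 1L
  }
  miss <= miss_frac * length(rr)
}

# Final stage: merge pairs of unpaired junction-terminated path ends whose
# tangents align across a chord (shallow-crossing shared segments).
bridge_shared_segments <- function(paths, edges, gap_max, turn_max, occ) {
  repeat {
    open_idx <- which(!vapply(paths, function(p) p$closed || p$debris, TRUE))
    cands <- list()
    for (pi in open_idx) {
      for (end in 1:2) {
        info <- path_end_info(paths[[pi]], edges, end)
        if (is.na(info$cluster)) next
        if (all(info$tangent == 0)) next
        cands[[length(cands) + 1L]] <- c(list(path = pi, end = end), info)
      }
    }
    if (length(cands) < 2) break
    best <- NULL
    for (i in seq_len(length(cands) - 1)) for (j in (i + 1):length(cands)) {
      a <- cands[[i]]; b <- cands[[j]]
      if (a$path == b$path) next
      if (!is.na(a$cluster) && !is.na(b$cluster) && a$cluster == b$cluster) next
      g <- b$pixel - a$pixel
      d <- sqrt(sum(g^2))
      if (d < 1e-9 || d > gap_max) next
      gu <- g / d
      ai <- angle_deg(a$tangent, gu)
      aj <- angle_deg(b$tangent, -gu)
      if (ai > turn_max || aj > turn_max) next
      if (!chord_on_skeleton(a$pixel, b$pixel, occ)) next
      score <- ai + aj
      if (is.null(best) || score < best$score)
        best <- list(i = i, j = j, score = score, d = d)
    }
    if (is.null(best)) break
    a <- cands[[best$i]]; b <- cands[[best$j]]
    pa <- paths[[a$path]]; pb <- paths[[b$path]]
    # orient a so its bridged end is the tail, b so its bridged end is the head
    if (a$end == 1L) pa <- reverse_path(pa)
    if (b$end == 2L) pb <- reverse_path(pb)
    merged <- list(pixels = rbind(pa$pixels, pb$pixels),
                   edges = c(pa$edges, pb$edges),
                   length_px = pa$length_px + pb$length_px + best$d,
                   joint_px = pa$joint_px + pb$joint_px,
                   gap_px = pa$gap_px + pb$gap_px + best$d,
                   closed = FALSE, debris = FALSE)
    paths[[a$path]] <- merged
    paths[[b$path]] <- NULL
  }
  paths
}

reverse_path <- function(p) {
  p$pixels <- p$pixels[rev(seq_len(nrow(p$pixels))), , drop = FALSE]
  p$edges <- rev(p$edges)
  p
}

#' Geometric length of a centerline pixel chain
#'
#' Sums the Euclidean step between consecutive chain pixels: 1 for an axial
#' step, `sqrt(2)` for a diagonal step. For an assembled filament path the
#' stored `length_px` (which also counts junction joints and bridged chords)
#' is returned.
#'
#' @param path an ordered (row, col) matrix, or one element of a
#'   [disambiguate()] result.
#' @param pixel_size_um optional physical pixel size; when given, the length
#'   is returned in micrometres.
#' @return numeric length.
#' @export
#' @examples
#' path_length(cbind(1, 1:10))            # 9
#' path_length(cbind(1:10, 1:10))         # 9 * sqrt(2)
path_length <- function(path, pixel_size_um = NULL) {
  len <- if (is.matrix(path)) {
    stopifnot(nrow(path) >= 1)
    chain_length(path)
  } else if (is.list(path) && !is.null(path$length_px)) {
    path$length_px
  } else stop("path must be a coordinate matrix or a filament path", call. = FALSE)
  if (!is.null(pixel_size_um)) len <- len * pixel_size_um
  len
}

#' @export
print.filament_paths <- function(x, ...) {
  lens <- vapply(x, function(p) p$length_px, 1)
  cat(sprintf("filament_paths: %d paths, total length %.1f px (median %.1f px)\n",
              length(x), sum(lens), stats::median(lens)))
  invisible(x)
}

# Principal-axis orientation of a path's pixels, in [0, pi).
path_orientation <- function(pixels) {
  if (nrow(pixels) < 2) return(0)
  x <- sweep(pixels, 2, colMeans(pixels))
  cv <- crossprod(x) / nrow(x)
  ev <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  atan2(ev[1], ev[2]) %% pi
}
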
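#' Skeleton component
#'
#' One 8-connected skeleton recovered in the smallest rectangular frame
#' containing it. Pixel coordinates are 0-based `(row, col)` within the
#' frame; `offset` places the frame in the full image, so full-image
#' coordinates are `frame coordinate + offset`.
#'
#' @param mask logical matrix (the frame) with the skeleton pixels `TRUE`.
#' @param offset integer `(row, col)` 0-based offset of the frame.
#' @return An object of class `skeleton_component`.
#' @export
skeleton_component <- function(mask, offset = c(0L, 0L)) {
  storage.mode(mask) <- "logical"
  stopifnot(any(mask), length(offset) == 2L)
  structure(list(mask = mask, offset = as.integer(offset)), class = "skeleton_component")
}

#' @export
print.skeleton_component <- function(x, ...) {
  cat(sprintf("<skeleton_component> %d px in %d x %d frame at (%d, %d)\n",
              sum(x$mask), nrow(x$mask), ncol(x$mask),
              x$offset[1L], x$offset[2L]))
  invisible(x)
}

# 0-based (row, col) pixels of a component, ordered by row-major index
skeleton_pixels <- function(skel) {
  rc <- which(skel$mask, arr.ind = TRUE) - 1L
  rc[order(rowmajor_index(rc, ncol(skel$mask))), , drop = FALSE]
}

#' Skeletonize a binary mask
#'
#' Homotopic thinning (Guo-Hall): boundary pixels are removed iteratively
#' without letting connected parts break apart or holes appear, leaving a
#' one-pixel-wide, 8-connected skeleton per input component. Each skeleton
#' is returned cropped to its smallest containing frame.
#'
#' @param mask logical matrix.
#' @return A list of [skeleton_component] objects (empty for an empty
#'   mask), in label order.
#' @export
skeletonize <- function(mask) {
  storage.mode(mask) <- "logical"
  if (!any(mask)) return(list())
  thin <- .thin_cpp(mask)
  lab <- .cc_label_cpp(thin, 8L)
  lapply(seq_len(max(lab)), function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    r0 <- min(idx[, 1L]); r1 <- max(idx[, 1L])
    c0 <- min(idx[, 2L]); c1 <- max(idx[, 2L])
    skeleton_component(lab[r0:r1, c0:c1, drop = FALSE] == l,
                       offset = c(r0 - 1L, c0 - 1L))
  })
}

#' Endpoint candidates nearest the four frame borders
#'
#' Endpoints are skeleton pixels with exactly one 8-neighbour. To keep the
#' longest-path search cheap, only up to four candidates are considered:
#' for each frame border (top, bottom, left, right) the endpoint closest to
#' it. When several endpoints are equidistant from a border the one with
#' the smaller row-major pixel index (closest to the upper-left corner) is
#' chosen. Duplicates are collapsed.
#'
#' @param skel a [skeleton_component].
#' @return Integer matrix (up to 4 rows) of 0-based `(row, col)` frame
#'   coordinates; zero rows when the skeleton is a closed loop.
#' @export
find_endpoint_candidates <- function(skel) {
  stopifnot(inherits(skel, "skeleton_component"))
  cnt <- .neighbour_count_cpp(skel$mask)
  ep <- which(skel$mask & cnt == 1L, arr.ind = TRUE) - 1L
  if (nrow(ep) == 0L)
    return(matrix(integer(), 0L, 2L, dimnames = list(NULL, c("row", "col"))))
  h <- nrow(skel$mask); w <- ncol(skel$mask)
  idx <- rowmajor_index(ep, w)
  border_dist <- cbind(top = ep[, 1L], bottom = (h - 1L) - ep[, 1L],
                       left = ep[, 2L], right = (w - 1L) - ep[, 2L])
  picks <- vapply(1:4, function(b) {
    d <- border_dist[, b]
    tied <- which(d == min(d))
    tied[which.min(idx[tied])]
  }, integer(1L))
  out <- ep[unique(picks), , drop = FALSE]
  colnames(out) <- c("row", "col")
  out
}

#' Geodesic distance along a skeleton
#'
#' Shortest-path distance from `origin` to every skeleton pixel, traversing
#' only skeleton pixels under 8-adjacency with quasi-euclidean step costs:
#' 1 for axial moves, sqrt(2) for diagonal moves.
#'
#' @param skel a [skeleton_component].
#' @param origin 0-based `(row, col)` frame coordinate on the skeleton.
#' @return Numeric matrix of distances over the frame; `Inf` off the
#'   skeleton or on unreachable pixels.
#' @export
geodesic_distance <- function(skel, origin) {
  stopifnot(inherits(skel, "skeleton_component"), length(origin) == 2L)
  .geodesic_cpp(skel$mask, as.integer(origin[1L]), as.integer(origin[2L]))
}

#' Strongest geodesic ends
#'
#' For each candidate endpoint, computes its geodesic map and finds the
#' farthest skeleton pixel; the pair with the overall largest geodesic
#' separation are the strongest geodesic ends (SGE). Ties are broken
#' deterministically by the row-major index of `end_a`, then of `end_b`.
#'
#' @param skel a [skeleton_component].
#' @param candidates matrix of 0-based `(row, col)` candidates, typically
#'   from [find_endpoint_candidates()].
#' @return List with `end_a`, `end_b` (0-based coordinates) and `max_dist`.
#' @export
find_sge <- function(skel, candidates) {
  stopifnot(nrow(candidates) >= 1L)
  w <- ncol(skel$mask)
  ord <- order(rowmajor_index(candidates, w))
  candidates <- candidates[ord, , drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(candidates))) {
    a <- candidates[i, ]
    dmap <- geodesic_distance(skel, a)
    dmap[!is.finite(dmap)] <- -Inf
    md <- max(dmap)
    hits <- which(dmap == md, arr.ind = TRUE) - 1L
    b <- hits[which.min(rowmajor_index(hits, w)), ]
    if (is.null(best) || md > best$max_dist + 1e-12)
      best <- list(end_a = unname(a), end_b = unname(b), max_dist = md)
  }
  best
}

#' Extract the spine between two skeleton endpoints
#'
#' Every skeleton pixel is assigned the sum of its geodesic distances to
#' the two ends. Pixels on a shortest path between the ends carry the
#' minimal sum -- exactly the geodesic length between them -- while pixels
#' on side branches carry larger sums, so the spine is recovered as the
#' regional minimum of the sum map (within a small tolerance absorbing
#' floating-point drift) and ordered by distance from `end_a`.
#'
#' @param skel a [skeleton_component].
#' @param end_a,end_b 0-based `(row, col)` skeleton coordinates.
#' @param tol sum-map tolerance; default `1e-6` times the frame diagonal.
#' @return An object of class `spine`: `path` (n x 2 matrix of 0-based
#'   full-image coordinates, ordered from `end_a` to `end_b`) and
#'   `geodesic_length_px`.
#' @export
extract_spine <- function(skel, end_a, end_b, tol = NULL) {
  stopifnot(inherits(skel, "skeleton_component"))
  if (is.null(tol))
    tol <- 1e-6 * sqrt(nrow(skel$mask)^2 + ncol(skel$mask)^2)
  da <- geodesic_distance(skel, end_a)
  db <- geodesic_distance(skel, end_b)
  L <- da[end_b[1L] + 1L, end_b[2L] + 1L]
  if (!is.finite(L)) stop("end_b not reachable from end_a")
  sum_map <- da + db
  on_spine <- is.finite(sum_map) & (sum_map <= L + tol)
  rc <- which(on_spine, arr.ind = TRUE) - 1L
  o <- order(da[on_spine], rowmajor_index(rc, ncol(skel$mask)))
  path <- rc[o, , drop = FALSE]
  path <- sweep(path, 2L, skel$offset, "+")
  colnames(path) <- c("row", "col")
  structure(list(path = path, geodesic_length_px = L), class = "spine")
}

#' @export
print.spine <- function(x, ...) {
  cat(sprintf("<spine> %d px, geodesic length %.3f px\n",
              nrow(x$path), x$geodesic_length_px))
  invisible(x)
}

# closed loop (no endpoints): the whole loop is its own spine, length =
# loop perimeter; path ordered by walking the cycle from the smallest
# row-major pixel
loop_spine <- function(skel) {
  px <- skeleton_pixels(skel)
  n <- nrow(px)
  w <- ncol(skel$mask)
  key <- rowmajor_index(px, w)
  lookup <- new.env(hash = TRUE, size = n)
  for (i in seq_len(n)) assign(as.character(key[i]), i, envir = lookup)
  nbrs <- function(i) {
    r <- px[i, 1L]; cc <- px[i, 2L]
    out <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      k <- as.character((r + dr) * w + (cc + dc))
      if (cc + dc >= 0 && cc + dc < w &&
          exists(k, envir = lookup, inherits = FALSE))
        out <- c(out, get(k, envir = lookup))
    }
    out
  }
  step_cost <- function(i, j)
    if (px[i, 1L] != px[j, 1L] && px[i, 2L] != px[j, 2L]) sqrt(2) else 1
  path <- integer(n); path[1L] <- 1L
  visited <- logical(n); visited[1L] <- TRUE
  len <- 0
  ok <- TRUE
  for (s in 2:n) {
    nb <- nbrs(path[s - 1L])
    nb <- nb[!visited[nb]]
    if (length(nb) == 0L) { ok <- FALSE; break }
    nxt <- nb[which.min(key[nb])]
    len <- len + step_cost(path[s - 1L], nxt)
    path[s] <- nxt; visited[nxt] <- TRUE
  }
  if (ok && path[n] %in% setdiff(nbrs(1L), path[2L])) {
    len <- len + step_cost(path[n], 1L)   # closing step of the cycle
    ordered <- px[path, , drop = FALSE]
  } else {
    # not a simple cycle (e.g. loop with an inner chord): fall back to an
    # ordering by geodesic distance and perimeter = sum of adjacency costs/2
    da <- geodesic_distance(skel, px[1L, ])
    ordered <- px[order(da[cbind(px[, 1L] + 1L, px[, 2L] + 1L)]), , drop = FALSE]
    len <- 0
    for (i in seq_len(n)) for (j in nbrs(i)) if (j > i)
      len <- len + step_cost(i, j)
  }
  pathm <- sweep(ordered, 2L, skel$offset, "+")
  colnames(pathm) <- c("row", "col")
  structure(list(path = pathm, geodesic_length_px = len), class = "spine")
}

#' Reprocess long residual branches
#'
#' After the primary spine is removed from its skeleton, residual branches
#' remain (e.g. the free arms where two filaments cross). Each residual
#' 8-connected component whose geodesic extent exceeds
#' `min_len_px` -- the minimum expected filament length, 31 px by
#' default -- is put through the same endpoint/SGE/spine procedure,
#' recursively, yielding supplementary spines.
#'
#' @param skel the original [skeleton_component].
#' @param spine the primary spine extracted from it.
#' @param min_len_px branches at most this long are pruned silently.
#' @return List of supplementary `spine` objects (possibly empty).
#' @export
reprocess_branches <- function(skel, spine, min_len_px = 31L) {
  residual <- skel$mask
  fr <- spine$path[, 1L] - skel$offset[1L] + 1L
  fc <- spine$path[, 2L] - skel$offset[2L] + 1L
  residual[cbind(fr, fc)] <- FALSE
  if (!any(residual)) return(list())
  out <- list()
  lab <- .cc_label_cpp(residual, 8L)
  for (l in seq_len(max(lab))) {
    idx <- which(lab == l, arr.ind = TRUE)
    r0 <- min(idx[, 1L]); r1 <- max(idx[, 1L])
    c0 <- min(idx[, 2L]); c1 <- max(idx[, 2L])
    sub <- skeleton_component(lab[r0:r1, c0:c1, drop = FALSE] == l,
                              offset = skel$offset + c(r0 - 1L, c0 - 1L))
    spines <- component_spines(sub, min_len_px, primary_min = TRUE)
    out <- c(out, spines)
  }
  out
}

# full spine recovery for one skeleton component: primary spine via the
# SGE, then recursive branch reprocessing; loops handled as whole spines.
# primary_min: drop the primary spine too when below min_len_px (used for
# residual branches, where short leftovers are pruning noise).
component_spines <- function(skel, min_len_px = 31L, primary_min = FALSE) {
  cand <- find_endpoint_candidates(skel)
  if (nrow(cand) == 0L) {
    sp <- loop_spine(skel)
    if (primary_min && sp$geodesic_length_px <= min_len_px) return(list())
    return(list(sp))
  }
  sge <- find_sge(skel, cand)
  if (primary_min && sge$max_dist <= min_len_px) return(list())
  sp <- extract_spine(skel, sge$end_a, sge$end_b)
  c(list(sp), reprocess_branches(skel, sp, min_len_px))
}

#' Extract all spines of a mask
#'
#' Convenience wrapper: skeletonize, then recover the primary spine of
#' every component and reprocess its long branches.
#'
#' @param mask logical matrix (after floc removal).
#' @param min_len_px minimum filament length for branch reprocessing.
#' @return List of `spine` objects in full-image coordinates.
#' @export
extract_spines <- function(mask, min_len_px = 31L) {
  skels <- skeletonize(mask)
  do.call(c, c(list(list()),
               lapply(skels, component_spines, min_len_px = min_len_px)))
}
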
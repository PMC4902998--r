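# independent oracles and random fixture generators, used by several files

# brute-force euclidean distance transform: nearest background pixel search
bf_distance_map <- function(mask) {
  out <- matrix(0, nrow(mask), ncol(mask))
  bg <- which(!mask, arr.ind = TRUE)
  obj <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(obj))) {
    out[obj[k, 1L], obj[k, 2L]] <-
      sqrt(min((bg[, 1L] - obj[k, 1L])^2 + (bg[, 2L] - obj[k, 2L])^2))
  }
  out
}

# quasi-euclidean shortest paths on the skeleton pixel graph via igraph:
# vertices = pixels, edges = 8-adjacency, weights 1 (axial) / sqrt(2)
igraph_geodesic <- function(mask, origin0) {
  px <- which(mask, arr.ind = TRUE) - 1L
  n <- nrow(px)
  id <- function(r, c) which(px[, 1L] == r & px[, 2L] == c)
  edges <- c(); weights <- c()
  for (k in seq_len(n)) {
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      j <- id(px[k, 1L] + dr, px[k, 2L] + dc)
      if (length(j) == 1L && j > k) {
        edges <- c(edges, k, j)
        weights <- c(weights, if (dr != 0 && dc != 0) sqrt(2) else 1)
      }
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  d <- igraph::distances(g, v = id(origin0[1L], origin0[2L]),
                         weights = weights)
  out <- matrix(Inf, nrow(mask), ncol(mask))
  out[cbind(px[, 1L] + 1L, px[, 2L] + 1L)] <- as.numeric(d)
  out
}

# random thin tree-shaped skeleton: grows 1-px arms from existing pixels,
# refusing pixels that would touch the tree anywhere but at their parent
# (so the result is a geometric tree: no cycles, no thick clumps)
random_tree_skeleton <- function(max_px = 50, size = 40) {
  m <- matrix(FALSE, size, size)
  start <- c(sample(5:(size - 5), 1L), sample(5:(size - 5), 1L))
  m[start[1L], start[2L]] <- TRUE
  pixels <- matrix(start, 1L)
  dirs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  n_arms <- sample(2:4, 1L)
  for (a in seq_len(n_arms)) {
    from <- pixels[sample(nrow(pixels), 1L), ]
    d <- dirs[sample(8L, 1L), ]
    cur <- from
    for (s in seq_len(sample(5:15, 1L))) {
      if (sum(m) >= max_px) break
      nxt <- cur + d
      if (any(nxt < 2L) || any(nxt > size - 1L)) break
      # every neighbour of the new pixel except the current one must be empty
      nb <- 0L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        if (m[nxt[1L] + dr, nxt[2L] + dc]) nb <- nb + 1L
      }
      if (nb > 1L) break
      m[nxt[1L], nxt[2L]] <- TRUE
      pixels <- rbind(pixels, nxt)
      cur <- nxt
    }
  }
  m
}

# random blob mask for distance-transform oracles
random_blob_mask <- function(size = 24, p = 0.35) {
  m <- matrix(runif(size * size) < p, size, size)
  m[1L, ] <- FALSE  # guarantee some background
  m
}

# exhaustive strongest-pair search over ALL skeleton endpoints (not just
# the 4 border candidates), via the igraph oracle
exhaustive_sge <- function(mask) {
  skel <- skeleton_component(mask)
  cnt <- filatrace:::.neighbour_count_cpp(mask)
  ep <- which(mask & cnt == 1L, arr.ind = TRUE) - 1L
  best <- list(max_dist = -Inf)
  for (i in seq_len(nrow(ep))) {
    d <- igraph_geodesic(mask, ep[i, ])
    for (j in seq_len(nrow(ep))) {
      v <- d[ep[j, 1L] + 1L, ep[j, 2L] + 1L]
      if (v > best$max_dist)
        best <- list(end_a = unname(ep[i, ]), end_b = unname(ep[j, ]),
                     max_dist = v)
    }
  }
  best
}

# handy constructors for pixel-drawn skeletons
mask_from_coords <- function(coords, size) {
  m <- matrix(FALSE, size[1L], size[2L])
  m[coords] <- TRUE
  m
}

# minimal filament_record for io tests
fake_record <- function(image_id, length_um, rrg = 5, n_px = 10) {
  path <- cbind(row = seq_len(n_px) - 1L, col = rep(0L, n_px))
  sp <- structure(list(path = path, geodesic_length_px = n_px - 1),
                  class = "spine")
  structure(list(spine = sp, rrg = rrg, length_um = length_um,
                 image_id = image_id), class = "filament_record")
}
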
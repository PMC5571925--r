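# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# All 26-neighborhood offsets, restricted to the requested connectivity.
neighbor_offsets <- function(connectivity = 26L) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  keep <- switch(as.character(connectivity),
    "6"  = rowSums(abs(g)) == 1L,
    "18" = rowSums(abs(g)) <= 2L,
    "26" = rep(TRUE, nrow(g)),
    stop("connectivity must be one of 6, 18, 26", call. = FALSE)
  )
  storage.mode(g) <- "integer"
  unname(g[keep, , drop = FALSE])
}

# One offset per antipodal pair of the 26-neighborhood: the 13 unique
# one-voxel displacement directions used for GLCM/GLRLM aggregation.
direction_offsets <- function(connectivity = 26L) {
  g <- neighbor_offsets(connectivity)
  keep <- apply(g, 1L, function(d) {
    nz <- d[d != 0L]
    nz[1L] > 0L
  })
  g[keep, , drop = FALSE]
}

# The 13 unique one-voxel displacement directions (fixed across the package).
DIRECTIONS_13 <- direction_offsets(26L)

lin_index <- function(ijk, dm) {
  ijk[, 1L] + (ijk[, 2L] - 1L) * dm[1L] + (ijk[, 3L] - 1L) * dm[1L] * dm[2L]
}

# Linear indices of all voxel pairs (from, to = from + d) fully inside a grid
# of dimension `dm`. Returns NULL when the offset admits no pair.
offset_pairs <- function(dm, d) {
  ax <- lapply(1:3, function(a) {
    lo <- max(1L, 1L - d[a])
    hi <- min(dm[a], dm[a] - d[a])
    if (lo > hi) integer(0) else lo:hi
  })
  if (any(lengths(ax) == 0L)) return(NULL)
  from <- as.matrix(expand.grid(ax[[1L]], ax[[2L]], ax[[3L]]))
  storage.mode(from) <- "integer"
  to <- from
  to[, 1L] <- to[, 1L] + d[1L]
  to[, 2L] <- to[, 2L] + d[2L]
  to[, 3L] <- to[, 3L] + d[3L]
  list(from = lin_index(from, dm), to = lin_index(to, dm))
}

# Connected-component labels over the TRUE voxels of a logical array.
# `values`: optional array; when given, edges only join equal-valued voxels
# (used for grey-level size zones). Returns an integer array with 0 outside.
label_components <- function(in_set, connectivity = 26L, values = NULL) {
  dm <- dim(in_set)
  idx <- which(in_set)
  labels <- array(0L, dm)
  if (length(idx) == 0L) return(labels)
  vid <- array(0L, dm)
  vid[idx] <- seq_along(idx)
  dirs <- direction_offsets(connectivity)
  edges_from <- integer(0)
  edges_to <- integer(0)
  for (r in seq_len(nrow(dirs))) {
    pr <- offset_pairs(dm, dirs[r, ])
    if (is.null(pr)) next
    ok <- in_set[pr$from] & in_set[pr$to]
    if (!is.null(values)) ok <- ok & (values[pr$from] == values[pr$to])
    if (any(ok)) {
      edges_from <- c(edges_from, vid[pr$from[ok]])
      edges_to <- c(edges_to, vid[pr$to[ok]])
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges_from)) {
    g <- igraph::add_edges(g, rbind(edges_from, edges_to))
  }
  labels[idx] <- as.integer(igraph::components(g)$membership)
  labels
}

# Connected component of `in_set` containing `seed` (voxel i,j,k).
seeded_component <- function(in_set, seed, connectivity = 26L) {
  dm <- dim(in_set)
  out <- array(FALSE, dm)
  s <- lin_index(matrix(as.integer(seed), nrow = 1L), dm)
  if (!in_set[s]) return(out)
  offs <- neighbor_offsets(connectivity)
  stride <- c(1L, dm[1L], dm[1L] * dm[2L])
  visited <- array(FALSE, dm)
  visited[s] <- TRUE
  frontier_ijk <- matrix(as.integer(seed), nrow = 1L)
  while (nrow(frontier_ijk) > 0L) {
    nb_ijk <- do.call(rbind, lapply(seq_len(nrow(offs)), function(r) {
      sweep(frontier_ijk, 2L, offs[r, ], "+")
    }))
    ok <- nb_ijk[, 1L] >= 1L & nb_ijk[, 1L] <= dm[1L] &
      nb_ijk[, 2L] >= 1L & nb_ijk[, 2L] <= dm[2L] &
      nb_ijk[, 3L] >= 1L & nb_ijk[, 3L] <= dm[3L]
    nb_ijk <- nb_ijk[ok, , drop = FALSE]
    if (nrow(nb_ijk) == 0L) break
    lin <- nb_ijk %*% stride - stride[2L] - stride[3L]
    lin <- as.integer(lin)
    keep <- in_set[lin] & !visited[lin]
    if (!any(keep)) break
    lin <- lin[keep]
    nb_ijk <- nb_ijk[keep, , drop = FALSE]
    dup <- duplicated(lin)
    lin <- lin[!dup]
    visited[lin] <- TRUE
    frontier_ijk <- nb_ijk[!dup, , drop = FALSE]
  }
  out[visited] <- TRUE
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
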
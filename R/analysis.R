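## Droplet analysis: chain-level DBSCAN clustering (contact or
## center-of-mass neighborhoods), the mixing coordinate
## m = sqrt(D11 D22)/D12 built from mean inter-chain COM distances, the
## droplet shape coordinate eta (sum of pairwise max axis-extent
## ratios; 3 = spherically symmetric), and slab density profiles.
## Chain COMs under periodic boundaries use the circular-mean method.

#' Periodic center of mass
#'
#' Mass-weighted circular-mean COM per axis: robust to chains/droplets
#' wrapping across the periodic boundary.
#'
#' @param coords coordinate matrix.
#' @param box box lengths.
#' @param masses optional weights (default equal).
#' @return length-3 COM inside `[0, box)`.
#' @export
periodic_com <- function(coords, box, masses = NULL) {
  if (is.null(masses)) masses <- rep(1, nrow(coords))
  w <- masses / sum(masses)
  out <- numeric(3)
  for (ax in 1:3) {
    th <- 2 * pi * coords[, ax] / box[ax]
    ang <- atan2(sum(w * sin(th)), sum(w * cos(th)))
    out[ax] <- (ang / (2 * pi) * box[ax]) %% box[ax]
  }
  out
}

# COM of every chain in a frame
.chain_coms <- function(coords, chains, box, masses = NULL) {
  t(vapply(chains, function(idx) {
    m <- if (is.null(masses)) NULL else masses[idx]
    periodic_com(coords[idx, , drop = FALSE], box, m)
  }, numeric(3)))
}

#' Chain-chain distance / contact matrix
#'
#' `metric = "contact"`: boolean adjacency, TRUE when any inter-chain
#' residue pair is within `contact_cutoff` (minimum image).
#' `metric = "com"`: periodic minimum-image distance between chain
#' centers of mass.
#'
#' @param coords frame coordinate matrix.
#' @param chains list of per-chain particle index vectors (a partition
#'   of the particles).
#' @param box box lengths.
#' @param metric `"contact"` or `"com"`.
#' @param contact_cutoff residue contact cutoff (A), default 10.
#' @param masses optional particle masses for the COM metric.
#' @return symmetric matrix (logical for contact, numeric for com).
#' @export
chain_distance_matrix <- function(coords, chains, box,
                                  metric = c("contact", "com"),
                                  contact_cutoff = 10, masses = NULL) {
  metric <- match.arg(metric)
  nch <- length(chains)
  if (any(vapply(chains, length, integer(1)) == 0))
    stop("empty chain in chain list")
  if (metric == "com") {
    coms <- .chain_coms(coords, chains, box, masses)
    M <- matrix(0, nch, nch)
    for (a in seq_len(nch - 1)) {
      d <- min_image(coms[(a + 1):nch, , drop = FALSE] -
                       matrix(coms[a, ], nch - a, 3, byrow = TRUE), box)
      M[a, (a + 1):nch] <- M[(a + 1):nch, a] <- row_norm(d)
    }
    M
  } else {
    M <- matrix(FALSE, nch, nch)
    cut2 <- contact_cutoff^2
    for (a in seq_len(nch - 1)) {
      xa <- coords[chains[[a]], , drop = FALSE]
      for (b in (a + 1):nch) {
        xb <- coords[chains[[b]], , drop = FALSE]
        hit <- FALSE
        for (ax_row in seq_len(nrow(xa))) {
          d <- min_image(xb - matrix(xa[ax_row, ], nrow(xb), 3,
                                     byrow = TRUE), box)
          if (any(rowSums(d * d) <= cut2)) { hit <- TRUE; break }
        }
        M[a, b] <- M[b, a] <- hit
      }
    }
    M
  }
}

#' Chain-level DBSCAN clustering
#'
#' Density-based clustering of whole chains. Neighborhoods: under the
#' contact metric, the chains in contact; under the COM metric, chains
#' with COM distance < `eps`. A chain is a core point when its
#' neighborhood (itself included) has at least `min_pts` members;
#' clusters grow from core points, border chains join the
#' first-discovered cluster, and clusters smaller than
#' `min_cluster_size` are relabeled noise. Deterministic for a fixed
#' chain order.
#'
#' @param matrix chain-chain matrix from [chain_distance_matrix()].
#' @param metric `"contact"` or `"com"` (how to read `matrix`).
#' @param eps neighborhood radius for the COM metric (A).
#' @param min_pts minimum neighborhood size for a core chain.
#' @param min_cluster_size minimum surviving cluster size.
#' @return object of class `cg_clusters`: `labels` (0 = noise, clusters
#'   numbered 1..n_d in discovery order), `n_droplets`, `sizes`.
#' @export
cluster_chains <- function(matrix, metric = c("contact", "com"),
                           eps = 0.5, min_pts = 20, min_cluster_size = 100) {
  metric <- match.arg(metric)
  stopifnot(eps > 0, min_pts > 0, min_cluster_size > 0)
  n <- nrow(matrix)
  adj <- if (metric == "contact") matrix & TRUE else matrix < eps
  diag(adj) <- TRUE
  neigh <- lapply(seq_len(n), function(a) which(adj[a, ]))
  core <- vapply(neigh, length, integer(1)) >= min_pts
  labels <- rep(0L, n)
  visited <- rep(FALSE, n)
  cl <- 0L
  for (p in seq_len(n)) {
    if (visited[p] || !core[p]) next
    cl <- cl + 1L
    queue <- p
    visited[p] <- TRUE
    labels[p] <- cl
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      if (!core[q]) next
      for (nb in neigh[[q]]) {
        if (labels[nb] == 0L) labels[nb] <- cl
        if (!visited[nb]) {
          visited[nb] <- TRUE
          if (core[nb]) queue <- c(queue, nb)
        }
      }
    }
  }
  # post-filter small clusters to noise and renumber contiguously
  sizes <- tabulate(labels, nbins = max(labels, 1))
  keep <- which(sizes >= min_cluster_size)
  remap <- integer(max(labels, 1))
  remap[keep] <- seq_along(keep)
  pos <- labels > 0L
  labels[pos] <- remap[labels[pos]]
  sizes <- tabulate(labels, nbins = max(labels, 0))
  structure(list(labels = labels, n_droplets = length(sizes),
                 sizes = sizes),
            class = "cg_clusters")
}

#' @export
print.cg_clusters <- function(x, ...) {
  cat(sprintf("<cg_clusters> %d droplet(s); sizes: %s; %d noise chains\n",
              x$n_droplets, paste(x$sizes, collapse = ", "),
              sum(x$labels == 0)))
  invisible(x)
}

#' Mixing coordinate of a two-population droplet
#'
#' `D_IJ` is the mean minimum-image COM distance over all chain pairs
#' with one chain from population I and one from J (self-pairs
#' excluded); the mixing coordinate is `m = sqrt(D11 D22) / D12`:
#' ~`2R/(separation)`-like small values for two separate droplets,
#' ~1 for complete mixing.
#'
#' @param coords frame coordinates.
#' @param chains per-chain index list.
#' @param labels_initial chain labels 1 or 2 (initial droplet identity).
#' @param box box lengths.
#' @param masses optional particle masses.
#' @return list with `D11`, `D22`, `D12`, `m`.
#' @export
mixing_metrics <- function(coords, chains, labels_initial, box,
                           masses = NULL) {
  stopifnot(length(labels_initial) == length(chains))
  if (sum(labels_initial == 1) < 2 || sum(labels_initial == 2) < 2)
    stop("each label needs >= 2 chains for the diagonal D terms")
  coms <- .chain_coms(coords, chains, box, masses)
  D <- chain_com_matrix(coms, box)
  avg <- function(I, J) {
    a <- which(labels_initial == I); b <- which(labels_initial == J)
    sub <- D[a, b, drop = FALSE]
    if (I == J) sum(sub) / (length(a) * (length(a) - 1))
    else mean(sub)
  }
  D11 <- avg(1, 1); D22 <- avg(2, 2); D12 <- avg(1, 2)
  list(D11 = D11, D22 = D22, D12 = D12, m = sqrt(D11 * D22) / D12)
}

# full COM distance matrix from precomputed COMs
chain_com_matrix <- function(coms, box) {
  n <- nrow(coms)
  M <- matrix(0, n, n)
  for (a in seq_len(n - 1)) {
    d <- min_image(coms[(a + 1):n, , drop = FALSE] -
                     matrix(coms[a, ], n - a, 3, byrow = TRUE), box)
    M[a, (a + 1):n] <- M[(a + 1):n, a] <- row_norm(d)
  }
  M
}

#' Droplet shape coordinate
#'
#' Per-axis extents d_x, d_y, d_z are the standard deviations of the
#' droplet particle coordinates about the droplet COM (minimum-image,
#' so a droplet straddling the boundary is handled); the shape
#' coordinate is
#' `eta = max(dx/dy, dy/dx) + max(dy/dz, dz/dy) + max(dz/dx, dx/dz)`.
#' `eta = 3` for any axis-symmetric distribution; larger values mean
#' anisotropy. With `use_range = TRUE` the extents are the coordinate
#' ranges instead.
#'
#' @param coords coordinates of the droplet particles.
#' @param box box lengths.
#' @param use_range use max-min extents instead of standard deviations.
#' @return eta (>= 3).
#' @export
shape_eta <- function(coords, box, use_range = FALSE) {
  stopifnot(nrow(coords) >= 2)
  com <- periodic_com(coords, box)
  rel <- min_image(coords - matrix(com, nrow(coords), 3, byrow = TRUE), box)
  d <- if (use_range) apply(rel, 2, function(v) diff(range(v)))
  else apply(rel, 2, stats::sd)
  if (any(d == 0)) stop("degenerate droplet: zero extent on an axis")
  max(d[1] / d[2], d[2] / d[1]) + max(d[2] / d[3], d[3] / d[2]) +
    max(d[3] / d[1], d[1] / d[3])
}

#' Slab density profile along an axis
#'
#' Time-averaged histogram of particle positions along one box axis,
#' normalized by slab volume (particles / A^3).
#'
#' @param frames list of coordinate matrices (a trajectory window).
#' @param box box lengths.
#' @param axis 1, 2 or 3.
#' @param bins number of slabs (>= 2).
#' @return data frame with `center` (A) and `density` (1/A^3).
#' @export
density_profile <- function(frames, box, axis = 3, bins = 50) {
  stopifnot(bins >= 2)
  if (!is.list(frames)) frames <- list(frames)
  edges <- seq(0, box[axis], length.out = bins + 1)
  counts <- numeric(bins)
  for (fr in frames) {
    z <- fr[, axis] %% box[axis]
    h <- findInterval(z, edges, rightmost.closed = TRUE)
    h[h < 1] <- 1; h[h > bins] <- bins
    counts <- counts + tabulate(h, nbins = bins)
  }
  slab_vol <- prod(box[-axis]) * diff(edges[1:2])
  data.frame(center = (edges[-1] + edges[-(bins + 1)]) / 2,
             density = counts / (length(frames) * slab_vol))
}
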
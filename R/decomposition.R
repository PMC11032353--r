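## Cell-based kd-tree domain decomposition: the cell grid is recursively
## bisected along cell boundaries so the two sides carry nearly equal
## particle counts, until one subdomain per process remains. Pair
## ownership follows the midpoint-cell rule; halo plans list the foreign
## boundary cells each subdomain needs. Everything runs in-process: the
## correctness surface is the identity between decomposed (owned-pair)
## energy sums and the serial result.

# linear cell id (1-based) from 0-based cell coordinates
.cell_id <- function(cx, cy, cz, nc) 1L + cx + nc[1] * (cy + nc[2] * cz)

.cell_xyz <- function(id, nc) {
  id0 <- id - 1L
  cx <- id0 %% nc[1]
  cy <- (id0 %/% nc[1]) %% nc[2]
  cz <- id0 %/% (nc[1] * nc[2])
  cbind(cx, cy, cz)
}

#' Particle-balanced kd-tree partition of the cell grid
#'
#' Recursively bisects the cell box along one axis at a cell boundary,
#' choosing the split that brings the left-side particle weight closest
#' to the target fraction (ceiling(n/2) : floor(n/2) for odd counts).
#' The split axis is the longest edge of the current sub-box in cells,
#' ties broken x, y, z; split-position ties take the smaller index.
#' Cells with zero particles are distributed by the same rule.
#'
#' @param grid a [build_cell_grid()] result.
#' @param counts_per_cell particle count per linear cell id.
#' @param n_subdomains number of subdomains (>= 1, <= number of cells).
#' @param method `"exact"` searches all recursive axis-aligned bisections
#'   (memoized min-max of the subdomain loads), `"greedy"` picks each
#'   split to balance the two sides locally; `"auto"` (default) uses the
#'   exact search on grids up to 512 cells and 64 subdomains.
#' @return object of class `cg_partition`: `assign` (subdomain id per
#'   cell), `cells` (per-subdomain cell id list), `counts`
#'   (per-subdomain particle counts), `imbalance` (max/mean), `ncell`.
#' @export
kdtree_partition <- function(grid, counts_per_cell, n_subdomains,
                             method = c("auto", "exact", "greedy")) {
  method <- match.arg(method)
  nc <- grid$ncell
  ncells <- prod(nc)
  stopifnot(length(counts_per_cell) == ncells)
  if (n_subdomains < 1) stop("n_subdomains must be >= 1")
  if (n_subdomains > ncells)
    stop("n_subdomains exceeds the number of cells (", ncells, ")")
  if (method == "auto")
    method <- if (ncells <= 512 && n_subdomains <= 64) "exact" else "greedy"
  assign <- integer(ncells)
  next_id <- 0L
  box_cells <- function(lo, hi) {
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    g <- expand.grid(cx = xs, cy = ys, cz = zs)
    .cell_id(g$cx, g$cy, g$cz, nc)
  }
  wbox <- function(lo, hi) sum(counts_per_cell[box_cells(lo, hi)])
  feas_splits <- function(lo, hi, ax, n_left, n_right) {
    ext <- hi - lo + 1L
    if (ext[ax] < 2L) return(integer(0))
    cand <- lo[ax]:(hi[ax] - 1L)
    other <- prod(ext[-ax])
    cand[(cand - lo[ax] + 1L) * other >= n_left &
           (hi[ax] - cand) * other >= n_right]
  }
  if (method == "exact") {
    memo <- new.env(parent = emptyenv())
    # minimal achievable max subdomain load for (box, n)
    best_val <- function(lo, hi, n) {
      key <- paste(c(lo, hi, n), collapse = ",")
      v <- memo[[key]]
      if (!is.null(v)) return(v)
      if (n == 1L) {
        v <- wbox(lo, hi)
      } else {
        nl <- as.integer(ceiling(n / 2)); nr <- n - nl
        v <- Inf
        for (ax in 1:3) {
          for (cv in feas_splits(lo, hi, ax, nl, nr)) {
            hl <- hi; hl[ax] <- cv
            lr <- lo; lr[ax] <- cv + 1L
            v <- min(v, max(best_val(lo, hl, nl), best_val(lr, hi, nr)))
          }
        }
      }
      memo[[key]] <- v
      v
    }
    recurse <- function(lo, hi, n) {
      if (n == 1L) {
        next_id <<- next_id + 1L
        assign[box_cells(lo, hi)] <<- next_id
        return(invisible())
      }
      nl <- as.integer(ceiling(n / 2)); nr <- n - nl
      target <- best_val(lo, hi, n)
      for (ax in 1:3) {
        for (cv in feas_splits(lo, hi, ax, nl, nr)) {
          hl <- hi; hl[ax] <- cv
          lr <- lo; lr[ax] <- cv + 1L
          if (max(best_val(lo, hl, nl), best_val(lr, hi, nr)) <= target) {
            recurse(lo, hl, nl)
            recurse(lr, hi, nr)
            return(invisible())
          }
        }
      }
      stop("no feasible split for ", n, " subdomains")
    }
  } else {
    recurse <- function(lo, hi, n) {
      if (n == 1L) {
        next_id <<- next_id + 1L
        assign[box_cells(lo, hi)] <<- next_id
        return(invisible())
      }
      n_left <- as.integer(ceiling(n / 2))
      n_right <- n - n_left
      frac <- n_left / n
      total <- wbox(lo, hi)
      ext <- hi - lo + 1L
      axes <- order(-ext, 1:3)  # longest first, ties x->y->z
      for (ax in axes) {
        cand <- feas_splits(lo, hi, ax, n_left, n_right)
        if (!length(cand)) next
        wl <- vapply(cand, function(cv) {
          hl <- hi; hl[ax] <- cv
          wbox(lo, hl)
        }, numeric(1))
        c_best <- cand[which.min(abs(wl - frac * total))]
        hi_l <- hi; hi_l[ax] <- c_best
        lo_r <- lo; lo_r[ax] <- c_best + 1L
        recurse(lo, hi_l, n_left)
        recurse(lo_r, hi, n_right)
        return(invisible())
      }
      stop("no feasible split for ", n, " subdomains in a ",
           paste(ext, collapse = "x"), " cell box")
    }
  }
  recurse(c(0L, 0L, 0L), nc - 1L, as.integer(n_subdomains))
  cells <- split(seq_len(ncells), assign)
  counts <- vapply(cells, function(idx) sum(counts_per_cell[idx]),
                   numeric(1))
  structure(list(assign = assign, cells = cells, counts = counts,
                 imbalance = partition_imbalance(counts),
                 ncell = nc, n_subdomains = as.integer(n_subdomains)),
            class = "cg_partition")
}

#' Load imbalance of per-subdomain particle counts
#' @param counts per-subdomain particle counts.
#' @return max count / mean count (1 = perfect balance); 1 when empty.
#' @export
partition_imbalance <- function(counts) {
  if (sum(counts) == 0) return(1)
  max(counts) / mean(counts)
}

#' @export
print.cg_partition <- function(x, ...) {
  cat(sprintf("<cg_partition> %d subdomains over %d x %d x %d cells, imbalance %.3f\n",
              x$n_subdomains, x$ncell[1], x$ncell[2], x$ncell[3],
              x$imbalance))
  invisible(x)
}

#' Halo (boundary-cell exchange) plan
#'
#' For each subdomain, the foreign cells within `shells` cells
#' (Chebyshev distance, periodic) of any owned cell, grouped by owning
#' subdomain. The plan is symmetric by construction: what A receives
#' from B is what B sends to A.
#'
#' @param partition a `cg_partition`.
#' @param grid the matching `cg_cell_grid`.
#' @param shells shell depth in cells (2 covers the electrostatic range
#'   under the half-threshold cell-size rule).
#' @return list with `receive[[A]][[as.character(B)]]` = sorted cell
#'   ids A imports from B, and the mirrored `send`.
#' @export
halo_plan <- function(partition, grid, shells = 2L) {
  nc <- grid$ncell
  ncells <- prod(nc)
  offs <- expand.grid(dx = -shells:shells, dy = -shells:shells,
                      dz = -shells:shells)
  xyz <- .cell_xyz(seq_len(ncells), nc)
  nsub <- partition$n_subdomains
  receive <- vector("list", nsub)
  for (A in seq_len(nsub)) {
    owned <- partition$cells[[A]]
    oxyz <- xyz[owned, , drop = FALSE]
    neigh <- integer(0)
    for (o in seq_len(nrow(offs))) {
      cx <- (oxyz[, 1] + offs$dx[o]) %% nc[1]
      cy <- (oxyz[, 2] + offs$dy[o]) %% nc[2]
      cz <- (oxyz[, 3] + offs$dz[o]) %% nc[3]
      neigh <- c(neigh, .cell_id(cx, cy, cz, nc))
    }
    halo <- setdiff(unique(neigh), owned)
    owners <- partition$assign[halo]
    receive[[A]] <- lapply(split(halo, owners), sort)
  }
  send <- vector("list", nsub)
  for (A in seq_len(nsub)) send[[A]] <- list()
  for (A in seq_len(nsub)) {
    for (Bc in names(receive[[A]])) {
      send[[as.integer(Bc)]][[as.character(A)]] <- receive[[A]][[Bc]]
    }
  }
  list(receive = receive, send = send, shells = as.integer(shells))
}

#' Midpoint-cell pair ownership
#'
#' Each pair belongs to the subdomain owning the cell that contains the
#' minimum-image midpoint of the two particles. Midpoints exactly on a
#' cell boundary land deterministically in the lower-index cell through
#' the floor binning.
#'
#' @param i,j particle index vectors (parallel).
#' @param coords coordinate matrix.
#' @param grid the `cg_cell_grid`.
#' @param partition the `cg_partition`.
#' @return integer vector of owning subdomain ids.
#' @export
assign_pair_owner <- function(i, j, coords, grid, partition) {
  d <- min_image(coords[j, , drop = FALSE] - coords[i, , drop = FALSE],
                 grid$box)
  mid <- wrap_coords(coords[i, , drop = FALSE] + 0.5 * d, grid$box)
  cx <- pmin(grid$ncell[1] - 1L, as.integer(floor(mid[, 1] / grid$edge[1])))
  cy <- pmin(grid$ncell[2] - 1L, as.integer(floor(mid[, 2] / grid$edge[2])))
  cz <- pmin(grid$ncell[3] - 1L, as.integer(floor(mid[, 3] / grid$edge[3])))
  partition$assign[.cell_id(cx, cy, cz, grid$ncell)]
}

#' Periodic load rebalancing
#'
#' At multiples of the update period, repartitions the (unchanged) cell
#' grid on the current per-cell particle counts and keeps whichever of
#' the old and new partitions has the lower imbalance; outside the
#' period, the partition is returned unchanged.
#'
#' @param partition current `cg_partition`.
#' @param grid the `cg_cell_grid` (cell size never changes here).
#' @param new_counts current per-cell particle counts.
#' @param step current MD step.
#' @param period update period in steps (`Inf` disables).
#' @return a `cg_partition`.
#' @export
rebalance <- function(partition, grid, new_counts, step, period) {
  if (!is.finite(period) || step %% period != 0) return(partition)
  old_counts <- vapply(partition$cells,
                       function(idx) sum(new_counts[idx]), numeric(1))
  old_imb <- partition_imbalance(old_counts)
  fresh <- kdtree_partition(grid, new_counts, partition$n_subdomains)
  if (fresh$imbalance <= old_imb) fresh else {
    partition$counts <- old_counts
    partition$imbalance <- old_imb
    partition
  }
}
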
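## Cell grid and the unified multi-cutoff neighbor-list scheme: one
## distance sweep populates the excluded-volume, DNA-pairing and HPS class
## lists (whose search thresholds are the class cutoffs plus a common
## buffer skin), the electrostatic list is built over charged particles
## only, and the protein-DNA recognition list is kept directed. Rebuilds
## are skipped while the maximum particle displacement stays below half
## the buffer.

#' Build the cell grid
#'
#' Cells are at least half the electrostatic neighbor-search distance on
#' each axis: per axis the cell count is `floor(box / (r_p_ele / 2))`
#' (minimum 1) so every cell edge is `>= r_p_ele / 2`. All particles are
#' binned after periodic wrapping.
#'
#' @param state a `cg_state` (or any list with `coords` and `box`).
#' @param r_p_ele electrostatic neighbor-search threshold (cutoff +
#'   buffer), A.
#' @return object of class `cg_cell_grid`: cell counts, edges, linear
#'   cell id per particle and per-cell particle index lists.
#' @export
build_cell_grid <- function(state, r_p_ele) {
  box <- state$box
  if (any(box < 2 * r_p_ele))
    stop(sprintf(
      "box too small for minimum-image search: need every edge >= %g A",
      2 * r_p_ele))
  ncell <- pmax(1L, as.integer(floor(box / (r_p_ele / 2))))
  edge <- box / ncell
  x <- state$coords
  n <- nrow(x)
  if (n > 0) {
    xw <- wrap_coords(x, box)
    ix <- pmin(ncell[1] - 1L, as.integer(floor(xw[, 1] / edge[1])))
    iy <- pmin(ncell[2] - 1L, as.integer(floor(xw[, 2] / edge[2])))
    iz <- pmin(ncell[3] - 1L, as.integer(floor(xw[, 3] / edge[3])))
    cell_of <- 1L + ix + ncell[1] * (iy + ncell[2] * iz)
  } else cell_of <- integer(0)
  members <- split(seq_len(n), factor(cell_of, levels = seq_len(prod(ncell))))
  structure(list(ncell = ncell, edge = edge, box = box,
                 cell_of = cell_of, members = members),
            class = "cg_cell_grid")
}

#' @export
print.cg_cell_grid <- function(x, ...) {
  cat(sprintf("<cg_cell_grid> %d x %d x %d cells, edges %.2f/%.2f/%.2f A, %d particles\n",
              x$ncell[1], x$ncell[2], x$ncell[3],
              x$edge[1], x$edge[2], x$edge[3], length(x$cell_of)))
  invisible(x)
}

# numeric pair key (i < j assumed); valid for systems below 2^26 particles
.pair_num_key <- function(i, j) pmin(i, j) * 2^26 + pmax(i, j)

# 1-2 / 1-3 (orders from params) exclusion pairs from bond connectivity,
# plus native-contact pairs, as numeric keys; computed once per topology
.exclusion_keys <- function(topology, orders = c(2L, 3L)) {
  b <- topology$bonds
  np <- nrow(topology$particles)
  keys <- numeric(0)
  if (!is.null(b) && nrow(b) > 0) {
    adj <- vector("list", np)
    for (t in seq_len(nrow(b))) {
      adj[[b$i[t]]] <- c(adj[[b$i[t]]], b$j[t])
      adj[[b$j[t]]] <- c(adj[[b$j[t]]], b$i[t])
    }
    if (2L %in% orders) keys <- c(keys, .pair_num_key(b$i, b$j))
    if (3L %in% orders) {
      for (v in seq_len(np)) {
        nb <- adj[[v]]
        if (length(nb) >= 2) {
          cmb <- utils::combn(sort(unique(nb)), 2)
          keys <- c(keys, .pair_num_key(cmb[1, ], cmb[2, ]))
        }
      }
    }
  }
  gop <- topology$native_contacts
  go_keys <- if (!is.null(gop) && nrow(gop) > 0)
    .pair_num_key(gop$i, gop$j) else numeric(0)
  list(bonded = unique(keys), go = go_keys)
}

#' Build the unified multi-cutoff neighbor lists
#'
#' One candidate sweep up to the HPS search threshold populates the three
#' distance-cascaded class lists: pairs closer than `r_p_exv` enter the
#' excluded-volume, DNA and HPS lists; pairs between `r_p_exv` and
#' `r_p_dna` the DNA and HPS lists; pairs beyond `r_p_dna` the HPS list
#' only. The electrostatic list is built separately over charged
#' particles up to `r_p_ele`. Bonded 1-2/1-3 pairs are excluded from all
#' lists; native-contact pairs are excluded from the class lists (the Go
#' term replaces them) but keep their electrostatic interaction. The
#' protein-DNA recognition candidate list indexes topology tuples within
#' their own threshold and is not i<j symmetrized.
#'
#' @param state a `cg_state`.
#' @param grid a [build_cell_grid()] result for the same coordinates.
#' @param params a [cg_parameters()] set (cutoffs + buffer).
#' @param topology the `cg_topology` (charges, kinds, exclusions).
#' @param exclusions optional precomputed result of the internal
#'   exclusion-key builder (cached by the simulation driver; derived
#'   from `topology` when NULL).
#' @return object of class `cg_neighbor_lists` with per-class pair data
#'   frames, the thresholds, and the reference coordinates of this build.
#' @export
build_neighbor_lists <- function(state, grid, params, topology,
                                 exclusions = NULL) {
  co <- params$cutoffs
  rp <- c(exv = co$exv, dna = co$dna, hps = co$hps, ele = co$ele) +
    params$buffer
  if (is.unsorted(rp)) stop("search thresholds must be ascending")
  x <- state$coords
  if (is.null(exclusions))
    exclusions <- .exclusion_keys(topology, params$exclusion$bonded_orders)
  drop_keys <- c(exclusions$bonded, exclusions$go)

  cand <- cpp_pairs_within(x, state$box, rp["hps"])
  keep <- rep(TRUE, length(cand$i))
  if (length(drop_keys))
    keep <- !(.pair_num_key(cand$i, cand$j) %in% drop_keys)
  ci <- cand$i[keep]; cj <- cand$j[keep]; cr <- cand$r[keep]
  mk <- function(sel) data.frame(i = ci[sel], j = cj[sel], r = cr[sel])
  lists <- list(
    exv = mk(cr < rp["exv"]),
    dna = mk(cr < rp["dna"]),
    hps = mk(cr < rp["hps"]))

  ch <- which(topology$particles$charge != 0)
  if (length(ch) >= 2) {
    ec <- cpp_pairs_within(x[ch, , drop = FALSE], state$box, rp["ele"])
    gi <- ch[ec$i]; gj <- ch[ec$j]
    ekeep <- rep(TRUE, length(gi))
    if (length(exclusions$bonded))
      ekeep <- !(.pair_num_key(gi, gj) %in% exclusions$bonded)
    lists$ele <- data.frame(i = gi[ekeep], j = gj[ekeep], r = ec$r[ekeep])
  } else {
    lists$ele <- data.frame(i = integer(0), j = integer(0), r = numeric(0))
  }

  pw <- topology$pwmcos_sites
  if (!is.null(pw) && nrow(pw) > 0) {
    r_pw <- params$pwmcos$r0 + 5 * params$pwmcos$w + params$buffer
    d <- min_image(x[pw$b, , drop = FALSE] - x[pw$c, , drop = FALSE],
                   state$box)
    lists$pwmcos <- which(row_norm(d) < r_pw)
  } else lists$pwmcos <- integer(0)

  structure(list(pairs = lists, thresholds = rp,
                 half_buffer = params$buffer / 2,
                 ref_coords = x, box = state$box),
            class = "cg_neighbor_lists")
}

#' @export
print.cg_neighbor_lists <- function(x, ...) {
  cat(sprintf("<cg_neighbor_lists> exv %d | dna %d | hps %d | ele %d | pwmcos %d\n",
              nrow(x$pairs$exv), nrow(x$pairs$dna), nrow(x$pairs$hps),
              nrow(x$pairs$ele), length(x$pairs$pwmcos)))
  cat(sprintf("  thresholds %s A, rebuild at %.2f A displacement\n",
              paste(signif(x$thresholds, 4), collapse = "/"),
              x$half_buffer))
  invisible(x)
}

#' Neighbor-list rebuild criterion
#'
#' TRUE when the maximum minimum-image displacement of any particle since
#' the last build has reached half the buffer skin; while FALSE, no pair
#' inside any force cutoff can be missing from its class list.
#'
#' @param state current `cg_state`.
#' @param lists the `cg_neighbor_lists` in use.
#' @return logical.
#' @export
needs_rebuild <- function(state, lists) {
  d <- min_image(state$coords - lists$ref_coords, state$box)
  max(row_norm(d)) >= lists$half_buffer
}
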
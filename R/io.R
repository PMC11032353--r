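## File formats: PDB-style bead coordinate files (one ATOM record per
## bead, chain-ID cycling + TER records so systems with thousands of
## chains round-trip), XYZ and DCD-style binary trajectories, YAML run
## configuration and topology serialization.

.chain_chars <- c(LETTERS, letters, as.character(0:9))

#' Write a bead structure in PDB format
#'
#' One ATOM record per bead; chains are separated by TER records with
#' the single-character chain ID cycling through A-Z, a-z, 0-9 (the TER
#' records, not the characters, delimit chains on read). A CRYST1
#' record stores the box.
#'
#' @param path output file.
#' @param coords N x 3 coordinates (A).
#' @param chain_id integer chain id per bead.
#' @param residue_index residue number per bead.
#' @param name bead name per bead (residue or site code).
#' @param box optional box lengths for the CRYST1 record.
#' @export
write_structure <- function(path, coords, chain_id,
                            residue_index = seq_len(nrow(coords)),
                            name = "CA", box = NULL) {
  stopifnot(nrow(coords) == length(chain_id))
  name <- rep_len(name, nrow(coords))
  residue_index <- rep_len(residue_index, nrow(coords))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(box))
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
      box[1], box[2], box[3]), con)
  chain_pos <- match(chain_id, unique(chain_id))
  cc <- .chain_chars[(chain_pos - 1L) %% length(.chain_chars) + 1L]
  serial <- seq_len(nrow(coords)) %% 100000L
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
    serial, substr(name, 1, 4), substr(name, 1, 3), cc,
    residue_index %% 10000L, coords[, 1], coords[, 2], coords[, 3])
  # insert TER after each chain
  out <- character(0)
  for (ch in unique(chain_pos)) {
    out <- c(out, lines[chain_pos == ch], "TER")
  }
  writeLines(c(out, "END"), con)
  invisible(path)
}

#' Read a bead structure in PDB format
#'
#' Parses ATOM records (fixed columns); occupancy and B-factor are
#' ignored. Chains are delimited by TER records. A missing or blank
#' chain column is rejected.
#'
#' @param path input file.
#' @return list with `coords`, `chain_id`, `residue_index`, `name`, and
#'   `box` (NULL when no CRYST1 record).
#' @export
read_structure <- function(path) {
  ln <- readLines(path)
  box <- NULL
  cry <- grep("^CRYST1", ln)
  if (length(cry))
    box <- as.numeric(c(substr(ln[cry[1]], 7, 15),
                        substr(ln[cry[1]], 16, 24),
                        substr(ln[cry[1]], 25, 33)))
  coords <- list(); chain <- integer(0); resi <- integer(0)
  name <- character(0)
  cur_chain <- 1L
  any_in_chain <- FALSE
  for (q in seq_along(ln)) {
    l <- ln[q]
    if (startsWith(l, "TER")) {
      if (any_in_chain) { cur_chain <- cur_chain + 1L; any_in_chain <- FALSE }
      next
    }
    if (!startsWith(l, "ATOM")) next
    if (nchar(l) < 54)
      stop("malformed ATOM record at line ", q, ": too short")
    xyz <- suppressWarnings(as.numeric(c(substr(l, 31, 38),
                                         substr(l, 39, 46),
                                         substr(l, 47, 54))))
    if (anyNA(xyz))
      stop("malformed ATOM record at line ", q, ": bad coordinates")
    if (substr(l, 22, 22) == " ")
      stop("malformed ATOM record at line ", q, ": missing chain ID")
    coords[[length(coords) + 1L]] <- xyz
    chain <- c(chain, cur_chain)
    resi <- c(resi, suppressWarnings(as.integer(substr(l, 23, 26))))
    name <- c(name, trimws(substr(l, 13, 16)))
    any_in_chain <- TRUE
  }
  list(coords = do.call(rbind, coords), chain_id = chain,
       residue_index = resi, name = name, box = box)
}

#' Append one frame to an XYZ trajectory
#'
#' @param con open writable connection (or path opened in append mode).
#' @param coords N x 3 coordinates.
#' @param comment comment line (step number, box, ...).
#' @export
write_xyz_frame <- function(con, coords, comment = "") {
  if (is.character(con)) {
    con <- file(con, "a")
    on.exit(close(con))
  }
  if (!isTRUE(tryCatch(isOpen(con), error = function(e) FALSE)))
    stop("connection is closed")
  writeLines(c(as.character(nrow(coords)), comment,
               sprintf("CG %12.5f %12.5f %12.5f",
                       coords[, 1], coords[, 2], coords[, 3])), con)
  invisible(con)
}

#' Read all frames of an XYZ trajectory
#' @param path file path.
#' @return list of coordinate matrices.
#' @export
read_xyz <- function(path) {
  ln <- readLines(path)
  frames <- list()
  q <- 1L
  while (q <= length(ln)) {
    n <- as.integer(ln[q])
    if (n == 0L) {
      frames[[length(frames) + 1L]] <- matrix(0, 0, 3)
    } else {
      block <- ln[(q + 2L):(q + 1L + n)]
      parts <- do.call(rbind, strsplit(trimws(block), "\\s+"))
      frames[[length(frames) + 1L]] <-
        matrix(as.numeric(parts[, 2:4]), ncol = 3)
    }
    q <- q + 2L + n
  }
  frames
}

#' Write a DCD-style binary trajectory
#'
#' CHARMM-flavor DCD: Fortran-record-delimited header, per-frame unit
#' cell record and X/Y/Z float records.
#'
#' @param path output file.
#' @param frames list of N x 3 coordinate matrices.
#' @param box box lengths.
#' @export
write_dcd <- function(path, frames, box) {
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(payload_fn, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4)
    payload_fn()
    writeBin(as.integer(nbytes), con, size = 4)
  }
  n <- nrow(frames[[1]])
  icntrl <- integer(20)
  icntrl[1] <- length(frames); icntrl[11] <- 1L; icntrl[20] <- 24L
  rec(function() {
    writeChar("CORD", con, 4, eos = NULL)
    writeBin(icntrl, con, size = 4)
  }, 84)
  title <- formatC("cgdroplet trajectory", width = 80, flag = "-")
  rec(function() {
    writeBin(1L, con, size = 4)
    writeChar(title, con, 80, eos = NULL)
  }, 84)
  rec(function() writeBin(as.integer(n), con, size = 4), 4)
  for (fr in frames) {
    cell <- c(box[1], 90, box[2], 90, 90, box[3])
    rec(function() writeBin(as.numeric(cell), con, size = 8), 48)
    for (ax in 1:3)
      rec(function() writeBin(as.numeric(fr[, ax]), con, size = 4), 4 * n)
  }
  invisible(path)
}

#' Read a DCD-style binary trajectory written by [write_dcd()]
#' @param path file path.
#' @return list with `frames` (list of N x 3 matrices) and `box`.
#' @export
read_dcd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  skip_marker <- function() readBin(con, "integer", 1, size = 4)
  skip_marker(); magic <- readChar(con, 4)
  if (!identical(magic, "CORD")) stop("not a DCD file")
  icntrl <- readBin(con, "integer", 20, size = 4); skip_marker()
  nframes <- icntrl[1]
  skip_marker(); ntit <- readBin(con, "integer", 1, size = 4)
  readChar(con, 80 * ntit); skip_marker()
  skip_marker(); n <- readBin(con, "integer", 1, size = 4); skip_marker()
  frames <- vector("list", nframes)
  box <- NULL
  for (f in seq_len(nframes)) {
    skip_marker(); cell <- readBin(con, "numeric", 6, size = 8)
    skip_marker()
    box <- cell[c(1, 3, 6)]
    m <- matrix(0, n, 3)
    for (ax in 1:3) {
      skip_marker()
      m[, ax] <- readBin(con, "numeric", n, size = 4)
      skip_marker()
    }
    frames[[f]] <- m
  }
  list(frames = frames, box = box)
}

#' Load a run configuration
#'
#' YAML file with sections `run` (dt_fs, steps, temperature_K,
#' friction_per_ps, seed), `cutoffs` (exv, dna, hps, ele), `buffer`,
#' `balance` (period) and `output` (stride). Missing values take the
#' standard defaults (dt 10 fs, friction 0.01/ps, cutoffs 12/18/20/35 A,
#' buffer 3 A). An empty file yields pure defaults.
#'
#' @param path YAML file (may not exist fields; empty = all defaults).
#' @return validated named list of class `cg_config`.
#' @export
load_config <- function(path = NULL) {
  raw <- if (!is.null(path) && file.exists(path) &&
               file.info(path)$size > 0) yaml::read_yaml(path) else list()
  if (is.null(raw)) raw <- list()
  def <- list(
    run = list(dt_fs = 10, steps = 1000L, temperature_K = 300,
               friction_per_ps = 0.01, seed = 1L),
    cutoffs = list(exv = 12, dna = 18, hps = 20, ele = 35),
    buffer = 3,
    balance = list(period = Inf),
    output = list(stride = 100L))
  cfg <- utils::modifyList(def, raw)
  if (cfg$run$dt_fs <= 0) stop("dt_fs must be > 0")
  co <- unlist(cfg$cutoffs[c("exv", "dna", "hps", "ele")])
  if (is.unsorted(co))
    stop("cutoffs must be given in ascending order exv <= dna <= hps <= ele")
  if (cfg$output$stride < 1) stop("output stride must be >= 1")
  structure(cfg, class = c("cg_config", "list"))
}

#' Save a run configuration
#' @param config a `cg_config` list.
#' @param path output YAML path.
#' @export
save_config <- function(config, path) {
  cfg <- unclass(config)
  # yaml has no native Inf for some parsers; store as the string ".inf"
  yaml::write_yaml(cfg, path, precision = 12L)
  invisible(path)
}

#' Serialize a topology to a YAML file
#' @param topology a `cg_topology`.
#' @param path output path.
#' @export
write_topology <- function(topology, path) {
  ser <- lapply(unclass(topology), function(el) {
    if (is.data.frame(el)) as.list(el) else el
  })
  yaml::write_yaml(ser, path, precision = 12L)
  invisible(path)
}

#' Read a topology from a YAML file written by [write_topology()]
#' @param path input path.
#' @return a `cg_topology`.
#' @export
read_topology <- function(path) {
  raw <- yaml::read_yaml(path)
  df <- function(el) if (is.null(el) || length(el) == 0) NULL else
    as.data.frame(el, stringsAsFactors = FALSE)
  cg_topology(particles = df(raw$particles),
              bonds = if (is.null(raw$bonds)) .empty_bonds() else
                df(raw$bonds),
              angles = if (is.null(raw$angles)) .empty_angles() else
                df(raw$angles),
              dihedrals = if (is.null(raw$dihedrals)) .empty_dihedrals()
              else df(raw$dihedrals),
              native_contacts = if (is.null(raw$native_contacts))
                .empty_contacts() else df(raw$native_contacts),
              dna_stack = df(raw$dna_stack), dna_pair = df(raw$dna_pair),
              dna_cross = df(raw$dna_cross),
              pwmcos_sites = df(raw$pwmcos_sites))
}
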
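#' Force-field parameter set
#'
#' Builds the complete parameter container used by the topology builders,
#' the force field, the neighbor-list machinery and the integrator. All
#' values can be overridden; the defaults are the published model constants
#' where the source models state them (HPS well depth 0.2 kcal/mol, HPS bond
#' force constant 2.39 kcal/mol/A^2 and reference length 3.8 A, excluded
#' volume strength 0.6 kcal/mol) and physically plausible package defaults
#' elsewhere (per-residue diameters, hydropathies, DNA Morse sets).
#'
#' @param temperature_K solution temperature (K).
#' @param salt_molarity salt molarity C (mol/L) entering the permittivity.
#' @param ionic_strength ionic strength I (mol/L); defaults to
#'   `salt_molarity` (1:1 salt).
#' @param cutoffs named numeric: per-class force cutoffs `exv`, `dna`,
#'   `hps`, `ele` (A), required ascending in that order.
#' @param buffer neighbor-list buffer skin (A).
#' @param residues data frame with columns `code`, `sigma`, `lambda`,
#'   `charge`, `mass` overriding the per-residue table.
#' @param overrides named list merged over the constructed set (shallow).
#'
#' @return An object of class `cg_parameters`.
#' @export
cg_parameters <- function(temperature_K = 300, salt_molarity = 0.15,
                          ionic_strength = NULL,
                          cutoffs = c(exv = 12, dna = 18, hps = 20, ele = 35),
                          buffer = 3,
                          residues = NULL,
                          overrides = list()) {
  cst <- physical_constants()
  if (is.null(residues)) {
    aa <- .aa_table
    residues <- data.frame(
      code   = aa$code,
      # diameter grows with residue size; spans the usual CG bead range
      sigma  = 4.5 + (aa$mass - min(aa$mass)) / diff(range(aa$mass)) * 2.1,
      lambda = (aa$kd + 4.5) / 9,  # normalized hydropathy in [0, 1]
      charge = aa$charge,
      mass   = aa$mass,
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("code", "sigma", "lambda", "charge", "mass") %in%
                  names(residues)))
  p <- list(
    constants = cst,
    environment = list(temperature_K = temperature_K,
                       salt_molarity = salt_molarity,
                       ionic_strength = if (is.null(ionic_strength))
                         salt_molarity else ionic_strength),
    cutoffs = as.list(cutoffs),
    buffer = buffer,
    hps = list(epsilon = 0.2, kb = 2.39, b0 = 3.8),
    aicg = list(eps_exv = 0.6, kb = 100, b0 = 3.8, go_epsilon = 0.3,
                contact_cutoff = 4.5,
                g13 = list(eps = 1.0, r0 = 5.5, w = 0.5),
                dihedral = list(eps = 1.0, phi0 = -1.0, sigma = 0.25)),
    residues = residues,
    # flexible statistical tables: per residue code, probability densities
    # on uniform grids (radians); NULL means the neutral default
    # P_theta ~ sin(theta), P_d uniform, which give flat energies
    flexible = list(angle = list(), dihedral = list()),
    dna = list(
      bond = list(k2 = 60, k4 = 600,
                  b0 = c(PS = 3.9, SP = 3.7, SB = 4.8)),
      angle = list(ka = 20,
                   theta0 = c(PSP = 2.094, SPS = 1.658,
                              PSB = 1.833, BSP = 2.531)),
      dihedral = list(gaussian = list(eps = 2, sigma0 = 0.3, phi0 = -2.53),
                      periodic = list(k = 2, n = 1, phi0 = -2.53)),
      stack = list(eps = 4.0, alpha = 2.0, r0 = 3.6,
                   theta0 = 1.55, gamma = pi / 6),
      pair  = list(eps = 10.0, alpha = 2.0, r0 = 5.9,
                   theta1_0 = 2.72, theta2_0 = 2.72, phi0 = -0.30,
                   gamma = pi / 6),
      cross = list(eps = 2.0, alpha = 4.0, r0 = 6.0,
                   theta3_0 = 1.90, thetaCS_0 = 2.10, gamma = pi / 8),
      exv = list(eps = 1.0,
                 sigma = c(P = 4.5, S = 6.2, A = 5.4, C = 5.4,
                           G = 5.4, T = 5.4)),
      site_mass = .dna_site_mass,
      phosphate_charge = -1
    ),
    pwmcos = list(eps_table = NULL,  # matrix [base A/C/G/T x PWM column]
                  w = 1.0, r0 = 6.0, gamma = pi / 9,
                  theta1_0 = 1.8, theta2_0 = 1.8, theta3_0 = 1.8),
    exclusion = list(bonded_orders = c(2L, 3L))  # exclude 1-2 and 1-3 pairs
  )
  for (nm in names(overrides)) p[[nm]] <- overrides[[nm]]
  class(p) <- "cg_parameters"
  validate_parameters(p)
  p
}

#' Validate a parameter set
#'
#' Checks the structural invariants: strictly positive, class-wise ascending
#' cutoffs (exv <= dna <= hps <= ele), positive buffer, positive sigma and
#' lambda tables, and normalized positive flexible tables.
#'
#' @param p a `cg_parameters` object.
#' @return `p`, invisibly; stops with a message on violation.
#' @export
validate_parameters <- function(p) {
  co <- p$cutoffs
  v <- c(co$exv, co$dna, co$hps, co$ele)
  if (any(v <= 0)) stop("cutoffs must be strictly positive")
  if (is.unsorted(v))
    stop("cutoffs must be ascending: exv <= dna <= hps <= ele (got ",
         paste(signif(v, 4), collapse = ", "), ")")
  if (p$buffer < 0) stop("buffer must be >= 0")
  if (any(p$residues$sigma <= 0)) stop("residue sigma values must be > 0")
  if (any(p$residues$lambda < 0)) stop("residue lambda values must be >= 0")
  for (kind in c("angle", "dihedral")) {
    for (nm in names(p$flexible[[kind]])) {
      tb <- p$flexible[[kind]][[nm]]
      if (any(tb$prob <= 0))
        stop("flexible ", kind, " table '", nm, "' must be strictly positive")
      h <- diff(tb$grid[1:2])
      if (abs(sum(tb$prob) * h - 1) > 1e-6)
        stop("flexible ", kind, " table '", nm,
             "' must integrate to 1 on its grid")
    }
  }
  invisible(p)
}

#' @export
print.cg_parameters <- function(x, ...) {
  cat("<cg_parameters>\n")
  cat(sprintf("  T = %g K, C = %g M, I = %g M\n",
              x$environment$temperature_K, x$environment$salt_molarity,
              x$environment$ionic_strength))
  cat(sprintf("  cutoffs (A): exv %g <= dna %g <= hps %g <= ele %g; buffer %g\n",
              x$cutoffs$exv, x$cutoffs$dna, x$cutoffs$hps, x$cutoffs$ele,
              x$buffer))
  cat(sprintf("  %d residue types; %d flexible angle / %d dihedral tables\n",
              nrow(x$residues), length(x$flexible$angle),
              length(x$flexible$dihedral)))
  invisible(x)
}

# residue-table lookup with a clear error for unknown codes
.residue_row <- function(params, code) {
  idx <- match(code, params$residues$code)
  if (anyNA(idx))
    stop("unknown residue code(s): ",
         paste(unique(code[is.na(idx)]), collapse = ", "))
  params$residues[idx, , drop = FALSE]
}
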
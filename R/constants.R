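## Internal unit system: kcal/mol (energy), Angstrom (length), K (temperature),
## fs (time), Da (mass), elementary charge (charge).

#' Physical constants used by the engine
#'
#' Returns the fixed physical constants in the package unit system
#' (kcal/mol, Angstrom, K, fs, Da, elementary charges).
#'
#' @return Named list: `kB` Boltzmann constant (kcal/mol/K), `coulomb`
#'   Coulomb factor (kcal Angstrom / mol / e^2), `ke_conv` value of
#'   1 Da Angstrom^2/fs^2 in kcal/mol, plus SI constants (`kB_SI`, `N_A`,
#'   `e_c`, `eps0`) used for the Debye length.
#' @export
physical_constants <- function() {
  list(
    kB      = 0.0019872041,   # kcal/mol/K
    coulomb = 332.0716,       # kcal*A/(mol*e^2): e^2/(4*pi*eps0) in these units
    ke_conv = 2390.0574,      # 1 Da*A^2/fs^2 in kcal/mol
    kB_SI   = 1.380649e-23,   # J/K
    N_A     = 6.02214076e23,  # 1/mol
    e_c     = 1.602176634e-19,# C
    eps0    = 8.8541878128e-12# F/m
  )
}

# canonical 20 amino acids with average residue masses (Da) and
# Kyte-Doolittle hydropathy (used only to build default lambda values)
.aa_table <- data.frame(
  code = c("A","R","N","D","C","E","Q","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V"),
  mass = c(71.0788, 156.1875, 114.1038, 115.0886, 103.1388,
           129.1155, 128.1307, 57.0519, 137.1411, 113.1594,
           113.1594, 128.1741, 131.1926, 147.1766, 97.1167,
           87.0782, 101.1051, 186.2132, 163.1760, 99.1326),
  kd   = c(1.8, -4.5, -3.5, -3.5, 2.5, -3.5, -3.5, -0.4, -3.2, 4.5,
           3.8, -3.9, 1.9, 2.8, -1.6, -0.8, -0.7, -0.9, -1.3, 4.2),
  charge = c(0, 1, 0, -1, 0, -1, 0, 0, 0, 0,
             0, 1, 0, 0, 0, 0, 0, 0, 0, 0),
  stringsAsFactors = FALSE
)

# DNA site masses (Da); phosphate carries -1 e
.dna_site_mass <- c(P = 94.97, S = 83.11, A = 134.12, C = 110.09,
                    G = 150.12, T = 125.11)

.dna_complement <- c(A = "T", T = "A", C = "G", G = "C")
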
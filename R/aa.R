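## Shared amino-acid constants and encoding helpers.

# Accepted residue alphabet: the 20 standard amino acids plus ambiguity code X.
# B/Z/U (and anything else) are rejected at input validation.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA21 <- c(AA20, "X")

# Average (not monoisotopic) residue masses in Da; Expasy/standard values.
# Chosen to match protein-scale molecular weights as printed in genome surveys.
AA_MASS <- c(
  A = 71.0788,  C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G = 57.0519,  H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P = 97.1167,  Q = 128.1307, R = 156.1875,
  S = 87.0782,  T = 101.1051, V = 99.1326,  W = 186.2132, Y = 163.1760)
WATER_MASS <- 18.0153

# Background composition (Swiss-Prot average frequencies), used for profile
# log-odds and for scanner calibration draws.
AA_BACKGROUND <- c(
  A = 0.0825, C = 0.0137, D = 0.0545, E = 0.0675, F = 0.0386,
  G = 0.0707, H = 0.0227, I = 0.0596, K = 0.0584, L = 0.0966,
  M = 0.0242, N = 0.0406, P = 0.0470, Q = 0.0393, R = 0.0553,
  S = 0.0656, T = 0.0534, V = 0.0687, W = 0.0108, Y = 0.0292)
AA_BACKGROUND <- AA_BACKGROUND / sum(AA_BACKGROUND)

# Residue classes used by the scanners.
HEPTAD_HYDRO <- c("L", "I", "V", "M", "F")   # a/d positions of coiled-coil heptads
NES_HYDRO    <- c("L", "I", "V", "F", "M")
BASIC_RES    <- c("K", "R")
AHA_AROMATIC <- c("W", "Y", "F")
AHA_HYDRO    <- c("L", "I", "V", "M")
AHA_ACIDIC   <- c("D", "E")

# Neutral polar alphabet the synthetic generator uses for heptad
# b/c/e/f/g positions, insertions and motif spacers: free of basic, acidic,
# aromatic and aliphatic-hydrophobic residues so that every scanner sees a
# featureless background there.
POLAR_NEUTRAL <- c("S", "T", "N", "Q", "G", "A", "P")

# Disorder-like alphabet for terminal flanks and the DBD-HR linker (which
# the motif scanners never see): polar plus charged/His, still without the
# hydrophobic and aromatic residues that drive the NES/AHA scanners.
DISORDER_SET <- c(POLAR_NEUTRAL, "D", "E", "H", "K", "R")

# pKa sets for net charge / isoelectric point (selectable; EMBOSS default).
PKA_SETS <- list(
  emboss = c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
             H = 6.5, K = 10.8, R = 12.5, Y = 10.1),
  sillero = c(Nterm = 8.2, Cterm = 3.2, C = 9.0, D = 4.0, E = 4.5,
              H = 6.4, K = 10.4, R = 12.0, Y = 10.46),
  dtaselect = c(Nterm = 8.0, Cterm = 3.1, C = 8.5, D = 4.4, E = 4.4,
                H = 6.5, K = 10.0, R = 12.0, Y = 10.0))

# Class geometry: HR-A/B insertion lengths and advisory linker ranges.
CLASS_INSERTION <- c(A = 21L, B = 0L, C = 7L)
LINKER_RANGE <- list(A = c(9L, 39L), B = c(50L, 78L), C = c(14L, 49L))

aa_check <- function(sequence, what = "sequence") {
  s <- toupper(sequence)
  if (!nzchar(s)) stop(what, " is empty")
  bad <- setdiff(strsplit(s, "")[[1]], AA21)
  if (length(bad) > 0)
    stop(what, " contains illegal residue characters: ",
         paste(unique(bad), collapse = ", "))
  s
}

# Encode a residue string as 1-based indices into AA21 (X = 21).
aa_encode <- function(sequence) {
  idx <- match(strsplit(toupper(sequence), "")[[1]], AA21)
  if (anyNA(idx)) stop("sequence contains characters outside the accepted alphabet")
  idx
}

aa_chars <- function(sequence) strsplit(toupper(sequence), "")[[1]]

# Deterministic per-stream RNG seed derived from a master seed and a label,
# so adding records never perturbs existing ones. Kept below 2^31.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
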
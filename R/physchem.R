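## Physicochemical properties: molecular weight, net charge, isoelectric
## point; and the digital-EST match criteria.

#' Protein molecular weight
#'
#' Sum of average residue masses plus one water mass (18.0153 Da). Average
#' (not monoisotopic) masses are used, matching protein-scale instrument and
#' survey conventions. The ambiguity code X has no mass and is rejected.
#'
#' @param sequence amino-acid string.
#' @return molecular weight in Daltons.
#' @export
molecular_weight <- function(sequence) {
  ch <- aa_chars(aa_check(sequence))
  if (any(!ch %in% names(AA_MASS)))
    stop("unknown residue for mass computation: ",
         paste(unique(setdiff(ch, names(AA_MASS))), collapse = ", "))
  sum(AA_MASS[ch]) + WATER_MASS
}

#' Protein net charge at a given pH
#'
#' Henderson-Hasselbalch sum over the N-terminus, C-terminus and the
#' ionizable side chains (D, E, C, Y, H, K, R) with a configurable pKa set.
#'
#' @param sequence amino-acid string.
#' @param pH pH in (0, 14).
#' @param pka_set one of `"emboss"` (default), `"sillero"`, `"dtaselect"`,
#'   or a named numeric vector with entries `Nterm`, `Cterm`, `C`, `D`, `E`,
#'   `H`, `K`, `R`, `Y`.
#' @return net charge in elementary charges.
#' @export
net_charge <- function(sequence, pH, pka_set = "emboss") {
  if (pH <= 0 || pH >= 14) stop("pH must be in (0, 14)")
  pka <- resolve_pka(pka_set)
  ch <- aa_chars(aa_check(sequence))
  if (any(!ch %in% AA20))
    stop("unknown residue for charge computation: ",
         paste(unique(setdiff(ch, AA20)), collapse = ", "))
  cnt <- table(factor(ch, levels = AA20))
  pos <- function(pk, n = 1) n / (1 + 10^(pH - pk))
  neg <- function(pk, n = 1) -n / (1 + 10^(pk - pH))
  pos(pka["Nterm"]) + neg(pka["Cterm"]) +
    pos(pka["K"], cnt["K"]) + pos(pka["R"], cnt["R"]) + pos(pka["H"], cnt["H"]) +
    neg(pka["D"], cnt["D"]) + neg(pka["E"], cnt["E"]) +
    neg(pka["C"], cnt["C"]) + neg(pka["Y"], cnt["Y"])
}

resolve_pka <- function(pka_set) {
  if (is.character(pka_set)) {
    if (!pka_set %in% names(PKA_SETS)) stop("unknown pKa set: ", pka_set)
    PKA_SETS[[pka_set]]
  } else pka_set
}

#' Isoelectric point by bisection
#'
#' Bisects [net_charge()] over pH 0-14 until the bracket width drops below
#' `tol`. Net charge is strictly decreasing in pH, so the zero crossing is
#' unique; converging on the bracket (rather than on the charge magnitude)
#' keeps the answer sharp even where the titration curve is nearly flat.
#'
#' @inheritParams net_charge
#' @param tol convergence tolerance on the pH bracket (default 0.005).
#' @return pI in pH units.
#' @export
isoelectric_point <- function(sequence, pka_set = "emboss", tol = 0.005) {
  if (tol <= 0) stop("tol must be > 0")
  lo <- 1e-6; hi <- 14 - 1e-6
  f <- function(x) net_charge(sequence, x, pka_set)
  while (hi - lo >= tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Per-protein physicochemical summary
#'
#' @param records a [protein_records()] table.
#' @param pka_set passed to [isoelectric_point()].
#' @return data.frame with `id`, `length`, `mw`, `pi`.
#' @export
physicochemical_properties <- function(records, pka_set = "emboss") {
  data.frame(id = records$id,
             length = nchar(records$sequence),
             mw = vapply(records$sequence, molecular_weight, numeric(1),
                         USE.NAMES = FALSE),
             pi = vapply(records$sequence, isoelectric_point, numeric(1),
                         pka_set = pka_set, USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

## ---- digital EST matching -----------------------------------------------

# Karlin-Altschul lambda for a match/mismatch scoring system with uniform
# base composition: solves sum p_i p_j exp(lambda * s_ij) = 1.
ka_lambda <- function(match, mismatch) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  stats::uniroot(f, c(1e-6, 10))$root
}

#' Match an EST against a coding sequence under digital-expression criteria
#'
#' Finds the optimal local alignment (Smith-Waterman, affine gaps) of the
#' EST against the CDS and applies the match criteria: identity above
#' `identity`, aligned length above `min_length` bp, and Karlin-Altschul
#' E-value `K * m * n * exp(-lambda * S)` below `evalue` for the configured
#' search space.
#'
#' @param cds,est nucleotide strings (A/C/G/T/N).
#' @param identity minimum identity over the aligned region (strict `>`).
#' @param min_length minimum alignment length in bp (strict `>`).
#' @param evalue maximum E-value (strict `<`).
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @param search_space `m * n` by default; set to the database size for
#'   realistic E-values.
#' @param K Karlin-Altschul K (approximate constant, default 0.1).
#' @return a list with the alignment statistics and E-value when all
#'   criteria hold, otherwise `NULL`.
#' @export
est_match <- function(cds, est, identity = 0.95, min_length = 200,
                      evalue = 1e-10, match = 1, mismatch = -2,
                      gap_open = 5, gap_extend = 2,
                      search_space = NULL, K = 0.1) {
  cds <- check_dna(cds, "cds"); est <- check_dna(est, "est")
  ca <- strsplit(cds, "")[[1]]; cb <- strsplit(est, "")[[1]]
  C <- matrix(mismatch, length(ca), length(cb))
  C[outer(ca, cb, "==") & outer(ca != "N", cb != "N", "&")] <- match
  res <- pairdp_cpp(C, gap_open, gap_extend, TRUE)
  if (length(res$ai) == 0) return(NULL)
  both <- res$ai > 0 & res$bi > 0
  idc <- sum(both & ca[pmax(res$ai, 1)] == cb[pmax(res$bi, 1)])
  alen <- length(res$ai)
  idfrac <- idc / sum(both)
  lambda <- ka_lambda(match, mismatch)
  if (is.null(search_space)) search_space <- as.numeric(length(ca)) * length(cb)
  ev <- K * search_space * exp(-lambda * res$score)
  if (idfrac > identity && alen > min_length && ev < evalue)
    list(score = res$score, identity = idfrac, length = alen, evalue = ev)
  else NULL
}

check_dna <- function(x, what) {
  x <- toupper(x)
  if (!nzchar(x)) stop(what, " is empty")
  if (grepl("[^ACGTN]", x)) stop(what, " is not a nucleotide sequence")
  x
}
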
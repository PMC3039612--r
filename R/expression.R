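## qPCR delta-delta-Ct relative expression.

#' Relative expression by the delta-delta-Ct method
#'
#' For each gene: `dCt = mean Ct(gene) - mean Ct(reference)` per condition;
#' `ddCt = dCt(treated) - dCt(calibrator)`; fold change `2^(-ddCt)`. `NA`
#' Ct values are the no-amplification sentinel: genes with no amplification
#' in either condition are reported as `not_expressed`.
#'
#' @param ct_table data.frame with columns `gene`, `condition`, `replicate`,
#'   `ct` (see [simulate_ct_table()] for the dialect); exactly two
#'   conditions.
#' @param reference_gene internal-control gene (e.g. `Actin1`); must
#'   amplify in both conditions.
#' @param calibrator_condition the baseline condition (default `control`).
#' @return data.frame with `gene`, `fold_change`, `category`
#'   (`up` / `down` / `unchanged` / `not_expressed`).
#' @export
relative_expression <- function(ct_table, reference_gene,
                                calibrator_condition = "control") {
  need <- c("gene", "condition", "replicate", "ct")
  if (!all(need %in% names(ct_table)))
    stop("ct_table must have columns: ", paste(need, collapse = ", "))
  conds <- unique(ct_table$condition)
  if (!calibrator_condition %in% conds)
    stop("calibrator condition not in table: ", calibrator_condition)
  if (length(conds) != 2)
    stop("expected exactly two conditions, got: ", paste(conds, collapse = ", "))
  treated <- setdiff(conds, calibrator_condition)
  if (!reference_gene %in% ct_table$gene)
    stop("reference gene missing from table: ", reference_gene)

  mean_ct <- function(g, cond) {
    v <- ct_table$ct[ct_table$gene == g & ct_table$condition == cond]
    if (length(v) == 0 || all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  ref_cal <- mean_ct(reference_gene, calibrator_condition)
  ref_trt <- mean_ct(reference_gene, treated)
  if (is.na(ref_cal) || is.na(ref_trt))
    stop("reference gene did not amplify in both conditions")

  genes <- setdiff(unique(ct_table$gene), reference_gene)
  rows <- lapply(genes, function(g) {
    cal <- mean_ct(g, calibrator_condition)
    trt <- mean_ct(g, treated)
    if (is.na(cal) && is.na(trt))
      return(data.frame(gene = g, fold_change = NA_real_,
                        category = "not_expressed", stringsAsFactors = FALSE))
    if (is.na(cal) || is.na(trt)) {
      warning("gene '", g, "' amplified in only one condition; no fold change")
      return(data.frame(gene = g, fold_change = NA_real_,
                        category = NA_character_, stringsAsFactors = FALSE))
    }
    ddct <- (trt - ref_trt) - (cal - ref_cal)
    fold <- 2^(-ddct)
    data.frame(gene = g, fold_change = fold,
               category = categorize_response(fold), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Categorize a fold change
#'
#' Strict thresholds: fold > 2 is `up`, fold < 0.5 is `down`, anything else
#' (including exactly 2 or 0.5) is `unchanged`.
#'
#' @param fold_change positive fold change(s).
#' @return character vector of categories.
#' @export
categorize_response <- function(fold_change) {
  if (any(is.na(fold_change)) || any(fold_change <= 0))
    stop("fold change must be > 0")
  ifelse(fold_change > 2, "up", ifelse(fold_change < 0.5, "down", "unchanged"))
}

#' Read a Ct table TSV
#'
#' Dialect: tab-separated columns `gene`, `condition`, `replicate`, `ct`;
#' the string `NA` marks no amplification.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop("Ct table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  need <- c("gene", "condition", "replicate", "ct")
  if (!all(need %in% names(tab)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  if (any(!is.na(tab$ct) & tab$ct <= 0)) stop("Ct values must be > 0")
  tab
}
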
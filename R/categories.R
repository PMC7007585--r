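# The seven diagnosis categories, their malignant subset, and the nevus
# ground-truth strata. These are study-design constants, not tunables.

DX_CATEGORIES <- c("AKIEC", "BCC", "BKL", "DF", "MEL", "NV", "VASC")
DX_MALIGNANT <- c("AKIEC", "BCC", "MEL")
NV_STRATA <- c("histopathology", "followup", "consensus")

#' Diagnosis categories
#'
#' The seven pigmented-skin-lesion diagnosis categories used throughout the
#' package: actinic keratosis/intraepithelial carcinoma (AKIEC), basal cell
#' carcinoma (BCC), benign keratinocytic lesions (BKL), dermatofibroma (DF),
#' melanoma (MEL), nevus (NV) and vascular lesions (VASC).
#'
#' @return Character vector of the 7 uppercase category codes.
#' @export
#' @examples
#' diagnosis_categories()
diagnosis_categories <- function() DX_CATEGORIES

#' Malignant diagnosis categories
#'
#' The subset of categories regarded as malignant when collapsing the
#' seven-class problem to binary malignancy detection: AKIEC, BCC and MEL.
#' All others (BKL, DF, NV, VASC) are benign.
#'
#' @return Character vector of the 3 malignant category codes.
#' @export
malignant_categories <- function() DX_MALIGNANT

#' Nevus ground-truth strata
#'
#' NV cases are stratified by how their ground truth was established:
#' histopathology, follow-up with digital dermatoscopy, or expert consensus.
#' Batches draw NV cases evenly from the three strata.
#'
#' @return Character vector of the 3 stratum codes.
#' @export
nv_strata <- function() NV_STRATA

#' Is a category malignant?
#'
#' @param x Character vector of category codes (may contain `NA` for
#'   invalid/timed-out answers).
#' @return Logical vector; `NA` where `x` is `NA`.
#' @export
#' @examples
#' is_malignant(c("BCC", "NV", NA))
is_malignant <- function(x) {
  bad <- !is.na(x) & !(x %in% DX_CATEGORIES)
  if (any(bad)) {
    abort(paste0("Unknown diagnosis categories: ",
                 paste(unique(x[bad]), collapse = ", ")))
  }
  ifelse(is.na(x), NA, x %in% DX_MALIGNANT)
}

assert_categories <- function(x, allow_na = FALSE) {
  bad <- !(x %in% DX_CATEGORIES)
  if (allow_na) bad <- bad & !is.na(x)
  if (any(bad)) {
    abort(paste0("Unknown diagnosis categories: ",
                 paste(unique(x[bad]), collapse = ", ")))
  }
  invisible(x)
}
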
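#' Packaged thiosemicarbazide study data
#'
#' Hand-keyed descriptor tables for 18 anticancer
#' 1-aryl-4-(phenoxy)acetylthiosemicarbazide derivatives measured on five
#' chromatographic systems: fitted retention parameters (log kw, -S, r2, n)
#' on C-18, IAM, and cholesterol phases; retention, binding constants, and
#' percent plasma-protein binding on immobilized HSA and AGP columns
#' (plus a QSAR-predicted binding constant, logK_IRFMN); and seven
#' calculated logP/logD descriptors from different algorithms.
#'
#' @return \code{thiosemicarbazide_retention()}: the retention-fit table
#'   (one row per compound, three systems side by side).
#'   \code{thiosemicarbazide_binding()}: the protein-column table.
#'   \code{thiosemicarbazide_logp()}: the calculated-logP table.
#'   \code{thiosemicarbazide_descriptors()}: the three merged into one wide
#'   descriptor table keyed by \code{compound_id}.
#' @name thiosemicarbazide_data
NULL

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "biomchrom")
  if (p == "") stop(sprintf("packaged data file '%s' not found", file), call. = FALSE)
  p
}

#' @rdname thiosemicarbazide_data
#' @export
thiosemicarbazide_retention <- function() {
  utils::read.csv(extdata_path("retention_fits.csv"))
}

#' @rdname thiosemicarbazide_data
#' @export
thiosemicarbazide_binding <- function() {
  utils::read.csv(extdata_path("protein_binding.csv"))
}

#' @rdname thiosemicarbazide_data
#' @export
thiosemicarbazide_logp <- function() {
  utils::read.csv(extdata_path("insilico_logp.csv"))
}

#' @rdname thiosemicarbazide_data
#' @export
thiosemicarbazide_descriptors <- function() {
  merge(merge(thiosemicarbazide_retention(), thiosemicarbazide_binding(),
              by = "compound_id"),
        thiosemicarbazide_logp(), by = "compound_id")
}

#' Illustrative protein-column calibration drugs (synthetic)
#'
#' A synthetic stand-in for the reference-drug calibration sets of
#' immobilized HSA and AGP columns (bromazepam, carbamazepine, diclofenac,
#' nicardipine, nizatidine, piroxicam for HSA; bromazepam, chlorpromazine,
#' imipramine, nicardipine, nizatidine, propranolol, warfarin for AGP).
#' The \code{ppb_lit} column holds round literature-style percent-binding
#' values and \code{logk} was constructed to place each drug on the
#' published calibration lines, so fitting this set recovers those lines;
#' it illustrates the calibration workflow and is not measured data.
#'
#' @return data.frame with columns \code{name}, \code{column_id},
#'   \code{logk}, \code{ppb_lit}.
#' @export
reference_drugs_synthetic <- function() {
  utils::read.csv(extdata_path("reference_drugs_synthetic.csv"))
}
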
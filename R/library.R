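#' Load the packaged 50-compound terpene library
#'
#' Returns the curated library of the 50 tested essential-oil constituents:
#' identity, curated SMILES, chemical class, and the experimental LC50
#' fixtures (µg/mL, 95% CI) for III/IV-instar larvae and pupae. Values are
#' transcribed as printed; internally inconsistent confidence intervals
#' (e.g. a lower bound above the point estimate) are flagged with a warning,
#' never silently corrected. Censored pupae entries ("> 2000") carry NA with
#' `lc50_pupae_censored = TRUE`.
#'
#' @param validate warn about printed CI anomalies (default TRUE)
#' @return data.frame of 50 rows, one per compound
#' @examples
#' lib <- compound_library(validate = FALSE)
#' subset(lib, name == "Carvacrol")$lc50_iii
#' @export
compound_library <- function(validate = TRUE) {
  path <- system.file("extdata", "compounds.csv", package = "terpQSAR")
  if (path == "") path <- file.path("inst", "extdata", "compounds.csv")
  lib <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                         stringsAsFactors = FALSE)
  stopifnot(identical(lib$id, 1:50), !anyDuplicated(lib$name))
  if (validate) {
    for (ep in c("lc50_iii", "lc50_iv", "lc50_pupae")) {
      lo <- lib[[paste0(ep, "_lo")]]; hi <- lib[[paste0(ep, "_hi")]]
      pt <- lib[[ep]]
      bad <- which(!is.na(pt) & !(lo <= pt & pt <= hi))
      if (length(bad) > 0)
        warning("printed ", ep, " confidence interval inconsistent for compound(s) ",
                paste(lib$id[bad], collapse = ", "),
                " (transcribed as printed)", call. = FALSE)
    }
  }
  lib
}

#' Load a transcribed descriptor table fixture
#'
#' The packaged verbatim transcriptions of the printed descriptor tables:
#' `"constitutional"` (structural counts), `"physchem"` (molecular and
#' physicochemical descriptors), `"reactivity"` (frontier-orbital energies and
#' conceptual-DFT descriptors), `"topological"` (graph-theoretical indices),
#' and the published model summaries `"models"` / `"model_terms"`.
#' Rows whose printed values are inconsistent with the curated structure
#' (mis-drawn source structures, print artifacts) carry `suspect = TRUE` and
#' are never used as computed-descriptor verification anchors.
#'
#' @param which one of "constitutional", "physchem", "reactivity",
#'   "topological", "models", "model_terms"
#' @return data.frame keyed by compound `id` (or model for the model tables)
#' @export
load_paper_table <- function(which = c("constitutional", "physchem",
                                       "reactivity", "topological",
                                       "models", "model_terms")) {
  which <- match.arg(which)
  fname <- switch(which,
    constitutional = "table3_constitutional.csv",
    physchem = "table5_physchem.csv",
    reactivity = "table6_reactivity.csv",
    topological = "table7_topological.csv",
    models = "published_models.csv",
    model_terms = "published_model_terms.csv")
  path <- system.file("extdata", fname, package = "terpQSAR")
  if (path == "") path <- file.path("inst", "extdata", fname)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Graphs for the whole compound library
#' @param lib optionally, a library data.frame from [compound_library()]
#' @return named list of [molgraph] objects (names = compound names)
#' @export
library_graphs <- function(lib = compound_library(validate = FALSE)) {
  gs <- lapply(lib$smiles, parse_smiles)
  names(gs) <- lib$name
  gs
}
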
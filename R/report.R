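#' Verify computed descriptors against the printed tables
#'
#' Recomputes constitutional, topological and physicochemical descriptors
#' from the curated structures and tabulates them against the transcribed
#' printed values, row by row. Rows flagged `suspect` in the fixtures (the
#' source's mis-drawn structures and print artifacts) are reported but
#' excluded from the agreement summary. TIE is reported with its documented
#' calibration deviation (see the methods vignette).
#'
#' @param ids compound ids to verify (default the curated anchor set
#'   15, 30, 34, 50)
#' @param lib compound library
#' @return list of data.frames: `constitutional`, `topological`, `physchem`,
#'   each long-format with computed/printed/delta columns
#' @export
verify_descriptors <- function(ids = c(15L, 30L, 34L, 50L),
                               lib = compound_library(validate = FALSE)) {
  t3 <- load_paper_table("constitutional")
  t5 <- load_paper_table("physchem")
  t7 <- load_paper_table("topological")
  rows3 <- list(); rows7 <- list(); rows5 <- list()
  for (id in ids) {
    g <- parse_smiles(lib$smiles[lib$id == id])
    nm <- lib$name[lib$id == id]
    cc <- constitutional_counts(g)
    pr3 <- t3[t3$id == id, ]
    for (s in names(cc)) {
      rows3[[length(rows3) + 1]] <- data.frame(
        id = id, name = nm, descriptor = s, computed = unname(cc[[s]]),
        printed = pr3[[s]], suspect = isTRUE_vec(pr3$suspect))
    }
    tp <- topological_profile(g)
    pr7 <- t7[t7$id == id, ]
    for (s in names(tp)) {
      rows7[[length(rows7) + 1]] <- data.frame(
        id = id, name = nm, descriptor = s, computed = unname(tp[[s]]),
        printed = pr7[[s]], suspect = isTRUE_vec(pr7$suspect))
    }
    pc <- physchem_profile(g)
    pr5 <- t5[t5$id == id, ]
    for (s in c("Ui", "Hy", "AMR", "TPSA", "MlogP", "AlogP")) {
      rows5[[length(rows5) + 1]] <- data.frame(
        id = id, name = nm, descriptor = s, computed = unname(pc[[s]]),
        printed = pr5[[s]], suspect = isTRUE_vec(pr5$suspect))
    }
  }
  fin <- function(rows) {
    d <- do.call(rbind, rows)
    d$delta <- d$computed - d$printed
    d
  }
  list(constitutional = fin(rows3), topological = fin(rows7),
       physchem = fin(rows5))
}

#' Regenerate the package's full reproduction report
#'
#' Runs the end-to-end reproduction workflow from the packaged fixtures:
#' (a) Koopmans consistency report for the printed reactivity table,
#' (b) refits of the published QSAR/QPAR models 1-4 beside printed
#' statistics, (c) descriptor verification for the anchor compounds,
#' (d) probit and GA simulation summaries under the given seed. Writes CSV
#' and JSON artifacts stamped with the configuration when `out_dir` is given.
#'
#' @param endpoint activity endpoint for the model refits
#' @param seed integer seed for the simulation blocks
#' @param out_dir optional output directory (created if missing)
#' @param models which published models to refit
#' @param probit_reps bioassay replicates in the simulation summary
#' @return the report bundle, invisibly a named list
#' @export
run_reproduce <- function(endpoint = "iv", seed = 1, out_dir = NULL,
                          models = 1:4, probit_reps = 100) {
  lib <- compound_library(validate = FALSE)
  bundle <- list(config = list(endpoint = endpoint, seed = seed,
                               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                               package_version = as.character(utils::packageVersion("terpQSAR"))))
  # (a) reactivity table consistency
  bundle$reactivity <- validate_reactivity_table()
  # (b) published-model refits
  refits <- list()
  for (fam in c("QSAR", "QPAR")) for (mo in models) {
    ev <- evaluate_published_model(fam, mo, lib)
    refits[[paste(fam, mo)]] <- data.frame(
      family = fam, model = mo, n = ev$n,
      r2_refit = ev$refit$r2, r2_printed = ev$printed$r2,
      q2_refit = ev$refit$q2, q2_printed = ev$printed$q2,
      s_refit = ev$refit$s, f_refit = ev$refit$f, f_printed = ev$printed$f,
      sign_matches = sum(ev$signs$sign_match), terms = nrow(ev$signs))
  }
  bundle$model_refits <- do.call(rbind, refits)
  # (c) descriptor verification
  bundle$descriptors <- verify_descriptors(lib = lib)
  # (d) simulation summaries
  sims <- gen_bioassay(lc50 = 50, slope = 2.5, replicates = probit_reps,
                       seed = seed)
  lc <- vapply(sims, function(ds) {
    tryCatch(fit_probit(ds)$lc50, error = function(e) NA_real_)
  }, numeric(1))
  bundle$probit_sim <- list(true_lc50 = 50, replicates = probit_reps,
                            mean_lc50 = mean(lc, na.rm = TRUE),
                            failed = sum(is.na(lc)))
  sim <- gen_qsar(seed = seed)
  ga <- ga_search(sim$X, sim$y, max_size = 3, pop_size = 40, generations = 40,
                  seed = seed, n_best = 1)
  bundle$ga_sim <- list(planted = paste(sort(sim$truth$planted), collapse = ","),
                        recovered = paste(sort(match(ga[[1]]$descriptors,
                                                     colnames(sim$X))), collapse = ","),
                        fitness = attr(ga, "fitness")[1],
                        realized_r2 = sim$truth$realized_r2)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(bundle$reactivity,
                     file.path(out_dir, "reactivity_consistency.csv"),
                     row.names = FALSE)
    utils::write.csv(bundle$model_refits,
                     file.path(out_dir, "model_refits.csv"), row.names = FALSE)
    for (nm in names(bundle$descriptors))
      utils::write.csv(bundle$descriptors[[nm]],
                       file.path(out_dir, paste0("descriptors_", nm, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(
      list(config = bundle$config, probit_sim = bundle$probit_sim,
           ga_sim = bundle$ga_sim),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(bundle)
}

#' Schema-validated CSV reader
#'
#' @param path CSV path
#' @param schema named character vector column -> class ("integer", "numeric",
#'   "character", "logical")
#' @return typed data.frame
#' @export
read_table_checked <- function(path, schema) {
  if (!file.exists(path)) stop("missing file: ", path)
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(d) == 0) stop("empty table: ", path)
  missing <- setdiff(names(schema), names(d))
  extra <- setdiff(names(d), names(schema))
  if (length(missing) > 0 || length(extra) > 0)
    stop("header mismatch in ", path,
         if (length(missing)) paste0("; expected but absent: ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ",
                                   paste(extra, collapse = ", ")))
  for (cn in names(schema))
    d[[cn]] <- switch(schema[[cn]],
                      integer = as.integer(d[[cn]]),
                      numeric = as.numeric(d[[cn]]),
                      logical = as.logical(d[[cn]]),
                      character = as.character(d[[cn]]))
  d
}
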
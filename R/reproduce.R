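#' One-shot reproduction run on the packaged tables
#'
#' Re-runs the whole desk-scale analysis on the shipped study tables:
#' \itemize{
#'   \item OLS and 8-component PCR QSPR models on the 20-compound
#'     calibration set, each with leave-one-out cross-validation;
#'   \item prediction of the 10 external compounds and validation against
#'     the published experimental rates (both model variants are reported
#'     side by side -- the published account is ambiguous about which one
#'     produced its table, so neither is singled out);
#'   \item PCA explained variances for the calibration block and for all
#'     30 compounds;
#'   \item the Pearson sign structure among the flagged descriptor pairs;
#'   \item the t0.1, unit-conversion and error-percentage audits of the
#'     printed tables.
#' }
#' Everything is deterministic; no random numbers are drawn.
#'
#' @param out_dir Optional directory; when given, the bundle is written
#'   as JSON plus the validation tables as CSV.
#' @return A nested list with components `models`, `validation`, `pca`,
#'   `pearson`, `audits`.
#' @export
reproduce <- function(out_dir = NULL) {
  cal <- qspr_dataset("calibration")
  prd <- qspr_dataset("prediction")

  fit_ols <- qspr(cal$x, cal$y, method = "ols")
  fit_pcr <- qspr(cal$x, cal$y, method = "pcr", n_components = 8)
  loo_ols <- loo_cv(cal$x, cal$y)
  loo_pcr <- loo_cv(cal$x, cal$y,
                    fitter = function(x, y) qspr(x, y, "pcr", 8))

  val <- list(
    ols = validate(prd$y, predict(fit_ols, prd$x), prd$compounds,
                   rmsec = sqrt(mean(fit_ols$residuals^2)),
                   rmsecv = loo_ols$rmsecv),
    pcr8 = validate(prd$y, predict(fit_pcr, prd$x), prd$compounds,
                    rmsec = sqrt(mean(fit_pcr$residuals^2)),
                    rmsecv = loo_pcr$rmsecv),
    loo_calibration = list(
      ols = validate(cal$y, loo_ols$predictions, cal$compounds),
      pcr8 = validate(cal$y, loo_pcr$predictions, cal$compounds)))

  t3 <- load_fixture("table3")
  all30 <- as.matrix(t3[, descriptor_names()])
  rownames(all30) <- t3$compound
  pca20 <- pca_descriptors(cal$x)
  pca30 <- pca_descriptors(all30)

  r <- pearson_matrix(cal$x)
  rdf <- grep("^RDF", colnames(r), value = TRUE)
  pearson <- list(
    negative_pairs = c(`E3m vs GATS5m` = r["E3m", "GATS5m"],
                       `nAtomLC vs MATS4s` = r["nAtomLC", "MATS4s"]),
    positive_pairs = c(`nT10HeteroRing vs nFRing` =
                         r["nT10HeteroRing", "nFRing"],
                       `nAtomLC vs MATS5c` = r["nAtomLC", "MATS5c"]),
    rdf_min_pairwise = min(r[rdf, rdf]))

  audits <- list(t01 = audit_t01(),
                 units = audit_unit_consistency(),
                 table4_errors = audit_table4_errors())

  bundle <- list(
    models = list(ols = fit_ols, pcr8 = fit_pcr),
    validation = val,
    pca = list(calibration_ev_percent = pca20$ev_percent,
               all30_ev_percent = pca30$ev_percent),
    pearson = pearson,
    audits = audits)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(val$ols$table,
                     file.path(out_dir, "prediction_ols.csv"),
                     row.names = FALSE)
    utils::write.csv(val$pcr8$table,
                     file.path(out_dir, "prediction_pcr8.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(pca = bundle$pca, pearson = pearson,
           rmse = list(ols = c(rmsec = val$ols$rmsec,
                               rmsecv = val$ols$rmsecv,
                               rmsep = val$ols$rmsep),
                       pcr8 = c(rmsec = val$pcr8$rmsec,
                                rmsecv = val$pcr8$rmsecv,
                                rmsep = val$pcr8$rmsep)),
           audits = list(
             t01_all_non_dhp_within_0.5pc =
               all(abs(audits$t01$rel_error[!audits$t01$dhp_series]) < 0.005),
             units_all_pass = all(audits$units$pass),
             table4_errors_all_pass = all(audits$table4_errors$pass))),
      file.path(out_dir, "reproduce.json"), auto_unbox = TRUE, digits = NA)
  }
  bundle
}
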
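# Packaged tables from the photostability study of 30 dihydropyridines:
# kinetics (rates, t0.1, lack of fit), the 17 selected molecular
# descriptors, the leave-one-out validation table, and the published
# regression equation. Values are stored exactly as printed, including
# the known internal inconsistencies that the audit functions flag.

.fixture_files <- c(
  table2 = "table2_kinetics.csv",
  table3 = "table3_descriptors.csv",
  table4 = "table4_validation.csv",
  printed_equation = "printed_equation.csv")

.fixture_md5 <- c(
  table2 = "8e10b3a226c39e5c305bac0837e73880",
  table3 = "cc0a9b0dc21c6fdf6e25aa028bc91af2",
  table4 = "2d1ff2987cf3f8e3f1b785841a582c3c",
  printed_equation = "ddbdbedd875b55c0e8c30aa9683d82f7")

#' The seventeen selected molecular descriptors
#'
#' @return Character vector of the descriptor names used throughout the
#'   QSPR layer, in table order.
#' @export
descriptor_names <- function() {
  c("ALogP", "AATSC5m", "MATS5c", "MATS4s", "GATS5m", "SCH-6", "VCH-5",
    "minHBd", "minHBint7", "nAtomLC", "nFRing", "nT10HeteroRing",
    "RDF40m", "RDF45m", "RDF85m", "RDF115e", "E3m")
}

#' Load a packaged data table
#'
#' Reads one of the shipped study tables, verifying its checksum so a
#' corrupted install fails loudly rather than silently shifting numbers.
#'
#' \describe{
#'   \item{`table2`}{Kinetics per compound: `k1` and optional `k2` (both
#'     x 1e-4 s^-1) with replicate SDs, fit `r2_percent`, `t01_min`,
#'     and the curve-resolution `lof_percent`.}
#'   \item{`table3`}{30 compounds x 17 descriptors plus a `role` column
#'     (20 calibration, 10 prediction).}
#'   \item{`table4`}{Leave-one-out validation: experimental and
#'     predicted rates (x 1e-3 s^-1) with the printed relative errors.}
#'   \item{`printed_equation`}{The published regression equation: a
#'     named coefficient vector over the 17 descriptors plus the
#'     intercept in both variants (as printed, `1.216e3`, and the
#'     magnitude-corrected `1.216e-3`; see [apply_printed_equation()]).}
#' }
#'
#' @param name One of `"table2"`, `"table3"`, `"table4"`,
#'   `"printed_equation"`.
#' @return A data frame, or a list for `"printed_equation"`.
#' @export
load_fixture <- function(name = c("table2", "table3", "table4",
                                  "printed_equation")) {
  name <- match.arg(name)
  path <- system.file("extdata", .fixture_files[[name]],
                      package = "photostab", mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, unname(.fixture_md5[[name]])))
    stop("checksum mismatch for ", .fixture_files[[name]],
         ": corrupted install")
  df <- utils::read.csv(path, check.names = FALSE)
  if (name == "printed_equation") {
    coefs <- stats::setNames(df$coefficient, df$term)
    return(list(
      coefficients = coefs[descriptor_names()],
      intercept_as_printed = unname(coefs[["intercept_as_printed"]]),
      intercept_corrected = unname(coefs[["intercept_as_printed"]]) * 1e-6))
  }
  df
}

#' Evaluate the published regression equation on a descriptor row
#'
#' Dot product of the printed per-descriptor coefficients with a
#' descriptor vector plus the chosen intercept. The printed intercept,
#' 1.216e3, is six orders of magnitude above every rate in the study and
#' cannot be literally correct; a magnitude-corrected variant (1.216e-3)
#' is offered alongside it. Neither variant is claimed to reproduce the
#' published predictions -- whether the printed coefficients apply to raw
#' or autoscaled descriptors is not stated -- so the output is labelled
#' with the variant and left for inspection.
#'
#' @param x Named numeric vector (or one-row data frame) carrying all 17
#'   descriptors.
#' @param intercept_variant `"corrected_1.216e-3"` or
#'   `"as_printed_1.216e3"`.
#' @return Named length-1 numeric: the k estimate under that variant.
#' @export
apply_printed_equation <- function(x, intercept_variant =
                                     c("corrected_1.216e-3",
                                       "as_printed_1.216e3")) {
  intercept_variant <- match.arg(intercept_variant)
  eq <- load_fixture("printed_equation")
  if (is.data.frame(x)) x <- unlist(x[1, , drop = TRUE])
  miss <- setdiff(descriptor_names(), names(x))
  if (length(miss))
    stop("missing descriptor(s): ", paste(miss, collapse = ", "))
  icpt <- if (intercept_variant == "as_printed_1.216e3")
    eq$intercept_as_printed else eq$intercept_corrected
  val <- icpt + sum(eq$coefficients * as.numeric(x[descriptor_names()]))
  stats::setNames(val, intercept_variant)
}

#' Calibration or prediction descriptor/response dataset
#'
#' Joins the descriptor table with the experimental rates (x 1e-3 s^-1,
#' the canonical response unit of the QSPR layer) for one role.
#'
#' @param role `"calibration"` (20 compounds) or `"prediction"` (10).
#' @return List with `x` (matrix, named columns), `y` (rates), and
#'   `compounds`.
#' @export
qspr_dataset <- function(role = c("calibration", "prediction")) {
  role <- match.arg(role)
  t3 <- load_fixture("table3")
  t4 <- load_fixture("table4")
  t3 <- t3[t3$role == role, ]
  x <- as.matrix(t3[, descriptor_names()])
  rownames(x) <- t3$compound
  y <- t4$`k_exp_1e-3_s-1`[match(t3$compound, t4$compound)]
  if (anyNA(y)) stop("compound IDs inconsistent across tables")
  list(x = x, y = y, compounds = t3$compound)
}

# Half a unit in the last printed decimal place of each value.
.half_ulp <- function(v) {
  dec <- vapply(v, function(x) {
    s <- format(x, trim = TRUE, scientific = FALSE)
    if (grepl("\\.", s)) nchar(sub(".*\\.", "", s)) else 0L
  }, integer(1))
  0.5 * 10^(-dec)
}

#' Audit: rate units agree between the kinetics and validation tables
#'
#' The kinetics table prints rates as k x 1e-4 s^-1, the validation table
#' as k x 1e-3 s^-1. Dividing the former by ten must agree with the
#' latter to within half a unit of the coarser of the two printed
#' precisions.
#'
#' @return Data frame per compound: both printed values on the 1e-3
#'   scale, their difference, the rounding allowance, and a `pass` flag.
#' @export
audit_unit_consistency <- function() {
  t2 <- load_fixture("table2")
  t4 <- load_fixture("table4")
  m <- match(t4$compound, t2$compound)
  k2on3 <- t2$`k1_1e-4_s-1`[m] / 10
  k4 <- t4$`k_exp_1e-3_s-1`
  tol <- pmax(.half_ulp(t2$`k1_1e-4_s-1`[m]) / 10, .half_ulp(k4)) + 1e-12
  data.frame(compound = t4$compound, k_table2_1e3 = k2on3,
             k_table4_1e3 = k4, diff = k2on3 - k4, allowance = tol,
             pass = abs(k2on3 - k4) <= tol)
}

#' Audit: the printed t0.1 values follow 0.1100 / k1
#'
#' Recomputes t0.1 from each printed k1 with the compatibility constant
#' (see [t01()]) and reports the relative deviation from the printed
#' t0.1. The DHP-series rows are known to violate the relation by a
#' factor of about 25 (a unit inconsistency inherited from earlier work);
#' they are flagged, never corrected.
#'
#' @return Data frame per compound with recomputed t0.1, relative error,
#'   and a `dhp_series` flag.
#' @export
audit_t01 <- function() {
  t2 <- load_fixture("table2")
  k1 <- t2$`k1_1e-4_s-1` * 1e-4
  recomputed <- t01(k1, mode = "published")
  data.frame(compound = t2$compound, t01_printed_min = t2$t01_min,
             t01_recomputed_min = recomputed,
             rel_error = (recomputed - t2$t01_min) / t2$t01_min,
             dhp_series = grepl("^DHP", t2$compound))
}

#' Audit: validation-table error percentages are internally consistent
#'
#' Recomputes `100 * (pred - exp) / exp` from the printed rate columns
#' and compares with the printed error column. Because both rates are
#' printed to three decimals and the published errors were computed from
#' unrounded values, the recomputation can differ by up to the
#' propagated half-ulp of the printed precision (large for the smallest
#' rates); that propagated allowance is reported per row alongside the
#' raw difference.
#'
#' @return Data frame per compound: recomputed error, printed error,
#'   absolute difference, rounding `allowance`, and `pass` (difference
#'   within allowance).
#' @export
audit_table4_errors <- function() {
  t4 <- load_fixture("table4")
  ex <- t4$`k_exp_1e-3_s-1`; pr <- t4$`k_pred_1e-3_s-1`
  rec <- 100 * (pr - ex) / ex
  allowance <- 100 * (.half_ulp(pr) / ex + .half_ulp(ex) * pr / ex^2) +
    .half_ulp(t4$error_percent)
  data.frame(compound = t4$compound, error_recomputed = rec,
             error_printed = t4$error_percent,
             abs_diff = abs(rec - t4$error_percent),
             allowance = allowance,
             pass = abs(rec - t4$error_percent) <= allowance)
}
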
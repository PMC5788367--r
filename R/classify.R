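#' @keywords internal
"_PACKAGE"

## Variant labels used throughout; bit values back the fast matching engine.
COW_VARIANTS <- c(classical = 1L, a1_asymmetry = 2L,
                  incomplete_pcom = 4L, fetal_pc = 8L)

DIAMETER_COLS <- c("a1_left", "a1_right", "p1_left", "p1_right",
                   "pcom_left", "pcom_right")

#' Classification rule thresholds for circle of Willis variants
#'
#' Bundles the three diameter thresholds that define the four variant
#' categories: the hypoplasia cut-off below which a vessel counts as
#' incomplete, the relative A1 diameter difference defining A1 asymmetry,
#' and the relative excess of the posterior communicating artery (PcomA)
#' over the ipsilateral P1 defining a fetal posterior circulation.
#'
#' @param hypoplasia_threshold_mm Diameter (mm) at or below which an A1, P1
#'   or PcomA segment is considered hypoplastic/absent. A classical circle
#'   requires all six diameters strictly above this value; an incomplete
#'   PcomA is a PcomA strictly below it. Default 0.8.
#' @param a1_asymmetry_fraction Relative difference between the two A1
#'   diameters, measured against the larger of the two, above which the
#'   configuration is A1-asymmetric. Default 0.33.
#' @param fetal_excess_fraction Fraction by which a PcomA must exceed the
#'   ipsilateral P1 diameter to count as fetal posterior circulation.
#'   Default 0.10.
#' @return An object of class `cow_rules`.
#' @export
#' @examples
#' cow_rules()
#' cow_rules(a1_asymmetry_fraction = 0.5)
cow_rules <- function(hypoplasia_threshold_mm = 0.8,
                      a1_asymmetry_fraction = 0.33,
                      fetal_excess_fraction = 0.10) {
  stopifnot(is.numeric(hypoplasia_threshold_mm),
            hypoplasia_threshold_mm > 0,
            is.numeric(a1_asymmetry_fraction),
            a1_asymmetry_fraction > 0, a1_asymmetry_fraction < 1,
            is.numeric(fetal_excess_fraction), fetal_excess_fraction > 0)
  structure(list(hypoplasia_threshold_mm = hypoplasia_threshold_mm,
                 a1_asymmetry_fraction = a1_asymmetry_fraction,
                 fetal_excess_fraction = fetal_excess_fraction),
            class = "cow_rules")
}

#' @export
print.cow_rules <- function(x, ...) {
  cat("Circle of Willis classification rules\n",
      "  hypoplasia threshold : >", x$hypoplasia_threshold_mm, "mm\n",
      "  A1 asymmetry         : >", 100 * x$a1_asymmetry_fraction,
      "% difference (vs larger A1)\n",
      "  fetal PC             : PcomA >", 100 * x$fetal_excess_fraction,
      "% larger than ipsilateral P1\n")
  invisible(x)
}

.check_diam <- function(..., .what) {
  vals <- c(...)
  if (anyNA(vals))
    stop("missing diameter measurement for ", .what, call. = FALSE)
  if (any(vals < 0))
    stop("negative diameter for ", .what, call. = FALSE)
  invisible(vals)
}

#' A1 asymmetry predicate
#'
#' The two proximal anterior cerebral artery (A1) segments are asymmetric
#' when their diameter difference, relative to the larger of the two,
#' exceeds the rule fraction. An absent vessel (diameter 0) against a
#' present one is a 100% difference; both absent is not classifiable.
#'
#' @param a1_left,a1_right A1 diameters in mm (0 = absent vessel).
#' @param rules A [cow_rules()] object.
#' @return Logical, vectorised over the diameter pair.
#' @export
is_a1_asymmetric <- function(a1_left, a1_right, rules = cow_rules()) {
  .check_diam(a1_left, a1_right, .what = "A1 segments")
  if (any(a1_left == 0 & a1_right == 0))
    stop("bilateral A1 absent: configuration outside the four categories",
         call. = FALSE)
  abs(a1_left - a1_right) / pmax(a1_left, a1_right) >
    rules$a1_asymmetry_fraction
}

#' Incomplete PcomA predicate
#'
#' True when either posterior communicating artery is hypoplastic or absent
#' (diameter strictly below the hypoplasia threshold).
#'
#' @param pcom_left,pcom_right PcomA diameters in mm (0 = absent vessel).
#' @inheritParams is_a1_asymmetric
#' @return Logical, vectorised.
#' @export
is_incomplete_pcom <- function(pcom_left, pcom_right, rules = cow_rules()) {
  .check_diam(pcom_left, pcom_right, .what = "PcomA segments")
  pcom_left < rules$hypoplasia_threshold_mm |
    pcom_right < rules$hypoplasia_threshold_mm
}

#' Fetal posterior circulation predicate (one side)
#'
#' True when the PcomA is more than the rule fraction larger than the
#' ipsilateral P1. The individual-level fetal PC status is the OR over the
#' two sides, as evaluated in [classify_cow()].
#'
#' @param pcom,p1 Same-side PcomA and P1 diameters in mm.
#' @inheritParams is_a1_asymmetric
#' @return Logical, vectorised.
#' @export
is_fetal_pc <- function(pcom, p1, rules = cow_rules()) {
  .check_diam(pcom, p1, .what = "PcomA/P1 pair")
  pcom > (1 + rules$fetal_excess_fraction) * p1
}

#' Classify a circle of Willis configuration from six vessel diameters
#'
#' Applies the four category rules: fetal posterior circulation (either
#' side's PcomA >10% larger than its P1), A1 asymmetry (>33% relative
#' difference), incomplete PcomA (either PcomA < 0.8 mm), and classical
#' circle (all six diameters > 0.8 mm with neither asymmetry nor fetal PC).
#' The three non-classical variants may co-occur; a classical circle
#' excludes every other category by definition. A configuration that fits
#' none of the four categories (e.g. a hypoplastic P1 with otherwise normal
#' vessels) yields an empty profile.
#'
#' @param diameters Named numeric vector or list with elements `a1_left`,
#'   `a1_right`, `p1_left`, `p1_right`, `pcom_left`, `pcom_right` (mm;
#'   0 codes an absent vessel, `NA` a missing measurement).
#' @inheritParams is_a1_asymmetric
#' @return Character vector of variant labels (subset of `"classical"`,
#'   `"a1_asymmetry"`, `"incomplete_pcom"`, `"fetal_pc"`), possibly empty.
#' @export
#' @examples
#' classify_cow(c(a1_left = 2.4, a1_right = 2.2, p1_left = 1.9,
#'                p1_right = 2.0, pcom_left = 1.2, pcom_right = 1.1))
classify_cow <- function(diameters, rules = cow_rules()) {
  d <- unlist(diameters)[DIAMETER_COLS]
  if (anyNA(d))
    stop("missing diameter(s): ",
         paste(DIAMETER_COLS[is.na(d)], collapse = ", "), call. = FALSE)
  fetal <- is_fetal_pc(d[["pcom_left"]], d[["p1_left"]], rules) ||
    is_fetal_pc(d[["pcom_right"]], d[["p1_right"]], rules)
  asym <- is_a1_asymmetric(d[["a1_left"]], d[["a1_right"]], rules)
  incom <- is_incomplete_pcom(d[["pcom_left"]], d[["pcom_right"]], rules)
  classical <- all(d > rules$hypoplasia_threshold_mm) && !asym && !fetal
  out <- c("classical", "a1_asymmetry", "incomplete_pcom", "fetal_pc")[
    c(classical, asym, incom, fetal)]
  out
}

#' Classify every row of a cohort diameter table
#'
#' @param data Data frame containing the six diameter columns.
#' @inheritParams is_a1_asymmetric
#' @return `data` with four 0/1 columns `classical`, `a1_asymmetry`,
#'   `incomplete_pcom`, `fetal_pc` appended (existing columns of those
#'   names are overwritten).
#' @export
classify_cohort <- function(data, rules = cow_rules()) {
  missing_cols <- setdiff(DIAMETER_COLS, names(data))
  if (length(missing_cols))
    stop("missing diameter column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  profiles <- lapply(seq_len(nrow(data)), function(i)
    classify_cow(unlist(data[i, DIAMETER_COLS]), rules))
  for (v in names(COW_VARIANTS))
    data[[v]] <- vapply(profiles, function(p) as.integer(v %in% p), 1L)
  data
}

## profile <-> bitmask helpers (internal; masks drive the matching engine)
profile_to_mask <- function(profile) {
  if (!length(profile)) return(0L)
  bad <- setdiff(profile, names(COW_VARIANTS))
  if (length(bad))
    stop("unknown variant label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if ("classical" %in% profile && length(profile) > 1L)
    stop("a classical profile cannot carry other variants", call. = FALSE)
  sum(COW_VARIANTS[unique(profile)])
}

mask_to_profile <- function(mask) {
  names(COW_VARIANTS)[bitwAnd(mask, COW_VARIANTS) > 0L]
}
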
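#' Variance-stabilising trait transformations
#'
#' Motility percentages (right-skewed) get a cubic transformation,
#' morphology percentages (left-skewed) a log transformation:
#' `t = y^3 * 1e-4` and `t = 100 * log(y + 1)`. The scalings keep the
#' transformed values on a percent-like scale (0 maps to 0, motility 100
#' maps to 100); they are a package choice, not an authoritative constant.
#' `direction = "inverse"` applies the exact functional inverse.
#'
#' @param values numeric vector; motility must lie in `[0, 100]`,
#'   morphology must be `>= 0`.
#' @param family `"motility_cubic"` or `"morphology_log"`.
#' @param direction `"forward"` (raw to analysis scale) or `"inverse"`.
#' @return Transformed numeric vector.
#' @examples
#' transform_trait(c(0, 50, 100), "motility_cubic")
#' @export
transform_trait <- function(values,
                            family = c("motility_cubic", "morphology_log"),
                            direction = c("forward", "inverse")) {
  family <- match.arg(family)
  direction <- match.arg(direction)
  v <- as.numeric(values)
  if (direction == "forward") {
    if (any(v < 0, na.rm = TRUE)) stop("negative input on the raw scale")
    if (family == "motility_cubic") {
      if (any(v > 100, na.rm = TRUE)) stop("motility must be in [0, 100]")
      v^3 * 1e-4
    } else {
      100 * log(v + 1)
    }
  } else {
    if (any(v < 0, na.rm = TRUE)) stop("transformed value out of range")
    if (family == "motility_cubic") {
      if (any(v > 100 + 1e-9, na.rm = TRUE)) stop("transformed motility out of range")
      (v * 1e4)^(1 / 3)
    } else {
      exp(v / 100) - 1
    }
  }
}

#' Assign records to age classes
#'
#' Ages 7-13 months are early production (`T1`), 14-23 peak production
#' (`T2`) and 24-60 post-peak production (`T3`). Ages outside 7-60 are
#' excluded (`NA`) with a warning.
#'
#' @param age_month integer vector of ages at collection, in months.
#' @return Character vector of class labels (`"T1"`, `"T2"`, `"T3"`) or
#'   `NA` for excluded ages.
#' @export
assign_age_class <- function(age_month) {
  if (any(age_month < 1, na.rm = TRUE)) stop("age must be >= 1 month")
  if (any(age_month != round(age_month), na.rm = TRUE)) {
    stop("age must be a whole number of months")
  }
  out <- rep(NA_character_, length(age_month))
  out[age_month >= 7 & age_month <= 13] <- "T1"
  out[age_month >= 14 & age_month <= 23] <- "T2"
  out[age_month >= 24 & age_month <= 60] <- "T3"
  if (anyNA(out)) {
    warning(sum(is.na(out)), " record(s) outside 7-60 months excluded")
  }
  out
}

#' Age-class definitions
#'
#' @return data.frame with the class labels, month bounds and the number
#'   of within-class monthly age factors (7, 10 and 37).
#' @export
age_classes <- function() {
  data.frame(label = c("T1", "T2", "T3"),
             lower = c(7L, 14L, 24L), upper = c(13L, 23L, 60L),
             n_age_factors = c(7L, 10L, 37L))
}

#' Minimum-ejaculate filter
#'
#' Keeps a boar's records within an age class only if the boar has at
#' least `min_per_class` records in that class. A boar left with no
#' records at all is removed and listed. With `whole_boar = TRUE` a boar
#' deficient in any class it appears in is removed entirely.
#'
#' @param records record table with `boar` and `age_class` columns.
#' @param min_per_class minimum records per boar-class cell (default 3).
#' @param whole_boar drop the whole boar when any of its classes is
#'   deficient (default `FALSE`: drop only the deficient class's records).
#' @return List with `records` (filtered) and `removed_boars` (character
#'   vector of boars no longer present).
#' @export
filter_min_records <- function(records, min_per_class = 3L, whole_boar = FALSE) {
  if (min_per_class < 1L) stop("min_per_class must be >= 1")
  if (!all(c("boar", "age_class") %in% names(records))) {
    stop("records need 'boar' and 'age_class' columns")
  }
  cnt <- table(records$boar, records$age_class)
  cell_ok <- cnt[cbind(match(records$boar, rownames(cnt)),
                       match(records$age_class, colnames(cnt)))] >= min_per_class
  keep <- if (whole_boar) {
    bad_boars <- rownames(cnt)[apply(cnt, 1L, function(x) any(x > 0 & x < min_per_class))]
    !(records$boar %in% bad_boars)
  } else {
    cell_ok
  }
  out <- records[keep, , drop = FALSE]
  removed <- setdiff(unique(records$boar), unique(out$boar))
  list(records = out, removed_boars = removed)
}
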
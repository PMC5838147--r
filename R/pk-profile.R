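#' Construct a concentration-time profile
#'
#' One subject/site/route series with its dose and assay LLOQ.
#' Concentrations strictly below the LLOQ are treated as
#' below-the-limit-of-quantification (BLQ) observations; see
#' [preprocess_blq()] for the censoring rules.
#'
#' @param subject_id Subject label.
#' @param site Sampling site: `"systemic"`, `"portal"` or `"jugular"`.
#' @param route `"iv_bolus"` or `"oral"`.
#' @param dose Dose in mg/kg (> 0).
#' @param times Sampling times in hours, strictly increasing, >= 0.
#' @param conc Concentrations (same length as `times`), >= 0.
#' @param conc_unit `"ng/mL"` or `"nM"`.
#' @param lloq Lower limit of quantification, same unit as `conc`.
#' @param molecular_weight g/mol; required only when unit conversion is
#'   needed (never guessed).
#' @return Object of class `"pk_profile"`.
#' @export
pk_profile <- function(subject_id = "s1",
                       site = c("systemic", "portal", "jugular"),
                       route = c("iv_bolus", "oral"),
                       dose, times, conc, conc_unit = c("ng/mL", "nM"),
                       lloq = 0, molecular_weight = NULL) {
  site <- match.arg(site)
  route <- match.arg(route)
  conc_unit <- match.arg(conc_unit)
  if (missing(dose) || !is.numeric(dose) || dose <= 0) {
    stop("a positive dose (mg/kg) is required", call. = FALSE)
  }
  times <- as.numeric(times)
  conc <- as.numeric(conc)
  if (length(times) != length(conc)) {
    stop("times and conc must have equal length", call. = FALSE)
  }
  if (any(times < 0) || any(diff(times) <= 0)) {
    stop("times must be non-negative and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("concentrations must be finite and >= 0", call. = FALSE)
  }
  structure(list(subject_id = subject_id, site = site, route = route,
                 dose = dose, times = times, conc = conc,
                 conc_unit = conc_unit, lloq = lloq,
                 molecular_weight = molecular_weight,
                 blq_note = NULL),
            class = "pk_profile")
}

#' @export
print.pk_profile <- function(x, ...) {
  cat(sprintf("pk_profile %s [%s, %s]: %d points, dose %g mg/kg, LLOQ %g %s\n",
              x$subject_id, x$site, x$route, length(x$times), x$dose,
              x$lloq, x$conc_unit))
  invisible(x)
}

is_blq <- function(profile) profile$conc < profile$lloq

#' Apply a below-LLOQ censoring rule to a profile
#'
#' Default rule (`"leading_zero"`): BLQ observations before the first
#' quantifiable point are set to 0 (absorption has not started);
#' embedded and trailing BLQ points are dropped, with a note recorded in
#' the returned profile.  Alternatives: `"drop_all"` removes every BLQ
#' point; `"zero_all"` sets every BLQ point to 0.
#'
#' @param profile A [pk_profile()].
#' @param rule Censoring rule (see above).
#' @return The censored [pk_profile()] (field `blq_note` describes what
#'   was done).
#' @export
preprocess_blq <- function(profile,
                           rule = c("leading_zero", "drop_all", "zero_all")) {
  stopifnot(inherits(profile, "pk_profile"))
  rule <- match.arg(rule)
  blq <- is_blq(profile)
  if (all(blq)) stop("all observations are below the LLOQ", call. = FALSE)
  if (!any(blq)) return(profile)
  keep <- rep(TRUE, length(blq))
  if (rule == "leading_zero") {
    first_q <- which(!blq)[1]
    leading <- blq & seq_along(blq) < first_q
    profile$conc[leading] <- 0
    keep <- !(blq & !leading)
    note <- sprintf("%d leading BLQ set to 0; %d embedded/trailing BLQ dropped",
                    sum(leading), sum(!keep))
  } else if (rule == "drop_all") {
    keep <- !blq
    note <- sprintf("%d BLQ dropped", sum(blq))
  } else {
    profile$conc[blq] <- 0
    note <- sprintf("%d BLQ set to 0", sum(blq))
  }
  profile$times <- profile$times[keep]
  profile$conc <- profile$conc[keep]
  profile$blq_note <- note
  profile
}

# ng/mL per nM = MW(g/mol) * 1e-3
conc_as_ng_ml <- function(value, unit, mw) {
  if (unit == "ng/mL") return(value)
  if (is.null(mw)) {
    stop("molecular_weight is required to convert nM concentrations; ",
         "it is never guessed", call. = FALSE)
  }
  value * mw * 1e-3
}
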
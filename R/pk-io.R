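#' Read concentration-time profiles from CSV
#'
#' Expected columns: `subject_id, site, route, dose_mg_per_kg, time_h,
#' conc, conc_unit, lloq` (optional `molecular_weight`).  Rows are
#' grouped into one [pk_profile()] per (subject, site, route).
#'
#' @param path CSV path.
#' @return Named list of [pk_profile()] objects
#'   (`subject_id/site/route`).
#' @export
read_pk_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "site", "route", "dose_mg_per_kg", "time_h",
            "conc", "conc_unit", "lloq")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("PK CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  key <- interaction(d$subject_id, d$site, d$route, drop = TRUE, sep = "/")
  out <- lapply(split(d, key), function(g) {
    g <- g[order(g$time_h), ]
    pk_profile(subject_id = as.character(g$subject_id[1]),
               site = g$site[1], route = g$route[1],
               dose = g$dose_mg_per_kg[1],
               times = g$time_h, conc = g$conc,
               conc_unit = g$conc_unit[1], lloq = g$lloq[1],
               molecular_weight = if ("molecular_weight" %in% names(g)) {
                 g$molecular_weight[1]
               } else NULL)
  })
  out
}

#' Write profiles to the package's PK CSV dialect
#'
#' @param profiles A [pk_profile()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pk_csv <- function(profiles, path) {
  if (inherits(profiles, "pk_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    data.frame(subject_id = p$subject_id, site = p$site, route = p$route,
               dose_mg_per_kg = p$dose, time_h = p$times, conc = p$conc,
               conc_unit = p$conc_unit, lloq = p$lloq,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
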
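## Toxic-unit scoring of pesticide residues and water-chemistry summaries.
## The toxic pressure of a water sample is the log10 sum of toxic units,
##   TU_sum = log10( sum_i C_i / E_i ),
## where C_i is the measured concentration of substance i (ug/L) and E_i
## the most sensitive acute endpoint (EC50/LC50, ug/L) available for the
## organism class. Detections quantified below the LOQ enter at half the
## LOQ.

#' Resolve the most sensitive endpoint per substance
#'
#' @param endpoints data frame with columns `substance`, `organism_class`
#'   (`"invertebrate"` or `"algae"`), `endpoint` (ug/L, > 0) and
#'   optionally `basis` (free text, e.g. "48 h EC50 Daphnia magna").
#' @param organism_class which class to resolve for.
#' @return named numeric vector: minimum endpoint per substance.
#' @export
resolve_endpoints <- function(endpoints,
                              organism_class = c("invertebrate", "algae")) {
  organism_class <- match.arg(organism_class)
  stopifnot(all(c("substance", "organism_class", "endpoint") %in%
                  names(endpoints)))
  sub <- endpoints[endpoints$organism_class == organism_class, , drop = FALSE]
  if (any(sub$endpoint <= 0)) stop("endpoints must be strictly positive")
  tapply(sub$endpoint, sub$substance, min)
}

#' Sum of toxic units (log10 scale)
#'
#' Scores the toxic pressure of one water sample from its pesticide
#' residue measurements: each detected substance contributes its
#' concentration divided by the most sensitive EC50/LC50 endpoint for the
#' chosen organism class; concentrations above 0 but below the LOQ are
#' substituted by half the LOQ; the score is the log10 of the summed
#' ratios.
#'
#' @param measurements data frame with columns `substance`, `conc` (ug/L,
#'   0 = not detected), `loq` (ug/L, > 0).
#' @param endpoints endpoint table, see [resolve_endpoints()].
#' @param organism_class `"invertebrate"` or `"algae"`.
#' @return `TU_sum` (dimensionless, log10 scale), or `NA` with attribute
#'   `no_detection = TRUE` when nothing was detected ("no toxic
#'   pressure", deliberately not 0, which would mean a unit toxic-unit
#'   sum).
#' @export
tu_sum <- function(measurements, endpoints,
                   organism_class = c("invertebrate", "algae")) {
  organism_class <- match.arg(organism_class)
  stopifnot(all(c("substance", "conc", "loq") %in% names(measurements)))
  if (any(measurements$loq <= 0)) stop("loq must be strictly positive")
  if (any(measurements$conc < 0)) stop("concentrations must be >= 0")
  det <- measurements[measurements$conc > 0, , drop = FALSE]
  if (nrow(det) == 0L) {
    return(structure(NA_real_, no_detection = TRUE))
  }
  ep <- resolve_endpoints(endpoints, organism_class)
  miss <- setdiff(unique(det$substance), names(ep))
  if (length(miss)) {
    stop("no ", organism_class, " endpoint for substance(s): ",
         paste(miss, collapse = ", "))
  }
  c_eff <- ifelse(det$conc < det$loq, det$loq / 2, det$conc)
  log10(sum(c_eff / ep[det$substance]))
}

#' Assemble a water-chemistry table
#'
#' One row per site with in-situ parameters and nutrient concentrations;
#' the pesticide measurements live in a separate long table keyed by
#' `site_id`. Derived columns: `nutrient_sum = nh4 + no3` (mg/L; the
#' eutrophication proxy -- phosphate and nitrite are carried but not
#' summed) and `n_detections` (substances with `conc > 0`).
#'
#' @param chem data frame with columns `site_id`, `wb_type` and numeric
#'   columns `temp`, `ec`, `ph`, `o2`, `nh4`, `no3`, `no2`, `po4`.
#' @param pesticides long data frame (`site_id`, `substance`, `conc`,
#'   `loq`), or `NULL`.
#' @param endpoints endpoint table, or `NULL` to skip TU columns.
#' @return `water_chemistry` data frame: input columns plus
#'   `nutrient_sum`, `n_detections`, and (with endpoints)
#'   `tu_invertebrate` and `tu_algae`.
#' @export
water_chemistry <- function(chem, pesticides = NULL, endpoints = NULL) {
  need <- c("site_id", "wb_type", "nh4", "no3")
  stopifnot(all(need %in% names(chem)))
  num_cols <- intersect(c("temp", "ec", "ph", "o2", "nh4", "no3", "no2",
                          "po4"), names(chem))
  if (any(vapply(chem[c("nh4", "no3")], function(v) any(v < 0), TRUE))) {
    stop("nutrient concentrations must be >= 0")
  }
  out <- chem
  out$nutrient_sum <- chem$nh4 + chem$no3
  if (!"n_detections" %in% names(out)) out$n_detections <- 0L
  out$n_detections <- as.integer(out$n_detections)
  if (!is.null(pesticides)) {
    det <- pesticides[pesticides$conc > 0, , drop = FALSE]
    cnt <- table(factor(det$site_id, levels = chem$site_id))
    out$n_detections <- as.integer(cnt[chem$site_id])
    if (!is.null(endpoints)) {
      out$tu_invertebrate <- vapply(chem$site_id, function(s) {
        as.numeric(tu_sum(pesticides[pesticides$site_id == s, , drop = FALSE],
                          endpoints, "invertebrate"))
      }, numeric(1))
      out$tu_algae <- vapply(chem$site_id, function(s) {
        as.numeric(tu_sum(pesticides[pesticides$site_id == s, , drop = FALSE],
                          endpoints, "algae"))
      }, numeric(1))
    }
  }
  class(out) <- c("water_chemistry", "data.frame")
  out
}

#' Per-type summaries of water quality
#'
#' Mean and sample standard deviation (n-1) of the pesticide detection
#' counts and of the nutrient sums (NH4+ + NO3-, mg/L), per water-body
#' type. The SD is `NA` for types with a single site.
#'
#' @param chem a [water_chemistry()] data frame (or any data frame with
#'   `site_id`, `wb_type`, `nutrient_sum`, `n_detections`).
#' @return data frame with one row per `wb_type`: `n_sites`,
#'   `detections_mean`, `detections_sd`, `nutrient_mean`, `nutrient_sd`.
#' @export
water_summaries <- function(chem) {
  stopifnot(all(c("site_id", "wb_type", "nutrient_sum", "n_detections") %in%
                  names(chem)))
  sd1 <- function(v) if (length(v) > 1) stats::sd(v) else NA_real_
  types <- sort(unique(chem$wb_type))
  out <- do.call(rbind, lapply(types, function(tp) {
    sub <- chem[chem$wb_type == tp, , drop = FALSE]
    data.frame(wb_type = tp, n_sites = nrow(sub),
               detections_mean = mean(sub$n_detections),
               detections_sd = sd1(sub$n_detections),
               nutrient_mean = mean(sub$nutrient_sum),
               nutrient_sd = sd1(sub$nutrient_sum),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read the water-chemistry fixture files
#'
#' Thin readers for the CSV layouts the package writes and accepts: a
#' per-site chemistry table, a long pesticide table and an endpoint table.
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_chemistry_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
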
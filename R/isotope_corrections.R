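#' Delta notation from isotope ratios
#'
#' Converts a measured heavy/light isotope ratio into per-mil delta
#' notation relative to a reference standard (VPDB for carbon, atmospheric
#' air for nitrogen):
#' \deqn{\delta X = (R_{sample}/R_{standard} - 1) \times 10^3}
#'
#' @param r_sample sample isotope ratio(s), strictly positive.
#' @param r_standard reference ratio(s), strictly positive.
#' @return per-mil delta value(s).
#' @examples
#' delta_from_ratio(1.01, 1) # 10 permil
#' @export
delta_from_ratio <- function(r_sample, r_standard) {
  if (any(!is.finite(r_sample)) || any(!is.finite(r_standard)) ||
      any(r_sample <= 0) || any(r_standard <= 0)) {
    stop("isotope ratios must be finite and strictly positive")
  }
  (r_sample / r_standard - 1) * 1e3
}

.correction_report <- function(axis, target_sites, reference_mean,
                               target_mean) {
  structure(list(
    axis = axis,
    target_sites = target_sites,
    reference_mean = reference_mean,
    target_mean = target_mean,
    offset_applied = target_mean - reference_mean
  ), class = "correction_report")
}

#' @export
print.correction_report <- function(x, ...) {
  cat(sprintf(
    "<correction_report> %s: target mean %.3f, reference mean %.3f, offset %.3f permil subtracted from %s\n",
    x$axis, x$target_mean, x$reference_mean, x$offset_applied,
    paste(x$target_sites, collapse = ", ")))
  invisible(x)
}

#' Serialize a correction report to JSON
#'
#' @param report a `correction_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_correction_report <- function(report, path) {
  stopifnot(inherits(report, "correction_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.warn_if_reapplied <- function(table, tag) {
  prov <- attr(table, "provenance")
  if (any(grepl(tag, prov, fixed = TRUE))) {
    warning("correction '", tag, "' appears to have been applied already; ",
            "re-applying is a no-op only if the group means still coincide",
            call. = FALSE)
  }
}

#' Remove the fertilizer d15N offset from ditch samples
#'
#' Organic fertilization enriches the nitrogen baseline of ditches, so
#' consumer d15N in ditches sits systematically above that in ponds. To
#' compare trophic structure across the two water-body types, the pooled
#' consumer mean d15N is computed per type and the difference
#' (ditch mean - pond mean) is subtracted from every ditch sample's d15N;
#' pond rows and the d13C axis are untouched. All sampled invertebrates
#' are treated as consumers.
#'
#' @param table a [sample_table()] containing both water-body types.
#' @return list with elements `table` (corrected `sample_table`) and
#'   `report` (a `correction_report` holding both means and the offset).
#' @export
correct_d15N_fertilizer <- function(table) {
  stopifnot(inherits(table, "sample_table"))
  if (!all(WB_TYPES %in% table$wb_type)) {
    stop("both water-body types (pond, ditch) are required for the ",
         "fertilizer correction")
  }
  .warn_if_reapplied(table, "d15N fertilizer correction")
  mean_pond <- mean(table$d15N[table$wb_type == "pond"])
  mean_ditch <- mean(table$d15N[table$wb_type == "ditch"])
  offset <- mean_ditch - mean_pond
  out <- as.data.frame(table)
  is_ditch <- out$wb_type == "ditch"
  out$d15N[is_ditch] <- out$d15N[is_ditch] - offset
  out <- sample_table(out, provenance = attr(table, "provenance"))
  out <- .append_provenance(out, sprintf(
    "d15N fertilizer correction: %.4f permil subtracted from ditches", offset))
  report <- .correction_report("d15N",
                               unique(table$site_id[is_ditch]),
                               reference_mean = mean_pond,
                               target_mean = mean_ditch)
  list(table = out, report = report)
}

#' Remove the maize (C4) d13C offset from selected pond samples
#'
#' Maize cultivation in a pond's catchment raises consumer d13C through the
#' C4 photosynthetic pathway of the crop. The correction computes the
#' pooled consumer mean d13C over the unaffected (reference) ponds and over
#' the maize-influenced ponds, and subtracts the difference from d13C of
#' samples in the maize sites only.
#'
#' @param table a [sample_table()].
#' @param maize_sites character vector of pond site ids under maize
#'   influence; must leave at least one pond as reference.
#' @return list with elements `table` and `report`, as for
#'   [correct_d15N_fertilizer()].
#' @export
correct_d13C_maize <- function(table, maize_sites) {
  stopifnot(inherits(table, "sample_table"), length(maize_sites) >= 1)
  pond_sites <- unique(table$site_id[table$wb_type == "pond"])
  if (!all(maize_sites %in% pond_sites)) {
    stop("maize_sites must all be pond sites; offending: ",
         paste(setdiff(maize_sites, pond_sites), collapse = ", "))
  }
  ref_sites <- setdiff(pond_sites, maize_sites)
  if (!length(ref_sites)) {
    stop("maize_sites cover every pond; no reference ponds remain")
  }
  .warn_if_reapplied(table, "d13C maize correction")
  in_maize <- table$site_id %in% maize_sites
  in_ref <- table$site_id %in% ref_sites
  mean_ref <- mean(table$d13C[in_ref])
  mean_maize <- mean(table$d13C[in_maize])
  offset <- mean_maize - mean_ref
  out <- as.data.frame(table)
  out$d13C[in_maize] <- out$d13C[in_maize] - offset
  out <- sample_table(out, provenance = attr(table, "provenance"))
  out <- .append_provenance(out, sprintf(
    "d13C maize correction: %.4f permil subtracted from %s", offset,
    paste(maize_sites, collapse = ", ")))
  report <- .correction_report("d13C", maize_sites,
                               reference_mean = mean_ref,
                               target_mean = mean_maize)
  list(table = out, report = report)
}
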
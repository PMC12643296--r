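#' @keywords internal
"_PACKAGE"

## Canonical functional feeding group levels. Six guilds; data files spell
## them many ways, so free text is normalized through .ffg_dictionary().
FFG_LEVELS <- c(
  "collector_filterer", "collector_gatherer", "grazer_scraper",
  "omnivore", "predator", "shredder"
)

## FFGs conventionally treated as primary consumers.
PRIMARY_CONSUMERS <- c(
  "collector_filterer", "collector_gatherer", "grazer_scraper", "shredder"
)

WB_TYPES <- c("pond", "ditch")

## strip everything but letters so "Collector/filterer", "collector-filterer"
## and "collector_filterer" all collapse to the same key
.ffg_key <- function(x) gsub("[^a-z]", "", tolower(x))

.ffg_dictionary <- function() {
  syn <- list(
    collector_filterer = c("collector_filterer", "collector/filterer",
                           "collector filterer", "filterer", "filter feeder",
                           "collectorfilterer"),
    collector_gatherer = c("collector_gatherer", "collector/gatherer",
                           "collector gatherer", "gatherer", "collector",
                           "collectorgatherer"),
    grazer_scraper     = c("grazer_scraper", "grazer/scraper", "grazer scraper",
                           "grazer", "scraper", "grazerscraper"),
    omnivore           = c("omnivore", "omnivorous"),
    predator           = c("predator", "predatory", "predators"),
    shredder           = c("shredder", "shredders")
  )
  out <- character(0)
  for (lvl in names(syn)) {
    keys <- .ffg_key(syn[[lvl]])
    out[keys] <- lvl
  }
  out
}

#' Normalize functional feeding group labels
#'
#' Maps free-text FFG labels (any case, `/`, `-`, `_` or space separated)
#' onto the six canonical guild names. Unknown labels map to `NA` rather
#' than being guessed.
#'
#' @param x character vector of raw labels.
#' @return character vector with values in the six canonical FFG names,
#'   `NA` where no dictionary entry matches.
#' @examples
#' normalize_ffg(c("Predator", "collector/filterer", "Grazer-Scraper"))
#' @export
normalize_ffg <- function(x) {
  dict <- .ffg_dictionary()
  out <- unname(dict[.ffg_key(as.character(x))])
  out
}

## column synonyms accepted in input tables, matched case-insensitively
.column_synonyms <- list(
  sample_id = c("sample_id", "sample", "id", "sampleid"),
  site_id   = c("site_id", "site", "water_body", "waterbody", "swb"),
  wb_type   = c("wb_type", "type", "water_body_type", "wbtype"),
  ffg       = c("ffg", "feeding_group", "functional_feeding_group", "guild"),
  taxon     = c("taxon", "taxa", "family", "order"),
  d13c      = c("d13c", "delta13c", "δ13c", "d_13c", "delta_13c", "c13"),
  d15n      = c("d15n", "delta15n", "δ15n", "d_15n", "delta_15n", "n15")
)

.match_columns <- function(nms) {
  low <- tolower(gsub("[^[:alnum:]δ]+", "_", nms))
  low <- gsub("^_|_$", "", low)
  out <- integer(0)
  for (canon in names(.column_synonyms)) {
    hit <- which(low %in% .column_synonyms[[canon]])
    if (length(hit)) out[canon] <- hit[1]
  }
  out
}

#' Construct a validated isotope sample table
#'
#' A `sample_table` is a data frame with one row per analyzed isotope sample
#' (a pooled capsule counts as one sample) and columns `sample_id`,
#' `site_id`, `wb_type` (`"pond"` or `"ditch"`), `ffg` (one of the six
#' guilds), `taxon`, `d13C` and `d15N` (both per-mil). Validation enforces
#' unique sample ids, a consistent water-body type per site, canonical FFG
#' levels and finite delta values.
#'
#' @param df data frame with the required columns.
#' @param provenance character vector of free-text provenance notes.
#' @return a `sample_table` object (data frame subclass).
#' @export
sample_table <- function(df, provenance = character(0)) {
  required <- c("sample_id", "site_id", "wb_type", "ffg", "d13C", "d15N")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (!"taxon" %in% names(df)) df$taxon <- NA_character_
  df <- df[c("sample_id", "site_id", "wb_type", "ffg", "taxon", "d13C", "d15N")]
  df$sample_id <- as.character(df$sample_id)
  df$site_id <- as.character(df$site_id)
  df$wb_type <- as.character(df$wb_type)
  df$ffg <- as.character(df$ffg)
  df$taxon <- as.character(df$taxon)
  df$d13C <- as.numeric(df$d13C)
  df$d15N <- as.numeric(df$d15N)

  if (nrow(df) == 0L) stop("sample table is empty")
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  bad_type <- setdiff(unique(df$wb_type), WB_TYPES)
  if (length(bad_type)) {
    stop("unknown wb_type: ", paste(bad_type, collapse = ", "))
  }
  bad_ffg <- setdiff(unique(df$ffg), FFG_LEVELS)
  if (length(bad_ffg)) {
    stop("unknown ffg: ", paste(bad_ffg, collapse = ", "))
  }
  if (!all(is.finite(df$d13C)) || !all(is.finite(df$d15N))) {
    stop("non-finite delta values present")
  }
  tt <- unique(df[c("site_id", "wb_type")])
  if (anyDuplicated(tt$site_id)) {
    stop("site(s) with inconsistent wb_type: ",
         paste(unique(tt$site_id[duplicated(tt$site_id)]), collapse = ", "))
  }
  rownames(df) <- NULL
  structure(df, provenance = provenance,
            class = c("sample_table", "data.frame"))
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("<sample_table> %d samples, %d sites (%d pond, %d ditch)\n",
              nrow(x), length(unique(x$site_id)),
              length(unique(x$site_id[x$wb_type == "pond"])),
              length(unique(x$site_id[x$wb_type == "ditch"]))))
  prov <- attr(x, "provenance")
  if (length(prov)) cat("provenance:", paste(prov, collapse = "; "), "\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

.append_provenance <- function(tab, note) {
  structure(tab, provenance = c(attr(tab, "provenance"), note),
            class = class(tab))
}

#' Read an isotope sample table from CSV/TSV
#'
#' Columns are matched case-insensitively against a synonym map (e.g.
#' `d15N`/`delta15N`), FFG labels are normalized through the fixed
#' dictionary, and rows with unmappable FFGs or non-numeric delta values
#' are rejected with row-level diagnostics (attached as attribute
#' `"rejected"` and reported via warnings).
#'
#' @param path path to a delimited text file with a header.
#' @param sep field separator; `NULL` (default) infers `"\t"` for `.tsv`
#'   files and `","` otherwise.
#' @return a validated [sample_table()].
#' @export
read_isotope_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "\"")
  if (nrow(raw) == 0L) stop("empty table: ", path)
  idx <- .match_columns(names(raw))
  required <- c("sample_id", "site_id", "wb_type", "ffg", "d13c", "d15n")
  miss <- setdiff(required, names(idx))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  df <- data.frame(
    sample_id = as.character(raw[[idx[["sample_id"]]]]),
    site_id   = as.character(raw[[idx[["site_id"]]]]),
    wb_type   = tolower(as.character(raw[[idx[["wb_type"]]]])),
    ffg       = normalize_ffg(raw[[idx[["ffg"]]]]),
    taxon     = if ("taxon" %in% names(idx))
      as.character(raw[[idx[["taxon"]]]]) else NA_character_,
    d13C      = suppressWarnings(as.numeric(raw[[idx[["d13c"]]]])),
    d15N      = suppressWarnings(as.numeric(raw[[idx[["d15n"]]]])),
    stringsAsFactors = FALSE
  )
  bad_ffg <- is.na(df$ffg)
  bad_num <- !is.finite(df$d13C) | !is.finite(df$d15N)
  reject <- bad_ffg | bad_num
  diagnostics <- character(0)
  if (any(reject)) {
    rows <- which(reject)
    reasons <- ifelse(bad_ffg[rows], "unmappable ffg", "non-numeric delta value")
    diagnostics <- sprintf("row %d (%s): %s", rows,
                           df$sample_id[rows], reasons)
    warning(length(rows), " row(s) rejected:\n  ",
            paste(diagnostics, collapse = "\n  "), call. = FALSE)
    df <- df[!reject, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no valid rows remain in ", path)
  tab <- sample_table(df, provenance = paste0("read from ", path))
  attr(tab, "rejected") <- diagnostics
  tab
}

#' Summarize sample counts per site, water-body type and FFG
#'
#' Computes the bookkeeping behind per-study sample accounting: counts per
#' (site, FFG) group, per-type FFG totals, per-type grand totals, and the
#' mean number of samples per site of each water-body type. Counts are in
#' analyzed-sample units (one pooled capsule = one sample).
#'
#' @param table a [sample_table()].
#' @return a `counts_summary` list with elements `per_group` (data frame
#'   `site_id`, `wb_type`, `ffg`, `n`), `per_type_ffg` (data frame
#'   `wb_type`, `ffg`, `n`), `per_type_total` (named integer),
#'   `per_type_mean_per_site` (named numeric) and `n_sites` (named integer).
#' @export
summarize_counts <- function(table) {
  stopifnot(inherits(table, "sample_table"))
  per_group <- as.data.frame(
    table(site_id = table$site_id, ffg = factor(table$ffg, FFG_LEVELS)),
    responseName = "n", stringsAsFactors = FALSE
  )
  site_type <- unique(data.frame(site_id = table$site_id,
                                 wb_type = table$wb_type,
                                 stringsAsFactors = FALSE))
  per_group <- merge(per_group, site_type, by = "site_id", sort = TRUE)
  per_group <- per_group[order(per_group$site_id, per_group$ffg),
                         c("site_id", "wb_type", "ffg", "n")]
  rownames(per_group) <- NULL
  .counts_summary(per_group)
}

## shared core: build a counts_summary from a per-(site, ffg) count frame
.counts_summary <- function(per_group) {
  stopifnot(all(c("site_id", "wb_type", "ffg", "n") %in% names(per_group)))
  per_group$n <- as.integer(per_group$n)
  agg <- stats::aggregate(n ~ wb_type + ffg, data = per_group, FUN = sum)
  agg <- agg[order(agg$wb_type, agg$ffg), c("wb_type", "ffg", "n")]
  rownames(agg) <- NULL
  tot <- tapply(per_group$n, per_group$wb_type, sum)
  n_sites <- tapply(per_group$site_id, per_group$wb_type,
                    function(s) length(unique(s)))
  structure(list(
    per_group = per_group,
    per_type_ffg = agg,
    per_type_total = stats::setNames(as.integer(tot), names(tot)),
    per_type_mean_per_site = stats::setNames(
      as.numeric(tot) / as.numeric(n_sites), names(tot)),
    n_sites = stats::setNames(as.integer(n_sites), names(n_sites))
  ), class = "counts_summary")
}

#' Build a counts summary from a wide counts table
#'
#' Accepts a wide count matrix as published in field-survey reports: one row
#' per FFG, one column per site, plus a mapping from site to water-body
#' type. Useful when only aggregated counts (not per-sample rows) are
#' available.
#'
#' @param counts data frame with column `ffg` and one numeric column per
#'   site.
#' @param type_map named character vector mapping site id to `"pond"` or
#'   `"ditch"`.
#' @return a `counts_summary`, as from [summarize_counts()].
#' @export
counts_summary_from_wide <- function(counts, type_map) {
  stopifnot("ffg" %in% names(counts))
  sites <- setdiff(names(counts), "ffg")
  if (!all(sites %in% names(type_map))) {
    stop("type_map missing site(s): ",
         paste(setdiff(sites, names(type_map)), collapse = ", "))
  }
  ffg <- normalize_ffg(counts$ffg)
  if (anyNA(ffg)) stop("unknown ffg label(s): ",
                       paste(counts$ffg[is.na(ffg)], collapse = ", "))
  long <- do.call(rbind, lapply(sites, function(s) {
    data.frame(site_id = s, wb_type = unname(type_map[s]), ffg = ffg,
               n = as.integer(counts[[s]]), stringsAsFactors = FALSE)
  }))
  .counts_summary(long)
}

#' Mean per-site sample count for a named FFG subset
#'
#' For each water-body type, sums the counts over the given FFGs and
#' divides by the number of sites of that type; this is the convention used
#' when reporting e.g. mean primary-consumer sample numbers per pond or
#' ditch.
#'
#' @param cs a `counts_summary`.
#' @param ffgs character vector of canonical FFG names; defaults to the
#'   four primary-consumer guilds.
#' @return named numeric vector, one value per water-body type.
#' @export
ffg_subset_mean <- function(cs, ffgs = PRIMARY_CONSUMERS) {
  stopifnot(inherits(cs, "counts_summary"))
  bad <- setdiff(ffgs, FFG_LEVELS)
  if (length(bad)) stop("unknown ffg: ", paste(bad, collapse = ", "))
  sub <- cs$per_type_ffg[cs$per_type_ffg$ffg %in% ffgs, , drop = FALSE]
  tot <- tapply(sub$n, factor(sub$wb_type, names(cs$n_sites)), sum)
  tot[is.na(tot)] <- 0
  stats::setNames(as.numeric(tot) / as.numeric(cs$n_sites[names(tot)]),
                  names(tot))
}

#' @export
print.counts_summary <- function(x, ...) {
  cat("<counts_summary>\n totals:",
      paste(sprintf("%s = %d", names(x$per_type_total), x$per_type_total),
            collapse = ", "),
      "\n mean samples per site:",
      paste(sprintf("%s = %.2f", names(x$per_type_mean_per_site),
                    x$per_type_mean_per_site), collapse = ", "), "\n")
  invisible(x)
}

#' Write a counts summary to CSV or JSON
#'
#' @param cs a `counts_summary`.
#' @param path output path; format chosen by extension (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_counts_summary <- function(cs, path) {
  stopifnot(inherits(cs, "counts_summary"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(
      per_group = cs$per_group,
      per_type_ffg = cs$per_type_ffg,
      per_type_total = as.list(cs$per_type_total),
      per_type_mean_per_site = as.list(cs$per_type_mean_per_site),
      n_sites = as.list(cs$n_sites)
    ), path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(cs$per_group, path, row.names = FALSE)
  }
  invisible(path)
}

#' Drop small sample groups
#'
#' Removes every group with fewer than `min_n` samples, where groups are
#' formed by site x FFG (default) or water-body type x FFG. Field protocols
#' commonly require at least three analyzed samples per group before a
#' niche is estimated; groups failing the threshold are dropped and
#' reported.
#'
#' @param table a [sample_table()].
#' @param min_n minimum group size to retain (>= 1); groups with
#'   `n < min_n` are dropped (strictly-below rule).
#' @param by grouping level: `"site"` (site x FFG) or `"type"`
#'   (water-body type x FFG).
#' @return filtered `sample_table`; dropped groups are recorded in the
#'   attribute `"dropped_groups"` (data frame) and in provenance.
#' @export
filter_min_group_size <- function(table, min_n = 3L, by = c("site", "type")) {
  stopifnot(inherits(table, "sample_table"), min_n >= 1)
  by <- match.arg(by)
  key <- if (by == "site") table$site_id else table$wb_type
  grp <- paste(key, table$ffg, sep = "\r")
  sizes <- table(grp)
  drop_keys <- names(sizes)[sizes < min_n]
  keep <- !(grp %in% drop_keys)
  if (!any(keep)) stop("all groups have fewer than ", min_n,
                       " samples; nothing left to analyze")
  dropped <- do.call(rbind, lapply(drop_keys, function(k) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    data.frame(group = parts[1], ffg = parts[2],
               n = as.integer(sizes[[k]]), stringsAsFactors = FALSE)
  }))
  if (is.null(dropped)) {
    dropped <- data.frame(group = character(0), ffg = character(0),
                          n = integer(0))
  }
  out <- sample_table(as.data.frame(table)[keep, , drop = FALSE],
                      provenance = attr(table, "provenance"))
  out <- .append_provenance(out, sprintf(
    "filtered groups (%s x ffg) with n < %d: %d dropped", by, min_n,
    nrow(dropped)))
  attr(out, "dropped_groups") <- dropped
  out
}
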
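## End-to-end orchestration: data (read or simulate) -> validation and
## group-size filtering -> delta corrections -> Layman + Bayesian niche
## estimation -> pond/ditch ellipse overlap -> toxic units and nutrient
## summaries -> BIOENV variable selection and dbRDA with permutation
## tests. Two correction states are carried through, mirroring the
## analysis convention: community-level (Layman.B, ordination) uses the
## d15N-only corrected data; FFG-level SEAc/overlap comparisons use the
## doubly corrected data.

#' Configure a full pipeline run
#'
#' @param scenario a [scenario_config()] to simulate from, or `NULL` when
#'   `table` is supplied.
#' @param table a [sample_table()] of field data (ignored when `scenario`
#'   is given).
#' @param chem optional list with `chem`, `pesticides`, `endpoints` (as
#'   from [simulate_water_chemistry()]); simulated from the scenario when
#'   `NULL`.
#' @param states correction states to compute: subset of
#'   `c("d15N_only", "d15N_and_d13C")`.
#' @param maize_sites sites for the d13C correction.
#' @param grouping Bayesian grouping scheme, see [fit_group_ensembles()].
#' @param n_draws posterior draws per group.
#' @param seed master seed; all stage seeds derive from it.
#' @param min_n minimum samples per analyzed group.
#' @param overlap_p ellipse coverage for overlap.
#' @param env_vars environmental variables offered to BIOENV.
#' @param excluded_env variables excluded before the dbRDA (analyst
#'   choice; short-lived in-situ readings are conventionally dropped).
#' @param n_perm permutations for the ordination tests.
#' @param out_dir directory for CSV/JSON artifacts; `NULL` writes nothing.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(scenario = NULL, table = NULL, chem = NULL,
                            states = c("d15N_only", "d15N_and_d13C"),
                            maize_sites = "Pond 3",
                            grouping = "site_by_ffg",
                            n_draws = 2000L, seed = 1L, min_n = 3L,
                            overlap_p = 0.95,
                            env_vars = c("nutrient_sum", "n_detections",
                                         "tu_algae", "tu_invertebrate",
                                         "ec", "o2"),
                            excluded_env = c("ec", "o2"),
                            n_perm = 199L, out_dir = NULL) {
  states <- match.arg(states, c("d15N_only", "d15N_and_d13C"),
                      several.ok = TRUE)
  if (is.null(scenario) && is.null(table)) {
    stop("either a scenario or a sample table is required")
  }
  structure(list(scenario = scenario, table = table, chem = chem,
                 states = states, maize_sites = maize_sites,
                 grouping = grouping, n_draws = as.integer(n_draws),
                 seed = as.integer(seed), min_n = as.integer(min_n),
                 overlap_p = overlap_p, env_vars = env_vars,
                 excluded_env = excluded_env, n_perm = as.integer(n_perm),
                 out_dir = out_dir),
            class = "pipeline_config")
}

.pipeline_write <- function(obj, name, out_dir, manifest) {
  if (is.null(out_dir)) return(manifest)
  path <- file.path(out_dir, name)
  if (is.data.frame(obj) || is.matrix(obj)) {
    utils::write.csv(as.data.frame(obj), path, row.names = FALSE)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  }
  rbind(manifest, data.frame(artifact = name, path = path,
                             md5 = unname(tools::md5sum(path)),
                             stringsAsFactors = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order and returns all intermediate results
#' plus, when `out_dir` is set, a manifest of written artifacts with MD5
#' checksums. The run is deterministic under a fixed configuration seed.
#'
#' @param cfg a [pipeline_config()].
#' @return a `pipeline_result` list with elements `table`, `counts`,
#'   `corrected` (per state: `table` and reports), `layman` (per state),
#'   `bayes_layman`, `sea_by_ffg`, `overlap` (per state), `chem`,
#'   `water_summary`, `ordination` (`bioenv`, `dbrda`, `perm_model`,
#'   `perm_terms`, `perm_axes`) and `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  manifest <- data.frame(artifact = character(0), path = character(0),
                         md5 = character(0), stringsAsFactors = FALSE)
  if (!is.null(cfg$out_dir) && !dir.exists(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## data
  table <- stage("data", {
    if (!is.null(cfg$scenario)) simulate_isotope_dataset(cfg$scenario)
    else cfg$table
  })
  counts <- stage("counts", summarize_counts(table))
  manifest <- .pipeline_write(counts$per_group, "counts_per_group.csv",
                              cfg$out_dir, manifest)

  filtered <- stage("filter", filter_min_group_size(table, cfg$min_n))

  ## corrections
  corrected <- list()
  st_n <- stage("correct_d15N", correct_d15N_fertilizer(filtered))
  if ("d15N_only" %in% cfg$states) corrected[["d15N_only"]] <- st_n
  if ("d15N_and_d13C" %in% cfg$states) {
    maize <- intersect(cfg$maize_sites, unique(filtered$site_id))
    corrected[["d15N_and_d13C"]] <- if (length(maize)) {
      st_nc <- correct_d13C_maize(st_n$table, maize)
      list(table = st_nc$table,
           report = list(d15N = st_n$report, d13C = st_nc$report))
    } else {
      list(table = st_n$table, report = list(d15N = st_n$report))
    }
  }

  ## Layman metrics per state and community
  layman <- stage("layman", lapply(corrected, function(s) {
    layman_by_community(s$table, "wb_type")
  }))
  for (nm in names(layman)) {
    manifest <- .pipeline_write(layman[[nm]],
                                paste0("layman_", nm, ".csv"),
                                cfg$out_dir, manifest)
  }

  ## Bayesian niches on the d15N-only state (community comparisons)
  base_state <- if ("d15N_only" %in% names(corrected)) "d15N_only" else
    names(corrected)[1]
  fits <- stage("bayes", fit_group_ensembles(
    corrected[[base_state]]$table, grouping = cfg$grouping,
    n_draws = cfg$n_draws, seed = derive_seed(cfg$seed, "bayes"),
    min_n = cfg$min_n))
  blay <- stage("bayes_layman",
                bayes_layman(fits$ensembles, fits$communities))
  blay_modes <- do.call(rbind, lapply(blay, function(b) {
    data.frame(community = b$community, metric = names(b$modes),
               mode = unname(b$modes), stringsAsFactors = FALSE)
  }))
  manifest <- .pipeline_write(blay_modes, "bayes_layman_modes.csv",
                              cfg$out_dir, manifest)

  ## SEAc per (type, ffg) on the doubly corrected state when available
  sea_state <- if ("d15N_and_d13C" %in% names(corrected))
    "d15N_and_d13C" else base_state
  sea_tab <- stage("seac", {
    tb <- corrected[[sea_state]]$table
    key <- paste(tb$wb_type, tb$ffg, sep = ".")
    idx <- split(seq_len(nrow(tb)), key)
    idx <- idx[vapply(idx, length, 1L) >= max(3L, cfg$min_n)]
    do.call(rbind, lapply(names(idx), function(k) {
      i <- idx[[k]]
      data.frame(group = k, wb_type = tb$wb_type[i[1]], ffg = tb$ffg[i[1]],
                 n = length(i), sea_c = sea_c(tb$d13C[i], tb$d15N[i]),
                 stringsAsFactors = FALSE)
    }))
  })
  manifest <- .pipeline_write(sea_tab, "seac_by_group.csv",
                              cfg$out_dir, manifest)

  ## pond/ditch ellipse overlap per FFG, per correction state
  overlap <- stage("overlap", lapply(corrected, function(s) {
    ffg_overlap_table(s$table, p = cfg$overlap_p, min_n = cfg$min_n)
  }))
  if (length(overlap)) {
    wide <- Reduce(function(a, b) merge(a, b, by = "ffg", all = TRUE),
                   lapply(names(overlap), function(nm) {
                     out <- overlap[[nm]][c("ffg", "overlap_pct")]
                     names(out)[2] <- paste0("overlap_pct_", nm)
                     out
                   }))
    manifest <- .pipeline_write(wide, "overlap_by_ffg.csv",
                                cfg$out_dir, manifest)
  }

  ## water chemistry and toxic units
  chem <- stage("chemistry", {
    if (!is.null(cfg$chem)) cfg$chem
    else if (!is.null(cfg$scenario)) simulate_water_chemistry(cfg$scenario)
    else NULL
  })
  water_summary <- NULL
  ordination <- NULL
  if (!is.null(chem)) {
    water_summary <- stage("water_summary", water_summaries(chem$chem))
    manifest <- .pipeline_write(water_summary, "water_summary.csv",
                                cfg$out_dir, manifest)

    ## ordination: per-site Layman metrics vs environmental stressors
    ordination <- stage("ordination", {
      resp_tab <- corrected[[base_state]]$table
      mm <- site_metric_matrix(resp_tab)
      env_all <- chem$chem[match(rownames(mm), chem$chem$site_id), ,
                           drop = FALSE]
      offered <- intersect(cfg$env_vars, names(env_all))
      env <- zscore_env(as.matrix(env_all[offered]))
      rownames(env) <- rownames(mm)
      resp <- suppressWarnings(dissimilarity(mm, "mahalanobis"))
      be <- bioenv_search(env, resp)
      keep <- setdiff(offered, cfg$excluded_env)
      X <- env[, keep, drop = FALSE]
      fit <- dbrda_fit(resp, X)
      list(bioenv = be, dbrda = fit, constrained_vars = keep,
           perm_model = permutation_test(resp, X, cfg$n_perm,
                                         derive_seed(cfg$seed, "perm model"),
                                         "model"),
           perm_terms = permutation_test(resp, X, cfg$n_perm,
                                         derive_seed(cfg$seed, "perm terms"),
                                         "terms"),
           perm_axes = permutation_test(resp, X, cfg$n_perm,
                                        derive_seed(cfg$seed, "perm axes"),
                                        "axes"))
    })
    manifest <- .pipeline_write(ordination$bioenv$all_subsets,
                                "bioenv_subsets.csv", cfg$out_dir, manifest)
    manifest <- .pipeline_write(
      as.data.frame(ordination$dbrda$site_scores),
      "dbrda_site_scores.csv", cfg$out_dir, manifest)
    manifest <- .pipeline_write(ordination$perm_model,
                                "dbrda_perm_model.csv", cfg$out_dir,
                                manifest)
  }

  structure(list(table = table, counts = counts, corrected = corrected,
                 layman = layman, bayes_layman = blay,
                 sea_by_ffg = sea_tab, overlap = overlap, chem = chem,
                 water_summary = water_summary, ordination = ordination,
                 manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$counts)
  if (!is.null(x$water_summary)) {
    cat(" water summaries:\n")
    print(x$water_summary)
  }
  if (!is.null(x$ordination)) {
    cat(sprintf(" dbRDA first-axis share of constrained inertia: %.1f%%\n",
                100 * x$ordination$dbrda$prop_explained[1] /
                  x$ordination$dbrda$constrained_prop))
  }
  invisible(x)
}
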
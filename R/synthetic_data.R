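## Synthetic study generator. Emulates the statistical structure the
## analysis assumes -- per-(site x FFG) bivariate-normal isotope clouds, a
## ditch-wide d15N fertilizer offset, a single-pond d13C maize (C4)
## offset, and per-site water chemistry with Bernoulli pesticide
## detections -- with the ground truth attached so every estimator can be
## checked closed-loop.

#' Stable seed derivation
#'
#' Derives a child seed from a base seed and a string label so that each
#' (module, group) pair gets its own reproducible pseudo-random stream:
#' adding a site or group does not perturb the draws of the others. The
#' result is always in `[1, 2^31 - 2]`.
#'
#' @param seed integer base seed.
#' @param label character scalar.
#' @return derived integer seed.
#' @export
derive_seed <- function(seed, label) {
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.numeric(seed %% m)
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 31 + ch) %% m
  }
  as.integer((h * 48271) %% (m - 1) + 1)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Build a simulation scenario
#'
#' @param sites data frame with `site_id`, `wb_type`.
#' @param groups data frame with one row per (site, FFG) group:
#'   `site_id`, `ffg`, `mu_c`, `mu_n` (group mean d13C / d15N, permil),
#'   `var_c`, `cov_cn`, `var_n` (covariance entries, permil^2) and `n`
#'   (samples to draw; rows with `n = 0` are allowed and yield nothing).
#' @param fertilizer_offset permil added to d15N of every ditch group
#'   (the signal the fertilizer correction must remove).
#' @param maize_sites site ids receiving the maize d13C offset.
#' @param maize_offset permil added to d13C of `maize_sites`.
#' @param chem_spec optional water-chemistry spec, see
#'   [chem_spec_default()].
#' @param seed integer base seed.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(sites, groups, fertilizer_offset = 0,
                            maize_sites = character(0), maize_offset = 0,
                            chem_spec = NULL, seed = 1L) {
  stopifnot(all(c("site_id", "wb_type") %in% names(sites)),
            all(c("site_id", "ffg", "mu_c", "mu_n", "var_c", "cov_cn",
                  "var_n", "n") %in% names(groups)),
            all(groups$n >= 0), is.finite(fertilizer_offset),
            is.finite(maize_offset))
  if (!all(groups$site_id %in% sites$site_id)) stop("group site unknown")
  bad <- with(groups, var_c <= 0 | var_n <= 0 |
                var_c * var_n - cov_cn^2 <= 0)
  if (any(bad)) stop("non-SPD covariance in group(s): ",
                     paste(which(bad), collapse = ", "))
  structure(list(sites = sites, groups = groups,
                 fertilizer_offset = fertilizer_offset,
                 maize_sites = maize_sites, maize_offset = maize_offset,
                 chem_spec = chem_spec, seed = as.integer(seed)),
            class = "scenario_config")
}

#' Simulate an isotope sample table from a scenario
#'
#' Draws `n` bivariate-normal samples per (site, FFG) group at the group
#' mean plus the type/site offsets, using one stably derived stream per
#' group. The realized ground truth (per-group means, covariances and the
#' applied offsets) is attached as attribute `"truth"`.
#'
#' @param cfg a [scenario_config()].
#' @return a [sample_table()] with a `"truth"` attribute.
#' @export
simulate_isotope_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  type_of <- stats::setNames(cfg$sites$wb_type, cfg$sites$site_id)
  rows <- list()
  for (i in seq_len(nrow(cfg$groups))) {
    g <- cfg$groups[i, ]
    if (g$n == 0) next
    sigma <- matrix(c(g$var_c, g$cov_cn, g$cov_cn, g$var_n), 2)
    mu <- c(g$mu_c, g$mu_n)
    if (type_of[[g$site_id]] == "ditch") {
      mu[2] <- mu[2] + cfg$fertilizer_offset
    }
    if (g$site_id %in% cfg$maize_sites) {
      mu[1] <- mu[1] + cfg$maize_offset
    }
    pts <- .with_seed(
      derive_seed(cfg$seed, paste("iso", g$site_id, g$ffg)),
      MASS::mvrnorm(g$n, mu, sigma))
    pts <- matrix(pts, ncol = 2)
    rows[[i]] <- data.frame(
      sample_id = sprintf("%s.%s.%03d", g$site_id, g$ffg, seq_len(g$n)),
      site_id = g$site_id, wb_type = type_of[[g$site_id]], ffg = g$ffg,
      taxon = NA_character_, d13C = pts[, 1], d15N = pts[, 2],
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  if (is.null(df)) stop("scenario generated no samples")
  tab <- sample_table(df, provenance = sprintf(
    "simulated scenario (seed %d, fertilizer offset %.2f, maize offset %.2f)",
    cfg$seed, cfg$fertilizer_offset, cfg$maize_offset))
  attr(tab, "truth") <- list(
    groups = cfg$groups, fertilizer_offset = cfg$fertilizer_offset,
    maize_sites = cfg$maize_sites, maize_offset = cfg$maize_offset)
  tab
}

#' Default water-chemistry specification
#'
#' A substance panel with limits of quantification and acute endpoints,
#' per-site detection probabilities and nutrient levels. Defaults mirror
#' the structure of an agricultural pond/ditch survey: ditches carry more
#' detections and higher nutrient sums than ponds.
#'
#' @param sites data frame with `site_id`, `wb_type`.
#' @param n_substances size of the substance panel.
#' @param detection_prob named numeric vector (per site) of per-substance
#'   detection probabilities; defaults give expected detection counts of
#'   about 2.7 per pond and 6 per ditch.
#' @param nutrient_mean named numeric vector (per site) of expected
#'   NH4+ + NO3- sums (mg/L); defaults around 0.25 (ponds) and 1.15
#'   (ditches).
#' @param below_loq_prob probability that a detection falls below the LOQ
#'   (exercising the half-LOQ substitution).
#' @return a `chem_spec` list.
#' @export
chem_spec_default <- function(sites, n_substances = 12,
                              detection_prob = NULL, nutrient_mean = NULL,
                              below_loq_prob = 0.15) {
  is_pond <- sites$wb_type == "pond"
  if (is.null(detection_prob)) {
    detection_prob <- stats::setNames(
      ifelse(is_pond, 2.7, 6.0) / n_substances, sites$site_id)
  }
  if (is.null(nutrient_mean)) {
    nutrient_mean <- stats::setNames(ifelse(is_pond, 0.25, 1.15),
                                     sites$site_id)
  }
  substances <- data.frame(
    substance = sprintf("substance_%02d", seq_len(n_substances)),
    loq = rep(c(0.01, 0.02, 0.05), length.out = n_substances),
    ec50_invertebrate = 10^seq(0.5, 3.5, length.out = n_substances),
    ec50_algae = 10^seq(3.2, 0.8, length.out = n_substances),
    stringsAsFactors = FALSE)
  structure(list(substances = substances,
                 detection_prob = detection_prob,
                 nutrient_mean = nutrient_mean,
                 below_loq_prob = below_loq_prob),
            class = "chem_spec")
}

#' Simulate water chemistry for a scenario
#'
#' Per site: nutrient concentrations around the specified means, Bernoulli
#' pesticide detections with lognormal concentrations (a fraction placed
#' below the LOQ to exercise the half-LOQ rule), and the endpoint table
#' for both organism classes.
#'
#' @param cfg a [scenario_config()] whose `chem_spec` is set (or `NULL`
#'   to use [chem_spec_default()]).
#' @return list with `chem` (a [water_chemistry()] data frame),
#'   `pesticides` (long table), `endpoints`, and `truth` (the spec used).
#' @export
simulate_water_chemistry <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  spec <- cfg$chem_spec
  if (is.null(spec)) spec <- chem_spec_default(cfg$sites)
  subs <- spec$substances
  endpoints <- rbind(
    data.frame(substance = subs$substance, organism_class = "invertebrate",
               endpoint = subs$ec50_invertebrate,
               basis = "48 h EC50 Daphnia magna (synthetic)",
               stringsAsFactors = FALSE),
    data.frame(substance = subs$substance, organism_class = "algae",
               endpoint = subs$ec50_algae,
               basis = "72 h EC50 Raphidocelis subcapitata (synthetic)",
               stringsAsFactors = FALSE))
  pest <- list(); chem_rows <- list()
  for (i in seq_len(nrow(cfg$sites))) {
    s <- cfg$sites$site_id[i]
    res <- .with_seed(derive_seed(cfg$seed, paste("chem", s)), {
      p <- spec$detection_prob[[s]]
      hit <- stats::runif(nrow(subs)) < p
      conc <- numeric(nrow(subs))
      if (any(hit)) {
        sub_loq <- stats::runif(sum(hit)) < spec$below_loq_prob
        c_det <- stats::rlnorm(sum(hit), meanlog = log(0.1), sdlog = 1)
        c_det[sub_loq] <- stats::runif(sum(sub_loq)) * 0.9 *
          subs$loq[hit][sub_loq] + 1e-6
        c_det[!sub_loq] <- pmax(c_det[!sub_loq], subs$loq[hit][!sub_loq])
        conc[hit] <- c_det
      }
      nut <- spec$nutrient_mean[[s]] *
        stats::rlnorm(1, meanlog = -0.02, sdlog = 0.2)
      nh4 <- nut * stats::runif(1, 0.05, 0.4)
      list(conc = conc,
           nh4 = nh4, no3 = nut - nh4,
           temp = stats::runif(1, 6, 13), ec = stats::runif(1, 500, 1600),
           ph = stats::runif(1, 6, 8), o2 = stats::runif(1, 5, 14),
           no2 = 0, po4 = stats::runif(1, 0.02, 0.5))
    })
    pest[[s]] <- data.frame(site_id = s, substance = subs$substance,
                            conc = res$conc, loq = subs$loq,
                            stringsAsFactors = FALSE)
    chem_rows[[s]] <- data.frame(
      site_id = s, wb_type = cfg$sites$wb_type[i], temp = res$temp,
      ec = res$ec, ph = res$ph, o2 = res$o2, nh4 = res$nh4,
      no3 = res$no3, no2 = res$no2, po4 = res$po4,
      stringsAsFactors = FALSE)
  }
  pesticides <- do.call(rbind, pest)
  rownames(pesticides) <- NULL
  chem <- do.call(rbind, chem_rows)
  rownames(chem) <- NULL
  list(chem = water_chemistry(chem, pesticides, endpoints),
       pesticides = pesticides, endpoints = endpoints, truth = spec)
}

## Sample-count template of the emulated field survey: rows are the six
## FFGs, columns the three ponds and four ditches.
.survey_count_template <- function() {
  m <- matrix(c(
    0, 0, 0, 3, 0, 0, 9,      # collector_filterer
    13, 5, 3, 11, 10, 10, 10, # collector_gatherer
    37, 8, 11, 16, 14, 18, 16,# grazer_scraper
    15, 31, 22, 28, 23, 30, 25,# omnivore
    19, 19, 14, 38, 45, 26, 60,# predator
    24, 7, 0, 18, 21, 10, 12  # shredder
  ), nrow = 6, byrow = TRUE)
  dimnames(m) <- list(FFG_LEVELS,
                      c("Pond 1", "Pond 2", "Pond 3",
                        "Ditch 1", "Ditch 2", "Ditch 3", "Ditch 4"))
  m
}

#' Survey-like scenario preset
#'
#' A ready-made scenario emulating the design of a three-pond, four-ditch
#' field survey: the per-(site x FFG) sample numbers follow the survey's
#' count template, group means follow a trophic ladder in d15N (primary
#' consumers low, omnivores intermediate, predators high) with
#' FFG-specific d13C baselines and small site-level shifts, ditches carry
#' a fertilizer d15N offset, and one pond ("Pond 3") carries a maize d13C
#' offset.
#'
#' @param seed base seed.
#' @param fertilizer_offset d15N offset applied to ditches (permil).
#' @param maize_offset d13C offset applied to Pond 3 (permil).
#' @param n_per_group override every group size with a constant (e.g. 50
#'   for recovery tests); `NULL` keeps the survey template counts.
#' @param site_sd standard deviation (permil) of the random site-level
#'   mean shifts; set to 0 for closed-loop offset-recovery tests where the
#'   type-level offsets must be the only systematic differences.
#' @return a [scenario_config()] with a default chemistry spec.
#' @export
scenario_survey_like <- function(seed = 1L, fertilizer_offset = 3.5,
                                 maize_offset = 8, n_per_group = NULL,
                                 site_sd = 0.5) {
  counts <- .survey_count_template()
  sites <- data.frame(
    site_id = colnames(counts),
    wb_type = rep(c("pond", "ditch"), c(3, 4)),
    stringsAsFactors = FALSE)
  base_mu <- rbind(
    collector_filterer = c(-30.0, 6.0),
    collector_gatherer = c(-29.0, 6.5),
    grazer_scraper     = c(-28.0, 5.5),
    omnivore           = c(-28.5, 8.0),
    predator           = c(-28.0, 10.0),
    shredder           = c(-27.0, 5.0))
  site_shift <- .with_seed(derive_seed(seed, "site shifts"), {
    matrix(stats::rnorm(2 * nrow(sites), 0, site_sd), ncol = 2,
           dimnames = list(sites$site_id, NULL))
  })
  groups <- do.call(rbind, lapply(colnames(counts), function(s) {
    data.frame(site_id = s, ffg = rownames(counts),
               mu_c = base_mu[, 1] + site_shift[s, 1],
               mu_n = base_mu[, 2] + site_shift[s, 2],
               var_c = 2.0, cov_cn = 0.3, var_n = 1.0,
               n = if (is.null(n_per_group)) counts[, s] else n_per_group,
               stringsAsFactors = FALSE)
  }))
  rownames(groups) <- NULL
  scenario_config(sites, groups,
                  fertilizer_offset = fertilizer_offset,
                  maize_sites = "Pond 3", maize_offset = maize_offset,
                  chem_spec = chem_spec_default(sites), seed = seed)
}
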
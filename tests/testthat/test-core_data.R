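test_that("read_isotope_table round-trips a well-formed CSV and normalizes labels", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "Sample_ID,Site,Type,FFG,Taxon,delta13C,delta15N",
    "a1,Pond 1,pond,Predator,Dytiscidae,-28.1,9.5",
    "a2,Pond 1,pond,grazer/scraper,Lymnaeidae,-27.0,5.2",
    "a3,Ditch 1,ditch,Collector-Gatherer,Cloeon,-29.4,6.8"
  ), path)
  tab <- read_isotope_table(path)
  expect_s3_class(tab, "sample_table")
  expect_equal(nrow(tab), 3)
  expect_setequal(tab$ffg, c("predator", "grazer_scraper",
                             "collector_gatherer"))
  expect_equal(tab$d13C, c(-28.1, -27.0, -29.4))
})

test_that("invalid rows are rejected with row-level diagnostics", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,site_id,wb_type,ffg,taxon,d13C,d15N",
    "a1,Pond 1,pond,predator,x,-28.1,9.5",
    "a2,Pond 1,pond,weird_guild,x,-27.0,5.2",
    "a3,Pond 1,pond,shredder,x,NA,6.8"
  ), path)
  expect_warning(tab <- read_isotope_table(path), "rejected")
  expect_equal(nrow(tab), 1)
  expect_length(attr(tab, "rejected"), 2)
  expect_match(attr(tab, "rejected")[1], "a2")
})

test_that("missing columns and empty tables are fatal", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,site_id,ffg,d13C,d15N",
               "a1,Pond 1,predator,-28,9"), path)
  expect_error(read_isotope_table(path), "wb_type")
})

test_that("sample_table validation enforces its invariants", {
  df <- data.frame(sample_id = c("a", "a"), site_id = "P1", wb_type = "pond",
                   ffg = "predator", d13C = -28, d15N = 9)
  expect_error(sample_table(df), "duplicate")
  df2 <- data.frame(sample_id = c("a", "b"), site_id = "P1",
                    wb_type = c("pond", "ditch"), ffg = "predator",
                    d13C = -28, d15N = 9)
  expect_error(sample_table(df2), "inconsistent")
  df3 <- data.frame(sample_id = "a", site_id = "P1", wb_type = "pond",
                    ffg = "predator", d13C = Inf, d15N = 9)
  expect_error(sample_table(df3), "finite")
})

test_that("summarize_counts is permutation-invariant and conserves totals", {
  sc <- scenario_survey_like(seed = 5)
  tab <- simulate_isotope_dataset(sc)
  cs <- summarize_counts(tab)
  perm <- sample_table(as.data.frame(tab)[sample.int(nrow(tab)), ])
  cs_perm <- summarize_counts(perm)
  expect_equal(cs_perm$per_type_total, cs$per_type_total)
  expect_equal(cs_perm$per_group, cs$per_group)
  ## conservation: per-type FFG sums equal the type totals
  for (tp in names(cs$per_type_total)) {
    expect_equal(sum(cs$per_type_ffg$n[cs$per_type_ffg$wb_type == tp]),
                 unname(cs$per_type_total[tp]))
  }
  ## mean per site x n sites = total
  expect_equal(cs$per_type_mean_per_site * cs$n_sites,
               as.numeric(cs$per_type_total) |>
                 setNames(names(cs$per_type_total)))
})

test_that("a single-sample table gives unit counts", {
  tab <- make_table(-28, 9, "Pond 1", "pond", "predator")
  cs <- summarize_counts(tab)
  expect_equal(unname(cs$per_type_total["pond"]), 1L)
  expect_equal(unname(cs$per_type_mean_per_site["pond"]), 1.0)
})

test_that("wide counts tables and per-sample tables agree", {
  sc <- scenario_survey_like(seed = 9)
  tab <- simulate_isotope_dataset(sc)
  cs <- summarize_counts(tab)
  wide <- do.call(data.frame, c(list(ffg = FFG_LEVELS, check.names = FALSE),
    lapply(sort(unique(tab$site_id)), function(s) {
      vapply(FFG_LEVELS, function(f) {
        sum(tab$site_id == s & tab$ffg == f)
      }, numeric(1))
    })))
  names(wide)[-1] <- sort(unique(tab$site_id))
  tm <- setNames(rep(c("ditch", "pond"), c(4, 3)), names(wide)[-1])
  cs2 <- counts_summary_from_wide(wide, tm)
  expect_equal(cs2$per_type_total[sort(names(cs2$per_type_total))],
               cs$per_type_total[sort(names(cs$per_type_total))])
  expect_equal(ffg_subset_mean(cs2), ffg_subset_mean(cs))
})

test_that("filter_min_group_size drops small groups, strictly below min_n", {
  tab <- make_table(
    d13C = rnorm(15, -28), d15N = rnorm(15, 8),
    site_id = "Pond 1", wb_type = "pond",
    ffg = rep(c("predator", "shredder", "omnivore"), c(2, 3, 10)))
  out <- filter_min_group_size(tab, 3)
  expect_setequal(unique(out$ffg), c("shredder", "omnivore"))
  expect_equal(attr(out, "dropped_groups")$ffg, "predator")
  ## n = 3 retained (boundary is strict <)
  expect_true("shredder" %in% out$ffg)
  ## idempotence
  out2 <- filter_min_group_size(out, 3)
  expect_equal(plain(out2), plain(out))
  ## min_n = 1 is the identity
  expect_equal(plain(filter_min_group_size(tab, 1)), plain(tab))
  expect_error(filter_min_group_size(tab, 100), "fewer than")
})
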
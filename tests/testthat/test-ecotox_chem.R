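simple_endpoints <- data.frame(
  substance = c("atrazine", "atrazine", "lindane"),
  organism_class = c("invertebrate", "invertebrate", "invertebrate"),
  endpoint = c(100, 250, 1),
  basis = "48 h EC50 Daphnia magna")

test_that("TU_sum closed forms hold", {
  ## one substance at its EC50: log10(1) = 0
  m1 <- data.frame(substance = "lindane", conc = 1, loq = 0.01)
  expect_equal(tu_sum(m1, simple_endpoints, "invertebrate"), 0)
  ## two substances each contributing 0.5
  ep <- data.frame(substance = c("a", "b"), organism_class = "invertebrate",
                   endpoint = c(2, 4))
  m2 <- data.frame(substance = c("a", "b"), conc = c(1, 2), loq = 0.01)
  expect_equal(tu_sum(m2, ep, "invertebrate"), 0)
  ## tiny ratio: log10(1e-4) = -4
  m3 <- data.frame(substance = "atrazine", conc = 0.01, loq = 0.001)
  expect_equal(tu_sum(m3, simple_endpoints, "invertebrate"), -4)
})

test_that("sub-LOQ detections are substituted at half the LOQ", {
  m <- data.frame(substance = "lindane", conc = 0.005, loq = 0.02)
  expect_equal(tu_sum(m, simple_endpoints, "invertebrate"), log10(0.01 / 1))
})

test_that("the most sensitive endpoint per substance is used", {
  ## atrazine has endpoints 100 and 250; the minimum (100) applies
  m <- data.frame(substance = "atrazine", conc = 100, loq = 0.01)
  expect_equal(tu_sum(m, simple_endpoints, "invertebrate"), 0)
})

test_that("no detections yield the sentinel, missing endpoints are fatal", {
  m0 <- data.frame(substance = "lindane", conc = 0, loq = 0.01)
  out <- tu_sum(m0, simple_endpoints, "invertebrate")
  expect_true(is.na(out))
  expect_true(attr(out, "no_detection"))
  m1 <- data.frame(substance = "mystery", conc = 1, loq = 0.01)
  expect_error(tu_sum(m1, simple_endpoints, "invertebrate"), "mystery")
})

test_that("TU_sum is monotone in concentrations and added substances", {
  set.seed(15)
  ep <- data.frame(substance = letters[1:5], organism_class = "invertebrate",
                   endpoint = runif(5, 1, 100))
  for (rep in 1:10) {
    conc <- runif(5, 0.01, 10)
    m <- data.frame(substance = letters[1:5], conc = conc, loq = 0.001)
    base <- tu_sum(m, ep, "invertebrate")
    ## increasing one concentration increases the score
    m_up <- m; m_up$conc[2] <- m_up$conc[2] * 2
    expect_gt(tu_sum(m_up, ep, "invertebrate"), base)
    ## dropping a substance decreases it
    expect_lt(tu_sum(m[-1, ], ep, "invertebrate"), base)
  }
})

test_that("splitting a concentration across duplicate rows leaves TU_sum unchanged", {
  ep <- data.frame(substance = "a", organism_class = "invertebrate",
                   endpoint = 10)
  whole <- data.frame(substance = "a", conc = 4, loq = 0.001)
  split2 <- data.frame(substance = c("a", "a"), conc = c(1.5, 2.5),
                       loq = 0.001)
  expect_equal(tu_sum(whole, ep, "invertebrate"),
               tu_sum(split2, ep, "invertebrate"))
})

survey_chem <- function() {
  path <- system.file("extdata", "water_chemistry_survey.csv",
                      package = "swbniche")
  water_chemistry(read_chemistry_csv(path))
}

test_that("nutrient sums reproduce the published NH4+NO3 column for all 7 sites", {
  chem <- survey_chem()
  expect_equal(chem$nutrient_sum,
               c(0.21, 0.23, 0.31, 1.96, 0.80, 0.44, 1.40))
})

test_that("per-type water summaries match the published means", {
  ws <- water_summaries(survey_chem())
  pond <- ws[ws$wb_type == "pond", ]
  ditch <- ws[ws$wb_type == "ditch", ]
  expect_equal(pond$nutrient_mean, 0.25)
  expect_equal(round(pond$nutrient_sd, 2), 0.05)
  expect_equal(ditch$nutrient_mean, 1.15)
  expect_equal(ditch$detections_mean, 6.0)
  expect_equal(round(ditch$detections_sd, 1), 1.4)
  expect_equal(round(pond$detections_mean, 1), 2.7)
  expect_equal(round(pond$detections_sd, 1), 1.5)
})

test_that("a single-site type reports an undefined SD", {
  chem <- data.frame(site_id = c("P1", "D1", "D2"),
                     wb_type = c("pond", "ditch", "ditch"),
                     nh4 = c(0.1, 0.2, 0.3), no3 = c(0.2, 0.5, 0.6),
                     n_detections = c(1L, 2L, 3L))
  chem <- water_chemistry(chem)
  ws <- water_summaries(chem)
  expect_true(is.na(ws$nutrient_sd[ws$wb_type == "pond"]))
  expect_false(is.na(ws$nutrient_sd[ws$wb_type == "ditch"]))
})
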
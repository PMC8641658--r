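test_that("read/write round-trips a cohort losslessly", {
  labs <- list(P1 = normal_labs(1:10),
               P2 = make_labs(list(AST = exp(seq(7, 4, length.out = 7)),
                                   ALT = 900, TBIL = 3.21, INR = 1.37,
                                   PLT = 88.5), 1:7))
  co <- make_cohort(labs)
  lp <- withr::local_tempfile(fileext = ".csv")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, lp, cp)
  co2 <- read_cohort(lp, cp)
  expect_equal(n_patients(co2), 2L)
  o <- function(df) df[do.call(order, df), sort(names(df))]
  expect_equal(o(co2$labs), o(co$labs), ignore_attr = TRUE)
  expect_equal(o(co2$outcomes), o(co$outcomes), ignore_attr = TRUE)
  # second round trip is byte-identical
  lp2 <- withr::local_tempfile(fileext = ".csv")
  cp2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co2, lp2, cp2)
  expect_identical(readLines(lp2), readLines(lp))
})

test_that("TBIL in umol/L is converted to mg/dL on ingest", {
  lp <- withr::local_tempfile(fileext = ".csv")
  cp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,pod,analyte,value,unit",
               "P1,7,TBIL,171.04,umol/L",
               "P1,7,INR,1.2,"), lp)
  writeLines(paste0("patient_id,meld,follow_up_days,death,death_day,",
                    "retransplant,retransplant_day\n",
                    "P1,12,400,0,,0,"), cp)
  co <- read_cohort(lp, cp)
  tbil <- co$labs$value[co$labs$analyte == "TBIL"]
  expect_equal(tbil, 10.0, tolerance = 1e-12)
})

test_that("invalid labs are rejected with patient and POD named", {
  labs <- data.frame(patient_id = "P9", pod = 4, analyte = "PLT", value = 0)
  expect_error(
    new_cohort(labs, make_clinical("P9"), make_outcomes("P9")),
    "non-positive PLT.*P9.*POD 4")
  dup <- data.frame(patient_id = "P9", pod = c(2, 2), analyte = "AST",
                    value = c(10, 20))
  expect_error(
    new_cohort(dup, make_clinical("P9"), make_outcomes("P9")),
    "duplicate observation.*P9.*AST.*POD 2")
  unk <- data.frame(patient_id = "P9", pod = 1, analyte = "GGT", value = 5)
  expect_error(
    new_cohort(unk, make_clinical("P9"), make_outcomes("P9")),
    "unknown analyte")
})

test_that("apply_exclusions tallies once per patient in printed order", {
  n <- 20
  ids <- sprintf("P%02d", 1:n)
  labs <- setNames(replicate(n, normal_labs(1:10), simplify = FALSE), ids)
  clinical <- do.call(rbind, lapply(ids, make_clinical))
  clinical$excl_age_lt18 <- c(rep(TRUE, 3), rep(FALSE, n - 3))
  # P4 flagged for both retransplantation and split: retransplantation wins
  clinical$excl_retransplantation <- ids == "P04"
  clinical$excl_split <- ids == "P04"
  co <- new_cohort(do.call(rbind, lapply(ids, function(id)
    cbind(patient_id = id, labs[[id]]))), clinical,
    do.call(rbind, lapply(ids, make_outcomes)))

  ex <- apply_exclusions(co)
  expect_equal(unname(ex$tally[c("age_lt18", "retransplantation", "split")]),
               c(3L, 1L, 0L))
  expect_equal(n_patients(ex$cohort), n - 4L)
  expect_equal(sum(ex$tally), n - n_patients(ex$cohort))
  # idempotent
  ex2 <- apply_exclusions(ex$cohort)
  expect_equal(sum(ex2$tally), 0L)
  expect_equal(n_patients(ex2$cohort), n_patients(ex$cohort))
})

test_that("clean cohorts pass the filter untouched; sparse labs do not", {
  co <- make_cohort(list(A = normal_labs(1:10), B = normal_labs(1:7)))
  ex <- apply_exclusions(co)
  expect_equal(sum(ex$tally), 0L)
  # a patient with POD 1-2 labs only cannot support any 7-day score
  co2 <- make_cohort(list(A = normal_labs(1:10), B = normal_labs(1:2)))
  ex2 <- apply_exclusions(co2)
  expect_equal(unname(ex2$tally[["insufficient_labs"]]), 1L)
  expect_equal(ex2$cohort$clinical$patient_id, "A")
})
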
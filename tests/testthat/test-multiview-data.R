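test_that("harm scores binarize at the severe cutoff and validate range", {
  expect_identical(harm_to_label(c(1L, 5L, 6L, 9L)), c(0L, 0L, 1L, 1L))
  expect_error(harm_to_label(0L, case_id = "x9"), "x9")
  expect_error(harm_to_label(10L), "1-9")
  expect_error(harm_to_label(5.5), "1-9")
})

test_that("view matrices enforce alignment and finite available rows", {
  expect_error(view_matrix("v", cbind(a = 1:3), c(TRUE, FALSE)), "mask length")
  expect_error(view_matrix("v", cbind(a = c(1, NA)), c(TRUE, TRUE)), "non-finite")
  v <- view_matrix("v", cbind(a = c(1, 99)), c(TRUE, FALSE))
  expect_true(is.na(v$values[2, 1]))  # unavailable rows carry no values
  expect_error(
    multiview_dataset(c("a", "a"), c(0, 1), list(v)), "duplicate case ids")
  expect_error(
    multiview_dataset(c("a", "b"), c(0, 1), list(v), harm_scores = c(0L, 7L)),
    "harm score out of range")
})

test_that("demographic encoding standardizes age and is local in sex", {
  rec <- toy_records()
  enc <- fit_demographics_encoder(rec)
  vm <- encode(enc, rec)
  # age equal to the fitting mean maps to 0
  rec2 <- rec; rec2$age <- rep(mean(rec$age), 4)
  expect_equal(unname(encode(enc, rec2)$values[, "age_z"]), rep(0, 4))
  # two records differing only in sex differ only in the sex indicator
  rec3 <- rec[c(1, 1), ]; rec3$sex <- c("female", "male")
  rows <- encode(enc, rec3)$values
  diffcols <- which(rows[1, ] != rows[2, ])
  expect_identical(colnames(rows)[diffcols], "sex_female")
  # unseen race maps to other_unknown with a warning
  rec4 <- rec; rec4$race[1] <- "martian"
  expect_warning(vm4 <- encode(enc, rec4), "other_unknown")
  expect_equal(unname(vm4$values[1, "race_other_unknown"]), 1)
  expect_true(all(vm$available))
})

test_that("diagnosis codes collapse to category stems and deduplicate", {
  rec <- toy_records()
  enc <- fit_diagnosis_encoder(rec)
  vm <- encode(enc, rec)
  # 428.0 and 428.21 collapse to one indicator set once
  expect_equal(unname(vm$values[1, "dx_428"]), 1)
  expect_identical(sort(colnames(vm$values)),
                   sort(paste0("dx_", c("250", "401", "428"))))
  # empty diagnosis list encodes as an all-zero available row
  expect_equal(sum(vm$values[3, ]), 0)
  expect_true(vm$available[3])
  expect_error(fit_diagnosis_encoder(rec[0, ]), "empty")
  # codes that cannot be collapsed are kept verbatim with a warning
  rec5 <- rec; rec5$diagnosis_codes[[2]] <- c("42")
  expect_warning(enc5 <- fit_diagnosis_encoder(rec5), "verbatim")
  expect_true("42" %in% enc5$categories)
})

test_that("procedure availability follows the any-code rule", {
  rec <- toy_records()
  vm <- encode(fit_procedure_encoder(rec), rec)
  expect_identical(vm$available, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unname(vm$values[3, c("px_C0010", "px_C0020")]), c(1, 1))
  # config switch: absence as an observed zero row
  vm2 <- encode(fit_procedure_encoder(rec, absent_as_missing = FALSE), rec)
  expect_true(all(vm2$available))
  expect_equal(sum(vm2$values[2, ]), 0)
})

test_that("bone-density views are available iff the measurement exists", {
  rec <- toy_records()
  vf <- encode(fit_bone_density_encoder(rec, "forearm"), rec)
  expect_identical(vf$available, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(unname(vf$values[2, ]), c(0.5, -1.2))
  bad <- rec; bad$bd_forearm[[2]] <- c(bmd = -1, t_score = 0)
  expect_error(validate_records(bad), "bmd > 0")
})

test_that("encoders are fit/transform separable and permutation equivariant", {
  co <- generate_cohort(scenario("all_view_signal", n_cases = 120), seed = 9)
  enc <- encode_cohort(co$records)
  # transforming the fitting cohort reproduces the fit output
  again <- apply_encoders(enc$encoders, co$records)
  expect_equal(again$views, enc$dataset$views)
  # permuting records permutes rows identically
  perm <- sample(nrow(co$records))
  permuted <- apply_encoders(enc$encoders, co$records[perm, ])
  for (vn in names(enc$dataset$views)) {
    expect_identical(permuted$views[[vn]]$values,
                     enc$dataset$views[[vn]]$values[perm, , drop = FALSE],
                     info = vn)
    expect_identical(permuted$views[[vn]]$available,
                     enc$dataset$views[[vn]]$available[perm])
  }
})

test_that("cohorts round-trip through save/load exactly", {
  co <- generate_cohort(scenario("table1_like", n_cases = 80), seed = 4)
  dir <- withr::local_tempdir()
  save_cohort(co$dataset, dir)
  back <- load_cohort(dir)
  expect_equal(back, co$dataset)

  # missing canonical view file -> explicit error naming the view
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  man$views$bd_forearm <- NULL
  yaml::write_yaml(man, file.path(dir, "manifest.yaml"))
  expect_error(load_cohort(dir), "bd_forearm")
})

test_that("cohort loading validates harm range and id alignment", {
  co <- generate_cohort(scenario("table1_like", n_cases = 30), seed = 4)
  dir <- withr::local_tempdir()
  save_cohort(co$dataset, dir)
  labs <- utils::read.csv(file.path(dir, "labels.csv"))
  labs$harm_score[2] <- 0
  utils::write.csv(labs, file.path(dir, "labels.csv"), row.names = FALSE)
  expect_error(load_cohort(dir), "harm score")

  save_cohort(co$dataset, dir)
  vw <- utils::read.csv(file.path(dir, "view_procedures.csv"), check.names = FALSE)
  vw$case_id[1] <- "rogue"
  utils::write.csv(vw, file.path(dir, "view_procedures.csv"), row.names = FALSE)
  expect_error(load_cohort(dir), "misaligned")
})

test_that("stratified splits preserve both classes and partition cases", {
  co <- generate_cohort(scenario("table1_like", n_cases = 200), seed = 2)
  sp <- train_test_split(co$dataset, 0.25, seed = 3)
  expect_setequal(c(sp$train$case_ids, sp$test$case_ids), co$dataset$case_ids)
  expect_gt(mean(sp$test$labels), 0)
  expect_gt(mean(sp$train$labels), 0)
})
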
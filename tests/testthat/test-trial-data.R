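test_that("well-formed trial CSVs parse to identical records (round trip)", {
  trials <- dplyr::bind_rows(
    ref_trial_row("g1"),
    ref_trial_row("g2", n_planted = 50L, n_germinated = 0L, depth_cm = 21,
                  provenance = "LocB", temperature = "25C", media = "sand",
                  pretreated = "yes", photoperiod = "0L/24D"),
    ref_trial_row("g3", n_planted = 1L, n_germinated = 1L, depth_cm = 0,
                  provenance = "Greenhouse")
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(validate_trials(trials), path)
  back <- read_trials(path)
  expect_equal(nrow(back), 3)
  expect_equal(back[, names(trials)], validate_trials(trials)[, names(trials)])

  # generator output survives the same round trip
  sim <- simulate_trials(study_preset(), seed = 2)$trials
  write_trials(sim, path)
  expect_equal(read_trials(path), sim)
})

test_that("validation fails fast with informative errors", {
  bad_count <- ref_trial_row(n_planted = 3L, n_germinated = 5L)
  expect_error(validate_trials(bad_count), "row 1.*exceeds n_planted")

  bad_level <- ref_trial_row(media = "vermiculite")
  expect_error(validate_trials(bad_level), "unknown media level")

  missing_col <- ref_trial_row()[, -2]
  expect_error(validate_trials(missing_col), "n_planted")

  # permissive mode drops, keeps the good row
  both <- dplyr::bind_rows(ref_trial_row("ok"), bad_count)
  expect_warning(kept <- validate_trials(both, permissive = TRUE),
                 "dropping")
  expect_equal(kept$group_id, "ok")
})

test_that("packaged decade-by-location table reproduces its printed totals", {
  t2 <- load_table2()
  expect_equal(sum(t2$planted), 10588L)
  by_loc <- tapply(t2$planted, t2$location, sum)
  expect_equal(as.vector(by_loc["1"]), 3644L)
  expect_equal(as.vector(by_loc[c("2", "3", "10")]), c(2871L, 208L, 1044L))
  expect_equal(as.vector(by_loc["Greenhouse"]), 62L)
  expect_true(all(t2$germinated <= t2$planted))

  # shares quoted for the study: origin marsh 34.4%, the four
  # research-center locations 73.4%
  expect_equal(100 * by_loc[["1"]] / sum(t2$planted), 34.4, tolerance = 0.002)
  serc <- sum(by_loc[c("1", "2", "3", "10")])
  expect_equal(100 * serc / sum(t2$planted), 73.4, tolerance = 0.002)
})

test_that("design matrix uses reference-level dummy coding", {
  at_ref <- validate_trials(ref_trial_row())
  d <- build_design(at_ref)
  expect_equal(ncol(d$X), 8)
  expect_true(all(d$X == 0))

  one_off <- validate_trials(ref_trial_row(media = "sand"))
  d2 <- build_design(one_off)
  expect_equal(sum(d2$X), 1)
  expect_equal(unname(d2$X[1, "media:sand"]), 1)

  expect_error(build_design(at_ref, c(temperature = "40C",
                                      media = "sand_soil",
                                      pretreated = "no",
                                      photoperiod = "12L/12D")),
               "not a declared level")
})

test_that("the full factorial design has full column rank and 0/1 block sums", {
  lv <- trial_levels()
  grid <- expand.grid(temperature = lv$temperature, media = lv$media,
                      pretreated = lv$pretreated,
                      photoperiod = lv$photoperiod,
                      stringsAsFactors = FALSE)
  trials <- dplyr::bind_rows(lapply(seq_len(nrow(grid)), function(i) {
    ref_trial_row(paste0("g", i), temperature = grid$temperature[i],
                  media = grid$media[i], pretreated = grid$pretreated[i],
                  photoperiod = grid$photoperiod[i])
  }))
  d <- build_design(trials)
  expect_equal(qr(cbind(1, d$X))$rank, 1 + 8)

  blocks <- split(colnames(d$X), sub(":.*", "", colnames(d$X)))
  for (cols in blocks) {
    expect_true(all(rowSums(d$X[, cols, drop = FALSE]) %in% c(0, 1)))
  }
})

test_that("depth slices index 2-cm intervals with a surface anchor", {
  expect_equal(depth_interval_id(c(0, 1, 1.9, 2, 3, 20)),
               c(1L, 1L, 1L, 1L, 2L, 10L))
  expect_error(depth_interval_id(-1))
})
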
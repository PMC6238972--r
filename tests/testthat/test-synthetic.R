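# Small dimensions keep these fast; the full-scale stated world (62 regions,
# 450 volumes, n = 8) is exercised in test-acceptance.R.

test_that("cohort spec validates its invariants", {
  expect_s3_class(cohort_spec(), "cohort_spec")
  expect_error(cohort_spec(n_per_group = 1), class = "chemoconn_invalid_spec")
  expect_error(cohort_spec(n_regions = 3), class = "chemoconn_invalid_spec")
  expect_error(cohort_spec(rescue_fraction = 1.2),
               class = "chemoconn_invalid_spec")
  expect_error(cohort_spec(groups = c("A", "A")),
               class = "chemoconn_invalid_spec")
  expect_error(cohort_spec(seed = 1.5), class = "chemoconn_invalid_spec")
})

test_that("identical specs give identical cohorts and leave the caller's RNG alone", {
  sp <- cohort_spec(n_per_group = 2, groups = c("PBS", "Cisplatin"),
                    n_regions = 10, n_timepoints = 60, seed = 4)
  set.seed(1); before <- runif(1)
  set.seed(1)
  c1 <- generate_cohort(sp)
  after <- runif(1)
  c2 <- generate_cohort(sp)
  expect_identical(c1$timeseries[[1]]$data, c2$timeseries[[1]]$data)
  expect_identical(c1$behavior, c2$behavior)
  expect_identical(c1$assays, c2$assays)
  expect_identical(before, after)   # generator restores RNG state
})

test_that("zero injected effect means one shared latent structure", {
  sp <- cohort_spec(n_per_group = 2, n_regions = 12, n_timepoints = 50,
                    path_length_effect = 0, seed = 8)
  gt <- generate_timeseries(sp)$ground_truth
  for (g in c("Cisplatin", "MSC", "Cisplatin+MSC"))
    expect_identical(gt$groups[[g]]$R, gt$groups[["PBS"]]$R)
})

test_that("full rescue reproduces the control structure exactly", {
  sp <- cohort_spec(n_per_group = 2, n_regions = 16, n_timepoints = 60,
                    path_length_effect = 0.15, rescue_fraction = 1, seed = 5)
  gt <- generate_timeseries(sp)$ground_truth
  expect_identical(gt$groups[["Cisplatin+MSC"]]$R, gt$groups[["PBS"]]$R)
  expect_lt(gt$expected_measured_L["Cisplatin"],
            gt$expected_measured_L["PBS"])
})

test_that("behavioral tables respect their constraints", {
  sp <- cohort_spec(n_per_group = 3, n_regions = 8, n_timepoints = 40,
                    seed = 2)
  beh <- generate_behavior(sp)
  expect_equal(nrow(beh$pbt), 3 * 4 * 11)
  expect_true(all(beh$pbt$escape_time >= 0))
  sched <- pbt_schedule()
  one <- beh$pbt[beh$pbt$subject_id == beh$pbt$subject_id[1], ]
  expect_equal(one$difficulty, sched$difficulty)
  expect_true(all(beh$noprt$t_novel >= 0 & beh$noprt$t_familiar >= 0))
  for (s in beh$ymaze$entries) {
    e <- strsplit(s, "")[[1]]
    expect_true(all(e %in% c("A", "B", "C")))
    expect_true(all(e[-1] != e[-length(e)]))   # no immediate self-reentry
  }
})

test_that("cisplatin discrimination index is centered at zero, controls above", {
  sp <- cohort_spec(n_per_group = 60, n_regions = 8, n_timepoints = 40,
                    groups = c("PBS", "Cisplatin"), seed = 10)
  beh <- generate_behavior(sp)
  di <- discrimination_index(beh$noprt$t_novel, beh$noprt$t_familiar)
  di_cis <- di[beh$noprt$group == "Cisplatin"]
  di_pbs <- di[beh$noprt$group == "PBS"]
  expect_equal(mean(di_cis), 0, tolerance = 0.07)   # ~2 SE at n = 60
  expect_gt(mean(di_pbs), 0.15)
})

test_that("assay tables carry the stated group structure", {
  sp <- cohort_spec(n_per_group = 6, groups = c("PBS", "Cisplatin"),
                    n_regions = 8, n_timepoints = 40, seed = 12)
  as <- generate_assays(sp)

  # rotenone/antimycin plateau is the minimum phase mean for every subject
  for (sid in unique(as$ocr$subject_id)) {
    tr <- as$ocr[as$ocr$subject_id == sid, ]
    pm <- tapply(tr$ocr, tr$phase, mean)
    expect_equal(names(which.min(pm)), "rot_aa")
  }

  # basal comparable, maximal reduced under cisplatin
  rm <- do.call(rbind, lapply(unique(as$ocr$subject_id), function(sid) {
    tr <- as$ocr[as$ocr$subject_id == sid, ]
    m <- respiratory_metrics(tr)
    data.frame(group = tr$group[1], basal = m$basal, max = m$max)
  }))
  b_gap <- abs(mean(rm$basal[rm$group == "Cisplatin"]) -
                 mean(rm$basal[rm$group == "PBS"]))
  expect_lt(b_gap, 6)   # within noise (sd 3, n = 6/group)
  expect_lt(mean(rm$max[rm$group == "Cisplatin"]) + 20,
            mean(rm$max[rm$group == "PBS"]))

  # atypia rate elevated under cisplatin
  pa <- sapply(split(as$mito, as$mito$group), function(d)
    classify_mitochondria(d)$percent_atypical)
  expect_gt(pa[["Cisplatin"]], pa[["PBS"]] + 10)

  # tumors grow, cisplatin delays growth
  tv <- tumor_volume(as$tumor$d1, as$tumor$d2, as$tumor$d3)
  last <- as$tumor$day == max(as$tumor$day)
  expect_gt(mean(tv[last & as$tumor$group == "PBS"]),
            mean(tv[last & as$tumor$group == "Cisplatin"]))
  first_day <- min(as$tumor$day)
  expect_gt(mean(tv[last]), mean(tv[as$tumor$day == first_day]))
})

test_that("injected DE reversal counts are recovered exactly by the classifier", {
  sp <- cohort_spec(n_per_group = 2, n_regions = 8, n_timepoints = 40,
                    seed = 3)
  as <- generate_assays(sp, n_up_reversed = 7, n_down_reversed = 4,
                        n_same_direction = 5, n_cis_only = 10,
                        n_msc_only = 12, n_null = 20)
  res <- de_reversal_sets(as$de_cis, as$de_msc)
  expect_equal(unname(res$counts["overlap"]), 16)
  expect_equal(unname(res$counts["up_reversed"]), 7)
  expect_equal(unname(res$counts["down_reversed"]), 4)
  expect_equal(unname(res$counts["same_direction"]), 5)
})

test_that("cohort files round-trip through plain text", {
  sp <- cohort_spec(n_per_group = 2, groups = c("PBS", "Cisplatin"),
                    n_regions = 6, n_timepoints = 30, seed = 9)
  co <- generate_cohort(sp, n_cis_only = 5, n_msc_only = 5, n_null = 5,
                        n_up_reversed = 2, n_down_reversed = 2,
                        n_same_direction = 1)
  dir <- tempfile("cohort")
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  expect_true(file.exists(file.path(dir, "behavior", "pbt.tsv")))
  expect_true(file.exists(file.path(dir, "assays", "de_cis.tsv")))
  ts_files <- list.files(file.path(dir, "timeseries"), full.names = TRUE)
  expect_length(ts_files, 4L)
  back <- read_region_ts(ts_files[1], "PBS_01", "PBS", sp$tr_seconds)
  orig <- co$timeseries[[sub("[.]tsv$", "", basename(ts_files[1]))]]
  expect_equal(back$data, orig$data, tolerance = 1e-12, ignore_attr = TRUE)
  unlink(dir, recursive = TRUE)
})

test_that("increasing the injected effect strictly lowers measured cisplatin path length", {
  # module-scale check on the expected measured path length target
  for (seed in c(1, 2)) {
    Ls <- sapply(c(0.05, 0.15, 0.25), function(eff) {
      sp <- cohort_spec(n_per_group = 2, groups = c("PBS", "Cisplatin"),
                        n_regions = 24, n_timepoints = 120,
                        path_length_effect = eff, seed = seed)
      gt <- generate_timeseries(sp)$ground_truth
      gt$expected_measured_L[["Cisplatin"]] /
        gt$expected_measured_L[["PBS"]]
    })
    expect_true(all(diff(Ls) < 0))
  }
})
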
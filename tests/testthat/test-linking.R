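ts <- function(min_offset) as.POSIXct("2015-06-01 12:00:00", tz = "UTC") +
  min_offset * 60

test_that("the +/-60 min window is closed and excludes a lab at +61 min", {
  ecgs <- data.frame(ecg_id = c("e1", "e2"), patient_id = "p1",
                     acquisition_time = c(ts(0), ts(1000)))
  labs <- data.frame(lab_id = c("l1", "l2"), patient_id = "p1",
                     analyte = "potassium", value = c(4, 5),
                     time = c(ts(61), ts(1060)))
  linked <- link_ecg_lab(ecgs, labs)
  # e1's only lab is at +61 min: excluded; e2's lab at +60 min: included
  expect_equal(linked$ecg_id, "e2")
  expect_equal(attr(linked, "n_dropped"), 1)
})

test_that("median assignment handles odd and even lab counts", {
  ecgs <- data.frame(ecg_id = "e1", patient_id = "p1",
                     acquisition_time = ts(0))
  mklabs <- function(vals) data.frame(
    lab_id = paste0("l", seq_along(vals)), patient_id = "p1",
    analyte = "potassium", value = vals,
    time = rep(ts(10), length(vals)))
  expect_equal(link_ecg_lab(ecgs, mklabs(c(3.5, 4.0, 5.0)))$target, 4.0)
  expect_equal(link_ecg_lab(ecgs, mklabs(c(3.5, 4.0, 5.0, 9.0)))$target, 4.5)
})

test_that("a hand-enumerated toy cohort links exactly as tabulated", {
  # 6 ECGs / 9 labs across 3 patients; expectations enumerated by hand from
  # the window rule and per-ECG medians
  ecgs <- data.frame(
    ecg_id = paste0("e", 1:6),
    patient_id = c("p1", "p1", "p2", "p2", "p3", "p3"),
    acquisition_time = c(ts(0), ts(180), ts(0), ts(90), ts(0), ts(500)))
  labs <- data.frame(
    lab_id = paste0("l", 1:9),
    patient_id = c("p1", "p1", "p1", "p2", "p2", "p2", "p2", "p3", "p3"),
    analyte = "potassium",
    value = c(3.0, 4.0, 6.0, 5.0, 5.5, 6.5, 7.0, 4.2, 4.4),
    time = c(ts(-30), ts(50), ts(200),         # p1
             ts(30), ts(60), ts(140), ts(400), # p2
             ts(50), ts(560)))                 # p3
  linked <- link_ecg_lab(ecgs, labs)
  # e1: labs at -30,+50 -> median(3,4) = 3.5
  # e2 (t=180): labs at 200 (+20), 50 (-130 out) -> 6.0
  # e3 (t=0): labs at 30,60 -> median(5,5.5) = 5.25
  # e4 (t=90): labs at 30,60,140 -> median(5,5.5,6.5) = 5.5
  # e5 (t=0): lab at 50 -> 4.2 ; lab 560 out
  # e6 (t=500): lab at 560 -> 4.4 ; lab 50 out
  expect_equal(linked$ecg_id, paste0("e", 1:6))
  expect_equal(linked$target, c(3.5, 6.0, 5.25, 5.5, 4.2, 4.4))
  expect_equal(linked$n_labs_in_window, c(2L, 1L, 2L, 3L, 1L, 1L))
})

test_that("patient partitions are disjoint and respect the cutoff", {
  co <- sample_cohort(analyte_profile("potassium"), 1000, duration = 1,
                      ecgs_per_patient = 1, labs_per_patient = 1, seed = 55)
  sp <- split_patients(co$patients, co$ecgs, seed = 9)
  p <- sp$patients
  expect_length(intersect(c(p$train, p$val), p$random_test), 0)
  expect_length(intersect(c(p$train, p$val), p$temporal_test), 0)
  expect_length(intersect(p$random_test, p$temporal_test), 0)
  # temporal membership is exactly the post-cutoff patients
  post <- co$patients$patient_id[co$patients$admission_date >= as.Date("2017-01-01")]
  expect_setequal(p$temporal_test, post)
  # realized fractions within 2 percentage points of (70, 10, 20)
  n <- nrow(co$patients)
  expect_lt(abs(length(c(p$train, p$val)) / n - 0.70), 0.02)
  expect_lt(abs(length(p$temporal_test) / n - 0.10), 0.02)
  expect_lt(abs(length(p$random_test) / n - 0.20), 0.02)
  # no ECG of a non-temporal patient on/after the cutoff survives
  kept <- unlist(sp$ecg_ids[c("train", "val", "random_test")])
  tms <- co$ecgs$acquisition_time[match(kept, co$ecgs$ecg_id)]
  expect_true(all(tms < as.POSIXct("2017-01-01", tz = "UTC")))
})

test_that("forced temporal membership and the empty-split error", {
  pat <- data.frame(patient_id = paste0("p", 1:20),
                    admission_date = as.Date(c(rep("2012-05-01", 10),
                                               rep("2017-03-01", 10))))
  ecgs <- data.frame(ecg_id = paste0("e", 1:20), patient_id = pat$patient_id,
                     acquisition_time = as.POSIXct(pat$admission_date,
                                                   tz = "UTC"))
  sp <- split_patients(pat, ecgs, seed = 3)
  expect_setequal(sp$patients$temporal_test, paste0("p", 11:20))
  pat$admission_date <- as.Date("2012-05-01")
  expect_error(split_patients(pat, ecgs), "temporal split empty")
})

test_that("evaluation partitions keep only each patient's first ECG", {
  co <- sample_cohort(analyte_profile("potassium"), 120, duration = 1,
                      ecgs_per_patient = count_dist(2), seed = 77)
  linked <- link_ecg_lab(co$ecgs, co$labs)
  sp <- split_patients(co$patients, co$ecgs, seed = 5)
  parts <- select_eval_ecgs(linked, co$ecgs, sp)
  for (nm in c("val", "random_test", "temporal_test")) {
    expect_false(any(duplicated(parts[[nm]]$patient_id)))
    # kept ECG is the earliest linked one of that patient (enumeration oracle)
    for (pid in parts[[nm]]$patient_id) {
      cand <- linked$ecg_id[linked$patient_id == pid &
                              linked$ecg_id %in% sp$ecg_ids[[nm]]]
      tms <- co$ecgs$acquisition_time[match(cand, co$ecgs$ecg_id)]
      expect_equal(parts[[nm]]$ecg_id[parts[[nm]]$patient_id == pid],
                   cand[which.min(tms)])
    }
  }
  # training keeps all linked ECGs of training patients
  expect_setequal(parts$train$ecg_id,
                  linked$ecg_id[linked$ecg_id %in% sp$ecg_ids$train])
})

test_that("the z-score normalizer round-trips and rejects degenerate targets", {
  p <- fit_normalizer(c(2, 4))
  expect_equal(p$mean, 3)
  expect_equal(p$sd, 1) # population convention
  expect_equal(apply_normalizer(c(2, 4), p), c(-1, 1))
  x <- rnorm(50, 10, 3)
  q <- fit_normalizer(x)
  expect_equal(invert_normalizer(apply_normalizer(x, q), q), x)
  expect_error(fit_normalizer(rep(4, 5)), "sd is zero")
})
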
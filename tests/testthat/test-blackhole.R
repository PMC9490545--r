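make_pairs <- function(enter_offsets_min, login = "2016-06-01 09:10:00") {
  n <- length(enter_offsets_min)
  ids <- sprintf("E%02d", seq_len(n))
  tm <- data.frame(encounter_id = ids, point_label = "PHYS_ENTER",
                   observed_time = ts_utc(login) - enter_offsets_min * 60,
                   stringsAsFactors = FALSE)
  pts <- data.frame(encounter_id = ids, label = "PHYS_LOGIN",
                    time = rep(ts_utc(login), n), provenance = "audit",
                    stringsAsFactors = FALSE)
  list(tm = tm, pts = pts)
}

test_that("constant paired differences calibrate to mean 2, SD 0", {
  x <- make_pairs(rep(2, 8))
  m <- calibrate_blackholes(x$tm, x$pts)
  e <- m$intervals$PHYS_ENTER_TO_LOGIN
  expect_equal(e$n, 8)
  expect_equal(e$mean, 2)
  expect_equal(e$sd, 0)
  expect_equal(e$n_clipped, 0)
})

test_that("a negative paired difference is clipped to zero and counted", {
  x <- make_pairs(c(2, 2, -1))   # one observation after the audit login
  m <- calibrate_blackholes(x$tm, x$pts)
  e <- m$intervals$PHYS_ENTER_TO_LOGIN
  expect_equal(e$n_clipped, 1)
  expect_equal(sort(e$sample), c(0, 2, 2))
  expect_true(all(e$sample >= 0))
})

test_that("an interval with no usable pairs is absent and imputation fails loudly", {
  x <- make_pairs(rep(1.5, 4))
  m <- calibrate_blackholes(x$tm, x$pts)
  expect_false("PHYS_LOGOFF_TO_EXIT" %in% names(m$intervals))
  pts <- rbind(x$pts,
               data.frame(encounter_id = x$pts$encounter_id,
                          label = "PHYS_LOGOFF",
                          time = x$pts$time + 600, provenance = "audit",
                          stringsAsFactors = FALSE))
  expect_error(impute_points(pts, m), "PHYS_LOGOFF_TO_EXIT")
})

test_that("calibration recovers the generating mean on synthetic data", {
  s <- simulate_clinic(sim_config(n_encounters = 800, seed = 41))
  p <- derive_workflow_points(s$events, s$location_map)
  m <- calibrate_blackholes(s$time_motion, p)
  e <- m$intervals$PHYS_ENTER_TO_LOGIN
  expect_lt(abs(e$mean - 2.62), 3 * 1.61 / sqrt(e$n) + 0.02)
})

test_that("variance decomposition: pure physician signal gives a 100% share", {
  set.seed(1)
  phys <- rep(sprintf("P%d", 1:5), each = 40)
  d <- as.numeric(factor(phys)) * 1.0
  n <- length(d)
  sh <- decompose_variance(d, phys, age = rnorm(n, 50, 10),
                           sex = sample(c("F", "M"), n, TRUE),
                           race = sample(c("W", "B"), n, TRUE),
                           ethnicity = sample(c("H", "N"), n, TRUE))
  expect_equal(unname(sh["physician"]), 100, tolerance = 1e-6)
  expect_equal(unname(sh["patient"]), 0, tolerance = 1e-6)
})

test_that("variance decomposition: pure noise attributes almost nothing", {
  set.seed(2)
  n <- 5000
  phys <- sample(sprintf("P%02d", 1:10), n, TRUE)
  sh <- decompose_variance(rnorm(n), phys, age = rnorm(n, 50, 10),
                           sex = sample(c("F", "M"), n, TRUE),
                           race = sample(c("W", "B", "A"), n, TRUE),
                           ethnicity = sample(c("H", "N"), n, TRUE))
  expect_lt(sh["physician"], 5)
  expect_lt(sh["patient"], 5)
  expect_equal(unname(sum(sh)), 100, tolerance = 1e-9)
})

test_that("a single physician leaves the share undefined, with a warning", {
  expect_warning(
    sh <- decompose_variance(rnorm(10), rep("P1", 10), age = rnorm(10),
                             sex = rep(c("F", "M"), 5), race = rep("W", 10),
                             ethnicity = rep("N", 10)),
    ">= 2 physicians")
  expect_true(is.na(sh["physician"]))
})

test_that("the generator's configured physician share is recovered", {
  s <- simulate_clinic(sim_config(n_encounters = 5000, n_physicians = 20,
                                  seed = 42))
  d <- (as.numeric(s$truth$PHYS_LOGIN) - as.numeric(s$truth$PHYS_ENTER)) / 60
  pat <- s$patients[match(s$encounters$patient_id, s$patients$patient_id), ]
  sh <- decompose_variance(d, s$encounters$physician_id, pat$age, pat$sex,
                           pat$race, pat$ethnicity)
  expect_lt(abs(sh["physician"] - 62.2), 5)
})

test_that("a singleton calibration sample imputes deterministically", {
  x <- make_pairs(rep(2, 3))
  pts <- rbind(x$pts,
               data.frame(encounter_id = x$pts$encounter_id,
                          label = "PHYS_LOGOFF", time = x$pts$time + 600,
                          provenance = "audit", stringsAsFactors = FALSE))
  m <- list(intervals = list(
    PHYS_ENTER_TO_LOGIN = list(sample = 2, n = 1),
    PHYS_LOGOFF_TO_EXIT = list(sample = 1, n = 1),
    PHYS_EXIT_TO_PATIENT_EXIT = list(sample = 3, n = 1)
  ))
  class(m) <- "blackhole_model"
  out <- impute_points(pts, m, seed = 1)
  w <- out[out$encounter_id == "E01", ]
  expect_equal(w$time[w$label == "PHYS_ENTER"], ts_utc("2016-06-01 09:08:00"))
  expect_equal(w$time[w$label == "PHYS_EXIT"], ts_utc("2016-06-01 09:21:00"))
  expect_equal(w$time[w$label == "PATIENT_EXIT"], ts_utc("2016-06-01 09:24:00"))
  expect_true(all(w$provenance[w$label %in%
                                 c("PHYS_ENTER", "PHYS_EXIT", "PATIENT_EXIT")] ==
                    "imputed"))
})

test_that("imputation is reproducible under a fixed seed and never moves audit points", {
  s <- simulate_clinic(sim_config(n_encounters = 120, seed = 43))
  p <- derive_workflow_points(s$events, s$location_map)
  m <- calibrate_blackholes(s$time_motion, p)
  a <- impute_points(p, m, seed = 99)
  b <- impute_points(p, m, seed = 99)
  expect_identical(a, b)
  c2 <- impute_points(p, m, seed = 100)
  expect_false(identical(a$time, c2$time))
  # audit rows unchanged, in content and count
  keep <- a$provenance == "audit"
  got <- a[keep, c("encounter_id", "label", "time")]
  want <- p[, c("encounter_id", "label", "time")]
  rownames(got) <- rownames(want) <- NULL
  expect_identical(got, want)
})

test_that("imputed durations come from the calibration sample's support", {
  s <- simulate_clinic(sim_config(n_encounters = 300, seed = 44))
  p <- derive_workflow_points(s$events, s$location_map)
  m <- calibrate_blackholes(s$time_motion, p)
  out <- impute_points(p, m, seed = 7)
  w <- points_wide_test(out)
  d <- (as.numeric(w$PHYS_LOGIN) - as.numeric(w$PHYS_ENTER)) / 60
  d <- d[!is.na(d)]
  samp <- m$intervals$PHYS_ENTER_TO_LOGIN$sample
  # every non-clipped draw must be an element of the sample
  in_support <- vapply(d, function(x) any(abs(samp - x) < 1e-9), logical(1))
  n_clip <- attr(out, "n_clipped")
  expect_gte(sum(in_support), length(d) - n_clip)
  # resampling oracle: mean of imputed interval near the sample mean
  se <- stats::sd(samp) / sqrt(length(d))
  expect_lt(abs(mean(d) - mean(samp)), 4 * se + 0.05)
})

test_that("imputed boundary points respect the canonical order", {
  s <- simulate_clinic(sim_config(n_encounters = 250, seed = 45))
  p <- derive_workflow_points(s$events, s$location_map)
  m <- calibrate_blackholes(s$time_motion, p)
  out <- impute_points(p, m, seed = 3)
  w <- points_wide_test(out)
  chk <- function(a, b) {
    ok <- !is.na(w[[a]]) & !is.na(w[[b]])
    all(as.numeric(w[[a]])[ok] <= as.numeric(w[[b]])[ok] + 1e-9)
  }
  expect_true(chk("MA_LOGOFF", "MA_EXIT"))
  expect_true(chk("MA_EXIT", "PHYS_ENTER"))
  expect_true(chk("PHYS_ENTER", "PHYS_LOGIN"))
  expect_true(chk("PHYS_LOGOFF", "PHYS_EXIT"))
  expect_true(chk("PHYS_EXIT", "PATIENT_EXIT"))
})

test_that("imputation bias of the boundary point shrinks with calibration size", {
  bias_at <- function(n, seed) {
    s <- simulate_clinic(sim_config(n_encounters = n, seed = seed))
    p <- derive_workflow_points(s$events, s$location_map)
    m <- calibrate_blackholes(s$time_motion, p)
    out <- impute_points(p, m, seed = seed + 1)
    w <- points_wide_test(out)
    i <- match(s$truth$encounter_id, w$encounter_id)
    mean((as.numeric(w$PHYS_ENTER)[i] - as.numeric(s$truth$PHYS_ENTER)) / 60,
         na.rm = TRUE)
  }
  b_small <- bias_at(100, 46)
  b_large <- bias_at(2000, 47)
  expect_lt(abs(b_large), 0.2)
  expect_lt(abs(b_large), abs(b_small) + 0.2)
})

test_that("model JSON serialization round-trips", {
  x <- make_pairs(c(1, 2, 3))
  m <- calibrate_blackholes(x$tm, x$pts)
  f <- tempfile(fileext = ".json")
  write_blackhole_model(m, f)
  m2 <- read_blackhole_model(f)
  expect_equal(m2$intervals$PHYS_ENTER_TO_LOGIN$sample,
               m$intervals$PHYS_ENTER_TO_LOGIN$sample)
  expect_equal(m2$intervals$PHYS_ENTER_TO_LOGIN$mean, 2)
})
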
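mini_encounters <- function() {
  data.frame(
    encounter_id = sprintf("E%02d", 1:10),
    patient_id = c(rep("A", 3), rep("B", 3), rep("C", 4)),
    physician_id = c(rep("P1", 6), rep("P2", 4)),
    date = as.Date("2016-06-01") + c(0, 10, 20, 0, 5, 9, 1, 2, 3, 4),
    scheduled_length_min = c(15, 30, 30, 15, 15, 20, 30, 40, 15, 30),
    los_level = c(3, 4, 3, 3, 4, 4, 2, 3, 4, 5),
    primary_dx = c("diabetes", "other", "hypertension", "other", "other",
                   "diabetes", "hyperlipidemia", "other", "other", "other"),
    dx_codes = c("E11;I10", "Z00", "I10", "J06", "M54", "E11", "E78;Z00",
                 "Z00", "K21", "F41"),
    period = "pre", exposure = FALSE, stringsAsFactors = FALSE
  )
}

mini_patients <- function() {
  data.frame(
    patient_id = c("A", "B", "C"), age = c(70, 45, 28),
    sex = c("F", "F", "M"), race = c("White", "Asian", "White"),
    ethnicity = c("NonHispanic", "Hispanic", "NonHispanic"),
    dm = c(1, 0, 0), htn = c(1, 0, 0), dyslip = c(0, 1, 1),
    charlson = c(3, 1, 0), stringsAsFactors = FALSE
  )
}

test_that("physician summaries aggregate panel proportions from counts", {
  ps <- summarize_physicians(mini_encounters(), mini_patients())
  p1 <- ps[ps$physician_id == "P1", ]
  expect_equal(p1$p_female, 1)          # patients A and B, both F
  expect_equal(p1$p_dm, 0.5)            # 3 of 6 encounters are A (dm)
  expect_equal(p1$p_hispanic, 0.5)
  expect_equal(p1$p_charlson_ge3, 0.5)
  expect_equal(p1$mean_appts_per_day, 6 / 5)
  p2 <- ps[ps$physician_id == "P2", ]
  expect_equal(p2$p_female, 0)
  expect_equal(p2$mean_appts_per_day, 1)
})

test_that("patient summaries convert encounter mixes to percentages", {
  su <- summarize_patients(mini_encounters(), mini_patients())
  a <- su[su$patient_id == "A", ]
  expect_equal(a$pct_appt15, 100 / 3)
  expect_equal(a$pct_appt30, 200 / 3)
  expect_equal(a$pct_dx_dm, 100 / 3)
  expect_equal(a$pct_dx_htn, 100 / 3)
  expect_equal(a$age, 70)
  expect_equal(a$female, 1)
})

test_that("constant features reduce the propensity score to prevalence", {
  feats <- data.frame(x = rep(1, 10), z = rep(0, 10))
  sc <- fit_propensity(feats, c(rep(1, 3), rep(0, 7)))
  expect_equal(as.numeric(sc), rep(0.3, 10), tolerance = 1e-6)
})

test_that("propensity coefficients are recovered from a known logistic model", {
  set.seed(8)
  n <- 2000
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
  beta <- c(-0.5, 0.8, -0.6)
  y <- rbinom(n, 1, plogis(beta[1] + beta[2] * x1 + beta[3] * x2))
  sc <- fit_propensity(data.frame(x1 = x1, x2 = x2), y)
  co <- attr(sc, "coefficients")
  se <- sqrt(diag(vcov(glm(y ~ x1 + x2, family = binomial()))))
  expect_true(all(abs(co - beta) < 3 * se))
  expect_true(all(sc > 0 & sc < 1))
  expect_equal(attr(sc, "method"), "mle")
})

test_that("separated data fall back to a penalized fit with a warning", {
  x <- c(rnorm(20, -3), rnorm(20, 3))
  y <- rep(c(0, 1), each = 20)
  expect_warning(sc <- fit_propensity(data.frame(x = x), y), "separation")
  expect_true(all(sc > 0 & sc < 1))
  expect_equal(attr(sc, "method"), "ridge")
})

test_that("greedy matching pairs nearest scores within an absolute caliper", {
  cases <- c(c1 = 0.9, c2 = 0.5)
  ctls <- c(k1 = 0.85, k2 = 0.55, k3 = 0.10)
  m <- greedy_match(cases, ctls, caliper = 0.1, caliper_scale = "absolute")
  expect_equal(m$pairs$case_id, c("c1", "c2"))
  expect_equal(m$pairs$control_id, c("k1", "k2"))
  expect_equal(length(m$unmatched), 0)
})

test_that("matching is deterministic, without replacement, and caliper-bounded", {
  set.seed(9)
  cases <- setNames(runif(50, 0.3, 0.9), sprintf("c%02d", 1:50))
  ctls <- setNames(runif(150, 0.1, 0.8), sprintf("k%03d", 1:150))
  m1 <- greedy_match(cases, ctls, caliper = 0.2)
  m2 <- greedy_match(cases, ctls, caliper = 0.2)
  expect_identical(m1$pairs, m2$pairs)
  expect_false(any(duplicated(m1$pairs$control_id)))
  lg <- function(p) log(p / (1 - p))
  d <- abs(lg(cases[m1$pairs$case_id]) - lg(ctls[m1$pairs$control_id]))
  expect_true(all(d <= m1$caliper_width + 1e-9))
})

test_that("an empty control pool leaves every case unmatched", {
  m <- greedy_match(c(a = 0.5), setNames(numeric(0), character(0)))
  expect_equal(nrow(m$pairs), 0)
  expect_equal(m$unmatched, "a")
})

test_that("a zero caliper matches only exact score ties", {
  cases <- c(a = 0.4, b = 0.6)
  ctls <- c(x = 0.4, y = 0.61)
  m <- greedy_match(cases, ctls, caliper = 0, caliper_scale = "absolute")
  expect_equal(m$pairs$case_id, "a")
  expect_equal(m$pairs$control_id, "x")
  expect_equal(m$unmatched, "b")
})

test_that("1:k matching takes up to k controls per case into one cluster", {
  cases <- c(a = 0.5)
  ctls <- c(x = 0.52, y = 0.48, z = 0.30)
  m <- greedy_match(cases, ctls, ratio = 2, caliper = 0.1,
                    caliper_scale = "absolute")
  expect_equal(nrow(m$pairs), 2)
  expect_setequal(m$pairs$control_id, c("x", "y"))
  expect_equal(unique(m$pairs$cluster_id), "a")
})

test_that("period assignment drops washout visits and uses the first visit", {
  enc <- data.frame(
    encounter_id = sprintf("E%d", 1:6),
    patient_id = c("A", "A", "B", "B", "C", "C"),
    date = as.Date(c("2015-06-01", "2016-08-01",   # A: first visit pre
                     "2016-04-15", "2016-05-20",   # B: washout only
                     "2016-07-01", "2017-01-01")), # C: post only
    stringsAsFactors = FALSE
  )
  out <- assign_period(enc, c("2015-04-01", "2016-03-31"),
                       c("2016-06-01", "2017-06-30"),
                       washout = c("2016-04-01", "2016-05-31"))
  expect_equal(out$n_dropped, 2)
  expect_false("B" %in% out$patients$patient_id)
  expect_equal(out$patients$period[out$patients$patient_id == "A"], "pre")
  expect_equal(out$patients$period[out$patients$patient_id == "C"], "post")
  expect_error(assign_period(enc, c("2015-01-01", "2016-12-31"),
                             c("2016-06-01", "2017-06-30")), "overlap")
})

test_that("eligibility requires a cardiometabolic code in the dx list", {
  enc <- mini_encounters()
  el <- eligible_encounters(enc)
  expect_setequal(el$encounter_id, c("E01", "E03", "E06", "E07"))
  # matched filter restricts to paired patients
  m <- list(pairs = data.frame(case_id = "A", control_id = "C",
                               cluster_id = "A", stringsAsFactors = FALSE))
  el2 <- eligible_encounters(enc, matched = m)
  expect_setequal(unique(el2$patient_id), c("A", "C"))
})

test_that("the printed-count arithmetic yields the reported primary-dx rate", {
  # 6599 eligible encounters of which 595 carry a cardiometabolic primary dx
  enc <- data.frame(primary_dx = c(rep("diabetes", 300),
                                   rep("hypertension", 200),
                                   rep("hyperlipidemia", 95),
                                   rep("other", 6004)),
                    stringsAsFactors = FALSE)
  expect_equal(round(pct_primary_cardiometabolic(enc), 2), 9.02)
})

test_that("SMDs are zero for identical groups and follow the pooled formula", {
  dat <- data.frame(id = c("a1", "a2", "b1", "b2"),
                    x = c(1, 1, 0, 0), y = c(2, 2, 2, 2))
  m <- list(pairs = data.frame(case_id = c("a1", "a2"),
                               control_id = c("b1", "b2"),
                               cluster_id = c("a1", "a2"),
                               stringsAsFactors = FALSE))
  bt <- balance_table(dat, c("a1", "a2"), c("b1", "b2"), m, c("x", "y"))
  expect_equal(bt$smd_pre[bt$covariate == "y"], 0)     # 0/0 -> 0
  expect_equal(bt$smd_post[bt$covariate == "y"], 0)
  # means 1 vs 0, within-group variance 0 -> divergent denominator guarded
  dat2 <- data.frame(id = c("a1", "a2", "b1", "b2"), x = c(1, 2, 0, 1))
  bt2 <- balance_table(dat2, c("a1", "a2"), c("b1", "b2"), m, "x")
  expect_equal(bt2$smd_pre, (1.5 - 0.5) / sqrt((0.5 + 0.5) / 2))
})

test_that("matching a confounded cohort restores covariate balance", {
  set.seed(10)
  n <- 2000
  dat <- data.frame(id = sprintf("u%04d", 1:n), age = rnorm(n, 55, 12),
                    dm = rbinom(n, 1, 0.4))
  pr <- plogis(-2.6 + 0.08 * (dat$age - 55) + 1.8 * dat$dm)
  case <- runif(n) < pr
  sc <- fit_propensity(dat[, c("age", "dm")], case)
  names(sc) <- dat$id
  m <- greedy_match(sc[dat$id[case]], sc[dat$id[!case]], caliper = 0.2)
  bt <- balance_table(dat, dat$id[case], dat$id[!case], m, c("age", "dm"))
  expect_gt(max(abs(bt$smd_pre)), 0.3)
  expect_lt(max(abs(bt$smd_post)), 0.1)
})
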
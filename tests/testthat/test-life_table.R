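# Chiang II life-table core: rate-to-probability conversion, column
# identities, the stratified schedule layout, and LE variance.

test_that("chiang_q matches the closed form and a discrete survival oracle", {
  expect_equal(chiang_q(0, 5), 0)
  expect_equal(chiang_q(0.3, NA), 1)  # open-ended: death is certain
  expect_equal(chiang_q(0.01, 5), 0.05 / 1.025)
  expect_error(chiang_q(-0.1, 5), "rate")
  expect_error(chiang_q(0.1, 5, a = 1.5), "a must be")

  # fine-grained discrete survival at constant hazard: feeding the
  # oracle's central rate into chiang_q recovers its death probability up
  # to the conversion's third-order error in n*M
  for (h in c(0.002, 0.02, 0.1)) {
    o <- discrete_survival_oracle(h, 5)
    expect_lt(abs(chiang_q(o$M, 5) - o$q), (5 * h)^3 / 10 + 1e-9)
  }

  # monotone in rate, saturating at 1
  r <- seq(0, 2, by = 0.05)
  expect_true(all(diff(chiang_q(r, 5)) > 0))
  expect_lt(1 - chiang_q(50, 5), 1e-2)
})

test_that("life-table columns satisfy the Chiang identities", {
  s <- age_schedule(c(20, 25, 30, 35), c(5, 5, 5, NA),
                    c(0.002, 0.004, 0.01, 0.15))
  lt <- build_life_table(s, radix = 1e5)
  k <- nrow(lt)
  expect_equal(sum(lt$d), 1e5)                      # everyone dies
  expect_equal(lt$T[k], lt$L[k])                    # terminal cumulation
  expect_true(all(diff(lt$l) < 0))                  # survivors decrease
  expect_equal(lt$l[-1], (lt$l - lt$d)[-k])
  expect_equal(lt$d, lt$l * lt$q)
  expect_equal(lt$L[-k], 5 * (lt$l[-k] - 0.5 * lt$d[-k]))
  expect_equal(lt$e[k], 1 / lt$M[k])                # open: e = 1/M
  expect_equal(lt$q[k], 1)
  expect_equal(lt$e, lt$T / lt$l)
})

test_that("constant-rate schedule matches the geometric closed form to 1e-10", {
  for (m in c(0.001, 0.01, 0.08)) {
    for (k in c(3, 10, 14)) {
      lt <- build_life_table(constant_schedule(m, 5, k))
      expect_equal(lt$e[1], constant_rate_le(m, 5, k), tolerance = 1e-10)
    }
  }
})

test_that("life expectancy is strictly decreasing in every rate", {
  base <- fx_ref
  lt0 <- build_life_table(base)
  for (i in seq_len(nrow(base))) {
    bump <- base
    bump$rate[i] <- bump$rate[i] * 2
    lt1 <- build_life_table(bump)
    expect_true(all(lt1$e[seq_len(i)] < lt0$e[seq_len(i)]),
                info = paste("doubling rate in interval", i))
  }
})

test_that("single-year table built from repeated 5-year rates agrees within 0.5 years", {
  r <- fx_ref
  ages1 <- 20:89
  rates1 <- rep(r$rate[-nrow(r)], each = 5)
  s1 <- age_schedule(c(ages1, 90), c(rep(1, 70), NA),
                     c(rates1, r$rate[nrow(r)]))
  e_single <- build_life_table(s1)$e[1]
  e_abridged <- build_life_table(r)$e[1]
  expect_lt(abs(e_single - e_abridged), 0.5)
})

test_that("schedule validation rejects malformed input", {
  expect_error(age_schedule(c(20, 30), c(5, NA), c(0.1, 0.2)), "contiguous")
  expect_error(age_schedule(c(20, 25), c(5, 5), c(0.1, 0.2)), "open-ended")
  expect_error(age_schedule(20, NA, -0.1), ">= 0")
  expect_error(build_life_table(age_schedule(c(20, 25), c(5, NA), c(0.1, 0))),
               "rate > 0")
  # counts inconsistent with the printed rate
  expect_error(age_schedule(c(20, 25), c(5, NA), c(0.1, 0.2),
                            deaths = c(500, 10), person_years = c(1000, 100)),
               "disagrees")
})

test_that("stratified schedule lays out select and ultimate intervals", {
  cfg <- extrapolation_config("none")
  s20 <- stratified_schedule(20, fx_rates, fx_ref, cfg)
  expect_equal(s20$age_start[1:3], c(20, 21, 25))
  expect_equal(s20$width[1:2], c(1, 4))
  expect_equal(s20$rate[1], fx_rates$rate[fx_rates$stratum == "first_year" &
                                            fx_rates$age_start == 20])
  expect_equal(s20$rate[2], fx_rates$rate[fx_rates$stratum == "survivor" &
                                            fx_rates$age_start == 20])
  expect_true(is.na(s20$width[nrow(s20)]))

  # boundary entry age: empty 4-year remainder is dropped
  s24 <- stratified_schedule(24, fx_rates, fx_ref, cfg)
  expect_equal(s24$age_start[1:2], c(24, 25))
  expect_equal(s24$width[1], 1)
  expect_equal(s24$rate[2], fx_rates$rate[fx_rates$stratum == "survivor" &
                                            fx_rates$age_start == 25])

  # survivor-only mode starts directly on ultimate rates
  s55 <- stratified_schedule(55, fx_rates, fx_ref, cfg, survivor_only = TRUE)
  expect_equal(s55$age_start[1], 55)
  expect_equal(s55$width[1], 5)
  expect_equal(s55$rate[1], fx_rates$rate[fx_rates$stratum == "survivor" &
                                            fx_rates$age_start == 55])

  # pooled stratum gives the plain unstratified layout
  pooled <- rate_table(fx_ref$age_start, fx_ref$width, "pooled", fx_ref$rate)
  sp <- stratified_schedule(20, pooled, fx_ref, cfg)
  expect_equal(sp$age_start[1], 20)
  expect_equal(sp$width[1], 5)

  expect_error(stratified_schedule(15, fx_rates, fx_ref, cfg), "youngest")
})

test_that("stratified LE equals pooled LE when the strata rates are equal", {
  common <- fx_ref$rate
  rt <- rate_table(rep(fx_ref$age_start, 2), rep(fx_ref$width, 2),
                   rep(c("first_year", "survivor"), each = nrow(fx_ref)),
                   rep(common, 2))
  pooled <- rate_table(fx_ref$age_start, fx_ref$width, "pooled", common)
  cfg <- extrapolation_config("none")
  # the 1+4-year split changes q only at third order in the rate, so the
  # two tables agree to well under a thousandth of a year
  e_strat <- build_life_table(stratified_schedule(20, rt, fx_ref, cfg))$e[1]
  e_pool <- build_life_table(stratified_schedule(20, pooled, fx_ref, cfg))$e[1]
  expect_equal(e_strat, e_pool, tolerance = 1e-6)
})

test_that("LE variance: zero without counts, matches a parametric bootstrap with them", {
  res0 <- le_with_ci(fx_ref)  # published rates carry no counts
  expect_equal(res0$se, 0)
  expect_gt(res0$le, 0)
  expect_equal(res0$ci95_halfwidth, 1.96 * res0$se)

  s <- counted_schedule(py = 2e4)
  res <- le_with_ci(s)
  expect_gt(res$se, 0)

  # bootstrap oracle: per closed interval resample deaths ~ Binomial(N, q)
  # with N = D/q (Chiang's implicit denominator); open interval deaths ~
  # Poisson(PY * M); rebuild LE from the resampled probabilities
  set.seed(421)
  k <- nrow(s)
  q <- chiang_q(s$rate, s$width)
  N <- round(s$deaths[-k] / q[-k])
  reps <- replicate(2000, {
    d_star <- rbinom(k - 1, N, q[-k])
    q_star <- d_star / N
    m_star <- q_star / (s$width[-k] - s$width[-k] * 0.5 * q_star)
    m_open <- rpois(1, s$person_years[k] * s$rate[k]) / s$person_years[k]
    build_life_table(age_schedule(s$age_start, s$width,
                                  c(m_star, m_open)))$e[1]
  })
  expect_equal(sd(reps), res$se, tolerance = 0.1)
})

test_that("extrapolated and reference rows contribute no LE variance", {
  s <- counted_schedule(py = 2e4)
  s$source[s$age_start >= 60] <- "extrapolated"
  v_part <- le_with_ci(s)$se
  s2 <- counted_schedule(py = 2e4)
  expect_lt(v_part, le_with_ci(s2)$se)
  s$source <- "reference"
  expect_equal(le_with_ci(s)$se, 0)
})

test_that("years of life lost is the reference gap, sign included", {
  expect_equal(yll(47.5, 62.2), 14.7)
  expect_equal(yll(30, 30), 0)
  expect_equal(yll(23.1, 28.9), 5.8)
  expect_equal(yll(37.2, 28.9), -8.3)  # biased open group overshoots
  expect_error(yll(-1, 10), ">= 0")
})

test_that("average LE reduces to single-age LE for a point mass and averages pairs", {
  cfg <- extrapolation_config("gompertz", 90)
  le20 <- build_life_table(stratified_schedule(20, fx_rates, fx_ref, cfg))$e[1]
  le30 <- build_life_table(stratified_schedule(30, fx_rates, fx_ref, cfg))$e[1]
  expect_equal(average_le(fx_rates, fx_ref, cfg,
                          data.frame(age = 20, weight = 1)), le20)
  expect_equal(average_le(fx_rates, fx_ref, cfg,
                          data.frame(age = c(20, 30), weight = c(1, 1))),
               (le20 + le30) / 2)
  expect_error(average_le(fx_rates, fx_ref, cfg,
                          data.frame(age = 20, weight = 0)), "not all zero")
})
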
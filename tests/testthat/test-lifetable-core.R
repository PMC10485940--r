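test_that("central death rates are deaths over person-years, with missing flagged", {
  pooled <- tibble::tibble(
    group_id = "all_pwd", sex = "male", age = 0L,
    person_years = 7325257, deaths = 201090
  )
  expect_equal(compute_mx(pooled)$mx, 201090 / 7325257)

  sched <- tibble::tibble(
    group_id = "g", sex = "female", age = 0:2,
    person_years = c(1000, 0, 500), deaths = c(0, 0, 10)
  )
  mx <- compute_mx(sched)$mx
  expect_identical(mx[1], 0)
  expect_true(is.na(mx[2])) # zero exposure is missing information, not rate 0
  expect_equal(mx[3], 0.02)

  bad <- dplyr::mutate(sched, deaths = c(-1, 0, 10))
  expect_error(compute_mx(bad), class = "lifehale_validation_error")
  gap <- dplyr::mutate(sched, age = c(0L, 2L, 3L))
  expect_error(compute_mx(gap), class = "lifehale_validation_error")
})

test_that("mx to qx conversion follows the actuarial identity and caps at 1", {
  expect_equal(mx_to_qx(0, 0.5), 0)
  expect_equal(mx_to_qx(0.01, 0.5), 0.01 / (1 + 0.5 * 0.01))
  # uncapped limit is 1 / (1 - ax) > 1, hence the cap
  expect_equal(mx_to_qx(1e6, 0.5), 1)
  expect_equal(mx_to_qx(1e6, 0.9), 1)
  # with ax = 0 the limit is exactly 1 and the cap never binds
  expect_lt(mx_to_qx(1e6, 0), 1)
  expect_error(mx_to_qx(-0.1, 0.5), class = "lifehale_validation_error")
})

test_that("separation factors use infant values at age 0 and midpoint elsewhere", {
  expect_equal(assign_ax("male", 0L), 0.05)
  expect_equal(assign_ax("female", 0L), 0.13)
  expect_equal(assign_ax("male", c(0L, 1L, 40L)), c(0.05, 0.5, 0.5))
  expect_equal(assign_ax("female", 40L), 0.5)
  expect_error(assign_ax("other", 0L), class = "lifehale_validation_error")
})

test_that("graduation reproduces constants and cubics, attenuates spikes", {
  expect_equal(greville_smooth(rep(0.01, 30), order = 9), rep(0.01, 30))

  x <- 0:29
  cubic <- (2e-3 + 1e-4 * x + 3e-6 * x^2 + 5e-8 * x^3)
  expect_equal(greville_smooth(cubic, order = 9), cubic, tolerance = 1e-10)
  expect_equal(greville_smooth(cubic, order = 9), local_cubic_oracle(cubic, 9),
    tolerance = 1e-10
  )

  spiked <- cubic
  spiked[15] <- spiked[15] + 0.05
  smoothed <- greville_smooth(spiked, order = 9)
  expect_lt(abs(smoothed[15] - cubic[15]), abs(spiked[15] - cubic[15]))
  # least-squares graduation shrinks the energy of the spike
  expect_lt(sum((smoothed - cubic)^2), sum((spiked - cubic)^2))

  expect_warning(out <- greville_smooth(rep(0.01, 5), order = 9), "shorter")
  expect_equal(out, rep(0.01, 5))
  expect_error(greville_smooth(rep(0.01, 30), order = 8),
    class = "lifehale_validation_error"
  )
})

test_that("certain death at every age leaves only the first-year fraction", {
  lt <- build_life_table(rep(1, 5), ax = c(0.05, rep(0.5, 4)), ages = 0:4)
  expect_equal(lt$ex[1], 0.05)
  expect_equal(lt$lx[2], 0)
  expect_error(build_life_table(rep(0.5, 5), rep(0.5, 5), 0:4, radix = 0),
    class = "lifehale_validation_error"
  )
})

test_that("constant-hazard expectation matches brute-force summation to 1e-9", {
  q <- rep(0.1, 31)
  ax <- rep(0.5, 31)
  m_closure <- 0.25
  lt <- build_life_table(q, ax, 0:30, radix = 1, mx_at_closure = m_closure)
  oracle <- brute_force_e0(q, ax, m_closure)
  expect_equal(lt$ex[1], oracle, tolerance = 1e-9)
})

test_that("life-table invariants hold for arbitrary probability schedules", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(20:80, 1)
    q <- runif(n, 0, 0.4)
    ax <- c(0.05, rep(0.5, n - 1))
    lt <- build_life_table(q, ax, seq_len(n) - 1L, mx_at_closure = runif(1, 0.2, 1))
    expect_true(all(diff(lt$lx) <= 1e-9))
    expect_true(all(lt$lx >= 0))
    expect_equal(lt$qx[n], 1)
    # conservation: everyone dies
    expect_equal(sum(lt$dx), 1e5, tolerance = 1e-9)
    # recursion consistency, bit for bit
    expect_identical(lt$Tx, rev(cumsum(rev(lt$Lx))))
    expect_identical(lt$ex[lt$lx > 0], (lt$Tx / lt$lx)[lt$lx > 0])
    expect_identical(lt$dx, lt$lx * lt$qx)
    # one year of age costs at most one year of expectation
    e <- lt$ex[!is.na(lt$ex)]
    expect_true(all(e[-length(e)] <= e[-1] + 1 + 1e-9))
  }
})

test_that("Chiang interval matches hand computation on a single mortal age", {
  # one mortal age (q = 0.2, D = 100) then the open interval
  q <- c(0.2, 1)
  ax <- c(0.5, 0.5)
  m_closure <- 0.5
  lt <- build_life_table(q, ax, 0:1, radix = 1e5, mx_at_closure = m_closure)
  out <- chiang_ci(lt, deaths = c(100, 50), quiet = TRUE)
  s2p <- 0.2^2 * 0.8 / 100
  e1 <- (1e5 * 0.8 / m_closure) / (1e5 * 0.8)
  s2e0 <- ((1 - 0.5) + e1)^2 * s2p # l0^2 / l0^2 = 1
  expect_equal(out$se_ex[1], sqrt(s2e0))
  expect_equal(out$lo95[1], out$ex[1] - 1.96 * sqrt(s2e0))
  expect_equal(out$hi95[1], out$ex[1] + 1.96 * sqrt(s2e0))
})

test_that("Chiang variance scales as 1/deaths and degenerates properly", {
  set.seed(5)
  q <- c(runif(40, 0.001, 0.2), 1)
  ax <- rep(0.5, 41)
  d <- round(runif(41, 50, 500))
  lt <- build_life_table(q, ax, 0:40, mx_at_closure = 0.7)
  a <- chiang_ci(lt, d, quiet = TRUE)
  b <- chiang_ci(lt, 4 * d, quiet = TRUE)
  expect_equal(b$se_ex, a$se_ex / 2)

  degenerate <- build_life_table(c(0, 0, 1), rep(0.5, 3), 0:2, mx_at_closure = 1)
  out <- chiang_ci(degenerate, c(0, 0, 100), quiet = TRUE)
  expect_equal(out$se_ex, rep(0, 3))

  expect_warning(
    chiang_ci(lt, rep(0, 41)),
    "no observed deaths"
  )
})

test_that("literal (unsquared) bracket variant is available and wider brackets differ", {
  q <- c(rep(0.05, 20), 1)
  lt <- build_life_table(q, rep(0.5, 21), 0:20, mx_at_closure = 0.6)
  sq <- chiang_ci(lt, rep(100, 21), quiet = TRUE)
  lit <- chiang_ci(lt, rep(100, 21), literal_bracket = TRUE, quiet = TRUE)
  # bracket (1-a)+e > 1 here, so squaring enlarges the variance
  expect_true(all(sq$se_ex[1:19] > lit$se_ex[1:19]))
})

test_that("full table from a synthetic schedule recovers the analytic LE", {
  sc <- synthetic_scenario(
    groups = tibble::tibble(
      group_id = "big", sex = "male", hazard_ratio = 1, first_age = 0L,
      exposure_scale = 1e8, missing_age_fraction = 0
    ),
    seed = 21
  )
  sched <- simulate_schedule(sc, "big")
  lt <- life_table(sched, smooth_order = NULL, quiet = TRUE)
  expect_lt(abs(lt$ex[1] - analytic_le(sc, "big", 0)), 0.1)

  # graduation neutrality: smoothing a well-behaved schedule moves LE < 0.5 y
  lt_s <- life_table(sched, smooth_order = 9, quiet = TRUE)
  expect_lt(abs(lt_s$ex[1] - lt$ex[1]), 0.5)
})

test_that("life table refuses schedules with unimputed gaps", {
  sched <- tibble::tibble(
    group_id = "g", sex = "male", age = 0:9,
    person_years = c(rep(1000, 5), NA, rep(1000, 4)),
    deaths = c(rep(5, 5), NA, rep(5, 4))
  )
  expect_error(life_table(sched), class = "lifehale_validation_error")
})

test_that("life-table CSV round trip preserves full precision", {
  sc <- synthetic_scenario(seed = 3)
  lt <- life_table(simulate_schedule(sc, "disabled"), quiet = TRUE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_lifetable_csv(lt, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$ex, lt$ex)
  expect_equal(back$se_ex, lt$se_ex)
})
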
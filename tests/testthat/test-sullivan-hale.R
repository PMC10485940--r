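make_lt <- function(seed = 2, group = "reference") {
  sc <- synthetic_scenario(seed = seed)
  life_table(simulate_schedule(sc, group), quiet = TRUE)
}

test_that("grouped prevalence expands as a step function with carry-down", {
  single <- tibble::tibble(age_lo = 0L, age_hi = 100L, pi = 0.1)
  out <- expand_prevalence(single, 0:100)
  expect_equal(out$pi, rep(0.1, 101))

  two <- tibble::tibble(age_lo = c(0L, 50L), age_hi = c(49L, 100L), pi = c(0.05, 0.2))
  out2 <- expand_prevalence(two, 0:100)
  expect_equal(out2$pi, c(rep(0.05, 50), rep(0.2, 51)))

  expect_error(expand_prevalence(two, 0:110), class = "lifehale_validation_error")
  late <- tibble::tibble(age_lo = 20L, age_hi = 100L, pi = 0.3)
  expect_warning(out3 <- expand_prevalence(late, 0:100), "inherit")
  expect_equal(out3$pi[1:20], rep(0.3, 20))

  gapped <- tibble::tibble(age_lo = c(0L, 60L), age_hi = c(49L, 100L), pi = c(0.1, 0.2))
  expect_error(expand_prevalence(gapped, 0:100), class = "lifehale_validation_error")
})

test_that("Sullivan identities hold exactly", {
  lt <- make_lt()
  ages <- lt$age
  zero <- sullivan_hale(lt, tibble::tibble(age = ages, pi = 0), quiet = TRUE)
  expect_equal(zero$hale, lt$ex, tolerance = 1e-12)
  expect_equal(zero$se_hale, lt$se_ex, tolerance = 1e-12)
  expect_equal(zero$hale_lo95, lt$lo95, tolerance = 1e-12)

  const <- sullivan_hale(lt, tibble::tibble(age = ages, pi = 0.3), quiet = TRUE)
  expect_equal(const$hale, 0.7 * lt$ex, tolerance = 1e-12)

  all_unhealthy <- sullivan_hale(lt, tibble::tibble(age = ages, pi = 1), quiet = TRUE)
  expect_equal(all_unhealthy$hale, rep(0, length(ages)))
})

test_that("unhealthy years are non-negative and decompose exactly", {
  lt <- make_lt(seed = 6)
  sc <- synthetic_scenario(seed = 6)
  prev <- simulate_prevalence(sc, "reference", "NHIS")
  h <- sullivan_hale(lt, prev, quiet = TRUE)
  unhealthy <- h$ex - h$hale
  expect_true(all(unhealthy >= -1e-12, na.rm = TRUE))
  oracle <- rev(cumsum(rev(lt$Lx * h$pi))) / lt$lx
  expect_equal(unhealthy, oracle, tolerance = 1e-12)
  expect_true(all(h$hale <= h$ex + 1e-12, na.rm = TRUE))
})

test_that("pointwise-lower prevalence dominates in HALE at every age", {
  lt <- make_lt(seed = 14)
  ages <- lt$age
  lo <- plogis((ages - 80) / 10) * 0.6
  hi <- lo + 0.15
  h_lo <- sullivan_hale(lt, tibble::tibble(age = ages, pi = lo), ci = FALSE)
  h_hi <- sullivan_hale(lt, tibble::tibble(age = ages, pi = hi), ci = FALSE)
  expect_true(all(h_lo$hale >= h_hi$hale - 1e-12, na.rm = TRUE))
})

test_that("HALE intervals follow the Chiang scaling law and a hand oracle", {
  # two-age toy table, hand evaluation of the adapted variance
  q <- c(0.2, 1)
  ax <- c(0.5, 0.5)
  lt <- build_life_table(q, ax, 0:1, radix = 1e5, mx_at_closure = 0.5)
  lt$deaths <- c(100, 50)
  pi_x <- c(0.1, 0.4)
  h <- sullivan_hale(lt, tibble::tibble(age = 0:1, pi = pi_x), quiet = TRUE)
  L_healthy <- lt$Lx * (1 - pi_x)
  hale0 <- sum(L_healthy) / lt$lx[1]
  hale1 <- L_healthy[2] / lt$lx[2]
  expect_equal(h$hale, c(hale0, hale1))
  s2p0 <- 0.2^2 * 0.8 / 100
  s2_hand <- ((1 - 0.5) * (1 - 0.1) + hale1)^2 * s2p0
  expect_equal(h$se_hale[1], sqrt(s2_hand))

  # deaths x4 at fixed rates halves the standard error
  lt4 <- lt
  lt4$deaths <- 4 * lt$deaths
  h4 <- sullivan_hale(lt4, tibble::tibble(age = 0:1, pi = pi_x), quiet = TRUE)
  expect_equal(h4$se_hale[1], h$se_hale[1] / 2)
})

test_that("the optional prevalence-variance term widens intervals and needs denominators", {
  lt <- make_lt(seed = 17)
  prev <- tibble::tibble(age = lt$age, pi = 0.2, denom = 500)
  base <- sullivan_hale(lt, prev, quiet = TRUE)
  wide <- sullivan_hale(lt, prev, prevalence_variance = TRUE, quiet = TRUE)
  expect_true(all(wide$se_hale >= base$se_hale, na.rm = TRUE))
  expect_gt(wide$se_hale[1], base$se_hale[1])
  no_denom <- tibble::tibble(age = lt$age, pi = 0.2)
  expect_error(
    sullivan_hale(lt, no_denom, prevalence_variance = TRUE, quiet = TRUE),
    class = "lifehale_validation_error"
  )
})

test_that("step expansion of a smooth curve stays near the smooth-truth HALE", {
  lt <- make_lt(seed = 19)
  ages <- lt$age
  smooth_pi <- 0.05 + 0.85 * plogis(0.1 * (ages - 75))
  bands <- tibble::tibble(age_lo = seq(0L, 95L, 5L), age_hi = seq(4L, 99L, 5L))
  bands <- dplyr::bind_rows(bands, tibble::tibble(age_lo = 100L, age_hi = 100L))
  bands$pi <- vapply(
    seq_len(nrow(bands)),
    function(i) mean(smooth_pi[ages >= bands$age_lo[i] & ages <= bands$age_hi[i]]),
    numeric(1)
  )
  h_smooth <- sullivan_hale(lt, tibble::tibble(age = ages, pi = smooth_pi), ci = FALSE)
  h_step <- sullivan_hale(lt, bands, ci = FALSE)
  expect_lt(abs(h_step$hale[1] - h_smooth$hale[1]), 0.3)
})

test_that("an old-age prevalence crossover flips the HALE gap sign after 70", {
  sc <- synthetic_scenario(seed = 23)
  lt_ref <- make_lt(seed = 23, group = "reference")
  lt_dis <- make_lt(seed = 23, group = "disabled")
  ages_r <- lt_ref$age
  ages_d <- lt_dis$age
  # reference: steep unhealthy rise after 70; subgroup: early plateau
  pi_ref <- 0.04 + 0.92 * plogis(0.25 * (ages_r - 77))
  pi_dis <- 0.25 + 0.15 * plogis(0.10 * (ages_d - 60))
  h_ref <- sullivan_hale(lt_ref, tibble::tibble(age = ages_r, pi = pi_ref), ci = FALSE)
  h_dis <- sullivan_hale(lt_dis, tibble::tibble(age = ages_d, pi = pi_dis), ci = FALSE)
  gap <- h_ref$hale - h_dis$hale[match(ages_r, ages_d)]
  expect_gt(gap[ages_r == 0], 0) # reference healthier at birth
  expect_lt(min(gap[ages_r > 70 & ages_r < 95]), 0) # subgroup ahead in old age
})
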
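test_that("discounting scales masses and parks the remainder unassigned", {
  fr <- make_frame(1)
  b <- belief_function(fr, c(I1 = 1))

  d1 <- discount(b, 1)
  expect_equal(d1$mass, unclass(b), ignore_attr = TRUE)
  expect_equal(d1$unassigned, 0)

  d0 <- discount(b, 0)
  expect_true(all(d0$mass == 0))
  expect_equal(d0$unassigned, 1)

  d3 <- discount(b, 1 / 3)
  expect_equal(d3$mass[subset_mask(fr, "I1")], 1 / 3)
  expect_equal(d3$unassigned, 2 / 3)
  expect_equal(sum(d3$mass) + d3$unassigned, 1)

  expect_error(discount(b, 1.1), "\\[0, 1\\]")
})

test_that("one combination step matches the hand-worked cases", {
  fr <- make_frame(1)
  r1 <- belief_function(fr, c(R1 = 1))
  i1 <- belief_function(fr, c(I1 = 1))
  vac <- belief_function(fr, c("R1+I1" = 1))

  # fully discounted source is an absorbing identity
  out <- wer_combine_step(discount(r1, 1), discount(i1, 0))
  expect_equal(out$mass[subset_mask(fr, "R1")], 1)
  expect_equal(out$unassigned, 0)

  # committed ego resists conflicting input; the conflict mass is discarded
  out <- wer_combine_step(discount(r1, 1), discount(i1, 1 / 3))
  expect_equal(out$mass[subset_mask(fr, "R1")], 1)

  # vacuous ego splits with a half-discounted committed source
  out <- wer_combine_step(discount(vac, 1), discount(r1, 0.5))
  expect_equal(out$mass[subset_mask(fr, "R1")], 0.5)
  expect_equal(out$mass[subset_mask(fr, "R1+I1")], 0.5)

  # undiscounted total conflict has no normalizer
  expect_error(wer_combine_step(discount(r1, 1), discount(i1, 1)),
               "total conflict")
})

test_that("combination matches the independent brute-force oracle", {
  set.seed(202)
  for (n in 1:2) {
    fr <- make_frame(n)
    for (rep in 1:20) {
      acc_b <- random_belief(fr)
      src_b <- random_belief(fr)
      c_acc <- runif(1)
      c_src <- runif(1)
      got <- wer_combine_step(discount(acc_b, c_acc), discount(src_b, c_src))
      want <- oracle_wer_step(oracle_from_belief(acc_b, c_acc),
                              oracle_from_belief(src_b, c_src))
      expect_oracle_equal(got$mass, fr, want$mass)
      expect_equal(got$unassigned, want$unassigned, tolerance = 1e-10)
    }
  }
})

test_that("the full social-learning fold matches the oracle for <= 3 sources", {
  set.seed(303)
  for (n in 1:2) {
    fr <- make_frame(n)
    for (rep in 1:15) {
      ego <- random_belief(fr)
      k <- sample(1:3, 1)
      ws <- sort(runif(k), decreasing = TRUE)
      sources <- lapply(seq_len(k), function(j) {
        list(belief = random_belief(fr), w = ws[j], r = runif(1))
      })
      got <- social_learn(ego, sources)
      want <- oracle_social_learn(ego, lapply(sources, function(s) {
        list(belief = s$belief, c = combined_coefficient(s$w, s$r))
      }))
      expect_oracle_equal(unclass(got), fr, want$mass, tol = 1e-9)
      expect_equal(sum(unclass(got)), 1, tolerance = 1e-9)
    }
  }
})

test_that("social learning is an identity without sources", {
  fr <- make_frame(1)
  set.seed(44)
  ego <- random_belief(fr, n_focal = 3)
  expect_identical(social_learn(ego, list()), ego)

  a <- list(belief = belief_function(fr, c(R1 = 1)), w = 0.5, r = 0.6)
  b <- list(belief = belief_function(fr, c(I1 = 1)), w = 0.5, r = 0.3)
  expect_error(social_learn(ego, list(b, list(belief = a$belief, w = 0.9, r = 0.5))),
               "descending weight")
})

test_that("learning direction and sequence change the outcome", {
  fr <- make_frame(1)
  m5 <- belief_function(fr, c(R1 = 0.7, "R1+I1" = 0.3))
  m7 <- belief_function(fr, c(I1 = 0.8, "R1+I1" = 0.2))
  # direction: who acts as ego determines the result
  i_learns <- social_learn(m5, list(list(belief = m7, w = 0.5, r = 0.6)))
  j_learns <- social_learn(m7, list(list(belief = m5, w = 0.5, r = 0.6)))
  expect_false(isTRUE(all.equal(unclass(i_learns), unclass(j_learns))))

  # sequence: position-dependent recursive reliabilities make the fold
  # order-sensitive even though the bare combination with fixed
  # coefficients is permutation-invariant
  ego <- belief_function(fr, c(R1 = 0.6, "R1+I1" = 0.4))
  jA <- belief_function(fr, c(R1 = 1))
  jB <- belief_function(fr, c(I1 = 1))
  seq_sources <- function(js) {
    lapply(seq_along(js), function(k) {
      list(belief = js[[k]], w = 0.5,
           r = map_reliability(recursive_reliability(ego, js[seq_len(k)], k)))
    })
  }
  o1 <- social_learn(ego, seq_sources(list(jA, jB)))
  o2 <- social_learn(ego, seq_sources(list(jB, jA)))
  expect_false(isTRUE(all.equal(unclass(o1), unclass(o2))))

  # with coefficients held fixed the fold commutes (conjunctive rule)
  a <- list(belief = jA, w = 0.5, r = 0.6)
  b <- list(belief = jB, w = 0.5, r = 0.3)
  expect_equal(unclass(social_learn(ego, list(a, b))),
               unclass(social_learn(ego, list(b, a))), tolerance = 1e-12)
})

test_that("a committed ego is unmoved by any conflicting source", {
  fr <- make_frame(2)
  ego <- belief_function(fr, c(I2 = 1))
  set.seed(55)
  for (rep in 1:10) {
    conflicting <- belief_function(fr, c(R1 = 1))
    out <- social_learn(ego, list(list(belief = conflicting,
                                       w = runif(1), r = runif(1))))
    expect_equal(mass_of(out, "I2"), 1)
  }
})

test_that("self-learning moves irregular mass to the chosen verb's regular form", {
  fr <- make_frame(1)
  b <- belief_function(fr, c(R1 = 0.3, I1 = 0.7))
  expect_equal(unclass(self_learn(b, 1, 0)), unclass(b))

  out <- self_learn(b, 1, 0.05)
  expect_equal(mass_of(out, "R1"), 0.335)
  expect_equal(mass_of(out, "I1"), 0.665)

  committed <- belief_function(fr, c(I1 = 1))
  expect_equal(unclass(self_learn(committed, 1, 0.05)), unclass(committed))

  # other verbs untouched
  fr2 <- make_frame(2)
  b2 <- belief_function(fr2, c(I1 = 0.5, I2 = 0.5))
  out2 <- self_learn(b2, 2, 0.1)
  expect_equal(mass_of(out2, "I1"), 0.5)
  expect_equal(mass_of(out2, "I2"), 0.45)
  expect_equal(mass_of(out2, "R2"), 0.05)
})

test_that("repeated self-learning is monotone with geometric irregular decay", {
  fr <- make_frame(1)
  b <- belief_function(fr, c(R1 = 0.2, I1 = 0.5, "R1+I1" = 0.3))
  alpha <- 0.1
  prevR <- mass_of(b, "R1")
  for (k in 1:30) {
    b <- self_learn(b, 1, alpha)
    expect_gte(mass_of(b, "R1"), prevR)
    prevR <- mass_of(b, "R1")
    expect_equal(mass_of(b, "I1"), 0.5 * (1 - alpha)^k, tolerance = 1e-12)
  }
})

test_that("forgetting shifts the strongest non-Theta mass towards ignorance", {
  fr <- make_frame(1)
  b <- belief_function(fr, c(R1 = 0.6, "R1+I1" = 0.4))
  expect_equal(unclass(forget(b, 0)), unclass(b))

  out <- forget(b, 0.04)
  expect_equal(mass_of(out, "R1"), 0.576)
  expect_equal(mass_of(out, "R1+I1"), 0.424)

  vac <- belief_function(fr, c("R1+I1" = 1))
  expect_equal(unclass(forget(vac, 0.04)), unclass(vac))

  # ties break towards the lowest bitmask
  tie <- belief_function(fr, c(R1 = 0.5, I1 = 0.5))
  out2 <- forget(tie, 0.1)
  expect_equal(mass_of(out2, "R1"), 0.45)
  expect_equal(mass_of(out2, "I1"), 0.5)
})

test_that("all learning operators conserve total mass", {
  set.seed(66)
  fr <- make_frame(2)
  for (rep in 1:20) {
    b <- random_belief(fr)
    expect_equal(sum(unclass(self_learn(b, sample(2, 1), runif(1)))), 1,
                 tolerance = 1e-9)
    expect_equal(sum(unclass(forget(b, runif(1)))), 1, tolerance = 1e-9)
    src <- list(list(belief = random_belief(fr), w = runif(1), r = runif(1)))
    expect_equal(sum(unclass(social_learn(b, src))), 1, tolerance = 1e-9)
    d <- discount(b, runif(1))
    expect_equal(sum(d$mass) + d$unassigned, 1, tolerance = 1e-9)
  }
})
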
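test_that("recruit probability follows the master-equation kernel", {
  expect_equal(recruit_prob(0, 0, pair()), 0.5)           # empty, symmetric
  expect_equal(recruit_prob(3, 8, pair()), 0.4)           # (3+1)/(8+2) at c = r
  # dispersal-dominated: state-independent cA/(cA+cB)
  hd <- pair(rA = 1e-12, rB = 1e-12, cA = 2, cB = 1)
  expect_equal(recruit_prob(0, 0, hd), 2 / 3, tolerance = 1e-9)
  expect_equal(recruit_prob(40, 100, hd), 2 / 3, tolerance = 1e-9)
  expect_error(recruit_prob(5, 3, pair()), "N_A")
})

test_that("exact AFD recursion: small cases and degenerate pools", {
  expect_equal(afd_exact(2, pair())$probabilities, rep(1 / 3, 3))
  # species B can never appear: all mass at N_A = N
  one_sided <- pair(cA = 1, cB = 0)
  expect_equal(afd_exact(10, one_sided)$probabilities, c(rep(0, 10), 1))
  expect_error(afd_exact(10000, pair()), "cap")
  expect_silent(afd_exact(0, pair()))
})

test_that("every AFD constructor returns a normalised distribution", {
  set.seed(42)
  for (i in 1:10) {
    tr <- pair(rA = runif(1, 0.1, 3), rB = runif(1, 0.1, 3),
               cA = runif(1, 0, 5), cB = runif(1, 0.01, 5))
    for (d in list(afd_exact(50, tr),
                   afd_binomial_limit(50, tr[[1]]$dispersal_rate,
                                      tr[[2]]$dispersal_rate),
                   afd_uniform_solution(50))) {
      expect_true(all(d$probabilities >= 0))
      expect_equal(sum(d$probabilities), 1, tolerance = 1e-12)
    }
  }
})

test_that("DP endpoints equal the Pochhammer closed forms across a sweep", {
  for (r in c(0.5, 1, 2)) {
    for (cc in c(1e-2, 1, 1e2)) {
      for (N in c(10, 100, 1000)) {
        tr <- pair(rA = r, rB = r, cA = cc, cB = cc)
        p <- afd_exact(N, tr)$probabilities
        expect_lt(abs(p[1] - prob_all_B(N, tr)), 1e-12)
        expect_lt(abs(p[N + 1] - prob_all_A(N, tr)), 1e-12)
      }
    }
  }
  # asymmetric traits too
  tr <- pair(rA = 0.7, rB = 1.3, cA = 0.2, cB = 2.5)
  p <- afd_exact(500, tr)$probabilities
  expect_lt(abs(p[1] - prob_all_B(500, tr)), 1e-12)
  expect_lt(abs(p[501] - prob_all_A(500, tr)), 1e-12)
})

test_that("boundary probabilities: prefactor, limits and stability at K = 1e5", {
  expect_equal(prob_all_B(1, pair()), 0.5)  # empty Pochhammer products
  # division-dominated limit with cA = 2 cB: P(0, N) -> cB/(cA+cB) = 1/3
  lowd <- pair(cA = 2e-8, cB = 1e-8)
  expect_equal(prob_all_B(1000, lowd), 1 / 3, tolerance = 1e-4)
  expect_equal(prob_all_A(1000, lowd), 2 / 3, tolerance = 1e-4)
  # log-space evaluation stays finite and sane at community size 1e5
  big <- prob_all_B(1e5, pair(cA = 0.1, cB = 0.1))
  expect_true(is.finite(big) && big >= 0 && big <= 0.5)
  expect_error(prob_all_B(10, pair(cA = 0, cB = 0)), "no assembly")
})

test_that("co-occurrence probability spans 0 to 1 and grows with dispersal", {
  expect_equal(prob_cooccurrence(1000, pair(cA = 1e-6, cB = 1e-6)), 0,
               tolerance = 1e-3)
  expect_equal(prob_cooccurrence(1000, pair(cA = 1e6, cB = 1e6)), 1,
               tolerance = 1e-6)
  cs <- 10^seq(-4, 4, length.out = 33)
  pc <- vapply(cs, function(cc) prob_cooccurrence(1e5, pair(cA = cc, cB = cc)),
               numeric(1))
  expect_true(all(diff(pc) >= -1e-12))
  expect_true(all(pc >= 0 & pc <= 1))
})

test_that("binomial limit distribution matches the dispersal-dominated DP", {
  expect_equal(afd_binomial_limit(2, 1, 1)$probabilities, c(1, 2, 1) / 4)
  bl <- afd_binomial_limit(200, 3, 1)
  expect_equal(commassembly:::afd_moments(bl)$mean, 200 * 3 / 4)
  ex <- afd_exact(200, pair(cA = 3e6, cB = 1e6))
  expect_lt(sum(abs(bl$probabilities - ex$probabilities)) / 2, 1e-2)
})

test_that("neutral moment recursion agrees with the DP oracle", {
  cases <- list(c(1, 1, 1), c(1, 1.7, 0.4), c(0.5, 0.02, 0.05), c(2, 30, 10))
  for (cs in cases) {
    for (N in c(5, 50, 500)) {
      tr <- pair(rA = cs[1], rB = cs[1], cA = cs[2], cB = cs[3])
      mdp <- commassembly:::afd_moments(afd_exact(N, tr))
      mr <- neutral_moments(N, cs[1], cs[2], cs[3])
      expect_equal(mr$raw_moments, mdp$raw_moments, tolerance = 1e-10)
      # mean is exactly N cA / (cA + cB), regime-independent
      expect_equal(mr$mean, N * cs[2] / (cs[2] + cs[3]), tolerance = 1e-12)
      # shape invariants of any distribution
      expect_gte(mr$variance, 0)
      expect_gte(mr$kurtosis, 1 - 1e-12)
      expect_gte(mr$kurtosis, mr$skewness^2 + 1 - 1e-12)
    }
  }
})

test_that("symmetric bimodality coefficient: closed form and limits", {
  # hand moments of the uniform on {0, 1, 2}: skewness 0, kurtosis 3/2
  expect_equal(bc_symmetric(2, r = 1, c = 1), 2 / 3)
  expect_equal(bc_symmetric(Inf, r = 1, c = 1), 5 / 9)
  expect_equal(bc_symmetric(Inf, r = 1, c = 1e6), 1 / 3, tolerance = 1e-5)
  expect_equal(bc_symmetric(Inf, r = 1, c = 1e-6), 1, tolerance = 1e-5)
  # the N-dependence washes out quickly at c = r
  for (N in c(1e4, 1e5, 1e6))
    expect_lt(abs(bc_symmetric(N, 1, 1) - 5 / 9), 1e-3)
  # closed form matches the DP-derived BC at moderate N
  m <- commassembly:::afd_moments(afd_exact(400, pair(cA = 0.3, cB = 0.3)))
  expect_equal(bc_symmetric(400, 1, 0.3), (m$skewness^2 + 1) / m$kurtosis,
               tolerance = 1e-10)
  expect_error(bc_symmetric(1, 1, 1), "N")
})

test_that("asymmetric-dispersal BC reduces to known limits and the recursion", {
  expect_equal(bc_asymmetric(1, 1, 1), 5 / 9)
  expect_equal(bc_asymmetric(1e-9, 2, 1), 1 / 3, tolerance = 1e-6)
  expect_equal(bc_asymmetric(1, 2, 2), bc_symmetric(Inf, 1, 2))
  for (cs in list(c(1.3, 0.6), c(2, 1), c(0.5, 0.5))) {
    m <- neutral_moments(1e4, 1, cs[1], cs[2])
    expect_equal(bc_asymmetric(1, cs[1], cs[2]),
                 (m$skewness^2 + 1) / m$kurtosis, tolerance = 1e-3)
  }
})

test_that("BC decreases monotonically with dispersal (symmetric neutral)", {
  cs <- 10^seq(-4, 4, length.out = 33)
  bc <- vapply(cs, function(cc) bc_asymmetric(1, cc, cc), numeric(1))
  expect_true(all(diff(bc) <= 1e-12))
  expect_equal(bc[1], 1, tolerance = 1e-3)
  expect_equal(bc[length(bc)], 1 / 3, tolerance = 1e-3)
})

test_that("uniform solution solves the master equation at c = r", {
  expect_equal(afd_uniform_solution(1)$probabilities, c(0.5, 0.5))
  expect_equal(afd_uniform_solution(5)$probabilities, rep(1 / 6, 6))
  for (N in c(2, 50, 500)) {
    expect_equal(afd_uniform_solution(N)$probabilities,
                 afd_exact(N, pair())$probabilities, tolerance = 1e-12)
  }
})

test_that("S-species limits: monodominance shares and multinomial composition", {
  expect_equal(monodominance_probs(c(1, 1, 1)), rep(1 / 3, 3))
  expect_equal(monodominance_probs(c(2, 1)), c(2 / 3, 1 / 3))
  # two-species case agrees with the Pochhammer closed forms as c -> 0
  lowd <- pair(cA = 2e-8, cB = 1e-8)
  expect_equal(monodominance_probs(c(2, 1)),
               c(prob_all_A(1000, lowd), prob_all_B(1000, lowd)),
               tolerance = 1e-4)
  ml <- multinomial_limit(c(1, 1, 2), 100)
  expect_equal(ml$mean, c(25, 25, 50))
  expect_equal(sum(ml$prob), 1)
  expect_error(monodominance_probs(c(0, 0)), "positive")
})
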
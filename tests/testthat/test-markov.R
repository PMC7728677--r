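# State space, rate matrix, transition probabilities, pruning, fitting.

test_that("state space is deterministic and bounded", {
  sp <- karyo_states(6, 12)
  expect_equal(nrow(sp), 8)
  expect_equal(rownames(sp)[1:4], c("6_XY", "6_neoXY", "8_XY", "8_neoXY"))
  expect_equal(nrow(karyo_states(6, 6)), 2)
  expect_error(karyo_states(8, 6), "must not exceed")
  expect_error(karyo_states(7, 13), "even")
  expect_error(karyo_states(2, 8), "at least 4")
})

test_that("rate matrix encodes exactly the four transition classes", {
  sp <- karyo_states(6, 12)
  r <- karyo_rates(delta = 0.1, gamma = 0.2, sigma = 0.3, rho = 0.4)
  Q <- karyo_rate_matrix(sp, r)
  expect_equal(Q["8_XY", "6_neoXY"], 0.3)            # SA-fusion
  expect_equal(Q["8_XY", "6_XY"], 0.1)               # AA-fusion
  expect_equal(Q["8_XY", "10_XY"], 0.2)              # fission
  expect_equal(Q["8_neoXY", "8_XY"], 0.4)            # neoXY decay
  expect_equal(Q["8_neoXY", "6_XY"], 0)              # no combined moves
  # reflecting boundaries by omission
  expect_equal(Q["6_XY", "6_neoXY"], 0)              # would leave bounds below
  expect_equal(sum(Q["12_XY", ] > 0), 2)             # no fission above max_i
  expect_equal(unname(rowSums(Q)), rep(0, 8), tolerance = 1e-14)
  expect_true(all(Q[upper.tri(Q) | lower.tri(Q)] >= 0))
  expect_equal(karyo_rate_matrix(sp, karyo_rates()), matrix(0, 8, 8,
               dimnames = list(rownames(sp), rownames(sp))))
  expect_error(karyo_rates(delta = -1), "non-negative")
})

test_that("transition probabilities match closed forms and Matrix::expm", {
  sp <- karyo_states(6, 12)
  expect_equal(transition_probs(karyo_rate_matrix(sp, karyo_rates(1, 1, 1, 1)), 0),
               diag(8), ignore_attr = TRUE)
  # rho-only chain: P(neoXY -> XY; t) = 1 - exp(-rho t)
  Qr <- karyo_rate_matrix(sp, karyo_rates(rho = 0.7))
  for (t in c(0.1, 1, 5)) {
    P <- transition_probs(Qr, t)
    expect_equal(P["8_neoXY", "8_XY"], 1 - exp(-0.7 * t), tolerance = 1e-12)
    expect_equal(P["8_XY", "8_XY"], 1)
  }
  set.seed(11)
  for (rep in 1:10) {
    Q <- karyo_rate_matrix(sp, karyo_rates(runif(1, 0, 3), runif(1, 0, 3),
                                           runif(1, 0, 3), runif(1, 0, 3)))
    t <- runif(1, 0, 4)
    P <- transition_probs(Q, t)
    expect_equal(unname(rowSums(P)), rep(1, 8), tolerance = 1e-9)
    expect_true(all(P >= 0))
    expect_equal(P, oracle_expm(Q, t), ignore_attr = TRUE, tolerance = 1e-9)
  }
  expect_error(transition_probs(Qr, -1), "non-negative")
})

test_that("pruning equals exhaustive enumeration on small trees", {
  fx <- fixture_4tip()
  pr <- karyofuse:::root_prior(fx$root, fx$space)
  ll <- karyo_loglik(fx$tree, fx$tips, fx$Q, fx$space, fx$root)
  oracle <- oracle_tree_lik(fx$tree, tip_indices(fx$tips, fx$space), fx$Q, pr)
  expect_equal(ll, log(oracle), tolerance = 1e-10)
  # flat root prior too
  llf <- karyo_loglik(fx$tree, fx$tips, fx$Q, fx$space, "flat")
  of <- oracle_tree_lik(fx$tree, tip_indices(fx$tips, fx$space), fx$Q,
                        rep(1 / 8, 8))
  expect_equal(llf, log(of), tolerance = 1e-10)
  # 3-taxon tree with random rates
  set.seed(5)
  tr3 <- read_newick("((A:0.3,B:0.8):0.2,C:1.1);", text = TRUE)
  for (rep in 1:5) {
    Q <- karyo_rate_matrix(fx$space, karyo_rates(runif(1), runif(1),
                                                 runif(1), runif(1)))
    tips3 <- data.frame(taxon = c("A", "B", "C"),
                        diploid_number = sample(c(6L, 8L, 10L, 12L), 3, TRUE),
                        system = sample(c("XY", "neoXY"), 3, TRUE))
    ll <- karyo_loglik(tr3, tips3, Q, fx$space, fx$root)
    oracle <- oracle_tree_lik(tr3, tip_indices(tips3, fx$space), Q, pr)
    if (oracle > 0) expect_equal(ll, log(oracle), tolerance = 1e-10)
    else expect_equal(ll, -Inf)
  }
})

test_that("degenerate trees give likelihood 1 or 0", {
  sp <- karyo_states(6, 12)
  Q <- karyo_rate_matrix(sp, karyo_rates(1, 1, 1, 1))
  star <- ape::read.tree(text = "((A:0,B:0):0,C:0);")
  root12 <- list(type = "fixed", i = 12L, system = "XY")
  tips_same <- data.frame(taxon = c("A", "B", "C"),
                          diploid_number = 12L, system = "XY")
  expect_equal(karyo_loglik(star, tips_same, Q, sp, root12), 0)
  tips_diff <- data.frame(taxon = c("A", "B", "C"),
                          diploid_number = c(12L, 10L, 12L), system = "XY")
  expect_equal(karyo_loglik(star, tips_diff, Q, sp, root12), -Inf)
  # unknown tip is reported by name
  expect_error(karyo_loglik(star, tips_same[-2, ], Q, sp, root12), "B")
})

test_that("maximum likelihood fitting behaves sanely", {
  sim <- synthesize(n_tips = 50, rates = karyo_rates(0.5, 0.5, 0.4, 1), seed = 3)
  fit <- karyo_fit(sim$tree, sim$tip_states, n_starts = 2, seed = 1)
  # ML beats the generating parameters on the same data
  Qtrue <- karyo_rate_matrix(sim$space, sim$true_rates)
  ll_true <- karyo_loglik(sim$tree, sim$tip_states, Qtrue, sim$space)
  expect_gte(fit$loglik, ll_true - 1e-6)
  expect_s3_class(fit, "karyo_fit")
  expect_equal(names(coef(fit)), c("delta", "gamma", "sigma", "rho"))
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  expect_equal(attr(logLik(fit), "df"), 4L)
  # constant tips at an interior state: every identifiable rate collapses
  # to the lower bound (rho stays unidentified with no neoXY time)
  tips_const <- data.frame(taxon = sim$tree$tip.label,
                           diploid_number = 10L, system = "XY")
  fit0 <- karyo_fit(sim$tree, tips_const, n_starts = 1, seed = 1,
                    root = list(type = "fixed", i = 10L, system = "XY"))
  expect_true(all(coef(fit0)[c("delta", "gamma", "sigma")] <= 1e-6))
  expect_equal(fit0$loglik, 0, tolerance = 1e-4)
  # disabling rho pins it at zero
  fit_nr <- karyo_fit(sim$tree, sim$tip_states, include_rho = FALSE,
                      n_starts = 1, seed = 1)
  expect_equal(unname(coef(fit_nr)["rho"]), 0)
  expect_equal(attr(logLik(fit_nr), "df"), 3L)
})
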
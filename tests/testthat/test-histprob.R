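test_that("the event-free probability has its closed forms", {
  zero <- make_builtin_model("homogeneous", list(gI = 0, gD = 0, gIL = 0,
                                                 gIR = 0))
  expect_equal(null_history_prob(zero, ancestry_seq(1:5), 0, 3)$value, 1)
  # constant R = 2 over a window of length 0.5
  m <- make_builtin_model("flanked", list(gI = 0, gD = 2, gIL = 0, gIR = 0))
  s <- ancestry_seq(1)            # one site -> exit rate 2 * 1 = 2
  expect_equal(null_history_prob(m, s, 0, 0.5)$value, exp(-1))
  # piecewise multiplier {1, 3} on the halves of a unit window, base rate 1
  m2 <- make_builtin_model("flanked",
    list(gI = 0, gD = 1, gIL = 0, gIR = 0,
         time_profile = list(type = "piecewise", breaks = c(0, 0.5, 1),
                             values = c(1, 3))))
  expect_equal(null_history_prob(m2, s, 0, 1)$value, exp(-2))
  expect_error(null_history_prob(m, s, 1, 0.5), "t_F < t_I")
})

test_that("single-event histories match the closed-form hypoexponential", {
  # r (e^{-R0 T} - e^{-R1 T})/(R1 - R0) for distinct exit rates
  m <- make_builtin_model("flanked", list(gI = 0, gD = 0.4, gIL = 0, gIR = 0))
  s <- ancestry_seq(1:3)                   # R0 = 1.2, after Del(2,2) R1 = 0.8
  T <- 0.7
  p <- history_prob(m, s, list(op_del(2, 2)), 0, T)
  expect_equal(p$value, 0.4 * (exp(-1.2 * T) - exp(-0.8 * T)) / (0.8 - 1.2),
               tolerance = 1e-12)
  # confluent branch: an insertion-only model with a length-independent rate
  m2 <- make_builtin_model("homogeneous", list(gI = 0, gD = 0, gIL = 0.9,
                                               gIR = 0))
  p2 <- history_prob(m2, s, list(op_ins(0, 1)), 0, T)
  expect_equal(p2$value, 0.9 * T * exp(-0.9 * T), tolerance = 1e-12)
  # N = 0 reduces to the event-free probability
  expect_equal(history_prob(m, s, list(), 0, T)$value,
               null_history_prob(m, s, 0, T)$value)
})

test_that("the divided-difference evaluator matches nested quadrature", {
  set.seed(3)
  for (i in 1:60) {
    N <- pick1(1:3)
    R <- stats::runif(N + 1, 0, 5)
    T <- stats::runif(1, 0.2, 2)
    expect_equal(hypoexp_integral(R, T), quad_simplex(R, T),
                 tolerance = 1e-9)
    expect_equal(hypoexp_integral(R, T), hypoexp_integral_dd(R, T),
                 tolerance = 1e-9)
  }
  # near-degenerate tuples (spacing 1e-6) engage the confluent regime
  for (i in 1:20) {
    R0 <- stats::runif(1, 0.5, 4)
    R <- R0 + c(0, 1e-6 * stats::runif(3))
    expect_equal(hypoexp_integral(R, 1), quad_simplex(R, 1),
                 tolerance = 1e-9)
  }
})

test_that("closed-form, quadrature and Monte-Carlo routes agree on a 2-event history", {
  m <- h_model()
  s0 <- ancestry_seq(1:7)
  ops <- list(op_del(2, 4), op_ins(3, 3))
  cf <- history_prob(m, s0, ops, 0, 1)
  qd <- history_prob(m, s0, ops, 0, 1, method = "quadrature")
  expect_equal(cf$value, qd$value, tolerance = 1e-10)
  set.seed(8)
  mc <- history_prob(m, s0, ops, 0, 1, method = "monte_carlo", mc_reps = 5e4)
  expect_lt(abs(mc$value - cf$value), 3 * mc$error)
})

test_that("piecewise-constant profiles route to quadrature consistently", {
  m <- make_builtin_model("homogeneous",
    list(gI = 0.05, gD = 0.06,
         time_profile = list(type = "piecewise", breaks = c(0, 0.4, 1),
                             values = c(2, 0.5))))
  s0 <- ancestry_seq(1:4)
  p <- history_prob(m, s0, list(op_del(2, 2)), 0, 1, method = "quadrature")
  set.seed(4)
  mc <- history_prob(m, s0, list(op_del(2, 2)), 0, 1, method = "monte_carlo",
                     mc_reps = 5e4)
  expect_lt(abs(mc$value - p$value), 3 * mc$error)
  expect_error(history_prob(m, s0, list(op_del(2, 2)), 0, 1,
                            method = "closed_form"), "constant")
})

test_that("class probabilities sum their interleavings", {
  m <- h_model()
  s0 <- ancestry_seq(1:7)
  lhs <- lhs_from_locals(s0, list(list(op_del(2, 4)), list(op_ins(6, 3))))
  members <- enumerate_class(s0, lhs)
  by_hand <- sum(vapply(members, function(h)
    history_prob(m, s0, h, 0, 1)$value, 0))
  expect_equal(lhs_class_prob(m, s0, lhs, 0, 1)$value, by_hand)
  # K = 1 class equals its single history
  lhs1 <- lhs_from_locals(s0, list(list(op_del(2, 4))))
  expect_equal(lhs_class_prob(m, s0, lhs1, 0, 1)$value,
               history_prob(m, s0, list(op_del(2, 4)), 0, 1)$value)
})

test_that("the four-event class total matches its Monte-Carlo estimate", {
  m <- h_model()
  s0 <- ancestry_seq(1:7)
  lhs <- normalize_to_lhs(s0, ex_history())
  cf <- lhs_class_prob(m, s0, lhs, 0, 1)$value
  set.seed(13)
  members <- enumerate_class(s0, lhs)
  mc <- lapply(members, function(h)
    history_prob(m, s0, h, 0, 1, method = "monte_carlo", mc_reps = 2e4))
  mc_total <- sum(vapply(mc, `[[`, 0, "value"))
  mc_se <- sqrt(sum(vapply(mc, `[[`, 0, "error")^2))
  expect_lt(abs(mc_total - cf), 3 * mc_se)
})

test_that("local multiplication factors behave", {
  m <- h_model()
  s0 <- ancestry_seq(1:7)
  expect_equal(local_mult_factor(m, s0, list(), 0, 1)$value, 1)
  f1 <- local_mult_factor(m, s0, list(op_del(2, 4)), 0, 1)$value
  expect_equal(f1, history_prob(m, s0, list(op_del(2, 4)), 0, 1)$value /
                 null_history_prob(m, s0, 0, 1)$value)
  # doubling the window tracks the quadrature oracle
  for (T in c(1, 2)) {
    q <- history_prob(m, s0, list(op_del(2, 4)), 0, T,
                      method = "quadrature")$value /
      null_history_prob(m, s0, 0, T)$value
    expect_equal(local_mult_factor(m, s0, list(op_del(2, 4)), 0, T)$value, q,
                 tolerance = 1e-9)
  }
})

test_that("per-class factorization holds for homogeneous rates and fails for flanked", {
  s0 <- ancestry_seq(1:7)
  lhs <- lhs_from_locals(s0, list(list(op_del(2, 4)), list(op_ins(6, 3))))
  g <- class_factorization_gap(h_model(), s0, lhs, 0, 1)
  expect_lt(g$gap, 1e-9)
  # K = 1: gap identically zero by definition
  g1 <- class_factorization_gap(h_model(), s0,
                                lhs_from_locals(s0, list(list(op_del(2, 4)))),
                                0, 1)
  expect_equal(g1$gap, 0)
  # flanked, short sequence, cross-zone deletions: gap > 0, sign tracking ddR
  fl <- fl_model()
  s4 <- ancestry_seq(1:4)
  lhs_fl <- lhs_from_locals(s4, list(list(op_del(2, 2)), list(op_del(4, 4))))
  gf <- class_factorization_gap(fl, s4, lhs_fl, 0, 1)
  expect_gt(gf$gap, 1e-6)
  dd <- delta_delta_exit(fl, s4, op_del(2, 2), op_del(4, 4))
  # positive ddR means the joint class decays faster than the product
  expect_equal(sign(1 - gf$mu_class / gf$mu_product), sign(dd))
})

test_that("class probability is invariant to the labeling order of locals", {
  m <- h_model()
  s0 <- ancestry_seq(1:7)
  a <- lhs_from_locals(s0, list(list(op_del(2, 4)), list(op_ins(6, 3))))
  b <- lhs_from_locals(s0, list(list(op_ins(6, 3)), list(op_del(2, 4))),
                       region_index = c(3L, 1L))
  expect_equal(lhs_class_prob(m, s0, a, 0, 1)$value,
               lhs_class_prob(m, s0, b, 0, 1)$value, tolerance = 1e-12)
})

test_that("truncated probability mass stays below one and grows with the budget", {
  m <- make_builtin_model("homogeneous", list(gI = 0.05, gD = 0.06))
  s0 <- ancestry_seq(1:2)
  T <- 0.3
  total_at <- function(nmax) {
    # all homology structures reachable within nmax effective events
    keys <- new.env(parent = emptyenv())
    reach <- function(s, depth) {
      key <- homology_key(build_pwa(s0, s))
      if (is.null(keys[[key]]) || keys[[key]] > depth) keys[[key]] <- depth
      if (depth == 0L) return(invisible())
      for (ch in enumerate_channels(m, s)) {
        s2 <- apply_op(s, ch$op, next_token = 50L + depth * 10L)
        attributes(s2) <- list(class = "ancestry_seq")
        reach(s2, depth - 1L)
      }
    }
    reach(s0, min(nmax, 2L))
    tot <- 0
    for (key in ls(keys)) {
      pwa <- pwa_from_key(key)
      tot <- tot + pwa_prob_direct(m, pwa, 0, T, N_max = nmax)$value
    }
    tot
  }
  t1 <- total_at(1L); t2 <- total_at(2L)
  expect_lt(t2, 1)
  expect_gt(t2, t1)
  expect_gt(t1, 0.9)   # small rates: most mass on few-event alignments
})
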
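test_that("long-indel construction obeys detailed balance", {
  # lambda1/mu1 = 1 forces lambda_l = mu_l
  m1 <- make_builtin_model("long_indel",
                           list(lambda1 = 0.1, mu1 = 0.1,
                                mu = 0.1 * (1:5)^-1.7 / sum((1:5)^-1.7)))
  expect_equal(m1$gI, m1$gD)
  # lambda1/mu1 = 0.5, mu_2 = 0.03 gives lambda_2 = 0.5^2 * 0.03
  m2 <- make_builtin_model("long_indel",
                           list(lambda1 = 0.015, mu1 = 0.03,
                                mu = c(0.03, 0.03, 0.01)))
  expect_equal(m2$gI[2], 0.5^2 * 0.03)
  # ratio property at every length
  li <- li_model()
  expect_equal(li$gI / li$gD, (0.02 / 0.03)^(1:4))
})

test_that("flanked deletions vanish outside the sequence", {
  fl <- fl_model()
  s <- ancestry_seq(1:4)
  ch <- enumerate_channels(fl, s)
  # effective Del(1,2): flanked has only the raw (1,2) window
  r_fl <- channel_rate(fl, s, op_del(1, 2))
  expect_equal(r_fl, fl$gD[2])
  # a sticking-out model aggregates additional raw windows onto the same op
  hm <- make_builtin_model("homogeneous", list(gI = fl$gI, gD = fl$gD))
  expect_gt(channel_rate(hm, s, op_del(1, 2)), r_fl)
})

test_that("homogeneous exit rates are exactly affine with the stated coefficients", {
  for (m in list(h_model(), dawg_model(), li_model())) {
    ab <- affine_coefficients(m)
    A_expected <- sum(m$gI) + sum(m$gD)
    B_expected <- sum((seq_len(m$LD) - 1) * m$gD) - sum(m$gI) +
      sum(m$gIL) + sum(m$gIR)
    expect_equal(ab$A, A_expected)
    expect_equal(ab$B, B_expected)
    Ls <- 1:30
    ex <- vapply(Ls, function(L) exit_rate(m, ancestry_seq(seq_len(L))), 0)
    expect_equal(ex, ab$A * Ls + ab$B, tolerance = 1e-14)
  }
})

test_that("flanked exit rates match the affine form iff L >= the deletion cutoff", {
  fl <- fl_model()      # L_D^CO = 6
  ab <- affine_coefficients(fl)
  B_fl <- -sum((seq_len(fl$LD) - 1) * fl$gD) - sum(fl$gI) +
    sum(fl$gIL) + sum(fl$gIR)
  direct <- function(L)
    (L - 1) * sum(fl$gI) + sum(fl$gIL) + sum(fl$gIR) +
      sum((L - seq_len(min(L, fl$LD)) + 1) * fl$gD[seq_len(min(L, fl$LD))])
  for (L in 1:10) {
    s <- ancestry_seq(seq_len(L))
    expect_equal(exit_rate(fl, s), direct(L), tolerance = 1e-14)
    if (L >= fl$LD - 1) {
      # the first missing deletion-length term carries a zero weight, so the
      # affine form already holds at L = L_D^CO - 1
      expect_equal(exit_rate(fl, s), ab$A * L + B_fl, tolerance = 1e-14)
    } else {
      expect_false(isTRUE(all.equal(exit_rate(fl, s), ab$A * L + B_fl)))
    }
  }
})

test_that("channel rates conserve the exit rate", {
  set.seed(5)
  models <- list(h_model(), dawg_model(), li_model(), fl_model(),
                 rh_model())
  for (i in 1:100) {
    m <- models[[pick1(seq_along(models))]]
    L <- pick1(0:12)
    s <- ancestry_seq(seq_len(L))
    ch <- enumerate_channels(m, s)
    tot <- if (length(ch)) sum(vapply(ch, `[[`, 0, "rate")) else 0
    expect_equal(tot, exit_rate(m, s), tolerance = 1e-12)
    # channels are distinct effective operators
    keys <- vapply(ch, function(c0) format_op(c0$op), "")
    expect_false(anyDuplicated(keys) > 0)
  }
})

test_that("empty sequences keep only the allowed insertion channels", {
  s0 <- ancestry_seq(integer(0))
  del_only <- make_builtin_model("homogeneous",
                                 list(gI = 0, gD = c(0.1, 0.05), gIL = 0,
                                      gIR = 0))
  expect_equal(exit_rate(del_only, s0), 0)
  expect_length(enumerate_channels(del_only, s0), 0)
  li <- li_model()
  expect_equal(exit_rate(li, s0), sum(li$whole))
  ch <- enumerate_channels(li, s0)
  expect_true(all(vapply(ch, function(c0) c0$op$type, "") == "I"))
})

test_that("a tiny homogeneous model enumerates the hand-counted channels", {
  m <- make_builtin_model("flanked", list(gI = 0.2, gD = 0.3))
  s <- ancestry_seq(1:2)
  ch <- enumerate_channels(m, s)
  keys <- sort(vapply(ch, function(c0) format_op(c0$op), ""))
  expect_equal(keys, sort(c("Ins(0,1)", "Ins(1,1)", "Ins(2,1)",
                            "Del(1,1)", "Del(2,2)")))
  expect_equal(sum(vapply(ch, `[[`, 0, "rate")), 3 * 0.2 + 2 * 0.3)
})

test_that("boundary-clipped deletions aggregate their raw channels", {
  m <- make_builtin_model("homogeneous", list(gI = 0.01, gD = c(0.3, 0.2, 0.1)))
  s <- ancestry_seq(1:2)
  # effective Del(1,2) pools raw (1,2), (0,2), (1,3), (0,3), (-1,1..) windows
  raw_sum <- 0
  for (l in 1:3) for (xB in (2 - l):2) {
    xE <- xB + l - 1
    if (max(1, xB) == 1 && min(2, xE) == 2) raw_sum <- raw_sum + m$gD[l]
  }
  expect_equal(channel_rate(m, s, op_del(1, 2)), raw_sum)
  expect_equal(raw_sum, 0.2 + 2 * 0.1)   # (1,2); (0,2),(1,3)
})

test_that("exit-rate increments are A * deltaL for homogeneous models", {
  m <- h_model()
  ab <- affine_coefficients(m)
  s <- ancestry_seq(1:8)
  for (op in list(op_ins(3, 2), op_del(2, 4), op_ins(0, 1), op_del(7, 8))) {
    expect_equal(delta_exit(m, s, op), ab$A * op_delta_L(op),
                 tolerance = 1e-12)
  }
  zero <- make_builtin_model("homogeneous", list(gI = 0, gD = 0, gIL = 0,
                                                 gIR = 0))
  expect_equal(delta_exit(zero, s, op_del(2, 2)), 0)
})

test_that("delta-delta exit rates witness (non)factorability", {
  m <- h_model()
  s <- ancestry_seq(1:8)
  expect_equal(delta_delta_exit(m, s, op_del(2, 2), op_del(6, 7)), 0,
               tolerance = 1e-12)
  expect_equal(delta_delta_exit(m, s, op_ins(2, 2), op_del(6, 7)), 0,
               tolerance = 1e-12)
  fl <- fl_model()
  s4 <- ancestry_seq(1:4)      # L = 4 < L_D^CO = 6
  dd <- delta_delta_exit(fl, s4, op_del(2, 2), op_del(4, 4))
  expect_gt(abs(dd), 1e-6)
  # cross-checked by four explicit exit-rate evaluations
  R <- function(st) exit_rate(fl, ancestry_seq(st))
  dd_manual <- (R(c(1, 2)) - R(c(1, 2, 3))) - (R(c(1, 3, 4)) - R(1:4))
  expect_equal(dd, dd_manual, tolerance = 1e-12)
  # region-heterogeneous cross-region pairs stay factorable
  rh <- rh_model()
  s12 <- ancestry_seq(1:12)
  expect_equal(delta_delta_exit(rh, s12, op_del(3, 3), op_ins(8, 1)), 0,
               tolerance = 1e-12)
})

test_that("condition probes pass and fail on the expected families", {
  cr <- check_conditions(dawg_model(), list(n = 120, seed = 1))
  expect_true(cr[[1]]$pass); expect_true(cr[[2]]$pass)
  cr2 <- check_conditions(fl_model(), list(n = 120, lengths = 4:5, seed = 1))
  expect_true(cr2[[1]]$pass); expect_false(cr2[[2]]$pass)
  expect_gt(length(cr2[[2]]$witnesses), 0)
  cr3 <- check_conditions(rh_model(), list(n = 120, seed = 3))
  expect_true(cr3[[1]]$pass); expect_true(cr3[[2]]$pass)
})

test_that("model constructors reject invalid parameters", {
  expect_error(make_builtin_model("homogeneous", list(gI = -0.1, gD = 0.1)),
               "negative")
  expect_error(make_builtin_model("region_hetero",
    list(gI = 0.02, gD = 0.03,
         regions = list(list(tokens = 1:3, dgI = 0, dgD = -0.5)))),
    "negative")
  expect_error(make_builtin_model("region_hetero",
    list(gI = 0.02, gD = 0.03,
         regions = list(list(tokens = 1:3), list(tokens = 3:5)))),
    "overlap")
})
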
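test_that("operators act as the worked history prescribes", {
  s <- ancestry_seq(1:7)
  s1 <- apply_op(s, op_del(3, 3))
  expect_equal(unclass(s1), c(1, 2, 4, 5, 6, 7), ignore_attr = TRUE)
  s2 <- apply_op(ancestry_seq(unclass(s1)), op_ins(5, 2))
  expect_equal(unclass(s2), c(1, 2, 4, 5, 6, 8, 9, 7), ignore_attr = TRUE)
  expect_error(apply_op(s, op_del(0, 0)), "empty clipped range")
  expect_error(apply_op(ancestry_seq(1:3), op_ins(4, 1)), "out of range")
  # sticking-out deletions are clipped
  s3 <- apply_op(ancestry_seq(1:4), op_del(-2, 2))
  expect_equal(unclass(s3), c(3, 4), ignore_attr = TRUE)
  expect_equal(attr(s3, "effective_op")$xB, 1L)
})

test_that("the four-event worked history replays to the printed final state", {
  rec <- apply_history(ex_ancestor(), ex_history())
  expect_equal(unclass(final_state(rec)), c(1, 5, 6, 8, 9, 10, 7),
               ignore_attr = TRUE)
  expect_length(rec$states, 5)
  # empty history leaves the state untouched
  rec0 <- apply_history(ex_ancestor(), list())
  expect_identical(unclass(final_state(rec0)), unclass(ex_ancestor()))
  # insert-then-delete restores the homology of the endpoints
  rec2 <- apply_history(ancestry_seq(1:4), list(op_ins(2, 2), op_del(3, 4)))
  expect_equal(unclass(final_state(rec2)), 1:4, ignore_attr = TRUE)
  # errors carry the failing step index
  expect_error(apply_history(ancestry_seq(1:3),
                             list(op_del(1, 3), op_del(1, 1))),
               "step 2")
})

test_that("the printed binary-equivalence example swaps as stated", {
  sp <- swap_pair(op_ins(6, 3), op_del(2, 4))
  expect_equal(format_op(sp$first), "Del(2,4)")
  expect_equal(format_op(sp$second), "Ins(3,3)")
  sp2 <- swap_pair(op_ins(5, 2), op_ins(1, 1))
  expect_equal(format_op(sp2$first), "Ins(1,1)")
  expect_equal(format_op(sp2$second), "Ins(6,2)")
  expect_error(swap_pair(op_del(2, 3), op_del(2, 3)), "not separable")
})

test_that("swapped pairs replay to identical final states (randomized)", {
  set.seed(11)
  hits <- 0L
  for (i in 1:500) {
    L <- pick1(6:12)
    s0 <- ancestry_seq(seq_len(L))
    first <- random_op(L)
    s1 <- apply_op(s0, first)
    attributes(s1) <- list(class = "ancestry_seq")
    second <- random_op(length(unclass(s1)))
    sw <- tryCatch(swap_pair(first, second), error = function(e) NULL)
    if (is.null(sw)) next
    hits <- hits + 1L
    fin1 <- final_state(apply_history(s0, list(first, second)))
    fin2 <- final_state(apply_history(s0, list(sw$first, sw$second)))
    expect_true(homology_equal(build_pwa(s0, fin1), build_pwa(s0, fin2)))
  }
  expect_gt(hits, 150)
})

test_that("the worked history normalizes to the printed local history set", {
  lhs <- normalize_to_lhs(ex_ancestor(), ex_history())
  expect_length(lhs$locals, 2)
  expect_equal(vapply(lhs$locals[[1]], format_op, ""),
               c("Del(3,3)", "Del(2,3)"))
  expect_equal(vapply(lhs$locals[[2]], format_op, ""),
               c("Ins(6,2)", "Ins(8,1)"))
  expect_equal(as.integer(lhs$N_k), c(2L, 2L))
  # LHS invariant: right-to-left replay reproduces the final state
  expect_equal(unclass(lhs_replay_final(lhs)), c(1, 5, 6, 8, 9, 10, 7),
               ignore_attr = TRUE)
})

test_that("single-event histories normalize trivially", {
  lhs <- normalize_to_lhs(ancestry_seq(1:5), list(op_del(2, 3)))
  expect_length(lhs$locals, 1)
  expect_equal(format_op(lhs$locals[[1]][[1]]), "Del(2,3)")
  expect_equal(class_size(lhs), 1L)
})

test_that("random histories satisfy the LHS replay invariant", {
  set.seed(23)
  for (i in 1:20) {
    s0 <- ancestry_seq(seq_len(pick1(5:9)))
    ops <- random_history(s0, 4L)
    fin <- final_state(apply_history(s0, ops))
    lhs <- normalize_to_lhs(s0, ops)
    expect_identical(unclass(lhs_replay_final(lhs)), unclass(fin))
  }
})

test_that("class sizes are the multinomial confirmed by enumeration", {
  lhs <- normalize_to_lhs(ex_ancestor(), ex_history())
  expect_equal(class_size(lhs), 6L)
  expect_length(enumerate_class(ex_ancestor(), lhs), 6)
  lhs3 <- lhs_from_locals(ancestry_seq(1:7),
                          list(list(op_del(1, 1)), list(op_del(3, 3)),
                               list(op_del(5, 5))))
  expect_equal(class_size(lhs3), 6L)
  expect_length(enumerate_class(ancestry_seq(1:7), lhs3), 6)
})

test_that("the two-event class contains exactly the two printed histories", {
  s0 <- ancestry_seq(1:7)
  lhs <- lhs_from_locals(s0, list(list(op_del(2, 4)), list(op_ins(6, 3))))
  mem <- enumerate_class(s0, lhs)
  sigs <- sort(vapply(mem, function(h)
    paste(vapply(h, format_op, ""), collapse = " "), ""))
  expect_equal(sigs, c("Del(2,4) Ins(3,3)", "Ins(6,3) Del(2,4)"))
})

test_that("class members all replay to the same state and re-normalize to one LHS", {
  set.seed(31)
  for (i in 1:10) {
    s0 <- ancestry_seq(seq_len(pick1(6:9)))
    ops <- random_history(s0, 3L)
    lhs <- normalize_to_lhs(s0, ops)
    mem <- enumerate_class(s0, lhs)
    expect_length(mem, class_size(lhs))
    # final states agree up to the (arbitrary) labels of inserted tokens
    fins <- vapply(mem, function(h)
      homology_key(build_pwa(s0, final_state(apply_history(s0, h)))), "")
    expect_length(unique(fins), 1)
    sigs <- vapply(mem, function(h) lhs_signature(normalize_to_lhs(s0, h)), "")
    expect_length(unique(sigs), 1)
    # the source history is among the members
    src <- paste(vapply(apply_history(s0, ops)$ops, format_op, ""),
                 collapse = " ")
    expect_true(src %in% vapply(mem, function(h)
      paste(vapply(h, format_op, ""), collapse = " "), ""))
  }
})

test_that("interleaving coordinates agree with binary-equivalence chains", {
  # for a two-event cross-region history the non-source member must equal
  # the swap_pair image
  set.seed(47)
  checked <- 0L
  for (i in 1:200) {
    L <- pick1(7:10)
    s0 <- ancestry_seq(seq_len(L))
    first <- random_op(L)
    s1 <- apply_op(s0, first)
    attributes(s1) <- list(class = "ancestry_seq")
    second <- random_op(length(unclass(s1)))
    sw <- tryCatch(swap_pair(first, second), error = function(e) NULL)
    if (is.null(sw)) next
    lhs <- normalize_to_lhs(s0, list(first, second))
    if (length(lhs$locals) != 2L) next
    mem <- enumerate_class(s0, lhs)
    sigs <- vapply(mem, function(h)
      paste(vapply(h, format_op, ""), collapse = " "), "")
    expect_true(paste(format_op(sw$first), format_op(sw$second)) %in% sigs)
    checked <- checked + 1L
  }
  expect_gt(checked, 50)
})
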
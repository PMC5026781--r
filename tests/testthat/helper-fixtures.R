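# Shared fixtures: the worked-example alignment/history and small models.

ex_ancestor <- function() ancestry_seq(1:7)
ex_descendant <- function() ancestry_seq(c(1, 5, 6, 8, 9, 10, 7))
ex_pwa <- function() build_pwa(ex_ancestor(), ex_descendant())
ex_history <- function() list(op_del(3, 3), op_ins(5, 2),
                              op_del(2, 3), op_ins(5, 1))

h_model <- function()
  make_builtin_model("homogeneous",
                     list(gI = c(0.02, 0.01, 0.005),
                          gD = c(0.03, 0.015, 0.007)))

dawg_model <- function()
  make_builtin_model("dawg", list(lambda_I = 0.03, lambda_D = 0.04,
                                  fI = c(.6, .25, .15), fD = c(.5, .3, .2)))

li_model <- function()
  make_builtin_model("long_indel",
                     list(lambda1 = 0.02, mu1 = 0.03,
                          mu = 0.03 * (1:4)^-1.7))

fl_model <- function(scale = 1)
  make_builtin_model("flanked",
                     list(gI = scale * c(0.02, 0.01),
                          gD = scale * c(0.03, 0.02, 0.01, 0.005, 0.002,
                                         0.001)))

rh_model <- function(tokens1 = 2:4, tokens2 = 8:10)
  make_builtin_model("region_hetero",
                     list(gI = 0.02, gD = 0.03,
                          regions = list(
                            list(tokens = tokens1, dgI = 0.05, dgD = 0.04),
                            list(tokens = tokens2, dgI = 0.01, dgD = 0.02))))

tree3 <- function() ape::read.tree(text = "((A:0.4,B:0.4):0.3,C:0.7);")
tree4 <- function()
  ape::read.tree(text = "((A:0.3,B:0.3):0.2,(C:0.25,D:0.25):0.25);")

# a random applicable operator on a state of length L
random_op <- function(L, max_l = 3L) {
  if (L >= 1L && stats::runif(1) < 0.5) {
    l <- pick1(seq_len(min(max_l, L)))
    a <- pick1(seq_len(L - l + 1L))
    op_del(a, a + l - 1L)
  } else {
    op_ins(pick1(0:L), pick1(seq_len(max_l)))
  }
}
pick1 <- function(v) v[sample.int(length(v), 1L)]

random_history <- function(s0, n, max_l = 3L) {
  st <- s0; ops <- list()
  counter <- max(unclass(s0)) + 1L
  for (i in seq_len(n)) {
    op <- random_op(seq_len_state2(st), max_l)
    ops[[i]] <- op
    st2 <- apply_op(st, op, next_token = counter)
    if (op$type == "I") counter <- counter + op$l
    attributes(st2) <- list(class = "ancestry_seq")
    st <- st2
  }
  ops
}
seq_len_state2 <- function(s) length(unclass(s))

# independent nested-quadrature oracle for the hypoexponential simplex
# integral over rates R_0..R_N and window T
quad_simplex <- function(R, T) {
  N <- length(R) - 1L
  inner <- function(v, tprev) {
    if (v > N) return(exp(-R[N + 1L] * (T - tprev)))
    stats::integrate(function(tau) vapply(tau, function(tt)
      exp(-R[v] * (tt - tprev)) * inner(v + 1L, tt), 0),
      tprev, T, rel.tol = 1e-11, subdivisions = 400L)$value
  }
  inner(1L, 0)
}

# parse a canonical pairwise homology key back into an alignment
pwa_from_key <- function(key) {
  rows <- strsplit(key, "|", fixed = TRUE)[[1]]
  parse <- function(r) {
    v <- strsplit(r, ",", fixed = TRUE)[[1]]
    ifelse(v == "-", NA_integer_, suppressWarnings(as.integer(v)))
  }
  structure(list(anc = parse(rows[1]), desc = parse(rows[2])),
            class = "pair_alignment")
}
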
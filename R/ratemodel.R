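#' Construct a built-in indel rate model
#'
#' Rates are defined "raw": deletion windows may stick out of the sequence
#' (the sequence is embedded in an effectively infinite chromosome), and
#' histories use effective clipped operators whose rate is the aggregate of
#' all raw channels with the same action.  All rates vanish beyond the
#' cut-off lengths \code{L_I^CO}, \code{L_D^CO}.
#'
#' Families:
#' \describe{
#'   \item{homogeneous}{space-homogeneous rates \code{g_I(l)}, \code{g_D(l)}
#'     with optional distinct end-insertion rates \code{g_IL}, \code{g_IR}.
#'     The exit rate is affine in the sequence length,
#'     \eqn{R = A L + B} with \eqn{A = \sum g_I + \sum g_D} and
#'     \eqn{B = \sum (l-1) g_D - \sum g_I + \sum (g_{IL} + g_{IR})}.}
#'   \item{dawg}{\code{g_I = lambda_I f_I(l)}, \code{g_D = lambda_D f_D(l)},
#'     end rates equal to the interior rate.}
#'   \item{long_indel}{detailed-balance family: supply \code{lambda1},
#'     \code{mu1} and the deletion-length rates \code{mu} (length
#'     \code{L_D^CO}); then \code{lambda_l = (lambda1/mu1)^l mu_l}, the end
#'     insertion rate is \code{(lambda1/mu1)^l sum_{l'>=l} mu_l'} and the
#'     whole-sequence insertion rate (used only at L = 0) is
#'     \code{(lambda1/mu1)^l sum_{l'>=l} l' mu_l'}.}
#'   \item{flanked}{space-homogeneous rates but deletions must fall entirely
#'     inside the sequence (biologically essential flanks forbid sticking
#'     out); the exit rate is affine only for \code{L >= L_D^CO}.}
#'   \item{region_hetero}{homogeneous baseline plus per-region rate
#'     increments \code{dgI}, \code{dgD} supported only inside tracked
#'     regions anchored as token sets on an initial state.}
#' }
#'
#' @param kind one of \code{"homogeneous"}, \code{"dawg"}, \code{"long_indel"},
#'   \code{"flanked"}, \code{"region_hetero"}.
#' @param params named list of family parameters (see Details).
#' @return An object of class \code{rate_model}.
#' @export
make_builtin_model <- function(kind = c("homogeneous", "dawg", "long_indel",
                                        "flanked", "region_hetero"),
                               params = list()) {
  kind <- match.arg(kind)
  p <- params
  chk <- function(v, nm) {
    if (any(v < 0)) stop(sprintf("negative rates in %s", nm)); as.numeric(v)
  }
  m <- switch(kind,
    homogeneous = {
      gI <- chk(p$gI, "gI"); gD <- chk(p$gD, "gD")
      list(gI = gI, gD = gD,
           gIL = chk(p$gIL %||% gI, "gIL"), gIR = chk(p$gIR %||% gI, "gIR"),
           sticking_out = TRUE)
    },
    dawg = {
      fI <- chk(p$fI, "fI"); fD <- chk(p$fD, "fD")
      fI <- fI / sum(fI); fD <- fD / sum(fD)
      gI <- p$lambda_I * fI; gD <- p$lambda_D * fD
      list(gI = gI, gD = gD, gIL = gI, gIR = gI, sticking_out = TRUE)
    },
    long_indel = {
      mu <- chk(p$mu, "mu")
      mu1 <- p$mu1 %||% mu[1]
      r <- p$lambda1 / mu1     # detailed-balance ratio lambda_1 / mu_1
      LD <- length(mu)
      LI <- p$LI %||% LD
      lam <- r^(seq_len(LI)) * mu[seq_len(LI)]
      lend <- r^(seq_len(LI)) *
        vapply(seq_len(LI), function(l) sum(mu[l:LD]), 0)
      lwhole <- r^(seq_len(LI)) *
        vapply(seq_len(LI), function(l) sum(seq(l, LD) * mu[l:LD]), 0)
      list(gI = lam, gD = mu, gIL = lend, gIR = lend, whole = lwhole,
           sticking_out = TRUE)
    },
    flanked = {
      gI <- chk(p$gI, "gI"); gD <- chk(p$gD, "gD")
      list(gI = gI, gD = gD,
           gIL = chk(p$gIL %||% gI, "gIL"), gIR = chk(p$gIR %||% gI, "gIR"),
           sticking_out = FALSE)
    },
    region_hetero = {
      gI <- chk(p$gI, "gI"); gD <- chk(p$gD, "gD")
      regions <- lapply(p$regions, function(rg) {
        list(tokens = as.integer(rg$tokens),
             dgI = as.numeric(rg$dgI %||% rep(0, length(gI))),
             dgD = as.numeric(rg$dgD %||% rep(0, length(gD))))
      })
      toks <- unlist(lapply(regions, `[[`, "tokens"))
      if (anyDuplicated(toks)) stop("tracked regions overlap")
      list(gI = gI, gD = gD, gIL = gI, gIR = gI, sticking_out = TRUE,
           region_spec = regions)
    })
  model <- structure(c(m, list(
    kind = kind,
    LI = length(m$gI), LD = length(m$gD),
    time_profile = p$time_profile %||% list(type = "constant"),
    regions = if (kind == "region_hetero")
      lapply(m$region_spec, `[[`, "tokens") else NULL)),
    class = "rate_model")
  # negative-total check for region increments
  if (kind == "region_hetero") {
    for (rg in model$region_spec) {
      if (any(model$gI + rg$dgI < 0) || any(model$gD + rg$dgD < 0))
        stop("region increment makes a total rate negative")
    }
  }
  model
}

#' @export
print.rate_model <- function(x, ...) {
  cat("<rate_model ", x$kind, "  L_I^CO=", x$LI, " L_D^CO=", x$LD,
      if (!x$sticking_out) "  (no sticking-out deletions)", "\n", sep = "")
  invisible(x)
}

# time-profile multiplier c(t) and its integral from a to b
profile_value <- function(model, t) {
  pr <- model$time_profile
  if (pr$type == "constant") return(rep(1, length(t)))
  if (pr$type == "piecewise") {
    idx <- findInterval(t, pr$breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    return(pr$values[idx])
  }
  stop("unsupported time profile")
}

profile_integral <- function(model, a, b) {
  pr <- model$time_profile
  if (pr$type == "constant") return(b - a)
  if (pr$type == "piecewise") {
    knots <- sort(unique(c(a, b, pr$breaks[pr$breaks > a & pr$breaks < b])))
    mids <- (knots[-1] + knots[-length(knots)]) / 2
    return(sum(diff(knots) * profile_value(model, mids)))
  }
  stop("unsupported time profile")
}

is_constant_profile <- function(model) model$time_profile$type == "constant"

# positional spans [xb, xe] of tracked regions in the current state (NULL for
# a region whose original tokens are all gone)
region_spans <- function(model, s) {
  if (is.null(model$region_spec)) return(list())
  v <- as.integer(unclass(s))
  lapply(model$region_spec, function(rg) {
    pos <- which(v %in% rg$tokens)
    if (!length(pos)) NULL else c(min(pos), max(pos))
  })
}

#' Total exit rate of a sequence state
#'
#' The sum of all insertion channels plus all raw deletion channels (including
#' sticking-out windows where the model allows them); its time integral gives
#' the no-event retention probability.  Closed-form per family; at L = 0 only
#' insertion channels remain (the whole-sequence term for the long-indel
#' family, the left-end rate otherwise).
#'
#' @param model a \code{rate_model}.
#' @param s an \code{ancestry_seq}.
#' @param t time (enters only through a non-constant time profile).
#' @return nonnegative rate.
#' @export
exit_rate <- function(model, s, t = 0) {
  L <- seq_len_state(s)
  cmult <- profile_value(model, t)
  if (L == 0L) {
    base <- if (model$kind == "long_indel") sum(model$whole) else sum(model$gIL)
    return(cmult * base)
  }
  ins <- (L - 1) * sum(model$gI) + sum(model$gIL) + sum(model$gIR)
  del <- if (model$sticking_out) {
    sum((L + seq_len(model$LD) - 1) * model$gD)
  } else {
    lmax <- min(L, model$LD)
    sum((L - seq_len(lmax) + 1) * model$gD[seq_len(lmax)])
  }
  extra <- 0
  if (!is.null(model$region_spec)) {
    spans <- region_spans(model, s)
    for (y in seq_along(spans)) {
      sp <- spans[[y]]
      if (is.null(sp)) next
      len <- sp[2] - sp[1] + 1L
      rg <- model$region_spec[[y]]
      extra <- extra + (len - 1) * sum(rg$dgI)
      lmax <- min(len, model$LD)
      if (lmax >= 1L)
        extra <- extra + sum((len - seq_len(lmax) + 1) * rg$dgD[seq_len(lmax)])
    }
  }
  cmult * (ins + del + extra)
}

#' Affine exit-rate coefficients of a space-homogeneous model
#'
#' @param model a \code{rate_model} with sticking-out deletions.
#' @param t time.
#' @return list with slope \code{A} and intercept \code{B} such that
#'   \code{exit_rate == A*L + B} for \code{L >= 1}.
#' @export
affine_coefficients <- function(model, t = 0) {
  cmult <- profile_value(model, t)
  A <- sum(model$gI) + sum(model$gD)
  B <- sum((seq_len(model$LD) - 1) * model$gD) - sum(model$gI) +
    sum(model$gIL) + sum(model$gIR)
  list(A = cmult * A, B = cmult * B)
}

#' Enumerate all single-event channels from a state
#'
#' Returns the distinct \emph{effective} operators applicable to \code{s},
#' each with the aggregated rate of every raw channel sharing its action
#' (sticking-out deletion windows are clipped and pooled).  The rates sum to
#' \code{exit_rate(model, s, t)}, which guarantees conservation of
#' probability.
#'
#' @inheritParams exit_rate
#' @return list of \code{list(op = indel_op, rate = numeric)}.
#' @export
enumerate_channels <- function(model, s, t = 0) {
  L <- seq_len_state(s)
  cmult <- profile_value(model, t)
  out <- list()
  if (L == 0L) {
    rates <- if (model$kind == "long_indel") model$whole else model$gIL
    for (l in seq_len(model$LI)) if (rates[l] > 0 || TRUE)
      out[[length(out) + 1L]] <- list(op = op_ins(0L, l), rate = cmult * rates[l])
    return(Filter(function(ch) ch$rate > 0, out))
  }
  spans <- region_spans(model, s)
  ins_extra <- function(x, l) {
    e <- 0
    for (y in seq_along(spans)) {
      sp <- spans[[y]]
      if (!is.null(sp) && x >= sp[1] && x <= sp[2] - 1L)
        e <- e + model$region_spec[[y]]$dgI[l]
    }
    e
  }
  for (x in 0:L) for (l in seq_len(model$LI)) {
    r <- if (x == 0L) model$gIL[l] else if (x == L) model$gIR[l] else model$gI[l]
    if (x > 0L && x < L) r <- r + ins_extra(x, l)
    if (r > 0)
      out[[length(out) + 1L]] <- list(op = op_ins(x, l), rate = cmult * r)
  }
  # deletions: aggregate raw windows by clipped action
  agg <- new.env(parent = emptyenv())
  add <- function(a, b, r) {
    key <- paste(a, b)
    assign(key, (get0(key, envir = agg, ifnotfound = 0)) + r, envir = agg)
  }
  for (l in seq_len(model$LD)) {
    xBs <- if (model$sticking_out) (2L - l):L else seq_len(max(0L, L - l + 1L))
    for (xB in xBs) {
      xE <- xB + l - 1L
      a <- max(1L, xB); b <- min(L, xE)
      if (a > b) next
      r <- model$gD[l]
      for (y in seq_along(spans)) {
        sp <- spans[[y]]
        if (!is.null(sp) && xB >= sp[1] && xE <= sp[2])
          r <- r + model$region_spec[[y]]$dgD[l]
      }
      if (r > 0) add(a, b, r)
    }
  }
  for (key in ls(agg)) {
    ab <- as.integer(strsplit(key, " ")[[1]])
    out[[length(out) + 1L]] <- list(op = op_del(ab[1], ab[2]),
                                    rate = cmult * get(key, envir = agg))
  }
  out
}

#' Rate of one effective operator
#'
#' The aggregated instantaneous rate of the effective operator \code{op} on
#' state \code{s}: the model rate for insertions, the pooled raw-window rate
#' for (possibly boundary-clipped) deletions.
#'
#' @inheritParams exit_rate
#' @param op an \code{indel_op} applicable to \code{s}.
#' @return nonnegative rate.
#' @export
channel_rate <- function(model, s, op, t = 0) {
  L <- seq_len_state(s)
  cmult <- profile_value(model, t)
  spans <- region_spans(model, s)
  if (op$type == "I") {
    if (op$x > L) stop("insertion anchor out of range")
    if (op$l > model$LI) return(0)
    if (L == 0L)
      return(cmult * (if (model$kind == "long_indel") model$whole[op$l]
                      else model$gIL[op$l]))
    r <- if (op$x == 0L) model$gIL[op$l]
         else if (op$x == L) model$gIR[op$l]
         else model$gI[op$l]
    if (op$x > 0L && op$x < L) {
      for (y in seq_along(spans)) {
        sp <- spans[[y]]
        if (!is.null(sp) && op$x >= sp[1] && op$x <= sp[2] - 1L)
          r <- r + model$region_spec[[y]]$dgI[op$l]
      }
    }
    return(cmult * r)
  }
  a <- op$xB; b <- op$xE
  if (a < 1L || b > L || a > b) stop("deletion not in effective (clipped) form")
  tot <- 0
  for (l in seq_len(model$LD)) {
    xBs <- if (model$sticking_out) (2L - l):L else seq_len(max(0L, L - l + 1L))
    for (xB in xBs) {
      xE <- xB + l - 1L
      if (max(1L, xB) != a || min(L, xE) != b) next
      r <- model$gD[l]
      for (y in seq_along(spans)) {
        sp <- spans[[y]]
        if (!is.null(sp) && xB >= sp[1] && xE <= sp[2])
          r <- r + model$region_spec[[y]]$dgD[l]
      }
      tot <- tot + r
    }
  }
  cmult * tot
}

#' Exit-rate increment of an event
#'
#' \eqn{\delta R = R(s') - R(s)} with \eqn{s'} the state after \code{op}.
#' For any space-homogeneous model this equals \eqn{A(t) \delta L}, the slope
#' times the length change, independently of where the event hits.
#'
#' @inheritParams channel_rate
#' @return signed rate.
#' @export
delta_exit <- function(model, s, op, t = 0) {
  s2 <- apply_op(s, op)
  attributes(s2) <- list(class = "ancestry_seq")
  exit_rate(model, s2, t) - exit_rate(model, s, t)
}

#' Degree of non-factorability of an event pair
#'
#' \eqn{\delta\delta R}: the change in the exit-rate increment of event
#' \code{op1} caused by first applying event \code{op2} in a different
#' inter-PAS region.  \code{op1} after \code{op2} is re-resolved by
#' identity-tracked replay (equivalently, the binary-equivalence coordinate
#' shift), so the same physical event is compared.  Identically zero whenever
#' the exit rate is affine in length; nonzero pairs witness non-factorable
#' alignment probabilities.
#'
#' @inheritParams exit_rate
#' @param op1,op2 \code{indel_op}s applicable to \code{s} in different
#'   regions (non-overlapping, non-adjacent footprints).
#' @return signed rate.
#' @export
delta_delta_exit <- function(model, s, op1, op2, t = 0) {
  d1 <- delta_exit(model, s, op1, t)
  s1 <- apply_op(s, op1)
  fp1 <- attr(s1, "footprint")
  s2 <- apply_op(s, op2)
  attributes(s2) <- list(class = "ancestry_seq")
  r <- resolve_footprint(s2, fp1)          # op1 re-expressed after op2
  d1b <- exit_rate(model, r$state, t) - exit_rate(model, s2, t)
  d1b - d1
}

#' Numeric falsification probe for the factorability conditions
#'
#' Condition (i): the rate of an indel event is independent of the portion of
#' the sequence outside the event's region.  Condition (ii): the exit-rate
#' increment of an event is likewise independent of outside context.  Both
#' are quantified over all states, so a finite randomized probe can only
#' falsify them: a pass means no witness was found at the given tolerance,
#' not a proof.  Each probe draws a state, an event confined to one side of a
#' randomly chosen preserved separator site, and an outside perturbation on
#' the other side; the event is re-resolved on the perturbed state by
#' identity tracking.  With tracked heterogeneity regions, events and
#' perturbations are confined to distinct tracked regions or spacers.
#'
#' @param model a \code{rate_model}.
#' @param probe_config list: \code{n} probes (default 200), \code{lengths}
#'   candidate sequence lengths, \code{seed}, \code{tol} (default 1e-9).
#' @return list of two \code{condition_report}s (conditions "i" and "ii"),
#'   each with \code{pass}, \code{witnesses}, \code{tol}, \code{n}.
#' @export
check_conditions <- function(model, probe_config = list()) {
  n <- probe_config$n %||% 200L
  lens <- probe_config$lengths %||% 6:14
  tol <- probe_config$tol %||% 1e-9
  if (!is.null(probe_config$seed)) set.seed(probe_config$seed)
  wit1 <- list(); wit2 <- list()
  for (i in seq_len(n)) {
    L <- sample(lens, 1L)
    s <- ancestry_seq(seq_len(L))
    windows <- probe_windows(model, s)
    if (is.null(windows)) next
    ev <- sample_op_in_window(model, windows$event, L)
    pe <- sample_op_in_window(model, windows$perturb, L)
    if (is.null(ev) || is.null(pe)) next
    r_before <- channel_rate(model, s, ev)
    d_before <- delta_exit(model, s, ev)
    sev <- apply_op(s, ev); fp <- attr(sev, "footprint")
    sp <- apply_op(s, pe, next_token = max(unclass(s)) + 1000L)
    attributes(sp) <- list(class = "ancestry_seq")
    res <- resolve_footprint(sp, fp)
    r_after <- channel_rate(model, sp, res$op)
    d_after <- exit_rate(model, res$state) - exit_rate(model, sp)
    if (abs(r_after - r_before) > tol)
      wit1[[length(wit1) + 1L]] <- list(state = unclass(s), event = ev,
                                        perturb = pe, before = r_before,
                                        after = r_after)
    if (abs(d_after - d_before) > tol)
      wit2[[length(wit2) + 1L]] <- list(state = unclass(s), event = ev,
                                        perturb = pe, before = d_before,
                                        after = d_after)
  }
  list(structure(list(condition = "i", pass = !length(wit1), witnesses = wit1,
                      tol = tol, n = n), class = "condition_report"),
       structure(list(condition = "ii", pass = !length(wit2), witnesses = wit2,
                      tol = tol, n = n), class = "condition_report"))
}

#' @export
print.condition_report <- function(x, ...) {
  cat("condition (", x$condition, "): ",
      if (x$pass) "pass" else sprintf("FAIL (%d witnesses)", length(x$witnesses)),
      "  [tol ", format(x$tol), ", ", x$n, " probes]\n", sep = "")
  invisible(x)
}

# choose disjoint event/perturbation windows separated by >= 1 untouched site
probe_windows <- function(model, s) {
  L <- seq_len_state(s)
  if (!is.null(model$region_spec)) {
    spans <- Filter(Negate(is.null), region_spans(model, s))
    if (length(spans) >= 2L) {
      pick <- sample(length(spans), 2L)
      a <- spans[[pick[1]]]; b <- spans[[pick[2]]]
      return(list(event = c(a[1], a[2]), perturb = c(b[1], b[2])))
    }
  }
  if (L < 4L) return(NULL)
  m <- sample(2:(L - 2L), 1L)
  w1 <- c(1L, m - 1L); w2 <- c(m + 1L, L)
  if (stats::runif(1) < 0.5) list(event = w1, perturb = w2)
  else list(event = w2, perturb = w1)
}

pick1 <- function(v) v[sample.int(length(v), 1L)]

sample_op_in_window <- function(model, w, L) {
  lo <- w[1]; hi <- w[2]
  if (hi < lo) return(NULL)
  if (stats::runif(1) < 0.5) {                      # deletion inside window
    l <- pick1(seq_len(min(model$LD, hi - lo + 1L)))
    a <- if (hi - l + 1L >= lo) pick1(lo:(hi - l + 1L)) else lo
    op_del(a, a + l - 1L)
  } else {                                          # insertion anchored inside
    xs <- (if (lo == 1L) 0L else lo):hi
    op_ins(pick1(xs), pick1(seq_len(model$LI)))
  }
}
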
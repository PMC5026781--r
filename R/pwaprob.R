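#' Minimum number of indel events for a pairwise alignment
#'
#' Each inter-PAS zone needs at least \code{ceiling(d / L_D^CO)} deletions
#' for its \code{d} deleted ancestral sites and \code{ceiling(i / L_I^CO)}
#' insertions for its \code{i} inserted sites; the zone minima add up because
#' no event may touch or cross a delimiter.  This per-region count matches
#' exhaustive search on small instances.
#'
#' @param pwa a \code{pair_alignment}.
#' @param model a \code{rate_model} (supplies the cutoffs and the optional
#'   region-merging hook).
#' @return integer.
#' @export
min_events <- function(pwa, model) {
  dec <- decompose_regions(pwa, model)
  tot <- 0L
  for (cols in dec$regions) {
    d <- sum(!is.na(pwa$anc[cols]))
    i <- sum(!is.na(pwa$desc[cols]))
    if ((d > 0L && model$LD < 1L) || (i > 0L && model$LI < 1L))
      stop("PWA infeasible under degenerate cutoffs")
    tot <- tot + ceiling(d / max(1L, model$LD)) + ceiling(i / max(1L, model$LI))
  }
  as.integer(tot)
}

# internal: context of one zone of a PWA on ancestor state sA
zone_context <- function(pwa, dec, kappa) {
  cols <- dec$regions[[kappa]]
  sA <- ancestry_seq(pwa$anc[!is.na(pwa$anc)])
  left_tok  <- if (kappa > 1L) dec$delimiter_tokens[kappa - 1L] else NA_integer_
  right_tok <- if (kappa <= length(dec$delimiter_tokens))
    dec$delimiter_tokens[kappa] else NA_integer_
  list(sA = sA,
       del_tokens = pwa$anc[cols][!is.na(pwa$anc[cols])],
       n_insert = sum(!is.na(pwa$desc[cols])),
       left_tok = left_tok, right_tok = right_tok)
}

#' Enumerate local indel histories consistent with one zone's sub-alignment
#'
#' Depth-first search over sequences of effective operators confined to one
#' inter-PAS zone of the alignment, acting in isolation on the full ancestor
#' state.  A history qualifies when its replay deletes exactly the zone's
#' ancestral sites and leaves exactly the zone's number of inserted sites,
#' with both flanking delimiters intact and no event outside the zone.
#' Non-parsimonious histories (insert-then-delete round trips and multi-step
#' decompositions) are included up to the event budget.  Search is pruned by
#' the cutoffs and by a reachability bound (the remaining budget must cover
#' the sites still to delete and insert).
#'
#' @param model a \code{rate_model}.
#' @param pwa a \code{pair_alignment}.
#' @param region zone index (1-based position in
#'   \code{decompose_regions(pwa, model)$regions}).
#' @param n_max maximum number of events for this zone.
#' @return list of local histories (each a list of \code{indel_op} in
#'   isolated coordinates on the ancestor); the empty history \code{list()}
#'   appears iff the zone's sub-alignment is empty.
#' @export
enumerate_local_histories <- function(model, pwa, region, n_max) {
  dec <- decompose_regions(pwa, model)
  ctx <- zone_context(pwa, dec, region)
  enumerate_zone_histories(model, ctx, n_max)
}

enumerate_zone_histories <- function(model, ctx, n_max) {
  sA <- ctx$sA
  counter0 <- if (seq_len_state(sA)) max(unclass(sA)) + 1L else 1L
  del_set <- as.integer(ctx$del_tokens)
  target_i <- ctx$n_insert
  LI <- model$LI; LD <- model$LD
  out <- list()
  recurse <- function(state, ops, counter) {
    v <- as.integer(unclass(state))
    posL <- if (is.na(ctx$left_tok)) 0L else match(ctx$left_tok, v)
    posR <- if (is.na(ctx$right_tok)) length(v) + 1L else match(ctx$right_tok, v)
    alive_del <- sum(v %in% del_set)
    alive_ins <- sum(v >= counter0 & seq_along(v) > posL & seq_along(v) < posR)
    if (alive_del == 0L && alive_ins == target_i)
      out[[length(out) + 1L]] <<- ops
    budget <- n_max - length(ops)
    if (budget <= 0L) return(invisible())
    lb <- ceiling((alive_del + max(0L, alive_ins - target_i)) / max(1L, LD)) +
      ceiling(max(0L, target_i - alive_ins) / max(1L, LI))
    # a non-parsimonious continuation from a goal state needs >= 2 events
    if (lb == 0L) lb <- 2L
    if (lb > budget) return(invisible())
    # deletions inside the zone
    if (posR - posL >= 2L) {
      for (a in (posL + 1L):(posR - 1L)) {
        for (b in a:min(posR - 1L, a + LD - 1L)) {
          st2 <- ancestry_seq(v[-(a:b)])
          recurse(st2, c(ops, list(op_del(a, b))), counter)
        }
      }
    }
    # insertions anchored inside the zone
    for (x in posL:(posR - 1L)) {
      for (l in seq_len(LI)) {
        fresh <- counter + seq_len(l) - 1L
        st2 <- ancestry_seq(append(v, fresh, after = x))
        recurse(st2, c(ops, list(op_ins(x, l))), counter + l)
      }
    }
    invisible()
  }
  recurse(sA, list(), counter0)
  out
}

#' Enumerate all alignment-consistent global histories up to a budget
#'
#' Takes every combination of per-zone local histories whose event counts
#' respect the budgets, forms the corresponding LHS, and expands each class
#' into its order-preserving interleavings.  The classes are disjoint and
#' every member replays to the target homology, realizing the direct-sum
#' structure of the set of alignment-consistent histories.
#'
#' @param model a \code{rate_model}.
#' @param pwa a \code{pair_alignment}.
#' @param N_max global event budget (must be \code{>= min_events}).
#' @param n_max_per_region optional integer vector of per-zone caps (recycled
#'   to the number of zones); when supplied, truncation is per-region with
#'   \code{N_max} defaulting to their sum, which is the truncation matched by
#'   the factorized route.
#' @return object of class \code{history_enumeration}: list with
#'   \code{classes} (each \code{list(lhs, histories, N)}), \code{N_min},
#'   \code{N_max}, \code{decomposition}.
#' @export
enumerate_global_histories <- function(model, pwa, N_max,
                                       n_max_per_region = NULL) {
  dec <- decompose_regions(pwa, model)
  nreg <- length(dec$regions)
  Nmin <- min_events(pwa, model)
  if (is.null(n_max_per_region)) {
    if (N_max < Nmin)
      return(structure(list(classes = list(), N_min = Nmin, N_max = N_max,
                            decomposition = dec,
                            note = "budget below the minimum event count"),
                       class = "history_enumeration"))
    caps <- rep(N_max, nreg)
  } else {
    caps <- rep_len(as.integer(n_max_per_region), nreg)
    if (missing(N_max) || is.null(N_max)) N_max <- sum(caps)
  }
  zone_min <- integer(nreg)
  locals_by_zone <- vector("list", nreg)
  for (k in seq_len(nreg)) {
    ctx <- zone_context(pwa, dec, k)
    zone_min[k] <- ceiling(length(ctx$del_tokens) / max(1L, model$LD)) +
      ceiling(ctx$n_insert / max(1L, model$LI))
    cap_k <- min(caps[k], N_max - sum(zone_min[-k]))
    locals_by_zone[[k]] <- if (cap_k < zone_min[k]) list()
      else enumerate_zone_histories(model, zone_context(pwa, dec, k), cap_k)
  }
  sA <- ancestry_seq(pwa$anc[!is.na(pwa$anc)])
  classes <- list()
  combos <- function(k, chosen, total) {
    if (total > N_max) return(invisible())
    if (k > nreg) {
      nonempty <- which(lengths(chosen) > 0L)
      lhs <- lhs_from_locals(sA, chosen[nonempty],
                             region_index = nonempty - 1L)
      hist <- enumerate_class(sA, lhs)
      classes[[length(classes) + 1L]] <<-
        list(lhs = lhs, histories = hist, N = total)
      return(invisible())
    }
    for (loc in locals_by_zone[[k]])
      combos(k + 1L, c(chosen, list(loc)), total + length(loc))
    invisible()
  }
  combos(1L, list(), 0L)
  classes <- Filter(function(cl) cl$N >= Nmin || cl$N == 0L, classes)
  # keep the null class only for a gapless target
  if (Nmin > 0L) classes <- Filter(function(cl) cl$N > 0L, classes)
  structure(list(classes = classes, N_min = Nmin, N_max = N_max,
                 decomposition = dec),
            class = "history_enumeration")
}

#' @export
print.history_enumeration <- function(x, ...) {
  nh <- sum(vapply(x$classes, function(cl) length(cl$histories), 1L))
  cat("<history_enumeration ", length(x$classes), " LHS classes, ", nh,
      " histories, N_min=", x$N_min, ", N_max=", x$N_max, ">\n", sep = "")
  invisible(x)
}

# heuristic residual-mass bound: Poisson tail at the largest exit rate seen
truncation_bound <- function(model, states, N_max, T) {
  Rmax <- max(vapply(states, function(s) exit_rate(model, s, 0), 0))
  stats::ppois(N_max, lambda = Rmax * T, lower.tail = FALSE)
}

#' Truncated perturbation expansion of a pairwise-alignment probability
#'
#' Sums \code{\link{history_prob}} over every alignment-consistent history up
#' to the budget.  Two summation routes are computed and compared: history by
#' history, and class by class (summing \code{\link{lhs_class_prob}} over the
#' LHS classes of the direct-sum decomposition); they must agree to numerical
#' precision.  A heuristic truncation bound (Poisson tail at the largest exit
#' rate seen, over the window) is reported; the state space is unbounded so
#' the bound is indicative, not rigorous.
#'
#' @inheritParams enumerate_global_histories
#' @param t_I,t_F time window.
#' @param method probability route passed to \code{\link{history_prob}}.
#' @return object of class \code{pwa_prob_report}: list with \code{value},
#'   \code{value_per_class}, \code{overall_factor} (the event-free
#'   probability of the ancestor), \code{classes} (per-class breakdown),
#'   \code{N_min}, \code{N_max}, \code{truncation_bound}, \code{method}.
#' @export
pwa_prob_direct <- function(model, pwa, t_I, t_F, N_max,
                            n_max_per_region = NULL, method = "auto") {
  enum <- enumerate_global_histories(model, pwa, N_max, n_max_per_region)
  sA <- ancestry_seq(pwa$anc[!is.na(pwa$anc)])
  null_p <- null_history_prob(model, sA, t_I, t_F)$value
  per_hist <- 0; per_class <- 0
  class_rows <- list()
  states_seen <- list(sA)
  gapless <- enum$N_min == 0L
  if (gapless) { per_hist <- null_p; per_class <- null_p }
  for (cl in enum$classes) {
    if (cl$N == 0L) next   # the null history is the overall factor itself
    vals <- vapply(cl$histories, function(ops)
      history_prob(model, sA, ops, t_I, t_F, method = method)$value, 0)
    per_hist <- per_hist + sum(vals)
    cp <- lhs_class_prob(model, sA, cl$lhs, t_I, t_F, method = method)$value
    per_class <- per_class + cp
    class_rows[[length(class_rows) + 1L]] <-
      list(signature = lhs_signature(cl$lhs), N = cl$N,
           size = length(cl$histories), prob = cp)
    for (ops in cl$histories[1])
      states_seen <- c(states_seen, apply_history(sA, ops)$states)
  }
  structure(list(value = per_hist, value_per_class = per_class,
                 overall_factor = null_p, classes = class_rows,
                 N_min = enum$N_min, N_max = enum$N_max,
                 truncation_bound = truncation_bound(model, states_seen,
                                                     enum$N_max, t_F - t_I),
                 method = method, route = "direct"),
            class = "pwa_prob_report")
}

#' @export
print.pwa_prob_report <- function(x, ...) {
  cat("<pwa_prob_report route=", x$route, "  P = ",
      format(x$value, digits = 12), ">\n", sep = "")
  invisible(x)
}

#' Multiplication factor of one alignment zone
#'
#' The total contribution of one inter-PAS zone to the factorized alignment
#' probability: the sum of \code{\link{local_mult_factor}} over every local
#' history consistent with the zone's sub-alignment, up to the budget.
#' Equals 1 for an empty zone whose budget admits only the empty history;
#' nondecreasing in the budget.
#'
#' @inheritParams enumerate_local_histories
#' @param t_I,t_F time window.
#' @param method probability route.
#' @return a \code{prob_result}.
#' @export
region_mult_factor <- function(model, pwa, region, t_I, t_F, n_max,
                               method = "auto") {
  locs <- enumerate_local_histories(model, pwa, region, n_max)
  sA <- ancestry_seq(pwa$anc[!is.na(pwa$anc)])
  val <- sum(vapply(locs, function(loc)
    local_mult_factor(model, sA, loc, t_I, t_F, method)$value, 0))
  prob_result(val, if (is_constant_profile(model)) "closed_form" else method)
}

#' Factorized pairwise-alignment probability
#'
#' The generalized-HMM-like computation: the event-free probability of the
#' ancestor times the product of per-zone multiplication factors.  Exactly
#' equal to the direct expansion at matched truncation when the model
#' satisfies the locality conditions (i) and (ii); for other models the two
#' routes differ and the discrepancy tracks the degree of non-factorability
#' \eqn{\delta\delta R}.
#'
#' @inheritParams pwa_prob_direct
#' @param n_max_per_region per-zone budgets (recycled; default: zone minimum
#'   + 1 extra event).
#' @param check if \code{TRUE}, run a quick \code{\link{check_conditions}}
#'   probe first and warn (but still report) when a condition fails.
#' @return a \code{pwa_prob_report} with per-zone \code{factors}.
#' @export
pwa_prob_factorized <- function(model, pwa, t_I, t_F, n_max_per_region = NULL,
                                method = "auto", check = FALSE) {
  dec <- decompose_regions(pwa, model)
  nreg <- length(dec$regions)
  if (check) {
    # probe at the input's own length scale: non-factorability can be
    # confined to short sequences (e.g. below the deletion cutoff)
    LA <- sum(!is.na(pwa$anc))
    rep2 <- check_conditions(model,
                             list(n = 60L, seed = 1L,
                                  lengths = seq(max(4L, LA - 2L), LA + 3L)))
    if (!rep2[[1]]$pass || !rep2[[2]]$pass)
      warning("model fails a factorability condition; ",
              "the factorized value is an approximation")
  }
  zone_min <- vapply(seq_len(nreg), function(k) {
    ctx <- zone_context(pwa, dec, k)
    as.integer(ceiling(length(ctx$del_tokens) / max(1L, model$LD)) +
                 ceiling(ctx$n_insert / max(1L, model$LI)))
  }, 1L)
  caps <- if (is.null(n_max_per_region)) zone_min + 1L
          else rep_len(as.integer(n_max_per_region), nreg)
  sA <- ancestry_seq(pwa$anc[!is.na(pwa$anc)])
  null_p <- null_history_prob(model, sA, t_I, t_F)$value
  factors <- vapply(seq_len(nreg), function(k)
    region_mult_factor(model, pwa, k, t_I, t_F, caps[k], method)$value, 0)
  structure(list(value = null_p * prod(factors), overall_factor = null_p,
                 factors = factors, n_max_per_region = caps,
                 N_min = min_events(pwa, model), N_max = sum(caps),
                 method = method, route = "factorized"),
            class = "pwa_prob_report")
}
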
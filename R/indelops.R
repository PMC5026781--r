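#' Indel operators
#'
#' \code{op_ins(x, l)} inserts \code{l} fresh sites between the \code{x}-th
#' and (\code{x}+1)-th sites (\code{x = 0} means the left end).
#' \code{op_del(xB, xE)} deletes the subsequence between (and including) the
#' \code{xB}-th and \code{xE}-th sites; ranges sticking out of the sequence
#' are clipped to \code{max(1, xB) .. min(L, xE)} on application (the sequence
#' is regarded as embedded in a chromosome of virtually infinite length).
#'
#' @param x insertion anchor, \code{0 <= x <= L}.
#' @param l inserted length, \code{>= 1}.
#' @param xB,xE deletion range, \code{xB <= xE}.
#' @return An object of class \code{indel_op}.
#' @export
op_ins <- function(x, l) {
  x <- as.integer(x); l <- as.integer(l)
  if (l < 1L) stop("insertion length must be >= 1")
  if (x < 0L) stop("insertion anchor must be >= 0")
  structure(list(type = "I", x = x, l = l), class = "indel_op")
}

#' @rdname op_ins
#' @export
op_del <- function(xB, xE) {
  xB <- as.integer(xB); xE <- as.integer(xE)
  if (xB > xE) stop("deletion range requires xB <= xE")
  structure(list(type = "D", xB = xB, xE = xE), class = "indel_op")
}

#' @export
print.indel_op <- function(x, ...) {
  cat(format_op(x), "\n"); invisible(x)
}

format_op <- function(op) {
  if (op$type == "I") sprintf("Ins(%d,%d)", op$x, op$l)
  else sprintf("Del(%d,%d)", op$xB, op$xE)
}

op_delta_L <- function(op) if (op$type == "I") op$l else -(op$xE - op$xB + 1L)

#' Apply a single indel operator to a sequence state
#'
#' Surviving sites keep their tokens and relative order; insertions splice in
#' fresh consecutive tokens drawn from a monotone counter.
#'
#' @param state an \code{ancestry_seq}.
#' @param op an \code{indel_op}.
#' @param next_token first fresh token for an insertion; defaults to one more
#'   than the largest token seen in \code{state}.
#' @return the new \code{ancestry_seq}; attribute \code{"footprint"} records
#'   the event's identity trace (deleted tokens, or anchor token plus inserted
#'   tokens) and attribute \code{"effective_op"} the clipped operator.
#' @export
apply_op <- function(state, op, next_token = NULL) {
  s <- as.integer(unclass(state)); L <- length(s)
  if (op$type == "I") {
    if (op$x > L) stop("insertion anchor out of range (x > L)")
    if (is.null(next_token)) next_token <- if (L) max(s) + 1L else 1L
    fresh <- as.integer(next_token + seq_len(op$l) - 1L)
    out <- append(s, fresh, after = op$x)
    fp <- list(type = "I",
               anchor = if (op$x == 0L) 0L else s[op$x],
               tokens = fresh)
    eff <- op
  } else {
    a <- max(1L, op$xB); b <- min(L, op$xE)
    if (a > b) stop("deletion with empty clipped range")
    fp <- list(type = "D", tokens = s[a:b])
    out <- s[-(a:b)]
    eff <- op_del(a, b)
  }
  res <- ancestry_seq(out)
  attr(res, "footprint") <- fp
  attr(res, "effective_op") <- eff
  res
}

#' Apply an indel history, recording every intermediate state
#'
#' @param state initial \code{ancestry_seq}.
#' @param ops list of \code{indel_op}, earliest first.
#' @return A \code{history_record}: list with \code{states} (s_0 .. s_N),
#'   \code{ops} (effective, clipped forms), \code{footprints}, and the token
#'   \code{counter} after the last insertion.
#' @export
apply_history <- function(state, ops) {
  s <- ancestry_seq(unclass(state))
  counter <- if (length(unclass(s))) max(unclass(s)) + 1L else 1L
  states <- list(s); fps <- list(); effs <- list()
  for (i in seq_along(ops)) {
    s2 <- tryCatch(apply_op(s, ops[[i]], next_token = counter),
                   error = function(e)
                     stop(sprintf("step %d (%s): %s", i, format_op(ops[[i]]),
                                  conditionMessage(e)), call. = FALSE))
    fps[[i]] <- attr(s2, "footprint")
    effs[[i]] <- attr(s2, "effective_op")
    if (ops[[i]]$type == "I") counter <- counter + ops[[i]]$l
    attributes(s2) <- list(class = "ancestry_seq")
    s <- s2
    states[[i + 1L]] <- s
  }
  structure(list(states = states, ops = effs, footprints = fps,
                 counter = counter),
            class = "history_record")
}

final_state <- function(rec) rec$states[[length(rec$states)]]

# Resolve a footprint against a concrete current state, returning the concrete
# operator and the new state.  Identity-tracked replay: positions are looked
# up from tokens, so no shift arithmetic compounds across interleavings.
resolve_footprint <- function(state, fp) {
  s <- as.integer(unclass(state))
  if (fp$type == "D") {
    pos <- match(fp$tokens, s)
    if (anyNA(pos)) stop("footprint tokens absent from state")
    if (!all(diff(pos) == 1L)) stop("footprint tokens not contiguous")
    list(op = op_del(min(pos), max(pos)), state = ancestry_seq(s[-pos]))
  } else {
    x <- if (fp$anchor == 0L) 0L else match(fp$anchor, s)
    if (is.na(x)) stop("anchor token absent from state")
    list(op = op_ins(x, length(fp$tokens)),
         state = ancestry_seq(append(s, fp$tokens, after = x)))
  }
}

#' Swap two temporally adjacent indel events separated by at least a PAS
#'
#' Implements the four binary equivalence relations between insertion and
#' deletion operators acting in different inter-PAS regions.  Given the pair
#' (\code{first}, \code{second}) applied in that temporal order, returns the
#' pair that applied in swapped order yields the identical final state on any
#' admissible sequence.  Verbally: the operator for the event on the left
#' along the sequence is unchanged by the swap; the operator for the event on
#' the right shifts its position left/right by the number of sites
#' deleted/inserted before it when it comes second.
#'
#' @param first,second \code{indel_op}s in temporal order.
#' @param direction \code{"auto"} tries the printed precondition with the pair
#'   matched to either side of the relation; \code{"forward"}/\code{"reverse"}
#'   force one matching.
#' @return list with elements \code{first}, \code{second}: the swapped pair.
#' @export
swap_pair <- function(first, second, direction = c("auto", "forward", "reverse")) {
  direction <- match.arg(direction)
  try_fwd <- direction %in% c("auto", "forward")
  try_rev <- direction %in% c("auto", "reverse")
  lp <- function(op) min(op$xE - op$xB + 1L, op$xE)  # clipped deleted length
  if (first$type == "I" && second$type == "I") {
    if (try_fwd && first$x > second$x)                       # second is left
      return(list(first = second, second = op_ins(first$x + second$l, first$l)))
    if (try_rev && second$x - first$l > first$x)             # second is right
      return(list(first = op_ins(second$x - first$l, second$l), second = first))
  } else if (first$type == "D" && second$type == "I") {
    if (try_fwd && first$xB > second$x + 1L)
      return(list(first = second,
                  second = op_del(first$xB + second$l, first$xE + second$l)))
    if (try_rev && second$x + lp(first) > first$xE)
      return(list(first = op_ins(second$x + lp(first), second$l), second = first))
  } else if (first$type == "I" && second$type == "D") {
    if (try_fwd && first$x > second$xE)
      return(list(first = second, second = op_ins(first$x - lp(second), first$l)))
    if (try_rev && second$xB - first$l > first$x + 1L)
      return(list(first = op_del(second$xB - first$l, second$xE - first$l),
                  second = first))
  } else {
    if (try_fwd && first$xB > second$xE + 1L)
      return(list(first = second,
                  second = op_del(first$xB - lp(second), first$xE - lp(second))))
    if (try_rev && second$xB + lp(first) > first$xE + 1L)
      return(list(first = op_del(second$xB + lp(first), second$xE + lp(first)),
                  second = first))
  }
  stop("events are not separable: no binary equivalence relation applies")
}

#' Normalize a global indel history to its local-history-set (LHS)
#'
#' Sorts the events of a global history into the inter-PAS regions of the
#' history's own resulting pairwise alignment, preserving temporal order
#' within each region, and re-expresses each region's events in isolated
#' coordinates on the initial state.  Every global history normalizes; the
#' LHS is the canonical representative of its equivalence class.
#'
#' @param initial \code{ancestry_seq} the history starts from.
#' @param ops list of \code{indel_op}.
#' @return An object of class \code{lhs}: list with \code{initial},
#'   \code{locals} (per-region lists of isolated-coordinate \code{indel_op}),
#'   \code{footprints} (per-region identity traces), \code{region_index}
#'   (which inter-PAS zone, 0-based from the left end zone), \code{N_k},
#'   \code{pwa} (the history's own PWA).
#' @export
normalize_to_lhs <- function(initial, ops) {
  rec <- apply_history(initial, ops)
  fin <- final_state(rec)
  pwa <- build_pwa(initial, fin)
  pas <- pas_set(pwa)
  # region of every token: zone i lies between pas[i] and pas[i+1] (0-based
  # left end zone = 0); PAS tokens are delimiters (region NA).
  reg <- new.env(parent = emptyenv())
  a <- as.integer(unclass(initial))
  zone <- 0L
  for (tok in a) {
    if (tok %in% pas) { zone <- zone + 1L; assign(as.character(tok), NA_integer_, reg) }
    else assign(as.character(tok), zone, reg)
  }
  region_of <- function(tok) {
    if (tok == 0L) return(0L)
    v <- get0(as.character(tok), envir = reg, ifnotfound = NULL)
    if (is.null(v)) stop("untracked token")
    v
  }
  ev_region <- integer(length(ops))
  for (i in seq_along(rec$footprints)) {
    fp <- rec$footprints[[i]]
    if (fp$type == "D") {
      rr <- vapply(fp$tokens, region_of, 1L)
      if (anyNA(rr) || length(unique(rr)) != 1L)
        stop("deletion footprint crosses a PAS of the history")   # impossible
      ev_region[i] <- rr[1]
    } else {
      anc_reg <- region_of(fp$anchor)
      if (is.na(anc_reg)) {                       # anchored right of a PAS
        anc_reg <- which(pas == fp$anchor)        # zone to its right
      }
      ev_region[i] <- anc_reg
      for (tok in fp$tokens) assign(as.character(tok), anc_reg, reg)
    }
  }
  regions_used <- sort(unique(ev_region))
  locals <- list(); fps <- list()
  for (k in seq_along(regions_used)) {
    idx <- which(ev_region == regions_used[k])
    fps[[k]] <- rec$footprints[idx]
    # isolated replay on the initial state gives isolated coordinates
    st <- ancestry_seq(unclass(initial))
    lops <- list()
    for (fp in fps[[k]]) {
      r <- resolve_footprint(st, fp)
      lops[[length(lops) + 1L]] <- r$op
      st <- r$state
    }
    locals[[k]] <- lops
  }
  structure(list(initial = ancestry_seq(unclass(initial)), locals = locals,
                 footprints = fps, region_index = regions_used,
                 N_k = lengths(locals), pwa = pwa),
            class = "lhs")
}

#' Build an LHS directly from isolated local histories
#'
#' @param initial \code{ancestry_seq}.
#' @param locals list (left-to-right along the ancestor) of lists of
#'   \code{indel_op} in isolated coordinates on \code{initial}.
#' @param region_index optional 0-based zone indices (defaults to the zones of
#'   the replayed result).
#' @return an \code{lhs}.
#' @export
lhs_from_locals <- function(initial, locals, region_index = NULL) {
  counter <- if (length(unclass(initial))) max(unclass(initial)) + 1L else 1L
  fps <- list()
  for (k in seq_along(locals)) {
    st <- ancestry_seq(unclass(initial))
    fk <- list()
    for (op in locals[[k]]) {
      st2 <- apply_op(st, op, next_token = counter)
      fk[[length(fk) + 1L]] <- attr(st2, "footprint")
      if (op$type == "I") counter <- counter + op$l
      attributes(st2) <- list(class = "ancestry_seq")
      st <- st2
    }
    fps[[k]] <- fk
  }
  obj <- structure(list(initial = ancestry_seq(unclass(initial)), locals = locals,
                        footprints = fps,
                        region_index = region_index %||% seq_along(locals) - 1L,
                        N_k = lengths(locals), pwa = NULL),
                   class = "lhs")
  obj$pwa <- build_pwa(initial, lhs_replay_final(obj))
  obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Replay locals in right-to-left region order (K first) on the initial state.
lhs_replay_final <- function(lhs) {
  st <- ancestry_seq(unclass(lhs$initial))
  for (k in rev(seq_along(lhs$footprints))) {
    for (fp in lhs$footprints[[k]]) {
      r <- resolve_footprint(st, fp)
      st <- r$state
    }
  }
  st
}

#' Number of global histories in an LHS equivalence class
#'
#' The members are the order-preserving interleavings of the K local event
#' lists, so the count is the multinomial coefficient
#' \eqn{N! / \prod_k N_k!}.  (The factorials in the denominator are confirmed
#' by explicit enumeration.)
#'
#' @param lhs an \code{lhs}.
#' @return integer.
#' @export
class_size <- function(lhs) {
  n <- lhs$N_k
  if (!length(n)) return(1L)
  tot <- 0L; out <- 1
  for (k in seq_along(n)) { tot <- tot + n[k]; out <- out * choose(tot, n[k]) }
  as.integer(round(out))
}

#' Enumerate every global history of an LHS equivalence class
#'
#' Generates all order-preserving interleavings of the local histories;
#' per-step operator parameters are derived by identity-tracked replay, so
#' coordinate shifts never compound.  Each member replays to the same final
#' state.
#'
#' @param initial \code{ancestry_seq} (must equal the LHS's initial state).
#' @param lhs an \code{lhs}.
#' @return list of histories; each history is a list of \code{indel_op}.
#' @export
enumerate_class <- function(initial, lhs) {
  if (!identical(as.integer(unclass(initial)), as.integer(unclass(lhs$initial))))
    stop("initial state does not match the LHS")
  K <- length(lhs$footprints)
  seqs <- interleavings(lhs$N_k)
  lapply(seqs, function(lab) {
    ptr <- integer(K)
    st <- ancestry_seq(unclass(initial))
    ops <- vector("list", length(lab))
    for (i in seq_along(lab)) {
      k <- lab[i]; ptr[k] <- ptr[k] + 1L
      r <- resolve_footprint(st, lhs$footprints[[k]][[ptr[k]]])
      ops[[i]] <- r$op
      st <- r$state
    }
    ops
  })
}

# All sequences over labels 1..K containing N_k copies of k, preserving
# within-label order (i.e., multiset permutations).
interleavings <- function(nk) {
  K <- length(nk)
  if (!K || sum(nk) == 0L) return(list(integer(0)))
  out <- list()
  recurse <- function(remaining, acc) {
    if (all(remaining == 0L)) { out[[length(out) + 1L]] <<- acc; return(invisible()) }
    for (k in seq_len(K)) if (remaining[k] > 0L) {
      r2 <- remaining; r2[k] <- r2[k] - 1L
      recurse(r2, c(acc, k))
    }
  }
  recurse(as.integer(nk), integer(0))
  out
}

# Canonical comparable signature of an LHS: region indices plus isolated ops.
lhs_signature <- function(lhs) {
  paste(vapply(seq_along(lhs$locals), function(k) {
    ops <- vapply(lhs$locals[[k]], format_op, "")
    paste0("r", lhs$region_index[k], ":", paste(ops, collapse = ";"))
  }, ""), collapse = "|")
}

#' @export
print.lhs <- function(x, ...) {
  cat("<lhs K=", length(x$locals), " N=", sum(x$N_k), ">\n", sep = "")
  for (k in seq_along(x$locals)) {
    cat("  k=", k, " (zone ", x$region_index[k], "): ",
        paste(vapply(x$locals[[k]], format_op, ""), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
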
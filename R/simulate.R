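#' Gillespie simulation of the indel process along a time axis
#'
#' Samples an indel history by the stochastic simulation algorithm: waiting
#' times are exponential at the total exit rate of the current state, and the
#' event channel is drawn proportionally to the aggregated effective-channel
#' rates.  Piecewise-constant time profiles are simulated piece by piece with
#' memoryless carry-over at the breakpoints.  The logged events replay
#' exactly to the final state.
#'
#' @param model a \code{rate_model} (constant or piecewise-constant profile).
#' @param s0 initial \code{ancestry_seq}.
#' @param t_I,t_F window.
#' @param counter first fresh ancestry token (default: \code{max(s0) + 1}).
#' @return object of class \code{sim_result}: list with \code{initial},
#'   \code{final}, \code{ops}, \code{times}, \code{counter}.
#' @export
gillespie_branch <- function(model, s0, t_I, t_F, counter = NULL) {
  s <- ancestry_seq(unclass(s0))
  if (is.null(counter))
    counter <- if (seq_len_state(s)) max(unclass(s)) + 1L else 1L
  pr <- model$time_profile
  knots <- if (pr$type == "constant") c(t_I, t_F)
           else sort(unique(c(t_I, t_F, pr$breaks[pr$breaks > t_I & pr$breaks < t_F])))
  ops <- list(); times <- numeric(0)
  t <- t_I
  piece <- 1L
  repeat {
    ch <- enumerate_channels(model, s, t)
    rates <- vapply(ch, `[[`, 0, "rate")
    Rtot_base <- sum(rates) / profile_value(model, t)
    if (Rtot_base <= 0) break
    # advance through profile pieces until an event fires or t_F is reached
    fired <- FALSE
    u <- stats::rexp(1)                 # unit-exponential quantile, carried over
    while (TRUE) {
      hi <- knots[findInterval(t, knots, rightmost.closed = TRUE,
                               all.inside = TRUE) + 1L]
      v <- profile_value(model, (t + hi) / 2)
      need <- u / max(Rtot_base * v, .Machine$double.xmin)
      if (Rtot_base * v > 0 && t + need <= hi) { t <- t + need; fired <- TRUE; break }
      u <- u - Rtot_base * v * (hi - t)
      t <- hi
      if (t >= t_F) break
    }
    if (!fired || t >= t_F) break
    k <- sample.int(length(ch), 1L, prob = rates)
    op <- ch[[k]]$op
    s2 <- apply_op(s, op, next_token = counter)
    if (op$type == "I") counter <- counter + op$l
    attributes(s2) <- list(class = "ancestry_seq")
    s <- s2
    ops[[length(ops) + 1L]] <- op
    times <- c(times, t)
  }
  structure(list(initial = ancestry_seq(unclass(s0)), final = s, ops = ops,
                 times = times, counter = counter, t_I = t_I, t_F = t_F),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result ", length(x$ops), " events on [",
      x$t_I, ", ", x$t_F, "]>\n", sep = "")
  invisible(x)
}

#' Simulate an indel history along a rooted tree
#'
#' Recursively simulates each branch from the root; the descendant state of a
#' branch seeds its child branches, so the branch histories are
#' interdependent exactly as the model prescribes.  The true multiple
#' alignment of the leaf states is assembled from a site registry that splices
#' every insertion (from any lineage) into a global column order, so two
#' sites align iff they share an ancestry token.  Per-branch random substreams
#' are derived from \code{(seed, branch index)}, making the result independent
#' of traversal order.
#'
#' @param models a \code{rate_model}, or a list of one per edge (indexed as
#'   in \code{tree$edge}).
#' @param tree a rooted \code{ape::phylo} with branch lengths.
#' @param root an \code{ancestry_seq}, or a \code{root_prior} to sample the
#'   root length from.
#' @param seed optional integer; per-branch substreams are derived from it.
#' @return object of class \code{tree_sim_result}: list with
#'   \code{node_states} (list indexed by node id), \code{branch} (per-edge
#'   \code{sim_result}), \code{msa} (the true \code{msa_alignment} among the
#'   leaves), \code{tree}.
#' @export
simulate_tree <- function(models, tree, root, seed = NULL) {
  if (inherits(models, "rate_model")) {
    mlist <- rep(list(models), nrow(tree$edge))
  } else mlist <- models
  ntip <- length(tree$tip.label)
  rootnode <- ntip + 1L
  if (inherits(root, "root_prior")) {
    L0 <- sample_root_length(root)
    root <- ancestry_seq(seq_len(L0))
  }
  times <- ape::node.depth.edgelength(tree)   # root-to-node path lengths
  node_states <- vector("list", max(tree$edge))
  node_states[[rootnode]] <- ancestry_seq(unclass(root))
  branch <- vector("list", nrow(tree$edge))
  counter <- if (seq_len_state(root)) max(unclass(root)) + 1L else 1L
  # site registry: global column order; sentinel 0 at the front
  registry <- c(0L, as.integer(unclass(root)))
  edges_from <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  recurse <- function(node) {
    for (e in edges_from[[as.character(node)]] %||% integer(0)) {
      child <- tree$edge[e, 2]
      if (!is.null(seed))
        set.seed((as.integer(seed) %% 1000003L) * 1009L + e)
      res <- gillespie_branch(mlist[[e]], node_states[[node]],
                              times[node], times[child], counter = counter)
      counter <<- res$counter
      registry <<- splice_history(registry, node_states[[node]], res)
      node_states[[child]] <<- res$final
      branch[[e]] <<- res
      recurse(child)
    }
  }
  recurse(rootnode)
  # assemble MSA columns: every registry token present in >= 1 leaf
  leafsets <- lapply(seq_len(ntip), function(i) as.integer(unclass(node_states[[i]])))
  alive <- registry[registry %in% unique(unlist(leafsets))]
  msa_rows <- lapply(leafsets, function(v) ifelse(alive %in% v, alive, NA_integer_))
  names(msa_rows) <- tree$tip.label
  structure(list(node_states = node_states, branch = branch,
                 msa = msa_alignment(msa_rows), tree = tree,
                 registry = registry),
            class = "tree_sim_result")
}

# replay one branch history over the registry, inserting fresh tokens at the
# right global positions (deleted tokens stay in the registry: they may be
# alive in other lineages)
splice_history <- function(registry, start_state, res) {
  st <- as.integer(unclass(start_state))
  # counter at branch start: the recorded end counter minus all fresh draws
  ins_ls <- vapply(res$ops, function(op) if (op$type == "I") op$l else 0L, 1L)
  counter <- res$counter - sum(ins_ls)
  for (op in res$ops) {
    if (op$type == "D") {
      st <- st[-(op$xB:op$xE)]
    } else {
      fresh <- counter + seq_len(op$l) - 1L
      anchor <- if (op$x == 0L) {
        # before the first site of the current state; splice right after the
        # registry predecessor of that site (sentinel if state empty at left)
        if (length(st)) {
          pos_first <- match(st[1], registry)
          registry[pos_first - 1L]
        } else 0L
      } else st[op$x]
      pos <- match(anchor, registry)
      registry <- append(registry, fresh, after = pos)
      st <- append(st, fresh, after = op$x)
      counter <- counter + op$l
    }
  }
  registry
}

#' Empirical distribution of pairwise homology structures
#'
#' Repeated branch simulations binned by the canonical homology of the
#' resulting ancestor-descendant alignment: the Monte-Carlo oracle for the
#' truncated expansion.
#'
#' @inheritParams gillespie_branch
#' @param T window length.
#' @param n_reps number of replicates.
#' @return data.frame with columns \code{key} (canonical homology
#'   signature), \code{count}, \code{freq}, \code{se}.
#' @export
empirical_distribution <- function(model, s0, T, n_reps) {
  keys <- vapply(seq_len(n_reps), function(i) {
    res <- gillespie_branch(model, s0, 0, T)
    homology_key(build_pwa(s0, res$final))
  }, "")
  tab <- sort(table(keys), decreasing = TRUE)
  p <- as.numeric(tab) / n_reps
  data.frame(key = names(tab), count = as.integer(tab), freq = p,
             se = sqrt(p * (1 - p) / n_reps), stringsAsFactors = FALSE)
}
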
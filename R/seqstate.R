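#' Ancestry-indexed sequence states
#'
#' A basic sequence state is an ordered array of pairwise-distinct ancestry
#' tokens (positive integers by convention).  Tokens are opaque identity
#' labels: two sites in different sequences are homologous if and only if they
#' carry the same token, and any bijective relabeling yields an equivalent
#' state.  Sites present in both an ancestor and its descendant are the
#' preserved ancestral sites (PASs); they delimit the local regions on which
#' alignment probabilities factorize.
#'
#' @param ids integer vector of pairwise-distinct tokens (may be empty).
#' @return An object of class \code{ancestry_seq} (an integer vector).
#' @export
ancestry_seq <- function(ids = integer(0)) {
  ids <- as.integer(ids)
  if (anyNA(ids)) stop("ancestry tokens must not be NA")
  if (anyDuplicated(ids)) stop("ancestry tokens must be pairwise distinct")
  structure(ids, class = "ancestry_seq")
}

#' @export
print.ancestry_seq <- function(x, ...) {
  cat("<ancestry_seq L=", length(x), ">  ", paste(unclass(x), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

seq_len_state <- function(s) length(unclass(s))

#' Pairwise alignment of two ancestry sequences
#'
#' Builds the unique homology structure between an ancestor and a descendant
#' from their shared tokens.  Shared tokens (the PASs) must occur in the same
#' relative order in both sequences; a violation means a rearrangement, which
#' is outside the scope of the pure indel model.  Within one inter-PAS zone
#' that contains both ancestor-only and descendant-only sites, all deletion
#' columns are emitted before all insertion columns; this fixes a canonical
#' column order without affecting the homology structure.
#'
#' @param ancestor,descendant \code{ancestry_seq} objects.
#' @return A \code{pair_alignment}: a list with integer vectors \code{anc} and
#'   \code{desc} of equal length, \code{NA} marking gaps.  No column is
#'   gap/gap.
#' @export
build_pwa <- function(ancestor, descendant) {
  a <- as.integer(unclass(ancestor))
  d <- as.integer(unclass(descendant))
  shared <- intersect(a, d)
  # order check: shared tokens must appear in the same relative order
  if (!identical(a[a %in% shared], d[d %in% shared])) {
    stop("shared tokens out of order: rearrangements are outside the model scope")
  }
  pas <- a[a %in% shared]
  anc_col <- integer(0); desc_col <- integer(0)
  ia <- 1L; id <- 1L
  emit_zone <- function(del, ins) {
    anc_col  <<- c(anc_col,  del, rep(NA_integer_, length(ins)))
    desc_col <<- c(desc_col, rep(NA_integer_, length(del)), ins)
  }
  for (p in c(pas, NA_integer_)) {   # NA sentinel flushes the final end zone
    if (is.na(p)) { ja <- length(a) + 1L; jd <- length(d) + 1L }
    else { ja <- which(a == p); jd <- which(d == p) }
    del <- if (ja > ia) a[ia:(ja - 1L)] else integer(0)
    ins <- if (jd > id) d[id:(jd - 1L)] else integer(0)
    emit_zone(del, ins)
    if (!is.na(p)) { anc_col <- c(anc_col, p); desc_col <- c(desc_col, p) }
    ia <- ja + 1L; id <- jd + 1L
  }
  structure(list(anc = anc_col, desc = desc_col), class = "pair_alignment")
}

#' @export
print.pair_alignment <- function(x, ...) {
  fmt <- function(v) paste(ifelse(is.na(v), "-", v), collapse = " ")
  cat("<pair_alignment ", length(x$anc), " columns>\n",
      "  anc : ", fmt(x$anc), "\n  desc: ", fmt(x$desc), "\n", sep = "")
  invisible(x)
}

#' Preserved ancestral sites of a pairwise alignment
#'
#' @param pwa a \code{pair_alignment}.
#' @return integer vector of tokens present in both rows, in order.
#' @export
pas_set <- function(pwa) {
  keep <- !is.na(pwa$anc) & !is.na(pwa$desc)
  as.integer(pwa$anc[keep])
}

#' Multiple-alignment homology structure
#'
#' @param rows named list of integer vectors (one per leaf, \code{NA} = gap),
#'   all of equal length; columns must not be all-gap.
#' @return An object of class \code{msa_alignment}.
#' @export
msa_alignment <- function(rows) {
  if (is.null(names(rows)) || any(names(rows) == ""))
    stop("msa rows must be named by their leaf labels")
  lens <- vapply(rows, length, 1L)
  if (length(unique(lens)) > 1L) stop("msa rows must have equal length")
  rows <- lapply(rows, as.integer)
  for (r in rows) {
    v <- r[!is.na(r)]
    if (anyDuplicated(v)) stop("duplicate token within one msa row")
  }
  if (length(rows[[1]])) {
    m <- do.call(rbind, rows)
    if (any(colSums(!is.na(m)) == 0L)) stop("all-gap msa column")
  }
  structure(list(rows = rows), class = "msa_alignment")
}

#' @export
print.msa_alignment <- function(x, ...) {
  cat("<msa_alignment ", length(x$rows), " rows x ",
      if (length(x$rows)) length(x$rows[[1]]) else 0L, " columns>\n", sep = "")
  for (nm in names(x$rows)) {
    v <- x$rows[[nm]]
    cat("  ", format(nm, width = 10), " ",
        paste(ifelse(is.na(v), "-", v), collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

msa_row_state <- function(msa, label) {
  ancestry_seq(msa$rows[[label]][!is.na(msa$rows[[label]])])
}

#' Region decomposition of an alignment
#'
#' Splits an alignment into the finest potentially local-history-accommodating
#' regions.  By default every PAS of a pairwise alignment (every gapless
#' column of a multiple alignment) is a delimiter; the zones between
#' consecutive delimiters, plus the two end zones, are the regions.  Empty
#' zones are kept: their multiplication factors default to 1 at parsimonious
#' truncation but can host "invisible" insert-then-delete histories when the
#' event budget allows.  A rate model with tracked heterogeneity regions
#' supplies a merging hook: delimiters interior to one tracked region (or to a
#' meta-region bridged by a deletion) are removed, so all events there are
#' lumped into a single local history.
#'
#' @param aln a \code{pair_alignment} or \code{msa_alignment}.
#' @param model optional \code{rate_model}; only its region-merging hook is
#'   consulted.
#' @return A list of class \code{region_decomposition} with elements
#'   \code{delimiters} (column indices), \code{delimiter_tokens},
#'   \code{regions} (list of integer vectors of column indices, possibly
#'   empty; \code{length(delimiters) + 1} of them, left end zone first).
#' @export
decompose_regions <- function(aln, model = NULL) {
  if (inherits(aln, "pair_alignment")) {
    ncol_ <- length(aln$anc)
    is_delim <- !is.na(aln$anc) & !is.na(aln$desc)
    delim_tokens <- aln$anc[is_delim]
  } else if (inherits(aln, "msa_alignment")) {
    ncol_ <- if (length(aln$rows)) length(aln$rows[[1]]) else 0L
    m <- if (ncol_) do.call(rbind, aln$rows) else matrix(integer(0), 0, 0)
    is_delim <- if (ncol_) colSums(is.na(m)) == 0L else logical(0)
    delim_tokens <- if (ncol_) aln$rows[[1]][is_delim] else integer(0)
  } else stop("unsupported alignment type")
  delim_idx <- which(is_delim)
  if (!is.null(model) && !is.null(model$regions) && length(delim_idx)) {
    drop <- vapply(seq_along(delim_idx), function(i) {
      region_hook_interior(model, aln, delim_tokens[i])
    }, logical(1))
    delim_idx <- delim_idx[!drop]
    delim_tokens <- delim_tokens[!drop]
  }
  bounds <- c(0L, delim_idx, ncol_ + 1L)
  regions <- lapply(seq_len(length(bounds) - 1L), function(i) {
    lo <- bounds[i] + 1L; hi <- bounds[i + 1L] - 1L
    if (lo > hi) integer(0) else lo:hi
  })
  structure(list(delimiters = delim_idx, delimiter_tokens = as.integer(delim_tokens),
                 regions = regions, ncol = ncol_),
            class = "region_decomposition")
}

# Is this delimiter token interior to a tracked heterogeneity region (or a
# deletion-bridged meta-region) of the model?  Tracked regions are anchored as
# token sets on the model's initial state; a PAS strictly between the leftmost
# and rightmost *appearance* (surviving token, or gap column descended from
# one) of a region's tokens is not allowed to split that region's local
# history.  Deletions bridging two tracked regions merge them: the meta-region
# is the convex hull of all regions touched by one gap run.
region_hook_interior <- function(model, aln, token) {
  if (!inherits(aln, "pair_alignment")) return(FALSE)
  spans <- tracked_region_spans(model, aln)
  col <- which(!is.na(aln$anc) & aln$anc == token)[1]
  any(vapply(spans, function(sp) col > sp[1] && col < sp[2], logical(1)))
}

tracked_region_spans <- function(model, aln) {
  ncol_ <- length(aln$anc)
  spans <- lapply(model$regions, function(tok) {
    cols <- which(aln$anc %in% tok)
    if (!length(cols)) return(NULL)
    c(min(cols), max(cols))
  })
  spans <- Filter(Negate(is.null), spans)
  if (length(spans) < 2L) return(spans)
  # merge regions bridged by one deletion gap run (contiguous anc-deleted run)
  del_run <- function(lo, hi) {
    if (hi < lo) return(FALSE)
    all(!is.na(aln$anc[lo:hi]) & is.na(aln$desc[lo:hi]))
  }
  ord <- order(vapply(spans, `[`, 1, 1))
  spans <- spans[ord]
  merged <- list(spans[[1]])
  for (i in seq_along(spans)[-1]) {
    last <- merged[[length(merged)]]
    if (spans[[i]][1] <= last[2] + 1L ||
        del_run(last[2] + 1L, spans[[i]][1] - 1L)) {
      merged[[length(merged)]] <- c(last[1], max(last[2], spans[[i]][2]))
    } else merged <- c(merged, spans[i])
  }
  merged
}

#' Canonical (relabel-invariant) form of an alignment
#'
#' Tokens are renumbered by first appearance in row-major column order, so two
#' alignments are homology-equal iff their canonical forms are identical.  For
#' multiple alignments the column order itself is canonicalized first: columns
#' that never co-occur in one row have no intrinsic order, so a deterministic
#' topological order (ties broken by leaf-presence pattern) is imposed.
#'
#' @param aln a \code{pair_alignment} or \code{msa_alignment}.
#' @return an object of the same class with canonical tokens (and, for MSAs,
#'   canonical column order).
#' @export
canonical_homology <- function(aln) {
  if (inherits(aln, "pair_alignment")) {
    relab <- canonical_relabel(rbind(aln$anc, aln$desc))
    return(structure(list(anc = relab[1, ], desc = relab[2, ]),
                     class = "pair_alignment"))
  }
  if (!inherits(aln, "msa_alignment")) stop("unsupported alignment type")
  m <- do.call(rbind, aln$rows)
  if (ncol(m)) m <- m[, msa_column_order(m), drop = FALSE]
  relab <- canonical_relabel(m)
  rows <- lapply(seq_len(nrow(relab)), function(i) relab[i, ])
  names(rows) <- names(aln$rows)
  structure(list(rows = rows), class = "msa_alignment")
}

canonical_relabel <- function(m) {
  if (!length(m)) return(m)
  map <- new.env(parent = emptyenv()); nxt <- 0L
  out <- m
  for (j in seq_len(ncol(m))) for (i in seq_len(nrow(m))) {
    v <- m[i, j]
    if (is.na(v)) next
    key <- as.character(v)
    if (is.null(map[[key]])) { nxt <- nxt + 1L; map[[key]] <- nxt }
    out[i, j] <- map[[key]]
  }
  out
}

# Deterministic topological order of MSA columns: respect each row's order;
# among currently available columns pick the one with the lexicographically
# smallest presence pattern (then lowest original index).
msa_column_order <- function(m) {
  nc <- ncol(m)
  preds <- vector("list", nc)       # columns that must precede each column
  for (i in seq_len(nrow(m))) {
    idx <- which(!is.na(m[i, ]))
    if (length(idx) > 1L)
      for (k in 2:length(idx)) preds[[idx[k]]] <- c(preds[[idx[k]]], idx[k - 1L])
  }
  indeg <- vapply(preds, length, 1L)
  succ <- vector("list", nc)
  for (j in seq_len(nc)) for (p in preds[[j]]) succ[[p]] <- c(succ[[p]], j)
  pattern <- apply(!is.na(m), 2, function(z) paste(as.integer(z), collapse = ""))
  avail <- which(indeg == 0L)
  out <- integer(0)
  while (length(avail)) {
    pick <- avail[order(pattern[avail], avail)][1]
    out <- c(out, pick)
    avail <- setdiff(avail, pick)
    for (s in succ[[pick]]) {
      indeg[s] <- indeg[s] - 1L
      if (indeg[s] == 0L) avail <- c(avail, s)
    }
  }
  stopifnot(length(out) == nc)
  out
}

#' Homology equality of two alignments
#'
#' @param a,b alignments of the same class.
#' @return logical.
#' @export
homology_equal <- function(a, b) {
  identical(unclass(canonical_homology(a)), unclass(canonical_homology(b)))
}

homology_key <- function(aln) {
  can <- canonical_homology(aln)
  if (inherits(can, "pair_alignment")) {
    paste(paste(ifelse(is.na(can$anc), "-", can$anc), collapse = ","),
          paste(ifelse(is.na(can$desc), "-", can$desc), collapse = ","),
          sep = "|")
  } else {
    paste(vapply(can$rows, function(v)
      paste(ifelse(is.na(v), "-", v), collapse = ","), ""), collapse = "|")
  }
}
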
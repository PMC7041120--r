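# Factor parameter graphs: the finitely many inequality regions in the
# parameters of a single gene, enumerated exactly.
#
# A gene with q input edges and p output thresholds has production value
# Lambda(c) = prod_e c_e, where the input combination c picks either L_e or
# U_e per input edge.  A parameter region fixes (i) an ordering of the p
# decay-scaled thresholds gamma*theta and (ii), for every threshold k and
# combination c, whether Lambda(c) lies above or below gamma*theta_k.  In
# log space products become sums, so region realizability is a linear
# feasibility problem; because only the gaps d_e = log U_e - log L_e enter
# the cross-combination comparisons, it reduces further to strict
# feasibility of an integer-coefficient cone in q <= 3 variables, which is
# decided exactly by Fourier-Motzkin elimination.

# ---- combination lattice ----------------------------------------------------

# all monotone (upward-closed) subsets of the q-dimensional Boolean lattice
# of input combinations; rows ordered by pattern integer.  Combination c
# (0-based) has bit e set when input edge e contributes U.
monotone_upsets <- function(q) {
  nc <- 2L^q
  combos <- 0:(nc - 1L)
  keep <- list()
  for (mask in 0:(2L^nc - 1L)) {
    memb <- bitwAnd(bitwShiftR(mask, combos), 1L) == 1L
    ok <- TRUE
    for (c1 in combos[memb[combos + 1L]]) {
      for (e in 0:(q - 1L)) {
        if (!memb[bitwOr(c1, bitwShiftL(1L, e)) + 1L]) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) keep[[length(keep) + 1L]] <- memb
  }
  m <- do.call(rbind, keep)
  m[order(m %*% 2^(seq_len(nc) - 1)), , drop = FALSE]
}

# weakly decreasing chains u_1 >= u_2 >= ... >= u_p (by inclusion) of rows
# of the upset matrix U; returns a list of row-index vectors.  These are
# exactly the candidate sign patterns compatible with threshold nesting.
upset_chains <- function(U, p) {
  n <- nrow(U)
  le <- matrix(FALSE, n, n)  # le[i, j]: upset i subset of upset j
  for (i in seq_len(n)) for (j in seq_len(n)) le[i, j] <- all(!U[i, ] | U[j, ])
  res <- list()
  rec <- function(pref) {
    if (length(pref) == p) { res[[length(res) + 1L]] <<- pref; return(invisible()) }
    for (nxt in which(le[, pref[length(pref)]])) rec(c(pref, nxt))
  }
  for (s in seq_len(n)) rec(s)
  res
}

# bit matrix of combinations: bits[c + 1, e] = 1 iff edge e contributes U in c
combo_bits <- function(q) {
  combos <- 0:(2L^q - 1L)
  m <- vapply(0:(q - 1L), function(e) bitwAnd(bitwShiftR(combos, e), 1L),
              integer(2L^q))
  matrix(m, nrow = 2L^q, ncol = q)
}

# ---- exact strict feasibility ----------------------------------------------

.gcd2 <- function(a, b) if (b == 0) a else .gcd2(b, a %% b)

.row_normalize <- function(M) {
  g <- apply(abs(M), 1, function(r) {
    r <- r[r > 0]
    if (!length(r)) 1 else Reduce(.gcd2, r)
  })
  M / g
}

# strict homogeneous feasibility of {x in R^nv : M x > 0} (x free) by
# Fourier-Motzkin elimination over the integers.  Exact: projections of
# open polyhedra are produced by pairwise elimination, and row-gcd
# normalisation plus deduplication keeps coefficients small.
fm_feasible <- function(M) {
  if (nrow(M) == 0L) return(TRUE)
  M <- unique(.row_normalize(M))
  nv <- ncol(M)
  for (v in seq_len(nv - 1L)) {
    if (nrow(M) == 0L) return(TRUE)
    if (any(rowSums(M != 0) == 0)) return(FALSE)   # row 0 > 0
    cv <- M[, 1]
    keep <- M[cv == 0, -1, drop = FALSE]
    P <- M[cv > 0, , drop = FALSE]
    N <- M[cv < 0, , drop = FALSE]
    if (nrow(P) && nrow(N)) {
      ia <- rep(seq_len(nrow(P)), each = nrow(N))
      ib <- rep(seq_len(nrow(N)), nrow(P))
      comb <- P[ia, 1] * N[ib, -1, drop = FALSE] -
              N[ib, 1] * P[ia, -1, drop = FALSE]
      M <- unique(.row_normalize(rbind(keep, comb)))
    } else {
      M <- unique(keep)
    }
  }
  if (nrow(M) == 0L) return(TRUE)
  a <- M[, 1]
  if (any(a == 0)) return(FALSE)
  !(any(a > 0) && any(a < 0))
}

# cone rows for a level assignment: lev[c] = number of thresholds below
# Lambda(c).  Cross-level separation S(c') - S(c) > 0 depends only on the
# per-edge gaps d_e > 0, with coefficient bit'(e) - bit(e).
level_cone_rows <- function(lev, q) {
  bits <- combo_bits(q)
  nc <- 2L^q
  rows <- list()
  for (i in seq_len(nc)) for (j in seq_len(nc)) {
    if (lev[i] < lev[j]) rows[[length(rows) + 1L]] <- bits[j, ] - bits[i, ]
  }
  rbind(do.call(rbind, rows), diag(q))
}

pattern_levels <- function(pattern) {
  if (is.null(dim(pattern))) pattern <- matrix(pattern, nrow = 1L)
  colSums(pattern)
}

#' Is a sign pattern realizable by positive parameters?
#'
#' Decides whether there exist parameters `0 < L_e < U_e` (one pair per
#' input edge) and decay-scaled thresholds `gamma*theta_1 < ... <
#' gamma*theta_p` realising a given sign pattern: entry `(k, c)` of
#' `pattern` is `TRUE` when the production value `Lambda(c)` must lie above
#' `gamma*theta_k`, `FALSE` when below, for input combination `c` (columns
#' are indexed by the combination's bit code: bit `e` set means edge `e`
#' contributes `U_e`).
#'
#' Taking logarithms turns the product inequalities into linear ones.  A
#' realizable pattern must be monotone in each row (combinations ordered by
#' the product order with `L_e < U_e`) and nested across rows (higher
#' thresholds have smaller above-sets); given both, realizability depends
#' only on the log-gaps `d_e = log U_e - log L_e > 0` and is decided
#' exactly, in integer arithmetic, by Fourier-Motzkin elimination of the
#' strict cone `{d > 0 : S(c') - S(c) > 0}` over cross-level combination
#' pairs.
#'
#' @param pattern Logical matrix, `p` threshold rows (ascending threshold
#'   order) by `2^q` combination columns.  A logical vector is taken as a
#'   single row.
#' @return `TRUE` or `FALSE`.
#' @examples
#' # single input, two outputs: L < g*t1 < g*t2 < U is realizable
#' realizable(rbind(c(FALSE, TRUE), c(FALSE, TRUE)))
#' # demanding U below t1 but L above t1 contradicts L < U
#' realizable(rbind(c(TRUE, FALSE), c(FALSE, FALSE)))
#' @export
realizable <- function(pattern) {
  if (is.null(dim(pattern))) pattern <- matrix(pattern, nrow = 1L)
  stopifnot(is.logical(pattern))
  nc <- ncol(pattern)
  q <- as.integer(round(log2(nc)))
  if (2L^q != nc) {
    abort("pattern must have 2^q columns", class = "switchmorse_pattern_error")
  }
  p <- nrow(pattern)
  # monotone rows: c <= c' bitwise implies above(c) <= above(c')
  bits <- combo_bits(q)
  for (k in seq_len(p)) {
    for (cc in 0:(nc - 1L)) {
      if (!pattern[k, cc + 1L]) next
      for (e in 0:(q - 1L)) {
        if (!pattern[k, bitwOr(cc, bitwShiftL(1L, e)) + 1L]) return(FALSE)
      }
    }
  }
  # nesting: above-set of threshold k+1 contained in that of threshold k
  if (p > 1L) {
    for (k in seq_len(p - 1L)) {
      if (any(pattern[k + 1L, ] & !pattern[k, ])) return(FALSE)
    }
  }
  fm_feasible(level_cone_rows(pattern_levels(pattern), q))
}

# ---- essentiality and layers ------------------------------------------------

#' Essentiality and layer of a factor region
#'
#' A region is *essential* when every edge of the gene carries information:
#' (a) each output threshold has at least one combination above and one
#' below it (every out-edge is actuated somewhere and silent somewhere),
#' and (b) for each input edge there are two combinations differing only in
#' that edge with different sign columns (every in-edge can change the
#' output).  At an inessential region the network behaves like one of its
#' proper subnetworks.
#'
#' The *layer* is one plus the number of `(threshold, combination)` pairs
#' with the production value above the threshold; it groups regions by the
#' qualitative expression level of the gene (layer 1: never actuates any
#' downstream edge; top layer: always actuates all of them).
#'
#' @param pattern Logical sign-pattern matrix as in [realizable()].
#' @return `region_essential()` returns `TRUE`/`FALSE`;
#'   `region_layer()` a positive integer.
#' @export
region_essential <- function(pattern) {
  if (is.null(dim(pattern))) pattern <- matrix(pattern, nrow = 1L)
  nc <- ncol(pattern)
  q <- as.integer(round(log2(nc)))
  if (any(rowSums(pattern) == 0L) || any(rowSums(pattern) == nc)) return(FALSE)
  combos <- 0:(nc - 1L)
  for (e in 0:(q - 1L)) {
    lo <- combos[bitwAnd(bitwShiftR(combos, e), 1L) == 0L]
    hi <- bitwOr(lo, bitwShiftL(1L, e))
    if (!any(pattern[, hi + 1L, drop = FALSE] != pattern[, lo + 1L, drop = FALSE]))
      return(FALSE)
  }
  TRUE
}

#' @rdname region_essential
#' @export
region_layer <- function(pattern) {
  if (is.null(dim(pattern))) pattern <- matrix(pattern, nrow = 1L)
  sum(pattern) + 1L
}

# ---- enumeration ------------------------------------------------------------

# permutations of 1:n in lexicographic order
lex_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (s in lex_permutations(n - 1L)) {
      rest <- setdiff(seq_len(n), i)
      out[[length(out) + 1L]] <- c(i, rest[s])
    }
  }
  out
}

pattern_integer <- function(pattern) {
  v <- as.numeric(t(pattern))
  sum(v * 2^(seq_along(v) - 1))
}

#' Enumerate the factor parameter graph of one gene
#'
#' Lists every realizable parameter region of a gene with `q >= 1` inputs
#' and `p >= 1` outputs: all `p!` threshold orderings combined with all
#' feasible sign patterns.  The search never enumerates raw sign patterns;
#' candidates are the nested chains of monotone cuts of the input
#' combination lattice (the only patterns compatible with monotone product
#' logic and threshold nesting), filtered by exact feasibility
#' ([realizable()]).  Feasibility does not depend on the threshold
#' ordering, so each feasible chain contributes one region per ordering.
#'
#' Regions are canonically ordered: threshold orderings lexicographically,
#' then sign patterns ascending by their bit-integer encoding.  This fixes
#' stable region indices for sampling and reporting.
#'
#' @param net A `regnet`.
#' @param gene Gene name.
#' @return A `factor_graph` tibble with one row per region: `region` (index),
#'   `order` (list: permutation giving, per ascending threshold rank, the
#'   out-edge slot owning it), `pattern` (list: logical sign-pattern matrix),
#'   `above` (count of above entries), `layer`, `essential`.
#' @examples
#' fg <- factor_graph(emt_network(), "Ovol2")
#' nrow(fg)            # 12 regions
#' sum(fg$essential)   # 2 essential regions
#' @export
factor_graph <- function(net, gene) {
  stopifnot(inherits(net, "regnet"))
  if (!gene %in% net$nodes) {
    abort(paste0("unknown gene: ", gene), class = "switchmorse_gene_error")
  }
  q <- length(net$inputs[[gene]])
  p <- length(net$outputs[[gene]])
  if (q == 0L || p == 0L) {
    abort(paste0("factor graph requires >= 1 input and >= 1 output edge (",
                 gene, " has ", q, " and ", p, ")"),
          class = "switchmorse_gene_error")
  }
  U <- monotone_upsets(q)
  ch <- upset_chains(U, p)
  feas <- vapply(ch, function(cr) {
    fm_feasible(level_cone_rows(colSums(U[cr, , drop = FALSE]), q))
  }, logical(1))
  ch <- ch[feas]
  pats <- lapply(ch, function(cr) {
    m <- U[cr, , drop = FALSE]
    rownames(m) <- NULL
    m
  })
  pats <- pats[order(vapply(pats, pattern_integer, numeric(1)))]
  orders <- lex_permutations(p)

  n_regions <- length(orders) * length(pats)
  order_col <- rep(orders, each = length(pats))
  pattern_col <- rep(pats, times = length(orders))
  fg <- tibble(
    region = seq_len(n_regions),
    order = order_col,
    pattern = pattern_col,
    above = vapply(pattern_col, function(m) sum(m), integer(1)),
    layer = vapply(pattern_col, region_layer, integer(1)),
    essential = vapply(pattern_col, region_essential, logical(1))
  )
  attr(fg, "region_key") <- paste(
    vapply(order_col, paste, character(1), collapse = ","),
    vapply(pattern_col, pattern_integer, numeric(1)))
  attr(fg, "gene") <- gene
  attr(fg, "q") <- q
  attr(fg, "p") <- p
  attr(fg, "inputs") <- net$inputs[[gene]]
  attr(fg, "outputs") <- net$outputs[[gene]]
  attr(fg, "net") <- net
  class(fg) <- c("factor_graph", class(fg))
  fg
}

#' Adjacency of factor-graph regions
#'
#' Two regions are adjacent when their defining inequality sets differ in
#' exactly one place: either a single sign flip (same threshold ordering,
#' sign patterns differing in one entry) or an adjacent transposition of two
#' consecutive thresholds whose sign-pattern rows coincide.  Both
#' correspond to crossing one codimension-1 boundary in parameter space.
#'
#' @param fg A `factor_graph`.
#' @return A tibble of undirected edges (`from` < `to`, region indices).
#' @export
factor_graph_edges <- function(fg) {
  stopifnot(inherits(fg, "factor_graph"))
  pat_int <- vapply(fg$pattern, pattern_integer, numeric(1))
  ord_key <- vapply(fg$order, paste, character(1), collapse = ",")
  from <- integer(0); to <- integer(0)
  # single sign flips within one ordering block
  for (ok in unique(ord_key)) {
    idx <- which(ord_key == ok)
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (a >= b) next
        i <- idx[a]; j <- idx[b]
        if (sum(fg$pattern[[i]] != fg$pattern[[j]]) == 1L) {
          from <- c(from, i); to <- c(to, j)
        }
      }
    }
  }
  # adjacent threshold transpositions with equal sign rows
  p <- attr(fg, "p")
  if (p > 1L) {
    for (i in seq_len(nrow(fg))) {
      oi <- fg$order[[i]]
      for (k in seq_len(p - 1L)) {
        if (!identical(fg$pattern[[i]][k, ], fg$pattern[[i]][k + 1L, ])) next
        oj <- oi; oj[c(k, k + 1L)] <- oj[c(k + 1L, k)]
        j <- which(ord_key == paste(oj, collapse = ",") &
                   pat_int == pat_int[i])
        if (length(j) == 1L && j > i) { from <- c(from, i); to <- c(to, j) }
      }
    }
  }
  tibble(from = from, to = to)
}

#' Human-readable inequalities of a factor region
#'
#' For a single-input gene the `2 + p` quantities `L`, `U` and the
#' decay-scaled thresholds are totally ordered by the sign pattern, and the
#' full chain of inequalities is returned, e.g.
#' `"L < gamma*theta_{Zeb1,Ovol2} < gamma*theta_{TGFb,Ovol2} < U"`.
#' For multi-input genes the above-set of each threshold is listed instead.
#'
#' @param fg A `factor_graph`.
#' @param region Region index.
#' @return Character scalar.
#' @export
region_inequalities <- function(fg, region) {
  stopifnot(inherits(fg, "factor_graph"))
  net <- attr(fg, "net")
  gene <- attr(fg, "gene")
  q <- attr(fg, "q"); p <- attr(fg, "p")
  row <- fg[fg$region == region, ]
  if (nrow(row) != 1L) {
    abort("no such region", class = "switchmorse_region_error")
  }
  ord <- row$order[[1]]
  pat <- row$pattern[[1]]
  out_targets <- net$edges$target[net$outputs[[gene]]]
  th_names <- paste0("gamma*theta_{", out_targets[ord], ",", gene, "}")
  if (q == 1L) {
    # L (combo 0) and U (combo 1) are totally ordered against the thresholds:
    # a combo with level v sits between threshold v and threshold v+1
    lev <- colSums(pat)
    syms <- c("L", "U")
    chain <- character(0)
    ci <- 1L  # next combo index (L then U, L always before U)
    for (k in 0:p) {
      while (ci <= 2L && lev[ci] == k) { chain <- c(chain, syms[ci]); ci <- ci + 1L }
      if (k < p) chain <- c(chain, th_names[k + 1L])
    }
    paste(chain, collapse = " < ")
  } else {
    bits <- combo_bits(q)
    in_edges <- net$inputs[[gene]]
    lab <- vapply(0:(2L^q - 1L), function(cc) {
      paste0(ifelse(bits[cc + 1L, ] == 1L, "U", "L"), "_{", gene, ",",
             net$edges$source[in_edges], "}", collapse = "*")
    }, character(1))
    per_th <- vapply(seq_len(p), function(k) {
      ab <- lab[pat[k, ]]
      paste0(th_names[k], " below {",
             paste(ab, collapse = ", "), "}")
    }, character(1))
    paste(per_th, collapse = "; ")
  }
}

#' @export
print.factor_graph <- function(x, ...) {
  cat("Factor parameter graph for ", attr(x, "gene"),
      " (", attr(x, "q"), " inputs, ", attr(x, "p"), " outputs): ",
      nrow(x), " regions, ", sum(x$essential), " essential, ",
      length(unique(x$layer)), " layers\n", sep = "")
  NextMethod()
}

#' @rdname factor_graph
#' @param x A `factor_graph`.
#' @param ... Unused.
#' @export
#' @method glance factor_graph
glance.factor_graph <- function(x, ...) {
  tibble(gene = attr(x, "gene"), q = attr(x, "q"), p = attr(x, "p"),
         n_regions = nrow(x), n_essential = sum(x$essential),
         n_layers = length(unique(x$layer)))
}

#' @rdname factor_graph
#' @export
#' @method tidy factor_graph
tidy.factor_graph <- function(x, ...) {
  tibble(gene = attr(x, "gene"),
         region = x$region,
         order = vapply(x$order, paste, character(1), collapse = ","),
         above = x$above, layer = x$layer, essential = x$essential)
}

#' Export a factor graph to JSON
#'
#' @param fg A `factor_graph`.
#' @param path Output file.
#' @param essential_only Drop inessential regions.
#' @return `path`, invisibly.
#' @export
write_factor_graph_json <- function(fg, path, essential_only = FALSE) {
  stopifnot(inherits(fg, "factor_graph"))
  keep <- if (essential_only) which(fg$essential) else seq_len(nrow(fg))
  regions <- lapply(keep, function(i) {
    list(region = fg$region[i],
         inequalities = region_inequalities(fg, fg$region[i]),
         order = fg$order[[i]],
         layer = fg$layer[i],
         essential = fg$essential[i])
  })
  edges <- factor_graph_edges(fg)
  if (essential_only) {
    edges <- filter(edges, .data$from %in% keep & .data$to %in% keep)
  }
  obj <- list(gene = attr(fg, "gene"), q = attr(fg, "q"), p = attr(fg, "p"),
              n_regions = length(regions), regions = regions,
              adjacency = edges)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
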
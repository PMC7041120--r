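# Built-in networks, synthetic random networks, concrete parameter
# instantiation inside any inequality region, and numeric oracles (a
# real-arithmetic state-transition-graph builder and a steep-Hill ODE
# integrator) used to cross-validate the combinatorial dynamics.

emt_spec_text <- paste(
  "# Six-gene EMT network; gene order fixes all reported labels",
  "Zeb1   : (Snail1)(~miR200)(~Ovol2)",
  "Snail1 : (TGFb)(~miR34a)",
  "miR200 : (~Zeb1)(~Snail1)",
  "miR34a : (~Zeb1)(~Snail1)",
  "TGFb   : (~Ovol2)(~miR200)",
  "Ovol2  : (~Zeb1)",
  sep = "\n")

toggle_spec_text <- "X : (~Y)\nY : (~X)"

#' Built-in networks
#'
#' `emt_network()` returns the six-gene, twelve-edge epithelial-mesenchymal
#' transition network (Zeb1, Snail1, miR200, miR34a, TGFb, Ovol2) with
#' pure-product logic: Snail1 activates Zeb1 while miR200 and Ovol2 repress
#' it; TGFb activates and miR34a represses Snail1; Zeb1 and Snail1 repress
#' both microRNAs; Ovol2 and miR200 repress TGFb; and Zeb1 represses Ovol2.
#' `toggle_switch_network()` returns the two-gene mutual-repression toggle
#' switch.
#'
#' @return A `regnet`.
#' @examples
#' glance(emt_network())
#' @export
emt_network <- function() parse_network(emt_spec_text)

#' @rdname emt_network
#' @export
toggle_switch_network <- function() parse_network(toggle_spec_text)

#' Random small product-logic networks
#'
#' Generates a random signed network on up to three genes obeying the
#' structural assumptions of the framework: no negative self-regulation,
#' at most one edge per ordered pair, every gene with at least one input
#' and one output.  Positive self-edges appear with probability `p_self`.
#' Used as an oracle corpus: small enough that the combinatorial dynamics
#' can be cross-checked against real-arithmetic constructions.
#'
#' @param n_nodes 2 or 3.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param p_self Probability of a positive self-edge per gene.
#' @return A `regnet`.
#' @export
random_network <- function(n_nodes, seed, p_self = 0.15) {
  stopifnot(n_nodes >= 2L, n_nodes <= 3L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  genes <- paste0("G", seq_len(n_nodes))
  repeat {
    src <- character(0); tgt <- character(0); sgn <- integer(0)
    for (i in seq_len(n_nodes)) for (j in seq_len(n_nodes)) {
      if (i == j) {
        if (stats::runif(1) < p_self) {
          src <- c(src, genes[j]); tgt <- c(tgt, genes[i]); sgn <- c(sgn, 1L)
        }
      } else if (stats::runif(1) < 0.55) {
        src <- c(src, genes[j]); tgt <- c(tgt, genes[i])
        sgn <- c(sgn, if (stats::runif(1) < 0.5) 1L else -1L)
      }
    }
    if (length(src) == 0L) next
    deg_in <- vapply(genes, function(g) sum(tgt == g), integer(1))
    deg_out <- vapply(genes, function(g) sum(src == g), integer(1))
    if (all(deg_in >= 1L) && all(deg_out >= 1L)) break
  }
  lines <- vapply(genes, function(g) {
    e <- which(tgt == g)
    paste0(g, " : ", paste0("(", ifelse(sgn[e] < 0L, "~", ""), src[e], ")",
                            collapse = ""))
  }, character(1))
  parse_network(paste(lines, collapse = "\n"))
}

# smallest integer gap vector d >= 1 separating the level groups of a sign
# pattern: S(c) = sum of d over U-bits of c, and combinations at a lower
# level must have strictly smaller S (gap >= 1).  Searched over an
# escalating integer grid; every enumerated region admits such a d.
find_gap_vector <- function(pattern, q) {
  lev <- pattern_levels(pattern)
  bits <- combo_bits(q)
  for (K in c(2L, 4L, 8L, 16L, 32L, 64L)) {
    D <- as.matrix(expand.grid(rep(list(seq_len(K)), q),
                               KEEP.OUT.ATTRS = FALSE))
    D <- D[order(rowSums(D)), , drop = FALSE]
    S <- D %*% t(bits)                       # candidates x combos
    ok <- rep(TRUE, nrow(D))
    ulev <- sort(unique(lev))
    if (length(ulev) > 1L) {
      for (t in seq_len(length(ulev) - 1L)) {
        lo <- apply(S[, lev == ulev[t], drop = FALSE], 1, max)
        hi <- apply(S[, lev == ulev[t + 1L], drop = FALSE], 1, min)
        ok <- ok & (lo + 1 <= hi)
      }
    }
    if (any(ok)) return(D[which(ok)[1], ])
  }
  abort("no integer gap vector found (unrealizable pattern?)",
        class = "switchmorse_instantiate_error")
}

#' Instantiate concrete parameters inside a parameter region
#'
#' Produces positive real parameters (decay rates, per-edge `L < U` and
#' thresholds) lying strictly inside the inequality region named by
#' `address`: every defining inequality holds with a log-space margin of at
#' least `margin`.  Construction is per gene in log space: an exact integer
#' gap vector separates the production levels of the input combinations,
#' and decay-scaled thresholds are spread evenly inside the gaps dictated
#' by the sign pattern.  All decay rates are 1.
#'
#' @param pg A `parameter_graph`.
#' @param address Parameter-node address.
#' @param margin Minimal log-space slack of every strict inequality.
#' @return A `concrete_parameters` object: named `gamma` vector and an edge
#'   table with `L`, `U`, `theta` per edge.
#' @export
instantiate_parameters <- function(pg, address, margin = 0.05) {
  stopifnot(inherits(pg, "parameter_graph"))
  addr <- addr_vector(pg, address)
  net <- pg$net
  nodes <- net$nodes
  edges <- net$edges
  L <- U <- theta <- rep(NA_real_, nrow(edges))
  gamma <- setNames(rep(1, length(nodes)), nodes)

  for (i in seq_along(nodes)) {
    g <- nodes[i]
    fg <- pg$factor_graphs[[g]]
    reg <- pg$active[[g]][addr[i]]
    pat <- fg$pattern[[reg]]
    ord <- fg$order[[reg]]
    q <- attr(fg, "q"); p <- attr(fg, "p")
    d <- find_gap_vector(pat, q)
    in_edges <- net$inputs[[g]]
    L[in_edges] <- 1
    U[in_edges] <- exp(d)
    # log-production of every combination, then thresholds in the gaps
    bits <- combo_bits(q)
    S <- as.numeric(bits %*% d)
    lev <- pattern_levels(pat)
    lo <- vapply(seq_len(p), function(k) {
      below <- S[lev < k]
      if (length(below)) max(below) else min(S) - 2
    }, numeric(1))
    hi <- vapply(seq_len(p), function(k) {
      above <- S[lev >= k]
      if (length(above)) min(above) else max(S) + 2
    }, numeric(1))
    t_log <- numeric(p)
    gap_id <- paste(lo, hi)
    for (gp in unique(gap_id)) {
      ks <- which(gap_id == gp)
      m <- length(ks)
      t_log[ks] <- lo[ks[1]] + (hi[ks[1]] - lo[ks[1]]) * seq_len(m) / (m + 1)
    }
    # threshold rank k is owned by out-edge slot ord[k]
    out_edges <- net$outputs[[g]]
    theta[out_edges[ord]] <- exp(t_log) / gamma[i]
  }
  params <- structure(
    list(gamma = gamma,
         edges = mutate(edges, L = L, U = U, theta = theta)),
    class = "concrete_parameters")
  verify_margin(pg, addr, params, margin)
  params
}

#' @export
print.concrete_parameters <- function(x, ...) {
  cat("Concrete switching parameters (", nrow(x$edges), " edges)\n", sep = "")
  print(x$edges)
  invisible(x)
}

# check that every inequality of the address holds with log-space slack
# >= margin; defence against construction bugs, not a solver
verify_margin <- function(pg, addr, params, margin) {
  net <- pg$net
  for (i in seq_along(net$nodes)) {
    g <- net$nodes[i]
    fg <- pg$factor_graphs[[g]]
    reg <- pg$active[[g]][addr[i]]
    pat <- fg$pattern[[reg]]
    ord <- fg$order[[reg]]
    q <- attr(fg, "q")
    in_edges <- net$inputs[[g]]
    out_edges <- net$outputs[[g]]
    bits <- combo_bits(q)
    lam <- as.numeric(
      exp(bits %*% log(params$edges$U[in_edges])) *
      exp((1 - bits) %*% log(params$edges$L[in_edges])))
    th <- params$gamma[i] * params$edges$theta[out_edges[ord]]
    if (any(diff(log(th)) < margin)) {
      abort("threshold ordering margin violated",
            class = "switchmorse_instantiate_error")
    }
    for (k in seq_along(th)) {
      gap <- log(lam) - log(th[k])
      want_above <- pat[k, ]
      if (any(gap[want_above] < margin) || any(-gap[!want_above] < margin)) {
        abort("sign-pattern margin violated",
              class = "switchmorse_instantiate_error")
      }
    }
  }
  invisible(TRUE)
}

#' Recover the parameter-node address of concrete parameters
#'
#' Reads off, for every gene, the threshold ordering and the sign of each
#' `Lambda(c)` versus `gamma * theta` comparison, and locates the matching
#' region in each factor graph.  Inverse of [instantiate_parameters()].
#'
#' @param pg A `parameter_graph`.
#' @param params A `concrete_parameters`.
#' @return Named integer address (active region indices).
#' @export
parameters_to_address <- function(pg, params) {
  stopifnot(inherits(pg, "parameter_graph"),
            inherits(params, "concrete_parameters"))
  net <- pg$net
  addr <- integer(length(net$nodes))
  for (i in seq_along(net$nodes)) {
    g <- net$nodes[i]
    fg <- pg$factor_graphs[[g]]
    q <- attr(fg, "q"); p <- attr(fg, "p")
    in_edges <- net$inputs[[g]]
    out_edges <- net$outputs[[g]]
    th <- params$gamma[i] * params$edges$theta[out_edges]
    ord <- order(th)
    bits <- combo_bits(q)
    lam <- as.numeric(
      exp(bits %*% log(params$edges$U[in_edges])) *
      exp((1 - bits) %*% log(params$edges$L[in_edges])))
    pat <- t(vapply(seq_len(p), function(k) lam > th[ord][k],
                    logical(2L^q)))
    if (p == 1L) pat <- matrix(pat, nrow = 1L)
    key <- paste(paste(as.integer(ord), collapse = ","),
                 pattern_integer(pat))
    hit <- which(attr(fg, "region_key") == key)
    if (length(hit) != 1L) {
      abort(paste0("parameters do not match a unique region for gene ", g),
            class = "switchmorse_instantiate_error")
    }
    act <- match(hit, pg$active[[g]])
    if (is.na(act)) {
      abort(paste0("region of gene ", g, " is outside the active mode (",
                   pg$modes[[g]], ")"),
            class = "switchmorse_instantiate_error")
    }
    addr[i] <- act
  }
  setNames(addr, net$nodes)
}

# representative interior point of every cell: geometric midpoints between
# consecutive thresholds, half the lowest threshold below, twice the
# highest above
cell_centers <- function(net, params) {
  nodes <- net$nodes
  lapply(seq_along(nodes), function(i) {
    th <- sort(params$edges$theta[net$outputs[[nodes[i]]]])
    p <- length(th)
    mids <- numeric(p + 1L)
    mids[1] <- th[1] / 2
    if (p > 1L) for (k in seq_len(p - 1L)) mids[k + 1L] <- sqrt(th[k] * th[k + 1L])
    mids[p + 1L] <- 2 * th[p]
    mids
  })
}

#' Real-arithmetic state transition graph (numeric oracle)
#'
#' Builds the state transition graph by direct numeric evaluation: a
#' representative point is placed in every cell, production values
#' `Lambda_i` are computed from the switching terms at that point, and each
#' face direction is decided by the sign of `-gamma_i * theta + Lambda_i`.
#' Shares no code path with the combinatorial builder [build_stg()], which
#' it cross-checks.
#'
#' @param net A `regnet`.
#' @param params A `concrete_parameters`.
#' @return An `stg` object.
#' @export
stg_from_parameters <- function(net, params) {
  space <- state_space(net)
  cells <- state_cells(space)
  strides <- state_strides(space)
  centers <- cell_centers(net, params)
  nodes <- net$nodes
  # numeric coordinates of every cell's representative point
  X <- vapply(seq_along(nodes), function(i) centers[[i]][cells[, i] + 1L],
              numeric(nrow(cells)))
  lambda <- vapply(seq_along(nodes), function(i) {
    g <- nodes[i]
    val <- rep(1, nrow(cells))
    for (e in net$inputs[[g]]) {
      xj <- X[, match(net$edges$source[e], nodes)]
      above <- xj > params$edges$theta[e]
      hi <- (net$edges$sign[e] > 0L) == above
      val <- val * ifelse(hi, params$edges$U[e], params$edges$L[e])
    }
    val
  }, numeric(nrow(cells)))

  from <- integer(0); to <- integer(0)
  for (i in seq_along(nodes)) {
    g <- nodes[i]
    th <- sort(params$edges$theta[net$outputs[[g]]])
    for (k in seq_along(th)) {
      low <- which(cells[, i] == k - 1L)
      upp <- low + strides[i]
      up_edge <- -params$gamma[i] * th[k] + lambda[low, i] > 0
      down_edge <- -params$gamma[i] * th[k] + lambda[upp, i] < 0
      from <- c(from, low[up_edge], upp[down_edge])
      to <- c(to, upp[up_edge], low[down_edge])
    }
  }
  outdeg <- tabulate(from, nrow(cells))
  self <- which(outdeg == 0L)
  structure(
    list(from = c(from, self), to = c(to, self), self = self,
         n_cells = nrow(cells), space = space, cells = cells,
         address = NULL),
    class = "stg")
}

#' Steep-Hill ODE attractor check
#'
#' Replaces each switching term by a Hill function with coefficient
#' `hill_n` and integrates the smooth system from the centre of each given
#' cell until the state is stationary (derivative norm below `1e-6` times
#' the state norm).  Reports the cell containing each endpoint.  For a
#' stable fixed-point cell of the combinatorial dynamics, a sufficiently
#' steep Hill system started at its centre is expected to stay in that
#' cell.
#'
#' @param net A `regnet`.
#' @param params A `concrete_parameters`.
#' @param hill_n Hill coefficient (>= 50 recommended).
#' @param cells Integer matrix of starting cells (one row per start), or a
#'   single cell vector.
#' @param t_chunk,max_chunks Integration window and budget.
#' @return Tibble with `start`, `end` (cell-label strings), `converged`.
#' @export
ode_attractor_check <- function(net, params, hill_n = 60, cells,
                                t_chunk = 10, max_chunks = 200) {
  stopifnot(inherits(net, "regnet"), hill_n >= 2)
  if (is.null(dim(cells))) cells <- matrix(as.integer(cells), nrow = 1L)
  space <- state_space(net)
  centers <- cell_centers(net, params)
  nodes <- net$nodes

  hill <- function(x, theta, n, up) {
    # computed through the logistic form to stay finite at large n
    z <- pmin(pmax(n * (log(theta) - log(pmax(x, 1e-12))), -700), 700)
    h <- 1 / (1 + exp(z))
    if (up) h else 1 - h
  }
  deriv <- function(t, x, parms) {
    dx <- numeric(length(nodes))
    for (i in seq_along(nodes)) {
      g <- nodes[i]
      val <- 1
      for (e in net$inputs[[g]]) {
        xj <- x[match(net$edges$source[e], nodes)]
        h <- hill(xj, params$edges$theta[e], hill_n,
                  up = net$edges$sign[e] > 0L)
        val <- val * (params$edges$L[e] +
                        (params$edges$U[e] - params$edges$L[e]) * h)
      }
      dx[i] <- -params$gamma[i] * x[i] + val
    }
    list(dx)
  }
  locate <- function(x) {
    vapply(seq_along(nodes), function(i) {
      th <- sort(params$edges$theta[net$outputs[[nodes[i]]]])
      sum(th < x[i])
    }, integer(1))
  }

  rows <- list()
  for (r in seq_len(nrow(cells))) {
    s <- check_cell(space, cells[r, ])
    x <- vapply(seq_along(nodes), function(i) centers[[i]][s[i] + 1L],
                numeric(1))
    converged <- FALSE
    for (ch in seq_len(max_chunks)) {
      sol <- deSolve::lsoda(x, c(0, t_chunk), deriv, NULL,
                            rtol = 1e-8, atol = 1e-10)
      x <- as.numeric(sol[nrow(sol), -1])
      dx <- unlist(deriv(0, x, NULL))
      if (max(abs(dx)) < 1e-6 * max(abs(x), 1)) { converged <- TRUE; break }
    }
    rows[[length(rows) + 1L]] <- tibble(
      start = cell_label(s), end = cell_label(locate(x)),
      converged = converged)
  }
  bind_rows(rows)
}

#' Write a built-in network specification to a file
#'
#' @param name `"emt"` or `"toggle"`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_builtin_network <- function(name, path) {
  txt <- switch(name,
    emt = emt_spec_text,
    toggle = toggle_spec_text,
    abort(paste0("unknown builtin network: ", name),
          class = "switchmorse_cli_error"))
  writeLines(txt, path)
  invisible(path)
}
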
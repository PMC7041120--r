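# Combinatorial dynamics at one parameter node: the state transition graph
# over phase-space cells and its condensation into a Morse graph.

addr_vector <- function(pg, address) {
  if (is.data.frame(address)) {
    stopifnot(nrow(address) == 1L)
    address <- unlist(address[1, , drop = TRUE])
  }
  address <- address[pg$net$nodes]
  if (any(is.na(address)) || any(address < 1L) || any(address > pg$counts)) {
    abort("malformed address", class = "switchmorse_address_error")
  }
  as.integer(address)
}

# per-cell combination index (1-based column into the sign-pattern matrix)
# for gene i at the given address: bit e is set when input edge e of gene i
# contributes its U value in that cell.
gene_combos <- function(pg, addr, i) {
  rt <- pg$runtime
  gi <- rt$genes[[i]]
  comb <- rep(1L, rt$n_cells)
  for (e in seq_along(gi$reg_idx)) {
    j <- gi$reg_idx[e]
    gj <- rt$genes[[j]]
    slot <- match(i, gj$out_targets)
    rank <- gj$rank_mat[addr[j], slot]
    above <- rt$cells[, j] > rank
    bit_u <- if (gi$sign[e] > 0L) above else !above
    comb <- comb + bit_u * 2L^(e - 1L)
  }
  comb
}

#' Active input combination of a gene in a cell
#'
#' Which of `L` and `U` each input edge contributes to the production value
#' of `gene` when the system sits in cell `s`, at the parameter node
#' `address`.  A regulator above the relevant threshold contributes `U` on
#' an activating edge and `L` on a repressing one (and vice versa below);
#' whether it is above depends on the regulator's threshold ordering, which
#' the address fixes.
#'
#' @param pg A `parameter_graph`.
#' @param address A parameter-node address (named integer vector or 1-row
#'   tibble of active region indices).
#' @param gene Gene name.
#' @param s Cell label.
#' @return Named character vector (`"L"`/`"U"`), one entry per input edge,
#'   named by regulator.
#' @export
input_combination <- function(pg, address, gene, s) {
  stopifnot(inherits(pg, "parameter_graph"))
  addr <- addr_vector(pg, address)
  i <- match(gene, pg$net$nodes)
  if (is.na(i)) abort(paste0("unknown gene: ", gene),
                      class = "switchmorse_gene_error")
  s <- check_cell(pg$space, s)
  rt <- pg$runtime
  gi <- rt$genes[[i]]
  out <- character(length(gi$reg_idx))
  for (e in seq_along(gi$reg_idx)) {
    j <- gi$reg_idx[e]
    gj <- rt$genes[[j]]
    rank <- gj$rank_mat[addr[j], match(i, gj$out_targets)]
    above <- s[j] > rank
    out[e] <- if ((gi$sign[e] > 0L) == above) "U" else "L"
  }
  setNames(out, pg$net$nodes[gi$reg_idx])
}

# raw edge lists of the state transition graph; shared by build_stg() and
# the fast survey path
stg_edges <- function(pg, addr) {
  rt <- pg$runtime
  from <- integer(0); to <- integer(0)
  for (i in seq_along(rt$genes)) {
    gi <- rt$genes[[i]]
    mem <- gi$mems[[addr[i]]]
    comb <- gene_combos(pg, addr, i)
    stride <- rt$strides[i]
    for (k in seq_len(rt$p[i])) {
      low <- gi$low_cells[[k]]
      upp <- low + stride
      # production is evaluated in the cell the trajectory leaves; for a
      # network without self-inputs the two sides agree and every face
      # carries exactly one edge
      up_edge <- mem[k, comb[low]]
      down_edge <- !mem[k, comb[upp]]
      if (is.na(gi$self_input) && any(up_edge == down_edge)) {
        abort("inconsistent wall direction (negative self-regulation?)",
              class = "switchmorse_stg_error")
      }
      from <- c(from, low[up_edge], upp[down_edge])
      to <- c(to, upp[up_edge], low[down_edge])
    }
  }
  outdeg <- tabulate(from, rt$n_cells)
  self <- which(outdeg == 0L)
  list(from = c(from, self), to = c(to, self), self = self)
}

#' Build the state transition graph at a parameter node
#'
#' The vertices are the phase-space cells.  For each face between two
#' cells adjacent in coordinate `i` at threshold rank `k`, the direction of
#' crossing is read off the address's sign pattern for gene `i`: if the
#' production value in the lower cell lies above the decay-scaled
#' threshold, the edge points upward, otherwise downward.  No real
#' arithmetic is involved.  A cell whose face edges are all incoming is a
#' fixed point and receives a self-edge.
#'
#' @param pg A `parameter_graph`.
#' @param address Parameter-node address.
#' @return An `stg` object: integer edge lists `from`/`to` over 1-based
#'   cell ids (row indices of the cell table), plus the state space.
#' @examples
#' pg <- parameter_graph(toggle_switch_network())
#' stg <- build_stg(pg, address_from_index(pg, 4))  # central region
#' @export
build_stg <- function(pg, address) {
  stopifnot(inherits(pg, "parameter_graph"))
  addr <- addr_vector(pg, address)
  ed <- stg_edges(pg, addr)
  structure(
    list(from = ed$from, to = ed$to, self = ed$self,
         n_cells = pg$runtime$n_cells, space = pg$space,
         cells = pg$runtime$cells, address = setNames(addr, pg$net$nodes)),
    class = "stg")
}

#' @export
print.stg <- function(x, ...) {
  cat("State transition graph: ", x$n_cells, " cells, ",
      length(x$from), " edges (", length(x$self), " self-edges)\n", sep = "")
  invisible(x)
}

# strongly connected components + terminality, shared by morse_graph() and
# the fast survey path.  Returns membership, component sizes, the set of
# recurrent components and the stable (terminal) ones.
stg_components <- function(from, to, n_cells) {
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
  if (igraph::vcount(g) < n_cells) {
    g <- igraph::add_vertices(g, n_cells - igraph::vcount(g))
  }
  m <- igraph::components(g, mode = "strong")$membership
  sizes <- tabulate(m)
  cross <- m[from] != m[to]
  with_out <- unique(m[from[cross]])
  has_loop <- unique(m[from[from == to]])
  recurrent <- sort(unique(c(which(sizes >= 2L), has_loop)))
  terminal <- setdiff(seq_along(sizes), with_out)
  # every terminal component of an STG is recurrent: a terminal singleton
  # has no outgoing face edge, hence a self-edge
  stopifnot(all(terminal %in% recurrent))
  list(membership = m, sizes = sizes, recurrent = recurrent,
       stable = terminal, cross_from = m[from[cross]], cross_to = m[to[cross]])
}

annotate_component <- function(cells_mat, members) {
  if (length(members) == 1L) {
    return(list(type = "FP", label = fp_label(cells_mat[members, ])))
  }
  const <- vapply(seq_len(ncol(cells_mat)), function(j) {
    length(unique(cells_mat[members, j])) == 1L
  }, logical(1))
  type <- if (any(const)) "XC" else "FC"
  list(type = type, label = type)
}

#' Morse graph of a state transition graph
#'
#' Condenses the STG onto its recurrent components: maximal sets of
#' mutually reachable cells containing at least one edge (non-trivial
#' strongly connected components, or self-looped singletons).  Reachability
#' between recurrent components induces an acyclic graph whose edges are
#' reported transitively reduced.  A component with no out-edges in the
#' condensation is *stable*.  Annotations: `FP` for a singleton fixed point
#' (labelled with its cell), `XC` for a cycle along which at least one
#' coordinate is constant, `FC` for a full cycle.
#'
#' @param stg An `stg` from [build_stg()].
#' @return A `morse_graph`: `nodes` tibble (`node`, `type`, `label`,
#'   `stable`, `size`, `cells` list column) and `edges` tibble (`from`,
#'   `to`, transitively reduced reachability).
#' @export
morse_graph <- function(stg) {
  stopifnot(inherits(stg, "stg"))
  sc <- stg_components(stg$from, stg$to, stg$n_cells)
  rec <- sc$recurrent
  ann <- lapply(rec, function(comp) {
    annotate_component(stg$cells, which(sc$membership == comp))
  })
  nodes <- tibble(
    node = seq_along(rec),
    type = vapply(ann, `[[`, character(1), "type"),
    label = vapply(ann, `[[`, character(1), "label"),
    stable = rec %in% sc$stable,
    size = sc$sizes[rec],
    cells = lapply(rec, function(comp) {
      stg$cells[which(sc$membership == comp), , drop = FALSE]
    })
  )
  # reachability between recurrent components through the condensation
  cond_edges <- unique(cbind(sc$cross_from, sc$cross_to))
  n_comp <- length(sc$sizes)
  reach_edges <- NULL
  if (nrow(cond_edges) > 0L && length(rec) > 1L) {
    cg <- igraph::graph_from_edgelist(cond_edges, directed = TRUE)
    if (igraph::vcount(cg) < n_comp) {
      cg <- igraph::add_vertices(cg, n_comp - igraph::vcount(cg))
    }
    pairs <- list()
    for (a in seq_along(rec)) {
      down <- igraph::subcomponent(cg, rec[a], mode = "out")
      hit <- which(rec %in% as.integer(down) & rec != rec[a])
      for (b in hit) pairs[[length(pairs) + 1L]] <- c(a, b)
    }
    if (length(pairs)) {
      reach <- do.call(rbind, pairs)
      # transitive reduction for display: drop a -> b if some c has
      # a -> c -> b
      keyset <- paste(reach[, 1], reach[, 2])
      keep <- vapply(seq_len(nrow(reach)), function(r) {
        a <- reach[r, 1]; b <- reach[r, 2]
        mids <- reach[reach[, 1] == a & reach[, 2] != b, 2]
        !any(paste(mids, b) %in% keyset)
      }, logical(1))
      reach_edges <- reach[keep, , drop = FALSE]
    }
  }
  edges <- if (is.null(reach_edges)) {
    tibble(from = integer(0), to = integer(0))
  } else {
    tibble(from = reach_edges[, 1], to = reach_edges[, 2])
  }
  structure(list(nodes = nodes, edges = edges,
                 address = stg$address, space = stg$space),
            class = "morse_graph")
}

#' @export
print.morse_graph <- function(x, ...) {
  n <- x$nodes
  cat("Morse graph: ", nrow(n), " recurrent components (",
      sum(n$stable), " stable)\n", sep = "")
  for (r in seq_len(nrow(n))) {
    cat(sprintf("  [%d] %s%s\n", n$node[r], n$label[r],
                if (n$stable[r]) " *stable*" else ""))
  }
  if (nrow(x$edges)) {
    cat("edges:", paste(paste0(x$edges$from, "->", x$edges$to),
                        collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname morse_graph
#' @param x A `morse_graph`.
#' @param ... Unused.
#' @export
#' @method tidy morse_graph
tidy.morse_graph <- function(x, ...) {
  select(x$nodes, "node", "type", "label", "stable", "size")
}

#' @rdname morse_graph
#' @export
#' @method glance morse_graph
glance.morse_graph <- function(x, ...) {
  tibble(n_morse_nodes = nrow(x$nodes),
         n_stable = sum(x$nodes$stable),
         n_fp = sum(x$nodes$type == "FP"),
         n_xc = sum(x$nodes$type == "XC"),
         n_fc = sum(x$nodes$type == "FC"),
         all_stable_fp = all(x$nodes$type[x$nodes$stable] == "FP"))
}

#' Stable fixed points of a Morse graph
#'
#' @param mg A `morse_graph`.
#' @return Tibble with one row per stable fixed point: the cell label
#'   columns (gene order of the network) and `label`.
#' @export
stable_fixed_points <- function(mg) {
  stopifnot(inherits(mg, "morse_graph"))
  idx <- which(mg$nodes$stable & mg$nodes$type == "FP")
  cells <- do.call(rbind, lapply(mg$nodes$cells[idx], function(m) m[1, ]))
  if (is.null(cells)) {
    cells <- matrix(integer(0), ncol = length(mg$space$nodes),
                    dimnames = list(NULL, mg$space$nodes))
  }
  out <- as_tibble(as.data.frame(cells))
  out$label <- mg$nodes$label[idx]
  out
}

# fast survey path: stable structure only, no Morse edges or annotations
# beyond what the tallies need
morse_summary <- function(pg, addr) {
  ed <- stg_edges(pg, addr)
  sc <- stg_components(ed$from, ed$to, pg$runtime$n_cells)
  fp_comps <- sc$stable[sc$sizes[sc$stable] == 1L]
  fp_cells <- match(fp_comps, sc$membership)
  unstable_rec <- setdiff(sc$recurrent, sc$stable)
  list(n_stable = length(sc$stable),
       all_fp = all(sc$sizes[sc$stable] == 1L),
       fp = pg$runtime$cells[fp_cells, , drop = FALSE],
       n_unstable_recurrent = length(unstable_rec))
}

#' Export a Morse graph to JSON or DOT
#'
#' @param mg A `morse_graph`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_morse_json <- function(mg, path) {
  obj <- list(
    address = as.list(mg$address),
    nodes = lapply(seq_len(nrow(mg$nodes)), function(r) {
      list(node = mg$nodes$node[r], annotation = mg$nodes$label[r],
           stable = mg$nodes$stable[r], size = mg$nodes$size[r])
    }),
    edges = mg$edges)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_morse_json
#' @export
write_morse_dot <- function(mg, path) {
  lines <- c("digraph morse {")
  for (r in seq_len(nrow(mg$nodes))) {
    lines <- c(lines, sprintf("  n%d [label=\"%s\"%s];", mg$nodes$node[r],
                              mg$nodes$label[r],
                              if (mg$nodes$stable[r]) ", peripheries=2" else ""))
  }
  for (r in seq_len(nrow(mg$edges))) {
    lines <- c(lines, sprintf("  n%d -> n%d;", mg$edges$from[r], mg$edges$to[r]))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}
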
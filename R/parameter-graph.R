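# Product parameter graphs: the global parameter decomposition is the
# product of the per-gene factor graphs, so the graph is never stored --
# only per-gene region tables, counts, and mixed-radix indexing.

#' Build a (product) parameter graph
#'
#' The parameter graph of a network is the product of the per-gene factor
#' parameter graphs: a parameter node picks one factor region per gene and
#' corresponds to one inequality region of the full parameter space.  Each
#' gene's factor can be taken in `"full"` mode (all regions) or
#' `"essential"` mode (only regions where every edge of that gene carries
#' information).  The all-essential product is the essential parameter
#' graph; setting exactly one gene to `"full"` gives that gene's *general*
#' parameter graph, used to scan dynamics against its expression level.
#'
#' Sizes are products of per-gene counts, kept exact (they are far below
#' 2^53, the integer-exact range of IEEE doubles; this is asserted).
#'
#' @param net A `regnet`.  Every gene must have at least one input and one
#'   output edge.
#' @param modes Named character vector mapping genes to `"full"` or
#'   `"essential"`; unnamed scalar recycles to all genes.  Default all
#'   `"full"`.
#' @return A `parameter_graph` object.
#' @examples
#' pg <- parameter_graph(toggle_switch_network())
#' pg_size(pg)  # 9
#' @export
parameter_graph <- function(net, modes = "full") {
  stopifnot(inherits(net, "regnet"))
  if (is.null(names(modes))) {
    stopifnot(length(modes) == 1L)
    modes <- setNames(rep(modes, length(net$nodes)), net$nodes)
  }
  bad <- setdiff(names(modes), net$nodes)
  if (length(bad)) {
    abort(paste0("unknown gene in modes: ", paste(bad, collapse = ", ")),
          class = "switchmorse_gene_error")
  }
  full <- setNames(rep("essential", length(net$nodes)), net$nodes)
  full[names(modes)] <- modes
  modes <- full
  stopifnot(all(modes %in% c("full", "essential")))

  fgs <- lapply(net$nodes, function(g) factor_graph(net, g))
  names(fgs) <- net$nodes
  active <- lapply(net$nodes, function(g) {
    if (modes[[g]] == "full") fgs[[g]]$region else fgs[[g]]$region[fgs[[g]]$essential]
  })
  names(active) <- net$nodes
  counts <- vapply(active, length, integer(1))
  size <- prod(as.numeric(counts))
  stopifnot(size < 2^53)

  pg <- structure(
    list(net = net, space = state_space(net), factor_graphs = fgs,
         modes = modes, active = active, counts = counts, size = size),
    class = "parameter_graph")
  pg$runtime <- pg_runtime(pg)
  pg
}

#' @rdname parameter_graph
#' @export
essential_parameter_graph <- function(net) {
  parameter_graph(net, "essential")
}

#' @rdname parameter_graph
#' @param gene Gene whose factor graph is taken in full mode while all
#'   others stay essential.
#' @export
general_parameter_graph <- function(net, gene) {
  parameter_graph(net, setNames(
    replace(rep("essential", length(net$nodes)), match(gene, net$nodes), "full"),
    net$nodes))
}

#' Number of parameter nodes
#'
#' @param pg A `parameter_graph`.
#' @return The exact product of per-gene factor sizes (double, exact below
#'   2^53).
#' @export
pg_size <- function(pg) {
  stopifnot(inherits(pg, "parameter_graph"))
  pg$size
}

#' @export
print.parameter_graph <- function(x, ...) {
  cat("Parameter graph over (", paste(x$net$nodes, collapse = ", "), ")\n",
      sep = "")
  cat("modes: ", paste0(x$net$nodes, "=", x$modes[x$net$nodes], collapse = ", "),
      "\n", sep = "")
  cat("per-gene region counts:", paste(x$counts, collapse = " x "),
      "=", format(x$size, big.mark = ",", scientific = FALSE), "nodes\n")
  invisible(x)
}

#' @rdname parameter_graph
#' @param x A `parameter_graph`.
#' @param ... Unused.
#' @export
#' @method glance parameter_graph
glance.parameter_graph <- function(x, ...) {
  tibble(n_genes = length(x$net$nodes),
         size = x$size,
         dimension = parameter_dimension(x$net),
         n_essential_modes = sum(x$modes == "essential"))
}

#' @rdname parameter_graph
#' @export
#' @method tidy parameter_graph
tidy.parameter_graph <- function(x, ...) {
  tibble(gene = x$net$nodes,
         mode = unname(x$modes[x$net$nodes]),
         n_regions = unname(x$counts[x$net$nodes]),
         n_layers = vapply(x$net$nodes, function(g) {
           length(unique(x$factor_graphs[[g]]$layer[x$active[[g]]]))
         }, integer(1)))
}

# ---- addressing -------------------------------------------------------------

#' Mixed-radix addressing of parameter nodes
#'
#' A parameter-node address is the tuple of per-gene indices into each
#' gene's active (mode-restricted) region list.  `address_from_index()`
#' decodes a 0-based integer `i` in `[0, pg_size(pg))` by mixed-radix
#' decomposition with the first gene varying fastest; `index_from_address()`
#' is its inverse.  Both are exact for all representable sizes.
#'
#' @param pg A `parameter_graph`.
#' @param i 0-based node index (double holding an exact integer).
#' @return `address_from_index()`: named integer vector of 1-based active
#'   region indices.  `index_from_address()`: double.
#' @export
address_from_index <- function(pg, i) {
  stopifnot(inherits(pg, "parameter_graph"))
  if (i < 0 || i >= pg$size || i != floor(i)) {
    abort("index out of range", class = "switchmorse_index_error")
  }
  a <- integer(length(pg$counts))
  for (g in seq_along(pg$counts)) {
    a[g] <- as.integer(i %% pg$counts[g]) + 1L
    i <- (i - (a[g] - 1L)) / pg$counts[g]
  }
  setNames(a, pg$net$nodes)
}

#' @rdname address_from_index
#' @param address Named integer vector as returned by
#'   `address_from_index()`.
#' @export
index_from_address <- function(pg, address) {
  stopifnot(inherits(pg, "parameter_graph"))
  address <- address[pg$net$nodes]
  if (any(is.na(address)) || any(address < 1L) ||
      any(address > pg$counts)) {
    abort("invalid address", class = "switchmorse_index_error")
  }
  stride <- 1
  i <- 0
  for (g in seq_along(pg$counts)) {
    i <- i + (address[g] - 1) * stride
    stride <- stride * pg$counts[g]
  }
  unname(i)
}

#' Uniform sampling of parameter nodes
#'
#' Draws i.i.d. uniform addresses from the product parameter graph.
#' Uniformity over a product is equivalent to independent per-gene uniform
#' region choices, which is how the sampler works (no global index is
#' formed).  An optional restriction pins one gene's component to a given
#' layer of its factor graph.
#'
#' @param pg A `parameter_graph`.
#' @param n Number of addresses.
#' @param seed Integer seed; the sampler is deterministic given `seed`.
#' @param restrict Optional `list(gene = , layer = )` restricting that
#'   gene's component to the active regions in the given layer.
#' @return A tibble with one integer column per gene (1-based indices into
#'   the gene's active region list) and attributes `seed` and `restrict`.
#' @export
sample_addresses <- function(pg, n, seed, restrict = NULL) {
  stopifnot(inherits(pg, "parameter_graph"))
  pools <- lapply(pg$net$nodes, function(g) seq_len(pg$counts[[g]]))
  names(pools) <- pg$net$nodes
  if (!is.null(restrict)) {
    g <- restrict$gene
    if (!g %in% pg$net$nodes) {
      abort(paste0("unknown gene: ", g), class = "switchmorse_gene_error")
    }
    lay <- pg$factor_graphs[[g]]$layer[pg$active[[g]]]
    pool <- which(lay == restrict$layer)
    if (length(pool) == 0L) {
      abort(paste0("empty layer ", restrict$layer, " for gene ", g,
                   " in mode ", pg$modes[[g]]),
            class = "switchmorse_layer_error")
    }
    pools[[g]] <- pool
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  cols <- lapply(pools, function(pool) {
    pool[sample.int(length(pool), n, replace = TRUE)]
  })
  out <- as_tibble(cols)
  attr(out, "seed") <- seed
  attr(out, "restrict") <- restrict
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Enumerate every address of a small parameter graph
#'
#' Exhaustive iteration is guarded by a work bound because product sizes
#' grow multiplicatively; surveys on large graphs should sample instead.
#'
#' @param pg A `parameter_graph`.
#' @param work_bound Refuse enumeration beyond this many nodes unless
#'   `force = TRUE`.
#' @param force Override the bound.
#' @return Tibble of all addresses (one integer column per gene).
#' @export
all_addresses <- function(pg, work_bound = 1e6, force = FALSE) {
  stopifnot(inherits(pg, "parameter_graph"))
  if (pg$size > work_bound && !force) {
    abort(paste0("parameter graph has ", format(pg$size, scientific = FALSE),
                 " nodes, above the work bound of ",
                 format(work_bound, scientific = FALSE),
                 "; pass force = TRUE to iterate anyway"),
          class = "switchmorse_work_bound_error")
  }
  grid <- expand.grid(lapply(pg$counts, seq_len), KEEP.OUT.ATTRS = FALSE)
  names(grid) <- pg$net$nodes
  as_tibble(grid)
}

#' Write sampled addresses as JSON lines
#'
#' One JSON object per line: the per-gene active-region indices, plus a
#' header line carrying the mode map and seed.
#'
#' @param pg A `parameter_graph`.
#' @param addresses Tibble from [sample_addresses()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_addresses_jsonl <- function(pg, addresses, path) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  header <- list(modes = as.list(pg$modes),
                 seed = attr(addresses, "seed"),
                 n = nrow(addresses))
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE), con)
  for (r in seq_len(nrow(addresses))) {
    writeLines(jsonlite::toJSON(as.list(addresses[r, ]), auto_unbox = TRUE), con)
  }
  invisible(path)
}

# ---- runtime tables for the dynamics ---------------------------------------

# Precomputed per-gene tables used by the state-transition-graph builder:
# input edges (regulator index, sign), pattern matrices per active region,
# and per active region the threshold rank owned by each out-edge target.
pg_runtime <- function(pg) {
  net <- pg$net
  space <- pg$space
  cells <- state_cells(space)
  strides <- state_strides(space)
  nodes <- net$nodes
  rt <- list(cells = cells, strides = strides,
             n_cells = space$n_cells, p = space$p)
  rt$genes <- lapply(seq_along(nodes), function(i) {
    g <- nodes[i]
    in_edges <- net$inputs[[g]]
    reg_idx <- match(net$edges$source[in_edges], nodes)
    sign <- net$edges$sign[in_edges]
    out_targets <- match(net$edges$target[net$outputs[[g]]], nodes)
    fg <- pg$factor_graphs[[g]]
    act <- pg$active[[g]]
    mems <- lapply(act, function(r) fg$pattern[[r]])
    # rank_mat[r, slot]: 0-based rank of out-slot `slot` in region r's order
    rank_mat <- t(vapply(act, function(r) {
      ord <- fg$order[[r]]
      match(seq_along(out_targets), ord) - 1L
    }, integer(length(out_targets))))
    if (length(out_targets) == 1L) rank_mat <- matrix(rank_mat, ncol = 1L)
    low_cells <- lapply(seq_len(space$p[i]), function(k) {
      which(cells[, i] == k - 1L)
    })
    list(gene = g, reg_idx = reg_idx, sign = sign,
         out_targets = out_targets, mems = mems, rank_mat = rank_mat,
         low_cells = low_cells, self_input = match(i, reg_idx))
  })
  names(rt$genes) <- nodes
  rt
}
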
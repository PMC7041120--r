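# Regulatory networks with pure-product switching logic, and the
# threshold-discretised phase space they induce.

#' Parse a regulatory network specification
#'
#' Reads the plain-text network format used throughout the package: one line
#' per gene, of the form `Target : (Reg1)(~Reg2)`, where each parenthesised
#' factor names one regulator and a leading `~` marks repression.  The
#' production term of a gene is the product of one switching term per input
#' edge, so the factors multiply; sums of regulators are not supported.
#' Lines may contain `#` comments and arbitrary whitespace.
#'
#' The switching model attaches to every edge j -> i a low production level
#' `L_ij`, a high level `U_ij` and a threshold `theta_ij` (with
#' `0 < L_ij < U_ij`), and to every gene a decay rate `gamma_i > 0`.  A gene
#' above one of its thresholds actuates the corresponding downstream edge;
#' activation contributes `U` above threshold and `L` below, repression the
#' mirror image.
#'
#' Validation enforces the structural assumptions of the framework: at most
#' one edge per ordered gene pair, every regulator declared as a gene, and no
#' negative self-regulation (which would make the transition rules of the
#' state transition graph ambiguous).  Positive self-edges are permitted.
#'
#' @param spec_text Character scalar (possibly multi-line) or character
#'   vector of lines.
#' @return A `regnet` object: gene names in declaration order, a signed edge
#'   table, and the per-gene input/output edge lists that define the
#'   product logic and the phase-space discretisation.
#' @examples
#' net <- parse_network("X : (~Y)\nY : (~X)")
#' tidy(net)
#' @seealso [emt_network()], [toggle_switch_network()], [state_space()]
#' @export
parse_network <- function(spec_text) {
  lines <- unlist(strsplit(paste(spec_text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) == 0L) {
    abort("empty network specification", class = "switchmorse_parse_error")
  }

  nodes <- character(0)
  raw <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z0-9_.-]+)\\s*:\\s*(.*?)\\s*$", ln))[[1]]
    if (length(m) == 0L) {
      abort(paste0("cannot parse network line: ", trimws(ln)),
            class = "switchmorse_parse_error")
    }
    target <- m[2]
    if (target %in% nodes) {
      abort(paste0("duplicate node declaration: ", trimws(ln)),
            class = "switchmorse_parse_error")
    }
    if (grepl("+", m[3], fixed = TRUE)) {
      abort(paste0("unsupported logic (only pure products of single-edge terms): ",
                   trimws(ln)),
            class = "switchmorse_logic_error")
    }
    nodes <- c(nodes, target)
    raw[[target]] <- m[3]
  }

  src <- character(0); tgt <- character(0); sgn <- integer(0)
  for (target in nodes) {
    body <- raw[[target]]
    toks <- regmatches(body,
      gregexpr("\\(\\s*(~?)\\s*([A-Za-z0-9_.-]+)\\s*\\)", body))[[1]]
    leftover <- gsub("\\(\\s*~?\\s*[A-Za-z0-9_.-]+\\s*\\)", "", body)
    if (grepl("\\S", leftover)) {
      abort(paste0("cannot parse regulators in line: ", target, " : ", body),
            class = "switchmorse_parse_error")
    }
    for (tk in toks) {
      rep_edge <- grepl("~", tk, fixed = TRUE)
      reg <- gsub("[()~[:space:]]", "", tk)
      if (!(reg %in% nodes) && !(reg %in% names(raw))) {
        abort(paste0("undeclared regulator '", reg, "' in line: ",
                     target, " : ", body),
              class = "switchmorse_parse_error")
      }
      if (reg == target && rep_edge) {
        abort(paste0("negative self-regulation is not allowed: ",
                     target, " : ", body),
              class = "switchmorse_validate_error")
      }
      if (any(src == reg & tgt == target)) {
        abort(paste0("duplicate edge ", reg, " -> ", target, " in line: ",
                     target, " : ", body),
              class = "switchmorse_validate_error")
      }
      src <- c(src, reg); tgt <- c(tgt, target)
      sgn <- c(sgn, if (rep_edge) -1L else 1L)
    }
  }
  # regulators may be declared after first use; re-check now that all nodes known
  bad <- setdiff(src, nodes)
  if (length(bad)) {
    abort(paste0("undeclared regulator(s): ", paste(bad, collapse = ", ")),
          class = "switchmorse_parse_error")
  }

  edges <- tibble(source = src, target = tgt, sign = sgn)
  new_regnet(nodes, edges)
}

new_regnet <- function(nodes, edges) {
  inputs <- lapply(nodes, function(g) which(edges$target == g))
  outputs <- lapply(nodes, function(g) which(edges$source == g))
  names(inputs) <- names(outputs) <- nodes
  structure(
    list(nodes = nodes, edges = edges, inputs = inputs, outputs = outputs),
    class = "regnet"
  )
}

#' Serialize a network to its specification text
#'
#' Inverse of [parse_network()] on the canonical form: one line per gene in
#' declaration order, regulators in edge-declaration order.
#'
#' @param net A `regnet`.
#' @return A character scalar.
#' @export
network_spec <- function(net) {
  stopifnot(inherits(net, "regnet"))
  lines <- vapply(net$nodes, function(g) {
    ids <- net$inputs[[g]]
    fac <- vapply(ids, function(e) {
      paste0("(", if (net$edges$sign[e] < 0L) "~" else "", net$edges$source[e], ")")
    }, character(1))
    paste0(g, " : ", paste(fac, collapse = ""))
  }, character(1))
  paste(lines, collapse = "\n")
}

#' @export
print.regnet <- function(x, ...) {
  cat("Regulatory network (", length(x$nodes), " genes, ",
      nrow(x$edges), " edges)\n", sep = "")
  cat(network_spec(x), "\n")
  invisible(x)
}

#' @export
format.regnet <- function(x, ...) network_spec(x)

#' @rdname parse_network
#' @param x A `regnet`.
#' @param ... Unused.
#' @export
#' @method tidy regnet
tidy.regnet <- function(x, ...) {
  mutate(x$edges,
         sign = ifelse(.data$sign > 0L, "activating", "repressing"))
}

#' @rdname parse_network
#' @export
#' @method glance regnet
glance.regnet <- function(x, ...) {
  tibble(n_genes = length(x$nodes),
         n_edges = nrow(x$edges),
         n_activating = sum(x$edges$sign > 0L),
         n_repressing = sum(x$edges$sign < 0L),
         parameter_dimension = parameter_dimension(x))
}

in_degree <- function(net) lengths(net$inputs)
out_degree <- function(net) lengths(net$outputs)

#' Discretised phase space of a switching network
#'
#' The output thresholds of each gene cut its axis into `p_i + 1` intervals,
#' where `p_i` is the gene's out-degree; the phase space decomposes into the
#' product of these intervals.  Each box (cell) is labelled by the integer
#' vector counting, per coordinate, how many of that gene's thresholds lie
#' below it.
#'
#' @param net A `regnet`.
#' @return A `state_space` object with per-gene state ranges `0..p_i`, the
#'   total cell count, and the identity of the out-edge owning each
#'   threshold slot.
#' @examples
#' state_space(toggle_switch_network())
#' @export
state_space <- function(net) {
  stopifnot(inherits(net, "regnet"))
  p <- out_degree(net)
  structure(
    list(nodes = net$nodes, p = p, sizes = p + 1L,
         n_cells = as.integer(prod(p + 1L)),
         threshold_targets = lapply(net$nodes, function(g) {
           net$edges$target[net$outputs[[g]]]
         })),
    class = "state_space"
  )
}

#' @export
print.state_space <- function(x, ...) {
  cat("State space over (", paste(x$nodes, collapse = ", "), ")\n", sep = "")
  cat("states per gene:", paste0(x$sizes, collapse = " x "),
      "=", x$n_cells, "cells\n")
  invisible(x)
}

# integer matrix of all cell labels, one row per cell, first coordinate
# varying fastest; row index = 1 + sum_i s_i * stride_i
state_cells <- function(space) {
  m <- as.matrix(expand.grid(lapply(space$sizes, function(s) 0:(s - 1L)),
                             KEEP.OUT.ATTRS = FALSE))
  colnames(m) <- space$nodes
  storage.mode(m) <- "integer"
  m
}

state_strides <- function(space) {
  c(1L, cumprod(space$sizes))[seq_along(space$sizes)]
}

check_cell <- function(space, s) {
  if (length(s) != length(space$sizes) ||
      any(s < 0L) || any(s > space$p)) {
    abort(paste0("cell label out of range: (", paste(s, collapse = ","), ")"),
          class = "switchmorse_cell_error")
  }
  invisible(as.integer(s))
}

#' Face-adjacent neighbours of a phase-space cell
#'
#' Two cells are adjacent when they share an (n-1)-dimensional face, i.e.
#' they differ by one in exactly one coordinate.  The face lies on one of
#' the moving gene's actuation thresholds; its rank (1 = lowest threshold)
#' is reported alongside.
#'
#' @param space A `state_space`.
#' @param s Integer cell label.
#' @return A tibble with one row per neighbour: `gene`, `direction`
#'   (coordinate index), `delta` (+1/-1), `threshold_rank` (1-based rank of
#'   the crossed threshold), and `neighbor` (list of integer labels).
#' @export
cell_adjacency <- function(space, s) {
  s <- check_cell(space, s)
  rows <- list()
  for (i in seq_along(s)) {
    for (d in c(-1L, 1L)) {
      v <- s[i] + d
      if (v < 0L || v > space$p[i]) next
      nb <- s; nb[i] <- v
      rows[[length(rows) + 1L]] <- tibble(
        gene = space$nodes[i], direction = i, delta = d,
        threshold_rank = if (d > 0L) s[i] + 1L else s[i],
        neighbor = list(nb))
    }
  }
  bind_rows(rows)
}

#' Dimension of the parameter space of a switching network
#'
#' One decay rate per gene plus a `(L, U, theta)` triple per edge: `n + 3k`
#' for `n` genes and `k` edges.
#'
#' @param net A `regnet`.
#' @return Integer.
#' @examples
#' parameter_dimension(emt_network())  # 42
#' @export
parameter_dimension <- function(net) {
  stopifnot(inherits(net, "regnet"))
  length(net$nodes) + 3L * nrow(net$edges)
}

cell_label <- function(s) paste0("(", paste(s, collapse = ","), ")")
fp_label <- function(s) paste0("FP(", paste(s, collapse = ","), ")")
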
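# Multistability surveys of the six-gene EMT network: classification of
# stable fixed points as epithelial / mesenchymal / intermediate, layer-wise
# ensemble statistics, k-stability spectra and phase-space occupancy.

emt_gene_order <- c("Zeb1", "Snail1", "miR200", "miR34a", "TGFb", "Ovol2")
emt_state_max <- c(3L, 3L, 2L, 1L, 1L, 2L)

is_emt_space <- function(space) {
  identical(space$nodes, emt_gene_order) &&
    identical(unname(space$p), emt_state_max)
}

#' Classify a fixed point as epithelial, mesenchymal or intermediate
#'
#' In the gene order (Zeb1, Snail1, miR200, miR34a, TGFb, Ovol2) the
#' epithelial state is any fixed point of the form `(0,0,*,*,*,2)` (Zeb1
#' and Snail1 silent, Ovol2 maximal) and the mesenchymal state any
#' `(3,3,*,*,*,0)`.  All other fixed points are intermediate.  The degree
#' of resemblance is measured on the (Zeb1, Snail1, Ovol2) projection by
#' the taxicab distance from the epithelial corner,
#' `d_E = s_Zeb1 + s_Snail1 + (2 - s_Ovol2)`, which splits the 4 x 4 x 3
#' projection grid into nine diagonals with `d_E + d_M = 8`.
#'
#' @param label Integer cell label (length 6) or a matrix/data frame of
#'   labels, in the gene order above.
#' @return A tibble with columns `class` (`"E"`, `"M"`, `"intermediate"`),
#'   `distance_from_E` and `distance_from_M`.
#' @examples
#' classify_fp(c(2, 0, 1, 1, 0, 1))
#' @export
classify_fp <- function(label) {
  m <- if (is.null(dim(label))) matrix(as.integer(label), nrow = 1L)
       else as.matrix(label)
  if (ncol(m) != 6L || any(m < 0L) ||
      any(sweep(m, 2, emt_state_max, `>`))) {
    abort("label is not a cell of the EMT state space",
          class = "switchmorse_cell_error")
  }
  d_e <- m[, 1] + m[, 2] + (2L - m[, 6])
  cls <- ifelse(m[, 1] == 0L & m[, 2] == 0L & m[, 6] == 2L, "E",
         ifelse(m[, 1] == 3L & m[, 2] == 3L & m[, 6] == 0L, "M",
                "intermediate"))
  tibble(class = cls, distance_from_E = as.integer(d_e),
         distance_from_M = 8L - as.integer(d_e))
}

# per-address tallies shared by survey_layers() and domain_occupancy()
census_one <- function(pg, addr, emt) {
  ms <- morse_summary(pg, addr)
  fp <- ms$fp
  out <- list(k = ms$n_stable, all_fp = ms$all_fp,
              n_unstable_recurrent = ms$n_unstable_recurrent,
              labels = apply(fp, 1, fp_label))
  if (emt) {
    out$has_e <- any(fp[, 1] == 0L & fp[, 2] == 0L & fp[, 6] == 2L)
    out$has_m <- any(fp[, 1] == 3L & fp[, 2] == 3L & fp[, 6] == 0L)
    out$diags <- unique(fp[, 1] + fp[, 2] + (2L - fp[, 6]))
  }
  out
}

#' Morse-graph census over a set of parameter nodes
#'
#' Computes the stable structure of the Morse graph at every address and
#' returns one row per address: number of stable nodes `k`, whether all
#' stable nodes are fixed points, and the stable fixed-point labels.
#'
#' @param pg A `parameter_graph`.
#' @param addresses Tibble of addresses ([sample_addresses()] /
#'   [all_addresses()]).
#' @return A tibble with columns `k`, `all_fp`, `n_unstable_recurrent` and
#'   list column `labels`.
#' @export
morse_census <- function(pg, addresses) {
  stopifnot(inherits(pg, "parameter_graph"))
  A <- as.matrix(addresses[, pg$net$nodes, drop = FALSE])
  rows <- lapply(seq_len(nrow(A)), function(r) {
    cs <- census_one(pg, A[r, ], emt = FALSE)
    tibble(k = cs$k, all_fp = cs$all_fp,
           n_unstable_recurrent = cs$n_unstable_recurrent,
           labels = list(cs$labels))
  })
  bind_rows(rows)
}

layer_seed <- function(seed, layer) {
  as.integer((as.numeric(seed) * 131 + layer) %% .Machine$integer.max)
}

#' Layer-wise multistability survey of an X-general EMT ensemble
#'
#' For the chosen gene `X`, builds the X-general parameter graph (X's
#' factor graph in full mode, every other gene essential) and tallies, for
#' each layer of X's factor graph, the dynamics over parameter nodes whose
#' X-component lies in that layer: proportions of nodes with monostable
#' epithelial or mesenchymal state, with the E or M state present at all,
#' per-diagonal fixed-point occurrence (distance-from-E bins 0..8, both
#' monostable-only and any), and the k-stability histogram.  Layers are
#' sampled uniformly (the default) or enumerated exhaustively when small
#' enough.
#'
#' @param net The EMT network ([emt_network()]).
#' @param gene One of Zeb1, Snail1, TGFb, Ovol2 (any EMT gene works).
#' @param n_per_layer Sample size per layer.
#' @param seed Integer seed; per-layer streams are derived from it.
#' @param layers Layers to survey (default: all layers of the gene's
#'   factor graph).
#' @param exhaustive Enumerate every node of each restricted layer instead
#'   of sampling; refused above `work_bound`.
#' @param work_bound Maximum number of Morse graphs an exhaustive run may
#'   compute.
#' @return A `layer_survey` tibble, one row per layer, with attributes
#'   `gene`, `seed`, `exhaustive` and `k_max`.
#' @export
survey_layers <- function(net, gene, n_per_layer = 2000, seed = 0,
                          layers = NULL, exhaustive = FALSE,
                          work_bound = 1e6) {
  stopifnot(inherits(net, "regnet"))
  space <- state_space(net)
  if (!is_emt_space(space)) {
    abort("layer surveys with E/M classification require the EMT network",
          class = "switchmorse_network_error")
  }
  pg <- general_parameter_graph(net, gene)
  fg <- pg$factor_graphs[[gene]]
  all_layers <- sort(unique(fg$layer))
  if (is.null(layers)) layers <- all_layers
  stopifnot(all(layers %in% all_layers))

  k_cap <- 12L
  rows <- list()
  for (lay in layers) {
    if (exhaustive) {
      pool <- which(fg$layer[pg$active[[gene]]] == lay)
      n_lay <- pg$size / pg$counts[[gene]] * length(pool)
      if (n_lay > work_bound) {
        abort(paste0("exhaustive layer survey needs ", n_lay,
                     " Morse graphs, above the work bound"),
              class = "switchmorse_work_bound_error")
      }
      counts2 <- pg$counts
      grids <- lapply(pg$net$nodes, function(g) {
        if (g == gene) pool else seq_len(counts2[[g]])
      })
      addr_tbl <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
      names(addr_tbl) <- pg$net$nodes
    } else {
      addr_tbl <- sample_addresses(pg, n_per_layer, layer_seed(seed, lay),
                                   restrict = list(gene = gene, layer = lay))
    }
    A <- as.matrix(addr_tbl[, pg$net$nodes, drop = FALSE])
    n <- nrow(A)
    acc <- list(mono_e = 0L, mono_m = 0L, e_pres = 0L, m_pres = 0L,
                diag_any = integer(9L), diag_mono = integer(9L),
                k_hist = integer(k_cap), non_fp = 0L)
    for (r in seq_len(n)) {
      cs <- census_one(pg, A[r, ], emt = TRUE)
      mono <- cs$k == 1L
      acc$e_pres <- acc$e_pres + cs$has_e
      acc$m_pres <- acc$m_pres + cs$has_m
      acc$mono_e <- acc$mono_e + (mono && cs$has_e)
      acc$mono_m <- acc$mono_m + (mono && cs$has_m)
      acc$diag_any[cs$diags + 1L] <- acc$diag_any[cs$diags + 1L] + 1L
      if (mono) acc$diag_mono[cs$diags + 1L] <- acc$diag_mono[cs$diags + 1L] + 1L
      kk <- min(cs$k, k_cap)
      acc$k_hist[kk] <- acc$k_hist[kk] + 1L
      acc$non_fp <- acc$non_fp + !cs$all_fp
    }
    row <- tibble(layer = lay, n = n, exhaustive = exhaustive,
                  mono_E = acc$mono_e / n, mono_M = acc$mono_m / n,
                  E_present = acc$e_pres / n, M_present = acc$m_pres / n,
                  non_fp_stable = acc$non_fp / n)
    for (d in 0:8) row[[paste0("mono_diag_", d)]] <- acc$diag_mono[d + 1L] / n
    for (d in 0:8) row[[paste0("diag_", d)]] <- acc$diag_any[d + 1L] / n
    for (k in seq_len(k_cap)) row[[paste0("k_", k)]] <- acc$k_hist[k] / n
    rows[[length(rows) + 1L]] <- row
  }
  out <- bind_rows(rows)
  k_cols <- paste0("k_", seq_len(k_cap))
  k_max <- max(c(1L, which(colSums(out[, k_cols]) > 0)))
  out <- out[, c(setdiff(names(out), k_cols), paste0("k_", seq_len(k_max)))]
  attr(out, "gene") <- gene
  attr(out, "seed") <- seed
  attr(out, "n_per_layer") <- n_per_layer
  attr(out, "exhaustive") <- exhaustive
  attr(out, "k_max") <- k_max
  class(out) <- c("layer_survey", class(out))
  out
}

#' k-stability spectrum of a layer survey
#'
#' @param survey A `layer_survey`.
#' @return Long tibble with columns `layer`, `k`, `proportion`; per-layer
#'   proportions sum to 1.
#' @export
multistability_spectrum <- function(survey) {
  stopifnot(inherits(survey, "layer_survey"))
  k_cols <- grep("^k_[0-9]+$", names(survey), value = TRUE)
  out <- tidyr::pivot_longer(
    as_tibble(survey)[, c("layer", k_cols)],
    dplyr::all_of(k_cols), names_to = "k", values_to = "proportion")
  out$k <- as.integer(sub("^k_", "", out$k))
  arrange(out, .data$layer, .data$k)
}

#' Phase-space domain occupancy of stable fixed points
#'
#' Which cells of phase space ever host a stable fixed point across an
#' ensemble of parameter nodes?  For sampled ensembles the count is a lower
#' bound that is non-decreasing in the sample size.
#'
#' @param pg A `parameter_graph`.
#' @param addresses Tibble of addresses; default draws `n` uniform samples.
#' @param n,seed Used only when `addresses` is missing.
#' @return A `domain_occupancy` object: sorted distinct stable-FP labels,
#'   their count and the occupied fraction of all cells.
#' @export
domain_occupancy <- function(pg, addresses = NULL, n = 2000, seed = 0) {
  stopifnot(inherits(pg, "parameter_graph"))
  if (is.null(addresses)) addresses <- sample_addresses(pg, n, seed)
  A <- as.matrix(addresses[, pg$net$nodes, drop = FALSE])
  seen <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(A))) {
    cs <- census_one(pg, A[r, ], emt = FALSE)
    for (lb in cs$labels) assign(lb, TRUE, envir = seen)
  }
  labels <- sort(ls(seen))
  structure(
    list(labels = labels, count = length(labels),
         n_cells = pg$space$n_cells,
         fraction = length(labels) / pg$space$n_cells,
         n_addresses = nrow(A), modes = pg$modes),
    class = "domain_occupancy")
}

#' @export
print.domain_occupancy <- function(x, ...) {
  cat("Domain occupancy: ", x$count, " of ", x$n_cells, " cells (",
      sprintf("%.1f%%", 100 * x$fraction), ") host a stable fixed point\n",
      "over ", x$n_addresses, " parameter nodes\n", sep = "")
  invisible(x)
}

#' @rdname domain_occupancy
#' @param x A `domain_occupancy`.
#' @param ... Unused.
#' @export
#' @method tidy domain_occupancy
tidy.domain_occupancy <- function(x, ...) {
  tibble(label = x$labels)
}

#' @rdname domain_occupancy
#' @export
#' @method glance domain_occupancy
glance.domain_occupancy <- function(x, ...) {
  tibble(count = x$count, n_cells = x$n_cells, fraction = x$fraction,
         n_addresses = x$n_addresses)
}

#' Write a survey or occupancy report to CSV and JSON
#'
#' Writes `<path>.csv` (one row per layer for surveys, one row per occupied
#' cell for occupancies) and `<path>.json` (full nested results including
#' seed, sample sizes and modes), with deterministic field order so that
#' identical inputs give byte-identical files.
#'
#' @param x A `layer_survey` or `domain_occupancy`.
#' @param path Output path prefix (without extension).
#' @return Character vector of the two files written, invisibly.
#' @export
write_report <- function(x, path) {
  UseMethod("write_report")
}

#' @export
write_report.layer_survey <- function(x, path) {
  if (nrow(x) == 0L) {
    abort("empty survey", class = "switchmorse_report_error")
  }
  csv <- paste0(path, ".csv")
  json <- paste0(path, ".json")
  utils::write.csv(as.data.frame(x), csv, row.names = FALSE)
  obj <- list(kind = "layer_survey",
              gene = attr(x, "gene"), seed = attr(x, "seed"),
              n_per_layer = attr(x, "n_per_layer"),
              exhaustive = attr(x, "exhaustive"),
              layers = lapply(seq_len(nrow(x)), function(r) as.list(x[r, ])))
  jsonlite::write_json(obj, json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, json))
}

#' @export
write_report.domain_occupancy <- function(x, path) {
  if (x$n_addresses == 0L) {
    abort("empty occupancy", class = "switchmorse_report_error")
  }
  csv <- paste0(path, ".csv")
  json <- paste0(path, ".json")
  utils::write.csv(data.frame(label = x$labels), csv, row.names = FALSE)
  obj <- list(kind = "domain_occupancy", modes = as.list(x$modes),
              n_addresses = x$n_addresses, count = x$count,
              n_cells = x$n_cells, fraction = x$fraction, labels = x$labels)
  jsonlite::write_json(obj, json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, json))
}

#' @rdname survey_layers
#' @param x A `layer_survey`.
#' @param ... Unused.
#' @export
#' @method glance layer_survey
glance.layer_survey <- function(x, ...) {
  tibble(gene = attr(x, "gene"), n_layers = nrow(x),
         seed = attr(x, "seed"), k_max = attr(x, "k_max"),
         exhaustive = attr(x, "exhaustive"))
}

#' @rdname survey_layers
#' @export
#' @method tidy layer_survey
tidy.layer_survey <- function(x, ...) {
  base <- c("layer", "n", "mono_E", "mono_M", "E_present", "M_present")
  tidyr::pivot_longer(as_tibble(x)[, base], -c("layer", "n"),
                      names_to = "statistic", values_to = "proportion")
}
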
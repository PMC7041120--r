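# enumerate all raw sign patterns for a (q, p) node and filter them with
# realizable(); independent of the chain search inside factor_graph()
brute_force_patterns <- function(q, p) {
  nb <- p * 2L^q
  keep <- list()
  for (mask in 0:(2L^nb - 1L)) {
    v <- bitwAnd(bitwShiftR(mask, 0:(nb - 1L)), 1L) == 1L
    pat <- matrix(v, nrow = p, byrow = TRUE)
    if (realizable(pat)) keep[[length(keep) + 1L]] <- pat
  }
  keep
}

pattern_key <- function(pat) paste(as.integer(t(pat)), collapse = "")

test_that("realizable() handles canonical and contradictory patterns", {
  # single input, two thresholds: L < g*t1 < g*t2 < U
  expect_true(realizable(rbind(c(FALSE, TRUE), c(FALSE, TRUE))))
  # U below a threshold that L is above contradicts L < U
  expect_false(realizable(matrix(c(TRUE, FALSE), nrow = 1)))
  # two-input cross-constraint: t1 above-set {UL, UU}, t2 above-set {LU, UU}
  # would need d1 > d2 and d2 > d1 simultaneously
  expect_false(realizable(rbind(c(FALSE, TRUE, FALSE, TRUE),
                                c(FALSE, FALSE, TRUE, TRUE))))
  # all-below and all-above are always realizable
  expect_true(realizable(matrix(FALSE, 2, 4)))
  expect_true(realizable(matrix(TRUE, 2, 4)))
  expect_error(realizable(matrix(FALSE, 1, 3)), "2\\^q")
})

test_that("chain enumeration matches brute-force pattern enumeration", {
  # small shapes where raw enumeration over all 2^(p*2^q) patterns is cheap;
  # scaffold networks give gene X the wanted in/out shape
  mk <- function(q, p) {
    # gene X with q inputs and p outputs inside a scaffold network
    if (q == 1L && p == 1L) parse_network("X : (Y)\nY : (X)")
    else if (q == 1L && p == 2L)
      parse_network("X : (~Y)\nY : (X)\nZ : (X)(Y)")
    else if (q == 2L && p == 1L)
      parse_network("X : (Y)(~Z)\nY : (X)(Z)\nZ : (Y)")
    else if (q == 2L && p == 2L)
      parse_network("X : (Y)(Z)\nY : (~X)(Z)\nZ : (X)(~Y)")
  }
  for (sh in list(c(1L, 1L), c(1L, 2L), c(2L, 1L), c(2L, 2L))) {
    q <- sh[1]; p <- sh[2]
    fg <- factor_graph(mk(q, p), "X")
    per_order <- unique(vapply(fg$pattern, pattern_key, character(1)))
    brute <- unique(vapply(brute_force_patterns(q, p), pattern_key,
                           character(1)))
    expect_setequal(per_order, brute)
    expect_identical(nrow(fg), length(brute) * as.integer(factorial(p)))
  }
})

test_that("Ovol2 factor graph reproduces the twelve canonical regions", {
  fg <- factor_graph(emt(), "Ovol2")
  expect_identical(nrow(fg), 12L)
  expect_identical(sort(unique(fg$layer)), 1:5)

  tZ <- "gamma*theta_{Zeb1,Ovol2}"
  tG <- "gamma*theta_{TGFb,Ovol2}"
  expected <- c(
    paste("L < U <", tZ, "<", tG),          # A1
    paste("L <", tZ, "< U <", tG),          # A2
    paste(tZ, "< L < U <", tG),             # A3
    paste("L <", tZ, "<", tG, "< U"),       # A4
    paste(tZ, "< L <", tG, "< U"),          # A5
    paste(tZ, "<", tG, "< L < U"),          # A6
    paste("L < U <", tG, "<", tZ),          # B1
    paste("L <", tG, "< U <", tZ),          # B2
    paste(tG, "< L < U <", tZ),             # B3
    paste("L <", tG, "<", tZ, "< U"),       # B4
    paste(tG, "< L <", tZ, "< U"),          # B5
    paste(tG, "<", tZ, "< L < U"))          # B6
  got <- vapply(fg$region, function(r) region_inequalities(fg, r),
                character(1))
  expect_identical(got, expected)

  # essential subset is exactly {A4, B4}; layers of the extremes
  expect_identical(fg$region[fg$essential], c(4L, 10L))
  expect_identical(fg$layer[c(1L, 6L)], c(1L, 5L))   # A1, A6
  expect_identical(fg$layer[3L], fg$layer[4L])       # A3 and A4 share a layer
  expect_identical(fg$layer[3L], 3L)
})

test_that("small EMT factor graphs have the expected shapes", {
  for (case in list(list("TGFb", 6L, 5L, 2L), list("miR34a", 6L, 5L, 2L),
                    list("miR200", 40L, 9L, 14L))) {
    fg <- factor_graph(emt(), case[[1]])
    expect_identical(nrow(fg), case[[2]])
    expect_identical(length(unique(fg$layer)), case[[3]])
    expect_identical(sum(fg$essential), case[[4]])
  }
})

test_that("TGFb factor graph is isomorphic to the A-half of Ovol2's", {
  fg_o <- factor_graph(emt(), "Ovol2")
  fg_t <- factor_graph(emt(), "TGFb")
  expect_identical(nrow(fg_t), 6L)
  # A-half: the six regions sharing the identity threshold ordering
  a_half <- which(vapply(fg_o$order, function(o) o[1] == 1L, logical(1)))
  e_o <- factor_graph_edges(fg_o)
  e_o <- e_o[e_o$from %in% a_half & e_o$to %in% a_half, ]
  g_o <- igraph::graph_from_edgelist(
    cbind(match(e_o$from, a_half), match(e_o$to, a_half)), directed = FALSE)
  e_t <- factor_graph_edges(fg_t)
  g_t <- igraph::graph_from_edgelist(cbind(e_t$from, e_t$to),
                                     directed = FALSE)
  expect_true(igraph::isomorphic(g_o, g_t))
  # matching layer histograms
  expect_identical(table(fg_o$layer[a_half]), table(fg_t$layer))
})

test_that("essentiality follows the information-carrying definition", {
  # 2-input, single threshold (TGFb shape): above-set {UU} is essential,
  # above-set {UL, UU} ignores the second input
  expect_true(region_essential(matrix(c(FALSE, FALSE, FALSE, TRUE), 1)))
  expect_false(region_essential(matrix(c(FALSE, TRUE, FALSE, TRUE), 1)))
  expect_true(region_essential(matrix(c(FALSE, TRUE, TRUE, TRUE), 1)))
  # dropping the input condition strictly enlarges the set for 2-input genes
  for (g in c("Snail1", "miR200", "miR34a", "TGFb")) {
    fg <- factor_graph(emt(), g)
    only_a <- vapply(fg$pattern, function(m) {
      !any(rowSums(m) == 0L) && !any(rowSums(m) == ncol(m))
    }, logical(1))
    expect_gt(sum(only_a), sum(fg$essential))
  }
})

test_that("layers count actuated inequalities and tile the factor graph", {
  for (g in c("Ovol2", "TGFb", "Snail1")) {
    fg <- factor_graph(emt(), g)
    expect_identical(fg$layer, fg$above + 1L)
    expect_identical(sum(table(fg$layer)), nrow(fg))
    p <- attr(fg, "p")
    # layer 1 holds exactly the all-below regions, one per ordering
    expect_identical(sum(fg$layer == 1L), as.integer(factorial(p)))
    expect_identical(sum(fg$layer == max(fg$layer)), as.integer(factorial(p)))
    expect_true(all(vapply(which(fg$layer == 1L),
                           function(r) !any(fg$pattern[[r]]), logical(1))))
  }
})

test_that("every enumerated region is realizable", {
  for (g in c("Ovol2", "TGFb", "miR200")) {
    fg <- factor_graph(emt(), g)
    expect_true(all(vapply(fg$pattern, realizable, logical(1))))
  }
})

test_that("factor graphs need at least one input and one output", {
  net <- parse_network("A : (B)\nB : (A)\nC : (A)")
  expect_error(factor_graph(net, "C"), ">= 1 input")
  expect_error(factor_graph(net, "missing"), "unknown gene")
})

test_that("perturbed instantiations inside each Ovol2 region keep its signs", {
  pg <- emt_pg("full")
  base <- rep(1L, 6)
  names(base) <- pg$net$nodes
  set.seed(99)
  for (r in 1:12) {
    a <- base; a[["Ovol2"]] <- r
    par <- instantiate_parameters(pg, a, margin = 0.05)
    for (draw in 1:50) {
      jit <- par
      jit$edges$L <- par$edges$L * exp(stats::runif(12, -0.02, 0.02))
      jit$edges$U <- par$edges$U * exp(stats::runif(12, -0.02, 0.02))
      jit$edges$theta <- par$edges$theta * exp(stats::runif(12, -0.02, 0.02))
      back <- parameters_to_address(pg, jit)
      expect_identical(unname(back), unname(a))
    }
  }
})
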
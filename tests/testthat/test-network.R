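test_that("toggle switch parses to two mutually repressing genes", {
  net <- parse_network("X : (~Y)\nY : (~X)")
  expect_identical(net$nodes, c("X", "Y"))
  expect_identical(nrow(net$edges), 2L)
  expect_true(all(net$edges$sign == -1L))
})

test_that("EMT network has the expected degree profile", {
  net <- emt()
  expect_identical(net$nodes,
                   c("Zeb1", "Snail1", "miR200", "miR34a", "TGFb", "Ovol2"))
  expect_identical(nrow(net$edges), 12L)
  deg_in <- lengths(net$inputs)
  deg_out <- lengths(net$outputs)
  expect_identical(unname(deg_in), c(3L, 2L, 2L, 2L, 2L, 1L))
  expect_identical(unname(deg_out), c(3L, 3L, 2L, 1L, 1L, 2L))
  # Ovol2: one input from Zeb1, outputs to Zeb1 and TGFb
  expect_identical(net$edges$source[net$inputs$Ovol2], "Zeb1")
  expect_setequal(net$edges$target[net$outputs$Ovol2], c("Zeb1", "TGFb"))
})

test_that("parse -> serialize -> parse is the identity on canonical form", {
  for (net in list(emt(), toggle(), random_network(3, 11))) {
    rt <- parse_network(network_spec(net))
    expect_identical(rt$nodes, net$nodes)
    expect_identical(rt$edges, net$edges)
  }
})

test_that("invalid specifications are rejected with the offending line", {
  expect_error(parse_network("X : (~X)"), "negative self-regulation")
  expect_error(parse_network("X : (Y)(Y)\nY : (X)"), "duplicate edge")
  expect_error(parse_network("X : (Z)"), "undeclared regulator")
  expect_error(parse_network("X : (X)\nX : (X)"), "duplicate node")
  expect_error(parse_network("X : (X + Y)\nY : (X)"), "unsupported logic")
  expect_error(parse_network("  "), "empty")
})

test_that("comments and whitespace are ignored", {
  net <- parse_network("# toggle\n  X :  ( ~ Y )  # repressed\nY : (~X)\n")
  expect_identical(nrow(net$edges), 2L)
})

test_that("state spaces have the right sizes", {
  expect_identical(state_space(toggle())$n_cells, 4L)
  expect_identical(state_space(emt())$n_cells, 576L)
  expect_identical(unname(state_space(emt())$sizes), c(4L, 4L, 3L, 2L, 2L, 3L))
  # single gene with a positive self-edge: one threshold, states {0, 1}
  self <- parse_network("A : (A)")
  expect_identical(state_space(self)$n_cells, 2L)
  expect_identical(unname(state_space(self)$p), 1L)
})

test_that("cell adjacency matches the face structure", {
  sp_t <- state_space(toggle())
  adj <- cell_adjacency(sp_t, c(0L, 0L))
  expect_identical(nrow(adj), 2L)
  expect_setequal(vapply(adj$neighbor, paste, character(1), collapse = ","),
                  c("1,0", "0,1"))

  sp_e <- state_space(emt())
  top <- cell_adjacency(sp_e, c(3L, 3L, 2L, 1L, 1L, 2L))
  expect_identical(nrow(top), 6L)
  expect_true(all(top$delta == -1L))
  # coordinates at 1 of 3, 1 of 3, 1 of 2, 0 of 1, 0 of 1, 1 of 2 give
  # 2+2+2+1+1+2 = 10 face neighbours
  mid <- cell_adjacency(sp_e, c(1L, 1L, 1L, 0L, 0L, 1L))
  expect_identical(nrow(mid), 10L)

  expect_error(cell_adjacency(sp_e, c(4L, 0L, 0L, 0L, 0L, 0L)),
               "out of range")
})

test_that("cell adjacency is symmetric with n..2n neighbours per cell", {
  sp <- state_space(emt())
  set.seed(1)
  for (r in 1:25) {
    s <- vapply(sp$p, function(p) sample(0:p, 1L), integer(1))
    adj <- cell_adjacency(sp, s)
    expect_gte(nrow(adj), 6L)
    expect_lte(nrow(adj), 12L)
    for (i in seq_len(nrow(adj))) {
      back <- cell_adjacency(sp, adj$neighbor[[i]])
      keys <- vapply(back$neighbor, paste, character(1), collapse = ",")
      expect_true(paste(s, collapse = ",") %in% keys)
    }
  }
})

test_that("parameter dimension is n + 3k", {
  expect_identical(parameter_dimension(emt()), 42L)
  expect_identical(parameter_dimension(toggle()), 8L)
  expect_identical(parameter_dimension(parse_network("A : (A)")), 4L)
})
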
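test_that("all nine toggle parameter nodes match the numeric oracle", {
  pg <- toggle_pg()
  net <- toggle()
  n_bistable <- 0L
  for (i in 0:8) {
    addr <- address_from_index(pg, i)
    stg <- build_stg(pg, addr)
    mg <- morse_graph(stg)
    fps <- stable_fixed_points(mg)
    # independent route: instantiate real parameters and evaluate the
    # vector field numerically on every face
    par <- instantiate_parameters(pg, addr)
    stg_num <- stg_from_parameters(net, par)
    expect_identical(sort(paste(stg$from, stg$to)),
                     sort(paste(stg_num$from, stg_num$to)))
    expect_gte(nrow(fps), 1L)
    if (nrow(fps) == 2L) n_bistable <- n_bistable + 1L
  }
  expect_identical(n_bistable, 1L)  # only the central node is bistable
})

test_that("the central toggle region is bistable with FP(0,1) and FP(1,0)", {
  pg <- toggle_pg()
  central <- c(X = 2L, Y = 2L)  # both genes in their L < g*theta < U region
  mg <- morse_graph(build_stg(pg, central))
  expect_identical(sort(stable_fixed_points(mg)$label),
                   c("FP(0,1)", "FP(1,0)"))
  expect_identical(nrow(mg$nodes), 2L)
})

test_that("the all-below EMT address decays to the origin", {
  pg <- emt_pg("full")
  addr <- setNames(rep(1L, 6), pg$net$nodes)  # region 1 = all-below everywhere
  stg <- build_stg(pg, addr)
  # every face edge points downward: target always below source
  down <- stg$to[stg$from != stg$to] < stg$from[stg$from != stg$to]
  expect_true(all(down))
  mg <- morse_graph(stg)
  expect_identical(stable_fixed_points(mg)$label, "FP(0,0,0,0,0,0)")
  expect_identical(nrow(mg$nodes), 1L)
})

test_that("input combinations follow the switching-term semantics", {
  pg <- toggle_pg()
  addr <- c(X = 2L, Y = 2L)
  # in cell (0,0) each repressor is below threshold, so both genes read U
  expect_identical(unname(input_combination(pg, addr, "X", c(0L, 0L))), "U")
  expect_identical(unname(input_combination(pg, addr, "Y", c(0L, 0L))), "U")
  expect_identical(unname(input_combination(pg, addr, "X", c(0L, 1L))), "L")

  pge <- emt_pg("full")
  ae <- setNames(rep(1L, 6), pge$net$nodes)
  # Ovol2 is repressed by Zeb1: above threshold means L
  high <- c(3L, 0L, 0L, 0L, 0L, 0L)
  expect_identical(unname(input_combination(pge, ae, "Ovol2", high)), "L")
  low <- c(0L, 0L, 0L, 0L, 0L, 0L)
  expect_identical(unname(input_combination(pge, ae, "Ovol2", low)), "U")
  # Snail1 reads (TGFb activator, miR34a repressor)
  cmb <- input_combination(pge, ae, "Snail1", c(0L, 0L, 0L, 0L, 1L, 0L))
  expect_identical(unname(cmb), c("U", "U"))
})

test_that("every face carries exactly one edge and Morse graphs are sane", {
  pg <- emt_pg("essential")
  n_faces <- sum(vapply(seq_along(pg$net$nodes), function(i) {
    pg$space$p[i] * pg$space$n_cells / pg$space$sizes[i]
  }, numeric(1)))
  a <- sample_addresses(pg, 25, seed = 5)
  for (r in seq_len(nrow(a))) {
    stg <- build_stg(pg, a[r, ])
    expect_identical(length(stg$from) - length(stg$self), as.integer(n_faces))
    # self-edge iff every face edge is incoming
    face_from <- stg$from[stg$from != stg$to]
    expect_identical(sort(stg$self),
                     sort(setdiff(which(tabulate(face_from,
                                                 stg$n_cells) == 0L),
                                  integer(0))))
    mg <- morse_graph(stg)
    expect_gte(sum(mg$nodes$stable), 1L)
    # acyclic: edges only between distinct nodes, no mutual pairs
    if (nrow(mg$edges)) {
      expect_true(all(mg$edges$from != mg$edges$to))
      keys <- paste(mg$edges$from, mg$edges$to)
      rev_keys <- paste(mg$edges$to, mg$edges$from)
      expect_false(any(keys %in% rev_keys))
    }
  }
})

test_that("oscillatory components occur but are never stable", {
  pg <- emt_pg("essential")
  a <- sample_addresses(pg, 60, seed = 17)
  saw_cycle <- FALSE
  for (r in seq_len(nrow(a))) {
    mg <- morse_graph(build_stg(pg, a[r, ]))
    cyc <- mg$nodes[mg$nodes$type != "FP", ]
    if (nrow(cyc)) {
      saw_cycle <- TRUE
      # partial (XC) and full (FC) cycles alike are only ever unstable
      expect_true(all(!cyc$stable))
      expect_true(all(cyc$type %in% c("XC", "FC")))
    }
  }
  expect_true(saw_cycle)  # oscillations do occur, but never as attractors
})

test_that("tidiers summarise Morse graphs", {
  mg <- morse_graph(build_stg(toggle_pg(), c(X = 2L, Y = 2L)))
  td <- tidy(mg)
  expect_identical(nrow(td), 2L)
  gl <- glance(mg)
  expect_identical(gl$n_stable, 2L)
  expect_true(gl$all_stable_fp)
})
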
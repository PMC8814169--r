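# Great-circle distances, Gabriel graph, inverse-distance weights, dbMEM
# spectra, Moran's I ordering, and forward selection.

test_that("haversine distances: known value, metric properties, validation", {
  expect_equal(greatcircle_km(cbind(lat = c(0, 0), lon = c(0, 0)))[1, 2], 0)
  d1 <- greatcircle_km(cbind(lat = c(0, 0), lon = c(0, 1)))[1, 2]
  expect_equal(d1, 6371.0088 * pi / 180, tolerance = 1e-4)
  set.seed(501)
  for (rep in 1:10) {
    co <- cbind(lat = runif(3, -60, 60), lon = runif(3, -170, 170))
    D <- greatcircle_km(co)
    expect_lte(D[1, 3], D[1, 2] + D[2, 3] + 1e-9)
  }
  expect_error(greatcircle_km(cbind(lat = c(91, 0), lon = c(0, 0))),
               "latitude")
  expect_error(greatcircle_km(cbind(lat = c(0, 0), lon = c(190, 0))),
               "longitude")
})

test_that("Gabriel graph matches hand-checked small cases", {
  # 3 collinear equally spaced points: long edge excluded
  co <- data.frame(lat = c(0, 0, 0), lon = c(0, 0.5, 1),
                   row.names = c("a", "b", "c"))
  g <- gabriel_graph(co)
  key <- paste(g$edges$from, g$edges$to)
  expect_setequal(key, c("a b", "b c"))
  # acute triangle: all three edges present
  co2 <- data.frame(lat = c(0, 0, 0.45), lon = c(0, 0.5, 0.25),
                    row.names = c("a", "b", "c"))
  expect_equal(nrow(gabriel_graph(co2)$edges), 3)
  # right angle at c (boundary): edge ab kept (ties keep the edge)
  expect_error(gabriel_graph(co[1:2, ]), "3 demes")
  expect_error(gabriel_graph(rbind(co, data.frame(lat = 0, lon = 0,
                                                  row.names = "d"))),
               "coincident")
})

test_that("weights are inverse kilometres on edges, zero elsewhere", {
  co <- data.frame(lat = c(0, 0.018, 0.036), lon = c(0, 0, 0),
                   row.names = c("a", "b", "c"))
  g <- gabriel_graph(co)
  W <- build_weights(g)
  d_ab <- g$dist_km["a", "b"]
  expect_equal(W["a", "b"], 1 / d_ab)
  expect_equal(W["a", "c"], 0)  # long collinear edge is not Gabriel
  expect_equal(diag(W), rep(0, 3), ignore_attr = TRUE)
  # doubling the separations halves the weights (1/d homogeneity)
  co2 <- co * 2
  W2 <- build_weights(gabriel_graph(co2))
  expect_equal(W2["a", "b"], W["a", "b"] / 2, tolerance = 1e-6)
  # a hand-made disconnected graph is rejected with its components listed
  g_bad <- g
  g_bad$edges <- g$edges[g$edges$from == "a" & g$edges$to == "b", ,
                         drop = FALSE]
  expect_error(build_weights(g_bad), "disconnected")
})

test_that("dbMEMs are centered-orthonormal, reconstruct HWH, order by Moran's I", {
  set.seed(502)
  for (nd in c(10, 25)) {
    co <- data.frame(lat = runif(nd, 31, 33), lon = runif(nd, 34, 36),
                     row.names = sprintf("d%02d", 1:nd))
    W <- build_weights(gabriel_graph(co))
    mems <- compute_dbmem(W)
    V <- mems$vectors
    expect_lt(max(abs(colMeans(V))), 1e-10)
    expect_lt(max(abs(crossprod(V) - diag(ncol(V)))), 1e-10)
    # reconstruction of the doubly centered matrix
    H <- diag(nd) - 1 / nd
    expect_lt(max(abs(V %*% diag(mems$values) %*% t(V) - H %*% W %*% H)),
              1e-8)
    # Moran's I is a monotone transform of the eigenvalue
    mi <- vapply(seq_len(ncol(V)), function(j) moran_i(V[, j], W),
                 numeric(1))
    expect_equal(order(mi), order(mems$values))
    expect_equal(mems$sign_class, ifelse(mems$values > 0,
                                         "positive", "negative"))
  }
  # 4-node path graph with unit weights vs dense eigendecomposition oracle
  Wp <- matrix(0, 4, 4)
  Wp[cbind(1:3, 2:4)] <- 1; Wp <- Wp + t(Wp)
  Hp <- diag(4) - 1 / 4
  oracle <- eigen(Hp %*% Wp %*% Hp, symmetric = TRUE)$values
  got <- compute_dbmem(Wp)
  expect_equal(sort(got$values),
               sort(oracle[abs(oracle) > 1e-8 * max(abs(oracle))]),
               tolerance = 1e-10)
  expect_error(compute_dbmem(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("MEMs expanded to individuals are constant within demes", {
  co <- data.frame(lat = runif(12, 31, 33), lon = runif(12, 34, 36),
                   row.names = sprintf("d%02d", 1:12))
  W <- build_weights(gabriel_graph(co))
  member <- sample(rownames(co), 50, replace = TRUE)
  mems <- compute_dbmem(W, membership = member)
  for (d in unique(member)) {
    rows <- mems$vectors_ind[member == d, , drop = FALSE]
    expect_equal(rows, rows[rep(1, nrow(rows)), , drop = FALSE],
                 ignore_attr = TRUE)
  }
})

test_that("forward selection finds a planted MEM and respects double stopping", {
  set.seed(503)
  co <- data.frame(lat = runif(20, 31, 33), lon = runif(20, 34, 36),
                   row.names = sprintf("d%02d", 1:20))
  W <- build_weights(gabriel_graph(co))
  mems <- compute_dbmem(W)
  # Y driven by MEM3: selected first
  Y <- 2 * mems$vectors[, 3] %o% rep(1, 4) +
    matrix(rnorm(20 * 4, sd = 0.3), 20, 4)
  sel <- forward_select(Y, mems, alpha = 0.05, n_perm = 199, seed = 1)
  expect_equal(sel$trace$candidate[1], "MEM3")
  expect_true("MEM3" %in% sel$selected)
  # stopping rule: cumulative adjusted R2 never exceeds the class global
  for (cls in names(sel$global)) {
    cls_steps <- sel$trace[sel$trace$class == cls & sel$trace$accepted, ]
    if (nrow(cls_steps))
      expect_lte(max(cls_steps$r2adj), sel$global[[cls]]$r2adj + 1e-10)
  }
  # deterministic given the seed
  sel2 <- forward_select(Y, mems, alpha = 0.05, n_perm = 199, seed = 1)
  expect_identical(sel$selected, sel2$selected)
  expect_identical(sel$trace, sel2$trace)
  # pure-noise response: selection is empty in most seeds (type-I control)
  empty <- 0
  for (s in 1:10) {
    set.seed(600 + s)
    Yn <- matrix(rnorm(20 * 3), 20, 3)
    sn <- forward_select(Yn, mems, alpha = 0.05, n_perm = 99, seed = s)
    if (length(sn$selected) == 0) empty <- empty + 1
  }
  expect_gte(empty, 8)
  expect_warning(forward_select(Y, mems, n_perm = 49, seed = 1), "99")
  expect_error(forward_select(matrix(0, 20, 2), mems), "zero variance")
})
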
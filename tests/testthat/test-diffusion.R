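path_abc <- data.frame(from = c("A", "B"), to = c("B", "C"))

test_that("column_normalize divides by degree and is column-stochastic", {
  wm <- column_normalize(path_abc)
  W <- as.matrix(wm$W)
  expect_identical(wm$nodes, c("A", "B", "C"))
  expect_equal(unname(W[, 1]), c(0, 1, 0))
  expect_equal(unname(W[, 2]), c(0.5, 0, 0.5))
  expect_equal(unname(W[, 3]), c(0, 1, 0))

  single <- column_normalize(data.frame(from = "A", to = "B"))
  expect_equal(unname(as.matrix(single$W)), rbind(c(0, 1), c(1, 0)))

  expect_error(column_normalize(path_abc, node_order = c("A", "B", "C", "Z")),
               "degree 0.*Z")
})

test_that("dense and sparse representations agree to 1e-12", {
  withr::local_seed(7)
  edges <- random_connected_edges(40)
  dense <- column_normalize(edges, sparse = FALSE)
  sparse <- column_normalize(edges, sparse = TRUE)
  expect_lt(max(abs(as.matrix(sparse$W) - dense$W)), 1e-12)
  expect_true(all(abs(Matrix::colSums(sparse$W) - 1) < 1e-12))
  p0 <- uniform_restart("N01", dense$nodes)
  expect_lt(sum(abs(diffuse(dense, p0)$p - diffuse(sparse, p0)$p)), 1e-12)
})

test_that("uniform_restart spreads mass equally over the seeds", {
  nodes <- paste0("n", 1:5)
  expect_equal(unname(uniform_restart(c("n1", "n2"), nodes)),
               c(0.5, 0.5, 0, 0, 0))
  expect_equal(unname(uniform_restart("n2", paste0("n", 1:3))), c(0, 1, 0))
  expect_equal(unname(uniform_restart(nodes, nodes)), rep(0.2, 5))
  expect_error(uniform_restart(character(0), nodes), "empty")
  expect_error(uniform_restart("nope", nodes), "not present")
})

test_that("steady state matches hand-computed fixed points", {
  # single edge A-B, seed A: p = (2/3, 1/3)
  ab <- column_normalize(data.frame(from = "A", to = "B"))
  p0 <- uniform_restart("A", ab$nodes)
  tight <- diffusion_params(tol = 1e-12)
  expect_equal(unname(diffuse(ab, p0, tight)$p), c(2, 1) / 3,
               tolerance = 1e-10)
  expect_equal(unname(diffuse_closed_form(ab, p0)$p), c(2, 1) / 3,
               tolerance = 1e-12)

  # path A-B-C, seed A: p = (7/12, 1/3, 1/12)
  abc <- column_normalize(path_abc)
  p0 <- uniform_restart("A", abc$nodes)
  expect_equal(unname(diffuse(abc, p0, tight)$p), c(7, 4, 1) / 12,
               tolerance = 1e-10)

  # restart-only limit: r = 1 reproduces p0 after one step
  res <- diffuse(abc, p0, diffusion_params(r = 1))
  expect_equal(unname(res$p), unname(p0))
  expect_equal(res$iterations, 1L)
  expect_equal(unname(diffuse_closed_form(abc, p0, r = 1)$p), unname(p0))
})

test_that("star-graph steady state is symmetric over the leaves", {
  star <- column_normalize(data.frame(from = "HUB", to = c("X1", "X2", "X3")))
  p0 <- uniform_restart("HUB", star$nodes)
  p <- diffuse_closed_form(star, p0)$p
  leaves <- p[c("X1", "X2", "X3")]
  expect_lt(diff(range(leaves)), 1e-14)
  # by hand: hub = 0.5*3*leaf + 0.5 and leaf = 0.5*hub/3
  expect_equal(unname(p["HUB"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(leaves[1]), 1 / 9, tolerance = 1e-12)
})

test_that("probability mass is conserved and iteration is a contraction", {
  withr::local_seed(11)
  edges <- random_connected_edges(30)
  wm <- column_normalize(edges)
  seeds <- sample(wm$nodes, 3)
  p0 <- uniform_restart(seeds, wm$nodes)
  params <- diffusion_params()
  res <- diffuse(wm, p0, params, trace = TRUE)
  expect_true(all(abs(rowSums(res$trajectory) - 1) < 1e-12))
  expect_true(all(res$trajectory >= 0))
  # distance to the fixed point contracts by at least (1 - r)
  pinf <- diffuse_closed_form(wm, p0, params$r)$p
  dist <- apply(res$trajectory, 1, function(p) sum(abs(p - pinf)))
  nz <- dist[-length(dist)] > 1e-13
  expect_true(all(dist[-1][nz] <= (1 - params$r) * dist[-length(dist)][nz] +
                    1e-13))
  # iteration count within the closed-form geometric bound
  bound <- ceiling(log(params$tol / 2) / log(1 - params$r))
  expect_lte(res$iterations, bound)
  expect_lt(res$final_residual, params$tol)
})

test_that("non-convergence within max_iter raises a convergence error", {
  wm <- column_normalize(path_abc)
  p0 <- uniform_restart("A", wm$nodes)
  expect_error(diffuse(wm, p0, diffusion_params(tol = 1e-14, max_iter = 3)),
               "did not converge")
})

test_that("power iteration matches the linear solve on random graphs", {
  withr::local_seed(2024)
  for (rep in 1:25) {
    n <- sample(3:50, 1)
    edges <- random_connected_edges(n)
    wm <- column_normalize(edges)
    seeds <- sample(wm$nodes, sample(seq_len(min(5, n)), 1))
    p0 <- uniform_restart(seeds, wm$nodes)
    r <- sample(c(0.3, 0.5, 0.8), 1)
    it <- diffuse(wm, p0, diffusion_params(r = r, tol = 1e-12))
    cf <- diffuse_closed_form(wm, p0, r)
    expect_lt(sum(abs(it$p - cf$p)), 1e-8 * n)
  }
})

test_that("unreachable nodes score zero and seeds retain restart mass", {
  # two components; seeds only in the first
  edges <- data.frame(from = c("A", "B", "A", "X"),
                      to = c("B", "C", "C", "Y"))
  wm <- column_normalize(edges)
  p0 <- uniform_restart("A", wm$nodes)
  p <- diffuse(wm, p0, diffusion_params(tol = 1e-12))$p
  expect_equal(unname(p[c("X", "Y")]), c(0, 0))
  expect_gte(p[["A"]], 0.5 * p0[["A"]])
})

test_that("permuting node_order permutes the steady state identically", {
  withr::local_seed(5)
  edges <- random_connected_edges(20)
  wm1 <- column_normalize(edges)
  perm <- sample(wm1$nodes)
  wm2 <- column_normalize(edges, node_order = perm)
  seeds <- sample(wm1$nodes, 2)
  p1 <- diffuse(wm1, uniform_restart(seeds, wm1$nodes),
                diffusion_params(tol = 1e-12))$p
  p2 <- diffuse(wm2, uniform_restart(seeds, wm2$nodes),
                diffusion_params(tol = 1e-12))$p
  expect_equal(p1[wm1$nodes], p2[wm1$nodes], tolerance = 1e-12)
})

test_that("rank_lncrnas keeps only lncRNAs, sorted with deterministic ties", {
  net <- toy_network()
  sub <- extract_subnetwork(net, "DA")
  wm <- column_normalize(sub)
  p0 <- uniform_restart(lncrwr:::node_key("PROTEIN", sub$seeds),
                        sub$node_order$key)
  ranked <- rank_lncrnas(diffuse(wm, p0), sub)
  expect_equal(ranked$lncrna_id, "L1")
  expect_equal(ranked$rank, 1L)
  expect_false(any(sub$proteins %in% ranked$lncrna_id))

  # synthetic tie: equal scores break by identifier ascending
  sub2 <- sub
  sub2$node_order <- data.frame(
    kind = c("LNCRNA", "LNCRNA", "PROTEIN"),
    identifier = c("LB", "LA", "G1"),
    key = c("LNCRNA:LB", "LNCRNA:LA", "PROTEIN:G1"),
    stringsAsFactors = FALSE
  )
  fake2 <- structure(list(p = setNames(c(0.1, 0.1, 0.8),
                                       sub2$node_order$key)),
                     class = "score_vector")
  ranked2 <- rank_lncrnas(fake2, sub2)
  expect_equal(ranked2$lncrna_id, c("LA", "LB"))
  expect_equal(ranked2$rank, c(1L, 2L))
})

test_that("rank_disease refuses ineligible subnetworks unless forced", {
  net <- toy_network()
  expect_error(suppressWarnings(rank_disease(net, "DB")), "not eligible")
  expect_warning(ranked <- rank_disease(net, "DB", force = TRUE), "FORCED")
  expect_true(nrow(ranked) >= 1)
  ok <- rank_disease(net, "DA")
  expect_equal(ok$disease_id[1], "DA")
})
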
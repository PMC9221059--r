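test_that("degree histograms match known graphs and the handshake identity", {
  tri <- make_net(clique_edges(c("A", "B", "C")))
  expect_equal(degree_distribution(tri),
               data.frame(degree = 2L, count = 3L))
  star <- make_net(data.frame(a = rep("HUB", 4),
                              b = c("L1", "L2", "L3", "L4")))
  expect_equal(degree_distribution(star),
               data.frame(degree = c(1L, 4L), count = c(4L, 1L)))
  # sum k * count_k = 2 |E| on random graphs
  set.seed(100)
  nodes <- sprintf("N%02d", 1:30)
  cmb <- utils::combn(nodes, 2)
  pick <- runif(ncol(cmb)) < 0.15
  rg <- make_net(data.frame(a = cmb[1, pick], b = cmb[2, pick]),
                 nodes = nodes)
  h <- degree_distribution(rg)
  expect_equal(sum(h$degree * h$count), 2 * nrow(rg$edges))
  expect_equal(sum(h$count), length(rg$nodes))
})

test_that("log-log fit recovers a constructed power law", {
  k <- 1:50
  hist <- data.frame(degree = k, count = round(1000 * k^(-1.5)))
  fit <- fit_power_law(hist)
  expect_equal(fit$alpha, -1.5, tolerance = 0.02)
  expect_gt(fit$corr_abs, 0.99)
  expect_lt(fit$corr, 0)  # signed correlation is negative for a decay
  # flat histogram has slope zero (and no defined correlation)
  flat <- fit_power_law(data.frame(degree = 1:10, count = rep(7, 10)))
  expect_equal(flat$alpha, 0, tolerance = 1e-12)
  expect_true(is.na(flat$corr))
  # too few points: no fit, with a warning
  expect_warning(
    none <- fit_power_law(data.frame(degree = 1:2, count = c(5, 3))),
    "3")
  expect_null(none)
})

test_that("expression assortativity counts matched-sign edges", {
  # uniform signs: every eligible subcommunity at 1
  nodes <- sprintf("N%02d", 1:13)
  path_edges <- data.frame(a = nodes[-13], b = nodes[-1])  # 12-edge path
  net <- make_net(path_edges, nodes = nodes)
  part <- data.frame(protein = nodes, community = 1, subcommunity = "SC1_1")
  all_plus <- setNames(rep(1, 13), nodes)
  r1 <- expression_assortativity(net, part, all_plus)
  expect_equal(r1$expass, 1)
  expect_equal(r1$n_edges, 12)
  # alternating signs along the path: perfect disassortativity
  alt <- setNames(rep(c(1, -1), length.out = 13), nodes)
  expect_equal(expression_assortativity(net, part, alt)$expass, 0)
  # invariant under a global sign flip
  expect_equal(expression_assortativity(net, part, -alt)$expass, 0)
  # random signs on a larger subcommunity hover near 1/2
  set.seed(101)
  big_nodes <- sprintf("B%03d", 1:60)
  cmb <- utils::combn(big_nodes, 2)
  pick <- sample(ncol(cmb), 100)
  bignet <- make_net(data.frame(a = cmb[1, pick], b = cmb[2, pick]),
                     nodes = big_nodes)
  bigpart <- data.frame(protein = big_nodes, community = 1,
                        subcommunity = "SC1_1")
  rnd <- setNames(sample(c(-1, 1), 60, TRUE), big_nodes)
  expect_equal(expression_assortativity(bignet, bigpart, rnd)$expass, 0.5,
               tolerance = 0.3)  # 0.5 +/- 0.15
  # the eligibility floor is strict: 10 edges are not enough
  small <- make_net(data.frame(a = nodes[1:10], b = nodes[2:11]),
                    nodes = nodes[1:11])
  smallpart <- data.frame(protein = nodes[1:11], community = 1,
                          subcommunity = "SC1_1")
  expect_equal(nrow(expression_assortativity(small, smallpart,
                                             all_plus[1:11])), 0)
  # a node without a sign is an error naming it
  expect_error(expression_assortativity(net, part, all_plus[-3]), "N03")
})

test_that("cis/trans classification partitions the edge set", {
  net <- make_net(data.frame(a = c("A", "A", "C"), b = c("B", "C", "D")))
  cm <- c(A = "17", B = "17", C = "X")  # D unmapped
  ct <- classify_cis_trans(net, cm)
  expect_equal(ct$n_cis, 1)      # A-B on 17
  expect_equal(ct$n_trans, 1)    # A-C on 17 vs X
  expect_equal(ct$n_unmapped, 1) # C-D
  expect_equal(ct$n_cis + ct$n_trans + ct$n_unmapped, nrow(net$edges))
  expect_equal(ct$per_chromosome,
               data.frame(chromosome = "17", n_cis = 1L))
  # random uniform chromosomes: cis fraction near 1 / n_chromosomes
  fx <- planted_fixture()
  cmap <- setNames(fx$ds$truth$chromosome, fx$ds$truth$protein)
  ct2 <- classify_cis_trans(fx$net, cmap)
  n_mapped <- ct2$n_cis + ct2$n_trans
  se <- sqrt((1 / 23) * (22 / 23) / n_mapped)
  expect_lt(abs(ct2$cis_fraction - 1 / 23), 3 * se)
})

test_that("component sizes match a union-find oracle", {
  two_tri <- make_net(rbind(clique_edges(c("A", "B", "C")),
                            clique_edges(c("D", "E", "F"))))
  expect_equal(component_sizes(two_tri), c(3L, 3L))
  conn <- make_net(clique_edges(sprintf("N%d", 1:7)))
  expect_equal(component_sizes(conn), 7L)
  set.seed(102)
  nodes <- sprintf("N%02d", 1:40)
  cmb <- utils::combn(nodes, 2)
  pick <- runif(ncol(cmb)) < 0.03
  rg <- make_net(data.frame(a = cmb[1, pick], b = cmb[2, pick]),
                 nodes = nodes)
  expect_equal(component_sizes(rg), components_oracle(rg$edges, rg$nodes))
  expect_equal(sum(component_sizes(rg)), length(rg$nodes))
})
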
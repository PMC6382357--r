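fc_table <- function(ids, log2fc) {
  data.frame(feature_id = ids, mean_a = 1, mean_b = 2^log2fc,
             fc = 2^log2fc, log2fc = log2fc, status = "ok",
             stringsAsFactors = FALSE)
}

test_that("edges require target evidence and opposite deregulation", {
  m_fc <- fc_table(c("m1", "m2", "m3"), c(1.5, 1.2, 1.0))
  p_fc <- fc_table(c("p1", "p2"), c(-1.0, 0.8))
  edges <- target_edges(data.frame(
    mirna_id = c("m1", "m2"), protein_id = c("p1", "p2"),
    evidence = c("strong", "strong")))

  net <- build_network(m_fc, p_fc, edges)
  # m1 up / p1 down with an edge: retained
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$mirna_id, "m1")
  # m2 up / p2 up: anti-correlation criterion fails
  expect_false("m2" %in% net$edges$mirna_id)
  # m3 up / p1 down but no target edge: excluded; nodes without edges drop
  expect_setequal(net$mirna_nodes$feature_id, "m1")
  expect_setequal(net$protein_nodes$feature_id, "p1")
})

test_that("evidence filtering and magnitude threshold behave as documented", {
  m_fc <- fc_table(c("m1", "m2"), c(1.5, 0.4))
  p_fc <- fc_table(c("p1", "p2"), c(-1.0, -2.0))
  edges <- target_edges(data.frame(
    mirna_id = c("m1", "m2"), protein_id = c("p1", "p2"),
    evidence = c("weak", "strong")))

  both <- build_network(m_fc, p_fc, edges)
  expect_equal(nrow(both$edges), 1L)  # m2 is flat at threshold 0.5
  strong <- build_network(m_fc, p_fc, edges, evidence = "strong_only")
  expect_equal(nrow(strong$edges), 0L)

  # lowering the threshold admits m2; raising it never adds edges
  loose <- build_network(m_fc, p_fc, edges, magnitude_threshold = 0.3)
  expect_equal(nrow(loose$edges), 2L)
  for (thr in c(0.5, 1.0, 2.0)) {
    n_thr <- nrow(build_network(m_fc, p_fc, edges,
                                magnitude_threshold = thr)$edges)
    expect_lte(n_thr, nrow(loose$edges))
  }

  # an edge naming an unknown feature is skipped with a message, not an error
  edges2 <- target_edges(data.frame(mirna_id = "ghost", protein_id = "p1",
                                    evidence = "weak"))
  expect_message(net2 <- build_network(m_fc, p_fc, edges2), "skipped")
  expect_equal(nrow(net2$edges), 0L)
})

test_that("every retained edge re-verifies against the criteria", {
  d <- generate_dataset(synthetic_config(seed = 4))
  s <- d$mirna_matrix$samples
  g <- function(cond, ent) s$sample_id[s$condition == cond & s$entity == ent]
  m_fc <- combine_entity_calls(
    fold_change(d$mirna_matrix, g("2D", "cell"), g("3D", "cell")),
    fold_change(d$mirna_matrix, g("2D", "EV"), g("3D", "EV")))
  p_fc <- fold_change(d$protein_matrix, g("2D", "EV"), g("3D", "EV"))
  net <- suppressMessages(build_network(m_fc, p_fc, d$edges))
  thr <- net$provenance$magnitude_threshold
  m_lfc <- setNames(m_fc$log2fc, m_fc$feature_id)
  p_lfc <- setNames(p_fc$log2fc, p_fc$feature_id)
  edge_key <- paste(d$edges$mirna_id, d$edges$protein_id)
  for (i in seq_len(nrow(net$edges))) {
    m <- net$edges$mirna_id[i]; p <- net$edges$protein_id[i]
    expect_true(paste(m, p) %in% edge_key)
    expect_true((m_lfc[m] >= thr & p_lfc[p] <= -thr) |
                  (m_lfc[m] <= -thr & p_lfc[p] >= thr))
  }
})

test_that("pearson mode keeps only strongly anti-correlated pairs", {
  samples <- toy_samples(n_rep = 4)
  ev <- samples[samples$entity == "EV", ]
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  m_vals <- rbind(m1 = x, m2 = x)
  p_vals <- rbind(p1 = 9 - x, p2 = x + 0.5)
  m_em <- expression_matrix(m_vals, ev)
  p_em <- expression_matrix(p_vals, ev)
  m_fc <- fc_table(c("m1", "m2"), c(1.5, 1.5))
  p_fc <- fc_table(c("p1", "p2"), c(-1, -1))
  edges <- target_edges(data.frame(mirna_id = c("m1", "m2"),
                                   protein_id = c("p1", "p2"),
                                   evidence = "strong"))
  net <- build_network(m_fc, p_fc, edges, mode = "pearson",
                       r_max = -0.5, mirna_matrix = m_em,
                       protein_matrix = p_em)
  expect_equal(net$edges$mirna_id, "m1")   # r(m1,p1) = -1; r(m2,p2) = +1
})

test_that("clusters are connected components with shared-target structure", {
  m_fc <- fc_table(c("m1", "m2", "m3"), c(1, 1, 1))
  p_fc <- fc_table(c("p1", "p2"), c(-1, -1))
  mk_net <- function(df) build_network(m_fc, p_fc, target_edges(df))

  shared <- mk_net(data.frame(mirna_id = c("m1", "m2"),
                              protein_id = c("p1", "p1"),
                              evidence = "strong"))
  cl <- extract_clusters(shared)
  expect_equal(length(cl), 1L)
  expect_setequal(cl[[1]]$mirnas, c("m1", "m2"))
  expect_identical(cl[[1]]$proteins, "p1")
  expect_identical(cl[[1]]$shared_targets, "p1")

  split2 <- mk_net(data.frame(mirna_id = c("m1", "m2"),
                              protein_id = c("p1", "p2"),
                              evidence = "strong"))
  cl2 <- extract_clusters(split2)
  expect_equal(length(cl2), 2L)
  # union of component node sets equals the network node set
  nodes <- unlist(lapply(cl2, function(x) c(x$mirnas, x$proteins)))
  expect_setequal(nodes, c(split2$mirna_nodes$feature_id,
                           split2$protein_nodes$feature_id))

  # same-sign pair leaves an empty network, hence an empty cluster list
  empty2 <- build_network(fc_table("m1", 1), fc_table("p2", 1),
                          target_edges(data.frame(mirna_id = "m1",
                                                  protein_id = "p2",
                                                  evidence = "strong")))
  expect_identical(extract_clusters(empty2), list())
})

test_that("planted coregulation is recovered with high precision and recall", {
  prec <- rec <- numeric(10)
  for (seed in 1:10) {
    d <- generate_dataset(synthetic_config(seed = seed))
    s <- d$mirna_matrix$samples
    g <- function(cond, ent)
      s$sample_id[s$condition == cond & s$entity == ent]
    m_fc <- combine_entity_calls(
      fold_change(d$mirna_matrix, g("2D", "cell"), g("3D", "cell")),
      fold_change(d$mirna_matrix, g("2D", "EV"), g("3D", "EV")))
    p_fc <- fold_change(d$protein_matrix, g("2D", "EV"), g("3D", "EV"))
    net <- suppressMessages(build_network(m_fc, p_fc, d$edges))
    tk <- paste(d$truth$planted_edges$mirna_id,
                d$truth$planted_edges$protein_id)
    fk <- paste(net$edges$mirna_id, net$edges$protein_id)
    tp <- sum(fk %in% tk)
    prec[seed] <- tp / length(fk)
    rec[seed] <- tp / length(tk)
  }
  expect_gte(mean(prec), 0.9)
  expect_gte(mean(rec), 0.9)
})
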
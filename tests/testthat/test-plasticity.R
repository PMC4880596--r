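make_connected_micro <- function(n_edges_apply = NULL) {
  # A(2 neurons) and B(2 neurons); neuron 1 of A gets axon elements bound
  # into synapses onto B's dendritic elements
  net <- make_micro_net(n_a = 2, n_b = 3)
  net
}

test_that("an empty report leaves the store untouched", {
  net <- make_micro_net()
  net <- set_z(net, 1, "Axon_ex", 2); net <- set_z(net, 3, "Den_ex", 2)
  net <- form_synapses(net, build_reports(net))
  before <- store_edges(net$store)
  rep0 <- build_reports(net, n_deleted = integer(length(net$elem$neuron)))
  net2 <- commit_deletions(net, rep0[rep0$n_to_delete > 0, ])
  expect_identical(store_edges(net2$store), before)
})

test_that("exhaustive deletion removes all synapses and frees the partners", {
  set.seed(2)
  net <- make_micro_net(n_a = 1, n_b = 3)
  net <- set_z(net, 1, "Axon_ex", 3)
  for (b in 2:4) net <- set_z(net, b, "Den_ex", 1)
  net <- form_synapses(net, build_reports(net))
  expect_equal(store_count(net$store), 3L)
  expect_equal(get_elem(net, 1, "Axon_ex")$connected, 3L)

  # delete all three axonal elements of neuron 1
  nd <- integer(length(net$elem$neuron))
  nd[net$elem_idx[match("Axon_ex", net$types), 1]] <- 3L
  net$elem$z[net$elem_idx[match("Axon_ex", net$types), 1]] <- 0
  net <- commit_deletions(net, build_reports(net, n_deleted = nd))
  expect_equal(store_count(net$store), 0L)
  expect_equal(get_elem(net, 1, "Axon_ex")$connected, 0L)
  # partners keep their element variable: connected -> vacant
  for (b in 2:4) {
    e <- get_elem(net, b, "Den_ex")
    expect_equal(e$connected, 0L)
    expect_equal(e$z, 1)
  }
  # a report that exceeds the connected count is a bookkeeping error
  expect_error(commit_deletions(net, build_reports(net, n_deleted = nd)),
               "exceeds connected")
})

test_that("deletion sampling is uniform over a neuron's synapses", {
  # neuron 1 holds 5 synapses; deleting 1 must hit each with frequency 1/5
  base <- make_micro_net(n_a = 1, n_b = 5)
  base <- set_z(base, 1, "Axon_ex", 5)
  for (b in 2:6) base <- set_z(base, b, "Den_ex", 1)
  set.seed(10)
  base <- form_synapses(base, build_reports(base))
  expect_equal(store_count(base$store), 5L)
  nd <- integer(length(base$elem$neuron))
  nd[base$elem_idx[match("Axon_ex", base$types), 1]] <- 1L
  base$elem$z[base$elem_idx[match("Axon_ex", base$types), 1]] <- 4

  set.seed(77)
  n_rep <- 4000
  hits <- integer(5)
  for (k in seq_len(n_rep)) {
    net <- base
    net$store <- store_clone(base$store)
    net <- commit_deletions(net, build_reports(net, n_deleted = nd))
    gone <- setdiff(2:6, store_edges(net$store)$post)
    hits[gone - 1L] <- hits[gone - 1L] + 1L
  }
  p <- chisq.test(hits, p = rep(1 / 5, 5))$p.value
  expect_gt(p, 0.01)
})

test_that("forced matching connects the only compatible elements", {
  # 2 vacant axons on A1, 2 vacant dendrites on B (neuron 3): exactly 2
  # parallel A1 -> 3 synapses, under every shuffle
  for (k in 1:20) {
    net <- make_micro_net(n_a = 1, n_b = 2)
    net <- set_z(net, 1, "Axon_ex", 2)
    net <- set_z(net, 2, "Den_ex", 2)
    net <- form_synapses(net, build_reports(net))
    e <- store_edges(net$store)
    expect_equal(nrow(e), 2)
    expect_equal(e$pre, c(1, 1))
    expect_equal(e$post, c(2, 2))
  }
  # no vacant pre elements -> no synapses
  net <- make_micro_net()
  net <- set_z(net, 3, "Den_ex", 4)
  net <- form_synapses(net, build_reports(net))
  expect_equal(store_count(net$store), 0L)
})

test_that("pairing follows the uniform matching distribution (3x3 oracle)", {
  # three pre holders and three post holders with one vacant element each:
  # the pairing is a uniform random bijection; all 6 matchings equally
  # likely. Chi-square against the enumerated uniform oracle.
  perms <- matrix(c(1,2,3, 1,3,2, 2,1,3, 2,3,1, 3,1,2, 3,2,1),
                  ncol = 3, byrow = TRUE)
  set.seed(123)
  n_rep <- 3000
  counts <- integer(6)
  for (k in seq_len(n_rep)) {
    net <- make_micro_net(n_a = 3, n_b = 3)
    for (a in 1:3) net <- set_z(net, a, "Axon_ex", 1)
    for (b in 4:6) net <- set_z(net, b, "Den_ex", 1)
    net <- form_synapses(net, build_reports(net))
    e <- store_edges(net$store)
    expect_equal(nrow(e), 3)
    match_vec <- e$post[order(e$pre)] - 3L
    hit <- which(apply(perms, 1, function(p) all(p == match_vec)))
    counts[hit] <- counts[hit] + 1L
  }
  p <- chisq.test(counts, p = rep(1 / 6, 6))$p.value
  expect_gt(p, 0.01)
})

test_that("autapse policy skips self-pairs but keeps the elements vacant", {
  # one neuron offering both the axon and the dendrite: nothing can form
  for (k in 1:10) {
    net <- make_micro_net(n_a = 1, n_b = 1)
    net <- set_z(net, 1, "Axon_ex", 1)
    net <- set_z(net, 1, "Den_ex", 1)
    net <- form_synapses(net, build_reports(net))
    expect_equal(store_count(net$store), 0L)
    expect_equal(get_elem(net, 1, "Axon_ex")$z, 1)   # still vacant
  }
  # with autapses allowed the pair forms
  net <- make_micro_net(n_a = 1, n_b = 1, allow_autapses = TRUE)
  net <- set_z(net, 1, "Axon_ex", 1)
  net <- set_z(net, 1, "Den_ex", 1)
  net <- form_synapses(net, build_reports(net))
  expect_equal(store_count(net$store), 1L)
})

test_that("reports keep vacancies and deletions separate (no netting)", {
  net <- make_micro_net()
  # neuron 1: gains 2 vacant axonal elements, must delete 1 dendritic one
  net <- set_z(net, 1, "Axon_ex", 2)
  row_d <- net$elem_idx[match("Den_ex", net$types), 1]
  net$elem$connected[row_d] <- 1L   # pretend one bound dendrite, z below
  nd <- integer(length(net$elem$neuron)); nd[row_d] <- 1L
  rep <- build_reports(net, n_deleted = nd)
  r1 <- rep[rep$neuron == 1 & rep$type_name == "Axon_ex", ]
  r2 <- rep[rep$neuron == 1 & rep$type_name == "Den_ex", ]
  expect_equal(r1$n_vacant, 2L)
  expect_equal(r1$n_to_delete, 0L)
  expect_equal(r2$n_vacant, 0L)
  expect_equal(r2$n_to_delete, 1L)
})

test_that("manual synapse deletion leaves two vacant counterpart elements", {
  set.seed(5)
  net <- make_micro_net(n_a = 1, n_b = 1)
  net <- set_z(net, 1, "Axon_ex", 1)
  net <- set_z(net, 2, "Den_ex", 1)
  net <- form_synapses(net, build_reports(net))
  expect_equal(store_count(net$store), 1L)
  net <- delete_synapses(net, 1L)
  expect_equal(store_count(net$store), 0L)
  # both counterparts survive as vacant elements
  rep <- build_reports(net)
  expect_equal(sum(rep$n_vacant), 2L)
  expect_equal(sum(rep$n_to_delete), 0L)
  check_conservation(net)
  # and they can re-match at the next update
  net <- form_synapses(net, build_reports(net))
  expect_equal(store_count(net$store), 1L)
})

test_that("element-synapse conservation holds through scripted churn", {
  set.seed(21)
  net <- make_micro_net(n_a = 4, n_b = 4)
  for (k in 1:30) {
    # random growth and shrinkage of z, then a full structural cycle
    net$elem$z <- pmax(net$elem$z + runif(length(net$elem$z), -0.8, 1.2), -1)
    f <- floor(pmax(net$elem$z, 0))
    nd <- pmax(0L, net$elem$connected - as.integer(f))
    rep <- build_reports(net, n_deleted = nd)
    net <- commit_deletions(net, rep)
    net <- form_synapses(net, rep)
    check_conservation(net)
  }
  expect_true(TRUE)
})
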
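test_that("neighbor Jaccard matches direct set arithmetic", {
  # N(i) = {a,b,c}, N(j) = {b,c,d}  ->  2/4
  net <- toy_net(edge_df("i", "a", "i", "b", "i", "c",
                         "j", "b", "j", "c", "j", "d"))
  expect_equal(neighbor_jaccard(net, "i", "j"), 0.5)
  # identical neighborhoods
  net2 <- toy_net(edge_df("i", "a", "i", "b", "j", "a", "j", "b"))
  expect_equal(neighbor_jaccard(net2, "i", "j"), 1.0)
  # disjoint neighborhoods
  net3 <- toy_net(edge_df("i", "a", "j", "b"))
  expect_equal(neighbor_jaccard(net3, "i", "j"), 0.0)
  expect_error(neighbor_jaccard(net3, "i", "zz"), "zz")
})

test_that("an edge (i,j) does not leak into its own neighborhood similarity", {
  # i-j edge present; without endpoint removal jaccard would see j in N(i)
  net <- toy_net(edge_df("i", "j", "i", "a", "j", "a"))
  expect_equal(neighbor_jaccard(net, "i", "j"), 1.0)  # N'(i)=N'(j)={a}
})

test_that("jaccard_max2_mean reproduces the hand-enumerated fixture", {
  net <- toy_net(edge_df("i", "v", "j", "u",
                         "u", "x", "u", "y", "v", "x",
                         "i", "x", "i", "y",
                         "j", "x"))
  # s_i over N(j)\{i}={u,x}: nj(i,u)={x,y}/{v,x,y,j}=1/2,
  #                          nj(i,x)={v}/{v,y,u,j}=1/4  -> mean .375
  # s_j over N(i)\{j}={v,x,y}: nj(j,v)=nj(j,x)=nj(j,y)=1/3 -> top-2 mean 1/3
  expect_equal(jaccard_max2_mean(net, "i", "j"),
               (0.375 + 1 / 3) / 2)
  expect_equal(jaccard_max2_mean(net, "i", "j"),
               oracle_jaccard_max2_mean(net, "i", "j"))
  # both isolated -> 0
  net0 <- build_network(edge_df("a", "b"), toy_attrs(c("a", "b", "i", "j")))
  expect_equal(jaccard_max2_mean(net0, "i", "j"), 0)
})

test_that("topology covariates match hand-computed small cases", {
  # triangle a-b-c plus pendant d on a
  net <- toy_net(edge_df("a", "b", "b", "c", "a", "c", "a", "d"))
  tc <- topology_covariates(net, "b", "c")
  expect_equal(unname(tc["degree_prod"]), 4)
  expect_equal(unname(tc["cccnw_max"]), 1.0)
  # P4 endpoints: leaves have betweenness 0
  p4 <- toy_net(edge_df("a", "b", "b", "c", "c", "d"))
  expect_equal(unname(topology_covariates(p4, "a", "d")["betw_prod"]), 0)
  expect_equal(unname(topology_covariates(p4, "a", "b")["degree_prod"]), 2)
})

test_that("atc_min_prod: zero annihilator and isolated fallback", {
  tax <- toy_taxonomy()
  # i shares a full code with j's neighbor u, and j with i's neighbor v
  net <- build_network(
    edge_df("j", "u", "i", "v"),
    toy_attrs(c("i", "j", "u", "v"),
              atc = c("A01AA01", "B01AA01", "A01AA01", "B01AA01")))
  expect_equal(atc_min_prod(net, tax, "i", "j"), 0)
  # isolated endpoints fall back to d_max each side
  net0 <- build_network(
    edge_df("a", "b"),
    toy_attrs(c("a", "b", "i", "j"),
              atc = c("A01AA01", "A01AA02", "B01AA01", "C01AA01")))
  expect_equal(atc_min_prod(net0, tax, "i", "j"), 10 * 10)
})

test_that("structural Jaccard covers the set-arithmetic cases", {
  expect_equal(structural_jaccard(c("f1", "f2", "f3"),
                                  c("f2", "f3", "f4", "f5")), 0.4)
  expect_equal(structural_jaccard(c("f1"), c("f1")), 1.0)
  expect_equal(structural_jaccard(character(), character()), 0.0)
})

test_that("str_max_prod attains 1 for structurally matched neighborhoods", {
  net <- build_network(
    edge_df("j", "u", "i", "v"),
    toy_attrs(c("i", "j", "u", "v"),
              subs = c("f1;f2", "f3", "f1;f2", "f3")))
  expect_equal(str_max_prod(net, "i", "j"), 1.0)
  # isolated drug -> 0
  net0 <- build_network(edge_df("a", "b"),
                        toy_attrs(c("a", "b", "i", "j"),
                                  subs = c("f1", "f1", "f1", "f1")))
  expect_equal(str_max_prod(net0, "i", "j"), 0.0)
})

test_that("every covariate equals brute force exactly on random small graphs", {
  set.seed(99)
  tax <- toy_taxonomy()
  for (rep in 1:25) {
    net <- random_small_net(n = sample(5:12, 1), p = stats::runif(1, .2, .7),
                            tax = tax)
    tab <- build_covariate_table(net, tax, pairs = "all")
    btw <- oracle_betweenness(net)
    rows <- sample(nrow(tab), min(6, nrow(tab)))
    for (r in rows) {
      i <- tab$drug_a[r]; j <- tab$drug_b[r]
      expect_equal(tab$jackard[r], oracle_neighbor_jaccard(net, i, j))
      expect_equal(tab$jackard_max2_mean[r],
                   oracle_jaccard_max2_mean(net, i, j))
      expect_equal(tab$degree_prod[r],
                   length(oracle_neighbors(net, i)) *
                     length(oracle_neighbors(net, j)))
      expect_equal(tab$betw_prod[r], btw[[i]] * btw[[j]], tolerance = 1e-12)
      expect_equal(tab$cccnw_max[r],
                   max(oracle_local_clustering(net, i),
                       oracle_local_clustering(net, j)))
      codes <- stats::setNames(net$drugs$atc_codes, net$drugs$drug_id)
      expect_equal(tab$atc_min[r], oracle_atc_min(codes[[i]], codes[[j]]))
      expect_equal(tab$atc_min_prod[r],
                   oracle_atc_min_prod(net, i, j, atc_max_distance(tax)))
      subs <- stats::setNames(net$drugs$substructures, net$drugs$drug_id)
      expect_equal(tab$str_jackard[r], oracle_jaccard(subs[[i]], subs[[j]]))
      expect_equal(tab$str_max_prod[r], oracle_str_max_prod(net, i, j))
    }
  }
})

test_that("table rows agree with the single-pair operations", {
  set.seed(12)
  tax <- toy_taxonomy()
  net <- random_small_net(n = 9, p = 0.5, tax = tax)
  tab <- build_covariate_table(net, tax, pairs = "all")
  r <- sample(nrow(tab), 1)
  i <- tab$drug_a[r]; j <- tab$drug_b[r]
  expect_equal(tab$jackard[r], neighbor_jaccard(net, i, j))
  expect_equal(tab$jackard_max2_mean[r], jaccard_max2_mean(net, i, j))
  tc <- topology_covariates(net, i, j)
  expect_equal(tab$degree_prod[r], unname(tc["degree_prod"]))
  expect_equal(tab$betw_prod[r], unname(tc["betw_prod"]))
  expect_equal(tab$cccnw_max[r], unname(tc["cccnw_max"]))
  expect_equal(tab$atc_min_prod[r], atc_min_prod(net, tax, i, j))
  expect_equal(tab$str_max_prod[r], str_max_prod(net, i, j))
})

test_that("covariates are symmetric, bounded, and respond to the response", {
  set.seed(17)
  net <- random_small_net(n = 10, p = 0.5)
  tax <- toy_taxonomy()
  tab <- build_covariate_table(net, tax, pairs = "all")
  expect_equal(nrow(tab), choose(10, 2))
  expect_equal(sum(tab$response), n_edges(net))
  for (cv in c("jackard", "jackard_max2_mean", "str_jackard",
               "str_max_prod", "cccnw_max")) {
    expect_true(all(tab[[cv]] >= 0 & tab[[cv]] <= 1), info = cv)
  }
  for (cv in c("degree_prod", "betw_prod", "atc_min", "atc_min_prod"))
    expect_true(all(tab[[cv]] >= 0), info = cv)
  # symmetry: swapping pair endpoints gives the same rows back
  swapped <- data.frame(drug_a = tab$drug_b[1:5], drug_b = tab$drug_a[1:5])
  tab2 <- build_covariate_table(net, tax, pairs = swapped)
  expect_equal(tab2, tab[1:5, ])
})

test_that("edits far from a pair leave its neighborhood Jaccard unchanged", {
  # removing an edge not incident to i, j, or their neighbors
  net <- toy_net(edge_df("i", "a", "j", "a", "x", "y", "y", "z"))
  before <- neighbor_jaccard(net, "i", "j")
  net2 <- toy_net(edge_df("i", "a", "j", "a", "x", "y"),
                  ids = net$drugs$drug_id)
  expect_equal(neighbor_jaccard(net2, "i", "j"), before)
})

test_that("adding a common neighbor never decreases neighbor Jaccard", {
  set.seed(23)
  for (rep in 1:10) {
    net <- random_small_net(n = 8, p = 0.4)
    ids <- net$drugs$drug_id
    pair <- sample(ids, 2)
    before <- neighbor_jaccard(net, pair[1], pair[2])
    if (before >= 1) next
    # attach a fresh drug to both endpoints
    attrs <- toy_attrs(c(ids, "znew"))
    edges <- rbind(net$edges[, c("drug_a", "drug_b")],
                   edge_df(pair[1], "znew", pair[2], "znew"))
    net2 <- build_network(edges, attrs)
    expect_gte(neighbor_jaccard(net2, pair[1], pair[2]), before)
  }
})

test_that("the covariate registry is swappable and validated", {
  net <- random_small_net(n = 6, p = 0.5)
  reg <- ppinet:::default_covariate_registry()
  reg$degree_sum <- function(ctx, ia, ib) ctx$deg[ia] + ctx$deg[ib]
  tab <- build_covariate_table(net, NULL, pairs = "all",
                               covariates = c("degree_prod", "degree_sum"),
                               registry = reg)
  degs <- vapply(tab$drug_a, function(d) length(oracle_neighbors(net, d)),
                 numeric(1))
  degs_b <- vapply(tab$drug_b, function(d) length(oracle_neighbors(net, d)),
                   numeric(1))
  expect_equal(tab$degree_sum, unname(degs + degs_b))
  expect_error(build_covariate_table(net, NULL, covariates = "nope"),
               "not in registry")
  expect_error(build_covariate_table(net, NULL, covariates = "atc_min"),
               "taxonomy")
})

test_that("empty pair sets give empty tables", {
  net <- random_small_net(n = 5, p = 0.5)
  tab <- build_covariate_table(net, toy_taxonomy(),
                               pairs = data.frame(drug_a = character(),
                                                  drug_b = character()))
  expect_equal(nrow(tab), 0L)
  expect_true(all(ppin_covariates() %in% names(tab)))
})
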
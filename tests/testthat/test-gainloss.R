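quartet <- function() read_tree_text("((A,B),(C,D));")
read_tree_text <- function(txt) {
  p <- tempfile(fileext = ".nwk")
  writeLines(txt, p)
  read_tree(p)
}

test_that("a clade of carriers is explained by one gain on its stem", {
  tr <- quartet()
  res <- wagner_parsimony(tr, c(A = 1, B = 1, C = 0, D = 0))
  expect_equal(res$cost, 1)
  expect_equal(res$n_gains, 1L)
  expect_equal(res$n_losses, 0L)
  # the gain sits on the internal branch to ancestor(A, B), not a tip branch
  expect_equal(res$terminal_gains, 0L)
  gain_edge <- res$edges[res$edges$event == "gain", ]
  expect_false(gain_edge$terminal)
  # matches the exhaustive oracle, which finds both optimal root states
  bf <- brute_force_parsimony(tr, c(A = 1, B = 1, C = 0, D = 0))
  expect_equal(bf$cost, 1)
  expect_equal(nrow(bf$assignments), 2L)
})

test_that("degenerate profiles reconstruct with zero events", {
  tr <- quartet()
  res0 <- wagner_parsimony(tr, c(A = 0, B = 0, C = 0, D = 0))
  expect_equal(res0$cost, 0)
  expect_equal(unname(res0$states), rep(0L, 7))
  s <- event_summary(res0)
  expect_equal(unlist(s), c(n_gains = 0L, n_losses = 0L,
                            terminal_gains = 0L, terminal_losses = 0L))
})

test_that("a single carrier is a terminal-branch (species-level) gain", {
  tr <- quartet()
  res <- wagner_parsimony(tr, c(A = 1, B = 0, C = 0, D = 0))
  expect_equal(res$n_gains, 1L)
  expect_equal(res$terminal_gains, 1L)
  gain_edge <- res$edges[res$edges$event == "gain", ]
  expect_equal(gain_edge$child_label, "A")
  expect_equal(brute_force_parsimony(tr, c(A = 1, B = 0, C = 0, D = 0))$cost, 1)
})

test_that("asymmetric costs change the optimum and still match the oracle", {
  tr <- quartet()
  prof <- c(A = 1, B = 1, C = 1, D = 0)
  for (gc in c(0.5, 1, 2, 3)) {
    res <- wagner_parsimony(tr, prof, gain_cost = gc)
    bf <- brute_force_parsimony(tr, prof, gain_cost = gc)
    expect_equal(res$cost, bf$cost, info = paste("gain_cost", gc))
    expect_equal(res$cost, gc * res$n_gains + res$n_losses)
  }
  # expensive gains: a present root with one terminal loss beats any gain
  res2 <- wagner_parsimony(tr, prof, gain_cost = 2)
  expect_equal(res2$cost, 1)
  expect_equal(c(res2$n_gains, res2$n_losses), c(0L, 1L))
  expect_equal(res2$edges$child_label[res2$edges$event == "loss"], "D")
})

test_that("inputs are validated", {
  tr <- quartet()
  expect_error(wagner_parsimony(tr, c(A = 1, B = 0, C = 0)), "leaf missing.*D")
  expect_error(wagner_parsimony(tr, c(A = 1, B = 0, C = 0, D = 2)), "0/1")
  expect_error(wagner_parsimony(tr, c(A = 1, B = 0, C = 0, D = 0),
                                gain_cost = 0), "positive")
  big <- ape::rtree(30)
  expect_error(brute_force_parsimony(big, setNames(rep(0, 30), big$tip.label)),
               "too large")
})

test_that("DP cost equals the exhaustive minimum on random trees and costs", {
  set.seed(211)
  for (i in 1:120) {
    n <- sample(4:12, 1)
    tr <- random_tree(n)
    prof <- setNames(sample(0:1, n, replace = TRUE), tr$tip.label)
    gc <- sample(c(0.5, 1, 2), 1)
    lc <- sample(c(0.5, 1, 2), 1)
    res <- wagner_parsimony(tr, prof, gc, lc)
    bf <- brute_force_parsimony(tr, prof, gc, lc)
    expect_equal(res$cost, bf$cost, info = paste("case", i))
    expect_equal(res$cost, gc * res$n_gains + lc * res$n_losses,
                 info = paste("case", i))
  }
})

test_that("multifurcations are handled natively", {
  tr <- read_tree_text("(A,B,C,(D,E));")
  prof <- c(A = 0, B = 0, C = 1, D = 1, E = 1)
  res <- wagner_parsimony(tr, prof)
  bf <- brute_force_parsimony(tr, prof)
  expect_equal(res$cost, bf$cost)
})

test_that("complementing the profile and swapping costs swaps gains and losses", {
  set.seed(223)
  for (i in 1:40) {
    n <- sample(4:14, 1)
    tr <- random_tree(n)
    prof <- setNames(sample(0:1, n, replace = TRUE), tr$tip.label)
    gc <- sample(c(0.5, 1, 2), 1); lc <- sample(c(0.5, 1, 2), 1)
    a <- wagner_parsimony(tr, prof, gc, lc, root_prefer = 0L)
    b <- wagner_parsimony(tr, 1 - prof, lc, gc, root_prefer = 1L)
    expect_equal(a$n_gains, b$n_losses, info = paste("case", i))
    expect_equal(a$n_losses, b$n_gains, info = paste("case", i))
    expect_equal(a$cost, b$cost, info = paste("case", i))
  }
})

test_that("adding a leaf identical to its sister never increases the cost", {
  set.seed(227)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    tr <- random_tree(n)
    prof <- setNames(sample(0:1, n, replace = TRUE), tr$tip.label)
    base <- wagner_parsimony(tr, prof)$cost
    # graft a twin next to tip 1
    sister <- tr$tip.label[[1]]
    tr2 <- ape::bind.tree(tr, ape::read.tree(text = "(new:0.1);"),
                          where = 1)
    prof2 <- c(prof, new = unname(prof[sister]))
    grown <- wagner_parsimony(tr2, prof2)$cost
    expect_lte(grown, base + 1e-12)
  }
})

test_that("simulated histories bound the parsimony reconstruction from above", {
  tr <- ape::rcoal(50)
  # absorbing cases
  h0 <- simulate_gainloss_history(tr, 0, 0.5, root_state = 0, seed = 5)
  expect_true(all(h0$tip_profile == 0))
  h1 <- simulate_gainloss_history(tr, 0.5, 0, root_state = 1, seed = 5)
  expect_true(all(h1$tip_profile == 1))
  # determinism under seed
  a <- simulate_gainloss_history(tr, 0.4, 0.2, seed = 11)
  b <- simulate_gainloss_history(tr, 0.4, 0.2, seed = 11)
  expect_identical(a, b)

  set.seed(229)
  for (i in 1:50) {
    tr <- ape::rcoal(sample(10:40, 1))
    h <- simulate_gainloss_history(tr, 0.4, 0.15, seed = 300 + i)
    res <- wagner_parsimony(tr, h$tip_profile)
    expect_lte(res$n_gains + res$n_losses, h$n_events,
               label = paste("case", i, "inferred"))
  }
})

test_that("profiles round-trip through their TSV form", {
  prof <- c(A = 1L, B = 0L, C = 1L)
  p <- tempfile(fileext = ".tsv")
  write_profile(prof, p)
  expect_identical(read_profile(p), prof)
})
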
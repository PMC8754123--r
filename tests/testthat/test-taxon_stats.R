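# build a calls+meta pair realising given per-taxon counts
mk_cohort <- function(taxa, n, n_pos, habitat = NULL) {
  total <- sum(n)
  gid <- sprintf("g%05d", seq_len(total))
  order_ <- rep(taxa, n)
  pos <- unlist(mapply(function(k, kp) c(rep(TRUE, kp), rep(FALSE, k - kp)),
                       n, n_pos, SIMPLIFY = FALSE))
  calls <- data.frame(genome_id = gid, sac_positive = pos)
  meta <- data.frame(genome_id = gid, species = gid, genus = order_,
                     family = order_, order = order_, class = "cl",
                     is_type_strain = TRUE,
                     habitat = if (is.null(habitat)) "unknown" else habitat)
  list(calls = calls, meta = meta)
}

test_that("per-taxon rates use half-up rounding and the minimum-count rule", {
  x <- mk_cohort(c("Actinomycetales", "Dermabacterales", "Antricoccales",
                   "Beutenbergiales"),
                 n = c(65, 12, 4, 5), n_pos = c(45, 8, 0, 0))
  rates <- positive_rates(x$calls, x$meta, rank = "order")
  get <- function(t) rates$rate[rates$taxon == t]
  expect_equal(get("Actinomycetales"), "69.23%")
  expect_equal(get("Dermabacterales"), "66.67%")
  expect_equal(get("Antricoccales"), "ND")     # n = 4 < 5
  expect_equal(get("Beutenbergiales"), "0.00%") # n = 5: computed
  # Total row counts are the column sums of the taxon rows
  tot <- rates[rates$taxon == "Total", ]
  expect_equal(tot$n_strains, sum(rates$n_strains) - tot$n_strains)
  expect_equal(tot$n_positive, sum(rates$n_positive) - tot$n_positive)
  expect_error(positive_rates(x$calls, x$meta, rank = "phylum"),
               "unknown rank")
})

test_that("type-strain restriction changes the species-level denominators", {
  x <- mk_cohort("A", 10, 6)
  x$meta$is_type_strain <- rep(c(TRUE, FALSE), 5)
  r_all <- positive_rates(x$calls, x$meta, rank = "order")
  r_type <- positive_rates(x$calls, x$meta, rank = "order",
                           type_strains_only = TRUE)
  expect_equal(r_all$n_strains[r_all$taxon == "A"], 10L)
  expect_equal(r_type$n_strains[r_type$taxon == "A"], 5L)
})

test_that("half-up rounding matches hand-computed ties and printed rates", {
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(2.675, 2), 2.68)  # binary-representation trap
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(round_half_up(100 * 45 / 65, 2), 69.23)
  expect_equal(round_half_up(100 * 8 / 12, 2), 66.67)
  expect_equal(round_half_up(100 * 1295 / 7180, 2), 18.04)
})

test_that("gene presence rates count the role anywhere in the genome", {
  calls <- data.frame(genome_id = sprintf("g%d", 1:10),
                      sac_positive = FALSE,
                      nanE = c(rep(1L, 3), rep(0L, 7)),
                      nanA = 1L)
  meta <- data.frame(genome_id = calls$genome_id, is_type_strain = TRUE,
                     habitat = "unknown")
  expect_equal(gene_presence_rates("nanE", calls, meta)$rate, "30.00%")
  expect_equal(gene_presence_rates("nanA", calls, meta)$rate, "100.00%")
  calls$nanE <- 0L
  expect_equal(gene_presence_rates("nanE", calls, meta)$rate, "0.00%")
  expect_error(gene_presence_rates("nanZ", calls, meta), "unknown role")
})

test_that("two-sided Fisher p matches the enumeration oracle and stats::fisher.test", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1.0)
  expect_equal(fisher_exact_2x2(5, 0, 0, 5), 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(1, 9, 11, 3), oracle_fisher(1, 9, 11, 3),
               tolerance = 1e-12)

  set.seed(73)
  for (i in 1:60) {
    t <- sample(0:25, 4, replace = TRUE)
    if (sum(t[1:2]) == 0 || sum(t[3:4]) == 0 ||
          sum(t[c(1, 3)]) == 0 || sum(t[c(2, 4)]) == 0) next
    p <- fisher_exact_2x2(t[1], t[2], t[3], t[4])
    expect_equal(p, oracle_fisher(t[1], t[2], t[3], t[4]),
                 tolerance = 1e-12, info = paste(t, collapse = ","))
    expect_equal(p, stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9, info = paste(t, collapse = ","))
    # symmetry: row swap, column swap, transpose
    expect_equal(p, fisher_exact_2x2(t[3], t[4], t[1], t[2]), tolerance = 1e-12)
    expect_equal(p, fisher_exact_2x2(t[2], t[1], t[4], t[3]), tolerance = 1e-12)
    expect_equal(p, fisher_exact_2x2(t[1], t[3], t[2], t[4]), tolerance = 1e-12)
  }
  # log-space: large counts do not overflow
  expect_gt(fisher_exact_2x2(50000, 50000, 50000, 50000), 0.9)
})

test_that("habitat association builds the 2x2 table and excludes unknowns", {
  x <- mk_cohort(c("A", "B"), n = c(609, 1360),
                 n_pos = c(151, 103))
  x$meta$habitat <- c(rep("animal", 609),
                      rep("non_animal", 1314), rep("unknown", 46))
  # make the 46 unknowns all negative: move them off the positive rows
  res <- habitat_association(x$calls, x$meta)
  expect_equal(res$n_unknown, 46L)
  expect_equal(unname(res$table["animal", "positive"]), 151L)
  expect_equal(unname(res$rates["animal"]), 24.79)
  expect_lt(res$p_value, 2.2e-16)

  zero <- matrix(c(0L, 10L, 0L, 10L), 2, byrow = TRUE,
                 dimnames = list(c("animal", "non_animal"),
                                 c("positive", "negative")))
  expect_warning(rz <- contingency_result(zero), "margin")
  expect_equal(rz$p_value, 1)
})

test_that("subset fractions reproduce their printed numerator/denominator pairs", {
  expect_equal(subset_fraction(103, 257), "40.08%")
  expect_equal(subset_fraction(29, 45), "64.44%")
  expect_equal(subset_fraction(421, 1969), "21.38%")
  expect_equal(subset_fraction(0, 10), "0.00%")
  expect_equal(subset_fraction(logical(0), logical(0)), "ND")
  expect_error(subset_fraction(c(TRUE, TRUE), c(TRUE, FALSE)), "subset")
})
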
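test_that("canonical windows: adjacent triples cluster, wide or split ones do not", {
  genes <- mk_genes("g1", c(c1 = 20))
  asg <- mk_asg(genes, list(c1 = list(nanA = 5, nanK = 6, nanE = 7)))
  cl <- find_canonical_clusters(genes, asg)
  expect_equal(nrow(cl), 1L)
  expect_equal(c(cl$min_ordinal, cl$max_ordinal), c(5L, 7L))

  # span 11 exceeds the 10-ORF window
  asg2 <- mk_asg(genes, list(c1 = list(nanA = 0, nanE = 5, nanK = 11)))
  expect_equal(nrow(find_canonical_clusters(genes, asg2)), 0L)
  # span exactly 10 is allowed
  asg3 <- mk_asg(genes, list(c1 = list(nanA = 0, nanE = 5, nanK = 10)))
  expect_equal(nrow(find_canonical_clusters(genes, asg3)), 1L)

  # core genes on different contigs never cluster
  genes2 <- mk_genes("g1", c(c1 = 10, c2 = 10))
  asg4 <- mk_asg(genes2, list(c1 = list(nanA = 0, nanK = 3),
                              c2 = list(nanE = 2)))
  expect_equal(nrow(find_canonical_clusters(genes2, asg4)), 0L)
})

test_that("two disjoint planted triples give two clusters that share no gene", {
  genes <- mk_genes("g1", c(c1 = 60))
  asg <- mk_asg(genes, list(c1 = list(nanA = c(5, 40), nanK = c(6, 42),
                                      nanE = c(7, 44))))
  cl <- find_canonical_clusters(genes, asg)
  expect_equal(nrow(cl), 2L)
  uids <- strsplit(cl$core_uids, ",")
  expect_equal(length(intersect(uids[[1]], uids[[2]])), 0L)
})

test_that("alternative paradigm needs clustered nanA/nanE-II plus rokA anywhere", {
  genes <- mk_genes("g1", c(c1 = 30, c2 = 10))
  with_roka <- mk_asg(genes, list(c1 = list(nanA = 4, nanE_II = 6),
                                  c2 = list(rokA = 1)))
  cl <- find_bacteroidetes_clusters(genes, with_roka)
  expect_equal(nrow(cl), 1L)
  expect_equal(c(cl$min_ordinal, cl$max_ordinal), c(4L, 6L))

  no_roka <- mk_asg(genes, list(c1 = list(nanA = 4, nanE_II = 6)))
  expect_equal(nrow(find_bacteroidetes_clusters(genes, no_roka)), 0L)

  too_far <- mk_asg(genes, list(c1 = list(nanA = 4, nanE_II = 16),
                                c2 = list(rokA = 1)))
  expect_equal(nrow(find_bacteroidetes_clusters(genes, too_far)), 0L)
})

test_that("structure typing is order-blind and gap-sensitive", {
  genes <- mk_genes("g1", c(c1 = 20))
  consec <- find_canonical_clusters(
    genes, mk_asg(genes, list(c1 = list(nanE = 5, nanA = 6, nanK = 7))))
  expect_equal(classify_structure(consec), "consecutive")

  gapped <- find_canonical_clusters(
    genes, mk_asg(genes, list(c1 = list(nanA = 5, nanK = 7, nanE = 8))))
  expect_equal(classify_structure(gapped), "inconsecutive")

  bac <- data.frame(paradigm = "bacteroidetes", core_ordinals = "1,2")
  expect_error(classify_structure(bac), "canonical")
})

test_that("context annotation maps transporters to ST families", {
  genes <- mk_genes("g1", c(c1 = 30))
  base <- list(nanA = 5, nanK = 6, nanE = 7)

  run <- function(extra) {
    asg <- mk_asg(genes, list(c1 = c(base, extra)), accessions = "COG2186")
    cl <- find_canonical_clusters(genes, asg)
    annotate_context(cl, genes, asg)
  }
  st3 <- run(list(transporter_ABC_ST3 = 9))
  expect_equal(st3$transporter_superfamily, "ABC")
  expect_equal(st3$transporter_st, "ST3")

  both <- run(list(transporter_ABC_ST3 = 9, transporter_MFS = 10))
  expect_equal(both$transporter_superfamily, "ABC,MFS")
  expect_equal(both$transporter_st, "ST3,ND")  # MFS family undetermined

  mfs <- run(list(transporter_MFS = 9))
  expect_equal(mfs$transporter_st, "ST1")
  sss <- run(list(transporter_SSS = 9))
  expect_equal(sss$transporter_st, "ST5")
  part <- run(list(transporter_ABC_partial = 9))
  expect_equal(part$transporter_superfamily, "ABC_partial")
  expect_equal(part$transporter_st, "ND")

  # beyond the 5-ORF flank the transporter is not attributed to the cluster
  far <- run(list(transporter_ABC_ST3 = 13))
  expect_equal(far$transporter_superfamily, "none")
})

test_that("regulators count within three ORFs of the span, flags and boundary work", {
  genes <- mk_genes("g1", c(c1 = 30))
  asg <- mk_asg(genes, list(c1 = list(nanA = 5, nanK = 6, nanE = 7,
                                      regulator = 3, nagB = 12, IS = 11)),
                accessions = "COG2186")
  cl <- annotate_context(find_canonical_clusters(genes, asg), genes, asg)
  expect_equal(cl$regulator_cogs, "COG2186")  # 2 ordinals upstream
  expect_false(cl$nagB_in_cluster)            # in flank but not in span
  expect_true(cl$IS_near)                     # flank counts for IS
  expect_true(cl$contig_boundary)             # span start within 10 of end

  far_reg <- mk_asg(genes, list(c1 = list(nanA = 12, nanK = 13, nanE = 14,
                                          regulator = 5)),
                    accessions = "COG1349")
  cl2 <- annotate_context(find_canonical_clusters(genes, far_reg), genes,
                          far_reg)
  expect_equal(cl2$regulator_cogs, "")        # 4 ordinals away: outside rule
  expect_false(cl2$contig_boundary)           # 12 and 15 both > 10 from ends

  # no transporter, span at the contig edge
  edge <- mk_asg(genes, list(c1 = list(nanA = 0, nanK = 1, nanE = 2)))
  cl3 <- annotate_context(find_canonical_clusters(genes, edge), genes, edge)
  expect_equal(cl3$transporter_superfamily, "none")
  expect_true(cl3$contig_boundary)
})

test_that("genome verdicts follow the cluster rule, not gene presence", {
  genes <- mk_genes("g1", c(c1 = 40, c2 = 40))
  # scattered nanA and nanK everywhere, no nanE: negative
  scattered <- mk_asg(genes, list(c1 = list(nanA = c(0, 20), nanK = 35),
                                  c2 = list(nanK = 5)))
  res <- call_genomes(genes, scattered)
  expect_false(res$calls$sac_positive)
  expect_equal(res$calls$nanA, 2L)

  canonical <- mk_asg(genes, list(c1 = list(nanA = 5, nanK = 6, nanE = 7)))
  expect_equal(call_genomes(genes, canonical)$calls$paradigms, "canonical")

  bac_only <- mk_asg(genes, list(c1 = list(nanA = 4, nanE_II = 6),
                                 c2 = list(rokA = 0)))
  res3 <- call_genomes(genes, bac_only)
  expect_true(res3$calls$sac_positive)
  expect_equal(res3$calls$paradigms, "bacteroidetes")
})

test_that("extra core copies next to the cluster are flanking, not core", {
  genes <- mk_genes("g1", c(c1 = 30))
  # second nanA at 10: farther from nanE than the in-cluster copy at 5
  asg <- mk_asg(genes, list(c1 = list(nanA = c(5, 10), nanK = 6, nanE = 7)))
  res <- call_genomes(genes, asg)
  expect_equal(nrow(res$clusters), 1L)
  expect_equal(res$clusters$max_ordinal, 7L)
  expect_equal(res$clusters$extra_nanA, 1L)
  expect_equal(res$calls$nanA, 2L)

  # equidistant copies: the tie resolves to the lower ordinal
  tie <- mk_asg(genes, list(c1 = list(nanA = c(5, 9), nanK = 6, nanE = 7)))
  res2 <- call_genomes(genes, tie)
  expect_equal(res2$clusters$min_ordinal, 5L)
  expect_equal(res2$clusters$max_ordinal, 7L)
})

test_that("detection is invariant to row order and uid relabeling", {
  set.seed(57)
  genes <- mk_genes("g1", c(c1 = 40))
  asg <- mk_asg(genes, list(c1 = list(nanA = c(3, 25), nanK = c(5, 30),
                                      nanE = 8)))
  ref <- find_canonical_clusters(genes, asg)

  perm <- sample(nrow(genes))
  shuffled <- find_canonical_clusters(genes[perm, ], asg[sample(nrow(asg)), ])
  expect_equal(shuffled, ref)

  relabel <- setNames(sprintf("x%03d", seq_len(nrow(genes))), genes$gene_uid)
  genes2 <- genes; genes2$gene_uid <- unname(relabel[genes$gene_uid])
  asg2 <- asg; asg2$gene_uid <- unname(relabel[asg$gene_uid])
  rel <- find_canonical_clusters(genes2, asg2)
  expect_equal(rel$min_ordinal, ref$min_ordinal)
  expect_equal(rel$max_ordinal, ref$max_ordinal)
})

test_that("detector agrees with the brute-force triple oracle on random genomes", {
  set.seed(101)
  for (i in 1:200) {
    rg <- random_core_genome(sprintf("g%03d", i))
    got <- find_canonical_clusters(rg$genes, rg$asg)
    want <- oracle_canonical(rg$genes, rg$asg)
    expect_equal(nrow(got) > 0, want$verdict, info = paste("genome", i))
    # every nanE in a valid triple is covered by a cluster, and vice versa
    covered <- sort(unique(unlist(lapply(seq_len(nrow(got)), function(j) {
      uids <- strsplit(got$core_uids[[j]], ",")[[1]]
      roles <- strsplit(got$core_roles[[j]], ",")[[1]]
      uids[roles == "nanE"]
    }))))
    expect_equal(as.character(covered), as.character(want$covered_nanE),
                 info = paste("genome", i))
    # every reported cluster contains at least one valid in-window triple
    # (merged clusters may span wider than the window itself)
    if (nrow(got) > 0) expect_true(all(cluster_has_valid_triple(got)))
  }
})

test_that("the chain rule is at least as permissive as the max-span rule", {
  genes <- mk_genes("g1", c(c1 = 40))
  # A..K 8 apart, K..E 8 apart: fails max-span (16), passes chaining
  asg <- mk_asg(genes, list(c1 = list(nanA = 0, nanK = 8, nanE = 16)))
  expect_equal(nrow(find_canonical_clusters(genes, asg)), 0L)
  expect_equal(nrow(find_canonical_clusters(genes, asg, rule = "chain")), 1L)
})
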
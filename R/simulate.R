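#' Configuration for the synthetic genome-annotation simulator
#'
#' The defaults state the world the generator emulates: a genome collection
#' where the nan cluster is an accessory trait present in roughly 13% of
#' species, scattered nanA/nanK homologs are near-universal (99.6% / 97.7%)
#' while nanE is essentially cluster-bound, the alternative
#' (Bacteroidetes-like) paradigm is vanishingly rare (~1% of positives),
#' about 79% of canonical clusters carry their core triple consecutively,
#' ABC/ST3 transporters dominate the transporter mix, nearly all clusters
#' have a flanking regulator and insertion sequences, and animal
#' host-associated species are enriched for the cluster (~59% of positives
#' vs ~27% of negatives, with ~2% of species of unknown source). Where the
#' source data state no value (genome sizes, taxonomy shape, gain/loss
#' rates), realistic desk-scale choices are fixed here and documented in the
#' methods vignette.
#'
#' @param n_genomes Number of genomes (all type strains, one per species).
#' @param genes_per_contig Length-2 integer range, genes drawn uniformly.
#' @param contigs_per_genome Contigs per genome.
#' @param cluster_prevalence Probability a species carries a nan cluster.
#' @param paradigm_canonical_frac Fraction of positives that are canonical.
#' @param consecutive_frac Fraction of canonical clusters with a gap-free
#'   core triple.
#' @param transporter_mix Named probabilities over
#'   ABC_ST3/ABC_ST7/MFS/SSS/ABC_MFS/partial/none (must sum to 1).
#' @param regulator_prob,sialidase_prob,it_frac,nanOx_cluster_prob,
#'   nagA_prob,nagB_prob,IS_prob,mobilome_prob Context probabilities;
#'   sialidase/nanOx/nagA/nagB sit inside the core span and are therefore
#'   only realised in inconsecutive clusters (gap positions).
#' @param extra_nanA_prob Probability of an additional nanA copy next to a
#'   canonical cluster.
#' @param decoy_nanA_prob,decoy_nanK_prob,decoy_sialidase_prob,
#'   decoy_nanOx_prob Genome-wide scattered homolog rates.
#' @param near_miss_prob Probability a genome carries a decoy with the right
#'   accession but an e-value 10-100x above the cutoff (exercises the
#'   threshold logic, not just accession matching).
#' @param n_orders,genera_per_order Taxonomy shape (species fill genera
#'   round-robin).
#' @param p_animal_pos,p_animal_neg,p_unknown Habitat assignment
#'   probabilities conditioned on cluster presence.
#' @param gain_rate,loss_rate Rates for the simulated gain/loss history on
#'   the coalescent species tree.
#' @param seed Master seed (required; all streams derive from it).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genomes = 200,
                       genes_per_contig = c(65, 95),
                       contigs_per_genome = 2,
                       cluster_prevalence = 0.13,
                       paradigm_canonical_frac = 0.99,
                       consecutive_frac = 0.79,
                       transporter_mix = c(ABC_ST3 = 0.84, ABC_ST7 = 0.025,
                                           MFS = 0.06, SSS = 0.035,
                                           ABC_MFS = 0.015, partial = 0.01,
                                           none = 0.015),
                       regulator_prob = 0.95,
                       sialidase_prob = 0.32, it_frac = 0.15,
                       nanOx_cluster_prob = 0.02,
                       nagA_prob = 0.28, nagB_prob = 0.48,
                       IS_prob = 0.95, mobilome_prob = 0.10,
                       extra_nanA_prob = 0.03,
                       decoy_nanA_prob = 0.996, decoy_nanK_prob = 0.977,
                       decoy_sialidase_prob = 0.31, decoy_nanOx_prob = 0.18,
                       near_miss_prob = 0.5,
                       n_orders = 5, genera_per_order = 4,
                       p_animal_pos = 0.59, p_animal_neg = 0.27,
                       p_unknown = 0.02,
                       gain_rate = 0.3, loss_rate = 0.1,
                       seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(cluster_prevalence, paradigm_canonical_frac, consecutive_frac,
             regulator_prob, sialidase_prob, it_frac, nanOx_cluster_prob,
             nagA_prob, nagB_prob, IS_prob, mobilome_prob, extra_nanA_prob,
             decoy_nanA_prob, decoy_nanK_prob, decoy_sialidase_prob,
             decoy_nanOx_prob, near_miss_prob, p_animal_pos, p_animal_neg,
             p_unknown, transporter_mix)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(transporter_mix) - 1) > 1e-9) {
    stop("transporter_mix must sum to 1")
  }
  if (n_genomes < 1) stop("counts must be positive")
  if (contigs_per_genome < 2) {
    stop("infeasible config: at least 2 contigs per genome (planted cluster ",
         "regions and scattered decoys live on separate contigs)")
  }
  if (genes_per_contig[[1L]] < 62) {
    stop("infeasible config: contigs must hold at least 62 genes to fit a ",
         "cluster region plus decoys separated by > 10 ordinals")
  }
  class(cfg) <- "sim_config"
  cfg
}

# independent deterministic substream per output section
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1009L + k
}

evalue_pass <- function(n, cutoff) cutoff * 10^-stats::runif(n, 2, 10)
evalue_fail <- function(n, cutoff) cutoff * 10^stats::runif(n, 1, 2)

#' Generate a seed-reproducible synthetic dataset with known ground truth
#'
#' Emits ordered gene tables, a domain-hit evidence table, genome metadata,
#' a coalescent species tree with a simulated gain/loss history, the SAC
#' presence profile, and a truth table recording everything that was
#' planted. Planted clusters satisfy the 10-ORF window rule by construction;
#' scattered decoy core genes are placed more than 10 ordinals from any
#' complementary core gene so they can never complete a window; evidence for
#' planted roles passes every threshold while near-miss decoys carry the
#' right accession with a failing e-value.
#'
#' @param config A [sim_config()].
#' @return list: `genes`, `evidence`, `meta`, `tree`, `profile`,
#'   `truth` (list with `genomes`, `history`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genomes
  gids <- sprintf("g%05d", seq_len(n))

  set.seed(derive_seed(config$seed, 1L))
  layout <- plan_genomes(config, gids)

  set.seed(derive_seed(config$seed, 2L))
  built <- build_genomes(config, layout)

  set.seed(derive_seed(config$seed, 3L))
  meta <- build_metadata(config, layout)

  set.seed(derive_seed(config$seed, 4L))
  tree <- ape::rcoal(n, tip.label = gids)

  history <- simulate_gainloss_history(tree, config$gain_rate,
                                       config$loss_rate, root_state = 0L,
                                       seed = derive_seed(config$seed, 5L))

  profile <- as.integer(layout$positive)
  names(profile) <- gids

  list(genes = built$genes, evidence = built$evidence, meta = meta,
       tree = tree, profile = profile,
       truth = list(genomes = built$truth, history = history))
}

# per-genome random decisions, before any gene is laid down
plan_genomes <- function(config, gids) {
  n <- length(gids)
  positive <- stats::runif(n) < config$cluster_prevalence
  paradigm <- ifelse(positive,
                     ifelse(stats::runif(n) < config$paradigm_canonical_frac,
                            "canonical", "bacteroidetes"),
                     NA_character_)
  consecutive <- paradigm == "canonical" &
    stats::runif(n) < config$consecutive_frac
  transporter <- sample(names(config$transporter_mix), n, replace = TRUE,
                        prob = config$transporter_mix)
  list(genome_id = gids, positive = positive, paradigm = paradigm,
       consecutive = consecutive, transporter = transporter,
       regulator = stats::runif(n) < config$regulator_prob,
       sialidase = stats::runif(n) < config$sialidase_prob,
       it = stats::runif(n) < config$it_frac,
       nanOx_cl = stats::runif(n) < config$nanOx_cluster_prob,
       nagA = stats::runif(n) < config$nagA_prob,
       nagB = stats::runif(n) < config$nagB_prob,
       IS = stats::runif(n) < config$IS_prob,
       mobilome = stats::runif(n) < config$mobilome_prob,
       extra_nanA = stats::runif(n) < config$extra_nanA_prob,
       decoy_nanA = stats::runif(n) < config$decoy_nanA_prob,
       decoy_nanK = stats::runif(n) < config$decoy_nanK_prob,
       decoy_sial = stats::runif(n) < config$decoy_sialidase_prob,
       decoy_nanOx = stats::runif(n) < config$decoy_nanOx_prob,
       near_miss = stats::runif(n) < config$near_miss_prob)
}

build_genomes <- function(config, layout) {
  n <- length(layout$genome_id)
  gene_rows <- vector("list", n)
  ev_rows <- vector("list", n)
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    g <- build_one_genome(config, layout, i)
    gene_rows[[i]] <- g$genes
    ev_rows[[i]] <- g$evidence
    truth_rows[[i]] <- g$truth
  }
  genes <- do.call(rbind, gene_rows)
  genes <- assign_ordinals(genes)
  list(genes = genes, evidence = do.call(rbind, ev_rows),
       truth = do.call(rbind, truth_rows))
}

# evidence helpers ----------------------------------------------------------

ev_row <- function(uid, source, accession, evalue, identity = NA_real_,
                   coverage = NA_real_) {
  data.frame(gene_uid = uid, source = source, accession = accession,
             evalue = evalue, identity_pct = identity,
             coverage_pct = coverage, stringsAsFactors = FALSE)
}

role_evidence <- function(uid, role, pass = TRUE) {
  e <- function(cut) if (pass) evalue_pass(1, cut) else evalue_fail(1, cut)
  switch(role,
    nanA = rbind(ev_row(uid, "pfam", "PF00701", e(1e-10)),
                 ev_row(uid, "cdd", "cd00954", e(1e-10))),
    nanK = rbind(ev_row(uid, "pfam", "PF00480", e(1e-10)),
                 ev_row(uid, "cdd", "PRK09434", e(1e-10))),
    nanE = rbind(ev_row(uid, "pfam", "PF04131", e(1e-10)),
                 ev_row(uid, "cdd", "PRK09435", e(1e-10))),
    nagA = ev_row(uid, "pfam", "PF01979", e(1e-10)),
    nagB = ev_row(uid, "pfam", "PF01182", e(1e-10)),
    sialidase = ev_row(uid, "pfam", "PF13088", e(1e-10)),
    it_sialidase_segment = ev_row(uid, "itseg", "RgNanH_seg", e(1e-10)),
    nanE_II = ev_row(uid, "blastp", "NanE-II_ref", e(1e-5),
                     identity = stats::runif(1, 40, 90)),
    rokA = ev_row(uid, "blastp", "RokA_ref", e(1e-5),
                  identity = stats::runif(1, 40, 90)),
    nanOx = ev_row(uid, "blastp", "NanOx_ref", e(1e-5),
                   identity = stats::runif(1, 40, 90)),
    transporter_ABC_ST3 = ev_row(uid, "pfam", "PF00496", e(1e-10)),
    transporter_ABC_ST7 = ev_row(uid, "pfam", "PF01547", e(1e-10)),
    transporter_ABC_partial = ev_row(uid, "pfam", "PF00528", e(1e-10)),
    transporter_MFS = ev_row(uid, "pfam", "PF07690", e(1e-10)),
    transporter_SSS = ev_row(uid, "pfam", "PF00474", e(1e-10)),
    regulator = ev_row(uid, "cog",
                       sample(c("COG2186", "COG1349", "COG1481", "COG2207"),
                              1L, prob = c(0.85, 0.05, 0.05, 0.05)),
                       e(1e-5), identity = stats::runif(1, 55, 95),
                       coverage = stats::runif(1, 60, 99)),
    IS = ev_row(uid, "isfinder", sprintf("IS%d", sample(100:999, 1L)),
                e(1e-5)),
    mobilome = ev_row(uid, "cog", "X", e(1e-5),
                      identity = stats::runif(1, 55, 95),
                      coverage = stats::runif(1, 60, 99)),
    stop("unknown role in generator: ", role)
  )
}

# layout of one genome: contig 1 carries the planted cluster region (if
# positive), contig 2 (or the tail of contig 1 when there is only one
# contig) carries the scattered decoys at >10-ordinal spacing
build_one_genome <- function(config, layout, i) {
  gid <- layout$genome_id[[i]]
  ncontig <- config$contigs_per_genome
  sizes <- sample(seq(config$genes_per_contig[[1L]],
                      config$genes_per_contig[[2L]]), ncontig, replace = TRUE)
  contigs <- sprintf("%s_c%d", gid, seq_len(ncontig))

  roles <- list()  # per contig: named integer vector ordinal -> role
  for (ci in seq_len(ncontig)) {
    roles[[ci]] <- character(sizes[[ci]])
  }

  truth <- data.frame(genome_id = gid, positive = layout$positive[[i]],
                      paradigm = NA_character_, contig_id = NA_character_,
                      min_ordinal = NA_integer_, max_ordinal = NA_integer_,
                      structure = NA_character_,
                      transporter_superfamily = "none", transporter_st = "ND",
                      regulator = FALSE, sialidase_in_cluster = FALSE,
                      it_sialidase_in_cluster = FALSE,
                      nanOx_in_cluster = FALSE, nanOx_in_genome = FALSE,
                      nagA_in_cluster = FALSE, nagB_in_cluster = FALSE,
                      IS_near = FALSE, mobilome_near = FALSE,
                      extra_nanA = 0L, n_nanA = 0L, n_nanK = 0L, n_nanE = 0L,
                      stringsAsFactors = FALSE)

  if (layout$positive[[i]]) {
    reg <- plan_cluster_region(config, layout, i)
    # place the region at a random base leaving >=12 ordinals on each side
    size1 <- sizes[[1L]]
    base <- sample(seq(13L, size1 - length(reg$roles) - 12L), 1L)
    idx <- base + seq_along(reg$roles)  # 1-based vector positions
    roles[[1L]][idx] <- reg$roles
    truth$paradigm <- reg$paradigm
    truth$contig_id <- contigs[[1L]]
    truth$min_ordinal <- base + reg$core_rel[[1L]]      # 0-based ordinals
    truth$max_ordinal <- base + reg$core_rel[[length(reg$core_rel)]]
    truth$structure <- reg$structure
    truth$transporter_superfamily <- reg$transporter_superfamily
    truth$transporter_st <- reg$transporter_st
    truth$regulator <- reg$regulator
    truth$sialidase_in_cluster <- reg$sialidase
    truth$it_sialidase_in_cluster <- reg$it
    truth$nanOx_in_cluster <- reg$nanOx
    truth$nagA_in_cluster <- reg$nagA
    truth$nagB_in_cluster <- reg$nagB
    truth$IS_near <- reg$IS
    truth$mobilome_near <- reg$mobilome
    truth$extra_nanA <- reg$extra_nanA
  }

  # scattered decoys, >= 12 ordinals apart, on the last contig
  decoys <- c(if (layout$decoy_nanA[[i]]) "nanA",
              if (layout$decoy_nanK[[i]]) "nanK",
              if (layout$decoy_sial[[i]]) "sialidase",
              if (layout$decoy_nanOx[[i]]) "nanOx",
              if (layout$positive[[i]] &&
                    layout$paradigm[[i]] == "bacteroidetes") "rokA",
              if (layout$near_miss[[i]]) "near_miss_nanE")
  ci <- ncontig
  slot <- 1L
  for (d in decoys) {
    pos <- slot
    if (pos > sizes[[ci]]) stop("infeasible config: contig too small for decoys")
    roles[[ci]][pos] <- d
    slot <- slot + 12L
  }

  # assemble gene and evidence tables
  gene_list <- vector("list", ncontig)
  ev_list <- list()
  for (ci in seq_len(ncontig)) {
    size <- sizes[[ci]]
    uids <- sprintf("%s_%04d", contigs[[ci]], seq_len(size))
    starts <- as.integer(seq_len(size) * 1000L - 999L)
    gene_list[[ci]] <- data.frame(
      genome_id = gid, contig_id = contigs[[ci]], gene_uid = uids,
      start = starts, end = starts + 899L,
      strand = sample(c("+", "-"), size, replace = TRUE),
      stringsAsFactors = FALSE)
    planted <- which(roles[[ci]] != "")
    for (p in planted) {
      r <- roles[[ci]][[p]]
      if (r == "near_miss_nanE") {
        ev_list[[length(ev_list) + 1L]] <-
          rbind(ev_row(uids[[p]], "pfam", "PF04131", evalue_fail(1, 1e-10)),
                ev_row(uids[[p]], "cdd", "PRK09435", evalue_fail(1, 1e-10)))
      } else if (r == "sialidase_IT") {
        ev_list[[length(ev_list) + 1L]] <-
          rbind(role_evidence(uids[[p]], "sialidase"),
                role_evidence(uids[[p]], "it_sialidase_segment"))
      } else {
        ev_list[[length(ev_list) + 1L]] <- role_evidence(uids[[p]], r)
      }
    }
    # wrong-accession background noise on a couple of plain genes
    plain <- which(roles[[ci]] == "")
    noise <- sample(plain, min(2L, length(plain)))
    for (p in noise) {
      ev_list[[length(ev_list) + 1L]] <-
        ev_row(uids[[p]], "pfam", "PF99999", evalue_pass(1, 1e-10))
    }
  }
  genes <- do.call(rbind, gene_list)
  evidence <- do.call(rbind, ev_list)

  all_roles <- unlist(roles)
  truth$n_nanA <- sum(all_roles == "nanA")
  truth$n_nanK <- sum(all_roles == "nanK")
  truth$n_nanE <- sum(all_roles == "nanE")
  truth$nanOx_in_genome <- any(all_roles == "nanOx") || truth$nanOx_in_cluster
  list(genes = genes, evidence = evidence, truth = truth)
}

# lay out the cluster region as a relative role vector:
# [regulator?] core-with-gaps [extra nanA?] transporter(s) [IS?] [mobilome?]
plan_cluster_region <- function(config, layout, i) {
  out <- list(paradigm = layout$paradigm[[i]])
  if (out$paradigm == "bacteroidetes") {
    gap <- sample(0:9, 1L)
    out$roles <- c("nanA", rep("", gap), "nanE_II")  # "" = plain filler gene
    out$core_rel <- c(0L, gap + 1L)
    out$structure <- NA_character_
    out$transporter_superfamily <- "none"; out$transporter_st <- "ND"
    out$regulator <- FALSE
    out$sialidase <- FALSE; out$it <- FALSE; out$nanOx <- FALSE
    out$nagA <- FALSE; out$nagB <- FALSE
    out$IS <- FALSE; out$mobilome <- FALSE
    out$extra_nanA <- 0L
    return(out)
  }

  # an extra nanA copy sits just beyond the core (consecutive clusters only,
  # matching where such copies are seen); nanE must then not be the last
  # core gene, so the in-core nanA stays the nearest partner of nanE
  extra_nanA <- layout$extra_nanA[[i]] && layout$consecutive[[i]]
  core_roles <- sample(c("nanA", "nanK", "nanE"))
  if (extra_nanA) {
    while (core_roles[[3L]] == "nanE") core_roles <- sample(core_roles)
  }
  # in-span context genes can only exist in the gaps of inconsecutive cores
  in_span <- character()
  if (!layout$consecutive[[i]]) {
    pool <- c(if (layout$sialidase[[i]])
                if (layout$it[[i]]) "sialidase_IT" else "sialidase",
              if (layout$nanOx_cl[[i]]) "nanOx",
              if (layout$nagA[[i]]) "nagA",
              if (layout$nagB[[i]]) "nagB")
    n_gap <- max(1L, min(length(pool) + sample(0:2, 1L), 8L))
    in_span <- c(pool, rep("", max(0L, n_gap - length(pool))))
    in_span <- sample(in_span)
  }
  # split the in-span genes into the two gaps of the core triple
  g1 <- if (length(in_span) == 0L) character() else
    in_span[seq_len(sample(0:length(in_span), 1L))]
  g2 <- setdiff(seq_along(in_span), seq_along(g1))
  g2 <- in_span[g2]
  core <- c(core_roles[[1L]], g1, core_roles[[2L]], g2, core_roles[[3L]])
  core_rel <- which(core %in% c("nanA", "nanK", "nanE")) - 1L

  before <- if (layout$regulator[[i]]) "regulator" else character()
  after <- character()
  if (extra_nanA) after <- c(after, "nanA")
  tr <- layout$transporter[[i]]
  tr_roles <- switch(tr,
    ABC_ST3 = "transporter_ABC_ST3", ABC_ST7 = "transporter_ABC_ST7",
    MFS = "transporter_MFS", SSS = "transporter_SSS",
    ABC_MFS = c("transporter_ABC_ST3", "transporter_MFS"),
    partial = "transporter_ABC_partial", none = character())
  after <- c(after, tr_roles)
  if (layout$IS[[i]]) after <- c(after, "IS")
  if (layout$mobilome[[i]]) after <- c(after, "mobilome")
  stopifnot(length(after) <= 5L)  # everything must stay inside the flank

  out$roles <- c(before, core, after)
  out$core_rel <- core_rel + length(before)
  out$structure <- if (max(core_rel) - min(core_rel) == 2L) "consecutive"
                   else "inconsecutive"
  out$transporter_superfamily <- switch(tr, ABC_ST3 = "ABC", ABC_ST7 = "ABC",
                                        MFS = "MFS", SSS = "SSS",
                                        ABC_MFS = "ABC,MFS",
                                        partial = "ABC_partial", none = "none")
  out$transporter_st <- switch(tr, ABC_ST3 = "ST3", ABC_ST7 = "ST7",
                               MFS = "ST1", SSS = "ST5", ABC_MFS = "ST3,ND",
                               partial = "ND", none = "ND")
  out$regulator <- layout$regulator[[i]]
  inconsec <- !layout$consecutive[[i]]
  out$sialidase <- inconsec && layout$sialidase[[i]]
  out$it <- inconsec && layout$sialidase[[i]] && layout$it[[i]]
  out$nanOx <- inconsec && layout$nanOx_cl[[i]]
  out$nagA <- inconsec && layout$nagA[[i]]
  out$nagB <- inconsec && layout$nagB[[i]]
  out$IS <- layout$IS[[i]]
  out$mobilome <- layout$mobilome[[i]]
  out$extra_nanA <- as.integer(extra_nanA)
  out
}

build_metadata <- function(config, layout) {
  n <- length(layout$genome_id)
  order_ids <- sprintf("order%02d", seq_len(config$n_orders))
  genus_ids <- sprintf("%s_genus%02d",
                       rep(order_ids, each = config$genera_per_order),
                       seq_len(config$genera_per_order))
  genus <- genus_ids[(seq_len(n) - 1L) %% length(genus_ids) + 1L]
  ord <- sub("_genus.*", "", genus)
  u <- stats::runif(n)
  p_animal <- ifelse(layout$positive, config$p_animal_pos,
                     config$p_animal_neg)
  habitat <- ifelse(u < config$p_unknown, "unknown",
                    ifelse(stats::runif(n) < p_animal, "animal",
                           "non_animal"))
  data.frame(genome_id = layout$genome_id,
             species = sprintf("sp_%s", layout$genome_id),
             genus = genus,
             family = paste0(ord, "_fam"),
             order = ord,
             class = "class01",
             is_type_strain = TRUE,
             habitat = habitat,
             stringsAsFactors = FALSE)
}

#' Write a synthetic dataset to disk in the pipeline's input formats
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  w(dataset$genes[, c("genome_id", "contig_id", "gene_uid", "start", "end",
                      "strand")], "genes.tsv")
  w(dataset$evidence, "evidence.tsv")
  w(dataset$meta, "metadata.tsv")
  w(dataset$truth$genomes, "truth_genomes.tsv")
  ape::write.tree(dataset$tree, file.path(dir, "species_tree.nwk"))
  write_profile(dataset$profile, file.path(dir, "profile.tsv"))
  invisible(dir)
}
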
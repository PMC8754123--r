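# Fixture builders: tiny genomes assembled in code, no files on disk.

# gene table for one genome; contigs = named integer vector (contig -> size)
mk_genes <- function(genome_id, contigs) {
  rows <- lapply(names(contigs), function(ctg) {
    n <- contigs[[ctg]]
    starts <- as.integer(seq_len(n) * 1000L - 999L)
    data.frame(genome_id = genome_id, contig_id = ctg,
               gene_uid = sprintf("%s_%s_%03d", genome_id, ctg, seq_len(n)),
               start = starts, end = starts + 899L, strand = "+",
               stringsAsFactors = FALSE)
  })
  assign_ordinals(do.call(rbind, rows))
}

# direct role-assignment rows (bypassing evidence thresholds) by ordinal
# spec: list of contig -> named list role -> ordinals (0-based)
mk_asg <- function(genes, spec, accessions = "") {
  rows <- list()
  for (ctg in names(spec)) {
    for (role in names(spec[[ctg]])) {
      for (ord in spec[[ctg]][[role]]) {
        uid <- genes$gene_uid[genes$contig_id == ctg & genes$ordinal == ord]
        stopifnot(length(uid) == 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          genome_id = genes$genome_id[[1L]], gene_uid = uid, role = role,
          accessions = accessions, best_evalue = 1e-20,
          pfam_confirmed = TRUE, cdd_confirmed = TRUE,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# brute-force cluster oracle: enumerate all (nanA, nanK, nanE) triples per
# contig and test max - min ordinal <= max_span; returns the genome verdict
# and the set of nanE ordinals participating in at least one valid triple
oracle_canonical <- function(genes, asg, max_span = 10) {
  pos <- merge(asg[asg$role %in% c("nanA", "nanK", "nanE"),
                   c("gene_uid", "role")],
               genes[, c("gene_uid", "genome_id", "contig_id", "ordinal")],
               by = "gene_uid")
  verdict <- FALSE
  covered <- character()
  for (key in unique(paste(pos$genome_id, pos$contig_id))) {
    sub <- pos[paste(pos$genome_id, pos$contig_id) == key, ]
    as_ <- sub$ordinal[sub$role == "nanA"]
    ks <- sub$ordinal[sub$role == "nanK"]
    es <- sub[sub$role == "nanE", ]
    if (length(as_) == 0 || length(ks) == 0 || nrow(es) == 0) next
    for (i in seq_len(nrow(es))) {
      e <- es$ordinal[[i]]
      for (a in as_) for (k in ks) {
        if (max(a, k, e) - min(a, k, e) <= max_span) {
          verdict <- TRUE
          covered <- c(covered, es$gene_uid[[i]])
        }
      }
    }
  }
  list(verdict = verdict, covered_nanE = sort(unique(covered)))
}

# random single-contig genome with scattered core genes, for oracle battery
random_core_genome <- function(genome_id, n_genes = 30) {
  genes <- mk_genes(genome_id, c(c1 = n_genes))
  k <- c(nanA = sample(0:3, 1), nanK = sample(0:3, 1), nanE = sample(0:2, 1))
  ords <- sample(0:(n_genes - 1), sum(k))
  roles <- rep(names(k), k)
  spec <- split(ords, roles)
  asg <- if (length(roles) > 0) mk_asg(genes, list(c1 = spec)) else
    data.frame(genome_id = character(), gene_uid = character(),
               role = character(), accessions = character(),
               best_evalue = numeric(), pfam_confirmed = logical(),
               cdd_confirmed = logical())
  list(genes = genes, asg = asg)
}

# does each reported cluster hold at least one (nanA, nanK, nanE) triple
# whose ordinal span is within the window?
cluster_has_valid_triple <- function(clusters, max_span = 10) {
  vapply(seq_len(nrow(clusters)), function(j) {
    roles <- strsplit(clusters$core_roles[[j]], ",")[[1]]
    ords <- as.integer(strsplit(clusters$core_ordinals[[j]], ",")[[1]])
    for (a in ords[roles == "nanA"]) for (k in ords[roles == "nanK"])
      for (e in ords[roles == "nanE"]) {
        if (max(a, k, e) - min(a, k, e) <= max_span) return(TRUE)
      }
    FALSE
  }, logical(1))
}

# independent two-sided Fisher oracle: full enumeration with choose(), no
# dhyper and no log-space tricks
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  tot <- choose(m + n2, k)
  prob <- function(x) choose(m, x) * choose(n2, k - x) / tot
  p_obs <- prob(a)
  xs <- max(0, k - n2):min(k, m)
  sum(vapply(xs, prob, 0)[vapply(xs, prob, 0) <= p_obs * (1 + 1e-7)])
}

# random tree with ape, tips relabelled deterministically
random_tree <- function(n_tips) {
  tr <- ape::rtree(n_tips)
  tr$tip.label <- sprintf("t%02d", seq_len(n_tips))
  tr
}
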
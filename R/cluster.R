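#' @title nan cluster detection by genomic-neighborhood rules
#' @description
#' A genome is called positive for sialic acid catabolism (SAC) when it
#' carries a nan gene cluster under one of two paradigms:
#' \itemize{
#'   \item canonical: nanA, nanK and nanE all within a 10-ORF window of each
#'     other (read as max - min ordinal of the triple <= 10, i.e. the three
#'     genes inside 11 consecutive ORFs);
#'   \item alternative ("Bacteroidetes-like"): nanA and nanE-II within 10
#'     ORFs of each other, with rokA present anywhere in the genome.
#' }
#' ORF distance is the difference of contig-local gene ordinals; clusters
#' never span contigs.
#' @name cluster-detection
NULL

# join role assignments to gene coordinates
role_positions <- function(genes, assignments) {
  idx <- match(assignments$gene_uid, genes$gene_uid)
  data.frame(genome_id = genes$genome_id[idx],
             contig_id = genes$contig_id[idx],
             ordinal = genes$ordinal[idx],
             gene_uid = assignments$gene_uid,
             role = assignments$role,
             stringsAsFactors = FALSE)
}

new_cluster_row <- function(genome_id, contig_id, paradigm, uids, roles,
                            ordinals) {
  o <- order(ordinals, roles)
  data.frame(genome_id = genome_id, contig_id = contig_id,
             paradigm = paradigm,
             core_uids = paste(uids[o], collapse = ","),
             core_roles = paste(roles[o], collapse = ","),
             core_ordinals = paste(ordinals[o], collapse = ","),
             min_ordinal = min(ordinals), max_ordinal = max(ordinals),
             stringsAsFactors = FALSE)
}

# merge candidate clusters sharing any core gene (union-find over clusters)
merge_shared <- function(members) {
  n <- length(members)
  if (n <= 1L) return(members)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (length(intersect(members[[i]]$uid, members[[j]]$uid)) > 0L) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  lapply(split(seq_len(n), comp), function(idx) {
    m <- do.call(rbind, members[idx])
    unique(m)
  })
}

#' Detect canonical nan clusters (nanA + nanK + nanE within a window)
#'
#' For every nanE gene, the nearest nanA and nanK on the same contig are
#' sought such that the ordinal span of the triple (max - min) does not
#' exceed `max_span`; among feasible partners the nearest is taken, ties
#' broken toward the lower ordinal. Candidate triples sharing any core gene
#' are merged into one cluster. Under `rule = "chain"` the window test is
#' instead connectivity: core genes are linked when within `max_span`
#' ordinals of each other and a connected component containing all three
#' roles is a cluster.
#'
#' @param genes Gene table with ordinals (see [read_gene_table()]).
#' @param assignments Role assignments from [assign_roles()].
#' @param max_span Window size in ORFs (default 10).
#' @param rule `"max_span"` (default) or `"chain"`.
#' @return data.frame, one row per cluster, sorted by
#'   (genome_id, contig_id, min_ordinal).
#' @export
find_canonical_clusters <- function(genes, assignments, max_span = 10,
                                    rule = c("max_span", "chain")) {
  rule <- match.arg(rule)
  pos <- role_positions(genes, assignments)
  pos <- pos[pos$role %in% CORE_ROLES, , drop = FALSE]
  out <- list()
  for (sub in split(pos, paste(pos$genome_id, pos$contig_id, sep = "\r"))) {
    if (!all(CORE_ROLES %in% sub$role)) next
    members <- if (rule == "max_span") {
      canonical_triples_maxspan(sub, max_span)
    } else {
      canonical_components_chain(sub, max_span)
    }
    if (length(members) == 0L) next
    members <- merge_shared(members)
    rows <- lapply(members, function(m) {
      new_cluster_row(sub$genome_id[[1L]], sub$contig_id[[1L]], "canonical",
                      m$uid, m$role, m$ordinal)
    })
    out <- c(out, rows)
  }
  finish_clusters(out)
}

canonical_triples_maxspan <- function(sub, max_span) {
  es <- sub[sub$role == "nanE", , drop = FALSE]
  as_ <- sub[sub$role == "nanA", , drop = FALSE]
  ks <- sub[sub$role == "nanK", , drop = FALSE]
  members <- list()
  for (i in seq_len(nrow(es))) {
    e <- es$ordinal[[i]]
    # feasible (A, K) pairs; pick nearest A, then nearest K, lower ordinal ties
    best <- NULL
    ao <- order(abs(as_$ordinal - e), as_$ordinal)
    for (ai in ao) {
      a <- as_$ordinal[[ai]]
      ko <- order(abs(ks$ordinal - e), ks$ordinal)
      for (ki in ko) {
        k <- ks$ordinal[[ki]]
        if (max(a, k, e) - min(a, k, e) <= max_span) {
          best <- c(ai, ki)
          break
        }
      }
      if (!is.null(best)) break
    }
    if (is.null(best)) next
    members[[length(members) + 1L]] <- data.frame(
      uid = c(es$gene_uid[[i]], as_$gene_uid[[best[1L]]],
              ks$gene_uid[[best[2L]]]),
      role = c("nanE", "nanA", "nanK"),
      ordinal = c(e, as_$ordinal[[best[1L]]], ks$ordinal[[best[2L]]]),
      stringsAsFactors = FALSE)
  }
  members
}

canonical_components_chain <- function(sub, max_span) {
  n <- nrow(sub)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in seq(i + 1L, n)) {
      if (abs(sub$ordinal[[i]] - sub$ordinal[[j]]) <= max_span) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  members <- list()
  for (idx in split(seq_len(n), comp)) {
    m <- sub[idx, , drop = FALSE]
    if (all(CORE_ROLES %in% m$role)) {
      members[[length(members) + 1L]] <-
        data.frame(uid = m$gene_uid, role = m$role, ordinal = m$ordinal,
                   stringsAsFactors = FALSE)
    }
  }
  members
}

#' Detect alternative-paradigm clusters (nanA + nanE-II, rokA in genome)
#'
#' nanA and nanE-II must lie within `max_span` ordinals on one contig, and
#' at least one rokA must be present anywhere in the genome (its location is
#' recorded but not constrained).
#'
#' @inheritParams find_canonical_clusters
#' @return data.frame of clusters with an extra `rokA_uids` column.
#' @export
find_bacteroidetes_clusters <- function(genes, assignments, max_span = 10) {
  pos <- role_positions(genes, assignments)
  out <- list()
  for (gid in unique(pos$genome_id[pos$role == "nanE_II"])) {
    gsub <- pos[pos$genome_id == gid, , drop = FALSE]
    roka <- gsub$gene_uid[gsub$role == "rokA"]
    if (length(roka) == 0L) next
    for (ctg in unique(gsub$contig_id[gsub$role == "nanE_II"])) {
      csub <- gsub[gsub$contig_id == ctg, , drop = FALSE]
      es <- csub[csub$role == "nanE_II", , drop = FALSE]
      as_ <- csub[csub$role == "nanA", , drop = FALSE]
      if (nrow(as_) == 0L) next
      members <- list()
      for (i in seq_len(nrow(es))) {
        e <- es$ordinal[[i]]
        d <- abs(as_$ordinal - e)
        feas <- which(d <= max_span)
        if (length(feas) == 0L) next
        ai <- feas[order(d[feas], as_$ordinal[feas])][[1L]]
        members[[length(members) + 1L]] <- data.frame(
          uid = c(es$gene_uid[[i]], as_$gene_uid[[ai]]),
          role = c("nanE_II", "nanA"),
          ordinal = c(e, as_$ordinal[[ai]]),
          stringsAsFactors = FALSE)
      }
      if (length(members) == 0L) next
      members <- merge_shared(members)
      rows <- lapply(members, function(m) {
        r <- new_cluster_row(gid, ctg, "bacteroidetes", m$uid, m$role,
                             m$ordinal)
        r$rokA_uids <- paste(sort(roka), collapse = ",")
        r
      })
      out <- c(out, rows)
    }
  }
  finish_clusters(out, bacteroidetes = TRUE)
}

finish_clusters <- function(rows, bacteroidetes = FALSE) {
  if (length(rows) == 0L) {
    df <- data.frame(genome_id = character(), contig_id = character(),
                     paradigm = character(), core_uids = character(),
                     core_roles = character(), core_ordinals = character(),
                     min_ordinal = integer(), max_ordinal = integer(),
                     stringsAsFactors = FALSE)
    if (bacteroidetes) df$rokA_uids <- character()
    return(df)
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$genome_id, df$contig_id, df$min_ordinal), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Classify the core-gene arrangement of a canonical cluster
#'
#' A cluster is of the consecutive type iff its core ordinals occupy a
#' gap-free run (for a plain triple: \{m, m+1, m+2\} in any role order);
#' otherwise other genes interrupt the core and the cluster is
#' inconsecutive.
#'
#' @param cluster One-row cluster data.frame (canonical paradigm).
#' @return `"consecutive"` or `"inconsecutive"`.
#' @export
classify_structure <- function(cluster) {
  if (cluster$paradigm != "canonical") {
    stop("structure typing applies to canonical clusters only")
  }
  ords <- sort(unique(as.integer(strsplit(cluster$core_ordinals, ",")[[1L]])))
  if (max(ords) - min(ords) == length(ords) - 1L) "consecutive"
  else "inconsecutive"
}

#' Annotate a cluster with transporters, regulators and context flags
#'
#' Searches outward from the core span: transporter, IS and mobilome genes
#' are looked for within the span and up to `flank` ordinals beyond it;
#' regulator (COG category K) genes within `regulator_flank` (3) ordinals;
#' sialidase / IT-sialidase / nanOx / nagA / nagB flags record in-span
#' presence, with nanOx additionally flagged genome-wide. Transporter
#' superfamilies map to sialic-acid transporter (ST) families as: ABC with
#' SBP_bac_5 -> ST3, ABC with SBP_bac_1 -> ST7, MFS -> ST1 (ST left ND when
#' an ABC system is also present), SSS -> ST5; a lone BPD_transp_1 permease
#' pair is a partial ABC system of undetermined family. `contig_boundary`
#' is set when the span lies within `boundary_dist` ordinals of a contig
#' end, where genes may be missing. Extra nanA/K/E copies in the flank
#' (outside the core) are counted per role.
#'
#' @param cluster One-row cluster data.frame.
#' @param genes Gene table with ordinals.
#' @param assignments Role assignments (genome-wide).
#' @param flank Flank width in ORFs for transporter/IS/mobilome search
#'   (default 5).
#' @param regulator_flank Flank width for regulator search (default 3).
#' @param boundary_dist Distance to a contig end that counts as a boundary
#'   (default 10).
#' @return The cluster row with annotation columns added.
#' @export
annotate_context <- function(cluster, genes, assignments, flank = 5,
                             regulator_flank = 3, boundary_dist = 10) {
  pos <- role_positions(genes, assignments)
  gpos <- pos[pos$genome_id == cluster$genome_id, , drop = FALSE]
  cpos <- gpos[gpos$contig_id == cluster$contig_id, , drop = FALSE]
  s1 <- cluster$min_ordinal
  s2 <- cluster$max_ordinal
  in_span <- cpos$ordinal >= s1 & cpos$ordinal <= s2
  in_flank <- cpos$ordinal >= s1 - flank & cpos$ordinal <= s2 + flank
  in_reg <- cpos$ordinal >= s1 - regulator_flank &
    cpos$ordinal <= s2 + regulator_flank

  # transporters: nearest systems around the core, span + flank
  tr <- unique(cpos$role[in_flank & startsWith(cpos$role, "transporter_")])
  fam <- character(); st <- character()
  if ("transporter_ABC_ST3" %in% tr) { fam <- c(fam, "ABC"); st <- c(st, "ST3") }
  if ("transporter_ABC_ST7" %in% tr) { fam <- c(fam, "ABC"); st <- c(st, "ST7") }
  if ("transporter_MFS" %in% tr) {
    fam <- c(fam, "MFS")
    st <- c(st, if (any(fam == "ABC")) "ND" else "ST1")
  }
  if ("transporter_SSS" %in% tr) { fam <- c(fam, "SSS"); st <- c(st, "ST5") }
  if (length(fam) == 0L && "transporter_ABC_partial" %in% tr) {
    fam <- "ABC_partial"; st <- "ND"
  }
  if (length(fam) == 0L) { fam <- "none"; st <- "ND" }
  cluster$transporter_superfamily <- paste(unique(fam), collapse = ",")
  cluster$transporter_st <- paste(st, collapse = ",")

  reg <- cpos[in_reg & cpos$role == "regulator", , drop = FALSE]
  reg_acc <- assignments$accessions[assignments$role == "regulator" &
                                      assignments$gene_uid %in% reg$gene_uid]
  cogs <- unlist(strsplit(reg_acc, ","))
  cogs <- sort(unique(grep("^COG", cogs, value = TRUE)))
  if (length(cogs) == 0L && nrow(reg) > 0L) cogs <- "K"
  cluster$regulator_cogs <- paste(cogs, collapse = ",")

  has_role_in <- function(role, where) any(cpos$role == role & where)
  seg_genes <- gpos$gene_uid[gpos$role == "it_sialidase_segment"]
  cluster$sialidase_in_cluster <- has_role_in("sialidase", in_span)
  cluster$it_sialidase_in_cluster <-
    any(cpos$role == "sialidase" & in_span & cpos$gene_uid %in% seg_genes)
  cluster$nanOx_in_cluster <- has_role_in("nanOx", in_span)
  cluster$nanOx_in_genome <- any(gpos$role == "nanOx")
  cluster$nagA_in_cluster <- has_role_in("nagA", in_span)
  cluster$nagB_in_cluster <- has_role_in("nagB", in_span)
  cluster$IS_near <- has_role_in("IS", in_flank)
  cluster$mobilome_near <- has_role_in("mobilome", in_flank)

  contig_max <- max(genes$ordinal[genes$genome_id == cluster$genome_id &
                                    genes$contig_id == cluster$contig_id])
  cluster$contig_boundary <- (s1 <= boundary_dist) ||
    (contig_max - s2 <= boundary_dist)

  core_uids <- strsplit(cluster$core_uids, ",")[[1L]]
  for (r in CORE_ROLES) {
    extra <- cpos$role == r & in_flank & !(cpos$gene_uid %in% core_uids)
    cluster[[paste0("extra_", r)]] <- sum(extra)
  }
  if (cluster$paradigm == "canonical") {
    cluster$structure <- classify_structure(cluster)
  } else {
    cluster$structure <- NA_character_
  }
  cluster
}

#' Single-genome SAC call
#'
#' Convenience wrapper over [call_genomes()] for one genome.
#'
#' @inheritParams call_genomes
#' @param genome_id Genome to call.
#' @return list with a one-row `calls` data.frame and its `clusters`.
#' @export
call_genome <- function(genes, assignments, genome_id, ...) {
  sel <- genes$genome_id == genome_id
  if (!any(sel)) stop("unknown genome_id: ", genome_id)
  call_genomes(genes[sel, , drop = FALSE],
               assignments[assignments$genome_id == genome_id, , drop = FALSE],
               ...)
}

#' Run full nan cluster detection and per-genome SAC calling
#'
#' Detects clusters under both paradigms, annotates their genomic context,
#' and reduces each genome to a verdict: SAC-positive iff it carries at
#' least one cluster. Scattered nanA/nanK homologs alone never make a
#' genome positive; nanE (or nanE-II plus rokA) in a shared neighborhood is
#' required.
#'
#' @inheritParams annotate_context
#' @param max_span Window size in ORFs (default 10).
#' @param rule Window semantics for the canonical paradigm.
#' @return list with `calls` (one row per genome: `genome_id`,
#'   `sac_positive`, `paradigms`, `n_clusters`, per-role copy-number
#'   columns) and `clusters` (annotated cluster table).
#' @export
call_genomes <- function(genes, assignments, max_span = 10,
                         rule = c("max_span", "chain"), flank = 5,
                         regulator_flank = 3, boundary_dist = 10) {
  rule <- match.arg(rule)
  can <- find_canonical_clusters(genes, assignments, max_span, rule)
  bac <- find_bacteroidetes_clusters(genes, assignments, max_span)
  if (nrow(can) > 0L) can$rokA_uids <- NA_character_
  clusters <- rbind(can, bac[, names(can), drop = FALSE])
  if (nrow(clusters) > 0L) {
    ann <- lapply(seq_len(nrow(clusters)), function(i) {
      annotate_context(clusters[i, , drop = FALSE], genes, assignments,
                       flank = flank, regulator_flank = regulator_flank,
                       boundary_dist = boundary_dist)
    })
    clusters <- do.call(rbind, ann)
    clusters <- clusters[order(clusters$genome_id, clusters$contig_id,
                               clusters$min_ordinal), , drop = FALSE]
    rownames(clusters) <- NULL
  }
  genomes <- sort(unique(genes$genome_id))
  cn <- copy_numbers(assignments, genomes)
  paradigms <- vapply(genomes, function(g) {
    p <- sort(unique(clusters$paradigm[clusters$genome_id == g]))
    paste(p, collapse = ",")
  }, character(1))
  calls <- data.frame(
    genome_id = genomes,
    sac_positive = genomes %in% clusters$genome_id,
    paradigms = unname(paradigms),
    n_clusters = vapply(genomes, function(g) {
      sum(clusters$genome_id == g)
    }, integer(1)),
    stringsAsFactors = FALSE)
  calls <- merge(calls, cn, by = "genome_id", sort = TRUE)
  rownames(calls) <- NULL
  list(calls = calls, clusters = clusters)
}
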
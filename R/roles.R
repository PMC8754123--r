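#' Assign functional roles to genes from domain-hit evidence
#'
#' Applies the role map's evidence patterns and thresholds to a table of
#' domain hits. A hit supports a role iff its source and accession match a
#' pattern and every stated threshold passes strictly (`evalue <
#' evalue_max`, `identity_pct > identity_min`, `coverage_pct >
#' coverage_min`). The three core catabolic roles (nanA, nanK, nanE) are
#' assigned only when both a Pfam hit and a CDD confirmation hit pass; all
#' other roles need a single passing pattern. A gene may carry several roles
#' when evidence for each passes independently.
#'
#' @param genes Gene table (provides the known gene_uids and their genomes).
#' @param hits Domain-hit table as from [read_evidence_table()].
#' @param rolemap Role map, default [default_role_map()].
#' @return data.frame with columns `genome_id`, `gene_uid`, `role`,
#'   `accessions` (comma-joined), `best_evalue`, `pfam_confirmed`,
#'   `cdd_confirmed`, ordered by (genome_id, gene_uid, role).
#' @export
assign_roles <- function(genes, hits, rolemap = default_role_map()) {
  validate_role_map(rolemap)
  if (anyDuplicated(genes$gene_uid)) {
    stop("gene_uid values must be unique across the gene table")
  }
  unknown <- setdiff(hits$gene_uid, genes$gene_uid)
  if (length(unknown) > 0L) {
    stop("evidence references unknown gene_uid(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  empty <- data.frame(genome_id = character(), gene_uid = character(),
                      role = character(), accessions = character(),
                      best_evalue = numeric(), pfam_confirmed = logical(),
                      cdd_confirmed = logical(), stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)

  # one pass per pattern row; hit tables are long, patterns are few
  passes <- vector("list", nrow(rolemap))
  for (i in seq_len(nrow(rolemap))) {
    pat <- rolemap[i, ]
    sel <- hits$source == pat$source &
      (pat$accession == "*" | hits$accession == pat$accession) &
      hits$evalue < pat$evalue_max
    if (!is.na(pat$identity_min)) {
      sel <- sel & !is.na(hits$identity_pct) &
        hits$identity_pct > pat$identity_min
    }
    if (!is.na(pat$coverage_min)) {
      sel <- sel & !is.na(hits$coverage_pct) &
        hits$coverage_pct > pat$coverage_min
    }
    if (any(sel)) {
      passes[[i]] <- data.frame(gene_uid = hits$gene_uid[sel],
                                role = pat$role,
                                source = hits$source[sel],
                                accession = hits$accession[sel],
                                evalue = hits$evalue[sel],
                                stringsAsFactors = FALSE)
    }
  }
  passes <- do.call(rbind, passes)
  if (is.null(passes) || nrow(passes) == 0L) return(empty)

  key <- paste(passes$gene_uid, passes$role, sep = "\r")
  agg <- lapply(split(seq_len(nrow(passes)), key), function(idx) {
    sub <- passes[idx, ]
    data.frame(gene_uid = sub$gene_uid[[1L]],
               role = sub$role[[1L]],
               accessions = paste(sort(unique(sub$accession)), collapse = ","),
               best_evalue = min(sub$evalue),
               pfam_confirmed = any(sub$source == "pfam"),
               cdd_confirmed = any(sub$source == "cdd"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  core <- out$role %in% CORE_ROLES
  out <- out[!core | (out$pfam_confirmed & out$cdd_confirmed), , drop = FALSE]
  out$genome_id <- genes$genome_id[match(out$gene_uid, genes$gene_uid)]
  out <- out[, c("genome_id", "gene_uid", "role", "accessions",
                 "best_evalue", "pfam_confirmed", "cdd_confirmed")]
  out <- out[order(out$genome_id, out$gene_uid, out$role), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split sialidase assignments into intramolecular trans- and hydrolytic types
#'
#' A sialidase gene is labelled an IT-sialidase iff the same gene also
#' carries a passing segmented RgNanH-type domain hit
#' (`it_sialidase_segment` role); otherwise it is a hydrolytic sialidase.
#' Segment evidence on a gene with no sialidase role is ignored with a
#' warning.
#'
#' @param assignments Role assignment table from [assign_roles()].
#' @return The table with an added `sialidase_subtype` column (`"IT"`,
#'   `"hydrolytic"`, or NA for non-sialidase rows).
#' @export
classify_sialidase <- function(assignments) {
  seg_genes <- assignments$gene_uid[assignments$role == "it_sialidase_segment"]
  sial_genes <- assignments$gene_uid[assignments$role == "sialidase"]
  orphan <- setdiff(seg_genes, sial_genes)
  if (length(orphan) > 0L) {
    warning("IT-sialidase segment evidence on non-sialidase gene(s), ",
            "ignored: ", paste(utils::head(orphan, 5L), collapse = ", "))
  }
  assignments$sialidase_subtype <- NA_character_
  is_sial <- assignments$role == "sialidase"
  assignments$sialidase_subtype[is_sial] <-
    ifelse(assignments$gene_uid[is_sial] %in% seg_genes, "IT", "hydrolytic")
  assignments
}

#' Per-genome role copy numbers
#'
#' @param assignments Role assignment table from [assign_roles()].
#' @param genomes Character vector of all genome ids to report (genomes with
#'   no assignment get zero counts).
#' @param roles Roles to count (default: all roles present plus the core
#'   roles).
#' @return data.frame, one row per genome, one integer column per role.
#' @export
copy_numbers <- function(assignments, genomes,
                         roles = union(CORE_ROLES, unique(assignments$role))) {
  out <- data.frame(genome_id = sort(unique(genomes)),
                    stringsAsFactors = FALSE)
  for (r in roles) {
    sub <- assignments[assignments$role == r, , drop = FALSE]
    tab <- table(factor(sub$genome_id, levels = out$genome_id))
    out[[r]] <- as.integer(tab)
  }
  out
}

#' Copy-number summary over positive genomes only
#'
#' Genomes lacking the role entirely are excluded before the order
#' statistics are taken, so the summary describes copy number among
#' carriers; a role absent everywhere yields an empty (NA) summary rather
#' than zeros.
#'
#' @param counts Wide copy-number table from [copy_numbers()].
#' @param role Role column to summarise.
#' @return One-row data.frame: `role`, `n_positive`, `q1`, `median`, `q3`.
#' @export
copy_number_summary <- function(counts, role) {
  if (!role %in% names(counts)) stop("unknown role: ", role)
  pos <- counts[[role]][counts[[role]] > 0]
  if (length(pos) == 0L) {
    return(data.frame(role = role, n_positive = 0L, q1 = NA_real_,
                      median = NA_real_, q3 = NA_real_))
  }
  q <- stats::quantile(pos, c(0.25, 0.5, 0.75), names = FALSE)
  data.frame(role = role, n_positive = length(pos), q1 = q[[1L]],
             median = q[[2L]], q3 = q[[3L]])
}
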
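#' Quality-filter genomes on completeness, contamination and marker content
#'
#' A genome is retained iff completeness > 95%, contamination < 5% and it
#' carries at least 75% of the 138 lineage marker genes. The completeness and
#' contamination cuts are strict (a genome at exactly 95% completeness is
#' dropped); the marker rule excludes only genomes strictly below 0.75.
#' Genomes with any missing metric are unevaluable and excluded with a
#' warning.
#'
#' @param metrics data.frame with `genome_id`, `completeness_pct`,
#'   `contamination_pct`, `marker_fraction`.
#' @param completeness_min Strict lower bound on completeness (default 95).
#' @param contamination_max Strict upper bound on contamination (default 5).
#' @param marker_min Inclusive lower bound on marker fraction (default 0.75).
#' @return Character vector of kept genome_ids.
#' @export
qc_filter <- function(metrics, completeness_min = 95, contamination_max = 5,
                      marker_min = 0.75) {
  need <- c("completeness_pct", "contamination_pct", "marker_fraction")
  vals <- metrics[, need, drop = FALSE]
  unevaluable <- !stats::complete.cases(vals)
  if (any(unevaluable)) {
    warning("excluding ", sum(unevaluable),
            " genome(s) with missing QC metrics: ",
            paste(utils::head(metrics$genome_id[unevaluable], 5L),
                  collapse = ", "))
  }
  keep <- !unevaluable &
    metrics$completeness_pct > completeness_min &
    metrics$contamination_pct < contamination_max &
    metrics$marker_fraction >= marker_min
  metrics$genome_id[keep]
}

#' Dereplicate genomes at an ANI threshold, retaining all type strains
#'
#' Type strains are retained unconditionally. Within each genus, non-type
#' strains are clustered by single linkage at ANI >= `threshold`; each
#' cluster keeps one representative, the lexicographically smallest
#' genome_id (a deterministic stand-in for dRep's scoring, which the source
#' workflow does not specify).
#'
#' @param ani Symmetric ANI percentage matrix (dimnames = genome ids).
#' @param meta Metadata data.frame with `genome_id`, `genus`,
#'   `is_type_strain`.
#' @param threshold ANI percentage at/above which two genomes are redundant.
#' @param tol Symmetry tolerance for the matrix check.
#' @return Sorted character vector of retained genome_ids.
#' @export
dereplicate <- function(ani, meta, threshold = 99.5, tol = 1e-6) {
  validate_ani_matrix(ani, tol = tol)
  ids <- rownames(ani)
  if (!all(ids %in% meta$genome_id)) {
    stop("genomes missing from metadata: ",
         paste(utils::head(setdiff(ids, meta$genome_id), 5L), collapse = ", "))
  }
  meta <- meta[match(ids, meta$genome_id), , drop = FALSE]
  kept <- ids[meta$is_type_strain]
  nontype <- ids[!meta$is_type_strain]
  for (g in unique(meta$genus[!meta$is_type_strain])) {
    members <- sort(nontype[meta$genus[match(nontype, ids)] == g])
    if (length(members) == 1L) {
      kept <- c(kept, members)
      next
    }
    # single-linkage components over the >= threshold graph (union-find)
    parent <- seq_along(members)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    sub <- ani[members, members, drop = FALSE]
    for (i in seq_len(length(members) - 1L)) {
      for (j in seq(i + 1L, length(members))) {
        if (sub[i, j] >= threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
    comp <- vapply(seq_along(members), find, integer(1))
    reps <- vapply(split(members, comp), min, character(1))
    kept <- c(kept, unname(reps))
  }
  sort(unique(kept))
}
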
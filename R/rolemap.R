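#' Built-in role/evidence map for sialic acid catabolism genes
#'
#' Maps each functional role to the evidence patterns (source + accession)
#' and per-source thresholds that a domain hit must pass. The Pfam/CDD
#' accessions for the enzyme roles are a documented reconstruction from
#' widely used families (the original supplementary mapping is not public);
#' the four anchors that are published are kept verbatim: SBP_bac_5
#' (PF00496) marks ABC transporters of the ST3 family, SBP_bac_1 (PF01547)
#' the ST7 family, BPD_transp_1 (PF00528) a truncated/partial ABC system,
#' and COG functional categories K and X mark regulators and mobilome genes.
#' Edit or replace the map via [read_role_map()] to use a different mapping;
#' the rule engine is independent of the accession choices.
#'
#' Thresholds are strict: a hit passes iff `evalue < evalue_max`,
#' `identity_pct > identity_min` and `coverage_pct > coverage_min` (NA
#' threshold = not required; a required threshold with a missing hit value
#' fails). Defaults mirror the annotation workflow: Pfam and CDD at
#' e < 1e-10; protein BLAST against reference NanE-II/RokA/NanOx sequences
#' at e < 1e-5 with identity > 30%; IS elements at e < 1e-5; COG assignments
#' at e < 1e-5 with coverage > 50% and identity > 50%.
#'
#' An accession of `"*"` matches any accession from that source (used for IS
#' hits, where any insertion-sequence family counts).
#'
#' @return data.frame with columns `role`, `source`, `accession`,
#'   `evalue_max`, `identity_min`, `coverage_min`.
#' @export
default_role_map <- function() {
  p <- function(role, source, accession, evalue_max, identity_min = NA_real_,
                coverage_min = NA_real_) {
    data.frame(role = role, source = source, accession = accession,
               evalue_max = evalue_max, identity_min = identity_min,
               coverage_min = coverage_min, stringsAsFactors = FALSE)
  }
  pfam_e <- 1e-10
  cdd_e <- 1e-10
  blast_e <- 1e-5
  rbind(
    # core catabolic enzymes: Pfam hit AND CDD confirmation both required
    p("nanA", "pfam", "PF00701", pfam_e),          # NAL/DHDPS lyase family
    p("nanA", "cdd",  "cd00954", cdd_e),           # NAL aldolase domain
    p("nanK", "pfam", "PF00480", pfam_e),          # ROK kinase family
    p("nanK", "cdd",  "PRK09434", cdd_e),          # ManNAc kinase model
    p("nanE", "pfam", "PF04131", pfam_e),          # ManNAc-6P epimerase
    p("nanE", "cdd",  "PRK09435", cdd_e),          # NanE model
    # accessory enzymes (Pfam only)
    p("nagA", "pfam", "PF01979", pfam_e),          # amidohydrolase (NagA)
    p("nagB", "pfam", "PF01182", pfam_e),          # GlcN6P deaminase (NagB)
    p("sialidase", "pfam", "PF13088", pfam_e),     # BNR repeat sialidase
    p("sialidase", "pfam", "PF02012", pfam_e),     # BNR repeat
    # alternative-pathway genes: reference-protein BLAST hits
    p("nanE_II", "blastp", "NanE-II_ref", blast_e, identity_min = 30),
    p("rokA",    "blastp", "RokA_ref",    blast_e, identity_min = 30),
    p("nanOx",   "blastp", "NanOx_ref",   blast_e, identity_min = 30),
    # IT-sialidase segment evidence (segment-HMM hit table)
    p("it_sialidase_segment", "itseg", "RgNanH_seg", pfam_e),
    # transporters (Pfam substrate-binding / permease families)
    p("transporter_ABC_ST3", "pfam", "PF00496", pfam_e),  # SBP_bac_5
    p("transporter_ABC_ST7", "pfam", "PF01547", pfam_e),  # SBP_bac_1
    p("transporter_ABC_partial", "pfam", "PF00528", pfam_e), # BPD_transp_1
    p("transporter_MFS", "pfam", "PF07690", pfam_e),      # MFS_1
    p("transporter_SSS", "pfam", "PF00474", pfam_e),      # SSF symporter
    # regulators: COG category K, plus the specific ids seen in nan clusters
    p("regulator", "cog", "COG2186", blast_e, 50, 50),    # fadR
    p("regulator", "cog", "COG1349", blast_e, 50, 50),    # glpR
    p("regulator", "cog", "COG1481", blast_e, 50, 50),    # whiA
    p("regulator", "cog", "COG2207", blast_e, 50, 50),    # acrR
    p("regulator", "cog", "K", blast_e, 50, 50),
    # mobile elements
    p("IS", "isfinder", "*", blast_e),
    p("mobilome", "cog", "X", blast_e, 50, 50)
  )
}

#' Roles whose assignment requires two-source (Pfam + CDD) confirmation
#' @export
CORE_ROLES <- c("nanA", "nanK", "nanE")

#' Read / write a role map config file
#'
#' The config is a flat commented TSV (`#` lines ignored) with the columns
#' of [default_role_map()]; empty threshold fields mean "not required".
#'
#' @param path Config file path.
#' @return data.frame role map.
#' @export
read_role_map <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  required <- c("role", "source", "accession", "evalue_max")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("role map is missing columns: ", paste(missing, collapse = ", "))
  }
  if (is.null(df$identity_min)) df$identity_min <- NA_real_
  if (is.null(df$coverage_min)) df$coverage_min <- NA_real_
  validate_role_map(df)
  df
}

#' @rdname read_role_map
#' @param rolemap Role map data.frame to write.
#' @export
write_role_map <- function(rolemap, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# nanclust role/evidence map.",
    "# One row per (role, source, accession) evidence pattern; thresholds are",
    "# strict (< for evalue_max, > for identity_min/coverage_min; empty = not",
    "# required). Accession '*' matches any accession from that source.",
    "# Enzyme-role Pfam/CDD accessions are reconstructions and may be edited."
  ), con)
  utils::write.table(rolemap, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

KNOWN_SOURCES <- c("pfam", "cdd", "blastp", "itseg", "isfinder", "cog")

validate_role_map <- function(rolemap) {
  bad <- setdiff(unique(rolemap$source), KNOWN_SOURCES)
  if (length(bad) > 0L) {
    stop("role map uses unknown source label(s): ", paste(bad, collapse = ", "))
  }
  if (any(rolemap$evalue_max < 0, na.rm = TRUE)) {
    stop("negative evalue_max in role map")
  }
  if (any(is.na(rolemap$evalue_max))) stop("evalue_max required for every pattern")
  invisible(rolemap)
}
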
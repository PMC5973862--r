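#' Call APOE epsilon diplotypes from rs429358 and rs7412 genotypes
#'
#' The three common APOE alleles are haplotypes of rs429358:C>T and
#' rs7412:C>T: epsilon4 carries the rs429358 minor (T) allele, epsilon2
#' the rs7412 minor (T) allele, epsilon3 neither. Under the assumption
#' that the T-T haplotype (the vanishingly rare epsilon1) is absent —
#' consistent with D' = -1 between the two SNPs in every dataset we
#' model — the unphased genotype pair determines the diplotype:
#' (0,0) E3E3, (1,0) E3E4, (2,0) E4E4, (0,1) E2E3, (0,2) E2E2,
#' (1,1) E2E4. Combinations requiring a T-T haplotype ((2,1), (1,2),
#' (2,2)) and any missing input return `"UNKNOWN"`.
#'
#' @param g429358 copies of the rs429358 minor (T) allele, in
#'   `{0, 1, 2, NA}`; vectorised.
#' @param g7412 copies of the rs7412 minor (T) allele, same coding.
#' @return character vector of diplotype calls among
#'   `E2E2, E2E3, E2E4, E3E3, E3E4, E4E4, UNKNOWN`.
#' @export
call_apoe_diplotype <- function(g429358, g7412) {
  stopifnot(length(g429358) == length(g7412))
  chk <- c(g429358, g7412)
  if (any(!is.na(chk) & !(chk %in% 0:2)))
    stop("genotype inputs must be in {0, 1, 2, NA}")
  # lookup over the 3x3 grid (row = g429358, col = g7412)
  grid <- matrix(c("E3E3", "E2E3", "E2E2",
                   "E3E4", "E2E4", "UNKNOWN",
                   "E4E4", "UNKNOWN", "UNKNOWN"),
                 nrow = 3, byrow = TRUE)
  out <- rep("UNKNOWN", length(g429358))
  ok <- !is.na(g429358) & !is.na(g7412)
  out[ok] <- grid[cbind(g429358[ok] + 1L, g7412[ok] + 1L)]
  out
}

#' Assign APOE analysis strata
#'
#' Maps diplotypes to the three-stratum scheme used for stratified
#' association: epsilon2 carriers (E2E2, E2E3), epsilon4 carriers (E3E4,
#' E4E4), and E3E3 homozygotes. E2E4 individuals carry both alleles and
#' are always excluded; UNKNOWN diplotypes are unassigned.
#'
#' @param diplotype character vector of diplotype calls from
#'   [call_apoe_diplotype()].
#' @return character vector among `E2_CARRIER, E4_CARRIER, E3E3,
#'   EXCLUDED_E2E4, UNASSIGNED`.
#' @export
assign_strata <- function(diplotype) {
  map <- c(E2E2 = "E2_CARRIER", E2E3 = "E2_CARRIER",
           E3E4 = "E4_CARRIER", E4E4 = "E4_CARRIER",
           E3E3 = "E3E3", E2E4 = "EXCLUDED_E2E4",
           UNKNOWN = "UNASSIGNED")
  bad <- setdiff(unique(diplotype), names(map))
  if (length(bad)) stop("invalid diplotype value(s): ",
                        paste(bad, collapse = ", "))
  unname(map[diplotype])
}

#' Carrier flags per diplotype
#'
#' `e4_carrier` marks any diplotype carrying an epsilon4 allele (E3E4,
#' E4E4 and E2E4), as used for case-control stratification by epsilon4
#' presence; `e2_carrier` likewise marks E2E2, E2E3 and E2E4 (presence
#' or absence of the epsilon2 allele, as in the epsilon2 marker scan).
#' Note the three-stratum scheme of [assign_strata()] instead excludes
#' E2E4 entirely. UNKNOWN yields `NA` flags.
#'
#' @param diplotype character vector of diplotype calls.
#' @return data.frame with logical columns `e2_carrier`, `e4_carrier`.
#' @export
apoe_carrier_flags <- function(diplotype) {
  known <- diplotype != "UNKNOWN"
  e2 <- ifelse(known, diplotype %in% c("E2E2", "E2E3", "E2E4"), NA)
  e4 <- ifelse(known, diplotype %in% c("E3E4", "E4E4", "E2E4"), NA)
  data.frame(e2_carrier = e2, e4_carrier = e4)
}

#' APOE calls for every sample of a dataset
#'
#' @param dataset a [genotype_dataset()] containing the two APOE SNPs.
#' @param rs429358,rs7412 marker ids of the two APOE SNPs (defaults
#'   `"rs429358"`, `"rs7412"`).
#' @return data.frame with `sample_id`, `diplotype`, `stratum`,
#'   `e2_carrier`, `e4_carrier`.
#' @export
apoe_calls <- function(dataset, rs429358 = "rs429358", rs7412 = "rs7412") {
  g4 <- dataset$calls[, marker_index(dataset, rs429358)]
  g2 <- dataset$calls[, marker_index(dataset, rs7412)]
  d <- call_apoe_diplotype(g4, g2)
  flags <- apoe_carrier_flags(d)
  data.frame(sample_id = dataset$samples$sample_id, diplotype = d,
             stratum = assign_strata(d), e2_carrier = flags$e2_carrier,
             e4_carrier = flags$e4_carrier, stringsAsFactors = FALSE)
}
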
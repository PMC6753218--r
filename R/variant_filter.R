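## Filtering and classification of annotated variant records.
##
## A variant table is a data frame with (at least) the columns
##   sample, gene, variant, inheritance_model (AD/AR/XL),
##   pop_frequency (fraction, NA = never observed), ref_depth, alt_depth,
##   inheritance_obs (observed segregation), acmg_criteria (comma-separated
##   codes), acmg_classification (asserted label, optional).

#' Population-frequency filter for dominant and recessive genes
#'
#' Keeps candidate pathogenic variants according to the gene's inheritance
#' model: for autosomal dominant genes only variants never observed in the
#' population database (frequency zero or absent) are retained; for
#' autosomal recessive genes variants below 0.01% are retained. X-linked
#' genes follow the dominant (zero-frequency) rule. Records without an
#' inheritance model are dropped with a warning.
#'
#' @param variants Variant data frame (see file header for columns).
#' @param ar_max Frequency ceiling for recessive genes (default `1e-4`,
#'   i.e. 0.01%, strict `<`).
#' @return The retained rows of `variants`.
#' @export
population_frequency_filter <- function(variants, ar_max = 1e-4) {
  if (nrow(variants) == 0L) return(variants)
  model <- as.character(variants$inheritance_model)
  known <- model %in% c("AD", "AR", "XL")
  if (any(!known)) {
    warning(sum(!known), " record(s) without a valid inheritance model; skipped")
  }
  freq <- variants$pop_frequency
  freq[is.na(freq)] <- 0      # absent from the database = novel
  keep <- known & ifelse(model == "AR", freq < ar_max, freq == 0)
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect low-allele-fraction (mosaic) candidate variants
#'
#' Deep panel coverage makes sub-heterozygous variants detectable: a record
#' is a mosaic candidate when its variant allele fraction lies in the
#' window \[0.05, 0.25\] (both ends included) and its variant-supporting
#' read count is strictly above 30. Records with zero total depth are
#' skipped with a warning.
#'
#' @param variants Variant data frame with `ref_depth` and `alt_depth`.
#' @param vaf_window Inclusive VAF window (default `c(0.05, 0.25)`).
#' @param min_alt_exclusive Allele-count threshold; candidates need
#'   `alt_depth` strictly greater (default 30).
#' @return The candidate rows with a `vaf` column appended.
#' @export
detect_mosaic_candidates <- function(variants, vaf_window = c(0.05, 0.25),
                                     min_alt_exclusive = 30) {
  if (nrow(variants) == 0L) {
    variants$vaf <- numeric(0)
    return(variants)
  }
  total <- variants$ref_depth + variants$alt_depth
  no_depth <- is.na(total) | total == 0
  if (any(no_depth)) {
    warning(sum(no_depth), " record(s) with zero total depth; skipped")
  }
  vaf <- ifelse(no_depth, NA_real_, variants$alt_depth / total)
  keep <- !no_depth &
    vaf >= vaf_window[1] & vaf <= vaf_window[2] &
    variants$alt_depth > min_alt_exclusive
  out <- variants[keep, , drop = FALSE]
  out$vaf <- vaf[keep]
  rownames(out) <- NULL
  out
}

acmg_pathogenic_codes <- c(
  "PVS1",
  paste0("PS", 1:4),
  paste0("PM", 1:6),
  paste0("PP", 1:5)
)
acmg_benign_codes <- c("BA1", paste0("BS", 1:4), paste0("BP", 1:7))

parse_acmg_codes <- function(evidence) {
  if (length(evidence) == 1L && is.character(evidence) && grepl(",", evidence)) {
    evidence <- strsplit(evidence, ",")[[1L]]
  }
  evidence <- trimws(as.character(evidence))
  evidence <- evidence[nzchar(evidence)]
  upgraded <- grepl("\\+$", evidence)
  base <- sub("\\+$", "", evidence)
  if (anyDuplicated(base)) stop_config("duplicate ACMG evidence codes")
  ok <- base %in% c(acmg_pathogenic_codes, acmg_benign_codes)
  if (any(!ok)) stop_config("unknown ACMG code(s): ", paste(base[!ok], collapse = ", "))
  data.frame(code = base, upgraded = upgraded, stringsAsFactors = FALSE)
}

#' Combine ACMG evidence codes into a classification
#'
#' Applies the published ACMG/AMP combining rules to a set of evidence
#' codes (PVS1, PS1-PS4, PM1-PM6, PP1-PP5, plus the benign-side BA1,
#' BS1-BS4, BP1-BP7). A trailing `+` on a code (e.g. `"PM6+"`) marks a
#' strength upgrade asserted by the analyst; by default such codes count
#' at their base strength, and with `modifier_upgrade = TRUE` they count
#' one tier higher (PP to PM, PM to PS, PS to PVS-equivalent).
#'
#' Pathogenic: PVS1 with (>=1 PS | >=2 PM | 1 PM + 1 PP | >=2 PP);
#' or >=2 PS; or 1 PS with (>=3 PM | 2 PM + >=2 PP | 1 PM + >=4 PP).
#' Likely Pathogenic: PVS1 + 1 PM; 1 PS + 1-2 PM; 1 PS + >=2 PP;
#' >=3 PM; 2 PM + >=2 PP; 1 PM + >=4 PP.
#' Benign: BA1 or >=2 BS. Likely Benign: 1 BS + 1 BP or >=2 BP.
#' Contradictory (both pathogenic-side and benign-side met) or
#' insufficient evidence gives VUS.
#'
#' @param evidence Character vector of codes, or one comma-separated string.
#' @param modifier_upgrade Count `+`-flagged codes one strength tier higher.
#' @return One of `"Pathogenic"`, `"Likely Pathogenic"`, `"VUS"`,
#'   `"Likely Benign"`, `"Benign"`.
#' @export
combine_acmg_evidence <- function(evidence, modifier_upgrade = FALSE) {
  codes <- parse_acmg_codes(evidence)
  tier <- substr(codes$code, 1L, 3L)
  tier[codes$code == "PVS1"] <- "PVS"
  tier[codes$code == "BA1"] <- "BA"
  tier <- substr(tier, 1L, 2L)
  tier[codes$code == "PVS1"] <- "PVS"
  if (modifier_upgrade) {
    up_from <- tier          # upgrade from the original tier, one step only
    tier[codes$upgraded & up_from == "PP"] <- "PM"
    tier[codes$upgraded & up_from == "PM"] <- "PS"
    tier[codes$upgraded & up_from == "PS"] <- "PVS"
  }
  pvs <- sum(tier == "PVS")
  ps <- sum(tier == "PS")
  pm <- sum(tier == "PM")
  pp <- sum(tier == "PP")
  ba <- sum(tier == "BA")
  bs <- sum(tier == "BS")
  bp <- sum(tier == "BP")

  pathogenic <-
    (pvs >= 1 && (ps >= 1 || pm >= 2 || (pm == 1 && pp >= 1) || pp >= 2)) ||
    ps >= 2 ||
    (ps == 1 && (pm >= 3 || (pm == 2 && pp >= 2) || (pm == 1 && pp >= 4)))
  likely_pathogenic <-
    (pvs >= 1 && pm == 1) ||
    (ps == 1 && pm >= 1 && pm <= 2) ||
    (ps == 1 && pp >= 2) ||
    pm >= 3 ||
    (pm == 2 && pp >= 2) ||
    (pm == 1 && pp >= 4)
  benign <- ba >= 1 || bs >= 2
  likely_benign <- (bs == 1 && bp >= 1) || bp >= 2

  path_side <- pathogenic || likely_pathogenic
  benign_side <- benign || likely_benign
  if (path_side && benign_side) return("VUS")
  if (pathogenic) return("Pathogenic")
  if (likely_pathogenic) return("Likely Pathogenic")
  if (benign) return("Benign")
  if (likely_benign) return("Likely Benign")
  "VUS"
}

#' Classify a variant table and flag discrepancies
#'
#' Applies [combine_acmg_evidence()] to each record's `acmg_criteria`
#' column and, when an asserted `acmg_classification` column is present,
#' compares the recomputed label against it. Disagreements are flagged,
#' never silently overwritten: both labels are kept.
#'
#' @param variants Data frame with an `acmg_criteria` column
#'   (comma-separated codes) and optionally `acmg_classification`.
#' @param modifier_upgrade Passed to [combine_acmg_evidence()].
#' @return `variants` with `classification` (recomputed) and, when an
#'   asserted label exists, logical `classification_discrepant` columns.
#' @export
classify_variants <- function(variants, modifier_upgrade = FALSE) {
  variants$classification <- vapply(
    variants$acmg_criteria, combine_acmg_evidence, character(1),
    modifier_upgrade = modifier_upgrade, USE.NAMES = FALSE
  )
  if ("acmg_classification" %in% names(variants)) {
    variants$classification_discrepant <-
      variants$classification != variants$acmg_classification
  }
  variants
}

inheritance_obs_levels <- c(
  "de novo",
  "from symptomatic parent",
  "from asymptomatic parent",
  "from mosaic carrier parent",
  "not evaluated"
)

normalize_inheritance_obs <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("not evaluated", length(x))
  out[grepl("de *novo", x)] <- "de novo"
  out[grepl("mosaic", x)] <- "from mosaic carrier parent"
  out[grepl("asymptomatic", x) & !grepl("mosaic", x)] <- "from asymptomatic parent"
  out[grepl("(^|[^a])symptomatic", x) & !grepl("asymptomatic|mosaic", x)] <-
    "from symptomatic parent"
  out
}

#' Tabulate observed inheritance of classified variants
#'
#' Counts records per observed-segregation category: de novo, inherited
#' from a symptomatic parent, inherited from an asymptomatic parent,
#' inherited from a parent carrying the variant in mosaic state, or not
#' evaluated. Free-text labels such as "From asymptomatic father" are
#' normalized to these categories.
#'
#' @param variants Data frame with an `inheritance_obs` column.
#' @return Named integer vector over all five categories (zeros included).
#' @export
tabulate_inheritance <- function(variants) {
  obs <- normalize_inheritance_obs(variants$inheritance_obs)
  tab <- table(factor(obs, levels = inheritance_obs_levels))
  setNames(as.integer(tab), inheritance_obs_levels)
}
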
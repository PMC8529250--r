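consequence_levels <- c("stop_gained", "frameshift", "splice_acceptor",
                        "splice_donor", "missense", "inframe_indel",
                        "synonymous", "intron", "UTR", "splice_region", "other")
trunc_levels <- c("high", "low", "not_applicable")
sift_levels <- c("deleterious", "tolerated", "absent")
polyphen_levels <- c("probably_damaging", "possibly_damaging", "benign", "absent")
clinvar_levels <- c("pathogenic", "likely_pathogenic", "VUS", "conflicting",
                    "likely_benign", "benign", "absent")
inheritance_levels <- c("AD", "AR", "XL", "other")
sex_levels <- c("male", "female", "unknown")

#' Default normalization map for ClinVar significance strings
#'
#' Maps common raw ClinVar clinical-significance spellings onto the
#' controlled vocabulary used by the annotation model. Combined calls
#' such as `"Pathogenic/Likely_pathogenic"` normalize to the weaker
#' member (`likely_pathogenic`), which still qualifies as known
#' pathogenic downstream. The map can be extended or overridden from a
#' YAML file via [read_annotations()].
#'
#' @return named character vector: raw string -> controlled value
#' @export
default_clinvar_map <- function() {
  m <- c("Pathogenic" = "pathogenic",
    "pathogenic" = "pathogenic",
    "Likely_pathogenic" = "likely_pathogenic",
    "likely_pathogenic" = "likely_pathogenic",
    "Pathogenic/Likely_pathogenic" = "likely_pathogenic",
    "Uncertain_significance" = "VUS",
    "VUS" = "VUS",
    "Conflicting_interpretations_of_pathogenicity" = "conflicting",
    "conflicting" = "conflicting",
    "Likely_benign" = "likely_benign",
    "likely_benign" = "likely_benign",
    "Benign" = "benign",
    "benign" = "benign",
    "Benign/Likely_benign" = "likely_benign",
    "absent" = "absent",
    "." = "absent")
  m
}

check_enum <- function(x, levels, col, path) {
  bad <- which(!is.na(x) & !(x %in% levels))
  if (length(bad)) {
    stop(sprintf("%s: invalid value '%s' in column '%s' at data line %d",
                 path, x[bad[1]], col, bad[1]))
  }
  x
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("cannot read table: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(path, ": missing required column(s): ", paste(miss, collapse = ", "))
  }
  df
}

#' Read the annotation snapshot table
#'
#' The annotation table carries the external knowledge consumed per
#' variant: gene symbol, functional consequence, truncation confidence
#' (high/low for protein-truncating calls), SIFT and PolyPhen-2
#' predictions, dbSNP rsid (empty = novel), presence in a second cohort,
#' ClinVar clinical significance, worldwide maximum allele frequency, and
#' reference-population allele counts in column pairs named
#' `ref_<pop>_ac` / `ref_<pop>_an`.
#'
#' @param tsv_path path to the annotation TSV
#' @param clinvar_map named character vector normalizing raw ClinVar
#'   strings, or a YAML file path holding such a map; defaults to
#'   [default_clinvar_map()]
#' @return data.frame of validated annotation records; unknown enum
#'   values are a hard error with the offending line
#' @export
read_annotations <- function(tsv_path, clinvar_map = default_clinvar_map()) {
  if (is.character(clinvar_map) && length(clinvar_map) == 1 &&
      file.exists(clinvar_map)) {
    clinvar_map <- unlist(yaml::read_yaml(clinvar_map))
  }
  req <- c("variant_key", "gene", "consequence", "truncation_confidence",
           "sift", "polyphen", "rsid", "in_second_cohort", "clinvar_class",
           "max_af")
  df <- read_tsv_checked(tsv_path, req)
  raw <- ifelse(is.na(df$clinvar_class), "absent", df$clinvar_class)
  mapped <- ifelse(raw %in% names(clinvar_map), unname(clinvar_map[raw]), raw)
  df$clinvar_class <- check_enum(mapped, clinvar_levels, "clinvar_class", tsv_path)
  df$consequence <- check_enum(df$consequence, consequence_levels,
                               "consequence", tsv_path)
  df$truncation_confidence <- check_enum(
    ifelse(is.na(df$truncation_confidence), "not_applicable",
           df$truncation_confidence),
    trunc_levels, "truncation_confidence", tsv_path)
  df$sift <- check_enum(ifelse(is.na(df$sift), "absent", df$sift),
                        sift_levels, "sift", tsv_path)
  df$polyphen <- check_enum(ifelse(is.na(df$polyphen), "absent", df$polyphen),
                            polyphen_levels, "polyphen", tsv_path)
  df$in_second_cohort <- as.logical(df$in_second_cohort)
  if (anyNA(df$in_second_cohort)) {
    stop(tsv_path, ": in_second_cohort must be TRUE/FALSE")
  }
  if (any(!is.na(df$max_af) & (df$max_af < 0 | df$max_af > 1))) {
    stop(tsv_path, ": max_af outside [0, 1]")
  }
  ac_cols <- grep("^ref_.+_ac$", names(df), value = TRUE)
  for (ac_col in ac_cols) {
    an_col <- sub("_ac$", "_an", ac_col)
    if (!an_col %in% names(df)) stop(tsv_path, ": ", ac_col, " without ", an_col)
    bad <- which(!is.na(df[[ac_col]]) &
                   (df[[ac_col]] < 0 | df[[ac_col]] > df[[an_col]]))
    if (length(bad)) {
      stop(sprintf("%s: ac > an or negative in %s at data line %d",
                   tsv_path, ac_col, bad[1]))
    }
  }
  df
}

#' Read the sample phenotype table
#'
#' Columns: `sample_id` (unique), `sex`, `age`, optional `qt_ms`
#' (QT/QTc interval, ms), `ldl_c` (mmol/l), `tg` (mmol/l), and
#' `clinical_flags` (comma-separated condition codes, may be empty).
#'
#' @param tsv_path path to the sample TSV
#' @return validated data.frame; `clinical_flags` is a list column of
#'   character vectors
#' @export
read_samples <- function(tsv_path) {
  df <- read_tsv_checked(tsv_path, c("sample_id", "sex", "age"))
  if (anyDuplicated(df$sample_id)) stop(tsv_path, ": duplicate sample_id")
  df$sex <- check_enum(ifelse(is.na(df$sex), "unknown", df$sex),
                       sex_levels, "sex", tsv_path)
  for (col in intersect(c("age", "qt_ms", "ldl_c", "tg"), names(df))) {
    if (any(!is.na(df[[col]]) & df[[col]] < 0)) {
      stop(tsv_path, ": negative values in ", col)
    }
  }
  flags <- if ("clinical_flags" %in% names(df)) df$clinical_flags else NA
  df$clinical_flags <- lapply(flags, function(s) {
    if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, ",", fixed = TRUE)[[1]]
  })
  df
}

#' Read the gene metadata table
#'
#' Columns: `gene` (unique symbol), `inheritance`
#' (`AD`/`AR`/`XL`/`other`), `is_acmg59` (logical membership in the
#' secondary-findings gene list).
#'
#' @param tsv_path path to the gene TSV
#' @return validated data.frame
#' @export
read_genes <- function(tsv_path) {
  df <- read_tsv_checked(tsv_path, c("gene", "inheritance", "is_acmg59"))
  if (anyDuplicated(df$gene)) stop(tsv_path, ": duplicate gene symbol")
  df$inheritance <- check_enum(
    ifelse(is.na(df$inheritance), "other", df$inheritance),
    inheritance_levels, "inheritance", tsv_path)
  df$is_acmg59 <- as.logical(df$is_acmg59)
  if (anyNA(df$is_acmg59)) stop(tsv_path, ": is_acmg59 must be TRUE/FALSE")
  df
}

#' Write a data.frame as TSV
#'
#' List columns (e.g. carrier lists, clinical flags) are flattened to
#' comma-separated strings, matching the dialect of the readers.
#'
#' @param df a data.frame
#' @param path output path
#' @return invisibly, the path
#' @export
write_tsv <- function(df, path) {
  flat <- df
  for (col in names(flat)) {
    if (is.list(flat[[col]])) {
      flat[[col]] <- vapply(flat[[col]], paste, "", collapse = ",")
    }
  }
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
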